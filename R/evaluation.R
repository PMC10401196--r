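#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Probability that a random case outscores a random control, with ties
#' counted half: computed from the rank sum of case scores.
#'
#' @param scores numeric predicted scores.
#' @param labels 0/1 outcomes (both classes required).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop_fmt("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and outcome;
#' lower is better calibrated.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels 0/1 outcomes.
#' @return mean of (p - y)^2.
#' @export
brier <- function(probs, labels) {
  stopifnot(length(probs) == length(labels), all(labels %in% c(0, 1)))
  if (any(probs < 0 | probs > 1)) stop_fmt("probabilities must lie in [0,1]")
  mean((probs - labels)^2)
}

#' Cross-site evaluation of models on every site
#'
#' Scores every model on every site's held-out partition (test split for
#' development sites; all persons for an external validation site) and
#' tabulates AUC and Brier score per model x site cell, plus each model's
#' mean AUC across sites — the headline comparison statistic. Sites whose
#' evaluation labels are single-class yield undefined AUC cells, which are
#' excluded from the means with a warning.
#'
#' @param models named list of fitted \code{dcn_fit} models.
#' @param sites named list of \code{site_dataset}s.
#' @param use_split \code{"test"} (default) or \code{"all"}.
#' @param weighted use evaluation-set-size weights for the mean AUC instead
#'   of the default unweighted mean.
#' @return an \code{evaluation_matrix}: list of \code{auc}, \code{brier}
#'   (model x site matrices), \code{n}, \code{n_cases} (per site),
#'   \code{mean_auc}, \code{mean_brier} (per model).
#' @export
cross_site_evaluate <- function(models, sites, use_split = c("test", "all"),
                                weighted = FALSE) {
  use_split <- match.arg(use_split)
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  if (is.null(names(sites)))
    names(sites) <- vapply(sites, `[[`, "", "site_id")
  A <- B <- matrix(NA_real_, length(models), length(sites),
                   dimnames = list(names(models), names(sites)))
  n <- n_cases <- stats::setNames(integer(length(sites)), names(sites))
  for (j in seq_along(sites)) {
    part <- site_partition(sites[[j]], use_split)
    n[j] <- length(part$y); n_cases[j] <- sum(part$y)
    single <- length(unique(part$y)) < 2
    if (single)
      warn_fmt("site %s has single-class evaluation labels; AUC undefined",
               names(sites)[j])
    for (i in seq_along(models)) {
      p <- predict(models[[i]], part$x)
      B[i, j] <- brier(p, part$y)
      if (!single) A[i, j] <- auc(p, part$y)
    }
  }
  w <- if (weighted) n else rep(1L, length(sites))
  mean_auc <- apply(A, 1, function(a) {
    ok <- !is.na(a)
    sum(w[ok] * a[ok]) / sum(w[ok])
  })
  mean_brier <- apply(B, 1, function(b) sum(w * b) / sum(w))
  structure(list(auc = A, brier = B, n = n, n_cases = n_cases,
                 mean_auc = mean_auc, mean_brier = mean_brier,
                 use_split = use_split, weighted = weighted),
            class = "evaluation_matrix")
}

#' @export
print.evaluation_matrix <- function(x, ...) {
  cat(sprintf("<evaluation_matrix> (%s split%s)\nAUC:\n", x$use_split,
              if (x$weighted) ", size-weighted means" else ""))
  print(round(cbind(x$auc, mean = x$mean_auc), 4))
  cat("Brier:\n")
  print(round(cbind(x$brier, mean = x$mean_brier), 4))
  invisible(x)
}

#' Class-balanced bootstrapped AUC
#'
#' Repeatedly downsamples controls (without replacement within each
#' replicate) to a fixed control:case ratio, keeping every case, and
#' summarises the replicate AUCs by their mean and percentile 95 percent
#' confidence interval. Probes sensitivity of the AUC to outcome imbalance.
#'
#' @param scores predicted scores.
#' @param labels 0/1 outcomes.
#' @param ratio controls per case r (1, 3, 4 or 9 in the standard protocol).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with \code{ratio}, \code{B}, \code{mean_auc}, \code{ci}
#'   (percentile 2.5/97.5), \code{replicates}.
#' @export
balanced_bootstrap_auc <- function(scores, labels, ratio, B = 1000L, seed = 1L) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  cases <- which(labels == 1); controls <- which(labels == 0)
  if (length(cases) < 1) stop_fmt("need at least one case")
  k <- ratio * length(cases)
  if (length(controls) < k)
    stop_fmt("need at least %d controls for ratio 1:%d (have %d)",
             k, ratio, length(controls))
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    keep <- c(cases, sample(controls, k))
    auc(scores[keep], labels[keep])
  }, 0))
  list(ratio = ratio, B = B, mean_auc = mean(reps),
       ci = unname(quantile(reps, c(0.025, 0.975))), replicates = reps)
}

#' Monte-Carlo Shapley attributions
#'
#' Model-agnostic permutation estimator: for each instance and each of
#' \code{n_permutations} random feature orderings, features are revealed one
#' by one (unrevealed features are imputed from a background row sampled per
#' permutation) and the marginal change in model output is credited to the
#' revealed feature. Attributions satisfy efficiency in expectation: they
#' sum to \code{f(x) - mean f(background)}.
#'
#' @param model a \code{dcn_fit}, or any function mapping an n x d numeric
#'   matrix to a numeric vector of outputs.
#' @param instances matrix of instances to explain (columns = features).
#' @param background matrix of background rows for imputation.
#' @param n_permutations Monte-Carlo permutations per instance (default 64).
#' @param seed integer seed.
#' @return an \code{attribution_report}: list with \code{values} (instance x
#'   feature matrix), \code{baseline} (mean background prediction),
#'   \code{ranking} (features by mean |value|).
#' @export
shapley_attributions <- function(model, instances, background,
                                 n_permutations = 64L, seed = 1L) {
  if (n_permutations < 1) stop_fmt("n_permutations must be >= 1")
  if (is.null(dim(background)) || nrow(background) < 1)
    stop_fmt("background must be a nonempty matrix")
  f <- if (is.function(model)) model else function(X) {
    colnames(X) <- colnames(instances) %||% model$feature_ids
    unname(predict(model, X))
  }
  instances <- as.matrix(instances)
  background <- as.matrix(background)
  d <- ncol(instances)
  stopifnot(ncol(background) == d)
  phi <- matrix(0, nrow(instances), d,
                dimnames = list(rownames(instances), colnames(instances)))
  with_seed(seed, {
    for (i in seq_len(nrow(instances))) {
      x <- instances[i, ]
      acc <- numeric(d)
      for (p in seq_len(n_permutations)) {
        bg <- background[sample.int(nrow(background), 1), ]
        perm <- sample.int(d)
        ## path of inputs: start at background, reveal features in perm order
        path <- matrix(rep(bg, d + 1), nrow = d + 1, byrow = TRUE)
        for (j in seq_len(d))
          path[(j + 1):(d + 1), perm[j]] <- x[perm[j]]
        out <- f(path)
        acc[perm] <- acc[perm] + diff(out)
      }
      phi[i, ] <- acc / n_permutations
    }
  })
  baseline <- mean(f(background))
  ranking <- colMeans(abs(phi))
  ord <- order(-ranking, colnames(phi) %||% as.character(seq_len(d)))
  structure(list(values = phi, baseline = baseline,
                 ranking = data.frame(
                   feature = (colnames(phi) %||% as.character(seq_len(d)))[ord],
                   mean_abs_value = unname(ranking[ord]),
                   stringsAsFactors = FALSE)),
            class = "attribution_report")
}

#' @export
print.attribution_report <- function(x, ...) {
  cat(sprintf("<attribution_report>: %d instance(s) x %d feature(s), baseline %.4f\n",
              nrow(x$values), ncol(x$values), x$baseline))
  print(head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' Export per-instance attributions as a long CSV
#'
#' Columns \code{instance,feature,value}, consumable by standard beeswarm
#' plotters.
#'
#' @param report an \code{attribution_report}.
#' @param path file path.
#' @export
write_attributions <- function(report, path) {
  v <- report$values
  df <- data.frame(instance = rep(rownames(v) %||% seq_len(nrow(v)), ncol(v)),
                   feature = rep(colnames(v) %||% seq_len(ncol(v)), each = nrow(v)),
                   value = as.numeric(v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
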