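#' Per-client gradient-boosting gain importances
#'
#' Fits a gradient-boosted tree ensemble (binary logistic objective) on one
#' client's training split and returns each covariate's total gain — the
#' summed training-loss reduction over all splits on that covariate.
#' Covariates never used by the ensemble (including all-zero columns) get
#' importance 0. Hyperparameters stay at conventional boosting defaults
#' (100 trees, learning rate 0.1); runs single-threaded for determinism.
#'
#' @param client a \code{site_dataset} (its train split is used), or a list
#'   with elements \code{x} (sparse/dense matrix) and \code{y} (0/1 labels).
#' @param nrounds number of boosting rounds (default 100).
#' @param seed integer seed.
#' @return named nonnegative numeric vector over all of the client's
#'   covariates (an importance vector), with attribute \code{"present"} —
#'   the covariates with any nonzero training value.
#' @export
local_importance <- function(client, nrounds = 100L, seed = 1L) {
  part <- if (inherits(client, "site_dataset")) site_partition(client, "train")
          else client
  x <- part$x; y <- part$y
  if (length(unique(y)) < 2)
    stop_fmt("training labels are single-class; cannot fit a boosting model")
  covs <- colnames(x)
  dm <- xgboost::xgb.DMatrix(as(x, "CsparseMatrix"), label = y, nthread = 1)
  bst <- with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.1, max_depth = 6,
                  nthread = 1, seed = as.integer(seed)),
    data = dm, nrounds = nrounds, verbose = 0))
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = bst))
  splits <- tr[tr$Feature != "Leaf", , drop = FALSE]
  gain_col <- if ("Gain" %in% names(splits)) "Gain" else "Quality"
  gain <- stats::setNames(rep(0, length(covs)), covs)
  if (nrow(splits)) {
    agg <- tapply(splits[[gain_col]], splits$Feature, sum)
    gain[names(agg)] <- as.numeric(agg)
  }
  present <- covs[Matrix::colSums(abs(x)) > 0]
  structure(gain, present = present)
}

#' Aggregate per-client importances into one federated ranking
#'
#' Keeps only covariates present (some nonzero training value) in every
#' client's data, scores each by the unweighted mean of the per-client gain
#' importances (a covariate missing from one client's model contributes 0),
#' and returns the ranking sorted by descending score with lexicographic
#' covariate-id tie-breaks.
#'
#' @param vectors list of importance vectors from
#'   \code{\link{local_importance}}.
#' @param presence optional list of character vectors of covariates present
#'   per client; defaults to each vector's \code{"present"} attribute.
#' @return data.frame with columns \code{covariate_id}, \code{score}, sorted.
#' @export
aggregate_importance <- function(vectors, presence = NULL) {
  stopifnot(length(vectors) >= 1)
  presence <- presence %||% lapply(vectors, attr, "present")
  stopifnot(length(presence) == length(vectors))
  shared <- Reduce(intersect, presence)
  if (!length(shared)) stop_fmt("no covariate is present in every client")
  shared <- sort(shared)
  per_client <- matrix(unlist(lapply(vectors, function(v) {
    out <- rep(0, length(shared))
    hit <- shared %in% names(v)
    out[hit] <- v[shared[hit]]
    out
  })), nrow = length(shared))
  score <- rowMeans(per_client)
  ord <- order(-score, shared)
  data.frame(covariate_id = shared[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

#' Early-stopped search over the number of selected features
#'
#' Walks an increasing grid of candidate feature counts N, asking the
#' supplied trainer for per-client tuning AUCs at each N and recording their
#' weighted mean. The search stops early once three consecutive grid steps
#' each improve the running best weighted AUC by no more than 2 percent
#' (relative). The chosen N is then the smallest evaluated N whose weighted
#' AUC reaches 98 percent of the best observed — the cheapest model within
#' striking distance of the optimum.
#'
#' @param grid strictly increasing integer vector of candidate N (starts at
#'   25 by default: \code{c(25, 50, 100, 200, 400, 800, 1600)}).
#' @param fl_trainer function(N) returning the per-client tuning AUCs of a
#'   model trained on the top-N features.
#' @param weights per-client weights for the mean AUC (tuning-set sizes);
#'   default equal.
#' @param improve_tol relative improvement threshold (default 0.02).
#' @param patience consecutive low-improvement steps before stopping
#'   (default 3).
#' @param keep_frac fraction of the best AUC the chosen N must attain
#'   (default 0.98).
#' @return a \code{selection_trace}: list with \code{grid} (evaluated N),
#'   \code{auc} (weighted mean per evaluated N), \code{stop_index},
#'   \code{chosen_n}, \code{chosen_auc}.
#' @export
search_top_n <- function(grid = c(25L, 50L, 100L, 200L, 400L, 800L, 1600L),
                         fl_trainer, weights = NULL,
                         improve_tol = 0.02, patience = 3L, keep_frac = 0.98) {
  grid <- as.integer(grid)
  if (length(grid) < 1 || any(diff(grid) <= 0))
    stop_fmt("grid must be strictly increasing")
  aucs <- numeric(0)
  best <- -Inf
  low_streak <- 0L
  stop_index <- length(grid)
  for (i in seq_along(grid)) {
    client_aucs <- fl_trainer(grid[i])
    w <- if (is.null(weights)) rep(1, length(client_aucs))
         else rep_len(weights, length(client_aucs))
    aucs[i] <- sum(w * client_aucs) / sum(w)
    if (i > 1) {
      rel_gain <- (aucs[i] - best) / best
      low_streak <- if (rel_gain <= improve_tol) low_streak + 1L else 0L
    }
    best <- max(best, aucs[i])
    if (low_streak >= patience) { stop_index <- i; break }
  }
  evaluated <- grid[seq_along(aucs)]
  ok <- which(aucs >= keep_frac * max(aucs))
  chosen <- ok[1]
  structure(list(grid = evaluated, auc = aucs, stop_index = length(aucs),
                 chosen_n = evaluated[chosen], chosen_auc = aucs[chosen]),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  print(data.frame(N = x$grid, weighted_auc = x$auc), row.names = FALSE)
  cat(sprintf("stopped after N = %d; chosen N = %d (AUC %.4f)\n",
              x$grid[x$stop_index], x$chosen_n, x$chosen_auc))
  invisible(x)
}

#' Federated feature selection on a federation dataset
#'
#' Convenience wiring of the full selection stage: per-client boosting
#' importances, cross-client aggregation with the all-present filter, and
#' (optionally) the early-stopped top-N search using federated training as
#' the evaluator.
#'
#' @param data a \code{federation_dataset} (development clients are used).
#' @param grid candidate N values; \code{NULL} skips the search and returns
#'   the ranking only.
#' @param dcn_builder function(d) returning a \code{\link{dcn_config}} for
#'   input dimension d.
#' @param fed_config \code{\link{federation_config}} for the trainer.
#' @param seed seed for the per-client boosting fits.
#' @return list with \code{ranking} (data.frame) and \code{trace}
#'   (\code{selection_trace} or NULL).
#' @export
select_features <- function(data, grid = c(25L, 50L, 100L, 200L, 400L, 800L, 1600L),
                            dcn_builder = dcn_config,
                            fed_config = federation_config(), seed = 1L) {
  clients <- data$clients
  seeds <- derive_seeds(seed, length(clients))
  vectors <- lapply(seq_along(clients), function(k)
    local_importance(clients[[k]], seed = seeds[k]))
  ranking <- aggregate_importance(vectors)
  trace <- NULL
  if (!is.null(grid)) {
    grid <- grid[grid <= nrow(ranking)]
    n_tune <- vapply(clients, function(cl) sum(cl$split == "tune"), 0)
    trainer <- function(N) {
      feats <- ranking$covariate_id[seq_len(N)]
      fit <- train_federated(clients, feature_ids = feats,
                             dcn_cfg = dcn_builder(length(feats)),
                             config = fed_config)
      vapply(clients, function(cl) {
        tu <- site_partition(cl, "tune")
        auc(predict(fit, tu$x), tu$y)
      }, 0)
    }
    trace <- search_top_n(grid, trainer, weights = n_tune)
  }
  list(ranking = ranking, trace = trace)
}
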