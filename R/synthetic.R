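#' Configuration for the synthetic multi-site cohort generator
#'
#' The generator emulates the statistical structure of multi-hospital
#' observational feature data: thousands of mostly-rare binary covariates,
#' a shared sparse logistic risk model driving a rare binary outcome, and
#' controllable inter-site covariate shift (one designated "shifted" site
#' with amplified heterogeneity, emulating a non-IID client).
#'
#' Defaults reproduce the study conditions: five sites with the development
#' cohort sizes 3917, 5799, 4873, 3042 plus a 4541-person external site;
#' per-site outcome prevalences matching the reported outcome counts
#' (30, 58, 146, 45 and 39 outcomes respectively, overall about 1.6
#' percent); 2,000 covariates at desk scale (up to 20,000 supported) with
#' marginal frequencies drawn log-uniformly on (1e-4, 0.5); 30 informative
#' covariates with alternating-sign log-odds between 0.5 and 1.5.
#'
#' @param n_sites total number of sites (last one is external when
#'   \code{external = TRUE}).
#' @param persons_per_site integer vector of cohort sizes, length \code{n_sites}.
#' @param n_covariates number of binary covariates K.
#' @param n_informative number of covariates with nonzero effect m.
#' @param effect_sizes log-odds per informative covariate (length m).
#' @param target_prevalence per-site outcome prevalence targets (recycled).
#' @param tau heterogeneity: SD of per-site normal shifts applied to each
#'   covariate's logit prevalence. 0 means IID sites.
#' @param shifted_site index of the designated non-IID site; it receives
#'   \code{3 * tau} heterogeneity.
#' @param external logical; reserve the last site for external validation.
#' @param prevalence_range range of the log-uniform law for covariate
#'   marginal frequencies.
#' @param informative_min_prevalence informative covariates are drawn only
#'   among covariates whose global marginal frequency is at least this
#'   (default 0.01): established clinical predictors are non-rare codes, and
#'   a risk effect carried by a one-in-ten-thousand covariate would be
#'   unidentifiable at realistic cohort sizes.
#' @param seed integer seed; the whole federation is deterministic given it.
#' @return a \code{generator_config} list.
#' @export
generator_config <- function(n_sites = 5,
                             persons_per_site = c(3917, 5799, 4873, 3042, 4541),
                             n_covariates = 2000,
                             n_informative = 30,
                             effect_sizes = (-1)^(seq_len(n_informative)) *
                               seq(0.5, 1.5, length.out = n_informative),
                             target_prevalence = c(30/3917, 58/5799, 146/4873,
                                                   45/3042, 39/4541),
                             tau = 0.5,
                             shifted_site = 4,
                             external = TRUE,
                             prevalence_range = c(1e-4, 0.5),
                             informative_min_prevalence = 0.01,
                             seed = 1L) {
  cfg <- list(n_sites = as.integer(n_sites),
              persons_per_site = as.integer(rep_len(persons_per_site, n_sites)),
              n_covariates = as.integer(n_covariates),
              n_informative = as.integer(n_informative),
              effect_sizes = as.numeric(effect_sizes),
              target_prevalence = rep_len(as.numeric(target_prevalence), n_sites),
              tau = as.numeric(tau),
              shifted_site = as.integer(shifted_site),
              external = isTRUE(external),
              prevalence_range = as.numeric(prevalence_range),
              informative_min_prevalence = as.numeric(informative_min_prevalence),
              seed = as.integer(seed))
  if (cfg$n_informative > cfg$n_covariates)
    stop_fmt("n_informative (%d) exceeds n_covariates (%d)",
             cfg$n_informative, cfg$n_covariates)
  if (length(cfg$effect_sizes) != cfg$n_informative)
    stop_fmt("effect_sizes must have length n_informative")
  if (cfg$tau < 0) stop_fmt("tau must be nonnegative")
  if (any(cfg$target_prevalence <= 0 | cfg$target_prevalence >= 1))
    stop_fmt("target prevalences must lie in (0,1)")
  if (any(cfg$prevalence_range <= 0) || any(cfg$prevalence_range >= 1) ||
      diff(cfg$prevalence_range) <= 0)
    stop_fmt("prevalence_range must be increasing within (0,1)")
  structure(cfg, class = "generator_config")
}

#' Calibrate a site intercept to hit a target outcome prevalence
#'
#' Monte-Carlo root finding: given the informative covariates' marginal
#' frequencies and effects, draws a probe population, and solves for the
#' intercept \code{alpha} such that the mean of
#' \code{sigmoid(alpha + x' beta)} equals the target prevalence.
#'
#' @param target_prevalence target outcome rate in (0,1).
#' @param beta log-odds of the informative covariates.
#' @param covariate_prevalences marginal Bernoulli frequencies of the
#'   informative covariates (same length as \code{beta}).
#' @param n_probe probe population size (default 1e5).
#' @param seed seed for the probe draw.
#' @return intercept \code{alpha} (log-odds scale).
#' @export
calibrate_intercept <- function(target_prevalence, beta, covariate_prevalences,
                                n_probe = 1e5, seed = 1L) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop_fmt("target prevalence must lie in (0,1)")
  m <- length(beta)
  stopifnot(length(covariate_prevalences) == m)
  eta0 <- if (m == 0) numeric(n_probe) else with_seed(seed, {
    x <- matrix(rbinom(n_probe * m, 1, rep(covariate_prevalences, each = n_probe)),
                nrow = n_probe)
    drop(x %*% beta)
  })
  f <- function(a) mean(sigmoid(a + eta0)) - target_prevalence
  lo <- -20; hi <- 5
  if (f(lo) > 0 || f(hi) < 0)
    stop_fmt("no intercept in [-20, 5] attains prevalence %.4g", target_prevalence)
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

## Draw one site's sparse covariate matrix: independent Bernoulli columns at
## site-specific prevalences. Returns a dgCMatrix with person/covariate names.
draw_site_matrix <- function(n, p_site, persons, covariates) {
  counts <- rbinom(length(p_site), n, p_site)
  jj <- rep.int(seq_along(p_site), counts)
  ii <- unlist(lapply(seq_along(p_site), function(j)
    if (counts[j] > 0) sample.int(n, counts[j]) else integer()), use.names = FALSE)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n, length(p_site)),
                            dimnames = list(persons, covariates))
  as(m, "CsparseMatrix")
}

#' Generate a synthetic federation of clinical sites
#'
#' For each covariate j a global marginal frequency p_j is drawn from the
#' log-uniform law; site s perturbs it on the logit scale by
#' \code{tau_s * z_sj} with standard-normal z (the designated shifted site
#' uses \code{3 tau}). Persons' covariates are independent Bernoulli draws at
#' the site frequencies; the outcome follows a shared sparse logistic model
#' \code{y ~ Bernoulli(sigmoid(alpha_s + x' beta))} whose site intercepts are
#' calibrated by \code{\link{calibrate_intercept}} to the per-site target
#' prevalences. The ground-truth model is returned for recovery testing.
#'
#' @param config a \code{\link{generator_config}}.
#' @return list with \code{data} (a \code{federation_dataset}) and
#'   \code{true_model} (informative covariate ids, effects, per-site
#'   intercepts and covariate frequency matrix).
#' @export
generate_federation <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 3L + 2L * cfg$n_sites)
  K <- cfg$n_covariates
  covariates <- sprintf("c%05d", seq_len(K))
  p_global <- with_seed(seeds[1], {
    exp(runif(K, log(cfg$prevalence_range[1]), log(cfg$prevalence_range[2])))
  })
  eligible <- which(p_global >= cfg$informative_min_prevalence)
  if (length(eligible) < cfg$n_informative)
    stop_fmt("only %d covariates reach informative_min_prevalence %g; need %d",
             length(eligible), cfg$informative_min_prevalence, cfg$n_informative)
  informative <- with_seed(seeds[2],
                           sort(eligible[sample.int(length(eligible),
                                                    cfg$n_informative)]))
  beta <- cfg$effect_sizes

  tau_site <- rep(cfg$tau, cfg$n_sites)
  if (cfg$shifted_site >= 1 && cfg$shifted_site <= cfg$n_sites)
    tau_site[cfg$shifted_site] <- 3 * cfg$tau
  z <- with_seed(seeds[3], matrix(rnorm(cfg$n_sites * K), nrow = cfg$n_sites))
  p_site <- sigmoid(sweep(z * tau_site, 2, logit(p_global), `+`))

  sites <- vector("list", cfg$n_sites)
  alpha <- numeric(cfg$n_sites)
  for (s in seq_len(cfg$n_sites)) {
    n <- cfg$persons_per_site[s]
    persons <- sprintf("s%d_p%06d", s, seq_len(n))
    ps <- p_site[s, ]
    alpha[s] <- calibrate_intercept(cfg$target_prevalence[s], beta,
                                    ps[informative], seed = seeds[3L + s])
    sd_gen <- seeds[3L + cfg$n_sites + s]
    site_id <- sprintf("site%d", s)
    sites[[s]] <- with_seed(sd_gen, {
      x <- draw_site_matrix(n, ps, persons, covariates)
      eta <- alpha[s] + as.numeric(x[, informative, drop = FALSE] %*% beta)
      y <- stats::setNames(rbinom(n, 1, sigmoid(eta)), persons)
      split_seed <- sample.int(.Machine$integer.max - 1L, 1)
      split_site(x, y, seed = split_seed, site_id = site_id)
    })
  }
  external <- NULL
  if (cfg$external) {
    external <- sites[[cfg$n_sites]]
    sites <- sites[-cfg$n_sites]
  }
  true_model <- list(informative = covariates[informative], beta = beta,
                     alpha = stats::setNames(alpha, sprintf("site%d", seq_len(cfg$n_sites))),
                     p_site = p_site, covariates = covariates)
  list(data = federation_dataset(sites, external), true_model = true_model)
}

#' Build a cohort whose cross-tabs match a printed baseline table exactly
#'
#' Constructs a two-group dataset (outcome cases vs controls) in which, for
#' every named binary characteristic, exactly the specified numbers of cases
#' and controls carry the characteristic. Used to feed the baseline-table
#' stage with published counts.
#'
#' @param spec data.frame with columns \code{characteristic},
#'   \code{cases_with}, \code{controls_with} (counts of carriers per group).
#' @param n_cases,n_controls group totals.
#' @param site_id site identifier.
#' @param seed seed for the train/tune/test split of the returned dataset.
#' @return a \code{site_dataset} whose per-characteristic cross-tabs equal
#'   \code{spec} exactly.
#' @export
generate_table_one_cohort <- function(spec, n_cases, n_controls,
                                      site_id = "pooled", seed = 1L) {
  stopifnot(is.data.frame(spec),
            all(c("characteristic", "cases_with", "controls_with") %in% names(spec)))
  if (anyDuplicated(spec$characteristic)) stop_fmt("duplicate characteristic names")
  if (any(spec$cases_with < 0) || any(spec$controls_with < 0))
    stop_fmt("counts must be nonnegative")
  if (any(spec$cases_with > n_cases))
    stop_fmt("characteristic '%s' has more carriers than cases",
             spec$characteristic[which(spec$cases_with > n_cases)[1]])
  if (any(spec$controls_with > n_controls))
    stop_fmt("characteristic '%s' has more carriers than controls",
             spec$characteristic[which(spec$controls_with > n_controls)[1]])
  n <- n_cases + n_controls
  persons <- sprintf("p%06d", seq_len(n))
  labels <- stats::setNames(c(rep(1L, n_cases), rep(0L, n_controls)), persons)
  ii <- integer(); jj <- integer()
  for (k in seq_len(nrow(spec))) {
    ci <- seq_len(spec$cases_with[k])                      # first cases carry it
    oi <- n_cases + seq_len(spec$controls_with[k])         # first controls carry it
    idx <- c(if (spec$cases_with[k] > 0) ci, if (spec$controls_with[k] > 0) oi)
    ii <- c(ii, idx)
    jj <- c(jj, rep.int(k, length(idx)))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, nrow(spec)),
                            dimnames = list(persons, spec$characteristic))
  split_site(as(m, "CsparseMatrix"), labels, seed = seed, site_id = site_id)
}
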