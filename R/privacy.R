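#' DP-SGD privacy specification
#'
#' Hyperparameters of differentially private SGD: per-example clip norm C,
#' noise multiplier sigma (noise SD is sigma * C on the summed clipped
#' gradient), Poisson-style sampling rate q = batch_size / n, number of
#' steps T, and the delta of the (epsilon, delta) guarantee.
#'
#' @param noise_multiplier sigma >= 0 (default 2.5).
#' @param clip_norm C > 0 (default 0.5).
#' @param sample_rate q in (0, 1].
#' @param steps T >= 0.
#' @param delta failure probability (default 1e-5).
#' @return a \code{privacy_spec}.
#' @export
privacy_spec <- function(noise_multiplier = 2.5, clip_norm = 0.5,
                         sample_rate = 0.01, steps = 0L, delta = 1e-5) {
  if (noise_multiplier < 0) stop_fmt("noise multiplier must be >= 0")
  if (clip_norm <= 0) stop_fmt("clip norm must be > 0")
  if (sample_rate <= 0 || sample_rate > 1) stop_fmt("sample rate must lie in (0,1]")
  if (steps < 0) stop_fmt("steps must be >= 0")
  if (delta <= 0 || delta >= 1) stop_fmt("delta must lie in (0,1)")
  structure(list(noise_multiplier = noise_multiplier, clip_norm = clip_norm,
                 sample_rate = sample_rate, steps = as.integer(steps),
                 delta = delta),
            class = "privacy_spec")
}

#' Clip a gradient vector to L2 norm C
#'
#' Returns \code{g * min(1, C / ||g||)}; the zero vector is returned
#' unchanged.
#'
#' @param g numeric gradient vector.
#' @param C positive clip norm.
#' @return vector with L2 norm at most C.
#' @export
clip_gradient <- function(g, C) {
  if (any(!is.finite(g))) stop_fmt("gradient must be finite")
  nrm <- sqrt(sum(g^2))
  if (nrm <= C || nrm == 0) g else g * (C / nrm)
}

#' One DP-SGD update
#'
#' Per-example gradients of the summed binary cross-entropy on the batch are
#' clipped to L2 norm C, summed, perturbed with isotropic Gaussian noise of
#' SD sigma * C, normalised by the batch size, and applied with the given
#' learning rate. With \code{sigma = 0} and \code{C = Inf} this is exactly a
#' plain minibatch SGD step (and consumes no random numbers). Uses the
#' session RNG; seed externally for determinism.
#'
#' @param params \code{dcn_params}.
#' @param config \code{\link{dcn_config}}.
#' @param X batch feature matrix (n x d), \code{y} 0/1 labels.
#' @param y labels.
#' @param C clip norm (may be \code{Inf}).
#' @param sigma noise multiplier (>= 0).
#' @param lr learning rate.
#' @return updated \code{dcn_params}.
#' @export
dp_sgd_step <- function(params, config, X, y, C, sigma, lr) {
  if (sigma < 0) stop_fmt("noise multiplier must be >= 0")
  n <- nrow(X)
  if (n == 0) stop_fmt("empty batch")
  pieces <- dcn_per_example_grads(params, config, X, y)
  norms <- grad_norms(pieces)
  cvec <- if (is.infinite(C)) rep(1, n) else pmin(1, C / pmax(norms, 1e-300))
  stopifnot(all(norms * cvec <= C * (1 + 1e-12) | norms == 0))
  g <- scaled_grad_sum(pieces, cvec, config)
  for (nm in names(g)) {
    noise <- if (sigma > 0) rnorm(length(g[[nm]]), 0, sigma * C) else 0
    params[[nm]] <- params[[nm]] - lr * (g[[nm]] + noise) / n
  }
  params
}

#' Renyi differential privacy of one subsampled Gaussian step
#'
#' For \code{q = 1} (no subsampling) the Gaussian mechanism gives
#' \code{alpha / (2 sigma^2)} exactly. For \code{q < 1} and integer order
#' alpha the standard binomial-expansion upper bound is evaluated in
#' log-space:
#' \deqn{\frac{1}{\alpha-1}\log \sum_{k=0}^{\alpha} \binom{\alpha}{k}
#'  (1-q)^{\alpha-k} q^k e^{k(k-1)/(2\sigma^2)}.}
#'
#' @param q sampling rate in (0, 1].
#' @param sigma noise multiplier > 0.
#' @param alpha Renyi order > 1 (integer when q < 1).
#' @return RDP value at order alpha for one step.
#' @export
rdp_of_step <- function(q, sigma, alpha) {
  if (sigma <= 0) stop_fmt("sigma must be > 0")
  if (alpha <= 1) stop_fmt("Renyi order must be > 1")
  if (q <= 0 || q > 1) stop_fmt("q must lie in (0,1]")
  if (q == 1) return(alpha / (2 * sigma^2))
  if (alpha != round(alpha))
    stop_fmt("subsampled bound implemented for integer orders")
  k <- 0:alpha
  terms <- lchoose(alpha, k) + (alpha - k) * log1p(-q) + k * log(q) +
    k * (k - 1) / (2 * sigma^2)
  log_sum_exp(terms) / (alpha - 1)
}

#' Compose DP-SGD steps and convert to an (epsilon, delta) guarantee
#'
#' Total RDP at each order is T times the per-step RDP; conversion takes
#' \code{epsilon = min_alpha [ T * RDP(alpha) + log(1/delta) / (alpha - 1) ]}
#' over the candidate orders.
#'
#' @param spec a \code{\link{privacy_spec}}.
#' @param orders candidate Renyi orders (default integers 2..64).
#' @return a \code{privacy_budget}: list with \code{epsilon}, \code{delta},
#'   \code{alpha_star} (the minimising order).
#' @export
compose_and_convert <- function(spec, orders = 2:64) {
  stopifnot(inherits(spec, "privacy_spec"))
  if (!length(orders)) stop_fmt("orders must be nonempty")
  if (any(orders <= 1)) stop_fmt("orders must exceed 1")
  if (spec$steps == 0)
    return(structure(list(epsilon = 0, delta = spec$delta, alpha_star = NA_real_),
                     class = "privacy_budget"))
  if (spec$noise_multiplier <= 0)
    stop_fmt("cannot account with zero noise multiplier")
  eps <- vapply(orders, function(a) {
    spec$steps * rdp_of_step(spec$sample_rate, spec$noise_multiplier, a) +
      log(1 / spec$delta) / (a - 1)
  }, 0)
  i <- which.min(eps)
  structure(list(epsilon = eps[i], delta = spec$delta, alpha_star = orders[i]),
            class = "privacy_budget")
}

#' @export
print.privacy_budget <- function(x, ...) {
  cat(sprintf("<privacy_budget>: epsilon = %.4f at delta = %g (alpha* = %s)\n",
              x$epsilon, x$delta, format(x$alpha_star)))
  invisible(x)
}

#' Select DP-SGD hyperparameters on a utility/privacy grid
#'
#' Evaluates mean tuning AUC for every (sigma, C) grid cell, keeps the cells
#' whose AUC is at least 95 percent of the best observed, and among those
#' returns the cell with the smallest composed privacy budget (epsilon does
#' not depend on C, so this is the largest feasible sigma); remaining ties
#' are broken by higher AUC, then larger C.
#'
#' @param sigmas,clips candidate noise multipliers and clip norms
#'   (default both \code{c(0.5, 1, 2.5, 5)}).
#' @param evaluator function(sigma, C) returning mean tuning AUC.
#' @param sample_rate,steps,delta accountant inputs for the epsilon of each
#'   sigma.
#' @param utility_floor fraction of the best AUC that must be preserved
#'   (default 0.95).
#' @return list with \code{sigma}, \code{clip_norm}, \code{epsilon},
#'   \code{auc} and the full evaluation \code{grid} data.frame.
#' @export
select_dp_hyperparameters <- function(evaluator,
                                      sigmas = c(0.5, 1, 2.5, 5),
                                      clips = c(0.5, 1, 2.5, 5),
                                      sample_rate = 0.01, steps = 100L,
                                      delta = 1e-5, utility_floor = 0.95) {
  grid <- expand.grid(sigma = sigmas, clip_norm = clips,
                      KEEP.OUT.ATTRS = FALSE)
  grid$auc <- mapply(evaluator, grid$sigma, grid$clip_norm)
  eps_of_sigma <- vapply(sigmas, function(s)
    compose_and_convert(privacy_spec(s, 1, sample_rate, steps, delta))$epsilon, 0)
  grid$epsilon <- eps_of_sigma[match(grid$sigma, sigmas)]
  feasible <- grid$auc >= utility_floor * max(grid$auc)
  if (!any(feasible)) stop_fmt("empty feasible set")   # cannot happen: best cell qualifies
  cand <- grid[feasible, ]
  cand <- cand[order(cand$epsilon, -cand$sigma, -cand$auc, -cand$clip_norm), ]
  list(sigma = cand$sigma[1], clip_norm = cand$clip_norm[1],
       epsilon = cand$epsilon[1], auc = cand$auc[1], grid = grid)
}
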