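#' Deep & Cross Network configuration
#'
#' The risk model combines an explicit feature-crossing tower (each layer
#' computes \code{x0 * (x_l' w) + b + x_l}, so degree-(l+1) multiplicative
#' interactions of the inputs are formed with only 2d parameters per layer)
#' with a conventional deep ReLU tower; the two towers are concatenated and
#' mapped to a probability through a single affine + sigmoid head. Selected
#' covariates enter as a dense numeric vector; no categorical embedding is
#' used (post-selection features are binary indicators).
#'
#' @param input_dim number of input features d.
#' @param n_cross number of cross layers (default 2).
#' @param deep_widths integer vector of deep-tower widths (default c(64, 32);
#'   may be empty for a cross-only model).
#' @param init_sd standard deviation of the Gaussian weight initialisation.
#' @return a \code{dcn_config}.
#' @export
dcn_config <- function(input_dim, n_cross = 2L, deep_widths = c(64L, 32L),
                       init_sd = 0.1) {
  input_dim <- as.integer(input_dim)
  n_cross <- as.integer(n_cross)
  deep_widths <- as.integer(deep_widths)
  if (input_dim < 1L) stop_fmt("input_dim must be >= 1")
  if (n_cross < 0L) stop_fmt("n_cross must be >= 0")
  if (length(deep_widths) && any(deep_widths < 1L))
    stop_fmt("deep widths must be positive")
  structure(list(input_dim = input_dim, n_cross = n_cross,
                 deep_widths = deep_widths, init_sd = init_sd),
            class = "dcn_config")
}

## Shapes of every named parameter array, in canonical (aggregation) order.
dcn_shapes <- function(config) {
  d <- config$input_dim
  shapes <- list()
  for (l in seq_len(config$n_cross)) {
    shapes[[sprintf("cross_w%d", l)]] <- d
    shapes[[sprintf("cross_b%d", l)]] <- d
  }
  inp <- d
  for (k in seq_along(config$deep_widths)) {
    w <- config$deep_widths[k]
    shapes[[sprintf("deep_W%d", k)]] <- c(w, inp)
    shapes[[sprintf("deep_c%d", k)]] <- w
    inp <- w
  }
  z_dim <- d + if (length(config$deep_widths)) tail(config$deep_widths, 1) else 0L
  shapes[["head_a"]] <- z_dim
  shapes[["head_a0"]] <- 1L
  shapes
}

#' Initialise DCN parameters
#'
#' Weights are drawn from N(0, init_sd^2); biases start at zero.
#'
#' @param config a \code{\link{dcn_config}}.
#' @param seed integer seed.
#' @return named list of parameter arrays (\code{dcn_params}).
#' @export
dcn_init <- function(config, seed = 1L) {
  shapes <- dcn_shapes(config)
  with_seed(seed, {
    params <- lapply(names(shapes), function(nm) {
      sh <- shapes[[nm]]
      is_bias <- grepl("^(cross_b|deep_c|head_a0)", nm)
      v <- if (is_bias) rep(0, prod(sh)) else rnorm(prod(sh), 0, config$init_sd)
      if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
    })
    names(params) <- names(shapes)
    structure(params, class = "dcn_params")
  })
}

#' Flatten / unflatten DCN parameters
#'
#' The flat vector form is what federated aggregation and the privacy
#' mechanism operate on; \code{dcn_unflatten(dcn_flatten(p)) == p}.
#'
#' @param params \code{dcn_params}.
#' @return numeric vector (\code{dcn_flatten}) / \code{dcn_params}
#'   (\code{dcn_unflatten}).
#' @export
dcn_flatten <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

#' @rdname dcn_flatten
#' @param v flat numeric vector.
#' @param config the \code{\link{dcn_config}} defining shapes.
#' @export
dcn_unflatten <- function(v, config) {
  shapes <- dcn_shapes(config)
  total <- sum(vapply(shapes, prod, 0))
  if (length(v) != total)
    stop_fmt("flat vector length %d does not match config (%d)", length(v), total)
  params <- list()
  off <- 0L
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    n <- prod(sh)
    x <- v[off + seq_len(n)]
    params[[nm]] <- if (length(sh) == 2L) matrix(x, sh[1], sh[2]) else x
    off <- off + n
  }
  structure(params, class = "dcn_params")
}

#' One cross layer
#'
#' Computes \code{x0 * (x_l' w) + b + x_l}: the input vector scaled by the
#' scalar projection of the current state, plus bias, plus a residual
#' connection.
#'
#' @param x0 original input vector (length d).
#' @param x_l current state vector (length d).
#' @param w,b layer weight and bias vectors (length d).
#' @return length-d vector.
#' @export
cross_layer <- function(x0, x_l, w, b) {
  d <- length(x0)
  if (length(x_l) != d || length(w) != d || length(b) != d)
    stop_fmt("cross_layer: all vectors must have length %d", d)
  x0 * sum(x_l * w) + b + x_l
}

## Batched forward pass keeping intermediates for backprop.
## X: n x d dense numeric matrix.
dcn_forward_full <- function(params, config, X) {
  n <- nrow(X); d <- config$input_dim
  if (ncol(X) != d) stop_fmt("input has %d columns, config expects %d", ncol(X), d)
  Xl <- X
  cross_states <- list(X)    # states X_0 .. X_Lc
  cross_s <- list()          # s_l = X_{l-1} w_l per layer
  for (l in seq_len(config$n_cross)) {
    w <- params[[sprintf("cross_w%d", l)]]
    b <- params[[sprintf("cross_b%d", l)]]
    s <- drop(Xl %*% w)
    Xl <- X * s + rep(b, each = n) + Xl
    cross_s[[l]] <- s
    cross_states[[l + 1L]] <- Xl
  }
  H <- X
  deep_states <- list(X)     # H_0 .. H_K (post-activation)
  deep_pre <- list()         # pre-activations A_k
  for (k in seq_along(config$deep_widths)) {
    W <- params[[sprintf("deep_W%d", k)]]
    cvec <- params[[sprintf("deep_c%d", k)]]
    A <- H %*% t(W) + rep(cvec, each = n)
    H <- pmax(A, 0)
    deep_pre[[k]] <- A
    deep_states[[k + 1L]] <- H
  }
  Z <- if (length(config$deep_widths)) cbind(Xl, H) else Xl
  logit <- drop(Z %*% params$head_a) + params$head_a0
  if (any(!is.finite(logit))) stop_fmt("non-finite intermediate in forward pass")
  list(p = sigmoid(logit), logit = logit, Z = Z,
       cross_states = cross_states, cross_s = cross_s,
       deep_states = deep_states, deep_pre = deep_pre)
}

#' DCN forward pass
#'
#' @param params \code{dcn_params}.
#' @param config \code{\link{dcn_config}}.
#' @param x a length-d vector or an n x d matrix.
#' @return predicted probability (vector of length n).
#' @export
dcn_forward <- function(params, config, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  dcn_forward_full(params, config, X)$p
}

#' Binary cross-entropy loss
#'
#' Mean of \code{-[y log p + (1-y) log(1-p)]}; probabilities at exactly 0 or
#' 1 are clamped to 1e-7 away from the boundary (with a warning).
#'
#' @param p predicted probabilities.
#' @param y 0/1 labels.
#' @return mean loss (scalar).
#' @export
bce_loss <- function(p, y) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  if (any(p < 0 | p > 1)) stop_fmt("probabilities must lie in [0,1]")
  eps <- 1e-7
  if (any(p <= 0 | p >= 1)) {
    warn_fmt("probabilities at 0/1 clamped to %.0e", eps)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

## Per-example gradient pieces of summed BCE loss wrt all parameters.
## Dense pieces are n x len matrices (one per-example gradient row each);
## outer pieces represent per-example outer(delta_i, input_i) gradients of
## matrix parameters without materialising n x out x in tensors:
##   squared norm_i  = |delta_i|^2 * |input_i|^2
##   clipped sum     = t(delta * c) %*% input
dcn_per_example_grads <- function(params, config, X, y, fwd = NULL) {
  n <- nrow(X)
  if (is.null(fwd)) fwd <- dcn_forward_full(params, config, X)
  d <- config$input_dim
  dlogit <- fwd$p - y                     # n, gradient wrt logit of per-example BCE
  dense <- list()
  outer_p <- list()
  dense$head_a <- fwd$Z * dlogit          # n x z_dim
  dense$head_a0 <- matrix(dlogit, ncol = 1)
  a <- params$head_a
  nK <- length(config$deep_widths)
  ## deep tower backward
  if (nK > 0) {
    a_deep <- a[d + seq_len(tail(config$deep_widths, 1))]
    delta <- outer(dlogit, a_deep) * (fwd$deep_pre[[nK]] > 0)
    for (k in rev(seq_len(nK))) {
      outer_p[[sprintf("deep_W%d", k)]] <- list(delta = delta,
                                                input = fwd$deep_states[[k]])
      dense[[sprintf("deep_c%d", k)]] <- delta
      if (k > 1) {
        W <- params[[sprintf("deep_W%d", k)]]
        delta <- (delta %*% W) * (fwd$deep_pre[[k - 1]] > 0)
      }
    }
  }
  ## cross tower backward
  if (config$n_cross > 0) {
    a_cross <- a[seq_len(d)]
    G <- matrix(rep(a_cross, each = n), nrow = n) * dlogit   # dL/dX_Lc, n x d
    X0 <- fwd$cross_states[[1]]
    for (l in rev(seq_len(config$n_cross))) {
      Xprev <- fwd$cross_states[[l]]
      tl <- rowSums(X0 * G)                                  # dL/ds_l
      dense[[sprintf("cross_b%d", l)]] <- G
      dense[[sprintf("cross_w%d", l)]] <- Xprev * tl
      w <- params[[sprintf("cross_w%d", l)]]
      G <- G + outer(tl, w)
    }
  }
  list(dense = dense, outer = outer_p, n = n)
}

## Per-example L2 norms of the full per-example gradients.
grad_norms <- function(pieces) {
  sq <- numeric(pieces$n)
  for (M in pieces$dense) sq <- sq + rowSums(M^2)
  for (op in pieces$outer) sq <- sq + rowSums(op$delta^2) * rowSums(op$input^2)
  sqrt(sq)
}

## Sum of per-example gradients scaled by per-example factors cvec.
scaled_grad_sum <- function(pieces, cvec, config) {
  shapes <- dcn_shapes(config)
  out <- list()
  for (nm in names(shapes)) {
    if (!is.null(pieces$dense[[nm]])) {
      g <- colSums(pieces$dense[[nm]] * cvec)
      out[[nm]] <- if (length(shapes[[nm]]) == 2L)
        matrix(g, shapes[[nm]][1], shapes[[nm]][2]) else g
    } else {
      op <- pieces$outer[[nm]]
      out[[nm]] <- t(op$delta * cvec) %*% op$input
    }
  }
  structure(out, class = "dcn_params")
}
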