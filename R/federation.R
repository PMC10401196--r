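#' Federated training configuration
#'
#' Defaults follow the study protocol: 5 federated rounds with 5 local
#' epochs per round (the local-only comparator trains 25 epochs instead);
#' minibatch size 256; SGD as the optimiser underlying DP-SGD. When
#' \code{privacy} is \code{NULL}, training runs without clipping or noise
#' (sigma = 0, C = Inf), i.e. plain SGD.
#'
#' @param rounds number of federated rounds R (default 5).
#' @param local_epochs local epochs per round E (default 5).
#' @param batch_size minibatch size (default 256).
#' @param lr learning rate (default 1e-3).
#' @param privacy \code{\link{privacy_spec}} or \code{NULL}.
#' @param seed integer seed governing all training randomness.
#' @return a \code{federation_config}.
#' @export
federation_config <- function(rounds = 5L, local_epochs = 5L, batch_size = 256L,
                              lr = 1e-3, privacy = NULL, seed = 1L) {
  if (rounds < 1) stop_fmt("rounds must be >= 1")
  if (local_epochs < 0) stop_fmt("local_epochs must be >= 0")
  if (!is.null(privacy)) stopifnot(inherits(privacy, "privacy_spec"))
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 privacy = privacy, seed = as.integer(seed)),
            class = "federation_config")
}

## Dense design matrix for the model's feature set; covariates a site lacks
## enter as zero columns (logged once).
make_design <- function(features, feature_ids) {
  have <- intersect(feature_ids, colnames(features))
  missing <- setdiff(feature_ids, colnames(features))
  X <- matrix(0, nrow(features), length(feature_ids),
              dimnames = list(rownames(features), feature_ids))
  if (length(have))
    X[, have] <- as.matrix(features[, have, drop = FALSE])
  if (length(missing))
    message(sprintf("%d model covariate(s) absent from site data, filled with zeros",
                    length(missing)))
  X
}

## Pooled train-split moments across clients; binary columns pass through
## unscaled (center 0, scale 1), others are standardised.
fit_standardizer <- function(clients, feature_ids) {
  n <- 0; s1 <- 0; s2 <- 0; binary <- rep(TRUE, length(feature_ids))
  for (cl in clients) {
    part <- site_partition(cl, "train")
    X <- make_design(part$x, feature_ids)
    n <- n + nrow(X)
    s1 <- s1 + colSums(X)
    s2 <- s2 + colSums(X^2)
    binary <- binary & apply(X, 2, function(v) all(v %in% c(0, 1)))
  }
  mu <- s1 / n
  sdv <- sqrt(pmax(s2 / n - mu^2, 0))
  center <- ifelse(binary, 0, mu)
  scale <- ifelse(binary | sdv == 0, 1, sdv)
  list(center = stats::setNames(center, feature_ids),
       scale = stats::setNames(scale, feature_ids))
}

apply_standardizer <- function(X, std) {
  if (is.null(std)) return(X)
  sweep(sweep(X, 2, std$center[colnames(X)]), 2, std$scale[colnames(X)], `/`)
}

## Minibatch (DP-)SGD for `epochs` passes over (X, y). Deterministic given
## seed: the per-epoch shuffles and the Gaussian noise share one stream.
## When `snapshot` is a function it is called after each epoch with
## (epoch, params) — used by the local comparator to record per-epoch models.
train_epochs <- function(params, config, X, y, epochs, batch_size, lr,
                         C, sigma, seed, snapshot = NULL) {
  n <- nrow(X)
  with_seed(seed, {
    for (e in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      for (st in starts) {
        idx <- perm[st:min(st + batch_size - 1, n)]
        params <- dp_sgd_step(params, config, X[idx, , drop = FALSE], y[idx],
                              C = C, sigma = sigma, lr = lr)
      }
      if (!is.null(snapshot)) snapshot(e, params)
    }
    params
  })
}

#' One client's local update from the current global weights
#'
#' Runs E epochs of DP-SGD on the client's training split starting from the
#' broadcast global parameters, and evaluates the updated weights' binary
#' cross-entropy on the client's tuning split.
#'
#' @param global \code{dcn_params} broadcast by the server.
#' @param client a \code{site_dataset}.
#' @param feature_ids model covariates (design-matrix columns).
#' @param dcn_cfg \code{\link{dcn_config}}.
#' @param config \code{\link{federation_config}} (supplies epochs, batch
#'   size, lr and privacy parameters).
#' @param seed seed for this client-round.
#' @param std optional standardizer applied to designs.
#' @return list with \code{params}, \code{n_train}, \code{tune_loss}.
#' @export
local_update <- function(global, client, feature_ids, dcn_cfg, config, seed,
                         std = NULL) {
  tr <- site_partition(client, "train")
  if (nrow(tr$x) == 0) stop_fmt("client %s has an empty train split", client$site_id)
  if (length(unique(tr$y)) < 2)
    warn_fmt("client %s has single-class training labels", client$site_id)
  Xtr <- apply_standardizer(make_design(tr$x, feature_ids), std)
  sigma <- if (is.null(config$privacy)) 0 else config$privacy$noise_multiplier
  C <- if (is.null(config$privacy)) Inf else config$privacy$clip_norm
  params <- train_epochs(global, dcn_cfg, Xtr, tr$y, config$local_epochs,
                         config$batch_size, config$lr, C, sigma, seed)
  tu <- site_partition(client, "tune")
  Xtu <- apply_standardizer(make_design(tu$x, feature_ids), std)
  loss <- bce_loss(dcn_forward(params, dcn_cfg, Xtu), tu$y)
  list(params = params, n_train = nrow(Xtr), tune_loss = loss)
}

#' Federated averaging
#'
#' Coordinate-wise sample-size-weighted mean of client parameter sets:
#' \code{sum_k (n_k / sum n) w_k}.
#'
#' @param params_list list of \code{dcn_params} (conformant shapes).
#' @param n numeric vector of client sizes (aggregation weights).
#' @return aggregated \code{dcn_params}.
#' @export
fedavg_aggregate <- function(params_list, n) {
  stopifnot(length(params_list) >= 1, length(n) == length(params_list), all(n > 0))
  ref <- params_list[[1]]
  w <- n / sum(n)
  for (p in params_list[-1]) {
    if (!identical(lapply(p, dim), lapply(ref, dim)) ||
        !identical(lapply(p, length), lapply(ref, length)) ||
        !identical(names(p), names(ref)))
      stop_fmt("parameter shapes do not match across clients")
  }
  out <- ref
  for (nm in names(ref)) {
    acc <- ref[[nm]] * w[1]
    for (k in seq_along(params_list)[-1])
      acc <- acc + params_list[[k]][[nm]] * w[k]
    out[[nm]] <- acc
  }
  out
}

#' Train the federated model
#'
#' Runs R rounds of broadcast, local DP-SGD update, and federated averaging
#' over the development clients. After each aggregation the global model's
#' binary cross-entropy is computed on every client's tuning split and
#' combined as a tune-size-weighted mean; the final model is the round
#' snapshot with the lowest aggregated tuning loss (ties broken toward the
#' earliest round).
#'
#' @param data a \code{federation_dataset} or list of \code{site_dataset}
#'   clients (at least one; the external site, if present, is not used).
#' @param feature_ids model covariates; defaults to all covariates of the
#'   first client.
#' @param dcn_cfg \code{\link{dcn_config}}; defaults to the package defaults
#'   at \code{length(feature_ids)} inputs.
#' @param config \code{\link{federation_config}}.
#' @param standardize standardise non-binary covariates by pooled train
#'   moments (default TRUE; binary covariates always pass through raw).
#' @return a fitted model of class \code{c("fed_dcn", "dcn_fit")} with the
#'   selected round's parameters, the per-round trace, and the per-round
#'   global snapshots.
#' @export
train_federated <- function(data, feature_ids = NULL, dcn_cfg = NULL,
                            config = federation_config(), standardize = TRUE) {
  clients <- if (inherits(data, "federation_dataset")) data$clients else data
  stopifnot(length(clients) >= 1)
  feature_ids <- feature_ids %||% colnames(clients[[1]]$features)
  dcn_cfg <- dcn_cfg %||% dcn_config(length(feature_ids))
  std <- if (standardize) fit_standardizer(clients, feature_ids) else NULL
  seeds <- derive_seeds(config$seed, 1L + config$rounds * length(clients))
  global <- dcn_init(dcn_cfg, seed = seeds[1])
  tune_designs <- lapply(clients, function(cl) {
    tu <- site_partition(cl, "tune")
    list(x = apply_standardizer(make_design(tu$x, feature_ids), std), y = tu$y)
  })
  n_tune <- vapply(tune_designs, function(d) length(d$y), 0)
  rounds <- vector("list", config$rounds)
  trace <- data.frame(round = seq_len(config$rounds), agg_tune_loss = NA_real_)
  for (r in seq_len(config$rounds)) {
    updates <- vector("list", length(clients))
    for (k in seq_along(clients)) {
      sd_rk <- seeds[1L + (r - 1L) * length(clients) + k]
      updates[[k]] <- tryCatch(
        local_update(global, clients[[k]], feature_ids, dcn_cfg, config,
                     seed = sd_rk, std = std),
        error = function(e) stop_fmt("client %s failed in round %d: %s",
                                     clients[[k]]$site_id, r, conditionMessage(e)))
    }
    global <- fedavg_aggregate(lapply(updates, `[[`, "params"),
                               vapply(updates, `[[`, 0, "n_train"))
    client_losses <- vapply(seq_along(clients), function(k)
      bce_loss(dcn_forward(global, dcn_cfg, tune_designs[[k]]$x),
               tune_designs[[k]]$y), 0)
    trace$agg_tune_loss[r] <- sum(n_tune / sum(n_tune) * client_losses)
    rounds[[r]] <- list(round = r, params = global,
                        client_tune_loss = stats::setNames(client_losses,
                                                           names(clients)),
                        local_tune_loss = vapply(updates, `[[`, 0, "tune_loss"))
  }
  best <- which.min(trace$agg_tune_loss)   # earliest minimum
  structure(list(params = rounds[[best]]$params, dcn_config = dcn_cfg,
                 feature_ids = feature_ids, standardizer = std,
                 config = config, trace = trace, rounds = rounds,
                 best_round = best, site_ids = names(clients)),
            class = c("fed_dcn", "dcn_fit"))
}

#' Train a local-only comparator model
#'
#' Trains on a single client's training split for \code{epochs} epochs
#' (default 25, matching the local comparator protocol), records the tuning
#' loss after every epoch, and returns the epoch snapshot with the lowest
#' tuning loss (earliest on ties).
#'
#' @param client a \code{site_dataset}.
#' @inheritParams train_federated
#' @param epochs training epochs (default 25).
#' @return fitted model of class \code{c("local_dcn", "dcn_fit")}.
#' @export
train_local <- function(client, feature_ids = NULL, dcn_cfg = NULL,
                        config = federation_config(), epochs = 25L,
                        standardize = TRUE) {
  stopifnot(inherits(client, "site_dataset"))
  feature_ids <- feature_ids %||% colnames(client$features)
  dcn_cfg <- dcn_cfg %||% dcn_config(length(feature_ids))
  std <- if (standardize) fit_standardizer(list(client), feature_ids) else NULL
  tr <- site_partition(client, "train")
  tu <- site_partition(client, "tune")
  if (nrow(tr$x) == 0 || nrow(tu$x) == 0)
    stop_fmt("client %s needs nonempty train and tune splits", client$site_id)
  if (length(unique(tr$y)) < 2)
    warn_fmt("client %s has single-class training labels", client$site_id)
  Xtr <- apply_standardizer(make_design(tr$x, feature_ids), std)
  Xtu <- apply_standardizer(make_design(tu$x, feature_ids), std)
  sigma <- if (is.null(config$privacy)) 0 else config$privacy$noise_multiplier
  C <- if (is.null(config$privacy)) Inf else config$privacy$clip_norm
  seeds <- derive_seeds(config$seed, 2L)
  init <- dcn_init(dcn_cfg, seed = seeds[1])
  snaps <- vector("list", epochs)
  losses <- numeric(epochs)
  rec <- function(e, p) {
    snaps[[e]] <<- p
    losses[e] <<- bce_loss(dcn_forward(p, dcn_cfg, Xtu), tu$y)
  }
  train_epochs(init, dcn_cfg, Xtr, tr$y, epochs, config$batch_size, config$lr,
               C, sigma, seed = seeds[2], snapshot = rec)
  best <- which.min(losses)
  structure(list(params = snaps[[best]], dcn_config = dcn_cfg,
                 feature_ids = feature_ids, standardizer = std,
                 config = config, trace = data.frame(epoch = seq_len(epochs),
                                                     tune_loss = losses),
                 best_epoch = best, site_ids = client$site_id),
            class = c("local_dcn", "dcn_fit"))
}

#' Predict risk probabilities from a fitted model
#'
#' @param object a \code{dcn_fit} (\code{fed_dcn} or \code{local_dcn}).
#' @param newdata a \code{site_dataset}, a sparse/dense matrix with covariate
#'   column names, or a plain numeric matrix with exactly the model's input
#'   columns.
#' @param split when \code{newdata} is a \code{site_dataset}, which
#'   partition to score (default "test"; "all" scores every person).
#' @param ... unused.
#' @return named vector of predicted probabilities.
#' @export
predict.dcn_fit <- function(object, newdata, split = "test", ...) {
  if (inherits(newdata, "site_dataset")) {
    part <- site_partition(newdata, split)
    newdata <- part$x
  }
  X <- if (!is.null(colnames(newdata)))
    make_design(newdata, object$feature_ids)
  else if (ncol(newdata) == length(object$feature_ids)) {
    colnames(newdata) <- object$feature_ids
    newdata
  } else stop_fmt("newdata must carry covariate column names or match input_dim")
  X <- apply_standardizer(as.matrix(X), object$standardizer)
  p <- dcn_forward(object$params, object$dcn_config, X)
  stats::setNames(p, rownames(X))
}

#' @export
coef.dcn_fit <- function(object, ...) {
  shapes <- dcn_shapes(object$dcn_config)
  nms <- unlist(lapply(names(shapes), function(nm)
    paste0(nm, "[", seq_len(prod(shapes[[nm]])), "]")), use.names = FALSE)
  stats::setNames(dcn_flatten(object$params), nms)
}

#' @export
print.fed_dcn <- function(x, ...) {
  cat(sprintf("<fed_dcn>: federated Deep & Cross Network over %d client(s)\n",
              length(x$site_ids)))
  cat(sprintf("  %d input features, %d cross layer(s), deep widths [%s]\n",
              x$dcn_config$input_dim, x$dcn_config$n_cross,
              paste(x$dcn_config$deep_widths, collapse = ", ")))
  cat(sprintf("  %d round(s) x %d local epoch(s); best round %d (tune loss %.4f)\n",
              x$config$rounds, x$config$local_epochs, x$best_round,
              x$trace$agg_tune_loss[x$best_round]))
  if (!is.null(x$config$privacy))
    cat(sprintf("  DP-SGD: sigma = %g, C = %g\n",
                x$config$privacy$noise_multiplier, x$config$privacy$clip_norm))
  invisible(x)
}

#' @export
print.local_dcn <- function(x, ...) {
  cat(sprintf("<local_dcn>: site '%s', %d input features; best epoch %d (tune loss %.4f)\n",
              x$site_ids, x$dcn_config$input_dim, x$best_epoch,
              x$trace$tune_loss[x$best_epoch]))
  invisible(x)
}

#' @export
summary.dcn_fit <- function(object, ...) {
  cat(if (inherits(object, "fed_dcn")) "Federated" else "Local",
      "Deep & Cross Network risk model\n")
  print(object)
  cat("Training trace:\n")
  print(object$trace, row.names = FALSE)
  invisible(object$trace)
}

#' Plot the training trace of a fitted model
#'
#' Aggregated tuning loss per round (federated) or tuning loss per epoch
#' (local), with the selected snapshot marked.
#'
#' @param x a \code{dcn_fit}.
#' @param ... passed to \code{plot.default}.
#' @export
plot.dcn_fit <- function(x, ...) {
  if (inherits(x, "fed_dcn")) {
    graphics::plot(x$trace$round, x$trace$agg_tune_loss, type = "b",
                   xlab = "federated round", ylab = "aggregated tuning loss", ...)
    graphics::points(x$best_round, x$trace$agg_tune_loss[x$best_round],
                     pch = 19, col = 2)
  } else {
    graphics::plot(x$trace$epoch, x$trace$tune_loss, type = "l",
                   xlab = "epoch", ylab = "tuning loss", ...)
    graphics::points(x$best_epoch, x$trace$tune_loss[x$best_epoch],
                     pch = 19, col = 2)
  }
  invisible(x)
}
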