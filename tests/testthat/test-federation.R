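test_that("federated averaging is the size-weighted mean, matching a brute-force oracle", {
  cfg <- dcn_config(3, n_cross = 1, deep_widths = 4)
  ## hand value: weights n = (1, 3) on "scalar" params 0 and 4 -> 3
  p0 <- dcn_unflatten(rep(0, sum(sapply(fedrisk:::dcn_shapes(cfg), prod))), cfg)
  p4 <- dcn_unflatten(rep(4, length(dcn_flatten(p0))), cfg)
  agg <- fedavg_aggregate(list(p0, p4), n = c(1, 3))
  expect_equal(unique(dcn_flatten(agg)), 3)

  ## fixed point: identical clients aggregate to themselves
  expect_equal(fedavg_aggregate(list(p4, p4, p4), n = c(2, 5, 1)), p4,
               ignore_attr = TRUE)

  ## random sets vs explicit weighted mean; convex-combination bounds
  withr::local_seed(50)
  for (rep in 1:5) {
    ps <- lapply(1:5, function(k) random_params(cfg, seed = 100 * rep + k))
    n <- sample(1:50, 5)
    agg <- dcn_flatten(fedavg_aggregate(ps, n))
    flat <- vapply(ps, dcn_flatten, numeric(length(agg)))
    expect_equal(agg, drop(flat %*% (n / sum(n))), tolerance = 1e-12)
    expect_true(all(agg >= apply(flat, 1, min) - 1e-12))
    expect_true(all(agg <= apply(flat, 1, max) + 1e-12))
  }
  expect_error(fedavg_aggregate(list(p0, random_params(dcn_config(4), 1)),
                                n = c(1, 1)), "shapes")
})

test_that("local updates honour the zero-epoch and zero-lr edge cases", {
  site <- tiny_site(120, 15, seed = 6)
  feats <- colnames(site$features)
  cfg <- dcn_config(length(feats), n_cross = 1, deep_widths = 4)
  g <- dcn_init(cfg, seed = 1)
  u0 <- local_update(g, site, feats, cfg,
                     federation_config(local_epochs = 0, seed = 2), seed = 3)
  expect_equal(u0$params, g, ignore_attr = TRUE)
  ulr0 <- local_update(g, site, feats, cfg,
                       federation_config(local_epochs = 2, lr = 0, seed = 2),
                       seed = 3)
  expect_equal(ulr0$params, g, ignore_attr = TRUE)
  ## loss equals evaluating the untouched global weights on the tune split
  tu <- fedrisk:::site_partition(site, "tune")
  expect_equal(ulr0$tune_loss, bce_loss(dcn_forward(g, cfg, as.matrix(tu$x)), tu$y))
  expect_equal(u0$n_train, sum(site$split == "train"))
})

test_that("identical clients with the same seed return identical updates", {
  site <- tiny_site(150, 12, seed = 7)
  feats <- colnames(site$features)
  cfg <- dcn_config(length(feats), n_cross = 1, deep_widths = 4)
  g <- dcn_init(cfg, seed = 4)
  fc <- federation_config(local_epochs = 2, lr = 0.1,
                          privacy = privacy_spec(1, 0.5, 0.5, 10), seed = 5)
  u1 <- local_update(g, site, feats, cfg, fc, seed = 77)
  u2 <- local_update(g, site, feats, cfg, fc, seed = 77)
  expect_identical(u1$params, u2$params)
})

test_that("one round of training returns the single aggregation; best round is the argmin", {
  sim <- tiny_federation(seed = 8)
  fed <- sim$data
  fit1 <- train_federated(fed, config = federation_config(rounds = 1, lr = 0.05,
                                                          seed = 6))
  expect_equal(fit1$best_round, 1L)
  expect_equal(nrow(fit1$trace), 1L)

  fit <- train_federated(fed, config = federation_config(rounds = 3, lr = 0.05,
                                                         seed = 6))
  expect_equal(fit$best_round, which.min(fit$trace$agg_tune_loss))
  expect_equal(fit$params, fit$rounds[[fit$best_round]]$params,
               ignore_attr = TRUE)
  ## aggregated loss is the tune-size-weighted mean of client losses
  n_tune <- vapply(fed$clients, function(cl) sum(cl$split == "tune"), 0)
  for (r in 1:3)
    expect_equal(fit$trace$agg_tune_loss[r],
                 sum(n_tune / sum(n_tune) * fit$rounds[[r]]$client_tune_loss))
})

test_that("federated training is deterministic given the seed", {
  sim <- tiny_federation(seed = 9)
  fc <- federation_config(rounds = 2, local_epochs = 2, lr = 0.1,
                          privacy = privacy_spec(0.5, 1, 0.5, 10), seed = 21)
  f1 <- train_federated(sim$data, config = fc)
  f2 <- train_federated(sim$data, config = fc)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$trace, f2$trace)
})

test_that("with one client and no noise, federation matches centralized SGD round for round", {
  site <- tiny_site(300, 20, seed = 10, prevalence = 0.25)
  feats <- colnames(site$features)
  cfg <- dcn_config(length(feats), n_cross = 2, deep_widths = c(8, 4))
  fc <- federation_config(rounds = 2, local_epochs = 3, batch_size = 32,
                          lr = 0.1, seed = 31)
  fit <- train_federated(list(one = site), feature_ids = feats, dcn_cfg = cfg,
                         config = fc, standardize = FALSE)
  ## centralized replay: same init, same per-round seeds, contiguous epochs
  seeds <- fedrisk:::derive_seeds(fc$seed, 1L + fc$rounds)
  tr <- fedrisk:::site_partition(site, "train")
  Xtr <- as.matrix(tr$x)[, feats]
  p <- dcn_init(cfg, seed = seeds[1])
  for (r in seq_len(fc$rounds)) {
    p <- fedrisk:::train_epochs(p, cfg, Xtr, tr$y, fc$local_epochs,
                                fc$batch_size, fc$lr, C = Inf, sigma = 0,
                                seed = seeds[1L + r])
    expect_equal(dcn_flatten(fit$rounds[[r]]$params), dcn_flatten(p),
                 tolerance = 1e-12)
  }
})

test_that("local comparator picks the epoch with the lowest tuning loss", {
  site <- tiny_site(250, 15, seed = 12, prevalence = 0.25)
  fit <- train_local(site, config = federation_config(lr = 0.1, seed = 41),
                     epochs = 6)
  expect_s3_class(fit, "local_dcn")
  expect_equal(nrow(fit$trace), 6L)
  expect_equal(fit$best_epoch, which.min(fit$trace$tune_loss))
  fit1 <- train_local(site, config = federation_config(lr = 0.1, seed = 41),
                      epochs = 1)
  expect_equal(fit1$best_epoch, 1L)
})

test_that("fitted models expose the standard S3 surface", {
  sim <- tiny_federation(seed = 13)
  fit <- train_federated(sim$data, config = federation_config(rounds = 2,
                                                              lr = 0.1, seed = 3))
  expect_output(print(fit), "fed_dcn")
  expect_output(summary(fit), "trace")
  cf <- coef(fit)
  expect_true(!is.null(names(cf)) && length(cf) == length(dcn_flatten(fit$params)))
  p <- predict(fit, sim$data$clients[[1]])
  te <- fedrisk:::site_partition(sim$data$clients[[1]], "test")
  expect_equal(length(p), length(te$y))
  expect_true(all(p > 0 & p < 1))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
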