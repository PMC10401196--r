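test_that("AUC matches hand values and handles ties and degenerate inputs", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC equals brute-force concordant-pair counting on random small inputs", {
  withr::local_seed(60)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auc(s, y), pair_count_auc(s, y))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(61)
  y <- rbinom(80, 1, 0.3); s <- rnorm(80) + y
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("Brier score is the mean squared probability error", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 4), c(0, 1, 0, 1)), 0.25)
  expect_equal(brier(c(0.9, 0.2), c(1, 0)), 0.025)
  expect_error(brier(c(1.1, 0.2), c(1, 0)), "\\[0,1\\]")
})

test_that("cross-site evaluation fills the model x site matrix consistently", {
  sim <- tiny_federation(n_sites = 3, seed = 14)
  fed <- sim$data
  fit <- train_federated(fed, config = federation_config(rounds = 2, lr = 0.1,
                                                         seed = 5))
  ## constant model: all-zero parameters predict 0.5 everywhere
  const <- fit
  const$params <- dcn_unflatten(rep(0, length(dcn_flatten(fit$params))),
                                fit$dcn_config)
  ev <- cross_site_evaluate(list(fitted = fit, constant = const), fed$clients)
  expect_equal(dim(ev$auc), c(2L, 3L))
  expect_equal(unname(ev$auc["constant", ]), rep(0.5, 3))
  expect_equal(unname(ev$brier["constant", ]), rep(0.25, 3))

  ## single model x single site equals direct metric calls
  te <- fedrisk:::site_partition(fed$clients[[2]], "test")
  p <- predict(fit, fed$clients[[2]])
  ev1 <- cross_site_evaluate(list(m = fit), fed$clients[2])
  expect_equal(unname(ev1$auc[1, 1]), auc(p, te$y))
  expect_equal(unname(ev1$brier[1, 1]), brier(p, te$y))

  ## permuting sites leaves the mean unchanged
  ev_perm <- cross_site_evaluate(list(fitted = fit, constant = const),
                                 fed$clients[c(3, 1, 2)])
  expect_equal(ev$mean_auc, ev_perm$mean_auc)
})

test_that("single-class sites yield undefined AUC cells excluded from means", {
  sim <- tiny_federation(n_sites = 2, seed = 15)
  fed <- sim$data
  fit <- train_federated(fed, config = federation_config(rounds = 1, lr = 0.1,
                                                         seed = 5))
  degenerate <- fed$clients[[2]]
  degenerate$labels[] <- 0L
  degenerate$site_id <- "allneg"
  expect_warning(
    ev <- cross_site_evaluate(list(m = fit),
                              list(a = fed$clients[[1]], allneg = degenerate)),
    "single-class")
  expect_true(is.na(ev$auc[1, "allneg"]))
  expect_equal(unname(ev$mean_auc), unname(ev$auc[1, "a"]))
})

test_that("balanced bootstrap keeps cases, downsamples controls, and is seeded", {
  withr::local_seed(62)
  y <- rep(c(1, 0), c(20, 200))
  s <- rnorm(220, y)
  r1 <- balanced_bootstrap_auc(s, y, ratio = 3, B = 50, seed = 9)
  r2 <- balanced_bootstrap_auc(s, y, ratio = 3, B = 50, seed = 9)
  expect_identical(r1$replicates, r2$replicates)
  expect_true(r1$ci[1] <= r1$mean_auc && r1$mean_auc <= r1$ci[2])
  expect_error(balanced_bootstrap_auc(s, y, ratio = 11, B = 10, seed = 1),
               "controls")

  ## constant scores: mean 0.5 with a degenerate interval
  rc <- balanced_bootstrap_auc(rep(0.2, 220), y, ratio = 1, B = 20, seed = 2)
  expect_equal(rc$mean_auc, 0.5)
  expect_equal(unname(rc$ci), c(0.5, 0.5))

  ## exactly r * n_cases controls: every replicate is the full-sample AUC
  y2 <- rep(c(1, 0), c(10, 30))
  s2 <- rnorm(40, y2)
  rf <- balanced_bootstrap_auc(s2, y2, ratio = 3, B = 25, seed = 3)
  expect_true(all(rf$replicates == auc(s2, y2)))
})

test_that("Shapley attributions recover the linear closed form and efficiency", {
  f <- function(X) 2 * X[, 1] + 3 * X[, 2]
  background <- rbind(c(0, 0), c(1, 1))       # mean (0.5, 0.5)
  inst <- matrix(c(1, 0), 1, 2)
  rep <- shapley_attributions(f, inst, background, n_permutations = 2000,
                              seed = 70)
  expect_equal(unname(rep$values[1, ]), c(1, -1.5), tolerance = 0.1)
  ## efficiency: attributions sum to f(x) - mean f(background)
  expect_equal(sum(rep$values[1, ]), f(inst) - rep$baseline, tolerance = 0.2)

  ## an ignored feature gets zero attribution
  g <- function(X) 5 * X[, 1]
  rep2 <- shapley_attributions(g, inst, background, n_permutations = 200,
                               seed = 71)
  expect_equal(unname(rep2$values[1, 2]), 0)
  expect_error(shapley_attributions(g, inst, background, n_permutations = 0),
               "n_permutations")
})

test_that("attribution export writes a long instance/feature/value CSV", {
  f <- function(X) X[, 1]
  rep <- shapley_attributions(f, matrix(1:4 / 4, 2, 2,
                                        dimnames = list(c("i1", "i2"),
                                                        c("f1", "f2"))),
                              matrix(0, 2, 2), n_permutations = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_attributions(rep, path)
  df <- read.csv(path)
  expect_equal(names(df), c("instance", "feature", "value"))
  expect_equal(nrow(df), 4)
})
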