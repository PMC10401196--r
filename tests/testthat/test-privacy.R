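test_that("gradient clipping scales onto the C ball and leaves inside vectors alone", {
  expect_equal(clip_gradient(c(3, 4), 1), c(0.6, 0.8))
  expect_equal(clip_gradient(c(0.3, 0.4), 1), c(0.3, 0.4))
  expect_equal(clip_gradient(c(3, 4), 2.5), c(1.5, 2))
  expect_equal(clip_gradient(c(0, 0), 1), c(0, 0))
})

test_that("dp_sgd_step with sigma 0 and infinite C equals an independent plain SGD step", {
  cfg <- dcn_config(3, n_cross = 1, deep_widths = 4)
  p <- random_params(cfg, seed = 8)
  withr::local_seed(9)
  X <- matrix(rnorm(15), 5, 3); y <- rbinom(5, 1, 0.5)
  lr <- 0.05
  upd <- dp_sgd_step(p, cfg, X, y, C = Inf, sigma = 0, lr = lr)
  ## independent path: mean-gradient step via per-row numeric differentiation
  v <- dcn_flatten(p)
  lossf <- function(vv) {
    pr <- dcn_forward(dcn_unflatten(vv, cfg), cfg, X)
    mean(-(y * log(pr) + (1 - y) * log(1 - pr)))
  }
  eps <- 1e-6
  num <- vapply(seq_along(v), function(i) {
    vp <- v; vm <- v; vp[i] <- v[i] + eps; vm[i] <- v[i] - eps
    (lossf(vp) - lossf(vm)) / (2 * eps)
  }, 0)
  expect_equal(dcn_flatten(upd), v - lr * num, tolerance = 1e-6)
})

test_that("per-example gradient norms never exceed C after clipping", {
  cfg <- dcn_config(4, n_cross = 2, deep_widths = c(5, 3))
  p <- random_params(cfg, seed = 10)
  withr::local_seed(11)
  X <- matrix(rnorm(40, 0, 2), 10, 4); y <- rbinom(10, 1, 0.5)
  pieces <- fedrisk:::dcn_per_example_grads(p, cfg, X, y)
  norms <- fedrisk:::grad_norms(pieces)
  C <- 0.1
  cvec <- pmin(1, C / norms)
  expect_true(all(norms * cvec <= C + 1e-12))
  ## the step itself runs its internal assertion
  expect_s3_class(dp_sgd_step(p, cfg, X, y, C = C, sigma = 0.5, lr = 0.1),
                  "dcn_params")
  expect_error(dp_sgd_step(p, cfg, X, y, C = C, sigma = -1, lr = 0.1), ">= 0")
})

test_that("single-step RDP matches the Gaussian closed form and a frozen high-precision value", {
  expect_equal(rdp_of_step(1, 1, 2), 1)
  expect_equal(rdp_of_step(1, 2, 8), 1)
  expect_equal(rdp_of_step(1, 0.5, 3), 6)
  ## q -> 0 limit
  expect_lt(rdp_of_step(1e-9, 1, 8), 1e-12)
  ## subsampled bound at q = 1 collapses to the Gaussian value
  expect_equal(rdp_of_step(1 - 1e-12, 1, 4), 4 / 2, tolerance = 1e-6)
  ## frozen arbitrary-precision evaluation of the binomial-expansion series
  expect_equal(rdp_of_step(0.01, 1, 8), 0.000893643907606032, tolerance = 1e-12)
  expect_error(rdp_of_step(0.5, 1, 1), "> 1")
  expect_error(rdp_of_step(0.5, 0, 2), "> 0")
})

test_that("composition and conversion minimise over Renyi orders", {
  b <- compose_and_convert(privacy_spec(1, 1, sample_rate = 1, steps = 1,
                                        delta = 1e-5))
  expect_equal(b$epsilon, 3 + log(1e5) / 5, tolerance = 1e-12)  # alpha = 6
  expect_equal(b$alpha_star, 6)
  b0 <- compose_and_convert(privacy_spec(1, 1, sample_rate = 1, steps = 0))
  expect_equal(b0$epsilon, 0)
  expect_error(compose_and_convert(privacy_spec(1, 1, 1, 1), orders = numeric()),
               "nonempty")
})

test_that("epsilon is monotone in steps, sampling rate and noise", {
  eps <- function(sigma, T, q = 0.05)
    compose_and_convert(privacy_spec(sigma, 1, q, T))$epsilon
  for (sigma in c(0.8, 1.5, 3)) {
    e <- vapply(c(10, 50, 200, 1000, 4000), function(T) eps(sigma, T), 0)
    expect_true(all(diff(e) > 0))
  }
  for (T in c(50, 500)) {
    e <- vapply(c(0.7, 1, 1.6, 2.5, 5), function(s) eps(s, T), 0)
    expect_true(all(diff(e) < 0))
    eq <- vapply(c(0.01, 0.05, 0.2, 1), function(q) eps(1.5, T, q), 0)
    expect_true(all(diff(eq) >= 0))
  }
})

test_that("DP hyperparameter selection matches a brute-force filter-then-argmin oracle", {
  sigmas <- c(0.5, 1, 2.5, 5); clips <- c(0.5, 1, 2.5, 5)
  withr::local_seed(12)
  auc_tab <- matrix(runif(16, 0.6, 0.8), 4, 4, dimnames = list(sigmas, clips))
  evalr <- function(s, C) auc_tab[as.character(s), as.character(C)]
  res <- select_dp_hyperparameters(evalr, sigmas, clips,
                                   sample_rate = 0.02, steps = 200)
  ## oracle: enumerate cells, filter, argmin epsilon with documented tie-breaks
  eps <- vapply(sigmas, function(s)
    compose_and_convert(privacy_spec(s, 1, 0.02, 200))$epsilon, 0)
  cells <- expand.grid(sigma = sigmas, clip = clips)
  cells$auc <- mapply(evalr, cells$sigma, cells$clip)
  cells$eps <- eps[match(cells$sigma, sigmas)]
  feas <- cells[cells$auc >= 0.95 * max(cells$auc), ]
  feas <- feas[order(feas$eps, -feas$sigma, -feas$auc, -feas$clip), ]
  expect_equal(res$sigma, feas$sigma[1])
  expect_equal(res$clip_norm, feas$clip[1])

  ## all-equal utilities: the largest sigma (smallest epsilon) wins
  res2 <- select_dp_hyperparameters(function(s, C) 0.7, sigmas, clips,
                                    sample_rate = 0.02, steps = 200)
  expect_equal(res2$sigma, 5)
})
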