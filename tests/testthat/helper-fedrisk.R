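# Fixture builders used across the suite; everything is generated in code.

# Random sparse long-format records for round-trip tests.
random_records <- function(n_persons, n_covs, density = 0.2, seed = 1) {
  withr::local_seed(seed)
  persons <- sprintf("p%03d", seq_len(n_persons))
  covs <- sprintf("c%03d", seq_len(n_covs))
  grid <- expand.grid(p = persons, c = covs, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  grid <- grid[keep, ]
  data.frame(person_id = grid$p, covariate_id = grid$c,
             value = round(runif(nrow(grid), 0.1, 5), 3),
             stringsAsFactors = FALSE)
}

# Small synthetic site with both outcome classes in every split.
tiny_site <- function(n = 200, K = 30, seed = 1, prevalence = 0.3,
                      site_id = "tiny") {
  cfg <- generator_config(n_sites = 1, persons_per_site = n, n_covariates = K,
                          n_informative = min(5, K),
                          effect_sizes = rep(1, min(5, K)),
                          target_prevalence = prevalence, tau = 0,
                          shifted_site = 1, external = FALSE,
                          informative_min_prevalence = 0, seed = seed)
  site <- generate_federation(cfg)$data$clients[[1]]
  site$site_id <- site_id
  site
}

# Small federation with learnable signal.
tiny_federation <- function(n_sites = 3, n = 400, K = 40, seed = 1,
                            prevalence = 0.2, tau = 0.3) {
  cfg <- generator_config(n_sites = n_sites, persons_per_site = rep(n, n_sites),
                          n_covariates = K, n_informative = 6,
                          effect_sizes = (-1)^(1:6) * seq(1, 2, length.out = 6),
                          target_prevalence = prevalence, tau = tau,
                          shifted_site = n_sites, external = FALSE,
                          informative_min_prevalence = 0, seed = seed)
  generate_federation(cfg)
}

# Brute-force AUC by concordant-pair counting (independent oracle).
pair_count_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Random conformant DCN parameter sets for aggregation tests.
random_params <- function(config, seed) {
  n <- sum(vapply(fedrisk:::dcn_shapes(config), prod, 0))
  withr::local_seed(seed)
  dcn_unflatten(rnorm(n), config)
}
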