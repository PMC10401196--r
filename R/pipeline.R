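#' End-to-end pipeline configuration
#'
#' One document wiring every stage: cohort simulation, federated feature
#' selection, federated + local training, cross-site and external
#' evaluation, and the baseline table. A single global seed deterministically
#' derives every stage seed.
#'
#' @param generator \code{\link{generator_config}}.
#' @param selection_grid candidate top-N values (NULL skips the search and
#'   uses \code{n_features} directly).
#' @param n_features number of features to train on when the search is
#'   skipped (default 100).
#' @param federation \code{\link{federation_config}}.
#' @param local_epochs epochs for the local comparators (default 25).
#' @param ratios balanced-evaluation control:case ratios.
#' @param bootstraps bootstrap replicates for balanced evaluation.
#' @param seed global seed.
#' @return a \code{run_config}.
#' @export
run_config <- function(generator = generator_config(),
                       selection_grid = NULL, n_features = 100L,
                       federation = federation_config(),
                       local_epochs = 25L,
                       ratios = c(1L, 3L, 4L, 9L), bootstraps = 1000L,
                       seed = 1L) {
  structure(list(generator = generator, selection_grid = selection_grid,
                 n_features = as.integer(n_features), federation = federation,
                 local_epochs = as.integer(local_epochs),
                 ratios = as.integer(ratios), bootstraps = as.integer(bootstraps),
                 seed = as.integer(seed)),
            class = "run_config")
}

log_stage <- function(stage, t0, ...) {
  extra <- paste(unlist(list(...)), collapse = " ")
  message(sprintf("[fedrisk] %-16s %6.1fs %s", stage,
                  as.numeric(proc.time()[3] - t0), extra))
}

#' Run the full federated analysis pipeline
#'
#' Executes simulate, feature selection, federated and local training,
#' cross-site + external evaluation with balanced bootstraps, and the
#' baseline table, writing all artifacts and a manifest into \code{out_dir}.
#' Deterministic given the config seed.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created if needed).
#' @return (invisibly) list with the fitted models, evaluation results and
#'   output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("fedrisk_run")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6L)
  t0 <- proc.time()[3]

  ## 1. simulate
  gen_cfg <- config$generator
  gen_cfg$seed <- seeds[1]
  sim <- generate_federation(gen_cfg)
  fed <- sim$data
  for (cl in fed$clients) {
    write_feature_table(cl$features,
                        file.path(out_dir, sprintf("%s_features.csv", cl$site_id)))
    write_labels(cl$labels, file.path(out_dir, sprintf("%s_labels.csv", cl$site_id)))
  }
  jsonlite::write_json(
    list(informative = sim$true_model$informative, beta = sim$true_model$beta,
         alpha = as.list(sim$true_model$alpha)),
    file.path(out_dir, "true_model.json"), auto_unbox = TRUE, digits = NA)
  log_stage("simulate", t0, sprintf("%d clients", length(fed$clients)))

  ## 2. federated feature selection
  sel <- select_features(fed, grid = config$selection_grid,
                         fed_config = config$federation, seed = seeds[2])
  n_feat <- if (!is.null(sel$trace)) sel$trace$chosen_n
            else min(config$n_features, nrow(sel$ranking))
  feats <- sel$ranking$covariate_id[seq_len(n_feat)]
  jsonlite::write_json(list(chosen_n = n_feat, features = feats),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("select-features", t0, sprintf("chosen N = %d", n_feat))

  ## 3. federated + local training
  fed_cfg <- config$federation
  fed_cfg$seed <- seeds[3]
  fed_fit <- train_federated(fed, feature_ids = feats, config = fed_cfg)
  local_fits <- lapply(fed$clients, function(cl) {
    lc <- fed_cfg
    lc$seed <- seeds[4] + match(cl$site_id, names(fed$clients))
    train_local(cl, feature_ids = feats, config = lc,
                epochs = config$local_epochs)
  })
  models <- c(list(federated = fed_fit),
              stats::setNames(local_fits, names(fed$clients)))
  log_stage("train", t0, sprintf("federated best round %d", fed_fit$best_round))

  ## 4. evaluation
  internal <- cross_site_evaluate(models, fed$clients, use_split = "test")
  external <- if (!is.null(fed$external))
    cross_site_evaluate(models, list(fed$external), use_split = "all")
  balanced <- lapply(config$ratios, function(r) {
    scores <- unlist(lapply(fed$clients, function(cl) {
      te <- site_partition(cl, "test")
      predict(fed_fit, te$x)
    }), use.names = FALSE)
    y <- unlist(lapply(fed$clients, function(cl) site_partition(cl, "test")$y),
                use.names = FALSE)
    res <- balanced_bootstrap_auc(scores, y, r, B = config$bootstraps,
                                  seed = seeds[5] + r)
    res$replicates <- NULL
    res
  })
  report <- list(internal = list(auc = internal$auc, brier = internal$brier,
                                 mean_auc = internal$mean_auc),
                 external = if (!is.null(external))
                   list(auc = external$auc, brier = external$brier),
                 balanced = balanced)
  jsonlite::write_json(report, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("evaluate", t0,
            sprintf("federated mean AUC %.3f", internal$mean_auc["federated"]))

  ## 5. baseline table on the planted informative covariates
  chars <- head(sim$true_model$informative, 10)
  t1 <- build_table_one(fed$clients, chars)
  write_table_one(t1, file.path(out_dir, "table_one.tsv"))
  log_stage("table-one", t0)

  manifest <- list(seed = config$seed, stage_seeds = seeds,
                   n_clients = length(fed$clients),
                   chosen_n = n_feat,
                   best_round = fed_fit$best_round,
                   mean_auc_internal = unname(internal$mean_auc["federated"]),
                   package_version = as.character(utils::packageVersion("fedrisk")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(models = models, internal = internal, external = external,
                 balanced = balanced, table_one = t1, selection = sel,
                 out_dir = out_dir))
}
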