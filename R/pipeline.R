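#' End-to-end run configuration
#'
#' Aggregates every stage's settings with defaults matching the reference
#' analysis: SC absolute threshold 0.1, FC density cutoff 0.5, SMOTE
#' balancing before the split, 10% test / 80%-20% train-validation split,
#' a 6+1-head two-layer GAT with top-20 readout, and the interpretability
#' settings (saliency threshold 0.02, clinical alpha 0.005). Serializable
#' to a single JSON document.
#'
#' @param mode `"multimodal-sc"` (SC graph + 24 features, default),
#'   `"multimodal-fc"`, `"unimodal-sc"`, `"unimodal-fc"` — the four model
#'   variants (graph matrix x feature blocks).
#' @param sc_threshold,fc_density Connectivity preprocessing parameters.
#' @param smote Apply SMOTE class balancing before splitting.
#' @param smote_k SMOTE neighbor count.
#' @param test_fraction,val_fraction,folds Split / CV settings.
#' @param model A `gat_config` (feature width is adjusted to the mode).
#' @param train A `train_config`.
#' @param saliency_threshold,clinical_alpha,fidelity_mask Interpretability
#'   settings.
#' @param run_cv Run k-fold cross-validation (the expensive stage).
#' @param permutations Label permutations for the significance test
#'   (0 disables; 1000 is the conventional choice).
#' @param permutation_mode `"retrain"` or `"cheap"`.
#' @param seed Master seed.
#' @return A `run_config`.
#' @export
run_config <- function(mode = c("multimodal-sc", "multimodal-fc",
                                "unimodal-sc", "unimodal-fc"),
                       sc_threshold = 0.1, fc_density = 0.5,
                       smote = TRUE, smote_k = 5L,
                       test_fraction = 0.10, val_fraction = 0.20,
                       folds = 10L, model = gat_config(),
                       train = train_config(),
                       saliency_threshold = 0.02, clinical_alpha = 0.005,
                       fidelity_mask = "uniform", run_cv = TRUE,
                       permutations = 0L,
                       permutation_mode = "cheap", seed = 1L) {
  mode <- match.arg(mode)
  structure(list(schema_version = 1L, mode = mode,
                 sc_threshold = sc_threshold, fc_density = fc_density,
                 smote = smote, smote_k = as.integer(smote_k),
                 test_fraction = test_fraction,
                 val_fraction = val_fraction, folds = as.integer(folds),
                 model = model, train = train,
                 saliency_threshold = saliency_threshold,
                 clinical_alpha = clinical_alpha,
                 fidelity_mask = fidelity_mask,
                 run_cv = run_cv, permutations = as.integer(permutations),
                 permutation_mode = permutation_mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

mode_parts <- function(mode) {
  switch(mode,
         "multimodal-sc" = list(features = "multimodal", graph = "SC"),
         "multimodal-fc" = list(features = "multimodal", graph = "FC"),
         "unimodal-sc" = list(features = "unimodal-sc", graph = "SC"),
         "unimodal-fc" = list(features = "unimodal-fc", graph = "FC"))
}

mode_n_features <- function(mode) {
  switch(mode_parts(mode)$features,
         multimodal = 24L, "unimodal-sc" = 13L, "unimodal-fc" = 11L)
}

preprocess_cohort <- function(ds, sc_threshold, fc_density) {
  ds$subjects <- lapply(ds$subjects, function(s) {
    s$sc <- threshold_absolute(s$sc, sc_threshold)
    s$fc <- threshold_density(fisher_z(s$fc), fc_density)
    s
  })
  ds
}

#' Run the full classification + interpretability pipeline
#'
#' Executes threshold -> features -> (optional) SMOTE -> split ->
#' normalize -> train (and optionally 10-fold CV) -> evaluate ->
#' interpret, writing metrics JSON, the saliency/attention/fidelity
#' reports, per-epoch history CSV and a reproducibility log into
#' `out_dir`. Deterministic: rerunning with the same config and cohort
#' reproduces the metrics byte-identically.
#'
#' @param ds A raw `cohort_dataset` (e.g. from [generate_cohort()] or
#'   [load_cohort()]).
#' @param cfg A `run_config`.
#' @param out_dir Output run directory (created; `NULL` skips writing).
#' @return A `pipeline_result` list: `splits`, `cv` (when run),
#'   `test_metrics`, `val_metrics`, `fidelity`, `saliency`, `salient`,
#'   `attention`, `clinical`, `permutation` (when run), `config`.
#' @export
run_pipeline <- function(ds, cfg = run_config(), out_dir = NULL) {
  parts <- mode_parts(cfg$mode)
  raw <- ds
  ds <- preprocess_cohort(ds, cfg$sc_threshold, cfg$fc_density)
  if (cfg$smote) {
    ds <- augment_cohort(ds, k_neighbors = cfg$smote_k, seed = cfg$seed)
  }
  gds <- build_graph_dataset(ds, mode = parts$features,
                             preprocessed = TRUE, seed = cfg$seed,
                             graph_modality = parts$graph)
  model_cfg <- cfg$model
  model_cfg$n_features <- mode_n_features(cfg$mode)
  sp <- split_dataset(gds$labels, cfg$test_fraction, cfg$val_fraction,
                      seed = cfg$seed)
  scaler <- fit_minmax(gds$features[sp$train])
  scaled <- apply_minmax(scaler, gds$features)
  cv <- NULL
  if (cfg$run_cv) {
    cv <- cross_validate(gds, idx = sort(c(sp$train, sp$val)),
                         folds = cfg$folds, model_cfg = model_cfg,
                         train_cfg = cfg$train, seed = cfg$seed)
  }
  model <- train_gat(gds, scaled, sp$train, sp$val, model_cfg = model_cfg,
                     train_cfg = cfg$train)
  ev_val <- eval_loss_acc(model, gds, sp$val, scaled)
  ev_test <- eval_loss_acc(model, gds, sp$test, scaled)
  val_metrics <- compute_metrics(gds$labels[sp$val], ev_val$preds)
  test_metrics <- compute_metrics(gds$labels[sp$test], ev_test$preds)
  fid <- fidelity_scores(model, scaled, gds$adj, gds$labels, idx = sp$val,
                         mask_mode = cfg$fidelity_mask)
  sal <- saliency_map(model, scaled, gds$adj, gds$labels, idx = sp$val)
  salient <- select_salient(sal, cfg$saliency_threshold, atlas = ds$atlas)
  att <- attention_summary(model, scaled, gds$adj, gds$labels,
                           idx = sp$val)
  clin <- correlate_clinical(salient, ds, gds$features,
                             alpha = cfg$clinical_alpha)
  perm <- NULL
  if (cfg$permutations > 0) {
    perm <- permutation_test(gds, sp$train, sp$val,
                             model_cfg = model_cfg, train_cfg = cfg$train,
                             n_permutations = cfg$permutations,
                             seed = cfg$seed,
                             mode = cfg$permutation_mode)
  }
  result <- structure(list(splits = sp, cv = cv,
                           val_metrics = val_metrics,
                           test_metrics = test_metrics, fidelity = fid,
                           saliency = sal, salient = salient,
                           attention = att, clinical = clin,
                           permutation = perm, model = model,
                           config = cfg),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_run_dir(result, gds, out_dir)
  result
}

write_run_dir <- function(result, gds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_list <- unclass(cfg)
  cfg_list$model <- unclass(cfg_list$model)
  cfg_list$train <- unclass(cfg_list$train)
  jsonlite::write_json(cfg_list, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  metrics <- list(
    validation = result$val_metrics[c("accuracy", "precision", "recall",
                                      "f1")],
    test = result$test_metrics[c("accuracy", "precision", "recall", "f1")])
  if (!is.null(result$cv)) {
    metrics$cv <- list(mean_accuracy = result$cv$mean_accuracy,
                       sd_accuracy = result$cv$sd_accuracy,
                       mean_f1 = result$cv$mean_f1)
  }
  if (!is.null(result$permutation)) {
    metrics$permutation <- result$permutation[c("p_value", "observed",
                                                "mode")]
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(result$fidelity),
                   file.path(out_dir, "fidelity.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(result$saliency)),
                   file.path(out_dir, "saliency.csv"), row.names = FALSE)
  utils::write.csv(result$salient, file.path(out_dir, "salient.csv"),
                   row.names = FALSE)
  utils::write.csv(result$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  if (!is.null(result$model$history) && nrow(result$model$history) > 0) {
    utils::write.csv(result$model$history,
                     file.path(out_dir, "history.csv"), row.names = FALSE)
  }
  for (p in seq_along(result$attention$layer1)) {
    utils::write.csv(result$attention$layer1[[p]]$symmetric,
                     file.path(out_dir, sprintf("attention_L1H%d.csv", p)),
                     row.names = FALSE)
  }
  utils::write.csv(result$attention$layer2[[1]]$symmetric,
                   file.path(out_dir, "attention_L2H1.csv"),
                   row.names = FALSE)
  log <- list(seed = cfg$seed,
              r_version = as.character(getRversion()),
              package_version = as.character(
                utils::packageVersion("braingat")),
              splits = result$splits,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
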