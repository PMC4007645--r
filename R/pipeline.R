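## End-to-end orchestration: simulate (or read) a training and a test
## cohort, preprocess both, compute amplitude scores, cluster the response
## transcripts, select a marker panel on the training cohort, evaluate it on
## the test cohort, and write every stage product with full parameter
## provenance. All randomness flows from the single master seed in the run
## configuration, so a run is bit-reproducible.

#' Run the full reporter-assay pipeline
#'
#' Executes simulate -> preprocess -> score -> cluster -> select-features ->
#' classify -> report. The training cohort drives feature selection; the
#' independently simulated (or supplied) test cohort is used only for
#' evaluation. Stage products are written under `out_dir` as TSV/JSON with
#' embedded parameters; log lines (stage, shapes, seed) go to standard
#' error.
#'
#' @param config a [run_config()].
#' @param sim_train,sim_test [sim_config()]s for the two cohorts; if
#'   `sim_test` is `NULL` the classification stage is skipped. Instead of a
#'   `sim_config`, a pre-built [expression_bundle()] may be supplied.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param quiet suppress log lines.
#' @return A list of class `pipeline_result` with every stage product.
#' @export
run_pipeline <- function(config, sim_train, sim_test = NULL, out_dir = NULL,
                         quiet = FALSE) {
  pr_assert(inherits(config, "run_config"), "config must be a run_config")
  say <- function(...) if (!quiet) message(sprintf(...))
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  materialise <- function(spec, label, architecture = NULL) {
    if (inherits(spec, "expression_bundle"))
      return(list(bundle = spec, truth = NULL))
    sim <- generate_bundle(spec, architecture = architecture)
    say("simulate[%s]: %d probes x %d samples (seed %d)", label,
        nrow(sim$bundle$intensities), ncol(sim$bundle$intensities),
        spec$seed)
    sim
  }
  train <- materialise(sim_train, "train")
  ## the test cohort measures new patients on the same platform: reuse the
  ## training cohort's probe architecture when both cohorts are simulated
  test <- if (!is.null(sim_test))
    materialise(sim_test, "test",
                architecture = train$truth$architecture)

  pp_train <- run_preprocess(train$bundle, config)
  say("preprocess[train]: %d -> %d (PALO) -> %d (2FC100DIF)",
      pp_train$provenance$n_input, pp_train$provenance$n_palo,
      pp_train$provenance$n_selected)

  sel_fcm <- subset_fcm(pp_train$fcm, pp_train$selected_probes)
  pca <- run_pca(sel_fcm$log2_fc)
  scores <- distance_to_reference(pca, sel_fcm$metadata,
                                  n_components = config$n_components_distance)
  say("score: %d samples, severe-vs-not p = %.4g", nrow(pca$scores),
      scores$p_value)

  k <- min(config$n_clusters, nrow(sel_fcm$log2_fc))
  dend <- hierarchical_cluster(sel_fcm$log2_fc)
  clusters <- cut_clusters(dend, k)
  say("cluster: %d transcripts into %d clusters", length(clusters), k)

  sepsis <- group_labels(sel_fcm$metadata) %in% c("severe", "not_severe")
  rk_x <- t(pp_train$fcm$log2_fc[, sepsis, drop = FALSE])
  rk_lab <- group_labels(sel_fcm$metadata)[sepsis]
  ranking <- geometric_backward_elimination(
    rk_x, rk_lab, r = config$ensemble_size, m = config$subset_size,
    k = config$knn_k, keep_ratio = config$keep_ratio,
    floor_features = config$floor_features, n_select = config$n_select,
    seed = stage_seed(config$seed, "rknn"),
    sample_ids = rownames(rk_x))
  say("select-features: %d stages, panel of %d, LOOCV accuracy %.3f",
      nrow(ranking$path), length(ranking$selected), ranking$loocv_accuracy)

  evaluation <- NULL
  pp_test <- NULL
  if (!is.null(test)) {
    pp_test <- run_preprocess(test$bundle, config)
    evaluation <- evaluate_severity_panel(pp_train, pp_test, ranking, config)
    say("classify: %s",
        paste(sprintf("%s/%s AUC=%.3f", evaluation$summary$target,
                      evaluation$summary$kind, evaluation$summary$auc),
              collapse = ", "))
  }

  report <- structure(list(
    config = unclass(config),
    provenance = list(train = unclass(pp_train$provenance),
                      test = if (!is.null(pp_test))
                        unclass(pp_test$provenance)),
    amplitude = list(
      group_means = tapply(scores$samples$distance, scores$samples$group,
                           mean),
      U = scores$U, p_value = scores$p_value),
    panel = ranking$selected,
    loocv_accuracy = ranking$loocv_accuracy,
    auc = if (!is.null(evaluation))
      setNames(evaluation$summary$auc,
               paste(evaluation$summary$target, evaluation$summary$kind,
                     sep = "_"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    if (!is.null(train$truth))
      write_stage_output(train$truth, file.path(out_dir, "truth_train.json"))
    write_stage_output(pp_train$provenance,
                       file.path(out_dir, "preprocess_provenance.json"))
    write_stage_output(scores, file.path(out_dir, "amplitude_scores.json"))
    write_stage_output(ranking, file.path(out_dir, "feature_ranking.json"))
    if (!is.null(evaluation))
      write_stage_output(evaluation, file.path(out_dir, "evaluation.json"))
    write_stage_output(report, file.path(out_dir, "report.json"))
    export_cluster_gene_lists(clusters, file.path(out_dir, "clusters"))
    say("report: written to %s", out_dir)
  }

  structure(list(train = train, test = test, preprocess = pp_train,
                 preprocess_test = pp_test, pca = pca, scores = scores,
                 dendrogram = dend, clusters = clusters, ranking = ranking,
                 evaluation = evaluation, report = report),
            class = "pipeline_result")
}
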