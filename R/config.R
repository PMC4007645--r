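## Run and simulation configuration objects. All tunable parameters of the
## pipeline live here, with the assay's published constants as defaults.

#' Pipeline run configuration
#'
#' Collects every tunable analysis parameter with its default. Defaults
#' follow the assay's published processing constants: detection p-value
#' cutoff 0.01 (PALO), intensity floor 10, differential filter at 2-fold
#' change and 100 intensity-unit difference, distances over the first 2
#' principal components, and 5 nearest neighbours for the RKNN ensemble.
#'
#' @param palo_alpha detection p-value cutoff; a probe is kept if its p-value
#'   is `<= palo_alpha` in at least one sample.
#' @param floor_value intensity floor applied after quantile normalization.
#' @param fc_threshold minimum linear fold change (two-sided via |log2 fc|).
#' @param dif_threshold minimum absolute intensity difference versus the
#'   medium-control mean.
#' @param min_samples number of stimulated samples that must pass both
#'   differential thresholds for a probe to be selected.
#' @param n_components_distance number of leading principal components used
#'   for the amplitude (distance-to-reference) statistic.
#' @param knn_k number of neighbours in each base kNN model (odd).
#' @param ensemble_size number of random-subset base models per RKNN stage.
#' @param subset_size features per base model; `NULL` means
#'   `floor(sqrt(p))`, the random-subspace heuristic.
#' @param keep_ratio fraction of features retained at each backward
#'   elimination stage (0 < keep_ratio < 1).
#' @param floor_features elimination stops once at most this many features
#'   remain.
#' @param n_select size of the selected marker panel.
#' @param n_clusters number of clusters cut from the transcript dendrogram.
#' @param bootstrap_reps bootstrap replicates for AUC confidence intervals.
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it via [stage_seed()]. Mandatory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(palo_alpha = 0.01,
                       floor_value = 10,
                       fc_threshold = 2,
                       dif_threshold = 100,
                       min_samples = 1,
                       n_components_distance = 2,
                       knn_k = 5,
                       ensemble_size = 2000,
                       subset_size = NULL,
                       keep_ratio = 0.8,
                       floor_features = 10,
                       n_select = 30,
                       n_clusters = 12,
                       bootstrap_reps = 2000,
                       seed = NULL) {
  pr_assert(!is.null(seed) && is.finite(seed),
            "seed is mandatory in a run configuration")
  pr_assert(palo_alpha > 0 && palo_alpha <= 1, "palo_alpha must be in (0, 1]")
  pr_assert(floor_value > 0, "floor_value must be positive")
  pr_assert(fc_threshold >= 0 && dif_threshold >= 0,
            "differential thresholds must be non-negative")
  pr_assert(keep_ratio > 0 && keep_ratio < 1,
            "keep_ratio must be strictly between 0 and 1")
  pr_assert(knn_k %% 2 == 1, "knn_k must be odd")
  pr_assert(min_samples >= 1 && n_components_distance >= 1 &&
              ensemble_size >= 1 && floor_features >= 1 && n_select >= 1 &&
              n_clusters >= 1 && bootstrap_reps >= 1,
            "counts must be >= 1")
  structure(list(palo_alpha = palo_alpha, floor_value = floor_value,
                 fc_threshold = fc_threshold, dif_threshold = dif_threshold,
                 min_samples = min_samples,
                 n_components_distance = n_components_distance,
                 knn_k = knn_k, ensemble_size = ensemble_size,
                 subset_size = subset_size, keep_ratio = keep_ratio,
                 floor_features = floor_features, n_select = n_select,
                 n_clusters = n_clusters, bootstrap_reps = bootstrap_reps,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Simulation configuration
#'
#' Parameters of the synthetic reporter-assay generator. Cohort defaults
#' mirror the study design's largest experiment: 19 uninfected plasma donors
#' and 35 sepsis donors split 20 severe / 15 not severe, all collected
#' within 48 h of admission, with 3 medium-alone control cultures per batch.
#'
#' The generative model is log-normal: each expressed probe has a log2
#' baseline `~ N(mu_b, sd_b)`; responsive probes add `delta_g * A_s` for
#' plasma-stimulated samples, where the per-sample response amplitude `A_s ~
#' N(a_group, amp_sd)`; severity-marker probes additionally add a
#' severe-specific contrast `delta'_g` so markers separate severe samples
#' beyond amplitude alone. Samples collected after 48 h have their amplitude
#' attenuated. See the methods vignette for the rationale behind each
#' default.
#'
#' @param n_probes total probes on the synthetic array.
#' @param fraction_unexpressed fraction of probes that are unexpressed
#'   (baseline near the floor, detection p-values > 0.01 everywhere).
#' @param n_uninfected,n_severe,n_not_severe plasma cohort sizes.
#' @param n_medium_controls medium-alone control cultures per batch.
#' @param n_batches number of culture batches (plasma samples are spread
#'   round-robin over batches; each batch has its own control arm).
#' @param n_resp number of plasma-responsive probes.
#' @param n_mark number of severity-marker probes (subset of responsive).
#' @param baseline_mean,baseline_sd log2 baseline distribution of expressed
#'   probes.
#' @param amplitude_means named vector of mean response amplitudes for
#'   uninfected, not_severe and severe plasma (arbitrary units).
#' @param amplitude_sd between-sample sd of the response amplitude.
#' @param delta_mean,delta_sd mean/sd of the per-probe log2 effect magnitude
#'   of responsive probes (per unit amplitude).
#' @param prob_up probability a responsive probe is up- rather than
#'   down-regulated.
#' @param marker_delta_mean,marker_delta_sd mean/sd of the severe-specific
#'   log2 contrast magnitude added to marker probes.
#' @param noise_sd per-cell log2 measurement noise sd.
#' @param batch_sd sd of the per-batch additive log2 shift.
#' @param frac_after_48h fraction of sepsis samples drawn after 48 h of
#'   admission (their amplitude is attenuated).
#' @param attenuation multiplier applied to the amplitude of after-48h
#'   samples.
#' @param seed generator seed (mandatory).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 10000,
                       fraction_unexpressed = 0.3,
                       n_uninfected = 19,
                       n_severe = 20,
                       n_not_severe = 15,
                       n_medium_controls = 3,
                       n_batches = 1,
                       n_resp = 700,
                       n_mark = 30,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       amplitude_means = c(uninfected = 0.2,
                                           not_severe = 1.0,
                                           severe = 2.5),
                       amplitude_sd = 0.75,
                       delta_mean = 0.6,
                       delta_sd = 0.2,
                       prob_up = 0.55,
                       marker_delta_mean = 1.0,
                       marker_delta_sd = 0.2,
                       noise_sd = 0.25,
                       batch_sd = 0.1,
                       frac_after_48h = 0,
                       attenuation = 0.15,
                       seed = NULL) {
  pr_assert(!is.null(seed) && is.finite(seed), "seed is mandatory")
  pr_assert(n_mark <= n_resp && n_resp <= n_probes,
            "need n_mark <= n_resp <= n_probes")
  pr_assert(fraction_unexpressed >= 0 && fraction_unexpressed < 1,
            "fraction_unexpressed must be in [0, 1)")
  pr_assert(n_resp <= round(n_probes * (1 - fraction_unexpressed)),
            "n_resp exceeds the number of expressed probes")
  pr_assert(all(c(n_uninfected, n_severe, n_not_severe, n_medium_controls,
                  n_batches) >= 1), "cohort sizes must be >= 1")
  pr_assert(all(c(baseline_sd, amplitude_sd, delta_sd, marker_delta_sd,
                  noise_sd) > 0) && batch_sd >= 0, "sds must be positive")
  pr_assert(all(c("uninfected", "not_severe", "severe") %in%
                  names(amplitude_means)),
            "amplitude_means must name uninfected, not_severe and severe")
  pr_assert(frac_after_48h >= 0 && frac_after_48h <= 1,
            "frac_after_48h must be in [0, 1]")
  pr_assert(attenuation >= 0 && attenuation <= 1,
            "attenuation must be in [0, 1]")
  structure(as.list(environment()), class = "sim_config")
}

#' Read a run or simulation configuration from YAML
#'
#' The file may contain top-level keys `run` and/or `sim`, each a mapping of
#' the arguments of [run_config()] / [sim_config()]. A top-level `seed` is
#' propagated to both unless overridden inside the block.
#'
#' @param path path to a YAML file.
#' @return A list with elements `run` (`run_config` or NULL) and `sim`
#'   (`sim_config` or NULL).
#' @export
read_config <- function(path) {
  pr_assert(file.exists(path), paste("no such config file:", path))
  raw <- yaml::read_yaml(path)
  fill_seed <- function(block) {
    if (is.null(block$seed) && !is.null(raw$seed)) block$seed <- raw$seed
    block
  }
  out <- list(run = NULL, sim = NULL)
  if (!is.null(raw$run))
    out$run <- do.call(run_config, fill_seed(raw$run))
  if (!is.null(raw$sim)) {
    blk <- fill_seed(raw$sim)
    if (!is.null(blk$amplitude_means))
      blk$amplitude_means <- unlist(blk$amplitude_means)
    out$sim <- do.call(sim_config, blk)
  }
  out
}
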