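## Synthetic reporter-assay generator. Emulates the statistical structure the
## downstream analysis assumes: a log-normal intensity model with additive
## log2 effects, a medium-alone control arm per batch, severity-graded
## response amplitudes, and a planted marker panel carrying a severe-specific
## contrast beyond amplitude alone.

#' Generate a synthetic expression bundle with known ground truth
#'
#' The generative model, per probe g and sample s (all on the log2 scale):
#'
#' * expressed probes draw a baseline `b_g ~ N(baseline_mean, baseline_sd)`;
#'   unexpressed probes sit near the intensity floor and carry detection
#'   p-values `~ U(0.02, 1)` (expressed: `~ U(0, 0.005)`);
#' * a medium-control sample in batch t measures `b_g + batch_t + e`,
#'   `e ~ N(0, noise_sd)`;
#' * a plasma-stimulated sample additionally gets `delta_g * A_s` on the
#'   responsive probes, where the sample's response amplitude
#'   `A_s ~ N(a_group, amplitude_sd)`; severity-marker probes further add a
#'   severe-specific contrast `delta'_g` for severe samples only, so the
#'   marker panel separates severe from not-severe beyond amplitude alone;
#' * samples collected after 48 h have `A_s` multiplied by `attenuation`,
#'   emulating the resolution of the plasma response after treatment onset.
#'
#' Intensities are returned on the linear scale (`2^log2`, hence positive).
#' The accompanying truth record identifies the responsive probes, the
#' marker subset, every sample's amplitude, and the per-probe effect sizes.
#'
#' Two cohorts measured on the same platform share their probe-level
#' architecture (which probes are expressed, responsive and markers, and
#' their effect sizes); to emulate that, pass the `architecture` element of
#' one cohort's truth record when generating the next cohort. The
#' architecture is drawn from a seed sub-stream of its own, so cohorts that
#' share a config seed share an architecture.
#'
#' @param config a [sim_config()].
#' @param architecture optional `sim_architecture` from a previous cohort's
#'   truth record, reused verbatim (its `n_probes` must match).
#' @return A list with elements `bundle` (an [expression_bundle()]) and
#'   `truth` (class `simulation_truth`, containing the architecture).
#' @export
#' @examples
#' sim <- generate_bundle(sim_config(n_probes = 200, n_resp = 20, n_mark = 5,
#'                                   n_uninfected = 4, n_severe = 4,
#'                                   n_not_severe = 3, seed = 1))
#' dim(sim$bundle$intensities)
#' length(sim$truth$severity_markers)
generate_bundle <- function(config, architecture = NULL) {
  pr_assert(inherits(config, "sim_config"), "config must be a sim_config")
  cf <- config
  if (is.null(architecture))
    architecture <- simulate_architecture(cf)
  pr_assert(inherits(architecture, "sim_architecture") &&
              architecture$n_probes == cf$n_probes,
            "architecture does not match n_probes")
  probe_ids <- architecture$probe_ids
  expressed <- architecture$expressed
  responsive <- architecture$responsive
  markers <- architecture$markers
  baseline <- architecture$baseline
  delta <- architecture$delta
  marker_delta <- architecture$marker_delta

  set.seed(stage_seed(cf$seed, "cohort"))

  ## sample table: a medium-control arm per batch, plasma samples round-robin
  batches <- sprintf("b%d", seq_len(cf$n_batches))
  med <- expand.grid(rep = seq_len(cf$n_medium_controls), batch = batches,
                     stringsAsFactors = FALSE)
  groups <- c(rep("uninfected", cf$n_uninfected),
              rep("severe", cf$n_severe),
              rep("not_severe", cf$n_not_severe))
  n_plasma <- length(groups)
  ## distinct cohorts (seeds) get distinct sample ids, as distinct patients
  ## would; downstream leak guards rely on this
  cohort <- sprintf("c%d", cf$seed %% 100000L)
  meta <- data.frame(
    sample_id = sprintf("%s.s%03d", cohort, seq_len(nrow(med) + n_plasma)),
    stimulus = c(rep("medium", nrow(med)), rep("plasma", n_plasma)),
    plasma_group = c(rep(NA, nrow(med)),
                     ifelse(groups == "uninfected", "uninfected", "sepsis")),
    severity = c(rep(NA, nrow(med)),
                 ifelse(groups == "uninfected", NA, groups)),
    collection_window = NA,
    donor = "D1", cell_type = "PMN",
    batch = c(med$batch, rep(batches, length.out = n_plasma)),
    stringsAsFactors = FALSE)

  sepsis_idx <- which(meta$stimulus == "plasma" & meta$plasma_group == "sepsis")
  n_late <- round(cf$frac_after_48h * length(sepsis_idx))
  late <- if (n_late > 0) sample(sepsis_idx, n_late) else integer(0)
  meta$collection_window[meta$stimulus == "plasma"] <- "within_48h"
  meta$collection_window[late] <- "after_48h"

  n_samples <- nrow(meta)
  batch_shift <- setNames(rnorm(cf$n_batches, 0, cf$batch_sd), batches)

  amplitude <- rep(NA_real_, n_samples)
  plasma <- which(meta$stimulus == "plasma")
  amplitude[plasma] <- rnorm(n_plasma, cf$amplitude_means[groups],
                             cf$amplitude_sd)
  amplitude[late] <- amplitude[late] * cf$attenuation

  log2m <- matrix(rnorm(cf$n_probes * n_samples, 0, cf$noise_sd),
                  cf$n_probes, n_samples)
  log2m <- log2m + baseline + rep(batch_shift[meta$batch],
                                  each = cf$n_probes)
  for (s in plasma) {
    log2m[responsive, s] <- log2m[responsive, s] +
      delta[responsive] * amplitude[s]
    if (identical(meta$severity[s], "severe"))
      log2m[markers, s] <- log2m[markers, s] + marker_delta[markers]
  }

  detection <- matrix(runif(cf$n_probes * n_samples, 0.02, 1),
                      cf$n_probes, n_samples)
  detection[expressed, ] <- runif(length(expressed) * n_samples, 0, 0.005)

  intens <- 2^log2m
  dimnames(intens) <- dimnames(detection) <- list(probe_ids, meta$sample_id)

  truth <- structure(list(
    responsive_probes = probe_ids[responsive],
    severity_markers = probe_ids[markers],
    amplitude = setNames(amplitude, meta$sample_id),
    group_means = cf$amplitude_means[c("uninfected", "not_severe", "severe")],
    delta = setNames(delta[responsive], probe_ids[responsive]),
    marker_delta = setNames(marker_delta[markers], probe_ids[markers]),
    architecture = architecture,
    seed = cf$seed), class = "simulation_truth")

  list(bundle = expression_bundle(intens, meta, detection), truth = truth)
}

## Probe-level architecture: identity of expressed / responsive / marker
## probes and their per-probe baseline and effect sizes. Drawn from its own
## seed sub-stream so it can be shared across cohorts.
simulate_architecture <- function(cf) {
  set.seed(stage_seed(cf$seed, "probes"))
  n_unexpr <- round(cf$n_probes * cf$fraction_unexpressed)
  unexpr <- sort(sample.int(cf$n_probes, n_unexpr))
  expressed <- setdiff(seq_len(cf$n_probes), unexpr)
  responsive <- sort(sample(expressed, cf$n_resp))
  markers <- sort(sample(responsive, cf$n_mark))

  baseline <- numeric(cf$n_probes)
  baseline[expressed] <- rnorm(length(expressed), cf$baseline_mean,
                               cf$baseline_sd)
  baseline[unexpr] <- rnorm(n_unexpr, 3, 0.5)  # near the floor of 10 (2^3.32)

  delta <- numeric(cf$n_probes)
  sign_up <- ifelse(runif(cf$n_resp) < cf$prob_up, 1, -1)
  delta[responsive] <- sign_up * abs(rnorm(cf$n_resp, cf$delta_mean,
                                           cf$delta_sd))
  ## the severe-specific contrast amplifies the probe's own response
  ## direction: a cancelling sign would make the marker separate severe from
  ## not-severe *less* than amplitude alone, defeating its purpose
  marker_delta <- numeric(cf$n_probes)
  marker_delta[markers] <- sign(delta[markers]) *
    abs(rnorm(cf$n_mark, cf$marker_delta_mean, cf$marker_delta_sd))

  structure(list(n_probes = cf$n_probes,
                 probe_ids = sprintf("P%05d", seq_len(cf$n_probes)),
                 expressed = expressed, unexpressed = unexpr,
                 responsive = responsive, markers = markers,
                 baseline = baseline, delta = delta,
                 marker_delta = marker_delta),
            class = "sim_architecture")
}

#' Deterministic 8-probe x 6-sample preprocessing fixture
#'
#' A hand-constructed bundle exercising every preprocessing branch. Samples
#' are two medium controls (M1, M2) and four plasma-stimulated samples
#' (S1 uninfected, S2 not-severe, S3 severe, S4 severe collected after
#' 48 h), all in one batch, so every fold change references the mean of M1
#' and M2. Every column holds the same multiset of eight values, which makes
#' quantile normalization an exact no-op and keeps all downstream arithmetic
#' hand-checkable:
#'
#' * F1 — floored probe (medium 4/8 -> floored mean 10); in S3 it reaches 40
#'   (fold change 4 but difference only 30: fails the difference arm);
#' * F2 — the only probe with all detection p-values > 0.01 (fails PALO);
#' * F3 — hits S3 at exactly 2.0-fold and exactly 100 difference
#'   (boundary-inclusive selection);
#' * F4 — down-regulated in S3 (fold change 0.25, difference -300);
#' * F5 — floored probe, never responsive;
#' * F6 — moderate change in S2/S3 (fold change 0.6, difference -80: fails
#'   both arms);
#' * F7 — strong responder in S3 (fold change 8, difference 350); its
#'   detection p-value in M1 is exactly 0.01 (boundary-inclusive PALO);
#' * F8 — drifts without ever passing both arms.
#'
#' Running the full preprocessing chain must therefore keep exactly
#' `{F3, F4, F7}`.
#'
#' @return An `expression_bundle`.
#' @export
generate_micro_fixture <- function() {
  vals <- c(
    ## M1,  M2,  S1,  S2,  S3,  S4
        4,   8,   4,   4,  40,   8,   # F1
       40,  40,  40,  40,   4,  40,   # F2
      100, 100, 120, 100, 200, 120,   # F3
      400, 400, 400, 400, 100, 400,   # F4
        8,   4,   8,   8,   8,   4,   # F5
      200, 200, 200, 120, 120, 200,   # F6
       50,  50,  50,  50, 400,  50,   # F7
      120, 120, 100, 200,  50, 100)   # F8
  intens <- matrix(vals, nrow = 8, byrow = TRUE,
                   dimnames = list(paste0("F", 1:8),
                                   c("M1", "M2", "S1", "S2", "S3", "S4")))
  det <- matrix(0.001, 8, 6, dimnames = dimnames(intens))
  det["F2", ] <- 0.5                      # fails PALO everywhere
  det["F7", ] <- c(0.01, 0.02, 0.02, 0.02, 0.02, 0.02)  # kept at boundary
  meta <- data.frame(
    sample_id = colnames(intens),
    stimulus = c("medium", "medium", "plasma", "plasma", "plasma", "plasma"),
    plasma_group = c(NA, NA, "uninfected", "sepsis", "sepsis", "sepsis"),
    severity = c(NA, NA, NA, "not_severe", "severe", "severe"),
    collection_window = c(NA, NA, "within_48h", "within_48h", "within_48h",
                          "after_48h"),
    donor = "D1", cell_type = "PMN", batch = "b1",
    stringsAsFactors = FALSE)
  expression_bundle(intens, meta, det)
}
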