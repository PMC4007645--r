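## Normalization and filtering chain: quantile normalization -> intensity
## floor -> PALO detection filter -> fold change against medium-alone control
## means -> combined fold-change / intensity-difference differential filter.

#' Quantile-normalize an intensity matrix
#'
#' Rescales every column to the common reference distribution given by the
#' row means of the column-sorted matrix; ties within a column receive the
#' mean of the reference values they span, and the rank order within each
#' column is preserved. Delegates to [limma::normalizeQuantiles()].
#'
#' @param intensities non-negative numeric matrix with at least 2 columns.
#' @return Matrix of the same shape and dimnames.
#' @export
#' @examples
#' quantile_normalize(cbind(a = c(5, 2, 3), b = c(4, 1, 2)))
quantile_normalize <- function(intensities) {
  pr_assert(is.matrix(intensities) && is.numeric(intensities),
            "intensities must be a numeric matrix", "bundle_value_error")
  if (anyNA(intensities))
    pr_abort("NaN/NA present in intensity matrix", "bundle_value_error")
  if (ncol(intensities) < 2) {
    warning("quantile normalization is a no-op on a single-column matrix")
    return(intensities)
  }
  out <- limma::normalizeQuantiles(intensities, ties = TRUE)
  dimnames(out) <- dimnames(intensities)
  out
}

#' Floor intensities
#'
#' Replaces every entry below `floor_value` by `floor_value` (the assay
#' convention sets intensities below 10 to 10, which also guarantees
#' positive fold-change denominators).
#'
#' @param intensities numeric matrix.
#' @param floor_value the floor (default 10).
#' @return Matrix with `min(result) >= floor_value`.
#' @export
floor_intensities <- function(intensities, floor_value = 10) {
  pmax(intensities, floor_value)
}

#' PALO detection filter ("present in at least one sample")
#'
#' Retains a probe iff its detection p-value is `<= alpha` (inclusive) in at
#' least one sample.
#'
#' @param bundle an [expression_bundle()] with detection p-values.
#' @param alpha detection p-value cutoff (default 0.01).
#' @return List with `bundle` (probes subset consistently across matrices)
#'   and `kept_probe_ids`.
#' @export
palo_filter <- function(bundle, alpha = 0.01) {
  if (is.null(bundle$detection_p))
    pr_abort("PALO filtering requires detection p-values, which this bundle lacks",
             "detection_missing_error")
  keep <- apply(bundle$detection_p, 1, min) <= alpha
  kept_ids <- rownames(bundle$intensities)[keep]
  list(bundle = subset_probes(bundle, kept_ids), kept_probe_ids = kept_ids)
}

#' Fold change against medium-alone control means
#'
#' Within each (cell_type, batch) stratum, each plasma-stimulated sample is
#' referenced to the per-probe mean intensity of that stratum's medium-alone
#' cultures: `fc = intensity / medium_mean` (linear ratio),
#' `dif = intensity - medium_mean` (intensity units). Medium samples are
#' excluded from the output columns. The bundle is expected to be already
#' quantile-normalized and floored, so denominators are at least the floor.
#'
#' @param bundle an [expression_bundle()].
#' @return An object of class `fold_change_matrix` with fields `fc`,
#'   `log2_fc`, `dif` (probes x stimulated samples), `medium_mean` (probes x
#'   strata), `sample_stratum`, and the stimulated samples' `metadata`.
#' @export
fold_change <- function(bundle) {
  meta <- bundle$metadata
  stratum <- paste(meta$cell_type, meta$batch, sep = "/")
  stim <- meta$stimulus != "medium"
  strata <- unique(stratum)
  medium_mean <- sapply(strata, function(st) {
    cols <- which(stratum == st & !stim)
    if (!length(cols))
      pr_abort(paste("stratum without medium samples:", st),
               "bundle_medium_error")
    rowMeans(bundle$intensities[, cols, drop = FALSE])
  })
  medium_mean <- matrix(medium_mean, nrow = nrow(bundle$intensities),
                        dimnames = list(rownames(bundle$intensities), strata))
  ref <- medium_mean[, stratum[stim], drop = FALSE]
  x <- bundle$intensities[, stim, drop = FALSE]
  fc <- x / ref
  dif <- x - ref
  colnames(fc) <- colnames(dif) <- colnames(x)
  structure(list(fc = fc, log2_fc = log2(fc), dif = dif,
                 medium_mean = medium_mean,
                 sample_stratum = setNames(stratum[stim], colnames(x)),
                 metadata = meta[stim, , drop = FALSE]),
            class = "fold_change_matrix")
}

#' Differential filter on fold change and intensity difference ("2FC100DIF")
#'
#' Selects a probe iff at least `min_samples` stimulated samples satisfy
#' both `|log2 fc| >= log2(fc_threshold)` and `|dif| >= dif_threshold`
#' (both boundaries inclusive; down-regulation counts through the absolute
#' values).
#'
#' @param fcm a [fold_change()] result.
#' @param fc_threshold minimum linear fold change (default 2).
#' @param dif_threshold minimum absolute intensity difference (default 100).
#' @param min_samples samples that must pass both arms (default 1).
#' @return Character vector of selected probe ids.
#' @export
fc_dif_filter <- function(fcm, fc_threshold = 2, dif_threshold = 100,
                          min_samples = 1) {
  pass <- (abs(fcm$log2_fc) >= log2(fc_threshold)) &
    (abs(fcm$dif) >= dif_threshold)
  rownames(fcm$fc)[rowSums(pass) >= min_samples]
}

#' Run the full preprocessing chain
#'
#' Chains quantile normalization (within each (cell_type, batch) stratum,
#' matching the convention that each culture experiment is processed
#' independently), intensity flooring, the PALO detection filter, fold
#' change against medium-control means, and the differential filter.
#' Provenance records the probe count surviving each stage together with
#' the parameters used.
#'
#' @param bundle an [expression_bundle()] with detection p-values.
#' @param config a [run_config()].
#' @return A list of class `preprocess_result`: `fcm` (fold changes of all
#'   PALO-surviving probes), `selected_probes` (ids passing the differential
#'   filter), and `provenance`.
#' @export
run_preprocess <- function(bundle, config) {
  pr_assert(inherits(bundle, "expression_bundle"), "bundle required")
  pr_assert(inherits(config, "run_config"), "config must be a run_config")
  meta <- bundle$metadata
  stratum <- paste(meta$cell_type, meta$batch, sep = "/")
  norm <- bundle$intensities
  for (st in unique(stratum)) {
    cols <- stratum == st
    if (sum(cols) >= 2)
      norm[, cols] <- quantile_normalize(norm[, cols, drop = FALSE])
  }
  norm <- floor_intensities(norm, config$floor_value)
  floored <- expression_bundle(norm, meta, bundle$detection_p)
  palo <- palo_filter(floored, config$palo_alpha)
  fcm <- fold_change(palo$bundle)
  selected <- fc_dif_filter(fcm, config$fc_threshold, config$dif_threshold,
                            config$min_samples)
  provenance <- structure(list(
    n_input = nrow(bundle$intensities),
    n_palo = length(palo$kept_probe_ids),
    n_selected = length(selected),
    n_stimulated_samples = ncol(fcm$fc),
    params = config[c("palo_alpha", "floor_value", "fc_threshold",
                      "dif_threshold", "min_samples")]),
    class = "preprocess_provenance")
  structure(list(fcm = fcm, selected_probes = selected,
                 provenance = provenance),
            class = "preprocess_result")
}

#' Restrict a fold-change matrix to a probe subset
#'
#' @param fcm a `fold_change_matrix`.
#' @param probe_ids probes to keep (order preserved as given).
#' @return A `fold_change_matrix` over the subset.
#' @export
subset_fcm <- function(fcm, probe_ids) {
  idx <- match(probe_ids, rownames(fcm$fc))
  pr_assert(!anyNA(idx), "unknown probe id in fold-change subset",
            "bundle_shape_error")
  out <- fcm
  for (f in c("fc", "log2_fc", "dif", "medium_mean"))
    out[[f]] <- fcm[[f]][idx, , drop = FALSE]
  out
}
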