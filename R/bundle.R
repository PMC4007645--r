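## ExpressionBundle: the assay's raw readout — a probes x samples intensity
## matrix, an optional detection p-value matrix of the same shape, and a
## per-sample metadata table.

.metadata_cols <- c("sample_id", "stimulus", "plasma_group", "severity",
                    "collection_window", "donor", "cell_type", "batch")

.allowed_levels <- list(
  stimulus          = c("medium", "plasma"),
  plasma_group      = c("uninfected", "sepsis"),
  severity          = c("severe", "not_severe"),
  collection_window = c("within_48h", "after_48h")
)

#' Construct and validate an expression bundle
#'
#' An expression bundle holds background-subtracted probe intensities
#' (probes x samples, arbitrary fluorescence units), optional detection
#' p-values of identical shape, and sample metadata. Metadata rows are
#' reordered to match the intensity columns. Validation enforces: identical
#' shape and ordering of the two matrices, a one-to-one match between matrix
#' samples and metadata rows, known category levels, and at least one
#' medium-alone control sample in every (cell_type, batch) stratum (required
#' downstream as the fold-change reference).
#'
#' @param intensities numeric matrix, probes x samples, non-negative, with
#'   probe ids as rownames and sample ids as colnames.
#' @param metadata data.frame with columns `sample_id`, `stimulus`
#'   (medium/plasma), `plasma_group` (uninfected/sepsis, NA for medium),
#'   `severity` (severe/not_severe, NA otherwise), `collection_window`
#'   (within_48h/after_48h), `donor`, `cell_type`, `batch`.
#' @param detection_p optional numeric matrix in `[0, 1]`, same shape and
#'   dimnames as `intensities`.
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(intensities, metadata, detection_p = NULL) {
  pr_assert(is.matrix(intensities) && !is.null(rownames(intensities)) &&
              !is.null(colnames(intensities)),
            "intensities must be a matrix with probe rownames and sample colnames",
            "bundle_shape_error")
  if (!is.numeric(intensities) || anyNA(intensities))
    pr_abort("intensities contain non-numeric or missing cells",
             "bundle_value_error")
  if (any(intensities < 0))
    pr_abort("intensities must be non-negative", "bundle_value_error")

  if (!is.null(detection_p)) {
    if (!identical(dim(detection_p), dim(intensities)))
      pr_abort("detection_p and intensities have different shapes",
               "bundle_shape_error")
    if (!identical(dimnames(detection_p), dimnames(intensities)))
      pr_abort("detection_p and intensities have different probe/sample ordering",
               "bundle_shape_error")
    if (!is.numeric(detection_p) || anyNA(detection_p) ||
        any(detection_p < 0 | detection_p > 1))
      pr_abort("detection_p must be numeric in [0, 1]", "bundle_value_error")
  }

  pr_assert(is.data.frame(metadata), "metadata must be a data.frame",
            "bundle_metadata_error")
  missing_cols <- setdiff(.metadata_cols, names(metadata))
  if (length(missing_cols))
    pr_abort(paste("metadata lacks columns:",
                   paste(missing_cols, collapse = ", ")),
             "bundle_metadata_error")
  metadata <- as.data.frame(metadata)[, .metadata_cols]
  for (col in .metadata_cols)
    metadata[[col]] <- as.character(metadata[[col]])

  samples <- colnames(intensities)
  not_in_meta <- setdiff(samples, metadata$sample_id)
  if (length(not_in_meta))
    pr_abort(paste("samples present in matrix but absent from metadata:",
                   paste(not_in_meta, collapse = ", ")),
             "bundle_metadata_error")
  not_in_matrix <- setdiff(metadata$sample_id, samples)
  if (length(not_in_matrix))
    pr_abort(paste("samples present in metadata but absent from matrix:",
                   paste(not_in_matrix, collapse = ", ")),
             "bundle_metadata_error")
  if (anyDuplicated(metadata$sample_id))
    pr_abort("duplicated sample_id in metadata", "bundle_metadata_error")
  metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL

  for (col in names(.allowed_levels)) {
    vals <- metadata[[col]]
    bad <- !is.na(vals) & !(vals %in% .allowed_levels[[col]])
    if (any(bad))
      pr_abort(sprintf("unknown %s value(s): %s", col,
                       paste(unique(vals[bad]), collapse = ", ")),
               "bundle_metadata_error")
  }
  pr_assert(!anyNA(metadata$stimulus), "stimulus must not be NA",
            "bundle_metadata_error")

  strata <- split(metadata$stimulus,
                  paste(metadata$cell_type, metadata$batch, sep = "/"))
  no_medium <- names(strata)[!vapply(strata, function(s) any(s == "medium"),
                                     logical(1))]
  if (length(no_medium))
    pr_abort(paste("stratum without medium-alone control sample(s):",
                   paste(no_medium, collapse = ", ")),
             "bundle_medium_error")

  structure(list(intensities = intensities,
                 detection_p = detection_p,
                 metadata = metadata),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d probes x %d samples (%s detection p-values)\n",
              nrow(x$intensities), ncol(x$intensities),
              if (is.null(x$detection_p)) "no" else "with"))
  tab <- table(group_labels(x$metadata))
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Clinical group label for each sample
#'
#' Collapses the stimulus / plasma group / severity metadata into the label
#' used throughout the analysis: `medium`, `uninfected`, `not_severe` or
#' `severe`.
#'
#' @param metadata an expression-bundle metadata data.frame.
#' @return Character vector, one label per metadata row.
#' @export
group_labels <- function(metadata) {
  ifelse(metadata$stimulus == "medium", "medium",
         ifelse(metadata$plasma_group == "uninfected", "uninfected",
                metadata$severity))
}

## Subset a bundle to a set of probes (by id), keeping matrices aligned.
subset_probes <- function(bundle, probe_ids) {
  keep <- match(probe_ids, rownames(bundle$intensities))
  pr_assert(!anyNA(keep), "unknown probe id in subset", "bundle_shape_error")
  expression_bundle(bundle$intensities[keep, , drop = FALSE],
                    bundle$metadata,
                    if (!is.null(bundle$detection_p))
                      bundle$detection_p[keep, , drop = FALSE])
}
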