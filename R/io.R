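## On-disk artifacts. Matrices travel as plain TSV (header row = sample ids,
## first column = probe id, no quoting, UTF-8, GEO series-matrix style);
## structured stage products travel as JSON envelopes carrying a schema name,
## a schema version, and the parameters/seed that produced them.

.schema_version <- 1L

#' Write / read a probes-by-samples matrix as TSV
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path file path.
#' @return `read_tsv_matrix` returns a numeric matrix.
#' @export
write_tsv_matrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  pr_assert(file.exists(path), paste("no such file:", path), "io_error")
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    pr_abort(paste("non-numeric cell(s) in matrix file", path),
             "bundle_value_error")
  rownames(m) <- ids
  m
}

#' Read an expression bundle from TSV files
#'
#' Reads a background-subtracted intensity matrix, an optional detection
#' p-value matrix, and a sample metadata table, and returns a validated
#' [expression_bundle()]. Sample order is harmonised to the intensity
#' matrix; a detection file may be omitted, in which case the PALO stage
#' will later refuse to run.
#'
#' @param intensity_path TSV of intensities (first column probe id, header
#'   row sample ids).
#' @param detection_path optional TSV of detection p-values, same layout.
#' @param metadata_path TSV sample table with the columns documented in
#'   [expression_bundle()].
#' @return An `expression_bundle`.
#' @export
read_expression_bundle <- function(intensity_path, detection_path = NULL,
                                   metadata_path) {
  intens <- read_tsv_matrix(intensity_path)
  det <- if (!is.null(detection_path)) read_tsv_matrix(detection_path)
  meta <- read.delim(metadata_path, check.names = FALSE,
                     stringsAsFactors = FALSE,
                     colClasses = "character", na.strings = c("NA", ""))
  expression_bundle(intens, meta, det)
}

#' Write an expression bundle (and optionally its simulation truth) to a
#' directory
#'
#' @param bundle an `expression_bundle`.
#' @param dir output directory (created if absent).
#' @param truth optional `simulation_truth` record, written as JSON.
#' @return The directory, invisibly.
#' @export
write_expression_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_matrix(bundle$intensities, file.path(dir, "intensities.tsv"))
  if (!is.null(bundle$detection_p))
    write_tsv_matrix(bundle$detection_p, file.path(dir, "detection.tsv"))
  write.table(bundle$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(truth))
    write_stage_output(truth, file.path(dir, "truth.json"))
  invisible(dir)
}

## -- JSON payload encoding ---------------------------------------------------
## Matrices are encoded explicitly (column-major values + dims + dimnames) so
## that write-then-read is the identity up to floating-point text round-trip.

encode_payload <- function(x) {
  if (is.matrix(x)) {
    list(`_type` = "matrix", dim = dim(x),
         rownames = rownames(x), colnames = colnames(x),
         values = as.vector(x))
  } else if (is.data.frame(x)) {
    list(`_type` = "data.frame", columns = lapply(as.list(x), encode_payload),
         names = names(x))
  } else if (is.list(x)) {
    lapply(x, encode_payload)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)  # JSON object, so names survive the round trip
  } else x
}

decode_payload <- function(x) {
  if (is.list(x) && identical(x$`_type`, "matrix")) {
    m <- matrix(unlist(x$values), nrow = x$dim[[1]], ncol = x$dim[[2]])
    rownames(m) <- unlist(x$rownames)
    colnames(m) <- unlist(x$colnames)
    m
  } else if (is.list(x) && identical(x$`_type`, "data.frame")) {
    df <- lapply(x$columns, function(col) {
      col <- decode_payload(col)
      if (is.list(col)) unlist_with_na(col) else col
    })
    names(df) <- unlist(x$names)
    as.data.frame(df, stringsAsFactors = FALSE)
  } else if (is.list(x)) {
    lapply(x, decode_payload)
  } else x
}

#' Write / read a structured stage product as JSON
#'
#' Every stage product (simulation truth, preprocessing provenance,
#' amplitude scores, feature rankings, classifier evaluations, ...) is
#' written as a JSON envelope recording the product's schema name, a schema
#' version, and the object itself. Reading restores the original class;
#' write-then-read is the identity up to floating-point text round-trip.
#' A file with an unknown schema version is rejected.
#'
#' @param x a classed stage product (any pmnreporter result object).
#' @param path output `.json` path.
#' @return `read_stage_output` returns the restored object.
#' @export
write_stage_output <- function(x, path) {
  env <- list(schema = paste0("pmnreporter/", class(x)[1]),
              schema_version = .schema_version,
              payload = encode_payload(unclass(x)))
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_stage_output
#' @export
read_stage_output <- function(path) {
  pr_assert(file.exists(path), paste("no such file:", path), "io_error")
  env <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(env$schema_version) ||
      !identical(as.integer(env$schema_version), .schema_version))
    pr_abort(sprintf("unknown schema version '%s' in %s",
                     env$schema_version, path), "schema_version_error")
  pr_assert(is.character(env$schema) && startsWith(env$schema, "pmnreporter/"),
            paste("not a pmnreporter stage output:", path),
            "schema_version_error")
  obj <- decode_payload(env$payload)
  ## scalar leaves arrive as length-1 lists; flatten atomic vectors
  obj <- rapply(obj, f = identity, how = "replace")
  obj <- flatten_atomic(obj)
  class(obj) <- sub("^pmnreporter/", "", env$schema)
  obj
}

## unlist a list of scalars in which JSON nulls stand for NA; returns the
## list unchanged when the non-null elements are not of a single atomic type
unlist_with_na <- function(x) {
  null_el <- vapply(x, is.null, logical(1))
  kinds <- vapply(x, function(e)
    if (is.null(e)) "null"
    else if (is.atomic(e) && length(e) == 1 && !is.matrix(e)) class(e)[1]
    else "x", character(1))
  non_null <- unique(kinds[kinds != "null"])
  if (any(kinds == "x") || length(non_null) > 1) return(x)
  if (!length(non_null)) non_null <- "logical"  # all-null column
  x[null_el] <- list(switch(non_null, character = NA_character_,
                            integer = NA_integer_, numeric = NA_real_, NA))
  unlist(x)
}

## unwrap lists whose elements are all length-1 atomics (or nulls = NA) of
## one type
flatten_atomic <- function(x) {
  if (is.list(x) && is.null(x$`_type`)) {
    x <- lapply(x, flatten_atomic)
    if (length(x) > 0 && (is.null(names(x)) || !anyDuplicated(names(x))) &&
        any(!vapply(x, is.null, logical(1)))) {
      flat <- unlist_with_na(x)
      if (!is.list(flat)) return(flat)
    }
    x
  } else x
}
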