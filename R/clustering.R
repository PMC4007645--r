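## Hierarchical clustering of response transcripts (rows = transcripts,
## profiles across stimulated samples), Euclidean metric, complete linkage,
## and export of per-cluster gene lists for external enrichment tools.

#' Hierarchical clustering of transcript response profiles
#'
#' Agglomerative clustering of the rows of a log2 fold-change matrix with
#' the Euclidean metric and complete linkage (via [stats::hclust()], whose
#' tie-breaking is deterministic for a fixed input ordering).
#'
#' @param log2_fc_rows transcripts x samples numeric matrix (>= 2 rows).
#' @return An object of class `transcript_dendrogram` with `merge`,
#'   `height` (non-decreasing), `order` (leaf order), `labels`, and the
#'   underlying `hclust` object.
#' @export
hierarchical_cluster <- function(log2_fc_rows) {
  pr_assert(is.matrix(log2_fc_rows) && nrow(log2_fc_rows) >= 2,
            "need at least 2 rows to cluster")
  hc <- hclust(dist(log2_fc_rows, method = "euclidean"), method = "complete")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, hclust = hc),
            class = "transcript_dendrogram")
}

#' Cut a transcript dendrogram into k clusters
#'
#' Labels are renumbered 1..k in leaf order (the first leaf of the
#' dendrogram belongs to cluster 1).
#'
#' @param dendrogram a [hierarchical_cluster()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Integer vector of cluster labels, named by transcript, in the
#'   input row order.
#' @export
cut_clusters <- function(dendrogram, k) {
  n <- length(dendrogram$order)
  pr_assert(k >= 1 && k <= n, "k must be between 1 and the number of rows")
  raw <- cutree(dendrogram$hclust, k = k)
  leaf_first <- raw[dendrogram$order]
  relabel <- setNames(seq_along(unique(leaf_first)), unique(leaf_first))
  out <- relabel[as.character(raw)]
  setNames(as.integer(out), names(raw))
}

#' Export per-cluster gene lists
#'
#' Writes one plain-text gene list per cluster (one id per line, input order
#' preserved), the artifact consumed by external pathway/enrichment tools.
#' Probe ids are translated through `annotation` when given and used
#' verbatim otherwise.
#'
#' @param assignment named cluster vector from [cut_clusters()].
#' @param dir output directory (created if absent).
#' @param annotation optional named character vector mapping probe id to
#'   gene symbol.
#' @return Named character vector of file paths, one per cluster.
#' @export
export_cluster_gene_lists <- function(assignment, dir, annotation = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(assignment)
  genes <- if (is.null(annotation)) ids else {
    mapped <- annotation[ids]
    ifelse(is.na(mapped), ids, mapped)
  }
  ks <- sort(unique(assignment))
  paths <- vapply(ks, function(k) {
    p <- file.path(dir, sprintf("cluster_%02d.txt", k))
    writeLines(genes[assignment == k], p)
    p
  }, character(1))
  setNames(paths, paste0("cluster_", ks))
}
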