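## Response-amplitude statistics: PCA of the log2 fold-change responses,
## Euclidean distance of each sample from the uninfected-plasma centroid in
## the leading component space, and the Mann-Whitney U-test between severity
## groups.

#' Principal component analysis of log2 fold-change responses
#'
#' Samples are the observations and probes the variables. The decomposition
#' is per-probe mean-centred and unscaled (singular value decomposition via
#' [stats::prcomp()]), with components ordered by decreasing variance. PCA
#' signs are arbitrary, so each component's sign is fixed deterministically:
#' the largest-magnitude loading of every component is made positive.
#'
#' @param log2_fc_matrix probes x samples numeric matrix.
#' @return An object of class `pca_result` with `scores` (samples x
#'   components), `loadings` (probes x components, orthonormal columns),
#'   `variance_fraction`, and the `center` vector.
#' @export
run_pca <- function(log2_fc_matrix) {
  pr_assert(is.matrix(log2_fc_matrix) && ncol(log2_fc_matrix) >= 2,
            "need a matrix with at least 2 samples")
  x <- t(log2_fc_matrix)
  if (all(apply(x, 2, stats::var) < .Machine$double.eps))
    pr_abort("constant matrix: no variance to decompose",
             "constant_matrix_error")
  pr <- prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pr$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)
  loadings <- sweep(pr$rotation, 2, flip, `*`)
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = pr$sdev^2 / sum(pr$sdev^2),
                 center = pr$center),
            class = "pca_result")
}

#' Response amplitude: distance to the reference-group centroid
#'
#' The amplitude of each sample's transcriptional response is its Euclidean
#' distance, over the first `n_components` PCA scores, from the centroid of
#' the samples stimulated with reference (by default uninfected) plasma.
#' When both severity groups are present among the scored samples, the
#' severe versus not-severe comparison by [mann_whitney_u()] is attached.
#'
#' @param pca a [run_pca()] result whose score rows are named by sample.
#' @param metadata metadata rows matching the scored samples.
#' @param reference_group group label of the reference samples.
#' @param n_components number of leading components used (default 2).
#' @return An object of class `amplitude_scores`: a per-sample table of
#'   distances and group labels, the centroid, and the Mann-Whitney U and
#'   two-sided p-value for severe vs not-severe (NA when either group is
#'   absent).
#' @export
distance_to_reference <- function(pca, metadata,
                                  reference_group = "uninfected",
                                  n_components = 2) {
  scores <- pca$scores
  n_components <- min(n_components, ncol(scores))
  samples <- rownames(scores)
  meta <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  pr_assert(!anyNA(meta$sample_id), "metadata is missing scored samples",
            "bundle_metadata_error")
  group <- group_labels(meta)
  ref <- group == reference_group
  if (!any(ref))
    pr_abort(paste("empty reference group:", reference_group),
             "empty_group_error")
  sub <- scores[, seq_len(n_components), drop = FALSE]
  centroid <- colMeans(sub[ref, , drop = FALSE])
  dist_to_ref <- sqrt(rowSums(sweep(sub, 2, centroid)^2))
  u <- p <- NA_real_
  if (any(group == "severe") && any(group == "not_severe")) {
    mw <- mann_whitney_u(dist_to_ref[group == "severe"],
                         dist_to_ref[group == "not_severe"])
    u <- mw$U
    p <- mw$p_value
  }
  structure(list(samples = data.frame(sample_id = samples, group = group,
                                      distance = unname(dist_to_ref),
                                      stringsAsFactors = FALSE),
                 reference_group = reference_group,
                 n_components = n_components,
                 centroid = centroid,
                 U = u, p_value = p),
            class = "amplitude_scores")
}

#' Mann-Whitney U-test
#'
#' `U` counts the (x, y) pairs with `x > y` plus half the tied pairs (the
#' convention of [stats::wilcox.test()]'s W for `x` versus `y`). The p-value
#' is exact when the pooled sample size is at most 12 and there are no ties,
#' and otherwise uses the normal approximation with tie and continuity
#' corrections; a perfectly centred U (`U = n_x n_y / 2`) reports p = 1 by
#' symmetry.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `U` and `p_value`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y))
    pr_abort("both groups must be non-empty", "empty_group_error")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (nx + ny) <= 12
  p <- if (alternative == "two.sided" && u == nx * ny / 2) 1 else
    suppressWarnings(wilcox.test(x, y, alternative = alternative,
                                 exact = exact, correct = TRUE)$p.value)
  list(U = unname(u), p_value = unname(p))
}

#' Confidence ellipse of a bivariate score cloud
#'
#' Fits a bivariate normal by the sample mean and covariance and returns the
#' ellipse at the chi-square quantile for the requested level (plotting
#' support for PCA score plots).
#'
#' @param scores n x 2 numeric matrix (n >= 3).
#' @param level coverage level (default 0.95).
#' @return List with `center`, `semi_axes` (major, minor), `rotation`
#'   (radians, direction of the major axis) and `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  pr_assert(is.matrix(scores) && ncol(scores) == 2 && nrow(scores) >= 3,
            "scores must be an n x 2 matrix with n >= 3")
  center <- colMeans(scores)
  s <- cov(scores)
  e <- eigen(s, symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], .Machine$double.eps))
    pr_abort("degenerate covariance: scores lie on a line",
             "degenerate_covariance_error")
  radius2 <- qchisq(level, df = 2)
  list(center = center,
       semi_axes = sqrt(e$values * radius2),
       rotation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       level = level)
}
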