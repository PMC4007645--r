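test_that("PCA puts collinear samples on a single component", {
  m <- rbind(p1 = c(0, 1, 2), p2 = c(0, 1, 2))
  colnames(m) <- c("a", "b", "c")
  pca <- run_pca(m)
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("PCA reconstructs the centred input and matches a covariance
           eigendecomposition oracle", {
  set.seed(10)
  m <- matrix(rnorm(20), 4, 5,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  pca <- run_pca(m)
  x <- t(m)
  centred <- sweep(x, 2, colMeans(x))
  expect_equal(pca$scores %*% t(pca$loadings), centred, tolerance = 1e-8,
               ignore_attr = TRUE)
  gram <- t(pca$loadings) %*% pca$loadings
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-9)
  ## independent oracle: eigenvalues of the sample covariance
  ev <- sort(eigen(cov(centred), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(pca$variance_fraction, ev / sum(ev), tolerance = 1e-8)
  ## sign convention: the dominant loading of every component is positive
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("PCA rejects a constant matrix", {
  m <- matrix(3, 4, 5, dimnames = list(paste0("p", 1:4), paste0("s", 1:5)))
  expect_error(run_pca(m), class = "constant_matrix_error")
})

test_that("distance to reference follows plane geometry", {
  scores <- rbind(u1 = c(-3, -4), u2 = c(3, 4), s1 = c(3, 4), s2 = c(0, 0))
  pca <- structure(list(scores = scores), class = "pca_result")
  meta <- data.frame(sample_id = rownames(scores),
                     stimulus = "plasma",
                     plasma_group = c("uninfected", "uninfected",
                                      "sepsis", "sepsis"),
                     severity = c(NA, NA, "severe", "severe"),
                     collection_window = "within_48h", donor = "D1",
                     cell_type = "PMN", batch = "b1",
                     stringsAsFactors = FALSE)
  sc <- distance_to_reference(pca, meta)
  d <- setNames(sc$samples$distance, sc$samples$sample_id)
  ## reference centroid is the origin; the 3-4-5 triangle
  expect_equal(unname(d["s1"]), 5)
  expect_equal(unname(d["s2"]), 0)
  expect_equal(unname(d["u1"]), 5)
  ## mean reference distance equals mean norm of centred reference scores
  ref <- scores[1:2, ]
  centred <- sweep(ref, 2, colMeans(ref))
  expect_equal(mean(d[c("u1", "u2")]), mean(sqrt(rowSums(centred^2))))
})

test_that("distances are invariant under translating all scores", {
  sim <- small_sim(6)
  pp <- run_preprocess(sim$bundle, run_config(seed = 6))
  sel <- subset_fcm(pp$fcm, pp$selected_probes)
  pca <- run_pca(sel$log2_fc)
  d1 <- distance_to_reference(pca, sel$metadata)$samples$distance
  shifted <- pca
  shifted$scores <- sweep(pca$scores, 2,
                          seq_len(ncol(pca$scores)), `+`)
  d2 <- distance_to_reference(shifted, sel$metadata)$samples$distance
  expect_equal(d1, d2, tolerance = 1e-9)
  ## empty reference group errors
  meta <- sel$metadata
  meta$plasma_group[meta$plasma_group == "uninfected"] <- "sepsis"
  meta$severity[is.na(meta$severity) & meta$stimulus == "plasma"] <- "severe"
  expect_error(distance_to_reference(pca, meta),
               class = "empty_group_error")
})

test_that("Mann-Whitney matches enumeration on small samples", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-9)
  expect_equal(mw$p_value, oracle_mw_exact(c(1, 2), c(3, 4)),
               tolerance = 1e-9)
  ## identical groups are perfectly null
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  ## exact enumeration oracle on random tie-free data
  set.seed(11)
  for (i in 1:10) {
    x <- round(rnorm(4), 6); y <- round(rnorm(5) + 0.5, 6)
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mw_exact(x, y),
                 tolerance = 1e-9)
  }
  expect_error(mann_whitney_u(numeric(0), 1), class = "empty_group_error")
})

test_that("normal approximation tracks enumeration for moderate samples", {
  set.seed(12)
  for (i in 1:5) {
    x <- rnorm(6); y <- rnorm(6) + 0.8
    approx_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(approx_p - oracle_mw_exact(x, y)), 0.02)
    ## and our U is wilcox.test's W
    expect_equal(mann_whitney_u(x, y)$U,
                 unname(wilcox.test(x, y)$statistic))
  }
})

test_that("confidence ellipse hits the chi-square radius on isotropic data", {
  set.seed(13)
  n <- 4000
  scores <- cbind(rnorm(n), rnorm(n))
  ell <- confidence_ellipse(scores, level = 0.95)
  r <- sqrt(qchisq(0.95, 2))  # 2.4477
  expect_equal(unname(ell$semi_axes), c(r, r), tolerance = 0.05)
  expect_equal(unname(ell$center), c(0, 0), tolerance = 0.06)
})

test_that("confidence ellipse is rotation-equivariant and rejects lines", {
  set.seed(14)
  scores <- cbind(rnorm(40, sd = 3), rnorm(40, sd = 1))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  e1 <- confidence_ellipse(scores)
  e2 <- confidence_ellipse(scores %*% t(rot))
  expect_equal(e2$semi_axes, e1$semi_axes, tolerance = 1e-8)
  expect_equal(e2$center, unname(as.vector(rot %*% e1$center)),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## major-axis direction rotates with the data (up to sign)
  v1 <- c(cos(e1$rotation), sin(e1$rotation))
  v2 <- c(cos(e2$rotation), sin(e2$rotation))
  expect_equal(abs(sum((rot %*% v1) * v2)), 1, tolerance = 1e-8)
  line <- cbind(1:5, 2 * (1:5) + 3)
  expect_error(confidence_ellipse(line),
               class = "degenerate_covariance_error")
})
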