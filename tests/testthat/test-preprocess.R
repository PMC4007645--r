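test_that("quantile normalization matches the hand-computed reference", {
  m <- cbind(s1 = c(5, 2, 3), s2 = c(4, 1, 2))
  ## sorted columns (2,3,5) and (1,2,4); row means (1.5, 2.5, 4.5)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(4.5, 1.5, 2.5))
  expect_equal(unname(out[, 2]), c(4.5, 1.5, 2.5))
})

test_that("quantile normalization is idempotent and a fixed point on equal columns", {
  set.seed(1)
  m <- matrix(rexp(60, 1 / 300), 15, 4,
              dimnames = list(paste0("p", 1:15), paste0("s", 1:4)))
  once <- quantile_normalize(m)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)
  same <- matrix(rep(sort(rexp(10, 1 / 300)), 3), 10, 3,
                 dimnames = list(paste0("p", 1:10), paste0("s", 1:3)))
  expect_equal(quantile_normalize(same), same)
})

test_that("quantile normalization preserves ranks and equalises column sums", {
  set.seed(2)
  for (i in 1:100) {
    m <- matrix(runif(40, 0, 1000), 10, 4)
    dimnames(m) <- list(paste0("p", 1:10), paste0("s", 1:4))
    out <- quantile_normalize(m)
    sums <- colSums(out)
    expect_lt(max(sums) - min(sums), 1e-8)
    for (j in 1:4)
      expect_identical(order(out[, j]), order(m[, j]))
  }
})

test_that("quantile normalization rejects NaN and warns on single columns", {
  m <- cbind(a = c(1, NaN), b = c(2, 3))
  rownames(m) <- c("p1", "p2")
  expect_error(quantile_normalize(m), class = "bundle_value_error")
  single <- cbind(a = c(1, 2)); rownames(single) <- c("p1", "p2")
  expect_warning(out <- quantile_normalize(single), "single-column")
  expect_equal(out, single)
})

test_that("flooring clamps low intensities and nothing else", {
  expect_equal(floor_intensities(c(12, 9.5, 0, 10)), c(12, 10, 10, 10))
  m <- matrix(c(100, 11, 10.0001, 50), 2)
  expect_equal(floor_intensities(m), m)
  set.seed(3)
  out <- floor_intensities(matrix(runif(50, -5, 100), 10, 5))
  expect_gte(min(out), 10)
})

test_that("PALO keeps a probe iff min detection p <= alpha, boundary inclusive", {
  b <- make_toy_bundle()
  det <- b$detection_p
  det["P01", ] <- c(0.005, rep(0.5, 7))   # kept
  det["P02", ] <- c(0.01, rep(0.9, 7))    # kept: boundary inclusive
  det["P03", ] <- c(0.02, 0.011, rep(0.7, 6))  # dropped
  b2 <- expression_bundle(b$intensities, b$metadata, det)
  res <- palo_filter(b2, alpha = 0.01)
  expect_true(all(c("P01", "P02") %in% res$kept_probe_ids))
  expect_false("P03" %in% res$kept_probe_ids)
  expect_identical(rownames(res$bundle$intensities), res$kept_probe_ids)
  expect_identical(dim(res$bundle$intensities), dim(res$bundle$detection_p))
})

test_that("fold change references each stratum's own medium mean", {
  b <- make_toy_bundle()
  intens <- b$intensities
  intens["P01", ] <- c(100, 440, 110, 110, 120, 500, 120, 120)
  ## b1 medium is T01 only (mean 100); b2 medium is T05 (mean 120)
  b2 <- expression_bundle(intens, b$metadata, b$detection_p)
  fcm <- fold_change(b2)
  expect_equal(fcm$fc["P01", "T02"], 4.4)
  expect_equal(fcm$dif["P01", "T02"], 340)
  expect_equal(fcm$fc["P01", "T06"], 500 / 120)
  expect_equal(fcm$dif["P01", "T06"], 500 - 120)
  ## identity sample: fc 1, dif 0
  expect_equal(fcm$fc["P01", "T03"], 1.1)
  expect_false(any(fcm$metadata$stimulus == "medium"))
  expect_equal(fcm$fc, 2^fcm$log2_fc, tolerance = 1e-9)
})

test_that("two-medium average gives fc 4 / dif 330 on the worked example", {
  meta <- data.frame(sample_id = c("M1", "M2", "S1"),
                     stimulus = c("medium", "medium", "plasma"),
                     plasma_group = c(NA, NA, "sepsis"),
                     severity = c(NA, NA, "severe"),
                     collection_window = c(NA, NA, "within_48h"),
                     donor = "D1", cell_type = "PMN", batch = "b1",
                     stringsAsFactors = FALSE)
  m <- matrix(c(100, 120, 440), 1, 3,
              dimnames = list("P1", meta$sample_id))
  fcm <- fold_change(expression_bundle(m, meta))
  expect_equal(unname(fcm$fc["P1", "S1"]), 4.0)
  expect_equal(unname(fcm$dif["P1", "S1"]), 330)
})

test_that("fold change is scale covariant within a stratum", {
  b <- make_toy_bundle()
  fcm <- fold_change(b)
  scaled <- b$intensities
  scaled[, b$metadata$batch == "b1"] <- 3 * scaled[, b$metadata$batch == "b1"]
  fcm2 <- fold_change(expression_bundle(scaled, b$metadata, b$detection_p))
  b1_cols <- fcm$metadata$sample_id[fcm$metadata$batch == "b1"]
  expect_equal(fcm2$fc[, b1_cols], fcm$fc[, b1_cols], tolerance = 1e-12)
  expect_equal(fcm2$dif[, b1_cols], 3 * fcm$dif[, b1_cols], tolerance = 1e-12)
})

test_that("differential filter is boundary inclusive and two-sided", {
  fc <- rbind(A = c(2.0, 1.0), B = c(3.0, 3.0), C = c(0.5, 1.0),
              D = c(1.9, 1.0))
  dif <- rbind(A = c(100, 0), B = c(50, 50), C = c(-150, 10),
               D = c(500, 0))
  colnames(fc) <- colnames(dif) <- c("S1", "S2")
  fcm <- structure(list(fc = fc, log2_fc = log2(fc), dif = dif),
                   class = "fold_change_matrix")
  sel <- fc_dif_filter(fcm)
  expect_true("A" %in% sel)           # exactly 2-fold and exactly 100
  expect_false("B" %in% sel)          # fold change fine, difference too small
  expect_true("C" %in% sel)           # down-regulation counts
  expect_false("D" %in% sel)          # difference fine, fold change short
  ## min_samples conjunct
  expect_false("A" %in% fc_dif_filter(fcm, min_samples = 2))
  ## degenerate thresholds select everything
  expect_setequal(fc_dif_filter(fcm, fc_threshold = 0, dif_threshold = 0),
                  rownames(fc))
})

test_that("the micro fixture survives preprocessing exactly as documented", {
  b <- generate_micro_fixture()
  ## constructed properties: one PALO-failing probe, one exact 2FC100DIF hit
  expect_identical(rownames(b$detection_p)[apply(b$detection_p, 1, min) > 0.01],
                   "F2")
  cfg <- run_config(seed = 1)
  pp <- run_preprocess(b, cfg)
  expect_setequal(pp$selected_probes, c("F3", "F4", "F7"))
  expect_equal(unname(pp$fcm$fc["F3", "S3"]), 2.0)
  expect_equal(unname(pp$fcm$dif["F3", "S3"]), 100)
  hits <- abs(pp$fcm$fc - 2) < 1e-9 & abs(pp$fcm$dif - 100) < 1e-9
  expect_equal(sum(hits), 1L)
  ## provenance counts are non-increasing through the chain
  prov <- pp$provenance
  expect_true(prov$n_input >= prov$n_palo && prov$n_palo >= prov$n_selected)
  expect_equal(c(prov$n_input, prov$n_palo, prov$n_selected), c(8, 7, 3))
})

test_that("probe selection is stable under sample column permutation", {
  sim <- small_sim(5)
  cfg <- run_config(seed = 5)
  sel1 <- run_preprocess(sim$bundle, cfg)$selected_probes
  perm <- sample(ncol(sim$bundle$intensities))
  b2 <- expression_bundle(sim$bundle$intensities[, perm],
                          sim$bundle$metadata[perm, ],
                          sim$bundle$detection_p[, perm])
  sel2 <- run_preprocess(b2, cfg)$selected_probes
  expect_setequal(sel1, sel2)
})
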