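## Independent brute-force oracles, deliberately written with the plainest
## possible double loops so they share no code path with the implementation.

## kNN prediction for one query by explicit pair distances; ties on distance
## broken by smaller training index, vote ties by the nearest neighbour.
oracle_knn_one <- function(train, labels, query, k) {
  d <- apply(train, 1, function(row) sqrt(sum((row - query)^2)))
  nn <- order(d)[1:k]
  counts <- table(labels[nn])
  winners <- names(counts)[counts == max(counts)]
  if (length(winners) == 1) winners else labels[nn[1]]
}

oracle_loocv <- function(x, labels, k) {
  hits <- 0
  for (i in seq_len(nrow(x))) {
    pred <- oracle_knn_one(x[-i, , drop = FALSE], labels[-i],
                           x[i, ], k)
    if (pred == labels[i]) hits <- hits + 1
  }
  hits / nrow(x)
}

## exact two-sided Mann-Whitney p-value by complete enumeration of label
## assignments (tie-free data only)
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xs, ys) sum(outer(xs, ys, `>`))
  obs <- u_stat(x, y)
  mu <- nx * ny / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  mean(abs(us - mu) >= abs(obs - mu))
}

## AUC by explicit concordant-pair counting
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## small two-stratum bundle used across io/preprocess tests
make_toy_bundle <- function(detection = TRUE) {
  set.seed(42)
  n_probes <- 12
  meta <- data.frame(
    sample_id = sprintf("T%02d", 1:8),
    stimulus = c("medium", "plasma", "plasma", "plasma",
                 "medium", "plasma", "plasma", "plasma"),
    plasma_group = c(NA, "uninfected", "sepsis", "sepsis",
                     NA, "uninfected", "sepsis", "sepsis"),
    severity = c(NA, NA, "severe", "not_severe",
                 NA, NA, "severe", "not_severe"),
    collection_window = c(NA, rep("within_48h", 3), NA, rep("within_48h", 3)),
    donor = "D1", cell_type = "PMN",
    batch = rep(c("b1", "b2"), each = 4),
    stringsAsFactors = FALSE)
  intens <- matrix(round(runif(n_probes * 8, 20, 4000), 2), n_probes, 8,
                   dimnames = list(sprintf("P%02d", 1:n_probes),
                                   meta$sample_id))
  det <- if (detection)
    matrix(round(runif(n_probes * 8, 0, 0.009), 5), n_probes, 8,
           dimnames = dimnames(intens))
  expression_bundle(intens, meta, det)
}

## tiny simulated cohort shared by slower tests
small_sim <- function(seed, n_probes = 400, n_resp = 60, n_mark = 12,
                      n_uninfected = 6, n_severe = 7, n_not_severe = 5, ...) {
  generate_bundle(sim_config(n_probes = n_probes, n_resp = n_resp,
                             n_mark = n_mark, n_uninfected = n_uninfected,
                             n_severe = n_severe,
                             n_not_severe = n_not_severe, seed = seed, ...))
}
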