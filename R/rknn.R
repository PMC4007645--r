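## Random k-nearest-neighbour feature selection (RKNN-FS): an ensemble of
## kNN base classifiers, each built on a random feature subset, scores every
## feature by the mean leave-one-out accuracy of the base models containing
## it ("support"); geometric backward elimination repeatedly keeps the
## best-supported features until a small panel remains. All tie rules are
## deterministic so an entire elimination path is reproducible from
## (data, parameters, seed).

## integer labels + level bookkeeping shared by the kNN routines
.as_label_int <- function(labels) {
  f <- factor(labels)
  list(int = as.integer(f), levels = levels(f))
}

## majority vote over the k nearest rows of a distance row; distance ties are
## broken by the smaller training index (stable order()), vote ties by the
## class of the single nearest neighbour
.vote <- function(dist_row, train_int, k, n_levels) {
  nn <- order(dist_row)[seq_len(k)]
  votes <- tabulate(train_int[nn], nbins = n_levels)
  top <- which(votes == max(votes))
  if (length(top) == 1L) top else train_int[nn[1L]]
}

#' k-nearest-neighbour classification
#'
#' Euclidean metric on the given feature columns; majority vote among the k
#' nearest training samples. Distance ties are broken by the smaller
#' training-sample index and vote ties by the class of the single nearest
#' neighbour, so predictions are deterministic.
#'
#' @param train n_train x p numeric matrix.
#' @param train_labels class labels of the training rows.
#' @param query n_query x p numeric matrix.
#' @param k neighbours (default 5); must not exceed `nrow(train)`.
#' @return Character vector of predicted labels, one per query row.
#' @export
knn_classify <- function(train, train_labels, query, k = 5) {
  train <- as.matrix(train); query <- as.matrix(query)
  pr_assert(k <= nrow(train), "k exceeds the number of training samples")
  pr_assert(length(train_labels) == nrow(train),
            "one label per training row required")
  lab <- .as_label_int(train_labels)
  d2 <- outer(rowSums(query^2), rowSums(train^2), `+`) -
    2 * tcrossprod(query, train)
  d2[d2 < 0] <- 0
  pred <- vapply(seq_len(nrow(query)), function(i)
    .vote(d2[i, ], lab$int, k, length(lab$levels)), integer(1))
  lab$levels[pred]
}

#' Leave-one-out cross-validated kNN accuracy
#'
#' Each sample is classified by [knn_classify()] trained on the other n-1
#' samples, restricted to the given feature subset; the result is the
#' fraction classified correctly.
#'
#' @param x n x p numeric matrix (samples x features).
#' @param labels class labels, length n.
#' @param features optional column subset (indices or names); default all.
#' @param k neighbours (default 5); requires `n >= k + 1`.
#' @return Accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(x, labels, features = NULL, k = 5) {
  x <- as.matrix(x)
  if (!is.null(features)) x <- x[, features, drop = FALSE]
  n <- nrow(x)
  pr_assert(n >= k + 1, "need at least k + 1 samples for leave-one-out")
  lab <- .as_label_int(labels)
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  correct <- 0L
  for (i in seq_len(n))
    if (.vote(d[i, ], lab$int, k, length(lab$levels)) == lab$int[i])
      correct <- correct + 1L
  correct / n
}

#' Fit a random-kNN ensemble
#'
#' Draws `r` feature subsets of size `m` (uniformly without replacement
#' within a subset, independently across base models) from the seeded
#' stream, and scores every base model by its leave-one-out accuracy on its
#' subset.
#'
#' @param x n x p numeric matrix (samples x features, named columns).
#' @param labels class labels, length n.
#' @param r number of base models.
#' @param m features per base model (`1 <= m <= p`); default
#'   `floor(sqrt(p))`.
#' @param k neighbours per base model (default 5).
#' @param seed seed for the subset stream (mandatory).
#' @param subsets optional explicit list of feature-index vectors overriding
#'   random sampling (then `r = length(subsets)`).
#' @return An object of class `rknn_model` with the subsets, per-model
#'   accuracies, and parameters.
#' @export
fit_rknn <- function(x, labels, r, m = NULL, k = 5, seed = NULL,
                     subsets = NULL) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (is.null(m)) m <- max(1L, floor(sqrt(p)))
  pr_assert(m >= 1 && m <= p, "need 1 <= m <= p")
  if (is.null(subsets)) {
    pr_assert(!is.null(seed), "seed is mandatory for random subset draws")
    pr_assert(r >= 1, "need r >= 1")
    set.seed(seed)
    subsets <- lapply(seq_len(r), function(i) sort(sample.int(p, m)))
  } else {
    r <- length(subsets)
  }
  accuracies <- vapply(subsets, function(s)
    loocv_accuracy(x, labels, features = s, k = k), numeric(1))
  structure(list(subsets = subsets, accuracies = accuracies,
                 feature_names = colnames(x),
                 r = r, m = m, k = k, seed = seed),
            class = "rknn_model")
}

#' Per-feature support scores of a random-kNN ensemble
#'
#' The support of a feature is the mean leave-one-out accuracy of the base
#' models whose subset contains it. Features covered by no base model have
#' undefined support and rank last; ranking is by descending support with
#' ties broken by feature id.
#'
#' @param model a [fit_rknn()] result.
#' @return A data.frame (class `feature_support`) with columns `feature`,
#'   `coverage` and `support`, sorted by rank.
#' @export
feature_support <- function(model) {
  p <- length(model$feature_names)
  idx <- unlist(model$subsets)
  acc <- rep(model$accuracies, lengths(model$subsets))
  coverage <- tabulate(idx, nbins = p)
  acc_sum <- numeric(p)
  tapply_sum <- tapply(acc, idx, sum)
  acc_sum[as.integer(names(tapply_sum))] <- tapply_sum
  support <- ifelse(coverage > 0, acc_sum / coverage, NA_real_)
  out <- data.frame(feature = model$feature_names, coverage = coverage,
                    support = support, stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$support), -Inf, out$support),
                   out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("feature_support", "data.frame")
  out
}

#' Geometric backward elimination over random-kNN support
#'
#' Repeatedly fits a random-kNN ensemble on the current feature set, ranks
#' features by support, and keeps the top `ceil(keep_ratio * p)` (always at
#' least one fewer), until at most `floor_features` remain. The winning
#' stage is the one with the highest mean base-model accuracy (ties go to
#' the smaller feature set); the selected panel is that stage's top
#' `n_select` features by support, and its leave-one-out accuracy is
#' reported; the winning-stage search considers only stages still holding at
#' least `n_select` features (all stages when none is that large). Each
#' stage draws its subsets from a seed derived from `seed`
#' and the stage number, so the whole path is reproducible.
#'
#' @param x n x p numeric matrix (samples x features, named columns).
#' @param labels class labels, length n.
#' @param r base models per stage.
#' @param m features per base model; default `floor(sqrt(p_current))`,
#'   recomputed at every stage.
#' @param k neighbours (default 5).
#' @param keep_ratio fraction of features kept per stage (default 0.8).
#' @param floor_features stop once at most this many features remain
#'   (default 10).
#' @param n_select size of the selected panel (default 30); when the
#'   winning stage is smaller, the whole stage set is selected.
#' @param seed master seed for the elimination path (mandatory).
#' @param standardize z-score every feature before computing distances
#'   (default TRUE). The Euclidean metric is scale-sensitive: without
#'   standardisation, transcripts with large fold-change dynamic range
#'   dominate every distance and low-amplitude but highly discriminative
#'   transcripts become invisible to the ensemble.
#' @param sample_ids optional ids of the samples behind `x`, recorded as
#'   provenance so that later evaluation can refuse a leaking panel.
#' @return An object of class `feature_ranking`: the elimination `path`
#'   (stage sizes and mean accuracies), the winning stage's support table,
#'   `selected` features, `loocv_accuracy` of the panel, and provenance.
#' @export
geometric_backward_elimination <- function(x, labels, r, m = NULL, k = 5,
                                           keep_ratio = 0.8,
                                           floor_features = 10,
                                           n_select = 30, seed = NULL,
                                           standardize = TRUE,
                                           sample_ids = NULL) {
  x <- as.matrix(x)
  pr_assert(!is.null(colnames(x)), "x must have feature (column) names")
  if (standardize) {
    sg <- apply(x, 2, sd)
    sg[sg == 0] <- 1
    x <- sweep(sweep(x, 2, colMeans(x)), 2, sg, `/`)
  }
  pr_assert(!is.null(seed), "seed is mandatory")
  pr_assert(keep_ratio > 0 && keep_ratio < 1,
            "keep_ratio must be in (0, 1)")
  pr_assert(ncol(x) >= floor_features,
            "fewer features than floor_features")
  current <- colnames(x)
  stages <- list()
  supports <- list()
  stage_no <- 0L
  repeat {
    stage_no <- stage_no + 1L
    p_cur <- length(current)
    m_cur <- if (is.null(m)) max(1L, floor(sqrt(p_cur))) else min(m, p_cur)
    model <- fit_rknn(x[, current, drop = FALSE], labels, r = r, m = m_cur,
                      k = k,
                      seed = stage_seed(seed, paste0("stage", stage_no)))
    supp <- feature_support(model)
    stages[[stage_no]] <- list(n_features = p_cur,
                               mean_accuracy = mean(model$accuracies),
                               m = m_cur)
    supports[[stage_no]] <- supp
    if (p_cur <= floor_features) break
    n_keep <- min(ceiling(keep_ratio * p_cur), p_cur - 1L)
    current <- supp$feature[seq_len(n_keep)]
  }
  path <- data.frame(stage = seq_along(stages),
                     n_features = vapply(stages, `[[`, numeric(1),
                                         "n_features"),
                     m = vapply(stages, `[[`, numeric(1), "m"),
                     mean_accuracy = vapply(stages, `[[`, numeric(1),
                                            "mean_accuracy"))
  ## winning stage: highest mean accuracy, ties to the smaller feature set.
  ## The search is restricted to stages that can still supply a full panel
  ## (>= n_select features) so the selected set has the intended size; when
  ## no stage is that large the whole path competes.
  eligible <- which(path$n_features >= n_select)
  if (!length(eligible)) eligible <- seq_len(nrow(path))
  win <- eligible[order(-path$mean_accuracy[eligible],
                        path$n_features[eligible])[1]]
  win_supp <- supports[[win]]
  selected <- win_supp$feature[seq_len(min(n_select, nrow(win_supp)))]
  structure(list(path = path,
                 winning_stage = win,
                 support = win_supp,
                 selected = selected,
                 loocv_accuracy = loocv_accuracy(x, labels,
                                                 features = selected, k = k),
                 params = list(r = r, m = m, k = k, keep_ratio = keep_ratio,
                               floor_features = floor_features,
                               n_select = n_select, seed = seed),
                 provenance = list(sample_ids = sample_ids,
                                   n_samples = nrow(x),
                                   n_features = ncol(x))),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("feature_ranking: %d stages, winning stage %d (%d features, mean base accuracy %.3f)\n",
              nrow(x$path), x$winning_stage,
              x$path$n_features[x$winning_stage],
              x$path$mean_accuracy[x$winning_stage]))
  cat(sprintf("  selected panel: %d features, LOOCV accuracy %.3f\n",
              length(x$selected), x$loocv_accuracy))
  invisible(x)
}
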