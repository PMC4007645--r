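## Severity prediction on the selected marker panel: an RBF-kernel support
## vector machine and a random forest, evaluated one-vs-rest on an
## independent cohort with ROC curves, AUC, and stratified-bootstrap
## confidence intervals.

#' Train a classifier and score an independent test cohort
#'
#' Fits the requested model on the training cohort only, after
#' standardising every feature with training-cohort mean and sd (sd 0 maps
#' to 1), and returns a continuous score per test sample for the target
#' class together with predicted labels. For the margin classifier the
#' score is the decision value; for the tree ensemble it is the
#' out-of-the-box class probability. Deterministic given the seed.
#'
#' @param train_x,train_labels training cohort (samples x features) and
#'   labels (>= 2 classes).
#' @param test_x test cohort with the same feature columns.
#' @param kind `"svm"` (radial-basis kernel, cost 1) or `"rf"` (500 trees).
#' @param target the class whose score is reported (default: first level).
#' @param seed seed for any model randomness.
#' @return List with `score` (numeric, higher means more target-like),
#'   `predicted` (character labels) and `kind`.
#' @export
train_and_score <- function(train_x, train_labels, test_x,
                            kind = c("svm", "rf"), target = NULL,
                            seed = 1L) {
  kind <- match.arg(kind)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  missing_f <- setdiff(colnames(train_x), colnames(test_x))
  if (length(missing_f))
    pr_abort(paste("features missing from test cohort:",
                   paste(head(missing_f, 5), collapse = ", ")),
             "bundle_shape_error")
  test_x <- test_x[, colnames(train_x), drop = FALSE]
  y <- factor(train_labels)
  if (nlevels(y) < 2)
    pr_abort("training labels contain a single class", "single_class_error")
  if (is.null(target)) target <- levels(y)[1]
  pr_assert(target %in% levels(y), "target must be a training class")

  mu <- colMeans(train_x)
  sg <- apply(train_x, 2, sd)
  sg[sg == 0] <- 1
  tr <- sweep(sweep(train_x, 2, mu), 2, sg, `/`)
  te <- sweep(sweep(test_x, 2, mu), 2, sg, `/`)

  set.seed(seed)
  if (kind == "svm") {
    fit <- e1071::svm(tr, y, kernel = "radial", cost = 1, scale = FALSE,
                      probability = FALSE)
    pred <- predict(fit, te, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    score <- numeric(nrow(te))
    ## orient every pairwise decision value toward the target class
    for (j in seq_len(ncol(dv))) {
      pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
      if (pair[1] == target) score <- score + dv[, j]
      else if (pair[2] == target) score <- score - dv[, j]
    }
    predicted <- as.character(pred)
  } else {
    fit <- randomForest::randomForest(tr, y, ntree = 500)
    prob <- predict(fit, te, type = "prob")
    score <- prob[, target]
    predicted <- as.character(predict(fit, te, type = "response"))
  }
  list(score = unname(score), predicted = predicted, kind = kind)
}

#' ROC curve
#'
#' Thresholds at the distinct score values (descending), tied scores
#' grouped so ties produce diagonal segments. The curve starts at (0, 0)
#' and ends at (1, 1) and is monotone non-decreasing in both coordinates.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or two-valued vector; `TRUE` (or the larger level)
#'   marks the positive class.
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tie group
  tp <- cumsum(p)[keep]
  fp <- cumsum(!p)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / sum(!pos)),
             tpr = c(0, tp / sum(pos)))
}

as_positive <- function(labels) {
  if (is.logical(labels)) pos <- labels
  else {
    u <- sort(unique(as.character(labels)))
    if (length(u) != 2)
      pr_abort("labels must contain exactly two classes", "single_class_error")
    pos <- as.character(labels) == u[2]
  }
  if (!any(pos) || all(pos))
    pr_abort("both classes must be present", "single_class_error")
  pos
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()]; equal to (concordant pairs + half
#' ties) / (n_pos * n_neg), and hence to the Mann-Whitney statistic scaled
#' by the number of class pairs.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.3, 0.8, 0.2), c(1, 1, 0, 0))  # 0.75
auc <- function(scores, labels) {
  rc <- roc_curve(scores, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + rc$tpr[-1]) / 2)
}

#' Stratified-bootstrap confidence interval for the AUC
#'
#' Resamples with replacement within each class, recomputes the AUC, and
#' returns the percentile interval. Degenerate resamples (undefined AUC)
#' are skipped and counted.
#'
#' @inheritParams roc_curve
#' @param level interval level (default 0.95).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed resampling seed.
#' @return List with `lower`, `upper`, `level`, `n_boot`, `n_skipped`,
#'   `seed`.
#' @export
auc_ci <- function(scores, labels, level = 0.95, n_boot = 2000, seed = 1L) {
  pos <- as_positive(labels)
  xp <- scores[pos]; xn <- scores[!pos]
  if (length(xp) < 2 || length(xn) < 2)
    pr_abort("each class needs >= 2 samples to resample", "empty_group_error")
  np <- length(xp); nn <- length(xn)
  set.seed(seed)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bp <- xp[sample.int(np, np, replace = TRUE)]
    bn <- xn[sample.int(nn, nn, replace = TRUE)]
    ## rank-based AUC on the resample
    r <- rank(c(bp, bn))
    stat[b] <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  }
  ok <- is.finite(stat)
  qs <- quantile(stat[ok], c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level, n_boot = n_boot,
       n_skipped = sum(!ok), seed = seed)
}

#' Evaluate a severity marker panel on an independent cohort
#'
#' Builds one-vs-rest evaluations of the panel for the `severe` and
#' `not_severe` classes with both classifier kinds (4 records). Feature
#' selection, standardisation statistics, and model fitting use the
#' training cohort only; a panel whose provenance overlaps the test cohort
#' samples is refused as an information leak. A target class absent from
#' the test cohort yields a record marked not evaluable.
#'
#' @param train_fcm,test_fcm [fold_change()] results (or `preprocess_result`
#'   objects) for the training and test cohorts.
#' @param panel a [geometric_backward_elimination()] ranking (its provenance
#'   is checked) or a plain character vector of probe ids.
#' @param config a [run_config()] (bootstrap replicates and seed).
#' @return An object of class `panel_evaluation`: a list of
#'   `classifier_evaluation` records keyed `<target>_<kind>`, each with ROC
#'   points, AUC, confidence interval and predicted labels, plus a summary
#'   data.frame.
#' @export
evaluate_severity_panel <- function(train_fcm, test_fcm, panel, config) {
  if (inherits(train_fcm, "preprocess_result")) train_fcm <- train_fcm$fcm
  if (inherits(test_fcm, "preprocess_result")) test_fcm <- test_fcm$fcm
  panel_ids <- panel
  if (inherits(panel, "feature_ranking")) {
    leak <- intersect(panel$provenance$sample_ids %||% character(0),
                      colnames(test_fcm$fc))
    if (length(leak))
      pr_abort(paste("panel was selected on samples present in the test",
                     "cohort (information leak):",
                     paste(head(leak, 5), collapse = ", ")),
               "leak_error")
    panel_ids <- panel$selected
  }
  train_x <- t(subset_fcm(train_fcm, panel_ids)$log2_fc)
  test_x <- t(subset_fcm(test_fcm, panel_ids)$log2_fc)
  train_lab <- group_labels(train_fcm$metadata)
  test_lab <- group_labels(test_fcm$metadata)

  evals <- list()
  for (target in c("severe", "not_severe")) {
    for (kind in c("svm", "rf")) {
      key <- paste(target, kind, sep = "_")
      if (!any(test_lab == target) || all(test_lab == target)) {
        evals[[key]] <- structure(list(kind = kind, target = target,
                                       evaluable = FALSE),
                                  class = "classifier_evaluation")
        next
      }
      bin_train <- ifelse(train_lab == target, target, "rest")
      bin_test <- test_lab == target
      sc <- train_and_score(train_x, bin_train, test_x, kind = kind,
                            target = target,
                            seed = stage_seed(config$seed,
                                              paste0("classify_", key)))
      rc <- roc_curve(sc$score, bin_test)
      a <- auc(sc$score, bin_test)
      ci <- auc_ci(sc$score, bin_test, level = 0.95,
                   n_boot = config$bootstrap_reps,
                   seed = stage_seed(config$seed, paste0("boot_", key)))
      ## percentile intervals are clamped to contain the point estimate
      ci$lower <- min(ci$lower, a); ci$upper <- max(ci$upper, a)
      evals[[key]] <- structure(list(kind = kind, target = target,
                                     evaluable = TRUE, roc = rc, auc = a,
                                     ci = ci,
                                     predicted = sc$predicted,
                                     score = sc$score),
                                class = "classifier_evaluation")
    }
  }
  summary <- do.call(rbind, lapply(names(evals), function(key) {
    e <- evals[[key]]
    data.frame(target = e$target, kind = e$kind,
               evaluable = isTRUE(e$evaluable),
               auc = if (isTRUE(e$evaluable)) e$auc else NA_real_,
               ci_lower = if (isTRUE(e$evaluable)) e$ci$lower else NA_real_,
               ci_upper = if (isTRUE(e$evaluable)) e$ci$upper else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(evaluations = evals, summary = summary,
                 panel = panel_ids,
                 config = config[c("bootstrap_reps", "seed")]),
            class = "panel_evaluation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
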