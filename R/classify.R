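#' Fit and apply a column scaler
#'
#' Mean-centers each feature column and scales it to unit standard
#' deviation, with parameters estimated on the training rows only and
#' applied unchanged to held-out rows (no information from a held-out
#' subject leaks into the scaling). Constant columns are centered and left
#' unscaled (scale guarded to 1).
#'
#' @param x Numeric training matrix (rows = subjects).
#' @return An object of class `feature_scaler` with `center` and `scale`.
#' @export
fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler A `feature_scaler`.
#' @param newdata Matrix (or single row) to transform.
#' @export
apply_scaler <- function(scaler, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(sweep(newdata, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# Linear soft-margin SVM wrapper around e1071/libsvm. Returns the primal
# weight vector oriented so that decision value w.x + b > 0 predicts the
# positive class; ties (decision value exactly 0) go to the positive class.
fit_linear_svm <- function(x, y, positive, cost = 1) {
  lev <- unique(as.character(y))
  assert_that(length(lev) == 2,
              "training fold does not contain both classes",
              class = "waveclass_degenerate")
  yf <- factor(as.character(y), levels = c(positive, setdiff(lev, positive)))
  m <- e1071::svm(x, yf, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  # libsvm orients the decision function toward its internally-first label
  # (order of appearance in the training data); flip so that positive
  # decision values always mean `positive`.
  if (m$levels[m$labels[1]] != positive) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

svm_decision <- function(fit, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.numeric(x %*% fit$w) + fit$b
}

#' Confusion counts and derived accuracy metrics
#'
#' @param truth,prediction Vectors of class labels.
#' @param positive The label counted as the "sensitivity" class.
#' @return Tibble with `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity`
#'   and `balanced_accuracy`, the latter three as percentages.
#' @export
confusion_metrics <- function(truth, prediction, positive) {
  truth <- as.character(truth); prediction <- as.character(prediction)
  tp <- sum(truth == positive & prediction == positive)
  fn <- sum(truth == positive & prediction != positive)
  tn <- sum(truth != positive & prediction != positive)
  fp <- sum(truth != positive & prediction == positive)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 balanced_accuracy = balanced_accuracy(sens, spec))
}

#' Balanced accuracy
#'
#' The arithmetic mean of sensitivity and specificity, robust to class
#' imbalance.
#'
#' @param sensitivity,specificity Percentages (or proportions; the result is
#'   on the same scale).
#' @return `(sensitivity + specificity) / 2`.
#' @examples
#' balanced_accuracy(96.97, 95.83)
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' Classification problem labels
#'
#' Derives the binary label vector for one of the two diagnostic problems:
#' `"case"` (subjects from either clinical group vs healthy controls; the
#' positive "sensitivity" class is `case`) or `"disorder"` (GAD subjects --
#' with or without comorbid MD -- vs MD-only subjects, healthy controls
#' excluded; positive class `GAD`).
#'
#' @param subjects Subjects tibble with `subject_id` and `group`.
#' @param problem `"case"` or `"disorder"`.
#' @return Tibble `subject_id`, `label` (factor, positive class first).
#' @export
problem_labels <- function(subjects, problem = c("case", "disorder")) {
  problem <- match.arg(problem)
  if (problem == "case") {
    lab <- ifelse(subjects$group %in% c("GAD", "MD"), "case", "control")
    tibble::tibble(subject_id = subjects$subject_id,
                   label = factor(lab, levels = c("case", "control")))
  } else {
    keep <- subjects$group %in% c("GAD", "MD")
    tibble::tibble(subject_id = subjects$subject_id[keep],
                   label = factor(as.character(subjects$group[keep]),
                                  levels = c("GAD", "MD")))
  }
}

# Normalize feature/label inputs: accept a modality_features or bare matrix,
# and a labels tibble (subject_id, label) or vector aligned with rows.
align_problem <- function(features, labels) {
  if (inherits(features, "modality_features")) {
    x <- features$x
    meta <- features$meta
    ids <- features$subject_ids
    modality <- features$modality
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
    meta <- tibble::tibble(column = seq_len(ncol(x)),
                           name = colnames(x) %||% sprintf("f%d", seq_len(ncol(x))),
                           voxel = NA_integer_,
                           region = colnames(x) %||% sprintf("f%d", seq_len(ncol(x))),
                           side = NA_character_)
    modality <- "matrix"
  }
  if (is.data.frame(labels)) {
    keep <- ids %in% labels$subject_id
    ids <- ids[keep]
    x <- x[keep, , drop = FALSE]
    y <- labels$label[match(ids, labels$subject_id)]
  } else {
    assert_that(length(labels) == nrow(x),
                "labels must be a tibble or a vector matching the rows")
    y <- labels
  }
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  list(x = x, y = y, ids = ids, meta = meta, modality = modality)
}

# Minimal LOOCV engine shared by the user-facing classifier, the
# permutation loops and the ensemble's inner folds. Returns held-out
# predictions (and decision values / per-fold models when asked) without
# any result bookkeeping.
loocv_core <- function(x, y, positive, cost = 1, scaling_fit = "train",
                       keep_fold_models = FALSE, collect_weights = FALSE) {
  n <- nrow(x)
  negative <- setdiff(levels(y), positive)
  global_scaler <- if (scaling_fit == "all") fit_scaler(x) else NULL
  preds <- character(n)
  dvs <- numeric(n)
  wsum <- if (collect_weights) numeric(ncol(x)) else NULL
  fold_models <- if (keep_fold_models) vector("list", n) else NULL
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- y[-i]
    assert_that(length(unique(ytr)) == 2,
                "a fold has a single-class training set",
                class = "waveclass_degenerate")
    scaler <- global_scaler %||% fit_scaler(xtr)
    fit <- fit_linear_svm(apply_scaler(scaler, xtr), ytr, positive,
                          cost = cost)
    dv <- svm_decision(fit, apply_scaler(scaler, x[i, , drop = FALSE]))
    preds[i] <- if (dv >= 0) positive else negative
    dvs[i] <- dv
    if (collect_weights) wsum <- wsum + fit$w
    if (keep_fold_models) {
      fold_models[[i]] <- list(w = fit$w, b = fit$b, scaler = scaler)
    }
  }
  list(preds = preds, dvs = dvs,
       w_mean = if (collect_weights) wsum / n,
       fold_models = fold_models)
}

#' Leave-one-out cross-validated linear SVM classification
#'
#' For each subject, a column scaler and a linear soft-margin SVM (cost
#' `cost`, no kernel) are fit on the remaining subjects and the held-out
#' subject is predicted from its decision value (ties predict the positive
#' class). Confusion counts are aggregated over folds into sensitivity,
#' specificity and balanced accuracy, and the per-fold primal weight vectors
#' are averaged into a weight map.
#'
#' @param features A `modality_features` or numeric matrix (rownames used as
#'   subject ids).
#' @param labels A tibble from [problem_labels()] (subjects absent from it,
#'   e.g. controls in the disorder problem, are dropped) or a label vector
#'   aligned with rows.
#' @param positive Positive class; defaults to the first factor level.
#' @param cost Soft-margin cost parameter C (default 1; no hyperparameter
#'   search is performed).
#' @param scaling_fit `"train"` (default) re-estimates the scaler inside
#'   every fold; `"all"` estimates it once on the full sample, mimicking
#'   pipelines that normalize before cross-validation.
#' @param keep_fold_models Keep per-fold weight vectors and scaler
#'   parameters (used by leakage diagnostics).
#' @return An object of class `wave_cv`: predictions tibble, confusion
#'   counts, `sensitivity`, `specificity`, `balanced_accuracy` (percent),
#'   fold-averaged `weight_vector`, `feature_meta`, and `correct` (named
#'   logical per subject, the ensemble's performance entries).
#' @export
loocv_classify <- function(features, labels, positive = NULL, cost = 1,
                           scaling_fit = c("train", "all"),
                           keep_fold_models = FALSE) {
  scaling_fit <- match.arg(scaling_fit)
  ap <- align_problem(features, labels)
  x <- ap$x; y <- ap$y; ids <- ap$ids
  positive <- positive %||% levels(y)[1]
  assert_that(positive %in% levels(y), "positive class not among labels")
  assert_that(all(table(y) >= 2), "need at least two subjects per class",
              class = "waveclass_degenerate")
  n <- nrow(x)
  core <- loocv_core(x, y, positive, cost = cost, scaling_fit = scaling_fit,
                     keep_fold_models = keep_fold_models,
                     collect_weights = TRUE)
  preds <- core$preds
  dvs <- core$dvs
  cm <- confusion_metrics(y, preds, positive)
  out <- list(
    modality = ap$modality,
    positive = positive,
    predictions = tibble::tibble(subject_id = ids, truth = as.character(y),
                                 prediction = preds, decision_value = dvs,
                                 correct = preds == as.character(y)),
    confusion = cm[, c("tp", "fn", "tn", "fp")],
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    balanced_accuracy = cm$balanced_accuracy,
    weight_vector = core$w_mean,
    feature_meta = ap$meta,
    correct = stats::setNames(preds == as.character(y), ids),
    n_folds = n,
    p_value = NA_real_,
    fold_models = core$fold_models
  )
  class(out) <- "wave_cv"
  out
}

#' @export
print.wave_cv <- function(x, ...) {
  cat(sprintf(paste0("<wave_cv: %s, n = %d>\n",
                     "  sensitivity %.2f%%, specificity %.2f%%, ",
                     "balanced accuracy %.2f%%\n"),
              x$modality, x$n_folds, x$sensitivity, x$specificity,
              x$balanced_accuracy))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' Permutation test for LOOCV classification accuracy
#'
#' Re-runs the full leave-one-out classification under randomly permuted
#' labels and compares the observed balanced accuracy against the null
#' distribution. The p-value uses the add-one estimator
#' `(#\{null >= observed\} + 1) / (n_perm + 1)`, which never returns exactly
#' zero. Permutations shuffle the whole label vector (unstratified).
#'
#' @inheritParams loocv_classify
#' @param n_perm Number of permutations (5000 in the reference analysis).
#' @param seed RNG seed for the permutations.
#' @param observed Optionally, a precomputed `wave_cv` for the unpermuted
#'   labels (avoids refitting it).
#' @return A `wave_cv` with `p_value` filled in and a `null_distribution`
#'   element (balanced accuracies under permutation).
#' @export
permutation_test <- function(features, labels, positive = NULL, n_perm = 5000,
                             seed = 1L, cost = 1,
                             scaling_fit = c("train", "all"),
                             observed = NULL) {
  scaling_fit <- match.arg(scaling_fit)
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  obs <- observed %||% loocv_classify(features, labels, positive = positive,
                                      cost = cost, scaling_fit = scaling_fit)
  ap <- align_problem(features, labels)
  y <- ap$y
  positive <- obs$positive
  null_bacc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- sample(y)
      preds <- loocv_core(ap$x, yp, positive, cost = cost,
                          scaling_fit = scaling_fit)$preds
      confusion_metrics(yp, preds, positive)$balanced_accuracy
    }, numeric(1))
  })
  obs$p_value <- (sum(null_bacc >= obs$balanced_accuracy) + 1) / (n_perm + 1)
  obs$null_distribution <- null_bacc
  obs$n_perm <- n_perm
  obs
}

#' Summarize a weight map by region
#'
#' Aggregates a per-feature linear SVM weight vector into per-region scores:
#' the mean of the absolute weights of all features (voxels or scores) in
#' the region, and that mean as a percentage of the sum over regions. Rows
#' are ranked by descending absolute weight (ties broken by region name then
#' side, for determinism); percentages are reported to two decimals.
#'
#' @param x A `wave_cv` (uses its fold-averaged weight vector and feature
#'   provenance) or a data frame with columns `region`, optional `side`, and
#'   `weight_abs` (already-aggregated absolute weights, e.g. from a
#'   published table) plus optional `n_features`.
#' @param ... Unused.
#' @return Tibble `rank`, `region`, `side`, `weight_abs`, `weight_perc`,
#'   `n_features`.
#' @export
summarize_region_weights <- function(x, ...) {
  UseMethod("summarize_region_weights")
}

#' @rdname summarize_region_weights
#' @export
summarize_region_weights.wave_cv <- function(x, ...) {
  meta <- x$feature_meta
  assert_that(!anyNA(meta$region), "every feature needs a region label",
              class = "waveclass_unlabeled")
  d <- tibble::tibble(region = meta$region, side = meta$side,
                      w = abs(x$weight_vector))
  agg <- dplyr::summarise(dplyr::group_by(d, .data$region, .data$side),
                          weight_abs = mean(.data$w),
                          n_features = dplyr::n(), .groups = "drop")
  rank_region_weights(agg)
}

#' @rdname summarize_region_weights
#' @export
summarize_region_weights.data.frame <- function(x, ...) {
  assert_that(all(c("region", "weight_abs") %in% names(x)),
              "need columns region and weight_abs")
  agg <- tibble::as_tibble(x)
  if (!"side" %in% names(agg)) agg$side <- NA_character_
  if (!"n_features" %in% names(agg)) agg$n_features <- NA_integer_
  rank_region_weights(agg[, c("region", "side", "weight_abs", "n_features")])
}

rank_region_weights <- function(agg) {
  agg <- dplyr::arrange(agg, dplyr::desc(.data$weight_abs), .data$region,
                        .data$side)
  agg$weight_perc <- round(100 * agg$weight_abs / sum(agg$weight_abs), 2)
  agg$rank <- seq_len(nrow(agg))
  agg[, c("rank", "region", "side", "weight_abs", "weight_perc", "n_features")]
}
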