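#' Nested leave-one-out multimodal ensemble classification
#'
#' Fuses per-modality linear SVM classifiers with WAVE weights inside a
#' nested leave-one-out scheme that keeps the outer held-out subject fully
#' independent: for each outer subject, (1) an inner LOOCV per modality on
#' the remaining n-1 subjects yields the binary performance matrix, (2)
#' [wave_weights()] turns it into classifier weights, (3) each modality's
#' classifier is refit on all n-1 subjects and casts a +/-1 vote on the
#' held-out subject, and (4) the fused prediction is the sign of the
#' weighted vote sum (ties predict the positive class).
#'
#' Every subject must be present in every modality; screen out subjects with
#' incomplete cortisol profiles first (see [multimodal_features()]).
#'
#' @param features_list Named list of `modality_features`, all with the same
#'   subjects (e.g. clinical, cortisol, gm, wm).
#' @param labels Labels tibble from [problem_labels()] or vector.
#' @inheritParams loocv_classify
#' @param tol,max_iter Passed to [wave_weights()].
#' @return An object of class `wave_ensemble`: `predictions` (per outer
#'   fold: subject, per-modality votes, fused prediction), `confusion`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`, `weight_trace`
#'   (outer folds x classifiers), `mean_weights`, and `p_value` (`NA` until
#'   [ensemble_permutation_test()]).
#' @export
nested_loocv_ensemble <- function(features_list, labels, positive = NULL,
                                  cost = 1, scaling_fit = c("train", "all"),
                                  tol = 1e-10, max_iter = 1000) {
  scaling_fit <- match.arg(scaling_fit)
  assert_that(length(features_list) >= 2, "need at least two modalities")
  k <- length(features_list)
  mods <- names(features_list) %||% paste0("m", seq_len(k))
  aps <- lapply(features_list, align_problem, labels = labels)
  ids <- aps[[1]]$ids
  for (ap in aps) {
    assert_that(identical(ap$ids, ids),
                "subject sets differ across modalities; align them first",
                class = "waveclass_mismatch")
  }
  y <- aps[[1]]$y
  positive <- positive %||% levels(y)[1]
  negative <- setdiff(levels(y), positive)
  n <- length(ids)
  assert_that(all(table(y) >= 3), "need at least three subjects per class",
              class = "waveclass_degenerate")

  votes <- matrix(0, n, k, dimnames = list(ids, mods))
  weight_trace <- matrix(NA_real_, n, k, dimnames = list(ids, mods))
  fused <- character(n)
  for (i in seq_len(n)) {
    inner <- setdiff(seq_len(n), i)
    X <- matrix(0L, n - 1, k, dimnames = list(ids[inner], mods))
    for (j in seq_len(k)) {
      xj <- aps[[j]]$x
      inner_preds <- loocv_core(xj[inner, , drop = FALSE], y[inner],
                                positive, cost = cost,
                                scaling_fit = scaling_fit)$preds
      X[, j] <- as.integer(inner_preds == as.character(y[inner]))
    }
    p <- wave_weights(X, tol = tol, max_iter = max_iter)$classifier_weights
    weight_trace[i, ] <- p
    for (j in seq_len(k)) {
      xj <- aps[[j]]$x
      scaler <- fit_scaler(if (scaling_fit == "all") xj
                           else xj[inner, , drop = FALSE])
      fit <- fit_linear_svm(apply_scaler(scaler, xj[inner, , drop = FALSE]),
                            y[inner], positive, cost = cost)
      dv <- svm_decision(fit, apply_scaler(scaler, xj[i, , drop = FALSE]))
      votes[i, j] <- if (dv >= 0) 1 else -1
    }
    fused[i] <- if (sum(p * votes[i, ]) >= 0) positive else negative
  }
  cm <- confusion_metrics(y, fused, positive)
  out <- list(
    modalities = mods,
    positive = positive,
    predictions = tibble::tibble(subject_id = ids, truth = as.character(y),
                                 prediction = fused,
                                 correct = fused == as.character(y)),
    votes = votes,
    confusion = cm[, c("tp", "fn", "tn", "fp")],
    sensitivity = cm$sensitivity,
    specificity = cm$specificity,
    balanced_accuracy = cm$balanced_accuracy,
    weight_trace = weight_trace,
    mean_weights = colMeans(weight_trace),
    n_folds = n,
    p_value = NA_real_
  )
  class(out) <- "wave_ensemble"
  out
}

#' @export
print.wave_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<wave_ensemble: %s; n = %d>\n",
                     "  sensitivity %.2f%%, specificity %.2f%%, ",
                     "balanced accuracy %.2f%%\n  mean weights: %s\n"),
              paste(x$modalities, collapse = " + "), x$n_folds,
              x$sensitivity, x$specificity, x$balanced_accuracy,
              paste(sprintf("%s=%.2f", x$modalities, x$mean_weights),
                    collapse = ", ")))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' Permutation significance of the fused classification
#'
#' The default (`type = "fixed"`) scheme holds the fused predictions and the
#' per-fold classifier weights fixed and scores them against permuted label
#' vectors, counting permutations whose balanced accuracy strictly exceeds
#' the observed one: `p = #\{permuted > observed\} / n_perm`. This estimator
#' can return exactly 0 when no permutation beats the observed accuracy.
#' `type = "full"` instead re-runs the whole nested ensemble per permutation
#' (expensive; provided as a sensitivity analysis) with the same strict
#' counting.
#'
#' @param result A `wave_ensemble` from [nested_loocv_ensemble()].
#' @param n_perm Number of permutations (5000 in the reference analysis).
#' @param seed RNG seed.
#' @param type `"fixed"` or `"full"`.
#' @param features_list,cost,scaling_fit Required for `type = "full"` only.
#' @return The `wave_ensemble` with `p_value` and `null_distribution` set.
#' @export
ensemble_permutation_test <- function(result, n_perm = 5000, seed = 1L,
                                      type = c("fixed", "full"),
                                      features_list = NULL, cost = 1,
                                      scaling_fit = "train") {
  type <- match.arg(type)
  assert_that(inherits(result, "wave_ensemble"), "result must be a wave_ensemble")
  truth <- result$predictions$truth
  obs <- result$balanced_accuracy
  null_bacc <- with_seed(seed, {
    if (type == "fixed") {
      vapply(seq_len(n_perm), function(b) {
        confusion_metrics(sample(truth), result$predictions$prediction,
                          result$positive)$balanced_accuracy
      }, numeric(1))
    } else {
      assert_that(!is.null(features_list),
                  "type = 'full' needs the features_list")
      ids <- result$predictions$subject_id
      vapply(seq_len(n_perm), function(b) {
        yp <- tibble::tibble(subject_id = ids, label = sample(truth))
        r <- nested_loocv_ensemble(features_list, yp,
                                   positive = result$positive, cost = cost,
                                   scaling_fit = scaling_fit)
        r$balanced_accuracy
      }, numeric(1))
    }
  })
  result$p_value <- sum(null_bacc > obs) / n_perm
  result$null_distribution <- null_bacc
  result$n_perm <- n_perm
  result
}

#' Pairwise comparison of classifier weights across outer folds
#'
#' Paired t-tests on the per-outer-fold WAVE classifier weights, for
#' assessing whether one modality is systematically weighted higher than
#' another. Pairs whose fold-wise weight differences have zero variance are
#' flagged; a constant nonzero difference reports p = 0 (deterministic
#' separation), an identically zero difference reports no p-value.
#'
#' @param result A `wave_ensemble`, or a numeric matrix of per-fold weights
#'   (folds x classifiers).
#' @return Tibble `classifier_1`, `classifier_2`, `mean_1`, `mean_2`,
#'   `mean_diff`, `statistic`, `df`, `p_value`, `zero_variance`.
#' @export
compare_classifier_weights <- function(result) {
  trace <- if (inherits(result, "wave_ensemble")) result$weight_trace
           else as.matrix(result)
  assert_that(nrow(trace) >= 2, "need at least two outer folds",
              class = "waveclass_degenerate")
  mods <- colnames(trace) %||% paste0("m", seq_len(ncol(trace)))
  pairs <- utils::combn(seq_len(ncol(trace)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    a <- pairs[1, c0]; b <- pairs[2, c0]
    d <- trace[, a] - trace[, b]
    zero_var <- stats::sd(d) < 1e-14
    if (zero_var) {
      # No fold-to-fold variability: a constant nonzero difference separates
      # the classifiers deterministically, a zero difference carries no test.
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = if (abs(mean(d)) > 1e-14) 0 else NA_real_)
    } else {
      tt <- stats::t.test(trace[, a], trace[, b], paired = TRUE)
    }
    tibble::tibble(classifier_1 = mods[a], classifier_2 = mods[b],
                   mean_1 = mean(trace[, a]), mean_2 = mean(trace[, b]),
                   mean_diff = mean(d),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter),
                   p_value = tt$p.value,
                   zero_variance = zero_var)
  })
}
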