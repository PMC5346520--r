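test_that("column scaling centers on the training rows only", {
  x <- matrix(c(1, 2, 3), ncol = 1)
  sc <- fit_scaler(x)
  expect_equal(as.vector(apply_scaler(sc, x)), c(-1, 0, 1))
  expect_equal(as.vector(apply_scaler(sc, matrix(2, 1, 1))), 0)
  # constant column: zero-scale guard
  xc <- cbind(x, 5)
  scc <- fit_scaler(xc)
  expect_equal(unname(scc$scale[2]), 1)
  expect_true(all(is.finite(apply_scaler(scc, xc))))
  # idempotence: re-scaling an already scaled matrix with its own params
  xs <- apply_scaler(sc, x)
  sc2 <- fit_scaler(xs)
  expect_lt(max(abs(apply_scaler(sc2, xs) - xs)), 1e-12)
})

test_that("LOOCV separates well-separated clouds perfectly", {
  prob <- separable_problem(10, gap = 8)
  cv <- loocv_classify(prob$x, prob$labels, positive = "pos")
  expect_equal(cv$balanced_accuracy, 100)
  expect_equal(cv$sensitivity, 100)
  expect_equal(cv$specificity, 100)
  expect_equal(cv$n_folds, 20)
})

test_that("LOOCV balanced accuracy sits at chance under shuffled labels", {
  prob <- separable_problem(10, gap = 8)
  baccs <- withr::with_seed(77, {
    vapply(1:50, function(r) {
      shuffled <- prob$labels
      shuffled$label <- sample(shuffled$label)
      loocv_classify(prob$x, shuffled, positive = "pos")$balanced_accuracy
    }, numeric(1))
  })
  expect_lt(abs(mean(baccs) - 50), 5)
})

test_that("confusion metrics reproduce the balanced-accuracy identity", {
  cm <- confusion_metrics(rep(c("case", "control"), c(33, 24)),
                          c(rep("case", 32), "control",
                            "case", rep("control", 23)),
                          positive = "case")
  expect_equal(cm$tp, 32)
  expect_equal(cm$fn, 1)
  expect_equal(cm$tn, 23)
  expect_equal(cm$fp, 1)
  expect_equal(cm$sensitivity, 100 * 32 / 33, tolerance = 1e-10)
  expect_equal(cm$specificity, 100 * 23 / 24, tolerance = 1e-10)
  expect_equal(cm$balanced_accuracy,
               (cm$sensitivity + cm$specificity) / 2)
  # printed-precision check: 96.97 / 95.83 / 96.40
  expect_equal(round(cm$sensitivity, 2), 96.97)
  expect_equal(round(cm$specificity, 2), 95.83)
  expect_equal(round(cm$balanced_accuracy, 2), 96.40)
})

test_that("every CV result satisfies the exact balanced-accuracy identity", {
  withr::with_seed(13, {
    for (r in 1:5) {
      n <- sample(6:12, 1)
      x <- matrix(rnorm(2 * n * 3), 2 * n)
      rownames(x) <- sprintf("R%02d", 1:(2 * n))
      y <- tibble::tibble(subject_id = rownames(x),
                          label = factor(rep(c("a", "b"), each = n)))
      cv <- loocv_classify(x, y, positive = "a")
      expect_identical(cv$confusion$tp + cv$confusion$fn, n)
      expect_identical(cv$confusion$tn + cv$confusion$fp, n)
      expect_equal(cv$balanced_accuracy,
                   (cv$sensitivity + cv$specificity) / 2)
    }
  })
})

test_that("the held-out subject never influences its own fold's model", {
  prob <- separable_problem(8, gap = 4, seed = 3)
  cv <- loocv_classify(prob$x, prob$labels, positive = "pos",
                       keep_fold_models = TRUE)
  i <- 5
  contaminated <- prob$x
  contaminated[i, ] <- 1e6 # absurd outlier as the held-out subject
  cv2 <- loocv_classify(contaminated, prob$labels, positive = "pos",
                        keep_fold_models = TRUE)
  expect_equal(cv2$fold_models[[i]]$scaler$center,
               cv$fold_models[[i]]$scaler$center, tolerance = 1e-12)
  expect_equal(cv2$fold_models[[i]]$scaler$scale,
               cv$fold_models[[i]]$scaler$scale, tolerance = 1e-12)
  expect_equal(cv2$fold_models[[i]]$w, cv$fold_models[[i]]$w,
               tolerance = 1e-10)
  # whereas the leaky whole-sample scaling does change
  cv3 <- loocv_classify(contaminated, prob$labels, positive = "pos",
                        scaling_fit = "all", keep_fold_models = TRUE)
  expect_gt(max(abs(cv3$fold_models[[i]]$scaler$center -
                      cv$fold_models[[i]]$scaler$center)), 1)
})

test_that("predictions are invariant to feature-column permutation", {
  prob <- separable_problem(7, p = 5, gap = 2, seed = 8)
  cv <- loocv_classify(prob$x, prob$labels, positive = "pos")
  perm <- c(3, 1, 5, 2, 4)
  cv2 <- loocv_classify(prob$x[, perm], prob$labels, positive = "pos")
  expect_identical(cv$predictions$prediction, cv2$predictions$prediction)
  expect_equal(unname(cv$weight_vector[perm]), unname(cv2$weight_vector),
               tolerance = 1e-8)
})

test_that("degenerate classification problems are rejected", {
  x <- matrix(rnorm(12), 6)
  rownames(x) <- sprintf("R%d", 1:6)
  y1 <- tibble::tibble(subject_id = rownames(x),
                       label = factor(c("a", rep("b", 5))))
  expect_error(loocv_classify(x, y1), class = "waveclass_degenerate")
})

test_that("permutation p has the add-one form and detects separation", {
  prob <- separable_problem(6, gap = 10, seed = 15)
  pt <- permutation_test(prob$x, prob$labels, positive = "pos",
                         n_perm = 199, seed = 99)
  expect_equal(pt$balanced_accuracy, 100)
  # add-one estimator: p = (#{null >= observed} + 1) / (n_perm + 1), so the
  # smallest reachable value is 1/200 (an unstratified shuffle can reproduce
  # the original labelling or its mirror and tie at 100%)
  k <- sum(pt$null_distribution >= 100)
  expect_equal(pt$p_value, (k + 1) / 200)
  expect_gte(pt$p_value, 1 / 200)
  expect_lte(pt$p_value, 0.05)
  expect_length(pt$null_distribution, 199)
})

test_that("region weight summaries normalize printed weight tables", {
  clin <- reference_clinical_weights()
  dis <- summarize_region_weights(clin[clin$problem == "disorder", ])
  expect_equal(dis$region[1], "IUS-12")
  expect_equal(dis$weight_perc, c(60.58, 17.07, 12.56, 9.79))
  case <- summarize_region_weights(clin[clin$problem == "case", ])
  expect_equal(case$weight_perc[case$region == "STAI-T"], 45.10)

  reg <- reference_region_weights()
  rc <- summarize_region_weights(reg[reg$problem == "case", ])
  expect_equal(rc$region[1], "Putamen")
  expect_equal(rc$side[1], "R")
  expect_equal(rc$weight_perc[1], 7.36)
  expect_equal(sum(rc$weight_perc), 100, tolerance = 0.01)

  expect_equal(summarize_region_weights(
    data.frame(region = "only", weight_abs = 0.3))$weight_perc, 100)
})

test_that("region percentages from a CV weight map sum to 100 and are
           scale-invariant", {
  cohort <- simulate_cohort(small_config(seed = 61))
  gm <- assemble_features(cohort, "gm")
  lab <- problem_labels(cohort$subjects, "case")
  cv <- loocv_classify(gm, lab)
  s1 <- summarize_region_weights(cv)
  expect_equal(sum(s1$weight_perc), 100, tolerance = 0.01)
  expect_true(all(diff(s1$weight_abs) <= 1e-15))
  cv_scaled <- cv
  cv_scaled$weight_vector <- cv$weight_vector * 37.5
  s2 <- summarize_region_weights(cv_scaled)
  expect_equal(s1$weight_perc, s2$weight_perc)
  expect_identical(s1$region, s2$region)
  # per-region feature counts match the atlas parcel sizes
  merged <- dplyr::inner_join(s1, cohort$atlas$table, by = c("region", "side"))
  expect_equal(merged$n_features, merged$n_voxels)
})
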