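test_that("identical modalities fuse to the single-modality LOOCV predictions", {
  prob <- separable_problem(8, gap = 2, seed = 19)
  feats <- list(a = as_mf(prob$x, "a"), b = as_mf(prob$x, "b"),
                c = as_mf(prob$x, "c"))
  ens <- nested_loocv_ensemble(feats, prob$labels, positive = "pos")
  single <- loocv_classify(prob$x, prob$labels, positive = "pos")
  expect_identical(ens$predictions$prediction, single$predictions$prediction)
  # all columns of the inner performance matrix identical: uniform weights
  expect_true(all(abs(ens$weight_trace - 1 / 3) < 1e-12))
})

test_that("a perfectly informative modality dominates noise modalities", {
  accs <- withr::with_seed(37, {
    vapply(1:20, function(r) {
      n <- 10
      ids <- sprintf("D%02d", 1:(2 * n))
      good <- separable_problem(n, gap = 10, seed = sample.int(1e6, 1))
      rownames(good$x) <- ids
      good$labels$subject_id <- ids
      noise1 <- matrix(rnorm(2 * n * 4), 2 * n, dimnames = list(ids, NULL))
      noise2 <- matrix(rnorm(2 * n * 4), 2 * n, dimnames = list(ids, NULL))
      feats <- list(good = as_mf(good$x, "good"),
                    n1 = as_mf(noise1, "n1"), n2 = as_mf(noise2, "n2"))
      ens <- nested_loocv_ensemble(feats, good$labels, positive = "pos")
      ens$balanced_accuracy
    }, numeric(1))
  })
  expect_gte(mean(accs), 95) # within 5 points of the perfect modality
})

test_that("the outer held-out subject cannot leak into its fold's weights", {
  prob <- separable_problem(7, gap = 3, seed = 47)
  other <- matrix(rnorm(14 * 3), 14, dimnames = list(rownames(prob$x), NULL))
  feats <- list(a = as_mf(prob$x, "a"), b = as_mf(other, "b"))
  ens <- nested_loocv_ensemble(feats, prob$labels, positive = "pos")
  i <- 4
  contaminated <- prob$x
  contaminated[i, ] <- 1e6
  feats2 <- list(a = as_mf(contaminated, "a"), b = as_mf(other, "b"))
  ens2 <- nested_loocv_ensemble(feats2, prob$labels, positive = "pos")
  # fold i's WAVE weights are built from the other n-1 subjects only
  expect_equal(ens2$weight_trace[i, ], ens$weight_trace[i, ],
               tolerance = 1e-12)
  # and the unperturbed modality's vote for subject i is unchanged
  expect_identical(ens2$votes[i, "b"], ens$votes[i, "b"])
})

test_that("ensemble permutation test uses strict counting and can reach zero", {
  prob <- separable_problem(8, gap = 10, seed = 53)
  feats <- list(a = as_mf(prob$x, "a"), b = as_mf(prob$x, "b"))
  ens <- nested_loocv_ensemble(feats, prob$labels, positive = "pos")
  expect_equal(ens$balanced_accuracy, 100)
  pt <- ensemble_permutation_test(ens, n_perm = 199, seed = 7)
  # nothing can strictly beat 100% balanced accuracy
  expect_identical(pt$p_value, 0)
  expect_length(pt$null_distribution, 199)
})

test_that("fixed and full permutation schemes agree on strongly null data", {
  prob <- noise_problem(6, seed = 59)
  feats <- list(a = as_mf(prob$x, "a"),
                b = as_mf(matrix(rnorm(48), 12,
                                 dimnames = list(rownames(prob$x), NULL)), "b"))
  ens <- nested_loocv_ensemble(feats, prob$labels, positive = "pos")
  p_fixed <- ensemble_permutation_test(ens, n_perm = 99, seed = 3)$p_value
  p_full <- ensemble_permutation_test(ens, n_perm = 19, seed = 3,
                                      type = "full",
                                      features_list = feats)$p_value
  expect_gt(p_fixed, 0.05)
  expect_gt(p_full, 0.05)
})

test_that("fused accuracy shows no optimistic bias on null cohorts", {
  # Leave-one-out accuracy under the null is pessimistically biased
  # ("anti-learning": removing the held-out subject shifts the decision
  # boundary away from its class), so the fused balanced accuracy on null
  # cohorts sits at or below chance. The property that must hold is the
  # absence of any optimistic bias, which would signal information leakage;
  # type-I error control is covered by the permutation-calibration test.
  accs <- vapply(1:12, function(s) {
    cohort <- simulate_cohort(small_null_config(
      seed = 100 + s, sizes = c(HC = 12, GAD = 7, MD = 5), n_comorbid = 3,
      modalities = c("clinical", "cortisol")))
    feats <- multimodal_features(cohort,
                                 modalities = c("clinical", "cortisol"))
    lab <- problem_labels(cohort$subjects, "case")
    nested_loocv_ensemble(feats, lab)$balanced_accuracy
  }, numeric(1))
  expect_lt(mean(accs), 50 + 5)
})

test_that("classifier weight comparisons flag zero variance and match a
           hand-computed paired t", {
  trace <- matrix(c(0.5, 0.5, 0.5, 0.25, 0.25, 0.25, 0.25, 0.25, 0.25),
                  3, 3, dimnames = list(NULL, c("a", "b", "c")))
  cmp <- compare_classifier_weights(trace)
  ab <- cmp[cmp$classifier_1 == "a" & cmp$classifier_2 == "b", ]
  expect_true(ab$zero_variance)
  expect_identical(ab$p_value, 0) # constant nonzero separation
  bc <- cmp[cmp$classifier_1 == "b" & cmp$classifier_2 == "c", ]
  expect_true(bc$zero_variance)
  expect_true(is.na(bc$p_value))

  withr::with_seed(67, {
    t2 <- cbind(a = rnorm(10, 0.5, 0.05), b = rnorm(10, 0.3, 0.05))
  })
  cmp2 <- compare_classifier_weights(t2)
  d <- t2[, 1] - t2[, 2]
  tstat <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(cmp2$statistic, tstat, tolerance = 1e-12)
  expect_equal(cmp2$df, 9)
  expect_equal(cmp2$p_value, 2 * pt(-abs(tstat), 9), tolerance = 1e-12)

  expect_error(compare_classifier_weights(t2[1, , drop = FALSE]),
               class = "waveclass_degenerate")
})
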