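test_that("default cohort has the configured group structure", {
  cohort <- simulate_cohort(cohort_config(seed = 7, modalities = c("clinical", "cortisol")))
  s <- cohort$subjects
  expect_equal(nrow(s), 57)
  expect_equal(as.vector(table(s$group)), c(24, 19, 14))
  expect_equal(sum(s$comorbid_md), 12)
  expect_true(all(s$group[s$comorbid_md] == "GAD"))
  # demographics realized as exact counts
  expect_equal(as.vector(tapply(s$sex == "female", s$group, sum)), c(17, 16, 12))
  expect_equal(as.vector(tapply(s$handedness == "right", s$group, sum)),
               c(21, 17, 11))
  expect_equal(sum(is.na(s$smoker)), 1)
  expect_true(all(is.na(s$smoker[s$group != "HC"]) == FALSE))
  # scores inside instrument ranges
  expect_true(all(s$pswq >= 16 & s$pswq <= 80))
  expect_true(all(s$bdi >= 0 & s$bdi <= 63))
  expect_true(all(s$ius12 >= 12 & s$ius12 <= 60))
  expect_true(all(s$stait >= 20 & s$stait <= 80))
})

test_that("simulation is deterministic given config and seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$cortisol, b$cortisol)
  expect_identical(a$gm[[1]], b$gm[[1]])
  c <- simulate_cohort(small_config(seed = 12))
  expect_false(identical(a$subjects$pswq, c$subjects$pswq))
})

test_that("questionnaire generation is calibrated to the configured moments", {
  # 200 replicate cohorts; Monte-Carlo mean of HC PSWQ within 3 SE of 36.00
  means <- vapply(1:200, function(s) {
    cohort <- simulate_cohort(cohort_config(seed = s, modalities = "clinical"))
    mean(cohort$subjects$pswq[cohort$subjects$group == "HC"])
  }, numeric(1))
  se <- 9.98 / sqrt(24 * 200)
  expect_lt(abs(mean(means) - 36.00), 3 * se)
})

test_that("cortisol log-AUC is calibrated to the configured group moments", {
  cfg <- cohort_config(group_sizes = c(HC = 150, GAD = 150, MD = 150),
                       n_comorbid = 75,
                       demographic_counts = small_demographics(c(150, 150, 150)),
                       missing_cortisol = 0, missing_smoking = 0,
                       modalities = c("clinical", "cortisol"), seed = 3)
  cohort <- simulate_cohort(cfg)
  feats <- screen_profiles(cohort$cortisol)$features
  d <- dplyr::inner_join(cohort$subjects, feats, by = "subject_id")
  for (g in c("HC", "GAD", "MD")) {
    cp <- cfg$cortisol_params[cfg$cortisol_params$group == g, ]
    x <- d$log_auc[d$group == g]
    expect_lt(abs(mean(x) - cp$mean), 3 * cp$sd / sqrt(150))
    expect_lt(abs(sd(x) - cp$sd), 4 * cp$sd / sqrt(2 * 149))
  }
})

test_that("null configuration yields no systematic group separation", {
  cohort <- simulate_cohort(small_null_config(seed = 5, sizes = c(HC = 40, GAD = 20, MD = 20),
                                              n_comorbid = 10,
                                              modalities = c("clinical", "cortisol")))
  an <- anova_oneway(cohort$subjects, pswq, group)
  expect_gt(an$p_value, 0.001)
  expect_equal(nrow(cohort$config$effect_table), 0)
})

test_that("inconsistent configurations are rejected", {
  expect_error(cohort_config(n_comorbid = 20), "n_comorbid")
  expect_error(cohort_config(sample_times = c(0, 10, 10, 55, 75, 100)),
               "strictly increasing")
  expect_error(cohort_config(group_sizes = c(HC = 0, GAD = 19, MD = 14)),
               "positive")
  expect_error(cohort_config(group_sizes = c(HC = 4, GAD = 4, MD = 4),
                             n_comorbid = 2),
               "demographic counts")
})

test_that("configurations round-trip through YAML and JSON files", {
  cfg_file <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 5",
    "n_comorbid: 2",
    "group_sizes: {HC: 4, GAD: 4, MD: 4}",
    "modalities: [clinical]",
    "demographic_counts:",
    "  - {group: HC, female: 3, right_handed: 4, secondary_school: 3, nonsmoker: 4}",
    "  - {group: GAD, female: 3, right_handed: 4, secondary_school: 3, nonsmoker: 4}",
    "  - {group: MD, female: 3, right_handed: 3, secondary_school: 3, nonsmoker: 3}"
  ), cfg_file)
  cfg <- cohort_config_from_file(cfg_file)
  expect_equal(unname(cfg$group_sizes[c("HC", "GAD", "MD")]), c(4, 4, 4))
  expect_equal(cfg$seed, 5L)
  cohort <- simulate_cohort(cfg)
  expect_equal(nrow(cohort$subjects), 12)

  json_file <- withr::local_tempfile(fileext = ".json")
  writeLines('{"seed": 9, "missing_cortisol": 0, "modalities": ["clinical", "cortisol"]}',
             json_file)
  cfg2 <- cohort_config_from_file(json_file)
  expect_equal(cfg2$seed, 9L)
  expect_equal(cfg2$missing_cortisol, 0)

  bad_file <- withr::local_tempfile(fileext = ".json")
  writeLines('{"not_a_field": 1}', bad_file)
  expect_error(cohort_config_from_file(bad_file), "unknown config fields")
})

test_that("regional effects land in the configured regions", {
  eff <- tibble::tibble(tissue = "gm", region = "Putamen", group = "GAD",
                        effect = 0.5)
  cfg <- small_config(seed = 2, effect_table = eff, noise_sd = 0.001,
                      subject_sd = 0, modalities = "gm")
  cohort <- simulate_cohort(cfg)
  atlas <- cohort$atlas
  put <- atlas$labels %in% atlas$table$label[atlas$table$region == "Putamen"]
  gad_id <- cohort$subjects$subject_id[cohort$subjects$group == "GAD"][1]
  hc_id <- cohort$subjects$subject_id[cohort$subjects$group == "HC"][1]
  ratio <- mean(cohort$gm[[gad_id]][put]) / mean(cohort$gm[[hc_id]][put])
  expect_equal(ratio, 1.5, tolerance = 0.02)
  other <- atlas$brain_mask & !atlas$wm_mask & !put
  ratio0 <- mean(cohort$gm[[gad_id]][other]) / mean(cohort$gm[[hc_id]][other])
  expect_equal(ratio0, 1.0, tolerance = 0.02)
})
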