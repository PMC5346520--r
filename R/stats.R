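#' One-way analysis of variance
#'
#' Standard one-way fixed-effects ANOVA from raw per-group observations,
#' returning the F statistic with its degrees of freedom. Use
#' [anova_oneway_from_summary()] when only group means, SDs and sizes are
#' available (e.g. when checking a published descriptives table); the two
#' paths give identical F when the raw data exactly realize the summaries.
#'
#' @param data Data frame of raw observations.
#' @param value,group Column names (unquoted) of the outcome and grouping
#'   variable.
#' @return Tibble `statistic` (F), `df_between`, `df_within`, `p_value`.
#' @examples
#' anova_oneway(data.frame(y = rnorm(30), g = rep(letters[1:3], 10)), y, g)
#' @export
anova_oneway <- function(data, value, group) {
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  tab <- table(g)
  assert_that(length(tab) >= 2, "need at least two groups")
  assert_that(all(tab >= 2), "every group needs n >= 2")
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  tibble::tibble(statistic = unname(ft$statistic),
                 df_between = unname(ft$parameter[1]),
                 df_within = unname(ft$parameter[2]),
                 p_value = ft$p.value)
}

#' @rdname anova_oneway
#' @param summary Data frame with one row per group and columns `n`, `mean`,
#'   `sd`.
#' @export
anova_oneway_from_summary <- function(summary) {
  assert_that(all(c("n", "mean", "sd") %in% names(summary)),
              "summary needs columns n, mean, sd")
  n <- summary$n; m <- summary$mean; s <- summary$sd
  assert_that(length(n) >= 2, "need at least two groups")
  assert_that(all(n >= 2), "every group needs n >= 2")
  assert_that(all(s > 0), "SDs must be positive")
  k <- length(n); N <- sum(n)
  grand <- sum(n * m) / N
  msb <- sum(n * (m - grand)^2) / (k - 1)
  msw <- sum((n - 1) * s^2) / (N - k)
  f <- msb / msw
  tibble::tibble(statistic = f, df_between = k - 1, df_within = N - k,
                 p_value = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction (the convention that
#' reproduces published group-comparison statistics for small psychiatric
#' samples), `df = (rows - 1)(cols - 1)`.
#'
#' @param counts Matrix or data frame of nonnegative integer counts
#'   (groups x categories).
#' @return Tibble `statistic`, `df`, `p_value`.
#' @examples
#' chi_square(rbind(c(17, 7), c(16, 3), c(12, 2)))
#' @export
chi_square <- function(counts) {
  m <- as.matrix(counts)
  assert_that(all(m >= 0) && sum(m) > 0, "counts must be nonnegative, total > 0")
  assert_that(all(rowSums(m) > 0) && all(colSums(m) > 0),
              "zero marginal row or column", class = "waveclass_degenerate")
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Post hoc pairwise group comparisons
#'
#' Pairwise comparisons following a one-way ANOVA. The default is Tukey's
#' HSD on the fitted ANOVA; `method = "games_howell"` uses the Games-Howell
#' procedure (Welch-adjusted, for unequal variances).
#'
#' @inheritParams anova_oneway
#' @param method `"tukey"` (default) or `"games_howell"`.
#' @param conf_level Confidence level (default 0.95, i.e. alpha = .05).
#' @return Tibble `group_1`, `group_2`, `estimate` (mean difference),
#'   `conf_low`, `conf_high`, `p_value`.
#' @export
posthoc_pairwise <- function(data, value, group,
                             method = c("tukey", "games_howell"),
                             conf_level = 0.95) {
  method <- match.arg(method)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- factor(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  assert_that(nlevels(g) >= 2, "need at least two groups")
  if (method == "tukey") {
    fit <- stats::aov(v ~ g)
    tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
    parts <- strsplit(rownames(tk), "-", fixed = TRUE)
    return(tibble::tibble(
      group_1 = vapply(parts, `[`, "", 1),
      group_2 = vapply(parts, `[`, "", 2),
      estimate = tk[, "diff"], conf_low = tk[, "lwr"],
      conf_high = tk[, "upr"], p_value = tk[, "p adj"]))
  }
  games_howell(v, g, conf_level)
}

# Games-Howell: pairwise Welch t with studentized-range reference.
games_howell <- function(v, g, conf_level) {
  lev <- levels(g)
  ns <- tapply(v, g, length)
  ms <- tapply(v, g, mean)
  vs <- tapply(v, g, stats::var)
  pairs <- utils::combn(lev, 2)
  k <- nlevels(g)
  purrr::map_dfr(seq_len(ncol(pairs)), function(c0) {
    a <- pairs[1, c0]; b <- pairs[2, c0]
    se2 <- vs[a] / ns[a] + vs[b] / ns[b]
    df <- se2^2 / ((vs[a] / ns[a])^2 / (ns[a] - 1) +
                     (vs[b] / ns[b])^2 / (ns[b] - 1))
    diff <- ms[a] - ms[b]
    tstat <- diff / sqrt(se2)
    p <- stats::ptukey(abs(tstat) * sqrt(2), k, df, lower.tail = FALSE)
    qcrit <- stats::qtukey(conf_level, k, df) / sqrt(2)
    tibble::tibble(group_1 = a, group_2 = b, estimate = unname(diff),
                   conf_low = unname(diff - qcrit * sqrt(se2)),
                   conf_high = unname(diff + qcrit * sqrt(se2)),
                   p_value = unname(p))
  })
}

#' Cohort description table
#'
#' Group-wise descriptive statistics and omnibus tests for a subjects table:
#' chi-square (no continuity correction) for categorical rows, one-way ANOVA
#' for continuous rows, mirroring a standard sample-characteristics table.
#' If cortisol release features are supplied, a log-AUC row is appended
#' (computed on the subjects with complete profiles).
#'
#' @param subjects Subjects tibble (see [simulate_cohort()]).
#' @param cortisol_features Optional tibble `subject_id`, `log_auc`.
#' @return Tibble `variable`, `type`, one mean-or-count column per group,
#'   `statistic`, `df`, `p_value`.
#' @export
cohort_summary_table <- function(subjects, cortisol_features = NULL) {
  groups <- levels(subjects$group)
  rows <- list()
  cat_row <- function(var, col, yes) {
    tab <- vapply(groups, function(g) {
      x <- col[subjects$group == g]
      c(sum(x == yes, na.rm = TRUE), sum(x != yes, na.rm = TRUE))
    }, numeric(2))
    ct <- chi_square(t(tab))
    out <- tibble::tibble(variable = var, type = "count")
    for (g in groups) out[[g]] <- tab[1, g]
    dplyr::bind_cols(out, ct[, c("statistic", "df", "p_value")])
  }
  num_row <- function(var, col, data = subjects) {
    an <- anova_oneway(data.frame(v = col, g = data$group), v, g)
    out <- tibble::tibble(variable = var, type = "mean (sd)")
    for (g in groups) {
      x <- col[data$group == g]
      out[[g]] <- sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE),
                          stats::sd(x, na.rm = TRUE))
    }
    dplyr::bind_cols(out,
                     tibble::tibble(statistic = an$statistic,
                                    df = an$df_between, p_value = an$p_value))
  }
  rows$sex <- cat_row("Female sex", subjects$sex, "female")
  rows$hand <- cat_row("Right-handed", subjects$handedness, "right")
  rows$edu <- cat_row("Secondary school", subjects$education, "secondary")
  rows$smoke <- cat_row("Nonsmoker", subjects$smoker, "no")
  rows$age <- num_row("Age in years", subjects$age)
  for (sc in c("pswq", "bdi", "ius12", "stait")) {
    rows[[sc]] <- num_row(toupper(sc), subjects[[sc]])
  }
  if (!is.null(cortisol_features)) {
    d <- dplyr::inner_join(subjects, cortisol_features, by = "subject_id")
    rows$cort <- num_row("log-AUC", d$log_auc, data = d)
  }
  out <- purrr::map_dfr(rows, function(r) {
    r[groups] <- lapply(r[groups], as.character)
    r
  })
  tibble::as_tibble(out)
}
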