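# Shared fixtures: scaled-down cohort configurations and toy classification
# problems built in code.

# Demographic counts shrunk proportionally for small test cohorts.
small_demographics <- function(sizes) {
  ref <- default_demographic_counts()
  ref$group <- c("HC", "GAD", "MD")
  for (col in c("female", "right_handed", "secondary_school", "nonsmoker")) {
    ref[[col]] <- pmin(sizes, ceiling(ref[[col]] / 24 * sizes))
  }
  ref
}

small_config <- function(seed = 1L, sizes = c(HC = 8, GAD = 6, MD = 6),
                         n_comorbid = 3, ...) {
  cohort_config(group_sizes = sizes, n_comorbid = n_comorbid,
                demographic_counts = small_demographics(unname(sizes[c("HC", "GAD", "MD")])),
                grid_shape = c(32L, 40L, 32L),
                seed = seed, ...)
}

small_null_config <- function(seed = 1L, sizes = c(HC = 10, GAD = 5, MD = 5),
                              n_comorbid = 2, ...) {
  qp <- default_questionnaire_params()
  hc <- qp[qp$group == "HC", ]
  qp <- dplyr::bind_rows(lapply(c("HC", "GAD", "MD"),
                                function(g) dplyr::mutate(hc, group = g)))
  cp <- tibble::tibble(group = c("HC", "GAD", "MD"), mean = 199.55, sd = 66.05)
  cohort_config(group_sizes = sizes, n_comorbid = n_comorbid,
                demographic_counts = small_demographics(unname(sizes[c("HC", "GAD", "MD")])),
                questionnaire_params = qp, cortisol_params = cp,
                effect_table = default_effect_table(0)[0, ],
                grid_shape = c(32L, 40L, 32L),
                missing_cortisol = 0,
                seed = seed, ...)
}

# Two well-separated Gaussian clouds; returns a matrix with subject-id
# rownames and a labels tibble.
separable_problem <- function(n_per_class = 10, p = 4, gap = 8, seed = 42) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p, gap / 2), n_per_class),
               matrix(rnorm(n_per_class * p, -gap / 2), n_per_class))
    ids <- sprintf("T%02d", seq_len(2 * n_per_class))
    rownames(x) <- ids
    labels <- tibble::tibble(
      subject_id = ids,
      label = factor(rep(c("pos", "neg"), each = n_per_class),
                     levels = c("pos", "neg")))
    list(x = x, labels = labels)
  })
}

noise_problem <- function(n_per_class = 10, p = 4, seed = 42) {
  separable_problem(n_per_class, p, gap = 0, seed = seed)
}

# Wrap a plain matrix (with rownames) as a modality_features object.
as_mf <- function(x, modality = "m") {
  waveclass:::new_modality_features(
    modality, x,
    tibble::tibble(column = seq_len(ncol(x)),
                   name = sprintf("f%d", seq_len(ncol(x))),
                   voxel = NA_integer_,
                   region = sprintf("f%d", seq_len(ncol(x))),
                   side = NA_character_),
    rownames(x))
}

# Independent fixed-point iteration used as the WAVE oracle: deliberately
# plain, with its own convergence loop.
wave_oracle <- function(X, tol = 1e-12, max_iter = 100000) {
  n <- nrow(X)
  k <- ncol(X)
  p <- rep(1 / k, k)
  q <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    q2 <- as.vector((1 - X) %*% p)
    if (sum(q2) == 0) q2 <- rep(1, n)
    q2 <- q2 / sum(q2)
    p2 <- as.vector(t(X) %*% q2)
    if (sum(p2) == 0) p2 <- rep(1, k)
    p2 <- p2 / sum(p2)
    if (max(abs(c(p2 - p, q2 - q))) < tol) {
      return(list(p = p2, q = q2))
    }
    p <- p2
    q <- q2
  }
  list(p = p, q = q)
}
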