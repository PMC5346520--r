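#' Weight-adjusted voting ensemble (WAVE) weights
#'
#' Computes the mutually reinforcing fixed point of classifier weights and
#' case (difficulty) weights from a binary performance matrix `X` (subjects
#' x classifiers, 1 = that classifier's held-out prediction for that subject
#' was correct). Subjects missed by currently well-weighted classifiers are
#' "difficult" (`q` proportional to `(1 - X) p`), and classifiers correct on
#' difficult subjects are up-weighted (`p` proportional to `t(X) q`). Both
#' vectors start uniform and are L1-normalized each step until the maximum
#' absolute change falls below `tol`. Degenerate inputs (all predictions
#' correct, or all wrong) return uniform weights with `degenerate = TRUE`.
#'
#' @param X Binary matrix, rows = subjects, columns = classifiers.
#' @param tol Convergence tolerance on the max absolute change (default
#'   1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return An object of class `wave_weights`: `classifier_weights` (p, sums
#'   to 1), `case_weights` (q, sums to 1), `iterations`, `converged`,
#'   `degenerate`.
#' @examples
#' X <- rbind(c(1, 0), c(1, 0), c(0, 1))
#' wave_weights(X)$classifier_weights
#' @export
wave_weights <- function(X, tol = 1e-10, max_iter = 1000) {
  X <- as.matrix(X)
  assert_that(length(X) > 0 && all(X %in% c(0, 1)),
              "X must be a nonempty binary matrix", class = "waveclass_domain")
  n <- nrow(X); k <- ncol(X)
  p <- rep(1 / k, k)
  q <- rep(1 / n, n)
  if (all(X == 1) || all(X == 0)) {
    return(new_wave_weights(p, q, 0L, TRUE, TRUE, colnames(X)))
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    q_new <- drop((1 - X) %*% p)
    q_new <- if (sum(q_new) > 0) q_new / sum(q_new) else rep(1 / n, n)
    p_new <- drop(crossprod(X, q_new))
    p_new <- if (sum(p_new) > 0) p_new / sum(p_new) else rep(1 / k, k)
    delta <- max(abs(c(p_new - p, q_new - q)))
    p <- p_new
    q <- q_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_wave_weights(p, q, it, converged, FALSE, colnames(X))
}

new_wave_weights <- function(p, q, iterations, converged, degenerate, nm) {
  if (!is.null(nm)) names(p) <- nm
  structure(list(classifier_weights = p, case_weights = q,
                 iterations = iterations, converged = converged,
                 degenerate = degenerate),
            class = "wave_weights")
}

#' @export
print.wave_weights <- function(x, ...) {
  cat("<wave_weights>\n  classifier weights:",
      paste(sprintf("%s=%.3f", names(x$classifier_weights) %||%
                      seq_along(x$classifier_weights),
                    x$classifier_weights), collapse = ", "),
      sprintf("\n  %d iterations, converged: %s%s\n", x$iterations,
              x$converged, if (x$degenerate) " (degenerate input)" else ""))
  invisible(x)
}
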