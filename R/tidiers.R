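#' Tidy per-subject predictions of a cross-validated classifier
#'
#' @param x A `wave_cv` or `wave_ensemble`.
#' @param ... Unused.
#' @return For `tidy()`, the per-subject held-out predictions; for
#'   `glance()`, a one-row tibble of aggregate performance.
#' @method tidy wave_cv
#' @export
tidy.wave_cv <- function(x, ...) {
  x$predictions
}

#' @rdname tidy.wave_cv
#' @method glance wave_cv
#' @export
glance.wave_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(modality = x$modality, n = x$n_folds),
    x$confusion,
    tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                   balanced_accuracy = x$balanced_accuracy,
                   p_value = x$p_value))
}

#' @rdname tidy.wave_cv
#' @method tidy wave_ensemble
#' @export
tidy.wave_ensemble <- function(x, ...) {
  dplyr::bind_cols(x$predictions,
                   tibble::as_tibble(x$votes),
                   tibble::as_tibble(x$weight_trace, .name_repair = ~
                                       paste0("weight_", .x)))
}

#' @rdname tidy.wave_cv
#' @method glance wave_ensemble
#' @export
glance.wave_ensemble <- function(x, ...) {
  out <- dplyr::bind_cols(
    tibble::tibble(modalities = paste(x$modalities, collapse = "+"),
                   n = x$n_folds),
    x$confusion,
    tibble::tibble(sensitivity = x$sensitivity, specificity = x$specificity,
                   balanced_accuracy = x$balanced_accuracy,
                   p_value = x$p_value))
  for (m in x$modalities) out[[paste0("weight_", m)]] <- x$mean_weights[[m]]
  out
}

#' @rdname tidy.wave_cv
#' @method tidy wave_weights
#' @export
tidy.wave_weights <- function(x, ...) {
  tibble::tibble(
    classifier = names(x$classifier_weights) %||%
      paste0("m", seq_along(x$classifier_weights)),
    weight = unname(x$classifier_weights))
}

#' Plot cross-validated classification performance
#'
#' Bar chart of sensitivity, specificity and balanced accuracy with a 50%
#' chance line.
#'
#' @param object A `wave_cv` or `wave_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wave_cv
#' @export
autoplot.wave_cv <- function(object, ...) {
  d <- tibble::tibble(
    metric = factor(c("sensitivity", "specificity", "balanced accuracy"),
                    levels = c("sensitivity", "specificity", "balanced accuracy")),
    value = c(object$sensitivity, object$specificity,
              object$balanced_accuracy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "percent", x = NULL,
                  title = sprintf("LOOCV performance (%s)", object$modality)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.wave_cv
#' @method autoplot wave_ensemble
#' @export
autoplot.wave_ensemble <- function(object, ...) {
  d <- tidyr::pivot_longer(
    tibble::as_tibble(object$weight_trace),
    dplyr::everything(), names_to = "classifier", values_to = "weight")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$classifier, y = .data$weight)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(title = "WAVE classifier weights across outer folds",
                  x = NULL, y = "classifier weight") +
    ggplot2::theme_minimal()
}

#' Plot a region weight summary
#'
#' Horizontal bar chart of per-region mean absolute weights from
#' [summarize_region_weights()].
#'
#' @param summary Tibble from [summarize_region_weights()].
#' @param top Number of top-ranked regions to show.
#' @return A ggplot object.
#' @export
plot_region_weights <- function(summary, top = 15) {
  d <- head(summary, top)
  lab <- ifelse(is.na(d$side), d$region, paste(d$region, d$side))
  d$label <- factor(lab, levels = rev(lab))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$weight_abs, y = .data$label)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "mean |weight|", y = NULL,
                  title = "Regional weight averages") +
    ggplot2::theme_minimal()
}
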