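# ggplot2 visualizations for the main result types.

#' @export
autoplot.axis_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(linetype = "dashed", color = "grey50") +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::labs(x = "observed axis position (mm)",
                  y = "out-of-fold predicted position (mm)",
                  title = sprintf("%s: r² = %.2f, MAE = %.2f mm",
                                  object$scheme, object$r2, object$mae)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.removal_trace <- function(object, ...) {
  df <- mutate(object, removed_cum = cumsum(lengths(.data$removed)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$removed_cum, y = .data$cv_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "probes removed", y = "10-fold CV r²",
                  title = paste0(attr(object, "mode"), " probe removal")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.split_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(x = .data$split_y, y = .data$accuracy)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = c(object$posterior_cut,
                                       object$anterior_cut),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "split position y (mm)",
                  y = "classification accuracy") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$r2, color = "red") +
    ggplot2::labs(x = "null r²", y = "count",
                  title = sprintf("observed r² = %.3f, p = %.4f",
                                  object$r2, object$p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cluster_solution <- function(object, ...) {
  ggplot2::ggplot(object$silhouette,
                  ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dashed") +
    ggplot2::labs(x = "number of clusters", y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.embedding_gradients <- function(object, ...) {
  df <- tibble(gradient = seq_along(object$variance_explained),
               variance_explained = object$variance_explained)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gradient,
                                   y = .data$variance_explained)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "gradient", y = "variance explained") +
    ggplot2::theme_minimal()
}
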