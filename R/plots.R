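#' Goodness-of-fit plot for an activity dataset
#'
#' Observed vs predicted activity with the identity line, training and test
#' compounds distinguished.
#'
#' @param ds A dataset with `observed`, `predicted` and `split` columns
#'   (e.g. from [load_paper_dataset()]).
#' @return A ggplot object.
#' @export
plot_goodness_of_fit <- function(ds) {
  ggplot2::ggplot(ds, ggplot2::aes(.data$observed, .data$predicted,
                                   colour = .data$split)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Observed pIC50", y = "Predicted pIC50",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Residual plot for an activity dataset
#'
#' @inheritParams plot_goodness_of_fit
#' @return A ggplot object.
#' @export
plot_residuals <- function(ds) {
  ggplot2::ggplot(ds, ggplot2::aes(.data$predicted, .data$residual,
                                   colour = .data$split)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Predicted pIC50", y = "Residual (predicted - observed)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot qsar_dataset
autoplot.qsar_dataset <- function(object, ...) plot_goodness_of_fit(object)

#' Scree / explained-variance plot for a PCA or PCR fit
#'
#' @param object A `qsar_pca` or `pcr_model`.
#' @param ... Unused.
#' @return A ggplot object showing per-component explained-variance shares;
#'   for a `pcr_model` the retained components are highlighted.
#' @export
#' @method autoplot qsar_pca
autoplot.qsar_pca <- function(object, ...) {
  df <- tibble::tibble(component = seq_along(object$shares),
                       share = object$shares)
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Principal component", y = "Explained variance share") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.qsar_pca
#' @export
#' @method autoplot pcr_model
autoplot.pcr_model <- function(object, ...) {
  df <- tibble::tibble(
    component = seq_along(object$pca$shares),
    share = object$pca$shares,
    retained = seq_along(object$pca$shares) <= object$p_prime
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$component, .data$share,
                                   fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "Principal component", y = "Explained variance share",
                  fill = "Retained") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
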