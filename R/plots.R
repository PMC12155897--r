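#' @export
autoplot.quadfit <- function(object, ...) {
  df <- tibble::tibble(actual = object$response, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$actual, .data$predicted)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed response (%)",
                  y = "fitted response (%)",
                  title = "Response-surface fit") +
    ggplot2::theme_minimal()
}

#' Contour plot of a fitted response surface for one factor pair
#'
#' Evaluates the fitted quadratic over a grid of two factors (actual units)
#' with the remaining factor held at a coded value.
#'
#' @param fit A `"quadfit"`.
#' @param which Indices of the two factors to plot (default 1, 2).
#' @param fix_coded Coded level of the held-out factor (default 0, center).
#' @param n Grid resolution per axis.
#' @return A ggplot.
#' @export
plot_surface <- function(fit, which = c(1, 2), fix_coded = 0, n = 60) {
  stopifnot(inherits(fit, "quadfit"), length(which) == 2)
  other <- setdiff(1:3, which)
  grid_coded <- as.matrix(expand.grid(seq(-1, 1, length.out = n),
                                      seq(-1, 1, length.out = n)))
  coded <- matrix(fix_coded, nrow(grid_coded), 3)
  coded[, which] <- grid_coded
  colnames(coded) <- fit$factors$name
  coded_tbl <- tibble::as_tibble(coded)
  df <- decode_design(coded_tbl, fit$factors)
  df$response <- predict(fit, coded_tbl, coded = TRUE)
  nx <- fit$factors$name[which[1]]
  ny <- fit$factors$name[which[2]]
  ggplot2::ggplot(df, ggplot2::aes(.data[[nx]], .data[[ny]],
                                   z = .data$response)) +
    ggplot2::geom_contour_filled(bins = 12) +
    ggplot2::labs(
      x = sprintf("%s (%s)", nx, fit$factors$units[which[1]]),
      y = sprintf("%s (%s)", ny, fit$factors$units[which[2]]),
      fill = "yield (%)",
      title = sprintf("Fitted surface (%s at coded %g)",
                      fit$factors$name[other], fix_coded)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mlp_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$hidden, .data$best_mse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hidden neurons",
                  y = "best validation MSE (normalized)",
                  title = "Hidden-layer size sweep") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ga_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("best", "mean"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "fitness (predicted yield, %)",
                  title = "Genetic-algorithm convergence") +
    ggplot2::theme_minimal()
}
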