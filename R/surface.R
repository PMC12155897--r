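# Quadratic-form matrix B of the fitted surface: diag = pure-quadratic
# coefficients, off-diag = half the interaction coefficients, so that
# y = b0 + b'x + x'Bx in coded units.
quad_form_matrix <- function(fit) {
  b <- fit$coefficients
  B <- diag(unname(b[8:10]))  # terms 8:10 are the pure quadratics
  B[1, 2] <- B[2, 1] <- b[[5]] / 2
  B[1, 3] <- B[3, 1] <- b[[6]] / 2
  B[2, 3] <- B[3, 2] <- b[[7]] / 2
  B
}

surface_optimum <- function(fit, coded_point, constrained) {
  coded <- tibble::as_tibble(as.list(stats::setNames(coded_point,
                                                     fit$factors$name)))
  actual <- decode_design(coded, fit$factors)
  B <- quad_form_matrix(fit)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-10
  nature <- if (any(abs(ev) < tol)) {
    warning("near-zero surface curvature: ridge/degenerate stationary system",
            call. = FALSE)
    "saddle"
  } else if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  structure(
    list(coded_point = stats::setNames(coded_point, fit$factors$name),
         actual_point = actual,
         predicted_response = predict(fit, coded, coded = TRUE),
         nature = nature,
         eigenvalues = ev,
         constrained = constrained),
    class = "surface_optimum"
  )
}

#' @export
print.surface_optimum <- function(x, ...) {
  cat(if (x$constrained) "Box-constrained" else "Stationary-point",
      " surface optimum (", x$nature, ")\n", sep = "")
  print(as.data.frame(x$actual_point), digits = 6)
  cat(sprintf("predicted response: %.4f\n", x$predicted_response))
  invisible(x)
}

#' @export
tidy.surface_optimum <- function(x, ...) {
  dplyr::bind_cols(
    x$actual_point,
    tibble::tibble(predicted = x$predicted_response, nature = x$nature,
                   constrained = x$constrained))
}

#' Stationary point of a fitted quadratic surface
#'
#' Solves the stationary-point system \eqn{2 B x = -b} of the quadratic
#' surface \eqn{y = b_0 + b'x + x'Bx} exactly, where `B` has the
#' pure-quadratic coefficients on its diagonal and half the interaction
#' coefficients off it. The nature of the point (maximum / minimum / saddle)
#' is classified by the eigenvalue signs of `B`; eigenvalues within 1e-10 of
#' zero indicate a ridge and are reported as a saddle with a warning.
#'
#' @param fit A `"quadfit"` from [fit_quadratic()].
#' @return A `"surface_optimum"`: coded and actual coordinates, predicted
#'   response, and nature. Use [tidy()] for a one-row tibble.
#' @examples
#' fit <- fit_quadratic(agpl_runs(), agpl_factors())
#' stationary_point(fit)
#' @export
stationary_point <- function(fit) {
  stopifnot(inherits(fit, "quadfit"))
  B <- quad_form_matrix(fit)
  if (abs(det(B)) < 1e-12) {
    stop("singular quadratic-form matrix: surface has a ridge; ",
         "use maximize_in_box() instead", call. = FALSE)
  }
  b_lin <- unname(fit$coefficients[2:4])
  x_star <- drop(solve(2 * B, -b_lin))
  surface_optimum(fit, x_star, constrained = FALSE)
}

#' Box-constrained maximum of a fitted quadratic surface
#'
#' Maximizes the fitted quadratic over a coded box by multistart bounded
#' quasi-Newton ascent (`optim(method = "L-BFGS-B")`) seeded from the best
#' points of a 21x21x21 grid; the result is never below the best grid
#' evaluation. A flat (all-zero) surface returns the box center.
#'
#' @param fit A `"quadfit"`.
#' @param lower,upper Coded bounds, length 3 or scalars. Default the
#'   experimental cube `[-1, 1]^3`.
#' @param n_starts Number of multistart seeds taken from the grid.
#' @return A `"surface_optimum"` with `constrained = TRUE`.
#' @examples
#' fit <- fit_quadratic(agpl_runs(), agpl_factors())
#' maximize_in_box(fit)
#' @export
maximize_in_box <- function(fit, lower = -1, upper = 1, n_starts = 8) {
  stopifnot(inherits(fit, "quadfit"))
  lower <- rep_len(lower, 3)
  upper <- rep_len(upper, 3)
  stopifnot(all(lower < upper))
  b0 <- fit$coefficients[[1]]
  b_lin <- unname(fit$coefficients[2:4])
  B <- quad_form_matrix(fit)
  if (all(abs(b_lin) < 1e-14) && all(abs(B) < 1e-14)) {
    return(surface_optimum(fit, (lower + upper) / 2, constrained = TRUE))
  }
  f <- function(x) b0 + sum(b_lin * x) + drop(t(x) %*% B %*% x)
  g <- function(x) b_lin + 2 * drop(B %*% x)

  grid1 <- purrr::map(1:3, ~seq(lower[.x], upper[.x], length.out = 21))
  grid <- as.matrix(expand.grid(grid1))
  vals <- grid %*% b_lin + rowSums((grid %*% B) * grid) + b0
  ord <- order(vals, decreasing = TRUE)
  starts <- grid[ord[seq_len(min(n_starts, nrow(grid)))], , drop = FALSE]

  best_x <- grid[ord[1], ]
  best_v <- vals[ord[1]]
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], fn = f, gr = g, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(fnscale = -1))
    if (opt$value > best_v) {
      best_v <- opt$value
      best_x <- opt$par
    }
  }
  surface_optimum(fit, best_x, constrained = TRUE)
}
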