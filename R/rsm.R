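quad_terms <- function(factors) {
  nm <- factors$name
  c("(Intercept)", nm,
    paste0(nm[1], ":", nm[2]), paste0(nm[1], ":", nm[3]),
    paste0(nm[2], ":", nm[3]),
    paste0(nm, "^2"))
}

# 17 x 10 model matrix of the full second-order polynomial in coded units
quad_model_matrix <- function(coded, factors) {
  x <- as.matrix(coded[factors$name])
  X <- cbind(1, x,
             x[, 1] * x[, 2], x[, 1] * x[, 3], x[, 2] * x[, 3],
             x[, 1]^2, x[, 2]^2, x[, 3]^2)
  colnames(X) <- quad_terms(factors)
  X
}

#' Fit a full second-order response-surface model
#'
#' Fits the 10-term quadratic polynomial
#' \deqn{y = b_0 + \sum_i b_i x_i + \sum_{i<j} b_{ij} x_i x_j + \sum_i b_{ii} x_i^2}
#' in coded units by ordinary least squares (QR decomposition via [lm()]).
#' Coefficients are reported in coded units so their magnitudes are directly
#' comparable across factors.
#'
#' @param data Design tibble with factor columns and a response column.
#' @param factors Factor-specification tibble ([factor_spec()]).
#' @param response Name of the response column. Default `"response"`.
#' @param coded Is `data` already in coded units? Default `FALSE` (actual).
#' @return An object of class `"quadfit"`: coefficients, the coded design,
#'   fitted values and residuals. Methods: [predict()], [tidy()],
#'   [glance()], [rsm_anova()], [stationary_point()], [maximize_in_box()],
#'   [autoplot()].
#' @examples
#' fit <- fit_quadratic(agpl_runs(), agpl_factors())
#' tidy(fit)
#' @export
fit_quadratic <- function(data, factors, response = "response",
                          coded = FALSE) {
  assert_three_factors(factors)
  if (!response %in% names(data)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (nrow(data) < 10L) {
    stop("need at least 10 runs with responses to fit the 10-term model",
         call. = FALSE)
  }
  coded_tbl <- if (coded) tibble::as_tibble(data) else code_design(data, factors)
  y <- coded_tbl[[response]]
  X <- quad_model_matrix(coded_tbl, factors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design: collinear column(s) ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  structure(
    list(coefficients = coef,
         factors = factors,
         coded = coded_tbl[factors$name],
         response = y,
         fitted = fitted,
         residuals = y - fitted,
         n = length(y)),
    class = "quadfit"
  )
}

#' @export
print.quadfit <- function(x, ...) {
  cat("Second-order response-surface model (coded units),",
      x$n, "runs\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' @param object A `"quadfit"` from [fit_quadratic()].
#' @param newdata Data frame with the factor columns (actual units unless
#'   `coded = TRUE`). Defaults to the fitting design.
#' @param coded Is `newdata` in coded units?
#' @param ... Unused.
#' @return Numeric vector of predicted responses (%).
#' @export
predict.quadfit <- function(object, newdata = NULL, coded = FALSE, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- tibble::as_tibble(newdata)
  coded_tbl <- if (coded) newdata else code_design(newdata, object$factors)
  unname(drop(quad_model_matrix(coded_tbl, object$factors) %*%
               object$coefficients))
}

#' @export
tidy.quadfit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @export
glance.quadfit <- function(x, ...) {
  an <- rsm_anova(x)
  tibble::tibble(r.squared = an$r2, adj.r.squared = an$adj_r2,
                 cv_percent = an$cv_percent, n = x$n)
}

#' ANOVA of a fitted response-surface model
#'
#' Partitions the corrected total sum of squares of a [fit_quadratic()] model
#' into the model, its nine individual terms, the residual, and (when the
#' design has replicate runs) lack-of-fit and pure-error components.
#'
#' Per-term sums of squares are partial (Type III), \eqn{SS_j = b_j^2/c_{jj}}
#' with \eqn{c_{jj}} the j-th diagonal of the inverse normal matrix
#' \eqn{(X'X)^{-1}}; with pure-quadratic columns non-orthogonal to the
#' intercept this is the convention response-surface software prints.
#' Sequential (Type I) sums of squares are available with
#' `type = "sequential"`. F statistics divide by the residual mean square
#' (the lack-of-fit F uses the pure-error mean square); p-values are
#' upper-tail F probabilities. Replicate groups for pure error are runs with
#' exactly equal coded level vectors.
#'
#' @param fit A `"quadfit"` object.
#' @param type `"partial"` (default) or `"sequential"` per-term sums of
#'   squares.
#' @return An object of class `"rsm_anova"`: the ANOVA rows plus the fit
#'   summary statistics \eqn{R^2}, adjusted \eqn{R^2}, the coefficient of
#'   variation (100 x root residual mean square / mean response) and the
#'   mean response. [tidy()] returns the table, [glance()] the summaries.
#' @examples
#' fit <- fit_quadratic(agpl_runs(), agpl_factors())
#' tidy(rsm_anova(fit))
#' glance(rsm_anova(fit))
#' @export
rsm_anova <- function(fit, type = c("partial", "sequential")) {
  stopifnot(inherits(fit, "quadfit"))
  type <- match.arg(type)
  y <- fit$response
  n <- fit$n
  X <- quad_model_matrix(fit$coded, fit$factors)
  p <- ncol(X)
  df_model <- p - 1L
  df_resid <- n - p
  ss_total <- sum((y - mean(y))^2)
  ss_resid <- sum(fit$residuals^2)
  ss_model <- ss_total - ss_resid
  ms_resid <- ss_resid / df_resid

  if (type == "partial") {
    cinv <- diag(solve(crossprod(X)))
    ss_terms <- fit$coefficients^2 / cinv
    ss_terms <- ss_terms[-1]  # drop intercept row
  } else {
    # sequential: SS added by each column in model order
    ss_terms <- numeric(df_model)
    for (j in 2:p) {
      fit_j <- qr.fitted(qr(X[, 1:j, drop = FALSE]), y)
      fit_jm1 <- qr.fitted(qr(X[, 1:(j - 1), drop = FALSE]), y)
      ss_terms[j - 1] <- sum((fit_j - mean(y))^2) - sum((fit_jm1 - mean(y))^2)
    }
    names(ss_terms) <- colnames(X)[-1]
  }

  # pure error from exact replicate groups of coded vectors
  key <- do.call(paste, c(fit$coded, sep = "\r"))
  groups <- split(y, key)
  reps <- groups[lengths(groups) > 1L]
  has_reps <- length(reps) > 0L
  if (has_reps) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1L)
    ss_lof <- ss_resid - ss_pe
    df_lof <- df_resid - df_pe
  } else {
    warning("no replicate runs: lack-of-fit and pure-error rows omitted",
            call. = FALSE)
  }

  row <- function(source, ss, df) {
    ms <- ss / df
    f <- ms / ms_resid
    tibble::tibble(source = source, ss = ss, df = as.integer(df), ms = ms,
                   statistic = f,
                   p.value = stats::pf(f, df, df_resid, lower.tail = FALSE))
  }
  term_rows <- purrr::map2_dfr(names(ss_terms), unname(ss_terms),
                               function(nm, ss) row(nm, ss, 1L))
  rows <- dplyr::bind_rows(row("Model", ss_model, df_model), term_rows)
  resid_row <- tibble::tibble(source = "Residual", ss = ss_resid,
                              df = as.integer(df_resid), ms = ms_resid,
                              statistic = NA_real_, p.value = NA_real_)
  rows <- dplyr::bind_rows(rows, resid_row)
  if (has_reps) {
    ms_pe <- ss_pe / df_pe
    f_lof <- (ss_lof / df_lof) / ms_pe
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(source = "Lack of Fit", ss = ss_lof,
                     df = as.integer(df_lof), ms = ss_lof / df_lof,
                     statistic = f_lof,
                     p.value = stats::pf(f_lof, df_lof, df_pe,
                                         lower.tail = FALSE)),
      tibble::tibble(source = "Pure Error", ss = ss_pe, df = as.integer(df_pe),
                     ms = ms_pe, statistic = NA_real_, p.value = NA_real_))
  }
  rows <- dplyr::bind_rows(
    rows,
    tibble::tibble(source = "Corrected Total", ss = ss_total,
                   df = as.integer(n - 1L), ms = NA_real_,
                   statistic = NA_real_, p.value = NA_real_))

  structure(
    list(table = rows,
         r2 = ss_model / ss_total,
         adj_r2 = 1 - (1 - ss_model / ss_total) * (n - 1) / df_resid,
         cv_percent = 100 * sqrt(ms_resid) / mean(y),
         response_mean = mean(y),
         type = type),
    class = "rsm_anova"
  )
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("Response-surface ANOVA (", x$type, " SS)\n", sep = "")
  print(as.data.frame(x$table), digits = 4)
  cat(sprintf("R2 = %.4f  adj R2 = %.4f  CV%% = %.2f\n",
              x$r2, x$adj_r2, x$cv_percent))
  invisible(x)
}

#' @export
tidy.rsm_anova <- function(x, ...) x$table

#' @export
glance.rsm_anova <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, adj.r.squared = x$adj_r2,
                 cv_percent = x$cv_percent, response_mean = x$response_mean)
}
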