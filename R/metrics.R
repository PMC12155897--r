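#' Model-comparison metrics over paired predictions and observations
#'
#' Computes the statistics conventionally used to compare response-surface
#' and neural-network predictions of the same experiment:
#' \itemize{
#'   \item `r.squared`: \eqn{1 - \sum(p_i - a_i)^2 / \sum(a_i - \bar a)^2}
#'   \item `mse`: \eqn{\frac1n \sum (p_i - a_i)^2}; `rmse` its square root
#'   \item `mad`: mean absolute deviation \eqn{\frac1n \sum |a_i - p_i|}
#'   \item `aad_pct`: absolute average deviation as a percent of the
#'     observation, \eqn{\frac{100}{n} \sum |a_i - p_i| / a_i}
#' }
#' Both absolute-deviation conventions circulate under the name "AAD";
#' `mad` is in response units, `aad_pct` is relative, and we report both.
#'
#' @param actual Observed responses.
#' @param predicted Model predictions, same length.
#' @return One-row tibble with columns `r.squared`, `mse`, `rmse`, `mad`,
#'   `aad_pct`, `n`. `aad_pct` is `NA` when any observation is zero.
#' @examples
#' fit <- fit_quadratic(agpl_runs(), agpl_factors())
#' model_metrics(agpl_runs()$response, predict(fit))
#' @export
model_metrics <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("'actual' and 'predicted' must have the same length", call. = FALSE)
  }
  n <- length(actual)
  if (n < 2L) stop("need at least 2 prediction pairs", call. = FALSE)
  err <- predicted - actual
  mse <- mean(err^2)
  aad <- if (any(actual == 0)) {
    warning("zero observed value: relative AAD undefined", call. = FALSE)
    NA_real_
  } else {
    100 * mean(abs(err) / actual)
  }
  tibble::tibble(
    r.squared = 1 - sum(err^2) / sum((actual - mean(actual))^2),
    mse = mse,
    rmse = sqrt(mse),
    mad = mean(abs(err)),
    aad_pct = aad,
    n = n
  )
}
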