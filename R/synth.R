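#' Simulate responses from a known quadratic surface
#'
#' Fills the `response` column of a design with draws from the
#' data-generating model the response-surface analysis assumes: a quadratic
#' mean in coded units plus i.i.d. Gaussian error. With `noise_sd = 0` the
#' fitted model must recover `coefficients` exactly, which anchors the
#' parameter-recovery tests.
#'
#' @param coefficients Length-10 numeric vector in model order (intercept,
#'   3 linear, 3 interactions in pair order (1,2), (1,3), (2,3), 3 pure
#'   quadratics), in coded units.
#' @param design Design tibble in actual units (e.g. from [bbd_design()]).
#' @param factors Factor-specification tibble.
#' @param noise_sd Gaussian error standard deviation in response units.
#' @param seed Optional integer seed.
#' @return The design tibble with `response` filled in.
#' @examples
#' truth <- c(14.9, 0.6, 0.1, 0.1, 0, 0, -0.5, -0.3, -0.5, -0.6)
#' sim_surface(truth, bbd_design(agpl_factors()), agpl_factors(),
#'             noise_sd = 0.1, seed = 1)
#' @export
sim_surface <- function(coefficients, design, factors, noise_sd = 0,
                        seed = NULL) {
  stopifnot(length(coefficients) == 10, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  coded <- code_design(design, factors)
  X <- quad_model_matrix(coded, factors)
  out <- tibble::as_tibble(design)
  out$response <- drop(X %*% coefficients) +
    stats::rnorm(nrow(X), 0, noise_sd)
  out
}

#' Simulate a linear calibration series
#'
#' @param slope,intercept Generating line.
#' @param x Standard levels.
#' @param noise_sd Gaussian noise on the signal.
#' @param seed Optional integer seed.
#' @return Tibble with columns `x`, `y`.
#' @examples
#' sim_calibration(16.784, -0.0218, seq(0, 0.12, length.out = 6))
#' @export
sim_calibration <- function(slope, intercept, x, noise_sd = 0, seed = NULL) {
  stopifnot(length(x) >= 2, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(x = x, y = slope * x + intercept +
                   stats::rnorm(length(x), 0, noise_sd))
}

# geometric-decay trace whose ratio-sum AUC equals `target` exactly:
# AUC(r) = 1 + r(1-r^n)/(1-r) is continuous and increasing in r on (0,1)
decay_trace <- function(target, n_times, f0) {
  stopifnot(target >= 1, target < n_times + 1)
  if (target == 1) return(c(f0, rep(0, n_times)))
  ratio <- stats::uniroot(
    function(r) 1 + r * (1 - r^n_times) / (1 - r) - target,
    lower = 1e-12, upper = 1 - 1e-12, tol = 1e-14)$root
  f0 * ratio^(0:n_times)
}

#' Simulate an ORAC kinetic plate with known Trolox equivalents
#'
#' Builds a long-format fluorescence plate whose sample wells have net AUC
#' equal to `slope * te + intercept` (plus optional Gaussian noise on the
#' AUC), together with AAPH-blank wells and Trolox standards spanning the
#' assay's working range, so [orac_te()] must recover `te_values` exactly
#' at zero noise. Each trace is an exponential decay shaped analytically to
#' hit its target AUC; the ORAC arithmetic only sees the ratio sums, so the
#' decay shape is a free modelling choice.
#'
#' @param te_values Planted sample Trolox equivalents (uM).
#' @param slope,intercept Generating net-AUC-vs-Trolox line. Defaults are
#'   a typical fluorescein/AAPH plate calibration.
#' @param trolox_conc Standard concentrations (uM).
#' @param blank_auc AUC of the AAPH blank wells.
#' @param noise_sd Gaussian noise added to each non-blank well's target AUC.
#' @param n_times Post-baseline readings (default 60, i.e. 2-min intervals
#'   over 120 min).
#' @param interval Reading interval in minutes.
#' @param f0 Baseline fluorescence (arbitrary units).
#' @param seed Optional integer seed.
#' @return Long tibble with columns `well`, `role`, `conc`, `time`,
#'   `signal`.
#' @examples
#' plate <- sim_plate(c(10, 25))
#' tidy(orac_te(plate))
#' @export
sim_plate <- function(te_values, slope = 0.8981, intercept = 2.8097,
                      trolox_conc = c(6.25, 12.5, 25, 50), blank_auc = 3,
                      noise_sd = 0, n_times = 60, interval = 2, f0 = 1000,
                      seed = NULL) {
  stopifnot(slope > 0, noise_sd >= 0, blank_auc >= 1)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, by = interval, length.out = n_times + 1)
  wells <- dplyr::bind_rows(
    tibble::tibble(well = "B1", role = "blank", conc = NA_real_,
                   target = blank_auc),
    tibble::tibble(well = paste0("T", seq_along(trolox_conc)),
                   role = "trolox", conc = trolox_conc,
                   target = blank_auc + slope * trolox_conc + intercept),
    tibble::tibble(well = paste0("S", seq_along(te_values)),
                   role = "sample", conc = NA_real_,
                   target = blank_auc + slope * te_values + intercept)
  )
  noisy <- wells$target +
    ifelse(wells$role == "blank", 0, stats::rnorm(nrow(wells), 0, noise_sd))
  purrr::map_dfr(seq_len(nrow(wells)), function(i) {
    tibble::tibble(well = wells$well[i], role = wells$role[i],
                   conc = wells$conc[i], time = times,
                   signal = decay_trace(noisy[i], n_times, f0))
  })
}
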