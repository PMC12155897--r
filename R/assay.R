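#' Total-phenolics yield from a colorimetric concentration
#'
#' Percent polyphenol yield of the dry raw material,
#' \eqn{Y = 100 \cdot C \cdot V \cdot r / W}, where the concentration comes
#' from a Folin-Ciocalteu gallic-acid calibration.
#'
#' @param concentration Assay concentration C in g/mL.
#' @param volume Extraction volume V in mL.
#' @param dilution Dilution ratio r (dimensionless, >= 1 for a diluted
#'   aliquot).
#' @param mass Dry sample mass W in g.
#' @return Yield in percent of dry mass. Vectorized.
#' @examples
#' polyphenol_yield(0.001, 100, 1, 2)  # 5 %
#' @export
polyphenol_yield <- function(concentration, volume, dilution, mass) {
  vals <- list(concentration = concentration, volume = volume,
               dilution = dilution, mass = mass)
  for (nm in names(vals)) {
    if (any(!is.finite(vals[[nm]]) | vals[[nm]] <= 0)) {
      stop("'", nm, "' must be strictly positive", call. = FALSE)
    }
  }
  100 * concentration * volume * dilution / mass
}

#' Fit a linear calibration line
#'
#' Ordinary least-squares line through calibration standards, e.g.
#' absorbance vs gallic-acid concentration, or net fluorescence AUC vs
#' Trolox concentration.
#'
#' @param x Standard levels (>= 3 distinct points).
#' @param y Measured signals.
#' @return A `"linear_calibration"`: `slope`, `intercept`, `r.squared`,
#'   `n`. Use [calibration_concentration()] to invert it.
#' @examples
#' cal <- fit_calibration(0:4, 2 * (0:4) + 1)
#' cal$slope
#' @export
fit_calibration <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 calibration points", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("degenerate calibration: constant x", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r.squared = r2,
         n = length(x)),
    class = "linear_calibration"
  )
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("y = %.4gx %+.4g  (R2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r.squared, x$n))
  invisible(x)
}

#' @export
glance.linear_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r.squared, n = x$n)
}

#' Invert a linear calibration
#'
#' @param calibration A `"linear_calibration"`.
#' @param y Measured signal(s).
#' @return The standard level(s) `(y - intercept)/slope`.
#' @export
calibration_concentration <- function(calibration, y) {
  if (calibration$slope <= 0) {
    stop("invalid calibration: slope must be positive", call. = FALSE)
  }
  (y - calibration$intercept) / calibration$slope
}

#' Area under a fluorescence-decay curve
#'
#' Ratio-sum AUC of a kinetic trace read at uniform intervals:
#' \eqn{AUC = 1 + \sum_{i \ge 1} f_i / f_0}, with \eqn{f_0} the baseline
#' (first) reading. No trapezoid correction is applied; the statistic
#' depends only on the ratios, so it is invariant to uniform scaling of the
#' readings.
#'
#' @param f Numeric vector of fluorescence readings, baseline first.
#' @return The AUC (dimensionless).
#' @examples
#' auc_curve(c(100, rep(100, 60)))  # constant trace: 61
#' @export
auc_curve <- function(f) {
  if (length(f) == 0) stop("empty fluorescence curve", call. = FALSE)
  if (!is.finite(f[1]) || f[1] <= 0) {
    stop("baseline reading f0 must be positive", call. = FALSE)
  }
  1 + sum(f[-1] / f[1])
}

plate_well_auc <- function(plate) {
  needed <- c("well", "role", "conc", "time", "signal")
  missing <- setdiff(needed, names(plate))
  if (length(missing)) {
    stop("plate is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  plate |>
    dplyr::arrange(.data$well, .data$time) |>
    dplyr::group_by(.data$well, .data$role, .data$conc) |>
    dplyr::summarise(auc = auc_curve(.data$signal), .groups = "drop")
}

#' ORAC Trolox equivalence from a kinetic plate
#'
#' Computes per-well ratio-sum AUCs ([auc_curve()]) from a long-format
#' plate, subtracts the mean AUC of the radical-generator (AAPH) blank
#' wells to obtain net AUCs, and converts sample net AUCs to Trolox
#' equivalents. The primary path interpolates on the net-AUC-vs-Trolox
#' calibration line (fitted from the plate's `trolox` wells unless a
#' calibration is supplied); the alternative single-point `"ratio"` path
#' scales by the mean net AUC per micromolar of the Trolox standards.
#' Negative equivalents are clamped to zero with a warning.
#'
#' @param plate Long tibble with columns `well`, `role` (one of `"blank"`,
#'   `"trolox"`, `"sample"`), `conc` (Trolox standards, uM; `NA` otherwise),
#'   `time` (min) and `signal`.
#' @param calibration Optional `"linear_calibration"` of net AUC vs Trolox
#'   concentration; fitted from the plate's standards when `NULL`.
#' @param mass_basis Micromoles of Trolox equivalents per gram of dry
#'   sample corresponding to 1 uM in the well (assay volume / mass
#'   conversion). Default 1 reports well-level uM.
#' @param method `"calibration"` (default) or `"ratio"`.
#' @return An `"orac_result"`: per-sample tibble (`well`, `auc`, `net_auc`,
#'   `te_um`, `te_umol_per_g`), the blank AUC and the calibration used.
#'   [tidy()] returns the sample tibble.
#' @export
orac_te <- function(plate, calibration = NULL, mass_basis = 1,
                    method = c("calibration", "ratio")) {
  method <- match.arg(method)
  aucs <- plate_well_auc(plate)
  blanks <- aucs[aucs$role == "blank", ]
  if (nrow(blanks) == 0) stop("plate has no blank wells", call. = FALSE)
  auc_blank <- mean(blanks$auc)
  trolox <- aucs[aucs$role == "trolox", ]
  samples <- aucs[aucs$role == "sample", ]
  if (nrow(samples) == 0) stop("plate has no sample wells", call. = FALSE)
  samples$net_auc <- samples$auc - auc_blank

  if (method == "calibration") {
    if (is.null(calibration)) {
      if (nrow(trolox) < 3) {
        stop("need >= 3 Trolox standards to fit the calibration",
             call. = FALSE)
      }
      calibration <- fit_calibration(trolox$conc, trolox$auc - auc_blank)
    }
    te <- calibration_concentration(calibration, samples$net_auc)
  } else {
    if (nrow(trolox) == 0) {
      stop("single-point path needs at least one Trolox standard",
           call. = FALSE)
    }
    per_um <- mean((trolox$auc - auc_blank) / trolox$conc)
    if (per_um <= 0) {
      stop("invalid standards: nonpositive net AUC per uM", call. = FALSE)
    }
    te <- samples$net_auc / per_um
  }
  if (any(te < -1e-9)) {
    warning("negative Trolox equivalents clamped to 0", call. = FALSE)
  }
  te <- pmax(te, 0)
  structure(
    list(samples = tibble::tibble(well = samples$well, auc = samples$auc,
                                  net_auc = samples$net_auc, te_um = te,
                                  te_umol_per_g = te * mass_basis),
         auc_blank = auc_blank,
         calibration = calibration,
         method = method),
    class = "orac_result"
  )
}

#' @export
print.orac_result <- function(x, ...) {
  cat("ORAC result (", x$method, " path), blank AUC ",
      signif(x$auc_blank, 5), "\n", sep = "")
  print(as.data.frame(x$samples), digits = 5)
  invisible(x)
}

#' @export
tidy.orac_result <- function(x, ...) x$samples
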