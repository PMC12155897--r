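#' Define an experimental factor with its coded levels
#'
#' A factor specification records the actual values that the coded levels
#' -1, 0 and +1 of a three-level response-surface design correspond to.
#' Levels must be equispaced: the center is the midpoint of `low` and `high`.
#'
#' @param name Column name of the factor in a design table.
#' @param low,high Actual values at coded -1 and +1. `low < high`.
#' @param center Actual value at coded 0. Defaults to `(low + high)/2` and
#'   must equal it (equispaced levels).
#' @param units Unit string, e.g. `"mL/g"`. Informational only.
#'
#' @return A one-row tibble with columns `name`, `units`, `low`, `center`,
#'   `high`. Bind rows of these to describe a multi-factor design.
#' @examples
#' factor_spec("liquid_solid_ratio", 20, 40, units = "mL/g")
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2,
                        units = "") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(low < center && center < high)) {
    stop("factor levels must satisfy low < center < high", call. = FALSE)
  }
  if (abs(center - (low + high) / 2) > 1e-9 * max(1, abs(center))) {
    stop("factor levels must be equispaced: center must equal (low + high)/2",
         call. = FALSE)
  }
  tibble::tibble(name = name, units = units,
                 low = low, center = center, high = high)
}

#' Factor specifications of the packaged polyphenol-extraction study
#'
#' The three ultrasound-assisted extraction factors of the packaged 17-run
#' Box-Behnken dataset: liquid-to-solid ratio (20/30/40 mL/g), ultrasonic
#' power (450/600/750 W) and extraction time (30/40/50 min). The response is
#' polyphenol yield in percent of dry leaf mass.
#'
#' @return A three-row factor-specification tibble (see [factor_spec()]).
#' @examples
#' agpl_factors()
#' @export
agpl_factors <- function() {
  dplyr::bind_rows(
    factor_spec("liquid_solid_ratio", 20, 40, units = "mL/g"),
    factor_spec("ultrasonic_power", 450, 750, units = "W"),
    factor_spec("extraction_time", 30, 50, units = "min")
  )
}

#' The packaged 17-run extraction experiment
#'
#' Loads the Box-Behnken experiment shipped with the package: 12 edge runs
#' plus 5 center replicates over the factors of [agpl_factors()], with the
#' measured polyphenol yield (%) as `response`. Factor columns are in actual
#' units.
#'
#' @return A 17-row tibble with columns `run`, the three factors, `response`.
#' @examples
#' agpl_runs()
#' @export
agpl_runs <- function() {
  path <- system.file("extdata", "agpl_runs.csv", package = "desopt",
                      mustWork = TRUE)
  read_design(path, agpl_factors())
}

assert_three_factors <- function(factors) {
  if (!is.data.frame(factors) || nrow(factors) != 3L) {
    stop("only 3-factor Box-Behnken designs are supported in this release",
         call. = FALSE)
  }
  invisible(factors)
}

#' Construct a three-factor Box-Behnken design
#'
#' Returns the 12 edge-midpoint runs (each pair of factors at +/-1 with the
#' third at 0) followed by `n_center` center replicates, in actual units.
#' Pairs are enumerated in factor order and each pair's sign combinations in
#' the order (-,-), (+,-), (-,+), (+,+); run order does not affect any fit.
#'
#' @param factors Three-row factor-specification tibble ([factor_spec()]).
#' @param n_center Number of replicate center runs (>= 1; >= 2 are needed to
#'   estimate pure error). The packaged study used 5.
#' @return A tibble with columns `run`, one per factor (actual units), and
#'   `response` (all `NA` until measured).
#' @examples
#' bbd_design(agpl_factors(), n_center = 5)
#' @export
bbd_design <- function(factors, n_center = 5) {
  assert_three_factors(factors)
  stopifnot(n_center >= 1)
  pm <- c(-1, 1, -1, 1)
  pm2 <- c(-1, -1, 1, 1)
  edges <- purrr::map(combn(3, 2, simplify = FALSE), function(pair) {
    m <- matrix(0, nrow = 4, ncol = 3)
    m[, pair[1]] <- pm
    m[, pair[2]] <- pm2
    m
  })
  coded <- rbind(do.call(rbind, edges),
                 matrix(0, nrow = n_center, ncol = 3))
  colnames(coded) <- factors$name
  design <- tibble::as_tibble(coded)
  actual <- decode_design(design, factors)
  dplyr::bind_cols(tibble::tibble(run = seq_len(nrow(actual))),
                   actual,
                   tibble::tibble(response = NA_real_))
}

#' Convert between actual and coded factor levels
#'
#' `code_level()` maps actual units onto the coded scale where the factor's
#' low/center/high become -1/0/+1; `decode_level()` is its exact inverse.
#' Values outside `[low, high]` are extrapolated linearly.
#'
#' @param actual,coded Numeric vectors of levels.
#' @param factor A one-row factor specification ([factor_spec()]).
#' @return Numeric vector of the same length.
#' @examples
#' x1 <- factor_spec("ratio", 20, 40)
#' code_level(35.5, x1)   # 0.55
#' decode_level(0.55, x1) # 35.5
#' @export
code_level <- function(actual, factor) {
  half <- (factor$high - factor$low) / 2
  if (half <= 0) stop("degenerate factor: high == low", call. = FALSE)
  (actual - factor$center) / half
}

#' @rdname code_level
#' @export
decode_level <- function(coded, factor) {
  factor$center + coded * (factor$high - factor$low) / 2
}

#' Convert the factor columns of a design table
#'
#' `code_design()` rewrites the factor columns of a data frame from actual
#' units to coded units; `decode_design()` does the reverse. Non-factor
#' columns pass through unchanged.
#'
#' @param data Data frame containing one column per factor.
#' @param factors Factor-specification tibble; every `name` must be a column
#'   of `data`.
#' @return A tibble with the factor columns transformed.
#' @export
code_design <- function(data, factors) {
  transform_design(data, factors, code_level)
}

#' @rdname code_design
#' @export
decode_design <- function(data, factors) {
  transform_design(data, factors, decode_level)
}

transform_design <- function(data, factors, fun) {
  missing <- setdiff(factors$name, names(data))
  if (length(missing)) {
    stop("design table is missing factor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  for (i in seq_len(nrow(factors))) {
    nm <- factors$name[i]
    out[[nm]] <- fun(out[[nm]], factors[i, ])
  }
  out
}

#' Read and write design tables
#'
#' Design CSVs have a `run` column, one column per factor and a `response`
#' column (possibly empty). Factor columns are in actual units unless
#' `coded = TRUE`, in which case every level of a declared Box-Behnken table
#' must lie in `[-1, 1]`. Writing then re-reading a table preserves all
#' values exactly (decimal text round trip).
#'
#' @param path File path.
#' @param factors Factor-specification tibble used to validate columns.
#' @param coded Are factor columns coded rather than actual units?
#' @param data Design tibble to write.
#' @return `read_design()` returns the design tibble; `write_design()`
#'   returns `data` invisibly.
#' @export
read_design <- function(path, factors, coded = FALSE) {
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) stop("cannot read design CSV: ", conditionMessage(e),
                             call. = FALSE)
  )
  needed <- c("run", factors$name, "response")
  missing <- setdiff(needed, names(raw))
  if (nrow(raw) == 0L) stop("design CSV has no runs", call. = FALSE)
  if (length(missing)) {
    stop("design CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[needed]
  for (col in needed) {
    vals <- out[[col]]
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & vals != "" & is.na(num))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in row %d, column '%s'",
                   vals[bad[1]], bad[1], col), call. = FALSE)
    }
    out[[col]] <- num
  }
  if (coded) {
    for (nm in factors$name) {
      bad <- which(abs(out[[nm]]) > 1 + 1e-12)
      if (length(bad)) {
        stop(sprintf("coded level %g outside [-1, 1] in row %d, column '%s'",
                     out[[nm]][bad[1]], bad[1], nm), call. = FALSE)
      }
    }
    out <- decode_design(out, factors)
  }
  out
}

#' @rdname read_design
#' @export
write_design <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
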