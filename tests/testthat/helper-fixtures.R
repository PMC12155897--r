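# Coefficients of the quadratic refit of the packaged 17-run experiment,
# frozen from an independent normal-equations solve of the printed data
# (see test-rsm.R for the live oracle).
refit_coefficients <- c(
  14.88, 0.6100, 0.0600, 0.1325,
  -0.0625, -0.0625, -0.4925,
  -0.33125, -0.50125, -0.62625
)

# closed-form BBD estimators: center mean, /8 linear contrasts, /4
# interaction contrasts, used as an independent oracle for the QR fit
bbd_contrast_fit <- function(coded, y) {
  x <- as.matrix(coded)
  lin <- vapply(1:3, function(i) {
    (sum(y[x[, i] == 1]) - sum(y[x[, i] == -1])) / 8
  }, numeric(1))
  int <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(p) {
    sel <- x[, p[1]] != 0 & x[, p[2]] != 0
    sum(y[sel] * x[sel, p[1]] * x[sel, p[2]]) / 4
  }, numeric(1))
  c(lin, int)
}

tiny_factors <- function() {
  dplyr::bind_rows(
    factor_spec("a", -1, 1),
    factor_spec("b", 0, 10),
    factor_spec("c", 100, 300)
  )
}
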