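fit17 <- fit_quadratic(agpl_runs(), agpl_factors())

test_that("quadratic fit agrees with closed-form BBD contrast estimators", {
  factors <- agpl_factors()
  des <- bbd_design(factors, n_center = 5)
  coded <- code_design(des, factors)[factors$name]
  set.seed(42)
  for (i in 1:100) {
    y <- rnorm(17, mean = 14, sd = 1)
    des$response <- y
    fit <- fit_quadratic(des, factors)
    oracle <- bbd_contrast_fit(coded, y)
    expect_equal(unname(fit$coefficients[2:7]), oracle, tolerance = 1e-10)
    # intercept equals the mean of the center-run responses
    expect_equal(unname(fit$coefficients[1]), mean(y[13:17]),
                 tolerance = 1e-10)
  }
})

test_that("the 17-run refit reproduces the published coefficient set", {
  expect_equal(unname(fit17$coefficients), refit_coefficients,
               tolerance = 2e-5)
  # prediction at the center equals the intercept; at (1,1,1) the sum
  center <- tibble::tibble(liquid_solid_ratio = 0, ultrasonic_power = 0,
                           extraction_time = 0)
  expect_equal(predict(fit17, center, coded = TRUE),
               unname(fit17$coefficients[1]))
  ones <- center + 1
  expect_equal(predict(fit17, ones, coded = TRUE),
               sum(fit17$coefficients))
})

test_that("constant and noiseless responses are fitted exactly", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 3)
  des$response <- 7.5
  fit <- fit_quadratic(des, factors)
  expect_equal(unname(fit$coefficients), c(7.5, rep(0, 9)), tolerance = 1e-10)

  truth <- c(10, 1, -2, 0.5, 0.3, -0.1, 0.2, -1, 0.7, -0.4)
  des2 <- sim_surface(truth, des, factors, noise_sd = 0)
  fit2 <- fit_quadratic(des2, factors)
  expect_equal(unname(fit2$coefficients), truth, tolerance = 1e-8)
  an <- rsm_anova(fit2)
  expect_lt(tidy(an)$ss[tidy(an)$source == "Residual"], 1e-8)
  expect_equal(an$r2, 1, tolerance = 1e-8)
})

test_that("rank-deficient designs raise a singular-design error", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 5)
  des$b <- des$a * 10 + 5  # collinear with factor a in coded units
  des$response <- rnorm(17)
  expect_error(fit_quadratic(des, factors), "singular design")
})

test_that("ANOVA satisfies its conservation identities on random fits", {
  factors <- agpl_factors()
  des <- bbd_design(factors, n_center = 5)
  set.seed(99)
  for (i in 1:20) {
    des$response <- rnorm(17, 14, 0.8)
    an <- rsm_anova(fit_quadratic(des, factors))
    tb <- tidy(an)
    ss <- function(src) tb$ss[tb$source == src]
    df <- function(src) tb$df[tb$source == src]
    expect_equal(ss("Model") + ss("Residual"), ss("Corrected Total"),
                 tolerance = 1e-8)
    expect_equal(ss("Lack of Fit") + ss("Pure Error"), ss("Residual"),
                 tolerance = 1e-8)
    expect_equal(df("Model") + df("Residual"), 16L)
    expect_true(all(tb$p.value >= 0 & tb$p.value <= 1, na.rm = TRUE))
    expect_lte(an$adj_r2, an$r2)
    expect_gt(an$cv_percent, 0)
  }
})

test_that("17-run ANOVA reproduces the self-consistent published cells", {
  an <- rsm_anova(fit17)
  tb <- tidy(an)
  cell <- function(src, col) tb[[col]][tb$source == src]
  expect_equal(cell("Model", "ss"), 7.66, tolerance = 1e-3)
  expect_equal(cell("Model", "statistic"), 8.92, tolerance = 1e-3)
  expect_lt(abs(cell("liquid_solid_ratio", "ss") - 2.98), 0.005)
  expect_equal(cell("liquid_solid_ratio", "statistic"), 31.20,
               tolerance = 1e-4)
  expect_lt(abs(cell("extraction_time", "ss") - 0.1405), 1e-4)
  expect_equal(cell("liquid_solid_ratio:extraction_time", "statistic"),
               0.1638, tolerance = 1e-3)
  expect_equal(cell("ultrasonic_power:extraction_time", "ss"), 0.9702,
               tolerance = 1e-4)
  expect_equal(cell("ultrasonic_power:extraction_time", "statistic"),
               10.17, tolerance = 1e-3)
  expect_equal(cell("liquid_solid_ratio^2", "ss"), 0.4620, tolerance = 1e-4)
  expect_equal(cell("ultrasonic_power^2", "ss"), 1.06, tolerance = 1e-2)
  expect_equal(cell("extraction_time^2", "ss"), 1.65, tolerance = 1e-2)
  expect_equal(cell("extraction_time^2", "statistic"), 17.31,
               tolerance = 1e-3)
  expect_equal(cell("Residual", "ss"), 0.6679, tolerance = 1e-4)
  expect_equal(cell("Pure Error", "ss"), 0.0262, tolerance = 1e-4)
  expect_equal(cell("Pure Error", "df"), 4L)
  expect_equal(an$adj_r2, 0.8167, tolerance = 1e-4)
  expect_equal(an$cv_percent, 2.18, tolerance = 1e-2)
  expect_equal(an$r2, 0.9198, tolerance = 1e-4)
})

test_that("sequential SS also partitions the model sum of squares", {
  an_seq <- rsm_anova(fit17, type = "sequential")
  tb <- tidy(an_seq)
  terms <- !tb$source %in% c("Model", "Residual", "Lack of Fit",
                             "Pure Error", "Corrected Total")
  expect_equal(sum(tb$ss[terms]), tb$ss[tb$source == "Model"],
               tolerance = 1e-8)
})

test_that("designs without replicates drop the lack-of-fit partition", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 1)
  des$response <- rnorm(13, 10, 1)
  expect_warning(an <- rsm_anova(fit_quadratic(des, factors)),
                 "no replicate")
  expect_false(any(tidy(an)$source %in% c("Lack of Fit", "Pure Error")))
})
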