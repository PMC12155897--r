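fit17 <- fit_quadratic(agpl_runs(), agpl_factors())

test_that("stationary point of the 17-run surface matches the study optimum", {
  opt <- stationary_point(fit17)
  expect_equal(opt$nature, "maximum")
  pt <- unlist(opt$actual_point)
  expect_equal(unname(pt), c(39.170, 595.054, 40.736), tolerance = 0.1 / 39)
  expect_lt(abs(pt[["liquid_solid_ratio"]] - 39.170), 0.1)
  expect_lt(abs(pt[["ultrasonic_power"]] - 595.054), 0.1)
  expect_lt(abs(pt[["extraction_time"]] - 40.736), 0.1)
  # predicted value at the optimum comes from the refit surface
  expect_equal(opt$predicted_response, 15.16, tolerance = 1e-2)
  # interior maximum dominates random points of the whole space
  set.seed(5)
  rand <- matrix(runif(3e4, -3, 3), ncol = 3)
  colnames(rand) <- agpl_factors()$name
  expect_true(all(opt$predicted_response >=
                    predict(fit17, tibble::as_tibble(rand), coded = TRUE)))
  # gradient vanishes at the reported point
  b <- fit17$coefficients
  B <- diag(unname(b[8:10]))
  B[1, 2] <- B[2, 1] <- b[[5]] / 2
  B[1, 3] <- B[3, 1] <- b[[6]] / 2
  B[2, 3] <- B[3, 2] <- b[[7]] / 2
  grad <- unname(b[2:4]) + 2 * drop(B %*% opt$coded_point)
  expect_lt(sqrt(sum(grad^2)), 1e-8)
})

test_that("stationary points classify simple surfaces correctly", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 3)
  bowl <- sim_surface(c(5, 0, 0, 0, 0, 0, 0, -1, -1, -1), des, factors)
  opt <- stationary_point(fit_quadratic(bowl, factors))
  expect_equal(unname(opt$coded_point), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(opt$nature, "maximum")
  cup <- sim_surface(c(5, 0, 0, 0, 0, 0, 0, 1, 1, 1), des, factors)
  expect_equal(stationary_point(fit_quadratic(cup, factors))$nature,
               "minimum")
  saddle <- sim_surface(c(5, 0, 0, 0, 0, 0, 0, 1, -1, 1), des, factors)
  expect_equal(stationary_point(fit_quadratic(saddle, factors))$nature,
               "saddle")
})

test_that("ridge systems are rejected with advice", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 3)
  flatish <- sim_surface(c(5, 1, 0, 0, 0, 0, 0, 0, 0, 0), des, factors)
  expect_error(stationary_point(fit_quadratic(flatish, factors)),
               "maximize_in_box")
})

test_that("box maximization finds interior, face and flat optima", {
  # interior: the 17-run stationary point lies inside the cube
  box <- maximize_in_box(fit17)
  stat <- stationary_point(fit17)
  expect_equal(unname(box$coded_point), unname(stat$coded_point),
               tolerance = 1e-5)
  expect_true(all(abs(box$coded_point) <= 1 + 1e-12))

  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 3)
  # linear surface maximized on a face
  ramp <- fit_quadratic(sim_surface(c(2, 1, 0, 0, 0, 0, 0, 0, 0, 0),
                                    des, factors), factors)
  expect_warning(opt <- maximize_in_box(ramp), "curvature")
  expect_equal(unname(opt$coded_point[1]), 1, tolerance = 1e-6)
  expect_equal(unname(opt$predicted_response), 3, tolerance = 1e-6)
  # flat surface returns the box center
  flat <- fit_quadratic(sim_surface(c(4, rep(0, 9)), des, factors), factors)
  expect_warning(fopt <- maximize_in_box(flat), "curvature")
  expect_equal(unname(fopt$coded_point), c(0, 0, 0))
  expect_equal(unname(fopt$predicted_response), 4)
})

test_that("box maximum never falls below the seeding-grid maximum", {
  factors <- tiny_factors()
  des <- bbd_design(factors, n_center = 3)
  set.seed(21)
  grid1 <- seq(-1, 1, length.out = 21)
  grid <- as.matrix(expand.grid(grid1, grid1, grid1))
  colnames(grid) <- factors$name
  for (i in 1:10) {
    truth <- c(rnorm(7), -abs(rnorm(3)))
    fit <- fit_quadratic(sim_surface(truth, des, factors), factors)
    opt <- maximize_in_box(fit)
    grid_best <- max(predict(fit, tibble::as_tibble(grid), coded = TRUE))
    expect_gte(opt$predicted_response + 1e-10, grid_best)
  }
})
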