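test_that("min-max normalization maps bounds to [-1, 1] and inverts exactly", {
  expect_equal(normalize_minmax(5, 5, 9), -1)
  expect_equal(normalize_minmax(7, 5, 9), 0)
  expect_equal(normalize_minmax(9, 5, 9), 1)
  # yield 13.36 under the 17-run response bounds (12.86, 14.95)
  expect_equal(normalize_minmax(13.36, 12.86, 14.95), -0.5215, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:10) {
    lo <- rnorm(1); hi <- lo + runif(1, 0.1, 5)
    x <- runif(100, lo - 1, hi + 1)
    expect_equal(denormalize_minmax(normalize_minmax(x, lo, hi), lo, hi), x,
                 tolerance = 1e-12)
  }
  expect_error(normalize_minmax(1, 2, 2), "degenerate")
})

test_that("network forward pass matches a scalar per-neuron oracle", {
  fit <- train_mlp(agpl_runs(), agpl_factors(), hidden = 3, restarts = 1,
                   seed = 4, epochs = 5)
  net <- fit$net
  tansig_ref <- function(x) 2 / (1 + exp(-2 * x)) - 1
  set.seed(9)
  pts <- cbind(runif(20, 20, 40), runif(20, 450, 750), runif(20, 30, 50))
  colnames(pts) <- agpl_factors()$name
  got <- predict(net, tibble::as_tibble(pts))
  for (k in 1:20) {
    xn <- numeric(3)
    for (j in 1:3) {
      xn[j] <- 2 * (pts[k, j] - net$norm$x_min[j]) /
        (net$norm$x_max[j] - net$norm$x_min[j]) - 1
    }
    acc <- net$b2
    for (h in seq_len(net$H)) {
      z <- net$b1[h]
      for (j in 1:3) z <- z + net$w1[h, j] * xn[j]
      acc <- acc + net$w2[h] * tansig_ref(z)
    }
    want <- net$norm$y_min + (acc + 1) * (net$norm$y_max - net$norm$y_min) / 2
    expect_equal(got[k], want, tolerance = 1e-12)
  }
  # all-zero parameters output the midpoint of the response range
  net0 <- net
  net0$w1[] <- 0; net0$b1[] <- 0; net0$w2[] <- 0; net0$b2 <- 0
  expect_equal(predict(net0, c(30, 600, 40)),
               (net$norm$y_min + net$norm$y_max) / 2)
  # tansig saturates monotonically to +/-1
  big <- desopt:::tansig(c(-50, -5, 0, 5, 50))
  expect_true(all(diff(big) >= 0))
  expect_equal(big[c(1, 5)], c(-1, 1), tolerance = 1e-4)
})

test_that("data splitting uses round-then-repair sizes and is seeded", {
  s17 <- split_data(17, seed = 1)
  expect_equal(unname(lengths(s17)), c(12, 3, 2))
  s100 <- split_data(100, seed = 1)
  expect_equal(unname(lengths(s100)), c(70, 15, 15))
  all_idx <- sort(unname(unlist(s17)))
  expect_equal(all_idx, 1:17)  # disjoint and exhaustive
  expect_identical(split_data(40, seed = 7), split_data(40, seed = 7))
  expect_error(split_data(2), "n >= 3")
})

test_that("LM training fits a noiseless quadratic surface closely", {
  factors <- agpl_factors()
  des <- sim_surface(refit_coefficients, bbd_design(factors, 5), factors,
                     noise_sd = 0)
  fit <- train_mlp(des, factors, hidden = 7, restarts = 20, seed = 2)
  # best training MSE on the normalized scale over restarts
  hist <- tidy(fit)
  expect_lte(min(hist$train), 1e-4)
  # training MSE never increases along accepted epochs
  expect_true(all(diff(hist$train) <= 1e-12))
})

test_that("a single tansig unit learns a noiseless linear response", {
  factors <- tiny_factors()
  des <- sim_surface(c(5, 0.3, -0.2, 0.1, rep(0, 6)),
                     bbd_design(factors, 3), factors)
  fit <- train_mlp(des, factors, hidden = 1, restarts = 20, seed = 6)
  expect_lte(min(fit$restarts$best_val_mse), 1e-5)
})

test_that("training records are reproducible and internally consistent", {
  a <- train_mlp(agpl_runs(), agpl_factors(), hidden = 4, restarts = 3,
                 seed = 11)
  b <- train_mlp(agpl_runs(), agpl_factors(), hidden = 4, restarts = 3,
                 seed = 11)
  expect_identical(a$net, b$net)
  expect_identical(a$restarts, b$restarts)
  expect_equal(unname(lengths(a$record$split)), c(12, 3, 2))
  expect_true(a$record$reason %in%
                c("epochs", "goal", "gradient", "mu", "validation"))
  if (a$record$reason == "validation") {
    expect_lt(a$record$best_epoch, a$record$final_epoch)
  }
  # returned parameters beat the initialization on the training subset
  seed_r <- a$restarts$seed[which.min(a$restarts$best_val_mse)]
  set.seed(seed_r)
  split <- split_data(17)
  theta0 <- runif(desopt:::mlp_n_par(4), -0.5, 0.5)
  runs <- agpl_runs()
  X <- as.matrix(runs[agpl_factors()$name])
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2,
              (apply(X, 2, max) - apply(X, 2, min)) / 2, "/") - 1
  tn <- normalize_minmax(runs$response, min(runs$response),
                         max(runs$response))
  mse0 <- mean((tn[split$train] -
                  desopt:::mlp_forward_norm(theta0, 4,
                                            Xn[split$train, ]))^2)
  net <- a$net
  predn <- normalize_minmax(predict(net, runs), net$norm$y_min,
                            net$norm$y_max)
  expect_lte(mean((tn[split$train] - predn[split$train])^2), mse0)
})

test_that("the LM step shrinks to zero as damping grows", {
  set.seed(13)
  theta <- runif(desopt:::mlp_n_par(2), -0.5, 0.5)
  Xn <- matrix(runif(30, -1, 1), ncol = 3)
  tn <- runif(10, -1, 1)
  fj <- desopt:::mlp_forward_jac(theta, 2, Xn)
  e <- tn - fj$yhat
  JtJ <- crossprod(fj$J)
  Jte <- drop(crossprod(fj$J, e))
  norms <- vapply(10^seq(-3, 6), function(mu) {
    sqrt(sum(solve(JtJ + mu * diag(nrow(JtJ)), Jte)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-5)
})

test_that("the neuron sweep is seeded and returns one row per size", {
  sw <- neuron_sweep(agpl_runs(), agpl_factors(), hidden = 1:3,
                     restarts = 2, seed = 3, epochs = 50)
  expect_s3_class(sw, "mlp_sweep")
  expect_equal(sw$hidden, 1:3)
  expect_true(all(sw$best_mse >= 0))
  sw2 <- neuron_sweep(agpl_runs(), agpl_factors(), hidden = 1:3,
                      restarts = 2, seed = 3, epochs = 50)
  expect_identical(sw, sw2)
})
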