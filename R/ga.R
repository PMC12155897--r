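#' Maximize a function over a box with a real-coded genetic algorithm
#'
#' Population-based maximization in actual units: uniform random
#' initialization in the box, tournament selection (size 2), blend (BLX-0.5)
#' crossover applied to a `crossover_fraction` share of the offspring,
#' per-gene Gaussian mutation (sd = 10% of the gene's range) with
#' probability `mutation_rate` clipped to the bounds, and elitism carrying
#' the `elite_count` best individuals unchanged, so the best fitness never
#' decreases across generations.
#'
#' @param fitness Function mapping a length-`d` numeric vector to a finite
#'   scalar fitness (larger is better).
#' @param lower,upper Numeric bounds of the search box (actual units).
#' @param pop_size Population size (default 100).
#' @param crossover_fraction Share of non-elite offspring produced by
#'   crossover (default 0.8).
#' @param mutation_rate Per-gene mutation probability (default 0.1).
#' @param generations Number of generations (default 300).
#' @param elite_count Individuals copied unchanged each generation
#'   (default 2).
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   result.
#' @return A `"ga_result"`: `best_point`, `best_fitness`, per-generation
#'   `history` (best and mean fitness) and `generations_run`. Methods:
#'   [tidy()] (history), [glance()], [autoplot()].
#' @examples
#' res <- ga_maximize(function(x) -sum((x - 1:3)^2), lower = rep(0, 3),
#'                    upper = rep(5, 3), generations = 50, seed = 1)
#' glance(res)
#' @export
ga_maximize <- function(fitness, lower, upper, pop_size = 100,
                        crossover_fraction = 0.8, mutation_rate = 0.1,
                        generations = 300, elite_count = 2, seed = NULL) {
  stopifnot(length(lower) == length(upper), all(lower < upper),
            pop_size >= 2, generations >= 1, elite_count < pop_size,
            crossover_fraction >= 0, crossover_fraction <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  range <- upper - lower
  mut_sd <- 0.1 * range

  evaluate <- function(pop) {
    f <- apply(pop, 1, fitness)
    if (any(!is.finite(f))) {
      bad <- pop[which(!is.finite(f))[1], ]
      stop("non-finite fitness at point (", paste(signif(bad, 6),
           collapse = ", "), ")", call. = FALSE)
    }
    f
  }
  clip <- function(pop) {
    pop <- pmax(pop, matrix(lower, nrow(pop), d, byrow = TRUE))
    pmin(pop, matrix(upper, nrow(pop), d, byrow = TRUE))
  }
  tournament <- function(f, k) {
    a <- sample.int(length(f), k, replace = TRUE)
    b <- sample.int(length(f), k, replace = TRUE)
    ifelse(f[a] >= f[b], a, b)
  }

  pop <- matrix(stats::runif(pop_size * d), pop_size, d)
  pop <- sweep(sweep(pop, 2, range, "*"), 2, lower, "+")
  fit <- evaluate(pop)
  best_i <- which.max(fit)
  best_point <- pop[best_i, ]
  best_fitness <- fit[best_i]
  history <- matrix(NA_real_, generations, 2,
                    dimnames = list(NULL, c("best", "mean")))

  n_children <- pop_size - elite_count
  n_cross <- round(crossover_fraction * n_children)
  alpha <- 0.5  # BLX blend width

  for (gen in seq_len(generations)) {
    elites <- pop[order(fit, decreasing = TRUE)[seq_len(elite_count)], ,
                  drop = FALSE]
    children <- matrix(NA_real_, n_children, d)
    if (n_cross > 0) {
      p1 <- pop[tournament(fit, n_cross), , drop = FALSE]
      p2 <- pop[tournament(fit, n_cross), , drop = FALSE]
      lo <- pmin(p1, p2)
      hi <- pmax(p1, p2)
      span <- hi - lo
      u <- matrix(stats::runif(n_cross * d), n_cross, d)
      children[seq_len(n_cross), ] <-
        lo - alpha * span + u * (1 + 2 * alpha) * span
    }
    if (n_children > n_cross) {
      keep <- tournament(fit, n_children - n_cross)
      children[(n_cross + 1):n_children, ] <- pop[keep, , drop = FALSE]
    }
    mutate <- matrix(stats::runif(n_children * d) < mutation_rate,
                     n_children, d)
    noise <- matrix(stats::rnorm(n_children * d), n_children, d) *
      rep(mut_sd, each = n_children)
    children <- children + mutate * noise
    pop <- clip(rbind(elites, children))
    fit <- evaluate(pop)
    gen_best <- which.max(fit)
    if (fit[gen_best] > best_fitness) {
      best_fitness <- fit[gen_best]
      best_point <- pop[gen_best, ]
    }
    history[gen, ] <- c(best_fitness, mean(fit))
  }
  if (!is.null(names(lower))) names(best_point) <- names(lower)
  structure(
    list(best_point = best_point, best_fitness = best_fitness,
         history = tibble::tibble(generation = seq_len(generations),
                                  best = history[, "best"],
                                  mean = history[, "mean"]),
         generations_run = generations),
    class = "ga_result"
  )
}

#' @export
print.ga_result <- function(x, ...) {
  cat("Genetic-algorithm maximum after", x$generations_run, "generations\n")
  cat("best point:", paste(signif(x$best_point, 6), collapse = ", "), "\n")
  cat("best fitness:", signif(x$best_fitness, 6), "\n")
  invisible(x)
}

#' @export
tidy.ga_result <- function(x, ...) x$history

#' @export
glance.ga_result <- function(x, ...) {
  pt <- as.list(x$best_point)
  if (is.null(names(x$best_point))) {
    names(pt) <- paste0("x", seq_along(pt))
  }
  dplyr::bind_cols(tibble::as_tibble(pt),
                   tibble::tibble(best_fitness = x$best_fitness,
                                  generations = x$generations_run))
}

#' Use a trained surrogate network as a GA fitness function
#'
#' Wraps a fitted network so the genetic algorithm can maximize its
#' predicted yield directly over the actual-unit factor box.
#'
#' @param fit An `"mlp_fit"` or `"mlp_net"`.
#' @return A function mapping an actual-unit factor vector to predicted
#'   response (%).
#' @examples
#' fit <- train_mlp(agpl_runs(), agpl_factors(), restarts = 3, seed = 1)
#' f <- fitness_from_surrogate(fit)
#' f(c(30, 600, 40))
#' @export
fitness_from_surrogate <- function(fit) {
  net <- if (inherits(fit, "mlp_fit")) fit$net else fit
  stopifnot(inherits(net, "mlp_net"))
  function(x) predict(net, matrix(x, nrow = 1))
}
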