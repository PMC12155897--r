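#' Min-max normalization onto [-1, 1]
#'
#' Linear map sending `lower` to -1 and `upper` to +1, as used to condition
#' network inputs and targets; `denormalize_minmax()` is its exact inverse.
#'
#' @param x Numeric vector.
#' @param lower,upper Observed variable bounds; `upper > lower`.
#' @return Numeric vector of the same length.
#' @examples
#' normalize_minmax(13.36, 12.86, 14.95)
#' @export
normalize_minmax <- function(x, lower, upper) {
  if (!(upper > lower)) {
    stop("degenerate variable: upper bound must exceed lower bound",
         call. = FALSE)
  }
  2 * (x - lower) / (upper - lower) - 1
}

#' @rdname normalize_minmax
#' @export
denormalize_minmax <- function(x, lower, upper) {
  if (!(upper > lower)) {
    stop("degenerate variable: upper bound must exceed lower bound",
         call. = FALSE)
  }
  lower + (x + 1) * (upper - lower) / 2
}

# hyperbolic-tangent sigmoid, written as in the network literature;
# algebraically equal to tanh(x)
tansig <- function(x) 2 / (1 + exp(-2 * x)) - 1

# parameter packing: theta = c(vec(w1), b1, w2, b2), length 5H + 1
mlp_n_par <- function(H) 5L * H + 1L

mlp_unpack <- function(theta, H) {
  list(w1 = matrix(theta[seq_len(3 * H)], nrow = H, ncol = 3),
       b1 = theta[3 * H + seq_len(H)],
       w2 = theta[4 * H + seq_len(H)],
       b2 = theta[5 * H + 1])
}

mlp_pack <- function(p) c(as.vector(p$w1), p$b1, p$w2, p$b2)

# forward pass on the normalized scale; Xn is n x 3
mlp_forward_norm <- function(theta, H, Xn) {
  p <- mlp_unpack(theta, H)
  A <- tansig(Xn %*% t(p$w1) + rep(p$b1, each = nrow(Xn)))
  drop(A %*% p$w2 + p$b2)
}

# Jacobian d yhat / d theta by backpropagation; returns list(yhat, J)
mlp_forward_jac <- function(theta, H, Xn) {
  p <- mlp_unpack(theta, H)
  n <- nrow(Xn)
  A <- tansig(Xn %*% t(p$w1) + rep(p$b1, each = n))     # n x H
  yhat <- drop(A %*% p$w2 + p$b2)
  D <- (1 - A^2) * rep(p$w2, each = n)                  # d yhat / d z1
  J <- cbind(D * Xn[, 1], D * Xn[, 2], D * Xn[, 3],     # w1 (column-major)
             D,                                          # b1
             A,                                          # w2
             rep(1, n))                                  # b2
  list(yhat = yhat, J = J)
}

#' Split observations into training / validation / test sets
#'
#' Random disjoint partition with sizes `round(n * fractions)` repaired by
#' largest remainder so they sum to `n` (ties broken in set order).
#'
#' @param n Number of observations (>= 3).
#' @param fractions Length-3 fractions summing to 1. Default 70/15/15.
#' @param seed Optional integer seed for reproducibility.
#' @return Named list of integer index vectors `train`, `validation`, `test`.
#' @examples
#' lengths(split_data(17, seed = 1))  # 12, 3, 2
#' @export
split_data <- function(n, fractions = c(0.70, 0.15, 0.15), seed = NULL) {
  stopifnot(n >= 3, length(fractions) == 3,
            abs(sum(fractions) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  raw <- n * fractions
  sizes <- floor(raw)
  rem <- raw - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(short)]
    sizes[bump] <- sizes[bump] + 1L
  }
  idx <- sample.int(n)
  list(train = sort(idx[seq_len(sizes[1])]),
       validation = sort(idx[sizes[1] + seq_len(sizes[2])]),
       test = sort(idx[sizes[1] + sizes[2] + seq_len(sizes[3])]))
}

mse <- function(x) mean(x^2)

# One Levenberg-Marquardt training run on pre-normalized data.
lm_train_run <- function(Xn, tn, split, H, epochs, goal, min_grad,
                         max_fail, mu_init, mu_max, init_range) {
  theta <- stats::runif(mlp_n_par(H), -init_range, init_range)
  tr <- split$train
  va <- split$validation
  te <- split$test
  eval_mse <- function(th, idx) {
    if (!length(idx)) return(NA_real_)
    mse(tn[idx] - mlp_forward_norm(th, H, Xn[idx, , drop = FALSE]))
  }
  mu <- mu_init
  history <- vector("list", epochs)
  best_val <- Inf
  best_theta <- theta
  best_epoch <- 0L
  fails <- 0L
  reason <- "epochs"
  fj <- mlp_forward_jac(theta, H, Xn[tr, , drop = FALSE])
  e <- tn[tr] - fj$yhat
  sse <- sum(e^2)
  epoch <- 0L
  while (epoch < epochs) {
    epoch <- epoch + 1L
    if (!is.finite(sse)) {
      stop("training diverged (non-finite loss) at epoch ", epoch,
           call. = FALSE)
    }
    grad <- 2 * drop(crossprod(fj$J, e))
    if (max(abs(grad)) < min_grad) { reason <- "gradient"; epoch <- epoch - 1L; break }
    JtJ <- crossprod(fj$J)
    Jte <- drop(crossprod(fj$J, e))
    accepted <- FALSE
    while (!accepted) {
      delta <- tryCatch(
        solve(JtJ + mu * diag(nrow(JtJ)), Jte),
        error = function(err) NULL)
      if (!is.null(delta)) {
        cand <- theta + delta
        fj_new <- mlp_forward_jac(cand, H, Xn[tr, , drop = FALSE])
        e_new <- tn[tr] - fj_new$yhat
        sse_new <- sum(e_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- cand; fj <- fj_new; e <- e_new; sse <- sse_new
          mu <- max(mu / 10, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) {
        mu <- mu * 10
        if (mu > mu_max) break
      }
    }
    if (!accepted) { reason <- "mu"; epoch <- epoch - 1L; break }
    train_mse <- sse / length(tr)
    val_mse <- eval_mse(theta, va)
    history[[epoch]] <- c(epoch = epoch, train = train_mse,
                          validation = val_mse, test = eval_mse(theta, te))
    if (length(va)) {
      if (val_mse < best_val) {
        best_val <- val_mse; best_theta <- theta; best_epoch <- epoch
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= max_fail) { reason <- "validation"; break }
      }
    } else {
      best_theta <- theta; best_epoch <- epoch; best_val <- train_mse
    }
    if (train_mse <= goal) { reason <- "goal"; break }
  }
  if (best_epoch == 0L) { best_theta <- theta; best_epoch <- max(epoch, 0L) }
  history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null,
                                                              logical(1))]))
  list(theta = best_theta, best_val = best_val, best_epoch = best_epoch,
       final_epoch = epoch, reason = reason, history = history)
}

mlp_net <- function(theta, H, factors, norm) {
  structure(c(mlp_unpack(theta, H),
              list(H = H, factors = factors, norm = norm)),
            class = "mlp_net")
}

#' Predict from a feed-forward surrogate network
#'
#' Normalizes the inputs, runs the tansig hidden layer and linear output,
#' and maps the output back to response units.
#'
#' @param object An `"mlp_net"` or `"mlp_fit"`.
#' @param newdata Data frame with the factor columns in actual units, or a
#'   numeric matrix/vector of actual-unit factor values.
#' @param ... Unused.
#' @return Numeric vector of predicted responses (%).
#' @export
predict.mlp_net <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata)) {
    as.matrix(newdata[object$factors$name])
  } else if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  Xn <- sweep(sweep(X, 2, object$norm$x_min), 2,
              (object$norm$x_max - object$norm$x_min) / 2, "/") - 1
  yn <- mlp_forward_norm(mlp_pack(object), object$H, Xn)
  denormalize_minmax(yn, object$norm$y_min, object$norm$y_max)
}

#' Train a 3-H-1 surrogate network by Levenberg-Marquardt
#'
#' Fits a single-hidden-layer perceptron (tansig hidden units, linear
#' output) to a designed experiment. Inputs and response are min-max
#' normalized to `[-1, 1]` over all runs, so a trained network predicts
#' identically regardless of which subset a point fell in. Each restart
#' draws a fresh random 70/15/15 train/validation/test split and fresh
#' uniform(-0.5, 0.5) initial weights, then runs damped Gauss-Newton
#' updates \eqn{\delta = (J'J + \mu I)^{-1} J'e} with the Jacobian computed
#' by backpropagation; \eqn{\mu} is divided by 10 on accepted steps and
#' multiplied by 10 on rejected ones. Training stops at the epoch cap, the
#' MSE goal, the gradient floor, \eqn{\mu} overflow, or after `max_fail`
#' consecutive epochs without a new validation minimum; the returned weights
#' are those of the best validation epoch.
#'
#' @param data Design tibble with factor columns (actual units) and response.
#' @param factors Factor-specification tibble.
#' @param response Response column name.
#' @param hidden Hidden-neuron count H (default 7, the 3-7-1 topology).
#' @param restarts Number of random restarts; the best is returned.
#' @param seed Integer seed governing all splits and initializations.
#' @param select How the best restart is chosen: `"validation"` (lowest
#'   best-epoch validation MSE, default) or `"all_r2"` (highest R-squared
#'   over all runs, the convention used when a surrogate is judged on the
#'   full experiment).
#' @param epochs,goal,min_grad,max_fail Stopping controls: epoch cap,
#'   training-MSE goal (normalized scale), gradient floor, and consecutive
#'   validation failures allowed. Defaults 1000, 1e-5, 1e-6, 6.
#' @param mu_init,mu_max Initial and maximal LM damping.
#' @param init_range Half-width of the uniform weight initialization.
#' @param fractions Split fractions, default `c(0.70, 0.15, 0.15)`.
#' @return An `"mlp_fit"`: the best network (`net`), its training record
#'   (`record`: split, per-epoch MSE history, stopping reason, epochs), and
#'   a per-restart summary tibble (`restarts`). Methods: [predict()],
#'   [tidy()] (epoch history), [glance()].
#' @examples
#' fit <- train_mlp(agpl_runs(), agpl_factors(), restarts = 5, seed = 1)
#' glance(fit)
#' @export
train_mlp <- function(data, factors, response = "response", hidden = 7,
                      restarts = 1, seed = NULL,
                      select = c("validation", "all_r2"),
                      epochs = 1000, goal = 1e-5, min_grad = 1e-6,
                      max_fail = 6, mu_init = 1e-3, mu_max = 1e10,
                      init_range = 0.5, fractions = c(0.70, 0.15, 0.15)) {
  select <- match.arg(select)
  stopifnot(hidden >= 1)
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  X <- as.matrix(data[factors$name])
  y <- data[[response]]
  norm <- list(x_min = apply(X, 2, min), x_max = apply(X, 2, max),
               y_min = min(y), y_max = max(y))
  Xn <- sweep(sweep(X, 2, norm$x_min), 2, (norm$x_max - norm$x_min) / 2,
              "/") - 1
  tn <- normalize_minmax(y, norm$y_min, norm$y_max)

  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, restarts)
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    set.seed(run_seeds[r])
    split <- split_data(nrow(Xn), fractions)
    run <- lm_train_run(Xn, tn, split, hidden, epochs, goal, min_grad,
                        max_fail, mu_init, mu_max, init_range)
    run$split <- split
    run$seed <- run_seeds[r]
    pred <- denormalize_minmax(mlp_forward_norm(run$theta, hidden, Xn),
                               norm$y_min, norm$y_max)
    run$all_r2 <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
    runs[[r]] <- run
  }
  summary <- purrr::map_dfr(seq_along(runs), function(r) {
    run <- runs[[r]]
    tibble::tibble(restart = r, seed = run$seed,
                   best_val_mse = run$best_val, all_r2 = run$all_r2,
                   epochs = run$final_epoch, reason = run$reason)
  })
  best_i <- if (select == "validation") which.min(summary$best_val_mse) else
    which.max(summary$all_r2)
  best <- runs[[best_i]]
  structure(
    list(net = mlp_net(best$theta, hidden, factors, norm),
         record = list(split = best$split, history = best$history,
                       reason = best$reason, final_epoch = best$final_epoch,
                       best_epoch = best$best_epoch, seed = best$seed),
         restarts = summary,
         select = select,
         data = tibble::as_tibble(data)),
    class = "mlp_fit"
  )
}

#' @export
predict.mlp_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  predict(object$net, newdata, ...)
}

#' @export
print.mlp_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("3-%d-1 tansig/purelin network, %d restart(s), stop: %s\n",
              x$net$H, nrow(x$restarts), x$record$reason))
  cat(sprintf("best validation MSE %.3g (normalized), all-run R2 %.4f\n",
              g$val_mse, g$all_r2))
  invisible(x)
}

#' @export
tidy.mlp_fit <- function(x, ...) x$record$history

#' @export
glance.mlp_fit <- function(x, ...) {
  best <- x$restarts[if (x$select == "validation")
    which.min(x$restarts$best_val_mse) else which.max(x$restarts$all_r2), ]
  tibble::tibble(hidden = x$net$H, n_par = mlp_n_par(x$net$H),
                 val_mse = best$best_val_mse, all_r2 = best$all_r2,
                 epochs = best$epochs, reason = best$reason,
                 restarts = nrow(x$restarts))
}

#' Sweep the hidden-layer size of the surrogate network
#'
#' Trains networks over a range of hidden-neuron counts and reports, for
#' each, the lowest best-validation-epoch MSE over the restarts; used to
#' choose the hidden-layer size by the elbow/minimum of the curve.
#'
#' @inheritParams train_mlp
#' @param hidden Integer vector of hidden sizes to try.
#' @return A tibble (class `"mlp_sweep"`) with columns `hidden`, `best_mse`.
#' @examples
#' neuron_sweep(agpl_runs(), agpl_factors(), hidden = 1:3,
#'              restarts = 2, seed = 1)
#' @export
neuron_sweep <- function(data, factors, response = "response",
                         hidden = 1:10, restarts = 5, seed = NULL, ...) {
  stopifnot(length(hidden) >= 1)
  if (!is.null(seed)) set.seed(seed)
  sweep_seeds <- sample.int(.Machine$integer.max, length(hidden))
  out <- purrr::map2_dfr(hidden, sweep_seeds, function(H, s) {
    fit <- train_mlp(data, factors, response, hidden = H,
                     restarts = restarts, seed = s, ...)
    tibble::tibble(hidden = H, best_mse = min(fit$restarts$best_val_mse))
  })
  class(out) <- c("mlp_sweep", class(out))
  out
}
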