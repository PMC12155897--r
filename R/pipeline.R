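#' Run the full optimization pipeline on a designed experiment
#'
#' Chains the package's stages on one design table: quadratic
#' response-surface fit and ANOVA, stationary-point and box-constrained
#' surface optima, neural-network surrogate training, genetic-algorithm
#' maximization of the surrogate, and side-by-side model-comparison
#' metrics. When `out_dir` is given, machine-readable results are written
#' there (`model.json`, `anova.csv`, `rsm_optimum.json`, `net.json`,
#' `ga.json`, `comparison.csv`, `report.txt`).
#'
#' @param data Design tibble in actual units with responses. Defaults to
#'   the packaged 17-run experiment.
#' @param factors Factor-specification tibble.
#' @param out_dir Optional output directory (created if missing).
#' @param seed Integer seed for the stochastic stages.
#' @param hidden,restarts Surrogate topology and restarts for [train_mlp()].
#' @param pop_size,generations GA controls for [ga_maximize()].
#' @param skip_ann If `TRUE`, run only the response-surface arm.
#' @return Invisibly, a named list with components `fit`, `anova`,
#'   `stationary`, `box_optimum`, `metrics`, and unless skipped `ann` and
#'   `ga`.
#' @examples
#' \donttest{
#' res <- run_pipeline(restarts = 5, generations = 50, seed = 1)
#' res$metrics
#' }
#' @export
run_pipeline <- function(data = agpl_runs(), factors = agpl_factors(),
                         out_dir = NULL, seed = 1, hidden = 7,
                         restarts = 30, pop_size = 100, generations = 300,
                         skip_ann = FALSE) {
  fit <- fit_quadratic(data, factors)
  an <- rsm_anova(fit)
  stat <- stationary_point(fit)
  box <- maximize_in_box(fit)
  rsm_metrics <- model_metrics(fit$response, fit$fitted) |>
    dplyr::mutate(model = "RSM", .before = 1)
  metrics <- rsm_metrics
  out <- list(fit = fit, anova = an, stationary = stat, box_optimum = box)

  if (!skip_ann) {
    ann <- train_mlp(data, factors, hidden = hidden, restarts = restarts,
                     seed = seed, select = "all_r2")
    ga <- ga_maximize(fitness_from_surrogate(ann),
                      lower = stats::setNames(factors$low, factors$name),
                      upper = stats::setNames(factors$high, factors$name),
                      pop_size = pop_size, generations = generations,
                      seed = seed)
    ann_metrics <- model_metrics(data$response, predict(ann)) |>
      dplyr::mutate(model = "ANN", .before = 1)
    metrics <- dplyr::bind_rows(metrics, ann_metrics)
    out$ann <- ann
    out$ga <- ga
  }
  out$metrics <- metrics

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wj <- function(x, file) jsonlite::write_json(
      x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA)
    wj(list(coefficients = as.list(fit$coefficients),
            factors = factors, n_runs = fit$n), "model.json")
    readr::write_csv(tidy(an), file.path(out_dir, "anova.csv"),
                     progress = FALSE)
    wj(list(stationary = tidy(stat), box = tidy(box)), "rsm_optimum.json")
    if (!skip_ann) {
      net <- out$ann$net
      wj(list(hidden = net$H, w1 = net$w1, b1 = net$b1, w2 = net$w2,
              b2 = net$b2, norm = net$norm,
              record = out$ann$record[c("reason", "final_epoch",
                                        "best_epoch", "seed")]),
         "net.json")
      wj(list(best_point = as.list(out$ga$best_point),
              best_fitness = out$ga$best_fitness,
              generations = out$ga$generations_run), "ga.json")
    }
    readr::write_csv(metrics, file.path(out_dir, "comparison.csv"),
                     progress = FALSE)
    report <- c(
      "Extraction optimization report",
      sprintf("runs: %d  seed: %d", fit$n, seed),
      sprintf("RSM R2 %.4f adj R2 %.4f CV%% %.2f", an$r2, an$adj_r2,
              an$cv_percent),
      sprintf("RSM stationary point (%s): %s -> %.4f%%", stat$nature,
              paste(signif(unlist(stat$actual_point), 6), collapse = ", "),
              stat$predicted_response),
      sprintf("RSM box maximum: %s -> %.4f%%",
              paste(signif(unlist(box$actual_point), 6), collapse = ", "),
              box$predicted_response),
      if (!skip_ann) sprintf("ANN-GA optimum: %s -> %.4f%%",
                             paste(signif(out$ga$best_point, 6),
                                   collapse = ", "),
                             out$ga$best_fitness))
    writeLines(report, file.path(out_dir, "report.txt"))
  }
  invisible(out)
}
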