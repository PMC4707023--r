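# broom-style tidiers and ggplot2 visualisations for run, experiment and
# comparison objects.

#' Tidy a GSGP run
#'
#' @param x A `gsgp_run`.
#' @param ... Unused.
#' @return The per-generation trace tibble: best train/test RMSE, best
#'   size (double approximation and exact decimal string), population
#'   median/mean size and operator event/success counters.
#' @method tidy gsgp_run
#' @export
tidy.gsgp_run <- function(x, ...) x$trace

#' One-row summary of a GSGP run
#'
#' @param x A `gsgp_run`.
#' @param ... Unused.
#' @return A one-row tibble with the system, final best fitnesses and the
#'   exact final best size.
#' @method glance gsgp_run
#' @export
glance.gsgp_run <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(system = if (x$config$elitist) "elitist" else "standard",
                 pop_size = x$config$pop_size,
                 generations = x$config$generations,
                 ms = x$config$ms,
                 best_train = last$best_train,
                 best_test = last$best_test,
                 best_size = last$best_size,
                 best_size_exact = last$best_size_exact)
}

#' @rdname tidy.gsgp_run
#' @method tidy gsgp_experiment
#' @export
tidy.gsgp_experiment <- function(x, ...) x$medians

#' @rdname glance.gsgp_run
#' @method glance gsgp_experiment
#' @export
glance.gsgp_experiment <- function(x, ...) {
  x$finals |>
    dplyr::group_by(.data$system, .data$ms) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     median_final_train = stats::median(.data$final_train),
                     median_final_test = stats::median(.data$final_test),
                     median_final_size = stats::median(.data$final_size),
                     .groups = "drop")
}

#' Tidy a final-size comparison
#'
#' @param x A `gsgp_size_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, Shapiro-Wilk p values, the
#'   Mann-Whitney U statistic, p value, alpha and verdict.
#' @method tidy gsgp_size_comparison
#' @export
tidy.gsgp_size_comparison <- function(x, ...) {
  tibble::tibble(label_a = x$labels[1], label_b = x$labels[2],
                 n_a = x$n_a, n_b = x$n_b,
                 shapiro_p_a = x$shapiro_p_a, shapiro_p_b = x$shapiro_p_b,
                 u_statistic = x$u_statistic, p_value = x$p_value,
                 alpha = x$alpha, verdict = x$verdict)
}

#' Plot the fitness trace of a GSGP run
#'
#' Best-individual training and test RMSE against generation.
#'
#' @param object A `gsgp_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsgp_run
#' @export
autoplot.gsgp_run <- function(object, ...) {
  df <- object$trace |>
    tidyr::pivot_longer(c("best_train", "best_test"),
                        names_to = "partition", values_to = "rmse") |>
    dplyr::mutate(partition = sub("^best_", "", .data$partition))
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$rmse,
                                   colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best RMSE", colour = NULL,
                  title = sprintf("%s GSGP, ms = %g",
                                  if (object$config$elitist) "elitist" else "standard",
                                  object$config$ms)) +
    ggplot2::theme_minimal()
}

#' Plot experiment median curves
#'
#' @param object A `gsgp_experiment`.
#' @param type `"fitness"` (median best train/test RMSE), `"size"`
#'   (median best size, log10 scale) or `"success"` (per-generation
#'   operator success rates).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gsgp_experiment
#' @export
autoplot.gsgp_experiment <- function(object, type = c("fitness", "size", "success"),
                                     ...) {
  type <- match.arg(type)
  if (type == "fitness") {
    df <- object$medians |>
      tidyr::pivot_longer(c("median_best_train", "median_best_test"),
                          names_to = "partition", values_to = "rmse") |>
      dplyr::mutate(partition = sub("^median_best_", "", .data$partition))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$rmse,
                                          colour = .data$system,
                                          linetype = .data$partition)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generation", y = "median best RMSE",
                    colour = NULL, linetype = NULL)
  } else if (type == "size") {
    p <- ggplot2::ggplot(object$medians,
                         ggplot2::aes(.data$generation, .data$median_best_size,
                                      colour = .data$system)) +
      ggplot2::geom_line() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "generation", y = "median best-model size (nodes)",
                    colour = NULL)
  } else {
    df <- object$success_rates |>
      tidyr::pivot_longer(c("xo_success_rate", "mut_success_rate"),
                          names_to = "operator", values_to = "rate") |>
      dplyr::mutate(operator = ifelse(.data$operator == "xo_success_rate",
                                      "crossover", "mutation"))
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$rate,
                                          colour = .data$operator,
                                          linetype = .data$system)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "generation", y = "success rate",
                    colour = NULL, linetype = NULL)
  }
  p + ggplot2::facet_wrap(~ms, labeller = ggplot2::label_both) +
    ggplot2::theme_minimal()
}

#' Plot a theoretical size-bound sequence
#'
#' The average-size bound against generation, on a log10 scale, with the
#' depth-17 manageability budget marked.
#'
#' @param bound A tibble from [size_growth_bound()].
#' @param budget Node budget drawn as a horizontal reference (default
#'   `2^17`).
#' @return A ggplot object.
#' @export
plot_size_bound <- function(bound, budget = 2^17) {
  ggplot2::ggplot(bound, ggplot2::aes(.data$generation, .data$bound)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = budget, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "average size bound (nodes)") +
    ggplot2::theme_minimal()
}
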