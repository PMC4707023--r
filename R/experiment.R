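# Multi-run experiment harness: for each system (standard / elitist), each
# mutation step and each run index, a fresh seeded 70/30 split and a fresh
# evolution; medians aggregated per generation and final best-model sizes
# compared between systems with the rank-based test.

#' Specify a multi-run GSGP experiment
#'
#' The study protocol at configurable scale: `n_runs` independent runs per
#' system and mutation step, each with its own uniform 70/30 data split,
#' reporting the per-generation median fitness of the best individual and
#' the median final best-model size. The reference protocol uses 30 runs
#' of 1000 generations; the default desk scale (10 runs, the
#' [run_config()] defaults of population 50 and 200 generations) is its
#' scaled-down analogue.
#'
#' @param dataset A [gp_dataset()], a preset name (see [synth_presets()])
#'   or a CSV path.
#' @param ms Numeric vector of mutation steps; study values
#'   `c(0.01, 0.1, 1)`.
#' @param systems Character subset of `c("standard", "elitist")`.
#' @param n_runs Independent runs per system and mutation step.
#' @param config Base [run_config()]; its seed and ms are overridden per
#'   run.
#' @param seed Base seed. Run `i` uses seed `seed + i` for both its data
#'   split and its evolution, and the two systems share seeds at equal run
#'   index so the comparison is paired.
#' @param train_fraction Fraction of instances in each training split.
#' @param output_dir Optional directory; when given, per-generation
#'   medians, per-run finals, traces and a JSON report (with the resolved
#'   configuration and every seed) are written there deterministically.
#' @param keep_traces Keep the per-run traces in the returned object.
#' @return An `experiment_spec` object for [run_experiment()].
#' @export
experiment_spec <- function(dataset, ms = c(0.01, 0.1, 1),
                            systems = c("standard", "elitist"),
                            n_runs = 30, config = run_config(),
                            seed = 1, train_fraction = 0.7,
                            output_dir = NULL, keep_traces = TRUE) {
  systems <- match.arg(systems, several.ok = TRUE)
  if (n_runs < 1) stop("experiment_spec: n_runs must be >= 1")
  if (any(ms <= 0)) stop("experiment_spec: ms values must be positive")
  structure(list(dataset = dataset, ms = ms, systems = systems,
                 n_runs = as.integer(n_runs), config = config,
                 seed = as.integer(seed), train_fraction = train_fraction,
                 output_dir = output_dir, keep_traces = isTRUE(keep_traces)),
            class = "gsgp_experiment_spec")
}

resolve_experiment_dataset <- function(dataset, seed) {
  if (inherits(dataset, "gp_dataset")) return(dataset)
  if (is.character(dataset) && length(dataset) == 1L) {
    if (file.exists(dataset)) return(read_dataset_csv(dataset))
    return(synth_dataset(preset = dataset, seed = seed))
  }
  stop("run_experiment: dataset must be a gp_dataset, a preset name or a CSV path")
}

#' Run a multi-run GSGP experiment
#'
#' Executes every system x mutation step x run combination of the spec,
#' then aggregates: per-generation medians of best train/test fitness and
#' best size per system and ms, the final best-model size table (exact
#' sizes as decimal strings), a [compare_final_sizes()] between the two
#' systems for each ms (when both systems are run), and the per-generation
#' operator success-rate curves. With `output_dir` set, artifacts are
#' written as CSV/JSON, byte-identical across repeated invocations of the
#' same spec.
#'
#' @param spec An [experiment_spec()].
#' @return An object of class `gsgp_experiment` with tibbles `medians`,
#'   `finals`, `success_rates`, a list `comparisons`, and `traces` (when
#'   kept).
#' @export
run_experiment <- function(spec) {
  if (!inherits(spec, "gsgp_experiment_spec")) {
    stop("run_experiment: spec must be an experiment_spec()")
  }
  out_dir <- spec$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
      stop(sprintf("run_experiment: output directory '%s' is not writable", out_dir))
    }
  }
  ds <- resolve_experiment_dataset(spec$dataset, spec$seed)

  traces <- list()
  finals <- list()
  k <- 0L
  for (ms_val in spec$ms) {
    for (system in spec$systems) {
      for (i in seq_len(spec$n_runs)) {
        run_seed <- spec$seed + i
        parts <- split_dataset(ds, spec$train_fraction, seed = run_seed)
        cfg <- spec$config
        cfg$ms <- ms_val
        cfg$seed <- run_seed
        cfg$elitist <- system == "elitist"
        run <- run_gsgp(parts$train, parts$test, cfg)
        k <- k + 1L
        traces[[k]] <- dplyr::mutate(run$trace, system = system,
                                     ms = ms_val, run = i, seed = run_seed,
                                     .before = 1L)
        last <- run$trace[nrow(run$trace), ]
        finals[[k]] <- tibble::tibble(
          system = system, ms = ms_val, run = i, seed = run_seed,
          final_train = last$best_train, final_test = last$best_test,
          final_size = last$best_size, final_size_exact = last$best_size_exact)
      }
    }
  }
  traces <- dplyr::bind_rows(traces)
  finals <- dplyr::bind_rows(finals)

  medians <- traces |>
    dplyr::group_by(.data$system, .data$ms, .data$generation) |>
    dplyr::summarise(
      median_best_train = stats::median(.data$best_train),
      median_best_test = stats::median(.data$best_test),
      median_best_size = stats::median(.data$best_size),
      n_runs = dplyr::n(), .groups = "drop")

  success_rates <- traces |>
    dplyr::filter(.data$generation > 0L) |>
    dplyr::group_by(.data$system, .data$ms, .data$generation) |>
    dplyr::summarise(
      xo_success_rate = sum(.data$xo_successes) / max(1L, sum(.data$xo_events)),
      mut_success_rate = sum(.data$mut_successes) / max(1L, sum(.data$mut_events)),
      xo_events = sum(.data$xo_events), mut_events = sum(.data$mut_events),
      .groups = "drop")

  comparisons <- list()
  if (all(c("standard", "elitist") %in% spec$systems)) {
    for (ms_val in spec$ms) {
      a <- finals$final_size[finals$system == "standard" & finals$ms == ms_val]
      b <- finals$final_size[finals$system == "elitist" & finals$ms == ms_val]
      comparisons[[as.character(ms_val)]] <-
        tryCatch(compare_final_sizes(a, b, alpha = 0.1,
                                     labels = c("standard", "elitist")),
                 error = function(e) e)
    }
  }

  out <- structure(list(spec = spec, dataset_name = ds$name,
                        medians = medians, finals = finals,
                        success_rates = success_rates,
                        comparisons = comparisons,
                        traces = if (spec$keep_traces) traces else NULL),
                   class = "gsgp_experiment")
  if (!is.null(out_dir)) write_experiment_artifacts(out, out_dir)
  out
}

write_experiment_artifacts <- function(exp, out_dir) {
  utils::write.csv(exp$medians, file.path(out_dir, "medians.csv"), row.names = FALSE)
  utils::write.csv(exp$finals, file.path(out_dir, "finals.csv"), row.names = FALSE)
  utils::write.csv(exp$success_rates, file.path(out_dir, "success_rates.csv"),
                   row.names = FALSE)
  if (!is.null(exp$traces)) {
    utils::write.csv(exp$traces, file.path(out_dir, "traces.csv"), row.names = FALSE)
  }
  spec <- exp$spec
  report <- list(
    dataset = exp$dataset_name,
    systems = spec$systems, ms = spec$ms, n_runs = spec$n_runs,
    base_seed = spec$seed,
    run_seeds = spec$seed + seq_len(spec$n_runs),
    train_fraction = spec$train_fraction,
    config = unclass(spec$config),
    comparisons = lapply(exp$comparisons, function(cmp) {
      if (inherits(cmp, "error")) list(error = conditionMessage(cmp))
      else jsonlite::fromJSON(size_comparison_to_json(cmp))
    }))
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}

#' @export
print.gsgp_experiment <- function(x, ...) {
  cat(sprintf("<gsgp experiment> dataset '%s': %s | ms in {%s} | %d runs each\n",
              x$dataset_name, paste(x$spec$systems, collapse = " vs "),
              paste(x$spec$ms, collapse = ", "), x$spec$n_runs))
  fin <- x$finals |>
    dplyr::group_by(.data$system, .data$ms) |>
    dplyr::summarise(median_final_train = stats::median(.data$final_train),
                     median_final_size = stats::median(.data$final_size),
                     .groups = "drop")
  print(fin)
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (inherits(cmp, "error")) {
      cat(sprintf("  ms = %s: size comparison unavailable (%s)\n", nm,
                  conditionMessage(cmp)))
    } else {
      cat(sprintf("  ms = %s: Mann-Whitney U = %g, p = %.4g -> sizes %s\n",
                  nm, cmp$u_statistic, cmp$p_value, cmp$verdict))
    }
  }
  invisible(x)
}
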