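# Generational loop for standard and elitist GSGP.
#
# Each offspring slot draws exactly one event (crossover, mutation or
# reproduction).  Success counters — a crossover child strictly fitter
# than both parents, a mutation child strictly fitter than its parent —
# are recorded in both systems; only the elitist system acts on them.

#' Root mean square error
#'
#' @param predicted,target Numeric vectors of equal, positive length.
#' @return `sqrt(mean((predicted - target)^2))`.
#' @export
rmse <- function(predicted, target) {
  if (length(predicted) != length(target) || length(predicted) < 1L) {
    stop("rmse: vectors must have equal length >= 1")
  }
  sqrt(mean((predicted - target)^2))
}

#' Evolution run configuration
#'
#' All parameters of a GSGP run. Operator events are mutually exclusive
#' per offspring slot, drawn with probabilities `p_xo`, `p_m`, `p_r`
#' (which must sum to 1). `ms` is the mutation step bounding the
#' per-coordinate semantic perturbation; the study values are 0.01, 0.1
#' and 1. With `elitist = TRUE` a crossover child enters the population
#' only if strictly fitter (lower training RMSE) than both parents and a
#' mutation child only if strictly fitter than its parent; otherwise a
#' parent survives, chosen by `surviving_parent` (`"best"` or
#' `"random"`). Ties reject the child, keeping the smaller model.
#'
#' Defaults not fixed by the experimental protocol (operator rates,
#' tournament size, initialisation depths, random-tree depth) are
#' explicit, documented assumptions; see the package vignette.
#'
#' @param pop_size Population size.
#' @param generations Number of generations to evolve.
#' @param p_xo,p_m,p_r Crossover / mutation / reproduction probabilities,
#'   summing to 1.
#' @param ms Mutation step (positive).
#' @param tournament_size Tournament size for selection.
#' @param elitist Apply the elitist replacement rule.
#' @param surviving_parent `"best"` or `"random"`: which parent survives a
#'   rejected crossover.
#' @param best_survives Copy the incumbent best unchanged into one slot of
#'   every new population.
#' @param seed Integer seed; the full run is reproducible bit-for-bit.
#' @param rt_max_depth Maximum depth of the random trees drawn by the
#'   semantic operators.
#' @param rt_method Generation method for random trees (`"grow"` or
#'   `"full"`).
#' @param init_depths Length-2 integer range for ramped half-and-half
#'   initialisation of the population.
#' @param ops Binary operator names for [primitive_set()].
#' @param constant_range Interval for ephemeral constants.
#' @param p_terminal,p_var Terminal/variable probabilities for tree
#'   generation.
#' @return An object of class `gsgp_config`.
#' @export
run_config <- function(pop_size = 50, generations = 200,
                       p_xo = 0.7, p_m = 0.25, p_r = 0.05,
                       ms = 1, tournament_size = 4,
                       elitist = FALSE,
                       surviving_parent = c("best", "random"),
                       best_survives = TRUE, seed = 1,
                       rt_max_depth = 4, rt_method = c("grow", "full"),
                       init_depths = c(2, 6),
                       ops = c("+", "-", "*", "/p"),
                       constant_range = c(-1, 1),
                       p_terminal = 0.3, p_var = 0.8) {
  surviving_parent <- match.arg(surviving_parent)
  rt_method <- match.arg(rt_method)
  if (abs(p_xo + p_m + p_r - 1) > 1e-12) {
    stop("run_config: p_xo + p_m + p_r must equal 1 (within 1e-12)")
  }
  if (any(c(p_xo, p_m, p_r) < 0)) stop("run_config: probabilities must be non-negative")
  if (pop_size < 1 || generations < 0) {
    stop("run_config: pop_size >= 1 and generations >= 0 required")
  }
  if (tournament_size < 1 || tournament_size > pop_size) {
    stop("run_config: tournament_size must lie in [1, pop_size]")
  }
  if (!is.numeric(ms) || ms <= 0) stop("run_config: ms must be positive")
  if (length(init_depths) != 2L || init_depths[1] > init_depths[2] || init_depths[1] < 0) {
    stop("run_config: init_depths must be a non-decreasing pair of non-negative depths")
  }
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_xo = p_xo, p_m = p_m, p_r = p_r, ms = ms,
                 tournament_size = as.integer(tournament_size),
                 elitist = isTRUE(elitist),
                 surviving_parent = surviving_parent,
                 best_survives = isTRUE(best_survives),
                 seed = as.integer(seed),
                 rt_max_depth = as.integer(rt_max_depth),
                 rt_method = rt_method,
                 init_depths = as.integer(init_depths),
                 ops = ops, constant_range = constant_range,
                 p_terminal = p_terminal, p_var = p_var),
            class = "gsgp_config")
}

#' @export
print.gsgp_config <- function(x, ...) {
  cat(sprintf("<gsgp config> pop %d, %d generations, p_xo/p_m/p_r = %.2f/%.2f/%.2f, ms = %g, %s system\n",
              x$pop_size, x$generations, x$p_xo, x$p_m, x$p_r, x$ms,
              if (x$elitist) "elitist" else "standard"))
  invisible(x)
}

# strictly-better-than ordering used everywhere: lower train RMSE, ties by
# smaller exact size, then lower id
ind_before <- function(a, b) {
  if (a$train_fit != b$train_fit) return(a$train_fit < b$train_fit)
  cmp <- big_cmp(a$size, b$size)
  if (cmp != 0L) return(cmp < 0L)
  a$id < b$id
}

best_index <- function(pop) {
  best <- 1L
  for (i in seq_along(pop)[-1]) if (ind_before(pop[[i]], pop[[best]])) best <- i
  best
}

#' Tournament selection
#'
#' Draws `k` distinct individuals uniformly at random and returns the one
#' with the lowest training RMSE; ties are broken by smaller exact size,
#' then lower id. `k = 1` is a uniform random draw; `k` equal to the
#' population size always returns the population best.
#'
#' @param pop List of `gsgp_individual`s.
#' @param k Tournament size, `1 <= k <= length(pop)`.
#' @return The selected `gsgp_individual`.
#' @export
tournament_select <- function(pop, k) {
  if (length(pop) < 1L) stop("tournament_select: empty population")
  if (k < 1L || k > length(pop)) stop("tournament_select: k must lie in [1, pop size]")
  idx <- sample.int(length(pop), k, replace = FALSE)
  pop[[idx[best_index(pop[idx])]]]
}

#' Elitist acceptance rule for crossover
#'
#' The child is accepted if and only if its training fitness is strictly
#' better (lower RMSE) than both parents'. Otherwise a surviving parent is
#' returned: the better of the two under `policy = "best"`, or either with
#' equal probability under `policy = "random"`. A child whose fitness
#' exactly equals the better parent's is rejected (strict inequality),
#' which keeps the smaller model.
#'
#' @param child,p1,p2 `gsgp_individual`s with training fitness computed.
#' @param policy `"best"` or `"random"`.
#' @return List with `accept` (logical) and `survivor` (the individual
#'   that enters the population).
#' @export
elitist_accept_crossover <- function(child, p1, p2, policy = c("best", "random")) {
  policy <- match.arg(policy)
  if (child$train_fit < min(p1$train_fit, p2$train_fit)) {
    return(list(accept = TRUE, survivor = child))
  }
  survivor <- if (policy == "best") {
    if (ind_before(p1, p2)) p1 else p2
  } else {
    if (stats::runif(1) < 0.5) p1 else p2
  }
  list(accept = FALSE, survivor = survivor)
}

#' Elitist acceptance rule for mutation
#'
#' The child is accepted if and only if it is strictly fitter (lower
#' training RMSE) than its parent; on a tie the parent is kept.
#'
#' @param child,parent `gsgp_individual`s.
#' @return List with `accept` and `survivor`.
#' @export
elitist_accept_mutation <- function(child, parent) {
  if (child$train_fit < parent$train_fit) {
    list(accept = TRUE, survivor = child)
  } else {
    list(accept = FALSE, survivor = parent)
  }
}

generation_stats <- function(gen, pop, xo_events = 0L, xo_successes = 0L,
                             mut_events = 0L, mut_successes = 0L) {
  b <- pop[[best_index(pop)]]
  sizes <- vapply(pop, function(i) as.numeric(i$size), 1)
  tibble::tibble(generation = as.integer(gen),
                 best_train = b$train_fit,
                 best_test = b$test_fit,
                 best_size = as.numeric(b$size),
                 best_size_exact = format(b$size),
                 median_size = stats::median(sizes),
                 mean_size = mean(sizes),
                 xo_events = as.integer(xo_events),
                 xo_successes = as.integer(xo_successes),
                 mut_events = as.integer(mut_events),
                 mut_successes = as.integer(mut_successes))
}

#' Advance a population by one generation
#'
#' Builds `pop_size` offspring. For each slot one event is drawn among
#' crossover, mutation and reproduction with probabilities
#' `(p_xo, p_m, p_r)`. Success counters (crossover child strictly fitter
#' than both parents; mutation child strictly fitter than its parent) are
#' recorded in both systems; with `elitist = TRUE` the acceptance rules
#' additionally decide which individual fills the slot. When
#' `best_survives` the incumbent best is copied unchanged into the first
#' slot.
#'
#' @param pop List of `gsgp_individual`s.
#' @param config A [run_config()].
#' @param store The pedigree store.
#' @param data List with `X_train`, `y_train`, `X_test`, `y_test` and
#'   `prims` (the primitive set).
#' @param gen Generation index recorded in the statistics row.
#' @return List with `pop` (the new population) and `stats` (a one-row
#'   tibble of generation statistics).
#' @export
step_generation <- function(pop, config, store, data, gen = NA_integer_) {
  n <- config$pop_size
  newpop <- vector("list", n)
  xo_e <- 0L; xo_s <- 0L; mut_e <- 0L; mut_s <- 0L
  slots <- seq_len(n)
  if (config$best_survives) {
    newpop[[1L]] <- pop[[best_index(pop)]]
    slots <- slots[-1L]
  }
  draw_rt <- function() {
    prepare_random_tree(data$prims, data, config$rt_max_depth,
                        config$rt_method, config$p_terminal, config$p_var)
  }
  for (s in slots) {
    u <- stats::runif(1)
    if (u < config$p_xo) {
      p1 <- tournament_select(pop, config$tournament_size)
      p2 <- tournament_select(pop, config$tournament_size)
      cand <- make_child_crossover(p1, p2, draw_rt(), data)
      xo_e <- xo_e + 1L
      success <- cand$train_fit < min(p1$train_fit, p2$train_fit)
      if (success) xo_s <- xo_s + 1L
      if (config$elitist && !success) {
        child <- new_individual(NA_integer_, cand$size, cand$train_sem,
                                cand$test_sem, cand$train_fit, cand$test_fit)
        newpop[[s]] <- elitist_accept_crossover(child, p1, p2,
                                                config$surviving_parent)$survivor
      } else {
        newpop[[s]] <- commit_child(store, cand)
      }
    } else if (u < config$p_xo + config$p_m) {
      p <- tournament_select(pop, config$tournament_size)
      cand <- make_child_mutation(p, draw_rt(), draw_rt(), config$ms, data)
      mut_e <- mut_e + 1L
      success <- cand$train_fit < p$train_fit
      if (success) mut_s <- mut_s + 1L
      if (config$elitist && !success) {
        newpop[[s]] <- p
      } else {
        newpop[[s]] <- commit_child(store, cand)
      }
    } else {
      newpop[[s]] <- tournament_select(pop, config$tournament_size)
    }
  }
  list(pop = newpop,
       stats = generation_stats(gen, newpop, xo_e, xo_s, mut_e, mut_s))
}

#' Run a GSGP evolution
#'
#' Seeds the random number stream, builds the initial population by ramped
#' half-and-half over `init_depths`, then iterates [step_generation()] for
#' `config$generations` generations, recording per-generation statistics
#' (including generation 0). Fitness is the RMSE between an individual's
#' semantics and the targets; acceptance decisions use training fitness
#' only, while test-partition semantics are propagated through the same
#' operator formulas so test fitness is available every generation without
#' reconstruction.
#'
#' @param train,test `gp_dataset`s (or lists with `X` and `y`), the data
#'   partitions.
#' @param config A [run_config()].
#' @return An object of class `gsgp_run`: the config, a per-generation
#'   `trace` tibble, the final `best` individual and the pedigree `store`.
#' @export
run_gsgp <- function(train, test, config) {
  if (!inherits(config, "gsgp_config")) stop("run_gsgp: config must be a run_config()")
  Xtr <- dataset_X(train); ytr <- dataset_y(train)
  Xte <- dataset_X(test); yte <- dataset_y(test)
  if (ncol(Xtr) != ncol(Xte)) stop("run_gsgp: train and test feature counts differ")
  set.seed(config$seed)
  prims <- primitive_set(config$ops, ncol(Xtr), config$constant_range)
  data <- list(X_train = Xtr, y_train = ytr, X_test = Xte, y_test = yte,
               prims = prims)
  store <- new_pedigree(ncol(Xtr))

  depths <- config$init_depths[1]:config$init_depths[2]
  pop <- vector("list", config$pop_size)
  for (j in seq_len(config$pop_size)) {
    d <- depths[((j - 1L) %% length(depths)) + 1L]
    m <- if (j %% 2L == 0L) "full" else "grow"
    tree <- generate_random_tree(prims, d, m, wrap = FALSE,
                                 p_terminal = config$p_terminal,
                                 p_var = config$p_var)
    pop[[j]] <- genesis_individual(tree, store, data)
  }

  stats <- vector("list", config$generations + 1L)
  stats[[1L]] <- generation_stats(0L, pop)
  if (config$generations > 0L) {
    for (g in seq_len(config$generations)) {
      res <- step_generation(pop, config, store, data, gen = g)
      pop <- res$pop
      stats[[g + 1L]] <- res$stats
    }
  }
  best <- pop[[best_index(pop)]]
  structure(list(config = config,
                 trace = dplyr::bind_rows(stats),
                 best = best,
                 final_pop = pop,
                 store = store),
            class = "gsgp_run")
}

#' @export
print.gsgp_run <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("<gsgp run> %s system, pop %d, %d generations\n",
              if (x$config$elitist) "elitist" else "standard",
              x$config$pop_size, x$config$generations))
  cat(sprintf("  best train RMSE %.6g | test RMSE %.6g | exact size %s\n",
              last$best_train, last$best_test, last$best_size_exact))
  invisible(x)
}
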