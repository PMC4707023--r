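# Size dynamics: the theoretical average-size recurrence, manageability
# horizon against the depth-17 node budget, and the rank-based comparison
# of final model sizes between two systems.

#' Theoretical upper bound on average program size
#'
#' With crossover, mutation and reproduction probabilities `p_xo`, `p_m`,
#' `p_r` (summing to 1) and random trees of maximum depth `D`, the average
#' size after `g` generations obeys the recurrence
#'
#' \deqn{S^{(t)} = p_{xo}(2 S^{(t-1)} + 2 B + 5) +
#'               p_m(S^{(t-1)} + 2 B + 4) + p_r S^{(t-1)},}
#'
#' where `B` is the per-tree node budget. Under `convention = "paper"`
#' (the default) `B = 2^D`, the binary-primitives counting convention the
#' bound was stated with; `convention = "strict"` uses the true worst case
#' `B = 2^(D+1) - 1` of a full binary tree. Reproduction contributes
#' nothing, and for `p_xo > 0` the sequence grows exponentially with
#' asymptotic ratio `1 + p_xo`.
#'
#' @param p_xo,p_m,p_r Event probabilities, summing to 1.
#' @param depth Maximum random-tree depth `D`.
#' @param s0 Initial average size (at generation 0).
#' @param generations Number of generations `g`.
#' @param convention `"paper"` (budget `2^D`) or `"strict"`
#'   (`2^(D+1) - 1`).
#' @param tree_budget Optional explicit per-tree node budget overriding
#'   the convention (e.g. to account for a squashing wrapper node).
#' @return A tibble with columns `generation` (0..g) and `bound`.
#' @export
size_growth_bound <- function(p_xo, p_m, p_r, depth, s0, generations,
                              convention = c("paper", "strict"),
                              tree_budget = NULL) {
  convention <- match.arg(convention)
  if (abs(p_xo + p_m + p_r - 1) > 1e-12 || any(c(p_xo, p_m, p_r) < 0)) {
    stop("size_growth_bound: p_xo, p_m, p_r must be non-negative and sum to 1")
  }
  if (generations < 0) stop("size_growth_bound: generations must be >= 0")
  if (depth < 0) stop("size_growth_bound: depth must be >= 0")
  if (s0 < 1) stop("size_growth_bound: s0 must be >= 1")
  B <- if (!is.null(tree_budget)) tree_budget
       else if (convention == "paper") 2^depth else 2^(depth + 1) - 1
  s <- numeric(generations + 1)
  s[1] <- s0
  for (t in seq_len(generations)) {
    prev <- s[t]
    s[t + 1] <- p_xo * (2 * prev + 2 * B + 5) +
      p_m * (prev + 2 * B + 4) +
      p_r * prev
  }
  tibble::tibble(generation = 0:generations, bound = s)
}

#' First generation at which a size summary exceeds a budget
#'
#' Scans a per-generation size sequence (e.g. the median best-model size,
#' or the theoretical bound) and returns the smallest generation whose
#' value exceeds `budget`, or `NA` if it never does. The default budget is
#' the depth-17 node budget `2^17 = 131072` separating manageable from
#' unmanageable models.
#'
#' @param sizes Numeric vector of per-generation sizes, or the tibble
#'   returned by [size_growth_bound()].
#' @param budget Node budget (default `2^17`).
#' @param generations Generation labels aligned with `sizes`; defaults to
#'   `0, 1, ...`.
#' @return The generation index, or `NA_integer_`.
#' @export
first_unmanageable_generation <- function(sizes, budget = 2^17,
                                          generations = NULL) {
  if (is.data.frame(sizes)) {
    if (is.null(generations)) generations <- sizes$generation
    sizes <- sizes$bound
  }
  if (length(sizes) < 1L) stop("first_unmanageable_generation: empty size sequence")
  if (budget < 1) stop("first_unmanageable_generation: budget must be >= 1")
  if (is.null(generations)) generations <- seq_along(sizes) - 1L
  hit <- which(sizes > budget)
  if (length(hit) == 0L) return(NA_integer_)
  as.integer(generations[hit[1L]])
}

#' Compare final model sizes between two systems
#'
#' Runs a Shapiro-Wilk normality check on each sample at level `alpha`
#' (recorded to justify the rank-based test; sizes across runs are
#' typically far from normal) and then the two-sided Mann-Whitney U test
#' of the null hypothesis that the two distributions are the same. The
#' verdict is `"different"` iff `p < alpha`. The exact null distribution
#' is used for small untied samples, the normal approximation with tie
#' correction otherwise.
#'
#' @param sample_a,sample_b Numeric vectors of final best-model sizes
#'   (one per run), each with at least 3 observations. `bigint` lists are
#'   accepted and ranked via their double value.
#' @param alpha Significance level, default 0.1.
#' @param labels Length-2 character naming the systems.
#' @return An object of class `gsgp_size_comparison` with the U statistic,
#'   p value, per-sample Shapiro-Wilk p values and the verdict.
#' @export
compare_final_sizes <- function(sample_a, sample_b, alpha = 0.1,
                                labels = c("a", "b")) {
  to_num <- function(x) {
    if (is.list(x)) vapply(x, function(v) as.numeric(big_int(v)), 1) else as.numeric(x)
  }
  a <- to_num(sample_a)
  b <- to_num(sample_b)
  if (length(a) < 3L || length(b) < 3L) {
    stop("compare_final_sizes: each sample needs at least 3 observations")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("compare_final_sizes: alpha must lie in (0, 1)")
  }
  if (stats::var(c(a, b)) == 0) {
    stop("compare_final_sizes: degenerate input, all observations identical")
  }
  shapiro_p <- function(x) {
    if (length(x) < 3L || length(x) > 5000L || stats::var(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  structure(list(sample_a = a, sample_b = b, labels = labels,
                 n_a = length(a), n_b = length(b),
                 shapiro_p_a = shapiro_p(a), shapiro_p_b = shapiro_p(b),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 alpha = alpha,
                 verdict = if (wt$p.value < alpha) "different" else "not different"),
            class = "gsgp_size_comparison")
}

#' @export
print.gsgp_size_comparison <- function(x, ...) {
  cat(sprintf("<size comparison> %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n_a, x$labels[2], x$n_b))
  cat(sprintf("  Shapiro-Wilk p: %.4g / %.4g (normality gate, alpha = %g)\n",
              x$shapiro_p_a, x$shapiro_p_b, x$alpha))
  cat(sprintf("  Mann-Whitney U = %g, two-sided p = %.4g -> %s\n",
              x$u_statistic, x$p_value, x$verdict))
  invisible(x)
}

#' Export a size comparison as JSON
#'
#' @param x A `gsgp_size_comparison`.
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
size_comparison_to_json <- function(x, path = NULL) {
  obj <- list(n_a = x$n_a, n_b = x$n_b,
              shapiro_p_a = x$shapiro_p_a, shapiro_p_b = x$shapiro_p_b,
              U = x$u_statistic, p = x$p_value,
              alpha = x$alpha, verdict = x$verdict)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
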