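# Shared fixtures and independent oracles, all built in code.

# Independent scalar interpreter: recurses node by node over one input row
# at a time, deliberately sharing no code with eval_tree().
oracle_eval_row <- function(t, row) {
  switch(t$kind,
    var = row[[t$i]],
    const = t$v,
    logis = 1 / (1 + exp(-oracle_eval_row(t$child, row))),
    op = {
      a <- oracle_eval_row(t$l, row)
      b <- oracle_eval_row(t$r, row)
      switch(t$op,
        "+" = a + b, "-" = a - b, "*" = a * b,
        "/p" = if (abs(b) <= 1e-6) 1 else a / b)
    })
}

oracle_eval <- function(t, X) {
  vapply(seq_len(nrow(X)), function(i) oracle_eval_row(t, X[i, ]), 1)
}

# Small evaluation context (matrices, targets, primitive set) for driving
# the semantic operators directly.
tiny_data <- function(n_train = 8, n_test = 4, p = 3, seed = 42) {
  set.seed(seed)
  X_train <- matrix(runif(n_train * p, -1, 1), n_train, p)
  X_test <- matrix(runif(n_test * p, -1, 1), n_test, p)
  list(X_train = X_train,
       y_train = runif(n_train, -1, 1),
       X_test = X_test,
       y_test = runif(n_test, -1, 1),
       prims = primitive_set(n_features = p))
}

# Prepare a hand-written tree for use as an operator random tree.
prep_rt <- function(tree, data) {
  if (is.character(tree)) tree <- expr_from_text(tree)
  list(tree = tree, size = node_count(tree),
       train_sem = eval_tree(tree, data$X_train),
       test_sem = eval_tree(tree, data$X_test))
}

genesis_from_text <- function(text, store, data) {
  genesis_individual(expr_from_text(text), store, data)
}

# Deterministic 50-operation lineage: a genesis individual taken through
# `n_xo` self-crossovers followed by `n_mut` mutations, all with small
# fixed random trees, so the result stays reconstructable.
build_lineage <- function(data, store, n_xo = 5, n_mut = 45, ms = 0.1, seed = 7) {
  set.seed(seed)
  ind <- genesis_from_text("(+ x1 (* x2 x3))", store, data)
  for (i in seq_len(n_xo)) {
    r <- prep_rt(generate_random_tree(data$prims, 2, "grow", wrap = TRUE), data)
    ind <- semantic_crossover(ind, ind, r, store, data)
  }
  for (i in seq_len(n_mut)) {
    r1 <- prep_rt(generate_random_tree(data$prims, 2, "grow", wrap = TRUE), data)
    r2 <- prep_rt(generate_random_tree(data$prims, 2, "grow", wrap = TRUE), data)
    ind <- semantic_mutation(ind, r1, r2, ms, store, data)
  }
  ind
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enum_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  stopifnot(anyDuplicated(pooled) == 0)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  # two-sided: double the smaller tail of min(U, U') as wilcox.test does
  u_lo <- min(u_obs, n * m - u_obs)
  min(1, 2 * mean(us <= u_lo))
}
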