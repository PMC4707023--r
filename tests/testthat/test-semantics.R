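# Operator semantics act on output vectors; sizes follow the exact
# lineage recurrence and agree with full reconstruction.

test_that("crossover semantics are the convex combination of the parents'", {
  data <- list(X_train = matrix(0, 2, 1), y_train = c(0, 0),
               X_test = matrix(0, 2, 1), y_test = c(0, 0),
               prims = primitive_set(n_features = 1))
  store <- new_pedigree(1)
  p1 <- genesis_from_text("1", store, data)
  p2 <- genesis_from_text("3", store, data)
  r_half <- prep_rt("(logis 0)", data) # logis(0) = 0.5 exactly
  child <- semantic_crossover(p1, p2, r_half, store, data)
  expect_identical(child$train_sem, c(2, 2)) # midpoint
  # degenerate weight r = 1 reproduces p1 exactly
  r_one <- list(tree = expr_from_text("1"), size = 1,
                train_sem = c(1, 1), test_sem = c(1, 1))
  child1 <- semantic_crossover(p1, p2, r_one, store, data)
  expect_identical(child1$train_sem, p1$train_sem)
})

test_that("crossover offspring size is size(p1) + size(p2) + 2 size(TR) + 5", {
  data <- tiny_data()
  store <- new_pedigree(3)
  p1 <- genesis_from_text("(+ x1 x2)", store, data)  # 3 nodes
  p2 <- genesis_from_text("(* x1 x3)", store, data)  # 3 nodes
  r <- prep_rt("0.5", data)                          # 1 node
  child <- semantic_crossover(p1, p2, r, store, data)
  expect_identical(format(child$size), "13")
  rec <- reconstruct_expression(child, store)
  expect_identical(node_count(rec), 13)
})

test_that("mutation semantics are a bounded perturbation of the parent's", {
  data <- list(X_train = matrix(c(1, 2), 2, 1), y_train = c(0, 0),
               X_test = matrix(1, 1, 1), y_test = 0,
               prims = primitive_set(n_features = 1))
  store <- new_pedigree(1)
  t <- genesis_from_text("x1", store, data) # semantics [1, 2]
  r1 <- list(tree = expr_from_text("1"), size = 1,
             train_sem = c(1, 0), test_sem = 1)
  r2 <- list(tree = expr_from_text("0"), size = 1,
             train_sem = c(0, 1), test_sem = 0)
  child <- semantic_mutation(t, r1, r2, 0.5, store, data)
  expect_identical(child$train_sem, c(1.5, 1.5))
  expect_identical(format(child$size), "7") # 1 + 1 + 1 + 4
  # ms -> 0 limit: semantics converge to the parent's
  tiny <- semantic_mutation(t, r1, r2, 1e-12, store, data)
  expect_equal(tiny$train_sem, t$train_sem, tolerance = 1e-10)
  expect_error(semantic_mutation(t, r1, r2, 0, store, data), "positive")
})

test_that("size_of_offspring implements the exact recurrence", {
  expect_identical(format(size_of_offspring("reproduction", 42)), "42")
  expect_identical(format(size_of_offspring("crossover", c(1, 1), 1)), "9")
  expect_identical(format(size_of_offspring("mutation", 1, c(1, 1))), "7")
  expect_error(size_of_offspring("cloning", 1), "unknown op_kind")
  # far beyond double precision, still exact
  huge <- big_int("9007199254740993") # 2^53 + 1
  out <- size_of_offspring("crossover", list(huge, huge), 1)
  expect_identical(format(out), "18014398509481993")
})

test_that("iterated self-crossover sizes match brute-force reconstruction", {
  data <- tiny_data()
  store <- new_pedigree(3)
  ind <- genesis_from_text("x1", store, data)
  r <- prep_rt("0.5", data)
  for (g in 1:6) {
    ind <- semantic_crossover(ind, ind, r, store, data)
    expect_identical(node_count(reconstruct_expression(ind, store)),
                     as.numeric(ind$size))
  }
  expect_identical(format(ind$size), "505") # s -> 2s + 7 from 1, six times
})

test_that("stored semantics equal re-evaluation of the reconstruction", {
  data <- tiny_data(n_train = 12, n_test = 6)
  store <- new_pedigree(3)
  set.seed(11)
  p1 <- genesis_individual(generate_random_tree(data$prims, 3, "grow"), store, data)
  p2 <- genesis_individual(generate_random_tree(data$prims, 3, "full"), store, data)
  r <- prep_rt(generate_random_tree(data$prims, 3, "grow", wrap = TRUE), data)
  child <- semantic_crossover(p1, p2, r, store, data)
  rec <- reconstruct_expression(child, store)
  expect_equal(eval_tree(rec, data$X_train), child$train_sem, tolerance = 1e-9)
  expect_equal(eval_tree(rec, data$X_test), child$test_sem, tolerance = 1e-9)
})

test_that("a 50-operation lineage satisfies all oracle equivalences", {
  data <- tiny_data(n_train = 10, n_test = 5)
  store <- new_pedigree(3)
  ind <- build_lineage(data, store, n_xo = 3, n_mut = 12)
  rec <- reconstruct_expression(ind, store)
  expect_identical(node_count(rec), as.numeric(ind$size))
  expect_equal(eval_tree(rec, data$X_train), ind$train_sem, tolerance = 1e-9)
  for (i in 1:3) {
    x <- data$X_test[i, ]
    expect_equal(evaluate_unseen(ind, x, store),
                 eval_tree(rec, matrix(x, 1)), tolerance = 1e-9)
  }
})

test_that("reconstruction refuses unmanageable models, naming the exact size", {
  data <- tiny_data()
  store <- new_pedigree(3)
  ind <- genesis_from_text("x1", store, data)
  r <- prep_rt("0.5", data)
  for (g in 1:25) ind <- semantic_crossover(ind, ind, r, store, data)
  expect_gt(as.numeric(ind$size), 2^20)
  err <- tryCatch(reconstruct_expression(ind, store, size_guard = 2^17),
                  gsgp_unmanageable = function(e) e)
  expect_s3_class(err, "gsgp_unmanageable")
  expect_match(conditionMessage(err), format(ind$size), fixed = TRUE)
  # the same lineage is still evaluable on unseen rows, and finite
  v <- evaluate_unseen(ind, data$X_test[1, ], store)
  expect_true(is.finite(v))
  # genesis individuals reconstruct to their own stored tree
  g0 <- genesis_from_text("(+ x1 x2)", store, data)
  expect_identical(expr_to_text(reconstruct_expression(g0, store)), "(+ x1 x2)")
  expect_equal(evaluate_unseen(g0, data$X_test[1, ], store),
               data$X_test[1, 1] + data$X_test[1, 2], tolerance = 1e-12)
})

test_that("crossover is coordinate-convex and mutation ms-bounded (properties)", {
  data <- list(X_train = matrix(0, 10, 1), y_train = rep(0, 10),
               X_test = matrix(0, 10, 1), y_test = rep(0, 10),
               prims = primitive_set(n_features = 1))
  set.seed(12)
  store <- new_pedigree(1)
  mk <- function(sem) {
    list(id = NA_integer_, size = big_int(1),
         train_sem = sem, test_sem = sem,
         train_fit = rmse(sem, data$y_train), test_fit = rmse(sem, data$y_test))
  }
  for (case in 1:500) {
    p1 <- mk(runif(10, -5, 5))
    p2 <- mk(runif(10, -5, 5))
    w <- runif(10)
    r <- list(tree = expr_from_text("0.5"), size = 1, train_sem = w, test_sem = w)
    child <- semantic_crossover(p1, p2, r, store, data)
    expect_true(all(child$train_sem >= pmin(p1$train_sem, p2$train_sem) - 1e-12))
    expect_true(all(child$train_sem <= pmax(p1$train_sem, p2$train_sem) + 1e-12))

    t <- mk(runif(10, -5, 5))
    ms <- runif(1, 0.01, 2)
    w1 <- runif(10); w2 <- runif(10)
    r1 <- list(tree = expr_from_text("0.1"), size = 1, train_sem = w1, test_sem = w1)
    r2 <- list(tree = expr_from_text("0.2"), size = 1, train_sem = w2, test_sem = w2)
    mut <- semantic_mutation(t, r1, r2, ms, store, data)
    expect_lte(max(abs(mut$train_sem - t$train_sem)), ms + 1e-12)
  }
})

test_that("operators never modify their parents (pedigree immutability)", {
  data <- tiny_data()
  store <- new_pedigree(3)
  p1 <- genesis_from_text("(+ x1 x2)", store, data)
  p2 <- genesis_from_text("x3", store, data)
  snap1 <- unserialize(serialize(p1, NULL))
  snap2 <- unserialize(serialize(p2, NULL))
  r <- prep_rt("(logis x1)", data)
  invisible(semantic_crossover(p1, p2, r, store, data))
  invisible(semantic_mutation(p1, prep_rt("0.3", data), prep_rt("0.6", data),
                              0.1, store, data))
  expect_identical(p1, snap1)
  expect_identical(p2, snap2)
})

test_that("operator contract violations raise structural errors", {
  data <- tiny_data()
  store <- new_pedigree(3)
  p1 <- genesis_from_text("x1", store, data)
  p2 <- genesis_from_text("x2", store, data)
  bad_r <- list(tree = expr_from_text("2"), size = 1,
                train_sem = rep(2, length(p1$train_sem)),
                test_sem = rep(2, length(p1$test_sem)))
  expect_error(semantic_crossover(p1, p2, bad_r, store, data), "outside \\[0, 1\\]")
  short_r <- list(tree = expr_from_text("0.5"), size = 1,
                  train_sem = 0.5, test_sem = 0.5)
  expect_error(semantic_crossover(p1, p2, short_r, store, data), "lengths")
})

test_that("pedigree JSON dump round-trips and resolves every reference", {
  data <- tiny_data()
  store <- new_pedigree(3)
  ind <- build_lineage(data, store, n_xo = 2, n_mut = 3)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  pedigree_to_json(store, path)
  store2 <- pedigree_from_json(path)
  expect_identical(length(store2$inds), length(store$inds))
  expect_identical(length(store2$trees), length(store$trees))
  rec1 <- reconstruct_expression(ind$id, store)
  rec2 <- reconstruct_expression(ind$id, store2)
  expect_identical(expr_to_text(rec1), expr_to_text(rec2))
  expect_identical(format(store2$inds[[ind$id]]$size), format(ind$size))
})
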