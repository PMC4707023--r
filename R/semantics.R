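# Memory-efficient GSGP representation: individuals carry semantics
# (output vectors on the train/test partitions), exact size and a lineage
# record; only generation-0 trees and the random trees drawn by the
# operators are ever stored as syntax.  Evolving n individuals for g
# generations costs O(ng); evaluating an unseen instance costs O(g).

#' Create an empty pedigree store
#'
#' Append-only pool of genesis and random trees plus lineage records for
#' every individual created, keyed by integer id. Entries are never
#' mutated after insertion; every parent or random-tree reference in a
#' lineage record resolves within the store.
#'
#' @param n_features Number of input variables the stored trees expect
#'   (used to validate unseen-instance rows); may be `NA` and set later.
#' @return An object of class `gsgp_pedigree` (an environment).
#' @export
new_pedigree <- function(n_features = NA_integer_) {
  e <- new.env(parent = emptyenv())
  e$trees <- list()
  e$inds <- list()
  e$n_features <- as.integer(n_features)
  class(e) <- "gsgp_pedigree"
  e
}

ped_add_tree <- function(store, tree) {
  id <- length(store$trees) + 1L
  store$trees[[id]] <- tree
  id
}

ped_add_ind <- function(store, record) {
  id <- length(store$inds) + 1L
  record$id <- id
  store$inds[[id]] <- record
  id
}

new_individual <- function(id, size, train_sem, test_sem, train_fit, test_fit) {
  structure(list(id = id, size = size,
                 train_sem = train_sem, test_sem = test_sem,
                 train_fit = train_fit, test_fit = test_fit),
            class = "gsgp_individual")
}

#' @export
print.gsgp_individual <- function(x, ...) {
  cat(sprintf("<gsgp individual #%d> size %s, train RMSE %.6g, test RMSE %.6g\n",
              x$id, format(x$size), x$train_fit, x$test_fit))
  invisible(x)
}

#' Create a generation-0 (genesis) individual from a syntax tree
#'
#' Evaluates the tree on both partitions, computes RMSE fitness and
#' records the tree in the pedigree store.
#'
#' @param tree An expression node.
#' @param store A [new_pedigree()] store.
#' @param data A list with `X_train`, `y_train`, `X_test`, `y_test`.
#' @return A `gsgp_individual`.
#' @export
genesis_individual <- function(tree, store, data) {
  tr <- eval_tree(tree, data$X_train)
  te <- eval_tree(tree, data$X_test)
  tid <- ped_add_tree(store, tree)
  size <- big_int(node_count(tree))
  id <- ped_add_ind(store, list(kind = "genesis", tree_id = tid, size = size))
  new_individual(id, size, tr, te,
                 rmse(tr, data$y_train), rmse(te, data$y_test))
}

# A random tree prepared for use by the semantic operators: wrapped syntax
# plus its semantics on both partitions.
prepare_random_tree <- function(prims, data, max_depth, method = "grow",
                                p_terminal = 0.3, p_var = 0.8) {
  tree <- generate_random_tree(prims, max_depth, method, wrap = TRUE,
                               p_terminal = p_terminal, p_var = p_var)
  list(tree = tree,
       size = node_count(tree),
       train_sem = eval_tree(tree, data$X_train),
       test_sem = eval_tree(tree, data$X_test))
}

check_unit_interval <- function(sem, what) {
  if (any(sem < 0 | sem > 1)) {
    stop(sprintf("%s: random-tree semantics outside [0, 1]", what))
  }
  invisible(TRUE)
}

# candidate offspring, not yet committed to the store
make_child_crossover <- function(p1, p2, r, data) {
  if (length(p1$train_sem) != length(p2$train_sem) ||
      length(p1$train_sem) != length(r$train_sem)) {
    stop("semantic_crossover: semantics lengths do not match")
  }
  check_unit_interval(r$train_sem, "semantic_crossover")
  check_unit_interval(r$test_sem, "semantic_crossover")
  tr <- p1$train_sem * r$train_sem + (1 - r$train_sem) * p2$train_sem
  te <- p1$test_sem * r$test_sem + (1 - r$test_sem) * p2$test_sem
  list(kind = "crossover",
       parents = c(p1$id, p2$id), r_trees = list(r), ms = NULL,
       size = p1$size + p2$size + big_int(2 * r$size + 5),
       train_sem = tr, test_sem = te,
       train_fit = rmse(tr, data$y_train), test_fit = rmse(te, data$y_test))
}

make_child_mutation <- function(t, r1, r2, ms, data) {
  if (!is.numeric(ms) || length(ms) != 1L || ms <= 0) {
    stop("semantic_mutation: ms must be a positive real")
  }
  if (length(t$train_sem) != length(r1$train_sem) ||
      length(t$train_sem) != length(r2$train_sem)) {
    stop("semantic_mutation: semantics lengths do not match")
  }
  check_unit_interval(r1$train_sem, "semantic_mutation")
  check_unit_interval(r2$train_sem, "semantic_mutation")
  tr <- t$train_sem + ms * (r1$train_sem - r2$train_sem)
  te <- t$test_sem + ms * (r1$test_sem - r2$test_sem)
  list(kind = "mutation",
       parents = t$id, r_trees = list(r1, r2), ms = ms,
       size = t$size + big_int(r1$size + r2$size + 4),
       train_sem = tr, test_sem = te,
       train_fit = rmse(tr, data$y_train), test_fit = rmse(te, data$y_test))
}

commit_child <- function(store, cand) {
  rtree_ids <- vapply(cand$r_trees, function(r) ped_add_tree(store, r$tree), 1L)
  id <- ped_add_ind(store, list(kind = cand$kind, parents = cand$parents,
                                rtree_ids = rtree_ids, ms = cand$ms,
                                size = cand$size))
  new_individual(id, cand$size, cand$train_sem, cand$test_sem,
                 cand$train_fit, cand$test_fit)
}

#' Geometric semantic crossover
#'
#' The offspring of parents `T1`, `T2` under a random tree `TR` with
#' outputs in `[0, 1]` is `(T1 * TR) + ((1 - TR) * T2)`. On semantics this
#' is the coordinate-wise convex combination
#' `s(i) = p1(i) * r(i) + (1 - r(i)) * p2(i)`, so every child coordinate
#' lies between the parents'. The exact offspring size is
#' `size(p1) + size(p2) + 2 * size(TR) + 5`: the combiner contributes two
#' copies of the random tree's genotype plus 5 nodes.
#'
#' @param p1,p2 Parent `gsgp_individual`s sharing data partitions.
#' @param r A prepared random tree as produced internally (list with
#'   `tree`, `size`, `train_sem`, `test_sem`, semantics within `[0, 1]`).
#' @param store The pedigree store; the random tree and the lineage record
#'   are appended.
#' @param data List with `y_train`, `y_test` (targets for fitness).
#' @return The offspring `gsgp_individual`.
#' @export
semantic_crossover <- function(p1, p2, r, store, data) {
  commit_child(store, make_child_crossover(p1, p2, r, data))
}

#' Geometric semantic mutation (ball mutation)
#'
#' The offspring of `T` under two distinct random trees with outputs in
#' `[0, 1]` and mutation step `ms > 0` is `T + ms * (TR1 - TR2)`: each
#' semantics coordinate is perturbed by at most `ms`. The exact offspring
#' size is `size(T) + size(TR1) + size(TR2) + 4` (the mutation-step
#' constant counts as one of the 4 combiner nodes).
#'
#' @param t Parent `gsgp_individual`.
#' @param r1,r2 Two independently drawn prepared random trees with
#'   `[0, 1]` semantics; each is stored (and counted) separately even if
#'   structurally equal.
#' @param ms Mutation step, positive.
#' @param store The pedigree store.
#' @param data List with `y_train`, `y_test`.
#' @return The offspring `gsgp_individual`.
#' @export
semantic_mutation <- function(t, r1, r2, ms, store, data) {
  commit_child(store, make_child_mutation(t, r1, r2, ms, data))
}

#' Exact offspring size recurrence
#'
#' Crossover: `s1 + s2 + 2*r + 5`. Mutation: `s + r1 + r2 + 4`.
#' Reproduction leaves the size unchanged; genesis returns the base size.
#' All arithmetic is exact arbitrary-precision integer arithmetic, so the
#' recurrence never overflows regardless of the generation count.
#'
#' @param op_kind One of `"crossover"`, `"mutation"`, `"reproduction"`,
#'   `"genesis"`.
#' @param parent_sizes Numeric or `bigint` parent sizes (2 for crossover,
#'   1 otherwise); for genesis, the base tree size.
#' @param random_tree_sizes Node counts of the random trees (1 for
#'   crossover — used twice — 2 for mutation).
#' @return A `bigint`.
#' @export
size_of_offspring <- function(op_kind, parent_sizes, random_tree_sizes = NULL) {
  as_bigs <- function(x) {
    if (inherits(x, "bigint")) list(x) else lapply(x, big_int)
  }
  p <- as_bigs(parent_sizes)
  r <- if (is.null(random_tree_sizes)) list() else as_bigs(random_tree_sizes)
  switch(op_kind,
    crossover = {
      if (length(p) != 2L || length(r) != 1L) {
        stop("size_of_offspring: crossover needs 2 parent sizes and 1 random-tree size")
      }
      p[[1]] + p[[2]] + r[[1]] * 2 + big_int(5)
    },
    mutation = {
      if (length(p) != 1L || length(r) != 2L) {
        stop("size_of_offspring: mutation needs 1 parent size and 2 random-tree sizes")
      }
      p[[1]] + r[[1]] + r[[2]] + big_int(4)
    },
    reproduction = ,
    genesis = {
      if (length(p) != 1L) stop("size_of_offspring: need exactly 1 size")
      p[[1]]
    },
    stop(sprintf("size_of_offspring: unknown op_kind '%s'", op_kind)))
}

ind_id <- function(ind) {
  if (inherits(ind, "gsgp_individual")) ind$id else as.integer(ind)
}

#' Reconstruct the full syntax tree of an individual
#'
#' Recursively expands the lineage: a crossover record becomes the
#' combiner `(T1 * TR) + ((1 - TR) * T2)` with two copies of the stored
#' random tree, a mutation record becomes `T + ms * (TR1 - TR2)`. The
#' reconstruction's node count equals the individual's exact recorded
#' size. Because sizes grow exponentially, reconstruction is refused when
#' the exact size exceeds `size_guard` (default `2^17`, the depth-17
#' manageability budget); the error carries the exact size.
#'
#' @param ind A `gsgp_individual` or an individual id.
#' @param store The pedigree store that recorded the lineage.
#' @param size_guard Maximum size (nodes) that will be materialised.
#' @return An expression node.
#' @export
reconstruct_expression <- function(ind, store, size_guard = 2^17) {
  id <- ind_id(ind)
  rec <- store$inds[[id]]
  if (is.null(rec)) stop(sprintf("reconstruct_expression: unknown individual id %d", id))
  if (big_cmp(rec$size, big_int(size_guard)) > 0L) {
    stop(structure(class = c("gsgp_unmanageable", "error", "condition"),
                   list(message = sprintf(
                     "model unmanageable: exact size %s exceeds the size guard %s",
                     format(rec$size), format(big_int(size_guard))),
                     call = sys.call(-1), size = rec$size)))
  }
  build <- function(id) {
    r <- store$inds[[id]]
    switch(r$kind,
      genesis = store$trees[[r$tree_id]],
      reproduction = build(r$parents[1]),
      crossover = {
        tr <- store$trees[[r$rtree_ids[1]]]
        expr_op("+",
                expr_op("*", build(r$parents[1]), tr),
                expr_op("*", expr_op("-", expr_const(1), tr),
                        build(r$parents[2])))
      },
      mutation = {
        t1 <- store$trees[[r$rtree_ids[1]]]
        t2 <- store$trees[[r$rtree_ids[2]]]
        expr_op("+", build(r$parents[1]),
                expr_op("*", expr_const(r$ms), expr_op("-", t1, t2)))
      },
      stop(sprintf("reconstruct_expression: unknown lineage kind '%s'", r$kind)))
  }
  build(id)
}

#' Evaluate an individual on an unseen input row
#'
#' Computes the model output on a single input row by recursing over the
#' lineage, evaluating each stored genesis/random tree on the row once and
#' combining values through the operator formulas — without materialising
#' the full expression. The number of tree evaluations grows with the
#' lineage size, not with the (possibly astronomically larger) model size.
#'
#' @param ind A `gsgp_individual` or id.
#' @param x A numeric vector, one value per input variable.
#' @param store The pedigree store.
#' @return A single numeric model output.
#' @export
evaluate_unseen <- function(ind, x, store) {
  if (!is.numeric(x) || is.null(dim(x)) && length(x) < 1L) {
    stop("evaluate_unseen: x must be a numeric input row")
  }
  x <- as.numeric(x)
  if (!is.na(store$n_features) && length(x) != store$n_features) {
    stop(sprintf("evaluate_unseen: row has %d values but the model expects %d",
                 length(x), store$n_features))
  }
  xm <- matrix(x, nrow = 1L)
  cache <- new.env(parent = emptyenv())
  ev_tree <- function(tid) eval_tree(store$trees[[tid]], xm)
  ev <- function(id) {
    key <- as.character(id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    r <- store$inds[[id]]
    val <- switch(r$kind,
      genesis = ev_tree(r$tree_id),
      reproduction = ev(r$parents[1]),
      crossover = {
        rv <- ev_tree(r$rtree_ids[1])
        ev(r$parents[1]) * rv + (1 - rv) * ev(r$parents[2])
      },
      mutation = ev(r$parents[1]) +
        r$ms * (ev_tree(r$rtree_ids[1]) - ev_tree(r$rtree_ids[2])),
      stop(sprintf("evaluate_unseen: unknown lineage kind '%s'", r$kind)))
    cache[[key]] <- val
    val
  }
  as.numeric(ev(ind_id(ind)))
}

#' Export a pedigree as a JSON lineage dump
#'
#' Trees are serialised in prefix text, individuals as records with id,
#' operator kind, parent ids, random-tree ids, mutation step and exact
#' size (decimal string).
#'
#' @param store The pedigree store.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
pedigree_to_json <- function(store, path = NULL) {
  obj <- list(
    n_features = store$n_features,
    trees = lapply(seq_along(store$trees), function(i) {
      list(id = i, expr = expr_to_text(store$trees[[i]]))
    }),
    individuals = lapply(store$inds, function(r) {
      list(id = r$id, kind = r$kind,
           parents = if (is.null(r$parents)) integer(0) else as.integer(r$parents),
           rtree_ids = if (is.null(r$rtree_ids)) integer(0) else as.integer(r$rtree_ids),
           tree_id = if (is.null(r$tree_id)) NULL else r$tree_id,
           ms = r$ms,
           size = format(r$size))
    }))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Rebuild a pedigree store from a JSON lineage dump
#'
#' @param path Path to a file written by [pedigree_to_json()].
#' @return A `gsgp_pedigree` store.
#' @export
pedigree_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  store <- new_pedigree(if (is.null(obj$n_features)) NA_integer_ else obj$n_features)
  for (tr in obj$trees) ped_add_tree(store, expr_from_text(tr$expr))
  for (r in obj$individuals) {
    ped_add_ind(store, list(
      kind = r$kind,
      parents = if (length(r$parents)) vapply(r$parents, as.integer, 1L) else NULL,
      rtree_ids = if (length(r$rtree_ids)) vapply(r$rtree_ids, as.integer, 1L) else NULL,
      tree_id = if (is.null(r$tree_id)) NULL else as.integer(r$tree_id),
      ms = if (is.null(r$ms)) NULL else as.numeric(r$ms),
      size = big_int(r$size)))
  }
  store
}
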