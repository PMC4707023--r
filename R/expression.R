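# Expression trees over binary arithmetic primitives.
#
# Nodes are plain nested lists: list(kind = "op", op, l, r),
# list(kind = "var", i), list(kind = "const", v) and the unary squashing
# wrapper list(kind = "logis", child) used to force random-tree outputs
# into [0, 1].  Every node, the wrapper included, counts as one node.

KNOWN_OPS <- c("+", "-", "*", "/p")
PDIV_EPS <- 1e-6

#' Primitive set for expression trees
#'
#' The function set is restricted to binary arithmetic operators: `+`, `-`,
#' `*` and protected division `/p`, which returns 1 whenever the absolute
#' value of the denominator is at most 1e-6. Terminals are input variables
#' `x1 ... x<n_features>` and ephemeral constants drawn uniformly from
#' `constant_range`.
#'
#' @param ops Character vector of binary operator names, a subset of
#'   `c("+", "-", "*", "/p")`.
#' @param n_features Number of input variables (at least 1).
#' @param constant_range Length-2 numeric, the closed interval ephemeral
#'   constants are drawn from.
#' @return An object of class `gsgp_prims`.
#' @export
primitive_set <- function(ops = KNOWN_OPS, n_features,
                          constant_range = c(-1, 1)) {
  ops <- as.character(ops)
  if (length(ops) < 1L || !all(ops %in% KNOWN_OPS)) {
    stop("primitive_set: ops must be a non-empty subset of ",
         paste(KNOWN_OPS, collapse = " "))
  }
  if (!is.numeric(n_features) || length(n_features) != 1L || n_features < 1) {
    stop("primitive_set: n_features must be a single integer >= 1")
  }
  if (length(constant_range) != 2L || constant_range[1] > constant_range[2]) {
    stop("primitive_set: constant_range must be a nonempty closed interval")
  }
  structure(list(ops = ops, n_features = as.integer(n_features),
                 constant_range = as.numeric(constant_range)),
            class = "gsgp_prims")
}

expr_op <- function(op, l, r) list(kind = "op", op = op, l = l, r = r)
expr_var <- function(i) list(kind = "var", i = as.integer(i))
expr_const <- function(v) list(kind = "const", v = as.numeric(v))
expr_logistic <- function(child) list(kind = "logis", child = child)

#' Generate a random expression tree
#'
#' Grow or full initialisation up to a maximum depth. With `wrap = TRUE`
#' the raw arithmetic tree is composed with a logistic squashing node
#' `1 / (1 + exp(-t))`, guaranteeing every output lies in `[0, 1]`; the
#' wrapper counts as one node in [node_count()]. Uses the current R random
#' number stream, so a fixed seed reproduces the tree.
#'
#' @param prims A [primitive_set()].
#' @param max_depth Maximum depth of the raw tree (a depth-0 tree is a
#'   single leaf).
#' @param method `"grow"` (terminals may appear before `max_depth`) or
#'   `"full"` (operators at every level above the deepest).
#' @param wrap Compose with the logistic squashing node so outputs lie in
#'   `[0, 1]`, as required of the random trees used by the semantic
#'   operators.
#' @param p_terminal Probability, under `"grow"`, of placing a terminal at
#'   an interior level.
#' @param p_var Probability that a terminal is a variable rather than an
#'   ephemeral constant.
#' @return An expression node (nested list).
#' @export
generate_random_tree <- function(prims, max_depth, method = c("grow", "full"),
                                 wrap = FALSE, p_terminal = 0.3, p_var = 0.8) {
  method <- match.arg(method)
  if (!is.numeric(max_depth) || length(max_depth) != 1L || max_depth < 0) {
    stop("generate_random_tree: max_depth must be a non-negative integer")
  }
  leaf <- function() {
    if (stats::runif(1) < p_var) {
      expr_var(sample.int(prims$n_features, 1L))
    } else {
      expr_const(stats::runif(1, prims$constant_range[1], prims$constant_range[2]))
    }
  }
  gen <- function(d) {
    if (d == 0 || (method == "grow" && stats::runif(1) < p_terminal)) {
      leaf()
    } else {
      op <- prims$ops[sample.int(length(prims$ops), 1L)]
      expr_op(op, gen(d - 1), gen(d - 1))
    }
  }
  t <- gen(max_depth)
  if (wrap) expr_logistic(t) else t
}

#' Count the nodes of an expression tree
#'
#' Every symbol counts as one node: operators, variables, constants and the
#' logistic squashing wrapper alike. This is the exact count used
#' throughout size accounting (so a crossover combiner adds exactly 5
#' nodes and a mutation combiner exactly 4).
#'
#' @param t An expression node.
#' @return The number of nodes, as a double (counts can exceed integer
#'   range when applied to reconstructed models).
#' @export
node_count <- function(t) {
  switch(t$kind,
    op = 1 + node_count(t$l) + node_count(t$r),
    logis = 1 + node_count(t$child),
    var = 1,
    const = 1,
    stop("node_count: malformed tree node"))
}

#' Depth of an expression tree
#'
#' A single leaf has depth 0; each operator or wrapper level adds 1.
#'
#' @param t An expression node.
#' @return Integer depth.
#' @export
tree_depth <- function(t) {
  switch(t$kind,
    op = 1L + max(tree_depth(t$l), tree_depth(t$r)),
    logis = 1L + tree_depth(t$child),
    var = 0L,
    const = 0L,
    stop("tree_depth: malformed tree node"))
}

#' Evaluate an expression tree on a data matrix
#'
#' Pointwise evaluation over the rows of `X`. Protected division returns 1
#' where the denominator's absolute value is at most 1e-6; the logistic
#' wrapper maps its argument through `1 / (1 + exp(-t))`. The result is
#' finite for finite input.
#'
#' @param t An expression node.
#' @param X Numeric matrix, one row per instance, one column per variable.
#' @return Numeric vector with one entry per row of `X`.
#' @export
eval_tree <- function(t, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  switch(t$kind,
    var = {
      if (t$i < 1L || t$i > ncol(X)) {
        stop(sprintf("eval_tree: variable x%d out of range (matrix has %d columns)",
                     t$i, ncol(X)))
      }
      X[, t$i]
    },
    const = rep.int(t$v, nrow(X)),
    logis = 1 / (1 + exp(-eval_tree(t$child, X))),
    op = {
      a <- eval_tree(t$l, X)
      b <- eval_tree(t$r, X)
      switch(t$op,
        "+" = a + b,
        "-" = a - b,
        "*" = a * b,
        "/p" = {
          out <- a / b
          out[abs(b) <= PDIV_EPS] <- 1
          out
        },
        stop(sprintf("eval_tree: unknown operator '%s'", t$op)))
    },
    stop("eval_tree: malformed tree node"))
}

#' Node budget of a depth-D tree under binary primitives
#'
#' The counting convention used by the average-size bound: with only binary
#' primitive functions, a tree of depth `depth` is budgeted `2^depth`
#' nodes. The depth-17 budget, `2^17 = 131072`, is the conventional
#' threshold separating manageable from unmanageable models (Koza's
#' standard depth limit). A strict full binary tree actually holds
#' `2^(depth+1) - 1` nodes; see [size_growth_bound()] for both conventions.
#'
#' @param depth Non-negative integer tree depth.
#' @return `2^depth` as a double.
#' @export
node_budget <- function(depth) {
  if (!is.numeric(depth) || length(depth) != 1L || is.na(depth) || depth < 0) {
    stop("node_budget: depth must be a single non-negative number")
  }
  2^depth
}

# ---- prefix-text serialisation ------------------------------------------

op_to_token <- c("+" = "+", "-" = "-", "*" = "*", "/p" = "pdiv")
token_to_op <- stats::setNames(names(op_to_token), op_to_token)

#' Serialise an expression tree to prefix text
#'
#' Parenthesised prefix form, e.g. `"(+ x1 (pdiv 0.5 x2))"`; the logistic
#' wrapper prints as `(logis ...)`. Constants are written with 17
#' significant digits so [expr_from_text()] round-trips exactly.
#'
#' @param t An expression node.
#' @return A single string.
#' @export
expr_to_text <- function(t) {
  switch(t$kind,
    var = paste0("x", t$i),
    const = formatC(t$v, digits = 17, format = "g"),
    logis = paste0("(logis ", expr_to_text(t$child), ")"),
    op = paste0("(", op_to_token[[t$op]], " ",
                expr_to_text(t$l), " ", expr_to_text(t$r), ")"),
    stop("expr_to_text: malformed tree node"))
}

#' Parse an expression tree from prefix text
#'
#' Inverse of [expr_to_text()].
#'
#' @param text A single string in parenthesised prefix form.
#' @return An expression node.
#' @export
expr_from_text <- function(text) {
  toks <- strsplit(gsub("\\)", " ) ", gsub("\\(", " ( ", text)), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else stop("expr_from_text: unexpected end of input")
  advance <- function() { tok <- peek(); pos <<- pos + 1L; tok }
  parse_node <- function() {
    tok <- advance()
    if (tok == "(") {
      head <- advance()
      node <- if (head == "logis") {
        expr_logistic(parse_node())
      } else if (head %in% names(token_to_op)) {
        l <- parse_node()
        r <- parse_node()
        expr_op(token_to_op[[head]], l, r)
      } else {
        stop(sprintf("expr_from_text: unknown operator '%s'", head))
      }
      if (advance() != ")") stop("expr_from_text: expected ')'")
      node
    } else if (grepl("^x[0-9]+$", tok)) {
      expr_var(as.integer(sub("^x", "", tok)))
    } else {
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) stop(sprintf("expr_from_text: cannot parse token '%s'", tok))
      expr_const(v)
    }
  }
  out <- parse_node()
  if (pos <= length(toks)) stop("expr_from_text: trailing tokens after expression")
  out
}
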