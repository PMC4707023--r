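# Minimal non-negative arbitrary-precision integers.
#
# GSGP offspring sizes grow exponentially with the generation count and
# overflow double precision within a few hundred generations, while the size
# recurrence only ever needs addition, multiplication by a small integer and
# comparison.  Limbs are stored little-endian in base 1e9, each limb a double
# in [0, 1e9), so limb sums stay exactly representable.

BIG_BASE <- 1e9

new_bigint <- function(limbs) {
  structure(list(limbs = limbs), class = "bigint")
}

#' Arbitrary-precision non-negative integer
#'
#' Exact integer arithmetic for program-size accounting. Offspring node
#' counts under geometric semantic operators grow exponentially and exceed
#' the 2^53 integer range of doubles long before a run ends, so sizes are
#' carried as arbitrary-precision integers. Supports `+`, `*` (by an
#' ordinary numeric scalar), comparison operators, `format()`,
#' `as.character()` and `as.numeric()` (the latter a possibly-inexact
#' double, `Inf` beyond about 1e308).
#'
#' @param x A single non-negative whole number (below 2^53), a decimal
#'   string, or an existing `bigint` (returned unchanged).
#' @return An object of class `bigint`.
#' @examples
#' big_int(7) + big_int(5)
#' big_int("123456789012345678901234567890") * 2
#' big_int(2)^NULL # not supported; only +, *, comparisons
#' @export
big_int <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x)) {
      stop("big_int: string must be a single non-negative decimal integer")
    }
    digs <- x
    limbs <- numeric(0)
    while (nchar(digs) > 0L) {
      take <- max(1L, nchar(digs) - 8L)
      limbs <- c(limbs, as.numeric(substr(digs, take, nchar(digs))))
      digs <- substr(digs, 1L, take - 1L)
    }
    return(new_bigint(big_trim(limbs)))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x) || x >= 2^53) {
    stop("big_int: need a single non-negative whole number below 2^53")
  }
  x <- as.numeric(x)
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  new_bigint(limbs)
}

big_trim <- function(l) {
  n <- length(l)
  while (n > 1L && l[n] == 0) n <- n - 1L
  l[seq_len(n)]
}

# carry-propagate limbs that may exceed the base (each < 2^53)
big_norm <- function(l) {
  i <- 1L
  while (i <= length(l)) {
    if (l[i] >= BIG_BASE) {
      carry <- floor(l[i] / BIG_BASE)
      l[i] <- l[i] - carry * BIG_BASE
      if (i == length(l)) l <- c(l, 0)
      l[i + 1L] <- l[i + 1L] + carry
    }
    i <- i + 1L
  }
  new_bigint(big_trim(l))
}

big_add <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  n <- max(length(la), length(lb))
  la <- c(la, numeric(n - length(la)))
  lb <- c(lb, numeric(n - length(lb)))
  big_norm(la + lb)
}

big_mul_small <- function(a, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k != floor(k) || k >= BIG_BASE) {
    stop("bigint: can only multiply by a non-negative integer below 1e9")
  }
  if (k == 0) return(big_int(0))
  big_norm(a$limbs * k)
}

# -1, 0, 1 as a < b, a == b, a > b
big_cmp <- function(a, b) {
  la <- a$limbs; lb <- b$limbs
  if (length(la) != length(lb)) {
    return(if (length(la) < length(lb)) -1L else 1L)
  }
  for (i in rev(seq_along(la))) {
    if (la[i] != lb[i]) return(if (la[i] < lb[i]) -1L else 1L)
  }
  0L
}

#' @export
Ops.bigint <- function(e1, e2) {
  if (.Generic %in% c("+", "==", "!=", "<", "<=", ">", ">=")) {
    a <- big_int(e1)
    b <- big_int(e2)
    if (.Generic == "+") return(big_add(a, b))
    cmp <- big_cmp(a, b)
    return(switch(.Generic,
      "==" = cmp == 0L, "!=" = cmp != 0L,
      "<" = cmp < 0L, "<=" = cmp <= 0L,
      ">" = cmp > 0L, ">=" = cmp >= 0L))
  }
  if (.Generic == "*") {
    if (inherits(e1, "bigint") && is.numeric(e2)) return(big_mul_small(e1, e2))
    if (inherits(e2, "bigint") && is.numeric(e1)) return(big_mul_small(e2, e1))
    stop("bigint: '*' needs one bigint and one small numeric scalar")
  }
  stop(sprintf("bigint: operation '%s' not supported", .Generic))
}

#' @export
format.bigint <- function(x, ...) {
  l <- rev(x$limbs)
  paste0(format(l[1], scientific = FALSE),
         paste(sprintf("%09.0f", l[-1]), collapse = ""))
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.numeric.bigint <- function(x, ...) {
  sum(x$limbs * BIG_BASE^(seq_along(x$limbs) - 1))
}

#' @export
as.double.bigint <- function(x, ...) as.numeric.bigint(x)

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint>", format(x), "\n")
  invisible(x)
}
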