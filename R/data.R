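# Tabular regression datasets: CSV reading/writing (last column is the
# target), seeded 70/30 splitting, and a synthetic generator emulating the
# shapes of the QSAR / engineering / biomedical study benchmarks so every
# stage is testable without external downloads.

#' Construct a regression dataset
#'
#' A dataset is a feature matrix `X` (one row per instance) plus a target
#' vector `y`; in tabular form the target is always the last column.
#'
#' @param X Numeric matrix or data frame of features.
#' @param y Numeric target vector, finite, one value per row of `X`.
#' @param name Label for the dataset.
#' @param feature_names Optional feature names; defaults to `x1, x2, ...`.
#' @return An object of class `gp_dataset`.
#' @export
gp_dataset <- function(X, y, name = "dataset", feature_names = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("gp_dataset: X and y disagree on instance count")
  if (nrow(X) < 2L) stop("gp_dataset: need at least 2 instances")
  if (anyNA(X) || anyNA(y)) stop("gp_dataset: missing values are not allowed")
  if (any(!is.finite(y))) stop("gp_dataset: target values must be finite")
  if (is.null(feature_names)) feature_names <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- feature_names
  structure(list(X = X, y = y, name = name, feature_names = feature_names),
            class = "gp_dataset")
}

dataset_X <- function(ds) {
  if (inherits(ds, "gp_dataset")) ds$X else as.matrix(ds$X)
}

dataset_y <- function(ds) {
  if (inherits(ds, "gp_dataset")) ds$y else as.numeric(ds$y)
}

#' @export
print.gp_dataset <- function(x, ...) {
  cat(sprintf("<gp dataset '%s'> %d instances x %d features + target\n",
              x$name, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' @export
dim.gp_dataset <- function(x) dim(x$X)

#' @importFrom tibble as_tibble
#' @method as_tibble gp_dataset
#' @export
as_tibble.gp_dataset <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$X))
  out$target <- x$y
  out
}

#' Read a regression dataset from CSV
#'
#' Rectangular numeric CSV; every column but the last is a feature, the
#' last column holds the known target values. Ragged rows and non-numeric
#' cells raise an error naming the offending row and column.
#'
#' @param path Path to the CSV file.
#' @param has_header Whether the first row holds column names.
#' @param name Dataset label; defaults to the file name.
#' @return A [gp_dataset()].
#' @export
read_dataset_csv <- function(path, has_header = FALSE, name = NULL) {
  if (!file.exists(path)) stop(sprintf("read_dataset_csv: no such file '%s'", path))
  nf <- utils::count.fields(path, sep = ",")
  if (length(nf) == 0L) stop("read_dataset_csv: empty file")
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("read_dataset_csv: ragged row %d has %d fields, expected %d",
                 bad, nf[bad], nf[1]))
  }
  df <- utils::read.csv(path, header = has_header, colClasses = "character")
  if (ncol(df) < 2L) stop("read_dataset_csv: need at least one feature column plus the target")
  num <- vapply(df, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(df)))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(df)))
  if (anyNA(num)) {
    pos <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("read_dataset_csv: non-numeric or missing cell at row %d, column %d ('%s')",
                 pos[1], pos[2], as.character(df[pos[1], pos[2]])))
  }
  p <- ncol(num) - 1L
  feature_names <- if (has_header) names(df)[seq_len(p)] else paste0("x", seq_len(p))
  gp_dataset(num[, seq_len(p), drop = FALSE], num[, p + 1L],
             name = if (is.null(name)) basename(path) else name,
             feature_names = feature_names)
}

#' Write a regression dataset to CSV
#'
#' Deterministic writer: values are printed with 17 significant digits so
#' a read/write round trip reproduces them exactly; the target is the last
#' column.
#'
#' @param ds A [gp_dataset()].
#' @param path Output path.
#' @param header Write a header row (feature names plus `target`).
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(ds, path, header = FALSE) {
  m <- cbind(ds$X, ds$y)
  txt <- apply(m, 1L, function(row) {
    paste(formatC(row, digits = 17, format = "g"), collapse = ",")
  })
  if (header) txt <- c(paste(c(ds$feature_names, "target"), collapse = ","), txt)
  writeLines(txt, path)
  invisible(path)
}

#' Split a dataset into train and test partitions
#'
#' Draws `round(train_fraction * n)` instances uniformly without
#' replacement for the training set; the rest form the test set. The
#' partition is disjoint and exhaustive and the same seed reproduces the
#' same split. The study protocol uses a fresh 70/30 split per run.
#'
#' @param ds A [gp_dataset()].
#' @param train_fraction Fraction of instances assigned to training,
#'   strictly between 0 and 1 (default 0.7).
#' @param seed Integer seed for the split.
#' @return List with elements `train` and `test`, both `gp_dataset`s.
#' @export
split_dataset <- function(ds, train_fraction = 0.7, seed = 1) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("split_dataset: train_fraction must lie strictly between 0 and 1")
  }
  n <- nrow(ds$X)
  n_train <- round(train_fraction * n)
  if (n_train < 1L || n_train >= n) {
    stop("split_dataset: split would leave an empty partition")
  }
  set.seed(seed)
  idx <- sort(sample.int(n, n_train))
  rest <- setdiff(seq_len(n), idx)
  list(train = gp_dataset(ds$X[idx, , drop = FALSE], ds$y[idx],
                          name = paste0(ds$name, "/train"),
                          feature_names = ds$feature_names),
       test = gp_dataset(ds$X[rest, , drop = FALSE], ds$y[rest],
                         name = paste0(ds$name, "/test"),
                         feature_names = ds$feature_names))
}

# Shapes follow the five study benchmarks; targets are nonlinear
# multi-variable expressions inside the GP search space, rescaled to the
# endpoint's natural range, plus Gaussian noise (~5-10% of the signal sd).
SYNTH_PRESETS <- list(
  bioavailability = list(n = 260, p = 241, offset = 50, scale = 25, noise_sd = 5,
                         truth = "(+ (* x1 x2) (- x3 (* x4 x4)))"),
  ppb = list(n = 131, p = 626, offset = 50, scale = 30, noise_sd = 5,
             truth = "(+ (* x1 x2) (- (* x3 x3) x4))"),
  ld50 = list(n = 234, p = 626, offset = 1000, scale = 600, noise_sd = 60,
              truth = "(+ (- x1 (* x2 x3)) (* x4 x4))"),
  concrete = list(n = 1030, p = 8, offset = 40, scale = 15, noise_sd = 3,
                  truth = "(+ (* x1 x2) (- x3 (* x4 x5)))"),
  parkinson = list(n = 6000, p = 19, offset = 25, scale = 10, noise_sd = 2,
                   truth = "(+ (* x1 x3) (- (* x2 x2) x4))"))

#' Available synthetic presets
#'
#' One preset per study benchmark shape: human oral bioavailability-like
#' (260 x 241), plasma protein binding-like (131 x 626), median lethal
#' dose-like (234 x 626), concrete strength-like (1030 x 8) and
#' Parkinson symptom score-like (6000 x 19).
#'
#' @return A tibble describing each preset.
#' @export
synth_presets <- function() {
  tibble::tibble(preset = names(SYNTH_PRESETS),
                 n_instances = vapply(SYNTH_PRESETS, function(p) p$n, 1),
                 n_features = vapply(SYNTH_PRESETS, function(p) p$p, 1),
                 offset = vapply(SYNTH_PRESETS, function(p) p$offset, 1),
                 scale = vapply(SYNTH_PRESETS, function(p) p$scale, 1),
                 noise_sd = vapply(SYNTH_PRESETS, function(p) p$noise_sd, 1),
                 ground_truth = vapply(SYNTH_PRESETS, function(p) p$truth, ""))
}

resolve_preset <- function(preset) {
  key <- sub("-like$", "", tolower(preset))
  if (!key %in% names(SYNTH_PRESETS)) {
    stop(sprintf("synth_dataset: unknown preset '%s' (see synth_presets())", preset))
  }
  SYNTH_PRESETS[[key]]
}

#' Generate a synthetic regression dataset
#'
#' Features are drawn uniformly from a box (default `[-1, 1]` per
#' dimension) and the target is
#' `y = offset + scale * truth(X) + Gaussian(0, noise_sd)`, where the
#' ground truth is an expression tree (or its prefix-text form) over the
#' features. Presets emulate the shapes and target scales of the study
#' benchmarks; any preset field can be overridden. With `noise_sd = 0` and
#' the ground truth inside the GP search space a perfect model has
#' training RMSE 0.
#'
#' @param preset Optional preset name (see [synth_presets()]; a `-like`
#'   suffix is accepted).
#' @param n_instances,n_features Shape of the dataset.
#' @param ground_truth Expression node or prefix text; must reference at
#'   most `n_features` variables.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (>= 0).
#' @param seed Integer seed; the same seed reproduces the dataset.
#' @param box Length-2 numeric, the per-feature sampling interval.
#' @param offset,scale Affine rescaling of the ground-truth signal.
#' @param name Dataset label.
#' @return A [gp_dataset()] with the ground-truth expression attached as
#'   attribute `"ground_truth"`.
#' @export
synth_dataset <- function(preset = NULL, n_instances = NULL, n_features = NULL,
                          ground_truth = NULL, noise_sd = NULL, seed = 1,
                          box = c(-1, 1), offset = NULL, scale = NULL,
                          name = NULL) {
  defaults <- if (!is.null(preset)) resolve_preset(preset)
              else list(n = 200, p = 5, offset = 0, scale = 1, noise_sd = 0.1,
                        truth = "(+ (* x1 x2) x3)")
  n <- if (is.null(n_instances)) defaults$n else n_instances
  p <- if (is.null(n_features)) defaults$p else n_features
  offset <- if (is.null(offset)) defaults$offset else offset
  scale <- if (is.null(scale)) defaults$scale else scale
  noise_sd <- if (is.null(noise_sd)) defaults$noise_sd else noise_sd
  truth <- if (is.null(ground_truth)) defaults$truth else ground_truth
  if (is.character(truth)) truth <- expr_from_text(truth)
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("synth_dataset: noise_sd must be non-negative")
  }
  max_var <- function(t) {
    switch(t$kind,
      var = t$i,
      op = max(max_var(t$l), max_var(t$r)),
      logis = max_var(t$child),
      0L)
  }
  if (max_var(truth) > p) {
    stop("synth_dataset: ground truth references more variables than n_features")
  }
  set.seed(seed)
  X <- matrix(stats::runif(n * p, box[1], box[2]), nrow = n, ncol = p)
  y <- offset + scale * eval_tree(truth, X) + stats::rnorm(n, 0, noise_sd)
  ds <- gp_dataset(X, y,
                   name = if (is.null(name)) {
                     if (is.null(preset)) "synthetic" else paste0(preset, "-like")
                   } else name)
  attr(ds, "ground_truth") <- truth
  ds
}
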