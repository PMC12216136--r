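#' Construct a feature table
#'
#' The central tabular container: a numeric patient-by-feature matrix with
#' column names, a two-level label factor, and the name of the positive
#' (disease-presence) class.
#'
#' @param x Numeric matrix, rows = patients, columns = named features.
#' @param y Label vector (coerced to factor) of length `nrow(x)`.
#' @param positive Label value treated as the positive class.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, y, positive = "presence") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.factor(y)
  if (length(y) != nrow(x)) stop("label length must equal nrow(x)")
  if (nlevels(y) > 2) stop("feature_table is strictly two-class")
  if (!positive %in% levels(y)) stop("positive class '", positive, "' not among labels")
  structure(list(x = x, y = y, positive = as.character(positive)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$x), " x ", ncol(x$x), " features; classes: ",
      paste(sprintf("%s=%d", levels(x$y), tabulate(x$y, nlevels(x$y))), collapse = ", "),
      " (positive: ", x$positive, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

# Reference layout of the 13 clinical predictors the generator emulates:
# continuous vitals plus small-alphabet integer-coded factors.
hd_feature_layout <- function() {
  list(
    names = c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
              "thalach", "exang", "oldpeak", "slope", "ca", "thal"),
    continuous = c(age = 1L, trestbps = 4L, chol = 5L, thalach = 8L, oldpeak = 10L),
    # location/scale roughly matching published summaries of the table
    cont_mu = c(age = 54, trestbps = 131, chol = 246, thalach = 150, oldpeak = 1.05),
    cont_sd = c(age = 9, trestbps = 17, chol = 51, thalach = 23, oldpeak = 1.1),
    levels = list(sex = 0:1, cp = 1:4, fbs = 0:1, restecg = 0:2, exang = 0:1,
                  slope = 1:3, ca = 0:3, thal = c(3L, 6L, 7L))
  )
}

#' Specification for the synthetic heart-disease-like generator
#'
#' Describes the shape of the emulated table: 303 rows split 165 presence /
#' 138 absence over 13 mixed-type predictors, with a planted informative
#' subset whose (standardized) values drive the label through a logistic
#' score. Defaults plant four strong clinically-plausible predictors
#' (cp, thalach, exang, oldpeak).
#'
#' @param n_rows Total number of patients.
#' @param n_presence,n_absence Exact class counts; must sum to `n_rows`.
#' @param n_features Number of candidate predictors (13 = the named layout).
#' @param informative_idx Integer indices (1-based) of the planted
#'   informative features.
#' @param effect_sizes Log-odds weights on the standardized informative
#'   columns, same length as `informative_idx`.
#' @param noise_sd Standard deviation of Gaussian noise added to the score.
#' @param categorical_idx Indices generated as small-alphabet integer codes.
#' @param seed Integer seed; regeneration is bit-identical.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_rows = 303L, n_presence = 165L, n_absence = 138L,
                       n_features = 13L,
                       informative_idx = c(3L, 8L, 9L, 10L),
                       effect_sizes = c(2, -2, 2, 2),
                       noise_sd = 1, categorical_idx = NULL, seed = 1L) {
  if (n_presence + n_absence != n_rows)
    stop("n_presence + n_absence must equal n_rows")
  if (any(c(n_rows, n_presence, n_absence, n_features) < 0))
    stop("counts must be nonnegative")
  if (length(effect_sizes) != length(informative_idx))
    stop("effect_sizes must match informative_idx in length")
  if (length(informative_idx) && (min(informative_idx) < 1 || max(informative_idx) > n_features))
    stop("informative_idx out of range")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(categorical_idx)) {
    lay <- hd_feature_layout()
    categorical_idx <- if (n_features == 13L)
      setdiff(seq_len(13L), unname(lay$continuous)) else integer(0)
  }
  structure(list(n_rows = as.integer(n_rows), n_presence = as.integer(n_presence),
                 n_absence = as.integer(n_absence), n_features = as.integer(n_features),
                 informative_idx = as.integer(informative_idx),
                 effect_sizes = as.numeric(effect_sizes),
                 noise_sd = noise_sd, categorical_idx = as.integer(categorical_idx),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# One column of raw feature values. Each column's stream is derived from the
# feature NAME, not its position, so reordering columns reorders values
# without changing them (permutation equivariance of the planted labels).
generate_feature_column <- function(name, n, spec) {
  lay <- hd_feature_layout()
  with_seed(derive_seed(spec$seed, paste0("feature:", name)), {
    if (name %in% names(lay$continuous) && match(name, lay$names) %in%
        setdiff(seq_along(lay$names), spec$categorical_idx)) {
      v <- rnorm(n, lay$cont_mu[[name]], lay$cont_sd[[name]])
      if (name == "oldpeak") v <- pmax(v, 0)
      v
    } else if (!is.null(lay$levels[[name]])) {
      as.numeric(sample(lay$levels[[name]], n, replace = TRUE))
    } else {
      rnorm(n)
    }
  })
}

#' Generate a heart-disease-like synthetic dataset
#'
#' Draws mixed continuous/categorical predictor columns, computes a logistic
#' score over the standardized planted informative columns plus seeded
#' Gaussian noise, and assigns the label by *ranking* the scores: the
#' `n_presence` highest-scoring rows become the presence class. Ranking
#' (rather than Bernoulli draws) makes the class counts exact; ties are
#' broken by row index.
#'
#' @param spec A [synth_spec()].
#' @return An object of class `synth_dataset` with elements `table`
#'   (a [feature_table()] whose labels are `presence`/`absence`),
#'   `truth_mask` (logical vector marking the planted informative columns),
#'   `score` (the latent logistic score) and `spec`.
#' @export
generate_hd_like <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_rows
  d <- spec$n_features
  lay <- hd_feature_layout()
  fnames <- if (d == 13L) lay$names else paste0("f", seq_len(d))
  X <- matrix(0, n, d, dimnames = list(NULL, fnames))
  for (j in seq_len(d)) {
    X[, j] <- if (fnames[j] %in% lay$names && d == 13L)
      generate_feature_column(fnames[j], n, spec)
    else with_seed(derive_seed(spec$seed, paste0("feature:", fnames[j])), rnorm(n))
  }

  score <- rep(0, n)
  for (k in seq_along(spec$informative_idx)) {
    col <- X[, spec$informative_idx[k]]
    s <- sd(col)
    z <- if (s > 0) (col - mean(col)) / s else col * 0
    score <- score + spec$effect_sizes[k] * z
  }
  if (spec$noise_sd > 0)
    score <- score + with_seed(derive_seed(spec$seed, "noise"),
                               rnorm(n, 0, spec$noise_sd))

  # top-n_presence scores -> presence; ties broken by row index
  ord <- order(-score, seq_len(n))
  y <- rep("absence", n)
  y[ord[seq_len(spec$n_presence)]] <- "presence"
  y <- factor(y, levels = c("absence", "presence"))

  mask <- rep(FALSE, d)
  mask[spec$informative_idx] <- TRUE
  names(mask) <- fnames
  structure(list(table = feature_table(X, y, positive = "presence"),
                 truth_mask = mask, score = score, spec = spec),
            class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset> planted informative:",
      paste(names(x$truth_mask)[x$truth_mask], collapse = ", "), "\n")
  print(x$table)
  invisible(x)
}

#' Generate labeled 1-D sequence fixtures
#'
#' Two classes of Gaussian sequences whose per-timestep means differ by
#' `separation` (class `neg` centred at 0, class `pos` at `separation`,
#' unit variance). `separation = 0` makes the classes indistinguishable.
#' Used as unit fixtures for the recurrent classifier.
#'
#' @param n Total number of sequences (split as evenly as possible).
#' @param length Sequence length (>= 1).
#' @param separation Mean difference between the classes.
#' @param seed Integer seed.
#' @return List with `x` (n x length matrix) and `y` (factor neg/pos).
#' @export
generate_sequences <- function(n, length, separation, seed = 1L) {
  stopifnot(length >= 1, n >= 2)
  n_pos <- n %/% 2L
  n_neg <- n - n_pos
  with_seed(seed, {
    xn <- matrix(rnorm(n_neg * length, 0, 1), n_neg, length)
    xp <- matrix(rnorm(n_pos * length, separation, 1), n_pos, length)
    list(x = rbind(xn, xp),
         y = factor(rep(c("neg", "pos"), c(n_neg, n_pos)), levels = c("neg", "pos")))
  })
}

#' Benchmark objective suite for the optimizers
#'
#' Standard continuous test functions with their boxes and known global
#' minima: sphere, Rosenbrock and Rastrigin.
#'
#' @return Named list; each entry has `fn`, `lower`, `upper` (scalars,
#'   replicated per dimension), `minimum` (function of dim) and `min_value`.
#' @export
benchmark_suite <- function() {
  list(
    sphere = list(fn = function(x) sum(x^2),
                  lower = -5.12, upper = 5.12,
                  minimum = function(d) rep(0, d), min_value = 0),
    rosenbrock = list(fn = function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2),
                      lower = -5, upper = 10,
                      minimum = function(d) rep(1, d), min_value = 0),
    rastrigin = list(fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
                     lower = -5.12, upper = 5.12,
                     minimum = function(d) rep(0, d), min_value = 0)
  )
}

#' Write / read a feature table as CSV
#'
#' Plain CSV with a header row; the label column is named `num` and coded
#' 1 = positive class, 0 = other, matching the conventional encoding of the
#' emulated dataset.
#'
#' @param table A [feature_table()].
#' @param path File path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- as.data.frame(table$x)
  df$num <- as.integer(table$y == table$positive)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param positive_label Value in the `num` column mapped to the positive class.
#' @export
read_feature_table <- function(path, positive_label = 1L) {
  df <- read.csv(path, check.names = FALSE)
  if (!"num" %in% names(df)) stop("label column 'num' not found in ", path)
  y <- ifelse(df$num == positive_label, "presence", "absence")
  x <- as.matrix(df[setdiff(names(df), "num")])
  feature_table(x, factor(y, levels = c("absence", "presence")), positive = "presence")
}
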