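#' Configuration for the spotted hyena optimizer
#'
#' @param pop_size Number of hyenas (>= 2).
#' @param max_iter Iteration budget.
#' @param epsilon Adaptive-stopping threshold: the run ends early once the
#'   best value improves by less than `epsilon` for `patience` consecutive
#'   iterations.
#' @param patience Number of consecutive below-threshold iterations that
#'   triggers the stop.
#' @param lower,upper Per-dimension box bounds (equal-length numeric
#'   vectors; the problem dimension is their length).
#' @param seed Integer seed (NULL = use the ambient RNG stream).
#' @return Object of class `shoa_config`.
#' @export
shoa_config <- function(pop_size = 30L, max_iter = 200L, epsilon = 1e-9,
                        patience = 50L, lower, upper, seed = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) stop("lower/upper length mismatch")
  if (any(lower >= upper)) stop("need lower < upper in every dimension")
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
                 epsilon = epsilon, patience = as.integer(patience),
                 lower = lower, upper = upper, seed = seed),
            class = "shoa_config")
}

#' Control parameters for one hyena update
#'
#' The schedule value `l` decreases linearly from 5 (at `iter = 0`) to 0
#' (at `iter = max_iter`); the coefficient vectors are `Y = 2 r1` (entries
#' in \[0, 2\]) and `Z = 2 l r2 - l` (entries in \[-l, l\]), with `r1`,
#' `r2` fresh uniform draws.
#'
#' @param iter Current iteration in `0..max_iter`.
#' @param max_iter Iteration budget (> 0).
#' @param dim Problem dimension (number of entries drawn for Y and Z).
#' @return List with `l`, `Y`, `Z`, `r1`, `r2`.
#' @export
control_params <- function(iter, max_iter, dim = 1L) {
  if (max_iter <= 0) stop("max_iter must be positive")
  if (iter < 0 || iter > max_iter) stop("iter must lie in 0..max_iter")
  l <- 5 - iter * (5 / max_iter)
  r1 <- runif(dim)
  r2 <- runif(dim)
  list(l = l, Y = 2 * r1, Z = 2 * l * r2 - l, r1 = r1, r2 = r2)
}

#' Encircling update toward a reference point
#'
#' Distance `R = |Y * ref - position|` (elementwise), new position
#' `ref - Z * R`, clamped to the box.
#'
#' @param position Current position.
#' @param reference Point being encircled (the prey, or a random point
#'   during exploration).
#' @param params A [control_params()] draw.
#' @param lower,upper Box bounds.
#' @return Updated position.
#' @export
encircle_update <- function(position, reference, params, lower, upper) {
  R <- abs(params$Y * reference - position)
  clamp(reference - params$Z * R, lower, upper)
}

# One full SHOA iteration. RNG draw order (relied on by the transcription
# oracle in the tests):
#   1. G ~ U(0.5, 1)                       (cluster radius scalar)
#   2. per member i = 1..pop: r1, r2       (control_params, dim draws each)
#   3. per cluster member, in ascending index order, whose mean |Z| exceeds
#      1: a random reference point (dim draws)
# Cluster membership: the N_h best members, where N_h = #{fitness within
# G * |f_best| of the best}, floored at 1. Cluster members encircle the
# best-so-far prey (or a random reference when exploring); every remaining
# member moves to the centroid of the updated cluster.
shoa_iterate <- function(positions, fitness, prey, iter, config) {
  dim <- length(config$lower)
  pop <- nrow(positions)
  G <- runif(1, 0.5, 1)
  f_best <- min(fitness)
  n_h <- max(1L, sum(fitness <= f_best + G * abs(f_best)))
  cluster <- order(fitness, seq_len(pop))[seq_len(n_h)]
  params <- lapply(seq_len(pop), function(i)
    control_params(iter, config$max_iter, dim))
  new_pos <- positions
  for (i in sort(cluster)) {
    ref <- if (mean(abs(params[[i]]$Z)) > 1)
      config$lower + runif(dim) * (config$upper - config$lower)
    else prey
    new_pos[i, ] <- encircle_update(positions[i, ], ref, params[[i]],
                                    config$lower, config$upper)
  }
  centroid <- colMeans(new_pos[sort(cluster), , drop = FALSE])
  for (i in setdiff(seq_len(pop), cluster))
    new_pos[i, ] <- clamp(centroid, config$lower, config$upper)
  new_pos
}

#' Spotted hyena optimization of a continuous objective
#'
#' Population search with encircling/hunting/attacking updates, a linearly
#' decaying control schedule, elitism (the best-so-far position replaces the
#' current worst member each iteration), and adaptive stopping: the run
#' terminates at `max_iter` or once the best value has improved by less than
#' `epsilon` for `patience` consecutive iterations.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param config A [shoa_config()].
#' @param on_iteration Optional callback `function(iter, best_value)` run
#'   after each iteration (used for tracing).
#' @return List with `par` (best position), `value`, `history` (best value
#'   per iteration, non-increasing) and `iterations`.
#' @export
shoa_minimize <- function(objective, config, on_iteration = NULL) {
  with_seed(config$seed, {
    dim <- length(config$lower)
    pop <- config$pop_size
    positions <- t(matrix(vapply(seq_len(pop), function(i)
      config$lower + runif(dim) * (config$upper - config$lower), numeric(dim)),
      nrow = dim))
    fitness <- apply(positions, 1, objective)
    if (any(!is.finite(fitness))) stop("objective returned a non-finite value")
    b <- which.min(fitness)
    prey <- positions[b, ]
    prey_value <- fitness[b]
    history <- numeric(0)
    streak <- 0L
    iterations <- 0L
    for (j in seq_len(config$max_iter)) {
      positions <- shoa_iterate(positions, fitness, prey, j - 1L, config)
      fitness <- apply(positions, 1, objective)
      if (any(!is.finite(fitness))) stop("objective returned a non-finite value")
      # elitism: the best-so-far prey replaces the current worst member
      w <- which.max(fitness)
      if (fitness[w] > prey_value) {
        positions[w, ] <- prey
        fitness[w] <- prey_value
      }
      prev_value <- prey_value
      b <- which.min(fitness)
      if (fitness[b] < prey_value) {
        prey <- positions[b, ]
        prey_value <- fitness[b]
      }
      history <- c(history, prey_value)
      iterations <- j
      if (!is.null(on_iteration)) on_iteration(j, prey_value)
      if (j > 1 && abs(prey_value - prev_value) < config$epsilon) {
        streak <- streak + 1L
        if (streak >= config$patience) break
      } else streak <- 0L
    }
    list(par = prey, value = prey_value, history = history,
         iterations = iterations)
  })
}

#' Binarize a continuous position into a feature mask
#'
#' Stochastic sigmoid transfer: bit `j` is set when
#' `sigmoid(position_j) > u_j` with `u_j ~ U(0, 1)`. An all-zero mask is
#' repaired by setting the bit with the largest sigmoid value, so a mask is
#' never empty.
#'
#' @param position Real vector.
#' @return Logical vector of the same length.
#' @export
binarize <- function(position) {
  p <- sigmoid(position)
  bits <- p > runif(length(position))
  if (!any(bits)) bits[which.max(p)] <- TRUE
  bits
}

#' Feature-selection fitness specification
#'
#' The wrapper fitness blends the classification error of the masked
#' feature set with a subset-size term: the default `parsimony` form is
#' `alpha * E + beta * |R|/|N|` (minimized, smaller subsets preferred); the
#' `as_printed` form `alpha * E + beta * (1 - |R|/|N|)` is retained behind
#' this switch (under minimization it rewards larger subsets).
#'
#' @param error_estimator Function mapping a logical mask to a
#'   classification error in \[0, 1\].
#' @param n_total Total number of candidate features |N|.
#' @param alpha,beta Nonnegative weights summing to 1 (defaults 0.99/0.01:
#'   error dominates, parsimony breaks ties).
#' @param form `"parsimony"` (default) or `"as_printed"`.
#' @return Object of class `fs_fitness_spec`.
#' @export
fs_fitness_spec <- function(error_estimator, n_total, alpha = 0.99,
                            beta = 0.01, form = c("parsimony", "as_printed")) {
  form <- match.arg(form)
  if (abs(alpha + beta - 1) > 1e-12) stop("alpha + beta must equal 1")
  if (alpha < 0 || beta < 0) stop("weights must be nonnegative")
  structure(list(error_estimator = error_estimator, n_total = as.integer(n_total),
                 alpha = alpha, beta = beta, form = form),
            class = "fs_fitness_spec")
}

#' Evaluate the feature-selection fitness of a mask
#'
#' @param mask Logical vector with at least one bit set.
#' @param spec A [fs_fitness_spec()].
#' @return Scalar fitness (lower is better).
#' @export
fs_fitness <- function(mask, spec) {
  stopifnot(inherits(spec, "fs_fitness_spec"))
  if (!any(mask)) stop("empty feature mask")
  E <- spec$error_estimator(mask)
  ratio <- sum(mask) / spec$n_total
  if (spec$form == "parsimony") spec$alpha * E + spec$beta * ratio
  else spec$alpha * E + spec$beta * (1 - ratio)
}

#' k-nearest-neighbour cross-validated error
#'
#' Cheap wrapper-learner error estimate: Euclidean k-NN under stratified
#' cross-validation. Vote ties are broken by the nearest neighbour's class;
#' distance ties by row index. Deterministic for a fixed `seed`.
#'
#' @param x Numeric matrix of candidate features.
#' @param y Two-class label vector.
#' @param k Number of neighbours.
#' @param folds Number of stratified CV folds.
#' @param seed Seed for the fold assignment.
#' @param repeats Number of CV repetitions (fresh fold assignments) whose
#'   error rates are averaged; repeats damp the variance of the wrapper
#'   signal on small training splits.
#' @return Misclassification rate in \[0, 1\].
#' @export
knn_cv_error <- function(x, y, k = 5L, folds = 5L, seed = 1L, repeats = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x)
  errs <- vapply(seq_len(repeats), function(rep) {
    fold_id <- integer(n)
    with_seed(seed + rep - 1L, {
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold_id[idx] <- rep_len(seq_len(folds), length(idx))
      }
    })
    wrong <- 0L
    for (f in seq_len(folds)) {
      te <- which(fold_id == f)
      tr <- which(fold_id != f)
      if (!length(te) || !length(tr)) next
      d2 <- outer(rowSums(x[te, , drop = FALSE]^2),
                  rowSums(x[tr, , drop = FALSE]^2), "+") -
        2 * x[te, , drop = FALSE] %*% t(x[tr, , drop = FALSE])
      kk <- min(k, length(tr))
      for (ii in seq_along(te)) {
        nb <- order(d2[ii, ], seq_along(tr))[seq_len(kk)]
        votes <- table(y[tr[nb]])
        top <- names(votes)[votes == max(votes)]
        pred <- if (length(top) == 1) top else as.character(y[tr[nb[1]]])
        if (pred != as.character(y[te[ii]])) wrong <- wrong + 1L
      }
    }
    wrong / n
  }, 0)
  mean(errs)
}

#' Wrapper feature selection with the spotted hyena optimizer
#'
#' Searches continuous positions over the candidate features, binarizes each
#' position with the stochastic sigmoid transfer, and scores the resulting
#' mask with [fs_fitness()]. The label column is never a candidate. Returns
#' the best mask encountered anywhere in the search.
#'
#' @param table A [feature_table()].
#' @param config A [shoa_config()] whose bounds are recycled to the feature
#'   count (default box \[-4, 4\] per feature).
#' @param spec Optional [fs_fitness_spec()]; by default a 5-NN stratified
#'   5-fold CV error estimator on `table` with alpha = 0.99.
#' @return List with `mask` (named logical), `fitness`, `error` (E of the
#'   best mask) and `trace` (data frame iteration/best_fitness/n_selected).
#' @export
select_features <- function(table, config = NULL, spec = NULL) {
  stopifnot(inherits(table, "feature_table"))
  d <- ncol(table$x)
  if (d < 2) stop("need at least 2 candidate features")
  if (is.null(config))
    config <- shoa_config(pop_size = 10L, max_iter = 30L, patience = 10L,
                          lower = rep(-4, d), upper = rep(4, d), seed = 1L)
  if (length(config$lower) != d)
    config[c("lower", "upper")] <- list(rep_len(config$lower, d), rep_len(config$upper, d))
  if (is.null(spec)) {
    cv_seed <- derive_seed(config$seed %||% 0L, "fs-cv")
    spec <- fs_fitness_spec(
      error_estimator = function(mask)
        knn_cv_error(table$x[, mask, drop = FALSE], table$y, seed = cv_seed,
                     repeats = 2L),
      n_total = d)
  }
  state <- new.env(parent = emptyenv())
  state$best <- Inf; state$mask <- NULL; state$error <- NA_real_
  state$trace <- list()
  objective <- function(pos) {
    mask <- binarize(pos)
    val <- fs_fitness(mask, spec)
    if (val < state$best) {
      state$best <- val
      state$mask <- mask
      state$error <- spec$error_estimator(mask)
    }
    val
  }
  res <- shoa_minimize(objective, config, on_iteration = function(j, v)
    state$trace[[j]] <- data.frame(iteration = j, best_fitness = state$best,
                                   n_selected = sum(state$mask)))
  mask <- setNames(state$mask, colnames(table$x))
  list(mask = mask, fitness = state$best, error = state$error,
       trace = do.call(rbind, state$trace), shoa = res)
}

#' Write a selection trace / mask to disk
#'
#' @param fs Result of [select_features()].
#' @param trace_path CSV path for the per-iteration trace (or NULL).
#' @param mask_path JSON path for the selected feature names (or NULL).
#' @export
write_selection <- function(fs, trace_path = NULL, mask_path = NULL) {
  if (!is.null(trace_path)) write.csv(fs$trace, trace_path, row.names = FALSE)
  if (!is.null(mask_path))
    writeLines(jsonlite::toJSON(names(fs$mask)[fs$mask]), mask_path)
  invisible(fs)
}
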