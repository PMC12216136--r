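#' Configuration for the (modified) coati optimizer
#'
#' @param pop_size Even population size >= 4 (the predation phase splits the
#'   population into halves).
#' @param max_iter Iteration budget T.
#' @param lower,upper Per-dimension box bounds (problem dimension = their
#'   length).
#' @param seed Integer seed (NULL = ambient stream).
#' @param dol_enabled Apply the dynamic-opposite-learning stage each
#'   iteration (the modification); FALSE gives the plain coati optimizer.
#' @return Object of class `coa_config`.
#' @export
coa_config <- function(pop_size = 30L, max_iter = 200L, lower, upper,
                       seed = NULL, dol_enabled = TRUE) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != length(upper)) stop("lower/upper length mismatch")
  if (any(lower >= upper)) stop("need lower < upper in every dimension")
  if (pop_size < 4 || pop_size %% 2 != 0) stop("pop_size must be even and >= 4")
  structure(list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
                 lower = lower, upper = upper, seed = seed,
                 dol_enabled = isTRUE(dol_enabled)),
            class = "coa_config")
}

# Uniform {1, 2} draw from one runif call (keeps the RNG stream trivially
# transcribable in the oracle tests).
draw_I <- function() floor(runif(1) * 2) + 1

#' Predation phase (tree + ground halves)
#'
#' The first half of the population pursues the best solution:
#' `x' = x + r (best - I x)` with `I` uniform on {1, 2} and `r` a fresh
#' uniform vector. A random "iguana" position is then dropped in the box,
#' and each member of the second half moves toward it when it is better
#' than the member's own value, away otherwise. Every proposal is clamped
#' and accepted only if it strictly improves that member (greedy rule).
#'
#' @param swarm List with `positions` (matrix), `fitness`, `best`,
#'   `best_value`.
#' @param objective Objective function.
#' @param lower,upper Box bounds.
#' @return Updated swarm (best refreshed).
#' @export
phase1_update <- function(swarm, objective, lower, upper) {
  pos <- swarm$positions; fit <- swarm$fitness
  pop <- nrow(pos); dim <- ncol(pos); half <- pop %/% 2
  for (i in seq_len(half)) {
    I <- draw_I()
    r <- runif(dim)
    prop <- clamp(pos[i, ] + r * (swarm$best - I * pos[i, ]), lower, upper)
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  iguana <- lower + runif(dim) * (upper - lower)
  f_ig <- objective(iguana)
  for (i in (half + 1):pop) {
    I <- draw_I()
    r <- runif(dim)
    prop <- if (f_ig < fit[i]) pos[i, ] + r * (iguana - I * pos[i, ])
            else pos[i, ] + r * (pos[i, ] - iguana)
    prop <- clamp(prop, lower, upper)
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  refresh_best(list(positions = pos, fitness = fit,
                    best = swarm$best, best_value = swarm$best_value))
}

#' Predator-escape phase with iteration-shrinking local bounds
#'
#' Local escape range `lb/t .. ub/t` at iteration `t` (1-based); each member
#' proposes `x + (1 - 2r) (lb_local + r (ub_local - lb_local))` with one
#' fresh uniform vector `r` used in both places, clamped to the global box
#' and accepted greedily.
#'
#' @inheritParams phase1_update
#' @param t Current iteration (>= 1).
#' @export
phase2_update <- function(swarm, objective, lower, upper, t) {
  stopifnot(t >= 1)
  pos <- swarm$positions; fit <- swarm$fitness
  lb_local <- lower / t; ub_local <- upper / t
  for (i in seq_len(nrow(pos))) {
    r <- runif(ncol(pos))
    prop <- clamp(pos[i, ] + (1 - 2 * r) * (lb_local + r * (ub_local - lb_local)),
                  lower, upper)
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  refresh_best(list(positions = pos, fitness = fit,
                    best = swarm$best, best_value = swarm$best_value))
}

#' Opposite and dynamic-opposite points
#'
#' `opposite_point` is the opposition-based-learning reflection
#' `a + b - x` within bounds \[a, b\]; `dynamic_opposite` perturbs toward a
#' randomly contracted opposite: `x + r1 (r2 x_o - x)`.
#'
#' @param x Position vector.
#' @param a,b Lower / upper opposition bounds.
#' @param r1,r2 Uniform draws in (0, 1).
#' @export
opposite_point <- function(x, a, b) a + b - x

#' @rdname opposite_point
#' @export
dynamic_opposite <- function(x, a, b, r1, r2) x + r1 * (r2 * opposite_point(x, a, b) - x)

#' Dynamic-opposite-learning stage
#'
#' Members are paired across population halves (i with i + pop/2). Each
#' member proposes `x + rc (rc (lb + ub - x_partner) - x_partner)` with a
#' fresh uniform vector `rc` (used in both places), against the *global*
#' box bounds; proposals are clamped and accepted greedily, sequentially on
#' the live population.
#'
#' @inheritParams phase1_update
#' @export
dol_update <- function(swarm, objective, lower, upper) {
  pos <- swarm$positions; fit <- swarm$fitness
  pop <- nrow(pos); half <- pop %/% 2
  for (i in seq_len(pop)) {
    partner <- if (i <= half) i + half else i - half
    rc <- runif(ncol(pos))
    opp <- pos[partner, ]
    prop <- clamp(pos[i, ] + rc * (rc * (lower + upper - opp) - opp), lower, upper)
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  refresh_best(list(positions = pos, fitness = fit,
                    best = swarm$best, best_value = swarm$best_value))
}

refresh_best <- function(swarm) {
  b <- which.min(swarm$fitness)
  if (swarm$fitness[b] < swarm$best_value) {
    swarm$best <- swarm$positions[b, ]
    swarm$best_value <- swarm$fitness[b]
  }
  swarm
}

#' Coati optimization with optional dynamic-opposite learning
#'
#' Each iteration runs the predation phase, the escape phase and (when
#' enabled) the DOL stage; every member update is greedy, so each member's
#' fitness and the best-so-far trace are monotone non-increasing. With
#' `dol_enabled = FALSE` the run is exactly the plain coati optimizer.
#'
#' @param objective Function mapping a position to a finite scalar.
#' @param config A [coa_config()].
#' @param on_iteration Optional callback `function(t, best_value)`.
#' @return List with `par`, `value`, `history` (best value per iteration)
#'   and `swarm` (final state).
#' @export
mcoa_minimize <- function(objective, config, on_iteration = NULL) {
  obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) stop("objective returned a non-finite value")
    v
  }
  with_seed(config$seed, {
    dim <- length(config$lower)
    pop <- config$pop_size
    positions <- t(matrix(vapply(seq_len(pop), function(i)
      config$lower + runif(dim) * (config$upper - config$lower), numeric(dim)),
      nrow = dim))
    fitness <- apply(positions, 1, obj)
    swarm <- refresh_best(list(positions = positions, fitness = fitness,
                               best = positions[1, ], best_value = Inf))
    history <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      swarm <- phase1_update(swarm, obj, config$lower, config$upper)
      swarm <- phase2_update(swarm, obj, config$lower, config$upper, t)
      if (config$dol_enabled)
        swarm <- dol_update(swarm, obj, config$lower, config$upper)
      history[t] <- swarm$best_value
      if (!is.null(on_iteration)) on_iteration(t, swarm$best_value)
    }
    list(par = swarm$best, value = swarm$best_value, history = history,
         swarm = swarm)
  })
}

#' Hyperparameter search space for the classifier
#'
#' Named box dimensions with scale and integrality; positions live in
#' \[0, 1\] per dimension and are decoded with [decode_position()]. The
#' default space brackets the standard recipe (learning rate 0.01, dropout
#' 0.5, batch 5) with a log scale for the learning rate.
#'
#' @param dims List of dimension descriptors (`name`, `lower`, `upper`,
#'   `scale` = "linear"|"log", `integer` flag).
#' @return Object of class `hyperparam_space`.
#' @export
hyperparam_space <- function(dims = NULL) {
  if (is.null(dims)) dims <- list(
    list(name = "learning_rate", lower = 1e-3, upper = 1e-1, scale = "log", integer = FALSE),
    list(name = "hidden_size", lower = 4, upper = 16, scale = "linear", integer = TRUE),
    list(name = "dropout", lower = 0, upper = 0.7, scale = "linear", integer = FALSE),
    list(name = "batch_size", lower = 2, upper = 16, scale = "linear", integer = TRUE))
  structure(list(dims = dims), class = "hyperparam_space")
}

#' @rdname hyperparam_space
#' @param space A `hyperparam_space`.
#' @param pos Numeric vector in \[0, 1\]^k.
#' @return Named list of decoded hyperparameter values.
#' @export
decode_position <- function(space, pos) {
  stopifnot(length(pos) == length(space$dims))
  out <- lapply(seq_along(pos), function(j) {
    d <- space$dims[[j]]
    p <- clamp(pos[j], 0, 1)
    v <- if (identical(d$scale, "log"))
      10^(log10(d$lower) + p * (log10(d$upper) - log10(d$lower)))
    else d$lower + p * (d$upper - d$lower)
    if (isTRUE(d$integer)) v <- as.integer(round(v))
    v
  })
  setNames(out, vapply(space$dims, `[[`, "", "name"))
}

#' Tune the classifier's hyperparameters with the modified coati optimizer
#'
#' Each swarm position decodes to a candidate configuration; an attention
#' BiGRU is trained on the training split and scored on the validation
#' split. The fitness maximizes validation precision TP/(TP+FP) by default
#' (minimizing 1 - P); `metric = "accuracy"` switches to (TP+TN)/total.
#' A candidate whose training fails scores worst and the search continues.
#'
#' @param space A [hyperparam_space()].
#' @param train,val Disjoint [feature_table()] splits.
#' @param config A [coa_config()] whose bounds are forced to \[0, 1\]^k.
#' @param metric `"precision"` (default) or `"accuracy"`.
#' @param epochs Training epochs per candidate evaluation (kept small: the
#'   tuner ranks configurations, the final model is retrained).
#' @param hidden_default Hidden size used when the space does not tune it.
#' @return List with `params` (decoded best), `fitness` (achieved metric),
#'   `trace` (best metric per iteration) and `mcoa` (raw optimizer result).
#' @export
tune_abigru <- function(space, train, val, config, metric = c("precision", "accuracy"),
                        epochs = 15L, hidden_default = 8L) {
  metric <- match.arg(metric)
  k <- length(space$dims)
  config[c("lower", "upper")] <- list(rep(0, k), rep(1, k))
  eval_seed <- derive_seed(config$seed %||% 0L, "tune-train")
  objective <- function(pos) {
    hp <- decode_position(space, pos)
    tryCatch({
      cfg <- train_config(learning_rate = hp$learning_rate %||% 0.01,
                          epochs = epochs,
                          dropout = hp$dropout %||% 0.5,
                          batch_size = hp$batch_size %||% 5L,
                          seed = eval_seed)
      model <- init_abigru(ncol(train$x),
                           hidden = hp$hidden_size %||% hidden_default,
                           classes = levels(train$y), seed = eval_seed)
      fit <- train_abigru(model, train, cfg = cfg)
      pred <- predict_abigru(fit$model, val)
      cts <- confusion_counts(val$y, pred$label, positive = train$positive)
      m <- if (metric == "precision") as.numeric(precision(cts))
           else (cts$tp + cts$tn) / cts$total
      1 - m
    }, error = function(e) 1)
  }
  res <- mcoa_minimize(objective, config)
  list(params = decode_position(space, res$par),
       fitness = 1 - res$value,
       trace = 1 - res$history,
       mcoa = res)
}
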