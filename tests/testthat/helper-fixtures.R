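# Shared fixtures and independent reference implementations.

# Published per-class / average metric blocks (percent, two decimals) used
# to validate the macro-averaging convention: each block is rows
# (positive-class tally, precision, recall, F, MCC, kappa) for the two
# classes plus the printed Average row.
reference_metric_blocks <- function() {
  cols <- c("accu_y", "prec_n", "reca_l", "f_measure", "mcc", "kappa")
  block <- function(pres, abs, avg) {
    m <- rbind(pres, abs, avg)
    dimnames(m) <- list(c("presence", "absence", "average"), cols)
    m
  }
  list(
    e500 = block(c(90.30, 96.13, 90.30, 93.13, 85.64, 85.70),
                 c(95.65, 89.19, 95.65, 92.31, 85.64, 85.70),
                 c(92.98, 92.66, 92.98, 92.72, 85.64, 85.70)),
    e1000 = block(c(92.12, 95.00, 92.12, 93.54, 86.12, 86.19),
                  c(94.20, 90.91, 94.20, 92.53, 86.12, 86.17),
                  c(93.16, 92.95, 93.16, 93.03, 86.12, 86.18)),
    e1500 = block(c(96.97, 97.56, 96.97, 97.26, 94.02, 94.10),
                  c(97.10, 96.40, 97.10, 96.75, 94.02, 94.08),
                  c(97.04, 96.98, 97.04, 97.01, 94.02, 94.09)),
    e2000 = block(c(93.94, 96.27, 93.94, 95.09, 89.41, 89.49),
                  c(95.65, 92.96, 95.65, 94.29, 89.41, 89.49),
                  c(94.80, 94.62, 94.80, 94.69, 89.41, 89.49)),
    e2500 = block(c(95.76, 95.76, 95.76, 95.76, 90.69, 90.75),
                  c(94.93, 94.93, 94.93, 94.93, 90.69, 90.75),
                  c(95.34, 95.34, 95.34, 95.34, 90.69, 90.75)),
    e3000 = block(c(97.36, 96.45, 98.79, 97.60, 94.70, 94.77),
                  c(97.36, 98.51, 95.65, 97.06, 94.70, 94.78),
                  c(97.36, 97.48, 97.22, 97.33, 94.70, 94.77)))
}

# Label vectors realizing a 2x2 confusion table, for correlation-based
# metric oracles.
vectors_from_counts <- function(tp, fp, tn, fn) {
  list(truth = c(rep("pos", tp + fn), rep("neg", tn + fp)),
       pred = c(rep("pos", tp), rep("neg", fn), rep("neg", tn), rep("pos", fp)))
}

# --- Literal transcription of the hyena update rules (encircling Eqs.,
# hunting cluster, centroid attack), consuming the RNG stream in the
# documented order. Independent of the package's internals.
oracle_shoa_iteration <- function(positions, fitness, prey, iter, max_iter,
                                  lower, upper) {
  pop <- nrow(positions); dim <- ncol(positions)
  G <- runif(1, 0.5, 1)
  f_best <- min(fitness)
  n_h <- max(1L, sum(fitness <= f_best + G * abs(f_best)))
  cluster <- order(fitness, seq_len(pop))[seq_len(n_h)]
  l <- 5 - iter * (5 / max_iter)
  prm <- list()
  for (i in seq_len(pop)) {
    r1 <- runif(dim); r2 <- runif(dim)
    prm[[i]] <- list(Y = 2 * r1, Z = 2 * l * r2 - l)
  }
  out <- positions
  for (i in sort(cluster)) {
    ref <- if (mean(abs(prm[[i]]$Z)) > 1) lower + runif(dim) * (upper - lower)
           else prey
    R_hp <- abs(prm[[i]]$Y * ref - positions[i, ])
    out[i, ] <- pmin(pmax(ref - prm[[i]]$Z * R_hp, lower), upper)
  }
  centroid <- colMeans(out[sort(cluster), , drop = FALSE])
  for (i in setdiff(seq_len(pop), cluster))
    out[i, ] <- pmin(pmax(centroid, lower), upper)
  out
}

# --- Literal transcription of the coati update rules (predation with
# tree/ground halves, random iguana, escape bounds lb/t..ub/t, greedy
# acceptance, paired dynamic-opposite stage).
oracle_coa_iteration <- function(pos, fit, best, best_value, t, lower, upper,
                                 objective, dol) {
  pop <- nrow(pos); dim <- ncol(pos); half <- pop %/% 2
  clampv <- function(x) pmin(pmax(x, lower), upper)
  for (i in seq_len(half)) {
    I <- floor(runif(1) * 2) + 1
    r <- runif(dim)
    prop <- clampv(pos[i, ] + r * (best - I * pos[i, ]))
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  ig <- lower + runif(dim) * (upper - lower)
  f_ig <- objective(ig)
  for (i in (half + 1):pop) {
    I <- floor(runif(1) * 2) + 1
    r <- runif(dim)
    prop <- if (f_ig < fit[i]) pos[i, ] + r * (ig - I * pos[i, ])
            else pos[i, ] + r * (pos[i, ] - ig)
    prop <- clampv(prop)
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  b <- which.min(fit)
  if (fit[b] < best_value) { best <- pos[b, ]; best_value <- fit[b] }
  for (i in seq_len(pop)) {
    r <- runif(dim)
    prop <- clampv(pos[i, ] + (1 - 2 * r) * (lower / t + r * (upper / t - lower / t)))
    f <- objective(prop)
    if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
  }
  b <- which.min(fit)
  if (fit[b] < best_value) { best <- pos[b, ]; best_value <- fit[b] }
  if (dol) {
    for (i in seq_len(pop)) {
      partner <- if (i <= half) i + half else i - half
      rc <- runif(dim)
      opp <- pos[partner, ]
      prop <- clampv(pos[i, ] + rc * (rc * (lower + upper - opp) - opp))
      f <- objective(prop)
      if (f < fit[i]) { pos[i, ] <- prop; fit[i] <- f }
    }
    b <- which.min(fit)
    if (fit[b] < best_value) { best <- pos[b, ]; best_value <- fit[b] }
  }
  list(pos = pos, fit = fit, best = best, best_value = best_value)
}

# Full reference run matching mcoa_minimize's documented stream usage.
oracle_coa_run <- function(objective, pop, iters, lower, upper, seed, dol) {
  set.seed(seed)
  dim <- length(lower)
  pos <- t(vapply(seq_len(pop), function(i)
    lower + runif(dim) * (upper - lower), numeric(dim)))
  fit <- apply(pos, 1, objective)
  b <- which.min(fit)
  best <- pos[b, ]; best_value <- fit[b]
  history <- numeric(iters)
  for (t in seq_len(iters)) {
    st <- oracle_coa_iteration(pos, fit, best, best_value, t, lower, upper,
                               objective, dol)
    pos <- st$pos; fit <- st$fit; best <- st$best; best_value <- st$best_value
    history[t] <- best_value
  }
  list(par = best, value = best_value, history = history, positions = pos)
}

# Collapse the hyperparameter space to the standard training recipe
# (lr 0.01, hidden 8, dropout 0.5, batch 5) -- used where a test targets
# pipeline mechanics rather than the search.
baseline_point_space <- function() {
  hyperparam_space(list(
    list(name = "learning_rate", lower = 0.01, upper = 0.01, scale = "linear", integer = FALSE),
    list(name = "hidden_size", lower = 8, upper = 8, scale = "linear", integer = TRUE),
    list(name = "dropout", lower = 0.5, upper = 0.5, scale = "linear", integer = FALSE),
    list(name = "batch_size", lower = 5, upper = 5, scale = "linear", integer = TRUE)))
}
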