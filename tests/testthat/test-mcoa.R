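sphere <- function(x) sum(x^2)

make_swarm <- function(pop, dim, lo, hi, objective, seed) {
  set.seed(seed)
  pos <- t(vapply(seq_len(pop), function(i) lo + runif(dim) * (hi - lo),
                  numeric(dim)))
  fit <- apply(pos, 1, objective)
  swarmdx:::refresh_best(list(positions = pos, fitness = fit,
                              best = pos[1, ], best_value = Inf))
}

test_that("each phase is greedy per member and respects the box", {
  lo <- rep(-5, 3); hi <- rep(5, 3)
  set.seed(14)
  for (rep in 1:5) {
    sw <- make_swarm(6, 3, lo, hi, sphere, seed = rep)
    s1 <- phase1_update(sw, sphere, lo, hi)
    expect_true(all(s1$fitness <= sw$fitness))
    s2 <- phase2_update(s1, sphere, lo, hi, t = rep)
    expect_true(all(s2$fitness <= s1$fitness))
    s3 <- dol_update(s2, sphere, lo, hi)
    expect_true(all(s3$fitness <= s2$fitness))
    for (s in list(s1, s2, s3)) {
      expect_true(all(sweep(s$positions, 2, lo, ">=")))
      expect_true(all(sweep(s$positions, 2, hi, "<=")))
      expect_equal(s$best_value, min(s$fitness))
      expect_equal(s$fitness, apply(s$positions, 1, sphere))
    }
  }
})

test_that("opposition operators evaluate exactly", {
  expect_equal(opposite_point(3, 0, 10), 7)
  expect_equal(dynamic_opposite(3, 0, 10, r1 = 1, r2 = 1), 7)
  expect_equal(dynamic_opposite(3, 0, 10, r1 = 0, r2 = 0.4), 3)  # r1 = 0: no move
  # box midpoint is an opposition fixed point
  expect_equal(opposite_point(2.5, 0, 5), 2.5)
  expect_equal(dynamic_opposite(c(1, 2), c(0, 0), c(4, 4), r1 = c(1, 1), r2 = c(1, 1)),
               c(3, 2))
})

test_that("escape-phase steps shrink with the iteration index", {
  lo <- rep(-6, 2); hi <- rep(6, 2)
  sw <- make_swarm(4, 2, lo, hi, sphere, seed = 3)
  for (t in c(1, 10, 100)) {
    set.seed(20)
    s <- phase2_update(sw, sphere, lo, hi, t = t)
    expect_true(all(abs(s$positions - sw$positions) <= max(hi - lo) / t + 1e-12))
  }
})

test_that("one iteration and full runs are bit-equal to the literal transcription", {
  lo <- rep(-5.12, 4); hi <- rep(5.12, 4)
  for (dol in c(TRUE, FALSE)) {
    got <- mcoa_minimize(sphere, coa_config(6, 3, lower = lo, upper = hi,
                                            seed = 101, dol_enabled = dol))
    want <- oracle_coa_run(sphere, 6, 3, lo, hi, seed = 101, dol = dol)
    expect_identical(got$par, want$par)
    expect_identical(got$value, want$value)
    expect_identical(got$history, want$history)
    expect_identical(got$swarm$positions, want$positions)
  }
})

test_that("disabling DOL reproduces the plain coati optimizer exactly", {
  lo <- rep(-5, 5); hi <- rep(5, 5)
  got <- mcoa_minimize(sphere, coa_config(8, 10, lower = lo, upper = hi,
                                          seed = 55, dol_enabled = FALSE))
  want <- oracle_coa_run(sphere, 8, 10, lo, hi, seed = 55, dol = FALSE)
  expect_identical(got$history, want$history)
  expect_identical(got$par, want$par)
})

test_that("history is monotone and invalid configurations are rejected", {
  res <- mcoa_minimize(sphere, coa_config(6, 40, lower = rep(-5, 3),
                                          upper = rep(5, 3), seed = 9))
  expect_true(all(diff(res$history) <= 0))
  expect_error(coa_config(5, 10, lower = 0, upper = 1), "even")
  expect_error(coa_config(2, 10, lower = 0, upper = 1), "even")
  expect_error(mcoa_minimize(function(x) Inf,
                             coa_config(4, 2, lower = 0, upper = 1, seed = 1)),
               "non-finite")
})

test_that("hyperparameter decoding honours scale, integrality and bounds", {
  sp <- hyperparam_space()
  lo <- decode_position(sp, rep(0, 4))
  hi <- decode_position(sp, rep(1, 4))
  expect_equal(lo$learning_rate, 1e-3)
  expect_equal(hi$learning_rate, 1e-1)
  mid <- decode_position(sp, rep(0.5, 4))
  expect_equal(mid$learning_rate, 1e-2)  # log-scale midpoint
  expect_true(is.integer(mid$hidden_size) && is.integer(mid$batch_size))
  expect_equal(mid$dropout, 0.35)
  out <- decode_position(sp, c(2, -1, 2, -1))  # clamped
  expect_equal(out$learning_rate, 0.1)
  expect_equal(out$hidden_size, 4L)
})

test_that("tuning a collapsed space returns that point with its measured metric", {
  sq <- generate_sequences(40, 3, separation = 3, seed = 2)
  tab <- feature_table(sq$x, sq$y, positive = "pos")
  sp <- stratified_split(tab, c(0.6, 0.4, 0), seed = 1)
  space <- hyperparam_space(list(
    list(name = "learning_rate", lower = 0.02, upper = 0.02, scale = "linear", integer = FALSE),
    list(name = "dropout", lower = 0.1, upper = 0.1, scale = "linear", integer = FALSE)))
  res <- tune_abigru(space, sp$train, sp$val,
                     coa_config(4, 1, lower = rep(0, 2), upper = rep(1, 2), seed = 3),
                     epochs = 2L, hidden_default = 4L)
  expect_equal(res$params$learning_rate, 0.02)
  expect_equal(res$params$dropout, 0.1)
  expect_true(res$fitness >= 0 && res$fitness <= 1)

  # accuracy metric equals the validation confusion-matrix accuracy
  res2 <- tune_abigru(space, sp$train, sp$val,
                      coa_config(4, 1, lower = rep(0, 2), upper = rep(1, 2), seed = 3),
                      metric = "accuracy", epochs = 2L, hidden_default = 4L)
  cfg <- train_config(learning_rate = 0.02, epochs = 2L, dropout = 0.1,
                      batch_size = 5L,
                      seed = swarmdx:::derive_seed(3, "tune-train"))
  model <- init_abigru(ncol(sp$train$x), hidden = 4L, classes = levels(sp$train$y),
                       seed = swarmdx:::derive_seed(3, "tune-train"))
  fit <- train_abigru(model, sp$train, cfg = cfg)
  pred <- predict_abigru(fit$model, sp$val)
  expect_equal(res2$fitness, mean(pred$label == sp$val$y), tolerance = 1e-12)
})
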