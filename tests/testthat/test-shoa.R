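test_that("control schedule and coefficient vectors obey their bounds", {
  set.seed(1)
  expect_equal(control_params(0, 100)$l, 5)
  expect_equal(control_params(100, 100)$l, 0)
  expect_equal(control_params(50, 100)$l, 2.5)
  p_end <- control_params(7, 7, dim = 4)
  expect_equal(p_end$Z, rep(0, 4))  # l = 0 forces Z = 0
  for (i in 1:20) {
    p <- control_params(sample(0:50, 1), 50, dim = 3)
    expect_true(all(p$Y >= 0 & p$Y <= 2))
    expect_true(all(abs(p$Z) <= p$l + 1e-12))
  }
  expect_error(control_params(1, 0), "positive")
})

test_that("encircling update follows the distance rule", {
  lo <- rep(-10, 1); hi <- rep(10, 1)
  # hand evaluation: position 2, prey 5, Y = 1, Z = 0.5 -> R = 3, new = 3.5
  prm <- list(Y = 1, Z = 0.5)
  expect_equal(encircle_update(2, 5, prm, lo, hi), 3.5)
  # Z = 0 lands exactly on the prey
  expect_equal(encircle_update(c(2, -3), c(1, 1), list(Y = c(1, 1), Z = c(0, 0)),
                               rep(-10, 2), rep(10, 2)), c(1, 1))
  # fixed point: position = prey with Y = 1
  expect_equal(encircle_update(4, 4, list(Y = 1, Z = 0.7), lo, hi), 4)
})

test_that("cluster attack centroid and full iteration match the literal transcription", {
  cfg <- shoa_config(pop_size = 5, max_iter = 20, lower = rep(-5, 3),
                     upper = rep(5, 3), seed = NULL)
  set.seed(31); pos <- matrix(runif(15, -5, 5), 5, 3)
  fit <- apply(pos, 1, function(x) sum(x^2))
  prey <- pos[which.min(fit), ]
  set.seed(77)
  got <- swarmdx:::shoa_iterate(pos, fit, prey, 3L, cfg)
  set.seed(77)
  want <- oracle_shoa_iteration(pos, fit, prey, 3, 20, cfg$lower, cfg$upper)
  expect_identical(got, want)

  # two members in 1-D at 0 and 4 forming the cluster -> centroid 2
  expect_equal(unname(colMeans(matrix(c(0, 4), 2, 1))), 2)
})

test_that("minimization converges, stays in bounds and stops adaptively", {
  res <- shoa_minimize(function(x) sum((x - 2)^2),
                       shoa_config(pop_size = 15, max_iter = 100, patience = 100,
                                   lower = 0, upper = 5, seed = 11))
  expect_lt(abs(res$par - 2), 1e-2)
  expect_true(all(diff(res$history) <= 0))

  # constant objective stops after exactly patience iterations beyond the first
  res2 <- shoa_minimize(function(x) 1,
                        shoa_config(pop_size = 4, max_iter = 50, epsilon = 1e-6,
                                    patience = 3, lower = rep(0, 2),
                                    upper = rep(1, 2), seed = 2))
  expect_equal(res2$iterations, 4L)

  # positions honour the box: optimum outside the box ends at its edge
  res3 <- shoa_minimize(function(x) sum((x - 10)^2),
                        shoa_config(pop_size = 10, max_iter = 60, patience = 60,
                                    lower = rep(-1, 2), upper = rep(1, 2), seed = 5))
  expect_true(all(res3$par >= -1 & res3$par <= 1))
  expect_equal(res3$par, c(1, 1), tolerance = 1e-6)

  expect_error(shoa_minimize(function(x) NaN,
                             shoa_config(pop_size = 4, max_iter = 5,
                                         lower = 0, upper = 1, seed = 1)),
               "non-finite")
})

test_that("sigmoid binarization sets certain bits and repairs empty masks", {
  set.seed(4)
  expect_true(all(binarize(rep(50, 6))))
  m <- binarize(rep(-50, 6))
  expect_equal(sum(m), 1)  # repair leaves exactly one bit
  set.seed(9); m1 <- binarize(c(0.3, -1, 2))
  set.seed(9); m2 <- binarize(c(0.3, -1, 2))
  expect_identical(m1, m2)
})

test_that("selection fitness blends error and subset size in both printed forms", {
  est <- function(mask) 0.1
  sp <- fs_fitness_spec(est, n_total = 13, alpha = 0.9, beta = 0.1)
  m9 <- c(rep(TRUE, 9), rep(FALSE, 4))
  expect_equal(fs_fitness(m9, sp), 0.9 * 0.1 + 0.1 * (9 / 13), tolerance = 1e-12)
  expect_equal(fs_fitness(m9, sp), 0.15923, tolerance = 1e-5)
  # boundary case separating the two readings: E = 0, full mask
  sp0 <- fs_fitness_spec(function(m) 0, n_total = 5, alpha = 0.9, beta = 0.1)
  sp0p <- fs_fitness_spec(function(m) 0, n_total = 5, alpha = 0.9, beta = 0.1,
                          form = "as_printed")
  expect_equal(fs_fitness(rep(TRUE, 5), sp0), 0.1)
  expect_equal(fs_fitness(rep(TRUE, 5), sp0p), 0)
  # alpha = 1 reduces to the error alone
  sp1 <- fs_fitness_spec(function(m) 0.37, n_total = 8, alpha = 1, beta = 0)
  expect_equal(fs_fitness(c(TRUE, FALSE, TRUE), sp1), 0.37)
  expect_error(fs_fitness_spec(est, 5, alpha = 0.5, beta = 0.1), "equal 1")
})

test_that("knn CV error is deterministic and sane on separable data", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  expect_lt(knn_cv_error(x, y, seed = 3), 0.05)
  expect_equal(knn_cv_error(x, y, seed = 3), knn_cv_error(x, y, seed = 3))
  # label-shuffled data gives roughly chance error
  expect_gt(knn_cv_error(x, sample(y), seed = 3), 0.25)
})

test_that("feature selection is deterministic and tracks no-signal error honestly", {
  ds <- generate_hd_like(synth_spec(n_rows = 80, n_presence = 44, n_absence = 36,
                                    n_features = 6, informative_idx = integer(0),
                                    effect_sizes = numeric(0),
                                    categorical_idx = integer(0), seed = 13))
  cfg <- shoa_config(pop_size = 6, max_iter = 6, patience = 6,
                     lower = rep(-4, 6), upper = rep(4, 6), seed = 8)
  fs1 <- select_features(ds$table, cfg)
  fs2 <- select_features(ds$table, cfg)
  expect_identical(fs1$mask, fs2$mask)
  # no signal: best wrapper error cannot be far below the majority-class rate
  expect_gt(fs1$error, 0.25)
  expect_equal(names(fs1$mask), colnames(ds$table$x))
  expect_s3_class(fs1$trace, "data.frame")
  expect_true(all(diff(fs1$trace$best_fitness) <= 0))
})
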