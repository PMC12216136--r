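zero_cell <- function(H, D) list(Wr = matrix(0, H, H + D), Wz = matrix(0, H, H + D),
                                 Wh = matrix(0, H, H + D), br = rep(0, H),
                                 bz = rep(0, H), bh = rep(0, H))

test_that("GRU step matches scalar hand computation and gating limits", {
  # scalar case: W_r = W_z = W = [1, 1], h = 0, x = 1
  cell <- list(Wr = matrix(c(1, 1), 1), Wz = matrix(c(1, 1), 1),
               Wh = matrix(c(1, 1), 1), br = 0, bz = 0, bh = 0)
  h <- gru_step(1, 0, cell)
  sig <- function(v) 1 / (1 + exp(-v))
  expect_equal(h, sig(1) * tanh(1), tolerance = 1e-12)
  expect_equal(h, 0.55677, tolerance = 1e-5)

  # all-zero weights halve the previous state (sigmoid(0) = 0.5, tanh(0) = 0)
  hp <- c(0.4, -1.2, 2)
  expect_equal(gru_step(0.7, hp, zero_cell(3, 1)), 0.5 * hp)

  # saturated update gate hands over to the candidate state
  cz <- zero_cell(1, 1); cz$bz <- 50; cz$bh <- 0.9
  expect_equal(gru_step(0, 0.3, cz), tanh(0.9), tolerance = 1e-9)

  expect_error(gru_step(c(1, 2), rep(0, 3), zero_cell(3, 1)), "shape")
})

test_that("new state is a componentwise convex combination (gate property)", {
  set.seed(10)
  for (i in 1:20) {
    H <- sample(2:5, 1)
    cell <- list(Wr = matrix(rnorm(H * (H + 1)), H), Wz = matrix(rnorm(H * (H + 1)), H),
                 Wh = matrix(rnorm(H * (H + 1)), H), br = rnorm(H), bz = rnorm(H),
                 bh = rnorm(H))
    h_prev <- rnorm(H)
    cc <- swarmdx:::gru_step_cache(rnorm(1), h_prev, cell)
    lo <- pmin(h_prev, cc$hh); hi <- pmax(h_prev, cc$hh)
    expect_true(all(cc$h >= lo - 1e-12 & cc$h <= hi + 1e-12))
  }
})

test_that("bidirectional pass equals an explicit two-loop reference", {
  m <- init_abigru(4, hidden = 3, seed = 7)
  set.seed(2); xs <- matrix(rnorm(4), 4, 1)
  got <- bigru_forward(xs, m)
  # reference: run each direction timestep by timestep through gru_step
  hf <- matrix(0, 3, 4); h <- rep(0, 3)
  for (t in 1:4) { h <- gru_step(xs[t, ], h, m$fwd); hf[, t] <- h }
  hb <- matrix(0, 3, 4); h <- rep(0, 3)
  for (t in 4:1) { h <- gru_step(xs[t, ], h, m$bwd); hb[, t] <- h }
  want <- m$comb$Wf %*% hf + m$comb$Wb %*% hb + m$comb$bc
  expect_equal(got, want, tolerance = 1e-12)

  # length-1 sequence: both directions see the same single input
  g1 <- bigru_forward(matrix(0.3), m)
  h1 <- gru_step(0.3, rep(0, 3), m$fwd)
  h2 <- gru_step(0.3, rep(0, 3), m$bwd)
  expect_equal(drop(g1), drop(m$comb$Wf %*% h1 + m$comb$Wb %*% h2 + m$comb$bc))
})

test_that("palindromic input with tied cells yields palindromic states", {
  m <- init_abigru(5, hidden = 4, seed = 3)
  m$bwd <- m$fwd
  m$comb$Wb <- m$comb$Wf
  xs <- matrix(c(0.2, -1, 0.5, -1, 0.2), 5, 1)
  st <- bigru_forward(xs, m)
  expect_equal(st, st[, 5:1], tolerance = 1e-12)
})

test_that("attention weights form a softmax over the scores", {
  # uniform scores average the states
  att <- list(Wa = matrix(0, 2, 2), ba = c(0, 0), va = c(1, 1))
  st <- matrix(rnorm(8), 2, 4)
  ap <- attention_pool(st, att)
  expect_equal(ap$weights, rep(0.25, 4))
  expect_equal(ap$context, rowMeans(st))

  # hand softmax: scores (0, log 2, log 4) -> weights (1/7, 2/7, 4/7)
  expect_equal(swarmdx:::softmax(c(0, log(2), log(4))), c(1, 2, 4) / 7)

  # a dominating score absorbs all the weight
  stw <- cbind(c(1, 0), c(0, 1))
  att2 <- list(Wa = diag(2) * 20, ba = c(0, 0), va = c(50, 0))
  ap2 <- attention_pool(stw, att2)
  expect_gt(ap2$weights[1], 0.999)
  expect_equal(ap2$context, stw[, 1], tolerance = 1e-3)

  # nonnegative, sum to 1 for arbitrary states
  set.seed(5)
  for (i in 1:10) {
    st <- matrix(rnorm(3 * 6, sd = 5), 3)
    a <- attention_pool(st, list(Wa = matrix(rnorm(9), 3), ba = rnorm(3),
                                 va = rnorm(3)))$weights
    expect_true(all(a >= 0))
    expect_equal(sum(a), 1, tolerance = 1e-9)
  }
})

test_that("tabular rows become one-feature-per-timestep sequences", {
  r <- row_to_sequence(1:9)
  expect_equal(dim(r), c(9L, 1L))
  expect_equal(drop(row_to_sequence(c(3, 1, 2))[c(2, 3, 1), ]),
               drop(row_to_sequence(c(3, 1, 2)[c(2, 3, 1)])))
  expect_equal(nrow(row_to_sequence(1:9, mask = c(rep(TRUE, 4), rep(FALSE, 5)))), 4)
  expect_error(row_to_sequence(numeric(0)), "empty")
})

test_that("analytic gradients match central finite differences", {
  m <- init_abigru(4, hidden = 3, seed = 42)
  set.seed(1)
  X <- matrix(rnorm(8), 2, 4)
  yi <- c(1L, 2L)
  lg <- swarmdx:::abigru_loss_grad(m, X, yi)
  theta <- swarmdx:::abigru_get_params(m)
  flat <- unlist(lapply(c("fwd", "bwd", "comb", "att", "head"),
                        function(b) lapply(lg$grads[[b]], as.numeric)))
  eps <- 1e-5
  num <- vapply(seq_along(theta), function(k) {
    tp <- theta; tp[k] <- theta[k] + eps
    lp <- swarmdx:::abigru_loss_grad(swarmdx:::abigru_set_params(m, tp), X, yi)$loss
    tp[k] <- theta[k] - eps
    lm <- swarmdx:::abigru_loss_grad(swarmdx:::abigru_set_params(m, tp), X, yi)$loss
    (lp - lm) / (2 * eps)
  }, 0)
  rel <- abs(flat - num) / pmax(abs(flat) + abs(num), 1e-4)
  expect_lt(max(rel), 1e-4)
})

test_that("training learns separable sequences and respects the zero-rate identity", {
  sq <- generate_sequences(60, 6, separation = 3, seed = 1)
  fit <- train_abigru(NULL, sq$x, sq$y,
                      train_config(epochs = 8, dropout = 0.2, seed = 2))
  pred <- predict_abigru(fit$model, sq$x)
  expect_gt(mean(pred$label == sq$y), 0.95)
  # loss strictly decreases over the first epochs on separable data
  expect_true(all(diff(fit$loss_history[1:5]) < 0))

  m0 <- init_abigru(6, hidden = 4, classes = c("neg", "pos"), seed = 3)
  frozen <- train_abigru(m0, sq$x, sq$y,
                         train_config(learning_rate = 0, epochs = 2, seed = 4))
  expect_identical(swarmdx:::abigru_get_params(frozen$model),
                   swarmdx:::abigru_get_params(m0))
  expect_equal(frozen$loss_history[1], frozen$loss_history[2])

  expect_error(train_abigru(NULL, sq$x, rep("pos", 60), train_config(epochs = 1)),
               "both classes")
})

test_that("prediction is a proper, deterministic probability model", {
  m <- init_abigru(3, hidden = 4, seed = 8)
  m$head$W2[] <- 0; m$head$b2[] <- 0  # symmetric head
  x <- matrix(rnorm(15), 5, 3)
  pr <- predict_abigru(m, x)
  expect_true(all(abs(pr$prob - 0.5) < 1e-12))
  expect_equal(pr$label, factor(rep("presence", 5), levels = c("absence", "presence")))

  m2 <- init_abigru(3, hidden = 4, seed = 9)
  p1 <- predict_abigru(m2, x)
  p2 <- predict_abigru(m2, x)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$prob), rep(1, 5), tolerance = 1e-9)
  expect_error(predict_abigru(m2, matrix(0, 2, 5)), "does not match")
})
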