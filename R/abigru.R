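#' Training configuration for the attention BiGRU
#'
#' Defaults follow the standard training recipe for this pipeline:
#' learning rate 0.01, ReLU head activation, 50 epochs, dropout 0.5 and
#' mini-batches of 5.
#'
#' @param learning_rate Gradient-descent step size in (0, 1].
#' @param epochs Number of passes over the training data.
#' @param dropout Dropout rate applied to the combined hidden states during
#'   training only.
#' @param batch_size Mini-batch size.
#' @param optimizer `"adam"` (default) or `"gd"` (plain mini-batch gradient
#'   descent). Plain GD at this learning rate is too slow to position-encode
#'   the tabular-as-sequence recasting at desk scale, so Adam is the
#'   default; the loss being minimized is identical.
#' @param seed Integer seed for shuffling, initialization of dropout masks.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, epochs = 50L, dropout = 0.5,
                         batch_size = 5L, optimizer = c("adam", "gd"),
                         seed = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(learning_rate >= 0, learning_rate <= 1, epochs >= 0,
            dropout >= 0, dropout < 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 dropout = dropout, batch_size = as.integer(batch_size),
                 optimizer = optimizer, seed = seed),
            class = "train_config")
}

new_gru_cell <- function(H, D, scale = NULL) {
  fan <- H + D
  s <- scale %||% (1 / sqrt(fan))
  m <- function() matrix(runif(H * fan, -s, s), H, fan)
  list(Wr = m(), Wz = m(), Wh = m(),
       br = rep(0, H), bz = rep(0, H), bh = rep(0, H))
}

#' Initialize an attention bidirectional GRU model
#'
#' Two GRU cells (one per direction), a shared linear combination of the two
#' directions' hidden states, tanh attention pooling over timesteps, and a
#' dense ReLU + softmax head for the two classes. Weights are seeded uniform
#' draws scaled by fan-in; biases start at zero.
#'
#' @param n_features Sequence length the model expects (tabular rows are
#'   recast one feature per timestep).
#' @param hidden Hidden state size H.
#' @param head_hidden Size of the dense head's hidden layer (default = H).
#' @param input_size Input dimension per timestep (1 for tabular recasting).
#' @param classes Character vector of the two class labels
#'   (second entry = positive class for tie-breaking).
#' @param seed Integer seed.
#' @return Object of class `abigru_model`.
#' @export
init_abigru <- function(n_features, hidden = 8L, head_hidden = NULL,
                        input_size = 1L, classes = c("absence", "presence"),
                        seed = 1L) {
  H <- as.integer(hidden); D <- as.integer(input_size)
  H2 <- as.integer(head_hidden %||% hidden)
  stopifnot(length(classes) == 2)
  with_seed(seed, {
    model <- list(
      H = H, D = D, H2 = H2, n_features = as.integer(n_features),
      classes = as.character(classes),
      fwd = new_gru_cell(H, D), bwd = new_gru_cell(H, D),
      comb = list(Wf = matrix(runif(H * H, -1, 1) / sqrt(H), H, H),
                  Wb = matrix(runif(H * H, -1, 1) / sqrt(H), H, H),
                  bc = rep(0, H)),
      att = list(Wa = matrix(runif(H * H, -1, 1) / sqrt(H), H, H),
                 ba = rep(0, H), va = runif(H, -1, 1) / sqrt(H)),
      head = list(W1 = matrix(runif(H2 * H, -1, 1) / sqrt(H), H2, H),
                  b1 = rep(0, H2),
                  W2 = matrix(runif(2 * H2, -1, 1) / sqrt(H2), 2, H2),
                  b2 = rep(0, 2)))
    class(model) <- "abigru_model"
    model
  })
}

#' @export
print.abigru_model <- function(x, ...) {
  cat("<abigru_model> H =", x$H, "; head =", x$H2,
      "; sequence length =", x$n_features,
      "; classes:", paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

#' One GRU cell step
#'
#' Gated recurrent unit update: reset gate `r = sigmoid(Wr [h, x] + br)`,
#' update gate `z = sigmoid(Wz [h, x] + bz)`, candidate state
#' `h~ = tanh(Wh [r*h, x] + bh)`, output `h' = (1-z)*h + z*h~`. The output
#' is a convex combination of the previous state and the candidate,
#' componentwise.
#'
#' @param x_t Input vector at this timestep (length D).
#' @param h_prev Previous hidden state (length H).
#' @param cell List with `Wr`, `Wz`, `Wh` (H x (H+D)) and biases `br`,
#'   `bz`, `bh`.
#' @return The new hidden state (length H).
#' @export
gru_step <- function(x_t, h_prev, cell) {
  gru_step_cache(x_t, h_prev, cell)$h
}

gru_step_cache <- function(x_t, h_prev, cell) {
  H <- length(h_prev)
  if (length(x_t) + H != ncol(cell$Wr)) stop("gru_step: shape mismatch")
  ci <- c(h_prev, x_t)
  r <- sigmoid(drop(cell$Wr %*% ci) + cell$br)
  z <- sigmoid(drop(cell$Wz %*% ci) + cell$bz)
  hh <- tanh(drop(cell$Wh %*% c(r * h_prev, x_t)) + cell$bh)
  h <- (1 - z) * h_prev + z * hh
  list(h = h, r = r, z = z, hh = hh, h_prev = h_prev, x = x_t)
}

# Run one direction over the sequence; `steps` is the processing order over
# timesteps. Returns hidden states indexed by TIMESTEP plus caches in
# processing order.
gru_run <- function(xs, cell, steps, H) {
  hs <- matrix(0, H, nrow(xs))
  caches <- vector("list", length(steps))
  h <- rep(0, H)
  for (s in seq_along(steps)) {
    t <- steps[s]
    cc <- gru_step_cache(xs[t, ], h, cell)
    h <- cc$h
    hs[, t] <- h
    caches[[s]] <- cc
  }
  list(states = hs, caches = caches)
}

#' Bidirectional GRU forward pass
#'
#' Runs the forward cell left-to-right and the backward cell right-to-left,
#' then combines the two per-timestep hidden states with shared weights:
#' `h_t = Wf h_t_fwd + Wb h_t_bwd + bc`.
#'
#' @param x_seq Sequence as a T x D matrix (a plain vector is treated as
#'   T x 1).
#' @param model An `abigru_model`.
#' @return H x T matrix of combined hidden states.
#' @export
bigru_forward <- function(x_seq, model) {
  bigru_forward_cache(x_seq, model)$combined
}

bigru_forward_cache <- function(x_seq, model) {
  if (is.null(dim(x_seq))) x_seq <- matrix(x_seq, ncol = model$D)
  T_ <- nrow(x_seq)
  if (T_ < 1) stop("empty sequence")
  fw <- gru_run(x_seq, model$fwd, seq_len(T_), model$H)
  bw <- gru_run(x_seq, model$bwd, rev(seq_len(T_)), model$H)
  combined <- model$comb$Wf %*% fw$states + model$comb$Wb %*% bw$states +
    model$comb$bc
  list(combined = combined, fw = fw, bw = bw, x = x_seq)
}

#' Attention pooling over hidden states
#'
#' Scores each timestep with `e_t = va . tanh(Wa h_t + ba)`, normalizes the
#' scores with a (max-stabilized) softmax, and returns the weighted sum of
#' the states as the context vector.
#'
#' @param states H x T matrix of per-timestep hidden states.
#' @param att List with `Wa` (H x H), `ba` (H), `va` (H).
#' @return List with `context` (length H) and `weights` (length T,
#'   nonnegative, summing to 1).
#' @export
attention_pool <- function(states, att) {
  states <- as.matrix(states)
  if (ncol(states) < 1) stop("attention_pool needs at least one state")
  u <- tanh(att$Wa %*% states + att$ba)
  e <- drop(crossprod(u, att$va))
  a <- exp(e - max(e))
  a <- a / sum(a)
  list(context = drop(states %*% a), weights = a, scores = e, u = u)
}

#' Recast a tabular row as a sequence
#'
#' Feature `j` becomes timestep `j` with a scalar input, in the
#' (post-selection) column order.
#'
#' @param row Numeric feature vector.
#' @param mask Optional logical feature mask applied first.
#' @return T x 1 matrix.
#' @export
row_to_sequence <- function(row, mask = NULL) {
  if (!is.null(mask)) row <- row[mask]
  if (!length(row)) stop("empty row after masking")
  matrix(as.numeric(row), ncol = 1)
}

relu <- function(x) pmax(x, 0)

softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# Full forward pass for one row with caches; dropout_mask (H x T, already
# scaled by 1/(1-p)) multiplies the combined states during training.
abigru_forward_cache <- function(x_seq, model, dropout_mask = NULL) {
  bg <- bigru_forward_cache(x_seq, model)
  C <- bg$combined
  if (!is.null(dropout_mask)) C <- C * dropout_mask
  at <- attention_pool(C, model$att)
  a1 <- drop(model$head$W1 %*% at$context) + model$head$b1
  z1 <- relu(a1)
  logits <- drop(model$head$W2 %*% z1) + model$head$b2
  p <- softmax(logits)
  list(bg = bg, C = C, dropout_mask = dropout_mask, at = at,
       a1 = a1, z1 = z1, logits = logits, p = p)
}

zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))

zero_grads <- function(model) {
  g <- list()
  for (blk in c("fwd", "bwd", "comb", "att", "head"))
    g[[blk]] <- lapply(model[[blk]], zero_like)
  g
}

# Backprop through one GRU direction. caches are in processing order;
# dstates is H x T indexed by timestep; steps is the processing order used
# in the forward pass. Accumulates into g (a cell-shaped grad list).
gru_backward <- function(cell, caches, dstates, steps, g) {
  H <- length(cell$br)
  carry <- rep(0, H)
  for (s in rev(seq_along(steps))) {
    t <- steps[s]
    cc <- caches[[s]]
    dh <- dstates[, t] + carry
    dz <- dh * (cc$hh - cc$h_prev)
    dhh <- dh * cc$z
    dh_prev <- dh * (1 - cc$z)
    da_h <- dhh * (1 - cc$hh^2)
    g$Wh <- g$Wh + da_h %o% c(cc$r * cc$h_prev, cc$x)
    g$bh <- g$bh + da_h
    drh <- drop(crossprod(cell$Wh[, seq_len(H), drop = FALSE], da_h))
    dr <- drh * cc$h_prev
    dh_prev <- dh_prev + drh * cc$r
    da_r <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + da_r %o% c(cc$h_prev, cc$x)
    g$br <- g$br + da_r
    dh_prev <- dh_prev + drop(crossprod(cell$Wr[, seq_len(H), drop = FALSE], da_r))
    da_z <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + da_z %o% c(cc$h_prev, cc$x)
    g$bz <- g$bz + da_z
    dh_prev <- dh_prev + drop(crossprod(cell$Wz[, seq_len(H), drop = FALSE], da_z))
    carry <- dh_prev
  }
  g
}

# Mean cross-entropy and analytic gradients over a batch.
# X: n x T matrix; y_idx: 1/2 class indices; masks: optional list of H x T
# dropout masks (pre-scaled).
abigru_loss_grad <- function(model, X, y_idx, masks = NULL) {
  n <- nrow(X)
  g <- zero_grads(model)
  loss <- 0
  for (i in seq_len(n)) {
    fc <- abigru_forward_cache(row_to_sequence(X[i, ]), model,
                               dropout_mask = if (is.null(masks)) NULL else masks[[i]])
    loss <- loss - log(max(fc$p[y_idx[i]], 1e-300))
    dlog <- fc$p
    dlog[y_idx[i]] <- dlog[y_idx[i]] - 1
    # head
    g$head$W2 <- g$head$W2 + dlog %o% fc$z1
    g$head$b2 <- g$head$b2 + dlog
    dz1 <- drop(crossprod(model$head$W2, dlog)) * (fc$a1 > 0)
    g$head$W1 <- g$head$W1 + dz1 %o% fc$at$context
    g$head$b1 <- g$head$b1 + dz1
    dV <- drop(crossprod(model$head$W1, dz1))
    # attention
    C <- fc$C
    T_ <- ncol(C)
    a <- fc$at$weights
    dC <- matrix(0, model$H, T_)
    da <- drop(crossprod(C, dV))
    dC <- dC + dV %o% a
    de <- a * (da - sum(a * da))
    u <- fc$at$u
    g$att$va <- g$att$va + drop(u %*% de)
    du <- model$att$va %o% de
    dpre <- du * (1 - u^2)
    g$att$Wa <- g$att$Wa + dpre %*% t(C)
    g$att$ba <- g$att$ba + rowSums(dpre)
    dC <- dC + crossprod(model$att$Wa, dpre)
    # dropout
    if (!is.null(fc$dropout_mask)) dC <- dC * fc$dropout_mask
    # direction combination
    hf <- fc$bg$fw$states
    hb <- fc$bg$bw$states
    g$comb$Wf <- g$comb$Wf + dC %*% t(hf)
    g$comb$Wb <- g$comb$Wb + dC %*% t(hb)
    g$comb$bc <- g$comb$bc + rowSums(dC)
    dhf <- crossprod(model$comb$Wf, dC)
    dhb <- crossprod(model$comb$Wb, dC)
    T_steps <- seq_len(nrow(fc$bg$x))
    g$fwd <- gru_backward(model$fwd, fc$bg$fw$caches, dhf, T_steps, g$fwd)
    g$bwd <- gru_backward(model$bwd, fc$bg$bw$caches, dhb, rev(T_steps), g$bwd)
  }
  scale <- 1 / n
  for (blk in c("fwd", "bwd", "comb", "att", "head"))
    g[[blk]] <- lapply(g[[blk]], function(m) m * scale)
  list(loss = loss / n, grads = g)
}

# Flatten / restore all trainable parameters (used by the finite-difference
# gradient check).
abigru_get_params <- function(model) {
  unlist(lapply(c("fwd", "bwd", "comb", "att", "head"),
                function(blk) lapply(model[[blk]], as.numeric)))
}

abigru_set_params <- function(model, theta) {
  k <- 1
  for (blk in c("fwd", "bwd", "comb", "att", "head")) {
    for (nm in names(model[[blk]])) {
      len <- length(model[[blk]][[nm]])
      v <- theta[k:(k + len - 1)]
      if (is.matrix(model[[blk]][[nm]]))
        model[[blk]][[nm]][] <- v
      else model[[blk]][[nm]] <- v
      k <- k + len
    }
  }
  model
}

#' Train the attention BiGRU by mini-batch gradient descent
#'
#' Minimizes mean cross-entropy with plain gradient descent at the
#' configured learning rate; dropout is applied to the combined hidden
#' states during training only (inverted scaling). The loss history records
#' the full-data loss (dropout disabled) after each epoch.
#'
#' @param model An `abigru_model` (or `NULL` to initialize one from the data
#'   shape).
#' @param x Numeric matrix (rows = samples, columns = sequence positions) or
#'   a [feature_table()].
#' @param y Two-class label vector (ignored when `x` is a feature table).
#' @param cfg A [train_config()].
#' @return List with `model` (trained) and `loss_history`.
#' @export
train_abigru <- function(model, x, y = NULL, cfg = train_config()) {
  if (inherits(x, "feature_table")) { y <- x$y; x <- x$x }
  x <- as.matrix(x)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need both classes present in training labels")
  if (is.null(model))
    model <- init_abigru(ncol(x), classes = levels(y), seed = cfg$seed %||% 1L)
  if (ncol(x) != model$n_features)
    stop("feature count (", ncol(x), ") does not match model (", model$n_features, ")")
  y_idx <- as.integer(factor(as.character(y), levels = model$classes))
  if (anyNA(y_idx)) stop("labels outside the model's classes")
  n <- nrow(x)
  p <- cfg$dropout
  blks <- c("fwd", "bwd", "comb", "att", "head")
  opt_m <- opt_v <- NULL
  if (identical(cfg$optimizer %||% "adam", "adam")) {
    opt_m <- lapply(setNames(blks, blks), function(b) lapply(model[[b]], zero_like))
    opt_v <- opt_m
  }
  step <- 0
  loss_history <- numeric(cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1, n)]
        masks <- if (p > 0)
          lapply(idx, function(i)
            matrix(rbinom(model$H * model$n_features, 1, 1 - p), model$H) / (1 - p))
        else NULL
        lg <- abigru_loss_grad(model, x[idx, , drop = FALSE], y_idx[idx], masks)
        if (!is.finite(lg$loss)) stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
        lr <- cfg$learning_rate
        if (is.null(opt_m)) {
          for (blk in blks)
            for (nm in names(model[[blk]]))
              model[[blk]][[nm]] <- model[[blk]][[nm]] - lr * lg$grads[[blk]][[nm]]
        } else {
          step <- step + 1
          for (blk in blks)
            for (nm in names(model[[blk]])) {
              g <- lg$grads[[blk]][[nm]]
              opt_m[[blk]][[nm]] <- 0.9 * opt_m[[blk]][[nm]] + 0.1 * g
              opt_v[[blk]][[nm]] <- 0.999 * opt_v[[blk]][[nm]] + 0.001 * g^2
              mh <- opt_m[[blk]][[nm]] / (1 - 0.9^step)
              vh <- opt_v[[blk]][[nm]] / (1 - 0.999^step)
              model[[blk]][[nm]] <- model[[blk]][[nm]] - lr * mh / (sqrt(vh) + 1e-8)
            }
        }
      }
      loss_history[ep] <- abigru_loss_grad(model, x, y_idx)$loss
    }
  })
  list(model = model, loss_history = loss_history)
}

#' Predict class probabilities and labels
#'
#' Deterministic at inference (no dropout). Ties go to the positive
#' (second) class.
#'
#' @param model A trained `abigru_model`.
#' @param x Numeric matrix or [feature_table()] with the model's feature
#'   count.
#' @return List with `prob` (n x 2 matrix, columns named by class) and
#'   `label` (factor).
#' @export
predict_abigru <- function(model, x) {
  if (inherits(x, "feature_table")) x <- x$x
  x <- as.matrix(x)
  if (ncol(x) != model$n_features)
    stop("feature count (", ncol(x), ") does not match model (", model$n_features, ")")
  prob <- t(vapply(seq_len(nrow(x)), function(i)
    abigru_forward_cache(row_to_sequence(x[i, ]), model)$p, numeric(2)))
  colnames(prob) <- model$classes
  lab <- ifelse(prob[, 2] >= prob[, 1], model$classes[2], model$classes[1])
  list(prob = prob, label = factor(lab, levels = model$classes))
}
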