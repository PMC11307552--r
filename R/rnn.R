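# Minimal bidirectional recurrent sequence classifier.
#
# Architecture: two stacked bidirectional tanh-recurrent layers (the first
# emitting its full output sequence, the second only its final state per
# direction), followed by a 2-way linear readout with softmax. This
# mirrors the bilstm(sequence) -> bilstm(last) -> dense(2) -> softmax
# stack commonly used for spike-sequence classification, with plain tanh
# recurrence instead of LSTM gates: the sequences here are short (<= 100
# bins) so gating is unnecessary, and the whole network stays dependency
# free. Trained with Adam, exact BPTT gradients (verified against finite
# differences in the test suite) and global-norm gradient clipping.
#
# Implementation note: all input-to-hidden products are computed in one
# BLAS call over a (n * T) x D stack of timesteps; only the small
# hidden-to-hidden recurrence runs sequentially.

rnn_init <- function(input_dim, hidden, seed = 1L) {
  with_seed_(seed, {
    glorot <- function(nin, nout)
      matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)),
             nin, nout)
    H <- hidden
    list(
      l1f.Wx = glorot(input_dim, H), l1f.Wh = glorot(H, H) * 0.5,
      l1f.b = numeric(H),
      l1b.Wx = glorot(input_dim, H), l1b.Wh = glorot(H, H) * 0.5,
      l1b.b = numeric(H),
      l2f.Wx = glorot(2 * H, H), l2f.Wh = glorot(H, H) * 0.5,
      l2f.b = numeric(H),
      l2b.Wx = glorot(2 * H, H), l2b.Wh = glorot(H, H) * 0.5,
      l2b.b = numeric(H),
      out.W = glorot(2 * H, 2), out.b = numeric(2))
  })
}

# One direction of a recurrent layer over a timestep stack.
# zstack: (n*T) x D, rows grouped by timestep. Returns the (n*T) x H
# state stack (same row layout).
rnn_layer_run_stack <- function(zstack, n, T_, Wx, Wh, b,
                                reverse = FALSE) {
  H <- ncol(Wh)
  inp <- zstack %*% Wx
  inp <- inp + rep(b, each = nrow(inp))
  hstack <- matrix(0, n * T_, H)
  h <- matrix(0, n, H)
  idx <- if (reverse) T_:1 else 1:T_
  for (t in idx) {
    rows <- ((t - 1) * n + 1):(t * n)
    h <- tanh(inp[rows, , drop = FALSE] + h %*% Wh)
    hstack[rows, ] <- h
  }
  hstack
}

# Forward pass. X: n x T matrix of (binary) inputs, input_dim 1.
rnn_forward <- function(params, X, keep = FALSE) {
  n <- nrow(X)
  T_ <- ncol(X)
  xstack <- matrix(as.numeric(X), n * T_, 1)   # column-stacked timesteps
  h1f <- rnn_layer_run_stack(xstack, n, T_, params$l1f.Wx, params$l1f.Wh,
                             params$l1f.b)
  h1b <- rnn_layer_run_stack(xstack, n, T_, params$l1b.Wx, params$l1b.Wh,
                             params$l1b.b, reverse = TRUE)
  zstack <- cbind(h1f, h1b)
  h2f <- rnn_layer_run_stack(zstack, n, T_, params$l2f.Wx, params$l2f.Wh,
                             params$l2f.b)
  h2b <- rnn_layer_run_stack(zstack, n, T_, params$l2b.Wx, params$l2b.Wh,
                             params$l2b.b, reverse = TRUE)
  last <- ((T_ - 1) * n + 1):(T_ * n)
  first <- 1:n
  U <- cbind(h2f[last, , drop = FALSE], h2b[first, , drop = FALSE])
  logits <- U %*% params$out.W + rep(params$out.b, each = n)
  m <- pmax(logits[, 1], logits[, 2])
  el <- exp(logits - m)
  probs <- el / rowSums(el)
  out <- list(probs = probs)
  if (keep)
    out$cache <- list(xstack = xstack, h1f = h1f, h1b = h1b,
                      zstack = zstack, h2f = h2f, h2b = h2b, U = U,
                      n = n, T_ = T_)
  out
}

# BPTT through one direction of a recurrent layer.
# dstack: external per-timestep gradients on the states ((n*T) x H).
# Returns dWx, dWh, db and the gradient w.r.t. the layer input stack.
rnn_layer_bptt <- function(dstack, hstack, zstack, n, T_, Wx, Wh,
                           reverse = FALSE) {
  H <- ncol(Wh)
  dastack <- matrix(0, n * T_, H)
  carry <- matrix(0, n, H)
  idx <- if (reverse) 1:T_ else T_:1      # reverse of the run order
  for (t in idx) {
    rows <- ((t - 1) * n + 1):(t * n)
    dh <- dstack[rows, , drop = FALSE] + carry
    da <- dh * (1 - hstack[rows, , drop = FALSE]^2)
    dastack[rows, ] <- da
    carry <- da %*% t(Wh)
  }
  # previous-state stack in run order: shift by one timestep
  hprev <- matrix(0, n * T_, H)
  if (T_ > 1) {
    if (reverse) {
      hprev[1:((T_ - 1) * n), ] <- hstack[(n + 1):(T_ * n), , drop = FALSE]
    } else {
      hprev[(n + 1):(T_ * n), ] <- hstack[1:((T_ - 1) * n), , drop = FALSE]
    }
  }
  list(dWx = t(zstack) %*% dastack,
       dWh = t(hprev) %*% dastack,
       db = colSums(dastack),
       dz = dastack %*% t(Wx))
}

# Cross-entropy loss and exact gradients for a batch. y: 0/1 (1 = pattern,
# second output unit).
rnn_loss_grads <- function(params, X, y) {
  fw <- rnn_forward(params, X, keep = TRUE)
  cc <- fw$cache
  n <- cc$n; T_ <- cc$T_
  H <- ncol(params$l1f.Wh)
  probs <- fw$probs
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), y + 1L)], 1e-12)))

  dlog <- (probs - cbind(1 - y, y)) / n
  g <- list()
  g$out.W <- t(cc$U) %*% dlog
  g$out.b <- colSums(dlog)
  dU <- dlog %*% t(params$out.W)

  # layer-2 state gradients enter only at the output timestep
  last <- ((T_ - 1) * n + 1):(T_ * n)
  d2f <- matrix(0, n * T_, H); d2f[last, ] <- dU[, 1:H]
  d2b <- matrix(0, n * T_, H); d2b[1:n, ] <- dU[, H + 1:H]
  b2f <- rnn_layer_bptt(d2f, cc$h2f, cc$zstack, n, T_, params$l2f.Wx,
                        params$l2f.Wh)
  b2b <- rnn_layer_bptt(d2b, cc$h2b, cc$zstack, n, T_, params$l2b.Wx,
                        params$l2b.Wh, reverse = TRUE)
  g$l2f.Wx <- b2f$dWx; g$l2f.Wh <- b2f$dWh; g$l2f.b <- b2f$db
  g$l2b.Wx <- b2b$dWx; g$l2b.Wh <- b2b$dWh; g$l2b.b <- b2b$db

  dz <- b2f$dz + b2b$dz
  b1f <- rnn_layer_bptt(dz[, 1:H, drop = FALSE], cc$h1f, cc$xstack, n, T_,
                        params$l1f.Wx, params$l1f.Wh)
  b1b <- rnn_layer_bptt(dz[, H + 1:H, drop = FALSE], cc$h1b, cc$xstack,
                        n, T_, params$l1b.Wx, params$l1b.Wh,
                        reverse = TRUE)
  g$l1f.Wx <- b1f$dWx; g$l1f.Wh <- b1f$dWh; g$l1f.b <- b1f$db
  g$l1b.Wx <- b1b$dWx; g$l1b.Wh <- b1b$dWh; g$l1b.b <- b1b$db
  list(loss = loss, grads = g[names(params)], probs = probs)
}

clip_global_norm <- function(grads, max_norm) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  grads
}

#' Training hyperparameters for the engram classifier
#'
#' Defaults follow the reference configuration (Adam, learning rate
#' 0.005, gradient clipping just below 1) with a desk-scaled epoch
#' ceiling: training stops early once training accuracy holds at 100%
#' for `patience` consecutive epochs, so `max_epochs` is a ceiling, not
#' a requirement.
#'
#' @param hidden Recurrent units per layer and direction (default 64).
#' @param max_epochs Epoch ceiling (default 200).
#' @param batch_size Minibatch size (default 250).
#' @param learning_rate Adam step size (default 0.005).
#' @param gradient_clip Global-norm gradient clip (default 0.99).
#' @param patience Consecutive perfect-accuracy epochs required to stop
#'   (default 2).
#' @param plateau_patience Epochs without loss improvement (by more than
#'   `1e-4`) tolerated before stopping with the best checkpoint
#'   (default 15).
#' @param seed Integer seed for initialization and shuffling.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(hidden = 64, max_epochs = 200, batch_size = 250,
                            learning_rate = 0.005, gradient_clip = 0.99,
                            patience = 2, plateau_patience = 15, seed = 1L) {
  assert_scalar_num(hidden, "hidden", 1)
  assert_scalar_num(max_epochs, "max_epochs", 1)
  assert_scalar_num(batch_size, "batch_size", 1)
  assert_scalar_num(learning_rate, "learning_rate", 0, strict_lower = TRUE)
  assert_scalar_num(gradient_clip, "gradient_clip", 0, strict_lower = TRUE)
  structure(list(hidden = as.integer(hidden),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 gradient_clip = gradient_clip,
                 patience = as.integer(patience),
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

# Core Adam training loop on matrices X (n x T) and labels y (0/1).
rnn_train <- function(X, y, spec, verbose = FALSE) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(y %in% c(0, 1)))
  params <- rnn_init(1L, spec$hidden, seed = spec$seed)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  perfect <- 0
  converged <- FALSE
  best_loss <- Inf
  best_params <- params
  stale <- 0
  plateau <- spec$plateau_patience %||% 15L
  with_seed_(derive_seed(spec$seed, 7919L), {
    for (ep in seq_len(spec$max_epochs)) {
      ord <- sample.int(nrow(X))
      ep_loss <- 0; ep_n <- 0; ep_correct <- 0
      for (b in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        lg <- rnn_loss_grads(params, X[b, , drop = FALSE], y[b])
        gr <- clip_global_norm(lg$grads, spec$gradient_clip)
        step <- step + 1
        for (k in names(params)) {
          m[[k]] <- b1 * m[[k]] + (1 - b1) * gr[[k]]
          v[[k]] <- b2 * v[[k]] + (1 - b2) * gr[[k]]^2
          mh <- m[[k]] / (1 - b1^step)
          vh <- v[[k]] / (1 - b2^step)
          params[[k]] <- params[[k]] -
            spec$learning_rate * mh / (sqrt(vh) + eps)
        }
        ep_loss <- ep_loss + lg$loss * length(b)
        ep_n <- ep_n + length(b)
        ep_correct <- ep_correct +
          sum((lg$probs[, 2] >= 0.5) == (y[b] == 1))
      }
      acc <- ep_correct / ep_n
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / ep_n,
                                           accuracy = acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep,
                        ep_loss / ep_n, acc))
      if (ep_loss / ep_n < best_loss - 1e-4) {
        best_loss <- ep_loss / ep_n
        best_params <- params
        stale <- 0
      } else stale <- stale + 1
      perfect <- if (acc >= 1) perfect + 1 else 0
      if (perfect >= spec$patience) { converged <- TRUE; break }
      if (stale >= plateau) break
    }
  })
  list(params = if (converged) params else best_params,
       history = history, converged = converged)
}

rnn_predict_probs <- function(params, X, chunk = 4096L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, 2)
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    out[i0:i1, ] <- rnn_forward(params, X[i0:i1, , drop = FALSE])$probs
  }
  out
}
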