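# Minimal LSTM sequence classifier in vectorised base R.
#
# One LSTM layer (hidden state read out at the last time step) feeding a dense
# softmax layer, trained with Adam on sparse categorical cross-entropy.
# Written here because no deep-learning backend is available; dimensions in
# play (S = 8 time steps, Q ~ 50 attributes, H = 128 units) keep full-batch
# matrix algebra cheap.
#
# Conventions: X is B x S x Q (batch, time, attributes), labels are 0-based
# integers. Gate weights are packed column-wise as [input, forget, cell,
# output] blocks of H columns each.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.orthogonal <- function(n, m) {
  # block-orthogonal recurrent init, one H x H block per gate
  a <- matrix(stats::rnorm(n * max(n, m)), max(n, m))
  q <- qr.Q(qr(a))[seq_len(n), seq_len(m), drop = FALSE]
  q
}

lstm_init <- function(Q, H, K) {
  lim_x <- sqrt(6 / (Q + 4 * H))
  Wx <- matrix(stats::runif(Q * 4 * H, -lim_x, lim_x), Q, 4 * H)
  Wh <- do.call(cbind, lapply(1:4, function(i) .orthogonal(H, H)))
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias 1: standard stability trick
  lim_y <- sqrt(6 / (H + K))
  Wy <- matrix(stats::runif(H * K, -lim_y, lim_y), H, K)
  by <- numeric(K)
  list(Wx = Wx, Wh = Wh, b = b, Wy = Wy, by = by, Q = Q, H = H, K = K)
}

lstm_forward <- function(par, X, keep_cache = FALSE) {
  B <- dim(X)[1]; S <- dim(X)[2]
  H <- par$H
  hs <- matrix(0, B, H)
  cs <- matrix(0, B, H)
  bmat <- matrix(par$b, B, 4 * H, byrow = TRUE)
  cache <- if (keep_cache) vector("list", S) else NULL
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  for (t in seq_len(S)) {
    Xt <- matrix(X[, t, ], B)
    Z <- Xt %*% par$Wx + hs %*% par$Wh + bmat
    i <- .sigmoid(Z[, gi, drop = FALSE])
    f <- .sigmoid(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    o <- .sigmoid(Z[, go, drop = FALSE])
    c_new <- f * cs + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                         c_prev = cs, h_prev = hs, tc = tc)
    }
    cs <- c_new
    hs <- h_new
  }
  logits <- hs %*% par$Wy + matrix(par$by, B, par$K, byrow = TRUE)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  list(probs = probs, h_last = hs, cache = cache)
}

lstm_loss_acc <- function(probs, y) {
  B <- nrow(probs)
  p <- pmax(probs[cbind(seq_len(B), y + 1L)], 1e-12)
  list(loss = -mean(log(p)),
       acc = mean(max.col(probs, ties.method = "first") - 1L == y))
}

lstm_backward <- function(par, X, y, fwd) {
  B <- dim(X)[1]; S <- dim(X)[2]
  H <- par$H; K <- par$K
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H)
  go <- (3 * H + 1):(4 * H)
  dlogit <- fwd$probs
  dlogit[cbind(seq_len(B), y + 1L)] <- dlogit[cbind(seq_len(B), y + 1L)] - 1
  dlogit <- dlogit / B
  grads <- list(Wy = crossprod(fwd$h_last, dlogit), by = colSums(dlogit),
                Wx = matrix(0, par$Q, 4 * H), Wh = matrix(0, H, 4 * H),
                b = numeric(4 * H))
  dh <- tcrossprod(dlogit, par$Wy)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(S))) {
    cc <- fwd$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_prev <- dc * cc$f
    dZ <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    grads$Wx <- grads$Wx + crossprod(cc$Xt, dZ)
    grads$Wh <- grads$Wh + crossprod(cc$h_prev, dZ)
    grads$b <- grads$b + colSums(dZ)
    dh <- tcrossprod(dZ, par$Wh)
    dc <- dc_prev
  }
  grads
}

adam_state <- function(par) {
  nm <- c("Wx", "Wh", "b", "Wy", "by")
  list(m = lapply(par[nm], function(x) x * 0),
       v = lapply(par[nm], function(x) x * 0),
       t = 0L)
}

adam_update <- function(par, grads, st, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(st$m)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}
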