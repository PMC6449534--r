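# Minimal neural-network layer library used by the passage and triage
# classifiers: dense, 1-D convolution over token positions, masked (Bi)LSTM,
# additive attention, dropout, softmax / sigmoid losses and an Adam
# optimizer. Forward passes cache what backward passes need; gradients are
# exact (verified against finite differences in the test suite).
#
# Conventions: batches of embedded passages are arrays (B, T, d); sequence
# lengths mask padded tail positions so padding never influences states.

# ---- RNG scoping -----------------------------------------------------------

# Evaluate `expr` under a local RNG seed without clobbering the caller's
# random state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  l <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -l, l), dim = dims)
}

# ---- Dense -----------------------------------------------------------------

dense_fwd <- function(X, W, b, relu = FALSE) {
  Z <- X %*% W + matrix(b, nrow(X), length(b), byrow = TRUE)
  list(out = if (relu) pmax(Z, 0) else Z, X = X, Z = Z)
}

dense_bwd <- function(X, Z, W, dout, relu = FALSE) {
  if (relu) dout <- dout * (Z > 0)
  list(dW = crossprod(X, dout), db = colSums(dout), dX = dout %*% t(W))
}

# ---- 1-D convolution over token positions ----------------------------------

# E: (B, T, d); W: (w*d, nf); returns relu'd feature maps (B, Tp, nf),
# Tp = T - w + 1. Column block k of W corresponds to token offset k.
conv1d_fwd <- function(E, W, b, w) {
  dims <- dim(E); B <- dims[1]; T <- dims[2]; d <- dims[3]
  Tp <- T - w + 1L
  stopifnot(Tp >= 1L)
  X2 <- matrix(0, B * Tp, w * d)
  for (k in seq_len(w)) {
    X2[, ((k - 1L) * d + 1L):(k * d)] <- matrix(E[, k:(k + Tp - 1L), , drop = FALSE], B * Tp, d)
  }
  Z <- X2 %*% W + matrix(b, B * Tp, length(b), byrow = TRUE)
  A <- pmax(Z, 0)
  list(out = array(A, dim = c(B, Tp, ncol(W))), X2 = X2, Z = Z, w = w,
       B = B, T = T, d = d, Tp = Tp)
}

conv1d_bwd <- function(cache, W, dout, need_dE = FALSE) {
  B <- cache$B; Tp <- cache$Tp; d <- cache$d; w <- cache$w
  dZ <- matrix(dout, B * Tp, ncol(W)) * (cache$Z > 0)
  dW <- crossprod(cache$X2, dZ)
  db <- colSums(dZ)
  dE <- NULL
  if (need_dE) {
    dX2 <- dZ %*% t(W)
    dE <- array(0, dim = c(B, cache$T, d))
    for (k in seq_len(w)) {
      dE[, k:(k + Tp - 1L), ] <- dE[, k:(k + Tp - 1L), , drop = FALSE] +
        array(dX2[, ((k - 1L) * d + 1L):(k * d)], dim = c(B, Tp, d))
    }
  }
  list(dW = dW, db = db, dE = dE)
}

# Valid conv length per sequence, at least 1 (all-pad inputs still produce a
# bias-driven column at position 1).
conv_lens <- function(lens, T, w) pmax(pmin(lens, T) - w + 1L, 1L)

# ---- Global max pooling with length masking --------------------------------

# A: (B, Tp, nf); lens: valid positions per batch item.
maxpool_fwd <- function(A, lens) {
  dims <- dim(A); B <- dims[1]; Tp <- dims[2]; nf <- dims[3]
  m <- matrix(aperm(A, c(2, 1, 3)), nrow = Tp)        # Tp x (B*nf), b fastest
  maskTB <- outer(seq_len(Tp), lens, `<=`)            # Tp x B
  m[!matrix(rep(maskTB, nf), nrow = Tp)] <- -Inf
  tm <- t(m)
  idx <- max.col(tm, ties.method = "first")
  vals <- tm[cbind(seq_len(nrow(tm)), idx)]
  list(out = matrix(vals, B, nf), idx = idx, B = B, Tp = Tp, nf = nf)
}

maxpool_bwd <- function(cache, dout) {
  B <- cache$B; Tp <- cache$Tp; nf <- cache$nf
  dA <- array(0, dim = c(B, Tp, nf))
  j <- seq_len(B * nf)
  bb <- ((j - 1L) %% B) + 1L
  ff <- ((j - 1L) %/% B) + 1L
  lin <- bb + (cache$idx - 1L) * B + (ff - 1L) * B * Tp
  dA[lin] <- dout[cbind(bb, ff)]
  dA
}

# ---- Masked LSTM -----------------------------------------------------------

lstm_init <- function(d, u) {
  list(Wx = glorot(d, 4 * u, c(d, 4 * u)),
       Wh = glorot(u, 4 * u, c(u, 4 * u)),
       b = c(rep(0, u), rep(1, u), rep(0, 2 * u)))  # forget-gate bias 1
}

# E: (B, T, d); lens: per-sequence valid length (0 allowed: state stays 0
# until treated as length-1 upstream). Returns final hidden states (B, u).
lstm_fwd <- function(E, lens, P) {
  dims <- dim(E); B <- dims[1]; T <- dims[2]
  u <- length(P$b) / 4L
  H <- matrix(0, B, u); C <- matrix(0, B, u)
  T_eff <- max(1L, min(T, max(lens)))   # masked tail steps are no-ops; skip them
  steps <- vector("list", T_eff)
  for (t in seq_len(T_eff)) {
    Xt <- matrix(E[, t, , drop = FALSE], B, dims[3])
    Z <- Xt %*% P$Wx + H %*% P$Wh + matrix(P$b, B, 4 * u, byrow = TRUE)
    i <- sigmoid(Z[, 1:u, drop = FALSE])
    f <- sigmoid(Z[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o <- sigmoid(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    Chat <- f * C + i * g
    tC <- tanh(Chat)
    Hhat <- o * tC
    m <- as.numeric(lens >= t)
    steps[[t]] <- list(Xt = Xt, i = i, f = f, g = g, o = o,
                       C_prev = C, H_prev = H, tC = tC, m = m)
    C <- m * Chat + (1 - m) * C
    H <- m * Hhat + (1 - m) * H
  }
  list(H = H, steps = steps, B = B, T = T, T_eff = T_eff, u = u)
}

lstm_bwd <- function(cache, P, dH_final, need_dE = TRUE) {
  B <- cache$B; T <- cache$T; u <- cache$u
  dWx <- array(0, dim = dim(P$Wx)); dWh <- array(0, dim = dim(P$Wh))
  db <- numeric(length(P$b))
  dH <- dH_final; dC <- matrix(0, B, u)
  dE <- if (need_dE) array(0, dim = c(B, T, nrow(P$Wx))) else NULL
  for (t in rev(seq_len(cache$T_eff))) {
    s <- cache$steps[[t]]
    m <- s$m
    dH_hat <- dH * m; dH_pass <- dH * (1 - m)
    dC_hat <- dC * m; dC_pass <- dC * (1 - m)
    do <- dH_hat * s$tC * s$o * (1 - s$o)
    dC2 <- dC_hat + dH_hat * s$o * (1 - s$tC^2)
    di <- dC2 * s$g * s$i * (1 - s$i)
    df <- dC2 * s$C_prev * s$f * (1 - s$f)
    dg <- dC2 * s$i * (1 - s$g^2)
    dZ <- cbind(di, df, dg, do)
    dWx <- dWx + crossprod(s$Xt, dZ)
    dWh <- dWh + crossprod(s$H_prev, dZ)
    db <- db + colSums(dZ)
    if (need_dE) dE[, t, ] <- dZ %*% t(P$Wx)
    dH <- dZ %*% t(P$Wh) + dH_pass
    dC <- dC2 * s$f + dC_pass
  }
  list(dWx = dWx, dWh = dWh, db = db, dE = dE)
}

# Reverse each sequence within its own length (tail padding stays in place).
reverse_seqs <- function(E, lens) {
  out <- array(0, dim = dim(E))
  for (b in seq_len(dim(E)[1])) {
    l <- min(lens[b], dim(E)[2])
    if (l > 0) out[b, 1:l, ] <- E[b, l:1, , drop = FALSE]
  }
  out
}

# Bidirectional LSTM over (B, T, d): concatenated final states (B, 2u).
bilstm_fwd <- function(E, lens, Pf, Pb) {
  lens1 <- pmax(lens, 1L)
  fw <- lstm_fwd(E, lens1, Pf)
  Erev <- reverse_seqs(E, lens1)
  bw <- lstm_fwd(Erev, lens1, Pb)
  list(H = cbind(fw$H, bw$H), fw = fw, bw = bw, lens1 = lens1)
}

bilstm_bwd <- function(cache, Pf, Pb, dH, need_dE = FALSE) {
  u <- cache$fw$u
  gf <- lstm_bwd(cache$fw, Pf, dH[, 1:u, drop = FALSE], need_dE = need_dE)
  gb <- lstm_bwd(cache$bw, Pb, dH[, (u + 1):(2 * u), drop = FALSE], need_dE = need_dE)
  dE <- NULL
  if (need_dE) dE <- gf$dE + reverse_seqs(gb$dE, cache$lens1)
  list(f = gf, b = gb, dE = dE)
}

# ---- Additive attention ----------------------------------------------------

attention_init <- function(m, a) {
  list(W = glorot(m, a, c(m, a)), b = numeric(a), v = glorot(a, 1, c(a)))
}

# H: (k, m) passage vectors. score_i = v' tanh(W h_i + b); weights softmax.
attention_fwd <- function(H, P) {
  Tn <- tanh(H %*% P$W + matrix(P$b, nrow(H), length(P$b), byrow = TRUE))
  s <- drop(Tn %*% P$v)
  w <- softmax_vec(s)
  doc <- drop(crossprod(H, w))
  list(weights = w, doc = doc, Tn = Tn, H = H)
}

attention_bwd <- function(cache, P, ddoc) {
  H <- cache$H; w <- cache$weights; Tn <- cache$Tn
  dH <- outer(w, ddoc)
  u <- drop(H %*% ddoc)
  ds <- w * (u - sum(w * u))
  dv <- drop(crossprod(Tn, ds))
  dpre <- outer(ds, drop(P$v)) * (1 - Tn^2)
  dW <- crossprod(H, dpre)
  db <- colSums(dpre)
  dH <- dH + dpre %*% t(P$W)
  list(dW = dW, db = db, dv = dv, dH = dH)
}

# ---- Activations, losses, dropout ------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# logits (B, K); y integer class index 1..K; optional per-example weights.
softmax_ce <- function(logits, y, wts = NULL) {
  P <- softmax_rows(logits)
  B <- nrow(P)
  if (is.null(wts)) wts <- rep(1, B)
  picked <- P[cbind(seq_len(B), y)]
  loss <- -sum(wts * log(pmax(picked, 1e-12))) / sum(wts)
  dZ <- P
  dZ[cbind(seq_len(B), y)] <- dZ[cbind(seq_len(B), y)] - 1
  dZ <- dZ * (wts / sum(wts))
  list(loss = loss, probs = P, dlogits = dZ)
}

sigmoid_bce <- function(logit, y) {
  p <- sigmoid(logit)
  loss <- -mean(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, probs = p, dlogits = (p - y) / length(y))
}

dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array((runif(length(X)) >= rate) / (1 - rate), dim = dim(X) %||% length(X))
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# ---- Parameter plumbing and Adam -------------------------------------------

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  for (nm in names(b)) if (!is.null(b[[nm]])) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)

# L2 penalty gradient on weight matrices (not biases / vectors).
apply_l2 <- function(grads, params, l2) {
  if (l2 <= 0) return(grads)
  for (nm in names(params)) {
    if (!is.null(dim(params[[nm]])) && length(dim(params[[nm]])) == 2L) {
      grads[[nm]] <- grads[[nm]] + 2 * l2 * params[[nm]]
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- Finite-difference gradient check (used by the test suite) -------------

numeric_grad <- function(f, params, nm, eps = 1e-5) {
  p <- params[[nm]]
  g <- p * 0
  for (i in seq_along(p)) {
    params[[nm]][i] <- p[i] + eps
    up <- f(params)
    params[[nm]][i] <- p[i] - eps
    dn <- f(params)
    params[[nm]][i] <- p[i]
    g[i] <- (up - dn) / (2 * eps)
  }
  g
}
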