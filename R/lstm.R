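# Masked many-to-one LSTM with Adam, implemented with vectorized base-R
# matrix algebra. Gate layout in all 4H-wide blocks: input (i), forget (f),
# cell candidate (g), output (o). Padding rows (mask FALSE) leave the hidden
# and cell state untouched, so predictions depend only on the unmasked
# prefix. Dropout follows the variational convention of recurrent networks:
# one input mask and one recurrent mask per word, reused at every timestep,
# with inverted scaling; evaluation is always deterministic.

sigmoid <- function(x) 1 / (1 + exp(-x))

# orthogonal matrix for recurrent weight init (QR of a standard normal)
orthogonal_init <- function(n) {
  q <- qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
  q * sign(diag(q))[col(q)]  # fix column signs for determinism across BLAS
}

glorot_uniform <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# parameter list; caller is responsible for seeding the RNG
lstm_init <- function(f, h, o) {
  W <- glorot_uniform(f, 4L * h)
  U <- do.call(cbind, lapply(1:4, function(k) orthogonal_init(h)))
  b <- numeric(4L * h)
  b[(h + 1L):(2L * h)] <- 1  # unit forget-gate bias stabilizes early training
  list(W = W, U = U, b = b,
       Wy = glorot_uniform(h, o), by = numeric(o))
}

# slice the (B x 15 x F) input array into per-timestep B x F matrices
slice_timesteps <- function(x, tmax) {
  b <- dim(x)[1]; f <- dim(x)[3]
  lapply(seq_len(tmax), function(t) matrix(x[, t, ], b, f))
}

# forward pass. dx (B x F) and dh (B x H) are dropout masks or NULL.
# Returns final hidden state and, if keep_cache, the per-step cache for BPTT.
lstm_forward <- function(params, x, mask, dx = NULL, dh_mask = NULL,
                         keep_cache = FALSE) {
  b <- dim(x)[1]
  h_dim <- nrow(params$Wy)
  tmax <- max(1L, max(which(colSums(mask) > 0), 0L))
  xs <- slice_timesteps(x, tmax)
  bmat <- matrix(params$b, b, length(params$b), byrow = TRUE)
  h <- matrix(0, b, h_dim)
  cc <- matrix(0, b, h_dim)
  idx_i <- seq_len(h_dim)
  idx_f <- idx_i + h_dim
  idx_g <- idx_f + h_dim
  idx_o <- idx_g + h_dim
  cache <- if (keep_cache) vector("list", tmax)
  for (t in seq_len(tmax)) {
    xt <- xs[[t]]
    if (!is.null(dx)) xt <- xt * dx
    hd <- if (!is.null(dh_mask)) h * dh_mask else h
    z <- xt %*% params$W + hd %*% params$U + bmat
    gi <- sigmoid(z[, idx_i, drop = FALSE])
    gf <- sigmoid(z[, idx_f, drop = FALSE])
    gg <- tanh(z[, idx_g, drop = FALSE])
    go <- sigmoid(z[, idx_o, drop = FALSE])
    c_new <- gf * cc + gi * gg
    tanh_c <- tanh(c_new)
    h_new <- go * tanh_c
    m <- as.numeric(mask[, t])
    if (keep_cache)
      cache[[t]] <- list(xt = xt, hd = hd, gi = gi, gf = gf, gg = gg, go = go,
                         c_prev = cc, tanh_c = tanh_c, m = m)
    # masked rows carry the previous state forward unchanged
    h <- h + m * (h_new - h)
    cc <- cc + m * (c_new - cc)
  }
  list(h = h, cache = cache, tmax = tmax)
}

# backpropagation through time. dh_final: gradient of the loss wrt the final
# hidden state (B x H). Returns gradients for W, U, b.
lstm_backward <- function(params, fwd, dh_final, dh_mask = NULL) {
  cache <- fwd$cache
  h_dim <- ncol(dh_final)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  dU <- matrix(0, nrow(params$U), ncol(params$U))
  db <- numeric(length(params$b))
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), h_dim)
  for (t in rev(seq_len(fwd$tmax))) {
    cc <- cache[[t]]
    m <- cc$m
    dh_new <- m * dh
    dc_new <- m * dc + dh_new * cc$go * (1 - cc$tanh_c^2)
    d_go <- dh_new * cc$tanh_c
    d_gi <- dc_new * cc$gg
    d_gf <- dc_new * cc$c_prev
    d_gg <- dc_new * cc$gi
    dz <- cbind(d_gi * cc$gi * (1 - cc$gi),
                d_gf * cc$gf * (1 - cc$gf),
                d_gg * (1 - cc$gg^2),
                d_go * cc$go * (1 - cc$go))
    dW <- dW + crossprod(cc$xt, dz)
    dU <- dU + crossprod(cc$hd, dz)
    db <- db + colSums(dz)
    dh_rec <- tcrossprod(dz, params$U)
    if (!is.null(dh_mask)) dh_rec <- dh_rec * dh_mask
    dh <- (1 - m) * dh + dh_rec
    dc <- (1 - m) * dc + dc_new * cc$gf
  }
  list(W = dW, U = dU, b = db)
}

apply_activation <- function(pre, activation) {
  switch(activation,
         relu = pmax(pre, 0),
         linear = pre,
         softmax = {
           e <- exp(pre - apply(pre, 1, max))
           e / rowSums(e)
         },
         stop_fmt("unknown activation '%s'", activation))
}

# loss value and gradient wrt the dense-layer preactivation.
# negative_cosine: L = -mean_b cos(y_b, t_b); categorical_cross_entropy:
# L = -mean_b sum_k t log p with p = softmax(pre).
loss_grad <- function(pre, y, targets, loss, activation) {
  b <- nrow(pre)
  if (loss == "negative_cosine") {
    ny <- pmax(sqrt(rowSums(y^2)), 1e-12)
    nt <- pmax(sqrt(rowSums(targets^2)), 1e-12)
    dot <- rowSums(y * targets)
    cosv <- dot / (ny * nt)
    dy <- -(targets / (ny * nt) - (cosv / ny^2) * y) / b
    dpre <- if (activation == "relu") dy * (pre > 0) else dy
    list(loss = -mean(cosv), dpre = dpre, metric = mean(cosv))
  } else {
    p <- pmin(pmax(y, 1e-12), 1)
    list(loss = -mean(rowSums(targets * log(p))),
         dpre = (y - targets) / b,
         metric = mean(max.col(y) == max.col(targets)))
  }
}

adam_state_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}
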