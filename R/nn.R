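# Minimal neural-network primitives used by the immunogenicity CNN.
# All layers operate on plain double matrices; convolutions over the
# sequence axis are expressed as k shifted matrix products so the heavy
# lifting stays in BLAS. Activations are laid out "position-blocked":
# a (B*P) x C matrix whose rows for position p are the contiguous block
# ((p-1)*B + 1):(p*B), which makes every kernel offset a contiguous
# row slice.

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# sample-major (B x P*C, columns position-major) -> position-blocked (B*P x C)
to_blocked <- function(X, n_channels) {
  B <- nrow(X)
  P <- ncol(X) / n_channels
  arr <- array(X, dim = c(B, n_channels, P))
  matrix(aperm(arr, c(1L, 3L, 2L)), nrow = B * P, ncol = n_channels)
}

linear_fwd <- function(X, W, b) {
  list(out = X %*% W + rep_row(b, nrow(X)), X = X)
}

linear_bwd <- function(dout, cache, W) {
  list(dX = dout %*% t(W),
       dW = crossprod(cache$X, dout),
       db = colSums(dout))
}

# 1-D convolution over positions, kernel size k, stride 1, valid padding.
# A: (B*P_in) x C_in position-blocked; W: (k*C_in) x C_out; b: C_out.
conv_fwd <- function(A, W, b, B, k) {
  C_in <- ncol(A)
  P_in <- nrow(A) / B
  P_out <- P_in - k + 1L
  out <- rep_row(b, B * P_out)
  for (o in seq_len(k) - 1L) {
    rows <- (o * B + 1L):((P_out + o) * B)
    wrows <- (o * C_in + 1L):((o + 1L) * C_in)
    out <- out + A[rows, , drop = FALSE] %*% W[wrows, , drop = FALSE]
  }
  list(out = out, A = A, B = B, k = k, C_in = C_in,
       P_in = P_in, P_out = P_out)
}

conv_bwd <- function(dout, cache, W) {
  B <- cache$B; k <- cache$k; C_in <- cache$C_in
  P_out <- cache$P_out
  dW <- matrix(0, nrow(W), ncol(W))
  dA <- matrix(0, nrow(cache$A), C_in)
  for (o in seq_len(k) - 1L) {
    rows <- (o * B + 1L):((P_out + o) * B)
    wrows <- (o * C_in + 1L):((o + 1L) * C_in)
    Aslice <- cache$A[rows, , drop = FALSE]
    dW[wrows, ] <- crossprod(Aslice, dout)
    dA[rows, ] <- dA[rows, , drop = FALSE] +
      dout %*% t(W[wrows, , drop = FALSE])
  }
  list(dA = dA, dW = dW, db = colSums(dout))
}

relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, mask = X > 0)
}

relu_bwd <- function(dout, cache) dout * cache$mask

# Batch normalization over rows, per column. `state` carries running
# mean/var for inference; population variance, epsilon 1e-5, momentum 0.9.
bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9,
                   eps = 1e-5) {
  N <- nrow(X)
  if (training && N > 1L) {
    mu <- colMeans(X)
    xc <- X - rep_row(mu, N)
    v <- colMeans(xc * xc)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xc <- X - rep_row(mu, N)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep_row(inv, N)
  out <- xhat * rep_row(gamma, N) + rep_row(beta, N)
  list(out = out, xhat = xhat, inv = inv, gamma = gamma, state = state)
}

bn_bwd <- function(dout, cache) {
  N <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep_row(cache$gamma, N)
  s1 <- colSums(dxhat) / N
  s2 <- colSums(dxhat * xhat) / N
  dX <- (dxhat - rep_row(s1, N) - xhat * rep_row(s2, N)) *
    rep_row(cache$inv, N)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# Inverted dropout; identity at inference.
dropout_fwd <- function(X, rate, training) {
  if (!training || rate <= 0) {
    return(list(out = X, mask = NULL, rate = rate))
  }
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X), ncol(X))
  list(out = X * mask / (1 - rate), mask = mask, rate = rate)
}

dropout_bwd <- function(dout, cache) {
  if (is.null(cache$mask)) return(dout)
  dout * cache$mask / (1 - cache$rate)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softplus <- function(z) ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))

# Weighted binary cross-entropy from logits; returns mean loss and dL/dz.
bce_from_logits <- function(z, y, w) {
  n <- length(z)
  loss <- sum(w * (softplus(z) - y * z)) / n
  dz <- w * (sigmoid(z) - y) / n
  list(loss = loss, dz = dz)
}

# He-normal initialization.
init_weight <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
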