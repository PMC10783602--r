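# Minimal neural-network primitives: single-hidden-layer perceptrons with
# hand-written backpropagation and an Adam optimizer over nested parameter
# lists. Everything is plain base-R matrix algebra, deterministic given the
# seed, which keeps training bit-reproducible.

# each activation provides f(x) and dmul(dY, R): the chain-rule product
# dY * f'(A) expressed through the cached output R = f(A), avoiding a
# second pass over the preactivations
activation_fns <- function(name) {
  switch(name,
    relu = list(f = function(x) x * (x > 0),
                dmul = function(dY, R) dY * (R > 0)),
    tanh = list(f = tanh,
                dmul = function(dY, R) dY * (1 - R^2)),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

# zero_out: start the output layer at zero (used for the prediction heads)
# so initial scores vanish, every ranking pair is active, and early
# gradients are dominated by the signal shared across slides rather than by
# per-slide noise directions
mlp_init <- function(d_in, hidden, d_out, zero_out = FALSE) {
  list(
    W1 = matrix(stats::rnorm(d_in * hidden, 0, sqrt(2 / d_in)), d_in, hidden),
    b1 = numeric(hidden),
    W2 = if (zero_out) matrix(0, hidden, d_out) else
      matrix(stats::rnorm(hidden * d_out, 0, sqrt(2 / hidden)), hidden, d_out),
    b2 = numeric(d_out)
  )
}

add_rowvec <- function(A, b) A + rep(b, each = nrow(A))

mlp_forward <- function(p, X, act) {
  A <- add_rowvec(X %*% p$W1, p$b1)
  R <- act$f(A)
  Y <- add_rowvec(R %*% p$W2, p$b2)
  list(Y = Y, R = R, X = X)
}

mlp_backward <- function(p, cache, dY, act) {
  dW2 <- crossprod(cache$R, dY)
  db2 <- colSums(dY)
  dR <- tcrossprod(dY, p$W2)
  dA <- act$dmul(dR, cache$R)
  dW1 <- crossprod(cache$X, dA)
  db1 <- colSums(dA)
  dX <- tcrossprod(dA, p$W1)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dX = dX)
}

# EdgeConv layer, factorized so the large matrix products run at node
# level rather than edge level. For the perceptron input
# Z = [h_dst || h_src - h_dst], the hidden preactivation is
#   Z W1 + b1 = (H (W1a - W1b))[dst, ] + (H W1b + b1)[src, ]
# with W1 = rbind(W1a, W1b); the output bias contributes deg(m) * b2 to
# the neighbour sum and is added after scattering. The same factorization
# applies to the gradients after scattering dA by dst and src.
edgeconv_layer_forward <- function(p, H, src, dst, n, act) {
  d_in <- ncol(H)
  W1a <- p$W1[seq_len(d_in), , drop = FALSE]
  W1b <- p$W1[d_in + seq_len(d_in), , drop = FALSE]
  P <- H %*% (W1a - W1b)
  Q <- add_rowvec(H %*% W1b, p$b1)
  R <- act$f(P[dst, , drop = FALSE] + Q[src, , drop = FALSE])
  Hout <- scatter_sum(R %*% p$W2, dst, n)
  deg <- tabulate(dst, n)
  Hout <- Hout + deg %o% p$b2
  list(H = Hout, R = R)
}

edgeconv_layer_backward <- function(p, cache, Hprev, dH, src, dst, n, act) {
  d_in <- ncol(Hprev)
  W1a <- p$W1[seq_len(d_in), , drop = FALSE]
  W1b <- p$W1[d_in + seq_len(d_in), , drop = FALSE]
  dM <- dH[dst, , drop = FALSE]
  dW2 <- crossprod(cache$R, dM)
  db2 <- colSums(dM)
  dR <- tcrossprod(dM, p$W2)
  dA <- act$dmul(dR, cache$R)
  db1 <- colSums(dA)
  S_dst <- scatter_sum(dA, dst, n)
  S_src <- scatter_sum(dA, src, n)
  dW1a <- crossprod(Hprev, S_dst)
  dW1srcT <- crossprod(Hprev, S_src)
  dW1 <- rbind(dW1a, dW1srcT - dW1a) # [H_dst' dA ; (H_src - H_dst)' dA]
  dHprev <- tcrossprod(S_dst, W1a - W1b) + tcrossprod(S_src, W1b)
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dHprev = dHprev)
}

# sum rows of M into n output rows by integer group index; appending a
# zero row per group guarantees every group 1..n appears, so the rowsum
# result is already in output order (no rowname round-trip)
scatter_sum <- function(M, idx, n) {
  rs <- rowsum(rbind(M, matrix(0, n, ncol(M))), c(idx, seq_len(n)))
  dimnames(rs) <- NULL
  rs
}

# Adam over nested lists of numeric leaves (PyTorch-style L2 weight decay
# folded into the gradient)
adam_init <- function(params) {
  zeros <- function(x) {
    if (is.list(x)) lapply(x, zeros) else x * 0
  }
  list(m = zeros(params), v = zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, weight_decay = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(rec, p, g, m, v)
      list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
           v = lapply(r, `[[`, "v"))
    } else {
      g <- g + weight_decay * p
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
    }
  }
  r <- rec(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}
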