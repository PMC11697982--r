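# Internal neural-network primitives: single-hidden-layer MLPs with tanh
# activations, analytic backprop, and an Adam optimizer operating on the
# flattened parameter vector.  Parameters are plain nested lists of numeric
# matrices/vectors so they can be unlist()ed and relist()ed losslessly.

mlp_new <- function(d_in, d_out, hidden, zero_last = TRUE) {
  # zero-initialized output layer => network starts as the zero map, which
  # gives identity-start coupling layers and residual dynamics
  list(
    W1 = matrix(stats::rnorm(d_in * hidden, sd = sqrt(1 / max(1, d_in))),
                d_in, hidden),
    b1 = numeric(hidden),
    W2 = if (zero_last) matrix(0, hidden, d_out) else
      matrix(stats::rnorm(hidden * d_out, sd = sqrt(1 / hidden)), hidden, d_out),
    b2 = numeric(d_out)
  )
}

mlp_forward <- function(par, X, cache = FALSE) {
  H <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  Y <- sweep(H %*% par$W2, 2, par$b2, "+")
  if (cache) list(out = Y, X = X, H = H) else list(out = Y)
}

mlp_backward <- function(par, cache, dY) {
  dW2 <- crossprod(cache$H, dY)
  db2 <- colSums(dY)
  dH <- dY %*% t(par$W2)
  dZ <- dH * (1 - cache$H^2)
  dW1 <- crossprod(cache$X, dZ)
  db1 <- colSums(dZ)
  dX <- dZ %*% t(par$W1)
  list(dX = dX, grad = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# Residual parameterization y + net(y): identity at initialization.
res_forward <- function(par, X, cache = FALSE) {
  mf <- mlp_forward(par, X, cache = cache)
  out <- X + mf$out
  if (cache) list(out = out, mlp = mf) else list(out = out)
}

res_backward <- function(par, cache, dY) {
  mb <- mlp_backward(par, cache$mlp, dY)
  list(dX = dY + mb$dX, grad = mb$grad)
}

# Exact Jacobian of a residual MLP at a single point y (q x q, rows = outputs).
res_jacobian <- function(par, y) {
  h <- tanh(drop(y %*% par$W1) + par$b1)
  v <- 1 - h^2
  M <- par$W1 %*% (v * par$W2)     # M[j, k] = d out_k / d y_j
  diag(length(y)) + t(M)
}

# ---- Adam on the flattened parameter tree ----------------------------------

adam_new <- function(params) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adam_step <- function(params, grad_flat, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  theta <- unlist(params, use.names = FALSE)
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad_flat
  state$v <- beta2 * state$v + (1 - beta2) * grad_flat^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(params = utils::relist(theta, params), state = state)
}

flat_grad <- function(grad_tree) unlist(grad_tree, use.names = FALSE)

tree_add <- function(a, b) {
  if (is.list(a)) Map(tree_add, a, b) else a + b
}

tree_zero <- function(x) {
  if (is.list(x)) lapply(x, tree_zero) else x * 0
}

# Seeds derived from a master seed stay below 2^31 (exact in doubles).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919 + 12345) %%
               2147483629)
}
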