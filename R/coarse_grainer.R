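#' Construct an invertible coarse-graining map
#'
#' Builds a stack of affine coupling layers (RealNVP-style) defining a
#' bijection \eqn{\psi: R^p \to R^p}.  Coarse-graining \eqn{\phi(x)} keeps the
#' first \eqn{q} coordinates of \eqn{\psi(x)} and discards the rest
#' (information discarding); anti-coarse-graining \eqn{\phi^\dagger(y)}
#' re-pads the discarded coordinates with standard-normal noise and applies
#' \eqn{\psi^{-1}}.  Encoder and decoder therefore share all parameters and
#' \eqn{\phi^\dagger \approx \phi^{-1}} by construction.
#'
#' Each coupling layer splits the coordinates by an alternating even/odd
#' index mask, passes one half through unchanged, and applies an elementwise
#' affine transform \code{b * exp(s(a)) + t(a)} to the other half, where the
#' scale \code{s} (bounded through tanh for conditioning) and shift \code{t}
#' come from a small MLP.  Output heads are zero-initialized so the map
#' starts as the identity.
#'
#' @param p Micro-state dimension.
#' @param q Macro-state dimension, \code{1 <= q <= p}.
#' @param n_layers Number of coupling layers (>= 1).
#' @param hidden Hidden width of each conditioner MLP.
#' @param seed Integer seed for parameter initialization.
#' @return An object of class \code{invertible_map}.
#' @examples
#' psi <- coarse_grainer(4, 2, seed = 1)
#' x <- matrix(rnorm(8), 2, 4)
#' y <- encode(psi, x)            # 2 x 2 macro states
#' @export
coarse_grainer <- function(p, q = p, n_layers = 3, hidden = 32, seed = 1) {
  stopifnot(p >= 1)
  if (q < 1 || q > p) stop("invalid parameter: q must satisfy 1 <= q <= p")
  if (n_layers < 1) stop("invalid parameter: n_layers must be >= 1")
  layers <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_layers), function(l) {
      odd <- seq(1, p, by = 2)
      even <- if (p >= 2) seq(2, p, by = 2) else integer(0)
      if (l %% 2 == 1) {
        A <- odd; B <- even
      } else {
        A <- even; B <- odd
      }
      if (length(B) == 0 || length(A) == 0) {
        list(A = A, B = B, net = NULL)      # p == 1: identity layer
      } else {
        list(A = A, B = B, net = mlp_new(length(A), 2 * length(B), hidden))
      }
    })
  })
  structure(
    list(p = p, q = q, n_layers = n_layers, hidden = hidden,
         init_seed = as.integer(seed), layers = layers),
    class = "invertible_map"
  )
}

#' @export
print.invertible_map <- function(x, ...) {
  cat(sprintf(
    "<invertible_map> p = %d, q = %d, %d coupling layers, hidden width %d\n",
    x$p, x$q, x$n_layers, x$hidden))
  invisible(x)
}

# Bound on each coupling layer's log-scale output: s = cap * tanh(raw / cap).
# A few layers can then amplify or attenuate coordinates by up to
# exp(n_layers * cap), enough to standardize near-deterministic discarded
# dimensions to the unit-normal scale used at decode time.
SCALE_CAP <- 3

couple_scale <- function(raw) SCALE_CAP * tanh(raw / SCALE_CAP)

as_batch <- function(x, d, what = "input") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != d)
    stop(sprintf("invalid input: %s has %d columns, expected %d",
                 what, ncol(x), d))
  if (!all(is.finite(x))) stop("invalid input: non-finite values in ", what)
  x
}

# Full bijection psi: R^p -> R^p.  Returns list(out, caches).
psi_forward <- function(map, X, cache = FALSE) {
  caches <- if (cache) vector("list", map$n_layers)
  for (l in seq_len(map$n_layers)) {
    ly <- map$layers[[l]]
    if (!length(ly$net)) next
    A <- X[, ly$A, drop = FALSE]
    mf <- mlp_forward(ly$net, A, cache = cache)
    nb <- length(ly$B)
    s <- couple_scale(mf$out[, seq_len(nb), drop = FALSE])
    tt <- mf$out[, nb + seq_len(nb), drop = FALSE]
    b <- X[, ly$B, drop = FALSE]
    X[, ly$B] <- b * exp(s) + tt
    if (cache) caches[[l]] <- list(mlp = mf, s = s, b = b)
  }
  list(out = X, caches = caches)
}

psi_inverse <- function(map, Z, cache = FALSE) {
  caches <- if (cache) vector("list", map$n_layers)
  for (l in rev(seq_len(map$n_layers))) {
    ly <- map$layers[[l]]
    if (!length(ly$net)) next
    A <- Z[, ly$A, drop = FALSE]
    mf <- mlp_forward(ly$net, A, cache = cache)
    nb <- length(ly$B)
    s <- couple_scale(mf$out[, seq_len(nb), drop = FALSE])
    tt <- mf$out[, nb + seq_len(nb), drop = FALSE]
    bp <- Z[, ly$B, drop = FALSE]
    Z[, ly$B] <- (bp - tt) * exp(-s)
    if (cache) caches[[l]] <- list(mlp = mf, s = s, bp = bp, tt = tt)
  }
  list(out = Z, caches = caches)
}

# Backprop through psi_forward.  dOut: gradient w.r.t. psi(X).
# Returns list(dX, grads) with grads mirroring map$layers.
psi_forward_backward <- function(map, caches, dOut) {
  grads <- vector("list", map$n_layers)
  for (l in rev(seq_len(map$n_layers))) {
    ly <- map$layers[[l]]
    if (!length(ly$net)) { grads[[l]] <- list(); next }
    cc <- caches[[l]]
    nb <- length(ly$B)
    dBp <- dOut[, ly$B, drop = FALSE]
    es <- exp(cc$s)
    db <- dBp * es
    ds <- dBp * cc$b * es
    ds_raw <- ds * (1 - (cc$s / SCALE_CAP)^2)
    dmlp <- cbind(ds_raw, dBp)
    mb <- mlp_backward(ly$net, cc$mlp, dmlp)
    dOut[, ly$B] <- db
    dOut[, ly$A] <- dOut[, ly$A, drop = FALSE] + mb$dX
    grads[[l]] <- mb$grad
  }
  list(dX = dOut, grads = grads)
}

# Backprop through psi_inverse.  dOut: gradient w.r.t. psi^{-1}(Z).
psi_inverse_backward <- function(map, caches, dOut) {
  grads <- vector("list", map$n_layers)
  for (l in seq_len(map$n_layers)) {
    ly <- map$layers[[l]]
    if (!length(ly$net)) { grads[[l]] <- list(); next }
    cc <- caches[[l]]
    db <- dOut[, ly$B, drop = FALSE]
    ems <- exp(-cc$s)
    dBp <- db * ems
    dtt <- -dBp
    ds <- -db * (cc$bp - cc$tt) * ems          # = -db * b
    ds_raw <- ds * (1 - (cc$s / SCALE_CAP)^2)
    dmlp <- cbind(ds_raw, dtt)
    mb <- mlp_backward(ly$net, cc$mlp, dmlp)
    dOut[, ly$B] <- dBp
    dOut[, ly$A] <- dOut[, ly$A, drop = FALSE] + mb$dX
    grads[[l]] <- mb$grad
  }
  list(dX = dOut, grads = grads)
}

#' Coarse-grain micro-states into macro-states
#'
#' Applies the bijection \eqn{\psi} and keeps its first \eqn{q} coordinates.
#'
#' @param map An \code{invertible_map} from [coarse_grainer()], or a fitted
#'   \code{nisplus_model} (whose input standardization is applied first).
#' @param x A p-vector, matrix or data frame of micro-states (rows = time).
#' @return A matrix with \code{q} columns of macro-states.
#' @export
encode <- function(map, x) {
  if (inherits(map, "nisplus_model")) {
    X <- as_batch(x, map$encoder$p, "micro-state")
    X <- sweep(sweep(X, 2, map$center), 2, map$scale, "/")
    map <- map$encoder
  } else {
    X <- as_batch(x, map$p, "micro-state")
  }
  psi_forward(map, X)$out[, seq_len(map$q), drop = FALSE]
}

#' Anti-coarse-grain macro-states back to micro-states
#'
#' Pads the discarded \eqn{p-q} coordinates with standard-normal noise drawn
#' under \code{noise_seed} and applies \eqn{\psi^{-1}}.  With \code{q = p} no
#' noise is drawn and the decode is the exact inverse of [encode()].
#'
#' @param map An \code{invertible_map} or fitted \code{nisplus_model} (whose
#'   standardization is undone on the way out).
#' @param y A q-vector or matrix of macro-states.
#' @param noise_seed Integer seed for the padding noise (reproducible).
#' @return A matrix with \code{p} columns of reconstructed micro-states.
#' @export
decode <- function(map, y, noise_seed = 1) {
  model <- NULL
  if (inherits(map, "nisplus_model")) {
    model <- map
    map <- map$encoder
  }
  Y <- as_batch(y, map$q, "macro-state")
  d <- map$p - map$q
  Z <- if (d > 0) {
    xi <- withr::with_seed(as.integer(noise_seed),
                           matrix(stats::rnorm(nrow(Y) * d), nrow(Y), d))
    cbind(Y, xi)
  } else Y
  out <- psi_inverse(map, Z)$out
  if (!is.null(model))
    out <- sweep(sweep(out, 2, model$scale, "*"), 2, model$center, "+")
  out
}

# Full p x p Jacobian of the bijection psi at a single point (all rows,
# regardless of the map's q).
psi_full_jacobian <- function(map, x) {
  X <- matrix(as.numeric(x), 1, map$p)
  fw <- psi_forward(map, X, cache = TRUE)
  J <- matrix(0, map$p, map$p)
  for (k in seq_len(map$p)) {
    dOut <- matrix(0, 1, map$p)
    dOut[1, k] <- 1
    J[k, ] <- psi_forward_backward(map, fw$caches, dOut)$dX
  }
  J
}

#' Jacobian of the coarse-graining map at a point
#'
#' Exact \eqn{q \times p} Jacobian \eqn{\partial\phi/\partial x} computed by
#' reverse-mode vector-Jacobian products through the coupling stack.  Used to
#' push ground-truth micro vector fields into the learned macro space.
#'
#' @param map An \code{invertible_map} or fitted \code{nisplus_model} (the
#'   Jacobian is then taken with respect to the raw, unstandardized input).
#' @param x A single micro-state (p-vector).
#' @return A \code{q x p} numeric matrix; row k is the gradient of macro
#'   coordinate k.
#' @export
encoder_jacobian <- function(map, x) {
  inv_scale <- NULL
  if (inherits(map, "nisplus_model")) {
    x <- (as.numeric(x) - map$center) / map$scale
    inv_scale <- 1 / map$scale
    map <- map$encoder
  }
  X <- as_batch(x, map$p, "micro-state")
  if (nrow(X) != 1) stop("invalid input: x must be a single micro-state")
  fw <- psi_forward(map, X, cache = TRUE)
  J <- matrix(0, map$q, map$p)
  for (k in seq_len(map$q)) {
    dOut <- matrix(0, 1, map$p)
    dOut[1, k] <- 1
    J[k, ] <- psi_forward_backward(map, fw$caches, dOut)$dX
  }
  if (!is.null(inv_scale)) J <- sweep(J, 2, inv_scale, "*")
  if (!all(is.finite(J))) stop("estimation failure: non-finite Jacobian")
  J
}
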