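#' Construct a forward/reverse macro-dynamics pair
#'
#' Both the forward one-step map \eqn{f} and the reverse map \eqn{g} are
#' residual MLPs \code{y + net(y)} with zero-initialized output heads, so
#' they start as the identity.  The reverse dynamics is the learnable
#' surrogate that turns EI maximization into a weighted regression: pulling
#' \eqn{g(y_{t+1})} toward \eqn{y_t} under uniform-intervention weights
#' maximizes the channel's mutual information.
#'
#' @param q Macro dimension.
#' @param hidden Hidden width of each MLP.
#' @param seed Integer seed for initialization.
#' @return An object of class \code{dynamics_pair}.
#' @export
dynamics_pair <- function(q, hidden = 32, seed = 1) {
  stopifnot(q >= 1, hidden >= 1)
  pars <- withr::with_seed(as.integer(seed), {
    list(f = mlp_new(q, q, hidden), g = mlp_new(q, q, hidden))
  })
  structure(list(q = q, hidden = hidden, f = pars$f, g = pars$g),
            class = "dynamics_pair")
}

#' @export
print.dynamics_pair <- function(x, ...) {
  cat(sprintf("<dynamics_pair> q = %d, hidden width %d\n", x$q, x$hidden))
  invisible(x)
}

#' One forward macro time step
#'
#' @param d A \code{dynamics_pair}.
#' @param y A q-vector or matrix of macro-states (rows = samples).
#' @return Predicted macro-state(s) one step ahead, same shape as a matrix.
#' @export
forward_step <- function(d, y) {
  Y <- as_batch(y, d$q, "macro-state")
  out <- res_forward(d$f, Y)$out
  if (!all(is.finite(out))) stop("model divergence: non-finite forward step")
  out
}

#' One reverse macro time step
#'
#' @param d A \code{dynamics_pair}.
#' @param y A q-vector or matrix of macro-states at time t+1.
#' @return Estimated macro-state(s) one step back.
#' @export
reverse_step <- function(d, y) {
  Y <- as_batch(y, d$q, "macro-state")
  out <- res_forward(d$g, Y)$out
  if (!all(is.finite(out))) stop("model divergence: non-finite reverse step")
  out
}

#' Predict the next micro-state through the macro pipeline
#'
#' Composition \eqn{\hat x_{t+1} = \phi^\dagger(f_q(\phi(x_t)))}: encode,
#' step forward in macro space, decode (with seeded padding noise).
#'
#' @param model A fitted \code{nisplus_model} (see [train_nisplus()]).
#' @param x_t Micro-state vector or matrix.
#' @param noise_seed Seed for the decoder's padding noise.
#' @return Matrix of predicted micro-states.
#' @export
predict_micro <- function(model, x_t, noise_seed = 1) {
  y <- encode(model, x_t)
  yhat <- forward_step(model$dynamics, y)
  decode(model, yhat, noise_seed = noise_seed)
}

#' Multi-step micro prediction by macro-space rollout
#'
#' Encodes the initial micro-state once, iterates the forward macro dynamics
#' \code{steps} times, and decodes each macro state (macro-space iteration;
#' re-encoding decoded states would inject decode noise into the rollout).
#' If any value exceeds the overflow guard the rollout is truncated and
#' flagged via the \code{"truncated"} attribute.
#'
#' @param model A fitted \code{nisplus_model}.
#' @param x_0 Initial micro-state (p-vector).
#' @param steps Number of steps (>= 1).
#' @param noise_seed Seed controlling the decoder noise (one derived seed
#'   per step).
#' @param guard Overflow guard on absolute values (default 1e6).
#' @return A \code{steps x p} matrix of predicted micro-states (row k =
#'   prediction at t + k), with attribute \code{"truncated"}.
#' @export
rollout <- function(model, x_0, steps, noise_seed = 1, guard = 1e6) {
  stopifnot(steps >= 1)
  p <- model$encoder$p
  y <- encode(model, matrix(as.numeric(x_0), 1, p))
  out <- matrix(NA_real_, steps, p)
  truncated <- FALSE
  for (k in seq_len(steps)) {
    y <- forward_step(model$dynamics, y)
    if (any(abs(y) > guard)) {
      truncated <- TRUE
      break
    }
    out[k, ] <- decode(model, y, noise_seed = derive_seed(noise_seed, k))
  }
  if (truncated) out <- out[seq_len(max(0, k - 1)), , drop = FALSE]
  attr(out, "truncated") <- truncated
  out
}
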