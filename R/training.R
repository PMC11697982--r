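#' Training configuration
#'
#' Collects the hyperparameters of the EI-maximizing training procedure.
#'
#' @param q Macro dimension (hyperparameter of the scale being fitted).
#' @param lambda Lagrange multiplier weighting the micro-prediction
#'   (forward) term against the reweighted reverse-dynamics term.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Master seed; fixes initialization, batching, decode noise and
#'   EI tracking, so identical configs give bitwise-identical training runs.
#' @param reweight_every Recompute inverse-probability weights every this
#'   many epochs (the encoder drifts, so the macro density must be refreshed).
#' @param warmup_epochs Initial epochs trained on the forward term only,
#'   stabilizing the encoder before density estimation starts.
#' @param error_threshold Normalized-MAE validity cut for causal-emergence
#'   reports (default 0.3).
#' @param ei_mc_samples Monte-Carlo draws for per-epoch EI tracking.
#' @param range_L \code{"auto"} (half-width of the observed macro bounding
#'   box, maximized over dimensions) or a positive number.
#' @param n_layers,hidden Encoder coupling layers and conditioner width.
#' @param dyn_hidden Hidden width of the dynamics MLPs.
#' @param holdout_frac Fraction of series held out for residual noise
#'   estimation and rollout evaluation.
#' @param clip_max Weight clip (see [compute_weights()]).
#' @param bandwidth KDE bandwidth (see [estimate_density()]).
#' @param n_restarts Independent training restarts (derived seeds); the
#'   model with the lowest held-out one-step prediction loss is kept.
#'   Restarts guard against the occasional bad optimization basin of the
#'   non-convex objective.
#' @return A list of class \code{nisplus_config}.
#' @export
train_config <- function(q, lambda = 1, epochs = 60, batch_size = 64,
                         learning_rate = 6e-3, seed = 1, reweight_every = 5,
                         warmup_epochs = 10, error_threshold = 0.3,
                         ei_mc_samples = 300, range_L = "auto",
                         n_layers = 6, hidden = 32, dyn_hidden = 32,
                         holdout_frac = 0.2, clip_max = 20,
                         bandwidth = "auto", standardize = TRUE,
                         n_restarts = 1) {
  stopifnot(q >= 1, lambda >= 0, epochs >= 1, error_threshold > 0,
            batch_size >= 1, learning_rate > 0, reweight_every >= 1)
  structure(
    list(q = as.integer(q), lambda = lambda, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         seed = as.integer(seed), reweight_every = as.integer(reweight_every),
         warmup_epochs = as.integer(warmup_epochs),
         error_threshold = error_threshold,
         ei_mc_samples = as.integer(ei_mc_samples), range_L = range_L,
         n_layers = as.integer(n_layers), hidden = as.integer(hidden),
         dyn_hidden = as.integer(dyn_hidden), holdout_frac = holdout_frac,
         clip_max = clip_max, bandwidth = bandwidth,
         standardize = isTRUE(standardize),
         n_restarts = as.integer(n_restarts)),
    class = "nisplus_config"
  )
}

# Normalize user data into a list of numeric matrices (one per trajectory).
series_list <- function(data) {
  if (is.data.frame(data) || is.matrix(data)) data <- list(data)
  if (!is.list(data) || length(data) == 0)
    stop("invalid input: data must be a matrix/tibble or list of them")
  lapply(data, function(s) {
    m <- as.matrix(as.data.frame(s))
    storage.mode(m) <- "double"
    if (!all(is.finite(m))) stop("invalid input: non-finite values in series")
    if (nrow(m) < 2) stop("invalid input: each series needs >= 2 time steps")
    m
  })
}

split_series <- function(series, frac, seed) {
  if (length(series) == 1) {
    s <- series[[1]]
    cut <- max(2, floor(nrow(s) * (1 - frac)))
    if (nrow(s) - cut < 2) return(list(train = series, hold = series))
    return(list(train = list(s[1:cut, , drop = FALSE]),
                hold = list(s[(cut + 1):nrow(s), , drop = FALSE])))
  }
  n_hold <- max(1, floor(length(series) * frac))
  idx <- withr::with_seed(seed, sample(length(series), n_hold))
  list(train = series[-idx], hold = series[idx])
}

stack_pairs <- function(series) {
  X0 <- do.call(rbind, lapply(series, function(s)
    s[-nrow(s), , drop = FALSE]))
  X1 <- do.call(rbind, lapply(series, function(s) s[-1, , drop = FALSE]))
  list(X0 = X0, X1 = X1)
}

#' Training loss of the EI-maximizing objective
#'
#' The unconstrained surrogate objective: a reweighted reverse-dynamics term
#' plus a Lagrangian micro-prediction term,
#' \deqn{L = \frac1B\sum_t w(x_t)\,\|y_t - g(y_{t+1})\|_1
#'       + \lambda\,\frac1B\sum_t \|\hat x_{t+1} - x_{t+1}\|_1,}
#' with \eqn{y = \phi(x)} and \eqn{\hat x_{t+1}} the decoded forward
#' prediction.  Norms are L1 per sample, averaged over the batch.
#'
#' @param model A \code{nisplus_model} (or a list with \code{encoder},
#'   \code{dynamics} and \code{config}).
#' @param x_t,x_t1 Matrices of aligned micro-state pairs.
#' @param weights Per-sample inverse-probability weights (default 1).
#' @param noise_seed Seed for the decoder's padding noise.
#' @return List with \code{total}, \code{forward} and \code{inverse} terms.
#' @export
nisplus_loss <- function(model, x_t, x_t1, weights = NULL, noise_seed = 1) {
  p <- model$encoder$p
  X0 <- as_batch(x_t, p); X1 <- as_batch(x_t1, p)
  if (nrow(X0) != nrow(X1)) stop("invalid input: unaligned batch")
  w <- weights %||% rep(1, nrow(X0))
  has_std <- inherits(model, "nisplus_model")
  obj <- if (has_std) model else model$encoder
  Y0 <- encode(obj, X0)
  Y1 <- encode(obj, X1)
  Xhat1 <- decode(obj, forward_step(model$dynamics, Y0),
                  noise_seed = noise_seed)
  if (has_std) {
    X1s <- sweep(sweep(X1, 2, model$center), 2, model$scale, "/")
    Xh1s <- sweep(sweep(Xhat1, 2, model$center), 2, model$scale, "/")
    fwd <- mean(rowSums(abs(Xh1s - X1s)))
  } else {
    fwd <- mean(rowSums(abs(Xhat1 - X1)))
  }
  inv <- mean(w * rowSums(abs(Y0 - reverse_step(model$dynamics, Y1))))
  if (!is.finite(fwd) || !is.finite(inv))
    stop("NaN loss: forward = ", fwd, ", inverse = ", inv)
  list(total = inv + model$config$lambda * fwd, forward = fwd, inverse = inv)
}

# One batch of loss + gradients.  Returns list(loss_fwd, loss_inv, grad)
# where grad is the flat gradient over params = list(enc, f, g).
# The reverse-dynamics residual is measured in units of the batch latent
# standard deviation (gradient flowing through the scale): the encoder's
# overall scale is a pure gauge of EI (noise and range rescale together),
# and without this normalization the weighted term would be minimized
# trivially by collapsing the latent space.
nisplus_batch_grad <- function(params, map_skel, q, lambda, X0, X1, w,
                               use_inverse = TRUE, scale_anchor = 0.01) {
  B <- nrow(X0)
  p <- map_skel$p
  enc <- map_skel
  enc$layers <- Map(function(ly, par) { ly$net <- par$net; ly },
                    enc$layers, params$enc)
  cF0 <- psi_forward(enc, X0, cache = TRUE)
  Y0 <- cF0$out[, seq_len(q), drop = FALSE]
  cF1 <- psi_forward(enc, X1, cache = TRUE)
  Y1 <- cF1$out[, seq_len(q), drop = FALSE]
  cf <- res_forward(params$f, Y0, cache = TRUE)
  d <- p - q
  XI <- if (d > 0) matrix(stats::rnorm(B * d), B, d) else NULL
  Zhat1 <- if (d > 0) cbind(cf$out, XI) else cf$out
  cInv <- psi_inverse(enc, Zhat1, cache = TRUE)
  Xhat1 <- cInv$out
  loss_fwd <- mean(rowSums(abs(Xhat1 - X1)))

  # forward-term backprop
  dXhat1 <- lambda * sign(Xhat1 - X1) / B
  binv <- psi_inverse_backward(enc, cInv$caches, dXhat1)
  gEnc <- binv$grads
  dYhat1 <- binv$dX[, seq_len(q), drop = FALSE]
  bf <- res_backward(params$f, cf, dYhat1)
  dY0 <- bf$dX
  gF <- bf$grad

  # batch latent scale (per dimension), shared by the inverse term's
  # normalization and the scale anchor
  mu <- colMeans(Y0)
  s_raw <- sqrt(colSums(sweep(Y0, 2, mu)^2) / max(1, B - 1))
  # floor well above zero: a latent dimension the warmup left near-constant
  # must not blow up the normalized residual before the anchor revives it
  floored <- s_raw < 1e-2
  s <- pmax(s_raw, 1e-2)
  ds <- numeric(q)

  # inverse (reweighted reverse-dynamics) term
  if (use_inverse) {
    cg <- res_forward(params$g, Y1, cache = TRUE)
    r <- Y0 - cg$out
    loss_inv <- mean(w * rowSums(sweep(abs(r), 2, s, "/")))
    dr <- sweep((w / B) * sign(r), 2, s, "/")
    a <- colSums((w / B) * abs(r))                # loss_inv = sum(a / s)
    ds <- ds - a / s^2
    dY0 <- dY0 + dr
    bg <- res_backward(params$g, cg, -dr)
    gG <- bg$grad
    dY1 <- bg$dX
  } else {
    loss_inv <- 0
    gG <- tree_zero(params$g)
    dY1 <- matrix(0, B, q)
  }

  # scale anchor: eta * sum_j |log s_j| pins the batch latent standard
  # deviation near 1.  The latent scale is a pure gauge of EI, but letting
  # it drift degrades decoder conditioning and generalization.
  if (scale_anchor > 0) ds <- ds + scale_anchor * sign(log(s)) / s
  ds[floored] <- 0
  dY0 <- dY0 + sweep(sweep(Y0, 2, mu), 2, ds / (max(1, B - 1) * s), "*")

  pad <- function(dY) {
    if (d > 0) cbind(dY, matrix(0, B, d)) else dY
  }
  b0 <- psi_forward_backward(enc, cF0$caches, pad(dY0))
  b1 <- psi_forward_backward(enc, cF1$caches, pad(dY1))
  gEnc <- tree_add(tree_add(gEnc, b0$grads), b1$grads)

  grad <- flat_grad(list(enc = lapply(gEnc, function(g) list(net = g)),
                         f = gF, g = gG))
  if (!all(is.finite(grad)) || !is.finite(loss_fwd) || !is.finite(loss_inv))
    stop("NaN loss: training diverged (forward = ", loss_fwd,
         ", inverse = ", loss_inv, ")")
  list(loss_fwd = loss_fwd, loss_inv = loss_inv, grad = grad)
}

#' Fit the EI-maximizing macro-dynamics model
#'
#' End-to-end training of the coarse-graining encoder, forward macro
#' dynamics f and reverse dynamics g by minibatch Adam on the surrogate
#' objective (see [nisplus_loss()]).  The first \code{warmup_epochs} epochs
#' use the micro-prediction term only; afterwards inverse-probability
#' weights (refreshed every \code{reweight_every} epochs) re-target the
#' macro distribution to uniform, emulating the do-intervention that makes
#' the objective maximize EI.  Dimension-averaged EI of the learned macro
#' dynamics is tracked each epoch on held-out residual noise.
#'
#' @param data A T x p matrix/tibble or a list of them (trajectories).
#' @param config A [train_config()].
#' @return An object of class \code{nisplus_model}: fields \code{encoder},
#'   \code{dynamics}, \code{config}, \code{history} (per-epoch tibble with
#'   losses and dimension-averaged EI in bits), \code{noise_sigmas},
#'   \code{range_L}.
#' @export
train_nisplus <- function(data, config) {
  stopifnot(inherits(config, "nisplus_config"))
  series <- series_list(data)
  n_restarts <- config$n_restarts %||% 1L
  if (n_restarts > 1) {
    best <- NULL
    best_score <- Inf
    for (r in seq_len(n_restarts)) {
      cfg_r <- config
      cfg_r$n_restarts <- 1L
      if (r > 1) cfg_r$seed <- derive_seed(config$seed, 7000 + r)
      cand <- train_nisplus(series, cfg_r)
      score <- as.numeric(eval_nmae(cand, steps = 1))
      if (score < best_score) {
        best <- cand
        best_score <- score
      }
    }
    return(best)
  }
  p <- ncol(series[[1]])
  q <- config$q
  if (q > p) stop("invalid parameter: q must be <= p")
  sp <- split_series(series, config$holdout_frac, derive_seed(config$seed, 1))
  tr <- stack_pairs(sp$train)
  ho <- stack_pairs(sp$hold)
  # per-dimension standardization (fitted on the training split): raw
  # coordinates on very different scales would saturate the tanh
  # conditioners and unbalance the L1 losses
  if (config$standardize) {
    center <- colMeans(tr$X0)
    scale <- pmax(apply(tr$X0, 2, stats::sd), 1e-8)
  } else {
    center <- rep(0, p)
    scale <- rep(1, p)
  }
  std <- function(X) sweep(sweep(X, 2, center), 2, scale, "/")
  tr$X0 <- std(tr$X0); tr$X1 <- std(tr$X1)
  ho$X0 <- std(ho$X0); ho$X1 <- std(ho$X1)
  N <- nrow(tr$X0)

  map <- coarse_grainer(p, q, n_layers = config$n_layers,
                        hidden = config$hidden,
                        seed = derive_seed(config$seed, 2))
  dyn <- dynamics_pair(q, hidden = config$dyn_hidden,
                       seed = derive_seed(config$seed, 3))
  params <- list(enc = lapply(map$layers, function(ly) list(net = ly$net)),
                 f = dyn$f, g = dyn$g)
  opt <- adam_new(params)
  history <- vector("list", config$epochs)
  w_all <- rep(1, N)

  withr::with_seed(derive_seed(config$seed, 4), {
    for (epoch in seq_len(config$epochs)) {
      warm <- epoch <= config$warmup_epochs
      cur_map <- set_map_params(map, params$enc)
      if (!warm && (epoch - config$warmup_epochs - 1) %%
            config$reweight_every == 0) {
        Ytr <- encode(cur_map, tr$X0)
        ws <- compute_weights(Ytr, bandwidth = config$bandwidth,
                              clip_max = config$clip_max)
        w_all <- ws$weights
      }
      # cosine-annealed step size: L1 losses leave a constant-lr jitter
      # floor, so the rate is decayed to refine the fit
      lr_e <- 1e-5 + 0.5 * (config$learning_rate - 1e-5) *
        (1 + cos(pi * (epoch - 1) / max(1, config$epochs - 1)))
      ord <- sample(N)
      lf <- li <- 0
      nb <- 0
      for (start in seq(1, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, N)]
        bg <- nisplus_batch_grad(params, map, q, config$lambda,
                                 tr$X0[idx, , drop = FALSE],
                                 tr$X1[idx, , drop = FALSE],
                                 w_all[idx], use_inverse = !warm)
        st <- adam_step(params, bg$grad, opt, lr_e)
        params <- st$params
        opt <- st$state
        lf <- lf + bg$loss_fwd; li <- li + bg$loss_inv; nb <- nb + 1
      }
      cur_map <- set_map_params(map, params$enc)
      cur_dyn <- dyn; cur_dyn$f <- params$f; cur_dyn$g <- params$g
      ei <- track_ei(cur_map, cur_dyn, tr, ho, config,
                     derive_seed(config$seed, 100 + epoch))
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss_forward = lf / nb, loss_inverse = li / nb,
        j = ei$j, range_L = max(ei$L))
    }
  })

  map <- set_map_params(map, params$enc)
  dyn$f <- params$f; dyn$g <- params$g
  ei_final <- track_ei(map, dyn, tr, ho, config, derive_seed(config$seed, 99))
  structure(
    list(encoder = map, dynamics = dyn, config = config,
         history = dplyr::bind_rows(history),
         noise_sigmas = ei_final$sigmas, range_L = ei_final$L,
         center = center, scale = scale,
         holdout = sp$hold, n_train_pairs = N),
    class = "nisplus_model"
  )
}

# Dynamics + Jacobian closures matching the space the model's EI is
# measured in (latent for q < p, micro for q = p; see track_ei).
model_ei_closures <- function(model) {
  map <- model$encoder
  dyn <- model$dynamics
  if (map$q < map$p) {
    list(f = function(y) drop(forward_step(dyn, matrix(y, 1))),
         jacobian = function(y) res_jacobian(dyn$f, y))
  } else {
    list(
      f = function(x) {
        drop(psi_inverse(map, res_forward(
          dyn$f, psi_forward(map, matrix(x, 1))$out)$out)$out)
      },
      jacobian = function(x) {
        y <- psi_forward(map, matrix(x, 1))$out
        xhat <- psi_inverse(map, res_forward(dyn$f, y)$out)$out
        solve(psi_full_jacobian(map, xhat)) %*%
          res_jacobian(dyn$f, drop(y)) %*% psi_full_jacobian(map, x)
      })
  }
}

set_map_params <- function(map, enc_params) {
  map$layers <- Map(function(ly, par) { ly$net <- par$net; ly },
                    map$layers, enc_params)
  map
}

# Dimension-averaged EI (bits) of the current forward dynamics.
#
# For q < p the EI is that of the learned macro dynamics f on the latent
# macro states: noise sigmas from held-out one-step latent residuals, range
# from the observed per-dimension latent bounding box.
#
# For q = p the model IS the learnt micro-dynamics, so its EI is measured
# on the micro states themselves, as the composed map
# F = psi^{-1} o f o psi: sigmas from held-out micro prediction residuals,
# range from the micro data box, Jacobian by the chain rule.  Measuring the
# reference scale in the data's own coordinates matters: in a learned
# latent gauge the training objective can make the dynamics look almost
# deterministic by re-expressing observation noise at tiny amplitude inside
# O(1) coordinates, which would inflate J(f_p) arbitrarily; the micro
# residual is pinned by the observation-noise floor instead.
track_ei <- function(map, dyn, tr, ho, config, seed) {
  q <- map$q
  p <- map$p
  if (q < p) {
    Y0h <- encode(map, ho$X0)
    Y1h <- encode(map, ho$X1)
    resid <- Y1h - forward_step(dyn, Y0h)
    sigmas <- pmax(sqrt(colMeans(resid^2)), 1e-6)
    L <- if (identical(config$range_L, "auto")) {
      Ytr <- encode(map, tr$X0)
      pmax((apply(Ytr, 2, max) - apply(Ytr, 2, min)) / 2, 1e-3)
    } else config$range_L
  } else {
    Xhat1 <- psi_inverse(map, res_forward(
      dyn$f, psi_forward(map, ho$X0)$out)$out)$out
    resid <- ho$X1 - Xhat1
    sigmas <- pmax(sqrt(colMeans(resid^2)), 1e-6)
    L <- if (identical(config$range_L, "auto")) {
      pmax((apply(tr$X0, 2, max) - apply(tr$X0, 2, min)) / 2, 1e-3)
    } else config$range_L
    L <- rep(L, length.out = p)
    # batched Monte-Carlo EI of the composed map psi^{-1} o f o psi, using
    # the triangular coupling Jacobians: ln|det J_psi| is just the sum of
    # the layer log-scales, so no matrix factorizations are needed
    mc <- config$ei_mc_samples
    logdets <- withr::with_seed(as.integer(seed), {
      X <- sweep(matrix(stats::runif(mc * p, -1, 1), mc, p), 2, L, "*")
      fw <- psi_forward(map, X, cache = TRUE)
      s_fwd <- psi_cache_logdet(fw$caches, mc)
      Yx <- fw$out
      ld_f <- vapply(seq_len(mc), function(i) {
        sv <- svd(res_jacobian(dyn$f, Yx[i, ]), nu = 0, nv = 0)$d
        sum(log(pmax(sv, 1e-12)))
      }, numeric(1))
      inv <- psi_inverse(map, res_forward(dyn$f, Yx)$out, cache = TRUE)
      s_inv <- psi_cache_logdet(inv$caches, mc)
      s_fwd + ld_f - s_inv
    })
    ei_nats <- mean(logdets) + sum(log(2 * L)) -
      (p / 2) * log(2 * pi * exp(1)) - sum(log(sigmas))
    return(list(j = ei_nats / log(2) / p, sigmas = sigmas, L = L))
  }
  est <- ei_continuous_mc(
    f = function(y) drop(forward_step(dyn, matrix(y, 1))),
    noise_sigmas = sigmas, range_L = L,
    mc_samples = config$ei_mc_samples, seed = seed,
    jacobian = function(y) res_jacobian(dyn$f, y),
    log_base = 2)
  list(j = est$j_dim_avg, sigmas = sigmas, L = L, est = est)
}

# Sum of coupling-layer log-scales per row: ln|det J_psi| for each sample.
psi_cache_logdet <- function(caches, n) {
  out <- numeric(n)
  for (cc in caches) {
    if (!is.null(cc)) out <- out + rowSums(cc$s)
  }
  out
}

#' @export
print.nisplus_model <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<nisplus_model> p = %d, q = %d; %d epochs on %d pairs\n",
    x$encoder$p, x$encoder$q, nrow(h), x$n_train_pairs))
  cat(sprintf(
    "  final: forward loss %.4g, inverse loss %.4g, J = %.3f bits/dim\n",
    h$loss_forward[nrow(h)], h$loss_inverse[nrow(h)], h$j[nrow(h)]))
  invisible(x)
}

#' Normalized mean absolute error
#'
#' MAE between prediction and truth divided by the mean absolute deviation
#' of the truth from its per-dimension mean, making the 0.3 validity
#' threshold scale-free.  Predicting the truth's mean scores exactly 1.
#'
#' @param pred,truth Matrices of identical shape (steps x p).
#' @return A non-negative scalar; if the truth is constant the raw MAE is
#'   returned with attribute \code{"unnormalized" = TRUE}.
#' @export
normalized_mae <- function(pred, truth) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("invalid input: pred and truth shapes differ")
  mae <- mean(abs(pred - truth))
  mad0 <- mean(abs(sweep(truth, 2, colMeans(truth))))
  if (mad0 < 1e-12) {
    warning("constant truth: returning unnormalized MAE")
    return(structure(mae, unnormalized = TRUE))
  }
  mae / mad0
}

# Multi-step prediction error of a fitted model on held-out series.
eval_nmae <- function(model, steps = 10, n_windows = 20) {
  segs_pred <- list(); segs_true <- list()
  k <- 0
  for (s in model$holdout) {
    if (nrow(s) < steps + 1) next
    starts <- unique(round(seq(1, nrow(s) - steps,
                               length.out = min(n_windows, nrow(s) - steps))))
    for (st in starts) {
      k <- k + 1
      pr <- rollout(model, s[st, ], steps,
                    noise_seed = derive_seed(model$config$seed, 500 + k))
      if (attr(pr, "truncated") || nrow(pr) < steps) return(Inf)
      segs_pred[[k]] <- pr
      segs_true[[k]] <- s[st + seq_len(steps), , drop = FALSE]
    }
  }
  if (k == 0) stop("invalid input: held-out series shorter than the rollout")
  normalized_mae(do.call(rbind, segs_pred), do.call(rbind, segs_true))
}

#' Quantify causal emergence at a given scale
#'
#' Trains a q-dimensional macro model and a p-dimensional reference model
#' (q = p, the learnt micro-dynamics) on the same data with the same seed
#' protocol, computes the dimension-averaged EI of each learned dynamics
#' (Monte-Carlo, noise from held-out residuals), and reports their
#' difference \eqn{\Delta J} together with the 10-step normalized MAE and a
#' validity flag (\code{nmae <= error_threshold}).  \eqn{\Delta J > 0} with
#' \code{valid = TRUE} indicates causal emergence.
#'
#' @param data As in [train_nisplus()].
#' @param q Macro dimension to test (1 <= q <= p).
#' @param config A [train_config()]; its \code{q} is overridden.
#' @param steps Rollout horizon for the error gate (default 10).
#' @return A one-row tibble of class \code{ce_report}: \code{q},
#'   \code{j_macro}, \code{j_micro}, \code{delta_j} (bits per dimension),
#'   \code{nmae}, \code{valid}.  The fitted models are attached as
#'   attributes \code{"model_q"} and \code{"model_p"}.
#' @export
quantify_ce <- function(data, q, config, steps = 10) {
  series <- series_list(data)
  p <- ncol(series[[1]])
  if (q < 1 || q > p) stop("invalid parameter: q must be in 1..p")
  cfg_q <- config; cfg_q$q <- as.integer(q)
  model_q <- train_nisplus(series, cfg_q)
  if (q == p) {
    model_p <- model_q
  } else {
    cfg_p <- config; cfg_p$q <- as.integer(p)
    model_p <- train_nisplus(series, cfg_p)
  }
  j_macro <- model_q$history$j[nrow(model_q$history)]
  j_micro <- model_p$history$j[nrow(model_p$history)]
  nmae <- as.numeric(eval_nmae(model_q, steps = steps))
  rep <- tibble::tibble(
    q = as.integer(q), j_macro = j_macro, j_micro = j_micro,
    delta_j = delta_j(j_macro, j_micro), nmae = nmae,
    valid = nmae <= config$error_threshold)
  class(rep) <- c("ce_report", class(rep))
  attr(rep, "model_q") <- model_q
  attr(rep, "model_p") <- model_p
  rep
}

#' Scan macro dimensions for the scale of strongest emergence
#'
#' Runs [quantify_ce()] for each candidate macro dimension with a shared
#' seed protocol, enabling \eqn{\Delta J}-versus-q curves and argmax scale
#' selection.
#'
#' @param data As in [train_nisplus()].
#' @param q_list Integer vector of candidate macro dimensions.
#' @param config A [train_config()].
#' @param steps Rollout horizon for the error gate.
#' @return A tibble with one [quantify_ce()] row per q, in \code{q_list}
#'   order.
#' @export
scan_q <- function(data, q_list, config, steps = 10) {
  series <- series_list(data)
  p <- ncol(series[[1]])
  if (any(q_list > p)) stop("invalid parameter: all q must be <= p")
  cfg_p <- config; cfg_p$q <- as.integer(p)
  model_p <- train_nisplus(series, cfg_p)
  j_micro <- model_p$history$j[nrow(model_p$history)]
  rows <- lapply(q_list, function(qq) {
    if (qq == p) {
      model_q <- model_p
    } else {
      cfg_q <- config; cfg_q$q <- as.integer(qq)
      model_q <- train_nisplus(series, cfg_q)
    }
    j_macro <- model_q$history$j[nrow(model_q$history)]
    nmae <- as.numeric(eval_nmae(model_q, steps = steps))
    tibble::tibble(q = as.integer(qq), j_macro = j_macro, j_micro = j_micro,
                   delta_j = delta_j(j_macro, j_micro), nmae = nmae,
                   valid = nmae <= config$error_threshold)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ce_scan", class(out))
  out
}
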