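# Shared fixtures.  Trained models are expensive, so they are built lazily
# and memoized for the whole test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Noisy SIR benchmark at low observational noise, and the causal-emergence
# report comparing the q = 2 macro scale with the q = p = 4 micro scale.
fx_sir_data <- function() {
  fixture("sir_data", function() {
    simulate_sir(n_traj = 30, T = 60, sigma = 1e-3, seed = 11)
  })
}

fx_sir_config <- function() {
  train_config(q = 2, epochs = 300, seed = 5, warmup_epochs = 10,
               batch_size = 64, learning_rate = 6e-3, n_layers = 6)
}

fx_sir_report <- function() {
  fixture("sir_report", function() {
    quantify_ce(fx_sir_data(), q = 2, fx_sir_config())
  })
}

fx_sir_model <- function() attr(fx_sir_report(), "model_q")

# Rotation-like linear dynamics with two true degrees of freedom observed in
# four duplicated noisy coordinates; scale scan over q = 1..4.
fx_lin_data <- function() {
  fixture("lin_data", function() {
    duplicated_linear_system(2, 4, noise = 0.01, T = 60, seed = 21,
                             n_traj = 15)
  })
}

fx_lin_scan <- function() {
  fixture("lin_scan", function() {
    cfg <- train_config(q = 2, epochs = 300, seed = 9, warmup_epochs = 10,
                        batch_size = 64, learning_rate = 6e-3, n_layers = 6)
    scan_q(fx_lin_data(), 1:4, cfg)
  })
}

# Deterministic 2-d linear system fitted at full dimension (q = p).
fx_lin_fit <- function() {
  fixture("lin_fit", function() {
    dat <- duplicated_linear_system(2, 2, noise = 0, T = 60, seed = 3,
                                    n_traj = 20)
    cfg <- train_config(q = 2, epochs = 250, seed = 7, warmup_epochs = 5,
                        batch_size = 64, learning_rate = 3e-3)
    list(data = dat, model = train_nisplus(dat, cfg))
  })
}

# Scaled-down two-group boids experiment (6 boids, 8 macro dimensions).
fx_boids <- function() {
  fixture("boids", function() {
    sims <- lapply(1:8, function(s)
      simulate_boids(n_boids = 6, T = 120, group_turn = 0.1, speed = 3,
                     canvas = 300, seed = 100 + s))
    dat <- lapply(sims, function(s) s$observed)
    cfg <- train_config(q = 8, epochs = 400, seed = 5, warmup_epochs = 10,
                        learning_rate = 2e-3)
    list(sims = sims, data = dat, model = train_nisplus(dat, cfg),
         groups = sims[[1]]$groups)
  })
}

# Mean signed per-step heading change of the listed boids in a rollout.
heading_drift <- function(M, ids) {
  tot <- 0
  for (i in ids) {
    vx <- M[, 4 * (i - 1) + 3]
    vy <- M[, 4 * (i - 1) + 4]
    a <- atan2(vy, vx)
    d <- diff(a)
    d <- atan2(sin(d), cos(d))
    tot <- tot + mean(d)
  }
  tot / length(ids)
}

# Brute-force mutual information I(X_t; X_{t+1}) of a Markov chain with
# uniformly intervened current state, from the explicit joint
# p(x, y) = tpm[x, y] / n.  Independent oracle for ei_discrete.
mi_brute_force <- function(tpm, log_base = 2) {
  n <- nrow(tpm)
  joint <- tpm / n
  px <- rowSums(joint)
  py <- colSums(joint)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (joint[i, j] > 0)
      tot <- tot + joint[i, j] *
        log(joint[i, j] / (px[i] * py[j]), base = log_base)
  }
  tot
}

# Random row-stochastic matrix.
random_tpm <- function(n) {
  m <- matrix(stats::rexp(n * n), n, n)
  sweep(m, 1, rowSums(m), "/")
}

# Closed-form EI (nats) of the linear Gaussian channel y' = A y + eps under
# a uniform intervention on [-L, L]^q.
linear_ei_closed_form <- function(A, sigmas, L) {
  q <- nrow(A)
  log(abs(det(A))) + q * log(2 * L) - (q / 2) * log(2 * pi * exp(1)) -
    sum(log(sigmas))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

perturb_net <- function(net, sd = 0.3) {
  lapply(net, function(m) m + stats::rnorm(length(m), sd = sd))
}

# An invertible map with non-trivial (randomly perturbed) parameters.
random_map <- function(p, q, n_layers = 3, seed = 1) {
  map <- coarse_grainer(p, q, n_layers = n_layers, hidden = 8, seed = seed)
  withr::with_seed(seed + 1, {
    for (l in seq_along(map$layers)) {
      if (!is.null(map$layers[[l]]$net))
        map$layers[[l]]$net <- perturb_net(map$layers[[l]]$net)
    }
  })
  map
}
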