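#' SIR vector field
#'
#' Time derivatives of the susceptible and infected fractions in the SIR
#' epidemic model \eqn{dS/dt = -\beta S I}, \eqn{dI/dt = \beta S I - \gamma I}
#' (the removed fraction follows from \eqn{R = 1 - S - I}).
#'
#' @param s,i Susceptible and infected fractions, with \code{s, i >= 0} and
#'   \code{s + i <= 1}.
#' @param beta Infection rate (default 1).
#' @param gamma Recovery rate (default 0.5).
#' @return A length-2 numeric vector \code{c(ds_dt, di_dt)}.
#' @export
sir_field <- function(s, i, beta = 1, gamma = 0.5) {
  tol <- 1e-12
  if (any(s < -tol) || any(i < -tol) || any(s + i > 1 + tol))
    stop("invalid input: (s, i) must lie in the simplex s, i >= 0, s + i <= 1")
  c(-beta * s * i, beta * s * i - gamma * i)
}

rk4_sir_step <- function(y, dt, beta, gamma) {
  f <- function(y) sir_field_raw(y[1], y[2], beta, gamma)
  k1 <- f(y)
  k2 <- f(y + dt / 2 * k1)
  k3 <- f(y + dt / 2 * k2)
  k4 <- f(y + dt * k3)
  y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# unchecked field for the integrator (intermediate RK stages may leave the
# simplex by O(dt) amounts)
sir_field_raw <- function(s, i, beta, gamma) {
  c(-beta * s * i, beta * s * i - gamma * i)
}

#' Simulate noisy SIR micro-state trajectories
#'
#' Generates the epidemic benchmark: latent macro-states \eqn{(S_t, I_t)}
#' integrated with fixed-step 4th-order Runge-Kutta, expanded into a 4-d
#' micro-state by duplication plus independent Gaussian observation noise:
#' \deqn{S' = (S, S) + \xi_1,\quad I' = (I, I) + \xi_2,\quad
#'       \xi_k \sim N(0, \sigma^2 I_2).}
#' Initial conditions are sampled uniformly on the simplex triangle
#' \eqn{\{S, I \ge 0,\ S + I \le 1\}}; with \code{region = "partial"} the
#' corner \eqn{S \le 1/3} is excluded, the out-of-distribution training
#' protocol.
#'
#' @param n_traj Number of trajectories.
#' @param T Time steps per trajectory.
#' @param sigma Observation-noise standard deviation (>= 0).
#' @param region \code{"full"} triangle or \code{"partial"} (S > 1/3 only).
#' @param beta,gamma,dt SIR parameters and integration step.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A list of tibbles (one per trajectory) with columns
#'   \code{x1..x4}; each carries the clean latent trajectory as attribute
#'   \code{"latent"} (a T x 2 matrix of S, I).
#' @examples
#' traj <- simulate_sir(n_traj = 2, T = 20, sigma = 1e-3, seed = 1)
#' head(traj[[1]])
#' @export
simulate_sir <- function(n_traj = 10, T = 100, sigma = 1e-3,
                         region = c("full", "partial"),
                         beta = 1, gamma = 0.5, dt = 0.01, seed = 1) {
  region <- match.arg(region)
  stopifnot(beta > 0, gamma > 0, dt > 0, sigma >= 0, n_traj >= 1, T >= 1)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_traj), function(k) {
      y <- sample_simplex_point(region)
      latent <- matrix(0, T, 2, dimnames = list(NULL, c("S", "I")))
      for (t in seq_len(T)) {
        latent[t, ] <- y
        y <- rk4_sir_step(y, dt, beta, gamma)
      }
      noise <- matrix(stats::rnorm(T * 4, sd = max(sigma, 0)), T, 4)
      if (sigma == 0) noise[] <- 0
      micro <- cbind(latent[, 1], latent[, 1], latent[, 2], latent[, 2]) +
        noise
      out <- tibble::as_tibble(as.data.frame(micro))
      names(out) <- paste0("x", 1:4)
      attr(out, "latent") <- latent
      out
    })
  })
}

sample_simplex_point <- function(region) {
  repeat {
    u <- stats::runif(2)
    if (sum(u) > 1) u <- 1 - u            # fold onto the triangle
    if (region == "full" || u[1] > 1 / 3) return(u)
  }
}

#' Simulate two-group boids flocking micro-states
#'
#' A Reynolds flocking model: each boid steers by cohesion, alignment and
#' separation within per-rule radii, and belongs to one of two groups with
#' opposite constant turning forces, so the groups trace arcs with opposite
#' curvature.  Speed is held constant and the canvas wraps toroidally.  The
#' micro-state at each step is \eqn{(x_i, y_i, v_{x,i}, v_{y,i})} for every
#' boid (4N columns).  Two noise channels are modelled: intrinsic noise adds
#' a per-boid, per-step heading perturbation uniform on
#' \eqn{\alpha\cdot[-\pi, \pi]} (it changes the dynamics itself), while
#' extrinsic noise \eqn{N(0, \delta_{max})} is added to the observations
#' only, leaving the clean trajectory untouched.
#'
#' @param n_boids Number of boids (split into two equal groups; default 16).
#' @param canvas Side length of the square toroidal canvas (default 300).
#' @param T Number of time steps.
#' @param group_turn Constant per-step turning angle (radians) of group 1;
#'   group 2 turns by the negative.
#' @param alpha Intrinsic-noise level in [0, 1].
#' @param delta_max Extrinsic (observational) noise standard deviation.
#' @param speed Constant boid speed (canvas units per step).
#' @param r_cohesion,r_separation Interaction radii.
#' @param w_cohesion,w_alignment,w_separation Rule weights.
#' @param init_radius All boids start inside a circle of this radius at the
#'   canvas center (seeded jitter), so repeated simulations sample the same
#'   region of state space.
#' @param group_headings Initial heading (radians) of each group.
#' @param seed Integer seed.
#' @return A list with tibbles \code{clean} and \code{observed}
#'   (T rows x 4N columns named \code{x1_1, y1_1, vx_1, vy_1, ...}), plus
#'   \code{groups}, the group index of each boid.
#' @export
simulate_boids <- function(n_boids = 16, canvas = 300, T = 100,
                           group_turn = 0.06, alpha = 0, delta_max = 0,
                           speed = 4,
                           r_cohesion = 60, r_separation = 12,
                           w_cohesion = 0.004, w_alignment = 0.08,
                           w_separation = 0.12, init_radius = 30,
                           group_headings = c(0, pi), seed = 1) {
  stopifnot(n_boids >= 1, alpha >= 0, alpha <= 1, delta_max >= 0, T >= 1)
  groups <- rep(1:2, length.out = n_boids)
  res <- withr::with_seed(as.integer(seed), {
    # all boids start near the canvas center with group-specific headings
    pos <- t(vapply(seq_len(n_boids), function(i) {
      r <- init_radius * sqrt(stats::runif(1))
      a <- stats::runif(1, 0, 2 * pi)
      canvas / 2 + r * c(cos(a), sin(a))
    }, numeric(2)))
    vel <- t(vapply(seq_len(n_boids), function(i) {
      a <- group_headings[groups[i]] + stats::rnorm(1, sd = 0.05)
      speed * c(cos(a), sin(a))
    }, numeric(2)))
    state <- matrix(0, T, 4 * n_boids)
    for (t in seq_len(T)) {
      state[t, ] <- as.vector(t(cbind(pos, vel)))
      upd <- boids_step(pos, vel, groups, canvas, group_turn, alpha, speed,
                        r_cohesion, r_separation,
                        w_cohesion, w_alignment, w_separation)
      pos <- upd$pos
      vel <- upd$vel
    }
    obs <- state
    if (delta_max > 0)
      obs <- state + matrix(stats::rnorm(length(state), sd = delta_max),
                            nrow(state), ncol(state))
    list(state = state, obs = obs)
  })
  nm <- as.vector(vapply(seq_len(n_boids), function(i)
    paste0(c("x", "y", "vx", "vy"), "_", i), character(4)))
  clean <- tibble::as_tibble(as.data.frame(res$state))
  observed <- tibble::as_tibble(as.data.frame(res$obs))
  names(clean) <- names(observed) <- nm
  list(clean = clean, observed = observed, groups = groups)
}

boids_step <- function(pos, vel, groups, canvas, group_turn, alpha, speed,
                       r_cohesion, r_separation,
                       w_cohesion, w_alignment, w_separation) {
  n <- nrow(pos)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  # nearest image on the torus
  dx <- dx - canvas * round(dx / canvas)
  dy <- dy - canvas * round(dy / canvas)
  d2 <- dx^2 + dy^2
  diag(d2) <- Inf
  newvel <- vel
  for (i in seq_len(n)) {
    steer <- c(0, 0)
    nb <- which(d2[i, ] < r_cohesion^2 & groups == groups[i])
    if (length(nb) > 0) {
      # cohesion: toward the (torus-consistent) neighbor centroid
      rel <- cbind(-dx[i, nb], -dy[i, nb])
      steer <- steer + w_cohesion * colMeans(rel)
      steer <- steer + w_alignment *
        (colMeans(vel[nb, , drop = FALSE]) - vel[i, ])
    }
    close <- which(d2[i, ] < r_separation^2)
    if (length(close) > 0) {
      rel <- cbind(dx[i, close], dy[i, close])
      steer <- steer + w_separation * colMeans(rel)
    }
    v <- vel[i, ] + steer
    turn <- if (groups[i] == 1) group_turn else -group_turn
    if (alpha > 0) turn <- turn + stats::runif(1, -alpha * pi, alpha * pi)
    rot <- matrix(c(cos(turn), sin(turn), -sin(turn), cos(turn)), 2, 2)
    v <- as.vector(rot %*% v)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v * speed / nv
    newvel[i, ] <- v
  }
  newpos <- (pos + newvel) %% canvas
  list(pos = newpos, vel = newvel)
}

#' Stable linear dynamics embedded by coordinate duplication
#'
#' Fixture generator for scale-scan tests: draws a random stable linear map
#' A (spectral radius < 1, redrawn until stable) in \code{dim_true}
#' dimensions, runs \eqn{z_{t+1} = A z_t}, and observes it in
#' \code{dim_obs} dimensions by cycling through the true coordinates
#' (duplication) plus Gaussian observation noise.  The observed series
#' therefore has exactly \code{dim_true} underlying degrees of freedom.
#'
#' @param dim_true True latent dimension.
#' @param dim_obs Observed dimension (>= dim_true).
#' @param noise Observation noise standard deviation.
#' @param T Steps per trajectory.
#' @param seed Integer seed.
#' @param n_traj Number of trajectories (independent random initial states).
#' @return A list of tibbles with columns \code{x1..x<dim_obs>}; each carries
#'   attributes \code{"latent"} (T x dim_true matrix) and \code{"A"}.
#' @export
duplicated_linear_system <- function(dim_true, dim_obs, noise = 0.01,
                                     T = 100, seed = 1, n_traj = 1) {
  if (dim_true > dim_obs)
    stop("invalid input: dim_true must be <= dim_obs")
  withr::with_seed(as.integer(seed), {
    # rotation-like stable map: orthogonal factor scaled just below 1, so
    # trajectories persist instead of collapsing to the origin
    repeat {
      Q <- qr.Q(qr(matrix(stats::rnorm(dim_true^2), dim_true, dim_true)))
      A <- 0.98 * Q
      if (max(Mod(eigen(A, only.values = TRUE)$values)) < 1) break
    }
    dup <- rep(seq_len(dim_true), length.out = dim_obs)
    lapply(seq_len(n_traj), function(k) {
      # initial states on a moderate radius band so every trajectory sweeps
      # a comparable region of state space
      z <- stats::rnorm(dim_true)
      z <- z / sqrt(sum(z^2)) * stats::runif(1, 0.5, 1.5)
      latent <- matrix(0, T, dim_true)
      for (t in seq_len(T)) {
        latent[t, ] <- z
        z <- drop(A %*% z)
      }
      eps <- matrix(stats::rnorm(T * dim_obs, sd = noise), T, dim_obs)
      if (noise == 0) eps[] <- 0
      obs <- latent[, dup, drop = FALSE] + eps
      out <- tibble::as_tibble(as.data.frame(obs))
      names(out) <- paste0("x", seq_len(dim_obs))
      attr(out, "latent") <- latent
      attr(out, "A") <- A
      out
    })
  })
}
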