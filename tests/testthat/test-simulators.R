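test_that("the SIR field matches the epidemic equations", {
  # disease-free equilibria
  for (s in c(0, 0.4, 1)) expect_equal(sir_field(s, 0), c(0, 0))
  # early-epidemic growth: di/dt = beta*s*i - gamma*i
  expect_equal(sir_field(0.99, 0.01), c(-0.0099, 0.0049), tolerance = 1e-12)
  # threshold beta*s = gamma stalls the infection
  expect_equal(sir_field(0.5, 0.2)[2], 0, tolerance = 1e-12)
  expect_error(sir_field(0.8, 0.3), "simplex")
  expect_error(sir_field(-0.1, 0.1), "simplex")
})

test_that("SIR trajectories duplicate the latent state and conserve mass", {
  traj <- simulate_sir(n_traj = 4, T = 50, sigma = 0, seed = 2)
  expect_length(traj, 4)
  for (s in traj) {
    m <- as.matrix(as.data.frame(s))
    # sigma = 0: the duplicated coordinates are identical
    expect_equal(m[, 1], m[, 2], tolerance = 1e-12)
    expect_equal(m[, 3], m[, 4], tolerance = 1e-12)
    lat <- attr(s, "latent")
    expect_true(all(lat >= -1e-9 & lat <= 1 + 1e-9))
    # S + I + R = 1 throughout, to integrator tolerance
    expect_lt(max(abs(rowSums(cbind(lat, 1 - rowSums(lat))) - 1)), 1e-6)
    # infections rise then fall when beta*S0 > gamma
    if (lat[1, 1] > 0.5 && lat[1, 2] > 0.01) {
      i <- lat[, 2]
      pk <- which.max(i)
      expect_true(all(diff(i[seq_len(pk)]) >= -1e-12))
      if (pk < length(i)) expect_true(all(diff(i[pk:length(i)]) <= 1e-12))
    }
  }
  # partial region excludes the S <= 1/3 corner
  part <- simulate_sir(n_traj = 20, T = 2, sigma = 0, region = "partial",
                       seed = 3)
  s0 <- vapply(part, function(s) attr(s, "latent")[1, 1], numeric(1))
  expect_true(all(s0 > 1 / 3))
  # seeded bitwise reproducibility
  expect_identical(simulate_sir(n_traj = 2, T = 10, sigma = 1e-3, seed = 9),
                   simulate_sir(n_traj = 2, T = 10, sigma = 1e-3, seed = 9))
})

test_that("boids obey constant-turn kinematics and the noise contracts", {
  # single boid, no neighbors: exact circular motion
  one <- simulate_boids(n_boids = 1, T = 40, group_turn = 0.12, alpha = 0,
                        delta_max = 0, speed = 3, seed = 4)
  M <- as.matrix(as.data.frame(one$clean))
  a <- atan2(M[, 4], M[, 3])
  d <- diff(a)
  d <- atan2(sin(d), cos(d))
  expect_lt(max(abs(d - 0.12)), 1e-6)
  speed <- sqrt(M[, 3]^2 + M[, 4]^2)
  expect_lt(max(abs(speed - 3)), 1e-9)

  # determinism
  expect_identical(simulate_boids(n_boids = 4, T = 20, seed = 5),
                   simulate_boids(n_boids = 4, T = 20, seed = 5))

  # extrinsic noise is observational only: clean series unchanged
  base <- simulate_boids(n_boids = 4, T = 20, delta_max = 0, seed = 6)
  noisy <- simulate_boids(n_boids = 4, T = 20, delta_max = 2, seed = 6)
  expect_identical(base$clean, noisy$clean)
  expect_false(isTRUE(all.equal(noisy$clean, noisy$observed)))

  # group centroids trace smooth arcs under zero noise: bounded per-step
  # direction change of the centroid displacement
  sim <- simulate_boids(n_boids = 8, T = 60, group_turn = 0.08, speed = 3,
                        alpha = 0, seed = 7)
  M <- as.matrix(as.data.frame(sim$clean))
  for (g in 1:2) {
    ids <- which(sim$groups == g)
    cx <- rowMeans(M[, 4 * (ids - 1) + 1, drop = FALSE])
    cy <- rowMeans(M[, 4 * (ids - 1) + 2, drop = FALSE])
    ang <- atan2(diff(cy), diff(cx))
    dd <- atan2(sin(diff(ang)), cos(diff(ang)))
    expect_lt(max(abs(dd)), 0.35)
  }
})

test_that("duplicated linear systems expose their true rank", {
  # exact recurrence when noise = 0, dim_true = dim_obs
  dat <- duplicated_linear_system(2, 2, noise = 0, T = 40, seed = 1)[[1]]
  m <- as.matrix(as.data.frame(dat))
  A <- attr(dat, "A")
  pred <- m[-nrow(m), ] %*% t(A)
  expect_lt(max(abs(pred - m[-1, ])), 1e-10)

  # duplicated columns correlate perfectly at zero noise
  d4 <- duplicated_linear_system(2, 4, noise = 0, T = 40, seed = 2)[[1]]
  m4 <- as.matrix(as.data.frame(d4))
  expect_equal(cor(m4[, 1], m4[, 3]), 1, tolerance = 1e-12)
  expect_equal(cor(m4[, 2], m4[, 4]), 1, tolerance = 1e-12)

  # sample covariance collapses to rank dim_true as noise -> 0
  dn <- duplicated_linear_system(2, 4, noise = 1e-6, T = 200, seed = 3)[[1]]
  ev <- eigen(cov(as.matrix(as.data.frame(dn))), only.values = TRUE)$values
  expect_lt(ev[3] / ev[2], 1e-6)

  expect_error(duplicated_linear_system(4, 2), "dim_true")
  expect_identical(duplicated_linear_system(2, 4, T = 20, seed = 5),
                   duplicated_linear_system(2, 4, T = 20, seed = 5))
})
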