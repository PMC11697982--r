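test_that("discrete EI reproduces the worked-example chain and degenerate cases", {
  # 2-state perfect channel: one bit
  expect_equal(ei_discrete(diag(2)), 1.0, tolerance = 1e-12)

  # the 8-state chain: exact closed form 3 - (7/8) log2(7)
  tpm <- fig_chain_tpm()
  expect_equal(ei_discrete(tpm), 3 - (7 / 8) * log2(7), tolerance = 1e-12)

  # identical rows carry no information about the next state
  same <- matrix(c(0.2, 0.3, 0.5), 3, 3, byrow = TRUE)
  expect_equal(ei_discrete(same), 0, tolerance = 1e-12)

  # permutation matrices achieve the log2(n) maximum
  for (n in c(2, 4, 7)) {
    perm <- diag(n)[sample(n), ]
    expect_equal(ei_discrete(perm), log2(n), tolerance = 1e-12)
  }

  # natural-log base scales EI by log(2)
  expect_equal(ei_discrete(diag(2), log_base = exp(1)), log(2),
               tolerance = 1e-12)
})

test_that("discrete EI equals brute-force mutual information on random chains", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    tpm <- random_tpm(n)
    expect_equal(ei_discrete(tpm), mi_brute_force(tpm), tolerance = 1e-10)
    expect_gte(ei_discrete(tpm), -1e-12)
  }
})

test_that("discrete EI validates its inputs", {
  bad <- matrix(c(0.5, 0.6, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_error(ei_discrete(bad), "row 1")
  expect_error(ei_discrete(diag(2), log_base = 1), "log_base")
  expect_error(ei_discrete(diag(2), log_base = -2), "log_base")
  expect_error(ei_discrete(matrix(1, 2, 3)), "square")
})

test_that("coarse-graining a chain preserves row-stochasticity and the worked example", {
  tpm <- fig_chain_tpm()
  macro <- coarse_grain_tpm(tpm, list(1:7, 8))
  expect_equal(macro, diag(2), tolerance = 1e-12)

  # singleton partition is the identity coarse-graining
  expect_equal(coarse_grain_tpm(tpm, as.list(1:8)), tpm, tolerance = 1e-12)

  # total aggregation gives the trivial one-state chain
  expect_equal(coarse_grain_tpm(tpm, list(1:8)), matrix(1), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    k <- sample(2:(n - 1), 1)
    groups <- split(sample(n), rep(seq_len(k), length.out = n))
    m <- coarse_grain_tpm(random_tpm(n), unname(groups))
    expect_equal(rowSums(m), rep(1, k), tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1 + 1e-12))
  }

  expect_error(coarse_grain_tpm(tpm, list(1:7)), "partition")
  expect_error(coarse_grain_tpm(tpm, list(1:7, 7:8)), "overlap")
})

test_that("causal-emergence degree is a guarded difference", {
  expect_equal(delta_j(1.0, 3 - (7 / 8) * log2(7)), 0.4564356,
               tolerance = 1e-6)
  expect_equal(delta_j(0.37, 0.37), 0)
  expect_equal(delta_j(0.2, 0.7), -0.5)
  # antisymmetry
  set.seed(1)
  for (rep in 1:10) {
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(delta_j(a, b), -delta_j(b, a), tolerance = 1e-12)
  }
  expect_error(delta_j(Inf, 1), "finite")
  expect_error(delta_j(1, NaN), "finite")
})

test_that("continuous EI matches closed forms for linear maps", {
  # identity map: zero-variance Monte Carlo, exact closed form
  for (q in c(1, 3)) {
    sig <- rep(0.05, q)
    est <- ei_continuous_mc(identity, noise_sigmas = sig, range_L = 2,
                            mc_samples = 50, seed = 1,
                            jacobian = function(y) diag(q))
    expect_equal(est$mc_stderr, 0, tolerance = 1e-10)
    expect_equal(est$ei_total,
                 q * log(4) - (q / 2) * log(2 * pi * exp(1)) - sum(log(sig)),
                 tolerance = 1e-10)
    expect_equal(est$j_dim_avg * q, est$ei_total, tolerance = 1e-12)
  }

  # a rotation is volume preserving: same EI as the identity
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  est_rot <- ei_continuous_mc(function(y) drop(R %*% y),
                              noise_sigmas = c(0.1, 0.2), range_L = 1.5,
                              mc_samples = 64, seed = 2)
  est_id <- ei_continuous_mc(identity, noise_sigmas = c(0.1, 0.2),
                             range_L = 1.5, mc_samples = 64, seed = 3)
  expect_equal(est_rot$ei_total, est_id$ei_total, tolerance = 1e-8)
})

test_that("continuous EI agrees with numerical mutual information for y = 2x", {
  # oracle: I(X;Y) for Y = 2X + eps, X ~ U(-1,1), eps ~ N(0, 0.01), by
  # numerical integration of h(Y) - h(Y | X)
  sigma <- 0.1
  h_cond <- 0.5 * log(2 * pi * exp(1) * sigma^2)
  f_y <- function(y) {
    # density of Y: convolution of U(-2,2)/4 with the Gaussian kernel
    (stats::pnorm((y + 2) / sigma) - stats::pnorm((y - 2) / sigma)) / 4
  }
  grid <- seq(-2.8, 2.8, length.out = 20001)
  fy <- f_y(grid)
  h_y <- -sum(ifelse(fy > 0, fy * log(fy), 0)) * diff(grid[1:2])
  oracle <- h_y - h_cond

  est <- ei_continuous_mc(function(y) 2 * y, noise_sigmas = sigma,
                          range_L = 1, mc_samples = 200, seed = 4)
  # linear map: MC variance is zero, so compare against a small absolute
  # band dominated by the uniform-boundary smoothing the closed form omits
  expect_lt(abs(est$ei_total - oracle), 0.06)
})

test_that("continuous EI rejects invalid parameters and degenerate maps stay finite", {
  expect_error(ei_continuous_mc(identity, noise_sigmas = 0.1, range_L = 1,
                                mc_samples = 0), "mc_samples")
  expect_error(ei_continuous_mc(identity, noise_sigmas = -1, range_L = 1),
               "noise_sigmas")
  expect_error(ei_continuous_mc(identity, noise_sigmas = 0.1, range_L = 0),
               "range_L")
  # rank-deficient Jacobian: singular values floored, EI finite and very low
  est <- ei_continuous_mc(function(y) c(y[1] + y[2], y[1] + y[2]),
                          noise_sigmas = c(0.1, 0.1), range_L = 1,
                          mc_samples = 16, seed = 1,
                          jacobian = function(y) matrix(1, 2, 2))
  expect_true(is.finite(est$ei_total))
  expect_lt(est$ei_total, -20)
})

test_that("transition matrices round-trip through CSV", {
  tpm <- random_tpm(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tpm(tpm, path)
  expect_equal(read_tpm(path), tpm, tolerance = 1e-12)
})
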