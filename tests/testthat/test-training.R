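test_that("the training loss decomposes as documented", {
  model <- list(encoder = random_map(4, 2, seed = 3),
                dynamics = dynamics_pair(2, seed = 4),
                config = train_config(q = 2, lambda = 0.5))
  withr::with_seed(5, {
    X0 <- matrix(rnorm(24), 6, 4)
    X1 <- matrix(rnorm(24), 6, 4)
  })
  l <- nisplus_loss(model, X0, X1, noise_seed = 2)
  expect_equal(l$total, l$inverse + 0.5 * l$forward, tolerance = 1e-12)

  # lambda = 0: total equals the inverse term alone
  model0 <- model
  model0$config$lambda <- 0
  l0 <- nisplus_loss(model0, X0, X1, noise_seed = 2)
  expect_equal(l0$total, l0$inverse, tolerance = 1e-12)

  # identity g on a static series: inverse term vanishes
  static <- nisplus_loss(model, X0, X0, noise_seed = 2)
  expect_equal(static$inverse, 0, tolerance = 1e-12)

  # a perfect model on noiseless data: both terms zero (q = p identity)
  ident <- list(encoder = coarse_grainer(2, 2, seed = 1),
                dynamics = dynamics_pair(2, seed = 1),
                config = train_config(q = 2, lambda = 1))
  Z <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  li <- nisplus_loss(ident, Z, Z)
  expect_equal(li$forward, 0, tolerance = 1e-10)
  expect_equal(li$inverse, 0, tolerance = 1e-10)

  expect_error(nisplus_loss(model, X0, X1[1:3, ]), "unaligned")
})

test_that("training is reproducible and tracks finite EI", {
  dat <- duplicated_linear_system(2, 2, noise = 0.01, T = 30, seed = 4,
                                  n_traj = 4)
  cfg <- train_config(q = 2, epochs = 12, seed = 21, warmup_epochs = 3,
                      ei_mc_samples = 50)
  m1 <- train_nisplus(dat, cfg)
  m2 <- train_nisplus(dat, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(unlist(m1$dynamics$f), unlist(m2$dynamics$f))
  expect_equal(nrow(m1$history), 12)
  expect_true(all(is.finite(m1$history$j)))
  expect_true(all(is.finite(m1$history$loss_forward)))
})

test_that("a deterministic linear micro system is fitted tightly at q = p", {
  lf <- fx_lin_fit()
  nm <- macrodyn:::eval_nmae(lf$model, steps = 10)
  expect_lt(nm, 0.05)
})

test_that("training on noisy SIR drives dimension-averaged EI upward", {
  m <- fx_sir_model()
  j <- m$history$j
  n <- length(j)
  expect_gt(mean(j[(n - 9):n]), mean(j[1:10]))
  expect_true(all(is.finite(j)))
})

test_that("normalized MAE is anchored and scale-free", {
  withr::with_seed(2, truth <- matrix(rnorm(60), 20, 3))
  expect_equal(normalized_mae(truth, truth), 0)
  anchor <- matrix(colMeans(truth), 20, 3, byrow = TRUE)
  expect_equal(normalized_mae(anchor, truth), 1, tolerance = 1e-12)
  pred <- truth + 0.1
  expect_equal(normalized_mae(2 * pred, 2 * truth),
               normalized_mae(pred, truth), tolerance = 1e-12)
  expect_error(normalized_mae(truth, truth[1:5, ]), "shapes")
  expect_warning(raw <- normalized_mae(matrix(1, 4, 2), matrix(2, 4, 2)),
                 "constant")
  expect_equal(as.numeric(raw), 1)
})

test_that("quantify_ce flags scales and degenerates correctly", {
  rep2 <- fx_sir_report()
  expect_s3_class(rep2, "ce_report")
  expect_equal(rep2$delta_j, rep2$j_macro - rep2$j_micro, tolerance = 1e-12)
  expect_identical(rep2$valid, rep2$nmae <= 0.3)

  # q = p: the same model plays both roles, so delta_j is exactly zero
  dat <- duplicated_linear_system(2, 2, noise = 0.01, T = 30, seed = 4,
                                  n_traj = 4)
  cfg <- train_config(q = 2, epochs = 10, seed = 2, warmup_epochs = 3,
                      ei_mc_samples = 50)
  r <- quantify_ce(dat, 2, cfg)
  expect_equal(r$delta_j, 0)
  expect_error(quantify_ce(dat, 5, cfg), "q must be")
})

test_that("pure-noise data fail the prediction validity gate", {
  withr::with_seed(13, {
    noise <- lapply(1:6, function(k) matrix(rnorm(40 * 3), 40, 3))
  })
  cfg <- train_config(q = 2, epochs = 40, seed = 3, warmup_epochs = 5,
                      ei_mc_samples = 50)
  r <- quantify_ce(noise, 2, cfg)
  expect_false(r$valid)
  expect_gt(r$nmae, 0.3)
})

test_that("scan_q reports scales in order with a shared micro reference", {
  sc <- fx_lin_scan()
  expect_equal(sc$q, 1:4)
  expect_equal(length(unique(sc$j_micro)), 1)
  expect_equal(sc$delta_j[sc$q == 4], 0)

  dat <- duplicated_linear_system(2, 2, noise = 0.01, T = 30, seed = 4,
                                  n_traj = 4)
  cfg <- train_config(q = 2, epochs = 10, seed = 2, warmup_epochs = 3,
                      ei_mc_samples = 50)
  single <- scan_q(dat, 2, cfg)
  expect_equal(nrow(single), 1)
  expect_equal(single$delta_j, 0)
  expect_error(scan_q(dat, c(1, 3), cfg), "q must be")
})

test_that("out-of-distribution training degrades but does not break prediction", {
  cfg <- train_config(q = 2, epochs = 120, seed = 17, warmup_epochs = 10,
                      ei_mc_samples = 100)
  full <- simulate_sir(n_traj = 16, T = 50, sigma = 1e-3, region = "full",
                       seed = 31)
  part <- simulate_sir(n_traj = 16, T = 50, sigma = 1e-3, region = "partial",
                       seed = 31)
  m_full <- train_nisplus(full, cfg)
  m_part <- train_nisplus(part, cfg)

  # evaluate both on the region the partial model never saw (S0 <= 1/3)
  withr::with_seed(32, {
    test <- simulate_sir(n_traj = 12, T = 20, sigma = 1e-3, seed = 33)
  })
  held <- Filter(function(s) attr(s, "latent")[1, 1] <= 1 / 3, test)
  expect_gt(length(held), 0)
  nm_one <- function(model) {
    preds <- lapply(held, function(s) {
      X <- as.matrix(as.data.frame(s))
      rollout(model, X[1, ], 5, noise_seed = 41)
    })
    truths <- lapply(held, function(s) as.matrix(as.data.frame(s))[2:6, ])
    normalized_mae(do.call(rbind, preds), do.call(rbind, truths))
  }
  nm_full <- nm_one(m_full)
  nm_part <- nm_one(m_part)
  expect_true(is.finite(nm_full) && is.finite(nm_part))
  expect_gte(nm_part, nm_full)
})

test_that("tidiers and plots summarize fitted models", {
  m <- fx_sir_model()
  td <- tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("epoch", "loss_forward", "loss_inverse", "j") %in%
                    names(td)))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$q, 2L)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(fx_lin_scan()), "ggplot")
  sal <- matrix(runif(8), 2, 4)
  expect_s3_class(plot_saliency(sal), "ggplot")
})
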