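#' Effective information of a discrete Markov chain
#'
#' Effective information (EI) is the mutual information between the current
#' and the next state of a Markov chain when the current state is forced, via
#' a do-intervention, to be uniformly distributed over the n states:
#' \deqn{EI = H(\bar y) - \frac{1}{n}\sum_i H(P_{i\cdot}),}
#' where \eqn{\bar y} is the column mean of the transition matrix and H is
#' Shannon entropy (with \eqn{0\log 0 = 0}).  EI is large when the dynamics
#' is both deterministic (low row entropies) and non-degenerate (spread-out
#' effect distribution).
#'
#' @param tpm An n x n row-stochastic transition probability matrix
#'   (row i = distribution of the next state given current state i).
#' @param log_base Logarithm base; 2 gives bits (default), \code{exp(1)} nats.
#' @return EI as a single number (>= 0).
#' @examples
#' ei_discrete(diag(2))                 # a perfect 1-bit channel
#' @export
ei_discrete <- function(tpm, log_base = 2) {
  tpm <- validate_tpm(tpm)
  check_log_base(log_base)
  ybar <- colMeans(tpm)
  (shannon_entropy(ybar, log_base) -
     mean(apply(tpm, 1, shannon_entropy, log_base = log_base)))
}

shannon_entropy <- function(p, log_base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = log_base))
}

check_log_base <- function(log_base) {
  if (!is.numeric(log_base) || length(log_base) != 1 ||
      !is.finite(log_base) || log_base <= 0 || log_base == 1)
    stop("invalid parameter: log_base must be positive and != 1")
}

validate_tpm <- function(tpm, tol = 1e-9) {
  if (is.data.frame(tpm)) tpm <- as.matrix(tpm)
  if (!is.matrix(tpm) || nrow(tpm) != ncol(tpm) || nrow(tpm) < 1)
    stop("invalid input: tpm must be a square matrix with n >= 1")
  if (any(tpm < -tol) || any(tpm > 1 + tol))
    stop("invalid input: transition probabilities must lie in [0, 1]")
  rs <- rowSums(tpm)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0)
    stop(sprintf("invalid input: row %d of tpm sums to %.12g, not 1",
                 bad[1], rs[bad[1]]))
  tpm
}

#' Coarse-grain a transition matrix under a state partition
#'
#' Groups micro-states into macro-states and forms the macro transition
#' matrix: entry (A, B) is the average over micro-states i in group A of the
#' total probability of transitioning into group B (uniform weighting within
#' groups).  The result is row-stochastic.
#'
#' @param tpm An n x n row-stochastic matrix.
#' @param partition A list of disjoint integer vectors covering 1..n.
#' @return The macro transition matrix (length(partition) square).
#' @examples
#' tpm <- fig_chain_tpm()   # 8-state chain: 7 mixing states + 1 absorbing
#' coarse_grain_tpm(tpm, list(1:7, 8))
#' @export
coarse_grain_tpm <- function(tpm, partition) {
  tpm <- validate_tpm(tpm)
  n <- nrow(tpm)
  if (!is.list(partition) || length(partition) < 1)
    stop("invalid partition: must be a non-empty list of index vectors")
  idx <- unlist(partition)
  if (any(duplicated(idx)))
    stop("invalid partition: groups overlap")
  if (!setequal(idx, seq_len(n)) || length(idx) != n)
    stop("invalid partition: groups must cover states 1..n exactly")
  if (any(lengths(partition) == 0))
    stop("invalid partition: empty group")
  m <- length(partition)
  macro <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    macro[a, b] <- mean(rowSums(tpm[partition[[a]], partition[[b]],
                                    drop = FALSE]))
  }
  macro
}

#' The 8-state worked-example chain
#'
#' A Markov chain in which states 1--7 each transition uniformly among
#' states 1--7 and state 8 is absorbing.  Grouping \{1..7\} into one
#' macro-state turns it into a perfect 2-state channel: the macro EI
#' (1 bit) exceeds the micro EI (about 0.544 bits), a minimal example of
#' causal emergence.
#'
#' @return An 8 x 8 row-stochastic matrix.
#' @export
fig_chain_tpm <- function() {
  tpm <- matrix(0, 8, 8)
  tpm[1:7, 1:7] <- 1 / 7
  tpm[8, 8] <- 1
  tpm
}

#' Degree of causal emergence
#'
#' The difference in (dimension-averaged) effective information between a
#' macro-scale and a micro-scale dynamics.  A positive value indicates
#' causal emergence: the coarse-grained dynamics has stronger causal effects
#' than the micro dynamics it summarizes.
#'
#' @param j_macro EI (or dimension-averaged EI) of the macro dynamics.
#' @param j_micro EI of the micro dynamics, in the same units.
#' @return \code{j_macro - j_micro}.
#' @export
delta_j <- function(j_macro, j_micro) {
  if (!is.numeric(j_macro) || !is.numeric(j_micro) ||
      !all(is.finite(c(j_macro, j_micro))))
    stop("invalid input: j_macro and j_micro must be finite numbers")
  j_macro - j_micro
}

#' Monte-Carlo effective information of a continuous dynamics
#'
#' Estimates the EI of a differentiable map \eqn{f: R^q \to R^q} viewed as a
#' Gaussian channel \eqn{y' = f(y) + \epsilon},
#' \eqn{\epsilon \sim N(0, \mathrm{diag}(\sigma^2))}, under a uniform
#' do-intervention \eqn{y \sim U([-L, L]^q)}:
#' \deqn{EI = E_y[\ln|\det J_f(y)|] + \sum_i\ln(2L_i) - \frac{q}{2}\ln(2\pi e)
#'       - \sum_i \ln\sigma_i,}
#' with the expectation taken by Monte-Carlo over \code{mc_samples} uniform
#' draws.  Singular values of the Jacobian are floored at 1e-12 so that
#' degenerate maps yield large-negative rather than non-finite EI.
#'
#' @param f A function mapping a q-vector to a q-vector.
#' @param noise_sigmas Positive q-vector of per-dimension output noise scales.
#' @param range_L Half-width of the intervention box (> 0): a scalar for a
#'   hypercube or a q-vector of per-dimension half-widths.  Per-dimension
#'   widths keep EI invariant under diagonal rescalings of the state space
#'   (noise, range and Jacobian terms then shift together).
#' @param mc_samples Number of Monte-Carlo draws (>= 1).
#' @param seed Integer seed for the draws.
#' @param jacobian Optional function returning the exact q x q Jacobian of
#'   \code{f} at a point; when NULL a central finite difference
#'   (\code{pracma::jacobian}) is used.
#' @param log_base Base for the information units; default natural log (nats).
#' @return An object of class \code{continuous_ei} with fields
#'   \code{ei_total}, \code{j_dim_avg} (\eqn{EI/q}), \code{mc_samples},
#'   \code{mc_stderr}, \code{range_L} and \code{noise_sigmas}.
#' @examples
#' est <- ei_continuous_mc(function(y) 2 * y, noise_sigmas = 0.1,
#'                         range_L = 1, mc_samples = 200, seed = 1)
#' est$ei_total   # ~ log(2) + log(2) - 0.5 * log(2 * pi * exp(1) * 0.01)
#' @export
ei_continuous_mc <- function(f, noise_sigmas, range_L, mc_samples = 1000,
                             seed = 1, jacobian = NULL, log_base = exp(1)) {
  if (mc_samples < 1) stop("invalid parameter: mc_samples must be >= 1")
  if (!all(is.finite(noise_sigmas)) || any(noise_sigmas <= 0))
    stop("invalid parameter: noise_sigmas must be positive")
  if (!all(is.finite(range_L)) || any(range_L <= 0))
    stop("invalid parameter: range_L must be > 0")
  check_log_base(log_base)
  q <- length(noise_sigmas)
  range_L <- rep(as.numeric(range_L), length.out = q)
  jac <- jacobian %||% function(y) pracma::jacobian(function(z) f(z), y)
  logdets <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(mc_samples), function(i) {
      y <- stats::runif(q, -range_L, range_L)      # recycles per dimension
      J <- jac(y)
      if (!all(is.finite(J)))
        stop("estimation failure: non-finite Jacobian at a sampled point")
      sv <- svd(J, nu = 0, nv = 0)$d
      sum(log(pmax(sv, 1e-12)))
    }, numeric(1))
  })
  ei_nats <- mean(logdets) + sum(log(2 * range_L)) -
    (q / 2) * log(2 * pi * exp(1)) - sum(log(noise_sigmas))
  scale <- log(log_base)
  se <- if (mc_samples > 1) stats::sd(logdets) / sqrt(mc_samples) else 0
  structure(
    list(ei_total = ei_nats / scale,
         j_dim_avg = ei_nats / scale / q,
         mc_samples = as.integer(mc_samples),
         mc_stderr = se / scale,
         range_L = range_L,
         noise_sigmas = noise_sigmas,
         log_base = log_base),
    class = "continuous_ei"
  )
}

#' @export
print.continuous_ei <- function(x, ...) {
  cat(sprintf(
    "<continuous_ei> EI = %.4f (J = %.4f per dim, base %.3g) +/- %.4f MC se, %d samples\n",
    x$ei_total, x$j_dim_avg, x$log_base, x$mc_stderr, x$mc_samples))
  invisible(x)
}

#' Read / write a transition matrix as CSV
#'
#' Plain n x n numeric CSV, one row per origin state; header optional on read.
#'
#' @param path File path.
#' @param tpm Matrix to write.
#' @return \code{read_tpm} returns the validated matrix.
#' @export
read_tpm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- utils::read.csv(path, header = FALSE, nrows = 1)
  has_header <- !all(vapply(first, is.numeric, logical(1)))
  m <- as.matrix(utils::read.csv(path, header = has_header))
  dimnames(m) <- NULL
  validate_tpm(m)
}

#' @rdname read_tpm
#' @export
write_tpm <- function(tpm, path) {
  utils::write.table(tpm, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
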