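#' Gaussian kernel density estimator over macro-states
#'
#' Product-Gaussian KDE with per-dimension bandwidths.  Used to estimate the
#' observed macro-state density \eqn{p(y)} whose inverse re-targets the
#' training distribution to the uniform do-intervention distribution.
#'
#' @param y_samples An N x q matrix (or data frame) of macro-state samples,
#'   N >= 2.
#' @param bandwidth \code{"auto"} (Scott's rule per dimension,
#'   \eqn{h_j = sd_j N^{-1/(q+4)}}) or a positive scalar / q-vector.
#' @return A function \code{function(points)} returning the density at the
#'   rows of \code{points}; bandwidths are attached as attribute
#'   \code{"bandwidth"}.
#' @export
estimate_density <- function(y_samples, bandwidth = "auto") {
  Y <- as.matrix(y_samples)
  if (nrow(Y) < 2) stop("invalid input: need at least 2 samples")
  if (!all(is.finite(Y))) stop("invalid input: non-finite samples")
  q <- ncol(Y)
  n <- nrow(Y)
  h <- if (identical(bandwidth, "auto")) {
    apply(Y, 2, stats::sd) * n^(-1 / (q + 4))
  } else {
    rep(as.numeric(bandwidth), length.out = q)
  }
  if (any(h <= 1e-12)) {
    warning("zero-variance dimension: bandwidth floored")
    h <- pmax(h, 1e-6)
  }
  norm_const <- 1 / (n * prod(h * sqrt(2 * pi)))
  f <- function(points) {
    P <- as.matrix(points)
    if (is.null(dim(points)) && q == 1) P <- matrix(points, ncol = 1)
    if (ncol(P) != q) stop("invalid input: wrong point dimension")
    out <- numeric(nrow(P))
    # chunked pairwise evaluation keeps memory bounded for large N
    chunk <- max(1L, floor(2e6 / n))
    for (start in seq(1, nrow(P), by = chunk)) {
      idx <- start:min(start + chunk - 1, nrow(P))
      acc <- matrix(0, length(idx), n)
      for (j in seq_len(q)) {
        D <- outer(P[idx, j], Y[, j], "-") / h[j]
        acc <- acc + D^2
      }
      out[idx] <- rowSums(exp(-acc / 2)) * norm_const
    }
    out
  }
  attr(f, "bandwidth") <- h
  f
}

#' Inverse-probability weights targeting a uniform macro distribution
#'
#' Computes per-sample weights \eqn{w_i \propto \tilde p(y_i) / \hat p(y_i)}
#' where \eqn{\tilde p} is uniform over the observed support box (a constant
#' that cancels into the normalization) and \eqn{\hat p} is the KDE of the
#' observed macro-states.  Weights are clipped at \code{clip_max} and
#' self-normalized to mean 1 (iterating clip and normalize until both hold).
#' Under these weights, weighted empirical expectations emulate expectations
#' under the do-intervention \eqn{y \sim U}.
#'
#' @param y_samples N x q matrix of macro-state samples.
#' @param bandwidth As in [estimate_density()].
#' @param clip_max Maximum allowed weight (default 20).
#' @return An object of class \code{weight_set}: list with \code{weights},
#'   \code{bandwidth}, \code{support_box} (2 x q matrix of lower/upper
#'   bounds) and \code{clip_max}.
#' @export
compute_weights <- function(y_samples, bandwidth = "auto", clip_max = 20) {
  Y <- as.matrix(y_samples)
  if (!all(is.finite(Y))) stop("invalid input: non-finite samples")
  box <- apply(Y, 2, range)
  if (nrow(Y) == 1) {
    w <- 1
    h <- rep(NA_real_, ncol(Y))
  } else if (all(apply(Y, 2, stats::sd) < 1e-12)) {
    warning("all samples identical: uniform weights")
    w <- rep(1, nrow(Y))
    h <- rep(NA_real_, ncol(Y))
  } else {
    dens <- estimate_density(Y, bandwidth)
    h <- attr(dens, "bandwidth")
    p_hat <- pmax(dens(Y), 1e-300)
    w <- 1 / p_hat
    w <- w / mean(w)       # normalize before clipping: 1/density units are
                           # arbitrary, the clip applies to relative weights
    for (it in 1:50) {
      w <- pmin(w, clip_max)
      w <- w / mean(w)
      if (max(w) <= clip_max * (1 + 1e-9)) break
    }
  }
  structure(list(weights = w, bandwidth = h, support_box = box,
                 clip_max = clip_max),
            class = "weight_set")
}

#' Dump a weight set to CSV for inspection
#'
#' One row per training sample, columns \code{index} and \code{weight}.
#'
#' @param ws A \code{weight_set} from [compute_weights()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_weights <- function(ws, path) {
  stopifnot(inherits(ws, "weight_set"))
  utils::write.csv(
    data.frame(index = seq_along(ws$weights), weight = ws$weights),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.weight_set <- function(x, ...) {
  cat(sprintf("<weight_set> n = %d, mean = %.6f, range [%.3g, %.3g], clip %g\n",
              length(x$weights), mean(x$weights), min(x$weights),
              max(x$weights), x$clip_max))
  invisible(x)
}
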