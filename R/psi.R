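#' Synergy-based emergence indicator \eqn{\Psi}
#'
#' An approximate sufficiency test for emergence of a candidate macro
#' variable V over a micro time series: the self-predictive mutual
#' information of the macro variable minus the summed single-variable
#' contributions of the micro dimensions,
#' \deqn{\Psi = I(V_t; V_{t+1}) - \sum_{j=1}^p I(x^{(j)}_t; V_{t+1}).}
#' \eqn{\Psi > 0} is sufficient (not necessary) for the macro variable to
#' carry synergistic predictive information beyond any single micro
#' dimension; double-counted redundancy can push \eqn{\Psi} below zero even
#' when emergence is present.
#'
#' @param micro A T x p matrix or data frame of micro-states, or a list of
#'   such trajectories (transitions are then pooled across trajectories,
#'   never across trajectory boundaries).
#' @param macro_v A length-T vector of candidate macro-states, time-aligned
#'   with \code{micro} (a list of vectors when \code{micro} is a list).
#' @param mi_estimator \code{"gaussian"} (default, continuous data; pairwise
#'   Gaussian mutual information \eqn{-\tfrac12\log_2(1-\rho^2)}) or
#'   \code{"discrete"} (plug-in estimate from joint frequencies of
#'   categorical data).
#' @return \eqn{\Psi} in bits.
#' @examples
#' x <- matrix(rnorm(400), 200, 2)
#' psi_indicator(x, rowMeans(x))
#' @export
psi_indicator <- function(micro, macro_v,
                          mi_estimator = c("gaussian", "discrete")) {
  mi_estimator <- match.arg(mi_estimator)
  as_mat <- function(m) {
    if (is.data.frame(m)) m <- as.matrix(m)
    if (is.null(dim(m))) m <- matrix(m, ncol = 1)
    m
  }
  if (is.list(micro) && !is.data.frame(micro)) {
    if (!is.list(macro_v) || length(macro_v) != length(micro))
      stop("invalid input: macro_v must be a list aligned with micro")
    micro <- lapply(micro, as_mat)
    ok <- mapply(function(m, v) nrow(m) == length(v), micro, macro_v)
    if (!all(ok))
      stop("invalid input: micro and macro_v must have the same length")
    if (any(vapply(micro, nrow, 1L) < 2))
      stop("invalid input: need at least 2 time steps")
    x_now <- do.call(rbind, lapply(micro, function(m)
      m[-nrow(m), , drop = FALSE]))
    v_now <- unlist(lapply(macro_v, function(v) v[-length(v)]))
    v_next <- unlist(lapply(macro_v, function(v) v[-1]))
    v_all <- unlist(macro_v)
  } else {
    micro <- as_mat(micro)
    T_ <- nrow(micro)
    if (length(macro_v) != T_)
      stop("invalid input: micro and macro_v must have the same length")
    if (T_ < 2) stop("invalid input: need at least 2 time steps")
    x_now <- micro[-T_, , drop = FALSE]
    v_now <- macro_v[-T_]
    v_next <- macro_v[-1]
    v_all <- macro_v
  }
  mi <- switch(mi_estimator, gaussian = mi_gaussian, discrete = mi_discrete)
  if (mi_estimator == "gaussian" && stats::sd(v_all) == 0) {
    warning("macro_v is constant; Psi = 0")
    return(0)
  }
  macro_term <- mi(v_now, v_next)
  micro_terms <- vapply(seq_len(ncol(x_now)), function(j) {
    mi(x_now[, j], v_next)
  }, numeric(1))
  macro_term - sum(micro_terms)
}

# Gaussian (parametric) mutual information between two scalar series, bits.
mi_gaussian <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  r <- stats::cor(a, b)
  r2 <- min(r^2, 1 - 1e-12)
  -0.5 * log2(1 - r2)
}

# Plug-in mutual information from the empirical joint of two discrete series.
mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p)
  pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}
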