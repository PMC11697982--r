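#' Integrated-gradients attribution of macro-dimensions to micro-variables
#'
#' Path-integral attribution of each learned macro coordinate
#' \eqn{\phi_k} to each micro dimension j:
#' \deqn{IG_{kj} = (x_j - b_j)\cdot\frac{1}{m}\sum_{s=1}^{m}
#'       \left.\frac{\partial\phi_k}{\partial x_j}\right|_{b + \frac{s-1/2}{m}(x-b)},}
#' a midpoint Riemann approximation along the straight line from the
#' baseline b to x.  IG satisfies completeness: each row sums to
#' \eqn{\phi_k(x) - \phi_k(b)} up to the quadrature error.
#'
#' @param encoder An \code{invertible_map} (the trained coarse-grainer) or a
#'   fitted \code{nisplus_model}.
#' @param x Micro-state p-vector to explain (raw units).
#' @param baseline Baseline p-vector (conventionally the dataset mean).
#' @param n_steps Path resolution (>= 8, default 64).
#' @return An object of class \code{attribution_map}: \code{values}
#'   (q x p matrix), \code{baseline}, \code{n_steps}, \code{normalized}.
#' @export
integrated_gradients <- function(encoder, x, baseline = NULL, n_steps = 64) {
  if (n_steps < 8) stop("invalid parameter: n_steps must be >= 8")
  spec <- if (inherits(encoder, "nisplus_model")) encoder$encoder else encoder
  p <- spec$p
  x <- as.numeric(x)
  baseline <- if (is.null(baseline)) numeric(p) else as.numeric(baseline)
  if (length(x) != p || length(baseline) != p)
    stop("invalid input: x and baseline must be p-vectors")
  acc <- matrix(0, spec$q, p)
  for (s in seq_len(n_steps)) {
    pt <- baseline + (s - 0.5) / n_steps * (x - baseline)
    acc <- acc + encoder_jacobian(encoder, pt)
  }
  values <- sweep(acc / n_steps, 2, x - baseline, "*")
  if (!all(is.finite(values)))
    stop("estimation failure: non-finite gradient on the path")
  structure(list(values = values, baseline = baseline,
                 n_steps = as.integer(n_steps), normalized = FALSE),
            class = "attribution_map")
}

#' @export
print.attribution_map <- function(x, ...) {
  cat(sprintf("<attribution_map> %d macro x %d micro dims, n_steps = %d%s\n",
              nrow(x$values), ncol(x$values), x$n_steps,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Aggregate attribution maps into a saliency matrix
#'
#' Mean absolute attribution over a collection of per-sample maps, with
#' optional zeroing of listed micro dimensions (e.g. velocity coordinates)
#' and per-row max-absolute normalization, matching the usual saliency
#' heat-map presentation.
#'
#' @param maps A list of \code{attribution_map} objects (or q x p matrices)
#'   of identical shape.
#' @param drop_dims Integer indices of micro dimensions to zero out.
#' @param normalize Scale each row to max-abs 1 (rows that are entirely
#'   zero are left as zero).
#' @return A q x p numeric saliency matrix.
#' @export
aggregate_saliency <- function(maps, drop_dims = integer(0),
                               normalize = TRUE) {
  if (length(maps) == 0) stop("invalid input: empty collection of maps")
  mats <- lapply(maps, function(m) {
    v <- if (inherits(m, "attribution_map")) m$values else as.matrix(m)
    abs(v)
  })
  dims <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == dims), logical(1))))
    stop("invalid input: maps have inconsistent shapes")
  sal <- Reduce(`+`, mats) / length(mats)
  if (length(drop_dims) > 0) sal[, drop_dims] <- 0
  if (normalize) {
    mx <- apply(sal, 1, max)
    sal <- sweep(sal, 1, ifelse(mx > 0, mx, 1), "/")
  }
  sal
}
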