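#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x A \code{nisplus_model}.
#' @param ... Unused.
#' @return A tibble with one row per epoch: losses and dimension-averaged
#'   EI (bits).
#' @export
tidy.nisplus_model <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A \code{nisplus_model}.
#' @param ... Unused.
#' @return A one-row tibble: dimensions, epochs, final losses, final J and
#'   the held-out residual noise scale.
#' @export
glance.nisplus_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    p = x$encoder$p, q = x$encoder$q, epochs = nrow(h),
    n_train_pairs = x$n_train_pairs,
    loss_forward = h$loss_forward[nrow(h)],
    loss_inverse = h$loss_inverse[nrow(h)],
    j = h$j[nrow(h)],
    sigma_mean = mean(x$noise_sigmas),
    range_L = max(x$range_L))
}

#' Plot the EI trajectory of a training run
#'
#' Dimension-averaged effective information (bits) of the learned macro
#' dynamics against training epoch; an upward trend shows the objective is
#' actually increasing the causal strength of the latent dynamics.
#'
#' @param object A \code{nisplus_model}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nisplus_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$j)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "epoch", y = "J (bits / dimension)",
                  title = sprintf("Dimension-averaged EI, q = %d",
                                  object$encoder$q)) +
    ggplot2::theme_minimal()
}

#' Plot a causal-emergence scale scan
#'
#' \eqn{\Delta J} against candidate macro dimension q; open points mark
#' scales whose prediction error failed the validity gate.
#'
#' @param object A \code{ce_scan} tibble from [scan_q()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ce_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$q, y = .data$delta_j,
                               shape = .data$valid)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_line(ggplot2::aes(group = 1), color = "grey40") +
    ggplot2::geom_point(size = 3, color = "firebrick") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::labs(x = "macro dimension q", y = expression(Delta * J),
                  shape = "error gate") +
    ggplot2::theme_minimal()
}

#' Saliency heat map of macro-to-micro attributions
#'
#' @param saliency A q x p matrix from [aggregate_saliency()].
#' @param micro_names Optional column labels.
#' @return A ggplot tile plot (macro dimensions on the y axis).
#' @export
plot_saliency <- function(saliency, micro_names = NULL) {
  q <- nrow(saliency); p <- ncol(saliency)
  df <- tidyr::expand_grid(macro = seq_len(q), micro = seq_len(p))
  df$value <- as.vector(t(saliency))
  labs <- micro_names %||% paste0("x", seq_len(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$micro, y = .data$macro,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "|IG|") +
    ggplot2::scale_x_continuous(breaks = seq_len(p), labels = labs) +
    ggplot2::scale_y_continuous(breaks = seq_len(q)) +
    ggplot2::labs(x = "micro dimension", y = "macro dimension") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
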