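#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace and density plot of a Metropolis-Hastings chain
#'
#' @param object an `mh_chain`.
#' @param ... unused.
#' @return a ggplot: traces (left) and marginal densities (right), one row
#'   per parameter.
#' @export
autoplot.mh_chain <- function(object, ...) {
  long <- tidy.mh_chain(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$.iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~term, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained draw", y = NULL, title = "MH chain traces") +
    ggplot2::theme_minimal()
}

#' Posterior density plot of a fitted tail object
#'
#' Marginal posterior densities of the sampled parameters with the posterior
#' mean marked.
#'
#' @param object a [pot_fit] with a chain.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pot_fit <- function(object, ...) {
  if (is.null(object$chain)) {
    stop("this fit has no chain to plot (deterministic mapping)", call. = FALSE)
  }
  long <- tidy.mh_chain(object$chain)
  means <- dplyr::summarise(dplyr::group_by(long, .data$term),
                            mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(data = means, ggplot2::aes(xintercept = .data$mean),
                        colour = "firebrick", linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density",
                  title = sprintf("Posterior (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot an MAE comparison table
#'
#' MAE of both parameters against sample size, one line per method,
#' faceted by family (and scenario, for mixture studies) and baseline scale.
#'
#' @param object a `mae_table`.
#' @param parameter `"xi"`, `"sigma"` or `"both"` (default).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mae_table <- function(object, parameter = c("both", "xi", "sigma"), ...) {
  parameter <- match.arg(parameter)
  long <- tidyr::pivot_longer(object, dplyr::all_of(c("mae_xi", "mae_sigma")),
                              names_to = "parameter", values_to = "mae",
                              names_prefix = "mae_")
  if (parameter != "both") long <- dplyr::filter(long, .data$parameter == !!parameter)
  facet_lhs <- if ("scenario" %in% names(long) || "spec_name" %in% names(long)) {
    "family + spec_name"
  } else if ("a" %in% names(long)) "family + a" else "family"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$mae,
                                     colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(stats::as.formula(paste(facet_lhs, "~ parameter")),
                        scales = "free_y") +
    ggplot2::labs(x = "sample size n", y = "mean absolute error") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot of a calibrated relation
#'
#' Per-p averaged estimates with the fitted curves.
#'
#' @param object a `relation_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.relation_fit <- function(object, ...) {
  p_seq <- seq(object$p_range[1], object$p_range[2], length.out = 50)
  curve <- stats::predict(object, p = p_seq)
  curve_long <- tidyr::pivot_longer(curve, dplyr::all_of(c("xi_z", "sigma_z")),
                                    names_to = "parameter", values_to = "value")
  pts <- tidyr::pivot_longer(
    dplyr::rename(object$per_p, xi_z = "xi", sigma_z = "sigma"),
    dplyr::all_of(c("xi_z", "sigma_z")), names_to = "parameter", values_to = "value")
  ggplot2::ggplot(curve_long, ggplot2::aes(x = .data$p, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(data = pts) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(y = NULL,
                  title = sprintf("Calibrated %s-baseline tail relation", object$family)) +
    ggplot2::theme_minimal()
}
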