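#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted tail object
#'
#' One row per parameter with the posterior mean and the 2.5%/97.5%
#' credible bounds.
#'
#' @param x a [pot_fit].
#' @param ... unused.
#' @return a tibble with columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.pot_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a fitted tail object
#'
#' @param x a [pot_fit].
#' @param ... unused.
#' @return a tibble with the method, `xi`, `sigma`, the number of
#'   observations used and the minimum acceptance rate.
#' @export
glance.pot_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    xi = unname(x$point["xi"])[1] %|NA|% NA_real_,
    sigma = unname(x$point["sigma"])[1] %|NA|% NA_real_,
    nobs = (x$m %||% x$n) %||% NA_integer_,
    min_acceptance = if (is.null(x$acceptance_rates)) NA_real_ else min(x$acceptance_rates)
  )
}

`%|NA|%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

#' Tidy a Metropolis-Hastings chain
#'
#' @param x an `mh_chain`.
#' @param ... unused.
#' @return the retained draws in long format: columns `.iteration`, `term`,
#'   `value`.
#' @export
tidy.mh_chain <- function(x, ...) {
  d <- x$draws
  d$.iteration <- seq_len(nrow(d))
  tidyr::pivot_longer(d, -".iteration", names_to = "term", values_to = "value")
}

#' One-row summary of a Metropolis-Hastings chain
#'
#' @param x an `mh_chain`.
#' @param ... unused.
#' @return a tibble with draw counts, config and the acceptance-rate range.
#' @export
glance.mh_chain <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    n_params = length(x$param_names),
    burn_in = x$config$burn_in,
    thinning = x$config$thinning,
    min_acceptance = min(x$acceptance_rates),
    max_acceptance = max(x$acceptance_rates)
  )
}

#' Tidy a calibrated relation fit
#'
#' @param x a `relation_fit`.
#' @param ... unused.
#' @return the per-p averaged estimates with the curve predictions attached.
#' @export
tidy.relation_fit <- function(x, ...) {
  pred <- stats::predict(x, p = x$per_p$p)
  dplyr::mutate(x$per_p, xi_curve = pred$xi_z, sigma_curve = pred$sigma_z)
}
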