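#' Specify a two-component location-scale mixture baseline
#'
#' A mixture \eqn{w\,F(\gamma_1, \delta_1) + (1-w)\,F(\gamma_2, \delta_2)}
#' where `F` is one of the stable families and \eqn{(\gamma, \delta)} are the
#' location and scale of the member \eqn{\delta Z + \gamma}. These are the
#' contaminated baselines used to probe the estimators away from the pure
#' stable families.
#'
#' @param family `"levy"`, `"cauchy"` or `"normal"`.
#' @param weight mixing probability of the first component, in (0, 1).
#' @param comp1,comp2 numeric `c(location, scale)` of the two components;
#'   scales must be positive.
#' @return an object of class `mixture_spec`.
#' @examples
#' mixture_spec("cauchy", comp1 = c(0, 0.5), comp2 = c(0, 2))
#' @export
mixture_spec <- function(family = c("levy", "cauchy", "normal"), weight = 0.5,
                         comp1 = c(0, 0.5), comp2 = c(0, 2)) {
  family <- match.arg(family)
  stopifnot(is.numeric(weight), length(weight) == 1, weight > 0, weight < 1,
            length(comp1) == 2, length(comp2) == 2,
            comp1[2] > 0, comp2[2] > 0)
  structure(list(family = family, weight = weight,
                 comp1 = as.numeric(comp1), comp2 = as.numeric(comp2)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("<mixture_spec> %.2g %s(%g, %g) + %.2g %s(%g, %g)\n",
              x$weight, x$family, x$comp1[1], x$comp1[2],
              1 - x$weight, x$family, x$comp2[1], x$comp2[2]))
  invisible(x)
}

#' The three benchmark mixture scenarios for a family
#'
#' Equal-weight mixtures \eqn{0.5 F(0, 1/2) + 0.5 F(0, 2)},
#' \eqn{0.5 F(0, 1) + 0.5 F(1, 1)} and \eqn{0.5 F(0, 1) + 0.5 F(1, 2)}.
#'
#' @param family `"levy"`, `"cauchy"` or `"normal"`.
#' @return a named list of three [mixture_spec()]s.
#' @export
mixture_scenarios <- function(family) {
  family <- stable_family(family)
  list(
    scale_mix    = mixture_spec(family, 0.5, c(0, 0.5), c(0, 2)),
    shift_mix    = mixture_spec(family, 0.5, c(0, 1), c(1, 1)),
    shift_scale  = mixture_spec(family, 0.5, c(0, 1), c(1, 2))
  )
}

#' Generate a synthetic baseline series
#'
#' Seeded draws from a stable family ([stable_spec()]), a Gamma baseline
#' ([gamma_spec()]) or a two-component mixture ([mixture_spec()]); mixtures
#' draw component membership first, then `location + scale * Z` within the
#' component.
#'
#' @param spec a `stable_spec`, `gamma_spec` or `mixture_spec`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @examples
#' synth_baseline(gamma_spec(2, 0.2), 10, seed = 1)
#' @export
synth_baseline <- function(spec, n, seed = NULL) {
  UseMethod("synth_baseline")
}

#' @export
synth_baseline.stable_spec <- function(spec, n, seed = NULL) {
  stable_sample(n, spec, seed = seed)
}

#' @export
synth_baseline.gamma_spec <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = spec$shape, rate = spec$rate)
}

#' @export
synth_baseline.mixture_spec <- function(spec, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pick1 <- stats::runif(n) < spec$weight
  z <- stable_sample(n, stable_spec(spec$family))
  loc <- ifelse(pick1, spec$comp1[1], spec$comp2[1])
  sc <- ifelse(pick1, spec$comp1[2], spec$comp2[2])
  loc + sc * z
}

#' @export
synth_baseline.default <- function(spec, n, seed = NULL) {
  stop("`spec` must be a stable_spec, gamma_spec or mixture_spec", call. = FALSE)
}
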