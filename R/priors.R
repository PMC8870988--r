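#' Specify a prior distribution for a tail or baseline parameter
#'
#' Supported families and the meaning of the two hyperparameters:
#' * `gamma` — shape `a`, rate `b` (density \eqn{\propto x^{a-1} e^{-bx}});
#' * `pareto1` — type-I Pareto with tail index `a` and support lower bound
#'   `b` (density \eqn{\propto x^{-(a+1)}} for \eqn{x > b});
#' * `inverse_gamma` — shape `a`, scale `b`
#'   (density \eqn{\propto x^{-(a+1)} e^{-b/x}});
#' * `normal` — mean `a`, standard deviation `b`.
#'
#' Defaults used by the fitters when no prior is supplied are weakly
#' informative: `gamma(0.01, 0.01)` for the light-tail parameters and the
#' baseline scales, `pareto1(1, 0.01)` for a heavy-tail shape,
#' `inverse_gamma(0.01, 0.01)` for a heavy-tail scale (and for the squared
#' Normal-baseline scale).
#'
#' @param family one of `"gamma"`, `"pareto1"`, `"inverse_gamma"`, `"normal"`.
#' @param a,b hyperparameters, see above.
#' @return an object of class `prior_spec`.
#' @examples
#' prior_spec("gamma", 0.01, 0.01)
#' prior_spec("pareto1", a = 1, b = 0.01)
#' @export
prior_spec <- function(family = c("gamma", "pareto1", "inverse_gamma", "normal"),
                       a, b) {
  family <- match.arg(family)
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(b), length(b) == 1)
  if (family %in% c("gamma", "inverse_gamma") && (a <= 0 || b <= 0)) {
    stop(sprintf("%s prior needs positive hyperparameters", family), call. = FALSE)
  }
  if (family == "pareto1" && (a <= 0 || b <= 0)) {
    stop("pareto1 prior needs a positive index and lower bound", call. = FALSE)
  }
  if (family == "normal" && b <= 0) {
    stop("normal prior needs a positive standard deviation", call. = FALSE)
  }
  structure(list(family = family, a = a, b = b), class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec> %s(a = %g, b = %g)\n", x$family, x$a, x$b))
  invisible(x)
}

check_prior <- function(prior, family, what) {
  if (!inherits(prior, "prior_spec") || prior$family != family) {
    stop(sprintf("`%s` must be a %s prior_spec", what, family), call. = FALSE)
  }
  invisible(prior)
}

# unnormalised log prior density
log_prior <- function(prior, x) {
  switch(prior$family,
    gamma = if (x <= 0) -Inf else (prior$a - 1) * log(x) - prior$b * x,
    pareto1 = if (x <= prior$b) -Inf else -(prior$a + 1) * log(x),
    inverse_gamma = if (x <= 0) -Inf else -(prior$a + 1) * log(x) - prior$b / x,
    normal = -(x - prior$a)^2 / (2 * prior$b^2)
  )
}
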