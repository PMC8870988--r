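#' Configure the Metropolis-Hastings engine
#'
#' Settings for the componentwise Gaussian random-walk sampler in [run_mh()].
#' Two presets bundle the chain lengths used throughout:
#' * `"paper"` — burn-in 10,000, thinning 25, 10,000 retained draws: the
#'   full-scale settings of the original simulation studies;
#' * `"desk"` — burn-in 1,000, thinning 5, 2,000 retained draws: accurate
#'   single-fit settings at interactive runtimes;
#' * `"quick"` — burn-in 500, thinning 2, 1,000 retained draws: the default
#'   for large replicated studies.
#'
#' @param n_keep retained draws after burn-in and thinning.
#' @param burn_in discarded initial iterations.
#' @param thinning keep every `thinning`-th draw after burn-in.
#' @param proposal_sds per-parameter proposal standard deviations, or
#'   `"auto"` to start from scale-aware defaults (adapted during burn-in when
#'   `adapt = TRUE`).
#' @param seed optional integer seed; identical configs give bit-identical
#'   chains.
#' @param init per-parameter starting values, or `"auto"` to let the caller
#'   (or a deterministic grid search) choose.
#' @param adapt adapt proposal scales during burn-in, targeting 25--40%
#'   acceptance; scales are frozen before the first retained draw, so the
#'   retained draws come from a fixed kernel.
#' @param preset `"desk"` (default), `"paper"` or `"quick"`; explicit
#'   `n_keep`/`burn_in`/`thinning` arguments override the preset.
#' @return an object of class `mh_config`.
#' @examples
#' mh_config(preset = "quick", seed = 1)
#' @export
mh_config <- function(n_keep = NULL, burn_in = NULL, thinning = NULL,
                      proposal_sds = "auto", seed = NULL, init = "auto",
                      adapt = TRUE, preset = c("desk", "paper", "quick")) {
  preset <- match.arg(preset)
  def <- switch(preset,
    paper = list(n_keep = 10000L, burn_in = 10000L, thinning = 25L),
    desk  = list(n_keep = 2000L,  burn_in = 1000L,  thinning = 5L),
    quick = list(n_keep = 1000L,  burn_in = 500L,   thinning = 2L)
  )
  n_keep <- as.integer(n_keep %||% def$n_keep)
  burn_in <- as.integer(burn_in %||% def$burn_in)
  thinning <- as.integer(thinning %||% def$thinning)
  stopifnot(n_keep >= 1, burn_in >= 0, thinning >= 1)
  if (is.numeric(proposal_sds) && any(proposal_sds <= 0)) {
    stop("`proposal_sds` must be positive", call. = FALSE)
  }
  structure(
    list(n_keep = n_keep, burn_in = burn_in, thinning = thinning,
         proposal_sds = proposal_sds, seed = seed, init = init,
         adapt = isTRUE(adapt), preset = preset),
    class = "mh_config"
  )
}

#' @export
print.mh_config <- function(x, ...) {
  cat(sprintf("<mh_config> n_keep = %d, burn_in = %d, thinning = %d, adapt = %s, seed = %s\n",
              x$n_keep, x$burn_in, x$thinning, x$adapt,
              if (is.null(x$seed)) "NULL" else format(x$seed)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic grid search for a finite starting point
auto_init <- function(log_target, n_params) {
  cand <- c(0.5, 1, 0.1, 2, 5, 0.01, 10, 50)
  grids <- rep(list(cand), n_params)
  pts <- as.matrix(do.call(expand.grid, grids))
  for (i in seq_len(nrow(pts))) {
    if (is.finite(log_target(pts[i, ]))) return(unname(pts[i, ]))
  }
  stop("no finite starting point found by the deterministic grid search; supply `init`",
       call. = FALSE)
}

#' Run a componentwise random-walk Metropolis-Hastings sampler
#'
#' Updates one parameter at a time, in declaration order, with a Gaussian
#' random-walk proposal; each proposal is accepted with probability
#' \eqn{\min\{1, \exp(\Delta \log \text{target})\}}. A `-Inf` log-target is
#' legal and means certain rejection (this is how support constraints enter);
#' `NaN` is a hard error. When `config$adapt` is `TRUE`, proposal scales are
#' tuned during burn-in (multiplied by 1.4 / divided by 1.4 when the windowed
#' acceptance exceeds 40% / falls below 25%, every 50 iterations) and frozen
#' afterwards, so retained draws come from a fixed kernel and the stationary
#' distribution is preserved.
#'
#' @param log_target function mapping a parameter vector to a scalar
#'   log-density (up to a constant).
#' @param config an [mh_config()].
#' @param init numeric starting vector; overrides `config$init`. With
#'   `"auto"`, a small deterministic grid is searched for a finite start.
#' @param param_names names for the parameters (defaults to `theta1`, ...).
#' @return an object of class `mh_chain`: list with `draws` (tibble,
#'   `n_keep` rows), `acceptance_rates` (per parameter, over the retained
#'   phase), `param_names`, `proposal_sds` (final, possibly adapted) and
#'   `config`.
#' @examples
#' ch <- run_mh(function(th) -th^2 / 2, mh_config(preset = "quick", seed = 1),
#'              init = 0, param_names = "z")
#' summarize_chain(ch)
#' @export
run_mh <- function(log_target, config = mh_config(), init = NULL,
                   param_names = NULL) {
  stopifnot(is.function(log_target), inherits(config, "mh_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  theta <- init %||% config$init
  if (identical(theta, "auto")) {
    if (is.null(param_names)) {
      stop("init = \"auto\" needs `param_names` to size the search grid", call. = FALSE)
    }
    theta <- auto_init(log_target, length(param_names))
  }
  theta <- as.numeric(theta)
  d <- length(theta)
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(d))
  stopifnot(length(param_names) == d)

  lp <- log_target(theta)
  if (is.nan(lp)) stop("log_target returned NaN at the starting point", call. = FALSE)
  if (!is.finite(lp)) stop("log_target is not finite at the starting point", call. = FALSE)

  sds <- config$proposal_sds
  if (identical(sds, "auto")) sds <- pmax(abs(theta) * 0.25, 0.05)
  sds <- rep_len(as.numeric(sds), d)

  n_iter <- config$burn_in + config$n_keep * config$thinning
  draws <- matrix(NA_real_, nrow = config$n_keep, ncol = d,
                  dimnames = list(NULL, param_names))
  acc_keep <- numeric(d)
  win_acc <- numeric(d); win_n <- 0L
  kept <- 0L

  for (i in seq_len(n_iter)) {
    in_burn <- i <= config$burn_in
    for (j in seq_len(d)) {
      prop <- theta
      prop[j] <- theta[j] + stats::rnorm(1, 0, sds[j])
      lpp <- log_target(prop)
      if (is.nan(lpp)) stop("log_target returned NaN during sampling", call. = FALSE)
      if (log(stats::runif(1)) < lpp - lp) {
        theta <- prop; lp <- lpp
        if (in_burn) win_acc[j] <- win_acc[j] + 1 else acc_keep[j] <- acc_keep[j] + 1
      }
    }
    if (in_burn) {
      win_n <- win_n + 1L
      if (config$adapt && win_n == 50L) {
        rate <- win_acc / 50
        sds[rate > 0.40] <- sds[rate > 0.40] * 1.4
        sds[rate < 0.25] <- sds[rate < 0.25] / 1.4
        win_acc[] <- 0; win_n <- 0L
      }
    } else if ((i - config$burn_in) %% config$thinning == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- theta
    }
  }

  structure(
    list(draws = tibble::as_tibble(draws),
         acceptance_rates = stats::setNames(acc_keep / (config$n_keep * config$thinning),
                                            param_names),
         param_names = param_names,
         proposal_sds = stats::setNames(sds, param_names),
         config = config),
    class = "mh_chain"
  )
}

#' @export
print.mh_chain <- function(x, ...) {
  cat(sprintf("<mh_chain> %d draws of (%s); acceptance %s\n",
              nrow(x$draws), paste(x$param_names, collapse = ", "),
              paste(sprintf("%s = %.2f", x$param_names, x$acceptance_rates),
                    collapse = ", ")))
  invisible(x)
}

#' Summarise a Metropolis-Hastings chain
#'
#' Per-parameter posterior mean (the point estimator used throughout) and
#' empirical 2.5% / 97.5% quantiles.
#'
#' @param chain an `mh_chain` from [run_mh()].
#' @return a tibble with columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
summarize_chain <- function(chain) {
  stopifnot(inherits(chain, "mh_chain"))
  draws <- chain$draws
  if (nrow(draws) == 0) stop("empty chain", call. = FALSE)
  purrr::map_dfr(names(draws), function(nm) {
    v <- draws[[nm]]
    qs <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(term = nm, estimate = mean(v),
                   conf.low = qs[1], conf.high = qs[2])
  })
}

#' Export a chain to CSV and a JSON summary
#'
#' Writes the retained draws as CSV (one column per parameter, one row per
#' draw) and, optionally, a JSON summary holding the posterior means,
#' 95% credible intervals, acceptance rates and the sampler configuration.
#'
#' @param chain an `mh_chain`.
#' @param csv path for the draws CSV.
#' @param json optional path for the JSON summary.
#' @return the CSV path, invisibly.
#' @export
write_chain <- function(chain, csv, json = NULL) {
  stopifnot(inherits(chain, "mh_chain"))
  utils::write.csv(chain$draws, csv, row.names = FALSE)
  if (!is.null(json)) {
    s <- summarize_chain(chain)
    jsonlite::write_json(
      list(summary = s,
           acceptance_rates = as.list(chain$acceptance_rates),
           config = unclass(chain$config)),
      json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(csv)
}

# batch-means Monte-Carlo standard error of the chain mean
mcse_batch <- function(x, n_batch = 25) {
  n <- length(x)
  size <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b) mean(x[((b - 1) * size + 1):(b * size)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}
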