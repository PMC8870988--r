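#' Configure a simulation study
#'
#' Bundles the grid and sampler settings of the comparative simulation
#' studies. The benchmark design uses sample sizes \eqn{n = 2^5, \ldots,
#' 2^{10}}, baseline scales \eqn{a = 2^{-2}, \ldots, 2^2}, tail level
#' `p = 0.9` and 100 replicates; the desk-scale default keeps the same grid
#' shape with `reps = 25` and quick chains.
#'
#' @param families character vector of baseline families
#'   (`"levy"`, `"cauchy"`, `"normal"`).
#' @param n_values sample sizes of the generated series.
#' @param a_values baseline scales.
#' @param p tail level in (0, 1).
#' @param reps replicates per grid cell.
#' @param methods subset of `c("mh", "bmh", "ipbmh")`.
#' @param seed integer master seed; every replicate seed derives from it.
#' @param mh_settings an [mh_config()] shared by all fits.
#' @param preset `"desk"` (reps 25) or `"paper"` (reps 100, paper-scale
#'   chains); explicit arguments override the preset.
#' @return an object of class `study_config`.
#' @examples
#' study_config(families = "cauchy", n_values = 32, a_values = 1, reps = 2)
#' @export
study_config <- function(families = c("levy", "cauchy", "normal"),
                         n_values = 2^(5:10), a_values = 2^(-2:2),
                         p = 0.9, reps = NULL, methods = c("mh", "bmh"),
                         seed = 1, mh_settings = NULL,
                         preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  families <- vapply(families, stable_family, character(1), USE.NAMES = FALSE)
  methods <- match.arg(methods, c("mh", "bmh", "ipbmh"), several.ok = TRUE)
  reps <- as.integer(reps %||% switch(preset, desk = 25L, paper = 100L))
  mh_settings <- mh_settings %||%
    switch(preset, desk = mh_config(preset = "quick"), paper = mh_config(preset = "paper"))
  stopifnot(length(families) >= 1, length(n_values) >= 1, length(a_values) >= 1,
            all(n_values >= 8), all(a_values > 0),
            length(p) == 1, p > 0, p < 1, reps >= 1,
            inherits(mh_settings, "mh_config"))
  structure(
    list(families = families, n_values = as.integer(n_values),
         a_values = as.numeric(a_values), p = p, reps = reps,
         methods = methods, seed = as.integer(seed), mh_settings = mh_settings,
         preset = preset),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> families: %s | n: %s | a: %s | p = %g | reps = %d | methods: %s\n",
              paste(x$families, collapse = ","),
              paste(x$n_values, collapse = ","),
              paste(x$a_values, collapse = ","),
              x$p, x$reps, paste(x$methods, collapse = ",")))
  invisible(x)
}

# derive a per-task integer seed from the master seed (stays below 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 7919) %% 2147483629) + 1L
}

# run one method on one simulated series; returns c(xi, sigma) or NULL
run_one_method <- function(method, x, family, p, cfg) {
  tail_obj <- extract_exceedances(x, p)
  if (method == "mh") {
    fit <- fit_mh_tail(tail_obj, family, config = cfg)
  } else if (method == "bmh") {
    fit <- fit_bmh(x, family, p, config = cfg)
  } else {
    base <- fit_baseline_scale(x, family, config = cfg)
    prior <- build_informative_prior(family, p, unname(base$point["a"]))
    fit <- fit_ipbmh(tail_obj, prior, config = cfg)
  }
  fit$point[c("xi", "sigma")]
}

# shared study loop: `cells` is a tibble with columns family, n, a (or
# scenario/spec), plus a truth lookup function(cell) -> c(xi, sigma) and a
# generator function(cell, seed) -> numeric series
run_study_grid <- function(cells, config, generate, truth_of) {
  grid <- tidyr::expand_grid(cell = seq_len(nrow(cells)), rep = seq_len(config$reps),
                             method = config$methods)
  task_id <- seq_len(nrow(grid))
  res <- purrr::pmap_dfr(
    list(grid$cell, grid$rep, grid$method, task_id),
    function(ci, rep, method, tid) {
      cell <- cells[ci, ]
      # one seed per (cell, rep): all methods see the same series
      data_seed <- derive_seed(config$seed, ci * 100003L + rep)
      x <- generate(cell, data_seed)
      cfg <- config$mh_settings
      cfg$seed <- derive_seed(config$seed, tid * 13L + 5L)
      est <- tryCatch(run_one_method(method, x, cell$family, config$p, cfg),
                      error = function(e) NULL)
      tr <- truth_of(cell)
      if (is.null(est)) {
        dplyr::bind_cols(cell, tibble::tibble(rep = rep, method = method,
                                              err_xi = NA_real_, err_sigma = NA_real_))
      } else {
        dplyr::bind_cols(cell, tibble::tibble(
          rep = rep, method = method,
          err_xi = abs(est[["xi"]] - tr[["xi"]]),
          err_sigma = abs(est[["sigma"]] - tr[["sigma"]])))
      }
    })
  n_fail <- sum(is.na(res$err_xi))
  if (n_fail > 0) {
    warning(sprintf("simulation study: %d replicate fit(s) failed and were excluded",
                    n_fail), call. = FALSE)
  }
  group_cols <- setdiff(names(res), c("rep", "err_xi", "err_sigma"))
  out <- res |>
    dplyr::filter(!is.na(.data$err_xi)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::summarise(
      mae_xi = mean(.data$err_xi),
      mae_sigma = mean(.data$err_sigma),
      q025_xi = stats::quantile(.data$err_xi, 0.025, names = FALSE),
      q975_xi = stats::quantile(.data$err_xi, 0.975, names = FALSE),
      q025_sigma = stats::quantile(.data$err_sigma, 0.025, names = FALSE),
      q975_sigma = stats::quantile(.data$err_sigma, 0.975, names = FALSE),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("mae_table", class(out))
  attr(out, "config") <- config
  out
}

#' Mean-absolute-error comparison of the estimators on pure stable baselines
#'
#' For every combination of family, sample size `n`, baseline scale `a` and
#' replicate: generate `n` draws of the scaled family, extract exceedances at
#' tail level `p`, run each requested method, and record the absolute errors
#' of \eqn{\hat\xi} and \eqn{\hat\sigma} against the closed-form/calibrated
#' truth `map_to_gpd(family_relation(family, p), a)`. Errors are aggregated
#' to MAE with 2.5%/97.5% error quantiles per cell. All methods see the same
#' simulated series within a replicate, and the whole table is deterministic
#' given `config$seed`. Failed fits are excluded with a warning, never
#' silently dropped.
#'
#' @param config a [study_config()].
#' @return a `mae_table` tibble: one row per (family, n, a, method) with
#'   columns `mae_xi`, `mae_sigma`, `q025_xi`, `q975_xi`, `q025_sigma`,
#'   `q975_sigma`, `n_reps`.
#' @export
run_mae_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cells <- tidyr::expand_grid(family = config$families,
                              n = config$n_values, a = config$a_values)
  run_study_grid(
    cells, config,
    generate = function(cell, seed) {
      synth_baseline(stable_spec(cell$family, a = cell$a), cell$n, seed = seed)
    },
    truth_of = function(cell) {
      est <- map_to_gpd(family_relation(cell$family, config$p), cell$a)
      c(xi = est$xi[1], sigma = est$sigma[1])
    }
  )
}

# cache of large-sample mixture truths, keyed by spec/p/seed
.mixture_truth_cache <- new.env(parent = emptyenv())

#' Large-sample reference tail parameters for a mixture baseline
#'
#' Mixtures have no closed-form tail relation, so the reference
#' \eqn{(\xi, \sigma)} used for error computation is a one-off large-sample
#' run: draw `n_oracle` mixture observations, extract exceedances at `p`,
#' and fit the family-appropriate classical MH sampler with a long chain.
#' The result is cached per (spec, p, n_oracle, seed) within the session and
#' is deterministic given `seed`.
#'
#' @param spec a [mixture_spec()].
#' @param p tail level.
#' @param n_oracle size of the reference sample (default 1e6).
#' @param mh_settings chain settings for the reference fit.
#' @param seed integer seed.
#' @return named vector `c(xi, sigma)`.
#' @export
mixture_truth <- function(spec, p, n_oracle = 1e6,
                          mh_settings = mh_config(n_keep = 2000, burn_in = 500,
                                                  thinning = 2),
                          seed = 1) {
  stopifnot(inherits(spec, "mixture_spec"))
  key <- paste(spec$family, spec$weight, paste(spec$comp1, collapse = ","),
               paste(spec$comp2, collapse = ","), p, n_oracle, seed, sep = "|")
  if (!is.null(.mixture_truth_cache[[key]])) return(.mixture_truth_cache[[key]])
  x <- synth_baseline(spec, n_oracle, seed = seed)
  tail_obj <- extract_exceedances(x, p)
  cfg <- mh_settings
  cfg$seed <- derive_seed(seed, 2L)
  fit <- fit_mh_tail(tail_obj, spec$family, config = cfg)
  out <- fit$point[c("xi", "sigma")]
  .mixture_truth_cache[[key]] <- out
  out
}

#' Mean-absolute-error comparison on mixture baselines
#'
#' As [run_mae_study()], but the generator draws from two-component mixtures
#' (default: the three benchmark scenarios of [mixture_scenarios()] for each
#' family in the config) and the error reference is the large-sample
#' [mixture_truth()] oracle. The methods still assume the pure family: this
#' measures robustness to baseline misspecification, where the informative-
#' priors method is expected to be the most reliable at small `n`.
#'
#' @param config a [study_config()]; `a_values` is ignored (mixture
#'   components fix the scales).
#' @param scenarios optional named list of [mixture_spec()]s to use instead
#'   of the three benchmark scenarios per family.
#' @param truth_seed seed for the truth oracle runs.
#' @return a `mae_table` tibble keyed by (family, scenario, n, method).
#' @export
run_mixture_study <- function(config, scenarios = NULL, truth_seed = 20220178) {
  stopifnot(inherits(config, "study_config"))
  specs <- list()
  if (is.null(scenarios)) {
    for (fam in config$families) {
      sc <- mixture_scenarios(fam)
      for (nm in names(sc)) {
        specs[[paste(fam, nm, sep = ".")]] <- sc[[nm]]
      }
    }
  } else {
    stopifnot(all(vapply(scenarios, inherits, logical(1), "mixture_spec")))
    specs <- scenarios
  }
  cells <- tidyr::expand_grid(spec_name = names(specs), n = config$n_values)
  cells$family <- vapply(specs[cells$spec_name], function(s) s$family, character(1))
  cells <- cells[, c("family", "spec_name", "n")]
  truths <- lapply(specs, mixture_truth, p = config$p, seed = truth_seed)
  run_study_grid(
    cells, config,
    generate = function(cell, seed) {
      synth_baseline(specs[[cell$spec_name]], cell$n, seed = seed)
    },
    truth_of = function(cell) truths[[cell$spec_name]]
  )
}

#' Write an MAE table to CSV
#'
#' @param table a `mae_table` from [run_mae_study()] or [run_mixture_study()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_mae_table <- function(table, path) {
  stopifnot(inherits(table, "mae_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a study configuration from a flat YAML or JSON file
#'
#' Recognised keys (all optional, defaults as in [study_config()]):
#' `families`, `n_values`, `a_values`, `p`, `reps`, `methods`, `seed`,
#' `preset`, and the chain settings `n_keep`, `burn_in`, `thinning`.
#' Unknown keys raise an error naming them.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("families", "n_values", "a_values", "p", "reps", "methods",
             "seed", "preset", "n_keep", "burn_in", "thinning")
  extra <- setdiff(names(obj), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown study-config key(s): %s (allowed: %s)",
                 paste(extra, collapse = ", "), paste(known, collapse = ", ")),
         call. = FALSE)
  }
  chain_keys <- intersect(c("n_keep", "burn_in", "thinning"), names(obj))
  mh <- if (length(chain_keys) > 0) {
    do.call(mh_config, obj[chain_keys])
  } else NULL
  args <- obj[setdiff(names(obj), chain_keys)]
  args$mh_settings <- mh
  do.call(study_config, args)
}
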