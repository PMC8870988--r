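# ---- acceptance-ratio structure -------------------------------------------

test_that("printed acceptance ratios equal exp(delta log-posterior), light tail", {
  set.seed(11)
  x <- rgpd(20, -0.2, 0.5)
  pk <- prior_spec("gamma", 1.3, 0.7)
  pd <- prior_spec("gamma", 2.1, 0.4)
  lt <- potbayes:::logpost_light(x, pk, pd)
  mx <- max(x)
  for (i in 1:100) {
    k0 <- runif(1, 0.05, 3); k1 <- runif(1, 0.05, 3)
    d0 <- mx + runif(1, 0.01, 5); d1 <- mx + runif(1, 0.01, 5)
    expect_equal(potbayes:::printed_log_ratio_light_k(k1, k0, d0, x, pk),
                 lt(c(k1, d0)) - lt(c(k0, d0)), tolerance = 1e-10)
    expect_equal(potbayes:::printed_log_ratio_light_delta(d1, d0, k0, x, pd),
                 lt(c(k0, d1)) - lt(c(k0, d0)), tolerance = 1e-10)
  }
})

test_that("printed acceptance ratios equal exp(delta log-posterior), heavy tail", {
  set.seed(12)
  x <- rgpd(20, 1, 2)
  px <- prior_spec("pareto1", 1.5, 0.02)
  ps <- prior_spec("inverse_gamma", 1.1, 0.9)
  lt <- potbayes:::logpost_heavy(x, px, ps)
  for (i in 1:100) {
    xi0 <- runif(1, 0.05, 3); xi1 <- runif(1, 0.05, 3)
    s0 <- runif(1, 0.2, 5); s1 <- runif(1, 0.2, 5)
    expect_equal(potbayes:::printed_log_ratio_heavy_xi(xi1, xi0, s0, x, px),
                 lt(c(xi1, s0)) - lt(c(xi0, s0)), tolerance = 1e-10)
    expect_equal(potbayes:::printed_log_ratio_heavy_sigma(s1, s0, xi0, x, ps),
                 lt(c(xi0, s1)) - lt(c(xi0, s0)), tolerance = 1e-10)
  }
})

test_that("printed acceptance ratios equal exp(delta log-posterior), IPBMH", {
  set.seed(13)
  x <- rgpd(20, 1, 3)
  prior <- build_informative_prior("cauchy", 0.9, a_hat = 1.2)
  lt <- potbayes:::logpost_ipbmh(x, prior)
  for (i in 1:100) {
    xi0 <- runif(1, 0.1, 3); xi1 <- runif(1, 0.1, 3)
    s0 <- runif(1, 0.5, 8); s1 <- runif(1, 0.5, 8)
    expect_equal(potbayes:::printed_log_ratio_ipbmh_xi(xi1, xi0, s0, x, prior),
                 lt(c(xi1, s0)) - lt(c(xi0, s0)), tolerance = 1e-10)
    expect_equal(potbayes:::printed_log_ratio_ipbmh_sigma(s1, s0, xi0, x, prior),
                 lt(c(xi0, s1)) - lt(c(xi0, s0)), tolerance = 1e-10)
  }
})

# ---- support handling -------------------------------------------------------

test_that("support violations give -Inf log posteriors (certain rejection)", {
  x <- rgpd(50, -0.2, 0.5, seed = 14)
  lt <- potbayes:::logpost_light(x, prior_spec("gamma", 0.01, 0.01),
                                 prior_spec("gamma", 0.01, 0.01))
  expect_identical(lt(c(0.5, max(x))), -Inf)       # delta at the max excess
  expect_identical(lt(c(-0.1, 2 * max(x))), -Inf)  # negative k
  lth <- potbayes:::logpost_heavy(x, prior_spec("pareto1", 1, 0.05),
                                  prior_spec("inverse_gamma", 0.01, 0.01))
  expect_identical(lth(c(0.04, 1)), -Inf)          # xi below the Pareto bound
  expect_identical(lth(c(1, -1)), -Inf)
  pr <- build_informative_prior("normal", 0.9, 1)
  lti <- potbayes:::logpost_ipbmh(x, pr)
  expect_identical(lti(c(-0.5, 0.4 * max(x))), -Inf)  # bound below max excess
  expect_true(is.finite(lti(c(-0.2, 1.2 * 0.2 * max(x)))))
})

# ---- parameter recovery -----------------------------------------------------

test_that("heavy-tail sampler recovers a Cauchy-like tail without bias", {
  # single-sample posterior means at m = 1000 carry ~6% data-sampling noise,
  # so recovery is asserted on the average over replicate samples
  pts <- vapply(1:3, function(r) {
    fit <- fit_mh_heavy(gpd_tail(1, 3.1831, m = 1000, seed = 20 + r),
                        config = desk_cfg(120 + r))
    fit$point[c("xi", "sigma")]
  }, numeric(2))
  expect_lt(abs(mean(pts["xi", ]) - 1), 0.1)
  expect_lt(abs(mean(pts["sigma", ]) / 3.1831 - 1), 0.1)
})

test_that("light-tail sampler recovers a Normal-like tail, with transforms", {
  tail <- gpd_tail(-0.151, 0.534, m = 1000, seed = 23)
  fit <- fit_mh_light(tail, config = desk_cfg(24))
  expect_lt(abs(fit$point["xi"] + 0.151), 0.05)
  expect_lt(abs(fit$point["sigma"] - 0.534), 0.08)
  expect_true(all(fit$acceptance_rates > 0.1 & fit$acceptance_rates < 0.6))
  # transforms are consistent with the raw draws
  expect_equal(unname(fit$point["xi"]), -unname(fit$point["k"]))
  d <- fit$chain$draws
  expect_equal(unname(fit$point["sigma"]), mean(d$k * d$delta))
})

test_that("recovery error shrinks with the tail sample size", {
  err_at <- function(m, fitter, xi, sigma) {
    errs <- vapply(1:6, function(r) {
      fit <- fitter(gpd_tail(xi, sigma, m, seed = 300 + r), config = quick_cfg(400 + r))
      abs(fit$point["xi"] - xi)
    }, numeric(1))
    mean(errs)
  }
  expect_lt(err_at(2000, fit_mh_heavy, 1, 3.1831),
            err_at(100, fit_mh_heavy, 1, 3.1831))
  expect_lt(err_at(2000, fit_mh_light, -0.151, 0.534),
            err_at(100, fit_mh_light, -0.151, 0.534))
})

# ---- baseline-scale conjugacy oracles --------------------------------------

test_that("Levy baseline sampler matches the Gamma conjugate posterior", {
  x <- stable_sample(512, stable_spec("levy", a = 1), seed = 25)
  fit <- fit_baseline_scale(x, "levy", config = desk_cfg(26))
  draws <- fit$chain$draws$a
  mcse <- potbayes:::mcse_batch(draws)
  expect_lt(abs(fit$point["a"] - levy_conjugate_mean(x)), 3 * mcse)
})

test_that("Normal baseline sampler matches the Inverse-Gamma conjugate posterior", {
  x <- stable_sample(512, stable_spec("normal", a = 2), seed = 27)
  fit <- fit_baseline_scale(x, "normal", config = desk_cfg(28))
  draws <- fit$chain$draws$a_sq
  mcse <- potbayes:::mcse_batch(draws)
  expect_lt(abs(fit$point["a_sq"] - normal_conjugate_mean_asq(x)), 3 * mcse)
  # a is summarised as the mean of sqrt draws, not sqrt of the mean
  expect_equal(unname(fit$point["a"]), mean(sqrt(fit$chain$draws$a_sq)))
})

test_that("baseline-scale error shrinks with the series length for every family", {
  mean_err <- function(family, n) {
    errs <- vapply(1:10, function(r) {
      x <- stable_sample(n, stable_spec(family, a = 1), seed = 700 + 17 * r)
      fit <- fit_baseline_scale(x, family, config = quick_cfg(800 + r))
      abs(unname(fit$point["a"]) - 1)
    }, numeric(1))
    mean(errs)
  }
  for (family in c("levy", "cauchy", "normal")) {
    errs <- vapply(c(32, 128, 512), function(n) mean_err(family, n), numeric(1))
    expect_true(all(diff(errs) < 0), info = family)
  }
})

test_that("Cauchy baseline sampler recovers the scale", {
  x <- stable_sample(512, stable_spec("cauchy", a = 2), seed = 29)
  fit <- fit_baseline_scale(x, "cauchy", config = desk_cfg(30))
  expect_lt(abs(fit$point["a"] - 2), 0.15)
  expect_error(fit_baseline_scale(c(-1, 2, 3), "levy"), "positive")
})

# ---- BMH --------------------------------------------------------------------

test_that("BMH maps the baseline scale through the family relation", {
  x <- stable_sample(512, stable_spec("cauchy", a = 1.5), seed = 31)
  fit <- fit_bmh(x, "cauchy", p = 0.9, config = desk_cfg(32))
  expect_identical(unname(fit$point["xi"]), 1)     # data-independent shape
  expect_equal(unname(fit$point["sigma"]),
               unname(fit$point["a"]) / (pi * 0.1), tolerance = 1e-12)
  expect_equal(unname(fit$point["sigma"]), 1.5 / (pi * 0.1), tolerance = 0.15)
  # propagated interval covers the point estimate
  s <- tidy(fit)
  sig <- s[s$term == "sigma", ]
  expect_true(sig$conf.low < sig$estimate && sig$estimate < sig$conf.high)
})

test_that("BMH on Levy data has shape exactly 2 whatever the data", {
  x <- stable_sample(256, stable_spec("levy", a = 0.5), seed = 33)
  fit <- fit_bmh(x, "levy", p = 0.9, config = quick_cfg(34))
  expect_identical(unname(fit$point["xi"]), 2)
  x2 <- stable_sample(256, stable_spec("levy", a = 4), seed = 35)
  fit2 <- fit_bmh(x2, "levy", p = 0.9, config = quick_cfg(36))
  expect_identical(unname(fit2$point["xi"]), 2)
})

# ---- informative priors -----------------------------------------------------

test_that("informative priors carry the tabulated widths", {
  pr <- build_informative_prior("normal", 0.9, 1)
  expect_equal(pr$xi_sd, 0.03)
  expect_equal(pr$sigma_sd, exp(-46.24 * 0.81 + 83.55 * 0.9 - 41.58))
  expect_equal(pr$xi_mean, -0.151)
  expect_equal(pr$sigma_mean, 0.534)
  expect_equal(build_informative_prior("cauchy", 0.9, 1)$xi_sd, 0.065)
  pl <- build_informative_prior("levy", 0.9, 1)
  expect_equal(pl$xi_sd, 0.1)
  expect_equal(pl$sigma_sd, exp(500.2 * 0.81 - 900.9 * 0.9 + 408.2))
})

test_that("IPBMH collapses to the prior means as the prior widths shrink", {
  tail <- gpd_tail(1, 3, m = 200, seed = 37)
  pr <- build_informative_prior("cauchy", 0.9, 1)
  pr$xi_sd <- 1e-6; pr$sigma_sd <- 1e-6
  fit <- fit_ipbmh(tail, pr, config = desk_cfg(38))
  expect_lt(abs(fit$point["xi"] - pr$xi_mean), 1e-3)
  expect_lt(abs(fit$point["sigma"] - pr$sigma_mean), 1e-3)
})

test_that("IPBMH with diffuse priors agrees with the classical heavy fit", {
  tail <- gpd_tail(1, 3.1831, m = 500, seed = 39)
  pr <- build_informative_prior("cauchy", 0.9, 1)
  pr$xi_sd <- pr$xi_sd * 1e4; pr$sigma_sd <- pr$sigma_sd * 1e4
  fit_ip <- fit_ipbmh(tail, pr, config = desk_cfg(40))
  fit_h <- fit_mh_heavy(tail, config = desk_cfg(40))
  expect_lt(abs(fit_ip$point["xi"] - fit_h$point["xi"]), 0.1)
  expect_lt(abs(fit_ip$point["sigma"] / fit_h$point["sigma"] - 1), 0.1)
})

test_that("IPBMH shrinks the shape from the classical estimate toward the prior", {
  for (r in 1:4) {
    tail <- gpd_tail(1.4, 3, m = 60, seed = 500 + r)
    pr <- build_informative_prior("cauchy", 0.9, 1)   # prior mean xi = 1
    fit_ip <- fit_ipbmh(tail, pr, config = quick_cfg(600 + r))
    fit_h <- fit_mh_heavy(tail, config = quick_cfg(600 + r))
    lo <- min(pr$xi_mean, fit_h$point["xi"]) - 0.05
    hi <- max(pr$xi_mean, fit_h$point["xi"]) + 0.05
    expect_gt(fit_ip$point["xi"], lo)
    expect_lt(fit_ip$point["xi"], hi)
  }
})

test_that("fit_mh_tail dispatches on the declared family", {
  tail_n <- gpd_tail(-0.151, 0.534, m = 200, seed = 41)
  expect_equal(fit_mh_tail(tail_n, "normal", config = quick_cfg(42))$method, "mh_light")
  tail_c <- gpd_tail(1, 3, m = 200, seed = 43)
  expect_equal(fit_mh_tail(tail_c, "cauchy", config = quick_cfg(44))$method, "mh_heavy")
  tail_g <- gpd_tail(0, 2, m = 200, seed = 45)
  fit_g <- fit_mh_tail(tail_g, "gamma", config = quick_cfg(46))
  expect_equal(fit_g$method, "mh_heavy")
  expect_equal(fit_g$priors$xi$b, 1e-3)
})
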