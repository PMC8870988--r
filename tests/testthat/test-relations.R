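test_that("stable tail constant has its closed-form values", {
  expect_equal(stable_tail_constant(1), 1 / pi)
  expect_equal(stable_tail_constant(0.5), 1 / sqrt(2 * pi))
  expect_equal(stable_tail_constant(2), 0, tolerance = 1e-15)
  expect_error(stable_tail_constant(0), "positive")
})

test_that("closed-form relation specialises exactly to the Levy and Cauchy laws", {
  p_grid <- seq(0.51, 0.9999, length.out = 41)
  levy <- prop1_relation(1 / 2, 1, p_grid)
  expect_true(all(levy$xi_z == 2))
  expect_equal(levy$sigma_z, (4 / pi) * (1 - p_grid)^-2, tolerance = 1e-12)
  cauchy <- prop1_relation(1, 0, p_grid)
  expect_true(all(cauchy$xi_z == 1))
  expect_equal(cauchy$sigma_z, 1 / (pi * (1 - p_grid)), tolerance = 1e-12)
  # the named-family dispatch is the same computation
  expect_equal(family_relation("levy", p_grid)$sigma_z, levy$sigma_z, tolerance = 1e-12)
  expect_equal(family_relation("cauchy", p_grid)$sigma_z, cauchy$sigma_z, tolerance = 1e-12)
  expect_equal(prop1_relation(1, 0, 0.99)$sigma_z, 31.83099, tolerance = 1e-6)
  expect_error(prop1_relation(2, 0, 0.9), "alpha < 2")
})

test_that("scale exponents: sigma_z grows as (1-p)^-2 for Levy, (1-p)^-1 for Cauchy", {
  p <- 1 - 10^seq(-1, -4, length.out = 10)
  slope <- function(fam) {
    rel <- family_relation(fam, p)
    coef(lm(log(rel$sigma_z) ~ log(1 - p)))[2]
  }
  expect_equal(unname(slope("levy")), -2, tolerance = 1e-10)
  expect_equal(unname(slope("cauchy")), -1, tolerance = 1e-10)
})

test_that("calibrated Normal-family polynomials evaluate and warn off-window", {
  rel <- family_relation("normal", 0.9)
  expect_equal(rel$xi_z, -0.151)
  expect_equal(rel$sigma_z, 0.534)
  rel2 <- family_relation("normal", 0.995)
  expect_equal(rel2$xi_z, -0.7 + 0.61 * 0.995)
  expect_warning(family_relation("normal", 0.5), "valid for p in")
})

test_that("scaling maps shape invariantly and scale multiplicatively", {
  rel <- family_relation("cauchy", 0.9)
  expect_equal(map_to_gpd(rel, 1)$sigma, rel$sigma_z)
  out <- map_to_gpd(rel, 2)
  expect_equal(out$xi, 1)
  expect_equal(out$sigma, 2 / (pi * 0.1), tolerance = 1e-12)
  for (a in c(0.25, 1, 7)) {
    expect_equal(map_to_gpd(rel, a)$xi, rel$xi_z)  # shape invariant in a
  }
  expect_error(map_to_gpd(rel, -1), "positive")
})

test_that("Gamma relation is exact for the exponential baseline and matches the formula", {
  for (rate in c(0.1, 0.5, 1, 4)) {
    out <- gamma_relation(gamma_spec(1, rate))
    expect_identical(out$xi, 0)
    expect_identical(out$sigma, 1 / rate)
  }
  out2 <- gamma_relation(gamma_spec(2, 1))
  expect_equal(out2$sigma, 1 + 0.22 * log(2)^2)
  # alternative reading of the calibrated formula, also exact at shape 1
  alt <- gamma_relation(gamma_spec(2, 1), reading = "log2")
  expect_equal(alt$sigma, 1 + 0.22 * log2(2)^2)
  expect_identical(gamma_relation(gamma_spec(1, 2), reading = "log2")$sigma, 0.5)
})

test_that("simulation calibration recovers the Cauchy constants", {
  fit <- calibrate_relation("cauchy", p_grid = c(0.90, 0.95, 0.99),
                            reps = 5, m = 300,
                            mh_settings = quick_cfg(), seed = 42)
  pred <- predict(fit, p = c(0.90, 0.95, 0.99))
  expect_true(all(abs(pred$xi_z - 1) < 0.1))
  truth <- 1 / (pi * (1 - c(0.90, 0.95, 0.99)))
  expect_true(all(abs(pred$sigma_z / truth - 1) < 0.25))
  expect_equal(fit$provenance$reps, 5)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("calibration on the Normal family tracks the known polynomial shape", {
  fit <- calibrate_relation("normal", p_grid = c(0.90, 0.95, 0.975),
                            reps = 5, m = 500,
                            mh_settings = quick_cfg(), seed = 43)
  ref <- family_relation("normal", 0.95)
  pred <- predict(fit, 0.95)
  expect_lt(abs(pred$xi_z - ref$xi_z), 0.1)
  expect_error(calibrate_relation("normal", p_grid = c(0.9, 0.95), reps = 2,
                                  m = 100, mh_settings = quick_cfg()),
               "3 grid points")
})

test_that("relation fits round-trip through JSON losslessly", {
  fit <- calibrate_relation("cauchy", p_grid = c(0.9, 0.95), reps = 2, m = 100,
                            mh_settings = quick_cfg(), seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_relation_fit(fit, path)
  back <- read_relation_fit(path)
  expect_equal(back$xi_curve, fit$xi_curve)
  expect_equal(back$sigma_curve, fit$sigma_curve)
  expect_equal(back$per_p, fit$per_p)
  expect_equal(predict(back, 0.92), predict(fit, 0.92))
})
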