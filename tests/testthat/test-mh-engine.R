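test_that("a flat target is always accepted and the draw count is exact", {
  cfg <- mh_config(n_keep = 200, burn_in = 100, thinning = 3, seed = 1)
  ch <- run_mh(function(th) 0, cfg, init = c(0, 0), param_names = c("a", "b"))
  expect_equal(unname(ch$acceptance_rates), c(1, 1))
  expect_equal(nrow(ch$draws), 200)
  # draw count honours the contract whatever the burn-in/thinning
  cfg2 <- mh_config(n_keep = 50, burn_in = 7, thinning = 11, seed = 2)
  ch2 <- run_mh(function(th) 0, cfg2, init = 0, param_names = "a")
  expect_equal(nrow(ch2$draws), 50)
})

test_that("the sampler reproduces a standard Normal target", {
  cfg <- mh_config(n_keep = 10000, burn_in = 1000, thinning = 5, seed = 3)
  ch <- run_mh(function(th) -th[1]^2 / 2, cfg, init = 0, param_names = "z")
  s <- summarize_chain(ch)
  expect_lt(abs(s$estimate), 0.05)
  expect_lt(abs(sd(ch$draws$z) - 1), 0.05)
  expect_equal(s$conf.low, -1.96, tolerance = 0.06)
  expect_equal(s$conf.high, 1.96, tolerance = 0.06)
})

test_that("identical configurations give bit-identical chains", {
  cfg <- mh_config(preset = "quick", seed = 99)
  lt <- function(th) -sum(th^2) / 2
  ch1 <- run_mh(lt, cfg, init = c(1, -1), param_names = c("x", "y"))
  ch2 <- run_mh(lt, cfg, init = c(1, -1), param_names = c("x", "y"))
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$acceptance_rates, ch2$acceptance_rates)
})

test_that("chain histogram matches a discretisable target (detailed balance)", {
  # Gamma(3, 2) target: compare binned chain frequencies with the density
  cfg <- mh_config(n_keep = 8000, burn_in = 1000, thinning = 5, seed = 4)
  ch <- run_mh(function(th) if (th[1] <= 0) -Inf else 2 * log(th[1]) - 2 * th[1],
               cfg, init = 1.5, param_names = "g")
  breaks <- qgamma(seq(0, 1, by = 0.1), 3, 2)
  obs <- table(cut(ch$draws$g, breaks))
  expect_gt(suppressWarnings(chisq.test(obs)$p.value), 0.01)
})

test_that("adaptation happens only during burn-in and targets mid acceptance", {
  cfg <- mh_config(n_keep = 2000, burn_in = 2000, thinning = 2,
                   proposal_sds = 40, seed = 5, adapt = TRUE)
  ch <- run_mh(function(th) -th[1]^2 / 2, cfg, init = 0, param_names = "z")
  # a wildly oversized proposal gets tuned down before retention starts
  expect_lt(ch$proposal_sds, 40)
  expect_gt(ch$acceptance_rates, 0.15)
  expect_lt(ch$acceptance_rates, 0.6)
  # without adaptation the scale is untouched
  cfg2 <- mh_config(n_keep = 200, burn_in = 200, thinning = 1,
                    proposal_sds = 40, seed = 6, adapt = FALSE)
  ch2 <- run_mh(function(th) -th[1]^2 / 2, cfg2, init = 0, param_names = "z")
  expect_equal(unname(ch2$proposal_sds), 40)
})

test_that("degenerate and invalid targets are handled as contracted", {
  # single-draw chain: the summary is that draw
  cfg <- mh_config(n_keep = 1, burn_in = 5, thinning = 1, seed = 7)
  ch <- run_mh(function(th) 0, cfg, init = 3.14, param_names = "c")
  s <- summarize_chain(ch)
  expect_equal(s$estimate, ch$draws$c[1])
  expect_equal(s$conf.low, s$conf.high)
  # NaN from the target is a hard error; -Inf at the start too
  expect_error(run_mh(function(th) NaN, cfg, init = 0, param_names = "x"), "NaN")
  expect_error(run_mh(function(th) -Inf, cfg, init = 0, param_names = "x"),
               "not finite")
  # auto-init grid finds a finite point for a positive-only target
  ch3 <- run_mh(function(th) if (th[1] <= 0.4) -Inf else -th[1],
                mh_config(n_keep = 10, burn_in = 10, thinning = 1, seed = 8),
                init = "auto", param_names = "s")
  expect_equal(nrow(ch3$draws), 10)
})

test_that("chains export to CSV and JSON summaries", {
  cfg <- mh_config(n_keep = 50, burn_in = 20, thinning = 1, seed = 9)
  ch <- run_mh(function(th) -th[1]^2 / 2, cfg, init = 0, param_names = "z")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_chain(ch, csv, js)
  back <- read.csv(csv)
  expect_equal(back$z, ch$draws$z)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$summary$estimate, mean(ch$draws$z))
})
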