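test_that("delta-T arithmetic and its guards", {
  expect_equal(compute_delta_t(3.5, 1.7), 1.8)
  expect_equal(compute_delta_t(3.5, 2.6), 0.9)
  expect_equal(compute_delta_t(2.2, 2.2), 0)
  expect_error(compute_delta_t(1.5, 2.0), "precede")
  expect_error(compute_delta_t(1.5, -1), ">= 0")
})

test_that("rate ratios report the truncated integer convention", {
  expect_equal(rate_ratio(7.32, 0.28)$reported, 26)
  expect_equal(rate_ratio(6.02, 0.28)$reported, 21)
  expect_equal(rate_ratio(10.22, 0.25)$reported, 40)
  expect_equal(rate_ratio(1, 1)$reported, 1)
  expect_equal(rate_ratio(7.32, 0.28)$ratio, 7.32 / 0.28)
  expect_error(rate_ratio(1, 0), "> 0")
})

test_that("scenario results are internally consistent by construction", {
  sr <- scenario_result(3.5, 1.7, nu_max = 7.32, nu_max_se = 1.0,
                        nu_min = 0.28, nu_min_se = 0.06)
  expect_equal(sr$delta_t, 1.8)
  expect_equal(sr$ratio, 7.32 / 0.28)
  expect_equal(sr$ratio_reported, trunc(sr$ratio))
  expect_error(scenario_result(1.5, 2.0, 1, 0, 1, 0), "precede")
})

fake_profile <- function(rates, mids, dup = c(TRUE, TRUE, rep(FALSE, length(rates) - 2)),
                         ses = rep(0.01, length(rates))) {
  df <- data.frame(edge = seq_along(rates), parent = 1, child = 2,
                   midpoint_age = mids, age_se = 0, rate = rates,
                   rate_sd = ses, rate_se = ses, dup_incident = dup)
  class(df) <- c("rate_profile", "data.frame")
  df
}

test_that("nu extrema summarise the profile windows", {
  # flat profile: nu_max = nu_min = r
  pf <- fake_profile(rep(0.4, 6), mids = c(3.2, 3.1, 2.0, 1.5, 1.0, 0.5))
  nu <- nu_extrema(pf)
  expect_equal(nu$nu_max, 0.4)
  expect_equal(nu$nu_min, 0.4)

  # cutoff above every midpoint: nu_min is the profile mean
  pf2 <- fake_profile(c(2, 1.5, 0.6, 0.5, 0.4, 0.3),
                      mids = c(3.2, 3.1, 2.0, 1.5, 1.0, 0.5))
  nu2 <- nu_extrema(pf2, proterozoic_cutoff = 10)
  expect_equal(nu2$nu_min, mean(pf2$rate))
  expect_equal(nu2$nu_max, mean(c(2, 1.5)))

  # fastest-branch option
  expect_equal(nu_extrema(pf2, use = "fastest")$nu_max, 2)

  # SE propagation: RMS of member SEs over sqrt(m)
  pf3 <- fake_profile(c(1, 2, 0.5, 0.5), mids = c(3, 3, 1, 1),
                      ses = c(0.2, 0.4, 0.1, 0.1))
  nu3 <- nu_extrema(pf3)
  expect_equal(nu3$nu_max_se, sqrt(mean(c(0.2, 0.4)^2)) / sqrt(2))

  expect_error(nu_extrema(pf2, proterozoic_cutoff = 0.1), "empty Proterozoic")
  pf4 <- fake_profile(c(1, 1), mids = c(1, 1), dup = c(FALSE, FALSE))
  expect_error(nu_extrema(pf4), "duplication-incident")
})

test_that("power-law fits recover exact and noisy exponents", {
  # exact y = 2 x^-1
  x <- c(0.5, 1, 2)
  f <- fit_power_law(x, 2 / x)
  expect_equal(f$exponent, -1, tolerance = 1e-10)
  expect_equal(f$prefactor, 2, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  # constant y: exponent 0
  f0 <- fit_power_law(c(1, 2, 3), rep(5, 3))
  expect_equal(f0$exponent, 0, tolerance = 1e-12)

  # lognormal noise: recovered within 2 regression SEs
  set.seed(31)
  xs <- seq(0.4, 3, length.out = 10)
  ys <- 1.7 * xs^(-1.4) * exp(rnorm(10, 0, 0.1))
  fn <- fit_power_law(xs, ys)
  expect_lt(abs(fn$exponent - (-1.4)), 2 * fn$exponent_se)

  expect_error(fit_power_law(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_power_law(c(-1, 1, 2), c(1, 1, 1)), "positive")
})

test_that("exponential-decay fits recover noise-free parameters", {
  ages <- seq(3.4, 0.2, length.out = 12)
  r <- 0.2 + (5 - 0.2) * exp(-2 * (max(ages) - ages))
  f <- fit_exponential_decay(ages, r)
  expect_lt(f$rmse, 1e-6)
  expect_equal(f$r0, 5, tolerance = 1e-4)
  expect_equal(f$lambda, 2, tolerance = 1e-4)
  expect_equal(f$plateau, 0.2, tolerance = 1e-4)

  # fitted curve is monotone in age when amplitude and lambda are positive
  expect_true(all(diff(f$fitted[order(ages)]) >= -1e-9))

  # constant data: zero amplitude at the observed level
  fc <- fit_exponential_decay(ages, rep(0.7, 12))
  expect_equal(fc$plateau + 0 * fc$r0, fc$plateau)
  expect_lt(abs(fc$plateau + (fc$r0 - fc$plateau) * 1 - 0.7), 1e-6)
  expect_lt(fc$rmse, 1e-8)

  expect_error(fit_exponential_decay(c(1, 2, 3), c(1, 1, 1)), "4 points")
})

test_that("a length-one scenario sweep equals a standalone clock run", {
  sp <- simulate_timetree(4, 2.0, seed = 51)
  model <- substitution_model("POISSON", frequencies = "uniform",
                              gamma_shape = 1, n_categories = 2)
  ds <- make_duplication_dataset(sp, 2.5, NULL, model, 80, seed = 52,
                                 target_ratio = 3)
  topo <- ds$truth$tree$phylo
  crown <- grep("_A$", topo$tip.label, value = TRUE)
  base <- list(calibration("root", 2.45, 2.55, bounds = "hard"))
  st <- clock_settings(substitution_model = model, n_chains = 1,
                       n_iterations = 80, burnin = 0.5, thin = 2, seed = 12,
                       sample_gamma_shape = FALSE)
  sw <- suppressWarnings(scenario_sweep(ds$alignment, topo, base, crown,
                                        mrca_ages = 2.0, dup_age = 2.5,
                                        settings = st))
  st2 <- st
  st2$seed <- paraclock:::derive_seed(st$seed, 1L)
  cal2 <- c(base, list(calibration(crown, 1.95, 2.05, bounds = "hard")))
  fit2 <- suppressWarnings(relaxed_clock(ds$alignment, topo, cal2, st2))
  expect_identical(sw$results[[1]]$fit$chains, fit2$chains)
  expect_equal(sw$results[[1]]$delta_t, 0.5)
  expect_equal(sw$table$delta_t, compute_delta_t(2.5, 2.0))

  # a scenario that cannot be ordered is recorded, not fatal
  sw_bad <- suppressWarnings(scenario_sweep(ds$alignment, topo, base, crown,
                                            mrca_ages = c(2.0, 3.0),
                                            dup_age = 2.5, settings = st))
  errs <- vapply(sw_bad$results, inherits, logical(1), "scenario_error")
  expect_equal(sum(errs), 1L)
  expect_equal(sum(!errs), 1L)
})
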