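# Shared small fixtures for the sampler tests
make_clock_fixture <- function(n_taxa = 6, root_age = 2, sigma2 = 0,
                               root_rate = 0.5, n_sites = 400, seed = 1) {
  tt <- simulate_timetree(n_taxa, root_age, seed = seed)
  tt <- simulate_branch_rates(tt, rate_process("autocorrelated",
                                               root_rate = root_rate,
                                               sigma2 = sigma2),
                              seed = seed + 1)
  model <- substitution_model("LG", gamma_shape = 1, n_categories = 4)
  aln <- simulate_alignment(tt, model, n_sites, seed = seed + 2)
  list(tt = tt, model = model, aln = aln)
}

test_that("identical seeds and settings give bit-identical chains", {
  fx <- make_clock_fixture(n_sites = 60)
  cal <- calibration("root", min_age = 1.8, max_age = 2.2, bounds = "hard")
  st <- clock_settings(substitution_model = fx$model, n_chains = 2,
                       n_iterations = 60, burnin = 0.5, thin = 1, seed = 5)
  f1 <- suppressWarnings(relaxed_clock(fx$aln, fx$tt$phylo, cal, st))
  f2 <- suppressWarnings(relaxed_clock(fx$aln, fx$tt$phylo, cal, st))
  expect_identical(f1$chains, f2$chains)
})

test_that("constant-rate data are recovered with near-flat rate profiles", {
  fx <- make_clock_fixture(n_taxa = 6, sigma2 = 0, root_rate = 0.5,
                           n_sites = 1500, seed = 11)
  # well-constrained timescale: hard intervals at the true node ages
  ph <- fx$tt$phylo
  cals <- list(calibration("root", 1.95, 2.05, bounds = "hard"))
  for (v in 8:(6 + ph$Nnode)) {
    tips <- ph$tip.label[unlist(phangorn::Descendants(ph, v, "tips"))]
    cals <- c(cals, list(calibration(tips, max(fx$tt$ages[v] - 0.05, 1e-3),
                                     fx$tt$ages[v] + 0.05, bounds = "hard")))
  }
  st <- clock_settings(substitution_model = fx$model, n_chains = 2,
                       n_iterations = 300, burnin = 0.5, thin = 2, seed = 2,
                       sample_gamma_shape = FALSE)
  fit <- suppressWarnings(relaxed_clock(fx$aln, ph, cals, st))
  prof <- rate_profile(fit)
  # per-branch posterior noise at this alignment length is ~10-15%, so the
  # recovery bar is set at 20% of the constant truth
  rel_err <- abs(prof$rate - 0.5) / 0.5
  expect_gte(mean(rel_err < 0.2), 0.9)
  # flat truth: profile spread is small relative to its level
  expect_lt(sd(prof$rate) / mean(prof$rate), 0.25)
})

test_that("the rate prior and age prior evaluate their closed forms", {
  # constant-rate configuration: increments are all exactly zero
  tt <- simulate_timetree(5, 2, seed = 3)
  edge <- tt$phylo$edge
  dt <- branch_durations(tt)
  sigma2 <- 0.4
  state <- list(ages = tt$ages, lr = rep(log(0.7), length(tt$ages)),
                sigma2 = sigma2, alpha = 1)
  settings <- clock_settings(rate_model = "autocorrelated",
                             root_rate_prior = list(meanlog = log(0.7), sdlog = 1),
                             sigma2_prior = list(shape = 2, rate = 0.5),
                             n_chains = 2)
  dat <- list(edge = edge, root = 6L, internal = 6:9)
  got <- paraclock:::rate_logprior_state(state, dat, settings)
  want <- dnorm(log(0.7), log(0.7), 1, log = TRUE) +
    sum(dnorm(0, 0, sqrt(sigma2 * dt), log = TRUE)) +
    dgamma(sigma2, 2, rate = 0.5, log = TRUE)
  expect_equal(got, want, tolerance = 1e-12)

  # uncorrelated kind reduces to an i.i.d. gamma log-density sum
  stu <- clock_settings(rate_model = "uncorrelated", n_chains = 2,
                        uncorrelated = list(shape = 2, scale = 0.3))
  stateu <- list(ages = tt$ages, rates = rep(0.5, nrow(edge)))
  gotu <- paraclock:::rate_logprior_state(stateu, dat, stu)
  expect_equal(gotu, sum(dgamma(rep(0.5, nrow(edge)), 2, scale = 0.3,
                                log = TRUE)), tolerance = 1e-12)
})

test_that("the tree-level rate prior matches its closed forms", {
  tt <- simulate_timetree(6, 2, seed = 21)
  proc <- rate_process("autocorrelated", root_rate = 0.7, sigma2 = 0.3)
  tt <- simulate_branch_rates(tt, proc, seed = 22)
  dt <- branch_durations(tt)
  lr <- tt$node_lograte
  want <- sum(dnorm(lr[tt$phylo$edge[, 2]], lr[tt$phylo$edge[, 1]],
                    sqrt(0.3 * dt), log = TRUE))
  expect_equal(rate_logprior(tt, proc), want, tolerance = 1e-12)

  # sigma2 = 0 is degenerate: zero log-density only for constant rates
  proc0 <- rate_process("autocorrelated", root_rate = 0.7, sigma2 = 0)
  tt0 <- simulate_branch_rates(tt, proc0, seed = 23)
  expect_identical(rate_logprior(tt0, proc0), 0)
  expect_identical(rate_logprior(tt, proc0), -Inf)

  # log-density decreases in sigma2 past the mode (normal scaling)
  big <- rate_process("autocorrelated", root_rate = 0.7, sigma2 = 1e6)
  expect_lt(rate_logprior(tt, big), rate_logprior(tt, proc))

  procu <- rate_process("uncorrelated", shape = 2, scale = 0.4)
  ttu <- simulate_branch_rates(tt, procu, seed = 24)
  expect_equal(rate_logprior(ttu, procu),
               sum(dgamma(ttu$branch_rates, 2, scale = 0.4, log = TRUE)),
               tolerance = 1e-12)
})

test_that("infeasible nested hard calibrations fail before sampling", {
  topo <- ape::read.tree(text = "((a,b),c);")
  cals <- list(calibration("root", min_age = 1.0, max_age = 1.5, bounds = "hard"),
               calibration(c("a", "b"), min_age = 2.0, max_age = 3.0,
                           bounds = "hard"))
  st <- clock_settings(n_chains = 2, n_iterations = 10, prior_only = TRUE)
  expect_error(relaxed_clock(NULL, topo, cals, st), "infeasible|feasible")
})

test_that("single-draw fits yield degenerate but exact profiles", {
  fx <- make_clock_fixture(n_sites = 40)
  cal <- calibration("root", min_age = 1.8, max_age = 2.2, bounds = "hard")
  st <- clock_settings(substitution_model = fx$model, n_chains = 1,
                       n_iterations = 20, burnin = 0.5, thin = 10, seed = 9)
  fit <- suppressWarnings(relaxed_clock(fx$aln, fx$tt$phylo, cal, st))
  pool <- pooled_samples(fit)
  expect_equal(nrow(pool), 1L)
  prof <- rate_profile(fit)
  expect_equal(prof$rate, unname(pool[1, paste0("rate_", prof$edge)]))
  expect_true(all(prof$rate_se == 0))
})

test_that("posterior credible intervals cover known root ages", {
  # parameter-recovery coverage over independent synthetic datasets
  n_rep <- 10
  hits <- 0
  for (i in seq_len(n_rep)) {
    fx <- make_clock_fixture(n_taxa = 8, root_age = 2, sigma2 = 0.05,
                             root_rate = 0.5, n_sites = 300, seed = 100 + 7 * i)
    cal <- calibration("root", min_age = 1.0, max_age = 3.0, bounds = "hard")
    st <- clock_settings(substitution_model = fx$model, n_chains = 2,
                         n_iterations = 800, burnin = 0.4, thin = 3,
                         seed = i, sample_gamma_shape = FALSE)
    fit <- suppressWarnings(relaxed_clock(fx$aln, fx$tt$phylo, cal, st))
    ci <- quantile(pooled_samples(fit)[, paste0("age_", 9)], c(0.025, 0.975))
    if (ci[1] <= 2 && 2 <= ci[2]) hits <- hits + 1
  }
  # binomial tolerance around the nominal 95%
  expect_gte(hits, round(0.75 * n_rep))
})

test_that("chain diagnostics flag disagreement and measure sample size", {
  set.seed(1)
  good <- lapply(1:2, function(i)
    matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("x", "y"))))
  d <- paraclock:::chain_diagnostics(good)
  expect_lt(max(d$rhat), 1.1)
  expect_gt(min(d$ess), 100)
  bad <- list(matrix(rnorm(200, 0), 200, 1, dimnames = list(NULL, "x")),
              matrix(rnorm(200, 8), 200, 1, dimnames = list(NULL, "x")))
  expect_gt(paraclock:::chain_diagnostics(bad)$rhat["x"], 2)
})
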