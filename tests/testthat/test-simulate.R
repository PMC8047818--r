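test_that("simulated chronograms satisfy the time-tree invariants", {
  tt <- simulate_timetree(10, 3.0, seed = 1)
  expect_equal(root_age(tt), 3.0)
  expect_true(all(tt$ages[1:10] == 0))
  expect_true(all(branch_durations(tt) > 0))
  internal_ages <- tt$ages[-(1:10)]
  expect_true(all(internal_ages > 0 & internal_ages <= 3.0))

  # two taxa: a single internal node at exactly the root age
  t2 <- simulate_timetree(2, 1.5, seed = 2)
  expect_equal(length(t2$ages), 3L)
  expect_equal(t2$ages[3], 1.5)

  expect_identical(simulate_timetree(6, 2, seed = 7)$ages,
                   simulate_timetree(6, 2, seed = 7)$ages)
  expect_error(simulate_timetree(1, 2), ">= 2")
})

test_that("autocorrelated rates collapse to the root rate at sigma2 = 0", {
  tt <- simulate_timetree(8, 2.0, seed = 3)
  proc <- rate_process("autocorrelated", root_rate = 0.7, sigma2 = 0)
  tt <- simulate_branch_rates(tt, proc, seed = 4)
  expect_equal(tt$branch_rates, rep(0.7, nrow(tt$phylo$edge)), tolerance = 1e-12)
})

test_that("log-rate variance at a fixed depth matches the Brownian closed form", {
  # 2-taxon tree: the tip log-rate after a path of duration T has variance
  # sigma2 * T under the Brownian log-rate walk
  tt <- simulate_timetree(2, 1.0, seed = 5)
  sigma2 <- 0.3
  proc <- rate_process("autocorrelated", root_rate = 1, sigma2 = sigma2)
  n <- 10000
  draws <- vapply(seq_len(n), function(i)
    simulate_branch_rates(tt, proc, seed = i)$node_lograte[1], numeric(1))
  v <- var(draws)
  se_var <- sigma2 * 1.0 * sqrt(2 / (n - 1))
  expect_lt(abs(v - sigma2 * 1.0), 3 * se_var)
  expect_lt(abs(mean(draws) - log(1)), 3 * sqrt(sigma2 / n))
})

test_that("uncorrelated rates are gamma distributed", {
  tt <- simulate_timetree(40, 2.0, seed = 6)
  proc <- rate_process("uncorrelated", shape = 3, scale = 0.2)
  tt <- simulate_branch_rates(tt, proc, seed = 7)
  expect_true(all(tt$branch_rates > 0))
  expect_lt(abs(mean(tt$branch_rates) - 0.6), 0.2)
})

test_that("forward simulation reproduces the 20-state p-distance closed form", {
  # total path 0.5 subs/site between two tips under POISSON/uniform:
  # expected p = (19/20)(1 - exp(-(20/19) 0.5)) = 0.37706
  tt <- simulate_timetree(2, 0.25, seed = 8)
  tt$branch_rates <- c(1, 1)
  m <- substitution_model("POISSON", frequencies = "uniform", n_categories = 1)
  aln <- simulate_alignment(tt, m, 100000, seed = 9)
  s <- alignment_strings(aln)
  p_obs <- p_distance(s[1], s[2])$p
  p_exp <- (19 / 20) * (1 - exp(-(20 / 19) * 0.5))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 1e5))

  # zero-length branches copy the root sequence to every tip
  tt0 <- simulate_timetree(4, 1, seed = 10)
  tt0$branch_rates <- rep(1e-12, nrow(tt0$phylo$edge))
  a0 <- simulate_alignment(tt0, m, 200, seed = 11, return_ancestral = TRUE)
  expect_true(all(alignment_strings(a0) == attr(a0, "root_seq")))

  expect_identical(alignment_strings(simulate_alignment(tt, m, 50, seed = 12)),
                   alignment_strings(simulate_alignment(tt, m, 50, seed = 12)))
})

test_that("site-pattern frequencies match analytic transition probabilities", {
  # 2 taxa, LG + G4: P(a at tip1, b at tip2) = sum_k (1/K) pi_a P_k(a,b | d)
  m <- substitution_model("LG", gamma_shape = 0.8, n_categories = 4)
  tt <- simulate_timetree(2, 0.2, seed = 13)
  tt$branch_rates <- c(1, 1)           # total distance 0.4
  n <- 100000
  aln <- simulate_alignment(tt, m, n, seed = 14)
  mat <- as.matrix(aln)
  ia <- match(mat[1, ], paraclock:::AA_CODES)
  ib <- match(mat[2, ], paraclock:::AA_CODES)
  # expected joint for a handful of common cells
  joint_exp <- matrix(0, 20, 20)
  for (k in 1:4) {
    P <- prob_matrix(m, 0.4, m$rates[k])
    joint_exp <- joint_exp + (m$pi * P) / 4
  }
  for (cell in list(c(1, 1), c(10, 10), c(1, 10), c(5, 2))) {
    obs <- mean(ia == cell[1] & ib == cell[2])
    e <- joint_exp[cell[1], cell[2]]
    expect_lt(abs(obs - e), 3 * sqrt(e * (1 - e) / n) + 1e-6)
  }
})

test_that("duplication datasets carry an exactly self-consistent truth record", {
  sp <- simulate_timetree(6, 3.0, seed = 20)
  m <- substitution_model("POISSON", n_categories = 1)
  proc <- rate_process("autocorrelated", root_rate = 1.5, sigma2 = 0.2)
  ds <- make_duplication_dataset(sp, 3.6, proc, m, 60, seed = 21)

  expect_equal(ds$truth$delta_t, 0.6, tolerance = 1e-9)
  expect_equal(n_seq(ds$alignment), 12L)           # 2 x species tips
  expect_equal(ds$truth$dup_age, 3.6)

  # truth values recomputable from the stored tree
  re <- duplication_truth(ds$truth$tree, ds$truth$proterozoic_cutoff)
  expect_equal(re$nu_max, ds$truth$nu_max)
  expect_equal(re$nu_min, ds$truth$nu_min)

  # sigma2 = 0: flat rates, ratio exactly 1
  proc0 <- rate_process("autocorrelated", root_rate = 0.8, sigma2 = 0)
  ds0 <- make_duplication_dataset(sp, 3.6, proc0, m, 10, seed = 22)
  expect_equal(ds0$truth$ratio, 1, tolerance = 1e-9)

  # generated tree passes the time-tree validator (re-construction)
  tt <- ds$truth$tree
  expect_silent(time_tree(tt$phylo, tt$ages, tt$branch_rates, tt$node_labels))

  expect_error(make_duplication_dataset(sp, 2.9, proc, m, 10, seed = 1),
               "exceed")
})

test_that("ratio-targeted envelopes realise the requested truth ratio", {
  sp <- simulate_timetree(8, 3.0, seed = 30)
  m <- substitution_model("POISSON", n_categories = 1)
  for (R in c(5, 20)) {
    ds <- make_duplication_dataset(sp, 3.5, NULL, m, 10, seed = 31,
                                   target_ratio = R)
    expect_equal(ds$truth$ratio, R, tolerance = 1e-9)
  }
})
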