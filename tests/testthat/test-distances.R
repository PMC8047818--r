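test_that("pairwise identity and p-distance handle gaps by pairwise deletion", {
  expect_equal(pairwise_identity("ACDA", "ACDA"), 1.0)
  expect_equal(pairwise_identity("AC-A", "AG-A"), 2 / 3)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0)
  expect_error(pairwise_identity("--", "AA"), "undefined")
  expect_error(pairwise_identity("AC", "ACD"), "equal length")

  pd <- p_distance("AAAA", "AAAT")
  expect_equal(pd$p, 0.25)
  expect_equal(pd$n_comparable, 4L)
  expect_equal(p_distance("ACDE", "ACDE")$p, 0)

  # p = 1 - identity on gap-free pairs
  a <- "ACDEFGHIKL"; b <- "ACDEFGHIKV"
  expect_equal(p_distance(a, b)$p, 1 - pairwise_identity(a, b))

  # a column gapped in one sequence is excluded entirely
  expect_equal(p_distance("AC-E", "ACD-")$p, 0)
})

test_that("distance corrections follow their closed forms", {
  expect_equal(correct_distance(0, "poisson"), 0)
  expect_equal(correct_distance(0, "gamma", 1), 0)
  expect_equal(correct_distance(0.5, "poisson"), log(2))
  expect_equal(correct_distance(0.5, "gamma", 1), 1.0)  # p/(1-p)
  expect_error(correct_distance(1, "poisson"), "infinite")
  expect_error(correct_distance(-0.1, "poisson"))

  # monotone increasing in p; gamma -> poisson as alpha -> Inf
  p <- seq(0, 0.9, by = 0.01)
  expect_true(all(diff(correct_distance(p, "poisson")) > 0))
  expect_true(all(diff(correct_distance(p, "gamma", 0.5)) > 0))
  expect_lt(max(abs(correct_distance(p, "gamma", 1e6) -
                    correct_distance(p, "poisson"))), 1e-4)
})

test_that("ML distance inverts the 20-state closed form under POISSON", {
  m <- substitution_model("POISSON", frequencies = "uniform", n_categories = 1)
  # build an exact-count pair: p = 0.3771 corresponds to d ~ 0.5
  n <- 10000
  nd <- round(0.3771 * n)
  a <- paste(rep("A", n), collapse = "")
  b <- paste(c(rep("C", nd), rep("A", n - nd)), collapse = "")
  got <- ml_pairwise_distance(a, b, m)
  expect_equal(got$distance,
               paraclock:::d_from_p_poisson20(nd / n), tolerance = 1e-4)

  # identical pair short-circuits to exactly zero
  expect_identical(ml_pairwise_distance(a, a, m)$distance, 0)

  # closed-form inversion across p grid
  for (p in c(0.05, 0.3, 0.6, 0.9)) {
    k <- round(p * 2000)
    x <- paste(rep("A", 2000), collapse = "")
    y <- paste(c(rep("R", k), rep("A", 2000 - k)), collapse = "")
    expect_equal(ml_pairwise_distance(x, y, m)$distance,
                 paraclock:::d_from_p_poisson20(k / 2000), tolerance = 1e-4)
  }
})

test_that("ML distance recovers a simulated JTT divergence", {
  model <- substitution_model("JTT", frequencies = "model", gamma_shape = 1,
                              n_categories = 4)
  tt <- simulate_timetree(2, 0.4, seed = 5)
  tt$branch_rates <- rep(1, 2)          # total path length 0.8 subs/site
  aln <- simulate_alignment(tt, model, 20000, seed = 6)
  s <- alignment_strings(aln)
  got <- ml_pairwise_distance(s[1], s[2], model)
  # Fisher-information SE at d ~ 0.8 with 2e4 sites is ~0.01
  expect_lt(abs(got$distance - 0.8), 0.05)
})

test_that("within-group means aggregate pairwise distances with bootstrap SE", {
  # three 10-column sequences with pairwise p of 0.1, 0.2, 0.3
  aln <- aa_alignment(c(a = "AAAAAAAAAA",
                        b = "CAAAAAAAAA",   # vs a: p = 0.1
                        c = "ADDAAAAAAA"))  # vs a: 0.2, vs b: 0.3
  r <- within_group_mean(aln, c("a", "b", "c"), model = "p", n_bootstrap = 0)
  expect_equal(r$mean, 0.2)
  expect_equal(r$n_pairs, 3L)

  # identical sequences: mean 0, SE 0
  aln0 <- aa_alignment(c(x = "AAAA", y = "AAAA", z = "AAAA"))
  r0 <- within_group_mean(aln0, c("x", "y", "z"), model = "poisson",
                          n_bootstrap = 50, seed = 1)
  expect_equal(r0$mean, 0)
  expect_equal(r0$se, 0)

  # two-member group equals the single pairwise distance
  r2 <- within_group_mean(aln, c("a", "b"), model = "poisson", n_bootstrap = 0)
  expect_equal(r2$mean, correct_distance(0.1, "poisson"))

  # differences model counts raw mismatches
  rd <- within_group_mean(aln, c("a", "b"), model = "differences", n_bootstrap = 0)
  expect_equal(rd$mean, 1)

  expect_error(within_group_mean(aln, c("a", "zz")), "zz")
  expect_error(within_group_mean(aln, "a"), "2 members")

  # bootstrap SE is reproducible under a seed and shrinks with length
  set.seed(3)
  mk <- function(L) {
    base <- sample(paraclock:::AA_CODES, L, TRUE)
    mut <- base; idx <- sample(L, round(0.2 * L)); mut[idx] <- "W"
    aa_alignment(c(u = paste(base, collapse = ""), v = paste(mut, collapse = "")))
  }
  ses <- vapply(c(100, 1000, 10000), function(L)
    within_group_mean(mk(L), c("u", "v"), model = "poisson",
                      n_bootstrap = 100, seed = 11)$se, numeric(1))
  expect_true(all(diff(ses) < 0))
  fixed <- mk(100)
  r_a <- within_group_mean(fixed, c("u", "v"), model = "poisson",
                           n_bootstrap = 100, seed = 11)
  r_b <- within_group_mean(fixed, c("u", "v"), model = "poisson",
                           n_bootstrap = 100, seed = 11)
  expect_identical(r_a$se, r_b$se)
})
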