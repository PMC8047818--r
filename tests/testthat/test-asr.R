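test_that("marginal posteriors equal the enumeration oracle on small trees", {
  set.seed(17)
  shapes <- c("((a,b),(c,d));", "(((a,b),c),(d,e));", "((a,b),c);")
  for (nwk in shapes) {
    tree <- ape::read.tree(text = nwk)
    ntip <- ape::Ntip(tree)
    for (rep in 1:3) {
      tree$edge.length <- runif(nrow(tree$edge), 0.05, 0.8)
      model <- substitution_model(sample(c("POISSON", "LG"), 1),
                                  gamma_shape = runif(1, 0.4, 1.5),
                                  n_categories = sample(1:2, 1))
      aln <- random_small_alignment(tree, 2, gap_prob = 0.1)
      states <- match(t(as.matrix(aln)[tree$tip.label, ]),
                      paraclock:::AA_CODES)
      states <- matrix(states, ncol = ntip)
      for (target in (ntip + 1):(ntip + tree$Nnode)) {
        rec <- marginal_asr(aln, tree, model, target, indel_mode = "none")
        for (s in 1:2) {
          want <- oracle_asr_site(states[s, ], tree, tree$edge.length,
                                  model, target)
          expect_equal(unname(rec$pp[, s]), want, tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("reconstruction behaves on concordant and symmetric signals", {
  m <- substitution_model("POISSON", frequencies = "uniform", n_categories = 1)
  star <- ape::read.tree(text = "((a:0.01,b:0.01):0.005,c:0.01);")
  aln <- aa_alignment(c(a = "A", b = "A", c = "A"))
  rec <- marginal_asr(aln, star, m, 4, indel_mode = "none")
  expect_gt(rec$pp["A", 1], 0.99)
  expect_identical(rec$map[1], "A")

  # 2+2 symmetric split: PP(A) = PP(C), MAP tie broken alphabetically to A
  sym <- ape::read.tree(text = "((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  aln2 <- aa_alignment(c(a = "A", b = "A", c = "C", d = "C"))
  rec2 <- marginal_asr(aln2, sym, m, 5, indel_mode = "none")
  expect_equal(unname(rec2$pp["A", 1]), unname(rec2$pp["C", 1]),
               tolerance = 1e-12)
  expect_identical(rec2$map[1], "A")

  expect_error(marginal_asr(aln2, sym, m, 2), "leaf")
  expect_equal(colSums(rec2$pp), 1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("indel reconstruction follows Fitch parsimony and the ML cutoff", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  # site 1: all gapped; site 2: all present; site 3: one sister pair gapped
  aln <- aa_alignment(c(a = "-A-", b = "-A-", c = "-AA", d = "-AA"))
  for (mode in c("ml", "parsimony")) {
    mask <- reconstruct_indels(aln, tree, 5, mode)
    expect_false(mask[1])
    expect_true(mask[2])
  }
  # hand-executed Fitch at the root for site 3: down(ab) = {absent},
  # down(cd) = {present}, root union = tie -> present
  expect_true(reconstruct_indels(aln, tree, 5, "parsimony")[3])
  # at the gapped pair's own ancestor the state is absent
  anc_ab <- ape::getMRCA(tree, c("a", "b"))
  expect_false(reconstruct_indels(aln, tree, anc_ab, "parsimony")[3])

  # ML cutoff: site 3 at the root has PP(present) ~ 0.5; a lenient cutoff
  # emits the residue, the default 0.7 does not
  expect_false(reconstruct_indels(aln, tree, 5, "ml", cutoff = 0.7)[3])
  expect_true(reconstruct_indels(aln, tree, 5, "ml", cutoff = 0.4)[3])
  expect_error(reconstruct_indels(aln, tree, 5, "ml", cutoff = 1.2), "cutoff")
})

test_that("reference-site mapping is a bijection on ungapped positions", {
  aln <- aa_alignment(c(ref = "A-CD", other = "AACD"))
  expect_equal(map_reference_site(aln, "ref", 1), 1L)
  expect_equal(map_reference_site(aln, "ref", 2), 3L)  # residue C
  expect_equal(map_reference_site(aln, "ref", 3), 4L)
  expect_error(map_reference_site(aln, "ref", 4), "outside")
  expect_error(map_reference_site(aln, "nope", 1), "nope")

  inv <- map_alignment_column(aln, "ref", 3)
  expect_identical(inv$residue, "C")
  expect_equal(inv$position, 2)
  expect_identical(map_alignment_column(aln, "ref", 2)$residue, "-")

  for (p in 1:3)
    expect_equal(map_alignment_column(aln, "ref",
                                      map_reference_site(aln, "ref", p))$position, p)
})

test_that("reconstruction agreement statistics count unmasked sites", {
  mk_rec <- function(map, present = rep(TRUE, length(map))) {
    pp <- matrix(1e-6, 20, length(map), dimnames = list(paraclock:::AA_CODES, NULL))
    for (i in seq_along(map)) pp[map[i], i] <- 1
    pp <- sweep(pp, 2, colSums(pp), "/")
    m <- map; m[!present] <- NA
    structure(list(target_node = 1L, pp = pp, map = m, present = present,
                   method = "test"), class = "ancestral_reconstruction")
  }
  r1 <- mk_rec(rep("A", 10))
  r2 <- mk_rec(c(rep("A", 9), "C"))
  cmp <- compare_reconstructions(list(r1, r2))
  expect_equal(cmp$mean_identity, 0.9)
  expect_equal(cmp$sd_identity, 0)

  cmp2 <- compare_reconstructions(list(r1, r1, r1))
  expect_equal(cmp2$mean_identity, 1)

  # one reconstruction against a reference reduces to pairwise identity
  ref <- paste(c(rep("A", 8), "C", "C"), collapse = "")
  cmp3 <- compare_reconstructions(list(r1), reference = ref)
  expect_equal(unname(cmp3$reference_identities), 0.8)

  # masked sites are excluded from the comparison
  r3 <- mk_rec(rep("A", 10), present = c(rep(TRUE, 5), rep(FALSE, 5)))
  cmp4 <- compare_reconstructions(list(r3, r2))
  expect_equal(cmp4$mean_identity, 1)   # only the 5 unmasked, matching sites
})

test_that("the true root sequence is recovered on shallow simulated trees", {
  model <- substitution_model("LG", n_categories = 1)
  tt <- simulate_timetree(8, 1.0, seed = 61)
  tt$branch_rates <- rep(0.12, nrow(tt$phylo$edge))  # tree depth 0.12 subs/site
  aln <- simulate_alignment(tt, model, 500, seed = 62, return_ancestral = TRUE)
  tree <- as.phylo.time_tree(tt)
  rec <- marginal_asr(aln, tree, model, ape::Ntip(tree) + 1L,
                      indel_mode = "none")
  truth <- strsplit(attr(aln, "root_seq"), "")[[1]]
  expect_gte(mean(rec$map == truth), 0.9)

  # posterior confidence in the truth rises as branches shorten
  tt2 <- tt; tt2$branch_rates <- rep(0.012, nrow(tt$phylo$edge))
  aln2 <- simulate_alignment(tt2, model, 500, seed = 63, return_ancestral = TRUE)
  rec2 <- marginal_asr(aln2, as.phylo.time_tree(tt2), model,
                       ape::Ntip(tree) + 1L, indel_mode = "none")
  truth2 <- strsplit(attr(aln2, "root_seq"), "")[[1]]
  pp1 <- mean(rec$pp[cbind(match(truth, paraclock:::AA_CODES), seq_along(truth))])
  pp2 <- mean(rec2$pp[cbind(match(truth2, paraclock:::AA_CODES), seq_along(truth2))])
  expect_gt(pp2, pp1)
})

test_that("per-site tables and MAP fasta round-trip", {
  m <- substitution_model("POISSON", frequencies = "uniform", n_categories = 1)
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  aln <- aa_alignment(c(a = "AC-", b = "AC-", c = "AD-", d = "AD-"))
  rec <- marginal_asr(aln, tree, m, 5, indel_mode = "parsimony")
  expect_identical(map_sequence(rec), paste0(rec$map[1], rec$map[2], "-"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asr_table(rec, path, alignment = aln, reference_id = "a")
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$present, c(TRUE, TRUE, FALSE))
})
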