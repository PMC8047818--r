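## Forward simulation: chronograms, branch-rate processes, alignments, and
## duplication-anchored paralog datasets with a decaying rate profile. Every
## downstream stage of the package is testable against these generators.

#' Rate process specification
#'
#' @param kind `"autocorrelated"` (lognormal: node log-rates follow Brownian
#'   motion along the tree) or `"uncorrelated"` (i.i.d. gamma branch rates).
#' @param root_rate Rate at the root, delta per Ga (> 0); autocorrelated
#'   kind.
#' @param sigma2 Variance of the log-rate Brownian increments per Ga
#'   (>= 0); autocorrelated kind.
#' @param shape,scale Gamma parameters of the uncorrelated kind (branch
#'   rate mean = shape * scale).
#' @return Object of class `rate_process`.
#' @export
rate_process <- function(kind = c("autocorrelated", "uncorrelated"),
                         root_rate = 1, sigma2 = 0.1,
                         shape = 2, scale = 0.5) {
  kind <- match.arg(kind)
  if (kind == "autocorrelated") {
    if (root_rate <= 0) stop("root_rate must be > 0")
    if (sigma2 < 0) stop("sigma2 must be >= 0")
  } else {
    if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0")
  }
  structure(list(kind = kind, root_rate = root_rate, sigma2 = sigma2,
                 shape = shape, scale = scale),
            class = "rate_process")
}

#' Simulate a random chronogram
#'
#' Draws a coalescent-style ultrametric topology and rescales its node
#' depths so the root sits exactly at `root_age`, with all tips extant
#' (age 0).
#'
#' @param n_taxa Number of tips (>= 2).
#' @param root_age Root age in Ga (> 0).
#' @param seed Integer seed.
#' @return A [time_tree] without rates; tips are labelled `t1..tn`.
#' @export
simulate_timetree <- function(n_taxa, root_age, seed = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (root_age <= 0) stop("root_age must be > 0")
  with_seed(seed, {
    ph <- ape::rcoal(n_taxa, tip.label = paste0("t", seq_len(n_taxa)))
    depths <- ape::node.depth.edgelength(ph)      # distance from root
    ages <- max(depths) - depths                  # ultrametric: tips at 0
    ages <- ages * (root_age / max(ages))
    ph$edge.length <- NULL
    time_tree(ph, ages)
  })
}

#' Simulate branch rates on a chronogram
#'
#' Autocorrelated kind: node log-rates follow a Brownian walk down the tree
#' (`log r_child ~ N(log r_parent, sigma2 * dt)`, no drift correction) and a
#' branch's rate is `exp` of the mean of its endpoint log-rates.
#' Uncorrelated kind: i.i.d. gamma branch rates.
#'
#' @param tree A [time_tree] with ages set.
#' @param process A [rate_process].
#' @param seed Integer seed.
#' @return The input [time_tree] with `branch_rates` (and, for the
#'   autocorrelated kind, `node_lograte`) filled.
#' @export
simulate_branch_rates <- function(tree, process, seed = NULL) {
  stopifnot(inherits(tree, "time_tree"), inherits(process, "rate_process"))
  edge <- tree$phylo$edge
  with_seed(seed, {
    if (process$kind == "uncorrelated") {
      tree$branch_rates <- rgamma(nrow(edge), shape = process$shape,
                                  scale = process$scale)
      tree$branch_rates <- pmax(tree$branch_rates, 1e-12)
    } else {
      n_nodes <- length(tree$ages)
      root <- ape::Ntip(tree$phylo) + 1L
      lr <- rep(NA_real_, n_nodes)
      lr[root] <- log(process$root_rate)
      ## preorder: parents before children
      pre <- ape::reorder.phylo(tree$phylo, "cladewise")$edge
      for (e in seq_len(nrow(pre))) {
        p <- pre[e, 1]; ch <- pre[e, 2]
        dt <- tree$ages[p] - tree$ages[ch]
        lr[ch] <- rnorm(1, mean = lr[p], sd = sqrt(process$sigma2 * dt))
      }
      tree$node_lograte <- lr
      tree$branch_rates <- exp((lr[edge[, 1]] + lr[edge[, 2]]) / 2)
    }
    tree
  })
}

#' Deterministic exponential rate envelope
#'
#' Assigns each branch the rate of the decay curve
#' `r(t) = plateau + (r0 - plateau) * exp(-lambda * (t_root - t))` evaluated
#' at the branch midpoint age `t` (Ga before present). Noise-free: used for
#' recovery tests of the decay fit and for duplication datasets with a known
#' rate ratio.
#'
#' @param tree A [time_tree].
#' @param r0 Rate at the root (delta per Ga).
#' @param lambda Decay constant per Ga (>= 0).
#' @param plateau Asymptotic recent rate (> 0).
#' @return The [time_tree] with deterministic `branch_rates`.
#' @export
envelope_rates <- function(tree, r0, lambda, plateau) {
  stopifnot(inherits(tree, "time_tree"))
  if (plateau <= 0 || r0 <= 0) stop("rates must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  t_root <- root_age(tree)
  mid <- branch_midpoints(tree)
  tree$branch_rates <- plateau + (r0 - plateau) * exp(-lambda * (t_root - mid))
  tree$node_lograte <- {
    lr <- log(plateau + (r0 - plateau) * exp(-lambda * (t_root - tree$ages)))
    lr
  }
  tree
}

#' Simulate an amino-acid alignment on a rate-annotated time tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies;
#' each site is assigned one of the K discrete-gamma categories uniformly;
#' states then evolve down the tree with transition matrices
#' `P(subs_e * r_cat)`. No indels are generated.
#'
#' @param tree A [time_tree] with branch rates.
#' @param model A [substitution_model].
#' @param n_sites Number of columns (>= 1).
#' @param seed Integer seed.
#' @param return_ancestral If `TRUE`, attach the root and internal node
#'   sequences as attributes `root_seq` / `node_seqs`.
#' @return An [aa_alignment] of the tip sequences.
#' @export
simulate_alignment <- function(tree, model, n_sites, seed = NULL,
                               return_ancestral = FALSE) {
  stopifnot(inherits(tree, "time_tree"), inherits(model, "substitution_model"))
  if (n_sites < 1) stop("n_sites must be >= 1")
  subs <- branch_subs(tree)
  ph <- tree$phylo
  ntip <- ape::Ntip(ph)
  n_nodes <- length(tree$ages)
  with_seed(seed, {
    K <- model$n_categories
    site_cat <- sample.int(K, n_sites, replace = TRUE)
    states <- matrix(NA_integer_, n_nodes, n_sites)
    root <- ntip + 1L
    states[root, ] <- sample.int(20, n_sites, replace = TRUE, prob = model$pi)
    pre <- ape::reorder.phylo(ph, "cladewise")
    ord <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                 paste(ph$edge[, 1], ph$edge[, 2]))
    for (i in seq_len(nrow(pre$edge))) {
      p <- pre$edge[i, 1]; ch <- pre$edge[i, 2]
      b <- subs[ord[i]]
      for (k in seq_len(K)) {
        idx <- which(site_cat == k)
        if (length(idx) == 0) next
        P <- prob_matrix(model, b, model$rates[k])
        cum <- P[states[p, idx], , drop = FALSE]
        u <- runif(length(idx))
        states[ch, idx] <- max.col(t(apply(cum, 1, cumsum)) >= u, "first")
      }
    }
    tip_seqs <- vapply(seq_len(ntip), function(i)
      paste(AA_CODES[states[i, ]], collapse = ""), character(1))
    aln <- aa_alignment(tip_seqs, ph$tip.label)
    if (return_ancestral) {
      attr(aln, "root_seq") <- paste(AA_CODES[states[root, ]], collapse = "")
      attr(aln, "node_seqs") <- vapply((ntip + 1L):n_nodes, function(i)
        paste(AA_CODES[states[i, ]], collapse = ""), character(1))
      attr(aln, "site_category") <- site_cat
    }
    aln
  })
}

#' Duplication-anchored paralog dataset with known truth
#'
#' Mirrors a species chronogram into two paralog subtrees (`_A` / `_B` tip
#' suffixes) joined at a duplication node of age `dup_age`, simulates a
#' decaying rate profile (fast at the duplication, stabilising toward the
#' present) and an alignment, and records the realised truth: delta-T (time
#' from the duplication to the paralog crown ancestors), nu_max (mean rate
#' of the two branches incident to the duplication node) and nu_min (mean
#' rate of branches with midpoint age below `proterozoic_cutoff`).
#'
#' @param species_tree A [time_tree] (ages set; rates ignored), e.g. from
#'   [simulate_timetree()].
#' @param dup_age Age of the duplication node, strictly greater than the
#'   species root age.
#' @param process A [rate_process] with `root_rate` the rate at the
#'   duplication node, or `NULL` when `envelope` is given.
#' @param model A [substitution_model].
#' @param n_sites Alignment length.
#' @param seed Integer seed.
#' @param proterozoic_cutoff Midpoint-age threshold (Ga) defining the
#'   nu_min window; default 2.5.
#' @param envelope Optional `list(r0, lambda, plateau)` for a deterministic
#'   exponential rate profile instead of the stochastic autocorrelated
#'   process (used when a known truth rate ratio is required).
#' @param target_ratio Optional target nu_max/nu_min; solves the envelope
#'   amplitude in closed form so the realised truth ratio equals it exactly
#'   (with `lambda` and `plateau` taken from `envelope` or their defaults
#'   2 per Ga and 0.25 delta per Ga).
#' @return List with `alignment` (an [aa_alignment]) and `truth` (class
#'   `duplication_truth`: the rate-annotated [time_tree] with labels `dup`,
#'   `crown_A`, `crown_B`, plus `delta_t`, `nu_max`, `nu_min`, `ratio`).
#' @export
make_duplication_dataset <- function(species_tree, dup_age, process, model,
                                     n_sites, seed = NULL,
                                     proterozoic_cutoff = 2.5,
                                     envelope = NULL, target_ratio = NULL) {
  stopifnot(inherits(species_tree, "time_tree"))
  sp_root <- root_age(species_tree)
  if (dup_age <= sp_root)
    stop("dup_age (", dup_age, ") must exceed the species root age (",
         sp_root, ")")
  joined <- join_paralog_trees(species_tree, dup_age)
  tt <- joined$tree

  if (!is.null(target_ratio)) {
    lambda <- envelope$lambda %||% 2
    plateau <- envelope$plateau %||% 0.25
    envelope <- solve_envelope_ratio(tt, target_ratio, lambda, plateau,
                                     proterozoic_cutoff)
  }
  if (!is.null(envelope)) {
    tt <- envelope_rates(tt, envelope$r0, envelope$lambda, envelope$plateau)
  } else {
    stopifnot(inherits(process, "rate_process"))
    tt <- simulate_branch_rates(tt, process, seed = derive_seed(seed, 1L))
  }

  aln <- simulate_alignment(tt, model, n_sites, seed = derive_seed(seed, 2L),
                            return_ancestral = TRUE)
  truth <- duplication_truth(tt, proterozoic_cutoff)
  list(alignment = aln, truth = truth)
}

## Solve the envelope amplitude so the realised nu_max/nu_min equals the
## target exactly. With rates r(mid) = plateau + A * exp(-lambda (t_root -
## mid)) and a/b the mean decay factors over the duplication-incident /
## Proterozoic-window branches, the ratio is linear-fractional in A.
solve_envelope_ratio <- function(tree, target_ratio, lambda, plateau,
                                 proterozoic_cutoff) {
  t_root <- root_age(tree)
  mid <- branch_midpoints(tree)
  decay <- exp(-lambda * (t_root - mid))
  dup <- tree$node_labels[["dup"]]
  a <- mean(decay[tree$phylo$edge[, 1] == dup])
  window <- mid < proterozoic_cutoff
  if (!any(window))
    stop("no branch midpoint below the cutoff (", proterozoic_cutoff, " Ga)")
  b <- mean(decay[window])
  denom <- a - target_ratio * b
  if (denom <= 0)
    stop("target ratio ", target_ratio, " is unreachable with lambda = ",
         lambda, " on this tree; increase lambda")
  A <- plateau * (target_ratio - 1) / denom
  list(r0 = plateau + A, lambda = lambda, plateau = plateau)
}

## Build the joined two-paralog chronogram from a species chronogram.
join_paralog_trees <- function(species_tree, dup_age) {
  dur_nwk <- function(suffix) {
    ph <- species_tree$phylo
    ph$tip.label <- paste0(ph$tip.label, suffix)
    ph$edge.length <- branch_durations(species_tree)
    stem <- dup_age - root_age(species_tree)
    nwk <- ape::write.tree(ph)
    sub(";$", sprintf(":%.10f", stem), nwk)
  }
  full <- ape::read.tree(text = paste0("(", dur_nwk("_A"), ",", dur_nwk("_B"), ");"))
  depths <- ape::node.depth.edgelength(full)
  ages <- dup_age - depths
  ages[abs(ages) < 1e-8] <- 0
  full$edge.length <- NULL
  ntip <- ape::Ntip(full)
  root <- ntip + 1L
  tipsA <- grep("_A$", full$tip.label, value = TRUE)
  tipsB <- grep("_B$", full$tip.label, value = TRUE)
  labels <- c(dup = root,
              crown_A = mrca_node(full, tipsA),
              crown_B = mrca_node(full, tipsB))
  list(tree = time_tree(full, ages, node_labels = labels))
}

#' Mirrored calibration set for a duplication dataset
#'
#' Builds the cross-calibration design used in duplication-anchored clock
#' studies: the duplication (root) node and every internal node older than
#' `min_age` are constrained by hard intervals of half-width `halfwidth`
#' around their true ages. Because the two paralog subtrees mirror the
#' same species history, equivalent nodes in both subtrees receive the
#' same constraint.
#'
#' @param truth A `duplication_truth` record.
#' @param min_age Only calibrate nodes older than this (Ga, default 0.3).
#' @param halfwidth Half-width of each hard interval (default 0.05 Ga).
#' @return List of [calibration] objects (root first).
#' @export
duplication_calibrations <- function(truth, min_age = 0.3, halfwidth = 0.05) {
  tt <- truth$tree
  ph <- tt$phylo
  ntip <- ape::Ntip(ph)
  root <- ntip + 1L
  cals <- list(calibration("root", truth$dup_age - halfwidth,
                           truth$dup_age + halfwidth, bounds = "hard"))
  for (v in (ntip + 1L):(ntip + ph$Nnode)) {
    if (v == root) next
    if (tt$ages[v] <= min_age) next
    tips <- ph$tip.label[unlist(phangorn::Descendants(ph, v, "tips"))]
    cals <- c(cals, list(calibration(tips, tt$ages[v] - halfwidth,
                                     tt$ages[v] + halfwidth, bounds = "hard")))
  }
  cals
}

#' Recompute the truth record of a duplication tree
#'
#' @param tree A rate-annotated [time_tree] carrying labels `dup`,
#'   `crown_A`, `crown_B`.
#' @param proterozoic_cutoff Midpoint-age threshold (Ga) for nu_min.
#' @return Object of class `duplication_truth`.
#' @export
duplication_truth <- function(tree, proterozoic_cutoff = 2.5) {
  stopifnot(inherits(tree, "time_tree"), !is.null(tree$branch_rates))
  lab <- tree$node_labels
  if (is.null(lab) || !all(c("dup", "crown_A", "crown_B") %in% names(lab)))
    stop("tree must carry 'dup', 'crown_A' and 'crown_B' node labels")
  dup <- lab[["dup"]]
  crown_age <- tree$ages[lab[["crown_A"]]]
  delta_t <- tree$ages[dup] - crown_age
  edge <- tree$phylo$edge
  dup_edges <- which(edge[, 1] == dup)
  nu_max <- mean(tree$branch_rates[dup_edges])
  mid <- branch_midpoints(tree)
  window <- mid < proterozoic_cutoff
  if (!any(window))
    stop("no branch midpoint below the cutoff (", proterozoic_cutoff, " Ga)")
  nu_min <- mean(tree$branch_rates[window])
  structure(list(tree = tree, delta_t = delta_t,
                 dup_age = tree$ages[dup], mrca_age = crown_age,
                 nu_max = nu_max, nu_min = nu_min,
                 ratio = nu_max / nu_min,
                 proterozoic_cutoff = proterozoic_cutoff),
            class = "duplication_truth")
}

#' @export
print.duplication_truth <- function(x, ...) {
  cat(sprintf("Duplication truth: dup %.3g Ga, crown %.3g Ga (delta-T %.3g Ga)\n",
              x$dup_age, x$mrca_age, x$delta_t))
  cat(sprintf("  nu_max %.4g, nu_min %.4g, ratio %.4g\n",
              x$nu_max, x$nu_min, x$ratio))
  invisible(x)
}

#' Write a truth record as JSON
#' @param truth A `duplication_truth`.
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(dup_age = truth$dup_age, mrca_age = truth$mrca_age,
         delta_t = truth$delta_t, nu_max = truth$nu_max,
         nu_min = truth$nu_min, ratio = truth$ratio,
         proterozoic_cutoff = truth$proterozoic_cutoff),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
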