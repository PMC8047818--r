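# Independent brute-force oracles: likelihood and marginal ancestral
# posteriors by explicit enumeration of all interior-state assignments.
# Deliberately unrelated to the package's pruning code paths.

oracle_site_likelihood <- function(tip_states, tree, blens, model) {
  # tip_states: integer vector (1..20, NA = gap) in tree$tip.label order
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  edge <- tree$edge
  K <- model$n_categories
  internal <- (ntip + 1):nn
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(internal))))
  lik <- 0
  for (k in seq_len(K)) {
    P <- lapply(seq_len(nrow(edge)), function(e)
      prob_matrix(model, blens[e], model$rates[k]))
    for (g in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[internal] <- grid[g, ]
      st[seq_len(ntip)] <- tip_states
      pr <- model$pi[st[ntip + 1]]
      for (e in seq_len(nrow(edge))) {
        b <- st[edge[e, 2]]
        if (is.na(b)) next              # gap: sum_b P[a, b] = 1
        pr <- pr * P[[e]][st[edge[e, 1]], b]
      }
      lik <- lik + pr / K
    }
  }
  lik
}

oracle_loglik <- function(alignment, tree, blens, model) {
  states <- match(t(as.matrix(alignment)[tree$tip.label, , drop = FALSE]),
                  paraclock:::AA_CODES)
  states <- matrix(states, ncol = ape::Ntip(tree), byrow = FALSE)
  sum(vapply(seq_len(nrow(states)), function(s)
    log(oracle_site_likelihood(states[s, ], tree, blens, model)),
    numeric(1)))
}

# marginal posterior at `target` for one site, by enumeration
oracle_asr_site <- function(tip_states, tree, blens, model, target) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  edge <- tree$edge
  K <- model$n_categories
  internal <- (ntip + 1):nn
  grid <- as.matrix(do.call(expand.grid, rep(list(1:20), length(internal))))
  joint <- numeric(20)
  for (k in seq_len(K)) {
    P <- lapply(seq_len(nrow(edge)), function(e)
      prob_matrix(model, blens[e], model$rates[k]))
    for (g in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[internal] <- grid[g, ]
      st[seq_len(ntip)] <- tip_states
      pr <- model$pi[st[ntip + 1]]
      for (e in seq_len(nrow(edge))) {
        b <- st[edge[e, 2]]
        if (is.na(b)) next
        pr <- pr * P[[e]][st[edge[e, 1]], b]
      }
      joint[st[target]] <- joint[st[target]] + pr / K
    }
  }
  joint / sum(joint)
}

random_small_alignment <- function(tree, n_sites, gap_prob = 0.1) {
  ntip <- ape::Ntip(tree)
  chars <- c(paraclock:::AA_CODES, "-")
  probs <- c(rep((1 - gap_prob) / 20, 20), gap_prob)
  seqs <- vapply(seq_len(ntip), function(i)
    paste(sample(chars, n_sites, replace = TRUE, prob = probs), collapse = ""),
    character(1))
  aa_alignment(seqs, tree$tip.label)
}
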