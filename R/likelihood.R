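## R-side wrapper over the compiled pruning engine.

## Build a likelihood engine for a fixed topology/alignment/model. The
## returned environment holds the external pointer plus the bookkeeping
## needed to map branches to engine slots.
plk_engine <- function(alignment, topology, model) {
  if (!inherits(topology, "phylo")) stop("topology must be an ape::phylo tree")
  if (!ape::is.rooted(topology)) stop("topology must be rooted")
  missing_tips <- setdiff(topology$tip.label, alignment_ids(alignment))
  if (length(missing_tips) > 0)
    stop("leaf (leaves) without a sequence: ", paste(missing_tips, collapse = ", "))
  post <- ape::reorder.phylo(topology, "postorder")
  states <- encode_states(alignment)[topology$tip.label, , drop = FALSE]
  ptr <- plk_engine_new(post$edge, ape::Ntip(topology), states,
                        model[c("V", "Vinv", "lambda", "pi", "rates")])
  list(ptr = ptr, topology = topology, post_edge = post$edge,
       n_nodes = ape::Ntip(topology) + topology$Nnode,
       ntip = ape::Ntip(topology), model = model)
}

## branch lengths indexed by child node (vector length n_nodes, root slot
## ignored)
blens_by_child <- function(engine, edge, subs) {
  v <- numeric(engine$n_nodes)
  v[edge[, 2]] <- subs
  v
}

#' Felsenstein pruning log-likelihood
#'
#' Log-likelihood of an aligned set of amino-acid sequences on a rooted
#' topology with fixed branch lengths, under a [substitution_model] with
#' discrete-gamma rate categories. Gaps are treated as missing data (unit
#' partial vectors); the root state is integrated against the model's
#' equilibrium frequencies, and categories carry equal prior weight.
#'
#' @param alignment An [aa_alignment] containing every leaf of `topology`.
#' @param topology Rooted `ape::phylo`.
#' @param branch_subs Numeric vector of expected substitutions/site, one per
#'   row of `topology$edge` (all >= 0).
#' @param model A [substitution_model].
#' @param per_site If `TRUE`, also return the per-site log-likelihoods.
#' @return The total log-likelihood, or (with `per_site`) a list with
#'   `loglik` and `site_loglik`.
#' @export
pruning_loglik <- function(alignment, topology, branch_subs, model,
                           per_site = FALSE) {
  if (length(branch_subs) != nrow(topology$edge))
    stop("branch_subs must have one entry per edge")
  if (any(branch_subs < 0)) stop("branch lengths must be >= 0")
  eng <- plk_engine(alignment, topology, model)
  ll <- plk_set_blens(eng$ptr, blens_by_child(eng, topology$edge, branch_subs))
  if (!per_site) return(ll)
  list(loglik = ll, site_loglik = plk_site_loglik(eng$ptr))
}
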