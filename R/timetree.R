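## Time trees: a rooted ape::phylo topology annotated with absolute node
## ages (Ga before present) and per-branch substitution rates (amino-acid
## substitutions per site per Ga). Branch length in expected
## substitutions/site is always rate x duration.

#' Time-calibrated tree with branch rates
#'
#' @param phylo A rooted `ape::phylo` tree (topology only; edge lengths are
#'   ignored).
#' @param ages Numeric vector of node ages in Ga before present, indexed by
#'   ape node number (tips `1..n`, then internal nodes). Tips must be at age
#'   0; every parent must be strictly older than its children.
#' @param branch_rates Optional numeric vector of per-branch rates (delta
#'   per Ga), one per row of `phylo$edge`, all > 0.
#' @param node_labels Optional named integer vector mapping labels (e.g.
#'   `"dup"`, `"crown_A"`) to node numbers.
#' @param node_lograte Optional per-node log-rates (used by the
#'   autocorrelated rate process, where a branch's rate is the exponential
#'   of the mean of its endpoint log-rates).
#' @return Object of class `time_tree`.
#' @export
time_tree <- function(phylo, ages, branch_rates = NULL, node_labels = NULL,
                      node_lograte = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape::phylo tree")
  if (!ape::is.rooted(phylo)) stop("tree must be rooted")
  n_nodes <- ape::Ntip(phylo) + phylo$Nnode
  if (length(ages) != n_nodes)
    stop("ages must have one entry per node (", n_nodes, ")")
  ntip <- ape::Ntip(phylo)
  if (any(abs(ages[seq_len(ntip)]) > 1e-8))
    stop("all tips must be at age 0 (extant sampling)")
  ages[seq_len(ntip)] <- 0
  dur <- ages[phylo$edge[, 1]] - ages[phylo$edge[, 2]]
  if (any(dur <= 0))
    stop("every parent age must strictly exceed its child ages")
  if (!is.null(branch_rates)) {
    if (length(branch_rates) != nrow(phylo$edge))
      stop("branch_rates must have one entry per edge")
    if (any(branch_rates <= 0)) stop("branch rates must be > 0")
  }
  if (!is.null(node_labels)) {
    if (is.null(names(node_labels)) || any(!nzchar(names(node_labels))))
      stop("node_labels must be a named vector")
    if (any(node_labels < 1 | node_labels > n_nodes))
      stop("node_labels refer to nonexistent nodes")
  }
  structure(list(phylo = phylo, ages = unname(ages),
                 branch_rates = if (is.null(branch_rates)) NULL else unname(branch_rates),
                 node_labels = node_labels,
                 node_lograte = node_lograte),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat("Time tree:", ape::Ntip(x$phylo), "tips, root age",
      sprintf("%.4g Ga", root_age(x)),
      if (!is.null(x$branch_rates)) "(rates set)" else "(no rates)", "\n")
  if (!is.null(x$node_labels))
    cat("  labels:", paste(names(x$node_labels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname time_tree
#' @param x A `time_tree`.
#' @export
root_age <- function(x) x$ages[ape::Ntip(x$phylo) + 1L]

#' @rdname time_tree
#' @export
branch_durations <- function(x) x$ages[x$phylo$edge[, 1]] - x$ages[x$phylo$edge[, 2]]

#' Expected substitutions per site on each branch (rate x duration)
#' @param x A `time_tree` with branch rates set.
#' @export
branch_subs <- function(x) {
  if (is.null(x$branch_rates)) stop("branch rates are not set")
  x$branch_rates * branch_durations(x)
}

#' Branch midpoint ages
#' @param x A `time_tree`.
#' @return Per-edge (parent age + child age) / 2, in Ga.
#' @export
branch_midpoints <- function(x) {
  (x$ages[x$phylo$edge[, 1]] + x$ages[x$phylo$edge[, 2]]) / 2
}

#' MRCA node number of a set of tips
#' @param phylo An `ape::phylo` tree or `time_tree`.
#' @param tips Tip labels.
#' @export
mrca_node <- function(phylo, tips) {
  if (inherits(phylo, "time_tree")) phylo <- phylo$phylo
  missing_tips <- setdiff(tips, phylo$tip.label)
  if (length(missing_tips) > 0)
    stop("tip(s) not in tree: ", paste(missing_tips, collapse = ", "))
  if (length(tips) == 1L) return(match(tips, phylo$tip.label))
  ape::getMRCA(phylo, tips)
}

#' Convert to an ape::phylo with substitution branch lengths
#' @param x A `time_tree` with rates.
#' @param ... Ignored.
#' @return `phylo` with `edge.length` in expected substitutions/site.
#' @export
as.phylo.time_tree <- function(x, ...) {
  ph <- x$phylo
  ph$edge.length <- branch_subs(x)
  ph
}

#' Write a time tree to Newick plus a node/rate annotation table
#'
#' The Newick branch lengths are expected substitutions/site; the companion
#' tab-delimited table lists node number, label, age (Ga) and the rate of
#' the branch above each node (delta per Ga).
#'
#' @param x A `time_tree` with rates.
#' @param newick_path,table_path Output paths.
#' @export
write_timetree <- function(x, newick_path, table_path) {
  ape::write.tree(as.phylo.time_tree(x), file = newick_path)
  edge <- x$phylo$edge
  parent_rate <- rep(NA_real_, length(x$ages))
  parent_rate[edge[, 2]] <- x$branch_rates
  labels <- rep("", length(x$ages))
  if (!is.null(x$node_labels)) labels[x$node_labels] <- names(x$node_labels)
  ntip <- ape::Ntip(x$phylo)
  labels[seq_len(ntip)] <- x$phylo$tip.label
  df <- data.frame(node = seq_along(x$ages), label = labels,
                   age_Ga = x$ages, branch_rate = parent_rate)
  write.table(df, table_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
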