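## Marginal ancestral sequence reconstruction at a target node on a fixed
## rooted tree with fixed branch lengths (expected substitutions/site),
## with ML or Fitch-parsimony placement of indels and reference-coordinate
## site mapping.

## Inside (pruning) messages per non-root node: list over nodes of
## K-slice list of 20 x S matrices, scaled per site jointly across
## categories. Scale factors cancel in the site-normalised posteriors.
asr_messages <- function(states, post_edge, blens_by_node, ntip, model) {
  S <- ncol(states); K <- model$n_categories
  n_nodes <- max(post_edge)
  msg <- vector("list", n_nodes)
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(post_edge)))
    children[[post_edge[i, 1]]] <- c(children[[post_edge[i, 1]]], post_edge[i, 2])
  Ps <- vector("list", n_nodes)
  for (i in seq_len(nrow(post_edge))) {
    v <- post_edge[i, 2]
    t <- blens_by_node[v]
    Ps[[v]] <- lapply(seq_len(K), function(k) prob_matrix(model, t, model$rates[k]))
    if (v <= ntip) {
      msg[[v]] <- lapply(seq_len(K), function(k) {
        M <- matrix(1, 20, S)
        obs <- which(!is.na(states[v, ]))
        if (length(obs)) M[, obs] <- Ps[[v]][[k]][, states[v, obs]]
        M
      })
    } else {
      part <- node_partial_r(msg, children[[v]], K)
      msg[[v]] <- lapply(seq_len(K), function(k) Ps[[v]][[k]] %*% part[[k]])
    }
  }
  list(msg = msg, children = children, Ps = Ps)
}

node_partial_r <- function(msg, kids, K) {
  part <- msg[[kids[1]]]
  for (w in kids[-1]) for (k in seq_len(K)) part[[k]] <- part[[k]] * msg[[w]][[k]]
  ## joint per-site rescale across categories
  mx <- Reduce(pmax, lapply(part, function(m) apply(m, 2, max)))
  mx[mx <= 0] <- 1
  for (k in seq_len(K)) part[[k]] <- sweep(part[[k]], 2, mx, "/")
  part
}

#' Marginal ancestral reconstruction at a node
#'
#' Per-site posterior distributions over the 20 residues at `target_node`,
#' integrating over all other nodes' states and the discrete-gamma
#' categories (inside-outside passes of the pruning recursion). Gaps are
#' missing data for the residue process; whether the target carries a
#' residue at all is decided by the indel reconstruction (`indel_mode`).
#'
#' @param alignment An [aa_alignment].
#' @param tree Rooted `ape::phylo` with `edge.length` in expected
#'   substitutions/site.
#' @param model A [substitution_model].
#' @param target_node Internal node number (or a tip label set whose MRCA is
#'   taken).
#' @param indel_mode `"ml"` (2-state Markov presence/absence, threshold
#'   `cutoff`), `"parsimony"` (Fitch, ties to present), or `"none"` (all
#'   sites present).
#' @param cutoff Posterior-probability threshold for ML indel placement
#'   (default 0.7).
#' @param indel_scale Multiplier applied to the branch lengths for the
#'   indel process (default 1).
#' @return Object of class `ancestral_reconstruction`: `pp` (20 x sites
#'   posterior matrix), `map` (MAP residues, `NA` where masked), `present`
#'   (indel mask), `target_node`, `method`.
#' @export
marginal_asr <- function(alignment, tree, model, target_node,
                         indel_mode = c("ml", "parsimony", "none"),
                         cutoff = 0.7, indel_scale = 1) {
  indel_mode <- match.arg(indel_mode)
  if (is.null(tree$edge.length)) stop("tree must carry branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ntip <- ape::Ntip(tree)
  if (is.character(target_node)) target_node <- mrca_node(tree, target_node)
  if (target_node <= ntip) stop("target node is a leaf; choose an internal node")
  missing_tips <- setdiff(tree$tip.label, alignment_ids(alignment))
  if (length(missing_tips) > 0)
    stop("leaf (leaves) without a sequence: ", paste(missing_tips, collapse = ", "))

  states <- encode_states(alignment)[tree$tip.label, , drop = FALSE]
  S <- ncol(states); K <- model$n_categories
  post <- ape::reorder.phylo(tree, "postorder")
  blens <- numeric(ntip + tree$Nnode)
  blens[post$edge[, 2]] <- post$edge.length
  ins <- asr_messages(states, post$edge, blens, ntip, model)

  ## outside pass, root -> target only along the path, but computing all is
  ## simple and cheap: preorder over edges
  root <- ntip + 1L
  outside <- vector("list", ntip + tree$Nnode)
  outside[[root]] <- lapply(seq_len(K), function(k)
    matrix(model$pi, 20, S))
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    u <- pre[i, 1]; v <- pre[i, 2]
    if (v <= ntip) next
    sibs <- setdiff(ins$children[[u]], v)
    out_u <- outside[[u]]
    contrib <- lapply(seq_len(K), function(k) {
      m <- out_u[[k]]
      for (w in sibs) m <- m * ins$msg[[w]][[k]]
      crossprod(ins$Ps[[v]][[k]], m)   # t(P) %*% (outside * sib msgs)
    })
    mx <- Reduce(pmax, lapply(contrib, function(m) apply(m, 2, max)))
    mx[mx <= 0] <- 1
    outside[[v]] <- lapply(contrib, function(m) sweep(m, 2, mx, "/"))
  }

  inside_t <- if (target_node == root)
    node_partial_r(ins$msg, ins$children[[root]], K)
  else node_partial_r(ins$msg, ins$children[[target_node]], K)
  joint <- matrix(0, 20, S)
  for (k in seq_len(K)) joint <- joint + outside[[target_node]][[k]] * inside_t[[k]]
  pp <- sweep(joint, 2, colSums(joint), "/")
  rownames(pp) <- AA_CODES

  map <- apply(pp, 2, function(col) {
    cands <- which(col >= max(col) - 1e-12)
    AA_CODES[cands[order(AA_CODES[cands])][1]]
  })

  present <- switch(indel_mode,
    none = rep(TRUE, S),
    ml = reconstruct_indels(alignment, tree, target_node, "ml",
                            cutoff = cutoff, indel_scale = indel_scale),
    parsimony = reconstruct_indels(alignment, tree, target_node, "parsimony"))
  map[!present] <- NA_character_

  structure(list(target_node = target_node, pp = pp, map = map,
                 present = present,
                 method = paste0(model$matrix_id, "+G", model$n_categories,
                                 "/", indel_mode)),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Ancestral reconstruction at node", x$target_node,
      "(", x$method, "):", length(x$map), "sites,",
      sum(!x$present), "masked\n")
  cat(sprintf("  mean MAP posterior %.3f\n", mean(map_pp(x), na.rm = TRUE)))
  invisible(x)
}

#' MAP residue posterior probabilities per site
#' @param x An `ancestral_reconstruction`.
#' @return Numeric vector (NA at masked sites).
#' @export
map_pp <- function(x) {
  out <- apply(x$pp, 2, max)
  out[!x$present] <- NA_real_
  out
}

#' MAP sequence as a string (masked sites as gaps)
#' @param x An `ancestral_reconstruction`.
#' @export
map_sequence <- function(x) {
  s <- x$map
  s[is.na(s)] <- GAP_CHAR
  paste(s, collapse = "")
}

#' Reconstruct indel presence/absence at a node
#'
#' `"ml"`: each column's gap pattern evolves as a symmetric 2-state Markov
#' character (rate 1) on the tree's branch lengths scaled by `indel_scale`;
#' the target carries a residue iff the marginal posterior of "present" is
#' at least `cutoff`. `"parsimony"`: Fitch small parsimony on the
#' presence/absence character, ambiguities at the target resolved to
#' present.
#'
#' @inheritParams marginal_asr
#' @param mode `"ml"` or `"parsimony"`.
#' @return Logical vector, `TRUE` where the target has a residue.
#' @export
reconstruct_indels <- function(alignment, tree, target_node,
                               mode = c("ml", "parsimony"), cutoff = 0.7,
                               indel_scale = 1) {
  mode <- match.arg(mode)
  if (mode == "ml" && (cutoff <= 0 || cutoff > 1))
    stop("cutoff must be in (0, 1]")
  ntip <- ape::Ntip(tree)
  if (is.character(target_node)) target_node <- mrca_node(tree, target_node)
  present_tip <- alignment$mat[tree$tip.label, , drop = FALSE] != GAP_CHAR
  S <- ncol(present_tip)
  n_nodes <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")

  if (mode == "parsimony") {
    ## Fitch downpass: state sets coded 1 = {absent}, 2 = {present},
    ## 3 = {absent, present}
    down <- matrix(0L, n_nodes, S)
    down[seq_len(ntip), ] <- ifelse(present_tip, 2L, 1L)
    for (i in seq_len(nrow(post$edge))) {
      u <- post$edge[i, 1]
      if (down[u, 1] != 0L) next
      kids <- post$edge[post$edge[, 1] == u, 2]
      inter <- rep(3L, S); uni <- rep(0L, S)
      first <- TRUE
      for (v in kids) {
        if (first) { inter <- down[v, ]; uni <- down[v, ]; first <- FALSE }
        else {
          inter <- bitwAnd(inter, down[v, ])
          uni <- bitwOr(uni, down[v, ])
        }
      }
      down[u, ] <- ifelse(inter != 0L, inter, uni)
    }
    ## uppass to the target: root final = downpass set (tie -> present)
    final <- matrix(0L, n_nodes, S)
    root <- ntip + 1L
    final[root, ] <- ifelse(down[root, ] == 3L, 2L, down[root, ])
    pre <- ape::reorder.phylo(tree, "cladewise")$edge
    for (i in seq_len(nrow(pre))) {
      u <- pre[i, 1]; v <- pre[i, 2]
      if (v <= ntip) next
      keep <- bitwAnd(down[v, ], final[u, ])
      amb <- ifelse(down[v, ] == 3L, 2L, down[v, ])  # tie -> present
      final[v, ] <- ifelse(keep != 0L, keep, amb)
    }
    return(final[target_node, ] == 2L)
  }

  ## ML mode: symmetric 2-state chain, P(stay) = (1 + exp(-2t)) / 2
  blens <- numeric(n_nodes)
  blens[post$edge[, 2]] <- post$edge.length * indel_scale
  msg <- array(1, dim = c(2, S, n_nodes))
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(post$edge)))
    children[[post$edge[i, 1]]] <- c(children[[post$edge[i, 1]]], post$edge[i, 2])
  P2 <- function(t) {
    stay <- (1 + exp(-2 * t)) / 2
    matrix(c(stay, 1 - stay, 1 - stay, stay), 2, 2)
  }
  for (i in seq_len(nrow(post$edge))) {
    v <- post$edge[i, 2]
    P <- P2(blens[v])
    inside <- if (v <= ntip) {
      rbind(as.numeric(!present_tip[v, ]), as.numeric(present_tip[v, ]))
    } else {
      part <- matrix(1, 2, S)
      for (w in children[[v]]) part <- part * msg[, , w]
      part
    }
    msg[, , v] <- P %*% inside
  }
  root <- ntip + 1L
  outside <- array(0.5, dim = c(2, S, n_nodes))
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    u <- pre[i, 1]; v <- pre[i, 2]
    if (v <= ntip) next
    m <- outside[, , u]
    for (w in setdiff(children[[u]], v)) m <- m * msg[, , w]
    outside[, , v] <- crossprod(P2(blens[v]), m)
  }
  inside_t <- matrix(1, 2, S)
  for (w in children[[target_node]]) inside_t <- inside_t * msg[, , w]
  joint <- outside[, , target_node] * inside_t
  pp_present <- joint[2, ] / colSums(joint)
  pp_present >= cutoff
}

#' Map a reference residue position to an alignment column
#'
#' @param alignment An [aa_alignment].
#' @param reference_id Identifier of the reference row.
#' @param reference_position 1-based position in the ungapped reference
#'   sequence.
#' @return 1-based alignment column index.
#' @export
map_reference_site <- function(alignment, reference_id, reference_position) {
  if (!reference_id %in% alignment_ids(alignment))
    stop("reference id not in alignment: ", reference_id)
  row <- alignment$mat[reference_id, ]
  ungapped <- which(row != GAP_CHAR)
  if (reference_position < 1 || reference_position > length(ungapped))
    stop("reference position ", reference_position,
         " outside the ungapped reference (length ", length(ungapped), ")")
  ungapped[reference_position]
}

#' Inverse of [map_reference_site()]
#'
#' @inheritParams map_reference_site
#' @param column 1-based alignment column.
#' @return List `residue` (the reference residue, or `"-"`) and `position`
#'   (1-based ungapped position, `NA` if the reference is gapped there).
#' @export
map_alignment_column <- function(alignment, reference_id, column) {
  row <- alignment$mat[reference_id, ]
  if (column < 1 || column > length(row)) stop("column out of range")
  if (row[column] == GAP_CHAR) return(list(residue = GAP_CHAR, position = NA_integer_))
  list(residue = row[column],
       position = sum(row[seq_len(column)] != GAP_CHAR))
}

#' Agreement between reconstructions
#'
#' Mean and SD of pairwise identity between the MAP sequences of several
#' reconstructions on the same column space (identity is computed on
#' mutually unmasked sites), optionally each against a designated reference
#' sequence, plus per-site posterior-probability summaries.
#'
#' @param reconstructions List of `ancestral_reconstruction` objects (>= 2,
#'   or 1 when `reference` is given).
#' @param reference Optional reference: an aligned sequence string of the
#'   same length.
#' @return List `mean_identity`, `sd_identity`, `pair_identities`,
#'   `reference_identities` (or NULL), `mean_map_pp` per reconstruction.
#' @export
compare_reconstructions <- function(reconstructions, reference = NULL) {
  if (inherits(reconstructions, "ancestral_reconstruction"))
    reconstructions <- list(reconstructions)
  S <- unique(vapply(reconstructions, function(r) length(r$map), integer(1)))
  if (length(S) != 1)
    stop("reconstructions are not on the same column space")
  if (length(reconstructions) < 2 && is.null(reference))
    stop("need at least 2 reconstructions, or 1 plus a reference")
  seqs <- vapply(reconstructions, map_sequence, character(1))
  pair_id <- NULL
  mean_id <- NA_real_; sd_id <- NA_real_
  if (length(seqs) >= 2) {
    pairs <- utils::combn(length(seqs), 2)
    pair_id <- apply(pairs, 2, function(pr)
      pairwise_identity(seqs[pr[1]], seqs[pr[2]]))
    mean_id <- mean(pair_id); sd_id <- if (length(pair_id) > 1) sd(pair_id) else 0
  }
  ref_id <- NULL
  if (!is.null(reference)) {
    if (nchar(reference) != S) stop("reference length mismatch")
    ref_id <- vapply(seqs, pairwise_identity, numeric(1), seq_b = reference)
  }
  list(mean_identity = mean_id, sd_identity = sd_id,
       pair_identities = pair_id, reference_identities = ref_id,
       mean_map_pp = vapply(reconstructions, function(r)
         mean(map_pp(r), na.rm = TRUE), numeric(1)))
}

#' Write a per-site reconstruction table
#'
#' Tab-delimited: column, reference residue/position (if a reference id is
#' given), MAP residue, top-3 posterior probabilities, indel state.
#'
#' @param rec An `ancestral_reconstruction`.
#' @param path Output path.
#' @param alignment Optional [aa_alignment] for reference mapping.
#' @param reference_id Optional reference row id.
#' @export
write_asr_table <- function(rec, path, alignment = NULL, reference_id = NULL) {
  S <- length(rec$map)
  top3 <- apply(rec$pp, 2, function(col) {
    o <- order(-col)[1:3]
    paste(sprintf("%s:%.3f", AA_CODES[o], col[o]), collapse = ",")
  })
  df <- data.frame(column = seq_len(S),
                   map_residue = ifelse(is.na(rec$map), GAP_CHAR, rec$map),
                   top3_pp = top3,
                   present = rec$present)
  if (!is.null(alignment) && !is.null(reference_id)) {
    refinfo <- lapply(seq_len(S), function(j)
      map_alignment_column(alignment, reference_id, j))
    df$ref_residue <- vapply(refinfo, `[[`, character(1), "residue")
    df$ref_position <- vapply(refinfo, function(r)
      if (is.na(r$position)) NA_integer_ else as.integer(r$position), integer(1))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
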