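## Pairwise and within-group corrected amino-acid distances with bootstrap
## uncertainty. Gap handling is pairwise deletion throughout: a column is
## compared only when neither member is a gap.

split_chars <- function(s) {
  if (length(s) == 1L && is.character(s)) strsplit(toupper(s), "", fixed = TRUE)[[1]]
  else as.character(s)
}

#' Pairwise sequence identity
#'
#' Identity = matches / comparable columns, where a column is comparable iff
#' neither sequence has a gap there.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (strings or character
#'   vectors).
#' @return Fraction in \[0, 1\].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  a <- split_chars(seq_a); b <- split_chars(seq_b)
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  comparable <- a != GAP_CHAR & b != GAP_CHAR
  if (!any(comparable))
    stop("identity undefined: no comparable (gap-free) columns")
  sum(a[comparable] == b[comparable]) / sum(comparable)
}

#' Observed proportion of differences (p-distance)
#'
#' @inheritParams pairwise_identity
#' @return List with `p` (mismatches / comparable columns) and
#'   `n_comparable`.
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- split_chars(seq_a); b <- split_chars(seq_b)
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  comparable <- a != GAP_CHAR & b != GAP_CHAR
  n <- sum(comparable)
  if (n == 0L) stop("p-distance undefined: no comparable columns")
  list(p = sum(a[comparable] != b[comparable]) / n, n_comparable = n)
}

#' Correct an observed distance for multiple hits
#'
#' Poisson correction `d = -log(1 - p)`; gamma-Poisson correction
#' `d = alpha * ((1 - p)^(-1/alpha) - 1)`, which tends to the Poisson form
#' as `alpha` grows.
#'
#' @param p Observed proportion(s) of differences, `0 <= p < 1`.
#' @param model `"poisson"` or `"gamma"`.
#' @param alpha Gamma shape parameter (default 1).
#' @return Corrected distance(s) in substitutions/site.
#' @export
correct_distance <- function(p, model = c("poisson", "gamma"), alpha = 1) {
  model <- match.arg(tolower(model[1]), c("poisson", "gamma"))
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1)) stop("p >= 1: corrected distance is infinite")
  if (model == "poisson") -log(1 - p)
  else {
    if (alpha <= 0) stop("alpha must be > 0")
    alpha * ((1 - p)^(-1 / alpha) - 1)
  }
}

## Observed-difference closed form of the 20-state equal-rates chain:
## p(d) = (19/20) (1 - exp(-(20/19) d)). Used by tests and as the POISSON
## sanity limit of the ML distance.
p_from_d_poisson20 <- function(d) (19 / 20) * (1 - exp(-(20 / 19) * d))
d_from_p_poisson20 <- function(p) -(19 / 20) * log(1 - (20 / 19) * p)

#' Maximum-likelihood pairwise distance
#'
#' One-dimensional ML distance under a [substitution_model] (+ discrete
#' gamma): maximises the sum over comparable sites of
#' `log sum_k (1/K) pi_a P(a -> b | d r_k)` by bounded search on \[0, 20\].
#'
#' @inheritParams pairwise_identity
#' @param model A [substitution_model].
#' @param max_distance Upper search bound (substitutions/site), default 20.
#' @return List with `distance` and `loglik`.
#' @export
ml_pairwise_distance <- function(seq_a, seq_b, model, max_distance = 20) {
  a <- split_chars(seq_a); b <- split_chars(seq_b)
  if (length(a) != length(b)) stop("sequences must be aligned (equal length)")
  comparable <- a != GAP_CHAR & b != GAP_CHAR
  if (!any(comparable)) stop("no comparable columns")
  ia <- match(a[comparable], AA_CODES)
  ib <- match(b[comparable], AA_CODES)
  N <- matrix(0, 20, 20)
  for (k in seq_along(ia)) N[ia[k], ib[k]] <- N[ia[k], ib[k]] + 1
  nz <- which(N > 0, arr.ind = TRUE)
  w <- N[nz]
  K <- model$n_categories
  loglik_at <- function(d) {
    M <- matrix(0, nrow(nz), 1)
    pr <- 0
    for (k in seq_len(K)) {
      P <- prob_matrix(model, d, model$rates[k])
      pr <- pr + (model$pi[nz[, 1]] * P[nz]) / K
    }
    sum(w * log(pr))
  }
  if (all(ia == ib)) {
    return(list(distance = 0, loglik = loglik_at(0)))
  }
  opt <- optimize(loglik_at, interval = c(1e-8, max_distance),
                  maximum = TRUE, tol = 1e-8)
  list(distance = opt$maximum, loglik = opt$objective)
}

#' Within-group mean distance with bootstrap standard error
#'
#' Mean over all unordered pairs of a group's corrected distances, with the
#' SE taken as the standard deviation of that mean over site-resampled
#' bootstrap replicates (columns resampled with replacement).
#'
#' @param alignment An [aa_alignment].
#' @param member_ids Identifiers of the group members (>= 2).
#' @param model `"differences"` (raw count), `"p"`, `"poisson"`, `"gamma"`,
#'   or `"ml"`.
#' @param alpha Gamma shape for `"gamma"` correction (default 1).
#' @param n_bootstrap Number of bootstrap replicates (default 500).
#' @param seed Seed for the bootstrap resampling.
#' @param subst_model [substitution_model] used when `model = "ml"`
#'   (default JTT with `gamma_shape = alpha`).
#' @return Object of class `group_distance`: `mean`, `se`, `n_pairs`,
#'   `model`, `alpha`, `n_bootstrap`.
#' @export
within_group_mean <- function(alignment, member_ids,
                              model = c("poisson", "differences", "p", "gamma", "ml"),
                              alpha = 1, n_bootstrap = 500, seed = NULL,
                              subst_model = NULL) {
  model <- match.arg(tolower(model[1]),
                     c("poisson", "differences", "p", "gamma", "ml"))
  ids <- alignment_ids(alignment)
  missing_ids <- setdiff(member_ids, ids)
  if (length(missing_ids) > 0)
    stop("member id(s) not in alignment: ", paste(missing_ids, collapse = ", "))
  if (length(member_ids) < 2) stop("a group needs at least 2 members")
  if (model == "ml" && is.null(subst_model))
    subst_model <- substitution_model("JTT", gamma_shape = alpha)

  sub <- alignment$mat[member_ids, , drop = FALSE]
  k <- nrow(sub)
  pair_idx <- utils::combn(k, 2)

  mean_dist <- function(mat) {
    d <- apply(pair_idx, 2, function(pr) {
      a <- mat[pr[1], ]; b <- mat[pr[2], ]
      comparable <- a != GAP_CHAR & b != GAP_CHAR
      n <- sum(comparable)
      if (n == 0L) return(NA_real_)
      if (model == "ml") {
        return(ml_pairwise_distance(a, b, subst_model)$distance)
      }
      diffs <- sum(a[comparable] != b[comparable])
      if (diffs == n && model %in% c("poisson", "gamma"))
        return(NA_real_)   # saturated pair: correction undefined, dropped
      switch(model,
             differences = diffs,
             p = diffs / n,
             poisson = correct_distance(diffs / n, "poisson"),
             gamma = correct_distance(diffs / n, "gamma", alpha))
    })
    mean(d, na.rm = TRUE)
  }

  m <- mean_dist(sub)
  se <- NA_real_
  if (n_bootstrap > 0) {
    L <- ncol(sub)
    boots <- with_seed(seed, vapply(seq_len(n_bootstrap), function(i) {
      cols <- sample.int(L, L, replace = TRUE)
      mean_dist(sub[, cols, drop = FALSE])
    }, numeric(1)))
    se <- sd(boots, na.rm = TRUE)
  }
  structure(list(mean = m, se = se, n_pairs = ncol(pair_idx),
                 model = model, alpha = alpha, n_bootstrap = n_bootstrap,
                 member_ids = member_ids),
            class = "group_distance")
}

#' @export
print.group_distance <- function(x, ...) {
  cat(sprintf("Within-group mean distance (%s%s): %.4f +/- %.4f (%d pairs, %d bootstraps)\n",
              x$model, if (x$model == "gamma") sprintf(", alpha=%g", x$alpha) else "",
              x$mean, x$se, x$n_pairs, x$n_bootstrap))
  invisible(x)
}

#' Write a table of group-distance results
#' @param results List of `group_distance` objects, named by group.
#' @param path Output path (tab-delimited).
#' @export
write_group_distances <- function(results, path) {
  df <- do.call(rbind, lapply(names(results), function(g) {
    r <- results[[g]]
    data.frame(group = g, model = r$model, alpha = r$alpha,
               mean = r$mean, se = r$se, n_pairs = r$n_pairs)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
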