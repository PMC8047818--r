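## Empirical amino-acid substitution models with discrete-gamma rate
## heterogeneity. The rate matrix Q is normalised to one expected
## substitution per site per unit branch length at equilibrium, so branch
## lengths are always in expected substitutions/site.

#' Amino-acid substitution model
#'
#' Builds a reversible 20-state rate matrix from an empirical exchangeability
#' set (or the equal-rates Poisson model), equilibrium frequencies, and a
#' discrete-gamma model of among-site rate variation (mean-category
#' discretisation, 4 categories by default).
#'
#' @param matrix_id One of `"POISSON"`, `"JTT"`, `"WAG"`, `"LG"`.
#' @param frequencies `"model"` (the matrix's own frequencies; uniform for
#'   POISSON), `"uniform"`, `"empirical"` (observed frequencies of
#'   `alignment`), or a numeric vector of 20 frequencies in `AA_CODES` order.
#' @param gamma_shape Shape parameter alpha of the gamma distribution of
#'   site rates (> 0). Ignored when `n_categories = 1`.
#' @param n_categories Number of discrete gamma categories (default 4).
#' @param alignment Optional [aa_alignment], required when
#'   `frequencies = "empirical"`.
#' @return An object of class `substitution_model` containing the scaled rate
#'   matrix `Q`, frequencies `pi`, its symmetric eigendecomposition (`V`,
#'   `Vinv`, `lambda`), and category rates `rates` (mean 1).
#' @examples
#' m <- substitution_model("LG", gamma_shape = 1)
#' rowSums(m$Q)  # ~0: proper rate matrix
#' @export
substitution_model <- function(matrix_id = c("POISSON", "JTT", "WAG", "LG"),
                               frequencies = "model",
                               gamma_shape = 1,
                               n_categories = 4,
                               alignment = NULL) {
  matrix_id <- match.arg(toupper(matrix_id[1]), c("POISSON", "JTT", "WAG", "LG"))
  if (!is.numeric(gamma_shape) || gamma_shape <= 0)
    stop("gamma_shape must be > 0")
  n_categories <- as.integer(n_categories)
  if (n_categories < 1) stop("n_categories must be >= 1")

  ex <- exchangeabilities(matrix_id)
  pi <- resolve_frequencies(frequencies, matrix_id, alignment)
  if (any(pi < 0)) stop("negative equilibrium frequency")
  if (abs(sum(pi) - 1) > 1e-9) stop("frequencies must sum to 1")

  Q <- ex * rep(pi, each = 20)          # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))              # expected rate at equilibrium
  Q <- Q / mu

  ## Reversible Q: symmetrise with D^(1/2) Q D^(-1/2) for a stable real
  ## eigendecomposition.
  d <- sqrt(pi)
  B <- (d %o% (1 / d)) * Q
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- (1 / d) * eig$vectors            # rows scaled
  Vinv <- t(eig$vectors) * rep(d, each = 20)

  rates <- if (n_categories == 1L) 1 else
    phangorn::discrete.gamma(gamma_shape, n_categories)

  structure(list(matrix_id = matrix_id, pi = pi, Q = Q,
                 V = V, Vinv = Vinv, lambda = eig$values,
                 gamma_shape = gamma_shape, n_categories = n_categories,
                 rates = rates),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat("Substitution model:", x$matrix_id,
      sprintf("+G(%g) x %d categories\n", x$gamma_shape, x$n_categories))
  invisible(x)
}

## Symmetric exchangeability matrix (diag 0). Empirical sets are taken from
## phangorn's bundled model data; row/column order matches AA_CODES.
exchangeabilities <- function(matrix_id) {
  if (matrix_id == "POISSON") {
    ex <- matrix(1, 20, 20); diag(ex) <- 0
    return(ex)
  }
  obj <- get(paste0(".", matrix_id), envir = asNamespace("phangorn"))
  ex <- matrix(0, 20, 20)
  ex[lower.tri(ex)] <- obj$Q
  ex <- ex + t(ex)
  dimnames(ex) <- list(AA_CODES, AA_CODES)
  ex
}

model_frequencies <- function(matrix_id) {
  if (matrix_id == "POISSON") return(rep(1 / 20, 20))
  bf <- get(paste0(".", matrix_id), envir = asNamespace("phangorn"))$bf
  unname(bf / sum(bf))
}

resolve_frequencies <- function(frequencies, matrix_id, alignment) {
  if (is.numeric(frequencies)) {
    if (length(frequencies) != 20L) stop("frequencies must have length 20")
    return(frequencies / sum(frequencies))
  }
  switch(match.arg(frequencies, c("model", "uniform", "empirical")),
    model = model_frequencies(matrix_id),
    uniform = rep(1 / 20, 20),
    empirical = {
      if (is.null(alignment))
        stop("frequencies = \"empirical\" requires an alignment")
      counts <- table(factor(alignment$mat[alignment$mat != GAP_CHAR],
                             levels = AA_CODES))
      f <- as.numeric(counts) + 1e-6   # floor so Q stays irreducible
      f / sum(f)
    })
}

#' Transition probability matrix
#'
#' @param model A [substitution_model].
#' @param t Branch length in expected substitutions/site.
#' @param rate Site-rate multiplier (e.g. a gamma category rate).
#' @return 20 x 20 stochastic matrix P(t * rate), rows = ancestral state.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  if (t < 0) stop("branch length must be >= 0")
  P <- model$V %*% (exp(model$lambda * t * rate) * model$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

## Integer-encode an alignment for the likelihood kernels: states 1..20 in
## AA_CODES order, NA for gap/missing. Rows = sequences.
encode_states <- function(alignment) {
  m <- match(alignment$mat, AA_CODES)
  dim(m) <- dim(alignment$mat)
  rownames(m) <- rownames(alignment$mat)
  m
}
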