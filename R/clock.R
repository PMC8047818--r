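## Bayesian relaxed molecular clock on a fixed rooted topology.
##
## Metropolis-within-Gibbs over node ages, node log-rates (autocorrelated
## lognormal kind) or branch rates (uncorrelated gamma kind), the log-rate
## diffusion variance sigma2, and the discrete-gamma shape. Branch lengths
## fed to the pruning engine are always rate x duration; under the
## autocorrelated kind a branch's rate is exp of the mean of its endpoint
## log-rates, matching the package's forward simulator.

#' Relaxed-clock sampler settings
#'
#' @param substitution_model A [substitution_model] (default LG + G4).
#' @param rate_model `"autocorrelated"` (lognormal Brownian log-rates) or
#'   `"uncorrelated"` (i.i.d. gamma branch rates).
#' @param age_prior `"uniform"` (uniform-on-ages given the root; default) or
#'   `"birth_death"` with `bd_params`.
#' @param bd_params List with `lambda`, `mu`, `rho` for the birth-death
#'   kernel.
#' @param n_chains Number of independent chains (default 4; at least 2 are
#'   needed for split-Rhat diagnostics).
#' @param n_iterations Sweeps per chain (default 20000).
#' @param burnin Fraction of sweeps discarded (default 0.25).
#' @param thin Keep every `thin`-th sweep after burn-in (default 10).
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param prior_only If `TRUE`, the likelihood is disabled (prior sampling).
#' @param sample_gamma_shape Sample the discrete-gamma shape (default TRUE;
#'   ignored when the model has one category or `prior_only`).
#' @param alpha_every Attempt the (costly, full-recompute) gamma-shape move
#'   every this many sweeps (default 2).
#' @param root_rate_prior List `meanlog`, `sdlog`: lognormal prior of the
#'   rate at the root (delta per Ga).
#' @param sigma2_prior List `shape`, `rate`: gamma prior of sigma2.
#' @param alpha_prior List `shape`, `rate`: gamma prior of the gamma shape.
#' @param uncorrelated List `shape`, `scale`: fixed hyperparameters of the
#'   uncorrelated-gamma rate prior.
#' @param tuning Proposal step sizes: `rate_sd` (log-rate random walk),
#'   `root_window` (root-age slide, Ga), `sigma2_step`, `alpha_step`
#'   (log-multiplier half-widths), `scale_step` (whole-tree age scaling).
#' @return Object of class `clock_settings`.
#' @export
clock_settings <- function(substitution_model = NULL,
                           rate_model = c("autocorrelated", "uncorrelated"),
                           age_prior = c("uniform", "birth_death"),
                           bd_params = list(lambda = 1, mu = 0.5, rho = 0.1),
                           n_chains = 4, n_iterations = 20000,
                           burnin = 0.25, thin = 10, seed = 1,
                           prior_only = FALSE,
                           sample_gamma_shape = TRUE, alpha_every = 2,
                           root_rate_prior = list(meanlog = 0, sdlog = 2),
                           sigma2_prior = list(shape = 2, rate = 0.5),
                           alpha_prior = list(shape = 2, rate = 1),
                           uncorrelated = list(shape = 2, scale = 0.5),
                           tuning = list()) {
  rate_model <- match.arg(rate_model)
  age_prior <- match.arg(age_prior)
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (n_chains < 2)
    warning("fewer than 2 chains: split-Rhat diagnostics unavailable")
  if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
  if (thin < 1) stop("thin must be >= 1")
  if (n_iterations < 2) stop("n_iterations must be >= 2")
  tun <- utils::modifyList(list(rate_sd = 0.4, root_window = 0.4,
                                sigma2_step = 0.8, alpha_step = 0.5,
                                scale_step = 0.06), tuning)
  structure(list(substitution_model = substitution_model,
                 rate_model = rate_model, age_prior = age_prior,
                 bd_params = bd_params, n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations), burnin = burnin,
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_only = isTRUE(prior_only),
                 sample_gamma_shape = isTRUE(sample_gamma_shape),
                 alpha_every = as.integer(alpha_every),
                 root_rate_prior = root_rate_prior,
                 sigma2_prior = sigma2_prior, alpha_prior = alpha_prior,
                 uncorrelated = uncorrelated, tuning = tun),
            class = "clock_settings")
}

## Birth-death node-age kernel density (conditional on the root age t1),
## after the standard birth-death-sampling construction. Integrates to 1
## over (0, t1).
bd_kernel_density <- function(t, t1, lambda, mu, rho) {
  if (lambda <= 0 || rho <= 0 || rho > 1 || mu < 0) stop("invalid birth-death parameters")
  if (abs(lambda - mu) < 1e-12) {
    (1 + rho * lambda * t1) / (t1 * (1 + rho * lambda * t)^2)
  } else {
    a <- lambda - mu
    P0 <- function(s) rho * a / (rho * lambda + (lambda * (1 - rho) - mu) * exp(-a * s))
    vt1 <- 1 - P0(t1) * exp(-a * t1) / rho
    lambda * P0(t)^2 * exp(-a * t) / (rho * vt1)
  }
}

## ---- internal: prior evaluation -------------------------------------------

## Joint log prior of ages: calibration densities at calibrated nodes plus
## the uniform-on-ages term 1/root^(n_int - 1) (or the birth-death kernel
## for non-root internal nodes).
age_logprior <- function(ages, cal_nodes, cal_list, root, internal, settings) {
  lp <- 0
  for (i in seq_along(cal_nodes))
    lp <- lp + calibration_logprior(ages[cal_nodes[i]], cal_list[[i]])
  if (!is.finite(lp)) return(-Inf)
  others <- setdiff(internal, root)
  if (settings$age_prior == "uniform") {
    lp <- lp - length(others) * log(ages[root])
  } else {
    bd <- settings$bd_params
    g <- bd_kernel_density(ages[others], ages[root], bd$lambda, bd$mu, bd$rho)
    if (any(g <= 0)) return(-Inf)
    lp <- lp + sum(log(g))
  }
  lp
}

## Rate-model log prior. Autocorrelated: Brownian increments of node
## log-rates over branch durations plus the root log-rate prior and the
## sigma2 hyperprior. Uncorrelated: i.i.d. gamma branch rates.
rate_logprior_state <- function(state, dat, settings) {
  if (settings$rate_model == "autocorrelated") {
    dt <- state$ages[dat$edge[, 1]] - state$ages[dat$edge[, 2]]
    if (any(dt <= 0)) return(-Inf)
    rp <- settings$root_rate_prior
    lp <- dnorm(state$lr[dat$root], rp$meanlog, rp$sdlog, log = TRUE)
    lp <- lp + sum(dnorm(state$lr[dat$edge[, 2]], state$lr[dat$edge[, 1]],
                         sqrt(state$sigma2 * dt), log = TRUE))
    sp <- settings$sigma2_prior
    lp + dgamma(state$sigma2, shape = sp$shape, rate = sp$rate, log = TRUE)
  } else {
    up <- settings$uncorrelated
    sum(dgamma(state$rates, shape = up$shape, scale = up$scale, log = TRUE))
  }
}

alpha_logprior <- function(alpha, settings) {
  ap <- settings$alpha_prior
  dgamma(alpha, shape = ap$shape, rate = ap$rate, log = TRUE)
}

total_logprior <- function(state, dat, settings) {
  lp <- age_logprior(state$ages, dat$cal_nodes, dat$cal_list, dat$root,
                     dat$internal, settings)
  if (!is.finite(lp)) return(-Inf)
  lp <- lp + rate_logprior_state(state, dat, settings)
  if (!is.finite(lp)) return(-Inf)
  if (settings$sample_gamma_shape && !settings$prior_only)
    lp <- lp + alpha_logprior(state$alpha, settings)
  lp
}

## Expected substitutions/site for a subset of edges (indexed by rows of
## dat$edge).
edge_subs <- function(state, dat, idx, settings) {
  dt <- state$ages[dat$edge[idx, 1]] - state$ages[dat$edge[idx, 2]]
  r <- if (settings$rate_model == "autocorrelated")
    exp((state$lr[dat$edge[idx, 1]] + state$lr[dat$edge[idx, 2]]) / 2)
  else state$rates[idx]
  r * dt
}

#' Log prior density of a rate-annotated time tree
#'
#' Evaluates the rate-model prior on a [time_tree]: under the
#' autocorrelated kind, the Brownian-increment density of the node
#' log-rates over the branch durations (a branch's rate being exp of the
#' mean of its endpoint log-rates, as everywhere in the package); under
#' the uncorrelated kind, the i.i.d. gamma density of the branch rates.
#'
#' @param tree A [time_tree] with rates set (for the autocorrelated kind
#'   it must carry `node_lograte`, as produced by
#'   [simulate_branch_rates()]).
#' @param process A [rate_process]; its `sigma2` (autocorrelated) or
#'   `shape`/`scale` (uncorrelated) parameterise the density.
#' @return Log density (the hyperprior terms of the full sampler are not
#'   included).
#' @export
rate_logprior <- function(tree, process) {
  stopifnot(inherits(tree, "time_tree"), inherits(process, "rate_process"))
  edge <- tree$phylo$edge
  dt <- branch_durations(tree)
  if (process$kind == "autocorrelated") {
    lr <- tree$node_lograte
    if (is.null(lr)) stop("tree carries no node log-rates")
    if (process$sigma2 <= 0) {
      dev <- abs(lr[edge[, 2]] - lr[edge[, 1]])
      return(if (all(dev < 1e-12)) 0 else -Inf)
    }
    sum(dnorm(lr[edge[, 2]], lr[edge[, 1]],
              sqrt(process$sigma2 * dt), log = TRUE))
  } else {
    if (is.null(tree$branch_rates)) stop("tree carries no branch rates")
    sum(dgamma(tree$branch_rates, shape = process$shape,
               scale = process$scale, log = TRUE))
  }
}

## ---- internal: initialisation ---------------------------------------------

init_state <- function(dat, settings, lr0 = NULL) {
  root_cal_i <- which(dat$cal_nodes == dat$root)
  if (length(root_cal_i) == 0)
    stop("a root calibration is required (the age prior is conditioned on ",
         "a proper root age)")
  rc <- dat$cal_list[[root_cal_i[1]]]
  lo <- if (!is.na(rc$min_age)) rc$min_age else 0.5 * rc$max_age
  hi <- if (!is.na(rc$max_age)) rc$max_age else rc$core_cap
  for (try in 1:200) {
    ages <- numeric(dat$n_nodes)
    ages[dat$root] <- runif(1, lo + 0.05 * (hi - lo), hi - 0.05 * (hi - lo))
    ok <- TRUE
    for (v in dat$preorder_internal) {         # parents before children
      if (v == dat$root) next
      vlo <- 0; vhi <- ages[dat$parent[v]]
      ci <- which(dat$cal_nodes == v)
      if (length(ci) > 0) {
        cal <- dat$cal_list[[ci[1]]]
        if (cal$bounds == "hard") {
          if (!is.na(cal$min_age)) vlo <- max(vlo, cal$min_age)
          if (!is.na(cal$max_age)) vhi <- min(vhi, cal$max_age)
        } else {
          if (!is.na(cal$min_age)) vlo <- max(vlo, 0.8 * cal$min_age)
          if (!is.na(cal$max_age)) vhi <- min(vhi, cal$max_age)
        }
      }
      if (vlo >= vhi) { ok <- FALSE; break }
      ages[v] <- runif(1, vlo + 0.05 * (vhi - vlo), vhi - 0.05 * (vhi - vlo))
    }
    if (!ok) next
    state <- list(ages = ages, sigma2 = NA_real_,
                  alpha = settings$substitution_model$gamma_shape %||% 1)
    if (settings$rate_model == "autocorrelated") {
      state$lr <- rnorm(dat$n_nodes, lr0 %||% settings$root_rate_prior$meanlog, 0.1)
      state$sigma2 <- settings$sigma2_prior$shape / settings$sigma2_prior$rate
    } else {
      up <- settings$uncorrelated
      state$rates <- pmax(rgamma(nrow(dat$edge), up$shape, scale = up$scale), 1e-8)
    }
    if (is.finite(total_logprior(state, dat, settings))) return(state)
  }
  stop("could not find a feasible starting state: the calibrations appear ",
       "to be non-overlapping (empty prior support)")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- the sampler -----------------------------------------------------------

run_chain <- function(dat, settings, chain_seed, alignment) {
  with_seed(chain_seed, {
    use_lik <- !settings$prior_only
    autoc <- settings$rate_model == "autocorrelated"
    tun <- settings$tuning
    edge <- dat$edge
    edge_p <- edge[, 1]; edge_c <- edge[, 2]
    n_edge <- nrow(edge)
    n_int <- length(dat$internal)
    ## per-node incident edge indices and the child-node keys of those edges
    inc <- lapply(seq_len(dat$n_nodes), function(v)
      which(edge_p == v | edge_c == v))
    cal_of <- integer(dat$n_nodes)
    cal_of[dat$cal_nodes] <- seq_along(dat$cal_nodes)

    state <- init_state(dat, settings)
    ages <- state$ages
    lr <- state$lr
    rates_u <- state$rates
    sigma2 <- state$sigma2
    alpha <- state$alpha

    ## start the rate field at maximum-likelihood branch lengths divided by
    ## the initial durations, when available (greatly shortens burn-in)
    if (autoc && !is.null(dat$ml_blens)) {
      dt0 <- ages[edge_p] - ages[edge_c]
      r0 <- pmin(pmax(dat$ml_blens[edge_c] / dt0, 1e-3), 1e3)
      lr_edge <- log(r0)
      lr <- numeric(dat$n_nodes)
      for (e in seq_len(n_edge)) lr[edge_c[e]] <- lr_edge[e]
      lr[dat$root] <- mean(lr_edge[edge_p == dat$root])
      lr <- lr + rnorm(dat$n_nodes, 0, 0.05)
      sigma2 <- pmin(pmax(mean((lr[edge_c] - lr[edge_p])^2 / dt0), 0.1), 10)
    }

    edge_dt <- ages[edge_p] - ages[edge_c]
    edge_rate <- if (autoc) exp((lr[edge_p] + lr[edge_c]) / 2) else rates_u
    edge_sub <- edge_rate * edge_dt

    mk_state <- function() list(ages = ages, lr = lr, rates = rates_u,
                                sigma2 = sigma2, alpha = alpha)
    logprior <- total_logprior(mk_state(), dat, settings)
    if (!is.finite(logprior)) stop("infeasible starting state")

    eng <- NULL; loglik <- 0
    if (use_lik) {
      model <- settings$substitution_model
      if (alpha != model$gamma_shape) model <- update_gamma_shape(model, alpha)
      eng <- plk_engine(alignment, dat$topology, model)
      loglik <- plk_set_blens(eng$ptr, blens_by_child(eng, edge, edge_sub))
    }

    rp <- settings$root_rate_prior
    sp <- settings$sigma2_prior
    up <- settings$uncorrelated
    bd_full <- settings$age_prior == "birth_death"
    root <- dat$root

    cal_term <- function(v, age) {
      if (cal_of[v] == 0L) return(0)
      calibration_logprior(age, dat$cal_list[[cal_of[v]]])
    }
    rate_terms <- function(idx, dt = edge_dt[idx], lrv = lr) {
      if (autoc)
        dnorm(lrv[edge_c[idx]], lrv[edge_p[idx]], sqrt(sigma2 * dt), log = TRUE)
      else numeric(length(idx))
    }
    ## non-root internal-node contribution of the age prior (node term only)
    node_age_term <- function(v, age) {
      if (!bd_full) return(0)
      bd <- settings$bd_params
      g <- bd_kernel_density(age, ages[root], bd$lambda, bd$mu, bd$rho)
      if (g <= 0) -Inf else log(g)
    }

    n_keep <- floor((settings$n_iterations * (1 - settings$burnin)) / settings$thin)
    first_kept <- ceiling(settings$n_iterations * settings$burnin) + 1L
    trace <- matrix(NA_real_, n_keep, n_int + n_edge + 4L)
    colnames(trace) <- c(paste0("age_", dat$internal),
                         paste0("rate_", seq_len(n_edge)),
                         "sigma2", "alpha", "loglik", "logprior")
    kept <- 0L
    acc <- c(age = 0, rate = 0, shift = 0, sigma2 = 0, alpha = 0, scale = 0)
    att <- acc

    metropolis <- function(dprior, keys, new_subs, log_hastings = 0) {
      ## returns TRUE and leaves the engine accepted on success
      if (!is.finite(dprior)) return(FALSE)
      new_ll <- if (use_lik && length(keys) > 0)
        plk_propose(eng$ptr, keys, new_subs) else loglik
      logr <- (new_ll - loglik) + dprior + log_hastings
      if (is.finite(logr) && log(runif(1)) < logr) {
        if (use_lik && length(keys) > 0) plk_accept(eng$ptr)
        loglik <<- new_ll; logprior <<- logprior + dprior
        TRUE
      } else {
        if (use_lik && length(keys) > 0) plk_reject(eng$ptr)
        FALSE
      }
    }

    for (it in seq_len(settings$n_iterations)) {
      ## ---- node ages
      for (v in dat$internal) {
        att["age"] <- att["age"] + 1
        kids <- dat$children[[v]]
        lo <- max(ages[kids])
        if (v == root) {
          a <- ages[v] + runif(1, -tun$root_window, tun$root_window)
          if (a <= lo) next
        } else {
          hi <- ages[dat$parent[v]]
          a <- runif(1, lo, hi)
        }
        aff <- inc[[v]]
        dtn <- ifelse(edge_p[aff] == v, a - ages[edge_c[aff]],
                      ages[edge_p[aff]] - a)
        dprior <- cal_term(v, a) - cal_term(v, ages[v]) +
          sum(rate_terms(aff, dt = dtn)) - sum(rate_terms(aff))
        if (v == root) {
          if (bd_full) {
            others <- setdiff(dat$internal, root)
            bd <- settings$bd_params
            gn <- bd_kernel_density(ages[others], a, bd$lambda, bd$mu, bd$rho)
            go <- bd_kernel_density(ages[others], ages[v], bd$lambda, bd$mu, bd$rho)
            dprior <- dprior + if (any(gn <= 0)) -Inf else sum(log(gn) - log(go))
          } else {
            dprior <- dprior - (n_int - 1) * (log(a) - log(ages[v]))
          }
        } else {
          dprior <- dprior + node_age_term(v, a) - node_age_term(v, ages[v])
        }
        subs_n <- edge_rate[aff] * dtn
        if (metropolis(dprior, edge_c[aff], subs_n)) {
          ages[v] <- a; edge_dt[aff] <- dtn; edge_sub[aff] <- subs_n
          acc["age"] <- acc["age"] + 1
        }
      }

      ## ---- rates
      if (autoc) {
        for (v in seq_len(dat$n_nodes)) {
          att["rate"] <- att["rate"] + 1
          lv <- lr[v] + rnorm(1, 0, tun$rate_sd)
          aff <- inc[[v]]
          lrn <- lr; lrn[v] <- lv
          dprior <- sum(rate_terms(aff, lrv = lrn)) - sum(rate_terms(aff))
          if (v == root)
            dprior <- dprior + dnorm(lv, rp$meanlog, rp$sdlog, log = TRUE) -
              dnorm(lr[v], rp$meanlog, rp$sdlog, log = TRUE)
          rn <- exp((lrn[edge_p[aff]] + lrn[edge_c[aff]]) / 2)
          subs_n <- rn * edge_dt[aff]
          if (metropolis(dprior, edge_c[aff], subs_n)) {
            lr[v] <- lv; edge_rate[aff] <- rn; edge_sub[aff] <- subs_n
            acc["rate"] <- acc["rate"] + 1
          }
        }
        ## ---- global log-rate shift (kept increments: only the root term
        ## of the prior moves; likelihood sees all branch lengths scaled)
        att["shift"] <- att["shift"] + 1
        eps <- rnorm(1, 0, tun$rate_sd / 2)
        dprior <- dnorm(lr[root] + eps, rp$meanlog, rp$sdlog, log = TRUE) -
          dnorm(lr[root], rp$meanlog, rp$sdlog, log = TRUE)
        subs_n <- edge_sub * exp(eps)
        if (metropolis(dprior, edge_c, subs_n)) {
          lr <- lr + eps; edge_rate <- edge_rate * exp(eps); edge_sub <- subs_n
          acc["shift"] <- acc["shift"] + 1
        }
        ## ---- subtree log-rate shift: all log-rates below (and including) a
        ## random internal node move together; only the stem increment of
        ## the Brownian prior changes
        {
          att["shift"] <- att["shift"] + 1
          u <- sample(dat$internal, 1)
          sub_nodes <- subtree_nodes(dat, u)
          eps <- rnorm(1, 0, tun$rate_sd / 2)
          if (u == root) {
            dprior <- dnorm(lr[root] + eps, rp$meanlog, rp$sdlog, log = TRUE) -
              dnorm(lr[root], rp$meanlog, rp$sdlog, log = TRUE)
            aff <- seq_len(n_edge)
          } else {
            stem <- which(edge_c == u)
            dprior <- dnorm(lr[u] + eps, lr[edge_p[stem]],
                            sqrt(sigma2 * edge_dt[stem]), log = TRUE) -
              rate_terms(stem)
            aff <- which(edge_c %in% sub_nodes)
          }
          rn <- edge_rate[aff] *
            exp(ifelse(edge_p[aff] %in% sub_nodes, eps, eps / 2))
          subs_n <- rn * edge_dt[aff]
          if (metropolis(dprior, edge_c[aff], subs_n)) {
            lr[sub_nodes] <- lr[sub_nodes] + eps
            edge_rate[aff] <- rn; edge_sub[aff] <- subs_n
            acc["shift"] <- acc["shift"] + 1
          }
        }
        ## ---- sigma2 (prior-only)
        att["sigma2"] <- att["sigma2"] + 1
        cc <- exp(runif(1, -tun$sigma2_step, tun$sigma2_step))
        s2n <- sigma2 * cc
        old_terms <- sum(rate_terms(seq_len(n_edge)))
        s2keep <- sigma2; sigma2 <- s2n
        new_terms <- sum(rate_terms(seq_len(n_edge)))
        sigma2 <- s2keep
        dprior <- new_terms - old_terms +
          dgamma(s2n, sp$shape, rate = sp$rate, log = TRUE) -
          dgamma(sigma2, sp$shape, rate = sp$rate, log = TRUE)
        if (metropolis(dprior, integer(0), numeric(0), log(cc))) {
          sigma2 <- s2n; acc["sigma2"] <- acc["sigma2"] + 1
        }
      } else {
        for (ei in seq_len(n_edge)) {
          att["rate"] <- att["rate"] + 1
          cc <- exp(runif(1, -tun$rate_sd, tun$rate_sd))
          rn <- rates_u[ei] * cc
          dprior <- dgamma(rn, up$shape, scale = up$scale, log = TRUE) -
            dgamma(rates_u[ei], up$shape, scale = up$scale, log = TRUE)
          sn <- rn * edge_dt[ei]
          if (metropolis(dprior, edge_c[ei], sn, log(cc))) {
            rates_u[ei] <- rn; edge_rate[ei] <- rn; edge_sub[ei] <- sn
            acc["rate"] <- acc["rate"] + 1
          }
        }
      }

      ## ---- discrete-gamma shape (full engine recompute)
      if (use_lik && settings$sample_gamma_shape &&
          settings$substitution_model$n_categories > 1 &&
          it %% settings$alpha_every == 0) {
        att["alpha"] <- att["alpha"] + 1
        cc <- exp(runif(1, -tun$alpha_step, tun$alpha_step))
        an <- alpha * cc
        dprior <- alpha_logprior(an, settings) - alpha_logprior(alpha, settings)
        new_ll <- plk_propose_rates(
          eng$ptr,
          phangorn::discrete.gamma(an, settings$substitution_model$n_categories))
        logr <- (new_ll - loglik) + dprior + log(cc)
        if (is.finite(logr) && log(runif(1)) < logr) {
          plk_accept(eng$ptr)
          alpha <- an; loglik <- new_ll; logprior <- logprior + dprior
          acc["alpha"] <- acc["alpha"] + 1
        } else plk_reject(eng$ptr)
      }

      ## ---- whole-tree age scaling
      {
        att["scale"] <- att["scale"] + 1
        cc <- exp(runif(1, -tun$scale_step, tun$scale_step))
        agn <- ages; agn[dat$internal] <- ages[dat$internal] * cc
        dtn <- agn[edge_p] - agn[edge_c]
        dprior <- sum(rate_terms(seq_len(n_edge), dt = dtn)) -
          sum(rate_terms(seq_len(n_edge)))
        for (i in seq_along(dat$cal_nodes)) {
          v <- dat$cal_nodes[i]
          dprior <- dprior + cal_term(v, agn[v]) - cal_term(v, ages[v])
          if (!is.finite(dprior)) break
        }
        if (is.finite(dprior)) {
          if (bd_full) {
            others <- setdiff(dat$internal, root)
            bd <- settings$bd_params
            gn <- bd_kernel_density(agn[others], agn[root], bd$lambda, bd$mu, bd$rho)
            go <- bd_kernel_density(ages[others], ages[root], bd$lambda, bd$mu, bd$rho)
            dprior <- dprior + if (any(gn <= 0)) -Inf else sum(log(gn) - log(go))
          } else {
            dprior <- dprior - (n_int - 1) * log(cc)
          }
        }
        subs_n <- edge_rate * dtn
        if (metropolis(dprior, edge_c, subs_n, n_int * log(cc))) {
          ages <- agn; edge_dt <- dtn; edge_sub <- subs_n
          acc["scale"] <- acc["scale"] + 1
        }
      }

      ## guard against slow numerical drift of the maintained prior
      if (it %% 100L == 0L)
        logprior <- total_logprior(mk_state(), dat, settings)

      if (it >= first_kept && (it - first_kept) %% settings$thin == 0 &&
          kept < n_keep) {
        kept <- kept + 1L
        trace[kept, ] <- c(ages[dat$internal], edge_rate,
                           sigma2, alpha, loglik, logprior)
      }
    }
    list(trace = trace[seq_len(kept), , drop = FALSE],
         acceptance = ifelse(att > 0, acc / att, NA),
         seed = chain_seed)
  })
}

## Maximum-likelihood branch lengths on the fixed topology (chain
## initialisation only; the sampler itself never uses them). Returns a
## vector indexed by child node, or NULL if the optimisation fails.
ml_branch_lengths <- function(alignment, topology, model) {
  tryCatch({
    pd <- phangorn::as.phyDat(as.matrix(alignment)[topology$tip.label, ,
                                                   drop = FALSE], type = "AA")
    tr <- topology
    tr$edge.length <- rep(0.2, nrow(tr$edge))
    Qv <- model$Q / rep(model$pi, each = 20)
    fit <- phangorn::pml(tr, pd, bf = model$pi, Q = Qv[lower.tri(Qv)],
                         k = model$n_categories, shape = model$gamma_shape)
    fit <- phangorn::optim.pml(fit, optEdge = TRUE,
                               control = phangorn::pml.control(trace = 0,
                                                               maxit = 8))
    out <- numeric(ape::Ntip(topology) + topology$Nnode)
    out[fit$tree$edge[, 2]] <- pmax(fit$tree$edge.length, 1e-6)
    out
  }, error = function(e) NULL)
}

## All nodes of the subtree rooted at u (including u)
subtree_nodes <- function(dat, u) {
  out <- integer(0); stack <- u
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- dat$children[[v]]
    if (!is.null(kids)) stack <- c(stack, kids)
  }
  out
}

update_gamma_shape <- function(model, alpha) {
  model$gamma_shape <- alpha
  if (model$n_categories > 1)
    model$rates <- phangorn::discrete.gamma(alpha, model$n_categories)
  model
}

#' Fit a Bayesian relaxed molecular clock
#'
#' Samples node ages (Ga), branch rates (delta per Ga) and hyperparameters
#' on a fixed rooted topology, under a [substitution_model] likelihood
#' (Felsenstein pruning, discrete-gamma rates, gaps as missing data), age
#' calibrations with hard or soft bounds, and either an
#' autocorrelated-lognormal or uncorrelated-gamma rate model.
#'
#' @param alignment An [aa_alignment] containing every leaf of `topology`
#'   (may be `NULL` for a prior-only run).
#' @param topology Rooted `ape::phylo`; its edge lengths, if any, are
#'   ignored.
#' @param calibrations A [calibration] or list of calibrations; a root
#'   calibration is required.
#' @param settings A [clock_settings].
#' @return Object of class `relaxed_clock`: retained posterior samples per
#'   chain, acceptance fractions, split-Rhat and effective sample sizes per
#'   scalar, and the inputs needed by the extractors ([rate_profile()],
#'   [summary.relaxed_clock()], [coef.relaxed_clock()]).
#' @seealso [rate_profile()], [nu_extrema()], [scenario_sweep()]
#' @export
relaxed_clock <- function(alignment, topology, calibrations, settings) {
  stopifnot(inherits(settings, "clock_settings"))
  if (!settings$prior_only) {
    if (is.null(settings$substitution_model))
      stop("settings$substitution_model is required unless prior_only")
    if (is.null(alignment)) stop("alignment is required unless prior_only")
  }
  if (!inherits(topology, "phylo")) stop("topology must be an ape::phylo tree")
  if (!ape::is.rooted(topology)) stop("topology must be rooted")

  res <- resolve_calibrations(calibrations, topology)
  ntip <- ape::Ntip(topology)
  n_nodes <- ntip + topology$Nnode
  edge <- topology$edge
  parent <- integer(n_nodes); parent[edge[, 2]] <- edge[, 1]
  parent[ntip + 1L] <- NA_integer_
  children <- vector("list", n_nodes)
  for (i in seq_len(nrow(edge)))
    children[[edge[i, 1]]] <- c(children[[edge[i, 1]]], edge[i, 2])
  edge_of_child <- integer(n_nodes); edge_of_child[edge[, 2]] <- seq_len(nrow(edge))
  pre <- ape::reorder.phylo(topology, "cladewise")$edge
  preorder_internal <- c(ntip + 1L, pre[pre[, 2] > ntip, 2])

  dat <- list(topology = topology, edge = edge, ntip = ntip,
              n_nodes = n_nodes, root = ntip + 1L,
              internal = (ntip + 1L):n_nodes,
              parent = parent, children = children,
              edge_of_child = edge_of_child,
              preorder_internal = preorder_internal,
              cal_nodes = res$nodes, cal_list = res$calibrations)

  ## quick infeasibility screen: nested hard calibrations must overlap
  check_calibration_feasibility(dat)

  if (!settings$prior_only && settings$rate_model == "autocorrelated")
    dat$ml_blens <- settings$ml_blens %||%
      ml_branch_lengths(alignment, topology, settings$substitution_model)

  chains <- lapply(seq_len(settings$n_chains), function(ch)
    run_chain(dat, settings, derive_seed(settings$seed, ch), alignment))

  traces <- lapply(chains, `[[`, "trace")
  diag <- chain_diagnostics(traces)
  fit <- structure(list(chains = traces,
                        acceptance = lapply(chains, `[[`, "acceptance"),
                        diagnostics = diag,
                        topology = topology, settings = settings,
                        calibrations = res$calibrations,
                        cal_nodes = res$nodes,
                        internal = dat$internal, edge = edge),
                   class = "relaxed_clock")
  bad <- diag$rhat[is.finite(diag$rhat)]
  if (length(bad) > 0 && max(bad) > 1.1)
    warning(sprintf("convergence advisory: max split-Rhat = %.3f (> 1.1); ",
                    max(bad)),
            "consider longer chains", call. = FALSE)
  fit
}

check_calibration_feasibility <- function(dat) {
  hard <- which(vapply(dat$cal_list, function(c) c$bounds == "hard", logical(1)))
  if (length(hard) < 2) return(invisible(TRUE))
  for (i in hard) for (j in hard) {
    ni <- dat$cal_nodes[i]; nj <- dat$cal_nodes[j]
    if (ni == nj && i < j) next
    ## is nj an ancestor of ni? then max(nj) must exceed min(ni)
    anc <- ni
    repeat {
      anc <- dat$parent[anc]
      if (is.na(anc)) break
      if (anc == nj) {
        maxj <- dat$cal_list[[j]]$max_age
        mini <- dat$cal_list[[i]]$min_age
        if (!is.na(maxj) && !is.na(mini) && maxj <= mini)
          stop("infeasible calibrations: ancestor node ", nj,
               " has max_age ", maxj, " <= descendant min_age ", mini)
        break
      }
    }
  }
  invisible(TRUE)
}

## ---- diagnostics -----------------------------------------------------------

## Split-Rhat and a Geyer-style effective sample size, per column of the
## per-chain trace matrices.
chain_diagnostics <- function(traces) {
  cols <- colnames(traces[[1]])
  rhat <- setNames(rep(NA_real_, length(cols)), cols)
  ess <- setNames(rep(NA_real_, length(cols)), cols)
  n <- min(vapply(traces, nrow, integer(1)))
  if (n < 4) return(list(rhat = rhat, ess = ess))
  for (j in seq_along(cols)) {
    halves <- list()
    for (tr in traces) {
      x <- tr[seq_len(n), j]
      h <- floor(n / 2)
      halves <- c(halves, list(x[1:h], x[(h + 1):(2 * h)]))
    }
    m <- length(halves); hn <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, var, numeric(1))
    W <- mean(vars); B <- hn * var(means)
    rhat[j] <- if (W > 0) sqrt(((hn - 1) / hn * W + B / hn) / W) else NA_real_
    ess[j] <- sum(vapply(traces, function(tr) ess_single(tr[seq_len(n), j]),
                         numeric(1)))
  }
  list(rhat = rhat, ess = ess)
}

ess_single <- function(x) {
  n <- length(x)
  if (var(x) == 0 || n < 8) return(n)
  lag_max <- min(n - 1, 200)
  rho <- acf(x, lag.max = lag_max, plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[k] + rho[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  max(1, n / (1 + 2 * s))
}

## ---- methods ---------------------------------------------------------------

#' @export
print.relaxed_clock <- function(x, ...) {
  n <- vapply(x$chains, nrow, integer(1))
  cat("Relaxed molecular clock fit\n")
  cat(sprintf("  %d chains x %d retained samples; %s rates, %s age prior%s\n",
              length(x$chains), n[1], x$settings$rate_model,
              x$settings$age_prior,
              if (x$settings$prior_only) " (prior only)" else ""))
  rh <- x$diagnostics$rhat
  rh <- rh[is.finite(rh)]
  if (length(rh)) cat(sprintf("  max split-Rhat %.3f\n", max(rh)))
  root_col <- paste0("age_", x$internal[1])
  root_draws <- unlist(lapply(x$chains, function(tr) tr[, root_col]))
  cat(sprintf("  posterior root age %.3f Ga [%.3f, %.3f]\n",
              mean(root_draws), quantile(root_draws, 0.025),
              quantile(root_draws, 0.975)))
  invisible(x)
}

#' Pool retained samples across chains
#' @param fit A `relaxed_clock` fit.
#' @return Matrix of pooled draws.
#' @export
pooled_samples <- function(fit) do.call(rbind, fit$chains)

#' @export
#' @method summary relaxed_clock
summary.relaxed_clock <- function(object, ...) {
  pool <- pooled_samples(object)
  age_cols <- grep("^age_", colnames(pool))
  df <- data.frame(
    node = object$internal,
    mean_age = colMeans(pool[, age_cols, drop = FALSE]),
    lower95 = apply(pool[, age_cols, drop = FALSE], 2, quantile, 0.025),
    upper95 = apply(pool[, age_cols, drop = FALSE], 2, quantile, 0.975),
    rhat = object$diagnostics$rhat[age_cols],
    ess = object$diagnostics$ess[age_cols])
  rownames(df) <- NULL
  structure(list(ages = df,
                 sigma2 = mean(pool[, "sigma2"]),
                 alpha = mean(pool[, "alpha"]),
                 n_samples = nrow(pool)),
            class = "summary.relaxed_clock")
}

#' @export
print.summary.relaxed_clock <- function(x, ...) {
  cat("Posterior node ages (Ga):\n")
  print(x$ages, digits = 4)
  if (is.finite(x$sigma2))
    cat(sprintf("posterior mean sigma2 = %.4g, gamma shape = %.4g (%d draws)\n",
                x$sigma2, x$alpha, x$n_samples))
  invisible(x)
}

#' @export
#' @method coef relaxed_clock
coef.relaxed_clock <- function(object, ...) {
  pool <- pooled_samples(object)
  colMeans(pool[, grep("^(age|rate)_", colnames(pool)), drop = FALSE])
}

#' @export
#' @method plot relaxed_clock
plot.relaxed_clock <- function(x, ...) {
  prof <- rate_profile(x)
  plot(prof, ...)
}
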