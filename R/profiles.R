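## Rate-through-time profiles and the delta-T scenario engine.

#' Posterior rate-through-time profile
#'
#' Per-branch posterior summaries from a [relaxed_clock] fit: posterior-mean
#' midpoint age (Ga), posterior-mean rate (delta per Ga), the Monte-Carlo
#' standard errors (posterior SD / sqrt(ESS)), and a flag for the branches
#' incident to the duplication node.
#'
#' @param fit A [relaxed_clock] fit.
#' @param dup_node Node number of the duplication; defaults to the root.
#' @return Object of class `rate_profile` (a data frame).
#' @export
rate_profile <- function(fit, dup_node = NULL) {
  stopifnot(inherits(fit, "relaxed_clock"))
  pool <- pooled_samples(fit)
  if (nrow(pool) == 0) stop("empty chains: nothing retained")
  ntip <- ape::Ntip(fit$topology)
  if (is.null(dup_node)) dup_node <- ntip + 1L
  edge <- fit$edge
  n_edge <- nrow(edge)

  age_of <- function(node) {
    if (node <= ntip) return(rep(0, nrow(pool)))
    pool[, paste0("age_", node)]
  }
  mid <- matrix(0, nrow(pool), n_edge)
  for (i in seq_len(n_edge))
    mid[, i] <- (age_of(edge[i, 1]) + age_of(edge[i, 2])) / 2
  rates <- pool[, paste0("rate_", seq_len(n_edge)), drop = FALSE]
  ess <- pmax(fit$diagnostics$ess[paste0("rate_", seq_len(n_edge))], 1)
  age_ess <- vapply(seq_len(n_edge), function(i) {
    nodes <- edge[i, ]
    e <- fit$diagnostics$ess[paste0("age_", nodes[nodes > ntip])]
    if (length(e) == 0 || all(is.na(e))) nrow(pool) else min(e, na.rm = TRUE)
  }, numeric(1))
  rate_sd <- apply(rates, 2, sd)
  df <- data.frame(
    edge = seq_len(n_edge),
    parent = edge[, 1], child = edge[, 2],
    midpoint_age = colMeans(mid),
    age_se = apply(mid, 2, sd) / sqrt(pmax(age_ess, 1)),
    rate = colMeans(rates),
    rate_sd = rate_sd,
    rate_se = rate_sd / sqrt(ifelse(is.na(ess), nrow(pool), ess)),
    dup_incident = edge[, 1] == dup_node)
  if (nrow(pool) == 1L) { df$rate_sd <- 0; df$rate_se <- 0; df$age_se <- 0 }
  class(df) <- c("rate_profile", "data.frame")
  df
}

#' @export
#' @method plot rate_profile
plot.rate_profile <- function(x, xlab = "Branch midpoint age (Ga)",
                              ylab = expression(paste("Rate (", delta, " ", Ga^-1, ")")),
                              ...) {
  graphics::plot(x$midpoint_age, x$rate, pch = 19,
                 col = ifelse(x$dup_incident, "firebrick", "grey30"),
                 xlim = rev(range(x$midpoint_age)), xlab = xlab, ylab = ylab, ...)
  graphics::arrows(x$midpoint_age, x$rate - x$rate_se,
                   x$midpoint_age, x$rate + x$rate_se,
                   length = 0.02, angle = 90, code = 3, col = "grey60")
  invisible(x)
}

#' Time span between a duplication and a crown ancestor
#'
#' @param dup_age Age of the duplication node (Ga).
#' @param mrca_age Age of the crown MRCA (Ga), `<= dup_age`.
#' @return `dup_age - mrca_age`, in Ga.
#' @examples
#' compute_delta_t(3.5, 1.7)  # 1.8
#' @export
compute_delta_t <- function(dup_age, mrca_age) {
  if (any(mrca_age < 0)) stop("ages must be >= 0")
  if (any(dup_age < mrca_age))
    stop("dup_age must not precede mrca_age")
  dup_age - mrca_age
}

#' Extract nu_max and nu_min from a rate profile
#'
#' `nu_max` is the mean posterior rate over the branches incident to the
#' duplication node (or the single fastest of them with
#' `use = "fastest"`); `nu_min` is the unweighted mean posterior rate over
#' branches whose midpoint age falls below `proterozoic_cutoff`. SEs are
#' propagated as the root-mean-square of the member SEs divided by
#' sqrt(m).
#'
#' @param profile A [rate_profile].
#' @param proterozoic_cutoff Midpoint-age threshold in Ga (default 2.5, the
#'   Archean-Proterozoic boundary).
#' @param use `"mean"` (default) or `"fastest"` for nu_max.
#' @return List `nu_max`, `nu_max_se`, `nu_min`, `nu_min_se`.
#' @export
nu_extrema <- function(profile, proterozoic_cutoff = 2.5,
                       use = c("mean", "fastest")) {
  use <- match.arg(use)
  dup <- which(profile$dup_incident)
  if (length(dup) == 0) stop("profile has no duplication-incident branch")
  window <- which(profile$midpoint_age < proterozoic_cutoff)
  if (length(window) == 0)
    stop("no branch midpoint below the cutoff (", proterozoic_cutoff,
         " Ga): empty Proterozoic window")
  agg <- function(idx) {
    m <- length(idx)
    list(value = mean(profile$rate[idx]),
         se = sqrt(mean(profile$rate_se[idx]^2)) / sqrt(m))
  }
  mx <- if (use == "fastest") {
    i <- dup[which.max(profile$rate[dup])]
    list(value = profile$rate[i], se = profile$rate_se[i])
  } else agg(dup)
  mn <- agg(window)
  list(nu_max = mx$value, nu_max_se = mx$se,
       nu_min = mn$value, nu_min_se = mn$se)
}

#' Rate ratio with the integer reporting convention
#'
#' The reported ratio is the float ratio truncated toward zero, the
#' convention under which the worked examples' printed integers are
#' recovered from their printed rate pairs.
#'
#' @param nu_max,nu_min Rates (delta per Ga), `nu_min > 0`.
#' @return List `ratio` (float) and `reported` (integer truncation).
#' @examples
#' rate_ratio(7.32, 0.28)$reported  # 26
#' @export
rate_ratio <- function(nu_max, nu_min) {
  if (any(nu_min <= 0)) stop("nu_min must be > 0")
  r <- nu_max / nu_min
  list(ratio = r, reported = trunc(r))
}

#' Single delta-T scenario result
#'
#' @param dup_age,mrca_age Scenario ages (Ga).
#' @param nu_max,nu_min Extracted rates; `*_se` their standard errors.
#' @param nu_max_se,nu_min_se Standard errors.
#' @return Object of class `scenario_result`, internally consistent by
#'   construction (`delta_t = dup_age - mrca_age`; reported ratio is the
#'   truncated float ratio).
#' @export
scenario_result <- function(dup_age, mrca_age, nu_max, nu_max_se,
                            nu_min, nu_min_se) {
  rr <- rate_ratio(nu_max, nu_min)
  structure(list(delta_t = compute_delta_t(dup_age, mrca_age),
                 dup_age = dup_age, mrca_age = mrca_age,
                 nu_max = nu_max, nu_max_se = nu_max_se,
                 nu_min = nu_min, nu_min_se = nu_min_se,
                 ratio = rr$ratio, ratio_reported = rr$reported),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf(
    "Scenario dup %.3g / MRCA %.3g Ga (delta-T %.3g): nu_max %.3g +/- %.2g, nu_min %.3g +/- %.2g, ratio %d (%.2f)\n",
    x$dup_age, x$mrca_age, x$delta_t, x$nu_max, x$nu_max_se,
    x$nu_min, x$nu_min_se, x$ratio_reported, x$ratio))
  invisible(x)
}

#' Sweep clock scenarios over a grid of crown-MRCA ages
#'
#' Re-runs the relaxed clock once per scenario with the crown-MRCA
#' calibration replaced by a narrow interval at each grid age, holding
#' everything else fixed, and extracts each scenario's nu_max / nu_min /
#' ratio. Per-scenario seeds are derived deterministically from the base
#' seed and the scenario index. A failing scenario is recorded as an error
#' and does not abort the sweep.
#'
#' @param alignment An [aa_alignment].
#' @param topology Rooted `ape::phylo` whose root is the duplication node.
#' @param base_calibrations List of [calibration]s applied to every
#'   scenario (must include the root/duplication constraint).
#' @param mrca_clade Tip labels whose MRCA is the crown node being swept,
#'   or a list of such label sets when the crown appears in several
#'   (paralog) subtrees — each receives the same scenario constraint
#'   (mirrored cross-calibration).
#' @param mrca_ages Numeric vector of scenario ages (Ga).
#' @param dup_age Duplication age used for the delta-T bookkeeping (Ga).
#' @param settings A [clock_settings].
#' @param mrca_halfwidth Half-width of the hard interval placed at each
#'   scenario age (default 0.05 Ga).
#' @param proterozoic_cutoff Passed to [nu_extrema()].
#' @return Object of class `scenario_sweep`: list of [scenario_result]s (or
#'   error records), ordered by delta-T descending, plus a results table.
#' @export
scenario_sweep <- function(alignment, topology, base_calibrations,
                           mrca_clade, mrca_ages, dup_age, settings,
                           mrca_halfwidth = 0.05,
                           proterozoic_cutoff = 2.5) {
  if (inherits(base_calibrations, "calibration"))
    base_calibrations <- list(base_calibrations)
  ord <- order(-(dup_age - mrca_ages))  # delta-T descending
  if (!settings$prior_only && settings$rate_model == "autocorrelated" &&
      is.null(settings$ml_blens))
    settings$ml_blens <- ml_branch_lengths(alignment, topology,
                                           settings$substitution_model)
  results <- vector("list", length(mrca_ages))
  for (k in seq_along(mrca_ages)) {
    age <- mrca_ages[k]
    res <- tryCatch({
      compute_delta_t(dup_age, age)  # validates ordering
      clades <- if (is.list(mrca_clade)) mrca_clade else list(mrca_clade)
      cals <- lapply(clades, function(cl)
        calibration(cl, min_age = age - mrca_halfwidth,
                    max_age = age + mrca_halfwidth, bounds = "hard"))
      st <- settings
      st$seed <- derive_seed(settings$seed, k)
      fit <- relaxed_clock(alignment, topology,
                           c(base_calibrations, cals), st)
      prof <- rate_profile(fit)
      nu <- nu_extrema(prof, proterozoic_cutoff)
      sr <- scenario_result(dup_age, age, nu$nu_max, nu$nu_max_se,
                            nu$nu_min, nu$nu_min_se)
      sr$fit <- fit
      sr
    }, error = function(e) {
      structure(list(mrca_age = age, dup_age = dup_age,
                     error = conditionMessage(e)),
                class = "scenario_error")
    })
    results[[k]] <- res
  }
  results <- results[ord]
  structure(list(results = results,
                 table = scenario_table(results)),
            class = "scenario_sweep")
}

scenario_table <- function(results) {
  rows <- lapply(results, function(r) {
    if (inherits(r, "scenario_error"))
      data.frame(delta_t = NA, dup_age = r$dup_age, mrca_age = r$mrca_age,
                 nu_max = NA, nu_max_se = NA, nu_min = NA, nu_min_se = NA,
                 ratio = NA, ratio_reported = NA, error = r$error)
    else
      data.frame(delta_t = r$delta_t, dup_age = r$dup_age,
                 mrca_age = r$mrca_age, nu_max = r$nu_max,
                 nu_max_se = r$nu_max_se, nu_min = r$nu_min,
                 nu_min_se = r$nu_min_se, ratio = r$ratio,
                 ratio_reported = r$ratio_reported, error = NA_character_)
  })
  do.call(rbind, rows)
}

#' @export
print.scenario_sweep <- function(x, ...) {
  cat("Delta-T scenario sweep (", nrow(x$table), " scenarios)\n", sep = "")
  print(x$table[, c("delta_t", "mrca_age", "nu_max", "nu_min",
                    "ratio", "ratio_reported")], digits = 4)
  invisible(x)
}

#' Power-law fit of rate versus delta-T
#'
#' Least squares on `log(nu_max) = log(a) + b log(delta_t)`; a negative
#' exponent `b` expresses the rise of the duplication-point rate as delta-T
#' shrinks.
#'
#' @param delta_ts,nu_maxes Positive numeric vectors (>= 3 points).
#' @return List `exponent`, `exponent_se`, `prefactor`, `r_squared`.
#' @export
fit_power_law <- function(delta_ts, nu_maxes) {
  if (length(delta_ts) < 3) stop("need at least 3 points")
  if (any(delta_ts <= 0) || any(nu_maxes <= 0))
    stop("power-law fit requires positive inputs")
  fit <- lm(log(nu_maxes) ~ log(delta_ts))
  s <- summary(fit)
  list(exponent = unname(coef(fit)[2]),
       exponent_se = unname(s$coefficients[2, 2]),
       prefactor = exp(unname(coef(fit)[1])),
       r_squared = s$r.squared)
}

#' Exponential-decay fit of rate through time
#'
#' Nonlinear least squares of
#' `r(t) = plateau + (r0 - plateau) * exp(-lambda * (t_max - t))` with `t`
#' the branch midpoint age (Ga before present); five deterministic
#' multi-starts, best RMSE kept.
#'
#' @param midpoint_ages,rates Numeric vectors (>= 4 points).
#' @return List `r0`, `lambda`, `plateau`, `rmse`, `fitted`.
#' @export
fit_exponential_decay <- function(midpoint_ages, rates) {
  if (length(midpoint_ages) < 4) stop("need at least 4 points")
  if (length(midpoint_ages) != length(rates)) stop("length mismatch")
  t_max <- max(midpoint_ages)
  x <- t_max - midpoint_ages          # elapsed time since the oldest point
  span <- max(rates) - min(rates)
  if (span < 1e-10 || sd(rates) < 1e-10) {
    # constant input: zero-amplitude curve at the observed level
    return(list(r0 = mean(rates), lambda = 0, plateau = mean(rates),
                rmse = sqrt(mean((rates - mean(rates))^2)),
                fitted = rep(mean(rates), length(rates))))
  }
  starts <- list(
    list(r0 = max(rates), lambda = 1, plateau = max(min(rates), 1e-6)),
    list(r0 = max(rates), lambda = 0.3, plateau = max(min(rates), 1e-6)),
    list(r0 = max(rates), lambda = 3, plateau = max(min(rates), 1e-6)),
    list(r0 = max(rates) + span, lambda = 2, plateau = max(mean(rates) / 2, 1e-6)),
    list(r0 = mean(rates), lambda = 0.01, plateau = max(mean(rates), 1e-6)))
  best <- NULL; best_rmse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rates ~ plateau + (r0 - plateau) * exp(-lambda * x),
                        start = st,
                        lower = c(r0 = 0, lambda = 0, plateau = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(residuals(fit)^2))
    if (rmse < best_rmse) { best <- fit; best_rmse <- rmse }
  }
  if (is.null(best))
    stop("exponential-decay fit failed to converge from all starts ",
         "(n = ", length(x), ", rate range ",
         paste(signif(range(rates), 3), collapse = " - "), ")")
  p <- coef(best)
  list(r0 = unname(p["r0"]), lambda = unname(p["lambda"]),
       plateau = unname(p["plateau"]), rmse = best_rmse,
       fitted = unname(fitted(best)))
}
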