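## Configuration-driven orchestration of the analysis stages with logging
## and reproducibility metadata. Config files are YAML; every output
## directory carries a manifest with the resolved-config hash and per-stage
## seeds and wall times.

config_defaults <- list(
  stages = c("simulate"),
  seed = 1L,
  output_dir = "paraclock_run",
  simulate = list(n_taxa = 16, root_age = 3.0, dup_age = 3.5,
                  n_sites = 500, rate_model = "autocorrelated",
                  root_rate = 2.0, sigma2 = 0.1,
                  matrix_id = "LG", gamma_shape = 1.0,
                  proterozoic_cutoff = 2.5),
  clock = list(matrix_id = "LG", gamma_shape = 1.0, n_categories = 4,
               rate_model = "autocorrelated", n_chains = 4,
               n_iterations = 20000, burnin = 0.25, thin = 10,
               root_min = 3.41, root_max = 4.52, bounds = "soft"),
  scenarios = list(mrca_ages = c(1.7, 2.6), dup_age = 3.5,
                   mrca_halfwidth = 0.05, proterozoic_cutoff = 2.5),
  distances = list(model = "poisson", alpha = 1.0, n_bootstrap = 500),
  asr = list(matrix_id = "LG", gamma_shape = 1.0, indel_mode = "ml",
             cutoff = 0.7),
  inputs = list(alignment = NULL, topology = NULL, calibrations = NULL)
)

known_keys <- function(template) {
  out <- names(template)
  for (n in names(template))
    if (is.list(template[[n]]) && !is.null(names(template[[n]])))
      out <- c(out, paste0(n, ".", names(template[[n]])))
  out
}

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys (itemised), fills
#' defaults, and attaches a provenance block (package version, master seed,
#' resolved-config hash, timestamp).
#'
#' @param path Path to a YAML file, or a named list.
#' @return Object of class `run_config`.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")

  flat <- names(cfg)
  for (n in names(cfg))
    if (is.list(cfg[[n]]) && !is.null(names(cfg[[n]])))
      flat <- c(flat, paste0(n, ".", names(cfg[[n]])))
  unknown <- setdiff(flat, known_keys(config_defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))

  resolved <- utils::modifyList(config_defaults, cfg)
  bad_stage <- setdiff(resolved$stages,
                       c("simulate", "distances", "clock", "scenarios", "asr"))
  if (length(bad_stage) > 0)
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (p in c("alignment", "topology", "calibrations")) {
    f <- resolved$inputs[[p]]
    if (!is.null(f) && !file.exists(f))
      stop("input path does not exist: ", p, " = ", f)
  }
  resolved$provenance <- list(
    package = "paraclock",
    version = as.character(packageVersion("paraclock")),
    seed = as.integer(resolved$seed),
    hash = config_hash(resolved),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  structure(resolved, class = "run_config")
}

## Hash of the resolved configuration (provenance block excluded so the
## hash is time-invariant).
config_hash <- function(cfg) {
  cfg$provenance <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(cfg[order(names(cfg))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.run_config <- function(x, ...) {
  cat("paraclock run config: stages", paste(x$stages, collapse = " -> "),
      "\n  seed", x$seed, " hash", substr(x$provenance$hash, 1, 12), "\n")
  invisible(x)
}

#' Run the configured pipeline stages
#'
#' Executes the requested stages in dependency order
#' (simulate -> distances -> clock -> scenarios -> asr), writing FASTA /
#' Newick / delimited tables / JSON under the output directory together
#' with a manifest recording the config hash, per-stage seeds and wall
#' times. A stage failure aborts the run after writing a partial-results
#' manifest.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list,
#'   validated on the fly).
#' @param output_dir Optional override of the configured output directory.
#' @return The output directory, invisibly; the manifest is
#'   `<output_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- output_dir %||% config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line); cat(line, "\n", file = logfile, append = TRUE)
  }
  manifest <- list(provenance = config$provenance, stages = list())
  order_all <- c("simulate", "distances", "clock", "scenarios", "asr")
  stages <- order_all[order_all %in% config$stages]
  env <- new.env()

  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    seed_st <- derive_seed(config$seed, match(st, order_all))
    logmsg("stage ", st, " (seed ", seed_st, ")")
    ok <- tryCatch({
      run_stage(st, config, env, out, seed_st)
      TRUE
    }, error = function(e) {
      logmsg("stage ", st, " FAILED: ", conditionMessage(e))
      manifest$stages[[st]] <<- list(status = "failed",
                                     error = conditionMessage(e))
      write_manifest()
      stop("pipeline aborted at stage '", st, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[st]] <- list(
      status = "ok", seed = seed_st,
      wall_seconds = round(proc.time()[["elapsed"]] - t0, 3))
    logmsg("stage ", st, " done (",
           manifest$stages[[st]]$wall_seconds, " s)")
  }
  write_manifest()
  invisible(out)
}

run_stage <- function(stage, config, env, out, seed) {
  switch(stage,
    simulate = {
      p <- config$simulate
      sp <- simulate_timetree(p$n_taxa, p$root_age, seed = seed)
      model <- substitution_model(p$matrix_id, gamma_shape = p$gamma_shape)
      proc <- rate_process("autocorrelated", root_rate = p$root_rate,
                           sigma2 = p$sigma2)
      ds <- make_duplication_dataset(sp, p$dup_age, proc, model,
                                     p$n_sites, seed = seed,
                                     proterozoic_cutoff = p$proterozoic_cutoff)
      env$alignment <- ds$alignment
      env$truth <- ds$truth
      env$topology <- ds$truth$tree$phylo
      write_fasta(ds$alignment, file.path(out, "alignment.fasta"))
      write_timetree(ds$truth$tree, file.path(out, "truth_tree.nwk"),
                     file.path(out, "truth_nodes.tsv"))
      write_truth_json(ds$truth, file.path(out, "truth.json"))
    },
    distances = {
      p <- config$distances
      aln <- pipeline_alignment(config, env)
      res <- list(all = within_group_mean(aln, alignment_ids(aln),
                                          model = p$model, alpha = p$alpha,
                                          n_bootstrap = p$n_bootstrap,
                                          seed = seed))
      write_group_distances(res, file.path(out, "distances.tsv"))
    },
    clock = {
      st <- pipeline_clock_settings(config, seed)
      aln <- pipeline_alignment(config, env)
      topo <- pipeline_topology(config, env)
      cals <- pipeline_calibrations(config, env)
      fit <- relaxed_clock(aln, topo, cals, st)
      env$fit <- fit
      trace <- pooled_samples(fit)
      write.table(round(trace, 6), file.path(out, "clock_trace.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prof <- rate_profile(fit)
      write.table(as.data.frame(prof), file.path(out, "rate_profile.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    scenarios = {
      p <- config$scenarios
      aln <- pipeline_alignment(config, env)
      topo <- pipeline_topology(config, env)
      st <- pipeline_clock_settings(config, seed)
      cals <- pipeline_calibrations(config, env)
      crown <- grep("_A$", topo$tip.label, value = TRUE)
      sw <- scenario_sweep(aln, topo, cals, crown, p$mrca_ages, p$dup_age,
                           st, mrca_halfwidth = p$mrca_halfwidth,
                           proterozoic_cutoff = p$proterozoic_cutoff)
      env$sweep <- sw
      write.table(sw$table, file.path(out, "scenarios.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    asr = {
      p <- config$asr
      aln <- pipeline_alignment(config, env)
      topo <- pipeline_topology(config, env)
      if (is.null(topo$edge.length)) {
        if (!is.null(env$truth)) topo <- as.phylo.time_tree(env$truth$tree)
        else stop("asr stage needs a topology with branch lengths")
      }
      model <- substitution_model(p$matrix_id, gamma_shape = p$gamma_shape)
      rec <- marginal_asr(aln, topo, model, ape::Ntip(topo) + 1L,
                          indel_mode = p$indel_mode, cutoff = p$cutoff)
      write_asr_table(rec, file.path(out, "asr_sites.tsv"))
      write_fasta(setNames(map_sequence(rec), "ancestral_MAP"),
                  file.path(out, "asr_map.fasta"))
    },
    stop("unknown stage: ", stage))
  invisible(NULL)
}

pipeline_alignment <- function(config, env) {
  if (!is.null(env$alignment)) return(env$alignment)
  f <- config$inputs$alignment
  if (is.null(f)) stop("no alignment: run the simulate stage or provide inputs.alignment")
  read_fasta(f)
}

pipeline_topology <- function(config, env) {
  if (!is.null(config$inputs$topology))
    return(ape::read.tree(config$inputs$topology))
  if (!is.null(env$topology)) return(env$topology)
  stop("no topology: run the simulate stage or provide inputs.topology")
}

pipeline_calibrations <- function(config, env) {
  if (!is.null(config$inputs$calibrations))
    return(read_calibration_table(config$inputs$calibrations))
  p <- config$clock
  list(calibration("root", min_age = p$root_min, max_age = p$root_max,
                   bounds = p$bounds))
}

pipeline_clock_settings <- function(config, seed) {
  p <- config$clock
  clock_settings(
    substitution_model = substitution_model(p$matrix_id,
                                            gamma_shape = p$gamma_shape,
                                            n_categories = p$n_categories),
    rate_model = p$rate_model, n_chains = p$n_chains,
    n_iterations = p$n_iterations, burnin = p$burnin, thin = p$thin,
    seed = seed)
}
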