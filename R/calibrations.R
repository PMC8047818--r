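## Node-age calibrations with hard or soft bounds.
##
## A soft calibration places a uniform "core" carrying 95% of the prior mass
## inside the bounds and exponential tails, continuous with the core density
## at each bound, carrying exactly the stated tail mass: 2.5% per side when
## both bounds are present, 5% for the single tail of a one-sided bound.
## One-sided calibrations close their unbounded side with a wide uniform
## core ending at `core_cap` (default 4.6 Ga, the age of the Earth) so the
## density is proper.

SOFT_TAIL_TWO_SIDED <- 0.025
SOFT_TAIL_ONE_SIDED <- 0.05

#' Age calibration on a clade
#'
#' @param clade Character vector of leaf identifiers (the constraint applies
#'   to their MRCA) or `"root"`.
#' @param min_age,max_age Bounds in Ga before present; either may be `NA`,
#'   but not both. `min_age < max_age` when both are given.
#' @param bounds `"soft"` (default) or `"hard"`.
#' @param core_cap Upper end of the uniform core for a one-sided minimum
#'   (and of a hard one-sided minimum's support); default 4.6 Ga.
#' @return Object of class `calibration`.
#' @examples
#' calibration("root", min_age = 3.41, max_age = 4.52, bounds = "soft")
#' @export
calibration <- function(clade, min_age = NA, max_age = NA,
                        bounds = c("soft", "hard"), core_cap = 4.6) {
  bounds <- match.arg(bounds)
  has_min <- !is.na(min_age); has_max <- !is.na(max_age)
  if (!has_min && !has_max) stop("at least one bound is required")
  if (has_min && has_max && min_age >= max_age)
    stop("min_age must be strictly less than max_age")
  if ((has_min && min_age < 0) || (has_max && max_age <= 0))
    stop("ages must be non-negative (max_age > 0)")
  if (has_min && !has_max && core_cap <= min_age)
    stop("core_cap must exceed min_age for a one-sided minimum")
  tail_mass <- if (has_min && has_max) SOFT_TAIL_TWO_SIDED else SOFT_TAIL_ONE_SIDED
  structure(list(clade = clade, min_age = min_age, max_age = max_age,
                 bounds = bounds, tail_mass = tail_mass, core_cap = core_cap),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cl <- if (identical(x$clade, "root")) "root" else
    paste0("MRCA(", paste(x$clade, collapse = ","), ")")
  cat(sprintf("Calibration on %s: [%s, %s] Ga, %s bounds\n", cl,
              ifelse(is.na(x$min_age), "-", format(x$min_age)),
              ifelse(is.na(x$max_age), "-", format(x$max_age)), x$bounds))
  invisible(x)
}

#' Calibration prior density
#'
#' Vectorised density of the calibration prior over age. Integrates to 1.
#'
#' @param cal A [calibration].
#' @param age Ages in Ga (vectorised).
#' @return Density values.
#' @export
calibration_density <- function(cal, age) {
  m <- cal$min_age; M <- cal$max_age
  has_min <- !is.na(m); has_max <- !is.na(M)
  if (cal$bounds == "hard") {
    lo <- if (has_min) m else 0
    hi <- if (has_max) M else cal$core_cap
    return(ifelse(age >= lo & age <= hi, 1 / (hi - lo), 0))
  }
  if (has_min && has_max) {
    tm <- SOFT_TAIL_TWO_SIDED
    h <- (1 - 2 * tm) / (M - m)
    theta <- h / tm
    ifelse(age < m, h * exp(theta * (age - m)),
           ifelse(age <= M, h, h * exp(-theta * (age - M))))
  } else if (has_min) {
    tm <- SOFT_TAIL_ONE_SIDED
    U <- cal$core_cap
    h <- (1 - tm) / (U - m)
    theta <- h / tm
    ifelse(age < m, h * exp(theta * (age - m)), ifelse(age <= U, h, 0))
  } else {
    tm <- SOFT_TAIL_ONE_SIDED
    h <- (1 - tm) / M
    theta <- h / tm
    ifelse(age < 0, 0, ifelse(age <= M, h, h * exp(-theta * (age - M))))
  }
}

#' Calibration log-prior contribution
#'
#' @param age Age in Ga (vectorised).
#' @param cal A [calibration].
#' @return Log density; `-Inf` outside the support of hard bounds.
#' @export
calibration_logprior <- function(age, cal) {
  d <- calibration_density(cal, age)
  ifelse(d > 0, log(d), -Inf)
}

#' Read a calibration table
#'
#' Tab-delimited with columns `clade` (semicolon-separated leaf ids, or
#' `root`), `min`, `max` (empty/NA for an absent bound), `bounds`
#' (`hard`/`soft`).
#'
#' @param path Input path.
#' @return List of [calibration] objects.
#' @export
read_calibration_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("clade", "min", "max", "bounds")
  if (!all(required %in% names(df)))
    stop("calibration table needs columns: ", paste(required, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    clade <- df$clade[i]
    if (!identical(clade, "root"))
      clade <- strsplit(clade, ";", fixed = TRUE)[[1]]
    calibration(clade,
                min_age = suppressWarnings(as.numeric(df$min[i])),
                max_age = suppressWarnings(as.numeric(df$max[i])),
                bounds = tolower(df$bounds[i]))
  })
}

## Map calibrations to node numbers on a topology. Returns a data.frame
## (node, index into the calibration list).
resolve_calibrations <- function(calibrations, topology) {
  if (inherits(calibrations, "calibration")) calibrations <- list(calibrations)
  nodes <- vapply(calibrations, function(cal) {
    if (identical(cal$clade, "root")) ape::Ntip(topology) + 1L
    else as.integer(mrca_node(topology, cal$clade))
  }, integer(1))
  list(nodes = nodes, calibrations = calibrations)
}
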