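# Initial cell-fate assignment from per-cell doses via the linear-quadratic
# survival model, including the dose scale factor aligning the sampled mean
# with the prescribed mean dose.

#' Linear-quadratic survival parameters
#'
#' Radiosensitivity of the AEC2 population. The shipped defaults
#' (alpha = 0.2 / Gy, beta = 0.02 / Gy^2, alpha/beta = 10 Gy, typical of an
#' early-responding epithelial population) place the critical-volume
#' survival plateau inside the 2.5-42.5 Gy dose range studied; see the
#' methods vignette. `sensitivity` scales both parameters, e.g.
#' `sensitivity = 0.9` reproduces the 10%-lower-radiosensitivity
#' perturbation.
#'
#' @param alpha linear coefficient, 1/Gy.
#' @param beta quadratic coefficient, 1/Gy^2.
#' @param sensitivity multiplier applied to both alpha and beta.
#' @return list of class `lq_params`.
#' @export
lq_params <- function(alpha = 0.2, beta = 0.02, sensitivity = 1) {
  if (alpha < 0 || beta < 0 || sensitivity < 0)
    stop("alpha, beta and sensitivity must be >= 0")
  structure(list(alpha = alpha * sensitivity, beta = beta * sensitivity),
            class = "lq_params")
}

#' LQ survival probability
#'
#' `exp(-alpha * D - beta * D^2)`, the probability that a cell receiving
#' dose D is not hit.
#'
#' @param dose absorbed dose, Gy (vectorized, must be >= 0).
#' @param params an [lq_params()].
#' @return survival probabilities in (0, 1].
#' @export
lq_survival <- function(dose, params = lq_params()) {
  if (any(dose < 0)) stop("dose must be >= 0")
  exp(-params$alpha * dose - params$beta * dose^2)
}

#' Dose scale factor
#'
#' The transport/sampling stage works in relative dose (the dose per history
#' grows linearly with the particle fluence); before assigning fates the
#' mean epithelial dose is aligned with the prescribed mean dose by a single
#' multiplicative factor.
#'
#' @param doses per-cell epithelial doses (relative units or Gy).
#' @param target_mean_dose prescribed mean dose, Gy.
#' @return scalar factor such that `factor * mean(doses) == target_mean_dose`.
#' @export
compute_scale_factor <- function(doses, target_mean_dose) {
  m <- mean(doses)
  if (!is.finite(m) || m <= 0)
    stop("mean epithelial dose must be > 0 to compute a scale factor")
  target_mean_dose / m
}

#' Fate-assignment configuration
#'
#' @param apoptotic_to_senescent_ratio fraction of hit AEC2 entering the
#'   apoptotic (rather than damaged/pre-senescent) branch; the reference
#'   configuration uses 0.
#' @param target_mean_dose prescribed mean epithelial dose per fraction, Gy.
#' @return list of class `fate_config`.
#' @export
fate_config <- function(apoptotic_to_senescent_ratio = 0,
                        target_mean_dose = 10) {
  if (apoptotic_to_senescent_ratio < 0 || apoptotic_to_senescent_ratio > 1)
    stop("apoptotic_to_senescent_ratio must be in [0, 1]")
  structure(list(apoptotic_to_senescent_ratio = apoptotic_to_senescent_ratio,
                 target_mean_dose = target_mean_dose),
            class = "fate_config")
}

#' Assign initial cell fates from scaled doses
#'
#' For each targetable AEC2 (healthy, and damaged cells are re-drawn in later
#' fractions) a uniform random number is compared against the LQ survival at
#' the cell's scaled dose: `u >= survival` marks a hit. Hit cells split
#' between apoptotic and damaged according to
#' `apoptotic_to_senescent_ratio`. Only AEC2 are radiation targets; all
#' other populations are unaffected. Fates are applied instantaneously (the
#' irradiation is orders of magnitude shorter than cell behavior times).
#'
#' @param report a `dose_report` (per-cell doses, already scaled to Gy).
#' @param geometry the `segment_geometry` the report refers to.
#' @param lq an [lq_params()].
#' @param cfg a [fate_config()].
#' @return data.frame cell_id, dose, fate (one row per targetable AEC2;
#'   fate in healthy/damaged/apoptotic).
#' @export
assign_fates <- function(report, geometry, lq = lq_params(),
                         cfg = fate_config()) {
  cells <- geometry$cells
  idx <- match(report$per_cell$cell_id, cells$cell_id)
  if (anyNA(idx)) stop("dose report does not match the geometry")
  targetable <- cells$type[idx] == "AEC2" &
    cells$state[idx] %in% c("healthy", "damaged")
  pc <- report$per_cell[targetable, , drop = FALSE]
  surv <- lq_survival(pc$dose, lq)
  hit <- stats::runif(nrow(pc)) >= surv
  fate <- rep("healthy", nrow(pc))
  if (any(hit)) {
    apop <- stats::runif(sum(hit)) < cfg$apoptotic_to_senescent_ratio
    fate[hit] <- ifelse(apop, "apoptotic", "damaged")
  }
  # cells already damaged stay at least damaged
  was_damaged <- cells$state[idx][targetable] == "damaged"
  fate[was_damaged & fate == "healthy"] <- "damaged"
  data.frame(cell_id = pc$cell_id, dose = pc$dose, fate = fate)
}

#' Fate audit file
#'
#' Writes / reads a two-column whitespace text file (cell_id, fate).
#'
#' @param fates data.frame from [assign_fates()].
#' @param file path of the fate file.
#' @return the path invisibly / a data.frame (cell_id, fate).
#' @export
write_fate_file <- function(fates, file) {
  writeLines(c("# cell_id fate",
               sprintf("%d %s", fates$cell_id, fates$fate)), file)
  invisible(file)
}

#' @rdname write_fate_file
#' @export
read_fate_file <- function(file) {
  lines <- readLines(file)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  tok <- strsplit(trimws(lines[body]), "[[:space:]]+")
  bad <- which(lengths(tok) != 2)
  if (length(bad))
    stop(sprintf("%s:%d: expected 2 fields", file, body[bad[1]]))
  id <- suppressWarnings(as.integer(vapply(tok, `[`, "", 1)))
  fate <- vapply(tok, `[`, "", 2)
  if (anyNA(id) || !all(fate %in% c(CELL_STATES)))
    stop(file, ": malformed fate line")
  data.frame(cell_id = id, fate = fate)
}
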