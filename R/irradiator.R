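# Per-cell dose production: parametric distribution samplers and a toy
# attenuation external-beam/isotropic transport model, plus scoring and the
# dose exchange files. The agent engine consumes only the per-cell dose
# vector, so the samplers parameterize the distribution *shapes* produced by
# full track-structure transport (approximately Gaussian for low-energy
# 4-field photon beams, narrow high-peak for plateau protons, multi-peaked
# with a large zero-dose mass for isotropic/high-energy setups).

#' Parametric dose-distribution parameters
#'
#' Relative-dose distribution used by [sample_parametric_doses()]. Doses are
#' in units of the (nominal) maximum dose; absolute scaling is deferred to
#' the fate module's scale factor.
#'
#' @param family "gaussian" or "mixture".
#' @param mean_fraction peak position as a fraction of the maximum dose.
#' @param cv coefficient of variation of the peak.
#' @param components for mixtures, data.frame with columns `weight`,
#'   `mean_fraction`, `sd` (weights must sum to 1).
#' @param zero_dose_mass probability of an exact 0 Gy cell.
#' @return list of class `distribution_params`.
#' @export
distribution_params <- function(family = c("gaussian", "mixture"),
                                mean_fraction = 0.5, cv = 0.2,
                                components = NULL, zero_dose_mass = 0) {
  family <- match.arg(family)
  if (cv < 0) stop("cv must be >= 0")
  if (zero_dose_mass < 0 || zero_dose_mass > 1)
    stop("zero_dose_mass must be in [0, 1]")
  if (family == "mixture") {
    if (is.null(components) || !nrow(components))
      stop("mixture family requires a non-empty components table")
    if (abs(sum(components$weight) - 1) > 1e-8)
      stop("mixture weights must sum to 1")
  }
  structure(list(family = family, mean_fraction = mean_fraction, cv = cv,
                 components = components, zero_dose_mass = zero_dose_mass),
            class = "distribution_params")
}

#' Dose-distribution presets per radiation quality
#'
#' Presets qualitatively matching the relative per-cell dose histograms of
#' the different source setups: 4-field external photon beams at 10 keV
#' (approximately Gaussian) and 1 keV (broader), an isotropic point source
#' (multiple peaks, long right tail, high zero-dose count), and a 60 MeV
#' plateau proton beam (pronounced narrow peak at ~80% of the maximum dose).
#' The proton peak's relative spread is strictly smaller than the photon
#' presets'.
#'
#' @param quality one of "photon_10keV", "photon_1keV", "isotropic",
#'   "proton_60MeV".
#' @return a [distribution_params()] object.
#' @export
dose_preset <- function(quality = c("photon_10keV", "photon_1keV",
                                    "isotropic", "proton_60MeV")) {
  switch(match.arg(quality),
    photon_10keV = distribution_params("gaussian", mean_fraction = 0.5,
                                       cv = 0.25, zero_dose_mass = 0),
    photon_1keV  = distribution_params("gaussian", mean_fraction = 0.45,
                                       cv = 0.40, zero_dose_mass = 0.02),
    isotropic    = distribution_params("mixture", zero_dose_mass = 0.25,
      components = data.frame(weight = c(0.5, 0.3, 0.2),
                              mean_fraction = c(0.15, 0.45, 0.8),
                              sd = c(0.05, 0.08, 0.12))),
    proton_60MeV = distribution_params("gaussian", mean_fraction = 0.8,
                                       cv = 0.08, zero_dose_mass = 0)
  )
}

#' External-source configuration for the toy transport model
#'
#' @param mode "external_beam" or "isotropic".
#' @param n_fields number of coplanar fields (1-4); fields lie on the XZ
#'   plane and successive fields are rotated by 90 degrees about the y axis.
#' @param particle "photon" or "proton".
#' @param energy_label free-text energy tag (e.g. "10 keV"); bookkeeping
#'   only, the toy transport works in relative dose.
#' @param histories emitted particles per field (> 0).
#' @param field_size rectangular field side, um (the cut-off shape is a
#'   rectangle covering the envelope by default).
#' @param mu attenuation coefficient, 1/um, of the toy exponential model.
#' @param energy_per_history energy carried by one history, J.
#' @return list of class `source_config`.
#' @export
source_config <- function(mode = c("external_beam", "isotropic"),
                          n_fields = 4L, particle = c("photon", "proton"),
                          energy_label = "10 keV", histories = 10000L,
                          field_size = 900, mu = 0,
                          energy_per_history = 1.6e-15) {
  mode <- match.arg(mode)
  particle <- match.arg(particle)
  if (histories <= 0) stop("histories must be > 0")
  if (mode == "external_beam" && (n_fields < 1 || n_fields > 4))
    stop("n_fields must be 1-4")
  structure(list(mode = mode, n_fields = as.integer(n_fields),
                 particle = particle, energy_label = energy_label,
                 histories = as.integer(histories), field_size = field_size,
                 mu = mu, energy_per_history = energy_per_history,
                 angular_spread = 0, energy_spread = 0),
            class = "source_config")
}

new_dose_report <- function(per_cell, geometry,
                            epithelial_radius_max = 6.5) {
  per_alveolus <- score_per_alveolus(per_cell, geometry,
                                     epithelial_radius_max)
  structure(list(per_cell = per_cell, per_alveolus = per_alveolus),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat("Dose report:", nrow(x$per_cell), "cells,",
      nrow(x$per_alveolus), "alveoli\n")
  epi <- x$per_cell$dose[x$per_cell$epithelial]
  if (length(epi))
    cat(sprintf("  epithelial dose: mean %.4g, sd %.4g, zero-dose %d\n",
                mean(epi), stats::sd(epi), sum(epi == 0)))
  invisible(x)
}

#' Sample per-cell doses from a parametric distribution
#'
#' Epithelial cells receive i.i.d. draws from the configured family
#' truncated at 0 (with an extra point mass at exactly 0); non-epithelial
#' cells receive dose 0 and are excluded from scoring. Deterministic given
#' the R random seed.
#'
#' @param geometry a `segment_geometry`.
#' @param params a [distribution_params()] (or [dose_preset()]).
#' @return a `dose_report`: `per_cell` data.frame (cell_id, alveolus_id,
#'   dose, epithelial) and `per_alveolus` data.frame (alveolus_id,
#'   mean_dose, n_epithelial).
#' @export
sample_parametric_doses <- function(geometry, params) {
  cells <- geometry$cells
  epi <- epithelial_mask(cells)
  n <- sum(epi)
  dose <- numeric(nrow(cells))
  if (n) {
    if (params$family == "gaussian") {
      mu <- params$mean_fraction
      dd <- stats::rnorm(n, mu, params$cv * mu)
    } else {
      comp <- sample.int(nrow(params$components), n, replace = TRUE,
                         prob = params$components$weight)
      dd <- stats::rnorm(n, params$components$mean_fraction[comp],
                         params$components$sd[comp])
    }
    dd <- pmax(dd, 0)
    if (params$zero_dose_mass > 0)
      dd[stats::runif(n) < params$zero_dose_mass] <- 0
    dose[epi] <- dd
  }
  per_cell <- data.frame(cell_id = cells$cell_id,
                         alveolus_id = cells$alveolus_id,
                         dose = dose, epithelial = epi)
  new_dose_report(per_cell, geometry)
}

# Rotate xz-plane vectors by k * 90 degrees about the y axis.
rot_y90 <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  x <- m[, 1]; z <- m[, 3]
  out <- m
  if (k == 1) { out[, 1] <- z;  out[, 3] <- -x }
  if (k == 2) { out[, 1] <- -x; out[, 3] <- -z }
  if (k == 3) { out[, 1] <- -z; out[, 3] <- x }
  out
}

#' Toy external-beam / isotropic transport
#'
#' Straight-line tracks with exponential attenuation: each history deposits
#' energy in every cell it intersects, proportional to the chord length
#' times `exp(-mu * path)` where `path` is the distance travelled inside the
#' world before entering the cell. Energy is converted to Gy via the cell
#' mass (water density, spherical volume). External-beam fields are parallel
#' rectangular beams on the XZ plane rotated by successive 90-degree turns
#' about y; the isotropic mode emits rays from the world center in
#' area-uniform random directions. Deterministic given the R random seed.
#'
#' @param geometry a `segment_geometry`.
#' @param source a [source_config()].
#' @return a `dose_report` (doses in Gy; all cells are scored, per-alveolus
#'   means use epithelial cells only).
#' @export
simulate_beam_transport <- function(geometry, source) {
  cells <- geometry$cells
  n <- nrow(cells)
  energy <- numeric(n)  # J per cell
  half_world <- geometry$world_side / 2
  if (n) {
    ctr <- cbind(cells$x, cells$y, cells$z)
    r <- cells$radius
    if (source$mode == "external_beam") {
      hw <- source$field_size / 2
      if (hw <= 0) stop("field does not intersect the envelope")
      for (f in seq_len(source$n_fields)) {
        # field f: beam along +x in the frame rotated by (f-1)*90 deg; rotate
        # the cells into the beam frame instead of the beam.
        cc <- rot_y90(ctr, -(f - 1))
        y0 <- stats::runif(source$histories, -hw, hw)
        z0 <- stats::runif(source$histories, -hw, hw)
        for (i in seq_len(n)) {
          d2 <- (y0 - cc[i, 2])^2 + (z0 - cc[i, 3])^2
          hit <- d2 < r[i]^2
          if (!any(hit)) next
          chord <- 2 * sqrt(r[i]^2 - d2[hit])
          path <- (cc[i, 1] + half_world) - chord / 2  # entry depth from wall
          energy[i] <- energy[i] + source$energy_per_history *
            sum(pmin(chord * 1e-2, 1) * exp(-source$mu * pmax(path, 0)))
        }
      }
    } else {
      u <- sample_on_sphere(source$histories, 1, c(0, 0, 0))
      for (i in seq_len(n)) {
        ci <- ctr[i, ]
        R2 <- sum(ci^2)
        if (R2 <= r[i]^2) { # source inside the cell: every ray hits
          energy[i] <- energy[i] + source$energy_per_history *
            source$histories * min(2 * r[i] * 1e-2, 1)
          next
        }
        t <- u %*% ci              # distance of closest approach along ray
        d2 <- R2 - t^2
        hit <- t > 0 & d2 < r[i]^2
        if (!any(hit)) next
        chord <- 2 * sqrt(r[i]^2 - d2[hit])
        path <- t[hit] - chord / 2
        energy[i] <- energy[i] + source$energy_per_history *
          sum(pmin(chord * 1e-2, 1) * exp(-source$mu * pmax(path, 0)))
      }
    }
  }
  mass_kg <- (4 / 3) * pi * cells$radius^3 * 1e-15  # water, 1e-12 g/um^3
  per_cell <- data.frame(cell_id = cells$cell_id,
                         alveolus_id = cells$alveolus_id,
                         dose = ifelse(mass_kg > 0, energy / mass_kg, 0),
                         epithelial = epithelial_mask(cells))
  new_dose_report(per_cell, geometry)
}

#' Per-alveolus mean epithelial dose
#'
#' Averages the per-cell doses over the epithelial cells of each alveolus.
#' Cells are filtered by size (radius), mirroring the scorer that skips
#' non-epithelial cells; alveoli without epithelial cells are flagged with
#' an `NA` mean.
#'
#' @param per_cell data.frame with `cell_id`, `alveolus_id`, `dose` (and
#'   optionally `epithelial`).
#' @param geometry the `segment_geometry` the doses refer to.
#' @param epithelial_radius_max size cut for the filter.
#' @return data.frame alveolus_id, mean_dose, n_epithelial.
#' @export
score_per_alveolus <- function(per_cell, geometry,
                               epithelial_radius_max = 6.5) {
  idx <- match(per_cell$cell_id, geometry$cells$cell_id)
  if (anyNA(idx))
    stop("unknown cell_id in dose table: ",
         per_cell$cell_id[which(is.na(idx))[1]])
  epi <- epithelial_mask(geometry$cells[idx, , drop = FALSE],
                         epithelial_radius_max)
  out <- data.frame(alveolus_id = geometry$alveoli$id)
  d <- per_cell$dose[epi]
  a <- per_cell$alveolus_id[epi]
  out$mean_dose <- vapply(out$alveolus_id, function(id) {
    di <- d[a == id]
    if (length(di)) mean(di) else NA_real_
  }, numeric(1))
  out$n_epithelial <- vapply(out$alveolus_id,
                             function(id) sum(a == id), integer(1))
  out
}

#' Gaussian fit of the relative dose histogram
#'
#' Builds the normalized histogram of the nonzero doses (as % of the
#' maximum, 50 bins by default) and least-squares fits a Gaussian bell to
#' the bin counts; exact-zero doses are counted separately and excluded
#' from the fit. With all doses identical the degenerate case is flagged
#' and `sd = 0` returned without a fit.
#'
#' @param doses numeric vector of per-cell doses.
#' @param bins histogram bin count.
#' @return list with `mean`, `sd` (percent of max dose), `amplitude`,
#'   `rss` (goodness, residual sum of squares on density scale),
#'   `zero_count`, `degenerate`.
#' @export
fit_dose_histogram <- function(doses, bins = 50L) {
  zero_count <- sum(doses == 0)
  d <- doses[doses > 0]
  if (length(d) < 10) stop("need >= 10 nonzero doses")
  pct <- 100 * d / max(d)
  if (stats::sd(pct) < 1e-12)
    return(list(mean = mean(pct), sd = 0, amplitude = NA_real_,
                rss = NA_real_, zero_count = zero_count, degenerate = TRUE))
  br <- seq(0, 100, length.out = bins + 1)
  hh <- graphics::hist(pct, breaks = br, plot = FALSE)
  df <- data.frame(x = hh$mids, y = hh$density)
  start <- list(A = max(df$y), m = stats::weighted.mean(df$x, df$y),
                s = max(stats::sd(pct), 2))
  fit <- minpack.lm::nlsLM(y ~ A * exp(-(x - m)^2 / (2 * s^2)), data = df,
                           start = start,
                           lower = c(0, 0, 1e-3), upper = c(Inf, 100, 200))
  cf <- stats::coef(fit)
  list(mean = unname(cf["m"]), sd = abs(unname(cf["s"])),
       amplitude = unname(cf["A"]),
       rss = sum(stats::residuals(fit)^2),
       zero_count = zero_count, degenerate = FALSE)
}

#' Dose exchange files
#'
#' `write_dose_files()` exports a dose report as two whitespace-delimited
#' text files: `doses_cell.txt` (cell_id, alveolus_id, dose_Gy) and
#' `doses_alveolus.txt` (alveolus_id, mean_dose_Gy). `read_dose_files()`
#' parses them back; malformed lines raise an error naming file and line.
#'
#' @param report a `dose_report`.
#' @param path directory to write into.
#' @return written file paths invisibly / a list with `per_cell` and
#'   `per_alveolus` data.frames.
#' @export
write_dose_files <- function(report, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  fc <- file.path(path, "doses_cell.txt")
  fa <- file.path(path, "doses_alveolus.txt")
  writeLines(c("# cell_id alveolus_id dose_Gy",
               sprintf("%d %d %.12g", report$per_cell$cell_id,
                       report$per_cell$alveolus_id, report$per_cell$dose)),
             fc)
  pa <- report$per_alveolus
  writeLines(c("# alveolus_id mean_dose_Gy",
               sprintf("%d %.12g", pa$alveolus_id, pa$mean_dose)), fa)
  invisible(c(fc, fa))
}

read_ws_table <- function(file, n_fields, what) {
  lines <- readLines(file)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body))
    return(matrix(numeric(), 0, n_fields))
  tok <- strsplit(trimws(lines[body]), "[[:space:]]+")
  bad <- which(lengths(tok) != n_fields)
  if (length(bad))
    stop(sprintf("%s:%d: expected %d fields, got %d", file, body[bad[1]],
                 n_fields, length(tok[[bad[1]]])))
  m <- suppressWarnings(do.call(rbind, lapply(tok, as.numeric)))
  if (anyNA(m)) {
    ln <- body[which(rowSums(is.na(m)) > 0)[1]]
    stop(sprintf("%s:%d: non-numeric %s field", file, ln, what))
  }
  m
}

#' @rdname write_dose_files
#' @export
read_dose_files <- function(path) {
  mc <- read_ws_table(file.path(path, "doses_cell.txt"), 3, "dose")
  ma <- read_ws_table(file.path(path, "doses_alveolus.txt"), 2, "dose")
  list(per_cell = data.frame(cell_id = as.integer(mc[, 1]),
                             alveolus_id = as.integer(mc[, 2]),
                             dose = mc[, 3]),
       per_alveolus = data.frame(alveolus_id = as.integer(ma[, 1]),
                                 mean_dose = ma[, 2]))
}
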