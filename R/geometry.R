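# Alveolar-segment geometry: alveoli layout and cell placement on spherical shells.

#' Cell types and state labels
#'
#' The segment is lined by six cell types on three concentric shells per
#' alveolus: mesenchymal cells (fibroblasts, myofibroblasts) on the outer
#' shell, epithelial cells (AEC1, AEC2) on the middle shell and macrophages
#' (M1, M2) on the inner shell. Only AEC2 can leave the healthy state.
#'
#' @format `CELL_TYPES` is a character vector of the six type labels;
#'   `CELL_STATES` the four state labels.
#' @export
CELL_TYPES <- c("AEC1", "AEC2", "fibroblast", "myofibroblast", "M1", "M2")

#' @rdname CELL_TYPES
#' @export
CELL_STATES <- c("healthy", "damaged", "senescent", "apoptotic")

# RGB color codes identifying the type in the structure exchange files.
TYPE_RGB <- c(
  AEC1          = "0,128,255",
  AEC2          = "0,0,255",
  fibroblast    = "0,255,0",
  myofibroblast = "255,165,0",
  M1            = "255,0,0",
  M2            = "128,0,128"
)

type_from_rgb <- function(rgb) {
  idx <- match(rgb, TYPE_RGB)
  if (anyNA(idx)) stop("unknown RGB type code: ", rgb[which(is.na(idx))[1]])
  names(TYPE_RGB)[idx]
}

shell_of_type <- function(type) {
  c(AEC1 = "middle", AEC2 = "middle",
    fibroblast = "outer", myofibroblast = "outer",
    M1 = "inner", M2 = "inner")[type]
}

#' Geometry configuration
#'
#' Parameters controlling the alveolar segment layout and cell seeding. The
#' default configuration reproduces the 18-alveoli segment: three layers of
#' six hollow spheres of diameter 260 um stacked in a cylindrical shape
#' inside a 900 um envelope box, itself centered in a 2000 um world cube.
#' Homeostatic per-type cell counts per alveolus are configuration (order
#' 1e2 AEC2 per alveolus); the shipped defaults are documented in the
#' methods vignette.
#'
#' @param n_layers number of stacked alveolus layers (cylinder axis = y).
#' @param alveoli_per_layer alveoli per ring.
#' @param alveolus_diameter alveolus diameter, um.
#' @param envelope_side side of the segment envelope box, um.
#' @param world_side side of the closed simulation world cube, um.
#' @param cell_diameter nominal cell diameter, um; sets the inner/outer shell
#'   offsets from the middle (epithelial) shell.
#' @param counts named integer vector: homeostatic cells per alveolus for
#'   each of [CELL_TYPES].
#' @param radii named numeric vector of cell radii, um. Epithelial radii must
#'   fall below `epithelial_radius_max` (the dose scorer filters cells by
#'   size, not by type).
#' @param epithelial_radius_max size cut distinguishing epithelial cells.
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(n_layers = 3L,
                            alveoli_per_layer = 6L,
                            alveolus_diameter = 260,
                            envelope_side = 900,
                            world_side = 2000,
                            cell_diameter = 10,
                            counts = c(AEC1 = 60L, AEC2 = 100L,
                                       fibroblast = 20L, myofibroblast = 5L,
                                       M1 = 6L, M2 = 6L),
                            radii = c(AEC1 = 6, AEC2 = 5,
                                      fibroblast = 7, myofibroblast = 8,
                                      M1 = 10.5, M2 = 10.5),
                            epithelial_radius_max = 6.5) {
  stopifnot(n_layers >= 1L, alveoli_per_layer >= 1L, alveolus_diameter > 0,
            envelope_side > 0, world_side >= envelope_side)
  counts <- counts[CELL_TYPES]
  names(counts) <- CELL_TYPES
  counts[is.na(counts)] <- 0L
  if (any(counts < 0)) stop("per-type cell counts must be >= 0")
  radii <- radii[CELL_TYPES]
  if (anyNA(radii)) stop("radii must be named for all cell types")
  structure(list(
    n_layers = as.integer(n_layers),
    alveoli_per_layer = as.integer(alveoli_per_layer),
    alveolus_diameter = alveolus_diameter,
    envelope_side = envelope_side,
    world_side = world_side,
    cell_diameter = cell_diameter,
    counts = as.integer(counts) |> stats::setNames(CELL_TYPES),
    radii = radii,
    epithelial_radius_max = epithelial_radius_max
  ), class = "geometry_config")
}

# Shell radii (um): middle = alveolus radius; inner/outer offset by one cell
# diameter ("hollow spheres" lined by three layers; offsets are a modelling
# choice, see the methods vignette).
shell_radii <- function(config) {
  r <- config$alveolus_diameter / 2
  c(inner = r - config$cell_diameter,
    middle = r,
    outer = r + config$cell_diameter)
}

# Alveoli centers: n_layers stacked rings of alveoli_per_layer centers at
# equal angular spacing about the y axis. Ring radius is the smallest giving
# adjacent-center separation >= diameter (touching, non-overlapping packing).
alveoli_centers <- function(config) {
  d <- config$alveolus_diameter
  m <- config$alveoli_per_layer
  ring_r <- if (m > 1) d / (2 * sin(pi / m)) else 0
  ys <- (seq_len(config$n_layers) - (config$n_layers + 1) / 2) * d
  ang <- 2 * pi * (seq_len(m) - 1) / m
  centers <- do.call(rbind, lapply(ys, function(y)
    cbind(ring_r * cos(ang), y, ring_r * sin(ang))))
  half <- config$envelope_side / 2
  if (max(abs(centers)) + d / 2 > half)
    stop("alveoli do not fit inside the envelope box without overlap: ",
         "reduce layers/alveoli per layer or the alveolus diameter")
  data.frame(id = seq_len(nrow(centers)),
             cx = centers[, 1], cy = centers[, 2], cz = centers[, 3],
             diameter = d)
}

# Area-uniform sampling of n points on a sphere of radius r centered at c0.
sample_on_sphere <- function(n, r, c0) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(c0[1] + r * s * cos(phi),
        c0[2] + r * s * sin(phi),
        c0[3] + r * z)
}

#' Build an alveolar segment
#'
#' Places `n_layers * alveoli_per_layer` alveoli inside the envelope and
#' seeds every alveolus with its homeostatic cell complement, drawn at
#' area-uniform random positions on the type's spherical shell. All cells
#' start healthy with zeroed type-specific counters. Deterministic given the
#' R random seed.
#'
#' @param config a [geometry_config()].
#' @return an object of class `segment_geometry`: list with `alveoli`
#'   (data.frame id, cx, cy, cz, diameter), `cells` (data.frame cell_id,
#'   alveolus_id, type, state, x, y, z, radius, shell, phagocytosed,
#'   bystander_steps, removal_steps), `shells`, `envelope_side`,
#'   `world_side` and the `config`.
#' @export
build_segment <- function(config = geometry_config()) {
  alv <- alveoli_centers(config)
  shells <- shell_radii(config)
  per_alv <- sum(config$counts)
  cells <- vector("list", nrow(alv))
  for (i in seq_len(nrow(alv))) {
    if (per_alv == 0L) next
    type <- rep(CELL_TYPES, times = config$counts)
    shl <- shell_of_type(type)
    pos <- matrix(0, length(type), 3)
    c0 <- c(alv$cx[i], alv$cy[i], alv$cz[i])
    for (s in c("inner", "middle", "outer")) {
      k <- which(shl == s)
      if (length(k)) pos[k, ] <- sample_on_sphere(length(k), shells[[s]], c0)
    }
    cells[[i]] <- data.frame(
      alveolus_id = alv$id[i], type = type, state = "healthy",
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      radius = unname(config$radii[type]), shell = unname(shl),
      phagocytosed = 0L, bystander_steps = 0L, removal_steps = -1L
    )
  }
  cells <- if (per_alv == 0L) empty_cells() else do.call(rbind, cells)
  cells <- cbind(cell_id = seq_len(nrow(cells)), cells)
  rownames(cells) <- NULL
  structure(list(alveoli = alv, cells = cells, shells = shells,
                 envelope_side = config$envelope_side,
                 world_side = config$world_side, config = config),
            class = "segment_geometry")
}

empty_cells <- function() {
  data.frame(alveolus_id = integer(), type = character(), state = character(),
             x = numeric(), y = numeric(), z = numeric(), radius = numeric(),
             shell = character(), phagocytosed = integer(),
             bystander_steps = integer(), removal_steps = integer())
}

#' @export
print.segment_geometry <- function(x, ...) {
  cat("Alveolar segment:", nrow(x$alveoli), "alveoli,",
      nrow(x$cells), "cells\n")
  cat("  alveolus diameter:", x$alveoli$diameter[1], "um;",
      "envelope:", x$envelope_side, "um; world:", x$world_side, "um\n")
  if (nrow(x$cells)) print(table(x$cells$type, x$cells$state))
  invisible(x)
}

#' Project positions back onto a spherical shell
#'
#' Translates each position to the requested radial distance from the shell
#' center while keeping its polar and azimuthal angles fixed (pure radial
#' rescaling). Applied after every movement to cancel accumulation of
#' floating-point drift off the shell.
#'
#' @param position numeric length-3 vector or n x 3 matrix, um.
#' @param center alveolus center, length-3.
#' @param radius target shell radius, um.
#' @return position(s) with `|pos - center| == radius` exactly (up to one
#'   rounding), same shape as the input.
#' @export
project_to_shell <- function(position, center, radius) {
  vec <- is.null(dim(position))
  p <- if (vec) matrix(position, 1) else as.matrix(position)
  d <- sweep(p, 2, center)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm == 0))
    stop("position coincides with the alveolus center: angles undefined")
  out <- sweep(d * (radius / nrm), 2, center, "+")
  if (vec) drop(out) else out
}

epithelial_mask <- function(cells, epithelial_radius_max = 6.5) {
  # the dose scorer filters by size, mirroring the per-cell hit processing
  cells$radius <= epithelial_radius_max
}

#' Export / import a segment structure
#'
#' Writes the structure exchange files: one whitespace-delimited text file
#' per alveolus (`alveolus_<id>.txt`, columns cell_id, x, y, z, radius,
#' RGB type code, state, then `key=value` attribute pairs) plus a
#' `manifest.txt` listing alveolus id, center and diameter together with the
#' segment-level sizes. `import_structure()` inverts the export
#' field-for-field.
#'
#' @param geometry a `segment_geometry`.
#' @param path directory to write into (created if missing).
#' @return `export_structure()` returns the written file paths invisibly;
#'   `import_structure()` returns a `segment_geometry`.
#' @export
export_structure <- function(geometry, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- file.path(path, "manifest.txt")
  hdr <- c(sprintf("# envelope_side %.9g", geometry$envelope_side),
           sprintf("# world_side %.9g", geometry$world_side),
           sprintf("# shells %.9g %.9g %.9g",
                   geometry$shells[["inner"]], geometry$shells[["middle"]],
                   geometry$shells[["outer"]]),
           "# alveolus_id cx cy cz diameter")
  rows <- sprintf("%d %.9g %.9g %.9g %.9g", geometry$alveoli$id,
                  geometry$alveoli$cx, geometry$alveoli$cy,
                  geometry$alveoli$cz, geometry$alveoli$diameter)
  writeLines(c(hdr, rows), man)
  written <- man
  for (id in geometry$alveoli$id) {
    cc <- geometry$cells[geometry$cells$alveolus_id == id, , drop = FALSE]
    if (!nrow(cc)) next
    f <- file.path(path, sprintf("alveolus_%d.txt", id))
    writeLines(sprintf(
      "%d %.12g %.12g %.12g %.9g %s %s phag=%d byst=%d rem=%d",
      cc$cell_id, cc$x, cc$y, cc$z, cc$radius,
      TYPE_RGB[cc$type], cc$state,
      cc$phagocytosed, cc$bystander_steps, cc$removal_steps), f)
    written <- c(written, f)
  }
  invisible(written)
}

parse_kv <- function(tok, key, file, ln) {
  hit <- grep(paste0("^", key, "="), tok, value = TRUE)
  if (length(hit) != 1)
    stop(sprintf("%s:%d: missing attribute '%s'", file, ln, key))
  as.integer(sub(".*=", "", hit))
}

#' @rdname export_structure
#' @export
import_structure <- function(path) {
  man <- file.path(path, "manifest.txt")
  if (!file.exists(man)) stop("no manifest.txt under ", path)
  lines <- readLines(man)
  get_hdr <- function(key) {
    h <- grep(paste0("^# ", key, " "), lines, value = TRUE)
    if (!length(h)) stop(man, ": missing header '# ", key, "'")
    as.numeric(strsplit(trimws(sub(paste0("^# ", key), "", h[1])), " +")[[1]])
  }
  envelope <- get_hdr("envelope_side")
  world <- get_hdr("world_side")
  shells <- stats::setNames(get_hdr("shells"), c("inner", "middle", "outer"))
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  alv <- if (length(body)) {
    tok <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(tok) != 5)
    if (length(bad))
      stop(sprintf("%s:%d: expected 5 fields, got %d", man,
                   bad[1], length(tok[[bad[1]]])))
    m <- do.call(rbind, lapply(tok, as.numeric))
    if (anyNA(m)) stop(man, ": non-numeric manifest field")
    data.frame(id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
               cz = m[, 4], diameter = m[, 5])
  } else data.frame(id = integer(), cx = numeric(), cy = numeric(),
                    cz = numeric(), diameter = numeric())
  cells <- list()
  for (i in seq_len(nrow(alv))) {
    f <- file.path(path, sprintf("alveolus_%d.txt", alv$id[i]))
    if (!file.exists(f)) next
    cl <- readLines(f)
    tok <- strsplit(trimws(cl), "[[:space:]]+")
    recs <- lapply(seq_along(tok), function(j) {
      t <- tok[[j]]
      if (length(t) < 7)
        stop(sprintf("%s:%d: expected >= 7 fields, got %d", f, j, length(t)))
      num <- suppressWarnings(as.numeric(t[1:5]))
      if (anyNA(num)) stop(sprintf("%s:%d: non-numeric coordinate field", f, j))
      type <- type_from_rgb(t[6])
      if (!t[7] %in% CELL_STATES)
        stop(sprintf("%s:%d: unknown state '%s'", f, j, t[7]))
      data.frame(cell_id = as.integer(num[1]), alveolus_id = alv$id[i],
                 type = type, state = t[7],
                 x = num[2], y = num[3], z = num[4], radius = num[5],
                 shell = unname(shell_of_type(type)),
                 phagocytosed = parse_kv(t, "phag", f, j),
                 bystander_steps = parse_kv(t, "byst", f, j),
                 removal_steps = parse_kv(t, "rem", f, j))
    })
    cells[[length(cells) + 1L]] <- do.call(rbind, recs)
  }
  cells <- if (length(cells)) do.call(rbind, cells) else
    cbind(cell_id = integer(), empty_cells())
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(alveoli = alv, cells = cells, shells = shells,
                 envelope_side = envelope, world_side = world,
                 config = NULL),
            class = "segment_geometry")
}
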