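# Voxelized reaction-diffusion solver (FTCS, Neumann zero-flux walls) for the
# extracellular substance network.

#' Extracellular substance parameters
#'
#' The engine tracks ten diffusing/decaying substances secreted and consumed
#' by the agents. The biologically named part of the network is MCP-1 (macrophage
#' recruitment), the MMP/TIMP/ECM triplet (matrix turnover) and the
#' M2-derived growth factors; the remaining entries are generic
#' senescence-associated and inflammatory cytokines completing the
#' ten-substance interface. Diffusion coefficients are um^2/s, decay rates
#' 1/s; concentrations are g/cm^3 for ECM and arbitrary units otherwise.
#'
#' @return data.frame with columns `name`, `D`, `decay`.
#' @export
substance_defaults <- function() {
  data.frame(
    name  = c("MCP1", "SASP", "IL6", "TNF", "MMP",
              "TIMP", "ECM", "TGFB", "PDGF", "IL13"),
    D     = c(50, 40, 60, 60, 30, 30, 0, 40, 40, 50),
    decay = c(2.3e-5, 2.3e-5, 2.3e-5, 2.3e-5, 1.2e-5,
              1.2e-5, 2.3e-6, 2.3e-5, 2.3e-5, 2.3e-5)
  )
}

#' Substance coupling (depletion) network
#'
#' Mass-action depletion terms applied after the diffusion/decay update:
#' TIMP neutralizes MMP (both consumed, mode `annihilate`) and MMP degrades
#' ECM (MMP acts catalytically, only ECM consumed, mode `degrade`). Rates
#' are per concentration unit per second.
#'
#' @return data.frame with columns `a`, `b`, `k`, `mode`.
#' @export
coupling_defaults <- function() {
  data.frame(a = c("TIMP", "MMP"), b = c("MMP", "ECM"),
             k = c(1e-4, 2e-5), mode = c("annihilate", "degrade"))
}

#' Create a diffusion grid
#'
#' Dissects the cubic simulation world into `n^3` cubic voxels holding one
#' concentration field per substance, advanced with a forward-in-time
#' central-in-space (FTCS) scheme under Neumann zero-flux boundary
#' conditions at the world faces.
#'
#' @param n voxels per axis (resolution is user-set; default 20 gives
#'   100-um voxels over the default 2000-um world, inside the CFL bound at
#'   dt = 20 s for the default diffusion coefficients).
#' @param world_side world cube side, um.
#' @param substances see [substance_defaults()].
#' @param couplings see [coupling_defaults()].
#' @param dt time step, s.
#' @param ecm_sat saturation concentration for ECM deposition, g/cm^3 (the
#'   alveolar space stores a bounded amount of matrix).
#' @return object of class `diffusion_grid`.
#' @export
diffusion_grid <- function(n = 20L, world_side = 2000,
                           substances = substance_defaults(),
                           couplings = coupling_defaults(),
                           dt = 20, ecm_sat = 0.5) {
  n <- as.integer(n)
  stopifnot(n >= 1L, world_side > 0, dt > 0,
            all(substances$D >= 0), all(substances$decay >= 0))
  h <- world_side / n
  st <- check_stability(substances, h, dt)
  if (!st$ok)
    stop(sprintf(
      "FTCS stability violated (dt = %g s > max stable %g s, binding: %s)",
      dt, st$max_dt, st$binding))
  conc <- matrix(0, n^3, nrow(substances),
                 dimnames = list(NULL, substances$name))
  structure(list(n = c(n, n, n), h = h,
                 origin = rep(-world_side / 2, 3),
                 world_side = world_side, dt = dt,
                 substances = substances, couplings = couplings,
                 ecm_sat = ecm_sat, conc = conc),
            class = "diffusion_grid")
}

#' @export
print.diffusion_grid <- function(x, ...) {
  cat(sprintf("Diffusion grid: %d x %d x %d voxels of %g um, dt = %g s\n",
              x$n[1], x$n[2], x$n[3], x$h, x$dt))
  cat("  substances:", paste(x$substances$name, collapse = ", "), "\n")
  invisible(x)
}

#' FTCS stability check
#'
#' Explicit 3D FTCS is stable and positivity-preserving when
#' `D * dt / h^2 <= 1/6` for every substance and the per-step decay
#' `decay * dt <= 1`. Returns the largest admissible dt and the binding
#' constraint.
#'
#' @param substances data.frame with `name`, `D`, `decay`.
#' @param h voxel side, um.
#' @param dt candidate time step, s.
#' @return list with `ok`, `max_dt`, `binding` (substance and constraint
#'   that binds).
#' @export
check_stability <- function(substances, h, dt) {
  dt_diff <- ifelse(substances$D > 0, h^2 / (6 * substances$D), Inf)
  dt_dec <- ifelse(substances$decay > 0, 1 / substances$decay, Inf)
  lim <- pmin(dt_diff, dt_dec)
  i <- which.min(lim)
  list(ok = dt <= lim[i] + 1e-12, max_dt = lim[i],
       binding = sprintf("%s (%s)", substances$name[i],
                         if (dt_diff[i] <= dt_dec[i]) "CFL" else "decay"))
}

#' Advance the grid one FTCS step
#'
#' One explicit update: central-difference Laplacian with zero-flux walls,
#' first-order decay, then the mass-action coupling sinks (see
#' [apply_couplings()]). Raises if `dt` violates the stability bound.
#'
#' @param grid a `diffusion_grid`.
#' @param dt time step, s (default the grid's own dt).
#' @param n_steps number of consecutive steps.
#' @param couplings apply the depletion couplings after diffusion/decay.
#' @return the updated grid.
#' @export
step_ftcs <- function(grid, dt = grid$dt, n_steps = 1L, couplings = TRUE) {
  st <- check_stability(grid$substances, grid$h, dt)
  if (!st$ok)
    stop(sprintf("dt = %g s violates stability (max %g s, binding: %s)",
                 dt, st$max_dt, st$binding))
  cm <- coupling_matrix(grid)
  for (i in seq_len(n_steps)) {
    grid$conc <- cpp_step_ftcs(grid$conc, grid$n[1], grid$n[2], grid$n[3],
                               grid$h, grid$substances$D,
                               grid$substances$decay, dt)
    if (couplings && nrow(cm))
      grid$conc <- cpp_apply_couplings(grid$conc, cm[, 1], cm[, 2],
                                       grid$couplings$k,
                                       cm[, 3], dt)
  }
  if (min(grid$conc) < -1e-12)
    stop("positivity violated after FTCS step")
  grid$conc[grid$conc < 0] <- 0
  grid
}

coupling_matrix <- function(grid) {
  cp <- grid$couplings
  if (is.null(cp) || !nrow(cp))
    return(matrix(integer(), 0, 3))
  ia <- match(cp$a, grid$substances$name)
  ib <- match(cp$b, grid$substances$name)
  if (anyNA(ia) || anyNA(ib)) stop("coupling names unknown to the grid")
  cbind(ia, ib, ifelse(cp$mode == "annihilate", 1L, 2L))
}

#' Apply the substance depletion couplings
#'
#' Mass-action sinks with a clamped implicit-in-sink update, so that removal
#' can never drive a voxel negative: for `annihilate` pairs the depleted
#' amount is identical for both partners (the difference of the two fields
#' is an exact invariant of the update); for `degrade` pairs only the target
#' is consumed.
#'
#' @inheritParams step_ftcs
#' @return the updated grid.
#' @export
apply_couplings <- function(grid, dt = grid$dt) {
  cm <- coupling_matrix(grid)
  if (nrow(cm))
    grid$conc <- cpp_apply_couplings(grid$conc, cm[, 1], cm[, 2],
                                     grid$couplings$k, cm[, 3], dt)
  grid
}

voxel_of <- function(grid, position) {
  p <- as.numeric(position)
  rel <- (p - grid$origin) / grid$h
  if (any(rel < 0) || any(rel >= grid$n + 1e-12))
    stop("position outside the simulation world")
  ijk <- pmin(floor(rel), grid$n - 1)
  as.integer(1 + ijk[1] + grid$n[1] * (ijk[2] + grid$n[2] * ijk[3]))
}

#' Agent-facing voxel access
#'
#' `grid_deposit()` adds `amount` (concentration units) to the voxel
#' containing `position`; ECM deposits are clamped at the grid's saturation
#' concentration. `grid_readout()` returns the voxel concentration.
#' `grid_total_mass()` sums a substance's concentration over all voxels.
#'
#' @param grid a `diffusion_grid`.
#' @param position length-3 position, um (world coordinates).
#' @param substance substance name.
#' @param amount concentration to add.
#' @return the updated grid / the concentration / the voxel-summed total.
#' @export
grid_deposit <- function(grid, position, substance, amount) {
  j <- match(substance, grid$substances$name)
  if (is.na(j)) stop("unknown substance: ", substance)
  v <- voxel_of(grid, position)
  new <- grid$conc[v, j] + amount
  if (substance == "ECM") new <- min(new, grid$ecm_sat)
  grid$conc[v, j] <- max(new, 0)
  grid
}

#' @rdname grid_deposit
#' @export
grid_readout <- function(grid, position, substance) {
  j <- match(substance, grid$substances$name)
  if (is.na(j)) stop("unknown substance: ", substance)
  unname(grid$conc[voxel_of(grid, position), j])
}

#' @rdname grid_deposit
#' @export
grid_total_mass <- function(grid, substance) {
  j <- match(substance, grid$substances$name)
  if (is.na(j)) stop("unknown substance: ", substance)
  sum(grid$conc[, j])
}

#' Mean concentration per substance over the whole grid
#' @param grid a `diffusion_grid`.
#' @return named numeric vector.
#' @export
grid_mean_concentration <- function(grid) {
  stats::setNames(colMeans(grid$conc), grid$substances$name)
}
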