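# Agent-based engine: world construction, behavior configuration and the
# 20 s step loop (secretion -> diffusion -> behaviors -> shell projection).
# The hot loop lives in compiled code; every behavior is also callable in
# isolation through the `phases` argument.

TYPE_CODE <- c(AEC1 = 1L, AEC2 = 2L, fibroblast = 3L, myofibroblast = 4L,
               M1 = 5L, M2 = 6L)
STATE_CODE <- c(healthy = 0L, damaged = 1L, senescent = 2L, apoptotic = 3L)

ENGINE_PHASES <- c("secrete", "diffuse", "bystander", "senesce", "apoptotic",
                   "phagocytose", "recruit", "repopulate", "mesenchymal",
                   "migrate")

#' Engine behavior configuration
#'
#' Rates are per day unless noted; speeds are um per 20 s step. The defaults
#' are the package's homeostatic parameterization (the gate is
#' [run_homeostasis_check()]): turnover rates are balanced so that in the
#' undamaged segment births equal deaths in expectation and all substance
#' concentrations are stationary. Damage-associated parameters
#' (`bystander_threshold`, `phagocytic_fraction`, `phagocytic_index`,
#' `apoptotic` split) follow the reference configuration: phagocytic
#' fraction 1, phagocytic index 1, bystander threshold 2.
#'
#' @param dt step length, s.
#' @param speed_mac,speed_mes,speed_epi migration speeds (um/step) of
#'   macrophages, mesenchymal cells and healthy epithelial cells.
#' @param speed_impaired speed of damaged/senescent AEC2 (slower than
#'   healthy); `immobility_prob` is their per-step probability of not moving
#'   at all.
#' @param immobility_prob see above.
#' @param neighbor_radius bystander neighborhood radius, um. The shells are
#'   not confluent at order-1e2 cells per alveolus, so the neighborhood must
#'   cover the mean epithelial spacing (~35 um at the default density) for
#'   senescent cells to have neighbors at all; see the methods vignette.
#' @param sense_radius radius of the epithelial-density neighborhood used by
#'   informed migration, um.
#' @param contact_range macrophage-senescent contact range for
#'   phagocytosis, um.
#' @param bystander_threshold minimum number of senescent neighbors before a
#'   healthy AEC2 accumulates indirect-damage exposure.
#' @param bystander_k per-step conversion hazard coefficient (1/s per
#'   exposure step): p = min(1, k * exposure_steps * dt).
#' @param bystander_fade per-step probability that one exposure-counter unit
#'   fades while the cell is not in a qualifying senescent neighborhood.
#'   Exposure accumulates (and the indirect-damage chain can run away) only
#'   where the neighborhood condition holds more often than the fade.
#' @param damaged_to_senescent_rate damaged -> senescent conversion rate
#'   (exponential waiting time), 1/day.
#' @param apoptotic_removal_mean_steps mean of the Poisson removal delay for
#'   apoptotic cells, steps.
#' @param aec1_death_rate,aec2_death_rate,aec2_prolif_rate,aec2_diff_rate
#'   epithelial turnover rates, 1/day; the defaults satisfy the homeostatic
#'   balance diff * N_AEC2 = death * N_AEC1 and prolif = death + diff.
#' @param repop_gain,repop_K signed saturating (Michaelis-type) regulation of
#'   proliferation/differentiation with the count deficit `d`, symmetric
#'   around the target: births carry `m = max(0, 1 + gain * d / (K + |d|))`
#'   and deaths its mirror `max(0, 2 - m)`, so the restoring force is equal
#'   on both sides of the target.
#' @param n_aec1_target,n_aec2_target,n_fib_target homeostatic per-alveolus
#'   counts (overridden from the geometry config by [new_world()]).
#' @param fib_prolif_rate,fib_death_rate fibroblast turnover, 1/day.
#' @param fib_gf_gain,fib_dis_gain fibroblast proliferation response to
#'   growth factor and epithelial disruption.
#' @param act_rate,act_gf_w,act_dis_w fibroblast -> myofibroblast activation
#'   rate (1/day) and its growth-factor/disruption weights.
#' @param dis_deadzone fraction of epithelial loss tolerated before the
#'   mesenchymal compartment reacts (homeostatic count noise must not
#'   trigger the terminal fibroblast -> myofibroblast switch).
#' @param gf_K,mcp_K half-saturation concentrations of the growth-factor and
#'   MCP-1 responses.
#' @param myo_ecm_secretion ECM deposition per myofibroblast, concentration
#'   units (g/cm^3 per voxel) per day; `ecm_act_gain` scales it with growth
#'   factor.
#' @param ecm_act_gain see above.
#' @param mcp1_secretion,sasp_secretion,gf_secretion,mmp_secretion,timp_secretion
#'   secretion rates, concentration units/day per cell.
#' @param recruit_rate macrophage influx, cells/day per unit MCP-1 per
#'   alveolus; zero influx at baseline (zero) MCP-1.
#' @param mac_lifespan_days mean residence time of recruited
#'   (monocyte-derived) macrophages; resident macrophages are permanent, so
#'   the homeostatic counts are unaffected.
#' @param mac_cap_factor cap on macrophages per alveolus as a multiple of
#'   the homeostatic count.
#' @param phagocytic_fraction fraction of macrophages able to phagocytose.
#' @param phagocytic_index maximum senescent cells cleared per macrophage.
#' @param cell_jitter placement offset of newborn cells, um.
#' @return list of class `behavior_config`.
#' @export
behavior_config <- function(dt = 20,
                            speed_mac = 1.0, speed_mes = 0.3,
                            speed_epi = 0.2, speed_impaired = 0.1,
                            immobility_prob = 0.5,
                            neighbor_radius = 40, sense_radius = 30,
                            contact_range = 20,
                            bystander_threshold = 2L, bystander_k = 2e-8,
                            bystander_fade = 0.05,
                            damaged_to_senescent_rate = 0.3,
                            apoptotic_removal_mean_steps = 2160,
                            aec1_death_rate = 0.01, aec2_death_rate = 0.004,
                            aec2_prolif_rate = 0.01, aec2_diff_rate = 0.006,
                            repop_gain = 20, repop_K = 1,
                            n_aec1_target = 60, n_aec2_target = 100,
                            n_fib_target = 20,
                            fib_prolif_rate = 5e-4, fib_death_rate = 5e-4,
                            fib_gf_gain = 5, fib_dis_gain = 2,
                            act_rate = 0.3, act_gf_w = 1, act_dis_w = 0.5,
                            dis_deadzone = 0.1,
                            gf_K = 0.5, mcp_K = 0.1,
                            myo_ecm_secretion = 0.02, ecm_act_gain = 10,
                            mcp1_secretion = 2, sasp_secretion = 1,
                            gf_secretion = 1, mmp_secretion = 1,
                            timp_secretion = 1,
                            recruit_rate = 10, mac_lifespan_days = 5,
                            mac_cap_factor = 4,
                            phagocytic_fraction = 1, phagocytic_index = 1L,
                            cell_jitter = 5) {
  cfg <- as.list(environment())
  rates <- cfg[grepl("rate|secretion|_k$", names(cfg))]
  if (any(unlist(rates) < 0)) stop("all rates must be >= 0")
  if (phagocytic_index < 1) stop("phagocytic_index must be >= 1")
  if (phagocytic_fraction < 0 || phagocytic_fraction > 1)
    stop("phagocytic_fraction must be in [0, 1]")
  if (bystander_threshold < 1) stop("bystander_threshold must be >= 1")
  structure(cfg, class = "behavior_config")
}

#' Create a live world from a segment geometry
#'
#' Couples the static geometry to a diffusion grid and the behavior
#' configuration. Homeostatic per-alveolus targets are taken from the
#' geometry's own config when present. Macrophages are marked phagocytic
#' with probability `phagocytic_fraction` and given `phagocytic_index`
#' clearance capacity. The ECM field is initialized at its analytic
#' homeostatic steady state (total deposition / decay, spread uniformly):
#' the grid-mean ECM concentration is then stationary from step one.
#'
#' @param geometry a `segment_geometry`.
#' @param grid a `diffusion_grid` covering the same world (default: 8 voxels
#'   per axis).
#' @param config a [behavior_config()].
#' @param init_ecm_baseline initialize the ECM steady state (disable for
#'   zero-substance experiments).
#' @return object of class `alveolar_world`.
#' @export
new_world <- function(geometry, grid = NULL, config = behavior_config(),
                      init_ecm_baseline = TRUE) {
  if (is.null(grid))
    grid <- diffusion_grid(n = 8L, world_side = geometry$world_side)
  if (!identical(grid$substances$name, substance_defaults()$name))
    stop("the engine requires the standard substance set (in order)")
  if (!is.null(geometry$config)) {
    cnt <- geometry$config$counts
    config$n_aec1_target <- unname(cnt[["AEC1"]])
    config$n_aec2_target <- unname(cnt[["AEC2"]])
    config$n_fib_target <- unname(cnt[["fibroblast"]])
    config$mac_cap <- config$mac_cap_factor *
      (cnt[["M1"]] + cnt[["M2"]])
  } else {
    config$mac_cap <- config$mac_cap_factor * 12
  }
  cells <- geometry$cells
  is_mac <- cells$type %in% c("M1", "M2")
  phago_left <- rep(-1L, nrow(cells))
  if (any(is_mac))
    phago_left[is_mac] <- ifelse(
      stats::runif(sum(is_mac)) < config$phagocytic_fraction,
      as.integer(config$phagocytic_index), -1L)
  # non-phagocytic macrophages carry -1 (patrol only); exhausted ones leave
  agents <- list(
    id = as.integer(cells$cell_id),
    type = unname(TYPE_CODE[cells$type]),
    state = unname(STATE_CODE[cells$state]),
    alv = as.integer(cells$alveolus_id),
    x = cells$x, y = cells$y, z = cells$z,
    radius = cells$radius,
    byst = as.integer(cells$bystander_steps),
    phago_left = phago_left,
    removal = as.integer(cells$removal_steps),
    phag_n = as.integer(cells$phagocytosed)
  )
  world <- structure(list(
    agents = agents, alveoli = geometry$alveoli, shells = geometry$shells,
    grid = grid, config = config, clock = 0,
    next_id = if (nrow(cells)) max(cells$cell_id) + 1L else 1L,
    envelope_side = geometry$envelope_side,
    world_side = geometry$world_side,
    geometry_config = geometry$config,
    series = NULL
  ), class = "alveolar_world")
  if (init_ecm_baseline) {
    n_myo <- sum(agents$type == TYPE_CODE[["myofibroblast"]])
    decay_day <- grid$substances$decay[grid$substances$name == "ECM"] * 86400
    if (n_myo > 0 && decay_day > 0) {
      base <- n_myo * config$myo_ecm_secretion / (decay_day * nrow(grid$conc))
      world$grid$conc[, "ECM"] <- base
    }
  }
  world
}

#' @export
print.alveolar_world <- function(x, ...) {
  cat(sprintf("Alveolar world: %d agents, %d alveoli, day %.2f\n",
              length(x$agents$id), nrow(x$alveoli),
              x$clock * x$config$dt / 86400))
  print(world_counts(x))
  invisible(x)
}

#' Population counts by type and state
#' @param world an `alveolar_world`.
#' @return named integer vector (AEC2 split by state).
#' @export
world_counts <- function(world) {
  a <- world$agents
  c(AEC1 = sum(a$type == 1L),
    AEC2_healthy = sum(a$type == 2L & a$state == 0L),
    AEC2_damaged = sum(a$type == 2L & a$state == 1L),
    AEC2_senescent = sum(a$type == 2L & a$state == 2L),
    AEC2_apoptotic = sum(a$type == 2L & a$state == 3L),
    fibroblast = sum(a$type == 3L),
    myofibroblast = sum(a$type == 4L),
    M1 = sum(a$type == 5L),
    M2 = sum(a$type == 6L))
}

series_colnames <- function(world) {
  c("step", "AEC1", "AEC2_healthy", "AEC2_damaged", "AEC2_senescent",
    "AEC2_apoptotic", "fibroblast", "myofibroblast", "M1", "M2",
    "fsu_surviving", "births", "removals",
    paste0("mean_", world$grid$substances$name))
}

#' Advance the world
#'
#' Runs `n_steps` 20 s updates. Each step executes, in fixed order:
#' substance secretion, the FTCS diffusion/decay/coupling update, bystander
#' exposure accounting and conversion, damaged -> senescent conversion,
#' apoptotic countdown and removal, phagocytosis, MCP-1-driven macrophage
#' recruitment, epithelial repopulation, mesenchymal dynamics, then
#' migration with shell projection. Bit-reproducible given `seed`.
#'
#' @param world an `alveolar_world`.
#' @param n_steps number of 20 s steps.
#' @param seed integer seed of the engine's own random stream (drawn from
#'   the R session RNG when omitted).
#' @param record_every cadence (steps) of the time-series rows (0 = only
#'   first/last).
#' @param phases character vector of behaviors to execute ("all" or any
#'   subset of secrete, diffuse, bystander, senesce, apoptotic, phagocytose,
#'   recruit, repopulate, mesenchymal, migrate) - used to exercise a single
#'   behavior in isolation.
#' @return the updated world; `world$series` accumulates the recorded
#'   time series (one row per record with per-type counts, FSU survival,
#'   cumulative births/removals and mean concentrations).
#' @export
run_world <- function(world, n_steps, seed = NULL, record_every = 4320L,
                      phases = "all") {
  stopifnot(inherits(world, "alveolar_world"), n_steps >= 0)
  if (is.null(seed))
    seed <- sample.int(.Machine$integer.max, 1)
  if (n_steps == 0) return(world)
  cm <- coupling_matrix(world$grid)
  cfg <- world$config
  cfg$mac_cap <- cfg$mac_cap %||% (cfg$mac_cap_factor * 12)
  cfg$mac_lifespan_steps <- cfg$mac_lifespan_days * 86400 / cfg$dt
  res <- cpp_run_world(
    world$agents, as.list(world$alveoli), unname(world$shells),
    world$grid$conc, world$grid$n, world$grid$h, world$grid$origin,
    world$grid$substances$D, world$grid$substances$decay,
    as.integer(cm[, 1]), as.integer(cm[, 2]),
    if (nrow(cm)) world$grid$couplings$k else numeric(),
    as.integer(cm[, 3]), world$grid$ecm_sat,
    world$next_id, cfg, as.integer(n_steps), as.numeric(seed),
    world$clock, as.integer(record_every), phases)
  world$agents <- res$agents
  colnames(res$conc) <- world$grid$substances$name
  world$grid$conc <- res$conc
  world$next_id <- res$next_id
  world$clock <- res$clock
  ser <- as.data.frame(res$series)
  names(ser) <- series_colnames(world)
  ser$day <- ser$step * world$config$dt / 86400
  world$series <- rbind(world$series, ser)
  world
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname run_world
#' @export
step_world <- function(world, seed = NULL) {
  run_world(world, 1L, seed = seed, record_every = 1L)
}

# --- single-behavior entry points (one 20 s step of just that behavior) ----

#' Individual engine behaviors
#'
#' Each function executes one 20 s step of a single behavior on the world
#' (the same compiled code the full step loop runs): bystander exposure
#' accounting and conversion, damaged -> senescent conversion, apoptotic
#' removal, phagocytosis, MCP-1-driven recruitment, epithelial
#' repopulation, mesenchymal dynamics and migration.
#'
#' @param world an `alveolar_world`.
#' @param seed engine stream seed.
#' @param n_steps steps to run.
#' @return the updated world.
#' @export
bystander_update <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "bystander")

#' @rdname bystander_update
#' @export
senesce_damaged <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "senesce")

#' @rdname bystander_update
#' @export
remove_apoptotic <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "apoptotic")

#' @rdname bystander_update
#' @export
phagocytose <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "phagocytose")

#' @rdname bystander_update
#' @export
recruit_macrophages <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "recruit")

#' @rdname bystander_update
#' @export
repopulate_epithelium <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "repopulate")

#' @rdname bystander_update
#' @export
mesenchymal_dynamics <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "mesenchymal")

#' @rdname bystander_update
#' @export
migrate_agents <- function(world, seed = NULL, n_steps = 1L)
  run_world(world, n_steps, seed, record_every = 0L, phases = "migrate")

#' Geodesic random-arc migration (single position)
#'
#' Moves a point on its spherical shell along a great-circle arc of exactly
#' `arc_length` in a random (or given) tangent direction - the elementary
#' move of macrophages and mesenchymal cells.
#'
#' @param position length-3 position on the shell, um.
#' @param center shell center.
#' @param arc_length commanded geodesic displacement, um.
#' @param direction optional length-3 direction whose tangential component
#'   sets the movement direction (random when NULL).
#' @return the new position (same shell radius).
#' @export
migrate_random_arc <- function(position, center, arc_length,
                               direction = NULL) {
  d <- position - center
  R <- sqrt(sum(d^2))
  if (R <= 0) stop("position coincides with the shell center")
  if (arc_length == 0) return(position)
  if (is.null(direction)) {
    zc <- stats::runif(1, -1, 1)
    ph <- stats::runif(1, 0, 2 * pi)
    sc <- sqrt(1 - zc^2)
    direction <- c(sc * cos(ph), sc * sin(ph), zc)
  }
  t <- direction - sum(direction * d) / R^2 * d
  tn <- sqrt(sum(t^2))
  if (tn < 1e-12) stop("direction has no tangential component")
  t <- t / tn
  th <- arc_length / R
  center + cos(th) * d + sin(th) * R * t
}

#' Neighborhood-informed epithelial migration (single cell)
#'
#' AEC1/AEC2 move preferentially towards depleted zones: the step direction
#' is the net repulsion from epithelial neighbors within the sensing
#' radius; with no neighbors (or a balanced neighborhood) the move falls
#' back to a random arc.
#'
#' @param world an `alveolar_world`.
#' @param cell_id id of an AEC1/AEC2 agent.
#' @return the new position of that cell, um (the world is not modified).
#' @export
migrate_informed <- function(world, cell_id) {
  a <- world$agents
  i <- match(cell_id, a$id)
  if (is.na(i) || !a$type[i] %in% c(1L, 2L))
    stop("cell_id is not an epithelial agent")
  p <- c(a$x[i], a$y[i], a$z[i])
  alv <- a$alv[i]
  k <- which(a$alv == alv & a$type %in% c(1L, 2L) & a$state != 3L &
               a$id != cell_id)
  dir <- c(0, 0, 0)
  if (length(k)) {
    dx <- p[1] - a$x[k]; dy <- p[2] - a$y[k]; dz <- p[3] - a$z[k]
    dd <- sqrt(dx^2 + dy^2 + dz^2)
    sel <- dd > 1e-9 & dd < world$config$sense_radius
    if (any(sel))
      dir <- c(sum(dx[sel] / dd[sel]), sum(dy[sel] / dd[sel]),
               sum(dz[sel] / dd[sel]))
  }
  ctr <- unlist(world$alveoli[world$alveoli$id == alv, c("cx", "cy", "cz")])
  speed <- world$config$speed_epi
  if (sqrt(sum(dir^2)) < 1e-6)
    migrate_random_arc(p, ctr, speed)
  else
    migrate_random_arc(p, ctr, speed, direction = dir)
}

#' Rebuild a segment geometry from the live world
#'
#' Used to hand the evolved structure back to the irradiator between
#' fractions.
#'
#' @param world an `alveolar_world`.
#' @return a `segment_geometry`.
#' @export
world_to_geometry <- function(world) {
  a <- world$agents
  type <- names(TYPE_CODE)[a$type]
  cells <- data.frame(
    cell_id = a$id, alveolus_id = a$alv, type = type,
    state = names(STATE_CODE)[a$state + 1L],
    x = a$x, y = a$y, z = a$z, radius = a$radius,
    shell = unname(shell_of_type(type)),
    phagocytosed = a$phag_n, bystander_steps = a$byst,
    removal_steps = a$removal)
  structure(list(alveoli = world$alveoli, cells = cells,
                 shells = world$shells,
                 envelope_side = world$envelope_side,
                 world_side = world$world_side,
                 config = world$geometry_config),
            class = "segment_geometry")
}

#' Apply assigned fates to the world
#'
#' Sets the state of each listed AEC2 to its drawn fate. Apoptotic cells get
#' their Poisson removal delay on the next engine step; movement is disabled
#' for them from this moment.
#'
#' @param world an `alveolar_world`.
#' @param fates data.frame from [assign_fates()].
#' @return the updated world.
#' @export
apply_fates <- function(world, fates) {
  i <- match(fates$cell_id, world$agents$id)
  if (anyNA(i)) stop("fate table references unknown agents")
  world$agents$state[i] <- unname(STATE_CODE[fates$fate])
  world$agents$removal[i][fates$fate == "apoptotic"] <- -1L
  world
}

#' Homeostasis gate
#'
#' Runs the undamaged world for `days` and reports the relative drift of
#' every per-type population count and of every substance's mean
#' concentration (absolute drift for substances at zero baseline). The gate
#' passes when all drifts stay within `tolerance`.
#'
#' @param world a freshly built `alveolar_world`.
#' @param days simulated days (20 in the tuning procedure).
#' @param seed engine seed.
#' @param tolerance relative drift tolerance (default 5%).
#' @return list with `pass`, `count_drift`, `conc_drift`, `world`.
#' @export
run_homeostasis_check <- function(world, days = 20, seed = NULL,
                                  tolerance = 0.05) {
  n_steps <- round(days * 86400 / world$config$dt)
  type_totals <- function(w) {
    # per-type totals; apoptotic cells in removal transit are part of the
    # population's normal turnover, not drift
    a <- w$agents
    vapply(names(TYPE_CODE),
           function(t) sum(a$type == TYPE_CODE[[t]]), numeric(1))
  }
  c0 <- type_totals(world)
  m0 <- grid_mean_concentration(world$grid)
  world <- run_world(world, n_steps, seed = seed)
  c1 <- type_totals(world)
  m1 <- grid_mean_concentration(world$grid)
  # compare populations present at baseline; states at zero stay zero
  nz <- c0 > 0
  count_drift <- rep(0, length(c0))
  names(count_drift) <- names(c0)
  count_drift[nz] <- (c1[nz] - c0[nz]) / c0[nz]
  count_drift[!nz] <- ifelse(c1[!nz] > 0, Inf, 0)
  cz <- m0 > 1e-15
  conc_drift <- numeric(length(m0))
  names(conc_drift) <- names(m0)
  conc_drift[cz] <- (m1[cz] - m0[cz]) / m0[cz]
  conc_drift[!cz] <- ifelse(m1[!cz] > 1e-12, Inf, 0)
  list(pass = all(abs(count_drift) <= tolerance) &&
         all(abs(conc_drift) <= tolerance),
       count_drift = count_drift, conc_drift = conc_drift, world = world)
}
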