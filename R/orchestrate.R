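# Control layer: homeostatic preparation, fraction loops, replicate
# campaigns and the targeted sensitivity suite.

#' Simulation profiles
#'
#' A profile bundles the geometry, grid resolution and horizon of a study.
#' `default_profile()` is the full-scale configuration: the 18-alveoli
#' segment, 1200-day horizon (5,184,000 steps of 20 s) with the early ECM
#' component read at day 90. `scaled_profile()` is the test-scale
#' configuration exercising the complete workflow in minutes: 3 alveoli with
#' reduced cell counts, a 250-um diffusion grid and a 30-day horizon with
#' the early component at day 10 (problem-size choices are discussed in the
#' methods vignette).
#'
#' @param horizon_days simulated days after the (last) fraction.
#' @param early_day day of the early ECM readout.
#' @return list of class `sim_profile`.
#' @export
default_profile <- function(horizon_days = 1200, early_day = 90) {
  structure(list(
    geometry = geometry_config(),
    grid_n = 20L,
    engine = behavior_config(),
    horizon_days = horizon_days, early_day = early_day,
    n_replicates = 10L,
    prepare_steps = 1000L
  ), class = "sim_profile")
}

#' @rdname default_profile
#' @export
scaled_profile <- function(horizon_days = 30, early_day = 10) {
  structure(list(
    geometry = geometry_config(
      n_layers = 1L, alveoli_per_layer = 3L,
      counts = c(AEC1 = 24L, AEC2 = 40L, fibroblast = 10L,
                 myofibroblast = 3L, M1 = 4L, M2 = 4L)),
    grid_n = 8L,
    engine = behavior_config(n_aec1_target = 24, n_aec2_target = 40,
                             n_fib_target = 10, neighbor_radius = 45),
    horizon_days = horizon_days, early_day = early_day,
    n_replicates = 5L,
    prepare_steps = 1000L
  ), class = "sim_profile")
}

#' Run configuration for a fractionation scheme
#'
#' @param n_fractions number of fractions (>= 1).
#' @param dose_per_fraction prescribed mean epithelial dose per fraction,
#'   Gy.
#' @param interval_hours time simulated in the engine after each fraction
#'   of a multi-fraction scheme (single fractions are instantaneous).
#' @param n_replicates independent repeats (fresh seed each).
#' @param seed master seed.
#' @param profile a [default_profile()] / [scaled_profile()].
#' @param preset dose-distribution preset name (see [dose_preset()]).
#' @param lq LQ radiosensitivity, see [lq_params()].
#' @param fate fate configuration, see [fate_config()].
#' @return list of class `run_config`; `total_dose` is
#'   `n_fractions * dose_per_fraction`.
#' @export
run_config <- function(n_fractions = 1L, dose_per_fraction = 10,
                       interval_hours = 24, n_replicates = NULL,
                       seed = 1L, profile = scaled_profile(),
                       preset = "photon_10keV", lq = lq_params(),
                       fate = fate_config()) {
  stopifnot(n_fractions >= 1L, dose_per_fraction >= 0, interval_hours > 0)
  structure(list(
    n_fractions = as.integer(n_fractions),
    dose_per_fraction = dose_per_fraction,
    total_dose = n_fractions * dose_per_fraction,
    interval_hours = interval_hours,
    n_replicates = as.integer(n_replicates %||% profile$n_replicates),
    seed = as.integer(seed), profile = profile, preset = preset,
    lq = lq, fate = fate
  ), class = "run_config")
}

#' Fraction schedule
#'
#' One engine block of `interval_hours` follows each fraction of a
#' multi-fraction scheme (5 fractions at 24 h add 5 simulated days before
#' the long run); a single fraction is delivered instantaneously and adds no
#' engine time.
#'
#' @param config a [run_config()].
#' @return data.frame with `fraction`, `delivery_step`,
#'   `engine_steps_after`.
#' @export
schedule_fractions <- function(config) {
  dt <- config$profile$engine$dt
  block <- if (config$n_fractions == 1L) 0L else
    as.integer(round(config$interval_hours * 3600 / dt))
  data.frame(
    fraction = seq_len(config$n_fractions),
    delivery_step = (seq_len(config$n_fractions) - 1L) * block,
    engine_steps_after = rep(block, config$n_fractions))
}

#' Prepare the homeostatic world
#'
#' Builds the segment and runs the preparatory engine block (1000 steps by
#' default) that settles the structure in healthy conditions; no external
#' data are needed. The returned list carries the world and the baseline
#' grid-mean ECM used by [delta_ecm()].
#'
#' @param profile a simulation profile.
#' @param seed master seed (drives both cell placement and the engine
#'   stream).
#' @return list with `world` and `baseline_ecm`.
#' @export
prepare_homeostatic_world <- function(profile = scaled_profile(), seed = 1L) {
  set.seed(seed)
  geom <- build_segment(profile$geometry)
  grid <- diffusion_grid(n = profile$grid_n,
                         world_side = profile$geometry$world_side)
  world <- new_world(geom, grid, profile$engine)
  world <- run_world(world, profile$prepare_steps,
                     seed = derive_seed(seed, 0L), record_every = 0L)
  list(world = world,
       baseline_ecm = unname(grid_mean_concentration(world$grid)[["ECM"]]))
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * k) %% 2147483629 + 1)
}

#' Deliver one fraction to the live world
#'
#' Freezes the system, hands the evolved structure to the irradiator,
#' scales the sampled doses so the mean epithelial dose matches the
#' prescription, draws the LQ fates and applies them. Instantaneous with
#' respect to the engine clock.
#'
#' @param world an `alveolar_world`.
#' @param dose_gy prescribed mean epithelial dose, Gy.
#' @param params a [distribution_params()] (or a [dose_preset()] name).
#' @param lq,fate see [lq_params()], [fate_config()].
#' @return list with the updated `world`, the scaled dose `report` and the
#'   `fates` table.
#' @export
deliver_fraction <- function(world, dose_gy, params = "photon_10keV",
                             lq = lq_params(), fate = fate_config()) {
  if (is.character(params)) params <- dose_preset(params)
  geom <- world_to_geometry(world)
  report <- sample_parametric_doses(geom, params)
  if (dose_gy > 0) {
    epi <- report$per_cell$epithelial
    f <- compute_scale_factor(report$per_cell$dose[epi], dose_gy)
    report$per_cell$dose <- report$per_cell$dose * f
    report$per_alveolus <- score_per_alveolus(report$per_cell, geom)
  } else {
    report$per_cell$dose <- 0
  }
  fates <- assign_fates(report, geom, lq, fate)
  hit <- fates[fates$fate != "healthy", , drop = FALSE]
  if (nrow(hit)) world <- apply_fates(world, hit)
  list(world = world, report = report, fates = fates)
}

#' Run one replicate of a fractionation scheme
#'
#' Executes the fraction loop on a copy of the prepared world, then the
#' long engine run, and reads the outcomes: early/late ΔECM, FSU survival
#' and the severity index.
#'
#' @param prepared output of [prepare_homeostatic_world()].
#' @param config a [run_config()].
#' @param replicate replicate index (seeds are derived from
#'   `config$seed` and this index).
#' @return one-row data.frame of outcomes.
#' @export
run_scheme <- function(prepared, config, replicate = 1L) {
  world <- prepared$world
  # the run follows the config's engine parameters; keep the world-derived
  # homeostatic targets and macrophage cap computed at construction
  eng <- config$profile$engine
  for (f in c("mac_cap", "n_aec1_target", "n_aec2_target", "n_fib_target"))
    eng[[f]] <- world$config[[f]]
  world$config <- eng
  sched <- schedule_fractions(config)
  rseed <- derive_seed(config$seed, 1000L + replicate)
  set.seed(rseed)  # drives dose sampling + fate draws
  k <- 0L
  for (f in seq_len(config$n_fractions)) {
    dl <- deliver_fraction(world, config$dose_per_fraction, config$preset,
                           config$lq, config$fate)
    world <- dl$world
    if (sched$engine_steps_after[f] > 0) {
      k <- k + 1L
      world <- run_world(world, sched$engine_steps_after[f],
                         seed = derive_seed(rseed, k), record_every = 0L)
    }
  }
  dt <- world$config$dt
  early_steps <- as.integer(round(config$profile$early_day * 86400 / dt))
  late_steps <- as.integer(round(
    (config$profile$horizon_days - config$profile$early_day) * 86400 / dt))
  world <- run_world(world, early_steps, seed = derive_seed(rseed, 98L),
                     record_every = 0L)
  de_early <- delta_ecm(world, prepared$baseline_ecm)
  world <- run_world(world, late_steps, seed = derive_seed(rseed, 99L),
                     record_every = 0L)
  de_late <- delta_ecm(world, prepared$baseline_ecm)
  sf <- fsu_survival(world)
  vol <- segment_volume(world)
  data.frame(total_dose = config$total_dose,
             dose_per_fraction = config$dose_per_fraction,
             fractions = config$n_fractions, replicate = replicate,
             seed = rseed,
             delta_ecm_early = de_early, delta_ecm_late = de_late,
             fsu_survival = sf,
             rsi = rsi(de_late, sf, vol))
}

#' Run a replicate campaign over a dose grid
#'
#' For every total dose and replicate: fresh seed, irradiation of the
#' prepared structure, fraction loop, long run and outcome extraction.
#' Returns the raw per-replicate rows, the aggregated dose-response table
#' (mean and SEM over replicates) and a manifest of the run.
#'
#' @param doses_per_fraction vector of per-fraction doses, Gy.
#' @param config a [run_config()] (its `dose_per_fraction` is overridden by
#'   each grid point).
#' @param prepared optionally, a pre-built [prepare_homeostatic_world()]
#'   output to reuse across campaigns.
#' @return list of class `campaign_result` with `rows`, `table`,
#'   `baseline_ecm`, `manifest`.
#' @export
run_campaign <- function(doses_per_fraction, config = run_config(),
                         prepared = NULL) {
  if (is.null(prepared))
    prepared <- prepare_homeostatic_world(config$profile, config$seed)
  rows <- list()
  for (d in doses_per_fraction) {
    cfg_d <- config
    cfg_d$dose_per_fraction <- d
    cfg_d$total_dose <- d * config$n_fractions
    for (r in seq_len(config$n_replicates)) {
      rows[[length(rows) + 1L]] <- run_scheme(prepared, cfg_d, r)
    }
  }
  rows <- do.call(rbind, rows)
  structure(list(
    rows = rows, table = aggregate_dose_response(rows),
    baseline_ecm = prepared$baseline_ecm,
    manifest = list(
      n_fractions = config$n_fractions,
      total_doses = doses_per_fraction * config$n_fractions,
      interval_hours = config$interval_hours,
      n_replicates = config$n_replicates, seed = config$seed,
      preset = config$preset,
      lq = unclass(config$lq),
      horizon_days = config$profile$horizon_days)
  ), class = "campaign_result")
}

#' @export
print.campaign_result <- function(x, ...) {
  cat(sprintf("Campaign: %d fraction(s), %d replicate(s), preset %s\n",
              x$manifest$n_fractions, x$manifest$n_replicates,
              x$manifest$preset))
  print(x$table, digits = 4)
  invisible(x)
}

#' Targeted sensitivity suite
#'
#' Runs the damage-associated perturbations against the standard
#' configuration on a shared dose grid: bystander threshold lowered from 2
#' to 1, halved damaged-to-senescent rate, and 10% lower radiosensitivity
#' (alpha and beta scaled by 0.9).
#'
#' @param doses_per_fraction shared dose grid, Gy.
#' @param config base [run_config()] (standard conditions).
#' @param variants subset of `c("standard", "threshold1", "half_senescence",
#'   "low_radiosensitivity")`.
#' @return named list of `campaign_result`s.
#' @export
sensitivity_suite <- function(doses_per_fraction, config = run_config(),
                              variants = c("standard", "threshold1",
                                           "half_senescence",
                                           "low_radiosensitivity")) {
  variants <- match.arg(variants, several.ok = TRUE)
  prepared <- prepare_homeostatic_world(config$profile, config$seed)
  out <- list()
  for (v in variants) {
    cfg <- config
    if (v == "threshold1") {
      cfg$profile$engine$bystander_threshold <- 1L
    } else if (v == "half_senescence") {
      cfg$profile$engine$damaged_to_senescent_rate <-
        config$profile$engine$damaged_to_senescent_rate / 2
    } else if (v == "low_radiosensitivity") {
      cfg$lq <- lq_params(config$lq$alpha, config$lq$beta, sensitivity = 0.9)
    }
    out[[v]] <- run_campaign(doses_per_fraction, cfg, prepared = prepared)
  }
  out
}
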