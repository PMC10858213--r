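# Engine behaviors, each exercised in isolation through the phase interface,
# plus the step-loop invariants.

test_that("random-arc migration moves by exactly the commanded arc", {
  ctr <- c(5, -2, 8); R <- 130
  p <- ctr + c(R, 0, 0)
  expect_equal(migrate_random_arc(p, ctr, 0), p)
  set.seed(1)
  for (arc in c(0.5, 5, 40)) {
    q <- migrate_random_arc(p, ctr, arc)
    expect_equal(sqrt(sum((q - ctr)^2)), R, tolerance = 1e-9)
    # great-circle oracle: geodesic = R * angle between the radial vectors
    ang <- acos(min(1, sum((p - ctr) * (q - ctr)) / R^2))
    expect_equal(R * ang, arc, tolerance = 1e-6)
  }
})

test_that("repeated random arcs cover the sphere", {
  ctr <- c(0, 0, 0); R <- 100
  set.seed(2)
  p <- ctr + c(R, 0, 0)
  zs <- replicate(4000, {
    q <- p
    for (i in 1:8) q <- migrate_random_arc(q, ctr, 60)
    q[3] / R
  })
  # area-uniform coverage: z/R is Uniform(-1, 1)
  expect_lt(abs(mean(zs)), 3 / sqrt(12 * 4000) * 2)
  expect_gt(min(zs), -1); expect_lt(max(zs), 1)
  expect_gt(stats::sd(zs), 0.45)  # not stuck near the start
})

test_that("informed migration heads toward the depleted cap", {
  # all epithelial neighbors packed on one side: the step must move away
  w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 20L, fibroblast = 0L,
                             myofibroblast = 0L, M1 = 0L, M2 = 0L))
  ctr <- unlist(w$alveoli[1, c("cx", "cy", "cz")])
  R <- w$shells[["middle"]]
  w <- place_on_middle_shell(w, 1, arc = 0)
  for (i in 2:20) w <- place_on_middle_shell(w, i, arc = 10 + i)
  p0 <- c(w$agents$x[1], w$agents$y[1], w$agents$z[1])
  set.seed(3)
  reps <- t(replicate(30, migrate_informed(w, 1)))
  # neighbors sit at increasing +y arcs; depletion is toward -y
  expect_true(all(reps[, 2] - p0[2] < 0))
  # empty neighborhood falls back to a random arc of the right length
  w2 <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 1L, fibroblast = 0L,
                              myofibroblast = 0L, M1 = 0L, M2 = 0L))
  q <- migrate_informed(w2, 1)
  d0 <- c(w2$agents$x[1], w2$agents$y[1], w2$agents$z[1]) - ctr
  ang <- acos(min(1, sum(d0 * (q - ctr)) / R^2))
  expect_equal(R * ang, w2$config$speed_epi, tolerance = 1e-6)
})

test_that("all agents stay on their shells through full steps", {
  set.seed(4)
  g <- build_segment(geometry_config(
    n_layers = 1L, alveoli_per_layer = 2L,
    counts = c(AEC1 = 10L, AEC2 = 15L, fibroblast = 5L, myofibroblast = 2L,
               M1 = 3L, M2 = 3L)))
  w <- new_world(g)
  w <- run_world(w, 200, seed = 11, record_every = 0)
  a <- w$agents
  ctr <- w$alveoli[match(a$alv, w$alveoli$id), c("cx", "cy", "cz")]
  d <- sqrt((a$x - ctr$cx)^2 + (a$y - ctr$cy)^2 + (a$z - ctr$cz)^2)
  shell <- c("middle", "middle", "outer", "outer", "inner", "inner")[a$type]
  expect_lt(max(abs(d - w$shells[shell])), 1e-6)
})

test_that("engine runs are bit-reproducible for a fixed seed", {
  w <- tiny_world(counts = c(AEC1 = 10L, AEC2 = 20L, fibroblast = 5L,
                             myofibroblast = 2L, M1 = 3L, M2 = 3L))
  a <- run_world(w, 300, seed = 77, record_every = 0)
  b <- run_world(w, 300, seed = 77, record_every = 0)
  expect_identical(a$agents, b$agents)
  expect_identical(a$grid$conc, b$grid$conc)
  c2 <- run_world(w, 300, seed = 78, record_every = 0)
  expect_false(identical(a$agents$x, c2$agents$x))
})

test_that("population changes balance the birth/removal ledger", {
  set.seed(5)
  w <- tiny_world(counts = c(AEC1 = 20L, AEC2 = 40L, fibroblast = 10L,
                             myofibroblast = 3L, M1 = 4L, M2 = 4L))
  n0 <- length(w$agents$id)
  w2 <- run_world(w, 3 * 4320, seed = 13, record_every = 4320)
  ser <- w2$series
  expect_true(all(rowSums(ser[, c("AEC1", "AEC2_healthy", "AEC2_damaged",
                                  "AEC2_senescent", "AEC2_apoptotic",
                                  "fibroblast", "myofibroblast",
                                  "M1", "M2")]) ==
                    n0 + ser$births - ser$removals))
})

test_that("with turnover disabled, counts are exactly conserved", {
  # migration only: 3 simulated days leave every population untouched
  w <- tiny_world(counts = c(AEC1 = 10L, AEC2 = 20L, fibroblast = 5L,
                             myofibroblast = 2L, M1 = 3L, M2 = 3L),
                  aec1_death_rate = 0, aec2_death_rate = 0,
                  aec2_prolif_rate = 0, aec2_diff_rate = 0,
                  fib_prolif_rate = 0, fib_death_rate = 0, act_rate = 0)
  c0 <- world_counts(w)
  w <- run_world(w, 3 * 4320, seed = 21, record_every = 0)
  expect_identical(world_counts(w), c0)
})

test_that("bystander threshold gates exposure accounting", {
  mk <- function(thr) {
    w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 10L, fibroblast = 0L,
                               myofibroblast = 0L, M1 = 0L, M2 = 0L),
                    bystander_threshold = thr, speed_epi = 0,
                    speed_impaired = 0, immobility_prob = 1)
    w$agents$state[1] <- 2L                       # one senescent cell
    w <- place_on_middle_shell(w, 1, arc = 0)
    w <- place_on_middle_shell(w, 2, arc = 10)    # healthy, 10 um away
    for (i in 3:10) w <- place_on_middle_shell(w, i, arc = 200 + 5 * i)
    w
  }
  # threshold 2, one senescent neighbor: counter unchanged
  w <- bystander_update(mk(2L), seed = 1, n_steps = 5)
  expect_equal(max(w$agents$byst), 0L)
  # threshold 1, one senescent neighbor: counter increments every step
  w <- bystander_update(mk(1L), seed = 1, n_steps = 5)
  expect_equal(w$agents$byst[2], 5L)
  expect_equal(sum(w$agents$byst), 5L)
  # a second senescent neighbor satisfies threshold 2
  w2 <- mk(2L)
  w2$agents$state[3] <- 2L
  w2 <- place_on_middle_shell(w2, 3, arc = 15)
  w2 <- bystander_update(w2, seed = 1, n_steps = 5)
  expect_equal(w2$agents$byst[2], 5L)
})

test_that("bystander conversion frequency matches the per-step hazard", {
  w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 4000L, fibroblast = 0L,
                             myofibroblast = 0L, M1 = 0L, M2 = 0L),
                  bystander_k = 2e-8)
  counter <- 5000L
  w$agents$byst[] <- counter   # preset exposure, no senescent cells around
  w <- bystander_update(w, seed = 31, n_steps = 1)
  p <- 2e-8 * counter * 20
  phat <- mean(w$agents$state == 1L)
  expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / 4000))
})

test_that("damaged to senescent conversion is an exponential clock", {
  w0 <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 1000L, fibroblast = 0L,
                              myofibroblast = 0L, M1 = 0L, M2 = 0L),
                   damaged_to_senescent_rate = 0)
  w0$agents$state[] <- 1L
  w <- senesce_damaged(w0, seed = 41, n_steps = 500)
  expect_equal(sum(w$agents$state == 2L), 0L)      # rate 0: no conversions
  mean_conv_steps <- function(rate, seed) {
    w <- w0; w$config$damaged_to_senescent_rate <- rate
    left <- integer(0)
    # step day-by-day and read off the survival curve of the damaged state
    surv <- numeric(12)
    for (d in 1:12) {
      w <- senesce_damaged(w, seed = seed + d, n_steps = 4320)
      surv[d] <- mean(w$agents$state == 1L)
    }
    surv
  }
  s <- mean_conv_steps(0.3, 100)
  expect_equal(s, exp(-0.3 * (1:12)), tolerance = 0.12)
  s2 <- mean_conv_steps(0.6, 200)
  # doubling the rate halves the mean conversion time
  expect_equal(log(s2[4]) / log(s[4]), 2, tolerance = 0.2)
})

test_that("apoptotic removal delay is Poisson and movement is disabled", {
  w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 2000L, fibroblast = 0L,
                             myofibroblast = 0L, M1 = 0L, M2 = 0L),
                  apoptotic_removal_mean_steps = 6)
  w$agents$state[] <- 3L
  x0 <- w$agents$x
  # apoptotic cells never move
  wm <- migrate_agents(w, seed = 51, n_steps = 20)
  expect_identical(wm$agents$x, x0)
  # first apoptotic step draws the delays; removal[i] = draw - 1 afterwards
  w1 <- remove_apoptotic(w, seed = 52, n_steps = 1)
  removed <- 2000 - length(w1$agents$id)
  draws <- c(w1$agents$removal + 1L, rep(0L, removed))
  expect_lt(abs(mean(draws) - 6), 3 * sqrt(6 / 2000))
  # mean 0: everything removed on the next step
  w0 <- w; w0$config$apoptotic_removal_mean_steps <- 0
  w0 <- remove_apoptotic(w0, seed = 53, n_steps = 1)
  expect_length(w0$agents$id, 0L)
})

test_that("macrophage recruitment follows local MCP-1", {
  base <- function(level) {
    w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 5L, fibroblast = 0L,
                               myofibroblast = 0L, M1 = 2L, M2 = 2L),
                    recruit_rate = 50, mac_cap_factor = 100)
    if (level > 0) {
      ctr <- unlist(w$alveoli[1, c("cx", "cy", "cz")])
      w$grid <- grid_deposit(w$grid, ctr, "MCP1", level)
    }
    w
  }
  w <- recruit_macrophages(base(0), seed = 61, n_steps = 1000)
  expect_equal(sum(w$agents$type %in% 5:6), 4L)  # zero influx at baseline
  recruits <- sapply(c(0.5, 2, 8), function(lv) {
    w <- recruit_macrophages(base(lv), seed = 62, n_steps = 800)
    sum(w$agents$type %in% 5:6) - 4L
  })
  expect_true(all(diff(recruits) > 0))  # monotone in MCP-1
  # recruits are placed on the inner shell
  w <- recruit_macrophages(base(5), seed = 63, n_steps = 500)
  a <- w$agents
  ctr <- unlist(w$alveoli[1, c("cx", "cy", "cz")])
  d <- sqrt((a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2)
  expect_lt(max(abs(d[a$type %in% 5:6] - w$shells[["inner"]])), 1e-6)
})

test_that("phagocytosis respects fraction and per-macrophage capacity", {
  mk <- function(frac, index, n_sen = 1L) {
    w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 6L, fibroblast = 0L,
                               myofibroblast = 0L, M1 = 1L, M2 = 0L),
                    phagocytic_fraction = frac,
                    phagocytic_index = index,
                    speed_mac = 0, speed_epi = 0, speed_impaired = 0,
                    immobility_prob = 1, seed = 3)
    # senescent cells stacked next to the macrophage (inner/middle shells
    # are 10 um apart; contact range is 20 um)
    mac <- which(w$agents$type == 5L)
    ctr <- unlist(w$alveoli[1, c("cx", "cy", "cz")])
    R <- w$shells[["inner"]]
    w$agents$x[mac] <- ctr[1] + R; w$agents$y[mac] <- ctr[2]
    w$agents$z[mac] <- ctr[3]
    for (i in seq_len(n_sen)) {
      w$agents$state[i] <- 2L
      w <- place_on_middle_shell(w, i, arc = i)
    }
    for (i in (n_sen + 1):6) w <- place_on_middle_shell(w, i, arc = 300 + i)
    w
  }
  # fraction 0: nothing is removed
  w <- phagocytose(mk(0, 1L, 2L), seed = 71, n_steps = 10)
  expect_equal(sum(w$agents$state == 2L), 2L)
  # fraction 1, index 1, one adjacent senescent: exactly one removal
  w <- phagocytose(mk(1, 1L, 1L), seed = 72, n_steps = 1)
  expect_equal(sum(w$agents$state == 2L), 0L)
  # index 2 removes at most 2 even with 4 adjacent senescent cells
  w0 <- mk(1, 2L, 4L)
  w <- phagocytose(w0, seed = 73, n_steps = 1)
  expect_equal(sum(w0$agents$state == 2L) - sum(w$agents$state == 2L), 2L)
})

test_that("epithelial repopulation responds to the local deficit", {
  mk <- function(n_aec2) {
    w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = n_aec2, fibroblast = 0L,
                               myofibroblast = 0L, M1 = 0L, M2 = 0L),
                    aec1_death_rate = 0, aec2_death_rate = 0,
                    aec2_diff_rate = 0)
    # homeostatic targets are normally derived from the geometry config;
    # pin them so the deficit is controlled by the seeded count alone
    w$config$n_aec1_target <- 0.0001
    w$config$n_aec2_target <- 40
    w
  }
  # fully depleted alveolus never repopulates (absorbing FSU death)
  w <- mk(10L); w$agents$state[] <- 2L
  w <- repopulate_epithelium(w, seed = 81, n_steps = 2000)
  expect_equal(sum(w$agents$state == 0L), 0L)
  expect_length(w$agents$id, 10L)
  # sub-homeostatic density: positive expected net growth
  w <- repopulate_epithelium(mk(10L), seed = 82, n_steps = 3 * 4320)
  expect_gt(length(w$agents$id), 10L)
  # homeostatic density: no systematic growth (births balance, here
  # death/diff are off so growth must be driven by the deficit term only)
  w0 <- mk(40L)
  w <- repopulate_epithelium(w0, seed = 83, n_steps = 4320)
  net <- length(w$agents$id) - 40L
  # at target the regulated prolif is ~base rate: expect about
  # 40 * 0.01 = 0.4 births/day; allow broad slack but no runaway
  expect_lt(net, 5L)
})

test_that("mesenchymal dynamics respond to growth factor", {
  mk <- function(gf) {
    w <- tiny_world(counts = c(AEC1 = 24L, AEC2 = 40L, fibroblast = 20L,
                               myofibroblast = 2L, M1 = 0L, M2 = 0L),
                    n_aec1_target = 24, n_aec2_target = 40)
    if (gf > 0) w$grid$conc[, "TGFB"] <- gf
    w
  }
  # healthy epithelium, baseline growth factor: stationary myofibroblasts
  w <- mesenchymal_dynamics(mk(0), seed = 91, n_steps = 3 * 4320)
  expect_equal(sum(w$agents$type == 4L), 2L)
  # saturating growth factor: fibroblasts activate and proliferate
  w2 <- mesenchymal_dynamics(mk(5), seed = 92, n_steps = 3 * 4320)
  expect_gt(sum(w2$agents$type == 4L), 2L)
  # ECM concentration never exceeds the saturation cap during a loaded run
  w3 <- mk(5)
  w3$agents$type[w3$agents$type == 3L] <- 4L  # all myofibroblasts
  w3 <- run_world(w3, 4320, seed = 93, record_every = 0,
                  phases = c("secrete", "diffuse"))
  expect_lte(max(w3$grid$conc[, "ECM"]), w3$grid$ecm_sat + 1e-12)
})

test_that("damaged and senescent cells move slower than healthy cells", {
  w <- tiny_world(counts = c(AEC1 = 0L, AEC2 = 400L, fibroblast = 0L,
                             myofibroblast = 0L, M1 = 0L, M2 = 0L))
  w$agents$state[1:200] <- 2L
  x0 <- cbind(w$agents$x, w$agents$y, w$agents$z)
  w1 <- migrate_agents(w, seed = 101, n_steps = 1)
  x1 <- cbind(w1$agents$x, w1$agents$y, w1$agents$z)
  step <- sqrt(rowSums((x1 - x0)^2))
  sen <- w$agents$state == 2L
  expect_gt(mean(step[!sen]), mean(step[sen]))
  # some impaired cells do not move at all in a step
  expect_gt(sum(step[sen] == 0), 0)
  expect_equal(sum(step[!sen] == 0), 0)
})
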