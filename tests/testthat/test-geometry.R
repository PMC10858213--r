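test_that("alveolus count and layout follow the configuration", {
  cases <- list(c(3L, 6L), c(1L, 1L), c(2L, 4L), c(1L, 3L))
  for (cs in cases) {
    g <- build_segment(geometry_config(n_layers = cs[1],
                                       alveoli_per_layer = cs[2]))
    expect_equal(nrow(g$alveoli), cs[1] * cs[2])
    # non-overlapping spheres: pairwise center separation >= diameter
    if (nrow(g$alveoli) > 1) {
      d <- as.matrix(dist(g$alveoli[, c("cx", "cy", "cz")]))
      expect_gte(min(d[upper.tri(d)]), g$alveoli$diameter[1] - 1e-9)
    }
    # all alveoli inside the envelope
    expect_lte(max(abs(as.matrix(g$alveoli[, c("cx", "cy", "cz")]))) +
                 g$alveoli$diameter[1] / 2, g$envelope_side / 2 + 1e-9)
  }
  expect_error(build_segment(geometry_config(alveoli_per_layer = 20L)),
               "fit")
})

test_that("default segment has 18 alveoli and the documented sizes", {
  g <- build_segment()
  expect_equal(nrow(g$alveoli), 18L)
  expect_equal(unique(g$alveoli$diameter), 260)
  expect_equal(g$envelope_side, 900)
  expect_equal(g$world_side, 2000)
})

test_that("degenerate configuration yields one alveolus and no cells", {
  g <- build_segment(geometry_config(
    n_layers = 1L, alveoli_per_layer = 1L,
    counts = c(AEC1 = 0L, AEC2 = 0L, fibroblast = 0L, myofibroblast = 0L,
               M1 = 0L, M2 = 0L)))
  expect_equal(nrow(g$alveoli), 1L)
  expect_equal(nrow(g$cells), 0L)
})

test_that("cells sit on their type's shell, area-uniformly", {
  g <- tiny_geometry(counts = c(AEC1 = 0L, AEC2 = 1000L, fibroblast = 0L,
                                myofibroblast = 0L, M1 = 0L, M2 = 0L),
                     seed = 42)
  ctr <- unlist(g$alveoli[1, c("cx", "cy", "cz")])
  # independent distance computation per cell
  d <- sqrt((g$cells$x - ctr[1])^2 + (g$cells$y - ctr[2])^2 +
              (g$cells$z - ctr[3])^2)
  expect_lt(max(abs(d - g$shells[["middle"]])), 1e-6)
  # empirical mean within 3 sigma of the center (sd of a coordinate on a
  # sphere of radius R is R/sqrt(3))
  R <- g$shells[["middle"]]
  se <- R / sqrt(3) / sqrt(1000)
  for (ax in 1:3)
    expect_lt(abs(mean(g$cells[[c("x", "y", "z")[ax]]]) - ctr[ax]), 3 * se)
})

test_that("shell assignment matches cell type", {
  set.seed(7)
  g <- build_segment()
  expect_true(all(g$cells$shell[g$cells$type %in% c("AEC1", "AEC2")] ==
                    "middle"))
  expect_true(all(g$cells$shell[g$cells$type %in%
                                  c("fibroblast", "myofibroblast")] ==
                    "outer"))
  expect_true(all(g$cells$shell[g$cells$type %in% c("M1", "M2")] == "inner"))
  for (s in c("inner", "middle", "outer")) {
    cc <- g$cells[g$cells$shell == s, ]
    ctr <- g$alveoli[match(cc$alveolus_id, g$alveoli$id),
                     c("cx", "cy", "cz")]
    d <- sqrt((cc$x - ctr$cx)^2 + (cc$y - ctr$cy)^2 + (cc$z - ctr$cz)^2)
    expect_lt(max(abs(d - g$shells[[s]])), 1e-6)
  }
})

test_that("build is reproducible for a fixed seed", {
  set.seed(123); g1 <- build_segment()
  set.seed(123); g2 <- build_segment()
  expect_identical(g1, g2)
})

test_that("shell projection rescales radially and preserves angles", {
  ctr <- c(10, -5, 3)
  R <- 130
  # already on the shell: unchanged
  p <- ctr + c(R, 0, 0)
  expect_equal(project_to_shell(p, ctr, R), p)
  # twice the radius along +x: same direction, length R
  expect_equal(project_to_shell(ctr + c(2 * R, 0, 0), ctr, R),
               ctr + c(R, 0, 0))
  # random off-shell points: angles preserved (independent spherical
  # coordinate conversion)
  set.seed(5)
  for (i in 1:50) {
    q <- ctr + stats::rnorm(3) * 50
    pr <- project_to_shell(q, ctr, R)
    v0 <- q - ctr; v1 <- pr - ctr
    expect_equal(sqrt(sum(v1^2)), R, tolerance = 1e-12)
    theta0 <- acos(v0[3] / sqrt(sum(v0^2))); phi0 <- atan2(v0[2], v0[1])
    theta1 <- acos(v1[3] / R); phi1 <- atan2(v1[2], v1[1])
    expect_equal(theta0, theta1, tolerance = 1e-9)
    expect_equal(phi0, phi1, tolerance = 1e-9)
  }
  expect_error(project_to_shell(ctr, ctr, R), "center")
})

test_that("structure export/import round-trips field-for-field", {
  set.seed(9)
  g <- build_segment(geometry_config(n_layers = 1L, alveoli_per_layer = 3L,
    counts = c(AEC1 = 5L, AEC2 = 8L, fibroblast = 3L, myofibroblast = 2L,
               M1 = 1L, M2 = 1L)))
  g$cells$state[3] <- "damaged"
  g$cells$bystander_steps[4] <- 7L
  dir <- withr::local_tempdir()
  export_structure(g, dir)
  g2 <- import_structure(dir)
  expect_equal(g2$alveoli, g$alveoli)
  expect_equal(g2$cells, g$cells, tolerance = 1e-9)
  expect_equal(g2$shells, g$shells)
  expect_equal(g2$envelope_side, g$envelope_side)
})

test_that("empty geometry exports a manifest only", {
  g <- build_segment(geometry_config(
    n_layers = 1L, alveoli_per_layer = 1L,
    counts = c(AEC1 = 0L, AEC2 = 0L, fibroblast = 0L, myofibroblast = 0L,
               M1 = 0L, M2 = 0L)))
  dir <- withr::local_tempdir()
  files <- export_structure(g, dir)
  expect_length(list.files(dir), 1L)
  g2 <- import_structure(dir)
  expect_equal(nrow(g2$cells), 0L)
  expect_equal(nrow(g2$alveoli), 1L)
})

test_that("hand-written structure files parse to the written values", {
  dir <- withr::local_tempdir()
  writeLines(c("# envelope_side 900", "# world_side 2000",
               "# shells 120 130 140",
               "# alveolus_id cx cy cz diameter",
               "1 0 0 0 260"), file.path(dir, "manifest.txt"))
  writeLines(c("1 130 0 0 5 0,0,255 healthy phag=0 byst=0 rem=-1",
               "2 0 130 0 10.5 255,0,0 healthy phag=3 byst=0 rem=-1"),
             file.path(dir, "alveolus_1.txt"))
  g <- import_structure(dir)
  expect_equal(g$cells$cell_id, c(1L, 2L))
  expect_equal(g$cells$type, c("AEC2", "M1"))
  expect_equal(g$cells$x, c(130, 0))
  expect_equal(g$cells$radius, c(5, 10.5))
  expect_equal(g$cells$phagocytosed, c(0L, 3L))
  expect_equal(g$cells$shell, c("middle", "inner"))
})

test_that("malformed structure lines raise errors naming file and line", {
  dir <- withr::local_tempdir()
  writeLines(c("# envelope_side 900", "# world_side 2000",
               "# shells 120 130 140", "1 0 0 0 260"),
             file.path(dir, "manifest.txt"))
  writeLines(c("1 130 0 0 5 0,0,255 healthy phag=0 byst=0 rem=-1",
               "2 oops 0 0 5 0,0,255 healthy phag=0 byst=0 rem=-1"),
             file.path(dir, "alveolus_1.txt"))
  expect_error(import_structure(dir), "alveolus_1.txt:2")
  writeLines("1 2 3", file.path(dir, "alveolus_1.txt"))
  expect_error(import_structure(dir), "alveolus_1.txt:1")
})
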