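# Small fixtures shared across tests; everything is generated in code.

# one alveolus with a chosen cell complement
tiny_geometry <- function(counts = c(AEC1 = 0L, AEC2 = 30L, fibroblast = 0L,
                                     myofibroblast = 0L, M1 = 0L, M2 = 0L),
                          seed = 1) {
  set.seed(seed)
  build_segment(geometry_config(n_layers = 1L, alveoli_per_layer = 1L,
                                counts = counts))
}

tiny_world <- function(counts = c(AEC1 = 0L, AEC2 = 30L, fibroblast = 0L,
                                  myofibroblast = 0L, M1 = 0L, M2 = 0L),
                       seed = 1, ...) {
  g <- tiny_geometry(counts, seed)
  new_world(g, config = behavior_config(...))
}

# place agent i of a world at geodesic arc `arc` from the +x pole of its
# middle shell (convenient for constructing known neighbor layouts)
place_on_middle_shell <- function(world, i, arc = 0) {
  ctr <- unlist(world$alveoli[1, c("cx", "cy", "cz")])
  R <- world$shells[["middle"]]
  th <- arc / R
  world$agents$x[i] <- ctr[1] + R * cos(th)
  world$agents$y[i] <- ctr[2] + R * sin(th)
  world$agents$z[i] <- ctr[3]
  world
}

# grid with a single diffusing, non-decaying substance (plus the standard
# names so the engine checks stay happy where needed)
plain_grid <- function(n = 5, world_side = 100, D = 10, decay = 0,
                       dt = 1) {
  subs <- data.frame(name = "X", D = D, decay = decay)
  diffusion_grid(n = n, world_side = world_side, substances = subs,
                 couplings = data.frame(a = character(), b = character(),
                                        k = numeric(), mode = character()),
                 dt = dt)
}

# dense linear operator of one FTCS diffusion+decay step (independent oracle)
ftcs_dense_operator <- function(n, h, D, decay, dt) {
  nv <- n^3
  idx <- function(i, j, k) 1 + i + n * (j + n * k)  # 0-based ijk
  A <- matrix(0, nv, nv)
  a <- D * dt / h^2
  for (k in 0:(n - 1)) for (j in 0:(n - 1)) for (i in 0:(n - 1)) {
    v <- idx(i, j, k)
    A[v, v] <- 1 - decay * dt
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    for (q in nb) {
      if (all(q >= 0) && all(q < n)) {
        A[v, idx(q[1], q[2], q[3])] <- A[v, idx(q[1], q[2], q[3])] + a
        A[v, v] <- A[v, v] - a
      }
    }
  }
  A
}
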