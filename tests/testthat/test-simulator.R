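# Initialization, forces against the all-pairs oracle, Langevin and
# rigid-body integration. Heavy statistical-mechanics checks live in
# test-acceptance.R; these are the fast module-level versions.

test_that("synapsin count follows the tether-circle rule", {
  expect_equal(synapsin_count(4.17, 0.5, 0), 0L)
  expect_equal(synapsin_count(4.17, 0.5, 0.7), 23L)
  expect_equal(synapsin_count(4.17, 0.5, 0.5), 16L)
  expect_equal(synapsin_count(c(3, 5), 0.5, 0.7),
               as.integer(floor(2 * pi * 2^(1 / 6) * c(3.5, 5.5) * 0.7
                                + 0.5)))
})

test_that("initial configurations are exact and reproducible", {
  cfg <- sim_config(model = "mono", box_length = 60, n_vesicles = 1,
                    vesicle_radius_sd = 0, lambda = 0.7, n_steps = 0,
                    snapshot_interval = 1, seed = 5)
  st <- initialize_configuration(cfg)
  expect_length(st$species, 1 + 23)
  syn <- which(st$species == "synapsin")
  r0 <- 2^(1 / 6) * (4.17 + 0.5)
  d <- sqrt(rowSums((st$positions[syn, , drop = FALSE] -
                     rep(st$positions[1, ], each = 23))^2))
  expect_equal(d, rep(r0, 23), tolerance = 1e-12)
  expect_true(all(st$velocities == 0))

  cfgb <- sim_config(model = "bi", box_length = 60, n_vesicles = 1,
                     vesicle_radius_sd = 0, lambda = 0.7, n_steps = 0,
                     snapshot_interval = 1, seed = 5)
  stb <- initialize_configuration(cfgb)
  expect_length(stb$species, 1 + 46)
  si <- vesicond:::state_internals(stb)
  dn <- si$dimer_n + 1
  dc <- si$dimer_c + 1
  dl <- sqrt(rowSums((stb$positions[dc, ] - stb$positions[dn, ])^2))
  expect_equal(dl, rep(1, 23), tolerance = 1e-9)
  # C bead radially outward from the N bead
  vc <- rep(stb$positions[1, ], each = 23)
  expect_true(all(rowSums((stb$positions[dc, ] - vc)^2) >
                  rowSums((stb$positions[dn, ] - vc)^2)))

  expect_identical(initialize_configuration(cfg),
                   initialize_configuration(cfg))
  tiny <- sim_config(model = "mono", box_length = 15, n_vesicles = 10,
                     n_steps = 0, snapshot_interval = 1)
  expect_error(initialize_configuration(tiny), "placement failure")
})

test_that("neighbor-list forces equal the all-pairs oracle", {
  for (model in c("mono", "bi")) for (seed in 1:3) {
    rs <- random_small_state(model, n_ves = 5, seed = seed)
    got <- compute_forces(rs$state, rs$config)
    want <- brute_forces(rs$state, rs$config)
    expect_equal(got$forces, want$forces, tolerance = 1e-12)
    expect_equal(got$potential_energy, want$potential_energy,
                 tolerance = 1e-12)
    # Newton: conservative forces sum to zero
    expect_lt(max(abs(colSums(got$forces))), 1e-10)
  }
})

test_that("damped free particle decays at the Langevin rate", {
  cfg <- sim_config(model = "mono", box_length = 50, n_vesicles = 1,
                    vesicle_radius_sd = 0, lambda = 0, eps = 0, kBT = 0,
                    dt = 1e-3, n_steps = 0, snapshot_interval = 1, seed = 1)
  st <- initialize_configuration(cfg)
  st$velocities[1, ] <- c(1.5, -0.7)
  v0 <- sqrt(sum(st$velocities[1, ]^2))
  n <- 2000 # t = 2 damping times
  out <- langevin_step(st, cfg, n_steps = n)
  v <- sqrt(sum(out$velocities[1, ]^2))
  expect_equal(v, v0 * exp(-n * cfg$dt / cfg$gamma), tolerance = 0.01)
})

test_that("identical seeds give identical trajectories", {
  cfg <- sim_config(model = "bi", box_length = 60, n_vesicles = 3,
                    lambda = 0.4, eps = 3, n_steps = 500,
                    snapshot_interval = 100, seed = 8)
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$vx, t2$vx)
})

test_that("snapshot bookkeeping", {
  cfg <- sim_config(model = "mono", box_length = 60, n_vesicles = 2,
                    lambda = 0.3, eps = 2, n_steps = 0,
                    snapshot_interval = 100, seed = 2)
  expect_equal(n_snapshots(run_simulation(cfg)), 1)
  cfg$n_steps <- 200
  tr <- run_simulation(validate_config(cfg))
  expect_equal(n_snapshots(tr), 3)
  expect_equal(tr$times, c(0, 100, 200) * cfg$dt)
  # first snapshot is the initial configuration
  st <- initialize_configuration(cfg)
  expect_equal(get_snapshot(tr, 1)$positions, st$positions)
})

test_that("rigid dimers: free translation, free rotation, rigidity", {
  cfg <- sim_config(model = "bi", box_length = 60, n_vesicles = 1,
                    vesicle_radius_sd = 0, lambda = 0.2, eps = 0, kBT = 0,
                    gamma = 1e12, dt = 1e-3, n_steps = 0,
                    snapshot_interval = 1, seed = 1)
  st <- initialize_configuration(cfg)
  si <- vesicond:::state_internals(st)
  dn <- si$dimer_n[1] + 1
  dc <- si$dimer_c[1] + 1
  # (a) uniform velocity on both beads: pure translation
  stA <- st
  stA$velocities[c(dn, dc), 1] <- 0.3
  # kill the tether force by keeping everything else still: move only
  # along the tether circle tangent is messy; instead translate the whole
  # system, which keeps every internal distance fixed
  stA$velocities[, 1] <- 0.3
  outA <- langevin_step(stA, cfg, 100)
  expect_equal(outA$positions[, 1] - st$positions[, 1],
               rep(0.3 * 100 * 1e-3, nrow(st$positions)), tolerance = 1e-9)
  sep <- function(s) {
    d <- s$positions[dc, ] - s$positions[dn, ]
    d <- d - 60 * round(d / 60)
    sqrt(sum(d^2))
  }
  expect_equal(sep(outA), 1, tolerance = 1e-9)
  # (b) opposite transverse bead velocities: pure rotation at omega
  stB <- st
  u <- (st$positions[dc, ] - st$positions[dn, ]) # bond direction
  perp <- c(-u[2], u[1])
  omega <- 0.4
  stB$velocities[dc, ] <- omega * perp / 2
  stB$velocities[dn, ] <- -omega * perp / 2
  # detach influence of the vesicle: huge gamma already disables friction;
  # eps = 0 kills pair forces; tether acts on the N bead, so advance only
  # a short time and compare to the rigid-rotation prediction
  outB <- langevin_step(stB, cfg, 10)
  uB <- outB$positions[dc, ] - outB$positions[dn, ]
  ang <- atan2(uB[2], uB[1]) - atan2(u[2], u[1])
  expect_equal(ang, omega * 10 * 1e-3, tolerance = 5e-3)
  expect_equal(sep(outB), 1, tolerance = 1e-9)
})

test_that("angular acceleration equals torque over moment of inertia", {
  # facing C beads of two dimers attract; reduce the per-bead forces to a
  # torque by hand and compare one tiny NVE step of the integrator
  cfg <- sim_config(model = "bi", box_length = 100, n_vesicles = 2,
                    lambda = 0.3, eps = 3, dt = 1e-5, n_steps = 0,
                    snapshot_interval = 1, seed = 1)
  st <- make_two_vesicle_config(1.0, "bi", lambda = 0.3)
  # shift the second vesicle sideways so the facing C-C pair sits in the
  # attractive shoulder off-axis and exerts a torque
  st$positions[st$vesicle_id == 2, 2] <-
    st$positions[st$vesicle_id == 2, 2] + 0.6
  si <- vesicond:::state_internals(st)
  f <- compute_forces(st, cfg)$forces
  dn <- si$dimer_n + 1
  dc <- si$dimer_c + 1
  k <- which.max(abs(f[dc, 1]) + abs(f[dc, 2])) # the interacting dimer
  com <- (st$positions[dn[k], ] + st$positions[dc[k], ]) / 2
  rN <- st$positions[dn[k], ] - com
  rC <- st$positions[dc[k], ] - com
  tau <- rN[1] * f[dn[k], 2] - rN[2] * f[dn[k], 1] +
         rC[1] * f[dc[k], 2] - rC[2] * f[dc[k], 1]
  inertia <- 2 * 1 * 0.5^2
  out <- langevin_step(st, cfg, 1, thermostat = FALSE)
  vN <- out$velocities[dn[k], ]
  vC <- out$velocities[dc[k], ]
  u <- out$positions[dc[k], ] - out$positions[dn[k], ]
  omega <- (u[1] * (vC[2] - vN[2]) - u[2] * (vC[1] - vN[1])) / sum(u^2)
  expect_equal(omega, tau / inertia * cfg$dt, tolerance = 1e-3)
})

test_that("tethers stay intact in an equilibrated run", {
  cfg <- sim_config(model = "mono", box_length = 90, n_vesicles = 5,
                    lambda = 0.7, eps = 3.5, n_steps = 2e4,
                    snapshot_interval = 2e3, seed = 4)
  tr <- run_simulation(cfg)
  st <- get_snapshot(tr, n_snapshots(tr))
  si <- vesicond:::state_internals(st)
  d <- st$positions[si$bond_a + 1, ] - st$positions[si$bond_b + 1, ]
  d <- d - st$box_length * round(d / st$box_length)
  bond_e <- 0.5 * cfg$bond_K * (sqrt(rowSums(d^2)) - si$bond_r0)^2
  expect_lt(max(bond_e), 10)
})

test_that("short NVE integration conserves energy", {
  cfg <- sim_config(model = "mono", box_length = 90, n_vesicles = 5,
                    lambda = 0.5, eps = 3, dt = 1e-3, n_steps = 2000,
                    snapshot_interval = 100, seed = 6)
  st <- initialize_configuration(cfg)
  set.seed(1)
  st$velocities[] <- rnorm(length(st$velocities))
  tr <- run_simulation(cfg, state = st, thermostat = FALSE)
  E <- tr$potential_energy + tr$kinetic_energy
  expect_lt(max(abs(E - E[1])) / abs(E[1]), 1e-4)
})
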