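#' @title Langevin dynamics driver
#' @description
#' Velocity-Verlet integration of the decorated-vesicle system with a
#' Langevin thermostat: total force `F = F_c + F_f + F_r` with conservative
#' `F_c`, viscous damping `F_f = -m v / gamma`, and a random force of scale
#' `sqrt(kBT m / (dt gamma))` whose per-component distribution is uniform
#' with mean zero and variance two (fluctuation-dissipation). Bi-domain
#' synapsin dimers are integrated as exact 2D rigid bodies (center of mass
#' plus orientation angle), so the N-C separation is conserved to machine
#' precision.
#' @name condensation-simulator
NULL

.sim_args <- function(state, config) {
  si <- state_internals(state)
  list(x = state$positions[, 1], y = state$positions[, 2],
       vx = state$velocities[, 1], vy = state$velocities[, 2],
       species = si$species, radius = state$radius, ves = si$ves,
       dimid = si$dim, bond_a = si$bond_a, bond_b = si$bond_b,
       bond_r0 = si$bond_r0, dimer_n = si$dimer_n, dimer_c = si$dimer_c,
       box = state$box_length,
       model = if (state$model == "bi") 1L else 0L,
       eps = config$eps, bondK = config$bond_K,
       cc_same_attract = config$cc_same_vesicle_attract,
       dimer_sep = config$dimer_separation)
}

#' Conservative forces and potential energy of a state
#'
#' Evaluates the full rule table (pair kernels plus harmonic tethers) under
#' the minimum-image convention, using the neighbor-list machinery of the
#' simulator; the result is identical to an all-pairs evaluation.
#'
#' @param state a `vc_state`.
#' @param config a [sim_config()] matching the state's model.
#' @return list with `forces` (n x 2 matrix, kBT/length) and
#'   `potential_energy` (kBT).
#' @export
compute_forces <- function(state, config) {
  stopifnot(inherits(state, "vc_state"), inherits(config, "vc_config"))
  if (state$model != config$model)
    stop("state and config use different models")
  a <- .sim_args(state, config)
  res <- do.call(compute_forces_cpp, a)
  list(forces = cbind(res$fx, res$fy), potential_energy = res$pe)
}

.run_core <- function(state, config, n_steps, snapshot_interval,
                      thermostat = TRUE, seed = config$seed) {
  a <- .sim_args(state, config)
  a$dt <- config$dt
  a$gamma <- config$gamma
  a$kBT <- config$kBT
  a$mass <- config$mass
  a$thermostat <- thermostat
  a$n_steps <- as.integer(n_steps)
  a$snapshot_interval <- as.integer(snapshot_interval)
  a$seed <- as.integer(seed %% .Machine$integer.max)
  do.call(run_sim_cpp, a)
}

.as_trajectory <- function(raw, state, config) {
  structure(list(config = config,
                 model = state$model,
                 box_length = state$box_length,
                 species = state$species,
                 radius = state$radius,
                 vesicle_id = state$vesicle_id,
                 dimer_id = state$dimer_id,
                 steps = raw$steps,
                 times = raw$steps * config$dt,
                 x = raw$x, y = raw$y, vx = raw$vx, vy = raw$vy,
                 potential_energy = raw$pe, kinetic_energy = raw$ke),
            class = "vc_trajectory")
}

#' Number of snapshots in a trajectory
#' @param trajectory a `vc_trajectory`.
#' @export
n_snapshots <- function(trajectory) length(trajectory$steps)

#' Extract one snapshot as a full particle state
#'
#' @param trajectory a `vc_trajectory`.
#' @param i snapshot index (1 = initial configuration).
#' @return a `vc_state`.
#' @export
get_snapshot <- function(trajectory, i) {
  stopifnot(i >= 1, i <= n_snapshots(trajectory))
  new_state(positions = cbind(trajectory$x[, i], trajectory$y[, i]),
            velocities = cbind(trajectory$vx[, i], trajectory$vy[, i]),
            species = trajectory$species, radius = trajectory$radius,
            vesicle_id = trajectory$vesicle_id,
            dimer_id = trajectory$dimer_id,
            box_length = trajectory$box_length, model = trajectory$model)
}

#' @export
print.vc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<vc_trajectory> %s model, %d particles, %d snapshots (t = %g .. %g)\n",
    x$model, length(x$species), n_snapshots(x), min(x$times), max(x$times)))
  invisible(x)
}

#' Run a condensation simulation
#'
#' Builds the initial configuration from `config` (unless `state` is
#' given), integrates `config$n_steps` Langevin steps, and records a
#' snapshot every `config$snapshot_interval` steps; the first snapshot is
#' the initial configuration. Fully reproducible for a fixed `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param state optional pre-built initial `vc_state` (defaults to
#'   [initialize_configuration()] on `config`).
#' @param thermostat set `FALSE` to disable damping and random forces
#'   (plain velocity-Verlet NVE integration, used by energy-conservation
#'   checks).
#' @param verbose print a one-line config echo and progress notes.
#' @return a `vc_trajectory`.
#' @export
run_simulation <- function(config, state = NULL, thermostat = TRUE,
                           verbose = FALSE) {
  stopifnot(inherits(config, "vc_config"))
  if (is.null(state)) state <- initialize_configuration(config)
  if (verbose) {
    message(sprintf(
      "simulate: %s model, %d particles, %g steps (dt %g), seed %d",
      config$model, length(state$species), config$n_steps, config$dt,
      config$seed))
  }
  raw <- .run_core(state, config, config$n_steps, config$snapshot_interval,
                   thermostat = thermostat)
  traj <- .as_trajectory(raw, state, config)
  if (verbose) message(sprintf("simulate: done, %d snapshots",
                               n_snapshots(traj)))
  traj
}

#' Advance a state by a fixed number of Langevin steps
#'
#' One call to the same integrator used by [run_simulation()]; with
#' `n_steps = 1` this is a single velocity-Verlet step.
#'
#' @param state a `vc_state`.
#' @param config a [sim_config()] with matching model.
#' @param n_steps number of steps to advance (default 1).
#' @param thermostat disable for NVE integration.
#' @param seed seed for the random-force stream.
#' @return the advanced `vc_state`.
#' @export
langevin_step <- function(state, config, n_steps = 1, thermostat = TRUE,
                          seed = config$seed) {
  stopifnot(inherits(state, "vc_state"), inherits(config, "vc_config"))
  if (state$model != config$model)
    stop("state and config use different models")
  raw <- .run_core(state, config, n_steps, n_steps, thermostat = thermostat,
                   seed = seed)
  i <- length(raw$steps)
  new_state(positions = cbind(raw$x[, i], raw$y[, i]),
            velocities = cbind(raw$vx[, i], raw$vy[, i]),
            species = state$species, radius = state$radius,
            vesicle_id = state$vesicle_id, dimer_id = state$dimer_id,
            box_length = state$box_length, model = state$model)
}
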