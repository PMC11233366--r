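#' @title Particle state and initial configurations
#' @name particle-state
NULL

.species_levels <- c("vesicle", "synapsin", "syn_N", "syn_C")

#' Number of synapsin linkers per vesicle
#'
#' `N = round(2 pi 2^{1/6} (r_vesicle + r_synapsin) lambda)` — the tether
#' circle circumference times the linear density, rounded half up.
#'
#' @param r_vesicle,r_synapsin radii, reduced units.
#' @param lambda linear synapsin density.
#' @return integer count (vectorized over `r_vesicle`).
#' @export
synapsin_count <- function(r_vesicle, r_synapsin = 0.5, lambda) {
  stopifnot(all(r_vesicle >= 0), r_synapsin >= 0, lambda >= 0)
  as.integer(floor(2 * pi * 2^(1 / 6) * (r_vesicle + r_synapsin) * lambda
                   + 0.5))
}

new_state <- function(positions, velocities, species, radius, vesicle_id,
                      dimer_id, box_length, model) {
  structure(list(positions = positions, velocities = velocities,
                 species = species, radius = radius,
                 vesicle_id = vesicle_id, dimer_id = dimer_id,
                 box_length = box_length, model = model),
            class = "vc_state")
}

#' @export
print.vc_state <- function(x, ...) {
  tab <- table(factor(x$species, levels = .species_levels))
  cat(sprintf("<vc_state> %s model, box %g: %s\n", x$model, x$box_length,
              paste(sprintf("%d %s", tab, names(tab))[tab > 0],
                    collapse = ", ")))
  invisible(x)
}

# Decorate one vesicle: bead positions on the tether circle (and radially
# outward C beads for the bi model). `phase` rotates the equally spaced
# pattern. Returns a list of per-bead rows.
.decorate_vesicle <- function(center, r_ves, r_syn, n_syn, model,
                              dimer_sep, phase = 0) {
  if (n_syn == 0)
    return(list(pos = matrix(numeric(0), 0, 2), species = character(0),
                dimer_local = integer(0)))
  r0 <- 2^(1 / 6) * (r_ves + r_syn)
  ang <- phase + 2 * pi * (seq_len(n_syn) - 1) / n_syn
  ux <- cos(ang); uy <- sin(ang)
  if (model == "mono") {
    pos <- cbind(center[1] + r0 * ux, center[2] + r0 * uy)
    list(pos = pos, species = rep("synapsin", n_syn),
         dimer_local = rep(NA_integer_, n_syn))
  } else {
    # N bead on the tether circle, C bead radially outward
    posN <- cbind(center[1] + r0 * ux, center[2] + r0 * uy)
    posC <- cbind(center[1] + (r0 + dimer_sep) * ux,
                  center[2] + (r0 + dimer_sep) * uy)
    pos <- matrix(NA_real_, 2 * n_syn, 2)
    pos[seq(1, 2 * n_syn, 2), ] <- posN
    pos[seq(2, 2 * n_syn, 2), ] <- posC
    list(pos = pos,
         species = rep(c("syn_N", "syn_C"), n_syn),
         dimer_local = rep(seq_len(n_syn), each = 2))
  }
}

#' Build the initial configuration for a run
#'
#' Vesicle radii are drawn from the configured truncated normal; vesicle
#' centers occupy random nodes of a square lattice whose spacing guarantees
#' that no two decorated vesicles overlap; synapsin beads are equally
#' spaced on the tether circle of radius `2^{1/6}(r_vesicle + r_synapsin)`
#' (bi model: N and C beads aligned radially, C outward, rigid separation
#' `dimer_separation`). Initial velocities are zero. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return a `vc_state`.
#' @export
initialize_configuration <- function(config) {
  stopifnot(inherits(config, "vc_config"))
  set.seed(config$seed)
  nv <- config$n_vesicles
  radii <- sample_simulation_radii(nv, config$vesicle_radius_mean,
                                   config$vesicle_radius_sd,
                                   config$min_vesicle_radius)$radii
  r_syn <- config$synapsin_radius
  dimer <- if (config$model == "bi") config$dimer_separation else 0
  # Outermost bead center distance from a vesicle center, plus half a
  # bead-bead interaction range as clearance.
  shell <- 2^(1 / 6) * (radii + r_syn) + dimer + 2^(1 / 6) * r_syn
  spacing <- 2 * max(shell) + 0.5
  n_side <- floor(config$box_length / spacing)
  if (n_side^2 < nv)
    stop(sprintf(
      "placement failure: %d lattice nodes (spacing %.2f) for %d vesicles; enlarge the box",
      n_side^2, spacing, nv))
  nodes <- sample.int(n_side^2, nv)
  cx <- ((nodes - 1) %% n_side + 0.5) * spacing
  cy <- ((nodes - 1) %/% n_side + 0.5) * spacing
  n_syn <- synapsin_count(radii, r_syn, config$lambda)
  phases <- stats::runif(nv, 0, 2 * pi)

  pos <- vector("list", nv + 1L)
  pos[[1L]] <- cbind(cx, cy)
  species <- list(rep("vesicle", nv))
  vid <- list(seq_len(nv))
  dimid <- list(rep(NA_integer_, nv))
  prad <- list(radii)
  dimer_counter <- 0L
  for (i in seq_len(nv)) {
    d <- .decorate_vesicle(c(cx[i], cy[i]), radii[i], r_syn, n_syn[i],
                           config$model, dimer, phases[i])
    pos[[i + 1L]] <- d$pos
    species[[i + 1L]] <- d$species
    vid[[i + 1L]] <- rep(i, nrow(d$pos))
    loc <- d$dimer_local
    dimid[[i + 1L]] <- ifelse(is.na(loc), NA_integer_, loc + dimer_counter)
    dimer_counter <- dimer_counter + max(c(0L, loc), na.rm = TRUE)
    prad[[i + 1L]] <- rep(r_syn, nrow(d$pos))
  }
  positions <- do.call(rbind, pos)
  positions <- positions %% config$box_length
  dimnames(positions) <- NULL
  new_state(positions,
            velocities = matrix(0, nrow(positions), 2),
            species = unlist(species),
            radius = unlist(prad),
            vesicle_id = unlist(vid),
            dimer_id = unlist(dimid),
            box_length = config$box_length,
            model = config$model)
}

#' Deterministic two-vesicle micro-fixture
#'
#' Two decorated vesicles on the x-axis with one bead of each facing the
#' other. `gap` is the center-to-center distance between the two facing
#' outermost beads (C beads in the bi model), so `gap` equal to the
#' bead-bead `sigma` puts that pair exactly at the flat-well boundary.
#'
#' @param gap facing-bead center separation, reduced units (`>= 0`).
#' @param model `"mono"` or `"bi"`.
#' @param r1,r2 vesicle radii.
#' @param lambda linear synapsin density.
#' @param synapsin_radius bead radius.
#' @param dimer_separation rigid bead separation (bi).
#' @param box_length periodic box edge; must comfortably contain the pair.
#' @param seed unused (the construction is deterministic); kept for
#'   interface uniformity.
#' @return a `vc_state`.
#' @export
make_two_vesicle_config <- function(gap, model = c("mono", "bi"),
                                    r1 = 4.17, r2 = 4.17, lambda = 0.3,
                                    synapsin_radius = 0.5,
                                    dimer_separation = 1,
                                    box_length = 100, seed = NULL) {
  model <- match.arg(model)
  stopifnot(gap >= 0, r1 > 0, r2 > 0)
  r_syn <- synapsin_radius
  dimer <- if (model == "bi") dimer_separation else 0
  out1 <- 2^(1 / 6) * (r1 + r_syn) + dimer
  out2 <- 2^(1 / 6) * (r2 + r_syn) + dimer
  sep <- out1 + gap + out2
  if (box_length < 2 * (sep + max(r1, r2)))
    stop("box too small for the requested two-vesicle geometry")
  c1 <- c(box_length / 2 - sep / 2, box_length / 2)
  c2 <- c(box_length / 2 + sep / 2, box_length / 2)
  n1 <- synapsin_count(r1, r_syn, lambda)
  n2 <- synapsin_count(r2, r_syn, lambda)
  d1 <- .decorate_vesicle(c1, r1, r_syn, n1, model, dimer, phase = 0)
  d2 <- .decorate_vesicle(c2, r2, r_syn, n2, model, dimer, phase = pi)
  positions <- rbind(c1, c2, d1$pos, d2$pos) %% box_length
  dimnames(positions) <- NULL
  nb1 <- nrow(d1$pos); nb2 <- nrow(d2$pos)
  nd1 <- max(c(0L, d1$dimer_local), na.rm = TRUE)
  new_state(positions,
            velocities = matrix(0, nrow(positions), 2),
            species = c("vesicle", "vesicle", d1$species, d2$species),
            radius = c(r1, r2, rep(r_syn, nb1 + nb2)),
            vesicle_id = c(1L, 2L, rep(1L, nb1), rep(2L, nb2)),
            dimer_id = c(NA_integer_, NA_integer_, d1$dimer_local,
                         d2$dimer_local + nd1),
            box_length = box_length,
            model = model)
}

# Internal: flatten a state into the arrays the C++ core consumes.
state_internals <- function(state) {
  sp_int <- match(state$species, .species_levels) - 1L
  if (anyNA(sp_int)) stop("unknown species token in state")
  ves0 <- state$vesicle_id - 1L
  dim0 <- ifelse(is.na(state$dimer_id), -1L, state$dimer_id - 1L)
  # Tethered bead -> owner vesicle bonds with r0 = 2^{1/6}(r_v + r_s)
  tethered <- which(state$species %in% c("synapsin", "syn_N"))
  owner <- state$vesicle_id[tethered]
  bond_r0 <- 2^(1 / 6) * (state$radius[owner] + state$radius[tethered])
  dimers <- NULL
  if (state$model == "bi") {
    nidx <- which(state$species == "syn_N")
    cidx <- which(state$species == "syn_C")
    nidx <- nidx[order(state$dimer_id[nidx])]
    cidx <- cidx[order(state$dimer_id[cidx])]
    if (length(nidx) != length(cidx) ||
        !identical(state$dimer_id[nidx], state$dimer_id[cidx]))
      stop("inconsistent dimer pairing in state")
    dimers <- list(n = nidx - 1L, c = cidx - 1L)
  } else {
    dimers <- list(n = integer(0), c = integer(0))
  }
  list(species = sp_int, ves = ves0, dim = dim0,
       bond_a = tethered - 1L, bond_b = owner - 1L, bond_r0 = bond_r0,
       dimer_n = dimers$n, dimer_c = dimers$c)
}

# Internal: positions of the interacting synapsin beads (mono: the bead;
# bi: the C domain), with their owning vesicle ids.
synapsin_positions <- function(state) {
  sel <- if (state$model == "bi") state$species == "syn_C"
         else state$species == "synapsin"
  list(positions = state$positions[sel, , drop = FALSE],
       vesicle_id = state$vesicle_id[sel])
}
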