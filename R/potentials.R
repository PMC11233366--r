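#' @title Pairwise interaction kernels
#' @description
#' Energy/force kernels used by the condensation simulator: a flat-bottomed
#' attractive cosine-squared well, the purely repulsive WCA
#' (Weeks-Chandler-Andersen) potential, and the harmonic tether that binds
#' synapsin beads to their vesicle. All energies are in kBT, lengths in
#' reduced units (1 unit = 10 nm).
#' @name interaction-potentials
NULL

#' Pair potential parameters
#'
#' @param eps well depth epsilon, kBT.
#' @param sigma equilibrium pair distance.
#' @param r_c interaction range (`sigma + 0.25` when built by [pair_sigma()]).
#' @return object of class `vc_pair_params`.
#' @export
pair_params <- function(eps, sigma, r_c = sigma + 0.25) {
  stopifnot(eps >= 0, sigma > 0, r_c > sigma)
  structure(list(eps = eps, sigma = sigma, r_c = r_c),
            class = "vc_pair_params")
}

#' Harmonic bond parameters
#'
#' @param K bond stiffness, kBT per length^2 (default 100).
#' @param r0 equilibrium bond distance.
#' @export
bond_params <- function(K = 100, r0) {
  stopifnot(K > 0, r0 > 0)
  structure(list(K = K, r0 = r0), class = "vc_bond_params")
}

.check_r <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0))
    stop("r must be positive")
  r
}

#' Cosine-squared attractive well
#'
#' `-eps` for `r < sigma`; `-eps cos^2(pi (r - sigma) / (2 (r_c - sigma)))`
#' on `[sigma, r_c)`; 0 beyond. Continuously differentiable at both
#' branch boundaries.
#'
#' @param r pair distance(s).
#' @param p a [pair_params()] object.
#' @return energy in kBT.
#' @export
cosine_square_energy <- function(r, p) {
  .check_r(r)
  e <- numeric(length(r))
  e[r < p$sigma] <- -p$eps
  mid <- r >= p$sigma & r < p$r_c
  u <- pi * (r[mid] - p$sigma) / (2 * (p$r_c - p$sigma))
  e[mid] <- -p$eps * cos(u)^2
  e
}

#' Radial force of the cosine-squared well
#'
#' Signed radial force `F = -dE/dr`; negative values pull the pair
#' together. Zero inside the flat well and beyond the cutoff.
#'
#' @inheritParams cosine_square_energy
#' @export
cosine_square_force <- function(r, p) {
  .check_r(r)
  f <- numeric(length(r))
  mid <- r >= p$sigma & r < p$r_c
  d <- p$r_c - p$sigma
  u <- pi * (r[mid] - p$sigma) / (2 * d)
  f[mid] <- -p$eps * sin(2 * u) * pi / (2 * d)
  f
}

#' WCA repulsive potential
#'
#' `eps [ (sigma/r)^12 - 2 (sigma/r)^6 + 1 ]` for `r < sigma`, 0 beyond;
#' both the energy and its slope vanish at `r = sigma`.
#'
#' @inheritParams cosine_square_energy
#' @export
wca_energy <- function(r, p) {
  .check_r(r)
  e <- numeric(length(r))
  inside <- r < p$sigma
  s6 <- (p$sigma / r[inside])^6
  e[inside] <- p$eps * (s6^2 - 2 * s6 + 1)
  e
}

#' Radial force of the WCA potential
#'
#' `F = -dE/dr = 12 eps (s^12 - s^6)/r`, positive (repulsive) inside sigma.
#'
#' @inheritParams cosine_square_energy
#' @export
wca_force <- function(r, p) {
  .check_r(r)
  f <- numeric(length(r))
  inside <- r < p$sigma
  s6 <- (p$sigma / r[inside])^6
  f[inside] <- 12 * p$eps * (s6^2 - s6) / r[inside]
  f
}

#' Harmonic tether energy
#'
#' `E = K (r - r0)^2 / 2`.
#'
#' @param r bond length(s), `>= 0`.
#' @param p a [bond_params()] object.
#' @export
harmonic_bond_energy <- function(r, p) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("r must be non-negative")
  0.5 * p$K * (r - p$r0)^2
}

#' Harmonic tether radial force
#'
#' `F = -K (r - r0)`.
#'
#' @inheritParams harmonic_bond_energy
#' @export
harmonic_bond_force <- function(r, p) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(r < 0))
    stop("r must be non-negative")
  -p$K * (r - p$r0)
}

#' Equilibrium distance and range for a particle pair
#'
#' `sigma = 2^{1/6} (r1 + r2)` and `r_c = sigma + 0.25`, symmetric in the
#' two radii.
#'
#' @param r1,r2 particle radii, reduced units.
#' @return list with `sigma` and `r_c`.
#' @export
pair_sigma <- function(r1, r2) {
  stopifnot(all(r1 > 0), all(r2 > 0))
  sigma <- 2^(1 / 6) * (r1 + r2)
  list(sigma = sigma, r_c = sigma + 0.25)
}

.species_by_model <- list(
  mono = c("vesicle", "synapsin"),
  bi   = c("vesicle", "syn_N", "syn_C")
)

#' Species-pair interaction rule
#'
#' Resolves which kernel governs a species pair under the selected synapsin
#' model. Mono-domain: synapsins on different vesicles attract
#' (cosine-squared); synapsins of the same vesicle repel (WCA); vesicles
#' always repel. Bi-domain: C-C pairs on different vesicles attract (same
#' vesicle only when `cc_same_vesicle_attract`), every other non-bonded
#' pair repels. The tether (vesicle to its own synapsin / N-domain) is a
#' harmonic bond.
#'
#' @param model `"mono"` or `"bi"`.
#' @param species_i,species_j species names: `vesicle`, `synapsin` (mono),
#'   `syn_N`, `syn_C` (bi).
#' @param same_vesicle do the two particles belong to the same vesicle?
#' @param same_dimer are the two beads the same rigid dimer (bi only)?
#' @param cc_same_vesicle_attract should C-C pairs of the same vesicle
#'   attract? `FALSE` by default: the literal all-C-C-attract reading makes
#'   each vesicle's linkers self-aggregate, which is the failure mode the
#'   two-bead model was introduced to avoid. Cross-vesicle C-C pairs
#'   always attract.
#' @return one of `"cos_sq_attractive"`, `"wca_repulsive"`,
#'   `"harmonic_bond"`, `"none"`.
#' @export
interaction_rule <- function(model, species_i, species_j, same_vesicle,
                             same_dimer = FALSE,
                             cc_same_vesicle_attract = FALSE) {
  model <- match.arg(model, c("mono", "bi"))
  valid <- .species_by_model[[model]]
  if (!(species_i %in% valid) || !(species_j %in% valid))
    stop(sprintf("species must be one of {%s} for the %s model",
                 paste(valid, collapse = ", "), model))
  sp <- sort(c(species_i, species_j))
  if (same_dimer) return("none")
  if (sp[1] == "vesicle" && sp[2] == "vesicle") return("wca_repulsive")
  if (model == "mono") {
    if (sp[1] == "synapsin" && sp[2] == "vesicle")
      return(if (same_vesicle) "harmonic_bond" else "wca_repulsive")
    # synapsin-synapsin
    return(if (same_vesicle) "wca_repulsive" else "cos_sq_attractive")
  }
  if (sp[1] == "syn_N" && sp[2] == "vesicle")
    return(if (same_vesicle) "harmonic_bond" else "wca_repulsive")
  if (sp[1] == "syn_C" && sp[2] == "vesicle") return("wca_repulsive")
  if (sp[1] == "syn_N" && sp[2] == "syn_N") return("wca_repulsive")
  if (sp[1] == "syn_C" && sp[2] == "syn_N") return("wca_repulsive")
  # C-C
  if (same_vesicle && !cc_same_vesicle_attract) return("wca_repulsive")
  "cos_sq_attractive"
}

#' Resolved species-pair rule matrix
#'
#' Expands [interaction_rule()] over all species pairs of a model, for
#' audit (`--dump-rules` in the CLI).
#'
#' @inheritParams interaction_rule
#' @return data.frame with columns `species_i`, `species_j`,
#'   `same_vesicle`, `kind`.
#' @export
rule_table <- function(model, cc_same_vesicle_attract = FALSE) {
  model <- match.arg(model, c("mono", "bi"))
  sp <- .species_by_model[[model]]
  grid <- expand.grid(species_i = sp, species_j = sp,
                      same_vesicle = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  grid <- grid[as.character(grid$species_i) <= as.character(grid$species_j), ]
  grid$kind <- mapply(interaction_rule, grid$species_i, grid$species_j,
                      grid$same_vesicle,
                      MoreArgs = list(model = model,
                                      cc_same_vesicle_attract =
                                        cc_same_vesicle_attract))
  rownames(grid) <- NULL
  grid
}
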