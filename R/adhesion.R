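#' @title Membrane adhesion energetics of deformed vesicles
#' @description
#' A vesicle adhering to a neighbor flattens against it and takes the shape
#' of a truncated sphere (spherical cap removed), parameterized by the half
#' contact angle `theta` and the deformed radius `R`. At constant lumen
#' volume the extra area must come from stretching the bilayer, so the
#' equilibrium contact angle balances the elastic stretching penalty
#' `K_a (A - A0)^2 / A0` against the adhesion gain `A_f |W_a|`. These
#' functions compute the cap geometry, the constant-volume deformation, and
#' the closed-form relation between contact angle and adhesion energy per
#' unit area.
#' @name adhesion-model
NULL

.kB <- 1.380649e-23 # J/K

#' Material parameters of the bilayer
#'
#' @param K_a area stretching modulus in mN/m (DOPC literature value 243).
#' @param T_K absolute temperature in K, used only to express `K_a` in
#'   thermal units (kBT/nm^2). Default 298 K.
#' @return an object of class `vc_material`.
#' @export
material_params <- function(K_a = 243, T_K = 298) {
  stopifnot(is.numeric(K_a), length(K_a) == 1L, is.finite(K_a), K_a >= 0)
  if (!is.numeric(T_K) || length(T_K) != 1L || !is.finite(T_K) || T_K <= 0)
    stop("T_K must be a positive temperature in Kelvin")
  structure(list(K_a = K_a, T_K = T_K), class = "vc_material")
}

#' @export
print.vc_material <- function(x, ...) {
  cat(sprintf("<vc_material> K_a = %g mN/m, T = %g K (%.4g kBT/nm^2)\n",
              x$K_a, x$T_K, stretching_modulus_in_thermal_units(x$K_a, x$T_K)))
  invisible(x)
}

#' Convert a stretching modulus from mN/m to kBT/nm^2
#'
#' `1 mN/m = 1e-3 J/m^2 = 1e-21 J/nm^2`, divided by `k_B T`.
#'
#' @param K_a stretching modulus, mN/m.
#' @param T_K absolute temperature, K.
#' @return modulus in kBT/nm^2.
#' @examples
#' stretching_modulus_in_thermal_units(243, 298) # about 59.1
#' @export
stretching_modulus_in_thermal_units <- function(K_a, T_K = 298) {
  stopifnot(is.numeric(K_a), all(K_a >= 0))
  if (any(!is.finite(T_K)) || any(T_K <= 0)) stop("T_K must be > 0")
  K_a * 1e-3 * 1e-18 / (.kB * T_K)
}

.check_theta <- function(theta) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta >= pi))
    stop("theta must lie in [0, pi) radians")
  theta
}

#' Geometry of a truncated-sphere (adhering) vesicle
#'
#' For a sphere of radius `R` flattened at half contact angle `theta`:
#' flat adhesion area `A_f = pi R^2 sin^2(theta)`, curved area
#' `A_c = 2 pi R^2 (1 + cos(theta))`, and enclosed volume
#' `V = (pi R^3 / 3) (1 + cos(theta))^2 (2 - cos(theta))`.
#'
#' @param theta half contact angle, radians, in `[0, pi)`.
#' @param R deformed sphere radius (same length unit throughout, e.g. nm).
#' @return list with `A_f`, `A_c`, `A = A_f + A_c`, `V`.
#' @export
spherical_cap_geometry <- function(theta, R) {
  .check_theta(theta)
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0))
    stop("R must be positive")
  ct <- cos(theta)
  A_f <- pi * R^2 * sin(theta)^2
  A_c <- 2 * pi * R^2 * (1 + ct)
  V <- pi * R^3 / 3 * (1 + ct)^2 * (2 - ct)
  list(A_f = A_f, A_c = A_c, A = A_f + A_c, V = V)
}

#' Deformed radius at constant volume
#'
#' Solves `V(theta, R) = (4/3) pi R0^3` for `R`; closed form
#' `R = R0 * (4 / ((1+cos)^2 (2-cos)))^{1/3}`.
#'
#' @param theta half contact angle, radians, in `[0, pi)`.
#' @param R0 undeformed vesicle radius.
#' @return deformed radius `R >= R0`.
#' @export
constant_volume_radius <- function(theta, R0) {
  .check_theta(theta)
  if (!is.numeric(R0) || any(!is.finite(R0)) || any(R0 <= 0))
    stop("R0 must be positive")
  ct <- cos(theta)
  R0 * (4 / ((1 + ct)^2 * (2 - ct)))^(1 / 3)
}

#' Area strain of a vesicle deformed at constant volume
#'
#' `alpha = (A(theta) - A0)/A0` with `A` evaluated at the constant-volume
#' radius; independent of `R0`. Closed form:
#' `alpha = (3 - cos)/ (2 (1+cos)^{1/2} (2-cos))^{2/3} - 1`.
#'
#' @param theta half contact angle, radians, in `[0, pi)`.
#' @return dimensionless area strain, 0 at `theta = 0`.
#' @export
area_strain <- function(theta) {
  .check_theta(theta)
  ct <- cos(theta)
  (3 - ct) / (2 * sqrt(1 + ct) * (2 - ct))^(2 / 3) - 1
}

#' Full spherical-cap description of a deformed vesicle
#'
#' @param theta half contact angle, radians.
#' @param R0 undeformed radius, nm.
#' @return object of class `vc_deformed_vesicle` with fields `R0`, `theta`,
#'   `R`, `A_f`, `A_c`, `A`, `A0`, `V`, `V0`, `alpha`.
#' @export
deformed_vesicle <- function(theta, R0) {
  R <- constant_volume_radius(theta, R0)
  g <- spherical_cap_geometry(theta, R)
  structure(list(R0 = R0, theta = theta, R = R,
                 A_f = g$A_f, A_c = g$A_c, A = g$A,
                 A0 = 4 * pi * R0^2,
                 V = g$V, V0 = 4 / 3 * pi * R0^3,
                 alpha = g$A / (4 * pi * R0^2) - 1),
            class = "vc_deformed_vesicle")
}

#' Total deformation energy of an adhering vesicle
#'
#' `U = K_a (A - A0)^2 / A0 - A_f |W_a|` with `K_a` expressed in thermal
#' units internally. Lengths in nm, energies in kBT.
#'
#' @param theta half contact angle, radians.
#' @param R0 undeformed radius, nm.
#' @param material a [material_params()] object.
#' @param W_a adhesion energy per unit area, kBT/nm^2 (absolute value).
#' @return list with `U`, `stretch_term`, `adhesion_term` (kBT);
#'   `U = stretch_term - adhesion_term`.
#' @export
total_energy <- function(theta, R0, material = material_params(), W_a) {
  stopifnot(inherits(material, "vc_material"),
            is.numeric(W_a), all(is.finite(W_a)), all(W_a >= 0))
  v <- deformed_vesicle(theta, R0)
  Ka <- stretching_modulus_in_thermal_units(material$K_a, material$T_K)
  stretch <- Ka * (v$A - v$A0)^2 / v$A0
  adh <- v$A_f * W_a
  list(U = stretch - adh, stretch_term = stretch, adhesion_term = adh)
}

#' Equilibrium contact angle for a given adhesion energy
#'
#' Minimizes [total_energy()] over `theta` in `[0, pi)` by bracketed 1-D
#' search (Brent). Monotone increasing in `W_a`; returns 0 at `W_a = 0`.
#'
#' @inheritParams total_energy
#' @param tol absolute tolerance on theta, radians.
#' @return half contact angle theta in radians.
#' @export
equilibrium_contact_angle <- function(W_a, material = material_params(),
                                      R0 = 1, tol = 1e-8) {
  stopifnot(is.numeric(W_a), length(W_a) == 1L, is.finite(W_a), W_a >= 0,
            material$K_a > 0)
  if (W_a == 0) return(0)
  f <- function(th) total_energy(th, R0, material, W_a)$U
  opt <- stats::optimize(f, interval = c(0, pi - 1e-6), tol = tol)
  th <- opt$minimum
  # optimize() never returns the endpoints; snap to 0 when the interior
  # minimum is not actually below U(0) = 0 (vanishing adhesion).
  if (opt$objective >= 0 && f(max(th, 1e-6)) >= 0) return(0)
  if (!is.finite(th)) stop("contact-angle minimization did not converge")
  th
}

#' Adhesion energy per unit area from the equilibrium contact angle
#'
#' Closed form obtained by minimizing the stretching-adhesion energy at
#' constant volume:
#' `|W_a| = 2 K_a (1 - cos theta) * alpha(theta)` with `alpha` the area
#' strain; equivalently the bracket `(3-cos)/ (2(1+cos)^{1/2}(2-cos))^{2/3} - 1`.
#' The result is independent of the vesicle radius.
#'
#' @param theta half contact angle, radians, in `[0, pi)`.
#' @param material a [material_params()] object.
#' @return adhesion energy per unit area, kBT/nm^2.
#' @examples
#' m <- material_params(243, 298)
#' adhesion_energy_from_angle(119 / 2 * pi / 180, m) # about 2.82
#' @export
adhesion_energy_from_angle <- function(theta, material = material_params()) {
  .check_theta(theta)
  stopifnot(material$K_a > 0)
  Ka <- stretching_modulus_in_thermal_units(material$K_a, material$T_K)
  2 * Ka * (1 - cos(theta)) * area_strain(theta)
}

#' Contact angle from adhesion-zone and vesicle diameters
#'
#' The adhesion-zone radius of a truncated sphere equals `R sin(theta)`,
#' so `theta = asin(d_adhesion / d_vesicle)` when both are measured on the
#' same (deformed) vesicle.
#'
#' @param adhesion_zone_diameter contact-site length, nm.
#' @param vesicle_diameter deformed vesicle diameter, nm.
#' @return half contact angle in `[0, pi/2]`, radians.
#' @export
contact_angle_from_contact_measurements <- function(adhesion_zone_diameter,
                                                    vesicle_diameter) {
  stopifnot(is.numeric(adhesion_zone_diameter), is.numeric(vesicle_diameter))
  if (any(vesicle_diameter <= 0)) stop("vesicle_diameter must be positive")
  if (any(adhesion_zone_diameter < 0) ||
      any(adhesion_zone_diameter > vesicle_diameter))
    stop("adhesion zone diameter must lie in [0, vesicle diameter]")
  asin(adhesion_zone_diameter / vesicle_diameter)
}

#' Batch adhesion energies from a table of contact-angle measurements
#'
#' @param df data.frame with columns `R1_nm`, `R2_nm`, `two_theta_deg`.
#' @param material a [material_params()] object.
#' @return the input with an added `W_a_kbt_per_nm2` column.
#' @export
adhesion_batch <- function(df, material = material_params()) {
  need <- c("R1_nm", "R2_nm", "two_theta_deg")
  if (!all(need %in% names(df)))
    stop("input must have columns ", paste(need, collapse = ", "))
  theta <- df$two_theta_deg / 2 * pi / 180
  df$W_a_kbt_per_nm2 <- vapply(theta, adhesion_energy_from_angle,
                               numeric(1), material = material)
  df
}
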