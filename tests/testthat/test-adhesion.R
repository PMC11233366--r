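# Spherical-cap geometry, constant-volume deformation, and the
# stretching-adhesion energy balance. Reference values: DOPC stretching
# modulus 243 mN/m; measured contact angles 2theta = 119, 125.1, 97.7
# degrees with adhesion energies 2.83, 3.66, 0.99 kBT/nm^2.

deg <- function(x) x * pi / 180
ref_two_theta <- c(119, 125.1, 97.7)
ref_wa <- c(2.83, 3.66, 0.99)
mat <- material_params(243, 298)

test_that("spherical cap geometry matches closed forms", {
  g <- spherical_cap_geometry(0, 2)
  expect_equal(g$A_f, 0)
  expect_equal(g$A_c, 16 * pi)
  expect_equal(g$V, 32 * pi / 3)
  h <- spherical_cap_geometry(pi / 2, 1)
  expect_equal(h$A_f, pi)
  expect_equal(h$A_c, 2 * pi)
  expect_equal(h$V, 2 * pi / 3)
  expect_equal(h$A, h$A_f + h$A_c)
  # deformed-sphere worked example
  d <- spherical_cap_geometry(deg(59.5), 1.0565)
  expect_equal(d$A_f, pi * 1.0565^2 * sin(deg(59.5))^2, tolerance = 1e-12)
  expect_equal(d$A_f, 2.603, tolerance = 1e-3)
  expect_error(spherical_cap_geometry(pi, 1), "theta")
  expect_error(spherical_cap_geometry(0.5, -1), "positive")
})

test_that("constant-volume radius conserves volume and is monotone", {
  expect_equal(constant_volume_radius(0, 1), 1)
  expect_equal(constant_volume_radius(pi / 2, 1), 2^(1 / 3),
               tolerance = 1e-12)
  expect_equal(constant_volume_radius(deg(59.5), 1), 1.0565,
               tolerance = 1e-4)
  th <- seq(0, pi - 1e-3, length.out = 400)
  R <- constant_volume_radius(th, 2.5)
  expect_true(all(diff(R) >= 0))
  expect_true(all(R >= 2.5))
  V <- spherical_cap_geometry(th, R)$V
  expect_true(all(abs(V - 4 / 3 * pi * 2.5^3) / (4 / 3 * pi * 2.5^3) < 1e-9))
})

test_that("area strain is zero at zero, increasing, R0-independent", {
  expect_equal(area_strain(0), 0)
  expect_equal(area_strain(deg(59.5)), 0.0485, tolerance = 2e-3)
  expect_equal(area_strain(deg(62.55)), 0.0575, tolerance = 2e-3)
  th <- seq(1e-4, pi / 2, length.out = 200)
  expect_true(all(diff(area_strain(th)) > 0))
  # strain via explicit geometry at several R0: identical by construction
  for (R0 in c(0.5, 1, 40)) {
    v <- deformed_vesicle(deg(50), R0)
    expect_equal(v$alpha, area_strain(deg(50)), tolerance = 1e-12)
  }
})

test_that("thermal-unit conversion of the stretching modulus", {
  expect_equal(stretching_modulus_in_thermal_units(243, 298),
               243e-21 / (1.380649e-23 * 298), tolerance = 1e-12)
  expect_equal(stretching_modulus_in_thermal_units(243, 298), 59.06,
               tolerance = 1e-3)
  expect_equal(stretching_modulus_in_thermal_units(0, 310), 0)
  expect_equal(stretching_modulus_in_thermal_units(243, 149),
               2 * stretching_modulus_in_thermal_units(243, 298),
               tolerance = 1e-12)
  expect_error(stretching_modulus_in_thermal_units(243, -1), "T_K")
})

test_that("total energy decomposition and its limits", {
  z <- total_energy(0, 3, mat, W_a = 1.7)
  expect_equal(z$U, 0)
  w0 <- total_energy(deg(40), 1, mat, W_a = 0)
  expect_gt(w0$U, 0)
  expect_equal(w0$adhesion_term, 0)
  u <- total_energy(deg(59.5), 1, mat, W_a = 2.823)
  expect_equal(u$U, u$stretch_term - u$adhesion_term)
  expect_equal(u$U, -5.60, tolerance = 1e-3)
})

test_that("equilibrium angle inverts the closed-form adhesion energy", {
  expect_equal(equilibrium_contact_angle(0, mat), 0)
  # reference rows, angle from energy
  th1 <- equilibrium_contact_angle(2.83, mat)
  expect_equal(2 * th1 / pi * 180, 119, tolerance = 0.5 / 119)
  th3 <- equilibrium_contact_angle(0.99, mat)
  expect_equal(2 * th3 / pi * 180, 97.7, tolerance = 0.5 / 97.7)
  # monotone in W_a
  W <- c(0.1, 0.5, 1, 2, 3, 4)
  th <- vapply(W, equilibrium_contact_angle, numeric(1), material = mat)
  expect_true(all(diff(th) > 0))
  # round trip W -> theta -> W
  back <- vapply(th, adhesion_energy_from_angle, numeric(1), material = mat)
  expect_true(all(abs(back - W) / W < 1e-5))
  # independent of the undeformed radius
  for (R0 in c(0.5, 1, 40))
    expect_equal(equilibrium_contact_angle(2, mat, R0 = R0),
                 equilibrium_contact_angle(2, mat, R0 = 1),
                 tolerance = 1e-6)
})

test_that("closed-form adhesion energy reproduces the reference rows", {
  wa <- vapply(deg(ref_two_theta / 2), adhesion_energy_from_angle,
               numeric(1), material = mat)
  expect_equal(wa, ref_wa, tolerance = 0.03)
  expect_equal(adhesion_energy_from_angle(1e-9, mat), 0, tolerance = 1e-12)
})

test_that("closed form is stationary for the energy functional", {
  # brute-force scan oracle: with W_a set to the closed-form value, the
  # energy minimum over theta must sit at the input angle
  th_grid <- seq(1e-4, pi - 1e-3, length.out = 2e4)
  for (tt in ref_two_theta) {
    th0 <- deg(tt / 2)
    W <- adhesion_energy_from_angle(th0, mat)
    U <- total_energy(th_grid, 1, mat, W)$U
    expect_lt(abs(th_grid[which.min(U)] - th0), 1e-3)
  }
})

test_that("contact angle from measured diameters", {
  expect_equal(contact_angle_from_contact_measurements(0, 60), 0)
  expect_equal(contact_angle_from_contact_measurements(45, 45), pi / 2)
  expect_equal(contact_angle_from_contact_measurements(15, 45), asin(1 / 3))
  expect_error(contact_angle_from_contact_measurements(50, 45), "diameter")
})

test_that("batch interface works on the packaged measurement fixture", {
  csv <- system.file("extdata", "adhesion_measurements.csv",
                     package = "vesicond")
  df <- adhesion_batch(read.csv(csv), mat)
  expect_named(df, c("R1_nm", "R2_nm", "two_theta_deg", "W_a_kbt_per_nm2"))
  expect_equal(df$W_a_kbt_per_nm2, ref_wa, tolerance = 0.03)
  expect_error(adhesion_batch(data.frame(x = 1)), "columns")
})
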