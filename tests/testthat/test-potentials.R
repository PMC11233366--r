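# Pair kernels: values at landmark distances, smoothness at branch
# boundaries, energy-force consistency, and the species-pair rule tables.

test_that("cosine-squared well has the right landmarks", {
  p <- pair_params(eps = 2, sigma = 1.5)
  expect_equal(p$r_c, 1.75)
  expect_equal(cosine_square_energy(0.9 * p$sigma, p), -2)
  expect_equal(cosine_square_energy(p$r_c, p), 0)
  expect_equal(cosine_square_energy((p$sigma + p$r_c) / 2, p), -1,
               tolerance = 1e-12)
  expect_error(cosine_square_energy(-1, p), "positive")
})

test_that("cosine-squared force vanishes in well and at cutoff", {
  p <- pair_params(eps = 1, sigma = 1)
  expect_equal(cosine_square_force(0.5, p), 0)
  expect_equal(cosine_square_force(p$r_c, p), 0)
  expect_equal(cosine_square_force(p$r_c + 1, p), 0)
  # |dE/dr| at the midpoint with range width 0.25: pi / (2 * 0.25)
  expect_equal(abs(cosine_square_force((p$sigma + p$r_c) / 2, p)), 2 * pi,
               tolerance = 1e-12)
})

test_that("WCA potential is zero-slope-zero at sigma and repulsive", {
  p <- pair_params(eps = 1.3, sigma = 2)
  expect_equal(wca_energy(p$sigma, p), 0)
  expect_equal(wca_energy(2 * p$sigma, p), 0)
  expect_equal(wca_energy(p$sigma / 2^(1 / 6), p), p$eps, tolerance = 1e-12)
  r <- seq(0.4, p$sigma - 1e-9, length.out = 300)
  expect_true(all(diff(wca_energy(r, p)) < 0))
  expect_true(all(wca_force(r, p) > 0))
})

test_that("harmonic tether energy and force", {
  b <- bond_params(K = 100, r0 = 2)
  expect_equal(harmonic_bond_energy(2, b), 0)
  expect_equal(harmonic_bond_energy(3, b), 50)
  expect_equal(harmonic_bond_energy(1.9, b), 0.5)
  expect_equal(harmonic_bond_force(1.9, b), 10)
})

test_that("energies are continuous and consistent with forces", {
  p <- pair_params(eps = 3.5, sigma = 1.2)
  b <- bond_params(K = 100, r0 = 1.8)
  h <- 1e-10
  for (r0 in c(p$sigma, p$r_c))
    expect_lt(abs(cosine_square_energy(r0 - h, p) -
                  cosine_square_energy(r0 + h, p)), 1e-8)
  expect_lt(abs(wca_energy(p$sigma - h, p) - wca_energy(p$sigma + h, p)),
            1e-8)
  # central differences vs analytic forces
  hh <- 1e-6
  r <- seq(0.8, p$r_c + 0.2, length.out = 97)
  r <- r[abs(r - p$sigma) > 1e-4 & abs(r - p$r_c) > 1e-4]
  num <- -(cosine_square_energy(r + hh, p) -
           cosine_square_energy(r - hh, p)) / (2 * hh)
  expect_equal(num, cosine_square_force(r, p), tolerance = 1e-6)
  rw <- seq(0.9, p$sigma - 1e-3, length.out = 50)
  numw <- -(wca_energy(rw + hh, p) - wca_energy(rw - hh, p)) / (2 * hh)
  expect_equal(numw, wca_force(rw, p), tolerance = 1e-6)
  rb <- seq(1.2, 2.6, length.out = 40)
  numb <- -(harmonic_bond_energy(rb + hh, b) -
            harmonic_bond_energy(rb - hh, b)) / (2 * hh)
  expect_equal(numb, harmonic_bond_force(rb, b), tolerance = 1e-6)
})

test_that("pair sigma is the mixing rule and symmetric", {
  s <- pair_sigma(0.5, 0.5)
  expect_equal(s$sigma, 2^(1 / 6), tolerance = 1e-12)
  expect_equal(s$r_c, 2^(1 / 6) + 0.25, tolerance = 1e-12)
  expect_equal(pair_sigma(4.17, 0.5)$sigma, 2^(1 / 6) * 4.67,
               tolerance = 1e-12)
  expect_equal(pair_sigma(1.2, 3.4), pair_sigma(3.4, 1.2))
})

test_that("mono-domain interaction rules", {
  expect_equal(interaction_rule("mono", "synapsin", "synapsin", TRUE),
               "wca_repulsive")
  expect_equal(interaction_rule("mono", "synapsin", "synapsin", FALSE),
               "cos_sq_attractive")
  expect_equal(interaction_rule("mono", "vesicle", "vesicle", FALSE),
               "wca_repulsive")
  expect_equal(interaction_rule("mono", "vesicle", "synapsin", TRUE),
               "harmonic_bond")
  expect_equal(interaction_rule("mono", "vesicle", "synapsin", FALSE),
               "wca_repulsive")
  expect_error(interaction_rule("mono", "syn_N", "vesicle", TRUE), "species")
})

test_that("bi-domain interaction rules", {
  for (sv in c(TRUE, FALSE)) {
    # literal all-C-C-attract reading, via the switch
    expect_equal(interaction_rule("bi", "syn_C", "syn_C", sv,
                                  cc_same_vesicle_attract = TRUE),
                 "cos_sq_attractive")
    expect_equal(interaction_rule("bi", "syn_N", "syn_C", sv),
                 "wca_repulsive")
    expect_equal(interaction_rule("bi", "vesicle", "syn_C", sv),
                 "wca_repulsive")
    expect_equal(interaction_rule("bi", "syn_N", "syn_N", sv),
                 "wca_repulsive")
  }
  expect_equal(interaction_rule("bi", "vesicle", "syn_N", TRUE),
               "harmonic_bond")
  expect_equal(interaction_rule("bi", "vesicle", "syn_N", FALSE),
               "wca_repulsive")
  # default: cross-vesicle C-C attract, same-vesicle C-C repel
  expect_equal(interaction_rule("bi", "syn_C", "syn_C", FALSE),
               "cos_sq_attractive")
  expect_equal(interaction_rule("bi", "syn_C", "syn_C", TRUE),
               "wca_repulsive")
  # a rigid dimer's own beads never interact
  expect_equal(interaction_rule("bi", "syn_N", "syn_C", TRUE,
                                same_dimer = TRUE), "none")
})

test_that("rule lookup is total and symmetric over species pairs", {
  for (model in c("mono", "bi")) {
    tab <- rule_table(model)
    expect_true(all(tab$kind %in%
      c("cos_sq_attractive", "wca_repulsive", "harmonic_bond", "none")))
    sp <- if (model == "mono") c("vesicle", "synapsin")
          else c("vesicle", "syn_N", "syn_C")
    expect_equal(nrow(tab), length(sp) * (length(sp) + 1))
    for (k in seq_len(nrow(tab)))
      expect_equal(interaction_rule(model, tab$species_j[k],
                                    tab$species_i[k], tab$same_vesicle[k]),
                   tab$kind[k])
  }
})
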