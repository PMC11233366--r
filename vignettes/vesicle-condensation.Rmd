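---
title: "Models and methods: synapsin-driven vesicle condensation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: synapsin-driven vesicle condensation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesicond)
```

# The scientific problem

Synapsin cross-links synaptic vesicles (and their artificial lipid-vesicle
mimics) into dense condensates — a cell-free model of the synaptic "reserve
pool" and an example of liquid-liquid phase separation in which one phase
is itself a structured fluid of vesicles and protein. The central puzzle is
why this condensation is self-limiting: attractive interactions alone would
predict unbounded coarsening, yet observed condensates stop growing at a
finite size. `vesicond` implements two computational pieces that address
this:

1. a **2D coarse-grained Langevin simulator** of vesicles decorated with
   tethered synapsin linkers, which reproduces condensate growth and its
   saturation as an emergent consequence of linker redistribution, and
2. a **membrane-adhesion energetics model** that converts the contact
   angles of vesicle pairs measured by cryo-EM into adhesion energies per
   unit area, quantifying the driving force that flattens bilayers into
   adhesion zones.

# The adhesion model

An adhering vesicle is a truncated sphere: flat adhesion disk of area
$A_f = \pi R^2 \sin^2\theta$, curved area $A_c = 2\pi R^2(1+\cos\theta)$,
volume $V = \tfrac{\pi R^3}{3}(1+\cos\theta)^2(2-\cos\theta)$, where
$\theta$ is the half contact angle (the measurable full angle between two
equal adhering vesicles is $2\theta$). The lumen volume is fixed
($V = V_0$, osmotically justified), so flattening requires stretching the
bilayer. In the strong-adhesion limit the bending energy is negligible and

$$U(\theta) = K_a \frac{(A - A_0)^2}{A_0} - A_f\,|W_a|,$$

with stretching modulus $K_a$ and adhesion energy per unit area $W_a$.
Minimizing over $\theta$ at constant volume gives the closed form

$$|W_a| = 2K_a\,(1-\cos\theta)\,\alpha(\theta),\qquad
\alpha(\theta) = \frac{3-\cos\theta}
{\left(2(1+\cos\theta)^{1/2}(2-\cos\theta)\right)^{2/3}} - 1,$$

where $\alpha$ is exactly the area strain of the constant-volume
deformation.

**A note on the exponent.** Printed statements of this relation sometimes
carry the exponent $3/2$ on the denominator bracket. That form is not
stationary for $U$ and yields negative energies at the measured angles
(e.g. $-37.5\,k_BT/\mathrm{nm}^2$ at $2\theta = 119^\circ$). The $2/3$ form
above is the one whose bracket equals the area strain; it agrees with
direct numerical minimization of $U$ to $<10^{-8}$ rad at every angle we
test, and reproduces the published energies (2.83, 3.66,
0.99 $k_BT/\mathrm{nm}^2$ at $2\theta$ = 119°, 125.1°, 97.7°) within
rounding. The package implements the $2/3$ form and tests it against a
brute-force scan of $U$.

**Units and temperature.** $K_a$ is taken in mN/m (DOPC literature value
243 mN/m) and converted to $k_BT/\mathrm{nm}^2$ internally; the conversion
temperature is not stated alongside the published energies, and any value
in 295-300 K reproduces them within 1%. The package defaults to 298 K and
exposes the parameter.

```{r adhesion}
mat <- material_params(K_a = 243, T_K = 298)
adhesion_energy_from_angle(119 / 2 * pi / 180, mat)
```

The inverse direction ([equilibrium_contact_angle()]) is a bracketed Brent
minimization of $U$ on $[0, \pi)$ with $10^{-8}$ rad tolerance; $U$ is
smooth and unimodal in the physical regime, and the round trip
$W_a \to \theta \to W_a$ is exact to $10^{-5}$ relative error. The
geometric reading used for micrograph-derived inputs is
adhesion-zone radius $= R\sin\theta$, i.e.
$\theta = \arcsin(d_\mathrm{adh}/d_\mathrm{ves})$; how the published
angles were measured from micrographs (tangent vs chord construction) is
not specified, so this is one defensible convention, not a reproduction of
that procedure.

# The condensation simulator

## Interactions

All particles are disks in a 2D periodic box (1 length unit = 10 nm,
energies in $k_BT$). Attractive pairs use a flat-bottomed cosine-squared
well: $E = -\varepsilon$ for $r<\sigma$, a smooth
$-\varepsilon\cos^2\!\big(\pi(r-\sigma)/(2(r_c-\sigma))\big)$ shoulder on
$[\sigma, r_c)$, zero beyond. Repulsive pairs use the WCA potential with
the same $\varepsilon$ and $\sigma$. For every pair
$\sigma = 2^{1/6}(r_1+r_2)$ and $r_c = \sigma + 0.25$. Synapsins are
tethered to their vesicle by a harmonic bond ($K = 100$, rest length
$\sigma$); they rearrange on the surface but cannot detach.

Two synapsin models:

* **mono-domain** — one bead of radius 0.5 (the AlphaFold radius of
  gyration, 5 nm); synapsins on *different* vesicles attract, synapsins of
  the *same* vesicle repel, vesicle-vesicle and vesicle-foreign-synapsin
  pairs repel.
* **bi-domain** — a rigid two-bead dimer (N + C, fixed separation 1, both
  radius 0.5); the N bead is tethered, C-C pairs attract, everything else
  repels.

Resolved rule tables are printable (`rule_table()`, CLI `--dump-rules`).
Choices the source text leaves open, decided here once: the tethered pair
interacts through the bond alone (the usual bonded-exclusion convention);
the attractive well is implemented exactly as printed, i.e. *flat* (no
inner repulsive core) for $r<\sigma$.

**Same-vesicle C-C pairs.** The bi-domain rules state C-C attraction
without a same/different-vesicle qualifier. Read literally (same-vesicle
C-C attract), each vesicle's C domains aggregate among themselves — at
$\varepsilon = 5$ this arrests cluster growth at a mean of ~3 vesicles,
i.e. it reproduces exactly the linker-self-aggregation failure mode that
motivated the two-bead model, and the saturation regime at
$\varepsilon = 3.5, \lambda = 0.5$ never appears on accessible time
scales. The mono-domain rules make same-vesicle pairs repulsive precisely
"to prevent aggregation of synapsins into one spot", and the same logic
must apply to the C domains for the bi-domain model to function. The
package therefore defaults to `cc_same_vesicle_attract = FALSE`
(cross-vesicle C-C attraction only); the literal reading remains available
as a config switch. With this default the simulator reproduces the
expected regime structure: growth saturation at moderate attraction and
linker density, continued coarsening elsewhere.

## Dynamics

Langevin dynamics with velocity-Verlet: $F = F_c + F_f + F_r$, viscous
damping $F_f = -m v/\gamma$ ($\gamma$ a damping *time*), and random force
$F_r = \sqrt{k_BT m/(\Delta t\,\gamma)}\,\eta$. The printed moment
conditions on $\eta$ (mean absolute value $1/2$, correlator
$2\delta(t-t')$) are mutually inconsistent for any uniform distribution;
we keep the correlator — the fluctuation-dissipation requirement — and
draw each component uniformly on $[-\sqrt6, \sqrt6]$ (mean 0, variance 2).
This is what makes the 2D equipartition and free-diffusion
($D = k_BT\gamma/m$) checks in the test suite pass; the mean-absolute
condition is dropped and documented here.

Constants not stated anywhere: $k_BT = 1$ (so $\varepsilon$ is in thermal
units), $m = 1$, $\gamma = 1$. These set the time scale only; cluster
*sizes* are comparable, absolute rates are not.

Bi-domain dimers are exact 2D rigid bodies integrated in center-of-mass +
orientation-angle coordinates (mass $2m$, moment of inertia $m d^2/2$);
the bond length is conserved to machine precision by construction.
Friction and random forces are applied per bead using the bead velocity
$v = V + \omega \times r$ and reduced to a COM force and torque.

Neighbor lists use per-pair cutoffs (interaction range + 0.3 skin),
rebuilt whenever any particle has moved 0.15 since the last build. A
single printed cutoff of 3.3 cannot cover vesicle-vesicle ranges
($\sigma \approx 9$-16 in reduced units), so the per-pair rule is used;
the forces are verified against an all-pairs oracle to $10^{-12}$.

## Initialization

Vesicle radii are drawn from a normal distribution (mean 4.17, sd 1.08,
i.e. 41.7 ± 10.8 nm) truncated below at 1.0 (10 nm) by resampling — the
untruncated normal admits non-positive radii, and 10 nm matches the
smallest vesicles resolved in the cryo-EM size histogram. Vesicle centers
occupy random nodes of a square lattice whose spacing guarantees that no
two decorated vesicles overlap; each vesicle carries
$N = \mathrm{round}(2\pi\,2^{1/6}(r_v + r_s)\lambda)$ synapsins (rounded
half up) equally spaced on the tether circle with a random phase; dimers
point radially, C outward. Velocities start at zero — the thermostat
equilibrates kinetic energy in a fraction of one time unit.

# Cluster analysis

Vesicles are grouped through their synapsins: interacting beads (the C
domain in the bi-domain model) closer than 4 reduced units (minimum-image)
join the same synapsin component, and vesicles join a cluster when their
synapsins do — position-based vesicle clustering alone is unreliable
because vesicles can be adjacent without being synapsin-bridged. The
parenthetical gloss of that cutoff in the source text ("8 × vesicle
radius") is read as 8 × the *synapsin* radius (= 4), the only reading
consistent with the number itself. Connectivity is union-find over a
spatial-index edge set, verified against adjacency-matrix connected
components.

The mean cluster size averages over clusters *including singletons* (so
"no clusters" reads as mean ≈ 1); the vesicle-weighted alternative is
exposed as an option. The growth classifier looks at the trailing 30% of
the curve: tail mean < 1.5 is `none`; otherwise the least-squares slope,
normalized to fractional growth across the tail window, below 0.05 is
`saturated`, else `growing`. The published record distinguishes these
regimes visually; these two thresholds are config keys chosen so the three
regimes separate cleanly, not measured quantities.

# Synthetic data: what it emulates and what it does not

* `sample_simulation_radii()` — the truncated-normal radius distribution
  used as simulator input.
* `sample_cryoem_radii()` — lognormal radii in nm whose arithmetic mean
  and sd equal the published histogram fit (41.3 nm, 10.8 nm at n = 586).
  The published "mean/sd" pair is interpreted as the distribution's
  arithmetic moments (moment-matched $\mu, \sigma$ on the log scale), not
  the log-scale parameters; the +5 nm segmentation-bias correction applies
  to raw image segmentation and is out of scope — generators produce
  corrected radii directly.
* `fit_lognormal()` — closed-form maximum likelihood (mean and 1/n-sd of
  log radii), reported back as arithmetic moments.
* `make_adhesion_fixture()` / `make_two_vesicle_config()` — deterministic
  measurement rows and two-vesicle micro-configurations for tests.

Every generator is a pure function of its parameters and seed. A green
test on synthetic data establishes parameter recovery and internal
consistency — not agreement with any real micrograph: the generators have
no segmentation noise, no polydispersity beyond the stated distribution,
and no spatial correlation between neighboring vesicles.

# Scaled-down validation runs

The published simulations use 200 vesicles in a 400 × 400 box for
$5\times10^7$ steps. The package's validation runs keep the *density*
(50 vesicles in a 200 × 200 box) and run $10^6$ steps of the published
$\Delta t = 5\times10^{-3}$ — 2% of the published duration, chosen so the
whole suite stays within a CI budget. Consequences, measured with this
package and stated honestly:

* the mono-domain pathology appears on this time scale as a
  partial-coalescence signature — each vesicle's synapsins aggregate into
  contact-packed patches that open long bare arcs, and cluster growth
  stalls at a few vesicles — but the tail mean (about 4.2 over three
  seeds) sits at, or slightly above, the upper edge of the reported
  order-of-three average;
* the bi-domain regime contrast (saturation at
  $\varepsilon = 3.5, \lambda = 0.5$ vs continued growth at
  $\varepsilon = 5, \lambda = 0.9$) is qualitative and rank-order only —
  the full-duration, full-size growth curves are not desk-reproducible.

Numerical safeguards: blow-up detection (non-finite coordinates abort with
the step index), placement failure is an explicit error, NVE integration
(thermostat off) conserves energy to $10^{-4}$ relative over $10^4$ steps
in the test suite.

# Known limitations

* Strictly 2D; no explicit membrane deformation, elasticity, or
  hydrodynamics; no synapsin binding/unbinding kinetics.
* The thermostat constants ($k_BT, \gamma, m$) are conventions, so
  absolute time scales and rates are not comparable to experiment.
* The adhesion model neglects curvature energy (valid only in the
  strong-adhesion limit) and assumes equal-size vesicle pairs.
* `classify_growth()` is a pragmatic classifier for curves the source
  describes visually; near-threshold curves are genuinely ambiguous.
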