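#' @title Synthetic inputs: radius distributions and fixtures
#' @description
#' Seeded generators for every input the pipeline needs: truncated-normal
#' vesicle radii in reduced simulation units, lognormal radii in nm
#' emulating the cryo-EM segmentation histogram, closed-form
#' maximum-likelihood lognormal fitting, and Table-1-style adhesion
#' measurement fixtures.
#' @name synthetic-data
NULL

#' Vesicle radii for simulation input (truncated normal)
#'
#' Draws from `Normal(mean, sd)` and resamples any value below
#' `min_radius`, i.e. a left-truncated normal. Reduced units
#' (1 unit = 10 nm); the default truncation at 1.0 (10 nm) matches the
#' smallest vesicles resolved by cryo-EM.
#'
#' @param n number of radii.
#' @param mean,sd normal parameters, reduced units (defaults 4.17, 1.08).
#' @param min_radius truncation bound, reduced units.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `vc_radius_sample`: list with `radii`,
#'   `distribution`, `parameters`, `seed`.
#' @export
sample_simulation_radii <- function(n, mean = 4.17, sd = 1.08,
                                    min_radius = 1.0, seed = NULL) {
  stopifnot(n >= 0, sd >= 0, min_radius > 0)
  if (sd == 0 && mean < min_radius)
    stop("infeasible truncation: zero-sd distribution below min_radius")
  if (stats::pnorm(min_radius, mean, sd) > 0.999 && sd > 0)
    stop("infeasible truncation: min_radius far above the distribution")
  if (!is.null(seed)) set.seed(seed)
  radii <- numeric(0)
  while (length(radii) < n) {
    draw <- stats::rnorm(max(n - length(radii), 1L), mean, sd)
    radii <- c(radii, draw[draw >= min_radius])
  }
  structure(list(radii = radii[seq_len(n)],
                 distribution = "normal_truncated",
                 parameters = c(mean = mean, sd = sd,
                                min_radius = min_radius),
                 units = "reduced", seed = seed),
            class = "vc_radius_sample")
}

#' Moment-matched lognormal parameters
#'
#' Maps an arithmetic `(mean, sd)` pair to the underlying `(log_mu,
#' log_sigma)` of a lognormal: `log_sigma^2 = log(1 + (sd/mean)^2)`,
#' `log_mu = log(mean) - log_sigma^2 / 2`.
#'
#' @param mean,sd arithmetic mean and standard deviation (> 0).
#' @return list with `log_mu`, `log_sigma`.
#' @export
lognormal_moments_to_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(log_mu = log(mean) - s2 / 2, log_sigma = sqrt(s2))
}

#' Arithmetic moments of a lognormal
#'
#' Inverse of [lognormal_moments_to_params()].
#'
#' @param log_mu,log_sigma parameters of the normal on the log scale.
#' @return list with `mean`, `sd`.
#' @export
lognormal_params_to_moments <- function(log_mu, log_sigma) {
  m <- exp(log_mu + log_sigma^2 / 2)
  list(mean = m, sd = m * sqrt(exp(log_sigma^2) - 1))
}

#' Vesicle radii emulating the cryo-EM histogram (lognormal)
#'
#' Draws lognormal radii in nm whose distribution mean and sd equal the
#' requested values (moment-matched parameters); defaults reproduce the
#' segmented-vesicle histogram fit (mean 41.3 nm, sd 10.8 nm, n = 586
#' vesicles in the source data).
#'
#' @param n number of radii.
#' @param mean,sd arithmetic mean and sd of the distribution, nm.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `vc_radius_sample` with radii in nm.
#' @export
sample_cryoem_radii <- function(n, mean = 41.3, sd = 10.8, seed = NULL) {
  stopifnot(n >= 0)
  p <- lognormal_moments_to_params(mean, sd)
  if (!is.null(seed)) set.seed(seed)
  radii <- stats::rlnorm(n, p$log_mu, p$log_sigma)
  structure(list(radii = radii, distribution = "lognormal",
                 parameters = c(mean = mean, sd = sd,
                                log_mu = p$log_mu, log_sigma = p$log_sigma),
                 units = "nm", seed = seed),
            class = "vc_radius_sample")
}

#' @export
print.vc_radius_sample <- function(x, ...) {
  cat(sprintf("<vc_radius_sample> n = %d, %s(%s) [%s]\n",
              length(x$radii), x$distribution,
              paste(sprintf("%s=%.4g", names(x$parameters), x$parameters),
                    collapse = ", "),
              x$units))
  invisible(x)
}

#' Maximum-likelihood lognormal fit
#'
#' Closed-form MLE: `log_mu` is the mean of the log radii and `log_sigma`
#' the (1/n) standard deviation of the log radii; the reported `mean` and
#' `sd` are the fitted distribution's arithmetic moments.
#'
#' @param radii positive radii (length >= 10); a `vc_radius_sample` is
#'   also accepted.
#' @return object of class `vc_lognormal_fit`: `mean`, `sd`, `log_mu`,
#'   `log_sigma`, `n`.
#' @export
fit_lognormal <- function(radii) {
  if (inherits(radii, "vc_radius_sample")) radii <- radii$radii
  if (length(radii) < 10) stop("need at least 10 radii")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite")
  lx <- log(radii)
  mu <- mean(lx)
  sig <- sqrt(mean((lx - mu)^2)) # MLE uses 1/n, not 1/(n-1)
  mom <- lognormal_params_to_moments(mu, sig)
  structure(list(mean = mom$mean, sd = mom$sd, log_mu = mu, log_sigma = sig,
                 n = length(radii)),
            class = "vc_lognormal_fit")
}

#' @export
print.vc_lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<vc_lognormal_fit> n = %d: mean = %.3f, sd = %.3f (log_mu = %.4f, log_sigma = %.4f)\n",
    x$n, x$mean, x$sd, x$log_mu, x$log_sigma))
  invisible(x)
}

#' Table-1-style adhesion measurement fixture
#'
#' Builds a synthetic `(R1, R2, 2theta, W_a)` record: both radii are the
#' constant-volume deformed radius for the given undeformed radius, and
#' `W_a` is the closed-form adhesion energy at the (optionally noisy)
#' angle. With zero noise the record round-trips exactly through
#' [adhesion_energy_from_angle()].
#'
#' @param two_theta_deg full contact angle, degrees.
#' @param R0_nm undeformed vesicle radius, nm.
#' @param material a [material_params()] object.
#' @param noise_sd_deg Gaussian noise (degrees) added to the angle before
#'   computing `W_a`.
#' @param seed integer seed (used only when `noise_sd_deg > 0`).
#' @return data.frame row with `R1_nm`, `R2_nm`, `two_theta_deg`,
#'   `W_a_kbt_per_nm2`.
#' @export
make_adhesion_fixture <- function(two_theta_deg, R0_nm = 35,
                                  material = material_params(),
                                  noise_sd_deg = 0, seed = NULL) {
  stopifnot(two_theta_deg > 0, two_theta_deg < 360)
  if (noise_sd_deg > 0) {
    if (!is.null(seed)) set.seed(seed)
    two_theta_deg <- two_theta_deg + stats::rnorm(length(two_theta_deg),
                                                  0, noise_sd_deg)
  }
  theta <- two_theta_deg / 2 * pi / 180
  R <- constant_volume_radius(theta, R0_nm)
  data.frame(R1_nm = R, R2_nm = R, two_theta_deg = two_theta_deg,
             W_a_kbt_per_nm2 = vapply(theta, adhesion_energy_from_angle,
                                      numeric(1), material = material))
}
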