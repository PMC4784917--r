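#' Fluid environment around the nanoparticles
#'
#' @param viscosity Dynamic viscosity eta of the suspending fluid (Pa s).
#'   Water at room temperature is about 1e-3.
#' @param temperature Absolute temperature T (K). Default 293 K (room
#'   temperature).
#' @param density Fluid mass density rho (kg/m^3). Default 1e3 (water).
#' @return An object of class `msb_environment`.
#' @export
#' @examples
#' msb_environment(viscosity = 1e-3, temperature = 293)
msb_environment <- function(viscosity = 1e-3, temperature = 293, density = 1e3) {
  stopifnot(is.numeric(viscosity), is.numeric(temperature), is.numeric(density))
  if (viscosity <= 0) stop("viscosity must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (density <= 0) stop("density must be positive")
  structure(list(viscosity = viscosity, temperature = temperature,
                 density = density),
            class = "msb_environment")
}

#' Oscillating drive field along +z
#'
#' The applied field is H(t) = H0 cos(2 pi f t) zhat.  Amplitudes are stored
#' as the magnetic flux density B0 = mu_0 H0 in tesla, the convention in which
#' experimental MSB drive amplitudes ("5 mT") are quoted.
#'
#' @param amplitude Peak amplitude B0 = mu_0 H0 (T).
#' @param frequency Drive frequency f (Hz).
#' @return An object of class `msb_drive_field`.
#' @export
#' @examples
#' msb_drive_field(amplitude = 5e-3, frequency = 1000)
msb_drive_field <- function(amplitude, frequency) {
  stopifnot(is.numeric(amplitude), is.numeric(frequency))
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (frequency <= 0) stop("frequency must be positive")
  structure(list(amplitude = amplitude, frequency = frequency),
            class = "msb_drive_field")
}

#' Nanoparticle population specification
#'
#' Mean and dispersion of the core (magnetic) and hydrodynamic radii, plus the
#' saturation magnetization of the core material.  Radii are stored as radii;
#' the hydrodynamic volume is computed from the diameter d = 2 r via
#' V = pi d^3 / 6.  Both radii are modelled as lognormal; by default the
#' standard deviation is 10% of the mean for each.
#'
#' @param mean_core_radius Mean core radius (m).
#' @param mean_hydro_radius Mean hydrodynamic radius (m).
#' @param Ms Saturation magnetization of the core material (A/m).
#' @param cv Coefficient of variation s_r / m_r applied to both radii
#'   (dimensionless, default 0.10).
#' @param sd_core_radius,sd_hydro_radius Optional explicit standard deviations
#'   (m); override `cv` when given.
#' @return An object of class `msb_particle_spec`.
#' @export
#' @examples
#' # typical MSB tracer: 20 nm core, 50 nm hydrodynamic radius, 250 kA/m
#' msb_particle_spec(20e-9, 50e-9, Ms = 250e3)
msb_particle_spec <- function(mean_core_radius, mean_hydro_radius, Ms,
                              cv = 0.10,
                              sd_core_radius = NULL, sd_hydro_radius = NULL) {
  if (mean_core_radius <= 0 || mean_hydro_radius <= 0)
    stop("mean radii must be positive")
  if (Ms <= 0) stop("Ms must be positive")
  if (cv < 0) stop("cv must be non-negative")
  s_core <- if (is.null(sd_core_radius)) cv * mean_core_radius else sd_core_radius
  s_hyd  <- if (is.null(sd_hydro_radius)) cv * mean_hydro_radius else sd_hydro_radius
  if (s_core < 0 || s_hyd < 0) stop("radius standard deviations must be non-negative")
  structure(list(mean_core_radius = mean_core_radius,
                 mean_hydro_radius = mean_hydro_radius,
                 sd_core_radius = s_core, sd_hydro_radius = s_hyd,
                 Ms = Ms),
            class = "msb_particle_spec")
}

#' Zero-field Brownian rotational relaxation time
#'
#' tau_B = 3 eta V / (k_B T) with hydrodynamic volume V = pi d^3 / 6.  This is
#' the timescale on which mechanical rotation of the whole particle decorrelates
#' its dipole orientation; binding, viscosity and temperature all act through it.
#'
#' @param viscosity Dynamic viscosity (Pa s).
#' @param d_hyd Hydrodynamic diameter (m).
#' @param temperature Temperature (K).
#' @return Relaxation time in seconds (vectorized over its arguments).
#' @export
#' @examples
#' brownian_relaxation_time(1e-3, 100e-9, 293)  # ~3.9e-4 s
brownian_relaxation_time <- function(viscosity, d_hyd, temperature) {
  if (any(viscosity <= 0)) stop("viscosity must be positive")
  if (any(d_hyd < 0)) stop("d_hyd must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive")
  V <- pi * d_hyd^3 / 6
  3 * viscosity * V / (msb_constants$k_B * temperature)
}

#' Unitless field amplitude
#'
#' xi0 = mu B0 / (k_B T): the Zeeman energy of the dipole at peak drive field
#' over the thermal energy.
#'
#' @param moment Magnetic moment magnitude mu (A m^2).
#' @param B0 Peak field amplitude mu_0 H0 (T).
#' @param temperature Temperature (K).
#' @return Dimensionless field amplitude (vectorized).
#' @export
unitless_field <- function(moment, B0, temperature) {
  if (any(moment < 0)) stop("moment must be non-negative")
  if (any(B0 < 0)) stop("B0 must be non-negative")
  if (any(temperature <= 0)) stop("temperature must be positive")
  moment * B0 / (msb_constants$k_B * temperature)
}

#' Unitless drive frequency
#'
#' Omega = f tau_B, the drive frequency in units of the inverse relaxation
#' time.  Omega > 1 means the field oscillates faster than the particle can
#' relax.
#'
#' @param frequency Drive frequency f (Hz).
#' @param tau_B Brownian relaxation time (s).
#' @return Dimensionless frequency (vectorized).
#' @export
unitless_frequency <- function(frequency, tau_B) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  if (any(tau_B <= 0)) stop("tau_B must be positive")
  frequency * tau_B
}

#' The master variable A = xi0 / Omega
#'
#' The single dimensionless group that parameterizes the mean rotational
#' dynamics when the deterministic torque dominates (xi0 > Omega).  Invariant
#' under scaling field and frequency (or relaxation time) by the same factor.
#'
#' @param xi0 Unitless field amplitude.
#' @param omega Unitless frequency.
#' @return Dimensionless master variable (vectorized).
#' @export
#' @examples
#' master_variable(6, 0.5)  # 12
master_variable <- function(xi0, omega) {
  if (any(xi0 < 0)) stop("xi0 must be non-negative")
  if (any(omega <= 0)) stop("omega must be positive")
  xi0 / omega
}

#' Rotational Reynolds number
#'
#' Re = rho f d^2 / eta, estimating rotational velocity as frequency times
#' hydrodynamic diameter.  For nanoparticle biosensing conditions Re ~ 1e-5,
#' which justifies dropping angular acceleration (inertia) from the dynamics.
#'
#' @param density Fluid density (kg/m^3).
#' @param frequency Rotation/drive frequency (Hz); may be zero.
#' @param d_hyd Hydrodynamic diameter (m).
#' @param viscosity Dynamic viscosity (Pa s).
#' @return Dimensionless Reynolds number (vectorized).
#' @export
#' @examples
#' reynolds_number(1e3, 1e3, 100e-9, 1e-3)  # 1e-5
reynolds_number <- function(density, frequency, d_hyd, viscosity) {
  if (any(density <= 0)) stop("density must be positive")
  if (any(frequency < 0)) stop("frequency must be non-negative")
  if (any(d_hyd <= 0)) stop("d_hyd must be positive")
  if (any(viscosity <= 0)) stop("viscosity must be positive")
  density * frequency * d_hyd^2 / viscosity
}

#' Magnetic moment from core radius
#'
#' mu = Ms * (4/3) pi r_core^3: the dipole moment of a uniformly magnetized
#' core at saturation.
#'
#' @param r_core Core radius (m).
#' @param Ms Saturation magnetization (A/m).
#' @return Moment in A m^2 (vectorized).
#' @export
moment_from_core <- function(r_core, Ms) {
  if (any(r_core < 0)) stop("r_core must be non-negative")
  if (any(Ms <= 0)) stop("Ms must be positive")
  Ms * (4 / 3) * pi * r_core^3
}

#' Lognormal scale parameter for a given coefficient of variation
#'
#' sigma_r = sqrt(log(1 + s_r^2 / m_r^2)): the log-scale standard deviation of
#' the moment-matched lognormal with mean m_r and standard deviation s_r.
#' @noRd
lognormal_sigma <- function(m_r, s_r) sqrt(log(1 + (s_r / m_r)^2))

#' Sample lognormally distributed particle radii
#'
#' Radii are drawn from the moment-matched lognormal: log-scale parameters
#' meanlog = log(m_r) - sigma_r^2/2 and sdlog = sigma_r with
#' sigma_r = sqrt(log(1 + s_r^2/m_r^2)), so the sample mean converges to `m_r`
#' and the sample standard deviation to `s_r`.  `s_r = 0` returns the
#' degenerate all-equal sample.
#'
#' @param m_r Mean radius (m).
#' @param s_r Standard deviation of the radius (m); default is 10% of the mean.
#' @param n Number of particles.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of `n` strictly positive radii.
#' @export
#' @examples
#' r <- sample_lognormal_radii(50e-9, 5e-9, 1000, seed = 1)
#' mean(r)
sample_lognormal_radii <- function(m_r, s_r = 0.10 * m_r, n, seed = NULL) {
  if (m_r <= 0) stop("m_r must be positive")
  if (s_r < 0) stop("s_r must be non-negative")
  if (n < 1) stop("n must be at least 1")
  if (s_r == 0) return(rep(m_r, n))
  sig <- lognormal_sigma(m_r, s_r)
  mlog <- log(m_r) - sig^2 / 2
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  stats::rlnorm(n, meanlog = mlog, sdlog = sig)
}

#' Sample a polydisperse particle ensemble
#'
#' Draws core and hydrodynamic radii independently (each lognormal with its own
#' mean and standard deviation from the spec) and derives per-particle volumes,
#' moments and relaxation times.  Draw order: core radii first, hydrodynamic
#' radii second.
#'
#' @param spec An [msb_particle_spec()].
#' @param env An [msb_environment()].
#' @param n Number of particles.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `msb_ensemble`: list with numeric vectors
#'   `r_core`, `r_hyd`, `V_core`, `V_hyd`, `moment` (A m^2), `tau_B` (s).
#' @export
#' @examples
#' spec <- msb_particle_spec(20e-9, 50e-9, Ms = 250e3)
#' ens <- sample_ensemble(spec, msb_environment(), n = 100, seed = 1)
#' mean(ens$tau_B)
sample_ensemble <- function(spec, env, n, seed = NULL) {
  stopifnot(inherits(spec, "msb_particle_spec"), inherits(env, "msb_environment"))
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  r_core <- sample_lognormal_radii(spec$mean_core_radius, spec$sd_core_radius, n)
  r_hyd <- sample_lognormal_radii(spec$mean_hydro_radius, spec$sd_hydro_radius, n)
  V_core <- (4 / 3) * pi * r_core^3
  V_hyd <- pi * (2 * r_hyd)^3 / 6
  moment <- moment_from_core(r_core, spec$Ms)
  tau_B <- brownian_relaxation_time(env$viscosity, 2 * r_hyd, env$temperature)
  structure(list(r_core = r_core, r_hyd = r_hyd, V_core = V_core,
                 V_hyd = V_hyd, moment = moment, tau_B = tau_B),
            class = "msb_ensemble")
}

#' Per-particle dimensionless parameters for an ensemble under a drive
#'
#' @param ensemble An [sample_ensemble()] result.
#' @param field An [msb_drive_field()].
#' @param env An [msb_environment()].
#' @return A list with vectors `xi0`, `omega` and scalars `xi0_mean`,
#'   `omega_mean`, `A` (the master variable of the mean parameters).
#' @export
ensemble_dimensionless <- function(ensemble, field, env) {
  stopifnot(inherits(ensemble, "msb_ensemble"),
            inherits(field, "msb_drive_field"),
            inherits(env, "msb_environment"))
  xi0 <- unitless_field(ensemble$moment, field$amplitude, env$temperature)
  omega <- unitless_frequency(field$frequency, ensemble$tau_B)
  list(xi0 = xi0, omega = omega,
       xi0_mean = mean(xi0), omega_mean = mean(omega),
       A = mean(xi0) / mean(omega))
}

#' Master variable of the mean ensemble parameters
#'
#' A = <xi0> / <Omega>, the polydisperse generalization of the single-particle
#' master variable: both dispersion channels (moment through the core volume,
#' relaxation time through the hydrodynamic volume) enter through the means.
#'
#' @inheritParams ensemble_dimensionless
#' @return Dimensionless scalar.
#' @export
ensemble_master_variable <- function(ensemble, field, env) {
  if (length(ensemble$moment) == 0) stop("ensemble is empty")
  ensemble_dimensionless(ensemble, field, env)$A
}

#' @export
print.msb_ensemble <- function(x, ...) {
  cat(sprintf("msb_ensemble: %d particles\n", length(x$r_core)))
  cat(sprintf("  core radius   %.3g +/- %.3g nm\n",
              mean(x$r_core) * 1e9, stats::sd(x$r_core) * 1e9))
  cat(sprintf("  hydro radius  %.3g +/- %.3g nm\n",
              mean(x$r_hyd) * 1e9, stats::sd(x$r_hyd) * 1e9))
  cat(sprintf("  tau_B         %.3g s (mean)\n", mean(x$tau_B)))
  invisible(x)
}
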