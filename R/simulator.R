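#' Simulation control parameters
#'
#' Bundles the numerical knobs of the stochastic integrator.  The time step
#' must resolve both the drive period and the relaxation dynamics: the rule is
#' dt* <= min(0.01 * Omega_min, 1e-3) for an oscillating drive, where
#' Omega_min is the smallest unitless frequency in the ensemble (the 1e-3 cap
#' guarantees at least 1000 steps per drive period even when Omega is large).
#' When `dt_star` is NULL it is chosen automatically from that rule and rounded
#' so that an integer number of steps tiles one drive period exactly, which
#' makes the Fourier analysis window exact.
#'
#' @param n_particles Number of independent dipoles to integrate.
#' @param n_periods_transient Drive periods discarded before recording; NULL
#'   (default) uses max(2, ceiling(3 * Omega_max)), roughly three relaxation
#'   times in dimensionless units.
#' @param n_periods_analysis Drive periods recorded for analysis.
#' @param dt_star Dimensionless time step; NULL for the automatic rule.
#' @param seed Integer seed controlling initial orientations and thermal noise.
#' @param noise Logical; FALSE integrates the noise-free dynamics.
#' @param init Initial orientation policy: "uniform" (uniform on the sphere)
#'   or "aligned" (all along +z).
#' @param n_blocks Number of independent sub-ensembles; block-level mean traces
#'   are retained so downstream statistics (e.g. harmonic amplitudes) can carry
#'   Monte-Carlo standard errors.
#' @return An object of class `sim_control`.
#' @export
sim_control <- function(n_particles = 1e4, n_periods_transient = NULL,
                        n_periods_analysis = 2, dt_star = NULL, seed = 1,
                        noise = TRUE, init = c("uniform", "aligned"),
                        n_blocks = 1) {
  init <- match.arg(init)
  if (n_particles < 1) stop("n_particles must be at least 1")
  if (!is.null(n_periods_transient) && n_periods_transient < 0)
    stop("n_periods_transient must be non-negative")
  if (n_periods_analysis < 1) stop("n_periods_analysis must be at least 1")
  if (!is.null(dt_star) && dt_star <= 0) stop("dt_star must be positive")
  if (n_blocks < 1 || n_blocks > n_particles)
    stop("n_blocks must be between 1 and n_particles")
  structure(list(n_particles = as.integer(n_particles),
                 n_periods_transient = n_periods_transient,
                 n_periods_analysis = as.integer(n_periods_analysis),
                 dt_star = dt_star, seed = as.integer(seed),
                 noise = isTRUE(noise), init = init,
                 n_blocks = as.integer(n_blocks)),
            class = "sim_control")
}

# Maximum admissible dt* for a given set of per-particle Omega values.
# The 1e-3 cap exists to resolve the drive period, so it applies only to
# oscillating drives; the static-field mode is governed by the Omega rule
# alone.
max_dt_star <- function(omega, static_field = FALSE) {
  if (static_field) 0.01 * min(omega) else min(0.01 * min(omega), 1e-3)
}

# Resolve dt* so that an integer number of steps tiles the unit t* interval.
resolve_dt_star <- function(control, omega, static_field = FALSE) {
  cap <- max_dt_star(omega, static_field)
  if (is.null(control$dt_star)) {
    spp <- ceiling(1 / cap)
    return(list(dt_star = 1 / spp, steps_per_period = as.integer(spp)))
  }
  if (control$dt_star > cap * (1 + 1e-12))
    stop(sprintf(paste0("dt_star = %g violates the step rule dt* <= %g ",
                        "(min(0.01*Omega_min, 1e-3)) for this ensemble"),
                 control$dt_star, cap))
  spp <- round(1 / control$dt_star)
  if (abs(spp * control$dt_star - 1) > 1e-9)
    stop("dt_star must divide the unit t* interval exactly")
  list(dt_star = 1 / spp, steps_per_period = as.integer(spp))
}

#' Deterministic drift term of the dimensionless Langevin equation
#'
#' (xi0 / 2 Omega) * m x (cos(2 pi t*) zhat x m): the viscous-limited magnetic
#' torque, always perpendicular to m.
#'
#' @param m Orientation 3-vector (unit length for physical states).
#' @param t_star Dimensionless time.
#' @param xi0,omega Dimensionless field amplitude and frequency.
#' @return Drift 3-vector.
#' @export
deterministic_drift <- function(m, t_star, xi0, omega) {
  stopifnot(length(m) == 3)
  if (omega <= 0) stop("omega must be positive")
  h <- cos(2 * pi * t_star)
  pref <- xi0 / (2 * omega)
  # m x (h zhat x m) = h * (zhat (m.m) - m m_z)
  mm <- sum(m * m)
  pref * h * c(-m[1] * m[3], -m[2] * m[3], mm - m[3]^2)
}

#' One two-step Heun update of an orientation vector
#'
#' Predictor: mbar = m + (xi0 dt*/2 Omega) m x (cos(2 pi t*) zhat x m)
#'                   + (m x N) sqrt(dt*/Omega).
#' Corrector: m' = m + (xi0 dt*/4 Omega) [mbar x (cos(2 pi (t*+dt*)) zhat x mbar)
#'                   + m x (cos(2 pi t*) zhat x m)]
#'                   + ((m + mbar)/2 x N) sqrt(dt*/Omega),
#' with the same Gaussian 3-vector N in both stages, then renormalized to unit
#' length.  Heun converges to the Stratonovich interpretation of the
#' multiplicative noise, which yields the Boltzmann stationary distribution.
#'
#' @param m Unit orientation 3-vector.
#' @param t_star Current dimensionless time.
#' @param dt_star Time step.
#' @param xi0,omega Dimensionless field amplitude and frequency.
#' @param noise Standard Gaussian 3-vector N(0,1); zeros for a deterministic
#'   step.
#' @param static_field Logical; TRUE freezes the drive factor cos(2 pi t*) at
#'   1 (constant field, time in units of tau_B).
#' @return Updated unit 3-vector.
#' @export
heun_step <- function(m, t_star, dt_star, xi0, omega, noise = c(0, 0, 0),
                      static_field = FALSE) {
  heun_step_cpp(as.numeric(m), t_star, dt_star, xi0, omega,
                as.numeric(noise), static_field)
}

# Initial orientations per the control policy, drawn from R's RNG stream.
draw_initial_orientations <- function(n, init) {
  if (init == "aligned")
    return(cbind(rep(0, n), rep(0, n), rep(1, n)))
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Integrate an ensemble given dimensionless parameters directly
#'
#' The workhorse behind [simulate_ensemble()] and [simulate_deterministic()].
#' Each particle i is integrated with its own (xi0_i, Omega_i); the returned
#' trace is the ensemble mean of m_z on a uniform t* grid covering
#' `n_periods_analysis` drive periods after the transient is discarded.
#'
#' Reproducibility: for a fixed `control$seed` the run is deterministic.  The
#' seed drives, in order, the initial orientations (R's RNG) and one
#' sub-stream seed per block for the thermal noise consumed inside the
#' compiled kernel (three standard normal deviates per particle per step,
#' particle-major).
#'
#' @param xi0,omega Numeric scalars or vectors of length `n_particles`.
#' @param control A [sim_control()].
#' @param static_field Logical; TRUE integrates under a constant field
#'   (cos factor frozen at 1, t* measured in units of tau_B).  Used for
#'   equilibrium checks.
#' @return A `mag_trace`: data.frame with columns `t_star`, `mz_mean`,
#'   `mz_sem`, plus attributes recording the grid and run metadata (and the
#'   per-block mean traces when `n_blocks > 1`).
#' @export
simulate_dimensionless <- function(xi0, omega, control = sim_control(),
                                   static_field = FALSE) {
  stopifnot(inherits(control, "sim_control"))
  n <- control$n_particles
  if (length(xi0) == 1) xi0 <- rep(xi0, n)
  if (length(omega) == 1) omega <- rep(omega, n)
  if (length(xi0) != n || length(omega) != n)
    stop("xi0 and omega must be scalars or length n_particles")
  if (any(xi0 < 0)) stop("xi0 must be non-negative")
  if (any(omega <= 0)) stop("omega must be positive")

  grid <- resolve_dt_star(control, omega, static_field)
  dt <- grid$dt_star
  spp <- grid$steps_per_period
  n_trans <- control$n_periods_transient
  if (is.null(n_trans)) n_trans <- max(2, ceiling(3 * max(omega)))
  steps_transient <- as.integer(n_trans) * spp
  steps_record <- control$n_periods_analysis * spp

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(control$seed)
  m0 <- draw_initial_orientations(n, control$init)
  block_seeds <- sample.int(.Machine$integer.max, control$n_blocks)

  # partition particles into contiguous blocks
  block_id <- rep(seq_len(control$n_blocks), length.out = n)
  block_id <- sort(block_id)

  sum_mz <- numeric(steps_record)
  sumsq_mz <- numeric(steps_record)
  block_means <- if (control$n_blocks > 1)
    matrix(NA_real_, steps_record, control$n_blocks) else NULL
  block_n <- integer(control$n_blocks)

  for (b in seq_len(control$n_blocks)) {
    idx <- which(block_id == b)
    block_n[b] <- length(idx)
    res <- heun_simulate_cpp(m0[idx, , drop = FALSE], xi0[idx], omega[idx],
                             dt, steps_transient, steps_record,
                             control$noise, static_field, block_seeds[b])
    sum_mz <- sum_mz + res$sum_mz
    sumsq_mz <- sumsq_mz + res$sumsq_mz
    if (!is.null(block_means)) block_means[, b] <- res$sum_mz / length(idx)
  }

  mz_mean <- sum_mz / n
  mz_sem <- if (n > 1) {
    v <- pmax(0, (sumsq_mz - n * mz_mean^2) / (n - 1))
    sqrt(v / n)
  } else rep(NA_real_, steps_record)

  t_star <- (steps_transient + seq_len(steps_record) - 1) * dt
  out <- data.frame(t_star = t_star, mz_mean = mz_mean, mz_sem = mz_sem)
  class(out) <- c("mag_trace", "data.frame")
  attr(out, "dt_star") <- dt
  attr(out, "steps_per_period") <- spp
  attr(out, "n_periods_analysis") <- control$n_periods_analysis
  attr(out, "n_periods_transient") <- as.integer(n_trans)
  attr(out, "n_particles") <- n
  attr(out, "xi0_mean") <- mean(xi0)
  attr(out, "omega_mean") <- mean(omega)
  attr(out, "omega_range") <- range(omega)
  attr(out, "noise") <- control$noise
  attr(out, "static_field") <- static_field
  attr(out, "seed") <- control$seed
  if (!is.null(block_means)) {
    attr(out, "block_mz") <- block_means
    attr(out, "block_n") <- block_n
  }
  out
}

#' Simulate a physical particle ensemble under an oscillating drive
#'
#' Converts the per-particle physical parameters to (xi0_i, Omega_i) and
#' integrates the dimensionless Langevin dynamics.  The returned trace also
#' records the ensemble master variable A = <xi0>/<Omega>.
#'
#' @param ensemble An [sample_ensemble()] result.
#' @param field An [msb_drive_field()].
#' @param env An [msb_environment()].
#' @param control A [sim_control()]; its `n_particles` must match the ensemble
#'   size.
#' @return A `mag_trace` (see [simulate_dimensionless()]).
#' @export
#' @examples
#' spec <- msb_particle_spec(20e-9, 50e-9, Ms = 250e3)
#' env <- msb_environment()
#' ens <- sample_ensemble(spec, env, n = 200, seed = 1)
#' fld <- msb_drive_field(5e-3, 2500)
#' tr <- simulate_ensemble(ens, fld, env,
#'                         sim_control(n_particles = 200, seed = 1))
#' head(tr)
simulate_ensemble <- function(ensemble, field, env, control = sim_control()) {
  dl <- ensemble_dimensionless(ensemble, field, env)
  if (length(dl$xi0) != control$n_particles)
    stop("control$n_particles must equal the ensemble size")
  out <- simulate_dimensionless(dl$xi0, dl$omega, control)
  attr(out, "A") <- dl$A
  out
}

#' Noise-free magneto-dynamics parameterized by the master variable alone
#'
#' Integrates dm/dt* = (A/2) m x (cos(2 pi t*) zhat x m) — the dimensionless
#' dynamics with the thermal torque dropped, in which the trajectory depends
#' on (t*, A) only.  Any (xi0, Omega) pair with xi0/Omega = A produces a
#' bit-identical trace on the same grid.
#'
#' @param A Master variable (>= 0).
#' @param control A [sim_control()]; `n_particles` and `noise` are overridden
#'   (single trajectory, noise off).
#' @param m0 Initial orientation, default the equator (1, 0, 0) — the +z pole
#'   is a (measure-zero) equilibrium of the noise-free dynamics.
#' @return A `mag_trace` with `mz_sem` NA (single trajectory).
#' @export
simulate_deterministic <- function(A, control = sim_control(), m0 = c(1, 0, 0)) {
  if (A < 0) stop("A must be non-negative")
  stopifnot(length(m0) == 3)
  nrm <- sqrt(sum(m0^2))
  if (nrm == 0) stop("m0 must be non-zero")
  m0 <- m0 / nrm
  grid <- resolve_dt_star(control, omega = 1, static_field = FALSE)
  dt <- grid$dt_star
  spp <- grid$steps_per_period
  n_trans <- control$n_periods_transient
  if (is.null(n_trans)) n_trans <- 2L
  steps_transient <- as.integer(n_trans) * spp
  steps_record <- control$n_periods_analysis * spp
  res <- heun_simulate_cpp(matrix(m0, 1, 3), A, 1.0, dt, steps_transient,
                           steps_record, FALSE, FALSE, control$seed)
  t_star <- (steps_transient + seq_len(steps_record) - 1) * dt
  out <- data.frame(t_star = t_star, mz_mean = res$sum_mz,
                    mz_sem = NA_real_)
  class(out) <- c("mag_trace", "data.frame")
  attr(out, "dt_star") <- dt
  attr(out, "steps_per_period") <- spp
  attr(out, "n_periods_analysis") <- control$n_periods_analysis
  attr(out, "n_periods_transient") <- as.integer(n_trans)
  attr(out, "n_particles") <- 1L
  attr(out, "xi0_mean") <- A
  attr(out, "omega_mean") <- 1
  attr(out, "noise") <- FALSE
  attr(out, "static_field") <- FALSE
  attr(out, "seed") <- control$seed
  out
}

#' @export
print.mag_trace <- function(x, ...) {
  cat(sprintf(paste0("mag_trace: %d samples over %d period(s), %d particles, ",
                     "dt* = %g\n"),
              nrow(x), attr(x, "n_periods_analysis"),
              attr(x, "n_particles"), attr(x, "dt_star")))
  cat(sprintf("  <xi0> = %.4g, <Omega> = %.4g, noise %s\n",
              attr(x, "xi0_mean"), attr(x, "omega_mean"),
              if (isTRUE(attr(x, "noise"))) "on" else "off"))
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

#' Maximum deviation between two mean-magnetization traces
#'
#' Compares `mz_mean` pointwise on a shared t* grid and reports the largest
#' absolute deviation together with the pooled Monte-Carlo standard error,
#' the basis of the "agree within k pooled SE" collapse checks.
#'
#' @param trace1,trace2 `mag_trace` objects on identical grids.
#' @param normalize Logical; TRUE compares the traces after dividing each by
#'   its own peak |mz_mean| — the form in which scaling collapse of the mean
#'   magnetization is assessed (the residual thermal-relaxation difference
#'   between runs sharing a master variable shows up mostly as an amplitude
#'   factor, which normalization removes).
#' @return List with `max_dev`, `rms_dev`, `pooled_se` (pointwise pooled SE at
#'   the location of the maximum deviation), and `max_z` = max over the grid
#'   of |difference| / pooled SE.
#' @export
trace_deviation <- function(trace1, trace2, normalize = FALSE) {
  if (nrow(trace1) != nrow(trace2) ||
      max(abs(trace1$t_star - trace2$t_star)) > 1e-9)
    stop("traces must share an identical t* grid")
  y1 <- trace1$mz_mean; y2 <- trace2$mz_mean
  s1 <- trace1$mz_sem; s2 <- trace2$mz_sem
  if (normalize) {
    p1 <- max(abs(y1)); p2 <- max(abs(y2))
    if (p1 == 0 || p2 == 0) stop("cannot normalize an all-zero trace")
    y1 <- y1 / p1; s1 <- s1 / p1
    y2 <- y2 / p2; s2 <- s2 / p2
  }
  d <- y1 - y2
  se <- sqrt(s1^2 + s2^2)
  z <- abs(d) / pmax(se, .Machine$double.eps)
  i <- which.max(abs(d))
  list(max_dev = max(abs(d)), rms_dev = sqrt(mean(d^2)),
       pooled_se = se[i], max_z = max(z))
}
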