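# Independent oracles and small utilities shared across tests.

k_B <- 1.380649e-23

# Closed-form solution of the noise-free dynamics
#   dm/dt* = (A/2) m x (cos(2 pi t*) zhat x m)
# starting from m_z(0) = m0z: the polar angle obeys
#   d log(tan(theta/2))/dt* = -(A/2) cos(2 pi t*),
# which integrates to m_z(t*) = tanh(atanh(m0z) + (A/4pi) sin(2 pi t*)).
# Derived independently of the integrator; used as an exact reference.
det_mz_closed_form <- function(A, t_star, m0z = 0) {
  tanh(atanh(m0z) + (A / (4 * pi)) * sin(2 * pi * t_star))
}

# Langevin function written out directly (independent of msbsim::langevin)
langevin_ref <- function(x) ifelse(x == 0, 0, 1 / tanh(x) - 1 / x)

# Pure-R transcription of the two-step Heun update (predictor Eq-style,
# corrector, same noise in both stages) used to cross-check the compiled
# kernel and to observe the pre-renormalization norm drift.
heun_step_r <- function(m, t_star, dt, xi0, omega, N, renormalize = TRUE) {
  torque <- function(a, h) {
    aa <- sum(a * a)
    h * c(-a[1] * a[3], -a[2] * a[3], aa - a[3]^2)
  }
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(dt / omega)
  c0 <- cos(2 * pi * t_star)
  c1 <- cos(2 * pi * (t_star + dt))
  mbar <- m + (xi0 * dt / (2 * omega)) * torque(m, c0) + s * cr(m, N)
  out <- m + (xi0 * dt / (4 * omega)) * (torque(mbar, c1) + torque(m, c0)) +
    0.5 * s * cr(m + mbar, N)
  if (renormalize) out / sqrt(sum(out^2)) else out
}

# Time-averaged ensemble mean of m_z with a block-based standard error.
block_time_average <- function(trace) {
  bm <- attr(trace, "block_mz")
  stopifnot(!is.null(bm))
  bmeans <- colMeans(bm)
  list(mean = mean(trace$mz_mean), se = stats::sd(bmeans) / sqrt(length(bmeans)))
}

# Harmonic amplitude with a block-based standard error for one index.
block_harmonic <- function(trace, l) {
  sp <- harmonic_spectrum(trace, l_max = l)
  list(a = sp$a_l[sp$l == l], se = sp$a_l_se[sp$l == l])
}

# A small sampled square wave trace covering one period (exact grid).
square_wave_trace <- function(n = 4000) {
  t <- (seq_len(n) - 1) / n
  sign(cos(2 * pi * t))
}
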