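#' Debye linear-response magnetization under a weak oscillating field
#'
#' For a weak drive (xi0 << 1) the mean magnetization along the field follows
#' the Debye form
#'   m_z(t*) = (xi0/3) [cos(2 pi t*) + 2 pi Omega sin(2 pi t*)] / (1 + (2 pi Omega)^2),
#' the rotating-dipole analogue of the one-pole ac susceptibility: an in-phase
#' (cos) component and an out-of-phase (sin) component whose ratio is
#' 2 pi Omega.
#'
#' @param xi0 Unitless field amplitude (intended xi0 << 1).
#' @param omega Unitless frequency Omega > 0.
#' @param t_star Dimensionless time (vectorized).
#' @return m_z values.
#' @export
#' @examples
#' debye_magnetization(0.1, 1 / (2 * pi), 0)  # 0.1/6
debye_magnetization <- function(xi0, omega, t_star) {
  if (any(xi0 < 0)) stop("xi0 must be non-negative")
  if (any(omega <= 0)) stop("omega must be positive")
  w <- 2 * pi * omega
  (xi0 / 3) * (cos(2 * pi * t_star) + w * sin(2 * pi * t_star)) / (1 + w^2)
}

#' High-frequency (Omega > 1) limit of the Debye magnetization
#'
#' m_z ~ (A / 6 pi) sin(2 pi t*): in the fast-drive limit the response is a
#' pure quadrature component whose amplitude depends on the master variable
#' A = xi0/Omega alone.
#'
#' @param A Master variable.
#' @param t_star Dimensionless time (vectorized).
#' @return m_z values.
#' @export
debye_high_omega <- function(A, t_star) {
  if (any(A < 0)) stop("A must be non-negative")
  (A / (6 * pi)) * sin(2 * pi * t_star)
}

#' Low-frequency expansion of the Debye magnetization, to first order in Omega
#'
#' Expanding 1/(1 + (2 pi Omega)^2) for small Omega and keeping terms up to
#' O(Omega) gives m_z ~ (xi0/3) [cos(2 pi t*) + 2 pi Omega sin(2 pi t*)]: the
#' leading term is the quasi-static Curie response (xi0/3) cos, and the first
#' correction is proportional to xi0 * Omega — the field-frequency product
#' ("slew rate").  The denominator contributes no O(Omega) term, only
#' O(Omega^2).
#'
#' @inheritParams debye_magnetization
#' @return m_z values.
#' @export
debye_low_omega_expansion <- function(xi0, omega, t_star) {
  if (any(xi0 < 0)) stop("xi0 must be non-negative")
  if (any(omega < 0)) stop("omega must be non-negative")
  (xi0 / 3) * (cos(2 * pi * t_star) + 2 * pi * omega * sin(2 * pi * t_star))
}

#' First-harmonic amplitude predicted by the Debye model
#'
#' Under the spectroscopy convention a_1 = |F_1| with F_l the 1/T_w-normalized
#' Fourier coefficient, the Debye trace gives
#' a_1 = (xi0/6) / sqrt(1 + (2 pi Omega)^2).
#'
#' @inheritParams debye_magnetization
#' @return Predicted a_1.
#' @export
debye_first_harmonic <- function(xi0, omega) {
  if (any(xi0 < 0)) stop("xi0 must be non-negative")
  if (any(omega <= 0)) stop("omega must be positive")
  (xi0 / 6) / sqrt(1 + (2 * pi * omega)^2)
}

#' Slew rate: the field-frequency product
#'
#' Physically B0 * f (T/s up to a 2 pi), dimensionlessly xi0 * Omega: the
#' leading correction in the low-Omega expansion of the linear response, and
#' the combination reported to control the dynamics in slow-drive regimes.
#' Invariant under (B0, f) -> (B0/c, c f).
#'
#' @param B0 Field amplitude (T) or unitless field xi0.
#' @param f Frequency (Hz) or unitless frequency Omega.
#' @return The product B0 * f (vectorized).
#' @export
slew_rate <- function(B0, f) {
  if (any(B0 < 0) || any(f < 0)) stop("inputs must be non-negative")
  B0 * f
}
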