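#' Physical constants used throughout the package
#'
#' Boltzmann's constant (exact SI value) and the vacuum permeability, the only
#' physical constants the dimensionless dynamics need.
#'
#' @format A named list with elements `k_B` (J/K) and `mu_0` (T m/A).
#' @export
#' @examples
#' msb_constants$k_B
msb_constants <- list(
  k_B  = 1.380649e-23,
  mu_0 = 4e-7 * pi
)
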