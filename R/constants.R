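#' Physical constants for the rate models
#'
#' Returns the constants entering the Arrhenius and MMRT equations, frozen
#' at the 2018 CODATA / SI exact values.  `kB_over_h` is the precomputed
#' Boltzmann-to-Planck ratio used in the Eyring-type prefactor
#' \eqn{\ln(k_B T / h)}.
#'
#' @return A list with components `R` (gas constant, J mol^-1 K^-1), `kB`
#'   (Boltzmann constant, J K^-1), `h` (Planck constant, J s) and
#'   `kB_over_h` (K^-1 s^-1).
#' @examples
#' phys_constants()$R
#' @export
phys_constants <- function() {
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  list(R = 8.314462618, kB = kB, h = h, kB_over_h = kB / h)
}
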