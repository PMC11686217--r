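# Unit system: user-facing frequencies are nu-values in MHz, magnetic fields in
# uT, distances in Angstrom, rate constants in us^-1, correlation times in ns.
# Internally every Hamiltonian and superoperator is in angular frequency,
# rad us^-1, so that 1 MHz contributes 2*pi rad us^-1.

.ge <- 2.0023
.mu0 <- 4 * pi * 1e-7            # T^2 m^3 / J
.muB <- 9.2740100783e-24         # J / T
.hbar <- 1.054571817e-34         # J s

# free-electron gyromagnetic ratio, as a nu-value: MHz per mT
.gamma_e_MHz_mT <- 28.0249514242
# rad us^-1 per uT
.gamma_e <- 2 * pi * .gamma_e_MHz_mT * 1e-3

# point-dipole coupling coefficient: d(r) = .d_coeff / r^3 in rad us^-1 (r in A)
.d_coeff <- (1e-7 * (.ge * .muB)^2 / .hbar) * 1e24

.mhz <- function(nu) 2 * pi * nu          # MHz -> rad us^-1
.to_mhz <- function(omega) omega / (2 * pi)

#' Electron Larmor frequency
#'
#' Precession frequency of a free electron spin in a magnetic field, as a
#' nu-value. At the geomagnetic field strength of 50 uT this is 1.4 MHz.
#'
#' @param b_ut Field magnitude in microtesla.
#' @return Frequency in MHz.
#' @export
#' @examples
#' larmor_frequency(50)
larmor_frequency <- function(b_ut) .gamma_e_MHz_mT * 1e-3 * b_ut

#' Point-dipole coupling parameter d(r)
#'
#' Scalar electron-electron dipolar coupling d(r) = mu0 ge^2 muB^2 / (4 pi r^3)
#' for two point electron spins separated by `r`.
#'
#' @param r Inter-radical distance in Angstrom.
#' @param unit `"MHz"` (nu-value, default) or `"rad_us"` (angular frequency).
#' @return Coupling strength, positive.
#' @export
#' @examples
#' dipolar_coupling(4.56)         # about 549 MHz
#' 3 * dipolar_coupling(4.5) / 1e3  # extreme tensor span in GHz, about 1.7
dipolar_coupling <- function(r, unit = c("MHz", "rad_us")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(r), all(r > 0))
  d <- .d_coeff / r^3
  if (unit == "MHz") d / (2 * pi) else d
}
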