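#' Physical constants and nucleus definitions
#'
#' Single table of the constants used to turn internuclear distances into
#' dipolar-coupling anisotropies, so that hand calculations with CODATA
#' values reproduce package numbers to four significant figures.
#'
#' @format A named list with elements `mu0` (vacuum permeability, T m/A),
#'   `hbar` (reduced Planck constant, J s), and `gamma` (named vector of
#'   gyromagnetic ratios in rad s^-1 T^-1 for `"1H"` and `"15N"`).
#' @export
nmr_constants <- list(
  mu0  = 4 * pi * 1e-7,
  hbar = 1.0545718e-34,
  gamma = c("1H" = 2.67522e8, "15N" = -2.7126e7)
)

#' Describe a spin-1/2 nucleus
#'
#' All supported isotopes are spin 1/2. The gyromagnetic ratio of 1H is
#' positive, that of 15N negative.
#'
#' @param isotope_label `"1H"` or `"15N"`.
#' @return A `nucleus_spec` list with `isotope_label` and
#'   `gyromagnetic_ratio` (rad s^-1 T^-1).
#' @examples
#' nucleus_spec("1H")$gyromagnetic_ratio
#' @export
nucleus_spec <- function(isotope_label) {
  if (!isotope_label %in% names(nmr_constants$gamma)) {
    stop("unsupported isotope: ", isotope_label, call. = FALSE)
  }
  structure(
    list(
      isotope_label = isotope_label,
      gyromagnetic_ratio = unname(nmr_constants$gamma[[isotope_label]]),
      spin = 0.5
    ),
    class = "nucleus_spec"
  )
}

#' @export
print.nucleus_spec <- function(x, ...) {
  cat(sprintf(
    "<nucleus_spec> %s  (spin 1/2, gamma = %.5g rad s^-1 T^-1)\n",
    x$isotope_label, x$gyromagnetic_ratio
  ))
  invisible(x)
}

#' Larmor frequency of an isotope at a given static field
#'
#' @param isotope isotope label, e.g. `"1H"`.
#' @param field_T static magnetic field in tesla (20.0 T corresponds to a
#'   ~850 MHz proton frequency).
#' @return Absolute Larmor frequency in Hz.
#' @export
larmor_frequency <- function(isotope, field_T) {
  abs(nmr_constants$gamma[[isotope]]) * field_T / (2 * pi)
}
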