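#' SERS enhancement factor
#'
#' `EF = (I_sers / C_sers) / (I_rs / C_rs)`: the concentration-normalized
#' intensity ratio between the surface-enhanced measurement and the normal
#' Raman reference of the reporter molecule.
#'
#' @param i_sers SERS band intensity (counts, > 0).
#' @param c_sers Reporter concentration in the SERS measurement
#'   (mol L^-1, > 0).
#' @param i_rs Normal Raman band intensity (counts, > 0).
#' @param c_rs Reporter concentration in the normal Raman measurement
#'   (mol L^-1, > 0).
#' @return Unitless enhancement factor.
#' @export
enhancement_factor <- function(i_sers, c_sers, i_rs, c_rs) {
  vals <- c(i_sers, c_sers, i_rs, c_rs)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all intensities and concentrations must be positive",
         call. = FALSE)
  }
  (i_sers / c_sers) / (i_rs / c_rs)
}

#' Relative standard deviation in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation; the
#' substrate-uniformity metric for replicate band intensities.
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return RSD in percent.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD undefined", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Band intensity at a wavenumber
#'
#' The maximum intensity within `center +/- halfwidth` cm^-1, the
#' band-intensity readout used for uniformity statistics.
#'
#' @param spectrum A [sers_spectrum()].
#' @param center Band position in cm^-1.
#' @param halfwidth Search half-window in cm^-1.
#' @return Peak intensity (counts).
#' @export
peak_intensity <- function(spectrum, center, halfwidth = 5) {
  sel <- abs(spectrum$wavenumbers - center) <= halfwidth
  if (!any(sel)) {
    stop("no grid point within the requested window", call. = FALSE)
  }
  max(spectrum$intensities[sel])
}

#' Substrate uniformity from replicate spectra
#'
#' Extracts the band intensity at `center` from every spectrum in the set
#' and returns the intensities and their RSD.
#'
#' @param set A [sers_set()] of replicate spectra.
#' @param center Band position in cm^-1.
#' @param halfwidth Search half-window in cm^-1.
#' @return A list with `intensities` and `rsd_percent`.
#' @export
substrate_uniformity <- function(set, center, halfwidth = 5) {
  ints <- vapply(seq_len(n_spectra(set)), function(i) {
    peak_intensity(get_spectrum(set, i), center, halfwidth)
  }, 0)
  list(intensities = ints, rsd_percent = rsd(ints))
}
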