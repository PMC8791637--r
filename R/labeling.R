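#' Spectral constants for Alexa dyes
#'
#' A280 correction factors and molar extinction coefficients used to
#' compute protein concentration and degree of labeling from absorbance
#' readings of a dye-conjugated protein. The dye absorbs at 280 nm too,
#' so `a280_correction` is the fraction of the dye-peak absorbance to
#' subtract from A280 before dividing by the protein's extinction
#' coefficient.
#'
#' @param dye_name one of `"Alexa488"`, `"Alexa568"`, `"Alexa647"`, or a
#'   custom name if the remaining arguments are supplied.
#' @param a280_correction unitless factor in (0, 1).
#' @param dye_extinction dye molar extinction coefficient (M^-1 cm^-1).
#' @param dye_peak_wavelength nm label of the dye absorbance peak.
#' @return a `DyeSpectralConstants` list.
#' @export
dye_spectral_constants <- function(dye_name,
                                   a280_correction = NULL,
                                   dye_extinction = NULL,
                                   dye_peak_wavelength = NULL) {
  known <- list(
    Alexa488 = list(a280_correction = 0.11, dye_extinction = 71000,
                    dye_peak_wavelength = 494),
    Alexa568 = list(a280_correction = 0.46, dye_extinction = 91300,
                    dye_peak_wavelength = 577),
    Alexa647 = list(a280_correction = 0.03, dye_extinction = 239000,
                    dye_peak_wavelength = 650))
  if (dye_name %in% names(known)) {
    k <- known[[dye_name]]
    if (is.null(a280_correction)) a280_correction <- k$a280_correction
    if (is.null(dye_extinction)) dye_extinction <- k$dye_extinction
    if (is.null(dye_peak_wavelength)) dye_peak_wavelength <- k$dye_peak_wavelength
  }
  if (is.null(a280_correction) || is.null(dye_extinction))
    stopf("unknown dye '%s': supply a280_correction and dye_extinction", dye_name)
  if (a280_correction <= 0 || a280_correction >= 1)
    stopf("a280_correction must lie in (0, 1)")
  if (dye_extinction <= 0) stopf("dye_extinction must be > 0")
  structure(list(dye_name = dye_name, a280_correction = a280_correction,
                 dye_extinction = dye_extinction,
                 dye_peak_wavelength = dye_peak_wavelength),
            class = "DyeSpectralConstants")
}

#' Protein concentration and degree of labeling from absorbances
#'
#' Standard two-wavelength arithmetic for a dye-conjugated protein:
#' concentration (M) is the dye-corrected A280 divided by the protein's
#' extinction coefficient, and the degree of labeling is the dye-peak
#' absorbance divided by the dye extinction times that concentration.
#'
#' @param a280 absorbance at 280 nm (>= 0).
#' @param a_dye absorbance at the dye peak (>= 0).
#' @param protein_ext_coef protein molar extinction coefficient (M^-1 cm^-1).
#' @param constants a [dye_spectral_constants()] object.
#' @return list with `concentration_M` and `degree_of_labeling`.
#' @export
labeling_metrics <- function(a280, a_dye, protein_ext_coef, constants) {
  stopifnot(inherits(constants, "DyeSpectralConstants"))
  if (a280 < 0 || a_dye < 0) stopf("absorbances must be >= 0")
  if (protein_ext_coef <= 0) stopf("protein_ext_coef must be > 0")
  conc <- (a280 - a_dye * constants$a280_correction) / protein_ext_coef
  if (conc <= 0)
    stopf("computed concentration <= 0: dye absorbance dominates A280")
  dol <- if (a_dye == 0) 0 else a_dye / (constants$dye_extinction * conc)
  list(concentration_M = conc, degree_of_labeling = dol)
}
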