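#' @include AllClasses.R
NULL

## Physical constants and instrument defaults. These are the values the
## synthetic module emulates and the analysis defaults to; all of them can
## be overridden per call or through the run configuration.
.MMHG_PA <- 133.322           # Pa per mmHg
.DEFAULT_WAVELENGTH <- 878    # nm, spectral-domain OCT centre wavelength
.DEFAULT_ASU <- 4.48          # um physical depth in tissue per axial pixel
.DEFAULT_RI <- 1.375          # corneal refractive index
.DEFAULT_LATERAL_PITCH <- 12.5  # um per A-scan
.DEFAULT_CORNEA_RADIUS <- 1.5 # mm, corneal radius of curvature
.DEFAULT_APERTURE_RADIUS <- 0.8 # mm, extensometry holder opening radius

#' Reference Prony constants for the murine cornea study groups
#'
#' 3-term Prony-series constants reported for wild-type (\code{"wt"}) and
#' collagen-V-haploinsufficient (\code{"col5a1"}, an Ehlers-Danlos model)
#' mouse corneas under stress relaxation at constant strain. These are the
#' ground-truth models the synthetic relaxation traces emulate.
#'
#' @param group \code{"wt"} or \code{"col5a1"}.
#' @return a \linkS4class{PronyModel} (moduli in Pa).
#' @examples
#' m <- mouseCorneaPronyConstants("wt")
#' relaxationModulus(m, c(0, 100)) / 1e6   # MPa at t = 0 and 100 s
#' @export
mouseCorneaPronyConstants <- function(group = c("wt", "col5a1")) {
  group <- match.arg(group)
  if (group == "wt")
    PronyModel(1.18e6, e = c(0.43, 0.51, 0.88) * 1e6, tau = c(3.1, 51, 124))
  else
    PronyModel(1.14e6, e = c(0.50, 0.62, 1.29) * 1e6, tau = c(3.1, 56, 57))
}

#' Reference cohort parameters for the murine cornea study groups
#'
#' Group-level means and standard deviations of the per-eye quantities
#' (central corneal thickness, OCE axial strain, OCE and extensometry
#' moduli) for wild-type and Col5a1+/- mice, 14 eyes per group. Used as the
#' default generating parameters when emulating the two-group cohort.
#'
#' @return named list of group specifications, each a list with fields
#'   \code{label}, \code{nEyes}, \code{cctMeanSd} (um), \code{strainMeanSd}
#'   (permil, negative = compression), \code{eOctMeanSd} (kPa),
#'   \code{eExtMeanSd} (kPa).
#' @export
mouseCorneaGroupParams <- function() {
  list(
    wt = list(label = "wt", nEyes = 14L,
              cctMeanSd = c(148, 10), strainMeanSd = c(-4.93, 1.92),
              eOctMeanSd = c(430, 103), eExtMeanSd = c(21.5, 5.7)),
    col5a1 = list(label = "col5a1", nEyes = 14L,
                  cctMeanSd = c(125, 11), strainMeanSd = c(-4.84, 1.99),
                  eOctMeanSd = c(506, 88), eExtMeanSd = c(30.7, 12.1))
  )
}

#' Convert a pressure in mmHg to Pa
#'
#' @param p pressure, mmHg.
#' @return pressure in Pa (133.322 Pa/mmHg).
#' @export
mmHgToPa <- function(p) p * .MMHG_PA

## Phase-unambiguous axial strain limit |eps| < lambda / (4 n asu):
## one pixel of depth separation maps strain to a phase step of
## 4 pi n eps asu / lambda, which must stay inside (-pi, pi].
.strainLimit <- function(wavelength_nm, refractiveIndex, asu_um) {
  (wavelength_nm * 1e-3) / (4 * refractiveIndex * asu_um)
}
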