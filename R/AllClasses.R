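#' @import methods
NULL

#' Loading geometry of a corneal measurement
#'
#' Describes the geometry under which a cornea is loaded, shared by the
#' elastography (pressure modulation of the intact globe) and extensometry
#' (force applied over a clamped aperture) analyses.
#'
#' @slot cct central corneal thickness in micrometres.
#' @slot radius radius in millimetres: the corneal radius of curvature
#'   (default 1.5 mm) for thin-shell pressure-to-stress conversion, or the
#'   holder aperture radius (0.8 mm) for extensometry.
#' @slot deltaP pressure modulation in mmHg (elastography only; \code{NA}
#'   when the load is a force).
#'
#' @seealso [laplaceStress()], [stressFromForce()]
#' @export
setClass("LoadingGeometry",
  representation(cct = "numeric", radius = "numeric", deltaP = "numeric"),
  prototype(cct = NA_real_, radius = 1.5, deltaP = NA_real_)
)

setValidity("LoadingGeometry", function(object) {
  msg <- character()
  if (length(object@cct) != 1L || !is.finite(object@cct) || object@cct <= 0)
    msg <- c(msg, "'cct' must be a single positive thickness [um]")
  if (length(object@radius) != 1L || !is.finite(object@radius) || object@radius <= 0)
    msg <- c(msg, "'radius' must be a single positive length [mm]")
  if (length(object@deltaP) != 1L)
    msg <- c(msg, "'deltaP' must be a single pressure [mmHg] or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a LoadingGeometry
#'
#' @param cct central corneal thickness, micrometres.
#' @param radius radius in millimetres (corneal curvature 1.5 mm for
#'   elastography; aperture radius 0.8 mm for extensometry).
#' @param deltaP pressure modulation in mmHg, or \code{NA} for force loading.
#' @return a \linkS4class{LoadingGeometry}.
#' @examples
#' LoadingGeometry(cct = 148, radius = 1.5, deltaP = -3)
#' @export
LoadingGeometry <- function(cct, radius = 1.5, deltaP = NA_real_) {
  new("LoadingGeometry", cct = as.numeric(cct), radius = as.numeric(radius),
      deltaP = as.numeric(deltaP))
}

#' Paired reference/deformed complex OCT B-scans
#'
#' Holds the raw complex B-scan recorded at ambient pressure (reference) and
#' the B-scan recorded after the pressure modulation (deformed), together
#' with the scan metadata needed to convert phase differences into axial
#' strain. Matrices are indexed (depth z, lateral x).
#'
#' @slot bRef complex matrix, reference B-scan.
#' @slot bDef complex matrix, deformed B-scan (same shape).
#' @slot meta named list with at least \code{wavelength} (nm), \code{asu}
#'   (axial sampling unit, micrometres of physical depth in tissue per
#'   pixel), \code{refractiveIndex}, \code{lateralPitch} (um per A-scan) and
#'   \code{deltaP} (mmHg). Phantom pairs additionally record ground truth
#'   (\code{trueStrain}, \code{trueCct}) and the seed.
#'
#' @export
setClass("OCEScanPair",
  representation(bRef = "matrix", bDef = "matrix", meta = "list")
)

setValidity("OCEScanPair", function(object) {
  msg <- character()
  if (!is.complex(object@bRef) || !is.complex(object@bDef))
    msg <- c(msg, "B-scans must be complex matrices")
  if (!identical(dim(object@bRef), dim(object@bDef)))
    msg <- c(msg, "reference and deformed B-scans must have identical shape")
  need <- c("wavelength", "asu", "refractiveIndex", "lateralPitch")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste0("meta lacks: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Smoothed complex cross-correlation of a B-scan pair
#'
#' The pixelwise conjugate product of reference and deformed scans after
#' spatial boxcar smoothing; its phase carries the axial displacement.
#'
#' @slot rs complex matrix, smoothed correlation (same shape as the scans).
#' @slot rsRaw complex matrix, unsmoothed pixelwise conjugate product; kept
#'   so the strain estimator can vector-average the depth-adjacent product
#'   itself (averaging the already-smoothed field before the product biases
#'   the phase toward zero through the window's shared-pixel terms).
#' @slot window integer length-2 (axial px, lateral px) smoothing window.
#' @slot meta scan metadata carried through from the pair.
#' @export
setClass("CorrelationField",
  representation(rs = "matrix", rsRaw = "matrix", window = "integer",
                 meta = "list")
)

setValidity("CorrelationField", function(object) {
  msg <- character()
  if (!is.complex(object@rs)) msg <- c(msg, "'rs' must be complex")
  if (!identical(dim(object@rs), dim(object@rsRaw)))
    msg <- c(msg, "'rs' and 'rsRaw' must have identical shape")
  if (length(object@window) != 2L || any(object@window < 1L))
    msg <- c(msg, "'window' must be two positive pixel counts")
  if (length(msg)) msg else TRUE
})

#' Per-pixel axial strain map
#'
#' @slot eps numeric matrix of dimensionless axial strain (negative =
#'   compression).
#' @slot mask logical matrix; TRUE where the estimate is valid tissue
#'   (finite, not phase-saturated).
#' @slot roi free-form descriptor of the region used for averaging.
#' @slot meta scan metadata carried through.
#' @export
setClass("StrainMap",
  representation(eps = "matrix", mask = "matrix", roi = "list", meta = "list"),
  prototype(roi = list())
)

setValidity("StrainMap", function(object) {
  msg <- character()
  if (!identical(dim(object@eps), dim(object@mask)))
    msg <- c(msg, "'eps' and 'mask' must have identical shape")
  if (!is.logical(object@mask)) msg <- c(msg, "'mask' must be logical")
  if (any(!is.finite(object@eps[object@mask])))
    msg <- c(msg, "strain must be finite wherever mask is TRUE")
  if (length(msg)) msg else TRUE
})

#' Force/indenter-travel trace from 2D extensometry
#'
#' Time series of applied force and axial indenter travel, with a protocol
#' segment label per sample (\code{"precondition"}, \code{"relaxation"},
#' \code{"ramp"}, or \code{""} when not yet assigned) and the loading
#' geometry needed for stress/strain conversion.
#'
#' @slot t sampling times, seconds, strictly increasing.
#' @slot force applied force, newtons, non-negative.
#' @slot travel axial indenter travel, micrometres.
#' @slot segment character label per sample.
#' @slot geometry a \linkS4class{LoadingGeometry} (aperture radius in mm,
#'   cct in um).
#' @export
setClass("ForceTrace",
  representation(t = "numeric", force = "numeric", travel = "numeric",
                 segment = "character", geometry = "LoadingGeometry")
)

setValidity("ForceTrace", function(object) {
  msg <- character()
  n <- length(object@t)
  if (n < 1L) msg <- c(msg, "trace must be non-empty")
  if (length(object@force) != n || length(object@travel) != n ||
      length(object@segment) != n)
    msg <- c(msg, "t, force, travel, segment must have equal length")
  if (n > 1L && any(diff(object@t) <= 0))
    msg <- c(msg, "'t' must be strictly increasing")
  if (any(object@force < 0, na.rm = TRUE))
    msg <- c(msg, "'force' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Prony-series relaxation modulus
#'
#' The generalised-Maxwell relaxation modulus
#' \deqn{E(t) = E_\infty + \sum_{i=1}^{N} E_i e^{-t/\tau_i},}
#' with long-term modulus \eqn{E_\infty} and \eqn{N} decaying terms. Terms
#' are kept sorted by ascending time constant; all moduli are stored in Pa.
#'
#' @slot eInf long-term modulus, Pa, positive.
#' @slot e short-term moduli \eqn{E_i}, Pa, non-negative.
#' @slot tau relaxation time constants \eqn{\tau_i}, s, positive, ascending.
#' @seealso [fitProny()], [relaxationModulus()]
#' @export
setClass("PronyModel",
  representation(eInf = "numeric", e = "numeric", tau = "numeric")
)

setValidity("PronyModel", function(object) {
  msg <- character()
  if (length(object@eInf) != 1L || !is.finite(object@eInf) || object@eInf <= 0)
    msg <- c(msg, "'eInf' must be a single positive modulus [Pa]")
  if (length(object@e) != length(object@tau))
    msg <- c(msg, "'e' and 'tau' must have equal length")
  if (any(object@e < 0)) msg <- c(msg, "all 'e' must be >= 0")
  if (any(object@tau <= 0)) msg <- c(msg, "all 'tau' must be > 0")
  if (is.unsorted(object@tau)) msg <- c(msg, "terms must be sorted by ascending tau")
  if (length(msg)) msg else TRUE
})

#' Construct a PronyModel
#'
#' Terms are sorted by ascending time constant.
#'
#' @param eInf long-term modulus, Pa.
#' @param e vector of short-term moduli, Pa.
#' @param tau vector of time constants, s (same length as \code{e}).
#' @return a \linkS4class{PronyModel}.
#' @examples
#' PronyModel(1.18e6, e = c(0.43, 0.51, 0.88) * 1e6, tau = c(3.1, 51, 124))
#' @export
PronyModel <- function(eInf, e = numeric(0), tau = numeric(0)) {
  o <- order(tau)
  new("PronyModel", eInf = as.numeric(eInf), e = as.numeric(e)[o],
      tau = as.numeric(tau)[o])
}

#' Result of a stress-relaxation analysis
#'
#' @slot reductionPct percent stress reduction over the relaxation horizon
#'   (default 100 s), relative to the initial post-load stress.
#' @slot prony fitted \linkS4class{PronyModel}.
#' @slot fitRSS residual sum of squares of the fit, Pa^2.
#' @export
setClass("RelaxationResult",
  representation(reductionPct = "numeric", prony = "PronyModel",
                 fitRSS = "numeric")
)

setValidity("RelaxationResult", function(object) {
  if (length(object@reductionPct) != 1L || is.na(object@reductionPct) ||
      object@reductionPct < 0 || object@reductionPct > 100)
    "reductionPct must lie in [0, 100]" else TRUE
})

#' Elastic modulus estimate from elastography
#'
#' @slot deltaSigma stress change induced by the pressure modulation, Pa.
#' @slot meanStrain mean central axial strain, dimensionless (signed;
#'   negative = compression).
#' @slot eModulus elastic modulus, Pa: the ratio of the stress and strain
#'   magnitudes, so a compressive strain under a pressure decrease yields a
#'   positive modulus.
#' @export
setClass("ModulusResult",
  representation(deltaSigma = "numeric", meanStrain = "numeric",
                 eModulus = "numeric")
)

setValidity("ModulusResult", function(object) {
  if (!isTRUE(all.equal(object@eModulus,
                        abs(object@deltaSigma) / abs(object@meanStrain))))
    "eModulus must equal |deltaSigma| / |meanStrain|" else TRUE
})
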