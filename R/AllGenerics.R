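#' @include AllClasses.R
NULL

#' Accessors for scan pairs, strain maps, traces and models
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{scanRef}/\code{scanDef}/\code{scanMeta} for
#' \linkS4class{OCEScanPair}; \code{strainValues}/\code{strainMask} for
#' \linkS4class{StrainMap}; \code{traceTime}/\code{traceForce}/
#' \code{traceTravel}/\code{traceSegment}/\code{traceGeometry} for
#' \linkS4class{ForceTrace}; \code{eInf}/\code{pronyE}/\code{pronyTau} for
#' \linkS4class{PronyModel}; \code{reductionPct}/\code{pronyFit} for
#' \linkS4class{RelaxationResult}; \code{eModulus} for
#' \linkS4class{ModulusResult}.
#'
#' @param object the object to access.
#' @return the slot contents (vector, matrix or list as documented on the
#'   class).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scanRef", function(object) standardGeneric("scanRef"))
#' @rdname accessors
#' @export
setGeneric("scanDef", function(object) standardGeneric("scanDef"))
#' @rdname accessors
#' @export
setGeneric("scanMeta", function(object) standardGeneric("scanMeta"))
#' @rdname accessors
#' @export
setGeneric("strainValues", function(object) standardGeneric("strainValues"))
#' @rdname accessors
#' @export
setGeneric("strainMask", function(object) standardGeneric("strainMask"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("traceForce", function(object) standardGeneric("traceForce"))
#' @rdname accessors
#' @export
setGeneric("traceTravel", function(object) standardGeneric("traceTravel"))
#' @rdname accessors
#' @export
setGeneric("traceSegment", function(object) standardGeneric("traceSegment"))
#' @rdname accessors
#' @export
setGeneric("traceGeometry", function(object) standardGeneric("traceGeometry"))
#' @rdname accessors
#' @export
setGeneric("eInf", function(object) standardGeneric("eInf"))
#' @rdname accessors
#' @export
setGeneric("pronyE", function(object) standardGeneric("pronyE"))
#' @rdname accessors
#' @export
setGeneric("pronyTau", function(object) standardGeneric("pronyTau"))
#' @rdname accessors
#' @export
setGeneric("reductionPct", function(object) standardGeneric("reductionPct"))
#' @rdname accessors
#' @export
setGeneric("pronyFit", function(object) standardGeneric("pronyFit"))
#' @rdname accessors
#' @export
setGeneric("eModulus", function(object) standardGeneric("eModulus"))

#' Evaluate a relaxation modulus over time
#'
#' @param object a \linkS4class{PronyModel}.
#' @param t times in seconds.
#' @return modulus E(t) in Pa, same length as \code{t}.
#' @export
setGeneric("relaxationModulus",
           function(object, t) standardGeneric("relaxationModulus"))

#' @rdname accessors
setMethod("scanRef", "OCEScanPair", function(object) object@bRef)
#' @rdname accessors
setMethod("scanDef", "OCEScanPair", function(object) object@bDef)
#' @rdname accessors
setMethod("scanMeta", "OCEScanPair", function(object) object@meta)
#' @rdname accessors
setMethod("strainValues", "StrainMap", function(object) object@eps)
#' @rdname accessors
setMethod("strainMask", "StrainMap", function(object) object@mask)
#' @rdname accessors
setMethod("traceTime", "ForceTrace", function(object) object@t)
#' @rdname accessors
setMethod("traceForce", "ForceTrace", function(object) object@force)
#' @rdname accessors
setMethod("traceTravel", "ForceTrace", function(object) object@travel)
#' @rdname accessors
setMethod("traceSegment", "ForceTrace", function(object) object@segment)
#' @rdname accessors
setMethod("traceGeometry", "ForceTrace", function(object) object@geometry)
#' @rdname accessors
setMethod("eInf", "PronyModel", function(object) object@eInf)
#' @rdname accessors
setMethod("pronyE", "PronyModel", function(object) object@e)
#' @rdname accessors
setMethod("pronyTau", "PronyModel", function(object) object@tau)
#' @rdname accessors
setMethod("reductionPct", "RelaxationResult", function(object) object@reductionPct)
#' @rdname accessors
setMethod("pronyFit", "RelaxationResult", function(object) object@prony)
#' @rdname accessors
setMethod("eModulus", "ModulusResult", function(object) object@eModulus)

#' @describeIn PronyModel-class evaluate E(t) = eInf + sum(e_i exp(-t/tau_i)).
#' @param t times, s.
setMethod("relaxationModulus", "PronyModel", function(object, t) {
  if (length(object@e) == 0L) return(rep(object@eInf, length(t)))
  object@eInf + as.vector(exp(-outer(t, object@tau, "/")) %*% object@e)
})

setMethod("show", "OCEScanPair", function(object) {
  d <- dim(object@bRef)
  m <- object@meta
  cat("OCEScanPair:", d[1], "depth px x", d[2], "A-scans\n")
  cat(sprintf("  lambda %.0f nm | asu %.2f um | n %.3f | lateral pitch %.1f um\n",
              m$wavelength, m$asu, m$refractiveIndex, m$lateralPitch))
  if (!is.null(m$deltaP)) cat(sprintf("  pressure modulation %.1f mmHg\n", m$deltaP))
  if (!is.null(m$trueStrain))
    cat(sprintf("  phantom ground truth: strain %.3f permil, cct %.1f um\n",
                1000 * m$trueStrain, m$trueCct))
})

setMethod("show", "StrainMap", function(object) {
  d <- dim(object@eps)
  cat("StrainMap:", d[1], "x", d[2], "px;", sum(object@mask), "valid px\n")
  if (sum(object@mask))
    cat(sprintf("  masked strain: mean %.3f permil, sd %.3f permil\n",
                1000 * mean(object@eps[object@mask]),
                1000 * stats::sd(object@eps[object@mask])))
})

setMethod("show", "ForceTrace", function(object) {
  cat(sprintf("ForceTrace: %d samples over %.1f s; force %.3f-%.3f N\n",
              length(object@t), diff(range(object@t)),
              min(object@force), max(object@force)))
  tab <- table(object@segment)
  cat("  segments:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "PronyModel", function(object) {
  cat(sprintf("PronyModel: E_inf = %.3g MPa, %d terms\n",
              object@eInf / 1e6, length(object@e)))
  if (length(object@e))
    for (i in seq_along(object@e))
      cat(sprintf("  E_%d = %.3g MPa, tau_%d = %.3g s\n",
                  i, object@e[i] / 1e6, i, object@tau[i]))
})

setMethod("show", "RelaxationResult", function(object) {
  cat(sprintf("RelaxationResult: %.1f%% stress reduction; fit RSS %.3g Pa^2\n",
              object@reductionPct, object@fitRSS))
  show(object@prony)
})

setMethod("show", "ModulusResult", function(object) {
  cat(sprintf("ModulusResult: dSigma %.1f Pa / strain %.3f permil -> E = %.1f kPa\n",
              object@deltaSigma, 1000 * object@meanStrain, object@eModulus / 1000))
})

setMethod("show", "LoadingGeometry", function(object) {
  cat(sprintf("LoadingGeometry: cct %.1f um, radius %.2f mm", object@cct, object@radius))
  if (is.finite(object@deltaP)) cat(sprintf(", deltaP %.1f mmHg", object@deltaP))
  cat("\n")
})
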