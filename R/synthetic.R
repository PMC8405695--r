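#' @include AllClasses.R AllGenerics.R constants.R
NULL

#' Simulate a speckle B-scan pair with a known imposed axial strain
#'
#' Builds a fully-developed-speckle phantom of a curved corneal layer and a
#' deformed copy whose phase encodes a uniform axial strain, emulating
#' quasi-static elastography under ambient pressure modulation. The tissue
#' is a circular-arc shell of apex thickness \code{cct} and curvature radius
#' \code{radius}; per-pixel reflectivity inside the shell is complex
#' circular Gaussian (zero outside). The deformed scan is the reference
#' with a depth-cumulative phase
#' \eqn{\phi(z) = 4\pi n \epsilon (z - z_{ant}) \, asu / \lambda}
#' so that the true per-pixel axial strain inside the tissue equals
#' \code{imposedStrain} exactly. Additive complex white Gaussian noise is
#' applied to both scans at \code{snrDb} decibels relative to the unit
#' speckle power.
#'
#' The imposed strain must lie inside the phase-unambiguous range
#' \eqn{|\epsilon| < \lambda/(4 n \, asu)} (35.6 permil at the defaults);
#' larger strains alias in the depth-adjacent phase difference and are
#' rejected.
#'
#' @param cct corneal thickness, um (apex). The realized thickness is
#'   quantized to whole pixels and recorded as \code{trueCct} in the
#'   metadata.
#' @param imposedStrain uniform axial strain (dimensionless; negative =
#'   compression). Default -4.84e-3.
#' @param nAscans number of A-scans (lateral width), default 1000.
#' @param nDepth depth pixels; default sized to fit the shell plus margin.
#' @param asu axial sampling unit, um of physical depth in tissue per pixel.
#' @param wavelength centre wavelength, nm.
#' @param refractiveIndex corneal refractive index.
#' @param lateralPitch lateral A-scan spacing, um.
#' @param radius corneal radius of curvature, mm.
#' @param deltaP pressure modulation, mmHg (metadata; used by the modulus
#'   pipeline).
#' @param snrDb signal-to-noise ratio in dB; \code{Inf} (default) for a
#'   noiseless pair.
#' @param apexDepth depth index of the anterior surface at the apex,
#'   default 12.
#' @param seed integer seed; the generator is bit-reproducible given it.
#' @return an \linkS4class{OCEScanPair} whose metadata records the ground
#'   truth (\code{trueStrain}, \code{trueCct}) and all scan parameters.
#' @examples
#' pair <- simulateScanPair(cct = 148, imposedStrain = -4.84e-3,
#'                          nAscans = 101, seed = 7)
#' pair
#' @export
simulateScanPair <- function(cct = 148, imposedStrain = -4.84e-3,
                             nAscans = 1000L, nDepth = NULL,
                             asu = .DEFAULT_ASU,
                             wavelength = .DEFAULT_WAVELENGTH,
                             refractiveIndex = .DEFAULT_RI,
                             lateralPitch = .DEFAULT_LATERAL_PITCH,
                             radius = .DEFAULT_CORNEA_RADIUS,
                             deltaP = -3, snrDb = Inf,
                             apexDepth = 12L, seed = 1L) {
  stopifnot(cct > 0, nAscans >= 1, asu > 0, lateralPitch > 0, radius > 0,
            apexDepth >= 1)
  lim <- .strainLimit(wavelength, refractiveIndex, asu)
  if (abs(imposedStrain) >= lim)
    stop(sprintf(paste("imposed strain %.4g exceeds the phase-unambiguous",
                       "limit lambda/(4 n asu) = %.4g (%.1f permil)"),
                 imposedStrain, lim, 1000 * lim))

  nAscans <- as.integer(nAscans)
  tpx <- max(2L, as.integer(round(cct / asu)))
  rUm <- radius * 1000
  xUm <- (seq_len(nAscans) - (nAscans + 1) / 2) * lateralPitch
  ## shell exists only under the arc; clip near the limbus where the
  ## circular-arc model degenerates
  valid <- abs(xUm) < 0.95 * rUm
  sagPx <- rep(NA_integer_, nAscans)
  sagPx[valid] <- as.integer(round((rUm - sqrt(rUm^2 - xUm[valid]^2)) / asu))
  anterior <- apexDepth + sagPx
  posterior <- anterior + tpx - 1L
  if (is.null(nDepth))
    nDepth <- max(posterior, na.rm = TRUE) + 12L
  nDepth <- as.integer(nDepth)
  posterior[!is.na(posterior) & posterior > nDepth] <- NA_integer_
  anterior[is.na(posterior)] <- NA_integer_

  mask <- matrix(FALSE, nDepth, nAscans)
  for (j in which(!is.na(anterior)))
    mask[anterior[j]:posterior[j], j] <- TRUE

  set.seed(as.integer(seed))
  n <- nDepth * nAscans
  bRef <- matrix(complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                         imaginary = stats::rnorm(n, sd = sqrt(0.5))),
                 nDepth, nAscans)
  bRef[!mask] <- 0 + 0i

  ## depth-cumulative phase ramp inside the tissue
  lambdaUm <- wavelength * 1e-3
  phi <- matrix(0, nDepth, nAscans)
  zIdx <- matrix(seq_len(nDepth), nDepth, nAscans)
  antM <- matrix(anterior, nDepth, nAscans, byrow = TRUE)
  inside <- mask
  phi[inside] <- 4 * pi * refractiveIndex * imposedStrain *
    ((zIdx[inside] - antM[inside]) * asu) / lambdaUm
  bDef <- bRef * exp(1i * phi)

  if (is.finite(snrDb)) {
    nsd <- sqrt(10^(-snrDb / 10) / 2)
    bRef <- bRef + matrix(complex(real = stats::rnorm(n, sd = nsd),
                                  imaginary = stats::rnorm(n, sd = nsd)),
                          nDepth, nAscans)
    bDef <- bDef + matrix(complex(real = stats::rnorm(n, sd = nsd),
                                  imaginary = stats::rnorm(n, sd = nsd)),
                          nDepth, nAscans)
  }

  meta <- list(wavelength = wavelength, asu = asu,
               refractiveIndex = refractiveIndex,
               lateralPitch = lateralPitch, nAscans = nAscans,
               radius = radius, deltaP = deltaP, snrDb = snrDb,
               seed = as.integer(seed),
               trueStrain = imposedStrain, trueCct = tpx * asu,
               anterior = anterior, posterior = posterior)
  new("OCEScanPair", bRef = bRef, bDef = bDef, meta = meta)
}

#' Simulate a stress-relaxation force trace from a Prony model
#'
#' Forward-evaluates the relaxation modulus at constant applied strain
#' \code{eps0}: \eqn{\sigma(t) = \epsilon_0 E(t)} plus optional Gaussian
#' noise (standard deviation \code{noiseSdRel} times the initial stress),
#' then converts stress to force through the thin-shell aperture relation
#' \eqn{F = \sigma \cdot 2\pi R \, cct}. Indenter travel is held constant
#' at the value producing \code{eps0}.
#'
#' @param prony a \linkS4class{PronyModel} (moduli in Pa).
#' @param eps0 applied tensile strain held during relaxation; default 0.18
#'   (the strain at which a 0.4 N preload on a 148 um wild-type-like cornea
#'   meets the reference relaxation modulus).
#' @param sampleRate sampling rate, Hz.
#' @param duration trace duration, s (default 120).
#' @param noiseSdRel Gaussian noise SD as a fraction of the initial stress.
#' @param geometry \linkS4class{LoadingGeometry} (aperture radius mm, cct um).
#' @param seed integer seed (used only when \code{noiseSdRel > 0}).
#' @return a \linkS4class{ForceTrace}, all samples labelled
#'   \code{"relaxation"}.
#' @examples
#' tr <- simulateRelaxationTrace(mouseCorneaPronyConstants("wt"))
#' tr
#' @export
simulateRelaxationTrace <- function(prony, eps0 = 0.18, sampleRate = 10,
                                    duration = 120, noiseSdRel = 0,
                                    geometry = LoadingGeometry(148, 0.8),
                                    seed = 1L) {
  stopifnot(is(prony, "PronyModel"), eps0 > 0, sampleRate > 0, duration > 0,
            noiseSdRel >= 0)
  validObject(prony)
  t <- seq(0, duration, by = 1 / sampleRate)
  sigma <- eps0 * relaxationModulus(prony, t)
  if (noiseSdRel > 0) {
    set.seed(as.integer(seed))
    sigma <- sigma + stats::rnorm(length(t), sd = noiseSdRel * sigma[1])
  }
  area <- 2 * pi * (geometry@radius * 1e-3) * (geometry@cct * 1e-6)  # m^2
  force <- pmax(0, sigma * area)
  dl <- travelFromStrain(eps0, geometry@radius) * 1000  # um
  new("ForceTrace", t = t, force = force,
      travel = rep(dl, length(t)),
      segment = rep("relaxation", length(t)), geometry = geometry)
}

#' Simulate a rupture-test ramp trace with a known window modulus
#'
#' Builds a force/travel ramp whose stress-strain curve is linear with
#' slope \code{targetModulus}, anchored at the start force, by inverting
#' the aperture stress relation and the arc-chord strain relation. The
#' strain is ramped at constant rate from 0 to \code{epsMax} over the
#' nominal programme duration \code{(fEnd - fStart)/rate}, so analysing the
#' trace with [modulusFromRamp()] recovers \code{targetModulus} in the
#' 10-15 percent window (exactly, when noiseless). A premature rupture can
#' be injected at \code{ruptureStrain}: the force drops instantaneously to
#' 20 percent of its running maximum and the travel freezes.
#'
#' Note the full 0.4-4.0 N force program is not reproduced: a linear
#' stress-strain law at a tens-of-kPa slope cannot span MPa-scale aperture
#' stresses inside the invertible strain range of the arc-chord relation
#' (strain < pi/2 - 1). The ramp embodies the quantity the analysis
#' measures - the window slope - at the programmed start load and duration.
#'
#' @param targetModulus stress-strain slope to embody, Pa.
#' @param geometry \linkS4class{LoadingGeometry} (aperture radius mm, cct um).
#' @param fStart,fEnd force program end points, N (\code{fStart < fEnd}).
#' @param rate nominal force rate, N/s; with the defaults the ramp lasts
#'   12 s.
#' @param sampleRate sampling rate, Hz.
#' @param epsMax largest strain generated (must exceed 0.15 for the window
#'   analysis; capped below the arc-chord invertibility limit).
#' @param noiseSdRel Gaussian force noise SD as a fraction of the force
#'   span of the ramp (the increment carrying the stress-strain slope, not
#'   the preload: the aperture stress at the preload already dwarfs the
#'   kPa-scale slope signal, so preload-relative noise would bury it).
#' @param ruptureStrain strain at which to inject a premature rupture, or
#'   \code{NA} (default) for none.
#' @param seed integer seed (used only when \code{noiseSdRel > 0}).
#' @return a \linkS4class{ForceTrace}, all samples labelled \code{"ramp"}.
#' @examples
#' tr <- simulateRampTrace(30.7e3, LoadingGeometry(125, 0.8))
#' modulusFromRamp(stressStrainCurve(tr)) / 1000   # kPa
#' @export
simulateRampTrace <- function(targetModulus, geometry = LoadingGeometry(148, 0.8),
                              fStart = 0.4, fEnd = 4.0, rate = 0.3,
                              sampleRate = 50, epsMax = 0.5,
                              noiseSdRel = 0, ruptureStrain = NA_real_,
                              seed = 1L) {
  stopifnot(targetModulus > 0, fStart < fEnd, rate > 0, sampleRate > 0)
  if (geometry@cct <= 0) stop("geometry with non-positive cct")
  epsMax <- min(epsMax, (pi / 2 - 1) * 0.999)
  if (epsMax <= 0.15)
    warning("epsMax <= 0.15: ramp will not cover the 10-15% strain window")
  duration <- (fEnd - fStart) / rate
  t <- seq(0, duration, by = 1 / sampleRate)
  eps <- epsMax * t / duration
  area <- 2 * pi * (geometry@radius * 1e-3) * (geometry@cct * 1e-6)
  sigma0 <- fStart / area
  sigma <- sigma0 + targetModulus * eps
  force <- sigma * area
  travel <- travelFromStrain(eps, geometry@radius) * 1000  # um
  if (noiseSdRel > 0) {
    set.seed(as.integer(seed))
    span <- max(force) - min(force)
    force <- pmax(0, force + stats::rnorm(length(t), sd = noiseSdRel * span))
  }
  if (!is.na(ruptureStrain) && ruptureStrain < epsMax) {
    k <- which(eps >= ruptureStrain)[1]
    if (!is.na(k) && k < length(t)) {
      force[k:length(t)] <- 0.2 * max(force[1:(k - 1)])
      travel[k:length(t)] <- travel[k - 1]
    }
  }
  new("ForceTrace", t = t, force = force, travel = travel,
      segment = rep("ramp", length(t)), geometry = geometry)
}

#' Simulate a complete three-phase extensometry protocol
#'
#' Concatenates the three protocol phases into one labelled trace:
#' three pre-conditioning load cycles between 0.04 and 0.4 N, a 120 s
#' stress-relaxation plateau at constant travel under the 0.4 N preload
#' (force decays following \code{prony}), and a rupture ramp embodying
#' \code{targetModulus}. Used as ground truth for protocol segmentation.
#'
#' @inheritParams simulateRelaxationTrace
#' @inheritParams simulateRampTrace
#' @param cycleDuration duration of one pre-conditioning cycle, s.
#' @return a \linkS4class{ForceTrace} with generator segment labels.
#' @export
simulateProtocolTrace <- function(prony, targetModulus = 25e3,
                                  geometry = LoadingGeometry(148, 0.8),
                                  eps0 = 0.18, sampleRate = 10,
                                  duration = 120, cycleDuration = 4,
                                  noiseSdRel = 0, seed = 1L) {
  stopifnot(is(prony, "PronyModel"))
  area <- 2 * pi * (geometry@radius * 1e-3) * (geometry@cct * 1e-6)
  e0 <- relaxationModulus(prony, 0)

  ## (1) three triangular load cycles 0.04 -> 0.4 -> 0.04 N; travel follows
  ## the instantaneous modulus quasi-statically
  tPre <- seq(0, 3 * cycleDuration, by = 1 / sampleRate)
  phase <- (tPre %% cycleDuration) / cycleDuration
  fPre <- 0.04 + (0.4 - 0.04) * (1 - abs(2 * phase - 1))
  epsPre <- pmin((fPre / area) / e0, (pi / 2 - 1) * 0.999)
  travelPre <- travelFromStrain(epsPre, geometry@radius) * 1000

  ## (2) relaxation at constant travel
  rel <- simulateRelaxationTrace(prony, eps0 = eps0, sampleRate = sampleRate,
                                 duration = duration, noiseSdRel = noiseSdRel,
                                 geometry = geometry, seed = seed)

  ## (3) rupture ramp
  ramp <- simulateRampTrace(targetModulus, geometry = geometry,
                            sampleRate = sampleRate,
                            noiseSdRel = noiseSdRel, seed = seed + 1L)

  dt <- 1 / sampleRate
  t <- c(tPre, rel@t + max(tPre) + dt, ramp@t + max(tPre) + dt + max(rel@t) + dt)
  new("ForceTrace",
      t = t,
      force = c(fPre, rel@force, ramp@force),
      travel = c(travelPre, rel@travel, ramp@travel),
      segment = c(rep("precondition", length(tPre)),
                  rel@segment, ramp@segment),
      geometry = geometry)
}

#' Simulate a two-group per-eye cohort table
#'
#' Draws per-eye thickness, strain and moduli from group-wise normal
#' distributions. With the default parameters
#' ([mouseCorneaGroupParams()]) this emulates the wild-type vs Col5a1+/-
#' study cohort of 14 eyes per group.
#'
#' @param groups list of group specifications (see
#'   [mouseCorneaGroupParams()] for the format).
#' @param seed integer seed.
#' @return a data.frame with columns \code{eye_id}, \code{group},
#'   \code{cct_um}, \code{strain_permil}, \code{E_oct_kPa},
#'   \code{E_ext_kPa}.
#' @examples
#' head(simulateCohort(seed = 3))
#' @export
simulateCohort <- function(groups = mouseCorneaGroupParams(), seed = 1L) {
  stopifnot(length(groups) >= 1)
  set.seed(as.integer(seed))
  rows <- lapply(groups, function(g) {
    stopifnot(g$nEyes >= 2,
              g$cctMeanSd[2] >= 0, g$strainMeanSd[2] >= 0,
              g$eOctMeanSd[2] >= 0, g$eExtMeanSd[2] >= 0)
    n <- g$nEyes
    data.frame(
      eye_id = sprintf("%s_%02d", g$label, seq_len(n)),
      group = g$label,
      cct_um = stats::rnorm(n, g$cctMeanSd[1], g$cctMeanSd[2]),
      strain_permil = stats::rnorm(n, g$strainMeanSd[1], g$strainMeanSd[2]),
      E_oct_kPa = stats::rnorm(n, g$eOctMeanSd[1], g$eOctMeanSd[2]),
      E_ext_kPa = stats::rnorm(n, g$eExtMeanSd[1], g$eExtMeanSd[2]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
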