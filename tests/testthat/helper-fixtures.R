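# Shared fixture builders; everything is generated in code at test time.

# scan pair with an arbitrary imposed phase field on a uniform-amplitude
# reference (no speckle): isolates the phase machinery from the speckle
# statistics
pairFromPhase <- function(phi, wavelength = 878, asu = 4.48, n = 1.375,
                          lateralPitch = 12.5, deltaP = -3) {
  bRef <- matrix(complex(real = 1, imaginary = 0), nrow(phi), ncol(phi))
  new("OCEScanPair", bRef = bRef, bDef = bRef * exp(1i * phi),
      meta = list(wavelength = wavelength, asu = asu, refractiveIndex = n,
                  lateralPitch = lateralPitch, nAscans = ncol(phi),
                  deltaP = deltaP))
}

# strip generator segment labels so protocol splitting has to work
unlabel <- function(trace) {
  new("ForceTrace", t = traceTime(trace), force = traceForce(trace),
      travel = traceTravel(trace),
      segment = rep("", length(traceTime(trace))),
      geometry = traceGeometry(trace))
}

# brute-force 1-D phase unwrap: wrap successive differences into (-pi, pi]
# and re-accumulate
unwrapPhase <- function(p) {
  d <- diff(p)
  d <- ((d + pi) %% (2 * pi)) - pi
  cumsum(c(p[1], d))
}

# noiseless relaxation stress samples for a Prony model (independent of
# the ForceTrace machinery)
pronyStress <- function(eInfMPa, eMPa, tauS, t, eps0) {
  eps0 * 1e6 * (eInfMPa + colSums(eMPa * exp(-outer(tauS, t, function(a, b) b / a))))
}
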