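#' @include AllClasses.R AllGenerics.R constants.R
NULL

## centered moving sum along dim 1 with half-window h, partial at edges
.movsum1 <- function(A, h) {
  n <- nrow(A)
  if (h == 0L) return(A)
  cs <- rbind(0, apply(A, 2, cumsum))
  hi <- pmin(n, seq_len(n) + h)
  lo <- pmax(0L, seq_len(n) - h - 1L)
  cs[hi + 1L, , drop = FALSE] - cs[lo + 1L, , drop = FALSE]
}

## 2-D boxcar moving average, odd window c(axial, lateral); edge pixels are
## averaged over the in-image part of the window
.boxcar2d <- function(A, window) {
  hz <- (window[1] - 1L) %/% 2L
  hx <- (window[2] - 1L) %/% 2L
  S <- t(.movsum1(t(.movsum1(A, hz)), hx))
  cz <- pmin(nrow(A), seq_len(nrow(A)) + hz) - pmax(0L, seq_len(nrow(A)) - hz - 1L)
  cx <- pmin(ncol(A), seq_len(ncol(A)) + hx) - pmax(0L, seq_len(ncol(A)) - hx - 1L)
  S / outer(cz, cx)
}

#' Complex cross-correlation of a B-scan pair
#'
#' Computes the pixelwise conjugate product
#' \eqn{R(z,x) = B_{ref}(z,x) \cdot B_{def}^*(z,x)} of the reference and
#' deformed complex B-scans and smooths it with a spatial boxcar,
#' giving the smoothed correlation field whose phase carries the axial
#' displacement between the scans.
#'
#' @param pair an \linkS4class{OCEScanPair}.
#' @param window odd integer pair (axial px, lateral px). The default
#'   \code{c(5, 9)} reproduces an effective strain-imaging resolution of
#'   about 22 um axially (asu 4.48 um) by 112 um laterally (pitch 12.5 um).
#' @return a \linkS4class{CorrelationField}.
#' @examples
#' pair <- simulateScanPair(nAscans = 64, seed = 1)
#' cf <- complexCrossCorrelation(pair)
#' @export
complexCrossCorrelation <- function(pair, window = c(5L, 9L)) {
  stopifnot(is(pair, "OCEScanPair"))
  validObject(pair)
  window <- as.integer(window)
  if (length(window) != 2L || any(window < 1L) || any(window %% 2L == 0L))
    stop("'window' must be two odd positive pixel counts (axial, lateral)")
  raw <- scanRef(pair) * Conj(scanDef(pair))
  rs <- complex(real = .boxcar2d(Re(raw), window),
                imaginary = .boxcar2d(Im(raw), window))
  dim(rs) <- dim(raw)
  new("CorrelationField", rs = rs, rsRaw = raw, window = window,
      meta = scanMeta(pair))
}

#' Axial strain from the depth-adjacent phase of a correlation field
#'
#' Converts the smoothed correlation field into per-pixel axial strain via
#' the angle of the depth-adjacent conjugate product:
#' \deqn{\Delta\epsilon(z,x) = \frac{\lambda \cdot
#'   \angle\left(R_s(z,x) R_s^*(z+1,x)\right)}{4\pi \, n \, asu}.}
#' No explicit phase unwrapping is performed; the angle is taken in
#' \eqn{(-\pi, \pi]}, which is wrap-free for strains below
#' \eqn{\lambda/(4 n \, asu)}. Pixels whose phase step saturates at
#' \eqn{\pm\pi} are flagged invalid in the mask. The last depth row
#' replicates its neighbour (the difference needs z+1).
#'
#' The spatial averaging (the correlation window) is applied to the
#' depth-adjacent product itself, as complex phasors before the angle is
#' taken: for a uniform strain every product pixel then carries exactly
#' the same phase, so the noiseless estimate is exact for any window,
#' while the vector averaging suppresses phase noise. (Taking the product
#' of the already-smoothed field instead leaves the window's shared-pixel
#' terms in the product, which systematically biases the phase toward
#' zero at permil-scale strains.)
#'
#' @param corr a \linkS4class{CorrelationField}.
#' @param tissueMask optional logical matrix restricting the validity mask
#'   to tissue (e.g. from [segmentCornea()] boundaries); by default the
#'   mask only flags finite, non-saturated pixels.
#' @return a \linkS4class{StrainMap}.
#' @export
axialStrain <- function(corr, tissueMask = NULL) {
  stopifnot(is(corr, "CorrelationField"))
  m <- corr@meta
  rs <- corr@rsRaw
  nz <- nrow(rs)
  if (nz < 2L) stop("need at least two depth pixels")
  prod <- rs[-nz, , drop = FALSE] * Conj(rs[-1L, , drop = FALSE])
  if (any(corr@window > 1L)) {
    sm <- complex(real = .boxcar2d(Re(prod), corr@window),
                  imaginary = .boxcar2d(Im(prod), corr@window))
    dim(sm) <- dim(prod)
    prod <- sm
  }
  ang <- Arg(prod)
  lambdaUm <- m$wavelength * 1e-3
  scale <- lambdaUm / (4 * pi * m$refractiveIndex * m$asu)
  eps <- scale * ang
  eps <- rbind(eps, eps[nz - 1L, , drop = FALSE])
  ok <- is.finite(eps) &
    rbind(abs(ang) < pi * (1 - 1e-9), rep(TRUE, ncol(rs)))
  if (!is.null(tissueMask)) {
    stopifnot(identical(dim(tissueMask), dim(eps)))
    ok <- ok & tissueMask
  }
  eps[!is.finite(eps)] <- 0
  new("StrainMap", eps = eps, mask = ok, roi = list(), meta = m)
}

#' Segment the cornea and extract central thickness
#'
#' Detects the anterior and posterior corneal interfaces per A-scan by
#' thresholding the log-intensity midway between the background and tissue
#' levels, median-filters the boundaries laterally, and averages the
#' geometric thickness over the central zone (0.5 mm diameter around the
#' lateral centre of the detected tissue). The axial sampling unit is the
#' physical depth per pixel in tissue, so thickness is the boundary pixel
#' count times \code{asu}.
#'
#' @param intensity non-negative matrix (depth x lateral), e.g.
#'   \code{Mod(scanRef(pair))^2}.
#' @param meta scan metadata list (needs \code{asu}, \code{lateralPitch}).
#' @param centralZone diameter of the central averaging zone, mm.
#' @return list with per-column \code{anterior} and \code{posterior} depth
#'   indices (NA where no tissue) and the central \code{cct} in um.
#' @examples
#' pair <- simulateScanPair(cct = 148, nAscans = 101, seed = 2)
#' segmentCornea(Mod(scanRef(pair))^2, scanMeta(pair))$cct
#' @export
segmentCornea <- function(intensity, meta, centralZone = 0.5) {
  stopifnot(is.matrix(intensity), all(intensity >= 0, na.rm = TRUE))
  nz <- nrow(intensity); nx <- ncol(intensity)
  li <- log10(intensity + max(intensity) * 1e-9 + .Machine$double.xmin)
  lo <- stats::quantile(li, 0.05, names = FALSE)
  hi <- stats::quantile(li, 0.995, names = FALSE)
  if (hi - lo < 0.5)
    stop("no detectable interfaces: image intensity is featureless")
  thr <- (lo + hi) / 2
  anterior <- posterior <- rep(NA_integer_, nx)
  for (j in seq_len(nx)) {
    above <- which(li[, j] > thr)
    if (length(above) >= 3L) {
      anterior[j] <- above[1]
      posterior[j] <- above[length(above)]
    }
  }
  okCols <- which(!is.na(anterior))
  if (length(okCols) < 3L)
    stop("no detectable interfaces: fewer than two interfaces found")
  ## median filter across x on the detected region to reject speckle dropouts
  k <- min(9L, length(okCols) - (1 - length(okCols) %% 2))
  if (k >= 3L) {
    anterior[okCols] <- as.integer(stats::runmed(anterior[okCols], k))
    posterior[okCols] <- as.integer(stats::runmed(posterior[okCols], k))
  }
  xc <- mean(okCols)
  halfPx <- (centralZone * 1000 / 2) / meta$lateralPitch
  central <- okCols[abs(okCols - xc) <= halfPx]
  if (length(central) < 3L)
    stop("central zone contains too few segmented A-scans")
  cct <- stats::median(posterior[central] - anterior[central] + 1L) * meta$asu
  list(anterior = anterior, posterior = posterior, cct = cct)
}

## logical tissue mask from per-column boundaries, optionally eroded
## axially by 'erode' pixels on each side
.boundaryMask <- function(anterior, posterior, nz, erode = 0L) {
  nx <- length(anterior)
  mask <- matrix(FALSE, nz, nx)
  for (j in seq_len(nx)) {
    if (is.na(anterior[j])) next
    a <- anterior[j] + erode
    p <- posterior[j] - erode
    if (a <= p) mask[a:p, j] <- TRUE
  }
  mask
}

#' Mean axial strain in the central region of interest
#'
#' Averages the masked strain over either the physical central zone (a
#' 0.5 mm diameter lateral band through the whole thickness, the default)
#' or a fixed 21 x 21 pixel box centred on the masked tissue.
#'
#' @param sm a \linkS4class{StrainMap} whose mask marks valid tissue.
#' @param mode \code{"physical"} (0.5 mm zone, whole thickness) or
#'   \code{"pixels"} (21 x 21 px central box).
#' @param diameter zone diameter for \code{"physical"}, mm.
#' @param px box side for \code{"pixels"}.
#' @return the mean strain (dimensionless), with attributes \code{mode}
#'   and \code{nPixels} recording the ROI actually used.
#' @export
meanCentralStrain <- function(sm, mode = c("physical", "pixels"),
                              diameter = 0.5, px = 21L) {
  stopifnot(is(sm, "StrainMap"))
  mode <- match.arg(mode)
  mask <- strainMask(sm)
  if (!any(mask)) stop("empty ROI: strain map has no valid pixels")
  nz <- nrow(mask); nx <- ncol(mask)
  colAny <- colSums(mask) > 0
  xc <- sum(seq_len(nx) * colSums(mask)) / sum(mask)
  zc <- sum(seq_len(nz) * rowSums(mask)) / sum(mask)
  roi <- matrix(FALSE, nz, nx)
  if (mode == "physical") {
    halfPx <- (diameter * 1000 / 2) / sm@meta$lateralPitch
    cols <- which(abs(seq_len(nx) - xc) <= halfPx)
    roi[, cols] <- TRUE
  } else {
    h <- (as.integer(px) - 1L) %/% 2L
    if (h < 0L) stop("'px' must be a positive box side")
    rows <- max(1L, round(zc) - h):min(nz, round(zc) + h)
    cols <- max(1L, round(xc) - h):min(nx, round(xc) + h)
    roi[rows, cols] <- TRUE
  }
  sel <- mask & roi
  if (!any(sel)) stop("empty ROI: no valid pixels inside the selected zone")
  out <- mean(strainValues(sm)[sel])
  attr(out, "mode") <- mode
  attr(out, "nPixels") <- sum(sel)
  out
}

#' Thin-shell (Laplace) membrane stress from a pressure modulation
#'
#' \deqn{\Delta\sigma = \frac{\Delta p \cdot R}{2 \, cct}}
#' with the pressure converted at 133.322 Pa/mmHg.
#'
#' @param g a \linkS4class{LoadingGeometry} with \code{deltaP} set (mmHg),
#'   \code{radius} in mm and \code{cct} in um.
#' @return stress change in Pa (signed like \code{deltaP}).
#' @examples
#' laplaceStress(LoadingGeometry(cct = 148, radius = 1.5, deltaP = 3))
#' @export
laplaceStress <- function(g) {
  stopifnot(is(g, "LoadingGeometry"))
  validObject(g)
  if (!is.finite(g@deltaP)) stop("geometry has no pressure modulation")
  mmHgToPa(g@deltaP) * (g@radius * 1e-3) / (2 * g@cct * 1e-6)
}

#' Elastic modulus from stress change and mean strain
#'
#' \eqn{E = |\Delta\sigma| / |\bar\epsilon|}: the ratio of magnitudes, so a
#' compressive (negative) strain under a pressure decrease yields a
#' positive modulus.
#'
#' @param deltaSigma stress change, Pa.
#' @param meanStrain mean axial strain (signed, dimensionless).
#' @return a \linkS4class{ModulusResult}.
#' @export
estimateModulus <- function(deltaSigma, meanStrain) {
  if (!is.finite(meanStrain) || meanStrain == 0)
    stop("mean strain is zero: modulus undefined")
  new("ModulusResult", deltaSigma = as.numeric(deltaSigma),
      meanStrain = as.numeric(meanStrain),
      eModulus = abs(deltaSigma) / abs(meanStrain))
}

#' End-to-end elastography analysis of a B-scan pair
#'
#' Runs the full pipeline: smoothed complex cross-correlation,
#' depth-adjacent phase differencing to axial strain, corneal segmentation
#' for central thickness, thin-shell stress conversion and the modulus
#' estimate. The tissue mask from segmentation is eroded axially by the
#' correlation half-window so boundary pixels (whose smoothing window mixes
#' tissue and background phase) do not bias the mean strain.
#'
#' @param pair an \linkS4class{OCEScanPair} (metadata must carry
#'   \code{deltaP} and \code{radius}).
#' @param window correlation smoothing window, odd (axial, lateral) px.
#' @param roiMode \code{"physical"} or \code{"pixels"} ROI for the mean
#'   strain (see [meanCentralStrain()]).
#' @return list with \code{cct_um}, \code{mean_strain_permil},
#'   \code{delta_sigma_Pa}, \code{E_kPa}, \code{roi_mode}, and the
#'   underlying \code{strainMap} and \code{result}
#'   (\linkS4class{ModulusResult}).
#' @examples
#' pair <- simulateScanPair(cct = 148, imposedStrain = -4.93e-3,
#'                          nAscans = 101, snrDb = 30, seed = 5)
#' out <- analyzeScanPair(pair)
#' out$E_kPa
#' @export
analyzeScanPair <- function(pair, window = c(5L, 9L),
                            roiMode = c("physical", "pixels")) {
  roiMode <- match.arg(roiMode)
  meta <- scanMeta(pair)
  cf <- complexCrossCorrelation(pair, window = window)
  seg <- segmentCornea(Mod(scanRef(pair))^2, meta)
  erode <- (as.integer(window[1]) - 1L) %/% 2L + 1L
  tissue <- .boundaryMask(seg$anterior, seg$posterior, nrow(scanRef(pair)),
                          erode = erode)
  sm <- axialStrain(cf, tissueMask = tissue)
  eps <- meanCentralStrain(sm, mode = roiMode)
  g <- LoadingGeometry(cct = seg$cct,
                       radius = if (!is.null(meta$radius)) meta$radius
                                else .DEFAULT_CORNEA_RADIUS,
                       deltaP = meta$deltaP)
  ds <- laplaceStress(g)
  res <- estimateModulus(ds, as.numeric(eps))
  list(cct_um = seg$cct,
       mean_strain_permil = 1000 * as.numeric(eps),
       delta_sigma_Pa = ds,
       E_kPa = eModulus(res) / 1000,
       roi_mode = roiMode,
       strainMap = sm,
       result = res)
}
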