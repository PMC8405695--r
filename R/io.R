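#' @include AllClasses.R AllGenerics.R constants.R
NULL

#' Write / read a B-scan pair container
#'
#' The pair is stored as a 4-page 32-bit float TIFF (reference real,
#' reference imaginary, deformed real, deformed imaginary) with a JSON
#' sidecar holding the scan metadata. Float TIFF pages must lie in [0, 1],
#' so the planes are affinely normalized; the scale and offset are
#' recorded in the sidecar and undone on read.
#'
#' @param pair an \linkS4class{OCEScanPair}.
#' @param prefix file path prefix; writes \code{<prefix>.tif} and
#'   \code{<prefix>.json}.
#' @return \code{writeScanPair} returns the prefix invisibly;
#'   \code{readScanPair} returns the \linkS4class{OCEScanPair}.
#' @export
writeScanPair <- function(pair, prefix) {
  stopifnot(is(pair, "OCEScanPair"))
  planes <- list(Re(pair@bRef), Im(pair@bRef), Re(pair@bDef), Im(pair@bDef))
  s <- max(abs(unlist(lapply(planes, range))), .Machine$double.eps)
  norm <- lapply(planes, function(p) p / (2 * s) + 0.5)
  tiff::writeTIFF(norm, paste0(prefix, ".tif"), bits.per.sample = 32L)
  meta <- pair@meta
  meta$anterior <- NULL; meta$posterior <- NULL  # derived, not serialized
  if (!is.null(meta$snrDb) && !is.finite(meta$snrDb)) meta$snrDb <- NULL
  side <- list(scale = s, offset = 0.5, pages = c("refRe", "refIm", "defRe", "defIm"),
               meta = meta)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname writeScanPair
#' @export
readScanPair <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  s <- side$scale
  planes <- lapply(pages, function(p) (p - side$offset) * 2 * s)
  toC <- function(re, im) {
    z <- complex(real = re, imaginary = im)
    dim(z) <- dim(re)
    z
  }
  meta <- side$meta
  meta$snrDb <- if (is.null(meta$snrDb)) Inf else meta$snrDb
  new("OCEScanPair", bRef = toC(planes[[1]], planes[[2]]),
      bDef = toC(planes[[3]], planes[[4]]), meta = meta)
}

#' Write / read a force trace CSV
#'
#' CSV with header \code{t_s,force_N,travel_um,segment}. The loading
#' geometry is not part of the CSV; supply it on read.
#'
#' @param trace a \linkS4class{ForceTrace}.
#' @param path CSV file path.
#' @param geometry \linkS4class{LoadingGeometry} to attach on read.
#' @return \code{readForceTrace} returns a \linkS4class{ForceTrace}.
#' @export
writeForceTrace <- function(trace, path) {
  stopifnot(is(trace, "ForceTrace"))
  utils::write.csv(
    data.frame(t_s = trace@t, force_N = trace@force,
               travel_um = trace@travel, segment = trace@segment),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeForceTrace
#' @export
readForceTrace <- function(path, geometry) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "force_N", "travel_um")
  if (!all(need %in% names(d)))
    stop("force trace CSV must have columns t_s, force_N, travel_um")
  seg <- if ("segment" %in% names(d)) as.character(d$segment)
         else rep("", nrow(d))
  seg[is.na(seg)] <- ""
  new("ForceTrace", t = d$t_s, force = d$force_N, travel = d$travel_um,
      segment = seg, geometry = geometry)
}

#' Write / read a cohort table CSV
#'
#' CSV with header
#' \code{eye_id,group,cct_um,strain_permil,E_oct_kPa,E_ext_kPa} (extra
#' derived columns are preserved).
#'
#' @param table cohort data.frame.
#' @param path CSV file path.
#' @export
writeCohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
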