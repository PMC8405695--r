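#' @include AllClasses.R AllGenerics.R constants.R synthetic.R oce.R extensometry.R cohort.R io.R
NULL

#' Default configuration for a study emulation run
#'
#' All physical constants and generator/analysis settings of
#' [runStudyEmulation()] in one document: group cohort parameters,
#' per-group Prony models, phantom settings (A-scans, SNR, pressure
#' modulation), trace settings (sampling, duration, noise), analysis
#' settings (ROI mode, smoothing window, aperture radius). The defaults
#' emulate the wild-type vs Col5a1+/- study conditions; the phantom
#' width is 201 A-scans per eye, which covers the 0.5 mm central
#' analysis zone with a wide margin while keeping a full cohort run fast.
#'
#' @param seed base seed; every stochastic stage derives its own seed from
#'   it deterministically.
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    groups = mouseCorneaGroupParams(),
    prony = list(wt = "wt", col5a1 = "col5a1"),
    phantom = list(nAscans = 201L, snrDb = 30, deltaP = -3,
                   asu = .DEFAULT_ASU, wavelength = .DEFAULT_WAVELENGTH,
                   refractiveIndex = .DEFAULT_RI,
                   lateralPitch = .DEFAULT_LATERAL_PITCH,
                   radius = .DEFAULT_CORNEA_RADIUS),
    trace = list(sampleRate = 10, duration = 120, noiseSdRel = 0.01,
                 eps0 = 0.18),
    analysis = list(roiMode = "physical", window = c(5L, 9L),
                    apertureRadius = .DEFAULT_APERTURE_RADIUS,
                    horizon = 100)
  )
}

.loadConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    cfg <- yaml::read_yaml(config)
    base <- defaultRunConfig(if (!is.null(cfg$seed)) cfg$seed else 1L)
    utils::modifyList(base, cfg)
  } else if (is.list(config)) {
    utils::modifyList(defaultRunConfig(
      if (!is.null(config$seed)) config$seed else 1L), config)
  } else if (is.null(config)) {
    defaultRunConfig()
  } else stop("config must be a list, a YAML path, or NULL")
}

.groupProny <- function(spec) {
  if (is(spec, "PronyModel")) return(spec)
  if (is.character(spec)) return(mouseCorneaPronyConstants(spec))
  PronyModel(spec$eInf, e = unlist(spec$e), tau = unlist(spec$tau))
}

#' Emulate the two-group corneal biomechanics study end to end
#'
#' For every eye of every group: draws the eye's true thickness and moduli
#' from the group distributions, synthesizes the corresponding B-scan pair
#' (with the axial strain implied by the Laplace stress at the drawn
#' thickness and OCE modulus) and force traces (relaxation from the group
#' Prony model, ramp from the drawn extensometry modulus), then runs the
#' full elastography and extensometry analyses, assembles the recovered
#' per-eye cohort table, and compares the groups with the normality-gated
#' workflow. Eyes whose analysis fails are reported and skipped; the run
#' continues.
#'
#' @param config a configuration list (see [defaultRunConfig()]), a YAML
#'   file path, or NULL for the defaults.
#' @param outDir output directory; created if missing. Writes
#'   \code{cohort.csv} (recovered per-eye values), \code{comparison.csv},
#'   \code{summary.csv}, per-eye JSON records under \code{eyes/}, a
#'   markdown \code{report.md} and a \code{provenance.json} (config,
#'   seeds, package version).
#' @return invisibly, a list with \code{cohort}, \code{comparison},
#'   \code{summary} (as returned by [summarizeCohort()]) and
#'   \code{errors}.
#' @examples
#' \donttest{
#' cfg <- defaultRunConfig(seed = 7)
#' cfg$groups$wt$nEyes <- 3L; cfg$groups$col5a1$nEyes <- 3L
#' cfg$phantom$nAscans <- 101L
#' res <- runStudyEmulation(cfg, outDir = tempfile("run"))
#' res$comparison
#' }
#' @export
runStudyEmulation <- function(config = NULL, outDir = "study_run") {
  cfg <- .loadConfig(config)
  if (length(cfg$groups) < 1L) stop("empty cohort: no groups configured")
  if (any(vapply(cfg$groups, function(g) g$nEyes < 1L, logical(1))))
    stop("empty cohort: every group needs at least one eye")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "eyes"), showWarnings = FALSE)

  set.seed(cfg$seed)
  eyeSeeds <- sample.int(2^31 - 2, sum(vapply(cfg$groups, `[[`, integer(1),
                                              "nEyes")) * 2L)
  ph <- cfg$phantom; an <- cfg$analysis; trc <- cfg$trace
  limit <- .strainLimit(ph$wavelength, ph$refractiveIndex, ph$asu)

  rows <- list(); errors <- character(); k <- 0L
  for (g in cfg$groups) {
    prony <- .groupProny(cfg$prony[[g$label]])
    for (i in seq_len(g$nEyes)) {
      k <- k + 1L
      sEye <- eyeSeeds[2L * k - 1L]
      set.seed(sEye)
      cct <- max(60, stats::rnorm(1, g$cctMeanSd[1], g$cctMeanSd[2]))
      eOct <- max(50, stats::rnorm(1, g$eOctMeanSd[1], g$eOctMeanSd[2]))
      eExt <- max(2, stats::rnorm(1, g$eExtMeanSd[1], g$eExtMeanSd[2]))
      id <- sprintf("%s_%02d", g$label, i)

      rec <- list(eye_id = id, group = g$label,
                  true_cct_um = cct, true_E_oct_kPa = eOct,
                  true_E_ext_kPa = eExt)
      row <- data.frame(eye_id = id, group = g$label,
                        cct_um = NA_real_, strain_permil = NA_real_,
                        E_oct_kPa = NA_real_, E_ext_kPa = NA_real_,
                        reduction_pct = NA_real_, ruptured = FALSE,
                        stringsAsFactors = FALSE)

      oce <- tryCatch({
        sigma <- abs(mmHgToPa(ph$deltaP)) * (ph$radius * 1e-3) /
          (2 * cct * 1e-6)
        epsTrue <- -min(sigma / (eOct * 1000), 0.95 * limit)
        pair <- simulateScanPair(
          cct = cct, imposedStrain = epsTrue, nAscans = ph$nAscans,
          asu = ph$asu, wavelength = ph$wavelength,
          refractiveIndex = ph$refractiveIndex,
          lateralPitch = ph$lateralPitch, radius = ph$radius,
          deltaP = ph$deltaP, snrDb = ph$snrDb, seed = sEye)
        analyzeScanPair(pair, window = an$window, roiMode = an$roiMode)
      }, error = function(e) {
        errors <<- c(errors, sprintf("%s [oce]: %s", id, conditionMessage(e)))
        NULL
      })
      if (!is.null(oce)) {
        row$cct_um <- oce$cct_um
        row$strain_permil <- oce$mean_strain_permil
        row$E_oct_kPa <- oce$E_kPa
        rec$oce <- oce[c("cct_um", "mean_strain_permil", "delta_sigma_Pa",
                         "E_kPa", "roi_mode")]
      }

      ext <- tryCatch({
        geom <- LoadingGeometry(cct = cct, radius = an$apertureRadius)
        rel <- simulateRelaxationTrace(
          prony, eps0 = trc$eps0, sampleRate = trc$sampleRate,
          duration = trc$duration, noiseSdRel = trc$noiseSdRel,
          geometry = geom, seed = eyeSeeds[2L * k])
        ramp <- simulateRampTrace(
          eExt * 1000, geometry = geom, noiseSdRel = trc$noiseSdRel,
          seed = eyeSeeds[2L * k])
        list(rel = analyzeTrace(rel, horizon = an$horizon),
             ramp = analyzeTrace(ramp))
      }, error = function(e) {
        errors <<- c(errors, sprintf("%s [ext]: %s", id, conditionMessage(e)))
        NULL
      })
      if (!is.null(ext)) {
        row$E_ext_kPa <- ext$ramp$E_ext_kPa
        row$reduction_pct <- ext$rel$reduction_pct
        row$ruptured <- isTRUE(ext$ramp$ruptured)
        rec$extensometry <- list(E_ext_kPa = ext$ramp$E_ext_kPa,
                                 reduction_pct = ext$rel$reduction_pct,
                                 prony = ext$rel$prony,
                                 ruptured = isTRUE(ext$ramp$ruptured))
      }

      jsonlite::write_json(rec, file.path(outDir, "eyes",
                                          paste0(id, ".json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      rows[[k]] <- row
    }
  }

  cohort <- do.call(rbind, rows)
  writeCohort(cohort, file.path(outDir, "cohort.csv"))
  summary <- summarizeCohort(cohort,
                             variables = c("cct_um", "strain_permil",
                                           "E_oct_kPa", "E_ext_kPa",
                                           "reduction_pct"))
  utils::write.csv(summary$summary, file.path(outDir, "summary.csv"),
                   row.names = FALSE)
  comparison <- NULL
  if (length(unique(cohort$group)) == 2L) {
    comparison <- tryCatch(
      compareCohort(cohort,
                    variables = c("cct_um", "strain_permil", "E_oct_kPa",
                                  "E_ext_kPa", "reduction_pct")),
      error = function(e) {
        errors <<- c(errors, sprintf("[comparison]: %s", conditionMessage(e)))
        NULL
      })
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(outDir, "comparison.csv"),
                       row.names = FALSE)
  }

  .writeReport(file.path(outDir, "report.md"), summary, comparison, errors)
  jsonlite::write_json(
    list(package = "CorneaBiomech",
         version = as.character(utils::packageVersion("CorneaBiomech")),
         seed = cfg$seed, config = cfg, n_errors = length(errors),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  invisible(list(cohort = cohort, comparison = comparison,
                 summary = summary, errors = errors))
}

.writeReport <- function(path, summary, comparison, errors) {
  lines <- c("# Study emulation report", "",
             "## Group summaries (mean +/- SD)", "")
  s <- summary$summary
  for (v in unique(s$variable)) {
    sv <- s[s$variable == v, ]
    lines <- c(lines, sprintf("- %s: %s", v, paste(
      sprintf("%s %.2f +/- %.2f (n=%d)", sv$group, sv$mean, sv$sd, sv$n),
      collapse = " vs ")))
  }
  if (!is.null(summary$ratios)) {
    lines <- c(lines, "", "## Between-group ratios of means", "",
               sprintf("- %s: factor %.1f", names(summary$ratios),
                       summary$ratios))
  }
  if (!is.null(comparison)) {
    lines <- c(lines, "", "## Two-sample comparisons", "",
               sprintf("- %s: %s test, p = %.4g", comparison$variable,
                       comparison$test, comparison$p_value))
  }
  if (length(errors))
    lines <- c(lines, "", "## Per-eye errors", "", paste("-", errors))
  writeLines(lines, path)
}
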