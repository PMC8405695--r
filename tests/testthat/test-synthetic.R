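test_that("zero imposed strain leaves the phase difference identically zero", {
  pair <- simulateScanPair(cct = 148, imposedStrain = 0, nAscans = 41,
                           seed = 11)
  phaseDiff <- Arg(scanRef(pair) * Conj(scanDef(pair)))
  tissue <- Mod(scanRef(pair)) > 0
  expect_true(all(phaseDiff[tissue] == 0))
  sm <- axialStrain(complexCrossCorrelation(pair, c(5, 9)))
  expect_equal(as.numeric(meanCentralStrain(sm)), 0, tolerance = 1e-12)
  # a zero mean strain leaves the modulus undefined
  expect_error(estimateModulus(laplaceStress(LoadingGeometry(148, 1.5, -3)),
                               0), "zero")
})

test_that("the imposed strain is encoded exactly as a per-pixel phase step", {
  eps <- -4.84e-3
  pair <- simulateScanPair(cct = 148, imposedStrain = eps, nAscans = 41,
                           seed = 3)
  m <- scanMeta(pair)
  expectedStep <- 4 * pi * m$refractiveIndex * eps * m$asu /
    (m$wavelength * 1e-3)
  phi <- Arg(Conj(scanRef(pair)) * scanDef(pair))
  j <- 21  # central A-scan
  a <- m$anterior[j]; p <- m$posterior[j]
  steps <- diff(unwrapPhase(phi[a:p, j]))
  expect_equal(steps, rep(expectedStep, length(steps)), tolerance = 1e-10)
})

test_that("strains beyond the phase-unambiguous range are rejected", {
  expect_error(simulateScanPair(imposedStrain = -40e-3, nAscans = 21),
               "phase-unambiguous")
  # the limit itself evaluates to lambda/(4 n asu)
  lim <- (878e-3) / (4 * 1.375 * 4.48)
  expect_error(simulateScanPair(imposedStrain = lim * 1.001, nAscans = 21))
  expect_s4_class(simulateScanPair(imposedStrain = lim * 0.9, nAscans = 21),
                  "OCEScanPair")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- simulateScanPair(nAscans = 31, snrDb = 25, seed = 42)
  b <- simulateScanPair(nAscans = 31, snrDb = 25, seed = 42)
  expect_identical(scanRef(a), scanRef(b))
  expect_identical(scanDef(a), scanDef(b))
  wt <- mouseCorneaPronyConstants("wt")
  t1 <- simulateRelaxationTrace(wt, noiseSdRel = 0.01, seed = 9)
  t2 <- simulateRelaxationTrace(wt, noiseSdRel = 0.01, seed = 9)
  expect_identical(traceForce(t1), traceForce(t2))
  c1 <- simulateCohort(seed = 5)
  c2 <- simulateCohort(seed = 5)
  expect_identical(c1, c2)
})

test_that("a degenerate Prony model yields a constant relaxation trace", {
  m <- PronyModel(2e6)
  tr <- simulateRelaxationTrace(m, eps0 = 0.1,
                                geometry = LoadingGeometry(148, 0.8))
  s <- stressFromForce(traceForce(tr), traceGeometry(tr))
  expect_equal(s, rep(0.1 * 2e6, length(s)), tolerance = 1e-12)
  expect_true(all(traceSegment(tr) == "relaxation"))
})

test_that("reference-constant relaxation traces match closed-form values", {
  wt <- mouseCorneaPronyConstants("wt")
  tr <- simulateRelaxationTrace(wt, eps0 = 0.18)
  s <- stressFromForce(traceForce(tr), traceGeometry(tr))
  # instantaneous modulus is the sum of all printed constants
  expect_equal(s[1] / 0.18 / 1e6, 1.18 + 0.43 + 0.51 + 0.88,
               tolerance = 1e-10)
  # noiseless stress is monotone non-increasing
  expect_true(all(diff(s) <= 0))
  # closed-form relative reduction at 100 s
  oracle <- pronyStress(1.18, c(0.43, 0.51, 0.88), c(3.1, 51, 124),
                        c(0, 100), 0.18)
  expect_equal(relaxationReduction(s, traceTime(tr)),
               100 * (oracle[1] - oracle[2]) / oracle[1], tolerance = 1e-10)
})

test_that("invalid trace specifications are rejected", {
  expect_error(PronyModel(-1e6, e = 1e6, tau = 10))
  expect_error(PronyModel(1e6, e = 1e6, tau = -10))
  expect_error(simulateRelaxationTrace(mouseCorneaPronyConstants("wt"),
                                       eps0 = -0.1))
  expect_error(simulateRampTrace(30.7e3, LoadingGeometry(148, 0.8),
                                 fStart = 4, fEnd = 0.4))
  expect_error(LoadingGeometry(cct = -5, radius = 0.8))
})

test_that("cohort draws reproduce the specified group distributions", {
  cohort <- simulateCohort(seed = 21)
  pars <- mouseCorneaGroupParams()
  for (g in pars) {
    x <- cohort$cct_um[cohort$group == g$label]
    expect_length(x, g$nEyes)
    se <- g$cctMeanSd[2] / sqrt(g$nEyes)
    expect_lt(abs(mean(x) - g$cctMeanSd[1]), 3 * se)
    y <- cohort$E_oct_kPa[cohort$group == g$label]
    expect_lt(abs(mean(y) - g$eOctMeanSd[1]),
              3 * g$eOctMeanSd[2] / sqrt(g$nEyes))
  }
})

test_that("zero-SD groups produce identical eyes at the mean", {
  spec <- list(list(label = "wt", nEyes = 4L, cctMeanSd = c(148, 0),
                    strainMeanSd = c(-4.93, 0), eOctMeanSd = c(430, 0),
                    eExtMeanSd = c(21.5, 0)))
  cohort <- simulateCohort(spec, seed = 1)
  expect_true(all(cohort$cct_um == 148))
  expect_true(all(cohort$E_oct_kPa == 430))
})

test_that("identical group specs rarely produce significant differences", {
  spec <- mouseCorneaGroupParams()
  spec$col5a1[c("cctMeanSd", "strainMeanSd", "eOctMeanSd", "eExtMeanSd")] <-
    spec$wt[c("cctMeanSd", "strainMeanSd", "eOctMeanSd", "eExtMeanSd")]
  spec$wt$nEyes <- spec$col5a1$nEyes <- 30L
  hits <- vapply(1:100, function(s) {
    co <- simulateCohort(spec, seed = s)
    compareGroups(co$cct_um[co$group == "wt"],
                  co$cct_um[co$group == "col5a1"])$pValue > 0.05
  }, logical(1))
  # nominal 95% non-rejection, allowing 3 binomial SDs at 100 draws
  expect_gte(mean(hits), 0.95 - 3 * sqrt(0.05 * 0.95 / 100))
})
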