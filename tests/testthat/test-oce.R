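test_that("correlation of a scan with itself has zero phase", {
  pair <- simulateScanPair(imposedStrain = 0, nAscans = 31, seed = 2)
  samePair <- new("OCEScanPair", bRef = scanRef(pair), bDef = scanRef(pair),
                  meta = scanMeta(pair))
  cf <- complexCrossCorrelation(samePair, window = c(5, 9))
  expect_true(all(Arg(cf@rs[Mod(cf@rs) > 0]) == 0))
})

test_that("a constant global phase appears negated in the correlation", {
  phi0 <- 0.7
  pair <- simulateScanPair(imposedStrain = 0, nAscans = 31, seed = 2)
  shifted <- new("OCEScanPair", bRef = scanRef(pair),
                 bDef = scanRef(pair) * exp(1i * phi0),
                 meta = scanMeta(pair))
  cf <- complexCrossCorrelation(shifted, window = c(3, 3))
  sel <- Mod(cf@rs) > 1e-9
  expect_equal(Arg(cf@rs[sel]), rep(-phi0, sum(sel)), tolerance = 1e-9)
})

test_that("a (1,1) window leaves the raw conjugate product unsmoothed", {
  pair <- simulateScanPair(nAscans = 21, seed = 4)
  cf <- complexCrossCorrelation(pair, window = c(1, 1))
  expect_equal(cf@rs, scanRef(pair) * Conj(scanDef(pair)))
})

test_that("shape mismatches and even windows are rejected", {
  pair <- simulateScanPair(nAscans = 21, seed = 4)
  expect_error(complexCrossCorrelation(pair, window = c(4, 9)), "odd")
  bad <- pair
  bad@bDef <- pair@bDef[-1, ]
  expect_error(validObject(bad), "identical shape")
})

test_that("phase fields map to strain by the documented scale", {
  meta <- list(wavelength = 878, asu = 4.48, n = 1.375)
  scale <- (878e-3) / (4 * pi * 1.375 * 4.48)
  # zero phase -> zero strain
  p0 <- pairFromPhase(matrix(0, 30, 11))
  sm0 <- axialStrain(complexCrossCorrelation(p0, c(1, 1)))
  expect_true(all(strainValues(sm0) == 0))
  # depth-linear phase, step pi per pixel -> strain at the saturation
  # limit lambda/(4 n asu), flagged invalid
  phi <- matrix(rep(-pi * (0:29), 11), 30, 11)
  pp <- pairFromPhase(phi)
  smp <- axialStrain(complexCrossCorrelation(pp, c(1, 1)))
  expect_equal(abs(strainValues(smp)[5, 5]), scale * pi, tolerance = 1e-12)
  expect_equal(1000 * abs(strainValues(smp)[5, 5]), 35.63, tolerance = 1e-2)
  expect_false(any(strainMask(smp)[1:29, ]))
  # a modest linear phase is recovered exactly and is valid
  phi2 <- matrix(rep(0.3 * (0:29), 11), 30, 11)
  sm2 <- axialStrain(complexCrossCorrelation(pairFromPhase(phi2), c(1, 1)))
  expect_equal(strainValues(sm2)[3, 3], scale * 0.3, tolerance = 1e-12)
  expect_true(all(strainMask(sm2)))
})

test_that("strain equals the unwrapped-phase finite-difference oracle", {
  pair <- simulateScanPair(cct = 148, imposedStrain = -4.93e-3,
                           nAscans = 41, seed = 8)
  m <- scanMeta(pair)
  sm <- axialStrain(complexCrossCorrelation(pair, c(1, 1)))
  scale <- (m$wavelength * 1e-3) / (4 * pi * m$refractiveIndex * m$asu)
  for (j in c(10, 21, 30)) {
    a <- m$anterior[j]; p <- m$posterior[j]
    # the estimator differences the correlation phase with depth
    phase <- Arg(scanRef(pair)[a:p, j] * Conj(scanDef(pair)[a:p, j]))
    oracle <- -scale * diff(unwrapPhase(phase))
    expect_equal(strainValues(sm)[a:(p - 1), j], oracle, tolerance = 1e-9)
  }
})

test_that("strain maps are invariant to a global phase on the deformed scan", {
  pair <- simulateScanPair(cct = 148, imposedStrain = -3e-3, nAscans = 41,
                           snrDb = 30, seed = 6)
  rot <- new("OCEScanPair", bRef = scanRef(pair),
             bDef = scanDef(pair) * exp(1i * 1.1), meta = scanMeta(pair))
  sm1 <- axialStrain(complexCrossCorrelation(pair, c(5, 9)))
  sm2 <- axialStrain(complexCrossCorrelation(rot, c(5, 9)))
  expect_equal(strainValues(sm1), strainValues(sm2), tolerance = 1e-9)
})

test_that("larger smoothing windows do not increase strain-map variance", {
  pair <- simulateScanPair(cct = 148, imposedStrain = -4e-3, nAscans = 81,
                           snrDb = 20, seed = 13)
  m <- scanMeta(pair)
  tissue <- CorneaBiomech:::.boundaryMask(m$anterior, m$posterior,
                                          nrow(scanRef(pair)), erode = 8L)
  vars <- vapply(list(c(1, 1), c(3, 3), c(3, 9), c(5, 9), c(9, 15)),
                 function(w) {
    sm <- axialStrain(complexCrossCorrelation(pair, w), tissueMask = tissue)
    var(strainValues(sm)[strainMask(sm)])
  }, numeric(1))
  expect_true(all(diff(vars) <= 0))
})

test_that("segmentation recovers phantom thickness within one pixel", {
  for (cct in c(148, 125)) {
    pair <- simulateScanPair(cct = cct, nAscans = 101, snrDb = 30,
                             seed = cct)
    seg <- segmentCornea(Mod(scanRef(pair))^2, scanMeta(pair))
    expect_lt(abs(seg$cct - cct), 4.48 + 1e-9)
    ok <- !is.na(seg$anterior)
    expect_true(all(seg$anterior[ok] < seg$posterior[ok]))
  }
})

test_that("featureless images fail segmentation", {
  expect_error(segmentCornea(matrix(1, 50, 50),
                             list(asu = 4.48, lateralPitch = 12.5)),
               "featureless|interfaces")
})

test_that("central averaging respects both ROI modes", {
  # uniform field: both modes return the value
  eps0 <- -3e-3
  uni <- new("StrainMap", eps = matrix(eps0, 40, 60),
             mask = matrix(TRUE, 40, 60), roi = list(),
             meta = list(lateralPitch = 12.5))
  for (m in c("physical", "pixels"))
    expect_equal(as.numeric(meanCentralStrain(uni, mode = m)), eps0)
  # half eps0, half zero, ROI spanning both halves equally
  half <- new("StrainMap",
              eps = cbind(matrix(eps0, 40, 30), matrix(0, 40, 30)),
              mask = matrix(TRUE, 40, 60), roi = list(),
              meta = list(lateralPitch = 12.5))
  wide <- meanCentralStrain(half, mode = "physical", diameter = 10)
  expect_equal(as.numeric(wide), eps0 / 2)
  expect_identical(attr(wide, "mode"), "physical")
  # empty mask errors
  none <- new("StrainMap", eps = matrix(0, 5, 5),
              mask = matrix(FALSE, 5, 5), roi = list(),
              meta = list(lateralPitch = 12.5))
  expect_error(meanCentralStrain(none), "empty ROI")
})

test_that("Laplace stress matches direct evaluation and its scaling laws", {
  expect_equal(laplaceStress(LoadingGeometry(148, 1.5, deltaP = 3)),
               3 * 133.322 * 1.5e-3 / (2 * 148e-6), tolerance = 1e-12)
  expect_equal(round(laplaceStress(LoadingGeometry(148, 1.5, deltaP = 3))),
               2027)
  expect_equal(round(laplaceStress(LoadingGeometry(125, 1.5, deltaP = 3))),
               2400)
  expect_identical(laplaceStress(LoadingGeometry(148, 1.5, deltaP = 0)), 0)
  # linear in deltaP and R, inverse in cct
  base <- laplaceStress(LoadingGeometry(100, 1.5, deltaP = 2))
  expect_equal(laplaceStress(LoadingGeometry(100, 1.5, deltaP = 4)), 2 * base)
  expect_equal(laplaceStress(LoadingGeometry(100, 3.0, deltaP = 2)), 2 * base)
  expect_equal(laplaceStress(LoadingGeometry(200, 1.5, deltaP = 2)), base / 2)
  expect_error(LoadingGeometry(0, 1.5, deltaP = 3))
})

test_that("modulus estimation is the documented magnitude ratio", {
  r <- estimateModulus(2027, -4.93e-3)
  expect_equal(eModulus(r) / 1000, 411.2, tolerance = 0.05)
  expect_equal(eModulus(estimateModulus(2400, -4.84e-3)) / 1000, 495.9,
               tolerance = 0.05)
  expect_equal(eModulus(estimateModulus(123.4, 1)), 123.4)
  expect_gt(eModulus(estimateModulus(-2027, -4.93e-3)), 0)
  expect_error(estimateModulus(2027, 0), "zero")
})
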