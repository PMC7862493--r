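test_that("sampleCurve reproduces constant and step curves", {
  const <- new("CumHist", kind = "DVH", abscissa = c(0, 10),
               ordinate = c(100, 100), structure = "s", sourceLabel = "t")
  expect_equal(sampleCurve(const, 50, axisMax = 10), rep(100, 50))

  ## uniform dose at half the axis maximum: step at sample ceiling(0.5 * 49)
  g <- tinyGrid(c(8, 8, 8))
  uni <- computeDVH(doseGridOn(5, g), array(TRUE, gridShape(g)), 100)
  s <- sampleCurve(uni, 50, axisMax = 10)
  expect_equal(s, c(rep(100, 25), rep(0, 25)))
})

test_that("sampleCurve matches an independent interpolation oracle", {
  set.seed(5)
  for (rep in 1:5) {
    curve <- randomMonotoneCurve(25, dmax = 80)
    axisMax <- 100
    s <- sampleCurve(curve, 50, axisMax = axisMax)
    t <- seq(0, 1, length.out = 50)
    oracle <- vapply(t, function(tt) {
      x <- tt * axisMax
      if (x > max(abscissa(curve))) 0
      else stats::approx(abscissa(curve), ordinate(curve), x,
                         ties = "ordered")$y
    }, numeric(1))
    expect_equal(s, oracle, tolerance = 1e-12)
  }
})

test_that("sampleCurve clips out-of-range abscissae with a warning", {
  over <- new("CumHist", kind = "DVH", abscissa = c(0, 8, 12),
              ordinate = c(100, 60, 0), structure = "s", sourceLabel = "t")
  expect_warning(s <- sampleCurve(over, 50, axisMax = 10), "clipping")
  expect_equal(s[50], 30) # interpolated at the clipped endpoint
  expect_error(sampleCurve(over, 50, axisMax = 0), "axisMax")
})

test_that("norm constants come from the stored per-record maxima", {
  r1 <- syntheticRecord(patient = "a")
  norms <- fitNormConstants(list(r1))
  expect_equal(norms@maxFieldDose, 1.2)
  expect_equal(norms@maxCpdvhPtvDose, 71)
  expect_equal(norms@maxClinicalPtvDose, 74)
  expect_equal(norms@maxDthDistance, 2)
  expect_equal(norms@minDthNorm, -0.5)

  ## adding a patient can only increase or preserve each constant
  r2 <- syntheticRecord(patient = "b")
  r2@meta$fieldMaxDose <- 1.5
  n2 <- fitNormConstants(list(r1, r2))
  expect_equal(n2@maxFieldDose, 1.5)
  expect_gte(n2@maxCpdvhPtvDose, norms@maxCpdvhPtvDose)
  expect_false(identical(n2@fittedOn, norms@fittedOn))
})

test_that("norm constants equal a brute-force rescan of the dose grids", {
  g <- coarseGrid()
  cohort <- generateCohort(cohortConfig("HN", nPatients = 3, masterSeed = 8,
                                        grid = g))
  b <- beamSet("HN")
  records <- lapply(seq_along(cohort), function(i)
    buildPlanRecord(cohort[[i]], b, 70, clinSeed = i))
  norms <- fitNormConstants(records)

  fieldMax <- -Inf; cpMax <- -Inf; clMax <- -Inf
  for (i in seq_along(cohort)) {
    ph <- cohort[[i]]
    body <- structureMask(ph, "body")
    ptvU <- structureMask(ph, "PTV54")
    fields <- lapply(gantryAngles(b), function(a) fieldDose(ph, a, b))
    conf <- conformalPlan(ph, b, 70, fields = fields)
    clin <- pseudoClinicalDose(ph, b, 70, seed = i, conformal = conf)
    fieldMax <- max(fieldMax, vapply(fields, function(f)
      max(doseValues(f)[body]), numeric(1)))
    cpMax <- max(cpMax, max(doseValues(conf)[ptvU]))
    clMax <- max(clMax, max(doseValues(clin)[ptvU]))
  }
  expect_equal(norms@maxFieldDose, fieldMax)
  expect_equal(norms@maxCpdvhPtvDose, cpMax)
  expect_equal(norms@maxClinicalPtvDose, clMax)
})

test_that("feature vectors have the printed dimensionalities", {
  rec <- syntheticRecord()
  norms <- fitNormConstants(list(rec))
  fI <- buildFeatures(rec, "oar1", "IDVHS", norms)
  expect_length(fI, 450)
  fD <- buildFeatures(rec, "oar1", "DTH_CPDVH", norms)
  expect_length(fD, 100)
  fP <- buildFeatures(rec, "PTV70", "IDVHS", norms)
  expect_length(fP, 450)
  expect_true(all(fI >= 0 & fI <= 100))
  expect_true(all(fD >= 0 & fD <= 100))
})

test_that("PTVs reject the geometric feature set", {
  rec <- syntheticRecord()
  norms <- fitNormConstants(list(rec))
  expect_error(buildFeatures(rec, "PTV70", "DTH_CPDVH", norms), "PTV")
})

test_that("an OAR with zero field dose yields the V(0)=100 anchor pattern", {
  rec <- syntheticRecord(oarDoseMax = 0)
  norms <- fitNormConstants(list(rec))
  f <- buildFeatures(rec, "oar1", "IDVHS", norms)
  parts <- matrix(f, nrow = 50)
  expect_equal(unname(parts[1, ]), rep(100, 9))
  expect_true(all(parts[-1, ] == 0))
})

test_that("field order is semantic in the IDVHs concatenation", {
  rec <- syntheticRecord()
  ## make the field curves distinguishable
  rec@curves$oar1$idvh[[1]] <- new("CumHist", kind = "DVH",
                                   abscissa = c(0, 0.2),
                                   ordinate = c(100, 0),
                                   structure = "oar1", sourceLabel = "f")
  norms <- fitNormConstants(list(rec))
  f1 <- buildFeatures(rec, "oar1", "IDVHS", norms)
  recPerm <- rec
  recPerm@curves$oar1$idvh <- rev(rec@curves$oar1$idvh)
  f2 <- buildFeatures(recPerm, "oar1", "IDVHS", norms)
  expect_false(identical(as.numeric(f1), as.numeric(f2)))
})

test_that("targets are monotone and recover doses within one bin width", {
  g <- coarseGrid()
  ph <- generateCohort(cohortConfig("HN", nPatients = 1, masterSeed = 12,
                                    grid = g))[[1]]
  rec <- buildPlanRecord(ph, beamSet("HN"), 70, clinSeed = 3)
  norms <- fitNormConstants(list(rec))
  for (nm in c(ptvNames(rec), oarNames(rec))) {
    y <- buildTarget(rec, nm, norms)
    expect_length(y, 50)
    expect_true(all(diff(y) <= 1e-9))
    expect_true(all(y >= 0 & y <= 100))
  }
  ## round trip: un-normalizing the sampled axis recovers Gy endpoints
  clin <- rec@curves$PTV70$clinical
  y <- buildTarget(rec, "PTV70", norms)
  axis <- seq(0, 1, length.out = 50) * norms@maxClinicalPtvDose
  binW <- norms@maxClinicalPtvDose / 49
  d95Sampled <- doseAtVolume(curveOn(axis, y), 95)
  expect_lt(abs(d95Sampled - doseAtVolume(clin, 95)), binW)
})
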