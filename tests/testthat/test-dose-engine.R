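## a slab phantom: full-grid body, one-voxel-column target along the beam
slabPhantom <- function(shape = c(16, 16, 8), spacing = c(0.25, 0.25, 0.25)) {
  g <- gridSpec(shape, spacing)
  body <- array(TRUE, shape)
  tgt <- array(FALSE, shape)
  tgt[8, , 4] <- TRUE
  new("Phantom", grid = g,
      structures = list(body = body, PTV70 = tgt, PTV60 = tgt, PTV54 = tgt),
      site = "HN", ptvNames = c("PTV70", "PTV60", "PTV54"),
      oarNames = character(), patientId = "slab", seed = 0)
}

test_that("depth dose decays as exp(-mu * depth) on a slab", {
  ph <- slabPhantom()
  b <- beamSet("HN", muPerCm = 0.05)
  f <- fieldDose(ph, 0, b) # beam travels towards +y
  v <- doseValues(f)[8, , 4]
  ## ratio between consecutive depths equals exp(-mu * dy) to 1e-6
  dy <- gridSpacing(ph@grid)[2]
  ratios <- v[-1] / v[-length(v)]
  expect_equal(ratios, rep(exp(-b@muPerCm * dy), length(ratios)),
               tolerance = 1e-6)
  ## the shallowest target voxel carries the maximum dose 1
  expect_equal(max(doseValues(f)[structureMask(ph, "PTV54")]), 1)
})

test_that("dose far outside the aperture is below 1e-4 of the maximum", {
  ph <- slabPhantom(c(40, 16, 8))
  b <- beamSet("HN")
  ph@structures$PTV54 <- array(FALSE, gridShape(ph@grid))
  ph@structures$PTV54[20, , 4] <- TRUE
  f <- fieldDose(ph, 0, b)
  ## lateral offset from the aperture edge
  latCm <- abs((1:40) - 20) * 0.25 - b@apertureMarginCm
  far <- latCm >= 5 * b@penumbraSigmaCm
  expect_true(all(doseValues(f)[far, , 4] < 1e-4))
})

test_that("opposed beams give mirror-image doses on a symmetric phantom", {
  g <- gridSpec(c(24, 24, 12), c(0.25, 0.25, 0.25))
  ctr <- c(3, 3, 1.5)
  body <- ellipsoidMask <- function(center, semi) {
    cc <- lapply(1:3, function(a)
      (seq_len(gridShape(g)[a]) - 0.5) * gridSpacing(g)[a])
    q <- outer(outer(((cc[[1]] - center[1]) / semi[1])^2,
                     ((cc[[2]] - center[2]) / semi[2])^2, `+`),
               ((cc[[3]] - center[3]) / semi[3])^2, `+`)
    q <= 1
  }
  body <- ellipsoidMask(ctr, c(2.6, 2.6, 1.4))
  tgt <- ellipsoidMask(ctr, c(1.0, 1.2, 0.8))
  ph <- new("Phantom", grid = g,
            structures = list(body = body, PTV70 = tgt, PTV60 = tgt,
                              PTV54 = tgt),
            site = "HN", ptvNames = c("PTV70", "PTV60", "PTV54"),
            oarNames = character(), patientId = "sym", seed = 0)
  b <- beamSet("HN")
  d0 <- doseValues(fieldDose(ph, 0, b))
  d180 <- doseValues(fieldDose(ph, 180, b))
  flipped <- d180[, dim(d180)[2]:1, , drop = FALSE]
  expect_lt(max(abs(d0 - flipped)) / max(d0), 1e-6)
})

test_that("rotating phantom and gantry together is consistent", {
  g <- gridSpec(c(24, 24, 12), c(0.25, 0.25, 0.25))
  set.seed(7)
  cc <- lapply(1:3, function(a)
    (seq_len(gridShape(g)[a]) - 0.5) * gridSpacing(g)[a])
  blob <- function(center, semi) {
    outer(outer(((cc[[1]] - center[1]) / semi[1])^2,
                ((cc[[2]] - center[2]) / semi[2])^2, `+`),
          ((cc[[3]] - center[3]) / semi[3])^2, `+`) <= 1
  }
  body <- blob(c(3, 3, 1.5), c(2.7, 2.4, 1.4))
  tgt <- blob(c(3.4, 2.8, 1.5), c(0.9, 1.1, 0.8))
  ph <- new("Phantom", grid = g,
            structures = list(body = body, PTV70 = tgt, PTV60 = tgt,
                              PTV54 = tgt),
            site = "HN", ptvNames = c("PTV70", "PTV60", "PTV54"),
            oarNames = character(), patientId = "rot", seed = 0)
  rot90 <- function(m) { # rotate -90 degrees about the grid centre
    t <- aperm(m, c(2, 1, 3))
    t[, dim(t)[2]:1, , drop = FALSE]
  }
  phRot <- ph
  phRot@structures <- lapply(ph@structures, rot90)
  b <- beamSet("HN")
  for (ang in c(0, 40)) {
    dOrig <- doseValues(fieldDose(ph, ang, b))
    dRot <- doseValues(fieldDose(phRot, (ang + 90) %% 360, b))
    expect_lt(max(abs(rot90(dOrig) - dRot)) / max(dOrig), 1e-6)
  }
})

test_that("conformal plan is the scaled equal-weight field sum", {
  ph <- generateCohort(cohortConfig("HN", nPatients = 1, masterSeed = 2,
                                    grid = coarseGrid()))[[1]]
  b <- beamSet("HN")
  fields <- lapply(gantryAngles(b), function(a) fieldDose(ph, a, b))
  plan <- conformalPlan(ph, b, 70, fields = fields)
  ## median dose in the highest PTV equals the prescription to 1e-9 relative
  med <- median(doseValues(plan)[structureMask(ph, "PTV70")])
  expect_equal(med, 70, tolerance = 1e-9)
  ## sum linearity: the scaled plan is proportional to the raw field sum
  rawSum <- Reduce(`+`, lapply(fields, doseValues))
  scale <- 70 / median(rawSum[structureMask(ph, "PTV70")])
  expect_equal(doseValues(plan), rawSum * scale, tolerance = 1e-12)

  ## a single-field beam set gives a plan proportional to that field
  b1 <- beamSet("HN", gantryAnglesDeg = 80)
  f1 <- fieldDose(ph, 80, b1)
  p1 <- conformalPlan(ph, b1, 70, fields = list(f1))
  nz <- doseValues(f1) > 0
  r <- doseValues(p1)[nz] / doseValues(f1)[nz]
  expect_lt(diff(range(r)), 1e-9 * mean(r))
})

test_that("angles outside [0, 360) are normalized with a warning", {
  ph <- slabPhantom()
  b <- beamSet("HN")
  expect_warning(f <- fieldDose(ph, 360 + 40, b), "normalized")
  expect_equal(doseValues(f), doseValues(fieldDose(ph, 40, b)))
})

test_that("pseudo-clinical dose reduces to the conformal plan when disabled", {
  ph <- generateCohort(cohortConfig("HN", nPatients = 1, masterSeed = 4,
                                    grid = coarseGrid()))[[1]]
  b <- beamSet("HN")
  conf <- conformalPlan(ph, b, 70)
  off <- sparingParams(sRange = c(0, 0), noiseSd = 0, hotspotFactor = 1)
  clin <- pseudoClinicalDose(ph, b, 70, off, seed = 1, conformal = conf)
  ptvU <- structureMask(ph, "PTV54")
  expect_equal(doseValues(clin)[!ptvU], doseValues(conf)[!ptvU])
  expect_true(all(doseValues(clin)[structureMask(ph, "PTV70")] == 70))
})

test_that("sparing strictly reduces dose outside the targets", {
  ph <- generateCohort(cohortConfig("HN", nPatients = 1, masterSeed = 4,
                                    grid = coarseGrid()))[[1]]
  b <- beamSet("HN")
  conf <- conformalPlan(ph, b, 70)
  sp <- sparingParams(sRange = c(0.5, 0.5), noiseSd = 0, hotspotFactor = 1)
  clin <- pseudoClinicalDose(ph, b, 70, sp, seed = 1, conformal = conf)
  out <- !structureMask(ph, "PTV54") & doseValues(conf) > 0
  expect_true(all(doseValues(clin)[out] < doseValues(conf)[out]))
  for (oar in c("lens_L", "lens_R"))
    expect_lt(mean(doseValues(clin)[structureMask(ph, oar)]),
              mean(doseValues(conf)[structureMask(ph, oar)]))
})

test_that("pseudo-clinical dose is deterministic given the seed", {
  ph <- generateCohort(cohortConfig("HN", nPatients = 1, masterSeed = 4,
                                    grid = coarseGrid()))[[1]]
  b <- beamSet("HN")
  conf <- conformalPlan(ph, b, 70)
  c1 <- pseudoClinicalDose(ph, b, 70, seed = 9, conformal = conf)
  c2 <- pseudoClinicalDose(ph, b, 70, seed = 9, conformal = conf)
  expect_identical(doseValues(c1), doseValues(c2))
  c3 <- pseudoClinicalDose(ph, b, 70, seed = 10, conformal = conf)
  expect_false(identical(doseValues(c1), doseValues(c3)))
})

test_that("pseudo-clinical target coverage stays clinical-like", {
  cohort <- generateCohort(cohortConfig("HN", nPatients = 10, masterSeed = 6,
                                        grid = coarseGrid()))
  b <- beamSet("HN")
  for (ph in cohort) {
    clin <- pseudoClinicalDose(ph, b, 70, seed = ph@seed)
    dvh <- computeDVH(clin, structureMask(ph, "PTV70"), 500, "PTV70")
    m <- suppressWarnings(doseMetrics(dvh))
    expect_gte(m$d98, 0.93 * 70)
    expect_lte(m$ui, 1.10)
  }
})
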