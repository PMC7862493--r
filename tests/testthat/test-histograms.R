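test_that("DVH matches direct counting on a four-voxel example", {
  g <- tinyGrid(c(8, 8, 8))
  v <- array(0, gridShape(g))
  m <- array(FALSE, gridShape(g))
  v[1:4] <- c(10, 20, 30, 40)
  m[1:4] <- TRUE
  curve <- computeDVH(doseGridOn(v, g), m, 2001)
  expect_equal(volumeAtDose(curve, 25), 50)
  expect_equal(volumeAtDose(curve, 40), 25)
  expect_equal(volumeAtDose(curve, 40 + 1e-9), 0)
  expect_equal(ordinate(curve)[1], 100)
})

test_that("uniform dose gives a step DVH", {
  g <- tinyGrid(c(8, 8, 8))
  m <- array(TRUE, gridShape(g))
  curve <- computeDVH(doseGridOn(7, g), m, 100)
  expect_true(all(ordinate(curve) == 100))
  expect_equal(max(abscissa(curve)), 7)
  expect_equal(volumeAtDose(curve, 7), 100)
  expect_equal(volumeAtDose(curve, 7.0001), 0)
})

test_that("DVH equals the brute-force threshold count at every bin", {
  g <- tinyGrid(c(10, 10, 10))
  set.seed(11)
  for (rep in 1:3) {
    v <- array(stats::rexp(1000, rate = 1 / 30), gridShape(g))
    m <- randomMask(g, 0.5)
    curve <- computeDVH(doseGridOn(v, g), m, 257)
    expect_identical(ordinate(curve),
                     bruteDvhOrdinate(v[m], abscissa(curve)))
  }
})

test_that("empty masks are an error naming the structure", {
  g <- tinyGrid(c(8, 8, 8))
  empty <- array(FALSE, gridShape(g))
  expect_error(computeDVH(doseGridOn(1, g), empty, 10, "cord"), "cord")
  expect_error(computeDTH(empty, array(TRUE, gridShape(g)), g,
                          structure = "cord"), "cord")
})

test_that("DTH of an OAR inside the PTV reaches 100% at r = 0", {
  g <- tinyGrid(c(12, 12, 12), c(0.2, 0.2, 0.2))
  ptv <- array(FALSE, gridShape(g)); ptv[4:9, 4:9, 4:9] <- TRUE
  oar <- array(FALSE, gridShape(g)); oar[6:7, 6:7, 6:7] <- TRUE
  curve <- computeDTH(oar, ptv, g, 100)
  expect_lte(max(abscissa(curve)), 0)
  expect_equal(ordinate(curve)[length(ordinate(curve))], 100)
})

test_that("DTH of a disjoint OAR is zero below the surface gap", {
  g <- tinyGrid(c(20, 12, 12), c(0.2, 0.2, 0.2))
  ptv <- array(FALSE, gridShape(g)); ptv[2:5, 4:9, 4:9] <- TRUE
  oar <- array(FALSE, gridShape(g)); oar[12:15, 4:9, 4:9] <- TRUE
  gap <- (12 - 5) * 0.2 # centre-to-centre along x
  curve <- computeDTH(oar, ptv, g, 500)
  voxDiag <- sqrt(sum(gridSpacing(g)^2))
  below <- abscissa(curve) < gap - voxDiag
  expect_true(all(ordinate(curve)[below] == 0))
  expect_gte(min(abscissa(curve)), gap - voxDiag)
})

test_that("signed distances agree with the all-pairs brute force", {
  g <- tinyGrid(c(12, 12, 12), c(0.2, 0.2, 0.3))
  set.seed(23)
  ptv <- array(FALSE, gridShape(g))
  ptv[3:7, 4:8, 5:9] <- TRUE
  ptv[8:9, 5:6, 6:7] <- TRUE
  oar <- randomMask(g, 0.15)
  ## EDT against the definitional all-pairs scan: identical arithmetic
  edt <- kbdvh:::signedDistance(ptv, g)
  brute <- bruteSignedDistance(ptv, g)
  expect_equal(edt, brute, tolerance = 1e-12)
  ## and against the PTV-surface-voxel scan, within half a voxel diagonal
  surf <- surfaceVoxels(ptv)
  halfDiag <- sqrt(sum(gridSpacing(g)^2)) / 2
  outside <- oar & !ptv
  dSurf <- abs(bruteSignedDistance(surf, g))
  expect_true(all(abs(abs(edt[outside]) - dSurf[outside]) <= halfDiag))
})

test_that("DTH is invariant under whole-voxel translations", {
  g <- tinyGrid(c(16, 16, 12), c(0.2, 0.2, 0.3))
  ptv <- array(FALSE, gridShape(g)); ptv[3:6, 3:6, 3:6] <- TRUE
  oar <- array(FALSE, gridShape(g)); oar[8:10, 4:6, 4:6] <- TRUE
  shift <- function(m, by) {
    out <- array(FALSE, dim(m))
    out[(1 + by[1]):dim(m)[1], (1 + by[2]):dim(m)[2],
        (1 + by[3]):dim(m)[3]] <-
      m[1:(dim(m)[1] - by[1]), 1:(dim(m)[2] - by[2]),
        1:(dim(m)[3] - by[3])]
    out
  }
  c1 <- computeDTH(oar, ptv, g, 200)
  c2 <- computeDTH(shift(oar, c(2, 1, 3)), shift(ptv, c(2, 1, 3)), g, 200)
  expect_equal(abscissa(c1), abscissa(c2), tolerance = 1e-12)
  expect_equal(ordinate(c1), ordinate(c2))
})

test_that("dose at volume inverts the curve with linear interpolation", {
  tri <- new("CumHist", kind = "DVH", abscissa = c(0, 50, 100),
             ordinate = c(100, 50, 0), structure = "s", sourceLabel = "t")
  expect_equal(doseAtVolume(tri, 95), 5)
  expect_equal(doseAtVolume(tri, 50), 50)
  expect_equal(doseAtVolume(tri, 0), 100)

  g <- tinyGrid(c(8, 8, 8))
  uni <- computeDVH(doseGridOn(42, g), array(TRUE, gridShape(g)), 100)
  for (y in c(10, 50, 90)) # warns: every volume level sits at the plateau
    expect_equal(suppressWarnings(doseAtVolume(uni, y)), 42)

  expect_error(doseAtVolume(new("CumHist", kind = "DTH", abscissa = 1,
                                ordinate = 100, structure = "s",
                                sourceLabel = "t"), 50), "DVH")
})

test_that("dose at volume matches dense numeric inversion", {
  set.seed(31)
  for (rep in 1:5) {
    curve <- randomMonotoneCurve()
    dense <- seq(0, max(abscissa(curve)), length.out = 200001)
    ord <- stats::approx(abscissa(curve), ordinate(curve), dense,
                         ties = "ordered")$y
    for (y in stats::runif(4, 1, 99)) {
      i <- which(ord <= y)[1]
      expect_equal(doseAtVolume(curve, y), dense[i],
                   tolerance = max(abscissa(curve)) / 200000 * 2)
    }
  }
})

test_that("volume at dose interpolates and vanishes beyond the curve", {
  tri <- new("CumHist", kind = "DVH", abscissa = c(0, 50, 100),
             ordinate = c(100, 50, 0), structure = "s", sourceLabel = "t")
  expect_equal(volumeAtDose(tri, 30), 70)
  expect_equal(volumeAtDose(tri, 0), 100)
  expect_equal(volumeAtDose(tri, 101), 0)
})

test_that("volume/dose round trip on strictly decreasing curves", {
  set.seed(37)
  for (rep in 1:5) {
    curve <- randomMonotoneCurve()
    for (y in stats::runif(5, 1, 99))
      expect_equal(volumeAtDose(curve, doseAtVolume(curve, y)), y,
                   tolerance = 1e-8)
  }
})

test_that("the DVH of a field sum dominates each component's DVH", {
  g <- tinyGrid(c(10, 10, 10))
  set.seed(41)
  m <- randomMask(g, 0.4)
  f1 <- array(stats::rexp(1000, 1 / 10), gridShape(g))
  f2 <- array(stats::rexp(1000, 1 / 20), gridShape(g))
  sumC <- computeDVH(doseGridOn(f1 + f2, g), m, 300)
  for (f in list(f1, f2)) {
    comp <- computeDVH(doseGridOn(f, g), m, 300)
    for (d in seq(0, max(f1 + f2), length.out = 30))
      expect_gte(volumeAtDose(sumC, d) - volumeAtDose(comp, d), -1e-9)
  }
})
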