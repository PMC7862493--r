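## shared fixtures and independent oracles for the test suite

tinyGrid <- function(shape = c(12, 12, 12), spacing = c(0.2, 0.2, 0.3)) {
  gridSpec(shape, spacing)
}

## coarse desk-scale grid for cohort-level tests
coarseGrid <- function() gridSpec(c(48, 48, 24), c(0.4, 0.4, 0.6))

randomMask <- function(grid, p = 0.2) {
  array(stats::runif(prod(gridShape(grid))) < p, gridShape(grid))
}

doseGridOn <- function(values, grid, label = "test") {
  new("DoseGrid", grid = grid, values = array(values, gridShape(grid)),
      label = label)
}

## brute-force cumulative "at least" DVH oracle
bruteDvhOrdinate <- function(v, thresholds) {
  vapply(thresholds, function(d) 100 * sum(v >= d) / length(v), numeric(1))
}

## All-pairs signed-distance oracle mirroring the EDT's coordinate
## arithmetic (positions i*h along each axis) so agreement is exact.
bruteSignedDistance <- function(mask, grid) {
  sp <- gridSpacing(grid)
  dims <- gridShape(grid)
  idx <- which(mask, arr.ind = TRUE)
  cidx <- which(!mask, arr.ind = TRUE)
  pos <- function(ind) cbind((ind[, 1] - 1) * sp[1], (ind[, 2] - 1) * sp[2],
                             (ind[, 3] - 1) * sp[3])
  pIn <- pos(idx)
  pOut <- pos(cidx)
  minDistTo <- function(p, set) {
    if (nrow(set) == 0) return(Inf)
    min(sqrt(((set[, 3] - p[3])^2 + ((set[, 2] - p[2])^2 +
              (set[, 1] - p[1])^2))))
  }
  out <- array(0, dim(mask))
  all <- which(array(TRUE, dim(mask)), arr.ind = TRUE)
  pAll <- pos(all)
  for (r in seq_len(nrow(all))) {
    i <- all[r, 1]; j <- all[r, 2]; k <- all[r, 3]
    if (mask[i, j, k]) {
      out[i, j, k] <- -minDistTo(pAll[r, ], pOut)
      if (!is.finite(out[i, j, k])) out[i, j, k] <- 0
    } else {
      out[i, j, k] <- minDistTo(pAll[r, ], pIn)
    }
  }
  out
}

## 6-connected surface voxels of a mask
surfaceVoxels <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- lapply(d, seq_len)
    dst <- src
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  nbAllIn <- shift(mask, 1, 1) & shift(mask, 1, -1) &
    shift(mask, 2, 1) & shift(mask, 2, -1) &
    shift(mask, 3, 1) & shift(mask, 3, -1)
  mask & !nbAllIn
}

## double-loop Nadaraya-Watson oracle
nwOracle <- function(X, Y, sigma, x) {
  n <- nrow(X)
  num <- numeric(ncol(Y))
  den <- 0
  for (i in seq_len(n)) {
    w <- exp(-sum((x - X[i, ])^2) / (2 * sigma^2))
    num <- num + w * Y[i, ]
    den <- den + w
  }
  num / den
}

## exact two-sided signed-rank p by full enumeration of all 2^n sign
## assignments (midranks for ties); p = 2 * min(P(W <= w), P(W >= w))
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(bits) {
    signs <- bitwAnd(bits, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  pLe <- mean(ws <= w + 1e-9)
  pGe <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pLe, pGe))
}

## a random strictly decreasing DVH-like curve on [0, dmax]
randomMonotoneCurve <- function(nPts = 30, dmax = 100) {
  a <- c(0, sort(stats::runif(nPts - 2, 0, dmax)), dmax)
  o <- c(100, sort(stats::runif(nPts - 2, 0, 100), decreasing = TRUE), 0)
  new("CumHist", kind = "DVH", abscissa = a, ordinate = o,
      structure = "rnd", sourceLabel = "rnd")
}

## build a PlanRecord from hand-made curves (for feature-contract tests)
syntheticRecord <- function(nAngles = 9, oarDoseMax = 1, patient = "p1") {
  mkDVH <- function(dmax, structure, label) {
    if (dmax <= 0)
      new("CumHist", kind = "DVH", abscissa = 0, ordinate = 100,
          structure = structure, sourceLabel = label)
    else
      new("CumHist", kind = "DVH", abscissa = c(0, dmax),
          ordinate = c(100, 0), structure = structure, sourceLabel = label)
  }
  mkDTH <- function(structure) {
    new("CumHist", kind = "DTH", abscissa = c(-1, 0, 2),
        ordinate = c(5, 30, 100), structure = structure,
        sourceLabel = "PTV_union")
  }
  str <- list(
    PTV70 = list(idvh = lapply(seq_len(nAngles),
                               function(i) mkDVH(1, "PTV70", "field")),
                 cpdvh = mkDVH(71, "PTV70", "CONFORMAL_PLAN"),
                 clinical = mkDVH(74, "PTV70", "CLINICAL")),
    oar1 = list(idvh = lapply(seq_len(nAngles),
                              function(i) mkDVH(oarDoseMax, "oar1", "field")),
                cpdvh = mkDVH(40, "oar1", "CONFORMAL_PLAN"),
                clinical = mkDVH(35, "oar1", "CLINICAL"),
                dth = mkDTH("oar1"))
  )
  new("PlanRecord", patientId = patient, site = "HN", curves = str,
      ptvNames = "PTV70", oarNames = "oar1",
      gantryAnglesDeg = seq(0, by = 40, length.out = nAngles),
      meta = list(fieldMaxDose = 1.2, cpdvhPtvMaxDose = 71,
                  clinicalPtvMaxDose = 74, prescriptionGy = 70))
}

curveOn <- function(absc, ord) {
  new("CumHist", kind = "DVH", abscissa = absc, ordinate = as.numeric(ord),
      structure = "sampled", sourceLabel = "sampled")
}
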