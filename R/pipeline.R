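#' @include AllClasses.R accessors.R dose.R histograms.R features.R grnn.R evaluation.R
NULL

#' Compute one patient's full curve bundle
#'
#' Runs the dose engine for one phantom (nine uniform-intensity fields, the
#' equal-weight conformal plan and the seeded pseudo-clinical plan) and
#' reduces everything to curves: per structure the nine individual-field
#' DVHs in the beam-set angle order, the conformal-plan DVH and the
#' clinical DVH, plus the signed DTH (against the highest-dose PTV) for
#' OARs. Scalar dose maxima needed later for cohort normalization are kept
#' in the record metadata; the dose grids themselves are discarded.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param beams a \code{\link{beamSet}}.
#' @param prescriptionGy prescription of the highest-dose PTV (Gy).
#' @param clinSeed seed for the pseudo-clinical plan.
#' @param params pseudo-clinical \code{\link{sparingParams}}.
#' @param nBins internal histogram resolution.
#' @return a \linkS4class{PlanRecord}.
#' @export
buildPlanRecord <- function(phantom, beams, prescriptionGy,
                            clinSeed = 0, params = sparingParams(),
                            nBins = 1000L) {
  fields <- lapply(beams@gantryAnglesDeg,
                   function(a) fieldDose(phantom, a, beams))
  conf <- conformalPlan(phantom, beams, prescriptionGy, fields = fields)
  clin <- pseudoClinicalDose(phantom, beams, prescriptionGy, params,
                             seed = clinSeed, conformal = conf)

  grid <- phantom@grid
  ptvUnion <- Reduce(`|`, lapply(ptvNames(phantom),
                                 function(p) structureMask(phantom, p)))
  body <- structureMask(phantom, "body")

  ## DTH against the union of the nested PTVs (equals the outermost PTV):
  ## the distance that drives achievable OAR sparing
  sdist <- signedDistance(ptvUnion, grid)
  strNames <- c(ptvNames(phantom), oarNames(phantom))
  curves <- lapply(strNames, function(nm) {
    m <- structureMask(phantom, nm)
    entry <- list(
      idvh = lapply(fields, function(f) computeDVH(f, m, nBins, nm)),
      cpdvh = computeDVH(conf, m, nBins, nm),
      clinical = computeDVH(clin, m, nBins, nm)
    )
    if (nm %in% oarNames(phantom)) {
      sd <- sdist[m]
      lo <- min(sd); hi <- max(sd)
      entry$dth <- if (hi - lo < .Machine$double.eps)
        new("CumHist", kind = "DTH", abscissa = hi, ordinate = 100,
            structure = nm, sourceLabel = "PTV_union")
      else {
        r <- seq(lo, hi, length.out = nBins)
        ord <- 100 * findInterval(r, sort(sd)) / length(sd)
        ord[length(ord)] <- 100
        new("CumHist", kind = "DTH", abscissa = r, ordinate = ord,
            structure = nm, sourceLabel = "PTV_union")
      }
    }
    entry
  })
  names(curves) <- strNames

  meta <- list(
    fieldMaxDose = max(vapply(fields, function(f) max(f@values[body]),
                              numeric(1))),
    cpdvhPtvMaxDose = max(conf@values[ptvUnion]),
    clinicalPtvMaxDose = max(clin@values[ptvUnion]),
    prescriptionGy = prescriptionGy
  )
  new("PlanRecord", patientId = patientId(phantom), site = site(phantom),
      curves = curves, ptvNames = ptvNames(phantom),
      oarNames = oarNames(phantom),
      gantryAnglesDeg = beams@gantryAnglesDeg, meta = meta)
}

#' Split a cohort into train and test patients
#'
#' Seeded uniform sampling without replacement for the test set; the
#' remainder trains. The two index sets are always disjoint and cover the
#' cohort.
#'
#' @param patientIds character vector of patient ids.
#' @param nTest number of test patients, < length(patientIds).
#' @param seed split seed.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
splitCohort <- function(patientIds, nTest, seed = 1) {
  n <- length(patientIds)
  if (nTest >= n) stop("'nTest' must be smaller than the cohort size")
  test <- withSeed(seed, function() sort(sample.int(n, nTest)))
  list(train = patientIds[-test], test = patientIds[test])
}

#' Configure an end-to-end run
#'
#' @param site \code{"HN"} or \code{"PELVIS"}.
#' @param nTrain,nTest split sizes; defaults are 70/20 for HN and 45/15
#'   for PELVIS.
#' @param methods feature methods to train.
#' @param seed master seed; cohort generation, the per-patient
#'   pseudo-clinical noise and the train/test split all derive named
#'   substreams from it.
#' @param grid the shared voxel grid.
#' @param outDir output directory (created), or \code{NULL} to keep
#'   results in memory only.
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(site = c("HN", "PELVIS"), nTrain = NULL, nTest = NULL,
                      methods = c("IDVHS", "DTH_CPDVH"), seed = 1,
                      grid = gridSpec(), outDir = NULL) {
  site <- match.arg(site)
  if (is.null(nTrain)) nTrain <- if (site == "HN") 70L else 45L
  if (is.null(nTest)) nTest <- if (site == "HN") 20L else 15L
  new("RunConfig", site = site, nTrain = as.integer(nTrain),
      nTest = as.integer(nTest), methods = methods, seed = as.numeric(seed),
      grid = grid, outDir = if (is.null(outDir)) NA_character_ else outDir)
}

## assemble the (X, Y) training matrices for one structure type and method
assembleXY <- function(records, type, method, norms) {
  rows <- list()
  for (r in records) {
    strs <- c(r@ptvNames, r@oarNames)
    for (nm in strs[structureType(strs) == type]) {
      if (method == "DTH_CPDVH" && nm %in% r@ptvNames) next
      rows[[length(rows) + 1L]] <- list(
        ## clipping warnings are expected: an OAR's conformal dose may
        ## exceed the cohort's PTV normalization maximum
        x = suppressWarnings(buildFeatures(r, nm, method, norms)),
        y = buildTarget(r, nm, norms),
        patient = r@patientId, structure = nm)
    }
  }
  if (length(rows) == 0) return(NULL)
  list(X = do.call(rbind, lapply(rows, `[[`, "x")),
       Y = do.call(rbind, lapply(rows, `[[`, "y")),
       patient = vapply(rows, `[[`, character(1), "patient"),
       structure = vapply(rows, `[[`, character(1), "structure"))
}

#' Run the full prediction pipeline
#'
#' Generates the synthetic cohort, computes per-patient doses and curves,
#' splits into training and test patients, fits the normalization constants
#' on the training patients only, trains one GRNN per structure type and
#' feature method (OARs with both methods, PTVs with IDVHs only), predicts
#' the test patients' clinical DVHs, and evaluates them (per-curve R^2 and
#' MAE, dose-volume endpoints, uniformity index and paired Wilcoxon
#' comparisons). Re-running with the same configuration reproduces the
#' results exactly.
#'
#' @param config a \code{\link{runConfig}}.
#' @param beams optional \code{\link{beamSet}} override.
#' @param params pseudo-clinical \code{\link{sparingParams}}.
#' @param cohort optional precomputed list of phantoms (bypasses
#'   generation; its length must be \code{nTrain + nTest}).
#' @param verbose print per-stage progress.
#' @return list with elements \code{records}, \code{split}, \code{norms},
#'   \code{models}, \code{predictions} (per-curve scores and endpoints) and
#'   \code{report} (comparison tables); written to \code{outDir} when
#'   configured.
#' @export
runPipeline <- function(config, beams = NULL, params = sparingParams(),
                        cohort = NULL, verbose = FALSE) {
  validObject(config)
  n <- config@nTrain + config@nTest
  say <- function(...) if (verbose) message(sprintf(...))

  say("[1/6] generating %d %s phantoms", n, config@site)
  if (is.null(cohort)) {
    ccfg <- cohortConfig(config@site, nPatients = n,
                         masterSeed = config@seed, grid = config@grid)
    cohort <- generateCohort(ccfg)
  } else if (length(cohort) != n)
    stop("precomputed cohort size does not match nTrain + nTest")
  if (is.null(beams)) beams <- beamSet(config@site)
  presc <- if (config@site == "HN") 70 else 50

  say("[2/6] dose engine + curves")
  records <- lapply(seq_along(cohort), function(i) {
    say("  patient %d/%d", i, n)
    buildPlanRecord(cohort[[i]], beams, presc,
                    clinSeed = patientSeed(config@seed, 100000 + i),
                    params = params)
  })
  ids <- vapply(records, patientId, character(1))
  names(records) <- ids

  say("[3/6] train/test split")
  split <- splitCohort(ids, config@nTest,
                       seed = patientSeed(config@seed, 999983))
  trainRec <- records[split$train]
  testRec <- records[split$test]

  say("[4/6] normalization constants (training patients only)")
  norms <- fitNormConstants(trainRec)
  if (any(split$test %in% norms@patients))
    stop("internal error: test patients leaked into normalization constants")

  say("[5/6] GRNN training")
  allStr <- c(records[[1]]@ptvNames, records[[1]]@oarNames)
  types <- unique(structureType(allStr))
  oarTypes <- unique(structureType(records[[1]]@oarNames))
  models <- list()
  for (type in types) {
    for (method in config@methods) {
      if (method == "DTH_CPDVH" && !type %in% oarTypes) next
      xy <- assembleXY(trainRec, type, method, norms)
      if (is.null(xy)) next
      models[[paste(type, method, sep = ".")]] <-
        grnnTrain(xy$X, xy$Y, method = method, structureType = type,
                  normsRef = norms@fittedOn)
    }
  }

  say("[6/6] prediction + evaluation")
  scoreRows <- list()
  metricRows <- list()
  for (r in testRec) {
    for (nm in c(r@ptvNames, r@oarNames)) {
      type <- structureType(nm)
      truth <- suppressWarnings(buildTarget(r, nm, norms))
      truthCurve <- curveFromSamples(truth, norms@maxClinicalPtvDose)
      tm <- suppressWarnings(doseMetrics(truthCurve))
      metricRows[[length(metricRows) + 1L]] <- cbind(
        data.frame(patient = r@patientId, structure = nm, type = type,
                   source = "TPS", stringsAsFactors = FALSE),
        as.data.frame(unclass(tm)))
      for (method in config@methods) {
        key <- paste(type, method, sep = ".")
        if (is.null(models[[key]])) next
        feats <- suppressWarnings(buildFeatures(r, nm, method, norms))
        pred <- postprocessCurve(predict(models[[key]], feats))
        predCurve <- curveFromSamples(pred, norms@maxClinicalPtvDose)
        pm <- suppressWarnings(doseMetrics(predCurve))
        scoreRows[[length(scoreRows) + 1L]] <- data.frame(
          patient = r@patientId, structure = nm, type = type,
          method = method, r_squared = rSquared(truth, pred),
          mae_pct = curveMAE(truth, pred), stringsAsFactors = FALSE)
        metricRows[[length(metricRows) + 1L]] <- cbind(
          data.frame(patient = r@patientId, structure = nm, type = type,
                     source = method, stringsAsFactors = FALSE),
          as.data.frame(unclass(pm)))
      }
    }
  }
  scores <- do.call(rbind, scoreRows)
  metrics <- do.call(rbind, metricRows)
  report <- assembleReport(scores, metrics, records[[1]]@ptvNames,
                           config@methods)

  out <- list(config = config, records = records, split = split,
              norms = norms, models = models,
              predictions = list(scores = scores, metrics = metrics),
              report = report)
  if (!is.na(config@outDir)) writeRunOutputs(out, config@outDir)
  out
}

## rebuild a Gy-axis CumHist from 50 normalized-axis samples
curveFromSamples <- function(values, axisMaxGy) {
  new("CumHist", kind = "DVH",
      abscissa = seq(0, 1, length.out = length(values)) * axisMaxGy,
      ordinate = as.numeric(values), structure = "sampled",
      sourceLabel = "sampled")
}

## Tables in the style of knowledge-based-planning reports: per-OAR R^2 and
## MAE per method (with a between-method paired test when both methods ran),
## per-OAR endpoint differences from the TPS arm, and PTV coverage.
assembleReport <- function(scores, metrics, ptvs, methods) {
  out <- list()
  oarScores <- scores[!scores$structure %in% ptvs, , drop = FALSE]
  if (nrow(oarScores) && length(methods) == 2) {
    long <- merge(
      oarScores[oarScores$method == methods[1],
                c("patient", "structure", "type", "r_squared", "mae_pct")],
      oarScores[oarScores$method == methods[2],
                c("patient", "structure", "r_squared", "mae_pct")],
      by = c("patient", "structure"), suffixes = c("_a", "_b"))
    sc <- rbind(
      data.frame(structure = long$type, parameter = "r_squared",
                 patient = paste(long$patient, long$structure),
                 a = long$r_squared_a, b = long$r_squared_b),
      data.frame(structure = long$type, parameter = "mae_pct",
                 patient = paste(long$patient, long$structure),
                 a = long$mae_pct_a, b = long$mae_pct_b))
    out$oar_accuracy <- comparisonReport(sc, labelA = methods[1],
                                         labelB = methods[2])
  } else if (nrow(oarScores)) {
    agg <- stats::aggregate(cbind(r_squared, mae_pct) ~ type + method,
                            oarScores, function(x) c(mean(x), stats::sd(x)))
    out$oar_accuracy <- do.call(data.frame, agg)
  }

  tps <- metrics[metrics$source == "TPS", , drop = FALSE]
  oarParams <- c(d0 = "d0", v30 = "v30", v40 = "v40")
  rows <- list()
  for (method in methods) {
    mm <- metrics[metrics$source == method, , drop = FALSE]
    mg <- merge(tps, mm, by = c("patient", "structure", "type"),
                suffixes = c("_tps", "_pred"))
    mg <- mg[!mg$structure %in% ptvs, , drop = FALSE]
    for (p in names(oarParams)) {
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, type = mg$type, patient = mg$patient,
        structure = mg$structure, parameter = p,
        tps = mg[[paste0(p, "_tps")]],
        pred = mg[[paste0(p, "_pred")]],
        abs_diff = absDiff(mg[[paste0(p, "_pred")]],
                           mg[[paste0(p, "_tps")]]))
    }
  }
  if (length(rows)) {
    longDiff <- do.call(rbind, rows)
    out$oar_endpoint_diff <- stats::aggregate(
      abs_diff ~ method + type + parameter, longDiff,
      function(x) c(mean = mean(x), sd = stats::sd(x)))
    out$oar_endpoint_diff <- do.call(data.frame, out$oar_endpoint_diff)
  }

  if ("IDVHS" %in% methods) {
    mm <- metrics[metrics$source == "IDVHS" & metrics$structure %in% ptvs, ,
                  drop = FALSE]
    tt <- tps[tps$structure %in% ptvs, , drop = FALSE]
    mg <- merge(tt, mm, by = c("patient", "structure", "type"),
                suffixes = c("_tps", "_pred"))
    if (nrow(mg)) {
      ptvRows <- list()
      for (p in c("d98", "d95", "d1", "ui")) {
        ptvRows[[p]] <- data.frame(
          structure = mg$structure, parameter = p, patient = mg$patient,
          a = mg[[paste0(p, "_tps")]], b = mg[[paste0(p, "_pred")]],
          diff_pct = pctDiff(mg[[paste0(p, "_pred")]],
                             mg[[paste0(p, "_tps")]]))
      }
      long <- do.call(rbind, ptvRows)
      cmp <- comparisonReport(long[, c("structure", "parameter", "patient",
                                       "a", "b")],
                              labelA = "TPS", labelB = "IDVHS")
      dpc <- stats::aggregate(diff_pct ~ structure + parameter, long,
                              function(x) c(mean = mean(x),
                                            sd = stats::sd(x)))
      dpc <- do.call(data.frame, dpc)
      out$ptv_coverage <- merge(cmp, dpc,
                                by = c("structure", "parameter"))
    }
  }
  out
}
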