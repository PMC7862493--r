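#' @include AllClasses.R accessors.R histograms.R
NULL

#' Determination coefficient between two sampled DVH curves
#'
#' \deqn{R^2 = 1 - \sum_i (V_{i,TPS} - V_{i,pred})^2 /
#'             \sum_i (V_{i,TPS} - \bar V_{TPS})^2}
#' over the 50 sampled volume values. May be negative; equals 1 exactly
#' when the curves agree at every sample. Undefined (an error) when the
#' reference curve is constant.
#'
#' @param vTps,vPred equal-length numeric curves (volume %), reference
#'   first.
#' @return scalar R squared.
#' @export
rSquared <- function(vTps, vPred) {
  if (length(vTps) != length(vPred))
    stop("curve lengths differ")
  denom <- sum((vTps - mean(vTps))^2)
  if (denom == 0)
    stop("R^2 is undefined for a constant reference curve")
  1 - sum((vTps - vPred)^2) / denom
}

#' Mean absolute error between two sampled DVH curves
#'
#' Mean absolute difference of the sampled volume values, in volume
#' percentage points.
#'
#' @inheritParams rSquared
#' @return scalar MAE (\%).
#' @export
curveMAE <- function(vTps, vPred) {
  if (length(vTps) != length(vPred))
    stop("curve lengths differ")
  mean(abs(vTps - vPred))
}

#' Dose-volume endpoints of a DVH
#'
#' Extracts D98, D95, D5, D1 and D0 (Gy), V30, V40, V50 and V60 (%), and
#' the uniformity index UI = D5 / D95 (infinite when D95 = 0).
#'
#' @param curve a DVH \linkS4class{CumHist} on a dose axis in Gy.
#' @return named list of class \code{"doseMetrics"}.
#' @export
doseMetrics <- function(curve) {
  if (curve@kind != "DVH") stop("dose metrics require a DVH curve")
  d <- function(y) doseAtVolume(curve, y)
  v <- function(x) volumeAtDose(curve, x)
  d95 <- d(95)
  d5 <- d(5)
  out <- list(d98 = d(98), d95 = d95, d5 = d5, d1 = d(1), d0 = d(0),
              v30 = v(30), v40 = v(40), v50 = v(50), v60 = v(60),
              ui = if (d95 > 0) d5 / d95 else Inf)
  class(out) <- "doseMetrics"
  out
}

#' @export
print.doseMetrics <- function(x, ...) {
  cat(sprintf("D98 %.2f  D95 %.2f  D5 %.2f  D1 %.2f  D0 %.2f Gy | ",
              x$d98, x$d95, x$d5, x$d1, x$d0))
  cat(sprintf("V30 %.1f  V40 %.1f  V50 %.1f  V60 %.1f %% | UI %.3f\n",
              x$v30, x$v40, x$v50, x$v60, x$ui))
  invisible(x)
}

## Plan optimization constraint catalogue (RTOG-style limits per site).
## type "le" compares value <= bound (inclusive), "ge" value >= bound.
constraintRules <- function() {
  rbind(
    data.frame(site = "HN", structure = "PTV70", parameter = "d0",
               bound = 75, type = "le"),
    data.frame(site = "HN", structure = "brainstem", parameter = "d0",
               bound = 60, type = "le"),
    data.frame(site = "HN", structure = "cord", parameter = "d0",
               bound = 50, type = "le"),
    data.frame(site = "HN", structure = "spinal_cord", parameter = "d0",
               bound = 50, type = "le"),
    data.frame(site = "HN", structure = "chiasm", parameter = "d0",
               bound = 60, type = "le"),
    data.frame(site = "HN", structure = "lens", parameter = "d0",
               bound = 10, type = "le"),
    data.frame(site = "HN", structure = "optic_nerve", parameter = "d0",
               bound = 60, type = "le"),
    data.frame(site = "HN", structure = "parotid", parameter = "v30",
               bound = 50, type = "le"),
    data.frame(site = "HN", structure = "temporal_lobe", parameter = "d0",
               bound = 72, type = "le"),
    data.frame(site = "PELVIS", structure = "PTV50", parameter = "d0",
               bound = 55, type = "le"),
    data.frame(site = "PELVIS", structure = "bladder", parameter = "v50",
               bound = 50, type = "le"),
    data.frame(site = "PELVIS", structure = "bladder", parameter = "v60",
               bound = 20, type = "le"),
    data.frame(site = "PELVIS", structure = "colon", parameter = "d0",
               bound = 50, type = "le"),
    data.frame(site = "PELVIS", structure = "bowel", parameter = "d0",
               bound = 50, type = "le"),
    data.frame(site = "PELVIS", structure = "bowel", parameter = "v50",
               bound = 5, type = "le"),
    data.frame(site = "PELVIS", structure = "femoral_head", parameter = "v50",
               bound = 5, type = "le")
  )
}

## strip laterality suffixes so parotid_L and parotid_R share one rule set
structureType <- function(name) sub("_(L|R)$", "", name)

#' Check plan-quality constraints for one structure
#'
#' Evaluates the site's dose optimization constraints (e.g. brainstem
#' D0 <= 60 Gy, parotid V30 <= 50\%, PTV70 D0 <= 75 Gy; bladder V50 <= 50\%
#' and V60 <= 20\%, femoral head V50 <= 5\%) against extracted dose
#' metrics. Bounds are inclusive. Structures without catalogued rules give
#' an empty result with a warning.
#'
#' @param metrics a \code{\link{doseMetrics}} result.
#' @param site \code{"HN"} or \code{"PELVIS"}.
#' @param structure structure name (laterality suffixes \code{_L}/\code{_R}
#'   are ignored for rule lookup).
#' @return data.frame with one row per applicable rule: structure,
#'   parameter, value, bound, type and pass.
#' @export
checkConstraints <- function(metrics, site, structure) {
  rules <- constraintRules()
  rules <- rules[rules$site == site &
                 rules$structure == structureType(structure), , drop = FALSE]
  if (nrow(rules) == 0) {
    warning("no constraint rules for structure '", structure,
            "' at site ", site)
    return(data.frame(structure = character(), parameter = character(),
                      value = numeric(), bound = numeric(),
                      type = character(), pass = logical()))
  }
  value <- vapply(rules$parameter, function(p) metrics[[p]], numeric(1))
  pass <- ifelse(rules$type == "le", value <= rules$bound,
                 value >= rules$bound)
  data.frame(structure = structure, parameter = rules$parameter,
             value = value, bound = rules$bound, type = rules$type,
             pass = pass, row.names = NULL)
}

## exact two-sided signed-rank p by convolution over rank contributions:
## the null distribution of W+ = sum of ranks of positive differences over
## all 2^n equiprobable sign assignments (midranks doubled to stay integer)
exactSignedRankP <- function(d) {
  r <- rank(abs(d))
  r2 <- as.integer(round(2 * r)) # doubled midranks are integers
  maxW <- sum(r2)
  dist <- numeric(maxW + 1)
  dist[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), dist[seq_len(maxW + 1 - ri)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w <- sum(r2[d > 0])
  pLe <- sum(dist[seq_len(w + 1)])
  pGe <- sum(dist[seq(w + 1, maxW + 1)])
  min(1, 2 * min(pLe, pGe))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank p-value for paired samples. Zero differences are
#' dropped; if every difference is zero the p-value is 1 with a warning.
#' The exact null distribution is enumerated (equivalently to all 2^n sign
#' assignments, with midranks for tied absolute differences) when the
#' number of nonzero differences is at most 25; otherwise, and whenever
#' \code{mode = "approx"}, the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b equal-length paired numeric vectors.
#' @param mode \code{"auto"} (exact when n <= 25), \code{"exact"} or
#'   \code{"approx"}.
#' @return two-sided p-value.
#' @export
wilcoxonSignedRank <- function(a, b, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  useExact <- switch(mode, exact = TRUE, approx = FALSE, auto = n <= 25L)
  if (useExact) {
    exactSignedRankP(d)
  } else {
    suppressWarnings(
      stats::wilcox.test(d, mu = 0, exact = FALSE, correct = TRUE)$p.value)
  }
}

summStat <- function(x) sprintf("%.3g +/- %.3g", mean(x), stats::sd(x))

#' Paired comparison report (per structure and parameter)
#'
#' Summarizes two paired arms the way knowledge-based-planning studies
#' tabulate them: per structure and parameter the mean and standard
#' deviation of each arm, the paired Wilcoxon signed-rank p-value and a
#' significance flag at p < 0.05. Inputs must be fully paired (same
#' patients in both arms).
#'
#' @param df data.frame with columns \code{structure}, \code{parameter},
#'   \code{patient}, \code{a} and \code{b} (one row per patient and
#'   endpoint; arm a is typically the reference/TPS arm).
#' @param labelA,labelB column-name labels for the two arms.
#' @return data.frame with one row per (structure, parameter).
#' @export
comparisonReport <- function(df, labelA = "a", labelB = "b") {
  need <- c("structure", "parameter", "patient", "a", "b")
  if (!all(need %in% names(df)))
    stop("input must have columns ", paste(need, collapse = ", "))
  if (anyNA(df$a) || anyNA(df$b)) {
    bad <- df[is.na(df$a) | is.na(df$b), ]
    stop("unpaired rows for: ",
         paste(unique(paste(bad$structure, bad$patient)), collapse = ", "))
  }
  groups <- split(df, list(df$structure, df$parameter), drop = TRUE)
  rows <- lapply(groups, function(g) {
    p <- wilcoxonSignedRank(g$a, g$b)
    data.frame(structure = g$structure[1], parameter = g$parameter[1],
               n = nrow(g),
               mean_a = mean(g$a), sd_a = stats::sd(g$a),
               mean_b = mean(g$b), sd_b = stats::sd(g$b),
               p_value = p, significant = p < 0.05, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "mean_a"] <- paste0("mean_", labelA)
  names(out)[names(out) == "sd_a"] <- paste0("sd_", labelA)
  names(out)[names(out) == "mean_b"] <- paste0("mean_", labelB)
  names(out)[names(out) == "sd_b"] <- paste0("sd_", labelB)
  rownames(out) <- NULL
  out[order(out$structure, out$parameter), ]
}

#' Absolute and percentage endpoint differences
#'
#' Helpers matching the usual report conventions: \code{absDiff} is
#' \code{|P_method - P_TPS|} and \code{pctDiff} is
#' \code{|P_method - P_TPS| / P_TPS * 100}.
#'
#' @param pMethod,pTps predicted and reference endpoint values.
#' @return numeric vector.
#' @export
absDiff <- function(pMethod, pTps) abs(pMethod - pTps)

#' @rdname absDiff
#' @export
pctDiff <- function(pMethod, pTps) abs(pMethod - pTps) / pTps * 100
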