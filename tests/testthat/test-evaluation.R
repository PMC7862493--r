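test_that("determination coefficient closed forms", {
  v <- c(0, 10, 20, 30, runif(46, 0, 100))
  expect_equal(rSquared(v, v), 1)
  expect_equal(rSquared(v, rep(mean(v), 50)), 0)
  ## constant offset: R^2 = 1 - 50 c^2 / SS_tot, by direct arithmetic
  off <- v + 5
  expect_equal(rSquared(v, off), 1 - 50 * 25 / sum((v - mean(v))^2))
  expect_error(rSquared(rep(3, 50), runif(50)), "constant")
  expect_error(rSquared(1:10, 1:9), "lengths")
})

test_that("curve MAE closed forms and metric properties", {
  v <- runif(50, 0, 100)
  expect_equal(curveMAE(v, v), 0)
  expect_equal(curveMAE(v, v + 2), 2)
  w <- runif(50, 0, 100)
  expect_equal(curveMAE(v, w), sum(abs(v - w)) / 50, tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:20) {
    a <- runif(50); b <- runif(50); c <- runif(50)
    expect_equal(curveMAE(a, b), curveMAE(b, a))
    expect_lte(curveMAE(a, c), curveMAE(a, b) + curveMAE(b, c) + 1e-12)
  }
})

test_that("dose metrics of uniform and triangular curves", {
  g <- tinyGrid(c(8, 8, 8))
  uni <- computeDVH(doseGridOn(70, g), array(TRUE, gridShape(g)), 100)
  m <- suppressWarnings(doseMetrics(uni))
  expect_equal(m$d98, 70); expect_equal(m$d95, 70); expect_equal(m$d5, 70)
  expect_equal(m$ui, 1)
  expect_equal(m$v30, 100); expect_equal(m$v40, 100)

  tri <- curveOn(c(0, 50, 100), c(100, 50, 0))
  mt <- doseMetrics(tri)
  expect_equal(mt$v30, 70)
  expect_equal(mt$v40, 60)
  expect_equal(mt$d95, 5)
  expect_equal(mt$d5, 95)
  expect_equal(mt$ui, 19)
})

test_that("endpoint ordering and UI >= 1 hold on random monotone curves", {
  set.seed(29)
  for (rep in 1:1000) {
    curve <- randomMonotoneCurve(12)
    m <- doseMetrics(curve)
    expect_true(m$d0 >= m$d1 && m$d1 >= m$d5 && m$d5 >= m$d95 &&
                m$d95 >= m$d98)
    expect_gte(m$ui, 1)
  }
})

test_that("the constraint catalogue reproduces the protocol examples", {
  mk <- function(...) structure(list(...), class = "doseMetrics")
  bs <- checkConstraints(mk(d0 = 59), "HN", "brainstem")
  expect_true(bs$pass[bs$parameter == "d0"])
  pa <- checkConstraints(mk(d0 = 30, v30 = 50.0), "HN", "parotid")
  expect_true(pa$pass[pa$parameter == "v30"]) # inclusive bound at equality
  pt <- checkConstraints(mk(d0 = 76), "HN", "PTV70")
  expect_false(pt$pass[pt$parameter == "d0"])
  ## laterality suffixes share the organ rule set
  pl <- checkConstraints(mk(d0 = 30, v30 = 61), "HN", "parotid_L")
  expect_false(pl$pass[pl$parameter == "v30"])
  expect_warning(res <- checkConstraints(mk(d0 = 1), "HN", "mystery"),
                 "no constraint rules")
  expect_equal(nrow(res), 0)
})

test_that("exact signed-rank p-values match full enumeration", {
  ## all-positive n = 5: p = 2/32
  expect_equal(wilcoxonSignedRank(6:10, 1:5, mode = "exact"), 0.0625)
  set.seed(31)
  for (n in 5:12) {
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(wilcoxonSignedRank(a, b, mode = "exact"),
                 enumSignedRankP(a - b), tolerance = 1e-12)
    ## with tied absolute differences (midranks)
    a2 <- round(rnorm(n) * 2) / 2; b2 <- round(rnorm(n) * 2) / 2
    if (any(a2 - b2 != 0))
      expect_equal(wilcoxonSignedRank(a2, b2, mode = "exact"),
                   enumSignedRankP(a2 - b2), tolerance = 1e-12)
  }
})

test_that("degenerate and approximate signed-rank behaviour", {
  a <- rnorm(8)
  expect_warning(p <- wilcoxonSignedRank(a, a), "zero")
  expect_equal(p, 1)
  ## exact and normal approximation agree to ~0.02 at n = 25
  set.seed(37)
  x <- rnorm(25); y <- rnorm(25, 0.3)
  pe <- wilcoxonSignedRank(x, y, mode = "exact")
  pa <- wilcoxonSignedRank(x, y, mode = "approx")
  expect_lt(abs(pe - pa), 0.02)
})

test_that("comparison reports summarize paired arms", {
  df <- data.frame(structure = rep(c("cord", "parotid"), each = 6),
                   parameter = "mae_pct",
                   patient = rep(sprintf("p%d", 1:6), 2),
                   a = c(1:6, 2:7), b = c(1:6, 3:8))
  rep1 <- suppressWarnings(comparisonReport(df, "TPS", "pred"))
  cordRow <- rep1[rep1$structure == "cord", ]
  expect_equal(cordRow$mean_TPS, cordRow$mean_pred)
  expect_equal(suppressWarnings(
    comparisonReport(df[df$structure == "cord", ])$p_value), 1)
  parRow <- rep1[rep1$structure == "parotid", ]
  expect_equal(parRow$mean_pred - parRow$mean_TPS, 1)
  expect_true(all(rep1$n == 6))

  expect_equal(absDiff(52, 50), 2)
  expect_equal(pctDiff(49, 50), 2)
})
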