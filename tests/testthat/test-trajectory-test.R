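test_that("column permutation preserves marginals and determinism", {
  set.seed(41)
  x <- matrix(rnorm(60), 20, 3)
  p1 <- permuteMatrix(x, seed = 9)
  p2 <- permuteMatrix(x, seed = 9)
  expect_identical(p1, p2)
  for (j in 1:3) expect_equal(sort(unname(p1[, j])), sort(x[, j]))
  expect_false(identical(p1, x))
  # constants are unchanged by permutation
  const <- matrix(5, 10, 2)
  expect_equal(unname(permuteMatrix(const, 1)), unname(const))
})

test_that("single-feature matrices give permutation-invariant statistics", {
  set.seed(42)
  x <- matrix(sort(rnorm(40)), 40, 1)
  xp <- permuteMatrix(x, seed = 3)
  a <- statTriple(buildMST(kmeansCenters(x, 5, seed = 1)))
  b <- statTriple(buildMST(kmeansCenters(xp, 5, seed = 1)))
  expect_identical(a, b)
})

test_that("add-one empirical p-values match hand counts", {
  expect_equal(pValue(1, rep(5, 99), tail = "lower"), 1 / 100)
  expect_equal(pValue(5, rep(5, 50), tail = "lower"), 1)
  expect_equal(pValue(5, rep(5, 50), tail = "upper"), 1)
  expect_equal(pValue(4, c(2, 3, 4, 5, 6), tail = "upper"), 2 / 3)
  expect_equal(pValue(4, c(2, 3, 4, 5, 6), tail = "lower"), 4 / 6)
})

test_that("p-values are monotone in the observed value", {
  set.seed(43)
  for (rep in 1:20) {
    null <- sample(0:20, 99, replace = TRUE)
    obs <- 0:20
    up <- vapply(obs, pValue, numeric(1), null = null, tail = "upper")
    lo <- vapply(obs, pValue, numeric(1), null = null, tail = "lower")
    expect_true(all(diff(up) <= 0))
    expect_true(all(diff(lo) >= 0))
  }
})

test_that("null distributions are reproducible and respect bounds", {
  set.seed(44)
  x <- matrix(rnorm(120), 60, 2)
  n1 <- nullDistribution(x, k = 10, statistic = "D1", B = 50, seed = 6)
  n2 <- nullDistribution(x, k = 10, statistic = "D1", B = 50, seed = 6)
  expect_identical(nullSamples(n1), nullSamples(n2))
  expect_length(nullSamples(n1), 50)
  expect_true(all(nullSamples(n1) >= 2 & nullSamples(n1) <= 9))
  # the default tail for D1 is the lower tail
  expect_equal(pValue(2, n1), pValue(2, nullSamples(n1), "lower"))
})

test_that("an exchangeable observed value has a well-spread null rank", {
  # on i.i.d. data the observed statistic is itself a draw from the null,
  # so its add-one p-value should not pile up near 0
  set.seed(45)
  p <- replicate(30, {
    x <- matrix(rnorm(160), 80, 2)
    obs <- trajpresence:::.pipelineTriple(x, 8,
                                          trajpresence:::mixSeed(1, 8, 0, 2))
    nd <- trajpresence:::.nullTriples(x, 8, 19, 1)
    pValue(obs[["D1"]], nd[, "D1"], "lower")
  })
  expect_gt(mean(p), 0.3)
  expect_gt(length(unique(p)), 3)
})

test_that("the report covers the requested sweep and statistics only", {
  set.seed(46)
  x <- simulateTrajectory("none", nCells = 60, seed = 2)$coordinates
  rep1 <- testTrajectoryPresence(x, kMin = 5, kMax = 9, nPermutations = 19,
                                 seed = 3, statistics = "Lmax")
  pk <- pValues(rep1)
  expect_equal(unique(pk$statistic), "Lmax")
  expect_equal(pk$k, 5:9)
  expect_named(medianP(rep1), "Lmax")
  expect_true(all(pk$p_value > 0 & pk$p_value <= 1))
  expect_error(testTrajectoryPresence(x, kMin = 5, kMax = 60,
                                      nPermutations = 19),
               class = "trajpresenceConfigError")
})

test_that("even-length sweeps use the midpoint median", {
  set.seed(47)
  x <- simulateTrajectory("none", nCells = 60, seed = 5)$coordinates
  rep1 <- testTrajectoryPresence(x, kMin = 5, kMax = 8, nPermutations = 19,
                                 seed = 3)
  pk <- pValues(rep1)
  for (s in trajStatistics()) {
    v <- sort(pk$p_value[pk$statistic == s])
    expect_equal(medianP(rep1)[[s]], (v[2] + v[3]) / 2)
  }
})

test_that("reports are bit-reproducible and round-trip through TSV", {
  x <- simulateTrajectory("linear", nCells = 70, seed = 8)$coordinates
  r1 <- testTrajectoryPresence(x, kMin = 5, kMax = 8, nPermutations = 19,
                               seed = 11)
  r2 <- testTrajectoryPresence(x, kMin = 5, kMax = 8, nPermutations = 19,
                               seed = 11)
  expect_identical(pValues(r1), pValues(r2))
  expect_identical(medianP(r1), medianP(r2))

  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeReport(r1, f1)
  writeReport(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
  body <- read.delim(f1, comment.char = "#")
  expect_equal(names(body), c("statistic", "k", "observed", "p_value"))
  footer <- grep("^# median", readLines(f1), value = TRUE)
  expect_length(footer, 3)
})

test_that("PCA placement in the permutation scheme is switchable", {
  set.seed(48)
  coords <- simulateTrajectory("linear", nCells = 60, seed = 9)$coordinates
  wide <- liftToExpression(coords, nGenes = 20, seed = 9)
  r1 <- testTrajectoryPresence(wide, kMin = 5, kMax = 6,
                               nPermutations = 19, seed = 1)
  expect_equal(reportConfig(r1)@pcaDims, 2L)  # auto PCA for wide input
  r2 <- testTrajectoryPresence(wide, kMin = 5, kMax = 6,
                               nPermutations = 19, seed = 1,
                               permuteBeforePCA = TRUE)
  expect_equal(pValues(r2)$k, pValues(r1)$k)
  expect_true(all(pValues(r2)$p_value > 0 & pValues(r2)$p_value <= 1))
})

test_that("plotReport writes a figure and rejects empty input", {
  x <- simulateTrajectory("none", nCells = 60, seed = 2)$coordinates
  r <- testTrajectoryPresence(x, kMin = 5, kMax = 7, nPermutations = 19,
                              seed = 3)
  f <- withr::local_tempfile(fileext = ".pdf")
  plotReport(r, f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_error(plotReport(r, "out.svg"), "unsupported")
})
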