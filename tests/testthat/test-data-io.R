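test_that("CSV and MTX loads agree and enforce invariants", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "m.csv")
  writeLines(c(",g1,g2", "c1,0,0", "c2,1,0", "c3,2,0"), csv)
  x <- loadMatrix(csv)
  expect_equal(dim(x), c(3L, 2L))
  expect_equal(rownames(x), c("c1", "c2", "c3"))
  expect_equal(unname(x[, 1]), c(0, 1, 2))

  mtx <- file.path(dir, "m.mtx")
  writeMatrix(x, mtx)
  expect_true(all(file.exists(file.path(dir, c("m.rownames.txt",
                                               "m.colnames.txt")))))
  y <- loadMatrix(mtx)
  expect_equal(y, x)
})

test_that("CSV load -> write -> load round-trips bit-identically", {
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "r.csv")
  set.seed(31)
  x0 <- matrix(rnorm(30), 10, 3,
               dimnames = list(paste0("c", 1:10), paste0("g", 1:3)))
  writeMatrix(x0, csv)
  x1 <- loadMatrix(csv)
  expect_identical(unname(x1), unname(x0))
  csv2 <- file.path(dir, "r2.csv")
  writeMatrix(x1, csv2)
  expect_identical(loadMatrix(csv2), x1)
})

test_that("malformed cells raise errors naming the location", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.csv")
  writeLines(c(",g1,g2", "c1,0,NA", "c2,1,0", "c3,2,0"), bad)
  expect_error(loadMatrix(bad), "row 'c1', column 'g2'",
               class = "trajpresenceValueError")
  bad2 <- file.path(dir, "bad2.csv")
  writeLines(c(",g1,g2", "c1,0,x", "c2,1,0", "c3,2,0"), bad2)
  expect_error(loadMatrix(bad2), "non-numeric",
               class = "trajpresenceValueError")
  expect_error(loadMatrix(file.path(dir, "absent.csv")),
               class = "trajpresenceParseError")
  tiny <- file.path(dir, "tiny.csv")
  writeLines(c(",g1", "c1,0", "c2,1"), tiny)
  expect_error(loadMatrix(tiny), "at least 3")
})

test_that("PCA preserves geometry on low-rank data", {
  set.seed(32)
  # rank-2 data embedded in 5 dimensions via a random linear map
  z <- matrix(rnorm(80), 40, 2)
  x <- z %*% matrix(rnorm(10), 2, 5)
  y <- reducePCA(x, 2)
  expect_equal(unname(as.matrix(dist(y))), unname(as.matrix(dist(x))),
               tolerance = 1e-9)
})

test_that("full-rank PCA conserves total variance", {
  set.seed(33)
  x <- matrix(rnorm(200), 40, 5)
  y <- reducePCA(x, 5)
  expect_equal(sum(apply(y, 2, var)), sum(apply(scale(x, scale = FALSE),
                                                2, var)),
               tolerance = 1e-9)
  expect_true(all(diff(apply(y, 2, var)) <= 1e-9))
})

test_that("component variances match an explicit eigendecomposition", {
  set.seed(34)
  x <- matrix(rnorm(500), 50, 10)
  y <- reducePCA(x, 2)
  ev <- sort(eigen(cov(x), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(unname(apply(y, 2, var)), ev[1:2], tolerance = 1e-9)
})

test_that("PCA scores are row-shuffle equivariant", {
  set.seed(35)
  x <- matrix(rnorm(120), 30, 4)
  y <- reducePCA(x, 2)
  perm <- sample(30)
  y2 <- reducePCA(x[perm, ], 2)
  expect_equal(unname(y2), unname(y[perm, ]), tolerance = 1e-9)
})

test_that("configuration invariants are enforced", {
  expect_error(runConfig(kMin = 2), class = "trajpresenceConfigError")
  expect_error(runConfig(kMin = 10, kMax = 5),
               class = "trajpresenceConfigError")
  expect_error(runConfig(nPermutations = 10),
               class = "trajpresenceConfigError")
  expect_error(runConfig(statistics = c("D1", "bogus")),
               class = "trajpresenceConfigError")
  expect_error(reducePCA(matrix(rnorm(20), 10, 2), 3), "min")
  cfg <- runConfig(kMin = 5, kMax = 20, nPermutations = 99, seed = 4)
  expect_s4_class(cfg, "RunConfig")
})
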