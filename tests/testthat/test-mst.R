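test_that("trajectoryTree validates tree structure", {
  expect_s4_class(pathTree(5), "TrajectoryTree")
  # a cycle on 3 nodes plus an isolated node: right edge count, not a tree
  expect_error(trajectoryTree(cbind(c(1, 2, 3), c(2, 3, 1)), nNodes = 4),
               "cycle")
  expect_error(trajectoryTree(cbind(1, 2), nNodes = 4), "matrix")
  expect_error(trajectoryTree(cbind(c(1, 1), c(2, 2)), nNodes = 3))
})

test_that("geometry forces the expected MST on simple configurations", {
  # collinear, equally spaced points give the path
  tr <- buildMST(rbind(c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(treeEdges(tr), cbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(sum(edgeWeights(tr)), 2)

  # three unit spokes around the origin; any cross edge costs sqrt(2) or 2
  tr <- buildMST(rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)))
  expect_equal(treeEdges(tr), cbind(rep(1L, 3), c(2L, 3L, 4L)))
  expect_equal(edgeWeights(tr), rep(1, 3))
  expect_equal(unname(statTriple(tr)), c(3L, 0L, 2L))
})

test_that("duplicated centers are legal and produce zero-weight edges", {
  tr <- buildMST(rbind(c(0, 0), c(0, 0), c(1, 0), c(2, 0)))
  expect_equal(sort(edgeWeights(tr)), c(0, 1, 1))
  expect_error(buildMST(rbind(c(0, 0), c(NA, 1), c(1, 1))), "finite")
})

test_that("Prim total weight matches an independent Kruskal oracle", {
  set.seed(401)
  for (rep in 1:40) {
    pts <- matrix(runif(24), 12, 2)
    tr <- buildMST(pts)
    expect_equal(sum(edgeWeights(tr)), kruskalWeight(pts),
                 tolerance = 1e-9)
  }
})

test_that("MST weight is minimal among random spanning trees", {
  set.seed(402)
  pts <- matrix(runif(20), 10, 2)
  D <- as.matrix(dist(pts))
  mstW <- sum(edgeWeights(buildMST(pts)))
  for (rep in 1:100) {
    e <- prueferToEdges(sample.int(10, 8, replace = TRUE), 10)
    expect_gte(sum(D[e]), mstW - 1e-12)
  }
})

test_that("two-sweep longest path equals the all-pairs oracle", {
  skip_if_not_installed("igraph")
  set.seed(403)
  for (rep in 1:60) {
    k <- sample(4:30, 1)
    tr <- randomPrueferTree(k)
    expect_identical(longestPathLength(tr), as.integer(igraphDiameter(tr)))
  }
})

test_that("degree counts satisfy the tree identities", {
  set.seed(404)
  for (rep in 1:50) {
    k <- sample(3:35, 1)
    tr <- randomPrueferTree(k)
    deg <- tabulate(as.vector(treeEdges(tr)), nbins = k)
    expect_equal(sum(deg), 2L * (k - 1L))
    expect_equal(countDegreeOne(tr) + countDegreeTwo(tr) + sum(deg >= 3L),
                 k)
    s <- statTriple(tr)
    expect_true(s["D1"] >= 2 && s["D1"] <= k - 1)
    expect_true(s["D2"] >= 0 && s["D2"] <= k - 2)
    expect_true(s["Lmax"] >= 2 && s["Lmax"] <= k - 1)
    # the three path-graph characterizations coincide
    expect_equal(s[["D1"]] == 2L, s[["D2"]] == k - 2L)
    expect_equal(s[["D1"]] == 2L, s[["Lmax"]] == k - 1L)
  }
})

test_that("statistics are invariant under relabeling and rigid motions", {
  set.seed(405)
  pts <- matrix(rnorm(30), 15, 2)
  ref <- statTriple(buildMST(pts))
  theta <- 0.83
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  moved <- pts %*% rot + matrix(c(3, -7), 15, 2, byrow = TRUE)
  expect_equal(statTriple(buildMST(moved)), ref)
  perm <- sample(15)
  expect_equal(statTriple(buildMST(pts[perm, ])), ref)
})

test_that("trees serialize to a readable edge list", {
  tr <- exampleTree10()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeTree(tr, path)
  df <- read.delim(path)
  expect_equal(names(df), c("from", "to", "weight"))
  expect_equal(nrow(df), 9)
})
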