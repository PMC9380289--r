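#' Statistics computed by the trajectory-presence test
#'
#' `trajStatistics()` returns the names of the three tree-shape statistics:
#' `"D1"` (number of degree-one nodes), `"D2"` (number of degree-two nodes)
#' and `"Lmax"` (length in edges of a longest path). `trajTails()` returns
#' the tail of the one-sided permutation test associated with each: a
#' trajectory makes the MST path-like, which *lowers* D1 and *raises* D2 and
#' Lmax, so D1 is lower-tailed and D2/Lmax are upper-tailed.
#'
#' @return `trajStatistics()`: a character vector of statistic names.
#'   `trajTails()`: a named character vector mapping statistic to
#'   `"lower"` or `"upper"`.
#' @examples
#' trajStatistics()
#' trajTails()
#' @export
trajStatistics <- function() c("D1", "D2", "Lmax")

#' @rdname trajStatistics
#' @export
trajTails <- function() c(D1 = "lower", D2 = "upper", Lmax = "upper")

#' RunConfig: configuration of a trajectory-presence run
#'
#' Holds the tunable parameters of [testTrajectoryPresence()]: the cluster
#' range swept, the number of permutations, the master seed, the number of
#' principal components kept (if any) and the statistics requested.
#'
#' @slot kMin integer, smallest number of clusters (>= 3).
#' @slot kMax integer, largest number of clusters (must not exceed n - 1
#'   for the data it is applied to; checked at run time).
#' @slot nPermutations integer, permutation count B (>= 19, the smallest B
#'   for which the add-one empirical p-value can reach 0.05).
#' @slot seed integer master seed; every random draw in the pipeline is
#'   derived from it.
#' @slot pcaDims integer, number of principal components to reduce to
#'   before testing, or `NA` to use the matrix as supplied.
#' @slot statistics character, subset of `trajStatistics()`.
#' @seealso [runConfig()]
#' @export
setClass("RunConfig",
  representation(
    kMin = "integer",
    kMax = "integer",
    nPermutations = "integer",
    seed = "integer",
    pcaDims = "integer",
    statistics = "character"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@kMin) != 1L || is.na(object@kMin) || object@kMin < 3L)
    msg <- c(msg, "kMin must be a single integer >= 3")
  if (length(object@kMax) != 1L || is.na(object@kMax) ||
      object@kMax < object@kMin)
    msg <- c(msg, "kMax must be a single integer >= kMin")
  if (length(object@nPermutations) != 1L || is.na(object@nPermutations) ||
      object@nPermutations < 19L)
    msg <- c(msg, "nPermutations must be >= 19")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single non-missing integer")
  if (length(object@pcaDims) != 1L ||
      (!is.na(object@pcaDims) && object@pcaDims < 1L))
    msg <- c(msg, "pcaDims must be NA or a single integer >= 1")
  if (length(object@statistics) < 1L ||
      !all(object@statistics %in% trajStatistics()) ||
      anyDuplicated(object@statistics))
    msg <- c(msg, "statistics must be a non-empty subset of trajStatistics()")
  if (length(msg)) msg else TRUE
})

#' CenterSet: k-means cluster centers of a point cloud
#'
#' The centers become the nodes of the complete Euclidean graph on which the
#' minimum spanning tree is built. Every cluster is guaranteed non-empty, so
#' a `CenterSet` with parameter k always supplies exactly k MST nodes.
#'
#' @slot centers k x d numeric matrix of cluster centers.
#' @slot sizes integer vector of length k, points per cluster (all >= 1,
#'   summing to the number of observations).
#' @slot assignment integer vector of length n mapping each observation to
#'   its cluster.
#' @slot totss total within-cluster sum of squares of the kept restart.
#' @seealso [kmeansCenters()], [buildMST()]
#' @export
setClass("CenterSet",
  representation(
    centers = "matrix",
    sizes = "integer",
    assignment = "integer",
    totss = "numeric"
  )
)

setValidity("CenterSet", function(object) {
  msg <- character()
  k <- nrow(object@centers)
  if (!is.numeric(object@centers) || any(!is.finite(object@centers)))
    msg <- c(msg, "centers must be a finite numeric matrix")
  if (length(object@sizes) != k)
    msg <- c(msg, "sizes must have one entry per center")
  if (any(object@sizes < 1L))
    msg <- c(msg, "every cluster must be non-empty")
  if (length(object@assignment) != sum(object@sizes))
    msg <- c(msg, "assignment length must equal sum(sizes)")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > k))
    msg <- c(msg, "assignment indices out of range")
  if (length(msg)) msg else TRUE
})

#' TrajectoryTree: a minimum spanning tree on cluster centers
#'
#' A tree on nodes `1..nNodes` with exactly `nNodes - 1` undirected edges
#' carrying non-negative Euclidean weights. Validity enforces that the edge
#' set is connected and acyclic (i.e. an actual spanning tree), which the
#' tree-shape statistics rely on.
#'
#' @slot nNodes integer number of nodes (>= 2).
#' @slot edges (nNodes - 1) x 2 integer matrix of undirected edges, each row
#'   stored with the smaller node id first.
#' @slot weights numeric vector of edge lengths, one per edge, all >= 0.
#' @seealso [trajectoryTree()], [buildMST()], [statTriple()]
#' @export
setClass("TrajectoryTree",
  representation(
    nNodes = "integer",
    edges = "matrix",
    weights = "numeric"
  )
)

setValidity("TrajectoryTree", function(object) {
  k <- object@nNodes
  e <- object@edges
  if (length(k) != 1L || is.na(k) || k < 2L)
    return("nNodes must be a single integer >= 2")
  if (!is.matrix(e) || ncol(e) != 2L || nrow(e) != k - 1L)
    return("edges must be an (nNodes - 1) x 2 matrix")
  if (any(e < 1L) || any(e > k) || any(e[, 1L] == e[, 2L]))
    return("edge endpoints must be distinct node ids in 1..nNodes")
  if (length(object@weights) != nrow(e) || any(object@weights < 0))
    return("weights must be non-negative, one per edge")
  # connectivity by union-find; k-1 edges + connected => acyclic
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(e))) {
    a <- find(e[i, 1L]); b <- find(e[i, 2L])
    if (a == b) return("edge set contains a cycle")
    parent[a] <- b
  }
  TRUE
})

#' NullDistribution: permutation null of one tree statistic at one k
#'
#' @slot statistic one of `trajStatistics()`.
#' @slot k integer number of clusters the null was computed at.
#' @slot samples integer vector of B statistic values on permuted data.
#' @seealso [nullDistribution()], [pValue()]
#' @export
setClass("NullDistribution",
  representation(
    statistic = "character",
    k = "integer",
    samples = "integer"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  if (length(object@statistic) != 1L ||
      !object@statistic %in% trajStatistics())
    msg <- c(msg, "statistic must be one of trajStatistics()")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 3L)
    msg <- c(msg, "k must be a single integer >= 3")
  if (length(object@samples) < 1L || any(is.na(object@samples)))
    msg <- c(msg, "samples must be a non-empty integer vector")
  if (length(msg) == 0L) {
    lo <- switch(object@statistic, D1 = 2L, D2 = 0L, Lmax = 2L)
    hi <- switch(object@statistic,
                 D1 = object@k - 1L, D2 = object@k - 2L, Lmax = object@k - 1L)
    if (any(object@samples < lo) || any(object@samples > hi))
      msg <- c(msg, sprintf("samples outside the attainable range [%d, %d]",
                            lo, hi))
  }
  if (length(msg)) msg else TRUE
})

#' TrajectoryTestReport: result of the full trajectory-presence test
#'
#' @slot perK data.frame with columns `statistic`, `k`, `observed`,
#'   `p_value`: one row per (statistic, k) pair in the sweep.
#' @slot medians named numeric vector, the median p-value per statistic --
#'   the reported evidence level for trajectory presence.
#' @slot config the [RunConfig-class] the report was produced under.
#' @seealso [testTrajectoryPresence()], [pValues()], [medianP()]
#' @export
setClass("TrajectoryTestReport",
  representation(
    perK = "data.frame",
    medians = "numeric",
    config = "RunConfig"
  )
)

setValidity("TrajectoryTestReport", function(object) {
  msg <- character()
  need <- c("statistic", "k", "observed", "p_value")
  if (!all(need %in% names(object@perK)))
    msg <- c(msg, "perK must have columns statistic, k, observed, p_value")
  else {
    if (any(object@perK$p_value <= 0) || any(object@perK$p_value > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
    stats <- unique(object@perK$statistic)
    if (!all(stats %in% trajStatistics()))
      msg <- c(msg, "unknown statistic in perK")
    if (!identical(sort(names(object@medians)), sort(stats)))
      msg <- c(msg, "medians must be named by the statistics present in perK")
  }
  if (length(msg)) msg else TRUE
})
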