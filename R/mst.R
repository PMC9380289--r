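#' Construct a tree from an explicit edge list
#'
#' Mainly useful for worked examples and tests; pipelines obtain trees
#' from [buildMST()]. Edge weights default to 1 (the three tree-shape
#' statistics ignore weights entirely).
#'
#' @param edges a 2-column matrix or data.frame of node id pairs (ids are
#'   positive integers).
#' @param weights optional numeric edge lengths, one per edge.
#' @param nNodes optional node count; defaults to the largest id seen.
#' @return A validated [TrajectoryTree-class].
#' @examples
#' # a 10-node tree: a long path with two extra branches
#' tr <- trajectoryTree(cbind(c(1, 2, 3, 4, 5, 6, 7, 3, 5),
#'                            c(2, 3, 4, 5, 6, 7, 8, 9, 10)))
#' statTriple(tr)
#' @export
trajectoryTree <- function(edges, weights = NULL, nNodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) valueError("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (is.null(nNodes)) nNodes <- max(edges)
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  ord <- order(edges[, 1L], edges[, 2L])
  new("TrajectoryTree", nNodes = as.integer(nNodes),
      edges = edges[ord, , drop = FALSE], weights = as.numeric(weights[ord]))
}

# Prim's algorithm on the complete Euclidean graph given its distance
# matrix. Deterministic tie rule: among equal-weight candidate edges the
# lexicographically smallest (min id, max id) pair wins, both when growing
# the tree and when updating a frontier node's best attachment. Ties are
# load-bearing: with duplicated centers or grid layouts they can change
# D1/D2/Lmax, so the rule is part of the contract.
.primMST <- function(D) {
  k <- nrow(D)
  inTree <- logical(k)
  inTree[1L] <- TRUE
  best <- D[1L, ]
  bestFrom <- rep(1L, k)
  edges <- matrix(0L, k - 1L, 2L)
  w <- numeric(k - 1L)
  for (step in seq_len(k - 1L)) {
    out <- which(!inTree)
    bw <- best[out]
    tied <- out[bw == min(bw)]
    if (length(tied) > 1L) {
      a <- pmin(bestFrom[tied], tied)
      b <- pmax(bestFrom[tied], tied)
      j <- tied[order(a, b)[1L]]
    } else {
      j <- tied
    }
    edges[step, ] <- c(min(bestFrom[j], j), max(bestFrom[j], j))
    w[step] <- best[j]
    inTree[j] <- TRUE
    out <- out[out != j]
    if (length(out)) {
      dj <- D[j, out]
      improve <- dj < best[out]
      # equal weight: prefer the lexicographically smaller pair
      tie <- dj == best[out] &
        (pmin(j, out) < pmin(bestFrom[out], out) |
           (pmin(j, out) == pmin(bestFrom[out], out) &
              pmax(j, out) < pmax(bestFrom[out], out)))
      upd <- out[improve | tie]
      best[upd] <- D[j, upd]
      bestFrom[upd] <- j
    }
  }
  list(edges = edges, weights = w)
}

#' Build the Euclidean minimum spanning tree on cluster centers
#'
#' Forms the complete graph on the centers with Euclidean edge weights and
#' extracts a minimum spanning tree with Prim's algorithm. Equal-weight
#' ties are broken towards the lexicographically smallest node-id pair, so
#' the tree (and hence the tree-shape statistics) is deterministic even
#' for duplicated centers or perfectly regular layouts.
#'
#' @param x a [CenterSet-class] or a numeric matrix of points (k x d,
#'   k >= 3, all entries finite; duplicated rows are allowed and yield
#'   zero-weight edges).
#' @param ... unused.
#' @return A [TrajectoryTree-class].
#' @examples
#' pts <- rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 1))
#' tr <- buildMST(pts)
#' treeEdges(tr)
#' sum(edgeWeights(tr))
#' @export
#' @name buildMST
NULL

#' @rdname buildMST
#' @export
setMethod("buildMST", "CenterSet", function(x, ...) {
  buildMST(centers(x))
})

#' @rdname buildMST
#' @export
setMethod("buildMST", "matrix", function(x, ...) {
  if (!is.numeric(x) || any(!is.finite(x)))
    valueError("centers must be a finite numeric matrix")
  k <- nrow(x)
  if (k < 3L) valueError("need at least 3 centers to build an MST")
  D <- as.matrix(stats::dist(x))
  res <- .primMST(D)
  trajectoryTree(res$edges, res$weights, nNodes = k)
})

.degrees <- function(tree) {
  tabulate(as.vector(tree@edges), nbins = tree@nNodes)
}

#' Count the degree-one (leaf) nodes of a tree
#'
#' The leaf count \eqn{D_1} is minimal (2) on a path graph and maximal
#' (k - 1) on a star tree; a trajectory in the data drives the MST on
#' cluster centers towards the path end of that spectrum, so small values
#' signal trajectory presence (lower-tailed test).
#'
#' @param tree a [TrajectoryTree-class].
#' @return integer leaf count.
#' @seealso [countDegreeTwo()], [longestPathLength()], [statTriple()]
#' @export
countDegreeOne <- function(tree) sum(.degrees(tree) == 1L)

#' Count the degree-two nodes of a tree
#'
#' \eqn{D_2} is maximal (k - 2) on a path graph and 0 on a star tree;
#' large values signal trajectory presence (upper-tailed test).
#'
#' @inheritParams countDegreeOne
#' @return integer count of nodes with exactly two incident edges.
#' @export
countDegreeTwo <- function(tree) sum(.degrees(tree) == 2L)

# Breadth-first sweep from `start`; returns the farthest node and its
# distance in edges.
.bfsFarthest <- function(adj, start) {
  k <- length(adj)
  distv <- rep(-1L, k)
  distv[start] <- 0L
  queue <- integer(k)
  queue[1L] <- start
  head <- 1L
  tail <- 1L
  while (head <= tail) {
    u <- queue[head]
    head <- head + 1L
    for (v in adj[[u]]) {
      if (distv[v] < 0L) {
        distv[v] <- distv[u] + 1L
        tail <- tail + 1L
        queue[tail] <- v
      }
    }
  }
  list(node = which.max(distv), dist = max(distv))
}

.adjacency <- function(tree) {
  adj <- vector("list", tree@nNodes)
  for (i in seq_len(nrow(tree@edges))) {
    a <- tree@edges[i, 1L]
    b <- tree@edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Length in edges of a longest simple path in a tree
#'
#' The unweighted tree diameter \eqn{L_{max}}, computed with the two-sweep
#' method: a breadth-first search from an arbitrary node finds one end of
#' a longest path, a second sweep from that end measures its length. Edge
#' weights play no role; path length is the number of edges. \eqn{L_{max}}
#' is k - 1 on a path graph and 2 on a star tree; large values signal
#' trajectory presence (upper-tailed test).
#'
#' @inheritParams countDegreeOne
#' @return integer diameter in edges.
#' @export
longestPathLength <- function(tree) {
  adj <- .adjacency(tree)
  first <- .bfsFarthest(adj, 1L)
  second <- .bfsFarthest(adj, first$node)
  as.integer(second$dist)
}

#' Compute the three tree-shape statistics of a tree
#'
#' @param tree a [TrajectoryTree-class].
#' @return A named integer vector with elements `D1`, `D2` and `Lmax`.
#' @examples
#' path8 <- trajectoryTree(cbind(1:7, 2:8))
#' statTriple(path8)  # (2, 6, 7): the path-graph extreme
#' @export
#' @name statTriple
NULL

#' @rdname statTriple
#' @export
setMethod("statTriple", "TrajectoryTree", function(tree) {
  c(D1 = countDegreeOne(tree),
    D2 = countDegreeTwo(tree),
    Lmax = longestPathLength(tree))
})

#' Serialize a tree to an edge-list TSV
#'
#' Writes columns `from`, `to`, `weight`, one row per edge, for debugging
#' or plotting with external tools.
#'
#' @param tree a [TrajectoryTree-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTree <- function(tree, path) {
  df <- data.frame(from = tree@edges[, 1L], to = tree@edges[, 2L],
                   weight = tree@weights)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
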