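# k-means partitioning of the point cloud. The cluster centers become the
# nodes of the Euclidean graph the MST is built on, so the contract here is
# stricter than a generic clustering: every cluster must be non-empty and
# the whole procedure must be deterministic given (seed, k).

# Core restarted k-means on a pre-validated double matrix. Rows are put
# in canonical (lexicographic) order before seeding, so the result is
# invariant to how the caller ordered the observations; the k-means++
# draws for restart r come from the (seed, k, r) stream. Returns the raw
# result list of the best restart plus the assignment mapped back to the
# caller's row order.
.kmeansCore <- function(x, k, seed, nRestarts = 10L, maxIter = 300L) {
  ord <- do.call(order, lapply(seq_len(ncol(x)), function(j) x[, j]))
  Xc <- x[ord, , drop = FALSE]
  dimnames(Xc) <- NULL
  U <- matrix(0, k, nRestarts)
  for (r in seq_len(nRestarts))
    U[, r] <- withSeed(mixSeed(seed, k, r), stats::runif(k))
  best <- kmeans_restarts(Xc, U, as.integer(maxIter))
  if (any(best$sizes == 0L))
    degenerateInputError(sprintf(
      "k = %d exceeds the number of distinct observations", k))
  assignment <- integer(nrow(x))
  assignment[ord] <- best$cluster
  best$assignment <- assignment
  best
}

#' Partition a point cloud into k clusters and return the centers
#'
#' Runs Lloyd's k-means with k-means++ initialisation, restarted
#' `nRestarts` times; the restart with the lowest total within-cluster sum
#' of squares is kept (ties keep the earliest restart). The per-restart
#' RNG streams are derived deterministically from `(seed, k, restart)`, so
#' every call is bit-reproducible, and initialisation operates on a
#' canonical (lexicographic) row ordering, so the result does not depend
#' on the order the observations are stored in. A cluster that empties
#' during iteration is re-seeded at the point currently farthest from its
#' assigned center, guaranteeing k non-empty clusters.
#'
#' @param x numeric matrix, observations x features.
#' @param k number of clusters; at least 3 (a spanning tree on fewer nodes
#'   carries no shape signal) and at most the number of rows.
#' @param seed integer master seed.
#' @param nRestarts number of k-means++ restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300); iteration
#'   also stops as soon as the assignment is stable.
#' @return A [CenterSet-class] with the k centers, cluster sizes and the
#'   per-observation assignment.
#' @examples
#' X <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 5), 30, 2))
#' cs <- kmeansCenters(X, k = 3, seed = 1)
#' clusterSizes(cs)
#' @export
kmeansCenters <- function(x, k, seed = 0L, nRestarts = 10L, maxIter = 300L) {
  x <- asDataMatrix(x)
  k <- as.integer(k)
  if (is.na(k) || k < 3L)
    valueError("k must be at least 3: an MST on fewer nodes has no shape")
  if (k > nrow(x))
    valueError(sprintf("k = %d exceeds the number of observations (%d)",
                       k, nrow(x)))
  storage.mode(x) <- "double"
  if (nrow(unique(x)) < k)
    degenerateInputError(sprintf(
      "k = %d exceeds the number of distinct observations (%d)",
      k, nrow(unique(x))))

  best <- .kmeansCore(x, k, as.integer(seed), as.integer(nRestarts),
                      as.integer(maxIter))
  new("CenterSet",
      centers = best$centers,
      sizes = as.integer(best$sizes),
      assignment = best$assignment,
      totss = best$totss)
}
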