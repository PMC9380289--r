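# The trajectory-presence test proper: permutation null, one-tailed
# p-values, sweep over the cluster range, median-p summary.

# purpose tags for the per-replicate seed streams
.TAG_PERM <- 1L
.TAG_KMEANS <- 2L

#' Permute a data matrix column-wise
#'
#' Independently reshuffles every feature column across the observations.
#' This destroys all inter-feature dependence -- and with it any
#' trajectory -- while preserving every marginal distribution exactly,
#' which is the null model the test compares against.
#'
#' @param x numeric matrix, observations x features.
#' @param seed integer seed; the permutation is deterministic given it.
#' @return A matrix of the same dimensions and dimnames in which every
#'   column is a permutation of the corresponding input column.
#' @examples
#' X <- cbind(a = 1:5, b = 11:15)
#' permuteMatrix(X, seed = 1)
#' @export
permuteMatrix <- function(x, seed = 0L) {
  x <- asDataMatrix(x)
  n <- nrow(x)
  withSeed(seed, {
    for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(n), j]
  })
  x
}

# column shuffle without revalidation, for the permutation hot path
.permuteCols <- function(x, seed) {
  n <- nrow(x)
  withSeed(seed, {
    for (j in seq_len(ncol(x))) x[, j] <- x[sample.int(n), j]
  })
  x
}

# the three counts straight from an edge matrix, skipping S4 wrapping
.statsFromEdges <- function(edges, k) {
  deg <- tabulate(edges, nbins = k)
  adj <- vector("list", k)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]
    b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  first <- .bfsFarthest(adj, 1L)
  second <- .bfsFarthest(adj, first$node)
  c(D1 = sum(deg == 1L), D2 = sum(deg == 2L),
    Lmax = as.integer(second$dist))
}

# One pipeline unit on a pre-validated double matrix: cluster, build the
# MST on the centers, read off the three counts.
.pipelineTriple <- function(x, k, kmSeed) {
  fit <- .kmeansCore(x, k, kmSeed)
  mst <- .primMST(as.matrix(stats::dist(fit$centers)))
  .statsFromEdges(mst$edges, k)
}

# B permuted-data triples at one k, one row per replicate. All three
# statistics are read off the SAME permuted-data MST per replicate: one
# clustering and one tree serve all requested statistics.
.nullTriples <- function(x, k, B, seed) {
  out <- matrix(0L, nrow = B, ncol = 3L,
                dimnames = list(NULL, trajStatistics()))
  for (b in seq_len(B)) {
    xp <- .permuteCols(x, mixSeed(seed, k, b, .TAG_PERM))
    out[b, ] <- .pipelineTriple(xp, k, mixSeed(seed, k, b, .TAG_KMEANS))
  }
  out
}

#' Permutation null distribution of one tree statistic
#'
#' Each of the B replicates permutes the matrix column-wise, re-runs
#' k-means, rebuilds the MST and records the statistic. Replicate seed
#' streams are derived from `(seed, k, replicate)`, so the distribution is
#' reproducible and every replicate is independent of the others.
#'
#' @param x numeric matrix, observations x features.
#' @param k number of clusters.
#' @param statistic one of [trajStatistics()].
#' @param B number of permutations (>= 19).
#' @param seed integer master seed.
#' @return A [NullDistribution-class].
#' @seealso [pValue()], [testTrajectoryPresence()]
#' @export
nullDistribution <- function(x, k, statistic = trajStatistics(), B = 1000L,
                             seed = 0L) {
  statistic <- match.arg(statistic)
  B <- as.integer(B)
  if (is.na(B) || B < 19L) configError("B must be at least 19")
  x <- asDataMatrix(x)
  samples <- .nullTriples(x, as.integer(k), B, as.integer(seed))[, statistic]
  new("NullDistribution", statistic = statistic, k = as.integer(k),
      samples = as.integer(samples))
}

#' One-tailed empirical p-value against a permutation null
#'
#' Uses the add-one empirical formula, which keeps the p-value strictly
#' positive and the test valid: lower tail
#' \eqn{p = (1 + \#\{s \le obs\}) / (1 + B)}, upper tail
#' \eqn{p = (1 + \#\{s \ge obs\}) / (1 + B)}. Ties with the observed value
#' count as extreme (conservative).
#'
#' @param observed the observed statistic value.
#' @param null a [NullDistribution-class] or a numeric vector of null
#'   samples.
#' @param tail `"lower"` or `"upper"`. When `null` is a
#'   [NullDistribution-class] the default is the tail associated with its
#'   statistic (see [trajTails()]).
#' @return A single p-value in (0, 1].
#' @examples
#' pValue(4, c(2, 3, 4, 5, 6), tail = "upper")  # (1 + 3) / 6
#' @export
pValue <- function(observed, null, tail = c("lower", "upper")) {
  if (is(null, "NullDistribution")) {
    if (missing(tail)) tail <- trajTails()[[null@statistic]]
    samples <- null@samples
  } else {
    samples <- null
  }
  tail <- match.arg(tail)
  if (length(samples) < 1L) valueError("null distribution is empty")
  B <- length(samples)
  hits <- if (tail == "lower") sum(samples <= observed)
          else sum(samples >= observed)
  (1 + hits) / (1 + B)
}

#' Test a point cloud for the presence of a trajectory
#'
#' The full pipeline. For every number of clusters k in
#' `[kMin, kMax]`: the data are partitioned with k-means, the Euclidean
#' MST is built on the cluster centers and the tree-shape statistics are
#' recorded; B column-permuted replicates supply the null distribution of
#' each statistic; one-tailed add-one empirical p-values are computed
#' (lower tail for `D1`, upper for `D2` and `Lmax`). The median p-value
#' per statistic across the sweep is the reported evidence level --
#' a summary of the per-k tests, not a calibrated p-value itself (no
#' multiplicity correction is applied across k or across statistics).
#'
#' The observed statistics at each k use the same k-means seed stream as
#' the permutation replicates, so a report is bit-reproducible from
#' `(x, config)` alone.
#'
#' @param x numeric matrix (observations x features), or anything
#'   [loadMatrix()] returns.
#' @param config a [RunConfig-class]; if `NULL`, one is assembled from
#'   the remaining arguments.
#' @param kMin,kMax,nPermutations,seed,statistics see [runConfig()].
#' @param pcaDims number of principal components to reduce to first;
#'   `"none"` or `NA` to skip. Default (`NULL`): reduce to 2 components
#'   when the matrix has more than 10 features, otherwise use it as is.
#' @param permuteBeforePCA logical; if `TRUE` (and PCA is in effect) each
#'   permutation replicate shuffles the raw matrix and re-runs PCA,
#'   instead of shuffling the reduced matrix (the default).
#' @return A [TrajectoryTestReport-class].
#' @examples
#' sim <- simulateTrajectory("linear", nCells = 120, seed = 1)
#' rep <- testTrajectoryPresence(sim$coordinates, kMin = 5, kMax = 8,
#'                               nPermutations = 49, seed = 1)
#' medianP(rep)
#' @export
testTrajectoryPresence <- function(x, config = NULL, kMin = 5L, kMax = 35L,
                                   nPermutations = 1000L, seed = 0L,
                                   pcaDims = NULL,
                                   statistics = trajStatistics(),
                                   permuteBeforePCA = FALSE) {
  raw <- asDataMatrix(x)
  if (is.null(config)) {
    if (is.null(pcaDims)) {
      pd <- if (ncol(raw) > 10L) 2L else NA_integer_
    } else if (identical(pcaDims, "none")) {
      pd <- NA_integer_
    } else {
      pd <- as.integer(pcaDims)
    }
    config <- runConfig(kMin = kMin, kMax = kMax,
                        nPermutations = nPermutations, seed = seed,
                        pcaDims = pd, statistics = statistics)
  }
  if (!is(config, "RunConfig")) configError("config must be a RunConfig")
  if (config@kMax > nrow(raw) - 1L)
    configError(sprintf("kMax = %d must be at most n - 1 = %d",
                        config@kMax, nrow(raw) - 1L))

  usePCA <- !is.na(config@pcaDims)
  X <- if (usePCA) reducePCA(raw, config@pcaDims) else raw
  ks <- seq.int(config@kMin, config@kMax)
  B <- config@nPermutations
  seed <- config@seed
  stats <- config@statistics
  tails <- trajTails()

  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    obs <- .pipelineTriple(X, k, mixSeed(seed, k, 0L, .TAG_KMEANS))
    if (permuteBeforePCA && usePCA) {
      null <- matrix(0L, B, 3L, dimnames = list(NULL, trajStatistics()))
      for (b in seq_len(B)) {
        xp <- reducePCA(permuteMatrix(raw, mixSeed(seed, k, b, .TAG_PERM)),
                        config@pcaDims)
        null[b, ] <- .pipelineTriple(xp, k,
                                     mixSeed(seed, k, b, .TAG_KMEANS))
      }
    } else {
      null <- .nullTriples(X, k, B, seed)
    }
    p <- vapply(stats, function(s)
      pValue(obs[[s]], null[, s], tails[[s]]), numeric(1))
    rows[[i]] <- data.frame(statistic = stats, k = k,
                            observed = as.integer(obs[stats]),
                            p_value = unname(p))
  }
  perK <- do.call(rbind, rows)
  perK <- perK[order(match(perK$statistic, trajStatistics()), perK$k), ]
  rownames(perK) <- NULL
  medians <- vapply(stats, function(s)
    stats::median(perK$p_value[perK$statistic == s]), numeric(1))
  new("TrajectoryTestReport", perK = perK, medians = medians,
      config = config)
}

#' Box plot of the per-k p-values of a report
#'
#' One box per statistic summarizing its p-values across the cluster
#' sweep, with the median marked. Written to `path` (device chosen by
#' extension: `.pdf` or `.png`) or drawn on the current device when
#' `path` is `NULL`.
#'
#' @param report a [TrajectoryTestReport-class].
#' @param path output file, or `NULL` to draw on the current device.
#' @param ... further arguments passed to [graphics::boxplot()].
#' @return `path` (or `NULL`), invisibly.
#' @export
#' @name plotReport
NULL

#' @rdname plotReport
#' @export
setMethod("plotReport", "TrajectoryTestReport",
          function(report, path = NULL, ...) {
  perK <- report@perK
  if (nrow(perK) == 0L) valueError("report contains no p-values to plot")
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    dev <- switch(ext, pdf = grDevices::pdf, png = grDevices::png,
                  valueError(sprintf("unsupported plot format '%s'", ext)))
    dev(path)
    on.exit(grDevices::dev.off())
  }
  lv <- intersect(trajStatistics(), unique(perK$statistic))
  graphics::boxplot(p_value ~ factor(statistic, levels = lv), data = perK,
                    ylim = c(0, 1), xlab = "statistic",
                    ylab = "p-value per k",
                    main = "Trajectory-presence test", ...)
  graphics::points(seq_along(lv), report@medians[lv], pch = 19,
                   col = "darkorange")
  invisible(path)
})

#' Write a report to a TSV file
#'
#' Columns `statistic`, `k`, `observed`, `p_value`, one row per (statistic,
#' k) pair, followed by footer comment lines `# median <statistic> <value>`.
#' Values are written with 17 significant digits so the file is bit-stable
#' for identical inputs.
#'
#' @param report a [TrajectoryTestReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  perK <- report@perK
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("statistic\tk\tobserved\tp_value", con)
  writeLines(sprintf("%s\t%d\t%d\t%.17g", perK$statistic, perK$k,
                     perK$observed, perK$p_value), con)
  writeLines(sprintf("# median %s %.17g", names(report@medians),
                     unname(report@medians)), con)
  invisible(path)
}
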