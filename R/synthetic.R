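# Synthetic point clouds with known trajectory topology. The generators
# are geometric, not transcriptomic: the test consumes low-dimensional
# (typically 2-D PCA) coordinates, so points are sampled directly on a
# planar backbone and blurred with isotropic Gaussian noise.
# liftToExpression() optionally maps coordinates to a wide noisy
# gene-expression-like matrix for end-to-end I/O tests.

.trajKinds <- c("none", "linear", "multifurcating", "converging_diverging",
                "disconnected_looping")

#' Default noise level per synthetic topology
#'
#' Per-kind presets for the isotropic Gaussian noise standard deviation,
#' in the same units as the backbone coordinates (backbones have extent
#' of order 1). The levels are fixed calibration choices: small enough
#' that each trajectory stays clearly detectable, large enough that the
#' clouds do not degenerate to their noiseless curves. `"none"` has no
#' backbone, so its preset is 0.
#'
#' @param kind one of the topology kinds (see [simulateTrajectory()]).
#' @return A single numeric noise standard deviation.
#' @examples
#' defaultNoiseSd("linear")
#' @export
defaultNoiseSd <- function(kind = .trajKinds) {
  kind <- match.arg(kind)
  presets <- c(none = 0, linear = 0.02, multifurcating = 0.02,
               converging_diverging = 0.02, disconnected_looping = 0.02)
  presets[[kind]]
}

# Backbone description: a list of branches, each with a name, an arc
# length and a map t in [0,1] -> 2-D point. Pseudotime is stored as the
# branch-local parameter t.
.backbone <- function(kind) {
  seg <- function(name, from, to) {
    from <- as.numeric(from); to <- as.numeric(to)
    list(name = name, length = sqrt(sum((to - from)^2)),
         f = function(t) cbind(from[1] + t * (to[1] - from[1]),
                               from[2] + t * (to[2] - from[2])))
  }
  switch(kind,
    linear = {
      # gentle sine bend so the curve is smooth but far from degenerate
      f <- function(t) cbind(t, 0.2 * sin(pi * t))
      tt <- seq(0, 1, length.out = 512)
      len <- sum(sqrt(rowSums(diff(f(tt))^2)))
      list(list(name = "main", length = len, f = f))
    },
    multifurcating = {
      root <- seg("root", c(0, 0), c(0.5, 0))
      ang <- c(-45, 0, 45) * pi / 180
      kids <- lapply(seq_along(ang), function(i)
        seg(paste0("branch_", letters[i]), c(0.5, 0),
            c(0.5 + 0.5 * cos(ang[i]), 0.5 * sin(ang[i]))))
      c(list(root), kids)
    },
    converging_diverging = list(
      seg("in_a", c(0, 0.4), c(0.4, 0)),
      seg("in_b", c(0, -0.4), c(0.4, 0)),
      seg("mid", c(0.4, 0), c(0.6, 0)),
      seg("out_a", c(0.6, 0), c(1, 0.4)),
      seg("out_b", c(0.6, 0), c(1, -0.4))),
    disconnected_looping = {
      # open arc covering 75% of a circle (gap 25% of the circumference)
      # plus a disjoint short segment well away from it
      arc <- list(name = "loop", length = 1.5 * pi * 0.5,
                  f = function(t) cbind(0.5 + 0.5 * cos(1.5 * pi * t),
                                        0.5 + 0.5 * sin(1.5 * pi * t)))
      list(arc, seg("segment", c(2, 0.5), c(2.4, 0.5)))
    },
    valueError(sprintf("unknown topology kind '%s'", kind))
  )
}

# Allocate n points across branches proportionally to arc length,
# largest-remainder rounding so the total is exact.
.allocate <- function(n, lengths) {
  raw <- n * lengths / sum(lengths)
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Simulate a point cloud with a known trajectory topology
#'
#' Generates `nCells` points in `dims` dimensions from one of five
#' topologies emulating the qualitative structure of dimension-reduced
#' single-cell data:
#' \describe{
#'   \item{`none`}{i.i.d. uniform points on the unit hypercube -- no
#'     structure of any kind.}
#'   \item{`linear`}{points along a single smooth curve.}
#'   \item{`multifurcating`}{a root segment splitting into three child
#'     branches at its end (one branch point, four branch labels).}
#'   \item{`converging_diverging`}{two branches merging into a shared
#'     middle segment that re-splits into two.}
#'   \item{`disconnected_looping`}{an open circular arc (75% of a circle)
#'     plus a disjoint short segment.}
#' }
#' Points are distributed over the backbone branches proportionally to
#' arc length, with branch-local positions drawn uniformly, then blurred
#' with isotropic Gaussian noise of standard deviation `noiseSd` in all
#' `dims` coordinates. For `dims > 2` the backbone lives in the first two
#' coordinates. Generation is deterministic given the arguments.
#'
#' @param kind topology, one of `"none"`, `"linear"`, `"multifurcating"`,
#'   `"converging_diverging"`, `"disconnected_looping"`.
#' @param nCells number of points (>= 50).
#' @param noiseSd Gaussian noise standard deviation; `NULL` uses the
#'   per-kind preset [defaultNoiseSd()].
#' @param seed integer seed.
#' @param dims embedding dimension (>= 2, default 2).
#' @return A list with elements
#'   `coordinates` (nCells x dims noisy matrix -- the test input),
#'   `clean` (the noiseless positions on the backbone), and
#'   `labels` (data.frame with ground-truth `branch` and branch-local
#'   `pseudotime`; pseudotime is `NA` for `kind = "none"`).
#' @examples
#' sim <- simulateTrajectory("multifurcating", nCells = 200, seed = 7)
#' table(sim$labels$branch)
#' @export
simulateTrajectory <- function(kind = .trajKinds, nCells = 500L,
                               noiseSd = NULL, seed = 0L, dims = 2L) {
  kind <- match.arg(kind)
  nCells <- as.integer(nCells)
  dims <- as.integer(dims)
  if (is.na(nCells) || nCells < 50L)
    valueError("nCells must be at least 50")
  if (is.na(dims) || dims < 2L) valueError("dims must be at least 2")
  if (is.null(noiseSd)) noiseSd <- defaultNoiseSd(kind)
  if (noiseSd < 0) valueError("noiseSd must be non-negative")

  withSeed(mixSeed(seed, match(kind, .trajKinds), nCells, dims), {
    if (kind == "none") {
      clean <- matrix(stats::runif(nCells * dims), nCells, dims)
      labels <- data.frame(branch = rep("none", nCells),
                           pseudotime = NA_real_)
    } else {
      branches <- .backbone(kind)
      counts <- .allocate(nCells, vapply(branches, `[[`, numeric(1),
                                         "length"))
      pieces <- vector("list", length(branches))
      for (i in seq_along(branches)) {
        t <- sort(stats::runif(counts[i]))
        pieces[[i]] <- list(xy = branches[[i]]$f(t), t = t,
                            name = branches[[i]]$name)
      }
      xy <- do.call(rbind, lapply(pieces, `[[`, "xy"))
      clean <- cbind(xy, matrix(0, nCells, dims - 2L))[, seq_len(dims),
                                                       drop = FALSE]
      labels <- data.frame(
        branch = rep(vapply(pieces, `[[`, character(1), "name"), counts),
        pseudotime = unlist(lapply(pieces, `[[`, "t")))
    }
    noise <- matrix(stats::rnorm(nCells * dims, sd = noiseSd),
                    nCells, dims)
    coords <- clean + noise
    rn <- paste0("cell", seq_len(nCells))
    dimnames(coords) <- list(rn, paste0("dim", seq_len(dims)))
    dimnames(clean) <- dimnames(coords)
    rownames(labels) <- rn
    list(coordinates = coords, clean = clean, labels = labels)
  })
}

#' Lift low-dimensional coordinates to a wide expression-like matrix
#'
#' Maps each coordinate vector through a fixed random linear loading
#' matrix into `nGenes` features and adds Gaussian noise, producing a
#' matrix shaped like log-normalized expression whose leading principal
#' components recover the input geometry. Intended for end-to-end tests
#' of the I/O and PCA path; it makes no attempt at count-level realism.
#'
#' @param x numeric matrix of coordinates (observations x dims).
#' @param nGenes number of output features (default 50).
#' @param noiseSd per-entry Gaussian noise standard deviation.
#' @param seed integer seed fixing the loading matrix and the noise.
#' @return An observations x `nGenes` matrix.
#' @export
liftToExpression <- function(x, nGenes = 50L, noiseSd = 0.1, seed = 0L) {
  x <- asDataMatrix(x)
  nGenes <- as.integer(nGenes)
  if (is.na(nGenes) || nGenes < 1L) valueError("nGenes must be >= 1")
  withSeed(mixSeed(seed, 777L, nGenes), {
    W <- matrix(stats::rnorm(ncol(x) * nGenes), ncol(x), nGenes)
    y <- x %*% W + matrix(stats::rnorm(nrow(x) * nGenes, sd = noiseSd),
                          nrow(x), nGenes)
    dimnames(y) <- list(rownames(x), paste0("gene", seq_len(nGenes)))
    y
  })
}
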