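#' Create a run configuration
#'
#' Bundles the parameters of the trajectory-presence test. Defaults follow
#' the published evaluation protocol: the cluster sweep covers
#' \eqn{5 \le k \le 35} (31 values), chosen so that very coarse clusterings
#' (which always look linear) and very fine ones (which always look
#' branched) do not dominate the evidence.
#'
#' @param kMin,kMax integer bounds of the cluster sweep; `kMin >= 3` and
#'   `kMax <= n - 1` for the matrix the config is used with.
#' @param nPermutations permutation count B (default 1000, which resolves
#'   p-values down to about 0.001); must be at least 19 so that the add-one
#'   empirical p-value can reach 0.05.
#' @param seed integer master seed; all randomness in the pipeline derives
#'   from it deterministically.
#' @param pcaDims number of principal components to reduce to before
#'   testing, or `NA` to test the matrix as supplied. The published
#'   analyses use 2-dimensional PCA projections.
#' @param statistics character subset of [trajStatistics()].
#' @return A validated [RunConfig-class] object.
#' @examples
#' runConfig(kMin = 5, kMax = 20, nPermutations = 99, seed = 1)
#' @export
runConfig <- function(kMin = 5L, kMax = 35L, nPermutations = 1000L,
                      seed = 0L, pcaDims = NA_integer_,
                      statistics = trajStatistics()) {
  tryCatch(
    new("RunConfig",
        kMin = as.integer(kMin), kMax = as.integer(kMax),
        nPermutations = as.integer(nPermutations),
        seed = as.integer(seed),
        pcaDims = as.integer(pcaDims),
        statistics = as.character(statistics)),
    error = function(e) configError(conditionMessage(e)))
}

.sidecarNames <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  c(rows = paste0(stem, ".rownames.txt"),
    cols = paste0(stem, ".colnames.txt"))
}

#' Read a data matrix from CSV, TSV or MatrixMarket files
#'
#' Observations (cells) are rows and features (genes or principal
#' components) are columns. CSV/TSV files must carry a header row and a
#' row-label first column. MatrixMarket input (`format = "mtx"`) expects
#' sidecar name files next to the matrix: for `X.mtx`, `X.rownames.txt`
#' and `X.colnames.txt`, one name per line; the sparse matrix is densified
#' on load. Matrices stored genes x cells can be transposed on the fly
#' with `transpose = TRUE`.
#'
#' Loading enforces the data-matrix invariants: at least 3 rows and 1
#' column, all entries finite (an `NA` or non-numeric cell is an error
#' naming the offending row and column), unique row and column labels.
#'
#' @param path path to the matrix file.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; default guesses from
#'   the file extension.
#' @param transpose logical; transpose after reading so that rows are
#'   observations (for genes x cells MatrixMarket exports).
#' @return A numeric matrix with row and column names.
#' @seealso [writeMatrix()], [reducePCA()]
#' @examples
#' path <- system.file("extdata", "linear_example.csv",
#'                     package = "trajpresence")
#' X <- loadMatrix(path)
#' dim(X)
#' @export
loadMatrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                       transpose = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     parseError(sprintf(
                       "cannot guess format from extension '%s'", ext)))
  }
  if (!file.exists(path))
    parseError(sprintf("file not found: %s", path))

  if (format == "mtx") {
    side <- .sidecarNames(path)
    missing <- side[!file.exists(side)]
    if (length(missing))
      parseError(sprintf("missing sidecar name file(s): %s",
                         paste(missing, collapse = ", ")))
    m <- tryCatch(Matrix::readMM(path), error = function(e)
      parseError(sprintf("malformed MatrixMarket file %s: %s",
                         path, conditionMessage(e))))
    x <- as.matrix(m)
    rn <- readLines(side[["rows"]])
    cn <- readLines(side[["cols"]])
    if (length(rn) != nrow(x) || length(cn) != ncol(x))
      parseError("sidecar name files do not match the matrix dimensions")
    dimnames(x) <- list(rn, cn)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                        check.names = FALSE, comment.char = "",
                        stringsAsFactors = FALSE, quote = "\""),
      error = function(e)
        parseError(sprintf("malformed %s file %s: %s",
                           format, path, conditionMessage(e))))
    for (j in seq_along(df)) {
      col <- df[[j]]
      if (!is.numeric(col)) {
        asNum <- suppressWarnings(as.numeric(col))
        i <- which(is.na(asNum) & !(col %in% c("NA", "NaN")))[1L]
        if (is.na(i)) i <- which(is.na(asNum))[1L]
        valueError(sprintf(
          "non-numeric value '%s' at row '%s', column '%s'",
          col[i], rownames(df)[i], colnames(df)[j]))
      }
      if (anyNA(col)) {
        i <- which(is.na(col))[1L]
        valueError(sprintf("missing value at row '%s', column '%s'",
                           rownames(df)[i], colnames(df)[j]))
      }
    }
    x <- as.matrix(df)
  }
  if (transpose) x <- t(x)
  asDataMatrix(x, sprintf("matrix loaded from %s", path))
}

#' Write a data matrix to CSV, TSV or MatrixMarket files
#'
#' The inverse of [loadMatrix()]. CSV/TSV output stores values with 17
#' significant digits so a load/write/load cycle reproduces the doubles
#' bit-for-bit. MatrixMarket output writes the two sidecar name files next
#' to the matrix.
#'
#' @param x numeric matrix with row and column names.
#' @param path output path.
#' @param format one of `"csv"`, `"tsv"`, `"mtx"`; default guesses from
#'   the extension as in [loadMatrix()].
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path, format = c("auto", "csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     valueError(sprintf(
                       "cannot guess format from extension '%s'", ext)))
  }
  x <- asDataMatrix(x)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(unname(x), sparse = TRUE), path)
    side <- .sidecarNames(path)
    writeLines(rownames(x), side[["rows"]])
    writeLines(colnames(x), side[["cols"]])
  } else {
    sep <- if (format == "csv") "," else "\t"
    chr <- matrix(sprintf("%.17g", x), nrow = nrow(x),
                  dimnames = dimnames(x))
    utils::write.table(chr, path, sep = sep, quote = FALSE,
                       col.names = NA, row.names = TRUE)
  }
  invisible(path)
}

#' Reduce a data matrix to its top principal components
#'
#' Columns are centered but not scaled to unit variance: the test operates
#' on raw PCA projections, and rescaling features would change the
#' Euclidean geometry that the minimum spanning tree is built on. For
#' reproducibility the sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x numeric matrix, observations x features.
#' @param d number of components to keep, `1 <= d <= min(n, p)`.
#' @return An n x d matrix of principal-component scores with columns
#'   `PC1..PCd`; per-component variance is non-increasing.
#' @examples
#' X <- matrix(rnorm(200), 50, 4)
#' Y <- reducePCA(X, 2)
#' apply(Y, 2, var)  # non-increasing
#' @export
reducePCA <- function(x, d) {
  x <- asDataMatrix(x)
  d <- as.integer(d)
  if (is.na(d) || d < 1L || d > min(dim(x)))
    valueError(sprintf("d must be in 1..min(n, p) = 1..%d", min(dim(x))))
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pr$x[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    v <- pr$rotation[, j]
    if (v[which.max(abs(v))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(d))
  rownames(scores) <- rownames(x)
  scores
}
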