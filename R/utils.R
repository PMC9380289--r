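# Internal helpers: seed streams, input validation, error conditions.

# Deterministic seed stream: mixes the master seed with any number of
# integer tags (k, replicate index, purpose tag) into a 31-bit seed.
# A multiplicative-congruential mix; all arithmetic stays below 2^53 so
# it is exact in doubles.
mixSeed <- function(...) {
  xs <- as.numeric(c(...))
  stopifnot(all(is.finite(xs)))
  h <- 104729
  for (x in xs) h <- (h * 69069 + (x %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Evaluate expr under a local RNG seed (fixed Mersenne-Twister kinds, so
# results do not depend on session RNG settings) without disturbing the
# caller's RNG state. Kept deliberately lean: it sits on the permutation
# hot path.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

tpError <- function(msg, class) {
  stop(structure(class = c(class, "trajpresenceError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

configError <- function(msg) tpError(msg, "trajpresenceConfigError")
valueError <- function(msg) tpError(msg, "trajpresenceValueError")
parseError <- function(msg) tpError(msg, "trajpresenceParseError")
degenerateInputError <- function(msg)
  tpError(msg, "trajpresenceDegenerateInputError")

# Coerce to a plain numeric matrix with unique dimnames and check the
# data-matrix invariants: n >= 3, p >= 1, all entries finite.
asDataMatrix <- function(x, what = "data matrix") {
  if (is(x, "Matrix")) x <- as.matrix(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    valueError(sprintf("%s must be a numeric matrix", what))
  if (nrow(x) < 3L)
    valueError(sprintf("%s must have at least 3 rows (observations)", what))
  if (ncol(x) < 1L)
    valueError(sprintf("%s must have at least 1 column (feature)", what))
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    valueError(sprintf(
      "%s contains a non-finite value at row %d, column %d",
      what, bad[[1L]], bad[[2L]]))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("obs", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    valueError(sprintf("%s has duplicated row labels", what))
  if (anyDuplicated(colnames(x)))
    valueError(sprintf("%s has duplicated column labels", what))
  storage.mode(x) <- "double"
  x
}
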