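#' @name accessors
#' @title Accessors for trajpresence classes
#'
#' @description Small accessor generics: `centers()` and `clusterSizes()`
#' read a [CenterSet-class]; `clusterAssignment()` returns its per-point
#' cluster labels; `treeEdges()`, `edgeWeights()` and `nNodes()` read a
#' [TrajectoryTree-class]; `nullSamples()` reads a
#' [NullDistribution-class]; `pValues()`, `medianP()` and `reportConfig()`
#' read a [TrajectoryTestReport-class].
#'
#' @param x an object of the documented class.
#' @return The slot content: matrices, integer vectors, a data.frame of
#'   per-k p-values, or a named numeric vector of median p-values.
NULL

#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("clusterAssignment",
           function(x) standardGeneric("clusterAssignment"))

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(x) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname accessors
#' @export
setGeneric("nullSamples", function(x) standardGeneric("nullSamples"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("medianP", function(x) standardGeneric("medianP"))

#' @rdname accessors
#' @export
setGeneric("reportConfig", function(x) standardGeneric("reportConfig"))

#' @rdname buildMST
#' @export
setGeneric("buildMST", function(x, ...) standardGeneric("buildMST"))

#' @rdname statTriple
#' @export
setGeneric("statTriple", function(tree) standardGeneric("statTriple"))

#' @rdname plotReport
#' @export
setGeneric("plotReport", function(report, path = NULL, ...)
  standardGeneric("plotReport"))

#' @rdname accessors
#' @export
setMethod("centers", "CenterSet", function(x) x@centers)

#' @rdname accessors
#' @export
setMethod("clusterSizes", "CenterSet", function(x) x@sizes)

#' @rdname accessors
#' @export
setMethod("clusterAssignment", "CenterSet", function(x) x@assignment)

#' @rdname accessors
#' @export
setMethod("treeEdges", "TrajectoryTree", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("edgeWeights", "TrajectoryTree", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("nNodes", "TrajectoryTree", function(x) x@nNodes)

#' @rdname accessors
#' @export
setMethod("nullSamples", "NullDistribution", function(x) x@samples)

#' @rdname accessors
#' @export
setMethod("pValues", "TrajectoryTestReport", function(x) x@perK)

#' @rdname accessors
#' @export
setMethod("medianP", "TrajectoryTestReport", function(x) x@medians)

#' @rdname accessors
#' @export
setMethod("reportConfig", "TrajectoryTestReport", function(x) x@config)

#' @export
setMethod("show", "RunConfig", function(object) {
  pd <- if (is.na(object@pcaDims)) "none" else object@pcaDims
  cat("RunConfig: k in [", object@kMin, ", ", object@kMax, "], B = ",
      object@nPermutations, ", seed = ", object@seed,
      ", pcaDims = ", pd, "\n  statistics: ",
      paste(object@statistics, collapse = ", "), "\n", sep = "")
})

#' @export
setMethod("show", "CenterSet", function(object) {
  cat("CenterSet with", nrow(object@centers), "centers in",
      ncol(object@centers), "dimensions\n")
  cat("  cluster sizes:", paste(object@sizes, collapse = ", "), "\n")
  cat("  total within-cluster SS:", format(object@totss), "\n")
})

#' @export
setMethod("show", "TrajectoryTree", function(object) {
  s <- statTriple(object)
  cat("TrajectoryTree with", object@nNodes, "nodes and",
      nrow(object@edges), "edges\n")
  cat("  total weight:", format(sum(object@weights)), "\n")
  cat("  D1 =", s["D1"], " D2 =", s["D2"], " Lmax =", s["Lmax"], "\n")
})

#' @export
setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution of", object@statistic, "at k =", object@k,
      "(B =", length(object@samples), "permutations)\n")
  print(summary(object@samples))
})

#' @export
setMethod("show", "TrajectoryTestReport", function(object) {
  cfg <- object@config
  cat("TrajectoryTestReport over k in [", cfg@kMin, ", ", cfg@kMax,
      "], B = ", cfg@nPermutations, "\n", sep = "")
  cat("Median p-values (evidence for trajectory presence):\n")
  for (s in names(object@medians))
    cat(sprintf("  %-5s %.4g\n", s, object@medians[[s]]))
})
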