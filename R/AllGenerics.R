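#' Accessors for SpectralCountExperiment
#'
#' `spcCounts()` returns the integer spectral-count matrix,
#' `proteinLengths()` the named vector of amino-acid lengths and
#' `lesionTrait()` the named binary trait vector (1 = HOT, 0 = COLD).
#'
#' @param x a [SpectralCountExperiment-class]
#' @return matrix or named vector, rows/names in dataset order.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spcCounts", function(x) standardGeneric("spcCounts"))

#' @rdname accessors
#' @export
setMethod("spcCounts", "SpectralCountExperiment", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname accessors
#' @export
setMethod("proteinLengths", "SpectralCountExperiment", function(x)
  setNames(SummarizedExperiment::rowData(x)$protein_length, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("lesionTrait", function(x) standardGeneric("lesionTrait"))

#' @rdname accessors
#' @export
setMethod("lesionTrait", "SpectralCountExperiment", function(x)
  setNames(as.integer(SummarizedExperiment::colData(x)$trait), colnames(x)))

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModulePartition", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("moduleColors", function(x) standardGeneric("moduleColors"))

#' @rdname accessors
#' @export
setMethod("moduleColors", "ModulePartition", function(x) x@colors)

#' @rdname accessors
#' @export
setGeneric("eigenproteins", function(x) standardGeneric("eigenproteins"))

#' @rdname accessors
#' @export
setMethod("eigenproteins", "ModulePartition", function(x) x@eigenproteins)

#' @rdname accessors
#' @export
setGeneric("kmeMatrix", function(x) standardGeneric("kmeMatrix"))

#' @rdname accessors
#' @export
setMethod("kmeMatrix", "ModulePartition", function(x) x@kme)

#' @rdname accessors
#' @export
setGeneric("tomMatrix", function(x) standardGeneric("tomMatrix"))

#' @rdname accessors
#' @export
setMethod("tomMatrix", "CoexpressionNetwork", function(x) x@tom)

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "CoexpressionNetwork", function(x) x@adjacency)

#' Venn summary of trait-wise protein detection
#'
#' Counts proteins detected (total spectral count > 0) in the HOT group
#' only, the COLD group only, or both, and expresses them as percentages of
#' all detected proteins. Percentages are reported raw (1 decimal shown) and
#' rounded to the nearest integer (half away from zero).
#'
#' @param x a [SpectralCountExperiment-class]
#' @return an object of class `VennSummary` (a list with `n_total`,
#'   `n_hot_unique`, `n_cold_unique`, `n_common`, `pct_*` and `pct_*_rounded`
#'   components).
#' @export
setGeneric("vennSummary", function(x) standardGeneric("vennSummary"))
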