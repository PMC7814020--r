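#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor cutree hclust as.dist pchisq phyper pt p.adjust
#'   quantile rnbinom rnorm rpois runif sd lm coef var median setNames
#'   rmultinom
#' @importFrom utils read.delim write.table packageVersion
NULL

#' SpectralCountExperiment: spectral-count proteomics with a binary trait
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' a protein x sample matrix of MS/MS spectral counts (assay `"counts"`),
#' per-protein amino-acid lengths (`rowData$protein_length`, used for NSAF
#' normalisation) and a binary per-sample trait (`colData$trait`; 1 = HOT,
#' 0 = COLD).
#'
#' Validity requires: integral non-negative counts, unique protein ids,
#' strictly positive lengths, and trait values in \{0, 1\}.
#'
#' @seealso [SpectralCountExperiment()] for construction,
#'   [readSpectralCounts()] to build one from TSV files.
#' @export
setClass("SpectralCountExperiment",
         contains = "SummarizedExperiment")

setValidity("SpectralCountExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(is.na(cnt)))
      msg <- c(msg, "counts contain missing values")
    else {
      if (any(cnt < 0)) {
        bad <- which(cnt < 0, arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("negative count at protein '%s', sample '%s'",
                              rownames(cnt)[bad[1]], colnames(cnt)[bad[2]]))
      }
      if (any(cnt != round(cnt))) {
        bad <- which(cnt != round(cnt), arr.ind = TRUE)[1, ]
        msg <- c(msg, sprintf("non-integer count at protein '%s', sample '%s'",
                              rownames(cnt)[bad[1]], colnames(cnt)[bad[2]]))
      }
    }
  }
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids))
    msg <- c(msg, "protein ids (rownames) are required")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate protein id '%s'",
                          ids[duplicated(ids)][1]))
  len <- SummarizedExperiment::rowData(object)$protein_length
  if (is.null(len))
    msg <- c(msg, "rowData column 'protein_length' is required")
  else if (any(is.na(len)) || any(len <= 0))
    msg <- c(msg, "protein_length must be positive for every protein")
  tr <- SummarizedExperiment::colData(object)$trait
  if (is.null(tr))
    msg <- c(msg, "colData column 'trait' is required")
  else if (!all(tr %in% c(0L, 1L)))
    msg <- c(msg, "trait must be coded 0 (COLD) / 1 (HOT)")
  if (length(msg)) msg else TRUE
})

#' Weighted co-expression network state
#'
#' Holds the pairwise Pearson correlation matrix, the similarity convention
#' (`"unsigned"`: \eqn{|r|}; `"signed"`: \eqn{(1+r)/2}), the soft-threshold
#' power, the resulting adjacency, and the topological overlap matrix (TOM).
#' Adjacency and TOM are symmetric with unit diagonal and entries in [0, 1].
#'
#' @slot corr symmetric matrix of pairwise Pearson r.
#' @slot power soft-threshold exponent (beta).
#' @slot networkType `"unsigned"` or `"signed"`.
#' @slot adjacency soft-thresholded similarity matrix.
#' @slot tom topological overlap matrix.
#' @export
setClass("CoexpressionNetwork",
         representation(corr = "matrix", power = "numeric",
                        networkType = "character", adjacency = "matrix",
                        tom = "matrix"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  if (length(object@power) != 1L || object@power <= 0)
    msg <- c(msg, "power must be a single positive number")
  if (!object@networkType %in% c("unsigned", "signed"))
    msg <- c(msg, "networkType must be 'unsigned' or 'signed'")
  for (nm in c("adjacency", "tom")) {
    m <- slot(object, nm)
    if (nrow(m) && (min(m) < -1e-10 || max(m) > 1 + 1e-10))
      msg <- c(msg, sprintf("%s entries must lie in [0, 1]", nm))
  }
  if (length(msg)) msg else TRUE
})

#' Module partition of a co-expression network
#'
#' Result of average-linkage clustering of the TOM dissimilarity followed by
#' the cut-height ladder. Module label 0 is reserved for unassigned proteins
#' (colour "grey"); non-zero labels are ordered by decreasing module size.
#' Eigenproteins (first principal component per module, sample scores) and
#' the kME module-membership matrix are filled in by
#' [moduleEigenproteins()] / [moduleMembership()] when the partition is built
#' through [buildNetwork()] or [runPipeline()].
#'
#' @slot labels named integer vector, one entry per protein; 0 = unassigned.
#' @slot colors named character vector mapping module id to colour name.
#' @slot dendrogram the `hclust` merge tree of 1 - TOM.
#' @slot eigenproteins module x sample matrix of eigenprotein scores.
#' @slot kme protein x module matrix of module-membership correlations.
#' @slot minModuleSize minimum size enforced for non-zero modules.
#' @export
setClass("ModulePartition",
         representation(labels = "integer", colors = "character",
                        dendrogram = "ANY", eigenproteins = "matrix",
                        kme = "matrix", minModuleSize = "integer"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by protein id")
  if (any(object@labels < 0))
    msg <- c(msg, "labels must be >= 0")
  sz <- table(object@labels[object@labels > 0])
  if (length(sz) && length(object@minModuleSize) &&
      any(sz < object@minModuleSize))
    msg <- c(msg, "non-zero modules smaller than minModuleSize")
  if (nrow(object@kme) && any(abs(object@kme) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "kme values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpectralCountExperiment-class compact display
#' @param object a `SpectralCountExperiment`
#' @export
setMethod("show", "SpectralCountExperiment", function(object) {
  tr <- lesionTrait(object)
  cat("SpectralCountExperiment:", nrow(object), "proteins x",
      ncol(object), "samples\n")
  cat("  trait: ", sum(tr == 1), " HOT / ", sum(tr == 0), " COLD\n", sep = "")
  cat("  total spectra:", sum(spcCounts(object)), "\n")
  invisible(object)
})

#' @describeIn CoexpressionNetwork-class compact display
#' @param object a `CoexpressionNetwork`
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
  cat("CoexpressionNetwork:", nrow(object@adjacency), "proteins,",
      object@networkType, "similarity, power", object@power, "\n")
  invisible(object)
})

#' @describeIn ModulePartition-class compact display
#' @param object a `ModulePartition`
#' @export
setMethod("show", "ModulePartition", function(object) {
  nmod <- length(unique(object@labels[object@labels > 0]))
  cat("ModulePartition:", nmod, "modules over", length(object@labels),
      "proteins;", sum(object@labels == 0), "unassigned (grey)\n")
  if (nmod) {
    sz <- sort(table(object@labels[object@labels > 0]), decreasing = TRUE)
    cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
        if (nmod > 10) "..." else "", "\n")
  }
  invisible(object)
})
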