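#' Construct a SpectralCountExperiment
#'
#' @param counts integer matrix, proteins x samples, with rownames
#'   (protein accessions) and colnames (sample ids).
#' @param lengths named numeric vector of amino-acid lengths; must cover
#'   every protein in `counts`.
#' @param trait named vector of sample traits: 1/0 or "HOT"/"COLD"
#'   (case-insensitive); must cover every sample.
#' @return a validated [SpectralCountExperiment-class]
#' @examples
#' cnt <- matrix(c(1, 0, 2, 3, 0, 0), 3, 2, byrow = TRUE,
#'               dimnames = list(c("P1", "P2", "P3"), c("S1", "S2")))
#' SpectralCountExperiment(cnt, c(P1 = 100, P2 = 200, P3 = 150),
#'                         c(S1 = "HOT", S2 = "COLD"))
#' @export
SpectralCountExperiment <- function(counts, lengths, trait) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have protein rownames and sample colnames")
  if (is.numeric(counts) && !is.integer(counts) &&
      !anyNA(counts) && all(counts == round(counts)))
    storage.mode(counts) <- "integer"
  miss <- setdiff(rownames(counts), names(lengths))
  if (length(miss))
    stop("no length for protein(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(colnames(counts), names(trait))
  if (length(miss))
    stop("no trait for sample(s): ", paste(miss, collapse = ", "))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(
      protein_length = as.numeric(lengths[rownames(counts)]),
      row.names = rownames(counts)),
    colData = S4Vectors::DataFrame(
      trait = .parseTrait(trait[colnames(counts)]),
      row.names = colnames(counts)))
  methods::validObject(obj <- methods::new("SpectralCountExperiment", se))
  obj
}

# map "HOT"/"COLD"/1/0 to integer 1/0; anything else is an error naming the
# offending label
.parseTrait <- function(x) {
  lab <- toupper(trimws(as.character(x)))
  out <- ifelse(lab %in% c("HOT", "1"), 1L,
                ifelse(lab %in% c("COLD", "0"), 0L, NA_integer_))
  if (anyNA(out))
    stop("unknown trait label '", lab[which(is.na(out))[1]],
         "' (expected HOT/COLD or 1/0)")
  out
}

#' Read a spectral-count dataset from TSV files
#'
#' Expects three tab-separated files: a counts table (first column
#' `protein_id`, remaining columns one per sample, integer cells), a lengths
#' table (`protein_id`, `length_aa`) and a traits table (`sample_id`,
#' `trait` with values HOT/COLD, case-insensitive, or 1/0). Lines starting
#' with `#` are ignored. Row and column order of the counts file is
#' preserved.
#'
#' Individual LC-MS/MS runs may be stored as separate columns; passing
#' `runMap` (data.frame with columns `run`, `sample`) aggregates run columns
#' into one column per sample by `aggregate` ("sum", the default, or
#' "mean" rounded to the nearest integer).
#'
#' @param countsPath,lengthsPath,traitsPath file paths.
#' @param runMap optional run-to-sample mapping (see Details).
#' @param aggregate how to combine runs of a sample: `"sum"` or `"mean"`.
#' @return a [SpectralCountExperiment-class]
#' @export
readSpectralCounts <- function(countsPath, lengthsPath, traitsPath,
                               runMap = NULL,
                               aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  for (p in c(countsPath, lengthsPath, traitsPath))
    if (!file.exists(p)) stop("file not found: ", p)
  ctab <- read.delim(countsPath, header = TRUE, sep = "\t",
                     comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
  if (ncol(ctab) < 2) stop("counts file needs protein_id plus sample columns")
  ids <- as.character(ctab[[1]])
  if (anyDuplicated(ids))
    stop("duplicate protein id '", ids[duplicated(ids)][1],
         "' in counts file")
  cnt <- as.matrix(ctab[, -1, drop = FALSE])
  if (!is.numeric(cnt) || anyNA(cnt))
    stop("counts file contains non-numeric or missing cells")
  bad <- which(cnt < 0 | cnt != round(cnt), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at protein '%s', column '%s'",
                 ids[bad[1, 1]], colnames(cnt)[bad[1, 2]]))
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- ids
  if (!is.null(runMap)) {
    if (!all(c("run", "sample") %in% colnames(runMap)))
      stop("runMap needs columns 'run' and 'sample'")
    miss <- setdiff(colnames(cnt), runMap$run)
    if (length(miss))
      stop("runMap does not cover run(s): ", paste(miss, collapse = ", "))
    smp <- as.character(runMap$sample[match(colnames(cnt), runMap$run)])
    agg <- vapply(unique(smp), function(s) {
      block <- cnt[, smp == s, drop = FALSE]
      v <- if (aggregate == "sum") rowSums(block) else rowMeans(block)
      as.integer(round(v))
    }, integer(nrow(cnt)))
    agg <- matrix(agg, nrow = nrow(cnt),
                  dimnames = list(rownames(cnt), unique(smp)))
    cnt <- agg
  }
  ltab <- read.delim(lengthsPath, header = TRUE, sep = "\t",
                     comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "length_aa") %in% colnames(ltab)))
    stop("lengths file needs columns protein_id, length_aa")
  lengths <- setNames(ltab$length_aa, ltab$protein_id)
  ttab <- read.delim(traitsPath, header = TRUE, sep = "\t",
                     comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "trait") %in% colnames(ttab)))
    stop("traits file needs columns sample_id, trait")
  trait <- setNames(ttab$trait, ttab$sample_id)
  SpectralCountExperiment(cnt, lengths, trait)
}

#' Write a spectral-count dataset as TSV files
#'
#' Emits `counts.tsv`, `lengths.tsv` and `traits.tsv` into `dir` in the
#' format read back by [readSpectralCounts()] (deterministic column order;
#' a `#` header comment line carries the tool version).
#'
#' @param x a [SpectralCountExperiment-class]
#' @param dir output directory (created if absent).
#' @return invisibly, the three file paths.
#' @export
writeSpectralCounts <- function(x, dir) {
  stopifnot(methods::is(x, "SpectralCountExperiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- paste0("# wpcna ", as.character(packageVersion("wpcna")))
  paths <- file.path(dir, c("counts.tsv", "lengths.tsv", "traits.tsv"))
  cdf <- data.frame(protein_id = rownames(x), spcCounts(x),
                    check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(cdf, paths[1], hdr)
  .writeTsv(data.frame(protein_id = rownames(x),
                       length_aa = proteinLengths(x)), paths[2], hdr)
  .writeTsv(data.frame(sample_id = colnames(x),
                       trait = ifelse(lesionTrait(x) == 1, "HOT", "COLD")),
            paths[3], hdr)
  invisible(paths)
}

.writeTsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Per-protein detection flags by trait group
#'
#' A protein is "detected" in a group when its total spectral count over the
#' samples of that group is greater than zero (any assigned spectrum).
#'
#' @param x a [SpectralCountExperiment-class]
#' @return logical matrix, proteins x c("hot", "cold").
#' @export
presenceFlags <- function(x) {
  stopifnot(methods::is(x, "SpectralCountExperiment"))
  tr <- lesionTrait(x)
  cnt <- spcCounts(x)
  cbind(hot  = rowSums(cnt[, tr == 1, drop = FALSE]) > 0,
        cold = rowSums(cnt[, tr == 0, drop = FALSE]) > 0)
}

#' @rdname vennSummary
#' @export
setMethod("vennSummary", "SpectralCountExperiment", function(x) {
  fl <- presenceFlags(x)
  nh <- sum(fl[, "hot"] & !fl[, "cold"])
  nc <- sum(!fl[, "hot"] & fl[, "cold"])
  nb <- sum(fl[, "hot"] & fl[, "cold"])
  vennSummaryCounts(nh + nc + nb, nh, nc)
})

#' Venn summary from detection counts
#'
#' Builds the same summary as [vennSummary()] directly from the three
#' detection counts (total detected, HOT-unique, COLD-unique), e.g. when
#' only published tallies are available.
#'
#' @param nTotal proteins detected in at least one group.
#' @param nHotUnique,nColdUnique proteins detected in exactly one group.
#' @return a `VennSummary` list; see [vennSummary()].
#' @examples
#' v <- vennSummaryCounts(1862, 476, 180)
#' v$pct_common_rounded  # 65
#' @export
vennSummaryCounts <- function(nTotal, nHotUnique, nColdUnique) {
  if (nTotal <= 0) stop("no detected proteins")
  if (nHotUnique < 0 || nColdUnique < 0 || nHotUnique + nColdUnique > nTotal)
    stop("inconsistent detection counts")
  nCommon <- nTotal - nHotUnique - nColdUnique
  pct <- 100 * c(hot_unique = nHotUnique, cold_unique = nColdUnique,
                 common = nCommon) / nTotal
  out <- list(n_total = nTotal, n_hot_unique = nHotUnique,
              n_cold_unique = nColdUnique, n_common = nCommon,
              pct_hot_unique = unname(pct["hot_unique"]),
              pct_cold_unique = unname(pct["cold_unique"]),
              pct_common = unname(pct["common"]),
              pct_hot_unique_rounded = .roundHalfAway(pct[["hot_unique"]]),
              pct_cold_unique_rounded = .roundHalfAway(pct[["cold_unique"]]),
              pct_common_rounded = .roundHalfAway(pct[["common"]]))
  class(out) <- "VennSummary"
  out
}

# nearest integer, halves away from zero (commercial rounding)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.VennSummary <- function(x, ...) {
  cat(sprintf("VennSummary: %d detected proteins\n", x$n_total))
  cat(sprintf("  HOT-unique : %5d (%5.1f%%, ~%d%%)\n", x$n_hot_unique,
              x$pct_hot_unique, x$pct_hot_unique_rounded))
  cat(sprintf("  COLD-unique: %5d (%5.1f%%, ~%d%%)\n", x$n_cold_unique,
              x$pct_cold_unique, x$pct_cold_unique_rounded))
  cat(sprintf("  common     : %5d (%5.1f%%, ~%d%%)\n", x$n_common,
              x$pct_common, x$pct_common_rounded))
  invisible(x)
}
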