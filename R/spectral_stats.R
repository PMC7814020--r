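#' Rsc: log2 fold change from pooled spectral counts
#'
#' Spectral-count fold change on the base-2 logarithmic scale with a
#' pseudo-count `f` guarding against zero counts:
#' \deqn{Rsc = \log_2\frac{n_2 + f}{n_1 + f} +
#'       \log_2\frac{t_1 - n_1 + f}{t_2 - n_2 + f}}
#' where \eqn{n_i} are the pooled counts of the protein in each group and
#' \eqn{t_i} the group totals. The value is the group-2 vs group-1 log2
#' ratio and is finite for all admissible inputs. Vectorised over proteins.
#'
#' @param n1,n2 per-protein pooled counts in group 1 / group 2.
#' @param t1,t2 total spectral counts of group 1 / group 2.
#' @param f pseudo-count, default 1.25.
#' @return numeric vector of log2 fold changes (group 2 vs group 1).
#' @examples
#' computeRsc(10, 40, 1000, 1000)   # ~1.92
#' @export
computeRsc <- function(n1, n2, t1, t2, f = 1.25) {
  .checkCounts(n1, n2, t1, t2)
  if (f <= 0) stop("pseudo-count f must be > 0")
  log2((n2 + f) / (n1 + f)) + log2((t1 - n1 + f) / (t2 - n2 + f))
}

.checkCounts <- function(n1, n2, t1, t2) {
  if (any(c(n1, n2, t1, t2) < 0)) stop("counts must be non-negative")
  if (any(t1 <= 0) || any(t2 <= 0)) stop("group totals must be positive")
  if (any(n1 > t1) || any(n2 > t2))
    stop("protein count exceeds its group total")
  invisible(TRUE)
}

#' NSAF: normalized spectral abundance factors
#'
#' Length-normalised relative abundance:
#' \eqn{NSAF_k = (SpC_k / L_k) / \sum_j (SpC_j / L_j)}. The result sums to 1
#' over the supplied proteins.
#'
#' @param counts per-protein spectral counts of one group (or sample).
#' @param lengths per-protein amino-acid lengths (same order).
#' @return numeric vector of NSAF values summing to 1.
#' @export
computeNsaf <- function(counts, lengths) {
  if (length(counts) != length(lengths))
    stop("counts and lengths differ in length")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("empty group: all spectral counts are zero")
  saf <- counts / lengths
  saf / sum(saf)
}

#' G-statistic test of equal proportional abundance
#'
#' Likelihood-ratio goodness-of-fit test on the 2-cell table (count of a
#' protein in each group against the group totals). Expected counts are
#' \eqn{E_i = (n_1+n_2)\,t_i/(t_1+t_2)}; \eqn{G = 2\sum_i n_i
#' \ln(n_i/E_i)} with the convention \eqn{0\ln(0/E) = 0}; the p-value is
#' the upper tail of the chi-square distribution with 1 degree of freedom.
#' Undetected proteins (\eqn{n_1+n_2 = 0}) get G = 0, p = 1 and
#' `detected = FALSE`. Vectorised over proteins.
#'
#' @inheritParams computeRsc
#' @return data.frame with columns `g_stat`, `p_value`, `detected`.
#' @examples
#' gTest(10, 0, 100, 100)  # G = 20*log(2) ~ 13.86
#' @export
gTest <- function(n1, n2, t1, t2) {
  .checkCounts(n1, n2, t1, t2)
  ns <- n1 + n2
  tt <- t1 + t2
  e1 <- ns * t1 / tt
  e2 <- ns * t2 / tt
  term <- function(n, e) ifelse(n == 0, 0, n * log(n / e))
  g <- 2 * (term(n1, e1) + term(n2, e2))
  g <- pmax(g, 0)          # guard tiny negative rounding
  p <- pchisq(g, df = 1, lower.tail = FALSE)
  det <- ns > 0
  g[!det] <- 0
  p[!det] <- 1
  data.frame(g_stat = g, p_value = p, detected = det)
}

#' Per-protein quantification table
#'
#' Pools spectral counts over the samples of each trait group and computes,
#' per protein: group counts, group NSAF (on pooled counts; each column sums
#' to 1 over the proteins detected in that group), the HOT-vs-COLD Rsc log2
#' fold change, the G statistic with its chi-square(1) p-value, and
#' detection flags.
#'
#' @param x a [SpectralCountExperiment-class] with both trait classes.
#' @param f pseudo-count for [computeRsc()], default 1.25.
#' @return data.frame, one row per protein, in dataset order.
#' @export
quantTable <- function(x, f = 1.25) {
  stopifnot(methods::is(x, "SpectralCountExperiment"))
  tr <- lesionTrait(x)
  if (length(unique(tr)) < 2)
    stop("both trait classes are required")
  cnt <- spcCounts(x)
  nHot <- rowSums(cnt[, tr == 1, drop = FALSE])
  nCold <- rowSums(cnt[, tr == 0, drop = FALSE])
  tHot <- sum(nHot)
  tCold <- sum(nCold)
  len <- proteinLengths(x)
  nsafH <- rep(0, nrow(cnt))
  nsafC <- rep(0, nrow(cnt))
  dh <- nHot > 0
  dc <- nCold > 0
  nsafH[dh] <- computeNsaf(nHot[dh], len[dh])
  nsafC[dc] <- computeNsaf(nCold[dc], len[dc])
  gt <- gTest(nCold, nHot, tCold, tHot)
  data.frame(protein_id = rownames(cnt),
             n_hot = nHot, n_cold = nCold,
             nsaf_hot = nsafH, nsaf_cold = nsafC,
             rsc = computeRsc(nCold, nHot, tCold, tHot, f),
             g_stat = gt$g_stat, p_value = gt$p_value,
             detected_hot = dh, detected_cold = dc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify proteins into the four trait groups
#'
#' Splits detected proteins into: `hot_unique` / `cold_unique` (detected in
#' one group only, irrespective of fold change) and `hot_up` / `cold_up`
#' (detected in both groups with `rsc > rscCut` resp. `rsc < -rscCut` and
#' `p_value < pCut`; strict inequalities). The `universe` holds every
#' detected protein. The four sets are pairwise disjoint.
#'
#' @param qt a quantification table from [quantTable()].
#' @param rscCut log2 fold-change threshold, default 1 (two-fold).
#' @param pCut G-test p-value threshold, default 0.05.
#' @return list of character vectors: `hot_unique`, `cold_unique`,
#'   `hot_up`, `cold_up`, `universe`.
#' @export
classifyGroups <- function(qt, rscCut = 1, pCut = 0.05) {
  if (rscCut <= 0 || pCut <= 0)
    stop("rscCut and pCut must be positive")
  det <- qt$detected_hot | qt$detected_cold
  both <- qt$detected_hot & qt$detected_cold
  list(hot_unique = qt$protein_id[qt$detected_hot & !qt$detected_cold],
       cold_unique = qt$protein_id[qt$detected_cold & !qt$detected_hot],
       hot_up = qt$protein_id[both & qt$rsc > rscCut & qt$p_value < pCut],
       cold_up = qt$protein_id[both & qt$rsc < -rscCut & qt$p_value < pCut],
       universe = qt$protein_id[det])
}
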