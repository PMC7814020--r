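#' Expression proxy from spectral counts
#'
#' Derives a real-valued protein x sample expression matrix for correlation
#' analysis. Transforms:
#' \describe{
#'   \item{`nsaf_log` (default)}{log2 of per-sample NSAF computed on
#'     pseudo-counted counts, \eqn{(SpC + pseudo)/L} column-renormalised.
#'     The pseudo-count keeps non-detected cells within ~1-2 log2 units of
#'     low-abundance detections, so Pearson correlations are not dominated
#'     by shared-zero patterns.}
#'   \item{`nsaf_log_eps`}{the plain variant log2(NSAF + eps) with NSAF on
#'     raw counts; zeros map to log2(eps).}
#'   \item{`log_count`}{log2(SpC + pseudo), no length normalisation.}
#'   \item{`raw`}{the counts unchanged.}
#' }
#' Proteins detected in fewer than `minDetect` samples or with zero
#' variance across samples are dropped (a message reports how many).
#'
#' @param x a [SpectralCountExperiment-class] with at least 3 samples.
#' @param transform one of `"nsaf_log"`, `"nsaf_log_eps"`, `"log_count"`,
#'   `"raw"`.
#' @param minDetect minimum number of samples with a positive count.
#' @param pseudo pseudo-count for the pseudo-counted transforms.
#' @param eps offset for `"nsaf_log_eps"`.
#' @return numeric matrix (retained proteins x samples) with attributes
#'   `derivation_tag` (the transform) and `dropped` (ids of removed
#'   proteins).
#' @export
makeExpression <- function(x, transform = c("nsaf_log", "nsaf_log_eps",
                                            "log_count", "raw"),
                           minDetect = 3, pseudo = 0.5, eps = 1e-6) {
  stopifnot(methods::is(x, "SpectralCountExperiment"))
  transform <- match.arg(transform)
  if (ncol(x) < 3)
    stop("correlation needs at least 3 samples")
  cnt <- spcCounts(x)
  len <- proteinLengths(x)
  expr <- switch(transform,
    nsaf_log = {
      rate <- (cnt + pseudo) / len
      log2(sweep(rate, 2, colSums(rate), "/"))
    },
    nsaf_log_eps = {
      rate <- cnt / len
      log2(sweep(rate, 2, colSums(rate), "/") + eps)
    },
    log_count = log2(cnt + pseudo),
    raw = cnt * 1.0)
  keep <- rowSums(cnt > 0) >= minDetect &
    apply(expr, 1, function(v) var(v) > 0)
  dropped <- rownames(cnt)[!keep]
  if (length(dropped))
    message(length(dropped),
            " protein(s) dropped (low detection or zero variance)")
  out <- expr[keep, , drop = FALSE]
  attr(out, "derivation_tag") <- transform
  attr(out, "dropped") <- dropped
  out
}

#' Pairwise Pearson correlation of protein profiles
#'
#' @param expr protein x sample expression matrix (no zero-variance rows).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(expr) {
  if (ncol(expr) < 3) stop("correlation needs at least 3 samples")
  v <- apply(expr, 1, var)
  if (any(v == 0))
    stop("zero-variance profile for protein '",
         rownames(expr)[which(v == 0)[1]],
         "' (drop it with makeExpression first)")
  r <- cor(t(expr))
  (r + t(r)) / 2
}

#' Soft-thresholded adjacency from correlations
#'
#' `unsigned`: similarity \eqn{s = |r|}; `signed`: \eqn{s = (1+r)/2}.
#' Adjacency is \eqn{a = s^\beta} with the diagonal fixed at 1.
#'
#' @param corr symmetric correlation matrix.
#' @param power soft-threshold exponent beta (> 0); 10 reproduces the
#'   default pipeline setting.
#' @param networkType `"unsigned"` (default) or `"signed"`.
#' @return adjacency matrix in [0, 1] with unit diagonal.
#' @export
adjacencyFromCor <- function(corr, power = 10,
                             networkType = c("unsigned", "signed")) {
  networkType <- match.arg(networkType)
  if (power <= 0) stop("power must be positive")
  s <- if (networkType == "signed") (1 + corr) / 2 else abs(corr)
  a <- s^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit across candidate powers
#'
#' For each candidate power the connectivities \eqn{k_i = \sum_{j \ne i}
#' a_{ij}} are binned into ~`nBins` equal-occupancy bins; the log10 degree
#' density per bin is regressed on the log10 mean connectivity and the
#' signed fit index \eqn{-\mathrm{sign}(slope)\,R^2} is reported together
#' with mean/median/max connectivity. The chosen power is the smallest one
#' whose signed \eqn{R^2} reaches `targetR2`; if none does, the power with
#' the best fit is returned with a warning. Degenerate connectivity
#' distributions (a single usable bin) yield `NA` fits, never an error.
#'
#' @param expr protein x sample expression matrix.
#' @param powers candidate soft-threshold powers (positive).
#' @param targetR2 signed R-squared considered an acceptable scale-free fit.
#' @param networkType passed to [adjacencyFromCor()].
#' @param nBins number of connectivity bins.
#' @return list with `fit_table` (data.frame: power, r2_signed, mean_k,
#'   median_k, max_k) and `power` (the chosen value).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, targetR2 = 0.8,
                              networkType = c("unsigned", "signed"),
                              nBins = 10) {
  networkType <- match.arg(networkType)
  if (!length(powers) || any(powers <= 0))
    stop("powers must be a non-empty vector of positive values")
  corr <- correlationMatrix(expr)
  s <- if (networkType == "signed") (1 + corr) / 2 else abs(corr)
  diag(s) <- 0
  tab <- do.call(rbind, lapply(powers, function(b) {
    k <- rowSums(s^b)
    data.frame(power = b, r2_signed = .scaleFreeR2(k, nBins),
               mean_k = mean(k), median_k = median(k), max_k = max(k))
  }))
  ok <- which(!is.na(tab$r2_signed) & tab$r2_signed >= targetR2)
  if (length(ok)) {
    chosen <- tab$power[ok[1]]
  } else if (all(is.na(tab$r2_signed))) {
    warning("scale-free fit undefined for every power; ",
            "falling back to the first candidate")
    chosen <- tab$power[1]
  } else {
    chosen <- tab$power[which.max(tab$r2_signed)]
    warning("no power reached target R^2 = ", targetR2,
            "; using best-fitting power ", chosen)
  }
  list(fit_table = tab, power = chosen)
}

# signed scale-free fit index from a connectivity vector; NA when the
# degree distribution collapses into < 3 usable bins
.scaleFreeR2 <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  br <- unique(quantile(k, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 4) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  cnt <- tabulate(bin, nbins = nlevels(bin))
  wid <- diff(br)
  dens <- (cnt / length(k)) / wid
  mk <- tapply(k, bin, mean)
  use <- cnt > 0 & dens > 0 & mk > 0
  if (sum(use) < 3) return(NA_real_)
  fit <- lm(log10(dens[use]) ~ log10(as.numeric(mk[use])))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Topological overlap matrix
#'
#' For \eqn{i \ne j}: \eqn{TOM_{ij} = (\ell_{ij} + a_{ij}) /
#' (\min(k_i, k_j) + 1 - a_{ij})} with \eqn{\ell_{ij} = \sum_{u \ne i,j}
#' a_{iu} a_{uj}} and \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1.
#' A zero denominator (fully isolated pair) yields TOM = 0.
#'
#' @param adj adjacency matrix with unit diagonal (from
#'   [adjacencyFromCor()]).
#' @return TOM similarity matrix in [0, 1] with unit diagonal.
#' @export
tomSimilarity <- function(adj) {
  if (nrow(adj) != ncol(adj)) stop("adjacency must be square")
  if (any(abs(diag(adj) - 1) > 1e-8))
    stop("adjacency must have unit diagonal")
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a                     # diag(a)=0 removes u = i, j terms
  den <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / den
  zero <- den <= 0
  if (any(zero[upper.tri(zero)]))
    message("isolated pair(s): TOM set to 0 where the denominator is 0")
  tom[zero] <- 0
  tom <- (tom + t(tom)) / 2
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Build the weighted co-expression network in one step
#'
#' Convenience composition of [correlationMatrix()], [adjacencyFromCor()]
#' and [tomSimilarity()].
#'
#' @inheritParams adjacencyFromCor
#' @param expr protein x sample expression matrix.
#' @return a [CoexpressionNetwork-class]
#' @export
buildNetwork <- function(expr, power = 10,
                         networkType = c("unsigned", "signed")) {
  networkType <- match.arg(networkType)
  corr <- correlationMatrix(expr)
  adj <- adjacencyFromCor(corr, power, networkType)
  methods::new("CoexpressionNetwork", corr = corr, power = power,
               networkType = networkType, adjacency = adj,
               tom = tomSimilarity(adj))
}

# fixed ordered module palette; grey is reserved for unassigned (label 0)
.modulePalette <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta",
  "sienna", "yellowgreen", "skyblue3", "plum", "orangered", "mediumpurple")

#' Detect modules by dynamic cut of the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity 1 - TOM,
#' followed by a static cut whose height is taken from a `deepSplit`
#' sensitivity ladder: the tree is cut at the fraction \{0.95, 0.90, 0.85,
#' 0.80, 0.75\}[`deepSplit` + 1] of the dendrogram height range (measured
#' from the lowest merge). Higher `deepSplit` cuts lower and splits more
#' aggressively. Branches smaller than `minModuleSize` are merged into the
#' unassigned label 0 ("grey"); remaining modules are renumbered by
#' decreasing size and given colours from a fixed ordered palette, so the
#' partition is reproducible and invariant to protein order up to
#' relabelling.
#'
#' @param tom TOM similarity matrix (or a
#'   [CoexpressionNetwork-class]).
#' @param minModuleSize smallest allowed module, default 5.
#' @param deepSplit split sensitivity, integer 0-4 (default 4).
#' @return a [ModulePartition-class] (eigenproteins/kME slots empty; see
#'   [moduleEigenproteins()]).
#' @export
detectModules <- function(tom, minModuleSize = 5, deepSplit = 4) {
  if (methods::is(tom, "CoexpressionNetwork")) tom <- tomMatrix(tom)
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  if (!deepSplit %in% 0:4) stop("deepSplit must be an integer in 0..4")
  n <- nrow(tom)
  ids <- rownames(tom)
  if (is.null(ids)) ids <- paste0("V", seq_len(n))
  if (n < minModuleSize) {
    labels <- setNames(rep(0L, n), ids)
    return(.newPartition(labels, NULL, minModuleSize))
  }
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  frac <- c(0.95, 0.90, 0.85, 0.80, 0.75)[deepSplit + 1]
  hr <- range(tree$height)
  cl <- cutree(tree, h = hr[1] + frac * diff(hr))
  sz <- table(cl)
  cl[cl %in% as.integer(names(sz)[sz < minModuleSize])] <- 0L
  labels <- setNames(.renumberBySize(cl), ids)
  .newPartition(labels, tree, minModuleSize)
}

# renumber non-zero labels by decreasing cluster size (ties: first
# appearance), keeping 0 for unassigned
.renumberBySize <- function(cl) {
  nz <- cl[cl != 0]
  if (!length(nz)) return(as.integer(cl))
  sz <- sort(table(nz), decreasing = TRUE)
  map <- setNames(seq_along(sz), names(sz))
  ifelse(cl == 0, 0L, as.integer(map[as.character(cl)]))
}

.newPartition <- function(labels, tree, minModuleSize,
                          eig = matrix(0, 0, 0), kme = matrix(0, 0, 0)) {
  mods <- sort(unique(labels[labels > 0]))
  pal <- rep_len(.modulePalette, max(length(mods), 1))
  colors <- setNames(c("grey", pal[seq_along(mods)]),
                     c("0", as.character(mods)))
  methods::new("ModulePartition", labels = labels, colors = colors,
               dendrogram = tree, eigenproteins = eig, kme = kme,
               minModuleSize = as.integer(minModuleSize))
}

#' Module eigenproteins (first principal components)
#'
#' Per non-zero module: member profiles are standardised (mean 0, sd 1
#' across samples) and the first right singular vector of the member x
#' sample matrix is taken as the eigenprotein (unit norm, one score per
#' sample). The sign is oriented so that the mean correlation with the
#' member profiles is non-negative.
#'
#' @param expr protein x sample expression matrix.
#' @param partition a [ModulePartition-class] or a named label vector.
#' @return matrix, modules ("WM1", "WM2", ...) x samples.
#' @export
moduleEigenproteins <- function(expr, partition) {
  labels <- if (methods::is(partition, "ModulePartition"))
    moduleLabels(partition) else partition
  labels <- labels[rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no non-zero modules")
  eig <- t(vapply(mods, function(m) {
    mem <- expr[labels == m, , drop = FALSE]
    if (nrow(mem) < 2)
      stop("module ", m, " has fewer than 2 members")
    z <- t(scale(t(mem)))          # standardise each profile
    z[is.na(z)] <- 0               # constant members carry no direction
    sv <- svd(z, nu = 0, nv = 1)
    e <- sv$v[, 1]
    cors <- suppressWarnings(cor(e, t(z)))
    if (mean(cors, na.rm = TRUE) < 0) e <- -e
    e
  }, numeric(ncol(expr))))
  dimnames(eig) <- list(paste0("WM", mods), colnames(expr))
  eig
}

#' Module membership (kME)
#'
#' Pearson correlation of every protein profile with every module
#' eigenprotein.
#'
#' @param expr protein x sample expression matrix.
#' @param eig eigenprotein matrix from [moduleEigenproteins()].
#' @return protein x module matrix of correlations in [-1, 1].
#' @export
moduleMembership <- function(expr, eig) {
  kme <- cor(t(expr), t(eig))
  dimnames(kme) <- list(rownames(expr), rownames(eig))
  kme
}

#' Fill a partition with eigenproteins and kME
#'
#' @param expr protein x sample expression matrix.
#' @param partition a [ModulePartition-class] from [detectModules()].
#' @return the partition with `eigenproteins` and `kme` slots populated.
#' @export
addModuleSummaries <- function(expr, partition) {
  stopifnot(methods::is(partition, "ModulePartition"))
  eig <- moduleEigenproteins(expr, partition)
  partition@eigenproteins <- eig
  partition@kme <- moduleMembership(expr, eig)
  methods::validObject(partition)
  partition
}

#' Merge modules with similar eigenproteins
#'
#' Optional post-processing: iteratively merges the pair of modules whose
#' eigenproteins are most correlated while their dissimilarity
#' \eqn{1 - r} is below `cutHeight`. Off by default in [runPipeline()].
#'
#' @param expr protein x sample expression matrix.
#' @param partition a [ModulePartition-class].
#' @param cutHeight eigenprotein dissimilarity threshold, default 0.25.
#' @return a relabelled [ModulePartition-class].
#' @export
mergeModules <- function(expr, partition, cutHeight = 0.25) {
  stopifnot(methods::is(partition, "ModulePartition"))
  labels <- moduleLabels(partition)
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eig <- moduleEigenproteins(expr, labels)
    ce <- cor(t(eig))
    diag(ce) <- -Inf
    i <- which(ce == max(ce), arr.ind = TRUE)[1, ]
    if (1 - ce[i[1], i[2]] >= cutHeight) break
    labels[labels == mods[i[2]]] <- mods[i[1]]
  }
  labels <- setNames(.renumberBySize(labels), names(labels))
  out <- .newPartition(labels, partition@dendrogram,
                       partition@minModuleSize)
  if (nrow(partition@eigenproteins)) out <- addModuleSummaries(expr, out)
  out
}
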