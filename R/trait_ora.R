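#' Module-trait association
#'
#' Pearson correlation of each module eigenprotein with the binary trait,
#' with a two-sided Student-t p-value (df = n_samples - 2). Modules are
#' classified `significant` (|r| > 0.5 and p < 0.05), `moderate`
#' (|r| > 0.4) or `none`; inequalities are strict. A constant eigenprotein
#' yields `NA` with a warning.
#'
#' @param eig eigenprotein matrix (modules x samples) from
#'   [moduleEigenproteins()].
#' @param trait named binary vector (1 = HOT, 0 = COLD) covering the
#'   samples.
#' @return data.frame: module, r, p, classification.
#' @export
moduleTraitCorrelation <- function(eig, trait) {
  trait <- trait[colnames(eig)]
  if (anyNA(trait)) stop("trait does not cover every sample")
  if (length(unique(trait)) < 2) stop("trait must contain both classes")
  n <- ncol(eig)
  if (n < 3) stop("at least 3 samples are required")
  res <- t(apply(eig, 1, function(e) {
    if (var(e) == 0) {
      warning("constant eigenprotein: correlation undefined")
      return(c(NA_real_, NA_real_))
    }
    r <- cor(e, trait)
    c(r, .corP(r, n))
  }))
  cls <- ifelse(is.na(res[, 1]), NA_character_,
         ifelse(abs(res[, 1]) > 0.5 & res[, 2] < 0.05, "significant",
         ifelse(abs(res[, 1]) > 0.4, "moderate", "none")))
  data.frame(module = rownames(eig), r = res[, 1], p = res[, 2],
             classification = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

# two-sided Student-t p-value for a Pearson correlation at sample size n
.corP <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  if (abs(r) == 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
}

#' Gene (protein) significance for a binary trait
#'
#' Absolute Pearson correlation of each protein profile with the trait.
#'
#' @param expr protein x sample expression matrix.
#' @param trait named binary vector covering the samples.
#' @return named numeric vector in [0, 1].
#' @export
geneSignificance <- function(expr, trait) {
  trait <- trait[colnames(expr)]
  if (anyNA(trait)) stop("trait does not cover every sample")
  gs <- abs(as.vector(cor(t(expr), trait)))
  setNames(gs, rownames(expr))
}

#' Module membership vs gene significance correlation
#'
#' Within one module, correlates |kME| with gene significance across the
#' member proteins and reports the Pearson r with its two-sided t p-value
#' (df = module size - 2). High values indicate that the proteins most
#' central to the module are also the most trait-associated.
#'
#' @param kme named vector of the module's kME values (members only, or a
#'   superset restricted by `members`).
#' @param gs named gene-significance vector from [geneSignificance()].
#' @param members character vector of member protein ids.
#' @return list with `r` and `p`.
#' @export
mmGsCorrelation <- function(kme, gs, members) {
  if (length(members) < 3)
    stop("module too small for MM-GS correlation (need >= 3 members)")
  mm <- abs(kme[members])
  g <- gs[members]
  if (anyNA(mm) || anyNA(g))
    stop("kME or gene significance missing for some members")
  r <- cor(mm, g)
  list(r = r, p = .corP(r, length(members)))
}

#' Upper-tail hypergeometric overlap probability
#'
#' Probability of observing at least `k` successes when drawing `m`
#' proteins without replacement from a universe of `N` containing `g`
#' group members:
#' \eqn{p = \sum_{i=k}^{\min(m,g)} \binom{g}{i}\binom{N-g}{m-i} /
#' \binom{N}{m}}. Vectorised.
#'
#' @param k observed overlap.
#' @param m module size.
#' @param g group size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @examples
#' hypergeomOverlap(3, 5, 4, 20)  # 496/15504
#' @export
hypergeomOverlap <- function(k, m, g, N) {
  if (any(k < 0 | m < 0 | g < 0 | N < 0))
    stop("counts must be non-negative")
  if (any(m > N) || any(g > N))
    stop("module or group larger than the universe")
  if (any(k > pmin(m, g)))
    stop("overlap exceeds min(module, group) size")
  phyper(k - 1, g, N - g, m, lower.tail = FALSE)
}

#' Hypergeometric over-representation screen of modules
#'
#' Tests every (module, protein-group) pair for over-representation of the
#' group inside the module with [hypergeomOverlap()], adjusts all cells
#' jointly by Benjamini-Hochberg, and aggregates per module over the four
#' groups: `screen_min_q` (most significant q) and `screen_max_q`
#' (least significant q). A module passes the screen when the chosen
#' aggregate is below `qCut`. The universe is the intersection of the
#' partition's proteins with `groups$universe`; modules, groups and
#' overlaps are all counted within it. Empty groups get p = 1 with a
#' warning; absence of passing modules is a valid result.
#'
#' @param partition a [ModulePartition-class] or named label vector.
#' @param groups list from [classifyGroups()].
#' @param qCut screening threshold on the aggregated q, default 0.05.
#' @param aggregate `"min_q"` (default) or `"max_q"`.
#' @return list with `cells` (module x group rows: overlap_k,
#'   module_size_m, group_size_g, universe_N, p_hyper, q) and `modules`
#'   (per-module screen_min_q, screen_max_q, screen_q, passes_screen;
#'   sorted by screen_q ascending).
#' @export
oraScreen <- function(partition, groups, qCut = 0.05,
                      aggregate = c("min_q", "max_q")) {
  aggregate <- match.arg(aggregate)
  if (qCut < 0) stop("qCut must be non-negative")
  labels <- if (methods::is(partition, "ModulePartition"))
    moduleLabels(partition) else partition
  universe <- intersect(names(labels), groups$universe)
  N <- length(universe)
  if (!N) stop("empty universe: partition and groups share no proteins")
  labU <- labels[universe]
  mods <- sort(unique(labU[labU > 0]))
  if (!length(mods)) stop("no non-zero modules in the universe")
  gnames <- c("hot_unique", "cold_unique", "hot_up", "cold_up")
  gsets <- lapply(groups[gnames], intersect, y = universe)
  if (any(lengths(gsets) == 0))
    warning("empty protein group(s): ",
            paste(gnames[lengths(gsets) == 0], collapse = ", "),
            " (cells get p = 1)")
  cells <- do.call(rbind, lapply(mods, function(mo) {
    mem <- universe[labU == mo]
    do.call(rbind, lapply(gnames, function(gn) {
      gs <- gsets[[gn]]
      data.frame(module = paste0("WM", mo), group = gn,
                 overlap_k = length(intersect(mem, gs)),
                 module_size_m = length(mem), group_size_g = length(gs),
                 universe_N = N, stringsAsFactors = FALSE)
    }))
  }))
  cells$p_hyper <- ifelse(cells$group_size_g == 0, 1,
                          hypergeomOverlap(cells$overlap_k,
                                           cells$module_size_m,
                                           cells$group_size_g,
                                           cells$universe_N))
  cells$q <- p.adjust(cells$p_hyper, method = "BH")
  agg <- vapply(split(cells$q, cells$module), function(q)
    c(min(q), max(q)), numeric(2))
  modules <- data.frame(module = colnames(agg),
                        screen_min_q = agg[1, ], screen_max_q = agg[2, ],
                        row.names = NULL, stringsAsFactors = FALSE)
  modules$screen_q <- if (aggregate == "min_q") modules$screen_min_q else
    modules$screen_max_q
  modules$passes_screen <- modules$screen_q < qCut
  modules <- modules[order(modules$screen_q, modules$module), ]
  rownames(modules) <- NULL
  list(cells = cells, modules = modules, aggregate = aggregate)
}
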