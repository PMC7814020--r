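#' Read a protein-protein interaction edge list
#'
#' Parses a two-column (optionally three, with a numeric weight)
#' tab-separated edge list into an undirected [igraph][igraph::graph]
#' graph. Self-loops are removed, duplicate undirected edges collapsed and
#' edges with an endpoint outside `nodeUniverse` dropped; a message reports
#' the removals. Malformed lines raise an error with the line number.
#'
#' @param path edge-list TSV (no header; lines starting with `#` ignored).
#' @param nodeUniverse character vector of admissible protein ids.
#' @return an undirected igraph with a `provenance` attribute; vertices are
#'   the universe members that appear in at least one kept edge.
#' @export
readEdgeList <- function(path, nodeUniverse) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2 | nf > 3)) {
    badLine <- which(keep)[which(nf < 2 | nf > 3)[1]]
    stop("malformed edge line ", badLine, ": expected 2 or 3 fields")
  }
  a <- vapply(fields, `[`, "", 1)
  b <- vapply(fields, `[`, "", 2)
  w <- vapply(fields, function(f) if (length(f) == 3)
    suppressWarnings(as.numeric(f[3])) else 1, numeric(1))
  if (anyNA(w)) {
    badLine <- which(keep)[which(is.na(w))[1]]
    stop("malformed edge line ", badLine, ": weight is not numeric")
  }
  self <- a == b
  if (any(self)) message(sum(self), " self-loop(s) removed")
  out <- !(a %in% nodeUniverse) | !(b %in% nodeUniverse)
  nOut <- sum(out & !self)
  if (nOut) message(nOut, " edge(s) outside the node universe dropped")
  use <- !self & !out
  lo <- pmin(a[use], b[use])
  hi <- pmax(a[use], b[use])
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) collapsed")
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo[!dup], to = hi[!dup], weight = w[use][!dup],
               stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::set_graph_attr(g, "provenance", path)
  g
}

#' Hub ranking of a module by interaction degree
#'
#' Computes the degree of every module member on the module-induced
#' subgraph of an interaction network and ranks members by decreasing
#' degree; ties are broken by decreasing intramodular connectivity
#' `kWithin` (when supplied) and then by lexicographic protein id, so the
#' ranking is deterministic. The top-20 flag and the hub flag (top 3 by
#' degree) follow the ranking. Members absent from the graph have degree 0.
#' When no edge is internal to the module, the ranking is flagged
#' degenerate (attribute `degenerate`).
#'
#' @param graph an igraph from [readEdgeList()].
#' @param members character vector of module protein ids.
#' @param kWithin optional named intramodular connectivity used for
#'   tie-breaking and `rank_kwithin` (defaults to 0).
#' @return data.frame per member: protein_id, degree, k_within,
#'   rank_degree, rank_kwithin, top20, is_hub.
#' @export
degreeRank <- function(graph, members, kWithin = NULL) {
  if (!length(members)) stop("module has no members")
  if (anyDuplicated(members)) stop("duplicate member ids")
  present <- intersect(members, igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, present)
  deg <- setNames(rep(0, length(members)), members)
  deg[igraph::V(sub)$name] <- igraph::degree(sub)
  kw <- setNames(rep(0, length(members)), members)
  if (!is.null(kWithin)) {
    kn <- intersect(names(kWithin), members)
    kw[kn] <- kWithin[kn]
  }
  ordDeg <- order(-deg, -kw, members)
  ordKw <- order(-kw, members)
  rankDeg <- rankKw <- integer(length(members))
  rankDeg[ordDeg] <- seq_along(members)
  rankKw[ordKw] <- seq_along(members)
  out <- data.frame(protein_id = members, degree = as.integer(deg),
                    k_within = as.numeric(kw),
                    rank_degree = rankDeg, rank_kwithin = rankKw,
                    top20 = rankDeg <= 20, is_hub = rankDeg <= 3,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_degree), ]
  rownames(out) <- NULL
  attr(out, "degenerate") <- all(deg == 0)
  out
}

#' Intramodular connectivity on the co-expression adjacency
#'
#' Splits each protein's total soft-thresholded connectivity into the part
#' within its own module (`k_within`; 0 for unassigned proteins) and the
#' rest (`k_out`); `k_within + k_out` equals the total connectivity.
#'
#' @param adj adjacency matrix from [adjacencyFromCor()].
#' @param partition a [ModulePartition-class] or named label vector.
#' @return data.frame: protein_id, module, k_within, k_out, k_total.
#' @export
intramodularConnectivity <- function(adj, partition) {
  labels <- if (methods::is(partition, "ModulePartition"))
    moduleLabels(partition) else partition
  labels <- labels[rownames(adj)]
  a <- adj
  diag(a) <- 0
  kTotal <- rowSums(a)
  kWithin <- vapply(seq_len(nrow(a)), function(i) {
    if (labels[i] == 0) return(0)
    sum(a[i, labels == labels[i]])
  }, numeric(1))
  data.frame(protein_id = rownames(adj), module = as.integer(labels),
             k_within = kWithin, k_out = kTotal - kWithin,
             k_total = kTotal, row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise correlation panel for selected proteins
#'
#' Pearson correlation and two-sided t p-value for every pair of the
#' requested proteins, as a square table plus a long-format list sorted by
#' decreasing |r|.
#'
#' @param expr protein x sample expression matrix (>= 3 samples).
#' @param ids protein ids to include; an unknown id is an error naming it.
#' @return list with `r` (square matrix), `p` (square matrix) and `pairs`
#'   (long data.frame: protein_a, protein_b, r, p).
#' @export
correlationPanel <- function(expr, ids) {
  miss <- setdiff(ids, rownames(expr))
  if (length(miss))
    stop("protein(s) not in the expression matrix: ",
         paste(miss, collapse = ", "))
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  sub <- expr[ids, , drop = FALSE]
  r <- cor(t(sub))
  n <- ncol(sub)
  p <- apply(r, c(1, 2), .corP, n = n)
  diag(p) <- 0
  ut <- which(upper.tri(r), arr.ind = TRUE)
  pairs <- data.frame(protein_a = ids[ut[, 1]], protein_b = ids[ut[, 2]],
                      r = r[ut], p = p[ut], stringsAsFactors = FALSE)
  pairs <- pairs[order(-abs(pairs$r), pairs$protein_a, pairs$protein_b), ]
  rownames(pairs) <- NULL
  list(r = r, p = p, pairs = pairs)
}
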