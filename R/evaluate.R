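#' Adjusted Rand index between two labelings
#'
#' Pair-counting agreement between two partitions, corrected for chance
#' (Hubert-Arabie). Label 0 ("unassigned") is treated as an ordinary class,
#' so leaving planted background unassigned counts as agreement.
#'
#' @param a,b label vectors of equal length.
#' @return the adjusted Rand index (1 = identical up to relabelling).
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Planted-structure recovery of the module pipeline
#'
#' Runs the network stage (expression, adjacency, TOM, module detection,
#' eigenproteins) on freshly simulated datasets and scores recovery against
#' the generator's ground truth: the adjusted Rand index between detected
#' and planted module labels (over all proteins; dropped or unassigned
#' proteins count as label 0), and, for every planted trait-linked module,
#' the |correlation| between the trait and the eigenprotein of the detected
#' module that overlaps it most.
#'
#' @param seeds integer vector of generator seeds, one replicate each.
#' @param preset generator preset name (see [simPreset()]).
#' @param config pipeline parameters ([pipelineConfig()]).
#' @return data.frame with one row per (seed, measure): seed, ari, and the
#'   per-trait-module recovery columns `trait_r` (NA when the preset plants
#'   no trait module).
#' @export
plantedRecovery <- function(seeds, preset = "default_paper_shape",
                            config = pipelineConfig()) {
  res <- lapply(seeds, function(s) {
    sim <- simulateDataset(simPreset(preset, seed = s))
    expr <- suppressMessages(
      makeExpression(sim$dataset, transform = config$transform,
                     minDetect = config$minDetect))
    net <- buildNetwork(expr, power = config$power,
                        networkType = config$networkType)
    part <- detectModules(net, minModuleSize = config$minModuleSize,
                          deepSplit = config$deepSplit)
    part <- addModuleSummaries(expr, part)
    truth <- sim$truth$module_of
    full <- setNames(rep(0L, length(truth)), names(truth))
    full[names(moduleLabels(part))] <- moduleLabels(part)
    tm <- simPreset(preset, seed = s)$traitModules
    traitR <- if (!length(tm)) NA_real_ else {
      eig <- eigenproteins(part)
      tr <- lesionTrait(sim$dataset)
      vapply(tm, function(m) {
        mem <- names(truth)[truth == m]
        dl <- full[mem]
        dl <- dl[dl > 0]
        if (!length(dl)) return(0)
        best <- as.integer(names(sort(table(dl), decreasing = TRUE))[1])
        abs(cor(eig[paste0("WM", best), ], tr))
      }, numeric(1))
    }
    data.frame(seed = s, ari = adjustedRandIndex(full, truth),
               trait_module = if (length(tm)) tm else NA_integer_,
               trait_r = traitR)
  })
  do.call(rbind, res)
}
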