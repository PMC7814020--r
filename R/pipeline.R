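#' Pipeline configuration
#'
#' Collects and validates every stage parameter of [runPipeline()].
#' Defaults follow the reference analysis: soft power 10, unsigned
#' similarity, minimum module size 5, deepSplit 4, |Rsc| > 1, p < 0.05 for
#' the upregulated groups and q < 0.05 for the ORA screen.
#'
#' @param power soft-threshold power, or `"auto"` to select by scale-free
#'   fit via [pickSoftThreshold()].
#' @param networkType `"unsigned"` or `"signed"`.
#' @param minModuleSize,deepSplit module detection parameters.
#' @param rscCut,pCut thresholds for [classifyGroups()].
#' @param qCut ORA screening threshold.
#' @param aggregate ORA aggregation, `"min_q"` or `"max_q"`.
#' @param transform,minDetect expression options for [makeExpression()].
#' @param fPseudo Rsc pseudo-count.
#' @param merge logical; merge similar modules (eigenprotein r > 0.75)
#'   before scoring. Off by default.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(power = 10, networkType = "unsigned",
                           minModuleSize = 5, deepSplit = 4,
                           rscCut = 1, pCut = 0.05, qCut = 0.05,
                           aggregate = "min_q", transform = "nsaf_log",
                           minDetect = 3, fPseudo = 1.25, merge = FALSE) {
  if (!identical(power, "auto") && (!is.numeric(power) || power <= 0))
    stop("power must be positive or 'auto'")
  if (!networkType %in% c("unsigned", "signed"))
    stop("networkType must be 'unsigned' or 'signed'")
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  if (!deepSplit %in% 0:4) stop("deepSplit must be in 0..4")
  if (rscCut <= 0 || pCut <= 0 || pCut > 1)
    stop("rscCut must be > 0 and pCut in (0, 1]")
  if (qCut < 0 || qCut > 1) stop("qCut must be in [0, 1]")
  if (!aggregate %in% c("min_q", "max_q"))
    stop("aggregate must be 'min_q' or 'max_q'")
  if (!transform %in% c("nsaf_log", "nsaf_log_eps", "log_count", "raw"))
    stop("unknown transform")
  if (minDetect < 1) stop("minDetect must be >= 1")
  if (fPseudo <= 0) stop("fPseudo must be > 0")
  cfg <- list(power = power, networkType = networkType,
              minModuleSize = minModuleSize, deepSplit = deepSplit,
              rscCut = rscCut, pCut = pCut, qCut = qCut,
              aggregate = aggregate, transform = transform,
              minDetect = minDetect, fPseudo = fPseudo,
              merge = isTRUE(merge))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full module-discovery pipeline
#'
#' Executes quantification, group classification, network construction,
#' module detection, module-trait correlation, the ORA screen and hub
#' ranking on one dataset, writing every intermediate artifact plus a
#' machine-readable `summary.json` into `outDir`. The pipeline contains no
#' randomness: rerunning with identical input and config reproduces
#' identical outputs byte for byte.
#'
#' Artifacts: `quant_table.tsv`, `groups.json`, `scalefree_fit.tsv` (when
#' `power = "auto"`), `modules.tsv`, `eigenproteins.tsv`,
#' `module_trait.tsv`, `ora_cells.tsv`, `ora_modules.tsv`, `hubs.tsv`,
#' `summary.json`.
#'
#' @param input a [SpectralCountExperiment-class], or a directory holding
#'   `counts.tsv`, `lengths.tsv`, `traits.tsv`.
#' @param outDir output directory (created if needed).
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @param edges optional path to a PPI edge list for degree-based hub
#'   ranking ([readEdgeList()]).
#' @param quiet suppress progress messages (warnings always shown).
#' @return invisibly, the run summary (also written as JSON).
#' @export
runPipeline <- function(input, outDir, config = pipelineConfig(),
                        edges = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  ds <- if (methods::is(input, "SpectralCountExperiment")) input else
    readSpectralCounts(file.path(input, "counts.tsv"),
                       file.path(input, "lengths.tsv"),
                       file.path(input, "traits.tsv"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  say <- function(...) if (!quiet) message("[wpcna] ", ...)
  hdr <- paste0("# wpcna ", as.character(packageVersion("wpcna")))
  stage <- "quant"
  summary <- tryCatch({
    say("quant: ", nrow(ds), " proteins, ", ncol(ds), " samples")
    qt <- quantTable(ds, f = config$fPseudo)
    .writeTsv(qt, file.path(outDir, "quant_table.tsv"), hdr)
    groups <- classifyGroups(qt, config$rscCut, config$pCut)
    jsonlite::write_json(groups, file.path(outDir, "groups.json"))
    venn <- vennSummary(ds)

    stage <- "network"
    expr <- suppressMessages(
      makeExpression(ds, transform = config$transform,
                     minDetect = config$minDetect))
    say("network: ", nrow(expr), " proteins enter the network (",
        length(attr(expr, "dropped")), " dropped)")
    power <- config$power
    if (identical(power, "auto")) {
      sft <- pickSoftThreshold(expr, networkType = config$networkType)
      .writeTsv(sft$fit_table, file.path(outDir, "scalefree_fit.tsv"), hdr)
      power <- sft$power
      say("network: auto-selected power ", power)
    }
    net <- buildNetwork(expr, power = power,
                        networkType = config$networkType)

    stage <- "modules"
    part <- detectModules(net, minModuleSize = config$minModuleSize,
                          deepSplit = config$deepSplit)
    if (config$merge) part <- mergeModules(expr, part)
    part <- addModuleSummaries(expr, part)
    labels <- moduleLabels(part)
    nMod <- length(unique(labels[labels > 0]))
    say("modules: ", nMod, " modules, ", sum(labels == 0), " unassigned")
    kme <- kmeMatrix(part)
    kmeOwn <- vapply(seq_along(labels), function(i)
      if (labels[i] == 0) NA_real_ else
        kme[i, paste0("WM", labels[i])], numeric(1))
    modTab <- data.frame(protein_id = names(labels),
                         module = as.integer(labels),
                         color = moduleColors(part)[as.character(labels)],
                         kme_own = kmeOwn, stringsAsFactors = FALSE)
    .writeTsv(modTab, file.path(outDir, "modules.tsv"), hdr)
    eig <- eigenproteins(part)
    .writeTsv(data.frame(module = rownames(eig), eig, check.names = FALSE),
              file.path(outDir, "eigenproteins.tsv"), hdr)

    stage <- "trait"
    trait <- lesionTrait(ds)
    mt <- moduleTraitCorrelation(eig, trait)
    .writeTsv(mt, file.path(outDir, "module_trait.tsv"), hdr)

    stage <- "ora"
    ora <- oraScreen(part, groups, qCut = config$qCut,
                     aggregate = config$aggregate)
    .writeTsv(ora$cells, file.path(outDir, "ora_cells.tsv"), hdr)
    .writeTsv(ora$modules, file.path(outDir, "ora_modules.tsv"), hdr)
    say("ora: ", sum(ora$modules$passes_screen), " module(s) pass the ",
        config$aggregate, " screen at q < ", config$qCut)

    stage <- "hubs"
    imc <- intramodularConnectivity(adjacencyMatrix(net), part)
    graph <- if (!is.null(edges))
      readEdgeList(edges, rownames(expr)) else NULL
    hubTab <- do.call(rbind, lapply(sort(unique(labels[labels > 0])),
                                    function(m) {
      mem <- names(labels)[labels == m]
      kw <- setNames(imc$k_within, imc$protein_id)[mem]
      if (!is.null(graph)) {
        dr <- degreeRank(graph, mem, kWithin = kw)
      } else {
        ordKw <- order(-kw, mem)
        rk <- integer(length(mem)); rk[ordKw] <- seq_along(mem)
        dr <- data.frame(protein_id = mem, degree = NA_integer_,
                         k_within = as.numeric(kw),
                         rank_degree = NA_integer_, rank_kwithin = rk,
                         top20 = rk <= 20, is_hub = rk <= 3,
                         stringsAsFactors = FALSE)
        dr <- dr[order(dr$rank_kwithin), ]
      }
      cbind(module = m, dr)
    }))
    .writeTsv(hubTab, file.path(outDir, "hubs.tsv"), hdr)

    list(tool_version = as.character(packageVersion("wpcna")),
         config = unclass(config),
         n_proteins = nrow(ds), n_samples = ncol(ds),
         n_network_proteins = nrow(expr),
         n_dropped = length(attr(expr, "dropped")),
         power_used = power,
         venn = list(pct_hot_unique = venn$pct_hot_unique,
                     pct_cold_unique = venn$pct_cold_unique,
                     pct_common = venn$pct_common),
         group_sizes = lapply(groups, length),
         modules_found = nMod,
         modules_passing_screen = sum(ora$modules$passes_screen),
         module_trait = mt)
  }, error = function(e) {
    file.create(file.path(outDir, paste0(stage, ".failed")))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
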