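# wpcna

Weighted protein co-expression network analysis for label-free
spectral-count proteomics with a binary trait.

## What it is for

In shotgun proteomics of microdissected tissue, each protein's abundance in
a sample is proxied by its spectral count (SpC) — the number of MS/MS
spectra assigned to it. Given a protein × sample count matrix from a
two-condition design (e.g. HOT vs COLD tumour regions, five lesions each),
`wpcna` discovers trait-associated protein modules in four steps:

1. **Quantify.** Pooled per-group counts give the log2 fold change
   *R*<sub>SC</sub> = log₂((n_H+f)/(n_C+f)) + log₂((t_C−n_C+f)/(t_H−n_H+f))
   (pseudo-count *f* = 1.25), NSAF relative abundances
   (SpC/L)/Σ(SpC/L), and a G-statistic likelihood-ratio test against the
   group totals (χ², 1 df). Proteins split into four disjoint groups:
   HOT-unique, COLD-unique (presence/absence) and HOT-up, COLD-up
   (|R<sub>SC</sub>| > 1 and p < 0.05).
2. **Network.** Pearson correlations of log2-NSAF profiles, soft-thresholded
   adjacency a = s^β (unsigned s = |r| by default, β = 10 or chosen by
   scale-free fit), topological overlap (TOM), average-linkage clustering of
   1 − TOM, and a deepSplit cut-height ladder with minimum module size 5.
   Modules are summarised by eigenproteins (first principal components) and
   per-protein module membership (kME).
3. **Screen.** Eigenprotein–trait correlation (|r| > 0.5 & p < 0.05
   significant, |r| > 0.4 moderate) and a hypergeometric over-representation
   screen of every module against the four protein groups, BH-adjusted
   jointly, with both min-q and max-q module verdicts at q < 0.05.
4. **Rank hubs.** Intramodular connectivity on the adjacency and, when a
   PPI edge list is supplied, degree on the module-induced subgraph; top-3
   hubs per module with deterministic tie-breaking.

A negative-binomial simulator with planted modules, trait effects and
presence/absence groups (`simPreset("default_paper_shape")`) provides
ground truth for every stage.

## Worked example

```r
library(wpcna)

sim <- simulateDataset(simPreset("default_paper_shape", seed = 7))
sim$dataset
#> SpectralCountExperiment: 1800 proteins x 10 samples
#>   trait: 5 HOT / 5 COLD
#>   total spectra: 264653

vennSummary(sim$dataset)
#> VennSummary: 1799 detected proteins
#>   HOT-unique :   466 ( 25.9%, ~26%)
#>   COLD-unique:   184 ( 10.2%, ~10%)
#>   common     :  1149 ( 63.9%, ~64%)

summary <- runPipeline(sim$dataset, "run1")
#> [wpcna] quant: 1800 proteins, 10 samples
#> [wpcna] network: 1678 proteins enter the network (122 dropped)
#> [wpcna] modules: 37 modules, 876 unassigned
#> [wpcna] ora: 24 module(s) pass the min_q screen at q < 0.05
```

The Venn block mirrors the detection structure planted by the preset
(~26% of detected proteins HOT-only, ~10% COLD-only). `run1/` then holds
the full audit trail: `quant_table.tsv` (per-protein R<sub>SC</sub>,
NSAF, G-test), `groups.json`, `modules.tsv` (module id, colour, own-module
kME), `eigenproteins.tsv`, `module_trait.tsv`, `ora_cells.tsv` /
`ora_modules.tsv` and `hubs.tsv`. For instance the module–trait table
starts:

```r
head(read.delim("run1/module_trait.tsv", comment.char = "#"), 3)
#>   module          r            p classification
#> 1    WM1 -0.9984190 2.728135e-11    significant
#> 2    WM2  0.6619596 3.706081e-02    significant
#> 3    WM3  0.8230925 3.440799e-03    significant
```

and the ORA verdicts (sorted by the aggregated q):

```r
head(read.delim("run1/ora_modules.tsv", comment.char = "#"), 3)
#>   module screen_min_q screen_max_q     screen_q passes_screen
#> 1    WM1 3.324622e-57            1 3.324622e-57         TRUE
#> 2    WM2 4.546997e-18            1 4.546997e-18         TRUE
#> 3    WM7 6.234357e-10            1 6.234357e-10         TRUE
```

WM1's eigenprotein tracks the trait almost perfectly (r = −0.998; the sign
is an orientation convention) and overlaps a differential protein group far
beyond chance — it is dominated by the planted COLD-favoured structure.
Reruns of `runPipeline()` on the same input are byte-identical; a shell
entry point is provided in `inst/scripts/run-pipeline.R`
(`simulate` and `run` subcommands).

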