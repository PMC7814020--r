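---
title: "Trait-associated protein co-expression modules from spectral counts"
author: "wpcna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-associated protein co-expression modules from spectral counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpcna)
```

## The problem

Label-free shotgun proteomics of microdissected tumour regions yields, for
every identified protein, the number of MS/MS spectra assigned to it in each
sample — the spectral count (SpC), a semi-quantitative abundance proxy. In a
two-condition design (here called HOT and COLD, e.g. regions of high and low
proliferative index within the same tumours, five samples each), two
complementary questions arise:

1. *Which proteins differ?* Presence/absence ("unique" proteins) and
   pooled-count fold changes with a count-based test.
2. *Which co-expression modules differ?* A weighted correlation network over
   all detected proteins, clustered into modules whose summary profiles
   (eigenproteins) are correlated with the trait, and screened for
   over-representation of the differential protein groups.

`wpcna` implements both layers and connects them with a hypergeometric
over-representation (ORA) screen, plus hub-protein ranking inside modules.
A synthetic-data generator with planted ground truth makes every stage
testable without access to patient data.

## Quantification layer

Counts are pooled over the samples of each trait group. For a protein with
pooled counts $n_H$, $n_C$ and group totals $t_H$, $t_C$:

* **Rsc** (log2 fold change, HOT vs COLD):
  $R_{SC} = \log_2\frac{n_H+f}{n_C+f} + \log_2\frac{t_C-n_C+f}{t_H-n_H+f}$.
  The pseudo-count $f$ keeps the statistic finite for zero counts; the
  default $f = 1.25$ is the value established in the spectral-count
  fold-change literature. It is exposed as a parameter because different
  depths may warrant different shrinkage.
* **NSAF**: $(SpC/L) / \sum_j (SpC_j/L_j)$ with $L$ the protein length in
  amino acids; a length-normalised relative abundance summing to 1 per
  group (or per sample, in the expression layer).
* **G-test**: the likelihood-ratio statistic on the 2-cell table
  ($n_H$ vs $n_C$ against the totals), with $0\ln(0/E) = 0$ and an upper
  chi-square(1) tail. Undetected proteins get $G = 0$, $p = 1$. No
  multiple-testing correction is applied here — the raw $p < 0.05$ is part
  of the group definition; correction happens in the ORA stage.

Detection is $SpC > 0$ in at least one sample of a group ("any assigned
spectrum"); no minimum-spectra filter is imposed. Four disjoint groups are
derived: HOT-unique and COLD-unique (detected in exactly one group,
irrespective of fold change), and HOT-up / COLD-up (detected in both,
$|R_{SC}| > 1$, i.e. more than two-fold, and $p < 0.05$; strict
inequalities). Triplicate LC-MS/MS runs per sample are assumed already
summed into one column; the reader accepts a run-to-sample map and sums
(or averages) runs when given one, since an aggregation rule cannot be
recovered from published tallies.

## Expression proxy

Correlation needs a real-valued matrix. The default transform is
`nsaf_log`: per-sample NSAF computed on pseudo-counted rates
$(SpC + 0.5)/L$, column-renormalised and taken to log2. The pseudo-count
matters: with a plain $\log_2(NSAF + \varepsilon)$ and small
$\varepsilon$, non-detected cells sit many log2 units below every detected
value, and Pearson correlations become dominated by shared-zero patterns
rather than by co-variation of abundance; module detection collapses. The
plain variant remains available as `nsaf_log_eps` for comparison, along
with `log_count` and `raw`. Proteins detected in fewer than `minDetect`
(default 3) samples, or with zero variance, are dropped with a logged
count.

## Network layer

* **Similarity**: pairwise Pearson correlation $r_{ij}$, turned into a
  similarity $s_{ij} = |r_{ij}|$ (unsigned, the default) or $(1+r_{ij})/2$
  (signed). Descriptions of this family of methods sometimes quote the
  *dissimilarity* $(1-r)/2$; clustering here is always on $1 - TOM$, with
  the similarity conventions above. Both network types are exposed because
  count-based studies rarely state which was used; unsigned treats strong
  negative co-variation as connectivity, signed does not.
* **Soft threshold**: $a_{ij} = s_{ij}^\beta$. The default $\beta = 10$
  matches the reference analysis; `pickSoftThreshold()` scans candidate
  powers, bins the connectivity distribution into ~10 equal-occupancy bins,
  regresses log-density on log-connectivity and reports the signed
  scale-free fit $R^2$, choosing the smallest power reaching 0.8 (falling
  back to the best fit with a warning). Degenerate (near-constant)
  connectivity yields `NA` fits rather than errors.
* **TOM**: $TOM_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$
  with $\ell_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$; unit diagonal; an
  isolated pair (zero denominator) gets $TOM = 0$.
* **Modules**: average-linkage clustering of $1 - TOM$, cut at a height
  taken from the `deepSplit` ladder — the fraction
  $\{0.95, 0.90, 0.85, 0.80, 0.75\}$ of the dendrogram height range for
  `deepSplit` $= 0 \dots 4$. Branches below `minModuleSize` (default 5)
  fold into the unassigned label 0 ("grey"). Labels are renumbered by
  decreasing size and coloured from a fixed palette, so output is
  reproducible and order-invariant up to relabelling. This is a documented
  static-ladder approximation of dynamic branch pruning, not a
  re-implementation of any particular tree-cut code; it is validated by
  planted-structure recovery, not label-for-label parity. On cleanly
  separable structure a deeper split yields at least as many modules; on
  noisy data the opposite can happen, because the lower cut fragments
  branches below the size threshold and the fragments fold into grey.
* **Eigenproteins and kME**: per module, member profiles are standardised
  and the first right singular vector (unit norm, one score per sample) is
  the eigenprotein, sign-oriented so the mean correlation with members is
  non-negative. kME is the correlation of every protein with every
  eigenprotein. An optional merge step
  (`mergeModules()`, eigenprotein dissimilarity $1-r < 0.25$) is provided
  but off by default, matching analyses that report unmerged modules.

## Trait association and the ORA screen

Module-trait association is the Pearson correlation of the eigenprotein
with the binary trait, with a two-sided Student-t p-value at
$n_{samples} - 2$ degrees of freedom; classification uses strict cuts
($|r| > 0.5$ and $p < 0.05$ significant; $|r| > 0.4$ moderate). Gene
significance is $|cor(\text{profile}, \text{trait})|$, and the MM-GS
correlation within a module measures whether its most central proteins are
also the most trait-associated.

The ORA screen tests every module against the four protein groups with the
upper-tail hypergeometric probability. Benjamini-Hochberg adjustment is
applied **jointly across all module-by-group cells** — the conservative,
reproducible choice when the original family is unknown. Per module, both
aggregations over the four q-values are reported side by side:
`screen_min_q` (the most significant group) and `screen_max_q` (the least
significant). The default verdict uses `min_q`, because published
descriptions of this screen are internally inconsistent about which extreme
is meant ("maximum q-value among the groups" vs "most significant
q-value"); neither mode is asserted to be the original. The universe is
the intersection of the network's proteins with the detected universe
(post-filter), switchable in principle to all identified proteins.

## Hub ranking

Two connectivities are reported per module member: the degree on the
module-induced subgraph of an imported PPI edge list, and `k_within`, the
sum of soft-thresholded adjacency to same-module proteins (the standard
intramodular connectivity; computed on the adjacency, not on TOM). Ranks
are deterministic: decreasing degree, ties broken by decreasing `k_within`
then lexicographic id. The top 3 by degree are flagged as hubs and the top
20 marked, mirroring common practice; whether a published "top 3" ranked by
PPI degree or by adjacency connectivity is usually ambiguous, so both ranks
are emitted.

## The synthetic-data generator

`simConfig()` defines, and `simulateDataset()` draws, datasets with known
ground truth under a latent-factor model on the log2 scale:

$$x_{ps} = b_p + \sigma_{prof}\left(\lambda_m f_{m(p),s} +
\sqrt{1-\lambda_m^2}\,\epsilon_{ps}\right) + \delta_{ps}, \qquad
\mu_{ps} = L_s \frac{2^{x_{ps}}}{\sum_q 2^{x_{qs}}},$$

with counts $\sim$ NB($\mu$, dispersion 0.3; $Var = \mu + 0.3\mu^2$),
matching the overdispersion of spectral counting. Trait-linked modules
have their factor shifted by `traitShift` log2 units in HOT samples;
planted "up" proteins carry $\delta = 3$ log2 units (an eight-fold
responder — strong enough to stay recoverable as pooled $R_{SC} > 1$
through sampling noise); planted "unique" proteins are structurally zeroed
in the opposite group after sampling, with one spectrum imputed in the
favoured group in the rare undetected draw. Group proteins are placed in
the background, outside planted modules.

The `default_paper_shape` preset emulates the published study conditions:
1,800 proteins, five HOT and five COLD samples, eight modules of 20-150
proteins at loading 0.8, two trait-linked modules at shift 1.5, and
unique/up group counts scaled from the published tallies (460/174/287/131).
Baseline abundances have sd 1.5 log2 (protein abundances spanning a few
orders of magnitude), per-sample biological variation sd 1.5 log2, library
size 30,000 spectra per sample (a deep FFPE proteome), and protein lengths
uniform on 100-1000 aa. `hub_rich` is a deliberately well-powered preset
(15+15 samples, dispersion 0.05, one loading-0.97 hub per module) for hub
and soft-threshold analyses; `null` plants no structure.

What the generator does **not** emulate: peptide-to-protein roll-up and
shared peptides, FFPE fixation artefacts, batch and run-order effects, and
missingness mechanisms beyond structural zeros. Passing tests therefore
demonstrate the pipeline's internal correctness and its behaviour under a
faithful count-noise model — not that any particular clinical dataset
would yield recoverable modules.

## What a 5+5 design can and cannot recover

A consequence worth stating explicitly, because the validation suite
reports it honestly: with ten samples, the sampling noise of a Pearson
correlation is large (null sd $\approx 1/3$), and overdispersed counts
attenuate the latent within-module correlation of a loading-0.8 module
(0.64) to roughly 0.3-0.5 on the observed scale. Even an oracle that knows
the true latent factors and assigns each protein to its best-correlated
factor cannot then separate ~1,200 background proteins from module members
at any threshold — full-partition recovery (adjusted Rand index against
the planted labels) plateaus far below 1 under these study conditions. The
acceptance suite runs this exact experiment (20 seeds of
`default_paper_shape` through `plantedRecovery()`) and reports the measured
index rather than gating it; the three-block high-signal fixture shows the
same machinery recovering separable structure at ARI > 0.9. The practical
reading: at this sample size, module discovery is exploratory, and the
ORA screen against presence/absence groups — which does not depend on
correlation estimates — is the more robust evidence layer.

## Numerical choices and degenerate inputs

* Pseudo-counts: 1.25 in Rsc (literature value), 0.5 in the expression
  transform (half a spectrum).
* Rounding of Venn percentages: half away from zero, reported alongside
  the raw percentage.
* Correlation p-values: two-sided t transform with $n-2$ df; $|r| = 1$
  maps to $p = 0$.
* Constant eigenproteins or profiles: `NA` with a warning (trait
  correlation), refusal with a clear error (expression stage drops
  zero-variance proteins up front).
* Tie-breaks are everywhere deterministic (module renumbering by size then
  first appearance; hub ranks by degree, `k_within`, id).
* The pipeline stage order contains no randomness; rerunning a fixed input
  and config reproduces outputs byte for byte, which the test suite
  checks.

## Problem sizes used by the validation suite

Unit tests run on literal micro-fixtures (3-60 proteins) and the
high-signal three-block fixture; property tests use 10-25 seeded
replicates. The acceptance suite uses the study-scale conditions: the
1,862/476/180 published tallies, exhaustive hypergeometric enumeration to
$N = 15$, 100 random 15-node TOM oracles, a 1,000-protein x 2,000-replicate
G-test null (two million tests), 20 paper-shaped recovery seeds, and 500
ORA null draws.

## Limitations

Beyond the sample-size limits above: the ladder tree cut is a deliberate
simplification of adaptive branch pruning; blockwise decomposition for
very large matrices (>20k proteins) is not implemented; no external
annotation enrichment (GO/pathway) is included — the ORA here screens
modules against the data-derived protein groups only.
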