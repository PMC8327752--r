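---
title: "hepanet: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hepanet: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepanet)
```

# The analysis model

`hepanet` implements a hub-gene discovery funnel for paired
tumor/adjacent-normal expression studies. The statistical backbone, stage
by stage:

1. **Sample QC** assumes that technically and biologically consistent
   samples of one tissue class correlate strongly with each other
   (driven by shared gene-level baseline expression), while aberrant
   samples — degraded RNA, mislabeled tissue, batch escapees — sit in
   visibly lower-correlation clusters. Average-linkage clustering of
   1 − r within each tissue class, cut into a configurable number of
   groups (defaults: 2 tumor, 3 normal), keeps the consistent group(s);
   because samples are paired, a subject survives only if both of its
   samples survive.
2. **Seed-gene selection** keeps high-variability genes by coefficient
   of variation, CV = sd/|mean|.
3. **Network construction** assumes approximate scale-free topology of
   the co-expression network; the soft power is diagnosed by regressing
   log-frequency on log-connectivity. Adjacency, topological overlap,
   average-linkage clustering, module detection, eigengenes, and
   eigengene-based module merging follow the standard weighted
   co-expression formulation (formulas in the README).
4. **Hub screening** models a gene's PPI neighborhood as a draw of
   c + o genes from the network's N genes, of which M belong to the
   trait-associated co-expression set; over-representation is the
   hypergeometric upper tail. This is the package's central statistic.
5. **Clinical statistics** use exact small-sample conventions chosen to
   reproduce published cohort-table arithmetic (see below).
6. **Enrichment** uses the weighted Kolmogorov–Smirnov running-sum
   statistic with phenotype-permutation significance, and its
   single-sample variant for immune-infiltration scoring.

# Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| soft power β | 6 | exponent | canonical unsigned-network choice; diagnosed by `pickSoftThreshold()` against signed R² ≥ 0.85 |
| minimum module size | 30 | genes | conventional floor for a stable eigengene |
| merge height | 0.25 | 1 − cor(ME) | merges modules whose eigengenes correlate ≥ 0.75 |
| edge threshold | 0.1 | TOM weight | standard export cut for the final network |
| CV cutoff | 3.6 | linear-scale CV | see "CV scale" below; a top-N variant is provided |
| QC groups | 2 tumor / 3 normal | clusters | mirrors the two-group tumor / three-group normal structure of the emulated cohort's sample dendrograms |
| QC consistency tolerance | 0.15 | Δ mean intra-cluster r | separates arbitrary splits of homogeneous data (observed Δ ≲ 0.1) from genuine outlier clusters (Δ ≈ 0.5 in the planted fixtures) |
| hub proportion threshold | 0.10 | c/(c+o) | the screening rule's published operating point |
| hub α | 0.05 | adjusted p | conventional |
| GSEA weight | 1 | exponent on \|metric\| | canonical weighted statistic |
| GSEA permutations | 1000 | count | canonical; ≥ 100 enforced |
| ssGSEA α | 0.25 | rank exponent | canonical single-sample weighting |

# The synthetic world

The generator (`simulationConfig()` defaults) emulates the cohort
structure this class of study analyzes:

* **54 subjects**, each with one tumor and one normal sample (the
  post-QC size of the emulated discovery cohort).
* **Three planted modules of 50 genes** at within-module correlation
  ρ = 0.9 among 250 genes, via a latent-factor model: module eigengene
  e = N(0,1) + d·trait with d = 2, gene = √ρ·e + √(1−ρ)·noise. d = 2
  yields module–trait correlations around 0.7, the strength of the
  leading trait modules such studies report. The latent-factor design
  matches the module-eigengene concept directly and scales linearly.
* **Per-gene baselines** b_g ~ N(8, 2) shared across samples. This is
  deliberate realism, not decoration: gene-level mean expression is what
  makes real samples correlate at r ≈ 0.8–0.95, and without it
  correlation-based sample QC has nothing to measure.
* **PPI graph**: preferential attachment, 2000 nodes, 3 edges per
  arrival. The 150 module genes then cover ~7.5% of the network,
  matching the coverage-rate regime of the emulated human interaction
  network (≈ 6.6%). Four planted hubs get 30-neighbor neighborhoods
  redrawn with each neighbor a co-expression gene independently with
  probability 0.4 — several-fold above background, as published hub
  proportions are.
* **Survival**: exponential event times, baseline hazard 0.05/month
  (median ≈ 14 months untreated-advanced-HCC scale), log hazard ratio
  log(1.921) for the high-expression class — the univariate hazard
  ratio scale reported for the emulated marker — and uniform censoring
  calibrated numerically to a 30% censoring fraction.
* **Clinical covariates**: marginal frequencies of a 90-patient
  tissue-microarray cohort (57 low / 33 high expression; AFP > 300 in
  42/90; TNM II–IV in 27/90; …), with odds ratios 3.0 (AFP) and 2.5
  (TNM) linking the second level to the high-expression class and the
  remaining covariates unassociated.

All generators are pure functions of (config, seed), with fixed seed
offsets per stage so stages can be regenerated independently.

**What the generator does not emulate** — and therefore what a green
test does *not* establish: microarray probe-level artifacts and
normalization residue, batch effects, heavy-tailed expression noise,
realistic PPI topology beyond the scale-free degree law (no cliques or
complex co-membership), correlated immune marker sets, and non-
proportional hazards. Green tests establish that the algorithms recover
planted structure of the stated kind at the stated strength, and that
the arithmetic of every closed-form statistic is exactly right; they do
not certify performance on real cohorts.

# Numerical and design choices

**Duplicate gene rows** keep the highest-mean row (common microarray
practice); **rows with missing values** are dropped and counted, not
imputed.

**CV scale.** A CV cutoff of 3.6 is unreachable on log2-scale microarray
data, where CVs sit near 0.1; it is entirely plausible on the linear
scale. `cvFilter()` therefore exponentiates log2 input by default
(`scale = "linear"`) and offers `scale = "asis"`. Both a cutoff mode and
a deterministic top-N mode exist, because the combination of cutoff and
claimed gene count in the emulated study cannot be reconciled exactly.

**QC cluster retention.** Within a tissue class, any cluster whose mean
intra-cluster correlation is within 0.15 of the best cluster is kept.
Keeping only the single best cluster would be unstable: arbitrary splits
of homogeneous data differ by small margins, and the procedure would
discard good samples and fail to be idempotent. Genuine outlier
clusters sit far below the margin. Singleton clusters are scored by
their mean correlation to the rest of the class — a singleton is never
"perfectly consistent". With these rules, QC is idempotent: re-running
it on its own output changes nothing.

**Module detection.** The reference dynamic hybrid tree-cut algorithm is
heavily parameterized (its PAM stage in particular), so `cutModules()`
substitutes a documented deterministic two-phase variant with the same
contract: (1) a static cut at the 0.99 quantile of merge heights;
(2) a recursive walk that accepts a branch as a module when it hangs
below its parent merge by more than the gap sensitivity (default 0.1),
re-cuts any branch of at least twice the minimum size whose internal
top gap also exceeds the sensitivity, descends otherwise, and sends
everything below the minimum size to "grey". Acceptance is by
planted-module recovery (adjusted Rand index), not label-for-label
identity with any particular reference implementation. Modules are
named by size rank along the conventional color sequence.

**Sign mode.** Unsigned adjacency is the default (β = 6 is the
canonical unsigned choice); signed is available. **Edge export** uses
TOM weights by default, adjacency optionally. **Eigengene sign** is
fixed by non-negative correlation with the module's mean standardized
profile, with a first-nonzero-positive fallback when that correlation
is undefined (e.g. a two-gene anti-correlated module).

**Module selection direction.** Trait-module ranking uses |r| by
default with the sign reported, because strongly negatively correlated
modules are biologically meaningful even when a study pursues only the
positive ones; a positive-only mode is available.

**Hub screening conventions.** The second published count column is
interpreted as neighbors *outside* the co-expression set, because
c/(c+o) then reproduces the published proportion column to six decimals
for every row, and the hypergeometric tail with c + o draws reproduces
the published p-values to three significant figures — the alternative
reading (total degree) fails both. The adjusted column labelled "FDR"
follows Bonferroni-style m·p arithmetic with m = M (the covered
co-expression genes), which tracks the published values to within ~2%;
both `bonferroni` (fidelity default) and `bh` (recommended for new
analyses) are implemented, and the result object records which was
used. The focal gene is not removed from M or N (negligible at scale;
documented constant). Degree-0 genes are excluded from testing; in
`bh` mode m is the tested count, in fidelity mode m stays M.

**Clinical conventions.** Pearson chi-square *without* Yates continuity
correction reproduces published cohort-table p-values exactly, the
corrected statistic does not; a correction flag exists. IHC boundary
percentages (25/50/75) bin upward (the interval notation in common use
is ambiguous); configurable. Median dichotomization sends ties at the
median to the low group; any strictly monotone transformation of the
values yields identical labels. Cox fits use Breslow tie handling
(adequate for month-resolution data; Efron available); fits are
delegated to the `survival` package, and the package's own tests verify
them against brute-force partial-likelihood and product-limit oracles.

**GSEA details.** The null is phenotype-label permutation; with fewer
than 7 samples in a group the permutation space is too small and the
implementation falls back to gene-set permutation with a logged
warning. Nominal p uses the add-one convention (never exactly 0), NES
divides ES by the mean |null ES| of the same sign, q is
Benjamini–Hochberg across sets. When a set covers the entire list the
miss ECDF falls back to the uniform i/n so the running sum remains a
proper bridge. ssGSEA scores are rank-based (hence invariant to
per-sample monotone transformations) and min–max normalized by the
global score range; sets with fewer than two genes present are flagged.

**Pipeline configuration** is JSON (one diff-able format, schema-checked
with precise error messages, `dumpConfig()`/`validateConfig()`
round-trip stable) rather than a bespoke key=value dialect. The
command-line surface is a thin wrapper (`inst/scripts/hepanet.R`) over
`writeSyntheticDataset()` and `runPipeline()`; the per-stage operations
are the exported functions themselves.

# Known limitations

* The QC consistency tolerance (0.15) is a heuristic calibrated to the
  generator's correlation scale; heavily batch-structured real data may
  need a different value or explicit group counts.
* The module detector is a contract-equivalent substitute, not a clone
  of any reference tree-cut implementation; on real data the two can
  split borderline branches differently.
* PPI confidence scores are read and preserved but unused by default
  (no threshold is applied unless requested).
* Multivariate Cox takes an explicit covariate list; no stratified or
  time-varying terms.
* GSEA q-values are BH across sets, not the NES-matched empirical FDR
  of the original formulation.
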