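# hepanet

Weighted co-expression network hub-gene discovery for hepatocellular
carcinoma (HCC), re-implemented as a tested, fully offline R package.

Tumor biomarker studies of the WGCNA family proceed through a long
funnel: paired tumor/adjacent-normal expression profiles are
quality-controlled by sample correlation clustering, variable genes are
selected by coefficient of variation, a soft-thresholded co-expression
network is built and cut into modules, trait-associated modules are
mapped onto a protein–protein interaction (PPI) network, and genes whose
PPI neighborhoods are enriched for co-expression genes are screened as
hubs — which are then taken to clinicopathological association tests,
survival analysis, and GSEA/ssGSEA-based functional and
immune-infiltration profiling. `hepanet` implements every stage of that
funnel behind explicit, individually testable functions, plus a
synthetic-data generator with planted structure so the whole pipeline is
verifiable without any external download.

It is aimed at computational biologists who want the statistical core of
such analyses (the screening statistic, the network construction, the
survival models) as reusable, audited building blocks rather than a
one-off script.

## The statistics at the core

**Co-expression network.** For genes *i*, *j* with Pearson correlation
*r<sub>ij</sub>*, the unsigned adjacency is *a<sub>ij</sub>* =
|*r<sub>ij</sub>*|<sup>β</sup> (default β = 6, chosen by the scale-free
topology criterion). The topological overlap

ω<sub>ij</sub> = (ℓ<sub>ij</sub> + a<sub>ij</sub>) / (min(k<sub>i</sub>,
k<sub>j</sub>) + 1 − a<sub>ij</sub>),  ℓ<sub>ij</sub> = Σ<sub>u</sub>
a<sub>iu</sub> a<sub>uj</sub>,  k<sub>i</sub> = Σ<sub>u</sub> a<sub>iu</sub>

drives average-linkage clustering of 1 − ω; modules (minimum size 30)
get eigengenes (first singular vector of the standardized module
submatrix), close modules merge below eigengene dissimilarity 0.25, and
module–trait association is the Pearson correlation of eigengene and
trait with the *t*-distribution p-value.

**Hub screening.** A gene with *c* co-expressed and *o* other PPI
neighbors, in a network of *N* genes covering *M* co-expression genes,
is scored by the upper-tail hypergeometric probability P(X ≥ c) with
*c + o* draws (one-sided Fisher exact test), adjusted by *m·p* with
*m = M*. Hubs require a co-expressed-neighbor proportion c/(c+o) ≥ 10%
and adjusted p < 0.05.

**Clinical statistics.** 2×2 Pearson chi-square without continuity
correction, four-level IHC percent-positive binning (scores 1–2 = low
expression), Kaplan–Meier / log-rank, and Cox proportional hazards with
Breslow ties (via the `survival` package).

**Enrichment.** Weighted Kolmogorov–Smirnov GSEA with phenotype-label
permutation (NES, nominal p, BH q), and per-sample ssGSEA (weighted
rank-ECDF difference, exponent α = 0.25) for immune-cell marker sets,
with Spearman correlation and survival-association summaries.

## Worked example

The published screening arithmetic from explicit neighborhood counts:

```r
library(hepanet)
tab <- hubTableFromCounts(
  genes = c("RPL19", "RPS12", "RPL27A", "RPL35A"),
  c = c(34, 26, 29, 20), o = c(158, 115, 145, 86),
  M = 1148, N = 17381)
screenCandidates(tab)[, c("gene", "proportion", "fisher_p",
                          "adjusted_p", "is_hub")]
#>     gene proportion fisher_p adjusted_p is_hub
#> 1  RPL19      0.177 1.18e-07   0.000135   TRUE
#> 2  RPS12      0.184 1.61e-06   0.001851   TRUE
#> 3 RPL27A      0.167 3.51e-06   0.004027   TRUE
#> 4 RPL35A      0.189 1.76e-05   0.020220   TRUE
```

All four ribosomal-protein genes clear both screens: ~17–19% of their
PPI neighbors are co-expression genes (against a 1148/17381 ≈ 6.6%
background), with strongly significant one-sided hypergeometric
p-values.

The full pipeline on the default synthetic world (54 tumor/normal pairs,
three planted 50-gene modules at ρ = 0.9, a 2000-node scale-free PPI
graph with four planted hubs):

```r
res <- runPipeline(list(outdir = "out", seed = 1,
                        enrichment = list(nPerm = 200)))
res$moduleTrait
#>      module     r        p   n
#> 2      blue 0.732 2.37e-19 108
#> 1 turquoise 0.686 2.72e-16 108
#> 3     brown 0.659 8.62e-15 108
hubGenes(res$hubScreen)
#> [1] "G0069" "G0042" "G0078"
res$plantedHubs
#> [1] "G0069" "G0013" "G0042" "G0078"
```

The three planted modules are recovered with strong tumor-trait
correlations, and three of the four planted hubs pass the screen at this
seed (the fourth, `G0013`, drew a 23% co-expressed neighborhood — above
the 10% proportion rule but short of Bonferroni significance at m =
150). Every stage writes a TSV artifact plus `run_report.json` under
`outdir`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full synthetic end-to-end analysis from scratch under the
given seed — generation, QC, CV filter, network and module detection,
module–trait association, PPI hub screening, clinical/survival analysis,
and enrichment — logging per-stage status, and writes the acceptance
report JSON to `--out`.
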