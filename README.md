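# lactDGE

Stage-wise transcriptome analysis for the lactation cycle: differential
expression, temporal expression patterns, co-expression hubs, and pathway
impact scoring, with a seeded ground-truth simulator.

## What this package is for

Bulk transcriptome studies of the ruminant mammary gland typically profile a
handful of animals at a few discrete physiological stages — peak lactation
(`L`), dry-off (`D`), and the non-lactating/non-pregnant involution period
(`NP`) — and then ask which genes change, how they change over the stage
sequence, which genes sit at the hubs of the co-expression network, and which
pathways absorb the perturbation. `lactDGE` implements that post-quantification
analysis chain as tested, reusable R functions for anyone working with a
gene-level count matrix from such a design (3 stages × few replicates,
overdispersed counts). Every stage of the chain can be exercised end-to-end on
synthetic data with planted ground truth, so its operating characteristics
(sensitivity, false discovery, pattern recovery, ranking stability) are
measurable rather than assumed.

## The methods at its core

**Normalization and abundance classes.** Counts are normalized to
RPKM = 10⁹ · c<sub>gs</sub> / (N<sub>s</sub> · L<sub>g</sub>) with
N<sub>s</sub> the sample's counted-read total and L<sub>g</sub> the gene
length (bp), then binned as low [0, 10), medium [10, 500), high [500, ∞)
RPKM. Stage-presence logic (gene expressed in a stage iff its stage-mean
RPKM > τ, default τ = 0) yields per-stage totals, the three-way Venn
partition, and stage-unique genes.

**Moderated differential testing.** For each stage pair, a random variance
model (RVM) moderated t-test on log₂(RPKM + 0.125): reciprocal true variances
are pooled across genes via 1/σ² ~ Gamma(a, b), under which the per-gene
sample variances satisfy s²·a·b ~ F(d, 2a). The maximum-likelihood (a, b)
give the moderated variance s̃² = (d·s² + 2/b)/(d + 2a) and a t-statistic
with d + 2a degrees of freedom — a substantial gain when d = n₁+n₂−2 is as
small as 4. A per-gene 2×2 chi-square test on summed counts is reported
alongside. DEGs require P < 0.05 and Benjamini–Hochberg FDR < 0.05 within the
comparison.

**Temporal patterns.** Integer model profiles over the stage sequence
(start at 0, at most ±2 level units per step; (2c+1)^(t−1) candidates;
greedy max-min selection down to 20) are assigned to genes by Pearson
correlation of the gene's log₂ ratio-to-first-stage vector with the profile
levels. Profile significance comes from exactly enumerating all t! stage
orderings; flagged profiles are grouped by single-linkage correlation ≥ 0.7.

**Co-expression hubs.** Pearson correlation over all samples on
log₂(RPKM + 0.125), edge kept iff |r| ≥ 0.92, computed in gene blocks so
memory stays O(block × n). Node (hub) genes are ranked by degree, ties kept.

**Dynamic Impact Approach (DIA).** Genes passing fold-change > 2 and
P < 0.001 feed per-term scores:
impact = (|D|/k) · mean|log₂FC| · mean(−log₁₀ P) over the term's filtered
DEGs D among its k measured members; flux = impact(up) − impact(down) gives
the direction. Impacts normalize to 0–100 per comparison, roll up to
category/subcategory means, and rank overall by the cross-comparison mean.

**Simulator.** `simulateCounts()` draws negative-binomial counts
(lognormal baselines, shared dispersion 0.1) for a 3-stage × 3-replicate
design, planting a configurable fraction of genes on integer temporal
templates with a 2-log₂-unit effect per level, and emits the truth table;
`simulateAnnotation()` builds a GMT-style term annotation whose "enriched"
terms oversample planted DE genes by a configurable odds multiplier.

## Worked example

```r
library(lactDGE)
se <- simulateCounts(simulationConfig(seed = 1))$se
se <- computeRPKM(se)
se
#> StageExperiment with 2000 genes, 9 samples
#>   stages: L(3) D(3) NP(3)
#>   assays: counts, rpkm
#>   gene lengths: 303-5000 bp

table(classifyAbundance(stageMeans(se)[, "L"]))
#>    low medium   high
#>    275   1490    235

deg <- testDEG(se)
table(deg$comparison, deg$is_deg)
#>           FALSE TRUE
#>   D_vs_NP  1868  132
#>   L_vs_D   1614  386
#>   L_vs_NP  1829  171

head(deg[deg$is_deg, c("gene_id","comparison","log2fc","p_rvm","fdr","direction")], 3)
#>     gene_id comparison    log2fc        p_rvm         fdr direction
#> 1 gene00001     L_vs_D  1.603878 0.0016198071 0.013361909        up
#> 2 gene00002     L_vs_D -2.541111 0.0003009946 0.004793143      down
#> 5 gene00005     L_vs_D -2.146242 0.0015866634 0.013167331      down
```

The abundance table says that at peak lactation 235 genes exceed 500 RPKM
while most sit in the medium band; the DEG table gives, per stage pair, how
many genes pass both the moderated-P and FDR gates, and each record carries
the fold change (oriented later-stage over earlier-stage), both test
p-values, and the call direction. `runPipeline(pipelineConfig(seed = 1),
"out/")` chains all five analysis stages, materializes every stage product as
TSV (`rpkm.tsv`, `deg_results.tsv`, `patterns.tsv`, `profiles.tsv`,
`network_edges.tsv`, `network_degrees.tsv`, `dia_impacts.tsv`) and writes a
deterministic `report.json`. A thin command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

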