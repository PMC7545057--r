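---
title: "Models and design choices behind the lactDGE pipeline"
author: "lactDGE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the lactDGE pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactDGE)
```

This vignette explains the statistical models the package implements, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions adopted where a published method leaves details open. It states
no empirical result that the package's test suite and acceptance script do
not themselves compute.

## The data model

The backbone container is a `StageExperiment`, a `SummarizedExperiment`
holding a genes × samples count matrix, a per-sample stage factor (default
ordering `L` — peak lactation, `D` — dry-off, `NP` — non-lactating/
non-pregnant involution), and per-gene lengths in bp. Validity enforces
non-negative finite values, unique identifiers, a stage for every sample and
at least one sample per stage. `computeRPKM()` adds an `rpkm` assay:

$$\mathrm{RPKM}_{gs} = \frac{10^9\, c_{gs}}{N_s\, L_g},$$

with $N_s$ the column sum of the counts. Using the counted-read total as the
library size is a deliberate choice: the sequencer-level mapped-read total is
not recoverable from a count matrix. Abundance classes are the conventional
low/medium/high bands with half-open boundaries $[0,10)$, $[10,500)$,
$[500,\infty)$ RPKM — half-open so the three bins are a true partition while
the "high means ≥ 500" edge is preserved. Stage presence uses stage-mean
RPKM $> \tau$ with $\tau = 0$ by default (any positive signal counts as
detected, which matches detection-style Venn counting on sparse designs);
$\tau$ is exposed in the configuration. Stage means are arithmetic means of
replicate RPKM, i.e. per-sample normalization happens before averaging.

## The random variance model

With three replicates per stage, per-gene variance estimates at
$d = n_1 + n_2 - 2 = 4$ degrees of freedom are hopeless on their own. The
random variance model pools them: reciprocal true variances are assumed
exchangeable across genes,

$$1/\sigma_g^2 \sim \mathrm{Gamma}(a,\, b) \quad\Longrightarrow\quad
  s_g^2\, a\, b \sim F(d,\, 2a),$$

and $(a, b)$ are fitted by maximizing the marginal $F$ likelihood over all
strictly positive sample variances (deterministic BFGS from a
moment-matched start, so refits are bit-identical). The moderated variance
and test are

$$\tilde s_g^2 = \frac{d\, s_g^2 + 2/b}{d + 2a}, \qquad
  t_g = \frac{\bar y_{g2} - \bar y_{g1}}
             {\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}} \sim t_{d + 2a},$$

computed on $\log_2(\mathrm{RPKM} + 0.125)$. As $d \to \infty$ the moderated
variance tends to the sample variance and the test to the ordinary pooled
t-test. The fit requires at least 50 positive variances and refuses an
all-zero variance vector. The exchangeability assumption is approximately
satisfied by the simulator's shared-dispersion counts — by design, so the
model's parameter recovery is testable (the test suite recovers the prior
shape within ±10% on 20,000 simulated variances against a profile-likelihood
grid oracle, and checks the null rejection rate at $\alpha = 0.05$ on 10,000
null genes against its exact binomial 99% band).

A per-gene Pearson chi-square test (1 df, no continuity correction) on the
2×2 table of summed group counts versus group library totals is reported
alongside. DEG calls gate on the moderated P and the within-comparison
Benjamini–Hochberg FDR (both < 0.05 by default); a strict mode additionally
requires the chi-square P below the cut. Gating on the moderated test and
reporting the count test alongside is the package's choice where the
combination rule is otherwise unstated. FDR is controlled within each
comparison, not pooled, because comparisons are reported separately.
Fold changes are $\log_2$ ratios of stage-mean RPKM with pseudocount 0.125
on both means (finite for stage-absent genes; exposed in the
configuration), oriented later-stage over earlier-stage so "up in D versus
L" is positive under the `L_vs_D` comparison.

## Temporal model profiles

Candidate profiles over $t$ stages are integer level vectors starting at 0
with steps bounded by $c$ units — exactly $(2c+1)^{t-1}$ of them, ordered
lexicographically by step vector with stable 0-based ids. Defaults
$t = 3, c = 2$ give 25 candidates, greedily thinned to 20 by max-min
selection seeded at the flat profile (distance $1 - r$; the flat profile is
at distance 1 from every non-flat profile and 0 from itself; ties go to the
lowest candidate id). Genes are transformed to
$\log_2$ ratios against the first stage and assigned to the
highest-correlation profile, ties to the lowest id; constant genes go to the
flat profile by convention.

Two structural facts matter when interpreting assignments:

* **Proportional profiles are indistinguishable.** Pearson correlation
  cannot separate a profile from its positive scalar multiples, and with
  $t = 3, c = 2$ the 25 candidates fall into only 15 proportionality
  classes, so any selection of 20 necessarily contains correlation-1
  duplicates. Under the lowest-id tie-break every tied gene lands on the
  lowest-id member of its class. Recovery analyses therefore plant
  class-canonical templates; a planted non-canonical template is recovered
  only up to its equivalence class.
* **Significance is exact, not sampled.** With $t \le 5$ stages, all $t!$
  stage orderings are enumerated, every gene is re-assigned under each
  ordering, and per-profile expected counts are the permutation averages.
  Each profile's P is the binomial upper tail at success probability
  expected/total, Bonferroni-corrected across profiles (the conventional
  family-wise guard for model-profile counting). More than 6 timepoints
  would need a sampling null, which is out of scope and raises an error.

Significant profiles are grouped by single-linkage over pairwise profile
correlation at 0.7 (exposed in the configuration) — the usual way
model-profile figures color related patterns.

## Co-expression network

Pearson correlations are computed on $\log_2(\mathrm{RPKM} + 0.125)$ across
all samples jointly — co-expression across the whole stage trajectory is
what distinguishes stage-coupled genes — and an edge is kept iff
$|r| \ge 0.92$ (boundary inclusive; a positive-only mode is available since
"correlated" can be read either way). Zero-variance genes yield no edges and
are reported in diagnostics. The blocked implementation keeps peak memory at
O(block × n) and is verified to reproduce the all-at-once computation
exactly. Hubs are ranked by degree with ties broken by gene id; when the
requested top-k boundary falls inside a tie, all tied genes are returned and
the overflow reported, since truncating inside a tie would be arbitrary.

## Dynamic Impact Approach

Genes passing the DIA input filter (fold change strictly above 2 and
moderated P below 0.001) feed per-term scores. For a term with $k$ measured
member genes and filtered DEG set $D$:

$$\mathrm{impact} = \frac{|D|}{k}\cdot
  \overline{|\log_2 \mathrm{FC}|}_D \cdot \overline{(-\log_{10} P)}_D,$$

with up/down versions restricting $D$ (proportions $|D_{up}|/k$,
$|D_{down}|/k$) and flux = impact(up) − impact(down). The product form is
chosen because it is zero exactly when a term has no filtered DEG and scales
with both magnitude and significance; an additive variant is available for
sensitivity analysis, and the log base is configurable (10 by default, the
conventional p-value transform). Proportions use measured member genes, not
nominal term size — unmeasured genes cannot contribute evidence. Impacts
normalize to 0–100 against the comparison's maximum, roll up to unweighted
subcategory/category means, and the overall ranking averages impact across
the comparisons. Terms with no measured member are skipped with a message;
missing category metadata groups under "uncategorized" with a warning.

A known behavior of the multiplicative score, visible in the package's own
simulations: a small term containing one extreme DEG can rival a large
genuinely enriched term, because the mean factors are unbounded while the
proportion factor only scales as $1/k$. Fold-change estimates at near-zero
counts amplify this — a planted 4-fold gene whose counts hit zero in one
stage can estimate at $|\log_2 \mathrm{FC}| \approx 8$ with a tiny P. This
is a property of the score and of pseudocount fold-change estimation, not of
the implementation, and it is why the enriched-term top-rank rate measured
by the acceptance script sits below a comfortable certainty even at
enrichment odds of 10.

## The synthetic-data generator

`simulateCounts()` emulates the statistical structure the analysis assumes:
a 3-stage × 3-replicate design; lognormal baseline expected counts
(meanlog $\log 60$, sdlog 1.5 — a realistic 3–4 decade dynamic range);
negative-binomial sampling with a single shared dispersion of 0.1 (typical
for biological replicates, and deliberately exchangeable so the RVM prior is
well-specified); a fraction (default 0.2) of genes planted on integer
temporal templates scaled by 2 log₂ units per level (default templates
(0,1,1), (0,−1,−1), (0,1,0), (0,−1,0): unit level steps so planted
fold changes between affected stages are 4-fold, balanced up/down, and all
inside the default selected profile set); and gene lengths uniform on
300–5000 bp. `simulateAnnotation()` draws term memberships without
replacement, weighting planted DE genes by the enrichment odds in "enriched"
terms. Everything is a pure function of the configuration including its
seed.

What the generator does **not** emulate: sequencing-depth differences between
samples beyond what composition induces, batch effects, gene length–coverage
bias, correlated gene modules (genes are independent given their stage
means), per-gene dispersion trends, and annotation ambiguity. Consequently a
passing test shows the algorithms behave as specified under their own
assumptions; it does not certify performance on real data, where all of the
above are present.

One consequence of the generator's absolute-scale means deserves emphasis:
planting multiplicative effects on 20% of genes changes the expected library
mass per stage (up to ~1.4× between stages under the defaults, occasionally
dominated by a single lognormal-tail gene). RPKM's total-count normalization
then shifts every flat gene's relative abundance, so DEG calls measured
against absolute-scale truth carry extra false positives in the affected
comparisons even though the test's type-I error under a global null is
calibrated. This is the classic composition bias of total-count
normalization — real lactating mammary libraries, dominated by a handful of
milk-protein transcripts, are an extreme natural example — and it is the
reason the package's ground-truth FDR regression values are what they are.
Methods that re-estimate size factors robustly (median-of-ratios, TMM) avoid
it, but RPKM is the pipeline's normalization by design.

## Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to make Monte-Carlo
bands tight while keeping a full run inside a couple of minutes on one CPU:
2,000 genes for pipeline-level checks, 10,000 for null calibration, 20,000
variances for prior recovery, 20 seeded replicates for rate estimates, and
150–600 genes for pattern/DIA calibration runs. Other conventions:
p-values are floored at the smallest positive double before $-\log$
transforms; the RVM optimizer works on log-parameters with a fixed start, so
fits are deterministic; report JSON is written with sorted keys and
9-significant-digit floats so identical runs are byte-identical; all tie
handling (profile ids, gene ids at equal degree, term ids at equal impact)
is lexicographic and documented at the function level.
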