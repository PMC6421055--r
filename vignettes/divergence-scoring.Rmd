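---
title: "Divergence scoring of aluminum-stress transcriptome responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence scoring of aluminum-stress transcriptome responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altox)
```

## The problem and the design

Aluminum toxicity on acidic soils inhibits root growth and depresses yield
in flax. Cultivars differ heritably in tolerance, so genes whose
transcriptional response to Al³⁺ *differs between tolerant and sensitive
genotypes* — while being *reproducible within each group* — are the natural
candidates for tolerance mechanisms. The design this package analyzes is a
4 × 2 × 2 layout: two resistant cultivars (Hermes, TMP1919), two sensitive
ones (Lira, Orshanskiy), control vs short-term Al³⁺ exposure, two biological
replicates — 16 RNA-seq libraries summarized as a gene-by-sample count
matrix (fractional expected counts are rounded half-to-even at ingest, with
a warning, because the downstream exact test needs integers).

## Filtering and normalization

Genes with raw CPM below 1.5 in all but at most `min_samples − 1` samples
are removed. The per-sample rule is a package convention: the cutoff is
applied in at least `min_samples = 2` samples (the smallest replicate-group
size), which keeps genes expressed in only one condition of one genotype.
Library sizes are kept at their pre-filter totals — dropping rows is a gene
selection step, not a change in sequencing depth.

Between-sample normalization is the trimmed mean of M-values, implemented
from scratch: reference = sample whose 75th-percentile count/library-size
ratio is closest to the mean; per-gene log-ratios M and abundances A over
genes positive in both sample and reference; double trim (30% on M, 5% on A,
both tails); precision-weighted mean of the surviving M values
(delta-method weights `(N−y)/(Ny)` summed over the two samples);
`2^` of that mean, re-centered to geometric mean 1. The test suite holds
this implementation to within 1e−6 of edgeR's `calcNormFactors` on seeded
data (in practice they agree to machine precision), and to the plain
`2^mean(M)` limit when trimming and weighting are switched off.

## Fold changes and the exact test

Fold change per grouping is the ratio of mean stress CPM to mean control CPM
with a pseudocount of 0.5 CPM added to both arm means (adjustable; it keeps
the ratio defined for genes silent in one arm and shrinks fold changes of
barely expressed genes). log2FC is its binary logarithm. Four groupings are
analyzed: the pool of all genotypes, the resistant pool, the sensitive pool,
and each genotype alone.

Significance comes from a conditional negative-binomial exact test, a
deliberately self-contained analogue of the classic two-group NB exact test:

* counts are scaled to the common mean effective library size and rounded;
* a single common dispersion φ (variance = μ + φμ²) is estimated across all
  genes by a pooled method-of-moments ratio estimator
  `φ̂ = Σ_g [SS_g − Σ_j (n_j−1) m_gj] / Σ_g Σ_j (n_j−1) m_gj²`, floored at
  0 (with single replicates per arm there is nothing to pool, and φ must be
  supplied explicitly);
* given the gene's total `s` across both arms, the first arm's sum follows a
  beta-binomial `BB(s, n₁/φ, n₂/φ)` (binomial `B(s, n₁/(n₁+n₂))` in the
  Poisson limit φ = 0), and the two-sided p-value doubles the smaller tail,
  capped at 1 — the doubling convention is stated because conventions
  differ.

Equivalence with edgeR's quantile-adjusted conditional likelihood is *not*
claimed. On all-null simulations the test is approximately calibrated
(type-I error ≈ 0.04–0.075 at α = 0.05 across seeds); the mild
anti-conservatism is the expected price of a single common dispersion when
true per-gene dispersions are gamma-spread — genes more dispersed than the
common value are slightly over-rejected. Ranking is by ascending p, ties by
descending |log2FC| then gene id, with BH FDR appended.

## Consistency and delta scores

The scoring that motivates the package: within each tolerance group, with
per-genotype log2 fold changes `x₁…xₙ`,

$$C = \frac{|\sum_i x_i|}{n \cdot \max_i |x_i|} \in [0, 1].$$

C is maximal (1) when changes are unidirectional and equal, zero when they
cancel, and scale-free, so magnitude enters only later. Two conventions are
ours and documented rather than prescribed: the numerator takes the absolute
value of the sum (so consistent *down*-regulation scores as high as
consistent up-regulation — a signed numerator would zero out the score
product for genes up in one group and down in the other, the very pattern of
interest), and `max|x| = 0` yields C = 1 (a group with identically zero
changes is perfectly consistent; divergence is judged by the third
component). The published rendering of the denominator is typographically
garbled; the form above is the simplest one satisfying every stated
property, and for two genotypes per group any constant-factor variant only
rescales all scores monotonically without changing the ranking.

Genes are ranked by

$$S_\Delta = C_{res} \cdot C_{sens} \cdot
  \max(|\bar m_{res}|, |\bar m_{sens}|) \cdot
  (\bar m_{res} - \bar m_{sens})^2,$$

with `m̄` the group means of log2FC. The squared third component *is* the
"two-fold greater weight" on between-group divergence — no extra factor is
applied. Exact laws the tests assert: S_Δ is symmetric under swapping the
group labels; scaling every log2FC by λ > 0 scales S_Δ by λ³ (scale-free C,
one λ from the max, λ² from the square); S_Δ = 0 whenever the group means
coincide or either group's changes exactly oppose each other. Ties are
broken by descending |m̄_res − m̄_sens|, then gene id, so output is
deterministic.

S_Δ carries no significance calibration — none is defined for it — so it is
a ranking, not a test. A permutation null could be built by shuffling
condition labels, but that is an extension beyond the scoring itself and is
not implemented.

## Top lists and GO over-representation

Top lists of up- (log2FC > 0) and downregulated (log2FC < 0) genes are drawn
from genes significant at raw p < 0.05, at sizes 50/100/300 plus an "all
significant" list; requested sizes are capped at the number of significant
genes in the direction. Over-representation of a GO term is the upper-tail
hypergeometric probability with the universe set to the *tested* (i.e.
post-filter) genes — standard practice; using the whole annotation would
inflate enrichment of broadly expressed categories. BH correction is applied
within each (direction, top size) stratum, mirroring per-list reporting.
Terms annotating fewer than 3 universe genes are skipped. The annotation map
is taken as given (flat, Trinotate-style); GO DAG ancestor propagation is
deliberately not performed.

For a biased gene sampling (e.g. length bias), `wallenius_enrich` replaces
the central hypergeometric with Wallenius' noncentral distribution, odds =
mean user weight inside the term / mean weight outside. The pmf is computed
from the standard integral representation
`P(X = x) = C(K,x) C(N−K,n−x) ∫₀¹ (1−t^{w/d})^x (1−t^{1/d})^{n−x} dt`,
`d = w(K−x) + (N−K−n+x)`, by adaptive quadrature at rel.tol 1e−12, and the
mass is normalized over the support; with unit weights it agrees with the
hypergeometric to < 1e−9 and it matches exact draw-by-draw urn enumeration
on small instances. This is a user-weighted variant: the spline-fitted
probability weighting of length-bias-aware GSEA tools is out of scope.

## qPCR validation and phenotype declines

ΔΔCt follows the usual two-step averaging: technical replicates per (gene,
sample), then biological replicates per condition; `dCt = Ct_target −
Ct_reference` per condition (reference: *ETIF3E*); `ΔΔCt = dCt_stress −
dCt_control`; the log2 relative expression is −ΔΔCt, assuming 100%
amplification efficiency (reported reaction efficiencies of ≥ 95% make the
correction negligible at the fold changes involved; an efficiency flag is
not implemented for that reason). −ΔΔCt, not 2^−ΔΔCt, is correlated with
sequencing log2FC: Spearman ranks are identical either way, but residual
diagnostics stay on one scale. The p-value is exact for ≤ 10 pairs, normal
approximation beyond.

Phenotype decline is `round_half_up(100 × stress mean / control mean, 1)` —
half-up because that is the rounding consistent with the printed cultivar
table this summary mirrors. Of the table's 12 cells, 10 are reproduced
exactly by this rule; the two Hermes exceptions (seed pods, where the
printed 96.6 equals the *inverted* ratio, and plant height, where
100 × 60.6/70.5 = 85.957 rounds to 86.0 against a printed 85.9, presumably
computed from unrounded means) are inherent inconsistencies of the printed
values, and no special-casing is done.

## The simulator: what it emulates and what it does not

`simulate_counts` draws NB counts with variance μ + φμ² and mean
`baseline × 2^(planted log2FC if stress) × library-size factor` for the full
16-sample design. Defaults, chosen once as realistic for bulk plant RNA-seq:
log-normal baselines (meanlog = log 100, sdlog = 1.5), per-gene φ ~
Gamma(2, 0.05) (mean 0.1), library factors Uniform(0.8, 1.2) on a 2e6-read
base. Planted classes cover the response patterns the scoring must separate
— shared up/down, group-specific up, divergent-opposite (± half the effect
per group, so the *between-group gap* equals the class effect size), and
within-group-inconsistent (opposite signs inside one group, which the
consistency score must null out); per-genotype planted log2FCs get
Gaussian jitter (sd 0.25) except for null genes, which are exactly 0. A
fixed seed makes counts, design and truth byte-identical across runs.

The simulator does *not* emulate: read-level artifacts (it starts at
counts), isoforms, batch effects, correlated genes, GC/length biases, or
outlier samples. Passing tests therefore demonstrate correctness of the
*methods* under the NB model they assume, not performance on any real
library; the printed-value checks (phenotype table, per-genotype log2FCs of
the named transcripts) are the only contact with real data.

Two numerical notes on test design. The generator's mean-structure recovery
check (planted log2FC re-estimated within ±0.5 for ≥ 90% of well-expressed
genes) is run at low dispersion (φ ~ Gamma(2, 0.01)): at φ ≈ 0.1 with two
replicates per arm, NB sampling noise alone has log2FC sd ≈ 0.45, so the
±0.5 window would measure noise, not the generator. And the 7-gene qPCR
panel is planted with evenly spread log2FCs over [−3, 3], the way a
validation panel is chosen to span the observed dynamic range; with
clustered values, rank stability at n = 7 reflects the panel, not ΔΔCt.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 120–5000-gene simulations,
200-rerun Monte-Carlo loops for the qPCR property, and a 2000-gene null for
calibration — sizes at which every Monte-Carlo assertion is stable across
seeds while the whole suite runs in well under a minute. All randomness
flows from explicit integer seeds; the pipeline fans its global seed out to
per-stage child seeds by fixed offsets so any stage can be reproduced in
isolation, and `manifest.tsv` records the seed, a config hash and per-stage
row counts.

## Known limitations

* The exact test uses one common dispersion: no tagwise shrinkage, no GLM
  framework; its p-values are a documented analogue, not an edgeR
  replication.
* S_Δ has no null distribution; top-k cutoffs are descriptive.
* Enrichment treats the annotation as flat; no ancestor propagation or
  evidence-code filtering.
* The CLI's `enrich` subcommand exposes only the hypergeometric method;
  weighted analysis is available through `wallenius_enrich()` in R.
* `build_top_lists` draws only from genes below the significance cutoff, so
  with very weak signal lists can be short (a warning is emitted).
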