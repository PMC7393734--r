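---
title: "Somatic mutation burden and hotspot enrichment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic mutation burden and hotspot enrichment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somaticburden)
```

`somaticburden` tests genomic features — genes or user-defined regions —
for an excess of somatic mutations in a tumor cohort. This vignette is
the package's own account of the statistical model, its assumptions, the
parameters that matter, the numerical decisions taken where the design
was genuinely open, and what the simulation-based validation does and
does not demonstrate.

## The sampling model

The null model treats somatic mutation as a homogeneous per-nucleotide,
per-sample Bernoulli process within each feature. Given a background
rate $p$ (mutations per nucleotide per sample) and a feature of testable
length $L$, the probability that one sample carries at least one
mutation in the feature is

$$p_n = 1 - (1 - p)^L.$$

The default *burden test* counts mutated samples: with $n$ of $N$ cohort
samples carrying at least one foreground mutation, the p-value is the
upper binomial tail

$$\sum_{i=n}^{N} \binom{N}{i} p_n^i (1 - p_n)^{N-i}.$$

"Foreground" is pipeline-specific: non-silent mutations for genes (the
coding module), any mutation for regions (the noncoding module). The
alternative *negative-binomial test* counts mutations rather than
samples: with $k$ total foreground mutations and $x = L N$ nucleotide
trials,

$$\sum_{r=0}^{x-k} \binom{k+r-1}{r} p^k (1-p)^r,$$

the probability that the $k$-th mutation arrives within $x$ trials. The
two tests answer different questions: the binomial test is insensitive
to recurrence within one sample (a hypermutated outlier contributes one
success), while the negative-binomial test rewards it. The test suite
asserts their characteristic disagreement on exactly such a fixture, as
well as the identity $\mathrm{NB}(k; x, p) = P(\mathrm{Bin}(x,p) \ge k)$
that links the two families.

Assumptions worth keeping in mind: positional homogeneity within a
feature (no trinucleotide-context or mappability structure), independence
across samples, and a background rate that is well estimated per sample.
Violations push the burden test toward anti-conservatism, which is the
reason the background machinery below exists.

## Background mutation rates

Four estimators are available, all producing per-sample rates that are
then aggregated per feature:

* **global** (`bg_method = "global"`): the sample's mutation count within
  all features divided by the total feature length. Every feature of a
  sample shares this rate. Cheap, stable, blind to regional variation.
* **local** (`"local"`): windows of `window_size` nucleotides (default
  1 Mb, intended range 1–2 Mb) are slid across the feature — from the
  placement with the feature at the window's right edge to the placement
  at its left edge, in steps of `window_size / 4`, clipped at chromosome
  bounds — and the maximal density is taken. Taking the maximum is
  deliberately conservative: a feature sitting next to a locally
  hypermutated stretch inherits that stretch's rate. A feature longer
  than the window falls back to a single feature-sized window, with a
  warning.
* **clustered** (`"clustered"`): features are grouped by genomic
  covariates (GC fraction computed from the genome FASTA, plus any
  bedGraph-style tracks such as replication timing) and the rate is
  pooled over cluster members, `sum(counts) / sum(lengths)`. Grouping
  uses affinity propagation on z-scored covariates with similarity
  $-\lVert z_i - z_j \rVert^2$, shared preference at the median
  similarity, damping 0.9, at most 1000 iterations, convergence declared
  after 100 iterations of stable exemplars. Features are processed in
  feature-id order, making the partition deterministic and input-order
  invariant. Non-convergence falls back to a single all-features cluster
  (equivalent to the global method) with a warning and an `ap_fallback`
  flag.
* **local_clustered** (`"local_clustered"`): the local window scan is run
  around every member of the feature's covariate cluster and members are
  pooled by a *length-weighted mean*. A max-of-maxima pooling was
  rejected as pathologically conservative — one noisy member would set
  the rate for its whole cluster.

For each feature, the testing rate is the **geometric mean** of
sample-wise rates over the samples with at least one foreground mutation
in that feature. Two numerical guards apply: each rate is floored at
`rate_floor` (default `1e-8`, about one mutation per 100 Mb) before the
geometric mean, since a single zero would annihilate it; and a feature
whose foreground set is empty is *untestable* — it is reported with
burden p-value 1 and an `untestable` flag rather than being dropped, so
that its row participates in the FDR families.

By default the background counts *all* mutation classes within features
(`bg_count_class = "all"`), so silent and non-coding genic mutations
inform the coding background; `"foreground"` restricts counting to the
tested class, keeping numerator and denominator commensurate. The choice
matters only when silent fractions are large.

## Hotspots, WAP, and evidence combination

Hotspots are built by a single left-to-right pass over sorted foreground
positions: a new group starts when the gap to the previous mutated
position exceeds `max_gap` (default 50 nt; the boundary is inclusive, so
positions exactly `max_gap` apart chain). Groups with fewer than
`min_hs_muts` mutations (default 5) or `min_hs_samples` distinct samples
(default 3) are dropped. Each surviving hotspot is tested on its own
span with the same test family as the burden test, using the enclosing
feature's aggregate rate. The span is the min-to-max mutated position,
not a fixed window, which matches the progressive-chaining construction.

The noncoding module also offers the weighted average proximity (WAP)
statistic: the mean over all unordered position pairs of a Gaussian
proximity weight $\exp(-d^2 / 2\sigma^2)$. The kernel form and the scale
$\sigma$ (`wap_scale`, default 30 nt) are package choices — the
literature describes WAP as a distance-decay pair score without fixing
the kernel — and both are exposed as parameters. Significance comes from
permutations that redraw the same number of positions uniformly within
the feature's intervals, with the add-one estimate
$(1 + \#\{W^{perm} \ge W^{obs}\})/(1 + B)$, so p-values are bounded
below by $1/(B+1)$ and the test is never anti-conservative by
resampling noise alone. Permutation nulls are context-free by design;
signature-aware nulls are out of scope.

Per feature, Fisher's method combines exactly the available component
p-values — burden always, the best (minimum) hotspot p-value when a
hotspot exists, and the WAP p-value only under `combine_wap = TRUE` —
with degrees of freedom $2m$ for $m$ components. A feature without a
hotspot therefore has `combined_p == burden_p`, never a penalty for
missing evidence. BH corrections run in three separate families: burden
p-values across features, combined p-values across features, and hotspot
p-values across the hotspot table; WAP p-values get their own column-wise
correction where computed.

## Numerical and engineering decisions

* All tail probabilities are evaluated through survival-function
  parameterisations (`pbinom`, `pnbinom`, `pchisq`), never by naive
  term-by-term summation; the naive sums survive only as independent
  oracles in the test suite, where the two routes are compared to
  relative tolerance 1e-10.
* $p_n$ is computed as `-expm1(L * log1p(-p))`, exact for the tiny rates
  and large lengths typical of whole genomes.
* Zero counts are never significant by construction: $n = 0$ and $k = 0$
  return exactly 1.
* Fisher components of exactly zero (possible only through underflow in
  extreme fixtures) are clamped to a configurable floor of 1e-300;
  negative inputs are errors.
* Internally all intervals are `GRanges` (1-based, closed), the
  R/Bioconductor idiom; BED input is converted once at import by
  rtracklayer and every report is 1-based inclusive. The test suite
  asserts that GTF coordinates round-trip unchanged into reports.
* Indels are assigned to the feature containing their start position;
  records duplicated within a sample (same position, ref, alt) are
  deduplicated; multi-allelic rows are split one record per alternate
  allele. Strand is carried but never used in statistics.
* Report rows are ordered by combined q, then combined p, then feature
  id, making outputs byte-stable. Parallel runs (`n_workers > 1`,
  forked) are byte-identical to serial runs because per-feature
  permutation seeds are derived by hashing feature ids against the
  master seed, independent of worker scheduling.

## The synthetic cohort generator

`generate_toy_annotations()` and `generate_cohort()` produce fully
self-contained inputs: a random-sequence FASTA, two-exon genes tiled on
alternating strands, promoter BEDs in a short (100 nt upstream of the
TSS) and a long (2 kb) dialect, and per-sample bgzip+tabix VCFs. Mutation
counts per sample and feature are Poisson with mean
`background_rate * multiplier * L`, placed uniformly within feature
intervals; planted hotspots add one mutation per carrier sample at a
uniform position inside a designated window; genic mutations are
labelled silent with probability `silent_fraction`. A truth table
records each feature's generating class.

The generator emulates exactly the null the tests assume — positionally
homogeneous, signature-free, strand-agnostic mutation — plus the two
alternatives of interest (rate elevation and positional clustering). It
deliberately does *not* emulate mutational signatures, covariate-driven
regional rate variation, mappability artifacts, copy-number or
structural variation, or caller-specific noise. Green validation runs
therefore demonstrate statistical correctness and calibration under the
model's own assumptions, not robustness to the full messiness of real
tumor genomes.

## Validation design and known limitations

The validation suite (`tests/testthat/test-acceptance.R`, reproducible
via `scripts/acceptance.R`) simulates cohorts of 100 samples over 500
two-kilobase regions on five 1 Mb chromosomes at a background of 1e-6
mutations per nucleotide per sample — whole-genome-realistic rates at a
desk-scale genome. It checks: formula oracles; null calibration (the
fraction of null features at nominal p < 0.05, which discreteness keeps
conservative, and the absence of FDR discoveries across ten seeds);
recovery of 10x-enriched features; background-rate recovery on null
features; the hotspot "rescue" of a 5-carrier, 50 nt cluster inside a
2 kb region whose burden signal alone is diluted, alongside the same
cluster being burden-significant in a 100 nt region; WAP behaviour on
coincident and on scattered positions; and byte-level determinism under
reruns and worker counts.

Two honest limitations surface in exactly these runs:

* **Power at sparse counts.** At 1e-6/nt/sample, a 2 kb feature at 10x
  background yields on average only two mutated samples per hundred —
  recurrence that small cannot clear an FDR threshold among 500
  competitors, and the recovery run reports precisely that shortfall.
  Detecting 10x enrichment in features this small needs larger cohorts,
  longer features, or higher rates; the package reports the ranking
  faithfully rather than inflating it.
* **Conditioning bias of the aggregate rate.** Restricting the geometric
  mean to samples mutated *in the feature* conditions on at least one
  hit, which at per-sample expectations near one mutation biases the
  aggregate upward (roughly two-fold in the validation regime, as the
  rate-recovery summary shows). The bias is conservative — it weakens
  p-values — and vanishes as per-sample counts grow, but users analysing
  very sparse cohorts should read the reported `bg_rate` as the testing
  rate, not as an unbiased genome-wide rate estimate.

Other knobs users should be deliberate about: `max_gap` trades hotspot
sensitivity against span dilution; `min_hs_muts`/`min_hs_samples` guard
against single-sample artifacts; `window_size` below ~1 Mb makes the
local method noisy for sparse genomes; and `combine_wap` changes the
meaning (and degrees of freedom) of the combined p-value, which is why
it is off by default and WAP is reported alongside instead.
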