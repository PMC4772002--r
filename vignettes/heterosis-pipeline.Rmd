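---
title: "Classifying hybrid expression patterns: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hybrid expression patterns: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetvig)
```

## The scientific problem

When two inbred lines are crossed, the F1 hybrid often outperforms both
parents — heterosis, or hybrid vigor. One route to understanding it is to ask,
gene by gene, how the hybrid's expression relates to its parents'. Three
qualitative regimes are distinguished:

* **additive** — the hybrid sits at the parental mid-point while the parents
  differ;
* **expression-level dominance (ELD)** — the hybrid is statistically
  indistinguishable from one parent while the parents differ, "paternal" or
  "maternal" according to which parent it tracks;
* **transgressive** — the hybrid is significantly above (up) or below (down)
  both parents.

Crossed with the ordering of the two parents, these regimes yield twelve
classes: additive {1, 12}, ELD-paternal {2 high, 11 low}, ELD-maternal
{4 high, 9 low}, transgressive-up {3, 7, 10} and transgressive-down
{5, 6, 8}. `hetvig` implements the full decision pipeline from raw counts to
these classes, together with phenotype-level heterosis statistics and
length-bias-aware enrichment, and ships a simulator whose ground truth makes
every stage testable.

## Differential expression model

Counts for gene *i* in sample *j* are modelled as negative binomial with mean
$s_j \mu_{i,\rho(j)}$ and variance $\mu + \alpha\mu^2$, where $s_j$ is a
per-sample size factor, $\rho(j)$ the sample's line, and $\alpha$ the
dispersion. The stages are:

1. **Normalization** (`size_factors_median_ratio`): for each sample, the
   median over all-nonzero genes of the count divided by the gene's geometric
   mean across samples. The median is taken on the ratio scale.
2. **Dispersion** (`estimate_dispersion`): a method-of-moments estimate on
   normalized counts pooled within replicate groups,
   $\hat\alpha = (v - \bar\mu \cdot \overline{1/s})/\bar\mu^2$ floored at
   zero, then a parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fit across
   genes by least squares, and finally the **maximum** of the gene's own
   estimate and the trend value. Taking the maximum is deliberately
   conservative: it trades a little power for robust control of false calls
   when per-gene estimates undershoot at 2–3 replicates. Designs without
   replicates fall back to pooled ("blind") estimation across all samples,
   with a warning — such calls should be treated as exploratory.
3. **Exact test** (`nb_exact_test`): conditioning on the pooled total $T$ of
   the two groups, each group's sum is treated as a single negative binomial —
   the aggregate of its replicates, with mean proportional to its summed size
   factors and aggregate size $s_g^2/(\alpha \sum_j s_{gj}^2)$ (Poisson when
   $\alpha = 0$). The two-sided p-value sums the probabilities of all splits
   $(a, T-a)$ whose probability does not exceed the observed split's
   (ties included, with a $1+10^{-8}$ relative guard against floating-point
   ties), normalized by the total. The enumeration is vectorized over the
   $T+1$ splits, so genes with totals in the tens of thousands remain cheap.
4. **Multiple testing**: Benjamini–Hochberg within each pairwise comparison
   separately (hybrid vs maternal, hybrid vs paternal, paternal vs maternal),
   significance at adjusted p < 0.05 with no additional fold-change filter.
   Per-comparison adjustment is the standard behavior of count-based DE
   tools; adjusting jointly across the three comparisons would be slightly
   more conservative and can be emulated by adjusting the pooled p-vector
   yourself.

## The classifier

`classify_gene` is a total function over the 27 combinations of the three
calls (each up/down/ns) and the ordering of the three means. The decision
order is: all-ns → nonDEG; both hybrid–parent calls up → transgressive-up
(3/7/10 split by the parental comparison); both down → transgressive-down
(6/8/5); one hybrid–parent call ns with the other two significant → ELD
toward the ns parent (2/11 paternal, 4/9 maternal, high/low by the parental
direction); all three significant with the hybrid strictly between the
parents → additive (1 or 12 by parent order). Any remaining combination —
for example parents differing while the hybrid separates from neither — is
labelled `conflicting` rather than forced into a class: the twelve classes
are mutually exclusive and the scheme defines no residual bucket, so the
package makes the residual explicit. Additivity is required to show
significance of *all three* comparisons plus strict betweenness, the stricter
of the two readings of the scheme.

Genes with zero counts in **every replicate of at least one line** are set
aside as `excluded` before classification (their within-line mean is not
estimable); the alternative reading — any single zero sample excludes — is
available via `zero_rule = "any_zero"`.

The classifier satisfies a reciprocal-cross symmetry worth stating: swapping
the maternal and paternal roles maps classes 2↔4, 11↔9, 3↔10, 6↔5, 1↔12 and
fixes 7, 8 and nonDEG. The test suite asserts this over the exhaustive sweep.

## Phenotype heterosis

For line means $P_1$, $P_2$ and $F_1$, the mid-parent value is
$\mathrm{MPV} = (P_1 + P_2)/2$ and the rate of heterosis
$\mathrm{RH} = 100\,(F_1 - \mathrm{MPV})/\mathrm{MPV}$. Significance of the
F1's deviation from the MPV uses a normal-approximation contrast with
independent line SEs,
$z = (F_1 - \mathrm{MPV})/\sqrt{SE_{F1}^2 + (SE_{P1}^2 + SE_{P2}^2)/4}$,
marked `**` below 0.01 and `*` below 0.05. This contrast is one reasonable
formalization of an F1-vs-mid-parent test; published tables built on other
procedures may mark borderline crosses differently, so the formula is kept
in one documented function that is easy to swap.

Two numerical points. First, published tables often compute RH from the MPV
*after* rounding it to two decimals; `heterosis_rate(..., round_mpv = TRUE)`
reproduces that, and the default computes from full precision (the two can
differ in the last printed digit). Second, reproducing printed values
requires decimal half-up rounding: base `round()` operates on the binary
representation (98.135 is stored just below the half and rounds to 98.13),
so the package provides `round_half_up()` for display.

## Length-bias-aware enrichment

Longer genes accumulate more reads and are more likely to reach significance
at a given expression level, so category enrichment among DE genes must not
treat all genes as exchangeable. The probability weighting function (PWF) is
fit by splitting genes into 40 equal-occupancy length bins, taking each
bin's DE fraction, and smoothing with isotonic regression
(pool-adjacent-violators via `stats::isoreg`) so the fit is monotone
nondecreasing in length; per-gene weights are the fitted bin values clipped
to $(10^{-4}, 1-10^{-4})$. Binned isotonic regression was chosen over a
monotone spline: it is deterministic, has no smoothing parameter beyond the
bin count, and converges to the same function as the bin count grows with
the gene count.

A term's enrichment p-value is the upper tail $P(X \ge k)$ of the Wallenius
noncentral hypergeometric distribution — the biased-urn law of drawing the
$n$ DE genes without replacement from the background where each in-term gene
carries weight `odds` = (mean PWF inside the term)/(mean PWF outside). The
pmf is evaluated through Fog's integral representation
$P(X = x) \propto \binom{K}{x}\binom{N-K}{n-x}\int_0^1
(1-t^{\omega/D})^x (1-t^{1/D})^{n-x}\,dt$, $D$ the total weight of unsampled
genes, computed on the log scale with adaptive quadrature and renormalized
over the support. With unit odds this reduces to the central hypergeometric,
which the tests enforce to $10^{-9}$ up to backgrounds of 200 genes; biased
cases are validated against a 200,000-draw weighted-sampling Monte-Carlo
oracle. Pathway-style analyses without a length model use the central
hypergeometric (`hypergeom_enrichment`). BH adjustment is applied within
each ontology separately, with the corrected-p threshold a parameter
(default 0.05) rather than a constant.

## The simulator and what it does (not) emulate

`simulate_trio_counts` draws counts
$\mathrm{NB}(s_j \mu_{i,\mathrm{line}}, \alpha)$ with the per-gene mean
triple determined exactly by the gene's class: additive hybrids at the
arithmetic parental mid-point; ELD hybrids at one parent's level; parents
separated by the fold change $f$; transgressive-up hybrids at $f \times$ the
higher parent; transgressive-down at the lower parent divided by $f$
(symmetric to "up" and always positive). Size factors are uniform on a
configurable range (default 0.7–1.4, typical library-size spread).
Defaults — base mean 200, fold change 4, dispersion 0.01, 2 replicates —
reflect a well-powered bulk RNA-seq design on moderately expressed genes;
tests that state other values say so. Seeding derives one deterministic
substream per gene from the experiment seed, so results are reproducible and
independent of gene order; `simulate_heterosis_experiment` reuses one truth
(classes and means) across several crosses while redrawing counts, so
cross-intersection operations have planted ground truth.

The simulator emulates the *mean structure* and NB sampling noise of a trio
experiment. It does not emulate: variable effect sizes (all DE genes share
one fold change), length-dependent counting (gene length enters only the
annotation fixture), batch or sex effects, outlier replicates, or
correlation between genes. Passing recovery tests therefore demonstrates
that the pipeline's inference chain is correct under its own model, not that
real tissue data will classify as cleanly.

One interaction deserves emphasis: median-of-ratios normalization assumes
most genes are unchanged. Simulations in which a large majority of genes are
differentially expressed with asymmetric direction shift the per-sample
median and, at very low dispersion, every small normalization bias becomes a
significant call. The validation suites therefore keep a nonDEG anchor in
the class mixture (the ultra-low-dispersion recovery test uses 70 % nonDEG),
which is also the realistic regime; the equal-mass-across-all-classes
recovery run is symmetric enough for the median anchor to hold.

## Problem sizes and determinism

The shipped validation runs use 1,200 genes over all thirteen labels
(3 replicates, fold change 4, dispersion 0.01) for category recovery, a
2,000-gene all-nonDEG run for the false-call rate, 2,000 replications of the
mid-parent null for the z-test's type-I rate, and backgrounds up to a few
thousand genes for enrichment power — sizes at which every statistical
property of interest is measurable with tight Monte-Carlo error while the
whole suite runs in well under a minute. All randomness flows from explicit
integer seeds; `run_pipeline` writes byte-identical outputs for identical
config and seed, and records a config hash and per-stage counts in its
manifest.

## Known limitations

* The NB exact test uses the aggregate-NB approximation for unequal
  replicate size factors (exact for equal ones); GLM-based designs with
  covariates are out of scope.
* The dispersion trend $a_0 + a_1/\mu$ is coarser than a local-regression
  fit; combined with maximum-sharing it is conservative by design.
* The classifier binds significance to padj < 0.05 per comparison; classes
  near decision boundaries (e.g. additive vs ELD at small parent separation)
  are power-limited, and `conflicting` rates rise as power falls.
* Enrichment treats terms independently: no term hierarchy, propagation, or
  pathway topology.
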