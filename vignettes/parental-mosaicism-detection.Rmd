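---
title: "Detecting parental mosaicism against a pooled control background"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parental mosaicism against a pooled control background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaiscan)
```

## The model

A de novo variant observed in a child is tested for low-level mosaicism
in each parent from ultra-deep targeted sequencing of parental blood
DNA. At the targeted position, the parent contributes an alternative
read count $k$ out of depth $d_p$, and the parents of the other families
captured in the same pool — who do not carry this variant — provide a
position-matched estimate of the sequencing background:

$$\hat p_0 = \frac{\sum_c \text{alt}_c}{\sum_c \text{depth}_c}$$

summed over controls with positive depth. The null hypothesis is that
the parent's alternative reads are background noise; the alternative is
an excess consistent with mosaicism. Because $\hat p_0$ is often
extremely small (frequently exactly zero), a one-sided exact Poisson
test is used on the count scale:

$$p = P(X \ge k), \qquad X \sim \text{Poisson}(\lambda_0),
  \qquad \lambda_0 = d_p\, \hat p_0 .$$

Two tests are run per family (father, mother), and significance is
declared at the experiment-wide Bonferroni level $\alpha =
0.05/(2\,n_{\text{fam}})$, recomputed from the number of testable
families in the input (for 189 families, $\alpha = 1.32\times10^{-4}$).
Ties at $p = \alpha$ are significant.

Model assumptions worth keeping in view:

* counts are treated as Poisson although the data-generating process is
  binomial; at depths of thousands and fractions below a few percent the
  approximation is excellent and errs on the conservative side (binomial
  variance is smaller);
* the pooled $\hat p_0$ is treated as known, not estimated; with
  ~46 controls at ~7000× the pooled depth exceeds $3\times10^5$ and the
  estimation noise is second-order;
* the position's background is assumed identical in parents and
  controls (same chemistry, same pool).

### The zero-background limit

When no control carries a single alternative read, $\lambda_0 = 0$ and
any $k \ge 1$ gives $p = 0$: one read over a clean background is
experiment-wide significant. This is a deliberate convention, not an
artifact — in noise-free sequence contexts (non-repetitive indels,
for instance) a single UMI-deduplicated read is genuine evidence, and
the deepest real mosaics are found exactly there. For analysts who want
a softer rule, `call_candidates(..., pseudocount = )` adds virtual
alternative reads to the control pool before forming $\hat p_0$;
the default is 0.

Conversely $k = 0$ gives $p = 1$ exactly: absence of reads is never
evidence. A parent with zero depth, or a position with no usable
control, is *untestable* and flagged as such — never counted as a
negative. A family in which both parents reach significance is flagged
as a suspect artifact (`both_parents_flag`) but reported, since a true
mosaic is carried by one parent.

## Power and detection limits

Detection power differs across positions for two reasons: depth and
background noise. For each position the power of the exact test is
evaluated on an allele-fraction grid with the *average control depth*
$\bar n$ as sample size:

* critical value $k^\* = \min\{k : P(X \ge k \mid \bar n \hat p_0) \le
  \alpha\}$;
* power at fraction $p_1$: $P(X \ge k^\* \mid \bar n p_1)$.

The alternative rate is $\bar n p_1$, i.e. the targeted fraction itself;
`power_at_af(..., add_background = TRUE)` switches to
$\bar n(p_0 + p_1)$ for sensitivity analysis. The *detection limit* at a
target power (default levels 0.8 and 0.9) is the smallest grid point
whose power reaches the level. For $\hat p_0 = 0$ the 90% limit has the
closed form $\ln(10)/\bar n$, which the test suite uses as an oracle.

Numerical and design choices:

* **Grid**: 400 log-spaced points on $[10^{-4}, 0.4]$ (0.01%–40%).
  Log spacing matches the dynamic range of mosaic fractions; the
  resolution bounds the limit's granularity at ~2% relative, well below
  biological variability. Both range and resolution are configurable in
  `power_spec()`.
* **$\bar n$ stays real-valued** — a Poisson rate needs no integer
  sample size.
* **Censoring**: a position whose curve never reaches the target power
  on the grid gets an undefined limit, flagged `censored`, and counts as
  "not detectable" at every threshold in `detectability_summary()`;
  quantiles are taken over defined limits only.
* **Monotonicity**: power is exactly non-decreasing in $p_1$ (the
  critical value is fixed by the null). In $\bar n$ it is monotone only
  up to the discreteness sawtooth of the non-randomized exact test when
  $\hat p_0 > 0$; the property tests assert exact monotonicity for the
  clean-background case and bounded ripple otherwise.
* **Exactness**: the non-randomized test is conservative — its achieved
  size $P(X \ge k^\* \mid \lambda_0)$ is $\le \alpha$ always, which the
  suite asserts across random rates.

## Pileup genotyping

Genotyping is motif counting in samtools-mpileup base strings. The
tokenizer follows the mpileup dialect: `.`/`,` reference matches by
strand, `ACGTN`/`acgtn` substitutions, `*`/`#` deletion placeholders,
`>`/`<` reference skips, `^X` (start marker, consuming one
mapping-quality character) and `$` (end marker) contributing no tokens,
and `+nSEQ`/`-nSEQ` indel motifs attached to the preceding base as
separate tokens. Counting rules:

* depth = base-level tokens (matches, substitutions, `*`), excluding
  reference skips; indel motifs are attachments, not depth;
* SNV alternative count = case-insensitive count of the alt base among
  substitutions;
* insertion/deletion alternative count = case-insensitive count of
  matching `+nSEQ`/`-nSEQ` motifs at the anchor position — `*`
  placeholders downstream count in depth but never as alternative, so
  one deletion event is counted once;
* base qualities are ignored: counts are post-UMI-deduplication
  consensus calls and no quality filter is part of the method;
* multi-nucleotide substitutions are rejected at target validation
  (targets are SNVs and short left-anchored indels).

Malformed strings (truncated indel motif, missing indel length,
dangling `^`, unknown symbol) are hard parse errors naming the offending
position; zero depth is a flagged row, not an error.

## The synthetic cohort generator

`cohort_config()` defaults describe the study design this pipeline
targets: 189 families in 8 pools; two parents plus up to 46 controls
(the other families' parents in the pool) per position; per-sample
depth $\sim \text{LogNormal}(\log 7225,\; 0.6)$ — median 7225×, with
the order-of-magnitude spread across positions that smMIP enrichment
produces; a 124:62 SNV:indel target mix (indels 1–5 nt, split
INS/DEL); 45:144 cohesinopathy:DD/ID/autism subgroup mix; and 7/189
planted parental mosaics with allele fraction log-uniform on
$[2\times10^{-4}, 0.315]$, paternal with probability 5/7.

The background-error model is **zero-inflated Beta**: with probability
0.7 a position is error-free (point mass at zero — the clean sequence
contexts where single-read detection operates), otherwise the error
rate is Beta with mean 0.3% (shape1 = 2), resampled above a 1% cap, so
noisy positions average 0.3% with occasional values approaching 1%.
The zero-inflation is a point mass deliberately: a continuous "almost
zero" error rate would make the zero-background $p=0$ rule
anti-conservative (a pooled control depth of $3\times10^5$ can draw
zero alternative reads while the parent draws one from the same noise),
and it would misrepresent the empirical phenomenon being modelled —
contexts with *no* observable noise.

Counts are **binomial**, not Poisson: controls and non-mosaic parents
draw $\text{Binomial}(d, e_i)$, the mosaic parent
$\text{Binomial}(d, e_i + \text{af}(1 - e_i))$. The signal composes
with noise, so AF estimates are slightly biased upward at noisy
positions — as in real data — and the Poisson test's size and power
become *tested properties* of the pipeline rather than assumptions.
Paternal ages are log-normal (median ≈ 33 y, log-sd 0.15) with a 4.1-y
downward shift for mosaic families, emulating the dilution of embryonic
mosaics relative to age-accumulating spermatogonial mutations; a
14/189 fraction of non-mosaic families has missing ages.

`emit_mpileup()` renders any simulated cohort as valid mpileup text
(randomized strand case, occasional `^I`/`$` markers) whose re-parsed
counts equal the planted counts exactly — the round-trip identity the
test suite enforces.

What the generator does **not** emulate: correlated noise across
positions in the same sequence context, capture bias beyond the depth
distribution, UMI family structure, strand bias, or contamination.
Passing tests therefore demonstrate the statistical machinery's
correctness and calibration under the stated models, not robustness to
every failure mode of real libraries.

## Cohort statistics

* Prevalence uses exact (Clopper–Pearson) binomial intervals and
  reports percentages to one decimal.
* The 2×2 association tests (variant type, subgroup) use the two-sided
  Fisher exact test under the probability-mass rule; the suite verifies
  it against full hypergeometric enumeration and its invariance under
  table transposition and row/column swaps.
* The paternal-age comparison mirrors R's Wilcoxon default — exact when
  both groups have fewer than 50 observations and no ties, otherwise
  the tie- and continuity-corrected normal approximation — and always
  records which branch ran. Missing ages are dropped pairwise.
* Candidate calls are treated as confirmed in the synthetic pipeline
  (orthogonal confirmation modelled as a pass-through), so prevalence
  counts candidates; in a real deployment the confirmation step slots
  between detection and reporting.

## Problem sizes and reproducibility

The default analysis scale is the full design: 189 families,
~8.9 thousand (sample, position) count rows, 378 tests. The
calibration checks in the test suite use 200 replicate null cohorts at
that scale for test size and 50 replicates with 7 planted mosaics each
(at twice the per-position 90% detection limit) for power — large
enough that the Monte-Carlo error bands in the assertions are a few
percent. The mpileup round-trip runs on a 20-family cohort, which at
~7000× depth already exercises ~4 million pileup symbols. Everything is
deterministic given the seeds fixed in the scripts and tests; the
generator uses R's RNG stream exclusively.

## Known limitations

* The Poisson-on-counts model ignores overdispersion between control
  samples; a position where one control is an outlier (e.g. a true rare
  variant in a control parent) inflates $\hat p_0$ and costs power
  rather than specificity.
* Detection limits use the *average* control depth, while a specific
  parent's depth may be lower; a mosaic at the limit in a shallow
  parent sample has less than nominal power.
* Blood sequencing cannot see mosaicism confined to the germline, and
  the blood allele fraction is an imperfect proxy for germline burden;
  the pipeline quantifies detectability in the assayed tissue only.
* `fisher_exact_2x2` and the Wilcoxon wrapper delegate to R's stats
  implementations; the package's contribution is the detection and
  power machinery, and the wrappers exist to fix conventions
  (two-sidedness, zero margins, method recording) and keep the report
  self-contained.
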