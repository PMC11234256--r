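---
title: "Comparative AP-MS interactome analysis with adaptive two-stage FDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative AP-MS interactome analysis with adaptive two-stage FDR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsenrich)
```

## The problem

In a comparative affinity-purification mass-spectrometry (AP-MS)
experiment, a tagged bait protein -- here procollagen-II, either wild-type
or carrying a disease-causing glycine substitution -- is immunoprecipitated
together with its interaction partners, and all co-purifying proteins are
quantified in a single TMT multiplex run: three wild-type bait channels,
three variant bait channels, and three no-transfection negative-control
channels. Two statistical questions follow:

1. **Which detected proteins are genuine bait interactors**, as opposed to
   proteins that stick to beads, antibody or tube regardless of the bait?
2. **Which genuine interactors engage the variant bait more (or less) than
   the wild-type bait**, and with what statistical confidence?

`apmsenrich` implements this analysis as composable stages with explicit
degenerate-input policies, together with a synthetic-data generator so the
error-rate guarantees of the whole pipeline can be verified by simulation.

## The model, stage by stage

### Negative-control filter

For each protein \(i\), the nonspecific-binding baseline is the arithmetic
mean of its **raw** abundances over the negative-control channels, with
missing values treated as zero. A protein is a *high-confidence
interactor* when its raw abundance exceeds twice this baseline (strictly)
in at least 4 of the 6 bait-expressing channels:

\[
\#\{c : a_{ic} > 2\,\bar{a}^{\mathrm{ctrl}}_{i}\} \ge 4 .
\]

Filtering happens before bait normalization because the control channels
contain no bait to normalize against. Two policies are deliberate: a zero
baseline (protein never seen in controls) passes wherever the experimental
signal is positive -- absence from the control is the strongest evidence of
bait dependence -- and a missing experimental value fails that channel.
Two variants of this rule circulate for the same published analysis
("4 of 6 samples" versus "all three replicates"); the 4-of-6 reading
annotates the published interactor table and is therefore the default,
with `filter_rule(mode = "all_replicates")` available for the stricter
reading. Both the threshold and the channel requirement are monotone:
tightening either can only shrink the retained set (a tested invariant).

### Bait normalization and fold enrichment

Within each bait-expressing channel \(c\), every abundance is divided by
the bait's abundance in that channel,
\(x_{ic} = a_{ic} / a_{\mathrm{bait},c}\), cancelling differences in
transfection efficiency, pull-down yield and channel loading. Any global
per-channel rescaling of the raw data therefore leaves all downstream
results unchanged (tested exactly). The *fold enrichment* of protein
\(i\) is

\[
\mathrm{FE}_i \;=\;
\frac{\overline{x}_{i,\mathrm{variant}}}{\overline{x}_{i,\mathrm{WT}}},
\]

the ratio of mean bait-normalized abundance in the variant condition to
the wild-type condition. Means rather than sums are used so that unequal
effective replicate counts (after missingness) behave sensibly; with equal
counts the two formulations are identical (asserted numerically in the
tests). A protein with no usable value in one condition, or a zero
wild-type mean, gets an undefined fold enrichment and is flagged rather
than dropped.

### Significance testing

Per protein, the three wild-type and three variant bait-normalized values
are compared with a two-sided pooled-variance (homoscedastic) *t*-test,
\(\mathrm{df} = n_1 + n_2 - 2\). By default the test runs on the
normalized scale directly, the literal reading of the published method;
`log_transform = TRUE` applies the test to \(\log_2\) values, which is the
exactly calibrated choice when noise is multiplicative, and is what the
simulation harness uses. Zero pooled variance is resolved
deterministically (\(p = 1\) for equal means, \(p = 0\) otherwise, both
reported) so that pipelines never silently lose proteins. A Welch variant
with Satterthwaite degrees of freedom is provided for settings where equal
variances cannot be assumed.

### Adaptive FDR: the two-stage step-up procedure

Multiple testing is corrected with the two-stage step-up procedure of
Benjamini, Krieger and Yekutieli at a desired FDR level \(q\) (default
10%). Stage one runs the linear (Benjamini--Hochberg) step-up at the
shrunken level \(q' = q/(1+q)\); its rejection count \(r_1\) gives the
null estimate \(\hat m_0 = m - r_1\). Stage two reruns the step-up at
level \(q'\) with \(\hat m_0\) in place of \(m\): reject rank \(k\) iff
\(p_{(k)} \le k\,q'/\hat m_0\). Edge cases follow the original procedure
(\(r_1 = 0\): accept all; \(r_1 = m\): reject all); ties share the larger
rank's threshold.

**q-values.** The procedure itself only yields accept/reject decisions at
one level, yet the field's software reports per-protein q-values without
defining them. This package defines the q-value as *the smallest desired
FDR level at which the procedure rejects the hypothesis*, computed on a
level grid (default step \(10^{-4}\)). Because the rejection set is a
prefix of the p-value order and grows monotonically with the level (a
tested invariant), the search runs as a per-rank binary search, and
decisions and q-values are mutually consistent by construction:
rejected at level \(q\) \(\iff\) q-value \(\le q\) for any grid level. A
closed-form variant (`bky_q_values_closed()`, essentially BH-adjusted
p-values scaled by \(\hat m_0/m\)) is provided clearly labelled as an
approximation; it omits the \(q/(1+q)\) shrinkage and fixes \(\hat m_0\)
at a single level, so the two definitions drift apart for large q-values.

On the packaged 26-protein worked example (`table1_fixture()`), the
procedure at the 10% level gives \(q' = 0.0909\), \(r_1 = 2\),
\(\hat m_0 = 24\), and rejects exactly the two proteins whose published
q-values fall below 0.10:

```{r table1}
tab <- table1_fixture()
res <- bky_two_stage(tab$p_value, q_target = 0.10)
res
tab$gene[res$rejected]
```

The exact published q-value magnitudes are not recomputable from the
printed table alone -- the p-values are rounded to four decimals, and
neither the q-value variant nor the hypothesis family (the 26 tabled
proteins versus all detected proteins) is stated -- so the package's
checks rest on the rejection *decision*, which is robust across those
choices, plus the oracle equivalences above.

## The synthetic-data generator

`simulate_apms()` draws complete experiments from a generative model that
mirrors the 3+3+3 design and the analysis assumptions, with ground-truth
labels:

| parameter | default | meaning |
|---|---|---|
| `n_background_binders` | 200 | bait-dependent preys with true fold 1 |
| `n_nonspecific` | 100 | binders with equal signal in all 9 channels |
| `n_differential` | 20 | preys enriched on the variant bait |
| `differential_fold` | 2.0 | planted variant/WT fold (the magnitude of the strongest published hit) |
| `noise_cv` | 0.10 | CV of multiplicative log-normal noise, a typical TMT reporter-level precision |
| `bait_level` | 1000 | mean bait abundance per experimental channel, ±10% uniform channel jitter |
| `control_carryover` | 0.3 | fraction of a prey's binding signal left in control channels |
| `binding_meanlog`, `binding_sdlog` | log(50), 1 | log-normal spread of per-prey binding scales |

Noise is multiplicative log-normal (unit mean), so the log2-scale t-test
is exactly calibrated and the raw-scale option is approximate -- which is
why the FDR harness tests on the log2 scale. The per-channel bait jitter
exercises exactly the artefact bait normalization must cancel. The
no-model-available quantities (noise CV, carryover, binding spread) are
stated assumptions chosen to be realistic for TMT AP-MS data, not values
taken from any dataset; they were fixed once, before any benchmarking.

What the generator deliberately does *not* emulate: peptide-to-protein
rollup, isotopic-impurity interference between TMT channels,
missing-not-at-random censoring of low-abundance proteins, and
correlated binding between preys (each prey's noise is independent apart
from the shared bait denominator). Passing simulation benchmarks
therefore demonstrates the statistical machinery is correct under its own
assumptions, not that real TMT data satisfy those assumptions.

`fdr_simulation()` composes the full pipeline over many replicates
(per-replicate seed = master seed + replicate index) and reports the
empirical FDR and power with Monte-Carlo standard errors. Under the
default configuration (220 bait-dependent proteins of which 20 are truly
differential), 500 replicates give an empirical FDR of about 8.5% at the
10% target -- controlled, as the theory promises under independence -- at
about 68% power to detect a 2-fold interaction change with triplicates at
10% noise. These are also the problem sizes used by the package's
acceptance checks (500 replicates; 200 recovery replicates for the
fold-enrichment bias check; 1,000 random p-value sets for the q-value
oracle equivalence), chosen so the full suite runs in about a minute.

## Blinded multi-rater tissue scoring

The second statistical component handles blinded image scoring of
intracellular retention: three independent raters count, per image, total
cells and cells with intracellular staining, across genotypes.

* **Point estimate**: per rater and genotype, the *pooled* proportion
  \(\sum \mathrm{pos} / \sum \mathrm{total}\) over that rater's images;
  the genotype estimate is the mean across raters, with the SEM across
  raters as the error bar. Pooling weighs each cell equally.
* **Significance**: per rater, a Welch *t*-test on *per-image* proportions
  between two genotypes; the reported p-value is the **maximum** across
  raters. Per-image proportions are the only replication unit that yields
  a within-rater variance (the published method does not state its unit
  of replication; both choices are recorded here). The max-p rule is
  conservative by construction -- a significant report means every blinded
  rater independently reached significance -- and under the null the
  reported p is far sub-uniform (rejections in well under 5% of null
  simulations, a tested property).
* No minimum-cells-per-image exclusion is applied by default (none is
  published); `simulate_rater_counts()` provides matched synthetic count
  tables with logit-scale image heterogeneity shared across raters.

`compare_measurements()` covers the remaining two-group comparisons
(apoptosis signal per area across sections, organoid diameters), with
Welch as the default variance mode since equal variances are rarely
defensible for such measurements and the published analyses do not name a
variant.

## Numerical and design notes

* **Missing values**: kept as `NA` at load; baseline treats them as 0,
  the filter fails the channel, normalization propagates them, fold
  enrichment and t-tests drop them (with a minimum of 2 values per group
  for testing).
* **Ties** in p-values share a step-up threshold and a q-value.
* **Sorting** of results: fold enrichment descending, ties by p-value
  ascending then protein id -- the printed-table convention, made total.
* **FDR family**: the filtered high-confidence set by default (the family
  the published table reports); `family = "all"` adjusts over every
  detected non-bait protein instead.
* **Determinism**: every generator is a pure function of its seed and
  restores the caller's RNG stream; the simulation harness derives
  per-replicate seeds by a plain counter so individual replicates can be
  reproduced in isolation.
* **Limitations**: no moderated-variance testing (the published analysis
  used plain t-tests on triplicates, and so does this package); no
  spectral-level processing -- the pipeline starts from a protein-level
  abundance table; no permutation or local FDR alternatives.
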