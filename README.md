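# apmsenrich

Comparative AP-MS interactome enrichment analysis with adaptive two-stage
FDR control.

## What this package is for

In a comparative affinity-purification mass-spectrometry (AP-MS)
experiment, a tagged bait protein (for example wild-type versus
disease-variant procollagen-II) is pulled down together with its
interaction partners, and all co-purifying proteins are quantified in one
TMT multiplex: 3 wild-type bait channels, 3 variant bait channels and 3
no-transfection negative controls. `apmsenrich` turns the resulting
protein-by-channel abundance table into a ranked table of differential
interactors:

1. **Negative-control filter** — protein *i* is a high-confidence
   interactor when its raw abundance exceeds 2× its averaged
   negative-control baseline (strictly) in ≥ 4 of the 6 bait-expressing
   channels.
2. **Bait normalization** — x<sub>ic</sub> = a<sub>ic</sub> /
   a<sub>bait,c</sub>, cancelling per-channel pull-down efficiency.
3. **Fold enrichment** — FE<sub>i</sub> = mean(x<sub>i,variant</sub>) /
   mean(x<sub>i,WT</sub>).
4. **Homoscedastic t-test** per protein across the replicates (Welch
   variant also provided), with explicit zero-variance and missing-value
   policies.
5. **Two-stage step-up FDR** (Benjamini–Krieger–Yekutieli) at a desired
   FDR *q*: BH step-up at q′ = q/(1+q) estimates the null count
   m̂₀ = m − r₁, then a second step-up runs with m̂₀ in place of m.
   Per-protein q-values are defined as the smallest level at which the
   procedure rejects (grid search).

It also implements the accompanying tissue-scoring statistics (blinded
multi-rater retention proportions with between-rater SEM and a
conservative max-p rule; two-group measurement comparisons), and a
synthetic-data generator with ground-truth labels for validating the
entire pipeline by simulation.

## Worked example

The packaged fixture `table1_fixture()` carries the 26 high-confidence
interactors of a published procollagen-II interactome with their printed
p-values. Re-running the two-stage procedure at the published 10% desired
FDR:

```r
library(apmsenrich)
tab <- table1_fixture()
res <- bky_two_stage(tab$p_value, q_target = 0.10)
res
#> two-stage step-up FDR: m = 26, q = 0.1 (q' = 0.09091), r1 = 2, m0 = 24, rejected = 2
tab$gene[res$rejected]
#> [1] "PLOD2" "P4HB"
round(res$q_values[match(c("P4HB", "PLOD2", "CALR"), tab$gene)], 4)
#> [1] 0.0106 0.0179 0.1023
```

Exactly the two proteins whose published q-values fall below 0.10 are
rejected — the protein disulfide-isomerase P4HB and the lysyl hydroxylase
PLOD2, the ER enzymes most enriched on the misfolding-prone bait — and
the search-based q-values land within rounding of the published ones
(0.0101, 0.0181, 0.1021).

A full synthetic run:

```r
sim <- simulate_apms(apms_sim_config(seed = 7))
out <- run_pipeline(sim$abundance, sim$layout,
                    pipeline_config(log_transform = TRUE, q_target = 0.10))
head(out, 3)
#>  protein gene fold_enrichment   p_value q_value significant high_confidence pass_count
#>  DIF_017 <NA>           2.262 3.349e-04  0.0251        TRUE            TRUE          6
#>  DIF_008 <NA>           2.220 5.551e-03  0.0812        TRUE            TRUE          6
#>  DIF_006 <NA>           2.071 9.083e-05  0.0204        TRUE            TRUE          6
```

The 100 nonspecific binders are removed by the filter (220 of 320
non-bait proteins retained), and the top fold-enrichment ranks are
occupied by the planted differential interactors (true fold 2).

Validating FDR control of the whole pipeline:

```r
f <- fdr_simulation(apms_sim_config(), reps = 500, q_target = 0.10, master_seed = 1)
round(c(fdr = f$fdr, se = f$fdr_se, power = f$power), 4)
#>    fdr     se  power
#> 0.0846 0.0064 0.6790
```

The empirical FDR stays below the 10% target, at ~68% power for 2-fold
interaction changes with triplicates at 10% noise.

See the vignette (`vignettes/comparative-interactome-analysis.Rmd`) for
the model details, parameter meanings and limitations.

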