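# csfsubtypes

Subtype discovery from cerebrospinal-fluid (CSF) proteomics, for
researchers studying heterogeneity in (pre-clinical) Alzheimer's disease:
individuals who are cognitively intact with normal amyloid/tau biomarkers
can already carry distinct CSF protein profiles — neuronal-hyperplasticity
-like, innate-immune-like, blood–brain-barrier-dysfunction-like — and this
package implements the full analytical pipeline that finds and
characterizes such subtypes, together with a synthetic-cohort generator so
the whole pipeline is testable without access-controlled cohort data.

## What it computes

* **Harmonization** of fragment-level MRM, RBM and ELISA measurements into
  one standardized subject × protein matrix: z-normalization to a control
  group, roll-up of correlated fragments (Pearson r > 0.5) into protein
  scores, platform reconciliation (average if r > 0.5, else keep MRM,
  exclude on r ≤ −0.5), 100%-completeness and panel filters, and an
  invertible nonnegativity shift.
* **Nonsmooth NMF**: V ≈ W·S·H with S = (1−θ)I + (θ/k)J, multiplicative
  updates (monotone rss), multi-restart **consensus clustering** with the
  cophenetic coefficient ρ of the consensus matrix, mean silhouette width,
  and **rank selection** by three criteria (ρ high; fit gain ≥ 2-fold over
  a permuted-data baseline; silhouette ≥ 0.5) with an explicit failure
  state when no rank qualifies.
* **Characterization**: loading-outlier detection and re-clustering,
  protein → subtype labelling, subtype-specific protein sets (higher than
  *every* other subtype at α), difference profiles, the overlap
  coefficient |A∩B| / min(|A|,|B|) against reference profiles, and
  brain-cell-type specificity labels (>50% dominance / <0.2 detection
  rules).
* **Longitudinal slopes**: per-subtype change per year in Aβ42, p181-tau
  and delayed-memory scores from random-intercept mixed models (β, SE, p),
  subtype × time interaction tests, and baseline comparisons.

## Worked example

```r
library(csfsubtypes)

cohort <- generate_cohort(cohort_config(seed = 42))  # 120 subjects, 300 proteins, k = 3
pp  <- preprocess_fragments(cohort$fragment_table, cohort$control_ids)
V   <- nonneg_shift(t(pp$matrix))                    # proteins x subjects, V >= 0
sel <- select_rank(V, ranks = 2:5, n_runs = 20, seed = 42)
print(sel)
#>  rank cophenetic silhouette      rss rss_perm  fit_gain fit_gain_perm
#>     2  0.9239498  0.7577264 31102.63 31962.99 1624.2899      707.8200
#>     3  0.9816282  0.9138091 29616.39 31234.90 1486.2373      728.0893
#>     4  0.9641246  0.6231001 28905.97 30563.01  710.4207      671.8836
#>     5  0.9370073  0.3947395 28251.55 29977.49  654.4206      585.5253
#>  crit_cophenetic crit_fit crit_silhouette admissible
#>            FALSE     TRUE            TRUE      FALSE
#>             TRUE     TRUE            TRUE       TRUE
#>             TRUE    FALSE            TRUE      FALSE
#>            FALSE    FALSE           FALSE      FALSE
#> Selected rank: 3
```

Rank 3 is the largest rank whose cophenetic coefficient sits on the
plateau (within 0.02 of the maximum), whose fit gain beats twice the
permuted-data gain, and whose silhouette clears 0.5 — the generator's true
number of subtypes. The consensus at that rank and the recovered labels:

```r
cons <- sel$consensus[["3"]]
print(cons)
#> nsNMF consensus: rank 3 | 20 runs | cophenetic 0.9816 | mean silhouette 0.9138
pred <- predict_subtypes(cons$best_model)
adjusted_rand_index(pred$labels, cohort$true_labels[names(pred$labels)])
#> 0.83
table(pred$labels)
#>  1  2  3
#> 38 48 34
```

Longitudinal slope of Aβ42 in subtype-1 subjects (the generator's default
trend is −4.4 pg/mL per year; this cohort draws 36 such subjects):

```r
fit_subtype_slope(cohort$longitudinal_table, "abeta42", 1)
#> abeta42 subtype 1: beta = -3.630 +/- 1.100 per year (p = 0.00148, 36 subjects, 112 obs, mixed)
```

A negative β means amyloid-β 1–42 is drifting toward abnormal levels in
that subtype. The single-call pipeline (`run_pipeline()`) chains all
stages — preprocess, rank selection, clustering, outlier recheck,
characterization, longitudinal — from one YAML/list config with one seed,
and writes a JSON + Markdown run report. A command-line front end with
`simulate | preprocess | cluster | characterize | longitudinal | run`
subcommands lives in `inst/cli/csfsubtypes.R`.

## Further reading

`vignettes/csf-subtyping-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, what the synthetic generator
does and does not emulate, numerical edge cases, and known limitations.
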