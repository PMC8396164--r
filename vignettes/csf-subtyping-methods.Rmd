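---
title: "Methods: CSF proteomic subtype discovery with nonsmooth NMF"
author: "csfsubtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSF proteomic subtype discovery with nonsmooth NMF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfsubtypes)
```

# The problem

Cerebrospinal-fluid (CSF) proteomics can separate individuals into
pathophysiological subtypes — e.g. neuronal hyperplasticity, innate immune
activation, and blood–brain barrier dysfunction profiles — even before the
classical Alzheimer biomarkers (amyloid-β 1–42, p181-tau) become abnormal.
`csfsubtypes` packages that analysis end to end: harmonizing
multi-platform protein measurements into one standardized matrix,
discovering subtypes by nonsmooth non-negative matrix factorization (nsNMF)
with consensus clustering, characterizing the subtypes (specific proteins,
overlap with reference difference profiles, brain-cell-type specificity),
and estimating longitudinal biomarker slopes per subtype. Because the
cohort-level data such analyses run on are access-controlled, the package
ships a synthetic-cohort generator with known ground truth; every stage is
tested against it.

# Preprocessing model

Measurements arrive as fragment-level values (targeted mass-spectrometry
MRM fragments), plus protein-level values from secondary platforms (RBM
multiplex immunoassay, ELISA). The harmonization chain is:

1. **z-normalization to controls.** Every fragment/protein is standardized
   by the mean and SD of a designated control group:
   $z = (v - \mu_{ctl})/\sigma_{ctl}$. Proteins with zero control SD are
   not standardizable and are dropped with a warning.
2. **Fragment roll-up.** Fragments of one protein are averaged into a
   protein score when they correlate (Pearson $r > 0.5$, strict
   inequality); fragments that do not correlate are left out. With more
   than two fragments the rule is under-determined, so retention is greedy:
   repeatedly drop the fragment with the lowest mean pairwise $r$ until
   every retained fragment's mean pairwise $r$ exceeds the threshold. This
   is deterministic and reduces to the plain keep/drop rule for two
   fragments. Fragment correlations are computed across all subjects (not
   controls only); that choice is configurable because the convention is
   not fixed in the field.
3. **Platform reconciliation.** For proteins measured on two platforms:
   $r > 0.5$ → average the standardized vectors; $-0.5 < r \le 0.5$ → keep
   the MRM measurement; $r \le -0.5$ (strong anticorrelation, a sign of an
   assay problem) → exclude the protein entirely.
4. **Completeness and panel filters.** Only proteins observed in 100% of
   subjects, and optionally only proteins on a disease-associated panel,
   are retained.
5. **Nonnegativity shift.** NMF needs $V \ge 0$ while z-scores are signed.
   The default subtracts the single global minimum from every entry. A
   per-protein shift is available but not the default: a global shift
   preserves all between-protein contrasts, which the subtype profiles
   rely on; the shift is recorded and invertible.

# The nsNMF model

The analysis matrix $V$ (proteins × subjects, nonnegative) is factorized as

$$V \approx W\,S\,H,\qquad
S = (1-\theta)\,I + \frac{\theta}{k}\,J,$$

with $W \ge 0$ the protein profiles, $H \ge 0$ the subject loadings, and
$S$ the nonsmooth mixing matrix ($J$ = all-ones). Smoothing one factor
forces sparseness on the other, which gives cleaner, more separable
subtype profiles. $\theta$ is not pinned down by the analyses this design
follows; the default is 0.5, the customary default of the reference implementation, and
it is exposed in every entry point. Optimization uses the standard
multiplicative updates for the Frobenius objective with $WS$ (resp. $SH$)
treated as the basis (coefficients), so the residual sum of squares is
non-increasing at every iteration — a property the test suite asserts
numerically on every run it makes. Convergence: relative rss change
$< 10^{-6}$ or 2000 iterations. Initialization: i.i.d. uniform(0,1) entries
scaled to $\sqrt{\bar V / k}$, deterministic given a seed.

Subjects are labelled by the argmax of their loading column (ties go to
the lowest component index, with a warning); new subjects are first
projected onto the fixed basis $WS$ by nonnegative least squares.

# Consensus, stability, and rank selection

NMF is stochastic, so classification can vary from run to run. Stability
is quantified over 50 restarts via the consensus matrix $C$ (fraction of
runs two subjects co-cluster) and its cophenetic coefficient $\rho$: the
correlation between the consensus dissimilarities $1 - C$ and the
cophenetic distances of their average-linkage hierarchical clustering
(average linkage is the convention of the consensus-NMF literature).
$\rho = 1$ means subjects are always classified the same; if all
dissimilarities are exactly equal the correlation is undefined and the
implementation returns 1 when the tree reproduces the distances exactly
(the perfectly stable endpoint) and 0 otherwise.

A candidate rank $k$ is accepted when

1. $\rho(k)$ is *high* — operationalized as within 0.02 of the maximum over
   the tested range, a deterministic version of "pick the plateau";
2. the fit gain over the next-lower rank is at least 2-fold the gain on a
   random solution: $\mathrm{rss}(k{-}1)-\mathrm{rss}(k) \ge
   2\,[\mathrm{rss}_{perm}(k{-}1)-\mathrm{rss}_{perm}(k)]$, where the
   random baseline shuffles each protein's values across subjects
   independently (marginals preserved, co-structure destroyed), with a
   fresh permutation per restart;
3. mean silhouette width on $1 - C$ under the consensus labels is ≥ 0.5.

The selected rank is the **largest** admissible one; when no rank
qualifies the result is an explicit failure state, never a silent default.
Pure-noise matrices reach that state in the acceptance suite.

Orientation note: the matrix is factorized proteins-as-rows, so $W$ holds
protein profiles and $H$ subject loadings (the dual-clustering reading).
Transposing would swap the roles; the chosen orientation is asserted
throughout the API.

# Subtype characterization

* **Loading outliers.** Analyses of this kind remove a handful of
  individuals with outlying cluster loadings and re-cluster, usually
  without stating the criterion. The package uses a robust z-score (median/MAD) on each
  subject's maximum raw loading, flagging $z > 3.5$ — a conventional
  robust-outlier cut — and refuses to drop more than 20% of subjects
  without an explicit override. This is an interpretation, and it is
  configurable rather than presented as ground truth.
* **Protein labels.** Each protein is labelled with the subtype showing
  its highest average level; exact ties stay unlabeled.
* **Specific proteins.** A protein is subtype-specific-increased when it is
  significantly higher in that subtype than in *each* other subtype
  (two-sided per-pair linear-model contrasts, both effects positive, both
  $p < \alpha$). The default is $\alpha = 0.05$ uncorrected — the
  conjunction requirement is itself a stringent filter — with
  Benjamini–Hochberg available by configuration. Under the null the two contrasts for a subtype share its
  group mean (correlation 0.5), which makes the per-direction
  false-inclusion rate of the conjunction approximately $\alpha^2$; the
  acceptance suite verifies this by simulation.
* **Overlap coefficient.** Consistency with reference difference profiles
  is scored by $|A \cap B| / \min(|A|,|B|)$, 0 = no overlap, 1 = one set
  contained in the other; undefined (error) for empty sets.
* **Cell-type specificity.** With a per-protein expression reference over
  five brain cell types, a protein is labelled *not detected* when all raw
  levels are < 0.2, else the cell type contributing > 50% of the row
  total, else *non-specific*. The detection threshold intentionally
  applies to raw levels and the dominance threshold to shares, so the rule
  is scale-invariant only above the detection floor — the tests assert
  exactly that asymmetry.
* **Covariate comparisons.** Continuous characteristics use a general
  linear model on the subtype factor with estimated marginal means and
  pairwise contrasts, standardized to the control group (age exempt);
  discrete ones use chi-square tests without continuity correction by
  default (the original does not specify; both are configurable).

# Longitudinal slopes

Repeated biomarkers (Aβ42 and p181-tau in pg/mL, ADAS-Cog delayed word
recall in score points, higher = worse) are modelled per subtype as

$$y_{ij} = \beta_0 + b_i + \beta_1 t_{ij} + \varepsilon_{ij},
\qquad b_i \sim N(0, \sigma_b^2),$$

a random-intercept mixed model: the original description says "general
linear models" but the data are repeated measures, and at ~15 subjects per
subtype random slopes are not estimable, so a random intercept is the
defensible middle ground. Wald $t$ p-values use between–within denominator
degrees of freedom ($n_{obs} - n_{subj} - 1$); Satterthwaite machinery is
deliberately not a dependency. When the intercept variance is inestimable
(e.g. noise-free fixtures) the estimator falls back to OLS with
subject-clustered robust (CR1) standard errors and flags it. Slope
differences between subtypes are tested by adding a subtype × time
interaction and reporting the joint Wald chi-square p-value; baseline
comparisons use each subject's earliest visit. No multiplicity correction
is applied across the marker × subtype grid, matching per-model reporting.

# What the synthetic generator emulates (and what it does not)

`generate_cohort()` draws, per subject, a simplex loading vector from a
symmetric Dirichlet and takes the argmax as the true subtype. The
`mixing_concentration` parameter is a *sharpness* dial: internally the
Dirichlet parameter is `1/mixing_concentration`, so large values
concentrate mass on the simplex vertices (hard assignment in the limit)
and small values give mixed memberships. This mapping was chosen so that
"concentration → ∞ means hard labels" holds, which matches NMF's
mixed-membership geometry while still yielding discrete ground truth.

Protein abundance is `baseline + profile_effect * (signature · loading) +
noise`: a log-normal positive baseline per protein, disjoint signature
sets per subtype (`frac_signature` of the panel each), Gaussian noise.
With hard loadings a signature protein is elevated by exactly
`profile_effect` noise-SD units in its subtype, which the tests verify
with a sample-mean oracle at n = 500. A designated random 20% subsample
plays the control group, so the z-normalization step is exercised honestly
rather than fed pre-standardized data. Fragments add independent Gaussian
measurement error on top of the protein signal (two fragments of a protein
correlate at least $\sigma^2_{noise}/(\sigma^2_{noise} +
\sigma^2_{frag})$ by construction), and a configurable fraction of
proteins gets a duplicate measurement tagged as a second platform.

Longitudinal trajectories are linear per subject with subject random
intercepts. Defaults encode the reported study design: 3.2 ± 1.2 visits
over 3 ± 1.9 years of follow-up (first visit at 0, later visits uniform
over the span — only means and SDs of the design are given, so uniform
is the least-committal choice), and the reported per-subtype slopes
(Aβ42 −4.4 / −3.7 / −5.6 pg/mL/yr; p-tau 2.6 / 3.1 / 1.29 pg/mL/yr;
memory 0.06 / 0.15 / 0.20 points/yr). Reported values for the subtype-2 p-tau trend disagree in sign between
summaries; the package uses +3.1 (an *increase*), the reading consistent
with the direction described.
Baseline means sit in the biomarker-normal range (230 pg/mL Aβ42, 18 pg/mL
p-tau, 3 recall points); residual SDs (12 / 5 / 0.5 marker units) and
intercept SDs (35 / 6 / 1.5) were chosen once so that simulated slope
standard errors land near the reported ± SEs at 12–17 subjects per
subtype, before any acceptance run, and were not revisited.

The generator deliberately does **not** simulate TMT reporter-ion physics,
missingness, or batch effects (the analysis uses only 100%-observed
proteins), nor real biological covariance between proteins beyond the
subtype structure. A green recovery test therefore establishes that the
pipeline recovers the *assumed* generating structure at realistic
signal-to-noise — not that real CSF data satisfies those assumptions.

# Numerical choices and degenerate inputs

* Multiplicative-update denominators are guarded by $10^{-12}$; numerators
  are exact so true zeros persist (the sparsity nsNMF is after).
* Correlation thresholds are strict (`r > 0.5`, not `>=`); a tie at
  exactly 0.5 falls on the "not correlated" side.
* Silhouette of a singleton-cluster subject is 0 by convention, logged.
* A consensus run whose factorization leaves a component empty is kept and
  logged, not silently re-run.
* Seeds: one global seed drives per-stage and per-restart child seeds via
  a fixed prime stride (`seed + 7919·index`, reduced mod $2^{31}$), so any
  stage can be reproduced in isolation.

# Known limitations

* The cophenetic "high" window (0.02) and the outlier rule are reasoned
  defaults for under-specified steps, not recovered constants.
* Wald-t inference with between–within df is mildly approximate at very
  small n; the null-calibration test bounds the practical impact.
* Pathway enrichment and transcription-factor analyses (external web
  services) and APOE genotyping are out of scope by design; the cell-type
  reference consumed here is a synthetic stand-in with the same schema as
  public brain RNA-seq references.
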