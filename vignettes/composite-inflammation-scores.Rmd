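---
title: "Composite inflammation scores: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite inflammation scores: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflaclust)
```

`inflaclust` derives per-patient composite scores of systemic (blood acute
phase reactant, APR) and intrathecal (CSF) inflammation and relates them to
diagnosis group and MS severity. This vignette is the package's account of
the statistical model behind each stage, the parameters that matter, what
the synthetic-cohort generator does and does not emulate, and the design
decisions taken where the procedure was genuinely open.

## 1. The measurement model

A biomarker value for analyte $j$, subject $i$, visit $t$ is treated as a
monotone (Box-Cox-inverse) transform of a latent Gaussian quantity

$$y_{ijt} = g_j^{-1}\big(s_j\,\eta_{ijt} + c_j\big), \qquad
\eta_{ijt} = \beta_j^\top x_i + \delta_{j,g(i)} + \ell_j F_{c(j),i} + u_{ij} + \varepsilon_{ijt},$$

where $s_j \in \{+1,-1\}$ is the inflammation polarity (negative APRs
serum albumin, iron and transferrin fall when inflammation rises),
$x_i$ are standardized covariates (age, sex, race),
$\delta_{j,g}$ is the diagnosis-group shift, $F_{c,i}$ is a standard-normal
latent factor shared by the analytes of cluster $c$ with loading
$\ell_j \in [0,1]$, $u_{ij} \sim N(0, 1-\ell_j^2)$ is the analyte's
uniqueness, and $\varepsilon_{ijt}$ is visit-level noise. The pipeline is
the estimation route back: undo $g_j$ by Box-Cox, standardize, remove
$\hat\beta_j^\top x_i$, flip $s_j$, and average within clusters so the
$u$'s and $\varepsilon$'s shrink while the shared $F$ survives.

## 2. Stage-by-stage choices

**ICC screening.** Visits are exchangeable repeated measures with no
rater or occasion structure, so the one-way random-effects ICC is the
appropriate variant: $\mathrm{ICC} = (MS_B - MS_W)/(MS_B + (k_0-1)MS_W)$
with the standard unbalanced-design $k_0 = (N - \sum n_i^2/N)/(a-1)$.
Estimates may be negative and are reported unclipped. Averaging across
visits is applied to *every* analyte regardless of ICC — the screening
justifies the averaging rather than gating it — and analytes at or below
the 0.8 stability flag are marked in `icc_report`, not excluded.

**Box-Cox + Z scores.** Per analyte, a positivity shift $1-\min(x)$ is
applied when any value is $\le 0$ (ESR and CRP can legitimately be zero),
and $\lambda$ maximizes the profile log-likelihood over a deterministic
grid, $-3$ to $3$ in steps of $0.01$ (coarser grids are a config option
for simulation studies; the resolution does not affect downstream
calibration). Z scoring uses the $n-1$ denominator and is computed on the
pooled HD+MS sample: between-group comparisons of the resulting residuals
only make sense when both groups share one standardization. A caveat worth
knowing: the Box-Cox $\lambda$ MLE is weakly identified when the
coefficient of variation is small — for near-normal data with mean far
from zero, individual $\hat\lambda$ scatter with sd up to $\sim$0.15 at
$n = 300$ even though the estimator is essentially unbiased. Package
checks therefore assess $\lambda$ recovery on averages over replicates.

**Covariate adjustment.** Per analyte, the candidate model is
`Z ~ diagnosis + age + sex + race + age:sex + age:race + sex:race`
(covariate-by-covariate interactions only; diagnosis-by-covariate
interactions are deliberately excluded so the diagnosis effect stays a
simple shift). A term is retained iff its type-II ANOVA p-value is below
0.05 — the package's concrete reading of "included if effects were
present" — and a selected interaction always brings both parents. The
reduced model is refit and only its covariate part is subtracted:
algebraically, `residual = intercept + diagnosis effect + OLS error`,
an identity the tests verify to $10^{-10}$. Diagnosis is never removed.
Sex and race are reference-coded with the largest category as reference;
race strata under 5 subjects collapse to "Other" (sparse strata would
otherwise produce unstable coefficients). Models are fit on the pooled
sample, since the same residuals feed HD-vs-MS comparisons.

**Polarity and clustering.** Negative-APR columns are multiplied by $-1$
*after* residualization by default. Because least squares is linear in the
response, flipping before or after residualization yields identical
residuals up to floating point (fitted coefficients flip sign); the
package proves this commutation in its test suite, which makes the
ordering immaterial. Clusters are connected components of the graph with
an edge where pairwise-complete Pearson $r \ge 0.3$ and raw $p < 0.05$.
The 0.3 default is a judgment call — no numeric criterion exists for
"correlated with each other" — and is exposed as `r_threshold`. Connected
components (rather than a hierarchical cut) match the transitive
"correlated pairs share a cluster" reading and are deterministic. Blood
clusters are derived on all patients; CSF clusters on MS patients only
(healthy donors carry no intrathecal inflammation signal to structure
them). The *frozen* partition is the reproduction default because the
reference analysis itself overrode data-driven grouping in the CSF —
nearly all CSF markers inter-correlate, and the split into myeloid
(sCD14, sCD163, CHI3L1), humoral (CSF IgG, IgG index, sBCMA), sCD27 and
CSF albumin is biology-driven; `cluster_mode = "derived"` re-derives both
compartments. Cluster scores are means over non-missing members, missing
only when every member is missing.

**Inference and FDR.** Marker-level group differences use the F-test of
the grouping term from a linear model; cluster scores between two groups
use the unpaired equal-variance t-test. Cross-compartment associations use
Pearson correlations of cluster scores; severity associations use Spearman
only, because MSSS/ARMSS/MS-DSS are right-skewed. Correlations use
pairwise-complete observations and report that N per cell. Each reported
table is its own Benjamini-Hochberg family (markers HD-vs-MS; cluster
group comparisons; each blood-by-CSF table per sub-cohort; each
cluster-by-severity grid per sub-cohort) — the most conservative family
layout consistent with per-table presentation. Pairs with fewer than 3
complete observations are flagged undefined and excluded from their
family. Spearman p-values use the t approximation with average-rank ties
(exact permutation distribution when $N \le 9$ without ties).

## 3. What the synthetic generator emulates

Defaults encode the study conditions: 51 HD, 118 RRMS and 173 PMS
subjects (PPMS/SPMS split 69/104 — the published total does not give the
split), 1–6 visits per subject drawn uniformly (mean 3.5, so a default
cohort carries ≈1,200 visits, matching the reported 1,163 total
patient-visits; the per-patient visit distribution itself is not
published), latent clusters equal to the frozen partition with loadings
0.8, diagnosis shifts of 0.15–0.7 SD on the inflammation scale patterned
on the direction and strength of the reported group differences,
age/sex/race confounding switched on (age means 39.4/42.3/55.3 years for
HD/RRMS/PMS with the reported SDs; sex and race frequencies from the
cohort table; e.g. ESR rises with age, ferritin is higher in males, WBC
lower in Black subjects), a latent-scale ICC target of 0.85, per-analyte
right skew (λ = 0 for CRP/ESR/ferritin/CHI3L1/sBCMA/sCD27/CSF IgG, 0.5
or 1 elsewhere), 15% completely-at-random missingness per biomarker cell,
and a severity coupling of 0.25 between the latent CSF humoral factor and
the severity predictor.

Two calibrations are analytic rather than tuned. First, the subject-level
random part has unit variance by construction ($\ell_j^2 + (1-\ell_j^2)$),
so the expected latent correlation of same-cluster analytes is the product
of their loadings. Second, visit noise solves
$\sigma^2_{visit} = (1 + V_{fixed})(1-\rho)/\rho$ for ICC target $\rho$,
where $V_{fixed}$ is the realized between-subject variance of the
covariate + diagnosis part — so the one-way ICC on the latent scale equals
the target in expectation even with confounding switched on. Skew offsets
$c_j$ are $\lambda$-dependent (2 for $\lambda < 0.75$, else 3): large
enough to keep the inverse transform's support safe, small enough to keep
$\lambda$ identifiable.

Severity scores are affine maps of the latent predictor onto their native
scales using the published group means and SDs (e.g. MSSS 1.8/4.2/6.7 for
HD/RRMS/PMS), clamped to $[0, 10]$, with small visit-level noise. Because
`severity_coupling` is defined against the latent *factor*, the measurable
Spearman between the humoral *cluster score* and severity is attenuated by
the score's uniqueness and visit noise to ≈0.21–0.23 when the coupling is
0.25 — the package's recovery checks account for this known attenuation.

What the generator does **not** emulate: informative missingness or
dropout, longitudinal progression dynamics (visits are exchangeable),
realistic assay units or calibration curves, diagnosis-by-covariate
interactions, and cross-compartment coupling (absent by default — the
reference result the null-calibration tests protect). Passing tests
therefore demonstrate statistical correctness of the pipeline under a
plausible data-generating process, not clinical validity on real cohorts.

## 4. Numerical and degenerate-input behavior

- Duplicate (subject, visit) keys, unknown diagnosis labels, ungrouped
  diagnoses, zero-variance or nearly-all-missing analytes, empty cluster
  definitions and rank-deficient designs all raise errors naming the
  offending analyte/term/rows.
- Constant covariates are dropped (with their interactions) before
  fitting rather than erroring — a column can be constant in a small
  sub-cohort without being degenerate in principle.
- Missingness propagates, never imputes: a residual is missing iff the
  Z score or a model-used covariate is missing; a cluster score is
  missing iff all members are; correlations use pairwise-complete rows
  and carry their N.
- ICC needs ≥2 subjects and ≥1 subject with ≥2 visits; otherwise an
  undefined-ICC error (the per-analyte report converts this to `NA` with
  a flag rather than aborting the pipeline).
- Cluster derivation refuses to run when any pair has fewer than 10
  pairwise-complete observations and advises the frozen partition.
- All pipeline stages are deterministic; `run_pipeline` twice on the same
  input is byte-identical, and the manifest hash changes iff the config
  or input changes. Randomness exists only in the generator and is fully
  seeded.

## 5. Problem sizes used by the checks

The package's simulation-based checks run at the study's own scale where
the quantity depends on it (group sizes 51/118/173; 500 subjects × 4
visits for ICC calibration; n = 300 for λ recovery and partition
recovery) and use replicate counts — 50 seeds per λ, 100 partition seeds,
200 recovery replicates, 500 null-calibration replicates — chosen so that
Monte-Carlo error is comfortably inside each assertion's band. Recovery
and calibration studies use the coarser λ grid (step 0.05), which leaves
their conclusions unchanged.

## 6. Known limitations

- The covariate-selection rule (type-II ANOVA at 0.05) is one defensible
  choice among several; selection-then-refit ignores selection
  uncertainty, which is acceptable here because the residuals, not the
  covariate p-values, are the inferential object.
- With `cluster_mode = "derived"`, connected components can chain two
  clusters through one borderline edge; the frozen default and the
  exposed `r_threshold` are the mitigations.
- The equal-variance t-test mirrors the reference analysis; it is not
  robust to strong variance heterogeneity between groups.
- Severity scales are consumed, never computed: MSSS/ARMSS/MS-DSS
  algorithms are out of scope.
- Sub-cohort analyses (RRMS-only, PMS-only) are diagnosis filters over
  the same operations; the package does not model PPMS/SPMS differences
  beyond their shared PMS shifts.
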