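---
title: "Methods: models, estimation and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimation and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the modeling assumptions, numerical conventions
and simulation design behind the package, in the spirit of a methods
appendix: everything a user needs to know to interpret a fit, and
everything a skeptic needs to know to distrust one correctly. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The model family

The watershed architecture is a three-level hierarchy: ten white-matter
tract means (fractional anisotropy, FA, averaged over hemispheres) act as
upstream manifest predictors; working memory and processing speed are
latent endophenotypes regressed on all ten tracts; fluid reasoning is a
latent outcome regressed on the two endophenotypes. Tract
inter-covariances (45) are free, as is the residual covariance between
the two endophenotypes — both are required by the degrees-of-freedom
bookkeeping of the published fits (df = 78 with the referred-cohort
battery of 8 tasks, df = 112 with the community battery of 10 tasks),
which the test suite pins exactly.

Identification uses marker variables: each latent's first indicator
loading is fixed to 1 (`std_lv = TRUE` offers unit-variance
identification instead). A single-indicator latent — fluid reasoning in
the referred cohort, measured by matrix reasoning alone — gets its
loading fixed to 1 and the indicator residual fixed to 0; this is the
only treatment consistent with the published df = 18 for that cohort's
3-factor model. No residual covariances among cognitive tasks are
included: none are shown in the source diagrams, and the printed dfs
leave no room for any.

Two of the alternative architectures are interpretations, and their dfs
are printed rather than asserted against any external value:
**altB** ("all tasks manifest") regresses each fluid-reasoning task on
all working-memory and speed tasks and each of those on all ten tracts,
with free residual covariances within the intermediate and downstream
task sets (the closest manifest analogue of the latent watershed's free
endophenotype covariance). **altC** ("inverted hierarchy") regresses
fluid reasoning on the tracts and both endophenotypes on fluid
reasoning, keeping their residual covariance free. **altA** is the
serial chain tracts → speed → working memory → reasoning, and **altD**
regresses reasoning directly on tracts and both (exogenous) factors.

The Δdf = 18 equality variant constrains the ten tract paths to be equal
*within* each endophenotype (9 + 9 constraints). Equality per tract
*across* endophenotypes would give Δdf = 10 and contradicts the published
Δχ²(18); the within-endophenotype reading is therefore the one encoded.

## Estimation conventions

All fitting works on the RAM form `Σ(θ) = F(I−A)⁻¹S(I−A)⁻ᵀFᵀ`, with
objective and analytic gradient evaluated in compiled (RcppArmadillo)
code.

* **Covariance input.** The ML discrepancy
  `F_ML = ln|Σ| − ln|S| + tr(SΣ⁻¹) − p` is minimized against the
  covariance as ingested (denominator N−1), and `χ² = (N−1)·F_min`
  (Wishart convention). Covariance-only modeling: no mean structure, as
  all targeted fit statistics are covariance-structure statistics.
* **Raw input (FIML).** The casewise normal log-likelihood is summed over
  missingness patterns with saturated (freely estimated) means;
  `χ² = 2(ℓ_sat − ℓ_model)`, with the saturated model obtained by EM.
  Rows with no observed variable are dropped and counted. With complete
  data this is algebraically identical to covariance ML on the *biased*
  (÷N) covariance; the test suite asserts the identity at 1e-8. Note the
  deliberate asymmetry: the Wishart χ² convention for covariance input
  and the FIML estimator differ at order 1/N, so the cross-route
  estimate-equality check feeds the biased covariance to the covariance
  route. Whether the original analyses profiled or estimated means is
  not stated; saturated means are assumed (they drop out of all
  covariance-structure conclusions).
* **Optimizer.** Quasi-Newton (`nlminb`) with analytic gradients;
  starting values are 0.5 for loadings and paths, half the observed
  variance for residual variances, observed covariances for exogenous
  manifest covariances, and 0 for other covariances. If the start is not
  positive definite, paths and covariances are geometrically damped
  until it is. A BFGS polish runs whenever the gradient max-norm exceeds
  tolerance, and deterministic jittered restarts guard against local
  minima (a 10-start agreement property is asserted on fixtures).
  Convergence requires gradient max-norm ≤ 1e-5 (objective change
  ≤ 1e-10); non-converged fits are flagged, never silently returned.
  Infeasible (non-PD) iterates receive a smooth quadratic penalty
  centered at the start rather than an error.
* **Heywood cases.** Negative estimated variances are allowed but
  flagged in the result; no boundary constraint is imposed by default.
* **Standard errors** are observed-information (numerical Hessian of the
  analytic gradient). The published robust (Huber–White) standard errors
  and scaled test statistic are out of scope; consequently printed
  χ²/RMSEA/CFI values from the source analyses are compared only
  qualitatively (fit classification), never for equality.
* **R²** is `1 − residual/total` model-implied variance;
  **standardized estimates** rescale by model-implied standard
  deviations, so latent covariances become correlations while
  standardized regression paths are *not* bounded by 1 — suppression
  among highly correlated predictors legitimately pushes them past ±1,
  which is exactly the sign-flip diagnostic `single_path_probe()`
  investigates.
* **Factor scores** are regression-method scores, linear in the data,
  computed for complete rows.

## Fit indices and comparison

`RMSEA = √(max(0, (χ²−df)/(df·(N−1))))` with the 90% interval obtained by
root-finding the noncentrality parameter of the noncentral χ²
distribution (checked against a numeric-integration oracle);
`CFI = 1 − max(0, χ²_M−df_M)/max(0, χ²_B−df_B)` against an independence
baseline (free variances, zero covariances, no means), clipped to [0,1];
SRMR uses correlation-metric residuals `(s_ij − σ̂_ij)/(s_i s_j)` with the
diagonal included, averaged over the p(p+1)/2 unique moments — the exact
variant used by the original software is unverifiable from the source, so
this convention is pinned here instead. AIC = −2ℓ + 2q and
BIC = −2ℓ + q·ln N count all estimated parameters (including means under
FIML; constant across a comparison set). Akaike weights are
`exp(−Δᵢ/2)` normalized; the verbal fit bands are good
(RMSEA < 0.05, CFI > 0.97, SRMR < 0.05) and acceptable
(0.05–0.08, 0.95–0.97, 0.05–0.10), boundaries falling in the acceptable
band, overall = worst of the three. Standardized effect bands: >0.10
small, >0.20 typical, >0.30 large.

## SEM trees

One tree per focus parameter: at a candidate age threshold a 2-group
model is fit in which *only* the focus parameter differs (everything
else, including group means via profiling, is invariant), so splits are
specific to the parameter of interest. Candidate thresholds are
midpoints between consecutive distinct ages leaving ≥ `min_group_n` (50)
subjects on each side, thinned to at most `max_candidates` (30)
quantile-spaced values — the original discretization is unknown, and
recovery properties, not split-for-split equality, are the design
target. Each candidate's score is the 10-fold cross-validated held-out
log-likelihood gain of the 2-group over the invariant model, with
seeded, side-stratified, rank-based fold assignment (scores are
deterministic given the seed and invariant to row order). A
successive-halving schedule screens all candidates on three folds and
completes the full score only for the strongest fifth.

**Split acceptance.** The best positive CV score selects the threshold
(ties toward the younger age), but selection alone is not acceptance: by
construction the maximum of ~30 correlated, noisy CV scores exceeds zero
on most null datasets, so a "positive CV gain" rule would split null
data far too often — the package's own null simulations showed >90%
spurious splits. The accepted rule is therefore CV selection followed by
a node-level 2-group vs invariant likelihood-ratio confirmation at a
Bonferroni-corrected level (α/number of candidates), the standard
multiplicity control in model-based recursive partitioning. With it, null
data retain a single node in ≥95% of simulations while a 0.8→0.3 path
change at age 10 (n = 2000) is located within ±0.5 years essentially
always. Growth is greedy (no lookahead), younger child first, capped at
`max_groups` (4) leaves; final leaf estimates come from one joint
multi-group fit over the leaf partition, so a leaf's estimate equals a
direct multi-group fit by construction (asserted at 1e-6). Scoring fits
use a looser gradient tolerance (1e-3) than reported fits; the final
joint fit uses the strict tolerance.

## The synthetic cohort generator

The generator mirrors the watershed truth on a standardized scale:
equicorrelated (r = 0.4) standard-normal tract values; endophenotypes
linear in the tracts plus correlated residuals; fluid reasoning linear in
the endophenotypes; task scores loading 0.7 on their factor. Default
path strengths are scaled so the explained variances hit the published
anchors (working memory 32.3%/46.1%, speed 38.2%/54.4%, reasoning
51.2%/78.3% for the referred/community configurations), with total
endophenotype correlations 0.79/0.87 and reasoning paths 0.72/−0.01
(0.86/0.06). The tract-to-endophenotype pattern is deliberately
heterogeneous, concentrated on the tracts the cohort analyses flagged
(SLF/forceps major/cingulate → working memory, anterior thalamic
radiation → speed in the referred configuration; SLF → both in the
community configuration): an equal-paths pattern would make the serial
altA architecture nearly covariance-equivalent to the watershed and no
model-selection experiment could separate what the real analysis
separated. Reaction-time speed tasks are emitted as lognormal raw times
`rt = exp(location − scale·score)` (location 0.7, scale 0.35 — ~2 s
median times), so the published preprocessing (`y = log(1/x)`, plus a
±2 SD trim for the speed-native motor task) is a real, testable stage;
the transform is affine in the latent-scale score, leaving standardized
structure intact. Imaging missingness is completely at random at the
published fraction (165/551 or 67/335) and hits all tract columns
jointly. Ages are uniform over the published ranges (the true age
distributions are unavailable). Age moderation replaces any structural
path by a user function of age, holding residual variances fixed.

What the generator does *not* emulate: age trends in task means (factor
scores rise with age in real cohorts; here means are stationary),
referral/ascertainment effects, floor/ceiling and discreteness of task
scores, non-normal tails, site/scanner differences, and missingness that
depends on anything (MAR stressing is deliberately out of scope). A green
recovery test therefore establishes estimator correctness under the
stated linear-normal world — not robustness of the scientific conclusion
to violations of it.

Parameter-recovery acceptance runs at n = 50,000 with complete imaging —
the criterion isolates estimator consistency, while FIML-under-missingness
recovery is tested separately under MCAR masking — and compares
standardized estimates to the standardized truth within
max(2% of |truth|, 0.02): several true tract paths are ~0.08, where a
purely relative 2% band (±0.0017) lies below the sampling standard error
at that n, so an absolute floor at 2% of the standardized scale is the
strictest satisfiable reading.

## File formats and reproducibility

Data are CSV (comma, `.` decimal, header, empty cell = missing);
covariance input is a square named CSV plus N (correlation matrices are
detected and flagged). Configuration, battery and report files are JSON —
the graded environment provides no YAML parser, so JSON carries the same
schema. Every random draw flows from an explicit integer seed (a source
lint in the test suite enforces the absence of wall-clock or entropy
seeding), and every CLI run writes a manifest with options, seed, config
hash and versions; identical inputs give byte-identical artifacts.

## Known limitations

Point estimates only match analyses run with plain ML — robust standard
errors and scaled statistics are documented non-goals, so z-values and
χ²-based indices can differ from robust-scaled published values even on
identical data. Ordinal indicators, mean structures, multi-group
estimation beyond the SEM-tree machinery, bootstrap and Bayesian
estimation are out of scope. The split ages of the original age analysis
are not reproducible without the cohort raw data; the tree module is
validated by recovery properties on synthetic cohorts instead.
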