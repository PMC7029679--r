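# watershed

Structural equation modeling of the hierarchical ("watershed")
architecture of fluid intelligence in developmental cohorts — white-matter
microstructure feeding intermediate cognitive endophenotypes (working
memory, processing speed), which in turn feed fluid reasoning — with SEM
Trees for age-varying parameters and a synthetic cohort generator so the
entire pipeline runs and is tested without any external data.

The package is aimed at researchers modeling brain–behavior hierarchies in
cohort data: it provides the estimation engine, the complete model
library for this analysis family, and the simulation machinery to check
that every stage behaves as claimed.

## The model

Cognition is measured by a 3-factor battery: working memory (`wm`), fluid
reasoning (`gf`) and processing speed (`speed`), each identified by a
marker indicator (first loading fixed to 1; a single-indicator factor gets
loading 1 and residual 0). Mean fractional anisotropy (FA) of the 10
Johns Hopkins atlas tracts enters as manifest upstream variables. The
watershed model is the path system

```
wm    ~ tract_1 + ... + tract_10
speed ~ tract_1 + ... + tract_10        (tract covariances free)
gf    ~ wm + speed                      (wm ~~ speed residual covariance free)
```

estimated by maximum likelihood on a covariance matrix
(`F_ML = ln|Σ| − ln|S| + tr(SΣ⁻¹) − p`, `χ² = (N−1)·F_min`) or by
full-information maximum likelihood (FIML) on raw data with missingness
(casewise normal likelihood with saturated means; `χ² = 2(ℓ_sat −
ℓ_model)`), in RAM form `Σ = F(I−A)⁻¹S(I−A)⁻ᵀFᵀ` with analytic gradients
in compiled code. Model comparison uses RMSEA (noncentral-χ² CI), CFI,
SRMR, nested Δχ² tests and Akaike weights
`w_i = exp(−Δᵢ/2)/Σⱼexp(−Δⱼ/2)`. SEM Trees split subjects on age where a
single focus parameter differs (all other parameters equality-constrained
across groups), selecting thresholds by 10-fold cross-validated
log-likelihood gain with a Bonferroni-corrected confirmation test.

## Worked example

```r
library(watershed)

cfg  <- cohort_config("calm", n = 551, seed = 7)   # referred-cohort battery
raw  <- generate_cohort(cfg)                       # speed tasks as raw RTs,
dat  <- preprocess_speed(raw, cfg$battery)$data    # 70% imaging missingness

fit <- sem_fit(build_watershed(cfg$battery, "original"), data = dat)
fit
#> watershed fit (raw input): chisq(78) = 73.83, p = 0.613, npar = 93
fit_indices(fit)
#> chisq(78) = 73.83, p = 0.613
#> RMSEA = 0.000 [0.000-0.021]  CFI = 1.000  SRMR = 0.036
#> AIC = 11600.63  BIC = 12079.23
round(100 * r_squared(fit, c("wm", "speed", "gf")), 1)
#>    wm speed    gf
#>  31.5  33.9  49.2
```

The model fits its own generating structure (good absolute fit), and white
matter explains ~32%/34% of working-memory/speed variance, which explain
~49% of fluid-reasoning variance — the configured anchors (32.3%, 38.2%,
51.2%) within sampling error at n = 551 with imaging for a 30% subset.

The measurement-model competition:

```r
mm <- lapply(c(single = "single", twoA = "twoA", twoB = "twoB",
               three = "three"),
             function(v) sem_fit(build_measurement_model(cfg$battery, v),
                                 data = dat))
information_criteria(mm)
#>   model chisq df npar loglik  aic  bic weight converged
#>  single    97 20   24  -3689 7426 7530  0.00%      TRUE
#>    twoA    78 19   25  -3680 7410 7517  0.00%      TRUE
#>    twoB    11 19   25  -3646 7343 7451 68.55%      TRUE
#>   three    11 18   26  -3646 7344 7457 31.45%      TRUE
```

Speed separates cleanly from reasoning (the single-factor and
reasoning+speed models get ~0% weight), while reasoning and working
memory are hard to tell apart in a referred cohort — the two-factor model
merging them takes most of the weight, mirroring the pattern this model
family was built to probe.

Age-varying paths are explored with a SEM tree on one focus parameter:

```r
cfg2 <- cohort_config("calm", n = 1500, imaging_fraction = 1, seed = 11,
                      age_effect = list("gf~wm" = function(a)
                        ifelse(a < 8, 0.8, ifelse(a < 12, 0.2, 0.9))))
dat2 <- preprocess_speed(age_moderated_cohort(cfg2), cfg2$battery)$data
tree <- grow_tree(build_cognitive_regression(cfg2$battery, "free"), dat2,
                  tree_config("gf~wm", seed = 1))
```

`tree$leaves` then holds the age segments and per-segment path estimates
(`tree_markdown()` renders the split/estimate table).

## Command line

```sh
Rscript inst/cli/watershed simulate --config cohort.json --seed 7 --out cohort.csv
Rscript inst/cli/watershed fit      --data cohort.csv --battery calm --model original --out fit.json
Rscript inst/cli/watershed compare  --data cohort.csv --models single,twoA,twoB,three --out cmp.json
Rscript inst/cli/watershed tree     --data cohort.csv --model free --focus "gf~wm" --out tree.json
Rscript inst/cli/watershed report   --data cohort.csv --battery calm --out report_dir
```

Every run writes a `manifest.json` (options, seed, config hash, versions);
identical seed and config give byte-identical artifacts.

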