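# neuropool

Hierarchical Bayesian multinomial classification of diagnostic groups
(cognitively normal, mild cognitive impairment, Alzheimer's dementia)
from per-region **relative annualized rates of change** of longitudinal
tau-PET SUVR or cortical thickness.

The package is aimed at neuroimaging statisticians who want to ask a
structural question: *does a classification model improve when it knows
that observations nest inside regions of interest (ROIs), and ROIs
inside functional brain networks?* It implements the full Bayesian
workflow for that question — four model structures of increasing
hierarchy, prior and posterior predictive checking, PSIS-LOO model
comparison, and posterior prediction curves — together with a synthetic
cohort generator with a closed-form coefficient oracle, so every stage
is testable end-to-end without access to a real cohort.

## The model

Each observation is one (subject, ROI) pair with outcome
$y_i \in \{\mathrm{CN}, \mathrm{MCI}, \mathrm{AD}\}$ and predictor $x_i$,
the ROI's relative annualized rate (normalized to $[-1, 1]$ per
modality):

$$y_i \sim \mathrm{Multinomial}(\pi_i),\qquad
\pi_{ij} = \mathrm{softmax}_j(\lambda^{(1)},\lambda^{(2)},\lambda^{(3)}),\qquad
\lambda^{(j)} = \beta_0^{(j)} + \beta_1^{(j)} x_i,$$

with CN as reference ($\lambda^{(\mathrm{CN})}=0$). The four structures
pool the coefficients differently:

| model | structure | coefficients |
|---|---|---|
| 1 | complete pooling | global $(\beta_0,\beta_1)$ |
| 2 | ROIs | $\beta_{[u]}$, Gaussian group prior, Half-Normal sds |
| 3 | networks | $\beta_{[v]}$ (Yeo-7 + subcortical cluster) |
| 4 | ROIs within networks | $\beta_{net[v]} + \beta_{net[v],roi[u]}$ |

Inference is adaptive Hamiltonian Monte Carlo (No-U-Turn sampling, 4
chains × 2,000 iterations, 1,000 warmup, non-centered
parameterization), written for this package with an Rcpp
log-posterior/gradient kernel; diagnostics are rank-normalized
split-R̂, bulk/tail ESS, MCSE, and divergence counts. Model comparison
is PSIS-LOO (Pareto-smoothed importance sampling leave-one-out
cross-validation) with generalized-Pareto tail fitting and the usual
`elpd_diff ± se_diff` comparison table.

## Worked example

Simulate a reduced synthetic cohort (19 CN / 6 MCI / 5 AD subjects, 12
ROIs in 4 networks — the study design at quarter scale), fit the
network model and the nested model, compare them, and draw a prediction
curve:

```r
library(neuropool)

atlas  <- make_synthetic_atlas(n_roi = 12, n_net = 4)
cohort <- simulate_cohort(cohort_config(atlas,
                                        n_per_group = c(19, 6, 5),
                                        seed = 1))
obs    <- assemble_observations(cohort$measures, atlas)
priors <- prior_config("weakly_informative")

fits <- lapply(c(3, 4), function(m)
  sample_posterior(structure_from_obs(m, obs), priors, obs,
                   sampler_config(n_iterations = 1000, n_warmup = 500,
                                  seed = m)))
names(fits) <- c("model3", "model4")

diagnostics_report(fits$model4)$max_rhat   # 1.0072
divergence_count(fits$model4)              # 0

compare_models(lapply(fits, psis_loo))
#>    model elpd_diff se_diff elpd_loo se_elpd_loo comparable
#> 1 model3     0.000  0.0000   -306.8       12.67       TRUE
#> 2 model4    -2.413  0.5758   -309.2       12.85       TRUE
```

The comparison table reads like the standard LOO table: models sorted
best-first, differences relative to the best model, and a flag for the
"se_diff < 4 means comparable predictive ability" rule of thumb — here
the two network-aware models are statistically comparable on this small
cohort.

Posterior class-probability curve for ROI 1 under the nested model
(equal-tailed 60%/89% credible bands; `x_raw` in raw rate units per
year):

```r
cv <- posterior_curves(fits$model4, "roi", id = 1)
head(cv[cv$category == "AD" & cv$x_raw > 0.4,
        c("x_raw", "mean", "lo60", "hi60", "lo89", "hi89")], 3)
#>  x_raw  mean  lo60  hi60  lo89  hi89
#>  0.405 0.506 0.262 0.746 0.114 0.882
#>  0.416 0.514 0.264 0.760 0.113 0.893
#>  0.427 0.522 0.267 0.774 0.112 0.903
```

At a tau-PET uptake increase of ~40%/yr the posterior probability of AD
is ~0.5 and rising in the rate — with wide uncertainty, as 5 AD
subjects warrant.

For real extracts, `build_atlas("tau_suvr")` gives the bilateral
76-ROI DKT + subcortical map with Yeo-7 network and Braak-stage
annotations (62 cortical ROIs for `"cortical_thickness"`), and
`read_measures()` / `assemble_observations()` consume a long-format CSV
(`subject_id,diagnosis,roi_label,hemisphere,modality,baseline,followup,
interval_days`).

## Further reading

The methods vignette (`vignettes/hierarchical-workflow.Rmd`) documents
the model and its assumptions, the prior choices and both presets, the
sampler internals, what the synthetic generator does and does not
emulate, the numerical edge-case policies, and known limitations.
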