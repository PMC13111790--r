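# mcace

Latent-factor complier-average-causal-effect (MCACE) models for randomized
trials with **multidimensional longitudinal outcomes** and **treatment
noncompliance**.

## The problem this package addresses

Trials of multifaceted interventions (behavioural programs, self-management
tools, care-coordination bundles) typically measure a few underlying
constructs — self-efficacy, interaction with providers — through many
correlated questionnaire endpoints collected at repeated visits, and a
substantial fraction of participants assigned to the intervention never
actually use it. Endpoint-by-endpoint analyses then face multiple testing,
power loss, and results that do not answer the construct-level question,
while intention-to-treat contrasts dilute the effect of actually receiving
the intervention.

`mcace` is for biostatisticians analyzing such trials. It combines principal
stratification with confirmatory factor analysis: subjects are partitioned
into **compliers** (take the treatment iff assigned) and **never-takers**
(never take it; with no treatment access in the control arm these are the
only strata), and within each stratum the K endpoints load on Q ≪ K latent
factors that follow linear mixed models. Writing Λ for the K×Q loading
matrix and stacking the K(J+1) responses per subject, the latent structure
integrates out in closed form,

    y | stratum m, arm a  ~  MVN( λ_m0 ⊗ 1  +  (Λ ⊗ I) X_a β_m ,
                                  (Λ⊗I) Z Σ_v Z' (Λ⊗I)' + (Λ⊗I)(Λ⊗I)'
                                  + diag(ξ_m) ⊗ 11' + diag(τ²_m) ⊗ I ),

and the observed-data likelihood multiplies the treated-complier and
treated-never-taker terms with a control-arm mixture weighted by a logistic
compliance model, marginalizing missing-at-random outcomes analytically.
Estimation is direct maximum likelihood (quasi-Newton with analytic
gradients in compiled code); standard errors come from the observed
information. The **CACE on factor q at visit j** is the treatment contrast
of the complier fixed effects, `(x_qj(1) − x_qj(0))' β_qc` — with the
quadratic time specification, `β_{Dt}·t + β_{Dt²}·t²` — and a single global
likelihood-ratio test of "no effect on any factor" replaces K
Bonferroni-corrected per-endpoint tests.

The package also ships the baseline it is designed to beat (per-outcome
univariate CACE fits with Bonferroni correction, and domain-score averages),
a full trial simulator with compliance strata and MAR dropout, and
replicated power / type-I-error / parameter-recovery harnesses.

## Worked example

Simulate a 300-subject trial under the shipped two-factor scenario (six
outcomes at months 0/3/6, 30% compliance, complier treatment-by-time effect
1.5, the motivating trial's dropout profile), fit the model, and test:

```r
library(mcace)

scen <- default_scenario(n_subjects = 300, p_compliance = 0.3, effect = 1.5,
                         missingness = example_missingness())
sim <- simulate_trial(scen, seed = 1)

fit <- mcace_fit(sim$data, scen$spec)
glance(fit)
#>   logLik    AIC    BIC n_free  nobs converged
#> 1 -9224. 18562. 18773.     57   300 TRUE

cace(fit, visit = 2)
#>   factor stratum visit  time estimate std.error statistic      p.value
#> 1      1 c           2     2     2.47     0.441      5.59 0.0000000228
#> 2      2 c           2     2     2.61     0.591      4.41 0.0000103
```

The generating CACE at month six is 2 × 1.5 = 3 on both factors; the fit
recovers 2.47 (SE 0.44) and 2.61 (SE 0.59), each within sampling error. The
global test against the no-treatment-effect specification:

```r
fit0 <- mcace_fit(sim$data, spec_drop_terms(scen$spec, c("D:t", "D:t2")))
global_lrt(fit, fit0)
#>   statistic    df  p.value alpha reject
#> 1      52.7     4 9.70e-11  0.05 TRUE
```

and the per-outcome comparator (`univariate_cace_all(sim$data)`) reports the
six endpoint-level CACE estimates with likelihood-ratio p-values and the
Bonferroni family-wise decision.

Model structure is declared, not hard-coded: `mcace_spec()` takes a loading
mask (`loading_confirmatory(list(c(1,2,3,5), c(4,6)), K = 6)` reproduces the
motivating study's self-efficacy / provider-interaction grouping), level-2
terms from the vocabulary `t, t2, D, D:t, D:t2` plus named baseline
covariates, per-factor random-effect terms, and compliance-model covariates.
`compare_models()` ranks candidate factor structures by AIC/BIC,
`posterior_compliance()` gives each control subject's posterior complier
probability, and `autoplot()` methods display power curves, estimand
trajectories, and recovery calibration. A thin command-line front end over
the same functions lives in `inst/cli/mcace.R` (subcommands `simulate`,
`fit`, `power`, `recover`, `report`; scenarios are YAML files, data are
long-format CSV).

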