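# slopehte

Bayesian discovery of patient subgroups with heterogeneous treatment
effects on the **3-year total eGFR slope** in chronic kidney disease (CKD)
trials, under **informative censoring**.

## The problem

CKD trials increasingly replace rare hard endpoints (dialysis,
transplantation, death) with the total eGFR slope over a horizon
T\* (typically 3 years). Two features make inference delicate:

1. eGFR decline is non-linear: an *acute* slope right after treatment
   initiation, then a *chronic* slope, joined at a change point t\*
   (default 1/3 year). The total slope is the weighted mix
   τ₀ = w·ζ₀ + (1−w)·ν₀ with w = t\*/T\*.
2. Dropout is informative: patients with low, rapidly declining eGFR leave
   the eGFR series earlier (dialysis/death), so naive mixed models are
   biased. A **shared-parameter (SP) model** ties a piecewise-exponential
   dropout hazard to the longitudinal random effects through the frailty
   z_i = exp(λ₀·trt + η₁·α_i + η₂·γ_i).

`slopehte` embeds **Bayesian decision trees** in this joint model: the
baseline eGFR level α₀(x) and control chronic slope γ₀(x) are within-leaf
linear, and the total treatment effect τ₀(x) is piecewise constant over the
leaves of a tree with the classic depth-penalizing prior
(p_split(d) = c₀(1+d)^(−d₀), c₀ = 0.95, d₀ = 2). Trees are sampled by
birth/death Metropolis–Hastings with the subject random effects integrated
out via a Laplace approximation and *all* regression coefficients
marginalized from the move ratio. Subgroups are reported **honestly**:
structure is discovered on a 60% split, effects are re-estimated on the
held-out 40%, repeated over B₃ splits, and summarized by the modal
("super-representative") tree with pooled per-leaf posteriors.

The package ships the full workflow: data model and readers, the two-slope
and survival submodels, the tree machinery, the round-trip Gibbs sampler
(C++ kernels), the honest pipeline, a trial simulator reproducing the
study's data-generating processes, and the simulation metrics
(ℓ₁, R₁, Htr, BEP).

## Worked example

Simulate a strong-heterogeneity trial (τ₀ = −1 for x₁ ≤ 0, +1 for x₁ > 0,
i.e. a harmed and a benefiting subgroup), run the honest pipeline, and
inspect the report:

```r
library(slopehte)

dat <- gen_trial(scenario("setting1", n = 800), seed = 22)
cfg <- sampler_config(B1 = 40, B2 = 40, seed = 9)
res <- hte_pipeline(dat, cfg, B3 = 10)
res
#> <hte_result> super-representative tree (frequency 50%): (x1<=-0.1555618383 * *)
#>   leaf E_n   E_p control_slope treatment_slope effect lower95 upper95 estimable
#> 1    1 159 0.328         -2.70           -4.03 -1.330   -2.05  -0.642      TRUE
#> 2    2 161 0.300         -3.41           -2.45  0.958    0.14   1.767      TRUE

res$ordering[2, 1]   # P(leaf-2 effect > leaf-1 effect | data)
#> [1] 1

pipeline_metrics(res, dat)
#>          l1 r1_propose  r1_naive htr J_super frequency
#> 1 0.2576865  0.0365625 0.5421875   0       2       0.5
```

Reading the output: the modal tree across 10 splits cuts x₁ near 0 (the
planted boundary); the honest per-leaf posteriors recover effects near the
true −1 and +1 eGFR units/yr (`effect` with 95% credible intervals);
`E_n`/`E_p` are the expected validation leaf size and uncensored (event)
proportion; the ordering probability says the second leaf benefits more in
every pooled posterior draw. In the metrics, `htr = 0` means heterogeneity
was correctly declared, and the sign-based treatment rule loses 0.04
units/yr against the oracle versus 0.54 for treat-all.

A command-line wrapper for simulate / fit / report / evaluate lives at
`inst/cli/slopehte.R`.

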