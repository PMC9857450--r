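# curemix

Bayesian parametric **mixture cure rate** (split-population) survival models
in R.

## The problem

Standard survival models assume everyone eventually experiences the event:
S(t) → 0. In many cohorts a substantial fraction never does — released
offenders who never reoffend, patients effectively cured — and the
Kaplan–Meier curve plateaus above zero. Fitting a standard model to such
data misattributes the plateau to an ever-slowing hazard. Mixture cure rate
models instead split the population into susceptibles and non-susceptibles
with a latent indicator U, and model *whether* the event happens separately
from *when*:

- **incidence** (long-term): π(z) = P(U = 1 | z) = logit⁻¹(z′β)
- **latency** (short-term, susceptibles only): Weibull survival
  S_s(t | x) = exp(−μ tʳ), μ = exp(x′α), shape r = 1/σ
  (exponential, lognormal, loglogistic and Gompertz latencies are also
  available)

so the population survival function is improper:

    S(t | x, z) = (1 − π(z)) + π(z) · S_s(t | x)  →  1 − π(z)  as t → ∞.

Incidence coefficients exponentiate to **odds ratios** for ever
experiencing the event; latency coefficients to **hazard-ratio-scale**
effects on its timing. Inference is fully Bayesian via a latent-indicator
Metropolis-within-Gibbs sampler (exact conditional draws of U; adaptive
Gaussian random-walk Metropolis for β, α, and log r), with DIC for model
comparison and Kaplan–Meier diagnostics for the cure plateau. The package is
aimed at applied survival analysts — in criminology, biostatistics or
reliability — who need cure-fraction inference with credible intervals
rather than point estimates.

## Worked example

Simulate a study-structured cohort (n = 800 here; the packaged fixture
defaults to n = 3068 with a 21-year follow-up, a ~48% cure fraction and four
covariates: two count, one binary, one standardized continuous), then fit
the full split-population model:

```r
library(curemix)

coh <- simulate_cohort(default_study_spec(n = 800, seed = 1))
df <- data.frame(time = coh$dataset$times, event = coh$dataset$events,
                 coh$covariates, AGE_std = coh$dataset$X[, "AGE"])

fit <- curemix(survival::Surv(time, event) ~ NP + NPS + AGE_std + UND16,
               cureform = ~ NP + NPS + AGE_std + UND16, data = df,
               follow_up_limit = 21,
               control = chain_control(burnin = 1000, iterations = 8000,
                                       thin = 8, seed = 2))
summary(fit)
```

```
Bayesian mixture cure rate model (weibull latency)
n = 800 subjects, 420 events; posterior mean cure fraction 0.465

             parameter    mean     sd   lower   upper ess
 incidence.(Intercept) -0.6022 0.1113 -0.8141 -0.3834 397
          incidence.NP  0.5035 0.0534  0.4051  0.6183 283
         incidence.NPS  0.1663 0.0877 -0.0096  0.3334 341
     incidence.AGE_std -0.2940 0.0823 -0.4485 -0.1318 333
       incidence.UND16  0.2433 0.1591 -0.0594  0.5665 387
   latency.(Intercept)  0.6522 0.0866  0.4841  0.8164 199
            latency.NP  1.1549 0.0526  1.0541  1.2520   9
           latency.NPS -0.7272 0.0924 -0.8655 -0.5637   4
       latency.AGE_std -1.8030 0.0878 -1.9519 -1.6255   9
         latency.UND16 -0.1795 0.1116 -0.4059  0.0372  18
                 shape  0.8954 0.0372  0.8252  0.9664  12

Long-term (OR) and short-term (HR) effects, exp(posterior mean) [95% CI]:
  NP           OR = 1.65 (1.50, 1.86)
  NPS          OR = 1.18 (0.99, 1.40)
  AGE_std      OR = 0.75 (0.64, 0.88)
  UND16        OR = 1.28 (0.94, 1.76)
  NP           HR = 3.17 (2.87, 3.50)
  NPS          HR = 0.48 (0.42, 0.57)
  AGE_std      HR = 0.16 (0.14, 0.20)
  UND16        HR = 0.84 (0.67, 1.04)

DIC = -860.458  (Dbar = -873.5244 , pD = 13.07)
```

Reading it: each prior non-sexual conviction multiplies the odds of ever
reoffending by ~1.65 and, among those who will reoffend, multiplies the
hazard (speed) of reoffending by ~3.2; the cure fraction (share never
reoffending) is about 46%; the Weibull shape below 1 (0.90, CI excluding 1)
says the reoffending hazard declines with time since release. The cohort was
generated with a true susceptible share of ~0.52 and shape 0.87, both inside
the intervals. The low ESS values on the latency block flag the slow-mixing
directions — lengthen the chain (the reference settings are
`chain_control()`'s defaults: 500,000 iterations thinned by 100) when the
numbers matter.

The nonparametric diagnostic for the plateau:

```r
km_fit(fit$ds)
```
```
Kaplan-Meier estimate: n = 800 subjects, 420 events
  plateau (survival at last event time): 0.475
```

Also available: `predict(fit, horizon = c(3, 10, 21))` for fixed-horizon
event probabilities, `group_probability()` for group-level probabilities by
two estimation methods (within-group averaging vs counterfactual averaging
over the full sample), `cure_compare()` for DIC tables across the
`standard` / `spm1` / `spm2` / `spm3` model hierarchy,
`fit_horizon_logistic()` for the fixed-horizon logistic baseline, and a
command-line front end:

```sh
curesurv simulate --n 3068 --seed 1 --out sim/
curesurv fit --data sim/cohort.csv --config config.yml --variant spm3 --out fit/
curesurv compare --data sim/cohort.csv --config config.yml --out cmp/
```

(`exec/curesurv`; delimiters auto-detected between comma and tab; column
roles, priors and chain settings via a YAML config.)

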