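# glmmscore

Bayesian predictive model evaluation for longitudinal count GLMMs.

## The problem

Clinical trials with a repeatedly measured count as the primary endpoint —
vertigo attacks per month, seizure counts, exacerbations — require the
statistical analysis plan (SAP) to pre-specify a mixed-model strategy for
sensitivity analyses: which count distribution (Poisson, negative binomial,
zero-inflated variants, or a variance-stabilizing transform with a normal
model), and which subject-level random effects (intercepts only, or
correlated intercepts and slopes). `glmmscore` is a toolbox for making that
choice *before* the trial data exist, using pilot or pre-study data: it fits
a menu of rival Bayesian generalized linear mixed models (GLMMs) and ranks
them by leave-one-out predictive performance.

## What it computes

For each candidate model with linear predictor
η<sub>ij</sub> = (β₀+b<sub>0i</sub>) + (β₁+b<sub>1i</sub>)t<sub>ij</sub> +
β₂x<sub>i</sub> + β₃x<sub>i</sub>t<sub>ij</sub> (log link for counts),
fitted by adaptive MCMC:

* **CPO** — the conditional predictive ordinate
  π(y<sub>ij</sub> | y<sub>−ij</sub>), estimated from a single full-data fit
  (harmonic-mean identity or Marshall–Spiegelhalter "ghost sampling"), with
  instability flags and an exact single-case-refit fallback;
* **Logarithmic score** — LS<sub>ij</sub> = −log CPO<sub>ij</sub>, a strictly
  proper scoring rule; models are ranked by the mean score (lower = better),
  with the arcsinh normal model's mean score back-transformed to the count
  scale so all models are comparable;
* **Adjusted PIT** — Pr(y<sup>new</sup> &lt; y | y<sub>−ij</sub>) +
  ½·Pr(y<sup>new</sup> = y | y<sub>−ij</sub>), the non-randomized probability
  integral transform for counts, with histogram data for calibration checks;
* **DIC** — D̄ + p<sub>D</sub> with the plug-in deviance at the posterior
  means of all latent quantities;
* **Paired Monte Carlo permutation tests** (9,999 permutations) for
  differences in mean scores between rival models;
* **AUC summaries** of how well the mean score separates a misspecified
  model from the true one across simulation replicates, over an 18-scenario
  grid of overdispersion (k = 0.5…50) × group size (n = 20, 50, 100).

## Worked example

Rank candidate models on synthetic pilot data shaped like a two-dose
vertigo pre-study (56 patients, 5 visits at months 0–12):

```r
library(glmmscore)

pilot <- generate_vertigo_like(n_low = 25, n_high = 31, seed = 7)
pr_is <- prior_spec(wishart_R = diag(c(1, 1/144)))  # slope prior on a monthly scale
menu <- list(model_spec("poisson", "I"),
             model_spec("poisson", "IS", priors = pr_is),
             model_spec("nb", "IS", priors = pr_is),
             model_spec("nmm_arcsinh", "I"))
cs <- run_case_study(pilot, menu,
                     control = mcmc_control(chains = 2, iter = 1500, seed = 1),
                     ghost = FALSE)
print(cs$ranking, digits = 4)
#>            model  Dbar  Dhat    pD   DIC mean_ls delta_ls delta_DIC noteworthy p_vs_best
#> 1    poisson(IS) 753.0 704.3 48.68 801.6   1.440  0.00000     0.000         no        NA
#> 2     poisson(I) 762.1 719.7 42.45 804.6   1.451  0.01086     2.962         no    0.1770
#> 3         nb(IS) 761.7 712.0 49.69 811.4   1.454  0.01401     9.740        yes    0.0034
#> 4 nmm_arcsinh(I) 529.4 492.3 37.08    NA   1.672  0.23158        NA       <NA>        NA
cat(cs$recommendation$text)
#> Best predictive model by mean logarithmic score: poisson(IS).
#> Statistically indistinguishable at the 5% level: poisson(I).
```

Reading the table: the random-slope Poisson model predicts best by mean log
score (the data were generated with subject-specific slopes), the
random-intercept Poisson cannot be distinguished from it by the paired
permutation test (p = 0.18), while the NB(IS) scores significantly worse
(p = 0.003) — there is no overdispersion to absorb. The arcsinh normal
model's mean score is back-transformed to the count scale for the ranking,
but its DIC and permutation test are not applicable (`NA`): a
transformed-outcome deviance is not comparable and its observation-level
scores live on another scale.

The simulation side of the package works the same way at any scale:

```r
sc <- run_scenario(n = 20, k = 0.5, r = 6,
                   models = c("nb", "poisson", "zinb", "nmm_arcsinh"), seed = 11)
sc
#> scenario n=20 per group, k=0.5, r=6 (0 failures)
#>   AUC(poisson vs nb) = 1.000
#>   AUC(zinb vs nb) = 0.556
#>   AUC(nmm_arcsinh vs nb) = 0.750
```

With heavy overdispersion (k = 0.5) the mean score separates the Poisson
model from the true NB perfectly, cannot separate the ZINB (which nests the
truth), and separates the arcsinh model partially — exactly the pattern the
method is designed to reveal.

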