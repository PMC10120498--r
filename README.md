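# bartcate

Two-stage Bayesian machine-learning analysis of heterogeneity of
treatment effect (HTE) in randomized trials, built around the setting of
a dexamethasone dosing trial in severe COVID-19 (12 mg/d vs 6 mg/d,
n = 982, two outcomes: days alive without life support at day 90
[DAWOLS] and 90-day mortality, ten pre-selected baseline effect
modifiers).

**Stage 1** fits Bayesian Additive Regression Trees (BART) — a sum of
`m` regression trees with a regularizing structure prior in which a node
at depth `d` splits with probability `base * (1 + d)^(-power)` — by
backfitting MCMC, jointly on the randomized arm `z` and covariates `x`.
Each patient's conditional average treatment effect (CATE)

&nbsp;&nbsp;&nbsp;&nbsp;τ(xᵢ) = f(1, xᵢ) − f(0, xᵢ)

is computed per posterior draw from the two counterfactual predictions
(days for DAWOLS; a risk difference for mortality, via latent-variable
probit/logit BART), giving per-patient posteriors, partial-dependence
curves and quartile-of-CATE tables. **Stage 2** ("fit-the-fit")
summarizes the posterior-mean CATEs with a depth-3 greedy regression
tree whose cutpoints are reported in original units (years, kg), with
95% credible intervals for each subgroup mean obtained by averaging the
members' CATE draws within each posterior draw. Around the core sit
tenfold cross-validation over the 27-configuration hyperparameter grid
(power 1/2/3 × base 0.25/0.5/0.95 × 50/200/400 trees), Geweke
convergence diagnostics, best/worst-case missing-outcome sensitivity
analyses, and a synthetic trial generator emulating the published
baseline table with configurable planted effects. The BART sampler's
hot loop is C++ (Rcpp); everything is reproducible from a seed.

Because the real trial data are access-restricted, the package is
organized so every stage is testable against synthetic trials with known
structure; the methods vignette
(`vignettes/bartcate-methods.Rmd`) documents the model, priors, generator
and design decisions in detail.

## Worked example

```r
library(bartcate)

sc  <- trial_scenario("diabetes-interaction")   # planted: 6 d benefit
ds  <- generate_trial(982, sc$marginals, sc$effects, seed = 42)  # without,
std <- standardize_covariates(ds)               # 2 d with diabetes
cate <- estimate_cate(std, "dawols",
                      bart_config(ntree = 200, nchain = 2,
                                  ntotal = 600, nburn = 100, seed = 42))
glance(cate)
#> # A tibble: 1 × 7
#>   outcome scale     n n_draws estimate conf.low conf.high
#> 1 dawols  days    971    1000     5.86     2.25      9.54

tree <- fit_subgroups(cate)   # depth-3 fit-the-fit tree, original units
cat(render_tree(tree, "text"))
#> all: 5.860 [2.250, 9.541]  (prop 1.000)
#>   diabetes <=     0.5: 6.488 [2.669, 10.564]  (prop 0.715)
#>     weight <= 89.0123: 6.160 [2.246, 10.339]  (prop 0.463)
#>     ...
#>   diabetes >     0.5: 4.288 [-1.021, 8.950]  (prop 0.285)
#>     ...
```

The sample-average effect is 5.86 days in favor of 12 mg/d (971 of 982
patients analyzed; 11 had a missing outcome), and the first split
recovers the planted modifier: patients without diabetes benefit about
6.5 days versus 4.3 days with diabetes, each box showing the subgroup
mean, its 95% credible interval, and the proportion of the sample.
`quartile_summary(cate)` gives the same posterior sliced by CATE
quartile:

```r
quartile_summary(cate)
#> # A tibble: 4 × 7
#>   quartile     n mean_outcome_12mg mean_outcome_6mg estimate conf.low conf.high
#> 1 Q1         242              55.4             51.3     4.08   -0.975      8.78
#> 2 Q2         243              56.6             50.9     5.67    1.92       9.48
#> 3 Q3         243              53.1             46.7     6.39    2.55      10.5
#> 4 Q4         243              48.6             41.3     7.28    2.92      11.7
```

`partial_dependence(cate, "age")` and the `autoplot()` methods plot the
CATE curves; `cross_validate()` selects hyperparameters;
`run_sensitivity()` reruns both stages under best/worst-case imputation;
`run_analysis(config, out_dir)` drives the whole pipeline from a YAML/JSON
config and writes a plain-text report bundle with a provenance manifest
(a thin CLI over the same functions is in `inst/cli/bartcate-cli.R`).

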