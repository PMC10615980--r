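# raterdrift

Bayesian estimation of **rater severity drift** in longitudinal performance
assessment data, for psychometricians and measurement practitioners who need
to know not just *how severe* each rater is, but *how their severity moves*
across a rating period.

## The model

Ordinal scores `k = 1..K` assigned by rater `r` to examinee `j` at time
point `t` follow a many-facet Rasch model with time-specific severities:

    P(u_jrt = k) ∝ exp Σ_{m=1..k} D(θ_j − β_rt − d_rm),   D = 1.7

with abilities `θ_j`, severities `β_rt`, and rater-specific step parameters
`d_rm` (`d_r1 = 0`, `Σ_{m≥2} d_rm = 0`). The distinguishing feature is a
first-order Markov prior on each rater's severity trajectory,

    β_r1 ~ N(0,1),   β_rt ~ N(β_{r,t−1}, σ_r),   σ_r ~ LN(μ_σ, 1),

so each rater gets an interpretable drift scale `σ_r` (≈0: stable rater;
large: strong drift), and the hyperparameter `μ_σ` (default −2) encodes how
common drift is believed to be. Ablations with independent severities
(`proposed_no_markov`) and shared steps (`baseline`, `baseline_markov`) are
included for comparison. Posteriors are sampled with a built-in No-U-Turn
HMC sampler (analytic gradients, compiled); point estimates are EAP;
split-chain R-hat, ESS and divergence counts are reported; WAIC and WBIC
support model and hyperparameter selection.

## Worked example

```r
library(raterdrift)

# a rating study: 100 examinees, 5 raters, 3 rating sessions, 5 categories,
# every rater scores every examinee once, a third of their queue per session
truth <- draw_parameters(100, 5, 3, K = 5, seed = 1)
design <- fully_crossed_design(100, 5, 3, seed = 2)
ratings <- simulate_scores(truth, design, seed = 3)
ratings
#> rating_data: 500 observations (J = 100 examinees, R = 5 raters, T = 3 time points, K = 5 categories)

fit <- fit_drift(ratings, "proposed",
                 config = sampler_config(chains = 3, iterations = 2000,
                                         warmup = 1000, seed = 4))
diagnostics(fit)
#> R-hat:  max 1.005 (threshold 1.1) -> ok
#> ESS:    min 569 (threshold 400) -> ok
#> Divergent transitions: 0 (0.00%)

est <- eap(fit)
round(est$sigma, 2)           # drift scales: which raters drift?
#> [1] 0.27 0.39 0.21 0.16 0.12
round(truth$sigma, 2)
#> [1] 0.18 0.56 0.01 0.15 0.04
rmse(est$theta, truth$theta)  # ability recovery
#> [1] 0.3469576
```

Rater 2 is the strongly drifting rater (true `σ = 0.56`) and receives the
largest posterior drift scale; abilities are recovered with the RMSE
expected at five ratings per examinee. Model comparison on the same data:

```r
waic(fit)
#> WAIC = 957.46 (lppd = -379.60, p_waic = 99.13); lower is better
wbic(ratings, "proposed")  # nats, tempered run, lower is better
compare_models(ratings)    # all four variants, minima flagged
```

A command-line front end over the same functions is installed at
`inst/cli/raterdrift.R` (subcommands `simulate`, `fit`, `compare`,
`recover`, `sweep`).

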