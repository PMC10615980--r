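---
title: "Modeling rater severity drift with a Markov many-facet Rasch model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rater severity drift with a Markov many-facet Rasch model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In rated performance assessments (essays, presentations, clinical exams), the
score an examinee receives depends not only on their ability but on which
rater scored them and *when*. Raters differ in overall severity, and a
rater's severity can drift across the rating period — a long grading session,
or several days of scoring. Ignoring drift biases ability estimates and makes
rater monitoring unreliable.

`raterdrift` implements a Bayesian many-facet Rasch model (MFRM) in which
each rater has a severity parameter *per time point*, and those time-specific
severities are tied together by a first-order Markov chain. The package
covers the full workflow: simulating realistic rating data, posterior
sampling, convergence diagnostics, information-criterion model comparison,
and parameter-recovery experiments.

## The model

A single item is scored on an ordinal scale $k \in \{1, \dots, K\}$. The
probability that examinee $j$ receives score $k$ from rater $r$ at time
point $t$ follows the adjacent-categories (partial-credit) kernel

$$
P_{jrtk} = \frac{\exp \sum_{m=1}^{k} D(\theta_j - \beta_{rt} - d_{rm})}
                {\sum_{l=1}^{K} \exp \sum_{m=1}^{l} D(\theta_j - \beta_{rt} - d_{rm})},
$$

with $D = 1.7$ the usual logistic scaling constant, $\theta_j$ the examinee
ability, $\beta_{rt}$ the severity of rater $r$ at time $t$, and $d_{rm}$
rater-specific step parameters capturing each rater's use of the score
categories (central tendency, range restriction). Identification requires
$d_{r1} = 0$ and $\sum_{m=2}^{K} d_{rm} = 0$.

The priors define the drift structure:

$$
\theta_j \sim N(0,1), \quad
\beta_{r1} \sim N(0,1), \quad
\beta_{rt} \sim N(\beta_{r,t-1}, \sigma_r)\ (t > 1), \quad
\sigma_r \sim LN(\mu_\sigma, 1), \quad
d_{rm} \sim N(0,1).
$$

The rater-specific scale $\sigma_r$ summarises how strongly rater $r$
drifts: values near zero mean stable severity, values near one mean strong
drift. The hyperparameter $\mu_\sigma$ (default $-2$) encodes the analyst's
prior belief about how common drift is; $-5$ expresses near-certainty that
raters are stable, $0$ is weakly informative. Values above 0 are
discouraged: they put substantial prior mass on drift scales larger than
the severity scale itself.

Three ablations are provided for comparison: `proposed_no_markov` replaces
the chain with i.i.d. $N(0,1)$ severities (temporal independence, the
classical assumption); `baseline` additionally shares one step vector
$d_m$ across raters; `baseline_markov` keeps shared steps but restores the
chain. The proposed model nests the baseline: with all step rows equal, the
likelihoods agree exactly.

### Identification and parameterisation choices

* The severity scale is identified through the priors ($\theta$ and
  $\beta_{r1}$ standard normal), not through sum-to-zero anchoring. Users
  should not expect anchored scales: an overall shift between abilities and
  severities is resolved only by the prior.
* The generative notation $d_{rm} \sim N(0,1)$ does not by itself say how
  the two constraints interact with the prior. The package reads it as the
  *conditional* law: independent standard normals on $(d_{r2},\dots,d_{rK})$
  conditioned on $\sum_{m=2}^{K} d_{rm} = 0$ — equivalently, centered
  normals with per-entry variance $1 - 1/(K-1)$. The sampler works on the
  $K-2$ free coordinates $(d_{r2},\dots,d_{r,K-1})$ with
  $d_{rK} = -\sum_{m=2}^{K-1} d_{rm}$ deterministic, and evaluates the
  normal density on *all* constrained entries including the forced last
  one (the form that writing `d ~ normal(0, 1)` over a sum-to-zero vector
  produces in probabilistic-programming practice). The simulator draws
  truth from the same conditional law. The plausible alternative —
  independent $N(0,1)$ on the free coordinates only, leaving the forced
  last step with variance $K-2$ — makes the implied last threshold far
  more dispersed than the others, which distorts both the generative
  difficulty of the data and the symmetry of the category thresholds;
  recovery experiments under that convention produce ability and step
  RMSEs well above the levels this model family is known to achieve,
  while the conditional convention reproduces them.
* For $K = 2$ the step vector is fully determined as $(0, 0)$ and the free
  block is empty.
* $\sigma_r$ is sampled on the log scale with the Jacobian included, so the
  chain targets the posterior of $\sigma_r$ itself. This respects
  positivity and substantially improves the Hamiltonian geometry.
* The severity chain is sampled in *non-centered* form: the sampler works
  with $\beta_{r1}$ and standardised innovations
  $z_{rt} = (\beta_{rt} - \beta_{r,t-1})/\sigma_r \sim N(0,1)$, and
  $\beta_{rt}$ is reconstructed deterministically. The posterior is
  unchanged, but the $\sigma_r \to 0$ funnel that the centered form
  creates — precisely the regime of stable raters, i.e. most raters —
  disappears, which is worth an order of magnitude in effective sample
  size per draw on stable-rater datasets.

## Posterior computation

The joint posterior is sampled with a No-U-Turn Hamiltonian Monte Carlo
sampler implemented in compiled code, with analytic gradients of the full
log posterior. The implementation follows the classic recursive
tree-doubling algorithm (slice variant) with dual-averaging step-size
adaptation and windowed estimation of a diagonal metric during warmup;
divergent transitions are flagged when the Hamiltonian error along a
trajectory exceeds 1000 and are reported as a fraction of post-warmup
transitions. Defaults are 3 chains, 5000 iterations with 2000 warmup
(9000 retained draws), a 0.98 target acceptance statistic (reducing
divergences in the funnel-like geometry that small drift scales create),
and a maximum tree depth of 10.

Chains are initialised from prior draws, independently per chain, with
per-chain seeds derived deterministically from the master seed; fits are
exactly reproducible given the seed. Point estimates are EAP (posterior
means over all retained draws); step estimates satisfy the identification
constraints exactly because the constraint map is linear. Convergence is
summarised by split-chain R-hat and an autocorrelation-based effective
sample size with Geyer initial-positive-sequence truncation; the customary
thresholds (R-hat < 1.1, ESS > 400) are reported as flags, never enforced,
and non-convergence is never an error.

The test suite pins the sampler to the model definition in two independent
ways: the compiled unnormalised log density must agree with a plain-R
`log_posterior()` at random parameter points to 1e-6, and its analytic
gradients must match central finite differences. On an empty dataset the
sampler must reproduce the $N(0,1)$ ability prior (Kolmogorov–Smirnov test),
and on a conjugate normal-mean toy model the same machinery must match the
closed-form posterior and marginal likelihood.

## Model comparison

`waic()` computes the widely applicable information criterion on the
deviance scale, $-2(\mathrm{lppd} - p_\mathrm{WAIC})$, with the penalty
summing per-observation posterior variances of the log-likelihood
(sample variance, $n-1$ denominator). `wbic()` runs a dedicated sampling
pass targeting the tempered posterior
$\pi(\omega)\, p(U \mid \omega)^{1/\log n}$ and returns the tempered
expectation of the negative log-likelihood in nats. The two criteria are on
different scales by construction and are reported side by side, never
compared to each other; for both, lower is better. These scale conventions
follow the cited literature for each criterion (WAIC as an estimate of
twice the generalisation error on the deviance scale; WBIC as an
approximation of the negative log marginal likelihood).

## The synthetic-data generator

Because rating data with documented drift are rarely shareable, the
generator is a first-class module emulating a realistic rating study:

* Abilities, initial severities and free step coordinates are standard
  normal; severities then follow the Markov chain.
* Drift scales come from a two-component log-normal mixture:
  $LN(-3, 1)$ for a stable 60% of raters and $LN(-1, 1)$ for a drifting
  40%, i.e. most raters hold steady while a minority drift markedly. The
  stable count is $\lfloor 0.6 R \rfloor$; component labels are randomly
  permuted over raters (which raters drift is not fixed by index).
* Two designs: *fully crossed* (every rater rates every examinee) and the
  *systematic link design*, in which examinee $j$ is rated by
  `n_raters` cyclically consecutive raters starting at
  $((j-1) \bmod R) + 1$. The cyclic construction keeps the
  examinee–rater graph connected, so all raters remain linkable to a
  common scale even though each examinee sees only 2–3 raters.
* Each rater scores each assigned examinee exactly once. The rater's
  workload is randomly permuted and split into $T$ contiguous blocks of
  near-equal size (differing by at most one, larger blocks first), one
  block per time point — mirroring a rater grading an even share of their
  queue per session in randomised order. A consequence worth noting:
  increasing $T$ *decreases* the data available per severity parameter,
  which is why severity RMSEs grow with $T$ in recovery experiments.

What the generator does *not* emulate: intentionally scripted rater
behaviour (monotone or alternating drift instructions, deliberate category
preferences), rater-by-examinee interactions, missingness that depends on
scores, or multi-item tests. Passing recovery tests therefore demonstrate
that the estimator recovers parameters *under the model's own generative
assumptions* — they do not validate the model against behaviour outside
those assumptions.

## Recovery experiments

`run_recovery()` reproduces the standard parameter-recovery design: a grid
over $J \in \{100, 200, 500\}$, $R \in \{5, 10\}$, $T \in \{3, 5\}$ with
$K = 5$; per replication it draws truth, simulates scores, refits, and
records pooled RMSE and bias per parameter family. Pooling is within
replication (all entities of a family together), then averaged across
replications. Failed fits are excluded with a warning and counted, never
retried. `paired_comparison()` pairs per-condition average RMSEs across
two reports (e.g. with/without the Markov prior) and applies a two-sided
paired t-test per family, flagging degenerate zero-variance pairings. The
σ mixture, seeds and datasets are shared across variants so ablation
contrasts are paired at the data level. Statistical power computations to
accompany the t-tests are deliberately out of scope.

### Problem sizes used in the shipped checks

The package's own acceptance checks re-run the recovery machinery at desk
scale, chosen to keep the full suite in the tens of minutes on one CPU:

* Single-condition checks at $(J, R, T) = (100, 5, 3)$ use 10 replications
  with 3 chains of 1000 warmup + 1000 retained draws. At this scale the
  Monte-Carlo standard error of a family's average RMSE (estimated from
  the replication spread) is a few hundredths, which is the tolerance the
  checks use (3 standard errors).
* Grid-level summaries (grand averages and Markov-vs-independent
  improvement figures across all 12 conditions and three designs) use one
  replication per condition with short two-chain runs (a few hundred
  retained draws per chain) at a 0.9 acceptance target. These reproduce the *direction and rough magnitude*
  of the full 50-replication experiment; per-condition values at one
  replication are individually noisy, deliberately so. The full-scale grid
  is a single function call away (`recovery_config()` defaults) for anyone
  prepared to leave it running overnight.

A practical note on heavy tails: with drift scales drawn from $LN(-1,1)$,
an occasional rater wanders to severities of $|\beta| > 4$, where nearly
all scores saturate at the extreme category and the likelihood stops
constraining that rater's severity from above. Per-replication severity
RMSEs are therefore heavy-tailed, and averages over few replications can
sit noticeably above or below the long-run mean. This is a property of the
generative design itself, not of the estimator.

## Numerical choices

* All category probabilities are computed in log space with log-sum-exp
  normalisation; the normalisation check tolerance is 1e-12.
* Scores and indices are 1-based everywhere at the interface; compiled
  internals are 0-based.
* CSV parsing is strict: out-of-range scores, duplicate
  (examinee, rater, time) triples, and non-integer fields are errors,
  never repaired.
* R-hat returns `Inf` when chains disagree with zero within-chain
  variance and `NaN` when all draws are identical; ESS returns 0 for
  constant chains.
* The WAIC penalty uses the $n-1$ sample-variance convention; a
  single-draw matrix yields a warning and a zero penalty.
* Per-chain seeds and per-replication seeds are drawn from the master seed
  via R's RNG, all below $2^{31}$; the compiled sampler uses its own
  portable generator (Box–Muller over `mt19937_64`) so draws do not depend
  on the C++ standard library's distribution implementations.

## Limitations

* Single-item setting only: no item difficulty facets, item-specific steps
  or rater-by-item interactions.
* First-order chain only; longer-range dependence is not modeled.
* The severity scale is prior-identified, so severities are comparable
  across fits only through the shared prior, not an anchored zero.
* WBIC requires its own tempered run per variant, doubling comparison cost.
* Very sparse designs (2 raters per examinee) with short chains can leave
  a handful of divergent transitions even at a 0.98 acceptance target;
  these are reported and should be checked before interpreting drift
  scales for individual raters.
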