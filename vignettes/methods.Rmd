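---
title: "Multidimensional provider profiling with dominance criteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional provider profiling with dominance criteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(provdom)
```

## The problem

Healthcare providers (and public-sector organisations generally) pursue
several objectives at once — treat patients quickly, cheaply, safely, and
with good functional outcomes — and the stakeholders who judge them do not
share a common set of weights across those objectives. Composite scores
therefore rest on weightings that someone can always legitimately dispute.
`provdom` implements the alternative: estimate each provider's
contribution to every performance dimension jointly, then classify
providers against a benchmark using only *dominance*: a provider dominates
the benchmark when it is better on every dimension simultaneously, is
dominated when worse on every dimension, and is otherwise non-comparable.
The only preference assumption is the sign of each dimension (more is
better, or worse) — exactly what the `orientation` field of a
`dimension_spec` records.

## The model

For patient $i$ in provider $j$ and dimension $k = 1, \dots, K$:

$$Y^{*}_{ijk} = \alpha_k + X_{ijk}'\beta_k + \theta_{jk} + \epsilon_{ijk},$$

where continuous dimensions observe a monotone transform of $Y^{*}$
(log1p for skewed length of stay, identity for an outcome score) and
binary dimensions observe $\mathbf{1}(Y^{*} > 0)$ (probit). The two random
terms are multivariate normal across dimensions:
$\theta_j \sim \mathrm{MVN}(0, \Sigma)$ with
$\Sigma = \mathrm{diag}(\tau)\,\rho_\theta\,\mathrm{diag}(\tau)$, and
$\epsilon_i \sim \mathrm{MVN}(0, \Omega)$ with
$\mathrm{var}(\epsilon_{ijk}) = \sigma_k^2$ for continuous dimensions and
fixed at $1$ for probit dimensions (scale identification). Risk-adjustment
covariate sets may differ by dimension and may be empty — waiting time is
deliberately unadjusted, since managing the waiting list is part of what
is being assessed. Continuous covariates are mean-centred so that
$\alpha_k$ is the conditional mean at average case mix, which also serves
as the default benchmark.

### Estimation

The estimator is a Gibbs sampler with data augmentation:

* truncated-normal draws of the probit latents given the other dimensions'
  residuals (the conditional distributions follow from $\Omega$);
* missing outcome cells drawn from their conditional normal given the
  observed dimensions, covariates and current parameters — this
  operationalises the assumption that outcomes are missing at random given
  everything modelled;
* conjugate normal updates for $(\alpha_k, \beta_k)$, dimension by
  dimension, conditioning on the other dimensions' residuals (a seemingly
  unrelated regressions adjustment);
* a joint conditional-MVN update of each $\theta_j$;
* inverse-Wishart updates for $\Sigma$ and $\Omega$.

The chain runs on the *unidentified* scale — probit residual variances are
left free under the inverse-Wishart — and each stored draw is rescaled to
the identified scale (probit variances exactly 1, with $\alpha$, $\beta$,
$\theta$, $\Sigma$ rescaled accordingly). We found rescaling the *state*
every iteration, rather than only the stored draws, measurably distorts
the stationary distribution of the provider-level correlations; rescaling
at storage is the marginal-augmentation scheme used by established
multivariate-probit samplers.

The phrase *Empirical Bayes estimates* is retained for the per-provider
posterior means $\hat\theta_j$ and covariances $V_j$ returned by
`provider_effects()`: they are precision-weighted (shrunken) summaries of
each provider's effect, and they are exactly the inputs the dominance
stage consumes.

### Priors and starting values

Defaults: coefficient variance $10^4$; inverse-Wishart with $K + 2$
degrees of freedom for both covariances, scale $0.01 I$ for $\Sigma$ and
$I$ for $\Omega$. The small $\Sigma$ scale matters: provider variances in
profiling applications are of order $10^{-2}$–$10^0$, and an identity
scale with $K+2$ degrees of freedom would add a unit of prior scatter to a
provider sum-of-squares of comparable magnitude, biasing $\tau$ upward by
tens of percent at $J = 100$. The $\Omega$ prior is swamped by $N$
patient-level observations, so its scale is immaterial.

Starting values are method-of-moments: raw provider-mean deviations for
$\theta$ and their covariance for $\Sigma$. This is not cosmetic. The
centred parameterisation has a funnel: a chain started at small $\Sigma$
shrinks the $\theta$ draws toward the correlation structure implied by the
current $\Sigma$, which reproduces itself in the next $\Sigma$ draw; the
provider-level correlations can then sit near $\pm 1$ for thousands of
iterations. Starting at the moment estimates places the chain inside the
region the posterior actually occupies.

### Identifiability of the provider-level correlations

A design lesson worth recording: the data inform $\rho_\theta$ only
through the *disattenuated* covariation of provider summaries, so each
dimension needs a reasonable signal share
$\tau_k^2 / (\tau_k^2 + \text{per-provider noise})$. For a continuous
dimension the noise is $\sigma_k^2 / n_j$; for a probit dimension with
event rate $p$ it is approximately
$p(1-p) / (n_j\,\phi(\Phi^{-1}(p))^2)$. When the share falls well below
about two thirds, the posterior for correlations involving that dimension
becomes wide and piles towards $\pm 1$ (the boundary is absorbing for the
point estimate, not for the interval — coverage remains honest). All
default generator settings keep the share at or above roughly two thirds
at the benchmark size $J = 100$, $n_j = 100$; rare events with small
$\tau$ are the combination to avoid, which is why the readmission
dimension defaults to $\tau = 0.3$ at a 5% event rate.

### Convergence gate

Split-$\hat R$ is computed for every intercept, $\tau_k$, $\sigma_k$ and
both correlation matrices; a fit with any value above 1.05 is flagged and
`provider_effects()` refuses to run on it unless `force = TRUE`. Short
exploratory chains routinely trip the gate; the gate is a refusal to
classify, not a refusal to fit.

## Dominance classification

Given $\hat\theta_j$ and $V_j$, orient every dimension so that positive
means better, and estimate by simulation the probability that the
provider's true effect lies in the all-positive orthant (dominant), the
all-negative orthant (dominated), or neither (non-comparable, the
complement — the three sum to one by construction). `dominance()` draws
from $\mathrm{MVN}(\hat\theta_j, V_j)$ by default ($S = 10{,}000$; the
Monte-Carlo standard error is reported) or resamples the stored MCMC
draws; ties at exactly zero count against the strict inequalities, a
measure-zero convention. `orthant_probability()` provides the
deterministic counterpart (Genz-type numerical integration, $K \le 6$,
absolute tolerance about $10^{-5}$) and is the oracle the simulation is
tested against.

`classify()` labels a provider dominant (dominated) when the corresponding
probability reaches a threshold; thresholds in $[0.5, 1]$ are accepted so
the published 0.50/0.80/0.90/0.99 grid can be reproduced. At exactly 0.5
the two rules could only collide if both probabilities were exactly 0.5;
dominant takes precedence. "Unclassified" is kept distinct from the
*probability* of being non-comparable: the former is a label outcome, the
latter a posterior quantity.

The comparison study (`compare_approaches()`) contrasts three routes:
univariate fits with a per-dimension "confidence box" rule, the
multivariate fit with the same box rule, and the multivariate fit with the
joint orthant probability. The box rule uses the Bonferroni form
$1 - (1 - \Pr^{*})/K$ per dimension, with `>=` at the boundary. Because
the Bonferroni inequality guarantees that a provider passing all
per-dimension cuts has joint probability at least $\Pr^{*}$, the box
classifications are provably nested inside the joint ones; the univariate
arm is additionally handicapped by its larger per-dimension posterior
variances. On positively correlated synthetic cohorts the package
reproduces the expected ordering: univariate $\subseteq$ intermediate
$\subseteq$ full, with counts non-increasing in the threshold.

## The synthetic cohort generator

`synthetic_config()` defaults emulate a hip-replacement profiling setting:
four dimensions (log-scale length of stay around 5.4 days; an outcome
score with mean 38.5 and residual SD 9.2; waiting beyond the 18-week
target at a 17% marginal rate; 28-day emergency readmission at 5%), three
standard covariates (a standard-normal pre-operative score, male with
probability 0.4, neighbourhood deprivation uniform on $[0, 0.24]$),
missingness rates (0.1%, 15.2%, 4%, 0%) applied MCAR by default or MAR
with a calibrated logistic in a named covariate, and provider/patient
correlation matrices with the pattern typical of this setting (shorter
stay with better outcome scores at provider level, and so on). Probit
intercepts are calibrated as $\Phi^{-1}(p)\sqrt{1+\tau_k^2}$ so the
*marginal* event rate matches after integrating over providers. The
provider SDs $\tau = (0.15, 1.5, 0.3, 0.3)$ and residual SDs are the
package's own choices (such second-moment parameters are rarely published)
selected for realism and for the identifiability condition above.

What the generator deliberately does **not** emulate: administrative
record linkage, coded comorbidity structures, top-coding interactions with
payment categories (top-coding is available but off by default), survey
instruments, or missingness that depends on the unobserved outcome.
Passing tests on this generator therefore demonstrate that the estimator
recovers the data-generating process it assumes — not that any particular
real dataset satisfies those assumptions.

### Endogenous provider choice

The selection layer places providers on a jittered unit-square lattice and
patients uniformly; a patient chooses a provider by conditional logit with
utility
$\gamma_1 d + \gamma_2 d^2 + \gamma_3 d^3 + c\,\mathbf{1}(\text{closest})
+ \lambda\, u_i\, d$, where $u_i$ is an unobserved standard-normal
severity. With $\lambda > 0$, sicker patients are less deterred by
distance, travel further, and sort systematically across providers; the
same $u_i$ enters every latent outcome with loading $\delta_k$ (default:
half a residual SD in each dimension's adverse direction), so naive
provider effects are biased. Two geometry findings shaped the defaults:
fully random sites make the provider mean of the first-stage residual
confound severity sorting with local market density (the correction then
over-corrects in some geographies), while a perfectly regular lattice
removes the remoteness variation that generates sorting in the first
place. The jittered lattice sits between: enough remoteness variation for
confounding to exist, without extreme density clumps. The default
$\lambda = 16$ puts the provider-level bias at the order of $\tau$ — the
regime a correction method is for.

## Two-stage residual inclusion

Stage one is a conditional logit of choice on the distance polynomial and
the closest-alternative indicator (features constant within a choice set
drop out; providers under 30 patients are removed from every choice set
and their patients dropped, with a count). Distances enter raw: on the
unit square they are $O(1)$ and centring a polynomial would only change
the coefficient scale. The scalar generalised residual is
$r_i = 1 - \hat p_i(\text{chosen})$ — the choice-model probability mass on
alternatives the patient rejected; it is a documented convention, chosen
because the second stage tests $K$ coefficients on *one* residual per
patient. Stage two refits the multivariate model with $r_i$ in every
dimension and reports a posterior Wald statistic
$m'V^{-1}m \sim \chi^2_K$ for the $K$ residual coefficients. The
corrected provider posteriors come from the refitted model. Under no
confounding the test holds its nominal size and the correction is a no-op
in expectation; under confounding it reduces the RMSE of the provider
effects because the residual's provider mean tracks the severity sorting.

## Numerical choices

* Truncated-normal draws use the inverse-CDF with probabilities clamped to
  $[10^{-15}, 1 - 10^{-15}]$; adequate for the $|z| \lesssim 8$ regime of
  these models.
* Posterior covariances that fail a Cholesky factorisation are
  eigenvalue-clipped at a relative tolerance of $10^{-10}$ with a warning.
* `orthant_probability()` runs the quasi-Monte-Carlo integrator on a fixed
  internal RNG substream (restoring the caller's RNG state), so repeated
  calls are identical.
* One master seed drives everything; stage seeds are derived by a fixed
  linear map (`derive_seed()`), so any stage can be re-run in isolation
  and a full pipeline re-run is byte-identical.
* Problem sizes used by the test-suite experiments: the recovery benchmark
  runs 10 replicates of $J = 100$, $n_j = 100$ with 1500-iteration chains;
  the power study uses $n_j = 400$ with planted effects at $\pm 2\tau$
  (planted symmetrically, so the benchmark intercept is not dragged by the
  plants); the selection studies use $J = 16$, $n_j = 150$. These sizes
  were chosen as the smallest at which the phenomena of interest are
  clearly measurable.

## Known limitations

* The centred-parameterisation Gibbs sampler mixes slowly when a
  dimension's provider-level signal share is poor; the moment-based start
  mitigates but does not remove this. An interweaving (ASIS) update would
  be the next step if weakly identified designs became a target.
* Posterior means of correlations are boundary-skewed in weakly identified
  designs (intervals remain calibrated); medians would be less skewed but
  posterior means are reported for comparability with standard practice.
* The scalar first-stage residual cannot absorb confounding whose sign
  varies across providers (for example, attractiveness loadings of mixed
  sign interacting with severity); it targets patient-level confounders
  with a consistent direction.
* Frequentist (Huber–White) uncertainty for the correlation matrices is
  not implemented; posterior SDs play that role here, which is a
  different, model-based notion of uncertainty.
* Fixed-effects (dummy-variable) provider estimation, survival and count
  outcome families, multiple imputation for missing covariates, and
  marginal-rate-of-substitution-bounded dominance cones are out of scope.
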