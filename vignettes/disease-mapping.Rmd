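---
title: "Spatio-temporal disease mapping against deprivation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal disease mapping against deprivation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cancer registries report incident cases by small administrative areas
(census tracts) and year.  Populations per tract are small — a few hundred
people — so yearly case counts are mostly 0, 1 or 2, and crude rates are
extremely noisy.  The question of interest is ecological: after accounting
for the age structure of each tract and for residual spatial and temporal
variation, do tracts with higher socioeconomic deprivation have higher or
lower incidence?

`bymst` implements the full chain needed to answer that question on a
tract-by-year panel: a composite deprivation index, a hierarchical
spatio-temporal model of counts, Bayesian estimation with credible
intervals for quintile relative risks, and model-comparison criteria.  It
also ships a synthetic-data generator emulating a registry-scale study
(542 tracts, 14 years, 35–95% zero counts), so the whole pipeline can be
validated by parameter recovery without access to confidential registry
data.

## The deprivation index (DP2)

Sixteen tract-level census indicators are aggregated with Pena's distance
method.  Each indicator is oriented (larger = more deprived), standardized
by its population standard deviation, and measured as a distance from a
fictitious least-deprived tract holding every per-indicator minimum.
Indicators are ranked by the absolute correlation of each with the current
index and re-aggregated with correction weights $1 - R^2_k$, where $R^2_k$
is from regressing indicator $k$ on all higher-ranked indicators; the rank
/ re-weight cycle repeats until the ordering stabilizes.  The first-ranked
indicator always has weight exactly 1, and duplicated information is
weighted out ($1 - R^2 = 0$ for a perfectly collinear indicator).

Conventions the literature leaves open, fixed here and tested:

* the standardizing $\sigma$ is the *population* (divisor $n$) standard
  deviation across tracts;
* quintiles use the empirical 20/40/60/80 percentiles of the tract-level
  index, unweighted by population, with ties assigned to the lower
  quintile (a deterministic rule).  Whether a population-weighted quintile
  would be preferable is a real question for registry use, but the
  tract-level index is the covariate the model consumes, so tracts are the
  units here.

Quintile 1 (least deprived) is the reference category; the model sees four
dummies Q2–Q5.

## The model

For tract $i$ and year $t$, with observed cases $O_{it}$ and population
$Pob_{it}$:

$$\log \mu_{it} = \log Pob_{it} + \beta_0 + \sum_{j=2}^{5}\beta_j Q_{j,i}
 + \gamma_1 P4564_{it} + \gamma_2 P65M_{it}
 + \upsilon_i + S_i + \tau_t + \eta_{it}$$

The population enters as an offset on the *crude* rate rather than through
expected counts, and the two age-band shares ($45$–$64$ and $\geq 65$; the
under-44 share is omitted to avoid collinearity) enter as covariates.
Modeling crude rates with age covariates — instead of regressing an
age-standardized ratio on an unstandardized predictor — avoids the
"mutual standardization" bias of ecological regressions.  The quantities
of interest are $\exp(\beta_j)$, quintile relative risks versus Q1.

Four random effects absorb residual structure:

* $\upsilon_i$ — iid Gaussian heterogeneity, SD $\sigma_{het}$;
* $S_i$ — a Gaussian field on tract centroids with Matérn correlation
  $\rho(h) = \frac{1}{2^{\nu-1}\Gamma(\nu)}(\kappa h)^\nu K_\nu(\kappa h)$,
  smoothness fixed at $\nu = 1$, marginal SD $\sigma_{sp}$.  The scale
  $\kappa$ maps to the practical range $\sqrt{8\nu}/\kappa$, the distance
  at which correlation has dropped to $\approx 0.14$ ("almost nil"; the
  exact value for $\nu = 1$ is 0.1397, and the distance at which it
  reaches 0.10 is $3.21/\kappa$);
* $\tau_t$ — a first-order random walk (RW1) over years with increment
  precision $\tau_{rw}$;
* $\eta_{it}$ — the spatio-temporal interaction.  The structure of this
  term was an open choice; we use independent RW1 paths over time within
  each tract sharing a single precision $\tau_{int}$ (a Knorr–Held type-II
  interaction), the simplest structure consistent with independent
  increments in time.

Because the intrinsic RW1 is improper and the intercept would otherwise be
confounded with field levels, all four fields are constrained to sum to
zero ($\eta$ per tract path) — at simulation time by recentring, and at
estimation time by construction of the proposals (below).

Two RW1 density conventions coexist in the literature: the density of the
$n-1$ increments, $\frac{n-1}{2}\log\frac{\tau}{2\pi} - \frac{\tau}{2}
\sum_t (x_{t+1}-x_t)^2$, and the generalized (pseudo-determinant) GMRF
density with precision $Q = \tau R$, which adds the constant
$\tfrac12\log\mathrm{pdet}(R) = \tfrac12\log n$.  They differ only by that
constant, which cancels in every MCMC ratio; `rw1_logdensity()` exposes
both via its `normalization` argument so each can be verified against its
own oracle.

## Observation families

* **Poisson**: $O_{it} \sim \mathrm{Poisson}(\mu_{it})$.
* **Zero-inflated Poisson (ZIP)**: with probability $p_0$ a structural
  zero, else Poisson.  Motivated by the zero-excess diagnostic: under a
  Poisson model the expected zero share is
  $\overline{\exp(-\mu_{it})}$ (`expected_zero_fraction()`), and registry
  counts can show far more zeros than that (the package's ZIP test-bed
  reproduces a ~39.5% observed vs ~13.5% expected gap at $p_0 = 0.3$,
  $\lambda = 2$).  $p_0$ is a single constant with a Uniform(0,1) prior;
  no covariate structure is placed on the mixing weight.
* **Bernoulli**: for very rare outcomes the response is dichotomized to
  "at least one case".  The link was an open choice (the dichotomization
  only requires *a* binomial model); we use the complementary log-log link
  with the population offset retained, $P(y_{it}=1) = 1 -
  \exp(-\mu_{it})$, because it makes the event probability exactly the
  Poisson at-least-one-case probability, so $\exp(\beta)$ keeps its
  rate-ratio interpretation and RR tables remain comparable across
  families.

## Inference

The original methodology in this literature uses deterministic
Laplace-type approximations with a finite-element Matérn representation;
at desk scale ($n \le$ a few hundred tracts) dense linear algebra is exact
and affordable, so `bymst` targets the same posterior by MCMC instead,
where every step can be checked against independent oracles:

* fixed effects: scalar adaptive random walks on covariate-centred
  parametrization (the intercept is reported back on the original scale);
* $\upsilon$, $S$, $\tau_t$: joint block proposals shaped by the prior
  ($S$ proposals are whitened by the Cholesky factor of the Matérn
  correlation) and *recentred to mean zero*, so the sum-to-zero
  constraints hold exactly at every iteration; prior densities for the
  constrained proper fields use the $(n-1)$-power normalization of the
  conditioned Gaussian;
* $\eta$: per-tract recentred RW1 proposals accepted independently per
  tract (valid because both the likelihood and the interaction prior
  factorize over tracts);
* $\tau_{rw}, \tau_{int}$: conjugate Gamma Gibbs updates on the increment
  quadratic forms;
* $\sigma_{het}, \sigma_{sp}, \kappa$: log-scale random walks ($\kappa$
  updates re-factorize the $n \times n$ correlation matrix — cheap at this
  size); $p_0$: logit-scale random walk;
* proposal scales adapt by Robbins–Monro toward 0.44 (scalar) / 0.234
  (block) acceptance during burn-in only, then freeze, so the retained
  chain is a valid Markov chain.

Priors (unstated in the motivating literature; weakly informative,
configurable via `prior_control()`): Normal(0, $10^2$) on $\beta_0$,
$\beta$, $\gamma$; half-Normal(0, 1) on $\sigma_{het}$, $\sigma_{sp}$;
Gamma(1, $5\times10^{-5}$) on $\tau_{rw}$, $\tau_{int}$; log-Normal on
$\kappa$ centred so the prior median practical range is half the domain
diameter, log-SD 1; Uniform(0,1) on $p_0$.

Defaults are 10 000 iterations, 5 000 burn-in, thinning 2, 3 chains — all
configurable, and the test suite runs shorter chains documented as such.
Numerical guards: a proposal is rejected if any $|\log\mu_{it}| > 30$
(count overflow), and a non-finite posterior ratio aborts with the
offending component named.  Diagnostics: split potential-scale-reduction
(exactly 1 for identical stationary chains by construction of the
pooled/within variance ratio) and Geyer initial-monotone effective sample
sizes, with a warning at $\widehat R > 1.05$.

Summaries follow the reporting conventions of the field: posterior mean of
$\exp(\beta)$ (not $\exp$ of the mean), equal-tailed 95% credible
intervals, a quintile flagged "significant" when its interval excludes 1,
and posterior means for the random-effect SDs ($\sigma_{het}$,
$\sigma_{sp}$ for the proper fields; the empirical path SDs for the
intrinsic RW1 terms, whose precision is not an SD).

## Model comparison

* **DIC**: $\bar D$ is the posterior mean deviance; the plug-in $D(\bar\theta)$
  evaluates the deviance at the posterior mean of *all* parameters, latent
  fields included (a literal reading of "deviance at the posterior mean of
  the parameters"; plug-ins that integrate out the fields would penalize
  differently); $p_D = \bar D - D(\bar\theta)$ and
  $\mathrm{DIC} = D(\bar\theta) + 2 p_D$.  For the ZIP family the deviance
  uses the full mixture likelihood including $p_0$, keeping $D$ comparable
  across families.
* **CPO / cv.ls**: leave-one-out predictive densities estimated from the
  single MCMC run by the harmonic-mean identity
  $CPO_i = [\frac1S \sum_s 1/p(y_i|\theta_s)]^{-1}$, computed in log space;
  $\mathrm{cv.ls} = -\mathrm{mean}(\log CPO_i)$.  Harmonic means can be
  unstable, so rows whose weights have relative Monte Carlo error above
  10% are flagged rather than silently trusted, and a zero per-draw
  likelihood surfaces as $CPO_i = 0$ with an explicit warning.  Lower DIC
  and lower cv.ls both indicate the preferred model.

## The synthetic world

The generator states one fixed world; its defaults are not tuned to test
outcomes:

* 542 tracts × 14 years (1993–2006) on a 50 km square with uniform
  centroids and Euclidean distances (real census geography, migration and
  age-period-cohort structure are out of scope);
* generating fixed effects: quintile RRs 0.8592, 0.8129, 0.7315, 0.5768
  and age coefficients 3.8208, 2.4520 — the reported effect scale this
  package is meant to recover;
* random-effect scale matched to reported values: $\sigma_{het} = 0.0295$,
  $\sigma_{sp} = 0.0956$, temporal path SD $\approx 0.03$
  ($\tau_{rw} = 1100$), interaction path SD $\approx 0.002$
  ($\tau_{int} = 2.5\times10^5$), practical range 20 km;
* the per-tract population scale is nowhere stated in the motivating
  study; the only published constraint is the share of zero tract-years
  (54.5% for the male study population).  We chose log-normal populations
  with median 600 and log-SD 0.4 — the scale implied by ~340 000 males
  over 542 tracts — and intercept $\beta_0 = -8$, which puts the crude
  rate near $10^{-3}$ cases/person-year and the zero share near 55%,
  inside the 40–70% acceptance band.  This was fixed once, from these
  demographic considerations, before any acceptance measurement;
* sixteen indicators are one smooth latent deprivation field plus noise,
  half stored sign-reversed to exercise orientation handling.

The model-selection study (`model_selection_study()`) deviates from this
world in three deliberate ways.  Quintile labels are randomized across
tracts: a spatially smooth deprivation index is absorbed by the Matérn
field of the no-quintile model, so the nested comparison would measure
spatial confounding rather than the criteria's ability to detect a real
effect.  Effects are enlarged to about three posterior SDs each (log-RRs
−1.0 to −2.5 at 40 tracts × 6 years), the regime in which DIC and cv.ls
are expected to agree.  And with the age terms dropped the intercept is
raised to −6.7 so the baseline crude rate stays at the world's
~10⁻³/person-year (without this the panel carries almost no cases and no
criterion can distinguish anything).

What a green recovery test establishes: that the full pipeline —
generator, DP2, quintile coding, sampler, summaries — estimates the
quintile effects without systematic bias and with approximately calibrated
intervals *when the data are generated by the model being fitted*.  It
does not establish robustness to real-data violations (irregular
geography, demographic drift, covariate-dependent zero inflation,
misspecified interaction structure), none of which the generator emulates.

### A known limitation: ordering of point estimates at small size

One acceptance property asks that the posterior-mean log-RRs decrease
strictly across quintiles in at least 90% of replicates at 60 tracts × 8
years.  At that size the posterior SE of each log-RR is about 0.2 (roughly
60 expected cases per quintile within the zero-share band), while the
generating gaps between adjacent quintiles are 0.055, 0.106 and 0.237.
The probability that three noisy differences with those means are all
negative is roughly $\Phi(0.30)\Phi(0.58)\Phi(1.3) \approx 0.4$ under
independence, and lower still because adjacent differences share a
coefficient with opposite signs; the acceptance run measures a monotone
share in the 0.2–0.5 range.  No estimator of these
coefficients can satisfy the 90% requirement in this world — the
*direction* of the gradient is recovered, the strict ordering of four
point estimates is not identifiable at this information level.  We report
the criterion honestly rather than enlarging populations beyond the stated
zero-share band or weakening the test.

## Numerical choices

* Matérn covariances are dense with Cholesky factorization; a diagonal
  jitter starting at $10^{-10}$ escalates tenfold at most six times before
  failing loudly.
* $\log O!$ uses `lgamma` throughout; ZIP zero terms and the cloglog
  Bernoulli log-probabilities are computed with `log1p`/`expm1` guards.
* DP2 convergence: ordering stability or maximum index change below
  `tol` ($10^{-8}$); non-convergence reports the last two orderings.
* Quintile ties break downward, making assignments reproducible.
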