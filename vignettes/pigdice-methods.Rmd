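---
title: "Models and methods behind pigdice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pigdice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In the 'pig' dice game a player accumulates rewards over a sequence of die
rolls — each winning face adds ten times its pips to the round's cumulative
sum — and after every winning roll chooses to *stop* (cash in the sum) or
*continue* (roll again, risking the whole sum on a losing face). The game is
a laboratory model of sequential decisions under risk: the cumulative sum is
the *switch value* (what stopping is worth), while the *choice conflict* — how
hard the decision feels — peaks where stopping and continuing are equally
attractive and falls off on both sides. Because most play happens below that
indifference point (IP), the two quantities are almost perfectly correlated
in the standard game, which is what makes their neural and behavioral
signatures so hard to tell apart. Raising the loss probability from 1/6 to
2/6 or 3/6 pulls the IP down and rebalances the design.

`pigdice` implements the full computational chain for studying this problem:
a generative task and agent simulator, hierarchical Bayesian choice and
response-time regressions with IP and conflict estimation, and a family of
19 diffusion decision models (DDMs) with trial-wise parameter modulation
compared by WAIC. Human data for this task are not publicly deposited, so
the simulator doubles as the package's data source: every analysis is
exercised on synthetic data whose generating truth is known.

# Expected-utility agents and indifference points

An agent with risk curvature $\alpha$ values a sum $s$ as $s^\alpha$. With
mean winning face $\bar Z$ (4, 4.25, 4 in the 1/6, 2/6, 3/6 conditions),
reward multiplier 10 and loss probability $p$:

$$EU_{stop} = s^{\alpha}, \qquad
  EU_{continue} = (s + 10\bar Z)^{\alpha}\,(1 - p).$$

Choices are softmax in the utilities with sensitivity $\theta$:
$p(stop) = 1 / (1 + e^{\theta (EU_{cont} - EU_{stop})})$. The IP solves
$EU_{stop} = EU_{continue}$; for $\alpha = 1$ it is $10 \sum_{\text{win}} z
/ |\text{losing faces}|$, evaluated in integer arithmetic so the three
standard conditions give exactly 200, 85, and 40 points. For general
$\alpha$ the closed form $10\bar Z / ((1-p)^{-1/\alpha} - 1)$ is used; a
bisection oracle in the test suite confirms it.

**Tie handling.** Rewards move on a 10-point grid, so whenever an agent's IP
is itself a multiple of 10 (all risk-neutral agents) a non-negligible share
of decisions happens *exactly at* the IP, where $p(stop) = 1/2$ and neither
side is privileged. `fraction_past_ip()` therefore attributes that atom half
to each side. This makes the statistic continuous in $\alpha$ and reproduces
the reported simulation benchmarks; counting ties strictly below (or above)
the IP shifts the single risk-neutral agent's 1/6 fraction by about −1.2
(+1.2) percentage points and leaves heterogeneous populations untouched,
since their IPs are irrational almost surely.

**Timing.** Sessions are time-limited, so the simulator charges each screen
event its experimental duration: a die animation drawn uniformly from the
1.5–3.75 s grid in 150 ms steps, 2 s outcome display (which contains the 2 s
response window), 2 s loss display, 2.5 s cash-in display. The agent
simulations specify no response-time process, so a decision consumes the
full response window; this choice only scales how many decisions fit into a
session, not where they fall relative to the IP. Sessions may end mid-round,
and the partial round's decisions count.

**Populations.** `population_spec()` draws $\alpha$ and $\theta$ as softplus
transforms of normals — location 0.5 and scale 0.3 for $\alpha$ (mean
$\approx 1$, risk-neutral on average), location −1.5 and scale 0.3 for
$\theta$ (mean $\approx 0.2$). The risk-averse preset solves the softplus
location numerically so the mean is exactly the requested value (only the
population mean is specified in the source material). The defaults are the
study conditions: 100 agents and 20 simulated minutes per condition for
population summaries, 120 minutes for the single-agent benchmark.

What the generator does *not* emulate: learning or fatigue across rounds
(agents are stationary), lapses and fast guesses, and any dependence of
preferences on condition order. Passing tests therefore demonstrate that the
estimators recover the models they assume, not that those models capture
every feature of human play.

# The choice model

`fit_choice_model()` is a hierarchical Bayesian logistic regression of the
decision on the cumulative sum, fit per condition within one joint model:

$$p(stop)_t = \text{logistic}(\beta_0 + \beta_1 \Sigma_t), \qquad
  \beta_{ij} \sim N(\mu_{\beta_i}, \sigma_{\beta_i}),$$

with hyper-priors $\mu_{\beta_0} \sim \text{Cauchy}(0,5)$,
$\sigma_{\beta_0} \sim \text{HalfCauchy}(0,1)$, $\mu_{\beta_1} \sim
\text{Cauchy}(0,1)$, $\sigma_{\beta_1} \sim \text{HalfCauchy}(0,0.5)$,
duplicated per condition. Two modeling choices deserve a note:

* **Orientation.** The regression is written for $p(stop)$, so the slope is
  positive when stopping becomes likelier with reward — matching the sign of
  every reported coefficient. The IP $= -\beta_0/\beta_1$ is identical under
  either orientation.
* **Raw covariate scale.** The cumulative sum enters in points (no
  standardization), keeping slopes interpretable per point (magnitudes of
  order 0.03–0.14 across conditions).

Sampling runs in JAGS (2 chains × 2000 iterations, first half discarded, by
default). Internally the sampler works with the exactly equivalent centered
pair $(u, \beta_1)$, $u = \beta_0 + \bar\Sigma \beta_1$, whose conditional
prior $u \mid \beta_1 \sim N(\mu_{\beta_0} + \bar\Sigma\beta_1,
\sigma_{\beta_0}^2)$ reproduces independent normal populations on
$(\beta_0, \beta_1)$ while removing the intercept–slope ridge that cripples
univariate samplers on an all-positive covariate. Participants lacking at
least one stop and one continue decision in a condition are inestimable and
are excluded from the hierarchy with a logged reason.

Derived quantities: the per-draw group IP; trial conflict $cc_t = |\beta_1|
p_t (1-p_t)$ (the derivative of the fitted curve, maximal at the IP,
evaluated at posterior-mean participant coefficients); Spearman correlations
of conflict with the cumulative sum per participant (the collinearity
diagnostic); the odds ratio $e^{\text{mean slope}}$; and a Bayesian $R^2$
computed per draw on the probability scale as explained variance over
explained variance plus expected Bernoulli noise,
$\mathrm{var}(p) / (\mathrm{var}(p) + \overline{p(1-p)})$ — the
variance-decomposition definition, stated here because the source only cites
it.

# The response-time model

`fit_rt_model()` regresses $\log RT$ on round number, within-round decision
number, cumulative sum, and (optionally) the trial conflict from the choice
model, with normal residuals and the same hierarchical structure
(intercept hyper-priors Cauchy(0,10)/HalfCauchy(0,5), slopes
Cauchy(0,5)/HalfCauchy(0,5)). The residual scale gets a HalfCauchy(0,1),
a standard weakly-informative choice for log-second residuals; the source
states no residual prior. Round and decision numbers enter 1-based and
untransformed. Conflict is estimated first and plugged in (two-stage), not
jointly sampled.

The conflict regressor is optional for a reason: conflict and cumulative sum
compete for the same variance, and the headline sign question — does the
reward-sum coefficient turn negative when the design puts many decisions
past the IP? — is posed for the three-regressor model (the coefficient
displays show round, decision number, and cumulative sum). With conflict in
the model, the conflict term absorbs the non-monotonicity and the reward
coefficient shrinks toward zero; both variants are available.

Decisions terminated by a rolled loss carry no response (the window never
opens), so such rows are excluded from RT fits; the softmax agent simulator
produces no RTs at all, and RT analyses are exercised on DDM-generated data.
`post_ip_rt_slopes()` complements the hierarchical fit with per-participant
OLS slopes of raw RT on the cumulative sum restricted past the IP, and
`rt_posterior_predictive_by_pstop()` buckets decisions by fitted stop
probability to compare replicated and observed mean RTs, with the focused
maximum-conflict (p ≈ .5) versus maximum-certainty (p ≈ 1) contrast.

# The diffusion model family

Joint choice/RT data are modeled with the four-parameter Wiener diffusion
(no across-trial variability parameters): evidence accumulates at drift
$d_t$ between boundaries 0 and $A_t$ starting at relative point $z_t$, and
"stop" maps to the upper boundary. Task variables enter through links:

$$d_t = \delta_0 + \delta_1 x_t, \qquad
  A_t = \log(1 + e^{\delta_0 + \delta_1 x_t}), \qquad
  z_t = \Phi(\delta_0 + \delta_1 x_t),$$

where $x_t$ is the cumulative sum or the decision number. The model space
crosses drift modulator (cumulative sum or decision number) with threshold
and start modulators (none or either covariate) and adds a fully fixed
baseline: 19 variants. The drift IP $-\delta_0/\delta_1$ is the value where
evidence favors neither response; at a centered start the model-implied
$p(stop)$ there is exactly one half and the expected decision time is
maximal — the model-embodied conflict signature.

**Likelihood.** The Wiener first-passage density is evaluated by the
standard pair of series expansions with the term counts chosen per
evaluation from their error bounds at truncation tolerance $10^{-7}$
(configurable), switching automatically between the small-time and
large-time regimes. The lower-boundary density is the primitive; the upper
boundary evaluates it under $(v, w) \to (-v, 1-w)$, an identity the test
suite asserts directly (it is also why negating the drift for "continue"
trials, as the fitting recipe is sometimes written, is the same
computation). Boundary probabilities use the closed form
$(1 - e^{-2vaw})/(1 - e^{-2va})$.

**Sampling trial data.** `rwiener_trials()` draws the boundary from its
analytic probability and the first-passage time by inverse CDF on a
quadratically spaced grid (512 points, extended geometrically until the
conditional mass is covered) — exact in distribution up to grid
interpolation. An independent small-step Euler–Maruyama walk
(`step = 1e-4`) serves as the Monte-Carlo oracle against which density and
sampler are validated; it shares no code with the series density.

**Hierarchical fitting.** Each condition gets its own parameter set and
hyper-parameters. Participant coefficients are normal around group means;
hyper-priors are Normal(0,10)/HalfNormal(0,10) for drift, threshold, and
non-decision time, Normal(0,0.8)/HalfNormal(0,0.5) for the starting point.
The non-decision time is hard-bounded to $[0,\ 0.99 \times \min RT_j]$ per
participant; following the common convention for bounded DDM parameters the
bound acts as an indicator on the joint prior (no hyper-parameter-dependent
renormalization), which keeps the group mean identified by the coefficients
themselves.

No pre-installed sampler speaks this likelihood, so fitting uses the
package's own adaptive Metropolis-within-Gibbs: component-wise random-walk
updates on participant coefficients (proposal scales tuned to 44%
acceptance during warmup), random-walk updates on group means and log
scales, plus two *ridge moves* per intercept/slope pair — a participant-level
shear (slope $+\delta$, intercept $-\delta \bar x_j$) and a group-level
shear moving all participants and the group means together. The shears
follow the likelihood ridge created by all-positive covariates and are what
makes the group-level slope posteriors mix (R-hats drop from ~3 to <1.2 at
equal cost). Defaults mirror the source recipe (4 chains × 8000, 7000
warmup); the packaged tests use 2 chains × ~1000–2500 iterations, which the
recovery checks show is adequate at their problem sizes.

**Model comparison.** `waic()` computes
$-2\sum_i[\log \overline{e^{\ell_i}} - \mathrm{var}(\ell_i)]$ over pointwise
log-likelihoods with SE from the trial-wise dispersion scaled by $\sqrt n$;
`compare_ddm_variants()` ranks variants and flags those whose WAIC
difference from the best does not exceed the paired difference SE ("not
credibly worse"). Posterior predictives replicate datasets from retained
draws and summarize mean RT by model-implied stop-probability bin, plus
per-participant fractions of decisions past the DDM-derived IP.

# Pipeline, gates, and exclusions

`run_pipeline()` wires the stages together (simulate → exclusions → choice →
RT → DDM → WAIC → reports) with one seed for every stochastic stage, a
plain-text log, and CSV outputs. Exclusions drop participants with under 5%
of either response type or more stops than continues at round beginnings
("beginning" defaults to the first decision of a round — the source does not
define the window, so it is configurable). Convergence gates require all
R-hats below 1.05 and, for samplers that report them, divergences and
treedepth saturation at or below 1%; the Gibbs/Metropolis samplers used here
report zero for both. A failed gate halts downstream stages unless
overridden.

# Problem sizes and limitations

The packaged tests and acceptance checks run at deliberately modest sizes
chosen to exercise every claim while keeping a full run in the minutes
range: populations of 10–100 agents, 2–20 simulated minutes per condition
(120 for the single-agent benchmark), DDM recovery at 20 participants × ~200
trials with 2 × 2500-iteration chains, model recovery at 10 × 120 with
2 × 1200, and a 10⁵-walk oracle per parameter set. At these sizes group-level
drift coefficients are recovered within their 95% HDIs and the generating
DDM variant wins the WAIC comparison in the large majority of repetitions;
individual-participant coefficients in near-separated logistic cells mix
more slowly and can flag R-hats between 1.05 and 1.3 at test-scale chain
lengths.

Known limitations: the empirical quantities reported for the human
experiments (group HDIs, Spearman summaries, printed WAICs) are not
reproducible without the undeposited data — the package substitutes
parameter-recovery and model-recovery evidence on its own generators; RT
residuals are homoskedastic log-normal by design; and the DDM sampler, while
validated on this model family, is a special-purpose tool rather than a
general probabilistic-programming backend.
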