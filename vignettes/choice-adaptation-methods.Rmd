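---
title: "Models and methods: memory, learning, and adaptation in dynamic risky choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: memory, learning, and adaptation in dynamic risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choiceadapt)
```

## The task

An agent chooses 100 times between two unlabeled options. The *reference*
option is safe: it pays 250 points with certainty (in the risky-vs-risky
variant it is instead a static 0/500 gamble at p = .50). The *dynamic*
option pays 500 or 0 points; its high-outcome probability is either
constant at .50 (static), rises linearly from .01 on trial 1 to 1.00 on
trial 100 (increasing), or is the mirror of that (decreasing). Feedback is
*partial* (only the chosen option's outcome is shown) or *full* (the
foregone outcome is shown too).

The two dynamic schedules cross the safe option's expected value midway:
before the crossing the risky option maximizes expected value in the
decreasing condition and the safe option in the increasing condition, and
after it the roles swap. Adaptation is measured as the *maximization rate*
— the proportion of choices of the higher-EV option — in the first period
(trials 1–50), second period (51–100), and the last 30 trials.

Two boundary conventions matter and are applied consistently:

* the increasing schedule ties exactly (p = .50) at trial 50; per-trial
  queries (`maximizing_option()`) return no maximizing option there, but
  period-level rates give the trial Period 1's label, so Period 1 rates use
  a full 50-trial denominator;
* the mirror decreasing schedule ties at trial 51 (1.01 − .01·51 = .50).
  No standard convention covers it, so it is left undefined and excluded
  from denominators and curves. (The mirror schedule cannot put the tie at
  trial 50 in both directions; we keep the stated endpoints and step size,
  accepting p = .51 at trial 50 when probabilities fall.)

## The instance-based learning model

Choice is driven by memory for individual outcome experiences. Option
*j*'s outcome *i* has activation at trial *t*

$$A_{j,i,t} = \sigma \ln\!\frac{1-\gamma_{j,i,t}}{\gamma_{j,i,t}}
  + \ln \sum_{t_p} (t - t_p)^{-d},$$

where the sum runs over the past trials on which that outcome was observed
for that option, $d \ge 0$ is the memory-decay exponent (high $d$ = strong
recency), $\sigma \ge 0$ scales logistic retrieval noise, and
$\gamma_{j,i,t}$ is a fresh Uniform(0,1) draw per option, outcome and trial.
Within an option, outcomes are retrieved with probability
$\propto e^{A/\tau}$ with $\tau = \sigma\sqrt{2}$ (computed with
max-subtraction; $\tau = 0$ is treated as the hard-argmax limit with
uniform tie splitting). The option's *blended value* is the
retrieval-weighted mean of its outcomes, and the agent deterministically
chooses the option with the higher blended value, breaking exact ties with
a fair coin. Under full feedback each trial stores two instances — the
obtained and the foregone outcome.

**Cold start.** The first choice is undefined with empty memory, so each
option is prepopulated with one pseudo-instance of 500 points (the
`default_outcome`) at pseudo-trial 0, removed permanently at the option's
first real instance. The optimistic value induces early exploration of both
options, the standard device in instance-based-learning practice; it is a
configuration knob and is recorded in fit metadata.

**Predictions for fitting.** The choice rule is deterministic but the
activations are stochastic, so per-trial choice probabilities are estimated
by simulation: memory is rebuilt from the participant's own experienced
history (*yoked* one-step-ahead prediction), and the choice the model would
make at each trial is simulated `n_sims` times over fresh noise draws; the
prediction is the fraction choosing the dynamic option, with exact
blended-value ties (reachable only at $\sigma = 0$) counted as one half —
the expectation of the tie-breaking coin. Predictions are clipped to
$[1/(2\,n_\text{sims}),\ 1 - 1/(2\,n_\text{sims})]$ so the log-likelihood
stays finite; the floor equals half the Monte-Carlo resolution. A
free-running variant (`predict_ibl(mode = "free")`), in which the model
generates its own history, is available for illustration but is not used
for likelihoods, which require predictions conditioned on what the
participant actually experienced.

## The reinforcement-learning models

Both models track a scalar expectancy $E_j$ per option and choose by
softmax, $P(j) = e^{\theta E_j} / \sum_k e^{\theta E_k}$:

* **delta rule** — $E_{j,t} = E_{j,t-1} + \delta_{j,t}\,\phi\,(r_{j,t} -
  E_{j,t-1})$, with learning rate $\phi \in [0,1]$; only updated options
  ($\delta = 1$) move, by a fixed fraction of the prediction error;
* **decay rule** — $E_{j,t} = d_{RL}\,E_{j,t-1} + \delta_{j,t}\,r_{j,t}$,
  with $d_{RL} \in [0,1]$; every expectancy decays multiplicatively and
  updated options gain the reward. Low $d_{RL}$ means strong recency.

Under full feedback both options carry $\delta = 1$ every trial, so the
expectancy trajectories — and hence the predicted probabilities — are
identical for any choice sequence given the same outcome stream (a property
the test suite asserts).

Numerical conventions, all configurable and recorded in fit metadata:
initial expectancies $E_{j,0} = 0$; payoffs divided by `outcome_scale`
= 500 before updating, so expectancies are O(1) and $\theta$ is
interpretable on a common scale; $\theta$ capped at 20 on that scale (a
softmax at $\theta = 20$ over unit-scale value differences is already
effectively deterministic).

## Fitting

Everything is individual-level maximum likelihood on the Bernoulli
likelihood of the observed dynamic/reference choices.

**IBL: grid search.** The likelihood surface is evaluated on a rectangular
$(d, \sigma)$ grid over $(0,5) \times (0,3)$. One noise stream is drawn per
participant and reused at every grid point (common random numbers), which
makes the Monte-Carlo surface smooth in the parameters and the whole fit
bitwise-reproducible from its seed; ties break toward smaller $d$, then
smaller $\sigma$. The working default is a 0.1 step with 200 simulated
predictions per trial; `grid_spec(profile = "exhaustive")` selects the
full 0.01-step grid with 1,000 predictions per trial (roughly three orders
of magnitude more computation).

**RL: multi-start simplex.** Start points come from a Latin-hypercube
design over the bounded box; Nelder–Mead runs in transformed coordinates
(logit for $\phi$ or $d_{RL}$, log for $\theta$, with the $\theta$ cap
applied inside the objective) and the best of the starts is mapped back.
The default is 25 starts; the recovery analyses below use 10, which pilot
runs showed is already past the point where additional starts change the
optimum for this smooth two-parameter likelihood.

## Synthetic cohorts

`generate_cohort()` creates participants with known ground truth:
per-participant generating model and parameters are drawn from declared
priors, and the matching simulator produces the trial stream. The default
priors place agents in the regimes fitted human cohorts occupy: $d \sim$
LogNormal(log 0.8, 0.6) truncated to (0,5); $\sigma \sim$ U(0.05, 1.5);
$\phi \sim$ Beta(1.5, 4); $d_{RL} \sim$ Beta(5, 1.5); $\theta \sim$
LogNormal(log 3, 0.5) for the delta rule and LogNormal(log 1, 0.6) for the
decay rule. The decay rule gets the lower $\theta$ center because its
steady-state expectancies, $r/(1-d_{RL})$, are several times larger than
the delta rule's (which stay convex combinations of scaled rewards): with a
shared $\theta$ scale a third of decay agents become pure perseverators
choosing one option on essentially every trial, behavior outside the range
real cohorts show. After the recalibration about 12% of decay agents
remain near-deterministic and the interquartile range of risky-choice
proportions is roughly .41–.60, comparable to observed cohorts.

What the generator emulates: the design cells, payoff schedules, feedback
regimes, and model-driven individual differences. What it does not:
awareness and strategy shifts, attention lapses, position biases,
free-text-codeable insight, or any within-participant model switching.
Passing recovery tests therefore show the pipeline identifies parameters of
agents that truly follow one of these models — not that humans do.

## Study conditions used by the checks

The test suite and `scripts/acceptance.R` run, at fixed problem sizes
chosen as the package's standard conditions:

* *Parameter recovery*: 40 agents per RL rule (10 per dynamic cell) and 20
  IBL agents (full feedback), 100 trials each; IBL fitted on a 0.25-step
  grid with 200 simulations per trial; recovery summarized by Spearman
  correlation between generating and recovered parameters.
* *Directional adaptation*: 500 agents per condition simulated at the
  fitted partial-feedback decay medians (d = 1.39 falling vs d = 0.60
  rising probabilities). No reference value pins down the matching noise
  level, so $\sigma$ = 0.25,
  the conventional activation-noise value in ACT-R modeling.
* *Generalization*: 200 calibration pairs drawn from the IBL priors, median
  split on $d$, 500 simulated agents per group in full-feedback test
  environments of both directions; the high-recency group's mean
  second-period maximization should exceed the low-recency group's.

The full-feedback choice for the generalization check is deliberate: in the
partial-feedback increasing environment synthetic pools sit at a floor
(mean second-period maximization below .01 for both groups) because agents
that abandoned the risky option early never observe its improvement — the
hot-stove asymmetry — leaving no room for a recency effect to register.

## Known limitations

* Recovery of $\phi$ and $d_{RL}$ is intrinsically noisy: generating draws
  with low $\theta$ (or very low $\phi$) produce near-chance choice
  sequences whose likelihood is flat in the recovery parameter, so those
  agents' fitted values are arbitrary and the cohort-level Spearman
  correlation fluctuates across cohort draws (roughly .35–.85 for $\phi$ in
  pilot runs). This is a property of maximum likelihood on uninformative
  data, not of the optimizer — additional starts do not change the fits.
* The default IBL grid (step 0.1) bounds parameter resolution at the grid
  step; the exhaustive profile removes this at substantial cost.
* The mirror decreasing schedule cannot reproduce a .50 probability at
  trial 50; see the boundary conventions above.
* Monte-Carlo likelihoods are clipped, so reported NLLs are bounded above;
  comparisons between models with very poor fits compress near the bound.
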