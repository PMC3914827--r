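---
title: "Recursive theory-of-mind agents and the evolution of strategic sophistication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recursive theory-of-mind agents and the evolution of strategic sophistication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Theory of mind (ToM) — attributing beliefs and intentions to others in order
to predict what they will do — is naturally graded by recursion depth: "I
think that you think that I think ...". `ktom` asks what depth of recursion
natural selection would favour, by (i) building learning agents whose only
difference is the depth of their recursive model of the opponent, (ii)
measuring how every phenotype pair fares in iterated competitive and
cooperative 2x2 games, and (iii) feeding the resulting expected payoffs into
replicator dynamics to find the evolutionarily stable phenotype mixtures as
a function of the proportion of cooperative encounters (`omega`) and the
number of game iterations (`tau`).

## Agents

All phenotypes share one decision rule: the softmax policy
`P(a = 1) = sigmoid((E[U(1)] - E[U(0)]) / beta)`, where the expectation is
taken over the agent's current prediction of the opponent's next action and
`beta` is an exploration temperature. Phenotypes differ only in how that
prediction is formed.

**0-ToM** treats the opponent's choice probability as a hidden log-odds
`x_t` drifting across trials as a Gaussian random walk with volatility
`sigma`. Its posterior N(mu, Sigma) is advanced by a variational (Laplace)
step: the predictive variance inflates by `sigma`, the mean moves along the
prediction error `o_t - sigmoid(mu)` with a step size set by the inflated
variance, and the variance contracts by the Bernoulli curvature. As
`sigma -> 0` this reproduces fictitious play: the posterior mean tracks the
opponent's empirical choice frequency.

**k-ToM** (k >= 1) adopts the intentional stance recursively: it assumes the
opponent is a k'-ToM agent for some k' < k, with unknown parameters. It
maintains

* a posterior `lambda` over the candidate levels 0..k-1,
* per candidate level, a Gaussian posterior on the opponent's hidden
  parameters `theta = (log-volatility, log-temperature)` (log transforms
  keep both positive; the prior is standard normal), and
* per candidate level, a live simulant of that level, run from the
  opponent's seat (the simulant observes *my* actions as its opponent's).

Each trial, the probability `s_k'` that a level-k' opponent would play
action 1 is computed from the simulant's state, marginalised over the
parameter posterior with the moment-matched sigmoid
`E[sigmoid(x)] ~ sigmoid(mu / sqrt(1 + (3/pi^2) v))`. The level posterior is
updated by Bayes' rule on the Bernoulli likelihood of the observed action;
the parameter posteriors take a natural-gradient step in which the
prediction error `o_t - s_k'` is propagated through the gradient of `s_k'`
with respect to `theta` and weighted by the level posterior; and every
simulant is advanced one trial with roles swapped. The agent's own
prediction is the `lambda`-mixture of the per-level predictive
probabilities. The recursion bottoms out at 0-ToM, so constructing a k-ToM
agent allocates `2^k` nested belief objects.

Two further phenotypes serve as non-mentalising controls: a
Rescorla-Wagner **reinforcement learner** (action values updated by
`q <- q + alpha (r - q)`, softmax choice), and a **Nash** player that plays
the analytic mixed equilibrium of the stage game on every trial.

### Numerical choices

* *Gradients.* The per-level action probability depends on the hidden
  parameters both directly (temperature) and through the simulant's
  prediction (volatility). Gradients are central finite differences with
  step `1e-4`, taken through the candidate opponent's last-step prediction
  only. This gives an implementation-independent contract (and a test
  oracle for any later analytic version). For level >= 1 simulants the
  last-step prediction does not depend on the volatility estimate, so that
  gradient component is exactly zero.
* *Marginal likelihoods.* The level posterior is updated with the
  parameter-marginal predictive probability (the moment-matched integral
  over the Gaussian posterior), not the plug-in probability at the
  posterior mean. This is both closer to exact Bayes and numerically
  gentler: plug-in probabilities saturate at low temperature and a single
  surprising action would then annihilate a level irreversibly.
* *Volatility inflation at prediction.* Predictive quantities always add
  the drift variance `sigma` to the stored posterior variance, mirroring
  the 0-ToM update; stored variances therefore remain posterior variances.
* *Degenerate ties.* Policies never return exactly 0 or 1 for finite
  `beta`, so action sampling needs no tie rule. Thresholded predictions
  (the "right half of the time" metric) break exact 0.5 ties with a fair
  coin drawn from a stream derived from the record's seed.
* *Underflow.* If all level likelihoods vanish numerically in one update,
  the previous level posterior is retained for that trial.

### Default parameters

All defaults live in `inst/extdata/defaults.yaml`, not in code:
`log(sigma) = -1` (volatility prior, all Bayesian phenotypes),
`beta = 0.1` (all phenotypes), RL learning rate `alpha = 0.1`, uniform
level prior, standard-normal priors on the opponent's log-parameters.
The volatility default keeps agents adaptive on the 512-trial horizon;
the temperature keeps choices strongly reward-driven while retaining
irreducible behavioural noise. The qualitative orderings reported below
were checked on a 3x3 grid around these defaults (`log sigma` in
{-2, -1, 0} x `beta` in {0.05, 0.1, 0.2}): the competitive ordering and
twin-pair results are stable across the neighbourhood, with the expected
erosion at the noisiest corner (`beta = 0.2`).

## Games

Payoff tables are configuration, not code (`inst/extdata/games.yaml`).
`hide_and_seek` is the symmetric zero-sum competition: player 1 (the
seeker) wins +1 when actions match, player 2 (the hider) wins +1 when they
differ. Its mixed Nash equilibrium is (0.5, 0.5) and a uniform policy is
exactly payoff-neutral against any opponent — the analytic anchor used in
the acceptance checks. `battle_of_the_sexes` is the unbalanced
coordination game: matching on 0 pays (2, 1), matching on 1 pays (1, 2),
mismatching pays (0, 0); its interior equilibrium is (1/3, 2/3). Actions
are coded 0/1 and every policy reports the probability of action 1.

## Tournaments and metrics

`payoff_matrix()` plays every phenotype pair for `tau` trials and averages
accumulated payoffs over `n_reps` Monte-Carlo repetitions (study
conditions: `tau = 512`, `n_reps = 500`; the test suite uses the same
values since the engine advances all repetitions in lock-step). Cumulative
payoffs are checkpointed at powers of two so a single tournament yields the
payoff matrix at every game length up to `tau`. Repetition `r` of pair `q`
uses the derived seed `child_seed(seed, q, r)`, so any single game can be
reproduced bit-exactly with `play_game()`.

Behavioural metrics operationalise the analyses of the simulation study:
`prediction_accuracy_slope()` regresses a player's per-trial prediction on
the opponent's true behavioural tendency — defined as the opponent's
recorded policy probability, the only continuous per-trial quantity the
generator possesses (the sampled action is a noisy binarisation of it);
`correct_prediction_rate()` thresholds predictions at 0.5;
`attributed_level()` is the argmax of the final level posterior, ties
broken toward the lower level. The slope regression uses all trials by
default; a burn-in can be applied by slicing the record.

## Evolutionary analysis

Expected payoff matrices of the two games are mixed as
`(1 - omega) M_hs + omega M_bos` — raw accumulated payoffs, no cross-game
normalisation, matching the single mixture the evolutionary model
prescribes. The caveat is inherited: absolute payoff levels of the two
games are not comparable, so `omega` confounds encounter probability with
payoff scale; `mixed_payoff(standardise = TRUE)` offers per-game
standardisation, off by default.

Replicator dynamics `df_i = f_i ((M f)_i - f' M f)` are integrated with
fixed-step classical RK4 (`dt = 0.01` after rescaling `M` by its largest
absolute entry, `t_max = 1e4`, convergence at `1e-8` on the vector field's
infinity norm), renormalising onto the simplex each step. The integrator
is a small compiled kernel; an R reference step is kept and the two are
held to `1e-12` agreement in the tests, alongside shift-invariance and
closed-form two-phenotype checks. `find_ess()` integrates from
simplex-uniform initial conditions (128 in the study configuration),
flags non-convergence as potential cycling, reports extinctions below
`1e-3`, and declares the equilibrium unique when all endpoints agree to
`1e-3` in max-norm.

## What the simulations show — and known limitations

With the shipped defaults the package reproduces the qualitative
phenomenology the model is known for:

* In the competitive game the payoff matrix is anti-symmetric, gains are
  positive whenever the row agent is deeper than the column agent, and the
  gain over 0-ToM *shrinks* as the depth gap grows (an informational cost
  of sophistication). Competitive-only selection fixes the deepest
  phenotype; extinction order follows sophistication.
* Twin pairs of level 0 and 1 predict each other at chance in the
  competitive game; twin 2-ToM pairs attribute level k-1 = 1 to each other
  there, while in the cooperative game they settle on heterogeneous
  attributions (one says 0, the other 1) and coordinate well.
* 0-ToM is driven extinct wherever games are long enough for learning to
  bite, at any cooperation proportion.

Two outcomes are weaker than the phenomenology sketched above and should
be read as genuine model behaviour under these defaults, not engine
artifacts:

* *Short cooperative games.* For `tau` between 4 and 16 and
  cooperation-heavy mixtures, 0-ToM retains a non-trivial equilibrium
  share: a handful of trials is too short for deeper phenotypes to
  out-coordinate it.
* *Deep-pair cooperation is asymmetric.* Among phenotypes of depth >= 2 in
  the cooperation game, the deeper partner systematically secures its
  preferred coordination cell (its early predictions are more moderated by
  parameter uncertainty, which makes it effectively more stubborn). As a
  consequence the cooperative stable state here is a mixture of 1-ToM with
  the *deepest* phenotype, rather than capping sophistication at depth 2.
  This balance is sensitive to the approximation stack (finite-difference
  gradients, moment-matched marginals) and to `(sigma, beta)`.
* In the strictly zero-sum limit (`omega = 0`) the Nash phenotype is
  exactly payoff-neutral against every opponent, so the replicator flow
  has a neutral direction and the Nash share at equilibrium is set by
  Monte-Carlo noise rather than selection; with any cooperative admixture
  Nash is selected against decisively. One-shot games (`tau = 1`) carry no
  information at all, so equilibria there are noise-determined.

The synthetic tournaments emulate behavioural noise (softmax sampling) and
learning dynamics, but not inter-individual parameter variability, payoff
perception noise, or any real subject data: passing tests certify the
model's internal phenomenology, not human behaviour.

## Problem sizes

Tournaments in the tests and the acceptance script run the full study
conditions (`tau = 512`, 500 repetitions, all 15-28 pairs) in a few
minutes thanks to the repetition-batched engine; phase diagrams use 32
initial conditions per cell in the tests and 128 for single stable-state
calls. `paper_full.yaml` and `paper_scaled.yaml` encode the full and
desk-scale experiment configurations for `run_experiment()`.
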