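---
title: "Quantifying degeneracy and redundancy in an active-inference word repetition model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying degeneracy and redundancy in an active-inference word repetition model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degenr)
```

## The measures

For an agent holding posterior beliefs $Q(s)$ about the hidden states $s$
that cause its observations $o$ under a generative model $P(s, o)$, the
variational free energy decomposes as

$$F \;=\; \underbrace{D_{KL}[Q(s)\,\|\,P(s)]}_{\text{complexity}}
      \;-\; \underbrace{\mathbb{E}_Q[\ln P(o \mid s)]}_{\text{accuracy}}
  \;=\; \underbrace{\mathbb{E}_Q[-\ln P(s,o)]}_{\text{energy}}
      \;-\; \underbrace{\mathbb{E}_Q[-\ln Q(s)]}_{\text{entropy}}.$$

This package identifies **degeneracy** with the posterior entropy
$\mathbb{E}_Q[-\ln Q(s)]$ — how many distinct causes remain live
explanations of the same outcome — and **redundancy** with the complexity
$D_{KL}[Q(s)\|P(s)]$, the cost of moving beliefs away from their priors.
With $\text{cost} = \mathbb{E}_Q[-\ln P(s)]$ the two are coupled:

$$\text{redundancy} \;=\; \text{cost} \;-\; \text{degeneracy}.$$

All quantities are in nats. `free_energy_components()` and
`redundancy_decomposition()` compute these from arbitrary posterior/prior
pairs and re-verify the identities (tolerance $10^{-8}$) before returning.

## The generative model

`word_repetition_model()` builds a three-epoch Markov decision process for
a word repetition trial:

* **Hidden factors** — *epoch* (3 levels; listen, repeat, evaluate),
  *target word* (red, blue, triangle, square; drawn by the experimenter and
  constant within a trial), *repeated word* (red, **read**, triangle,
  square, blue; set by the agent's articulation, the only controllable
  factor).
* **Outcome modalities** — *proprioception* (still/moving; moving exactly
  at epoch 2), *audition* (the four word sounds; the target at epoch 1, the
  spoken word afterwards) and *evaluation* (neutral/positive/negative;
  positive at epoch 3 iff the spoken word *sounds like* the target).
* **The spurious level.** "read" is a homophone of "red": spoken, it
  produces auditory "red" and earns a positive evaluation when the target
  is "red". It duplicates the function of "red" — a redundant, degenerate
  hypothesis — without ever being wrong. The experimenter scores by sound,
  so the environment treats read≡red as a match.
* **Policies** — five deep policies, one per sayable word, each repeating
  its word at both controllable transitions. After an action is emitted,
  policies inconsistent with it are pruned from the posterior.
* **Preferences** — +0.5 nats of log-preference for a positive evaluation
  at epoch 3; all other preferences are flat.

Likelihood concentration parameters start at 1 on every (outcome, context)
pair the paradigm can generate and 0.5 elsewhere: a weak 2:1 prior in favor
of the true contingencies, which is what makes likelihood learning
non-trivial. Each likelihood carries only its stated conditional
dependencies: conditioning contexts that the dependency structure does not
distinguish (e.g. the target word, for audition at epoch 2) share one tied
Dirichlet parameter, and learning pools their evidence. Initial-state
counts are 10 per plausible level (epoch 1 for the epoch factor, every
level for the word factors, i.e. uniform target priors).

**Transition priors.** Two departures from a fully vague initialization
are deliberate, and matter. First, the transition arrays — the epoch chain,
the identity dynamics of the target word, and the mapping from articulation
choices to spoken words — carry a confident concentration of 10 on their
plausible entries. These encode task structure and motor efficacy that a
subject brings to the experiment (trials always advance; the experimenter
never swaps the target mid-trial; choosing to say "blue" produces "blue").
With 1/0.5 transition counts the agent cannot hold the target in working
memory across epochs, the latent credit assignment that drives likelihood
learning never converges (accuracy stays at chance indefinitely), and the
posterior sharpness that the paradigm's own belief-updating figures display
is unattainable. Second, transition learning is off by default
(`learn$b = FALSE`): accumulating transition pseudocounts from uncertain
state estimates lets off-diagonal mass snowball — a positive-feedback
corruption familiar from EM with vague initializations — until the model
believes the target wanders. `accumulate_dirichlet()` supports transition
learning for models that enable it.

## Belief updating

`infer_states()` minimizes a *structured* variational free energy: the
trajectory posterior factorizes across hidden factors, but each factor's
temporal chain is kept intact and solved exactly by forward–backward
message passing given the other factors' marginals (evidence messages are
expectations of the joint log-likelihood of observed outcomes). Each sweep
is an exact coordinate update on the structured bound, so the free energy
is non-increasing across sweeps by construction; iteration stops after 16
sweeps or when the decrease falls below 1/128 nats. Two properties guided
this choice over a fully factorized (per-time-point) mean field:

* For a single factor the scheme is *exact* (posterior and $-\ln$ evidence
  to machine precision), which the test suite exploits with analytic and
  brute-force-enumeration oracles.
* Fully factorized updates on near-deterministic chains are overconfident
  — forward and backward messages reinforce each other — which erases
  precisely the posterior uncertainty that in silico lesions are supposed
  to create.

Dirichlet-held arrays enter the updates through their expected
log-probabilities, $\psi(a) - \psi(a_0)$ (`expected_log_probability()`);
plain probability arrays (as in the test oracles) enter through their
logarithms. Every logarithm is floored at $e^{-16}$.

**Policy selection.** The expected free energy of a policy sums risk (KL
divergence of predicted outcomes from the softmax of the log-preferences)
and ambiguity (expected conditional entropy of the likelihood) over the
remaining time points. While an array is plastic, the expected information
gain about its concentration parameters (novelty, $\tfrac12(1/a - 1/a_0)$
averaged under the predictive distribution) is subtracted. Novelty is not
decorative here: without it, learning makes familiar actions ever less
ambiguous and the agent perseverates on whatever it happened to say first.
When learning is disabled (all evaluation groups), novelty vanishes and
policy selection is purely pragmatic/epistemic about states. The policy
posterior is $\pi = \sigma(-F - \gamma G)$ with precision $\gamma = 1/\beta$
updated by the fixed point $\beta = \beta_0 + (\pi - \pi_G)\cdot G$
($\beta_0 = 1$). Actions are sampled from the $\alpha$-powered policy
marginal with $\alpha = 16$.

## Trial measures and aggregation

After each epoch's observation, per-factor components are computed from
the Bayesian model average of the policy-conditioned expectations, against
the *policy-averaged predictive* beliefs held at the end of the previous
epoch (for epoch 1: the exact prior chain marginals under a uniform policy
prior). Resolving an indecisive policy mixture by observation therefore
counts as complexity — which is exactly what makes imprecise (lesioned)
models expensive. The epoch's expected log-likelihood is shared equally
across factors so the identities survive aggregation.

The reduction to one scalar per trial is configurable
(`fe_aggregation()`); the defaults — components at the epoch's current
time point, summed over factors and epochs, averaged over trials and
subjects — were calibrated once against the published control conditions
of the word-repetition study and then frozen. While learning is enabled,
the KL divergence from pre- to post-update Dirichlet beliefs
(`dirichlet_update_complexity()`) is added to the trial's complexity (and,
via the identities, to F, cost and energy): belief updating extends to
parameters, and this term — large while counts are small, vanishing as
evidence accumulates — is what distinguishes the learning phase from
frozen-model evaluation runs.

## The synthetic environment

The environment module *is* the experiment: `init_trial()` draws a target
(uniform over four words unless forced), `emit_outcome()` generates
outcomes deterministically from the true state by the paradigm rules, and
`apply_action()` advances the trial. The deterministic design mirrors the
paradigm's description; the only stochasticity is the target draw and the
agent's own action sampling. A forced epoch-3 "negative" evaluation turns
a trial into an oddball (violation) trial. What this generator does *not*
emulate: acoustic/phonetic variability, lexicons beyond four words,
articulation dynamics below the word level, or any trial-to-trial
nonstationarity — so passing tests demonstrate internal consistency of the
theory's measures, not fidelity to empirical speech data.

## Experiments

* `run_learning_phase()` — 50 subjects × 500 trials by default (per-subject
  seed = base seed + subject index), Dirichlet learning on, returning
  learning curves, per-trial measures and each subject's post-learning
  model.
* `make_nonspurious()` — structure learning: every likelihood parameter
  that the dependency structure assigns to spoken "read" is set to
  concentration 10, making its predictions uniform (the offline removal of
  a redundant parameter).
* `lesion()` — precision lesions: each conditioning column's normalized
  probabilities are raised to the exponent and rescaled to preserve the
  column total; the largest entries shrink and the smallest grow. The
  extrinsic (A) lesion applies exponent 0.4 to the evaluation likelihood;
  the intrinsic (B) lesion exponent 0.5 to the target-word transitions.
* `run_all_groups()` — the eight evaluation groups
  ({Control, B, A, A and B} × {spurious Y/N}); all groups reuse the same
  post-learning subjects with learning disabled, so differences are purely
  structural and comparisons are paired. The Control/Y row summarizes the
  learning run itself (500 trials per agent; behavioral accuracy over the
  last 10 trials); all other rows are fresh 10-trial runs.
* `run_violation_paradigm()` + `erp_traces()` — standard and deviant
  (forced-"wrong") trials with full iteration traces; the simulated local
  field potential is the first temporal derivative of a selected
  expectation (default: the predicted probability of a positive evaluation
  at epoch 3), each epoch mapped onto 250 ms of peristimulus time, and the
  mismatch wave is deviant − standard, averaged over subjects.

## Numerical choices and degenerate inputs

* log floor $e^{-16}$ everywhere a logarithm is taken; zero-sum
  concentration columns raise errors rather than being floored.
* Variational iteration: 16 sweeps maximum, early stop at
  $\Delta F < 1/128$ nats; evoked-response runs force all sweeps so traces
  share a grid.
* Precision updates clip $\beta$ at a small positive floor (with a
  warning) if an extreme G vector drives it nonpositive.
* Ties in action sampling are resolved by the RNG stream alone; a single
  seed governs target draws and action draws, split per subject.
* The epoch-1 prior uses exact chain propagation, not variational
  iteration: with no data, mean-field fixed points on a near-deterministic
  chain can break the symmetry of the prior and collapse it to an
  arbitrary corner.
* Serialization (`model_to_json()`) writes counts at full precision so
  models round-trip bit-stably.

## Problem sizes

The default test suite simulates small cohorts (2 subjects × 150 trials)
for unit and property tests; the acceptance tests and
`scripts/acceptance.R` run the full study design (50 subjects × 500
learning trials, eight 50 × 10 evaluation groups, 50-subject violation
paradigm), a few minutes of compute on one CPU.

## Known limitations

* The absolute scale of the published results table depends on an
  aggregation pipeline that its source does not fully document; this
  package's convention was calibrated once against the two control
  conditions and reproduces the orderings, the learning effects, the
  behavioral superadditivity of dual lesions and the evoked-response
  collapse, but not every printed magnitude (the evaluation-lesion rows in
  particular imply accounting — e.g. exactly-zero accuracies, −7.5-nat
  accuracies — that the model as described does not generate).
* Structured variational inference is exact per factor but still
  factorizes across factors; cross-factor posterior correlations (e.g.
  between target and spoken word given an evaluation) are represented only
  through their marginals.
* The paradigm is three epochs long with a four-word lexicon; hierarchical
  articulation, longer narratives and continuous-time neuronal dynamics
  are out of scope.
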