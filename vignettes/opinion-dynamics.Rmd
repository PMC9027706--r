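---
title: "Opinion dynamics with networks of active-inference agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opinion dynamics with networks of active-inference agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(opinionet)
```

## The model

`opinionet` simulates opinion formation on a social network in which every
agent is a discrete-state active-inference agent: a partially observed
Markov decision process (POMDP) whose perception and action both follow
from its own categorical generative model of the world.

An agent with $K$ neighbours entertains $K + 3$ hidden-state factors:

* **Idea** — a binary environmental state recording which of two mutually
  exclusive Ideas is true (levels *Idea1*, *Idea2*);
* **MetaBelief$_k$**, one per neighbour — a binary "belief about neighbour
  $k$'s belief" (*BelieveIdea1*, *BelieveIdea2*);
* **SelfTweetState** — which of two hashtags the agent itself is currently
  posting;
* **WhoAttendState** — which one of its $K$ neighbours it is currently
  reading ($K$ levels).

It receives $K + 2$ observation modalities: its own tweet (a noiseless
identity mapping), one ternary tweet-observation channel per neighbour
(*Null*, *Hashtag1*, *Hashtag2*), and a noiseless observation of whom it is
attending. The *Null* level is delivered on every channel the agent is not
attending; its likelihood row is constant across hidden states, so it is
exactly uninformative.

### Hashtag semantics and epistemic confirmation bias

The attended channel links a neighbour's believed Idea to the hashtag they
are expected to post through the 2×2 *hashtag semantics* matrix

$$h = \begin{pmatrix} p_h & 1-p_h \\ 1-p_h & p_h \end{pmatrix},$$

with reliability $p_h = 0.73$ by default — the value obtained by pushing a
two-element one-hot vector through a softmax at precision 1, i.e. a
"medium" reliability midway between the uninformative (0.5) and noiseless
(1.0) extremes. On exactly those slices of the likelihood where the
neighbour's believed opinion coincides with the believed Idea
(MetaBelief$_k$ = Idea), the columns of $h$ are sharpened by a column-wise
softmax at precision $\gamma_k$, the **epistemic confirmation bias**
(`build_neighbour_tweet_likelihood()`). Like-minded neighbours therefore
look like more reliable channels, which biases both inference (their posts
move beliefs more) and action (reading them promises more information
gain). Mismatched slices keep the raw $h$: it is already column-stochastic,
and the sharpening is defined only for the matched case.

### Dynamics

Idea and meta-belief factors evolve by precision-scaled identity
transitions: the 2×2 identity through a column softmax at precision
$\omega^{Idea}$ (inverse environmental volatility, fixed at 9.0) or
$\omega^{Soc}$ (inverse social volatility, per neighbour). Low
$\omega^{Soc}$ means neighbours' opinions are believed to drift quickly:
the posterior over an unattended neighbour's belief relaxes towards flat at
logit rate $2\sigma(\omega)-1$ per step, which makes re-reading them
progressively more informative. Tweet and attendance states are fully
controllable — deterministic one-hot transitions driven by the two control
factors.

### Perception

Each timestep the agent propagates yesterday's posterior through the
transitions (`empirical_prior()`) and conditions on the observation bundle
(`update_state_beliefs()`). In this model every factor is informed by at
most one modality, and the only multi-factor modality is the attended
tweet channel over (MetaBelief$_k$, Idea). The posterior is therefore
computed exactly, by enumerating that 2×2 joint and marginalising. A
mean-field coordinate-ascent iterator (`method = "meanfield"`, tolerance
1e-6, at most 10 sweeps, initialised at the prior, log-floor 1e-16) is
included for comparison; its product-form fixed point tracks the exact
marginals to about 1e-3 but is *not* identical to them, which is why exact
enumeration is the default.

### Action

Policies are the $2K$ one-step (tweet, attend) pairs. With a flat
observation prior the expected free energy of a policy reduces to the
negative expected information gain of its observations
(`expected_free_energy()`), computed as predicted-observation entropy
minus expected ambiguity — equivalently the mutual information between the
observation and the predictive joint over its dependent factors. Only the
attended channel can contribute: identity modalities over one-hot
predictive states and Null channels resolve nothing.

The policy posterior is
$Q(\pi) \propto \exp\{\beta\,(-G(\pi)) + \ln P_0(\pi)\}$, where the prior
$P_0$ factorises into the current Idea posterior pushed through an
identity *tweet link* (an agent tends to post what it believes) and the
normalised Dirichlet habit expectation $\varepsilon / \sum \varepsilon$
over attendance. The policy precision $\beta$ defaults to 16, the
conventional setting for discrete active-inference agents. After every
action the habit counts are nudged,
$\varepsilon \leftarrow \varepsilon + \eta\, Q(u^{Who})$, so attendance
choices harden into a prior to repeat them at learning rate $\eta$.

### Action selection: a deliberate hybrid

How an action is drawn from the control posteriors is the one place where
the model's written description and the behaviour it is meant to produce
pull in different directions, and we resolved it empirically:

* sampling *both* controls from their marginals makes the tweet
  probability proportional to the Idea belief (as the tweet-link construct
  intends), but the expected-free-energy differences between neighbours
  are only of order 0.02–0.4 nats, so attendance stays near 50/50 and the
  canonical "echo" regime (a strongly biased agent attending one
  neighbour on the vast majority of steps) never materialises;
* taking the argmax of *both* controls produces the attendance regimes,
  but turns the tweet into a threshold rule and freezes several collective
  effects, because trajectories become insensitive to belief magnitudes.

The default `action_selection = "hybrid"` therefore samples the tweet and
argmaxes the attendance; the two pure modes remain available on every
runner. This choice was fixed before the package's trend checks were run,
on the basis of the single-agent regimes alone.

## The simulation loop

`run_trial()` wires agents into an undirected Erdős–Rényi graph
(`generate_er_network()`; graphs with isolated nodes are rejected and
redrawn, since a neighbourless agent has no observation channels). All
agents update synchronously: observations at $t$ are routed from the
action snapshot at $t-1$ (`route_observations()`), so within-timestep
processing order cannot matter — each agent's two random draws per step
are pre-drawn into a per-agent table to keep this exact. Bootstrap actions
at $t=0$ are sampled before any observation: the tweet from the initial
Idea belief through the tweet link, the attendance uniformly.

Heterogeneity follows the study conditions: each agent's per-neighbour
$\gamma$ and $\omega^{Soc}$ vectors are independent normal draws centred
on the condition means with variance 0.1 (interpreted as a variance, not a
standard deviation), clipped below at 0.05 to keep precisions positive.
Initial Idea beliefs are flat by default, or drawn uniformly from an
interval such as (0.4, 0.6).

```{r}
tr <- run_trial(trial_config(N = 15, p = 0.2, T_steps = 100, seed = 1))
round(final_idea_beliefs(tr), 3)
polarisation_index(final_idea_beliefs(tr))
```

## Collective outcome metrics

* `polarisation_index()` — max minus min of the final Idea1 beliefs; its
  across-trial mean is close to the fraction of trials ending in two
  opposing camps.
* `consensus_reached()` — all final beliefs strictly on one side of 0.5
  (exactly 0.5 is conservatively counted as non-consensus).
* `cluster_outcomes()` — each connected component classified as *Idea1*,
  *Idea2*, or *unresolved*; sparse graphs often split into components that
  settle independently, and with flat initial beliefs the resolved
  components split near 50/50 between the Ideas by symmetry.
* `reattendance_rate()` — per agent, the count of attendances of its
  favourite neighbour; aggregated over agents by maximum (the function's
  default, bounded by $T$) or mean. **Sweeps default to the mean**: under
  argmax attendance some agent locks onto a single neighbour in almost
  every trial, so the per-trial maximum saturates at $T$ and carries no
  condition signal, while the mean preserves the drop in re-attendance as
  $\omega^{Soc}$ grows.

## What the simulator emulates — and what it does not

The generator *is* the study design: binary opinions, hashtag-mediated
communication, one read per timestep, static undirected random graphs,
and no environmental signal — agents only ever observe each other, so
"truth" plays no role and outcomes are purely social. Real opinion data
violate most of these idealisations (multi-valued and porous opinions,
directed and dynamic follower graphs, algorithmic feeds, exogenous
evidence). Passing trend checks therefore validates the mechanism — that
confirmation-biased information seeking, volatility-driven curiosity, and
habit formation trade off to produce consensus or echo chambers — not any
quantitative claim about real social networks.

Known limitations worth stating plainly:

* The confirmation-bias effect on *collective* polarisation is weaker here
  than the strongest published claims for comparable models: raising
  $\gamma$ also strengthens belief coupling (an unexpected post from a
  trusted like-minded source carries a likelihood ratio of ~17 at
  $\gamma = 9$) and adds a general exploration bonus, and in dense
  networks these push towards consensus about as hard as selective
  exposure pushes away from it. In this implementation the γ-effect on
  polarisation at high connectivity is approximately zero, and habit
  learning raises re-attendance clearly but leaves mean polarisation
  unchanged — under argmax attendance the confirmation-bias lock already
  dominates before habits accumulate.
* With symmetric scripted sources, a low-bias/low-volatility agent's
  attendance posterior stays at 50/50; the argmax rule then alternates
  deterministically and its Idea belief is pinned to one half — the
  "quick convergence under stable neighbours at low bias" regime does not
  occur under any of the three action rules.
* Mean-field inference is provided for comparison only; it is an
  approximation and deliberately not used in the runners.
* Networks beyond a few hundred agents are out of scope; the loop is pure
  R (~0.3 s per 15-agent, 100-step trial on one core).

## Problem sizes and numerics used by the test-suite

The package's own checks run scaled-down versions of the study designs:
single trials and sweeps at $N = 15$, $T = 100$, with $S = 20$ trials per
condition for trend checks and $S = 100$ for the component-symmetry check
(the sizes at which the effects are comfortably outside Monte-Carlo
noise, while the whole suite stays in the minutes range). Full 15×15
condition grids at $S = 100$ remain available through `cmd_sweep()`.
All entropies and information gains are in nats; probabilities are floored
at 1e-16 before logarithms; every constructed table is column-stochastic
to 1e-12 by construction and asserted as such in the tests.
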