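---
title: "An adaptive dynamic neural field model of rule-based reach decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An adaptive dynamic neural field model of rule-based reach decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

In context-dependent visuomotor tasks a spatial cue and a contextual (color)
cue jointly determine the rewarded reach goal: under the *direct* rule the
goal is the cue location, under the *inferred* rule it is the diametrically
opposite location (cue + 180°). Monkeys learn such mappings over weeks of
staged training, and their frontoparietal reach areas encode *both* potential
goals during the memory period of ambiguous trials, with choice preferences
that track the reward schedule. `dnfreach` implements a neural-process
account of this behavior: perception, working memory, association learning
and action selection are all carried by interconnected dynamic neural fields
(DNFs), and one reward-modulated Hebbian mechanism simultaneously learns the
visuomotor mapping and adapts choice preferences.

## Model

### Field dynamics

Every field is an Amari-type leaky integrator over a feature lattice. With
activation $u(x,t)$, resting level $h<0$, time constant $\tau$, external
input $s(x,t)$, interaction kernel $k$ and sigmoid output
$f(u) = 1/(1+e^{-\beta u})$ (soft threshold at 0):

$$\tau \dot u(x,t) = -u(x,t) + h + s(x,t) + \int k(x-x')\,f(u(x',t))\,dx' + q\,\xi(x,t)$$

The kernel has local Gaussian excitation and long-range/global inhibition.
Depending on the balance the field is *input-driven* (peaks die with the
input), *self-sustained* (peaks survive as working memory) or *selective*
(global inhibition allows only one winning peak). Integration is explicit
Euler with additive Gaussian noise whose amplitude scales with
$\sqrt{dt}$, so the accumulated noise variance per unit model time is
independent of the step size.

### Architecture

Five components, mirroring a frontoparietal reach circuit:

* a 1-D circular **spatial input field** over cue/reach direction
  (input-driven), fed by Gaussian stimulus bumps;
* **context nodes** (one per rule) with self-excitation and mutual
  inhibition, so a briefly cued rule latches for the rest of the trial;
* a 2-D **association field** (direction × an initially unspecific context
  dimension) in the self-sustained single-peak regime — the model's working
  memory and the substrate of rule learning;
* a 1-D **motor preparation field** with soft competition, which can hold
  several candidate plans at once;
* a 1-D **motor field** with strong winner-take-all dynamics, held
  subthreshold until a go signal disinhibits it.

Fixed topological projections implement the *direct pathway*
(spatial → preparation → motor and back), which produces default reaches to
salient stimuli before any learning. Two plastic projections implement the
*indirect pathway*: `W_ca` from the context nodes into the association field
(all-to-all, initialized with small i.i.d. random weights) and `W_ap` from
the association field to the preparation field (initialized as a
wrapped-Gaussian topological map, index shift 0°).

### Reward-modulated learning

After each trial the motor response is read out (circular centroid of the
tallest smoothed motor peak above threshold $\theta$) and compared with the
rewarded goal: $R=+1$ within ±8° (inclusive), $R=-1$ otherwise. Once per
trial, using field outputs averaged over the post-go selection window:

* **instar** (context → association): for $R=+1$,
  $\Delta W_{cx} = \varepsilon^{+} f^{asc}_x (f^{ctx}_c - W_{cx})$ — active
  association sites pull their incoming weights toward the context pattern;
  no presynaptic normalization, so many regions can adopt the same context
  (divergence). For $R=-1$ co-active weights decay,
  $\Delta W = -\varepsilon^{-} N f^{asc} f^{ctx} W$, with $N$ chosen per
  trial so the summed magnitude is comparable to a rewarded trial.
* **outstar** (association → preparation): for $R=+1$,
  $\Delta W_{xy} = \varepsilon^{+} f^{asc}_x (f^{prp}_y - W_{xy})$ — active
  sites copy the postsynaptic pattern of the actually executed reach
  (convergence). For $R=-1$ the connection to the active preparation region
  is weakened and the removed amount is redistributed uniformly over that
  site's inactive targets, preserving each source's total outgoing weight;
  this raises the probability of a different response on the next identical
  trial.

Weights are clipped to $[0, w_{max}]$; both rules gate on the association
output, so silent sites never change.

## Tasks, schedules and what the simulations emulate

* **IR training**: context + spatial cue at trial start, a target cue at the
  rewarded goal at the end of the memory period whose salience fades
  linearly 1 → 0 over the session (1000 trials, 80 % inferred, four cardinal
  cue directions). The go signal follows the target-cue onset directly and
  the cue stays visible through selection, as the trained reach is to a
  shown target early in training.
* **DMG**: both cues briefly at trial start; probes the learned state with
  the learning rate forced to zero.
* **PMG-CI / PMG-NC**: spatial cue first; the context instruction arrives at
  the end of the memory period (CI) or never (NC, free choice between cue
  and cue+180°). Free-choice rewards come from the **EPRS** (fair coin,
  history-free) or the **BMRS** (reward probability of a goal decreases with
  its recent choice fraction over a 20-trial window), with NC:CI trials
  mixed 40:60.

The generator's defaults are these study conditions. What the synthetic
sessions do *not* emulate: motivational fluctuations, eye/hand fixation
mechanics, monkey-specific short-term adjustments of trial parameters, and
neural spiking variability — passing tests therefore validate the model
mechanism, not a fit to raw monkey data.

## How the learned solution works

During IR training the association peak for a cue sits at some position
along the context dimension; instar updates make that region selective for
the active rule, and outstar updates re-aim its outgoing projection at the
reach actually made (180° shifted for inferred trials). Patches selective
for each rule self-organize at each trained direction; untrained directions
keep zero index shift and no context sensitivity. DMG and CI trials are
solved by the context input steering (or late-shifting) the peak onto the
matching patch. In free choice nothing steers the peak; its position is
decided by noise against the learned landscape, and because inferred
patches dominate after 80 %-inferred training, the inferred reach wins with
high probability — the learning history biases the decision. The BMRS then
punishes that bias: failed inferred reaches weaken the inferred projection
and spread weight toward silent targets until both goals are represented
during memory (the two-ridge signature) and choices re-balance.

## Parameters that matter

| parameter | default (fast preset) | role |
|---|---|---|
| `tau`, `dt` | 10, 1 model-time units | Euler step is `dt = tau/10` |
| `h` | −2 (fields), −3 (association), −4 (motor) | resting levels |
| `beta` | 4 | sigmoid steepness, threshold at 0 |
| association `a_exc`, `sigma_x`, `sigma_y` | 10, 11.5°, 4.5 units | self-sustainment and peak mobility |
| association `g_inh` | 90 × mean output | single-peak selection |
| `g_spt_prp` vs `g_asc_prp` | 5 vs 100 (per normalized area) | the direct-default / learned-override balance |
| `g_ctx_asc` | 1.8 | context steering; `g_ctx_asc · w_max < |h|` so context input alone cannot ignite a peak |
| `g_go` | 3.5 | go-gate disinhibition of the motor field |
| `eps_pos`, `eps_neg` | 0.1, 0.06 | learning rates (`eps_pos ≤ 2·eps_neg` keeps failed-trial updates within the factor-2 normalization contract) |
| `theta`, tolerance | 0.5, ±8° | response readout and reward window |

All spatially integrating gains are expressed in resolution-independent
units (kernel strengths as integrals of unit-sum profiles, global
inhibition per mean output, projections per normalized field area), so the
same constants describe the same regimes on both lattice presets.

## Numerical and design choices

* **Lattices.** The default preset samples direction at 2° (180 samples;
  association field 180 × 30). The `fast` preset (4°, 90 × 15, halved epoch
  durations) resolves the ±8° reward window comfortably and keeps a trial at
  a few milliseconds of compute; all shipped studies and the acceptance
  analysis run on it, and the regime gates pass on both presets.
* **Synchronous updates.** Every projection input is computed from the
  previous step's outputs, removing any dependence on component ordering.
* **Engines.** The per-step dynamics exist twice: a pure-R reference
  (`step_model()`) and a compiled integrator used by `run_trial()`;
  a test asserts noise-free trajectory equivalence below 1e-10. All noise is
  drawn from R's RNG in both engines, so a session is byte-identical under
  `set.seed()`.
* **Context-dimension boundary.** Bounded with zero-padded interactions;
  border sites receive less recurrent excitation, which pushes peaks toward
  the interior — the rarely trained rule tends to settle nearer the borders.
* **Peak mobility.** The context-dimension kernel width (4.5 units) is the
  crux of late context instructions: the instructed region partially
  overlaps the standing memory peak and pulls it over. The spatial width
  (11.5°) sets how often an oblique-cue peak drifts onto an adjacent
  trained patch (the adjacent-direction error) rather than staying put
  (the context error).
* **Initial context weights.** `W_ca` starts as i.i.d. uniform draws on
  `[0, 0.25]`. The scale matters: with much smaller initial weights the
  rarely trained (direct) rule can fail to claim territory at some
  directions — its trial-formation bias is then too weak to escape the
  dominant patch, and the direction's direct mapping is lost. At 0.25 the
  random map reliably breaks the symmetry at every direction.
* **Selection as a system property.** Under sustained strong bimodal
  drive the isolated motor field can hold two peaks; in the assembled
  architecture the motor-to-preparation feedback suppresses the losing
  plan at its source and field noise breaks exact ties, so the gated
  motor field always ends with a single peak. The selection regime gate
  therefore tests the assembled model.
* **Degenerate inputs.** A trial with no suprathreshold motor response is
  logged as aborted, excluded from performance denominators, and triggers no
  learning. Exact ties between motor peaks are broken by a seeded uniform
  pick and flagged in the log.
* **Snapshot timing.** Learning uses outputs averaged over the second half
  of the go epoch, after the motor-field winner has suppressed competing
  preparation peaks, so the outstar target reflects the executed reach.
* **BMRS punishment.** The schedule sets raw reward odds
  $(1-\text{choice fraction})^{\gamma}$ per goal (renormalized),
  with $\gamma = 2$ by default. A linear penalty ($\gamma = 1$) satisfies
  the same qualitative contract but, in this implementation, lets rewarded
  inferred trials rebuild the inferred projection faster than punishment
  erodes it, stalling re-balancing around 25 % direct choices; the steeper
  penalty moves the equilibrium into the low 30s. The balanced policy is
  reward-maximizing (at 50 %) for every $\gamma$, and the exponent is a
  `session_config()` option.
* **Multi-context training.** With more than two rules the non-default
  contexts share the inferred fraction equally; capacity degrades with the
  number of rules through interference between context patches, as expected
  from the fixed context-dimension extent.

## Problem sizes of the shipped studies

Training sessions use 1000 trials; DMG/CI probes 400 trials; free-choice
phases 500 (EPRS) and 1250 (BMRS) mixed trials at the 40:60 NC:CI ratio;
generalization probes 200 trials; the training-ratio sweep uses nine
fractions with 350–400 training trials each. These sizes give binomial
standard errors of 1–4 percentage points on the reported rates.

## Known limitations

* The re-balanced direct-choice fraction under the BMRS settles around
  0.35-0.47 across training runs, at and below the published 41 %: the
  free-choice peak position along the context dimension is set at
  formation and only the weight landscape — not the formation statistics —
  is reversible by reward.
* The generalization error split leans a few points toward
  adjacent-direction errors (roughly 70/30 vs the published 60/40), and
  the inherent free-choice bias ranges 0.78-0.95 across training runs
  (published 0.93), because the self-organized patch geometry differs
  between runs.
* The logistic midpoint of the training-ratio sweep lands slightly above
  0.5 (≈ 0.53–0.6 depending on training length), a weaker direct-default
  asymmetry than the published 0.63.
* No eligibility traces or habituating teaching signal: learning stops only
  when the session's learning flag is off.

## Reproducing the analyses

```{r}
library(dnfreach)
set.seed(1)
cfg <- model_config("fast")
m <- init_model(cfg)
train <- run_session(m, session_config("ir", 1000))
probe <- run_session(train$model, session_config("dmg", 400))
session_performance(probe$log)
weight_difference_map(train$model)   # context-preference patches
index_shift_map(train$model)         # 0 deg vs ~180 deg projection shifts
```

`run_experiment()` packages the four standard studies (IR training,
generalization, reward-schedule switch, ratio sweep) with CSV artifacts,
and `scripts/acceptance.R` recomputes the headline numbers end to end.
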