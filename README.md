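# dnfreach

An adaptive dynamic neural field (DNF) model of rule-based reach decisions.

In context-dependent reaching tasks a spatial cue and a color (context) cue
together determine the rewarded goal: reach *to* the cue ("direct" rule) or
to the diametrically opposite location ("inferred" rule, cue + 180°).
`dnfreach` simulates how a network of interconnected Amari-type activation
fields — a spatial input field, latching context nodes, a two-dimensional
association field, a motor preparation field and a gated motor field —
perceives such cues, holds them in bump-attractor working memory, learns
arbitrary context-dependent visuomotor mappings through reward-modulated
instar/outstar Hebbian rules, and competitively selects reach goals. Because
mapping learning and action selection share one substrate, the model's
learning history biases its free choices, and changing reward contingencies
re-balance them. The package is aimed at computational/systems neuroscientists
studying sensorimotor decision making and reward-driven plasticity.

Each field obeys

    tau * du/dt = -u + h + s(x,t) + (k * f(u))(x) + noise,
    f(u) = 1 / (1 + exp(-beta * u)),

with local excitatory / long-range inhibitory kernels `k` whose balance puts
a field into an input-driven, self-sustained (working memory) or
winner-take-all (selection) regime. The two plastic projections are updated
once per trial by the reward-dependent instar rule
`dW = eps * f_assoc * (f_ctx - W)` (context → association) and outstar rule
`dW = eps * f_assoc * (f_prep - W)` (association → preparation), with
normalized weight decay / redistribution on failed trials.

## Worked example

```r
library(dnfreach)
set.seed(1)

cfg   <- model_config("fast")            # 4 deg lattice, desk-scale epochs
model <- init_model(cfg)

# staged inferred-reach training: 1000 trials, 80 % inferred context,
# target cue fading linearly from salience 1 to 0
train <- run_session(model, session_config("ir", 1000))

# definite motor-goal probes (both cues at trial start, learning off)
probe <- run_session(train$model, session_config("dmg", 400))
session_performance(probe$log)
#> $percent_correct
#> [1] 100
#> $n_scored
#> [1] 400
#> $n_aborted
#> [1] 0

# free choice: spatial cue only, either goal rewarded at 50:50
free <- run_session(train$model,
                    session_config("pmg", 500, nc_ratio = 0.4,
                                   schedule = "eprs", learn = TRUE))
choice_fractions(free$log)$frac_inferred
#> [1] 0.8702703
```

After training, `weight_difference_map()` shows context-preferring patches
only at the four trained directions and `index_shift_map()` shows the
~180° projection shift exactly inside the inferred-preferring patches —
the learned, local implementation of the "rule". The 100 % above is the
fraction of probe reaches within ±8° of the rewarded goal; the 0.87 is the
inherent free-choice bias toward the inferred reach induced purely by the
80:20 training statistics (the reward schedule itself is indifferent).

`run_experiment()` bundles the standard studies — `"ir-training"`,
`"generalization"` (oblique-cue probes with the error taxonomy),
`"reward-schedule-switch"` (equal-probability vs bias-minimizing reward)
and `"ratio-sweep"` (choice bias vs training statistics with logistic
fits) — and writes config, trial logs, weight maps and analysis tables as
CSV/YAML into an output directory.

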