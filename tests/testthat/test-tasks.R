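test_that("the target-cue fade schedule is linear from 1 to 0", {
  expect_equal(fade(0, 1000), 1)
  expect_equal(fade(1000, 1000), 0)
  expect_equal(fade(500, 1000), 0.5)
  expect_true(all(diff(fade(0:100, 100)) < 0))
})

test_that("IR trials pair contexts, goals and saliences as specified", {
  cfg <- fast_cfg()
  set.seed(1)
  sp <- make_ir_trial(1, cfg, n_trials = 1000)
  expect_equal(sp$goal, wrap_dir(sp$cue_dir + cfg$rotations[sp$context]))
  expect_equal(sp$salience, 1)
  last <- make_ir_trial(1000, cfg, n_trials = 1000)
  expect_equal(last$salience, 0)
  # context mixture: inferred share 0.8 within binomial tolerance
  ctx <- replicate(10000, make_ir_trial(5, cfg, 1000)$context)
  expect_equal(mean(ctx == 2), 0.8, tolerance = 0.01)
  # IR timeline: go directly after the target-cue presentation
  tl <- dnfreach:::trial_timeline(cfg, "IR")
  expect_equal(tl$go_t0, tl$target_t0 + cfg$timing$target)
})

test_that("DMG trials present both cues together with uniform marginals", {
  cfg <- fast_cfg()
  set.seed(2)
  sp <- replicate(5000, make_dmg_trial(cfg), simplify = FALSE)
  ctx <- vapply(sp, `[[`, 1L, "context")
  expect_equal(mean(ctx == 1), 0.5, tolerance = 0.02)
  cue <- vapply(sp, `[[`, 1, "cue_dir")
  expect_gt(stats::chisq.test(table(cue))$p.value, 0.01)
  # no target-cue window in the DMG timeline
  tl <- dnfreach:::trial_timeline(cfg, "DMG")
  expect_null(tl$target_t0)
  expect_equal(tl$go_t0, tl$mem_t1)
})

test_that("PMG trials separate the cues in time as specified", {
  cfg <- fast_cfg()
  set.seed(3)
  tl <- dnfreach:::trial_timeline(cfg, "PMG-CI")
  expect_equal(tl$ci_t0, tl$mem_t1)          # instruction at memory end
  expect_lt(tl$ci_t0, tl$go_t0)              # ... before the go signal
  nc <- make_pmg_trial("NC", cfg, dirs = 90)
  expect_equal(sort(nc$goals), sort(wrap_dir(c(90, 270))))
  expect_true(is.na(nc$context))
  # mixed sessions draw the free-choice type with the configured ratio
  draws <- replicate(4000, runif(1) < 0.4)
  expect_equal(mean(draws), 0.4, tolerance = 0.03)
})

test_that("the equal-probability schedule is a fair history-free coin", {
  cfg <- fast_cfg()
  spec <- make_pmg_trial("NC", cfg, dirs = 0)
  set.seed(4)
  draws <- replicate(10000, eprs_draw(spec))
  expect_equal(mean(draws == 0), 0.5, tolerance = 0.015)
  set.seed(99); a <- replicate(20, eprs_draw(spec))
  set.seed(99); b <- replicate(20, eprs_draw(spec))
  expect_identical(a, b)
})

test_that("the bias-minimizing schedule punishes the over-chosen goal", {
  cfg <- fast_cfg()
  spec <- make_pmg_trial("NC", cfg, dirs = 0)
  st <- bmrs_state(20)
  set.seed(5)
  expect_equal(bmrs_update_and_draw(st, spec)$probs, c(0.5, 0.5))  # empty window
  for (i in 1:20) st <- bmrs_record(st, 2L)      # all-inferred history
  d <- bmrs_update_and_draw(st, spec)
  expect_equal(d$probs[2], 0)                    # inferred reward prob minimal
  expect_equal(d$probs[1], 1)                    # direct maximal
  st2 <- bmrs_state(20)
  for (i in 1:10) st2 <- bmrs_record(bmrs_record(st2, 1L), 2L)
  expect_equal(bmrs_update_and_draw(st2, spec)$probs, c(0.5, 0.5)) # balanced
  # window is sliding
  expect_length(st$window, 20)
})

test_that("only the balanced policy maximizes reward under the BMRS", {
  # policy-sweep oracle: an agent choosing the direct goal with fixed
  # probability p earns the most reward (-> 50 %) only near p = 0.5
  cfg <- fast_cfg()
  spec <- make_pmg_trial("NC", cfg, dirs = 0)
  set.seed(6)
  reward_rate <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(p) {
    st <- bmrs_state(20)
    hits <- 0
    for (i in 1:400) {
      d <- bmrs_update_and_draw(st, spec)
      choice <- if (runif(1) < p) 1L else 2L
      hits <- hits + (spec$goals[choice] == d$goal)
      st <- bmrs_record(st, choice)
    }
    hits / 400
  }, 0)
  expect_equal(which.max(reward_rate), 3L)
  expect_equal(reward_rate[3], 0.5, tolerance = 0.07)
})

test_that("trials and sessions are reproducible and respect the learning flag", {
  m <- ir_trained_model()
  spec <- make_dmg_trial(m$cfg, dirs = 90, contexts = 2)
  set.seed(7); r1 <- run_trial(m, spec, learn = FALSE)
  set.seed(7); r2 <- run_trial(m, spec, learn = FALSE)
  expect_identical(r1$reach, r2$reach)
  expect_identical(r1$f_prp, r2$f_prp)
  # learning-off sessions leave the weights bit-identical
  set.seed(8)
  pr <- run_session(m, session_config("dmg", 5))
  expect_identical(pr$model$W_ca, m$W_ca)
  expect_identical(pr$model$W_ap, m$W_ap)
  # full session log reproducibility from (config, seed)
  set.seed(9); l1 <- run_session(m, session_config("dmg", 5))$log
  set.seed(9); l2 <- run_session(m, session_config("dmg", 5))$log
  expect_identical(l1, l2)
})

test_that("an aborted trial triggers no learning and is logged as such", {
  set.seed(10)
  # a model whose go gate stays shut cannot respond: force by zero go boost
  cfg <- fast_cfg(proj = list(g_go = 0))
  m <- init_model(cfg)
  res <- run_trial(m, make_dmg_trial(cfg, dirs = 90, contexts = 1),
                   learn = TRUE)
  expect_true(res$aborted)
  expect_true(is.na(res$reach))
  expect_identical(res$model$W_ca, m$W_ca)
})
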