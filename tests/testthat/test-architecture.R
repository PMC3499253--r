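test_that("model initialization is seeded and structured as documented", {
  set.seed(11); m1 <- init_model(fast_cfg())
  set.seed(11); m2 <- init_model(fast_cfg())
  expect_identical(m1$W_ca, m2$W_ca)
  expect_identical(m1$W_ap, m2$W_ap)
  # topological outgoing map: zero index shift at every association site
  expect_true(all(index_shift_map(m1) == 0))
  # initial context weights carry no spatial structure: the autocorrelation
  # of the weight-difference map along the spatial dimension is ~0 beyond lag 0
  wd <- weight_difference_map(m1)
  ac <- apply(wd, 2, function(col) stats::acf(col, lag.max = 5,
                                              plot = FALSE)$acf[-1])
  expect_lt(max(abs(rowMeans(ac))), 0.15)
  # fields start at their resting levels
  expect_true(all(m1$u_prp == m1$cfg$fields$prp$h))
})

test_that("a spatial cue induces a ridge that condenses to one association peak", {
  set.seed(2)
  m <- init_model(quiet_cfg())
  cue <- input_bump(m$pre$lat_x, 90, m$cfg$stim$amp_spt, m$cfg$stim$sigma_spt)
  for (t in 1:30) m <- step_model(m, list(spt_profile = cue))
  # early input to the association field is a vertical ridge: localized in x,
  # near-uniform along the context dimension
  f <- model_outputs(m)$asc
  xprof <- apply(f, 1, max)
  expect_equal(m$pre$lat_x$pos[which.max(xprof)], 90, tolerance = 8)
  for (t in 1:120) m <- step_model(m, list(spt_profile = cue))
  f <- model_outputs(m)$asc
  # after condensation the peak is localized in BOTH dimensions
  expect_lt(sum(apply(f, 2, max) > 0.5), m$cfg$lattice$n_y)
  expect_gt(max(f), 0.9)
  expect_equal(dnfreach:::count_peaks(apply(f, 1, max), 0.5), 1L)
})

test_that("the untrained model produces the default direct reach", {
  set.seed(3)
  m <- init_model(fast_cfg())
  res <- run_trial(m, make_dmg_trial(m$cfg, dirs = 90, contexts = 1),
                   learn = FALSE)
  expect_false(res$aborted)
  expect_lt(circ_dist(res$reach, 90), 8)
})

test_that("the go gate controls motor peak formation and enforces one winner", {
  set.seed(4)
  cfg <- fast_cfg()   # field noise breaks the tie between the equal inputs
  m <- init_model(cfg)
  # drive the preparation field with two equal bumps through a fake
  # association state: inject via spatial cue held on at two locations
  two <- input_bump(m$pre$lat_x, 0, cfg$stim$amp_spt, cfg$stim$sigma_spt) +
    input_bump(m$pre$lat_x, 180, cfg$stim$amp_spt, cfg$stim$sigma_spt)
  m <- set_go_gate(m, FALSE)
  for (t in 1:150) m <- step_model(m, list(spt_profile = two, go = FALSE))
  f_mot <- model_outputs(m)$mot
  expect_lt(max(f_mot), cfg$learn$theta)   # gate off: no response possible
  expect_gt(max(model_outputs(m)$prp), 0.5)
  for (t in 1:120) m <- step_model(m, list(spt_profile = two, go = TRUE))
  f_mot <- model_outputs(m)$mot
  expect_gt(max(f_mot), cfg$learn$theta)
  # winner-take-all: exactly one above-threshold motor peak
  expect_equal(dnfreach:::count_peaks(f_mot, 0.5), 1L)
})

test_that("motor feedback reinforces the selected plan and suppresses others", {
  set.seed(5)
  cfg <- quiet_cfg()
  m <- init_model(cfg)
  expect_equal(max(abs(motor_feedback(m))), 0, tolerance = 1e-3)
  # build a motor peak, then check the feedback profile
  bump <- input_bump(m$pre$lat_x, 45, cfg$stim$amp_spt, cfg$stim$sigma_spt)
  for (t in 1:150) m <- step_model(m, list(spt_profile = bump, go = TRUE))
  fb <- motor_feedback(m)
  expect_equal(m$pre$lat_x$pos[which.max(fb)], 45, tolerance = 8)
  expect_lt(min(fb), 0)   # global suppression elsewhere
})

test_that("the full noise-free model is rotation equivariant before learning", {
  run_cue <- function(dir) {
    set.seed(6)   # same weight init for both runs
    m <- init_model(quiet_cfg())
    m$W_ca[] <- 0.02   # strip random asymmetry; equivariance needs homogeneity
    res <- run_trial(m, make_dmg_trial(m$cfg, dirs = dir, contexts = 1),
                     learn = FALSE)
    res
  }
  r0 <- run_cue(90); r1 <- run_cue(270)   # 180 deg is a lattice multiple
  shift <- 180 / r0$model$pre$lat_x$dx
  n <- length(r0$f_prp)
  rot <- r0$f_prp[((seq_len(n) - 1 - shift) %% n) + 1]
  expect_equal(r1$f_prp, rot, tolerance = 1e-6)
  expect_equal(circ_dist(r1$reach, r0$reach + 180), 0, tolerance = 1e-3)
})

test_that("compiled and reference integrators produce the same trajectory", {
  set.seed(8)
  cfg <- quiet_cfg()
  m <- init_model(cfg)
  spec <- make_dmg_trial(cfg, dirs = 90, contexts = 2)
  r_cpp <- run_trial(m, spec, learn = FALSE, engine = "cpp")
  r_ref <- run_trial(m, spec, learn = FALSE, engine = "R")
  expect_equal(r_cpp$model$u_prp, r_ref$model$u_prp, tolerance = 1e-10)
  expect_equal(r_cpp$model$u_asc, r_ref$model$u_asc, tolerance = 1e-10)
  expect_equal(r_cpp$f_mot, r_ref$f_mot, tolerance = 1e-10)
  expect_equal(r_cpp$reach, r_ref$reach)
})

test_that("association memory peaks survive the whole memory period", {
  set.seed(9)
  m <- init_model(fast_cfg())
  res <- run_trial(m, make_pmg_trial("NC", m$cfg, dirs = 270), learn = FALSE)
  # snapshot is taken after cue offset + memory + instruction gap + go:
  # a surviving above-threshold association peak proves self-sustainment
  expect_gt(max(res$f_asc), 0.9)
})
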