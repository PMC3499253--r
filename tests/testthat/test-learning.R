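test_that("response readout finds the centroid of the tallest motor peak", {
  lat <- make_lattice(90, 360, circular = TRUE)
  expect_true(is.na(read_response(rep(0, 90), lat)$dir))
  # single symmetric bump: centroid within half a lattice step
  r <- read_response(gauss_bump(lat, 135), lat, theta = 0.5, smooth_sigma = 4)
  expect_lt(circ_dist(r$dir, 135), lat$dx / 2 + 1e-9)
  expect_false(r$tie)
  # two bumps: the taller one wins
  f <- gauss_bump(lat, 40, 1) * 0.95 + gauss_bump(lat, 220, 1)
  r2 <- read_response(f, lat, theta = 0.5, smooth_sigma = 4)
  expect_lt(circ_dist(r2$dir, 220), 5)
  # exact tie: a uniform random pick between the two, flagged
  f3 <- gauss_bump(lat, 0) + gauss_bump(lat, 180)
  set.seed(1)
  r3 <- read_response(f3, lat, theta = 0.5, smooth_sigma = 4)
  expect_true(r3$tie)
  expect_true(min(circ_dist(r3$dir, c(0, 180))) < 5)
  # wrap-around bump centered at 0 is handled circularly
  r4 <- read_response(gauss_bump(lat, 2), lat)
  expect_lt(circ_dist(r4$dir, 2), lat$dx / 2 + 1e-9)
})

test_that("reward window is circular and inclusive at the boundary", {
  expect_equal(evaluate_reward(90, 90), 1)
  expect_equal(evaluate_reward(98, 90), 1)     # exactly 8 deg: inclusive
  expect_equal(evaluate_reward(98.1, 90), -1)
  expect_equal(evaluate_reward(2, 358), 1)     # circular distance 4 deg
})

test_that("instar converges to the context pattern like the scalar recurrence", {
  # constant outputs: the weight follows w <- w + eps*f*(c - w), whose closed
  # form is c - (c - w0) * (1 - eps*f)^n
  f_asc <- c(0.9, 0, 0.4)
  f_ctx <- c(1, 0.02)
  W <- matrix(0.05, 2, 3)
  eps <- 0.1
  W_n <- W
  for (i in 1:40) W_n <- instar_update(W_n, f_asc, f_ctx, R = 1, eps_pos = eps)
  closed <- matrix(0, 2, 3)
  for (c_i in 1:2) for (x_i in 1:3)
    closed[c_i, x_i] <- f_ctx[c_i] -
      (f_ctx[c_i] - 0.05) * (1 - eps * f_asc[x_i])^40
  expect_equal(W_n, closed, tolerance = 1e-10)
  # postsynaptic gating: silent association sites never change
  expect_equal(W_n[, 2], c(0.05, 0.05))
})

test_that("instar supports divergence: two regions grow without competing", {
  # two association sites paired with the same context node under a
  # symmetric schedule end with equal weights
  W <- matrix(0.03, 2, 4)
  f_ctx <- c(1, 0)
  for (i in 1:60) {
    W <- instar_update(W, c(0.8, 0, 0.8, 0), f_ctx, R = 1)
  }
  expect_equal(W[1, 1], W[1, 3], tolerance = 1e-6)
  expect_gt(W[1, 1], 0.9)
})

test_that("negative-reward updates are normalized and bounded", {
  set.seed(3)
  W <- matrix(runif(2 * 6, 0.2, 0.8), 2, 6)
  f_asc <- runif(6); f_ctx <- c(0.9, 0.1)
  Wp <- instar_update(W, f_asc, f_ctx, R = 1, eps_pos = 0.1, eps_neg = 0.06)
  Wn <- instar_update(W, f_asc, f_ctx, R = -1, eps_pos = 0.1, eps_neg = 0.06)
  mag_pos <- sum(abs(Wp - W)); mag_neg <- sum(abs(Wn - W))
  expect_gt(mag_neg, mag_pos / 2)
  expect_lt(mag_neg, mag_pos * 2)
  # bounds hold under arbitrary update sequences
  for (i in 1:50) {
    W <- instar_update(W, runif(6), runif(2), R = sample(c(-1, 1), 1))
    expect_true(all(W >= 0 & W <= 1))
  }
})

test_that("outstar copies the preparation pattern and redistributes on failure", {
  n_prp <- 10
  f_prp <- c(rep(0, 4), 0.9, 1, 0.9, rep(0, 3))   # selected reach pattern
  f_asc <- c(1, 0, 0.5)
  W <- matrix(0.1, 3, n_prp)
  Wn <- W
  for (i in 1:150) Wn <- outstar_update(Wn, f_asc, f_prp, R = 1)
  expect_equal(Wn[1, ], f_prp, tolerance = 1e-6)    # active site copies pattern
  expect_equal(Wn[2, ], rep(0.1, n_prp))            # presynaptic gating
  # failure: weights to the active region drop, some inactive target grows,
  # and each active source's total outgoing weight is preserved
  Wm <- matrix(0.3, 3, n_prp)
  Wf <- outstar_update(Wm, f_asc, f_prp, R = -1)
  expect_lt(Wf[1, 6], Wm[1, 6])
  expect_true(any(Wf[1, f_prp < 0.1] > Wm[1, f_prp < 0.1]))
  expect_equal(sum(Wf[1, ]), sum(Wm[1, ]), tolerance = 1e-10)
})

test_that("per-trial learning respects the learning flag and gating", {
  set.seed(4)
  m <- init_model(fast_cfg())
  fake <- list(f_asc = runif(m$cfg$lattice$n_x * m$cfg$lattice$n_y) *
                 (runif(m$cfg$lattice$n_x * m$cfg$lattice$n_y) > 0.98),
               f_ctx = c(1, 0), f_prp = gauss_bump(m$pre$lat_x, 90),
               R = 1, aborted = FALSE)
  m_off <- apply_trial_learning(m, fake, learn = FALSE)
  expect_identical(m_off$W_ca, m$W_ca)
  expect_identical(m_off$W_ap, m$W_ap)
  m_on <- apply_trial_learning(m, fake, learn = TRUE)
  # only columns/rows touched by active sites change
  act <- fake$f_asc > 0
  expect_true(all(m_on$W_ca[, !act] == m$W_ca[, !act]))
  expect_true(any(m_on$W_ca[, act] != m$W_ca[, act]))
  expect_true(all(m_on$W_ap[!act, ] == m$W_ap[!act, ]))
})

test_that("failure increases the chance of a different response next time", {
  # repeated punishment of the same outgoing pattern must strictly reduce
  # the drive toward the punished reach relative to alternatives
  f_prp <- gauss_bump(make_lattice(90, 360, TRUE), 270)
  f_asc <- c(1)
  # outgoing pattern partially aligned with the punished reach
  W <- matrix(0.8 * f_prp + 0.05, 1)
  drive0 <- W[1, ] %*% f_prp
  for (i in 1:10) W <- outstar_update(W, f_asc, f_prp, R = -1)
  expect_lt(W[1, ] %*% f_prp, drive0)
  # mass moved toward previously silent directions
  expect_gt(sum(W[1, f_prp < 0.1]), 0)
})
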