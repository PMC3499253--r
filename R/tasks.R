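#' Target-cue fade schedule
#'
#' Salience of the target cue during inferred-reach (IR) training, reduced
#' linearly from 1 to 0 over the training session.
#'
#' @param k Trial counter (0-based).
#' @param n_trials Schedule length.
#' @return Salience in `[0, 1]`; `fade(0) = 1`, `fade(n_trials) = 0`.
#' @export
fade <- function(k, n_trials) pmax(0, pmin(1, 1 - k / n_trials))

# epoch timeline (0-based step indices) for a task kind
trial_timeline <- function(cfg, task) {
  tm <- cfg$timing
  cue_t0 <- tm$settle
  cue_t1 <- cue_t0 + tm$cue
  mem_t1 <- cue_t1 + tm$memory
  tl <- list(cue_t0 = cue_t0, cue_t1 = cue_t1, mem_t0 = cue_t1, mem_t1 = mem_t1)
  if (task == "IR") {
    # target cue comes up at the end of the memory period; the go signal
    # follows its presentation directly and the cue stays visible through
    # movement selection (the trained reach is to the shown target)
    tl$target_t0 <- mem_t1
    tl$go_t0 <- mem_t1 + tm$target
    tl$target_t1 <- tl$go_t0 + tm$go
  } else if (task == "DMG") {
    tl$go_t0 <- mem_t1
  } else { # PMG-CI / PMG-NC: context-instruction (or silent) epoch, then go
    tl$ci_t0 <- mem_t1; tl$ci_t1 <- mem_t1 + tm$ci
    tl$go_t0 <- tl$ci_t1
  }
  tl$n_steps <- tl$go_t0 + tm$go
  tl$snap_t0 <- tl$go_t0 + floor(tm$go / 2)   # post-go selection window
  tl$snap_t1 <- tl$n_steps
  tl
}

#' Construct an IR training trial
#'
#' The context is drawn with the configured inferred fraction (for more
#' than two contexts the non-zero-rotation contexts share that fraction
#' equally), the spatial cue is uniform over the trained directions, and a
#' target cue at the rewarded goal is shown at the end of the memory period
#' with salience `fade(k - 1, n_trials - 1)`; the go signal follows the
#' target cue directly.
#'
#' @param k Trial index (1-based).
#' @param cfg Model configuration.
#' @param n_trials Session length (sets the fade schedule).
#' @param p_inferred Total probability of non-direct contexts.
#' @param dirs Cue directions to sample from.
#' @return A `trial_spec` list.
#' @export
make_ir_trial <- function(k, cfg, n_trials = 1000, p_inferred = 0.8,
                          dirs = cfg$trained_dirs) {
  nc <- cfg$n_contexts
  p <- c(1 - p_inferred, rep(p_inferred / (nc - 1), nc - 1))
  context <- sample.int(nc, 1, prob = p)
  cue <- sample(dirs, 1)
  goal <- wrap_dir(cue + cfg$rotations[context])
  structure(list(task = "IR", cue_dir = cue, context = context, goal = goal,
                 goals = goal, salience = fade(k - 1, n_trials - 1)),
            class = "trial_spec")
}

#' Construct a DMG probe trial
#'
#' Spatial and contextual cue are presented simultaneously and briefly at
#' the beginning of the memory period; contexts and cue directions are
#' equiprobable. DMG sessions probe the network state: the session runner
#' forces learning off.
#'
#' @param cfg Model configuration.
#' @param dirs Cue directions to sample from.
#' @param contexts Context indices to sample from.
#' @return A `trial_spec`.
#' @export
make_dmg_trial <- function(cfg, dirs = cfg$trained_dirs,
                           contexts = seq_len(cfg$n_contexts)) {
  context <- if (length(contexts) == 1) contexts else sample(contexts, 1)
  cue <- if (length(dirs) == 1) dirs else sample(dirs, 1)
  goal <- wrap_dir(cue + cfg$rotations[context])
  structure(list(task = "DMG", cue_dir = cue, context = context, goal = goal,
                 goals = goal, salience = 0), class = "trial_spec")
}

#' Construct a PMG trial (context instruction or free choice)
#'
#' The spatial cue comes first; in PMG-CI the contextual cue is delivered
#' at the end of the memory period and resolves the ambiguity between the
#' two potential goals, in PMG-NC no context is ever shown and the trial
#' carries both potential goals (cue and cue + 180 for the two-rule
#' model); which one is rewarded is decided by the reward schedule.
#'
#' @param kind `"CI"` or `"NC"`.
#' @param cfg Model configuration.
#' @param dirs Cue directions to sample from.
#' @return A `trial_spec`.
#' @export
make_pmg_trial <- function(kind = c("CI", "NC"), cfg,
                           dirs = cfg$trained_dirs) {
  kind <- match.arg(kind)
  cue <- if (length(dirs) == 1) dirs else sample(dirs, 1)
  if (kind == "CI") {
    context <- sample.int(2, 1)   # direct vs inferred instruction
    goal <- wrap_dir(cue + cfg$rotations[context])
    structure(list(task = "PMG-CI", cue_dir = cue, context = context,
                   goal = goal, goals = goal, salience = 0),
              class = "trial_spec")
  } else {
    goals <- wrap_dir(cue + cfg$rotations[1:2])   # {cue, cue + 180}
    structure(list(task = "PMG-NC", cue_dir = cue, context = NA_integer_,
                   goal = NA_real_, goals = goals, salience = 0),
              class = "trial_spec")
  }
}

#' Equal-probability reward schedule draw
#'
#' Both potential goals of a free-choice trial are rewarded with equal
#' probability, independent of history and of the model's choices.
#'
#' @param spec A PMG-NC `trial_spec`.
#' @return The rewarded goal direction.
#' @export
eprs_draw <- function(spec) {
  stopifnot(spec$task == "PMG-NC")
  spec$goals[sample.int(length(spec$goals), 1)]
}

#' Bias-minimizing reward schedule
#'
#' `bmrs_state()` creates the schedule state: a sliding window (default 20)
#' of the goal indices chosen on recent free-choice trials.
#' `bmrs_update_and_draw()` sets each goal's reward probability to one
#' minus that goal's fraction in the window (renormalized over the two
#' goals), punishing any behavioral bias, and draws the rewarded goal; an
#' empty window falls back to 50:50. At balanced behavior both
#' probabilities are 0.5, which is the reward-maximizing policy.
#' `bmrs_record()` appends a choice to the window.
#'
#' @param window_size Number of recent free choices tracked.
#' @return `bmrs_state()`: a `bmrs_state` list; `bmrs_update_and_draw()`:
#'   a list with `goal` (rewarded direction) and `probs` (per-goal reward
#'   probability); `bmrs_record()`: the updated state.
#' @export
bmrs_state <- function(window_size = 20) {
  structure(list(window = integer(0), size = window_size), class = "bmrs_state")
}

#' @rdname bmrs_state
#' @param state A `bmrs_state`.
#' @param spec A PMG-NC `trial_spec`.
#' @param gamma Punishment steepness: raw per-goal reward odds are
#'   `(1 - choice fraction)^gamma` before renormalization. `gamma = 1`
#'   is a linear penalty; larger values punish a strong bias harder while
#'   leaving the balanced point (all fractions equal) at even odds.
#' @export
bmrs_update_and_draw <- function(state, spec, gamma = 2) {
  stopifnot(spec$task == "PMG-NC")
  k <- length(spec$goals)
  if (length(state$window) == 0) {
    probs <- rep(1 / k, k)
  } else {
    frac <- tabulate(state$window, nbins = k) / length(state$window)
    raw <- (1 - frac)^gamma
    probs <- if (sum(raw) > 0) raw / sum(raw) else rep(1 / k, k)
  }
  goal <- spec$goals[sample.int(k, 1, prob = probs)]
  list(goal = goal, probs = probs)
}

#' @rdname bmrs_state
#' @param choice Index of the chosen goal (into `spec$goals`).
#' @export
bmrs_record <- function(state, choice) {
  state$window <- c(state$window, as.integer(choice))
  if (length(state$window) > state$size)
    state$window <- state$window[-1]
  state
}

# build the stimulus schedule of a trial for the integrator
build_schedule <- function(cfg, pre, spec) {
  tl <- trial_timeline(cfg, spec$task)
  st <- cfg$stim
  bumps <- list(input_bump(pre$lat_x, spec$cue_dir, st$amp_spt, st$sigma_spt))
  wins <- matrix(c(tl$cue_t0, tl$cue_t1), 1, 2)
  ctx_stim <- matrix(numeric(0), 0, 4)
  if (spec$task %in% c("IR", "DMG")) {
    ctx_stim <- matrix(c(spec$context - 1, st$amp_ctx, tl$cue_t0, tl$cue_t1), 1, 4)
  } else if (spec$task == "PMG-CI") {
    ctx_stim <- matrix(c(spec$context - 1, st$amp_ctx, tl$ci_t0, tl$ci_t1), 1, 4)
  }
  if (spec$task == "IR" && spec$salience > 0) {
    bumps <- c(bumps, list(input_bump(pre$lat_x, spec$goal,
                                      st$amp_spt * spec$salience, st$sigma_spt)))
    wins <- rbind(wins, c(tl$target_t0, tl$target_t1))
  }
  list(tl = tl, bump_mat = do.call(cbind, bumps), bump_win = wins,
       ctx_stim = ctx_stim)
}

#' Run one trial
#'
#' Steps the model through the trial's stimulus timeline (cue inputs,
#' context input, target cue at its salience, go gate), reads out the
#' response from the motor field, realizes the reward against the trial's
#' rewarded goal, and (if enabled) applies the per-trial learning step
#' from output snapshots averaged over the post-go selection window. A
#' trial without a suprathreshold motor response before trial end is
#' logged as aborted and triggers no learning.
#'
#' @param model A `dnf_model`.
#' @param spec A `trial_spec`. For free-choice trials the realized rewarded
#'   goal must be supplied in `spec$rewarded_goal` (drawn by the session's
#'   reward schedule).
#' @param learn Apply the learning rules after the trial?
#' @param trace Record the preparation-field output over time (decimated)?
#' @param trace_stride Steps between trace samples.
#' @param engine `"cpp"` (compiled integrator) or `"R"` (reference
#'   implementation; identical dynamics, used for validation).
#' @return A `trial_result` list: the spec, `reach` (deg or `NA`),
#'   `reward`, `aborted`, `tie`, `choice` (index of the chosen goal),
#'   output snapshots, the updated model under `$model`, and optionally
#'   `trace` (preparation output, sites x time) with `trace_times`.
#' @export
run_trial <- function(model, spec, learn = TRUE, trace = FALSE,
                      trace_stride = 10, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  cfg <- model$cfg
  model <- reset_fields(model)
  sch <- build_schedule(cfg, model$pre, spec)
  tl <- sch$tl
  if (engine == "cpp") {
    par <- cpp_par(cfg)
    seed <- 0L  # unused: compiled path draws noise from R's RNG
    st <- model[c("u_spt", "u_ctx", "u_asc", "u_prp", "u_mot", "W_ca")]
    st$W_ap_t <- t(model$W_ap)
    res <- sim_trial_cpp(st,
                         model$pre[c("k_spt", "k_prp", "k_mot", "asc_px",
                                     "asc_py", "p_spt_prp", "p_spt_asc",
                                     "p_prp_mot", "p_mot_prp", "area")],
                         par, sch$bump_mat, sch$bump_win, sch$ctx_stim,
                         tl$go_t0, tl$n_steps, cfg$dt, tl$snap_t0, tl$snap_t1,
                         if (trace) trace_stride else 0L, seed)
  } else {
    res <- sim_trial_r(model, sch, trace, trace_stride)
  }
  model$u_spt <- as.numeric(res$u_spt); model$u_ctx <- as.numeric(res$u_ctx)
  model$u_asc <- matrix(res$u_asc, cfg$lattice$n_x, cfg$lattice$n_y)
  model$u_prp <- as.numeric(res$u_prp); model$u_mot <- as.numeric(res$u_mot)

  rr <- read_response(as.numeric(res$f_mot), model$pre$lat_x,
                      cfg$learn$theta, cfg$learn$smooth_sigma)
  aborted <- is.na(rr$dir)
  rewarded_goal <- if (spec$task == "PMG-NC") spec$rewarded_goal else spec$goal
  # free-choice specs probed without a schedule draw carry no rewarded goal
  if (is.null(rewarded_goal)) rewarded_goal <- NA_real_
  reward <- if (aborted || is.na(rewarded_goal)) NA_integer_ else
    evaluate_reward(rr$dir, rewarded_goal, cfg$learn$tolerance)
  choice <- if (aborted) NA_integer_ else
    which.min(circ_dist(rr$dir, spec$goals))
  out <- list(spec = spec, reach = rr$dir, tie = rr$tie, reward = reward,
              aborted = aborted, choice = choice,
              rewarded_goal = rewarded_goal,
              f_asc = as.numeric(res$f_asc), f_ctx = as.numeric(res$f_ctx),
              f_prp = as.numeric(res$f_prp), f_mot = as.numeric(res$f_mot))
  class(out) <- "trial_result"
  if (!aborted && !is.na(reward) && isTRUE(learn)) {
    tr <- list(f_asc = out$f_asc, f_ctx = out$f_ctx, f_prp = out$f_prp,
               R = reward, aborted = FALSE)
    model <- apply_trial_learning(model, tr, learn = TRUE)
  }
  if (trace) {
    nr <- res$n_rec
    out$trace <- matrix(res$trace_prp, nrow = cfg$lattice$n_x)[, seq_len(nr),
                                                               drop = FALSE]
    out$trace_times <- (seq_len(nr) - 1) * trace_stride
    out$timeline <- tl
  }
  out$model <- model
  out
}

# flat parameter list for the compiled integrator
cpp_par <- function(cfg) {
  f <- cfg$fields
  list(tau = c(f$spt$tau, cfg$ctx$tau, f$asc$tau, f$prp$tau, f$mot$tau),
       h = c(f$spt$h, cfg$ctx$h, f$asc$h, f$prp$h, f$mot$h),
       q = c(f$spt$q, cfg$ctx$q, f$asc$q, f$prp$q, f$mot$q),
       beta = c(f$spt$beta, cfg$ctx$beta, f$asc$beta, f$prp$beta, f$mot$beta),
       w_self = cfg$ctx$w_self, w_mut = cfg$ctx$w_mut,
       g_ctx_asc = cfg$proj$g_ctx_asc, g_asc_prp = cfg$proj$g_asc_prp,
       g_mot_prp_inh = cfg$proj$g_mot_prp_inh, g_go = cfg$proj$g_go,
       asc_a_exc = f$asc$a_exc, asc_g_inh = f$asc$g_inh)
}

# reference R integrator over a prebuilt schedule (mirrors sim_trial_cpp)
sim_trial_r <- function(model, sch, trace = FALSE, trace_stride = 10) {
  cfg <- model$cfg
  tl <- sch$tl
  snap <- list(f_ctx = 0, f_asc = 0, f_prp = 0, f_mot = 0)
  snap_n <- 0
  tr <- NULL; tr_i <- 0
  if (trace) tr <- matrix(0, cfg$lattice$n_x,
                          ceiling(tl$n_steps / trace_stride))
  for (t in seq_len(tl$n_steps) - 1L) {
    active <- which(sch$bump_win[, 1] <= t & t < sch$bump_win[, 2])
    spt <- if (length(active))
      list(profile = rowSums(sch$bump_mat[, active, drop = FALSE])) else NULL
    ctx <- numeric(cfg$n_contexts)
    if (nrow(sch$ctx_stim) > 0) {
      for (b in seq_len(nrow(sch$ctx_stim)))
        if (sch$ctx_stim[b, 3] <= t && t < sch$ctx_stim[b, 4])
          ctx[sch$ctx_stim[b, 1] + 1] <- ctx[sch$ctx_stim[b, 1] + 1] +
            sch$ctx_stim[b, 2]
    }
    stimuli <- list(ctx = ctx, go = t >= tl$go_t0,
                    spt_profile = spt$profile)
    model <- step_model(model, stimuli, cfg$dt)
    if (t >= tl$snap_t0 && t < tl$snap_t1) {
      o <- model_outputs(model)
      snap$f_ctx <- snap$f_ctx + o$ctx; snap$f_asc <- snap$f_asc + o$asc
      snap$f_prp <- snap$f_prp + o$prp; snap$f_mot <- snap$f_mot + o$mot
      snap_n <- snap_n + 1
    }
    if (trace && t %% trace_stride == 0) {
      tr_i <- tr_i + 1
      tr[, tr_i] <- model_outputs(model)$prp
    }
  }
  if (snap_n > 0) snap <- lapply(snap, function(x) x / snap_n)
  c(model[c("u_spt", "u_ctx", "u_asc", "u_prp", "u_mot")],
    list(f_ctx = snap$f_ctx, f_asc = snap$f_asc, f_prp = snap$f_prp,
         f_mot = snap$f_mot, trace_prp = tr, n_rec = tr_i))
}

#' Session configuration
#'
#' Describes a block of trials run with persistent model and schedule
#' state. Kinds: `"ir"` (IR training with fading target cue), `"dmg"`
#' (definite motor-goal probes, learning forced off), `"generalize"`
#' (DMG-style probes at novel cue directions, learning off), `"pmg"`
#' (mixture of free-choice PMG-NC and instructed PMG-CI trials under a
#' reward schedule).
#'
#' @param kind Session kind (above).
#' @param n_trials Number of trials.
#' @param p_inferred IR only: total fraction of non-direct-context trials.
#' @param nc_ratio PMG only: fraction of free-choice (NC) trials.
#' @param schedule PMG only: `"eprs"` or `"bmrs"`.
#' @param learn Learning flag (ignored for dmg/generalize, always off).
#' @param dirs Cue directions (defaults to the trained directions).
#' @param contexts dmg/generalize: context indices to sample.
#' @param window_size BMRS sliding-window length.
#' @return A `session_config` list.
#' @export
session_config <- function(kind = c("ir", "dmg", "generalize", "pmg"),
                           n_trials = 400, p_inferred = 0.8, nc_ratio = 0.4,
                           schedule = c("eprs", "bmrs"), learn = NULL,
                           dirs = NULL, contexts = NULL, window_size = 20,
                           bmrs_gamma = 2) {
  kind <- match.arg(kind)
  schedule <- match.arg(schedule)
  stopifnot(n_trials >= 1, p_inferred >= 0, p_inferred <= 1,
            nc_ratio >= 0, nc_ratio <= 1)
  if (is.null(learn)) learn <- switch(kind, ir = TRUE, pmg = FALSE,
                                      dmg = FALSE, generalize = FALSE)
  if (kind %in% c("dmg", "generalize") && isTRUE(learn))
    learn <- FALSE   # probe sessions never change the weights
  structure(list(kind = kind, n_trials = as.integer(n_trials),
                 p_inferred = p_inferred, nc_ratio = nc_ratio,
                 schedule = schedule, learn = learn, dirs = dirs,
                 contexts = contexts, window_size = window_size,
                 bmrs_gamma = bmrs_gamma),
            class = "session_config")
}

#' Run a session of trials
#'
#' Trials are run sequentially with persistent model weights and reward
#' schedule state. All randomness (trial draws, schedule draws, field
#' noise) flows from R's RNG, so a session is reproducible from
#' `(config, seed)`.
#'
#' @param model A `dnf_model`.
#' @param session A [session_config()].
#' @param trace Record preparation-field traces per trial?
#' @param trace_stride Steps between trace samples.
#' @return A list with the updated `model`, the trial `log` (one data
#'   frame row per trial), `traces` (list, if requested) and the final
#'   BMRS `bmrs` state.
#' @export
run_session <- function(model, session, trace = FALSE, trace_stride = 10) {
  cfg <- model$cfg
  n <- session$n_trials
  dirs <- session$dirs %||% cfg$trained_dirs
  contexts <- session$contexts %||% seq_len(cfg$n_contexts)
  logs <- vector("list", n)
  traces <- if (trace) vector("list", n) else NULL
  bstate <- bmrs_state(session$window_size)
  for (i in seq_len(n)) {
    spec <- switch(session$kind,
      ir = make_ir_trial(i, cfg, n, session$p_inferred, dirs),
      dmg = make_dmg_trial(cfg, dirs, contexts),
      generalize = make_dmg_trial(cfg, dirs, contexts),
      pmg = if (runif(1) < session$nc_ratio)
        make_pmg_trial("NC", cfg, dirs) else make_pmg_trial("CI", cfg, dirs))
    p_rew <- NA_real_
    if (spec$task == "PMG-NC") {
      if (session$schedule == "bmrs") {
        d <- bmrs_update_and_draw(bstate, spec, session$bmrs_gamma)
        spec$rewarded_goal <- d$goal
        p_rew <- d$probs[1]
      } else {
        spec$rewarded_goal <- eprs_draw(spec)
        p_rew <- 0.5
      }
    }
    res <- run_trial(model, spec, learn = session$learn, trace = trace,
                     trace_stride = trace_stride)
    model <- res$model
    if (spec$task == "PMG-NC" && !res$aborted)
      bstate <- bmrs_record(bstate, res$choice)
    logs[[i]] <- data.frame(
      trial = i, task = spec$task, cue_dir = spec$cue_dir,
      context = spec$context %||% NA_integer_,
      goal_dir = spec$goal, rewarded_goal = res$rewarded_goal %||% NA_real_,
      reach_dir = res$reach, reward = res$reward, aborted = res$aborted,
      tie = res$tie, choice = res$choice %||% NA_integer_,
      salience = spec$salience, p_reward_1 = p_rew)
    if (trace) traces[[i]] <- res[c("trace", "trace_times", "timeline")]
  }
  list(model = model, log = do.call(rbind, logs), traces = traces,
       bmrs = bstate)
}

#' Fraction of correct, non-aborted trials in a session log
#'
#' Aborted trials are excluded from the denominator and reported
#' separately.
#'
#' @param log A session log.
#' @return List with `percent_correct`, `n_scored`, `n_aborted`.
#' @export
session_performance <- function(log) {
  scored <- log[!log$aborted, , drop = FALSE]
  list(percent_correct = 100 * mean(scored$reward == 1),
       n_scored = nrow(scored), n_aborted = sum(log$aborted))
}
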