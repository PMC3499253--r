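#' Classify generalization errors
#'
#' Each scored reach is classified by its circular deviation from the
#' rewarded goal: `correct` within the reward tolerance; `context_error`
#' at a deviation of about 180 degrees (the direct reach performed in an
#' inferred trial); `adjacent_direction_error` at a deviation of about 45
#' degrees landing on a trained direction; everything else `other`.
#' Deviations are also binned on the task's 45-degree grid.
#'
#' @param log A session log from [run_session()].
#' @param trained_dirs Trained cue directions.
#' @param tolerance Reward tolerance (deg).
#' @param approx_window Half-width of the "about 45 / 180 degrees" windows.
#' @return A list with `classes` (per-trial factor), `proportions`
#'   (named, sums to 1 over scored trials), and `deviation_hist`
#'   (counts per 45-degree bin of signed deviation).
#' @export
classify_errors <- function(log, trained_dirs = c(0, 90, 180, 270),
                            tolerance = 8, approx_window = 10) {
  scored <- log[!log$aborted, , drop = FALSE]
  dev <- (scored$reach_dir - scored$goal_dir) %% 360
  dev <- ifelse(dev > 180, dev - 360, dev)    # signed deviation in (-180, 180]
  absdev <- abs(dev)
  near_trained <- vapply(scored$reach_dir, function(r)
    min(circ_dist(r, trained_dirs)) <= approx_window, TRUE)
  cls <- ifelse(absdev <= tolerance, "correct",
         ifelse(abs(absdev - 180) <= approx_window, "context_error",
         ifelse(abs(absdev - 45) <= approx_window & near_trained,
                "adjacent_direction_error", "other")))
  cls <- factor(cls, levels = c("correct", "context_error",
                                "adjacent_direction_error", "other"))
  bins <- seq(-180, 180, by = 45)
  bin <- bins[vapply(dev, function(d) which.min(abs(d - bins)), 1L)]
  bin[bin == -180] <- 180
  prop <- table(cls) / max(1L, length(cls))
  list(classes = cls,
       proportions = stats::setNames(as.numeric(prop), names(prop)),
       deviation_hist = table(factor(bin, levels = seq(-135, 180, by = 45))),
       deviation = dev)
}

#' Fraction of inferred choices in free-choice trials
#'
#' @param log A session log containing PMG-NC trials.
#' @return List with `frac_inferred`, `frac_direct` (over scored NC
#'   trials) and `n`.
#' @export
choice_fractions <- function(log) {
  nc <- log[log$task == "PMG-NC" & !log$aborted, , drop = FALSE]
  list(frac_inferred = mean(nc$choice == 2), frac_direct = mean(nc$choice == 1),
       n = nrow(nc))
}

#' Sweep the training input statistics
#'
#' For each training inferred-fraction, trains a fresh model on the IR
#' task, then probes free-choice behavior (PMG-NC under the
#' equal-probability schedule, learning off) and the memory-period
#' activation difference between the preferred (inferred) and
#' opposite-to-preferred goal representation in the motor preparation
#' field.
#'
#' @param fractions Grid of inferred-training fractions in `[0, 1]`.
#' @param cfg Base model configuration.
#' @param n_train IR training trials per fraction.
#' @param n_probe Free-choice probe trials per fraction.
#' @return A data frame (`bias_curve`): `fraction`, `frac_inferred` (NC
#'   inferred-choice fraction), `act_diff` (mean memory-period PD - OD
#'   preparation output).
#' @export
sweep_training_ratio <- function(fractions, cfg, n_train = 1000,
                                 n_probe = 100) {
  rows <- lapply(fractions, function(fr) {
    model <- init_model(cfg)
    tr <- run_session(model, session_config("ir", n_train, p_inferred = fr))
    pr <- run_session(tr$model,
                      session_config("pmg", ceiling(n_probe / 0.4),
                                     nc_ratio = 0.4, schedule = "eprs",
                                     learn = FALSE),
                      trace = TRUE)
    cf <- choice_fractions(pr$log)
    ad <- memory_activation_diff(pr$log, pr$traces, tr$model$pre$lat_x)
    data.frame(fraction = fr, frac_inferred = cf$frac_inferred,
               act_diff = ad, n_nc = cf$n)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bias_curve", class(out))
  out
}

# mean memory-period preparation output at the inferred goal minus at the
# direct goal, over NC trials
memory_activation_diff <- function(log, traces, lat_x) {
  idx <- which(log$task == "PMG-NC")
  if (!length(idx)) return(NA_real_)
  diffs <- vapply(idx, function(i) {
    tr <- traces[[i]]
    if (is.null(tr$trace)) return(NA_real_)
    mem <- tr$trace_times >= tr$timeline$mem_t0 & tr$trace_times < tr$timeline$mem_t1
    prof <- rowMeans(tr$trace[, mem, drop = FALSE])
    cue <- log$cue_dir[i]
    i_dir <- which.min(circ_dist(lat_x$pos, cue))
    i_inf <- which.min(circ_dist(lat_x$pos, cue + 180))
    prof[i_inf] - prof[i_dir]
  }, 0)
  mean(diffs, na.rm = TRUE)
}

#' Fit a logistic choice curve
#'
#' Least-squares fit of `L(x) = 1 / (1 + exp(-beta (x - m)))` to a bias
#' curve (choice fraction vs. training fraction); `fit_scaled_sigmoid()`
#' fits `a L(x) + b` for the activation curve. Both use a coarse grid
#' search followed by `optim` refinement, which is robust for the small
#' grids produced by [sweep_training_ratio()].
#'
#' @param x Predictor values (training inferred fraction), >= 5 points.
#' @param y Observed values.
#' @return List with `m`, `beta` (and `a`, `b` for the scaled fit) and
#'   `mse`.
#' @export
fit_logistic <- function(x, y) {
  check_curve(x, y)
  obj <- function(p) mean((plogis(p[2] * (x - p[1])) - y)^2)
  p0 <- grid_start(obj, ms = seq(min(x), max(x), length.out = 25),
                   betas = c(2, 5, 10, 20, 40, 80))
  fit <- stats::optim(p0, obj)
  list(m = fit$par[1], beta = fit$par[2], mse = fit$value)
}

#' @rdname fit_logistic
#' @export
fit_scaled_sigmoid <- function(x, y) {
  check_curve(x, y)
  obj <- function(p) {
    l <- plogis(p[2] * (x - p[1]))
    mean((p[3] * l + p[4] - y)^2)
  }
  rng <- diff(range(y))
  p0 <- NULL; best <- Inf
  for (m in seq(min(x), max(x), length.out = 15))
    for (b in c(2, 5, 10, 20, 40)) {
      p <- c(m, b, rng, min(y))
      v <- obj(p)
      if (v < best) { best <- v; p0 <- p }
    }
  fit <- stats::optim(p0, obj, control = list(maxit = 2000))
  list(m = fit$par[1], beta = fit$par[2], a = fit$par[3], b = fit$par[4],
       mse = fit$value)
}

check_curve <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need at least 5 grid points")
  if (diff(range(y)) < 1e-12) stop("degenerate (constant) curve")
  invisible(TRUE)
}

grid_start <- function(obj, ms, betas) {
  best <- Inf; p0 <- c(ms[1], betas[1])
  for (m in ms) for (b in betas) {
    v <- obj(c(m, b))
    if (v < best) { best <- v; p0 <- c(m, b) }
  }
  p0
}

#' PD/OD-aligned pseudo-population trace
#'
#' Builds the averaged, normalized preparation-field output over
#' (direction relative to preferred direction) x time. Each field site's
#' preferred direction (PD) is estimated from DMG probe trials as the cue
#' direction maximizing its mean memory-period output (ties broken by the
#' first maximum); for the topographic preparation field this recovers the
#' site's own direction label. Traces are re-indexed so each site's PD
#' maps to offset 0, normalized per site to its maximum over the session,
#' and averaged across trials.
#'
#' @param log Session log with traces recorded.
#' @param traces Trace list from [run_session()].
#' @param lat_x Direction lattice of the model.
#' @param pd Optional precomputed per-site PD (degrees); default aligns
#'   each site to the trial's inferred goal (cue + 180), matching
#'   DMG-estimated PDs for an IR-trained model probed with NC trials.
#' @param tasks Which tasks' trials enter the average.
#' @return A list: `trace` (offset x time matrix, values in `[0, 1]`),
#'   `offsets` (deg relative to PD), `times`, `timeline`.
#' @export
population_trace <- function(log, traces, lat_x, pd = NULL,
                             tasks = c("PMG-NC", "PMG-CI")) {
  idx <- which(log$task %in% tasks & !vapply(traces, function(t)
    is.null(t$trace), TRUE))
  if (!length(idx)) stop("no traces recorded for the requested tasks")
  n_x <- lat_x$n
  acc <- 0; n_acc <- 0
  for (i in idx) {
    tr <- traces[[i]]$trace
    # align: PD of each site = its direction label; rotate so the trial's
    # inferred goal (the PD of sites representing it) is at offset 0
    ref <- if (is.null(pd)) wrap_dir(log$cue_dir[i] + 180) else pd
    shift <- which.min(circ_dist(lat_x$pos, ref)) - 1L
    rot <- tr[((seq_len(n_x) - 1L + shift) %% n_x) + 1L, , drop = FALSE]
    mx <- max(rot)
    if (mx > 0) rot <- rot / mx
    acc <- acc + rot; n_acc <- n_acc + 1
  }
  avg <- acc / n_acc
  offs <- lat_x$pos
  offs[offs > 180] <- offs[offs > 180] - 360
  list(trace = avg, offsets = offs, times = traces[[idx[1]]]$trace_times,
       timeline = traces[[idx[1]]]$timeline, n_trials = n_acc)
}

#' Count stable memory-period ridges in a population trace
#'
#' Counts the connected regions (along the direction offset) whose mean
#' memory-period activation exceeds a threshold fraction of the trace
#' maximum: one ridge signals a biased representation (single prepared
#' goal), two ridges a balanced representation of both potential goals.
#'
#' @param pt A [population_trace()] result.
#' @param thresh Threshold as a fraction of the trace maximum.
#' @return Integer number of ridges.
#' @export
count_memory_ridges <- function(pt, thresh = 0.4) {
  mem <- pt$times >= pt$timeline$mem_t0 & pt$times < pt$timeline$mem_t1
  prof <- rowMeans(pt$trace[, mem, drop = FALSE])
  count_peaks(prof / max(prof), thresh)
}
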