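#' Read the selected reach direction from the motor field
#'
#' A response is declared iff the circularly smoothed motor-field output
#' exceeds the response threshold `theta` somewhere. The reach direction is
#' the circular centroid of the tallest connected above-threshold region;
#' an exact tie between equally tall regions is broken by a uniform random
#' pick (using the session RNG) and flagged in the result.
#'
#' @param f_mot Motor field output vector (values in (0,1)).
#' @param lattice The circular direction lattice.
#' @param theta Response threshold (output units).
#' @param smooth_sigma Gaussian smoothing width in degrees.
#' @return A list with `dir` (degrees, or `NA` for no response) and
#'   `tie` (logical).
#' @export
read_response <- function(f_mot, lattice, theta = 0.5, smooth_sigma = 4) {
  sm <- circ_conv(f_mot, unit_profile(lattice, smooth_sigma))
  if (max(sm) <= theta) return(list(dir = NA_real_, tie = FALSE))
  above <- sm > theta
  # label circular connected segments
  n <- length(sm)
  seg <- integer(n)
  lab <- 0L
  prev_above <- FALSE
  for (i in seq_len(n)) {
    if (above[i]) {
      if (!prev_above) lab <- lab + 1L
      seg[i] <- lab
    }
    prev_above <- above[i]
  }
  if (above[1] && above[n] && seg[1] != seg[n])
    seg[seg == seg[1]] <- seg[n]   # merge wrap-around segment
  segs <- unique(seg[seg > 0])
  heights <- vapply(segs, function(sg) max(sm[seg == sg]), 0)
  best <- which(heights >= max(heights) - 1e-9)   # numerically exact tie
  tie <- length(best) > 1
  pick <- segs[if (tie) best[sample.int(length(best), 1)] else best]
  idx <- which(seg == pick)
  w <- sm[idx]
  ang <- lattice$pos[idx] * pi / 180
  dir <- atan2(sum(w * sin(ang)), sum(w * cos(ang))) * 180 / pi
  list(dir = wrap_dir(dir), tie = tie)
}

#' Evaluate the reward signal for a reach
#'
#' The trial is a success (`R = +1`) iff the circular distance between the
#' reach and the rewarded goal direction is within the tolerance window
#' (inclusive, default 8 degrees), and a failure (`R = -1`) otherwise.
#'
#' @param reach Reach direction, degrees.
#' @param goal Rewarded goal direction, degrees.
#' @param tolerance Half-width of the reward window, degrees.
#' @return `+1` or `-1`.
#' @export
evaluate_reward <- function(reach, goal, tolerance = 8) {
  stopifnot(is.finite(reach), is.finite(goal))
  if (circ_dist(reach, goal) <= tolerance) 1 else -1
}

#' Reward-dependent instar update (context -> association weights)
#'
#' For a rewarded trial (`R = +1`) the incoming weights of active
#' association sites move toward the current context-node output pattern:
#' `dW(c,x) = eps_pos * f_asc(x) * (f_ctx(c) - W(c,x))`. Only sites with
#' non-zero association output change (postsynaptic gating); there is no
#' competition between sites, so multiple regions can acquire a preference
#' for the same context. For a failed trial (`R = -1`) weights between
#' co-active pairs are decreased, `dW = -eps_neg * N * f_asc * f_ctx * W`,
#' with a per-trial normalization `N` that makes the summed weight change
#' comparable in magnitude to a rewarded trial with the same outputs.
#' Weights are clipped to `[0, w_max]`.
#'
#' @param W_ca Weight matrix, contexts x association sites.
#' @param f_asc Association output snapshot (vector over sites).
#' @param f_ctx Context-node output snapshot.
#' @param R Reward signal, +1 or -1.
#' @param eps_pos,eps_neg Learning rates, `eps_pos > eps_neg > 0`.
#' @param w_max Upper weight bound.
#' @return Updated weight matrix.
#' @export
instar_update <- function(W_ca, f_asc, f_ctx, R, eps_pos = 0.1,
                          eps_neg = 0.06, w_max = 1) {
  fa <- matrix(f_asc, nrow = nrow(W_ca), ncol = length(f_asc), byrow = TRUE)
  pos_form <- fa * (f_ctx - W_ca)     # target-tracking term of the instar rule
  if (R > 0) {
    W <- W_ca + eps_pos * pos_form
  } else {
    neg_form <- fa * f_ctx * W_ca
    denom <- sum(abs(neg_form))
    N <- if (denom > 0) sum(abs(pos_form)) / denom else 0
    W <- W_ca - eps_neg * N * neg_form
  }
  W[W < 0] <- 0
  W[W > w_max] <- w_max
  W
}

#' Reward-dependent outstar update (association -> preparation weights)
#'
#' For a rewarded trial the outgoing weight pattern of each active
#' association site moves toward the postsynaptic preparation-field output
#' (which reflects the actually performed reach):
#' `dW(x,y) = eps_pos * f_asc(x) * (f_prp(y) - W(x,y))`. For a failed
#' trial, connections from active sites to the active preparation region
#' are weakened and the amount removed from each site is redistributed
#' uniformly over that site's inactive targets, so the projection to
#' currently inactive regions is strengthened and the probability of a
#' different response in the next identical trial increases. The weakening
#' is `eps_neg`-scaled with the same per-trial magnitude normalization as
#' the instar rule; weights are clipped to `[0, w_max]`.
#'
#' @param W_ap Weight matrix, association sites x preparation positions.
#' @param f_asc Association output snapshot.
#' @param f_prp Preparation output snapshot (post-selection).
#' @param R Reward signal.
#' @param eps_pos,eps_neg Learning rates.
#' @param w_max Upper weight bound.
#' @param act_thresh Output level above which a preparation target counts
#'   as active for the failure redistribution.
#' @return Updated weight matrix.
#' @export
outstar_update <- function(W_ap, f_asc, f_prp, R, eps_pos = 0.1,
                           eps_neg = 0.06, w_max = 1, act_thresh = 0.1) {
  act <- which(f_asc > 1e-4)
  if (length(act) == 0) return(W_ap)
  Wa <- W_ap[act, , drop = FALSE]
  fa <- f_asc[act]
  pos_form <- fa * (matrix(f_prp, length(act), length(f_prp), byrow = TRUE) - Wa)
  if (R > 0) {
    Wa <- Wa + eps_pos * pos_form
  } else {
    on <- f_prp > act_thresh
    if (any(on) && any(!on)) {
      neg_form <- fa * matrix(f_prp * on, length(act), length(f_prp), byrow = TRUE) * Wa
      denom <- sum(abs(neg_form))
      N <- if (denom > 0) sum(abs(pos_form)) / denom else 0
      dec <- eps_neg * N * neg_form
      Wa <- Wa - dec
      Wa[, !on] <- Wa[, !on] + rowSums(dec) / sum(!on)
    }
  }
  Wa[Wa < 0] <- 0
  Wa[Wa > w_max] <- w_max
  W_ap[act, ] <- Wa
  W_ap
}

#' Apply the per-trial learning step to a model
#'
#' Both plastic projections are updated once, from the trial's stored
#' output snapshots (averaged over the post-go selection window). No update
#' happens on aborted (no-response) trials or when learning is disabled.
#'
#' @param model A `dnf_model`.
#' @param trial_result A trial result from [run_trial()] carrying snapshots
#'   `f_asc`, `f_ctx`, `f_prp` and the reward `R`.
#' @param learn Logical learning flag (sessions with the flag off leave
#'   weights untouched).
#' @return The updated model.
#' @export
apply_trial_learning <- function(model, trial_result, learn = TRUE) {
  if (!isTRUE(learn) || trial_result$aborted) return(model)
  lc <- model$cfg$learn
  model$W_ca <- instar_update(model$W_ca, trial_result$f_asc,
                              trial_result$f_ctx, trial_result$R,
                              lc$eps_pos, lc$eps_neg, model$cfg$init$w_max)
  model$W_ap <- outstar_update(model$W_ap, trial_result$f_asc,
                               trial_result$f_prp, trial_result$R,
                               lc$eps_pos, lc$eps_neg, model$cfg$init$w_max,
                               lc$act_thresh)
  model
}
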