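#' Initialize the five-component reach model
#'
#' Assembles the architecture: 1-D spatial input field, context node group,
#' 2-D association field (spatial x context), 1-D motor preparation field
#' and 1-D motor field, with fixed topological projections (spatial ->
#' preparation, spatial -> association ridge, preparation <-> motor) and
#' two plastic projections: context -> association (`W_ca`, small i.i.d.
#' random initial weights without spatial structure) and association ->
#' preparation (`W_ap`, wrapped-Gaussian topological map with zero index
#' shift, i.e. each association column initially projects most strongly to
#' its own direction).
#'
#' @param cfg A [model_config()] configuration.
#' @param check If `TRUE`, run the dynamic regime gates
#'   ([validate_regimes()]) before building; errors name the failed gate.
#' @return An object of class `dnf_model`.
#' @export
init_model <- function(cfg, check = FALSE) {
  validate_config(cfg)
  if (check) validate_regimes(cfg)
  pre <- precompute(cfg)
  n_x <- cfg$lattice$n_x; n_y <- cfg$lattice$n_y
  nxy <- n_x * n_y
  W_ca <- matrix(runif(cfg$n_contexts * nxy, 0, cfg$init$w_ca_init),
                 nrow = cfg$n_contexts)
  # topological outgoing profile, identical for every context row of a column
  dmat <- outer(pre$lat_x$pos, pre$lat_x$pos, circ_dist)
  w_row <- cfg$init$w_ap_amp * exp(-dmat^2 / (2 * cfg$init$w_ap_sigma^2))
  W_ap <- w_row[rep(seq_len(n_x), times = n_y), , drop = FALSE]
  m <- structure(list(
    cfg = cfg, pre = pre,
    u_spt = rep(cfg$fields$spt$h, n_x),
    u_ctx = rep(cfg$ctx$h, cfg$n_contexts),
    u_asc = matrix(cfg$fields$asc$h, n_x, n_y),
    u_prp = rep(cfg$fields$prp$h, n_x),
    u_mot = rep(cfg$fields$mot$h, n_x),
    W_ca = W_ca, W_ap = W_ap, go = FALSE
  ), class = "dnf_model")
  m
}

# Precompute lattices, interaction kernels and projection profiles.
# Kernel amplitudes in the config are integrated strengths: local components
# become unit-sum Gaussian profiles scaled by the strength, global inhibition
# a constant -g_inh / n so that its convolution equals -g_inh * mean(output).
precompute <- function(cfg) {
  n_x <- cfg$lattice$n_x; n_y <- cfg$lattice$n_y
  lat_x <- make_lattice(n_x, 360, circular = TRUE, name = "direction")
  lat_y <- make_lattice(n_y, cfg$lattice$extent_y, circular = FALSE,
                        name = "context")
  k1 <- function(f) cfg$fields[[f]]$a_exc *
    unit_profile(lat_x, cfg$fields[[f]]$sigma_exc) - cfg$fields[[f]]$g_inh / n_x
  pj <- function(g, sig) g * unit_profile(lat_x, sig)
  list(
    lat_x = lat_x, lat_y = lat_y,
    k_spt = k1("spt"), k_prp = k1("prp"), k_mot = k1("mot"),
    asc_px = unit_profile(lat_x, cfg$fields$asc$sigma_x),
    asc_py = unit_profile(lat_y, cfg$fields$asc$sigma_y),
    p_spt_prp = pj(cfg$proj$g_spt_prp, cfg$proj$sig_spt_prp),
    p_spt_asc = pj(cfg$proj$g_spt_asc, cfg$proj$sig_spt_asc),
    p_prp_mot = pj(cfg$proj$g_prp_mot, cfg$proj$sig_prp_mot),
    p_mot_prp = pj(cfg$proj$g_mot_prp, cfg$proj$sig_mot_prp),
    area = (lat_x$dx * lat_y$dx) / (360 * cfg$lattice$extent_y)
  )
}

#' Set the go gate
#'
#' With the gate off the motor field is held at its low resting level and
#' cannot form a peak from preparation input alone; switching it on adds a
#' uniform excitatory boost (disinhibition) so that a peak can form at the
#' location favored by the preparation field.
#'
#' @param model A `dnf_model`.
#' @param on Logical.
#' @return The updated model.
#' @export
set_go_gate <- function(model, on) {
  model$go <- isTRUE(on)
  model
}

#' Motor-to-preparation feedback input
#'
#' Topological excitatory feedback from the motor field onto the
#' preparation field plus a global suppression proportional to the total
#' motor output, so that once a reach is selected the corresponding motor
#' plan is reinforced in the preparation field and competing plans are
#' suppressed.
#'
#' @param model A `dnf_model`.
#' @return Numeric input vector to the preparation field.
#' @export
motor_feedback <- function(model) {
  f_mot <- sigmoid_output(model$u_mot, model$cfg$fields$mot$beta)
  circ_conv(f_mot, model$pre$p_mot_prp) -
    model$cfg$proj$g_mot_prp_inh * mean(f_mot)
}

#' One synchronous update of the whole model
#'
#' All projection inputs are computed from the previous step's field
#' outputs, then every field and the context nodes take one Euler step.
#' This is the reference (pure R) implementation of the model dynamics;
#' [run_trial()] uses an equivalent compiled path for whole trials.
#'
#' @param model A `dnf_model`.
#' @param stimuli A list with elements `spt` (data frame of spatial inputs
#'   with columns `dir`, `amp`, `sigma`; may be empty), `ctx` (external
#'   input per context node) and `go` (logical gate level). Missing
#'   elements default to no input / gate unchanged.
#' @param dt Time step.
#' @return The updated model.
#' @export
step_model <- function(model, stimuli = list(), dt = 1) {
  cfg <- model$cfg; pre <- model$pre
  if (!is.null(stimuli[["go"]])) model$go <- isTRUE(stimuli[["go"]])
  f_spt <- sigmoid_output(model$u_spt, cfg$fields$spt$beta)
  f_ctx <- sigmoid_output(model$u_ctx, cfg$ctx$beta)
  f_asc <- sigmoid_output(model$u_asc, cfg$fields$asc$beta)
  f_prp <- sigmoid_output(model$u_prp, cfg$fields$prp$beta)
  f_mot <- sigmoid_output(model$u_mot, cfg$fields$mot$beta)

  in_spt <- numeric(cfg$lattice$n_x)
  if (!is.null(stimuli[["spt_profile"]])) in_spt <- in_spt + stimuli[["spt_profile"]]
  if (!is.null(stimuli[["spt"]]) && NROW(stimuli[["spt"]]) > 0) {
    sp <- stimuli[["spt"]]
    for (i in seq_len(NROW(sp)))
      in_spt <- in_spt + input_bump(pre$lat_x, sp$dir[i], sp$amp[i], sp$sigma[i])
  }
  in_ctx <- stimuli[["ctx"]] %||% numeric(cfg$n_contexts)

  ridge <- circ_conv(f_spt, pre$p_spt_asc)
  ctx_in <- as.numeric(crossprod(model$W_ca, f_ctx))     # length nxy
  in_asc <- matrix(ctx_in * cfg$proj$g_ctx_asc, cfg$lattice$n_x,
                   cfg$lattice$n_y) + ridge               # ridge recycled by column

  fb <- circ_conv(f_mot, pre$p_mot_prp) - cfg$proj$g_mot_prp_inh * mean(f_mot)
  in_prp <- circ_conv(f_spt, pre$p_spt_prp) +
    cfg$proj$g_asc_prp * pre$area *
      as.numeric(crossprod(model$W_ap, as.vector(f_asc))) + fb
  in_mot <- circ_conv(f_prp, pre$p_prp_mot) +
    if (model$go) cfg$proj$g_go else 0

  step1 <- function(u, f, k, p, s) {
    lat <- circ_conv(f, k)
    noise <- if (p$q > 0) p$q * sqrt(dt) * rnorm(length(u)) else 0
    u + (dt / p$tau) * (-u + p$h + s + lat) + noise
  }
  model$u_spt <- step1(model$u_spt, f_spt, pre$k_spt, cfg$fields$spt, in_spt)
  pc <- cfg$ctx
  lat_ctx <- pc$w_self * f_ctx - pc$w_mut * (sum(f_ctx) - f_ctx)
  noise_c <- if (pc$q > 0) pc$q * sqrt(dt) * rnorm(cfg$n_contexts) else 0
  model$u_ctx <- model$u_ctx +
    (dt / pc$tau) * (-model$u_ctx + pc$h + in_ctx + lat_ctx) + noise_c
  pa <- cfg$fields$asc
  ex <- apply(f_asc, 2, function(col) circ_conv(col, pre$asc_px))
  ex <- t(apply(ex, 1, function(row) bounded_conv(row, pre$asc_py)))
  lat_asc <- pa$a_exc * ex - pa$g_inh * mean(f_asc)
  noise_a <- if (pa$q > 0) pa$q * sqrt(dt) *
    matrix(rnorm(length(model$u_asc)), nrow = cfg$lattice$n_x) else 0
  model$u_asc <- model$u_asc +
    (dt / pa$tau) * (-model$u_asc + pa$h + in_asc + lat_asc) + noise_a
  model$u_prp <- step1(model$u_prp, f_prp, pre$k_prp, cfg$fields$prp, in_prp)
  model$u_mot <- step1(model$u_mot, f_mot, pre$k_mot, cfg$fields$mot, in_mot)
  model
}

#' Field outputs of a model
#'
#' @param model A `dnf_model`.
#' @return List of sigmoid outputs `spt`, `ctx`, `asc`, `prp`, `mot`.
#' @export
model_outputs <- function(model) {
  cfg <- model$cfg
  list(spt = sigmoid_output(model$u_spt, cfg$fields$spt$beta),
       ctx = sigmoid_output(model$u_ctx, cfg$ctx$beta),
       asc = sigmoid_output(model$u_asc, cfg$fields$asc$beta),
       prp = sigmoid_output(model$u_prp, cfg$fields$prp$beta),
       mot = sigmoid_output(model$u_mot, cfg$fields$mot$beta))
}

# reset field activations to resting level between trials (weights persist)
reset_fields <- function(model) {
  cfg <- model$cfg
  model$u_spt[] <- cfg$fields$spt$h
  model$u_ctx[] <- cfg$ctx$h
  model$u_asc[] <- cfg$fields$asc$h
  model$u_prp[] <- cfg$fields$prp$h
  model$u_mot[] <- cfg$fields$mot$h
  model$go <- FALSE
  model
}

#' Fig-3-style weight diagnostics
#'
#' `weight_difference_map()` returns the difference of incoming context
#' weights (second minus first context node, i.e. inferred minus direct for
#' the two-rule model) at every association-field site. `index_shift_map()`
#' returns, per site, the circular offset between the site's own direction
#' and the direction in the preparation field to which it projects most
#' strongly (0 before training everywhere; about 180 in inferred-preferring
#' regions after training).
#'
#' @param model A `dnf_model`.
#' @param ctx_pair Indices of the two context nodes to difference.
#' @return A `n_x` x `n_y` matrix.
#' @export
weight_difference_map <- function(model, ctx_pair = c(2, 1)) {
  n_x <- model$cfg$lattice$n_x; n_y <- model$cfg$lattice$n_y
  matrix(model$W_ca[ctx_pair[1], ] - model$W_ca[ctx_pair[2], ], n_x, n_y)
}

#' @rdname weight_difference_map
#' @export
index_shift_map <- function(model) {
  n_x <- model$cfg$lattice$n_x; n_y <- model$cfg$lattice$n_y
  pos <- model$pre$lat_x$pos
  best <- pos[max.col(model$W_ap, ties.method = "first")]
  own <- rep(pos, times = n_y)
  d <- (best - own) %% 360
  matrix(ifelse(d > 180, d - 360, d), n_x, n_y)
}
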