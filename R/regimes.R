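# Dynamic regime gates: short noise-free single-field simulations that check
# the configured interaction parameters put each field into its intended
# regime before a model is trained.

# field_state for a named 1-D field of the config, converting integrated
# kernel strengths into literal sampled-kernel amplitudes
cfg_field_state <- function(cfg, name) {
  fc <- cfg$fields[[name]]
  lat <- make_lattice(cfg$lattice$n_x, 360, circular = TRUE)
  offs <- (seq_len(lat$n) - 1) * lat$dx
  d <- pmin(offs, 360 - offs)
  raw_sum <- sum(exp(-d^2 / (2 * fc$sigma_exc^2)))
  kp <- kernel_params(a_exc = fc$a_exc / raw_sum, sigma_exc = fc$sigma_exc,
                      g_inh = fc$g_inh / lat$n)
  st <- field_state(lat, field_params(fc$tau, fc$h, 0, fc$beta), kp)
  st
}

cfg_asc_state <- function(cfg) {
  fc <- cfg$fields$asc
  lat_x <- make_lattice(cfg$lattice$n_x, 360, circular = TRUE)
  lat_y <- make_lattice(cfg$lattice$n_y, cfg$lattice$extent_y)
  field_state(list(lat_x, lat_y), field_params(fc$tau, fc$h, 0, fc$beta),
              list(a_exc = fc$a_exc, sigma_x = fc$sigma_x,
                   sigma_y = fc$sigma_y, g_inh = fc$g_inh))
}

run_field <- function(st, s, n, dt = 1) {
  for (i in seq_len(n)) st <- field_step(st, s, dt)
  st
}

#' Check the dynamic regime gates of a configuration
#'
#' Verifies by short noise-free simulation that (a) the spatial input field
#' is input-driven (a cue-induced peak decays after input removal), (b) the
#' association field is in the self-sustained memory regime (a peak induced
#' by transient localized input persists for the configured memory
#' duration), and (c) the motor field under the go gate is in the selection
#' regime (two equal bimodal inputs leave exactly one above-threshold
#' peak).
#'
#' @param cfg A [model_config()] configuration.
#' @return `TRUE` invisibly; otherwise an error naming the failed gate.
#' @export
validate_regimes <- function(cfg) {
  dt <- cfg$dt
  thr <- 0.5
  # (a) input-driven spatial field
  st <- cfg_field_state(cfg, "spt")
  bump <- input_bump(st$lattice, 90, cfg$stim$amp_spt, cfg$stim$sigma_spt)
  st <- run_field(st, bump, cfg$timing$cue, dt)
  if (max(sigmoid_output(st$u, st$params$beta)) < thr)
    stop("regime gate failed: spatial input field does not respond to a cue")
  st <- run_field(st, 0, 10 * st$params$tau, dt)
  if (max(sigmoid_output(st$u, st$params$beta)) > 0.1)
    stop("regime gate failed: spatial input field is not input-driven (peak persists)")
  # (b) memory regime in the association field
  st <- cfg_asc_state(cfg)
  dx <- circ_dist(st$lattice[[1]]$pos, 90)
  dy <- abs(st$lattice[[2]]$pos - cfg$lattice$extent_y / 2)
  s2 <- outer(exp(-dx^2 / (2 * cfg$stim$sigma_spt^2)),
              exp(-dy^2 / (2 * cfg$fields$asc$sigma_y^2))) * cfg$proj$g_spt_asc
  st <- run_field(st, s2, cfg$timing$cue, dt)
  st <- run_field(st, 0, cfg$timing$memory, dt)
  f <- sigmoid_output(st$u, st$params$beta)
  if (max(f) < thr)
    stop("regime gate failed: association field peak is not self-sustained over the memory period")
  # (c) selection: with the go gate on, two equally salient spatial inputs
  # must leave exactly one above-threshold motor peak. Selection is a
  # system-level property (motor-to-preparation feedback suppresses the
  # losing plan at its source, field noise breaks the tie), so the gate
  # runs the assembled architecture rather than the isolated field.
  model <- init_model(cfg)
  two <- input_bump(model$pre$lat_x, 0, cfg$stim$amp_spt, cfg$stim$sigma_spt) +
    input_bump(model$pre$lat_x, 180, cfg$stim$amp_spt, cfg$stim$sigma_spt)
  for (rep in 1:3) {
    m <- reset_fields(model)
    for (t in seq_len(cfg$timing$cue + 50))
      m <- step_model(m, list(spt_profile = two, go = FALSE), dt)
    for (t in seq_len(cfg$timing$go))
      m <- step_model(m, list(spt_profile = two, go = TRUE), dt)
    if (count_peaks(model_outputs(m)$mot, thr) != 1)
      stop("regime gate failed: gated motor field does not select a single peak from bimodal input")
  }
  invisible(TRUE)
}

# number of connected above-threshold segments on a circular lattice
count_peaks <- function(f, thr) {
  above <- f > thr
  if (!any(above)) return(0L)
  if (all(above)) return(1L)
  transitions <- sum(above & !c(above[length(above)], above[-length(above)]))
  transitions
}
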