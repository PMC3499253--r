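#' Model and experiment configuration
#'
#' Builds the full parameter set of the adaptive DNF reach model: lattice
#' resolutions, per-field dynamics and interaction kernels, inter-field
#' projection gains, learning-rule constants, stimulus parameters and the
#' trial epoch timeline. All gains that integrate over lattice samples are
#' expressed as resolution-independent quantities (kernel amplitudes as
#' integrated strengths of unit-sum profiles, global inhibition per mean
#' field output, projections per normalized field area), so the same
#' constants describe the same dynamical regimes at different resolutions.
#'
#' @param preset `"default"` (2 degree spatial sampling, 180 x 30
#'   association lattice, full epoch durations) or `"fast"` (4 degree
#'   sampling, 90 x 15, halved epochs) for desk-scale simulation studies.
#' @param n_contexts Number of context nodes / mapping rules (2-4).
#' @param rotations Cue-to-goal rotation per context, degrees. Defaults to
#'   `c(0, 180)`, `c(0, 180, 90)` or `c(0, 180, 90, 270)` depending on
#'   `n_contexts`.
#' @param ... Named overrides merged into the config (top-level or nested
#'   via lists, e.g. `learn = list(eps_pos = 0.2)`).
#' @return A named list of class `dnf_config`.
#' @examples
#' cfg <- model_config("fast")
#' cfg$lattice$n_x
#' @export
model_config <- function(preset = c("default", "fast"), n_contexts = 2,
                         rotations = NULL, ...) {
  preset <- match.arg(preset)
  fast <- preset == "fast"
  if (is.null(rotations)) {
    rotations <- switch(as.character(n_contexts),
                        "2" = c(0, 180),
                        "3" = c(0, 180, 90),
                        "4" = c(0, 180, 90, 270),
                        stop("n_contexts must be 2, 3 or 4 unless rotations are given"))
  }
  stopifnot(length(rotations) == n_contexts)
  cfg <- list(
    preset = preset,
    lattice = list(
      n_x = if (fast) 90L else 180L,      # spatial samples over 360 deg
      n_y = if (fast) 15L else 30L,       # context-dimension samples
      extent_y = 30                        # context extent, abstract units
    ),
    dt = 1,
    n_contexts = as.integer(n_contexts),
    rotations = rotations,
    trained_dirs = c(0, 90, 180, 270),
    fields = list(
      # spatial input field: input-driven regime (stabilized representation
      # of a present cue, decays after cue offset)
      spt = list(tau = 10, h = -2, q = 0.05, beta = 4,
                 a_exc = 1.5, sigma_exc = 6, g_inh = 10),
      # association field: memory + selection regime (self-sustained single
      # peak); sigma_x in degrees, sigma_y in context units
      asc = list(tau = 10, h = -3, q = 0.12, beta = 4,
                 a_exc = 10, sigma_x = 11.5, sigma_y = 4.5, g_inh = 90),
      # motor preparation field: soft competition, peaks need input
      prp = list(tau = 10, h = -2, q = 0.05, beta = 4,
                 a_exc = 2, sigma_exc = 6, g_inh = 15),
      # motor field: strong winner-take-all, gated by the go signal
      mot = list(tau = 10, h = -4, q = 0.05, beta = 4,
                 a_exc = 4, sigma_exc = 6, g_inh = 40)
    ),
    ctx = list(tau = 10, h = -2, q = 0.02, beta = 4, w_self = 4, w_mut = 6),
    proj = list(
      g_spt_prp = 5,    sig_spt_prp = 5,   # direct pathway (default reach)
      g_spt_asc = 3.5,  sig_spt_asc = 5,   # ridge input to association field
      g_ctx_asc = 1.8,                     # context nodes -> association (x W_ca)
      g_asc_prp = 100,                     # association -> preparation (x W_ap, per area)
      g_prp_mot = 3,    sig_prp_mot = 5,
      g_mot_prp = 1,    sig_mot_prp = 5,   # selection feedback, excitatory part
      g_mot_prp_inh = 10,                  # selection feedback, global suppression
      g_go = 3.5                           # go-gate disinhibition of motor field
    ),
    init = list(w_ca_init = 0.25, w_ap_amp = 1, w_ap_sigma = 6, w_max = 1),
    learn = list(eps_pos = 0.1, eps_neg = 0.06, theta = 0.5,
                 smooth_sigma = 4, tolerance = 8, act_thresh = 0.1),
    stim = list(amp_spt = 6, sigma_spt = 5, amp_ctx = 5),
    timing = if (fast) {
      list(settle = 20, cue = 100, memory = 300, target = 80, ci = 200, go = 120)
    } else {
      list(settle = 20, cue = 200, memory = 600, target = 160, ci = 400, go = 240)
    }
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "dnf_config"
  validate_config(cfg)
  cfg
}

# recursive merge of named overrides into a config list
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Validate a configuration
#'
#' Checks structural invariants (positive time constants and widths,
#' negative resting levels, probability-like quantities in range). Dynamic
#' regime gates are checked separately by [validate_regimes()] since they
#' require short simulations.
#'
#' @param cfg A `dnf_config`.
#' @return The config, invisibly; errors name the violated invariant.
#' @export
validate_config <- function(cfg) {
  for (fn in names(cfg$fields)) {
    f <- cfg$fields[[fn]]
    if (!(f$tau > 0)) stop(sprintf("fields$%s$tau must be > 0", fn))
    if (!(f$h < 0)) stop(sprintf("fields$%s$h must be negative", fn))
    if (!(f$q >= 0)) stop(sprintf("fields$%s$q must be >= 0", fn))
    if (!(f$beta > 0)) stop(sprintf("fields$%s$beta must be > 0", fn))
  }
  if (!(cfg$ctx$h < 0)) stop("ctx$h must be negative")
  if (!(cfg$dt > 0 && cfg$dt * 10 <= min(vapply(cfg$fields, `[[`, 1, "tau"))))
    stop("dt must satisfy tau >= 10 * dt for all fields")
  if (!(cfg$learn$eps_pos > cfg$learn$eps_neg && cfg$learn$eps_neg > 0))
    stop("learning rates must satisfy eps_pos > eps_neg > 0")
  if (!(cfg$learn$tolerance > 0)) stop("learn$tolerance must be > 0")
  if (cfg$n_contexts != length(cfg$rotations))
    stop("rotations must have one entry per context")
  invisible(cfg)
}

#' Load / save a configuration (YAML)
#'
#' Configurations round-trip losslessly through YAML. Loading validates the
#' structural invariants and rejects unknown top-level keys.
#'
#' @param path File path.
#' @return `load_config()` returns a validated `dnf_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known <- names(model_config("fast"))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg <- merge_config(model_config(raw$preset %||% "default",
                                   n_contexts = raw$n_contexts %||% 2,
                                   rotations = raw$rotations),
                      raw[setdiff(names(raw), c("preset", "n_contexts", "rotations"))])
  class(cfg) <- "dnf_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg A `dnf_config` to write.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
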