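# Shared fixtures, built once per test run. Training a model takes about a
# minute, so the IR-trained two-context model is cached and reused by every
# test that needs a trained network.

.fixture_cache <- new.env(parent = emptyenv())

fast_cfg <- function(...) model_config("fast", ...)

# noise-free config for deterministic dynamics checks
quiet_cfg <- function(...) {
  model_config("fast",
               fields = list(spt = list(q = 0), asc = list(q = 0),
                             prp = list(q = 0), mot = list(q = 0)),
               ctx = list(q = 0), ...)
}

ir_trained_model <- function() {
  if (is.null(.fixture_cache$trained)) {
    set.seed(4242)
    m <- init_model(fast_cfg())
    .fixture_cache$trained <- run_session(m, session_config("ir", 1000))$model
  }
  .fixture_cache$trained
}

# a Gaussian output bump used to synthesize motor-field patterns
gauss_bump <- function(lat, center, height = 1, sigma = 8) {
  height * exp(-circ_dist(lat$pos, center)^2 / (2 * sigma^2))
}

# EPRS free-choice phase continued from the trained model (learning on),
# and the BMRS continuation from its end state; cached as a chain.
eprs_phase <- function() {
  if (is.null(.fixture_cache$eprs)) {
    m <- ir_trained_model()
    set.seed(515)
    .fixture_cache$eprs <- run_session(
      m, session_config("pmg", 500, nc_ratio = 0.4, schedule = "eprs",
                        learn = TRUE), trace = TRUE)
  }
  .fixture_cache$eprs
}

bmrs_phase <- function() {
  if (is.null(.fixture_cache$bmrs)) {
    ep <- eprs_phase()
    set.seed(616)
    .fixture_cache$bmrs <- run_session(
      ep$model, session_config("pmg", 1250, nc_ratio = 0.4, schedule = "bmrs",
                               learn = TRUE), trace = TRUE)
  }
  .fixture_cache$bmrs
}
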