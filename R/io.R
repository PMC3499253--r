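#' Run a named experiment preset
#'
#' Composes training, probing and analysis into the standard experiment
#' recipes and writes all artifacts (config copy, trial logs, weight
#' matrices, analysis tables, run metadata) as plain CSV/YAML files into
#' an output directory.
#'
#' Presets:
#' \describe{
#'   \item{`ir-training`}{IR training session plus a DMG probe with the
#'     resulting performance.}
#'   \item{`generalization`}{IR training, then DMG-style probes at novel
#'     oblique cue directions with the error taxonomy.}
#'   \item{`reward-schedule-switch`}{IR training, free-choice probing
#'     under the equal-probability schedule, then continued learning under
#'     the bias-minimizing schedule; choice fractions for both phases.}
#'   \item{`ratio-sweep`}{Training-statistics sweep with logistic fits.}
#' }
#'
#' @param name Preset name (above).
#' @param cfg Model configuration (a [model_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; all child randomness derives from it.
#' @param n_train,n_probe Trial counts for training and probe sessions.
#' @return The output directory, invisibly; artifacts on disk.
#' @export
run_experiment <- function(name = c("ir-training", "generalization",
                                    "reward-schedule-switch", "ratio-sweep"),
                           cfg = model_config(), out_dir = tempfile("dnfexp"),
                           seed = 1, n_train = 1000, n_probe = 400) {
  name <- match.arg(name)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  save_config(cfg, file.path(out_dir, "config.yaml"))
  meta <- list(preset = name, seed = seed, n_train = n_train,
               n_probe = n_probe, r_version = R.version.string,
               package_version = as.character(utils::packageVersion("dnfreach")))
  yaml::write_yaml(meta, file.path(out_dir, "run.yaml"))
  wcsv <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)

  model <- init_model(cfg)
  tr <- run_session(model, session_config("ir", n_train))
  wcsv(tr$log, "ir_training_log.csv")
  model <- tr$model
  wcsv(as.data.frame(model$W_ca), "W_ca.csv")
  wcsv(as.data.frame(weight_difference_map(model)), "weight_difference_map.csv")
  wcsv(as.data.frame(index_shift_map(model)), "index_shift_map.csv")

  if (name == "ir-training") {
    pr <- run_session(model, session_config("dmg", n_probe))
    wcsv(pr$log, "dmg_probe_log.csv")
    perf <- session_performance(pr$log)
    wcsv(data.frame(percent_correct = perf$percent_correct,
                    n_scored = perf$n_scored, n_aborted = perf$n_aborted),
         "performance.csv")
  } else if (name == "generalization") {
    obl <- wrap_dir(cfg$trained_dirs + 45)
    pr <- run_session(model, session_config("generalize", n_probe,
                                            dirs = obl, contexts = 2))
    wcsv(pr$log, "generalization_log.csv")
    ce <- classify_errors(pr$log, cfg$trained_dirs, cfg$learn$tolerance)
    wcsv(data.frame(class = names(ce$proportions),
                    proportion = ce$proportions), "error_taxonomy.csv")
    wcsv(as.data.frame(ce$deviation_hist), "deviation_histogram.csv")
  } else if (name == "reward-schedule-switch") {
    ep <- run_session(model, session_config("pmg", n_probe,
                                            schedule = "eprs", learn = FALSE))
    wcsv(ep$log, "eprs_log.csv")
    bm <- run_session(model, session_config("pmg", n_probe,
                                            schedule = "bmrs", learn = TRUE))
    wcsv(bm$log, "bmrs_log.csv")
    cf_e <- choice_fractions(ep$log); cf_b <- choice_fractions(bm$log)
    wcsv(data.frame(phase = c("eprs", "bmrs"),
                    frac_inferred = c(cf_e$frac_inferred, cf_b$frac_inferred),
                    frac_direct = c(cf_e$frac_direct, cf_b$frac_direct),
                    n_nc = c(cf_e$n, cf_b$n)), "choice_fractions.csv")
  } else if (name == "ratio-sweep") {
    curve <- sweep_training_ratio(seq(0.1, 0.9, by = 0.1), cfg,
                                  n_train = n_train,
                                  n_probe = min(n_probe, 100))
    wcsv(curve, "bias_curve.csv")
    fl <- fit_logistic(curve$fraction, curve$frac_inferred)
    wcsv(data.frame(m = fl$m, beta = fl$beta, mse = fl$mse), "logistic_fit.csv")
  }
  invisible(out_dir)
}

#' Save / load model weights as CSV
#'
#' The two plastic weight matrices are the model's learned state; fields
#' reset between trials, so (config, weights) fully determine behavior.
#'
#' @param model A `dnf_model`.
#' @param dir Directory for `W_ca.csv` / `W_ap.csv`.
#' @export
save_weights <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model$W_ca, file.path(dir, "W_ca.csv"), row.names = FALSE)
  utils::write.csv(model$W_ap, file.path(dir, "W_ap.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_weights
#' @export
load_weights <- function(model, dir) {
  model$W_ca <- as.matrix(utils::read.csv(file.path(dir, "W_ca.csv")))
  model$W_ap <- as.matrix(utils::read.csv(file.path(dir, "W_ap.csv")))
  dimnames(model$W_ca) <- NULL; dimnames(model$W_ap) <- NULL
  model
}
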