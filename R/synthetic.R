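#' Default ground-truth validity scenario
#'
#' The study conditions emulated by the generator: a left-hemifield target
#' (exogenous input to right V2, with a fraction spreading to left V2), with
#' invalid-cue effects confined to superficial-pyramidal gain and its
#' top-down modulation. The sign pattern follows the asymmetric gain
#' redeployment the model family predicts for switching attention between
#' hemifields:
#' \itemize{
#'   \item left V2 is profoundly disinhibited in invalid trials
#'     (\eqn{\Delta\gamma = -\ln 2});
#'   \item left V3 gain slightly decreases (\eqn{\Delta\gamma = +\ln 1.25});
#'   \item right V5 gain slightly increases (\eqn{\Delta\gamma = -\ln 1.25});
#'   \item parietal gain does not change (the generating model excludes
#'     parietal gain differences);
#'   \item backward modulation strengthens on every modulatory edge
#'     (\eqn{\Delta M = +\ln 1.5}) except the edges from right PC, which
#'     weaken (\eqn{\Delta M = -\ln 1.25}).
#' }
#'
#' @param snr_db sensor signal-to-noise ratio (dB), default 10.
#' @param n_trials trials per condition for raw-trial generation, default 128.
#' @param n_channels sensor count, default 64.
#' @param trial_jitter list with `amp_sd` (lognormal amplitude scale sd) and
#'   `lat_sd` (latency jitter sd, ms).
#' @param outlier_fraction fraction of trials replaced by high-amplitude
#'   artifact trials (default 0).
#' @param seed master seed for dataset generation.
#' @return object of class `scenario_spec`: list with the ground-truth
#'   `network`, noise/trial settings and the generating model flags.
#' @export
default_validity_scenario <- function(snr_db = 10, n_trials = 128,
                                      n_channels = 64,
                                      trial_jitter = list(amp_sd = 0.1,
                                                          lat_sd = 10),
                                      outlier_fraction = 0, seed = 1) {
  effects <- list(
    delta_gamma = c("V2.L" = -log(2), "V3.L" = log(1.25), "V5.R" = -log(1.25)),
    delta_M = as.list(c(
      "V2.L<-V3.L" = log(1.5), "V2.L<-V5.L" = log(1.5),
      "V3.L<-PC.L" = log(1.5), "V5.L<-PC.L" = log(1.5),
      "V2.R<-V3.R" = log(1.5), "V2.R<-V5.R" = log(1.5),
      "V3.R<-PC.R" = -log(1.25), "V5.R<-PC.R" = -log(1.25))))
  network <- build_posner_network(list(effects = effects))
  structure(list(network = network, snr_db = snr_db, n_trials = n_trials,
                 n_channels = n_channels, trial_jitter = trial_jitter,
                 outlier_fraction = outlier_fraction, seed = seed,
                 model = model_spec(1, 0, 1)),
            class = "scenario_spec")
}

#' @rdname default_validity_scenario
#' @details `null_scenario()` returns the same scenario with every condition
#'   effect set to zero (generating model `(0 0 0)`); valid and invalid
#'   responses then differ only by measurement noise.
#' @export
null_scenario <- function(snr_db = 10, n_trials = 128, n_channels = 64,
                          trial_jitter = list(amp_sd = 0.1, lat_sd = 10),
                          outlier_fraction = 0, seed = 1) {
  sc <- default_validity_scenario(snr_db, n_trials, n_channels, trial_jitter,
                                  outlier_fraction, seed)
  sc$network$effects <- condition_effects()
  sc$model <- model_spec(0, 0, 0)
  sc
}

# check that the generating model flags cover exactly the nonzero effects
check_truth_consistency <- function(spec) {
  eff <- spec$network$effects
  src <- spec$network$sources
  extra <- src$label[src$name != "PC"]
  par <- src$label[src$name == "PC"]
  ok_g <- (!any(eff$delta_gamma[extra] != 0) || spec$model$extrastriate_gain) &&
          (!any(eff$delta_gamma[par] != 0) || spec$model$parietal_gain)
  ok_m <- !any(eff$delta_M != 0) || spec$model$modulation
  if (!(ok_g && ok_m))
    stop("generating model flags are inconsistent with nonzero effects",
         call. = FALSE)
  invisible(TRUE)
}

#' Generate a synthetic evoked-response dataset
#'
#' Integrates the ground-truth network per condition, projects the source
#' activity to sensors through a synthetic lead field, samples at the sensor
#' rate and adds white noise at the scenario's SNR. Deterministic given the
#' scenario seed.
#'
#' @param spec a [default_validity_scenario()] (or modified copy).
#' @param sfreq sensor sampling rate (Hz), default 200.
#' @param window peristimulus window (ms), default `c(-50, 400)`.
#' @param dt integration step (ms).
#' @return list with `dataset` (a [sensor_dataset()]) and `truth` (a
#'   `truth_record`: ground-truth effects, generating model, scenario).
#' @export
generate_dataset <- function(spec, sfreq = 200, window = c(-50, 400), dt = 1) {
  check_truth_consistency(spec)
  lead <- make_lead_field(spec$n_channels, spec$network$sources$label)
  clean <- clean_sensor_responses(spec$network, lead, sfreq, window, dt)
  ds <- sensor_dataset(clean, sfreq = sfreq, window = window, lead = lead)
  ds <- add_sensor_noise(ds, spec$snr_db, seed = spec$seed)
  truth <- structure(list(effects = spec$network$effects, model = spec$model,
                          scenario = spec, outliers = list()),
                     class = "truth_record")
  list(dataset = ds, truth = truth)
}

# noiseless projected responses per condition, sampled at sfreq
clean_sensor_responses <- function(network, lead, sfreq = 200,
                                   window = c(-50, 400), dt = 1,
                                   weights = contribution_weights()) {
  times <- seq(window[1], window[2], by = 1000 / sfreq)
  lapply(c(valid = "valid", invalid = "invalid"), function(cond) {
    act <- integrate_network(network, cond, window, dt)
    sens <- project_to_sensors(act, lead, weights)
    idx <- vapply(times, function(t) which.min(abs(act$time - t)), integer(1))
    out <- sens[, idx, drop = FALSE]
    colnames(out) <- NULL
    out
  })
}

#' Generate raw trial sets
#'
#' Produces per-condition trial sets suitable for the preprocessing chain:
#' each trial is the clean wide-window sensor response with per-trial latency
#' and amplitude jitter plus white noise, generated at a raw acquisition rate.
#' A seeded fraction of trials is replaced by high-amplitude artifact trials;
#' their indices are recorded in the truth record.
#'
#' @param spec a [default_validity_scenario()].
#' @param raw_sfreq acquisition sampling rate (Hz), default 600.
#' @param window wide recording window around target onset (ms).
#' @param artifact_scale amplitude multiplier for outlier trials (default 20).
#' @return list with `trials` (named list of [trial_set()] per condition) and
#'   `truth` (including per-condition outlier indices).
#' @export
generate_raw_trials <- function(spec, raw_sfreq = 600, window = c(-300, 700),
                                artifact_scale = 20) {
  if (spec$n_trials < 2) stop("need at least two trials", call. = FALSE)
  if (spec$outlier_fraction < 0 || spec$outlier_fraction >= 1)
    stop("outlier_fraction must lie in [0, 1)", call. = FALSE)
  check_truth_consistency(spec)
  lead <- make_lead_field(spec$n_channels, spec$network$sources$label)
  dt <- 1
  dense_t <- seq(window[1], window[2], by = dt)
  raw_t <- seq(window[1], window[2], by = 1000 / raw_sfreq)
  onset_index <- which.min(abs(raw_t))
  clean <- lapply(c(valid = "valid", invalid = "invalid"), function(cond) {
    act <- integrate_network(spec$network, cond, window, dt)
    project_to_sensors(act, lead)
  })
  p_sig <- mean(unlist(lapply(clean, function(d) d^2)))
  sd_noise <- sqrt(p_sig / 10^(spec$snr_db / 10))
  jit <- spec$trial_jitter
  out <- with_seed(spec$seed, {
    lapply(clean, function(cl) {
      n_out <- floor(spec$outlier_fraction * spec$n_trials)
      idx_out <- if (n_out > 0) sort(sample.int(spec$n_trials, n_out)) else integer(0)
      trials <- lapply(seq_len(spec$n_trials), function(k) {
        lat <- rnorm(1, 0, jit$lat_sd %||% 0)
        amp <- exp(rnorm(1, 0, jit$amp_sd %||% 0))
        shifted <- t(apply(cl, 1, function(x)
          stats::approx(dense_t + lat, x, xout = raw_t, rule = 2)$y))
        tr <- amp * shifted +
          matrix(rnorm(nrow(cl) * length(raw_t), sd = sd_noise),
                 nrow(cl), length(raw_t))
        if (k %in% idx_out) tr <- artifact_scale * tr
        rownames(tr) <- rownames(cl)
        tr
      })
      list(set = trial_set(trials, raw_sfreq, onset_index = onset_index),
           outliers = idx_out)
    })
  })
  trials <- lapply(out, `[[`, "set")
  for (cond in names(trials)) trials[[cond]]$condition <- cond
  truth <- structure(list(effects = spec$network$effects, model = spec$model,
                          scenario = spec,
                          outliers = lapply(out, `[[`, "outliers")),
                     class = "truth_record")
  list(trials = trials, truth = truth)
}
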