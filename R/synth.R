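# Synthetic epoched EEG with planted feature codes, plus simulated behavior.
#
# Each task feature (shared rule; stimulus, response and conjunction of each
# plan) is a stationary unit-norm spatial pattern over channels, amplitude-
# modulated per trial phase and carried by a band-limited oscillation. This
# is the simplest generative structure the decoding + RSA chain assumes, so
# every downstream stage can be validated against known planted codes.

.conjrsa_features <- c("rule", "stim_high", "stim_low", "resp_high",
                       "resp_low", "conj_high", "conj_low")
.conjrsa_feature_levels <- c(rule = 3L, stim_high = 4L, stim_low = 4L,
                             resp_high = 4L, resp_low = 4L,
                             conj_high = 12L, conj_low = 12L)

#' Configuration for the synthetic EEG + behavior generator
#'
#' Defaults emulate the study conditions: 20 scalp channels sampled at
#' 250 Hz on a -200..2200 ms epoch, trial phases encoding (0-750 ms),
#' preparation (750-1500 ms) and test (1500-2200 ms); stimulus codes strong
#' during encoding and decaying, the shared rule sustained from preparation,
#' conjunctions emerging during preparation, responses appearing only in the
#' test phase; and priority- and selection-dependent gain on conjunction and
#' response codes during the test phase (output gating). Behavioral
#' parameters default to the empirical condition means: RT 371/428 ms and
#' error rates .11/.22 for high/low tested priority, swap shares .74/.81 of
#' committed errors.
#'
#' @param n_channels number of scalp channels (20).
#' @param fs sampling rate, Hz.
#' @param epoch_ms epoch window in ms relative to stimulus onset.
#' @param phase_ms named list of phase windows (ms).
#' @param amp_schedule named list: per feature a numeric
#'   `c(encoding=, preparation=, test=)` of base amplitudes (arbitrary
#'   units, vs. unit-variance noise).
#' @param test_gain named list: per feature a numeric
#'   `c(tested=, untested=)` multiplier applied in the test phase depending
#'   on whether the plan carrying the feature is tested (the shared rule is
#'   always "tested").
#' @param carrier_hz named list of carrier frequencies per feature (may be
#'   length > 1; components are mixed with equal energy).
#' @param noise_sd white-noise SD (the amplitude unit).
#' @param background_amp amplitude of per-trial random oscillatory
#'   background in each of the five canonical bands (delta..gamma).
#' @param amp_jitter_sd SD of the per-trial log-normal amplitude jitter on
#'   conjunction codes (trial-to-trial representation strength).
#' @param rt_mean,rt_sd RT distribution (ms) by tested priority.
#' @param error_rate error probability by tested priority.
#' @param swap_share share of committed errors that are swaps, by priority.
#' @param rt_coupling ms of RT change per unit (centred) conjunction
#'   amplitude of the tested plan; 0 decouples EEG and behavior.
#' @param include_eog append simulated VEOG/HEOG channels (with occasional
#'   blink artifacts at `blink_rate`) for artifact-rejection testing.
#' @param blink_rate fraction of trials with a blink on VEOG.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_channels = 20L, fs = 250, epoch_ms = c(-200, 2200),
                             phase_ms = list(encoding = c(0, 750),
                                             preparation = c(750, 1500),
                                             test = c(1500, 2200)),
                             amp_schedule = NULL, test_gain = NULL,
                             carrier_hz = NULL, noise_sd = 1,
                             background_amp = 0.3, amp_jitter_sd = 0.3,
                             rt_mean = c(high = 371, low = 428),
                             rt_sd = c(high = 90, low = 100),
                             error_rate = c(high = 0.11, low = 0.22),
                             swap_share = c(high = 0.74, low = 0.81),
                             rt_coupling = 0,
                             include_eog = TRUE, blink_rate = 0.05,
                             seed = 1L) {
  amp_schedule <- amp_schedule %||% list(
    rule      = c(encoding = 0.4, preparation = 0.9, test = 0.9),
    stim_high = c(encoding = 1.2, preparation = 0.35, test = 0.35),
    stim_low  = c(encoding = 1.2, preparation = 0.35, test = 0.35),
    resp_high = c(encoding = 0.0, preparation = 0.0, test = 0.7),
    resp_low  = c(encoding = 0.0, preparation = 0.0, test = 0.5),
    conj_high = c(encoding = 0.0, preparation = 0.5, test = 0.7),
    conj_low  = c(encoding = 0.0, preparation = 0.45, test = 0.6))
  # output gating: tested plans are released more strongly, and the
  # priority-dependent asymmetry (high boosted more when tested) yields a
  # priority x test-type interaction on conjunction and response codes
  test_gain <- test_gain %||% list(
    rule = c(tested = 1, untested = 1),
    stim_high = c(tested = 1, untested = 1),
    stim_low = c(tested = 1, untested = 1),
    resp_high = c(tested = 1.4, untested = 0.6),
    resp_low = c(tested = 1.1, untested = 0.9),
    conj_high = c(tested = 1.5, untested = 0.7),
    conj_low = c(tested = 1.1, untested = 0.9))
  carrier_hz <- carrier_hz %||% list(
    rule = 6, stim_high = 10, stim_low = 10, resp_high = 20, resp_low = 20,
    conj_high = c(6, 20), conj_low = c(6, 20))
  for (f in .conjrsa_features) {
    stopifnot(all(amp_schedule[[f]] >= 0), length(amp_schedule[[f]]) == 3L)
  }
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 epoch_ms = epoch_ms, phase_ms = phase_ms,
                 amp_schedule = amp_schedule, test_gain = test_gain,
                 carrier_hz = carrier_hz, noise_sd = noise_sd,
                 background_amp = background_amp, amp_jitter_sd = amp_jitter_sd,
                 rt_mean = rt_mean, rt_sd = rt_sd, error_rate = error_rate,
                 swap_share = swap_share, rt_coupling = rt_coupling,
                 include_eog = isTRUE(include_eog), blink_rate = blink_rate,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Draw the planted spatial patterns
#'
#' One unit-norm random loading vector over scalp channels per level of each
#' feature (rule: 3; stimulus and response per plan: 4; conjunction per
#' plan: 12). Reproducible under the config seed.
#'
#' @param config a [generator_config()].
#' @return a `feature_patterns` list: per feature a levels x channels
#'   matrix with unit-norm rows.
#' @export
plant_patterns <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    out <- lapply(.conjrsa_feature_levels, function(k) {
      m <- matrix(stats::rnorm(k * config$n_channels), nrow = k)
      m / sqrt(rowSums(m^2))
    })
    structure(out, class = "feature_patterns")
  })
}

# per-sample phase labels for a time vector (ms)
phase_of <- function(times_ms, phase_ms) {
  ph <- rep(NA_character_, length(times_ms))
  for (nm in names(phase_ms)) {
    w <- phase_ms[[nm]]
    sel <- times_ms >= w[1] & (times_ms < w[2] |
             (nm == names(phase_ms)[length(phase_ms)] & times_ms <= w[2]))
    ph[sel] <- nm
  }
  ph
}

# level index of each feature for one trial
trial_feature_levels <- function(trial) {
  rule_i <- match(trial$rule, .conjrsa_rules)
  c(rule = rule_i,
    stim_high = match(trial$stim_high, .conjrsa_locations),
    stim_low = match(trial$stim_low, .conjrsa_locations),
    resp_high = match(trial$correct_response_high, .conjrsa_locations),
    resp_low = match(trial$correct_response_low, .conjrsa_locations),
    conj_high = trial$const_high,
    conj_low = trial$const_low)
}

#' Simulate epoched EEG for a trial design
#'
#' Each trial's signal is the sum over active features of
#' `amplitude(feature, phase, tested) x jitter x loading x oscillation`
#' plus white Gaussian noise and a faint per-trial oscillatory background in
#' the five canonical bands. Amplitudes differ by tested status only inside
#' the test phase (output gating). The per-trial conjunction amplitude
#' jitters are returned in the `trial_amp` attribute so behavior can be
#' coupled to representation strength.
#'
#' @param designs a [generate_design()] table.
#' @param patterns a [plant_patterns()] set.
#' @param config the [generator_config()] used for the patterns.
#' @return an `epoched_eeg` object: list with `data` (trials x channels x
#'   samples array), `times` (ms), `channels`, `scalp` (indices of scalp
#'   channels), `fs`.
#' @export
simulate_epochs <- function(designs, patterns, config) {
  stopifnot(inherits(config, "generator_config"),
            inherits(patterns, "feature_patterns"))
  for (f in .conjrsa_features) {
    if (nrow(patterns[[f]]) != .conjrsa_feature_levels[[f]] ||
        ncol(patterns[[f]]) != config$n_channels)
      stop_conjrsa("pattern set does not match generator config", "conjrsa_config_error")
  }
  n_trials <- nrow(designs)
  times <- seq(config$epoch_ms[1], config$epoch_ms[2], by = 1000 / config$fs)
  n_samp <- length(times)
  ph <- phase_of(times, config$phase_ms)
  tsec <- times / 1000
  n_eog <- if (config$include_eog) 2L else 0L
  n_ch <- config$n_channels + n_eog
  band_centers <- c(2, 6, 10, 20, 33)

  with_seed(config$seed + 1L, {
    jit <- matrix(exp(stats::rnorm(n_trials * 2, 0, config$amp_jitter_sd)),
                  ncol = 2, dimnames = list(NULL, c("conj_high", "conj_low")))
    dat <- array(stats::rnorm(n_trials * n_ch * n_samp, 0, config$noise_sd),
                 dim = c(n_trials, n_ch, n_samp))
    # precompute per-phase base amplitude envelope positions
    env_phase <- matrix(0, nrow = 3, ncol = n_samp,
                        dimnames = list(c("encoding", "preparation", "test"), NULL))
    for (p in rownames(env_phase)) env_phase[p, ] <- as.numeric(ph %in% p)
    for (i in seq_len(n_trials)) {
      tr <- as.list(designs[i, ])
      lev <- trial_feature_levels(tr)
      sig <- matrix(0, nrow = config$n_channels, ncol = n_samp)
      for (f in .conjrsa_features) {
        sched <- config$amp_schedule[[f]]
        if (all(sched == 0)) next
        plan_tested <- if (f == "rule") "tested" else {
          plan <- if (grepl("_high$", f)) "high" else "low"
          if (identical(tr$tested, plan)) "tested" else "untested"
        }
        gain <- config$test_gain[[f]][[plan_tested]]
        env <- sched[["encoding"]] * env_phase["encoding", ] +
          sched[["preparation"]] * env_phase["preparation", ] +
          sched[["test"]] * gain * env_phase["test", ]
        jmul <- if (f %in% colnames(jit)) jit[i, f] else 1
        freqs <- config$carrier_hz[[f]]
        osc <- rep(0, n_samp)
        for (fc in freqs)
          osc <- osc + sin(2 * pi * fc * tsec + stats::runif(1, 0, 2 * pi))
        osc <- osc / sqrt(length(freqs))
        sig <- sig + jmul * outer(patterns[[f]][lev[[f]], ], env * osc)
      }
      # oscillatory background: random spatial weights + phase per band
      if (config$background_amp > 0) {
        for (fc in band_centers) {
          w <- stats::rnorm(config$n_channels)
          w <- w / sqrt(sum(w^2))
          sig <- sig + config$background_amp *
            outer(w, sin(2 * pi * fc * tsec + stats::runif(1, 0, 2 * pi)))
        }
      }
      dat[i, seq_len(config$n_channels), ] <-
        dat[i, seq_len(config$n_channels), ] + sig
      if (n_eog > 0 && stats::runif(1) < config$blink_rate) {
        # square blink pulse on VEOG, 200 ms, ~400 uV
        onset <- sample(which(times >= 0 & times <= 1800), 1L)
        idx <- onset:min(n_samp, onset + round(0.2 * config$fs))
        dat[i, config$n_channels + 1L, idx] <-
          dat[i, config$n_channels + 1L, idx] + 400
      }
    }
    channels <- c(sprintf("CH%02d", seq_len(config$n_channels)),
                  if (n_eog > 0) c("VEOG", "HEOG"))
    structure(list(data = dat, times = times, channels = channels,
                   scalp = seq_len(config$n_channels), fs = config$fs,
                   trial = designs$trial),
              class = "epoched_eeg", trial_amp = jit)
  })
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf("Epoched EEG: %d trials x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate behavior for a trial design
#'
#' RT is drawn from a normal distribution whose mean depends on the tested
#' plan's priority (optionally shifted by `rt_coupling` times the centred
#' conjunction amplitude of the tested plan); a drawn RT above the current
#' adaptive cutoff is an omission. Errors occur with a priority-dependent
#' rate and are split into swap vs other responses by the configured swap
#' share. The cutoff evolves trial-to-trial via [update_cutoff()].
#'
#' @param designs a [generate_design()] table.
#' @param config a [generator_config()].
#' @param trial_amp optional trials x 2 matrix (columns `conj_high`,
#'   `conj_low`) of conjunction amplitudes, e.g. the `trial_amp` attribute
#'   of [simulate_epochs()]; required when `rt_coupling != 0`.
#' @param seed seed; defaults to `config$seed + 2`.
#' @return a data.frame with columns `trial`, `rt` (ms; NA for omissions),
#'   `response` (location or NA), `correct`, `error_class`, `cutoff` (ms,
#'   deadline in force on that trial).
#' @export
simulate_behavior <- function(designs, config, trial_amp = NULL, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(designs)
  if (config$rt_coupling != 0 && is.null(trial_amp))
    stop_conjrsa("rt_coupling != 0 requires trial_amp", "conjrsa_config_error")
  with_seed(seed %||% (config$seed + 2L), {
    state <- cutoff_state()
    rt <- rep(NA_real_, n)
    response <- rep(NA_character_, n)
    correct <- logical(n)
    eclass <- character(n)
    cutoff <- numeric(n)
    amp_shift <- rep(0, n)
    if (!is.null(trial_amp) && config$rt_coupling != 0) {
      a <- ifelse(designs$tested == "high", trial_amp[, "conj_high"],
                  trial_amp[, "conj_low"])
      amp_shift <- config$rt_coupling * (a - mean(a))
    }
    for (i in seq_len(n)) {
      cutoff[i] <- state$current
      pri <- designs$tested[i]
      draw_rt <- stats::rnorm(1, config$rt_mean[[pri]] + amp_shift[i],
                              config$rt_sd[[pri]])
      tested_resp <- if (pri == "high") designs$correct_response_high[i]
                     else designs$correct_response_low[i]
      untested_resp <- if (pri == "high") designs$correct_response_low[i]
                       else designs$correct_response_high[i]
      if (draw_rt > state$current || draw_rt < 0) {
        # no response registered within the deadline
        response[i] <- NA_character_
        correct[i] <- FALSE
        eclass[i] <- "omission"
      } else {
        rt[i] <- draw_rt
        is_err <- stats::runif(1) < config$error_rate[[pri]]
        if (!is_err) {
          response[i] <- tested_resp
        } else if (!designs$overlap[i] &&
                   stats::runif(1) < config$swap_share[[pri]]) {
          response[i] <- untested_resp
        } else {
          response[i] <- sample(setdiff(.conjrsa_locations,
                                        c(tested_resp, untested_resp)), 1L)
        }
        correct[i] <- identical(response[i], tested_resp)
        eclass[i] <- if (designs$overlap[i]) {
          if (correct[i]) "correct" else "other"
        } else {
          classify_response(as.list(designs[i, ]), response[i])
        }
      }
      state <- update_cutoff(state, correct[i])
    }
    data.frame(trial = designs$trial, rt = rt, response = response,
               correct = correct, error_class = eclass, cutoff = cutoff,
               stringsAsFactors = FALSE)
  })
}
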