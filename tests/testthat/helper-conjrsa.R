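# Shared fixtures: all synthetic, built in code at test time.

zero_amp <- c(encoding = 0, preparation = 0, test = 0)

# amplitude schedule with every feature silent except those in `...`
amp_schedule_only <- function(...) {
  on <- list(...)
  sched <- list(rule = zero_amp, stim_high = zero_amp, stim_low = zero_amp,
                resp_high = zero_amp, resp_low = zero_amp,
                conj_high = zero_amp, conj_low = zero_amp)
  for (nm in names(on)) sched[[nm]] <- on[[nm]]
  sched
}

flat_gain <- function() {
  g <- c(tested = 1, untested = 1)
  list(rule = g, stim_high = g, stim_low = g, resp_high = g, resp_low = g,
       conj_high = g, conj_low = g)
}

# one simulated subject run through the full per-subject chain
fit_subject <- function(seed, sched, gains = flat_gain(), n_trials = 144L,
                        decimate = 20L, repeats = 2L,
                        lambda_grid = c(0.1, 0.5), noise_sd = 1) {
  cfg <- generator_config(seed = seed, amp_schedule = sched, test_gain = gains,
                          noise_sd = noise_sd)
  sim <- simulate_subject(cfg, n_trials = n_trials, subject_seed = seed)
  keep <- reject_artifacts(sim$eeg, c(veog = "VEOG", heog = "HEOG"))
  conjunction_rsa(sim$eeg, sim$design, sim$behavior, keep = keep,
                  decoder = decoder_spec(repeats = repeats,
                                         lambda_grid = lambda_grid),
                  decimate = decimate, seed = seed)
}

# per-subject mean phase scores for one model: subjects x 3 phases
subject_phase_means <- function(fits, model) {
  t(vapply(fits, function(f) {
    ps <- phase_scores(f$scores)
    ps <- ps[ps$model == model, ]
    c(encoding = mean(ps$encoding, na.rm = TRUE),
      preparation = mean(ps$preparation, na.rm = TRUE),
      test = mean(ps$test, na.rm = TRUE))
  }, numeric(3)))
}

# hand-rolled rsa_score container for stats-level tests
fake_rsa_score <- function(tmat_by_plan_model, times, designs) {
  d <- c(dim(tmat_by_plan_model[[1]][[1]]), 2L, 4L)
  models <- c("rule", "stimulus", "response", "conjunction")
  tv <- array(NA_real_, dim = d, dimnames = list(NULL, NULL,
                                                 c("high", "low"), models))
  for (p in c("high", "low")) for (m in models)
    tv[, , p, m] <- tmat_by_plan_model[[p]][[m]]
  structure(list(t = tv, mask = array(FALSE, dim = d, dimnames = dimnames(tv)),
                 times = times, designs = designs),
            class = "rsa_score", masked_fraction = 0)
}

# binomial 99% CI half-width
binom99 <- function(p, n) stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
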