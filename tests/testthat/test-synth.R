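test_that("planted patterns are unit-norm, level-complete and reproducible", {
  cfg <- generator_config(seed = 5)
  pat <- plant_patterns(cfg)
  expect_identical(dim(pat$rule), c(3L, 20L))
  expect_identical(dim(pat$stim_high), c(4L, 20L))
  expect_identical(dim(pat$conj_high), c(12L, 20L))
  expect_identical(dim(pat$conj_low), c(12L, 20L))
  for (f in names(pat)) {
    expect_equal(sqrt(rowSums(pat[[f]]^2)), rep(1, nrow(pat[[f]])))
    expect_gt(min(dist(pat[[f]])), 0)  # distinct loadings per level
  }
  expect_equal(pat, plant_patterns(cfg))
  expect_false(isTRUE(all.equal(pat$rule, plant_patterns(generator_config(seed = 6))$rule)))
})

test_that("simulated epochs have the declared geometry and fail on mismatched patterns", {
  cfg <- generator_config(seed = 2)
  pat <- plant_patterns(cfg)
  d <- generate_design(8, seed = 2)
  eeg <- simulate_epochs(d, pat, cfg)
  expect_identical(dim(eeg$data), c(8L, 22L, 601L))  # 20 scalp + VEOG/HEOG
  expect_equal(diff(eeg$times), rep(4, 600))
  expect_equal(range(eeg$times), c(-200, 2200))
  expect_true(all(is.finite(eeg$data)))
  expect_identical(eeg$channels[21:22], c("VEOG", "HEOG"))
  # same config -> identical data
  expect_equal(eeg$data, simulate_epochs(d, pat, cfg)$data)
  bad <- pat
  bad$rule <- bad$rule[1:2, ]
  expect_error(simulate_epochs(d, bad, cfg), class = "conjrsa_config_error")
})

test_that("single planted code at vanishing noise is low-rank and perfectly decodable", {
  cfg <- generator_config(seed = 8, noise_sd = 0, background_amp = 0,
                          include_eog = FALSE, blink_rate = 0,
                          amp_schedule = amp_schedule_only(
                            stim_high = c(encoding = 3, preparation = 3, test = 3)),
                          test_gain = flat_gain())
  pat <- plant_patterns(cfg)
  d <- generate_design(32, p_overlap = 0, seed = 8)
  eeg <- simulate_epochs(d, pat, cfg)
  # rank of the raw channel snapshot is at most the number of active levels
  snap <- eeg$data[, , 200]
  expect_lte(qr(snap, tol = 1e-6)$rank, 4L)
  bp <- band_power(eeg)
  x <- build_features(bp, 200)
  lab <- match(d$stim_high, task_locations())
  pr <- fit_predict_cv(x, lab, decoder_spec(repeats = 2, lambda_grid = 0.1), seed = 1)
  expect_equal(attr(pr, "accuracy"), 1)
})

test_that("silent generator yields chance decoding and null RSA scores", {
  cfg <- generator_config(seed = 21, amp_schedule = amp_schedule_only(),
                          test_gain = flat_gain(), include_eog = FALSE,
                          blink_rate = 0)
  pat <- plant_patterns(cfg)
  d <- generate_design(216, p_overlap = 0, seed = 21)
  eeg <- simulate_epochs(d, pat, cfg)
  bp <- band_power(eeg)
  x <- build_features(bp, 250)
  pr <- fit_predict_cv(x, d$const_high, decoder_spec(repeats = 2, lambda_grid = 0.3),
                       seed = 2)
  expect_lt(abs(attr(pr, "accuracy") - 1 / 12), binom99(1 / 12, 216))
  # single-trial RSA t-values centred on zero (one-sample test at alpha .01)
  ts <- t(vapply(seq_len(nrow(pr)), function(i)
    as.numeric(rsa_regress(pr[i, ], model_vectors(d$const_high[i]))), numeric(4)))
  for (m in 1:4) expect_gt(stats::t.test(ts[, m])$p.value, 0.01)
})

test_that("more noise lowers decoding accuracy of a fixed planted code", {
  acc_at <- function(noise) {
    cfg <- generator_config(seed = 31, noise_sd = noise, include_eog = FALSE,
                            amp_schedule = amp_schedule_only(
                              stim_high = c(encoding = 1, preparation = 1, test = 1)),
                            test_gain = flat_gain())
    pat <- plant_patterns(cfg)
    d <- generate_design(96, p_overlap = 0, seed = 31)
    eeg <- simulate_epochs(d, pat, cfg)
    x <- build_features(band_power(eeg), 250)
    attr(fit_predict_cv(x, match(d$stim_high, task_locations()),
                        decoder_spec(repeats = 2, lambda_grid = 0.3), seed = 3),
         "accuracy")
  }
  expect_gt(acc_at(0.5), acc_at(2))
})

test_that("simulated behavior reflects priority, swap share, the cutoff and coupling", {
  cfg <- generator_config(seed = 12)
  d <- generate_design(1500, seed = 12)
  b <- simulate_behavior(d, cfg)
  expect_identical(nrow(b), 1500L)
  # registered responses always beat the deadline
  expect_true(all(is.na(b$rt) | b$rt <= b$cutoff))
  expect_true(all(is.na(b$response) == (b$error_class == "omission")))
  # high-priority tests are faster and more accurate
  hi <- d$tested == "high" & !d$overlap
  lo <- d$tested == "low" & !d$overlap
  expect_lt(mean(b$rt[hi & b$correct], na.rm = TRUE),
            mean(b$rt[lo & b$correct], na.rm = TRUE))
  expect_lt(mean(!b$correct[hi]), mean(!b$correct[lo]))
  # swap share of committed errors near the configured rates
  err <- !b$correct & !is.na(b$response) & !d$overlap
  swap_share <- mean(b$error_class[err] == "swap")
  expect_lt(abs(swap_share - weighted.mean(c(0.74, 0.81), c(sum(err & hi), sum(err & lo)))),
            0.1)
  # cutoff trajectory follows the update rule: next cutoff differs only by a
  # legal step (or streak bookkeeping)
  dc <- diff(b$cutoff)
  expect_true(all(abs(dc) < 1e-9 | round(abs(dc), 1) %in% c(11.8, 23.5, 35.3)))
  expect_equal(b$cutoff[1], 1200)
  # rt_coupling shifts RT with the tested plan's conjunction amplitude
  amp <- matrix(exp(stats::rnorm(3000, 0, 0.3)), ncol = 2,
                dimnames = list(NULL, c("conj_high", "conj_low")))
  cfg2 <- generator_config(seed = 12, rt_coupling = -60)
  b2 <- simulate_behavior(d, cfg2, trial_amp = amp, seed = 99)
  a <- ifelse(d$tested == "high", amp[, 1], amp[, 2])
  sel <- b2$correct & !is.na(b2$rt)
  expect_lt(stats::coef(stats::lm(b2$rt[sel] ~ a[sel]))[2], -30)
  expect_error(simulate_behavior(d, cfg2), class = "conjrsa_config_error")
})
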