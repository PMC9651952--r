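# The package's central model fit: from epoched EEG + trial design to
# single-trial RSA scores for both action plans.

#' Fit the conjunction-RSA model to epoched EEG
#'
#' Runs the full single-trial analysis chain on one subject's data:
#' band-limited Morlet power features (5 bands x electrodes, z-scored
#' across electrodes within band), time-resolved 12-way cross-validated
#' shrinkage-LDA decoding of each action plan's constellation, and the RSA
#' regression of logit classification probabilities on rule / stimulus /
#' response / conjunction model vectors with per-constellation RT and
#' accuracy nuisance regressors.
#'
#' Overlap trials (both plans mapping to the same response) and, when a
#' keep mask is given, artifact trials are excluded before decoding.
#'
#' @param eeg an `epoched_eeg` for one subject.
#' @param design the matching [generate_design()] table.
#' @param behavior optional matching behavior table (enables the nuisance
#'   regressors).
#' @param keep optional logical keep mask from [reject_artifacts()].
#' @param wavelet a [wavelet_spec()].
#' @param decoder a [decoder_spec()].
#' @param decimate decode every `decimate`-th sample (4 ms grid; 10 gives a
#'   40 ms grid).
#' @param window_ms restrict decoding to this ms window (default: full
#'   epoch).
#' @param seed integer seed for fold randomization.
#' @return a `conj_rsa` object: list with `scores` ([score_timecourse()]
#'   result), `profiles` (both plans' probability profiles), `design`,
#'   `behavior`, `times`, `call`.
#' @seealso [phase_scores()], [cluster_permutation()], [behavior_model()]
#' @export
conjunction_rsa <- function(eeg, design, behavior = NULL, keep = NULL,
                            wavelet = wavelet_spec(), decoder = decoder_spec(),
                            decimate = 10L, window_ms = NULL, seed = 1L) {
  stopifnot(inherits(eeg, "epoched_eeg"), nrow(design) == dim(eeg$data)[1])
  sel <- !design$overlap
  if (!is.null(keep)) sel <- sel & as.logical(keep)
  design_a <- design[sel, , drop = FALSE]
  behavior_a <- if (!is.null(behavior)) behavior[sel, , drop = FALSE]
  eeg_a <- eeg
  eeg_a$data <- eeg$data[sel, , , drop = FALSE]
  bp <- band_power(eeg_a, spec = wavelet)
  t_idx <- seq(1L, dim(bp)[4], by = as.integer(decimate))
  if (!is.null(window_ms))
    t_idx <- t_idx[eeg$times[t_idx] >= window_ms[1] & eeg$times[t_idx] <= window_ms[2]]
  profiles <- decode_both_plans(bp, design_a, spec = decoder, times = eeg$times,
                                t_idx = t_idx, seed = seed)
  stats <- if (!is.null(behavior_a))
    list(high = constellation_stats(design_a, behavior_a, "high"),
         low = constellation_stats(design_a, behavior_a, "low"))
  scores <- score_timecourse(profiles, design_a, subject_stats = stats)
  structure(list(scores = scores, profiles = profiles, design = design_a,
                 behavior = behavior_a, times = profiles$high$times,
                 call = match.call()),
            class = "conj_rsa")
}

#' @export
print.conj_rsa <- function(x, ...) {
  cat("Conjunction RSA fit\n")
  cat(sprintf("  trials analysed: %d (overlap/artifact trials excluded)\n",
              nrow(x$design)))
  cat(sprintf("  decoded samples: %d (%g..%g ms)\n", length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  mean 12-way accuracy: high %.3f, low %.3f (chance %.3f)\n",
              mean(x$profiles$high$accuracy), mean(x$profiles$low$accuracy),
              1 / 12))
  invisible(x)
}

#' Phase-averaged mean RSA scores
#'
#' @param object a `conj_rsa` fit.
#' @param ... unused.
#' @return matrix of mean t-values, rows = plan:model, columns = phases.
#' @export
coef.conj_rsa <- function(object, ...) {
  ps <- phase_scores(object$scores)
  phases <- setdiff(names(ps), c("trial", "plan", "model"))
  agg <- stats::aggregate(ps[phases], ps[c("plan", "model")], mean, na.rm = TRUE)
  m <- as.matrix(agg[phases])
  rownames(m) <- paste(agg$plan, agg$model, sep = ":")
  m
}

#' @export
summary.conj_rsa <- function(object, ...) {
  out <- list(coef = coef(object),
              accuracy = c(high = mean(object$profiles$high$accuracy),
                           low = mean(object$profiles$low$accuracy)),
              masked_fraction = attr(object$scores, "masked_fraction"),
              n_trials = nrow(object$design))
  class(out) <- "summary.conj_rsa"
  out
}

#' @export
print.summary.conj_rsa <- function(x, ...) {
  cat("Conjunction RSA fit:", x$n_trials, "trials\n")
  cat(sprintf("12-way decoding accuracy (chance %.3f): high %.3f, low %.3f\n",
              1 / 12, x$accuracy["high"], x$accuracy["low"]))
  cat(sprintf("outlier-masked scores: %.2f%%\n\n", 100 * x$masked_fraction))
  cat("Mean single-trial RSA t-values by phase:\n")
  print(round(x$coef, 3))
  invisible(x)
}

#' Plot mean RSA score time courses
#'
#' One panel per model; solid line = high-priority plan, dashed = low.
#' Vertical lines mark the phase boundaries (750, 1500 ms).
#'
#' @param x a `conj_rsa` fit.
#' @param models which models to draw.
#' @param ... passed to `matplot`.
#' @export
plot.conj_rsa <- function(x, models = c("rule", "stimulus", "response",
                                        "conjunction"), ...) {
  tt <- x$scores$t
  tt[x$scores$mask] <- NA
  old <- graphics::par(mfrow = c(length(models), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in models) {
    y <- cbind(high = colMeans(tt[, , "high", m], na.rm = TRUE),
               low = colMeans(tt[, , "low", m], na.rm = TRUE))
    graphics::matplot(x$times, y, type = "l", lty = c(1, 2), col = c(2, 1),
                      xlab = "time (ms)", ylab = "mean t", main = m, ...)
    graphics::abline(v = c(0, 750, 1500), lty = 3, col = "grey")
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}
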