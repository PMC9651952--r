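# Time-resolved 12-way decoding of action constellations.
#
# Classifier: linear discriminant analysis with the pooled covariance shrunk
# toward a scaled identity, Sigma(lambda) = (1 - lambda) S + lambda nu I with
# nu = mean(diag(S)). The shrinkage strength is tuned on a small grid by
# cross-validated accuracy, then out-of-fold class probabilities are averaged
# over repeated randomized fold assignments.

#' Decoder specification
#'
#' @param k number of cross-validation folds (default 4).
#' @param repeats number of repeated randomized fold assignments (default 8).
#' @param lambda_grid shrinkage-strength grid tuned by inner CV accuracy
#'   (first repeat's fold assignment); ties resolve to the strongest
#'   shrinkage for stability.
#' @param priors `"uniform"` or `"empirical"` class priors.
#' @return a `decoder_spec` list.
#' @export
decoder_spec <- function(k = 4L, repeats = 8L,
                         lambda_grid = c(0, 0.01, 0.1, 0.3, 0.5, 1),
                         priors = c("empirical", "uniform")) {
  stopifnot(is_count(k), k >= 2, is_count(repeats),
            all(lambda_grid >= 0), all(lambda_grid <= 1))
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 lambda_grid = lambda_grid, priors = match.arg(priors)),
            class = "decoder_spec")
}

# stratified fold assignment: deal each class's shuffled members round-robin
# into folds (equal counts per class up to the surplus, which lands in
# randomly rotated folds)
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    w <- which(labels == cl)
    idx <- w[sample.int(length(w))]
    if (length(idx) < 2L)
      stop_conjrsa(sprintf("constellation %s has fewer than 2 trials; cannot stratify", cl),
                   "conjrsa_stratification_error")
    fold[idx] <- ((sample.int(k, 1L) + seq_along(idx) - 2L) %% k) + 1L
  }
  # every class must appear in every training set (= all folds but one)
  tab <- table(labels, fold)
  if (any(rowSums(tab > 0) < 2L))
    stop_conjrsa("a constellation is confined to a single fold", "conjrsa_stratification_error")
  fold
}

# fit shrinkage LDA: returns what predict_slda needs
fit_slda <- function(x, y, lambda, priors = "empirical", classes = NULL) {
  classes <- classes %||% sort(unique(y))
  p <- ncol(x)
  mu <- matrix(0, nrow = length(classes), ncol = p)
  S <- matrix(0, p, p)
  n <- nrow(x)
  for (ci in seq_along(classes)) {
    xi <- x[y == classes[ci], , drop = FALSE]
    mu[ci, ] <- colMeans(xi)
    if (nrow(xi) > 1L) S <- S + crossprod(sweep(xi, 2L, mu[ci, ]))
  }
  S <- S / max(1L, n - length(classes))
  nu <- mean(diag(S))
  if (nu <= 0) nu <- 1
  Sl <- (1 - lambda) * S + lambda * nu * diag(p)
  diag(Sl) <- diag(Sl) + 1e-8 * nu   # jitter keeps lambda = 0 well defined
  R <- chol(Sl)
  prior <- if (priors == "uniform") rep(1 / length(classes), length(classes))
           else as.numeric(table(factor(y, levels = classes))) / n
  list(classes = classes, mu = mu, R = R, log_prior = log(prior))
}

# posterior class probabilities under the fitted Gaussian discriminant
predict_slda <- function(fit, x) {
  # delta_c(x) = x' Si mu_c - 0.5 mu_c' Si mu_c + log pi_c
  Mi <- backsolve(fit$R, forwardsolve(t(fit$R), t(fit$mu)))  # Sigma^-1 mu_c
  lin <- x %*% Mi
  const <- -0.5 * colSums(t(fit$mu) * Mi) + fit$log_prior
  d <- sweep(lin, 2L, const, "+")
  d <- d - apply(d, 1L, max)
  e <- exp(d)
  e / rowSums(e)
}

cv_probs <- function(x, y, fold, lambda, k, priors, classes) {
  out <- matrix(0, nrow = nrow(x), ncol = length(classes))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- fit_slda(x[tr, , drop = FALSE], y[tr], lambda, priors, classes)
    out[!tr, ] <- predict_slda(fit, x[!tr, , drop = FALSE])
  }
  out
}

#' Cross-validated class probabilities at one time point
#'
#' Partitions trials into `k` stratified folds with (near-)equal counts of
#' each action constellation, tunes the shrinkage strength on the grid by
#' cross-validated accuracy, then averages out-of-fold class probabilities
#' across `repeats` randomized fold assignments at the tuned strength. All
#' trials (including error trials) are used for training.
#'
#' @param x trials x features matrix (see [build_features()]).
#' @param labels constellation ids (integer 1-12 or factor levels).
#' @param spec a [decoder_spec()].
#' @param seed integer seed controlling fold randomization; same seed gives
#'   identical probabilities.
#' @return trials x n_classes probability matrix (rows sum to 1), with
#'   attributes `lambda` (tuned value) and `accuracy` (mean out-of-fold
#'   top-1 accuracy across repeats).
#' @export
fit_predict_cv <- function(x, labels, spec = decoder_spec(), seed = 1L) {
  stopifnot(inherits(spec, "decoder_spec"), nrow(x) == length(labels))
  classes <- sort(unique(labels))
  with_seed(seed, {
    folds <- lapply(seq_len(spec$repeats), function(r) stratified_folds(labels, spec$k))
    # tune lambda on the first repeat's assignment
    lambda <- spec$lambda_grid[1]
    if (length(spec$lambda_grid) > 1L) {
      acc <- vapply(spec$lambda_grid, function(l) {
        pr <- cv_probs(x, labels, folds[[1L]], l, spec$k, spec$priors, classes)
        mean(classes[max.col(pr, ties.method = "first")] == labels)
      }, numeric(1))
      lambda <- spec$lambda_grid[max(which(acc == max(acc)))]
    }
    probs <- matrix(0, nrow = nrow(x), ncol = length(classes))
    accs <- numeric(spec$repeats)
    for (r in seq_len(spec$repeats)) {
      pr <- cv_probs(x, labels, folds[[r]], lambda, spec$k, spec$priors, classes)
      probs <- probs + pr
      accs[r] <- mean(classes[max.col(pr, ties.method = "first")] == labels)
    }
    probs <- probs / spec$repeats
    structure(probs, lambda = lambda, accuracy = mean(accs))
  })
}

#' Time-resolved decoding of one plan
#'
#' Runs [fit_predict_cv()] at each requested time sample of a band-power
#' array (one independent decoder per 4 ms sample; `decimate` thins the
#' sample grid for desk-scale runs).
#'
#' @param bp `band_power` array (trials x bands x channels x samples).
#' @param labels constellation ids per trial.
#' @param spec a [decoder_spec()].
#' @param times sample times in ms (length = samples dimension).
#' @param decimate keep every `decimate`-th sample.
#' @param t_idx explicit sample indices (overrides `decimate`).
#' @param seed integer seed.
#' @return a `class_prob_profile`: list with `prob` (trials x time x
#'   classes), `labels`, `times` (ms of decoded samples), `accuracy` and
#'   `lambda` per time.
#' @export
decode_timecourse <- function(bp, labels, spec = decoder_spec(), times,
                              decimate = 1L, t_idx = NULL, seed = 1L) {
  n_samp <- dim(bp)[4]
  stopifnot(length(times) == n_samp)
  t_idx <- t_idx %||% seq(1L, n_samp, by = as.integer(decimate))
  classes <- sort(unique(labels))
  prob <- array(0, dim = c(dim(bp)[1], length(t_idx), length(classes)))
  acc <- lam <- numeric(length(t_idx))
  for (j in seq_along(t_idx)) {
    xt <- build_features(bp, t_idx[j])
    pr <- fit_predict_cv(xt, labels, spec, seed = seed + 7L * j)
    prob[, j, ] <- pr
    acc[j] <- attr(pr, "accuracy"); lam[j] <- attr(pr, "lambda")
  }
  structure(list(prob = prob, labels = labels, classes = classes,
                 times = times[t_idx], t_idx = t_idx,
                 accuracy = acc, lambda = lam),
            class = "class_prob_profile")
}

#' @export
print.class_prob_profile <- function(x, ...) {
  cat(sprintf("Class probability profile: %d trials x %d times x %d classes; mean accuracy %.3f\n",
              dim(x$prob)[1], dim(x$prob)[2], dim(x$prob)[3], mean(x$accuracy)))
  invisible(x)
}

#' Decode both action plans
#'
#' Trains separate decoders on the same features: the high-plan decoder on
#' (rule, high-priority stimulus) constellation labels, the low-plan decoder
#' on (rule, low-priority stimulus) labels. Overlap trials must already be
#' excluded from `bp`/`designs`.
#'
#' @param bp `band_power` array for the analysed trials.
#' @param designs matching [generate_design()] rows (no overlap trials).
#' @inheritParams decode_timecourse
#' @return list with elements `high` and `low`, each a
#'   `class_prob_profile`.
#' @export
decode_both_plans <- function(bp, designs, spec = decoder_spec(), times,
                              decimate = 1L, t_idx = NULL, seed = 1L) {
  if (any(designs$overlap))
    stop_conjrsa("overlap trials must be excluded before decoding",
                 "conjrsa_invalid_argument")
  stopifnot(dim(bp)[1] == nrow(designs))
  if (length(unique(designs$const_high)) < 12L ||
      length(unique(designs$const_low)) < 12L)
    stop_conjrsa("all 12 constellations must occur for each plan",
                 "conjrsa_stratification_error")
  list(high = decode_timecourse(bp, designs$const_high, spec, times,
                                decimate, t_idx, seed = seed),
       low = decode_timecourse(bp, designs$const_low, spec, times,
                               decimate, t_idx, seed = seed + 104729L))
}
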