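# Representational similarity analysis on classification-probability
# profiles: per trial, time point and action plan, the 12 logit-transformed
# class probabilities are regressed simultaneously on four indicator model
# vectors (rule-match, stimulus-match, response-match, conjunction identity)
# plus intercept and per-constellation RT/accuracy nuisance regressors. The
# t-value of each indicator is that model's single-trial RSA score.

.conjrsa_models <- c("rule", "stimulus", "response", "conjunction")

#' RSA model vectors for a true constellation
#'
#' Builds the four length-12 indicator predictors against the true
#' constellation: rule-match (four 1s: the constellations sharing the rule),
#' stimulus-match (three 1s), response-match (three 1s) and conjunction
#' (one-hot at the true id), plus intercept and optional z-scored
#' per-constellation mean-RT and accuracy nuisance columns.
#'
#' @param true_id constellation id (1-12) of the decoded plan's true
#'   constellation.
#' @param constellations the [constellation_table()].
#' @param nuisance optional 12 x m matrix of nuisance regressors (e.g.
#'   columns `rt`, `acc` from [constellation_stats()]).
#' @return a 12 x (5 + m) model matrix with columns `intercept`, `rule`,
#'   `stimulus`, `response`, `conjunction`, then nuisance columns.
#' @export
model_vectors <- function(true_id, constellations = constellation_table(),
                          nuisance = NULL) {
  stopifnot(is_count(true_id), true_id <= nrow(constellations))
  tr <- constellations[constellations$id == true_id, ]
  X <- cbind(intercept = 1,
             rule = as.numeric(constellations$rule == tr$rule),
             stimulus = as.numeric(constellations$stimulus == tr$stimulus),
             response = as.numeric(constellations$response == tr$response),
             conjunction = as.numeric(constellations$id == tr$id))
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    stopifnot(nrow(nuisance) == nrow(constellations))
    X <- cbind(X, nuisance)
  }
  X
}

#' Per-constellation behavioral nuisance regressors
#'
#' Mean RT (correct, committed trials) and accuracy per constellation of the
#' given plan, z-scored across the 12 constellations; empty cells are set to
#' the mean (0 after z-scoring). Held fixed across time points.
#'
#' @param designs,behavior matching design and behavior tables (overlap
#'   trials excluded).
#' @param plan `"high"` or `"low"`.
#' @return 12 x 2 matrix with columns `rt`, `acc`.
#' @export
constellation_stats <- function(designs, behavior, plan = c("high", "low")) {
  plan <- match.arg(plan)
  ids <- designs[[paste0("const_", plan)]]
  rt <- acc <- rep(NA_real_, 12L)
  for (c_id in 1:12) {
    sel <- ids == c_id
    if (!any(sel)) next
    b <- behavior[sel, ]
    acc[c_id] <- mean(b$correct)
    ok <- b$correct & !is.na(b$rt)
    if (any(ok)) rt[c_id] <- mean(b$rt[ok])
  }
  zfill <- function(v) {
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    z[!is.finite(z)] <- 0
    z
  }
  cbind(rt = zfill(rt), acc = zfill(acc))
}

# OLS machinery for a fixed model matrix, vectorized over many outcome
# vectors: returns coefficients, t-values of the 4 indicator columns
rsa_ols_engine <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # nuisance collinear with indicators: drop nuisance columns
    warning("rank-deficient RSA design; dropping nuisance regressors")
    X <- X[, 1:5, drop = FALSE]
    qrX <- qr(X)
  }
  XtXi <- chol2inv(qr.R(qrX))
  A <- XtXi %*% t(X)              # coefficient operator
  H <- X %*% A
  df <- nrow(X) - ncol(X)
  idx <- match(.conjrsa_models, colnames(X))
  list(X = X, A = A, M = diag(nrow(X)) - H, df = df,
       d = diag(XtXi)[idx], idx = idx)
}

rsa_ols_t <- function(eng, Y, s2_min = 1e-8) {
  # Y: 12 x m matrix of logit profiles. Profiles the design fits (nearly)
  # perfectly -- e.g. probabilities collapsed onto the clipping bound, which
  # ties the logits -- have no calibrated residual scale: their t-values are
  # computed against the floored scale (kept finite) and flagged degenerate
  # so score_timecourse() can mask them.
  B <- eng$A %*% Y
  rss <- colSums((eng$M %*% Y)^2)
  s2 <- rss / eng$df
  degenerate <- s2 < s2_min
  tv <- B[eng$idx, , drop = FALSE] / sqrt(outer(eng$d, pmax(s2, s2_min)))
  tv[abs(tv) < 1e-9] <- 0          # uniform profile -> exactly 0
  rownames(tv) <- .conjrsa_models
  list(t = tv, degenerate = degenerate)
}

#' Regress one probability profile on the RSA model vectors
#'
#' Logit-transforms the 12 classification probabilities (clipped to
#' `[eps, 1 - eps]`) and regresses them on all model vectors
#' simultaneously by ordinary least squares; returns the t-statistic of
#' each of the four indicators. A profile with no residual variance (e.g.
#' uniform probabilities) returns t = 0 for all models.
#'
#' @param profile numeric vector of 12 classification probabilities.
#' @param mm a [model_vectors()] matrix.
#' @param eps logit clipping bound.
#' @return named numeric vector of t-values (`rule`, `stimulus`,
#'   `response`, `conjunction`).
#' @export
rsa_regress <- function(profile, mm, eps = 1e-6) {
  stopifnot(length(profile) == nrow(mm), all(profile >= 0), all(profile <= 1))
  eng <- rsa_ols_engine(mm)
  r <- rsa_ols_t(eng, matrix(clip_logit(profile, eps), ncol = 1))
  structure(drop(r$t), degenerate = unname(r$degenerate))
}

#' Single-trial RSA scores over the time course
#'
#' Applies the RSA regression to every trial, decoded time point and action
#' plan, then masks values exceeding 5 SD from the per-time-sample mean
#' (per plan and model). The masked fraction is reported as an attribute.
#'
#' @param profiles list with `high` and `low` [decode_timecourse()]
#'   profiles (as from [decode_both_plans()]).
#' @param designs the matching design rows.
#' @param subject_stats optional list with `high`/`low` nuisance matrices
#'   from [constellation_stats()].
#' @param eps logit clipping bound.
#' @param sd_cut outlier cut in SD units.
#' @return an `rsa_score` object: list with `t` (trials x time x 2 plans x
#'   4 models array), `mask` (same shape, TRUE = excluded), `times`,
#'   `designs`; attribute `masked_fraction`.
#' @export
score_timecourse <- function(profiles, designs, subject_stats = NULL,
                             eps = 1e-6, sd_cut = 5) {
  plans <- c("high", "low")
  n_trials <- nrow(designs)
  n_time <- length(profiles$high$times)
  tv <- array(NA_real_, dim = c(n_trials, n_time, 2L, 4L),
              dimnames = list(NULL, NULL, plans, .conjrsa_models))
  const <- constellation_table()
  for (pi in seq_along(plans)) {
    plan <- plans[pi]
    prof <- profiles[[plan]]
    ids <- designs[[paste0("const_", plan)]]
    nus <- subject_stats[[plan]]
    engines <- lapply(1:12, function(id)
      rsa_ols_engine(model_vectors(id, const, nuisance = nus)))
    for (id in sort(unique(ids))) {
      sel <- which(ids == id)
      # stack trials x time into columns of one 12 x m problem
      Y <- clip_logit(aperm(prof$prob[sel, , , drop = FALSE], c(3, 1, 2)), eps)
      dim(Y) <- c(12L, length(sel) * n_time)
      r <- rsa_ols_t(engines[[id]], Y)                # $t: 4 x m
      deg <- matrix(r$degenerate, nrow = length(sel))
      for (mi in 1:4) {
        tm <- matrix(r$t[mi, ], nrow = length(sel))
        tm[deg] <- NA_real_                           # masked below
        tv[sel, , pi, mi] <- tm
      }
    }
  }
  # outlier exclusion: values beyond sd_cut SDs of the per-sample mean are
  # masked, re-estimating mean and SD after each exclusion until convergence
  # (a single pass is blind to extreme values that inflate the SD itself)
  mask <- is.na(tv)
  for (pi in 1:2) for (mi in 1:4) for (j in seq_len(n_time)) {
    m <- mask[, j, pi, mi]
    v <- tv[, j, pi, mi]
    repeat {
      keep <- !m
      if (sum(keep) < 3L) break
      mu <- mean(v[keep]); s <- stats::sd(v[keep])
      if (!is.finite(s) || s == 0) break
      new <- keep & abs(v - mu) > sd_cut * s
      if (!any(new)) break
      m <- m | new
    }
    mask[, j, pi, mi] <- m
  }
  structure(list(t = tv, mask = mask, times = profiles$high$times,
                 designs = designs),
            class = "rsa_score", masked_fraction = mean(mask))
}

#' @export
print.rsa_score <- function(x, ...) {
  d <- dim(x$t)
  cat(sprintf("RSA scores: %d trials x %d times x %d plans x %d models (%.2f%% masked)\n",
              d[1], d[2], d[3], d[4], 100 * attr(x, "masked_fraction")))
  invisible(x)
}

#' Average RSA scores over non-overlapping time windows
#'
#' @param scores an `rsa_score`.
#' @param width window width in ms (must be a multiple of the decoded
#'   sample step). Masked cells are excluded from window means; a fully
#'   masked window is `NA`.
#' @return an `rsa_score` with windowed `t` (no mask; `times` are window
#'   centres). Trailing samples not filling a window are dropped.
#' @export
window_average <- function(scores, width = 40) {
  stopifnot(inherits(scores, "rsa_score"))
  times <- scores$times
  step <- if (length(times) > 1L) diff(times)[1] else width
  if (abs(width / step - round(width / step)) > 1e-9 || width < step)
    stop_conjrsa("window width must be a positive multiple of the sample step",
                 "conjrsa_invalid_argument")
  per <- as.integer(round(width / step))
  n_win <- length(times) %/% per
  if (n_win < 1L) stop_conjrsa("epoch shorter than one window", "conjrsa_invalid_argument")
  d <- dim(scores$t)
  out <- array(NA_real_, dim = c(d[1], n_win, d[3], d[4]),
               dimnames = c(list(NULL, NULL), dimnames(scores$t)[3:4])
  )
  centers <- numeric(n_win)
  tt <- scores$t
  tt[scores$mask] <- NA_real_
  for (w in seq_len(n_win)) {
    j <- ((w - 1L) * per + 1L):(w * per)
    centers[w] <- mean(times[j])
    out[, w, , ] <- apply(tt[, j, , , drop = FALSE], c(1, 3, 4), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  structure(list(t = out, mask = array(FALSE, dim(out)), times = centers,
                 designs = scores$designs),
            class = "rsa_score", masked_fraction = 0)
}
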