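# Group-level inference: per-time trial-level models, cluster-based
# permutation over time, phase-window averages, multilevel brain-behavior
# models, and behavioral summaries with repeated-measures ANOVA.

#' Assemble a long score table for group statistics
#'
#' Binds per-subject [score_timecourse()] results (for one model, both
#' plans) into the wide case x time layout the time-course statistics use.
#'
#' @param scores_by_subject named list (subject id -> `rsa_score`).
#' @param model one of `"rule"`, `"stimulus"`, `"response"`,
#'   `"conjunction"`.
#' @return list with `y` (cases x time matrix of scores, mask as NA),
#'   `cases` (data.frame: `subject`, `trial`, `priority` of the scored
#'   plan, `tested` 1 if that plan was tested), `times`.
#' @export
score_table <- function(scores_by_subject, model = "conjunction") {
  if (is.null(names(scores_by_subject)))
    names(scores_by_subject) <- sprintf("S%02d", seq_along(scores_by_subject))
  ylist <- list(); cases <- list()
  for (s in names(scores_by_subject)) {
    sc <- scores_by_subject[[s]]
    for (plan in c("high", "low")) {
      y <- sc$t[, , plan, model]
      y[sc$mask[, , plan, model]] <- NA_real_
      ylist[[length(ylist) + 1L]] <- y
      cases[[length(cases) + 1L]] <- data.frame(
        subject = s, trial = sc$designs$trial,
        priority = plan,
        tested = as.integer(sc$designs$tested == plan),
        stringsAsFactors = FALSE)
    }
  }
  list(y = do.call(rbind, ylist), cases = do.call(rbind, cases),
       times = scores_by_subject[[1L]]$times)
}

# two-stage statistic: per-subject OLS of y_t on the model matrix, then a
# one-sample t across subjects on the effect coefficient, per time point
two_stage_t <- function(y, cases, formula, effect, subject = "subject") {
  mm <- stats::model.matrix(formula, cases)
  j <- match(effect, colnames(mm))
  if (is.na(j)) stop_conjrsa(sprintf("effect '%s' not a column of the model matrix (%s)",
                                     effect, paste(colnames(mm), collapse = ", ")),
                             "conjrsa_invalid_argument")
  subs <- unique(cases[[subject]])
  coefs <- matrix(NA_real_, nrow = length(subs), ncol = ncol(y))
  for (si in seq_along(subs)) {
    rows <- which(cases[[subject]] == subs[si])
    Xs <- mm[rows, , drop = FALSE]
    qx <- qr(Xs)
    ys <- y[rows, , drop = FALSE]
    if (anyNA(ys)) {
      # masked scores: mean-impute within subject/time before the OLS
      for (tc in which(colSums(is.na(ys)) > 0L)) {
        v <- ys[, tc]
        v[is.na(v)] <- mean(v, na.rm = TRUE)
        ys[, tc] <- v
      }
    }
    coefs[si, ] <- qr.coef(qx, ys)[j, ]
  }
  n <- colSums(!is.na(coefs))
  mu <- colMeans(coefs, na.rm = TRUE)
  se <- apply(coefs, 2L, stats::sd, na.rm = TRUE) / sqrt(n)
  list(t = mu / se, df = max(n) - 1L, coefs = coefs)
}

#' Per-time trial-level model of RSA scores
#'
#' Fits, at each decoded time sample, a trial-level model of the score on
#' the requested effects and returns the effect's t-statistic over time.
#' `method = "lmer"` fits a mixed model with a subject random intercept
#' (falling back to the two-stage statistic on convergence failure, with a
#' message); `method = "two-stage"` (default) estimates the effect per
#' subject by OLS and tests the coefficients across subjects.
#'
#' @param tab a [score_table()] (or any list with `y`, `cases`, `times`).
#' @param formula RHS formula over columns of `tab$cases`, e.g.
#'   `~ priority * tested`.
#' @param effect model-matrix column name to test, e.g.
#'   `"prioruserlow:tested"`; check `colnames(model.matrix(...))`.
#' @param method `"two-stage"` or `"lmer"`.
#' @return list with `t` (per-time statistic), `df`, `times`.
#' @export
timecourse_model <- function(tab, formula, effect,
                             method = c("two-stage", "lmer")) {
  method <- match.arg(method)
  if (method == "two-stage") {
    r <- two_stage_t(tab$y, tab$cases, formula, effect)
    return(list(t = r$t, df = r$df, times = tab$times))
  }
  tv <- rep(NA_real_, ncol(tab$y))
  full <- stats::update.formula(formula, y ~ . + (1 | subject))
  for (tc in seq_len(ncol(tab$y))) {
    df <- tab$cases
    df$y <- tab$y[, tc]
    df <- df[!is.na(df$y), ]
    fit <- tryCatch(
      suppressMessages(lmerTest::lmer(full, data = df,
                                      control = lme4::lmerControl(calc.derivs = FALSE))),
      error = function(e) NULL)
    if (is.null(fit)) {
      message("lmer failed at sample ", tc, "; using two-stage statistic")
      r <- two_stage_t(tab$y[, tc, drop = FALSE], tab$cases, formula, effect)
      tv[tc] <- r$t
    } else {
      co <- stats::coef(summary(fit))
      row <- match(effect, rownames(co))
      tv[tc] <- co[row, "t value"]
    }
  }
  list(t = tv, df = length(unique(tab$cases$subject)) - 1L, times = tab$times)
}

# contiguous runs above threshold; returns list of index vectors
supra_clusters <- function(t_series, thr, sign = 1) {
  hit <- if (sign > 0) t_series > thr else t_series < -thr
  hit[is.na(hit)] <- FALSE
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  Map(seq, starts[r$values], ends[r$values])
}

#' Cluster-based permutation test over time
#'
#' Forms clusters of consecutive time samples whose trial-level statistic
#' exceeds the cluster-forming threshold (p < `cluster_alpha`, two-sided on
#' the t distribution), sums the t-values in each cluster, and compares each
#' cluster's mass against the distribution of the maximum cluster mass over
#' `n_perm` permutations in which the condition labels are shuffled within
#' subject. Positive and negative clusters are tested against their own
#' max-mass null distributions; reported p-values are two-tailed (tail p
#' doubled), so `p < 0.05` is the conventional familywise criterion.
#'
#' @param tab a [score_table()].
#' @param formula,effect as in [timecourse_model()].
#' @param shuffle character vector of `tab$cases` columns whose rows are
#'   permuted jointly within subject to build the null (default: all
#'   variables in `formula`).
#' @param n_perm number of permutations (>= 200).
#' @param cluster_alpha cluster-forming threshold.
#' @param seed integer seed.
#' @return data.frame (possibly 0 rows) with `start_ms`, `end_ms`, `mass`,
#'   `p`, `sign`, `effect`; attribute `t_series` carries the observed
#'   per-time statistic.
#' @export
cluster_permutation <- function(tab, formula, effect, shuffle = NULL,
                                n_perm = 1000L, cluster_alpha = 0.05,
                                seed = 1L) {
  stopifnot(n_perm >= 200L)
  shuffle <- shuffle %||% all.vars(formula)
  obs <- two_stage_t(tab$y, tab$cases, formula, effect)
  thr <- stats::qt(1 - cluster_alpha / 2, df = obs$df)
  mass_of <- function(tser, idx) sum(tser[idx])
  cl_pos <- supra_clusters(obs$t, thr, +1)
  cl_neg <- supra_clusters(obs$t, thr, -1)
  sub_rows <- split(seq_len(nrow(tab$cases)), tab$cases$subject)
  null_max <- matrix(0, nrow = n_perm, ncol = 2L)  # pos, neg masses
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      cs <- tab$cases
      for (rows in sub_rows) {
        perm <- rows[sample.int(length(rows))]
        cs[rows, shuffle] <- tab$cases[perm, shuffle, drop = FALSE]
      }
      pt <- two_stage_t(tab$y, cs, formula, effect)$t
      pmx <- vapply(supra_clusters(pt, thr, +1), mass_of, numeric(1), tser = pt)
      nmx <- vapply(supra_clusters(pt, thr, -1), mass_of, numeric(1), tser = pt)
      null_max[b, 1L] <- if (length(pmx)) max(pmx) else 0
      null_max[b, 2L] <- if (length(nmx)) min(nmx) else 0
    }
  })
  res <- list()
  add <- function(idx, sgn) {
    m <- mass_of(obs$t, idx)
    ptail <- if (sgn > 0) (1 + sum(null_max[, 1L] >= m)) / (n_perm + 1)
             else (1 + sum(null_max[, 2L] <= m)) / (n_perm + 1)
    data.frame(start_ms = tab$times[idx[1L]], end_ms = tab$times[idx[length(idx)]],
               mass = m, p = min(1, 2 * ptail), sign = sgn, effect = effect,
               stringsAsFactors = FALSE)
  }
  for (idx in cl_pos) res[[length(res) + 1L]] <- add(idx, +1L)
  for (idx in cl_neg) res[[length(res) + 1L]] <- add(idx, -1L)
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(start_ms = numeric(0), end_ms = numeric(0),
                         mass = numeric(0), p = numeric(0), sign = integer(0),
                         effect = character(0), stringsAsFactors = FALSE)
  attr(out, "t_series") <- obs$t
  attr(out, "df") <- obs$df
  out
}

#' Phase-window averages of RSA scores
#'
#' Mean score per trial, plan and model within the a priori phase windows:
#' encoding 0-750 ms, preparation 750-1500 ms, test 1500-2200 ms. Masked
#' samples are excluded; a fully masked window is `NA`.
#'
#' @param scores an `rsa_score`.
#' @param phase_ms named list of windows (ms).
#' @return data.frame with `trial`, `plan`, `model`, one column per phase.
#' @export
phase_scores <- function(scores,
                         phase_ms = list(encoding = c(0, 750),
                                         preparation = c(750, 1500),
                                         test = c(1500, 2200))) {
  stopifnot(inherits(scores, "rsa_score"))
  tt <- scores$t
  tt[scores$mask] <- NA_real_
  plans <- dimnames(tt)[[3]]; models <- dimnames(tt)[[4]]
  last <- names(phase_ms)[length(phase_ms)]
  rows <- list()
  for (plan in plans) for (model in models) {
    df <- data.frame(trial = scores$designs$trial, plan = plan, model = model,
                     stringsAsFactors = FALSE)
    for (ph in names(phase_ms)) {
      w <- phase_ms[[ph]]
      sel <- scores$times >= w[1] &
        (scores$times < w[2] | (ph == last & scores$times <= w[2]))
      df[[ph]] <- rowMeans(tt[, sel, plan, model, drop = FALSE], na.rm = TRUE)
      df[[ph]][is.nan(df[[ph]])] <- NA_real_
    }
    rows[[length(rows) + 1L]] <- df
  }
  do.call(rbind, rows)
}

#' Multilevel brain-behavior model
#'
#' Regresses trial-to-trial behavior on the test-phase RSA scores of all
#' action features of both plans plus the test-context main effect.
#' For RT the outcome is modelled with a linear mixed model after excluding
#' error trials; for accuracy a multilevel logistic regression on all
#' scored trials. A subject random intercept is always included, plus a
#' random slope on `slope_term` (the headline predictor). On convergence
#' failure the random slope is dropped; if that also fails, a two-stage
#' per-subject regression is used (both logged via `message`).
#'
#' @param df one row per trial with columns: `subject`, the outcome
#'   (`rt` ms or `correct` logical), the predictors.
#' @param outcome `"rt"` or `"accuracy"`.
#' @param predictors character vector of predictor column names.
#' @param slope_term predictor receiving a subject random slope (default the
#'   first predictor); `NULL` for intercept-only random effects.
#' @return data.frame coefficient table: `term`, `beta`, `se`, `stat`
#'   (t or z), `ci_lo`, `ci_hi`, `p`; attribute `fit_method`.
#' @export
behavior_model <- function(df, outcome = c("rt", "accuracy"), predictors,
                           slope_term = predictors[1L]) {
  outcome <- match.arg(outcome)
  stopifnot(all(predictors %in% names(df)), "subject" %in% names(df))
  if (outcome == "rt") {
    df <- df[df$correct & !is.na(df$rt), ]
    lhs <- "rt"
  } else {
    df <- df[!is.na(df$correct), ]
    df$correct <- as.integer(df$correct)
    lhs <- "correct"
  }
  rhs <- paste(predictors, collapse = " + ")
  re_full <- if (!is.null(slope_term)) sprintf("(1 + %s | subject)", slope_term)
             else "(1 | subject)"
  make_form <- function(re) stats::as.formula(paste(lhs, "~", rhs, "+", re))
  fit_one <- function(re) {
    if (outcome == "rt")
      lmerTest::lmer(make_form(re), data = df, REML = TRUE,
                     control = lme4::lmerControl(calc.derivs = FALSE))
    else
      lme4::glmer(make_form(re), data = df, family = stats::binomial,
                  control = lme4::glmerControl(calc.derivs = FALSE))
  }
  fit <- NULL; method <- "lmer"
  for (re in unique(c(re_full, "(1 | subject)"))) {
    fit <- tryCatch(suppressMessages(suppressWarnings(fit_one(re))),
                    error = function(e) NULL)
    if (!is.null(fit)) { if (re != re_full) {
      method <- "lmer-no-slope"; message("random slope dropped (convergence)") }
      break }
  }
  if (!is.null(fit)) {
    co <- stats::coef(summary(fit))
    stat_col <- if (outcome == "rt") "t value" else "z value"
    se <- co[, "Std. Error"]
    beta <- co[, "Estimate"]
    p <- if ("Pr(>|t|)" %in% colnames(co)) co[, "Pr(>|t|)"]
         else if ("Pr(>|z|)" %in% colnames(co)) co[, "Pr(>|z|)"]
         else 2 * stats::pnorm(-abs(beta / se))
    out <- data.frame(term = rownames(co), beta = beta, se = se,
                      stat = co[, stat_col], ci_lo = beta - 1.96 * se,
                      ci_hi = beta + 1.96 * se, p = p,
                      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    # two-stage fallback: per-subject GLM, coefficients tested across subjects
    message("mixed model failed; using two-stage per-subject regression")
    method <- "two-stage"
    subs <- unique(df$subject)
    cf <- NULL
    for (s in subs) {
      d <- df[df$subject == s, ]
      f <- stats::as.formula(paste(lhs, "~", rhs))
      m <- if (outcome == "rt") stats::lm(f, data = d)
           else suppressWarnings(stats::glm(f, data = d, family = stats::binomial))
      cf <- rbind(cf, stats::coef(m))
    }
    beta <- colMeans(cf); se <- apply(cf, 2, stats::sd) / sqrt(nrow(cf))
    stat <- beta / se
    p <- 2 * stats::pt(-abs(stat), df = nrow(cf) - 1L)
    out <- data.frame(term = colnames(cf), beta = beta, se = se, stat = stat,
                      ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se, p = p,
                      row.names = NULL, stringsAsFactors = FALSE)
  }
  attr(out, "fit_method") <- method
  out
}

#' Trial-wise association of high- and low-priority conjunction strength
#'
#' At each time sample, tests whether the two plans' conjunction scores
#' covary across trials, with subject treated as a random factor: the
#' association slope is estimated per subject and tested across subjects
#' (`method = "two-stage"`, default) or by `lmer` with a subject random
#' intercept.
#'
#' @param scores_by_subject named list of `rsa_score` objects.
#' @param method `"two-stage"` or `"lmer"`.
#' @return list with `t`, `df`, `times`.
#' @export
score_correlation <- function(scores_by_subject,
                              method = c("two-stage", "lmer")) {
  method <- match.arg(method)
  if (is.null(names(scores_by_subject)))
    names(scores_by_subject) <- sprintf("S%02d", seq_along(scores_by_subject))
  ylist <- xlist <- list(); cases <- list()
  for (s in names(scores_by_subject)) {
    sc <- scores_by_subject[[s]]
    yh <- sc$t[, , "high", "conjunction"]
    yl <- sc$t[, , "low", "conjunction"]
    yh[sc$mask[, , "high", "conjunction"]] <- NA
    yl[sc$mask[, , "low", "conjunction"]] <- NA
    ylist[[s]] <- yh; xlist[[s]] <- yl
    cases[[s]] <- data.frame(subject = s, n = nrow(yh), stringsAsFactors = FALSE)
  }
  times <- scores_by_subject[[1L]]$times
  subs <- names(scores_by_subject)
  if (method == "two-stage") {
    slopes <- matrix(NA_real_, length(subs), length(times))
    for (si in seq_along(subs)) {
      yh <- ylist[[si]]; yl <- xlist[[si]]
      for (tc in seq_along(times)) {
        ok <- !is.na(yh[, tc]) & !is.na(yl[, tc])
        if (sum(ok) > 3 && stats::sd(yl[ok, tc]) > 0)
          slopes[si, tc] <- stats::cov(yh[ok, tc], yl[ok, tc]) / stats::var(yl[ok, tc])
      }
    }
    n <- colSums(!is.na(slopes))
    tser <- colMeans(slopes, na.rm = TRUE) /
      (apply(slopes, 2, stats::sd, na.rm = TRUE) / sqrt(n))
    return(list(t = tser, df = max(n) - 1L, times = times))
  }
  tser <- rep(NA_real_, length(times))
  for (tc in seq_along(times)) {
    d <- do.call(rbind, lapply(subs, function(s)
      data.frame(subject = s, y = ylist[[s]][, tc], x = xlist[[s]][, tc])))
    d <- d[stats::complete.cases(d), ]
    fit <- tryCatch(suppressMessages(lmerTest::lmer(y ~ x + (1 | subject), data = d)),
                    error = function(e) NULL)
    if (!is.null(fit)) tser[tc] <- stats::coef(summary(fit))["x", "t value"]
  }
  list(t = tser, df = length(subs) - 1L, times = times)
}

#' Behavioral summary and repeated-measures ANOVA
#'
#' Per subject and tested priority: mean RT of correct committed trials,
#' error rate (incorrect, including omissions, out of scored trials), swap
#' share of committed errors, and mean cutoff. Overlap trials are excluded.
#' Each measure is tested with a one-way within-subject ANOVA on tested
#' priority.
#'
#' @param behavior,designs stacked multi-subject tables with a `subject`
#'   column (matching row order within subject).
#' @return list with `cells` (subject x priority means) and `anova`
#'   (data.frame: `measure`, `F`, `MSE`, `df1`, `df2`, `p`). Subjects
#'   without committed errors in a cell are excluded from the swap-share
#'   ANOVA (logged via `message`).
#' @export
behavior_summary <- function(behavior, designs) {
  stopifnot("subject" %in% names(behavior), "subject" %in% names(designs))
  d <- cbind(designs, behavior[, setdiff(names(behavior), c("subject", "trial"))])
  d <- d[!d$overlap, ]
  cells <- list()
  for (s in unique(d$subject)) for (pri in c("high", "low")) {
    x <- d[d$subject == s & d$tested == pri, ]
    committed <- x[!is.na(x$response), ]
    errs <- committed[!committed$correct, ]
    cells[[length(cells) + 1L]] <- data.frame(
      subject = s, priority = pri,
      rt = mean(x$rt[x$correct & !is.na(x$rt)]),
      error_rate = mean(!x$correct),
      swap_share = if (nrow(errs)) mean(errs$error_class == "swap") else NA_real_,
      cutoff = mean(x$cutoff),
      n = nrow(x), stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  rm_anova <- function(measure) {
    cc <- cells[, c("subject", "priority", measure)]
    names(cc)[3] <- "y"
    bad <- unique(cc$subject[is.na(cc$y)])
    if (length(bad)) {
      message(sprintf("%s: excluding subject(s) %s (undefined cell)",
                      measure, paste(bad, collapse = ", ")))
      cc <- cc[!cc$subject %in% bad, ]
    }
    if (length(unique(cc$subject)) < 2L)
      return(data.frame(measure = measure, F = NA, MSE = NA, df1 = NA,
                        df2 = NA, p = NA))
    cc$subject <- factor(cc$subject); cc$priority <- factor(cc$priority)
    fit <- stats::aov(y ~ priority + Error(subject / priority), data = cc)
    tab <- summary(fit)[["Error: subject:priority"]][[1L]]
    data.frame(measure = measure, F = tab["priority", "F value"],
               MSE = tab["Residuals", "Mean Sq"],
               df1 = tab["priority", "Df"], df2 = tab["Residuals", "Df"],
               p = tab["priority", "Pr(>F)"], stringsAsFactors = FALSE)
  }
  anova <- do.call(rbind, lapply(c("rt", "error_rate", "swap_share", "cutoff"),
                                 rm_anova))
  list(cells = cells, anova = anova)
}
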