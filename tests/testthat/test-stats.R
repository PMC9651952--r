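null_tab <- function(ns = 6, ntr = 30, nt = 20, seed = 1) {
  set.seed(seed)
  cases <- do.call(rbind, lapply(seq_len(ns), function(s) data.frame(
    subject = sprintf("S%d", s), trial = seq_len(ntr),
    cond = stats::rbinom(ntr, 1, 0.5), stringsAsFactors = FALSE)))
  list(y = matrix(stats::rnorm(nrow(cases) * nt), ncol = nt), cases = cases,
       times = seq(0, by = 40, length.out = nt))
}

test_that("per-time models recover planted window effects and stay null elsewhere", {
  tab <- null_tab(ns = 8, ntr = 60, nt = 30, seed = 2)
  r0 <- timecourse_model(tab, ~ cond, "cond")
  expect_length(r0$t, 30)
  expect_lt(abs(mean(r0$t)), 0.5)
  expect_identical(r0$t, timecourse_model(tab, ~ cond, "cond")$t)  # deterministic
  # plant a strong condition effect in samples 10:15 only
  tab2 <- tab
  tab2$y[tab$cases$cond == 1, 10:15] <- tab2$y[tab$cases$cond == 1, 10:15] + 1.2
  r1 <- timecourse_model(tab2, ~ cond, "cond")
  thr <- stats::qt(0.975, r1$df)
  expect_true(all(r1$t[10:15] > thr))
  # elsewhere stays mostly sub-threshold (isolated noise crossings allowed)
  expect_lt(mean(abs(r1$t[-(8:17)]) > thr), 0.25)
  expect_gt(min(r1$t[10:15]), max(r1$t[-(8:17)]))
  # the lmer route agrees with the two-stage route on a strong effect
  r2 <- timecourse_model(list(y = tab2$y[, 10, drop = FALSE], cases = tab2$cases,
                              times = tab2$times[10]), ~ cond, "cond",
                         method = "lmer")
  expect_gt(r2$t[1], thr)
})

test_that("cluster permutation finds the planted cluster and nothing in flat noise", {
  tab <- null_tab(ns = 6, ntr = 40, nt = 25, seed = 4)
  tab$y <- tab$y * 0.01   # essentially flat: no suprathreshold samples
  cl0 <- cluster_permutation(tab, ~ cond, "cond", n_perm = 200, seed = 5)
  expect_identical(nrow(cl0), 0L)
  # one strong 5-sample (200 ms on the 40 ms grid) effect
  tab2 <- null_tab(ns = 6, ntr = 40, nt = 25, seed = 6)
  win <- 11:15
  tab2$y[tab2$cases$cond == 1, win] <- tab2$y[tab2$cases$cond == 1, win] + 1.5
  cl <- cluster_permutation(tab2, ~ cond, "cond", n_perm = 300, seed = 7)
  sig <- cl[cl$p < 0.05, ]
  expect_identical(nrow(sig), 1L)
  expect_lte(sig$start_ms, tab2$times[win[1]] + 40)
  expect_gte(sig$end_ms, tab2$times[win[5]] - 40)
  expect_identical(cl, cluster_permutation(tab2, ~ cond, "cond", n_perm = 300, seed = 7))
  expect_error(cluster_permutation(tab2, ~ cond, "cond", n_perm = 50))
})

test_that("phase scores average the a priori windows and propagate masks", {
  times <- seq(-200, 2200, by = 40)
  n <- 5
  d <- generate_design(n, p_overlap = 0, seed = 5)
  tmat <- matrix(rep(seq_len(n), length(times)), nrow = n)  # constant per trial
  sc <- fake_rsa_score(list(high = list(rule = tmat, stimulus = tmat,
                                        response = tmat, conjunction = tmat),
                            low = list(rule = tmat, stimulus = tmat,
                                       response = tmat, conjunction = tmat)),
                       times, d)
  ps <- phase_scores(sc)
  expect_identical(nrow(ps), as.integer(n * 8))  # 2 plans x 4 models
  expect_equal(ps$encoding, ps$preparation)
  expect_equal(ps$test, rep(seq_len(n), 8))
  # fully masked encoding window for one trial/model -> NA
  sc$mask[2, times >= 0 & times < 750, "high", "rule"] <- TRUE
  ps2 <- phase_scores(sc)
  row <- ps2$trial == 2 & ps2$plan == "high" & ps2$model == "rule"
  expect_true(is.na(ps2$encoding[row]))
  expect_equal(ps2$test[row], 2)
})

test_that("brain-behavior model finds planted coupling and stays silent when shuffled", {
  set.seed(20)
  ns <- 12; ntr <- 120
  df <- do.call(rbind, lapply(seq_len(ns), function(s) {
    conj_h <- stats::rnorm(ntr)
    tested <- stats::rbinom(ntr, 1, 0.7)
    rt <- 400 - 25 * conj_h + 30 * stats::rnorm(ntr)
    data.frame(subject = sprintf("S%02d", s), rt = rt, correct = TRUE,
               conj_h = conj_h, stim_h = stats::rnorm(ntr), tested = tested)
  }))
  ct <- behavior_model(df, "rt", c("conj_h", "stim_h", "tested"))
  expect_lt(ct$beta[ct$term == "conj_h"], -18)
  expect_lt(abs(ct$beta[ct$term == "conj_h"] + 25),
            2 * ct$se[ct$term == "conj_h"])
  expect_lt(abs(ct$stat[ct$term == "stim_h"]), 3)
  # shuffled outcome: every predictor silent
  df2 <- df
  set.seed(21)
  df2$rt <- sample(df2$rt)
  ct2 <- behavior_model(df2, "rt", c("conj_h", "stim_h", "tested"))
  expect_true(all(abs(ct2$stat[ct2$term != "(Intercept)"]) < 3))
  # logistic path: planted accuracy coupling recovered with the right sign
  df$correct <- stats::runif(nrow(df)) < stats::plogis(1 + 0.8 * df$conj_h)
  ca <- behavior_model(df, "accuracy", c("conj_h", "stim_h", "tested"))
  expect_gt(ca$beta[ca$term == "conj_h"], 0.4)
  expect_gt(ca$stat[ca$term == "conj_h"], 4)
})

test_that("conjunction strength correlation is null for independent plans, positive for yoked ones", {
  set.seed(30)
  ns <- 6; ntr <- 80; nt <- 6
  times <- seq(0, by = 40, length.out = nt)
  mk_scores <- function(rho) {
    lapply(seq_len(ns), function(s) {
      d <- generate_design(ntr, p_overlap = 0, seed = 100 + s)
      shared <- matrix(stats::rnorm(ntr * nt), ntr)
      hi <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(ntr * nt), ntr)
      lo <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(ntr * nt), ntr)
      z <- matrix(0, ntr, nt)
      fake_rsa_score(list(high = list(rule = z, stimulus = z, response = z,
                                      conjunction = hi),
                          low = list(rule = z, stimulus = z, response = z,
                                     conjunction = lo)), times, d)
    })
  }
  r_ind <- score_correlation(mk_scores(0))
  expect_true(all(abs(r_ind$t) < stats::qt(0.995, r_ind$df)))
  r_dep <- score_correlation(mk_scores(0.6))
  expect_true(all(r_dep$t > stats::qt(0.995, r_dep$df)))
})

test_that("behavior summary matches a closed-form repeated-measures ANOVA", {
  # three subjects with hand-chosen cell means
  mk <- function(subject, rt_hi, rt_lo) {
    d <- generate_design(80, p_overlap = 0, seed = match(subject, c("A", "B", "C")))
    b <- data.frame(trial = d$trial,
                    rt = ifelse(d$tested == "high", rt_hi, rt_lo),
                    response = ifelse(d$tested == "high",
                                      d$correct_response_high, d$correct_response_low),
                    correct = TRUE, error_class = "correct", cutoff = 1200,
                    subject = subject, stringsAsFactors = FALSE)
    d$subject <- subject
    list(d = d, b = b)
  }
  parts <- Map(mk, c("A", "B", "C"), c(350, 360, 420), c(420, 400, 480))
  designs <- do.call(rbind, lapply(parts, `[[`, "d"))
  behavior <- do.call(rbind, lapply(parts, `[[`, "b"))
  s <- behavior_summary(behavior, designs)
  expect_equal(sort(s$cells$rt[s$cells$priority == "high"]), c(350, 360, 420))
  # closed-form one-way within-subject ANOVA on the 3 x 2 cell means
  m <- matrix(c(350, 420, 360, 400, 420, 480), nrow = 3, byrow = TRUE)
  gm <- mean(m)
  ss_cond <- 3 * sum((colMeans(m) - gm)^2)
  ss_subj <- 2 * sum((rowMeans(m) - gm)^2)
  ss_err <- sum((m - outer(rowMeans(m), colMeans(m), "+") + gm)^2)
  f_hand <- (ss_cond / 1) / (ss_err / 2)
  row <- s$anova[s$anova$measure == "rt", ]
  expect_equal(row$F, f_hand, tolerance = 1e-10)
  expect_equal(row$MSE, ss_err / 2, tolerance = 1e-10)
  expect_equal(c(row$df1, row$df2), c(1, 2))
  # error-free subjects are excluded from the swap-share ANOVA with a message
  expect_message(behavior_summary(behavior, designs), "swap_share")
  expect_true(is.na(s$anova$F[s$anova$measure == "swap_share"]))
})

test_that("behavior summary excludes omissions from RT means and overlap trials entirely", {
  d <- generate_design(200, p_overlap = 0.3, seed = 9)
  d$subject <- "S1"
  b <- simulate_behavior(d, generator_config(seed = 9))
  b$subject <- "S1"
  d2 <- d; d2$subject <- "S2"
  b2 <- simulate_behavior(d2, generator_config(seed = 10)); b2$subject <- "S2"
  s <- behavior_summary(rbind(b, b2), rbind(d, d2))
  keep <- !d$overlap & d$subject == "S1"
  hi <- keep & d$tested == "high" & b$correct & !is.na(b$rt)
  expect_equal(s$cells$rt[s$cells$subject == "S1" & s$cells$priority == "high"],
               mean(b$rt[hi]))
  expect_identical(sum(s$cells$n[s$cells$subject == "S1"]), sum(!d$overlap))
})
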