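test_that("model vectors carry the indicator structure of the four representations", {
  ct <- constellation_table()
  for (id in 1:12) {
    mm <- model_vectors(id, ct)
    expect_identical(colnames(mm), c("intercept", "rule", "stimulus",
                                     "response", "conjunction"))
    expect_equal(sum(mm[, "rule"]), 4)
    expect_equal(sum(mm[, "stimulus"]), 3)
    expect_equal(sum(mm[, "response"]), 3)
    expect_equal(mm[, "conjunction"], as.numeric(ct$id == id))
    expect_false(isTRUE(all.equal(mm[, "response"], mm[, "stimulus"])))
    expect_identical(qr(mm)$rank, 5L)
  }
  nus <- cbind(rt = stats::rnorm(12), acc = stats::rnorm(12))
  mm <- model_vectors(3, ct, nuisance = nus)
  expect_identical(ncol(mm), 7L)
  expect_equal(unname(mm[, "rt"]), unname(nus[, "rt"]))
})

test_that("rsa regression t-values match an independent lm() oracle", {
  set.seed(10)
  ct <- constellation_table()
  for (rep in 1:20) {
    id <- sample(12, 1)
    nus <- cbind(rt = stats::rnorm(12), acc = stats::rnorm(12))
    mm <- model_vectors(id, ct, nuisance = nus)
    p <- stats::runif(12, 0.01, 1); p <- p / sum(p)
    got <- rsa_regress(p, mm)
    # oracle: textbook OLS via stats::lm on the logit profile
    y <- log(p / (1 - p))
    df <- data.frame(y = y, mm[, -1])
    fit <- summary(stats::lm(y ~ ., data = df))
    want <- stats::coef(fit)[c("rule", "stimulus", "response", "conjunction"),
                             "t value"]
    expect_equal(as.numeric(got), unname(want), tolerance = 1e-8)
  }
})

test_that("degenerate profiles are handled: uniform gives zeros, concentrated favors conjunction", {
  mm <- model_vectors(5)
  expect_equal(as.numeric(rsa_regress(rep(1 / 12, 12), mm)), rep(0, 4))
  p <- exp(4 * (1:12 == 5)); p <- p / sum(p)
  tt <- rsa_regress(p, mm)
  expect_identical(names(which.max(tt)), "conjunction")
  expect_true(isTRUE(attr(tt, "degenerate")))  # flagged for masking downstream
})

test_that("permuting probabilities among same-rule constellations preserves the rule score", {
  set.seed(11)
  ct <- constellation_table()
  id <- 6
  mm <- model_vectors(id, ct)[, 1:2]  # intercept + rule only
  p <- stats::runif(12, 0.02, 1); p <- p / sum(p)
  base <- summary(stats::lm(log(p / (1 - p)) ~ mm[, "rule"]))$coefficients[2, "t value"]
  same_rule <- which(ct$rule == ct$rule[id])
  for (rep in 1:5) {
    p2 <- p
    p2[same_rule] <- p[sample(same_rule)]
    got <- summary(stats::lm(log(p2 / (1 - p2)) ~ mm[, "rule"]))$coefficients[2, "t value"]
    expect_equal(got, base, tolerance = 1e-9)
  }
})

test_that("the four indicators are mutually non-redundant", {
  # planting one indicator leaves residual structure the other three miss
  ct <- constellation_table()
  mm <- model_vectors(4, ct)
  for (k in c("rule", "stimulus", "response", "conjunction")) {
    others <- setdiff(c("rule", "stimulus", "response", "conjunction"), k)
    y <- mm[, k] + stats::rnorm(12, sd = 1e-3)
    res <- stats::resid(stats::lm(y ~ mm[, others]))
    expect_gt(abs(stats::cor(res, mm[, k])), 0.5)
  }
})

test_that("logit clipping is inert for interior probabilities", {
  set.seed(12)
  mm <- model_vectors(9)
  for (rep in 1:10) {
    p <- stats::runif(12, 1e-4, 1 - 1e-4)
    p <- 1e-4 + (1 - 2e-4) * (p - min(p)) / diff(range(p))  # keep in [1e-4, 1-1e-4]
    t1 <- rsa_regress(p, mm, eps = 1e-6)
    t2 <- rsa_regress(p, mm, eps = 1e-12)
    expect_lt(max(abs(t1 - t2)), 1e-6)
  }
})

test_that("score time courses mask outliers locally and report the masked fraction", {
  set.seed(13)
  n <- 60; nt <- 5
  d <- generate_design(n, p_overlap = 0, seed = 13)
  prob <- array(stats::rexp(n * nt * 12), dim = c(n, nt, 12))
  prob <- prob / array(rep(apply(prob, c(1, 2), sum), 12), dim(prob))
  prof <- list(prob = prob, times = seq(0, by = 40, length.out = nt))
  profiles <- list(high = prof, low = prof)
  sc <- score_timecourse(profiles, d)
  expect_identical(dim(sc$t), c(as.integer(n), as.integer(nt), 2L, 4L))
  expect_true(all(is.finite(sc$t[!sc$mask])))
  expect_identical(sc$t, score_timecourse(profiles, d)$t)  # deterministic
  expect_lt(attr(sc, "masked_fraction"), 0.05)
  # inject one wild probability profile: that cell masked, neighbors intact
  prob2 <- prob
  spike <- rep(1e-9 / 11, 12)
  spike[d$const_high[7]] <- 1 - 1e-9           # saturated, perfectly fit profile
  prob2[7, 3, ] <- spike
  profiles2 <- list(high = list(prob = prob2, times = prof$times), low = prof)
  sc2 <- score_timecourse(profiles2, d)
  expect_true(sc2$mask[7, 3, "high", "conjunction"])
  expect_false(any(sc2$mask[7, c(1, 2, 4, 5), "high", "conjunction"]))
})

test_that("window averaging downsamples on the 40 ms grid and respects masks", {
  n <- 4
  times <- seq(-200, 2200, by = 4)           # 601 samples
  d <- generate_design(n, p_overlap = 0, seed = 3)
  tv <- array(2.5, dim = c(n, length(times), 2, 4),
              dimnames = list(NULL, NULL, c("high", "low"),
                              c("rule", "stimulus", "response", "conjunction")))
  sc <- structure(list(t = tv, mask = array(FALSE, dim(tv), dimnames(tv)),
                       times = times, designs = d),
                  class = "rsa_score", masked_fraction = 0)
  w <- window_average(sc, 40)
  expect_identical(dim(w$t)[2], 60L)         # 2400 ms / 40 ms
  expect_true(all(w$t == 2.5))
  expect_error(window_average(sc, 30), class = "conjrsa_invalid_argument")
  # a fully masked window yields NA, not zero
  sc$mask[2, 1:10, "high", "rule"] <- TRUE
  w2 <- window_average(sc, 40)
  expect_true(is.na(w2$t[2, 1, "high", "rule"]))
  expect_equal(w2$t[2, 2, "high", "rule"], 2.5)
})
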