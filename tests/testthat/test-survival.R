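test_that("the Kaplan-Meier estimator matches hand-computed product-limit values", {
  # 6 subjects, censoring interleaved with events:
  # times 2, 4+, 6, 8, 10+, 12 (+ = censored)
  tbl <- survival_table(paste0("p", 1:6),
                        time = c(2, 4, 6, 8, 10, 12),
                        event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
                        group = "all")
  km <- km_estimate(tbl)
  ev <- km[km$n_event > 0, ]
  # S(2) = 5/6; S(6) = 5/6 * 3/4; S(8) = 5/8 * 2/3; S(12) = 0
  expect_equal(ev$time, c(2, 6, 8, 12))
  expect_equal(ev$survival, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  # and agrees with the looping oracle
  expect_equal(ev$survival, oracle_km(tbl$time, tbl$event)$surv, tolerance = 1e-12)

  # all censored -> survival stays at 1
  cens <- survival_table(paste0("c", 1:4), c(3, 5, 7, 9), rep(FALSE, 4), "all")
  expect_true(all(km_estimate(cens)$survival == 1))

  # no censoring: three deaths step 2/3, 1/3, 0
  ev3 <- survival_table(paste0("e", 1:3), c(1, 2, 3), rep(TRUE, 3), "all")
  expect_equal(km_estimate(ev3)$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  expect_error(km_estimate(tbl, group = "nope"), "no subjects")
  expect_error(survival_table("a", 0, TRUE, "g"), "positive")
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(17)
  times <- round(rexp(40, 0.1) + 0.5, 2)
  tbl <- survival_table(paste0("s", 1:40), times, rep(TRUE, 40), "all")
  km <- km_estimate(tbl)
  emp <- sapply(km$time, function(t) mean(times > t))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("the log-rank test matches the observed-minus-expected oracle", {
  # identical groups: statistic 0, p 1
  base <- data.frame(time = c(3, 5, 7, 9), event = c(TRUE, TRUE, FALSE, TRUE))
  dup <- survival_table(paste0("d", 1:8), rep(base$time, 2), rep(base$event, 2),
                        rep(c("a", "b"), each = 4))
  lr0 <- logrank_test(dup)
  expect_equal(lr0$chi_square, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1, tolerance = 1e-12)

  # 6-subject worked fixture
  tbl <- survival_table(paste0("p", 1:6),
                        time = c(2, 4, 6, 8, 10, 12),
                        event = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                        group = c("a", "a", "a", "b", "b", "b"))
  lr <- logrank_test(tbl)
  expect_equal(lr$chi_square, oracle_logrank(tbl$time, tbl$event, tbl$group),
               tolerance = 1e-9)
  expect_equal(lr$p, pchisq(lr$chi_square, 1, lower.tail = FALSE))

  # and on a larger random fixture
  set.seed(41)
  big <- survival_table(paste0("r", 1:60),
                        time = rexp(60, 0.1) + 0.01,
                        event = runif(60) < 0.8,
                        group = sample(c("a", "b"), 60, replace = TRUE))
  lrb <- logrank_test(big)
  expect_equal(lrb$chi_square, oracle_logrank(big$time, big$event, big$group),
               tolerance = 1e-9)

  expect_error(logrank_test(survival_table("x", 1, TRUE, "only")), "two groups")
  expect_error(logrank_test(survival_table(c("x", "y"), c(1, 2), c(FALSE, FALSE),
                                           c("a", "b"))), "no events")
})

test_that("log-rank p-values are approximately uniform under permuted labels", {
  set.seed(53)
  n <- 60
  time <- rexp(n, 0.1) + 0.01
  event <- runif(n) < 0.85
  ps <- replicate(300, {
    g <- sample(rep(c("a", "b"), each = n / 2))
    logrank_test(survival_table(paste0("s", 1:n), time, event, g))$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the Mantel-Haenszel hazard ratio behaves and recovers a known rate ratio", {
  base <- data.frame(time = c(3, 5, 7, 9), event = c(TRUE, TRUE, FALSE, TRUE))
  dup <- survival_table(paste0("d", 1:8), rep(base$time, 2), rep(base$event, 2),
                        rep(c("a", "b"), each = 4))
  expect_equal(hazard_ratio(dup)$hr, 1, tolerance = 1e-12)

  set.seed(71)
  tbl <- survival_table(paste0("s", 1:80),
                        time = c(rexp(40, 0.3), rexp(40, 0.1)) + 0.001,
                        event = rep(TRUE, 80),
                        group = rep(c("fast", "slow"), each = 40))
  hr <- hazard_ratio(tbl)
  flipped <- tbl
  flipped$group <- ifelse(tbl$group == "fast", "afast", "xslow")
  hr2 <- hazard_ratio(flipped)  # numerator still the faster-dying group
  expect_equal(hr2$hr, hr$hr, tolerance = 1e-12)
  relabeled <- tbl
  relabeled$group <- ifelse(tbl$group == "fast", "z_fast", "a_slow")
  expect_equal(hazard_ratio(relabeled)$hr, 1 / hr$hr, tolerance = 1e-12)

  # exponential simulation, true rate ratio 3: median estimate within [2.5, 3.6]
  set.seed(73)
  hrs <- replicate(60, {
    t <- c(rexp(100, 0.3), rexp(100, 0.1))
    cens <- runif(200) > 0.9
    tt <- ifelse(cens, t * runif(200), t)
    s <- survival_table(paste0("s", 1:200), tt + 1e-9, !cens,
                        rep(c("high", "low"), each = 100))
    hazard_ratio(s)$hr
  })
  expect_gt(median(hrs), 2.5)
  expect_lt(median(hrs), 3.6)

  # p < 0.05 iff the 95% CI excludes 1, on clean fixtures
  set.seed(79)
  for (i in 1:10) {
    ratio <- sample(c(1, 3), 1)
    t <- c(rexp(60, 0.1 * ratio), rexp(60, 0.1))
    s <- survival_table(paste0("s", 1:120), t + 1e-9, rep(TRUE, 120),
                        rep(c("high", "low"), each = 60))
    hr <- hazard_ratio(s)
    excludes <- hr$ci_lower > 1 || hr$ci_upper < 1
    expect_equal(hr$p < 0.05, excludes)
  }
})

test_that("median splits label four groups with median values going low", {
  d <- data.frame(subject = paste0("s", 1:4),
                  asgr2 = c(1, 2, 3, 4), clec12a = c(4, 3, 2, 1))
  out <- median_split_groups(d, c("asgr2", "clec12a"))
  expect_equal(out$group, c("lo/hi", "lo/hi", "hi/lo", "hi/lo"))
  expect_equal(sum(out$asgr2_level == "hi"), 2L)
  expect_equal(sum(out$clec12a_level == "hi"), 2L)

  # a value exactly at the median goes to the low stratum
  d2 <- data.frame(m1 = c(1, 2, 3), m2 = c(3, 2, 1))
  out2 <- median_split_groups(d2, c("m1", "m2"))
  expect_equal(out2$group[2], "lo/lo")

  # explicit positivity cutoffs (e.g. 37% CD45+, 7.4% M-MDSC)
  d3 <- data.frame(cd45 = c(50, 37, 20), mdsc = c(9, 7.4, 2))
  out3 <- median_split_groups(d3, c("cd45", "mdsc"),
                              thresholds = c(cd45 = 37, mdsc = 7.4))
  expect_equal(out3$group, c("hi/hi", "lo/lo", "lo/lo"))

  expect_error(median_split_groups(data.frame(a = c(1, 1), b = c(1, 2)),
                                   c("a", "b")), "constant")
})
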