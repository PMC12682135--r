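test_that("baseline status uses the latest sample at or before day 0", {
  expect_identical(baseline_status(make_traj(c("L", "U"), days = c(-7, 30))),
                   "detected")
  expect_identical(baseline_status(make_traj(c("L", "U"), days = c(-14, -3))),
                   "undetected")
  expect_error(baseline_status(make_traj(c("L", "L"), days = c(10, 40))),
               "not evaluable")
})

test_that("landmark status follows the window and pre-progression rules", {
  traj <- make_traj(c("U", "U", "L", "U"), days = c(-7, 30, 90, 150))
  pos <- landmark_status(traj, make_course())
  expect_identical(pos$status, "POSITIVE")
  expect_identical(pos$n_samples_in_window, 1L)

  # progression before the detected sample removes it from evaluation
  excl <- landmark_status(traj, make_course(progression_day = 80))
  expect_identical(excl$status, "NOT_EVALUABLE")
  expect_identical(excl$n_samples_in_window, 0L)

  neg <- landmark_status(make_traj(c("L", "U", "U"), days = c(-7, 70, 110)),
                         make_course())
  expect_identical(neg$status, "NEGATIVE")

  none <- landmark_status(make_traj(c("L", "L"), days = c(-7, 30)),
                          make_course())
  expect_identical(none$status, "NOT_EVALUABLE")
})

test_that("adding a detected in-window sample can only move status to POSITIVE", {
  base <- make_traj(c("L", "U"), days = c(-7, 70))
  for (course in list(make_course(), make_course(progression_day = 200))) {
    before <- landmark_status(base, course)$status
    extended <- rbind(base, maf_row(100, "L"))
    after <- landmark_status(extended, course)$status
    expect_identical(after, "POSITIVE")
    expect_true(before %in% c("NEGATIVE", "NOT_EVALUABLE", "POSITIVE"))
  }
})

test_that("product-limit estimate matches hand computation and edge cases", {
  km <- km_estimate(c(2, 4, 6, 8), c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(km$curve$surv, c(0.75, 0.5, 0.25, 0))
  # median: smallest time with S <= 0.5
  expect_identical(km$median, 4)

  cens <- km_estimate(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_true(all(cens$curve$surv == 1))
  expect_true(is.na(cens$median))

  one <- km_estimate(3, TRUE)
  expect_equal(one$curve$surv, 0)
  expect_identical(one$median, 3)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(5)
  times <- sample(1:50, 30, replace = TRUE)
  km <- km_estimate(times, rep(TRUE, 30))
  for (i in seq_len(nrow(km$curve))) {
    expect_equal(km$curve$surv[i], mean(times > km$curve$time[i]))
  }
})

test_that("KM agrees with survival::survfit under censoring", {
  skip_if_not_installed("survival")
  set.seed(9)
  times <- rexp(40, 1 / 100)
  events <- runif(40) < 0.7
  km <- km_estimate(times, events)
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  ev_times <- km$curve$time[km$curve$n_event > 0]
  expect_equal(km$curve$surv[km$curve$n_event > 0],
               summary(sf, times = ev_times)$surv, tolerance = 1e-10)
})

test_that("log-rank test matches an independent risk-table oracle", {
  # independent computation written directly from the risk-table definition
  oracle <- function(t1, e1, t2, e2) {
    tt <- c(t1, t2); ee <- c(e1, e2)
    g <- rep(1:2, c(length(t1), length(t2)))
    u <- 0; v <- 0
    for (s in sort(unique(tt[ee]))) {
      y1 <- sum(tt >= s & g == 1); y2 <- sum(tt >= s & g == 2)
      d1 <- sum(tt == s & ee & g == 1); d2 <- sum(tt == s & ee & g == 2)
      d <- d1 + d2; y <- y1 + y2
      u <- u + d1 - d * y1 / y
      if (y > 1) v <- v + d * (y1 / y) * (1 - y1 / y) * (y - d) / (y - 1)
    }
    u^2 / v
  }
  t1 <- c(1, 2, 3); t2 <- c(4, 5, 6)
  lr <- logrank_test(t1, rep(TRUE, 3), t2, rep(TRUE, 3))
  expect_equal(lr$chisq, oracle(t1, rep(TRUE, 3), t2, rep(TRUE, 3)))

  set.seed(13)
  ta <- rexp(12, 0.02); tb <- rexp(10, 0.05)
  ea <- runif(12) < 0.8; eb <- runif(10) < 0.8
  expect_equal(logrank_test(ta, ea, tb, eb)$chisq, oracle(ta, ea, tb, eb))
})

test_that("log-rank agrees with survival::survdiff and is label-invariant", {
  skip_if_not_installed("survival")
  set.seed(21)
  ta <- rexp(15, 0.01); tb <- rexp(15, 0.03)
  ea <- runif(15) < 0.8; eb <- runif(15) < 0.8
  lr <- logrank_test(ta, ea, tb, eb)
  sd <- survival::survdiff(
    survival::Surv(c(ta, tb), c(ea, eb)) ~ rep(1:2, c(15, 15)))
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)

  swap <- logrank_test(tb, eb, ta, ea)
  expect_equal(swap$chisq, lr$chisq)
  expect_equal(swap$observed - swap$expected,
               -(lr$observed - lr$expected), tolerance = 1e-10)

  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
})

test_that("pearson correlation matches the covariance formula and cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)

  y <- c(2.3, 1.1, 4.8, 3.2, 6.0)
  hand_r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- pearson_correlation(x, y)
  expect_equal(res$r, hand_r)
  ct <- cor.test(x, y)
  expect_equal(res$p_value, ct$p.value)

  expect_error(pearson_correlation(c(1, 1, 1), y[1:3]), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("wilcoxon rank-sum exact branch reproduces enumeration", {
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 1 / 3)

  # identical multisets: every assignment is as extreme as observed
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2))$p_value, 1)

  # untied data: agrees with wilcox.test's exact p
  set.seed(3)
  x <- rnorm(5); y <- rnorm(6) + 1
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("wilcoxon branches agree near the exact/normal threshold", {
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6) + runif(1, 0, 1.5)
    exact <- wilcoxon_rank_sum(x, y, exact_max_n = 12)$p_value
    normal <- wilcoxon_rank_sum(x, y, exact_max_n = 0)$p_value
    expect_lt(abs(exact - normal), 0.02)
  }
})

test_that("endpoint times implement OS and PFS definitions", {
  clin <- rbind(
    make_course("P1", progression_day = 100, death_day = 300),
    make_course("P2", progression_day = NA, death_day = 200),
    make_course("P3"))
  os <- endpoint_times(clin, "OS")
  expect_equal(os$time, c(300, 200, 720))
  expect_equal(os$event, c(TRUE, TRUE, FALSE))
  pfs <- endpoint_times(clin, "PFS")
  expect_equal(pfs$time, c(100, 200, 720))
  expect_equal(pfs$event, c(TRUE, TRUE, FALSE))
})

test_that("stratified survival separates extreme cohorts and validates arms", {
  mafs <- list(); clin <- list()
  for (i in 1:5) {
    pid <- sprintf("N%d", i)
    mafs[[pid]] <- make_traj(c("U", "U", "U"), days = c(-7, 90, 120),
                             patient_id = pid)
    clin[[pid]] <- make_course(pid)  # never progresses
  }
  for (i in 1:5) {
    pid <- sprintf("Q%d", i)
    mafs[[pid]] <- make_traj(c("L", "L", "L"), days = c(-7, 90, 120),
                             patient_id = pid)
    clin[[pid]] <- make_course(pid, progression_day = 150 + i * 10)
  }
  maf <- do.call(rbind, mafs)
  clinical <- do.call(rbind, clin)

  res <- stratified_survival(maf, clinical, "landmark", "PFS")
  expect_true(is.na(res$medians_days[["negative"]]))
  expect_false(is.na(res$medians_days[["positive"]]))
  expect_lt(res$logrank$p_value, 0.05)
  expect_identical(unname(res$n), c(5L, 5L))

  # all patients positive -> no negative arm
  expect_error(stratified_survival(maf[maf$detected, ],
                                   clinical[6:10, ], "landmark", "PFS"),
               "per ctDNA status")
})
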