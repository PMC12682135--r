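test_that("pairwise transitions follow the CI-based rule table", {
  pair <- function(a, b) {
    t <- make_traj(c(a, b), days = c(0, 30))
    compare_pair(t[1, ], t[2, ])$kind
  }
  expect_identical(pair("L", "U"), "CLEARANCE")
  expect_identical(pair("H", "U"), "CLEARANCE")
  expect_identical(pair("U", "L"), "INCREASE")   # redetection at any level
  expect_identical(pair("U", "U"), "REMAINS_NEGATIVE")
  expect_identical(pair("L", "H"), "INCREASE")   # CI [1,2] vs [5,7]
  expect_identical(pair("H", "L"), "DECREASE")
  expect_identical(pair("L", "L"), "STABLE")

  # overlapping CIs fail both significance rules, in either direction
  a <- maf_row(0, "L"); a$maf_ci_low <- 1; a$maf_ci_high <- 2
  b <- maf_row(30, "L"); b$maf_ci_low <- 1.5; b$maf_ci_high <- 3
  c <- maf_row(60, "L"); c$maf_ci_low <- 1; c$maf_ci_high <- 2
  expect_identical(compare_pair(a, b)$kind, "STABLE")
  expect_identical(compare_pair(b, c)$kind, "STABLE")

  expect_error(compare_pair(b, a), "increasing day")
})

test_that("clearance and redetection are symmetric under status inversion", {
  for (s in c("L", "H")) {
    t <- make_traj(c(s, "U"), days = c(0, 30))
    rev <- make_traj(c("U", s), days = c(0, 30))
    expect_identical(compare_pair(t[1, ], t[2, ])$kind, "CLEARANCE")
    expect_identical(compare_pair(rev[1, ], rev[2, ])$kind, "INCREASE")
  }
})

test_that("increase confirmation needs a non-decreasing positive next sample", {
  # non-decreasing positive next sample (overlapping CIs) confirms
  expect_identical(confirm_increase(make_traj(c("U", "L", "L")), 2), "confirmed")
  # significantly higher next sample also confirms
  expect_identical(confirm_increase(make_traj(c("U", "L", "H")), 2), "confirmed")
  # increase as final sample of follow-up is unconfirmed
  expect_identical(confirm_increase(make_traj(c("U", "L")), 2), "unconfirmed")
  # followed by clearance: unconfirmed
  expect_identical(confirm_increase(make_traj(c("U", "L", "U")), 2), "unconfirmed")
  # followed by a significant decrease: unconfirmed
  expect_identical(confirm_increase(make_traj(c("U", "H", "L")), 2), "unconfirmed")

  expect_error(confirm_increase(make_traj(c("U", "L")), 5), "out of range")
  expect_error(confirm_increase(make_traj(c("L", "L")), 2), "not an INCREASE")
})

test_that("trajectory classification aggregates events and flags", {
  single <- classify_trajectory(make_traj("L", days = -7))
  expect_identical(nrow(single$events), 0L)
  expect_false(single$any_clearance)
  expect_false(single$any_increase_after_treatment_start)

  cl <- classify_trajectory(make_traj(c("L", "U", "U", "U")))
  expect_identical(cl$events$kind,
                   c("CLEARANCE", "REMAINS_NEGATIVE", "REMAINS_NEGATIVE"))
  expect_true(cl$any_clearance)
  expect_false(cl$any_increase_after_treatment_start)

  up <- classify_trajectory(make_traj(c("U", "L", "H")))
  expect_identical(up$events$kind, c("INCREASE", "INCREASE"))
  expect_identical(up$events$confirmed, c("confirmed", "unconfirmed"))
  expect_true(up$any_increase_after_treatment_start)
})

test_that("summary flags ignore transitions completed before treatment start", {
  # clearance between two pre-treatment samples does not count
  t <- make_traj(c("L", "U", "U"), days = c(-20, -5, 30))
  cl <- classify_trajectory(t)
  expect_identical(cl$events$kind[1], "CLEARANCE")
  expect_false(cl$any_clearance)
  # but baseline -> first on-treatment sample does
  t2 <- make_traj(c("L", "U"), days = c(-5, 30))
  expect_true(classify_trajectory(t2)$any_clearance)
})

test_that("progression relation categories and lead time follow the day rules", {
  up <- make_traj(c("L", "H"), days = c(-5, 100))
  rel <- relate_to_progression(up, make_course(progression_day = 180))
  expect_identical(rel$category, "INCREASE_BEFORE_PROGRESSION")
  expect_identical(rel$lead_time_days, 80)

  flat <- make_traj(c("L", "L"), days = c(-5, 100))
  expect_identical(
    relate_to_progression(flat, make_course(progression_day = 180))$category,
    "NO_INCREASE")

  # an increase dated the progression day itself is at-progression
  same <- relate_to_progression(up, make_course(progression_day = 100))
  expect_identical(same$category, "INCREASE_AT_OR_AFTER_PROGRESSION")
  expect_identical(same$lead_time_days, 0)

  noprog <- relate_to_progression(up, make_course())
  expect_identical(noprog$category, "NO_PROGRESSION")
  expect_true(noprog$any_increase)
  expect_true(is.na(noprog$lead_time_days))

  expect_error(relate_to_progression(up, make_course(progression_day = -10)),
               "before treatment start")
})

test_that("sankey counts reproduce a cohort of known construction", {
  # 12 progressors: 5 increase before progression, 3 at/after, 4 without
  # an increase; 2 non-progressors without increase. Total 14.
  mafs <- list(); clin <- list()
  add <- function(pid, statuses, days, prog) {
    mafs[[pid]] <<- make_traj(statuses, days = days, patient_id = pid)
    clin[[pid]] <<- make_course(pid, progression_day = prog)
  }
  for (i in 1:5) add(sprintf("B%d", i), c("L", "H", "H"), c(-5, 60, 120), 150)
  for (i in 1:3) add(sprintf("A%d", i), c("L", "L", "H"), c(-5, 60, 200), 150)
  for (i in 1:4) add(sprintf("N%d", i), c("L", "L", "L"), c(-5, 60, 120), 150)
  for (i in 1:2) add(sprintf("F%d", i), c("L", "L"), c(-5, 60), NA_real_)
  maf <- do.call(rbind, mafs)
  clinical <- do.call(rbind, clin)

  tab <- sankey_counts(maf, clinical)
  expect_identical(sum(tab$n), 14L)
  get <- function(prog, inc, timing) {
    sel <- tab$progressed == prog & tab$any_increase == inc &
      (is.na(tab$timing) | tab$timing == timing)
    tab$n[sel][1]
  }
  expect_identical(get(TRUE, TRUE, "before"), 5L)
  expect_identical(get(TRUE, TRUE, "at_or_after"), 3L)
  expect_identical(get(TRUE, FALSE, NA), 4L)
  expect_identical(get(FALSE, FALSE, NA), 2L)

  # progressors with an increase after progression: 8 total had an increase
  expect_identical(sum(tab$n[tab$progressed & tab$any_increase]), 8L)
})

test_that("sankey handles empty and singleton cohorts", {
  empty <- sankey_counts(make_traj("L")[0, ], make_course()[0, ])
  expect_identical(sum(empty$n), 0L)
  expect_identical(nrow(empty), 5L)

  one <- sankey_counts(make_traj(c("L", "L")), make_course())
  expect_identical(sum(one$n), 1L)
  expect_identical(one$n[!one$progressed & !one$any_increase], 1L)

  dup <- rbind(make_course("P1"), make_course("P1"))
  expect_error(sankey_counts(make_traj(c("L", "L")), dup), "duplicate")
})

test_that("vectorized trajectory classification agrees with pairwise calls", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:6, 1)
    statuses <- sample(c("U", "L", "H"), n, replace = TRUE)
    traj <- make_traj(statuses)
    cls <- classify_trajectory(traj)
    for (i in 2:n) {
      ev <- compare_pair(traj[i - 1, ], traj[i, ])
      expect_identical(cls$events$kind[i - 1], ev$kind)
      if (ev$kind == "INCREASE") {
        expect_identical(cls$events$confirmed[i - 1],
                         confirm_increase(traj, i))
      }
    }
  }
})
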