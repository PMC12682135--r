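#' Baseline ctDNA status of a patient
#'
#' The baseline status is the detection call of the latest sample drawn at
#' or before treatment start (day 0). Patients without any baseline sample
#' are not evaluable and raise an error, mirroring the standard exclusion
#' of such patients from baseline analyses.
#'
#' @inheritParams confirm_increase
#'
#' @return `"detected"` or `"undetected"`.
#' @export
baseline_status <- function(traj) {
  validate_trajectory(traj)
  pre <- traj[traj$collection_day <= 0, , drop = FALSE]
  if (nrow(pre) == 0L) {
    stop("no baseline sample at or before day 0: patient not evaluable",
         call. = FALSE)
  }
  if (pre$detected[nrow(pre)]) "detected" else "undetected"
}

#' Landmark ctDNA status within a post-treatment window
#'
#' A patient is landmark-positive when at least one evaluable sample inside
#' the window is ctDNA-detected, landmark-negative when evaluable samples
#' exist and all are undetected, and not evaluable otherwise. Only samples
#' taken strictly before progression are evaluable, so post-progression
#' ctDNA cannot leak into the landmark stratification. The default window
#' of days 60-122 operationalises "2-4 months after treatment start".
#'
#' @inheritParams confirm_increase
#' @param course One-row data frame (or named list) with `progression_day`
#'   (`NA` if no progression).
#' @param window_days Numeric length-2 vector, inclusive day bounds
#'   (default `c(60, 122)`).
#'
#' @return A one-row tibble: `status` (`"POSITIVE"`, `"NEGATIVE"` or
#'   `"NOT_EVALUABLE"`) and `n_samples_in_window`.
#' @export
landmark_status <- function(traj, course, window_days = c(60, 122)) {
  validate_trajectory(traj)
  stopifnot(length(window_days) == 2L, window_days[1] < window_days[2])
  prog <- course$progression_day
  has_prog <- !is.null(prog) && length(prog) == 1L && !is.na(prog)
  keep <- traj$collection_day >= window_days[1] &
          traj$collection_day <= window_days[2]
  if (has_prog) keep <- keep & traj$collection_day < prog
  inw <- traj[keep, , drop = FALSE]
  status <- if (nrow(inw) == 0L) {
    "NOT_EVALUABLE"
  } else if (any(inw$detected)) {
    "POSITIVE"
  } else {
    "NEGATIVE"
  }
  tibble::tibble(status = status, n_samples_in_window = nrow(inw))
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Right-censored product-limit estimator. At tied times, events are
#' processed before censorings. The median is the smallest time at which
#' the survival estimate drops to 0.5 or below, and is `NA` when the curve
#' never reaches 0.5.
#'
#' @param times Follow-up times (days, >= 0).
#' @param events Logical event indicators (`TRUE` = event,
#'   `FALSE` = censored).
#'
#' @return A list of class `"km_curve"`: tibble `curve` with `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, plus `median` and `n`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1L,
            all(times >= 0))
  events <- as.logical(events)
  ut <- sort(unique(times))
  n <- length(times)
  n_risk <- n_event <- n_censor <- integer(length(ut))
  surv <- numeric(length(ut))
  s <- 1
  at_risk <- n
  for (i in seq_along(ut)) {
    t <- ut[i]
    d <- sum(times == t & events)
    c_ <- sum(times == t & !events)
    n_risk[i] <- at_risk
    n_event[i] <- d
    n_censor[i] <- c_
    if (d > 0) s <- s * (1 - d / at_risk)
    surv[i] <- s
    at_risk <- at_risk - d - c_
  }
  med_idx <- which(surv <= 0.5 & n_event > 0)
  median <- if (length(med_idx)) ut[min(med_idx)] else NA_real_
  structure(list(
    curve = tibble::tibble(time = ut, n_risk = n_risk, n_event = n_event,
                           n_censor = n_censor, surv = surv),
    median = median,
    n = n
  ), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n,
      "; events =", sum(x$curve$n_event),
      "; median =", if (is.na(x$median)) "not reached" else x$median, "\n")
  print(x$curve, ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank test comparing two survival
#' distributions: at each distinct event time the observed events in group
#' A are compared with their hypergeometric expectation given the risk
#' sets, and the summed observed-minus-expected is referred to a 1-df
#' chi-square.
#'
#' @param time_a,event_a Times and logical event indicators, group A.
#' @param time_b,event_b Times and logical event indicators, group B.
#'
#' @return A list: `chisq`, `p_value`, `observed` and `expected` events in
#'   group A, `variance`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  time <- c(time_a, time_b)
  event <- as.logical(c(event_a, event_b))
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  ev_times <- sort(unique(time[event]))
  o_a <- e_a <- v <- 0
  for (t in ev_times) {
    at <- time >= t
    n1 <- sum(at & grp == 1L)
    n2 <- sum(at & grp == 2L)
    nt <- n1 + n2
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & grp == 1L)
    o_a <- o_a + d1
    e_a <- e_a + d * n1 / nt
    if (nt > 1) {
      v <- v + d * (n1 / nt) * (n2 / nt) * (nt - d) / (nt - 1)
    }
  }
  if (v == 0) {
    # no informative event time (e.g. all events in wells of size 1)
    return(list(chisq = 0, p_value = 1, observed = o_a, expected = e_a,
                variance = 0))
  }
  chisq <- (o_a - e_a)^2 / v
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1,
                                              lower.tail = FALSE),
       observed = o_a, expected = e_a, variance = v)
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson correlation; the p-value uses the exact t transform
#' `t = r sqrt((n-2)/(1-r^2))` with n-2 degrees of freedom (two-sided).
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with non-zero
#'   variance.
#'
#' @return A list: `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  n <- length(x)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' Wilcoxon rank-sum (Mann-Whitney) test with an exact small-sample branch
#'
#' Ranks use midranks for ties. For combined sample sizes up to
#' `exact_max_n` the two-sided p-value is computed by exhaustive
#' enumeration of all group assignments of the observed rank multiset
#' (probability of a rank sum at least as far from its null expectation as
#' observed), which remains exact under ties. Larger samples use the
#' normal approximation with the usual tie correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param exact_max_n Combined size at or below which enumeration is used
#'   (default 12).
#'
#' @return A list: `statistic` (rank sum of `x`), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max_n = 12L) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  rk <- rank(c(x, y))
  w <- sum(rk[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (n <= exact_max_n) {
    combos <- utils::combn(n, nx)
    sums <- colSums(matrix(rk[combos], nrow = nx))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    ties <- table(rk)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 == 0) {
      return(list(statistic = w, p_value = 1, method = "normal"))
    }
    # continuity-corrected normal deviate
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal")
  }
}

#' Per-patient survival endpoints from the clinical table
#'
#' OS time is days to death (event) or last follow-up (censored); PFS time
#' is days to the earlier of progression and death (event) or last
#' follow-up (censored). All times are measured from treatment start
#' (day 0).
#'
#' @param clinical Clinical table (`patient_id`, `progression_day`,
#'   `death_day`, `last_followup_day`).
#' @param endpoint `"OS"` or `"PFS"`.
#'
#' @return Tibble: `patient_id`, `time`, `event`.
#' @export
endpoint_times <- function(clinical, endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  prog <- clinical$progression_day
  death <- clinical$death_day
  fup <- clinical$last_followup_day
  if (endpoint == "OS") {
    event <- !is.na(death)
    time <- ifelse(event, death, fup)
  } else {
    first <- pmin(prog, death, na.rm = TRUE)
    event <- !is.na(prog) | !is.na(death)
    time <- ifelse(event, first, fup)
  }
  tibble::tibble(patient_id = clinical$patient_id, time = time, event = event)
}

#' Survival stratified by baseline or landmark ctDNA status
#'
#' Splits the cohort by ctDNA status — at baseline, or within a landmark
#' window using only pre-progression samples — and compares OS or PFS
#' between the ctDNA-negative and ctDNA-positive groups with Kaplan-Meier
#' curves and a log-rank test. Patients whose status is not evaluable (no
#' baseline sample, or no evaluable sample in the window) are dropped.
#' Medians are reported in days and months (30.44 days per month).
#'
#' @param maf Per-sample MAF table (one assay per patient).
#' @param clinical Clinical table, one row per patient.
#' @param grouping `"baseline"` or `"landmark"`.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param window_days Landmark window (used when `grouping = "landmark"`).
#'
#' @return A list: `groups` (tibble patient_id/group), `curves`
#'   (named list of `km_curve`, `"negative"` and `"positive"`), `logrank`
#'   (see [logrank_test()]), `medians_days`, `medians_months` (named
#'   numeric), `n` (named integer).
#' @export
stratified_survival <- function(maf, clinical,
                                grouping = c("baseline", "landmark"),
                                endpoint = c("OS", "PFS"),
                                window_days = c(60, 122)) {
  grouping <- match.arg(grouping)
  endpoint <- match.arg(endpoint)
  groups <- lapply(clinical$patient_id, function(pid) {
    traj <- maf[!is.na(maf$patient_id) & maf$patient_id == pid, , drop = FALSE]
    if (nrow(traj) == 0L) return(NA_character_)
    course <- clinical[clinical$patient_id == pid, , drop = FALSE]
    if (grouping == "baseline") {
      tryCatch(
        if (baseline_status(traj) == "detected") "positive" else "negative",
        error = function(e) NA_character_)
    } else {
      st <- landmark_status(traj, course, window_days)$status
      switch(st, POSITIVE = "positive", NEGATIVE = "negative", NA_character_)
    }
  })
  groups <- tibble::tibble(patient_id = clinical$patient_id,
                           group = unlist(groups))
  keep <- !is.na(groups$group)
  ep <- endpoint_times(clinical[keep, , drop = FALSE], endpoint)
  grp <- groups$group[keep]
  if (sum(grp == "negative") < 1L || sum(grp == "positive") < 1L) {
    stop("need at least one evaluable patient per ctDNA status group",
         call. = FALSE)
  }
  neg <- grp == "negative"
  curves <- list(
    negative = km_estimate(ep$time[neg], ep$event[neg]),
    positive = km_estimate(ep$time[!neg], ep$event[!neg])
  )
  lr <- logrank_test(ep$time[neg], ep$event[neg],
                     ep$time[!neg], ep$event[!neg])
  med <- c(negative = curves$negative$median,
           positive = curves$positive$median)
  list(
    groups = groups,
    curves = curves,
    logrank = lr,
    medians_days = med,
    medians_months = med / 30.44,
    n = c(negative = sum(neg), positive = sum(!neg))
  )
}
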