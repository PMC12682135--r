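#' Classify the transition between two consecutive ctDNA samples
#'
#' Implements the CI-based transition taxonomy used for longitudinal ctDNA
#' monitoring: clearance is a transition from detectable to undetectable
#' ctDNA; an increase is a significant rise in MAF with non-overlapping 95%
#' confidence intervals, or detection following a previously undetectable
#' sample; a decrease is a significant reduction with non-overlapping CIs.
#' Two detected samples with overlapping CIs are STABLE; two undetected
#' samples REMAINS_NEGATIVE.
#'
#' @param prev,curr One-row data frames (or named lists) with fields
#'   `detected`, `maf_ci_low`, `maf_ci_high`, `collection_day`; `prev` must
#'   be collected strictly earlier.
#'
#' @return A one-row tibble: `kind` (one of `"CLEARANCE"`, `"DECREASE"`,
#'   `"INCREASE"`, `"STABLE"`, `"REMAINS_NEGATIVE"`), `from_day`, `to_day`,
#'   `confirmed` (`NA`; filled in by [classify_trajectory()] for
#'   increases).
#' @export
compare_pair <- function(prev, curr) {
  if (!(prev$collection_day < curr$collection_day)) {
    stop("samples must be in strictly increasing day order", call. = FALSE)
  }
  kind <- if (prev$detected && !curr$detected) {
    "CLEARANCE"
  } else if (!prev$detected && curr$detected) {
    "INCREASE"
  } else if (!prev$detected && !curr$detected) {
    "REMAINS_NEGATIVE"
  } else if (curr$maf_ci_low > prev$maf_ci_high) {
    "INCREASE"
  } else if (curr$maf_ci_high < prev$maf_ci_low) {
    "DECREASE"
  } else {
    "STABLE"
  }
  tibble::tibble(kind = kind,
                 from_day = prev$collection_day,
                 to_day = curr$collection_day,
                 confirmed = NA_character_)
}

validate_trajectory <- function(traj) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 1L)
  if (is.unsorted(traj$collection_day, strictly = TRUE)) {
    stop("trajectory days must be strictly increasing", call. = FALSE)
  }
  if (length(unique(traj$assay)) > 1L) {
    stop("trajectory must use a single assay", call. = FALSE)
  }
  invisible(traj)
}

#' Confirm or refute a ctDNA increase using the following sample
#'
#' An increase is confirmed when the next sample is a non-decreasing
#' positive sample: detected and not a significant (CI-based) decrease.
#' It is unconfirmed when the next sample is undetected, significantly
#' lower, or absent because follow-up ended.
#'
#' @param traj A trajectory: data frame of MAF rows for one patient and
#'   assay, in strictly increasing `collection_day` order.
#' @param increase_index Row index of the *second* sample of the increase
#'   transition (the sample the trajectory rose to).
#'
#' @return `"confirmed"` or `"unconfirmed"`.
#' @export
confirm_increase <- function(traj, increase_index) {
  validate_trajectory(traj)
  i <- increase_index
  if (i < 2L || i > nrow(traj)) {
    stop("increase_index out of range", call. = FALSE)
  }
  ev <- compare_pair(traj[i - 1L, ], traj[i, ])
  if (ev$kind != "INCREASE") {
    stop("transition at increase_index is not an INCREASE", call. = FALSE)
  }
  if (i == nrow(traj)) {
    return("unconfirmed")
  }
  nxt <- traj[i + 1L, ]
  follow <- compare_pair(traj[i, ], nxt)
  if (nxt$detected && !(follow$kind %in% c("DECREASE", "CLEARANCE"))) {
    "confirmed"
  } else {
    "unconfirmed"
  }
}

# Vectorized transition classification over a whole trajectory; one row per
# consecutive pair. Semantically identical to compare_pair/confirm_increase
# applied pairwise (a property test asserts the agreement).
classify_core <- function(det, lo, hi, day) {
  n <- length(det)
  p <- seq_len(n - 1L)
  q <- p + 1L
  kind <- ifelse(det[p] & !det[q], "CLEARANCE",
          ifelse(!det[p] & det[q], "INCREASE",
          ifelse(!det[p] & !det[q], "REMAINS_NEGATIVE",
          ifelse(lo[q] > hi[p], "INCREASE",
          ifelse(hi[q] < lo[p], "DECREASE", "STABLE")))))
  confirmed <- rep(NA_character_, n - 1L)
  for (j in which(kind == "INCREASE")) {
    confirmed[j] <- if (j + 1L <= n - 1L && det[j + 2L] &&
                        !(kind[j + 1L] %in% c("DECREASE", "CLEARANCE"))) {
      "confirmed"
    } else {
      "unconfirmed"
    }
  }
  tibble::tibble(kind = kind, from_day = day[p], to_day = day[q],
                 confirmed = confirmed)
}

#' Classify a full ctDNA trajectory into transition events
#'
#' Applies [compare_pair()] to consecutive samples, annotates each increase
#' as confirmed/unconfirmed via [confirm_increase()], and summarises the
#' post-treatment course. The summary flags only consider transitions whose
#' destination sample was taken after treatment start (`to_day > 0`,
#' treatment start = day 0), so the baseline-to-first-on-treatment
#' transition counts as post-treatment.
#'
#' @inheritParams confirm_increase
#'
#' @return A list with `events` (tibble: `kind`, `from_day`, `to_day`,
#'   `confirmed`) and logical flags `any_clearance`, `any_decrease`,
#'   `any_increase_after_treatment_start`.
#' @export
classify_trajectory <- function(traj) {
  validate_trajectory(traj)
  n <- nrow(traj)
  if (n == 1L) {
    return(list(
      events = tibble::tibble(kind = character(0), from_day = numeric(0),
                              to_day = numeric(0), confirmed = character(0)),
      any_clearance = FALSE, any_decrease = FALSE,
      any_increase_after_treatment_start = FALSE))
  }
  events <- classify_core(traj$detected, traj$maf_ci_low, traj$maf_ci_high,
                          traj$collection_day)
  post <- events$to_day > 0
  list(
    events = events,
    any_clearance = any(post & events$kind == "CLEARANCE"),
    any_decrease = any(post & events$kind == "DECREASE"),
    any_increase_after_treatment_start = any(post & events$kind == "INCREASE")
  )
}

#' Relate molecular increase events to radiological progression
#'
#' Determines whether a post-treatment ctDNA increase anticipated clinical
#' progression, and by how long. "Before progression" uses a strict day
#' inequality: an increase dated the very day of progression counts as
#' at-progression, keeping lead-time claims conservative. Lead time is
#' measured from the earliest qualifying increase.
#'
#' @inheritParams confirm_increase
#' @param course One-row data frame (or named list) for the patient with at
#'   least `progression_day` (`NA` when the patient has not progressed).
#'
#' @return A one-row tibble: `category` (one of
#'   `"INCREASE_BEFORE_PROGRESSION"`, `"INCREASE_AT_OR_AFTER_PROGRESSION"`,
#'   `"NO_INCREASE"`, `"NO_PROGRESSION"`), `lead_time_days` (`NA` unless an
#'   increase and a progression both exist), `any_increase`.
#' @export
relate_to_progression <- function(traj, course) {
  cls <- classify_trajectory(traj)
  prog <- course$progression_day
  has_prog <- !is.null(prog) && length(prog) == 1L && !is.na(prog)
  if (has_prog && prog < 0) {
    stop("progression before treatment start", call. = FALSE)
  }
  inc_days <- cls$events$to_day[cls$events$kind == "INCREASE" &
                                cls$events$to_day > 0]
  any_inc <- length(inc_days) > 0L
  if (!has_prog) {
    category <- "NO_PROGRESSION"
    lead <- NA_real_
  } else if (!any_inc) {
    category <- "NO_INCREASE"
    lead <- NA_real_
  } else if (any(inc_days < prog)) {
    category <- "INCREASE_BEFORE_PROGRESSION"
    lead <- prog - min(inc_days)
  } else {
    category <- "INCREASE_AT_OR_AFTER_PROGRESSION"
    lead <- prog - min(inc_days)
  }
  tibble::tibble(category = category, lead_time_days = lead,
                 any_increase = any_inc)
}

#' Cross-tabulate progression, ctDNA increase and increase timing
#'
#' Produces the event accounting behind a progression/increase Sankey
#' diagram: every patient falls in exactly one of five cells defined by
#' whether they progressed, whether they had a post-treatment ctDNA
#' increase, and (for progressors with an increase) whether the first
#' increase preceded progression.
#'
#' @param maf Per-sample MAF table (as from [quantify_samples()]) covering
#'   one assay per patient.
#' @param clinical Clinical table with one row per patient
#'   (`patient_id`, `progression_day`, ...). Duplicate patient ids are an
#'   error.
#'
#' @return A tibble with columns `progressed`, `any_increase`, `timing`
#'   (`"before"`, `"at_or_after"` or `NA`) and `n`; `sum(n)` equals the
#'   number of patients.
#' @export
sankey_counts <- function(maf, clinical) {
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient ids in clinical table", call. = FALSE)
  }
  cells <- tibble::tibble(
    progressed = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    any_increase = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    timing = c("before", "at_or_after", NA, NA, NA),
    n = 0L
  )
  for (pid in clinical$patient_id) {
    traj <- maf[!is.na(maf$patient_id) & maf$patient_id == pid, , drop = FALSE]
    if (nrow(traj) == 0L) next
    course <- clinical[clinical$patient_id == pid, , drop = FALSE]
    rel <- relate_to_progression(traj, course)
    i <- switch(rel$category,
      INCREASE_BEFORE_PROGRESSION = 1L,
      INCREASE_AT_OR_AFTER_PROGRESSION = 2L,
      NO_INCREASE = 3L,
      NO_PROGRESSION = if (rel$any_increase) 4L else 5L)
    cells$n[i] <- cells$n[i] + 1L
  }
  cells
}
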