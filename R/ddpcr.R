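#' Poisson mean copies per droplet from partition counts
#'
#' Digital PCR distributes template molecules over partitions approximately
#' at random, so the number of molecules per droplet is Poisson. The
#' fraction of negative droplets estimates `exp(-lambda)`, giving the
#' classical estimator `lambda = -ln((n_total - n_pos) / n_total)`.
#'
#' @param n_pos Number of positive droplets (single channel).
#' @param n_total Number of accepted droplets; must be positive.
#'
#' @return Estimated mean copies per droplet (dimensionless, >= 0).
#'
#' @details Saturated wells (`n_pos == n_total`) carry no upper information
#' about the concentration and are rejected with an error rather than
#' clipped; such samples need dilution upstream.
#'
#' @examples
#' lambda_from_counts(2000, 20000)  # -log(0.9)
#' @export
lambda_from_counts <- function(n_pos, n_total) {
  check_counts(n_pos, n_total)
  -log((n_total - n_pos) / n_total)
}

check_counts <- function(n_pos, n_total) {
  stopifnot(length(n_pos) == 1L, length(n_total) == 1L,
            is.finite(n_pos), is.finite(n_total))
  if (n_total <= 0) {
    stop("empty well: n_total must be > 0", call. = FALSE)
  }
  if (n_pos < 0 || n_pos > n_total) {
    stop("n_pos must satisfy 0 <= n_pos <= n_total", call. = FALSE)
  }
  if (n_pos == n_total) {
    stop("saturated well: all droplets positive, concentration not estimable",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Wilson score interval for a binomial proportion; returns c(low, high).
# Vector-safe: with vector k/n returns a 2-row matrix.
wilson_interval <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  # boundary proportions have exact bounds; avoid float residue
  hi[p == 1] <- 1
  lo[p == 0] <- 0
  if (length(p) == 1L) c(lo, hi) else rbind(lo, hi)
}

# Vectorized concentration estimate; assumes 0 <= k < n already checked.
conc_vec <- function(k, n, vol_nl, level) {
  lam <- -log((n - k) / n)
  ci <- wilson_interval(n - k, n, level)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 2)
  lam_hi <- ifelse(ci[1, ] <= 0, Inf, -log(ci[1, ]))
  lam_lo <- pmax(0, -log(ci[2, ]))
  v <- vol_nl * 1e-3
  list(conc = lam / v, lo = lam_lo / v, hi = lam_hi / v)
}

#' Absolute concentration with a single-well confidence interval
#'
#' Converts partition counts to copies per microlitre of reaction and
#' attaches a confidence interval reflecting single-sample assay
#' uncertainty: a Wilson score interval on the negative-droplet fraction is
#' pushed through the monotone map `p -> -ln(p) / V`. The score interval
#' never collapses to zero width at boundary counts, so even a well with
#' zero positives gets a non-degenerate upper bound.
#'
#' @param n_pos,n_total Positive and total accepted droplet counts.
#' @param droplet_volume_nl Volume per droplet in nanolitres
#'   (default 0.85, the QX200 convention).
#' @param level Confidence level (default 0.95).
#'
#' @return A list of class `"concentration_estimate"` with elements
#'   `lambda` (copies per droplet), `conc_per_ul`, `ci_low`, `ci_high`
#'   (copies per microlitre), `n_pos`, `n_total`, `droplet_volume_nl`,
#'   `level`.
#'
#' @examples
#' concentration_with_ci(2000, 20000, 0.85)
#' @export
concentration_with_ci <- function(n_pos, n_total, droplet_volume_nl = 0.85,
                                  level = 0.95) {
  stopifnot(droplet_volume_nl > 0, level > 0, level < 1)
  lam <- lambda_from_counts(n_pos, n_total)
  v_ul <- droplet_volume_nl * 1e-3
  ci_p <- wilson_interval(n_total - n_pos, n_total, level)
  # lower bound on the negative fraction maps to the upper concentration bound
  lam_hi <- if (ci_p[1] <= 0) Inf else -log(ci_p[1])
  lam_lo <- max(0, -log(ci_p[2]))
  structure(list(
    lambda = lam,
    conc_per_ul = lam / v_ul,
    ci_low = lam_lo / v_ul,
    ci_high = lam_hi / v_ul,
    n_pos = as.integer(n_pos),
    n_total = as.integer(n_total),
    droplet_volume_nl = droplet_volume_nl,
    level = level
  ), class = "concentration_estimate")
}

#' Merge replicate wells of one sample and assay
#'
#' Replicate ddPCR wells of the same reaction are statistically equivalent
#' to a single larger well, so counts are summed componentwise and the
#' result is treated as one meta-well. Estimating from pooled counts is not
#' the same as averaging per-well estimates; the pooled estimator is the
#' maximum-likelihood one.
#'
#' @param wells A data frame of droplet wells (columns `well_id`,
#'   `sample_id`, `assay`, `n_total`, `n_mut_pos`, `n_wt_pos`, `is_ntc`,
#'   `droplet_volume_nl`), all for the same sample and assay, none a
#'   no-template control.
#'
#' @return A one-row tibble: the merged meta-well.
#' @export
merge_wells <- function(wells) {
  stopifnot(is.data.frame(wells), nrow(wells) >= 1L)
  if (any(wells$is_ntc)) {
    stop("cannot merge no-template-control wells into a sample", call. = FALSE)
  }
  if (length(unique(wells$sample_id)) != 1L ||
      length(unique(wells$assay)) != 1L) {
    stop("wells to merge must share sample_id and assay", call. = FALSE)
  }
  if (length(unique(wells$droplet_volume_nl)) != 1L) {
    stop("wells to merge must share droplet_volume_nl", call. = FALSE)
  }
  tibble::tibble(
    well_id = paste(wells$well_id, collapse = "+"),
    sample_id = wells$sample_id[1],
    assay = wells$assay[1],
    n_total = sum(wells$n_total),
    n_mut_pos = sum(wells$n_mut_pos),
    n_wt_pos = sum(wells$n_wt_pos),
    is_ntc = FALSE,
    droplet_volume_nl = wells$droplet_volume_nl[1]
  )
}

#' Limit of blank from no-template-control wells
#'
#' The detection floor is one droplet more than the largest mutant-positive
#' count seen in any no-template control, with a configurable minimum
#' (`k_min`, default 3 droplets — a common ddPCR practice). A sample is
#' called detected only when its merged mutant-positive droplet count
#' reaches this threshold.
#'
#' @param ntc_wells Data frame of wells with `is_ntc = TRUE` (may have
#'   zero rows).
#' @param k_min Minimum threshold in droplets (default 3).
#'
#' @return Integer threshold (minimum mutant droplets for detection). When
#'   no NTC wells are supplied, returns `k_min` with a warning.
#' @export
estimate_lob <- function(ntc_wells, k_min = 3L) {
  stopifnot(is.data.frame(ntc_wells), k_min >= 1)
  if (nrow(ntc_wells) == 0L) {
    warning("no NTC wells supplied; limit of blank falls back to k_min = ",
            k_min, call. = FALSE)
    return(as.integer(k_min))
  }
  if (!all(ntc_wells$is_ntc)) {
    stop("estimate_lob expects only NTC wells", call. = FALSE)
  }
  as.integer(max(k_min, 1L + max(ntc_wells$n_mut_pos)))
}

#' Mutant allele frequency with a confidence interval and detection call
#'
#' MAF (%) is the mutant concentration as a percentage of mutant plus
#' wild type. Its confidence interval comes from the delta method on the
#' log concentration ratio, using each concentration's CI half-width as a
#' standard-error surrogate, mapped back through `x -> 100 x / (1 + x)`.
#' A sample is `detected` when its mutant-positive droplets reach the limit
#' of blank; undetected samples are reported as MAF 0 with a one-sided
#' upper bound computed from a mutant count of `lob - 1` (the largest count
#' still compatible with non-detection), so that undetected samples remain
#' comparable on plots.
#'
#' @param mut,wt `concentration_estimate` objects for the mutant and
#'   wild-type channel of the same sample (see [concentration_with_ci()]).
#' @param lob Limit of blank in droplets (see [estimate_lob()]).
#' @param mut_droplets Merged mutant-positive droplet count used for the
#'   detection call (defaults to `mut$n_pos`).
#'
#' @return A one-row tibble with `maf_pct`, `maf_ci_low`, `maf_ci_high`,
#'   `mut_conc`, `wt_conc` (copies/µl), `detected`, `mut_droplets`.
#' @export
maf_with_ci <- function(mut, wt, lob, mut_droplets = mut$n_pos) {
  stopifnot(inherits(mut, "concentration_estimate"),
            inherits(wt, "concentration_estimate"),
            lob >= 1)
  if (mut$conc_per_ul + wt$conc_per_ul <= 0) {
    stop("no template detected in either channel: sample not evaluable",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - mut$level) / 2)
  detected <- mut_droplets >= lob

  to_maf <- function(r) 100 * r / (1 + r)

  if (!detected) {
    # one-sided bound: the largest mutant signal compatible with non-detection
    k_bound <- max(0L, as.integer(lob) - 1L)
    up <- concentration_with_ci(k_bound, mut$n_total, mut$droplet_volume_nl,
                                mut$level)
    hi <- if (wt$conc_per_ul > 0) to_maf(up$ci_high / wt$conc_per_ul) else 100
    maf <- 0
    lo <- 0
  } else if (wt$conc_per_ul == 0) {
    # no wild-type template: MAF pinned at 100 with a lower bound from the
    # wild-type upper CI
    maf <- 100
    hi <- 100
    lo <- if (wt$ci_high > 0) to_maf(mut$ci_low / wt$ci_high) else 100
  } else {
    r <- mut$conc_per_ul / wt$conc_per_ul
    se_log <- function(est) {
      ((est$ci_high - est$ci_low) / (2 * z)) / est$conc_per_ul
    }
    s <- sqrt(se_log(mut)^2 + se_log(wt)^2)
    maf <- to_maf(r)
    lo <- to_maf(r * exp(-z * s))
    hi <- to_maf(r * exp(z * s))
  }

  tibble::tibble(
    maf_pct = maf,
    maf_ci_low = lo,
    maf_ci_high = min(100, hi),
    mut_conc = mut$conc_per_ul,
    wt_conc = wt$conc_per_ul,
    detected = detected,
    mut_droplets = as.integer(mut_droplets)
  )
}

#' Quantify every sample in a droplet-count table
#'
#' Groups non-NTC wells by sample and assay, merges replicates, estimates
#' mutant and wild-type concentrations, derives the limit of blank from the
#' pooled NTC wells, and returns one MAF row per sample. Samples whose
#' merged mutant or wild-type channel is saturated are excluded and listed
#' in the `"warnings"` attribute instead of aborting the run.
#'
#' @param droplets Data frame in the droplet CSV dialect (see
#'   [read_droplet_csv()]).
#' @param manifest Optional sample manifest with columns `sample_id`,
#'   `patient_id`, `collection_day` to annotate the result.
#' @param k_min Minimum limit of blank in droplets (default 3).
#' @param level Confidence level for all intervals (default 0.95).
#'
#' @return A tibble with one row per (sample, assay):
#'   `sample_id`, `patient_id`, `assay`, `collection_day`, `maf_pct`,
#'   `maf_ci_low`, `maf_ci_high`, `mut_conc`, `wt_conc`, `detected`,
#'   `mut_droplets`. Attributes: `lob` (droplets), `k_min`, `level`,
#'   `warnings` (character vector of excluded-sample messages).
#' @export
quantify_samples <- function(droplets, manifest = NULL, k_min = 3L,
                             level = 0.95) {
  stopifnot(is.data.frame(droplets))
  ntc <- droplets[droplets$is_ntc, , drop = FALSE]
  smp <- droplets[!droplets$is_ntc, , drop = FALSE]
  if (nrow(smp) == 0L) {
    stop("droplet table contains no sample wells", call. = FALSE)
  }
  warnings <- character(0)
  lob <- withCallingHandlers(
    estimate_lob(ntc, k_min = k_min),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )

  # merge replicate wells by (sample, assay), then quantify all samples in
  # one vectorized pass (semantically identical to concentration_with_ci +
  # maf_with_ci per sample; a test asserts the two routes agree)
  key <- paste(smp$sample_id, smp$assay, sep = "\r")
  vol_spread <- tapply(smp$droplet_volume_nl, key,
                       function(v) diff(range(v)))
  if (any(vol_spread > 0)) {
    stop("wells to merge must share droplet_volume_nl", call. = FALSE)
  }
  agg <- rowsum(cbind(n_total = smp$n_total, n_mut = smp$n_mut_pos,
                      n_wt = smp$n_wt_pos), key, reorder = FALSE)
  first <- !duplicated(key)
  sample_id <- smp$sample_id[first]
  assay <- smp$assay[first]
  vol <- smp$droplet_volume_nl[first]
  n_tot <- unname(agg[, "n_total"])
  k_mut <- unname(agg[, "n_mut"])
  k_wt <- unname(agg[, "n_wt"])

  drop <- k_mut >= n_tot | k_wt >= n_tot
  if (any(drop)) {
    warnings <- c(warnings, paste0(
      "sample ", sample_id[drop],
      " excluded: saturated well: all droplets positive, concentration not",
      " estimable"))
    sample_id <- sample_id[!drop]; assay <- assay[!drop]; vol <- vol[!drop]
    n_tot <- n_tot[!drop]; k_mut <- k_mut[!drop]; k_wt <- k_wt[!drop]
  }
  if (length(sample_id) == 0L) {
    stop("no sample could be quantified", call. = FALSE)
  }
  mut <- conc_vec(k_mut, n_tot, vol, level)
  wt <- conc_vec(k_wt, n_tot, vol, level)

  empty <- mut$conc + wt$conc <= 0
  if (any(empty)) {
    warnings <- c(warnings, paste0(
      "sample ", sample_id[empty],
      " excluded: no template detected in either channel: sample not",
      " evaluable"))
    keep <- !empty
    sample_id <- sample_id[keep]; assay <- assay[keep]; vol <- vol[keep]
    n_tot <- n_tot[keep]; k_mut <- k_mut[keep]; k_wt <- k_wt[keep]
    mut <- lapply(mut, `[`, keep); wt <- lapply(wt, `[`, keep)
  }
  if (length(sample_id) == 0L) {
    stop("no sample could be quantified", call. = FALSE)
  }

  z <- stats::qnorm(1 - (1 - level) / 2)
  to_maf <- function(r) 100 * r / (1 + r)
  detected <- k_mut >= lob
  m <- length(sample_id)
  maf <- lo <- numeric(m)
  hi <- rep(100, m)

  und <- !detected
  if (any(und)) {
    up <- conc_vec(rep(max(0L, lob - 1L), sum(und)), n_tot[und], vol[und],
                   level)
    hi[und] <- ifelse(wt$conc[und] > 0, to_maf(up$hi / wt$conc[und]), 100)
  }
  d0 <- detected & wt$conc == 0
  if (any(d0)) {
    maf[d0] <- 100
    lo[d0] <- ifelse(wt$hi[d0] > 0, to_maf(mut$lo[d0] / wt$hi[d0]), 100)
  }
  dd <- detected & wt$conc > 0
  if (any(dd)) {
    r <- mut$conc[dd] / wt$conc[dd]
    s <- sqrt((((mut$hi[dd] - mut$lo[dd]) / (2 * z)) / mut$conc[dd])^2 +
              (((wt$hi[dd] - wt$lo[dd]) / (2 * z)) / wt$conc[dd])^2)
    maf[dd] <- to_maf(r)
    lo[dd] <- to_maf(r * exp(-z * s))
    hi[dd] <- to_maf(r * exp(z * s))
  }

  out <- tibble::tibble(
    sample_id = sample_id, assay = assay,
    maf_pct = maf, maf_ci_low = lo, maf_ci_high = pmin(100, hi),
    mut_conc = mut$conc, wt_conc = wt$conc,
    detected = detected, mut_droplets = as.integer(k_mut))

  if (!is.null(manifest)) {
    idx <- match(out$sample_id, manifest$sample_id)
    out$patient_id <- manifest$patient_id[idx]
    out$collection_day <- manifest$collection_day[idx]
  } else {
    out$patient_id <- NA_character_
    out$collection_day <- NA_real_
  }
  out <- out[, c("sample_id", "patient_id", "assay", "collection_day",
                 "maf_pct", "maf_ci_low", "maf_ci_high", "mut_conc",
                 "wt_conc", "detected", "mut_droplets")]
  out <- out[order(out$patient_id, out$collection_day, out$sample_id), ]
  attr(out, "lob") <- lob
  attr(out, "k_min") <- as.integer(k_min)
  attr(out, "level") <- level
  attr(out, "warnings") <- warnings
  out
}
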