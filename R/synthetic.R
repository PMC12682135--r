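#' Parameters for the synthetic ctDNA monitoring cohort
#'
#' Returns the full parameter list for [simulate_cohort()] with defaults
#' emulating a small metastatic uveal melanoma cohort monitored by
#' GNAQ/GNA11 hotspot ddPCR during liver-directed therapy plus checkpoint
#' inhibition: tumor-burden-linked ctDNA shedding with a low-shedder
#' subgroup, per-response-class burden kinetics (complete responders clear
#' ctDNA, progressors regrow it), Poisson droplet partitioning with rare
#' false-positive droplets, a fixed blood-draw and imaging schedule, and a
#' progression hazard tied to true ctDNA status in the 2-4-month landmark
#' window.
#'
#' @param n_patients Cohort size (default 18).
#' @param seed Integer seed fixing the whole cohort bit-for-bit.
#' @param ... Overrides for any default listed below.
#'
#' @return A named list of class `"cohort_params"`. Key entries:
#' \describe{
#'   \item{assay_mix}{Probabilities over the three hotspot assays
#'     (default 9:5:4 for GNA11 Q209L / GNAQ Q209P / GNAQ Q209L).}
#'   \item{baseline_burden}{`c(meanlog, sdlog)` of the log-normal RECIST
#'     sum of target lesions (mm).}
#'   \item{shedding_coef}{Mutant genome-equivalents per ml plasma per mm of
#'     RECIST sum for a typical shedder.}
#'   \item{p_low_shedder, low_shedder_factor}{Fraction of patients shedding
#'     essentially no ctDNA, and their shedding multiplier.}
#'   \item{background_cfdna}{`c(meanlog, sdlog)` of wild-type
#'     genome-equivalents per ml plasma.}
#'   \item{response_class_probs}{Probabilities over CR/PR/SD/PD.}
#'   \item{kinetics}{Per-day log-burden rates per response class plus the
#'     complete-response clearance-day range and partial-response floor.}
#'   \item{progression_hazard}{`baseline_rate` (per day, for
#'     landmark-negatives; default ln 2 / 338 days, i.e. an 11.1-month
#'     median) and `landmark_hr` (true hazard ratio for landmark-positive
#'     status; default 3).}
#'   \item{regrowth}{Probability and timing of ctDNA regrowth around
#'     progression, restart level and growth rate.}
#'   \item{sampling_schedule, imaging_schedule}{Blood-draw and imaging
#'     days relative to treatment start (baseline draws at day -7/-14).}
#'   \item{droplet}{`mean_total_droplets`, `droplet_volume_nl`,
#'     `false_positive_rate` per droplet (mutant channel).}
#'   \item{plasma_ml, extraction_to_reaction_fraction, max_input_ng}{Plasma
#'     volume per draw (2 ml), fraction of extracted cfDNA loaded per
#'     reaction, and the input-mass cap per reaction (36 ng).}
#'   \item{lob_copies}{Copies per reaction treated as truly detectable when
#'     assigning the design-level landmark flag (default 3).}
#' }
#' @export
cohort_params <- function(n_patients = 18L, seed = 1L, ...) {
  p <- list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    assay_mix = c(GNA11_Q209L = 9, GNAQ_Q209P = 5, GNAQ_Q209L = 4) / 18,
    baseline_burden = c(meanlog = log(60), sdlog = 0.45),
    shedding_coef = 2.5,
    p_low_shedder = 0.4,
    low_shedder_factor = 0.002,
    background_cfdna = c(meanlog = log(2000), sdlog = 0.5),
    response_class_probs = c(CR = 0.2, PR = 0.2, SD = 0.4, PD = 0.2),
    kinetics = list(
      cr_decay = 0.06, cr_clearance_range = c(30, 60),
      pr_decay = 0.04, pr_floor = 0.15, pr_late_decay = 0.002,
      sd_decay = 0.002,
      pd_growth = 0.008,
      radiology_damping = 0.5
    ),
    progression_hazard = list(
      baseline_rate = log(2) / (11.1 * 30.44),
      landmark_hr = 3
    ),
    regrowth = list(
      prob = 0.75, p_before = 0.625,
      lead_range = c(25, 65), delay_range = c(5, 40),
      restart_burden_mm = 4, growth_rate = 0.08
    ),
    death_lag_mean_days = 240,
    max_followup_day = 720,
    sampling_schedule = c(-7, 21, 42, 63, 90, 120, 150, 180, 240, 300, 360,
                          450, 540),
    imaging_schedule = c(-14, 90, 180, 270, 360, 450, 540),
    droplet = list(mean_total_droplets = 17000, droplet_volume_nl = 0.85,
                   false_positive_rate = 5e-6),
    n_ntc_wells = 6L,
    plasma_ml = 2,
    extraction_to_reaction_fraction = 0.5,
    max_input_ng = 36,
    lob_copies = 3,
    mut_ceiling_per_ml = 2e4,
    landmark_window = c(60, 122),
    ldh = list(base = 200, exponent = 0.9, sd = 0.25, uln = 250)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  stopifnot(abs(sum(p$assay_mix) - 1) < 1e-8,
            abs(sum(p$response_class_probs) - 1) < 1e-8)
  structure(p, class = "cohort_params")
}

#' Simulate one ddPCR well by Poisson partitioning
#'
#' Template molecules are distributed over droplets at random, so a droplet
#' is positive in a channel when it holds at least one molecule of that
#' species (probability `1 - exp(-copies / n_total)`) or, in the mutant
#' channel, when a false-positive event occurs.
#'
#' @param mut_copies,wt_copies Expected molecules of each species in the
#'   reaction (>= 0).
#' @param droplet_params List with `mean_total_droplets`,
#'   `droplet_volume_nl`, `false_positive_rate`.
#' @param well_id,sample_id,assay Identifiers for the emitted well row.
#' @param is_ntc Whether this is a no-template-control well.
#'
#' @return A one-row tibble in the droplet-well dialect.
#' @export
simulate_well <- function(mut_copies, wt_copies, droplet_params,
                          well_id = "W1", sample_id = "S1",
                          assay = "GNA11_Q209L", is_ntc = FALSE) {
  stopifnot(mut_copies >= 0, wt_copies >= 0)
  n_total <- stats::rpois(1L, droplet_params$mean_total_droplets)
  n_total <- max(n_total, 1L)
  p_mut <- 1 - exp(-mut_copies / n_total)
  p_mut <- p_mut + (1 - p_mut) * droplet_params$false_positive_rate
  p_wt <- 1 - exp(-wt_copies / n_total)
  tibble::tibble(
    well_id = well_id,
    sample_id = sample_id,
    assay = assay,
    n_total = n_total,
    n_mut_pos = stats::rbinom(1L, n_total, p_mut),
    n_wt_pos = stats::rbinom(1L, n_total, p_wt),
    is_ntc = is_ntc,
    droplet_volume_nl = droplet_params$droplet_volume_nl
  )
}

# Relative mutant-shedding kinetic f(t) for one patient (1 at t <= 0).
# Returns a function of time (days).
shedding_kinetic <- function(class, kin, clearance_day) {
  switch(class,
    CR = function(t) ifelse(t <= 0, 1,
                            ifelse(t >= clearance_day, 0,
                                   exp(-kin$cr_decay * t))),
    PR = function(t) ifelse(t <= 0, 1,
                            pmax(kin$pr_floor * exp(-kin$pr_late_decay * t),
                                 exp(-kin$pr_decay * t))),
    SD = function(t) ifelse(t <= 0, 1, exp(-kin$sd_decay * t)),
    PD = function(t) ifelse(t <= 0, 1, exp(kin$pd_growth * t))
  )
}

#' Simulate a complete synthetic monitoring cohort with ground truth
#'
#' Generates droplet-level ddPCR wells, a sample manifest, clinical courses
#' and an imaging table for `params$n_patients` patients, together with the
#' generator-side truth needed for parameter-recovery tests. Per patient:
#' an assay and a baseline tumor burden are drawn; mutant shedding is
#' linear in the RECIST sum (with a low-shedder subgroup); the response
#' class drives on-treatment kinetics (complete responders stop shedding at
#' a clearance day, partial responders decay to a floor, progressive
#' disease grows); a design-level landmark flag (true copies above
#' `lob_copies` in the 2-4-month window) multiplies the progression hazard
#' by the true hazard ratio; progressors may regrow ctDNA starting before
#' or after the progression day; every scheduled draw is converted to
#' expected copies per reaction and partitioned into droplets by
#' [simulate_well()]; no-template controls carry false positives only.
#'
#' The returned `truth` includes, besides the raw per-draw copy numbers:
#' `sankey`, the generator's own progression/increase accounting of the
#' cohort it emitted (computed by quantifying the emitted wells, so it is
#' consistent with the observable tables by construction and a file-based
#' rerun of the pipeline must reproduce it exactly); and an idealized
#' analysis (`maf_ideal`, `sankey_ideal`, `landmark`) from noise-free
#' expected droplet counts, defining what a perfect assay would report —
#' the reference for noise-tolerant concordance checks such as landmark
#' status recovery.
#'
#' @param params A [cohort_params()] list.
#' @param idealized_truth Whether to run the noise-free reference analysis
#'   (default `TRUE`); parameter-recovery simulations that only need the
#'   raw truth can turn it off.
#'
#' @return A list: `droplets`, `manifest`, `clinical`, `imaging` (tibbles
#'   in the pipeline CSV dialects) and `truth` (list with `patients`,
#'   `draws` and, when `idealized_truth` is on, `sankey`, `maf_ideal`,
#'   `sankey_ideal`, `landmark`).
#' @export
simulate_cohort <- function(params = cohort_params(),
                            idealized_truth = TRUE) {
  stopifnot(inherits(params, "cohort_params") || is.list(params))
  if (length(params$sampling_schedule) == 0L ||
      length(params$imaging_schedule) == 0L) {
    stop("sampling and imaging schedules must be non-empty", call. = FALSE)
  }
  set.seed(params$seed)
  kin <- params$kinetics
  dp <- params$droplet
  win <- params$landmark_window

  pat_rows <- list(); draw_rows <- list(); well_rows <- list()
  man_rows <- list(); clin_rows <- list(); img_rows <- list()

  for (i in seq_len(params$n_patients)) {
    pid <- sprintf("P%02d", i)
    assay <- sample(names(params$assay_mix), 1L, prob = params$assay_mix)
    burden0 <- stats::rlnorm(1L, params$baseline_burden[["meanlog"]],
                             params$baseline_burden[["sdlog"]])
    low_shedder <- stats::runif(1L) < params$p_low_shedder
    shed_mult <- if (low_shedder) params$low_shedder_factor else
      stats::rlnorm(1L, 0, 0.6)
    class <- sample(names(params$response_class_probs), 1L,
                    prob = params$response_class_probs)
    clearance_day <- stats::runif(1L, kin$cr_clearance_range[1],
                                  kin$cr_clearance_range[2])
    f <- shedding_kinetic(class, kin, clearance_day)

    cfdna_per_ml <- stats::rlnorm(1L, params$background_cfdna[["meanlog"]],
                                  params$background_cfdna[["sdlog"]])
    total_ng <- cfdna_per_ml * params$plasma_ml * 0.0033
    frac <- min(params$extraction_to_reaction_fraction,
                params$max_input_ng / total_ng)
    eff_ml <- params$plasma_ml * frac  # effective plasma volume per reaction
    wt_rxn <- cfdna_per_ml * eff_ml

    base_mut_ml <- function(t) {
      params$shedding_coef * shed_mult * burden0 * f(t)
    }

    # design-level landmark flag: true copies in the window, no filtering
    win_days <- params$sampling_schedule[
      params$sampling_schedule >= win[1] & params$sampling_schedule <= win[2]]
    lm_pos <- any(base_mut_ml(win_days) * eff_ml >= params$lob_copies)

    rate <- params$progression_hazard$baseline_rate *
      ifelse(lm_pos, params$progression_hazard$landmark_hr, 1)
    t_prog <- stats::rexp(1L, rate)
    progressed <- t_prog <= params$max_followup_day
    prog_day <- if (progressed) round(t_prog) else NA_real_

    regrow_onset <- NA_real_
    if (progressed && stats::runif(1L) < params$regrowth$prob) {
      regrow_onset <- if (stats::runif(1L) < params$regrowth$p_before) {
        prog_day - stats::runif(1L, params$regrowth$lead_range[1],
                                params$regrowth$lead_range[2])
      } else {
        prog_day + stats::runif(1L, params$regrowth$delay_range[1],
                                params$regrowth$delay_range[2])
      }
      # molecular relapse of a complete responder cannot precede the
      # clearance it relapses from
      if (class == "CR") {
        regrow_onset <- max(regrow_onset, clearance_day + 30)
      }
    }

    # regrowth restarts shedding at the level of a small regrown tumor, so
    # patients who shed no ctDNA stay negative at relapse too
    restart_ml <- params$shedding_coef * shed_mult *
      params$regrowth$restart_burden_mm

    mut_ml <- function(t) {
      base <- base_mut_ml(t)
      if (!is.na(regrow_onset)) {
        on <- t >= regrow_onset
        base[on] <- pmax(base[on], restart_ml) *
          exp(params$regrowth$growth_rate * (t[on] - regrow_onset))
      }
      # shedding saturates; also keeps simulated wells off full saturation
      pmin(base, params$mut_ceiling_per_ml)
    }

    death_day <- NA_real_
    last_fup <- params$max_followup_day
    if (progressed) {
      d <- prog_day + round(stats::rexp(1L, 1 / params$death_lag_mean_days))
      if (d <= params$max_followup_day) {
        death_day <- d
        last_fup <- d
      }
    }

    ldh <- params$ldh$base * (burden0 / 60)^params$ldh$exponent *
      exp(stats::rnorm(1L, 0, params$ldh$sd))
    largest <- burden0 * stats::runif(1L, 0.4, 0.8)
    m_stage <- if (largest <= 30) "M1a" else if (largest <= 80) "M1b" else
      "M1c"
    extrahepatic <- stats::runif(1L) < 0.4

    days <- params$sampling_schedule[params$sampling_schedule <= last_fup]
    mut_rxn <- mut_ml(days) * eff_ml
    nd <- length(days)
    sid <- sprintf("%s_S%02d", pid, seq_len(nd))
    # vectorized droplet partitioning (same model as simulate_well)
    n_total <- pmax(stats::rpois(nd, dp$mean_total_droplets), 1L)
    p_mut <- 1 - exp(-mut_rxn / n_total)
    p_mut <- p_mut + (1 - p_mut) * dp$false_positive_rate
    p_wt <- 1 - exp(-wt_rxn / n_total)
    well_rows[[i]] <- list(
      well_id = paste0(sid, "_W1"), sample_id = sid,
      assay = rep(assay, nd), n_total = n_total,
      n_mut_pos = stats::rbinom(nd, n_total, p_mut),
      n_wt_pos = stats::rbinom(nd, n_total, p_wt),
      is_ntc = rep(FALSE, nd),
      droplet_volume_nl = rep(dp$droplet_volume_nl, nd))
    man_rows[[i]] <- list(
      sample_id = sid, patient_id = rep(pid, nd), collection_day = days,
      plasma_ml = rep(params$plasma_ml, nd),
      cfdna_ng_loaded = rep(round(total_ng * frac, 2), nd))
    draw_rows[[i]] <- list(
      patient_id = rep(pid, nd), sample_id = sid, collection_day = days,
      mut_copies_rxn = mut_rxn, wt_copies_rxn = rep(wt_rxn, nd))

    img_days <- params$imaging_schedule[params$imaging_schedule <= last_fup]
    recist <- burden0 * f(pmax(img_days, 0))^kin$radiology_damping *
      exp(stats::rnorm(length(img_days), 0, 0.05))
    base_recist <- recist[which.min(img_days)]
    pct <- 100 * (recist - base_recist) / base_recist
    call <- ifelse(pct <= -95, "CR",
                   ifelse(pct <= -30, "PR", ifelse(pct >= 20, "PD", "SD")))
    call[img_days <= 0] <- "baseline"
    img_rows[[i]] <- list(
      patient_id = rep(pid, length(img_days)), day = img_days,
      recist_sum_mm = round(recist, 1), response_call = call)

    clin_rows[[i]] <- list(
      patient_id = pid, treatment_start_day = 0,
      ldh_value = round(ldh, 1), ldh_above_uln = ldh > params$ldh$uln,
      m_stage = m_stage, extrahepatic = extrahepatic,
      recist_sum_mm = round(base_recist, 1),
      progression_day = prog_day, death_day = death_day,
      last_followup_day = last_fup)

    pat_rows[[i]] <- list(
      patient_id = pid, assay = assay, response_class = class,
      low_shedder = low_shedder, shed_mult = shed_mult,
      burden0_mm = burden0, cfdna_per_ml = cfdna_per_ml,
      landmark_hazard_positive = lm_pos,
      regrowth_onset_day = regrow_onset,
      progression_day = prog_day, death_day = death_day)
  }

  # NTC wells: false positives only
  assays <- names(params$assay_mix)
  for (j in seq_len(params$n_ntc_wells)) {
    w <- simulate_well(0, 0, dp, well_id = sprintf("NTC_W%d", j),
                       sample_id = sprintf("NTC%d", j),
                       assay = assays[(j - 1L) %% length(assays) + 1L],
                       is_ntc = TRUE)
    well_rows[[length(well_rows) + 1L]] <- as.list(w)
  }

  droplets <- bind_row_lists(well_rows)
  manifest <- bind_row_lists(man_rows)
  clinical <- bind_row_lists(clin_rows)
  imaging <- bind_row_lists(img_rows)
  patients <- bind_row_lists(pat_rows)
  draws <- bind_row_lists(draw_rows)

  truth <- if (!idealized_truth) {
    list(patients = patients, draws = draws)
  } else c(list(patients = patients, draws = draws,
                # the generator's own accounting of the cohort it emitted:
                # quantify the emitted wells and cross-tabulate, so truth is
                # consistent with the observable tables by construction
                sankey = sankey_counts(
                  quantify_samples(droplets, manifest,
                                   k_min = params$lob_copies),
                  clinical)),
             idealized_analysis(draws, patients, manifest, clinical, params))

  list(droplets = droplets, manifest = manifest, clinical = clinical,
       imaging = imaging, truth = truth)
}

# Noise-free reference analysis: expected droplet counts, same pipeline.
idealized_analysis <- function(draws, patients, manifest, clinical, params) {
  dp <- params$droplet
  n_total <- round(dp$mean_total_droplets)
  assay <- patients$assay[match(draws$patient_id, patients$patient_id)]
  wells <- tibble::tibble(
    well_id = paste0(draws$sample_id, "_ideal"),
    sample_id = draws$sample_id,
    assay = assay,
    n_total = n_total,
    n_mut_pos = pmin(n_total - 1L,
                     round(n_total * (1 - exp(-draws$mut_copies_rxn /
                                                n_total)))),
    n_wt_pos = pmin(n_total - 1L,
                    round(n_total * (1 - exp(-draws$wt_copies_rxn /
                                               n_total)))),
    is_ntc = FALSE,
    droplet_volume_nl = dp$droplet_volume_nl
  )
  maf_ideal <- quantify_samples(wells, manifest, k_min = params$lob_copies)
  sankey_ideal <- sankey_counts(maf_ideal, clinical)
  landmark <- tibble::tibble(
    patient_id = clinical$patient_id,
    status = vapply(clinical$patient_id, function(pid) {
      traj <- maf_ideal[maf_ideal$patient_id == pid, , drop = FALSE]
      course <- clinical[clinical$patient_id == pid, , drop = FALSE]
      landmark_status(traj, course, params$landmark_window)$status
    }, character(1), USE.NAMES = FALSE))
  list(maf_ideal = maf_ideal, sankey_ideal = sankey_ideal,
       landmark = landmark)
}
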