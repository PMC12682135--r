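# Shared fixture builders. Status codes used throughout:
#   "U" undetected, "L" detected-low (CI [1, 2]%), "H" detected-high
#   (CI [5, 7]%) — fixed non-overlapping CI geometry.

maf_row <- function(day, status, patient_id = "P1", sample_id = NULL,
                    assay = "GNA11_Q209L") {
  geom <- switch(status,
    U = list(maf = 0, lo = 0, hi = 0.05, det = FALSE),
    L = list(maf = 1.5, lo = 1, hi = 2, det = TRUE),
    H = list(maf = 6, lo = 5, hi = 7, det = TRUE))
  tibble::tibble(
    sample_id = if (is.null(sample_id)) paste0(patient_id, "_d", day) else
      sample_id,
    patient_id = patient_id,
    assay = assay,
    collection_day = day,
    maf_pct = geom$maf, maf_ci_low = geom$lo, maf_ci_high = geom$hi,
    mut_conc = geom$maf, wt_conc = 100,
    detected = geom$det, mut_droplets = if (geom$det) 50L else 0L)
}

make_traj <- function(statuses, days = NULL, patient_id = "P1") {
  if (is.null(days)) days <- seq(-7, by = 30, length.out = length(statuses))
  do.call(rbind, Map(maf_row, days, statuses,
                     MoreArgs = list(patient_id = patient_id)))
}

make_course <- function(patient_id = "P1", progression_day = NA_real_,
                        death_day = NA_real_, last_followup_day = 720) {
  tibble::tibble(patient_id = patient_id, treatment_start_day = 0,
                 progression_day = progression_day, death_day = death_day,
                 last_followup_day = last_followup_day)
}

well_row <- function(n_mut_pos, n_total, n_wt_pos = 1000,
                     sample_id = "S1", assay = "GNA11_Q209L",
                     well_id = "W1", is_ntc = FALSE,
                     droplet_volume_nl = 0.85) {
  tibble::tibble(well_id = well_id, sample_id = sample_id, assay = assay,
                 n_total = n_total, n_mut_pos = n_mut_pos,
                 n_wt_pos = n_wt_pos, is_ntc = is_ntc,
                 droplet_volume_nl = droplet_volume_nl)
}
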