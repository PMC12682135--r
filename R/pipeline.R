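#' Read a droplet-count CSV
#'
#' Expects the exact header
#' `well_id,sample_id,assay,n_total,n_mut_pos,n_wt_pos,is_ntc,droplet_volume_nl`.
#' Rows violating the count invariants are reported by row number.
#'
#' @param path Path to the CSV file.
#' @return A tibble of droplet wells.
#' @export
read_droplet_csv <- function(path) {
  expected <- c("well_id", "sample_id", "assay", "n_total", "n_mut_pos",
                "n_wt_pos", "is_ntc", "droplet_volume_nl")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), expected)) {
    stop("droplet CSV schema error: expected columns ",
         paste(expected, collapse = ","), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop("droplet CSV schema error: file has no data rows", call. = FALSE)
  }
  df$is_ntc <- as.logical(df$is_ntc)
  bad <- which(df$n_total <= 0 | df$n_mut_pos < 0 | df$n_wt_pos < 0 |
               df$n_mut_pos > df$n_total | df$n_wt_pos > df$n_total |
               df$droplet_volume_nl <= 0 | is.na(df$is_ntc))
  if (length(bad)) {
    stop("droplet CSV schema error at data row ", bad[1],
         ": count/volume invariants violated", call. = FALSE)
  }
  tibble::as_tibble(df)
}

read_table_csv <- function(path, required) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), " schema error: missing columns ",
         paste(miss, collapse = ","), call. = FALSE)
  }
  tibble::as_tibble(df)
}

write_csv_file <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Build a pipeline run configuration
#'
#' Collects the paths and analysis settings shared by the pipeline stages.
#' Configurations can also be loaded from YAML with [load_config()]. The
#' configuration (minus the output directory) is hashed and the hash is
#' embedded in every metadata artifact, so outputs are traceable to their
#' settings and reruns with unchanged inputs are byte-identical.
#'
#' @param out_dir Output directory (created if needed by the run functions).
#' @param droplets_csv,manifest_csv,clinical_csv,imaging_csv Input paths.
#' @param window_days Landmark window, inclusive days (default `c(60, 122)`).
#' @param ci_level Confidence level (default 0.95).
#' @param k_min Minimum limit of blank in droplets (default 3).
#' @param droplet_volume_nl Droplet volume used by `simulate` (default 0.85).
#' @param months_divisor Days per month used for reporting (default 30.44).
#' @param n_patients,seed Cohort size and seed used by `simulate`.
#'
#' @return A named list of class `"run_config"`.
#' @export
make_config <- function(out_dir,
                        droplets_csv = file.path(out_dir, "droplets.csv"),
                        manifest_csv = file.path(out_dir, "manifest.csv"),
                        clinical_csv = file.path(out_dir, "clinical.csv"),
                        imaging_csv = file.path(out_dir, "imaging.csv"),
                        window_days = c(60, 122),
                        ci_level = 0.95,
                        k_min = 3L,
                        droplet_volume_nl = 0.85,
                        months_divisor = 30.44,
                        n_patients = 18L,
                        seed = 1L) {
  structure(list(
    out_dir = out_dir,
    droplets_csv = droplets_csv, manifest_csv = manifest_csv,
    clinical_csv = clinical_csv, imaging_csv = imaging_csv,
    window_days = window_days, ci_level = ci_level, k_min = as.integer(k_min),
    droplet_volume_nl = droplet_volume_nl, months_divisor = months_divisor,
    n_patients = as.integer(n_patients), seed = as.integer(seed)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [make_config()].
#' @return A `"run_config"` list.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$out_dir)) stop("config must set out_dir", call. = FALSE)
  do.call(make_config, y)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  stable <- config[setdiff(names(config), "out_dir")]
  yaml::write_yaml(stable[order(names(stable))], f)
  unname(tools::md5sum(f))
}

ensure_outdir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  invisible(config$out_dir)
}

#' Pipeline stage: simulate a synthetic cohort to disk
#'
#' Writes `droplets.csv`, `manifest.csv`, `clinical.csv`, `imaging.csv` and
#' `truth.json` into the configured input paths / output directory.
#'
#' @param config A [make_config()] list.
#' @param params Optional [cohort_params()]; defaults are built from the
#'   config's `n_patients`, `seed` and `droplet_volume_nl`.
#' @return Invisibly, the [simulate_cohort()] result.
#' @export
run_simulate <- function(config, params = NULL) {
  ensure_outdir(config)
  if (is.null(params)) {
    params <- cohort_params(n_patients = config$n_patients,
                            seed = config$seed)
    params$droplet$droplet_volume_nl <- config$droplet_volume_nl
    params$landmark_window <- config$window_days
  }
  sim <- simulate_cohort(params)
  write_csv_file(sim$droplets, config$droplets_csv)
  write_csv_file(sim$manifest, config$manifest_csv)
  write_csv_file(sim$clinical, config$clinical_csv)
  write_csv_file(sim$imaging, config$imaging_csv)
  write_json_file(list(
    config_hash = config_hash(config),
    patients = sim$truth$patients,
    sankey = sim$truth$sankey,
    landmark_ideal = sim$truth$landmark
  ), file.path(config$out_dir, "truth.json"))
  invisible(sim)
}

#' Pipeline stage: quantify MAF for every sample
#'
#' Reads the droplet and manifest CSVs, runs [quantify_samples()], and
#' writes `maf_table.csv` plus `quantify_meta.json` (limit of blank,
#' `k_min`, droplet volume, CI level, excluded-well warnings, config hash).
#'
#' @param config A [make_config()] list.
#' @return Invisibly, the MAF tibble.
#' @export
run_quantify <- function(config) {
  ensure_outdir(config)
  droplets <- read_droplet_csv(config$droplets_csv)
  manifest <- read_table_csv(config$manifest_csv,
                             c("sample_id", "patient_id", "collection_day"))
  maf <- quantify_samples(droplets, manifest, k_min = config$k_min,
                          level = config$ci_level)
  write_csv_file(maf, file.path(config$out_dir, "maf_table.csv"))
  write_json_file(list(
    config_hash = config_hash(config),
    lob_droplets = attr(maf, "lob"),
    k_min = attr(maf, "k_min"),
    ci_level = attr(maf, "level"),
    droplet_volume_nl = unique(droplets$droplet_volume_nl),
    n_samples = nrow(maf),
    warnings = as.list(attr(maf, "warnings"))
  ), file.path(config$out_dir, "quantify_meta.json"))
  invisible(maf)
}

require_artifact <- function(config, name) {
  path <- file.path(config$out_dir, name)
  if (!file.exists(path)) {
    stop("missing upstream artifact: ", name,
         " (run the earlier pipeline stages first)", call. = FALSE)
  }
  path
}

read_maf_table <- function(path) {
  maf <- read_table_csv(path, c("sample_id", "patient_id", "assay",
                                "collection_day", "maf_pct", "maf_ci_low",
                                "maf_ci_high", "detected"))
  maf$detected <- as.logical(maf$detected)
  maf
}

#' Pipeline stage: classify every patient's ctDNA trajectory
#'
#' Reads the MAF table and clinical CSV and writes `events.csv`
#' (per-transition events with confirmation status) and `relations.csv`
#' (per-patient progression relation and lead time).
#'
#' @param config A [make_config()] list.
#' @return Invisibly, a list with `events` and `relations` tibbles.
#' @export
run_classify <- function(config) {
  ensure_outdir(config)
  maf <- read_maf_table(require_artifact(config, "maf_table.csv"))
  clinical <- read_table_csv(config$clinical_csv,
                             c("patient_id", "progression_day",
                               "death_day", "last_followup_day"))
  ev_rows <- list(); rel_rows <- list()
  for (pid in clinical$patient_id) {
    traj <- maf[maf$patient_id == pid, , drop = FALSE]
    if (nrow(traj) == 0L) next
    course <- clinical[clinical$patient_id == pid, , drop = FALSE]
    cls <- classify_trajectory(traj)
    if (nrow(cls$events)) {
      ev_rows[[pid]] <- tibble::tibble(patient_id = pid, cls$events)
    }
    rel <- relate_to_progression(traj, course)
    rel_rows[[pid]] <- tibble::tibble(patient_id = pid, rel)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    tibble::tibble(patient_id = character(0), kind = character(0),
                   from_day = numeric(0), to_day = numeric(0),
                   confirmed = character(0))
  relations <- do.call(rbind, rel_rows)
  write_csv_file(events, file.path(config$out_dir, "events.csv"))
  write_csv_file(relations, file.path(config$out_dir, "relations.csv"))
  invisible(list(events = events, relations = relations))
}

#' Pipeline stage: landmark ctDNA status per patient
#'
#' Writes `landmark.csv` with each patient's status in the configured
#' window (pre-progression samples only).
#'
#' @param config A [make_config()] list.
#' @return Invisibly, the landmark tibble.
#' @export
run_landmark <- function(config) {
  ensure_outdir(config)
  maf <- read_maf_table(require_artifact(config, "maf_table.csv"))
  clinical <- read_table_csv(config$clinical_csv,
                             c("patient_id", "progression_day",
                               "death_day", "last_followup_day"))
  out <- do.call(rbind, lapply(clinical$patient_id, function(pid) {
    traj <- maf[maf$patient_id == pid, , drop = FALSE]
    if (nrow(traj) == 0L) {
      return(tibble::tibble(patient_id = pid, status = "NOT_EVALUABLE",
                            n_samples_in_window = 0L))
    }
    course <- clinical[clinical$patient_id == pid, , drop = FALSE]
    st <- landmark_status(traj, course, config$window_days)
    tibble::tibble(patient_id = pid, st)
  }))
  write_csv_file(out, file.path(config$out_dir, "landmark.csv"))
  invisible(out)
}

#' Pipeline stage: report bundle
#'
#' Assembles the figure-level data artifacts from the upstream stages:
#' `swimmer.json` (per-patient timeline of ctDNA status and clinical
#' events), `sankey.csv` (progression x increase x timing counts),
#' `series.csv` (per-patient MAF with CI and RECIST percent change from
#' baseline on a shared day axis) and `survival_summary.json` (per-group
#' medians in months, log-rank chi-square and p, for baseline and landmark
#' stratifications of OS and PFS, where both groups are populated).
#'
#' @param config A [make_config()] list.
#' @return Invisibly, a list with the bundle contents.
#' @export
run_report <- function(config) {
  ensure_outdir(config)
  maf <- read_maf_table(require_artifact(config, "maf_table.csv"))
  require_artifact(config, "events.csv")
  landmark <- read_table_csv(require_artifact(config, "landmark.csv"),
                             c("patient_id", "status"))
  clinical <- read_table_csv(config$clinical_csv,
                             c("patient_id", "progression_day", "death_day",
                               "last_followup_day"))
  imaging <- read_table_csv(config$imaging_csv,
                            c("patient_id", "day", "recist_sum_mm"))

  sankey <- sankey_counts(maf, clinical)
  write_csv_file(sankey, file.path(config$out_dir, "sankey.csv"))

  # per-patient series: MAF samples and RECIST % change from baseline
  series <- list()
  for (pid in clinical$patient_id) {
    m <- maf[maf$patient_id == pid, , drop = FALSE]
    if (nrow(m)) {
      series[[paste0(pid, "_maf")]] <- tibble::tibble(
        patient_id = pid, day = m$collection_day, series = "maf_pct",
        value = m$maf_pct, ci_low = m$maf_ci_low, ci_high = m$maf_ci_high)
    }
    im <- imaging[imaging$patient_id == pid, , drop = FALSE]
    if (nrow(im)) {
      base_idx <- which(im$day <= 0)
      base <- if (length(base_idx)) im$recist_sum_mm[base_idx[
        which.max(im$day[base_idx])]] else NA_real_
      series[[paste0(pid, "_recist")]] <- tibble::tibble(
        patient_id = pid, day = im$day, series = "recist_pct_change",
        value = 100 * (im$recist_sum_mm - base) / base,
        ci_low = NA_real_, ci_high = NA_real_)
    }
  }
  series <- do.call(rbind, series)
  write_csv_file(series, file.path(config$out_dir, "series.csv"))

  swimmer <- lapply(clinical$patient_id, function(pid) {
    m <- maf[maf$patient_id == pid, , drop = FALSE]
    cl <- clinical[clinical$patient_id == pid, , drop = FALSE]
    list(patient_id = pid,
         followup_days = cl$last_followup_day,
         progression_day = cl$progression_day,
         death_day = cl$death_day,
         landmark_status = landmark$status[landmark$patient_id == pid],
         samples = lapply(seq_len(nrow(m)), function(i) {
           list(day = m$collection_day[i], detected = m$detected[i],
                maf_pct = m$maf_pct[i])
         }))
  })
  write_json_file(list(config_hash = config_hash(config),
                       patients = swimmer),
                  file.path(config$out_dir, "swimmer.json"))

  surv <- list()
  for (grouping in c("baseline", "landmark")) {
    for (endpoint in c("OS", "PFS")) {
      res <- tryCatch(
        stratified_survival(maf, clinical, grouping, endpoint,
                            config$window_days),
        error = function(e) NULL)
      if (is.null(res)) next
      surv[[paste0(grouping, "_", tolower(endpoint))]] <- list(
        n = as.list(res$n),
        median_months = as.list(res$medians_days / config$months_divisor),
        logrank_chisq = res$logrank$chisq,
        logrank_p = res$logrank$p_value)
    }
  }
  write_json_file(c(list(config_hash = config_hash(config)), surv),
                  file.path(config$out_dir, "survival_summary.json"))

  invisible(list(sankey = sankey, series = series, swimmer = swimmer,
                 survival = surv))
}
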