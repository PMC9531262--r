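# Cohort serialization: one clinical CSV, one long-format measurement CSV
# and a JSON sidecar with the seed and generator configuration. Floats are
# written with 17 significant digits so save -> load is the identity.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

#' Save a cohort to a directory
#'
#' Writes `clinical.csv` (one row per measured patient-day),
#' `measurements.csv` (long format: one row per patient-day, single
#' measurement, time index and frequency channel) and `cohort.json`
#' (seed and generator configuration).
#'
#' @param cohort An [generate_cohort()] cohort.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "acg_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  clin <- cohort_clinical(cohort)
  clin_out <- data.table::as.data.table(clin)
  for (col in c("lactate", "pct", "creatinine", "bilirubin", "severity")) {
    data.table::set(clin_out, j = col, value = fmt_num(clin_out[[col]]))
  }
  data.table::fwrite(clin_out, file.path(path, "clinical.csv"), quote = FALSE)

  freqs <- cohort$frequency_grid$frequencies
  nf <- length(freqs)
  chunks <- lapply(cohort$records, function(r) {
    lapply(r$sessions, function(s) {
      tt <- nrow(s$tof)
      data.table::data.table(
        patient_id = r$patient_id, day = r$day,
        measurement_index = s$measurement_index,
        t_index = rep(seq_len(tt), nf),
        frequency_mhz = rep(freqs, each = tt),
        tof_us = fmt_num(as.numeric(s$tof)),
        att_db = fmt_num(as.numeric(s$att)),
        signal_strength = fmt_num(rep(s$signal_strength, tt * nf)))
    })
  })
  meas <- data.table::rbindlist(unlist(chunks, recursive = FALSE))
  data.table::fwrite(meas, file.path(path, "measurements.csv"), quote = FALSE)

  cfg <- cohort$config
  sidecar <- list(
    seed = cohort$seed,
    frequencies_mhz = freqs,
    config = cfg[setdiff(names(cfg), c("grid", "medium"))],
    medium = unclass(cfg$medium))
  jsonlite::write_json(sidecar, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a cohort from a directory
#'
#' Inverse of [save_cohort()]: validates the schema (every measurement
#' must hold a complete time x frequency grid) and reconstructs the
#' cohort object. Save -> load is the identity on all numeric fields.
#'
#' @param path Directory written by [save_cohort()].
#' @return An `acg_cohort`.
#' @export
load_cohort <- function(path) {
  clin_f <- file.path(path, "clinical.csv")
  meas_f <- file.path(path, "measurements.csv")
  json_f <- file.path(path, "cohort.json")
  for (f in c(clin_f, meas_f, json_f)) if (!file.exists(f)) stopf("missing file: %s", f)

  sidecar <- jsonlite::read_json(json_f, simplifyVector = TRUE)
  freqs <- as.numeric(sidecar$frequencies_mhz)
  grid <- frequency_grid(freqs)
  cfg_fields <- sidecar$config
  medium <- do.call(medium_params, as.list(sidecar$medium))
  cfg_args <- cfg_fields[setdiff(names(cfg_fields),
                                 setdiff(names(cfg_fields), names(formals(cohort_config))))]
  cfg_args$grid <- grid
  cfg_args$medium <- medium
  config <- do.call(cohort_config, cfg_args)

  clin <- as.data.frame(data.table::fread(clin_f, colClasses = list(
    character = "patient_id", logical = "cam_icu")))
  need <- c("patient_id", "group", "day", "sofa", "icdsc", "cam_icu",
            "lactate", "pct", "creatinine", "bilirubin", "severity")
  if (!all(need %in% names(clin))) {
    stopf("clinical.csv missing columns: %s",
          paste(setdiff(need, names(clin)), collapse = ", "))
  }

  meas <- as.data.frame(data.table::fread(meas_f,
                                          colClasses = list(character = "patient_id")))
  nf <- length(freqs)
  meas <- meas[order(meas$patient_id, meas$day, meas$measurement_index,
                     meas$frequency_mhz, meas$t_index), , drop = FALSE]

  records <- list()
  for (i in seq_len(nrow(clin))) {
    row <- clin[i, , drop = FALSE]
    mm <- meas[meas$patient_id == row$patient_id & meas$day == row$day, , drop = FALSE]
    sessions <- lapply(sort(unique(mm$measurement_index)), function(mi) {
      sm <- mm[mm$measurement_index == mi, , drop = FALSE]
      tt <- max(sm$t_index)
      if (nrow(sm) != tt * nf ||
          !all(table(sm$frequency_mhz) == tt) ||
          !all(table(sm$t_index) == nf)) {
        bad_t <- names(which(table(sm$t_index) != nf))[1]
        stopf("incomplete frequency grid for patient %s day %d t_index %s",
              row$patient_id, row$day, bad_t %||% "?")
      }
      tof <- matrix(sm$tof_us, tt, nf)
      att <- matrix(sm$att_db, tt, nf)
      colnames(tof) <- colnames(att) <- sprintf("f%02d", seq_len(nf))
      structure(list(tof = tof, att = att, t_samples = tt,
                     signal_strength = sm$signal_strength[1],
                     measurement_index = as.integer(mi)),
                class = "acg_measurement")
    })
    records[[i]] <- list(
      patient_id = row$patient_id, group = row$group, day = as.integer(row$day),
      severity = row$severity, sofa = as.integer(row$sofa),
      icdsc = as.integer(row$icdsc), cam_icu = row$cam_icu,
      lactate = row$lactate, pct = row$pct, creatinine = row$creatinine,
      bilirubin = row$bilirubin, sessions = sessions)
  }
  structure(list(records = records, frequency_grid = grid, config = config,
                 seed = as.integer(sidecar$seed)),
            class = "acg_cohort")
}
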