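#' Frequency grid of an ACG acquisition
#'
#' Acoustocerebrography interrogates the brain with a set of ultrasound
#' carrier frequencies; the device used here as the reference design spans
#' 0.5--2.5 MHz with 10 components. The grid fixes the number `F` of
#' frequency channels of every measurement.
#'
#' @param frequencies Strictly increasing numeric vector of center
#'   frequencies in MHz (default: 10 values evenly spaced on 0.5--2.5).
#' @return An object of class `acg_frequency_grid`.
#' @export
#' @examples
#' frequency_grid()
frequency_grid <- function(frequencies = seq(0.5, 2.5, length.out = 10)) {
  if (length(frequencies) < 2) stopf("need at least 2 frequencies")
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stopf("frequencies must be finite and positive")
  }
  if (any(diff(frequencies) <= 0)) stopf("frequencies must be strictly increasing")
  structure(list(frequencies = as.numeric(frequencies)),
            class = "acg_frequency_grid")
}

#' @export
print.acg_frequency_grid <- function(x, ...) {
  cat(sprintf("ACG frequency grid: %d channels, %.2f-%.2f MHz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Acoustic medium parameters for the toy propagation model
#'
#' A deliberately simple dispersive medium: phase velocity rises linearly
#' with frequency (the Kramers--Kronig motivation for multifrequency
#' acquisition) and attenuation is linear in frequency times path length.
#' Units follow the ACG convention: millimetres, microseconds, decibels.
#'
#' @param path_length Transcranial path length in mm.
#' @param speed_base Sound speed at zero frequency, mm/us.
#' @param dispersion_slope Velocity increase per MHz, (mm/us)/MHz.
#' @param attenuation_slope Attenuation per MHz per mm, dB/(MHz*mm).
#' @param noise_sd_tof,noise_sd_att Gaussian measurement noise SDs (us, dB).
#' @return An object of class `acg_medium`.
#' @export
medium_params <- function(path_length = 140,
                          speed_base = 1.50,
                          dispersion_slope = 0.012,
                          attenuation_slope = 0.022,
                          noise_sd_tof = 0,
                          noise_sd_att = 0) {
  if (path_length <= 0) stopf("path_length must be positive")
  if (speed_base <= 0) stopf("speed_base must be positive")
  if (noise_sd_tof < 0 || noise_sd_att < 0) stopf("noise SDs must be >= 0")
  structure(list(path_length = path_length, speed_base = speed_base,
                 dispersion_slope = dispersion_slope,
                 attenuation_slope = attenuation_slope,
                 noise_sd_tof = noise_sd_tof, noise_sd_att = noise_sd_att),
            class = "acg_medium")
}

#' Simulate one received multifrequency pulse
#'
#' Closed-form per-frequency time of flight and attenuation for a single
#' transmitted pulse through the medium:
#' `tof(f) = L / (c0 + s*f) + N(0, sd_tof)` and
#' `att(f) = a * f * L + N(0, sd_att)`.
#' Deterministic given the state of R's random number generator.
#'
#' @param grid An [frequency_grid()].
#' @param medium A [medium_params()].
#' @return List with numeric vectors `tof` (us) and `att` (dB), one entry
#'   per grid frequency.
#' @export
#' @examples
#' set.seed(1)
#' simulate_received_pulse(frequency_grid(), medium_params())
simulate_received_pulse <- function(grid, medium) {
  stopifnot(inherits(grid, "acg_frequency_grid"), inherits(medium, "acg_medium"))
  f <- grid$frequencies
  speed <- medium$speed_base + medium$dispersion_slope * f
  if (any(speed <= 0)) {
    stopf("unphysical medium: non-positive speed at %.3g MHz", f[which(speed <= 0)[1]])
  }
  nf <- length(f)
  tof <- medium$path_length / speed
  att <- medium$attenuation_slope * f * medium$path_length
  if (medium$noise_sd_tof > 0) tof <- tof + stats::rnorm(nf, 0, medium$noise_sd_tof)
  if (medium$noise_sd_att > 0) att <- att + stats::rnorm(nf, 0, medium$noise_sd_att)
  list(tof = tof, att = att)
}

#' Cohort generator configuration
#'
#' Defaults encode the study design emulated by the simulator: 10 septic
#' (SG) and 10 control (CG) patients, SG measured on days 1, 3, 7 and 14,
#' CG on days 1 and 3, each session partitioned into 10 single
#' measurements of `t_samples` time points at the grid frequencies.
#'
#' The signal model for one measurement is a shared smooth latent series
#' common to all frequency channels plus severity-scaled independent
#' smooth components per channel (desynchronization) plus white sensor
#' noise; a healthy brain keeps the channels in sync, disease decouples
#' them.
#'
#' @param n_sg,n_cg Group sizes.
#' @param days_sg,days_cg Measured days per group (day 1 = inclusion).
#' @param n_measurements Single measurements per session.
#' @param t_samples Time samples per single measurement (>= 2).
#' @param grid [frequency_grid()].
#' @param medium [medium_params()] giving the TOF/ATT baselines.
#' @param severity_shape_sg,severity_shape_cg Beta shape pairs for the
#'   latent severity of each group.
#' @param latent_ar AR(1) coefficient of the smooth latent series.
#' @param tof_loading,att_loading Amplitude (us, dB) of the shared latent
#'   dynamic in each modality.
#' @param loading_tilt Relative spread of channel loadings across the
#'   band (channels are affine, not identical, images of the latent).
#' @param eta_scale_tof,eta_scale_att Amplitude of the severity-scaled
#'   independent per-channel components at severity 1.
#' @param obs_noise_tof,obs_noise_att White sensor-noise SDs (us, dB).
#' @param att_severity_gain,disp_severity_gain Relative increase of the
#'   medium attenuation/dispersion slopes at severity 1 (edema raises
#'   absorption of the higher frequencies).
#' @param signal_strength_mean,signal_strength_sd Normal parameters of
#'   the recording quality metadata, truncated to \[0, 100\]%.
#' @param sofa_noise_sd,icdsc_noise_sd Gaussian noise of the clinical
#'   score links.
#' @param recovery_halflife_sg,recovery_halflife_cg Half-life (days) of
#'   the exponential decay of severity after inclusion: postoperative
#'   controls recover quickly, septic patients slowly.
#' @param min_signal_strength Sessions keep only measurements at or above
#'   this strength (default 0 = filter off).
#' @return Object of class `acg_cohort_config`.
#' @export
cohort_config <- function(n_sg = 10, n_cg = 10,
                          days_sg = c(1, 3, 7, 14), days_cg = c(1, 3),
                          n_measurements = 10, t_samples = 256,
                          grid = frequency_grid(),
                          medium = medium_params(),
                          severity_shape_sg = c(5, 2),
                          severity_shape_cg = c(1.2, 8),
                          latent_ar = 0.9,
                          tof_loading = 0.4, att_loading = 0.8,
                          loading_tilt = 0.4,
                          eta_scale_tof = 0.5, eta_scale_att = 1.0,
                          obs_noise_tof = 0.02, obs_noise_att = 0.05,
                          att_severity_gain = 0.35,
                          disp_severity_gain = 0.15,
                          signal_strength_mean = 80.9,
                          signal_strength_sd = 14.6,
                          sofa_noise_sd = 1.2, icdsc_noise_sd = 0.8,
                          recovery_halflife_sg = 14, recovery_halflife_cg = 2,
                          min_signal_strength = 0) {
  if (n_sg < 1 || n_cg < 1) stopf("group sizes must be >= 1")
  if (t_samples < 2) stopf("t_samples must be >= 2: dimensionality is undefined on a single sample")
  if (n_measurements < 1) stopf("n_measurements must be >= 1")
  if (!all(days_sg %in% c(1, 3, 7, 14)) || !all(days_cg %in% c(1, 3))) {
    stopf("days_sg must be within {1,3,7,14} and days_cg within {1,3}")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "acg_cohort_config")
}

# smooth standardized AR(1) series, one column per channel
smooth_series <- function(t_samples, n_series, ar) {
  e <- matrix(stats::rnorm(t_samples * n_series), t_samples, n_series)
  z <- stats::filter(e, filter = ar, method = "recursive")
  z <- matrix(as.numeric(z), t_samples, n_series)
  # standardize each column so amplitudes are controlled by the loadings
  mu <- colMeans(z)
  sd <- apply(z, 2, stats::sd)
  sd[sd == 0] <- 1
  sweep(sweep(z, 2, mu, "-"), 2, sd, "/")
}

#' Generate one single ACG measurement
#'
#' Produces a `t_samples x F` TOF matrix and ATT matrix. Each channel is
#' `baseline(f) + loading(f) * z(t) + severity * eta_scale * eta_f(t) +
#' white noise`, with `z` a shared smooth latent series and `eta_f`
#' independent smooth series per channel. At severity 0 with zero noise
#' the channels are affine images of one latent series (rank-1 data).
#' Consumes the current RNG stream; seed the caller for reproducibility.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param grid [frequency_grid()].
#' @param config [cohort_config()].
#' @param measurement_index Index 1..n_measurements within the session.
#' @return Object of class `acg_measurement`: list with `tof`, `att`
#'   (`t_samples x F` matrices), `signal_strength`, `measurement_index`.
#' @export
generate_measurement <- function(severity, grid = frequency_grid(),
                                 config = cohort_config(),
                                 measurement_index = 1L) {
  if (severity < 0 || severity > 1) stopf("severity must be in [0, 1]")
  tt <- config$t_samples
  if (tt < 2) stopf("t_samples must be >= 2")
  f <- grid$frequencies
  nf <- length(f)

  medium <- config$medium
  medium_sev <- medium_params(
    path_length = medium$path_length,
    speed_base = medium$speed_base,
    dispersion_slope = medium$dispersion_slope * (1 + config$disp_severity_gain * severity),
    attenuation_slope = medium$attenuation_slope * (1 + config$att_severity_gain * severity),
    noise_sd_tof = 0, noise_sd_att = 0)
  base <- simulate_received_pulse(grid, medium_sev)

  # channel loadings: affine tilt across the band, never zero
  rel <- if (nf > 1) (seq_len(nf) - 1) / (nf - 1) else 0
  load_shape <- 1 - config$loading_tilt / 2 + config$loading_tilt * rel

  z <- smooth_series(tt, 1L, config$latent_ar)[, 1]
  build <- function(baseline, loading_amp, eta_scale, obs_sd) {
    m <- outer(z, loading_amp * load_shape) +
      matrix(baseline, tt, nf, byrow = TRUE)
    if (severity > 0 && eta_scale > 0) {
      eta <- smooth_series(tt, nf, config$latent_ar)
      m <- m + severity * eta_scale * eta
    }
    if (obs_sd > 0) m <- m + matrix(stats::rnorm(tt * nf, 0, obs_sd), tt, nf)
    colnames(m) <- sprintf("f%02d", seq_len(nf))
    m
  }
  tof <- build(base$tof, config$tof_loading, config$eta_scale_tof, config$obs_noise_tof)
  att <- build(base$att, config$att_loading, config$eta_scale_att, config$obs_noise_att)

  ss <- stats::rnorm(1, config$signal_strength_mean, config$signal_strength_sd)
  ss <- min(100, max(0, ss))

  structure(list(tof = tof, att = att, t_samples = tt,
                 signal_strength = ss,
                 measurement_index = as.integer(measurement_index)),
            class = "acg_measurement")
}

# clinical score links: linear in severity with Gaussian noise, clipped;
# labs log-normal with location increasing in severity
draw_clinical <- function(severity, group, day, config) {
  sofa <- max(0, min(24, round(2 + 12 * severity + stats::rnorm(1, 0, config$sofa_noise_sd))))
  if (group == "CG") {
    icdsc <- 0L
  } else {
    icdsc <- max(0, min(8, round(1 + 5 * severity + stats::rnorm(1, 0, config$icdsc_noise_sd))))
    # enrollment condition: septic patients are delirious at inclusion
    if (day == 1) icdsc <- max(4L, icdsc)
  }
  cam_icu <- if (group == "CG") FALSE else icdsc >= 4
  list(
    sofa = as.integer(sofa), icdsc = as.integer(icdsc), cam_icu = cam_icu,
    lactate = stats::rlnorm(1, log(0.9) + 1.2 * severity, 0.35),
    pct = stats::rlnorm(1, log(0.3) + 5.5 * severity, 0.6),
    creatinine = stats::rlnorm(1, log(75) + 0.9 * severity, 0.25),
    bilirubin = stats::rlnorm(1, log(10) + 1.0 * severity, 0.4))
}

#' Generate a synthetic ACG cohort
#'
#' Draws latent severities (septic group high, controls low), links the
#' clinical scores and laboratory values to severity, and simulates all
#' measurement sessions. Patient ids interleave the two groups
#' (`P01` = SG, `P02` = CG, ...) so that "first 10 / last 10 patients"
#' splits are balanced. Identical `(config, seed)` gives an identical
#' cohort.
#'
#' @param config [cohort_config()].
#' @param seed Integer seed; all randomness flows through it.
#' @return Object of class `acg_cohort`: list with `records` (one entry
#'   per measured patient-day), `frequency_grid`, `config`, `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_sg = 2, n_cg = 2, t_samples = 16), seed = 1)
#' coh
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "acg_cohort_config"))
  if (missing(seed)) stopf("an explicit seed is required")
  set.seed(as.integer(seed))

  n_total <- config$n_sg + config$n_cg
  groups <- character(n_total)
  # interleave SG/CG by id while both remain
  sg_left <- config$n_sg; cg_left <- config$n_cg
  for (i in seq_len(n_total)) {
    take_sg <- (i %% 2 == 1 && sg_left > 0) || cg_left == 0
    if (take_sg) { groups[i] <- "SG"; sg_left <- sg_left - 1 }
    else { groups[i] <- "CG"; cg_left <- cg_left - 1 }
  }
  ids <- sprintf("P%02d", seq_len(n_total))
  severities <- numeric(n_total)
  severities[groups == "SG"] <- stats::rbeta(
    config$n_sg, config$severity_shape_sg[1], config$severity_shape_sg[2])
  severities[groups == "CG"] <- stats::rbeta(
    config$n_cg, config$severity_shape_cg[1], config$severity_shape_cg[2])

  records <- list()
  for (i in seq_len(n_total)) {
    days <- if (groups[i] == "SG") config$days_sg else config$days_cg
    halflife <- if (groups[i] == "SG") config$recovery_halflife_sg else config$recovery_halflife_cg
    for (day in days) {
      sev_day <- severities[i] * 2^(-(day - 1) / halflife)
      clin <- draw_clinical(sev_day, groups[i], day, config)
      sessions <- lapply(seq_len(config$n_measurements), function(m) {
        generate_measurement(sev_day, config$grid, config, m)
      })
      if (config$min_signal_strength > 0) {
        keep <- vapply(sessions, function(s) s$signal_strength >= config$min_signal_strength,
                       logical(1))
        if (any(keep)) sessions <- sessions[keep]
      }
      records[[length(records) + 1L]] <- c(
        list(patient_id = ids[i], group = groups[i], day = as.integer(day),
             severity = sev_day),
        clin, list(sessions = sessions))
    }
  }
  structure(list(records = records, frequency_grid = config$grid,
                 config = config, seed = as.integer(seed)),
            class = "acg_cohort")
}

#' @export
print.acg_cohort <- function(x, ...) {
  clin <- cohort_clinical(x)
  cat(sprintf("ACG cohort: %d patients (%d SG, %d CG), %d patient-days, %d freq channels, seed %d\n",
              length(unique(clin$patient_id)),
              length(unique(clin$patient_id[clin$group == "SG"])),
              length(unique(clin$patient_id[clin$group == "CG"])),
              nrow(clin), length(x$frequency_grid$frequencies), x$seed))
  invisible(x)
}

#' Clinical table of a cohort
#'
#' One row per measured patient-day with the group, scores, labs and the
#' (synthetic-only) latent severity.
#'
#' @param cohort An [generate_cohort()] result.
#' @return `data.frame` ordered by (patient_id, day).
#' @export
cohort_clinical <- function(cohort) {
  stopifnot(inherits(cohort, "acg_cohort"))
  rows <- lapply(cohort$records, function(r) {
    data.frame(patient_id = r$patient_id, group = r$group, day = r$day,
               sofa = r$sofa, icdsc = r$icdsc, cam_icu = r$cam_icu,
               lactate = r$lactate, pct = r$pct, creatinine = r$creatinine,
               bilirubin = r$bilirubin, severity = r$severity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$patient_id, out$day), , drop = FALSE]
}
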