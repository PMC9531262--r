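#' Explained-variance profile of a time-by-frequency matrix
#'
#' Principal component analysis of a `T x F` matrix of frequency-channel
#' time series (TOF or ATT): columns are mean-centered (not variance
#' scaled), the singular value decomposition is taken, and squared
#' singular values are normalised to explained-variance fractions sorted
#' in descending order. The profile is padded with zeros to length `F`.
#'
#' All-constant (zero total variance) input is degenerate: the profile is
#' defined as `c(1, 0, ...)` and flagged, with a warning.
#'
#' @param data Numeric `T x F` matrix, `T >= 2`, `F >= 2`, finite.
#' @return Numeric vector of length `F` summing to 1, non-increasing,
#'   with attribute `degenerate` (logical).
#' @export
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' explained_variance_profile(x)
explained_variance_profile <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stopf("need at least 2 time samples")
  if (ncol(data) < 2) stopf("need at least 2 frequency channels")
  if (!all(is.finite(data))) stopf("data must be finite")
  nf <- ncol(data)
  xc <- sweep(data, 2, colMeans(data), "-")
  total <- sum(xc^2)
  if (total <= 1e-300) {
    warning("zero total variance: all-constant data, profile defined as (1, 0, ...)",
            call. = FALSE)
    out <- c(1, rep(0, nf - 1))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d <- svd(xc, nu = 0, nv = 0)$d
  ratios <- d^2 / sum(d^2)
  out <- c(ratios, rep(0, max(0, nf - length(ratios))))[seq_len(nf)]
  out <- sort(out, decreasing = TRUE)
  attr(out, "degenerate") <- FALSE
  out
}

#' Dimensionality of frequency-channel data
#'
#' The minimal number of principal components whose cumulative explained
#' variance reaches `threshold` -- a measure of asynchronicity of the
#' frequency channels. Perfectly synchronous (rank-1) data has
#' dimensionality 1; fully desynchronised channels push it towards `F`.
#' The cumulative comparison uses `>=` with an absolute tolerance of
#' 1e-12 so the count is deterministic across linear-algebra backends.
#'
#' @inheritParams explained_variance_profile
#' @param threshold Explained-variance fraction in (0, 1\]; 0.90 is the
#'   conventional figure-level choice, 0.95 a stricter alternative.
#' @return Integer in `1..F`.
#' @export
#' @examples
#' z <- rnorm(50)
#' x <- cbind(z, 2 * z + 1, -z)  # rank 1
#' dimensionality(x, 0.95)
dimensionality <- function(data, threshold = 0.90) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  profile <- explained_variance_profile(data)
  dimensionality_from_profile(profile, threshold)
}

# shared cumulative-count rule, also used on precomputed profiles
dimensionality_from_profile <- function(profile, threshold) {
  as.integer(which(cumsum(profile) >= threshold - 1e-12)[1])
}

#' Per-measurement and per-patient-day dimensionality of a cohort
#'
#' Computes the dimensionality of every single measurement of every
#' measured patient-day, for the requested modalities, and the
#' per-patient-day mean (the session average used for patient-level
#' analysis). Rows with `measurement_index == "mean"` carry the average.
#'
#' @param cohort An [generate_cohort()] (or [load_cohort()]) cohort.
#' @param modality Character vector, subset of `c("tof", "att")`.
#' @param threshold Explained-variance threshold, see [dimensionality()].
#' @return `data.frame` with columns patient_id, day, measurement_index
#'   (character; `"mean"` for the session average), modality, threshold,
#'   dimensionality.
#' @export
patient_day_dimensionality <- function(cohort, modality = c("tof", "att"),
                                       threshold = 0.90) {
  stopifnot(inherits(cohort, "acg_cohort"))
  modality <- match.arg(modality, c("tof", "att"), several.ok = TRUE)
  out <- list()
  for (r in cohort$records) {
    if (length(r$sessions) == 0) {
      warning(sprintf("no sessions for %s day %d: record skipped",
                      r$patient_id, r$day), call. = FALSE)
      next
    }
    for (mod in modality) {
      dims <- vapply(r$sessions, function(s) dimensionality(s[[mod]], threshold),
                     integer(1))
      idx <- vapply(r$sessions, function(s) s$measurement_index, integer(1))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = r$patient_id, day = r$day,
        measurement_index = c(as.character(idx), "mean"),
        modality = mod, threshold = threshold,
        dimensionality = c(as.numeric(dims), mean(dims)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Wide per-patient-day dimensionality summary
#'
#' Session-mean dimensionality per patient-day in wide form, with a
#' composite column averaging the two modalities (the default input of
#' the correlation report).
#'
#' @inheritParams patient_day_dimensionality
#' @return `data.frame` with columns patient_id, day, dim_tof, dim_att,
#'   dim_mean, ordered by (patient_id, day).
#' @export
dimensionality_summary <- function(cohort, threshold = 0.90) {
  long <- patient_day_dimensionality(cohort, c("tof", "att"), threshold)
  means <- long[long$measurement_index == "mean", ]
  wide <- stats::reshape(
    means[, c("patient_id", "day", "modality", "dimensionality")],
    idvar = c("patient_id", "day"), timevar = "modality", direction = "wide")
  names(wide) <- sub("^dimensionality\\.", "dim_", names(wide))
  wide$dim_mean <- (wide$dim_tof + wide$dim_att) / 2
  rownames(wide) <- NULL
  wide[order(wide$patient_id, wide$day), , drop = FALSE]
}
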