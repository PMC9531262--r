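# Feature vocabulary. Names follow the grammar {modality}_{f_i}[_{f_j}]_{stat}
# with modality one of tof/att/tofatt and "all" for band-level features.
# With the default 10-channel grid the table has 1010 columns:
#   per-channel stats            2 x 12 x 10  = 240
#   within-modality pair stats   2 x  7 x 45  = 630
#   cross-modality correlations      10 x 10  = 100
#   cross-modality same-frequency     3 x 10  =  30
#   spectral slopes across the band               4
#   PCA summaries (dim @ .90/.95, PC1 share)      6

channel_stat_names <- c("mean", "sd", "median", "iqr", "min", "max",
                        "range", "cv", "slope", "acf1", "acf2", "rmsdiff")
pair_stat_names <- c("cor", "dcor", "meandiff", "meanratio",
                     "sddiff", "sdratio", "iqrratio")
xmod_pair_stat_names <- c("meanprod", "meanratio", "sdratio")

#' Feature names of the measurement feature vocabulary
#'
#' Deterministic, unique column names of [build_feature_table()] for a
#' given frequency grid.
#'
#' @param grid [frequency_grid()].
#' @return Character vector (length 1010 for the default 10-channel grid).
#' @export
acg_feature_names <- function(grid = frequency_grid()) {
  nf <- length(grid$frequencies)
  fl <- sprintf("f%02d", seq_len(nf))
  ut <- which(upper.tri(diag(nf)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  pair_lab <- sprintf("%s_%s", fl[ut[, 1]], fl[ut[, 2]])
  c(
    unlist(lapply(c("tof", "att"), function(mod)
      unlist(lapply(channel_stat_names, function(s) sprintf("%s_%s_%s", mod, fl, s))))),
    unlist(lapply(c("tof", "att"), function(mod)
      unlist(lapply(pair_stat_names, function(s) sprintf("%s_%s_%s", mod, pair_lab, s))))),
    sprintf("tofatt_%s_%s_cor", rep(fl, each = nf), rep(fl, nf)),
    unlist(lapply(xmod_pair_stat_names, function(s) sprintf("tofatt_%s_%s_%s", fl, fl, s))),
    sprintf("%s_all_specslope_%s", rep(c("tof", "att"), each = 2), c("mean", "sd")),
    sprintf("%s_all_%s", rep(c("tof", "att"), each = 3), c("dim090", "dim095", "pc1var")))
}

# summaries of one T x F channel matrix
channel_summaries <- function(m) {
  tt <- nrow(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  med <- apply(m, 2, stats::median)
  qs <- apply(m, 2, stats::quantile, probs = c(0.25, 0.75), names = FALSE)
  mn <- apply(m, 2, min)
  mx <- apply(m, 2, max)
  dm <- diff(m)
  list(mean = mu, sd = sdv, median = med, iqr = qs[2, ] - qs[1, ],
       min = mn, max = mx, range = mx - mn,
       cv = safe_ratio(sdv, abs(mu)),
       slope = ls_slope(seq_len(tt), m),
       acf1 = col_acf(m, 1), acf2 = col_acf(m, 2),
       rmsdiff = sqrt(colMeans(dm^2)),
       cormat = safe_cor(m), dcormat = safe_cor(dm))
}

pca_summaries <- function(m) {
  p <- suppressWarnings(explained_variance_profile(m))
  c(dimensionality_from_profile(p, 0.90),
    dimensionality_from_profile(p, 0.95),
    p[1])
}

# feature vector of one single measurement; order must match acg_feature_names()
measurement_features <- function(meas, grid) {
  nf <- length(grid$frequencies)
  f <- grid$frequencies
  s <- list(tof = channel_summaries(meas$tof), att = channel_summaries(meas$att))
  ut <- which(upper.tri(diag(nf)), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  i <- ut[, 1]; j <- ut[, 2]

  chan <- unlist(lapply(s, function(cs)
    unlist(cs[channel_stat_names], use.names = FALSE)))
  pairs <- unlist(lapply(s, function(cs) c(
    cs$cormat[ut], cs$dcormat[ut],
    cs$mean[i] - cs$mean[j], safe_ratio(cs$mean[i], cs$mean[j]),
    cs$sd[i] - cs$sd[j], safe_ratio(cs$sd[i], cs$sd[j]),
    safe_ratio(cs$iqr[i], cs$iqr[j]))))
  xcor <- safe_cor(meas$tof, meas$att)  # nf x nf, tof rows x att cols
  xsame <- c(s$tof$mean * s$att$mean,
             safe_ratio(s$tof$mean, s$att$mean),
             safe_ratio(s$tof$sd, s$att$sd))
  spec <- c(ls_slope(f, cbind(s$tof$mean, s$tof$sd)),
            ls_slope(f, cbind(s$att$mean, s$att$sd)))
  pca <- c(pca_summaries(meas$tof), pca_summaries(meas$att))

  c(chan, pairs, as.numeric(t(xcor)), xsame, spec, pca)
}

#' Build the patient-day (or measurement) feature table
#'
#' Computes the full deterministic feature vector of every single
#' measurement and, at the default granularity, averages the 10
#' measurement-level vectors of each session into one row per measured
#' patient-day (patient-level analysis works on session averages). The
#' vocabulary mixes attenuation-based values, TOF-based values and
#' TOF-ATT interaction features; see [acg_feature_names()].
#'
#' @param cohort An [generate_cohort()] cohort.
#' @param granularity `"patient_day"` (session mean, default) or
#'   `"measurement"` (one row per single measurement).
#' @return Object of class `acg_feature_table`: list with `values`
#'   (`N x P` matrix), `feature_names`, `row_index` (`data.frame` of
#'   patient_id, day and, at measurement granularity,
#'   measurement_index), `targets` (aligned clinical columns), and
#'   `granularity`.
#' @export
build_feature_table <- function(cohort, granularity = c("patient_day", "measurement")) {
  stopifnot(inherits(cohort, "acg_cohort"))
  granularity <- match.arg(granularity)
  grid <- cohort$frequency_grid
  fnames <- acg_feature_names(grid)

  rows <- list(); idx <- list(); tgt <- list()
  for (r in cohort$records) {
    for (s in r$sessions) {
      rows[[length(rows) + 1L]] <- measurement_features(s, grid)
      idx[[length(idx) + 1L]] <- data.frame(
        patient_id = r$patient_id, day = r$day,
        measurement_index = s$measurement_index, stringsAsFactors = FALSE)
      tgt[[length(tgt) + 1L]] <- data.frame(
        group = r$group, sofa = r$sofa, icdsc = r$icdsc, cam_icu = r$cam_icu,
        lactate = r$lactate, pct = r$pct, creatinine = r$creatinine,
        bilirubin = r$bilirubin, stringsAsFactors = FALSE)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- fnames
  row_index <- do.call(rbind, idx)
  targets <- do.call(rbind, tgt)

  if (granularity == "patient_day") {
    key <- paste(row_index$patient_id, row_index$day, sep = "|")
    ukey <- unique(key)
    values <- rowsum(values, group = key, reorder = FALSE) /
      as.vector(table(factor(key, levels = unique(key))))
    first <- match(ukey, key)
    row_index <- row_index[first, c("patient_id", "day"), drop = FALSE]
    targets <- targets[first, , drop = FALSE]
  }
  ord <- if (granularity == "measurement") {
    order(row_index$patient_id, row_index$day, row_index$measurement_index)
  } else {
    order(row_index$patient_id, row_index$day)
  }
  values <- values[ord, , drop = FALSE]
  row_index <- row_index[ord, , drop = FALSE]
  rownames(row_index) <- NULL
  targets <- targets[ord, , drop = FALSE]
  rownames(targets) <- NULL
  rownames(values) <- if (granularity == "patient_day") {
    paste(row_index$patient_id, row_index$day, sep = "|")
  } else {
    paste(row_index$patient_id, row_index$day, row_index$measurement_index, sep = "|")
  }
  structure(list(values = values, feature_names = fnames,
                 row_index = row_index, targets = targets,
                 granularity = granularity, standardized = FALSE),
            class = "acg_feature_table")
}

#' @export
print.acg_feature_table <- function(x, ...) {
  cat(sprintf("ACG feature table: %d rows (%s) x %d features%s\n",
              nrow(x$values), x$granularity, ncol(x$values),
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}

#' Z-score the columns of a feature table
#'
#' Centers each feature to mean 0 and scales to unit SD so that the
#' first principal component of any feature subset is independent of
#' feature units. Constant columns map to all-zero columns. Idempotent.
#'
#' @param table An [build_feature_table()] table.
#' @return The table with standardized `values` and `standardized = TRUE`.
#' @export
standardize_features <- function(table) {
  stopifnot(inherits(table, "acg_feature_table"))
  v <- table$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  v <- sweep(v, 2, mu, "-")
  nz <- sdv > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, sdv[nz], "/")
  v[, !nz] <- 0
  table$values <- v
  table$standardized <- TRUE
  table
}
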