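#' Group-comparison table (septic vs control)
#'
#' For each continuous clinical parameter on a given day: median and
#' 0.25--0.75 quartiles per group (linear-interpolation quantiles), a
#' Kruskal--Wallis test across the groups followed by the Mann--Whitney
#' U test for the pairwise comparison (the reported p); CAM-ICU rates
#' are compared with the chi-squared test on the 2x2 contingency table.
#' No multiple-testing correction is applied by default (`p_adjust =
#' "none"`); Holm is available.
#'
#' @param clinical A [cohort_clinical()] data.frame (or any data.frame
#'   with `group`, `day` and the parameter columns).
#' @param parameters Character vector of column names to compare.
#' @param day Day to compare (default 1 = inclusion).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return `data.frame` with one row per parameter: group medians and
#'   quartiles, `p_value`, `test`, `significant` (p < 0.05).
#' @export
group_compare <- function(clinical,
                          parameters = c("sofa", "icdsc", "cam_icu", "lactate",
                                         "pct", "creatinine", "bilirubin"),
                          day = 1, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  d <- clinical[clinical$day == day, , drop = FALSE]
  if (!all(c("SG", "CG") %in% d$group)) stopf("both groups must be present on day %s", day)

  rows <- list()
  for (p in parameters) {
    if (!p %in% names(d)) {
      warning(sprintf("parameter '%s' absent: row skipped", p), call. = FALSE)
      next
    }
    x <- d[[p]]
    if (is.logical(x)) {
      tab <- table(factor(d$group, levels = c("CG", "SG")),
                   factor(x, levels = c(FALSE, TRUE)))
      pv <- suppressWarnings(stats::chisq.test(tab)$p.value)
      rows[[p]] <- data.frame(
        parameter = p,
        cg_median = mean(x[d$group == "CG"]), cg_q25 = NA_real_, cg_q75 = NA_real_,
        sg_median = mean(x[d$group == "SG"]), sg_q25 = NA_real_, sg_q75 = NA_real_,
        p_value = pv, p_kruskal = NA_real_, test = "chi-squared",
        stringsAsFactors = FALSE)
    } else {
      qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
      qc <- qs(x[d$group == "CG"]); qsg <- qs(x[d$group == "SG"])
      suppressWarnings({
        kw <- stats::kruskal.test(x, factor(d$group))$p.value  # omnibus step
        pv <- stats::wilcox.test(x[d$group == "SG"], x[d$group == "CG"],
                                 exact = NULL)$p.value
      })
      rows[[p]] <- data.frame(
        parameter = p,
        cg_median = qc[2], cg_q25 = qc[1], cg_q75 = qc[3],
        sg_median = qsg[2], sg_q25 = qsg[1], sg_q75 = qsg[3],
        p_value = pv, p_kruskal = kw, test = "kruskal-wallis/mann-whitney",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (p_adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  out$significant <- out$p_value < 0.05
  out
}

#' Correlation table: ACG features vs clinical parameters
#'
#' Absolute Pearson correlations of (a) the dimensionality summary
#' (per-modality and their mean) and (b) the GA-selected first principal
#' component with each clinical parameter, per patient-day. The GA
#' column of a parameter uses the GA run targeted at that parameter.
#'
#' @param dim_summary A [dimensionality_summary()] data.frame.
#' @param ga_scores Named list mapping parameter name to the per-row
#'   [pc1_scores()] of the GA individual selected for that parameter
#'   (aligned with `clinical` rows); entries may be missing.
#' @param clinical [cohort_clinical()]-style data.frame aligned with
#'   `dim_summary` by `(patient_id, day)`.
#' @param parameters Parameters, in reporting order.
#' @return `data.frame` with columns parameter, r_dim (composite),
#'   r_dim_tof, r_dim_att, r_ga (absolute values; `NA` when undefined
#'   or unavailable).
#' @export
correlation_table <- function(dim_summary, ga_scores = list(), clinical,
                              parameters = c("sofa", "icdsc", "lactate", "pct",
                                             "creatinine", "bilirubin")) {
  key_dim <- paste(dim_summary$patient_id, dim_summary$day, sep = "|")
  key_cl <- paste(clinical$patient_id, clinical$day, sep = "|")
  m <- match(key_cl, key_dim)
  if (anyNA(m)) stopf("dimensionality rows not aligned with clinical rows")
  ds <- dim_summary[m, , drop = FALSE]

  abs_r <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    abs(stats::cor(x, y))
  }
  rows <- lapply(parameters, function(p) {
    y <- as.numeric(clinical[[p]])
    ga <- ga_scores[[p]]
    data.frame(parameter = p,
               r_dim = abs_r(ds$dim_mean, y),
               r_dim_tof = abs_r(ds$dim_tof, y),
               r_dim_att = abs_r(ds$dim_att, y),
               r_ga = if (is.null(ga)) NA_real_ else abs_r(as.numeric(ga), y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
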