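# Figure analogs. ggplot2 is suggested, not imported; the helpers fail
# with a clear message when it is absent.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stopf("ggplot2 is required for plotting")
  }
}

#' Scatterplot of ATT vs TOF dimensionality
#'
#' One point per patient-day, coloured by a clinical score: the
#' patient-level dimensionality view.
#'
#' @param dim_summary A [dimensionality_summary()] data.frame.
#' @param clinical Aligned [cohort_clinical()] data.frame.
#' @param color_by Clinical column used for the colour scale.
#' @param day Optional day filter.
#' @return A ggplot object.
#' @export
plot_dimensionality <- function(dim_summary, clinical, color_by = "sofa",
                                day = NULL) {
  need_ggplot()
  key_dim <- paste(dim_summary$patient_id, dim_summary$day, sep = "|")
  key_cl <- paste(clinical$patient_id, clinical$day, sep = "|")
  d <- cbind(dim_summary, score = clinical[[color_by]][match(key_dim, key_cl)])
  if (!is.null(day)) d <- d[d$day == day, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dim_tof, y = .data$dim_att,
                                  colour = .data$score)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = color_by) +
    ggplot2::labs(x = "dimensionality (TOF)", y = "dimensionality (ATT)") +
    ggplot2::theme_minimal()
}

#' Scatterplot of two GA-derived components
#'
#' Plots the first-principal-component scores of two GA-selected
#' feature subsets against each other, coloured by a clinical score.
#'
#' @param scores_x,scores_y Numeric [pc1_scores()] vectors.
#' @param score Clinical score vector for the colour scale.
#' @param labs Axis/legend labels (length 3).
#' @return A ggplot object.
#' @export
plot_ga_components <- function(scores_x, scores_y, score,
                               labs = c("GA component 1", "GA component 2", "score")) {
  need_ggplot()
  d <- data.frame(x = scores_x, y = scores_y, score = score)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$score)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = labs[3]) +
    ggplot2::labs(x = labs[1], y = labs[2]) +
    ggplot2::theme_minimal()
}
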