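#' Scatterplot of evidence score versus publication count
#'
#' The dashboard view: one point per disease-gene association, mean-rank
#' score on the x-axis, publication count on the y-axis, coloured by target
#' development level (Tclin/Tchem/Tbio/Tdark) where available.
#'
#' @param object A `ct_associations` tibble from [score_associations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_associations <- function(object, ...) {
  df <- scatter_export(object)
  df$tdl <- factor(df$tdl, levels = ct_tdl_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$meanRankScore, y = .data$nPub,
                                   colour = .data$tdl)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "meanRankScore", y = "publications (nPub)",
                  colour = "TDL") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the recency decay curve
#'
#' Shows the study weight `2 * exp(-t / h)` as a function of study age under
#' a piecewise half-life configuration, making the deliberate (and
#' documented) discontinuity at the age threshold visible.
#'
#' @param config A [decay_config()].
#' @param max_age Right edge of the age axis in years.
#' @return A ggplot object.
#' @export
plot_decay_curve <- function(config = decay_config(), max_age = 30) {
  t <- seq(0, max_age, by = 0.05)
  df <- tibble(
    age_years = t,
    weight = decay_weight(t, config),
    branch = ifelse(t <= config$age_threshold,
                    sprintf("h = %g y (recent)", config$h_recent),
                    sprintf("h = %g y (old)", config$h_old))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years, y = .data$weight,
                                   colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "study age (years)", y = "decay weight",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
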