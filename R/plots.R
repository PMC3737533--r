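# ggplot2 visualisations.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_eval <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = 1 - .data$specificity,
                               y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot the emission distributions of a fitted model
#'
#' Bound (pos) vs background (neg) histograms per feature; conservation
#' panels are faceted by stratum.
#'
#' @param object An `hmm_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hmm_model <- function(object, ...) {
  dat <- tidy(object) |>
    filter(.data$component == "emission") |>
    mutate(panel = ifelse(is.na(.data$stratum) | .data$stratum == "ALL",
                          .data$feature,
                          paste0(.data$feature, " (", .data$stratum, ")")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$estimate,
                                    fill = .data$side)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::scale_fill_manual(values = c(pos = "#2166ac", neg = "grey55")) +
    ggplot2::labs(x = "bin", y = "probability mass", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot footprint-overlap fraction by score bin
#'
#' @param object A `score_bin_overlap`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_bin_overlap <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = factor(.data$bin), y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "score bin", y = "fraction overlapping footprints") +
    ggplot2::theme_minimal()
}

#' Plot a positional cluster-score profile
#'
#' @param profile Tibble from [positional_profile()].
#' @return A ggplot faceted by splice site.
#' @export
plot_positional_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_area(fill = "#2166ac", alpha = 0.7) +
    ggplot2::facet_wrap(~splice_site, nrow = 1) +
    ggplot2::labs(x = "offset from splice site (nt)",
                  y = "mean cluster score coverage") +
    ggplot2::theme_minimal()
}
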