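# ggplot2 quick-look methods for the main result objects.

#' Plot a PCA age axis
#'
#' Samples on PC1/PC2, colored by age, shaped by group, with vertical
#' lines at each (group, age) PC1 median — the representatives of
#' metabolic age.
#'
#' @param object An `age_axis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.age_axis <- function(object, ...) {
  s <- object$scores
  meds <- s |>
    group_by(.data$group, .data$age_months) |>
    summarise(m = median(.data$PC1), .groups = "drop")
  ggplot(s, aes(.data$PC1, .data$PC2, colour = factor(.data$age_months),
                shape = .data$group)) +
    geom_point(size = 2) +
    geom_vline(data = meds,
               aes(xintercept = .data$m, colour = factor(.data$age_months),
                   linetype = .data$group),
               alpha = 0.6) +
    labs(
      x = sprintf("PC1 (%.0f%%) — metabolic age", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$var_explained[2]),
      colour = "age (months)", shape = NULL, linetype = NULL
    ) +
    theme_minimal()
}

#' Plot a metabolic-noise trajectory
#'
#' Median-of-CV per group across ages; stars mark ages where the
#' hen-permutation comparison fell below 0.05.
#'
#' @param object A `noise_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noise_trajectory <- function(object, ...) {
  comp <- attr(object, "comparisons")
  p <- ggplot(as_tibble(object),
              aes(.data$age_months, .data$median_cv, colour = .data$group)) +
    geom_line() + geom_point(size = 2) +
    scale_colour_manual(values = c(control = "firebrick",
                                   molted = "forestgreen")) +
    labs(x = "age (months)", y = "metabolic noise (median CV)",
         colour = NULL) +
    theme_minimal()
  if (!is.null(comp) && nrow(comp) && any(comp$p_value < 0.05)) {
    stars <- comp |> filter(.data$p_value < 0.05)
    ymax <- max(object$median_cv)
    p <- p + annotate("text", x = stars$age_months, y = ymax * 1.05,
                      label = "*", size = 6)
  }
  p
}

#' Plot predicted vs true laying efficiency
#'
#' @param object A `prediction_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.prediction_eval <- function(object, ...) {
  g <- glance(object)
  ggplot(as_tibble(object),
         aes(.data$true_efficiency, .data$predicted_efficiency)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    geom_point(aes(colour = factor(.data$age_months)), size = 2) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "firebrick", linewidth = 0.6) +
    labs(x = "true laying efficiency", y = "predicted laying efficiency",
         colour = "age (months)",
         subtitle = sprintf("R = %.2f (Pearson), p = %.2g", g$r, g$p_value)) +
    theme_minimal()
}

#' Median laying-efficiency curves per group
#'
#' @param laying A laying log tibble (with `group`).
#' @param ... Unused.
#' @return A ggplot of cohort median efficiency by month.
#' @export
plot_laying_efficiency <- function(laying, ...) {
  calendar <- attr(laying, "calendar")
  months <- sort(unique(laying$month))
  hens <- distinct(laying, .data$hen_id, .data$group)
  curves <- tidyr::crossing(group = unique(hens$group), month = months) |>
    rowwise() |>
    mutate(median_efficiency = cohort_median_efficiency(
      laying, hens$hen_id[hens$group == .data$group], .data$month)) |>
    ungroup()
  ggplot(curves, aes(.data$month, .data$median_efficiency,
                     colour = .data$group)) +
    geom_line() + geom_point() +
    scale_colour_manual(values = c(control = "firebrick",
                                   molted = "forestgreen")) +
    labs(x = "age (months)", y = "median laying efficiency", colour = NULL) +
    theme_minimal()
}
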