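# ggplot2 helpers for the main result types.

#' Heatmap of a bootstrapped contact matrix
#'
#' @param object A `contact_matrix`.
#' @param value Which matrix to draw: `"boot_mean"` (default) or `"point"`.
#' @param log_scale Use a log10 colour scale (useful for region matrices,
#'   where off-diagonal entries are orders of magnitude smaller).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_matrix
#' @export
autoplot.contact_matrix <- function(object, value = c("boot_mean", "point"),
                                    log_scale = FALSE, ...) {
  value <- match.arg(value)
  df <- tidy(object)
  df$fill <- df[[value]]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$participant_group,
                                        y = .data$contact_group,
                                        fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "participant group", y = "contact group",
                  fill = "contacts/day", title = object$stratum) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (log_scale) {
    p + ggplot2::scale_fill_viridis_c(trans = "log10")
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Stacked bars of per-period contact composition
#'
#' @param object A [composition_table()].
#' @param ... Unused.
#' @return A ggplot object: mean contacts/participant/day per period,
#'   stacked by attribute level.
#' @method autoplot composition_table
#' @export
autoplot.composition_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$period,
                                       y = .data$mean_contacts,
                                       fill = .data$level)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "period", y = "contacts/participant/day",
                  fill = object$attribute[1]) +
    ggplot2::theme_minimal()
}

#' Forest plot of posterior rate ratios
#'
#' @param fit A `contact_fit`.
#' @return A ggplot object with one row per covariate level, point estimate
#'   and 95% interval, reference levels at 1.
#' @export
plot_rate_ratios <- function(fit) {
  df <- rate_ratio_table(fit)
  df$label <- paste(df$term, df$level, sep = ": ")
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(x = "rate ratio (95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}
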