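# Figure builders mirroring the three panels reported per threshold mode:
# (A) PET+ yield vs threshold, (B) test counts on a log10 scale, (C) cost
# change by PET-to-plasma ratio. Plots are regeneration aids; all assertions
# in the test suite run on the CSV/JSON artifacts.

#' Plot PET-positive yield against the invitation threshold
#'
#' @param screening A `screening_result` from [screen_sweep()].
#' @return A ggplot object.
#' @export
plot_yield <- function(screening) {
  df <- as.data.frame(screening)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = 100 * .data$ppv)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 100 * attr(screening, "prevalence"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = sprintf("%s risk threshold", df$mode[1]),
                  y = "PET+ rate among invited (%)") +
    ggplot2::theme_minimal()
  if (!all(is.na(df$ppv_lo)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 100 * .data$ppv_lo, ymax = 100 * .data$ppv_hi),
      alpha = 0.2, fill = "#2c7fb8")
  p
}

#' Plot plasma and PET test counts against the invitation threshold
#'
#' Counts are shown on a log10 scale.
#'
#' @inheritParams plot_yield
#' @return A ggplot object.
#' @export
plot_test_counts <- function(screening) {
  df <- as.data.frame(screening)
  long <- rbind(
    data.frame(threshold = df$threshold, count = df$n_pet, test = "PET"),
    data.frame(threshold = df$threshold, count = df$n_plasma, test = "plasma"))
  long <- long[!is.na(long$count) & long$count > 0, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$count,
                                     colour = .data$test)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = sprintf("%s risk threshold", df$mode[1]),
                  y = "tests required (log10)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot recruitment cost change by PET-to-plasma cost ratio
#'
#' @param costs A `cost_result` from [cost_sweep()].
#' @return A ggplot object.
#' @export
plot_cost_savings <- function(costs) {
  df <- as.data.frame(costs)
  y <- if (all(is.na(df$delta_boot))) df$delta_pct else df$delta_boot
  df$delta_shown <- y
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$delta_shown,
                                   colour = factor(.data$ratio))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = sprintf("%s risk threshold", df$mode[1]),
                  y = "cost change vs no pre-screening (%)",
                  colour = "PET:plasma ratio") +
    ggplot2::theme_minimal()
}

save_mode_figure <- function(screening, costs, path) {
  panels <- list(plot_yield(screening), plot_test_counts(screening),
                 plot_cost_savings(costs))
  grDevices::png(path, width = 1800, height = 600, res = 110)
  on.exit(grDevices::dev.off())
  # three panels side by side via grid viewports
  grid::grid.newpage()
  lay <- grid::grid.layout(1, 3)
  grid::pushViewport(grid::viewport(layout = lay))
  for (i in 1:3) {
    grid::pushViewport(grid::viewport(layout.pos.col = i))
    print(panels[[i]], newpage = FALSE)
    grid::popViewport()
  }
  invisible(path)
}
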