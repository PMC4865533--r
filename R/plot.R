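# ggplot2 views of simulation states and results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation state
#'
#' Renders the label grid (deep cells green, superficial cells red,
#' separator/anchors grey, cavity and medium near-white) with the
#' chemoattractant shown as contour lines when present.
#'
#' @param object a `cpm_state`.
#' @param show_conc overlay chemoattractant contours.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cpm_state <- function(object, show_conc = TRUE, ...) {
  lab <- object$labels
  kind_by_id <- stats::setNames(object$cells$kind, object$cells$id)
  w <- nrow(lab); h <- ncol(lab)
  df <- tibble::tibble(
    x = rep(seq_len(w), times = h),
    y = rep(seq_len(h), each = w),
    label = as.vector(lab))
  df$class <- dplyr::case_when(
    df$label == LAB_EXT ~ "external",
    df$label == LAB_CAV ~ "cavity",
    df$label == LAB_SEP ~ "separator",
    df$label == LAB_ANC ~ "anchor",
    kind_by_id[as.character(df$label)] == "DC" ~ "DC",
    TRUE ~ "SC")
  # shade individual cells for a visual aid
  df$shade <- ifelse(df$label >= LAB_CELL0, (df$label %% 5) / 10, 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class,
                                      alpha = 1 - .data$shade)) +
    ggplot2::scale_fill_manual(values = c(
      DC = "#2e8b57", SC = "#c23b3b", cavity = "#f2f4f7",
      external = "#ffffff", separator = "#555555", anchor = "#222222")) +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (sites)", y = "y (sites)",
                  title = sprintf("t = %.0f min", object$time_min)) +
    ggplot2::theme_minimal()
  if (show_conc && any(object$conc > 0)) {
    cf <- tibble::tibble(x = df$x, y = df$y, conc = as.vector(object$conc))
    p <- p + ggplot2::geom_contour(data = cf,
                                   ggplot2::aes(z = .data$conc),
                                   color = "#3355bb", alpha = 0.5,
                                   bins = 8)
  }
  p
}

#' Plot a radial chemoattractant profile
#'
#' @param profile output of [radial_profile()].
#' @return a ggplot object: mean concentration against depth below the SL.
#' @export
plot_radial_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$depth_um, .data$mean_conc)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth below separator (um)",
                  y = "mean concentration (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot thickness (or another metric) by condition
#'
#' @param tbl a summary table from [figure_tables()] (columns `scenario`,
#'   `mean`, `sd`).
#' @param ylab y-axis label.
#' @return a ggplot bar chart with SD error bars.
#' @export
plot_condition_means <- function(tbl, ylab = "thickness (cell diameters)") {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$scenario, .data$mean)) +
    ggplot2::geom_col(fill = "#7a9cc6") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot the secretion-level sweep
#'
#' Expansion and thickness against the secretion level multiplier, the
#' saturation curve of the chemoattractant dose response.
#'
#' @param sweep the `sweep` table from [figure_tables()].
#' @return a ggplot object with both series on free y scales.
#' @export
plot_secretion_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(sweep,
                              cols = c("expansion_mean", "thickness_mean"),
                              names_to = "metric", values_to = "value")
  long$metric <- sub("_mean", "", long$metric)
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$value,
                                     color = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "secretion level (x control)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
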