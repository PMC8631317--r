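#' Ranked delta-width plot of a screen
#'
#' One point per strain, ordered by percent deviation from its plate's
#' AWP, with the two selection tails highlighted and the tail cutoffs
#' drawn as dotted lines.
#'
#' @param object A [screen_strains()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.width_screen <- function(object, ...) {
  rec <- object$records[order(object$records$delta_width_pct), ]
  rec$idx <- seq_len(nrow(rec))
  cuts <- range(rec$delta_width_pct[!rec$selected])
  ggplot2::ggplot(rec, ggplot2::aes(.data$idx, .data$delta_width_pct)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected), size = 0.6) +
    ggplot2::geom_hline(yintercept = cuts, linetype = "dotted") +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey55", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "strain (ranked)",
      y = expression(Delta * "width vs plate AWP (%)"),
      colour = "selected"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a growth fit
#'
#' Log-scaled OD600 against time with the selected mid-exponential
#' regression window shaded and the fitted exponential overlaid.
#'
#' @param object An [estimate_gt()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.growth_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$curve,
    ggplot2::aes(.data$time_min, .data$od600)
  ) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (min)", y = "OD600") +
    ggplot2::theme_minimal()
  if (identical(object$qc, "ok")) {
    win <- object$curve[
      object$curve$time_min >= object$window[1] &
        object$curve$time_min <= object$window[2],
    ]
    od0 <- win$od600[1]
    t0 <- win$time_min[1]
    fitline <- tibble::tibble(
      time_min = win$time_min,
      od600 = od0 * exp(object$mu_per_min * (win$time_min - t0))
    )
    p <- p +
      ggplot2::annotate("rect",
        xmin = object$window[1], xmax = object$window[2],
        ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue"
      ) +
      ggplot2::geom_line(data = fitline, colour = "steelblue")
  }
  p
}

#' Width-length scatter of measured cells
#'
#' @param measurements A [measure_cells()] (optionally [filter_cells()])
#'   tibble.
#' @return A ggplot of length against width, minicells and uneven-width
#'   cells highlighted.
#' @export
plot_cell_measurements <- function(measurements) {
  m <- measurements
  m$class <- dplyr::case_when(
    m$minicell ~ "minicell",
    m$uneven_width ~ "uneven width",
    TRUE ~ "rod"
  )
  ggplot2::ggplot(
    m[!is.na(m$width_um), ],
    ggplot2::aes(.data$width_um, .data$length_um, colour = .data$class)
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "width (µm)", y = "length (µm)", colour = NULL) +
    ggplot2::theme_minimal()
}
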