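#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a width screen
#'
#' @param x A [screen_strains()] result.
#' @param ... Unused.
#' @return The ranked per-strain record tibble.
#' @exportS3Method generics::tidy
tidy.width_screen <- function(x, ...) {
  x$records
}

#' Summarise a width screen in one row
#'
#' @param x A [screen_strains()] result.
#' @param ... Unused.
#' @return One-row tibble: strain/plate counts, AWP range, selection size
#'   and the extreme delta-widths.
#' @exportS3Method generics::glance
glance.width_screen <- function(x, ...) {
  tibble::tibble(
    n_strains = nrow(x$records),
    n_plates = nrow(x$plates),
    n_selected = sum(x$records$selected),
    n_reacquire = nrow(x$reacquire),
    awp_min = min(x$plates$awp),
    awp_max = max(x$plates$awp),
    delta_min_pct = min(x$records$delta_width_pct),
    delta_max_pct = max(x$records$delta_width_pct)
  )
}

#' Tidy a growth fit
#'
#' @param x An [estimate_gt()] result.
#' @param ... Unused.
#' @return One-row tibble of the fitted quantities.
#' @exportS3Method generics::tidy
tidy.growth_fit <- function(x, ...) {
  tibble::tibble(
    gt_min = x$gt_min, mu_per_min = x$mu_per_min,
    window_start = x$window[1], window_end = x$window[2],
    r2 = x$r2_window, qc = x$qc
  )
}

#' @rdname tidy.growth_fit
#' @exportS3Method generics::glance
glance.growth_fit <- function(x, ...) {
  tidy.growth_fit(x)
}
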