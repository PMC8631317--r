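#' Summarise the cells of each well
#'
#' Per-well aggregates over kept cells: cell count, mean and SD of width,
#' and mean length over non-minicell cells (near-spherical minicells carry
#' no rod length and are excluded from length statistics). Wells with fewer
#' than `min_cells` measurable cells are flagged `qc = "reacquire"`: in a
#' live screen such a four-field acquisition would be repeated rather than
#' scored.
#'
#' @param cells Per-cell tibble with at least `plate_id`, `well_id`,
#'   `width_um`; optional `strain_id`, `length_um`, `kept`, `minicell`.
#' @param min_cells Minimum measurable cells per well (default 30).
#' @return Tibble: `plate_id`, `well_id`, `strain_id`, `n_cells`,
#'   `mean_width`, `width_sd`, `mean_length`, `qc`.
#' @export
summarize_wells <- function(cells, min_cells = 30L) {
  stopifnot(all(c("plate_id", "well_id", "width_um") %in% names(cells)))
  if (!"kept" %in% names(cells)) cells$kept <- TRUE
  if (!"minicell" %in% names(cells)) cells$minicell <- FALSE
  if (!"strain_id" %in% names(cells)) cells$strain_id <- NA_character_
  if (!"length_um" %in% names(cells)) cells$length_um <- NA_real_
  cells |>
    dplyr::filter(.data$kept) |>
    dplyr::group_by(.data$plate_id, .data$well_id) |>
    dplyr::summarise(
      strain_id = dplyr::first(.data$strain_id),
      n_cells = dplyr::n(),
      mean_width = mean(.data$width_um),
      width_sd = sd(.data$width_um),
      mean_length = mean(.data$length_um[!.data$minicell]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      width_sd = dplyr::coalesce(.data$width_sd, 0),
      qc = dplyr::if_else(.data$n_cells < min_cells, "reacquire", "ok")
    )
}

#' Average cell width per plate (AWP)
#'
#' The internal normalisation reference of a plate-based width screen: the
#' arithmetic mean width of *all* measured cells of a plate (equivalently
#' the cell-count-weighted mean of well means). Pooling the whole plate --
#' typically well over 10^4 cells -- gives a reference far more robust than
#' any single control well, and requires no wild-type well on the plate.
#' Wells flagged for re-acquisition are excluded.
#'
#' @param cells Per-cell tibble (`plate_id`, `well_id`, `width_um`,
#'   optional `kept`).
#' @param min_cells Re-acquisition threshold passed to [summarize_wells()].
#' @return Tibble: `plate_id`, `awp`, `n_cells_total`, `n_wells`.
#' @export
#' @examples
#' cells <- simulate_screen(n_strains = 96, cells_per_well = 50, seed = 1)
#' compute_awp(cells)
compute_awp <- function(cells, min_cells = 30L) {
  if (nrow(cells) == 0) abort("empty plate: no cells to average.")
  if (!"kept" %in% names(cells)) cells$kept <- TRUE
  wells <- summarize_wells(cells, min_cells = min_cells)
  ok <- dplyr::filter(wells, .data$qc == "ok")
  if (nrow(ok) == 0) abort("no well passes the minimum-cell QC; nothing to average.")
  ok |>
    dplyr::group_by(.data$plate_id) |>
    dplyr::summarise(
      awp = sum(.data$mean_width * .data$n_cells) / sum(.data$n_cells),
      n_cells_total = sum(.data$n_cells),
      n_wells = dplyr::n(),
      .groups = "drop"
    )
}

#' Percent width deviation from the plate reference
#'
#' `delta_width = (strain_mean - awp) * 100 / awp`: positive when the
#' strain is wider than its plate's average cell.
#'
#' @param strain_mean Strain mean width, micrometres. Vectorised.
#' @param awp Plate AWP, micrometres (> 0).
#' @return Percent deviation.
#' @export
#' @examples
#' delta_width(1.15, 1.0)
delta_width <- function(strain_mean, awp) {
  if (any(awp <= 0)) abort("`awp` must be > 0.")
  (strain_mean - awp) * 100 / awp
}

#' Two-tailed percentile hit calling
#'
#' Selects the `tail_fraction` most extreme strains in each direction:
#' `k = round(tail_fraction * N)` per tail (at least 1 per tail when
#' `N >= 2`, and capped so the two tails never overlap). Fixed tail counts
#' realise the "keep the strains outside the 0.5th and 99.5th percentile"
#' rule exactly: at N = 3,983 and 0.5% per tail, k = 20 and 40 strains are
#' selected. Ties are broken by ascending strain id so the call is
#' deterministic.
#'
#' @param records Tibble with `strain_id` and `delta_width_pct`.
#' @param tail_fraction Fraction selected per tail (default 0.005).
#' @return The records, ranked by ascending `delta_width_pct`
#'   (`rank` a permutation of 1..N), with `tail` (`"low"`, `"high"`,
#'   `"none"`) and `selected`, sorted by `abs(delta_width_pct)` descending.
#' @export
call_hits <- function(records, tail_fraction = 0.005) {
  stopifnot(all(c("strain_id", "delta_width_pct") %in% names(records)))
  n <- nrow(records)
  if (n < 1) abort("need at least one record.")
  if (anyNA(records$delta_width_pct)) {
    abort("all records must have a defined delta_width_pct.")
  }
  k <- round(tail_fraction * n)
  if (n >= 2) k <- max(k, 1L)
  k <- min(k, floor(n / 2))
  ord <- order(records$delta_width_pct, records$strain_id)
  records <- records[ord, ]
  records$rank <- seq_len(n)
  records$tail <- "none"
  if (k > 0) {
    records$tail[seq_len(k)] <- "low"
    records$tail[(n - k + 1):n] <- "high"
  }
  records$selected <- records$tail != "none"
  records[order(-abs(records$delta_width_pct), records$strain_id), ]
}

#' How much can outlier wells move the plate reference?
#'
#' Under equal per-well cell counts, `n_outlier_wells` wells whose strains
#' deviate by `effect` percent shift the plate's average width by exactly
#' `(n_outlier_wells / wells_per_plate) * effect` percent. Ten wells at
#' +13% on a 96-well plate -- the worst case a real screen plausibly
#' produces -- move the reference by only ~1.35%, which is why a per-plate
#' average is a safe internal reference.
#'
#' @param n_outlier_wells Number of affected wells.
#' @param effect Their common width effect, percent.
#' @param wells_per_plate Wells on the plate (> 0).
#' @return AWP shift, percent.
#' @export
#' @examples
#' awp_sensitivity(10, 13, 96)
awp_sensitivity <- function(n_outlier_wells, effect, wells_per_plate = 96L) {
  if (wells_per_plate <= 0) abort("`wells_per_plate` must be > 0.")
  if (n_outlier_wells < 0 || n_outlier_wells > wells_per_plate) {
    abort("`n_outlier_wells` must be in [0, wells_per_plate].")
  }
  (n_outlier_wells / wells_per_plate) * effect
}

#' Run the plate-normalised width screen
#'
#' The stage-1 screening pipeline: summarise wells, compute each plate's
#' AWP (excluding re-acquisition wells), express every strain's mean width
#' as a percent deviation from its own plate's AWP, and call the
#' `tail_fraction` most extreme strains per tail.
#'
#' @param cells Per-cell tibble (`plate_id`, `well_id`, `width_um`,
#'   optional `strain_id`, `kept`, `minicell`, `length_um`).
#' @param layout Optional plate-layout tibble (`plate_id`, `well_id`,
#'   `strain_id`) joined onto the cells when they carry no strain ids.
#' @param tail_fraction Selection fraction per tail.
#' @param min_cells Re-acquisition threshold.
#' @return An object of class `width_screen`: list with `records` (ranked
#'   strain table with `delta_width_pct`, `tail`, `selected`), `wells`,
#'   `plates`, `reacquire` (wells needing re-acquisition) and `params`.
#'   [generics::tidy()] returns the records, [generics::glance()] a one-row
#'   summary, [ggplot2::autoplot()] the ranked delta-width plot.
#' @export
#' @examples
#' cells <- simulate_screen(
#'   n_strains = 192, cells_per_well = 50,
#'   planted = tibble::tibble(strain_id = "S0001", delta_pct = 15), seed = 1
#' )
#' scr <- screen_strains(cells)
#' head(tidy(scr))
screen_strains <- function(cells, layout = NULL, tail_fraction = 0.005,
                           min_cells = 30L) {
  if (!is.null(layout)) {
    cells <- cells |>
      dplyr::select(-dplyr::any_of("strain_id")) |>
      dplyr::left_join(
        dplyr::select(layout, "plate_id", "well_id", "strain_id"),
        by = c("plate_id", "well_id")
      )
  }
  wells <- summarize_wells(cells, min_cells = min_cells)
  plates <- compute_awp(cells, min_cells = min_cells)
  scored <- wells |>
    dplyr::filter(.data$qc == "ok") |>
    dplyr::left_join(plates, by = "plate_id") |>
    dplyr::mutate(delta_width_pct = delta_width(.data$mean_width, .data$awp)) |>
    dplyr::select(
      "strain_id", "plate_id", "well_id", "n_cells",
      "mean_width", "awp", "delta_width_pct"
    )
  records <- call_hits(scored, tail_fraction = tail_fraction)
  structure(
    list(
      records = records,
      wells = wells,
      plates = plates,
      reacquire = dplyr::filter(wells, .data$qc == "reacquire"),
      params = list(tail_fraction = tail_fraction, min_cells = min_cells)
    ),
    class = "width_screen"
  )
}

#' @export
print.width_screen <- function(x, ...) {
  cat(
    "<width_screen> ", nrow(x$records), " strains on ",
    nrow(x$plates), " plate(s); ", sum(x$records$selected),
    " selected (", 100 * x$params$tail_fraction, "% per tail); ",
    nrow(x$reacquire), " well(s) to re-acquire\n",
    sep = ""
  )
  invisible(x)
}
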