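#' Spherocylinder surface, volume and S/V ratio
#'
#' Models a rod-shaped cell as a cylinder of diameter `w` and total
#' pole-to-pole length `l` capped by two hemispheres:
#' `S = pi * w * l`, `V = pi * w^2 * (3l - w) / 12`, so
#' `S/V = 12 l / (w (3l - w))`. At `l = w` this degenerates to a sphere
#' (`S = pi w^2`, `V = pi w^3 / 6`, `S/V = 6/w`).
#'
#' @param width_um Diameter `w`, micrometres (> 0). Vectorised.
#' @param length_um Pole-to-pole length `l`, micrometres (>= `w`).
#' @return Tibble: `surface_um2`, `volume_um3`, `sv_um_1`.
#' @export
#' @examples
#' spherocylinder_sv(1, 4)
spherocylinder_sv <- function(width_um, length_um) {
  if (any(width_um <= 0)) abort("`width_um` must be > 0.")
  if (any(length_um < width_um - 1e-12)) {
    abort("`length_um` must be >= `width_um` (hemispherical caps would overlap).")
  }
  S <- pi * width_um * length_um
  V <- pi * width_um^2 * (3 * length_um - width_um) / 12
  tibble::tibble(surface_um2 = S, volume_um3 = V, sv_um_1 = S / V)
}

#' Measure one segmented cell
#'
#' Combines the medial axis and width profile into a per-cell record:
#' width is the mean of the pole-excluded profile diameters, length is the
#' axis arc length plus one width (restoring the two hemispherical caps,
#' `w/2` each), and surface/volume descriptors come from
#' [spherocylinder_sv()]. Cells whose profile is entirely pole (spheres and
#' near-spheres) are flagged `minicell` and their width falls back to the
#' maximum profile diameter. A width coefficient of variation above
#' `uneven_cv` flags `uneven_width` (cells whose diameter varies along
#' their own length).
#'
#' @param mask A [segment_image()] result.
#' @param label Component label.
#' @param image Optional intensity image for ridge-refined widths.
#' @param uneven_cv CV threshold for the `uneven_width` flag.
#' @param smooth_window Axis smoothing window, see [extract_medial_axis()].
#' @param ... Passed to [width_profile()].
#' @return One-row tibble: `cell_id`, `width_um`, `width_cv`, `length_um`,
#'   `surface_um2`, `volume_um3`, `sv_um_1`, `area_um2`, `solidity`,
#'   `touches_border`, `minicell`, `uneven_width`, `too_small`, `flags`.
#' @export
measure_cell <- function(mask, label, image = NULL, uneven_cv = 0.12,
                         smooth_window = 5L, ...) {
  px <- mask$pixel_size
  comp <- mask_component(mask, label)
  area_px <- sum(comp)
  idx <- which(comp, arr.ind = TRUE)
  touches <- any(idx[, 1] == 1 | idx[, 1] == nrow(comp) |
    idx[, 2] == 1 | idx[, 2] == ncol(comp))
  sol <- component_solidity(comp)

  row <- tibble::tibble(
    cell_id = label,
    width_um = NA_real_, width_cv = NA_real_, length_um = NA_real_,
    surface_um2 = NA_real_, volume_um3 = NA_real_, sv_um_1 = NA_real_,
    area_um2 = area_px * px^2, solidity = sol, touches_border = touches,
    minicell = FALSE, uneven_width = FALSE, too_small = FALSE,
    flags = ""
  )

  axis <- extract_medial_axis(mask, label, smooth_window = smooth_window)
  if (is.null(axis) && area_px >= 4) {
    ## spheres and near-spheres thin to a point: fall back to a minimal
    ## axis through the centroid so the profile machinery (and its
    ## minicell path) still applies
    ctr <- colMeans(idx) # (row, col), 1-based
    dir <- if (nrow(idx) > 2) {
      eigen(stats::cov(idx[, 2:1]))$vectors[, 1]
    } else {
      c(1, 0)
    }
    pts <- rbind(
      c(ctr[2] - 1, ctr[1] - 1) - 0.5 * dir,
      c(ctr[2] - 1, ctr[1] - 1) + 0.5 * dir
    )
    axis <- structure(
      list(
        points = tibble::tibble(x_um = pts[, 1] * px, y_um = pts[, 2] * px),
        arc_length_um = px,
        label = label
      ),
      class = "medial_axis"
    )
  }
  if (is.null(axis)) {
    row$too_small <- TRUE
    row$flags <- "too_small"
    return(row)
  }
  prof <- width_profile(mask, axis, image = image, ...)
  kept <- prof$diameter_um[prof$retained]
  if (length(kept) == 0) {
    ## entirely within the cap-exclusion zones: spherical / minicell
    row$minicell <- TRUE
    row$width_um <- max(prof$diameter_um, na.rm = TRUE)
    row$length_um <- max(row$width_um, axis$arc_length_um + row$width_um)
  } else {
    row$width_um <- mean(kept)
    row$width_cv <- if (length(kept) > 1) sd(kept) / mean(kept) else 0
    row$length_um <- axis$arc_length_um + row$width_um
    if (!is.na(row$width_cv) && row$width_cv > uneven_cv) {
      row$uneven_width <- TRUE
    }
  }
  if (row$length_um < row$width_um) row$length_um <- row$width_um
  sv <- spherocylinder_sv(row$width_um, row$length_um)
  row$surface_um2 <- sv$surface_um2
  row$volume_um3 <- sv$volume_um3
  row$sv_um_1 <- sv$sv_um_1
  row$flags <- paste(
    c(
      if (row$minicell) "minicell",
      if (row$uneven_width) "uneven_width"
    ),
    collapse = ","
  )
  row
}

#' Segment and measure every cell in an image
#'
#' The main morphometry entry point: segments the image, measures each
#' component, and returns one tidy row per cell. Pass the result to
#' [filter_cells()] to apply the exclusion rules before aggregation.
#'
#' @param image 2-D intensity matrix or a [render_scene()] result (whose
#'   image and optics are then used).
#' @param optics [optics_model()]; ignored when `image` is a rendered scene.
#' @param use_image_refinement Refine widths to the membrane intensity
#'   ridge (recommended; see [width_profile()]).
#' @param ... Passed to [segment_image()] and [measure_cell()].
#' @return Tibble of per-cell measurements (see [measure_cell()]).
#' @export
#' @examples
#' cells <- place_cells(sample_well(2, seed = 5), c(90, 90), 0.115, seed = 5)
#' sc <- render_scene(scene_spec(c(90, 90), cells, 5), optics_dialect("hcs", noise = FALSE))
#' measure_cells(sc)[, c("cell_id", "width_um", "length_um")]
measure_cells <- function(image, optics = NULL, use_image_refinement = TRUE,
                          ...) {
  if (inherits(image, "rendered_scene")) {
    optics <- image$optics
    image <- image$image
  }
  if (is.null(optics)) abort("`optics` must be supplied for a raw image.")
  dots <- list(...)
  seg_args <- dots[names(dots) %in%
    c("smooth_sigma_um", "min_area_um2", "close_radius_px")]
  mc_args <- dots[names(dots) %in%
    c("uneven_cv", "smooth_window", "cap_factor", "step_px",
      "max_halfwidth_um")]
  mask <- do.call(segment_image, c(list(image, optics), seg_args))
  if (mask$n_labels == 0) {
    return(tibble::tibble(
      cell_id = integer(), width_um = double(), width_cv = double(),
      length_um = double(), surface_um2 = double(), volume_um3 = double(),
      sv_um_1 = double(), area_um2 = double(), solidity = double(),
      touches_border = logical(), minicell = logical(),
      uneven_width = logical(), too_small = logical(), flags = character()
    ))
  }
  purrr::map_dfr(seq_len(mask$n_labels), function(lab) {
    do.call(measure_cell, c(
      list(mask, lab, image = if (use_image_refinement) image else NULL),
      mc_args
    ))
  })
}

#' Apply the cell exclusion rules
#'
#' Applies, in order: border-touching exclusion; area range; solidity below
#' `solidity_min` (aggregates of touching cells); and the minicell rule
#' (`length < k_mini * width`). Minicells are *flagged* rather than
#' excluded: they stay available for width statistics (configurable) but
#' are always excluded from length aggregation, since near-spherical
#' minicells have no meaningful rod length. Every exclusion is recorded
#' with its reason; rows are never dropped, so
#' `sum(kept) + sum(!kept) == nrow(measurements)`.
#'
#' @param measurements [measure_cells()] output.
#' @param min_area_um2,max_area_um2 Retained area range.
#' @param solidity_min Minimum solidity; below it a component is judged an
#'   aggregate of touching cells.
#' @param k_mini Minicell rule: `length < k_mini * width`.
#' @param keep_minicell_width Keep minicells in width statistics.
#' @return The measurements with `kept` (logical), `exclude_reason`
#'   (`NA` when kept) and an updated `minicell` column.
#' @export
filter_cells <- function(measurements,
                         min_area_um2 = 0.15, max_area_um2 = 25,
                         solidity_min = 0.7, k_mini = 1.5,
                         keep_minicell_width = TRUE) {
  m <- measurements
  n <- nrow(m)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & m$too_small] <- "too_small"
  reason[is.na(reason) & m$touches_border] <- "border"
  area_bad <- m$area_um2 < min_area_um2 | m$area_um2 > max_area_um2
  reason[is.na(reason) & area_bad] <- "area"
  reason[is.na(reason) & m$solidity < solidity_min] <- "aggregate"
  mini <- m$minicell |
    (!is.na(m$length_um) & !is.na(m$width_um) &
      m$length_um < k_mini * m$width_um)
  if (!keep_minicell_width) reason[is.na(reason) & mini] <- "minicell"
  m$minicell <- mini
  m$exclude_reason <- reason
  m$kept <- is.na(reason)
  m
}
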