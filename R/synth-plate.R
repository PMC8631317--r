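#' Standard 96-well identifiers
#'
#' @param n_wells Number of wells (row-major A01..H12 order for 96).
#' @return Character vector of well ids.
#' @export
well_ids <- function(n_wells = 96L) {
  full <- as.vector(t(outer(LETTERS[1:8], 1:12, function(r, c) {
    sprintf("%s%02d", r, c)
  })))
  if (n_wells <= 96) {
    full[seq_len(n_wells)]
  } else {
    sprintf("W%03d", seq_len(n_wells))
  }
}

#' Specify a screening plate
#'
#' A plate specification maps wells to strains and to the per-well width and
#' length distributions from which cells are drawn, together with any
#' planted width effects (percent changes applied multiplicatively to the
#' well's mean width before sampling) and the seed that makes the plate
#' reproducible. Defaults emulate one plate of an arrayed deletion-library
#' screen: 96 wells, ~200 measurable cells per well, within-well width SD
#' 0.08 um.
#'
#' @param plate_id Plate identifier.
#' @param layout Tibble with columns `well_id`, `strain_id`, `width_mean`,
#'   `width_sd`, `length_mean`, `length_sd`, `n_cells`. If `NULL`, a
#'   uniform default layout of `n_wells` wells is built.
#' @param planted_effects Tibble with columns `strain_id`, `delta_pct`
#'   (percent width change relative to the plate baseline), or `NULL`.
#' @param seed Integer seed.
#' @param n_wells Wells on the default layout.
#' @param width_mean,width_sd,length_mean,length_sd,n_cells Defaults used
#'   when `layout` is `NULL`.
#' @return An object of class `plate_spec`.
#' @export
plate_spec <- function(plate_id = "P01", layout = NULL, planted_effects = NULL,
                       seed = 1L, n_wells = 96L,
                       width_mean = 1.15, width_sd = 0.08,
                       length_mean = 4.0, length_sd = 0.8, n_cells = 200L) {
  if (is.null(layout)) {
    ids <- well_ids(n_wells)
    layout <- tibble::tibble(
      well_id = ids,
      strain_id = paste0(plate_id, "_", ids),
      width_mean = width_mean, width_sd = width_sd,
      length_mean = length_mean, length_sd = length_sd,
      n_cells = as.integer(n_cells)
    )
  }
  need <- c(
    "well_id", "strain_id", "width_mean", "width_sd",
    "length_mean", "length_sd", "n_cells"
  )
  miss <- setdiff(need, names(layout))
  if (length(miss)) abort(paste0("layout lacks columns: ", paste(miss, collapse = ", ")))
  if (any(layout$n_cells < 0)) abort("n_cells must be >= 0.")
  if (any(layout$width_mean <= 0)) abort("width_mean must be positive.")
  if (!is.null(planted_effects)) {
    if (!all(c("strain_id", "delta_pct") %in% names(planted_effects))) {
      abort("planted_effects needs columns strain_id, delta_pct.")
    }
    unknown <- setdiff(planted_effects$strain_id, layout$strain_id)
    if (length(unknown)) {
      abort(paste0(
        "planted_effects refer to strains absent from the layout: ",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      plate_id = plate_id, layout = layout,
      planted_effects = planted_effects, seed = as.integer(seed)
    ),
    class = "plate_spec"
  )
}

apply_planted <- function(layout, planted) {
  if (is.null(planted) || nrow(planted) == 0) {
    return(layout)
  }
  layout |>
    dplyr::left_join(planted, by = "strain_id") |>
    dplyr::mutate(
      width_mean = .data$width_mean * (1 + dplyr::coalesce(.data$delta_pct, 0) / 100)
    ) |>
    dplyr::select(-"delta_pct")
}

#' Generate a plate of cells, with or without images
#'
#' At `"measurement"` fidelity the generator emits the per-cell ground-truth
#' table directly -- the fast path for screening statistics, where the
#' imaging and measurement steps would only add unbiased noise. At
#' `"image"` fidelity each well is additionally rendered as four
#' fields of view (the acquisition pattern of a high-content screen), and
#' the truth table records the field each cell landed in.
#'
#' @param plate A [plate_spec()].
#' @param fidelity `"measurement"` or `"image"`.
#' @param optics [optics_model()] used at image fidelity.
#' @param image_shape Field-of-view shape in pixels (image fidelity).
#' @param fields Fields of view per well (image fidelity).
#' @return A list of class `generated_plate`: `cells` (tibble with
#'   `plate_id`, `well_id`, `strain_id`, per-cell true `width_um`,
#'   `length_um`, `shape_class`, and `field` at image fidelity) and
#'   `images` (named list of matrices, `NULL` at measurement fidelity).
#' @export
#' @examples
#' pl <- plate_spec("P01", n_wells = 4, n_cells = 50, seed = 1)
#' gp <- generate_plate(pl, "measurement")
#' dplyr::count(gp$cells, well_id)
generate_plate <- function(plate, fidelity = c("measurement", "image"),
                           optics = optics_dialect("hcs"),
                           image_shape = c(220, 220), fields = 4L) {
  stopifnot(inherits(plate, "plate_spec"))
  fidelity <- match.arg(fidelity)
  layout <- apply_planted(plate$layout, plate$planted_effects)

  well_cells <- purrr::pmap(layout, function(well_id, strain_id, width_mean,
                                             width_sd, length_mean, length_sd,
                                             n_cells, ...) {
    cells <- sample_well(
      n_cells = n_cells, width_mean = width_mean, width_sd = width_sd,
      length_mean = length_mean, length_sd = length_sd,
      seed = derive_seed(plate$seed, plate$plate_id, well_id),
      strain_id = strain_id
    )
    cells$well_id <- well_id
    cells
  })
  cells <- dplyr::bind_rows(well_cells)
  if (nrow(cells)) cells$plate_id <- plate$plate_id

  images <- NULL
  if (fidelity == "image" && nrow(cells)) {
    images <- list()
    out <- vector("list", length(well_cells))
    for (wi in seq_along(well_cells)) {
      wc <- well_cells[[wi]]
      if (nrow(wc) == 0) {
        out[[wi]] <- wc
        next
      }
      wid <- wc$well_id[1]
      wc$field <- rep_len(seq_len(fields), nrow(wc))
      split_fields <- split(wc, wc$field)
      for (fk in names(split_fields)) {
        fc <- split_fields[[fk]]
        fseed <- derive_seed(plate$seed, plate$plate_id, wid, fk)
        fc <- place_cells(fc, image_shape, optics$pixel_size, seed = fseed)
        sc <- render_scene(
          scene_spec(image_shape, fc, seed = fseed), optics
        )
        images[[sprintf("%s_%s_f%s", plate$plate_id, wid, fk)]] <- sc$image
        split_fields[[fk]] <- fc
      }
      out[[wi]] <- dplyr::bind_rows(split_fields)
    }
    cells <- dplyr::bind_rows(out)
    cells$plate_id <- plate$plate_id
  }

  keep <- intersect(
    c(
      "plate_id", "well_id", "strain_id", "field", "width_um", "length_um",
      "shape_class", "center_x", "center_y", "orientation"
    ),
    names(cells)
  )
  structure(
    list(cells = cells[keep], images = images, plate = plate),
    class = "generated_plate"
  )
}

#' Simulate a whole multi-plate screen at measurement fidelity
#'
#' Fast vectorised generator for screen-level statistics: `n_strains`
#' strains are arrayed across plates (filling each plate up to
#' `wells_per_plate` wells), every well contributes `cells_per_well`
#' measured cells, and per-plate baselines drift by `plate_jitter_pct`
#' (SD, percent) around `width_mean` -- the plate-to-plate variation that
#' motivates normalising each strain against its own plate's average width.
#' Strains listed in `planted` get their width mean shifted by `delta_pct`
#' percent; all strains are assigned to plates by a seeded shuffle so
#' planted hits scatter across plates.
#'
#' @param n_strains Number of strains.
#' @param wells_per_plate Wells used per plate.
#' @param cells_per_well Measured cells per strain.
#' @param width_mean Screen-wide baseline mean width, um.
#' @param width_sd Within-well cell-to-cell SD, um.
#' @param plate_jitter_pct SD of the per-plate baseline, percent.
#' @param planted Tibble (`strain_id`, `delta_pct`) of planted effects; the
#'   default `NULL` plants none. Strain ids are `S0001`, `S0002`, ...
#' @param seed Integer root seed.
#' @return A tibble of per-cell records: `plate_id`, `well_id`, `strain_id`,
#'   `width_um`, plus the true per-strain effect `delta_true_pct`.
#' @export
#' @examples
#' scr <- simulate_screen(n_strains = 192, cells_per_well = 50, seed = 1)
#' dplyr::n_distinct(scr$plate_id)
simulate_screen <- function(n_strains = 3983L, wells_per_plate = 96L,
                            cells_per_well = 200L,
                            width_mean = 1.15, width_sd = 0.08,
                            plate_jitter_pct = 1,
                            planted = NULL, seed = 1L) {
  strains <- sprintf("S%04d", seq_len(n_strains))
  delta <- setNames(rep(0, n_strains), strains)
  if (!is.null(planted) && nrow(planted)) {
    if (!all(planted$strain_id %in% strains)) {
      abort("planted strain ids must be among S0001..S<n_strains>.")
    }
    delta[planted$strain_id] <- planted$delta_pct
  }
  order_idx <- with_seed(derive_seed(seed, "array"), sample(n_strains))
  strains <- strains[order_idx]
  n_plates <- ceiling(n_strains / wells_per_plate)
  plate_of <- rep(seq_len(n_plates), each = wells_per_plate)[seq_len(n_strains)]
  well_of <- well_ids(wells_per_plate)[
    (seq_len(n_strains) - 1L) %% wells_per_plate + 1L
  ]
  plate_base <- with_seed(
    derive_seed(seed, "plate-baseline"),
    width_mean * (1 + rnorm(n_plates, 0, plate_jitter_pct / 100))
  )

  per_plate <- lapply(seq_len(n_plates), function(p) {
    idx <- which(plate_of == p)
    means <- plate_base[p] * (1 + delta[strains[idx]] / 100)
    w <- with_seed(
      derive_seed(seed, "cells", p),
      rnorm(length(idx) * cells_per_well,
        mean = rep(means, each = cells_per_well), sd = width_sd
      )
    )
    tibble::tibble(
      plate_id = sprintf("P%02d", p),
      well_id = rep(well_of[idx], each = cells_per_well),
      strain_id = rep(strains[idx], each = cells_per_well),
      width_um = pmax(w, 0.2),
      delta_true_pct = rep(unname(delta[strains[idx]]), each = cells_per_well)
    )
  })
  dplyr::bind_rows(per_plate)
}
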