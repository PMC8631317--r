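#' Construct a table of cell specifications
#'
#' A cell specification fixes the true geometry of one simulated cell: its
#' centre and orientation in the field, its true diameter (`width_um`) and
#' pole-to-pole length (`length_um`), its shape class, and rendering
#' parameters (membrane intensity, number of fixation-induced membrane
#' foci). For `"tapered"` cells the diameter varies linearly along the cell
#' from `taper_w0_um` at one pole to `taper_w1_um` at the other, and
#' `width_um` is their mean.
#'
#' @param center_x,center_y Cell centre, micrometres.
#' @param orientation Long-axis angle, radians.
#' @param width_um True diameter, micrometres (> 0).
#' @param length_um True pole-to-pole length, micrometres (>= width: a cell
#'   is at least a sphere).
#' @param shape_class One of `"straight"`, `"tapered"`, `"minicell"`,
#'   `"chain_member"`.
#' @param taper_w0_um,taper_w1_um End diameters for tapered cells (both > 0);
#'   `NA` otherwise.
#' @param membrane_intensity Membrane band intensity, ADU.
#' @param focus_count Number of bright membrane puncta (fixation artifacts).
#' @return A tibble with one row per cell, class `cell_spec` columns.
#' @export
#' @examples
#' cell_spec(width_um = 1, length_um = 4)
cell_spec <- function(center_x = 0, center_y = 0, orientation = 0,
                      width_um = 1, length_um = 4,
                      shape_class = "straight",
                      taper_w0_um = NA_real_, taper_w1_um = NA_real_,
                      membrane_intensity = 3000, focus_count = 0L) {
  cells <- tibble::tibble(
    center_x = as.double(center_x),
    center_y = as.double(center_y),
    orientation = as.double(orientation),
    width_um = as.double(width_um),
    length_um = as.double(length_um),
    shape_class = as.character(shape_class),
    taper_w0_um = as.double(taper_w0_um),
    taper_w1_um = as.double(taper_w1_um),
    membrane_intensity = as.double(membrane_intensity),
    focus_count = as.integer(focus_count)
  )
  validate_cells(cells)
  cells
}

validate_cells <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c(
    "center_x", "center_y", "orientation", "width_um", "length_um",
    "shape_class"
  )
  missing <- setdiff(need, names(cells))
  if (length(missing)) {
    abort(paste0("cell table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(cells) == 0) {
    return(invisible(cells))
  }
  if (any(cells$width_um <= 0)) abort("all cell widths must be > 0.")
  if (any(cells$length_um < cells$width_um - 1e-12)) {
    abort("cell length must be >= width (a cell is at least a sphere).")
  }
  bad <- !cells$shape_class %in%
    c("straight", "tapered", "minicell", "chain_member")
  if (any(bad)) abort("unknown shape_class.")
  tp <- cells$shape_class == "tapered"
  if (any(tp)) {
    w0 <- cells$taper_w0_um[tp]
    w1 <- cells$taper_w1_um[tp]
    if (anyNA(w0) || anyNA(w1) || any(w0 <= 0) || any(w1 <= 0)) {
      abort("tapered cells need positive taper_w0_um and taper_w1_um.")
    }
  }
  invisible(cells)
}

#' Sample a well's cell population
#'
#' Draws `n_cells` cell specifications for one well. Widths are
#' `Normal(width_mean, width_sd)` truncated below at 0.2 um; lengths are
#' `Normal(length_mean, length_sd)` truncated below at each cell's width.
#' The defaults reproduce the population structure of an exponentially
#' growing wild-type population measured on a high-content microscope:
#' mean width near 1.15 um with a cell-to-cell SD in the 0.07-0.09 um
#' range, about 225 measurable cells per well.
#'
#' @param n_cells Number of cells (>= 0).
#' @param width_mean,width_sd Width distribution, micrometres.
#' @param length_mean,length_sd Length distribution, micrometres.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param strain_id Optional strain label attached to each row.
#' @param minicell_frac,tapered_frac,chain_frac Fractions of cells rendered
#'   as minicells (near-spherical), tapered cells (linearly varying width,
#'   end diameters drawn between 0.7x and 1.4x the nominal width) and chain
#'   members. The remainder are straight rods.
#' @param focus_rate Mean number of fixation foci per cell (Poisson).
#' @return A tibble of cell specifications (plus `strain_id` if given).
#' @export
#' @examples
#' w <- sample_well(n_cells = 225, width_mean = 1.15, width_sd = 0.08, seed = 1)
#' mean(w$width_um)
sample_well <- function(n_cells = 225,
                        width_mean = 1.15, width_sd = 0.08,
                        length_mean = 4.0, length_sd = 0.8,
                        seed = 1L,
                        strain_id = NULL,
                        minicell_frac = 0, tapered_frac = 0, chain_frac = 0,
                        focus_rate = 0) {
  if (n_cells < 0) abort("`n_cells` must be >= 0.")
  if (width_mean <= 0 || length_mean <= 0) {
    abort("distribution means must be positive.")
  }
  if (width_sd < 0 || length_sd < 0) abort("SDs must be >= 0.")
  if (n_cells == 0) {
    return(cell_spec(
      center_x = double(), center_y = double(), orientation = double(),
      width_um = double(), length_um = double(), shape_class = character(),
      membrane_intensity = double(), focus_count = integer()
    ))
  }
  cells <- with_seed(seed, {
    w <- pmax(rnorm(n_cells, width_mean, width_sd), 0.2)
    l <- pmax(rnorm(n_cells, length_mean, length_sd), w)
    cls <- rep("straight", n_cells)
    u <- stats::runif(n_cells)
    cls[u < chain_frac + tapered_frac + minicell_frac] <- "chain_member"
    cls[u < tapered_frac + minicell_frac] <- "tapered"
    cls[u < minicell_frac] <- "minicell"
    mini <- cls == "minicell"
    if (any(mini)) {
      w[mini] <- pmax(0.45 + rnorm(sum(mini), 0, 0.05), 0.25)
      l[mini] <- w[mini] * stats::runif(sum(mini), 1.0, 1.3)
    }
    t0 <- t1 <- rep(NA_real_, n_cells)
    tp <- cls == "tapered"
    if (any(tp)) {
      t0[tp] <- w[tp] * stats::runif(sum(tp), 0.7, 1.0)
      t1[tp] <- w[tp] * stats::runif(sum(tp), 1.0, 1.4)
      w[tp] <- (t0[tp] + t1[tp]) / 2
    }
    foci <- if (focus_rate > 0) stats::rpois(n_cells, focus_rate) else 0L
    cell_spec(
      center_x = 0, center_y = 0,
      orientation = stats::runif(n_cells, 0, pi),
      width_um = w, length_um = l, shape_class = cls,
      taper_w0_um = t0, taper_w1_um = t1,
      membrane_intensity = 3000, focus_count = foci
    )
  })
  if (!is.null(strain_id)) cells$strain_id <- strain_id
  cells
}
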