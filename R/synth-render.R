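#' Assemble a scene for rendering
#'
#' A scene fixes everything the renderer needs: the image shape in pixels,
#' the table of cell specifications (with centres already placed, see
#' [place_cells()]), and the seed that makes the rendered image bit-for-bit
#' reproducible.
#'
#' @param image_shape Integer `(rows, cols)` of the field, pixels.
#' @param cells Cell table as produced by [cell_spec()] / [sample_well()],
#'   with centres in micrometres.
#' @param seed Integer seed controlling every stochastic element of the
#'   render (noise, focus placement).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(image_shape, cells, seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 1))
  validate_cells(cells)
  structure(
    list(
      image_shape = as.integer(image_shape),
      cells = cells,
      seed = as.integer(seed)
    ),
    class = "scene_spec"
  )
}

## Minimum distance between two 2-D segments (a1-b1, a2-b2).
segment_distance <- function(a1, b1, a2, b2) {
  pt_seg <- function(p, a, b) {
    v <- b - a
    L2 <- sum(v^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * v) / L2))
    sqrt(sum((p - (a + t * v))^2))
  }
  ## sample-based lower bound is enough at cell scale: endpoints vs segments
  ## plus midpoints (segments here are short and never near-parallel-crossing
  ## after placement rejection).
  cand <- c(
    pt_seg(a1, a2, b2), pt_seg(b1, a2, b2),
    pt_seg(a2, a1, b1), pt_seg(b2, a1, b1),
    pt_seg((a1 + b1) / 2, a2, b2), pt_seg((a2 + b2) / 2, a1, b1)
  )
  min(cand)
}

cell_axis_endpoints <- function(cell) {
  u <- c(cos(cell$orientation), sin(cell$orientation))
  ctr <- c(cell$center_x, cell$center_y)
  if (identical(cell$shape_class, "tapered")) {
    r0 <- cell$taper_w0_um / 2
    r1 <- cell$taper_w1_um / 2
  } else {
    r0 <- r1 <- cell$width_um / 2
  }
  list(
    a = ctr - (cell$length_um / 2 - r0) * u,
    b = ctr + (cell$length_um / 2 - r1) * u,
    r0 = r0, r1 = r1
  )
}

#' Place cells in a field without overlap
#'
#' Assigns centres and orientations to a cell table by rejection sampling so
#' that no two cell bodies overlap and each cell (including its caps) lies
#' inside the field. Consecutive runs of `"chain_member"` cells (up to
#' `chain_run`) are placed collinearly, touching pole-to-pole, emulating the
#' unseparated chains produced by fixation.
#'
#' @param cells Cell table ([sample_well()] output).
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size Micrometres per pixel.
#' @param seed Integer seed.
#' @param margin_um Extra clearance kept between cells, micrometres.
#' @param max_tries Placement attempts per cell before giving up.
#' @param chain_run Maximum cells per rendered chain.
#' @return The cell table with `center_x`, `center_y`, `orientation` filled.
#' @export
place_cells <- function(cells, image_shape, pixel_size, seed = 1L,
                        margin_um = 0.8, max_tries = 200L, chain_run = 3L) {
  validate_cells(cells)
  n <- nrow(cells)
  if (n == 0) {
    return(cells)
  }
  fw <- (image_shape[2] - 1) * pixel_size # x extent, um
  fh <- (image_shape[1] - 1) * pixel_size # y extent, um
  placed <- list()
  with_seed(derive_seed(seed, "place"), {
    i <- 1L
    while (i <= n) {
      run <- 1L
      if (cells$shape_class[i] == "chain_member") {
        while (run < chain_run && i + run <= n &&
          cells$shape_class[i + run] == "chain_member") {
          run <- run + 1L
        }
      }
      idx <- i:(i + run - 1L)
      total_l <- sum(cells$length_um[idx])
      half <- total_l / 2 + max(cells$width_um[idx]) / 2
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        th <- stats::runif(1, 0, pi)
        u <- c(cos(th), sin(th))
        cx <- stats::runif(1, half, max(fw - half, half))
        cy <- stats::runif(1, half, max(fh - half, half))
        ## centres of run members along u, touching pole-to-pole
        offs <- cumsum(cells$length_um[idx]) - cells$length_um[idx] / 2 -
          total_l / 2
        cand <- lapply(seq_along(idx), function(k) {
          cc <- cells[idx[k], ]
          cc$center_x <- cx + offs[k] * u[1]
          cc$center_y <- cy + offs[k] * u[2]
          cc$orientation <- th
          cc
        })
        clash <- FALSE
        for (cc in cand) {
          e1 <- cell_axis_endpoints(as.list(cc))
          for (pp in placed) {
            dmin <- segment_distance(e1$a, e1$b, pp$a, pp$b)
            if (dmin < max(e1$r0, e1$r1) + pp$r + margin_um) {
              clash <- TRUE
              break
            }
          }
          if (clash) break
        }
        if (!clash) {
          for (k in seq_along(idx)) {
            cells[idx[k], c("center_x", "center_y", "orientation")] <-
              cand[[k]][, c("center_x", "center_y", "orientation")]
          }
          for (cc in cand) {
            e1 <- cell_axis_endpoints(as.list(cc))
            placed[[length(placed) + 1L]] <-
              list(a = e1$a, b = e1$b, r = max(e1$r0, e1$r1))
          }
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place cell %d without overlap after %d tries; use a larger field or fewer cells.",
          i, max_tries
        ))
      }
      i <- i + run
    }
  })
  cells
}

block_downsample <- function(m, s) {
  if (s == 1L) {
    return(m)
  }
  nr <- nrow(m) / s
  nc <- ncol(m) / s
  dim(m) <- c(s, nr, s, nc)
  m1 <- colSums(m) # (nr, s, nc)
  m2 <- colSums(aperm(m1, c(2, 1, 3))) # (nr, nc)
  m2 / s^2
}

gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) {
    return(m)
  }
  as.matrix(EBImage::gblur(m, sigma = sigma_px))
}

#' Render a membrane-stained scene
#'
#' Draws every cell as a uniform-intensity fluorescent band of thickness
#' `band_px` pixels centred on the projected outline of its (possibly
#' tapered) spherocylinder, adds fixation foci, convolves with the optics'
#' Gaussian PSF, then adds background, Gaussian-approximated shot noise and
#' read noise, and quantises to the camera bit depth. Geometry is evaluated
#' on a `supersample`-times finer grid so the thin band is anti-aliased.
#' Identical `(scene, optics)` inputs reproduce the image bit-exactly.
#'
#' @param scene A [scene_spec()].
#' @param optics An [optics_model()].
#' @param band_px Membrane band thickness before blurring, pixels.
#' @param supersample Sub-pixel sampling factor for geometry evaluation.
#' @param max_overlap Maximum tolerated pairwise overlap fraction
#'   (penetration depth relative to the sum of cell radii); scenes beyond it
#'   are rejected with a diagnostic.
#' @return A list of class `rendered_scene`: `image` (numeric matrix, ADU),
#'   `truth` (tibble of per-cell ground truth: true width/length, shape
#'   class, centre in pixels), `optics`, `scene`.
#' @export
#' @examples
#' cells <- place_cells(sample_well(3, seed = 2), c(80, 80), 0.115, seed = 2)
#' sc <- render_scene(scene_spec(c(80, 80), cells, seed = 2),
#'   optics_dialect("hcs", noise = FALSE)
#' )
#' dim(sc$image)
render_scene <- function(scene, optics, band_px = 1, supersample = 4L,
                         max_overlap = 0.2) {
  stopifnot(inherits(scene, "scene_spec"), inherits(optics, "optics_model"))
  nr <- scene$image_shape[1]
  nc <- scene$image_shape[2]
  if (nr < 1 || nc < 1) abort("zero-area image.")
  px <- optics$pixel_size
  cells <- scene$cells
  n <- nrow(cells)
  ## centres must lie inside the field
  if (n > 0) {
    if (any(cells$center_x < 0 | cells$center_x > (nc - 1) * px |
      cells$center_y < 0 | cells$center_y > (nr - 1) * px)) {
      abort("cell centre outside the field; use place_cells() or a larger field.")
    }
    ## overlap rejection on core segments
    ends <- lapply(seq_len(n), function(i) cell_axis_endpoints(as.list(cells[i, ])))
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          d <- segment_distance(
            ends[[i]]$a, ends[[i]]$b,
            ends[[j]]$a, ends[[j]]$b
          )
          rsum <- max(ends[[i]]$r0, ends[[i]]$r1) +
            max(ends[[j]]$r0, ends[[j]]$r1)
          if (d < rsum) {
            frac <- (rsum - d) / rsum
            if (frac > max_overlap) {
              abort(sprintf(
                "cells %d and %d overlap by %.0f%% of their summed radii (max_overlap = %.0f%%); scene rejected.",
                i, j, 100 * frac, 100 * max_overlap
              ))
            }
          }
        }
      }
    }
  }

  s <- as.integer(supersample)
  band_um <- band_px * px
  sub_px <- px / s
  hi <- matrix(0, nr * s, nc * s)
  ## sub-pixel centre coordinates in um: sub-pixel k (0-based) of pixel j sits
  ## at (j + (k + 0.5)/s - 0.5) * px
  coord_of <- function(idx0) (floor(idx0 / s) + ((idx0 %% s) + 0.5) / s - 0.5) * px

  focus_sigma <- 0.08 # um; sub-diffraction punctum before PSF
  for (i in seq_len(n)) {
    cc <- as.list(cells[i, ])
    e <- cell_axis_endpoints(cc)
    rmax <- max(e$r0, e$r1)
    pad <- rmax + band_um + 2 * focus_sigma
    x0 <- max(0L, floor((min(e$a[1], e$b[1]) - pad) / sub_px))
    x1 <- min(nc * s - 1L, ceiling((max(e$a[1], e$b[1]) + pad) / sub_px))
    y0 <- max(0L, floor((min(e$a[2], e$b[2]) - pad) / sub_px))
    y1 <- min(nr * s - 1L, ceiling((max(e$a[2], e$b[2]) + pad) / sub_px))
    if (x1 < x0 || y1 < y0) next
    xs <- coord_of(x0:x1)
    ys <- coord_of(y0:y1)
    X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    Y <- matrix(ys, length(ys), length(xs))
    v <- e$b - e$a
    L2 <- sum(v^2)
    if (L2 == 0) {
      tt <- 0
      D <- sqrt((X - e$a[1])^2 + (Y - e$a[2])^2)
      rad <- e$r0
    } else {
      tt <- ((X - e$a[1]) * v[1] + (Y - e$a[2]) * v[2]) / L2
      tt <- pmin(pmax(tt, 0), 1)
      D <- sqrt((X - (e$a[1] + tt * v[1]))^2 + (Y - (e$a[2] + tt * v[2]))^2)
      rad <- e$r0 + (e$r1 - e$r0) * tt
    }
    shell <- abs(D - rad) <= band_um / 2
    patch <- cc$membrane_intensity * shell
    nf <- cc$focus_count %||% 0L
    if (!is.na(nf) && nf > 0) {
      pos <- with_seed(derive_seed(scene$seed, "focus", i), {
        tf <- stats::runif(nf)
        side <- sample(c(-1, 1), nf, replace = TRUE)
        list(t = tf, side = side)
      })
      nhat <- if (L2 == 0) c(0, 1) else c(-v[2], v[1]) / sqrt(L2)
      for (k in seq_len(nf)) {
        rk <- e$r0 + (e$r1 - e$r0) * pos$t[k]
        fp <- e$a + pos$t[k] * v + pos$side[k] * rk * nhat
        R2 <- (X - fp[1])^2 + (Y - fp[2])^2
        patch <- patch + 1.5 * cc$membrane_intensity *
          exp(-R2 / (2 * focus_sigma^2))
      }
    }
    hi[(y0:y1) + 1L, (x0:x1) + 1L] <-
      hi[(y0:y1) + 1L, (x0:x1) + 1L] + patch
  }

  hi <- gaussian_blur(hi, optics$psf_sigma / sub_px)
  img <- block_downsample(hi, s) + optics$background

  if (is.finite(optics$photon_scale) || optics$read_noise_sd > 0) {
    img <- with_seed(derive_seed(scene$seed, "noise"), {
      out <- img
      if (is.finite(optics$photon_scale)) {
        out <- out + rnorm(length(out), 0, sqrt(pmax(out, 0) / optics$photon_scale))
      }
      if (optics$read_noise_sd > 0) {
        out <- out + rnorm(length(out), 0, optics$read_noise_sd)
      }
      out
    })
    img <- matrix(img, nr, nc)
    img <- round(pmin(pmax(img, 0), 2^optics$bit_depth - 1))
  } else {
    img <- pmin(pmax(img, 0), 2^optics$bit_depth - 1)
  }

  truth <- tibble::tibble(
    cell_id = seq_len(n),
    width_true_um = cells$width_um[seq_len(n)],
    length_true_um = cells$length_um[seq_len(n)],
    shape_class = cells$shape_class[seq_len(n)],
    center_x_px = cells$center_x[seq_len(n)] / px,
    center_y_px = cells$center_y[seq_len(n)] / px,
    orientation = cells$orientation[seq_len(n)]
  )
  if (n == 0) truth <- truth[0, ]
  if ("strain_id" %in% names(cells)) truth$strain_id <- cells$strain_id

  structure(
    list(image = img, truth = truth, optics = optics, scene = scene),
    class = "rendered_scene"
  )
}

#' @export
print.rendered_scene <- function(x, ...) {
  cat(
    "<rendered_scene> ", nrow(x$image), "x", ncol(x$image), " px, ",
    nrow(x$truth), " cells\n",
    sep = ""
  )
  invisible(x)
}
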