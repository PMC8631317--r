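# Fixtures built in code: single-cell renders, curved-tube masks, and
# measurement-level screen tables used across the test files.

# Render one centred cell and return the rendered scene.
render_single_cell <- function(width_um = 1.0, length_um = 4.0,
                               orientation = 0, dialect = "epi",
                               shape_class = "straight",
                               taper_w0_um = NA, taper_w1_um = NA,
                               noise = FALSE, seed = 1L,
                               shape_px = NULL) {
  optics <- optics_dialect(dialect, noise = noise)
  if (is.null(shape_px)) {
    side <- ceiling((length_um + 4.0) / optics$pixel_size)
    shape_px <- c(side, side)
  }
  ctr <- (shape_px[2] - 1) / 2 * optics$pixel_size
  cells <- cell_spec(
    center_x = ctr, center_y = (shape_px[1] - 1) / 2 * optics$pixel_size,
    orientation = orientation, width_um = width_um, length_um = length_um,
    shape_class = shape_class, taper_w0_um = taper_w0_um,
    taper_w1_um = taper_w1_um
  )
  render_scene(scene_spec(shape_px, cells, seed = seed), optics)
}

# Binary mask of a curved tube: points within `tube_r` px of a circular arc
# of radius `R` px spanning [a0, a1]; returned as a labeled_mask with
# pixel_size 1 so lengths read in pixels.
curved_tube_mask <- function(R = 45, tube_r = 6, a0 = 10 * pi / 180,
                             a1 = 80 * pi / 180, dim_px = c(100, 100),
                             center = c(8, 8)) {
  nr <- dim_px[1]
  nc <- dim_px[2]
  tt <- seq(a0, a1, length.out = 400)
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  D2 <- matrix(Inf, nr, nc)
  for (k in seq_along(tt)) {
    D2 <- pmin(D2, (X - center[1] - R * cos(tt[k]))^2 +
      (Y - center[2] - R * sin(tt[k]))^2)
  }
  structure(
    list(
      labels = matrix(as.integer(sqrt(D2) <= tube_r), nr, nc),
      n_labels = 1L, pixel_size = 1
    ),
    class = "labeled_mask"
  )
}

# Per-cell verification table: `n_rep` replicates of `n_cells` widths for a
# wild type plus one candidate shifted by `delta_pct`.
make_verification_cells <- function(delta_pct, n_rep = 3, n_cells = 250,
                                    wt_mean = 0.96, sd = 0.08, seed = 1,
                                    uneven_frac = 0,
                                    strain = "MUT") {
  rows <- list()
  for (r in seq_len(n_rep)) {
    set.seed(seed * 1000 + r)
    wt <- rnorm(n_cells, wt_mean, sd)
    mu <- rnorm(n_cells, wt_mean * (1 + delta_pct / 100), sd)
    rows[[length(rows) + 1]] <- tibble::tibble(
      strain_id = "WT", replicate = r, width_um = wt, uneven_width = FALSE
    )
    rows[[length(rows) + 1]] <- tibble::tibble(
      strain_id = strain, replicate = r, width_um = mu,
      uneven_width = seq_len(n_cells) <= round(uneven_frac * n_cells)
    )
  }
  dplyr::bind_rows(rows)
}

# Independent Mann-Whitney oracle: full enumeration of all C(m+n, m)
# group labelings; two-sided p as twice the smaller tail (capped at 1),
# matching the exact convention of stats::wilcox.test.
mw_enumeration <- function(a, b) {
  m <- length(a)
  n <- length(b)
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - m * (m + 1) / 2
  })
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Independent capsule surface/volume oracle by numerical integration of the
# solid of revolution: caps integrated in angle, cylinder in x.
capsule_sv_numeric <- function(w, l) {
  r <- w / 2
  cyl <- l - w
  s_cap <- stats::integrate(
    function(th) 2 * pi * r * cos(th) * r,
    0, pi / 2,
    rel.tol = 1e-10
  )$value
  surface <- 2 * s_cap + 2 * pi * r * cyl
  v_cap <- stats::integrate(
    function(x) pi * (r^2 - x^2),
    0, r,
    rel.tol = 1e-10
  )$value
  volume <- 2 * v_cap + pi * r^2 * cyl
  c(surface = surface, volume = volume, sv = surface / volume)
}
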