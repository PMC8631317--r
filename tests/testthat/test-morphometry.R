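test_that("segmentation finds separated cells and tolerates blank images", {
  cells <- place_cells(sample_well(5, seed = 3), c(160, 160), 0.115, seed = 3)
  sc <- render_scene(scene_spec(c(160, 160), cells, 3), optics_dialect("hcs"))
  mask <- segment_image(sc$image, sc$optics)
  expect_equal(mask$n_labels, 5)

  blank <- segment_image(matrix(0, 50, 50), optics_dialect("hcs"))
  expect_equal(blank$n_labels, 0)
  expect_error(segment_image(array(0, c(4, 4, 2)), optics_dialect("hcs")), "matrix")
})

test_that("width is recovered within one pixel in both dialects", {
  for (d in c("hcs", "epi")) {
    optics <- optics_dialect(d, noise = FALSE)
    for (ang in c(0, pi / 6, pi / 4, pi / 2)) {
      sc <- render_single_cell(1.0, 4.0, orientation = ang, dialect = d)
      m <- measure_cells(sc)
      expect_lt(abs(m$width_um - 1.0), optics$pixel_size)
      # length accuracy: one pixel on the research scope; the pixelated
      # high-content images carry a little more pole uncertainty
      tol_l <- if (d == "epi") optics$pixel_size else 0.2
      expect_lt(abs(m$length_um - 4.0), tol_l)
    }
  }
})

test_that("measured width is rotation invariant to half a pixel", {
  widths <- vapply(c(0, pi / 6, pi / 4, pi / 2), function(ang) {
    measure_cells(render_single_cell(1.0, 4.0, orientation = ang,
      dialect = "epi"))$width_um
  }, 0)
  expect_lt(diff(range(widths)), 0.5 * 0.065)
})

test_that("the medial axis of a straight rod approximates length minus width", {
  sc <- render_single_cell(1.0, 4.0, orientation = pi / 6, dialect = "epi")
  mask <- segment_image(sc$image, sc$optics)
  ax <- extract_medial_axis(mask, 1)
  expect_lt(abs(ax$arc_length_um - 3.0), 0.065)
  # points ordered pole to pole along the principal axis
  proj <- ax$points$x_um * cos(pi / 6) + ax$points$y_um * sin(pi / 6)
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
})

test_that("the medial axis follows a curved cell's centreline", {
  mask <- curved_tube_mask(R = 45, tube_r = 6)
  ax <- extract_medial_axis(mask, 1)
  true_arc <- 45 * (80 - 10) * pi / 180
  expect_lt(abs(ax$arc_length_um - true_arc) / true_arc, 0.02)
})

test_that("spheres degenerate to minicell candidates", {
  sc <- render_single_cell(0.5, 0.55, dialect = "epi",
    shape_class = "minicell", shape_px = c(80, 80))
  m <- measure_cells(sc)
  expect_true(m$minicell)
  expect_gte(m$length_um, m$width_um)
  expect_lt(abs(m$width_um - 0.5), 2 * 0.065)
})

test_that("tapered cells show a wide profile and an uneven-width flag", {
  sc <- render_single_cell(1.05, 4.5, orientation = pi / 6, dialect = "epi",
    shape_class = "tapered", taper_w0_um = 0.7, taper_w1_um = 1.4)
  mask <- segment_image(sc$image, sc$optics)
  ax <- extract_medial_axis(mask, 1)
  prof <- width_profile(mask, ax, image = sc$image)
  kept <- prof$diameter_um[prof$retained]
  expect_lt(min(kept), 0.9)
  expect_gt(max(kept), 1.2)
  m <- measure_cells(sc)
  expect_gt(m$width_cv, 0.12)
  expect_true(m$uneven_width)
})

test_that("cap exclusion removes pole points and drives the minicell path", {
  sc <- render_single_cell(1.0, 4.0, dialect = "epi")
  mask <- segment_image(sc$image, sc$optics)
  ax <- extract_medial_axis(mask, 1)
  prof <- width_profile(mask, ax, image = sc$image)
  d_cap <- 0.5 * median(prof$diameter_um, na.rm = TRUE)
  expect_true(all(!prof$retained[prof$arc_pos_um < d_cap]))
  expect_true(any(prof$retained))
})

test_that("spherocylinder geometry matches its closed form and limits", {
  sphere <- spherocylinder_sv(1, 1)
  expect_equal(sphere$surface_um2, pi)
  expect_equal(sphere$volume_um3, pi / 6)
  expect_equal(sphere$sv_um_1, 6)

  rod <- spherocylinder_sv(1, 4)
  expect_equal(rod$surface_um2, 4 * pi, tolerance = 1e-12)
  expect_equal(rod$volume_um3, pi * 11 / 12, tolerance = 1e-12)
  expect_equal(rod$sv_um_1, 48 / 11, tolerance = 1e-12)

  a <- spherocylinder_sv(0.9, 3.7)
  b <- spherocylinder_sv(1.8, 7.4)
  expect_equal(b$sv_um_1, a$sv_um_1 / 2, tolerance = 1e-12)

  expect_error(spherocylinder_sv(1, 0.8), "caps")
  expect_error(spherocylinder_sv(0, 1))
})

test_that("spherocylinder S and V agree with numerical capsule integration", {
  set.seed(42)
  for (i in 1:100) {
    w <- runif(1, 0.4, 2)
    l <- w + runif(1, 0, 5)
    num <- capsule_sv_numeric(w, l)
    cf <- spherocylinder_sv(w, l)
    expect_lt(abs(cf$surface_um2 - num["surface"]) / num["surface"], 1e-6)
    expect_lt(abs(cf$volume_um3 - num["volume"]) / num["volume"], 1e-6)
  }
})

test_that("profile-maxima width matches the shell diameter and is symmetric", {
  sc <- render_single_cell(1.0, 4.0, dialect = "epi")
  optics <- sc$optics
  ctr <- (nrow(sc$image) - 1) / 2 * optics$pixel_size
  p0 <- c(ctr, ctr - 1.2)
  p1 <- c(ctr, ctr + 1.2)
  w1 <- profile_maxima_width(sc$image, p0, p1, optics$pixel_size)
  expect_lt(abs(w1 - 1.0), optics$pixel_size)
  expect_equal(profile_maxima_width(sc$image, p1, p0, optics$pixel_size), w1)
  expect_error(
    profile_maxima_width(sc$image, c(0.2, 0.2), c(0.2, 1.4), optics$pixel_size),
    "no membrane peaks"
  )
})

test_that("exclusion rules flag borders, aggregates and minicells", {
  # border-touching cell
  optics <- optics_dialect("hcs", noise = FALSE)
  cells <- cell_spec(center_x = 0.4, center_y = 3, orientation = pi / 2,
    width_um = 1, length_um = 4)
  sc <- render_scene(scene_spec(c(80, 80), cells, 1), optics)
  m <- filter_cells(measure_cells(sc))
  expect_false(m$kept)
  expect_equal(m$exclude_reason, "border")

  # L-shaped touching pair segments as one low-solidity aggregate
  pair <- cell_spec(center_x = c(5.0, 7.3), center_y = c(5.0, 7.0),
    orientation = c(0, pi / 2), width_um = 0.8, length_um = 5)
  scp <- render_scene(scene_spec(c(110, 110), pair, 1), optics, max_overlap = 1)
  mp <- filter_cells(measure_cells(scp))
  expect_equal(nrow(mp), 1)
  expect_lt(mp$solidity, 0.7)
  expect_equal(mp$exclude_reason, "aggregate")

  # short cell: flagged minicell but kept for width by default
  mini <- tibble::tibble(
    cell_id = 1:2, width_um = c(1, 1), width_cv = 0.01,
    length_um = c(1.2, 4), surface_um2 = 1, volume_um3 = 1, sv_um_1 = 1,
    area_um2 = c(1, 4), solidity = 0.95, touches_border = FALSE,
    minicell = FALSE, uneven_width = FALSE, too_small = FALSE, flags = ""
  )
  fm <- filter_cells(mini)
  expect_true(fm$minicell[1])
  expect_false(fm$minicell[2])
  expect_true(all(fm$kept))
  fm2 <- filter_cells(mini, keep_minicell_width = FALSE)
  expect_false(fm2$kept[1])
  expect_equal(fm2$exclude_reason[1], "minicell")
})

test_that("filtering conserves cells: kept plus excluded equals all", {
  cells <- place_cells(sample_well(8, seed = 13, minicell_frac = 0.2),
    c(200, 200), 0.115, seed = 13)
  sc <- render_scene(scene_spec(c(200, 200), cells, 13), optics_dialect("hcs"))
  m <- filter_cells(measure_cells(sc))
  expect_equal(sum(m$kept) + sum(!m$kept), nrow(m))
  expect_true(all(!is.na(m$exclude_reason[!m$kept])))
  expect_true(all(is.na(m$exclude_reason[m$kept])))
})
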