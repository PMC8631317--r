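test_that("sample_well draws calibrated, reproducible populations", {
  w <- sample_well(n_cells = 225, width_mean = 1.15, width_sd = 0.08, seed = 1)
  expect_equal(nrow(w), 225)
  expect_lt(abs(mean(w$width_um) - 1.15), 3 * 0.08 / sqrt(225))
  expect_true(all(w$length_um >= w$width_um))

  expect_equal(nrow(sample_well(n_cells = 0)), 0)
  w0 <- sample_well(n_cells = 50, width_mean = 1.1, width_sd = 0, seed = 2)
  expect_true(all(w0$width_um == 1.1))

  expect_identical(sample_well(100, seed = 9), sample_well(100, seed = 9))
  expect_error(sample_well(10, width_mean = -1), "positive")
})

test_that("well-mean dispersion matches the standard error of the mean", {
  means <- vapply(1:1000, function(s) {
    mean(sample_well(
      n_cells = 225, width_mean = 1.15, width_sd = 0.08,
      seed = s
    )$width_um)
  }, 0)
  se_expected <- 0.08 / sqrt(225)
  expect_lt(abs(sd(means) - se_expected) / se_expected, 0.15)
})

test_that("rendering is deterministic and conserves ground truth", {
  cells <- place_cells(sample_well(30, seed = 7), c(300, 300), 0.115, seed = 7)
  sc1 <- render_scene(scene_spec(c(300, 300), cells, seed = 7), optics_dialect("hcs"))
  sc2 <- render_scene(scene_spec(c(300, 300), cells, seed = 7), optics_dialect("hcs"))
  expect_identical(sc1$image, sc2$image)
  expect_equal(nrow(sc1$truth), nrow(cells))
  expect_equal(sc1$truth$width_true_um, cells$width_um)
  expect_equal(sc1$truth$length_true_um, cells$length_um)
})

test_that("an unblurred shell has outer edges one width (plus band) apart", {
  optics <- optics_model(0.1, psf_sigma = 0, background = 0,
    photon_scale = Inf, read_noise_sd = 0)
  cells <- cell_spec(center_x = 3, center_y = 3, orientation = 0,
    width_um = 1, length_um = 4)
  sc <- render_scene(scene_spec(c(61, 61), cells, 1), optics)
  midcol <- sc$image[, 31] # crosses the cell centre perpendicular to the axis
  on <- which(midcol > 0)
  outer_span_um <- (max(on) - min(on) + 1) * optics$pixel_size
  # shell outer-edge-to-outer-edge: w plus the 1-px band, within 1 px
  expect_lt(abs(outer_span_um - 1.0), 2 * optics$pixel_size + 1e-9)
})

test_that("truth is optics-independent and both dialects are segmentable", {
  for (d in c("hcs", "epi")) {
    sc <- render_single_cell(1.0, 4.0, orientation = pi / 7, dialect = d)
    mask <- segment_image(sc$image, sc$optics)
    expect_equal(mask$n_labels, 1)
    expect_equal(sc$truth$width_true_um, 1.0)
    expect_equal(sc$truth$length_true_um, 4.0)
  }
})

test_that("invalid scenes are rejected with diagnostics", {
  overlapping <- cell_spec(
    center_x = c(3, 3.2), center_y = c(3, 3.1),
    orientation = 0, width_um = 1, length_um = 4
  )
  expect_error(
    render_scene(scene_spec(c(80, 80), overlapping, 1), optics_dialect("hcs")),
    "overlap"
  )
  outside <- cell_spec(center_x = 50, center_y = 3, width_um = 1, length_um = 4)
  expect_error(
    render_scene(scene_spec(c(80, 80), outside, 1), optics_dialect("hcs")),
    "outside the field"
  )
  expect_error(scene_spec(c(0, 10), cell_spec()), "image_shape")
})

test_that("blur widens but never thins the apparent shell", {
  # FWHM of a midline cross-profile is non-decreasing in psf_sigma
  fwhm <- vapply(c(0, 0.06, 0.12, 0.2), function(ps) {
    optics <- optics_model(0.065, psf_sigma = ps, background = 0,
      photon_scale = Inf, read_noise_sd = 0)
    cells <- cell_spec(center_x = 3, center_y = 3, width_um = 1, length_um = 4)
    sc <- render_scene(scene_spec(c(93, 93), cells, 1), optics)
    prof <- sc$image[, 47]
    half <- max(prof) / 2
    # width of the upper membrane peak at half maximum
    top <- which(prof >= half & seq_along(prof) < 47)
    (max(top) - min(top) + 1) * 0.065
  }, 0)
  expect_true(all(diff(fwhm) >= 0))
})

test_that("generate_plate pools to the programmed plate statistics", {
  pl <- plate_spec("P01", n_wells = 96, n_cells = 200, width_mean = 1.15,
    width_sd = 0.08, seed = 11)
  gp <- generate_plate(pl, "measurement")
  expect_equal(nrow(gp$cells), 96 * 200)
  expect_lt(abs(mean(gp$cells$width_um) - 1.15) / 1.15, 0.005)

  planted <- tibble::tibble(strain_id = "P01_A01", delta_pct = 13)
  gp2 <- generate_plate(
    plate_spec("P01", n_wells = 96, n_cells = 200, width_mean = 1.15,
      width_sd = 0.08, seed = 11, planted_effects = planted),
    "measurement"
  )
  hit <- gp2$cells[gp2$cells$strain_id == "P01_A01", ]
  expect_lt(abs(mean(hit$width_um) / 1.15 - 1.13), 0.02)

  expect_identical(generate_plate(pl, "measurement")$cells, gp$cells)
  expect_error(generate_plate(pl, "fancy"))
})

test_that("image-fidelity plates render four fields per well with truth", {
  pl <- plate_spec("P01", n_wells = 2, n_cells = 12, seed = 3)
  gp <- generate_plate(pl, "image", optics = optics_dialect("hcs"),
    image_shape = c(200, 200))
  expect_length(gp$images, 2 * 4)
  expect_true(all(grepl("^P01_[A-H]\\d\\d_f\\d$", names(gp$images))))
  expect_setequal(unique(gp$cells$field), 1:4)
  expect_equal(nrow(gp$cells), 24)
})

test_that("simulated growth curves follow the logistic model", {
  # pure exponential limit: doubling every gt_true minutes
  gm <- growth_model(od0 = 0.01, gt_true = 20, lag = 0,
    carrying_capacity = 1e6, noise_sd = 0)
  gc <- simulate_growth_curve(gm, seq(0, 120, by = 5))
  expect_lt(abs(gc$od600[gc$time_min == 60] - 0.08) / 0.08, 0.001)
  ratio <- gc$od600[gc$time_min == 40] / gc$od600[gc$time_min == 20]
  expect_lt(abs(ratio - 2), 0.002)

  # before the lag the culture sits at od0
  gm2 <- growth_model(od0 = 0.01, gt_true = 20, lag = 90, noise_sd = 0)
  gc2 <- simulate_growth_curve(gm2, c(0, 30, 60, 89))
  expect_true(all(gc2$od600 == 0.01))

  expect_error(simulate_growth_curve(gm, numeric(0)), "non-empty")
  expect_error(simulate_growth_curve(gm, c(0, 10, 10)), "increasing")
  expect_error(growth_model(od0 = 0.01, carrying_capacity = 0.005), "exceed")
})

test_that("simulate_screen arrays strains across plates reproducibly", {
  scr <- simulate_screen(n_strains = 300, wells_per_plate = 96,
    cells_per_well = 40, seed = 5)
  expect_equal(dplyr::n_distinct(scr$strain_id), 300)
  expect_equal(dplyr::n_distinct(scr$plate_id), 4) # ceiling(300/96)
  expect_equal(nrow(scr), 300 * 40)
  expect_identical(scr, simulate_screen(n_strains = 300, wells_per_plate = 96,
    cells_per_well = 40, seed = 5))
})
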