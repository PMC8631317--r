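make_cells <- function(widths_by_well, plate_id = "P01", n_each = NULL) {
  purrr::imap_dfr(widths_by_well, function(w, well) {
    tibble::tibble(
      plate_id = plate_id, well_id = well, strain_id = paste0("S_", well),
      width_um = w, length_um = 4, kept = TRUE, minicell = FALSE
    )
  })
}

test_that("well summaries apply the minimum-cell QC rule", {
  cells <- make_cells(list(
    A01 = rep(1.0, 29), # one short of measurable
    A02 = rep(1.0, 225),
    A03 = c(0.9, 1.0, 1.1)
  ))
  ws <- summarize_wells(cells, min_cells = 30)
  expect_equal(ws$qc[ws$well_id == "A01"], "reacquire")
  expect_equal(ws$qc[ws$well_id == "A02"], "ok")
  expect_equal(ws$mean_width[ws$well_id == "A02"], 1.0)
  expect_equal(ws$width_sd[ws$well_id == "A02"], 0)

  ws3 <- summarize_wells(cells, min_cells = 3)
  expect_equal(ws3$mean_width[ws3$well_id == "A03"], 1.0)
  expect_equal(ws3$width_sd[ws3$well_id == "A03"], 0.1)
})

test_that("minicells are excluded from length but not width summaries", {
  cells <- tibble::tibble(
    plate_id = "P01", well_id = "A01", strain_id = "S1",
    width_um = c(1.0, 1.0, 0.6), length_um = c(4, 4, 0.7),
    kept = TRUE, minicell = c(FALSE, FALSE, TRUE)
  )
  ws <- summarize_wells(cells, min_cells = 1)
  expect_equal(ws$mean_length, 4)
  expect_equal(ws$mean_width, mean(c(1, 1, 0.6)))
})

test_that("AWP is the per-cell mean, equal to the weighted well-mean", {
  widths <- c(
    lapply(well_ids(86), function(w) rep(1.000, 50)),
    lapply(87:96, function(i) rep(1.130, 50))
  )
  names(widths) <- well_ids(96)
  cells <- make_cells(widths)
  pr <- compute_awp(cells, min_cells = 1)
  expect_equal(pr$awp, (86 + 10 * 1.13) / 96, tolerance = 1e-12)
  expect_equal(pr$n_cells_total, 96 * 50)

  two <- make_cells(list(A01 = rep(1.0, 100), A02 = rep(1.2, 300)))
  expect_equal(compute_awp(two, min_cells = 1)$awp, 1.15, tolerance = 1e-12)

  expect_error(compute_awp(two[0, ]), "empty")
})

test_that("AWP is invariant under well permutation", {
  set.seed(1)
  cells <- make_cells(setNames(
    lapply(1:12, function(i) rnorm(30 + 5 * i, 1 + i / 100, 0.05)),
    well_ids(12)
  ))
  a1 <- compute_awp(cells, min_cells = 1)$awp
  a2 <- compute_awp(cells[sample(nrow(cells)), ], min_cells = 1)$awp
  expect_equal(a1, a2, tolerance = 1e-12)
  # equals the cell-count-weighted mean of well means
  ws <- summarize_wells(cells, min_cells = 1)
  expect_equal(a1, sum(ws$mean_width * ws$n_cells) / sum(ws$n_cells),
    tolerance = 1e-12)
})

test_that("delta_width implements the plate-relative percent deviation", {
  expect_equal(delta_width(1.15, 1.00), 15)
  expect_equal(delta_width(1.0, 1.0), 0)
  expect_equal(delta_width(0.964, 0.975), (0.964 - 0.975) * 100 / 0.975)
  expect_lt(abs(delta_width(0.964, 0.975) - (-1.128)), 0.001)
  expect_error(delta_width(1, 0), "awp")
})

test_that("tail selection sizes follow round(tail_fraction * N)", {
  set.seed(3)
  rec <- tibble::tibble(
    strain_id = sprintf("S%04d", 1:3983),
    delta_width_pct = rnorm(3983, 0, 2)
  )
  hits <- call_hits(rec, 0.005)
  expect_equal(sum(hits$selected), 40)
  expect_setequal(hits$rank, 1:3983)
  # selected are exactly the extremes
  lo <- sort(rec$delta_width_pct)[20]
  hi <- sort(rec$delta_width_pct, decreasing = TRUE)[20]
  expect_true(all(hits$delta_width_pct[hits$selected] <= lo |
    hits$delta_width_pct[hits$selected] >= hi))

  rec200 <- rec[1:200, ]
  expect_equal(sum(call_hits(rec200, 0.005)$selected), 2)

  for (n in c(2, 7, 50, 401, 1000)) {
    k <- max(1, round(0.005 * n))
    expect_equal(sum(call_hits(rec[1:n, ], 0.005)$selected), min(2 * k, n))
  }
})

test_that("ties in delta-width break deterministically by strain id", {
  rec <- tibble::tibble(
    strain_id = sprintf("S%02d", 1:10),
    delta_width_pct = rep(1.5, 10)
  )
  h1 <- call_hits(rec, 0.05)
  h2 <- call_hits(rec[sample(10), ], 0.05)
  expect_equal(sum(h1$selected), 2)
  expect_identical(
    sort(h1$strain_id[h1$selected]),
    sort(h2$strain_id[h2$selected])
  )
  expect_setequal(h1$strain_id[h1$selected], c("S01", "S10"))
})

test_that("awp_sensitivity matches the exact contamination arithmetic", {
  expect_equal(awp_sensitivity(10, 13, 96), 10 * 13 / 96, tolerance = 1e-15)
  expect_equal(awp_sensitivity(0, 99, 96), 0)
  expect_equal(awp_sensitivity(96, 7.5, 96), 7.5)
  expect_error(awp_sensitivity(5, 10, 0), "wells_per_plate")
  expect_error(awp_sensitivity(-1, 10, 96))
})

test_that("contaminating wells shifts every other strain by the predicted amount", {
  base <- make_cells(setNames(lapply(1:96, function(i) rep(1.0, 40)),
    well_ids(96)))
  contaminated <- base
  hot <- base$well_id %in% well_ids(96)[1:10]
  contaminated$width_um[hot] <- 1.13
  awp0 <- compute_awp(base, min_cells = 1)$awp
  awp1 <- compute_awp(contaminated, min_cells = 1)$awp
  shift_pred <- awp_sensitivity(10, 13, 96)
  # the brute-force per-cell AWP shift equals the closed form exactly
  expect_equal((awp1 - awp0) / awp0 * 100, shift_pred, tolerance = 1e-12)
  # and every unaffected strain's delta moves by the induced reference shift
  d_cont <- delta_width(1.0, awp1)
  expect_equal(d_cont, -100 * shift_pred / (100 + shift_pred), tolerance = 1e-9)
})

test_that("screen_strains runs the full stage-1 pipeline", {
  planted <- tibble::tibble(strain_id = c("S0007", "S0100"), delta_pct = c(15, -12))
  cells <- simulate_screen(n_strains = 192, wells_per_plate = 96,
    cells_per_well = 60, planted = planted, seed = 4)
  scr <- screen_strains(cells, tail_fraction = 0.005)
  expect_s3_class(scr, "width_screen")
  rec <- tidy(scr)
  expect_equal(nrow(rec), 192)
  expect_setequal(rec$strain_id[rec$selected], c("S0007", "S0100"))
  expect_equal(rec$tail[rec$strain_id == "S0007"], "high")
  expect_equal(rec$tail[rec$strain_id == "S0100"], "low")
  g <- glance(scr)
  expect_equal(g$n_selected, 2)
  expect_equal(g$n_plates, 2)
})

test_that("re-acquisition wells are excluded from the AWP and hit calling", {
  cells <- make_cells(list(
    A01 = rep(2.0, 5), # under-sampled outlier well
    A02 = rep(1.0, 50), A03 = rep(1.0, 50), A04 = rep(1.1, 50)
  ))
  scr <- screen_strains(cells, min_cells = 30, tail_fraction = 0.2)
  expect_equal(nrow(scr$reacquire), 1)
  expect_equal(scr$reacquire$well_id, "A01")
  expect_false("S_A01" %in% tidy(scr)$strain_id)
  expect_equal(scr$plates$awp, mean(c(rep(1, 100), rep(1.1, 50))),
    tolerance = 1e-12)
})
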