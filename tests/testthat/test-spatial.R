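test_that("erosion-based membrane of a 10 x 4 rectangle is the 24-px perimeter ring", {
  cell <- matrix(FALSE, 12, 16)
  cell[5:8, 4:13] <- TRUE   # 4 rows x 10 cols
  rm <- derive_regions(cell, band_px = 1)
  expect_equal(sum(rm$membrane), 40 - 16)   # 10x4 minus 8x2 interior
  expect_equal(sum(rm$cytoplasm), 16)
  expect_equal(sum(rm$nucleoid), 0)
})

test_that("region masks partition the cell exactly", {
  geom <- cell_geometry()
  rm <- make_region_masks(geom, 0.08, c(20, 45))
  expect_true(all(!(rm$membrane & rm$nucleoid)))
  expect_true(all(!(rm$membrane & rm$cytoplasm)))
  expect_true(all(!(rm$nucleoid & rm$cytoplasm)))
  expect_identical(rm$membrane | rm$nucleoid | rm$cytoplasm, rm$cell)
  expect_equal(sum(rm$membrane) + sum(rm$nucleoid) + sum(rm$cytoplasm),
               sum(rm$cell))

  # no nucleoid: cytoplasm is cell minus membrane
  g0 <- cell_geometry(nucleoid_axes = c(0, 0))
  rm0 <- make_region_masks(g0, 0.08, c(20, 45))
  expect_equal(sum(rm0$nucleoid), 0)
  expect_identical(rm0$cytoplasm, rm0$cell & !rm0$membrane)

  # derive_regions partition on an arbitrary stain image
  set.seed(4)
  cell <- matrix(FALSE, 30, 30); cell[8:24, 5:27] <- TRUE
  stain <- matrix(runif(900), 30, 30) + ifelse(cell, 1, 0)
  rmx <- derive_regions(cell, stain, band_px = 1)
  expect_identical(rmx$membrane | rmx$nucleoid | rmx$cytoplasm, rmx$cell)
  expect_true(all(!(rmx$nucleoid & rmx$membrane)))
})

test_that("a sub-pixel membrane band is widened to one pixel with a warning", {
  geom <- cell_geometry(membrane_band = 0.01)
  expect_warning(rm <- make_region_masks(geom, 0.1, c(16, 36)),
                 "widened to one pixel")
  expect_gt(sum(rm$membrane), 0)
})

test_that("enrichment follows the count-share over area-share formula", {
  # two-region toy: nucleoid 30 px, cytoplasm 70 px, counts 60 / 40
  cell <- matrix(FALSE, 10, 12); cell[1:10, 1:10] <- TRUE
  nuc <- matrix(FALSE, 10, 12); nuc[1:3, 1:10] <- TRUE
  masks <- structure(list(cell = cell, nucleoid = nuc,
                          membrane = matrix(FALSE, 10, 12),
                          cytoplasm = cell & !nuc, pixel_size = 1),
                     class = "region_masks")
  set.seed(2)
  locs <- data.frame(
    x_um = c(runif(60, 0, 10), runif(40, 0, 10)),
    y_um = c(runif(60, 0, 3), runif(40, 3, 10)))
  enr <- compute_enrichment(locs, masks)
  expect_equal(enr$enrichment[enr$region == "nucleoid"], (60 / 100) / (30 / 100))
  expect_equal(enr$enrichment[enr$region == "cytoplasm"], (40 / 100) / (70 / 100))
  # area-weighted mean enrichment over the partition is exactly 1
  # (the zero-area membrane has undefined enrichment and zero weight)
  w <- enr$area_um2 / sum(enr$area_um2)
  def <- !is.na(enr$enrichment)
  expect_equal(sum(w[def] * enr$enrichment[def]), 1, tolerance = 1e-12)

  # all localizations in a half-area nucleoid: enrichment 2, others 0
  nuc2 <- matrix(FALSE, 10, 12); nuc2[1:5, 1:10] <- TRUE
  masks2 <- structure(list(cell = cell, nucleoid = nuc2,
                           membrane = matrix(FALSE, 10, 12),
                           cytoplasm = cell & !nuc2, pixel_size = 1),
                      class = "region_masks")
  locs2 <- data.frame(x_um = runif(500, 0, 10), y_um = runif(500, 0, 5))
  enr2 <- compute_enrichment(locs2, masks2)
  expect_equal(enr2$enrichment[enr2$region == "nucleoid"], 2.0)
  expect_equal(enr2$enrichment[enr2$region == "cytoplasm"], 0)
})

test_that("uniform localizations are unenriched everywhere", {
  geom <- cell_geometry()
  px <- 0.0865
  rm <- make_region_masks(geom, px, c(16, 40))
  set.seed(8)
  # uniform over the field; out-of-cell points are dropped by the formula,
  # leaving points uniform over the pixelated cell itself
  locs <- data.frame(x_um = runif(4e5, 0, 40 * px), y_um = runif(4e5, 0, 16 * px))
  enr <- compute_enrichment(locs, rm)
  expect_true(all(abs(enr$enrichment - 1) < 0.05))
  w <- enr$area_um2 / sum(enr$area_um2)
  expect_equal(sum(w * enr$enrichment), 1, tolerance = 1e-9)
})

test_that("enrichment is stable under uniform subsampling of localizations", {
  geom <- cell_geometry()
  px <- 0.0865
  rm <- make_region_masks(geom, px, c(16, 40))
  set.seed(10)
  pts <- sptq:::sample_in_cell(4e4, geom)
  # enrich the nucleoid 2:1 over the rest
  inside <- (pts[, 1] / geom$nucleoid_axes[1])^2 +
            (pts[, 2] / geom$nucleoid_axes[2])^2 <= 1
  keep <- inside | (runif(nrow(pts)) < 0.5)
  locs <- data.frame(x_um = pts[keep, 1] + 40 * px / 2,
                     y_um = pts[keep, 2] + 16 * px / 2)
  full <- compute_enrichment(locs, rm)$enrichment
  subs <- replicate(10, {
    ix <- sample(nrow(locs), nrow(locs) %/% 4)
    compute_enrichment(locs[ix, ], rm)$enrichment
  })
  expect_equal(rowMeans(subs), full, tolerance = 0.03)
})

test_that("per-region speeds separate fast from slow zones", {
  cell <- matrix(TRUE, 10, 10)
  nuc <- matrix(FALSE, 10, 10); nuc[1:5, ] <- TRUE
  masks <- structure(list(cell = cell, nucleoid = nuc,
                          membrane = matrix(FALSE, 10, 10),
                          cytoplasm = cell & !nuc, pixel_size = 1),
                     class = "region_masks")
  steps <- structure(data.frame(traj_id = 1, frame = 1:40,
                                osd_um = rep(c(0.3, 0.05), each = 20),
                                osd2_um2 = rep(c(0.09, 0.0025), each = 20),
                                x_mid = 5,
                                y_mid = rep(c(2, 8), each = 20),
                                dt_s = 0.00576),
                     class = c("step_table", "data.frame"))
  locs <- data.frame(x_um = steps$x_mid, y_um = steps$y_mid)
  enr <- compute_enrichment(locs, masks, steps = steps)
  v_nuc <- enr$mean_speed_um_s[enr$region == "nucleoid"]
  v_cyt <- enr$mean_speed_um_s[enr$region == "cytoplasm"]
  expect_equal(v_nuc, 0.3 / 0.00576)
  expect_equal(v_cyt, 0.05 / 0.00576)
})
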