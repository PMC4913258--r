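test_that("radius_from_area is the equivalent-circle radius", {
  expect_equal(radius_from_area(pi), 1)
  expect_equal(radius_from_area(4 * pi), 2)
  expect_error(radius_from_area(0))
  expect_error(radius_from_area(-3))
})

test_that("a rasterised disk recovers its radius within half a pixel", {
  px <- 0.098
  r_true <- 0.49
  n <- 31
  ctr <- (n - 1) / 2
  xs <- (0:(n - 1) - ctr) * px
  hit <- outer(xs^2, xs^2, `+`) <= r_true^2
  r_est <- radius_from_area(sum(hit) * px^2)
  expect_lt(abs(r_est - r_true), 0.05)
})

test_that("classify_size partitions (0, Inf) with closed growing interval", {
  expect_equal(as.character(classify_size(0.15)), "budding")
  expect_equal(as.character(classify_size(0.45)), "growing")
  expect_equal(as.character(classify_size(1.2)), "large")
  # boundaries belong to the growing class by convention
  expect_equal(as.character(classify_size(c(0.2, 0.8))),
               c("growing", "growing"))
  # every radius maps to exactly one class, fractions sum to 1
  set.seed(1)
  r <- rexp(500, 2) + 1e-3
  sb <- size_breakdown(r)
  expect_equal(sb$fraction_budding + sb$fraction_growing + sb$fraction_large,
               1)
  expect_error(classify_size(0))
})

test_that("distance to nucleus edge matches the analytic circle", {
  px <- 0.098
  n <- 301
  ctr_um <- 150 * px
  xs <- (0:(n - 1)) * px
  nucleus <- outer((xs - ctr_um)^2, (xs - ctr_um)^2, `+`) <= 6.5^2
  # centroid 10 um from the centre -> 3.5 um from the edge
  d <- distance_to_nucleus_edge(ctr_um + 10, ctr_um, nucleus, px)
  expect_lt(abs(d - 3.5), 0.05)
  # a centroid on the boundary is ~0; inside is exactly 0
  d_edge <- distance_to_nucleus_edge(ctr_um + 6.5, ctr_um, nucleus, px)
  expect_lt(d_edge, 0.05)
  d_in <- distance_to_nucleus_edge(ctr_um + 3, ctr_um, nucleus, px)
  expect_equal(d_in, 0)
  expect_error(distance_to_nucleus_edge(1, 1, nucleus & FALSE, px))
})

test_that("measured nucleus distances track the generator's placement", {
  # budding-free, well-cleared droplets so that detection is complete and
  # the comparison isolates the distance measurement itself
  tr <- sample_ground_truth(tiny_preset(count = 25, budding = 0), 3,
                            seed = 33, min_clearance_um = 0.5)
  fld <- render_stack(tr, optics_model(), seed = 2, noise = FALSE)
  regions <- split_cells(fld$stack, fld$cell_masks, fld$nucleus_masks)
  res <- lapply(regions, analyze_region, params = analysis_params())
  meas <- dplyr::bind_rows(lapply(res, `[[`, "droplets"))
  # truth distances from nucleus edge (nucleus centred on the cell)
  td <- dplyr::inner_join(tr$droplets, tr$cells, by = "cell_id")
  truth_d <- sqrt((td$x_um - td$centre_x_um)^2 +
                  (td$y_um - td$centre_y_um)^2) - td$nucleus_radius_um
  expect_lt(abs(median(meas$nuc_dist_um) - median(truth_d)) /
              median(truth_d), 0.05)
})

test_that("summarize_cell aggregates counts, volumes and radii", {
  fld <- tiny_field()
  rg <- split_cells(fld$stack, fld$cell_masks, fld$nucleus_masks)[[1]]
  # a fabricated 1000-voxel object: volume = 1000 x 0.098^2 x 0.3
  v <- array(0, dim(rg$substack$voxels))
  v[1:10, 1:10, 1:10] <- 99
  l3 <- label_3d(v, 50)
  dr <- tibble::tibble(
    cell_id = 1L, label = 1L, x_um = 1, y_um = 1, area_um2 = pi,
    r_um = 1, size_class = classify_size(1), nuc_dist_um = 1,
    plane_index = 0L
  )
  cs <- summarize_cell(dr, l3, rg)
  expect_equal(cs$total_volume_um3, 1000 * 0.098^2 * 0.3, tolerance = 1e-9)
  expect_equal(cs$droplet_count, 1L)
  expect_equal(cs$median_radius_um, 1)
  expect_equal(cs$cell_radius_um, radius_from_area(cs$cell_area_um2))
  # zero droplets: count 0, missing median
  empty <- dr[0, ]
  cs0 <- summarize_cell(empty, NULL, rg)
  expect_equal(cs0$droplet_count, 0L)
  expect_true(is.na(cs0$median_radius_um))
})

test_that("total volume is additive and invariant to label permutation", {
  v <- array(0, c(12, 12, 4))
  v[2:4, 2:4, 2] <- 10
  v[8:10, 8:10, 3] <- 10
  l3 <- label_3d(v, 5)
  expect_equal(sum(l3$voxel_counts), sum(v > 5))
  expect_equal(sum(rev(l3$voxel_counts)), sum(l3$voxel_counts))
})

test_that("measure_droplets returns physical units and classes", {
  lab <- matrix(0L, 40, 40)
  lab[10:14, 10:14] <- 1L   # 25 px -> r ~ 0.276 um
  lab[25:27, 30:32] <- 2L   # 9 px  -> r ~ 0.166 um
  fld <- tiny_field()
  rg <- split_cells(fld$stack, fld$cell_masks, fld$nucleus_masks)[[1]]
  lab_full <- matrix(0L, nrow(rg$cell_mask), ncol(rg$cell_mask))
  lab_full[seq_len(40), seq_len(40)] <- lab
  dr <- measure_droplets(lab_full, rg, plane_index = 3)
  expect_equal(nrow(dr), 2)
  expect_equal(dr$area_um2, c(25, 9) * 0.098^2)
  expect_equal(dr$r_um, radius_from_area(dr$area_um2))
  expect_equal(as.character(dr$size_class), c("growing", "budding"))
  expect_equal(dr$x_um[1], 11 * 0.098)  # centroid of cols 10:14, 0-based
})
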