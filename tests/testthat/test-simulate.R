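test_that("fixing the seed fixes ground truth and rendering bit-for-bit", {
  p <- tiny_preset()
  t1 <- sample_ground_truth(p, 3, seed = 21)
  t2 <- sample_ground_truth(p, 3, seed = 21)
  expect_identical(t1$droplets, t2$droplets)
  expect_identical(t1$cells$cell_area_um2, t2$cells$cell_area_um2)

  f1 <- render_stack(t1, optics_model(), seed = 5)
  f2 <- render_stack(t2, optics_model(), seed = 5)
  expect_identical(f1$stack$voxels, f2$stack$voxels)
  expect_identical(f1$cell_masks, f2$cell_masks)
})

test_that("degenerate mixtures produce the requested radius class only", {
  all_budding <- treatment_preset(
    "bud", droplet_count_median = 30, budding_weight = 1, large_weight = 0,
    growing_peak_mean_um = 0.4, growing_peak_sd_um = 0.1,
    nucleus_distance_median_um = 4, cell_area_median_um2 = 700,
    nucleus_radius_median_um = 4.5, cell_to_cell_dispersion = 0
  )
  tr <- sample_ground_truth(all_budding, 1, seed = 3)
  expect_true(all(tr$droplets$r_um < 0.2))
  expect_true(all(tr$droplets$r_um > 0))
})

test_that("droplet centres lie inside the cell and outside the nucleus", {
  tr <- sample_ground_truth(tiny_preset(count = 25), 4, seed = 17)
  for (i in tr$cells$cell_id) {
    cell <- tr$cells[tr$cells$cell_id == i, ]
    d <- tr$droplets[tr$droplets$cell_id == i, ]
    dx <- d$x_um - cell$centre_x_um
    dy <- d$y_um - cell$centre_y_um
    radial <- sqrt(dx^2 + dy^2)
    expect_true(all(radial > cell$nucleus_radius_um))
    f <- lipidquant:::cell_outline(cell$outline[[1]]$a, cell$outline[[1]]$phi)
    expect_true(all(radial < cell$base_radius_um * f(atan2(dy, dx))))
  }
})

test_that("hard-sphere placement keeps droplets from interpenetrating", {
  tr <- sample_ground_truth(tiny_preset(count = 30), 2, seed = 8)
  for (i in tr$cells$cell_id) {
    d <- tr$droplets[tr$droplets$cell_id == i, ]
    if (nrow(d) < 2) next
    dd <- as.matrix(stats::dist(cbind(d$x_um, d$y_um, d$z_um)))
    rr <- outer(d$r_um, d$r_um, `+`)
    diag(dd) <- Inf
    expect_true(all(dd >= rr - 1e-9))
  }
})

test_that("mixture class fractions converge to the configured weights", {
  # law of large numbers at >= 1e4 droplets, 3 binomial SDs
  p <- make_preset("oleate")
  set.seed(123)
  r <- lipidquant:::sample_radii(p, 2e4)
  for (cls in list(
    c(p$budding_weight, mean(r < 0.2)),
    c(p$large_weight, mean(r > 0.8))
  )) {
    tol <- 3 * sqrt(cls[1] * (1 - cls[1]) / 2e4)
    expect_lt(abs(cls[2] - cls[1]), tol)
  }
})

test_that("ground-truth total volume is the exact sum of sphere volumes", {
  tr <- sample_ground_truth(tiny_preset(), 3, seed = 4)
  ts <- truth_cell_summary(tr)
  manual <- tapply(4 / 3 * pi * tr$droplets$r_um^3, tr$droplets$cell_id, sum)
  expect_equal(ts$total_volume_um3[ts$cell_id %in% names(manual)],
               as.numeric(manual))
  expect_equal(ts$n_droplets, as.integer(table(tr$droplets$cell_id)),
               ignore_attr = TRUE)
})

test_that("zero-droplet truth renders Poisson background only", {
  p <- tiny_preset(count = 0, dispersion = 0)
  tr <- sample_ground_truth(p, 1, seed = 2)
  expect_equal(nrow(tr$droplets), 0)
  o <- optics_model(background_rate = 2, dead_time_s = 0)
  fld <- render_stack(tr, o, seed = 9)
  v <- fld$stack$voxels
  expect_equal(mean(v), 2, tolerance = 0.01)       # Poisson mean
  expect_equal(stats::var(as.vector(v)), 2, tolerance = 0.05)
  expect_true(all(v == round(v)))
})

test_that("rendered intensity integrates to the analytic sphere volume", {
  # one sphere, PSF off, noise off: integrated signal proportional to
  # (4/3) pi r^3 within the rasterisation tolerance
  p <- tiny_preset(count = 1, dispersion = 0)
  tr <- sample_ground_truth(p, 1, seed = 6)
  tr$droplets <- tibble::tibble(
    cell_id = 1L, x_um = tr$cells$centre_x_um + 6,
    y_um = tr$cells$centre_y_um, z_um = 3.6, r_um = 0.49
  )
  o <- optics_model(psf_sigma_lateral_um = 0, psf_sigma_axial_um = 0,
                    background_rate = 0)
  fld <- render_stack(tr, o, seed = 1, noise = FALSE)
  integral <- sum(fld$stack$voxels) * voxel_volume_um3(fld$stack) /
    o$droplet_brightness
  expect_equal(integral, 4 / 3 * pi * 0.49^3, tolerance = 0.15)
  # sub-voxel droplet is still rendered, never dropped
  tr$droplets$r_um <- 0.03
  fld2 <- render_stack(tr, o, seed = 1, noise = FALSE)
  expect_gt(sum(fld2$stack$voxels), 0)
})

test_that("a PSF-blurred render conserves total signal", {
  p <- tiny_preset(count = 5, dispersion = 0)
  tr <- sample_ground_truth(p, 1, seed = 31)
  o0 <- optics_model(psf_sigma_lateral_um = 0, psf_sigma_axial_um = 0,
                     background_rate = 0)
  o1 <- optics_model(background_rate = 0)
  s0 <- sum(render_stack(tr, o0, seed = 1, noise = FALSE)$stack$voxels)
  s1 <- sum(render_stack(tr, o1, seed = 1, noise = FALSE)$stack$voxels)
  expect_equal(s1, s0, tolerance = 0.02)  # only boundary leakage differs
})

test_that("dead_time = 0 leaves Poisson counts unsaturated", {
  p <- tiny_preset(count = 3, dispersion = 0)
  tr <- sample_ground_truth(p, 1, seed = 13)
  o_free <- optics_model(dead_time_s = 0)
  o_sat <- optics_model(dead_time_s = 5e-7)
  v_free <- render_stack(tr, o_free, seed = 77)$stack$voxels
  v_sat <- render_stack(tr, o_sat, seed = 77)$stack$voxels
  expect_true(all(v_sat <= v_free))
  expect_gt(max(v_free), max(v_sat))  # bright voxels saturate
})

test_that("masks label every cell and nuclei sit inside their cells", {
  tr <- sample_ground_truth(tiny_preset(), 4, seed = 19)
  fld <- render_stack(tr, optics_model(), seed = 1, noise = FALSE)
  expect_setequal(setdiff(unique(as.vector(fld$cell_masks)), 0L), 1:4)
  inside <- fld$nucleus_masks == 0 | fld$nucleus_masks == fld$cell_masks
  expect_true(all(inside))
  # mask areas match the sampled cell areas to pixel accuracy
  for (i in 1:4) {
    a_mask <- sum(fld$cell_masks == i) * 0.098^2
    expect_equal(a_mask, tr$cells$cell_area_um2[i], tolerance = 0.02)
  }
})
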