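test_that("split_cells crops one region per label with correct areas", {
  masks <- disk_mask(list(c(25, 25), c(25, 70), c(70, 45)), r = 12,
                     labels = TRUE)
  nuc <- disk_mask(list(c(25, 25), c(25, 70), c(70, 45)), r = 4,
                   labels = TRUE)
  s <- ld_stack(array(1, c(100, 100, 2)))
  regions <- split_cells(s, masks, nuc)
  expect_length(regions, 3)
  for (i in 1:3) {
    expect_equal(regions[[i]]$cell_id, i)
    expect_equal(sum(regions[[i]]$cell_mask) * 0.098^2,
                 sum(masks == i) * 0.098^2)
    expect_true(all(regions[[i]]$nucleus_mask | !regions[[i]]$nucleus_mask))
    # voxels outside the footprint are zeroed
    expect_equal(sum(regions[[i]]$substack$voxels[, , 1]),
                 sum(regions[[i]]$cell_mask))
  }
})

test_that("split_cells: empty masks give an empty list; orphans error", {
  s <- ld_stack(array(0, c(20, 20, 1)))
  empty <- matrix(0L, 20, 20)
  expect_length(split_cells(s, empty, empty), 0)
  nuc <- empty; nuc[10, 10] <- 3L
  expect_error(split_cells(s, empty, nuc), "no matching cell")
})

test_that("border-touching cells are flagged", {
  masks <- matrix(0L, 40, 40)
  masks[1:10, 5:15] <- 1L       # touches row 1
  masks[20:30, 20:30] <- 2L
  s <- ld_stack(array(0, c(40, 40, 1)))
  regions <- split_cells(s, masks, matrix(0L, 40, 40))
  expect_true(regions[[1]]$border)
  expect_false(regions[[2]]$border)
})

test_that("select_brightest_plane returns a 0-based argmax, ties low", {
  v <- array(1, c(10, 10, 4))
  mask <- matrix(TRUE, 10, 10)
  rg <- structure(list(cell_id = 1L, cell_mask = mask,
                       nucleus_mask = mask & FALSE,
                       substack = ld_stack(v), border = FALSE),
                  class = "ld_region")
  expect_equal(select_brightest_plane(rg), 0L)       # tie -> lowest
  v[, , 3] <- 2
  rg$substack <- ld_stack(v)
  expect_equal(select_brightest_plane(rg), 2L)
  rg$substack <- ld_stack(v[, , 1, drop = FALSE])
  expect_equal(select_brightest_plane(rg), 0L)       # single plane
})

test_that("Otsu threshold separates a bimodal image and recovers droplets", {
  img <- matrix(10, 50, 50)
  img[20:30, 20:30] <- 100
  fg <- threshold_droplets(img, method = "otsu")
  t <- attr(fg, "threshold")
  expect_gt(t, 10); expect_lt(t, 100)
  expect_equal(sum(fg), 11 * 11)   # droplets fully recovered
})

test_that("flat and out-of-range thresholds give empty foregrounds", {
  img <- matrix(5, 20, 20)
  expect_warning(fg <- threshold_droplets(img, method = "otsu"), "flat")
  expect_equal(sum(fg), 0)
  img2 <- matrix(rpois(400, 10), 20, 20)
  fg2 <- threshold_droplets(img2, method = "fixed",
                            fixed_value = max(img2) + 1)
  expect_equal(sum(fg2), 0)
})

test_that("threshold methods order sensibly on droplet-like data", {
  set.seed(21)
  img <- matrix(rpois(200 * 200, 0.4), 200, 200)
  img[80:90, 80:90] <- rpois(121, 50)
  t_lin <- attr(threshold_droplets(img, method = "otsu"), "threshold")
  t_sqrt <- attr(threshold_droplets(img, method = "otsu_sqrt"), "threshold")
  t_poi <- attr(threshold_droplets(img, method = "poisson"), "threshold")
  expect_true(t_poi < t_sqrt)
  expect_true(t_sqrt < t_lin)
  expect_lte(t_poi, 5)   # near-background detection level
})

test_that("watershed separates overlapping disk chains exactly", {
  for (k in 2:5) {
    m <- disk_mask(disk_chain(k), r = 6) > 0
    lab <- watershed_split(m, 1)
    expect_equal(max(lab), k)
    expect_equal(sum(lab > 0), sum(m))   # area conserved exactly
  }
})

test_that("watershed: disjoint disks keep exact areas; single disk unsplit", {
  m <- disk_mask(list(c(20, 20), c(60, 60)), r = 8) > 0
  lab <- watershed_split(m, 1)
  expect_equal(max(lab), 2)
  expect_equal(sort(tabulate(lab[lab > 0])), rep(sum(m) / 2, 2))
  one <- disk_mask(list(c(30, 30)), r = 10) > 0
  expect_equal(max(watershed_split(one, 1)), 1)
  # two overlapping disks, centres 8 px apart, radii 5
  two <- disk_mask(list(c(30, 26), c(30, 34)), r = 5) > 0
  expect_equal(max(watershed_split(two, 1)), 2)
})

test_that("watershed labels are contiguous from 1 and empty masks work", {
  lab <- watershed_split(matrix(FALSE, 10, 10), 1)
  expect_equal(max(lab), 0)
  m <- disk_mask(disk_chain(3), r = 6) > 0
  lab3 <- watershed_split(m, 1)
  expect_setequal(setdiff(unique(as.vector(lab3)), 0L), 1:3)
})

test_that("label_3d counts separated spheres with 26-connectivity", {
  v <- array(0, c(20, 20, 8))
  v[5:8, 5:8, 2:4] <- 10         # block 1
  v[12:15, 12:15, 5:7] <- 10     # block 2, > 1 voxel gap
  l3 <- label_3d(v, threshold = 5)
  expect_equal(length(l3$voxel_counts), 2)
  expect_equal(sort(l3$voxel_counts), c(48L, 48L))
  # diagonal contact is connected under 26-connectivity
  v2 <- array(0, c(6, 6, 2))
  v2[2, 2, 1] <- 10; v2[3, 3, 2] <- 10
  expect_equal(length(label_3d(v2, 5)$voxel_counts), 1)
  # single-voxel objects are kept (no minimum size)
  v3 <- array(0, c(5, 5, 3)); v3[3, 3, 2] <- 10
  expect_equal(label_3d(v3, 5)$voxel_counts, 1L)
})

test_that("lowering the threshold never decreases foreground volume", {
  fld <- tiny_field()
  rg <- split_cells(fld$stack, fld$cell_masks, fld$nucleus_masks)[[1]]
  vols <- vapply(c(40, 20, 10, 5), function(t) {
    sum(label_3d(rg, t)$voxel_counts)
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("3D object count matches ground truth on a clean render", {
  p <- tiny_preset(count = 8, budding = 0, large = 0, dispersion = 0)
  tr <- sample_ground_truth(p, 1, seed = 23, min_clearance_um = 1)
  fld <- render_stack(tr, optics_model(), seed = 1, noise = FALSE)
  rg <- split_cells(fld$stack, fld$cell_masks, fld$nucleus_masks)[[1]]
  l3 <- label_3d(rg, threshold = optics_model()$background_rate + 1)
  expect_equal(length(l3$voxel_counts), nrow(tr$droplets))
})
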