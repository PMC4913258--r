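# Synthetic droplet-laden cells with full ground truth.
#
# Cells are convex-ish polygons (radial cosine perturbation of a disk)
# containing a disk nucleus; droplets are hard (non-interpenetrating)
# spheres placed peri-nuclearly, with larger droplets biased nearer the
# nucleus, in a thin axial band about the stack mid-plane.

Z_MID_UM <- 3.6      # stack mid-plane (plane 12 of 25 at 0.3 um)
N_Z_DEFAULT <- 25L
Z_BAND_SD_UM <- 0.15 # axial placement band (truncated at +-0.3 um)
Z_BAND_MAX_UM <- 0.3
RADIUS_BIAS_PER_UM <- 0.25 # shrink of placement scale per um of radius

# radial perturbation of the cell outline: R(theta) = R0 * (1 + f(theta))
cell_outline <- function(a, phi) {
  function(theta) {
    f <- 0
    for (m in seq_along(a)) f <- f + a[m] * cos((m + 1) * theta + phi[m])
    1 + f
  }
}

#' Sample ground truth for a population of droplet-laden cells
#'
#' Draws per-cell geometry (polygonal footprint, disk nucleus) and a
#' droplet list (centre and radius) from a [treatment_preset()].  Droplet
#' counts are log-normal around the preset median; radii follow the
#' three-component budding/growing/large mixture; placement distance from
#' the nucleus edge is exponential with the preset's peri-nuclear scale,
#' shrunk for larger radii so that large droplets sit nearer the nucleus.
#' Droplets are hard spheres: centres are rejected until no pair of
#' spheres overlaps (with a bounded number of attempts).  Cells are laid
#' out on a square grid of tiles sized to the largest cell.
#'
#' @param preset a one-row `ld_preset` tibble.
#' @param n_cells number of cells (>= 1).
#' @param seed integer seed fixing all randomness.
#' @param min_clearance_um extra minimum edge-to-edge clearance between
#'   droplets (um); 0 allows touching spheres.
#' @return a list of class `ld_truth` with tibbles `cells` (one row per
#'   cell: geometry, tile centre) and `droplets` (one row per droplet:
#'   `cell_id`, `x_um`, `y_um`, `z_um`, `r_um`), plus layout attributes.
#' @examples
#' tr <- sample_ground_truth(make_preset("control"), n_cells = 2, seed = 1)
#' nrow(tr$cells)
#' @export
sample_ground_truth <- function(preset, n_cells, seed,
                                min_clearance_um = 0) {
  stopifnot(inherits(preset, "ld_preset"))
  if (!is.numeric(n_cells) || n_cells < 1) {
    stop("n_cells must be a positive integer", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  set.seed(as.integer(seed))
  p <- as.list(preset[1, ])

  counts <- pmax(0L, as.integer(round(
    p$droplet_count_median * exp(stats::rnorm(n_cells, 0, p$cell_to_cell_dispersion))
  )))
  areas <- p$cell_area_median_um2 * exp(stats::rnorm(n_cells, 0, p$cell_area_sdlog))
  nuc_r <- p$nucleus_radius_median_um *
    exp(stats::rnorm(n_cells, 0, p$nucleus_radius_sdlog))

  # outline perturbations and base radii scaled to the sampled areas
  shapes <- vector("list", n_cells)
  base_r <- numeric(n_cells)
  theta_grid <- seq(0, 2 * pi, length.out = 721)[-721]
  for (i in seq_len(n_cells)) {
    a <- pmin(0.06, pmax(-0.06, stats::rnorm(3, 0, 0.035)))
    phi <- stats::runif(3, 0, 2 * pi)
    f <- cell_outline(a, phi)
    norm2 <- mean(f(theta_grid)^2)
    base_r[i] <- sqrt(areas[i] / (pi * norm2))
    shapes[[i]] <- list(a = a, phi = phi)
  }

  tile_um <- 2 * (max(base_r * 1.07) + 2)
  ncols <- ceiling(sqrt(n_cells))
  nrows <- ceiling(n_cells / ncols)
  col <- (seq_len(n_cells) - 1L) %% ncols
  row <- (seq_len(n_cells) - 1L) %/% ncols
  cx <- (col + 0.5) * tile_um
  cy <- (row + 0.5) * tile_um

  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    centre_x_um = cx, centre_y_um = cy,
    cell_area_um2 = areas, base_radius_um = base_r,
    nucleus_x_um = cx, nucleus_y_um = cy,
    nucleus_radius_um = nuc_r,
    n_droplets = counts,
    outline = shapes
  )

  drops <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    n <- counts[i]
    if (n == 0L) {
      drops[[i]] <- tibble::tibble(
        cell_id = integer(), x_um = numeric(), y_um = numeric(),
        z_um = numeric(), r_um = numeric()
      )
      next
    }
    radii <- sort(sample_radii(preset, n), decreasing = TRUE)
    f <- cell_outline(shapes[[i]]$a, shapes[[i]]$phi)
    acc_x <- acc_y <- acc_z <- acc_r <- numeric(n)
    placed <- 0L
    for (r in radii) {
      scale_r <- p$perinuclear_scale_um *
        exp(-RADIUS_BIAS_PER_UM * (r - p$growing_peak_mean_um))
      ok <- FALSE
      x <- y <- NA_real_; z <- Z_MID_UM
      for (batch in 1:4) {
        # propose a batch of peri-nuclear positions at once
        K <- 50L
        d <- stats::rexp(K, 1 / scale_r) + 0.02
        th <- stats::runif(K, 0, 2 * pi)
        radial <- nuc_r[i] + d
        xs <- cx[i] + radial * cos(th)
        ys <- cy[i] + radial * sin(th)
        zs <- Z_MID_UM + pmax(-Z_BAND_MAX_UM, pmin(Z_BAND_MAX_UM,
                                                   stats::rnorm(K, 0, Z_BAND_SD_UM)))
        # inside the cell footprint with margin for the droplet radius
        inside <- radial + r + 0.2 <= base_r[i] * f(th)
        for (j in which(inside)) {
          if (is.na(x)) { x <- xs[j]; y <- ys[j] }  # inside-cell fallback
          if (placed > 0L) {
            dd <- (acc_x[1:placed] - xs[j])^2 + (acc_y[1:placed] - ys[j])^2 +
              (acc_z[1:placed] - zs[j])^2
            if (any(dd < (acc_r[1:placed] + r + min_clearance_um)^2)) next
          }
          x <- xs[j]; y <- ys[j]; z <- zs[j]
          ok <- TRUE
          break
        }
        if (ok) break
      }
      if (is.na(x)) {
        # extremely crowded cell: place at the nucleus edge, contact allowed
        th1 <- stats::runif(1, 0, 2 * pi)
        x <- cx[i] + (nuc_r[i] + 0.1) * cos(th1)
        y <- cy[i] + (nuc_r[i] + 0.1) * sin(th1)
        z <- Z_MID_UM
      }
      placed <- placed + 1L
      acc_x[placed] <- x; acc_y[placed] <- y
      acc_z[placed] <- z; acc_r[placed] <- r
    }
    drops[[i]] <- tibble::tibble(
      cell_id = i, x_um = acc_x, y_um = acc_y, z_um = acc_z, r_um = acc_r
    )
  }

  structure(
    list(
      cells = cells,
      droplets = dplyr::bind_rows(drops),
      preset = preset,
      seed = as.integer(seed),
      tile_um = tile_um, ncols = ncols, nrows = nrows,
      z_mid_um = Z_MID_UM
    ),
    class = "ld_truth"
  )
}

#' @export
print.ld_truth <- function(x, ...) {
  cat(sprintf(
    "<ld_truth> %d cell(s), %d droplet(s) | preset '%s', seed %d\n",
    nrow(x$cells), nrow(x$droplets), x$preset$name, x$seed
  ))
  invisible(x)
}

#' Total ground-truth lipid volume
#'
#' Sum of (4/3) pi r^3 over the truth droplet list, per cell.
#'
#' @param truth an `ld_truth` object.
#' @return tibble with `cell_id`, `n_droplets`, `total_volume_um3`,
#'   `median_radius_um` (per-cell ground truth aggregates).
#' @export
truth_cell_summary <- function(truth) {
  base <- tibble::tibble(cell_id = truth$cells$cell_id)
  agg <- truth$droplets |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      n_droplets = dplyr::n(),
      total_volume_um3 = sum(4 / 3 * pi * .data$r_um^3),
      median_radius_um = stats::median(.data$r_um),
      .groups = "drop"
    )
  dplyr::left_join(base, agg, by = "cell_id") |>
    tidyr::replace_na(list(n_droplets = 0L, total_volume_um3 = 0))
}

# rasterise one cell's footprint / nucleus into a label matrix section
rasterise_cell <- function(cell, tile_um, pixel_size_um, nx, ny) {
  f <- cell_outline(cell$outline[[1]]$a, cell$outline[[1]]$phi)
  r_max <- cell$base_radius_um * 1.07
  ix0 <- max(0L, floor((cell$centre_x_um - r_max) / pixel_size_um))
  ix1 <- min(nx - 1L, ceiling((cell$centre_x_um + r_max) / pixel_size_um))
  iy0 <- max(0L, floor((cell$centre_y_um - r_max) / pixel_size_um))
  iy1 <- min(ny - 1L, ceiling((cell$centre_y_um + r_max) / pixel_size_um))
  xs <- (ix0:ix1) * pixel_size_um - cell$centre_x_um
  ys <- (iy0:iy1) * pixel_size_um - cell$centre_y_um
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  rad <- sqrt(X^2 + Y^2)
  ang <- atan2(Y, X)
  inside <- rad <= cell$base_radius_um * f(ang)
  nucleus <- sqrt((X + cell$centre_x_um - cell$nucleus_x_um)^2 +
                    (Y + cell$centre_y_um - cell$nucleus_y_um)^2) <=
    cell$nucleus_radius_um
  list(iy = (iy0:iy1) + 1L, ix = (ix0:ix1) + 1L,
       cell = inside, nucleus = nucleus & inside)
}

#' Render a ground-truth population into a calibrated image stack
#'
#' Droplets are rasterised as solid spheres with sub-voxel partial
#' intensity (each sphere's integrated expected signal equals its analytic
#' volume times the droplet brightness), convolved with the anisotropic
#' Gaussian PSF of `optics`, added to the background rate, Poisson-sampled,
#' and passed through the forward nonparalyzable dead-time map
#' `n_obs = n / (1 + n * tau / T)`.  Exact cell and nucleus label masks are
#' emitted alongside.
#'
#' @param truth an `ld_truth` from [sample_ground_truth()].
#' @param optics an [optics_model()].
#' @param seed integer seed for the photon noise.
#' @param noise draw Poisson counts (`TRUE`) or return expected counts
#'   (`FALSE`, also disables the dead-time map).
#' @param n_z number of z planes (default 25).
#' @return a list of class `ld_field`: `stack` (an [ld_stack()]),
#'   `cell_masks` and `nucleus_masks` (integer label matrices), and
#'   `truth`.
#' @export
render_stack <- function(truth, optics = optics_model(), seed = 1,
                         noise = TRUE, n_z = N_Z_DEFAULT) {
  stopifnot(inherits(truth, "ld_truth"), inherits(optics, "ld_optics"))
  dx <- optics$pixel_size_um; dz <- optics$z_step_um
  nx <- as.integer(round(truth$ncols * truth$tile_um / dx))
  ny <- as.integer(round(truth$nrows * truth$tile_um / dx))
  vox_vol <- dx * dx * dz

  if (nrow(truth$droplets) > 0) {
    max_ext <- max(truth$droplets$z_um + truth$droplets$r_um)
    if (max_ext > (n_z - 1) * dz + dz / 2) {
      warning("largest droplet extends beyond the top z plane; clipped")
    }
  }

  # Each droplet is rasterised (sub-voxel partial intensity; integrated
  # signal equals its analytic volume) and PSF-blurred on a local patch,
  # then accumulated into the field: the scene is sparse, so per-patch
  # convolution is much cheaper than blurring the whole field.
  expected <- array(0, c(ny, nx, n_z))
  off <- c(-1, 0, 1) / 3
  s_lat <- optics$psf_sigma_lateral_um / dx
  s_ax <- optics$psf_sigma_axial_um / dz
  pad_xy <- if (s_lat > 0) ceiling(4 * s_lat) + 1L else 1L
  pad_z <- if (s_ax > 0) ceiling(4 * s_ax) + 1L else 1L
  dr <- truth$droplets
  for (j in seq_len(nrow(dr))) {
    x <- dr$x_um[j]; y <- dr$y_um[j]; z <- dr$z_um[j]; r <- dr$r_um[j]
    ix <- (floor((x - r) / dx) - pad_xy):(ceiling((x + r) / dx) + pad_xy)
    iy <- (floor((y - r) / dx) - pad_xy):(ceiling((y + r) / dx) + pad_xy)
    iz <- (floor((z - r) / dz) - pad_z):(ceiling((z + r) / dz) + pad_z)
    cov <- array(0, c(length(iy), length(ix), length(iz)))
    for (oz in off) for (oy in off) for (ox in off) {
      dx2 <- ((ix + ox) * dx - x)^2
      dy2 <- ((iy + oy) * dx - y)^2
      dz2 <- ((iz + oz) * dz - z)^2
      inside <- outer(outer(dy2, dx2, `+`), dz2, `+`) <= r * r
      cov <- cov + inside
    }
    cov <- cov / 27
    s <- sum(cov)
    target_vox <- (4 / 3 * pi * r^3) / vox_vol
    if (s > 0) {
      cov <- cov * (target_vox / s)   # flux-conserving rasterisation
    } else {
      # sphere smaller than the subsample grid: all mass in nearest voxel
      cov[
        which.min(abs(iy * dx - y)), which.min(abs(ix * dx - x)),
        which.min(abs(iz * dz - z))
      ] <- target_vox
    }
    if (s_lat > 0 || s_ax > 0) {
      cov <- gaussian_blur3(cov, sigma_y = s_lat, sigma_x = s_lat,
                            sigma_z = s_ax)
    }
    # clip the patch to the field and accumulate
    kx <- ix >= 0L & ix <= nx - 1L
    ky <- iy >= 0L & iy <= ny - 1L
    kz <- iz >= 0L & iz <= n_z - 1L
    expected[iy[ky] + 1L, ix[kx] + 1L, iz[kz] + 1L] <-
      expected[iy[ky] + 1L, ix[kx] + 1L, iz[kz] + 1L] +
      cov[ky, kx, kz, drop = FALSE]
  }
  expected <- expected * optics$droplet_brightness + optics$background_rate

  if (noise) {
    set.seed(as.integer(seed))
    counts <- array(stats::rpois(length(expected), expected), dim(expected))
    if (optics$dead_time_s > 0) {
      ratio <- optics$dead_time_s / optics$dwell_time_s
      counts <- round(counts / (1 + counts * ratio))
      storage.mode(counts) <- "integer"   # halve the memory footprint
    }
    rm(expected)
  } else {
    counts <- expected
  }

  cell_masks <- matrix(0L, ny, nx)
  nucleus_masks <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(truth$cells))) {
    ras <- rasterise_cell(truth$cells[i, ], truth$tile_um, dx, nx, ny)
    sub <- cell_masks[ras$iy, ras$ix]
    sub[ras$cell] <- truth$cells$cell_id[i]
    cell_masks[ras$iy, ras$ix] <- sub
    subn <- nucleus_masks[ras$iy, ras$ix]
    subn[ras$nucleus] <- truth$cells$cell_id[i]
    nucleus_masks[ras$iy, ras$ix] <- subn
  }

  stack <- ld_stack(
    counts, pixel_size_um = dx, z_step_um = dz,
    dwell_time_s = optics$dwell_time_s,
    dead_time_s = if (noise) optics$dead_time_s else 0
  )
  structure(
    list(stack = stack, cell_masks = cell_masks,
         nucleus_masks = nucleus_masks, truth = truth, optics = optics),
    class = "ld_field"
  )
}

#' Simulate a population as a set of multi-cell fields
#'
#' Splits `n_cells` into fields of at most `cells_per_field` cells (as a
#' microscope would image several cells per field of view), sampling and
#' rendering each field with seeds derived from the master seed.
#'
#' @inheritParams sample_ground_truth
#' @inheritParams render_stack
#' @param cells_per_field cells per rendered field (default 9).
#' @return a list of class `ld_fieldset`: `fields` (list of `ld_field`),
#'   `truth_cells` and `truth_droplets` (row-bound ground truth with
#'   globally unique `cell_id`).
#' @export
simulate_fields <- function(preset, n_cells, seed,
                            optics = optics_model(),
                            cells_per_field = 9L, noise = TRUE,
                            n_z = N_Z_DEFAULT, min_clearance_um = 0) {
  n_fields <- ceiling(n_cells / cells_per_field)
  fields <- vector("list", n_fields)
  offset <- 0L
  all_cells <- list(); all_drops <- list()
  for (f in seq_len(n_fields)) {
    nf <- min(cells_per_field, n_cells - (f - 1L) * cells_per_field)
    s_truth <- (as.numeric(seed) + 7919 * f) %% 2147483647
    tr <- sample_ground_truth(preset, nf, seed = s_truth,
                              min_clearance_um = min_clearance_um)
    fld <- render_stack(tr, optics, seed = (s_truth + 1) %% 2147483647,
                        noise = noise, n_z = n_z)
    cells <- tr$cells; cells$cell_id <- cells$cell_id + offset
    drops <- tr$droplets
    if (nrow(drops) > 0) drops$cell_id <- drops$cell_id + offset
    cells$field <- f; if (nrow(drops) > 0) drops$field <- f
    all_cells[[f]] <- cells; all_drops[[f]] <- drops
    fld$cell_id_offset <- offset
    fields[[f]] <- fld
    offset <- offset + nf
  }
  structure(
    list(fields = fields,
         truth_cells = dplyr::bind_rows(all_cells),
         truth_droplets = dplyr::bind_rows(all_drops),
         preset = preset, seed = as.integer(seed)),
    class = "ld_fieldset"
  )
}
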