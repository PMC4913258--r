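# Field- and population-level analysis drivers tying the segmentation and
# morphometry operations together.

#' Default analysis parameters
#'
#' The droplet analysis uses distinct documented threshold operating
#' points: a per-cell *counting* threshold (Poisson background-quantile
#' detection — sensitive enough to catch faint sub-resolution droplets),
#' a field-pooled *sizing* threshold (the droplet-boundary rule:
#' background plus a PSF-derived fraction of the median droplet peak —
#' boundary-accurate for resolvable droplets), and a field-pooled
#' *volume* threshold (the same boundary fraction applied to the robust
#' droplet plateau over all in-footprint voxels, floored at the Poisson
#' detection level).  See the methods vignette for the rationale.
#'
#' @param counting_method threshold method for droplet counting
#'   (default `"poisson"`).
#' @param alpha_px per-pixel false-detection rate for the Poisson
#'   counting threshold.
#' @param sizing_method `"droplet_boundary"` (default), `"otsu_sqrt"`,
#'   `"otsu"` or `"fixed"`.
#' @param boundary_fraction for `"droplet_boundary"`: the sizing
#'   threshold is background + this fraction of the median droplet peak
#'   amplitude.  Default 1/3: the boundary isophote of a Gaussian-blurred
#'   sphere of radius ~3 PSF sigma lies at ~0.4 of its peak, reduced
#'   slightly for droplets sitting somewhat off the selected plane (see
#'   the methods vignette for the derivation).
#' @param sizing_fixed_value,volume_fixed_value thresholds in counts when
#'   the corresponding method is `"fixed"`.
#' @param volume_method threshold for the 3D volume analysis:
#'   `"droplet_boundary"` (default; background + `boundary_fraction` of
#'   the robust droplet plateau, the 95th percentile of above-floor
#'   voxels pooled over the field), `"otsu"` (field-pooled) or
#'   `"fixed"`.
#' @param min_seed_distance watershed seed suppression depth (px).
#' @param exclude_border drop border-touching cells from population
#'   statistics (default TRUE).
#' @return a named list of parameters.
#' @export
analysis_params <- function(counting_method = "poisson",
                            alpha_px = 1e-3,
                            sizing_method = "droplet_boundary",
                            boundary_fraction = 1 / 3,
                            sizing_fixed_value = NULL,
                            volume_method = "droplet_boundary",
                            volume_fixed_value = NULL,
                            min_seed_distance = 0.5,
                            exclude_border = TRUE) {
  list(
    counting_method = counting_method,
    alpha_px = alpha_px,
    sizing_method = sizing_method,
    boundary_fraction = boundary_fraction,
    sizing_fixed_value = sizing_fixed_value,
    volume_method = volume_method,
    volume_fixed_value = volume_fixed_value,
    min_seed_distance = min_seed_distance,
    exclude_border = exclude_border
  )
}

# First pass over a region: brightest plane, counting segmentation, and
# the quantities pooled thresholds are built from.
region_counting_pass <- function(region, params) {
  k0 <- select_brightest_plane(region)
  img <- region$substack$voxels[, , k0 + 1L]
  fg_cnt <- threshold_droplets(img, region$cell_mask,
                               method = params$counting_method,
                               fixed_value = params$sizing_fixed_value,
                               alpha_px = params$alpha_px %||% 1e-3)
  lab_cnt <- watershed_split(fg_cnt, params$min_seed_distance)
  idx <- which(lab_cnt > 0)
  peaks <- if (length(idx) > 0) {
    as.numeric(tapply(img[idx], lab_cnt[idx], max))
  } else {
    numeric()
  }
  mask_px <- img[region$cell_mask]
  list(
    plane_index = k0, img = img, n_count = max(lab_cnt),
    counting_threshold = attr(fg_cnt, "threshold"),
    bg = stats::median(mask_px), mask_px = mask_px, peaks = peaks
  )
}

# Field-pooled thresholds from the counting passes of all regions:
# sizing from the droplet-boundary rule (or Otsu variants on pooled
# brightest-plane pixels), volume from Otsu over all in-mask voxels
# (strided subsample for speed).
field_thresholds <- function(regions, params, passes = NULL) {
  sizing <- params$sizing_fixed_value
  volume <- params$volume_fixed_value
  if (is.null(passes)) {
    passes <- lapply(regions, region_counting_pass, params = params)
  }
  alpha <- params$alpha_px %||% 1e-3
  bg <- stats::median(vapply(passes, `[[`, numeric(1), "bg"))
  # never measure below the Poisson detection level: a cell population
  # with no detected droplets must not have its background split by Otsu
  floor_t <- stats::qpois(1 - alpha, bg)
  if (params$sizing_method == "droplet_boundary") {
    peaks <- unlist(lapply(passes, `[[`, "peaks"))
    # calibrate the boundary rule on unambiguous droplets only: peaks at
    # the detection floor are indistinguishable from background specks
    peaks <- peaks[peaks > stats::qpois(1 - alpha^2, bg)]
    sizing <- if (length(peaks) == 0) Inf else
      max(bg + params$boundary_fraction * (stats::median(peaks) - bg),
          floor_t)
  } else if (params$sizing_method %in% c("otsu", "otsu_sqrt")) {
    px <- unlist(lapply(passes, `[[`, "mask_px"))
    t_raw <- if (params$sizing_method == "otsu_sqrt") {
      otsu_threshold(sqrt(px))^2
    } else {
      otsu_threshold(px)
    }
    sizing <- if (is.na(t_raw)) Inf else max(t_raw, floor_t)
  }
  if (params$volume_method %in% c("droplet_boundary", "otsu")) {
    vx <- unlist(lapply(regions, function(rg) {
      v <- rg$substack$voxels[array(rg$cell_mask, dim(rg$substack$voxels))]
      v[seq(1, length(v), by = 7L)]
    }))
    bg_vox <- stats::median(vx)
    floor_vol <- stats::qpois(1 - alpha, bg_vox)
    if (params$volume_method == "droplet_boundary") {
      # plateau = robust high quantile of droplet (above-floor) voxels;
      # the boundary isophote sits at boundary_fraction of it
      above <- vx[vx > floor_vol]
      volume <- if (length(above) < 50) floor_vol else
        max(bg_vox + params$boundary_fraction *
              (stats::quantile(above, 0.95, names = FALSE) - bg_vox),
            floor_vol)
    } else {
      t_vol <- otsu_threshold(vx)
      volume <- if (is.na(t_vol)) floor_vol else max(t_vol, floor_vol)
    }
  }
  list(sizing = sizing, volume = volume)
}

#' Analyse one cell region
#'
#' Runs the 2D counting segmentation, the 2D sizing segmentation, and the
#' 3D volume segmentation on a single cell, returning droplet records and
#' the cell summary.
#'
#' @param region an `ld_region`.
#' @param sizing_threshold,volume_threshold thresholds in counts
#'   (computed per cell from `params` when `NULL`).
#' @param params an [analysis_params()] list.
#' @param pass a precomputed counting pass for this region (internal;
#'   computed when `NULL`).
#' @return list with `droplets` (tibble), `summary` (one-row tibble),
#'   `plane_index`, `thresholds`.
#' @export
analyze_region <- function(region, sizing_threshold = NULL,
                           volume_threshold = NULL,
                           params = analysis_params(), pass = NULL) {
  if (is.null(pass)) pass <- region_counting_pass(region, params)
  if (is.null(sizing_threshold) || is.null(volume_threshold)) {
    th <- field_thresholds(list(region), params, passes = list(pass))
    sizing_threshold <- sizing_threshold %||% th$sizing
    volume_threshold <- volume_threshold %||% th$volume
  }

  fg_size <- threshold_droplets(pass$img, region$cell_mask,
                                method = "fixed",
                                fixed_value = sizing_threshold)
  lab_size <- watershed_split(fg_size, params$min_seed_distance)
  droplets <- measure_droplets(lab_size, region,
                               plane_index = pass$plane_index)

  l3 <- label_3d(region, volume_threshold)

  list(
    droplets = droplets,
    summary = summarize_cell(droplets, l3, region,
                             droplet_count = pass$n_count),
    plane_index = pass$plane_index,
    thresholds = list(
      counting = pass$counting_threshold,
      sizing = sizing_threshold, volume = volume_threshold
    )
  )
}

#' Analyse a rendered field
#'
#' Splits a field into cell regions, computes field-pooled sizing and
#' volume thresholds, and analyses each cell.
#'
#' @param field an `ld_field` from [render_stack()] (preprocess it first
#'   with [preprocess_stack()] on `field$stack` if it contains raw
#'   counts).
#' @param params an [analysis_params()] list.
#' @param cell_id_offset added to cell ids (for multi-field runs).
#' @return list with `droplets`, `cells` (tibbles) and `report` (per-cell
#'   thresholds and plane indices).
#' @export
analyze_field <- function(field, params = analysis_params(),
                          cell_id_offset = 0L) {
  regions <- split_cells(field$stack, field$cell_masks,
                         field$nucleus_masks)
  if (length(regions) == 0) {
    return(list(droplets = tibble::tibble(), cells = tibble::tibble(),
                report = tibble::tibble()))
  }
  passes <- lapply(regions, region_counting_pass, params = params)
  th <- field_thresholds(regions, params, passes = passes)
  res <- purrr::map2(regions, passes, function(rg, p) {
    analyze_region(rg, sizing_threshold = th$sizing,
                   volume_threshold = th$volume, params = params, pass = p)
  })
  droplets <- dplyr::bind_rows(lapply(res, `[[`, "droplets"))
  cells <- dplyr::bind_rows(lapply(res, `[[`, "summary"))
  if (nrow(droplets) > 0) droplets$cell_id <- droplets$cell_id + cell_id_offset
  cells$cell_id <- cells$cell_id + cell_id_offset
  report <- tibble::tibble(
    cell_id = cells$cell_id,
    plane_index = vapply(res, `[[`, integer(1), "plane_index"),
    counting_threshold = vapply(res, function(r) r$thresholds$counting,
                                numeric(1)),
    sizing_threshold = th$sizing %||% NA_real_,
    volume_threshold = th$volume %||% NA_real_
  )
  list(droplets = droplets, cells = cells, report = report)
}

#' Simulate and analyse a treatment preset field by field
#'
#' Equivalent to [simulate_fields()] followed by [analyze_fieldset()]
#' (identical seeds and results), but each field is rendered, analysed
#' and discarded before the next is built, so memory stays bounded at a
#' single field regardless of population size.
#'
#' @inheritParams simulate_fields
#' @inheritParams analyze_fieldset
#' @return list with measurement tibbles `droplets`, `cells`, `report`
#'   and ground-truth tibbles `truth_cells`, `truth_droplets`.
#' @export
analyze_preset <- function(preset, n_cells, seed,
                           optics = optics_model(),
                           cells_per_field = 9L, noise = TRUE,
                           min_clearance_um = 0,
                           params = analysis_params(),
                           wavelet_levels = 3L, threshold_scale = 1.5,
                           denoise_stacks = TRUE) {
  n_fields <- ceiling(n_cells / cells_per_field)
  offset <- 0L
  outs <- vector("list", n_fields)
  all_cells <- list(); all_drops <- list()
  for (f in seq_len(n_fields)) {
    nf <- min(cells_per_field, n_cells - (f - 1L) * cells_per_field)
    s_truth <- (as.numeric(seed) + 7919 * f) %% 2147483647
    tr <- sample_ground_truth(preset, nf, seed = s_truth,
                              min_clearance_um = min_clearance_um)
    fld <- render_stack(tr, optics, seed = (s_truth + 1) %% 2147483647,
                        noise = noise)
    fld$stack <- preprocess_stack(
      fld$stack, wavelet_levels = wavelet_levels,
      threshold_scale = threshold_scale,
      denoise_stack = denoise_stacks && noise
    )
    res <- analyze_field(fld, params, cell_id_offset = offset)
    res$droplets$field <- f
    res$cells$field <- f
    outs[[f]] <- res
    cells <- tr$cells; cells$cell_id <- cells$cell_id + offset
    drops <- tr$droplets
    if (nrow(drops) > 0) drops$cell_id <- drops$cell_id + offset
    cells$field <- f; if (nrow(drops) > 0) drops$field <- f
    all_cells[[f]] <- cells; all_drops[[f]] <- drops
    offset <- offset + nf
    rm(fld, tr); gc(FALSE)
  }
  list(
    droplets = dplyr::bind_rows(lapply(outs, `[[`, "droplets")),
    cells = dplyr::bind_rows(lapply(outs, `[[`, "cells")),
    report = dplyr::bind_rows(lapply(outs, `[[`, "report")),
    truth_cells = dplyr::bind_rows(all_cells),
    truth_droplets = dplyr::bind_rows(all_drops)
  )
}

#' Preprocess and analyse a simulated field set
#'
#' For each field of an `ld_fieldset`: preprocess the stack (dead-time
#' correction, optional denoising, power normalisation), then run the
#' droplet analysis.  For large populations prefer [analyze_preset()],
#' which never holds more than one rendered field in memory.
#'
#' @param fieldset an `ld_fieldset` from [simulate_fields()].
#' @param params an [analysis_params()] list.
#' @param wavelet_levels,threshold_scale denoiser settings (see
#'   [denoise()]).
#' @param denoise_stacks apply the denoiser (default TRUE; turn off for
#'   noise-free renders).
#' @return list with tibbles `droplets`, `cells` and `report`.
#' @export
analyze_fieldset <- function(fieldset, params = analysis_params(),
                             wavelet_levels = 3L, threshold_scale = 1.5,
                             denoise_stacks = TRUE) {
  outs <- vector("list", length(fieldset$fields))
  for (i in seq_along(fieldset$fields)) {
    fld <- fieldset$fields[[i]]
    fld$stack <- preprocess_stack(
      fld$stack, wavelet_levels = wavelet_levels,
      threshold_scale = threshold_scale, denoise_stack = denoise_stacks
    )
    outs[[i]] <- analyze_field(fld, params,
                               cell_id_offset = fld$cell_id_offset)
    outs[[i]]$droplets$field <- i
    outs[[i]]$cells$field <- i
  }
  list(
    droplets = dplyr::bind_rows(lapply(outs, `[[`, "droplets")),
    cells = dplyr::bind_rows(lapply(outs, `[[`, "cells")),
    report = dplyr::bind_rows(lapply(outs, `[[`, "report"))
  )
}
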