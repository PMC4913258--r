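# Physical measurements of labelled droplets and per-cell summaries.

#' Equivalent-circle radius from an area
#'
#' `r = sqrt(area / pi)`: the radius of a circle with the measured area.
#' Used for droplets, nuclei and whole cells alike.
#'
#' @param area_um2 area(s) in um^2, > 0.
#' @return radius (um), vectorised.
#' @examples
#' radius_from_area(pi)   # 1
#' @export
radius_from_area <- function(area_um2) {
  if (any(area_um2 <= 0)) stop("area must be positive", call. = FALSE)
  sqrt(area_um2 / pi)
}

#' Droplet size classes
#'
#' Classifies radii into `budding` (r < 0.2 um), `growing`
#' (0.2 <= r <= 0.8 um) and `large` (r > 0.8 um).  The class boundaries
#' are assigned to the growing class (closed interval).
#'
#' @param r_um droplet radius/radii (um), > 0.
#' @param boundaries the two class boundaries (um), default `c(0.2, 0.8)`.
#' @return factor with levels `budding`, `growing`, `large`.
#' @examples
#' classify_size(c(0.15, 0.45, 1.0))
#' @export
classify_size <- function(r_um, boundaries = c(0.2, 0.8)) {
  stopifnot(length(boundaries) == 2, boundaries[1] < boundaries[2])
  if (any(r_um <= 0)) stop("radii must be positive", call. = FALSE)
  cls <- ifelse(r_um < boundaries[1], "budding",
                ifelse(r_um > boundaries[2], "large", "growing"))
  factor(cls, levels = c("budding", "growing", "large"))
}

# inner-boundary pixel centres of a logical mask, in local um coordinates
mask_boundary_um <- function(mask, pixel_size_um) {
  ny <- nrow(mask); nx <- ncol(mask)
  pad <- matrix(FALSE, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- mask
  core <- pad[2:(ny + 1L), 2:(nx + 1L)]
  interior <- core &
    pad[1:ny, 2:(nx + 1L)] & pad[3:(ny + 2L), 2:(nx + 1L)] &
    pad[2:(ny + 1L), 1:nx] & pad[2:(ny + 1L), 3:(nx + 2L)]
  idx <- which(core & !interior, arr.ind = TRUE)
  cbind(x = (idx[, 2] - 1) * pixel_size_um,
        y = (idx[, 1] - 1) * pixel_size_um)
}

#' Distance from droplet centroids to the nucleus edge
#'
#' In-plane Euclidean distance from each centroid to the nearest nucleus
#' boundary pixel centre; 0 for centroids falling inside the nucleus mask.
#'
#' @param x_um,y_um centroid coordinates (um), in the same local frame as
#'   the mask (pixel `i` 0-based at `i * pixel_size_um`).
#' @param nucleus_mask logical nucleus mask.
#' @param pixel_size_um lateral pixel size (um).
#' @return numeric vector of distances (um).
#' @export
distance_to_nucleus_edge <- function(x_um, y_um, nucleus_mask,
                                     pixel_size_um) {
  if (sum(nucleus_mask) == 0) stop("empty nucleus mask", call. = FALSE)
  bd <- mask_boundary_um(nucleus_mask, pixel_size_um)
  n <- length(x_um)
  out <- numeric(n)
  ix <- pmin(ncol(nucleus_mask), pmax(1L, round(x_um / pixel_size_um) + 1L))
  iy <- pmin(nrow(nucleus_mask), pmax(1L, round(y_um / pixel_size_um) + 1L))
  inside <- nucleus_mask[cbind(iy, ix)]
  for (i in seq_len(n)) {
    if (inside[i]) next
    out[i] <- sqrt(min((bd[, 1] - x_um[i])^2 + (bd[, 2] - y_um[i])^2))
  }
  out
}

#' Measure droplets from a 2D label image
#'
#' Computes, per label: area, equivalent-circle radius, size class,
#' centroid, and distance from the centroid to the nucleus edge.
#'
#' @param labels2d integer label matrix from [watershed_split()].
#' @param region the `ld_region` the labels belong to.
#' @param plane_index 0-based z index the labels were computed on.
#' @return a tibble with one row per droplet: `cell_id`, `label`,
#'   `x_um`, `y_um` (local to the region crop), `area_um2`, `r_um`,
#'   `size_class`, `nuc_dist_um`, `plane_index`.
#' @export
measure_droplets <- function(labels2d, region, plane_index = NA_integer_) {
  px <- region$substack$pixel_size_um
  n <- max(labels2d)
  if (n == 0) {
    return(tibble::tibble(
      cell_id = integer(), label = integer(), x_um = numeric(),
      y_um = numeric(), area_um2 = numeric(), r_um = numeric(),
      size_class = factor(character(), c("budding", "growing", "large")),
      nuc_dist_um = numeric(), plane_index = integer()
    ))
  }
  idx <- which(labels2d > 0)
  lab <- labels2d[idx]
  rows <- (idx - 1L) %% nrow(labels2d)       # 0-based
  cols <- (idx - 1L) %/% nrow(labels2d)
  areas <- tabulate(lab, nbins = n)
  cx <- rowsum(cols, lab)[, 1] / areas * px
  cy <- rowsum(rows, lab)[, 1] / areas * px
  area_um2 <- areas * px^2
  r <- radius_from_area(area_um2)
  nd <- if (sum(region$nucleus_mask) > 0) {
    distance_to_nucleus_edge(cx, cy, region$nucleus_mask, px)
  } else {
    rep(NA_real_, n)
  }
  tibble::tibble(
    cell_id = region$cell_id, label = seq_len(n),
    x_um = unname(cx), y_um = unname(cy),
    area_um2 = area_um2, r_um = r, size_class = classify_size(r),
    nuc_dist_um = nd, plane_index = as.integer(plane_index)
  )
}

#' Per-cell summary of droplet measurements
#'
#' Aggregates a cell's droplet records and 3D volumes into the per-cell
#' quantities used for population statistics.  Droplet count comes from
#' the 2D watershed analysis; total lipid volume from the 3D
#' connected-component voxel counts (`voxel_count * pixel^2 * z-step`);
#' cell and nucleus radii from their mask areas via [radius_from_area()].
#'
#' @param droplets droplet tibble from [measure_droplets()] (one cell).
#' @param labels3d an `ld_labels3d` from [label_3d()] for the same cell
#'   (or `NULL` for 2D-only analyses).
#' @param region the `ld_region`.
#' @param droplet_count droplet count to record; defaults to
#'   `nrow(droplets)` but may come from a more sensitive counting
#'   segmentation.
#' @return one-row tibble: `cell_id`, `droplet_count`,
#'   `total_volume_um3`, `median_radius_um`, `cell_area_um2`,
#'   `cell_radius_um`, `nucleus_radius_um`, `border`.
#' @export
summarize_cell <- function(droplets, labels3d = NULL, region,
                           droplet_count = nrow(droplets)) {
  px <- region$substack$pixel_size_um
  vox <- voxel_volume_um3(region$substack)
  cell_area <- sum(region$cell_mask) * px^2
  nuc_area <- sum(region$nucleus_mask) * px^2
  tibble::tibble(
    cell_id = region$cell_id,
    droplet_count = as.integer(droplet_count),
    total_volume_um3 = if (is.null(labels3d)) NA_real_ else
      sum(labels3d$voxel_counts) * vox,
    median_radius_um = if (nrow(droplets) == 0) NA_real_ else
      stats::median(droplets$r_um),
    cell_area_um2 = cell_area,
    cell_radius_um = radius_from_area(cell_area),
    nucleus_radius_um = if (nuc_area > 0) radius_from_area(nuc_area)
      else NA_real_,
    border = region$border
  )
}
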