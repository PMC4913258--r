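# Partition stacks into single cells and segment droplets per cell,
# in 2D (counts/areas/centroids) and 3D (volumes).

#' Split a multi-cell stack into single-cell regions
#'
#' Crops the stack to each labelled cell footprint, zeroing voxels outside
#' the footprint, and pairs it with the matching nucleus mask.  Cells whose
#' bounding box touches the image border are flagged (and excluded from
#' population statistics by default downstream).
#'
#' @param stack an [ld_stack()].
#' @param cell_masks integer label matrix of cell footprints (0 =
#'   background), same y/x dimensions as the stack.
#' @param nucleus_masks integer label matrix of nuclei, labels matching
#'   `cell_masks`.
#' @return a list of `ld_region` objects (fields: `cell_id`, `cell_mask`,
#'   `nucleus_mask`, `substack`, `border`, `origin_px` 0-based y/x offset
#'   of the crop).
#' @export
split_cells <- function(stack, cell_masks, nucleus_masks) {
  stopifnot(inherits(stack, "ld_stack"),
            all(dim(cell_masks) == dim(stack$voxels)[1:2]),
            all(dim(nucleus_masks) == dim(cell_masks)))
  cell_ids <- sort(setdiff(unique(as.integer(cell_masks)), 0L))
  nuc_ids <- setdiff(unique(as.integer(nucleus_masks)), 0L)
  orphan <- setdiff(nuc_ids, cell_ids)
  if (length(orphan) > 0) {
    stop("nucleus label(s) with no matching cell: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  lapply(cell_ids, function(id) {
    sel <- cell_masks == id
    rows <- range(which(rowSums(sel) > 0))
    cols <- range(which(colSums(sel) > 0))
    cmask <- sel[rows[1]:rows[2], cols[1]:cols[2]]
    nmask <- (nucleus_masks == id)[rows[1]:rows[2], cols[1]:cols[2]]
    sub <- stack$voxels[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
    sub <- sub * array(cmask, dim(sub))  # zero outside the footprint
    substack <- stack
    substack$voxels <- sub
    border <- rows[1] == 1L || cols[1] == 1L ||
      rows[2] == nrow(cell_masks) || cols[2] == ncol(cell_masks)
    structure(
      list(cell_id = id, cell_mask = cmask, nucleus_mask = nmask,
           substack = substack, border = border,
           origin_px = c(y = rows[1] - 1L, x = cols[1] - 1L)),
      class = "ld_region"
    )
  })
}

#' @export
print.ld_region <- function(x, ...) {
  cat(sprintf(
    "<ld_region> cell %d | %d x %d px footprint (%.0f um^2), %s\n",
    x$cell_id, ncol(x$cell_mask), nrow(x$cell_mask),
    sum(x$cell_mask) * x$substack$pixel_size_um^2,
    if (x$border) "touches border" else "interior"
  ))
  invisible(x)
}

#' Index of the brightest z plane of a cell region
#'
#' Returns the 0-based z index maximising total in-footprint intensity;
#' ties break toward the lower index.
#'
#' @param region an `ld_region` from [split_cells()].
#' @return integer 0-based plane index.
#' @export
select_brightest_plane <- function(region) {
  v <- region$substack$voxels
  stopifnot(dim(v)[3] >= 1)
  sums <- apply(v * array(region$cell_mask, dim(v)), 3, sum)
  which.max(sums) - 1L   # which.max takes the first (lowest) maximum
}

# Otsu threshold of a numeric vector via a 256-bin histogram; NA if flat.
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(NA_real_)
  h <- tabulate(
    pmin(n_bins, 1L + floor((values - rng[1]) / diff(rng) * n_bins)),
    nbins = n_bins
  )
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  between <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Threshold droplet candidate pixels within a cell
#'
#' Computes a threshold from the intensities inside the cell mask only and
#' returns the binary foreground.  Methods:
#' * `"otsu"`: Otsu's between-class-variance threshold on the intensity
#'   histogram.
#' * `"otsu_sqrt"`: Otsu on the variance-stabilised `sqrt(I)` scale — the
#'   natural scale for photon counts; lands at a lower, boundary-accurate
#'   operating point than linear Otsu (used for droplet sizing).
#' * `"otsu_log"`: Otsu on `log2(1 + I)` — an even more sensitive
#'   operating point for strongly unbalanced histograms.
#' * `"poisson"`: background quantile detection — the threshold is the
#'   smallest count that pure Poisson background (rate = in-mask median)
#'   would exceed with probability below `alpha_px` per pixel; the
#'   sensitive operating point used for droplet counting.
#' * `"fixed"`: a user-supplied threshold in counts.
#'
#' A flat (no-contrast) image yields an empty foreground with a warning.
#'
#' @param image numeric matrix (one z plane).
#' @param mask logical matrix restricting the threshold computation (e.g.
#'   the cell footprint); default uses the whole image.
#' @param method `"otsu"`, `"otsu_sqrt"`, `"otsu_log"`, `"poisson"` or
#'   `"fixed"`.
#' @param fixed_value threshold in counts for `method = "fixed"`.
#' @param alpha_px per-pixel false-detection rate for
#'   `method = "poisson"` (default 1e-3).
#' @return logical foreground matrix with attributes `threshold` and
#'   `method`.
#' @export
threshold_droplets <- function(image, mask = NULL,
                               method = c("otsu", "otsu_sqrt", "otsu_log",
                                          "poisson", "fixed"),
                               fixed_value = NULL, alpha_px = 1e-3) {
  method <- match.arg(method)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  vals <- image[mask]
  if (length(vals) == 0) stop("empty cell mask", call. = FALSE)
  t <- switch(method,
    otsu = otsu_threshold(vals),
    otsu_sqrt = {
      ts <- otsu_threshold(sqrt(vals))
      if (is.na(ts)) NA_real_ else ts^2
    },
    otsu_log = {
      tl <- otsu_threshold(log2(vals + 1))
      if (is.na(tl)) NA_real_ else 2^tl - 1
    },
    poisson = {
      if (diff(range(vals)) == 0) NA_real_
      else stats::qpois(1 - alpha_px, stats::median(vals))
    },
    fixed = {
      if (is.null(fixed_value)) {
        stop("fixed_value required for method = 'fixed'", call. = FALSE)
      }
      fixed_value
    }
  )
  if (is.na(t)) {
    warning("flat image: no contrast inside the mask; empty foreground")
    fg <- matrix(FALSE, nrow(image), ncol(image))
    t <- Inf
  } else {
    fg <- image > t & mask
  }
  attr(fg, "threshold") <- t
  attr(fg, "method") <- method
  fg
}

#' Separate touching droplets by distance-transform watershed
#'
#' Splits connected foreground blobs at saddle points of the Euclidean
#' distance transform, so adjacent droplets are counted separately.  Every
#' foreground pixel receives exactly one label, hence total area is
#' conserved exactly.  Shallow distance maxima are suppressed: a candidate
#' seed must rise at least `min_seed_distance` pixels (in distance units)
#' above the saddle connecting it to a neighbouring object, which prevents
#' over-segmentation of bumpy blobs.
#'
#' @param mask logical (or 0/1) matrix of droplet foreground.
#' @param min_seed_distance h-maximum suppression depth in pixels
#'   (default 1).
#' @return integer label matrix (labels contiguous from 1, 0 =
#'   background).
#' @export
watershed_split <- function(mask, min_seed_distance = 1) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  if (sum(m) == 0) {
    return(matrix(0L, nrow(mask), ncol(mask)))
  }
  d <- EBImage::distmap(m)
  w <- EBImage::watershed(d, tolerance = min_seed_distance, ext = 1L)
  lab <- EBImage::imageData(w)[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  storage.mode(lab) <- "integer"
  # contiguous relabelling from 1
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    lab <- matrix(match(lab, ids, nomatch = 0L) , nrow(lab), ncol(lab))
    storage.mode(lab) <- "integer"
  }
  lab
}

# 26-neighbourhood linear offsets in a padded (ny, nx, nz) array
offsets26 <- function(ny, nx) {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  as.integer(g$dy + g$dx * ny + g$dz * ny * nx)
}

#' 3D connected-component labelling of thresholded droplets
#'
#' Labels the voxels above `threshold` with 26-connectivity.  No minimum
#' object size is imposed: single-voxel droplets are kept.
#'
#' @param x an `ld_region`, [ld_stack()] or 3D array.
#' @param threshold counts threshold (>= 0); foreground is `x > threshold`.
#' @return a list of class `ld_labels3d`: `labels` (integer array),
#'   `voxel_counts` (per-label voxel counts), `threshold`.
#' @export
label_3d <- function(x, threshold) {
  stopifnot(threshold >= 0)
  v <- if (inherits(x, "ld_region")) x$substack$voxels
       else if (inherits(x, "ld_stack")) x$voxels
       else x
  stopifnot(is.array(v), length(dim(v)) == 3L)
  d <- dim(v)
  ny <- d[1] + 2L; nx <- d[2] + 2L; nz <- d[3] + 2L
  fg <- array(FALSE, c(ny, nx, nz))
  fg[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- v > threshold
  offs <- offsets26(ny, nx)
  lab <- integer(ny * nx * nz)
  fgv <- as.logical(fg)
  seeds <- which(fgv)
  n_comp <- 0L
  ptr <- 1L
  counts <- integer(0)
  while (ptr <= length(seeds)) {
    s <- seeds[ptr]; ptr <- ptr + 1L
    if (lab[s] != 0L) next
    n_comp <- n_comp + 1L
    lab[s] <- n_comp
    size <- 1L
    frontier <- s
    while (length(frontier) > 0) {
      cand <- rep(frontier, each = 26L) + offs
      cand <- unique(cand[fgv[cand] & lab[cand] == 0L])
      if (length(cand) == 0) break
      lab[cand] <- n_comp
      size <- size + length(cand)
      frontier <- cand
    }
    counts[n_comp] <- size
  }
  lab <- array(lab, c(ny, nx, nz))[
    2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE
  ]
  structure(
    list(labels = lab, voxel_counts = counts, threshold = threshold),
    class = "ld_labels3d"
  )
}

#' @export
print.ld_labels3d <- function(x, ...) {
  cat(sprintf("<ld_labels3d> %d object(s) above threshold %.3g\n",
              length(x$voxel_counts), x$threshold))
  invisible(x)
}
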