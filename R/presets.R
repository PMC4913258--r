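#' Imaging model for the synthetic renderer
#'
#' Describes the measurement physics used by [render_stack()]: voxel
#' calibration, Gaussian point-spread function, background rate, droplet
#' brightness, and the photon-counting detector's dwell and dead times.
#'
#' Defaults correspond to coherent Raman imaging with a 1.3-NA oil
#' objective detected at 663 nm: lateral pixel size 0.098 um, axial step
#' 0.3 um, pixel dwell 9.6 us.  The PSF sigmas reflect the effective
#' multiplicative (pump-squared times Stokes) excitation volume, which is
#' somewhat sharper than the one-photon diffraction limit: sigma 0.12 um
#' lateral and 0.30 um axial.  All fields are configurable.
#'
#' @param pixel_size_um lateral pixel size (um), > 0.
#' @param z_step_um axial plane spacing (um), > 0.
#' @param psf_sigma_lateral_um,psf_sigma_axial_um Gaussian PSF sigmas (um);
#'   0 disables blurring along that axis.
#' @param background_rate expected background counts per voxel, >= 0.
#' @param droplet_brightness expected counts per voxel fully inside a
#'   droplet (before PSF/noise), >= 0.
#' @param dwell_time_s pixel dwell time (s).
#' @param dead_time_s nonparalyzable detector dead time (s); 0 disables
#'   the saturation map.
#' @return a list of class `ld_optics`.
#' @export
optics_model <- function(pixel_size_um = 0.098, z_step_um = 0.3,
                         psf_sigma_lateral_um = 0.12,
                         psf_sigma_axial_um = 0.30,
                         background_rate = 0.3, droplet_brightness = 60,
                         dwell_time_s = 9.6e-6, dead_time_s = 1e-7) {
  stopifnot(
    pixel_size_um > 0, z_step_um > 0,
    psf_sigma_lateral_um >= 0, psf_sigma_axial_um >= 0,
    background_rate >= 0, droplet_brightness >= 0,
    dwell_time_s > 0, dead_time_s >= 0, dead_time_s < dwell_time_s
  )
  structure(
    list(
      pixel_size_um = pixel_size_um, z_step_um = z_step_um,
      psf_sigma_lateral_um = psf_sigma_lateral_um,
      psf_sigma_axial_um = psf_sigma_axial_um,
      background_rate = background_rate,
      droplet_brightness = droplet_brightness,
      dwell_time_s = dwell_time_s, dead_time_s = dead_time_s
    ),
    class = "ld_optics"
  )
}

# ---- droplet radius mixture -------------------------------------------------
#
# Three components on (0, r_max]:
#   budding: half-normal(sd = budding_sd) truncated to (budding_min, 0.2]
#   growing: normal(growing_mean, growing_sd) truncated to (0.2, 0.8]
#   large:   0.8 + Exponential(scale = tail_scale) truncated to (0.8, r_max]
# Class boundaries 0.2 and 0.8 um are the budding/growing/large limits.

mixture_pars <- function(preset) {
  p <- as.list(preset[1, ])
  list(
    w_b = p$budding_weight, w_l = p$large_weight,
    w_g = 1 - p$budding_weight - p$large_weight,
    b_sd = p$budding_sd_um, b_min = p$budding_min_um,
    g_mu = p$growing_peak_mean_um, g_sd = p$growing_peak_sd_um,
    tail = p$large_tail_scale_um, r_max = p$r_max_um
  )
}

# component CDFs (vectorised in x)
cdf_budding <- function(x, b_sd, b_min) {
  lo <- stats::pnorm(b_min / b_sd); hi <- stats::pnorm(0.2 / b_sd)
  pmin(1, pmax(0, (stats::pnorm(pmin(x, 0.2) / b_sd) - lo) / (hi - lo))) *
    (x > b_min)
}
cdf_growing <- function(x, g_mu, g_sd) {
  lo <- stats::pnorm(0.2, g_mu, g_sd); hi <- stats::pnorm(0.8, g_mu, g_sd)
  pmin(1, pmax(0, (stats::pnorm(pmin(x, 0.8), g_mu, g_sd) - lo) / (hi - lo))) *
    (x > 0.2)
}
cdf_large <- function(x, tail, r_max) {
  cmax <- 1 - exp(-(r_max - 0.8) / tail)
  pmin(1, pmax(0, (1 - exp(-pmax(0, pmin(x, r_max) - 0.8) / tail)) / cmax))
}

mixture_cdf <- function(x, mp) {
  mp$w_b * cdf_budding(x, mp$b_sd, mp$b_min) +
    mp$w_g * cdf_growing(x, mp$g_mu, mp$g_sd) +
    mp$w_l * cdf_large(x, mp$tail, mp$r_max)
}

# component quantile functions (p in [0,1])
q_budding <- function(p, b_sd, b_min) {
  lo <- stats::pnorm(b_min / b_sd); hi <- stats::pnorm(0.2 / b_sd)
  b_sd * stats::qnorm(lo + p * (hi - lo))
}
q_growing <- function(p, g_mu, g_sd) {
  lo <- stats::pnorm(0.2, g_mu, g_sd); hi <- stats::pnorm(0.8, g_mu, g_sd)
  stats::qnorm(lo + p * (hi - lo), g_mu, g_sd)
}
q_large <- function(p, tail, r_max) {
  cmax <- 1 - exp(-(r_max - 0.8) / tail)
  0.8 - tail * log(1 - p * cmax)
}

# E[r^3] of the mixture (um^3 before the 4/3 pi factor)
mixture_moment3 <- function(mp) {
  m3 <- function(q, ...) {
    stats::integrate(function(p) q(p, ...)^3, 0, 1, rel.tol = 1e-9)$value
  }
  mp$w_b * m3(q_budding, mp$b_sd, mp$b_min) +
    mp$w_g * m3(q_growing, mp$g_mu, mp$g_sd) +
    mp$w_l * m3(q_large, mp$tail, mp$r_max)
}

# Mean single-droplet volume (um^3) implied by a preset's mixture.
preset_mean_droplet_volume <- function(preset) {
  4 / 3 * pi * mixture_moment3(mixture_pars(preset))
}

# Solve the large-tail scale so that count_median * E[v] = volume target.
solve_tail_scale <- function(target_mean_v, w_b, w_l, g_mu, g_sd,
                             b_sd, b_min, r_max) {
  f <- function(s) {
    mp <- list(w_b = w_b, w_l = w_l, w_g = 1 - w_b - w_l, b_sd = b_sd,
               b_min = b_min, g_mu = g_mu, g_sd = g_sd, tail = s,
               r_max = r_max)
    4 / 3 * pi * mixture_moment3(mp) - target_mean_v
  }
  lo <- 0.02; hi <- 30
  if (f(lo) >= 0) return(lo)  # target below feasible floor: thinnest tail
  if (f(hi) <= 0) {
    stop("volume target infeasible for this radius mixture", call. = FALSE)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
}

#' Construct a treatment preset for the synthetic generator
#'
#' A preset packages the population targets one treatment condition should
#' reproduce: the median droplet count per cell, the three-component radius
#' mixture (budding / growing / large, with class boundaries at 0.2 and
#' 0.8 um), the peri-nuclear placement scale, and cell/nucleus geometry.
#' The large-tail scale is calibrated so that the expected total lipid
#' volume per median cell matches `total_volume_target_um3` (unless that
#' target is infeasibly small for the mixture, in which case the thinnest
#' tail is used and the implied volume recorded).
#'
#' @param name preset label.
#' @param droplet_count_median median droplets per cell (>= 0).
#' @param total_volume_target_um3 target median total lipid volume per cell
#'   (um^3); `NA` to skip calibration and give `large_tail_scale_um`.
#' @param budding_weight,large_weight mixture weights in `[0, 1]`, summing
#'   to at most 1 (the remainder is the growing weight).
#' @param growing_peak_mean_um,growing_peak_sd_um truncated-Gaussian
#'   parameters of the growing component on (0.2, 0.8] um.
#' @param nucleus_distance_median_um target median droplet-to-nucleus-edge
#'   distance (um).
#' @param cell_area_median_um2,nucleus_radius_median_um cell geometry
#'   medians.
#' @param cell_to_cell_dispersion log-normal sdlog of per-cell droplet
#'   count.
#' @param large_tail_scale_um exponential tail scale (um); calibrated from
#'   the volume target when that is given.
#' @param budding_sd_um,budding_min_um half-normal scale and lower cut of
#'   the budding component (um).
#' @param r_max_um hard upper truncation of droplet radii (um).
#' @param cell_area_sdlog,nucleus_radius_sdlog log-normal dispersions of
#'   the cell geometry.
#' @return a one-row tibble of class `ld_preset`.
#' @seealso [make_preset()] for the four named treatment conditions.
#' @export
treatment_preset <- function(name, droplet_count_median,
                             total_volume_target_um3 = NA,
                             budding_weight, large_weight,
                             growing_peak_mean_um, growing_peak_sd_um,
                             nucleus_distance_median_um,
                             cell_area_median_um2, nucleus_radius_median_um,
                             cell_to_cell_dispersion = 0.25,
                             large_tail_scale_um = 0.25,
                             budding_sd_um = 0.10, budding_min_um = 0.05,
                             r_max_um = 2.5,
                             cell_area_sdlog = 0.15,
                             nucleus_radius_sdlog = 0.06) {
  stopifnot(
    droplet_count_median >= 0,
    budding_weight >= 0, budding_weight <= 1,
    large_weight >= 0, large_weight <= 1,
    budding_weight + large_weight <= 1,
    growing_peak_mean_um > 0, growing_peak_sd_um > 0,
    nucleus_distance_median_um > 0, cell_area_median_um2 > 0,
    nucleus_radius_median_um > 0, cell_to_cell_dispersion >= 0,
    budding_sd_um > 0, budding_min_um > 0, r_max_um > 0.8
  )
  if (!is.na(total_volume_target_um3) && droplet_count_median > 0) {
    large_tail_scale_um <- solve_tail_scale(
      total_volume_target_um3 / droplet_count_median,
      budding_weight, large_weight, growing_peak_mean_um,
      growing_peak_sd_um, budding_sd_um, budding_min_um, r_max_um
    )
  }
  out <- tibble::tibble(
    name = name,
    droplet_count_median = droplet_count_median,
    total_volume_target_um3 = total_volume_target_um3,
    budding_weight = budding_weight,
    large_weight = large_weight,
    growing_peak_mean_um = growing_peak_mean_um,
    growing_peak_sd_um = growing_peak_sd_um,
    large_tail_scale_um = large_tail_scale_um,
    budding_sd_um = budding_sd_um,
    budding_min_um = budding_min_um,
    r_max_um = r_max_um,
    perinuclear_scale_um = nucleus_distance_median_um / log(2),
    nucleus_distance_median_um = nucleus_distance_median_um,
    cell_area_median_um2 = cell_area_median_um2,
    nucleus_radius_median_um = nucleus_radius_median_um,
    cell_to_cell_dispersion = cell_to_cell_dispersion,
    cell_area_sdlog = cell_area_sdlog,
    nucleus_radius_sdlog = nucleus_radius_sdlog
  )
  # record the volume actually implied by the calibrated mixture
  out$implied_volume_um3 <- droplet_count_median *
    preset_mean_droplet_volume(out)
  class(out) <- c("ld_preset", class(tibble::tibble()))
  out
}

#' Named treatment presets
#'
#' Returns the calibrated generator preset for one of the four treatment
#' conditions of the differentiated-HepaRG lipid accumulation experiment:
#'
#' * `control`: untreated; median 7 droplets per cell (from the ~30-fold
#'   count increase of the combined treatment over control), radius median
#'   0.22 um, 2.7% large droplets.
#' * `entinostat`: HDAC-inhibitor treatment; median 121 droplets,
#'   103 um^3 median total lipid volume, 2.7% large droplets, growing peak
#'   near 0.40 um, median nucleus distance 6.4 um.
#' * `oleate`: fatty-acid overload; median 96 droplets, 152 um^3,
#'   7.9% large droplets, median nucleus distance 8.0 um, smaller cells
#'   (990 um^2).
#' * `combined`: both treatments; median 199 droplets, 536 um^3,
#'   78.3% growing / 13.3% large, growing peak near 0.45 um.
#'
#' The control volume is mixture-implied rather than the naive
#' 536/2000 um^3, because a 2.7% large-droplet fraction already
#' contributes more volume per droplet than that figure allows; the
#' printed radius-distribution statistics take precedence.  The control
#' budding weight is solved so the mixture's median radius is 0.22 um.
#'
#' @param name one of `"control"`, `"entinostat"`, `"oleate"`,
#'   `"combined"`.
#' @return a one-row tibble of class `ld_preset`.
#' @examples
#' make_preset("combined")$droplet_count_median  # 199
#' @export
make_preset <- function(name) {
  valid <- c("control", "entinostat", "oleate", "combined")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown preset; valid options are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  switch(name,
    control = {
      # solve budding weight for a mixture median radius of 0.22 um
      g_mu <- 0.38; g_sd <- 0.13; w_l <- 0.027
      fg <- cdf_growing(0.22, g_mu, g_sd)
      w_b <- stats::uniroot(
        function(w) w + (1 - w - w_l) * fg - 0.5, c(0.05, 0.95)
      )$root
      treatment_preset(
        "control", droplet_count_median = 7,
        total_volume_target_um3 = NA, large_tail_scale_um = 0.2,
        budding_weight = w_b, large_weight = w_l,
        growing_peak_mean_um = g_mu, growing_peak_sd_um = g_sd,
        nucleus_distance_median_um = 6.6,
        cell_area_median_um2 = 1200, nucleus_radius_median_um = 6.5,
        cell_to_cell_dispersion = 0.45
      )
    },
    entinostat = treatment_preset(
      "entinostat", droplet_count_median = 121,
      total_volume_target_um3 = 103,
      budding_weight = 0.12, large_weight = 0.027,
      growing_peak_mean_um = 0.40, growing_peak_sd_um = 0.10,
      nucleus_distance_median_um = 6.4,
      cell_area_median_um2 = 1484, nucleus_radius_median_um = 6.7,
      cell_to_cell_dispersion = 0.20
    ),
    oleate = treatment_preset(
      "oleate", droplet_count_median = 96,
      total_volume_target_um3 = 152,
      budding_weight = 0.12, large_weight = 0.079,
      growing_peak_mean_um = 0.40, growing_peak_sd_um = 0.12,
      nucleus_distance_median_um = 8.0,
      cell_area_median_um2 = 990, nucleus_radius_median_um = 6.4,
      cell_to_cell_dispersion = 0.35
    ),
    combined = treatment_preset(
      "combined", droplet_count_median = 199,
      total_volume_target_um3 = 536,
      budding_weight = 1 - 0.783 - 0.133, large_weight = 0.133,
      growing_peak_mean_um = 0.45, growing_peak_sd_um = 0.10,
      nucleus_distance_median_um = 6.8,
      cell_area_median_um2 = 1427, nucleus_radius_median_um = 6.5,
      cell_to_cell_dispersion = 0.20
    )
  )
}

# Draw n radii from a preset's mixture (uses the current RNG stream).
sample_radii <- function(preset, n) {
  mp <- mixture_pars(preset)
  if (n == 0) return(numeric())
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(mp$w_b, mp$w_g, mp$w_l))
  u <- stats::runif(n)
  r <- numeric(n)
  r[comp == 1L] <- q_budding(u[comp == 1L], mp$b_sd, mp$b_min)
  r[comp == 2L] <- q_growing(u[comp == 2L], mp$g_mu, mp$g_sd)
  r[comp == 3L] <- q_large(u[comp == 3L], mp$tail, mp$r_max)
  r
}
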