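# End-to-end orchestration: simulate (or load) -> preprocess -> segment ->
# quantify -> population statistics -> report, under a single master seed.

#' Build a reproducible pipeline configuration
#'
#' All module parameters in one serialisable list.  A configuration saved
#' with its outputs reproduces the run: the same config and seed give
#' byte-identical tables.
#'
#' @param presets character vector of treatment presets to simulate (any
#'   of `"control"`, `"entinostat"`, `"oleate"`, `"combined"`).
#' @param n_cells cells per preset (recycled).
#' @param seed master seed; per-preset and per-field streams are derived
#'   from it.
#' @param out_dir output directory (`NULL` = do not write files).
#' @param cells_per_field cells per rendered field.
#' @param noise render with Poisson noise and dead-time saturation.
#' @param denoise_stacks run the wavelet denoiser during preprocessing.
#' @param wavelet_levels,threshold_scale denoiser settings.
#' @param optics named list of [optics_model()] overrides.
#' @param counting_method,sizing_method,volume_method,min_seed_distance
#'   segmentation settings (see [analysis_params()]).
#' @param alpha significance level for pairwise tests.
#' @param adjust p-adjustment method for pairwise tests.
#' @param qpcr_file optional CSV of Cp values (see [read_qpcr()]).
#' @param reference_condition untreated condition label for qPCR folds.
#' @param input optional named list for non-simulated input:
#'   `stack_tiff`, `cell_masks_tiff`, `nucleus_masks_tiff`.
#' @return a list of class `ld_config`.
#' @export
run_config <- function(presets = c("control", "entinostat", "oleate",
                                   "combined"),
                       n_cells = 50L, seed = 1L, out_dir = NULL,
                       cells_per_field = 9L, noise = TRUE,
                       denoise_stacks = TRUE, wavelet_levels = 3L,
                       threshold_scale = 1.5, optics = list(),
                       counting_method = "poisson",
                       sizing_method = "droplet_boundary",
                       volume_method = "droplet_boundary",
                       min_seed_distance = 0.5, alpha = 0.01,
                       adjust = "none", qpcr_file = NULL,
                       reference_condition = "control", input = NULL) {
  structure(
    list(
      presets = presets,
      n_cells = rep_len(as.integer(n_cells), length(presets)),
      seed = as.integer(seed), out_dir = out_dir,
      cells_per_field = as.integer(cells_per_field), noise = noise,
      denoise_stacks = denoise_stacks,
      wavelet_levels = as.integer(wavelet_levels),
      threshold_scale = threshold_scale, optics = optics,
      counting_method = counting_method, sizing_method = sizing_method,
      volume_method = volume_method,
      min_seed_distance = min_seed_distance, alpha = alpha,
      adjust = adjust, qpcr_file = qpcr_file,
      reference_condition = reference_condition, input = input
    ),
    class = c("ld_config", "list")
  )
}

preset_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * (i - 1)) %% 2147483647)
}

#' Run the full droplet-quantification pipeline
#'
#' For simulated runs: renders each treatment preset as a set of fields,
#' preprocesses (dead-time correction, denoising, power normalisation),
#' segments and measures droplets per cell, and computes population
#' statistics (box summaries, radius median/half-IQR, size breakdown, and
#' all-pairs rank-sum tests on per-cell droplet counts and total lipid
#' volumes when more than one preset is run).  For non-simulated input a
#' stack plus cell and nucleus masks are required.  If `out_dir` is set,
#' tables are written as CSV, the statistics report and resolved config
#' as JSON, and a processing log as plain text.
#'
#' @param config an [run_config()] list.
#' @return (invisibly) a list with tibbles `droplets`, `cells`,
#'   `truth_droplets`, `truth_cells`, the `stats` report list, `qpcr`
#'   fold table (or NULL), and the resolved `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "ld_config"))
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  optics <- do.call(optics_model, config$optics)
  params <- analysis_params(
    counting_method = config$counting_method,
    sizing_method = config$sizing_method,
    volume_method = config$volume_method,
    min_seed_distance = config$min_seed_distance
  )

  if (!is.null(config$input)) {
    inp <- config$input
    if (is.null(inp$cell_masks_tiff) || is.null(inp$nucleus_masks_tiff)) {
      stop("non-simulated input requires cell_masks_tiff and ",
           "nucleus_masks_tiff label images alongside the stack; ",
           "provide them in config$input", call. = FALSE)
    }
    stack <- read_stack_tiff(inp$stack_tiff)
    field <- list(
      stack = preprocess_stack(
        stack, config$wavelet_levels, config$threshold_scale,
        denoise_stack = config$denoise_stacks
      ),
      cell_masks = read_mask_tiff(inp$cell_masks_tiff),
      nucleus_masks = read_mask_tiff(inp$nucleus_masks_tiff)
    )
    res <- analyze_field(field, params)
    droplets <- res$droplets; cells <- res$cells
    droplets$treatment <- "input"; cells$treatment <- "input"
    truth_droplets <- truth_cells <- tibble::tibble()
    note("analysed user-supplied stack %s: %d cells, %d droplets",
         inp$stack_tiff, nrow(cells), nrow(droplets))
  } else {
    all_d <- list(); all_c <- list(); all_td <- list(); all_tc <- list()
    for (i in seq_along(config$presets)) {
      pname <- config$presets[i]
      preset <- make_preset(pname)
      res <- analyze_preset(
        preset, config$n_cells[i], seed = preset_seed(config$seed, i),
        optics = optics, cells_per_field = config$cells_per_field,
        noise = config$noise, params = params,
        wavelet_levels = config$wavelet_levels,
        threshold_scale = config$threshold_scale,
        denoise_stacks = config$denoise_stacks
      )
      res$droplets$treatment <- pname
      res$cells$treatment <- pname
      td <- res$truth_droplets; td$treatment <- pname
      tc <- res$truth_cells; tc$treatment <- pname
      all_d[[i]] <- res$droplets; all_c[[i]] <- res$cells
      all_td[[i]] <- td; all_tc[[i]] <- tc
      note("preset %-10s: %3d cells -> %5d droplets measured",
           pname, nrow(res$cells), nrow(res$droplets))
    }
    droplets <- dplyr::bind_rows(all_d)
    cells <- dplyr::bind_rows(all_c)
    truth_droplets <- dplyr::bind_rows(all_td)
    truth_cells <- dplyr::bind_rows(all_tc) |>
      dplyr::select(-dplyr::any_of("outline"))
  }

  keep <- if (nrow(cells) > 0 && params$exclude_border) !cells$border
    else rep(TRUE, nrow(cells))
  stats_cells <- cells[keep, , drop = FALSE]

  stats <- list()
  if (nrow(stats_cells) > 0) {
    stats$per_treatment <- stats_cells |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(
        n_cells = dplyr::n(),
        count_median = stats::median(.data$droplet_count),
        count_p25 = stats::quantile(.data$droplet_count, 0.25, names = FALSE),
        count_p75 = stats::quantile(.data$droplet_count, 0.75, names = FALSE),
        volume_median_um3 = stats::median(.data$total_volume_um3),
        volume_p25 = stats::quantile(.data$total_volume_um3, 0.25, names = FALSE),
        volume_p75 = stats::quantile(.data$total_volume_um3, 0.75, names = FALSE),
        .groups = "drop"
      )
    if (nrow(droplets) > 0) {
      stats$radii <- droplets |>
        dplyr::group_by(.data$treatment) |>
        dplyr::summarise(
          median_half_iqr(.data$r_um), n_droplets = dplyr::n(),
          .groups = "drop"
        )
      stats$size_breakdown <- droplets |>
        dplyr::group_by(.data$treatment) |>
        dplyr::summarise(size_breakdown(.data$r_um), .groups = "drop")
      stats$nucleus_distance <- droplets |>
        dplyr::filter(!is.na(.data$nuc_dist_um)) |>
        dplyr::group_by(.data$treatment) |>
        dplyr::summarise(
          median_distance_um = stats::median(.data$nuc_dist_um),
          .groups = "drop"
        )
    }
    if (length(unique(stats_cells$treatment)) >= 2) {
      stats$pairwise_counts <- pairwise_tests(
        stats_cells, .data$droplet_count, .data$treatment,
        alpha = config$alpha, adjust = config$adjust
      )
      stats$pairwise_volumes <- pairwise_tests(
        stats_cells, .data$total_volume_um3, .data$treatment,
        alpha = config$alpha, adjust = config$adjust
      )
      note("pairwise tests: %d/%d count pairs, %d/%d volume pairs rejected at alpha = %g",
           sum(stats$pairwise_counts$reject), nrow(stats$pairwise_counts),
           sum(stats$pairwise_volumes$reject), nrow(stats$pairwise_volumes),
           config$alpha)
    }
  }

  qpcr <- NULL
  if (!is.null(config$qpcr_file)) {
    qpcr <- fold_induction(read_qpcr(config$qpcr_file),
                           reference_condition = config$reference_condition)
    note("qPCR: %d gene x condition folds computed", nrow(qpcr))
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      readr::write_csv(df, file.path(config$out_dir, name))
    }
    wr(droplets, "droplets.csv")
    wr(cells, "cell_summaries.csv")
    if (nrow(truth_droplets) > 0) wr(truth_droplets, "truth_droplets.csv")
    if (nrow(truth_cells) > 0) wr(truth_cells, "truth_cells.csv")
    if (!is.null(stats$pairwise_counts)) {
      wr(stats$pairwise_counts, "pairwise_counts.csv")
      wr(stats$pairwise_volumes, "pairwise_volumes.csv")
    }
    if (!is.null(qpcr)) wr(qpcr, "fold_induction.csv")
    jsonlite::write_json(
      stats, file.path(config$out_dir, "stats_summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
    cfg <- config
    class(cfg) <- "list"
    jsonlite::write_json(
      cfg, file.path(config$out_dir, "config.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
  }

  invisible(list(
    droplets = droplets, cells = cells,
    truth_droplets = truth_droplets, truth_cells = truth_cells,
    stats = stats, qpcr = qpcr, config = config, log = log_lines
  ))
}
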