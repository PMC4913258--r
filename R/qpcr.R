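# Comparative-Ct (2^-dCp) relative expression and fold induction for
# qPCR panels normalised to 18S ribosomal RNA.

#' Relative expression by the comparative-Ct method
#'
#' `2^-(cp_target - cp_reference)`, with `dCp = Cp(target) - Cp(18S)`.
#'
#' @param cp_target,cp_reference crossing-point (Cp) cycle values; finite,
#'   vectorised.
#' @return relative expression, dimensionless.
#' @examples
#' relative_expression(30, 20)  # dCp = 10 -> 2^-10
#' @export
relative_expression <- function(cp_target, cp_reference) {
  if (any(!is.finite(cp_target)) || any(!is.finite(cp_reference))) {
    stop("Cp values must be finite", call. = FALSE)
  }
  2^-(cp_target - cp_reference)
}

#' Fold induction (treated versus untreated) of comparative-Ct expression
#'
#' For each gene and condition, computes per-replicate `2^-dCp` and the
#' fold induction relative to the reference (untreated) condition.  By
#' default the ratio of the *means of* `2^-dCp` across replicates is used
#' (`"mean_of_powers"`); `"power_of_mean"` instead uses `2^-mean(dCp)`.
#' Optionally a Welch two-sample t-test on the per-replicate `2^-dCp`
#' values against the reference is reported.
#'
#' @param data a data frame with columns `gene`, `condition`,
#'   `replicate`, `cp_target`, `cp_ref`.
#' @param reference_condition the untreated condition label.
#' @param method `"mean_of_powers"` (default) or `"power_of_mean"`.
#' @param t_test add a `p_value` column from a two-sample t-test against
#'   the reference (default FALSE; requires >= 2 replicates per side).
#' @return a tibble with one row per gene x condition: `gene`,
#'   `condition`, `fold`, `n_replicates` (and `p_value` if requested).
#'   The reference condition's fold is 1 by construction.
#' @examples
#' d <- data.frame(
#'   gene = "Scd", condition = rep(c("treated", "control"), each = 3),
#'   replicate = rep(1:3, 2),
#'   cp_target = c(29, 30, 31, 30, 30, 30), cp_ref = 20
#' )
#' fold_induction(d, reference_condition = "control")$fold  # 1.1875, 1
#' @export
fold_induction <- function(data, reference_condition,
                           method = c("mean_of_powers", "power_of_mean"),
                           t_test = FALSE) {
  method <- match.arg(method)
  need <- c("gene", "condition", "replicate", "cp_target", "cp_ref")
  if (!all(need %in% names(data))) {
    stop("data must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!reference_condition %in% data$condition) {
    stop("reference condition '", reference_condition,
         "' not present in data", call. = FALSE)
  }
  data <- dplyr::mutate(
    data, expr = relative_expression(.data$cp_target, .data$cp_ref),
    dcp = .data$cp_target - .data$cp_ref
  )
  agg <- data |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(
      mean_expr = if (method == "mean_of_powers") mean(.data$expr)
        else 2^-mean(.data$dcp),
      n_replicates = dplyr::n(),
      exprs = list(.data$expr),
      .groups = "drop"
    )
  ref <- agg |>
    dplyr::filter(.data$condition == reference_condition) |>
    dplyr::select("gene", ref_expr = "mean_expr", ref_exprs = "exprs")
  out <- agg |>
    dplyr::inner_join(ref, by = "gene")
  if (any(out$ref_expr == 0)) {
    stop("untreated mean expression is zero; fold undefined",
         call. = FALSE)
  }
  out$fold <- out$mean_expr / out$ref_expr
  if (t_test) {
    out$p_value <- purrr::map2_dbl(out$exprs, out$ref_exprs, function(x, y) {
      if (length(x) < 2 || length(y) < 2) return(NA_real_)
      if (stats::sd(c(x, y)) == 0) return(1)
      stats::t.test(x, y)$p.value
    })
  }
  out |>
    dplyr::select(dplyr::any_of(c("gene", "condition", "fold",
                                  "n_replicates", "p_value"))) |>
    dplyr::arrange(.data$gene, .data$condition)
}

#' Read a qPCR Cp table
#'
#' CSV with columns `gene`, `condition`, `replicate`, `cp_target`,
#' `cp_ref` (Cp of the 18S reference).
#'
#' @param path CSV file path.
#' @return a tibble.
#' @export
read_qpcr <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
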