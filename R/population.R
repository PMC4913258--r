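# Population-level descriptive statistics and nonparametric group
# comparisons, following the reporting conventions of the droplet experiment:
# box limits at the 25th/75th percentiles, whiskers at mean +- 1 sd,
# dispersion as half the interquartile range, and unadjusted pairwise
# Wilcoxon rank-sum tests at the 1% level.

#' Box-and-whisker summary statistics
#'
#' Percentiles use linear interpolation (type 7); `sd` is the sample
#' standard deviation (0 for a single value); whiskers are mean +- 1 sd.
#'
#' @param values numeric vector, length >= 1.
#' @return one-row tibble: `p25`, `median`, `p75`, `mean`, `sd`,
#'   `whisker_low`, `whisker_high`, `n`.
#' @examples
#' box_stats(1:5)
#' @export
box_stats <- function(values) {
  if (length(values) == 0) stop("box_stats of empty vector", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  m <- mean(values)
  s <- if (length(values) == 1) 0 else stats::sd(values)
  tibble::tibble(
    p25 = q[1], median = q[2], p75 = q[3], mean = m, sd = s,
    whisker_low = m - s, whisker_high = m + s, n = length(values)
  )
}

#' Median and half interquartile range
#'
#' The droplet-radius dispersion convention: the median with
#' half the interquartile range, `(p75 - p25) / 2`.
#'
#' @param values numeric vector, length >= 1.
#' @return one-row tibble: `median`, `half_iqr`.
#' @examples
#' median_half_iqr(1:5)  # median 3, half_iqr 1
#' @export
median_half_iqr <- function(values) {
  if (length(values) == 0) stop("median_half_iqr of empty vector",
                                call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], half_iqr = (q[3] - q[1]) / 2)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum statistic with mid-ranks for ties.  For small samples
#' (`n_a + n_b <= exact_limit`) the two-sided p-value is computed by exact
#' enumeration of all rank assignments (ties included); otherwise by
#' normal approximation with tie-corrected variance and continuity
#' correction.  Two identical constant samples give p = 1 with a warning.
#'
#' @param a,b numeric samples (both nonempty).
#' @param exact_limit switch to exact enumeration when
#'   `length(a) + length(b)` is at most this (default 16).
#' @return an object of class `ld_ranksum` with fields `statistic` (rank
#'   sum of `a`), `z`, `p_value`, `n_a`, `n_b`, `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1 exactly
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 16L) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  m <- length(a); n <- length(b); N <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)              # mid-ranks for ties
  W <- sum(r[seq_len(m)])
  mu <- m * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    warning("all values identical across both groups; p = 1")
    return(structure(
      list(statistic = W, z = 0, p_value = 1, n_a = m, n_b = n,
           method = "degenerate (no variation)"),
      class = "ld_ranksum"
    ))
  }
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  if (N <= exact_limit) {
    sums <- utils::combn(N, m, FUN = function(i) sum(r[i]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
    method <- "exact enumeration"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie-corrected, continuity)"
  }
  structure(
    list(statistic = W, z = z, p_value = p, n_a = m, n_b = n,
         method = method),
    class = "ld_ranksum"
  )
}

#' @export
print.ld_ranksum <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon rank-sum: W = %.6g, z = %.3f, two-sided p = %.4g (%s; n = %d, %d)\n",
    x$statistic, x$z, x$p_value, x$method, x$n_a, x$n_b
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ld_ranksum <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, z = x$z, p_value = x$p_value,
    n_a = x$n_a, n_b = x$n_b, method = x$method
  )
}

#' @export
glance.ld_ranksum <- function(x, ...) tidy(x)

#' All-pairs rank-sum tests across treatment groups
#'
#' Tests every unordered pair of groups on a per-cell variable with
#' [wilcoxon_rank_sum()].  No multiplicity adjustment is applied by
#' default (matching the experiment's unadjusted pairwise reporting); set
#' `adjust` to a [stats::p.adjust()] method to change that.
#'
#' @param data a data frame (e.g. cell summaries) with one row per cell.
#' @param variable column to test (tidy-eval, e.g. `droplet_count`).
#' @param group grouping column (e.g. `treatment`).
#' @param alpha significance level for the rejection decision
#'   (default 0.01).
#' @param adjust p-adjustment method (default `"none"`).
#' @return a tibble with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `statistic`, `z`, `p_value`, `p_adj`, `reject`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 10), x = c(1:10, 11:20))
#' pairwise_tests(d, x, g)
#' @export
pairwise_tests <- function(data, variable, group, alpha = 0.01,
                           adjust = "none") {
  var_q <- rlang::enquo(variable); grp_q <- rlang::enquo(group)
  df <- dplyr::transmute(
    data,
    value = !!var_q, group = as.character(!!grp_q)
  )
  df <- df[!is.na(df$value), ]
  groups <- unique(df$group)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(df$group)
  if (any(sizes < 2)) {
    stop("population with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(groups, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    a <- df$value[df$group == g1]; b <- df$value[df$group == g2]
    t <- wilcoxon_rank_sum(a, b)
    tibble::tibble(
      group1 = g1, group2 = g2, n1 = length(a), n2 = length(b),
      statistic = t$statistic, z = t$z, p_value = t$p_value
    )
  })
  res$p_adj <- stats::p.adjust(res$p_value, method = adjust)
  res$reject <- res$p_adj < alpha
  attr(res, "alpha") <- alpha
  res
}

#' Droplet size-class breakdown
#'
#' Fractions of budding, growing and large droplets.  Accepts a droplet
#' tibble (uses `size_class`, or classifies `r_um`) or a numeric vector
#' of radii.
#'
#' @param droplets droplet tibble or numeric radii (um), >= 1 droplet.
#' @return one-row tibble: `fraction_budding`, `fraction_growing`,
#'   `fraction_large`, `n` (fractions sum to 1 exactly).
#' @export
size_breakdown <- function(droplets) {
  cls <- if (is.numeric(droplets)) {
    classify_size(droplets)
  } else if ("size_class" %in% names(droplets)) {
    droplets$size_class
  } else {
    classify_size(droplets$r_um)
  }
  if (length(cls) == 0) stop("no droplets", call. = FALSE)
  tab <- table(factor(cls, c("budding", "growing", "large")))
  f <- as.numeric(tab) / length(cls)
  tibble::tibble(
    fraction_budding = f[1], fraction_growing = f[2],
    fraction_large = f[3], n = length(cls)
  )
}
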