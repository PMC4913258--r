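test_that("box_stats matches the sort-and-interpolate oracle", {
  expect_equal(
    box_stats(c(1, 2, 3, 4, 5))[, c("p25", "median", "p75", "mean")],
    tibble::tibble(p25 = 2, median = 3, p75 = 4, mean = 3)
  )
  one <- box_stats(7)
  expect_equal(unlist(one[, c("p25", "median", "p75", "mean", "sd")]),
               c(p25 = 7, median = 7, p75 = 7, mean = 7, sd = 0))
  set.seed(14)
  x <- rnorm(37)
  bs <- box_stats(x)
  # independent oracle: type-7 interpolation done by hand
  h <- function(p) {
    s <- sort(x); hh <- (length(x) - 1) * p
    s[floor(hh) + 1] + (hh - floor(hh)) * (s[floor(hh) + 2] - s[floor(hh) + 1])
  }
  expect_equal(bs$p25, h(0.25)); expect_equal(bs$p75, h(0.75))
  expect_equal(bs$whisker_high, mean(x) + sd(x))
  expect_error(box_stats(numeric()))
})

test_that("median and half-IQR follow the reporting convention", {
  mh <- median_half_iqr(c(1, 2, 3, 4, 5))
  expect_equal(mh$median, 3); expect_equal(mh$half_iqr, 1)
  const <- median_half_iqr(rep(4.2, 9))
  expect_equal(const$half_iqr, 0)
  expect_error(median_half_iqr(numeric()))
})

test_that("rank-sum test: extreme separation gives exact p = 0.1", {
  t <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t$p_value, 2 / 20)    # 2 of the C(6,3) = 20 assignments
  expect_equal(t$statistic, 6)
  expect_match(t$method, "exact")
})

test_that("identical samples give p ~ 1, z ~ 0", {
  t <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t$p_value, 1)
  expect_equal(t$z, 0, tolerance = 1e-12)
  expect_warning(t2 <- wilcoxon_rank_sum(rep(2, 5), rep(2, 5)), "identical")
  expect_equal(t2$p_value, 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3))
})

test_that("exact enumeration matches brute force for all n_a + n_b <= 12,
           including ties", {
  set.seed(8)
  cases <- list()
  for (na in 2:6) for (nb in 2:(12 - na)) {
    cases[[length(cases) + 1]] <- list(
      a = sample(1:5, na, replace = TRUE),     # heavy ties
      b = sample(1:5, nb, replace = TRUE)
    )
    cases[[length(cases) + 1]] <- list(a = rnorm(na), b = rnorm(nb))
  }
  for (cs in cases) {
    got <- wilcoxon_rank_sum(cs$a, cs$b)$p_value
    expect_equal(got, brute_force_ranksum_p(cs$a, cs$b),
                 info = paste(c(cs$a, "|", cs$b), collapse = " "))
  }
})

test_that("tie-free exact p agrees with stats::wilcox.test", {
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(sample(3:7, 1)); b <- rnorm(sample(3:7, 1))
    ours <- wilcoxon_rank_sum(a, b)$p_value
    ref <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(ours, ref)
  }
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(16)
  a <- rlnorm(30); b <- rlnorm(25, meanlog = 0.5)
  p0 <- wilcoxon_rank_sum(a, b)$p_value
  for (f in list(log, sqrt, function(x) x^3, function(x) 2 * x + 7)) {
    expect_equal(wilcoxon_rank_sum(f(a), f(b))$p_value, p0)
  }
})

test_that("tidy/glance methods expose the test results", {
  t <- wilcoxon_rank_sum(1:5, 6:10)
  td <- generics::tidy(t)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("statistic", "z", "p_value", "n_a", "n_b", "method"))
  expect_equal(generics::glance(t)$p_value, t$p_value)
})

test_that("pairwise_tests covers all unordered pairs and validates input", {
  set.seed(2)
  d <- tibble::tibble(
    g = rep(c("a", "b", "c", "d"), each = 12),
    x = c(rnorm(12, 0), rnorm(12, 0), rnorm(12, 5), rnorm(12, 10))
  )
  res <- pairwise_tests(d, x, g)
  expect_equal(nrow(res), 4 * 3 / 2)
  # identical populations (a vs b drawn from one distribution) rarely
  # reject; strongly separated pairs always do
  expect_true(res$reject[res$group1 == "c" & res$group2 == "d" |
                           res$group1 == "a" & res$group2 == "c"][1])
  expect_error(pairwise_tests(d[d$g == "a", ], x, g), "2 groups")
  bad <- rbind(d, tibble::tibble(g = "e", x = 1))
  expect_error(pairwise_tests(bad, x, g), "fewer than 2")
})

test_that("two identical populations yield no rejections", {
  set.seed(4)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 40), x = rep(rnorm(40), 2))
  res <- pairwise_tests(d, x, g)
  expect_false(any(res$reject))
})

test_that("multiplicity adjustment is off by default but available", {
  set.seed(6)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 20),
                      x = c(rnorm(20), rnorm(20, 1), rnorm(20, 2)))
  raw <- pairwise_tests(d, x, g)
  expect_equal(raw$p_adj, raw$p_value)
  holm <- pairwise_tests(d, x, g, adjust = "holm")
  expect_true(all(holm$p_adj >= raw$p_value - 1e-12))
})

test_that("size_breakdown fractions are exact and sum to 1", {
  sb <- size_breakdown(c(0.5, 0.5, 0.5))
  expect_equal(unlist(sb[, 1:3]),
               c(fraction_budding = 0, fraction_growing = 1,
                 fraction_large = 0))
  sb2 <- size_breakdown(c(0.1, 0.5, 1.0))
  expect_equal(unlist(sb2[, 1:3]),
               c(fraction_budding = 1 / 3, fraction_growing = 1 / 3,
                 fraction_large = 1 / 3))
  expect_error(size_breakdown(numeric()))
  # also accepts droplet tibbles
  dr <- tibble::tibble(r_um = c(0.1, 0.3))
  expect_equal(size_breakdown(dr)$fraction_budding, 0.5)
})
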