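# Shared fixtures, built in code.

# label matrix with k disks (optionally overlapping) on an n x n grid
disk_mask <- function(centers, r, n = 100, labels = FALSE) {
  m <- matrix(0L, n, n)
  for (i in seq_along(centers)) {
    cc <- centers[[i]]
    yy <- matrix(seq_len(n), n, n)
    xx <- t(yy)
    hit <- (yy - cc[1])^2 + (xx - cc[2])^2 <= r^2
    m[hit] <- if (labels) i else 1L
  }
  m
}

# a zigzag chain of k overlapping disks, neighbouring centres >= 1.5 r apart
disk_chain <- function(k, r = 6, spacing = 10) {
  lapply(seq_len(k), function(i) c(30 + (i %% 2) * 3, 15 + (i - 1) * spacing))
}

# minimal single-cell preset for fast synthetic fixtures
tiny_preset <- function(count = 12, budding = 0.1, large = 0.05,
                        area = 700, nucleus = 4.5, dispersion = 0.2) {
  treatment_preset(
    "tiny", droplet_count_median = count,
    total_volume_target_um3 = NA, large_tail_scale_um = 0.3,
    budding_weight = budding, large_weight = large,
    growing_peak_mean_um = 0.4, growing_peak_sd_um = 0.1,
    nucleus_distance_median_um = 4, cell_area_median_um2 = area,
    nucleus_radius_median_um = nucleus,
    cell_to_cell_dispersion = dispersion
  )
}

# a small rendered single-cell field, reused across segmentation tests
tiny_field <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- sample_ground_truth(tiny_preset(), 1, seed = 11)
      cache <<- render_stack(tr, optics_model(), seed = 12)
    }
    cache
  }
})

# brute-force two-sided rank-sum p-value by bitmask enumeration of all
# subsets (independent of the combn-based implementation path)
brute_force_ranksum_p <- function(a, b) {
  m <- length(a)
  r <- rank(c(a, b))
  N <- length(r)
  W <- sum(r[seq_len(m)])
  sums <- c()
  for (bits in 0:(2^N - 1)) {
    sel <- which(bitwAnd(bits, 2^(0:(N - 1))) > 0)
    if (length(sel) == m) sums <- c(sums, sum(r[sel]))
  }
  eps <- 1e-9
  min(1, 2 * min(mean(sums <= W + eps), mean(sums >= W - eps)))
}
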