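# Shared fixtures, built in code.

# Small genome for fast end-to-end checks.
tiny_config <- function(seed = 7L, ...) {
  sim_config(seed = seed,
             chrom_sizes = c(chrX = 5e4, chr2L = 5e4, chr2R = 5e4),
             n_genes = 15L, n_enhancers = 12L, depth = 4e4, ...)
}

# A deterministic toy track: `values` on consecutive bins of one chromosome.
toy_track <- function(values, bin_size = 100, chrom = "chr1",
                      chrom_size = length(values) * bin_size) {
  bins <- bin_genome(stats::setNames(chrom_size, chrom), bin_size)
  macc_track(bins, values)
}

# Closed-form least-squares slope, written long-hand (normal equations);
# independent oracle for compute_macc.
ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# Brute-force per-bp anchor profile: explicit loops and manual linear
# interpolation between bin centers; independent oracle for site_profile.
brute_profile <- function(track, anchors, flank_bp, step = 10) {
  offsets <- seq(-flank_bp, flank_bp, by = step)
  M <- matrix(NA_real_, nrow(anchors), length(offsets))
  for (i in seq_len(nrow(anchors))) {
    idx <- which(track$bins$chrom == anchors$chrom[i])
    centers <- (track$bins$start[idx] + track$bins$end[idx]) / 2
    sc <- track$score[idx]
    for (j in seq_along(offsets)) {
      p <- anchors$pos[i] + offsets[j]
      if (p <= centers[1]) {
        v <- sc[1]
      } else if (p >= centers[length(centers)]) {
        v <- sc[length(sc)]
      } else {
        k <- max(which(centers <= p))
        w <- (p - centers[k]) / (centers[k + 1] - centers[k])
        v <- (1 - w) * sc[k] + w * sc[k + 1]
      }
      M[i, j] <- v
    }
    if (!is.null(anchors$strand) && anchors$strand[i] == "-") {
      M[i, ] <- rev(M[i, ])
    }
  }
  list(offsets = offsets, mean = colMeans(M), matrix = M)
}
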