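# Shared fixtures and independent oracles.

# Naive exhaustive segmentation oracle: at every recursion level, loop over
# all split positions with stats::t.test and apply the same acceptance rules
# as the implementation. Deliberately independent of the package's
# cumulative-sum scan.
oracle_best_split <- function(x, lo, hi, min_points) {
  n <- hi - lo + 1L
  if (n < 2L * min_points) return(NULL)
  best <- NULL
  for (k in (lo + min_points - 1L):(hi - min_points)) {
    left <- x[lo:k]
    right <- x[(k + 1L):hi]
    lp <- if (stats::var(left) == 0 && stats::var(right) == 0) {
      if (mean(left) == mean(right)) 0 else -Inf
    } else {
      tt <- tryCatch(stats::t.test(left, right), error = function(e) NULL)
      if (is.null(tt)) 0 else {
        log(2) + stats::pt(-abs(unname(tt$statistic)), unname(tt$parameter),
                           log.p = TRUE)
      }
    }
    if (is.null(best) || lp < best$log_p) {
      best <- list(index = k, log_p = lp, p_value = exp(lp),
                   mean_left = mean(left), mean_right = mean(right))
    }
  }
  best
}

oracle_segment <- function(x, params) {
  noise <- if (length(x) >= 3L) estimate_noise(x) else 0
  recurse <- function(lo, hi) {
    bs <- oracle_best_split(x, lo, hi, params$min_points)
    if (!is.null(bs) && bs$log_p < log(params$alpha) &&
        abs(bs$mean_left - bs$mean_right) >= params$min_magnitude_factor * noise) {
      return(rbind(recurse(lo, bs$index), recurse(bs$index + 1L, hi)))
    }
    data.frame(start_idx = lo, end_idx = hi)
  }
  if (length(x) < params$min_points) {
    return(data.frame(start_idx = 1L, end_idx = length(x)))
  }
  recurse(1L, length(x))
}

# Staircase chromosome: segment lengths and levels drawn under the caller's
# RNG; returns intensities, positions, and true breakpoints (probe index of
# the last probe before each break).
make_staircase <- function(n_segments = 4L, len_range = c(150L, 300L),
                           step = 0.5, noise_sd = 0.1, base = 2) {
  lens <- sample(len_range[1]:len_range[2], n_segments, replace = TRUE)
  lev <- base
  levels <- numeric(n_segments)
  levels[1] <- lev
  for (i in 2:n_segments) {
    # random walk, reflected away from zero
    d <- sample(c(-step, step), 1)
    if (lev + d < 0.5) d <- step
    lev <- lev + d
    levels[i] <- lev
  }
  x <- unlist(mapply(function(l, n) rnorm(n, mean = l, sd = noise_sd),
                     levels, lens, SIMPLIFY = FALSE))
  list(intensities = x, positions = seq_along(x) * 1000,
       breaks = cumsum(lens)[-n_segments], levels = levels, lens = lens)
}

# Tiny probe-set builder for unit tests.
toy_probes <- function(intensity, chrom = "1", allele_ratio = NA_real_,
                       platform = "SNP500K") {
  probe_set(data.frame(chrom = chrom, pos = seq_along(intensity) * 1000,
                       intensity = intensity, allele_ratio = allele_ratio),
            sample_id = "toy", platform = platform)
}

# One-segment table for ploidy unit tests.
seg_row <- function(chrom, mean_intensity, n_probes = 500L,
                    start_pos = 1, end_pos = 1e6) {
  data.frame(chrom = chrom, start_pos = start_pos, end_pos = end_pos,
             start_idx = 1L, end_idx = n_probes, n_probes = n_probes,
             mean_intensity = mean_intensity, boundary_p = NA_real_,
             low_coverage = FALSE)
}

# Band state constructor bypassing density estimation (for consistency-score
# unit tests with exact band centers).
band_state <- function(centers = numeric(), balanced = FALSE, loh = FALSE,
                       determined = TRUE) {
  structure(list(determined = determined, band_centers = centers,
                 balanced = balanced, loh = loh, n_snp = 100L),
            class = "allelic_state")
}
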