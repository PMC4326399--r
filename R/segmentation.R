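#' Segmentation parameters
#'
#' Parameters of the breakpoint-detection algorithm. A breakpoint is accepted
#' when (1) the two neighboring regions have statistically different average
#' intensities at `p < alpha`, (2) among admissible split positions the one
#' with the smallest p-value is chosen, (3) both resulting regions contain at
#' least `min_points` probes, and (4) the magnitude of the mean change is at
#' least `min_magnitude_factor` times the per-chromosome noise estimate.
#'
#' @param platform `"SNP500K"` or `"SNP6"`; fixes the default `min_points`
#'   (100 and 200 respectively).
#' @param alpha breakpoint significance threshold (default 0.001).
#' @param min_points minimum probes per segment; overrides the platform
#'   default when given.
#' @param min_magnitude_factor minimum mean change relative to the
#'   chromosome noise estimate (default 0.3).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(platform = c("SNP500K", "SNP6"), alpha = 0.001,
                                min_points = NULL, min_magnitude_factor = 0.3) {
  platform <- match.arg(platform)
  if (is.null(min_points)) min_points <- if (platform == "SNP6") 200L else 100L
  min_points <- as.integer(min_points)
  stopifnot(alpha > 0, alpha < 1, min_points >= 2L, min_magnitude_factor >= 0)
  structure(
    list(platform = platform, alpha = alpha, min_points = min_points,
         min_magnitude_factor = min_magnitude_factor),
    class = "segmentation_params"
  )
}

#' Robust per-chromosome noise estimate
#'
#' Probe-level noise standard deviation estimated from lag-1 differences:
#' `mad(diff(x)) / sqrt(2)` (the MAD already carries the 1.4826 Gaussian
#' consistency constant). Differencing removes slow level changes, so a true
#' copy-number step inflates at most a single difference and the median makes
#' the estimate insensitive to it.
#'
#' @param intensities ordered numeric vector (>= 3 values).
#' @return estimated noise sd (>= 0).
#' @export
estimate_noise <- function(intensities) {
  if (length(intensities) < 3L) stop("noise estimation needs >= 3 probes")
  mad(diff(intensities)) / sqrt(2)
}

# Vectorized Welch two-sample t-test p-values for every admissible split of
# x[lo..hi] (1-based inclusive). Returns NULL when the window is too short.
welch_split_scan <- function(x, lo, hi, min_points) {
  n <- hi - lo + 1L
  if (n < 2L * min_points) return(NULL)
  xs <- x[lo:hi]
  cs <- cumsum(xs)
  css <- cumsum(xs * xs)
  k <- min_points:(n - min_points) # size of the left side
  n1 <- k
  n2 <- n - k
  s1 <- cs[k]
  m1 <- s1 / n1
  m2 <- (cs[n] - s1) / n2
  v1 <- pmax(0, (css[k] - n1 * m1 * m1) / (n1 - 1))
  v2 <- pmax(0, (css[n] - css[k] - n2 * m2 * m2) / (n2 - 1))
  se2 <- v1 / n1 + v2 / n2
  # work on the log scale: p-values at strong breakpoints underflow double
  # precision, and ties at 0 would mislocalize the split
  log_p <- rep(0, length(k))
  pos <- se2 > 0
  if (any(pos)) {
    tstat <- (m1[pos] - m2[pos]) / sqrt(se2[pos])
    df <- se2[pos]^2 / ((v1[pos] / n1[pos])^2 / (n1[pos] - 1) +
                          (v2[pos] / n2[pos])^2 / (n2[pos] - 1))
    log_p[pos] <- log(2) + pt(-abs(tstat), df, log.p = TRUE)
  }
  # zero pooled variance: identical constants give p = 1, a level change in
  # noiseless data is certain (p = 0)
  log_p[!pos] <- ifelse(m1[!pos] == m2[!pos], 0, -Inf)
  list(k = k, log_p = log_p, mean_left = m1, mean_right = m2)
}

#' Best split of an intensity window
#'
#' Scans every split position leaving at least `min_points` probes on each
#' side of `intensities[lo..hi]` and returns the one whose Welch two-sample
#' t-test between the two sides attains the smallest p-value (ties broken by
#' the leftmost position). Indices are 1-based; the returned `index` is the
#' last probe of the left side.
#'
#' @param intensities numeric vector.
#' @param lo,hi window bounds (1-based, inclusive); default whole vector.
#' @param min_points minimum probes per side.
#' @return `NULL` when the window admits no split, else a list with `index`,
#'   `p_value`, `log_p` (the comparison scale, immune to underflow),
#'   `mean_left`, `mean_right`.
#' @export
best_split <- function(intensities, lo = 1L, hi = length(intensities),
                       min_points = 100L) {
  scan <- welch_split_scan(intensities, lo, hi, min_points)
  if (is.null(scan)) return(NULL)
  i <- which.min(scan$log_p)
  list(index = lo + scan$k[i] - 1L, p_value = exp(scan$log_p[i]),
       log_p = scan$log_p[i],
       mean_left = scan$mean_left[i], mean_right = scan$mean_right[i])
}

#' Segment one chromosome by recursive bisection
#'
#' Applies [best_split()] top-down: a split is accepted iff its p-value is
#' below `alpha`, both sides hold at least `min_points` probes, and the two
#' side means differ by at least `min_magnitude_factor` times the chromosome
#' noise estimate ([estimate_noise()], fixed once before recursion); accepted
#' halves are recursed into. The returned segments tile all probes of the
#' chromosome. A chromosome with fewer than `min_points` probes yields a
#' single segment flagged `low_coverage`.
#'
#' @param intensities,positions equal-length numeric vectors, sorted by
#'   position.
#' @param params a [segmentation_params()].
#' @param chrom chromosome label recorded in the output.
#' @return data.frame with one row per segment: `chrom`, `start_pos`,
#'   `end_pos`, `start_idx`, `end_idx` (1-based inclusive probe indices),
#'   `n_probes`, `mean_intensity`, `boundary_p` (p-value of the accepted test
#'   at the segment's left breakpoint, `NA` at the chromosome start) and
#'   `low_coverage`.
#' @export
segment_chromosome <- function(intensities, positions, params = segmentation_params(),
                               chrom = "1") {
  n <- length(intensities)
  stopifnot(n == length(positions), n >= 1L)
  if (is.unsorted(positions)) stop("positions must be sorted")
  make_row <- function(lo, hi, boundary_p, flagged = FALSE) {
    data.frame(
      chrom = chrom, start_pos = positions[lo], end_pos = positions[hi],
      start_idx = lo, end_idx = hi, n_probes = hi - lo + 1L,
      mean_intensity = mean(intensities[lo:hi]), boundary_p = boundary_p,
      low_coverage = flagged
    )
  }
  if (n < params$min_points) {
    return(make_row(1L, n, NA_real_, flagged = TRUE))
  }
  noise <- if (n >= 3L) estimate_noise(intensities) else 0
  floor_mag <- params$min_magnitude_factor * noise
  recurse <- function(lo, hi, left_p) {
    bs <- best_split(intensities, lo, hi, params$min_points)
    if (!is.null(bs) && bs$log_p < log(params$alpha) &&
        abs(bs$mean_left - bs$mean_right) >= floor_mag) {
      return(rbind(
        recurse(lo, bs$index, left_p),
        recurse(bs$index + 1L, hi, bs$p_value)
      ))
    }
    make_row(lo, hi, left_p)
  }
  out <- recurse(1L, n, NA_real_)
  rownames(out) <- NULL
  out
}

#' Segment every chromosome of a probe set
#'
#' Runs [segment_chromosome()] per chromosome on a (normalized) probe set and
#' concatenates the results. `min_points` defaults from the probe set's
#' platform when `params` is not supplied.
#'
#' @param probes a [probe_set()], normalized with [normalize_baseline2()].
#' @param params a [segmentation_params()]; defaults to the platform's.
#' @return segment table (see [segment_chromosome()]) with a `sample_id`
#'   attribute. Probe indices are per-chromosome.
#' @export
segment_sample <- function(probes, params = NULL) {
  stopifnot(inherits(probes, "probe_set"))
  if (nrow(probes) == 0L) stop("empty probe set")
  if (is.null(params)) params <- segmentation_params(attr(probes, "platform"))
  chroms <- unique(probes$chrom)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    sel <- probes$chrom == ch
    segment_chromosome(probes$intensity[sel], probes$pos[sel], params, chrom = ch)
  }))
  rownames(out) <- NULL
  attr(out, "sample_id") <- attr(probes, "sample_id")
  out
}
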