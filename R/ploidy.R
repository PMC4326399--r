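#' Detect the allelic state of a segment
#'
#' Clusters a segment's SNP allele ratios into mirror-symmetric heterozygous
#' bands. Ratios and their mirror images are pooled and a fixed-bandwidth
#' kernel density is scanned for modes; modes within `hom_margin` of 0 or 1
#' are homozygous bands and are excluded. The segment is `balanced` when a
#' single heterozygous mode survives within `balance_tol` of 0.5, and `loh`
#' when no heterozygous mode survives (the copy-neutral LOH / UPD pattern:
#' bands only near 0 and 1). Fewer than `min_probes` ratios give the state
#' `undetermined`, which is excluded from ploidy evidence.
#'
#' @param allele_ratios numeric vector of allele ratios in \[0, 1\] (NA
#'   allowed, dropped).
#' @param min_probes minimum ratios required (default 30).
#' @param hom_margin homozygous exclusion margin around 0 and 1 (default
#'   0.08).
#' @param balance_tol distance from 0.5 within which a single band counts as
#'   balanced (default 0.05).
#' @param bw kernel density bandwidth (default 0.02, half the band-matching
#'   tolerance used by [consistency_score()]).
#' @param min_mode_density minimum kernel density at the strongest mode for
#'   the ratios to count as banded evidence (default 1.5; a uniform,
#'   structureless ratio distribution has density ~1 everywhere and is
#'   reported undetermined rather than over-interpreted).
#' @return list of class `allelic_state`: `determined`, `band_centers`
#'   (mirror-closed, sorted), `balanced`, `loh`, `n_snp`.
#' @export
detect_allelic_state <- function(allele_ratios, min_probes = 30L,
                                 hom_margin = 0.08, balance_tol = 0.05,
                                 bw = 0.02, min_mode_density = 1.5) {
  r <- allele_ratios[!is.na(allele_ratios)]
  if (any(r < 0 | r > 1)) stop("allele ratios must lie in [0, 1]")
  state <- function(determined, centers = numeric(), balanced = FALSE, loh = FALSE) {
    structure(list(determined = determined, band_centers = centers,
                   balanced = balanced, loh = loh, n_snp = length(r)),
              class = "allelic_state")
  }
  if (length(r) < min_probes) return(state(FALSE))
  aug <- c(r, 1 - r) # enforce mirror symmetry of the estimate
  d <- density(aug, bw = bw, from = 0, to = 1, n = 512)
  y <- d$y
  if (max(y) < min_mode_density) return(state(FALSE))
  is_peak <- y > c(-Inf, head(y, -1)) & y >= c(tail(y, -1), -Inf)
  # boundary bins count as peaks when the density leans on them
  is_peak[1] <- y[1] > y[2]
  is_peak[length(y)] <- y[length(y)] > y[length(y) - 1]
  centers <- d$x[is_peak & y >= 0.2 * max(y)]
  het <- centers[centers > hom_margin & centers < 1 - hom_margin]
  if (length(het) == 0L) return(state(TRUE, loh = TRUE))
  # merge near-coincident modes (density jitter around a single band)
  het <- sort(het)
  grp <- cumsum(c(1, diff(het) > balance_tol))
  het <- as.numeric(tapply(het, grp, mean))
  # mirror-close the band set
  folded <- sort(unique(round(pmin(het, 1 - het), 6)))
  centers <- sort(unique(c(folded, 1 - folded)))
  balanced <- length(het) == 1L && abs(het - 0.5) <= balance_tol
  if (balanced) centers <- het
  state(TRUE, centers = centers, balanced = balanced)
}

#' Allelic states for every segment of a sample
#'
#' @param probes a [probe_set()] with allele ratios.
#' @param segments segment table from [segment_sample()].
#' @param ... passed to [detect_allelic_state()].
#' @return list of `allelic_state`, one per segment row.
#' @export
segment_allelic_states <- function(probes, segments, ...) {
  lapply(seq_len(nrow(segments)), function(i) {
    sel <- probes$chrom == segments$chrom[i] &
      probes$pos >= segments$start_pos[i] & probes$pos <= segments$end_pos[i]
    detect_allelic_state(probes$allele_ratio[sel], ...)
  })
}

#' Integer copies implied by an intensity on a candidate baseline
#'
#' On a genome whose true baseline is `P` copies, baseline-2 normalization
#' maps `c` copies to intensity `2 c / P`; inverting and rounding half-up
#' gives the implied integer copy count.
#'
#' @param mean_intensity segment mean intensity (>= 0).
#' @param baseline_ploidy candidate baseline `P` (integer >= 1).
#' @return integer copies `round(mean_intensity * P / 2)` (half-up).
#' @examples
#' implied_copies(2.0, 4) # a "normal-looking" segment on a tetraploid baseline
#' @export
implied_copies <- function(mean_intensity, baseline_ploidy) {
  stopifnot(all(mean_intensity >= 0), baseline_ploidy >= 1)
  as.integer(round_half_up(mean_intensity * baseline_ploidy / 2))
}

# Band positions predicted for c total tumor copies at a given purity, for
# every parental split a = 0..c of a germline-heterozygous locus. The a = 0
# and a = c splits are included because with normal-cell admixture they
# detach from ratio 0/1 (e.g. c = 1 at purity 0.85 gives 0.13/0.87) and are
# then observed as heterozygous bands.
predicted_bands <- function(c_total, purity) {
  denom <- purity * c_total + (1 - purity) * 2
  if (denom <= 0) return(numeric())
  a <- 0:c_total
  (purity * a + (1 - purity)) / denom
}

#' Consistency of observed allelic states with a candidate ploidy
#'
#' For each evidentiary segment (determined allelic state), the candidate
#' baseline `P` implies a real-valued copy estimate by inverting the purity
#' mixture: `c_est = ((I/2) (p P + 2 (1-p)) - 2 (1-p)) / p` for intensity
#' `I` (which reduces to `I P / 2` at purity 1). Two requirements follow:
#' `c_est` must lie within `copy_tol` of an integer `c` (a wrong baseline
#' maps true integer copy states to systematically non-integer estimates,
#' which is what makes low-purity samples fail gracefully instead of
#' resolving to an arbitrary ploidy), and `c` predicts the band positions
#' `(p a + (1-p)) / (p c + 2 (1-p))` for every parental split `a = 0..c`
#' (the endpoint splits leave residual normal-cell bands away from 0/1
#' whenever purity is below 1). The segment is
#' consistent iff every observed band center matches a predicted band within
#' `band_tol`, a balanced segment implies an even `c` (0.5 requires the
#' `a = c/2` split), and an LOH segment is always attainable (the `a = 0` or
#' `a = c` split). The score is the probe-count-weighted fraction of
#' evidentiary segments that are consistent, so a short boundary sliver
#' (greedy bisection can strand a `min_points`-sized mixed segment at an
#' amplicon edge) cannot veto whole-chromosome evidence.
#'
#' @param segments segment table (needs `mean_intensity`).
#' @param states list of `allelic_state` parallel to `segments` (from
#'   [segment_allelic_states()]).
#' @param candidate_p candidate baseline ploidy.
#' @param purity assumed tumor-cell fraction (default 1).
#' @param band_tol band matching tolerance (default 0.04).
#' @param copy_tol maximum distance of the copy estimate from an integer
#'   (default 0.25).
#' @return list: `score` in \[0, 1\] (`NA` when no segment is evidentiary),
#'   `n_evidentiary`, `consistent` (logical per segment, `NA` for
#'   undetermined).
#' @export
consistency_score <- function(segments, states, candidate_p, purity = 1,
                              band_tol = 0.04, copy_tol = 0.25) {
  stopifnot(nrow(segments) == length(states))
  consistent <- rep(NA, nrow(segments))
  for (i in seq_len(nrow(segments))) {
    st <- states[[i]]
    if (!isTRUE(st$determined)) next
    intensity <- segments$mean_intensity[i]
    c_est <- if (purity > 0) {
      ((intensity / 2) * (purity * candidate_p + 2 * (1 - purity)) -
         2 * (1 - purity)) / purity
    } else {
      intensity * candidate_p / 2
    }
    cc <- max(0L, as.integer(round_half_up(c_est)))
    if (abs(c_est - cc) > copy_tol) {
      consistent[i] <- FALSE
      next
    }
    if (isTRUE(st$loh)) {
      consistent[i] <- TRUE
      next
    }
    bands <- predicted_bands(cc, purity)
    ok <- length(st$band_centers) > 0 && length(bands) > 0 &&
      all(vapply(st$band_centers,
                 function(b) min(abs(b - bands)) <= band_tol, logical(1)))
    if (isTRUE(st$balanced) && cc %% 2L != 0L) ok <- FALSE
    consistent[i] <- ok
  }
  n_ev <- sum(!is.na(consistent))
  w <- if ("n_probes" %in% names(segments)) segments$n_probes else
    rep(1, nrow(segments))
  ev <- !is.na(consistent)
  list(score = if (n_ev > 0)
         sum(w[ev] * consistent[ev]) / sum(w[ev]) else NA_real_,
       n_evidentiary = n_ev, consistent = consistent)
}

#' Infer sample ploidy from segment intensities and allelic states
#'
#' Scans candidate baselines `P` over `p_range` and returns the smallest `P`
#' whose [consistency_score()] reaches `score_floor` - the lowest possible
#' ploidy consistent with the combined copy-number / allelic-balance
#' evidence. `is_lower_bound` is `TRUE` when `P + 1` also reaches the floor
#' (the precise state is indeterminate and the estimate is a lower bound,
#' rendered with a "+"). Per-chromosome implied copies are probe-weighted
#' medians of segment implied copies under the chosen baseline, and the
#' sample is flagged polyploid when the median over chromosomes is 3 copies
#' or more. When no candidate reaches the floor the call is unresolved (the
#' best candidate and score are still reported).
#'
#' @param segments segment table from [segment_sample()].
#' @param states allelic states from [segment_allelic_states()].
#' @param purity assumed tumor-cell fraction (default 1).
#' @param p_range candidate baselines (default `2:12`).
#' @param score_floor minimum consistency score (default 0.95).
#' @param band_tol,copy_tol passed to [consistency_score()].
#' @return list of class `ploidy_call`: `resolved`, `min_ploidy`,
#'   `is_lower_bound`, `polyploid`, `per_chromosome_copies` (named),
#'   `upd_flags` (row indices of copy-neutral LOH segments), `scores` (per
#'   candidate), `best_p`, `best_score`, `n_evidentiary`.
#' @export
infer_ploidy <- function(segments, states, purity = 1, p_range = 2:12,
                         score_floor = 0.95, band_tol = 0.04, copy_tol = 0.25) {
  scores <- vapply(p_range, function(P) {
    consistency_score(segments, states, P, purity, band_tol, copy_tol)$score
  }, numeric(1))
  names(scores) <- as.character(p_range)
  n_ev <- consistency_score(segments, states, p_range[1], purity, band_tol,
                            copy_tol)$n_evidentiary
  if (n_ev == 0L) {
    return(structure(list(resolved = FALSE, min_ploidy = NA_integer_,
                          is_lower_bound = NA, polyploid = NA,
                          per_chromosome_copies = NULL, upd_flags = integer(),
                          scores = scores, best_p = NA_integer_,
                          best_score = NA_real_, n_evidentiary = 0L),
                     class = "ploidy_call"))
  }
  hit <- which(scores >= score_floor)
  if (length(hit) == 0L) {
    best <- which.max(scores)
    return(structure(list(resolved = FALSE, min_ploidy = NA_integer_,
                          is_lower_bound = NA, polyploid = NA,
                          per_chromosome_copies = NULL, upd_flags = integer(),
                          scores = scores, best_p = p_range[best],
                          best_score = scores[[best]], n_evidentiary = n_ev),
                     class = "ploidy_call"))
  }
  min_p <- p_range[hit[1]]
  next_i <- hit[1] + 1L
  lower_bound <- next_i <= length(p_range) && !is.na(scores[next_i]) &&
    scores[next_i] >= score_floor
  seg_copies <- implied_copies(segments$mean_intensity, min_p)
  per_chrom <- vapply(split(seq_len(nrow(segments)), segments$chrom), function(idx) {
    median(rep(seg_copies[idx], segments$n_probes[idx]))
  }, numeric(1))
  per_chrom <- per_chrom[order(chrom_order(names(per_chrom)))]
  upd <- which(vapply(states, function(s) isTRUE(s$determined) && isTRUE(s$loh),
                      logical(1)) & seg_copies >= 2L)
  structure(list(resolved = TRUE, min_ploidy = as.integer(min_p),
                 is_lower_bound = lower_bound,
                 polyploid = median(per_chrom) >= 3,
                 per_chromosome_copies = per_chrom, upd_flags = upd,
                 scores = scores, best_p = as.integer(min_p),
                 best_score = scores[[hit[1]]], n_evidentiary = n_ev),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  if (!x$resolved) {
    cat(sprintf("ploidy unresolved (best P = %s, score %.2f, %d evidentiary segments)\n",
                x$best_p, x$best_score, x$n_evidentiary))
  } else {
    cat(sprintf("minimal ploidy %d%s, polyploid: %s (%d evidentiary segments)\n",
                x$min_ploidy, if (isTRUE(x$is_lower_bound)) "+" else "",
                x$polyploid, x$n_evidentiary))
  }
  invisible(x)
}

#' Absolute HER2 copy estimate under an inferred ploidy
#'
#' @param her2_cn HER2 segment intensity (from [her2_call()]).
#' @param ploidy_call a resolved [infer_ploidy()] call.
#' @return list: `copies` (integer), `is_lower_bound`, `label` (e.g. `"4+"`).
#' @export
her2_absolute_copies <- function(her2_cn, ploidy_call) {
  stopifnot(inherits(ploidy_call, "ploidy_call"))
  if (!isTRUE(ploidy_call$resolved)) {
    stop("ploidy call is unresolved; no absolute HER2 copy estimate")
  }
  copies <- implied_copies(her2_cn, ploidy_call$min_ploidy)
  lb <- isTRUE(ploidy_call$is_lower_bound)
  list(copies = copies, is_lower_bound = lb,
       label = paste0(copies, if (lb) "+" else ""))
}
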