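#' Classify a segment mean into a copy-number status
#'
#' Thresholds on the baseline-2 intensity scale: `< 1.8` is a deletion,
#' `> 2.2` an amplification, and the closed interval `[1.8, 2.2]` normal
#' (the copy-number range of 0.2 around state 2; the boundary value 1.80 is
#' a published normal call, fixing inclusivity).
#'
#' @param mean_intensity numeric vector of segment means (>= 0, finite).
#' @return character vector: `"del"`, `"normal"` or `"amp"`.
#' @examples
#' classify_cn(c(1.72, 1.80, 1.98, 2.35))
#' @export
classify_cn <- function(mean_intensity) {
  stopifnot(is.numeric(mean_intensity), all(is.finite(mean_intensity)),
            all(mean_intensity >= 0))
  ifelse(mean_intensity < 1.8, "del",
         ifelse(mean_intensity > 2.2, "amp", "normal"))
}

# probe-count-weighted mean of segment means over an interval; weights are
# segment probe counts prorated by the base-pair fraction of the segment
# inside the interval
interval_weighted_mean <- function(segments, interval) {
  sel <- segments$chrom == interval$chrom &
    segments$end_pos >= interval$start & segments$start_pos <= interval$end
  if (!any(sel)) {
    stop(sprintf("no segment overlaps interval %s:%d-%d", interval$chrom,
                 as.integer(interval$start), as.integer(interval$end)))
  }
  s <- segments[sel, , drop = FALSE]
  span <- pmax(1, s$end_pos - s$start_pos + 1)
  ov <- pmin(s$end_pos, interval$end) - pmax(s$start_pos, interval$start) + 1
  w <- s$n_probes * ov / span
  weighted.mean(s$mean_intensity, w)
}

#' HER2-locus call with the HER2-vs-centromere relation label
#'
#' Computes the probe-count-weighted mean segment intensity over the HER2
#' interval and over a centromere-proximal chromosome 17 interval, classifies
#' the HER2 value with [classify_cn()], and labels the relation between the
#' two values: `balance` when they differ by at most `tol`, `HER2plus` when
#' HER2 exceeds the centromeric value by more than `tol`, `centplus`
#' conversely. A co-amplified sample (`balance` despite an amplified HER2
#' value) is exactly the configuration that masks the FISH HER2/CEP17 ratio.
#'
#' @param segments segment table for the sample (must cover chromosome 17).
#' @param her2_interval,cent_interval interval lists (see [parse_interval()]);
#'   default [default_intervals()].
#' @param tol relation tolerance on the intensity scale (default 0.2, the
#'   copy-number range used for status calling).
#' @return list of class `her2_call`: `her2_cn`, `cent_cn`, `relation`,
#'   `status`, `fold_class` (`"high"` >= 4-fold, `"moderate"` amplified below
#'   4-fold, `"none"`).
#' @export
her2_call <- function(segments, her2_interval = default_intervals()$her2,
                      cent_interval = default_intervals()$cent, tol = 0.2) {
  if (is.character(her2_interval)) her2_interval <- parse_interval(her2_interval)
  if (is.character(cent_interval)) cent_interval <- parse_interval(cent_interval)
  her2_cn <- interval_weighted_mean(segments, her2_interval)
  cent_cn <- interval_weighted_mean(segments, cent_interval)
  d <- her2_cn - cent_cn
  relation <- if (abs(d) <= tol) "balance" else if (d > 0) "HER2plus" else "centplus"
  status <- classify_cn(her2_cn)
  fold_class <- if (her2_cn >= 4) "high" else if (status == "amp") "moderate" else "none"
  structure(
    list(her2_cn = her2_cn, cent_cn = cent_cn, relation = relation,
         status = status, fold_class = fold_class),
    class = "her2_call"
  )
}

#' @export
print.her2_call <- function(x, ...) {
  cat(sprintf("HER2 %.2f vs centromere %.2f: %s, status %s (fold class %s)\n",
              x$her2_cn, x$cent_cn, x$relation, x$status, x$fold_class))
  invisible(x)
}

#' Cohort copy-number status summary
#'
#' Counts of [classify_cn()] statuses over a cohort of HER2 segment values,
#' plus the amplification fold strata: `high` for values of at least 4.0
#' (four-fold or greater), `moderate` for amplified values below 4.0.
#'
#' @param cn_values numeric vector of segment copy numbers.
#' @return list with `status` (named counts amp/del/normal) and `fold`
#'   (named counts high/moderate).
#' @examples
#' cohort_status_summary(load_table1()$snp_cn)
#' @export
cohort_status_summary <- function(cn_values) {
  stopifnot(length(cn_values) > 0)
  st <- classify_cn(cn_values)
  list(
    status = c(amp = sum(st == "amp"), del = sum(st == "del"),
               normal = sum(st == "normal")),
    fold = c(high = sum(cn_values >= 4),
             moderate = sum(st == "amp" & cn_values < 4))
  )
}

#' Span of the minimal amplicon in kilobases
#'
#' @param start,end 1-based genomic bounds, `end > start`.
#' @return `(end - start) / 1000`, rounded half-up to the nearest integer kb.
#' @examples
#' minimal_amplicon_span(37642255, 37970066)
#' @export
minimal_amplicon_span <- function(start, end) {
  if (end <= start) stop("amplicon end must exceed start")
  as.integer(round_half_up((end - start) / 1000))
}
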