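#' Construct a probe set
#'
#' A `probe_set` is the pipeline's raw input: an ordered table of probe-level
#' copy-number intensities (genome mean defined as 2 after normalization) and
#' optional allele ratios, one row per probe, sorted by chromosome and
#' position.
#'
#' @param probes data.frame with columns `chrom` (1-22, X), `pos` (1-based
#'   base position), `intensity` (non-negative copy-number-scale call) and
#'   optionally `allele_ratio` (fraction of A-allele signal in \[0,1\], `NA`
#'   for copy-number-only probes).
#' @param sample_id sample identifier.
#' @param platform `"SNP500K"` or `"SNP6"`; controls the default minimum
#'   segment size in [segmentation_params()].
#' @return object of class `probe_set`: the validated, sorted probe table
#'   with `sample_id` and `platform` attributes.
#' @examples
#' ps <- probe_set(data.frame(chrom = "17", pos = c(10, 20), intensity = c(2, 2)))
#' nrow(ps)
#' @export
probe_set <- function(probes, sample_id = "sample", platform = c("SNP500K", "SNP6")) {
  platform <- match.arg(platform)
  stopifnot(is.data.frame(probes))
  req <- c("chrom", "pos", "intensity")
  miss <- setdiff(req, names(probes))
  if (length(miss)) stop("probe table lacks column(s): ", paste(miss, collapse = ", "))
  probes <- as.data.frame(probes)[, intersect(c(req, "allele_ratio"), names(probes))]
  if (!"allele_ratio" %in% names(probes)) probes$allele_ratio <- NA_real_
  probes$chrom <- as.character(probes$chrom)
  if (nrow(probes) == 0L) stop("probe set is empty")
  if (any(probes$pos < 1)) stop("probe positions must be >= 1")
  if (any(probes$intensity < 0, na.rm = TRUE)) stop("probe intensities must be >= 0")
  ar <- probes$allele_ratio
  if (any(ar < 0 | ar > 1, na.rm = TRUE)) stop("allele ratios must lie in [0, 1]")
  ord <- order(chrom_order(probes$chrom), probes$pos)
  if (is.unsorted(ord)) {
    message("probe table was not sorted by (chrom, pos); sorting")
    probes <- probes[ord, , drop = FALSE]
  }
  if (anyDuplicated(probes[c("chrom", "pos")])) {
    stop("duplicate probe positions within a chromosome")
  }
  rownames(probes) <- NULL
  structure(probes,
    sample_id = as.character(sample_id), platform = platform,
    class = c("probe_set", "data.frame")
  )
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf(
    "probe_set '%s' (%s): %d probes on %d chromosome(s), %d with allele ratios\n",
    attr(x, "sample_id"), attr(x, "platform"), nrow(x),
    length(unique(x$chrom)), sum(!is.na(x$allele_ratio))
  ))
  invisible(x)
}

#' Read probe-level data from a headered TSV
#'
#' The dialect is a tab-separated file with header columns `chrom`, `pos`,
#' `intensity` and optionally `allele_ratio`; positions are 1-based. Rows
#' with a missing intensity are dropped (a message reports the count);
#' unsorted input is sorted with a message.
#'
#' @param path file path.
#' @param sample_id,platform passed to [probe_set()]; `sample_id` defaults to
#'   the file name without extension.
#' @return a [probe_set()].
#' @export
read_probes <- function(path, sample_id = NULL,
                        platform = c("SNP500K", "SNP6")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("probe file does not exist: ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                      colClasses = list(character = "chrom")),
    error = function(e) stop("cannot parse probe file ", path, ": ", conditionMessage(e))
  )
  req <- c("chrom", "pos", "intensity")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stop("probe file lacks column(s): ", paste(miss, collapse = ", "))
  for (col in intersect(c("pos", "intensity", "allele_ratio"), names(dt))) {
    if (!is.numeric(dt[[col]])) {
      suppressWarnings(num <- as.numeric(dt[[col]]))
      bad <- which(is.na(num) & !(dt[[col]] %in% c("NA", "", NA)))
      if (length(bad)) {
        stop(sprintf("malformed value in column '%s' at line %d of %s",
                     col, bad[1] + 1L, path))
      }
      dt[[col]] <- num
    }
  }
  n_na <- sum(is.na(dt$intensity))
  if (n_na > 0L) {
    message(sprintf("dropped %d probe(s) with missing intensity", n_na))
    dt <- dt[!is.na(dt$intensity), , drop = FALSE]
  }
  if (nrow(dt) == 0L) stop("no usable probes in ", path)
  probe_set(dt, sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
            platform = platform)
}

#' Write a probe set to TSV
#'
#' @param probes a [probe_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(probes, path) {
  stopifnot(inherits(probes, "probe_set"))
  data.table::fwrite(as.data.frame(probes), path, sep = "\t", na = "NA")
  invisible(path)
}

#' Normalize probe intensities to the baseline-2 scale
#'
#' Rescales all intensities by a single global factor so that the unweighted
#' arithmetic mean over every probe of every chromosome equals 2 - the array
#' convention in which the genome-wide average signal is defined to be
#' copy-number state 2. Probe-to-probe ratios are preserved exactly. Note the
#' deliberate consequence: a uniformly tetraploid genome is rescaled to look
#' diploid, which is why polyploidy must be recovered from allelic balance
#' (see [infer_ploidy()]).
#'
#' @param probes a [probe_set()].
#' @return the probe set with rescaled intensities (mean exactly 2 within
#'   1e-9).
#' @examples
#' ps <- probe_set(data.frame(chrom = "1", pos = 1:3, intensity = c(1, 2, 3)))
#' mean(normalize_baseline2(ps)$intensity)
#' @export
normalize_baseline2 <- function(probes) {
  stopifnot(inherits(probes, "probe_set"))
  m <- mean(probes$intensity)
  if (!is.finite(m) || m <= 0) stop("cannot normalize: genome-wide mean intensity is not positive")
  probes$intensity <- probes$intensity * (2 / m)
  probes
}

#' Write segments in SEG format
#'
#' Standard tab-separated SEG layout: `sample`, `chrom`, `start`, `end`,
#' `num_probes`, `mean`. Segments must not overlap within a chromosome.
#'
#' @param segments segment table from [segment_sample()] (or any data.frame
#'   with `chrom`, `start_pos`, `end_pos`, `n_probes`, `mean_intensity`).
#' @param path output path.
#' @param sample_id sample name for the first column; defaults to the table's
#'   `sample_id` attribute, else `"sample"`.
#' @return `path`, invisibly.
#' @export
write_segments_seg <- function(segments, path, sample_id = NULL) {
  segments <- as.data.frame(segments)
  req <- c("chrom", "start_pos", "end_pos", "n_probes", "mean_intensity")
  miss <- setdiff(req, names(segments))
  if (length(miss)) stop("segment table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(segments) > 0) {
    sp <- split(segments, segments$chrom)
    for (s in sp) {
      s <- s[order(s$start_pos), , drop = FALSE]
      if (nrow(s) > 1 && any(s$start_pos[-1] <= s$end_pos[-nrow(s)])) {
        stop("overlapping segments on chromosome ", s$chrom[1])
      }
    }
  }
  out <- data.frame(
    sample = rep(sample_id %||% attr(segments, "sample_id") %||% "sample",
                 nrow(segments)),
    chrom = segments$chrom,
    start = segments$start_pos,
    end = segments$end_pos,
    num_probes = segments$n_probes,
    mean = round(segments$mean_intensity, 4)
  )
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a SEG file back into a segment table
#'
#' @param path SEG file written by [write_segments_seg()].
#' @return data.frame with `chrom`, `start_pos`, `end_pos`, `n_probes`,
#'   `mean_intensity` and a `sample_id` attribute.
#' @export
read_segments_seg <- function(path) {
  if (!file.exists(path)) stop("SEG file does not exist: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "chrom"))
  out <- data.frame(
    chrom = as.character(dt$chrom),
    start_pos = dt$start,
    end_pos = dt$end,
    n_probes = dt$num_probes,
    mean_intensity = dt$mean
  )
  attr(out, "sample_id") <- if (nrow(dt)) dt$sample[1] else "sample"
  out
}

#' Hg19 chromosome lengths
#'
#' Packaged table of chromosome lengths (1-22, X) on the Hg19 assembly, used
#' by the synthetic-genome generator.
#'
#' @return data.frame with `chrom` and `length`.
#' @export
hg19_lengths <- function() {
  dt <- data.table::fread(extdata_path("hg19_lengths.tsv"), data.table = FALSE,
                          colClasses = list(character = "chrom"))
  dt
}
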