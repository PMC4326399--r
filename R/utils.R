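# Internal helpers shared across modules.

# round() in base R rounds half to even; the copy-number quantization and the
# kb span both need arithmetic half-up rounding.
round_half_up <- function(x) floor(x + 0.5)

# Chromosome labels in canonical order (1-22, X); used for sorting and
# validation everywhere.
CHROM_LEVELS <- c(as.character(1:22), "X")

chrom_order <- function(chrom) {
  ord <- match(as.character(chrom), CHROM_LEVELS)
  if (anyNA(ord)) {
    bad <- unique(as.character(chrom)[is.na(ord)])
    stop("unknown chromosome label(s): ", paste(bad, collapse = ", "))
  }
  ord
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a genomic interval string
#'
#' Accepts `"chr17:37642255-37970066"` or `"17:37642255-37970066"` (1-based,
#' inclusive) and returns its components.
#'
#' @param x interval string.
#' @return list with `chrom`, `start`, `end`.
#' @examples
#' parse_interval("chr17:37642255-37970066")
#' @export
parse_interval <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^(chr)?([0-9XY]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) == 0L) stop("cannot parse interval string: ", x)
  start <- as.numeric(gsub(",", "", m[4]))
  end <- as.numeric(gsub(",", "", m[5]))
  if (end < start) stop("interval end precedes start: ", x)
  list(chrom = m[3], start = start, end = end)
}

#' Default HER2 and centromere-proximal chromosome 17 intervals (Hg19)
#'
#' The HER2 interval is the minimal recurrently amplified region on 17q12
#' (chr17:37,642,255-37,970,066, Hg19). The CEP17-homologous centromeric
#' interval is not published; the default is a window flanking the chromosome
#' 17 centromeric gap (chr17:22,200,000-25,800,000, Hg19), configurable in
#' every function that consumes it.
#'
#' @return list of two interval lists (as from [parse_interval()]).
#' @export
default_intervals <- function() {
  list(
    her2 = list(chrom = "17", start = 37642255, end = 37970066),
    cent = list(chrom = "17", start = 22200000, end = 25800000)
  )
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "her2snp")
  if (!nzchar(p)) {
    # fall back for load_all()-style development trees
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("packaged file not found: ", file)
  p
}
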