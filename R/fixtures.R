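# Packaged per-sample clinical tables for the 65-tumor cohort.
#
# table1.tsv: IHC score, HER2/CEP17 FISH ratio, SNP segment copy number at
# the HER2 locus, the HER2-vs-centromere relation label and the copy-number
# status, with re-analysis (revised) IHC/FISH values for samples 49, 60, 63.
# table2.tsv: per-sample polyploidy flag, HER2 copy-number estimate (lowest
# possible value, "+" marks a lower bound) and the 3D-FISH per-nucleus HER2
# count for the nine samples so examined.

# Frozen integrity constant: sum of the 65 HER2 segment copy numbers as
# transcribed, to the printed 2-decimal precision.
TABLE1_CN_CHECKSUM <- 171.80

#' Load the packaged 65-sample clinical table
#'
#' Returns one record per tumor sample: original (and, for samples 49, 60 and
#' 63, revised) IHC score and HER2/CEP17 FISH ratio, the SNP segment copy
#' number at the HER2 locus, the published HER2-vs-centromere relation label
#' (`balance`, `HER2plus`, `centplus`) and the published copy-number status
#' (`amp`, `normal`, `del`). Decimal commas of the printed table are already
#' converted to points.
#'
#' @return data.frame of 65 `clinical_record` rows with columns `sample`,
#'   `ihc`, `fish`, `ihc_revised`, `fish_revised`, `snp_cn`, `relation`,
#'   `status`.
#' @examples
#' t1 <- load_table1()
#' table(t1$status)
#' @export
load_table1 <- function() {
  t1 <- data.table::fread(extdata_path("table1.tsv"), sep = "\t",
                          data.table = FALSE)
  if (nrow(t1) != 65L) stop("table1 fixture corrupt: expected 65 records, got ", nrow(t1))
  if (abs(sum(t1$snp_cn) - TABLE1_CN_CHECKSUM) > 1e-9) {
    stop("table1 fixture corrupt: copy-number checksum mismatch")
  }
  if (!identical(sort(t1$sample), 1:65)) stop("table1 fixture corrupt: sample ids")
  rev_rows <- t1$sample[!is.na(t1$ihc_revised) | !is.na(t1$fish_revised)]
  if (!identical(sort(rev_rows), c(49L, 60L, 63L))) {
    stop("table1 fixture corrupt: revised values outside samples 49/60/63")
  }
  if (!all(t1$relation %in% c("balance", "HER2plus", "centplus")) ||
      !all(t1$status %in% c("amp", "normal", "del"))) {
    stop("table1 fixture corrupt: label vocabulary")
  }
  # FISH must be present wherever the original IHC score is 2+ (equivocal).
  if (any(t1$ihc == 2 & is.na(t1$fish))) stop("table1 fixture corrupt: IHC 2+ without FISH")
  class(t1) <- c("clinical_table", "data.frame")
  t1
}

#' Load the packaged polyploidy summary table
#'
#' Per-sample polyploidy flag, HER2 copy-number estimate (a "+" suffix marks
#' the lowest possible estimate of an indeterminate higher state) and the
#' per-nucleus HER2 count from 3D confocal FISH for the nine verified
#' samples.
#'
#' @return data.frame with columns `sample`, `polyploid` (logical),
#'   `her2_estimate` (character, as printed), `fish_3d` (character or NA).
#' @examples
#' t2 <- load_table2()
#' sum(t2$polyploid)
#' @export
load_table2 <- function() {
  t2 <- data.table::fread(extdata_path("table2.tsv"), sep = "\t",
                          data.table = FALSE,
                          colClasses = list(character = c("her2_estimate", "fish_3d")))
  if (nrow(t2) != 65L) stop("table2 fixture corrupt: expected 65 records, got ", nrow(t2))
  t2$polyploid <- t2$polyploid == "Yes"
  if (sum(t2$polyploid) != 45L) stop("table2 fixture corrupt: polyploid count")
  t2
}
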