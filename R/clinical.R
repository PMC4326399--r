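#' Classify a sample from IHC score and FISH ratio
#'
#' Clinical rule: IHC 3+ is HER2 positive; IHC 2+ is equivocal and resolved
#' by FISH (positive iff the HER2/CEP17 ratio is 2.0 or more, the inclusive
#' cut-off); IHC 0 and 1+ are negative without FISH.
#'
#' @param ihc IHC score in `0:3`.
#' @param fish_ratio HER2/CEP17 ratio (>= 0); required iff `ihc == 2`.
#' @return list of class `ihc_fish_call`: `classification` (`"positive"` /
#'   `"negative"`) and `basis` (`ihc3`, `ihc2_fish_amplified`,
#'   `ihc2_fish_not_amplified`, `ihc_low`).
#' @examples
#' ihc_fish_classify(2, 2.42)
#' @export
ihc_fish_classify <- function(ihc, fish_ratio = NA_real_) {
  if (!ihc %in% 0:3) stop("IHC score must be 0, 1, 2 or 3")
  if (ihc == 2 && is.na(fish_ratio)) {
    stop("IHC 2+ is equivocal: a FISH ratio is required")
  }
  if (!is.na(fish_ratio) && fish_ratio < 0) stop("FISH ratio must be >= 0")
  basis <- if (ihc == 3) "ihc3"
    else if (ihc == 2 && fish_ratio >= 2) "ihc2_fish_amplified"
    else if (ihc == 2) "ihc2_fish_not_amplified"
    else "ihc_low"
  structure(
    list(classification = if (basis %in% c("ihc3", "ihc2_fish_amplified"))
           "positive" else "negative",
         basis = basis),
    class = "ihc_fish_call"
  )
}

#' Virtual FISH ratio from absolute copy numbers
#'
#' The FISH readout is the ratio of HER2 to CEP17 (centromere) signals per
#' nucleus, called amplified at a cut-off of 2 (inclusive). Being a ratio it
#' is scale-invariant: co-amplification of both loci, or whole-genome
#' polyploidy, leaves it unchanged - the masking effect the SNP segment call
#' does not suffer from.
#'
#' @param her2_copies,cep17_copies per-nucleus copy numbers; `cep17_copies`
#'   must be positive.
#' @return list: `ratio`, `amplified` (`ratio >= 2`).
#' @examples
#' virtual_fish(4, 4) # co-amplified: ratio 1, not amplified
#' @export
virtual_fish <- function(her2_copies, cep17_copies) {
  stopifnot(her2_copies >= 0)
  if (cep17_copies <= 0) stop("CEP17 copies must be positive")
  ratio <- her2_copies / cep17_copies
  list(ratio = ratio, amplified = ratio >= 2)
}

#' IHC/FISH versus SNP concordance analysis
#'
#' Classifies each record's clinical HER2 status with [ihc_fish_classify()]
#' (original values by default; `use_revised = TRUE` substitutes the
#' re-analysis values where present), calls the SNP status positive iff the
#' published segment status is `amp`, and tabulates agreement.
#'
#' @param records clinical table as returned by [load_table1()].
#' @param use_revised use revised IHC/FISH values where available.
#' @return list of class `concordance_report`: `n`, `n_concordant`,
#'   `n_discrepant`, `n_ihc_fish_positive`, `discrepant_by_ihc` (count and
#'   denominator per original IHC score), `discrepant_split` (negative /
#'   positive clinical calls among discrepant samples), `discrepant_ids`,
#'   `unresolvable_ids`.
#' @examples
#' rep <- concordance(load_table1())
#' rep$n_discrepant
#' @export
concordance <- function(records, use_revised = FALSE) {
  records <- as.data.frame(records)
  req <- c("sample", "ihc", "fish", "snp_cn", "status")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  ihc <- records$ihc
  fish <- records$fish
  if (use_revised) {
    has_rev_i <- !is.na(records$ihc_revised %||% rep(NA, nrow(records)))
    has_rev_f <- !is.na(records$fish_revised %||% rep(NA, nrow(records)))
    ihc[has_rev_i] <- records$ihc_revised[has_rev_i]
    fish[has_rev_f] <- records$fish_revised[has_rev_f]
  }
  clin_pos <- rep(NA, nrow(records))
  for (i in seq_len(nrow(records))) {
    call <- tryCatch(ihc_fish_classify(ihc[i], fish[i]), error = function(e) NULL)
    if (!is.null(call)) clin_pos[i] <- call$classification == "positive"
  }
  unresolvable <- records$sample[is.na(clin_pos)]
  ok <- !is.na(clin_pos)
  snp_pos <- records$status == "amp"
  disc <- ok & (clin_pos != snp_pos)
  conc <- ok & (clin_pos == snp_pos)
  by_ihc <- t(vapply(sort(unique(records$ihc)), function(s) {
    c(discrepant = sum(disc & records$ihc == s),
      n = sum(ok & records$ihc == s))
  }, numeric(2)))
  rownames(by_ihc) <- as.character(sort(unique(records$ihc)))
  structure(
    list(
      n = sum(ok),
      n_concordant = sum(conc),
      n_discrepant = sum(disc),
      n_ihc_fish_positive = sum(clin_pos[ok]),
      discrepant_by_ihc = by_ihc,
      discrepant_split = c(negative = sum(disc & !clin_pos),
                           positive = sum(disc & clin_pos)),
      discrepant_ids = sort(records$sample[disc]),
      unresolvable_ids = unresolvable,
      use_revised = use_revised
    ),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf(
    "concordance over %d samples%s: %d concordant, %d discrepant (%d clin-negative, %d clin-positive); %d IHC/FISH positive\n",
    x$n, if (x$use_revised) " (revised values)" else "",
    x$n_concordant, x$n_discrepant,
    x$discrepant_split[["negative"]], x$discrepant_split[["positive"]],
    x$n_ihc_fish_positive
  ))
  invisible(x)
}
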