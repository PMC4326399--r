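#' Pipeline configuration
#'
#' Collects every tunable of the simulate / segment / call / ploidy /
#' concordance chain with the published defaults: breakpoint threshold
#' `alpha = 0.001`, platform-dependent minimum segment size, magnitude
#' factor 0.3, status thresholds 1.8 / 2.2 (inside [classify_cn()]), FISH
#' cut-off 2.0, and the default Hg19 HER2 / centromere-proximal intervals.
#'
#' @param platform `"SNP500K"` or `"SNP6"`.
#' @param alpha,min_points,min_magnitude_factor see [segmentation_params()].
#' @param her2_interval,cent_interval interval strings or lists.
#' @param purity assumed tumor purity for ploidy inference.
#' @param p_range,score_floor see [infer_ploidy()].
#' @param seed pipeline seed (used when the input is a simulation spec).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(platform = "SNP500K", alpha = 0.001,
                            min_points = NULL, min_magnitude_factor = 0.3,
                            her2_interval = default_intervals()$her2,
                            cent_interval = default_intervals()$cent,
                            purity = 1, p_range = 2:12, score_floor = 0.95,
                            seed = NULL) {
  if (is.character(her2_interval)) her2_interval <- parse_interval(her2_interval)
  if (is.character(cent_interval)) cent_interval <- parse_interval(cent_interval)
  structure(
    list(
      platform = platform,
      seg = segmentation_params(platform, alpha = alpha, min_points = min_points,
                                min_magnitude_factor = min_magnitude_factor),
      her2_interval = her2_interval, cent_interval = cent_interval,
      purity = purity, p_range = p_range, score_floor = score_floor,
      seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Run the full per-sample pipeline
#'
#' Normalizes, segments, makes the HER2 / centromere call, infers ploidy
#' from allelic states, and derives the virtual HER2/CEP17 FISH decision.
#' When `out_dir` is given, writes `\{sample\}.seg`, `\{sample\}.json` and a
#' `manifest.json` recording parameters, seed and package version; the same
#' config and seed always reproduce byte-identical outputs.
#'
#' @param input a [probe_set()], or a [karyotype_spec()] to simulate first
#'   (using `config$seed` when the spec carries none).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list of class `sample_report`: `sample_id`, `n_probes`,
#'   `segments`, `her2` ([her2_call()]), `virtual_fish`, `ploidy`
#'   ([infer_ploidy()]), `her2_copies` (absolute estimate or `NULL`).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  if (inherits(input, "karyotype_spec")) {
    if (is.null(input$seed)) input$seed <- config$seed
    input <- simulate_probeset(input)
  }
  stopifnot(inherits(input, "probe_set"))
  probes <- normalize_baseline2(input)
  segments <- segment_sample(probes, config$seg)
  message(sprintf("sample %s: %d probes -> %d segments",
                  attr(probes, "sample_id"), nrow(probes), nrow(segments)))
  her2 <- her2_call(segments, config$her2_interval, config$cent_interval)
  vf <- virtual_fish(her2$her2_cn, her2$cent_cn)
  states <- segment_allelic_states(probes, segments)
  ploidy <- infer_ploidy(segments, states, purity = config$purity,
                         p_range = config$p_range,
                         score_floor = config$score_floor)
  her2_copies <- if (isTRUE(ploidy$resolved)) {
    her2_absolute_copies(her2$her2_cn, ploidy)
  }
  report <- structure(
    list(sample_id = attr(probes, "sample_id"), n_probes = nrow(probes),
         segments = segments, her2 = her2, virtual_fish = vf,
         ploidy = ploidy, her2_copies = her2_copies),
    class = "sample_report"
  )
  if (!is.null(out_dir)) write_report_bundle(report, config, out_dir)
  report
}

write_report_bundle <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sid <- report$sample_id
  write_segments_seg(report$segments, file.path(out_dir, paste0(sid, ".seg")),
                     sample_id = sid)
  js <- list(
    sample_id = sid,
    n_probes = report$n_probes,
    her2 = report$her2[c("her2_cn", "cent_cn", "relation", "status", "fold_class")],
    virtual_fish = report$virtual_fish,
    ploidy = report$ploidy[c("resolved", "min_ploidy", "is_lower_bound",
                             "polyploid", "best_score")],
    per_chromosome_copies = as.list(report$ploidy$per_chromosome_copies),
    her2_copies = report$her2_copies
  )
  jsonlite::write_json(js, file.path(out_dir, paste0(sid, ".json")),
                       auto_unbox = TRUE, digits = 10, null = "null", na = "null")
  manifest <- list(
    package = "her2snp",
    version = as.character(utils::packageVersion("her2snp")),
    seed = config$seed,
    platform = config$platform,
    segmentation = config$seg[c("alpha", "min_points", "min_magnitude_factor")],
    her2_interval = config$her2_interval,
    cent_interval = config$cent_interval,
    purity = config$purity,
    p_range = range(config$p_range),
    score_floor = config$score_floor
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null", na = "null")
  invisible(out_dir)
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("sample %s: %d probes, %d segments\n", x$sample_id, x$n_probes,
              nrow(x$segments)))
  print(x$her2)
  cat(sprintf("virtual FISH ratio %.2f (%samplified)\n", x$virtual_fish$ratio,
              if (x$virtual_fish$amplified) "" else "not "))
  print(x$ploidy)
  invisible(x)
}

#' Cohort summary table
#'
#' One row per sample report, mirroring the clinical comparison layout:
#' HER2 segment value, relation label, status, virtual FISH ratio and
#' decision, and the ploidy call. Missing values are rendered `"n/a"` when
#' written.
#'
#' @param reports list of `sample_report` (from [run_pipeline()]).
#' @param path optional TSV output path.
#' @return data.frame (invisibly written to `path` when given).
#' @export
emit_summary_table <- function(reports, path = NULL) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(r) {
    pl <- r$ploidy
    data.frame(
      sample = r$sample_id,
      her2_cn = round(r$her2$her2_cn, 2),
      cent_cn = round(r$her2$cent_cn, 2),
      relation = r$her2$relation,
      status = r$her2$status,
      fish_ratio = round(r$virtual_fish$ratio, 2),
      fish_amplified = r$virtual_fish$amplified,
      min_ploidy = if (isTRUE(pl$resolved)) {
        paste0(pl$min_ploidy, if (isTRUE(pl$is_lower_bound)) "+" else "")
      } else NA_character_,
      polyploid = if (isTRUE(pl$resolved)) pl$polyploid else NA,
      her2_copies = if (!is.null(r$her2_copies)) r$her2_copies$label else NA_character_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) {
    data.table::fwrite(out, path, sep = "\t", na = "n/a")
  }
  out
}

#' Read back a cohort summary TSV
#'
#' @param path TSV written by [emit_summary_table()].
#' @return data.frame with `"n/a"` restored to `NA`.
#' @export
read_summary_table <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "n/a", data.table = FALSE,
                    colClasses = list(character = c("sample", "min_ploidy",
                                                    "her2_copies")))
}
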