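#' Region copy state
#'
#' One genomic region with explicit parental (maternal/paternal) copy counts,
#' overriding the karyotype background.
#'
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive bounds.
#' @param copies_a,copies_b non-negative integer parental copy counts.
#' @return one-row data.frame.
#' @export
region_state <- function(chrom, start, end, copies_a, copies_b) {
  stopifnot(start >= 1, end >= start, copies_a >= 0, copies_b >= 0,
            copies_a == round(copies_a), copies_b == round(copies_b))
  data.frame(chrom = as.character(chrom), start = start, end = end,
             copies_a = as.integer(copies_a), copies_b = as.integer(copies_b))
}

#' Karyotype specification for the tumor-genome simulator
#'
#' Describes the stated world a synthetic sample is drawn from: a background
#' ploidy with its parental allele split, regional overrides, tumor purity,
#' probe noise, probe density and germline heterozygosity.
#'
#' @param background_ploidy integer >= 1, total background copies.
#' @param background_split length-2 integer vector `(a, b)` summing to
#'   `background_ploidy`; defaults to the most balanced split.
#' @param regions data.frame of [region_state()] rows overriding the
#'   background (may be `NULL`).
#' @param purity tumor-cell fraction in \[0, 1\]; the remaining fraction is
#'   diploid heterozygous normal tissue.
#' @param noise_sd Gaussian probe-intensity noise sd on the copy-number
#'   scale (default 0.1, a plausible post-normalization array noise floor).
#' @param baf_sd Gaussian allele-ratio noise sd (default 0.03).
#' @param probes_per_mb probe density (default 160, roughly a 500K array
#'   over the Hg19 genome).
#' @param het_fraction fraction of probes heterozygous in the germline
#'   (default 0.3).
#' @param seed RNG seed; `NULL` uses the current RNG stream.
#' @return list of class `karyotype_spec`.
#' @export
karyotype_spec <- function(background_ploidy = 2L, background_split = NULL,
                           regions = NULL, purity = 1, noise_sd = 0.1,
                           baf_sd = 0.03, probes_per_mb = 160,
                           het_fraction = 0.3, seed = NULL) {
  background_ploidy <- as.integer(background_ploidy)
  stopifnot(background_ploidy >= 1L)
  if (is.null(background_split)) {
    background_split <- c(ceiling(background_ploidy / 2), floor(background_ploidy / 2))
  }
  background_split <- as.integer(background_split)
  if (length(background_split) != 2L || sum(background_split) != background_ploidy ||
      any(background_split < 0L)) {
    stop("background_split must be two non-negative integers summing to background_ploidy")
  }
  if (purity < 0 || purity > 1) stop("purity must lie in [0, 1]")
  stopifnot(noise_sd >= 0, baf_sd >= 0, probes_per_mb > 0,
            het_fraction >= 0, het_fraction <= 1)
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)
    stopifnot(all(c("chrom", "start", "end", "copies_a", "copies_b") %in% names(regions)))
    regions$chrom <- as.character(regions$chrom)
    if (any(regions$end < regions$start)) stop("region end precedes start")
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
        stop("overlapping regions on chromosome ", ch)
      }
    }
  }
  structure(
    list(background_ploidy = background_ploidy, background_split = background_split,
         regions = regions, purity = purity, noise_sd = noise_sd, baf_sd = baf_sd,
         probes_per_mb = probes_per_mb, het_fraction = het_fraction, seed = seed),
    class = "karyotype_spec"
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Simulate probe-level SNP-array data for one tumor sample
#'
#' Probes are placed uniformly at random along each chromosome. For a probe
#' in a region with tumor parental copies `(a, b)` (total `c`) and purity
#' `p`, the pre-normalization expected intensity is `p*c + (1-p)*2` plus
#' Gaussian noise; a germline-heterozygous probe's expected allele ratio is
#' `(p*a' + (1-p)) / (p*c + (1-p)*2)` where `a'` is `a` or `b` with equal
#' probability (array allele labeling is arbitrary, so bands come in mirror
#' pairs), plus noise, clipped to \[0, 1\]. Germline-homozygous probes sit
#' near ratio 0 or 1. The result is passed through [normalize_baseline2()],
#' so whole-genome ploidy is deliberately invisible at the intensity level.
#'
#' @param spec a [karyotype_spec()].
#' @param genome data.frame with `chrom`, `length`; default [hg19_lengths()].
#' @param chroms optional subset of chromosome labels to simulate.
#' @param sample_id,platform passed to [probe_set()].
#' @return normalized [probe_set()], with the spec attached as attribute
#'   `truth`.
#' @examples
#' ps <- simulate_probeset(karyotype_spec(seed = 1, probes_per_mb = 2),
#'                         chroms = c("1", "17"))
#' @export
simulate_probeset <- function(spec, genome = hg19_lengths(), chroms = NULL,
                              sample_id = "sim", platform = "SNP500K") {
  stopifnot(inherits(spec, "karyotype_spec"))
  if (!is.null(chroms)) genome <- genome[genome$chrom %in% as.character(chroms), , drop = FALSE]
  if (nrow(genome) == 0L) stop("genome table is empty")
  if (!is.null(spec$regions)) {
    bad <- !spec$regions$chrom %in% genome$chrom
    if (any(bad)) stop("region chromosome(s) absent from genome: ",
                       paste(unique(spec$regions$chrom[bad]), collapse = ", "))
    len <- genome$length[match(spec$regions$chrom, genome$chrom)]
    if (any(spec$regions$end > len)) stop("region exceeds chromosome bounds")
  }
  p <- spec$purity
  with_seed(spec$seed, {
    per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
      ch <- genome$chrom[i]
      n <- max(2L, as.integer(round(genome$length[i] / 1e6 * spec$probes_per_mb)))
      pos <- sort(sample.int(genome$length[i], n))
      a <- rep(spec$background_split[1], n)
      b <- rep(spec$background_split[2], n)
      regs <- spec$regions[spec$regions$chrom == ch, , drop = FALSE]
      if (!is.null(regs) && nrow(regs)) {
        for (j in seq_len(nrow(regs))) {
          in_r <- pos >= regs$start[j] & pos <= regs$end[j]
          a[in_r] <- regs$copies_a[j]
          b[in_r] <- regs$copies_b[j]
        }
      }
      cc <- a + b
      intensity <- pmax(0, p * cc + (1 - p) * 2 + rnorm(n, sd = spec$noise_sd))
      het <- runif(n) < spec$het_fraction
      # arbitrary per-probe allele labeling: the tracked parental haplotype
      # is A for half the probes
      a_lab <- ifelse(runif(n) < 0.5, a, b)
      denom <- p * cc + (1 - p) * 2
      mu_het <- ifelse(denom > 0, (p * a_lab + (1 - p)) / denom, 0.5)
      mu_hom <- ifelse(runif(n) < 0.5, 1, 0) # germline AA or BB
      mu <- ifelse(het, mu_het, mu_hom)
      ratio <- pmin(1, pmax(0, mu + rnorm(n, sd = spec$baf_sd)))
      data.frame(chrom = ch, pos = pos, intensity = intensity, allele_ratio = ratio)
    })
    probes <- do.call(rbind, per_chrom)
    ps <- normalize_baseline2(probe_set(probes, sample_id = sample_id,
                                        platform = platform))
    attr(ps, "truth") <- spec
    ps
  })
}

#' Karyotype for a named tumor scenario
#'
#' The scenarios mirror the configurations the pipeline must resolve:
#' `diploid` (normal), `focal_amp` (selective HER2-region amplification),
#' `coamp` (HER2 and centromere-proximal regions amplified to the same
#' extent, the FISH-masking pattern), `cnloh` (copy-neutral LOH of a whole
#' chromosome), `polyploid` (whole-genome ploidy `P` with informative
#' whole-chromosome gains/losses that pin down `P`), and `polyploid_focal`
#' (polyploid plus a focal HER2 amplification).
#'
#' For the polyploid scenarios the background split is the most balanced one
#' and four chromosomes deviate: single-copy gain and loss (chromosomes 4
#' and 5, skewed allele splits), a `floor(P/2)`-copy gain and loss
#' (chromosomes 2 and 3), keeping the genome mean near `P` so baseline-2
#' normalization maps the background close to intensity 2.
#'
#' @param scenario scenario name (above).
#' @param ploidy background total copies for the polyploid scenarios
#'   (default 4).
#' @param purity,noise_sd,baf_sd,probes_per_mb,het_fraction,seed passed to
#'   [karyotype_spec()].
#' @return a [karyotype_spec()].
#' @export
scenario_karyotype <- function(scenario = c("diploid", "focal_amp", "coamp",
                                            "cnloh", "polyploid", "polyploid_focal"),
                               ploidy = 4L, purity = 1, noise_sd = 0.1,
                               baf_sd = 0.03, probes_per_mb = 160,
                               het_fraction = 0.3, seed = NULL) {
  scenario <- match.arg(scenario)
  P <- as.integer(ploidy)
  lens <- hg19_lengths()
  chrlen <- function(ch) lens$length[lens$chrom == ch]
  her2_region <- function(a, b) region_state("17", 36000001, 42000000, a, b)
  cent_region <- function(a, b) region_state("17", 20000001, 26000000, a, b)
  whole <- function(ch, a, b) region_state(ch, 1, chrlen(ch), a, b)
  regions <- switch(scenario,
    diploid = NULL,
    focal_amp = her2_region(4L, 1L),
    coamp = rbind(cent_region(3L, 2L), her2_region(3L, 2L)),
    cnloh = whole("4", 2L, 0L),
    polyploid = polyploid_regions(P),
    polyploid_focal = rbind(polyploid_regions(P),
                            her2_region(ceiling(P / 2) + 4L, floor(P / 2)))
  )
  bg <- if (scenario %in% c("polyploid", "polyploid_focal")) P else 2L
  karyotype_spec(background_ploidy = bg, regions = regions, purity = purity,
                 noise_sd = noise_sd, baf_sd = baf_sd,
                 probes_per_mb = probes_per_mb, het_fraction = het_fraction,
                 seed = seed)
}

# helper: split c_tot into (c_tot - minor, minor), clamped
whole_split <- function(c_tot, minor) {
  minor <- min(minor, c_tot)
  c(c_tot - minor, minor)
}

# Informative whole-chromosome deviations for a background ploidy P:
# chr4 gains one copy, chr5 loses one, chr2 gains floor(P/2), chr3 loses
# floor(P/2); allele splits are skewed so the heterozygous bands of the
# deviating chromosomes discriminate P from its divisors.
polyploid_regions <- function(P) {
  lens <- hg19_lengths()
  chrlen <- function(ch) lens$length[lens$chrom == ch]
  k <- max(1L, as.integer(floor(P / 2)))
  mk <- function(ch, c_tot) {
    c_tot <- max(1L, as.integer(c_tot))
    sp <- whole_split(c_tot, if (c_tot >= 3L) 2L else min(1L, c_tot))
    region_state(ch, 1, chrlen(ch), sp[1], sp[2])
  }
  mk_loss <- function(ch, c_tot) {
    c_tot <- max(1L, as.integer(c_tot))
    sp <- whole_split(c_tot, min(1L, c_tot - 1L))
    region_state(ch, 1, chrlen(ch), sp[1], sp[2])
  }
  rbind(
    mk("2", P + k), mk_loss("3", P - k),
    mk("4", P + 1L), mk_loss("5", P - 1L)
  )
}

#' Simulate a labeled cohort of tumor samples
#'
#' Draws `n_samples` synthetic samples from a mixture of named scenarios
#' (see [scenario_karyotype()]), with per-sample purity drawn uniformly from
#' `purity_range` and, for polyploid scenarios, ploidy drawn uniformly from
#' `ploidy_range`. Scenario counts are fixed by rounding the mixture
#' proportions (largest remainders get the leftover samples), so the same
#' seed yields an identical cohort.
#'
#' @param n_samples number of samples.
#' @param mix named numeric vector of scenario proportions summing to 1.
#' @param seed cohort seed (drives per-sample seeds).
#' @param purity_range length-2 numeric; default `c(0.7, 1)`.
#' @param ploidy_range integer candidates for polyploid scenarios, default
#'   `3:8`.
#' @param chroms,probes_per_mb,noise_sd,baf_sd,het_fraction simulation
#'   controls passed through; `chroms` defaults to chromosomes 1-6 and 17
#'   (a desk-scale genome that still contains every scenario's regions).
#' @return list with one element per sample: `probes` (a [probe_set()]),
#'   `truth` (the [karyotype_spec()]) and `scenario`.
#' @export
make_cohort <- function(n_samples, mix = c(diploid = 1), seed = 1L,
                        purity_range = c(0.7, 1), ploidy_range = 3:8,
                        chroms = c("1", "2", "3", "4", "5", "6", "17"),
                        probes_per_mb = 4, noise_sd = 0.1, baf_sd = 0.03,
                        het_fraction = 0.3) {
  stopifnot(n_samples >= 1)
  known <- c("diploid", "focal_amp", "coamp", "cnloh", "polyploid", "polyploid_focal")
  if (is.null(names(mix)) || !all(names(mix) %in% known)) {
    stop("unknown scenario in mix; known: ", paste(known, collapse = ", "))
  }
  if (abs(sum(mix) - 1) > 1e-8) stop("scenario mix proportions must sum to 1")
  counts <- floor(mix * n_samples)
  rem <- n_samples - sum(counts)
  if (rem > 0) {
    extra <- order(mix * n_samples - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  scenarios <- rep(names(mix), counts)
  with_seed(seed, {
    purities <- runif(n_samples, purity_range[1], purity_range[2])
    ploidies <- sample(rep(ploidy_range, 2), n_samples, replace = TRUE)
    sample_seeds <- sample.int(.Machine$integer.max, n_samples)
    lapply(seq_len(n_samples), function(i) {
      spec <- scenario_karyotype(scenarios[i], ploidy = ploidies[i],
                                 purity = purities[i], noise_sd = noise_sd,
                                 baf_sd = baf_sd, probes_per_mb = probes_per_mb,
                                 het_fraction = het_fraction, seed = sample_seeds[i])
      probes <- simulate_probeset(spec, chroms = chroms,
                                  sample_id = sprintf("sim%02d", i))
      list(probes = probes, truth = spec, scenario = scenarios[i])
    })
  })
}
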