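---
title: "HER2 copy-number calling from SNP arrays: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HER2 copy-number calling from SNP arrays: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(her2snp)
```

## The problem

Clinical HER2 (ERBB2) testing in breast cancer rests on immunohistochemistry
(IHC, protein staining scored 0/1+/2+/3+) and fluorescence in situ
hybridization (FISH, the per-nucleus ratio of HER2 probe signals to the
chromosome 17 centromere probe CEP17). Both have known blind spots: the FISH
ratio is invariant to any change that scales both signals together, so
co-amplification of the centromeric region or whole-genome polyploidy leaves
the ratio near 1 while the absolute HER2 copy number is elevated.
High-density SNP arrays measure an absolute, genome-anchored copy-number
signal plus allele ratios, and can expose exactly those hidden cases.

`her2snp` re-implements that analysis as a reusable, tested pipeline:
probe-level normalization, breakpoint segmentation, threshold-based status
calling, HER2-vs-centromere relation labeling, polyploidy inference from
allelic balance, a virtual FISH ratio, and the concordance analysis against
a packaged 65-tumor clinical table.

## Signal model

Probe intensities are expressed on the copy-number scale where the
genome-wide mean is defined to be state 2 (`normalize_baseline2()`). For a
locus with `c` tumor copies at tumor-cell fraction (purity) `p`, the
pre-normalization expectation is `p*c + (1-p)*2`; normalization divides by
the genome average, which is why a uniformly tetraploid genome is mapped
back onto the diploid picture — the central identifiability problem the
allelic-balance analysis resolves.

At a germline-heterozygous SNP with parental copies `(a, b)`, `a + b = c`,
the expected allele ratio is

    r = (p*a + (1-p)) / (p*c + 2*(1-p)),

so heterozygous loci cluster in mirror-symmetric bands `{r, 1-r}` (array
allele labeling is arbitrary, so every downstream rule is mirror-symmetric).
Balanced segments show a single band at 0.5; copy-neutral LOH shows no
heterozygous band at normal intensity.

## Segmentation

`segment_sample()` detects breakpoints per chromosome by top-down recursive
bisection. A candidate split is scanned exhaustively over all admissible
positions and accepted iff

1. the two sides differ by a Welch two-sample t-test at `p < 0.001`;
2. among candidates the smallest p-value wins (ties to the leftmost index);
3. both sides contain at least `min_points` probes (100 for 500K-class
   arrays, 200 for SNP 6.0-class);
4. the mean change is at least 0.3 times the per-chromosome noise estimate
   (`estimate_noise()`: MAD of lag-1 differences divided by sqrt(2), robust
   to the level shifts it is meant to measure).

Two numerical details matter. P-values at strong breakpoints underflow
double precision, so candidate selection happens on the log scale
(`pt(..., log.p = TRUE)`); comparing raw p-values ties at zero and
mislocalizes breakpoints by dozens of probes. And greedy bisection is known
to misplace the first cut on "bump" profiles; with adequate probe density
the recursion self-corrects, but it can strand a `min_points`-sized mixed
sliver at an amplicon edge — which is why downstream evidence is
probe-count weighted (below). No post-hoc merging of adjacent segments is
performed.

## Copy-number status and the HER2 call

Segment means classify as deletion below 1.8, amplification above 2.2, and
normal on the closed interval [1.8, 2.2] (`classify_cn()`); the boundary
value 1.80 is a published normal call, fixing inclusivity. `her2_call()`
evaluates the probe-weighted mean over the HER2 interval
(chr17:37,642,255-37,970,066, Hg19) and a centromere-proximal window
(default chr17:22,200,000-25,800,000 — the CEP17-homologous interval is not
published, so this default is configurable) and labels the relation
`balance` / `HER2plus` / `centplus` with tolerance 0.2, the same width as
the status band. Amplifications of at least 4-fold are classed `high`,
others `moderate`. `virtual_fish()` is the ratio of the two values with the
clinical inclusive cut-off of 2 — provably scale-invariant, which is the
formal statement of the masking effect.

## Ploidy inference

`infer_ploidy()` scans candidate baselines `P = 2..12` and returns the
smallest one consistent with the joint copy-number/allelic evidence — the
lowest possible estimate, flagged `+` when `P + 1` is equally consistent. A
sample is polyploid when the median implied copy number across chromosomes
is 3 or more.

For each segment with a determined allelic state, a candidate `P` implies a
real-valued copy estimate by inverting the purity mixture,
`c_est = ((I/2)(pP + 2(1-p)) - 2(1-p))/p`. Consistency requires:

- `c_est` within 0.25 of an integer `c` (a wrong baseline maps true integer
  states to systematically non-integer estimates; this is what makes
  low-purity samples come back *unresolved* instead of resolving to an
  arbitrary ploidy);
- every observed band center within 0.04 of a predicted band
  `(pa + (1-p))/(pc + 2(1-p))` for some split `a = 0..c` — endpoints
  included, because with normal-cell admixture the `a ∈ {0, c}` splits
  detach from ratio 0/1 (at purity 0.85 a single-copy segment shows residual
  bands at 0.13/0.87);
- balanced segments require `c` even; LOH segments are attainable under any
  baseline.

The score is the probe-count-weighted fraction of consistent evidentiary
segments; a candidate passes at a floor of 0.95. Purity is an input
parameter (default 1.0); joint purity-ploidy optimization is an extension
point, not implemented. `implied_copies()` itself keeps the simple
quantization `round(I*P/2)` (half-up) used for reporting absolute HER2
copies (`her2_absolute_copies()`), matching the deduction that an intensity
near 2 with allelic balance on a tetraploid baseline means 4 copies.

Band detection (`detect_allelic_state()`) pools ratios with their mirror
images, scans a fixed-bandwidth (0.02) kernel density for modes, drops
homozygous modes within 0.08 of 0/1, and requires at least 30 ratios and a
minimum mode density of 1.5 (a uniform, structureless distribution has
density ~1 and must not count as evidence). Segments failing these gates
are `undetermined` and excluded.

## The synthetic world

`simulate_probeset()` emulates exactly the signal model above: probes
placed uniformly at random on Hg19 chromosome lengths, homoscedastic
Gaussian intensity noise (default sd 0.1) and allele-ratio noise (default
sd 0.03), a 30% germline heterozygosity rate, and per-probe random allele
labeling. Scenario generators cover diploid, focal HER2 amplification,
HER2+centromere co-amplification, copy-neutral LOH, and whole-genome
polyploidy with informative chromosome-level gains/losses that pin the
baseline down (a uniformly tetraploid genome is *deliberately* unresolvable
below 4 — minimality then reports 2 — so the polyploid scenarios include
odd-copy deviations, as real tumors do).

What the generator does not model: probe-specific effects, GC waves,
intensity saturation at high amplification (the published segment value
11.10 against an estimated 25+ copies suggests the real platform
compresses), linkage structure, and more than two cell populations. A green
simulation test therefore establishes correctness of the *stated* model,
not robustness to every array artifact.

Test and cohort simulations are scaled down for run time (chromosome
subsets, a few probes per Mb). Focal-amplicon scenarios use at least 20
probes/Mb so a 6 Mb amplicon comfortably exceeds `min_points`; on the real
~160 probes/Mb platform even the ~328 kb minimal amplicon does.

## Clinical comparison

`ihc_fish_classify()` encodes the clinical rule (3+ positive; 2+ equivocal,
resolved by FISH at the inclusive ratio cut-off 2.0; 0/1+ negative), and
`concordance()` compares it against the SNP status (positive = amplified)
over the packaged table. Original IHC/FISH values drive the headline
numbers; `use_revised = TRUE` substitutes the re-analysis values of samples
49, 60 and 63, which converts exactly those three to concordant. The
packaged tables are validated on load (row count, checksum, label
vocabulary, revised-value placement).

## Numerical choices and degenerate inputs

- Half-up rounding (`floor(x + 0.5)`) for copy quantization and the kb span
  (base R rounds half to even).
- All-zero intensities, empty probe sets, sub-`min_points` chromosomes
  (single flagged segment), IHC 2+ without FISH, unresolved ploidy: each
  fails loudly or is flagged, never silently guessed.
- Determinism: every simulation takes a seed; `run_pipeline()` writes a
  manifest and identical config+seed reproduce byte-identical outputs.

## Known limitations

- The per-sample polyploidy estimates of the original 65-tumor cohort are
  not reproducible here: raw arrays are unavailable, so ploidy logic is
  validated on simulations only.
- The published balance/HER2+/cent+ labels per sample are not re-derived
  (the centromeric comparison values are unpublished); the relation rule is
  exercised on synthetic data.
- Ploidy candidates above 12 are out of range by default; tumors with
  extreme amplification plus saturation (e.g. a segment value of 8 mapping
  to an estimated 7 copies under no linear model) are recorded, not fitted.
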