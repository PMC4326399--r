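test_that("detect_allelic_state classifies balance, imbalance, LOH and thin data", {
  withr::local_seed(1)
  bal <- detect_allelic_state(pmin(1, pmax(0, rnorm(200, 0.5, 0.03))))
  expect_true(bal$determined)
  expect_true(bal$balanced)
  expect_false(bal$loh)
  expect_equal(bal$band_centers, 0.5, tolerance = 0.02)

  r <- pmin(1, pmax(0, rnorm(300, sample(c(1 / 3, 2 / 3), 300, TRUE), 0.03)))
  im <- detect_allelic_state(r)
  expect_false(im$balanced)
  expect_equal(sort(im$band_centers), c(1 / 3, 2 / 3), tolerance = 0.02)

  loh <- detect_allelic_state(pmin(1, pmax(0, rnorm(200, sample(c(0.01, 0.99), 200, TRUE), 0.015))))
  expect_true(loh$loh)
  expect_length(loh$band_centers, 0)

  thin <- detect_allelic_state(runif(10))
  expect_false(thin$determined)
  expect_error(detect_allelic_state(c(0.5, 1.4)), "\\[0, 1\\]")
})

test_that("implied_copies quantizes intensity on a candidate baseline", {
  expect_equal(implied_copies(2.0, 4), 4L)
  expect_equal(implied_copies(1.6, 4), 3L)
  expect_equal(implied_copies(2.2, 4), 4L)
  expect_equal(implied_copies(2.0, 2), 2L)
  expect_equal(implied_copies(2.25, 4), 5L) # half-up at .5
})

test_that("consistency_score separates candidate baselines", {
  # diploid: balanced at 2 plus one (2,1) trisomy at 3
  segs <- rbind(seg_row("1", 2.0), seg_row("2", 2.0), seg_row("3", 3.0))
  states <- list(band_state(0.5, balanced = TRUE),
                 band_state(0.5, balanced = TRUE),
                 band_state(c(1 / 3, 2 / 3)))
  expect_equal(consistency_score(segs, states, 2)$score, 1)
  # P = 3: the balanced segments imply 3 copies, impossible to balance
  expect_lt(consistency_score(segs, states, 3)$score, 1)
  # undetermined states are excluded; all-undetermined is unevaluable
  none <- list(band_state(determined = FALSE), band_state(determined = FALSE),
               band_state(determined = FALSE))
  cs <- consistency_score(segs, none, 2)
  expect_true(is.na(cs$score))
  expect_equal(cs$n_evidentiary, 0L)
  # LOH segments are attainable under any baseline
  expect_equal(consistency_score(seg_row("1", 2.0), list(band_state(loh = TRUE)), 2)$score, 1)
  # non-integer copy estimate under the candidate baseline is inconsistent
  expect_equal(consistency_score(seg_row("1", 2.7), list(band_state(c(1 / 3, 2 / 3))), 2)$score, 0)
})

test_that("a weakly imbalanced near-2 chromosome forces at least four copies", {
  # genome-wide allelic balance at intensity ~2 with one chromosome just
  # under 2 showing a weak imbalance: inconsistent with a diploid baseline,
  # consistent with a tetraploid one
  p <- 0.3
  i_bal <- 2.02
  i_imb <- 1.79
  segs <- rbind(seg_row("13", i_bal), seg_row("14", i_imb), seg_row("15", i_bal))
  b14 <- (p * 2 + (1 - p)) / (p * 3 + (1 - p) * 2)
  states <- list(band_state(0.5, balanced = TRUE),
                 band_state(c(1 - b14, b14)),
                 band_state(0.5, balanced = TRUE))
  cs2 <- consistency_score(segs, states, 2, purity = p)
  expect_false(cs2$consistent[2])
  expect_equal(consistency_score(segs, states, 4, purity = p)$score, 1)
})

test_that("infer_ploidy recovers simulated baselines and reports minimality", {
  run_one <- function(scenario, ploidy, purity, seed, density = 4,
                      chroms = c("1", "2", "3", "4", "5", "6", "17")) {
    spec <- scenario_karyotype(scenario, ploidy = ploidy, purity = purity,
                               probes_per_mb = density, seed = seed)
    ps <- simulate_probeset(spec, chroms = chroms)
    segs <- suppressMessages(segment_sample(ps))
    states <- segment_allelic_states(ps, segs)
    infer_ploidy(segs, states, purity = purity)
  }

  tetra <- run_one("polyploid", 4L, 0.9, seed = 31)
  expect_true(tetra$resolved)
  expect_equal(tetra$min_ploidy, 4L)
  expect_true(tetra$polyploid)
  # minimality: no smaller candidate reaches the floor
  expect_true(all(tetra$scores[as.integer(names(tetra$scores)) < 4] < 0.95))

  dip <- run_one("focal_amp", 2L, 0.9, seed = 32, density = 60,
                 chroms = c("1", "2", "17"))
  expect_true(dip$resolved)
  expect_equal(dip$min_ploidy, 2L)
  expect_false(dip$polyploid)

  octo <- run_one("polyploid", 8L, 0.85, seed = 33)
  expect_equal(octo$min_ploidy, 8L)
  expect_true(octo$polyploid)

  # copy-neutral LOH flags UPD segments without breaking the diploid call
  loh <- run_one("cnloh", 2L, 1, seed = 34, density = 2)
  expect_equal(loh$min_ploidy, 2L)
  expect_gt(length(loh$upd_flags), 0L)

  # pure-noise ratios: unevaluable
  withr::local_seed(35)
  ps <- toy_probes(rnorm(600, 2, 0.1), allele_ratio = runif(600))
  segs <- segment_sample(ps)
  states <- segment_allelic_states(ps, segs)
  noise_call <- infer_ploidy(segs, states)
  expect_false(noise_call$resolved)
})

test_that("ploidy calls are mirror-symmetric in the allele labeling", {
  spec <- scenario_karyotype("polyploid", ploidy = 3L, purity = 0.85,
                             probes_per_mb = 4, seed = 36)
  ps <- simulate_probeset(spec, chroms = c("1", "2", "3", "4", "5", "6", "17"))
  segs <- suppressMessages(segment_sample(ps))
  flip <- ps
  flip$allele_ratio <- 1 - flip$allele_ratio
  st1 <- segment_allelic_states(ps, segs)
  st2 <- segment_allelic_states(flip, segs)
  for (i in seq_along(st1)) {
    expect_equal(st1[[i]]$balanced, st2[[i]]$balanced)
    expect_equal(st1[[i]]$loh, st2[[i]]$loh)
    expect_equal(st1[[i]]$band_centers, st2[[i]]$band_centers, tolerance = 1e-6)
  }
  c1 <- infer_ploidy(segs, st1, purity = 0.85)
  c2 <- infer_ploidy(segs, st2, purity = 0.85)
  expect_equal(c1$min_ploidy, c2$min_ploidy)
  expect_equal(c1$polyploid, c2$polyploid)
})

test_that("her2_absolute_copies scales the HER2 value by the inferred baseline", {
  pc <- structure(list(resolved = TRUE, min_ploidy = 4L, is_lower_bound = FALSE),
                  class = "ploidy_call")
  expect_equal(her2_absolute_copies(2.0, pc)$copies, 4L)
  expect_equal(her2_absolute_copies(3.0, pc)$label, "6")
  pc$is_lower_bound <- TRUE
  expect_equal(her2_absolute_copies(2.0, pc)$label, "4+")
  pc2 <- structure(list(resolved = FALSE), class = "ploidy_call")
  expect_error(her2_absolute_copies(2.0, pc2), "unresolved")
})
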