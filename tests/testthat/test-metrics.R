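test_that("half-height width follows the per-site rule on a hand-worked signal", {
  ## flank 4 (span 9), bg_margin 1: max 10, threshold 5, background is the
  ## lower median of the two outer 2-value windows, run (6,10,10,6) -> 4
  sig <- c(1, 1, 4, 6, 10, 10, 6, 4, 1)
  r <- half_height_width(sig, flank = 4, bg_margin = 1)
  expect_equal(r$max_value, 10)
  expect_equal(r$threshold, 5)
  expect_equal(r$background, 1)
  expect_equal(r$width, 4)
  expect_equal(r$qc_flag, "ok")
  expect_equal(r$max_offset, 0)   # leftmost of the tied maxima

  expect_error(half_height_width(sig, flank = 3), "span")
})

test_that("flat and zero-background signals are flagged but still measured", {
  flat <- rep(2, 9)
  r <- half_height_width(flat, flank = 4, bg_margin = 1)
  expect_equal(r$qc_flag, "flat")
  expect_equal(r$width, 9)

  zb <- c(0, 0, 0, 2, 8, 2, 0, 0, 0)
  r2 <- half_height_width(zb, flank = 4, bg_margin = 1)
  expect_equal(r2$qc_flag, "zero_background")
  expect_equal(r2$width, 1)   # only the 8 clears 4
})

test_that("half-height width is invariant under positive scaling", {
  set.seed(12)
  for (i in 1:20) {
    flank <- 30
    sig <- abs(rnorm(2 * flank + 1, 1)) + 3 * dnorm(-flank:flank, 0, 5)
    a <- half_height_width(sig, flank = flank, bg_margin = 5)
    b <- half_height_width(sig * runif(1, 0.01, 100), flank = flank,
                           bg_margin = 5)
    expect_equal(a$width, b$width)
    expect_equal(a$max_offset, b$max_offset)
  }
})

test_that("half-height width agrees with the exhaustive scan oracle", {
  set.seed(100)
  for (i in 1:200) {
    flank <- sample(10:100, 1)   # spans up to 201
    bg_margin <- sample(2:(flank - 1), 1)
    sig <- rpois(2 * flank + 1, 2) + 5 * dnorm(-flank:flank, 0, flank / 6)
    got <- half_height_width(sig, flank = flank, bg_margin = bg_margin)
    want <- oracle_half_height(sig, flank, bg_margin)
    expect_equal(got$width, want$width)
    expect_equal(got$background, want$background)
  }
})

test_that("midrise thresholding raises the threshold above half-max", {
  sig <- c(4, 4, 4, 5, 8, 5, 4, 4, 4)
  hm <- half_height_width(sig, flank = 4, bg_margin = 1)
  mr <- half_height_width(sig, flank = 4, bg_margin = 1,
                          threshold_mode = "midrise")
  expect_equal(hm$threshold, 4)
  expect_equal(mr$threshold, 4 + (8 - 4) / 2)
  expect_lt(mr$width, hm$width)
})

test_that("batch half-height widths summarize quartiles over rows", {
  g <- toy_genome()
  fs <- toy_fragments(g, n = 600, seed = 2, len_min = 20, len_max = 50)
  sites <- random_sites(g, n = 15, seed = 44, width = 19)
  tr <- normalize_coverage(compute_coverage(fs, g))
  flank <- 300
  ok <- sites$center - flank >= 0 &
    sites$center + flank <= g$chrom_lengths[sites$chrom] - 1
  m <- site_matrix(tr, sites[ok, ], flank = flank)
  hh <- half_height_widths(m, flank = flank, bg_margin = 50)
  expect_equal(nrow(hh$per_site), nrow(m))
  expect_true(all(hh$per_site$width >= 1))
  expect_equal(names(hh$summary), c("q25", "median", "q75"))
  for (i in seq_len(nrow(m))) {
    expect_equal(hh$per_site$width[i],
                 half_height_width(m[i, ], flank, 50)$width)
  }
})

test_that("split-mode peak pair uses per-profile argmaxes", {
  fs <- fragment_set(data.frame(chrom = "chr1", start = 100, end = 119))
  site <- motif_sites(data.frame(chrom = "chr1", start = 100, end = 119,
                                 strand = "+"))
  ep <- end_profile(fs, site, flank = 20)
  pp <- peak_pair_separation(ep, source = "split")
  expect_equal(pp$left_peak_offset, -9)
  expect_equal(pp$right_peak_offset, 10)
  expect_equal(pp$separation, 19)
  expect_true(pp$separation_defined)
})

test_that("combined-mode peak pair on a hand-evaluated profile", {
  prof <- structure(list(offsets = -3:3,
                         left_counts = c(0, 5, 1, 0, 1, 6, 0),
                         right_counts = rep(0, 7),
                         combined = c(0, 5, 1, 0, 1, 6, 0),
                         mode = "paired_end", flank = 3, n_sites = 1),
                    class = "EndProfile")
  pp <- peak_pair_separation(prof, source = "combined",
                             min_peak_distance = 2)
  expect_equal(pp$left_peak_offset, -2)
  expect_equal(pp$right_peak_offset, 2)
  expect_equal(pp$separation, 4)
  expect_equal(pp$n_predominant_peaks, 2)
})

test_that("unimodal profiles flag the separation as undefined", {
  prof <- structure(list(offsets = -3:3,
                         left_counts = c(0, 1, 2, 6, 2, 1, 0),
                         right_counts = rep(0, 7),
                         combined = c(0, 1, 2, 6, 2, 1, 0),
                         mode = "paired_end", flank = 3, n_sites = 1),
                    class = "EndProfile")
  pp <- peak_pair_separation(prof, source = "combined")
  expect_equal(pp$n_predominant_peaks, 1)
  expect_false(pp$separation_defined)
  expect_true(is.na(pp$separation))

  zero <- prof; zero$combined <- rep(0, 7)
  expect_error(peak_pair_separation(zero), "all zero")
})

test_that("spacing filter keeps exactly the well-separated sites", {
  s <- motif_sites(data.frame(chrom = "chr1",
                              start = c(0, 300, 900) - 0,
                              end = c(0, 300, 900) + 19,
                              name = c("a", "b", "c"), strand = "+"))
  ## centers 9, 309, 909: a<->b 300 apart (both fail), c's nearest is 600
  kept <- motif_spacing_filter(s, min_sep = 500)
  expect_equal(kept$name, "c")

  one <- motif_spacing_filter(s[1, , drop = FALSE], min_sep = 500)
  expect_equal(nrow(one), 1)

  two_chrom <- motif_sites(data.frame(chrom = c("chr1", "chr2"),
                                      start = c(100, 110),
                                      end = c(119, 129), strand = "+"))
  expect_equal(nrow(motif_spacing_filter(two_chrom, 500)), 2)
})

test_that("spacing filter agrees with pairwise brute force and is idempotent", {
  for (seed in 1:40) {
    sites <- random_sites(toy_genome(), n = sample(2:30, 1), seed = seed)
    min_sep <- sample(c(100, 300, 500, 1000), 1)
    got <- motif_spacing_filter(sites, min_sep)
    want <- oracle_spacing(sites, min_sep)
    expect_equal(got$name, want$name)
    twice <- motif_spacing_filter(got, min_sep)
    expect_equal(twice$name, got$name)
    expect_true(all(got$name %in% sites$name))
  }
})

test_that("split-mode separation recovers the footprint length with exact chew-back", {
  g <- genome_info(c(chr1 = 2e5))
  for (fp in c(10, 17, 24, 33, 40)) {
    sites <- tile_motif_sites(g, 30, width = fp, strand = "+")
    cfg <- synth_config(footprint_len = fp, chew_p = 1,
                        fragments_per_site = 30, background_rate = 0,
                        seed = fp)
    sim <- simulate_tf_chip(g, sites, cfg)
    ep <- end_profile(sim$fragments, sites, flank = 60)
    pp <- peak_pair_separation(ep, source = "split")
    expect_equal(pp$separation, fp)
  }
  ## with stochastic chew-back the overhang mode is still 0, so the modal
  ## ends remain the footprint edges
  for (fp in c(12, 28)) {
    sites <- tile_motif_sites(g, 60, width = fp, strand = "+")
    cfg <- synth_config(footprint_len = fp, chew_p = 0.5,
                        fragments_per_site = 200, background_rate = 0,
                        seed = fp)
    sim <- simulate_tf_chip(g, sites, cfg)
    ep <- end_profile(sim$fragments, sites, flank = 60)
    expect_equal(peak_pair_separation(ep, source = "split")$separation, fp)
  }
})
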