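track_from_values <- function(values, genome) {
  structure(list(values = values, scale = "raw_counts",
                 n_total_mapped = 1, genome = genome),
            class = "CoverageTrack")
}

test_that("site matrix extracts oriented windows and drops edge sites", {
  g <- genome_info(c(chr1 = 100))
  v <- numeric(100); v[48:52] <- c(1, 2, 3, 4, 5)   # coords 47..51
  tr <- track_from_values(list(chr1 = v), g)
  plus <- motif_sites(data.frame(chrom = "chr1", start = 40, end = 59,
                                 name = "p", strand = "+"))  # center 49
  m <- site_matrix(tr, plus, flank = 2)
  expect_equal(unname(m[1, ]), c(1, 2, 3, 4, 5))
  expect_equal(colnames(m), as.character(-2:2))

  minus <- plus; minus$strand <- "-"
  m2 <- site_matrix(tr, minus, flank = 2)
  expect_equal(unname(m2[1, ]), c(5, 4, 3, 2, 1))

  near_edge <- motif_sites(data.frame(chrom = "chr1", start = 0, end = 11,
                                      strand = "+"))  # center 5
  both <- motif_sites(rbind(plus[, c("chrom", "start", "end", "strand")],
                            near_edge[, c("chrom", "start", "end", "strand")]))
  m3 <- site_matrix(tr, both, flank = 10)
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "n_dropped"), 1)
  expect_error(site_matrix(tr, plus[0, ], flank = 2), "empty")
})

test_that("average profile is the column mean and conserves the matrix total", {
  one <- matrix(c(1, 5, 2), nrow = 1)
  expect_equal(unname(average_profile(one)), c(1, 5, 2))
  two <- rbind(c(0, 2), c(2, 0))
  expect_equal(unname(average_profile(two)), c(1, 1))
  set.seed(4)
  m <- matrix(rpois(20 * 11, 3), nrow = 20)
  expect_equal(sum(average_profile(m)) * nrow(m) / 1, sum(m))
  expect_error(average_profile(m[0, , drop = FALSE]), "rows")
})

test_that("fragment exactly spanning a 19-bp motif yields end peaks 19 bp apart", {
  fs <- fragment_set(data.frame(chrom = "chr1", start = 100, end = 119))
  plus <- motif_sites(data.frame(chrom = "chr1", start = 100, end = 119,
                                 strand = "+"))  # center 109
  ep <- end_profile(fs, plus, flank = 20)
  expect_equal(ep$offsets[ep$left_counts > 0], -9)
  expect_equal(ep$offsets[ep$right_counts > 0], 10)
  expect_equal(10 - (-9), 19)

  ## minus-strand site: roles swap, offsets negate, separation still 19
  minus <- plus; minus$strand <- "-"
  em <- end_profile(fs, minus, flank = 20)
  expect_equal(em$offsets[em$left_counts > 0], -10)
  expect_equal(em$offsets[em$right_counts > 0], 9)

  ## fragment wholly outside the window contributes nothing
  far <- fragment_set(data.frame(chrom = "chr1", start = 500, end = 540))
  ef <- end_profile(far, plus, flank = 20)
  expect_true(all(ef$combined == 0))
})

test_that("end profile matches brute-force per-site counting on random data", {
  g <- toy_genome()
  for (seed in 1:3) {
    fs <- toy_fragments(g, n = 120, seed = seed, len_min = 15, len_max = 60)
    sites <- random_sites(g, n = 12, seed = seed + 50)
    ep <- end_profile(fs, sites, flank = 80)
    want <- oracle_end_profile(fs, sites, 80)
    expect_equal(ep$left_counts, want$left)
    expect_equal(ep$right_counts, want$right)
    expect_equal(ep$combined, want$left + want$right)
  }
})

test_that("single-end bias mode counts forward 5' and reverse 3' ends only", {
  fr <- data.frame(chrom = "chr1",
                   start = c(90, 95, 130),
                   end = c(115, 120, 160),
                   strand = c("+", "-", "-"))
  fs <- fragment_set(fr)
  site <- motif_sites(data.frame(chrom = "chr1", start = 100, end = 119,
                                 strand = "+"))  # center 109
  ep <- end_profile(fs, site, flank = 60, mode = "single_end_bias")
  expect_equal(sum(ep$left_counts), 1)                  # only the "+" read
  expect_equal(ep$offsets[ep$left_counts > 0], 90 - 109)
  expect_equal(sum(ep$right_counts), 2)                 # the two "-" reads
  expect_equal(ep$offsets[ep$right_counts > 0], c(120, 160) - 109)
  fs_nostrand <- fragment_set(fr[, c("chrom", "start", "end")])
  expect_error(end_profile(fs_nostrand, site, 60, mode = "single_end_bias"),
               "strand")
})

test_that("V-plot places counts at (length, midpoint offset) and normalizes", {
  site <- motif_sites(data.frame(chrom = "chr1", start = 100, end = 119,
                                 strand = "+"))  # center 109
  fs <- fragment_set(data.frame(chrom = "chr1", start = 95, end = 125))
  ## length 30, midpoint floor((95+125)/2) = 110 -> offset +1
  v <- vplot(fs, site, flank = 10, len_min = 20, len_max = 40)
  expect_equal(sum(v$matrix), 1)
  expect_equal(v$matrix["30", "1"], 1)

  vp <- vplot(fs, site, flank = 2, len_min = 29, len_max = 33,
              normalization = "per_pixel")
  expect_equal(sum(vp$matrix > 0), 1)
  expect_equal(max(vp$matrix), 1 / 25)
})

test_that("V-plot totals and column sums match the midpoint histogram", {
  g <- toy_genome()
  fs <- toy_fragments(g, n = 200, seed = 17, len_min = 10, len_max = 80)
  sites <- random_sites(g, n = 8, seed = 99)
  flank <- 60
  v <- vplot(fs, sites, flank = flank, len_min = 1, len_max = 100)
  ## brute-force midpoint histogram over (site, fragment) incidences
  mids <- fragment_midpoint(fs$fragments$start, fs$fragments$end)
  hist <- numeric(2 * flank + 1)
  for (i in seq_len(nrow(sites))) {
    on_ch <- fs$fragments$chrom == sites$chrom[i]
    off <- mids[on_ch] - sites$center[i]
    if (sites$strand[i] == "-") off <- -off
    off <- off[abs(off) <= flank]
    for (o in off) hist[o + flank + 1] <- hist[o + flank + 1] + 1
  }
  expect_equal(unname(colSums(v$matrix)), hist)
  expect_equal(v$n_incidences, sum(hist))
})

test_that("flipping every site strand reverses profiles exactly", {
  g <- toy_genome()
  fs <- toy_fragments(g, n = 150, seed = 23, len_min = 15, len_max = 50)
  sites <- random_sites(g, n = 10, seed = 31)
  flipped <- sites
  flipped$strand <- ifelse(sites$strand == "+", "-", "+")

  tr <- compute_coverage(fs, g)
  m <- site_matrix(tr, sites, flank = 30)
  mf <- site_matrix(tr, flipped, flank = 30)
  expect_equal(unname(mf), unname(m[, ncol(m):1]), ignore_attr = TRUE)

  v <- vplot(fs, sites, flank = 30, len_min = 1, len_max = 80)
  vf <- vplot(fs, flipped, flank = 30, len_min = 1, len_max = 80)
  expect_equal(vf$matrix, v$matrix[, ncol(v$matrix):1, drop = FALSE],
               ignore_attr = TRUE)
})

test_that("profile, end-profile and V-plot writers emit offset-headed TSV", {
  g <- genome_info(c(chr1 = 200))
  tr <- track_from_values(list(chr1 = rep(1, 200)), g)
  sites <- motif_sites(data.frame(chrom = "chr1", start = 90, end = 109,
                                  name = "a", strand = "+"))
  m <- site_matrix(tr, sites, flank = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_profile_matrix(m, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(names(tab), c("site_id", as.character(-3:3)))

  fs <- fragment_set(data.frame(chrom = "chr1", start = 90, end = 109))
  ep <- end_profile(fs, sites, flank = 5)
  write_end_profile(ep, path)
  tab2 <- read.delim(path)
  expect_equal(tab2$offset, -5:5)
  expect_equal(sum(tab2$combined), sum(ep$combined))

  v <- vplot(fs, sites, flank = 5, len_min = 15, len_max = 25)
  write_vplot(v, path)
  tab3 <- read.delim(path, check.names = FALSE)
  expect_equal(tab3$length, 15:25)
})
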