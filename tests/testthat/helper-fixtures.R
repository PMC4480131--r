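## Fixture builders and independent brute-force oracles shared by the suite.

toy_genome <- function(len = c(chr1 = 10000, chr2 = 5000)) genome_info(len)

toy_fragments <- function(genome = toy_genome(), n = 200, seed = 42,
                          len_min = 10, len_max = 200) {
  set.seed(seed)
  clen <- genome$chrom_lengths
  ch <- sample(names(clen), n, replace = TRUE)
  len <- sample(len_min:len_max, n, replace = TRUE)
  start <- floor(runif(n) * (clen[ch] - len))
  fragment_set(data.frame(chrom = ch, start = start, end = start + len,
                          stringsAsFactors = FALSE),
               genome = genome)
}

random_sites <- function(genome = toy_genome(), n = 20, width = 19,
                         seed = 7) {
  set.seed(seed)
  clen <- genome$chrom_lengths
  ch <- sample(names(clen), n, replace = TRUE)
  start <- floor(runif(n) * (clen[ch] - width))
  motif_sites(data.frame(chrom = ch, start = start, end = start + width,
                         name = sprintf("s%d", seq_len(n)),
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         stringsAsFactors = FALSE))
}

## --- independent oracles -------------------------------------------------

## exhaustive re-implementation of the per-site half-height rule: threshold,
## split the above-threshold offsets into runs, take the run holding the
## leftmost maximum
oracle_half_height <- function(signal, flank, bg_margin) {
  n <- 2 * flank + 1
  bg <- sort(c(signal[1:(bg_margin + 1)], signal[(n - bg_margin):n]))
  background <- bg[floor((length(bg) + 1) / 2)]
  mx <- max(signal)
  thr <- mx / 2
  above <- which(signal >= thr)
  runs <- split(above, cumsum(c(1, diff(above) != 1)))
  argmax <- which(signal == mx)[1]
  run <- runs[[which(vapply(runs, function(r) argmax %in% r, logical(1)))]]
  list(background = background, width = length(run))
}

## O(n^2) pairwise spacing filter
oracle_spacing <- function(sites, min_sep) {
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    same <- sites$chrom == sites$chrom[i]
    same[i] <- FALSE
    if (!any(same)) return(TRUE)
    min(abs(sites$center[same] - sites$center[i])) >= min_sep
  }, logical(1))
  sites[keep, , drop = FALSE]
}

## per-bp scan peak caller: walk every position, accumulate runs, bridge
## gaps, then drop narrow peaks
oracle_peaks <- function(values, threshold, min_width, max_gap) {
  peaks <- list()
  cur_start <- NA
  cur_end <- NA
  for (i in seq_along(values)) {
    if (values[i] >= threshold) {
      if (is.na(cur_start)) {
        cur_start <- i
      } else if (i - cur_end - 1 > max_gap) {
        peaks[[length(peaks) + 1]] <- c(cur_start, cur_end)
        cur_start <- i
      }
      cur_end <- i
    }
  }
  if (!is.na(cur_start)) peaks[[length(peaks) + 1]] <- c(cur_start, cur_end)
  out <- do.call(rbind, peaks)
  if (is.null(out)) return(matrix(numeric(), ncol = 2))
  out[out[, 2] - out[, 1] + 1 >= min_width, , drop = FALSE]
}

## direct per-(site, fragment) end counting
oracle_end_profile <- function(fragset, sites, flank) {
  offs <- -flank:flank
  left <- right <- setNames(numeric(length(offs)), offs)
  fr <- fragset$fragments
  for (i in seq_len(nrow(sites))) {
    c0 <- sites$center[i]
    on_ch <- fr$chrom == sites$chrom[i]
    if (sites$strand[i] == "+") {
      lo <- fr$start[on_ch] - c0
      ro <- fr$end[on_ch] - c0
    } else {
      lo <- c0 - fr$end[on_ch]
      ro <- c0 - fr$start[on_ch]
    }
    for (o in lo[abs(lo) <= flank]) left[as.character(o)] <-
        left[as.character(o)] + 1
    for (o in ro[abs(ro) <= flank]) right[as.character(o)] <-
        right[as.character(o)] + 1
  }
  list(left = unname(left), right = unname(right))
}

## minimal SAM text for the BAM ingestion test: two proper pairs on chr1
## (inserts [100,205) and [300,340)), one low-mapq pair, one discordant pair
write_toy_sam <- function(path) {
  seq25 <- strrep("A", 25)
  q25 <- strrep("I", 25)
  lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:10000",
    "@SQ\tSN:chr2\tLN:5000",
    paste("pair1", 99, "chr1", 101, 60, "25M", "=", 181, 105, seq25, q25,
          sep = "\t"),
    paste("pair1", 147, "chr1", 181, 60, "25M", "=", 101, -105, seq25, q25,
          sep = "\t"),
    paste("pair2", 99, "chr1", 301, 60, "25M", "=", 316, 40, seq25, q25,
          sep = "\t"),
    paste("pair2", 147, "chr1", 316, 60, "25M", "=", 301, -40, seq25, q25,
          sep = "\t"),
    paste("pair3", 99, "chr1", 501, 5, "25M", "=", 601, 125, seq25, q25,
          sep = "\t"),
    paste("pair3", 147, "chr1", 601, 5, "25M", "=", 501, -125, seq25, q25,
          sep = "\t"),
    paste("pair4", 97, "chr1", 701, 60, "25M", "chr2", 50, 0, seq25, q25,
          sep = "\t"),
    paste("pair4", 145, "chr2", 50, 60, "25M", "chr1", 701, 0, seq25, q25,
          sep = "\t"))
  writeLines(lines, path)
  path
}
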