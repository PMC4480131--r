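#' Per-base fragment coverage
#'
#' The value at each base pair is the number of fragments whose interval
#' spans that position — the fragments themselves are the protected
#' footprints, so coverage of the full insert (not 5' ends) is the signal.
#'
#' @param fragset A [fragment_set()] whose fragments lie within `genome`.
#' @param genome A [genome_info()].
#' @return A `CoverageTrack`: list with `values` (named list of per-bp
#'   numeric vectors, one per chromosome of the genome), `scale`
#'   (`"raw_counts"`), `n_total_mapped`, `genome`.
#' @export
compute_coverage <- function(fragset, genome) {
  stopifnot(inherits(fragset, "FragmentSet"), inherits(genome, "GenomeInfo"))
  fr <- fragset$fragments
  miss <- setdiff(unique(fr$chrom), names(genome$chrom_lengths))
  if (length(miss)) stop("fragment chromosome not in genome: ", miss[1L])
  out <- which(fr$end > genome$chrom_lengths[fr$chrom] | fr$start < 0)
  if (length(out))
    stop("fragment outside genome bounds: ", fr$chrom[out[1L]], ":",
         fr$start[out[1L]], "-", fr$end[out[1L]])
  values <- lapply(names(genome$chrom_lengths), function(ch) {
    len <- genome$chrom_lengths[[ch]]
    sel <- fr$chrom == ch
    if (!any(sel)) return(numeric(len))
    cov <- IRanges::coverage(
      IRanges::IRanges(start = fr$start[sel] + 1L, end = fr$end[sel]),
      width = len)
    as.numeric(cov)
  })
  names(values) <- names(genome$chrom_lengths)
  structure(list(values = values, scale = "raw_counts",
                 n_total_mapped = fragset$n_total_mapped,
                 genome = genome),
            class = "CoverageTrack")
}

#' Normalize a raw coverage track
#'
#' Applies the standard depth/genome-size normalization: the fraction of
#' mapped fragments spanning each base-pair position, multiplied by the
#' genome size. A track with average value v therefore reads directly as
#' "v-fold over the genome-wide expectation of one", and the genome-wide
#' mean of the normalized track equals the mean fragment length of the set.
#'
#' @param track Raw-count `CoverageTrack` from [compute_coverage()].
#' @param n_total_mapped Denominator; defaults to the count recorded at
#'   ingestion (before any size-class filtering).
#' @param genome_size Multiplier; defaults to the track's genome size.
#' @return Normalized `CoverageTrack` with the denominators recorded.
#' @export
normalize_coverage <- function(track,
                               n_total_mapped = track$n_total_mapped,
                               genome_size = track$genome$genome_size) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (track$scale != "raw_counts")
    stop("track is already normalized")
  if (is.null(n_total_mapped) || is.na(n_total_mapped) || n_total_mapped <= 0)
    stop("n_total_mapped must be a positive count")
  if (genome_size <= 0) stop("genome_size must be positive")
  track$values <- lapply(track$values,
                         function(v) v / n_total_mapped * genome_size)
  track$scale <- "normalized"
  track$n_total_mapped <- n_total_mapped
  track$genome_size <- genome_size
  track
}

#' Ratio of a ChIP track over an input track
#'
#' Element-wise division of two normalized tracks over the same genome, with
#' a pseudocount added to the input at zero positions to keep the ratio
#' finite.
#'
#' @param chip,input Normalized `CoverageTrack`s on the same genome.
#' @param pseudocount Value substituted where the input is zero (default 0.1).
#' @return A `CoverageTrack` of ratios (`scale` = `"normalized"`).
#' @export
input_normalize <- function(chip, input, pseudocount = 0.1) {
  stopifnot(inherits(chip, "CoverageTrack"), inherits(input, "CoverageTrack"))
  if (!identical(names(chip$values), names(input$values)))
    stop("chip and input tracks are defined over different chromosomes")
  chip$values <- Map(function(a, b) a / pmax(b, pseudocount),
                     chip$values, input$values)
  chip
}

#' Call peaks by simple thresholding
#'
#' Maximal runs of base pairs at or above `threshold`; runs separated by at
#' most `max_gap` bp of sub-threshold signal are merged, and merged runs
#' shorter than `min_width` bp are discarded. Low noise makes this simple
#' rule sufficient for MNase footprint data; no statistical model is fit.
#'
#' @param track A `CoverageTrack` (raw or normalized).
#' @param threshold Minimum value for a position to be inside a peak
#'   (required; in the units of the track).
#' @param min_width Minimum merged-peak width in bp (default 10).
#' @param max_gap Maximum sub-threshold gap to bridge, in bp (default 0).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `max_value`, `mean_value`, sorted by coordinate.
#' @export
threshold_peaks <- function(track, threshold, min_width = 10L, max_gap = 0L) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (threshold <= 0) stop("threshold must be positive")
  res <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    r <- rle(v >= threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- cbind(starts[r$values], ends[r$values])  # 1-based inclusive
    if (!nrow(runs)) return(NULL)
    ## merge runs separated by <= max_gap below-threshold bp
    merged <- runs[1L, , drop = FALSE]
    if (nrow(runs) > 1L) for (i in 2L:nrow(runs)) {
      gap <- runs[i, 1L] - merged[nrow(merged), 2L] - 1L
      if (gap <= max_gap) merged[nrow(merged), 2L] <- runs[i, 2L]
      else merged <- rbind(merged, runs[i, , drop = FALSE])
    }
    w <- merged[, 2L] - merged[, 1L] + 1L
    merged <- merged[w >= min_width, , drop = FALSE]
    if (!nrow(merged)) return(NULL)
    data.frame(
      chrom = ch,
      start = merged[, 1L] - 1L,
      end = merged[, 2L],
      max_value = vapply(seq_len(nrow(merged)),
                         function(i) max(v[merged[i, 1L]:merged[i, 2L]]),
                         numeric(1)),
      mean_value = vapply(seq_len(nrow(merged)),
                          function(i) mean(v[merged[i, 1L]:merged[i, 2L]]),
                          numeric(1)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), max_value = numeric(),
                      mean_value = numeric(), stringsAsFactors = FALSE)
  res[chrom_order(res$chrom, res$start, res$end), , drop = FALSE]
}

#' Write peaks as BED6
#'
#' Score is `max_value` rescaled linearly so the genome-wide maximum maps
#' to 1000 (BED convention), rounded to integer.
#'
#' @param peaks data.frame from [threshold_peaks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  score <- if (nrow(peaks)) round(peaks$max_value / max(peaks$max_value) * 1000)
           else integer()
  utils::write.table(
    data.frame(peaks$chrom, peaks$start, peaks$end,
               sprintf("peak_%d", seq_len(nrow(peaks))), score,
               rep(".", nrow(peaks))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a coverage track as bedGraph
#'
#' Run-length encoded: adjacent equal values are merged into one 0-based
#' half-open interval and zero-valued runs are omitted, so reading the file
#' back over the same genome reproduces the track exactly.
#'
#' @param track A `CoverageTrack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_track()]
#' @export
write_track <- function(track, path) {
  stopifnot(inherits(track, "CoverageTrack"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep], ends[keep],
                     format(r$values[keep], digits = 17, trim = TRUE,
                            scientific = FALSE)),
               con)
  }
  invisible(path)
}

#' Read a bedGraph file into a CoverageTrack
#'
#' @param path bedGraph file (0-based half-open intervals).
#' @param genome [genome_info()] the track is defined over.
#' @param scale `"raw_counts"` or `"normalized"` tag for the result.
#' @return A `CoverageTrack`.
#' @export
read_track <- function(path, genome, scale = "raw_counts") {
  stopifnot(inherits(genome, "GenomeInfo"))
  values <- lapply(genome$chrom_lengths, function(len) numeric(len))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|#)", lines)]
  if (length(lines)) {
    tab <- utils::read.table(text = lines, header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "value"))
    miss <- setdiff(unique(tab$chrom), names(genome$chrom_lengths))
    if (length(miss)) stop("bedGraph chromosome not in genome: ", miss[1L])
    if (any(tab$end > genome$chrom_lengths[tab$chrom]))
      stop("bedGraph interval beyond chromosome end in ", path)
    for (i in seq_len(nrow(tab)))
      values[[tab$chrom[i]]][(tab$start[i] + 1L):tab$end[i]] <- tab$value[i]
  }
  structure(list(values = values, scale = scale,
                 n_total_mapped = NA_real_, genome = genome),
            class = "CoverageTrack")
}

#' @export
print.CoverageTrack <- function(x, ...) {
  cat("CoverageTrack (", x$scale, ") over ",
      length(x$values), " chromosome(s); max ",
      format(max(vapply(x$values, max, numeric(1)))), "\n", sep = "")
  invisible(x)
}
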