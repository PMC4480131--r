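#' Half-height width of a single site's peak
#'
#' Resolution statistic for one motif-centered signal window: the maximum
#' signal within `+/-flank` of the motif defines the peak; the background is
#' the lower median of the signal over the two outermost `bg_margin`-bp
#' windows (offsets `-flank..-(flank - bg_margin)` and
#' `(flank - bg_margin)..+flank`, inclusive); the width is the number of
#' contiguous base pairs, in the run containing the maximum, whose signal is
#' at least the half-height.
#'
#' The half-height can be read two ways. The ratio of maximum to background
#' rescales the signal by a positive constant, which does not change which
#' offsets satisfy "at least half of the maximum"; the default
#' `threshold_mode = "half_max"` therefore thresholds at `max / 2` on the
#' given signal and keeps the background for QC (`qc_flag =
#' "zero_background"` if it is not positive — the width is still computed,
#' since under this reading the threshold does not involve the background).
#' `"midrise"` instead thresholds at `background + (max - background) / 2`.
#'
#' @param signal Numeric vector of length `2*flank + 1`, the signal at
#'   offsets `-flank..+flank` around one site.
#' @param flank Half-window in bp (default 1000).
#' @param bg_margin Width of each outer background window in bp
#'   (default 100).
#' @param threshold_mode `"half_max"` (default) or `"midrise"`.
#' @return List of class `HalfHeightResult`: `max_value`, `max_offset`
#'   (leftmost argmax, in bp), `background`, `threshold`, `width` (bp),
#'   `qc_flag` (`"ok"`, `"flat"` or `"zero_background"`).
#' @export
half_height_width <- function(signal, flank = 1000L, bg_margin = 100L,
                              threshold_mode = c("half_max", "midrise")) {
  threshold_mode <- match.arg(threshold_mode)
  n <- 2L * flank + 1L
  if (length(signal) != n)
    stop("signal must span exactly 2*flank+1 = ", n, " offsets, got ",
         length(signal))
  if (bg_margin >= flank) stop("bg_margin must be smaller than flank")
  offsets <- -flank:flank
  bg_idx <- c(seq_len(bg_margin + 1L), (n - bg_margin):n)
  background <- unname(lower_median(signal[bg_idx]))
  signal <- unname(signal)
  max_value <- max(signal)
  max_i <- which.max(signal)  # leftmost argmax
  flat <- length(unique(signal)) == 1L
  threshold <- switch(threshold_mode,
                      half_max = max_value / 2,
                      midrise = background + (max_value - background) / 2)
  above <- signal >= threshold
  ## contiguous run of above-threshold offsets containing the maximum
  lo <- max_i
  while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
  hi <- max_i
  while (hi < n && above[hi + 1L]) hi <- hi + 1L
  width <- hi - lo + 1L
  qc <- if (flat) "flat" else if (background <= 0) "zero_background" else "ok"
  structure(list(max_value = max_value, max_offset = offsets[max_i],
                 background = background, threshold = threshold,
                 width = width, qc_flag = qc),
            class = "HalfHeightResult")
}

#' Half-height widths for every row of a profile matrix
#'
#' Batch form of [half_height_width()], the surface behind per-size-class
#' resolution box plots.
#'
#' @param matrix A [site_matrix()] built with the same `flank`.
#' @param flank Half-window in bp (default 1000).
#' @param bg_margin Background window width in bp (default 100).
#' @param threshold_mode Passed to [half_height_width()].
#' @return List with `per_site` (data.frame: `site_id`, `max_value`,
#'   `max_offset`, `background`, `width`, `qc_flag`) and `summary`
#'   (quartiles of `width` over sites with `qc_flag != "flat"`).
#' @export
half_height_widths <- function(matrix, flank = 1000L, bg_margin = 100L,
                               threshold_mode = c("half_max", "midrise")) {
  threshold_mode <- match.arg(threshold_mode)
  rows <- lapply(seq_len(nrow(matrix)), function(i)
    half_height_width(matrix[i, ], flank = flank, bg_margin = bg_margin,
                      threshold_mode = threshold_mode))
  per_site <- data.frame(
    site_id = rownames(matrix) %||% sprintf("site_%d", seq_len(nrow(matrix))),
    max_value = vapply(rows, `[[`, numeric(1), "max_value"),
    max_offset = vapply(rows, `[[`, numeric(1), "max_offset"),
    background = vapply(rows, `[[`, numeric(1), "background"),
    width = vapply(rows, `[[`, numeric(1), "width"),
    qc_flag = vapply(rows, `[[`, character(1), "qc_flag"),
    stringsAsFactors = FALSE)
  usable <- per_site$width[per_site$qc_flag != "flat"]
  summary <- if (length(usable))
    stats::quantile(usable, c(0.25, 0.5, 0.75), names = FALSE)
  else rep(NA_real_, 3L)
  names(summary) <- c("q25", "median", "q75")
  list(per_site = per_site, summary = summary)
}

## first offsets of local-maximum plateaus of x
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k == 1L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_max <- vapply(seq_len(k), function(i) {
    left_ok <- i == 1L || r$values[i] > r$values[i - 1L]
    right_ok <- i == k || r$values[i] > r$values[i + 1L]
    left_ok && right_ok
  }, logical(1))
  starts[is_max]
}

#' Separation of the fragment-end peak pair flanking a motif
#'
#' Locates the left-end and right-end peaks of a motif-centered
#' [end_profile()] and reports their distance, the direct analogue of the
#' peak pairs that exonuclease-based methods call with dedicated software.
#' A fragment population chewed back exactly to a 19-bp footprint gives
#' peaks at offsets -9 and +10 and a separation of 19 bp.
#'
#' @param profile An [end_profile()].
#' @param source `"split"` (default): left peak = argmax of the left-end
#'   counts, right peak = argmax of the right-end counts (leftmost position
#'   on ties). `"combined"`: the two highest local maxima of the combined
#'   counts at least `min_peak_distance` bp apart.
#' @param prominence_frac A local maximum counts as predominant when its
#'   height is at least this fraction of the global maximum (default 0.5).
#' @param min_peak_distance Minimum distance in bp between reported combined
#'   peaks (default 5).
#' @return List of class `PeakPairResult`: `left_peak_offset`,
#'   `right_peak_offset`, `separation` (right minus left; `NA` with
#'   `separation_defined = FALSE` unless the peaks straddle offset 0),
#'   `n_predominant_peaks`.
#' @export
peak_pair_separation <- function(profile, source = c("split", "combined"),
                                 prominence_frac = 0.5,
                                 min_peak_distance = 5L) {
  source <- match.arg(source)
  stopifnot(inherits(profile, "EndProfile"))
  if (all(profile$combined == 0)) stop("end profile is all zero")
  offs <- profile$offsets
  if (source == "split") {
    left <- offs[which.max(profile$left_counts)]
    right <- offs[which.max(profile$right_counts)]
    x <- profile$combined
    cand_i <- local_maxima(x)
    npred <- count_predominant(x, cand_i, prominence_frac, min_peak_distance)
  } else {
    x <- profile$combined
    cand_i <- local_maxima(x)
    if (length(cand_i) == 0L) cand_i <- which.max(x)
    kept <- suppress_close_peaks(x, cand_i, min_peak_distance)
    npred <- sum(x[kept] >= prominence_frac * max(x))
    if (length(kept) < 2L) {
      return(structure(list(left_peak_offset = offs[kept[1L]],
                            right_peak_offset = NA_real_,
                            separation = NA_real_,
                            separation_defined = FALSE,
                            n_predominant_peaks = npred),
                       class = "PeakPairResult"))
    }
    top2 <- kept[order(-x[kept], offs[kept])][1:2]
    left <- min(offs[top2])
    right <- max(offs[top2])
  }
  defined <- is.finite(left) && is.finite(right) && left < 0 && right > 0
  structure(list(left_peak_offset = left, right_peak_offset = right,
                 separation = if (defined) right - left else NA_real_,
                 separation_defined = defined,
                 n_predominant_peaks = npred),
            class = "PeakPairResult")
}

## greedy height-ordered suppression of peaks closer than min_dist
suppress_close_peaks <- function(x, cand_i, min_dist) {
  ord <- cand_i[order(-x[cand_i], cand_i)]
  kept <- integer(0)
  for (i in ord)
    if (!length(kept) || all(abs(i - kept) >= min_dist))
      kept <- c(kept, i)
  sort(kept)
}

count_predominant <- function(x, cand_i, prominence_frac, min_dist) {
  if (!length(cand_i)) return(1L)
  kept <- suppress_close_peaks(x, cand_i, min_dist)
  sum(x[kept] >= prominence_frac * max(x))
}

#' @export
print.PeakPairResult <- function(x, ...) {
  cat("PeakPairResult: left", x$left_peak_offset, "right",
      x$right_peak_offset, "separation",
      if (x$separation_defined) paste0(x$separation, " bp") else "undefined",
      "(", x$n_predominant_peaks, "predominant peak(s))\n")
  invisible(x)
}

#' Keep only well-separated motif sites
#'
#' Retains exactly the sites whose nearest neighbor on the same chromosome
#' — center-to-center, evaluated against the original input set — is at
#' least `min_sep` bp away. Crowded sites are removed symmetrically: if two
#' sites are too close, both go.
#'
#' @param sites A [motif_sites()] table.
#' @param min_sep Minimum center-to-center separation in bp (default 500).
#' @return The retained subset, same class and column layout.
#' @export
motif_spacing_filter <- function(sites, min_sep = 500L) {
  if (nrow(sites) < 2L) return(sites)
  keep <- rep(TRUE, nrow(sites))
  for (ch in unique(sites$chrom)) {
    idx <- which(sites$chrom == ch)
    if (length(idx) < 2L) next
    cent <- sites$center[idx]
    o <- order(cent)
    gaps <- diff(cent[o])
    nn <- pmin(c(Inf, gaps), c(gaps, Inf))  # nearest-neighbor distance
    keep[idx[o]] <- nn >= min_sep
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write per-site half-height results as TSV
#' @param widths Result of [half_height_widths()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_width_table <- function(widths, path) {
  utils::write.table(widths$per_site, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
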