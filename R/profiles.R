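#' Per-site signal matrix around motif centers
#'
#' Extracts track values at offsets `-flank..+flank` around each site's
#' center. Rows of minus-strand sites are reversed so that every row reads
#' in motif orientation. Sites whose window would cross a chromosome
#' boundary are dropped (padding would fabricate signal); the number dropped
#' is recorded in the `"n_dropped"` attribute.
#'
#' @param track A `CoverageTrack`.
#' @param sites A [motif_sites()] table.
#' @param flank Half-window in bp (>= 1).
#' @return Numeric matrix (class `ProfileMatrix`) with one row per retained
#'   site (rownames = site names) and `2*flank + 1` columns named by offset.
#' @export
site_matrix <- function(track, sites, flank) {
  stopifnot(inherits(track, "CoverageTrack"))
  if (nrow(sites) == 0L) stop("empty site list")
  if (flank < 1) stop("flank must be >= 1")
  offsets <- -flank:flank
  clen <- track$genome$chrom_lengths
  miss <- setdiff(unique(sites$chrom), names(clen))
  if (length(miss)) stop("site chromosome not in track genome: ", miss[1L])
  ok <- sites$center - flank >= 0 & sites$center + flank <= clen[sites$chrom] - 1
  kept <- sites[ok, , drop = FALSE]
  if (nrow(kept) == 0L) stop("all site windows cross chromosome boundaries")
  m <- t(vapply(seq_len(nrow(kept)), function(i) {
    v <- track$values[[kept$chrom[i]]][(kept$center[i] - flank + 1):
                                         (kept$center[i] + flank + 1)]
    if (kept$strand[i] == "-") rev(v) else v
  }, numeric(length(offsets))))
  dimnames(m) <- list(kept$name, offsets)
  structure(m, class = c("ProfileMatrix", class(m)),
            n_dropped = sum(!ok))
}

#' Column means of a profile matrix
#'
#' @param matrix A [site_matrix()] (or any sites x offsets matrix) with at
#'   least one row.
#' @return Named numeric vector of per-offset means (names = offsets).
#' @export
average_profile <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L)
    stop("profile matrix has no rows")
  colMeans(matrix)
}

#' Fragment-end counts in motif-relative coordinates
#'
#' For each (site, fragment) incidence, the fragment's left end contributes
#' at offset `start - center` and its right end at offset `end - center`,
#' when within `+/-flank`. The right end is the half-open end coordinate —
#' the first unprotected bp — so a fragment exactly spanning a 19-bp motif
#' produces end peaks at offsets -9 and +10, separated by 19 bp. For
#' minus-strand sites offsets are negated and the left/right roles swap, so
#' all sites read in motif orientation.
#'
#' Mode `"single_end_bias"` reproduces the sonication-bias read-out from
#' single-end data: left ends are the 5' positions (`start`) of
#' forward-strand reads only, and right ends the 3' positions (`end`) of
#' reverse-strand reads only; the fragment table must carry a `strand`
#' column.
#'
#' @param fragset A [fragment_set()].
#' @param sites A [motif_sites()] table.
#' @param flank Half-window in bp.
#' @param mode `"paired_end"` (default) or `"single_end_bias"`.
#' @return An `EndProfile`: list with `offsets`, `left_counts`,
#'   `right_counts`, `combined`, `mode`, `flank`, `n_sites`.
#' @export
end_profile <- function(fragset, sites,
                        flank, mode = c("paired_end", "single_end_bias")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fragset, "FragmentSet"))
  if (nrow(sites) == 0L) stop("empty site list")
  fr <- fragset$fragments
  if (mode == "single_end_bias") {
    if (is.null(fr$strand))
      stop("single_end_bias mode needs a strand column on the fragments")
    left_src <- fr$start[fr$strand == "+"]
    right_src <- fr$end[fr$strand == "-"]
    left_chrom <- fr$chrom[fr$strand == "+"]
    right_chrom <- fr$chrom[fr$strand == "-"]
  } else {
    left_src <- fr$start
    right_src <- fr$end
    left_chrom <- right_chrom <- fr$chrom
  }
  n <- 2L * flank + 1L
  left_counts <- right_counts <- numeric(n)
  for (ch in unique(sites$chrom)) {
    ls <- sort(left_src[left_chrom == ch])
    rs <- sort(right_src[right_chrom == ch])
    sch <- sites[sites$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(sch))) {
      c0 <- sch$center[i]
      cl <- tabulate_window(ls, c0 - flank, c0 + flank)
      cr <- tabulate_window(rs, c0 - flank, c0 + flank)
      if (sch$strand[i] == "+") {
        left_counts <- left_counts + cl
        right_counts <- right_counts + cr
      } else {
        ## a right end at genomic position p maps to motif offset center - p
        ## and plays the "left" role in motif orientation (and vice versa)
        left_counts <- left_counts + rev(cr)
        right_counts <- right_counts + rev(cl)
      }
    }
  }
  structure(list(offsets = -flank:flank,
                 left_counts = left_counts,
                 right_counts = right_counts,
                 combined = left_counts + right_counts,
                 mode = mode, flank = flank, n_sites = nrow(sites)),
            class = "EndProfile")
}

#' @export
print.EndProfile <- function(x, ...) {
  cat("EndProfile (", x$mode, "): flank ", x$flank, " bp, ",
      sum(x$left_counts), " left / ", sum(x$right_counts),
      " right end(s) over ", x$n_sites, " site(s)\n", sep = "")
  invisible(x)
}

#' Fragment midpoint-versus-length map (V-plot)
#'
#' Each (site, fragment) incidence with fragment length in
#' `[len_min, len_max]` and strand-flipped midpoint offset within
#' `+/-flank` adds one count at (length, offset). The apex of the resulting
#' "V" — the minimum occupied length at offset 0 — marks the minimal
#' protected footprint.
#'
#' @param fragset A [fragment_set()].
#' @param sites A [motif_sites()] table.
#' @param flank Half-window in bp.
#' @param len_min,len_max Inclusive fragment-length range of the rows.
#' @param normalization `"none"` (counts, default); `"per_pixel"` divides
#'   every value by the number of matrix pixels; `"per_fragment"` divides by
#'   the number of counted incidences.
#' @return A `VPlotMatrix`: list with `matrix` (lengths x offsets), `lengths`,
#'   `offsets`, `normalization`, `n_incidences`.
#' @export
vplot <- function(fragset, sites, flank, len_min, len_max,
                  normalization = c("none", "per_pixel", "per_fragment")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(fragset, "FragmentSet"))
  if (len_min > len_max) stop("need len_min <= len_max")
  if (flank < 1) stop("flank must be >= 1")
  fr <- fragset$fragments
  lengths <- len_min:len_max
  offsets <- -flank:flank
  nr <- length(lengths); nc <- length(offsets)
  idx_all <- vector("list", nrow(sites))
  for (ch in unique(sites$chrom)) {
    sel <- fr$chrom == ch
    mid <- fragment_midpoint(fr$start[sel], fr$end[sel])
    o <- order(mid)
    mid <- mid[o]
    flen <- fr$length[sel][o]
    which_sites <- which(sites$chrom == ch)
    for (i in which_sites) {
      c0 <- sites$center[i]
      lo <- findInterval(c0 - flank - 0.5, mid) + 1L
      hi <- findInterval(c0 + flank + 0.5, mid)
      if (hi < lo) next
      off <- mid[lo:hi] - c0
      if (sites$strand[i] == "-") off <- -off
      ln <- flen[lo:hi]
      keep <- ln >= len_min & ln <= len_max
      if (!any(keep)) next
      idx_all[[i]] <- (ln[keep] - len_min + 1) + nr * (off[keep] + flank)
    }
  }
  idx <- unlist(idx_all) %||% integer(0)
  counts <- tabulate(idx, nbins = nr * nc)
  m <- matrix(as.numeric(counts), nrow = nr, ncol = nc,
              dimnames = list(lengths, offsets))
  n_inc <- sum(counts)
  m <- switch(normalization,
              none = m,
              per_pixel = m / (nr * nc),
              per_fragment = if (n_inc > 0) m / n_inc else m)
  structure(list(matrix = m, lengths = lengths, offsets = offsets,
                 normalization = normalization, n_incidences = n_inc),
            class = "VPlotMatrix")
}

#' Apex of a V-plot
#'
#' The minimum occupied fragment length at motif offset 0 — an estimator of
#' the minimal protected footprint length.
#'
#' @param v A [vplot()] result.
#' @return Length in bp, or `NA` if the offset-0 column is empty.
#' @export
vplot_apex <- function(v) {
  stopifnot(inherits(v, "VPlotMatrix"))
  col <- v$matrix[, as.character(0)]
  occ <- which(col > 0)
  if (!length(occ)) return(NA_real_)
  v$lengths[occ[1L]]
}

#' @export
print.VPlotMatrix <- function(x, ...) {
  cat("VPlotMatrix: lengths ", min(x$lengths), "-", max(x$lengths),
      " bp x offsets +/-", max(x$offsets), "; ", x$n_incidences,
      " incidence(s), normalization ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Plot method for V-plots
#' @param x A [vplot()] result.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.VPlotMatrix <- function(x, ...) {
  graphics::image(x$offsets, x$lengths, t(x$matrix),
                  xlab = "midpoint offset (bp)", ylab = "fragment length (bp)",
                  ...)
  invisible(x)
}

#' Plot method for end profiles
#' @param x An [end_profile()] result.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.EndProfile <- function(x, ...) {
  graphics::plot(x$offsets, x$left_counts, type = "l", col = "blue",
                 xlab = "offset (bp)", ylab = "end count",
                 ylim = range(c(x$left_counts, x$right_counts)), ...)
  graphics::lines(x$offsets, x$right_counts, col = "red")
  graphics::legend("topright", c("left ends", "right ends"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Write a sites-by-offsets matrix as TSV with an offset header
#' @param matrix A [site_matrix()] result (or any matrix with offset
#'   colnames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  df <- data.frame(site_id = rownames(matrix) %||%
                     sprintf("site_%d", seq_len(nrow(matrix))),
                   matrix, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an end profile as TSV (offset, left, right, combined)
#' @param profile An [end_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_end_profile <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offsets, left = profile$left_counts,
               right = profile$right_counts, combined = profile$combined),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a V-plot matrix as TSV (rows = lengths, columns = offsets)
#' @param v A [vplot()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vplot <- function(v, path) {
  df <- data.frame(length = v$lengths, v$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
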