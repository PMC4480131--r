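#' Read paired-end fragments from BEDPE, fragment BED or BAM
#'
#' Each proper mate pair becomes one fragment spanning the outer extent of the
#' two mates (the sequenced insert, i.e. the protected footprint). Discordant
#' pairs — mates on different chromosomes, unmapped mates, or mapping quality
#' below `mapq_min` — are discarded and counted in the provenance log.
#' 3-column BED rows are taken verbatim as fragments.
#'
#' @param path Input file. BEDPE (6 or 10 columns), BED3, or a
#'   coordinate-sorted BAM (requires the Rsamtools package).
#' @param format One of `"auto"`, `"bedpe"`, `"bed"`, `"bam"`. `"auto"`
#'   dispatches on the `.bam` extension, then on column count (>= 6 numeric
#'   mate columns = BEDPE, 3 columns = BED).
#' @param mapq_min Minimum mapping quality for BAM records (applied to the
#'   leftmost mate of each pair); BED/BEDPE carry no mapping quality and are
#'   not filtered.
#' @param genome Optional [genome_info()] used to validate coordinates.
#' @return A [fragment_set()]; `n_total_mapped` equals the retained count.
#' @export
read_fragments <- function(path, format = c("auto", "bedpe", "bed", "bam"),
                           mapq_min = 20L, genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    if (grepl("\\.bam$", path, ignore.case = TRUE)) {
      format <- "bam"
    } else {
      first <- readLines(path, n = 1L)
      if (!length(first)) stop("empty file: ", path)
      nf <- length(strsplit(trimws(first), "[ \t]+")[[1L]])
      format <- if (nf >= 6L) "bedpe" else "bed"
    }
  }
  res <- switch(format,
    bedpe = read_bedpe_fragments(path),
    bed = read_bed_fragments(path),
    bam = read_bam_fragments(path, mapq_min)
  )
  if (nrow(res$fragments) == 0L)
    stop("no fragments retained from ", path,
         " (", res$discarded, " record(s) discarded)")
  fragment_set(res$fragments,
               n_total_mapped = nrow(res$fragments),
               provenance = c(
                 paste0("source: ", path, " (", format, ")"),
                 paste0("retained ", nrow(res$fragments), " fragment(s), discarded ",
                        res$discarded, " discordant/filtered record(s)")),
               genome = genome)
}

read_bedpe_fragments <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#", fill = FALSE),
    error = function(e) stop("malformed BEDPE in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 6L) stop("BEDPE needs >= 6 columns, found ", ncol(tab))
  for (j in c(2L, 3L, 5L, 6L)) {
    if (!is.numeric(tab[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[j]]))))[1L]
      stop("non-numeric coordinate in BEDPE column ", j, ", line ",
           if (is.na(bad)) 1L else bad)
    }
  }
  concordant <- tab[[1L]] == tab[[4L]] & tab[[1L]] != "." & tab[[4L]] != "." &
    tab[[2L]] >= 0 & tab[[5L]] >= 0
  frags <- data.frame(
    chrom = tab[[1L]][concordant],
    start = pmin(tab[[2L]][concordant], tab[[5L]][concordant]),
    end = pmax(tab[[3L]][concordant], tab[[6L]][concordant]),
    stringsAsFactors = FALSE)
  list(fragments = frags, discarded = sum(!concordant))
}

read_bed_fragments <- function(path) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#", fill = FALSE),
    error = function(e) stop("malformed BED in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 3L) stop("fragment BED needs >= 3 columns")
  if (!is.numeric(tab[[2L]]) || !is.numeric(tab[[3L]]))
    stop("non-numeric coordinates in ", path)
  bad <- which(tab[[3L]] <= tab[[2L]])
  if (length(bad)) stop("end <= start at line ", bad[1L], " of ", path)
  frags <- data.frame(chrom = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
                      stringsAsFactors = FALSE)
  if (ncol(tab) >= 6L && all(tab[[6L]] %in% c("+", "-")))
    frags$strand <- tab[[6L]]
  list(fragments = frags, discarded = 0L)
}

read_bam_fragments <- function(path, mapq_min) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("reading BAM requires the Rsamtools package")
  ## one record per pair: the leftmost mate carries isize > 0, and the
  ## insert (outer span of both mates) is [pos-1, pos-1+isize) in 0-based
  ## half-open coordinates
  flag <- Rsamtools::scanBamFlag(isPaired = TRUE, isProperPair = TRUE,
                                 isUnmappedQuery = FALSE,
                                 hasUnmappedMate = FALSE,
                                 isSecondaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("rname", "pos", "isize", "mapq", "mrnm"))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  n_pairs_in <- ceiling(length(b$pos) / 2)
  keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize > 0 &
    (is.na(b$mapq) | b$mapq >= mapq_min) &
    (is.na(b$mrnm) | as.character(b$mrnm) == as.character(b$rname))
  frags <- data.frame(chrom = as.character(b$rname)[keep],
                      start = b$pos[keep] - 1,
                      end = b$pos[keep] - 1 + b$isize[keep],
                      stringsAsFactors = FALSE)
  list(fragments = frags, discarded = n_pairs_in - nrow(frags))
}

#' Construct a table of stranded motif/anchor sites
#'
#' The anchor coordinate (`center`) of each site is
#' `start + floor((width - 1) / 2)`: base 10 of a 19-bp motif, and the
#' left-of-center base for even widths. All motif-relative offsets in the
#' package are measured from this coordinate.
#'
#' @param sites data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive); optional `name`, `score`, `strand`.
#' @return data.frame of class `motif_sites` with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `center`.
#' @export
motif_sites <- function(sites) {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(sites) || !all(req %in% names(sites)))
    stop("sites must be a data.frame with columns chrom, start, end")
  bad <- which(sites$end - sites$start < 1)
  if (length(bad))
    stop("zero- or negative-width site at row ", bad[1L])
  sites$chrom <- as.character(sites$chrom)
  out <- data.frame(
    chrom = sites$chrom,
    start = as.numeric(sites$start),
    end = as.numeric(sites$end),
    name = if (!is.null(sites$name)) as.character(sites$name)
           else sprintf("site_%d", seq_len(nrow(sites))),
    score = if (!is.null(sites$score)) as.numeric(sites$score) else 0,
    strand = if (!is.null(sites$strand)) as.character(sites$strand) else "+",
    stringsAsFactors = FALSE)
  if (!all(out$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out$center <- out$start + floor((out$end - out$start - 1) / 2)
  class(out) <- c("motif_sites", "data.frame")
  out
}

#' Read motif/anchor sites from a BED3 or BED6 file
#'
#' @param path BED file; strand (column 6) defaults to "+" with a warning
#'   when absent.
#' @return [motif_sites()] data.frame.
#' @export
read_sites <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                      comment.char = "#", fill = FALSE),
    error = function(e) stop("malformed BED in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 3L) stop("site BED needs >= 3 columns")
  bad <- which(tab[[3L]] <= tab[[2L]])
  if (length(bad))
    stop("end <= start at line ", bad[1L], " of ", path)
  df <- data.frame(chrom = tab[[1L]], start = tab[[2L]], end = tab[[3L]],
                   stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) df$name <- as.character(tab[[4L]])
  if (ncol(tab) >= 5L) df$score <- tab[[5L]]
  if (ncol(tab) >= 6L) {
    df$strand <- tab[[6L]]
  } else {
    warning("no strand column in ", path, "; defaulting all sites to '+'")
  }
  motif_sites(df)
}

#' Write a FragmentSet as 3-column BED
#'
#' @param fragset A [fragment_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragset, path) {
  utils::write.table(
    fragset$fragments[, c("chrom", "start", "end")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write motif sites as BED6
#' @param sites [motif_sites()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(
    sites[, c("chrom", "start", "end", "name", "score", "strand")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
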