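#' Construct a FragmentSet
#'
#' A `FragmentSet` is the atomic container of the pipeline: a coordinate-sorted
#' table of sequenced protein-protected DNA fragments (0-based half-open
#' intervals) together with `n_total_mapped`, the number of fragments retained
#' at ingestion. `n_total_mapped` is deliberately carried through size-class
#' filtering unchanged, because it is the denominator of the coverage
#' normalization: signal is expressed as the fraction of *all* mapped
#' fragments spanning a position, times the genome size.
#'
#' @param fragments `data.frame` with columns `chrom` (character), `start`
#'   (0-based inclusive), `end` (0-based exclusive); an optional `strand`
#'   column ("+" or "-") is kept for single-end bias analysis.
#' @param n_total_mapped Number of fragments retained at ingestion; defaults
#'   to `nrow(fragments)`.
#' @param provenance Character vector logging source and filters applied.
#' @param genome Optional [genome_info()]; if given, fragments are checked
#'   against chromosome bounds.
#' @return Object of class `FragmentSet`: a list with elements `fragments`
#'   (sorted data.frame with a `length` column added), `n_total_mapped`,
#'   `provenance`.
#' @export
fragment_set <- function(fragments, n_total_mapped = nrow(fragments),
                         provenance = character(), genome = NULL) {
  req <- c("chrom", "start", "end")
  if (!is.data.frame(fragments) || !all(req %in% names(fragments)))
    stop("fragments must be a data.frame with columns chrom, start, end")
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.numeric(fragments$start)
  fragments$end <- as.numeric(fragments$end)
  if (nrow(fragments)) {
    bad <- which(fragments$start < 0 | fragments$end <= fragments$start)
    if (length(bad))
      stop("invalid fragment interval at row ", bad[1L], ": ",
           fragments$chrom[bad[1L]], ":", fragments$start[bad[1L]], "-",
           fragments$end[bad[1L]])
  }
  if (!is.null(genome)) {
    miss <- setdiff(unique(fragments$chrom), names(genome$chrom_lengths))
    if (length(miss)) stop("fragment chromosome not in genome: ", miss[1L])
    out <- which(fragments$end > genome$chrom_lengths[fragments$chrom])
    if (length(out))
      stop("fragment outside genome bounds: ", fragments$chrom[out[1L]], ":",
           fragments$start[out[1L]], "-", fragments$end[out[1L]])
  }
  if (n_total_mapped < nrow(fragments))
    stop("n_total_mapped cannot be smaller than the fragment count")
  o <- chrom_order(fragments$chrom, fragments$start, fragments$end)
  fragments <- fragments[o, , drop = FALSE]
  rownames(fragments) <- NULL
  fragments$length <- fragments$end - fragments$start
  structure(
    list(fragments = fragments, n_total_mapped = as.numeric(n_total_mapped),
         provenance = as.character(provenance)),
    class = "FragmentSet"
  )
}

#' Number of fragments currently in a FragmentSet
#' @param fragset A [fragment_set()].
#' @return Integer count.
#' @export
n_fragments <- function(fragset) nrow(fragset$fragments)

#' @export
print.FragmentSet <- function(x, ...) {
  cat("FragmentSet:", nrow(x$fragments), "fragment(s) of", x$n_total_mapped,
      "mapped\n")
  if (nrow(x$fragments)) {
    len <- x$fragments$length
    cat("  length range:", min(len), "-", max(len), "bp (median",
        stats::median(len), ")\n")
  }
  for (p in x$provenance) cat("  |", p, "\n")
  invisible(x)
}
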