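#' Genome description: chromosome names, lengths and total size
#'
#' A `GenomeInfo` holds the chromosome lengths of the reference the fragments
#' were mapped to, plus the total genome size used as the multiplier in
#' coverage normalization.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @return An object of class `GenomeInfo` with elements `chrom_lengths`
#'   (named integer-valued vector) and `genome_size` (their sum).
#' @examples
#' g <- genome_info(c(chr1 = 1e6, chr2 = 5e5))
#' g$genome_size
#' @export
genome_info <- function(chrom_lengths) {
  if (!is.numeric(chrom_lengths) || length(chrom_lengths) < 1L)
    stop("chrom_lengths must be a non-empty numeric vector")
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every chromosome length must be named")
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1L])
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0) ||
      any(chrom_lengths != floor(chrom_lengths)))
    stop("chromosome lengths must be positive integers")
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), nm)
  structure(
    list(chrom_lengths = chrom_lengths, genome_size = sum(chrom_lengths)),
    class = "GenomeInfo"
  )
}

#' Read a two-column chrom.sizes table
#'
#' @param path Path to a whitespace-delimited file with columns
#'   chromosome name and length in bp.
#' @return A [genome_info()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  genome_info(stats::setNames(tab$length, tab$chrom))
}

#' @export
print.GenomeInfo <- function(x, ...) {
  cat("GenomeInfo:", length(x$chrom_lengths), "chromosome(s),",
      format(x$genome_size, big.mark = ","), "bp total\n")
  invisible(x)
}
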