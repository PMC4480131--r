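#' Define a fragment size class
#'
#' Size classes stratify paired-end fragments by insert length, isolating
#' sub-nucleosomal, factor-sized footprints (e.g. 20-50 bp) from nucleosomal
#' (~147 bp) and composite long fragments. Bounds are inclusive on both ends:
#' "20-70 bp" retains lengths 20 and 70.
#'
#' @param min_len,max_len Inclusive length bounds in bp.
#' @param label Optional text label; defaults to `"MIN-MAX"`.
#' @return A `size_class` list with `min_len`, `max_len`, `label`.
#' @export
size_class <- function(min_len, max_len, label = NULL) {
  if (min_len < 1 || max_len < min_len)
    stop("need 1 <= min_len <= max_len")
  structure(list(min_len = min_len, max_len = max_len,
                 label = label %||% paste0(min_len, "-", max_len)),
            class = "size_class")
}

#' Parse a "MIN-MAX" or "MIN:MAX" string into a size class
#' @param x Character like "20-50".
#' @return A [size_class()].
#' @export
parse_size_class <- function(x) {
  parts <- suppressWarnings(as.numeric(strsplit(x, "[-:]")[[1L]]))
  if (length(parts) != 2L || anyNA(parts)) stop("cannot parse size class: ", x)
  size_class(parts[1L], parts[2L], label = x)
}

#' Restrict a FragmentSet to one size class
#'
#' Retains fragments with `min_len <= length <= max_len`. `n_total_mapped`
#' is preserved from the parent set so that normalized coverage of a size
#' class remains comparable across classes (same denominator).
#'
#' @param fragset A [fragment_set()].
#' @param class A [size_class()].
#' @return A filtered `FragmentSet` (possibly empty).
#' @export
filter_by_size <- function(fragset, class) {
  stopifnot(inherits(fragset, "FragmentSet"), inherits(class, "size_class"))
  keep <- fragset$fragments$length >= class$min_len &
    fragset$fragments$length <= class$max_len
  out <- fragset
  out$fragments <- fragset$fragments[keep, , drop = FALSE]
  rownames(out$fragments) <- NULL
  out$provenance <- c(fragset$provenance,
                      paste0("size-class filter ", class$label, ": kept ",
                             sum(keep), "/", length(keep)))
  out
}

#' Integer histogram of fragment lengths
#'
#' @param fragset Non-empty [fragment_set()].
#' @return `length_distribution` object: `counts` (named integer vector,
#'   names are lengths in bp) and `total`.
#' @seealso [fraction_in()], [fraction_below()]
#' @export
length_distribution <- function(fragset) {
  stopifnot(inherits(fragset, "FragmentSet"))
  if (nrow(fragset$fragments) == 0L)
    stop("cannot form a length distribution from an empty FragmentSet")
  tab <- table(fragset$fragments$length)
  structure(list(counts = stats::setNames(as.integer(tab),
                                          names(tab)),
                 total = nrow(fragset$fragments)),
            class = "length_distribution")
}

#' Fraction of fragments with length in an inclusive range
#' @param dist A [length_distribution()].
#' @param min_len,max_len Inclusive bounds in bp.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_in <- function(dist, min_len, max_len) {
  len <- as.numeric(names(dist$counts))
  sum(dist$counts[len >= min_len & len <= max_len]) / dist$total
}

#' Fraction of fragments shorter than a threshold
#' @param dist A [length_distribution()].
#' @param threshold Length threshold in bp.
#' @param strict If `TRUE` (default) count lengths `< threshold`, else
#'   `<= threshold`.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_below <- function(dist, threshold, strict = TRUE) {
  len <- as.numeric(names(dist$counts))
  keep <- if (strict) len < threshold else len <= threshold
  sum(dist$counts[keep]) / dist$total
}

#' @export
print.length_distribution <- function(x, ...) {
  cat("length_distribution:", x$total, "fragment(s),",
      length(x$counts), "distinct length(s)\n")
  invisible(x)
}

#' Write a length distribution as two-column TSV (length, count)
#' @param dist A [length_distribution()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_length_distribution <- function(dist, path) {
  utils::write.table(
    data.frame(length = as.integer(names(dist$counts)),
               count = unname(dist$counts)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Fragment midpoint coordinate
#'
#' `floor((start + end) / 2)` in 0-based coordinates; even-length fragments
#' take the left of the two central positions.
#'
#' @param start,end 0-based half-open fragment coordinates (vectorized).
#' @return Numeric vector of midpoint coordinates.
#' @export
fragment_midpoint <- function(start, end) floor((start + end) / 2)
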