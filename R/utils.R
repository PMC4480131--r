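`%||%` <- function(a, b) if (is.null(a)) b else a

## counts of sorted integer positions falling at each coordinate lo..hi
tabulate_window <- function(sorted_pos, lo, hi) {
  n <- as.integer(hi - lo + 1L)
  if (length(sorted_pos) == 0L) return(integer(n))
  idx <- findInterval(c(lo - 1L, hi), sorted_pos)
  if (idx[2L] <= idx[1L]) return(integer(n))
  tabulate(sorted_pos[(idx[1L] + 1L):idx[2L]] - lo + 1L, nbins = n)
}

## run code with a temporary RNG state; caller's stream is untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## locale-independent (C collation) ordering used everywhere coordinates are sorted
chrom_order <- function(chrom, start, end) {
  order(chrom, start, end, method = "radix")
}

## lower median: for an even count, the smaller of the two central values
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}
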