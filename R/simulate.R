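#' Parameters of the synthetic fragment generators
#'
#' The generators emulate the statistical structure of MNase-footprint ChIP
#' fragment data: factor footprints with stochastic exonuclease chew-back
#' overhangs, nucleosome-sized and long composite background fragments,
#' accessibility-biased sonication breaks, and length-dependent bead size
#' selection. Every generator is fully reproducible for a fixed `seed`.
#'
#' @param footprint_len Protected footprint length in bp (default 19, a
#'   CTCF-sized motif).
#' @param chew_p Geometric success probability of the per-side chew-back
#'   overhang (support 0, 1, 2, ...; mode 0). Default 0.5; `chew_p = 1`
#'   means exact chew-back to the footprint edges.
#' @param fragments_per_site Poisson mean of footprint fragments per site
#'   (default 200).
#' @param nucleosome_len_mean,nucleosome_len_sd Normal length model of
#'   nucleosome-sized background fragments, bp (defaults 147 / 10).
#' @param background_rate Background fragments per kb of genome
#'   (default 0.5).
#' @param background_len_logmean,background_len_logsd Log-normal length
#'   model of long composite background fragments (defaults log(250) / 0.35).
#' @param sonication_len_min,sonication_len_max Uniform sonicated fragment
#'   length bounds in bp (defaults 200 / 500).
#' @param accessibility_bias_weight Mixture weight of anchor-centered break
#'   hotspots relative to the uniform component (default 0 = unbiased).
#' @param selection_midpoint_len Length at which the bead size selection
#'   retains fragments with probability 1/2 (default 170 bp, the unbound
#'   fraction cutoff of a 1.1x bead:DNA ratio).
#' @param selection_steepness Logistic steepness of the retention curve, per
#'   bp (default 0.08); `Inf` gives a hard cutoff retaining lengths strictly
#'   below the midpoint.
#' @param seed Integer seed driving all randomness of the generators.
#' @return A validated list of class `SynthConfig`.
#' @export
synth_config <- function(footprint_len = 19L,
                         chew_p = 0.5,
                         fragments_per_site = 200,
                         nucleosome_len_mean = 147,
                         nucleosome_len_sd = 10,
                         background_rate = 0.5,
                         background_len_logmean = log(250),
                         background_len_logsd = 0.35,
                         sonication_len_min = 200L,
                         sonication_len_max = 500L,
                         accessibility_bias_weight = 0,
                         selection_midpoint_len = 170L,
                         selection_steepness = 0.08,
                         seed = 1L) {
  if (footprint_len < 1) stop("footprint_len must be >= 1")
  if (!(chew_p > 0 && chew_p <= 1)) stop("chew_p must be in (0, 1]")
  if (fragments_per_site < 0) stop("fragments_per_site must be >= 0")
  if (nucleosome_len_mean < 1 || nucleosome_len_sd < 0)
    stop("invalid nucleosome length model")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (sonication_len_min < 1 || sonication_len_max < sonication_len_min)
    stop("need 1 <= sonication_len_min <= sonication_len_max")
  if (accessibility_bias_weight < 0)
    stop("accessibility_bias_weight must be >= 0")
  if (selection_midpoint_len < 1) stop("selection_midpoint_len must be >= 1")
  structure(list(footprint_len = footprint_len, chew_p = chew_p,
                 fragments_per_site = fragments_per_site,
                 nucleosome_len_mean = nucleosome_len_mean,
                 nucleosome_len_sd = nucleosome_len_sd,
                 background_rate = background_rate,
                 background_len_logmean = background_len_logmean,
                 background_len_logsd = background_len_logsd,
                 sonication_len_min = sonication_len_min,
                 sonication_len_max = sonication_len_max,
                 accessibility_bias_weight = accessibility_bias_weight,
                 selection_midpoint_len = selection_midpoint_len,
                 selection_steepness = selection_steepness,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

#' Evenly spaced synthetic motif sites
#'
#' Convenience generator of anchor sites for simulation studies: `n` sites
#' of width `width`, evenly spaced along the concatenated genome with a
#' margin at each chromosome end, strands alternating (or fixed).
#'
#' @param genome A [genome_info()].
#' @param n Number of sites.
#' @param width Site width in bp (default 19).
#' @param strand `"alternate"` (default), `"+"` or `"-"`.
#' @return A [motif_sites()] table.
#' @export
tile_motif_sites <- function(genome, n, width = 19L, strand = "alternate") {
  clen <- genome$chrom_lengths
  ## apportion sites to chromosomes proportional to length
  n_per <- floor(n * clen / sum(clen))
  rem <- n - sum(n_per)
  if (rem > 0) n_per[order(-clen)[seq_len(rem)]] <- n_per[order(-clen)[seq_len(rem)]] + 1
  dfs <- lapply(names(clen), function(ch) {
    k <- n_per[[ch]]
    if (k == 0) return(NULL)
    spacing <- floor(clen[[ch]] / (k + 1))
    start <- spacing * seq_len(k)
    data.frame(chrom = ch, start = start, end = start + width,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  df$name <- sprintf("site_%d", seq_len(nrow(df)))
  df$strand <- switch(strand,
                      alternate = rep_len(c("+", "-"), nrow(df)),
                      rep(strand, nrow(df)))
  motif_sites(df)
}

#' Simulate MNase-footprint ChIP fragments with ground truth
#'
#' Per site, a Poisson number of footprint fragments is drawn; each spans
#' the site exactly, extended outward on each side by an independent
#' geometric(`chew_p`) overhang (support 0, 1, ...; mode 0) modelling
#' incomplete exonuclease chew-back. Background fragments — half
#' nucleosome-sized (normal), half long composites (log-normal), emulating
#' the nucleosomal and crosslinked-composite size classes of real libraries
#' — are placed uniformly at `background_rate` per kb. Fragments that would
#' extend past a chromosome end are discarded (not truncated) and counted
#' in the provenance.
#'
#' @param genome A [genome_info()].
#' @param sites A [motif_sites()] table within the genome.
#' @param config A [synth_config()]; `config$seed` makes the output fully
#'   reproducible.
#' @return List with `fragments` (a [fragment_set()]) and `truth`
#'   (data.frame aligned to the sorted fragments: `chrom`, `start`, `end`,
#'   `origin` in footprint/nucleosome/background, `site_id`,
#'   `overhang_left`, `overhang_right`).
#' @export
simulate_tf_chip <- function(genome, sites, config) {
  stopifnot(inherits(genome, "GenomeInfo"), inherits(config, "SynthConfig"))
  clen <- genome$chrom_lengths
  miss <- setdiff(unique(sites$chrom), names(clen))
  if (length(miss)) stop("site chromosome not in genome: ", miss[1L])
  if (any(sites$end > clen[sites$chrom]))
    stop("site extends beyond its chromosome")
  with_seed(config$seed, {
    n_per_site <- stats::rpois(nrow(sites), config$fragments_per_site)
    sid <- rep(seq_len(nrow(sites)), n_per_site)
    n_fp <- length(sid)
    lov <- stats::rgeom(n_fp, config$chew_p)
    rov <- stats::rgeom(n_fp, config$chew_p)
    fp <- data.frame(chrom = sites$chrom[sid],
                     start = sites$start[sid] - lov,
                     end = sites$end[sid] + rov,
                     origin = "footprint",
                     site_id = sites$name[sid],
                     overhang_left = lov, overhang_right = rov,
                     stringsAsFactors = FALSE)
    ## background: nucleosome-sized + long composite fragments
    n_bg <- stats::rpois(1L, config$background_rate * genome$genome_size / 1000)
    bg <- NULL
    if (n_bg > 0) {
      is_nuc <- stats::runif(n_bg) < 0.5
      len <- numeric(n_bg)
      len[is_nuc] <- pmax(1, round(stats::rnorm(sum(is_nuc),
                                                config$nucleosome_len_mean,
                                                config$nucleosome_len_sd)))
      len[!is_nuc] <- pmax(1, round(stats::rlnorm(sum(!is_nuc),
                                                  config$background_len_logmean,
                                                  config$background_len_logsd)))
      ch <- sample(names(clen), n_bg, replace = TRUE,
                   prob = clen / sum(clen))
      start <- floor(stats::runif(n_bg) * clen[ch])
      bg <- data.frame(chrom = ch, start = start, end = start + len,
                       origin = ifelse(is_nuc, "nucleosome", "background"),
                       site_id = NA_character_,
                       overhang_left = NA_real_, overhang_right = NA_real_,
                       stringsAsFactors = FALSE)
    }
    all <- rbind(fp, bg)
    within <- all$start >= 0 & all$end <= clen[all$chrom]
    n_clipped <- sum(!within)
    all <- all[within, , drop = FALSE]
    o <- chrom_order(all$chrom, all$start, all$end)
    all <- all[o, , drop = FALSE]
    rownames(all) <- NULL
    fragset <- fragment_set(
      all[, c("chrom", "start", "end")],
      provenance = c(
        sprintf("simulate_tf_chip: %d site(s), seed %d", nrow(sites),
                config$seed),
        sprintf("emitted %d footprint + %d background fragment(s), discarded %d clipped",
                sum(all$origin == "footprint"),
                sum(all$origin != "footprint"), n_clipped)),
      genome = genome)
    list(fragments = fragset,
         truth = all[, c("chrom", "start", "end", "origin", "site_id",
                         "overhang_left", "overhang_right")])
  })
}

#' Simulate sonicated ChIP fragments with accessibility-biased breaks
#'
#' Models conventional sonication: fragment lengths are uniform on
#' `[sonication_len_min, sonication_len_max]`, and one end of each fragment
#' is a break position drawn from a mixture of a uniform component (weight
#' 1) and Gaussian hotspots of sd 50 bp at the anchor centers (total weight
#' `accessibility_bias_weight`), emulating the elevated break probability
#' of accessible chromatin. The break is assigned to the left or right end
#' with equal probability.
#'
#' @param genome A [genome_info()].
#' @param anchors A [motif_sites()] table of accessible anchors (e.g. TSS).
#' @param config A [synth_config()].
#' @param n_fragments Number of fragments to emit (default 10000).
#' @return List with `fragments` (a [fragment_set()]) and `truth`
#'   (data.frame: `chrom`, `start`, `end`, `origin` = "sonicated",
#'   `site_id` of the hotspot that produced the break or `NA`).
#' @export
simulate_sonicated_chip <- function(genome, anchors, config,
                                    n_fragments = 10000L) {
  stopifnot(inherits(genome, "GenomeInfo"), inherits(config, "SynthConfig"))
  clen <- genome$chrom_lengths
  w <- config$accessibility_bias_weight
  with_seed(config$seed + 1L, {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), site_id = character(),
                      stringsAsFactors = FALSE)
    while (nrow(out) < n_fragments) {
      n_draw <- 2L * (n_fragments - nrow(out)) + 100L
      from_hotspot <- stats::runif(n_draw) < w / (1 + w) & nrow(anchors) > 0
      site_i <- rep(NA_integer_, n_draw)
      brk <- numeric(n_draw)
      ch <- character(n_draw)
      n_hot <- sum(from_hotspot)
      if (n_hot > 0) {
        site_i[from_hotspot] <- sample.int(nrow(anchors), n_hot, replace = TRUE)
        brk[from_hotspot] <- round(stats::rnorm(
          n_hot, anchors$center[site_i[from_hotspot]], 50))
        ch[from_hotspot] <- anchors$chrom[site_i[from_hotspot]]
      }
      n_uni <- sum(!from_hotspot)
      if (n_uni > 0) {
        ch_u <- sample(names(clen), n_uni, replace = TRUE,
                       prob = clen / sum(clen))
        brk[!from_hotspot] <- floor(stats::runif(n_uni) * clen[ch_u])
        ch[!from_hotspot] <- ch_u
      }
      len <- floor(stats::runif(n_draw, config$sonication_len_min,
                                config$sonication_len_max + 1))
      right_side <- stats::runif(n_draw) < 0.5
      start <- ifelse(right_side, brk - len, brk)
      end <- start + len
      ok <- start >= 0 & end <= clen[ch]
      add <- data.frame(chrom = ch[ok], start = start[ok], end = end[ok],
                        site_id = ifelse(is.na(site_i[ok]), NA_character_,
                                         anchors$name[site_i[ok]]),
                        stringsAsFactors = FALSE)
      out <- rbind(out, add)
    }
    out <- out[seq_len(n_fragments), , drop = FALSE]
    o <- chrom_order(out$chrom, out$start, out$end)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
    fragset <- fragment_set(
      out[, c("chrom", "start", "end")],
      provenance = sprintf(
        "simulate_sonicated_chip: %d fragment(s), bias weight %g, seed %d",
        n_fragments, w, config$seed),
      genome = genome)
    truth <- data.frame(out[, c("chrom", "start", "end")],
                        origin = "sonicated", site_id = out$site_id,
                        stringsAsFactors = FALSE)
    list(fragments = fragset, truth = truth)
  })
}

#' Length-dependent size selection with an enrichment report
#'
#' Emulates bead-based size selection: each fragment is retained
#' independently with logistic probability
#' `1 / (1 + exp(steepness * (length - midpoint)))`, non-increasing in
#' length, equal to 1/2 at the midpoint. `selection_steepness = Inf` is a
#' hard cutoff retaining exactly lengths strictly below the midpoint. The
#' report carries the short-fragment enrichment statistic: the fraction of
#' fragments under 50 bp before and after selection, and their ratio (fold
#' enrichment).
#'
#' @param fragset A [fragment_set()].
#' @param config A [synth_config()] (fields `selection_midpoint_len`,
#'   `selection_steepness`, `seed`).
#' @param report_below Length threshold of the enrichment report in bp
#'   (default 50).
#' @return List with `fragments` (retained `FragmentSet`; `n_total_mapped`
#'   reset to the retained count, as resequencing a selected library
#'   redefines the mapped total) and `report` (list: `n_before`, `n_after`,
#'   `fraction_below_before`, `fraction_below_after`, `fold_enrichment`).
#' @export
apply_size_selection <- function(fragset, config, report_below = 50) {
  stopifnot(inherits(fragset, "FragmentSet"), inherits(config, "SynthConfig"))
  len <- fragset$fragments$length
  p <- retention_probability(len, config)
  keep <- with_seed(config$seed + 2L, stats::runif(length(len)) < p)
  out <- fragset
  out$fragments <- fragset$fragments[keep, , drop = FALSE]
  rownames(out$fragments) <- NULL
  out$n_total_mapped <- sum(keep)
  out$provenance <- c(fragset$provenance,
                      sprintf("size selection (midpoint %g bp): kept %d/%d",
                              config$selection_midpoint_len, sum(keep),
                              length(keep)))
  before <- mean(len < report_below)
  after <- if (any(keep)) mean(len[keep] < report_below) else NA_real_
  list(fragments = out,
       report = list(n_before = length(len), n_after = sum(keep),
                     fraction_below_before = before,
                     fraction_below_after = after,
                     fold_enrichment = after / before))
}

#' Retention probability of the size-selection model
#' @param length Fragment length(s) in bp.
#' @param config A [synth_config()].
#' @return Probability vector, non-increasing in length.
#' @export
retention_probability <- function(length, config) {
  if (is.infinite(config$selection_steepness))
    return(as.numeric(length < config$selection_midpoint_len))
  1 / (1 + exp(config$selection_steepness *
                 (length - config$selection_midpoint_len)))
}

#' Write a simulation truth table as TSV
#' @param truth Truth data.frame from a simulate call.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
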