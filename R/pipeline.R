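#' Validate a pipeline run configuration
#'
#' A run configuration (R list or YAML file) names either input fragment
#' data or a `simulate` block, plus the genome, optional sites, analysis
#' windows and size classes. All problems are collected and reported
#' together.
#'
#' @param config Named list, or path to a YAML file.
#' @return The normalized configuration list (defaults filled in), or an
#'   error aggregating every validation failure.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  errs <- character()
  has_frag <- !is.null(config$fragments)
  has_sim <- !is.null(config$simulate)
  if (has_frag == has_sim)
    errs <- c(errs, "exactly one of 'fragments' and 'simulate' must be present")
  if (is.null(config$genome))
    errs <- c(errs, "'genome' (chrom.sizes path or name: length map) is required")
  if (is.null(config$out_dir))
    errs <- c(errs, "'out_dir' is required")
  if (has_frag && !file.exists(config$fragments %||% ""))
    errs <- c(errs, paste0("fragments file not found: ", config$fragments))
  if (!is.null(config$sites) && is.character(config$sites) &&
      !file.exists(config$sites))
    errs <- c(errs, paste0("sites file not found: ", config$sites))
  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "))
  config$seed <- config$seed %||% 1L
  config$size_classes <- config$size_classes %||% list("20-50", "20-70")
  config$flank_profile <- config$flank_profile %||% 40L
  config$flank_ends <- config$flank_ends %||% 100L
  config$flank_widths <- config$flank_widths %||% 1000L
  config$min_sep <- config$min_sep %||% 500L
  config$vplot <- config$vplot %||% list()
  config$vplot$flank <- config$vplot$flank %||% 100L
  config$vplot$len_min <- config$vplot$len_min %||% 1L
  config$vplot$len_max <- config$vplot$len_max %||% 250L
  config
}

#' Run the full fragment-analysis pipeline
#'
#' Orchestrates simulate (or load) -> size-class coverage -> motif-centered
#' profiles, end profiles and V-plot -> resolution metrics, writing every
#' product into `out_dir` together with a log and a machine-readable
#' summary. Identical config and seed give numerically identical outputs;
#' every file is regenerated from scratch on rerun.
#'
#' @param config Named list or YAML path; see [validate_run_config()].
#'   Keys: `genome` (chrom.sizes path, or a named name: length map),
#'   `fragments` (BED/BEDPE/BAM path) or `simulate` (list with `n_sites`,
#'   `site_width`, optional `n_fragments`/`type = "tf"|"sonicated"` and any
#'   [synth_config()] field), `sites` (BED path; defaults to the simulated
#'   sites), `size_classes`, `flank_profile`, `flank_ends`, `flank_widths`,
#'   `vplot` (`flank`, `len_min`, `len_max`), `threshold` (optional peak
#'   threshold in normalized units), `min_sep`, `out_dir`, `seed`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  logmsg("mnasechip ", as.character(utils::packageVersion("mnasechip")),
         " | seed ", config$seed)

  genome <- if (is.character(config$genome)) read_chrom_sizes(config$genome)
            else genome_info(unlist(config$genome))
  logmsg("genome: ", length(genome$chrom_lengths), " chromosome(s), ",
         genome$genome_size, " bp")

  sites <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sc_args <- sim[intersect(names(sim), names(formals(synth_config)))]
    sc_args$seed <- sc_args$seed %||% config$seed
    scfg <- do.call(synth_config, sc_args)
    sites <- tile_motif_sites(genome, n = sim$n_sites %||% 50L,
                              width = sim$site_width %||% scfg$footprint_len)
    type <- sim$type %||% "tf"
    res <- if (type == "sonicated")
      simulate_sonicated_chip(genome, sites, scfg,
                              n_fragments = sim$n_fragments %||% 10000L)
    else simulate_tf_chip(genome, sites, scfg)
    fragset <- res$fragments
    truth <- res$truth
    write_fragments(fragset, file.path(config$out_dir, "fragments.bed"))
    write_truth(truth, file.path(config$out_dir, "truth.tsv"))
    write_sites(sites, file.path(config$out_dir, "sites.bed"))
    logmsg("simulated ", n_fragments(fragset), " fragment(s) (", type,
           ") at ", nrow(sites), " site(s)")
  } else {
    fragset <- read_fragments(config$fragments, genome = genome,
                              mapq_min = config$mapq_min %||% 20L)
    logmsg("loaded ", n_fragments(fragset), " fragment(s) from ",
           config$fragments)
  }
  if (!is.null(config$sites)) sites <- read_sites(config$sites)
  for (p in fragset$provenance) logmsg("  | ", p)

  ## fragment-length distribution
  dist <- length_distribution(fragset)
  write_length_distribution(dist, file.path(config$out_dir, "lengths.tsv"))

  ## per-size-class normalized coverage
  summary <- list(seed = config$seed,
                  n_fragments = n_fragments(fragset),
                  n_total_mapped = fragset$n_total_mapped,
                  size_classes = list())
  classes <- lapply(config$size_classes, function(x)
    if (inherits(x, "size_class")) x else parse_size_class(as.character(x)))
  tracks <- list()
  for (cl in classes) {
    fs <- filter_by_size(fragset, cl)
    label <- gsub("[^0-9A-Za-z]+", "_", cl$label)
    entry <- list(label = cl$label, n_fragments = n_fragments(fs))
    if (n_fragments(fs) > 0) {
      tr <- normalize_coverage(compute_coverage(fs, genome))
      tracks[[cl$label]] <- tr
      write_track(tr, file.path(config$out_dir,
                                paste0("coverage_", label, ".bedGraph")))
      if (!is.null(config$threshold)) {
        pk <- threshold_peaks(tr, config$threshold,
                              min_width = config$min_width %||% 10L,
                              max_gap = config$max_gap %||% 0L)
        write_peaks(pk, file.path(config$out_dir,
                                  paste0("peaks_", label, ".bed")))
        entry$n_peaks <- nrow(pk)
      }
    }
    logmsg("size class ", cl$label, ": ", n_fragments(fs), " fragment(s)")
    summary$size_classes[[cl$label]] <- entry
  }

  ## motif-centered read-outs
  if (!is.null(sites) && length(tracks)) {
    sites_f <- motif_spacing_filter(sites, min_sep = config$min_sep)
    logmsg("spacing filter (>= ", config$min_sep, " bp): ", nrow(sites_f),
           "/", nrow(sites), " site(s) retained")
    summary$n_sites <- nrow(sites)
    summary$n_sites_spaced <- nrow(sites_f)
    if (nrow(sites_f)) {
      main <- tracks[[1L]]
      pm <- site_matrix(main, sites_f, flank = config$flank_profile)
      write_profile_matrix(pm, file.path(config$out_dir, "profile_matrix.tsv"))
      avg <- average_profile(pm)
      utils::write.table(
        data.frame(offset = as.integer(names(avg)), mean_signal = avg),
        file.path(config$out_dir, "average_profile.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)

      fs_main <- filter_by_size(fragset, classes[[1L]])
      ep <- end_profile(fs_main, sites_f, flank = config$flank_ends)
      write_end_profile(ep, file.path(config$out_dir, "end_profile.tsv"))
      pp <- tryCatch(peak_pair_separation(ep, source = "split"),
                     error = function(e) NULL)
      if (!is.null(pp)) {
        summary$end_peak_separation <-
          if (pp$separation_defined) pp$separation else NA
        logmsg("end-peak separation: ",
               if (pp$separation_defined) paste0(pp$separation, " bp")
               else "undefined")
      }

      vp <- vplot(fragset, sites_f, flank = config$vplot$flank,
                  len_min = config$vplot$len_min,
                  len_max = config$vplot$len_max)
      write_vplot(vp, file.path(config$out_dir, "vplot.tsv"))
      summary$vplot_apex <- vplot_apex(vp)

      wflank <- config$flank_widths
      wide_ok <- sites_f$center - wflank >= 0 &
        sites_f$center + wflank <=
          genome$chrom_lengths[sites_f$chrom] - 1
      if (any(wide_ok)) {
        wm <- site_matrix(main, sites_f[wide_ok, , drop = FALSE],
                          flank = wflank)
        hh <- half_height_widths(wm, flank = wflank,
                                 bg_margin = config$bg_margin %||% 100L)
        write_width_table(hh, file.path(config$out_dir,
                                        "half_height_widths.tsv"))
        summary$half_height_width <- as.list(hh$summary)
        logmsg("half-height width median: ", hh$summary[["median"]], " bp")
      }
    }
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  logmsg("done; outputs in ", config$out_dir)
  invisible(summary)
}
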