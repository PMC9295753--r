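# End-to-end driver: synthetic data -> loop statistics -> report bundle.

#' Build a validated pipeline configuration
#'
#' One flat configuration object for the whole pipeline; every threshold has
#' the documented default and is echoed into the run manifest, so a config
#' plus a seed fully determines the report. `run_config()` with no
#' arguments is the shipped demo configuration (synthetic data at a scale
#' that runs end-to-end in well under five minutes on one CPU).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param synthetic Generate inputs with the synthetic module? When FALSE,
#'   `loops_bedpe` and `tads_bed` must point at input files and only the
#'   loop-architecture stages run.
#' @param loops_bedpe,tads_bed Input paths (non-synthetic mode).
#' @param percentile,convention,min_distance Loop-summary parameters.
#' @param span,n_boot Overlap-curve parameters.
#' @param slack_bp Loop-matching slack (bp).
#' @param threshold_nm ORCA contact threshold (nm).
#' @param fc_cut,p_cut Differential-site thresholds.
#' @param n_short,n_long Synthetic loop counts per class.
#' @param n_cells_wt,n_cells_mt Synthetic ORCA cell counts (the imaging
#'   cohort sizes of the motivating study).
#' @param contact_prob_wt,contact_prob_mt Planted contact probabilities for
#'   the imaged pair in the two genotypes.
#' @param conserved_frac Planted fraction of conserved loops.
#' @param concordant_frac Planted fraction of caller-B loops shared with A.
#' @param depth Contact-matrix expected total read pairs.
#' @param n_sites Candidate differential sites.
#' @param effect_size Planted |log2FC| at affected sites.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, synthetic = TRUE,
                       loops_bedpe = NULL, tads_bed = NULL,
                       percentile = 0.01,
                       convention = c("midpoint", "inner_edge"),
                       min_distance = 1e6, span = 0.6, n_boot = 50,
                       slack_bp = 1e4, threshold_nm = 150,
                       fc_cut = 1, p_cut = 0.05,
                       n_short = 1000, n_long = 1000,
                       n_cells_wt = 2190, n_cells_mt = 520,
                       contact_prob_wt = 0.4, contact_prob_mt = 0.05,
                       conserved_frac = 0.3, concordant_frac = 0.92,
                       depth = 5e6, n_sites = 300, effect_size = 2) {
  convention <- match.arg(convention)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (!cfg$synthetic) {
    for (field in c("loops_bedpe", "tads_bed"))
      if (is.null(cfg[[field]]))
        stop("config field '", field, "' is required when synthetic = FALSE",
             call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; absent keys get the
#' documented defaults (and are still echoed into the run manifest).
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Jitter loop anchors by up to max_jitter bp (shared shift per anchor).
jitter_loops <- function(x, max_jitter) {
  n <- nrow(x)
  j1 <- round(stats::runif(n, -max_jitter, max_jitter))
  j2 <- round(stats::runif(n, -max_jitter, max_jitter))
  loops(x$chrom, pmax(x$start1 + j1, 0), pmax(x$end1 + j1, 1),
        x$start2 + j2, x$end2 + j2, mark = x$mark, score = x$score)
}

#' Run the full pipeline
#'
#' Executes synthetic generation (if configured) and every analysis stage,
#' writing per-stage tables, a machine-readable `summary.json` and a
#' `manifest.txt` (seed, package version, parameters, input checksums) into
#' `out_dir`. Identical config + seed gives a byte-identical summary. Any
#' stage failure aborts with the stage name.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @param out_dir Output directory (created; existing files overwritten).
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(out_dir, ...)
  summary <- list(seed = config$seed)
  data_files <- character(0)

  if (config$synthetic) {
    sim <- run_stage("simulate", {
      genome <- synthetic_genome(seed = config$seed)
      arch <- make_tads_and_compartments(genome, seed = config$seed + 1L)
      gen <- make_loops(loop_spec(n_short = config$n_short,
                                  n_long = config$n_long),
                        genome, seed = config$seed + 2L)
      extra_peaks <- make_peaks(genome, n = 200, width = 5e3,
                                seed = config$seed + 3L, label = "EZH2 peaks")
      ezh2 <- interval_set(c(gen$nucleation$chrom, extra_peaks$chrom),
                           c(gen$nucleation$start, extra_peaks$start),
                           c(gen$nucleation$end, extra_peaks$end),
                           label = "EZH2 peaks")
      track <- make_signal_track(merge_intervals(ezh2), genome,
                                 peak_height = 10, background = 0.5,
                                 seed = config$seed + 4L)
      # Locus-scale contact map: a dedicated 40-Mb region genome at 25 kb
      # with one planted 3.8-Mb loop (a Wnt6-Pax3-scale contact), so cis
      # bin-pair enumeration stays small.
      region <- synthetic_genome(chrom_sizes = c(chrR = 4e7), bin_size = 2.5e4,
                                 seed = config$seed)
      focal <- loops("chrR", 18e6, 18.01e6, 21.8e6, 21.81e6, mark = "H3K27me3")
      cm <- make_contact_matrix(region, focal, depth = config$depth,
                                seed = config$seed + 5L)
      orca_wt <- make_orca_traces(
        config$n_cells_wt, c("Hoxa", "Cntr", "Vax2"),
        data.frame(a = "Hoxa", b = "Vax2", prob = config$contact_prob_wt),
        genotype = "WT", seed = config$seed + 6L)
      orca_mt <- make_orca_traces(
        config$n_cells_mt, c("Hoxa", "Cntr", "Vax2"),
        data.frame(a = "Hoxa", b = "Vax2", prob = config$contact_prob_mt),
        genotype = "MT", seed = config$seed + 7L)
      traces <- orca_traces(rbind(
        as.data.frame(orca_wt$traces),
        transform(as.data.frame(orca_mt$traces),
                  cell_id = cell_id + config$n_cells_wt)),
        barcodes = c("Hoxa", "Cntr", "Vax2"))
      long <- gen$loops[gen$loops$mark == "H3K27me3", , drop = FALSE]
      anchor_del <- long[which.max(anchor_distance(long)), , drop = FALSE]
      deletion <- interval_set(anchor_del$chrom, anchor_del$start1 - 5e4,
                               anchor_del$end1 + 5e4)
      # Candidate differential sites: half are EZH2-occupied (reuse peak
      # intervals), half are EZH2-free random placements, mirroring a
      # histone-signal site universe where occupancy splits the sites.
      n_occ <- min(nrow(extra_peaks), floor(config$n_sites / 2))
      rand_sites <- make_peaks(genome, n = config$n_sites - n_occ,
                               width = 5e3, seed = config$seed + 8L,
                               label = "sites")
      sites <- interval_set(
        c(extra_peaks$chrom[seq_len(n_occ)], rand_sites$chrom),
        c(extra_peaks$start[seq_len(n_occ)], rand_sites$start),
        c(extra_peaks$end[seq_len(n_occ)], rand_sites$end),
        label = "sites")
      diff <- make_differential_table(sites, ezh2, arch$compartments,
                                      deletion,
                                      effect_size = config$effect_size,
                                      seed = config$seed + 9L)
      list(genome = genome, arch = arch, gen = gen, ezh2 = ezh2,
           peaks = extra_peaks, track = track, cm = cm, focal = focal,
           traces = traces, deletion = deletion, diff = diff)
    })
    run_stage("write_inputs", {
      write_bedpe(sim$gen$loops, path("loops.bedpe"))
      write_bed(sim$arch$tads, path("tads.bed"))
      write_bed(sim$arch$compartments, path("compartments.bed"))
      write_bed(sim$gen$nucleation, path("nucleation.bed"))
      write_bed(sim$ezh2, path("ezh2.bed"))
      write_bedgraph(sim$track, path("signal.bedgraph"))
      write_contact_matrix(sim$cm, path("matrix.txt"), path("bins.bed"))
      write_orca_traces(sim$traces, path("orca.tsv"))
      write_differential_table(sim$diff$table, path("differential.tsv"))
      data_files <- c("loops.bedpe", "tads.bed", "compartments.bed",
                       "nucleation.bed", "ezh2.bed", "signal.bedgraph",
                       "matrix.txt", "bins.bed", "orca.tsv",
                       "differential.tsv")
    })
    lps <- sim$gen$loops
    tads <- sim$arch$tads
  } else {
    lps <- run_stage("read_inputs", read_bedpe(config$loops_bedpe))
    tads <- run_stage("read_inputs", read_bed(config$tads_bed, label = "TADs"))
  }

  summary$loops <- run_stage("loop_summary", {
    per_mark <- lapply(split(seq_len(nrow(lps)), lps$mark), function(idx) {
      s <- summarize_loops(lps[idx, , drop = FALSE], tads,
                           percentile = config$percentile,
                           convention = config$convention)
      utils::write.table(s$per_loop,
                         path(paste0("per_loop_", s$per_loop$mark[1], ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s[c("n_loops", "median_distance", "top_percentile_median_distance",
          "median_tads_crossed", "top_percentile_median_tads")]
    })
    out <- list(per_mark = per_mark)
    if (all(c("H3K27me3", "H3K27ac") %in% lps$mark)) {
      d <- anchor_distance(lps, config$convention)
      tc <- tads_crossed(lps, tads)
      me3 <- lps$mark == "H3K27me3"; ac <- lps$mark == "H3K27ac"
      out$p_distance <- compare_distributions(d[me3], d[ac])$p_value
      out$p_tads <- compare_distributions(tc[me3], tc[ac])$p_value
    }
    out
  })

  if (config$synthetic) {
    me3 <- lps[lps$mark == "H3K27me3", , drop = FALSE]

    summary$nucleation <- run_stage("nucleation", {
      cl <- classify_nucleation(me3, sim$gen$nucleation,
                                min_distance = config$min_distance,
                                convention = config$convention)
      cl[c("n_loops", "frac_both", "frac_one", "frac_neither", "frac_any",
           "frac_one_given_any")]
    })

    summary$enrichment <- run_stage("enrichment", {
      centers <- center_choice(anchors(me3), sim$ezh2, "peak_in_anchor")
      prof <- aggregate_profile(centers, sim$track)
      utils::write.table(
        data.frame(offset = prof$offset, value = prof$values),
        path("profile.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
      curve <- overlap_distance_curve(me3, sim$ezh2, span = config$span,
                                      n_boot = config$n_boot,
                                      seed = config$seed + 10L)
      utils::write.table(curve$fitted, path("overlap_curve.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_centers = prof$n_anchors,
           profile_peak = max(prof$values),
           profile_edge = mean(prof$values[c(1, length(prof$values))]),
           anchor_overlap_frac = anchor_peak_overlap_fraction(me3, sim$ezh2))
    })

    summary$virtual4c <- run_stage("virtual_4c", {
      vp <- interval_set(sim$focal$chrom, sim$focal$start1, sim$focal$end1)
      v4c <- virtual_4c(sim$cm, vp, smooth_bins = 1)
      utils::write.table(v4c$profile, path("virtual4c.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      mid2 <- floor((sim$focal$start2 + sim$focal$end2) / 2)
      partner_bin <- sim$cm$bins$bin[sim$cm$bins$chrom == sim$focal$chrom &
                                       sim$cm$bins$start <= mid2 &
                                       mid2 < sim$cm$bins$end]
      prof <- v4c$profile
      k <- match(partner_bin, prof$bin)
      flank <- setdiff(pmax(pmin(k + (-10:10), nrow(prof)), 1), k + (-1:1))
      local_bg <- stats::median(prof$value[flank])
      list(partner_bin = partner_bin,
           partner_value = prof$value[k],
           partner_local_enrichment = if (local_bg > 0)
             prof$value[k] / local_bg else NA_real_,
           partner_is_local_max = prof$value[k] ==
             max(prof$value[pmax(pmin(k + (-10:10), nrow(prof)), 1)]))
    })

    summary$concordance <- run_stage("concordance", {
      set_pinned_seed(config$seed + 11L)
      n <- nrow(lps)
      keep <- stats::runif(n) < config$concordant_frac
      other <- rbind(jitter_loops(lps[keep, , drop = FALSE],
                                  config$slack_bp / 2),
                     make_loops(loop_spec(n_short = sum(!keep), n_long = 0),
                                sim$genome, seed = config$seed + 12L)$loops)
      m <- match_loops(lps, other, slack_bp = config$slack_bp)
      list(frac_a = m$frac_a, frac_b = m$frac_b, n_shared = nrow(m$shared))
    })

    summary$conservation <- run_stage("conservation", {
      set_pinned_seed(config$seed + 13L)
      n <- nrow(me3)
      keep <- stats::runif(n) < config$conserved_frac
      mapped <- rbind(jitter_loops(me3[keep, , drop = FALSE],
                                   config$slack_bp / 2),
                      make_loops(loop_spec(n_short = 0, n_long = sum(!keep)),
                                 sim$genome, seed = config$seed + 14L)$loops)
      list(shared_frac = as.numeric(conserved_loops(me3, mapped,
                                                    config$slack_bp)))
    })

    summary$orca <- run_stage("orca", {
      pd <- pair_distances(sim$traces, "Hoxa", "Vax2")
      wt <- pd$distances[pd$distances$genotype == "WT", , drop = FALSE]
      pd_wt <- structure(list(pair = pd$pair, distances = wt,
                              n_informative = nrow(wt),
                              n_excluded = config$n_cells_wt - nrow(wt),
                              n_cells = config$n_cells_wt),
                         class = "pair_distances")
      cmp <- compare_genotypes(sim$traces, "Hoxa", "Vax2", c("WT", "MT"))
      list(contact_freq_wt = contact_frequency(pd_wt, config$threshold_nm),
           n_informative_wt = pd_wt$n_informative,
           median_wt = cmp$median_1, median_mt = cmp$median_2,
           p_genotype = cmp$p_value)
    })

    summary$differential <- run_stage("differential", {
      cls <- classify_differential_sites(sim$diff$table,
                                         fc_cut = config$fc_cut,
                                         p_cut = config$p_cut)
      ann <- annotate_sites(cls, sim$deletion, sim$ezh2,
                            sim$arch$compartments)
      utils::write.table(as.data.frame(ann), path("sites_classified.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      strat <- stratified_summary(ann)
      truth <- sim$diff$truth$planted_effect
      down <- ann$status == "down"
      list(n_down = sum(down), n_up = sum(ann$status == "up"),
           sensitivity = if (any(truth)) mean(down[truth]) else NA_real_,
           fpr_ezh2 = if (any(ann$ezh2_occupied))
             mean(down[ann$ezh2_occupied]) else NA_real_,
           fisher_p = strat$genomewide$fisher_p)
    })
  }

  run_stage("report", {
    jsonlite::write_json(summary, path("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest <- c(list(seed = config$seed,
                       loopscape_version =
                         as.character(utils::packageVersion("loopscape"))),
                  unclass(config)[!vapply(unclass(config), is.null, TRUE)])
    if (length(data_files)) {
      sums <- tools::md5sum(path(data_files))
      names(sums) <- paste0("md5_", data_files)
      manifest <- c(manifest, as.list(sums))
    }
    write_manifest(manifest, path("manifest.txt"))
  })
  invisible(summary)
}
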