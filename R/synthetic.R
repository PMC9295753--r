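# Seeded generators for every input the pipeline consumes. All generators
# pin the RNG algorithm (Mersenne-Twister / inversion / rejection sampling)
# so a fixed seed gives bit-identical output across platforms, and each
# returns enough ground truth to score downstream recovery.

set_pinned_seed <- function(seed) {
  if (!is.null(seed))
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  invisible(NULL)
}

#' Synthetic genome specification
#'
#' Defines the coordinate system all generators share. The default genome is
#' deliberately small (three chromosomes, 150 Mb total) so contact-matrix
#' enumeration and the full pipeline stay fast; loop distances scale down
#' with it.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths (bp). The
#'   default is a six-chromosome, ~1 Gb genome: large enough that
#'   independently placed anchors rarely collide (so planted anchor flags
#'   are recoverable by overlap), small enough that every analysis runs in
#'   seconds. Locus-scale generators (contact matrices) are usually run on
#'   a dedicated smaller region genome.
#' @param tad_mean_size Mean TAD size in bp (the ~1 Mb scale typical of
#'   mammalian Hi-C).
#' @param bin_size Contact-map resolution in bp.
#' @param seed Default seed for generators run from this spec.
#' @return A list of class `"synthetic_genome"`.
#' @export
synthetic_genome <- function(chrom_sizes = c(chr1 = 2e8, chr2 = 1.9e8,
                                             chr3 = 1.8e8, chr4 = 1.7e8,
                                             chr5 = 1.6e8, chr6 = 1e8),
                             tad_mean_size = 1e6, bin_size = 5e4, seed = 1L) {
  stopifnot(all(chrom_sizes > 0), tad_mean_size > 0, bin_size > 0,
            !is.null(names(chrom_sizes)))
  structure(list(chrom_sizes = chrom_sizes, tad_mean_size = tad_mean_size,
                 bin_size = bin_size, seed = as.integer(seed)),
            class = "synthetic_genome")
}

#' Loop generator specification
#'
#' Two loop classes mimic the contrast between enhancer-associated
#' (H3K27ac) loops, whose anchor distances are roughly log-normal at the
#' sub-megabase scale, and Polycomb (H3K27me3) loops whose distance
#' distribution is asymmetric with a long upper tail. The long class is a
#' log-normal body mixed with a Pareto tail so its top-percentile median
#' clearly exceeds the short class's. Nucleation-point flags are planted
#' per anchor with the given probabilities.
#'
#' @param n_short,n_long Loop counts per class.
#' @param short_log_median,long_log_median Log-normal body medians (bp).
#' @param short_sdlog,long_sdlog Log-normal sdlog parameters.
#' @param long_tail_weight Mixture weight of the Pareto tail in the long class.
#' @param long_tail_exponent Pareto shape of the tail.
#' @param long_tail_xmin Pareto scale (minimum tail distance, bp).
#' @param frac_nucleation_both P(both anchors are nucleation points).
#' @param frac_nucleation_one P(exactly one anchor is).
#' @param anchor_width Anchor width in bp (loop-calling resolution).
#' @return A list of class `"loop_spec"`.
#' @export
loop_spec <- function(n_short = 2000, n_long = 2000,
                      short_log_median = 2e5, long_log_median = 5e5,
                      short_sdlog = 0.6, long_sdlog = 0.8,
                      long_tail_weight = 0.15, long_tail_exponent = 2,
                      long_tail_xmin = 1e6,
                      frac_nucleation_both = 0.25, frac_nucleation_one = 0.37,
                      anchor_width = 1e4) {
  stopifnot(frac_nucleation_both >= 0, frac_nucleation_one >= 0,
            frac_nucleation_both + frac_nucleation_one <= 1,
            long_tail_weight >= 0, long_tail_weight <= 1,
            long_tail_exponent > 0, anchor_width > 0)
  structure(as.list(environment()), class = "loop_spec")
}

rpareto <- function(n, xmin, shape) xmin * stats::runif(n)^(-1 / shape)

#' Generate synthetic loops with ground truth
#'
#' Distances are drawn per class from the distributions in [loop_spec()];
#' anchors are placed uniformly subject to fitting on a chromosome
#' (chromosomes weighted by length). A distance that fits on no chromosome
#' is resampled up to `max_retries` times, then an error is raised. The
#' realized midpoint distance equals the drawn (rounded) distance exactly.
#'
#' @param spec A [loop_spec()].
#' @param genome A [synthetic_genome()].
#' @param seed Integer seed.
#' @param max_retries Resampling bound per loop.
#' @return List with elements `loops` (a `"loops"` frame), `truth`
#'   (per-loop class, distance and nucleation flags) and `nucleation`
#'   (interval set of nucleation-point anchors).
#' @export
make_loops <- function(spec = loop_spec(), genome = synthetic_genome(),
                       seed = genome$seed, max_retries = 100) {
  set_pinned_seed(seed)
  w <- spec$anchor_width
  draw_distance <- function(cls) {
    if (cls == "H3K27ac") {
      stats::rlnorm(1, log(spec$short_log_median), spec$short_sdlog)
    } else if (stats::runif(1) < spec$long_tail_weight) {
      rpareto(1, spec$long_tail_xmin, spec$long_tail_exponent)
    } else {
      stats::rlnorm(1, log(spec$long_log_median), spec$long_sdlog)
    }
  }
  sizes <- genome$chrom_sizes
  n_total <- spec$n_short + spec$n_long
  cls <- rep(c("H3K27ac", "H3K27me3"), c(spec$n_short, spec$n_long))
  chrom <- character(n_total); s1 <- numeric(n_total); s2 <- numeric(n_total)
  dist <- numeric(n_total)
  for (k in seq_len(n_total)) {
    placed <- FALSE
    for (r in seq_len(max_retries)) {
      d <- round(draw_distance(cls[k]))
      fits <- sizes >= d + w   # need mid1 - w/2 >= 0 and mid1 + d + w/2 <= L
      if (d < w || !any(fits)) next
      ch <- sample(names(sizes)[fits], 1, prob = sizes[fits])
      mid1 <- floor(stats::runif(1, w / 2, sizes[[ch]] - d - w / 2))
      chrom[k] <- ch
      s1[k] <- mid1 - w / 2
      s2[k] <- mid1 + d - w / 2
      dist[k] <- d
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place a loop of the requested distance after ",
           max_retries, " retries", call. = FALSE)
  }
  # Nucleation points are PRC2 features: flags are planted on the
  # H3K27me3 class only.
  u <- stats::runif(n_total)
  both <- u < spec$frac_nucleation_both & cls == "H3K27me3"
  one <- !both & u < spec$frac_nucleation_both + spec$frac_nucleation_one &
    cls == "H3K27me3"
  left_side <- stats::runif(n_total) < 0.5
  nucl_left <- both | (one & left_side)
  nucl_right <- both | (one & !left_side)
  lp <- loops(chrom, s1, s1 + w, s2, s2 + w, mark = cls)
  truth <- data.frame(loop = seq_len(n_total), chrom = chrom, mark = cls,
                      distance = dist, nucl_left = nucl_left,
                      nucl_right = nucl_right, stringsAsFactors = FALSE)
  anc <- anchors(lp)
  flagged <- anc[c(which(nucl_left), nrow(lp) + which(nucl_right)), , drop = FALSE]
  nucleation <- interval_set(flagged$chrom, flagged$start, flagged$end,
                             label = "nucleation points")
  list(loops = lp, truth = truth, nucleation = nucleation)
}

#' Generate a TAD tiling and A/B compartments
#'
#' TAD sizes are gamma-distributed (shape 4) around `tad_mean_size` and tile
#' each chromosome without gaps or overlaps. Compartments alternate A/B,
#' each spanning a geometrically distributed number of whole TADs, so every
#' compartment boundary coincides with a TAD boundary.
#'
#' @param genome A [synthetic_genome()].
#' @param seed Integer seed.
#' @param tads_per_compartment Mean number of TADs per compartment segment.
#' @return List with interval sets `tads` and `compartments` (the latter
#'   with `name` = "A"/"B").
#' @export
make_tads_and_compartments <- function(genome = synthetic_genome(),
                                       seed = genome$seed,
                                       tads_per_compartment = 3) {
  set_pinned_seed(seed)
  mean_size <- genome$tad_mean_size
  t_chrom <- character(); t_start <- numeric(); t_end <- numeric()
  c_chrom <- character(); c_start <- numeric(); c_end <- numeric(); c_lab <- character()
  for (ch in names(genome$chrom_sizes)) {
    L <- genome$chrom_sizes[[ch]]
    n_guess <- ceiling(L / mean_size * 2) + 5
    sizes <- round(stats::rgamma(n_guess, shape = 4, rate = 4 / mean_size))
    sizes <- pmax(sizes, round(mean_size / 10))
    ends <- cumsum(sizes)
    n <- which(ends >= L)[1]
    ends <- ends[seq_len(n)]; ends[n] <- L
    starts <- c(0, ends[-n])
    keep <- ends > starts          # guard against a zero-width final TAD
    starts <- starts[keep]; ends <- ends[keep]; n <- length(starts)
    t_chrom <- c(t_chrom, rep(ch, n)); t_start <- c(t_start, starts)
    t_end <- c(t_end, ends)
    lab <- if (stats::runif(1) < 0.5) "A" else "B"
    i <- 1
    while (i <= n) {
      span <- min(stats::rgeom(1, 1 / tads_per_compartment) + 1, n - i + 1)
      c_chrom <- c(c_chrom, ch); c_start <- c(c_start, starts[i])
      c_end <- c(c_end, ends[i + span - 1]); c_lab <- c(c_lab, lab)
      lab <- if (lab == "A") "B" else "A"
      i <- i + span
    }
  }
  list(tads = interval_set(t_chrom, t_start, t_end, label = "TADs"),
       compartments = interval_set(c_chrom, c_start, c_end, name = c_lab,
                                   label = "A/B compartments"))
}

#' Generate random non-overlapping peak intervals
#'
#' Utility generator for peak-like interval sets (EZH2 peaks, candidate
#' differential sites, ...). Peaks are placed uniformly (chromosomes
#' weighted by length) and re-drawn on overlap.
#'
#' @param genome A [synthetic_genome()].
#' @param n Number of peaks.
#' @param width Peak width in bp.
#' @param seed Integer seed.
#' @param label Set label.
#' @return Interval set sorted by position.
#' @export
make_peaks <- function(genome = synthetic_genome(), n = 300, width = 5e3,
                       seed = genome$seed, label = "peaks") {
  set_pinned_seed(seed)
  sizes <- genome$chrom_sizes
  chrom <- character(0); start <- numeric(0)
  tries <- 0
  while (length(start) < n && tries < 50 * n) {
    tries <- tries + 1
    ch <- sample(names(sizes), 1, prob = sizes)
    s <- floor(stats::runif(1, 0, sizes[[ch]] - width))
    clash <- chrom == ch & abs(start - s) < width
    if (!any(clash)) { chrom <- c(chrom, ch); start <- c(start, s) }
  }
  if (length(start) < n) stop("could not place ", n, " non-overlapping peaks",
                              call. = FALSE)
  ord <- order(chrom, start)
  interval_set(chrom[ord], start[ord], start[ord] + width, label = label)
}

#' Generate a synthetic binned contact matrix
#'
#' Cis-only sparse matrix with power-law distance decay: the expected count
#' between bins i and j is proportional to `(1 + |i - j|)^-decay_exponent`,
#' multiplied by `dot_enrichment` for bin pairs holding the two anchors of a
#' planted loop. Counts are Poisson-sampled so the realized total
#' approximates `depth`; the realized total filtered read pairs is recorded
#' on the returned object.
#'
#' @param genome A [synthetic_genome()].
#' @param loops Optional `"loops"` frame of dots to plant.
#' @param depth Expected total read-pair count.
#' @param decay_exponent Power-law decay exponent (Hi-C-like ~1).
#' @param dot_enrichment Fold enrichment at planted loop-anchor bin pairs.
#' @param seed Integer seed.
#' @return A [contact_matrix()] object.
#' @export
make_contact_matrix <- function(genome = synthetic_genome(), loops = NULL,
                                depth = 2e6, decay_exponent = 1,
                                dot_enrichment = 8, seed = genome$seed) {
  set_pinned_seed(seed)
  bins <- genome_bins(genome)
  i_all <- integer(0); j_all <- integer(0); lam <- numeric(0)
  for (ch in names(genome$chrom_sizes)) {
    idx <- which(bins$chrom == ch)
    n <- length(idx)
    i_loc <- rep(seq_len(n), n:1)
    j_loc <- sequence(n:1, from = seq_len(n))
    lam_ch <- (1 + (j_loc - i_loc))^(-decay_exponent)
    if (!is.null(loops) && nrow(loops)) {
      lsub <- loops[loops$chrom == ch, , drop = FALSE]
      if (nrow(lsub)) {
        a <- pmin(floor(midpoint(data.frame(start = lsub$start1, end = lsub$end1)) /
                          genome$bin_size) + 1, n)
        b <- pmin(floor(midpoint(data.frame(start = lsub$start2, end = lsub$end2)) /
                          genome$bin_size) + 1, n)
        lo <- pmin(a, b); hi <- pmax(a, b)
        pos <- (lo - 1) * n - (lo - 1) * (lo - 2) / 2 + (hi - lo + 1)
        lam_ch[pos] <- lam_ch[pos] * dot_enrichment
      }
    }
    i_all <- c(i_all, idx[i_loc]); j_all <- c(j_all, idx[j_loc])
    lam <- c(lam, lam_ch)
  }
  lam <- lam * depth / sum(lam)
  counts <- stats::rpois(length(lam), lam)
  keep <- counts > 0
  contact_matrix(bins,
                 data.frame(bin1 = i_all[keep], bin2 = j_all[keep],
                            count = counts[keep]),
                 total = sum(counts), bin_size = genome$bin_size)
}

genome_bins <- function(genome) {
  out <- lapply(names(genome$chrom_sizes), function(ch) {
    L <- genome$chrom_sizes[[ch]]
    starts <- seq(0, L - 1, by = genome$bin_size)
    data.frame(chrom = ch, start = starts, end = pmin(starts + genome$bin_size, L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$bin <- seq_len(nrow(out))
  out
}

#' Generate a peak-shaped signal track
#'
#' Piecewise-constant bedGraph-like track: constant background everywhere
#' plus a symmetric triangular bump of the stated height over each peak,
#' discretized into `steps_per_peak` equal steps (even, so the bump's
#' integral is exactly `height * width / 2`). Optional Poisson noise
#' resamples each run value at its expected count.
#'
#' @param peaks Interval set of peaks (non-overlapping).
#' @param genome A [synthetic_genome()].
#' @param peak_height Bump height at the peak center (depth/bp).
#' @param background Background level (depth/bp).
#' @param steps_per_peak Even number of steps discretizing each bump.
#' @param noise Add Poisson noise per run?
#' @param seed Integer seed (used when `noise`).
#' @return Track `data.frame` (chrom, start, end, value).
#' @export
make_signal_track <- function(peaks, genome = synthetic_genome(),
                              peak_height = 10, background = 0.5,
                              steps_per_peak = 10, noise = FALSE,
                              seed = genome$seed) {
  stopifnot(steps_per_peak %% 2 == 0, steps_per_peak > 0)
  set_pinned_seed(seed)
  rows <- list()
  for (ch in names(genome$chrom_sizes)) {
    L <- genome$chrom_sizes[[ch]]
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(p$start[-1] < p$end[-nrow(p)]))
      stop("peaks must be non-overlapping", call. = FALSE)
    cursor <- 0
    for (k in seq_len(nrow(p))) {
      if (p$start[k] > cursor)
        rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = cursor,
                                               end = p$start[k], value = background)
      w <- p$end[k] - p$start[k]
      edges <- p$start[k] + round(w * (0:steps_per_peak) / steps_per_peak)
      mids <- (edges[-1] + edges[-length(edges)]) / 2
      center <- (p$start[k] + p$end[k]) / 2
      tri <- peak_height * (1 - abs(mids - center) / (w / 2))
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = edges[-length(edges)],
                                             end = edges[-1],
                                             value = background + tri)
      cursor <- p$end[k]
    }
    if (cursor < L)
      rows[[length(rows) + 1]] <- data.frame(chrom = ch, start = cursor, end = L,
                                             value = background)
  }
  track <- do.call(rbind, rows)
  rownames(track) <- NULL
  if (noise) {
    len <- track$end - track$start
    track$value <- stats::rpois(nrow(track), track$value * len) / len
  }
  sort_track(track)
}

#' Generate synthetic ORCA traces
#'
#' Each cell is a 3D Gaussian-step polymer over the ordered barcodes
#' (step sd `step_sd` nm). For each designated barcode pair, with its
#' contact probability the second barcode is resampled uniformly inside a
#' ball of radius `contact_radius` around the first. Each barcode is then
#' dropped independently with `missing_rate` (dropout is independent per
#' barcode per cell; correlated dropout of real imaging is not modelled).
#'
#' @param n_cells Number of cells.
#' @param barcodes Ordered character vector of probe names.
#' @param contact_pairs `data.frame` with columns `a`, `b`, `prob`, or NULL.
#' @param contact_radius Contact radius in nm.
#' @param step_sd Per-axis step standard deviation in nm.
#' @param missing_rate Per-barcode dropout probability.
#' @param genotype Genotype label stored per cell.
#' @param seed Integer seed.
#' @return List with `traces` (an [orca_traces()] frame) and `truth`
#'   (per cell and pair, whether a contact was planted).
#' @export
make_orca_traces <- function(n_cells, barcodes,
                             contact_pairs = NULL, contact_radius = 150,
                             step_sd = 600, missing_rate = 0.05,
                             genotype = "WT", seed = 1L) {
  stopifnot(n_cells > 0, length(barcodes) >= 2,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(contact_pairs))
    stopifnot(all(c("a", "b", "prob") %in% names(contact_pairs)),
              all(contact_pairs$prob >= 0 & contact_pairs$prob <= 1),
              all(c(contact_pairs$a, contact_pairs$b) %in% barcodes))
  set_pinned_seed(seed)
  nb <- length(barcodes)
  # positions: [cell, barcode, axis]; cumulative Gaussian steps from origin
  steps <- array(stats::rnorm(n_cells * nb * 3, sd = step_sd), c(n_cells, nb, 3))
  steps[, 1, ] <- 0
  pos <- steps
  for (k in 2:nb) pos[, k, ] <- pos[, k - 1, ] + steps[, k, ]
  truth <- NULL
  if (!is.null(contact_pairs)) {
    for (r in seq_len(nrow(contact_pairs))) {
      ia <- match(contact_pairs$a[r], barcodes)
      ib <- match(contact_pairs$b[r], barcodes)
      planted <- stats::runif(n_cells) < contact_pairs$prob[r]
      m <- sum(planted)
      if (m > 0) {
        dir <- matrix(stats::rnorm(m * 3), ncol = 3)
        dir <- dir / sqrt(rowSums(dir^2))
        rad <- contact_radius * stats::runif(m)^(1 / 3)
        pos[planted, ib, ] <- pos[planted, ia, ] + dir * rad
      }
      truth <- rbind(truth, data.frame(cell_id = seq_len(n_cells),
                                       a = contact_pairs$a[r],
                                       b = contact_pairs$b[r],
                                       planted_contact = planted,
                                       stringsAsFactors = FALSE))
    }
  }
  present <- matrix(stats::runif(n_cells * nb) >= missing_rate, n_cells, nb)
  cell <- rep(seq_len(n_cells), nb)
  bc <- rep(seq_len(nb), each = n_cells)
  keep <- as.vector(present)
  df <- data.frame(cell_id = cell[keep],
                   genotype = rep_len(genotype, sum(keep)),
                   barcode_id = barcodes[bc[keep]],
                   x_nm = pos[cbind(cell, bc, 1)][keep],
                   y_nm = pos[cbind(cell, bc, 2)][keep],
                   z_nm = pos[cbind(cell, bc, 3)][keep],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cell_id, match(df$barcode_id, barcodes)), , drop = FALSE]
  rownames(df) <- NULL
  list(traces = orca_traces(df, barcodes = barcodes), truth = truth)
}

#' Generate a post-fit differential-site table
#'
#' Emulates the downstream shape of a differential analysis after an anchor
#' deletion: sites that lack EZH2 occupancy AND lie in the deletion's
#' compartment receive a negative log2 fold change of magnitude
#' `effect_size` (plus Gaussian noise) and small adjusted p-values; all
#' other sites are null (log2FC noise around 0, uniform adjusted p). Sites
#' overlapping the deletion are emitted with an `in_deletion` flag for
#' downstream exclusion.
#'
#' @param sites Interval set of candidate sites.
#' @param ezh2 Interval set of EZH2 peaks.
#' @param compartments Compartment interval set (`name` = "A"/"B").
#' @param deletion Single-row interval `data.frame` (the deleted anchor).
#' @param effect_size Planted |log2FC| at affected sites.
#' @param noise_sd Gaussian sd on log2FC.
#' @param seed Integer seed.
#' @return List with `table` (site, log2fc, padj, in_deletion) and `truth`
#'   (per-site planted-effect flag).
#' @export
make_differential_table <- function(sites, ezh2, compartments, deletion,
                                    effect_size = 2, noise_sd = 0.25,
                                    seed = 1L) {
  set_pinned_seed(seed)
  n <- nrow(sites)
  site_comp <- compartment_of(sites, compartments)
  del_comp <- compartment_of(deletion, compartments)[1]
  in_del <- overlap_any(sites, deletion)
  target <- !overlap_any(sites, ezh2) &
    !is.na(site_comp) & !is.na(del_comp) & site_comp == del_comp &
    !in_del & effect_size != 0
  log2fc <- stats::rnorm(n, 0, noise_sd)
  log2fc[target] <- log2fc[target] - effect_size
  padj <- stats::runif(n)
  padj[target] <- stats::runif(sum(target), 1e-6, 0.01)
  tab <- data.frame(chrom = sites$chrom, start = sites$start, end = sites$end,
                    log2fc = log2fc, padj = padj, in_deletion = in_del,
                    stringsAsFactors = FALSE)
  list(table = tab,
       truth = data.frame(site = seq_len(n), planted_effect = target,
                          in_deletion = in_del))
}

#' Compartment label at interval midpoints
#'
#' @param x Interval `data.frame`.
#' @param compartments Compartment interval set with `name` labels.
#' @return Character vector of labels (NA where the midpoint is uncovered).
#' @export
compartment_of <- function(x, compartments) {
  stopifnot(!is.null(compartments$name))
  mids <- midpoint(x)
  out <- rep(NA_character_, nrow(x))
  for (ch in unique(x$chrom)) {
    xi <- which(x$chrom == ch)
    comp <- compartments[compartments$chrom == ch, , drop = FALSE]
    if (!nrow(comp)) next
    comp <- comp[order(comp$start), , drop = FALSE]
    pos <- findInterval(mids[xi], comp$start)
    ok <- pos >= 1 & pos <= nrow(comp)
    ok[ok] <- mids[xi][ok] < comp$end[pos[ok]]
    out[xi[ok]] <- comp$name[pos[ok]]
  }
  out
}
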