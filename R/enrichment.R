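# Windowed signal aggregation at anchor/peak centers and loess-smoothed
# overlap-vs-distance curves.

# Piecewise-linear cumulative evaluators for one chromosome of a track:
# mass(x) = integral of value up to x, cover(x) = covered bp up to x.
# Built once, evaluated vectorized; invariant to fragmentation of runs.
track_cumulator <- function(track, chrom) {
  t <- track[track$chrom == chrom, , drop = FALSE]
  t <- t[order(t$start), , drop = FALSE]
  starts <- t$start; len <- t$end - t$start; vals <- t$value
  cum_mass <- c(0, cumsum(vals * len))
  cum_cover <- c(0, cumsum(len))
  eval_cum <- function(x, cum, rate) {
    i <- findInterval(x, starts)
    j <- pmax(i, 1L)
    within <- pmin(pmax(x - starts[j], 0), len[j])
    out <- cum[j] + rate[j] * within
    out[i == 0L] <- 0
    out
  }
  list(mass = function(x) eval_cum(x, cum_mass, vals),
       cover = function(x) eval_cum(x, cum_cover, rep(1, length(vals))))
}

#' Aggregate signal profile around centers
#'
#' For each center's midpoint, the +/- `window_bp/2` stretch of the track is
#' binned at `bin_bp`; per-bin signal mass summed over centers is divided by
#' the per-bin covered base pairs (so windows truncated at chromosome/track
#' ends contribute only covered bases) and by `library_depth / 1e6`,
#' yielding normalized library depth per base pair per center.
#'
#' @param centers Interval `data.frame` of centers (see [center_choice()]).
#' @param track Signal track (chrom, start, end, value), as from
#'   [read_bedgraph()] or [make_signal_track()].
#' @param window_bp Total window size in bp (default 10 kb).
#' @param bin_bp Profile bin width in bp (default 50); must divide the window.
#' @param library_depth Total track mass used for normalization; defaults to
#'   `sum(value * width)` over the whole track.
#' @return A list of class `"enrichment_profile"`: `offset` (bin centers
#'   relative to the window center), `values`, `covered_bp`, `n_anchors`,
#'   `n_skipped`, `window_bp`, `bin_bp`, `library_depth`.
#' @export
aggregate_profile <- function(centers, track, window_bp = 1e4, bin_bp = 50,
                              library_depth = NULL) {
  stopifnot(nrow(centers) > 0, window_bp %% bin_bp == 0)
  if (is.null(library_depth))
    library_depth <- sum(track$value * (track$end - track$start))
  stopifnot(library_depth > 0)
  nbins <- window_bp / bin_bp
  mass <- numeric(nbins); cover <- numeric(nbins)
  track_chroms <- unique(track$chrom)
  n_skipped <- sum(!centers$chrom %in% track_chroms)
  if (n_skipped)
    message(n_skipped, " center(s) on chromosomes absent from the track were skipped")
  n_used <- 0L
  for (ch in intersect(unique(centers$chrom), track_chroms)) {
    cs <- centers[centers$chrom == ch, , drop = FALSE]
    acc <- track_cumulator(track, ch)
    e0 <- midpoint(cs) - window_bp / 2
    edges <- outer(e0, (0:nbins) * bin_bp, "+")   # centers x (nbins+1)
    m <- matrix(acc$mass(edges), nrow = nrow(edges))
    cv <- matrix(acc$cover(edges), nrow = nrow(edges))
    mass <- mass + colSums(m[, -1, drop = FALSE] - m[, -(nbins + 1), drop = FALSE])
    cover <- cover + colSums(cv[, -1, drop = FALSE] - cv[, -(nbins + 1), drop = FALSE])
    n_used <- n_used + nrow(cs)
  }
  values <- ifelse(cover > 0, mass / cover / (library_depth / 1e6), 0)
  structure(list(offset = -window_bp / 2 + (seq_len(nbins) - 0.5) * bin_bp,
                 values = values, covered_bp = cover,
                 n_anchors = n_used, n_skipped = n_skipped,
                 window_bp = window_bp, bin_bp = bin_bp,
                 library_depth = library_depth),
            class = "enrichment_profile")
}

#' Choose profile centers from anchors and peaks
#'
#' `"peak_in_anchor"` returns one center per peak overlapping any anchor
#' (the peak midpoint) — the convention for profiling external ChIP signal
#' at peaks inside loop anchors. `"anchor_midpoint"` centers on each anchor
#' midpoint directly.
#'
#' @param anchors Interval `data.frame` of anchors (see [anchors()]).
#' @param peaks Peak interval set (used by `"peak_in_anchor"`).
#' @param mode Centering mode.
#' @return Interval `data.frame` of 1-bp center intervals.
#' @export
center_choice <- function(anchors, peaks = NULL,
                          mode = c("peak_in_anchor", "anchor_midpoint")) {
  mode <- match.arg(mode)
  if (mode == "anchor_midpoint") {
    m <- midpoint(anchors)
    return(interval_set(anchors$chrom, m, m + 1))
  }
  stopifnot(!is.null(peaks))
  hit <- overlap_any(peaks, anchors)
  p <- peaks[hit, , drop = FALSE]
  if (!nrow(p)) return(interval_set(character(), numeric(), numeric()))
  m <- midpoint(p)
  interval_set(p$chrom, m, m + 1)
}

# Degree-1 local regression with tricube weights over the nearest
# ceiling(span * n) points; implemented directly so fits are reproducible
# bit-for-bit. Returns predictions at `grid`.
loess_tricube <- function(x, y, grid, span = 0.6) {
  stopifnot(span > 0, span <= 1, length(x) == length(y))
  n <- length(x)
  k <- max(2L, ceiling(span * n))
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d, partial = min(k, n))[min(k, n)]
    if (h == 0) return(mean(y[d == 0]))
    w <- (1 - pmin(d / h, 1)^3)^3
    sw <- sum(w)
    xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
    denom <- sum(w * (x - xm)^2)
    b <- if (denom > 1e-12 * sw) sum(w * (x - xm) * (y - ym)) / denom else 0
    ym + b * (x0 - xm)
  }, numeric(1))
}

#' Overlap-versus-distance curve with loess trend and bootstrap CI
#'
#' Relates each loop's anchor distance (log10 scale for fitting) to a
#' binary indicator of peak overlap (default: the loop has >= 1 anchor
#' overlapping the peak set; `unit = "per_anchor"` scores each distinct
#' anchor, using the minimum distance among the loops it belongs to). The
#' trend is a degree-1 tricube loess (default span 0.6); the 95% CI comes
#' from percentile bootstrap over loops (or anchors), clamped to [0, 1].
#'
#' @param x A `"loops"` data frame.
#' @param peaks Peak interval set.
#' @param span Loess span in (0, 1].
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Seed for the bootstrap.
#' @param unit `"per_loop"` (default) or `"per_anchor"`.
#' @param grid_n Number of grid points for the fitted curve.
#' @param convention Distance convention.
#' @return A list of class `"overlap_curve"`: `points` (distance, overlap),
#'   `fitted` (distance, fit, lower, upper) or NULL when n < 10, `span`,
#'   `n_boot`, `unit`.
#' @export
overlap_distance_curve <- function(x, peaks, span = 0.6, n_boot = 200,
                                   seed = 1L, unit = c("per_loop", "per_anchor"),
                                   grid_n = 50,
                                   convention = c("midpoint", "inner_edge")) {
  unit <- match.arg(unit); convention <- match.arg(convention)
  stopifnot(span > 0, span <= 1)
  d <- anchor_distance(x, convention)
  anc <- anchors(x)
  hit <- overlap_any(anc, peaks)
  if (unit == "per_loop") {
    y <- as.numeric(tapply(hit, anc$loop, any)[as.character(seq_len(nrow(x)))])
    dist <- d
  } else {
    key <- paste(anc$chrom, anc$start, anc$end)
    y <- as.numeric(tapply(hit, key, any))
    dist <- as.numeric(tapply(d[anc$loop], key, min))
  }
  pts <- data.frame(distance = dist, overlap = y)
  n <- nrow(pts)
  if (n < 10) {
    message("fewer than 10 points; returning raw points without a fit")
    return(structure(list(points = pts, fitted = NULL, span = span,
                          n_boot = n_boot, unit = unit),
                     class = "overlap_curve"))
  }
  lx <- log10(pts$distance)
  grid <- seq(min(lx), max(lx), length.out = grid_n)
  fit <- pmin(pmax(loess_tricube(lx, pts$overlap, grid, span), 0), 1)
  set_pinned_seed(seed)
  boots <- matrix(NA_real_, n_boot, grid_n)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- loess_tricube(lx[idx], pts$overlap[idx], grid, span)
  }
  lo <- pmin(pmax(apply(boots, 2, stats::quantile, 0.025, names = FALSE), 0), 1)
  hi <- pmin(pmax(apply(boots, 2, stats::quantile, 0.975, names = FALSE), 0), 1)
  structure(list(points = pts,
                 fitted = data.frame(distance = 10^grid, fit = fit,
                                     lower = lo, upper = hi),
                 span = span, n_boot = n_boot, unit = unit),
            class = "overlap_curve")
}
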