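#' Number of TADs crossed by each loop
#'
#' Counts TADs fully contained in the loop interior `[end1, start2)` —
#' "between the anchors" is read as strict containment between the anchors'
#' inner edges; TADs straddling an anchor are not counted. Loops with no
#' interior (abutting anchors) cross 0 TADs.
#'
#' @param x A `"loops"` data frame.
#' @param tads TAD interval set.
#' @return Integer vector, one count per loop.
#' @export
tads_crossed <- function(x, tads) {
  validate_loops(x)
  out <- integer(nrow(x))
  has_interior <- x$start2 > x$end1
  if (any(has_interior)) {
    interior <- data.frame(chrom = x$chrom[has_interior],
                           start = x$end1[has_interior],
                           end = x$start2[has_interior])
    out[has_interior] <- count_contained(interior, tads)
  }
  out
}

#' Summarize a loop set: distances, TADs crossed, top-percentile medians
#'
#' Per-loop anchor distances and TAD-crossing counts, overall medians, and
#' "top percentile" medians where the top set is the `ceiling(percentile*n)`
#' loops with the largest value of the ranking variable — ranked by distance
#' for the distance summary and (independently) by TAD count for the TAD
#' summary. Medians of even-length samples use the midpoint rule.
#'
#' @param x A `"loops"` data frame (nonempty).
#' @param tads TAD interval set.
#' @param percentile Top-fraction cut in (0, 1]; default 0.01 (top 1%).
#' @param convention Distance convention, see [anchor_distance()].
#' @return A list of class `"loop_summary"`: `n_loops`, `median_distance`,
#'   `top_percentile_median_distance`, `median_tads_crossed`,
#'   `top_percentile_median_tads`, `percentile`, `convention` and the
#'   `per_loop` data frame.
#' @export
summarize_loops <- function(x, tads, percentile = 0.01,
                            convention = c("midpoint", "inner_edge")) {
  convention <- match.arg(convention)
  if (nrow(x) == 0) stop("cannot summarize an empty loop set", call. = FALSE)
  stopifnot(percentile > 0, percentile <= 1)
  d <- anchor_distance(x, convention)
  tc <- tads_crossed(x, tads)
  k <- ceiling(percentile * nrow(x))
  top_d <- sort(d, decreasing = TRUE)[seq_len(k)]
  top_t <- sort(tc, decreasing = TRUE)[seq_len(k)]
  structure(list(
    n_loops = nrow(x),
    median_distance = stats::median(d),
    top_percentile_median_distance = stats::median(top_d),
    median_tads_crossed = stats::median(tc),
    top_percentile_median_tads = stats::median(top_t),
    percentile = percentile,
    convention = convention,
    tad_rule = "fully-contained-in-interior",
    per_loop = data.frame(chrom = x$chrom, mark = x$mark, distance = d,
                          tads_crossed = tc, stringsAsFactors = FALSE)
  ), class = "loop_summary")
}

#' @export
print.loop_summary <- function(x, ...) {
  cat("Loop set summary (", x$n_loops, " loops, ", x$convention,
      " distances)\n", sep = "")
  cat(sprintf("  median distance:            %.3g Mb\n", x$median_distance / 1e6))
  cat(sprintf("  top-%g%% median distance:     %.3g Mb\n",
              100 * x$percentile, x$top_percentile_median_distance / 1e6))
  cat(sprintf("  median TADs crossed:        %g\n", x$median_tads_crossed))
  cat(sprintf("  top-%g%% median TADs crossed: %g\n",
              100 * x$percentile, x$top_percentile_median_tads))
  invisible(x)
}

#' Classify loops by nucleation-point occupancy of their anchors
#'
#' Restricts to loops whose anchor distance strictly exceeds `min_distance`
#' (default 1 Mb, the "spanning over 1 Mb" cut used for Polycomb loops),
#' labels each as having nucleation points at both anchors, exactly one, or
#' neither, and reports the fraction with at least one nucleation anchor
#' plus, among those, the fraction with exactly one.
#'
#' @param x A `"loops"` data frame.
#' @param nucleation Interval set of nucleation points.
#' @param min_distance Strict lower distance bound in bp.
#' @param convention Distance convention.
#' @return A list of class `"nucleation_classification"` with per-loop
#'   labels and aggregate fractions.
#' @export
classify_nucleation <- function(x, nucleation, min_distance = 1e6,
                                convention = c("midpoint", "inner_edge")) {
  convention <- match.arg(convention)
  d <- anchor_distance(x, convention)
  sub <- x[d > min_distance, , drop = FALSE]
  n <- nrow(sub)
  left_hit <- overlap_any(data.frame(chrom = sub$chrom, start = sub$start1,
                                     end = sub$end1), nucleation)
  right_hit <- overlap_any(data.frame(chrom = sub$chrom, start = sub$start2,
                                      end = sub$end2), nucleation)
  label <- ifelse(left_hit & right_hit, "both_anchors",
                  ifelse(left_hit | right_hit, "one_anchor", "neither"))
  n_both <- sum(label == "both_anchors")
  n_one <- sum(label == "one_anchor")
  structure(list(
    n_loops = n, min_distance = min_distance, convention = convention,
    label = label,
    frac_both = if (n) n_both / n else NA_real_,
    frac_one = if (n) n_one / n else NA_real_,
    frac_neither = if (n) 1 - (n_both + n_one) / n else NA_real_,
    frac_any = if (n) (n_both + n_one) / n else NA_real_,
    frac_one_given_any = if (n_both + n_one) n_one / (n_both + n_one) else NA_real_
  ), class = "nucleation_classification")
}

#' @export
print.nucleation_classification <- function(x, ...) {
  cat("Nucleation classification of", x$n_loops, "loops spanning >",
      format(x$min_distance, scientific = FALSE), "bp\n")
  cat(sprintf("  >=1 nucleation anchor: %.1f%%  (exactly one among those: %.1f%%)\n",
              100 * x$frac_any, 100 * x$frac_one_given_any))
  invisible(x)
}

#' Fraction of anchors (or loops) overlapping a peak set
#'
#' @param x A `"loops"` data frame.
#' @param peaks Peak interval set.
#' @param unit `"per_anchor"`: fraction of all 2n anchors overlapping >= 1
#'   peak; `"per_loop"`: fraction of loops with >= 1 overlapping anchor.
#' @return A single fraction.
#' @export
anchor_peak_overlap_fraction <- function(x, peaks,
                                         unit = c("per_anchor", "per_loop")) {
  unit <- match.arg(unit)
  anc <- anchors(x)
  hit <- overlap_any(anc, peaks)
  if (unit == "per_anchor") {
    mean(hit)
  } else {
    mean(tapply(hit, anc$loop, any)[as.character(seq_len(nrow(x)))])
  }
}
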