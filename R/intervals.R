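#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based starts,
#' half-open ends (`[start, end)`). Zero-length or negative-length intervals
#' are rejected rather than silently dropped, and strand is ignored.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer-valued vector of 0-based start positions.
#' @param end Integer-valued vector of exclusive end positions.
#' @param name Optional per-interval labels (e.g. compartment "A"/"B").
#' @param label Optional label for the whole set (e.g. "TADs", "EZH2 peaks").
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end` (and `name`
#'   when given), carrying the set label as attribute `"label"`.
#' @export
#' @examples
#' tads <- interval_set("chr1", c(0, 1e6), c(1e6, 2e6), label = "TADs")
interval_set <- function(chrom, start, end, name = NULL, label = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- as.character(name)
  validate_intervals(x)
  if (!is.null(label)) attr(x, "label") <- label
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, " coordinates must not be NA", call. = FALSE)
  if (any(x$start < 0))
    stop(what, " starts must be >= 0", call. = FALSE)
  if (any(x$end <= x$start))
    stop(what, "s must satisfy start < end (zero-length intervals are rejected)",
         call. = FALSE)
  invisible(x)
}

#' Interval midpoints
#'
#' Midpoint of `[start, end)` defined as `floor((start + end) / 2)`.
#'
#' @param x Interval `data.frame` (see [interval_set()]).
#' @return Numeric vector of midpoints.
#' @export
midpoint <- function(x) floor((x$start + x$end) / 2)

#' Pairwise interval overlap
#'
#' Half-open overlap test: intervals overlap iff they share a chromosome and
#' `a.start < b.end && b.start < a.end`. A shared endpoint (abutting
#' intervals) is NOT an overlap.
#'
#' @param a,b Interval `data.frame`s, recycled to a common length.
#' @return Logical vector.
#' @export
interval_overlaps <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] &
    a$start[ia] < b$end[ib] &
    b$start[ib] < a$end[ia]
}

# For each query interval, does it overlap >= 1 subject interval?
# Counting uses sorted sweep per chromosome: among subjects on the query's
# chromosome, #overlapping = #(s.start < q.end) - #(s.end <= q.start).
#' Count subject intervals overlapping each query interval
#'
#' @param query,subject Interval `data.frame`s.
#' @return Integer vector, one count per query row (half-open semantics).
#' @export
overlap_count <- function(query, subject) {
  validate_intervals(query); validate_intervals(subject)
  out <- integer(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    s <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0L) next
    starts <- sort(s$start); ends <- sort(s$end)
    n_start_before <- findInterval(query$end[qi] - 0.5, starts)
    n_end_before <- findInterval(query$start[qi] + 0.5, ends)
    out[qi] <- n_start_before - n_end_before
  }
  out
}

#' @rdname overlap_count
#' @return `overlap_any()`: logical vector, one flag per query row.
#' @export
overlap_any <- function(query, subject) overlap_count(query, subject) > 0L

#' Count intervals fully contained in a container
#'
#' An interval `s` counts iff it shares the container's chromosome and
#' `container.start <= s.start` and `s.end <= container.end` (full
#' containment; partial overlaps are excluded).
#'
#' @param container Interval `data.frame` (one or more containers).
#' @param set Interval `data.frame` to count from.
#' @return Integer vector, one count per container row.
#' @export
count_contained <- function(container, set) {
  validate_intervals(container)
  if (nrow(set)) validate_intervals(set)
  vapply(seq_len(nrow(container)), function(i) {
    sum(set$chrom == container$chrom[i] &
          set$start >= container$start[i] &
          set$end <= container$end[i])
  }, integer(1))
}

#' Merge overlapping intervals
#'
#' Collapses overlapping (not merely abutting) intervals per chromosome
#' into their union; `name` and `label` attributes of the merged rows are
#' dropped.
#'
#' @param x Interval `data.frame`.
#' @return Interval `data.frame` of disjoint intervals, sorted.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  x <- x[order(x$chrom, x$start, x$end), , drop = FALSE]
  out_chrom <- character(); out_start <- numeric(); out_end <- numeric()
  for (ch in unique(x$chrom)) {
    s <- x$start[x$chrom == ch]; e <- x$end[x$chrom == ch]
    cur_s <- s[1]; cur_e <- e[1]
    for (k in seq_along(s)[-1]) {
      if (s[k] < cur_e) cur_e <- max(cur_e, e[k])
      else {
        out_chrom <- c(out_chrom, ch); out_start <- c(out_start, cur_s)
        out_end <- c(out_end, cur_e)
        cur_s <- s[k]; cur_e <- e[k]
      }
    }
    out_chrom <- c(out_chrom, ch); out_start <- c(out_start, cur_s)
    out_end <- c(out_end, cur_e)
  }
  interval_set(out_chrom, out_start, out_end)
}

#' Construct a set of chromatin loops
#'
#' A loop is an ordered pair of anchors on one chromosome; the left anchor
#' must precede the right (`end1 <= start2`). Interchromosomal pairs and
#' overlapping anchors are rejected at construction.
#'
#' @param chrom Chromosome (shared by both anchors).
#' @param start1,end1 Left anchor coordinates (0-based half-open).
#' @param start2,end2 Right anchor coordinates.
#' @param mark Loop class: `"H3K27me3"`, `"H3K27ac"` or `"unlabeled"`.
#' @param score Optional confidence score.
#' @return A `data.frame` of class `"loops"`.
#' @export
loops <- function(chrom, start1, end1, start2, end2,
                  mark = "unlabeled", score = NA_real_) {
  x <- data.frame(chrom = as.character(chrom),
                  start1 = as.numeric(start1), end1 = as.numeric(end1),
                  start2 = as.numeric(start2), end2 = as.numeric(end2),
                  mark = as.character(mark), score = as.numeric(score),
                  stringsAsFactors = FALSE)
  validate_loops(x)
  class(x) <- c("loops", "data.frame")
  x
}

validate_loops <- function(x) {
  validate_intervals(data.frame(chrom = x$chrom, start = x$start1, end = x$end1),
                     "left anchor")
  validate_intervals(data.frame(chrom = x$chrom, start = x$start2, end = x$end2),
                     "right anchor")
  if (any(x$end1 > x$start2))
    stop("left anchor must precede right anchor (end1 <= start2)", call. = FALSE)
  bad <- x$mark %in% c("H3K27me3", "H3K27ac", "unlabeled")
  if (!all(bad)) stop("mark must be H3K27me3, H3K27ac or unlabeled", call. = FALSE)
  invisible(x)
}

#' Extract loop anchors as intervals
#'
#' @param x A `"loops"` data frame.
#' @param side `"left"`, `"right"` or `"both"` (left anchors then right).
#' @return Interval `data.frame` with a `loop` column giving the source row.
#' @export
anchors <- function(x, side = c("both", "left", "right")) {
  side <- match.arg(side)
  left <- data.frame(chrom = x$chrom, start = x$start1, end = x$end1,
                     loop = seq_len(nrow(x)), side = "left",
                     stringsAsFactors = FALSE)
  right <- data.frame(chrom = x$chrom, start = x$start2, end = x$end2,
                      loop = seq_len(nrow(x)), side = "right",
                      stringsAsFactors = FALSE)
  switch(side, left = left, right = right, both = rbind(left, right))
}

#' Distance between loop anchors
#'
#' The convention is a required, logged parameter because published loop
#' sets rarely state theirs: `"midpoint"` is midpoint-to-midpoint
#' (`|mid(right) - mid(left)|`), `"inner_edge"` is `start2 - end1`.
#'
#' @param x A `"loops"` data frame (intrachromosomal by construction).
#' @param convention `"midpoint"` (default) or `"inner_edge"`.
#' @return Numeric vector of distances in bp (nonnegative).
#' @export
#' @examples
#' l <- loops("chr1", 1000, 2000, 9000, 10000)
#' anchor_distance(l)                  # 8000
#' anchor_distance(l, "inner_edge")    # 7000
anchor_distance <- function(x, convention = c("midpoint", "inner_edge")) {
  convention <- match.arg(convention)
  validate_loops(x)
  if (convention == "midpoint") {
    abs(floor((x$start2 + x$end2) / 2) - floor((x$start1 + x$end1) / 2))
  } else {
    x$start2 - x$end1
  }
}
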