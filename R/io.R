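#' Read a BED3+ interval file
#'
#' Tab-separated, 0-based half-open. Header lines starting with `track`,
#' `browser` or `#` are skipped. Column 4, when present, is kept as `name`.
#' Zero-length records are rejected at parse time.
#'
#' @param path File path.
#' @param label Optional set label stored as an attribute.
#' @return Interval `data.frame` (see [interval_set()]).
#' @export
read_bed <- function(path, label = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  if (!any(keep)) return(interval_set(character(), numeric(), numeric(), label = label))
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- min(lengths(f))
  if (ncol < 3) stop("BED file needs >= 3 columns: ", path, call. = FALSE)
  chrom <- vapply(f, `[[`, "", 1L)
  start <- as.numeric(vapply(f, `[[`, "", 2L))
  end <- as.numeric(vapply(f, `[[`, "", 3L))
  name <- if (ncol >= 4) vapply(f, `[[`, "", 4L) else NULL
  interval_set(chrom, start, end, name = name, label = label)
}

#' Write intervals as BED
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- x[intersect(c("chrom", "start", "end", "name"), names(x))]
  utils::write.table(format(cols, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read loops from a BEDPE file
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, and optionally
#' name and score. Anchors are re-ordered so the left anchor precedes the
#' right; interchromosomal rows are counted and excluded with a warning.
#' When `name` is `H3K27me3`/`H3K27ac` it is used as the loop mark.
#'
#' @param path File path.
#' @param mark Mark assigned when the file carries none.
#' @return A `"loops"` data frame.
#' @export
read_bedpe <- function(path, mark = "unlabeled") {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- if (length(f)) min(lengths(f)) else 0L
  if (length(f) && ncol < 6) stop("BEDPE file needs >= 6 columns: ", path, call. = FALSE)
  if (!length(f))
    return(loops(character(), numeric(), numeric(), numeric(), numeric()))
  col <- function(i) vapply(f, `[[`, "", i)
  c1 <- col(1); s1 <- as.numeric(col(2)); e1 <- as.numeric(col(3))
  c2 <- col(4); s2 <- as.numeric(col(5)); e2 <- as.numeric(col(6))
  nm <- if (ncol >= 7) col(7) else rep(mark, length(c1))
  sc <- if (ncol >= 8) suppressWarnings(as.numeric(col(8))) else rep(NA_real_, length(c1))
  cis <- c1 == c2
  if (any(!cis))
    warning(sum(!cis), " interchromosomal row(s) excluded from ", path, call. = FALSE)
  c1 <- c1[cis]; s1 <- s1[cis]; e1 <- e1[cis]
  s2 <- s2[cis]; e2 <- e2[cis]; nm <- nm[cis]; sc <- sc[cis]
  swap <- s1 > s2 | (s1 == s2 & e1 > e2)
  if (any(swap)) {
    tmp_s <- s1[swap]; tmp_e <- e1[swap]
    s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
    s2[swap] <- tmp_s; e2[swap] <- tmp_e
  }
  mk <- ifelse(nm %in% c("H3K27me3", "H3K27ac"), nm, mark)
  loops(c1, s1, e1, s2, e2, mark = mk, score = sc)
}

#' Write loops as BEDPE
#'
#' @param x A `"loops"` data frame.
#' @param path Output path.
#' @export
write_bedpe <- function(x, path) {
  out <- data.frame(x$chrom, x$start1, x$end1, x$chrom, x$start2, x$end2,
                    x$mark, ifelse(is.na(x$score), ".", format(x$score)))
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph signal track
#'
#' Four tab-separated columns (chrom, start, end, value); `track`/`#`
#' header lines skipped. Runs may be unsorted; they are sorted per
#' chromosome on read. Overlapping runs are rejected.
#'
#' @param path File path.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  f <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (length(f) && min(lengths(f)) < 4)
    stop("bedGraph needs 4 columns: ", path, call. = FALSE)
  x <- data.frame(chrom = vapply(f, `[[`, "", 1L),
                  start = as.numeric(vapply(f, `[[`, "", 2L)),
                  end = as.numeric(vapply(f, `[[`, "", 3L)),
                  value = as.numeric(vapply(f, `[[`, "", 4L)),
                  stringsAsFactors = FALSE)
  sort_track(x)
}

sort_track <- function(x) {
  x <- x[order(x$chrom, x$start), , drop = FALSE]
  rownames(x) <- NULL
  by_start <- split(seq_len(nrow(x)), x$chrom)
  for (idx in by_start) {
    if (length(idx) > 1 && any(x$start[idx][-1] < x$end[idx][-length(idx)]))
      stop("overlapping bedGraph runs on ", x$chrom[idx[1]], call. = FALSE)
  }
  x
}

#' @rdname read_bedgraph
#' @param x Track `data.frame`.
#' @param path Output path.
#' @export
write_bedgraph <- function(x, path) {
  utils::write.table(
    data.frame(x$chrom,
               format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE),
               format(x$value, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read ORCA trace table
#'
#' Tab-separated with header: `cell_id`, `genotype`, `barcode_id`, `x_nm`,
#' `y_nm`, `z_nm` (coordinates in nanometres; missing barcodes are simply
#' absent rows).
#'
#' @param path File path.
#' @return An `"orca_traces"` data frame (see [orca_traces()]).
#' @export
read_orca_traces <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  orca_traces(x)
}

#' @rdname read_orca_traces
#' @param x An `"orca_traces"` data frame.
#' @export
write_orca_traces <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a differential-site table
#'
#' Tab-separated with header; requires columns `chrom`, `start`, `end`,
#' `log2fc`, `padj` (`padj` may be NA for independence-filtered rows).
#'
#' @param path File path.
#' @return `data.frame` of sites with effect estimates.
#' @export
read_differential_table <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "log2fc", "padj")
  if (!all(need %in% names(x)))
    stop("differential table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  validate_intervals(x, "site")
  if (any(!is.finite(x$log2fc))) stop("log2fc must be finite", call. = FALSE)
  x
}

#' @rdname read_differential_table
#' @param x Differential table.
#' @export
write_differential_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write/read a key-value manifest
#'
#' One `key = value` pair per line; used by the generators and the pipeline
#' to record seeds and parameters next to each dataset.
#'
#' @param x Named list of scalar values.
#' @param path File path.
#' @export
write_manifest <- function(x, path) {
  writeLines(paste0(names(x), " = ",
                    vapply(x, function(v) paste(format(v, scientific = FALSE),
                                                collapse = ","), "")),
             path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  kv <- regmatches(lines, regexec("^([^=]+) = (.*)$", lines))
  out <- lapply(kv, `[`, 3L)
  names(out) <- trimws(vapply(kv, `[`, "", 2L))
  out
}
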