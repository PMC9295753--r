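#' Sparse binned contact matrix
#'
#' Symmetric cis/trans contact counts stored as an upper-triangle triplet
#' table against a bin table tiling the genome at `bin_size`. Queries are
#' symmetric by construction: `(i, j)` and `(j, i)` are the same record.
#'
#' @param bins Bin table `data.frame` (chrom, start, end, bin) with 1-based
#'   consecutive `bin` indices.
#' @param counts Triplet `data.frame` (bin1, bin2, count); pairs are
#'   normalized so `bin1 <= bin2` and duplicate pairs are summed.
#' @param total Total filtered read pairs; defaults to `sum(count)`.
#' @param bin_size Bin size in bp.
#' @return A list of class `"contact_matrix"`.
#' @export
contact_matrix <- function(bins, counts, total = NULL, bin_size = NULL) {
  stopifnot(all(c("chrom", "start", "end", "bin") %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(counts)))
  if (is.null(bin_size)) bin_size <- max(bins$end - bins$start)
  lo <- pmin(counts$bin1, counts$bin2); hi <- pmax(counts$bin1, counts$bin2)
  counts <- stats::aggregate(count ~ bin1 + bin2,
                             data.frame(bin1 = lo, bin2 = hi,
                                        count = counts$count),
                             FUN = sum)
  if (is.null(total)) total <- sum(counts$count)
  structure(list(bins = bins, counts = counts, total = total,
                 bin_size = bin_size),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", nrow(x$bins), "bins at",
      format(x$bin_size, scientific = FALSE), "bp,",
      nrow(x$counts), "nonzero pairs,", x$total, "filtered read pairs\n")
  invisible(x)
}

#' Read / write a contact matrix as triplet text plus a bin table
#'
#' The counts file has three tab-separated columns (bin1, bin2, count,
#' 1-based bin indices); the bin table is BED3 plus a fourth `bin` column.
#' The total filtered read pairs may be supplied or recomputed as the
#' count sum.
#'
#' @param counts_path,bins_path File paths.
#' @param total Optional total filtered read pairs.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(counts_path, bins_path, total = NULL) {
  cn <- utils::read.table(counts_path, sep = "\t",
                          col.names = c("bin1", "bin2", "count"))
  bn <- utils::read.table(bins_path, sep = "\t",
                          col.names = c("chrom", "start", "end", "bin"))
  contact_matrix(bn, cn, total = total)
}

#' @rdname read_contact_matrix
#' @param x A `"contact_matrix"`.
#' @export
write_contact_matrix <- function(x, counts_path, bins_path) {
  utils::write.table(x$counts, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(format(x$bins[c("chrom", "start", "end", "bin")],
                            scientific = FALSE, trim = TRUE),
                     bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Virtual 4C profile from a contact matrix
#'
#' Sums matrix rows over all bins overlapping the viewpoint (cis only) and
#' scales by `1e6 / total filtered read pairs`, i.e. counts per million
#' filtered read pairs per bin. Optionally applies a centered running mean
#' over `smooth_bins` bins (odd; partial windows at chromosome ends).
#' Viewpoint bins' self-interaction values are reported but flagged.
#'
#' @param x A [contact_matrix()].
#' @param viewpoint Single interval `data.frame` row (chrom, start, end).
#' @param smooth_bins Odd smoothing window in bins; 1 = no smoothing.
#' @return A list of class `"virtual4c"` with the per-bin `profile`
#'   data frame (chrom, start, end, bin, value, is_viewpoint).
#' @export
virtual_4c <- function(x, viewpoint, smooth_bins = 1) {
  stopifnot(inherits(x, "contact_matrix"), nrow(viewpoint) == 1,
            smooth_bins >= 1, smooth_bins %% 2 == 1)
  ch <- viewpoint$chrom[1]
  cis <- x$bins[x$bins$chrom == ch, , drop = FALSE]
  if (!nrow(cis)) stop("viewpoint chromosome ", ch, " absent from bin table",
                       call. = FALSE)
  vp_bins <- cis$bin[cis$start < viewpoint$end[1] & viewpoint$start[1] < cis$end]
  if (!length(vp_bins)) stop("viewpoint maps to no bin", call. = FALSE)
  idx <- stats::setNames(seq_len(nrow(cis)), cis$bin)
  prof <- numeric(nrow(cis))
  cn <- x$counts
  sel1 <- cn$bin1 %in% vp_bins & cn$bin2 %in% cis$bin
  if (any(sel1)) {
    tab <- tapply(cn$count[sel1], cn$bin2[sel1], sum)
    prof[idx[names(tab)]] <- prof[idx[names(tab)]] + tab
  }
  sel2 <- cn$bin2 %in% vp_bins & cn$bin1 %in% cis$bin & cn$bin1 != cn$bin2
  if (any(sel2)) {
    tab <- tapply(cn$count[sel2], cn$bin1[sel2], sum)
    prof[idx[names(tab)]] <- prof[idx[names(tab)]] + tab
  }
  value <- prof * 1e6 / x$total
  if (smooth_bins > 1) {
    half <- (smooth_bins - 1) / 2
    csum <- cumsum(c(0, value))
    n <- length(value)
    lo <- pmax(seq_len(n) - half, 1); hi <- pmin(seq_len(n) + half, n)
    value <- (csum[hi + 1] - csum[lo]) / (hi - lo + 1)
  }
  structure(list(profile = data.frame(chrom = cis$chrom, start = cis$start,
                                      end = cis$end, bin = cis$bin,
                                      value = value,
                                      is_viewpoint = cis$bin %in% vp_bins),
                 viewpoint = viewpoint, smooth_bins = smooth_bins,
                 total = x$total),
            class = "virtual4c")
}

#' Match two loop sets with positional slack
#'
#' Two loops match iff their left anchors overlap after symmetric extension
#' of both by `slack_bp` AND their right anchors do likewise. Matching is a
#' greedy one-to-one assignment by ascending combined anchor-midpoint
#' offset (ties broken by leftmost coordinates), so shared fractions are
#' well-defined.
#'
#' @param a,b `"loops"` data frames.
#' @param slack_bp Symmetric anchor extension in bp (default one 10-kb bin).
#' @return List: `shared` (idx_a, idx_b, offset), `a_only`, `b_only`,
#'   `frac_a`, `frac_b` (shared fraction relative to each set).
#' @export
match_loops <- function(a, b, slack_bp = 1e4) {
  stopifnot(slack_bp >= 0)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(list(shared = data.frame(idx_a = integer(), idx_b = integer(),
                                    offset = numeric()),
                a_only = seq_len(nrow(a)), b_only = seq_len(nrow(b)),
                frac_a = if (nrow(a)) 0 else NA_real_,
                frac_b = if (nrow(b)) 0 else NA_real_))
  mids_a1 <- floor((a$start1 + a$end1) / 2); mids_a2 <- floor((a$start2 + a$end2) / 2)
  mids_b1 <- floor((b$start1 + b$end1) / 2); mids_b2 <- floor((b$start2 + b$end2) / 2)
  cand <- list(); ci <- 0
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i] &
                 a$start1[i] - slack_bp < b$end1 + slack_bp &
                 b$start1 - slack_bp < a$end1[i] + slack_bp &
                 a$start2[i] - slack_bp < b$end2 + slack_bp &
                 b$start2 - slack_bp < a$end2[i] + slack_bp)
    if (length(j)) {
      ci <- ci + 1
      cand[[ci]] <- data.frame(
        idx_a = i, idx_b = j,
        offset = abs(mids_a1[i] - mids_b1[j]) + abs(mids_a2[i] - mids_b2[j]))
    }
  }
  if (!ci)
    return(list(shared = data.frame(idx_a = integer(), idx_b = integer(),
                                    offset = numeric()),
                a_only = seq_len(nrow(a)), b_only = seq_len(nrow(b)),
                frac_a = 0, frac_b = 0))
  cand <- do.call(rbind, cand)
  ord <- order(cand$offset, a$start1[cand$idx_a], b$start1[cand$idx_b])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ia <- cand$idx_a[r]; ib <- cand$idx_b[r]
    if (!used_a[ia] && !used_b[ib]) {
      keep[r] <- TRUE; used_a[ia] <- TRUE; used_b[ib] <- TRUE
    }
  }
  shared <- cand[keep, , drop = FALSE]
  rownames(shared) <- NULL
  list(shared = shared,
       a_only = which(!used_a), b_only = which(!used_b),
       frac_a = sum(used_a) / nrow(a), frac_b = sum(used_b) / nrow(b))
}

#' Fraction of native loops conserved in a mapped loop set
#'
#' Both sets must already be expressed in the same genome's coordinates
#' (cross-species coordinate mapping happens upstream). Mixed chromosome
#' naming ("chr1" vs "1") between the sets is rejected with a hint.
#'
#' @param native,mapped `"loops"` data frames in one coordinate system.
#' @param slack_bp Matching slack, see [match_loops()].
#' @return Fraction of `native` loops matched, with the full match result
#'   as attribute `"match"`.
#' @export
conserved_loops <- function(native, mapped, slack_bp = 1e4) {
  has_prefix <- function(x) grepl("^chr", x$chrom)
  if (nrow(native) && nrow(mapped) &&
      (any(has_prefix(native)) != any(has_prefix(mapped))))
    stop("mixed chromosome naming between loop sets ('chr1' vs '1'); ",
         "normalize names before matching", call. = FALSE)
  m <- match_loops(native, mapped, slack_bp)
  structure(m$frac_a, match = m)
}
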