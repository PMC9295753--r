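#' ORCA trace set
#'
#' Per-cell 3D positions (nm) of sequentially imaged genomic barcodes, as a
#' long table: one row per localized barcode per cell. Missing barcodes are
#' simply absent rows; a cell contributes to a pair's statistics only when
#' both barcodes are localized.
#'
#' @param x `data.frame` with columns `cell_id`, `genotype`, `barcode_id`,
#'   `x_nm`, `y_nm`, `z_nm`.
#' @param barcodes Ordered probe names; defaults to order of appearance.
#' @return `x` with class `"orca_traces"` and a `"barcodes"` attribute.
#' @export
orca_traces <- function(x, barcodes = NULL) {
  need <- c("cell_id", "genotype", "barcode_id", "x_nm", "y_nm", "z_nm")
  if (!all(need %in% names(x)))
    stop("ORCA traces need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(x$x_nm)) || !all(is.finite(x$y_nm)) || !all(is.finite(x$z_nm)))
    stop("ORCA coordinates must be finite", call. = FALSE)
  if (is.null(barcodes)) barcodes <- unique(x$barcode_id)
  if (!all(x$barcode_id %in% barcodes))
    stop("trace rows carry barcodes outside the probe design", call. = FALSE)
  if (anyDuplicated(x[c("cell_id", "barcode_id")]))
    stop("duplicate (cell, barcode) localizations", call. = FALSE)
  structure(x, barcodes = barcodes, class = c("orca_traces", "data.frame"))
}

#' Pairwise 3D distances for one barcode pair
#'
#' Euclidean distance between two barcodes in every cell where both are
#' localized; cells missing either barcode are excluded and counted.
#'
#' @param traces An [orca_traces()] frame.
#' @param a,b Barcode names (must be in the probe design).
#' @return A list of class `"pair_distances"`: `pair`, `distances`
#'   (cell_id, genotype, distance_nm), `n_informative`, `n_excluded`,
#'   `n_cells`.
#' @export
pair_distances <- function(traces, a, b) {
  barcodes <- attr(traces, "barcodes")
  if (!a %in% barcodes || !b %in% barcodes)
    stop("unknown barcode: ", paste(setdiff(c(a, b), barcodes), collapse = ", "),
         call. = FALSE)
  ta <- traces[traces$barcode_id == a, , drop = FALSE]
  tb <- traces[traces$barcode_id == b, , drop = FALSE]
  m <- merge(ta[c("cell_id", "genotype", "x_nm", "y_nm", "z_nm")],
             tb[c("cell_id", "x_nm", "y_nm", "z_nm")],
             by = "cell_id", suffixes = c("_a", "_b"))
  d <- sqrt((m$x_nm_a - m$x_nm_b)^2 + (m$y_nm_a - m$y_nm_b)^2 +
              (m$z_nm_a - m$z_nm_b)^2)
  n_cells <- length(unique(traces$cell_id))
  structure(list(pair = c(a, b),
                 distances = data.frame(cell_id = m$cell_id,
                                        genotype = m$genotype,
                                        distance_nm = d),
                 n_informative = nrow(m),
                 n_excluded = n_cells - nrow(m),
                 n_cells = n_cells),
            class = "pair_distances")
}

#' Contact frequency at a distance threshold
#'
#' Fraction of informative cells whose pair distance is strictly below
#' `threshold_nm` (the "<150 nm" imaging definition of contact). The
#' denominator is informative cells only; the raw cell count is available
#' on the input object.
#'
#' @param x A [pair_distances()] result.
#' @param threshold_nm Contact threshold in nm (strict `<`).
#' @return Fraction in [0, 1].
#' @export
contact_frequency <- function(x, threshold_nm = 150) {
  stopifnot(inherits(x, "pair_distances"))
  if (x$n_informative == 0)
    stop("no informative cells for pair ", paste(x$pair, collapse = "-"),
         call. = FALSE)
  mean(x$distances$distance_nm < threshold_nm)
}

#' Compare pair distances between two genotypes
#'
#' Per-genotype distance medians and a two-sided Wilcoxon rank-sum p-value
#' (via [compare_distributions()]).
#'
#' @param traces An [orca_traces()] frame containing both genotypes.
#' @param a,b Barcode names of the pair.
#' @param genotypes Length-2 character vector `(reference, alternative)`.
#' @return List: `median_1`, `median_2` (nm, in `genotypes` order), `n_1`,
#'   `n_2`, `p_value`.
#' @export
compare_genotypes <- function(traces, a, b, genotypes = c("WT", "MT")) {
  stopifnot(length(genotypes) == 2)
  pd <- pair_distances(traces, a, b)
  d1 <- pd$distances$distance_nm[pd$distances$genotype == genotypes[1]]
  d2 <- pd$distances$distance_nm[pd$distances$genotype == genotypes[2]]
  if (!length(d1) || !length(d2))
    stop("both genotype groups need informative cells", call. = FALSE)
  w <- compare_distributions(d1, d2)
  list(median_1 = stats::median(d1), median_2 = stats::median(d2),
       n_1 = length(d1), n_2 = length(d2), p_value = w$p_value)
}
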