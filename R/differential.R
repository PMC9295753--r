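#' Classify differential sites by effect size and adjusted p
#'
#' Strict thresholds on both sides: a site is significant iff
#' `|log2fc| > fc_cut` AND `padj < p_cut` (a site at exactly the cutoff is
#' not significant); direction comes from the sign of `log2fc`. Missing
#' `padj` (independence-filtered rows) means non-significant. The default
#' cuts (1, 0.05) are the histone-signal convention; `fc_cut = 0.5` is the
#' convention for differential EZH2 peak signal.
#'
#' @param table Differential table (chrom, start, end, log2fc, padj).
#' @param fc_cut Strict |log2FC| threshold (> 0).
#' @param p_cut Strict adjusted-p threshold (> 0).
#' @return The table with a `status` column (`"down"`, `"ns"`, `"up"`),
#'   classed `"site_classification"`; thresholds kept as attributes.
#' @export
classify_differential_sites <- function(table, fc_cut = 1, p_cut = 0.05) {
  stopifnot(fc_cut > 0, p_cut > 0)
  sig <- !is.na(table$padj) & table$padj < p_cut & abs(table$log2fc) > fc_cut
  table$status <- ifelse(sig & table$log2fc < 0, "down",
                         ifelse(sig, "up", "ns"))
  structure(table, fc_cut = fc_cut, p_cut = p_cut,
            class = c("site_classification", class(table)))
}

#' Annotate classified sites with deletion, EZH2 and compartment context
#'
#' Flags sites overlapping the deletion (any-bp overlap) for exclusion,
#' marks cis (same chromosome as the deletion), EZH2 occupancy (any-bp peak
#' overlap) and whether the site's compartment label equals the deletion's.
#' Compartment labels are taken at interval midpoints; a deletion spanning
#' a compartment boundary keeps the label at its midpoint with a warning.
#'
#' @param cls A [classify_differential_sites()] result.
#' @param deletion Single-row interval `data.frame` (the deleted anchor).
#' @param ezh2 EZH2 peak interval set.
#' @param compartments Compartment interval set (`name` = "A"/"B").
#' @return `cls` with added columns `excluded`, `cis`, `ezh2_occupied`,
#'   `compartment`, `same_compartment`, `distance_to_deletion` (bp between
#'   midpoints, NA in trans).
#' @export
annotate_sites <- function(cls, deletion, ezh2, compartments) {
  stopifnot(nrow(deletion) == 1)
  n_comp <- sum(interval_overlaps(compartments, deletion))
  if (n_comp > 1)
    warning("deletion spans a compartment boundary; using the label at its ",
            "midpoint", call. = FALSE)
  del_comp <- compartment_of(deletion, compartments)[1]
  cls$excluded <- overlap_any(cls, deletion)
  cls$cis <- cls$chrom == deletion$chrom[1]
  cls$ezh2_occupied <- overlap_any(cls, ezh2)
  cls$compartment <- compartment_of(cls, compartments)
  cls$same_compartment <- !is.na(cls$compartment) & !is.na(del_comp) &
    cls$compartment == del_comp
  cls$distance_to_deletion <- ifelse(
    cls$cis, abs(midpoint(cls) - midpoint(deletion)[1]), NA_real_)
  cls
}

#' Stratified contingency summary of annotated differential sites
#'
#' Cross-tabulates significance status by EZH2 occupancy and
#' same-compartment membership among non-excluded sites, genome-wide and
#' cis-only, and reports a two-sided Fisher exact test (point-probability
#' method, via [stats::fisher.test()]) on the 2x2 (down vs not) x
#' (EZH2-occupied vs not) table for each scope.
#'
#' @param cls An [annotate_sites()] result.
#' @return List of class `"stratified_summary"` with per-scope `counts`
#'   (data frame) and `fisher_p`.
#' @export
stratified_summary <- function(cls) {
  need <- c("status", "excluded", "cis", "ezh2_occupied", "same_compartment")
  if (!all(need %in% names(cls)))
    stop("annotate_sites() must be run before stratified_summary()",
         call. = FALSE)
  one_scope <- function(x) {
    counts <- as.data.frame(table(
      status = factor(x$status, c("down", "ns", "up")),
      ezh2_occupied = factor(x$ezh2_occupied, c(FALSE, TRUE)),
      same_compartment = factor(x$same_compartment, c(FALSE, TRUE))))
    tab <- matrix(c(sum(x$status == "down" & !x$ezh2_occupied),
                    sum(x$status == "down" & x$ezh2_occupied),
                    sum(x$status != "down" & !x$ezh2_occupied),
                    sum(x$status != "down" & x$ezh2_occupied)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("down", "not_down"),
                                  c("ezh2_absent", "ezh2_occupied")))
    p <- if (sum(tab) == 0 || all(tab[1, ] == 0)) 1
         else stats::fisher.test(tab)$p.value
    list(counts = counts, fisher_table = tab, fisher_p = p)
  }
  keep <- !cls$excluded
  structure(list(genomewide = one_scope(cls[keep, , drop = FALSE]),
                 cis = one_scope(cls[keep & cls$cis, , drop = FALSE])),
            class = "stratified_summary")
}

#' @export
print.stratified_summary <- function(x, ...) {
  cat("Differential-site stratification (non-excluded sites)\n")
  for (scope in c("genomewide", "cis")) {
    cat(" ", scope, ": Fisher p (down x EZH2) =",
        format.pval(x[[scope]]$fisher_p), "\n")
    print(x[[scope]]$fisher_table)
  }
  invisible(x)
}

#' Flag transcripts in an expression scatter comparison
#'
#' Classifies each transcript as higher/lower/ns under strict cuts
#' (`log2fc > fc_cut` with `padj < p_cut` for higher; `log2fc < -fc_cut`
#' for lower) and flags membership in the deleted-gene and partner-gene
#' lists regardless of significance.
#'
#' @param table `data.frame` with columns `gene`, `log2fc`, `padj`
#'   (gene names unique).
#' @param deleted_genes,partner_genes Character vectors of gene names.
#' @param fc_cut,p_cut Strict thresholds.
#' @return The table with `class` (`"higher"`/`"lower"`/`"ns"`),
#'   `is_deleted`, `is_partner` columns.
#' @export
expression_scatter_flags <- function(table, deleted_genes = character(),
                                     partner_genes = character(),
                                     fc_cut = 1, p_cut = 0.05) {
  stopifnot(all(c("gene", "log2fc", "padj") %in% names(table)))
  if (anyDuplicated(table$gene))
    stop("gene names must be unique per row", call. = FALSE)
  sig <- !is.na(table$padj) & table$padj < p_cut
  table$class <- ifelse(sig & table$log2fc > fc_cut, "higher",
                        ifelse(sig & table$log2fc < -fc_cut, "lower", "ns"))
  table$is_deleted <- table$gene %in% deleted_genes
  table$is_partner <- table$gene %in% partner_genes
  table
}
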