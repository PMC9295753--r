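test_that("significance requires strict cuts on both effect and padj", {
  tab <- data.frame(chrom = "chr1", start = (0:4) * 1000, end = (0:4) * 1000 + 500,
                    log2fc = c(1.0, -2, 1.5, -1.2, 3),
                    padj = c(0.01, 0.001, 0.05, NA, 0.049))
  cls <- classify_differential_sites(tab)
  expect_equal(cls$status, c("ns",     # |fc| == cut exactly
                             "down",
                             "ns",     # padj == cut exactly
                             "ns",     # missing padj
                             "up"))
  set.seed(83)
  rnd <- data.frame(chrom = "chr1", start = 0:199 * 100, end = 0:199 * 100 + 50,
                    log2fc = rnorm(200, 0, 1.5),
                    padj = ifelse(runif(200) < 0.1, NA, runif(200)))
  cls <- classify_differential_sites(rnd, fc_cut = 0.5, p_cut = 0.1)
  manual <- ifelse(!is.na(rnd$padj) & rnd$padj < 0.1 & abs(rnd$log2fc) > 0.5,
                   ifelse(rnd$log2fc < 0, "down", "up"), "ns")
  expect_identical(cls$status, manual)
})

test_that("classification is monotone in the thresholds", {
  set.seed(89)
  tab <- data.frame(chrom = "chr1", start = 0:499 * 100, end = 0:499 * 100 + 50,
                    log2fc = rnorm(500, 0, 2), padj = runif(500))
  n_sig <- function(fc, p)
    sum(classify_differential_sites(tab, fc, p)$status != "ns")
  expect_gte(n_sig(0.5, 0.05), n_sig(1, 0.05))
  expect_gte(n_sig(1, 0.05), n_sig(1, 0.01))
})

test_that("annotation flags deletion overlap, cis, EZH2 and compartment", {
  comp <- interval_set("chr1", c(0, 5e5), c(5e5, 1e6),
                       name = c("A", "B"))
  ezh2 <- interval_set("chr1", 2e5, 2.1e5)
  del <- interval_set("chr1", 1e5, 1.5e5)          # in compartment A
  tab <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                    start = c(1.2e5, 2.05e5, 6e5, 1e5),
                    end = c(1.3e5, 2.15e5, 6.1e5, 1.1e5),
                    log2fc = c(-3, -3, -3, -3), padj = rep(1e-4, 4))
  ann <- annotate_sites(classify_differential_sites(tab), del, ezh2, comp)
  expect_equal(ann$excluded, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(ann$cis, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(ann$ezh2_occupied, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(ann$same_compartment, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(ann$status[1], "down")   # excluded but still classified
  # deletion spanning a boundary warns and uses its midpoint compartment
  del2 <- interval_set("chr1", 4.9e5, 5.2e5)
  expect_warning(annotate_sites(classify_differential_sites(tab), del2,
                                ezh2, comp), "boundary")
})

test_that("annotation agrees with a nested-loop overlap oracle", {
  set.seed(97)
  comp <- interval_set("chr1", c(0, 4e4, 9e4), c(4e4, 9e4, 2e5),
                       name = c("A", "B", "A"))
  ezh2 <- random_intervals(30, chroms = "chr1", max_pos = 2e5, max_len = 2e3)
  del <- interval_set("chr1", 2e4, 3e4)
  tab <- data.frame(chrom = "chr1", start = 0:99 * 2000,
                    end = 0:99 * 2000 + 1000,
                    log2fc = rnorm(100), padj = runif(100))
  ann <- annotate_sites(classify_differential_sites(tab), del, ezh2, comp)
  expect_identical(ann$ezh2_occupied, oracle_overlap_count(tab, ezh2) > 0)
  expect_identical(ann$excluded, oracle_overlap_count(tab, del) > 0)
})

test_that("stratified Fisher test matches hypergeometric enumeration", {
  tab <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab))
  set.seed(101)
  for (rep in 1:20) {
    t2 <- matrix(rpois(4, 5), 2)
    if (sum(t2) == 0) next
    expect_equal(fisher.test(t2)$p.value, oracle_fisher_p(t2),
                 tolerance = 1e-12)
  }
})

test_that("a null table yields empty signal cells and Fisher p = 1", {
  comp <- interval_set("chr1", 0, 1e6, name = "A")
  tab <- data.frame(chrom = "chr1", start = 0:49 * 1e4, end = 0:49 * 1e4 + 5e3,
                    log2fc = rep(0.1, 50), padj = rep(0.9, 50))
  ann <- annotate_sites(classify_differential_sites(tab),
                        interval_set("chr1", 990000, 999999),
                        interval_set("chr1", 0, 1e4), comp)
  s <- stratified_summary(ann)
  expect_equal(sum(s$genomewide$fisher_table["down", ]), 0)
  expect_equal(s$genomewide$fisher_p, 1)
  expect_error(stratified_summary(classify_differential_sites(tab)),
               "annotate_sites")
})

test_that("planted EZH2-lacking same-compartment effects are recovered", {
  g <- synthetic_genome()
  arch <- make_tads_and_compartments(g, seed = 103)
  ezh2_peaks <- make_peaks(g, n = 150, width = 1e4, seed = 104)
  rand_sites <- make_peaks(g, n = 150, width = 5e3, seed = 105)
  sites <- interval_set(c(ezh2_peaks$chrom, rand_sites$chrom),
                        c(ezh2_peaks$start, rand_sites$start),
                        c(ezh2_peaks$end, rand_sites$end))
  del <- interval_set("chr1", 5e6, 5.2e6)
  made <- make_differential_table(sites, ezh2_peaks, arch$compartments, del,
                                  effect_size = 2, seed = 106)
  ann <- annotate_sites(classify_differential_sites(made$table),
                        del, ezh2_peaks, arch$compartments)
  truth <- made$truth$planted_effect
  down <- ann$status == "down"
  expect_gt(mean(down[truth]), 0.9)                      # sensitivity
  expect_lt(mean(down[ann$ezh2_occupied]), 0.1)          # FPR in occupied
  expect_lt(stratified_summary(ann)$genomewide$fisher_p, 0.01)
})

test_that("expression flags classify transcripts and mark memberships", {
  tab <- data.frame(gene = c("Pax3", "Wnt6", "Actb", "Hoxa2"),
                    log2fc = c(1.5, -4, 0.2, 1.2),
                    padj = c(0.04, 1e-5, 0.9, 0.2))
  fl <- expression_scatter_flags(tab, deleted_genes = "Wnt6",
                                 partner_genes = "Pax3")
  expect_equal(fl$class, c("higher", "lower", "ns", "ns"))
  expect_true(fl$is_partner[1]); expect_true(fl$is_deleted[2])
  expect_false(any(fl$is_partner[-1]))
  dup <- rbind(tab, tab[1, ])
  expect_error(expression_scatter_flags(dup), "unique")
})
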