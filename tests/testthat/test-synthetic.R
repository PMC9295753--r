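test_that("loop generation is deterministic and honors class counts", {
  g <- synthetic_genome()
  a <- make_loops(loop_spec(n_short = 50, n_long = 30), g, seed = 9)
  b <- make_loops(loop_spec(n_short = 50, n_long = 30), g, seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$loops$mark == "H3K27me3"), 30)

  none <- make_loops(loop_spec(n_short = 20, n_long = 0), g, seed = 2)
  expect_equal(sum(none$loops$mark == "H3K27me3"), 0)
  expect_equal(nrow(none$truth), 20)
  expect_false(any(none$truth$nucl_left | none$truth$nucl_right))
})

test_that("realized anchor distances equal the ground-truth manifest", {
  gen <- make_loops(loop_spec(n_short = 200, n_long = 200),
                    synthetic_genome(), seed = 4)
  expect_equal(anchor_distance(gen$loops, "midpoint"), gen$truth$distance)
  expect_true(all(gen$loops$end2 <=
                    synthetic_genome()$chrom_sizes[gen$loops$chrom]))
})

test_that("nucleation set contains exactly the flagged anchors", {
  gen <- make_loops(loop_spec(n_short = 100, n_long = 100),
                    synthetic_genome(), seed = 6)
  expect_equal(nrow(gen$nucleation),
               sum(gen$truth$nucl_left) + sum(gen$truth$nucl_right))
  flagged_left <- gen$truth$nucl_left
  expect_true(all(overlap_any(
    data.frame(chrom = gen$loops$chrom[flagged_left],
               start = gen$loops$start1[flagged_left],
               end = gen$loops$end1[flagged_left]),
    gen$nucleation)))
})

test_that("TADs tile each chromosome; compartments respect TAD boundaries", {
  g <- synthetic_genome(chrom_sizes = c(chrA = 1e7), tad_mean_size = 1e6)
  arch <- make_tads_and_compartments(g, seed = 3)
  tads <- arch$tads
  expect_gte(nrow(tads), 5); expect_lte(nrow(tads), 20)
  tads <- tads[order(tads$start), ]
  expect_equal(tads$start[1], 0)
  expect_equal(tads$end[nrow(tads)], 1e7)
  expect_equal(tads$start[-1], tads$end[-nrow(tads)])  # no gaps, no overlap

  comp <- arch$compartments[order(arch$compartments$start), ]
  boundaries <- c(tads$start, tads$end)
  expect_true(all(comp$start %in% boundaries))
  expect_true(all(comp$end %in% boundaries))
  expect_true(all(comp$name[-1] != comp$name[-nrow(comp)]))  # alternating
})

test_that("contact matrix stores a symmetric upper triangle with decay", {
  g <- synthetic_genome(chrom_sizes = c(chr1 = 2e7), bin_size = 1e5)
  cm <- make_contact_matrix(g, depth = 5e5, decay_exponent = 1, seed = 8)
  expect_true(all(cm$counts$bin1 <= cm$counts$bin2))
  expect_equal(cm$total, sum(cm$counts$count))

  # mean count decays with bin separation (coarse distance bands)
  d <- cm$counts$bin2 - cm$counts$bin1
  n <- nrow(cm$bins)
  band <- cut(d, c(-1, 0, 5, 20, 80, n))
  full <- tapply(cm$counts$count, band, sum)
  pairs_per_d <- n - 0:(n - 1)
  band_pairs <- tapply(pairs_per_d, cut(0:(n - 1), c(-1, 0, 5, 20, 80, n)), sum)
  expect_true(all(diff(as.numeric(full / band_pairs)) < 0))
})

test_that("planted dot dominates its neighborhood at high depth", {
  g <- synthetic_genome(chrom_sizes = c(chr1 = 5e6), bin_size = 1e5)
  dot <- loops("chr1", 1e6, 1.1e6, 3.5e6, 3.6e6)
  cm <- make_contact_matrix(g, dot, depth = 2e6, dot_enrichment = 8, seed = 2)
  full <- matrix(0, nrow(cm$bins), nrow(cm$bins))
  full[cbind(cm$counts$bin1, cm$counts$bin2)] <- cm$counts$count
  full[cbind(cm$counts$bin2, cm$counts$bin1)] <- cm$counts$count
  a <- 11; b <- 36  # bins holding the anchor midpoints
  nb <- full[a + (-5:5), b + (-5:5)]
  expect_equal(max(nb), full[a, b])
})

test_that("signal track geometry: background, bump integral, constancy", {
  g <- synthetic_genome(chrom_sizes = c(chr1 = 1e5))
  empty <- make_signal_track(interval_set(character(), numeric(), numeric()),
                             g, background = 0.7)
  expect_equal(nrow(empty), 1)
  expect_equal(empty$value, 0.7)

  pk <- interval_set("chr1", 40000, 50000)
  tr <- make_signal_track(pk, g, peak_height = 6, background = 0.5,
                          noise = FALSE)
  in_peak <- tr$start >= 40000 & tr$end <= 50000
  integral <- sum(tr$value[in_peak] * (tr$end - tr$start)[in_peak])
  expect_equal(integral, 0.5 * 10000 + 6 * 10000 / 2)
})

test_that("ORCA generator honors contact, radius and missingness contracts", {
  all_contact <- make_orca_traces(200, c("A", "B", "C"),
                                  data.frame(a = "A", b = "C", prob = 1),
                                  contact_radius = 150, missing_rate = 0,
                                  seed = 3)
  pd <- pair_distances(all_contact$traces, "A", "C")
  expect_true(all(pd$distances$distance_nm < 150))

  gone <- make_orca_traces(50, c("A", "B"), missing_rate = 1, seed = 1)
  expect_equal(nrow(gone$traces), 0)

  some <- make_orca_traces(2000, c("A", "B"),
                           data.frame(a = "A", b = "B", prob = 0.4),
                           missing_rate = 0, seed = 5)
  est <- contact_frequency(pair_distances(some$traces, "A", "B"))
  expect_lt(abs(est - 0.4), 3 * sqrt(0.4 * 0.6 / 2000))
})

test_that("differential generator: null calibration and occupancy gating", {
  g <- synthetic_genome()
  arch <- make_tads_and_compartments(g, seed = 2)
  sites <- make_peaks(g, n = 400, width = 5e3, seed = 3)
  ezh2 <- make_peaks(g, n = 100, width = 1e4, seed = 4)
  del <- interval_set("chr1", 1e6, 1.2e6)

  null <- make_differential_table(sites, ezh2, arch$compartments, del,
                                  effect_size = 0, seed = 6)
  n_sig <- sum(null$table$padj < 0.05)
  expect_lt(abs(n_sig - 0.05 * 400), 3 * sqrt(400 * 0.05 * 0.95) + 1)
  expect_false(any(null$truth$planted_effect))

  occupied <- make_differential_table(sites, sites, arch$compartments, del,
                                      effect_size = 2, seed = 7)
  expect_false(any(occupied$truth$planted_effect))
})
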