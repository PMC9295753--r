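flat_track <- function(value = 2, len = 1e6) {
  data.frame(chrom = "chr1", start = 0, end = len, value = value)
}

test_that("constant track yields a flat profile at the normalized level", {
  tr <- flat_track(2)
  centers <- interval_set("chr1", c(1e5, 3e5, 5e5), c(1e5, 3e5, 5e5) + 1)
  prof <- aggregate_profile(centers, tr, window_bp = 1e4, bin_bp = 50)
  depth <- 2 * 1e6
  expect_equal(length(prof$values), 200)
  expect_true(all(abs(prof$values - 2 / (depth / 1e6)) < 1e-12))
})

test_that("a delta bump lands in exactly one profile bin", {
  tr <- data.frame(chrom = "chr1",
                   start = c(0, 100000, 100050),
                   end = c(100000, 100050, 2e5),
                   value = c(0, 40, 0))
  center <- interval_set("chr1", 100000, 100100)  # midpoint 100050
  prof <- aggregate_profile(center, tr, window_bp = 1e4, bin_bp = 50,
                            library_depth = 1e6)
  nonzero <- which(prof$values > 0)
  expect_length(nonzero, 1)
  expect_equal(prof$offset[nonzero], -25)  # bin [100000,100050) is left of mid
})

test_that("doubling library depth halves the profile exactly", {
  tr <- flat_track(3)
  centers <- interval_set("chr1", 2e5, 2e5 + 1)
  p1 <- aggregate_profile(centers, tr, library_depth = 1e6)
  p2 <- aggregate_profile(centers, tr, library_depth = 2e6)
  expect_equal(p1$values, 2 * p2$values)
})

test_that("profile is invariant to fragmentation of track runs", {
  set.seed(41)
  edges <- sort(c(0, sample(1:999 * 1000, 30), 1e6))
  vals <- runif(length(edges) - 1, 0, 5)
  tr <- data.frame(chrom = "chr1", start = edges[-length(edges)],
                   end = edges[-1], value = vals)
  # split every run in two at its midpoint
  mids <- floor((tr$start + tr$end) / 2)
  frag <- rbind(data.frame(chrom = "chr1", start = tr$start, end = mids,
                           value = tr$value),
                data.frame(chrom = "chr1", start = mids, end = tr$end,
                           value = tr$value))
  frag <- frag[frag$end > frag$start, ]
  centers <- interval_set("chr1", c(1e5, 4e5, 9e5), c(1e5, 4e5, 9e5) + 1)
  expect_equal(aggregate_profile(centers, tr, library_depth = 1e6)$values,
               aggregate_profile(centers, frag, library_depth = 1e6)$values)
})

test_that("windows truncated at track ends keep the background level", {
  tr <- flat_track(4, len = 1e5)
  near_start <- interval_set("chr1", 1000, 1001)  # window [-4000, 6000)
  prof <- aggregate_profile(near_start, tr, window_bp = 1e4, bin_bp = 100,
                            library_depth = 1e6)
  covered <- prof$covered_bp > 0
  expect_true(all(abs(prof$values[covered] - 4) < 1e-12))
  expect_true(all(prof$values[!covered] == 0))
})

test_that("round trip: triangular bumps are recovered at their centers", {
  g <- synthetic_genome(chrom_sizes = c(chr1 = 2e6))
  peaks <- interval_set("chr1", c(5e5, 1.2e6), c(5e5 + 1e4, 1.2e6 + 1e4))
  tr <- make_signal_track(peaks, g, peak_height = 8, background = 0.5,
                          noise = FALSE)
  centers <- center_choice(peaks, mode = "anchor_midpoint")
  prof <- aggregate_profile(centers, tr, window_bp = 1e4, bin_bp = 500)
  scale <- prof$library_depth / 1e6
  # bin [ -500, 0 ) sits in the discretized triangle's 5th step:
  # background + height * (1 - 500/5000) = 0.5 + 7.2
  mid_bin <- length(prof$values) / 2
  expect_equal(prof$values[mid_bin] * scale, 7.7)
  # outermost bins sit in the first step: 0.5 + height * (1 - 4500/5000)
  edge_mean <- mean(prof$values[c(1, length(prof$values))]) * scale
  expect_equal(edge_mean, 1.3)
})

test_that("center choice matches a brute-force overlap oracle", {
  set.seed(43)
  x <- random_loops(40)
  anc <- anchors(x)
  peaks <- random_intervals(60, max_pos = 1.3e6, max_len = 5000)
  got <- center_choice(anc, peaks, "peak_in_anchor")
  want <- peaks[oracle_overlap_count(peaks, anc) > 0, ]
  expect_equal(got$start, floor((want$start + want$end) / 2))
  mids <- center_choice(anc, mode = "anchor_midpoint")
  expect_equal(nrow(mids), nrow(anc))
  none <- center_choice(anc, interval_set("chr9", 0, 10), "peak_in_anchor")
  expect_equal(nrow(none), 0)
})

test_that("loess at span 1 on linear data equals least squares", {
  set.seed(47)
  x <- sort(runif(40, 0, 10))
  y <- 2 * x + 1
  grid <- seq(1, 9, length.out = 11)
  fit <- loopscape:::loess_tricube(x, y, grid, span = 1)
  ols <- predict(lm(y ~ x), data.frame(x = grid))
  expect_lt(max(abs(fit - unname(ols))), 1e-6)
  const <- loopscape:::loess_tricube(x, rep(3, 40), grid, span = 0.4)
  expect_equal(const, rep(3, 11))
})

test_that("all-overlapping loops give a unit curve with zero-width CI", {
  set.seed(51)
  x <- random_loops(50, chroms = "chr1")
  everything <- interval_set("chr1", 0, 2e6)
  cv <- overlap_distance_curve(x, everything, n_boot = 20, seed = 2)
  expect_true(all(cv$fitted$fit == 1))
  expect_true(all(cv$fitted$upper - cv$fitted$lower == 0))
})

test_that("stepwise overlap probability yields a rising fitted curve", {
  set.seed(53)
  n <- 300
  d <- round(10^runif(n, 4.5, 6.5))
  s1 <- round(runif(n, 0, 1e7))
  x <- loops("chr1", s1, s1 + 1000, s1 + 1000 + d, s1 + 2000 + d)
  dist <- anchor_distance(x)
  p_hit <- ifelse(dist > 3e5, 0.9, 0.1)
  hit <- runif(n) < p_hit
  # peaks exactly on the anchors of "hit" loops, far offset otherwise
  peaks <- interval_set("chr1", ifelse(hit, x$start1, x$start1 + 2e7),
                        ifelse(hit, x$end1, x$end1 + 2e7))
  cv <- overlap_distance_curve(x, peaks, span = 0.6, n_boot = 30, seed = 3)
  low <- cv$fitted$fit[cv$fitted$distance < 2e5]
  high <- cv$fitted$fit[cv$fitted$distance > 5e5]
  expect_lt(max(low), 0.35)
  expect_gt(min(high), 0.65)
})

test_that("curves refuse to fit fewer than 10 points", {
  x <- random_loops(5, chroms = "chr1")
  expect_message(cv <- overlap_distance_curve(x, interval_set("chr1", 0, 1e7)),
                 "fewer than 10")
  expect_null(cv$fitted)
  expect_equal(nrow(cv$points), 5)
})
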