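# Brute-force oracles and random-instance builders shared across tests.
# Oracles are deliberately naive (nested loops over rows) so they stay
# independent of the package's sweep/containment implementations.

oracle_pair_overlap <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

oracle_overlap_count <- function(query, subject) {
  qc <- query$chrom; qs <- query$start; qe <- query$end
  sc <- subject$chrom; ss <- subject$start; se <- subject$end
  out <- integer(length(qc))
  for (i in seq_along(qc)) {
    hits <- 0L
    for (j in seq_along(sc))
      if (qc[i] == sc[j] && qs[i] < se[j] && ss[j] < qe[i]) hits <- hits + 1L
    out[i] <- hits
  }
  out
}

oracle_count_contained <- function(container, set) {
  cc <- container$chrom; cs <- container$start; ce <- container$end
  sc <- set$chrom; ss <- set$start; se <- set$end
  out <- integer(length(cc))
  for (i in seq_along(cc)) {
    hits <- 0L
    for (j in seq_along(sc))
      if (sc[j] == cc[i] && ss[j] >= cs[i] && se[j] <= ce[i]) hits <- hits + 1L
    out[i] <- hits
  }
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             max_pos = 1e5, max_len = 500) {
  start <- floor(runif(n, 0, max_pos))
  len <- floor(runif(n, 1, max_len))
  interval_set(sample(chroms, n, replace = TRUE), start, start + len)
}

random_loops <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                         max_width = 2000, max_gap = 2e5) {
  chrom <- sample(chroms, n, replace = TRUE)
  s1 <- floor(runif(n, 0, max_pos))
  w1 <- floor(runif(n, 1, max_width))
  gap <- floor(runif(n, 0, max_gap))
  w2 <- floor(runif(n, 1, max_width))
  loops(chrom, s1, s1 + w1, s1 + w1 + gap, s1 + w1 + gap + w2)
}

# Two-sided point-probability Fisher p for a 2x2 table, by direct
# hypergeometric enumeration.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating every assignment of pooled
# ranks to sample one (doubling rule, capped at 1).
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Us <- apply(combn(N, n1), 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(Us <= U_obs + 1e-9), mean(Us >= U_obs - 1e-9)))
}
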