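# Independent oracles, kept deliberately naive and separate from the
# package's own code paths.

# brute-force cumulative-difference statistic over the base order A<C<G<T
oracle_ks <- function(p, q) {
  best <- 0
  cp <- 0
  cq <- 0
  for (i in 1:4) {
    cp <- cp + p[i]
    cq <- cq + q[i]
    d <- abs(cp - cq)
    if (d > best) best <- d
  }
  best
}

# exhaustive genotype search: best diploid genotype by the naive statistic
oracle_best_genotype <- function(counts_f, e_f, counts_r, e_r, ref) {
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  bases <- c("A", "C", "G", "T")
  expect_dist <- function(gt, e) {
    q <- numeric(4)
    for (a in strsplit(gt, "")[[1]]) {
      for (b in 1:4) {
        q[b] <- q[b] + 0.5 * (if (bases[b] == a) 1 - e else e / 3)
      }
    }
    q
  }
  score <- sapply(gts, function(gt) {
    d_f <- oracle_ks(counts_f / sum(counts_f), expect_dist(gt, e_f))
    d_r <- oracle_ks(counts_r / sum(counts_r), expect_dist(gt, e_r))
    max(d_f, d_r)
  })
  nonref <- sapply(gts, function(gt)
    sum(strsplit(gt, "")[[1]] != ref))
  gts[order(score, nonref, gts)][1]
}

# plain mean + k * sample-SD cutoff
oracle_cutoff <- function(x, k = 3) mean(x) + k * sd(x)
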