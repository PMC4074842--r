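# window scan fixtures: fragments whose mates sit on chosen chromosomes
tx_fixture <- function(mate_chroms, starts = NULL, L = 10000L) {
  n <- length(mate_chroms)
  starts <- starts %||% seq(101L, by = 50L, length.out = n)
  mate_start <- ifelse(mate_chroms == "chr1", starts + 200L, 500L)
  make_records(starts = starts, inserts = rep(300L, n), L = L,
               mate_chrom = mate_chroms, mate_start = mate_start)
}

test_that("windows count totals, discordants and the highest hit", {
  # 10 fragments in one window: read1 mates 4x chr7, 2x chr9, 4x same
  rec <- tx_fixture(c(rep("chr7", 4), rep("chr9", 2), rep("chr1", 4)))
  w <- scan_windows(rec, tx_params())
  w1 <- w[w$chrom == "chr1" & w$start == 1, ]
  expect_equal(w1$total, 14) # 10 read1 + 4 proper-pair read2
  expect_equal(w1$discordant, 6)
  expect_equal(w1$hit_chrom, "chr7")
  expect_equal(w1$hit_count, 4)
  expect_equal(w1$proportion, 4 / 14)
  # counting conservation across all windows
  expect_equal(sum(w$total), nrow(rec$reads))
  expect_true(all(w$hit_count <= w$discordant & w$discordant <= w$total))
})

test_that("highest-hit ties break by reference order", {
  rec <- tx_fixture(c("chr9", "chr9", "chr7", "chr7", "chr1", "chr1"))
  # reference order of this fixture is alphabetical: chr1, chr7, chr9
  w <- scan_windows(rec, tx_params())
  expect_equal(w$hit_chrom[w$chrom == "chr1" & w$start == 1], "chr7")
})

test_that("outlier cutoff equals the direct mean + 3 SD computation", {
  mkw <- function(props) data.frame(
    chrom = "chr1", start = seq(1, by = 2000, length.out = length(props)),
    end = seq(2000, by = 2000, length.out = length(props)),
    total = 100L, discordant = as.integer(props * 100),
    hit_chrom = "chr2", hit_count = as.integer(props * 100),
    proportion = props)
  props <- c(rep(0.01, 99), 0.31)
  res <- outlier_cutoff(mkw(props), tx_params())
  expect_equal(res$cutoff, oracle_cutoff(props))
  expect_equal(res$mean, 0.013)
  # small arrays against the oracle
  for (x in list(c(0.1, 0.2), c(0, 0, 0.5), runif(7), c(0.2, 0.2, 0.2))) {
    expect_equal(outlier_cutoff(mkw(x), tx_params())$cutoff,
                 oracle_cutoff(x))
  }
  # all-equal proportions: cutoff = common value, nothing flagged
  eqw <- mkw(rep(0.2, 10))
  cut <- outlier_cutoff(eqw, tx_params())
  expect_equal(cut$cutoff, 0.2)
  rec <- tx_fixture(rep("chr7", 3))
  expect_equal(nrow(detect_translocations(eqw, cut, rec, tx_params())), 0)
  # single-window scopes yield no cutoff
  expect_message(one <- outlier_cutoff(mkw(0.5)[1, ], tx_params()),
                 "no calls")
  expect_true(is.na(one$cutoff))
})

test_that("detection gates on support and records read-span regions", {
  # an enriched window over a quiet, deep background: 600 proper
  # fragments across chr1 plus 12 discordant pairs whose mates cluster on
  # chr9 near 55,000
  n_bg <- 600L
  starts <- c(seq(101L, by = 80L, length.out = n_bg),
              seq(10401L, by = 60L, length.out = 12))
  mate_chroms <- c(rep("chr1", n_bg), rep("chr9", 12))
  mate_start <- c(seq(101L, by = 80L, length.out = n_bg) + 200L,
                  seq(55001L, by = 50L, length.out = 12))
  rec <- make_records(starts = starts, inserts = rep(300L, n_bg + 12),
                      L = 60000L, mate_chrom = mate_chroms,
                      mate_start = mate_start)
  w <- scan_windows(rec, tx_params())
  cut <- outlier_cutoff(w, tx_params())
  calls <- detect_translocations(w, cut, rec, tx_params())
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chrom_a, "chr1")
  expect_equal(calls$chrom_b, "chr9")
  expect_equal(calls$support, 12)
  expect_equal(calls$start_a, 10401L)
  expect_equal(calls$end_a, 10401L + 11L * 60L)
  # support below min_hit_reads suppresses the call
  strict <- tx_params(min_hit_reads = 20L)
  expect_equal(nrow(detect_translocations(w, cut, rec, strict)), 0)
})

test_that("normal overlap elimination honors the padding", {
  tcall <- data.frame(chrom_a = "chr1", start_a = 10000L, end_a = 12000L,
                      chrom_b = "chr5", start_b = 50000L, end_b = 51000L,
                      support = 10L, proportion = 0.1, zscore = 5,
                      somatic = NA)
  ncall_overlap <- data.frame(chrom_a = "chr1", start_a = 11000L,
                              end_a = 13000L, chrom_b = "chr5",
                              start_b = 90000L, end_b = 91000L,
                              support = 8L, proportion = 0.1, zscore = 4,
                              somatic = NA)
  expect_equal(nrow(subtract_normal(tcall, ncall_overlap, tx_params())), 0)
  # no normal call within padding: retained and flagged somatic
  far <- ncall_overlap
  far$start_a <- 20000L; far$end_a <- 21000L
  kept <- subtract_normal(tcall, far, tx_params())
  expect_equal(nrow(kept), 1)
  expect_true(kept$somatic)
  # a gap of 800 < 1000 bp of padding still eliminates
  near <- ncall_overlap
  near$start_a <- 12800L; near$end_a <- 13800L
  expect_equal(nrow(subtract_normal(tcall, near, tx_params())), 0)
})

test_that("uniform background yields no calls in seeded replicates", {
  chroms <- setNames(rep(100000L, 6), paste0("c", 1:6))
  n_calls <- vapply(1:10, function(i) {
    cfg <- sim_config(chromosomes = chroms, seed = 7000 + i)
    pair <- simulate_pair(cfg, simulate_reference(cfg),
                          with_sequences = FALSE)
    nrow(tx_detect(pair$tumor)$calls)
  }, numeric(1))
  expect_gte(mean(n_calls == 0), 0.95)
})

test_that("spiked events are recovered and germline events eliminated", {
  chroms <- c(chr1 = 300000L, chr2 = 300000L, chr3 = 300000L)
  cfg <- sim_config(chromosomes = chroms, seed = 55,
                    translocations = data.frame(
                      chrom_a = c("chr1", "chr2", "chr1"),
                      pos_a = c(100000L, 200000L, 250000L),
                      chrom_b = c("chr2", "chr3", "chr3"),
                      pos_b = c(150000L, 100000L, 50000L),
                      origin = c("somatic", "somatic", "germline")))
  pair <- simulate_pair(cfg, simulate_reference(cfg),
                        with_sequences = FALSE)
  res <- somatic_translocations(pair$tumor, pair$normal)
  tr <- pair$truth$translocations[
    pair$truth$translocations$origin == "somatic", ]
  rep <- evaluate_against_truth(list(translocations = res$calls),
                                pair$truth)
  expect_equal(rep$recall[rep$class == "tx"], 1)
  expect_equal(rep$precision[rep$class == "tx"], 1)
  # each breakpoint region within 2 kb of truth
  for (i in seq_len(nrow(tr))) {
    hit <- res$calls[res$calls$chrom_a == tr$chrom_a[i] &
                       abs(res$calls$start_a - tr$pos_a[i]) <= 2000, ]
    expect_gte(nrow(hit), 1)
    expect_true(any(abs(hit$start_b - tr$pos_b[i]) <= 2000))
  }
  # the germline event never appears in somatic output
  expect_false(any(res$calls$chrom_a == "chr1" &
                     abs(res$calls$start_a - 250000L) < 3000))
  expect_false(any(res$calls$chrom_b == "chr3" &
                     abs(res$calls$start_b - 50000L) < 3000 &
                     res$calls$chrom_a == "chr1"))
})
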