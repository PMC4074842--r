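test_that("insert model gives mean, sample SD and the 3-SD gate", {
  r <- make_records(starts = c(100L, 200L, 300L),
                    inserts = c(300L, 300L, 300L))
  m <- estimate_insert_model(r)
  expect_equal(m$mean, 300)
  expect_equal(m$sd, 0)
  expect_equal(m$max_accepted, 300)
  r2 <- make_records(starts = c(100L, 200L), inserts = c(290L, 310L))
  m2 <- estimate_insert_model(r2)
  expect_equal(m2$mean, 300)
  expect_equal(m2$sd, sqrt(200), tolerance = 1e-12)
  expect_equal(m2$max_accepted, 300 + 3 * sqrt(200), tolerance = 1e-12)
  one <- make_records(starts = 100L, inserts = 300L)
  expect_error(estimate_insert_model(one), "at least 2")
})

test_that("physical coverage spans inserts and respects the gate", {
  r <- make_records(starts = c(1001L, 2000L), inserts = c(300L, 300L),
                    L = 5000L)
  m <- structure(list(mean = 300, sd = 0, max_accepted = 300, n = 2),
                 class = "insert_size_model")
  cov <- physical_coverage(r, m)
  v <- as.integer(cov[["chr1"]])
  expect_equal(sum(v), 600) # conservation: sum of accepted inserts
  expect_true(all(v[1001:1300] == 1))
  expect_equal(v[1000], 0)
  expect_equal(v[1301], 0)
  # a fragment one bp over the gate contributes nothing
  r2 <- make_records(starts = c(1001L, 2000L), inserts = c(301L, 300L),
                     L = 5000L)
  cov2 <- physical_coverage(r2, m)
  expect_equal(sum(as.integer(cov2[["chr1"]])), 300)
  # overlapping pairs add
  r3 <- make_records(starts = c(1001L, 1001L), inserts = c(300L, 300L),
                     L = 5000L)
  expect_true(all(as.integer(physical_coverage(r3, m)[["chr1"]])[1001:1300]
                  == 2))
})

test_that("window means tile at the step and drop partial windows", {
  flat <- S4Vectors::Rle(10, 10000)
  w <- window_coverage(list(chr1 = flat), cnv_params())
  expect_true(all(w$coverage == 10))
  expect_equal(w$start, seq(1, 8001, by = 1000))
  expect_true(all(w$end - w$start + 1 == 2000))
  # half-covered window averages to half
  half <- S4Vectors::Rle(c(10, 0), c(1000, 1000))
  w2 <- window_coverage(list(chr1 = half), cnv_params())
  expect_equal(w2$coverage, 5)
  # chromosome shorter than the window yields nothing
  expect_message(
    w3 <- window_coverage(list(chr1 = S4Vectors::Rle(1, 1500)),
                          cnv_params()),
    "shorter")
  expect_equal(nrow(w3), 0)
})

test_that("median normalization and its degenerate cases", {
  expect_equal(normalize_windows(c(8, 8, 8, 8)), c(1, 1, 1, 1))
  expect_equal(normalize_windows(c(4, 8, 8, 16)), c(0.5, 1, 1, 2))
  expect_error(normalize_windows(c(0, 0)), "zero")
})

test_that("log2 ratios: identity, zero replacement, repeat masking", {
  grid <- data.frame(chrom = "chr1", start = seq(1, 9001, by = 1000))
  grid$end <- grid$start + 1999L
  mkw <- function(cov) cbind(grid, coverage = cov)
  # identity
  w <- log2_ratio_windows(mkw(rep(8, 10)), mkw(rep(8, 10)))
  expect_true(all(w$log2_ratio == 0))
  expect_false(any(w$masked))
  # tumor zero against normal 8 with equal normalization: log2(1/8) = -3
  tum <- c(rep(8, 9), 0)
  nor <- rep(8, 10)
  w2 <- log2_ratio_windows(mkw(tum), mkw(nor))
  expect_equal(w2$log2_ratio[10], -3)
  expect_true(all(is.finite(w2$log2_ratio[!w2$masked])))
  # germline window beyond 2^3 x median is masked, and only that one
  nor3 <- c(rep(8, 9), 8 * 2^3.4)
  w3 <- log2_ratio_windows(mkw(rep(8, 10)), mkw(nor3))
  expect_equal(which(w3$masked), 10)
  expect_true(is.na(w3$log2_ratio[10]))
  expect_identical(w3$masked, log2(w3$normal_norm) > 3)
  # mismatched grids are refused
  bad <- mkw(rep(8, 10)); bad$start[1] <- 2
  expect_error(log2_ratio_windows(bad, mkw(rep(8, 10))), "grid")
})

test_that("segment merging follows runs of same-direction windows", {
  mkwin <- function(ratios) {
    n <- length(ratios)
    data.frame(chrom = "chr1", start = seq(1, by = 1000, length.out = n),
               end = seq(2000, by = 1000, length.out = n),
               log2_ratio = ratios, masked = FALSE)
  }
  segs <- segment_calls(mkwin(c(0, 1.2, 1.2, 1.2, 1.2, 1.2, 0)))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_windows, 5)
  expect_equal(segs$direction, "gain")
  expect_equal(segs$mean_log2, 1.2)
  # alternating windows give singleton segments
  alt <- segment_calls(mkwin(c(1.2, 0, 1.2, 0, 1.2)))
  expect_equal(nrow(alt), 3)
  expect_true(all(alt$n_windows == 1))
  # all-neutral yields nothing; losses direction-checked
  expect_equal(nrow(segment_calls(mkwin(rep(0.2, 6)))), 0)
  expect_equal(segment_calls(mkwin(c(-1.4, -1.2)))$direction, "loss")
})

test_that("identical tumor and normal records give all-zero ratios", {
  pr <- small_pair(seed = 61, discordant_rate = 0)
  res <- cnv_scan(pr$normal, pr$normal)
  expect_true(all(abs(res$windows$log2_ratio[!res$windows$masked]) < 1e-12))
  expect_equal(nrow(res$segments), 0)
})

test_that("spiked gain and homozygous deletion are recovered in ratio", {
  chroms <- c(chr1 = 600000L, chr2 = 600000L)
  cfg <- sim_config(chromosomes = chroms, seed = 71, discordant_rate = 0,
                    cnv_segments = data.frame(
                      chrom = c("chr1", "chr2"),
                      start = c(200001L, 300001L),
                      end = c(240000L, 320000L),
                      ratio = c(2, 0)))
  ref <- simulate_reference(cfg)
  pair <- simulate_pair(cfg, ref, with_sequences = FALSE)
  res <- cnv_scan(pair$tumor, pair$normal)
  w <- res$windows
  expect_true(all(is.finite(w$log2_ratio[!w$masked])))
  gain <- w[w$chrom == "chr1" & w$start >= 202001 & w$end <= 238000, ]
  expect_lt(abs(mean(gain$log2_ratio) - 1), 0.25)
  del <- w[w$chrom == "chr2" & w$start >= 302001 & w$end <= 318000, ]
  expect_true(all(is.finite(del$log2_ratio)))
  expect_lte(mean(del$log2_ratio), -2)
  segs <- res$segments
  expect_true(any(segs$direction == "gain" & segs$chrom == "chr1"))
  expect_true(any(segs$direction == "loss" & segs$chrom == "chr2"))
})
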