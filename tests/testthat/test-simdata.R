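test_that("config validation enforces the declared invariants", {
  expect_error(sim_config(chromosomes = c(chr1 = 0L)), "positive")
  expect_error(sim_config(chromosomes = c(chr1 = 1000L),
                          discordant_rate = 0, cellularity = 0),
               "cellularity")
  expect_error(sim_config(chromosomes = c(chr1 = 1000L),
                          discordant_rate = 0, insert_sd = -1),
               "insert_sd")
  expect_error(sim_config(chromosomes = c(chr1 = 1000L),
                          discordant_rate = 0,
                          somatic_snvs = data.frame(chrom = "chr1",
                                                    pos = 2000L,
                                                    vaf = 0.5)),
               "outside")
  expect_error(sim_config(chromosomes = c(chr1 = 1000L),
                          discordant_rate = 0,
                          somatic_snvs = data.frame(chrom = "chrX",
                                                    pos = 10L, vaf = 0.5)),
               "undeclared")
  expect_error(sim_config(chromosomes = c(chr1 = 1000L)),
               "2 chromosomes")
  expect_error(sim_config(
    chromosomes = c(chr1 = 10000L), discordant_rate = 0,
    cnv_segments = data.frame(chrom = "chr1", start = c(1L, 500L),
                              end = c(1000L, 1500L), ratio = c(2, 2))),
    "overlap")
  expect_error(sim_config(
    chromosomes = c(chr1 = 10000L), discordant_rate = 0,
    translocations = data.frame(chrom_a = "chr1", pos_a = 100L,
                                chrom_b = "chr1", pos_b = 5000L)),
    "interchromosomal")
})

test_that("simulated references have declared lengths and are seeded", {
  cfg <- sim_config(chromosomes = c(chr1 = 1000L, chr2 = 500L),
                    discordant_rate = 0, seed = 3)
  ref <- simulate_reference(cfg)
  expect_equal(unname(Biostrings::width(ref)), c(1000L, 500L))
  expect_true(all(strsplit(as.character(ref[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  expect_identical(as.character(simulate_reference(cfg)),
                   as.character(ref))
  cfg2 <- sim_config(chromosomes = c(chr1 = 1000L, chr2 = 500L),
                     discordant_rate = 0, seed = 4)
  expect_false(identical(as.character(simulate_reference(cfg2)),
                         as.character(ref)))
})

test_that("identical config and seed reproduce identical records and truth", {
  mk <- function() small_pair(
    seed = 21,
    somatic_snvs = data.frame(chrom = "chr1", pos = 10000L, vaf = 0.5),
    somatic_indels = data.frame(chrom = "chr1", pos = 30000L, type = "del",
                                len = 2L, vaf = 0.5),
    translocations = data.frame(chrom_a = "chr1", pos_a = 50000L,
                                chrom_b = "chr2", pos_b = 20000L))
  a <- mk(); b <- mk()
  expect_identical(a$truth, b$truth)
  expect_identical(as.data.frame(a$tumor$fragments),
                   as.data.frame(b$tumor$fragments))
  expect_identical(as.data.frame(a$tumor$reads),
                   as.data.frame(b$tumor$reads))
  expect_identical(as.data.frame(a$normal$reads),
                   as.data.frame(b$normal$reads))
})

test_that("fragment placement hits the configured depth and insert model", {
  cfg <- sim_config(chromosomes = c(chr1 = 1000000L), normal_depth = 30,
                    tumor_depth = 30, discordant_rate = 0, seed = 9)
  ref <- simulate_reference(cfg)
  pair <- simulate_pair(cfg, ref, with_sequences = FALSE)
  fr <- pair$normal$fragments
  realized <- nrow(fr) * 2 * cfg$read_length / 1e6
  expect_lt(abs(realized - 30) / 30, 0.05)
  # insert moments within 3 standard errors
  n <- nrow(fr)
  expect_lt(abs(mean(fr$insert) - cfg$insert_mean),
            3 * cfg$insert_sd / sqrt(n))
  expect_lt(abs(sd(fr$insert) - cfg$insert_sd),
            3 * cfg$insert_sd / sqrt(2 * (n - 1)) + 0.5)
  expect_true(all(fr$insert >= 2 * cfg$read_length))
})

test_that("somatic allele fractions are diluted by cellularity", {
  # >= 50 copy-neutral SNVs at VAF 0.5, cellularity 0.6 -> mean alt
  # fraction near 0.3, within 3 standard errors
  chroms <- c(chr1 = 500000L)
  pos <- seq(5000L, 495000L, by = 8000L)
  cfg <- sim_config(chromosomes = chroms, cellularity = 0.6,
                    discordant_rate = 0, seed = 13,
                    somatic_snvs = data.frame(chrom = "chr1", pos = pos,
                                              vaf = 0.5))
  expect_gte(length(pos), 50)
  ref <- simulate_reference(cfg)
  pair <- simulate_pair(cfg, ref)
  pm <- pileup_from_records(pair$tumor, ref)
  tr <- pair$truth$snvs
  alt_i <- match(tr$alt, c("A", "C", "G", "T"))
  obs <- vapply(seq_len(nrow(tr)), function(i) {
    cnt <- pm$chroms[[tr$chrom[i]]]$counts[, tr$pos[i]]
    (cnt[alt_i[i]] + cnt[alt_i[i] + 4]) / sum(cnt)
  }, numeric(1))
  expected <- 0.5 * 0.6
  depth_each <- vapply(seq_len(nrow(tr)), function(i)
    sum(pm$chroms[[tr$chrom[i]]]$counts[, tr$pos[i]]), numeric(1))
  se <- sqrt(expected * (1 - expected) / sum(depth_each))
  expect_lt(abs(mean(obs) - expected), 3 * se + 0.01)
  # a germline-free normal: alt fraction ~ 0
  pm_n <- pileup_from_records(pair$normal, ref)
  obs_n <- vapply(seq_len(nrow(tr)), function(i) {
    cnt <- pm_n$chroms[[tr$chrom[i]]]$counts[, tr$pos[i]]
    (cnt[alt_i[i]] + cnt[alt_i[i] + 4]) / sum(cnt)
  }, numeric(1))
  expect_lt(mean(obs_n), 0.01)
})

test_that("a spiked het SNP is visible on both alleles at depth", {
  pr <- small_pair(seed = 31,
                   germline_snvs = data.frame(chrom = "chr1", pos = 25000L))
  pm <- pileup_from_records(pr$normal, pr$reference)
  tr <- pr$truth$snvs
  cnt <- pm$chroms[["chr1"]]$counts[, tr$pos[1]]
  pooled <- cnt[1:4] + cnt[5:8]
  ref_i <- match(tr$ref[1], c("A", "C", "G", "T"))
  alt_i <- match(tr$alt[1], c("A", "C", "G", "T"))
  expect_gt(pooled[ref_i], 0)
  expect_gt(pooled[alt_i], 0)
})

test_that("copy-ratio-zero segments carry no overlapping tumor fragment", {
  seg <- data.frame(chrom = "chr1", start = 20001L, end = 30000L, ratio = 0)
  pr <- small_pair(seed = 41, cnv_segments = seg)
  fr <- pr$tumor$fragments
  ov <- fr$chrom == "chr1" & fr$start <= seg$end &
    (fr$start + fr$insert - 1L) >= seg$start
  expect_equal(sum(ov), 0)
  # and the normal is untouched there
  frn <- pr$normal$fragments
  ovn <- frn$chrom == "chr1" & frn$start <= seg$end &
    (frn$start + frn$insert - 1L) >= seg$start
  expect_gt(sum(ovn), 0)
})

test_that("spiked translocations emit clustered discordant pairs", {
  tx <- data.frame(chrom_a = "chr1", pos_a = 40000L, chrom_b = "chr2",
                   pos_b = 10000L)
  pr <- small_pair(seed = 51, translocations = tx, discordant_rate = 0)
  fr <- pr$tumor$fragments
  disc <- fr[fr$proper == FALSE, ]
  expect_equal(nrow(disc), round(0.5 * 40)) # 0.5 x local depth
  expect_true(all(disc$chrom == "chr1" & disc$mate_chrom == "chr2"))
  expect_true(all(abs(disc$start - 40000L) <= 600))
  expect_true(all(disc$mate_start >= 10000L & disc$mate_start <= 10400L))
  # somatic origin: no discordant pairs in the normal
  expect_equal(sum(!pr$normal$fragments$proper), 0)
})
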