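test_that("zero-quality bases are trimmed, other bases untouched", {
  col <- make_column(c("A", "A", "G"), c(30, 0, 20),
                     c("A", "C"), c(15, 0))
  tr <- trim_zero_quality(col)
  expect_equal(tr$fwd$base, c("A", "G"))
  expect_equal(tr$fwd$qual, c(30, 20))
  expect_equal(tr$rev$base, "A")
  # identity on a clean column
  clean <- clean_column()
  expect_equal(trim_zero_quality(clean)$fwd, clean$fwd)
  # all-zero column empties out
  allz <- make_column(c("A", "A"), c(0, 0), "G", 0)
  expect_equal(nrow(trim_zero_quality(allz)$fwd), 0)
  expect_equal(nrow(trim_zero_quality(allz)$rev), 0)
})

test_that("locus error rate is the mean quality-implied probability", {
  expect_equal(locus_error_rate(rep(30, 5)), 0.001)
  expect_equal(locus_error_rate(c(10, 20)), 0.055)
  expect_error(locus_error_rate(integer(0)), "empty strand")
})

test_that("expected genotype distributions follow the diploid error model", {
  expect_equal(unname(expected_base_distribution("AA", 0)), c(1, 0, 0, 0))
  expect_equal(unname(expected_base_distribution("AG", 0)),
               c(0.5, 0, 0.5, 0))
  expect_equal(unname(expected_base_distribution("AA", 0.03)),
               c(0.97, 0.01, 0.01, 0.01))
  expect_equal(sum(expected_base_distribution("CT", 0.1)), 1)
  expect_error(expected_base_distribution("AN", 0), "A/C/G/T")
})

test_that("ks_distance matches hand values and rejects bad input", {
  expect_equal(ks_distance(c(0.5, 0, 0.5, 0), c(1, 0, 0, 0)), 0.5)
  p <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(ks_distance(p, p), 0)
  q <- unname(expected_base_distribution("AA", 0.01))
  expect_equal(ks_distance(c(0.8, 0, 0.2, 0), q),
               oracle_ks(c(0.8, 0, 0.2, 0), q))
  expect_error(ks_distance(c(0.5, 0.5, 0.5, 0.5), p), "probability")
})

test_that("ks_distance equals the brute-force oracle on an exhaustive grid", {
  # all discrete distributions with denominator 20 on a 4-letter alphabet
  combos <- expand.grid(a = 0:20, b = 0:20, c = 0:20)
  combos <- combos[combos$a + combos$b + combos$c <= 20, ]
  grid <- cbind(combos, d = 20 - rowSums(combos)) / 20
  expect_gte(nrow(grid), 1000)
  set.seed(42)
  probes <- grid[sample(nrow(grid), 25), ]
  for (j in seq_len(nrow(probes))) {
    q <- as.numeric(probes[j, ])
    d_pkg <- apply(grid, 1, function(p) ks_distance(as.numeric(p), q))
    d_ora <- apply(grid, 1, function(p) oracle_ks(as.numeric(p), q))
    expect_equal(d_pkg, d_ora)
    # symmetry on a subsample
    for (i in sample(nrow(grid), 10)) {
      p <- as.numeric(grid[i, ])
      expect_identical(ks_distance(p, q), ks_distance(q, p))
      expect_identical(ks_distance(p, q) == 0, all(p == q))
    }
  }
})

test_that("call_genotype recovers genotypes and demands trimmed input", {
  p <- snv_params("lenient")
  hom <- clean_column(n_ref_f = 10, n_ref_r = 10)
  g <- call_genotype(hom, p)
  expect_equal(g$genotype, "AA")
  expect_equal(g$status, "callable")
  expect_equal(g$genotype,
               oracle_best_genotype(c(10, 0, 0, 0), 0.001,
                                    c(10, 0, 0, 0), 0.001, "A"))
  het <- clean_column(n_ref_f = 6, n_alt_f = 6, n_ref_r = 6, n_alt_r = 6)
  g2 <- call_genotype(het, p)
  expect_equal(g2$genotype, "AG")
  expect_equal(g2$status, "callable")
  expect_equal(g2$genotype,
               oracle_best_genotype(c(6, 0, 6, 0), 0.001,
                                    c(6, 0, 6, 0), 0.001, "A"))
  untrimmed <- make_column("A", 0, "A", 30)
  expect_error(call_genotype(untrimmed, p), "trim")
})

test_that("a variant seen on one strand only is not called", {
  onesided <- make_column(rep("G", 12), rep(30, 12),
                          rep("A", 12), rep(30, 12), ref = "A")
  g <- call_genotype(onesided, snv_params("lenient"))
  expect_equal(g$status, "ambiguous")
  expect_false(identical(g$genotype, "GG"))
})

test_that("exact expected distributions return their genotype at distance 0", {
  for (gt in c("AA", "AC", "AG", "CT", "GT", "TT")) {
    al <- strsplit(gt, "")[[1]]
    mk <- function() {
      b <- c(rep(al[1], 10), rep(al[2], 10))
      data.frame(base = b, qual = rep(600, 20)) # error rate ~ 0
    }
    col <- pileup_column("chr1", 1L, "A", fwd = mk(), rev = mk())
    g <- call_genotype(col, snv_params("lenient"))
    expect_equal(g$genotype, gt)
    expect_lt(g$combined_dist, 1e-9)
  }
})

test_that("adding alt reads to both strands never reverts a variant call", {
  p <- snv_params("lenient")
  last_was_variant <- FALSE
  for (k in 0:12) {
    col <- clean_column(n_ref_f = 12, n_alt_f = k, n_ref_r = 12,
                        n_alt_r = k)
    g <- call_genotype(col, p)
    is_variant <- g$status == "callable" && grepl("G", g$genotype)
    if (last_was_variant) expect_true(is_variant)
    last_was_variant <- is_variant
  }
  expect_true(last_was_variant)
})

test_that("high-quality hom-ref gate applies depth, distance and fraction", {
  p <- snv_params("lenient")
  good <- clean_column(n_ref_f = 10, n_ref_r = 10)
  expect_true(is_high_quality_homref(call_genotype(good, p), good, p))
  shallow <- clean_column(n_ref_f = 2, n_ref_r = 2)
  expect_false(is_high_quality_homref(call_genotype(shallow, p), shallow, p))
  # 20 ref + 3 alt: fraction 0.13 > 0.02
  dirty <- clean_column(n_ref_f = 10, n_alt_f = 2, n_ref_r = 10,
                        n_alt_r = 1)
  expect_false(is_high_quality_homref(call_genotype(dirty, p), dirty, p))
})

test_that("tumor variant consensus needs both strands and pooled fraction", {
  p <- snv_params("lenient") # 2 per strand, fraction 0.05
  col <- clean_column(n_ref_f = 17, n_alt_f = 3, n_ref_r = 17, n_alt_r = 3)
  cons <- tumor_variant_consensus(col, p)
  expect_equal(cons$alt, "G")
  expect_equal(cons$fraction, 6 / 40)
  onesided <- clean_column(n_ref_f = 15, n_alt_f = 5, n_ref_r = 20,
                           n_alt_r = 0)
  expect_null(tumor_variant_consensus(onesided, p))
  expect_null(tumor_variant_consensus(clean_column(), p))
})

test_that("strict thresholds are uniformly no looser than lenient", {
  s <- snv_params("strict"); l <- snv_params("lenient")
  expect_gte(s$min_depth_total, l$min_depth_total)
  expect_gte(s$min_depth_strand, l$min_depth_strand)
  expect_lte(s$d_max, l$d_max)
  expect_gte(s$consensus_min_alt_per_strand, l$consensus_min_alt_per_strand)
  expect_gte(s$consensus_min_alt_fraction, l$consensus_min_alt_fraction)
})

test_that("somatic calling on columns enforces the matched-normal gate", {
  # somatic: tumor variant, clean deep normal
  t_col <- clean_column(n_ref_f = 14, n_alt_f = 6, n_ref_r = 14,
                        n_alt_r = 6)
  n_col <- clean_column(n_ref_f = 15, n_ref_r = 15)
  calls <- call_somatic_snvs(list(n_col), list(t_col), profile = "lenient")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$alt, "G")
  expect_equal(calls$profile, "lenient")
  # germline het normal blocks the call
  het_n <- clean_column(n_ref_f = 10, n_alt_f = 10, n_ref_r = 10,
                        n_alt_r = 10)
  expect_equal(nrow(call_somatic_snvs(list(het_n), list(t_col),
                                      profile = "lenient")), 0)
  # shallow normal blocks the call
  thin_n <- clean_column(n_ref_f = 2, n_ref_r = 1)
  expect_equal(nrow(call_somatic_snvs(list(thin_n), list(t_col),
                                      profile = "lenient")), 0)
  # profile provenance: strong variant fires both threshold sets
  both <- call_somatic_snvs(list(n_col), list(t_col), profile = "both")
  expect_equal(both$profile, "both")
})

test_that("matrix-based somatic calling agrees with the column path", {
  pr <- small_pair(seed = 19,
                   somatic_snvs = data.frame(chrom = "chr1",
                                             pos = c(20000L, 40000L),
                                             vaf = c(0.6, 0.9)),
                   germline_snvs = data.frame(chrom = "chr2", pos = 30000L))
  pm_n <- pileup_from_records(pr$normal, pr$reference)
  pm_t <- pileup_from_records(pr$tumor, pr$reference)
  calls <- call_somatic_snvs(pm_n, pm_t, profile = "both")
  tr <- pr$truth$snvs[pr$truth$snvs$origin == "somatic", ]
  expect_setequal(paste(calls$chrom, calls$pos), paste(tr$chrom, tr$pos))
  # same loci through the column interface
  cols_of <- function(records) {
    tmp <- tempfile(fileext = ".tsv")
    emit_pileups(records, pr$reference, tmp)
    tab <- read_pileups(tmp)
    tab <- tab[tab$chrom %in% tr$chrom & tab$pos %in% tr$pos, ]
    as_pileup_columns(tab)
  }
  col_calls <- call_somatic_snvs(cols_of(pr$normal), cols_of(pr$tumor),
                                 profile = "both")
  expect_equal(col_calls$pos, calls$pos)
  expect_equal(col_calls$alt, calls$alt)
  expect_equal(col_calls$t_alt_fwd, calls$t_alt_fwd)
  # strand rule: every somatic call has alt evidence on both strands
  expect_true(all(calls$t_alt_fwd > 0 & calls$t_alt_rev > 0))
})
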