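# small in-code fixtures shared across test files

make_column <- function(fwd_bases, fwd_quals, rev_bases, rev_quals,
                        ref = "A", chrom = "chr1", pos = 100L) {
  pileup_column(chrom, pos, ref,
                fwd = data.frame(base = fwd_bases, qual = fwd_quals,
                                 stringsAsFactors = FALSE),
                rev = data.frame(base = rev_bases, qual = rev_quals,
                                 stringsAsFactors = FALSE))
}

# a clean column: n_ref reference reads plus n_alt alt reads per strand
clean_column <- function(ref = "A", alt = "G", n_ref_f = 10, n_alt_f = 0,
                         n_ref_r = 10, n_alt_r = 0, qual = 30) {
  make_column(c(rep(ref, n_ref_f), rep(alt, n_alt_f)),
              rep(qual, n_ref_f + n_alt_f),
              c(rep(ref, n_ref_r), rep(alt, n_alt_r)),
              rep(qual, n_ref_r + n_alt_r),
              ref = ref)
}

# hand-built read_pairs with proper fragments only (no sequences)
make_records <- function(starts, inserts, chrom = "chr1", L = 10000L,
                         read_len = 100L, sample = "test",
                         mate_chrom = NULL, mate_start = NULL,
                         ops1 = NULL) {
  n <- length(starts)
  proper <- if (is.null(mate_chrom)) rep(TRUE, n) else mate_chrom == chrom
  mate_chrom <- mate_chrom %||% rep(chrom, n)
  mate_start <- mate_start %||% (starts + inserts - read_len)
  frags <- data.table::data.table(
    frag_id = seq_len(n), chrom = chrom, start = starts,
    insert = as.integer(inserts), proper = proper,
    mate_chrom = mate_chrom, mate_start = as.integer(mate_start))
  ops1 <- ops1 %||% rep("", n)
  r1 <- data.table::data.table(
    frag_id = seq_len(n), read = 1L, chrom = chrom, start = starts,
    strand = "+", mate_chrom = mate_chrom,
    mate_start = as.integer(mate_start), ops = ops1,
    span = read_len, cigar = paste0(read_len, "M"),
    seq = NA_character_, qual = NA_character_)
  r2 <- data.table::data.table(
    frag_id = seq_len(n), read = 2L, chrom = mate_chrom,
    start = as.integer(mate_start), strand = "-", mate_chrom = chrom,
    mate_start = starts, ops = "", span = read_len,
    cigar = paste0(read_len, "M"), seq = NA_character_,
    qual = NA_character_)
  reads <- rbind(r1, r2)
  data.table::setorder(reads, chrom, start, frag_id, read)
  cl <- setNames(rep(as.integer(L), length(unique(c(chrom, mate_chrom)))),
                 sort(unique(c(chrom, mate_chrom))))
  somaticpair:::new_read_pairs(frags, reads, cl, sample, read_len)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_pair <- function(seed = 7, ...) {
  cfg <- sim_config(chromosomes = c(chr1 = 60000L, chr2 = 60000L),
                    seed = seed, ...)
  ref <- simulate_reference(cfg)
  c(simulate_pair(cfg, ref), list(reference = ref, config = cfg))
}
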