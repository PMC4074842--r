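#' Write read-pair records as a coordinate-sorted SAM file
#'
#' Emits one SAM line per read with proper pair/mate flags, mate position and
#' signed template length, and a header naming every chromosome. Records must
#' arrive coordinate-sorted (non-decreasing start within each chromosome);
#' unsorted input or an undeclared chromosome is an error.
#'
#' @param records a `read_pairs` object with sequences
#'   (`simulate_pair(..., with_sequences = TRUE)`).
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
emit_alignments <- function(records, path) {
  reads <- records$reads
  cl <- records$chrom_lengths
  if (any(!reads$chrom %in% names(cl)))
    stop_config("read on a chromosome missing from the header")
  unsorted <- reads[, any(diff(start) < 0), by = chrom][V1 == TRUE]
  if (nrow(unsorted) > 0)
    stop_config("records are not coordinate-sorted (%s)", unsorted$chrom[1])

  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(cl), as.integer(cl)))
  r <- reads[order(factor(chrom, levels = names(cl)), start, frag_id, read)]
  frag <- records$fragments[match(r$frag_id, records$fragments$frag_id)]
  flag <- 1L +
    fifelse(frag$proper, 2L, 0L) +
    fifelse(r$strand == "-", 16L, 32L) +
    fifelse(r$read == 1L, 64L, 128L)
  tlen <- fifelse(frag$proper, fifelse(r$read == 1L, frag$insert,
                                       -frag$insert), 0L)
  seqf <- fifelse(is.na(r$seq), "*", r$seq)
  qualf <- fifelse(is.na(r$qual), "*", r$qual)
  lines <- sprintf("frag%d\t%d\t%s\t%d\t60\t%s\t%s\t%d\t%d\t%s\t%s",
                   r$frag_id, flag, r$chrom, r$start, r$cigar,
                   fifelse(r$mate_chrom == r$chrom, "=", r$mate_chrom),
                   r$mate_start, tlen, seqf, qualf)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, lines), con, sep = "\n")
  invisible(path)
}

#' Read a SAM/BAM file into read-pair records
#'
#' Parses alignments through Rsamtools (SAM input is converted with
#' [Rsamtools::asBam()] first), reconstructs fragments by pairing reads on
#' their name, and extracts per-read indel operations from the CIGARs.
#' Inserted sequences are recovered from the read sequence; deleted
#' sequences are recovered from `reference` when supplied.
#'
#' @param path SAM or BAM path.
#' @param sample sample label to attach.
#' @param reference optional `DNAStringSet` for deleted-base sequences.
#' @return A `read_pairs` object.
#' @export
read_sam_records <- function(path, sample = "sample", reference = NULL) {
  is_bam <- grepl("\\.bam$", path, ignore.case = TRUE)
  bam <- if (is_bam) path else
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "cigar", "mrnm", "mpos", "isize",
                                        "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(b$pos)
  if (n == 0) {
    empty <- data.table(frag_id = integer(0), chrom = character(0),
                        start = integer(0), insert = integer(0),
                        proper = logical(0), mate_chrom = character(0),
                        mate_start = integer(0))
    reads <- data.table(frag_id = integer(0), read = integer(0),
                        chrom = character(0), start = integer(0),
                        strand = character(0), mate_chrom = character(0),
                        mate_start = integer(0), ops = character(0),
                        span = integer(0), cigar = character(0),
                        seq = character(0), qual = character(0))
    return(new_read_pairs(empty, reads, hdr, sample, 0L))
  }
  flag <- b$flag
  reads <- data.table(
    qname = b$qname,
    read = fifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = as.character(b$rname), start = b$pos,
    strand = fifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    mate_chrom = fifelse(is.na(b$mrnm), as.character(b$rname),
                         as.character(b$mrnm)),
    mate_start = b$mpos,
    proper = bitwAnd(flag, 2L) > 0L,
    isize = b$isize,
    cigar = b$cigar,
    seq = as.character(b$seq), qual = as.character(b$qual))
  reads[, frag_id := as.integer(factor(qname, levels = unique(qname)))]
  read_len <- max(GenomicAlignments::cigarWidthAlongQuerySpace(reads$cigar))
  reads[, span := GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)]
  reads[, ops := cigar_ops_strings(cigar, start, seq, chrom, reference)]

  frags <- reads[read == 1L,
                 .(frag_id, chrom, start, insert = abs(isize), proper,
                   mate_chrom, mate_start)]
  frags[proper == FALSE, insert := 0L]
  # leftmost start for proper pairs where read2 is leftmost
  frags[proper == TRUE & mate_start < start, start := mate_start]
  setorder(frags, chrom, start)
  keep <- c("frag_id", "read", "chrom", "start", "strand", "mate_chrom",
            "mate_start", "ops", "span", "cigar", "seq", "qual")
  reads <- reads[, ..keep]
  setorder(reads, chrom, start, frag_id, read)
  new_read_pairs(frags, reads, hdr, sample, read_len)
}

# per-read ";"-joined "pos:type:len:seq" strings from CIGARs
cigar_ops_strings <- function(cigar, start, seq, chrom, reference = NULL) {
  out <- character(length(cigar))
  gapped <- grep("[ID]", cigar)
  if (!length(gapped)) return(out)
  refr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar[gapped], ops = c("I", "D"), pos = start[gapped], with.ops = TRUE)
  qryr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cigar[gapped], ops = c("I", "D"), with.ops = TRUE)
  for (k in seq_along(gapped)) {
    i <- gapped[k]
    rr <- refr[[k]]
    qr <- qryr[[k]]
    if (length(rr) == 0) next
    opn <- names(rr)
    parts <- character(length(rr))
    for (j in seq_along(rr)) {
      if (opn[j] == "D") {
        p0 <- IRanges::start(rr)[j]
        l <- IRanges::width(rr)[j]
        sq <- if (!is.null(reference))
          ref_base_at(reference, chrom[i], p0, l) else ""
        parts[j] <- sprintf("%d:del:%d:%s", p0, l, sq)
      } else {
        # insertion recorded after the preceding reference base
        p0 <- IRanges::start(rr)[j] - 1L
        l <- IRanges::width(qr)[j]
        sq <- if (!is.na(seq[i]) && seq[i] != "*")
          substr(seq[i], IRanges::start(qr)[j], IRanges::end(qr)[j]) else ""
        parts[j] <- sprintf("%d:ins:%d:%s", p0, l, sq)
      }
    }
    out[i] <- paste(parts, collapse = ";")
  }
  out
}
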