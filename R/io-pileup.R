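# reference positions consumed by each read base (NA for inserted bases)
refpos_of_read <- function(start, cigar) {
  if (grepl("^\\d+M$", cigar)) {
    rl <- as.integer(sub("M", "", cigar))
    return(seq.int(start, start + rl - 1L))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("\\d+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  out <- integer(0)
  p <- start
  for (j in seq_along(ops)) {
    if (ops[j] %in% c("M", "=", "X")) {
      out <- c(out, seq.int(p, p + lens[j] - 1L))
      p <- p + lens[j]
    } else if (ops[j] %in% c("D", "N")) {
      p <- p + lens[j]
    } else if (ops[j] %in% c("I", "S")) {
      out <- c(out, rep(NA_integer_, lens[j]))
    }
  }
  out
}

#' Write per-locus pileups as a tab-delimited table
#'
#' One row per covered locus: chromosome, 1-based position, reference base,
#' then the forward-strand base string and phred+33 quality string followed
#' by the reverse-strand pair. Empty strands are written as `*`. The table
#' contains the raw pileup including zero-quality bases; trimming happens in
#' the caller ([trim_zero_quality()]), not here.
#'
#' @param records a `read_pairs` object with sequences.
#' @param reference `DNAStringSet` the records align to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
emit_pileups <- function(records, reference, path) {
  reads <- records$reads
  if (nrow(reads) > 0 && anyNA(reads$seq))
    stop_config("records carry no sequences; regenerate with sequences")
  cl <- records$chrom_lengths
  if (any(!reads$chrom %in% names(cl)))
    stop_config("read on a chromosome missing from the reference")
  unsorted <- reads[, any(diff(start) < 0), by = chrom][V1 == TRUE]
  if (nrow(unsorted) > 0) stop_config("records are not coordinate-sorted")

  out <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    chrom <- names(cl)[ci]
    r <- reads[chrom, on = "chrom", nomatch = NULL]
    if (nrow(r) == 0) next
    rl <- nchar(r$seq)
    simple <- grepl("^\\d+M$", r$cigar)
    pos_list <- vector("list", nrow(r))
    pos_list[simple] <- lapply(which(simple), function(i)
      seq.int(r$start[i], r$start[i] + rl[i] - 1L))
    for (i in which(!simple))
      pos_list[[i]] <- refpos_of_read(r$start[i], r$cigar[i])
    dt <- data.table(
      pos = unlist(pos_list),
      base = unlist(strsplit(r$seq, "", fixed = TRUE)),
      qv = unlist(strsplit(r$qual, "", fixed = TRUE)),
      strand = rep(r$strand, rl))
    dt <- dt[!is.na(pos)]
    agg <- dt[, .(bases = paste(base, collapse = ""),
                  quals = paste(qv, collapse = "")), by = .(pos, strand)]
    wide <- data.table(pos = sort(unique(agg$pos)))
    f <- agg[strand == "+"][wide, on = "pos"]
    rv <- agg[strand == "-"][wide, on = "pos"]
    refb <- strsplit(as.character(reference[[chrom]]), "")[[1]]
    out[[ci]] <- data.table(
      chrom = chrom, pos = wide$pos, ref = refb[wide$pos],
      fwd_bases = fifelse(is.na(f$bases), "*", f$bases),
      fwd_quals = fifelse(is.na(f$quals), "*", f$quals),
      rev_bases = fifelse(is.na(rv$bases), "*", rv$bases),
      rev_quals = fifelse(is.na(rv$quals), "*", rv$quals))
  }
  tab <- rbindlist(out)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("#chrom", "pos", "ref", "fwd_bases", "fwd_quals",
                     "rev_bases", "rev_quals"), collapse = "\t"), con)
  if (nrow(tab) > 0) {
    writeLines(do.call(paste, c(as.list(tab), sep = "\t")), con)
  }
  invisible(path)
}

#' Read a pileup table written by [emit_pileups()]
#'
#' @param path pileup TSV path.
#' @return A data.frame with one row per locus.
#' @export
read_pileups <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "character",
                                  "character", "character", "character",
                                  "character"),
                   comment.char = "", check.names = FALSE)
  names(df) <- c("chrom", "pos", "ref", "fwd_bases", "fwd_quals",
                 "rev_bases", "rev_quals")
  df
}

#' Convert pileup-table rows into pileup columns
#'
#' @param tab a data.frame from [read_pileups()].
#' @return A list of [pileup_column()] objects.
#' @export
as_pileup_columns <- function(tab) {
  lapply(seq_len(nrow(tab)), function(i) {
    decode <- function(bs, qs) {
      if (bs == "*") return(data.frame(base = character(0),
                                       qual = integer(0)))
      data.frame(base = strsplit(bs, "")[[1]],
                 qual = utf8ToInt(qs) - 33L, stringsAsFactors = FALSE)
    }
    pileup_column(tab$chrom[i], tab$pos[i], tab$ref[i],
                  fwd = decode(tab$fwd_bases[i], tab$fwd_quals[i]),
                  rev = decode(tab$rev_bases[i], tab$rev_quals[i]))
  })
}

#' Genome-wide pileup summary matrices
#'
#' Accumulates, per chromosome, per-strand base counts and summed
#' quality-implied error probabilities over every locus. Zero-quality bases
#' are trimmed during accumulation, so downstream genotype comparisons see
#' trimmed pileups; these counts are sufficient statistics for the
#' KS-distance caller (empirical base distribution plus mean error rate).
#'
#' @param records a `read_pairs` object with sequences.
#' @param reference `DNAStringSet` the records align to.
#' @return An object of class `pileup_matrix`.
#' @export
pileup_from_records <- function(records, reference) {
  reads <- records$reads
  if (nrow(reads) > 0 && anyNA(reads$seq))
    stop_config("records carry no sequences; regenerate with sequences")
  cl <- chrom_lengths_of(reference)
  chroms <- list()
  for (chrom in names(cl)) {
    r <- reads[chrom, on = "chrom", nomatch = NULL]
    res <- cpp_pileup_counts(r$start - 1L,
                             as.integer(r$strand == "-"),
                             r$seq, r$qual, r$cigar, as.integer(cl[[chrom]]))
    chroms[[chrom]] <- res
  }
  structure(list(chroms = chroms, chrom_lengths = cl, reference = reference,
                 sample = records$sample),
            class = "pileup_matrix")
}

#' @export
print.pileup_matrix <- function(x, ...) {
  cat("pileup_matrix [", x$sample, "]: ", length(x$chroms),
      " chromosome(s), ", sum(x$chrom_lengths), " bp\n", sep = "")
  invisible(x)
}

# counts (4 per strand) and error sums at one locus of a pileup_matrix
matrix_column <- function(pm, chrom, pos) {
  m <- pm$chroms[[chrom]]
  counts <- m$counts[, pos]
  list(cf = counts[1:4], cr = counts[5:8],
       ef = m$errsum[1, pos], er = m$errsum[2, pos])
}
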