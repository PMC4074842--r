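#' Read-pair records
#'
#' The substrate of every detector: one row per sequenced fragment
#' (`$fragments`: leftmost start, outer insert span, mate chromosome,
#' proper-pair flag) and one row per aligned read (`$reads`: position,
#' strand, CIGAR, indel operations, and optionally sequence/quality).
#' Coordinates are 1-based.
#'
#' @param fragments,reads data.tables as produced by the simulator or the
#'   SAM reader.
#' @param chrom_lengths named chromosome-length vector.
#' @param sample sample label.
#' @param read_length read length in bp.
#' @return An object of class `read_pairs`.
#' @keywords internal
new_read_pairs <- function(fragments, reads, chrom_lengths, sample,
                           read_length) {
  structure(list(fragments = fragments, reads = reads,
                 chrom_lengths = chrom_lengths, sample = sample,
                 read_length = as.integer(read_length)),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat("read_pairs [", x$sample, "]: ", nrow(x$fragments), " fragments, ",
      nrow(x$reads), " reads, ", length(x$chrom_lengths),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Subset read pairs by fragment
#' @param x a `read_pairs` object.
#' @param frag_ids fragment ids to keep.
#' @return A `read_pairs` object restricted to those fragments.
#' @keywords internal
subset_fragments <- function(x, frag_ids) {
  new_read_pairs(x$fragments[x$fragments$frag_id %in% frag_ids],
                 x$reads[x$reads$frag_id %in% frag_ids],
                 x$chrom_lengths, x$sample, x$read_length)
}

# parse ";"-joined "pos:type:len:seq" op strings into a long table
parse_ops <- function(reads) {
  has <- which(nzchar(reads$ops))
  if (!length(has)) {
    return(data.table(ridx = integer(0), chrom = character(0),
                      pos = integer(0), type = character(0),
                      len = integer(0), seq = character(0)))
  }
  parts <- strsplit(reads$ops[has], ";", fixed = TRUE)
  n_each <- lengths(parts)
  flat <- strsplit(unlist(parts), ":", fixed = TRUE)
  m <- matrix(unlist(lapply(flat, function(p) {
    if (length(p) == 3) c(p, "") else p
  })), ncol = 4, byrow = TRUE)
  data.table(ridx = rep(has, n_each),
             chrom = rep(reads$chrom[has], n_each),
             pos = as.integer(m[, 1]), type = m[, 2],
             len = as.integer(m[, 3]), seq = m[, 4])
}
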