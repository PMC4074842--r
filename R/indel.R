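#' Somatic indel parameters
#'
#' @param insert_min,insert_max inclusive insert-size interval (bp) a tumor
#'   fragment must fall in to contribute indel evidence.
#' @param flank bp examined on each side of a candidate in the normal.
#' @param min_tumor_support minimum tumor reads sharing an identical indel.
#' @param min_normal_depth minimum normal reads overlapping the flanked
#'   region for a confident somatic label.
#' @param max_normal_indel_reads maximum normal indel-bearing reads allowed
#'   in the flanked region of a somatic indel (0: none).
#' @return An object of class `indel_params`.
#' @export
indel_params <- function(insert_min = 50L, insert_max = 500L, flank = 5L,
                         min_tumor_support = 3L, min_normal_depth = 8L,
                         max_normal_indel_reads = 0L) {
  if (insert_min > insert_max) stop_config("insert_min > insert_max")
  if (flank < 0 || min_tumor_support < 0 || min_normal_depth < 0 ||
      max_normal_indel_reads < 0)
    stop_config("indel thresholds must be >= 0")
  structure(list(insert_min = as.integer(insert_min),
                 insert_max = as.integer(insert_max),
                 flank = as.integer(flank),
                 min_tumor_support = as.integer(min_tumor_support),
                 min_normal_depth = as.integer(min_normal_depth),
                 max_normal_indel_reads = as.integer(max_normal_indel_reads)),
            class = "indel_params")
}

#' Filter read pairs by insert size
#'
#' Retains exactly the fragments whose absolute insert length lies inside
#' the inclusive `[insert_min, insert_max]` interval (the first step of the
#' two-step somatic indel strategy); order is preserved and the operation is
#' idempotent.
#'
#' @param records a `read_pairs` object.
#' @param params an [indel_params()].
#' @return The filtered `read_pairs` object.
#' @export
filter_by_insert <- function(records, params = indel_params()) {
  fr <- records$fragments
  keep <- fr$frag_id[abs(fr$insert) >= params$insert_min &
                       abs(fr$insert) <= params$insert_max]
  subset_fragments(records, keep)
}

#' Collect indel candidates from gapped tumor alignments
#'
#' Identical indel operations — same chromosome, position, type, length and
#' sequence — are grouped across reads; a group becomes a candidate when its
#' support reaches `min_tumor_support`. Coordinates are 1-based: a deletion
#' spans `[start, start + len - 1]` on the reference; an insertion sits
#' after `start` (point footprint).
#'
#' @param records a `read_pairs` object (typically after
#'   [filter_by_insert()]).
#' @param params an [indel_params()].
#' @return A data.frame of candidates with `tumor_support`.
#' @export
collect_indel_candidates <- function(records, params = indel_params()) {
  ops <- parse_ops(records$reads)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), type = character(0),
                      len = integer(0), seq = character(0),
                      tumor_support = integer(0), stringsAsFactors = FALSE)
  if (nrow(ops) == 0) return(empty)
  grp <- ops[, .(tumor_support = .N), by = .(chrom, pos, type, len, seq)]
  grp <- grp[tumor_support >= params$min_tumor_support]
  if (nrow(grp) == 0) return(empty)
  grp[, `:=`(start = pos,
             end = fifelse(type == "del", pos + len - 1L, pos))]
  setorder(grp, chrom, start)
  out <- grp[, .(chrom, start, end, type, len, seq, tumor_support)]
  setDF(out)
  out
}

# shared region test machinery: returns per-candidate normal overlap depth
# and indel-bearing read counts
normal_region_counts <- function(candidates, normal, params) {
  n <- nrow(candidates)
  depth <- integer(n)
  indel_reads <- integer(n)
  reads <- normal$reads
  ops <- parse_ops(reads)
  cl <- normal$chrom_lengths
  for (chrom_name in unique(candidates$chrom)) {
    ci <- which(candidates$chrom == chrom_name)
    L <- cl[[chrom_name]] %||% Inf
    r0 <- pmax(1L, candidates$start[ci] - params$flank)
    r1 <- pmin(as.integer(L), candidates$end[ci] + params$flank)
    regions <- IRanges::IRanges(start = r0, end = r1)
    r <- reads[chrom == chrom_name]
    if (nrow(r) > 0) {
      spans <- IRanges::IRanges(start = r$start,
                                end = r$start + r$span - 1L)
      depth[ci] <- IRanges::countOverlaps(regions, spans)
      o <- ops[chrom == chrom_name]
      if (nrow(o) > 0) {
        op_rng <- IRanges::IRanges(
          start = o$pos,
          end = fifelse(o$type == "del", o$pos + o$len - 1L, o$pos))
        hits <- IRanges::findOverlaps(regions, op_rng)
        # count distinct reads, not distinct ops
        if (length(hits) > 0) {
          dt <- data.table(q = S4Vectors::queryHits(hits),
                           ridx = o$ridx[S4Vectors::subjectHits(hits)])
          cnt <- unique(dt)[, .N, by = q]
          indel_reads[ci[cnt$q]] <- cnt$N
        }
      }
    }
  }
  list(depth = depth, indel_reads = indel_reads)
}

status_from_counts <- function(depth, indel_reads, params) {
  ifelse(indel_reads > params$max_normal_indel_reads, "germline_or_artifact",
         ifelse(depth >= params$min_normal_depth, "somatic",
                "low_normal_coverage"))
}

#' Test one indel candidate against the matched normal
#'
#' Examines the region from `flank` bp upstream of the candidate start to
#' `flank` bp downstream of its end in the normal sample (intersected with
#' the chromosome). The candidate is `somatic` only if no more than
#' `max_normal_indel_reads` normal reads carry an indel operation
#' intersecting the region *and* at least `min_normal_depth` normal reads
#' overlap it; indel evidence in the normal yields `germline_or_artifact`,
#' and a clean but shallow region yields `low_normal_coverage`.
#'
#' @param candidate one row of [collect_indel_candidates()] output (or a
#'   list with `chrom`, `start`, `end`).
#' @param normal the normal-sample `read_pairs`.
#' @param params an [indel_params()].
#' @return The status string.
#' @export
normal_region_test <- function(candidate, normal, params = indel_params()) {
  cand <- as.data.frame(as.list(candidate)[c("chrom", "start", "end")],
                        stringsAsFactors = FALSE)
  cand$start <- as.integer(cand$start); cand$end <- as.integer(cand$end)
  cnt <- normal_region_counts(cand, normal, params)
  status_from_counts(cnt$depth, cnt$indel_reads, params)
}

#' Two-step somatic indel calling on a matched pair
#'
#' Step 1 removes tumor fragments with inserts outside
#' `[insert_min, insert_max]` and collects identical-indel candidates from
#' the surviving gapped reads; step 2 applies the flanked normal-region
#' test to each candidate. All candidates are returned with their status;
#' the somatic subset is `status == "somatic"`.
#'
#' @param tumor,normal `read_pairs` objects on the same reference.
#' @param params an [indel_params()].
#' @return A data.frame of candidates with `tumor_support`,
#'   `normal_depth`, `normal_indel_reads` and `status`.
#' @export
call_somatic_indels <- function(tumor, normal, params = indel_params()) {
  if (!identical(tumor$chrom_lengths, normal$chrom_lengths))
    stop_config("tumor and normal records disagree on the reference")
  filtered <- filter_by_insert(tumor, params)
  cands <- collect_indel_candidates(filtered, params)
  if (nrow(cands) == 0) {
    cands$normal_depth <- integer(0)
    cands$normal_indel_reads <- integer(0)
    cands$status <- character(0)
    return(cands)
  }
  cnt <- normal_region_counts(cands, normal, params)
  cands$normal_depth <- cnt$depth
  cands$normal_indel_reads <- cnt$indel_reads
  cands$status <- status_from_counts(cnt$depth, cnt$indel_reads, params)
  cands
}
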