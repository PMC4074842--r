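# Plain-text writers for the standard formats the pipeline emits. All
# writers are deterministic byte-for-byte given the same inputs: fixed
# number formatting, no timestamps. VCF positions are 1-based; BED, BEDPE
# and BedGraph intervals are converted to 0-based half-open on output.

fmt_num <- function(x, digits = 6) {
  as.character(signif(x, digits))
}

write_lines_atomic <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

vcf_header <- function(contigs, info_lines = character(0),
                       format_lines = character(0),
                       samples = character(0)) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  c("##fileformat=VCFv4.2",
    "##source=somaticpair",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    info_lines, format_lines,
    paste(cols, collapse = "\t"))
}

#' Write somatic SNV calls as VCF v4.2
#'
#' Per-strand tumor depths and alt counts go into the TUMOR sample FORMAT
#' fields; the normal KS distance, depth and the threshold-profile
#' provenance go into INFO.
#'
#' @param calls a [call_somatic_snvs()] data.frame.
#' @param path output path.
#' @param contigs named chromosome-length vector.
#' @return `path`, invisibly.
#' @export
write_vcf_snvs <- function(calls, path, contigs) {
  hdr <- vcf_header(
    contigs,
    info_lines = c(
      '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic event">',
      '##INFO=<ID=KSN,Number=1,Type=Float,Description="Normal combined KS distance">',
      '##INFO=<ID=NDP,Number=1,Type=Integer,Description="Normal depth">',
      '##INFO=<ID=PROFILE,Number=1,Type=String,Description="Threshold profile provenance">'),
    format_lines = c(
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
      '##FORMAT=<ID=ADF,Number=1,Type=Integer,Description="Alt reads, forward strand">',
      '##FORMAT=<ID=ADR,Number=1,Type=Integer,Description="Alt reads, reverse strand">',
      '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Alt fraction">'),
    samples = "TUMOR")
  rows <- if (nrow(calls) == 0) character(0) else sprintf(
    "%s\t%d\t.\t%s\t%s\t.\tPASS\tSOMATIC;KSN=%s;NDP=%d;PROFILE=%s\tDP:ADF:ADR:AF\t%d:%d:%d:%s",
    calls$chrom, calls$pos, calls$ref, calls$alt,
    fmt_num(calls$n_dist), calls$n_depth, calls$profile,
    calls$t_depth_fwd + calls$t_depth_rev, calls$t_alt_fwd,
    calls$t_alt_rev, fmt_num(calls$alt_fraction))
  write_lines_atomic(c(hdr, rows), path)
}

indel_vcf_alleles <- function(df, reference) {
  # anchored VCF representation: POS is the base before the event
  n <- nrow(df)
  pos <- integer(n); ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    if (df$type[i] == "del") {
      pos[i] <- df$start[i] - 1L
      anchor <- ref_base_at(reference, df$chrom[i], pos[i])
      ref[i] <- paste0(anchor, df$seq[i])
      alt[i] <- anchor
    } else {
      pos[i] <- df$start[i]
      anchor <- ref_base_at(reference, df$chrom[i], pos[i])
      ref[i] <- anchor
      alt[i] <- paste0(anchor, df$seq[i])
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Write indel candidates as VCF v4.2
#'
#' The somatic/germline_or_artifact/low_normal_coverage status goes into
#' FILTER (`PASS` for somatic), supports into the sample columns.
#'
#' @param candidates a [call_somatic_indels()] data.frame.
#' @param path output path.
#' @param reference `DNAStringSet` (for anchor bases).
#' @return `path`, invisibly.
#' @export
write_vcf_indels <- function(candidates, path, reference) {
  contigs <- chrom_lengths_of(reference)
  hdr <- vcf_header(
    contigs,
    info_lines = c(
      '##INFO=<ID=SOMATIC,Number=0,Type=Flag,Description="Somatic event">',
      '##INFO=<ID=TYPE,Number=1,Type=String,Description="ins or del">',
      '##INFO=<ID=STATUS,Number=1,Type=String,Description="Normal-region test status">'),
    format_lines = c(
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
      '##FORMAT=<ID=SU,Number=1,Type=Integer,Description="Supporting reads">'),
    samples = c("NORMAL", "TUMOR"))
  rows <- character(0)
  if (nrow(candidates) > 0) {
    al <- indel_vcf_alleles(candidates, reference)
    filt <- ifelse(candidates$status == "somatic", "PASS",
                   candidates$status)
    info <- sprintf("%sTYPE=%s;STATUS=%s",
                    ifelse(candidates$status == "somatic", "SOMATIC;", ""),
                    candidates$type, candidates$status)
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s\tDP:SU\t%d:%d\t.:%d",
                    candidates$chrom, al$pos, al$ref, al$alt, filt, info,
                    candidates$normal_depth, candidates$normal_indel_reads,
                    candidates$tumor_support)
  }
  write_lines_atomic(c(hdr, rows), path)
}

#' Write per-window log2 ratios as BedGraph
#'
#' Masked windows are skipped (they carry no ratio).
#'
#' @param windows the [log2_ratio_windows()] output.
#' @param path output path.
#' @param name track name.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, path, name = "log2_ratio") {
  keep <- !windows$masked & !is.na(windows$log2_ratio)
  w <- windows[keep, , drop = FALSE]
  lines <- c(sprintf("track type=bedGraph name=%s", name),
             sprintf("%s\t%d\t%d\t%s", w$chrom, w$start - 1L, w$end,
                     fmt_num(w$log2_ratio)))
  write_lines_atomic(lines, path)
}

#' Write genomic intervals as BED
#'
#' @param df a data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   optionally `name` and `score` columns to fill BED columns 4-5.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  lines <- if (nrow(df) == 0) character(0)
  else if (!is.null(df$score)) {
    sprintf("%s\t%d\t%d\t%s\t%s", df$chrom, df$start - 1L, df$end,
            df$name %||% ".", fmt_num(df$score))
  } else {
    sprintf("%s\t%d\t%d", df$chrom, df$start - 1L, df$end)
  }
  write_lines_atomic(lines, path)
}

#' Write translocation calls as BEDPE
#'
#' Columns: the two breakpoint regions (0-based half-open), a name, the
#' hit-discordant support as score, two `.` strands, then the proportion,
#' z-score and somatic flag.
#'
#' @param calls a translocation-call data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(calls, path) {
  lines <- if (nrow(calls) == 0) character(0) else sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\ttx%d\t%d\t.\t.\t%s\t%s\t%s",
    calls$chrom_a, calls$start_a - 1L, calls$end_a,
    calls$chrom_b, calls$start_b - 1L, calls$end_b,
    seq_len(nrow(calls)), calls$support, fmt_num(calls$proportion),
    fmt_num(calls$zscore),
    ifelse(is.na(calls$somatic), ".", ifelse(calls$somatic, "somatic",
                                             "shared")))
  write_lines_atomic(lines, path)
}

#' Write a truth set to a directory
#'
#' SNVs and indels go to `truth.vcf` (origin and VAF in INFO), CNV
#' segments to `truth_cnv.bed` (0-based half-open, copy ratio in the score
#' column), translocations to `truth_tx.bedpe`.
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @param reference `DNAStringSet` (for indel anchor bases).
#' @return The directory, invisibly.
#' @export
write_truth <- function(truth, dir, reference) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- chrom_lengths_of(reference)
  hdr <- vcf_header(
    contigs,
    info_lines = c(
      '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="germline or somatic">',
      '##INFO=<ID=VAF,Number=1,Type=Float,Description="Variant allele fraction in carrier cells">',
      '##INFO=<ID=TYPE,Number=1,Type=String,Description="snv, ins or del">'))
  rows <- character(0)
  if (nrow(truth$snvs) > 0) {
    rows <- c(rows, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\tORIGIN=%s;VAF=%s;TYPE=snv",
      truth$snvs$chrom, truth$snvs$pos, truth$snvs$ref, truth$snvs$alt,
      truth$snvs$origin, fmt_num(truth$snvs$vaf)))
  }
  if (nrow(truth$indels) > 0) {
    al <- indel_vcf_alleles(truth$indels, reference)
    rows <- c(rows, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t.\tORIGIN=%s;VAF=%s;TYPE=%s",
      truth$indels$chrom, al$pos, al$ref, al$alt, truth$indels$origin,
      fmt_num(truth$indels$vaf), truth$indels$type))
  }
  write_lines_atomic(c(hdr, rows), file.path(dir, "truth.vcf"))
  cnv <- truth$cnv_segments
  write_bed(data.frame(chrom = cnv$chrom, start = cnv$start, end = cnv$end,
                       name = rep("cnv", nrow(cnv)), score = cnv$ratio,
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_cnv.bed"))
  tx <- truth$translocations
  tx_lines <- if (nrow(tx) == 0) character(0) else sprintf(
    "%s\t%d\t%d\t%s\t%d\t%d\ttruth%d\t.\t.\t.\t%s",
    tx$chrom_a, tx$pos_a - 1L, tx$pos_a, tx$chrom_b, tx$pos_b - 1L,
    tx$pos_b, seq_len(nrow(tx)), tx$origin)
  write_lines_atomic(tx_lines, file.path(dir, "truth_tx.bedpe"))
  invisible(dir)
}

#' Write an evaluation report as TSV and JSON
#'
#' @param report an [evaluate_against_truth()] data.frame.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(report, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
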