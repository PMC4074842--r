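#' Simulation configuration for a matched tumor/normal pair
#'
#' Describes the genome, sequencing model and spiked events for
#' [simulate_reference()] and [simulate_pair()]. Defaults emulate a typical
#' short-read WGS run: 100 bp paired-end reads, 300 +/- 30 bp inserts
#' (truncated at twice the read length so mates never overlap), 40x mean
#' sequence coverage per sample, phred qualities around Q35 with a 1%
#' zero-quality fraction, and a 0.1% background rate of stray
#' interchromosomal read pairs (mapping artifacts).
#'
#' Somatic variants are observed in tumor reads at allele fraction
#' `VAF * cellularity` at copy-neutral loci: only the `cellularity` fraction
#' of biopsy cells is tumor, which dilutes every somatic signal.
#'
#' All positions are 1-based; intervals are closed.
#'
#' @param chromosomes named integer vector of chromosome lengths (bp).
#' @param read_length read length in bp.
#' @param insert_mean,insert_sd insert-size (outer fragment span) model, bp.
#' @param normal_depth,tumor_depth mean sequence coverage per sample (x).
#' @param cellularity tumor cell fraction in `(0, 1]`.
#' @param base_quality_mean,base_quality_sd phred base-quality model.
#' @param zero_quality_fraction fraction of bases emitted with quality 0.
#' @param discordant_rate background probability that a fragment is emitted
#'   as a stray interchromosomal pair (requires >= 2 chromosomes).
#' @param tx_pair_factor spiked translocations emit
#'   `round(tx_pair_factor * tumor_depth)` discordant pairs per breakpoint
#'   unless a per-event `n_pairs` is given.
#' @param seed integer master seed; all streams derive from it via
#'   [substream_seed()].
#' @param germline_snvs data.frame with columns `chrom`, `pos`, optional
#'   `alt`, optional `genotype` (`"het"` default, or `"hom"`).
#' @param somatic_snvs data.frame with columns `chrom`, `pos`, `vaf`,
#'   optional `alt`.
#' @param germline_indels,somatic_indels data.frame with columns `chrom`,
#'   `pos`, `type` (`"ins"`/`"del"`), `len`, optional `seq` (insertions),
#'   and for somatic events `vaf` (germline events are heterozygous).
#' @param cnv_segments data.frame with columns `chrom`, `start`, `end`,
#'   `ratio` (true tumor copy ratio; 1 = neutral, 0 = homozygous deletion).
#' @param translocations data.frame with columns `chrom_a`, `pos_a`,
#'   `chrom_b`, `pos_b`, optional `origin` (`"somatic"` default or
#'   `"germline"`), optional `n_pairs`.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(chromosomes = c(chr1 = 100000), seed = 7)
#' @export
sim_config <- function(chromosomes,
                       read_length = 100L,
                       insert_mean = 300,
                       insert_sd = 30,
                       normal_depth = 40,
                       tumor_depth = 40,
                       cellularity = 0.6,
                       base_quality_mean = 35,
                       base_quality_sd = 4,
                       zero_quality_fraction = 0.01,
                       discordant_rate = 0.001,
                       tx_pair_factor = 0.5,
                       seed = 1L,
                       germline_snvs = NULL,
                       somatic_snvs = NULL,
                       germline_indels = NULL,
                       somatic_indels = NULL,
                       cnv_segments = NULL,
                       translocations = NULL) {
  cfg <- structure(list(
    chromosomes = chromosomes,
    read_length = as.integer(read_length),
    insert_mean = insert_mean, insert_sd = insert_sd,
    normal_depth = normal_depth, tumor_depth = tumor_depth,
    cellularity = cellularity,
    base_quality_mean = base_quality_mean,
    base_quality_sd = base_quality_sd,
    zero_quality_fraction = zero_quality_fraction,
    discordant_rate = discordant_rate,
    tx_pair_factor = tx_pair_factor,
    seed = as.integer(seed),
    germline_snvs = germline_snvs, somatic_snvs = somatic_snvs,
    germline_indels = germline_indels, somatic_indels = somatic_indels,
    cnv_segments = cnv_segments, translocations = translocations
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  ch <- cfg$chromosomes
  if (length(ch) == 0 || is.null(names(ch)) || any(!nzchar(names(ch))))
    stop_config("chromosomes must be a non-empty named length vector")
  if (any(ch <= 0)) stop_config("chromosome lengths must be positive")
  if (anyDuplicated(names(ch))) stop_config("duplicate chromosome names")
  if (!(cfg$cellularity > 0 && cfg$cellularity <= 1))
    stop_config("cellularity must be in (0, 1]")
  if (cfg$insert_sd < 0) stop_config("insert_sd must be >= 0")
  if (cfg$read_length <= 0) stop_config("read_length must be positive")
  if (cfg$insert_mean < 2 * cfg$read_length)
    stop_config("insert_mean must be at least 2 * read_length")
  if (cfg$zero_quality_fraction < 0 || cfg$zero_quality_fraction >= 1)
    stop_config("zero_quality_fraction must be in [0, 1)")
  if (cfg$discordant_rate > 0 && length(ch) < 2)
    stop_config("discordant_rate > 0 requires at least 2 chromosomes")

  in_chrom <- function(chrom, pos, what) {
    if (any(!chrom %in% names(ch)))
      stop_config("%s on undeclared chromosome", what)
    if (any(pos < 1 | pos > ch[chrom]))
      stop_config("%s coordinate outside its chromosome", what)
  }
  snv_keys <- character(0)
  for (nm in c("germline_snvs", "somatic_snvs")) {
    df <- cfg[[nm]]
    if (is.null(df)) next
    stopifnot(all(c("chrom", "pos") %in% names(df)))
    in_chrom(df$chrom, df$pos, nm)
    if (nm == "somatic_snvs") {
      if (!"vaf" %in% names(df) || any(df$vaf <= 0 | df$vaf > 1))
        stop_config("somatic_snvs must carry vaf in (0, 1]")
    }
    snv_keys <- c(snv_keys, paste(df$chrom, df$pos))
  }
  if (anyDuplicated(snv_keys)) stop_config("two spiked SNVs share a locus")
  for (nm in c("germline_indels", "somatic_indels")) {
    df <- cfg[[nm]]
    if (is.null(df)) next
    stopifnot(all(c("chrom", "pos", "type", "len") %in% names(df)))
    if (any(!df$type %in% c("ins", "del"))) stop_config("indel type must be ins/del")
    if (any(df$len < 1)) stop_config("indel length must be >= 1")
    in_chrom(df$chrom, df$pos + ifelse(df$type == "del", df$len, 0L), nm)
    in_chrom(df$chrom, df$pos, nm)
  }
  if (!is.null(cfg$cnv_segments)) {
    df <- cfg$cnv_segments
    stopifnot(all(c("chrom", "start", "end", "ratio") %in% names(df)))
    if (any(df$start > df$end)) stop_config("cnv segment start > end")
    if (any(df$ratio < 0)) stop_config("cnv ratio must be >= 0")
    in_chrom(df$chrom, df$start, "cnv_segments")
    in_chrom(df$chrom, df$end, "cnv_segments")
    for (cc in unique(df$chrom)) {
      d <- df[df$chrom == cc, , drop = FALSE]
      d <- d[order(d$start), , drop = FALSE]
      if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
        stop_config("cnv segments overlap on %s", cc)
    }
  }
  if (!is.null(cfg$translocations)) {
    df <- cfg$translocations
    stopifnot(all(c("chrom_a", "pos_a", "chrom_b", "pos_b") %in% names(df)))
    in_chrom(df$chrom_a, df$pos_a, "translocations")
    in_chrom(df$chrom_b, df$pos_b, "translocations")
    if (any(df$chrom_a == df$chrom_b))
      stop_config("translocations must be interchromosomal")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", length(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes), "bp;",
      sprintf("%gx/%gx normal/tumor, cellularity %g, seed %d\n",
              x$normal_depth, x$tumor_depth, x$cellularity, x$seed))
  for (nm in c("germline_snvs", "somatic_snvs", "germline_indels",
               "somatic_indels", "cnv_segments", "translocations")) {
    n <- if (is.null(x[[nm]])) 0L else nrow(x[[nm]])
    if (n) cat(" ", nm, ":", n, "\n")
  }
  invisible(x)
}
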