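#' Pipeline configuration
#'
#' Collects the input paths (or a simulation config for self-contained
#' runs), the per-detector parameter bundles, the stage list and the seed.
#'
#' @param out_dir output directory.
#' @param simulation optional [sim_config()]; when present the pipeline
#'   simulates its own matched pair and evaluates calls against the truth
#'   set.
#' @param normal_sam,tumor_sam,reference_fasta input paths for
#'   non-simulated runs.
#' @param stages detector subset to run.
#' @param snv_profile `"lenient"`, `"strict"` or `"both"`.
#' @param snv,cnv,indel,tx parameter bundles.
#' @param write_alignments,write_pileups emit SAM / pileup TSV files for a
#'   simulated pair (sequence-level outputs; skip for large simulations).
#' @param log_level `"info"` or `"quiet"`.
#' @param seed integer seed for simulated runs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            simulation = NULL,
                            normal_sam = NULL, tumor_sam = NULL,
                            reference_fasta = NULL,
                            stages = c("snv", "cnv", "indel", "tx"),
                            snv_profile = c("both", "lenient", "strict"),
                            snv = NULL, cnv = cnv_params(),
                            indel = indel_params(), tx = tx_params(),
                            write_alignments = TRUE, write_pileups = FALSE,
                            log_level = c("info", "quiet"),
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- structure(list(
    out_dir = out_dir, simulation = simulation,
    normal_sam = normal_sam, tumor_sam = tumor_sam,
    reference_fasta = reference_fasta, stages = stages,
    snv_profile = match.arg(snv_profile), snv = snv, cnv = cnv,
    indel = indel, tx = tx,
    write_alignments = write_alignments, write_pileups = write_pileups,
    log_level = match.arg(log_level), seed = as.integer(seed)
  ), class = "pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$simulation)) {
    for (p in c("normal_sam", "tumor_sam", "reference_fasta")) {
      if (is.null(cfg[[p]]))
        stop_config("non-simulated run requires %s", p)
      if (!file.exists(cfg[[p]]))
        stop_config("%s does not exist: %s", p, cfg[[p]])
    }
  } else {
    stopifnot(inherits(cfg$simulation, "sim_config"))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file mirrors the [pipeline_config()] arguments; parameter bundles
#' are nested maps (`simulation`, `snv`, `cnv`, `indel`, `tx`), and
#' simulation spike lists are lists of records.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_df <- function(x) if (is.null(x)) NULL else
    as.data.frame(do.call(rbind, lapply(x, as.data.frame)),
                  stringsAsFactors = FALSE)
  sim <- NULL
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    chroms <- unlist(s$chromosomes)
    args <- s[setdiff(names(s), c("chromosomes", "germline_snvs",
                                  "somatic_snvs", "germline_indels",
                                  "somatic_indels", "cnv_segments",
                                  "translocations"))]
    spikes <- lapply(s[intersect(names(s), c(
      "germline_snvs", "somatic_snvs", "germline_indels", "somatic_indels",
      "cnv_segments", "translocations"))], function(x) {
        if (is.data.frame(x)) x else as_df(x)
      })
    sim <- do.call(sim_config, c(list(chromosomes = chroms), args, spikes))
  }
  args <- raw[setdiff(names(raw), c("simulation", "snv", "cnv", "indel",
                                    "tx"))]
  if (!is.null(raw$snv)) args$snv <- do.call(snv_params, raw$snv)
  if (!is.null(raw$cnv)) args$cnv <- do.call(cnv_params, raw$cnv)
  if (!is.null(raw$indel)) args$indel <- do.call(indel_params, raw$indel)
  if (!is.null(raw$tx)) args$tx <- do.call(tx_params, raw$tx)
  args$simulation <- sim
  do.call(pipeline_config, args)
}

plog <- function(cfg, ...) {
  if (cfg$log_level != "quiet") {
    message(sprintf("[somaticpair %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(...))
  }
}

#' Run the somatic-detection pipeline
#'
#' Simulates (or loads) a matched tumor/normal pair, runs the requested
#' detectors on the same inputs, writes every output in its standard
#' format, and — when a truth set is available — evaluates the calls
#' against it. Deterministic given the config and seed.
#'
#' @param config a [pipeline_config()].
#' @param only optional character vector restricting the stages for this
#'   run (subset of the config's stages).
#' @return A list with `paths` (the written files), per-class `calls`,
#'   `truth` (simulated runs) and `report` (when evaluated), invisibly.
#' @export
run_pipeline <- function(config, only = NULL) {
  validate_pipeline_config(config)
  stages <- config$stages
  if (!is.null(only)) {
    bad <- setdiff(only, stages)
    if (length(bad))
      stop_config("unknown/disabled stage(s): %s", paste(bad, collapse = ","))
    stages <- intersect(stages, only)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  truth <- NULL

  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    need_seq <- "snv" %in% stages || config$write_alignments ||
      config$write_pileups
    plog(config, "simulating reference (%d bp)", sum(sim_cfg$chromosomes))
    reference <- simulate_reference(sim_cfg)
    plog(config, "simulating matched pair (sequences: %s)", need_seq)
    pair <- simulate_pair(sim_cfg, reference, with_sequences = need_seq)
    normal <- pair$normal; tumor <- pair$tumor; truth <- pair$truth
    paths$reference <- file.path(config$out_dir, "reference.fa")
    Biostrings::writeXStringSet(reference, paths$reference)
    paths$truth_dir <- file.path(config$out_dir, "truth")
    write_truth(truth, paths$truth_dir, reference)
    if (config$write_alignments) {
      paths$normal_sam <- file.path(config$out_dir, "normal.sam")
      paths$tumor_sam <- file.path(config$out_dir, "tumor.sam")
      emit_alignments(normal, paths$normal_sam)
      emit_alignments(tumor, paths$tumor_sam)
    }
    if (config$write_pileups) {
      paths$normal_pileup <- file.path(config$out_dir, "normal.pileup.tsv")
      paths$tumor_pileup <- file.path(config$out_dir, "tumor.pileup.tsv")
      emit_pileups(normal, reference, paths$normal_pileup)
      emit_pileups(tumor, reference, paths$tumor_pileup)
    }
  } else {
    plog(config, "reading reference and alignments")
    reference <- Biostrings::readDNAStringSet(config$reference_fasta)
    names(reference) <- sub("\\s.*$", "", names(reference))
    normal <- read_sam_records(config$normal_sam, "normal", reference)
    tumor <- read_sam_records(config$tumor_sam, "tumor", reference)
  }

  calls <- list()
  if ("snv" %in% stages) {
    plog(config, "snv: building pileups and calling")
    n_pm <- pileup_from_records(normal, reference)
    t_pm <- pileup_from_records(tumor, reference)
    calls$snvs <- call_somatic_snvs(n_pm, t_pm,
                                    profile = config$snv_profile,
                                    params = config$snv)
    paths$snv_vcf <- file.path(config$out_dir, "somatic_snvs.vcf")
    write_vcf_snvs(calls$snvs, paths$snv_vcf, chrom_lengths_of(reference))
    plog(config, "snv: %d somatic calls", nrow(calls$snvs))
  }
  if ("cnv" %in% stages) {
    plog(config, "cnv: scanning windows")
    cnv_res <- cnv_scan(tumor, normal, config$cnv)
    calls$cnv_windows <- cnv_res$windows
    calls$cnv_segments <- cnv_res$segments
    paths$cnv_bedgraph <- file.path(config$out_dir, "cnv_log2.bedgraph")
    write_bedgraph(cnv_res$windows, paths$cnv_bedgraph)
    masked <- cnv_res$windows[cnv_res$windows$masked, , drop = FALSE]
    paths$cnv_masked_bed <- file.path(config$out_dir, "cnv_masked.bed")
    write_bed(masked, paths$cnv_masked_bed)
    segs <- cnv_res$segments
    paths$cnv_segments_bed <- file.path(config$out_dir, "cnv_segments.bed")
    write_bed(data.frame(chrom = segs$chrom, start = segs$start,
                         end = segs$end, name = segs$direction,
                         score = segs$mean_log2, stringsAsFactors = FALSE),
              paths$cnv_segments_bed)
    plog(config, "cnv: %d segments", nrow(segs))
  }
  if ("indel" %in% stages) {
    plog(config, "indel: two-step somatic filter")
    calls$indels <- call_somatic_indels(tumor, normal, config$indel)
    paths$indel_vcf <- file.path(config$out_dir, "somatic_indels.vcf")
    write_vcf_indels(calls$indels, paths$indel_vcf, reference)
    plog(config, "indel: %d candidates, %d somatic", nrow(calls$indels),
         sum(calls$indels$status == "somatic"))
  }
  if ("tx" %in% stages) {
    plog(config, "tx: discordant-window scan")
    tx_res <- somatic_translocations(tumor, normal, config$tx)
    calls$translocations <- tx_res$calls
    paths$tx_bedpe <- file.path(config$out_dir, "translocations.bedpe")
    write_bedpe(tx_res$calls, paths$tx_bedpe)
    paths$tx_windows <- file.path(config$out_dir, "tx_windows.tsv")
    write.table(tx_res$tumor$windows, paths$tx_windows, sep = "\t",
                quote = FALSE, row.names = FALSE)
    plog(config, "tx: %d somatic calls", nrow(tx_res$calls))
  }

  report <- NULL
  if (!is.null(truth)) {
    report <- evaluate_against_truth(calls, truth)
    paths$report_dir <- config$out_dir
    write_report(report, config$out_dir)
  }
  invisible(list(paths = paths, calls = calls, truth = truth,
                 report = report))
}

match_counts <- function(n_truth, n_calls, truth_matched, call_matched) {
  tp <- sum(truth_matched)
  fn <- n_truth - tp
  fp <- sum(!call_matched)
  data.frame(
    tp = tp, fp = fp, fn = fn,
    precision = if (n_calls > 0) sum(call_matched) / n_calls else NA_real_,
    recall = if (n_truth > 0) tp / n_truth else NA_real_)
}

#' Evaluate calls against a simulated truth set
#'
#' Matching rules: an SNV matches on chromosome, position and alt allele; an
#' indel on chromosome, type and start within `indel_flank`; a CNV segment
#' on direction plus reciprocal overlap of at least `cnv_reciprocal`; a
#' translocation when both breakpoint regions lie within `tx_distance` of
#' the true breakpoints (either orientation). Somatic truth events are the
#' positives for snv/indel/tx; all spiked segments for cnv.
#'
#' @param calls a named list as produced by [run_pipeline()] (`snvs`,
#'   `indels`, `cnv_segments`, `translocations`; absent classes are
#'   skipped).
#' @param truth a `truth_set`.
#' @param rules list of matching tolerances.
#' @return A data.frame with one row per event class: tp, fp, fn,
#'   precision, recall (NA when undefined).
#' @export
evaluate_against_truth <- function(calls, truth,
                                   rules = list(indel_flank = 5L,
                                                cnv_reciprocal = 0.5,
                                                tx_distance = 2000L)) {
  out <- list()
  if (!is.null(calls$snvs)) {
    tr <- truth$snvs[truth$snvs$origin == "somatic", , drop = FALSE]
    key_t <- paste(tr$chrom, tr$pos, tr$alt)
    key_c <- paste(calls$snvs$chrom, calls$snvs$pos, calls$snvs$alt)
    out$snv <- match_counts(nrow(tr), nrow(calls$snvs),
                            key_t %in% key_c, key_c %in% key_t)
  }
  if (!is.null(calls$indels)) {
    tr <- truth$indels[truth$indels$origin == "somatic", , drop = FALSE]
    cc <- calls$indels[calls$indels$status == "somatic", , drop = FALSE]
    t_hit <- vapply(seq_len(nrow(tr)), function(i) {
      any(cc$chrom == tr$chrom[i] & cc$type == tr$type[i] &
            abs(cc$start - tr$start[i]) <= rules$indel_flank)
    }, logical(1))
    c_hit <- vapply(seq_len(nrow(cc)), function(i) {
      any(tr$chrom == cc$chrom[i] & tr$type == cc$type[i] &
            abs(tr$start - cc$start[i]) <= rules$indel_flank)
    }, logical(1))
    out$indel <- match_counts(nrow(tr), nrow(cc), t_hit, c_hit)
  }
  if (!is.null(calls$cnv_segments)) {
    tr <- truth$cnv_segments
    tr_dir <- ifelse(tr$ratio > 1, "gain", "loss")
    cc <- calls$cnv_segments
    recip <- function(s1, e1, s2, e2) {
      ov <- pmin(e1, e2) - pmax(s1, s2) + 1
      ov > 0 & ov >= rules$cnv_reciprocal * (e1 - s1 + 1) &
        ov >= rules$cnv_reciprocal * (e2 - s2 + 1)
    }
    t_hit <- vapply(seq_len(nrow(tr)), function(i) {
      any(cc$chrom == tr$chrom[i] & cc$direction == tr_dir[i] &
            recip(tr$start[i], tr$end[i], cc$start, cc$end))
    }, logical(1))
    c_hit <- vapply(seq_len(nrow(cc)), function(i) {
      any(tr$chrom == cc$chrom[i] & tr_dir == cc$direction[i] &
            recip(cc$start[i], cc$end[i], tr$start, tr$end))
    }, logical(1))
    out$cnv <- match_counts(nrow(tr), nrow(cc), t_hit, c_hit)
  }
  if (!is.null(calls$translocations)) {
    tr <- truth$translocations[truth$translocations$origin == "somatic", ,
                               drop = FALSE]
    cc <- calls$translocations
    near <- function(chrom_r, s, e, chrom_p, p, d) {
      chrom_r == chrom_p & s - d <= p & e + d >= p
    }
    pair_match <- function(ci, ti) {
      fwd <- near(cc$chrom_a[ci], cc$start_a[ci], cc$end_a[ci],
                  tr$chrom_a[ti], tr$pos_a[ti], rules$tx_distance) &
        near(cc$chrom_b[ci], cc$start_b[ci], cc$end_b[ci],
             tr$chrom_b[ti], tr$pos_b[ti], rules$tx_distance)
      rev <- near(cc$chrom_a[ci], cc$start_a[ci], cc$end_a[ci],
                  tr$chrom_b[ti], tr$pos_b[ti], rules$tx_distance) &
        near(cc$chrom_b[ci], cc$start_b[ci], cc$end_b[ci],
             tr$chrom_a[ti], tr$pos_a[ti], rules$tx_distance)
      fwd || rev
    }
    t_hit <- vapply(seq_len(nrow(tr)), function(ti)
      any(vapply(seq_len(nrow(cc)), function(ci) pair_match(ci, ti),
                 logical(1))), logical(1))
    c_hit <- vapply(seq_len(nrow(cc)), function(ci)
      any(vapply(seq_len(nrow(tr)), function(ti) pair_match(ci, ti),
                 logical(1))), logical(1))
    out$tx <- match_counts(nrow(tr), nrow(cc), t_hit, c_hit)
  }
  if (length(out) == 0) {
    return(data.frame(class = character(0), tp = integer(0),
                      fp = integer(0), fn = integer(0),
                      precision = numeric(0), recall = numeric(0)))
  }
  res <- do.call(rbind, out)
  data.frame(class = names(out), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Damaging-variant percentage, as printed in study summaries
#'
#' The percentage of coding variants predicted damaging, rounded to the
#' nearest integer (halves away from zero) — the arithmetic used in
#' published per-patient summaries such as "115 coding variants, 61
#' damaging (53%)".
#'
#' @param total_coding number of coding variants (> 0).
#' @param damaging number predicted damaging (between 0 and `total_coding`).
#' @return The integer percentage.
#' @examples
#' summarize_damaging_fraction(115, 61) # 53
#' summarize_damaging_fraction(90, 38)  # 42
#' @export
summarize_damaging_fraction <- function(total_coding, damaging) {
  if (length(total_coding) != 1 || length(damaging) != 1 ||
      total_coding <= 0 || damaging < 0 || damaging > total_coding)
    stop_config("need 0 <= damaging <= total_coding and total_coding > 0")
  as.integer(round_half_away(100 * damaging / total_coding))
}
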