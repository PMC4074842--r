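#' Simulate a reference genome
#'
#' One uniform-random sequence over A/C/G/T per declared chromosome, at the
#' declared length. Deterministic under the config seed (each chromosome
#' draws from its own substream).
#'
#' @param config a [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  seqs <- vapply(names(config$chromosomes), function(ch) {
    set_substream(config$seed, paste0("ref:", ch))
    paste(sample(DNA_BASES, config$chromosomes[[ch]], replace = TRUE),
          collapse = "")
  }, character(1))
  Biostrings::DNAStringSet(setNames(seqs, names(config$chromosomes)))
}

ref_base_at <- function(reference, chrom, pos, len = 1L) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos + len - 1L))
}

# Resolve spike lists against the reference into a fully specified truth set:
# ref/alt alleles, indel sequences, VAFs and origins.
resolve_truth <- function(config, reference) {
  set_substream(config$seed, "alleles")
  snvs <- list()
  for (nm in c("germline_snvs", "somatic_snvs")) {
    df <- config[[nm]]
    if (is.null(df) || nrow(df) == 0) next
    origin <- if (nm == "germline_snvs") "germline" else "somatic"
    ref <- mapply(ref_base_at, df$chrom, df$pos,
                  MoreArgs = list(reference = reference), USE.NAMES = FALSE)
    alt <- df$alt %||% rep(NA_character_, nrow(df))
    for (i in which(is.na(alt) | !nzchar(alt))) {
      alt[i] <- sample(setdiff(DNA_BASES, ref[i]), 1L)
    }
    if (any(alt == ref)) stop_config("spiked SNV alt equals the reference base")
    gt <- if (origin == "germline") {
      (df$genotype %||% rep("het", nrow(df)))
    } else rep(NA_character_, nrow(df))
    vaf <- if (origin == "germline") ifelse(gt == "hom", 1, 0.5) else df$vaf
    snvs[[nm]] <- data.frame(chrom = df$chrom, pos = df$pos, ref = ref,
                             alt = alt, vaf = vaf, origin = origin,
                             stringsAsFactors = FALSE)
  }
  snvs <- if (length(snvs)) do.call(rbind, unname(snvs)) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), vaf = numeric(0), origin = character(0))

  indels <- list()
  for (nm in c("germline_indels", "somatic_indels")) {
    df <- config[[nm]]
    if (is.null(df) || nrow(df) == 0) next
    origin <- if (nm == "germline_indels") "germline" else "somatic"
    sq <- df$seq %||% rep(NA_character_, nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$type[i] == "del") {
        sq[i] <- ref_base_at(reference, df$chrom[i], df$pos[i], df$len[i])
      } else if (is.na(sq[i]) || !nzchar(sq[i])) {
        sq[i] <- paste(sample(DNA_BASES, df$len[i], replace = TRUE),
                       collapse = "")
      }
    }
    vaf <- if (origin == "germline") rep(0.5, nrow(df)) else
      (df$vaf %||% rep(0.5, nrow(df)))
    indels[[nm]] <- data.frame(
      chrom = df$chrom, pos = df$pos,
      start = df$pos,
      end = ifelse(df$type == "del", df$pos + df$len - 1L, df$pos),
      type = df$type, len = as.integer(df$len), seq = sq,
      vaf = vaf, origin = origin, stringsAsFactors = FALSE)
  }
  indels <- if (length(indels)) do.call(rbind, unname(indels)) else
    data.frame(chrom = character(0), pos = integer(0), start = integer(0),
               end = integer(0), type = character(0), len = integer(0),
               seq = character(0), vaf = numeric(0), origin = character(0))

  cnv <- config$cnv_segments %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               ratio = numeric(0))
  tx <- config$translocations
  if (is.null(tx)) {
    tx <- data.frame(chrom_a = character(0), pos_a = integer(0),
                     chrom_b = character(0), pos_b = integer(0),
                     origin = character(0), n_pairs = integer(0))
  } else {
    tx$origin <- tx$origin %||% rep("somatic", nrow(tx))
    tx$n_pairs <- as.integer(tx$n_pairs %||%
      rep(round(config$tx_pair_factor * config$tumor_depth), nrow(tx)))
  }
  structure(list(snvs = snvs, indels = indels, cnv_segments = cnv,
                 translocations = tx),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$snvs), "SNVs,", nrow(x$indels), "indels,",
      nrow(x$cnv_segments), "CNV segments,",
      nrow(x$translocations), "translocations\n")
  invisible(x)
}

# ---- fragment and read generation ------------------------------------------

sim_sample_fragments <- function(config, sample) {
  ch <- config$chromosomes
  rl <- config$read_length
  depth <- if (sample == "normal") config$normal_depth else config$tumor_depth
  frags <- vector("list", length(ch))
  for (ci in seq_along(ch)) {
    chrom <- names(ch)[ci]
    L <- ch[[ci]]
    set_substream(config$seed, paste0("frag:", sample, ":", chrom))
    n <- max(0L, round(L * depth / (2 * rl)))
    ins <- draw_truncnorm_int(n, config$insert_mean, config$insert_sd, 2L * rl)
    ok <- ins <= L
    ins <- ins[ok]
    st <- 1L + as.integer(floor(runif(length(ins)) * (L - ins + 1)))
    dt <- data.table(chrom = chrom, start = st, insert = ins)

    # tumor fragment density scales with the true copy ratio
    if (sample == "tumor" && !is.null(config$cnv_segments)) {
      segs <- config$cnv_segments[config$cnv_segments$chrom == chrom, ,
                                  drop = FALSE]
      for (si in seq_len(nrow(segs))) {
        s0 <- segs$start[si]; s1 <- segs$end[si]; r <- segs$ratio[si]
        mid <- dt$start + dt$insert %/% 2L
        in_seg <- mid >= s0 & mid <= s1
        if (r < 1) {
          keep <- !in_seg | (runif(nrow(dt)) < r)
          if (r == 0) {
            overlaps <- dt$start <= s1 & (dt$start + dt$insert - 1L) >= s0
            keep <- keep & !overlaps
          }
          dt <- dt[keep]
        } else if (r > 1) {
          n_extra <- round((r - 1) * n * (s1 - s0 + 1) / L)
          if (n_extra > 0) {
            e_ins <- draw_truncnorm_int(n_extra, config$insert_mean,
                                        config$insert_sd, 2L * rl)
            e_mid <- s0 + as.integer(floor(runif(n_extra) * (s1 - s0 + 1)))
            e_st <- pmin(pmax(e_mid - e_ins %/% 2L, 1L), L - e_ins + 1L)
            dt <- rbind(dt, data.table(chrom = chrom, start = e_st,
                                       insert = e_ins))
          }
        }
      }
    }

    dt[, `:=`(proper = TRUE, mate_chrom = chrom,
              mate_start = start + insert - rl)]

    # background stray interchromosomal pairs (mapping-artifact emulation)
    if (config$discordant_rate > 0 && length(ch) >= 2 && nrow(dt) > 0) {
      sel <- which(runif(nrow(dt)) < config$discordant_rate)
      if (length(sel)) {
        others <- setdiff(names(ch), chrom)
        mc <- others[1L + as.integer(floor(runif(length(sel)) * length(others)))]
        ms <- 1L + as.integer(floor(runif(length(sel)) * (ch[mc] - rl + 1)))
        dt[sel, `:=`(proper = FALSE, insert = 0L,
                     mate_chrom = mc, mate_start = ms)]
      }
    }

    # spiked translocation support: clustered discordant pairs at breakpoints
    tx <- config$translocations
    if (!is.null(tx) && nrow(tx) > 0) {
      tx$origin <- tx$origin %||% rep("somatic", nrow(tx))
      tx$n_pairs <- as.integer(tx$n_pairs %||%
        rep(round(config$tx_pair_factor * depth), nrow(tx)))
      use <- tx[tx$chrom_a == chrom &
                  (sample == "tumor" | tx$origin == "germline"), ,
                drop = FALSE]
      for (ti in seq_len(nrow(use))) {
        np <- use$n_pairs[ti]
        lo_a <- max(1L, use$pos_a[ti] - 500L)
        hi_a <- max(lo_a, min(use$pos_a[ti] - rl, L - rl + 1L))
        Lb <- ch[[use$chrom_b[ti]]]
        lo_b <- min(use$pos_b[ti], Lb - rl + 1L)
        hi_b <- min(use$pos_b[ti] + 400L, Lb - rl + 1L)
        dt <- rbind(dt, data.table(
          chrom = chrom,
          start = lo_a + as.integer(floor(runif(np) * (hi_a - lo_a + 1))),
          insert = 0L, proper = FALSE,
          mate_chrom = use$chrom_b[ti],
          mate_start = lo_b + as.integer(floor(runif(np) * (hi_b - lo_b + 1)))))
      }
    }
    frags[[ci]] <- dt
  }
  frags <- rbindlist(frags)
  frags[, chrom := factor(chrom, levels = names(ch))]
  setorder(frags, chrom, start)
  frags[, chrom := as.character(chrom)]
  frags[, frag_id := .I]
  frags[]
}

reads_from_fragments <- function(frags) {
  r1 <- frags[, .(frag_id, read = 1L, chrom, start, strand = "+",
                  mate_chrom, mate_start)]
  r2 <- frags[, .(frag_id, read = 2L, chrom = mate_chrom, start = mate_start,
                  strand = "-", mate_chrom = chrom, mate_start = start)]
  reads <- rbind(r1, r2)
  reads[, `:=`(ops = "", span = NA_integer_, cigar = NA_character_,
               seq = NA_character_, qual = NA_character_)]
  setorder(reads, chrom, start, frag_id, read)
  reads[]
}

# Draw per-read indel carrier status for one sample. An indel is carried only
# by reads that anchor it with >= `anchor` aligned bases on each side.
assign_indel_ops <- function(reads, events, anchor = 5L, read_len) {
  if (nrow(events) == 0) {
    return(data.table(ridx = integer(0), pos = integer(0), type = character(0),
                      len = integer(0), seq = character(0)))
  }
  out <- vector("list", nrow(events))
  starts_by_chrom <- split(seq_len(nrow(reads)), reads$chrom)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    idxs <- starts_by_chrom[[ev$chrom]]
    if (is.null(idxs)) next
    st <- reads$start[idxs]
    if (ev$type == "del") {
      m1 <- ev$pos - st
      elig <- m1 >= anchor & m1 <= read_len - anchor
    } else {
      m1 <- ev$pos - st + 1L
      elig <- m1 >= anchor & m1 <= read_len - ev$len - anchor
    }
    elig_idx <- idxs[elig]
    if (!length(elig_idx)) next
    carrier <- elig_idx[runif(length(elig_idx)) < ev$af]
    if (!length(carrier)) next
    out[[i]] <- data.table(ridx = carrier, pos = as.integer(ev$pos),
                           type = ev$type, len = as.integer(ev$len),
                           seq = ev$seq)
  }
  ops <- rbindlist(out)
  if (nrow(ops) == 0) {
    return(data.table(ridx = integer(0), pos = integer(0), type = character(0),
                      len = integer(0), seq = character(0)))
  }
  setorder(ops, ridx, pos)
  # drop overlapping ops within a read (keep the leftmost)
  ops[, keep := {
    k <- rep(TRUE, .N)
    if (.N > 1) {
      last_end <- pos[1] + ifelse(type[1] == "del", len[1], 0L)
      for (j in 2:.N) {
        if (pos[j] <= last_end) k[j] <- FALSE
        else last_end <- pos[j] + ifelse(type[j] == "del", len[j], 0L)
      }
    }
    k
  }, by = ridx]
  ops <- ops[keep == TRUE][, keep := NULL]
  ops[]
}

assign_snv_subs <- function(reads, events, read_len) {
  if (nrow(events) == 0) {
    return(data.table(ridx = integer(0), pos = integer(0), alt = character(0)))
  }
  out <- vector("list", nrow(events))
  idx_by_chrom <- split(seq_len(nrow(reads)), reads$chrom)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    idxs <- idx_by_chrom[[ev$chrom]]
    if (is.null(idxs)) next
    st <- reads$start[idxs]
    elig_idx <- idxs[st <= ev$pos & st + read_len - 1L >= ev$pos]
    if (!length(elig_idx)) next
    carrier <- elig_idx[runif(length(elig_idx)) < ev$af]
    if (length(carrier)) {
      out[[i]] <- data.table(ridx = carrier, pos = as.integer(ev$pos),
                             alt = ev$alt)
    }
  }
  subs <- rbindlist(out)
  if (nrow(subs) == 0) {
    return(data.table(ridx = integer(0), pos = integer(0), alt = character(0)))
  }
  setorder(subs, ridx, pos)
  subs[]
}

cigar_from_ops <- function(pos, type, len, read_start, read_len) {
  if (length(pos) == 0) return(paste0(read_len, "M"))
  parts <- character(0)
  consumed <- 0L
  p <- read_start
  for (j in seq_along(pos)) {
    if (type[j] == "del") {
      m <- pos[j] - p
      parts <- c(parts, paste0(m, "M"), paste0(len[j], "D"))
      consumed <- consumed + m
      p <- pos[j] + len[j]
    } else {
      m <- pos[j] - p + 1L
      parts <- c(parts, paste0(m, "M"), paste0(len[j], "I"))
      consumed <- consumed + m + len[j]
      p <- pos[j] + 1L
    }
  }
  if (consumed < read_len) parts <- c(parts, paste0(read_len - consumed, "M"))
  paste(parts, collapse = "")
}

sim_sample_reads <- function(config, reference, sample, truth,
                             with_sequences = TRUE) {
  rl <- config$read_length
  frags <- sim_sample_fragments(config, sample)
  reads <- reads_from_fragments(frags)

  snv_events <- truth$snvs
  snv_events$af <- ifelse(snv_events$origin == "germline", snv_events$vaf,
                          if (sample == "tumor")
                            snv_events$vaf * config$cellularity else 0)
  snv_events <- snv_events[snv_events$af > 0, , drop = FALSE]
  ind_events <- truth$indels
  ind_events$af <- ifelse(ind_events$origin == "germline", ind_events$vaf,
                          if (sample == "tumor")
                            ind_events$vaf * config$cellularity else 0)
  ind_events <- ind_events[ind_events$af > 0, , drop = FALSE]

  set_substream(config$seed, paste0("variants:", sample))
  ops <- assign_indel_ops(reads, ind_events, anchor = 5L, read_len = rl)
  subs <- assign_snv_subs(reads, snv_events, read_len = rl)

  # record ops on the reads (1-based "pos:type:len:seq", ";"-joined)
  if (nrow(ops) > 0) {
    op_str <- ops[, .(ops = paste(sprintf("%d:%s:%d:%s", pos, type, len, seq),
                                  collapse = ";")), by = ridx]
    reads[op_str$ridx, ops := op_str$ops]
  }
  del_extra <- integer(nrow(reads))
  if (nrow(ops) > 0) {
    de <- ops[type == "del", .(extra = sum(len)), by = ridx]
    del_extra[de$ridx] <- de$extra
  }
  reads[, span := rl + del_extra]
  cig <- rep(paste0(rl, "M"), nrow(reads))
  if (nrow(ops) > 0) {
    for (ri in unique(ops$ridx)) {
      o <- ops[ridx == ri]
      cig[ri] <- cigar_from_ops(o$pos, o$type, o$len, reads$start[ri], rl)
    }
  }
  reads[, cigar := cig]

  if (with_sequences) {
    for (chrom in names(config$chromosomes)) {
      ridx <- which(reads$chrom == chrom)
      if (!length(ridx)) next
      pos_of <- match(seq_len(nrow(reads)), ridx) # global -> local index
      o_sel <- ops[["ridx"]] %in% ridx
      s_sel <- subs[["ridx"]] %in% ridx
      o <- ops[o_sel]
      s <- subs[s_sel]
      # cpp positions/indices are 0-based
      op_pos0 <- ifelse(o$type == "del", o$pos - 1L, o$pos)
      set_substream(config$seed, paste0("seq:", sample, ":", chrom))
      res <- cpp_make_reads(
        as.character(reference[[chrom]]),
        reads$start[ridx] - 1L, rl,
        as.integer(pos_of[o$ridx] - 1L), as.integer(op_pos0),
        as.integer(o$type == "del"),
        o$len, as.character(o$seq),
        as.integer(pos_of[s$ridx] - 1L), s$pos - 1L, as.character(s$alt),
        config$base_quality_mean, config$base_quality_sd,
        config$zero_quality_fraction)
      reads[ridx, `:=`(seq = as.character(res$seq),
                       qual = as.character(res$qual),
                       cigar = as.character(res$cigar),
                       span = as.integer(res$span))]
    }
  }

  new_read_pairs(frags, reads, config$chromosomes, sample, rl)
}

#' Simulate a matched tumor/normal read-pair set with a known truth set
#'
#' Places paired-end fragments uniformly at the configured depths, draws
#' insert sizes from a truncated normal (minimum twice the read length),
#' injects germline variants into both samples and somatic variants into the
#' tumor at allele fraction `VAF * cellularity`, scales tumor fragment
#' density inside spiked CNV segments by the true copy ratio (ratio 0 leaves
#' no tumor fragment overlapping the segment), emits clustered discordant
#' pairs at spiked translocation breakpoints, and draws per-base qualities
#' with quality-implied miscalls.
#'
#' @param config a [sim_config()].
#' @param reference the [simulate_reference()] output (or a compatible
#'   `DNAStringSet` matching the config chromosomes).
#' @param with_sequences generate per-read sequences and qualities. Skipping
#'   them (`FALSE`) is cheaper and sufficient for the copy-number, indel and
#'   translocation detectors, which use only positions, inserts and indel
#'   operations; fragment placement and variant carrier draws are identical
#'   either way.
#' @return A list with elements `normal` and `tumor` (class `read_pairs`)
#'   and `truth` (class `truth_set`).
#' @export
simulate_pair <- function(config, reference, with_sequences = TRUE) {
  validate_sim_config(config)
  cl <- chrom_lengths_of(reference)
  if (!identical(sort(names(cl)), sort(names(config$chromosomes))) ||
      any(cl[names(config$chromosomes)] != config$chromosomes)) {
    stop_config("reference does not match the configured chromosomes")
  }
  truth <- resolve_truth(config, reference)
  normal <- sim_sample_reads(config, reference, "normal", truth,
                             with_sequences)
  tumor <- sim_sample_reads(config, reference, "tumor", truth,
                            with_sequences)
  list(normal = normal, tumor = tumor, truth = truth, config = config)
}

#' Random spike lists for simulation configs
#'
#' Draws well-separated variant positions and event attributes for use as
#' `sim_config()` spike lists. Somatic SNV VAFs are drawn uniformly from
#' `vaf_range` (clonal heterozygous events sit at 0.5; loss-of-heterozygosity
#' or amplified events approach 1).
#'
#' @param chromosomes named length vector, as in [sim_config()].
#' @param seed integer seed.
#' @param n_germline_snvs,n_somatic_snvs,n_germline_indels,n_somatic_indels
#'   event counts.
#' @param vaf_range somatic SNV VAF range.
#' @param indel_len_range indel length range (bp).
#' @param spacing minimum distance between spiked events, bp.
#' @param margin distance kept clear of chromosome ends, bp.
#' @return A named list of spike data.frames.
#' @export
sim_spikes <- function(chromosomes, seed = 1L,
                       n_germline_snvs = 0L, n_somatic_snvs = 0L,
                       n_germline_indels = 0L, n_somatic_indels = 0L,
                       vaf_range = c(0.3, 1), indel_len_range = c(1L, 10L),
                       spacing = 150L, margin = 1000L) {
  set.seed(substream_seed(seed, "spikes"))
  n_total <- n_germline_snvs + n_somatic_snvs + n_germline_indels +
    n_somatic_indels
  if (n_total == 0) return(list())
  # candidate grid, shuffled: guarantees the spacing
  grid <- rbindlist(lapply(names(chromosomes), function(ch) {
    p <- seq(margin, chromosomes[[ch]] - margin, by = spacing)
    data.table(chrom = ch, pos = as.integer(p))
  }))
  if (nrow(grid) < n_total)
    stop_config("chromosomes too small for the requested spike count")
  grid <- grid[sample(.N, n_total)]
  take <- function(n) {
    if (n == 0) return(NULL)
    out <- grid[seq_len(n)]
    grid <<- grid[-seq_len(n)]
    out
  }
  res <- list()
  g <- take(n_germline_snvs)
  if (!is.null(g)) res$germline_snvs <- data.frame(g, genotype = "het")
  s <- take(n_somatic_snvs)
  if (!is.null(s)) {
    res$somatic_snvs <- data.frame(
      s, vaf = runif(n_somatic_snvs, vaf_range[1], vaf_range[2]))
  }
  mk_indels <- function(n) {
    d <- take(n)
    if (is.null(d)) return(NULL)
    data.frame(d,
               type = sample(c("ins", "del"), n, replace = TRUE),
               len = sample(indel_len_range[1]:indel_len_range[2], n,
                            replace = TRUE))
  }
  gi <- mk_indels(n_germline_indels)
  if (!is.null(gi)) res$germline_indels <- gi
  si <- mk_indels(n_somatic_indels)
  if (!is.null(si)) res$somatic_indels <- data.frame(si, vaf = 0.5)
  res
}
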