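#' Translocation-scan parameters
#'
#' @param window non-overlapping window width in bp.
#' @param sd_multiplier outlier cutoff is `mean + sd_multiplier * sd` of the
#'   hit-discordant proportions in scope.
#' @param min_hit_reads minimum hit-discordant support of a call (guards
#'   against proportion outliers in near-empty windows).
#' @param somatic_overlap_padding bp of padding when eliminating tumor calls
#'   that overlap normal calls.
#' @param stats_scope compute the cutoff per chromosome (default) or
#'   genome-wide.
#' @return An object of class `tx_params`.
#' @export
tx_params <- function(window = 2000L, sd_multiplier = 3, min_hit_reads = 5L,
                      somatic_overlap_padding = 1000L,
                      stats_scope = c("per_chromosome", "genome_wide")) {
  if (window <= 0 || sd_multiplier <= 0 || somatic_overlap_padding < 0)
    stop_config("invalid translocation parameters")
  structure(list(window = as.integer(window), sd_multiplier = sd_multiplier,
                 min_hit_reads = as.integer(min_hit_reads),
                 somatic_overlap_padding = as.integer(somatic_overlap_padding),
                 stats_scope = match.arg(stats_scope)),
            class = "tx_params")
}

#' Count discordant reads in non-overlapping windows
#'
#' Windows tile each chromosome at the window width. Per window: the total
#' aligned read count, the discordant count (mate on a different
#' chromosome), the mate-chromosome histogram's mode (the "highest hit";
#' ties go to the chromosome earliest in reference order), the
#' hit-discordant count and its proportion of the total aligned reads.
#' Windows containing no reads are omitted.
#'
#' @param records a `read_pairs` object.
#' @param params a [tx_params()].
#' @return A data.frame of `discordant_window` rows.
#' @export
scan_windows <- function(records, params = tx_params()) {
  reads <- records$reads
  cl <- records$chrom_lengths
  ref_order <- names(cl)
  w <- params$window
  dt <- reads[, .(chrom, start, mate_chrom)]
  dt[, win := (start - 1L) %/% w]
  totals <- dt[, .(total = .N,
                   discordant = sum(mate_chrom != chrom)),
               by = .(chrom, win)]
  hist <- dt[mate_chrom != chrom, .N, by = .(chrom, win, mate_chrom)]
  if (nrow(hist) > 0) {
    hist[, idx := match(mate_chrom, ref_order)]
    setorder(hist, chrom, win, -N, idx)
    top <- hist[, .SD[1], by = .(chrom, win)]
    totals <- top[, .(chrom, win, hit_chrom = mate_chrom, hit_count = N)][
      totals, on = c("chrom", "win")]
  } else {
    totals[, `:=`(hit_chrom = NA_character_, hit_count = 0L)]
  }
  totals[is.na(hit_count), hit_count := 0L]
  totals[, `:=`(start = win * w + 1L,
                end = pmin((win + 1L) * w, cl[chrom]),
                proportion = hit_count / total)]
  setorder(totals, chrom, start)
  out <- totals[, .(chrom, start, end, total, discordant, hit_chrom,
                    hit_count, proportion)]
  setDF(out)
  out
}

#' Outlier cutoff on hit-discordant proportions
#'
#' The proportions across a scope (each chromosome, or the whole genome)
#' are treated as draws from a common distribution; the cutoff is
#' `mean + sd_multiplier * sd` with the sample (n-1) standard deviation.
#' Scopes with fewer than 2 windows yield no cutoff (and so no calls); when
#' the SD is zero the cutoff equals the mean and only windows strictly
#' above it can be flagged, so uniform scopes yield none.
#'
#' @param windows a [scan_windows()] data.frame.
#' @param params a [tx_params()].
#' @return A data.frame with one row per scope: `scope`, `n`, `mean`, `sd`,
#'   `cutoff`.
#' @export
outlier_cutoff <- function(windows, params = tx_params()) {
  dt <- as.data.table(windows)
  dt[, scope := if (params$stats_scope == "per_chromosome") chrom else
    "genome"]
  res <- dt[, .(n = .N, mean = mean(proportion),
                sd = if (.N >= 2) sd(proportion) else NA_real_),
            by = scope]
  res[, cutoff := fifelse(n >= 2, mean + params$sd_multiplier * sd,
                          NA_real_)]
  small <- res[n < 2]
  if (nrow(small) > 0) {
    message("scope(s) with < 2 windows yield no calls: ",
            paste(small$scope, collapse = ", "))
  }
  setDF(res)
  res
}

#' Detect translocation candidates from flagged windows
#'
#' A window is flagged when its hit-discordant proportion exceeds the scope
#' cutoff and its hit-discordant support reaches `min_hit_reads`. Adjacent
#' flagged windows sharing the same highest-hit chromosome merge into one
#' call. The breakpoint regions are the spans of the hit-discordant reads:
#' region A from their positions in the flagged window(s), region B from
#' their mates' positions on the highest-hit chromosome. The z-score of the
#' most extreme member window is recorded.
#'
#' @param windows a [scan_windows()] data.frame.
#' @param cutoffs an [outlier_cutoff()] data.frame computed from the same
#'   windows.
#' @param records the `read_pairs` the windows came from.
#' @param params a [tx_params()].
#' @return A data.frame of translocation calls (`somatic` is `NA` until
#'   [subtract_normal()]).
#' @export
detect_translocations <- function(windows, cutoffs, records,
                                  params = tx_params()) {
  empty <- data.frame(chrom_a = character(0), start_a = integer(0),
                      end_a = integer(0), chrom_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      support = integer(0), proportion = numeric(0),
                      zscore = numeric(0), somatic = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  dt <- as.data.table(windows)
  cut_dt <- as.data.table(cutoffs)
  dt[, scope := if (params$stats_scope == "per_chromosome") chrom else
    "genome"]
  dt <- cut_dt[dt, on = "scope"]
  flagged <- dt[!is.na(cutoff) & proportion > cutoff &
                  hit_count >= params$min_hit_reads]
  if (nrow(flagged) == 0) return(empty)
  flagged[, zscore := (proportion - mean) / sd]
  # merge adjacent flagged windows sharing the highest hit
  setorder(flagged, chrom, start)
  w <- params$window
  flagged[, run_id := cumsum(
    c(TRUE, !(chrom[-1] == chrom[-.N] & hit_chrom[-1] == hit_chrom[-.N] &
                start[-1] == end[-.N] + 1L)))]
  reads <- records$reads
  out <- flagged[, {
    bc <- .BY$c
    hc <- hit_chrom[1]
    s0 <- min(start); s1 <- max(end)
    r <- reads[chrom == bc & start >= s0 & start <= s1 &
                 mate_chrom == hc]
    # localize the mate-side breakpoint to the modal mate window (+/- one
    # window): stray hit-chromosome mates elsewhere would otherwise inflate
    # the region far beyond the scan's resolution
    mw <- (r$mate_start - 1L) %/% w
    tab <- data.table(win = mw)[, .N, by = win][order(-N, win)]
    keep_r <- abs(mw - tab$win[1]) <= 1L
    rk <- r[keep_r]
    .(chrom_a = bc, start_a = min(rk$start), end_a = max(rk$start),
      chrom_b = hc, start_b = min(rk$mate_start),
      end_b = max(rk$mate_start), support = nrow(rk),
      proportion = max(proportion), zscore = max(zscore))
  }, by = .(run_id, c = chrom)][, `:=`(run_id = NULL, c = NULL)]
  out[, somatic := NA]
  setDF(out)
  out
}

#' Run the translocation scan on one sample
#'
#' @param records a `read_pairs` object.
#' @param params a [tx_params()].
#' @return A list with `windows`, `cutoffs` and `calls`.
#' @export
tx_detect <- function(records, params = tx_params()) {
  windows <- scan_windows(records, params)
  cutoffs <- outlier_cutoff(windows, params)
  calls <- detect_translocations(windows, cutoffs, records, params)
  list(windows = windows, cutoffs = cutoffs, calls = calls)
}

#' Eliminate tumor translocations also present in the normal
#'
#' A tumor call is removed when either of its breakpoint regions, padded by
#' `somatic_overlap_padding`, overlaps either region of any normal call on
#' the same chromosome; survivors are flagged somatic.
#'
#' @param tumor_calls,normal_calls [detect_translocations()] outputs from
#'   the two samples.
#' @param params a [tx_params()].
#' @return The surviving tumor calls with `somatic = TRUE`.
#' @export
subtract_normal <- function(tumor_calls, normal_calls,
                            params = tx_params()) {
  if (nrow(tumor_calls) == 0) return(tumor_calls)
  pad <- params$somatic_overlap_padding
  if (nrow(normal_calls) == 0) {
    tumor_calls$somatic <- TRUE
    return(tumor_calls)
  }
  n_regions <- rbind(
    data.frame(chrom = normal_calls$chrom_a, start = normal_calls$start_a,
               end = normal_calls$end_a, stringsAsFactors = FALSE),
    data.frame(chrom = normal_calls$chrom_b, start = normal_calls$start_b,
               end = normal_calls$end_b, stringsAsFactors = FALSE))
  overlaps_any <- function(chrom, start, end) {
    hit <- n_regions$chrom == chrom &
      n_regions$start <= end + pad & n_regions$end >= start - pad
    any(hit)
  }
  drop <- vapply(seq_len(nrow(tumor_calls)), function(i) {
    overlaps_any(tumor_calls$chrom_a[i], tumor_calls$start_a[i],
                 tumor_calls$end_a[i]) ||
      overlaps_any(tumor_calls$chrom_b[i], tumor_calls$start_b[i],
                   tumor_calls$end_b[i])
  }, logical(1))
  out <- tumor_calls[!drop, , drop = FALSE]
  if (nrow(out) > 0) out$somatic <- TRUE
  row.names(out) <- NULL
  out
}

#' Somatic translocations from a matched pair
#'
#' Calls tumor and normal separately and eliminates the regions of overlap.
#'
#' @param tumor,normal `read_pairs` objects.
#' @param params a [tx_params()].
#' @return A list with per-sample scans (`tumor`, `normal`) and the somatic
#'   `calls`.
#' @export
somatic_translocations <- function(tumor, normal, params = tx_params()) {
  td <- tx_detect(tumor, params)
  nd <- tx_detect(normal, params)
  calls <- subtract_normal(td$calls, nd$calls, params)
  list(tumor = td, normal = nd, calls = calls)
}
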