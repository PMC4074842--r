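#' Copy-number scan parameters
#'
#' @param window window width in bp (2 kb default).
#' @param step sliding-window step in bp (half a window by default, so
#'   windows overlap).
#' @param repeat_mask_log2 germline windows whose normalized coverage
#'   exceeds `2^repeat_mask_log2` (log2 > 3 by default) are masked as
#'   high-repeat regions (centromere-like) and excluded from ratios.
#' @param zero_replacement raw window coverages of zero are replaced by this
#'   value before normalization, so homozygous deletions give finite,
#'   floored log2 ratios instead of `-Inf`.
#' @param call_threshold_log2 minimum `|log2 ratio|` of a gain/loss window.
#' @return An object of class `cnv_params`.
#' @export
cnv_params <- function(window = 2000L, step = 1000L, repeat_mask_log2 = 3,
                       zero_replacement = 1, call_threshold_log2 = 1.0) {
  if (window <= 0 || step <= 0 || step > window)
    stop_config("need window > 0 and 0 < step <= window")
  if (repeat_mask_log2 <= 0 || zero_replacement <= 0 ||
      call_threshold_log2 <= 0)
    stop_config("cnv thresholds must be positive")
  structure(list(window = as.integer(window), step = as.integer(step),
                 repeat_mask_log2 = repeat_mask_log2,
                 zero_replacement = zero_replacement,
                 call_threshold_log2 = call_threshold_log2),
            class = "cnv_params")
}

#' Estimate the insert-size model of a sample
#'
#' Mean and sample standard deviation of the insert (outer span) over proper
#' pairs with both mates on the same chromosome; fragments longer than
#' `mean + 3 sd` are excluded from physical coverage downstream.
#'
#' @param records a `read_pairs` object.
#' @return A list of class `insert_size_model` with `mean`, `sd`,
#'   `max_accepted` and `n`.
#' @export
estimate_insert_model <- function(records) {
  fr <- records$fragments
  ins <- fr[proper == TRUE & mate_chrom == chrom & insert > 0, insert]
  if (length(ins) < 2)
    stop_config("need at least 2 proper pairs to estimate the insert model")
  m <- mean(ins); s <- sd(ins)
  structure(list(mean = m, sd = s, max_accepted = m + 3 * s,
                 n = length(ins)),
            class = "insert_size_model")
}

#' @export
print.insert_size_model <- function(x, ...) {
  cat(sprintf("insert_size_model: mean %.1f, sd %.2f, max accepted %.1f (n=%d)\n",
              x$mean, x$sd, x$max_accepted, x$n))
  invisible(x)
}

#' Per-base physical coverage gated by insert size
#'
#' Every proper pair whose insert is positive and no longer than the model's
#' `max_accepted` increments the coverage of each base its outer span
#' covers; all other pairs contribute nothing. Spans extending past a
#' chromosome end are clipped with a warning.
#'
#' @param records a `read_pairs` object.
#' @param model an [estimate_insert_model()] result.
#' @param chrom_lengths optional named length vector (defaults to the
#'   records' own).
#' @return An [IRanges::RleList]-like list of per-chromosome coverage
#'   vectors (run-length encoded).
#' @export
physical_coverage <- function(records, model, chrom_lengths = NULL) {
  stopifnot(inherits(model, "insert_size_model"))
  cl <- chrom_lengths %||% records$chrom_lengths
  fr <- records$fragments
  acc <- fr[proper == TRUE & mate_chrom == chrom & insert > 0 &
              insert <= model$max_accepted]
  out <- setNames(vector("list", length(cl)), names(cl))
  for (chrom_name in names(cl)) {
    L <- as.integer(cl[[chrom_name]])
    f <- acc[chrom == chrom_name]
    if (nrow(f) > 0 && any(f$start + f$insert - 1L > L)) {
      warning("fragment span clipped at the end of ", chrom_name,
              call. = FALSE)
    }
    ir <- IRanges::IRanges(start = f$start,
                           end = pmin(f$start + f$insert - 1L, L))
    out[[chrom_name]] <- IRanges::coverage(ir, width = L)
  }
  methods::as(out, "SimpleRleList")
}

#' Mean physical coverage in sliding windows
#'
#' Windows tile each chromosome at `params$step`; each carries the mean
#' per-base physical coverage over its `params$window` bases. Trailing
#' partial windows are dropped so every window has the same width;
#' chromosomes shorter than one window yield none.
#'
#' @param track a coverage list from [physical_coverage()].
#' @param params a [cnv_params()].
#' @return A data.frame with `chrom`, `start`, `end` (1-based closed) and
#'   `coverage`.
#' @export
window_coverage <- function(track, params = cnv_params()) {
  out <- list()
  for (chrom in names(track)) {
    rle <- track[[chrom]]
    L <- length(rle)
    if (L < params$window) {
      message("chromosome ", chrom, " shorter than one window; skipped")
      next
    }
    starts <- seq.int(1L, L - params$window + 1L, by = params$step)
    v <- IRanges::Views(rle, start = starts, width = params$window)
    out[[chrom]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + params$window - 1L,
                               coverage = IRanges::viewMeans(v))
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), coverage = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Normalize window coverages by the genome-wide median
#'
#' Each value is divided by the sample's median positive window coverage,
#' so the normalized genome-wide median is 1 and tumor/normal depth
#' differences cancel in the ratio.
#'
#' @param values numeric window coverages.
#' @param params a [cnv_params()] (unused fields kept for signature
#'   symmetry).
#' @return Normalized values.
#' @export
normalize_windows <- function(values, params = cnv_params()) {
  if (length(values) == 0) stop_config("no windows to normalize")
  med <- median(values[values > 0])
  if (!is.finite(med) || med <= 0)
    stop_config("all window coverages are zero; cannot normalize")
  values / med
}

#' Tumor/normal log2 ratios over a shared window grid
#'
#' Raw window coverages of zero are replaced by `zero_replacement` before
#' normalization, which floors homozygous-deletion ratios at a finite,
#' depth-dependent value instead of `-Inf`. Windows whose normalized
#' germline coverage exceeds `2^repeat_mask_log2` are marked `masked`
#' (high-repeat regions such as centromeres) and carry no ratio; every
#' emitted ratio is finite.
#'
#' @param tumor,normal window data.frames from [window_coverage()] on the
#'   same grid.
#' @param params a [cnv_params()].
#' @return A data.frame of coverage windows with raw and normalized
#'   coverages, `log2_ratio` (NA on masked windows) and `masked`.
#' @export
log2_ratio_windows <- function(tumor, normal, params = cnv_params()) {
  if (nrow(tumor) != nrow(normal) ||
      !all(tumor$chrom == normal$chrom) || !all(tumor$start == normal$start))
    stop_config("tumor and normal window grids differ")
  t_raw <- tumor$coverage
  n_raw <- normal$coverage
  t_repl <- ifelse(t_raw == 0, params$zero_replacement, t_raw)
  n_repl <- ifelse(n_raw == 0, params$zero_replacement, n_raw)
  t_norm <- normalize_windows(t_repl, params)
  n_norm <- normalize_windows(n_repl, params)
  masked <- log2(n_norm) > params$repeat_mask_log2
  ratio <- ifelse(masked, NA_real_, log2(t_norm / n_norm))
  data.frame(chrom = tumor$chrom, start = tumor$start, end = tumor$end,
             normal_raw = n_raw, tumor_raw = t_raw,
             normal_norm = n_norm, tumor_norm = t_norm,
             log2_ratio = ratio, masked = masked,
             stringsAsFactors = FALSE)
}

#' Merge runs of gain/loss windows into copy-number segments
#'
#' Maximal runs of consecutive unmasked windows with `log2_ratio` at or
#' beyond `call_threshold_log2` (same sign) become one segment; the segment
#' log2 is the mean over its member windows.
#'
#' @param windows the [log2_ratio_windows()] output, sorted.
#' @param params a [cnv_params()].
#' @return A data.frame of segments: `chrom`, `start`, `end`, `mean_log2`,
#'   `direction` (`gain`/`loss`), `n_windows`.
#' @export
segment_calls <- function(windows, params = cnv_params()) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mean_log2 = numeric(0),
                      direction = character(0), n_windows = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(windows) == 0) return(empty)
  dt <- as.data.table(windows)
  dt[, direction := fifelse(
    masked | is.na(log2_ratio), "none",
    fifelse(log2_ratio >= params$call_threshold_log2, "gain",
            fifelse(log2_ratio <= -params$call_threshold_log2, "loss",
                    "none")))]
  dt[, run_id := rleid_vec(paste(chrom, direction))]
  if (!any(dt$direction != "none")) return(empty)
  segs <- dt[direction != "none",
             .(chrom = chrom[1], start = min(start), end = max(end),
               mean_log2 = mean(log2_ratio), direction = direction[1],
               n_windows = .N),
             by = run_id][, run_id := NULL]
  if (nrow(segs) == 0) return(empty)
  setDF(segs)
  segs
}

rleid_vec <- function(x) {
  if (length(x) == 0) return(integer(0))
  cumsum(c(TRUE, x[-1] != x[-length(x)]))
}

#' Run the full copy-number scan on a tumor/normal pair
#'
#' Convenience wrapper: per-sample insert model, insert-gated physical
#' coverage, shared window grid, zero replacement, median normalization,
#' repeat masking, log2 ratios and segmentation.
#'
#' @param tumor,normal `read_pairs` objects.
#' @param params a [cnv_params()].
#' @return A list with `windows`, `segments` and the two insert models.
#' @export
cnv_scan <- function(tumor, normal, params = cnv_params()) {
  if (!identical(tumor$chrom_lengths, normal$chrom_lengths))
    stop_config("tumor and normal records disagree on the reference")
  tm <- estimate_insert_model(tumor)
  nm <- estimate_insert_model(normal)
  t_track <- physical_coverage(tumor, tm)
  n_track <- physical_coverage(normal, nm)
  t_win <- window_coverage(t_track, params)
  n_win <- window_coverage(n_track, params)
  windows <- log2_ratio_windows(t_win, n_win, params)
  list(windows = windows, segments = segment_calls(windows, params),
       tumor_insert_model = tm, normal_insert_model = nm)
}
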