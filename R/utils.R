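DNA_BASES <- c("A", "C", "G", "T")

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' A single master seed drives every random stream in the simulator; each
#' stage (reference, fragment placement, sequence errors, ...) draws from its
#' own named substream so stages are reproducible in isolation.
#'
#' @param seed integer master seed.
#' @param name character stream name.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (c in utf8ToInt(name)) h <- (h * 31 + c) %% m
  as.integer((h + (abs(seed) %% m) * 977) %% m)
}

set_substream <- function(seed, name) {
  set.seed(substream_seed(seed, name))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# rounding half away from zero, for printed-percentage arithmetic
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# truncated-normal integer draws with a hard lower bound (rejection sampling)
draw_truncnorm_int <- function(n, mean, sd, min) {
  if (sd == 0) return(rep.int(as.integer(max(round(mean), min)), n))
  x <- as.integer(round(rnorm(n, mean, sd)))
  bad <- which(x < min)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    x[bad] <- as.integer(round(rnorm(length(bad), mean, sd)))
    bad <- bad[x[bad] < min]
    guard <- guard + 1L
  }
  x[x < min] <- as.integer(min)
  x
}

# named chromosome-length vector from a DNAStringSet or named numeric
chrom_lengths_of <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    setNames(Biostrings::width(reference), names(reference))
  } else if (is.numeric(reference) && !is.null(names(reference))) {
    reference
  } else {
    stop_config("expected a DNAStringSet or a named length vector")
  }
}
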