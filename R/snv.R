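GENOTYPES <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
GT_A1 <- substr(GENOTYPES, 1, 1)
GT_A2 <- substr(GENOTYPES, 2, 2)

#' A single pileup column
#'
#' Per-strand base calls with phred qualities at one locus: the substrate of
#' the genotype caller.
#'
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param ref reference base (A/C/G/T).
#' @param fwd,rev data.frames with columns `base` and `qual` (phred >= 0),
#'   one row per read base on that strand.
#' @return An object of class `pileup_column`.
#' @export
pileup_column <- function(chrom, pos, ref, fwd = NULL, rev = NULL) {
  empty <- data.frame(base = character(0), qual = integer(0))
  fwd <- fwd %||% empty
  rev <- rev %||% empty
  for (d in list(fwd, rev)) {
    stopifnot(all(c("base", "qual") %in% names(d)))
    if (any(d$qual < 0)) stop_config("negative base quality")
  }
  if (!ref %in% DNA_BASES) stop_config("reference base must be one of ACGT")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 fwd = fwd, rev = rev),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("pileup_column %s:%d ref=%s depth=%d(+)/%d(-)\n",
              x$chrom, x$pos, x$ref, nrow(x$fwd), nrow(x$rev)))
  invisible(x)
}

#' Trim zero-quality bases from a pileup column
#'
#' Zero-quality bases carry no information and are removed from both strands
#' before any distribution comparison; strand assignment of the remaining
#' bases is preserved and the input is left untouched.
#'
#' @param column a [pileup_column()].
#' @return A new `pileup_column` containing exactly the bases with
#'   quality > 0.
#' @export
trim_zero_quality <- function(column) {
  stopifnot(inherits(column, "pileup_column"))
  column$fwd <- column$fwd[column$fwd$qual > 0, , drop = FALSE]
  column$rev <- column$rev[column$rev$qual > 0, , drop = FALSE]
  column
}

#' Mean quality-implied error probability of one strand
#'
#' The per-strand miscall probability entering the expected genotype
#' distributions: the mean of `10^(-Q/10)` over the strand's (trimmed)
#' bases.
#'
#' @param quals integer phred qualities (length >= 1).
#' @return A probability in `(0, 1]`.
#' @export
locus_error_rate <- function(quals) {
  if (length(quals) == 0) stop_config("error rate undefined on an empty strand")
  mean(10^(-quals / 10))
}

#' Expected base distribution of a diploid genotype
#'
#' Each of the two alleles contributes half the mass: `1 - e` to itself and
#' `e/3` to each other base, where `e` is the locus-strand error
#' probability.
#'
#' @param genotype two alleles, as a 2-character string (e.g. `"AG"`) or a
#'   length-2 character vector.
#' @param e error probability in `[0, 1)`.
#' @return A named probability vector over (A, C, G, T) summing to 1.
#' @export
expected_base_distribution <- function(genotype, e = 0) {
  al <- if (length(genotype) == 2) genotype else
    strsplit(genotype, "")[[1]]
  if (length(al) != 2 || any(!al %in% DNA_BASES))
    stop_config("genotype must be two of A/C/G/T")
  if (e < 0 || e >= 1) stop_config("error probability must be in [0, 1)")
  q <- setNames(numeric(4), DNA_BASES)
  for (a in al) {
    contrib <- rep(e / 3, 4)
    contrib[match(a, DNA_BASES)] <- 1 - e
    q <- q + 0.5 * contrib
  }
  q
}

#' Kolmogorov-Smirnov-like distance between two base distributions
#'
#' The maximum absolute difference between the cumulative distributions over
#' the fixed base order A < C < G < T. Symmetric, in `[0, 1]`, and zero
#' exactly when the distributions coincide.
#'
#' @param p,q probability vectors over (A, C, G, T), each summing to 1.
#' @return The distance, a number in `[0, 1]`.
#' @export
ks_distance <- function(p, q) {
  if (length(p) != 4 || length(q) != 4 ||
      abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9 ||
      any(p < 0) || any(q < 0)) {
    stop_config("inputs must be probability vectors over (A, C, G, T)")
  }
  max(abs(cumsum(p) - cumsum(q)))
}

#' Genotype-caller thresholds
#'
#' Two named bundles mirror the dual-threshold somatic compilation: `strict`
#' (fewer false positives) and `lenient` (fewer false negatives); every
#' strict threshold is at least as tight as its lenient counterpart. The
#' `hq_*` gates define the "high-quality homozygous reference" test applied
#' to the matched normal.
#'
#' @param profile `"strict"`, `"lenient"`, or `"custom"` (which starts from
#'   lenient values).
#' @param min_depth_total,min_depth_strand callable-depth gates (reads).
#' @param d_max maximum combined KS distance of a callable genotype.
#' @param hq_d_max,hq_min_depth,hq_max_alt_fraction high-quality hom-ref
#'   gates for the normal sample.
#' @param consensus_min_alt_per_strand,consensus_min_alt_fraction tumor
#'   Variant Consensus gates: minimum alt reads on *each* strand and minimum
#'   pooled alt fraction.
#' @return An object of class `snv_params`.
#' @export
snv_params <- function(profile = c("lenient", "strict", "custom"),
                       min_depth_total = NULL, min_depth_strand = NULL,
                       d_max = NULL, hq_d_max = 0.05, hq_min_depth = 8L,
                       hq_max_alt_fraction = 0.02,
                       consensus_min_alt_per_strand = NULL,
                       consensus_min_alt_fraction = NULL) {
  profile <- match.arg(profile)
  base <- if (profile == "strict") {
    list(min_depth_total = 10L, min_depth_strand = 3L, d_max = 0.10,
         consensus_min_alt_per_strand = 3L, consensus_min_alt_fraction = 0.10)
  } else {
    list(min_depth_total = 6L, min_depth_strand = 2L, d_max = 0.20,
         consensus_min_alt_per_strand = 2L, consensus_min_alt_fraction = 0.05)
  }
  p <- structure(list(
    profile = profile,
    min_depth_total = min_depth_total %||% base$min_depth_total,
    min_depth_strand = min_depth_strand %||% base$min_depth_strand,
    d_max = d_max %||% base$d_max,
    hq_d_max = hq_d_max, hq_min_depth = as.integer(hq_min_depth),
    hq_max_alt_fraction = hq_max_alt_fraction,
    consensus_min_alt_per_strand = consensus_min_alt_per_strand %||%
      base$consensus_min_alt_per_strand,
    consensus_min_alt_fraction = consensus_min_alt_fraction %||%
      base$consensus_min_alt_fraction
  ), class = "snv_params")
  with(p, {
    if (min_depth_total < 0 || min_depth_strand < 0 || d_max < 0 ||
        hq_d_max < 0 || hq_min_depth < 0)
      stop_config("snv thresholds must be >= 0")
    if (hq_max_alt_fraction < 0 || hq_max_alt_fraction > 1 ||
        consensus_min_alt_fraction < 0 || consensus_min_alt_fraction > 1)
      stop_config("fractions must be in [0, 1]")
  })
  p
}

column_counts <- function(column) {
  count1 <- function(d) {
    tab <- table(factor(d$base, levels = DNA_BASES))
    as.integer(tab)
  }
  keepACGT <- function(d) d[d$base %in% DNA_BASES, , drop = FALSE]
  fwd <- keepACGT(column$fwd)
  rev <- keepACGT(column$rev)
  list(cf = count1(fwd), cr = count1(rev),
       ef = if (nrow(fwd)) sum(10^(-fwd$qual / 10)) else 0,
       er = if (nrow(rev)) sum(10^(-rev$qual / 10)) else 0)
}

# KS distances of one strand's empirical distribution to all 10 genotype
# expectations. `counts` is a length-4 count vector, `e` the strand error
# rate.
strand_distances <- function(counts, e) {
  depth <- sum(counts)
  p <- counts / depth
  cp <- cumsum(p)
  vapply(seq_along(GENOTYPES), function(g) {
    q <- expected_base_distribution(c(GT_A1[g], GT_A2[g]), e)
    max(abs(cp - cumsum(q)))
  }, numeric(1))
}

# deterministic argmin: smallest distance, then fewer non-reference alleles,
# then lexicographic genotype order
best_genotype <- function(dists, ref) {
  nonref <- (GT_A1 != ref) + (GT_A2 != ref)
  ord <- order(dists, nonref, GENOTYPES)
  ord[1]
}

# core genotype computation from per-strand counts and error sums
genotype_core <- function(cf, ef_sum, cr, er_sum, ref, params) {
  df <- sum(cf); dr <- sum(cr)
  strands <- list()
  if (df >= 1) strands$fwd <- list(counts = cf, e = min(ef_sum / df, 0.999))
  if (dr >= 1) strands$rev <- list(counts = cr, e = min(er_sum / dr, 0.999))
  if (length(strands) == 0) {
    return(list(genotype = NA_character_, combined_dist = NA_real_,
                status = "low_depth", depth_fwd = df, depth_rev = dr,
                strand_best = character(0), strand_dist = numeric(0)))
  }
  dist_mat <- vapply(strands, function(s) strand_distances(s$counts, s$e),
                     numeric(length(GENOTYPES)))
  dist_mat <- matrix(dist_mat, nrow = length(GENOTYPES))
  sbest <- apply(dist_mat, 2, function(d) GENOTYPES[best_genotype(d, ref)])
  sdist <- vapply(seq_along(strands), function(j)
    min(dist_mat[, j]), numeric(1))
  # combined call: minimise the worst strand distance over strands that
  # meet the per-strand depth gate (all present strands if none does)
  use <- which(vapply(strands, function(s)
    sum(s$counts) >= params$min_depth_strand, logical(1)))
  if (length(use) == 0) use <- seq_along(strands)
  comb <- apply(dist_mat[, use, drop = FALSE], 1, max)
  gi <- best_genotype(comb, ref)
  genotype <- GENOTYPES[gi]
  combined <- comb[gi]

  callable <- (df + dr) >= params$min_depth_total &&
    df >= params$min_depth_strand && dr >= params$min_depth_strand &&
    combined <= params$d_max
  status <- if ((df + dr) < params$min_depth_total ||
                df < params$min_depth_strand ||
                dr < params$min_depth_strand) "low_depth"
  else if (combined > params$d_max) "ambiguous"
  else "callable"
  # both strands must provide evidence: a non-reference call stands only if
  # every strand's own best genotype contains the same non-reference allele
  nonref_alleles <- setdiff(unique(c(substr(genotype, 1, 1),
                                     substr(genotype, 2, 2))), ref)
  if (status == "callable" && length(nonref_alleles) > 0) {
    supported <- all(vapply(nonref_alleles, function(a)
      all(grepl(a, sbest, fixed = TRUE)), logical(1)))
    if (!supported) status <- "ambiguous"
  }
  list(genotype = genotype, combined_dist = combined, status = status,
       depth_fwd = df, depth_rev = dr,
       strand_best = setNames(sbest, names(strands)),
       strand_dist = setNames(sdist, names(strands)))
}

#' Call a diploid genotype from a trimmed pileup column
#'
#' For each strand the empirical base distribution is compared, via
#' [ks_distance()], to the expected distribution of all 10 unordered diploid
#' genotypes under that strand's mean error rate; the combined call
#' minimises the worst per-strand distance. A non-reference call is demoted
#' to `ambiguous` unless every strand's own best genotype contains the same
#' non-reference allele — both strands must provide evidence for the
#' variation.
#'
#' @param column a trimmed [pileup_column()] (zero-quality bases present
#'   raise an error; see [trim_zero_quality()]).
#' @param params an [snv_params()] bundle.
#' @return An object of class `genotype_call` with fields `genotype`,
#'   `combined_dist`, `status` (`callable`/`low_depth`/`ambiguous`),
#'   per-strand depths, best genotypes and distances.
#' @export
call_genotype <- function(column, params = snv_params()) {
  stopifnot(inherits(column, "pileup_column"))
  if (any(column$fwd$qual == 0) || any(column$rev$qual == 0))
    stop_config("column contains zero-quality bases; trim first")
  cc <- column_counts(column)
  core <- genotype_core(cc$cf, cc$ef, cc$cr, cc$er, column$ref, params)
  structure(c(list(chrom = column$chrom, pos = column$pos,
                   ref = column$ref), core),
            class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("genotype_call %s:%d %s (D=%.4g, %s, depth %d+/%d-)\n",
              x$chrom, x$pos, x$genotype %||% "NA",
              x$combined_dist, x$status, x$depth_fwd, x$depth_rev))
  invisible(x)
}

#' Is a normal-sample call a high-quality homozygous-reference genotype?
#'
#' The somatic gate on the matched normal: the call must be hom-ref and
#' callable, with combined distance, total depth and pooled non-reference
#' fraction inside the `hq_*` thresholds.
#'
#' @param call a [call_genotype()] result.
#' @param column the (trimmed) column the call was derived from.
#' @param params an [snv_params()] bundle.
#' @return `TRUE` or `FALSE`.
#' @export
is_high_quality_homref <- function(call, column, params = snv_params()) {
  stopifnot(inherits(call, "genotype_call"))
  cc <- column_counts(column)
  depth <- sum(cc$cf) + sum(cc$cr)
  if (depth == 0) return(FALSE)
  ref_i <- match(call$ref, DNA_BASES)
  alt_frac <- (depth - cc$cf[ref_i] - cc$cr[ref_i]) / depth
  !is.na(call$genotype) &&
    call$genotype == paste0(call$ref, call$ref) &&
    call$status == "callable" &&
    call$combined_dist <= params$hq_d_max &&
    depth >= params$hq_min_depth &&
    alt_frac <= params$hq_max_alt_fraction
}

consensus_core <- function(cf, cr, ref, params) {
  ref_i <- match(ref, DNA_BASES)
  pooled <- cf + cr
  pooled[ref_i] <- -1L
  ai <- which.max(pooled) # ties: first in A<C<G<T order
  alt_f <- cf[ai]; alt_r <- cr[ai]
  depth <- sum(cf) + sum(cr)
  if (depth == 0 || (alt_f + alt_r) == 0) return(NULL)
  frac <- (alt_f + alt_r) / depth
  if (alt_f >= params$consensus_min_alt_per_strand &&
      alt_r >= params$consensus_min_alt_per_strand &&
      frac >= params$consensus_min_alt_fraction) {
    list(alt = DNA_BASES[ai], alt_fwd = alt_f, alt_rev = alt_r,
         fraction = frac)
  } else NULL
}

#' Tumor Variant Consensus test on one pileup column
#'
#' The sensitivity-oriented tumor-side rule: report the most frequent
#' non-reference allele if it is supported by at least
#' `consensus_min_alt_per_strand` reads on each strand and reaches the
#' pooled `consensus_min_alt_fraction`.
#'
#' @param column a trimmed [pileup_column()].
#' @param params an [snv_params()] bundle.
#' @return `NULL`, or a list with `alt`, per-strand alt counts and the
#'   pooled fraction.
#' @export
tumor_variant_consensus <- function(column, params = snv_params()) {
  stopifnot(inherits(column, "pileup_column"))
  if (any(column$fwd$qual == 0) || any(column$rev$qual == 0))
    stop_config("column contains zero-quality bases; trim first")
  cc <- column_counts(column)
  consensus_core(cc$cf, cc$cr, column$ref, params)
}

#' Call somatic SNVs from matched tumor/normal pileups
#'
#' A locus is somatic when the tumor Variant Consensus fires *and* the
#' matched normal shows a high-quality homozygous-reference genotype. With
#' `profile = "both"` the union of the strict and lenient threshold sets is
#' returned with per-record provenance (`"strict"`, `"lenient"` or
#' `"both"`), mirroring a dual-threshold compilation.
#'
#' @param normal,tumor [pileup_from_records()] matrices, or lists of
#'   [pileup_column()] objects covering the same loci.
#' @param profile `"lenient"`, `"strict"` or `"both"`.
#' @param params optional [snv_params()] overriding the profile bundles
#'   (single-profile runs only).
#' @return A data.frame with one row per somatic SNV: locus, ref, alt,
#'   per-strand tumor alt counts and depths, pooled alt fraction, normal
#'   depth and KS distance, and profile provenance.
#' @export
call_somatic_snvs <- function(normal, tumor,
                              profile = c("lenient", "strict", "both"),
                              params = NULL) {
  profile <- match.arg(profile)
  profiles <- switch(profile,
    lenient = list(lenient = params %||% snv_params("lenient")),
    strict = list(strict = params %||% snv_params("strict")),
    both = list(strict = snv_params("strict"),
                lenient = snv_params("lenient")))
  if (inherits(normal, "pileup_matrix") && inherits(tumor, "pileup_matrix")) {
    if (!identical(normal$chrom_lengths, tumor$chrom_lengths))
      stop_config("normal and tumor pileups disagree on the reference")
    somatic_from_matrices(normal, tumor, profiles)
  } else if (is.list(normal) && is.list(tumor)) {
    somatic_from_columns(normal, tumor, profiles)
  } else {
    stop_config("normal and tumor must both be pileup matrices or column lists")
  }
}

empty_somatic_df <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), t_alt_fwd = integer(0),
             t_alt_rev = integer(0), t_depth_fwd = integer(0),
             t_depth_rev = integer(0), alt_fraction = numeric(0),
             n_depth = integer(0), n_dist = numeric(0),
             profile = character(0), stringsAsFactors = FALSE)
}

somatic_record <- function(chrom, pos, ref, cons, n_core, prov) {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             alt = cons$alt, t_alt_fwd = cons$alt_fwd,
             t_alt_rev = cons$alt_rev,
             t_depth_fwd = cons$depth_fwd, t_depth_rev = cons$depth_rev,
             alt_fraction = cons$fraction,
             n_depth = n_core$depth_fwd + n_core$depth_rev,
             n_dist = n_core$combined_dist, profile = prov,
             stringsAsFactors = FALSE)
}

somatic_from_columns <- function(normal, tumor, profiles) {
  key <- function(cols) vapply(cols, function(c)
    paste(c$chrom, c$pos), character(1))
  nk <- key(normal)
  out <- list()
  for (tc in tumor) {
    tc <- trim_zero_quality(tc)
    fired <- list()
    for (pn in names(profiles)) {
      cons <- tumor_variant_consensus(tc, profiles[[pn]])
      if (!is.null(cons)) fired[[pn]] <- cons
    }
    if (length(fired) == 0) next
    ni <- match(paste(tc$chrom, tc$pos), nk)
    if (is.na(ni)) next
    nc <- trim_zero_quality(normal[[ni]])
    hq_by <- vapply(names(fired), function(pn) {
      ncall <- call_genotype(nc, profiles[[pn]])
      is_high_quality_homref(ncall, nc, profiles[[pn]])
    }, logical(1))
    fired <- fired[hq_by]
    if (length(fired) == 0) next
    prov <- if (length(fired) == 2) "both" else names(fired)[1]
    cons <- fired[[length(fired)]] # lenient (or the only) consensus counts
    cc <- column_counts(tc)
    cons$depth_fwd <- sum(cc$cf); cons$depth_rev <- sum(cc$cr)
    ncall <- call_genotype(nc, profiles[[length(profiles)]])
    out[[length(out) + 1]] <-
      somatic_record(tc$chrom, tc$pos, tc$ref, cons, ncall, prov)
  }
  if (length(out) == 0) return(empty_somatic_df())
  do.call(rbind, out)
}

somatic_from_matrices <- function(normal, tumor, profiles) {
  out <- list()
  # the loosest profile drives candidate screening; stricter profiles are
  # re-evaluated per candidate
  loosest <- profiles[[length(profiles)]]
  for (chrom in names(tumor$chrom_lengths)) {
    tm <- tumor$chroms[[chrom]]
    refb <- strsplit(as.character(tumor$reference[[chrom]]), "")[[1]]
    ref_i <- match(refb, DNA_BASES)
    L <- length(ref_i)
    cf <- tm$counts[1:4, , drop = FALSE]
    cr <- tm$counts[5:8, , drop = FALSE]
    df <- colSums(cf); dr <- colSums(cr)
    depth <- df + dr
    # pooled non-reference counts; the reference row is excluded from the
    # argmax by masking it out
    pooled <- cf + cr
    pooled[cbind(ref_i, seq_len(L))] <- -1L
    ai <- max.col(t(pooled), ties.method = "first")
    sel <- cbind(ai, seq_len(L))
    alt_f <- cf[sel]; alt_r <- cr[sel]
    alt_tot <- alt_f + alt_r
    cand <- which(
      alt_f >= loosest$consensus_min_alt_per_strand &
      alt_r >= loosest$consensus_min_alt_per_strand &
      depth > 0 & alt_tot / pmax(depth, 1L) >=
        loosest$consensus_min_alt_fraction)
    for (pos in cand) {
      fired <- list()
      for (pn in names(profiles)) {
        cons <- consensus_core(cf[, pos], cr[, pos], refb[pos],
                               profiles[[pn]])
        if (!is.null(cons)) fired[[pn]] <- cons
      }
      if (length(fired) == 0) next
      nm <- matrix_column(normal, chrom, pos)
      if (sum(nm$cf) + sum(nm$cr) == 0) next
      hq <- vapply(names(fired), function(pn) {
        ncore <- genotype_core(nm$cf, nm$ef, nm$cr, nm$er, refb[pos],
                               profiles[[pn]])
        nref_i <- match(refb[pos], DNA_BASES)
        ndepth <- ncore$depth_fwd + ncore$depth_rev
        alt_frac <- (ndepth - nm$cf[nref_i] - nm$cr[nref_i]) / ndepth
        !is.na(ncore$genotype) &&
          ncore$genotype == paste0(refb[pos], refb[pos]) &&
          ncore$status == "callable" &&
          ncore$combined_dist <= profiles[[pn]]$hq_d_max &&
          ndepth >= profiles[[pn]]$hq_min_depth &&
          alt_frac <= profiles[[pn]]$hq_max_alt_fraction
      }, logical(1))
      fired <- fired[hq]
      if (length(fired) == 0) next
      prov <- if (length(fired) == 2) "both" else names(fired)[1]
      cons <- fired[[length(fired)]]
      cons$depth_fwd <- df[pos]; cons$depth_rev <- dr[pos]
      ncore <- genotype_core(nm$cf, nm$ef, nm$cr, nm$er, refb[pos],
                             loosest)
      out[[length(out) + 1]] <-
        somatic_record(chrom, pos, refb[pos], cons, ncore, prov)
    }
  }
  if (length(out) == 0) return(empty_somatic_df())
  res <- do.call(rbind, out)
  res[order(match(res$chrom, names(tumor$chrom_lengths)), res$pos), ,
      drop = FALSE]
}
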