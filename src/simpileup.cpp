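#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline int base_index(char b) {
  switch (b) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// Draw a phred quality from the configured normal model, clamped to [2, 41],
// with probability zero_frac replaced by 0 (zero-quality bases exist so the
// trimming rule is exercised downstream).
static inline int draw_quality(double qmean, double qsd, double zero_frac) {
  if (unif_rand() < zero_frac) return 0;
  int q = (int)std::lround(qmean + qsd * norm_rand());
  if (q < 2) q = 2;
  if (q > 41) q = 41;
  return q;
}

// Build aligned read sequences, base qualities and CIGARs for a set of reads
// on one chromosome. Indel ops and alt-allele substitutions are pre-drawn at
// the R level and passed as per-read assignments; this routine constructs the
// reference-oriented sequence (SAM convention), then injects miscalls at the
// error rate implied by each emitted base quality (capped at 0.75, i.e. a
// uniformly random base for quality 0).
//
// ops_*  : indel assignments, op_read is a 0-based read index (sorted).
// sub_*  : alt substitutions (ref position + alt base), sub_read 0-based.
// [[Rcpp::export]]
List cpp_make_reads(std::string ref,
                    IntegerVector starts,
                    int read_len,
                    IntegerVector op_read, IntegerVector op_pos,
                    IntegerVector op_type, IntegerVector op_len,
                    CharacterVector op_seq,
                    IntegerVector sub_read, IntegerVector sub_pos,
                    CharacterVector sub_alt,
                    double qmean, double qsd, double zero_frac) {
  const int n = starts.size();
  const long reflen = (long)ref.size();
  CharacterVector seq_out(n), qual_out(n), cigar_out(n);
  IntegerVector span_out(n);

  int oi = 0, si = 0;
  const int nop = op_read.size(), nsub = sub_read.size();
  std::string seq(read_len, 'N'), qual(read_len, '!');
  std::vector<long> refpos(read_len);
  std::string cigar;
  cigar.reserve(32);

  for (int r = 0; r < n; ++r) {
    long start = starts[r];
    long p = start;     // current reference position
    int i = 0;          // read offset
    cigar.clear();
    int run_m = 0;

    // indel ops assigned to this read, ordered by position
    while (i < read_len) {
      bool applied = false;
      if (oi < nop && op_read[oi] == r) {
        long opos = op_pos[oi];
        if (p == opos) {
          if (run_m > 0) { cigar += std::to_string(run_m); cigar += 'M'; run_m = 0; }
          int l = op_len[oi];
          if (op_type[oi] == 0) { // insertion before ref position opos
            std::string ins = as<std::string>(op_seq[oi]);
            for (int k = 0; k < l && i < read_len; ++k) {
              seq[i] = ins[k]; refpos[i] = -1; ++i;
            }
            cigar += std::to_string(l); cigar += 'I';
          } else {                // deletion of ref[opos .. opos+l)
            p += l;
            cigar += std::to_string(l); cigar += 'D';
          }
          ++oi;
          applied = true;
        }
      }
      if (!applied) {
        if (p >= reflen) break;
        seq[i] = ref[p]; refpos[i] = p;
        ++i; ++p; ++run_m;
      }
    }
    if (run_m > 0) { cigar += std::to_string(run_m); cigar += 'M'; }
    // skip any remaining ops assigned to this read (op fell past read end)
    while (oi < nop && op_read[oi] == r) ++oi;
    int used = i;
    for (; i < read_len; ++i) { seq[i] = 'N'; refpos[i] = -1; }

    // alt-allele substitutions at matched reference positions
    while (si < nsub && sub_read[si] == r) {
      long vp = sub_pos[si];
      char alt = as<std::string>(sub_alt[si])[0];
      for (int k = 0; k < used; ++k) {
        if (refpos[k] == vp) { seq[k] = alt; break; }
      }
      ++si;
    }

    // qualities and quality-implied miscalls
    for (int k = 0; k < used; ++k) {
      int q = draw_quality(qmean, qsd, zero_frac);
      qual[k] = (char)(33 + q);
      double err = (q == 0) ? 0.75 : std::pow(10.0, -q / 10.0);
      if (err > 0.75) err = 0.75;
      if (unif_rand() < err) {
        int bi = base_index(seq[k]);
        if (bi >= 0) {
          int nb = (int)(unif_rand() * 3.0); if (nb > 2) nb = 2;
          if (nb >= bi) ++nb;
          seq[k] = BASES[nb];
        }
      }
    }

    seq_out[r] = seq.substr(0, used);
    qual_out[r] = qual.substr(0, used);
    cigar_out[r] = cigar;
    span_out[r] = (int)(p - start);
  }

  return List::create(_["seq"] = seq_out, _["qual"] = qual_out,
                      _["cigar"] = cigar_out, _["span"] = span_out);
}

// Accumulate per-strand pileup base counts and error-probability sums over a
// chromosome. Zero-quality bases are trimmed (excluded) here, matching the
// caller's contract that comparisons see trimmed pileups only; N bases are
// dropped likewise. Rows of `counts`: A,C,G,T forward then A,C,G,T reverse.
// `errsum` rows: forward, reverse sums of 10^(-Q/10) over retained bases.
// [[Rcpp::export]]
List cpp_pileup_counts(IntegerVector starts, IntegerVector strand,
                       CharacterVector seqs, CharacterVector quals,
                       CharacterVector cigars, int chrom_len) {
  IntegerMatrix counts(8, chrom_len);
  NumericMatrix errsum(2, chrom_len);
  const int n = starts.size();

  for (int r = 0; r < n; ++r) {
    long p = starts[r];
    const char *s = CHAR(STRING_ELT(seqs, r));
    const char *q = CHAR(STRING_ELT(quals, r));
    const char *c = CHAR(STRING_ELT(cigars, r));
    int i = 0;
    int srow = (strand[r] == 0) ? 0 : 4;
    int erow = (strand[r] == 0) ? 0 : 1;
    while (*c) {
      int len = 0;
      while (*c >= '0' && *c <= '9') { len = len * 10 + (*c - '0'); ++c; }
      char op = *c ? *c++ : 'M';
      if (op == 'M' || op == '=' || op == 'X') {
        for (int k = 0; k < len; ++k, ++i, ++p) {
          if (p < 0 || p >= chrom_len) continue;
          int qv = q[i] - 33;
          if (qv <= 0) continue; // zero-quality trim
          int bi = base_index(s[i]);
          if (bi < 0) continue;
          counts(srow + bi, p) += 1;
          errsum(erow, p) += std::pow(10.0, -qv / 10.0);
        }
      } else if (op == 'D' || op == 'N') {
        p += len;
      } else if (op == 'I' || op == 'S') {
        i += len;
      }
    }
  }
  return List::create(_["counts"] = counts, _["errsum"] = errsum);
}
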