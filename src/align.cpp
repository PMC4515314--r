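#include <Rcpp.h>
using namespace Rcpp;

// Ungapped exhaustive aligner over small genomes.  Each contig is given as
// its base string plus a parallel "alternate" string carrying the sidecar
// allele at catalogued variant positions ('.' elsewhere).  A read base at a
// sidecar position counts as a match when it equals the genome base or, in
// allele-aware mode, the sidecar base.  'N' never matches.

static inline char complement_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

struct Placement {
  int contig;
  int pos;     // 0-based
  bool fwd;
  int mm;
};

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads,
                     CharacterVector contigs,
                     CharacterVector alt_masks,
                     int max_mismatch,
                     bool allele_aware) {
  const int n_reads = reads.size();
  const int n_contigs = contigs.size();

  std::vector<std::string> genome(n_contigs), alts(n_contigs);
  for (int c = 0; c < n_contigs; ++c) {
    genome[c] = as<std::string>(contigs[c]);
    alts[c] = as<std::string>(alt_masks[c]);
  }

  IntegerVector out_status(n_reads);     // 0 unique, 1 multimapped, 2 unmapped
  IntegerVector out_contig(n_reads, NA_INTEGER);
  IntegerVector out_pos(n_reads, NA_INTEGER);
  LogicalVector out_fwd(n_reads, NA_LOGICAL);
  IntegerVector out_mm(n_reads, NA_INTEGER);

  for (int r = 0; r < n_reads; ++r) {
    std::string fw = as<std::string>(reads[r]);
    const int L = fw.size();
    std::string rc(L, 'N');
    for (int j = 0; j < L; ++j) rc[L - 1 - j] = complement_base(fw[j]);

    int best = max_mismatch + 1;
    int n_best = 0;
    Placement bp = {0, 0, true, 0};

    for (int c = 0; c < n_contigs; ++c) {
      const std::string &G = genome[c];
      const std::string &A = alts[c];
      const int glen = G.size();
      if (L > glen) continue;
      for (int s = 0; s + L <= glen; ++s) {
        for (int strand = 0; strand < 2; ++strand) {
          const std::string &rd = strand == 0 ? fw : rc;
          int mm = 0;
          for (int j = 0; j < L; ++j) {
            const char rb = rd[j];
            const char gb = G[s + j];
            bool match = (rb == gb && rb != 'N');
            if (!match && allele_aware) {
              const char ab = A[s + j];
              if (ab != '.' && rb == ab && rb != 'N') match = true;
            }
            if (!match && ++mm > max_mismatch) break;
          }
          if (mm <= max_mismatch) {
            if (mm < best) {
              best = mm;
              n_best = 1;
              bp = {c, s, strand == 0, mm};
            } else if (mm == best) {
              ++n_best;
            }
          }
        }
      }
    }

    if (n_best == 0) {
      out_status[r] = 2;
    } else if (n_best > 1) {
      out_status[r] = 1;
      out_mm[r] = best;
    } else {
      out_status[r] = 0;
      out_contig[r] = bp.contig + 1;
      out_pos[r] = bp.pos;
      out_fwd[r] = bp.fwd;
      out_mm[r] = bp.mm;
    }
  }

  return List::create(_["status"] = out_status,
                      _["contig"] = out_contig,
                      _["pos0"] = out_pos,
                      _["forward"] = out_fwd,
                      _["mismatches"] = out_mm);
}
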