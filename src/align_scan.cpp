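#include <Rcpp.h>
#include <array>
using namespace Rcpp;

// Ungapped end-to-end scan of every read against every reference sequence,
// both orientations, all offsets (Bowtie-1 "-v" semantics). Only the
// minimum-mismatch stratum is kept per read; a stratum larger than max_hits
// suppresses the read. Offsets are 0-based here; the R wrapper converts.
//
// status per read: 0 = unaligned, 1 = aligned (stratum emitted),
//                  2 = suppressed (stratum size > max_hits).
// [[Rcpp::export]]
List scan_align(CharacterVector reads, CharacterVector reads_rc,
                CharacterVector refs, int max_mismatch, int max_hits) {
  const int n_reads = reads.size();
  const int n_refs = refs.size();
  std::vector<std::string> R(n_refs);
  for (int j = 0; j < n_refs; ++j) R[j] = as<std::string>(refs[j]);

  IntegerVector status(n_reads);
  IntegerVector best_nmm(n_reads, NA_INTEGER);
  IntegerVector stratum_size(n_reads, 0);
  std::vector<int> out_read, out_ref, out_off, out_rc, out_nmm;

  for (int i = 0; i < n_reads; ++i) {
    const std::string fw = as<std::string>(reads[i]);
    const std::string rc = as<std::string>(reads_rc[i]);
    const int L = (int)fw.size();
    int best = max_mismatch + 1;
    std::vector<std::array<int, 3>> hits;  // ref, offset, is_rc

    if (L > 0) {
      for (int ori = 0; ori < 2; ++ori) {
        const std::string &rd = ori ? rc : fw;
        for (int j = 0; j < n_refs; ++j) {
          const std::string &rf = R[j];
          const int RL = (int)rf.size();
          for (int o = 0; o + L <= RL; ++o) {
            int mm = 0;
            for (int k = 0; k < L; ++k) {
              if (rd[k] != rf[o + k]) {
                if (++mm > best) break;
              }
            }
            if (mm <= max_mismatch && mm <= best) {
              if (mm < best) {
                best = mm;
                hits.clear();
              }
              hits.push_back({j, o, ori});
            }
          }
        }
      }
    }

    if (hits.empty()) {
      status[i] = 0;
    } else {
      best_nmm[i] = best;
      stratum_size[i] = (int)hits.size();
      if ((int)hits.size() > max_hits) {
        status[i] = 2;
      } else {
        status[i] = 1;
        for (const auto &h : hits) {
          out_read.push_back(i + 1);
          out_ref.push_back(h[0] + 1);
          out_off.push_back(h[1]);
          out_rc.push_back(h[2]);
          out_nmm.push_back(best);
        }
      }
    }
  }

  return List::create(
      _["status"] = status, _["best_nmm"] = best_nmm,
      _["stratum_size"] = stratum_size, _["read"] = wrap(out_read),
      _["ref"] = wrap(out_ref), _["offset"] = wrap(out_off),
      _["is_rc"] = wrap(out_rc), _["nmm"] = wrap(out_nmm));
}
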