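#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Mismatch-tolerant matching of junction probe cores against reads.
//
// A read supports a probe core (width W) if some read offset aligns the whole
// core with at most max_mm mismatches; any non-ACGT base (N) counts as a
// mismatch. Matching is exact-by-pigeonhole: the core is split into
// (max_mm + 1) contiguous segments, so any qualifying alignment must contain
// at least one segment matching exactly. Segments are indexed in direct-address
// tables of 2-bit codes; each read offset costs (max_mm + 1) table lookups and
// candidate hits are verified over the full core.

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".match_probe_cores")]]
List match_probe_cores(CharacterVector reads, CharacterVector cores,
                       int max_mm) {
  const int n_reads = reads.size();
  const int n_cores = cores.size();
  std::vector<int> hit_read, hit_core;
  if (n_cores == 0 || n_reads == 0)
    return List::create(_["read"] = IntegerVector(0),
                        _["core"] = IntegerVector(0));

  const int W = LENGTH(STRING_ELT(cores, 0));
  for (int i = 1; i < n_cores; ++i)
    if (LENGTH(STRING_ELT(cores, i)) != W)
      stop("all probe cores must have equal width");
  if (max_mm < 0) stop("max_mm must be >= 0");
  const int n_seg = max_mm + 1;
  if (W < n_seg) stop("core width must be at least max_mm + 1");

  // segment layout: as even as possible, longer segments first
  std::vector<int> seg_off(n_seg), seg_len(n_seg);
  {
    int base = W / n_seg, extra = W % n_seg, off = 0;
    for (int s = 0; s < n_seg; ++s) {
      seg_len[s] = base + (s < extra ? 1 : 0);
      if (seg_len[s] > 12) stop("segment length > 12 unsupported");
      seg_off[s] = off;
      off += seg_len[s];
    }
  }

  // encode cores; build one direct-address table per segment
  std::vector< std::vector<int8_t> > core_enc(n_cores,
                                              std::vector<int8_t>(W));
  std::vector< std::vector< std::vector<int> > > tables(n_seg);
  for (int s = 0; s < n_seg; ++s)
    tables[s].assign(size_t(1) << (2 * seg_len[s]), std::vector<int>());
  for (int i = 0; i < n_cores; ++i) {
    const char *p = CHAR(STRING_ELT(cores, i));
    for (int j = 0; j < W; ++j) core_enc[i][j] = (int8_t) base_code(p[j]);
    for (int s = 0; s < n_seg; ++s) {
      unsigned code = 0;
      bool ok = true;
      for (int j = 0; j < seg_len[s]; ++j) {
        int b = core_enc[i][seg_off[s] + j];
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (unsigned) b;
      }
      if (ok) tables[s][code].push_back(i);
    }
  }

  std::vector<int8_t> enc;          // per-read base codes
  std::vector<char> matched(n_cores, 0);
  std::vector<int> touched;

  for (int r = 0; r < n_reads; ++r) {
    SEXP rs = STRING_ELT(reads, r);
    const int L = LENGTH(rs);
    if (L < W) continue;
    const char *rp = CHAR(rs);
    enc.resize(L);
    for (int j = 0; j < L; ++j) enc[j] = (int8_t) base_code(rp[j]);
    touched.clear();

    for (int p = 0; p + W <= L; ++p) {
      for (int s = 0; s < n_seg; ++s) {
        unsigned code = 0;
        bool ok = true;
        const int o = p + seg_off[s];
        for (int j = 0; j < seg_len[s]; ++j) {
          int b = enc[o + j];
          if (b < 0) { ok = false; break; }
          code = (code << 2) | (unsigned) b;
        }
        if (!ok) continue;
        const std::vector<int> &cand = tables[s][code];
        for (size_t t = 0; t < cand.size(); ++t) {
          const int ci = cand[t];
          if (matched[ci]) continue;
          int mm = 0;
          const int8_t *ce = core_enc[ci].data();
          for (int j = 0; j < W; ++j) {
            if (enc[p + j] != ce[j] || ce[j] < 0) {
              if (++mm > max_mm) break;
            }
          }
          if (mm <= max_mm) {
            matched[ci] = 1;
            touched.push_back(ci);
            hit_read.push_back(r + 1);
            hit_core.push_back(ci + 1);
          }
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) matched[touched[t]] = 0;
  }

  return List::create(_["read"] = wrap(hit_read),
                      _["core"] = wrap(hit_core));
}
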