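#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches, even against another 4.
static inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline uint8_t comp_code(uint8_t b) {
  return b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
}

// splitmix64: per-read deterministic stream, independent of batch order.
static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double runif01(uint64_t& state) {
  return (double)(splitmix64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t fnv1a(const char* s) {
  uint64_t h = 1469598103934665603ULL;
  for (; *s; ++s) {
    h ^= (uint8_t)(*s);
    h *= 1099511628211ULL;
  }
  return h;
}

static std::vector<uint8_t> encode_seq(const char* s) {
  std::vector<uint8_t> v;
  for (; *s; ++s) v.push_back(base_code(*s));
  return v;
}

// Ungapped end-to-end up-to-k-mismatch best-hit alignment of each read
// against both strands of every reference. Among placements in the best
// mismatch stratum one is chosen uniformly at random via reservoir
// sampling, with the RNG keyed by (read_id, seed) so results do not
// depend on batch composition or order.
// [[Rcpp::export(name = ".align_batch_cpp")]]
List align_batch_cpp(CharacterVector ref_seqs, CharacterVector read_ids,
                     CharacterVector read_seqs, int k, double seed) {
  const int n_ref = ref_seqs.size();
  const int n_read = read_ids.size();
  std::vector<std::vector<uint8_t> > refs(n_ref);
  for (int r = 0; r < n_ref; ++r) refs[r] = encode_seq(CHAR(STRING_ELT(ref_seqs, r)));

  IntegerVector out_ref(n_read, NA_INTEGER);
  IntegerVector out_pos(n_read, NA_INTEGER);
  IntegerVector out_strand(n_read, NA_INTEGER);  // 0 = "+", 1 = "-"
  IntegerVector out_mm(n_read, NA_INTEGER);
  IntegerVector out_len(n_read, NA_INTEGER);

  const uint64_t seed64 = (uint64_t)((int64_t)seed);

  for (int i = 0; i < n_read; ++i) {
    std::vector<uint8_t> fwd = encode_seq(CHAR(STRING_ELT(read_seqs, i)));
    const int w = (int)fwd.size();
    out_len[i] = w;
    if (w == 0) continue;
    std::vector<uint8_t> rc(w);
    for (int j = 0; j < w; ++j) rc[j] = comp_code(fwd[w - 1 - j]);

    uint64_t state = fnv1a(CHAR(STRING_ELT(read_ids, i))) ^
                     (seed64 * 0x9E3779B97F4A7C15ULL + 0x632BE59BD9B4E019ULL);
    splitmix64(state);  // burn-in mixes id hash with seed

    int best = k + 1, tie = 0;
    int b_ref = -1, b_pos = -1, b_strand = 0;

    for (int r = 0; r < n_ref; ++r) {
      const std::vector<uint8_t>& ref = refs[r];
      const int L = (int)ref.size();
      if (L < w) continue;
      for (int strand = 0; strand < 2; ++strand) {
        const uint8_t* q = strand ? rc.data() : fwd.data();
        for (int p = 0; p + w <= L; ++p) {
          const int bound = best <= k ? best : k;
          int mm = 0;
          const uint8_t* rp = ref.data() + p;
          for (int j = 0; j < w; ++j) {
            const uint8_t a = rp[j], b = q[j];
            if (a != b || a > 3) {
              if (++mm > bound) break;
            }
          }
          if (mm > bound) continue;
          if (mm < best) {
            best = mm; tie = 1;
            b_ref = r; b_pos = p; b_strand = strand;
          } else {  // mm == best: reservoir-sample uniformly over ties
            ++tie;
            if (runif01(state) < 1.0 / (double)tie) {
              b_ref = r; b_pos = p; b_strand = strand;
            }
          }
        }
      }
    }

    if (best <= k) {
      out_ref[i] = b_ref + 1;  // 1-based index into ref_seqs
      out_pos[i] = b_pos;      // 0-based offset on + strand
      out_strand[i] = b_strand;
      out_mm[i] = best;
    }
  }

  return List::create(_["ref"] = out_ref, _["pos"] = out_pos,
                      _["strand"] = out_strand, _["mismatches"] = out_mm,
                      _["read_len"] = out_len);
}

// End-anchored adapter search: smallest i such that read[i..end] matches a
// prefix of the adapter with mismatches <= floor(rate * overlap) and
// overlap >= min_overlap. Returns the insert length i, or -1 when unmatched.
// [[Rcpp::export(name = ".trim_adapter_batch_cpp")]]
IntegerVector trim_adapter_batch_cpp(CharacterVector seqs, std::string adapter,
                                     int min_overlap, double rate) {
  const int n = seqs.size();
  const int alen = (int)adapter.size();
  std::vector<uint8_t> ad = encode_seq(adapter.c_str());
  IntegerVector out(n, -1);
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> s = encode_seq(CHAR(STRING_ELT(seqs, i)));
    const int len = (int)s.size();
    const int i_min = len - alen > 0 ? len - alen : 0;
    const int i_max = len - min_overlap;
    for (int ins = i_min; ins <= i_max; ++ins) {
      const int ov = len - ins;
      const int allowed = (int)std::floor(rate * ov);
      int mm = 0;
      for (int j = 0; j < ov; ++j) {
        const uint8_t a = s[ins + j], b = ad[j];
        if (a != b || a > 3) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) { out[i] = ins; break; }
    }
  }
  return out;
}
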