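#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Alignment model: a read is placed on the window at an offset with at most one
// internal deletion gap (gap length 0 = ungapped). Every read base is either a
// match (+1) or mismatch (-2), so score = nr - 3 * mismatches. Ties are broken
// by smallest offset, then smallest gap start (0 for ungapped), then smallest
// gap length. 'N' (or any non-ACGT symbol) matches nothing, including itself.

static const uint8_t CODE_N = 4;

static std::vector<uint8_t> encode_dna(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
    case 'A': case 'a': v[i] = 0; break;
    case 'C': case 'c': v[i] = 1; break;
    case 'G': case 'g': v[i] = 2; break;
    case 'T': case 't': v[i] = 3; break;
    default: v[i] = CODE_N;
    }
  }
  return v;
}

static inline bool base_match(uint8_t a, uint8_t b) {
  return a == b && a != CODE_N;
}

struct Aln {
  bool aligned = false;
  int offset = -1;    // 0-based start of the read on the window
  int gap_start = 0;  // read bases consumed before the gap; 0 = ungapped
  int gap_len = 0;
  int mism = 0;
  int score = 0;
};

// candidate comparator: better score first, then smallest offset / gap_start / gap_len
static inline bool better(int score, int off, int g, int l, const Aln& cur) {
  if (!cur.aligned) return true;
  if (score != cur.score) return score > cur.score;
  if (off != cur.offset) return off < cur.offset;
  if (g != cur.gap_start) return g < cur.gap_start;
  return l < cur.gap_len;
}

// cumulative mismatches of read[0..i) placed at window offset o
static void mism_prefix(const std::vector<uint8_t>& win,
                        const std::vector<uint8_t>& rd,
                        int o, std::vector<int>& out) {
  int nr = (int) rd.size();
  out.resize(nr + 1);
  out[0] = 0;
  for (int i = 0; i < nr; ++i)
    out[i + 1] = out[i] + (base_match(win[o + i], rd[i]) ? 0 : 1);
}

static Aln exact_split_align(const std::vector<uint8_t>& win,
                             const std::vector<uint8_t>& rd,
                             int max_del) {
  int nw = (int) win.size(), nr = (int) rd.size();
  int max_off = nw - nr; // largest offset at which the read (one segment) fits
  Aln best;
  if (max_off < 0) return best;
  // prefix-mismatch arrays for every offset, computed once
  std::vector<std::vector<int>> M(max_off + 1);
  for (int o = 0; o <= max_off; ++o) mism_prefix(win, rd, o, M[o]);
  for (int o = 0; o <= max_off; ++o) {
    // ungapped candidate (gap_start 0, gap_len 0)
    int mm = M[o][nr];
    int sc = nr - 3 * mm;
    if (better(sc, o, 0, 0, best))
      best = {true, o, 0, 0, mm, sc};
    // single internal gap: read = rd[0..g) + rd[g..nr), suffix shifted by l
    for (int g = 1; g <= nr - 1; ++g) {
      for (int l = 1; l <= max_del && o + l <= max_off; ++l) {
        int m2 = M[o][g] + M[o + l][nr] - M[o + l][g];
        int s2 = nr - 3 * m2;
        if (better(s2, o, g, l, best))
          best = {true, o, g, l, m2, s2};
      }
    }
  }
  return best;
}

static IntegerVector aln_to_vec(const Aln& a) {
  return IntegerVector::create(
    _["aligned"] = a.aligned ? 1 : 0, _["offset"] = a.offset,
    _["gap_start"] = a.gap_start, _["gap_len"] = a.gap_len,
    _["mismatches"] = a.mism, _["score"] = a.score);
}

// [[Rcpp::export]]
IntegerVector cpp_split_align_exact(std::string window, std::string read,
                                    int max_del, int min_score) {
  std::vector<uint8_t> win = encode_dna(window), rd = encode_dna(read);
  Aln best = exact_split_align(win, rd, max_del);
  if (best.aligned && best.score < min_score) best.aligned = false;
  return aln_to_vec(best);
}

// ---------------------------------------------------------------------------
// Seeded read mapper. Exact k-mer seeds propose candidate offsets; candidates
// are evaluated ungapped and as single-gap splits between candidate offset
// pairs; reads that no candidate explains fall back to the exhaustive search.

struct SeedIndex {
  int k;
  std::unordered_map<uint32_t, std::vector<int>> pos;
};

static bool pack_kmer(const std::vector<uint8_t>& s, int at, int k, uint32_t& key) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    uint8_t c = s[at + i];
    if (c == CODE_N) return false;
    v = (v << 2) | c;
  }
  key = v;
  return true;
}

static SeedIndex build_index(const std::vector<uint8_t>& win, int k) {
  SeedIndex idx;
  idx.k = k;
  for (int i = 0; i + k <= (int) win.size(); ++i) {
    uint32_t key;
    if (pack_kmer(win, i, k, key)) idx.pos[key].push_back(i);
  }
  return idx;
}

static int ungapped_mism_capped(const std::vector<uint8_t>& win,
                                const std::vector<uint8_t>& rd,
                                int o, int cap) {
  int nr = (int) rd.size(), mm = 0;
  for (int i = 0; i < nr; ++i) {
    if (!base_match(win[o + i], rd[i]) && ++mm > cap) return mm;
  }
  return mm;
}

// [[Rcpp::export]]
IntegerMatrix cpp_map_reads(std::string window, CharacterVector reads,
                            int max_del, int seed_k, int seed_step,
                            int accept_ungapped_mm,
                            double min_score_frac) {
  std::vector<uint8_t> win = encode_dna(window);
  int nw = (int) win.size();
  SeedIndex idx = build_index(win, seed_k);
  int n = reads.size();
  IntegerMatrix out(n, 6);
  colnames(out) = CharacterVector::create("aligned", "offset", "gap_start",
                                          "gap_len", "mismatches", "score");
  for (int r = 0; r < n; ++r) {
    std::string rs = as<std::string>(reads[r]);
    std::vector<uint8_t> rd = encode_dna(rs);
    int nr = (int) rd.size();
    int max_off = nw - nr;
    Aln best;
    if (max_off < 0) { out(r, 0) = 0; continue; }
    int min_score = (int) std::ceil(min_score_frac * nr);

    // 1. candidate offsets from spaced exact seeds
    std::vector<int> cand;
    for (int p = 0; p <= nr - seed_k; p += seed_step) {
      uint32_t key;
      if (!pack_kmer(rd, p, seed_k, key)) continue;
      auto it = idx.pos.find(key);
      if (it == idx.pos.end()) continue;
      for (int wp : it->second) {
        int o = wp - p;
        if (o >= 0 && o <= max_off) cand.push_back(o);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    // 2. ungapped screen over candidates
    int best_mm = nr + 1;
    for (int o : cand) {
      int mm = ungapped_mism_capped(win, rd, o, best_mm);
      int sc = nr - 3 * mm;
      if (better(sc, o, 0, 0, best)) best = {true, o, 0, 0, mm, sc};
      if (mm < best_mm) best_mm = mm;
    }
    if (best.aligned && best.mism <= accept_ungapped_mm) {
      out(r, 0) = 1; out(r, 1) = best.offset; out(r, 2) = 0; out(r, 3) = 0;
      out(r, 4) = best.mism; out(r, 5) = best.score;
      continue;
    }

    // 3. split search. Stage one scans seed-evidenced offset pairs (a real
    // junction read normally has seeds on both sides of the gap). Stage two
    // sweeps every gap length at every candidate offset; it exists for
    // junction reads whose short overhang carries no seed, so it is skipped
    // when a near-perfect ungapped placement already explains the read and
    // no offset pair hints at a junction.
    std::map<int, std::vector<int>> pref; // offset -> prefix mismatch array
    auto get_pref = [&](int o) -> std::vector<int>& {
      auto& A = pref[o];
      if (A.empty()) mism_prefix(win, rd, o, A);
      return A;
    };
    auto scan_pair = [&](int o1, int l) {
      if (o1 < 0 || o1 + l > max_off) return;
      auto& A1 = get_pref(o1);
      auto& A2 = get_pref(o1 + l);
      for (int g = 1; g <= nr - 1; ++g) {
        int mm = A1[g] + A2[nr] - A2[g];
        int sc = nr - 3 * mm;
        if (better(sc, o1, g, l, best)) best = {true, o1, g, l, mm, sc};
      }
    };
    for (size_t a = 0; a < cand.size(); ++a) {
      for (size_t b = a + 1; b < cand.size(); ++b) {
        int l = cand[b] - cand[a];
        if (l >= 1 && l <= max_del) scan_pair(cand[a], l);
      }
    }
    if (!best.aligned || (best.gap_len == 0 && best.mism > 2)) {
      for (int o : cand) {
        for (int l = 1; l <= max_del; ++l) {
          scan_pair(o, l);     // candidate as left-segment offset
          scan_pair(o - l, l); // candidate as right-segment offset
        }
      }
    }
    if (best.aligned && best.score >= min_score) {
      out(r, 0) = 1; out(r, 1) = best.offset; out(r, 2) = best.gap_start;
      out(r, 3) = best.gap_len; out(r, 4) = best.mism; out(r, 5) = best.score;
      continue;
    }

    // 4. exhaustive fallback for reads the seeds could not place
    Aln ex = exact_split_align(win, rd, max_del);
    if (ex.aligned && ex.score >= min_score) {
      out(r, 0) = 1; out(r, 1) = ex.offset; out(r, 2) = ex.gap_start;
      out(r, 3) = ex.gap_len; out(r, 4) = ex.mism; out(r, 5) = ex.score;
    } else {
      out(r, 0) = 0;
    }
  }
  return out;
}
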