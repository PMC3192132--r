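#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Ungapped seed-and-verify Hamming matcher shared by the read mapper and the
// flank search. Seeds are exact k-mers; k is capped at L/(max_mm+1) so that
// any fully-contained placement with <= max_mm mismatches is guaranteed to
// contain at least one clean seed (pigeonhole). N (or any non-ACGT symbol)
// always counts as a mismatch, so a clean seed never contains N.

static inline uint8_t enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> encode(const std::string& s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp(const std::vector<uint8_t>& v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

static inline bool mm_at(uint8_t a, uint8_t b) {
  return a != b || a == 4 || b == 4;
}

// Hamming distance of q placed at t[start..]; early exit above cap.
static int ham(const std::vector<uint8_t>& q, const std::vector<uint8_t>& t,
               int start, int cap) {
  int d = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (mm_at(q[i], t[start + i])) {
      if (++d > cap) return d;
    }
  }
  return d;
}

static std::string mm_offsets_str(const std::vector<uint8_t>& q,
                                  const std::vector<uint8_t>& t, int start) {
  std::string out;
  for (size_t i = 0; i < q.size(); ++i) {
    if (mm_at(q[i], t[start + i])) {
      if (!out.empty()) out += ",";
      out += std::to_string(start + (int)i);
    }
  }
  return out;
}

struct KmerIndex {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map;
};

static KmerIndex build_index(const std::vector<std::vector<uint8_t>>& targets, int k) {
  KmerIndex idx;
  idx.k = k;
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t ti = 0; ti < targets.size(); ++ti) {
    const std::vector<uint8_t>& t = targets[ti];
    if ((int)t.size() < k) continue;
    uint64_t key = 0;
    int run = 0;  // valid (non-N) bases accumulated
    for (size_t p = 0; p < t.size(); ++p) {
      if (t[p] == 4) { run = 0; key = 0; continue; }
      key = ((key << 2) | t[p]) & mask;
      if (++run >= k) {
        idx.map[key].push_back(std::make_pair((int)ti, (int)(p - k + 1)));
      }
    }
  }
  return idx;
}

// Collect candidate placements (target, start) for one oriented query via the
// index; caller verifies. Seeds at offsets j*k for j = 0..max_mm.
static void seed_candidates(const std::vector<uint8_t>& q, const KmerIndex& idx,
                            const std::vector<int>& tlen, int max_mm,
                            std::vector<std::pair<int,int>>& out) {
  int k = idx.k;
  int L = (int)q.size();
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int j = 0; j <= max_mm; ++j) {
    int off = j * k;
    if (off + k > L) break;
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      if (q[off + i] == 4) { ok = false; break; }
      key = ((key << 2) | q[off + i]) & mask;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<std::pair<int,int>>>::const_iterator
      it = idx.map.find(key);
    if (it == idx.map.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h) {
      int ti = it->second[h].first;
      int start = it->second[h].second - off;
      if (start < 0 || start + L > tlen[ti]) continue;
      out.push_back(std::make_pair(ti, start));
    }
  }
}

struct Placement {
  int target;    // 0-based
  int start;     // 0-based
  bool fwd;      // query orientation
  int n_mm;
};

// All placements of q (both orientations) with distance <= max_mm.
static std::vector<Placement> placements_for(
    const std::vector<uint8_t>& qf,
    const std::vector<std::vector<uint8_t>>& targets,
    const std::vector<int>& tlen,
    int max_mm, const KmerIndex* idx) {
  std::vector<Placement> res;
  std::vector<uint8_t> qr = revcomp(qf);
  for (int ori = 0; ori < 2; ++ori) {
    const std::vector<uint8_t>& q = ori == 0 ? qf : qr;
    std::vector<std::pair<int,int>> cand;
    if (idx) {
      seed_candidates(q, *idx, tlen, max_mm, cand);
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
    } else {
      for (size_t ti = 0; ti < targets.size(); ++ti)
        for (int s = 0; s + (int)q.size() <= tlen[ti]; ++s)
          cand.push_back(std::make_pair((int)ti, s));
    }
    for (size_t c = 0; c < cand.size(); ++c) {
      int d = ham(q, targets[cand[c].first], cand[c].second, max_mm);
      if (d <= max_mm) {
        Placement p;
        p.target = cand[c].first;
        p.start = cand[c].second;
        p.fwd = (ori == 0);
        p.n_mm = d;
        res.push_back(p);
      }
    }
  }
  return res;
}

static std::vector<std::vector<uint8_t>> encode_all(const CharacterVector& x) {
  std::vector<std::vector<uint8_t>> v(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) v[i] = encode(as<std::string>(x[i]));
  return v;
}

static int pick_k(int min_qlen, int max_mm, int seed_k) {
  int k = min_qlen / (max_mm + 1);
  if (k > seed_k) k = seed_k;
  if (k > 31) k = 31;
  return k;
}

// [[Rcpp::export]]
DataFrame cpp_hamming_all(CharacterVector queries, CharacterVector targets,
                          int max_mm, int seed_k = 16) {
  std::vector<std::vector<uint8_t>> T = encode_all(targets);
  std::vector<int> tlen(T.size());
  for (size_t i = 0; i < T.size(); ++i) tlen[i] = (int)T[i].size();
  std::vector<std::vector<uint8_t>> Q = encode_all(queries);
  int min_q = INT_MAX;
  for (size_t i = 0; i < Q.size(); ++i) min_q = std::min(min_q, (int)Q[i].size());
  if (Q.empty()) min_q = 0;
  int k = pick_k(min_q, max_mm, seed_k);
  KmerIndex idx;
  bool use_idx = (k >= 4);
  if (use_idx) idx = build_index(T, k);

  std::vector<int> o_query, o_target, o_start, o_nmm;
  std::vector<std::string> o_strand, o_mm;
  for (size_t qi = 0; qi < Q.size(); ++qi) {
    std::vector<Placement> pl =
      placements_for(Q[qi], T, tlen, max_mm, use_idx ? &idx : (KmerIndex*)0);
    std::vector<uint8_t> qr = revcomp(Q[qi]);
    for (size_t p = 0; p < pl.size(); ++p) {
      o_query.push_back((int)qi + 1);
      o_target.push_back(pl[p].target + 1);
      o_start.push_back(pl[p].start);
      o_strand.push_back(pl[p].fwd ? "+" : "-");
      o_nmm.push_back(pl[p].n_mm);
      const std::vector<uint8_t>& q = pl[p].fwd ? Q[qi] : qr;
      o_mm.push_back(mm_offsets_str(q, T[pl[p].target], pl[p].start));
    }
  }
  return DataFrame::create(
    _["query"] = o_query, _["target"] = o_target, _["start"] = o_start,
    _["strand"] = o_strand, _["n_mismatches"] = o_nmm,
    _["mismatch_positions"] = o_mm, _["stringsAsFactors"] = false);
}

// Best-placement mapping with the ambiguity policy: minimum-distance placement
// reported; minimum achieved in more than one distinct target => read dropped;
// ties within one target => leftmost start, then forward orientation.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector targets,
                        int max_mm, int seed_k = 16) {
  std::vector<std::vector<uint8_t>> T = encode_all(targets);
  std::vector<int> tlen(T.size());
  for (size_t i = 0; i < T.size(); ++i) tlen[i] = (int)T[i].size();
  std::vector<std::vector<uint8_t>> Q = encode_all(reads);
  int min_q = INT_MAX;
  for (size_t i = 0; i < Q.size(); ++i) min_q = std::min(min_q, (int)Q[i].size());
  if (Q.empty()) min_q = 0;
  int k = pick_k(min_q, max_mm, seed_k);
  KmerIndex idx;
  bool use_idx = (k >= 4);
  if (use_idx) idx = build_index(T, k);

  std::vector<int> o_read, o_target, o_start, o_nmm;
  std::vector<std::string> o_strand, o_mm;
  for (size_t qi = 0; qi < Q.size(); ++qi) {
    std::vector<Placement> pl =
      placements_for(Q[qi], T, tlen, max_mm, use_idx ? &idx : (KmerIndex*)0);
    if (pl.empty()) continue;
    int best = INT_MAX;
    for (size_t p = 0; p < pl.size(); ++p) best = std::min(best, pl[p].n_mm);
    int first_t = -1;
    bool ambiguous = false;
    int sel = -1;
    for (size_t p = 0; p < pl.size(); ++p) {
      if (pl[p].n_mm != best) continue;
      if (first_t == -1) first_t = pl[p].target;
      else if (pl[p].target != first_t) { ambiguous = true; break; }
      if (sel == -1 || pl[p].start < pl[sel].start ||
          (pl[p].start == pl[sel].start && pl[p].fwd && !pl[sel].fwd))
        sel = (int)p;
    }
    if (ambiguous || sel < 0) continue;
    const Placement& w = pl[sel];
    o_read.push_back((int)qi + 1);
    o_target.push_back(w.target + 1);
    o_start.push_back(w.start);
    o_strand.push_back(w.fwd ? "+" : "-");
    o_nmm.push_back(w.n_mm);
    std::vector<uint8_t> q = w.fwd ? Q[qi] : revcomp(Q[qi]);
    o_mm.push_back(mm_offsets_str(q, T[w.target], w.start));
  }
  return DataFrame::create(
    _["read"] = o_read, _["target"] = o_target, _["start"] = o_start,
    _["strand"] = o_strand, _["n_mismatches"] = o_nmm,
    _["mismatch_positions"] = o_mm, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs, LogicalVector flip) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (flip[i % flip.size()]) {
      std::string r(s.size(), 'N');
      for (size_t j = 0; j < s.size(); ++j) {
        char c = s[s.size() - 1 - j];
        switch (c) {
          case 'A': r[j] = 'T'; break; case 'T': r[j] = 'A'; break;
          case 'C': r[j] = 'G'; break; case 'G': r[j] = 'C'; break;
          case 'a': r[j] = 't'; break; case 't': r[j] = 'a'; break;
          case 'c': r[j] = 'g'; break; case 'g': r[j] = 'c'; break;
          default: r[j] = 'N';
        }
      }
      out[i] = r;
    } else {
      out[i] = s;
    }
  }
  return out;
}

// In-place style base substitution used by the read simulator: read_idx and
// pos are 1-based parallel vectors; base is the replacement character.
// [[Rcpp::export]]
CharacterVector cpp_apply_substitutions(CharacterVector reads,
                                        IntegerVector read_idx,
                                        IntegerVector pos,
                                        CharacterVector base) {
  std::vector<std::string> v(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) v[i] = as<std::string>(reads[i]);
  for (R_xlen_t i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1;
    int p = pos[i] - 1;
    if (r >= 0 && r < (int)v.size() && p >= 0 && p < (int)v[r].size())
      v[r][p] = as<std::string>(base[i])[0];
  }
  return wrap(v);
}
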