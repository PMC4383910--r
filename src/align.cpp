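#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Shared scoring convention: a k-residue gap costs gap_open + k * gap_extend
// (gap_extend may be fractional, e.g. 2.5). Bases outside {A,C,G,T} never
// match anything, including themselves.

static inline int base2i(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default:  c = 'N';
    }
  }
  return r;
}

static inline double subst(char a, char b, double match, double mismatch) {
  int ia = base2i(a), ib = base2i(b);
  if (ia < 0 || ib < 0) return mismatch;
  return (ia == ib) ? match : mismatch;
}

// ---------------------------------------------------------------------------
// Full Smith-Waterman / Gotoh local alignment with traceback.
// Independent of the seeded search; used as the exact oracle.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_sw_local(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["identities"] = 0);
  }
  const double NEG = -1e18;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  // traceback codes: H: 0 stop, 1 diag, 2 from E (gap in a), 3 from F (gap in b)
  // E/F: 0 opened from H, 1 extended
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t)i * (m + 1) + j;
      double e_open = Hcur[j - 1] - gap_open - gap_extend;
      double e_ext  = Ecur[j - 1] - gap_extend;
      Ecur[j] = std::max(e_open, e_ext);
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      double f_open = Hprev[j] - gap_open - gap_extend;
      double f_ext  = Fprev[j] - gap_extend;
      Fcur[j] = std::max(f_open, f_ext);
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      double diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      double h = 0.0; uint8_t code = 0;
      if (diag > h) { h = diag; code = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; code = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; code = 3; }
      Hcur[j] = h; tbH[idx] = code;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["identities"] = 0);
  }
  // traceback
  int i = bi, j = bj, ident = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t c = tbH[idx];
      if (c == 0) break;
      if (c == 1) {
        if (base2i(a[i - 1]) >= 0 && a[i - 1] == b[j - 1]) ++ident;
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t c = tbE[idx];
      --j;
      if (c == 0) state = 0;
    } else {
      uint8_t c = tbF[idx];
      --i;
      if (c == 0) state = 0;
    }
  }
  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = bi,
                      _["b_start"] = j, _["b_end"] = bj,
                      _["identities"] = ident);
}

// ---------------------------------------------------------------------------
// Seeded search: exact word matches between query and subject (both senses),
// each seed extended outward by anchored affine-gap DP; the reported hit is
// the best local alignment constrained to contain the seed word.
// ---------------------------------------------------------------------------

struct ExtResult {
  double score = 0.0;
  int alen = 0, blen = 0;        // consumed lengths of a and b on best path
  int identities = 0;
  // diagonal match cells on the best path, as offsets into a and b
  std::vector<std::pair<int,int>> matches; // (a_off, b_off) of exact matches
};

// Anchored extension: alignments start at (0,0); best over all end cells.
// Ties prefer shorter alignments (smaller i, then j), keeping output stable.
static ExtResult extend_anchored(const std::string& a, const std::string& b,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
  ExtResult res;
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return res;
  const double NEG = -1e18;
  std::vector<double> H((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG);
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[at(0, j)] = std::max(H[at(0, j - 1)] - gap_open - gap_extend,
                           E[at(0, j - 1)] - gap_extend);
    tbE[at(0, j)] = (E[at(0, j - 1)] - gap_extend >
                     H[at(0, j - 1)] - gap_open - gap_extend) ? 1 : 0;
    H[at(0, j)] = E[at(0, j)];
    tbH[at(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = std::max(H[at(i - 1, 0)] - gap_open - gap_extend,
                           F[at(i - 1, 0)] - gap_extend);
    tbF[at(i, 0)] = (F[at(i - 1, 0)] - gap_extend >
                     H[at(i - 1, 0)] - gap_open - gap_extend) ? 1 : 0;
    H[at(i, 0)] = F[at(i, 0)];
    tbH[at(i, 0)] = 3;
  }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t idx = at(i, j);
      double e_open = H[at(i, j - 1)] - gap_open - gap_extend;
      double e_ext  = E[at(i, j - 1)] - gap_extend;
      E[idx] = std::max(e_open, e_ext);
      tbE[idx] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[at(i - 1, j)] - gap_open - gap_extend;
      double f_ext  = F[at(i - 1, j)] - gap_extend;
      F[idx] = std::max(f_open, f_ext);
      tbF[idx] = (f_ext > f_open) ? 1 : 0;
      double diag = H[at(i - 1, j - 1)] +
        subst(a[i - 1], b[j - 1], match, mismatch);
      double h = diag; uint8_t code = 1;
      if (E[idx] > h) { h = E[idx]; code = 2; }
      if (F[idx] > h) { h = F[idx]; code = 3; }
      H[idx] = h; tbH[idx] = code;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  res.score = best; res.alen = bi; res.blen = bj;
  if (bi == 0 && bj == 0) return res;
  int i = bi, j = bj, state = 0;
  while (i > 0 || j > 0) {
    size_t idx = at(i, j);
    if (state == 0) {
      if (i == 0) { state = 1; continue; }
      if (j == 0) { state = 2; continue; }
      uint8_t c = tbH[idx];
      if (c == 1) {
        if (base2i(a[i - 1]) >= 0 && a[i - 1] == b[j - 1]) {
          ++res.identities;
          res.matches.push_back(std::make_pair(i - 1, j - 1));
        }
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      uint8_t c = tbE[idx]; --j; if (c == 0) state = 0;
    } else {
      uint8_t c = tbF[idx]; --i; if (c == 0) state = 0;
    }
  }
  std::reverse(res.matches.begin(), res.matches.end());
  return res;
}

struct MatchRun { long diag; int q_start, q_end; }; // query coords, half-open

struct RawHit {
  int q_start, q_end, s_start, s_end; // half-open, strand-local query coords
  double score; int identities;
};

static void seed_pass(const std::string& q, const std::string& s,
                      const std::vector<std::vector<int>>& index,
                      int word, double match, double mismatch,
                      double gap_open, double gap_extend,
                      std::vector<RawHit>& hits) {
  const int qlen = (int)q.size(), slen = (int)s.size();
  if (qlen < word) return;
  int gap_budget = (gap_extend > 0)
    ? (int)std::ceil(qlen * std::max(match, 1.0) / gap_extend) + 2
    : qlen;
  std::vector<MatchRun> runs; // exact-match runs >= word already on a hit path
  for (int qi = 0; qi + word <= qlen; ++qi) {
    unsigned key = 0; bool ok = true;
    for (int k = 0; k < word; ++k) {
      int c = base2i(q[qi + k]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (unsigned)c;
    }
    if (!ok) continue;
    for (int sj : index[key]) {
      long d = (long)sj - qi;
      bool redundant = false;
      for (const MatchRun& r : runs) {
        if (r.diag == d && r.q_start <= qi && qi + word <= r.q_end) {
          redundant = true; break;
        }
      }
      if (redundant) continue;
      // left extension on reversed prefixes
      int lw = std::min(sj, qi + gap_budget);
      std::string la(q.rbegin() + (qlen - qi), q.rend());
      std::string lb(s.rbegin() + (slen - sj), s.rbegin() + (slen - sj) + lw);
      ExtResult L = extend_anchored(la, lb, match, mismatch,
                                    gap_open, gap_extend);
      // right extension on suffixes
      int rw = std::min(slen - sj - word, (qlen - qi - word) + gap_budget);
      std::string ra = q.substr(qi + word);
      std::string rb = s.substr(sj + word, rw);
      ExtResult R = extend_anchored(ra, rb, match, mismatch,
                                    gap_open, gap_extend);
      double score = L.score + word * match + R.score;
      RawHit h;
      h.q_start = qi - L.alen; h.q_end = qi + word + R.alen;
      h.s_start = sj - L.blen; h.s_end = sj + word + R.blen;
      h.score = score;
      h.identities = L.identities + word + R.identities;
      // collect exact-match cells of the whole path in (q, s) coords
      std::vector<std::pair<int,int>> cells;
      for (auto& p : L.matches)
        cells.push_back(std::make_pair(qi - 1 - p.first, sj - 1 - p.second));
      std::reverse(cells.begin(), cells.end());
      for (int k = 0; k < word; ++k)
        cells.push_back(std::make_pair(qi + k, sj + k));
      for (auto& p : R.matches)
        cells.push_back(std::make_pair(qi + word + p.first,
                                       sj + word + p.second));
      // exact runs of length >= word become pruning intervals
      size_t a0 = 0;
      while (a0 < cells.size()) {
        size_t a1 = a0 + 1;
        long dd = (long)cells[a0].second - cells[a0].first;
        while (a1 < cells.size() &&
               cells[a1].first == cells[a1 - 1].first + 1 &&
               (long)cells[a1].second - cells[a1].first == dd) ++a1;
        int len = (int)(a1 - a0);
        if (len >= word) {
          MatchRun r; r.diag = dd;
          r.q_start = cells[a0].first; r.q_end = cells[a0].first + len;
          runs.push_back(r);
        }
        a0 = a1;
      }
      hits.push_back(h);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_seed_extend(std::string query, std::string subject,
                          int word, double match, double mismatch,
                          double gap_open, double gap_extend,
                          double min_score, int min_len) {
  const int slen = (int)subject.size();
  // index subject words
  std::vector<std::vector<int>> index((size_t)1 << (2 * word));
  for (int j = 0; j + word <= slen; ++j) {
    unsigned key = 0; bool ok = true;
    for (int k = 0; k < word; ++k) {
      int c = base2i(subject[j + k]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (unsigned)c;
    }
    if (ok) index[key].push_back(j);
  }
  std::vector<RawHit> fwd, rev;
  seed_pass(query, subject, index, word, match, mismatch,
            gap_open, gap_extend, fwd);
  std::string qrc = revcomp(query);
  seed_pass(qrc, subject, index, word, match, mismatch,
            gap_open, gap_extend, rev);
  const int qlen = (int)query.size();
  std::vector<int> qs, qe, ss, se, ident;
  std::vector<double> sc;
  std::vector<std::string> sense;
  auto push = [&](const RawHit& h, bool is_fwd) {
    if (h.score < min_score) return;
    if (h.q_end - h.q_start < min_len) return;
    if (is_fwd) { qs.push_back(h.q_start); qe.push_back(h.q_end); }
    else { // map reverse-complement query coords back to gene orientation
      qs.push_back(qlen - h.q_end); qe.push_back(qlen - h.q_start);
    }
    ss.push_back(h.s_start); se.push_back(h.s_end);
    sc.push_back(h.score); ident.push_back(h.identities);
    sense.push_back(is_fwd ? "same" : "opposite");
  };
  for (const RawHit& h : fwd) push(h, true);
  for (const RawHit& h : rev) push(h, false);
  return DataFrame::create(_["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se,
                           _["sense"] = sense, _["score"] = sc,
                           _["identities"] = ident,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Background scrub for the synthetic generator: walk the sequence once,
// and wherever a window matches the template word set, change one
// background (maskable) base so that every window covering it is clean.
// Non-maskable positions (planted copies, guards) are never altered.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_scrub(std::string seq, LogicalVector mask,
                      LogicalVector flags, int word,
                      IntegerVector forbid) {
  const int n = (int)seq.size();
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base2i(seq[i]);
  auto key_at = [&](int s) -> long {
    long k = 0;
    for (int i = 0; i < word; ++i) {
      int c = b[s + i];
      if (c < 0) return -1;
      k = (k << 2) | c;
    }
    return k;
  };
  auto is_flagged = [&](int s) {
    if (s < 0 || s + word > n) return false;
    long k = key_at(s);
    return k >= 0 && flags[k];
  };
  // only windows at or before the scan frontier constrain a fix;
  // windows further right get their own turn (and their own background
  // positions) later in the pass
  auto pos_ok = [&](int p, int frontier) {
    int hi = std::min(p, frontier);
    for (int s = p - word + 1; s <= hi; ++s) {
      if (is_flagged(s)) return false;
    }
    return true;
  };
  for (int pass = 0; pass < 3; ++pass) {
    bool dirty = false;
    for (int s = 0; s + word <= n; ++s) {
      if (!is_flagged(s)) continue;
      bool fixed = false;
      for (int p = s + word - 1; p >= s && !fixed; --p) {
        if (!mask[p]) continue;
        int orig = b[p];
        int order[4] = {0, 1, 2, 3};
        for (int i = 3; i > 0; --i) {
          int j = (int)(unif_rand() * (i + 1));
          if (j > i) j = i;
          std::swap(order[i], order[j]);
        }
        for (int t = 0; t < 4 && !fixed; ++t) {
          if (order[t] == orig) continue;
          if (forbid[p] >= 0 && order[t] == forbid[p]) continue;
          b[p] = order[t];
          if (pos_ok(p, s)) fixed = true;
        }
        if (!fixed) b[p] = orig;
      }
      if (!fixed) {
        // try changing two background positions of the window jointly
        std::vector<int> mpos;
        for (int p = s; p < s + word; ++p) if (mask[p]) mpos.push_back(p);
        for (size_t u = 0; u < mpos.size() && !fixed; ++u) {
          for (size_t v = u + 1; v < mpos.size() && !fixed; ++v) {
            int p1 = mpos[u], p2 = mpos[v];
            int o1 = b[p1], o2 = b[p2];
            for (int c1 = 0; c1 < 4 && !fixed; ++c1) {
              if (forbid[p1] >= 0 && c1 == forbid[p1]) continue;
              for (int c2 = 0; c2 < 4 && !fixed; ++c2) {
                if (forbid[p2] >= 0 && c2 == forbid[p2]) continue;
                if (c1 == o1 && c2 == o2) continue;
                b[p1] = c1; b[p2] = c2;
                if (pos_ok(p1, s) && pos_ok(p2, s)) fixed = true;
              }
            }
            if (!fixed) { b[p1] = o1; b[p2] = o2; }
          }
        }
      }
      if (!fixed) dirty = true;
      // if no maskable fix exists the final verification will reject
    }
    if (!dirty) break;
  }
  static const char LUT[5] = "ACGT";
  for (int i = 0; i < n; ++i) {
    if (b[i] >= 0) seq[i] = LUT[b[i]];
  }
  return seq;
}

// Anchored-extension score summary used by the synthetic generator to
// pick safe fragment flanks: best score over all non-empty anchored
// alignments of a (query continuation) vs b (candidate flank), and the
// best score among paths consuming all of b (exposure to what follows
// the flank).
// [[Rcpp::export]]
List cpp_ext_score(std::string a, std::string b,
                   double match, double mismatch,
                   double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    E[at(0, j)] = std::max(H[at(0, j - 1)] - gap_open - gap_extend,
                           E[at(0, j - 1)] - gap_extend);
    H[at(0, j)] = E[at(0, j)];
  }
  for (int i = 1; i <= n; ++i) {
    F[at(i, 0)] = std::max(H[at(i - 1, 0)] - gap_open - gap_extend,
                           F[at(i - 1, 0)] - gap_extend);
    H[at(i, 0)] = F[at(i, 0)];
  }
  double best = NEG, best_end = NEG;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t idx = at(i, j);
      E[idx] = std::max(H[at(i, j - 1)] - gap_open - gap_extend,
                        E[at(i, j - 1)] - gap_extend);
      F[idx] = std::max(H[at(i - 1, j)] - gap_open - gap_extend,
                        F[at(i - 1, j)] - gap_extend);
      double diag = H[at(i - 1, j - 1)] +
        subst(a[i - 1], b[j - 1], match, mismatch);
      double h = diag;
      if (E[idx] > h) h = E[idx];
      if (F[idx] > h) h = F[idx];
      H[idx] = h;
      if (h > best) best = h;
      if (j == m && h > best_end) best_end = h;
    }
  }
  return List::create(_["max_all"] = best, _["max_end"] = best_end);
}
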