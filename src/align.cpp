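#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// 2-bit encode; -1 for non-ACGT
static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

struct Hsp { int qs, qe, ss, se, score, matches, len; };

// Ungapped X-drop extension from a seed match at (qp, sp) of length w.
static Hsp ungapped_extend(const std::string &q, const std::string &s,
                           int qp, int sp, int w, int match, int mismatch,
                           int xdrop) {
  int score = w * match;
  int best = score;
  int qe = qp + w - 1, se = sp + w - 1;   // inclusive ends
  int bqe = qe, bse = se;
  // right
  int i = qe + 1, j = se + 1, cur = score;
  while (i < (int)q.size() && j < (int)s.size()) {
    cur += (q[i] == s[j]) ? match : mismatch;
    if (cur > best) { best = cur; bqe = i; bse = j; }
    if (best - cur > xdrop) break;
    ++i; ++j;
  }
  int qs = qp, ss = sp, bqs = qp, bss = sp;
  i = qp - 1; j = sp - 1; cur = best;
  int best2 = best;
  while (i >= 0 && j >= 0) {
    cur += (q[i] == s[j]) ? match : mismatch;
    if (cur > best2) { best2 = cur; bqs = i; bss = j; }
    if (best2 - cur > xdrop) break;
    --i; --j;
  }
  Hsp h;
  h.qs = bqs; h.qe = bqe; h.ss = bss; h.se = bse; h.score = best2;
  h.len = h.qe - h.qs + 1;
  h.matches = 0;
  for (int k = 0; k < h.len; ++k)
    if (q[h.qs + k] == s[h.ss + k]) ++h.matches;
  return h;
}

// Banded X-drop gapped extension in one direction starting after (q0,s0).
// Returns best (dq, ds, score_delta) with dq,ds = extension lengths.
static void gapped_dir(const std::string &q, const std::string &s,
                       int q0, int s0, int dir, int match, int mismatch,
                       int gap_open, int gap_ext, int band, int xdrop,
                       int &bdq, int &bds, int &bscore, int &bmatch) {
  // coordinates i (query offset >=1), j (subject offset >=1)
  int qmax = dir > 0 ? (int)q.size() - 1 - q0 : q0;
  int smax = dir > 0 ? (int)s.size() - 1 - s0 : s0;
  bdq = 0; bds = 0; bscore = 0; bmatch = 0;
  if (qmax <= 0 || smax <= 0) return;
  const int NEG = -1000000000;
  int width = 2 * band + 1;
  std::vector<int> prev(width, NEG), cur(width, NEG);
  std::vector<int> mprev(width, 0), mcur(width, 0);
  // prev corresponds to i=0: cell j-i in [-band,band]; score = gap penalties
  for (int d = 0; d < width; ++d) {
    int j = d - band; // i=0 -> j = d-band
    if (j == 0) { prev[d] = 0; mprev[d] = 0; }
    else if (j > 0 && j <= smax)
      prev[d] = gap_open + gap_ext * (j - 1);
  }
  int best = 0;
  for (int i = 1; i <= std::min(qmax, smax + band); ++i) {
    int rowbest = NEG;
    for (int d = 0; d < width; ++d) {
      int j = i + d - band;
      cur[d] = NEG; mcur[d] = 0;
      if (j < 0 || j > smax) continue;
      if (j == 0) {
        cur[d] = gap_open + gap_ext * (i - 1);
        mcur[d] = 0;
      } else {
        char qc = dir > 0 ? q[q0 + i] : q[q0 - i];
        char sc = dir > 0 ? s[s0 + j] : s[s0 - j];
        int mm = (qc == sc) ? match : mismatch;
        int diag = prev[d] == NEG ? NEG : prev[d] + mm;
        int up = (d + 1 < width && prev[d + 1] != NEG)
                     ? prev[d + 1] + gap_open : NEG;   // gap in subject
        int left = (d - 1 >= 0 && cur[d - 1] != NEG)
                       ? cur[d - 1] + gap_open : NEG;  // gap in query
        int v = std::max(diag, std::max(up, left));
        if (v <= NEG / 2) continue;
        cur[d] = v;
        if (v == diag) mcur[d] = mprev[d] + (qc == sc ? 1 : 0);
        else if (v == up) mcur[d] = mprev[d + 1];
        else mcur[d] = mcur[d - 1];
        if (v > best) best = v;
        if (v > bscore) { bscore = v; bdq = i; bds = j; bmatch = mcur[d]; }
      }
      if (cur[d] > rowbest) rowbest = cur[d];
    }
    if (rowbest == NEG || best - rowbest > xdrop) break;
    std::swap(prev, cur);
    std::swap(mprev, mcur);
  }
}

// Seeded local-alignment search: exact word seeding, ungapped X-drop
// extension, banded gapped extension.  Coordinates returned 1-based closed.
// [[Rcpp::export]]
DataFrame cpp_search(std::string query, std::string subject, int word_size,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int xdrop_ungapped, int xdrop_gapped, int band,
                     int min_score) {
  std::vector<Hsp> hits;
  int m = query.size(), n = subject.size();
  if (m >= word_size && n >= word_size) {
    // index query words
    std::unordered_map<uint64_t, std::vector<int> > index;
    uint64_t key = 0, maskk = (word_size >= 32) ? ~0ULL
        : ((1ULL << (2 * word_size)) - 1);
    int run = 0;
    for (int i = 0; i < m; ++i) {
      int c = code(query[i]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & maskk;
      if (++run >= word_size) index[key].push_back(i - word_size + 1);
    }
    // scan subject; per-diagonal extension end to skip redundant seeds
    std::unordered_map<int, int> diag_end;
    key = 0; run = 0;
    for (int j = 0; j < n; ++j) {
      int c = code(subject[j]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | c) & maskk;
      if (++run < word_size) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      int sp = j - word_size + 1;
      for (int qp : it->second) {
        int d = sp - qp;
        auto de = diag_end.find(d);
        if (de != diag_end.end() && sp <= de->second) continue;
        Hsp h = ungapped_extend(query, subject, qp, sp, word_size, match,
                                mismatch, xdrop_ungapped);
        diag_end[d] = h.se;
        // gapped extension outward from the ungapped HSP ends
        int rdq, rds, rsc, rmt, ldq, lds, lsc, lmt;
        gapped_dir(query, subject, h.qe, h.se, +1, match, mismatch, gap_open,
                   gap_ext, band, xdrop_gapped, rdq, rds, rsc, rmt);
        gapped_dir(query, subject, h.qs, h.ss, -1, match, mismatch, gap_open,
                   gap_ext, band, xdrop_gapped, ldq, lds, lsc, lmt);
        Hsp g = h;
        g.qe += rdq; g.se += rds; g.qs -= ldq; g.ss -= lds;
        g.score = h.score + rsc + lsc;
        g.matches = h.matches + rmt + lmt;
        g.len = std::max(g.qe - g.qs, g.se - g.ss) + 1;
        if (g.score >= min_score) {
          diag_end[d] = std::max(diag_end[d], g.se);
          hits.push_back(g);
        }
      }
    }
  }
  // drop duplicates (same subject+query span) and near-duplicates contained
  // in a better hit on the same diagonal neighbourhood
  std::sort(hits.begin(), hits.end(), [](const Hsp &a, const Hsp &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.ss != b.ss) return a.ss < b.ss;
    return a.qs < b.qs;
  });
  std::vector<Hsp> keep;
  for (const Hsp &h : hits) {
    bool dup = false;
    for (const Hsp &k : keep) {
      int ov = std::min(h.se, k.se) - std::max(h.ss, k.ss) + 1;
      int qov = std::min(h.qe, k.qe) - std::max(h.qs, k.qs) + 1;
      if (ov > 0 && qov > 0 &&
          ov >= (int)(0.8 * (h.se - h.ss + 1)) &&
          qov >= (int)(0.8 * (h.qe - h.qs + 1))) { dup = true; break; }
    }
    if (!dup) keep.push_back(h);
  }
  int k = keep.size();
  IntegerVector qs(k), qe(k), ss(k), se(k), sc(k), len(k), mt(k);
  for (int i = 0; i < k; ++i) {
    qs[i] = keep[i].qs + 1; qe[i] = keep[i].qe + 1;
    ss[i] = keep[i].ss + 1; se[i] = keep[i].se + 1;
    sc[i] = keep[i].score; len[i] = keep[i].len; mt[i] = keep[i].matches;
  }
  return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se,
                           _["score"] = sc, _["length"] = len,
                           _["matches"] = mt);
}

// Full Smith-Waterman enumeration of non-overlapping local alignments with
// affine gaps (subject positions of a reported alignment are masked, DP
// repeated).  Quadratic; intended as an exact oracle on small instances.
// [[Rcpp::export]]
DataFrame cpp_sw_all(std::string query, std::string subject, int match,
                     int mismatch, int gap_open, int gap_ext, int min_score,
                     int max_hits) {
  int m = query.size(), n = subject.size();
  const int NEG = -1000000000;
  std::vector<bool> masked(n, false);
  std::vector<int> oqs, oqe, oss, ose, osc;
  size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<int> H(sz, 0), E(sz, NEG), F(sz, NEG);
  std::vector<signed char> tb(sz, 0);  // 0 stop, 1 diag, 2 up(E), 3 left(F)
  for (int iter = 0; iter < max_hits; ++iter) {
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
      size_t row = (size_t)i * (n + 1), prow = row - (n + 1);
      for (int j = 1; j <= n; ++j) {
        size_t idx = row + j;
        if (masked[j - 1]) { H[idx] = 0; E[idx] = NEG; F[idx] = NEG; tb[idx] = 0; continue; }
        E[idx] = std::max(H[prow + j] + gap_open + gap_ext,
                          E[prow + j] + gap_ext);
        F[idx] = std::max(H[idx - 1] + gap_open + gap_ext,
                          F[idx - 1] + gap_ext);
        int sub = (query[i - 1] == subject[j - 1]) ? match : mismatch;
        int diag = H[prow + j - 1] + sub;
        int v = std::max(0, std::max(diag, std::max(E[idx], F[idx])));
        H[idx] = v;
        tb[idx] = (v == 0) ? 0 : (v == diag ? 1 : (v == E[idx] ? 2 : 3));
        if (v > best) { best = v; bi = i; bj = j; }
      }
    }
    if (best < min_score) break;
    // traceback along H states (gap runs followed greedily)
    int i = bi, j = bj;
    while (i > 0 && j > 0 && H[(size_t)i * (n + 1) + j] > 0) {
      signed char t = tb[(size_t)i * (n + 1) + j];
      if (t == 1) { --i; --j; }
      else if (t == 2) --i;
      else if (t == 3) --j;
      else break;
    }
    oqs.push_back(i + 1); oqe.push_back(bi);
    oss.push_back(j + 1); ose.push_back(bj);
    osc.push_back(best);
    for (int p = j; p < bj; ++p) masked[p] = true;
  }
  return DataFrame::create(_["qstart"] = oqs, _["qend"] = oqe,
                           _["sstart"] = oss, _["send"] = ose,
                           _["score"] = osc);
}

// Direct-repeat (LTR pair) scan: for every diagonal shift k it scores the
// anchored repeat pair 5' start a (0..anchor), 3' end offset b (0..anchor),
// repeat length L-k-a-b, using prefix sums of diagonal base matches.
// Score = matches - mispen * mismatches.  Returns the best qualifying pair.
// [[Rcpp::export]]
List cpp_ltr_scan(std::string seq, int min_ltr, int anchor, int mispen,
                  double min_identity) {
  int L = seq.size();
  long bestscore = -1000000000L;
  int ba = -1, bb = -1, blen = 0, bmatch = 0;
  std::vector<int> pref(L + 1, 0);
  for (int k = min_ltr; k <= L - min_ltr; ++k) {
    int dlen = L - k;
    pref[0] = 0;
    for (int i = 0; i < dlen; ++i)
      pref[i + 1] = pref[i] + (seq[i] == seq[i + k] ? 1 : 0);
    for (int a = 0; a <= anchor; ++a) {
      for (int b = 0; b <= anchor; ++b) {
        int len = L - k - a - b;
        if (len < min_ltr || len > k) continue;
        int matches = pref[a + len] - pref[a];
        double ident = (double)matches / len;
        if (ident < min_identity) continue;
        long score = (long)matches - (long)mispen * (len - matches);
        if (score > bestscore ||
            (score == bestscore && (a < ba || (a == ba && b < bb)))) {
          bestscore = score; ba = a; bb = b; blen = len; bmatch = matches;
        }
      }
    }
  }
  if (ba < 0) return List::create(_["found"] = false);
  return List::create(_["found"] = true,
                      _["ltr5_start"] = ba + 1,
                      _["ltr5_end"] = ba + blen,
                      _["ltr3_start"] = L - bb - blen + 1,
                      _["ltr3_end"] = L - bb,
                      _["length"] = blen,
                      _["matches"] = bmatch,
                      _["identity"] = (double)bmatch / blen,
                      _["score"] = (double)bestscore);
}
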