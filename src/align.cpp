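#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap local alignment. A gap of length L costs gap_open + L * gap_ext
// (so the first gapped base costs gap_open + gap_ext), matching the
// convention of Biostrings::pairwiseAlignment.

static const int NEG = -1000000000;

// [[Rcpp::export]]
IntegerMatrix cpp_sw_scores(CharacterVector queries, CharacterVector refs,
                            int match = 1, int mismatch = -1,
                            int gap_open = 3, int gap_ext = 1) {
  int nq = queries.size(), nr = refs.size();
  IntegerMatrix out(nq, nr);
  int gi = gap_open + gap_ext;
  std::vector<std::string> rs(nr);
  for (int k = 0; k < nr; ++k) rs[k] = as<std::string>(refs[k]);
  for (int qi = 0; qi < nq; ++qi) {
    std::string q = as<std::string>(queries[qi]);
    int m = (int)q.size();
    for (int k = 0; k < nr; ++k) {
      const std::string &r = rs[k];
      int n = (int)r.size();
      std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Eprev(n + 1, NEG), Ecur(n + 1, NEG);
      int best = 0;
      for (int i = 1; i <= m; ++i) {
        int F = NEG;
        Ecur[0] = NEG;
        Hcur[0] = 0;
        char qc = q[i - 1];
        for (int j = 1; j <= n; ++j) {
          int e = std::max(Hcur[j - 1] - gi, Ecur[j - 1] - gap_ext);
          F = std::max(Hprev[j] - gi, F - gap_ext);
          int s = (qc == r[j - 1]) ? match : mismatch;
          int h = Hprev[j - 1] + s;
          if (e > h) h = e;
          if (F > h) h = F;
          if (h < 0) h = 0;
          Hcur[j] = h;
          Ecur[j] = e;
          if (h > best) best = h;
        }
        std::swap(Hprev, Hcur);
        std::swap(Eprev, Ecur);
      }
      out(qi, k) = best;
    }
  }
  return out;
}

// Full DP with traceback. Returns 1-based coordinates and per-column
// alignment mapping (diagonal columns only: positions where both query and
// reference are consumed).
// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string r,
                  int match = 1, int mismatch = -1,
                  int gap_open = 3, int gap_ext = 1) {
  int m = (int)q.size(), n = (int)r.size();
  int gi = gap_open + gap_ext;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  auto idx = [n](int i, int j) { return i * (n + 1) + j; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[idx(i, j - 1)] - gi, E[idx(i, j - 1)] - gap_ext);
      int f = std::max(H[idx(i - 1, j)] - gi, F[idx(i - 1, j)] - gap_ext);
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      int h = H[idx(i - 1, j - 1)] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      H[idx(i, j)] = h;
      E[idx(i, j)] = e;
      F[idx(i, j)] = f;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> qpos, rpos;
  std::vector<bool> is_match;
  int n_gap_cols = 0;
  int i = bi, j = bj;
  char state = 'H';
  int qstart = bi, rstart = bj;
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H[idx(i, j)];
      if (h == 0) break;
      int s = (q[i - 1] == r[j - 1]) ? match : mismatch;
      if (h == H[idx(i - 1, j - 1)] + s) {
        qpos.push_back(i);
        rpos.push_back(j);
        is_match.push_back(q[i - 1] == r[j - 1]);
        --i; --j;
      } else if (h == E[idx(i, j)]) {
        state = 'E';
      } else {
        state = 'F';
      }
    } else if (state == 'E') {
      // gap in query, reference base consumed
      ++n_gap_cols;
      if (E[idx(i, j)] == E[idx(i, j - 1)] - gap_ext) { --j; }
      else { --j; state = 'H'; }
    } else {
      ++n_gap_cols;
      if (F[idx(i, j)] == F[idx(i - 1, j)] - gap_ext) { --i; }
      else { --i; state = 'H'; }
    }
    qstart = i + 1;
    rstart = j + 1;
  }
  std::reverse(qpos.begin(), qpos.end());
  std::reverse(rpos.begin(), rpos.end());
  std::reverse(is_match.begin(), is_match.end());
  int n_match = 0;
  for (size_t k = 0; k < is_match.size(); ++k) if (is_match[k]) ++n_match;
  return List::create(
      _["score"] = best, _["query_start"] = qstart, _["query_end"] = bi,
      _["ref_start"] = rstart, _["ref_end"] = bj,
      _["query_pos"] = wrap(qpos), _["ref_pos"] = wrap(rpos),
      _["is_match"] = wrap(is_match), _["n_match"] = n_match,
      _["n_columns"] = (int)(qpos.size() + n_gap_cols));
}

// Exhaustive-offset merging of a read pair. seq2 must already be
// reverse-complemented (and qual2 reversed). Offset s is the 1-based start
// of seq2 relative to seq1; N bases neither match nor mismatch.
// [[Rcpp::export]]
List cpp_merge_pair(std::string s1, std::string s2, IntegerVector q1,
                    IntegerVector q2, int min_overlap = 10,
                    double max_mismatch_rate = 0.1) {
  int L1 = (int)s1.size(), L2 = (int)s2.size();
  int best_matches = -1, best_s = 0, best_overlap = 0, best_mm = 0;
  for (int s = 1 - (L2 - min_overlap); s <= L1 - min_overlap + 1; ++s) {
    int lo = std::max(1, s), hi = std::min(L1, s + L2 - 1);
    int overlap = hi - lo + 1;
    if (overlap < min_overlap) continue;
    int matches = 0, mm = 0;
    for (int p = lo; p <= hi; ++p) {
      char a = s1[p - 1], b = s2[p - s];
      if (a == 'N' || b == 'N') continue;
      if (a == b) ++matches; else ++mm;
    }
    if ((double)mm / overlap > max_mismatch_rate) continue;
    if (matches > best_matches ||
        (matches == best_matches && overlap > best_overlap)) {
      best_matches = matches;
      best_s = s;
      best_overlap = overlap;
      best_mm = mm;
    }
  }
  if (best_matches < 0) {
    return List::create(_["merged"] = false);
  }
  int s = best_s;
  int from = std::min(1, s), to = std::max(L1, s + L2 - 1);
  std::string out;
  std::vector<int> qual;
  out.reserve(to - from + 1);
  for (int p = from; p <= to; ++p) {
    bool in1 = (p >= 1 && p <= L1);
    bool in2 = (p >= s && p <= s + L2 - 1);
    if (in1 && in2) {
      char a = s1[p - 1], b = s2[p - s];
      int qa = q1[p - 1], qb = q2[p - s];
      if (a == b) { out.push_back(a); qual.push_back(std::max(qa, qb)); }
      else if (a == 'N') { out.push_back(b); qual.push_back(qb); }
      else if (b == 'N') { out.push_back(a); qual.push_back(qa); }
      else if (qa >= qb) { out.push_back(a); qual.push_back(qa); }
      else { out.push_back(b); qual.push_back(qb); }
    } else if (in1) {
      out.push_back(s1[p - 1]);
      qual.push_back(q1[p - 1]);
    } else {
      out.push_back(s2[p - s]);
      qual.push_back(q2[p - s]);
    }
  }
  return List::create(_["merged"] = true, _["sequence"] = out,
                      _["quality"] = wrap(qual), _["overlap_len"] = best_overlap,
                      _["n_mismatches_in_overlap"] = best_mm,
                      _["offset"] = best_s);
}

// Longest common substring; ties broken toward the smallest start in `a`,
// then the smallest start in `b`. Returns (length, a_start, b_start), 1-based.
// [[Rcpp::export]]
IntegerVector cpp_lcs(std::string a, std::string b) {
  int m = (int)a.size(), n = (int)b.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  int best = 0, ai = 0, bi = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (cur[j] > best) {
        best = cur[j];
        ai = i - cur[j] + 1;
        bi = j - cur[j] + 1;
      } else if (cur[j] == best && best > 0) {
        int cand_a = i - cur[j] + 1, cand_b = j - cur[j] + 1;
        if (cand_a < ai || (cand_a == ai && cand_b < bi)) { ai = cand_a; bi = cand_b; }
      }
    }
    std::swap(prev, cur);
  }
  return IntegerVector::create(best, ai, bi);
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) return -1;
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}
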