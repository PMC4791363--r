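#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Local alignment engine shared by local_align(), read recruitment and the
// ANI/AAI fragment machinery. Sequences are encoded against an alphabet
// string; any character outside the alphabet gets code = alphabet size and
// must be penalized by an extra row/column of the scoring matrix (built on
// the R side). Gap penalty is linear (one cost per gap column).

struct Hit {
  int score = 0;
  int qstart = 0, qend = 0;   // 0-based half-open on the query
  int sstart = 0, send = 0;   // 0-based half-open on the subject
  int columns = 0, matches = 0;
};

static std::vector<int> encode(const std::string& s, const std::string& alphabet) {
  int code[256];
  std::fill(code, code + 256, (int)alphabet.size());
  for (size_t i = 0; i < alphabet.size(); ++i)
    code[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = code[(unsigned char)s[i]];
  return out;
}

// Exact Smith-Waterman with full DP matrix and traceback.
// Tie-breaking: the best cell is the first maximum in row-major scan order
// (smallest query index, then smallest subject index); pointer preference
// on equal scores is diagonal > up (gap in subject) > left (gap in query).
static Hit sw_full(const std::vector<int>& a, const std::vector<int>& b,
                   const int* S, int nr, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  Hit best;
  if (n == 0 || m == 0) return best;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  std::vector<uint8_t> ptr((size_t)n * m, 0); // 0 stop, 1 diag, 2 up, 3 left
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + S[a[i - 1] * nr + b[j - 1]];
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int h = diag; uint8_t p = 1;
      if (up > h) { h = up; p = 2; }
      if (left > h) { h = left; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      cur[j] = h;
      ptr[(size_t)(i - 1) * m + (j - 1)] = p;
      if (h > best.score) { best.score = h; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  // traceback
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t p = ptr[(size_t)(i - 1) * m + (j - 1)];
    if (p == 0) break;
    best.columns++;
    if (p == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] < nr - 1) best.matches++;
      --i; --j;
    } else if (p == 2) { --i; } else { --j; }
  }
  best.qstart = i; best.qend = bi;
  best.sstart = j; best.send = bj;
  return best;
}

// Banded Smith-Waterman restricted to diagonals d = j - i in [dlo, dhi].
static Hit sw_banded(const std::vector<int>& a, const std::vector<int>& b,
                     const int* S, int nr, int gap, int dlo, int dhi) {
  const int n = (int)a.size(), m = (int)b.size();
  Hit best;
  if (n == 0 || m == 0) return best;
  dlo = std::max(dlo, -n + 1 - 0); // j - i >= 1 - n
  dhi = std::min(dhi, m - 1);
  if (dlo > dhi) return best;
  const int W = dhi - dlo + 1;
  const int NEG = INT32_MIN / 4;
  std::vector<int> prev(W, 0), cur(W, 0);
  std::vector<uint8_t> ptr((size_t)(n + 1) * W, 0);
  int bi = 0, bc = 0;
  // row i = 0: j = dlo + c must be >= 0; score 0 where valid
  for (int c = 0; c < W; ++c) prev[c] = (dlo + c >= 0 && dlo + c <= m) ? 0 : NEG;
  for (int i = 1; i <= n; ++i) {
    for (int c = 0; c < W; ++c) {
      int j = i + dlo + c;
      if (j < 0 || j > m) { cur[c] = NEG; continue; }
      // virtual boundary column j = 0: a zero-score start anchor, so
      // alignments beginning at the subject edge are not penalized
      if (j == 0) { cur[c] = 0; continue; }
      int diag = (prev[c] <= NEG / 2) ? NEG : prev[c] + S[a[i - 1] * nr + b[j - 1]];
      int up = (c + 1 < W && prev[c + 1] > NEG / 2) ? prev[c + 1] + gap : NEG;
      int left = (c - 1 >= 0 && cur[c - 1] > NEG / 2) ? cur[c - 1] + gap : NEG;
      int h = diag; uint8_t p = 1;
      if (up > h) { h = up; p = 2; }
      if (left > h) { h = left; p = 3; }
      if (h <= 0) { h = 0; p = 0; }
      cur[c] = h;
      ptr[(size_t)i * W + c] = p;
      if (h > best.score) { best.score = h; bi = i; bc = c; }
    }
    std::swap(prev, cur);
  }
  int i = bi, c = bc;
  while (i > 0) {
    uint8_t p = ptr[(size_t)i * W + c];
    if (p == 0) break;
    best.columns++;
    int j = i + dlo + c;
    if (p == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] < nr - 1) best.matches++;
      --i;                       // same c: diagonal keeps d constant
    } else if (p == 2) { --i; ++c; }
    else { --c; }
  }
  best.qstart = i; best.qend = bi;
  best.sstart = i + dlo + c; best.send = bi + dlo + bc;
  return best;
}

// Global (Needleman-Wunsch) alignment with linear gaps, end gaps
// penalized. Used for full-length gene identity: a local or free-end-gap
// alignment can collapse onto a short perfect island between unrelated
// sequences and report spuriously high identity, while a global alignment
// spreads the comparison across both sequences.
static Hit sw_global(const std::vector<int>& a, const std::vector<int>& b,
                     const int* S, int nr, int gap) {
  const int n = (int)a.size(), m = (int)b.size();
  Hit best;
  if (n == 0 || m == 0) return best;
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<uint8_t> ptr((size_t)n * m, 0);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + S[a[i - 1] * nr + b[j - 1]];
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      int h = diag; uint8_t p = 1;
      if (up > h) { h = up; p = 2; }
      if (left > h) { h = left; p = 3; }
      cur[j] = h;
      ptr[(size_t)(i - 1) * m + (j - 1)] = p;
    }
    std::swap(prev, cur);
  }
  best.score = prev[m];
  int i = n, j = m;
  while (i > 0 || j > 0) {
    best.columns++;
    if (i == 0) { --j; continue; }      // leading gap row
    if (j == 0) { --i; continue; }      // leading gap column
    uint8_t p = ptr[(size_t)(i - 1) * m + (j - 1)];
    if (p == 1) {
      if (a[i - 1] == b[j - 1] && a[i - 1] < nr - 1) best.matches++;
      --i; --j;
    } else if (p == 2) { --i; } else { --j; }
  }
  best.qstart = 0; best.qend = n;
  best.sstart = 0; best.send = m;
  return best;
}

// k-mer index of a subject sequence: hash -> positions (capped per k-mer).
struct KmerIndex {
  std::unordered_map<uint64_t, std::vector<int>> map;
  int k;
  int nbits;
};

static void build_index(KmerIndex& idx, const std::vector<int>& s,
                        int k, int alpha_len, int max_occ) {
  idx.k = k;
  int nbits = 1; while ((1 << nbits) < alpha_len + 1) ++nbits;
  idx.nbits = nbits;
  const uint64_t mask = (k * nbits >= 64) ? ~0ULL : ((1ULL << (k * nbits)) - 1);
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] >= alpha_len) { run = 0; h = 0; continue; }
    h = ((h << nbits) | (uint64_t)s[i]) & mask;
    if (++run >= k) {
      auto& v = idx.map[h];
      if ((int)v.size() < max_occ) v.push_back(i - k + 1);
    }
  }
}

// Best-diagonal seeded alignment: collect shared k-mer diagonals, take the
// window of width `band` with most seeds (smallest diagonal on ties), then
// run banded DP with padding around it.
static Hit sw_seeded(const std::vector<int>& q, const std::vector<int>& s,
                     const KmerIndex& idx, const int* S, int nr, int gap,
                     int alpha_len, int band) {
  const int k = idx.k, nbits = idx.nbits;
  const uint64_t mask = (k * nbits >= 64) ? ~0ULL : ((1ULL << (k * nbits)) - 1);
  std::vector<int> diags;
  uint64_t h = 0; int run = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    if (q[i] >= alpha_len) { run = 0; h = 0; continue; }
    h = ((h << nbits) | (uint64_t)q[i]) & mask;
    if (++run >= k) {
      auto it = idx.map.find(h);
      if (it != idx.map.end())
        for (int sp : it->second) diags.push_back(sp - (i - k + 1));
    }
  }
  if (diags.empty()) return Hit();
  std::sort(diags.begin(), diags.end());
  int bestCount = 0, bestD = diags[0];
  size_t lo = 0;
  for (size_t hi = 0; hi < diags.size(); ++hi) {
    while (diags[hi] - diags[lo] >= band) ++lo;
    int count = (int)(hi - lo + 1);
    if (count > bestCount) { bestCount = count; bestD = diags[lo]; }
  }
  return sw_banded(q, s, S, nr, gap, bestD - band, bestD + 2 * band);
}

static List hit_to_list(const Hit& h) {
  return List::create(
    _["score"] = h.score, _["columns"] = h.columns, _["matches"] = h.matches,
    _["identity"] = h.columns > 0 ? (double)h.matches / h.columns : NA_REAL,
    _["qstart"] = h.qstart, _["qend"] = h.qend,
    _["sstart"] = h.sstart, _["send"] = h.send);
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, std::string alphabet,
                    IntegerMatrix S, int gap, std::string method,
                    int k, int band, double full_cutoff_cells, int max_occ) {
  std::vector<int> ai = encode(a, alphabet), bi = encode(b, alphabet);
  const int nr = S.nrow();
  std::vector<int> Sf(S.begin(), S.end());
  std::vector<int> St((size_t)nr * nr);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nr; ++c) St[(size_t)r * nr + c] = Sf[(size_t)c * nr + r];
  double cells = (double)(ai.size() + 1) * (double)(bi.size() + 1);
  bool full = (method == "full") ||
              (method == "auto" && cells <= full_cutoff_cells);
  Hit h;
  if (full) {
    h = sw_full(ai, bi, St.data(), nr, gap);
  } else {
    KmerIndex idx;
    build_index(idx, bi, k, (int)alphabet.size(), max_occ);
    h = sw_seeded(ai, bi, idx, St.data(), nr, gap, (int)alphabet.size(), band);
  }
  List out = hit_to_list(h);
  out["method"] = full ? "full" : "seeded";
  return out;
}

// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string a, std::string b, std::string alphabet,
                      IntegerMatrix S, int gap) {
  std::vector<int> ai = encode(a, alphabet), bi = encode(b, alphabet);
  const int nr = S.nrow();
  std::vector<int> Sf(S.begin(), S.end());
  std::vector<int> St((size_t)nr * nr);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nr; ++c) St[(size_t)r * nr + c] = Sf[(size_t)c * nr + r];
  Hit h = sw_global(ai, bi, St.data(), nr, gap);
  List out = hit_to_list(h);
  out["method"] = "global";
  return out;
}

// Align many queries against one subject (subject indexed once).
// Returns a numeric matrix, one row per query:
// score, columns, matches, qstart, qend, sstart, send.
// [[Rcpp::export(name = ".align_many_cpp")]]
NumericMatrix align_many_cpp(CharacterVector queries, std::string subject,
                             std::string alphabet, IntegerMatrix S, int gap,
                             int k, int band, double full_cutoff_cells,
                             int max_occ) {
  std::vector<int> si = encode(subject, alphabet);
  const int nr = S.nrow();
  std::vector<int> Sf(S.begin(), S.end());
  std::vector<int> St((size_t)nr * nr);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nr; ++c) St[(size_t)r * nr + c] = Sf[(size_t)c * nr + r];
  KmerIndex idx;
  build_index(idx, si, k, (int)alphabet.size(), max_occ);
  const int nq = queries.size();
  NumericMatrix out(nq, 7);
  colnames(out) = CharacterVector::create("score", "columns", "matches",
                                          "qstart", "qend", "sstart", "send");
  for (int r = 0; r < nq; ++r) {
    std::vector<int> qi = encode(as<std::string>(queries[r]), alphabet);
    double cells = (double)(qi.size() + 1) * (double)(si.size() + 1);
    Hit h = (cells <= full_cutoff_cells)
      ? sw_full(qi, si, St.data(), nr, gap)
      : sw_seeded(qi, si, idx, St.data(), nr, gap, (int)alphabet.size(), band);
    out(r, 0) = h.score;  out(r, 1) = h.columns; out(r, 2) = h.matches;
    out(r, 3) = h.qstart; out(r, 4) = h.qend;
    out(r, 5) = h.sstart; out(r, 6) = h.send;
    if (r % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
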