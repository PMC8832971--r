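// Global protein alignment (Gotoh three-state affine-gap DP) plus batch
// drivers used by flank clustering and the reciprocity filter.
//
// Conventions:
//  - a gap run of length L costs open + L * ext (both penalties positive),
//    matching the Biostrings::pairwiseAlignment gapOpening/gapExtension
//    semantics so the two can be cross-checked score-for-score;
//  - traceback tie-break preference is fixed (diagonal > gap-in-target >
//    gap-in-query) so results are deterministic;
//  - identity = identical aligned pairs / aligned columns excluding terminal
//    gap columns; coverage = columns with both residues / length of the
//    shorter sequence.
#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>
using namespace Rcpp;

static const std::string AA_ORDER = "ACDEFGHIKLMNPQRSTVWYBZX*";

struct AlnStats {
  double score;
  double identity;
  double coverage;
  int cols;      // aligned columns excluding terminal gaps
  int matches;   // identical aligned residue pairs
};

static void build_lookup(int lookup[256]) {
  const int x_idx = (int)AA_ORDER.find('X');
  for (int i = 0; i < 256; ++i) lookup[i] = x_idx;
  for (size_t i = 0; i < AA_ORDER.size(); ++i)
    lookup[(unsigned char)AA_ORDER[i]] = (int)i;
}

struct Workspace {
  std::vector<double> M, X, Y;
  std::vector<unsigned char> tM, tX, tY;
};

static AlnStats gotoh(const std::string& a, const std::string& b,
                      const std::vector<double>& S, double open, double ext,
                      const int lookup[256], Workspace& ws) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  const int W = m + 1;
  const size_t need = (size_t)(n + 1) * W;
  if (ws.M.size() < need) {
    ws.M.resize(need); ws.X.resize(need); ws.Y.resize(need);
    ws.tM.resize(need); ws.tX.resize(need); ws.tY.resize(need);
  }
  std::vector<double>& M = ws.M;
  std::vector<double>& X = ws.X;
  std::vector<double>& Y = ws.Y;
  std::vector<unsigned char>& tM = ws.tM;
  std::vector<unsigned char>& tX = ws.tX;
  std::vector<unsigned char>& tY = ws.tY;
  std::fill(M.begin(), M.begin() + need, NEG);
  std::fill(X.begin(), X.begin() + need, NEG);
  std::fill(Y.begin(), Y.begin() + need, NEG);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(open + ext * i);
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(open + ext * j);
    tY[j] = (j == 1) ? 0 : 2;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) ai[i] = lookup[(unsigned char)a[i]];
  for (int j = 0; j < m; ++j) bi[j] = lookup[(unsigned char)b[j]];
  for (int i = 1; i <= n; ++i) {
    const int row = i * W, prow = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const double s = S[ai[i - 1] * 24 + bi[j - 1]];
      // M: a[i] aligned with b[j]
      double best = M[prow + j - 1];
      unsigned char tb = 0;
      if (X[prow + j - 1] > best) { best = X[prow + j - 1]; tb = 1; }
      if (Y[prow + j - 1] > best) { best = Y[prow + j - 1]; tb = 2; }
      M[row + j] = best + s; tM[row + j] = tb;
      // X: gap in b (consume a[i])
      double xb = M[prow + j] - (open + ext);
      unsigned char xt = 0;
      if (X[prow + j] - ext > xb) { xb = X[prow + j] - ext; xt = 1; }
      if (Y[prow + j] - (open + ext) > xb) { xb = Y[prow + j] - (open + ext); xt = 2; }
      X[row + j] = xb; tX[row + j] = xt;
      // Y: gap in a (consume b[j])
      double yb = M[row + j - 1] - (open + ext);
      unsigned char yt = 0;
      if (X[row + j - 1] - (open + ext) > yb) { yb = X[row + j - 1] - (open + ext); yt = 1; }
      if (Y[row + j - 1] - ext > yb) { yb = Y[row + j - 1] - ext; yt = 2; }
      Y[row + j] = yb; tY[row + j] = yt;
    }
  }
  // traceback
  int i = n, j = m;
  double sc = M[n * W + m];
  int state = 0;
  if (X[n * W + m] > sc) { sc = X[n * W + m]; state = 1; }
  if (Y[n * W + m] > sc) { sc = Y[n * W + m]; state = 2; }
  std::string ca, cb;
  ca.reserve(n + m); cb.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char tb = tM[i * W + j];
      ca.push_back(a[i - 1]); cb.push_back(b[j - 1]);
      --i; --j; state = tb;
    } else if (state == 1) {
      unsigned char tb = tX[i * W + j];
      ca.push_back(a[i - 1]); cb.push_back('-');
      --i; state = tb;
    } else {
      unsigned char tb = tY[i * W + j];
      ca.push_back('-'); cb.push_back(b[j - 1]);
      --j; state = tb;
    }
  }
  std::reverse(ca.begin(), ca.end());
  std::reverse(cb.begin(), cb.end());
  const int L = (int)ca.size();
  int first = 0, last = L - 1;
  while (first < L && (ca[first] == '-' || cb[first] == '-')) ++first;
  while (last >= 0 && (ca[last] == '-' || cb[last] == '-')) --last;
  int matches = 0, cols = 0, both = 0;
  for (int kk = 0; kk < L; ++kk)
    if (ca[kk] != '-' && cb[kk] != '-') ++both;
  for (int kk = first; kk <= last; ++kk) {
    ++cols;
    if (ca[kk] == cb[kk] && ca[kk] != '-') ++matches;
  }
  AlnStats st;
  st.score = sc;
  st.cols = cols;
  st.matches = matches;
  st.identity = cols > 0 ? (double)matches / cols : 0.0;
  const int shorter = std::min(n, m);
  st.coverage = shorter > 0 ? (double)both / shorter : 0.0;
  return st;
}

static std::vector<double> flatten_submat(const NumericMatrix& submat) {
  if (submat.nrow() != 24 || submat.ncol() != 24)
    stop("substitution matrix must be 24 x 24 in internal alphabet order");
  std::vector<double> S(24 * 24);
  for (int i = 0; i < 24; ++i)
    for (int j = 0; j < 24; ++j) S[i * 24 + j] = submat(i, j);
  return S;
}

// distinct 4-mer fingerprint (sorted codes) for the prescreen
static std::vector<int> kmer_set(const std::string& s, const int lookup[256]) {
  std::vector<int> ks;
  if (s.size() < 4) return ks;
  ks.reserve(s.size());
  for (size_t i = 0; i + 4 <= s.size(); ++i) {
    int code = 0;
    for (int k = 0; k < 4; ++k) code = code * 24 + lookup[(unsigned char)s[i + k]];
    ks.push_back(code);
  }
  std::sort(ks.begin(), ks.end());
  ks.erase(std::unique(ks.begin(), ks.end()), ks.end());
  return ks;
}

static double kmer_overlap(const std::vector<int>& a, const std::vector<int>& b) {
  if (a.empty() || b.empty()) return 0.0;
  size_t i = 0, j = 0, shared = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) { ++shared; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return (double)shared / (double)std::min(a.size(), b.size());
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b, NumericMatrix submat,
                    double gap_open, double gap_ext) {
  int lookup[256];
  build_lookup(lookup);
  std::vector<double> S = flatten_submat(submat);
  Workspace ws;
  AlnStats st = gotoh(a, b, S, gap_open, gap_ext, lookup, ws);
  return List::create(_["score"] = st.score, _["identity"] = st.identity,
                      _["coverage"] = st.coverage, _["aligned_cols"] = st.cols,
                      _["matches"] = st.matches);
}

// [[Rcpp::export(name = ".align_batch_cpp")]]
DataFrame align_batch_cpp(std::string query, CharacterVector targets,
                          NumericMatrix submat, double gap_open, double gap_ext,
                          double min_len_ratio, double min_kmer_frac) {
  int lookup[256];
  build_lookup(lookup);
  std::vector<double> S = flatten_submat(submat);
  const int n = targets.size();
  NumericVector score(n, NA_REAL), identity(n, NA_REAL), coverage(n, NA_REAL);
  LogicalVector computed(n, false);
  Workspace ws;
  std::vector<int> qk = kmer_set(query, lookup);
  const double qlen = (double)query.size();
  for (int t = 0; t < n; ++t) {
    std::string tg = as<std::string>(targets[t]);
    double ratio = std::min(qlen, (double)tg.size()) /
                   std::max(qlen, (double)tg.size());
    if (ratio < min_len_ratio) continue;
    if (min_kmer_frac > 0.0) {
      std::vector<int> tk = kmer_set(tg, lookup);
      if (kmer_overlap(qk, tk) < min_kmer_frac) continue;
    }
    AlnStats st = gotoh(query, tg, S, gap_open, gap_ext, lookup, ws);
    score[t] = st.score; identity[t] = st.identity; coverage[t] = st.coverage;
    computed[t] = true;
  }
  return DataFrame::create(_["score"] = score, _["identity"] = identity,
                           _["coverage"] = coverage, _["computed"] = computed);
}

// [[Rcpp::export(name = ".align_all_pairs_cpp")]]
DataFrame align_all_pairs_cpp(CharacterVector seqs, NumericMatrix submat,
                              double gap_open, double gap_ext,
                              double min_len_ratio, double min_kmer_frac) {
  int lookup[256];
  build_lookup(lookup);
  std::vector<double> S = flatten_submat(submat);
  const int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  std::vector<std::vector<int> > ks(n);
  if (min_kmer_frac > 0.0)
    for (int i = 0; i < n; ++i) ks[i] = kmer_set(ss[i], lookup);
  std::vector<int> ia, ja;
  std::vector<double> sc, id, cv;
  Workspace ws;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double la = (double)ss[i].size(), lb = (double)ss[j].size();
      double ratio = std::min(la, lb) / std::max(la, lb);
      if (ratio < min_len_ratio) continue;
      if (min_kmer_frac > 0.0 && kmer_overlap(ks[i], ks[j]) < min_kmer_frac)
        continue;
      AlnStats st = gotoh(ss[i], ss[j], S, gap_open, gap_ext, lookup, ws);
      ia.push_back(i + 1); ja.push_back(j + 1);
      sc.push_back(st.score); id.push_back(st.identity); cv.push_back(st.coverage);
    }
    Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = ia, _["j"] = ja, _["score"] = sc,
                           _["identity"] = id, _["coverage"] = cv);
}
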