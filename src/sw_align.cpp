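#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Affine-gap Smith-Waterman with traceback.
// Gap of length g costs gap_open + g * gap_ext (NCBI convention with
// gap_open = 11, gap_ext = 1).  Characters absent from `alphabet` score
// like 'X'; '*' rows/columns in the substitution matrix carry the usual
// strongly negative penalty, so local alignments never cross stops.
//
// Returns best score and the traceback of the best-scoring cell:
// 1-based inclusive query/target coordinates, #identities and alignment
// columns (for identity and coverage).

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string q, std::string t, IntegerMatrix sub,
                  std::string alphabet, int gap_open, int gap_ext) {
  const int m = q.size(), n = t.size();
  int idx[256];
  const int xi_default = alphabet.find('X') != std::string::npos
    ? (int)alphabet.find('X') : 0;
  for (int i = 0; i < 256; ++i) idx[i] = xi_default;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;

  std::vector<int> qi(m), ti(n);
  for (int i = 0; i < m; ++i) qi[i] = idx[(unsigned char)q[i]];
  for (int j = 0; j < n; ++j) ti[j] = idx[(unsigned char)t[j]];

  const int NEG = -1000000000;
  const int go = gap_open + gap_ext;  // cost of first gapped residue
  const int na = alphabet.size();
  // flat copy of the substitution matrix (row-major by query index)
  std::vector<int> S((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b)
      S[(size_t)a * na + b] = sub(a, b);
  // rolling rows for scores; full byte traceback for the three states
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG), Ecur(n + 1, NEG);   // gap in query
  std::vector<int> Fcur(n + 1, NEG);                       // gap in target
  // origin of H (0=stop,1=diag,2=up(E),3=left(F)) and gap-extension
  // flags for E and F
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
    const int* srow = &S[(size_t)qi[i - 1] * na];
    const int* hp = Hprev.data();
    const int* ep = Eprev.data();
    int* hc = Hcur.data();
    int* ec = Ecur.data();
    int* fc = Fcur.data();
    unsigned char* th = &tbH[(size_t)i * (n + 1)];
    unsigned char* te = &tbE[(size_t)i * (n + 1)];
    unsigned char* tf = &tbF[(size_t)i * (n + 1)];
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (move up, consume query)
      int e_open = hp[j] - go, e_ext = ep[j] - gap_ext;
      int e = e_open >= e_ext ? e_open : e_ext;
      te[j] = e_ext > e_open ? 1 : 0;
      // F: gap in target (move left, consume target)
      int f_open = hc[j - 1] - go, f_ext = fc[j - 1] - gap_ext;
      int f = f_open >= f_ext ? f_open : f_ext;
      tf[j] = f_ext > f_open ? 1 : 0;
      int diag = hp[j - 1] + srow[ti[j - 1]];
      int h = 0; unsigned char o = 0;
      if (diag > h) { h = diag; o = 1; }
      if (e > h) { h = e; o = 2; }
      if (f > h) { h = f; o = 3; }
      hc[j] = h; ec[j] = e; fc[j] = f;
      th[j] = o;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  int qs = 0, qe = 0, ts = 0, te = 0, matches = 0, cols = 0;
  if (best > 0) {
    qe = bi; te = bj;
    int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
    while (i > 0 && j > 0) {
      if (state == 0) {
        unsigned char o = tbH[(size_t)i * (n + 1) + j];
        if (o == 0) break;
        if (o == 1) {
          if (q[i - 1] == t[j - 1]) ++matches;
          ++cols; --i; --j;
        } else if (o == 2) state = 1;
        else state = 2;
      } else if (state == 1) {
        unsigned char ext = tbE[(size_t)i * (n + 1) + j];
        ++cols; --i;
        state = ext ? 1 : 0;
      } else {
        unsigned char ext = tbF[(size_t)i * (n + 1) + j];
        ++cols; --j;
        state = ext ? 2 : 0;
      }
    }
    qs = i + 1; ts = j + 1;
  }
  return List::create(_["score"] = best, _["q_start"] = qs,
                      _["q_end"] = qe, _["t_start"] = ts, _["t_end"] = te,
                      _["matches"] = matches, _["columns"] = cols);
}

// Score-only Smith-Waterman of many queries against one target, reusing
// buffers and skipping traceback; used for bulk screens (novelty filter).

// [[Rcpp::export(name = ".sw_scores_cpp")]]
IntegerVector sw_scores_cpp(CharacterVector queries, std::string t,
                            IntegerMatrix sub, std::string alphabet,
                            int gap_open, int gap_ext) {
  const int n = t.size();
  const int na = alphabet.size();
  int idx[256];
  const int xi_default = alphabet.find('X') != std::string::npos
    ? (int)alphabet.find('X') : 0;
  for (int i = 0; i < 256; ++i) idx[i] = xi_default;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;
  std::vector<int> S((size_t)na * na);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < na; ++b)
      S[(size_t)a * na + b] = sub(a, b);
  std::vector<int> ti(n);
  for (int j = 0; j < n; ++j) ti[j] = idx[(unsigned char)t[j]];

  const int NEG = -1000000000;
  const int go = gap_open + gap_ext;
  std::vector<int> Hprev(n + 1), Hcur(n + 1), Eprev(n + 1), Ecur(n + 1),
    Fcur(n + 1);
  IntegerVector out(queries.size());
  for (R_xlen_t qk = 0; qk < queries.size(); ++qk) {
    std::string q = as<std::string>(queries[qk]);
    const int m = q.size();
    std::fill(Hprev.begin(), Hprev.end(), 0);
    std::fill(Eprev.begin(), Eprev.end(), NEG);
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      Hcur[0] = 0; Ecur[0] = NEG; Fcur[0] = NEG;
      const int* srow = &S[(size_t)idx[(unsigned char)q[i - 1]] * na];
      const int* hp = Hprev.data();
      const int* ep = Eprev.data();
      int* hc = Hcur.data();
      int* ec = Ecur.data();
      int* fc = Fcur.data();
      for (int j = 1; j <= n; ++j) {
        int e_open = hp[j] - go, e_ext = ep[j] - gap_ext;
        int e = e_open >= e_ext ? e_open : e_ext;
        int f_open = hc[j - 1] - go, f_ext = fc[j - 1] - gap_ext;
        int f = f_open >= f_ext ? f_open : f_ext;
        int diag = hp[j - 1] + srow[ti[j - 1]];
        int h = diag > 0 ? diag : 0;
        if (e > h) h = e;
        if (f > h) h = f;
        hc[j] = h; ec[j] = e; fc[j] = f;
        if (h > best) best = h;
      }
      std::swap(Hprev, Hcur);
      std::swap(Eprev, Ecur);
    }
    out[qk] = best;
  }
  return out;
}
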