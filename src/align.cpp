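#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

// IUPAC nucleotide bitmasks: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static int iupac_mask(char c) {
  switch (toupper(c)) {
  case 'A': return 1; case 'C': return 2; case 'G': return 4; case 'T': return 8;
  case 'U': return 8;
  case 'R': return 1|4; case 'Y': return 2|8; case 'S': return 2|4;
  case 'W': return 1|8; case 'K': return 4|8; case 'M': return 1|2;
  case 'B': return 2|4|8; case 'D': return 1|4|8; case 'H': return 1|2|8;
  case 'V': return 1|2|4; case 'N': return 1|2|4|8;
  default: return 0;
  }
}

static const int NEG = INT_MIN / 4;

struct SWEnd { int score, qend, send; };

// Score-only affine local alignment (Gotoh); gap of length k costs
// gap_open + k * gap_ext (NCBI convention). Returns best score and the
// 1-based (inclusive) end coordinates of the best-scoring cell.
static SWEnd sw_forward(const std::string& q, const std::string& s,
                        int match, int mismatch, int gap_open, int gap_ext) {
  int n = (int)q.size(), m = (int)s.size();
  std::vector<int> H(n + 1, 0), E(n + 1, NEG);
  SWEnd best = {0, 0, 0};
  for (int j = 1; j <= m; ++j) {
    int diag = 0;       // H[i-1][j-1]
    int F = NEG;        // gap in subject (vertical move over query)
    char sc = s[j - 1];
    for (int i = 1; i <= n; ++i) {
      E[i] = std::max(H[i] - gap_open - gap_ext, E[i] - gap_ext);
      F = std::max(H[i - 1] - gap_open - gap_ext, F - gap_ext);
      int sub = (toupper(q[i - 1]) == toupper(sc)) ? match : mismatch;
      int h = diag + sub;
      if (E[i] > h) h = E[i];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[i];
      H[i] = h;
      if (h > best.score) { best.score = h; best.qend = i; best.send = j; }
    }
  }
  return best;
}

// Global affine alignment with traceback over small substrings; used to
// recover the column composition of the optimal local alignment once its
// end points are known. Returns nident / ncols via pointers.
static int nw_trace(const std::string& q, const std::string& s,
                    int match, int mismatch, int gap_open, int gap_ext,
                    bool iupac, std::string* aq, std::string* as) {
  int n = (int)q.size(), m = (int)s.size();
  std::vector<std::vector<int> > H(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int> > F(n + 1, std::vector<int>(m + 1, NEG));
  H[0][0] = 0;
  for (int j = 1; j <= m; ++j) {
    E[0][j] = -gap_open - j * gap_ext;
    H[0][j] = E[0][j];
  }
  for (int i = 1; i <= n; ++i) {
    F[i][0] = -gap_open - i * gap_ext;
    H[i][0] = F[i][0];
  }
  for (int i = 1; i <= n; ++i) {
    int qm = iupac ? iupac_mask(q[i - 1]) : 0;
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_ext, E[i][j - 1] - gap_ext);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_ext, F[i - 1][j] - gap_ext);
      bool eq = iupac ? ((qm & iupac_mask(s[j - 1])) != 0)
                      : (toupper(q[i - 1]) == toupper(s[j - 1]));
      int h = H[i - 1][j - 1] + (eq ? match : mismatch);
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      H[i][j] = h;
    }
  }
  // traceback (preference: diagonal, then E (gap in query string), then F)
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      int qm = iupac ? iupac_mask(q[i - 1]) : 0;
      bool eq = iupac ? ((qm & iupac_mask(s[j - 1])) != 0)
                      : (toupper(q[i - 1]) == toupper(s[j - 1]));
      if (H[i][j] == H[i - 1][j - 1] + (eq ? match : mismatch)) {
        ra += q[i - 1]; rb += s[j - 1]; --i; --j; continue;
      }
    }
    if (j > 0 && H[i][j] == E[i][j]) {
      // consume a run of subject characters aligned to gaps
      int k = 1;
      while (j - k > 0 &&
             E[i][j] != H[i][j - k] - gap_open - k * gap_ext) ++k;
      for (int t = 0; t < k; ++t) { ra += '-'; rb += s[j - 1 - t]; }
      j -= k; continue;
    }
    if (i > 0) {
      int k = 1;
      while (i - k > 0 &&
             F[i][j] != H[i - k][j] - gap_open - k * gap_ext) ++k;
      for (int t = 0; t < k; ++t) { ra += q[i - 1 - t]; rb += '-'; }
      i -= k; continue;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  *aq = ra; *as = rb;
  return H[n][m];
}

//' Exact local alignment of a query against one subject strand
//'
//' Smith--Waterman with affine gaps (a gap of length k costs
//' gap_open + k * gap_ext). Exhaustive dynamic programming; intended as an
//' oracle and for short sequences, not for genome-scale work.
//'
//' @noRd
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match, int mismatch, int gap_open, int gap_ext) {
  SWEnd fwd = sw_forward(query, subject, match, mismatch, gap_open, gap_ext);
  if (fwd.score <= 0) {
    return List::create(_["score"] = 0, _["nident"] = 0, _["ncols"] = 0,
                        _["qstart"] = NA_INTEGER, _["qend"] = NA_INTEGER,
                        _["sstart"] = NA_INTEGER, _["send"] = NA_INTEGER);
  }
  // locate start by aligning reversed prefixes ending at the best cell
  std::string qr(query.begin(), query.begin() + fwd.qend);
  std::string sr(subject.begin(), subject.begin() + fwd.send);
  std::reverse(qr.begin(), qr.end());
  std::reverse(sr.begin(), sr.end());
  SWEnd rev = sw_forward(qr, sr, match, mismatch, gap_open, gap_ext);
  int qstart = fwd.qend - rev.qend;  // 0-based start
  int sstart = fwd.send - rev.send;
  std::string qs = query.substr(qstart, fwd.qend - qstart);
  std::string ss = subject.substr(sstart, fwd.send - sstart);
  std::string aq, as;
  nw_trace(qs, ss, match, mismatch, gap_open, gap_ext, false, &aq, &as);
  int nident = 0, ncols = (int)aq.size();
  for (int k = 0; k < ncols; ++k)
    if (aq[k] != '-' && as[k] != '-' && toupper(aq[k]) == toupper(as[k]))
      ++nident;
  return List::create(_["score"] = fwd.score, _["nident"] = nident,
                      _["ncols"] = ncols,
                      _["qstart"] = qstart + 1, _["qend"] = fwd.qend,
                      _["sstart"] = sstart + 1, _["send"] = fwd.send);
}

//' Exact global alignment with affine gaps and IUPAC-aware matching
//'
//' Needleman--Wunsch; a gap of length k costs gap_open + k * gap_ext and
//' terminal gaps are penalized. Two bases match when their IUPAC sets
//' intersect (when iupac = TRUE).
//'
//' @noRd
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  int match, int mismatch, int gap_open, int gap_ext,
                  bool iupac) {
  std::string aa, ab;
  int score = nw_trace(a, b, match, mismatch, gap_open, gap_ext, iupac, &aa, &ab);
  return List::create(_["score"] = score,
                      _["aligned_a"] = aa, _["aligned_b"] = ab);
}
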