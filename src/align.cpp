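#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Semiglobal (free-end-gap) Needleman-Wunsch with affine gap penalties.
// A gap run of length k costs gap_open + (k - 1) * gap_ext; runs touching
// either sequence end are free. Three-state DP (M = match/mismatch,
// X = gap in b / consume a, Y = gap in a / consume b) with deterministic
// tie-breaking M > X > Y so traceback prefers diagonal, then gap-in-b.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List cpp_align_overlap(std::string a, std::string b,
                       NumericMatrix submat, std::string alphabet,
                       double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  int idx[256];
  int n_unknown = alphabet.find('N');
  if (n_unknown < 0) n_unknown = 0;
  for (int i = 0; i < 256; ++i) idx[i] = n_unknown;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = i;

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  const int W = m + 1;
#define AT(mat, i, j) mat[(i) * W + (j)]

  AT(M, 0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) AT(X, i, 0) = 0.0;  // free leading gap in b
  for (int j = 1; j <= m; ++j) AT(Y, 0, j) = 0.0;  // free leading gap in a

  for (int i = 1; i <= n; ++i) {
    const int ra = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const double s = submat(ra, idx[(unsigned char)b[j - 1]]);
      double dm = AT(M, i - 1, j - 1), dx = AT(X, i - 1, j - 1),
             dy = AT(Y, i - 1, j - 1);
      double best = dm >= dx ? (dm >= dy ? dm : dy) : (dx >= dy ? dx : dy);
      AT(M, i, j) = best + s;

      double xm = AT(M, i - 1, j) - gap_open;
      double xx = AT(X, i - 1, j) - gap_ext;
      double xy = AT(Y, i - 1, j) - gap_open;
      // interior only: the j == 0 column stays at its free value
      AT(X, i, j) = xm >= xx ? (xm >= xy ? xm : xy) : (xx >= xy ? xx : xy);

      double ym = AT(M, i, j - 1) - gap_open;
      double yy = AT(Y, i, j - 1) - gap_ext;
      double yx = AT(X, i, j - 1) - gap_open;
      AT(Y, i, j) = ym >= yy ? (ym >= yx ? ym : yx) : (yy >= yx ? yy : yx);
    }
  }

  // Best boundary cell (free trailing gaps): scan last row then last column.
  auto cell_best = [&](int i, int j, int &state) {
    double vm = AT(M, i, j), vx = AT(X, i, j), vy = AT(Y, i, j);
    if (vm >= vx && vm >= vy) { state = 0; return vm; }
    if (vx >= vy) { state = 1; return vx; }
    state = 2; return vy;
  };
  double best = NEG_INF;
  int bi = n, bj = m, bstate = 0;
  for (int j = m; j >= 0; --j) {
    int st; double v = cell_best(n, j, st);
    if (v > best) { best = v; bi = n; bj = j; bstate = st; }
  }
  for (int i = n - 1; i >= 0; --i) {
    int st; double v = cell_best(i, m, st);
    if (v > best) { best = v; bi = i; bj = m; bstate = st; }
  }

  std::string ra_out, rb_out;  // built reversed
  ra_out.reserve(n + m); rb_out.reserve(n + m);
  for (int k = n; k > bi; --k) { ra_out.push_back(a[k - 1]); rb_out.push_back('-'); }
  for (int k = m; k > bj; --k) { ra_out.push_back('-'); rb_out.push_back(b[k - 1]); }

  int i = bi, j = bj, state = bstate;
  while (i > 0 || j > 0) {
    if (i == 0) { ra_out.push_back('-'); rb_out.push_back(b[j - 1]); --j; continue; }
    if (j == 0) { ra_out.push_back(a[i - 1]); rb_out.push_back('-'); --i; continue; }
    if (state == 0) {
      ra_out.push_back(a[i - 1]); rb_out.push_back(b[j - 1]);
      double dm = AT(M, i - 1, j - 1), dx = AT(X, i - 1, j - 1),
             dy = AT(Y, i - 1, j - 1);
      --i; --j;
      state = (dm >= dx && dm >= dy) ? 0 : (dx >= dy ? 1 : 2);
    } else if (state == 1) {
      ra_out.push_back(a[i - 1]); rb_out.push_back('-');
      double vm = AT(M, i - 1, j) - gap_open;
      double vx = AT(X, i - 1, j) - gap_ext;
      double vy = AT(Y, i - 1, j) - gap_open;
      --i;
      state = (vm >= vx && vm >= vy) ? 0 : (vx >= vy ? 1 : 2);
    } else {
      ra_out.push_back('-'); rb_out.push_back(b[j - 1]);
      double vm = AT(M, i, j - 1) - gap_open;
      double vy = AT(Y, i, j - 1) - gap_ext;
      double vx = AT(X, i, j - 1) - gap_open;
      --j;
      state = (vm >= vy && vm >= vx) ? 0 : (vy >= vx ? 2 : 1);
    }
  }
#undef AT
  std::reverse(ra_out.begin(), ra_out.end());
  std::reverse(rb_out.begin(), rb_out.end());
  return List::create(_["aligned_a"] = ra_out, _["aligned_b"] = rb_out,
                      _["score"] = best);
}

// [[Rcpp::export]]
double cpp_crc32(RawVector data) {
  static uint32_t table[256];
  static bool have_table = false;
  if (!have_table) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t c = i;
      for (int k = 0; k < 8; ++k)
        c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    have_table = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}
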