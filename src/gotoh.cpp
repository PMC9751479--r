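#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh, three-state DP with full traceback).
// States: M = a[i] aligned to b[j]; X = gap in b (a[i] unmatched, "deletion"
// relative to a-as-reference); Y = gap in a ("insertion").
// A gap of length L costs gap_open + L * gap_extend.
// Tie-breaking on traceback prefers M > X > Y, so alignments are deterministic
// and indels are pushed toward consistent anchors.

static const double NEG_INF = -1e18;

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = (int) a.size();
  const int m = (int) b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // traceback: 2 bits per state, packed per cell
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);

  std::vector<double> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<double> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);

  // row 0
  Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = -(gap_open + j * gap_extend);
    tb[j] |= (uint8_t)(2 << 4); // Y from Y
  }

  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t) i * (m + 1);
    Mcur[0] = NEG_INF;
    Xcur[0] = -(gap_open + i * gap_extend);
    Ycur[0] = NEG_INF;
    tb[row] |= (uint8_t)(1 << 2); // X from X
    const char ai = a[(size_t) i - 1];
    for (int j = 1; j <= m; ++j) {
      const char bj = b[(size_t) j - 1];
      double s = (ai == bj && ai != 'N') ? match : mismatch;
      uint8_t cell = 0;

      // M: diagonal, predecessor preference M > X > Y on ties
      double best = Mprev[j - 1]; uint8_t pred = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; pred = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; pred = 2; }
      Mcur[j] = best + s;
      cell |= pred;

      // X: gap in b, consume a[i]
      double xm = Mprev[j] - (gap_open + gap_extend);
      double xx = Xprev[j] - gap_extend;
      double xy = Yprev[j] - (gap_open + gap_extend);
      best = xm; pred = 0;
      if (xx > best) { best = xx; pred = 1; }
      if (xy > best) { best = xy; pred = 2; }
      Xcur[j] = best;
      cell |= (uint8_t)(pred << 2);

      // Y: gap in a, consume b[j]
      double ym = Mcur[j - 1] - (gap_open + gap_extend);
      double yx = Xcur[j - 1] - (gap_open + gap_extend);
      double yy = Ycur[j - 1] - gap_extend;
      best = ym; pred = 0;
      if (yx > best) { best = yx; pred = 1; }
      if (yy > best) { best = yy; pred = 2; }
      Ycur[j] = best;
      cell |= (uint8_t)(pred << 4);

      tb[row + j] = cell;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  // final state, preference M > X > Y on ties
  double score = Mprev[m]; int state = 0;
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }

  std::string aa, bb;
  aa.reserve(n + m); bb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    uint8_t cell = tb[(size_t) i * (m + 1) + j];
    if (state == 0) {
      aa.push_back(a[(size_t) i - 1]); bb.push_back(b[(size_t) j - 1]);
      state = cell & 3; --i; --j;
    } else if (state == 1) {
      aa.push_back(a[(size_t) i - 1]); bb.push_back('-');
      state = (cell >> 2) & 3; --i;
    } else {
      aa.push_back('-'); bb.push_back(b[(size_t) j - 1]);
      state = (cell >> 4) & 3; --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = score);
}
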