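#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// miRNA/site duplex alignment minimising the Allen complementarity penalty.
//
// The miRNA (5'->3') is aligned against the reverse of the site so that
// column j of the reversed site faces the antiparallel pairing partner.
// Scores are kept as integers in half-units (allen2 = 2 * Allen score).
//
// Penalty scheme (1-based miRNA position i):
//   Watson-Crick pair  0
//   G:U wobble         0.5 * mult(i)
//   mismatch           1   * mult(i)
//   bulged nucleotide  1   * mult  (miRNA-side: mult(i); site-side: doubled
//                      only when both flanking miRNA positions lie in 2..13)
//   mult(i) = 2 if 2 <= i <= 13 else 1
//
// Alignment is semi-global: the whole miRNA is consumed, unaligned site
// overhangs at either end are free.  Ties are broken toward fewer bulges,
// then toward the 5'-most site placement, then pair > miRNA-gap > site-gap.

static const int INF = 1 << 28;

static inline int enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1; // ambiguity codes never pair
  }
}

// 2 = Watson-Crick, 1 = G:U wobble, 0 = no pair
static inline int pair_class(int a, int b) {
  if (a < 0 || b < 0) return 0;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // A:U
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 2; // G:C
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // G:U
  return 0;
}

static inline int mult_pos(int i) { return (i >= 2 && i <= 13) ? 2 : 1; }
static inline int mult_bulge_site(int i) { return (i >= 2 && i <= 12) ? 2 : 1; }

struct AlnResult {
  int allen2;
  int bulges;
  int site_start; // 1-based within window, 5'->3'
  int site_end;
  std::string ops; // '=' WC, 'o' GU, 'x' mismatch, 'm' miRNA bulge, 't' site bulge
};

// Align one miRNA against one site window.  mi: encoded miRNA (len M),
// r: encoded reversed window (len W).
static AlnResult align_one(const std::vector<int>& mi, const std::vector<int>& r) {
  const int M = (int)mi.size();
  const int W = (int)r.size();
  // value matrices
  std::vector<int> D((M + 1) * (W + 1), INF), B((M + 1) * (W + 1), INF);
  auto at = [W](int i, int k) { return i * (W + 1) + k; };

  for (int k = 0; k <= W; ++k) { D[at(0, k)] = 0; B[at(0, k)] = 0; }
  for (int i = 1; i <= M; ++i) {
    D[at(i, 0)] = D[at(i - 1, 0)] + 2 * mult_pos(i);
    B[at(i, 0)] = B[at(i - 1, 0)] + 1;
  }
  for (int i = 1; i <= M; ++i) {
    for (int k = 1; k <= W; ++k) {
      int pc = pair_class(mi[i - 1], r[k - 1]);
      int cdiag = (pc == 2) ? 0 : (pc == 1 ? mult_pos(i) : 2 * mult_pos(i));
      int d = D[at(i - 1, k - 1)] + cdiag, b = B[at(i - 1, k - 1)];
      // miRNA-side bulge at position i
      int du = D[at(i - 1, k)] + 2 * mult_pos(i), bu = B[at(i - 1, k)] + 1;
      if (du < d || (du == d && bu < b)) { d = du; b = bu; }
      // site-side bulge between miRNA positions i and i+1 (free overhang at i == M)
      int dl, bl;
      if (i == M) { dl = D[at(i, k - 1)]; bl = B[at(i, k - 1)]; }
      else { dl = D[at(i, k - 1)] + 2 * mult_bulge_site(i); bl = B[at(i, k - 1)] + 1; }
      if (dl < d || (dl == d && bl < b)) { d = dl; b = bl; }
      D[at(i, k)] = d;
      B[at(i, k)] = b;
    }
  }

  // traceback from (M, W); preference pair > miRNA-gap > site-gap
  AlnResult res;
  res.allen2 = D[at(M, W)];
  res.bulges = B[at(M, W)];
  std::string rops;
  int i = M, k = W;
  int k1 = -1; // last (highest) r column consumed by a non-overhang op
  while (i > 0) {
    int d = D[at(i, k)], b = B[at(i, k)];
    bool moved = false;
    if (k > 0) {
      int pc = pair_class(mi[i - 1], r[k - 1]);
      int cdiag = (pc == 2) ? 0 : (pc == 1 ? mult_pos(i) : 2 * mult_pos(i));
      if (D[at(i - 1, k - 1)] + cdiag == d && B[at(i - 1, k - 1)] == b) {
        rops.push_back(pc == 2 ? '=' : (pc == 1 ? 'o' : 'x'));
        if (k1 < 0) k1 = k;
        --i; --k; moved = true;
      }
    }
    if (!moved && D[at(i - 1, k)] + 2 * mult_pos(i) == d && B[at(i - 1, k)] + 1 == b) {
      rops.push_back('m');
      --i; moved = true;
    }
    if (!moved && k > 0) {
      if (i == M) {
        if (D[at(i, k - 1)] == d && B[at(i, k - 1)] == b) { --k; moved = true; } // trailing overhang
      } else if (D[at(i, k - 1)] + 2 * mult_bulge_site(i) == d && B[at(i, k - 1)] + 1 == b) {
        rops.push_back('t');
        if (k1 < 0) k1 = k;
        --k; moved = true;
      }
    }
    if (!moved) stop("duplex traceback failed (internal error)");
  }
  int k0 = k; // leading overhang length in r
  std::reverse(rops.begin(), rops.end());
  res.ops = rops;
  if (k1 < 0) { // no site nucleotide consumed (degenerate: all-miRNA-bulge)
    res.site_start = 0; res.site_end = -1;
  } else {
    res.site_start = W - k1 + 1;
    res.site_end = W - k0;
  }
  return res;
}

// Scan sliding windows of a sequence with one miRNA.  Returns one row per
// window: window start (1-based), allen2, bulges, absolute site interval
// (1-based inclusive) and the op string.
// [[Rcpp::export(name = ".scan_duplex_cpp")]]
List scan_duplex_cpp(std::string mirna, std::string seq, int window, int step) {
  const int M = (int)mirna.size();
  const int L = (int)seq.size();
  if (M < 1) stop("empty miRNA");
  if (window > L) stop("window longer than sequence");
  if (step < 1) stop("step must be >= 1");
  std::vector<int> mi(M);
  for (int i = 0; i < M; ++i) mi[i] = enc_base(mirna[i]);
  std::vector<int> sq(L);
  for (int i = 0; i < L; ++i) sq[i] = enc_base(seq[i]);

  int n = (L - window) / step + 1;
  IntegerVector start(n), allen2(n), bulges(n), site_start(n), site_end(n);
  CharacterVector ops(n);
  std::vector<int> r(window);
  for (int w = 0; w < n; ++w) {
    int s0 = w * step; // 0-based window start
    for (int k = 0; k < window; ++k) r[k] = sq[s0 + window - 1 - k];
    AlnResult a = align_one(mi, r);
    start[w] = s0 + 1;
    allen2[w] = a.allen2;
    bulges[w] = a.bulges;
    site_start[w] = a.site_start > 0 ? s0 + a.site_start : NA_INTEGER;
    site_end[w] = a.site_start > 0 ? s0 + a.site_end : NA_INTEGER;
    ops[w] = a.ops;
  }
  return List::create(_["start"] = start, _["allen2"] = allen2,
                      _["bulges"] = bulges, _["site_start"] = site_start,
                      _["site_end"] = site_end, _["ops"] = ops);
}
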