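#include <Rcpp.h>
using namespace Rcpp;

// Symmetric (half-sample) extension lookup: position p relative to the
// signal, reflected as ... x1 x0 | x0 x1 ... xn-1 | xn-1 xn-2 ...
static inline int sym_index(int p, int n) {
  while (p < 0 || p >= n) {
    if (p < 0) p = -p - 1;
    if (p >= n) p = 2 * n - 1 - p;
  }
  return p;
}

// One analysis step: convolve the symmetrically extended signal with the
// decomposition filters and keep every second sample. Output length is
// floor((n + F - 1) / 2), the standard non-expansive convention.
// [[Rcpp::export(name = ".dwt_step")]]
List dwt_step(NumericVector x, NumericVector lo, NumericVector hi) {
  const int n = x.size(), F = lo.size();
  const int L = (n + F - 1) / 2;
  NumericVector cA(L), cD(L);
  for (int k = 0; k < L; ++k) {
    double sa = 0.0, sd = 0.0;
    // ext[i] = x[sym(i - (F-1))]; coefficient k reads ext[F + 2k - j]
    for (int j = 0; j < F; ++j) {
      int p = 2 * k + 1 - j;           // (F + 2k - j) - (F - 1)
      double v = x[sym_index(p, n)];
      sa += lo[j] * v;
      sd += hi[j] * v;
    }
    cA[k] = sa;
    cD[k] = sd;
  }
  return List::create(_["cA"] = cA, _["cD"] = cD);
}

// One synthesis step: upsample both coefficient arrays, convolve with the
// reconstruction filters, sum, and trim to the requested output length.
// [[Rcpp::export(name = ".idwt_step")]]
NumericVector idwt_step(NumericVector cA, NumericVector cD,
                        NumericVector lo, NumericVector hi, int n_out) {
  const int L = cA.size(), F = lo.size();
  if (cD.size() != L) stop("coefficient arrays differ in length");
  const int full = 2 * L - F + 2;
  if (n_out > full || n_out < 1)
    stop("requested output length %d not reachable from %d coefficients",
         n_out, L);
  NumericVector y(n_out);
  // y[t] = sum_k cA[k] lo[t + F - 2 - 2k] + cD[k] hi[...], filter index in [0, F)
  for (int t = 0; t < n_out; ++t) {
    const int m = t + F - 2;
    double s = 0.0;
    int kmin = (m - F + 1 + 1) / 2;  // smallest k with m - 2k <= F - 1
    if (kmin < 0) kmin = 0;
    int kmax = m / 2;
    if (kmax > L - 1) kmax = L - 1;
    for (int k = kmin; k <= kmax; ++k) {
      const int j = m - 2 * k;
      s += cA[k] * lo[j] + cD[k] * hi[j];
    }
    y[t] = s;
  }
  return y;
}

// Full multilevel analysis: returns detail coefficients per level plus the
// final approximation, together with the per-level input lengths needed for
// exact reconstruction.
// [[Rcpp::export(name = ".wavedec_c")]]
List wavedec_c(NumericVector x, NumericVector lo, NumericVector hi,
               int levels) {
  List details(levels);
  IntegerVector lens(levels);
  NumericVector cur = x;
  for (int l = 0; l < levels; ++l) {
    lens[l] = cur.size();
    List step = dwt_step(cur, lo, hi);
    details[l] = step["cD"];
    cur = as<NumericVector>(step["cA"]);
  }
  return List::create(_["approx"] = cur, _["details"] = details,
                      _["lengths"] = lens);
}

static NumericVector recon_from(NumericVector seed, int from_level,
                                bool is_detail, List details,
                                IntegerVector lens, NumericVector rlo,
                                NumericVector rhi) {
  // Reconstruct a single band back to the top, all other coefficients zero.
  NumericVector cur = seed;
  for (int l = from_level; l >= 0; --l) {
    NumericVector cD(Rf_xlength(as<NumericVector>(details[l])));
    NumericVector cA(cur.size());
    if (is_detail && l == from_level) {
      cD = seed;
      cA = NumericVector(seed.size());
    } else {
      cA = cur;
      // cD stays zero, but must match cA's length at this level
      cD = NumericVector(cur.size());
    }
    cur = idwt_step(cA, cD, rlo, rhi, lens[l]);
  }
  return cur;
}

// Time-domain reconstruction of every band of a multilevel decomposition.
// Columns: D1 (finest) ... D<levels>, then A<levels>; each of length n.
// [[Rcpp::export(name = ".band_recon_c")]]
NumericMatrix band_recon_c(NumericVector x, NumericVector lo,
                           NumericVector hi, NumericVector rlo,
                           NumericVector rhi, int levels) {
  List dec = wavedec_c(x, lo, hi, levels);
  List details = dec["details"];
  IntegerVector lens = dec["lengths"];
  NumericVector approx = dec["approx"];
  const int n = x.size();
  NumericMatrix out(n, levels + 1);
  for (int l = 0; l < levels; ++l) {
    NumericVector cD = details[l];
    NumericVector band = recon_from(cD, l, true, details, lens, rlo, rhi);
    out(_, l) = band;
  }
  NumericVector av = recon_from(approx, levels - 1, false, details, lens,
                                rlo, rhi);
  out(_, levels) = av;
  return out;
}
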