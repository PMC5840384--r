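#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log-likelihood over occupied joint-genotype classes
static double tp_ll(const int *codes, const int *vals, int k,
                    const double *C, double r) {
  double s = 0.0, q = 1.0 - r;
  for (int t = 0; t < k; ++t) {
    const double *c = C + 3 * codes[t];
    double p = c[0] * q * q + c[1] * r * q + c[2] * r * r;
    if (p <= 0.0) return R_NegInf;
    s += vals[t] * std::log(p);
  }
  return s;
}

// golden-section maximisation of tp_ll on [lo, hi]
static double tp_opt(const int *codes, const int *vals, int k,
                     const double *C, double lo, double hi, double tol,
                     double *fmax) {
  const double gr = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = tp_ll(codes, vals, k, C, x1);
  double f2 = tp_ll(codes, vals, k, C, x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a); f2 = tp_ll(codes, vals, k, C, x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a); f1 = tp_ll(codes, vals, k, C, x1);
    }
  }
  double x = (f1 > f2) ? x1 : x2;
  *fmax = (f1 > f2) ? f1 : f2;
  return x;
}

// [[Rcpp::export]]
List tp_scan_cpp(IntegerMatrix geno, IntegerVector ct, NumericVector coef,
                 double tol) {
  const int nm = geno.nrow(), no = geno.ncol();
  const R_xlen_t npair = (R_xlen_t)nm * (nm - 1) / 2;
  IntegerVector oi(npair), oj(npair), ophase(npair), on(npair);
  NumericVector orf(npair), olod(npair);
  std::vector<int> cnt(256, 0), codes(256), vals(256);
  const double *tabs = coef.begin();
  R_xlen_t out = 0;
  for (int i = 0; i < nm - 1; ++i) {
    const int t1 = ct[i] - 1;
    for (int j = i + 1; j < nm; ++j) {
      const int t2 = ct[j] - 1;
      const int tt = t1 * 3 + t2;
      int k = 0, n = 0;
      for (int o = 0; o < no; ++o) {
        int g1 = geno(i, o), g2 = geno(j, o);
        if (g1 == NA_INTEGER || g2 == NA_INTEGER) continue;
        int jc = (g1 - 1) * 16 + (g2 - 1);
        if (cnt[jc]++ == 0) codes[k++] = jc;
        ++n;
      }
      oi[out] = i + 1; oj[out] = j + 1; on[out] = n;
      if (n < 2) {
        for (int t = 0; t < k; ++t) cnt[codes[t]] = 0;
        orf[out] = NA_REAL; olod[out] = 0.0; ophase[out] = NA_INTEGER;
        ++out;
        continue;
      }
      for (int t = 0; t < k; ++t) { vals[t] = cnt[codes[t]]; cnt[codes[t]] = 0; }
      double bestll = R_NegInf, bestrf = NA_REAL;
      int bestph = 0;
      for (int ph = 0; ph < 4; ++ph) {
        const double *C = tabs + (R_xlen_t)(tt * 4 + ph) * 256 * 3;
        double fmax;
        double r = tp_opt(codes.data(), vals.data(), k, C, 1e-6, 0.4999,
                          tol, &fmax);
        if (fmax > bestll + 1e-9 ||
            (std::abs(fmax - bestll) <= 1e-9 && r < bestrf)) {
          bestll = fmax; bestrf = r; bestph = ph + 1;
        }
      }
      // likelihood at rf = 0.5 is phase-independent
      const double *C0 = tabs + (R_xlen_t)(tt * 4) * 256 * 3;
      double ll0 = tp_ll(codes.data(), vals.data(), k, C0, 0.5);
      double lod = (bestll - ll0) / std::log(10.0);
      orf[out] = bestrf;
      olod[out] = lod > 0.0 ? lod : 0.0;
      ophase[out] = bestph;
      ++out;
    }
  }
  return List::create(_["i"] = oi, _["j"] = oj, _["rf"] = orf,
                      _["lod"] = olod, _["phase"] = ophase, _["n"] = on);
}
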