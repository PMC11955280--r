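#include <Rcpp.h>
using namespace Rcpp;

// Marginalized (forward-algorithm) log-likelihood of encounter histories for
// the joint live-encounter / dead-recovery multi-state model.
//
// Internal 7-state space: 0 alive sub1, 1 died-this-interval sub1,
// 2 alive sub2, 3 died sub2, 4 alive outside, 5 died outside, 6 dead before.
// The one-area (5-state) layout is the special case with subarea 2
// unreachable (m12 = m21 = m23 = 0).
//
// Observation codes in y: 1 detected sub1, 2 recovered sub1, 3 detected sub2,
// 4 recovered sub2, 5 detected outside, 6 recovered outside, 7 not detected.
//
// Transition into occasion t uses the rate matrices' column t (interval
// (t-1, t]; mortality before movement), emission at t uses column t. The
// likelihood conditions on the state at first capture.

// [[Rcpp::export]]
NumericVector msdr_forward_cpp(IntegerMatrix y,
                               IntegerVector first, IntegerVector last,
                               NumericMatrix s1, NumericMatrix s2,
                               NumericMatrix s3,
                               NumericMatrix p1, NumericMatrix p2,
                               NumericMatrix p3,
                               NumericMatrix r1, NumericMatrix r2,
                               NumericMatrix r3,
                               NumericMatrix m12, NumericMatrix m13,
                               NumericMatrix m21, NumericMatrix m23) {
  const int n = y.nrow();
  NumericVector ll(n);
  double a[7], b[7];

  for (int i = 0; i < n; ++i) {
    const int f = first[i] - 1, l = last[i] - 1;
    double lli = 0.0;
    for (int k = 0; k < 7; ++k) a[k] = 0.0;
    const int c0 = y(i, f);
    if (c0 == 1) a[0] = 1.0;
    else if (c0 == 3) a[2] = 1.0;
    else if (c0 == 5) a[4] = 1.0;
    else { ll[i] = R_NegInf; continue; }  // first record must be alive

    bool ok = true;
    for (int t = f + 1; t <= l; ++t) {
      const double sA = s1(i, t), sB = s2(i, t), sO = s3(i, t);
      const double mAB = m12(i, t), mAO = m13(i, t);
      const double mBA = m21(i, t), mBO = m23(i, t);
      // prediction step (mortality before movement)
      b[0] = a[0] * sA * (1.0 - mAB - mAO) + a[2] * sB * mBA;
      b[1] = a[0] * (1.0 - sA);
      b[2] = a[0] * sA * mAB + a[2] * sB * (1.0 - mBA - mBO);
      b[3] = a[2] * (1.0 - sB);
      b[4] = a[0] * sA * mAO + a[2] * sB * mBO + a[4] * sO;
      b[5] = a[4] * (1.0 - sO);
      b[6] = a[1] + a[3] + a[5] + a[6];
      // emission step
      const int c = y(i, t);
      const double pp[6] = { p1(i, t), r1(i, t), p2(i, t), r2(i, t),
                             p3(i, t), r3(i, t) };
      if (c == 7) {
        for (int k = 0; k < 6; ++k) b[k] *= (1.0 - pp[k]);
      } else {
        const double w = b[c - 1] * pp[c - 1];
        for (int k = 0; k < 7; ++k) b[k] = 0.0;
        b[c - 1] = w;
      }
      double tot = 0.0;
      for (int k = 0; k < 7; ++k) tot += b[k];
      if (!(tot > 0.0)) { ok = false; break; }
      lli += std::log(tot);
      for (int k = 0; k < 7; ++k) a[k] = b[k] / tot;
    }
    ll[i] = ok ? lli : R_NegInf;
  }
  return ll;
}
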