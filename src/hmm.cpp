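#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward posterior for the 4-state inheritance-origin HMM.
//
// States are ordered (s1,m1), (s1,m2), (s2,m1), (s2,m2): which of the
// sire's (s) and dam's (m) two haplotypes the offspring's gametes copy.
// emis:   n x 4 emission likelihoods (rows with no information are all 1).
// rec_s:  length n-1 per-interval switch probabilities for the paternal
//         gamete (Haldane recombination fractions between adjacent SNPs).
// rec_m:  same for the maternal gamete.
// Transition probabilities factorize over the two gametes. Scaled
// forward-backward; returns the n x 4 posterior (rows sum to 1).
// [[Rcpp::export]]
NumericMatrix fb_posterior(NumericMatrix emis, NumericVector rec_s,
                           NumericVector rec_m) {
  const int n = emis.nrow();
  NumericMatrix alpha(n, 4), beta(n, 4), post(n, 4);
  std::vector<double> scale(n);

  // forward
  double s0 = 0.0;
  for (int k = 0; k < 4; ++k) {
    alpha(0, k) = 0.25 * emis(0, k);
    s0 += alpha(0, k);
  }
  if (s0 <= 0) { s0 = 1.0; for (int k = 0; k < 4; ++k) alpha(0, k) = 0.25; }
  scale[0] = s0;
  for (int k = 0; k < 4; ++k) alpha(0, k) /= s0;

  for (int t = 1; t < n; ++t) {
    const double rs = rec_s[t - 1], rm = rec_m[t - 1];
    // transition factorizes over the two gametes, but the joint posterior at
    // t-1 need not, so take the full 4x4 product
    double pred[4];
    for (int k = 0; k < 4; ++k) pred[k] = 0.0;
    const double ts[2] = {1 - rs, rs};
    const double tm[2] = {1 - rm, rm};
    for (int j = 0; j < 4; ++j) {
      const int sj = j >> 1, mj = j & 1;
      const double aj = alpha(t - 1, j);
      if (aj == 0.0) continue;
      for (int k = 0; k < 4; ++k) {
        const int sk = k >> 1, mk = k & 1;
        pred[k] += aj * ts[sj == sk ? 0 : 1] * tm[mj == mk ? 0 : 1];
      }
    }
    double st = 0.0;
    for (int k = 0; k < 4; ++k) {
      alpha(t, k) = pred[k] * emis(t, k);
      st += alpha(t, k);
    }
    if (st <= 0) {
      st = 1.0;
      for (int k = 0; k < 4; ++k) alpha(t, k) = pred[k];
      double s2 = pred[0] + pred[1] + pred[2] + pred[3];
      for (int k = 0; k < 4; ++k) alpha(t, k) /= s2;
    } else {
      for (int k = 0; k < 4; ++k) alpha(t, k) /= st;
    }
    scale[t] = st;
  }

  // backward
  for (int k = 0; k < 4; ++k) beta(n - 1, k) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    const double rs = rec_s[t], rm = rec_m[t];
    const double ts[2] = {1 - rs, rs};
    const double tm[2] = {1 - rm, rm};
    double mx = 0.0;
    for (int k = 0; k < 4; ++k) {
      double acc = 0.0;
      const int sk = k >> 1, mk = k & 1;
      for (int j = 0; j < 4; ++j) {
        const int sj = j >> 1, mj = j & 1;
        acc += ts[sk == sj ? 0 : 1] * tm[mk == mj ? 0 : 1] *
               emis(t + 1, j) * beta(t + 1, j);
      }
      beta(t, k) = acc;
      if (acc > mx) mx = acc;
    }
    if (mx <= 0) mx = 1.0;
    for (int k = 0; k < 4; ++k) beta(t, k) /= mx;
  }

  for (int t = 0; t < n; ++t) {
    double tot = 0.0;
    for (int k = 0; k < 4; ++k) {
      post(t, k) = alpha(t, k) * beta(t, k);
      tot += post(t, k);
    }
    if (tot <= 0) { tot = 1.0; for (int k = 0; k < 4; ++k) post(t, k) = 0.25; }
    else for (int k = 0; k < 4; ++k) post(t, k) /= tot;
  }
  return post;
}
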