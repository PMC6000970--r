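#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the admixture model with independent allele-frequency
// priors: each of an individual's two allele copies at a biallelic locus has
// a latent cluster of origin z ~ Categorical(q_i); the allele is Bernoulli
// with the cluster's frequency p_kl ~ Beta(1,1); q_i ~ Dirichlet(alpha).
// Genotypes are coded 0/1/2 alt copies, NA = missing.
//
// [[Rcpp::export]]
List admixture_gibbs_cpp(IntegerMatrix geno, int K, int burnin, int iter,
                         double alpha) {
  const int n = geno.nrow(), L = geno.ncol();
  const int total = burnin + iter;

  // allele copies per call: values 0/1, -1 for absent (missing genotype)
  // copy a = 0 unless g==2; copy b = 1 unless g==0
  std::vector<signed char> xa(n * (size_t)L, -1), xb(n * (size_t)L, -1);
  for (int i = 0; i < n; ++i)
    for (int l = 0; l < L; ++l) {
      int g = geno(i, l);
      if (g == NA_INTEGER) continue;
      size_t id = (size_t)i * L + l;
      xa[id] = (g == 2) ? 1 : 0;
      xb[id] = (g == 0) ? 0 : 1;
    }

  std::vector<signed char> za(n * (size_t)L), zb(n * (size_t)L);
  NumericMatrix P(K, L), Q(n, K);
  NumericMatrix Psum(K, L), Qsum(n, K);
  NumericVector lnl(iter);

  // initialise assignments uniformly
  for (size_t id = 0; id < (size_t)n * L; ++id) {
    za[id] = (signed char)(unif_rand() * K);
    zb[id] = (signed char)(unif_rand() * K);
  }

  std::vector<double> prob(K);
  for (int t = 0; t < total; ++t) {
    // update P | z, x
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l) {
        double a = 1.0, b = 1.0;
        for (int i = 0; i < n; ++i) {
          size_t id = (size_t)i * L + l;
          if (xa[id] >= 0 && za[id] == k) { if (xa[id]) a++; else b++; }
          if (xb[id] >= 0 && zb[id] == k) { if (xb[id]) a++; else b++; }
        }
        P(k, l) = R::rbeta(a, b);
      }

    // update Q | z and z | Q, P
    for (int i = 0; i < n; ++i) {
      std::vector<double> m(K, alpha);
      for (int l = 0; l < L; ++l) {
        size_t id = (size_t)i * L + l;
        if (xa[id] >= 0) m[za[id]] += 1.0;
        if (xb[id] >= 0) m[zb[id]] += 1.0;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { m[k] = R::rgamma(m[k], 1.0); s += m[k]; }
      for (int k = 0; k < K; ++k) Q(i, k) = m[k] / s;

      for (int l = 0; l < L; ++l) {
        size_t id = (size_t)i * L + l;
        if (xa[id] < 0) continue;
        for (int rep = 0; rep < 2; ++rep) {
          signed char x = rep == 0 ? xa[id] : xb[id];
          double tot = 0.0;
          for (int k = 0; k < K; ++k) {
            double pk = x ? P(k, l) : 1.0 - P(k, l);
            prob[k] = Q(i, k) * pk;
            tot += prob[k];
          }
          double u = unif_rand() * tot, c = 0.0;
          int pick = K - 1;
          for (int k = 0; k < K; ++k) { c += prob[k]; if (u <= c) { pick = k; break; } }
          if (rep == 0) za[id] = (signed char)pick; else zb[id] = (signed char)pick;
        }
      }
    }

    if (t >= burnin) {
      double ll = 0.0;
      for (int i = 0; i < n; ++i)
        for (int l = 0; l < L; ++l) {
          size_t id = (size_t)i * L + l;
          if (xa[id] < 0) continue;
          double pa = 0.0, pb = 0.0;
          for (int k = 0; k < K; ++k) {
            pa += Q(i, k) * (xa[id] ? P(k, l) : 1.0 - P(k, l));
            pb += Q(i, k) * (xb[id] ? P(k, l) : 1.0 - P(k, l));
          }
          ll += std::log(pa) + std::log(pb);
        }
      lnl[t - burnin] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
    }
  }

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qsum(i, k) /= iter;
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) /= iter;

  return List::create(_["Q"] = Qsum, _["P"] = Psum, _["lnL"] = lnl);
}
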