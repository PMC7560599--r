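#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of bivariate
// Gaussians with a conjugate Normal-Inverse-Gamma base measure applied
// independently per dimension (diagonal covariance). The point-estimate
// partition is chosen among the stored posterior samples by Dahl's
// least-squares criterion against the posterior coassignment matrix.

struct Prior {
  double m0, k0, a0, b0;
};

static inline double log_t_pred(double x, double n, double sum,
                                double ssq, const Prior &pr) {
  double kn = pr.k0 + n;
  double mn = (pr.k0 * pr.m0 + sum) / kn;
  double an = pr.a0 + 0.5 * n;
  double bn = pr.b0;
  if (n > 0) {
    double mean = sum / n;
    double ss = ssq - sum * sum / n;
    if (ss < 0) ss = 0;
    bn += 0.5 * ss + pr.k0 * n * (mean - pr.m0) * (mean - pr.m0) / (2.0 * kn);
  }
  double nu = 2.0 * an;
  double scale2 = bn * (kn + 1.0) / (an * kn);
  double z = (x - mn) * (x - mn) / (nu * scale2);
  return R::lgammafn((nu + 1.0) / 2.0) - R::lgammafn(nu / 2.0) -
         0.5 * std::log(nu * M_PI * scale2) -
         (nu + 1.0) / 2.0 * std::log1p(z);
}

// [[Rcpp::export]]
List dp_gibbs_cluster(NumericVector x, NumericVector y,
                      double alpha, int n_sweeps, int burn_in, int thin,
                      double m0, double k0, double a0, double b0) {
  int n = x.size();
  Prior pr = {m0, k0, a0, b0};

  std::vector<int> z(n, 0);
  std::vector<int> count;
  std::vector<double> sx, sy, ssx, ssy;
  std::vector<int> freelist;

  // start from a single cluster
  count.push_back(n);
  double tx = 0, ty = 0, tssx = 0, tssy = 0;
  for (int i = 0; i < n; ++i) {
    tx += x[i]; ty += y[i]; tssx += x[i] * x[i]; tssy += y[i] * y[i];
  }
  sx.push_back(tx); sy.push_back(ty); ssx.push_back(tssx); ssy.push_back(tssy);

  std::vector<std::vector<int> > stored;
  std::vector<double> logp;
  std::vector<int> active;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int i = 0; i < n; ++i) {
      int c = z[i];
      count[c]--; sx[c] -= x[i]; sy[c] -= y[i];
      ssx[c] -= x[i] * x[i]; ssy[c] -= y[i] * y[i];
      if (count[c] == 0) freelist.push_back(c);

      active.clear();
      for (size_t cc = 0; cc < count.size(); ++cc)
        if (count[cc] > 0) active.push_back((int)cc);

      int m = (int)active.size();
      logp.assign(m + 1, 0.0);
      double best = -1e300;
      for (int a = 0; a < m; ++a) {
        int cc = active[a];
        logp[a] = std::log((double)count[cc]) +
                  log_t_pred(x[i], count[cc], sx[cc], ssx[cc], pr) +
                  log_t_pred(y[i], count[cc], sy[cc], ssy[cc], pr);
        if (logp[a] > best) best = logp[a];
      }
      logp[m] = std::log(alpha) + log_t_pred(x[i], 0, 0, 0, pr) +
                log_t_pred(y[i], 0, 0, 0, pr);
      if (logp[m] > best) best = logp[m];

      double tot = 0;
      for (int a = 0; a <= m; ++a) { logp[a] = std::exp(logp[a] - best); tot += logp[a]; }
      double u = R::unif_rand() * tot, acc = 0;
      int pick = m;
      for (int a = 0; a <= m; ++a) { acc += logp[a]; if (u <= acc) { pick = a; break; } }

      int cnew;
      if (pick == m) {
        if (!freelist.empty()) { cnew = freelist.back(); freelist.pop_back(); }
        else {
          cnew = (int)count.size();
          count.push_back(0); sx.push_back(0); sy.push_back(0);
          ssx.push_back(0); ssy.push_back(0);
        }
      } else cnew = active[pick];
      z[i] = cnew;
      count[cnew]++; sx[cnew] += x[i]; sy[cnew] += y[i];
      ssx[cnew] += x[i] * x[i]; ssy[cnew] += y[i] * y[i];
    }
    if (sweep >= burn_in && ((sweep - burn_in) % thin == 0))
      stored.push_back(z);
  }

  int S = (int)stored.size();
  // posterior coassignment matrix
  std::vector<double> P((size_t)n * n, 0.0);
  for (int s = 0; s < S; ++s) {
    const std::vector<int> &zs = stored[s];
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        if (zs[i] == zs[j]) P[(size_t)i * n + j] += 1.0;
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) P[(size_t)i * n + j] /= S;

  // Dahl least-squares choice among stored partitions
  int best_s = 0;
  double best_score = 1e300;
  for (int s = 0; s < S; ++s) {
    const std::vector<int> &zs = stored[s];
    double score = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double d = (zs[i] == zs[j] ? 1.0 : 0.0) - P[(size_t)i * n + j];
        score += d * d;
      }
    if (score < best_score) { best_score = score; best_s = s; }
  }

  // relabel chosen partition contiguously
  const std::vector<int> &zb = stored[best_s];
  std::vector<int> relab(count.size() + n, -1);
  IntegerVector out(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (relab[zb[i]] < 0) relab[zb[i]] = next++;
    out[i] = relab[zb[i]] + 1;
  }
  return List::create(_["assignment"] = out,
                      _["n_clusters"] = next,
                      _["n_samples"] = S);
}
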