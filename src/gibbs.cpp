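#include <Rcpp.h>
using namespace Rcpp;

// Collapsed data-augmentation Gibbs sampler for the binary admixture model:
//   z_ij | q_i        ~ Categorical(q_i)
//   x_ij | z_ij = k   ~ Bernoulli(f_kj)
//   f_kj              ~ Beta(beta, beta)
//   q_i               ~ Dirichlet(alpha * 1_K)
// X is N x M with entries 0/1 and NA (masked cells, skipped everywhere).
// Uses R's RNG so set.seed() in R makes runs reproducible.

static int sample_categorical(const double *w, int K) {
  double tot = 0.0;
  for (int k = 0; k < K; ++k) tot += w[k];
  double u = unif_rand() * tot, acc = 0.0;
  for (int k = 0; k < K; ++k) {
    acc += w[k];
    if (u <= acc) return k;
  }
  return K - 1;
}

// Greedy L2 matching of rows of f to rows of ref; returns perm with
// perm[k] = row of f assigned to reference cluster k.
static std::vector<int> match_labels(const NumericMatrix &f,
                                     const NumericMatrix &ref) {
  int K = f.nrow(), M = f.ncol();
  std::vector<std::vector<double>> cost(K, std::vector<double>(K));
  for (int a = 0; a < K; ++a)
    for (int b = 0; b < K; ++b) {
      double s = 0.0;
      for (int j = 0; j < M; ++j) {
        double d = ref(a, j) - f(b, j);
        s += d * d;
      }
      cost[a][b] = s;
    }
  std::vector<int> perm(K, -1);
  std::vector<bool> used_a(K, false), used_b(K, false);
  for (int step = 0; step < K; ++step) {
    double best = R_PosInf;
    int ba = -1, bb = -1;
    for (int a = 0; a < K; ++a) {
      if (used_a[a]) continue;
      for (int b = 0; b < K; ++b) {
        if (used_b[b]) continue;
        if (cost[a][b] < best) { best = cost[a][b]; ba = a; bb = b; }
      }
    }
    perm[ba] = bb;
    used_a[ba] = true;
    used_b[bb] = true;
  }
  return perm;
}

// [[Rcpp::export]]
List gibbs_admixture_cpp(IntegerMatrix X, int K, int burn_in, int n_iter,
                         int thin, double alpha, double beta) {
  if (K < 1) stop("K must be >= 1");
  if (thin < 1) stop("thin must be >= 1");
  int N = X.nrow(), M = X.ncol();

  NumericMatrix q(N, K), f(K, M);
  IntegerMatrix z(N, M);
  GetRNGstate();

  // init: uniform q, Beta-prior draws for f, z from q
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;
  for (int k = 0; k < K; ++k)
    for (int j = 0; j < M; ++j) f(k, j) = R::rbeta(beta, beta);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < M; ++j)
      z(i, j) = (int)(unif_rand() * K) % K;

  int total = burn_in + n_iter;
  int n_rec = 0;
  NumericMatrix q_sum(N, K), f_sum(K, M), f_ref(K, M);
  std::vector<double> lnl_trace;
  lnl_trace.reserve(n_iter / thin + 1);
  std::vector<double> w(K);
  std::vector<std::vector<double>> ones(K, std::vector<double>(M)),
      zeros(K, std::vector<double>(M));
  std::vector<double> cnt(K);

  for (int it = 0; it < total; ++it) {
    // z | q, f  and sufficient statistics for f, q
    for (int k = 0; k < K; ++k)
      std::fill(ones[k].begin(), ones[k].end(), 0.0),
      std::fill(zeros[k].begin(), zeros[k].end(), 0.0);
    for (int i = 0; i < N; ++i) {
      std::fill(cnt.begin(), cnt.end(), 0.0);
      for (int j = 0; j < M; ++j) {
        int x = X(i, j);
        if (x == NA_INTEGER) continue;
        for (int k = 0; k < K; ++k)
          w[k] = q(i, k) * (x == 1 ? f(k, j) : 1.0 - f(k, j));
        int zk = (K == 1) ? 0 : sample_categorical(w.data(), K);
        z(i, j) = zk;
        cnt[zk] += 1.0;
        if (x == 1) ones[zk][j] += 1.0; else zeros[zk][j] += 1.0;
      }
      // q_i | z ~ Dirichlet(alpha + cnt)
      if (K == 1) {
        q(i, 0) = 1.0;
      } else {
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          double g = R::rgamma(alpha + cnt[k], 1.0);
          if (g <= 0) g = 1e-300;
          q(i, k) = g;
          tot += g;
        }
        for (int k = 0; k < K; ++k) q(i, k) /= tot;
      }
    }
    // f | z
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < M; ++j) {
        double fk = R::rbeta(beta + ones[k][j], beta + zeros[k][j]);
        if (fk < 1e-12) fk = 1e-12;
        if (fk > 1.0 - 1e-12) fk = 1.0 - 1e-12;
        f(k, j) = fk;
      }

    if (it >= burn_in && (it - burn_in) % thin == 0) {
      // marginal log-likelihood at current (q, f)
      double lnl = 0.0;
      for (int i = 0; i < N; ++i)
        for (int j = 0; j < M; ++j) {
          int x = X(i, j);
          if (x == NA_INTEGER) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k)
            s += q(i, k) * (x == 1 ? f(k, j) : 1.0 - f(k, j));
          lnl += std::log(s);
        }
      lnl_trace.push_back(lnl);

      // relabel against the first recorded sample before averaging
      if (n_rec == 0) {
        for (int k = 0; k < K; ++k)
          for (int j = 0; j < M; ++j) f_ref(k, j) = f(k, j);
      }
      std::vector<int> perm = match_labels(f, f_ref);
      for (int k = 0; k < K; ++k) {
        int src = perm[k];
        for (int j = 0; j < M; ++j) f_sum(k, j) += f(src, j);
        for (int i = 0; i < N; ++i) q_sum(i, k) += q(i, src);
      }
      ++n_rec;
    }
  }
  PutRNGstate();

  if (n_rec == 0) stop("no post-burn-in samples recorded; increase n_iter");
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < M; ++j) f_sum(k, j) /= n_rec;
    for (int i = 0; i < N; ++i) q_sum(i, k) /= n_rec;
  }
  // renormalise q rows against accumulated rounding
  for (int i = 0; i < N; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += q_sum(i, k);
    for (int k = 0; k < K; ++k) q_sum(i, k) /= tot;
  }

  return List::create(_["q"] = q_sum, _["f"] = f_sum,
                      _["lnl_trace"] = NumericVector(lnl_trace.begin(), lnl_trace.end()),
                      _["n_recorded"] = n_rec);
}
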