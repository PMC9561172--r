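// SparCC-style compositional correlation estimation.
//
// Per iteration: resample component fractions from a Dirichlet(count + 1)
// posterior, form the variation matrix t_ij = Var(log x_i/x_j), solve the
// sparse-correlation basis system (diagonal p-1, off-diagonal 1) for basis
// variances, convert to correlations, then run exclusion rounds that drop the
// currently strongest |rho| > threshold pair from the system and re-solve.
// Final rho is the element-wise median over iterations, clamped to [-1, 1].
//
// Uses an internal xoshiro256++ generator (seeded from the caller-supplied
// integer) so results are deterministic across platforms and independent of
// R's global RNG state.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    // seed the state via splitmix64
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {  // Marsaglia polar
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    return u * std::sqrt(-2.0 * std::log(q) / q);
  }
  // Marsaglia-Tsang; valid for alpha >= 1 (shapes here are count + 1 >= 1)
  inline double gamma(double alpha) {
    double d = alpha - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x = norm();
      double v = 1.0 + c * x;
      if (v <= 0.0) continue;
      v = v * v * v;
      double u = unif();
      double x2 = x * x;
      if (u < 1.0 - 0.0331 * x2 * x2) return d * v;
      if (std::log(u) < 0.5 * x2 + d * (1.0 - v + std::log(v))) return d * v;
    }
  }
  inline arma::uvec perm(arma::uword n) {  // Fisher-Yates
    arma::uvec p(n);
    for (arma::uword i = 0; i < n; ++i) p[i] = i;
    for (arma::uword i = n - 1; i > 0; --i) {
      arma::uword j = (arma::uword)(unif() * (double)(i + 1));
      if (j > i) j = i;
      std::swap(p[i], p[j]);
    }
    return p;
  }
};

// One full SparCC fit (median over `iterations` resamples) on a counts matrix
// (samples x taxa). n_bad (out) counts taxon pairs zeroed for non-positive
// basis variance.
arma::mat sparcc_fit(const arma::mat &counts, int iterations, int exclude_iterations,
                     double threshold, Xoshiro256pp &rng, int &n_bad) {
  const arma::uword n = counts.n_rows, p = counts.n_cols;
  arma::cube rhos(p, p, (arma::uword)iterations);
  n_bad = 0;

  for (int it = 0; it < iterations; ++it) {
    // Dirichlet(count + 1) fractions, then log
    arma::mat L(n, p);
    for (arma::uword i = 0; i < n; ++i) {
      double tot = 0.0;
      for (arma::uword j = 0; j < p; ++j) {
        double g = rng.gamma(counts(i, j) + 1.0);
        L(i, j) = g;
        tot += g;
      }
      for (arma::uword j = 0; j < p; ++j) L(i, j) = std::log(L(i, j) / tot);
    }
    arma::mat C = arma::cov(L);            // p x p covariance of log fractions
    arma::vec v = C.diag();
    arma::mat V = arma::repmat(v, 1, p) + arma::repmat(v.t(), p, 1) - 2.0 * C;
    V.diag().zeros();

    // basis system
    arma::mat M(p, p, arma::fill::ones);
    M.diag() += (double)p - 2.0;           // diagonal = p - 1
    arma::vec rs = arma::sum(V, 1);
    arma::vec omega = arma::solve(M, rs, arma::solve_opts::fast);

    arma::umat excluded(p, p, arma::fill::zeros);
    arma::uvec excl_count(p, arma::fill::zeros);

    auto to_rho = [&](arma::mat &rho) {
      for (arma::uword a = 0; a < p; ++a) {
        for (arma::uword b = 0; b < p; ++b) {
          if (a == b) { rho(a, b) = 1.0; continue; }
          double wa = omega[a], wb = omega[b];
          if (wa <= 0.0 || wb <= 0.0) { rho(a, b) = 0.0; continue; }
          double r = (wa + wb - V(a, b)) / (2.0 * std::sqrt(wa * wb));
          rho(a, b) = std::max(-1.0, std::min(1.0, r));
        }
      }
    };
    arma::mat rho(p, p);
    to_rho(rho);

    for (int e = 0; e < exclude_iterations; ++e) {
      // strongest not-yet-excluded off-diagonal pair among still-solvable taxa
      double best = 0.0; arma::uword bi = 0, bj = 0; bool found = false;
      for (arma::uword a = 0; a < p; ++a) {
        for (arma::uword b = a + 1; b < p; ++b) {
          if (excluded(a, b)) continue;
          if (excl_count[a] >= p - 3 || excl_count[b] >= p - 3) continue;
          double r = std::fabs(rho(a, b));
          if (r > best) { best = r; bi = a; bj = b; found = true; }
        }
      }
      if (!found || best <= threshold) break;
      excluded(bi, bj) = excluded(bj, bi) = 1;
      ++excl_count[bi]; ++excl_count[bj];
      rs[bi] -= V(bi, bj); rs[bj] -= V(bi, bj);
      M(bi, bj) = M(bj, bi) = 0.0;
      M(bi, bi) -= 1.0; M(bj, bj) -= 1.0;
      omega = arma::solve(M, rs, arma::solve_opts::fast);
      to_rho(rho);
    }

    for (arma::uword a = 0; a < p; ++a)
      for (arma::uword b = a + 1; b < p; ++b)
        if (omega[a] <= 0.0 || omega[b] <= 0.0) ++n_bad;
    rhos.slice((arma::uword)it) = rho;
  }

  arma::mat med(p, p);
  arma::vec buf((arma::uword)iterations);
  for (arma::uword a = 0; a < p; ++a) {
    for (arma::uword b = 0; b < p; ++b) {
      for (int it = 0; it < iterations; ++it) buf[(arma::uword)it] = rhos(a, b, (arma::uword)it);
      med(a, b) = arma::median(buf);
    }
  }
  med = 0.5 * (med + med.t());
  med.diag().ones();
  med.clamp(-1.0, 1.0);
  return med;
}

}  // namespace

// [[Rcpp::export(name = ".sparcc_fit_cpp")]]
List sparcc_fit_cpp(arma::mat counts, int iterations, int exclude_iterations,
                    double threshold, double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  int n_bad = 0;
  arma::mat rho = sparcc_fit(counts, iterations, exclude_iterations, threshold, rng, n_bad);
  return List::create(_["rho"] = rho, _["n_nonpositive_basis"] = n_bad);
}

// Permutation null: each replicate independently permutes every taxon's
// column, refits, and accumulates #{|rho_null| >= |rho_obs|} per pair.
// [[Rcpp::export(name = ".sparcc_perm_exceed_cpp")]]
arma::mat sparcc_perm_exceed_cpp(arma::mat counts, arma::mat abs_rho_obs, int n_boot,
                                 int iterations, int exclude_iterations,
                                 double threshold, double seed) {
  Xoshiro256pp rng((uint64_t)seed);
  const arma::uword n = counts.n_rows, p = counts.n_cols;
  arma::mat exceed(p, p, arma::fill::zeros);
  for (int b = 0; b < n_boot; ++b) {
    arma::mat perm(n, p);
    for (arma::uword j = 0; j < p; ++j) {
      arma::uvec idx = rng.perm(n);
      for (arma::uword i = 0; i < n; ++i) perm(i, j) = counts(idx[i], j);
    }
    int n_bad = 0;
    arma::mat rho = sparcc_fit(perm, iterations, exclude_iterations, threshold, rng, n_bad);
    exceed += arma::conv_to<arma::mat>::from(arma::abs(rho) >= abs_rho_obs);
    if ((b & 15) == 0) Rcpp::checkUserInterrupt();
  }
  return exceed;
}
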