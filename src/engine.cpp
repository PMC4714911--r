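// Adaptive Metropolis-within-Gibbs sampler for the geogenetic-map model.
//
// Block layout (0-based), K populations:
//   0 = a0, 1 = a1, 2 = a2, 3..K+2 = eta_k, K+3..2K+2 = w_k,
//   2K+3..3K+2 = G_k, 3K+3..4K+2 = Gstar_k
// Locations live in a (2K) x 2 matrix: rows 0..K-1 are G, K..2K-1 are Gstar.
// On the sphere, coordinates are held in radians internally and exchanged
// with R in degrees; distances are arcs on the unit sphere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

struct Engine {
  int K, p, nb;
  bool sphere;
  double Ldf;
  arma::mat Psi;          // K x p
  arma::mat Ahat_cholL;   // p x p lower Cholesky factor of L * Psi' omega_hat Psi
  double const_part;      // data-dependent part of the Wishart log density
  arma::vec Sbar;

  // priors
  double rate_a0, rate_a1, rate_eta, a2_lo, a2_hi, beta_a, beta_b;
  arma::mat Gmu, Gsmu;    // K x 2 (radians if sphere)
  double sigma_G, sigma_Gs;

  // state
  double a0, a1, a2;
  arma::vec eta, w;
  arma::mat loc;          // 2K x 2
  arma::mat D, E;         // 2K x 2K distances and exp(-(a1 D)^a2)
  double log_lik, log_prior_tot;

  double dist_pts(double x1, double y1, double x2, double y2) const {
    if (!sphere) {
      const double dx = x1 - x2, dy = y1 - y2;
      return std::sqrt(dx * dx + dy * dy);
    }
    const double s1 = std::sin((y1 - y2) * 0.5), s2 = std::sin((x1 - x2) * 0.5);
    double h = s1 * s1 + std::cos(y1) * std::cos(y2) * s2 * s2;
    if (h > 1.0) h = 1.0;
    if (h < 0.0) h = 0.0;
    return 2.0 * std::asin(std::sqrt(h));
  }

  void rebuild_D() {
    const int n = 2 * K;
    for (int i = 0; i < n; ++i) {
      D(i, i) = 0.0;
      for (int j = 0; j < i; ++j) {
        const double d = dist_pts(loc(i, 0), loc(i, 1), loc(j, 0), loc(j, 1));
        D(i, j) = d;
        D(j, i) = d;
      }
    }
  }

  void rebuild_E() {
    const int n = 2 * K;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j <= i; ++j) {
        const double e = std::exp(-std::pow(a1 * D(i, j), a2));
        E(i, j) = e;
        E(j, i) = e;
      }
  }

  // refresh row/column r of D and E after moving location r
  void update_row(int r) {
    const int n = 2 * K;
    for (int j = 0; j < n; ++j) {
      double d = (j == r) ? 0.0
                          : dist_pts(loc(r, 0), loc(r, 1), loc(j, 0), loc(j, 1));
      D(r, j) = d; D(j, r) = d;
      double e = std::exp(-std::pow(a1 * d, a2));
      E(r, j) = e; E(j, r) = e;
    }
  }

  // Wishart log-likelihood of the projected sample covariance at the
  // current (a0, E, w, eta) state; -Inf when not positive definite.
  double compute_loglik() const {
    arma::mat omega(K, K);
    const double inv_a0 = 1.0 / a0;
    for (int i = 0; i < K; ++i) {
      const double ui = 1.0 - w(i);
      for (int j = 0; j <= i; ++j) {
        const double uj = 1.0 - w(j);
        double v = ui * uj * E(i, j) + w(i) * uj * E(K + i, j) +
                   w(j) * ui * E(i, K + j) + w(i) * w(j) * E(K + i, K + j);
        v *= inv_a0;
        omega(i, j) = v;
        omega(j, i) = v;
      }
      omega(i, i) += eta(i) + 1.0 / Sbar(i);
    }
    arma::mat V = Psi.t() * omega * Psi;
    arma::mat R;
    if (!arma::chol(R, V, "lower")) return -arma::datum::inf;
    double ldV = 0.0;
    for (int i = 0; i < p; ++i) ldV += std::log(R(i, i));
    ldV *= 2.0;
    // tr(V^-1 A) = ||R^-1 La||_F^2 with V = R R', A = La La'
    arma::mat M = arma::solve(arma::trimatl(R), Ahat_cholL);
    const double tr = arma::accu(M % M);
    return const_part - 0.5 * Ldf * ldV - 0.5 * tr;
  }

  double loc_prior(int r) const {
    const bool isG = r < K;
    const arma::mat& mu = isG ? Gmu : Gsmu;
    const int k = isG ? r : r - K;
    const double s = isG ? sigma_G : sigma_Gs;
    const double d = dist_pts(loc(r, 0), loc(r, 1), mu(k, 0), mu(k, 1));
    return -0.5 * d * d / (s * s) - std::log(TWO_PI * s * s);
  }

  double block_prior(int b) const {
    if (b == 0) {
      if (a0 <= 0) return -arma::datum::inf;
      return std::log(rate_a0) - rate_a0 * a0;
    }
    if (b == 1) {
      if (a1 <= 0) return -arma::datum::inf;
      return std::log(rate_a1) - rate_a1 * a1;
    }
    if (b == 2) {
      if (a2 <= a2_lo || a2 > a2_hi) return -arma::datum::inf;
      return -std::log(a2_hi - a2_lo);
    }
    if (b <= 2 + K) {
      const double e = eta(b - 3);
      if (e < 0) return -arma::datum::inf;
      return std::log(rate_eta) - rate_eta * e;
    }
    if (b <= 2 + 2 * K) {
      const double wk = w(b - 3 - K);
      if (wk < 0 || wk > 0.5) return -arma::datum::inf;
      return std::log(2.0) + R::dbeta(2.0 * wk, beta_a, beta_b, 1);
    }
    if (b <= 2 + 3 * K) return loc_prior(b - 3 - 2 * K);
    return loc_prior(K + (b - 3 - 3 * K));
  }
};

static double lmvgamma_c(int p, double a) {
  double s = 0.25 * p * (p - 1) * std::log(M_PI);
  for (int j = 1; j <= p; ++j) s += R::lgammafn(a + (1.0 - j) / 2.0);
  return s;
}

// [[Rcpp::export(name = ".mcmc_engine")]]
List mcmc_engine(const arma::mat& omega_hat, const arma::mat& Psi_in,
                 double Ldf, const arma::vec& Sbar, List state0,
                 bool sphere, const IntegerVector& free_blocks,
                 List priors, double n_iter_d, double thin_d,
                 int adapt_window, double zeta_cap,
                 const arma::vec& zeta0) {
  Engine eng;
  eng.K = Sbar.n_elem;
  eng.Psi = Psi_in;
  eng.p = Psi_in.n_cols;
  eng.nb = 3 + 4 * eng.K;
  eng.sphere = sphere;
  eng.Ldf = Ldf;
  eng.Sbar = Sbar;

  arma::mat Ahat = Ldf * (Psi_in.t() * omega_hat * Psi_in);
  arma::mat cA;
  if (!arma::chol(cA, Ahat, "lower"))
    stop("projected sample covariance is not positive definite");
  eng.Ahat_cholL = cA;
  double ldA = 0.0;
  for (int i = 0; i < eng.p; ++i) ldA += std::log(cA(i, i));
  ldA *= 2.0;
  eng.const_part = 0.5 * (Ldf - eng.p - 1) * ldA -
                   0.5 * Ldf * eng.p * std::log(2.0) -
                   lmvgamma_c(eng.p, Ldf / 2.0);

  eng.rate_a0 = priors["rate_a0"]; eng.rate_a1 = priors["rate_a1"];
  eng.rate_eta = priors["rate_eta"];
  NumericVector a2b = priors["a2_bounds"];
  eng.a2_lo = a2b[0]; eng.a2_hi = a2b[1];
  NumericVector wb = priors["w_beta"];
  eng.beta_a = wb[0]; eng.beta_b = wb[1];
  eng.Gmu = as<arma::mat>(priors["Gmu"]);
  eng.Gsmu = as<arma::mat>(priors["Gsmu"]);
  eng.sigma_G = priors["sigma_G"]; eng.sigma_Gs = priors["sigma_Gstar"];

  eng.a0 = state0["a0"]; eng.a1 = state0["a1"]; eng.a2 = state0["a2"];
  eng.eta = as<arma::vec>(state0["eta"]);
  eng.w = as<arma::vec>(state0["w"]);
  arma::mat G = as<arma::mat>(state0["G"]);
  arma::mat Gs = as<arma::mat>(state0["Gstar"]);
  eng.loc = arma::join_cols(G, Gs);
  const double deg2rad = M_PI / 180.0;
  if (sphere) {
    eng.loc *= deg2rad;
    eng.Gmu *= deg2rad;
    eng.Gsmu *= deg2rad;
  }

  const int K = eng.K, nb = eng.nb;
  eng.D.set_size(2 * K, 2 * K);
  eng.E.set_size(2 * K, 2 * K);
  eng.rebuild_D();
  eng.rebuild_E();
  eng.log_lik = eng.compute_loglik();
  if (!std::isfinite(eng.log_lik))
    stop("likelihood not finite at the initial state");

  // total log prior over free blocks
  std::vector<bool> is_free(nb, false);
  for (int i = 0; i < free_blocks.size(); ++i) is_free[free_blocks[i]] = true;
  eng.log_prior_tot = 0.0;
  for (int b = 0; b < nb; ++b)
    if (is_free[b]) eng.log_prior_tot += eng.block_prior(b);
  if (!std::isfinite(eng.log_prior_tot))
    stop("prior not finite at the initial state");

  const long long n_iter = (long long)n_iter_d;
  const long long thin = (long long)thin_d;
  const long long n_samp = n_iter / thin;
  const int npar = 3 + 6 * K;

  arma::mat samples(n_samp, npar);
  arma::vec out_ll(n_samp), out_lp(n_samp);
  arma::mat zeta_hist(n_samp, nb);
  arma::mat acc_hist(n_samp, nb), prop_hist(n_samp, nb);

  arma::vec zeta = zeta0;
  std::vector<long long> acc_tot(nb, 0), prop_tot(nb, 0);
  std::vector<int> win_acc(nb, 0), win_cnt(nb, 0);
  std::vector<long long> epoch(nb, 1);

  const int nfree = free_blocks.size();
  RNGScope scope;

  long long si = 0;
  for (long long it = 1; it <= n_iter; ++it) {
    const int b = free_blocks[(int)(unif_rand() * nfree) % nfree];
    const double step = std::exp(zeta(b));

    bool accepted = false;
    double save1 = 0, save2 = 0;
    int movedrow = -1;
    arma::vec oldD, oldE;

    // propose, evaluate, commit-or-restore
    if (b == 0) {
      save1 = eng.a0;
      eng.a0 = eng.a0 + step * norm_rand();
      const double lp_new = eng.block_prior(0);
      if (std::isfinite(lp_new)) {
        const double lp_old = std::log(eng.rate_a0) - eng.rate_a0 * save1;
        const double ll_new = eng.compute_loglik();
        if (std::log(unif_rand()) < (ll_new - eng.log_lik) + (lp_new - lp_old)) {
          eng.log_lik = ll_new;
          eng.log_prior_tot += lp_new - lp_old;
          accepted = true;
        }
      }
      if (!accepted) eng.a0 = save1;
    } else if (b == 1 || b == 2) {
      double lp_old, lp_new;
      if (b == 1) { save1 = eng.a1; eng.a1 += step * norm_rand(); }
      else        { save1 = eng.a2; eng.a2 += step * norm_rand(); }
      lp_new = eng.block_prior(b);
      if (std::isfinite(lp_new)) {
        if (b == 1) lp_old = std::log(eng.rate_a1) - eng.rate_a1 * save1;
        else        lp_old = -std::log(eng.a2_hi - eng.a2_lo);
        arma::mat oldEm = eng.E;
        eng.rebuild_E();
        const double ll_new = eng.compute_loglik();
        if (std::log(unif_rand()) < (ll_new - eng.log_lik) + (lp_new - lp_old)) {
          eng.log_lik = ll_new;
          eng.log_prior_tot += lp_new - lp_old;
          accepted = true;
        } else {
          eng.E = oldEm;
        }
      }
      if (!accepted) { if (b == 1) eng.a1 = save1; else eng.a2 = save1; }
    } else if (b <= 2 + 2 * K) {
      // eta_k or w_k: covariance rebuild only (E unchanged)
      const bool is_eta = b <= 2 + K;
      const int k = is_eta ? (b - 3) : (b - 3 - K);
      double* val = is_eta ? &eng.eta(k) : &eng.w(k);
      save1 = *val;
      const double lp_old = eng.block_prior(b);
      *val = *val + step * norm_rand();
      const double lp_new = eng.block_prior(b);
      if (std::isfinite(lp_new)) {
        const double ll_new = eng.compute_loglik();
        if (std::log(unif_rand()) < (ll_new - eng.log_lik) + (lp_new - lp_old)) {
          eng.log_lik = ll_new;
          eng.log_prior_tot += lp_new - lp_old;
          accepted = true;
        }
      }
      if (!accepted) *val = save1;
    } else {
      // location move: G_k (row k) or Gstar_k (row K + k)
      movedrow = (b <= 2 + 3 * K) ? (b - 3 - 2 * K) : (K + b - 3 - 3 * K);
      save1 = eng.loc(movedrow, 0); save2 = eng.loc(movedrow, 1);
      const double lp_old = eng.block_prior(b);
      if (eng.sphere) {
        const double delta = std::fabs(step * norm_rand());
        const double gamma = TWO_PI * unif_rand();
        const double phi = save2, lam = save1;
        const double phi2 = std::asin(std::sin(phi) * std::cos(delta) +
                                      std::cos(phi) * std::sin(delta) *
                                      std::cos(gamma));
        double lam2 = lam + std::atan2(std::sin(gamma) * std::sin(delta) *
                                       std::cos(phi),
                                       std::cos(delta) -
                                       std::sin(phi) * std::sin(phi2));
        // wrap to (-pi, pi]; |lam2| < 2 pi here so one step suffices
        if (lam2 > M_PI) lam2 -= TWO_PI;
        else if (lam2 <= -M_PI) lam2 += TWO_PI;
        eng.loc(movedrow, 0) = lam2; eng.loc(movedrow, 1) = phi2;
      } else {
        eng.loc(movedrow, 0) += step * norm_rand();
        eng.loc(movedrow, 1) += step * norm_rand();
      }
      const double lp_new = eng.block_prior(b);
      oldD = eng.D.col(movedrow); oldE = eng.E.col(movedrow);
      eng.update_row(movedrow);
      const double ll_new = eng.compute_loglik();
      if (std::isfinite(lp_new) &&
          std::log(unif_rand()) < (ll_new - eng.log_lik) + (lp_new - lp_old)) {
        eng.log_lik = ll_new;
        eng.log_prior_tot += lp_new - lp_old;
        accepted = true;
      } else {
        eng.loc(movedrow, 0) = save1; eng.loc(movedrow, 1) = save2;
        for (int j = 0; j < 2 * K; ++j) {
          eng.D(movedrow, j) = oldD(j); eng.D(j, movedrow) = oldD(j);
          eng.E(movedrow, j) = oldE(j); eng.E(j, movedrow) = oldE(j);
        }
      }
    }

    prop_tot[b]++;
    if (accepted) { acc_tot[b]++; win_acc[b]++; }
    if (++win_cnt[b] == adapt_window) {
      const double rate = (double)win_acc[b] / adapt_window;
      const double a = std::min(0.01, 1.0 / std::sqrt((double)epoch[b]));
      zeta(b) += (rate > 0.44) ? a : -a;
      if (zeta(b) > zeta_cap) zeta(b) = zeta_cap;
      if (zeta(b) < -zeta_cap) zeta(b) = -zeta_cap;
      epoch[b]++;
      win_acc[b] = 0; win_cnt[b] = 0;
    }

    if (it % thin == 0) {
      const double rad2deg = sphere ? 180.0 / M_PI : 1.0;
      samples(si, 0) = eng.a0; samples(si, 1) = eng.a1; samples(si, 2) = eng.a2;
      for (int k = 0; k < K; ++k) {
        samples(si, 3 + k) = eng.eta(k);
        samples(si, 3 + K + k) = eng.w(k);
        samples(si, 3 + 2 * K + k) = eng.loc(k, 0) * rad2deg;
        samples(si, 3 + 3 * K + k) = eng.loc(k, 1) * rad2deg;
        samples(si, 3 + 4 * K + k) = eng.loc(K + k, 0) * rad2deg;
        samples(si, 3 + 5 * K + k) = eng.loc(K + k, 1) * rad2deg;
      }
      out_ll(si) = eng.log_lik;
      out_lp(si) = eng.log_prior_tot;
      for (int bb = 0; bb < nb; ++bb) {
        zeta_hist(si, bb) = zeta(bb);
        acc_hist(si, bb) = (double)acc_tot[bb];
        prop_hist(si, bb) = (double)prop_tot[bb];
      }
      si++;
    }
    if (it % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  const double rad2deg = sphere ? 180.0 / M_PI : 1.0;
  arma::mat Gout = eng.loc.rows(0, K - 1) * rad2deg;
  arma::mat Gsout = eng.loc.rows(K, 2 * K - 1) * rad2deg;
  return List::create(
    _["samples"] = samples, _["log_lik"] = out_ll, _["log_prior"] = out_lp,
    _["zeta_hist"] = zeta_hist, _["acc_hist"] = acc_hist,
    _["prop_hist"] = prop_hist, _["zeta"] = zeta,
    _["final_state"] = List::create(
      _["a0"] = eng.a0, _["a1"] = eng.a1, _["a2"] = eng.a2,
      _["eta"] = eng.eta, _["w"] = eng.w, _["G"] = Gout, _["Gstar"] = Gsout),
    _["final_log_lik"] = eng.log_lik,
    _["final_log_prior"] = eng.log_prior_tot);
}
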