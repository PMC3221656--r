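#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs sampler for the hierarchical multinomial-Dirichlet
// model.  Individual preference rows p_j have the conjugate full conditional
// Dirichlet(x_j + w*q) and are updated by exact Gibbs draws; the population
// mean q uses a Dirichlet proposal centred at the current value (Hastings
// corrected) and the concentration w a Gaussian random walk on log(w)
// (Jacobian corrected).  All randomness comes from R's RNG stream, so
// set.seed() in R makes runs fully reproducible.

static const double GAMMA_FLOOR = 1e-300;

// log Dirichlet density at y with parameter a (both length K, y interior)
static double ldirichlet(const std::vector<double>& y,
                         const std::vector<double>& a) {
  double sa = 0.0, out = 0.0;
  const int K = y.size();
  for (int k = 0; k < K; ++k) {
    sa += a[k];
    out += (a[k] - 1.0) * std::log(y[k]) - R::lgammafn(a[k]);
  }
  return out + R::lgammafn(sa);
}

// summed log conditional prior of all J preference rows given alpha = w*q,
// using precomputed column sums of log p (clp)
static double cond_prior(const int J, const double w,
                         const std::vector<double>& q,
                         const std::vector<double>& clp) {
  const int K = q.size();
  double out = J * R::lgammafn(w);
  for (int k = 0; k < K; ++k) {
    const double a = w * q[k];
    out += (a - 1.0) * clp[k] - J * R::lgammafn(a);
  }
  return out;
}

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(IntegerMatrix x, NumericVector prior_alpha, double w_upper,
                   int n_burn, int n_steps, int thin,
                   double q_scale, double w_sd, bool constrain_q,
                   NumericVector p_init, NumericVector q_init, double w_init) {
  const int J = x.nrow(), K = x.ncol();
  const int n_store = n_steps / thin;
  if (n_store < 1) stop("no draws would be stored: thin > n_steps");

  // multinomial coefficient, constant across draws
  double lmc = 0.0;
  std::vector<double> ntot(J, 0.0);
  for (int j = 0; j < J; ++j) {
    double nj = 0.0;
    for (int k = 0; k < K; ++k) {
      nj += x(j, k);
      lmc -= R::lgammafn(x(j, k) + 1.0);
    }
    ntot[j] = nj;
    lmc += R::lgammafn(nj + 1.0);
  }

  std::vector<double> p(J * K), q(K), qprop(K), clp(K);
  for (int i = 0; i < J * K; ++i) p[i] = p_init[i];
  for (int k = 0; k < K; ++k) q[k] = q_init[k];
  double w = w_init;

  NumericMatrix q_draws(n_store, K);
  NumericVector w_draws(n_store), dev_draws(n_store);
  NumericVector p_draws(static_cast<R_xlen_t>(n_store) * J * K);
  long acc_q = 0, try_q = 0, acc_w = 0, try_w = 0;
  int stored = 0;

  const int total_steps = n_burn + n_steps;
  for (int step = 0; step < total_steps; ++step) {
    // --- Gibbs update of individual preference rows: Dirichlet(x_j + w q)
    for (int k = 0; k < K; ++k) clp[k] = 0.0;
    for (int j = 0; j < J; ++j) {
      double rs = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(x(j, k) + w * q[k], 1.0);
        if (g < GAMMA_FLOOR) g = GAMMA_FLOOR;
        p[j * K + k] = g;
        rs += g;
      }
      for (int k = 0; k < K; ++k) {
        p[j * K + k] /= rs;
        clp[k] += std::log(p[j * K + k]);
      }
    }

    // --- MH update of q with Dirichlet(q_scale * q) proposal
    if (!constrain_q) {
      ++try_q;
      double ps = 0.0;
      for (int k = 0; k < K; ++k) {
        double g = R::rgamma(q_scale * q[k], 1.0);
        if (g < GAMMA_FLOOR) g = GAMMA_FLOOR;
        qprop[k] = g;
        ps += g;
      }
      for (int k = 0; k < K; ++k) qprop[k] /= ps;

      double lr = cond_prior(J, w, qprop, clp) - cond_prior(J, w, q, clp);
      for (int k = 0; k < K; ++k) {
        lr += (prior_alpha[k] - 1.0) * (std::log(qprop[k]) - std::log(q[k]));
      }
      // Hastings: g(q | d*qprop) / g(qprop | d*q)
      std::vector<double> a_fwd(K), a_rev(K);
      for (int k = 0; k < K; ++k) {
        a_fwd[k] = q_scale * q[k];
        a_rev[k] = q_scale * qprop[k];
      }
      lr += ldirichlet(q, a_rev) - ldirichlet(qprop, a_fwd);
      if (std::log(R::unif_rand()) < lr) {
        q = qprop;
        ++acc_q;
      }
    }

    // --- MH update of w: Gaussian random walk on log w
    {
      ++try_w;
      const double wprop = w * std::exp(R::norm_rand() * w_sd);
      if (wprop < w_upper) {
        double lr = cond_prior(J, wprop, q, clp) - cond_prior(J, w, q, clp) +
                    std::log(wprop) - std::log(w);
        if (std::log(R::unif_rand()) < lr) {
          w = wprop;
          ++acc_w;
        }
      }
    }

    // --- store post-burnin draws
    if (step >= n_burn && (step - n_burn + 1) % thin == 0 && stored < n_store) {
      double llik = lmc;
      for (int j = 0; j < J; ++j) {
        for (int k = 0; k < K; ++k) {
          if (x(j, k) > 0) llik += x(j, k) * std::log(p[j * K + k]);
        }
      }
      const double dev = -2.0 * (llik + cond_prior(J, w, q, clp));
      for (int k = 0; k < K; ++k) q_draws(stored, k) = q[k];
      w_draws[stored] = w;
      dev_draws[stored] = dev;
      double* dst = REAL(p_draws) + static_cast<R_xlen_t>(stored) * J * K;
      for (int i = 0; i < J * K; ++i) dst[i] = p[i];
      ++stored;
    }

    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  p_draws.attr("dim") = IntegerVector::create(K, J, n_store);
  return List::create(
      _["q"] = q_draws, _["w"] = w_draws, _["p"] = p_draws,
      _["deviance"] = dev_draws,
      _["accept_q"] = constrain_q ? NA_REAL : double(acc_q) / double(try_q),
      _["accept_w"] = double(acc_w) / double(try_w));
}
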