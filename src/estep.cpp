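// Fused Bock-Aitkin E-step for the 2PL marginal likelihood.
//
// Given item parameters, quadrature nodes and (log) prior weights, computes
// the marginal log-likelihood, the posterior node weights per person, and the
// expected per-item correct/administered counts r-bar and n-bar that the
// M-step consumes. x0 holds responses with NA recoded to 0; m is the observed
// indicator, so persons with missing items contribute only through the items
// they answered.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// [[Rcpp::export]]
Rcpp::List estep_core(const arma::mat& x0, const arma::mat& m,
                      const arma::vec& a, const arma::vec& b,
                      const arma::vec& nodes, const arma::vec& log_w,
                      const bool want_posterior) {
  const arma::uword J = a.n_elem, Q = nodes.n_elem;
  arma::mat logp(J, Q), log1mp(J, Q);
  for (arma::uword q = 0; q < Q; ++q) {
    for (arma::uword j = 0; j < J; ++j) {
      const double z = a[j] * (nodes[q] - b[j]);
      // stable log-sigmoid: log p and log(1-p) = log p - z
      const double lp =
          z > 0 ? -std::log1p(std::exp(-z)) : z - std::log1p(std::exp(z));
      logp(j, q) = lp;
      log1mp(j, q) = lp - z;
    }
  }
  arma::mat ll = x0 * logp + (m - x0) * log1mp; // n x Q
  ll.each_row() += log_w.t();
  const arma::vec mx = arma::max(ll, 1);
  ll.each_col() -= mx;
  arma::mat w = arma::exp(ll);
  const arma::vec rs = arma::sum(w, 1);
  const double loglik = arma::accu(arma::log(rs) + mx);
  w.each_col() /= rs;
  arma::mat rbar = x0.t() * w;
  arma::mat nbar = m.t() * w;
  const arma::rowvec pw = arma::sum(w, 0);
  if (want_posterior) {
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("rbar") = rbar,
                              Rcpp::Named("nbar") = nbar,
                              Rcpp::Named("pw") = pw,
                              Rcpp::Named("posterior") = w);
  }
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("rbar") = rbar,
                            Rcpp::Named("nbar") = nbar,
                            Rcpp::Named("pw") = pw);
}

// Safeguarded per-item Newton M-step on the expected complete-data
// log-likelihood, jointly in (a_j, b_j). Steps that fail to improve the item
// objective are halved and, failing that, rejected, so the EM never decreases
// the marginal likelihood. Returns the updated parameters together with the
// final objective and gradient norm per item so the caller can run a bounded
// quasi-Newton fallback on any item left off a stationary point.

static inline double item_obj(const arma::rowvec& r, const arma::rowvec& n,
                              const arma::vec& nodes, const double aj,
                              const double bj, const bool use_prior,
                              const double prior_sd) {
  double o = 0.0;
  for (arma::uword q = 0; q < nodes.n_elem; ++q) {
    const double z = aj * (nodes[q] - bj);
    const double lp =
        z > 0 ? -std::log1p(std::exp(-z)) : z - std::log1p(std::exp(z));
    o += r[q] * lp + (n[q] - r[q]) * (lp - z);
  }
  if (use_prior) {
    const double la = std::log(aj);
    o -= la * la / (2.0 * prior_sd * prior_sd);
  }
  return o;
}

// [[Rcpp::export]]
Rcpp::List mstep_core(const arma::vec& a0, const arma::vec& b0,
                      const arma::mat& rbar, const arma::mat& nbar,
                      const arma::vec& nodes, const double a_lo,
                      const double a_hi, const double b_lo, const double b_hi,
                      const bool use_prior, const double prior_sd,
                      const int max_newton) {
  const arma::uword J = a0.n_elem, Q = nodes.n_elem;
  arma::vec a = a0, b = b0, obj(J), grad_norm(J);
  for (arma::uword j = 0; j < J; ++j) {
    const arma::rowvec r = rbar.row(j), n = nbar.row(j);
    double aj = a[j], bj = b[j];
    double oj = item_obj(r, n, nodes, aj, bj, use_prior, prior_sd);
    double ga = 0.0, gb = 0.0;
    for (int it = 0; it < max_newton; ++it) {
      ga = 0.0;
      gb = 0.0;
      double haa = 0.0, hbb = 0.0, hab = 0.0;
      for (arma::uword q = 0; q < Q; ++q) {
        const double t = nodes[q] - bj;
        const double p = 1.0 / (1.0 + std::exp(-aj * t));
        const double e = r[q] - n[q] * p;
        const double w = n[q] * p * (1.0 - p);
        ga += e * t;
        gb -= e;
        haa -= w * t * t;
        hbb -= w;
        hab += w * t;
      }
      gb *= aj;
      hbb *= aj * aj;
      hab = aj * hab + gb / aj; // a*sum(w*t) - sum(e)
      if (use_prior) {
        const double la = std::log(aj);
        ga -= la / (aj * prior_sd * prior_sd);
        haa -= (1.0 - la) / (aj * aj * prior_sd * prior_sd);
      }
      if (std::max(std::abs(ga), std::abs(gb)) < 1e-9) break;
      const double det = haa * hbb - hab * hab;
      double da, db;
      if (std::isfinite(det) && det > 0 && haa < 0) {
        da = -(hbb * ga - hab * gb) / det;
        db = -(-hab * ga + haa * gb) / det;
      } else {
        da = (ga > 0 ? 0.1 : -0.1);
        db = (gb > 0 ? 0.1 : -0.1);
      }
      double step = 1.0;
      bool accepted = false;
      for (int h = 0; h < 6; ++h) {
        const double at = std::min(std::max(aj + step * da, a_lo), a_hi);
        const double bt = std::min(std::max(bj + step * db, b_lo), b_hi);
        const double ot = item_obj(r, n, nodes, at, bt, use_prior, prior_sd);
        if (std::isfinite(ot) && ot >= oj - 1e-12) {
          if (std::max(std::abs(at - aj), std::abs(bt - bj)) < 1e-10) {
            aj = at;
            bj = bt;
            oj = ot;
            accepted = false; // converged in place
            break;
          }
          aj = at;
          bj = bt;
          oj = ot;
          accepted = true;
          break;
        }
        step *= 0.5;
      }
      if (!accepted) break;
    }
    a[j] = aj;
    b[j] = bj;
    obj[j] = oj;
    grad_norm[j] = std::max(std::abs(ga), std::abs(gb));
  }
  return Rcpp::List::create(Rcpp::Named("a") = a, Rcpp::Named("b") = b,
                            Rcpp::Named("obj") = obj,
                            Rcpp::Named("grad_norm") = grad_norm);
}
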