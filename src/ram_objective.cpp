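// RAM covariance-structure objective and analytic gradient.
//
// For one group: val = w * ( log|Sigma(theta)| + tr(Sigma^{-1} S) )
// with Sigma = F (I-A)^{-1} S0 (I-A)^{-T} F', manifests occupying the
// leading p rows of the variable ordering. Gradient uses
// dF = tr(W dSigma), W = w (Sigma^{-1} - Sigma^{-1} S Sigma^{-1}),
// mapped through the RAM structure. Returns ok = false when (I-A) is
// singular or Sigma is not positive definite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List ram_group_obj(const arma::vec& theta,
                   const arma::mat& A0, const arma::mat& S0,
                   const arma::umat& Acells, const arma::uvec& Apar,
                   const arma::umat& Scells, const arma::uvec& Spar,
                   const int p, const arma::mat& Ssamp,
                   const double w, const int npar,
                   const bool want_grad) {
  const arma::uword nv = A0.n_rows;
  arma::mat A = A0, S = S0;
  for (arma::uword k = 0; k < Acells.n_rows; ++k)
    A(Acells(k, 0), Acells(k, 1)) = theta(Apar(k));
  for (arma::uword k = 0; k < Scells.n_rows; ++k) {
    S(Scells(k, 0), Scells(k, 1)) = theta(Spar(k));
    S(Scells(k, 1), Scells(k, 0)) = theta(Spar(k));
  }
  arma::mat B;
  if (!arma::inv(B, arma::eye(nv, nv) - A))
    return List::create(Named("ok") = false);
  arma::mat V = B * S * B.t();
  arma::mat Sig = V.submat(0, 0, p - 1, p - 1);
  Sig = 0.5 * (Sig + Sig.t());
  arma::mat R;
  if (!arma::chol(R, Sig))
    return List::create(Named("ok") = false);
  const double logdet = 2.0 * arma::accu(arma::log(R.diag()));
  arma::mat Ri = arma::inv(arma::trimatu(R));
  arma::mat Sigi = Ri * Ri.t();
  const double val = w * (logdet + arma::accu(Sigi % Ssamp));
  if (!want_grad)
    return List::create(Named("ok") = true, Named("val") = val);

  arma::mat W = w * (Sigi - Sigi * Ssamp * Sigi);
  arma::mat Wf(nv, nv, arma::fill::zeros);
  Wf.submat(0, 0, p - 1, p - 1) = W;
  arma::mat WfB = Wf * B;
  arma::mat E = B.t() * WfB;   // gradient wrt S cells
  arma::mat K = V * WfB;       // gradient wrt A cells (transposed index)
  arma::vec grad(npar, arma::fill::zeros);
  for (arma::uword k = 0; k < Acells.n_rows; ++k)
    grad(Apar(k)) += 2.0 * K(Acells(k, 1), Acells(k, 0));
  for (arma::uword k = 0; k < Scells.n_rows; ++k) {
    const double g = E(Scells(k, 0), Scells(k, 1));
    grad(Spar(k)) += (Scells(k, 0) == Scells(k, 1)) ? g : 2.0 * g;
  }
  return List::create(Named("ok") = true, Named("val") = val,
                      Named("grad") = grad);
}

// Casewise FIML objective over missingness patterns (saturated means).
// theta = structural parameters, mu = manifest means. Patterns supply
// observed-column index sets, counts, means and biased covariances.
// [[Rcpp::export]]
List ram_fiml_obj(const arma::vec& theta, const arma::vec& mu,
                  const arma::mat& A0, const arma::mat& S0,
                  const arma::umat& Acells, const arma::uvec& Apar,
                  const arma::umat& Scells, const arma::uvec& Spar,
                  const int p, const List& patterns,
                  const double invN, const int npar,
                  const bool want_grad) {
  const arma::uword nv = A0.n_rows;
  arma::mat A = A0, S = S0;
  for (arma::uword k = 0; k < Acells.n_rows; ++k)
    A(Acells(k, 0), Acells(k, 1)) = theta(Apar(k));
  for (arma::uword k = 0; k < Scells.n_rows; ++k) {
    S(Scells(k, 0), Scells(k, 1)) = theta(Spar(k));
    S(Scells(k, 1), Scells(k, 0)) = theta(Spar(k));
  }
  arma::mat B;
  if (!arma::inv(B, arma::eye(nv, nv) - A))
    return List::create(Named("ok") = false);
  arma::mat V = B * S * B.t();
  arma::mat Sig = V.submat(0, 0, p - 1, p - 1);
  Sig = 0.5 * (Sig + Sig.t());

  const double LOG2PI = std::log(2.0 * M_PI);
  double val = 0.0;
  arma::mat W(p, p, arma::fill::zeros);
  arma::vec gmu(p, arma::fill::zeros);
  for (int g = 0; g < patterns.size(); ++g) {
    List pt = patterns[g];
    arma::uvec o = as<arma::uvec>(pt["o"]);       // zero-based
    const double ng = as<double>(pt["n"]);
    arma::vec xbar = as<arma::vec>(pt["xbar"]);
    arma::mat Sg = as<arma::mat>(pt["S"]);
    arma::mat So = Sig.submat(o, o);
    arma::mat R;
    if (!arma::chol(R, So))
      return List::create(Named("ok") = false);
    arma::mat Ri = arma::inv(arma::trimatu(R));
    arma::mat Soi = Ri * Ri.t();
    arma::vec d = xbar - mu.elem(o);
    arma::mat C = Sg + d * d.t();
    val += 0.5 * ng * (o.n_elem * LOG2PI +
                       2.0 * arma::accu(arma::log(R.diag())) +
                       arma::accu(Soi % C));
    if (want_grad) {
      W.submat(o, o) += 0.5 * ng * (Soi - Soi * C * Soi);
      gmu.elem(o) -= ng * (Soi * d);
    }
  }
  val *= invN;
  if (!want_grad)
    return List::create(Named("ok") = true, Named("val") = val);

  arma::mat Wf(nv, nv, arma::fill::zeros);
  Wf.submat(0, 0, p - 1, p - 1) = W;
  arma::mat WfB = Wf * B;
  arma::mat E = B.t() * WfB;
  arma::mat K = V * WfB;
  arma::vec grad(npar + p, arma::fill::zeros);
  for (arma::uword k = 0; k < Acells.n_rows; ++k)
    grad(Apar(k)) += 2.0 * K(Acells(k, 1), Acells(k, 0));
  for (arma::uword k = 0; k < Scells.n_rows; ++k) {
    const double g = E(Scells(k, 0), Scells(k, 1));
    grad(Spar(k)) += (Scells(k, 0) == Scells(k, 1)) ? g : 2.0 * g;
  }
  for (int j = 0; j < p; ++j) grad(npar + j) = gmu(j);
  grad *= invN;
  return List::create(Named("ok") = true, Named("val") = val,
                      Named("grad") = grad);
}
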