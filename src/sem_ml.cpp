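// Maximum-likelihood discrepancy for manifest-variable path models,
// RAM-style: Sigma(theta) = (I - B)^-1 Psi (I - B)^-T with diagonal Psi.
// Called once per optimiser step; the randomised-null test refits the
// model thousands of times, hence the compiled hot path.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double FML_BAD = 1e10;

// Rebuild (A, Sigma, psi) from the free-parameter vector.
// theta = [edge coefficients (bRow/bCol order), free psi (psiIdx order)];
// psiBase holds fixed variances (e.g. exogenous variances pinned to S).
static bool build_sigma(const vec& theta, const uword p,
                        const uvec& bRow, const uvec& bCol,
                        const uvec& psiIdx, const vec& psiBase,
                        mat& A, mat& Sigma, vec& psi) {
  mat B(p, p, fill::zeros);
  for (uword k = 0; k < bRow.n_elem; ++k) B(bRow[k], bCol[k]) = theta[k];
  psi = psiBase;
  for (uword k = 0; k < psiIdx.n_elem; ++k)
    psi[psiIdx[k]] = theta[bRow.n_elem + k];
  mat ImB = eye(p, p) - B;
  if (rcond(ImB) < 1e-12) return false;
  if (!inv(A, ImB)) return false;
  Sigma = A * diagmat(psi) * A.t();
  Sigma = 0.5 * (Sigma + Sigma.t());
  return true;
}

// [[Rcpp::export(name = ".semFmlCpp")]]
double semFmlCpp(const arma::vec& theta, const arma::mat& S,
                 const arma::uvec& bRow, const arma::uvec& bCol,
                 const arma::uvec& psiIdx, const arma::vec& psiBase,
                 const double logdetS) {
  const uword p = S.n_rows;
  mat A, Sigma;
  vec psi;
  if (!build_sigma(theta, p, bRow, bCol, psiIdx, psiBase, A, Sigma, psi))
    return FML_BAD;
  mat L;
  if (!chol(L, Sigma)) return FML_BAD;  // Sigma not PD: retreat
  double logdetSigma = 2.0 * sum(log(L.diag()));
  mat SigInvS;
  if (!solve(SigInvS, Sigma, S, solve_opts::no_approx)) return FML_BAD;
  double f = logdetSigma - logdetS + trace(SigInvS) - (double)p;
  if (!std::isfinite(f)) return FML_BAD;
  return f;
}

// Analytic gradient of F_ML.
// dF = tr(W dSigma), W = Sigma^-1 - Sigma^-1 S Sigma^-1;
// d/dB_ij = 2 (Sigma W A)_{ji}; d/dpsi_kk = (A' W A)_{kk}.
// [[Rcpp::export(name = ".semFmlGradCpp")]]
arma::vec semFmlGradCpp(const arma::vec& theta, const arma::mat& S,
                        const arma::uvec& bRow, const arma::uvec& bCol,
                        const arma::uvec& psiIdx, const arma::vec& psiBase) {
  const uword p = S.n_rows;
  const uword nB = bRow.n_elem;
  vec g(nB + psiIdx.n_elem, fill::zeros);
  mat A, Sigma;
  vec psi;
  if (!build_sigma(theta, p, bRow, bCol, psiIdx, psiBase, A, Sigma, psi))
    return g;  // objective already returns FML_BAD here
  mat SigInv;
  if (!inv_sympd(SigInv, Sigma)) return g;
  mat W = SigInv - SigInv * S * SigInv;
  mat T1 = Sigma * W * A;    // edge gradients
  mat G2 = A.t() * W * A;    // variance gradients
  for (uword k = 0; k < nB; ++k) g[k] = 2.0 * T1(bCol[k], bRow[k]);
  for (uword k = 0; k < psiIdx.n_elem; ++k)
    g[nB + k] = G2(psiIdx[k], psiIdx[k]);
  return g;
}

// [[Rcpp::export(name = ".semImpliedCpp")]]
arma::mat semImpliedCpp(const arma::vec& theta, const int p,
                        const arma::uvec& bRow, const arma::uvec& bCol,
                        const arma::uvec& psiIdx, const arma::vec& psiBase) {
  mat A, Sigma;
  vec psi;
  if (!build_sigma(theta, (uword)p, bRow, bCol, psiIdx, psiBase, A, Sigma, psi))
    Rcpp::stop("structural system is singular: (I - B) is not invertible");
  return Sigma;
}
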