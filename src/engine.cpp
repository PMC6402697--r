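// Inner loops of the mean-field variational EM engines.
//
// resp_stats: categorical responsibilities aggregated by mutation category
//   (exact for exchangeable tokens), returning expected per-signature token
//   counts, Dirichlet sufficient statistics and the collapsed
//   log-normalizer sum used in the ELBO.
//
// eta_obj / eta_grad: the per-sample logistic-normal variational objective
//   over (lambda, log nu^2) for all samples jointly, with the auxiliary
//   normalizer profiled out so the bound term is N_dm * logsumexp over the
//   modality block of lambda + nu^2/2. Passed to stats::optim (L-BFGS-B).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// X: D x V counts; Elogphi: K x V; Lam: D x K (lambda block, or E[log theta]
// for LDA). Returns s (D x K expected token counts), gstat (K x V) and
// xlogz = sum_dv X_dv * logsumexp_k(Lam_dk + Elogphi_kv).
// [[Rcpp::export]]
List resp_stats(const arma::mat& X, const arma::mat& Elogphi,
                const arma::mat& Lam) {
    const int D = X.n_rows, V = X.n_cols, K = Elogphi.n_rows;
    arma::mat s(D, K, arma::fill::zeros);
    arma::mat g(K, V, arma::fill::zeros);
    double xlogz = 0.0;
    arma::vec a(K), e(K);
    for (int d = 0; d < D; ++d) {
        for (int v = 0; v < V; ++v) {
            const double x = X(d, v);
            if (x <= 0.0) continue;
            for (int k = 0; k < K; ++k) a[k] = Lam(d, k) + Elogphi(k, v);
            const double m = a.max();
            double Z = 0.0;
            for (int k = 0; k < K; ++k) { e[k] = std::exp(a[k] - m); Z += e[k]; }
            xlogz += x * (m + std::log(Z));
            const double xz = x / Z;
            for (int k = 0; k < K; ++k) {
                const double r = xz * e[k];
                s(d, k) += r;
                g(k, v) += r;
            }
        }
    }
    return List::create(_["s"] = s, _["gstat"] = g, _["xlogz"] = xlogz);
}

static void unpack(const arma::vec& par, int D, int Kt,
                   arma::mat& Lam, arma::mat& L) {
    Lam = arma::reshape(par.subvec(0, D * Kt - 1), D, Kt);
    L = arma::reshape(par.subvec(D * Kt, 2 * D * Kt - 1), D, Kt);
}

// negative objective (for minimization). par = [vec(Lambda); vec(log nu2)].
// s: D x Kt expected token counts; Nmat: D x M per-modality token totals;
// SigInv: Kt x Kt; mu: Kt; bstart/bsize: 0-based block starts and sizes.
// [[Rcpp::export]]
double eta_obj(const arma::vec& par, const arma::mat& s, const arma::mat& Nmat,
               const arma::mat& SigInv, const arma::vec& mu,
               const arma::ivec& bstart, const arma::ivec& bsize) {
    const int D = s.n_rows, Kt = s.n_cols, M = bstart.n_elem;
    arma::mat Lam, L;
    unpack(par, D, Kt, Lam, L);
    arma::mat V = arma::exp(L);
    arma::mat A = Lam.each_row() - mu.t();
    double f = -0.5 * arma::accu((A * SigInv) % A);
    f -= 0.5 * arma::accu(V.each_row() % arma::diagvec(SigInv).t());
    f += arma::accu(s % Lam);
    f += 0.5 * arma::accu(L);
    for (int m = 0; m < M; ++m) {
        const int j0 = bstart[m], j1 = bstart[m] + bsize[m] - 1;
        arma::mat B = Lam.cols(j0, j1) + 0.5 * V.cols(j0, j1);
        arma::vec mx = arma::max(B, 1);
        arma::vec lse = mx + arma::log(arma::sum(
            arma::exp(B.each_col() - mx), 1));
        f -= arma::dot(Nmat.col(m), lse);
    }
    return -f;
}

// gradient of eta_obj
// [[Rcpp::export]]
arma::vec eta_grad(const arma::vec& par, const arma::mat& s,
                   const arma::mat& Nmat, const arma::mat& SigInv,
                   const arma::vec& mu, const arma::ivec& bstart,
                   const arma::ivec& bsize) {
    const int D = s.n_rows, Kt = s.n_cols, M = bstart.n_elem;
    arma::mat Lam, L;
    unpack(par, D, Kt, Lam, L);
    arma::mat V = arma::exp(L);
    arma::mat A = Lam.each_row() - mu.t();
    arma::mat W(D, Kt, arma::fill::zeros);
    for (int m = 0; m < M; ++m) {
        const int j0 = bstart[m], j1 = bstart[m] + bsize[m] - 1;
        arma::mat B = Lam.cols(j0, j1) + 0.5 * V.cols(j0, j1);
        arma::vec mx = arma::max(B, 1);
        arma::mat E = arma::exp(B.each_col() - mx);
        arma::vec Z = arma::sum(E, 1);
        E.each_col() /= Z;
        E.each_col() %= Nmat.col(m);
        W.cols(j0, j1) = E;
    }
    arma::mat dLam = -(A * SigInv) + s - W;
    arma::mat dL = V % ((-0.5) * arma::repmat(arma::diagvec(SigInv).t(), D, 1)
                        - 0.5 * W) + 0.5;
    arma::vec g(2 * D * Kt);
    g.subvec(0, D * Kt - 1) = arma::vectorise(dLam);
    g.subvec(D * Kt, 2 * D * Kt - 1) = arma::vectorise(dL);
    return -g;
}
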