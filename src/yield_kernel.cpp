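// Batch singlet-yield solver used by the orientation / rate-grid scans.
//
// For each field direction the effective Hamiltonian H_eff = H - iK is
// diagonalized and the whole problem is moved into its (non-unitary)
// eigenbasis, where the reactive Liouvillian is diagonal with eigenvalues
// -i(lam_a - conj(lam_b)). The Nakajima-Zwanzig memory integral over the
// exponential correlation function is then analytic per matrix element
// (a Lorentzian spectral density at the complex eigenvalue difference), so
// the relaxation superoperator is assembled directly in that basis and the
// s = 0 Laplace system is solved densely. Results match the pure-R
// reference path (reactive_liouvillian + nz_superoperator + singlet_yield)
// to solver precision; a test asserts this.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Assemble the NZ superoperator in the H_eff eigenbasis and add it to M.
// At: transformed channel operators Vi * A_i * V, one slice per channel.
// gmat(a,b) = 1 / (1/tauc + i(lam_a - conj(lam_b))).
static void add_nz_eigenbasis(cx_mat& M, const field<cx_mat>& At,
                              const mat& cov, const cx_mat& gmat) {
  const uword n = gmat.n_rows;
  const uword m = At.n_elem;
  for (uword j = 0; j < m; ++j) {
    for (uword k = 0; k < m; ++k) {
      const double cjk = cov(j, k);
      if (cjk == 0.0) continue;
      const cx_mat& Aj = At(j);
      const cx_mat& Ak = At(k);
      const cx_mat cAj = conj(Aj);
      const cx_mat cAk = conj(Ak);
      // T1 (block-diagonal in the slow index b):
      //   R[(b,a),(b,c)] -= cjk * [Aj diag(g(.,b)) Ak]_{a,c}
      for (uword b = 0; b < n; ++b) {
        cx_mat M1 = Aj * diagmat(gmat.col(b)) * Ak;
        M.submat(b * n, b * n, b * n + n - 1, b * n + n - 1) -= cjk * M1;
      }
      // T4 (block-diagonal in the fast index a):
      //   R[(b,a),(d,a)] -= cjk * [conj(Aj) diag(g(a,.)) conj(Ak)]_{b,d}
      for (uword a = 0; a < n; ++a) {
        cx_vec ga = gmat.row(a).st();
        cx_mat M4 = cAj * diagmat(ga) * cAk;
        for (uword b = 0; b < n; ++b)
          for (uword d = 0; d < n; ++d)
            M(a + n * b, a + n * d) -= cjk * M4(b, d);
      }
      // T2 + T3 (cross terms):
      //   R[(b,a),(d,c)] += cjk * ( Aj_{ac} g(c,b) conj(Ak)_{bd}
      //                           + conj(Aj)_{bd} g(a,d) Ak_{ac} )
      for (uword b = 0; b < n; ++b) {
        for (uword d = 0; d < n; ++d) {
          const cx_double cAk_bd = cAk(b, d);
          const cx_double cAj_bd = cAj(b, d);
          for (uword c = 0; c < n; ++c) {
            const cx_double g_cb = gmat(c, b);
            for (uword a = 0; a < n; ++a) {
              M(a + n * b, c + n * d) +=
                cjk * (Aj(a, c) * g_cb * cAk_bd +
                       cAj_bd * gmat(a, d) * Ak(a, c));
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::mat yield_batch_cpp(const arma::cx_mat& H0,
                          const arma::cx_mat& SX,
                          const arma::cx_mat& SY,
                          const arma::cx_mat& SZ,
                          const arma::mat& dirs,
                          const double omega,
                          const arma::cx_mat& PS,
                          const arma::cx_mat& PT,
                          const double kS,
                          const double kT,
                          const arma::cx_mat& rho0,
                          const Rcpp::List& channel_ops,
                          const arma::mat& cov,
                          const double tauc,
                          const bool with_nz) {
  const uword n = H0.n_rows;
  const uword nd = dirs.n_rows;
  const cx_double I(0.0, 1.0);
  const cx_mat K = 0.5 * kS * PS + 0.5 * kT * PT;

  field<cx_mat> Aops(channel_ops.size());
  for (int i = 0; i < channel_ops.size(); ++i)
    Aops(i) = Rcpp::as<cx_mat>(channel_ops[i]);

  mat out(nd, 2);
  for (uword q = 0; q < nd; ++q) {
    cx_mat H = H0 + omega * (dirs(q, 0) * SX + dirs(q, 1) * SY +
                             dirs(q, 2) * SZ);
    cx_mat Heff = H - I * K;
    cx_vec lam;
    cx_mat V;
    if (!eig_gen(lam, V, Heff))
      Rcpp::stop("eig_gen failed at orientation %d", (int)(q + 1));
    cx_mat Vi = inv(V);

    cx_mat M(n * n, n * n, fill::zeros);
    for (uword b = 0; b < n; ++b)
      for (uword a = 0; a < n; ++a)
        M(a + n * b, a + n * b) = -I * (lam(a) - std::conj(lam(b)));

    if (with_nz && Aops.n_elem > 0) {
      cx_mat gmat(n, n);
      for (uword a = 0; a < n; ++a)
        for (uword b = 0; b < n; ++b)
          gmat(a, b) = 1.0 / (1.0 / tauc + I * (lam(a) - std::conj(lam(b))));
      field<cx_mat> At(Aops.n_elem);
      for (uword i = 0; i < Aops.n_elem; ++i) At(i) = Vi * Aops(i) * V;
      add_nz_eigenbasis(M, At, cov, gmat);
    }

    cx_mat rho0p = Vi * rho0 * Vi.t();
    cx_vec x = solve(-M, vectorise(rho0p));
    cx_mat X = V * reshape(x, n, n) * V.t();
    out(q, 0) = kS * real(trace(PS * X));
    out(q, 1) = kT * real(trace(PT * X));
  }
  return out;
}
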