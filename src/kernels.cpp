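// Compiled kernels for the panel-data CTMM likelihood, score and Hessian.
//
// All heavy lifting is the matrix exponential of small dense matrices
// (S <= ~9 states).  Derivatives of Exp() are obtained from the block
// upper-triangular construction: the upper-right S x S block of
// Exp([[A, E], [0, A]]) is the Frechet derivative of Exp at A in
// direction E (scaling-and-squaring Pade under the hood via
// arma::expmat).  Second derivatives re-apply the same construction at
// the 2S level (a 4S x 4S exponential).
//
// Per observation interval only ONE block exponential is needed for the
// full score vector: by the adjoint identity
//   [L(A, E)]_{s,s'} = sum_{ab} E_{ab} K_{ab},  K = L(A^T, e_s e_{s'}^T),
// K collects the (s,s') entry of the derivative in every direction at
// once, and every model parameter perturbs A through the rank-one
// pattern e_i (e_j - e_i)^T of its transition.  The Hessian uses the
// same identity one level up: one 4S x 4S exponential per (interval,
// allowed transition) yields the second-derivative entries against all
// other parameters.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

static const double PROB_FLOOR = 1e-300;

// ---- basic building blocks -------------------------------------------------

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& A) {
  return expmat(A);
}

// Frechet derivative of Exp at A in direction E: upper-right block of
// Exp([[A, E], [0, A]]).
// [[Rcpp::export]]
arma::mat cpp_frechet_expm(const arma::mat& A, const arma::mat& E) {
  const uword S = A.n_rows;
  mat C(2 * S, 2 * S, fill::zeros);
  C.submat(0, 0, S - 1, S - 1) = A;
  C.submat(0, S, S - 1, 2 * S - 1) = E;
  C.submat(S, S, 2 * S - 1, 2 * S - 1) = A;
  mat F = expmat(C);
  return F.submat(0, S, S - 1, 2 * S - 1);
}

// expmat that reports failure (ill-conditioned / overflowing input)
// instead of throwing: optimization steps can wander into extreme
// parameter regions and the caller must be able to reject the point.
static bool safe_expmat(const mat& C, mat& out) {
  if (!C.is_finite()) return false;
  try {
    out = expmat(C);
  } catch (...) {
    return false;
  }
  return out.is_finite();
}

// Frechet derivative returning both Exp(A) and the derivative block.
static bool frechet_pair(const mat& A, const mat& E, mat& P, mat& L) {
  const uword S = A.n_rows;
  mat C(2 * S, 2 * S, fill::zeros);
  C.submat(0, 0, S - 1, S - 1) = A;
  C.submat(0, S, S - 1, 2 * S - 1) = E;
  C.submat(S, S, 2 * S - 1, 2 * S - 1) = A;
  mat F;
  if (!safe_expmat(C, F)) return false;
  P = F.submat(0, 0, S - 1, S - 1);
  L = F.submat(0, S, S - 1, 2 * S - 1);
  return true;
}

// Second directional derivative of Exp at A in directions (E1, E2) with
// curvature term E12 = d^2 A: rows 1..S, columns 3S+1..4S of
// Exp([[C1, C2], [0, C1]]), C1 = [[A, E1], [0, A]], C2 = [[E2, E12], [0, E2]].
// [[Rcpp::export]]
arma::mat cpp_second_frechet_expm(const arma::mat& A, const arma::mat& E1,
                                  const arma::mat& E2, const arma::mat& E12) {
  const uword S = A.n_rows;
  mat C(4 * S, 4 * S, fill::zeros);
  // C1 on both diagonal 2S blocks
  C.submat(0, 0, S - 1, S - 1) = A;
  C.submat(0, S, S - 1, 2 * S - 1) = E1;
  C.submat(S, S, 2 * S - 1, 2 * S - 1) = A;
  C.submat(2 * S, 2 * S, 3 * S - 1, 3 * S - 1) = A;
  C.submat(2 * S, 3 * S, 3 * S - 1, 4 * S - 1) = E1;
  C.submat(3 * S, 3 * S, 4 * S - 1, 4 * S - 1) = A;
  // C2 upper-right
  C.submat(0, 2 * S, S - 1, 3 * S - 1) = E2;
  C.submat(0, 3 * S, S - 1, 4 * S - 1) = E12;
  C.submat(S, 3 * S, 2 * S - 1, 4 * S - 1) = E2;
  mat F = expmat(C);
  return F.submat(0, 3 * S, S - 1, 4 * S - 1);
}

// ---- model plumbing --------------------------------------------------------

struct ModelSpec {
  int S;                 // number of states
  int K;                 // number of allowed transitions
  int R;                 // number of covariates
  bool indep;            // transition-independent covariate effects
  bool log_scale;        // q0 parameterized as log(q0)
  ivec from_t, to_t;     // allowed transitions (0-based)
  vec q0;                // raw baseline intensities, length K
  mat beta;              // K x R (dependent) or 1 x R (independent)
  int P;                 // number of parameters
};

static ModelSpec make_spec(int S, const IntegerMatrix& allowed,
                           const NumericVector& q0, const NumericMatrix& beta,
                           bool indep, bool log_scale) {
  ModelSpec ms;
  ms.S = S;
  ms.K = allowed.nrow();
  ms.R = beta.ncol();
  ms.indep = indep;
  ms.log_scale = log_scale;
  ms.from_t.set_size(ms.K);
  ms.to_t.set_size(ms.K);
  for (int k = 0; k < ms.K; ++k) {
    ms.from_t[k] = allowed(k, 0);
    ms.to_t[k] = allowed(k, 1);
  }
  ms.q0 = as<vec>(wrap(q0));
  ms.beta = as<mat>(wrap(beta));
  ms.P = indep ? (ms.K + ms.R) : (ms.K * (1 + ms.R));
  return ms;
}

// parameter index -> theta position (transition-major layout:
// dependent: k*(1+R) gives q0_k, then its R betas;
// independent: q0_1..q0_K then beta_1..beta_R)
static inline int idx_q0(const ModelSpec& ms, int k) {
  return ms.indep ? k : k * (1 + ms.R);
}
static inline int idx_beta(const ModelSpec& ms, int k, int r) {
  return ms.indep ? (ms.K + r) : (k * (1 + ms.R) + 1 + r);
}

// per-interval intensities: eta_k = z' beta_k, qk = q0_k exp(eta_k)
static void interval_rates(const ModelSpec& ms, const rowvec& z, vec& qk) {
  qk.set_size(ms.K);
  for (int k = 0; k < ms.K; ++k) {
    double eta = 0.0;
    if (ms.R > 0) {
      const rowvec& b = ms.indep ? ms.beta.row(0) : ms.beta.row(k);
      eta = dot(z, b);
    }
    qk[k] = ms.q0[k] * std::exp(eta);
  }
}

static void build_A(const ModelSpec& ms, const vec& qk, double tau, mat& A) {
  A.zeros(ms.S, ms.S);
  for (int k = 0; k < ms.K; ++k) {
    A(ms.from_t[k], ms.to_t[k]) += qk[k];
    A(ms.from_t[k], ms.from_t[k]) -= qk[k];
  }
  A *= tau;
}

// first-order coefficient of parameter p on transition k:
// dA/dtheta_p = coef * tau * (E_{ij} - E_{ii})
// raw scale:  q0_k -> exp(eta); beta_{k,r} -> qk z_r
// log scale:  log q0_k -> qk;   beta unchanged
// (for the independent mode beta_r acts on every transition; handled by
// looping k at the call sites)
static inline double coef_q0(const ModelSpec& ms, const vec& qk, int k) {
  return ms.log_scale ? qk[k] : qk[k] / ms.q0[k];
}
static inline double coef_beta(const vec& qk, int k, double zr) {
  return qk[k] * zr;
}

// ---- log-likelihood --------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_panel_loglik(int S, const IntegerMatrix& allowed,
                            const NumericVector& q0, const NumericMatrix& beta,
                            bool indep, bool log_scale,
                            const IntegerVector& from_s, const IntegerVector& to_s,
                            const NumericVector& tau, const NumericMatrix& Z,
                            const IntegerVector& use) {
  ModelSpec ms = make_spec(S, allowed, q0, beta, indep, log_scale);
  mat Zm = as<mat>(wrap(Z));
  vec qk;
  mat A;
  double ll = 0.0;
  int n_floor = 0;
  for (int u = 0; u < use.size(); ++u) {
    int n = use[u];
    rowvec z;
    if (ms.R > 0) z = Zm.row(n);
    interval_rates(ms, z, qk);
    build_A(ms, qk, tau[n], A);
    mat Pm;
    if (!safe_expmat(A, Pm)) {
      ll = -datum::inf;
      break;
    }
    double p = Pm(from_s[n], to_s[n]);
    if (p < PROB_FLOOR) { p = PROB_FLOOR; ++n_floor; }
    ll += std::log(p);
  }
  return List::create(_["loglik"] = ll, _["n_floored"] = n_floor);
}

// ---- score -----------------------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_panel_score(int S, const IntegerMatrix& allowed,
                           const NumericVector& q0, const NumericMatrix& beta,
                           bool indep, bool log_scale,
                           const IntegerVector& from_s, const IntegerVector& to_s,
                           const NumericVector& tau, const NumericMatrix& Z,
                           const IntegerVector& use) {
  ModelSpec ms = make_spec(S, allowed, q0, beta, indep, log_scale);
  mat Zm = as<mat>(wrap(Z));
  vec qk;
  mat A, Pt, K;
  vec g(ms.P, fill::zeros);
  double ll = 0.0;
  bool degenerate = false;
  mat U(S, S);
  for (int u = 0; u < use.size(); ++u) {
    int n = use[u];
    rowvec z;
    if (ms.R > 0) z = Zm.row(n);
    interval_rates(ms, z, qk);
    build_A(ms, qk, tau[n], A);
    // adjoint: K_{ab} = d[Exp(A)]_{s,s'} / dA_{ab}
    U.zeros();
    U(from_s[n], to_s[n]) = 1.0;
    if (!frechet_pair(A.t(), U, Pt, K)) { degenerate = true; continue; }
    double p = Pt(to_s[n], from_s[n]);  // Pt = Exp(A)^T
    if (!(p > 0.0) || p < PROB_FLOOR) { degenerate = true; continue; }
    ll += std::log(p);
    for (int k = 0; k < ms.K; ++k) {
      int i = ms.from_t[k], j = ms.to_t[k];
      double kd = tau[n] * (K(i, j) - K(i, i)) / p;
      g[idx_q0(ms, k)] += coef_q0(ms, qk, k) * kd;
      for (int r = 0; r < ms.R; ++r)
        g[idx_beta(ms, k, r)] += coef_beta(qk, k, z[r]) * kd;
    }
  }
  if (degenerate) g.fill(datum::nan);
  return List::create(_["loglik"] = ll, _["gradient"] = g,
                      _["degenerate"] = degenerate);
}

// ---- Pade (block-matrix) Hessian ------------------------------------------

// curvature coefficient c2 for a pair of parameters on the SAME transition k:
// d^2 A / dtheta dtheta' = c2 * tau * (E_{ij} - E_{ii})
// raw:  (q0,q0) -> 0, (q0,beta_r) -> z_r exp(eta), (beta_r,beta_u) -> qk z_r z_u
// log:  (phi,phi) -> qk, (phi,beta_r) -> qk z_r,   (beta_r,beta_u) -> qk z_r z_u
// [[Rcpp::export]]
Rcpp::List cpp_panel_hessian_pade(int S, const IntegerMatrix& allowed,
                                  const NumericVector& q0, const NumericMatrix& beta,
                                  bool indep, bool log_scale,
                                  const IntegerVector& from_s, const IntegerVector& to_s,
                                  const NumericVector& tau, const NumericMatrix& Z,
                                  const IntegerVector& use) {
  ModelSpec ms = make_spec(S, allowed, q0, beta, indep, log_scale);
  const int P = ms.P, K_ = ms.K, R = ms.R;
  mat Zm = as<mat>(wrap(Z));
  vec qk;
  mat A, Pt, K;
  mat H(P, P, fill::zeros);
  double ll = 0.0;
  int n_excluded = 0;
  mat U(S, S);
  mat C1t(2 * S, 2 * S), V(2 * S, 2 * S), dum, K2;
  // scratch: first-derivative entry d_p and per-transition coefficient lists
  vec dent(P);                 // (dExp)_{s,s'} per parameter
  mat coefs(K_, 1 + R);        // first-order coefficients per transition
  mat D2ent(P, P);             // (d^2 Exp)_{s,s'} per parameter pair
  for (int u = 0; u < use.size(); ++u) {
    int n = use[u];
    rowvec z;
    if (ms.R > 0) z = Zm.row(n);
    interval_rates(ms, z, qk);
    build_A(ms, qk, tau[n], A);
    U.zeros();
    U(from_s[n], to_s[n]) = 1.0;
    if (!frechet_pair(A.t(), U, Pt, K)) { ++n_excluded; continue; }
    double p = Pt(to_s[n], from_s[n]);
    if (!(p > 0.0) || p < PROB_FLOOR) { ++n_excluded; continue; }
    ll += std::log(p);
    const double p2 = p * p;
    // first-derivative entries per parameter (accumulated so that the
    // transition-independent mode's shared beta slots sum over transitions)
    dent.zeros();
    for (int k = 0; k < K_; ++k) {
      int i = ms.from_t[k], j = ms.to_t[k];
      double kd = tau[n] * (K(i, j) - K(i, i));
      coefs(k, 0) = coef_q0(ms, qk, k);
      dent[idx_q0(ms, k)] += coefs(k, 0) * kd;
      for (int r = 0; r < R; ++r) {
        coefs(k, 1 + r) = coef_beta(qk, k, z[r]);
        dent[idx_beta(ms, k, r)] += coefs(k, 1 + r) * kd;
      }
    }
    // bilinear second-derivative entries: for each transition k1, one
    // 4S x 4S exponential gives B(D_{k1}, D_{k2}) entries for all k2.
    // B2(k1,k2) = (d^2 Exp)_{s,s'} for unit directions tau*(E_ij - E_ii).
    mat B2(K_, K_);
    for (int k1 = 0; k1 < K_; ++k1) {
      int i1 = ms.from_t[k1], j1 = ms.to_t[k1];
      // C1 = [[A, D1],[0, A]], D1 = tau*(E_{i1 j1} - E_{i1 i1})
      C1t.zeros();
      C1t.submat(0, 0, S - 1, S - 1) = A.t();
      C1t.submat(S, S, 2 * S - 1, 2 * S - 1) = A.t();
      mat D1(S, S, fill::zeros);
      D1(i1, j1) = tau[n];
      D1(i1, i1) = -tau[n];
      C1t.submat(S, 0, 2 * S - 1, S - 1) = D1.t();
      V.zeros();
      V(from_s[n], S + to_s[n]) = 1.0;
      if (!frechet_pair(C1t, V, dum, K2)) { K2.zeros(2 * S, 2 * S); }
      for (int k2 = 0; k2 < K_; ++k2) {
        int i2 = ms.from_t[k2], j2 = ms.to_t[k2];
        double a = K2(i2, j2) - K2(i2, i2);
        double b = K2(S + i2, S + j2) - K2(S + i2, S + i2);
        B2(k1, k2) = tau[n] * (a + b);
      }
    }
    // (d^2 Exp)_{s,s'} accumulated per parameter pair over all ordered
    // transition pairs, then the quotient rule is applied ONCE per pair
    // (shared slots in the transition-independent mode sum naturally)
    D2ent.zeros();
    for (int k1 = 0; k1 < K_; ++k1) {
      double kd1 = tau[n] * (K(ms.from_t[k1], ms.to_t[k1]) -
                             K(ms.from_t[k1], ms.from_t[k1]));
      for (int k2 = 0; k2 < K_; ++k2) {
        for (int a = 0; a < 1 + R; ++a) {
          int pa = (a == 0) ? idx_q0(ms, k1) : idx_beta(ms, k1, a - 1);
          for (int b = 0; b < 1 + R; ++b) {
            int pb = (b == 0) ? idx_q0(ms, k2) : idx_beta(ms, k2, b - 1);
            double d2 = coefs(k1, a) * coefs(k2, b) * B2(k1, k2);
            if (k1 == k2) {
              // curvature term (same transition only)
              double c2;
              if (a == 0 && b == 0)
                c2 = ms.log_scale ? qk[k1] : 0.0;
              else if (a == 0 || b == 0) {
                double zr = (a == 0) ? z[b - 1] : z[a - 1];
                c2 = (ms.log_scale ? qk[k1] : qk[k1] / ms.q0[k1]) * zr;
              } else
                c2 = qk[k1] * z[a - 1] * z[b - 1];
              d2 += c2 * kd1;
            }
            D2ent(pa, pb) += d2;
          }
        }
      }
    }
    H += D2ent / p;
    H -= (dent * dent.t()) / p2;
  }
  H = 0.5 * (H + H.t());
  return List::create(_["H"] = H, _["loglik"] = ll,
                      _["n_excluded"] = n_excluded);
}

// ---- power-series Hessian --------------------------------------------------

// Truncated transition kernel G = I + A + A^2/2 in place of Exp(A);
// the Hessian of sum log G_{s,s'} is assembled from exact derivatives of
// the truncated form.
// [[Rcpp::export]]
Rcpp::List cpp_panel_hessian_power(int S, const IntegerMatrix& allowed,
                                   const NumericVector& q0, const NumericMatrix& beta,
                                   bool indep, bool log_scale,
                                   const IntegerVector& from_s, const IntegerVector& to_s,
                                   const NumericVector& tau, const NumericMatrix& Z,
                                   const IntegerVector& use) {
  ModelSpec ms = make_spec(S, allowed, q0, beta, indep, log_scale);
  const int P = ms.P, K_ = ms.K, R = ms.R;
  mat Zm = as<mat>(wrap(Z));
  vec qk;
  mat A;
  mat H(P, P, fill::zeros);
  double ll = 0.0;
  int n_excluded = 0;
  vec dent(P);
  mat coefs(K_, 1 + R);
  mat D2ent(P, P);
  for (int u = 0; u < use.size(); ++u) {
    int n = use[u];
    int s = from_s[n], sp = to_s[n];
    rowvec z;
    if (ms.R > 0) z = Zm.row(n);
    interval_rates(ms, z, qk);
    build_A(ms, qk, tau[n], A);
    mat G = 0.5 * (A * A);
    G += A;
    G.diag() += 1.0;
    double g = G(s, sp);
    if (!(g > 0.0)) { ++n_excluded; continue; }
    ll += std::log(g);
    const double g2 = g * g;
    // entry of dG in unit direction D_k = E_{ij} - E_{ii} (times tau):
    // [D + (DA + AD)/2]_{s,sp}
    vec kd(K_);
    for (int k = 0; k < K_; ++k) {
      int i = ms.from_t[k], j = ms.to_t[k];
      double d = 0.0;
      if (s == i) d += (sp == j) - (sp == i);
      if (s == i) d += 0.5 * (A(j, sp) - A(i, sp));
      d += 0.5 * A(s, i) * ((sp == j) - (sp == i));
      kd[k] = tau[n] * d;
      coefs(k, 0) = coef_q0(ms, qk, k);
      for (int r = 0; r < R; ++r) coefs(k, 1 + r) = coef_beta(qk, k, z[r]);
    }
    dent.zeros();
    for (int k = 0; k < K_; ++k) {
      dent[idx_q0(ms, k)] += coefs(k, 0) * kd[k];
      for (int r = 0; r < R; ++r)
        dent[idx_beta(ms, k, r)] += coefs(k, 1 + r) * kd[k];
    }
    // bilinear entries: [ (D1 D2 + D2 D1)/2 ]_{s,sp} * tau^2
    mat B2(K_, K_);
    for (int k1 = 0; k1 < K_; ++k1) {
      int i1 = ms.from_t[k1], j1 = ms.to_t[k1];
      for (int k2 = k1; k2 < K_; ++k2) {
        int i2 = ms.from_t[k2], j2 = ms.to_t[k2];
        // (D1 D2)_{s,sp} = [d_{j1 i2} - d_{i1 i2}] * d(s==i1) * (d(sp==j2)-d(sp==i2))
        double d12 = 0.0, d21 = 0.0;
        if (s == i1)
          d12 = (double)((j1 == i2) - (i1 == i2)) * ((sp == j2) - (sp == i2));
        if (s == i2)
          d21 = (double)((j2 == i1) - (i2 == i1)) * ((sp == j1) - (sp == i1));
        B2(k1, k2) = B2(k2, k1) = 0.5 * tau[n] * tau[n] * (d12 + d21);
      }
    }
    D2ent.zeros();
    for (int k1 = 0; k1 < K_; ++k1) {
      for (int k2 = 0; k2 < K_; ++k2) {
        for (int a = 0; a < 1 + R; ++a) {
          int pa = (a == 0) ? idx_q0(ms, k1) : idx_beta(ms, k1, a - 1);
          for (int b = 0; b < 1 + R; ++b) {
            int pb = (b == 0) ? idx_q0(ms, k2) : idx_beta(ms, k2, b - 1);
            double d2 = coefs(k1, a) * coefs(k2, b) * B2(k1, k2);
            if (k1 == k2) {
              double c2;
              if (a == 0 && b == 0)
                c2 = ms.log_scale ? qk[k1] : 0.0;
              else if (a == 0 || b == 0) {
                double zr = (a == 0) ? z[b - 1] : z[a - 1];
                c2 = (ms.log_scale ? qk[k1] : qk[k1] / ms.q0[k1]) * zr;
              } else
                c2 = qk[k1] * z[a - 1] * z[b - 1];
              d2 += c2 * kd[k1];
            }
            D2ent(pa, pb) += d2;
          }
        }
      }
    }
    H += D2ent / g;
    H -= (dent * dent.t()) / g2;
  }
  H = 0.5 * (H + H.t());
  return List::create(_["H"] = H, _["loglik"] = ll,
                      _["n_excluded"] = n_excluded);
}
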