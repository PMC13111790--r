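// Observed-data log-likelihood of the latent-factor MCACE model, with an
// analytic gradient.
//
// The marginal model within a (stratum, arm) is multivariate normal with
//   mu_m,a  = lambda_m0 (x) 1 + G X_a beta_m,          G = Lambda (x) I_{J+1}
//   Sigma_m = G (Z Sigma_v Z' + eps_var I) G'
//           + diag(xi_m) (x) 11' + diag(tau2_m) (x) I
// and the observed-data likelihood multiplies, over subjects, the complier
// component (treated compliers), the never-taker component (treated
// never-takers) and the complier/never-taker mixture (controls), each
// restricted to the subject's observed entries (MAR marginalization).
//
// Gradients use the Gaussian adjoint identities
//   d l = u' d mu + <(u u' - S^-1)/2, d Sigma_oo>,  u = S^-1 (y - mu)_o,
// accumulated per stratum into a full-matrix adjoint Q_m and mean adjoints,
// then chained into the structured parameters. In the control-arm mixture the
// component adjoints are weighted by the posterior compliance probabilities.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double LOG2PI = 1.837877066409345483560659472811;

struct Layout {
  int K, J1, Q, KJ, QJ, r, pw, nload, p;
  arma::ivec sizes;    // 11 blocks
  arma::ivec offsets;  // 0-based
  arma::uvec loadk, loadq;  // 0-based positions of free loadings
  arma::ivec rq;       // per-factor random dims
};

struct Pars {
  arma::vec lam0c, lam0n, betac, betan, xic, xin, t2c, t2n, eta;
  arma::mat Lambda;               // K x Q
  arma::mat Sv;                   // r x r
  std::vector<arma::mat> Lq;      // per-factor lower-chol (transformed scale)
};

static Layout read_layout(const List& ctx) {
  Layout L;
  L.K = as<int>(ctx["K"]); L.J1 = as<int>(ctx["J1"]); L.Q = as<int>(ctx["Q"]);
  L.KJ = L.K * L.J1; L.QJ = L.Q * L.J1;
  L.pw = as<int>(ctx["pw"]);
  L.sizes = as<arma::ivec>(ctx["sizes"]);
  L.offsets = as<arma::ivec>(ctx["offsets"]);
  L.loadk = as<arma::uvec>(ctx["loadk"]);
  L.loadq = as<arma::uvec>(ctx["loadq"]);
  L.nload = L.loadk.n_elem;
  L.rq = as<arma::ivec>(ctx["rq"]);
  L.r = arma::sum(L.rq);
  L.p = arma::sum(L.sizes);
  return L;
}

// Blocks: 0 l0c, 1 l0n, 2 load, 3 betac, 4 betan, 5 xic, 6 xin, 7 t2c,
//         8 t2n, 9 sigv, 10 eta
static arma::vec block(const arma::vec& th, const Layout& L, int b) {
  if (L.sizes(b) == 0) return arma::vec();
  return th.subvec(L.offsets(b), L.offsets(b) + L.sizes(b) - 1);
}

static Pars unpack(const arma::vec& th, const Layout& L, const List& ctx,
                   bool transformed) {
  Pars P;
  P.lam0c = block(th, L, 0); P.lam0n = block(th, L, 1);
  arma::vec load = block(th, L, 2);
  P.betac = block(th, L, 3); P.betan = block(th, L, 4);
  P.xic = block(th, L, 5); P.xin = block(th, L, 6);
  P.t2c = block(th, L, 7); P.t2n = block(th, L, 8);
  arma::vec sv = block(th, L, 9);
  P.eta = block(th, L, 10);
  if (transformed) {
    P.xic = arma::exp(P.xic); P.xin = arma::exp(P.xin);
    P.t2c = arma::exp(P.t2c); P.t2n = arma::exp(P.t2n);
  }
  P.Lambda = as<arma::mat>(ctx["Lfixed"]);
  for (int l = 0; l < L.nload; ++l) P.Lambda(L.loadk(l), L.loadq(l)) = load(l);
  P.Sv.zeros(L.r, L.r);
  P.Lq.resize(L.Q);
  int pos = 0, off = 0;
  for (int q = 0; q < L.Q; ++q) {
    int rq = L.rq(q);
    if (rq == 0) { P.Lq[q] = arma::mat(); continue; }
    arma::mat M(rq, rq, arma::fill::zeros);
    for (int j = 0; j < rq; ++j)          // column-major lower triangle
      for (int i = j; i < rq; ++i)
        M(i, j) = sv(pos++);
    if (transformed) {
      for (int j = 0; j < rq; ++j) M(j, j) = std::exp(M(j, j));
      P.Lq[q] = M;
      P.Sv.submat(off, off, off + rq - 1, off + rq - 1) = M * M.t();
    } else {
      arma::mat S = arma::symmatl(M);
      P.Lq[q] = arma::mat();
      P.Sv.submat(off, off, off + rq - 1, off + rq - 1) = S;
    }
    off += rq;
  }
  return P;
}

static double softplus(double x) {
  if (x > 30) return x;
  if (x < -30) return std::exp(x);
  return std::log1p(std::exp(x));
}

// Sigma_m = Shared + diag(xi) (x) 11' + diag(tau2) (x) I
static arma::mat sigma_m(const arma::mat& Shared, const arma::vec& xi,
                         const arma::vec& tau2, int K, int J1) {
  arma::mat S = Shared;
  for (int k = 0; k < K; ++k) {
    S.submat(k * J1, k * J1, (k + 1) * J1 - 1, (k + 1) * J1 - 1) += xi(k);
    for (int j = 0; j < J1; ++j) S(k * J1 + j, k * J1 + j) += tau2(k);
  }
  return S;
}

struct CompCache {
  arma::mat L, Sinv;   // lower chol and inverse of the observed sub-cov
  double logdet;
  bool ok;
};

static CompCache prep_comp(const arma::mat& Sig, const arma::uvec& o) {
  CompCache c;
  c.ok = false;
  arma::mat S = Sig.submat(o, o);
  S = 0.5 * (S + S.t());
  if (!S.is_finite()) return c;
  c.ok = arma::chol(c.L, S, "lower");
  if (!c.ok) {
    S.diag() += 1e-10 * arma::mean(S.diag());
    c.ok = arma::chol(c.L, S, "lower");
    if (!c.ok) return c;
  }
  if (arma::min(c.L.diag()) < 1e-150) { c.ok = false; return c; }
  c.logdet = 2.0 * arma::sum(arma::log(c.L.diag()));
  arma::mat Li;
  if (!arma::inv(Li, arma::trimatl(c.L))) { c.ok = false; return c; }
  c.Sinv = Li.t() * Li;
  return c;
}

// per-subject log densities and S^-1 residuals for one component
static void comp_dens(const CompCache& c, const arma::mat& Y,
                      const arma::vec& mu, const arma::uvec& o,
                      arma::vec& ll, arma::mat& U) {
  int d = o.n_elem;
  arma::mat R = Y;
  R.each_col() -= mu.elem(o);
  arma::mat Wm = arma::solve(arma::trimatl(c.L), R);
  arma::rowvec quad = arma::sum(Wm % Wm, 0);
  ll = (-0.5 * d * LOG2PI - 0.5 * c.logdet) - 0.5 * quad.t();
  U = arma::solve(arma::trimatu(c.L.t()), Wm);
}

// [[Rcpp::export]]
List cpp_mcace_eval(const arma::vec& theta, const List& ctx, bool transformed,
                    bool want_grad) {
  Layout L = read_layout(ctx);
  Pars P = unpack(theta, L, ctx, transformed);
  arma::mat Xc1 = as<arma::mat>(ctx["Xc1"]);
  arma::mat Xc0 = as<arma::mat>(ctx["Xc0"]);
  arma::mat Xn  = as<arma::mat>(ctx["Xn"]);
  arma::mat Z   = as<arma::mat>(ctx["Z"]);
  double eps_var = as<double>(ctx["eps_var"]);
  List buckets = ctx["buckets"];

  // G = Lambda (x) I
  arma::mat G(L.KJ, L.QJ, arma::fill::zeros);
  for (int k = 0; k < L.K; ++k)
    for (int q = 0; q < L.Q; ++q)
      for (int j = 0; j < L.J1; ++j)
        G(k * L.J1 + j, q * L.J1 + j) = P.Lambda(k, q);

  arma::mat C(L.QJ, L.QJ, arma::fill::zeros);
  if (L.r > 0) C = Z * P.Sv * Z.t();
  C.diag() += eps_var;
  arma::mat GC = G * C;            // KJ x QJ
  arma::mat Shared = GC * G.t();
  arma::mat Sig_c = sigma_m(Shared, P.xic, P.t2c, L.K, L.J1);
  arma::mat Sig_n = sigma_m(Shared, P.xin, P.t2n, L.K, L.J1);

  arma::vec rep1(L.J1, arma::fill::ones);
  arma::vec vc1 = (Xc1.n_cols > 0) ? arma::vec(Xc1 * P.betac) : arma::vec(L.QJ, arma::fill::zeros);
  arma::vec vc0 = (Xc0.n_cols > 0) ? arma::vec(Xc0 * P.betac) : arma::vec(L.QJ, arma::fill::zeros);
  arma::vec vn  = (Xn.n_cols  > 0) ? arma::vec(Xn  * P.betan) : arma::vec(L.QJ, arma::fill::zeros);
  arma::vec mu_c1 = arma::kron(P.lam0c, rep1) + G * vc1;
  arma::vec mu_c0 = arma::kron(P.lam0c, rep1) + G * vc0;
  arma::vec mu_n  = arma::kron(P.lam0n, rep1) + G * vn;

  double total = 0.0;
  bool failed = false;

  arma::mat Qacc_c, Qacc_n;
  arma::vec u_c1, u_c0, u_n, geta;
  if (want_grad) {
    Qacc_c.zeros(L.KJ, L.KJ); Qacc_n.zeros(L.KJ, L.KJ);
    u_c1.zeros(L.KJ); u_c0.zeros(L.KJ); u_n.zeros(L.KJ);
    geta.zeros(L.pw);
  }

  int nb = buckets.size();
  try {
  for (int b = 0; b < nb && !failed; ++b) {
    List bk = buckets[b];
    int type = as<int>(bk["type"]);  // 0 = S11, 1 = S10, 2 = S00
    arma::uvec o = as<arma::uvec>(bk["obs"]);
    arma::mat Y = as<arma::mat>(bk["Y"]);   // d x n
    arma::mat Wc = as<arma::mat>(bk["W"]);  // n x pw
    int n = Y.n_cols;
    arma::vec lp = Wc * P.eta;
    arma::vec logp(n), log1mp(n);
    for (int i = 0; i < n; ++i) {
      logp(i) = -softplus(-lp(i));
      log1mp(i) = -softplus(lp(i));
    }
    arma::vec pvec = arma::exp(logp);

    if (type == 0 || type == 1) {
      const arma::mat& Sig = (type == 0) ? Sig_c : Sig_n;
      const arma::vec& mu  = (type == 0) ? mu_c1 : mu_n;
      CompCache cc = prep_comp(Sig, o);
      if (!cc.ok) { failed = true; break; }
      arma::vec ll; arma::mat U;
      comp_dens(cc, Y, mu, o, ll, U);
      total += arma::sum(ll) + ((type == 0) ? arma::sum(logp) : arma::sum(log1mp));
      if (want_grad) {
        arma::vec usum = arma::sum(U, 1);
        arma::mat M = 0.5 * (U * U.t() - double(n) * cc.Sinv);
        if (type == 0) {
          u_c1.elem(o) += usum;
          Qacc_c.submat(o, o) += M;
          geta += Wc.t() * (1.0 - pvec);
        } else {
          u_n.elem(o) += usum;
          Qacc_n.submat(o, o) += M;
          geta += Wc.t() * (-pvec);
        }
      }
    } else {
      CompCache cc = prep_comp(Sig_c, o);
      CompCache cn = prep_comp(Sig_n, o);
      if (!cc.ok || !cn.ok) { failed = true; break; }
      arma::vec llc, lln; arma::mat Uc, Un;
      comp_dens(cc, Y, mu_c0, o, llc, Uc);
      comp_dens(cn, Y, mu_n, o, lln, Un);
      arma::vec a = logp + llc, bb = log1mp + lln;
      arma::vec mx = arma::max(a, bb);
      arma::vec ll = mx + arma::log(arma::exp(a - mx) + arma::exp(bb - mx));
      total += arma::sum(ll);
      if (want_grad) {
        arma::vec wc = arma::exp(a - ll);
        arma::vec wn = 1.0 - wc;
        u_c0.elem(o) += Uc * wc;
        u_n.elem(o) += Un * wn;
        arma::mat Ucw = Uc; Ucw.each_row() %= wc.t();
        arma::mat Unw = Un; Unw.each_row() %= wn.t();
        Qacc_c.submat(o, o) += 0.5 * (Ucw * Uc.t() - arma::sum(wc) * cc.Sinv);
        Qacc_n.submat(o, o) += 0.5 * (Unw * Un.t() - arma::sum(wn) * cn.Sinv);
        geta += Wc.t() * (wc - pvec);
      }
    }
  }
  } catch (const std::exception& e) {
    failed = true;
  }

  if (failed) {
    return List::create(_["loglik"] = -1e15,
                        _["grad"] = NumericVector(L.p),
                        _["ok"] = false);
  }
  if (!want_grad) {
    return List::create(_["loglik"] = total, _["ok"] = true);
  }

  arma::vec g(L.p, arma::fill::zeros);
  // measurement intercepts
  arma::vec uc = u_c1 + u_c0;
  for (int k = 0; k < L.K; ++k) {
    double sc = 0, sn = 0;
    for (int j = 0; j < L.J1; ++j) {
      sc += uc(k * L.J1 + j);
      sn += u_n(k * L.J1 + j);
    }
    g(L.offsets(0) + k) = sc;
    g(L.offsets(1) + k) = sn;
  }
  // fixed effects
  if (L.sizes(3) > 0) {
    arma::vec gb = Xc1.t() * (G.t() * u_c1) + Xc0.t() * (G.t() * u_c0);
    g.subvec(L.offsets(3), L.offsets(3) + L.sizes(3) - 1) = gb;
  }
  if (L.sizes(4) > 0) {
    arma::vec gb = Xn.t() * (G.t() * u_n);
    g.subvec(L.offsets(4), L.offsets(4) + L.sizes(4) - 1) = gb;
  }
  // loadings: mean part + covariance part
  if (L.nload > 0) {
    arma::mat Rc = Qacc_c * GC;   // KJ x QJ
    arma::mat Rn = Qacc_n * GC;
    for (int l = 0; l < L.nload; ++l) {
      int k = L.loadk(l), q = L.loadq(l);
      double val = 0;
      for (int j = 0; j < L.J1; ++j) {
        int rk = k * L.J1 + j, rqj = q * L.J1 + j;
        val += u_c1(rk) * vc1(rqj) + u_c0(rk) * vc0(rqj) + u_n(rk) * vn(rqj);
        val += 2.0 * (Rc(rk, rqj) + Rn(rk, rqj));
      }
      g(L.offsets(2) + l) = val;
    }
  }
  // xi (block sums) and tau2 (block traces)
  for (int k = 0; k < L.K; ++k) {
    double xc = arma::accu(Qacc_c.submat(k * L.J1, k * L.J1, (k + 1) * L.J1 - 1, (k + 1) * L.J1 - 1));
    double xn = arma::accu(Qacc_n.submat(k * L.J1, k * L.J1, (k + 1) * L.J1 - 1, (k + 1) * L.J1 - 1));
    double tc = 0, tn = 0;
    for (int j = 0; j < L.J1; ++j) {
      tc += Qacc_c(k * L.J1 + j, k * L.J1 + j);
      tn += Qacc_n(k * L.J1 + j, k * L.J1 + j);
    }
    g(L.offsets(5) + k) = xc;
    g(L.offsets(6) + k) = xn;
    g(L.offsets(7) + k) = tc;
    g(L.offsets(8) + k) = tn;
  }
  // Sigma_v
  if (L.r > 0 && L.sizes(9) > 0) {
    arma::mat GtQG = G.t() * (Qacc_c + Qacc_n) * G;   // QJ x QJ
    arma::mat Sacc = Z.t() * GtQG * Z;                // r x r, symmetric
    int pos = L.offsets(9), off = 0;
    for (int q = 0; q < L.Q; ++q) {
      int rq = L.rq(q);
      if (rq == 0) continue;
      arma::mat Sb = Sacc.submat(off, off, off + rq - 1, off + rq - 1);
      if (transformed) {
        arma::mat gradL = 2.0 * Sb * P.Lq[q];
        for (int j = 0; j < rq; ++j)
          for (int i = j; i < rq; ++i)
            g(pos++) = (i == j) ? gradL(j, j) * P.Lq[q](j, j) : gradL(i, j);
      } else {
        for (int j = 0; j < rq; ++j)
          for (int i = j; i < rq; ++i)
            g(pos++) = (i == j) ? Sb(i, i) : 2.0 * Sb(i, j);
      }
      off += rq;
    }
  }
  // eta
  if (L.pw > 0) g.subvec(L.offsets(10), L.offsets(10) + L.pw - 1) = geta;

  // chain rule for log-variance coordinates
  if (transformed) {
    for (int k = 0; k < L.K; ++k) {
      g(L.offsets(5) + k) *= P.xic(k);
      g(L.offsets(6) + k) *= P.xin(k);
      g(L.offsets(7) + k) *= P.t2c(k);
      g(L.offsets(8) + k) *= P.t2n(k);
    }
  }
  return List::create(_["loglik"] = total, _["grad"] = g, _["ok"] = true);
}

// [[Rcpp::export]]
double cpp_mcace_loglik(const arma::vec& theta, const List& ctx, bool transformed) {
  List out = cpp_mcace_eval(theta, ctx, transformed, false);
  return as<double>(out["loglik"]);
}

// [[Rcpp::export]]
arma::vec cpp_mcace_grad(const arma::vec& theta, const List& ctx, bool transformed) {
  List out = cpp_mcace_eval(theta, ctx, transformed, true);
  return as<arma::vec>(out["grad"]);
}

// Central-difference gradient of the log-likelihood (verification fallback).
// [[Rcpp::export]]
arma::vec cpp_mcace_grad_fd(const arma::vec& theta, const List& ctx,
                            bool transformed, double rel_step = 1e-6) {
  int p = theta.n_elem;
  arma::vec g(p);
  for (int i = 0; i < p; ++i) {
    double h = rel_step * std::max(1.0, std::abs(theta(i)));
    arma::vec tp = theta, tm = theta;
    tp(i) += h; tm(i) -= h;
    g(i) = (cpp_mcace_loglik(tp, ctx, transformed) -
            cpp_mcace_loglik(tm, ctx, transformed)) / (2 * h);
  }
  return g;
}

// Central-difference Hessian of the log-likelihood from the analytic gradient.
// [[Rcpp::export]]
arma::mat cpp_mcace_hessian(const arma::vec& theta, const List& ctx,
                            bool transformed, double rel_step = 1e-5) {
  int p = theta.n_elem;
  arma::mat H(p, p);
  for (int i = 0; i < p; ++i) {
    double h = rel_step * std::max(1.0, std::abs(theta(i)));
    arma::vec tp = theta, tm = theta;
    tp(i) += h; tm(i) -= h;
    H.col(i) = (cpp_mcace_grad(tp, ctx, transformed) -
                cpp_mcace_grad(tm, ctx, transformed)) / (2 * h);
  }
  return 0.5 * (H + H.t());
}
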