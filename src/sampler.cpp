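// Hot loops of the joint sampler: the inner Gibbs/Metropolis iterations for
// the shared-parameter block (random effects, fixed coefficients, variance
// components, survival parameters) and the birth/death Metropolis-Hastings
// sweep over one decision tree with its leaf coefficients integrated out.
// All randomness uses R's RNG, so set.seed() on the R side makes runs
// reproducible.

#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Bartlett decomposition draw from Wishart(df, S).
static arma::mat wishart_draw(double df, const arma::mat& S) {
  const int p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (int i = 1; i < p; ++i)
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  arma::mat LA = L * A;
  return LA * LA.t();
}

// Total survival log-likelihood plus N(0, tau0sq) prior on psi.
// psi = (lambda0, lambda_1..lambda_K, eta1, eta2).
static double surv_logpost(const arma::vec& psi, const arma::mat& b,
                           const arma::vec& event, const arma::mat& Delta,
                           const arma::ivec& tidx, const arma::vec& trt,
                           double tau0sq) {
  const int K = Delta.n_cols;
  const double lam0 = psi(0);
  const arma::vec lambda = psi.subvec(1, K);
  const double eta1 = psi(K + 1), eta2 = psi(K + 2);
  arma::vec Lam0 = Delta * arma::exp(lambda);
  arma::vec lin = lam0 * trt + eta1 * b.col(0) + eta2 * b.col(2);
  double ll = 0.0;
  for (arma::uword i = 0; i < event.n_elem; ++i) {
    if (event(i) > 0.5) ll += lin(i) + lambda(tidx(i));
    ll -= std::exp(lin(i)) * Lam0(i);
  }
  ll -= 0.5 * arma::dot(psi, psi) / tau0sq;
  return ll;
}

// One batch of B inner Gibbs iterations for the shared-parameter block,
// conditional on the three trees (encoded in the fixed design F).
// [[Rcpp::export]]
List cpp_sp_inner(const arma::vec& y, const arma::ivec& subj,
                  const arma::vec& Avec, const arma::vec& Cvec,
                  const arma::mat& F, const arma::ivec& starts,
                  const arma::vec& event, const arma::mat& Delta,
                  const arma::ivec& tidx, const arma::vec& trt,
                  List state, double tau0sq, double a0, double b0,
                  double wish_df, int B, int keep, bool adapt) {
  const int n = starts.n_elem - 1;
  const int N = y.n_elem;
  const int q = F.n_cols;
  const int K = Delta.n_cols;

  arma::vec theta = as<arma::vec>(state["theta"]);
  arma::mat b = as<arma::mat>(state["b"]);
  double sigma2 = as<double>(state["sigma2"]);
  arma::mat Sigma = as<arma::mat>(state["Sigma"]);
  arma::vec psi = as<arma::vec>(state["psi"]);
  arma::vec rw_scale = as<arma::vec>(state["rw_scale"]);

  arma::mat Siginv = arma::inv_sympd(Sigma);
  arma::mat FtF = F.t() * F;

  // per-subject Z'Z with Z = (1, A, C)
  arma::mat ZtZ(n, 6);
  for (int i = 0; i < n; ++i) {
    double z22 = 0, z23 = 0, z33 = 0, z12 = 0, z13 = 0;
    for (int r = starts(i); r < starts(i + 1); ++r) {
      z12 += Avec(r); z13 += Cvec(r);
      z22 += Avec(r) * Avec(r); z23 += Avec(r) * Cvec(r);
      z33 += Cvec(r) * Cvec(r);
    }
    ZtZ(i, 0) = starts(i + 1) - starts(i);
    ZtZ(i, 1) = z12; ZtZ(i, 2) = z13;
    ZtZ(i, 3) = z22; ZtZ(i, 4) = z23; ZtZ(i, 5) = z33;
  }

  int re_acc = 0, re_tot = 0;
  arma::vec psi_acc(K + 3, arma::fill::zeros);
  arma::mat keep_theta(q, std::max(keep, 0));
  arma::vec keep_sigma2(std::max(keep, 0));
  arma::mat keep_psi(K + 3, std::max(keep, 0));

  for (int it = 0; it < B; ++it) {
    // ---- random effects: conjugate proposal + survival MH correction ----
    arma::vec e = y - F * theta;
    arma::mat Zte(n, 3, arma::fill::zeros);
    for (int r = 0; r < N; ++r) {
      int i = subj(r);
      Zte(i, 0) += e(r);
      Zte(i, 1) += Avec(r) * e(r);
      Zte(i, 2) += Cvec(r) * e(r);
    }
    const double lam0 = psi(0);
    const double eta1 = psi(K + 1), eta2 = psi(K + 2);
    arma::vec Lam0 = Delta * arma::exp(psi.subvec(1, K));
    const bool informative = (eta1 != 0.0 || eta2 != 0.0);
    for (int i = 0; i < n; ++i) {
      // posterior precision M = (Z'Z + Sigma^-1)/sigma2; hand-coded 3x3
      // Cholesky keeps this inner loop cheap
      const double m11 = (ZtZ(i, 0) + Siginv(0, 0)) / sigma2;
      const double m21 = (ZtZ(i, 1) + Siginv(1, 0)) / sigma2;
      const double m31 = (ZtZ(i, 2) + Siginv(2, 0)) / sigma2;
      const double m22 = (ZtZ(i, 3) + Siginv(1, 1)) / sigma2;
      const double m32 = (ZtZ(i, 4) + Siginv(2, 1)) / sigma2;
      const double m33 = (ZtZ(i, 5) + Siginv(2, 2)) / sigma2;
      const double l11 = std::sqrt(m11);
      const double l21 = m21 / l11;
      const double l31 = m31 / l11;
      const double l22 = std::sqrt(m22 - l21 * l21);
      const double l32 = (m32 - l31 * l21) / l22;
      const double l33 = std::sqrt(m33 - l31 * l31 - l32 * l32);
      const double r1 = Zte(i, 0) / sigma2, r2 = Zte(i, 1) / sigma2,
        r3 = Zte(i, 2) / sigma2;
      // forward solve L y = r, backward solve L' mean = y
      const double y1 = r1 / l11;
      const double y2 = (r2 - l21 * y1) / l22;
      const double y3 = (r3 - l31 * y1 - l32 * y2) / l33;
      double me3 = y3 / l33;
      double me2 = (y2 - l32 * me3) / l22;
      double me1 = (y1 - l21 * me2 - l31 * me3) / l11;
      // draw: mean + L'^{-1} z
      const double z1 = norm_rand(), z2 = norm_rand(), z3 = norm_rand();
      const double p3 = z3 / l33;
      const double p2 = (z2 - l32 * p3) / l22;
      const double p1 = (z1 - l21 * p2 - l31 * p3) / l11;
      arma::vec prop(3);
      prop(0) = me1 + p1; prop(1) = me2 + p2; prop(2) = me3 + p3;
      if (!informative) {
        b.row(i) = prop.t();
        ++re_acc;
      } else {
        double ci = std::exp(lam0 * trt(i)) * Lam0(i);
        double lin_old = eta1 * b(i, 0) + eta2 * b(i, 2);
        double lin_new = eta1 * prop(0) + eta2 * prop(2);
        double dll = event(i) * (lin_new - lin_old) -
          ci * (std::exp(lin_new) - std::exp(lin_old));
        if (std::log(unif_rand()) < dll) { b.row(i) = prop.t(); ++re_acc; }
      }
      ++re_tot;
    }

    // ---- fixed coefficients theta | b (conjugate Gaussian) ----
    arma::vec ystar(N);
    for (int r = 0; r < N; ++r) {
      int i = subj(r);
      ystar(r) = y(r) - (b(i, 0) + b(i, 1) * Avec(r) + b(i, 2) * Cvec(r));
    }
    arma::mat P = FtF / sigma2;
    P.diag() += 1.0 / tau0sq;
    arma::vec rhs = F.t() * ystar / sigma2;
    arma::mat Uq = arma::chol(P);
    arma::vec mean_q = arma::solve(P, rhs, arma::solve_opts::likely_sympd);
    arma::vec zq(q);
    for (int k = 0; k < q; ++k) zq(k) = norm_rand();
    theta = mean_q + arma::solve(arma::trimatu(Uq), zq);

    // ---- sigma2 | rest (inverse gamma) ----
    arma::vec resid = ystar - F * theta;
    double SSR = arma::dot(resid, resid);
    double btSb = arma::accu((b * Siginv) % b);
    double shape = a0 + 0.5 * (N + 3.0 * n);
    double rate = b0 + 0.5 * (SSR + btSb);
    sigma2 = 1.0 / R::rgamma(shape, 1.0 / rate);

    // ---- Sigma^{-1} | rest (Wishart) ----
    arma::mat Spost = b0 * arma::eye(3, 3) + b.t() * b / sigma2;
    Siginv = wishart_draw(wish_df + n, arma::inv_sympd(Spost));
    Sigma = arma::inv_sympd(Siginv);

    // ---- survival parameters psi (componentwise random walk) ----
    double cur = surv_logpost(psi, b, event, Delta, tidx, trt, tau0sq);
    for (int j = 0; j < K + 3; ++j) {
      arma::vec cand = psi;
      cand(j) += rw_scale(j) * norm_rand();
      double ll = surv_logpost(cand, b, event, Delta, tidx, trt, tau0sq);
      bool acc = std::log(unif_rand()) < (ll - cur);
      if (acc) { psi = cand; cur = ll; psi_acc(j) += 1.0; }
      if (adapt && it < B / 2) {
        double step = std::min(0.25, 1.0 / std::sqrt(it + 1.0));
        rw_scale(j) *= std::exp(step * ((acc ? 1.0 : 0.0) - 0.44));
      }
    }

    if (keep > 0 && it >= B - keep) {
      int col = it - (B - keep);
      keep_theta.col(col) = theta;
      keep_sigma2(col) = sigma2;
      keep_psi.col(col) = psi;
    }
  }

  return List::create(
    _["theta"] = theta, _["b"] = b, _["sigma2"] = sigma2,
    _["Sigma"] = Sigma, _["psi"] = psi, _["rw_scale"] = rw_scale,
    _["re_accept"] = re_tot > 0 ? double(re_acc) / re_tot : 1.0,
    _["psi_accept"] = psi_acc / double(B),
    _["keep_theta"] = keep_theta, _["keep_sigma2"] = keep_sigma2,
    _["keep_psi"] = keep_psi);
}

// ---------------------------------------------------------------------------
// Tree sweep
// ---------------------------------------------------------------------------

struct FlatTree {
  std::vector<int> var, left, right, parent, depth;
  std::vector<double> cut;
  std::vector<bool> active;

  int add_node(int par, int dep) {
    var.push_back(-1); cut.push_back(NA_REAL);
    left.push_back(-1); right.push_back(-1);
    parent.push_back(par); depth.push_back(dep);
    active.push_back(true);
    return (int)var.size() - 1;
  }
  bool is_leaf(int nd) const { return active[nd] && var[nd] < 0; }
  int n_leaves() const {
    int c = 0;
    for (size_t i = 0; i < var.size(); ++i) if (is_leaf((int)i)) ++c;
    return c;
  }
  void leaves(std::vector<int>& out) const {
    out.clear();
    for (size_t i = 0; i < var.size(); ++i) if (is_leaf((int)i)) out.push_back((int)i);
  }
  void prunable(std::vector<int>& out) const {
    out.clear();
    for (size_t i = 0; i < var.size(); ++i) {
      if (active[i] && var[i] >= 0 && is_leaf(left[i]) && is_leaf(right[i]))
        out.push_back((int)i);
    }
  }
  void preorder_leaves(int nd, std::vector<int>& out) const {
    if (var[nd] < 0) { out.push_back(nd); return; }
    preorder_leaves(left[nd], out);
    preorder_leaves(right[nd], out);
  }
};

static double p_split_cpp(int depth, double c0, double d0) {
  return c0 * std::pow(1.0 + depth, -d0);
}

// Collapsed marginal likelihood of the whole longitudinal dataset with ALL
// regression coefficient blocks integrated out (random effects already
// marginalized into the per-subject basis Gram scalars `kappa`). Column
// layout matches the R-side design: [alpha leaves (pa each)] [gamma leaves
// (ps each)] [tau leaves (1 each)] [beta (ps)] [zeta (ps)].
//
// kappa rows per subject: (k11, k1A, k1C, kAA, kAC, kCC, k1r, kAr, kCr)
// where kPQ = P' V^-1 Q for time bases P,Q in {1, A, C} and r the residual
// after the Laplace mean shift; V is the random-effect-marginal covariance.
struct JointMarginal {
  const arma::mat& Xa; const arma::mat& Xs; const arma::mat& kappa;
  const arma::vec& trt; double wrat; double fac_scale; // 1/(1-w)
  double tau0sq; int pa, ps, n;

  JointMarginal(const arma::mat& Xa_, const arma::mat& Xs_,
                const arma::mat& kappa_, const arma::vec& trt_,
                double wrat_, double fac_scale_, double tau0sq_)
    : Xa(Xa_), Xs(Xs_), kappa(kappa_), trt(trt_), wrat(wrat_),
      fac_scale(fac_scale_), tau0sq(tau0sq_),
      pa(Xa_.n_cols), ps(Xs_.n_cols), n(Xa_.n_rows) {}

  // con = -0.5 * (q log tau0sq + logdet A - b' A^-1 b); A,b assembled from
  // the three leaf-assignment vectors (values 0..J-1).
  double eval(const std::vector<int>& a0, const std::vector<int>& a1,
              const std::vector<int>& a2, int J0, int J1, int J2,
              arma::mat* Aout = nullptr, arma::vec* bout = nullptr) const {
    const int q = pa * J0 + ps * J1 + J2 + 2 * ps;
    arma::mat A(q, q, arma::fill::zeros);
    A.diag() += 1.0 / tau0sq;
    arma::vec b(q, arma::fill::zeros);
    const int off_g = pa * J0, off_t = pa * J0 + ps * J1;
    const int off_b = off_t + J2, off_z = off_b + ps;

    arma::vec tb(5), tr(5);
    for (int i = 0; i < n; ++i) {
      const double k11 = kappa(i, 0), k1A = kappa(i, 1), k1C = kappa(i, 2);
      const double kAA = kappa(i, 3), kAC = kappa(i, 4), kCC = kappa(i, 5);
      const double k1r = kappa(i, 6), kAr = kappa(i, 7), kCr = kappa(i, 8);
      const double ti = trt(i), fac = ti * fac_scale;
      // time-basis Gram between the 5 column groups:
      // g0: 1 | g1: C | g2: fac*C | g3: A | g4: ti*(A - wrat*C)
      double t00 = k11, t01 = k1C, t03 = k1A;
      double t02 = fac * k1C, t04 = ti * (k1A - wrat * k1C);
      double t11 = kCC, t13 = kAC;
      double t12 = fac * kCC, t14 = ti * (kAC - wrat * kCC);
      double t22 = fac * fac * kCC, t23 = fac * kAC;
      double t24 = ti * fac * (kAC - wrat * kCC);
      double t33 = kAA, t34 = ti * (kAA - wrat * kAC);
      double t44 = ti * ti * (kAA - 2 * wrat * kAC + wrat * wrat * kCC);
      double r0 = k1r, r1 = kCr, r2 = fac * kCr, r3 = kAr;
      double r4 = ti * (kAr - wrat * kCr);

      const int c0 = a0[i] * pa;          // alpha block offset
      const int c1 = off_g + a1[i] * ps;  // gamma block offset
      const int c2 = off_t + a2[i];       // tau column
      const arma::rowvec xa = Xa.row(i), xs = Xs.row(i);

      for (int u = 0; u < pa; ++u) {
        const double xau = xa(u);
        b(c0 + u) += r0 * xau;
        for (int v = u; v < pa; ++v) A(c0 + u, c0 + v) += t00 * xau * xa(v);
        for (int v = 0; v < ps; ++v) {
          const double xsv = xs(v);
          A(c0 + u, c1 + v) += t01 * xau * xsv;
          A(c0 + u, off_b + v) += t03 * xau * xsv;
          A(c0 + u, off_z + v) += t04 * xau * xsv;
        }
        A(c0 + u, c2) += t02 * xau;
      }
      for (int u = 0; u < ps; ++u) {
        const double xsu = xs(u);
        b(c1 + u) += r1 * xsu;
        b(off_b + u) += r3 * xsu;
        b(off_z + u) += r4 * xsu;
        for (int v = u; v < ps; ++v) {
          const double xsv = xs(v);
          A(c1 + u, c1 + v) += t11 * xsu * xsv;
          A(off_b + u, off_b + v) += t33 * xsu * xsv;
          A(off_z + u, off_z + v) += t44 * xsu * xsv;
        }
        for (int v = 0; v < ps; ++v) {
          const double xsv = xs(v);
          A(c1 + u, off_b + v) += t13 * xsu * xsv;
          A(c1 + u, off_z + v) += t14 * xsu * xsv;
          A(off_b + u, off_z + v) += t34 * xsu * xsv;
        }
        A(c1 + u, c2) += t12 * xsu;
        A(c2, off_b + u) += t23 * xsu;
        A(c2, off_z + u) += t24 * xsu;
      }
      A(c2, c2) += t22;
      b(c2) += r2;
    }
    // every fill above touches the upper triangle only
    A = arma::symmatu(A);

    arma::mat U;
    if (!arma::chol(U, A)) return -arma::datum::inf;
    double ld = 2.0 * arma::accu(arma::log(U.diag()));
    arma::vec w1 = arma::solve(arma::trimatl(U.t()), b);
    if (Aout) *Aout = A;
    if (bout) *bout = b;
    return -0.5 * (q * std::log(tau0sq) + ld) + 0.5 * arma::dot(w1, w1);
  }
};

// Eligible (variable, cut) pairs for splitting the given members.
static void eligible_pairs_cpp(const std::vector<int>& members,
                               const arma::mat& Xsplit,
                               const std::vector<arma::vec>& grids,
                               int min_leaf, bool both_arms,
                               const arma::vec& trt,
                               std::vector<std::pair<int,int> >& out) {
  out.clear();
  const int m = (int)grids.size();
  for (int v = 0; v < m; ++v) {
    const arma::vec& g = grids[v];
    for (int c = 0; c < (int)g.n_elem; ++c) {
      int nl = 0, nr = 0, tl0 = 0, tl1 = 0, tr0 = 0, tr1 = 0;
      for (int idx : members) {
        if (Xsplit(idx, v) <= g(c)) {
          ++nl;
          if (trt(idx) > 0.5) ++tl1; else ++tl0;
        } else {
          ++nr;
          if (trt(idx) > 0.5) ++tr1; else ++tr0;
        }
      }
      if (nl < min_leaf || nr < min_leaf) continue;
      if (both_arms && (tl0 == 0 || tl1 == 0 || tr0 == 0 || tr1 == 0)) continue;
      out.push_back(std::make_pair(v, c));
    }
  }
}


// B birth/death Metropolis-Hastings moves over one of the three trees, with
// every regression coefficient block integrated out of the acceptance ratio
// (random effects marginalized via the Laplace-tilted covariance baked into
// `kappa`), followed by a joint conjugate draw of all coefficients.
// `which_tree` is 0 (alpha0), 1 (gamma0) or 2 (tau0); the other two trees'
// leaf assignments stay fixed.
// [[Rcpp::export]]
List cpp_tree_sweep(List treeR, const arma::mat& Xsplit, List gridsR,
                    const arma::mat& Xa, const arma::mat& Xs,
                    const arma::mat& kappa, const arma::vec& trt,
                    double wrat, double fac_scale,
                    const arma::ivec& assign0, const arma::ivec& assign1,
                    const arma::ivec& assign2, int which_tree,
                    int J0_fixed, int J1_fixed, int J2_fixed,
                    double tau0sq, double c0, double d0,
                    int min_leaf, bool both_arms, int B, bool prior_only) {
  const int n = Xsplit.n_rows;
  const int m = gridsR.size();
  std::vector<arma::vec> grids(m);
  for (int v = 0; v < m; ++v) grids[v] = as<arma::vec>(gridsR[v]);

  JointMarginal jm(Xa, Xs, kappa, trt, wrat, fac_scale, tau0sq);

  // decode tree (1-based, NA -> -1)
  FlatTree T;
  {
    IntegerVector var = treeR["var"];
    NumericVector cut = treeR["cut"];
    IntegerVector left = treeR["left"], right = treeR["right"];
    IntegerVector parent = treeR["parent"], depth = treeR["depth"];
    for (int i = 0; i < var.size(); ++i) {
      T.var.push_back(var[i] == NA_INTEGER ? -1 : var[i] - 1);
      T.cut.push_back(cut[i]);
      T.left.push_back(left[i] == NA_INTEGER ? -1 : left[i] - 1);
      T.right.push_back(right[i] == NA_INTEGER ? -1 : right[i] - 1);
      T.parent.push_back(parent[i] == NA_INTEGER ? -1 : parent[i] - 1);
      T.depth.push_back(depth[i]);
      T.active.push_back(true);
    }
  }

  // node-id assignment for the tree being updated
  std::vector<int> avec(n);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (T.var[nd] >= 0)
      nd = (Xsplit(i, T.var[nd]) <= T.cut[nd]) ? T.left[nd] : T.right[nd];
    avec[i] = nd;
  }

  // fixed ordinal assignments of the other two trees (0-based)
  std::vector<int> a0f(n), a1f(n), a2f(n);
  for (int i = 0; i < n; ++i) {
    a0f[i] = assign0(i) - 1; a1f[i] = assign1(i) - 1; a2f[i] = assign2(i) - 1;
  }

  // evaluate the collapsed marginal under the current tree-k assignment
  std::vector<int> lv;
  auto eval_current = [&](const std::vector<int>& node_assign,
                          arma::mat* Aout = nullptr,
                          arma::vec* bout = nullptr) -> double {
    if (prior_only && !Aout) return 0.0;
    T.leaves(lv);
    std::vector<int> node2ord(T.var.size(), -1);
    for (size_t j = 0; j < lv.size(); ++j) node2ord[lv[j]] = (int)j;
    std::vector<int> ak(n);
    for (int i = 0; i < n; ++i) ak[i] = node2ord[node_assign[i]];
    int Jk = (int)lv.size();
    const std::vector<int>& u0 = (which_tree == 0) ? ak : a0f;
    const std::vector<int>& u1 = (which_tree == 1) ? ak : a1f;
    const std::vector<int>& u2 = (which_tree == 2) ? ak : a2f;
    int J0 = (which_tree == 0) ? Jk : J0_fixed;
    int J1 = (which_tree == 1) ? Jk : J1_fixed;
    int J2 = (which_tree == 2) ? Jk : J2_fixed;
    return jm.eval(u0, u1, u2, J0, J1, J2, Aout, bout);
  };

  double con_cur = eval_current(avec);
  int accepted = 0;
  std::vector<int> pn;
  std::vector<std::pair<int,int> > pairs;

  for (int it = 0; it < B; ++it) {
    T.leaves(lv);
    const int J = (int)lv.size();
    const double p_birth = (J == 1) ? 1.0 : 0.5;
    const bool do_birth = unif_rand() < p_birth;

    if (do_birth) {
      int leaf = lv[(int)(unif_rand() * J) % J];
      std::vector<int> mem;
      for (int i = 0; i < n; ++i) if (avec[i] == leaf) mem.push_back(i);
      eligible_pairs_cpp(mem, Xsplit, grids, min_leaf, both_arms, trt, pairs);
      if (pairs.empty()) continue; // null iteration
      std::pair<int,int> pick = pairs[(int)(unif_rand() * pairs.size()) % pairs.size()];
      double cutval = grids[pick.first](pick.second);

      // propose: grow, reroute members, evaluate, maybe revert
      int l = T.add_node(leaf, T.depth[leaf] + 1);
      int r = T.add_node(leaf, T.depth[leaf] + 1);
      T.var[leaf] = pick.first; T.cut[leaf] = cutval;
      T.left[leaf] = l; T.right[leaf] = r;
      std::vector<int> avec_new = avec;
      for (int idx : mem)
        avec_new[idx] = (Xsplit(idx, pick.first) <= cutval) ? l : r;
      double con_prop = eval_current(avec_new);

      int dep = T.depth[leaf];
      double ps = p_split_cpp(dep, c0, d0), ps1 = p_split_cpp(dep + 1, c0, d0);
      double d_prior = std::log(ps) + 2.0 * std::log(1.0 - ps1) -
        std::log(1.0 - ps) - std::log((double)m) -
        std::log((double)grids[pick.first].n_elem);
      T.prunable(pn);
      double log_fwd = std::log(p_birth) - std::log((double)J) -
        std::log((double)pairs.size());
      double log_rev = std::log(0.5) - std::log((double)pn.size());

      if (std::log(unif_rand()) <
          (con_prop - con_cur) + d_prior + (log_rev - log_fwd)) {
        avec = avec_new;
        con_cur = con_prop;
        ++accepted;
      } else {
        T.var[leaf] = -1; T.cut[leaf] = NA_REAL;
        T.left[leaf] = -1; T.right[leaf] = -1;
        T.active[l] = false; T.active[r] = false;
      }
    } else {
      T.prunable(pn);
      if (pn.empty()) continue;
      const int npr = (int)pn.size();
      int nd = pn[(int)(unif_rand() * npr) % npr];
      int l = T.left[nd], r = T.right[nd];
      int var_saved = T.var[nd];
      double cut_saved = T.cut[nd];

      std::vector<int> mem;
      for (int i = 0; i < n; ++i) if (avec[i] == l || avec[i] == r) mem.push_back(i);
      // propose: prune, evaluate, maybe revert
      T.var[nd] = -1; T.cut[nd] = NA_REAL;
      T.left[nd] = -1; T.right[nd] = -1;
      T.active[l] = false; T.active[r] = false;
      std::vector<int> avec_new = avec;
      for (int idx : mem) avec_new[idx] = nd;
      double con_prop = eval_current(avec_new);

      int dep = T.depth[nd];
      double ps = p_split_cpp(dep, c0, d0), ps1 = p_split_cpp(dep + 1, c0, d0);
      double d_prior = std::log(1.0 - ps) - std::log(ps) -
        2.0 * std::log(1.0 - ps1) + std::log((double)m) +
        std::log((double)grids[var_saved].n_elem);

      const int J_new = J - 1;
      eligible_pairs_cpp(mem, Xsplit, grids, min_leaf, both_arms, trt, pairs);
      int n_pairs = pairs.empty() ? 1 : (int)pairs.size();
      double p_birth_new = (J_new == 1) ? 1.0 : 0.5;
      double log_fwd = std::log(0.5) - std::log((double)npr);
      double log_rev = std::log(p_birth_new) - std::log((double)J_new) -
        std::log((double)n_pairs);

      if (std::log(unif_rand()) <
          (con_prop - con_cur) + d_prior + (log_rev - log_fwd)) {
        avec = avec_new;
        con_cur = con_prop;
        ++accepted;
      } else {
        T.var[nd] = var_saved; T.cut[nd] = cut_saved;
        T.left[nd] = l; T.right[nd] = r;
        T.active[l] = true; T.active[r] = true;
      }
    }
  }

  // final evaluation in preorder leaf order + joint coefficient draw
  std::vector<int> plv;
  T.preorder_leaves(0, plv);
  std::vector<int> node2ord(T.var.size(), -1);
  for (size_t j = 0; j < plv.size(); ++j) node2ord[plv[j]] = (int)j;
  std::vector<int> ak(n);
  for (int i = 0; i < n; ++i) ak[i] = node2ord[avec[i]];
  const std::vector<int>& u0 = (which_tree == 0) ? ak : a0f;
  const std::vector<int>& u1 = (which_tree == 1) ? ak : a1f;
  const std::vector<int>& u2 = (which_tree == 2) ? ak : a2f;
  int Jk = (int)plv.size();
  int J0 = (which_tree == 0) ? Jk : J0_fixed;
  int J1 = (which_tree == 1) ? Jk : J1_fixed;
  int J2 = (which_tree == 2) ? Jk : J2_fixed;
  arma::mat Afin;
  arma::vec bfin;
  double con_fin = jm.eval(u0, u1, u2, J0, J1, J2, &Afin, &bfin);
  arma::vec mean = arma::solve(Afin, bfin, arma::solve_opts::likely_sympd);
  arma::mat U = arma::chol(Afin);
  arma::vec z(Afin.n_rows);
  for (arma::uword k2 = 0; k2 < z.n_elem; ++k2) z(k2) = norm_rand();
  arma::vec theta = mean + arma::solve(arma::trimatu(U), z);

  // re-encode the tree compactly in preorder
  std::vector<int> order;
  std::function<void(int)> rec = [&](int nd) {
    order.push_back(nd);
    if (T.var[nd] >= 0) { rec(T.left[nd]); rec(T.right[nd]); }
  };
  rec(0);
  std::vector<int> newid(T.var.size(), -1);
  for (size_t k2 = 0; k2 < order.size(); ++k2) newid[order[k2]] = (int)k2;
  int nn = (int)order.size();
  IntegerVector var(nn), left(nn), right(nn), parent(nn), depth(nn);
  NumericVector cut(nn);
  for (int k2 = 0; k2 < nn; ++k2) {
    int nd = order[k2];
    var[k2] = T.var[nd] < 0 ? NA_INTEGER : T.var[nd] + 1;
    cut[k2] = T.cut[nd];
    left[k2] = T.left[nd] < 0 ? NA_INTEGER : newid[T.left[nd]] + 1;
    right[k2] = T.right[nd] < 0 ? NA_INTEGER : newid[T.right[nd]] + 1;
    parent[k2] = T.parent[nd] < 0 ? NA_INTEGER : newid[T.parent[nd]] + 1;
    depth[k2] = T.depth[nd];
  }
  IntegerVector assign_out(n);
  for (int i = 0; i < n; ++i) assign_out[i] = ak[i] + 1;

  return List::create(
    _["tree"] = List::create(_["var"] = var, _["cut"] = cut, _["left"] = left,
                             _["right"] = right, _["parent"] = parent,
                             _["depth"] = depth),
    _["assign"] = assign_out, _["theta"] = theta,
    _["accepted"] = accepted, _["log_marginal_part"] = con_fin);
}
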