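// Gibbs/Metropolis samplers for random-regression (animal) models of a
// labile seasonal-timing trait, plus pedigree inbreeding coefficients.
// All randomness goes through R's RNG so set.seed() controls everything.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  arma::vec z(n);
  for (int i = 0; i < n; ++i) z[i] = R::norm_rand();
  return z;
}

// inverse-Wishart draw, density |S|^(nu/2) |Sig|^-((nu+d+1)/2) exp(-tr(S Sig^-1)/2)
static arma::mat riwish(double df, const arma::mat& S) {
  int d = S.n_rows;
  arma::mat Ss = arma::symmatu(S);
  arma::mat Sinv;
  if (!arma::inv_sympd(Sinv, Ss))
    Sinv = arma::inv(Ss + 1e-8 * arma::eye(d, d));
  arma::mat L = arma::chol(arma::symmatu(Sinv), "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  arma::mat out;
  if (!arma::inv_sympd(out, arma::symmatu(W)))
    out = arma::inv(arma::symmatu(W) + 1e-10 * arma::eye(d, d));
  return arma::symmatu(out);
}

static double rinvgamma(double shape, double rate) {
  return rate / R::rgamma(shape, 1.0);
}

// sample from N(P^-1 b, P^-1); jitters the precision if needed
static arma::vec mvn_prec(const arma::mat& P, const arma::vec& b, int* njit) {
  arma::mat Ps = arma::symmatu(P);
  arma::mat R;
  double ridge = 0.0;
  int d = P.n_rows;
  while (!arma::chol(R, Ps + ridge * arma::eye(d, d))) {
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 10.0;
    if (njit) ++(*njit);
    if (ridge > 1e2) stop("non-finite precision matrix in Gibbs update");
  }
  arma::vec mu = arma::solve(arma::trimatl(R.t()), b);
  mu = arma::solve(arma::trimatu(R), mu);
  return mu + arma::solve(arma::trimatu(R), rnorm_vec(d));
}

// draw from N(P^-1 b, P^-1) for d <= 6 without heap allocation:
// in-place Cholesky P = L L', solve L t = b, L' mu = t, and add L'^-1 z
static void samp_small(double* P, double* b, int d, double* out, int* njit) {
  double L[36];
  double ridge = 0.0;
  for (;;) {
    bool ok = true;
    for (int j = 0; j < d && ok; ++j) {
      double s = P[j * d + j] + ridge;
      for (int k = 0; k < j; ++k) s -= L[j * d + k] * L[j * d + k];
      if (s <= 0.0) { ok = false; break; }
      L[j * d + j] = std::sqrt(s);
      for (int i = j + 1; i < d; ++i) {
        double v = P[i * d + j];
        for (int k = 0; k < j; ++k) v -= L[i * d + k] * L[j * d + k];
        L[i * d + j] = v / L[j * d + j];
      }
    }
    if (ok) break;
    ridge = (ridge == 0.0) ? 1e-8 : ridge * 10.0;
    if (njit) ++(*njit);
    if (ridge > 1e3) stop("non-finite precision matrix in Gibbs update");
  }
  double t[6], mu[6];
  for (int i = 0; i < d; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i * d + k] * t[k];
    t[i] = s / L[i * d + i];
  }
  for (int i = d - 1; i >= 0; --i) {
    double s = t[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * mu[k];
    mu[i] = s / L[i * d + i];
  }
  // sample: out = mu + L'^-1 z
  double z[6];
  for (int i = 0; i < d; ++i) z[i] = R::norm_rand();
  for (int i = d - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * out[k];
    out[i] = s / L[i * d + i];
  }
  for (int i = 0; i < d; ++i) out[i] += mu[i];
}

static arma::mat inv2s(const arma::mat& S) {
  arma::mat out;
  if (!arma::inv_sympd(out, arma::symmatu(S)))
    out = arma::inv(arma::symmatu(S) + 1e-10 * arma::eye(S.n_rows, S.n_rows));
  return arma::symmatu(out);
}

// record lists grouped by an index vector (CSR layout)
struct Groups {
  std::vector<int> ptr, idx;
  int ng;
  void build(const arma::ivec& gidx, int n_groups) {
    ng = n_groups;
    ptr.assign(ng + 1, 0);
    idx.resize(gidx.n_elem);
    for (arma::uword i = 0; i < gidx.n_elem; ++i) ptr[gidx[i] + 1]++;
    for (int g = 0; g < ng; ++g) ptr[g + 1] += ptr[g];
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (arma::uword i = 0; i < gidx.n_elem; ++i) idx[fill[gidx[i]]++] = i;
  }
};

// Meuwissen & Luo (1992) inbreeding coefficients.
// dam/sire are 1-based row indices (0 = unknown); topo is a 1-based
// topological order with parents before offspring.
// [[Rcpp::export]]
arma::vec ml_inbreeding(const arma::ivec& dam, const arma::ivec& sire,
                        const arma::ivec& topo) {
  int n = dam.n_elem;
  arma::vec F(n, arma::fill::zeros), D(n, arma::fill::zeros);
  std::vector<int> ord(n);
  for (int t = 0; t < n; ++t) ord[topo[t] - 1] = t;
  std::vector<double> w(n, 0.0);
  for (int t = 0; t < n; ++t) {
    int i = topo[t] - 1;
    int d = dam[i] - 1, s = sire[i] - 1;
    if (d >= 0 && s >= 0) {
      // traverse ancestors, youngest first, accumulating A(i,i)
      double Aii = 0.0;
      std::priority_queue<std::pair<int, int> > pq; // (ord, index)
      w[i] = 1.0;
      pq.push(std::make_pair(ord[i], i));
      while (!pq.empty()) {
        int j = pq.top().second;
        pq.pop();
        if (w[j] == 0.0) continue; // processed already (duplicate push)
        double wj = w[j];
        w[j] = 0.0;
        int dj = dam[j] - 1, sj = sire[j] - 1;
        double Dj;
        if (j == i) {
          Dj = 0.5 - 0.25 * (F[d] + F[s]);
        } else {
          Dj = D[j];
        }
        Aii += wj * wj * Dj;
        if (dj >= 0) {
          if (w[dj] == 0.0) pq.push(std::make_pair(ord[dj], dj));
          w[dj] += wj / 2.0;
        }
        if (sj >= 0) {
          if (w[sj] == 0.0) pq.push(std::make_pair(ord[sj], sj));
          w[sj] += wj / 2.0;
        }
      }
      F[i] = Aii - 1.0;
    } else {
      F[i] = 0.0;
    }
    // Mendelian-sampling variance, now that F[i]'s parents are final
    if (d >= 0 && s >= 0) D[i] = 0.5 - 0.25 * (F[d] + F[s]);
    else if (d >= 0) D[i] = 0.75 - 0.25 * F[d];
    else if (s >= 0) D[i] = 0.75 - 0.25 * F[s];
    else D[i] = 1.0;
  }
  return F;
}

// Univariate random-regression (animal) model Gibbs sampler.
//
// y = X beta + u_f(i) . (1, tc) + g_k(i) . (1, tc) + yr + nb + e,
// e_i ~ N(0, sigma2_e[group(i)]);
// u_f ~ N(0, S_pe) (permanent environment, dim 1 or 2),
// g ~ N(0, G kron A) via the sparse A-inverse (dim 2, optional),
// yr ~ N(0, s2yr), nb ~ N(0, s2nb).
//
// Conjugate updates throughout: Gaussian blocks for beta and each random
// block (PE and additive effects of a phenotyped female are sampled
// jointly, 4-dim, to decorrelate the two terms; unphenotyped pedigree
// members get single-site updates), inverse-Wishart for S_pe and G,
// inverse-gamma for scalar and group residual variances.
// [[Rcpp::export]]
List rram_gibbs(const arma::vec& y, const arma::mat& X,
                const arma::ivec& fem, const arma::vec& tc,
                const arma::ivec& rg, const arma::ivec& yr,
                const arma::ivec& nb,
                int n_fem, int n_yr, int n_nb, int n_rg,
                bool pe_slope,
                const arma::sp_mat& Ainv, const arma::ivec& fem2ind,
                List prior, List control) {
  int n = y.n_elem;
  int p = X.n_cols;
  int dpe = pe_slope ? 2 : 1;
  int n_ind = Ainv.n_rows;
  bool has_add = n_ind > 0;

  int n_iter = as<int>(control["n_iter"]);
  int burn = as<int>(control["burn"]);
  int thin = as<int>(control["thin"]);
  bool fix_resid = control.containsElementNamed("fix_resid") &&
    !Rf_isNull(control["fix_resid"]);
  bool fix_pe = control.containsElementNamed("fix_pe_cov") &&
    !Rf_isNull(control["fix_pe_cov"]);
  // parameter expansion: effects are alpha .* eta with eta ~ N(0, Psi),
  // alpha ~ N(0, diag(alpha_V)); reported covariances are D_a Psi D_a
  bool px = control.containsElementNamed("px") && as<bool>(control["px"]) &&
    !fix_pe;
  double aV = px ? as<double>(prior["alpha_V"]) : 1.0;

  double nu_pe = as<double>(prior["nu_pe"]);
  arma::mat V_pe = as<arma::mat>(prior["V_pe"]);
  double nu_g = as<double>(prior["nu_g"]);
  arma::mat V_g = as<arma::mat>(prior["V_g"]);
  double a_sc = as<double>(prior["a_scalar"]);
  double b_sc = as<double>(prior["b_scalar"]);

  Groups by_fem, by_yr, by_nb, by_rg;
  by_fem.build(fem, n_fem);
  if (n_yr > 0) by_yr.build(yr, n_yr);
  if (n_nb > 0) by_nb.build(nb, n_nb);
  by_rg.build(rg, n_rg);

  // unphenotyped pedigree members
  std::vector<int> orphan;
  if (has_add) {
    std::vector<bool> pheno(n_ind, false);
    for (int f = 0; f < n_fem; ++f)
      if (fem2ind[f] >= 0) pheno[fem2ind[f]] = true;
    for (int k = 0; k < n_ind; ++k) if (!pheno[k]) orphan.push_back(k);
  }

  // state
  arma::vec beta(p, arma::fill::zeros);
  arma::mat u(n_fem, dpe, arma::fill::zeros);
  arma::mat g(std::max(n_ind, 1), 2, arma::fill::zeros);
  arma::vec yre(std::max(n_yr, 1), arma::fill::zeros);
  arma::vec nbe(std::max(n_nb, 1), arma::fill::zeros);
  double vy = arma::var(y);
  arma::vec s2e(n_rg);
  s2e.fill(vy / 2.0);
  if (fix_resid) s2e = as<arma::vec>(control["fix_resid"]);
  arma::mat Spe = arma::eye(dpe, dpe) * vy / 4.0;
  if (dpe == 2) Spe(1, 1) = 0.05;
  if (fix_pe) Spe = as<arma::mat>(control["fix_pe_cov"]);
  arma::mat G = arma::eye(2, 2);
  G(0, 0) = vy / 4.0; G(1, 1) = 0.05;
  double s2yr = vy / 4.0, s2nb = vy / 10.0;
  arma::vec ape(dpe, arma::fill::ones), ag(2, arma::fill::ones);

  arma::vec r = y; // residual given all-zero effects
  int njit = 0;

  int n_store = (n_iter - burn) / thin;
  int ncol = p + (dpe == 2 ? 3 : 1) + (has_add ? 3 : 0) +
    (n_yr > 0 ? 1 : 0) + (n_nb > 0 ? 1 : 0) + n_rg;
  arma::mat store(n_store, ncol);
  int srow = 0;

  arma::vec w(n);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n; ++i) w[i] = 1.0 / s2e[rg[i]];

    // fixed effects
    if (p > 0) {
      r += X * beta;
      arma::mat Xw = X;
      Xw.each_col() %= w;
      arma::mat M = X.t() * Xw;
      arma::vec v = Xw.t() * r;
      beta = mvn_prec(M, v, &njit);
      r -= X * beta;
    }

    arma::mat Speinv = inv2s(Spe);
    arma::mat Ginv = has_add ? inv2s(G) : arma::mat();
    arma::mat Gchol;
    if (has_add) Gchol = arma::chol(arma::symmatu(G) +
      1e-12 * arma::eye(2, 2), "lower");

    // per-female joint PE (+ additive) block
    int dim_max = dpe + (has_add ? 2 : 0);
    arma::mat P(dim_max, dim_max);
    arma::vec b(dim_max), th(dim_max), s(2);
    double ap0 = ape[0], ap1 = (dpe == 2) ? ape[1] : 0.0;
    double ag0 = ag[0], ag1 = ag[1];
    for (int f = 0; f < n_fem; ++f) {
      int k = has_add ? fem2ind[f] : -1;
      double u0 = ap0 * u(f, 0), u1 = (dpe == 2) ? ap1 * u(f, 1) : 0.0;
      double g0 = (k >= 0) ? ag0 * g(k, 0) : 0.0;
      double g1 = (k >= 0) ? ag1 * g(k, 1) : 0.0;
      double sw = 0, swt = 0, swt2 = 0, b0 = 0, b1 = 0;
      for (int m = by_fem.ptr[f]; m < by_fem.ptr[f + 1]; ++m) {
        int i = by_fem.idx[m];
        double t = tc[i];
        double rs = r[i] + u0 + u1 * t + g0 + g1 * t;
        r[i] = rs; // add back; subtract new contribution below
        sw += w[i]; swt += w[i] * t; swt2 += w[i] * t * t;
        b0 += w[i] * rs; b1 += w[i] * t * rs;
      }
      int dim = dpe + (k >= 0 ? 2 : 0);
      P.zeros(); b.zeros();
      // data part: design row for eta is (ap0[, ap1 t]), for xi (ag0, ag1 t)
      // cross-products couple the two blocks
      P(0, 0) += ap0 * ap0 * sw; b(0) += ap0 * b0;
      if (dpe == 2) {
        P(0, 1) += ap0 * ap1 * swt; P(1, 0) += ap0 * ap1 * swt;
        P(1, 1) += ap1 * ap1 * swt2; b(1) += ap1 * b1;
      }
      P.submat(0, 0, dpe - 1, dpe - 1) += Speinv;
      if (k >= 0) {
        int o = dpe;
        P(o, o) += ag0 * ag0 * sw; P(o, o + 1) += ag0 * ag1 * swt;
        P(o + 1, o) += ag0 * ag1 * swt; P(o + 1, o + 1) += ag1 * ag1 * swt2;
        b(o) += ag0 * b0; b(o + 1) += ag1 * b1;
        // cross block between the two scaled designs
        P(0, o) += ap0 * ag0 * sw; P(0, o + 1) += ap0 * ag1 * swt;
        P(o, 0) += ap0 * ag0 * sw; P(o + 1, 0) += ap0 * ag1 * swt;
        if (dpe == 2) {
          P(1, o) += ap1 * ag0 * swt; P(1, o + 1) += ap1 * ag1 * swt2;
          P(o, 1) += ap1 * ag0 * swt; P(o + 1, 1) += ap1 * ag1 * swt2;
        }
        // additive conditional prior given the rest of the pedigree
        double qkk = Ainv(k, k);
        s.zeros();
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k);
             it != Ainv.end_col(k); ++it) {
          int j = it.row();
          if (j != k) { s[0] += (*it) * g(j, 0); s[1] += (*it) * g(j, 1); }
        }
        P(o, o) += qkk * Ginv(0, 0); P(o, o + 1) += qkk * Ginv(0, 1);
        P(o + 1, o) += qkk * Ginv(1, 0); P(o + 1, o + 1) += qkk * Ginv(1, 1);
        b(o) += -(Ginv(0, 0) * s[0] + Ginv(0, 1) * s[1]);
        b(o + 1) += -(Ginv(1, 0) * s[0] + Ginv(1, 1) * s[1]);
      }
      arma::vec th(dim);
      samp_small(P.memptr(), b.memptr(), dim, th.memptr(), &njit);
      u(f, 0) = th[0];
      if (dpe == 2) u(f, 1) = th[1];
      if (k >= 0) { g(k, 0) = th[dpe]; g(k, 1) = th[dpe + 1]; }
      double nu0 = ap0 * u(f, 0), nu1 = (dpe == 2) ? ap1 * u(f, 1) : 0.0;
      double ng0 = (k >= 0) ? ag0 * g(k, 0) : 0.0;
      double ng1 = (k >= 0) ? ag1 * g(k, 1) : 0.0;
      for (int m = by_fem.ptr[f]; m < by_fem.ptr[f + 1]; ++m) {
        int i = by_fem.idx[m];
        r[i] -= nu0 + nu1 * tc[i] + ng0 + ng1 * tc[i];
      }
    }

    // unphenotyped pedigree members: prior-conditional draw
    if (has_add) {
      for (size_t oi = 0; oi < orphan.size(); ++oi) {
        int k = orphan[oi];
        double qkk = Ainv(k, k);
        arma::vec s(2, arma::fill::zeros);
        for (arma::sp_mat::const_col_iterator it = Ainv.begin_col(k);
             it != Ainv.end_col(k); ++it) {
          int j = it.row();
          if (j != k) { s[0] += (*it) * g(j, 0); s[1] += (*it) * g(j, 1); }
        }
        double sq = std::sqrt(qkk);
        double z0 = R::norm_rand(), z1 = R::norm_rand();
        g(k, 0) = -s[0] / qkk + Gchol(0, 0) * z0 / sq;
        g(k, 1) = -s[1] / qkk + (Gchol(1, 0) * z0 + Gchol(1, 1) * z1) / sq;
      }
    }

    // working-scale (parameter-expansion) updates: GLS of the residual on
    // the raw-effect columns, with a N(0, alpha_V) prior on each scale
    if (px) {
      double c00 = 0, c01 = 0, c11 = 0, d0 = 0, d1 = 0;
      for (int i = 0; i < n; ++i) {
        int f = fem[i];
        double x0 = u(f, 0);
        double x1 = (dpe == 2) ? u(f, 1) * tc[i] : 0.0;
        double rs = r[i] + ape[0] * x0 + ((dpe == 2) ? ape[1] * x1 : 0.0);
        r[i] = rs;
        c00 += w[i] * x0 * x0; d0 += w[i] * x0 * rs;
        if (dpe == 2) {
          c01 += w[i] * x0 * x1; c11 += w[i] * x1 * x1; d1 += w[i] * x1 * rs;
        }
      }
      if (dpe == 2) {
        double Pm[4] = {c00 + 1.0 / aV, c01, c01, c11 + 1.0 / aV};
        double bv[2] = {d0, d1}, out[2];
        samp_small(Pm, bv, 2, out, &njit);
        ape[0] = out[0]; ape[1] = out[1];
      } else {
        double prec = c00 + 1.0 / aV;
        ape[0] = d0 / prec + R::norm_rand() / std::sqrt(prec);
      }
      for (int i = 0; i < n; ++i) {
        int f = fem[i];
        r[i] -= ape[0] * u(f, 0) +
          ((dpe == 2) ? ape[1] * u(f, 1) * tc[i] : 0.0);
      }
      if (has_add) {
        c00 = c01 = c11 = d0 = d1 = 0;
        for (int i = 0; i < n; ++i) {
          int k = fem2ind[fem[i]];
          double x0 = g(k, 0), x1 = g(k, 1) * tc[i];
          double rs = r[i] + ag[0] * x0 + ag[1] * x1;
          r[i] = rs;
          c00 += w[i] * x0 * x0; c01 += w[i] * x0 * x1;
          c11 += w[i] * x1 * x1;
          d0 += w[i] * x0 * rs; d1 += w[i] * x1 * rs;
        }
        double Pm[4] = {c00 + 1.0 / aV, c01, c01, c11 + 1.0 / aV};
        double bv[2] = {d0, d1}, out[2];
        samp_small(Pm, bv, 2, out, &njit);
        ag[0] = out[0]; ag[1] = out[1];
        for (int i = 0; i < n; ++i) {
          int k = fem2ind[fem[i]];
          r[i] -= ag[0] * g(k, 0) + ag[1] * g(k, 1) * tc[i];
        }
      }
    }

    // year and nest-box intercepts
    if (n_yr > 0) {
      for (int j = 0; j < n_yr; ++j) {
        double sw = 0, b = 0;
        for (int m = by_yr.ptr[j]; m < by_yr.ptr[j + 1]; ++m) {
          int i = by_yr.idx[m];
          r[i] += yre[j];
          sw += w[i]; b += w[i] * r[i];
        }
        double prec = 1.0 / s2yr + sw;
        double newv = b / prec + R::norm_rand() / std::sqrt(prec);
        yre[j] = newv;
        for (int m = by_yr.ptr[j]; m < by_yr.ptr[j + 1]; ++m)
          r[by_yr.idx[m]] -= newv;
      }
      double ss = arma::dot(yre.head(n_yr), yre.head(n_yr));
      s2yr = rinvgamma(a_sc + n_yr / 2.0, b_sc + ss / 2.0);
    }
    if (n_nb > 0) {
      for (int j = 0; j < n_nb; ++j) {
        double sw = 0, b = 0;
        for (int m = by_nb.ptr[j]; m < by_nb.ptr[j + 1]; ++m) {
          int i = by_nb.idx[m];
          r[i] += nbe[j];
          sw += w[i]; b += w[i] * r[i];
        }
        double prec = 1.0 / s2nb + sw;
        double newv = b / prec + R::norm_rand() / std::sqrt(prec);
        nbe[j] = newv;
        for (int m = by_nb.ptr[j]; m < by_nb.ptr[j + 1]; ++m)
          r[by_nb.idx[m]] -= newv;
      }
      double ss = arma::dot(nbe.head(n_nb), nbe.head(n_nb));
      s2nb = rinvgamma(a_sc + n_nb / 2.0, b_sc + ss / 2.0);
    }

    // covariance components
    if (!fix_pe) {
      arma::mat S = u.t() * u;
      Spe = riwish(nu_pe + n_fem, V_pe + S);
    }
    if (has_add) {
      arma::mat S = g.t() * (Ainv * g);
      G = riwish(nu_g + n_ind, V_g + arma::symmatu(S));
    }
    if (!fix_resid) {
      for (int l = 0; l < n_rg; ++l) {
        double ss = 0;
        int nl = by_rg.ptr[l + 1] - by_rg.ptr[l];
        for (int m = by_rg.ptr[l]; m < by_rg.ptr[l + 1]; ++m) {
          double ri = r[by_rg.idx[m]];
          ss += ri * ri;
        }
        s2e[l] = rinvgamma(a_sc + nl / 2.0, b_sc + ss / 2.0);
      }
    }

    if (!r.is_finite()) stop("sampler diverged (non-finite state) at iteration %d", iter + 1);

    if (iter >= burn && (iter - burn) % thin == 0 && srow < n_store) {
      int c = 0;
      for (int j = 0; j < p; ++j) store(srow, c++) = beta[j];
      // effective (reported) covariances fold the working scales back in
      store(srow, c++) = ape[0] * ape[0] * Spe(0, 0);
      if (dpe == 2) {
        store(srow, c++) = ape[0] * ape[1] * Spe(0, 1);
        store(srow, c++) = ape[1] * ape[1] * Spe(1, 1);
      }
      if (has_add) {
        store(srow, c++) = ag[0] * ag[0] * G(0, 0);
        store(srow, c++) = ag[0] * ag[1] * G(0, 1);
        store(srow, c++) = ag[1] * ag[1] * G(1, 1);
      }
      if (n_yr > 0) store(srow, c++) = s2yr;
      if (n_nb > 0) store(srow, c++) = s2nb;
      for (int l = 0; l < n_rg; ++l) store(srow, c++) = s2e[l];
      ++srow;
    }
  }

  return List::create(_["samples"] = store.rows(0, srow - 1),
                      _["n_jitter"] = njit);
}

// Bivariate model: Gaussian laying date (random-regression with
// within-individual centred temperature) + overdispersed-Poisson lifetime
// reproductive success, joined by a 3x3 unstructured female covariance
// matrix over (LD intercept, LD slope, LRS intercept). The LRS residual
// variance is held fixed (default 0.01). The LRS latent log-mean gets
// random-walk Metropolis updates, plus a joint shift move with its female
// intercept to beat the tight coupling induced by the small fixed residual.
// [[Rcpp::export]]
List bivrrm_gibbs(const arma::vec& y, const arma::mat& X,
                  const arma::ivec& fem, const arma::vec& tc,
                  const arma::ivec& rg, const arma::ivec& yr,
                  const arma::ivec& nb,
                  int n_fem, int n_yr, int n_nb, int n_rg,
                  const arma::vec& lrs, double ve_lrs,
                  List prior, List control) {
  int n = y.n_elem;
  int p = X.n_cols;

  int n_iter = as<int>(control["n_iter"]);
  int burn = as<int>(control["burn"]);
  int thin = as<int>(control["thin"]);

  double nu3 = as<double>(prior["nu_fem"]);
  arma::mat V3 = as<arma::mat>(prior["V_fem"]);
  double a_sc = as<double>(prior["a_scalar"]);
  double b_sc = as<double>(prior["b_scalar"]);

  Groups by_fem, by_yr, by_nb, by_rg;
  by_fem.build(fem, n_fem);
  if (n_yr > 0) by_yr.build(yr, n_yr);
  if (n_nb > 0) by_nb.build(nb, n_nb);
  by_rg.build(rg, n_rg);

  arma::vec beta(p, arma::fill::zeros);
  arma::mat fe(n_fem, 3, arma::fill::zeros); // a, b, c per female
  arma::vec t_lat(n_fem, arma::fill::zeros); // c + e on the log scale
  double alphaW = std::log(arma::mean(lrs) + 0.05);
  arma::vec yre(std::max(n_yr, 1), arma::fill::zeros);
  arma::vec nbe(std::max(n_nb, 1), arma::fill::zeros);
  double vy = arma::var(y);
  arma::vec s2e(n_rg); s2e.fill(vy / 2.0);
  double s2yr = vy / 4.0, s2nb = vy / 10.0;
  arma::mat S3 = arma::eye(3, 3);
  S3(0, 0) = vy / 4.0; S3(1, 1) = 0.05; S3(2, 2) = 0.5;

  arma::vec r = y;
  int njit = 0;
  double step_t = 0.4, step_a = 0.1;
  int acc_t = 0, try_t = 0, acc_a = 0, try_a = 0;

  int n_store = (n_iter - burn) / thin;
  int ncol = p + 1 + 6 + (n_yr > 0 ? 1 : 0) + (n_nb > 0 ? 1 : 0) + n_rg;
  arma::mat store(n_store, ncol);
  int srow = 0;

  arma::vec w(n);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (int i = 0; i < n; ++i) w[i] = 1.0 / s2e[rg[i]];

    if (p > 0) {
      r += X * beta;
      arma::mat Xw = X;
      Xw.each_col() %= w;
      arma::mat M = X.t() * Xw;
      arma::vec v = Xw.t() * r;
      beta = mvn_prec(M, v, &njit);
      r -= X * beta;
    }

    arma::mat S3inv = inv2s(S3);

    // joint (a, b, c) per female: Gaussian records inform (a, b); the
    // latent t = c + e (e fixed variance) informs c
    for (int f = 0; f < n_fem; ++f) {
      double a0 = fe(f, 0), b0v = fe(f, 1);
      double sw = 0, swt = 0, swt2 = 0, d0 = 0, d1 = 0;
      for (int m = by_fem.ptr[f]; m < by_fem.ptr[f + 1]; ++m) {
        int i = by_fem.idx[m];
        double t = tc[i];
        double rs = r[i] + a0 + b0v * t;
        r[i] = rs;
        sw += w[i]; swt += w[i] * t; swt2 += w[i] * t * t;
        d0 += w[i] * rs; d1 += w[i] * t * rs;
      }
      arma::mat P = S3inv;
      arma::vec b(3, arma::fill::zeros);
      P(0, 0) += sw; P(0, 1) += swt; P(1, 0) += swt; P(1, 1) += swt2;
      P(2, 2) += 1.0 / ve_lrs;
      b[0] += d0; b[1] += d1; b[2] += t_lat[f] / ve_lrs;
      arma::vec th(3);
      samp_small(P.memptr(), b.memptr(), 3, th.memptr(), &njit);
      fe(f, 0) = th[0]; fe(f, 1) = th[1]; fe(f, 2) = th[2];
      for (int m = by_fem.ptr[f]; m < by_fem.ptr[f + 1]; ++m) {
        int i = by_fem.idx[m];
        r[i] -= th[0] + th[1] * tc[i];
      }
    }

    // latent LRS log-means: RW Metropolis, then a joint (c, t) shift move
    // using the conditional prior of c given (a, b)
    double q22 = S3inv(2, 2);
    for (int f = 0; f < n_fem; ++f) {
      double c = fe(f, 2), t0 = t_lat[f];
      double lam0 = std::exp(alphaW + t0);
      // move 1: t only
      double t1 = t0 + step_t * R::norm_rand();
      double lam1 = std::exp(alphaW + t1);
      double lr = lrs[f] * (t1 - t0) - (lam1 - lam0) -
        (std::pow(t1 - c, 2) - std::pow(t0 - c, 2)) / (2.0 * ve_lrs);
      ++try_t;
      if (std::log(R::unif_rand()) < lr) { t_lat[f] = t1; ++acc_t; }
      // move 2: shift c and t together; (t - c) unchanged, so only the
      // Poisson likelihood and the conditional prior of c change
      t0 = t_lat[f];
      // conditional mean of c | a,b in precision form: -(Q31 a + Q32 b)/Q33
      double mu_c = -(S3inv(2, 0) * fe(f, 0) + S3inv(2, 1) * fe(f, 1)) / q22;
      double delta = step_t * R::norm_rand();
      double c1 = c + delta, t1b = t0 + delta;
      lam0 = std::exp(alphaW + t0);
      double lam1b = std::exp(alphaW + t1b);
      double lr2 = lrs[f] * delta - (lam1b - lam0) -
        q22 * (std::pow(c1 - mu_c, 2) - std::pow(c - mu_c, 2)) / 2.0;
      if (std::log(R::unif_rand()) < lr2) {
        fe(f, 2) = c1; t_lat[f] = t1b;
      }
    }

    // overall LRS intercept: RW Metropolis
    {
      double sum_elat = 0.0;
      for (int f = 0; f < n_fem; ++f) sum_elat += std::exp(t_lat[f]);
      double da = step_a * R::norm_rand();
      double lr = arma::accu(lrs) * da -
        (std::exp(alphaW + da) - std::exp(alphaW)) * sum_elat;
      ++try_a;
      if (std::log(R::unif_rand()) < lr) { alphaW += da; ++acc_a; }
    }

    // adapt MH steps during burn-in
    if (iter < burn && iter % 50 == 49) {
      double ar_t = try_t ? (double)acc_t / try_t : 0.3;
      double ar_a = try_a ? (double)acc_a / try_a : 0.3;
      step_t *= std::exp(ar_t - 0.35);
      step_a *= std::exp(ar_a - 0.35);
      step_t = std::min(std::max(step_t, 1e-3), 5.0);
      step_a = std::min(std::max(step_a, 1e-3), 5.0);
      acc_t = try_t = acc_a = try_a = 0;
    }

    if (n_yr > 0) {
      for (int j = 0; j < n_yr; ++j) {
        double sw = 0, b = 0;
        for (int m = by_yr.ptr[j]; m < by_yr.ptr[j + 1]; ++m) {
          int i = by_yr.idx[m];
          r[i] += yre[j];
          sw += w[i]; b += w[i] * r[i];
        }
        double prec = 1.0 / s2yr + sw;
        double newv = b / prec + R::norm_rand() / std::sqrt(prec);
        yre[j] = newv;
        for (int m = by_yr.ptr[j]; m < by_yr.ptr[j + 1]; ++m)
          r[by_yr.idx[m]] -= newv;
      }
      double ss = arma::dot(yre.head(n_yr), yre.head(n_yr));
      s2yr = rinvgamma(a_sc + n_yr / 2.0, b_sc + ss / 2.0);
    }
    if (n_nb > 0) {
      for (int j = 0; j < n_nb; ++j) {
        double sw = 0, b = 0;
        for (int m = by_nb.ptr[j]; m < by_nb.ptr[j + 1]; ++m) {
          int i = by_nb.idx[m];
          r[i] += nbe[j];
          sw += w[i]; b += w[i] * r[i];
        }
        double prec = 1.0 / s2nb + sw;
        double newv = b / prec + R::norm_rand() / std::sqrt(prec);
        nbe[j] = newv;
        for (int m = by_nb.ptr[j]; m < by_nb.ptr[j + 1]; ++m)
          r[by_nb.idx[m]] -= newv;
      }
      double ss = arma::dot(nbe.head(n_nb), nbe.head(n_nb));
      s2nb = rinvgamma(a_sc + n_nb / 2.0, b_sc + ss / 2.0);
    }

    {
      arma::mat S = fe.t() * fe;
      S3 = riwish(nu3 + n_fem, V3 + S);
    }
    for (int l = 0; l < n_rg; ++l) {
      double ss = 0;
      int nl = by_rg.ptr[l + 1] - by_rg.ptr[l];
      for (int m = by_rg.ptr[l]; m < by_rg.ptr[l + 1]; ++m) {
        double ri = r[by_rg.idx[m]];
        ss += ri * ri;
      }
      s2e[l] = rinvgamma(a_sc + nl / 2.0, b_sc + ss / 2.0);
    }

    if (!r.is_finite() || !t_lat.is_finite())
      stop("sampler diverged (non-finite state) at iteration %d", iter + 1);

    if (iter >= burn && (iter - burn) % thin == 0 && srow < n_store) {
      int c = 0;
      for (int j = 0; j < p; ++j) store(srow, c++) = beta[j];
      store(srow, c++) = alphaW;
      store(srow, c++) = S3(0, 0); store(srow, c++) = S3(0, 1);
      store(srow, c++) = S3(1, 1); store(srow, c++) = S3(0, 2);
      store(srow, c++) = S3(1, 2); store(srow, c++) = S3(2, 2);
      if (n_yr > 0) store(srow, c++) = s2yr;
      if (n_nb > 0) store(srow, c++) = s2nb;
      for (int l = 0; l < n_rg; ++l) store(srow, c++) = s2e[l];
      ++srow;
    }
  }

  return List::create(_["samples"] = store.rows(0, srow - 1),
                      _["n_jitter"] = njit,
                      _["mh_steps"] = NumericVector::create(step_t, step_a));
}
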