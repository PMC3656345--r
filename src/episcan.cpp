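// Logistic-regression engine for SNP x SNP dosage-interaction scans.
//
// The permutation min-p null re-fits every pairwise interaction model in
// every label-permutation replicate (millions of fits per calibration run).
// The designs are small (intercept + 2 dosages + product + a handful of
// covariates), so BLAS/LAPACK call overhead dominates any library-based IRLS;
// the Newton/IRLS loop below is therefore hand-rolled and allocation-free:
// one fused pass accumulates the score and the weighted information, a
// dense Cholesky factorizes it, and the same workspace is reused across all
// fits of a scan.  Standard errors come from the inverse observed
// information at the optimum (for the logistic likelihood the observed
// information equals X'WX).

#include <RcppArmadillo.h>
#include <vector>
#include <cmath>
#include <cstring>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::mat;
using arma::vec;
using arma::uvec;
using arma::uword;

static const int ST_OK = 0;
static const int ST_NON_CONVERGED = 1;
static const int ST_COLLINEAR = 2;

struct FitInfo {
  double loglik;
  int iterations;
  int status;
};

// exp(-a) for a >= 0, accurate to ~1e-14 relative: range-reduce by log 2,
// degree-12 Taylor on |r| <= log(2)/2, scale by 2^-k via exponent bits.
__attribute__((always_inline)) static inline double exp_neg(double a) {
  a = a < 745.0 ? a : 745.0;                      // clamp: exp(-745) ~ 5e-324
  double t = a * 1.4426950408889634074;           // a / ln 2
  double k = std::floor(t + 0.5);
  double r = -a + k * 0.6931471803691238164;      // -(a - k ln2), hi part
  r += k * 1.9082149292705877e-10;                // lo part of ln 2
  // Estrin evaluation of the degree-11 Taylor polynomial on |r| <= ln2/2
  double r2 = r * r, r4 = r2 * r2;
  double q0 = (1.0 + r) + r2 * (0.5 + r * (1.0 / 6.0));
  double q1 = (1.0 / 24.0 + r * (1.0 / 120.0)) +
              r2 * (1.0 / 720.0 + r * (1.0 / 5040.0));
  double q2 = (1.0 / 40320.0 + r * (1.0 / 362880.0)) +
              r2 * (1.0 / 3628800.0 + r * (1.0 / 39916800.0));
  double p = q0 + r4 * (q1 + r4 * q2);
  // multiply by 2^-k via the exponent bits
  int64_t bits;
  std::memcpy(&bits, &p, 8);
  bits -= (int64_t)k << 52;
  std::memcpy(&p, &bits, 8);
  return p;
}

// log(1 + z) for z in [0, 1], accurate to ~1e-13: atanh series in
// s = z / (2 + z) <= 1/3, odd powers through s^21.
__attribute__((always_inline)) static inline double log1p_unit(double z) {
  double s = z / (2.0 + z);
  double s2 = s * s, s4 = s2 * s2;
  double q0 = 1.0 + s2 * (1.0 / 3.0);
  double q1 = (1.0 / 5.0) + s2 * (1.0 / 7.0);
  double q2 = (1.0 / 9.0) + s2 * (1.0 / 11.0);
  double q3 = (1.0 / 13.0) + s2 * (1.0 / 15.0);
  double q4 = (1.0 / 17.0) + s2 * (1.0 / 19.0);
  double p = q0 + s4 * (q1 + s4 * (q2 + s4 * (q3 + s4 * (q4 + s4 * (1.0 / 21.0)))));
  return 2.0 * s * p;
}

// Workspace for IRLS fits with n rows and p columns (column-major X).
struct Irls {
  int n = 0, p = 0;
  std::vector<double> X;                   // n * p, column-major
  std::vector<double> eta, resid, w;       // length n
  std::vector<double> beta, beta_new, delta, score;  // length p
  std::vector<double> A, L;                // p * p; info matrix and Cholesky

  void resize(int n_, int p_) {
    n = n_; p = p_;
    X.assign((size_t)n * p, 0.0);
    eta.assign(n, 0.0); resid.assign(n, 0.0); w.assign(n, 0.0);
    beta.assign(p, 0.0); beta_new.assign(p, 0.0);
    delta.assign(p, 0.0); score.assign(p, 0.0);
    A.assign((size_t)p * p, 0.0); L.assign((size_t)p * p, 0.0);
  }
  double* col(int j) { return X.data() + (size_t)j * n; }
  const double* col(int j) const { return X.data() + (size_t)j * n; }

  // eta_i = sum_j X_ij beta_j for the supplied coefficients
  void compute_eta(const double* b) {
    std::fill(eta.begin(), eta.end(), 0.0);
    for (int j = 0; j < p; ++j) {
      const double bj = b[j];
      if (bj == 0.0) continue;
      const double* xj = col(j);
      for (int i = 0; i < n; ++i) eta[i] += bj * xj[i];
    }
  }

  double eta_pass(const double* y);

  void accumulate();

  // Cholesky A = L L' (A upper-triangular by column as filled above);
  // returns false when a pivot collapses (rank deficiency)
  bool cholesky() {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) dmax = std::max(dmax, A[(size_t)j * p + j]);
    const double tol = 1e-8 * std::sqrt(dmax);
    for (int j = 0; j < p; ++j) {
      double d = A[(size_t)j * p + j];
      for (int k = 0; k < j; ++k) {
        double ljk = L[(size_t)k * p + j];
        d -= ljk * ljk;
      }
      if (!(d > 0.0) || std::sqrt(d) < tol) return false;
      double lj = std::sqrt(d);
      L[(size_t)j * p + j] = lj;
      for (int i = j + 1; i < p; ++i) {
        double s = A[(size_t)j * p + i];  // A upper: entry (j, i), j < i
        for (int k = 0; k < j; ++k)
          s -= L[(size_t)k * p + i] * L[(size_t)k * p + j];
        L[(size_t)j * p + i] = s / lj;
      }
    }
    return true;
  }

  // solve L L' x = b (in place on x)
  void chol_solve(const double* b, double* x) const {
    for (int i = 0; i < p; ++i) {
      double s = b[i];
      for (int k = 0; k < i; ++k) s -= L[(size_t)k * p + i] * x[k];
      x[i] = s / L[(size_t)i * p + i];
    }
    for (int i = p - 1; i >= 0; --i) {
      double s = x[i];
      for (int k = i + 1; k < p; ++k) s -= L[(size_t)i * p + k] * x[k];
      x[i] = s / L[(size_t)i * p + i];
    }
  }

  // (A^-1)[jj] via one basis-vector solve against the current Cholesky
  double inv_diag(int j) const {
    std::vector<double> e(p, 0.0), v(p);
    e[j] = 1.0;
    chol_solve(e.data(), v.data());
    return v[j];
  }
};

// Hot loops as runtime-dispatched multi-versioned functions: an AVX2+FMA
// clone is picked on capable CPUs, with a portable baseline otherwise.
// The elementwise pass is branch-light so the vector clone actually
// vectorizes (libm exp/log1p would block that; hence the polynomials above).
__attribute__((target_clones("default", "arch=haswell")))
double Irls::eta_pass(const double* y) {
  double ll = 0.0;
  const double* e = eta.data();
  double* rp = resid.data();
  double* wp = w.data();
  #pragma omp simd reduction(+:ll)
  for (int i = 0; i < n; ++i) {
    double ee = e[i];
    double a = std::abs(ee);
    double ex = exp_neg(a);            // exp(-|eta|) in (0, 1]
    double inv = 1.0 / (1.0 + ex);
    double mu = (ee >= 0) ? inv : ex * inv;
    double lse = (ee > 0 ? ee : 0.0) + log1p_unit(ex);
    ll += y[i] * ee - lse;
    rp[i] = y[i] - mu;
    wp[i] = mu * (1.0 - mu);
  }
  return ll;
}

__attribute__((target_clones("default", "arch=haswell")))
void Irls::accumulate() {
  // score = X'resid and A(upper) = X'WX as contiguous column dot products
  const double* rp = resid.data();
  const double* wp = w.data();
  for (int j = 0; j < p; ++j) {
    const double* xj = col(j);
    double sj = 0.0;
    #pragma omp simd reduction(+:sj)
    for (int i = 0; i < n; ++i) sj += rp[i] * xj[i];
    score[j] = sj;
    for (int k = j; k < p; ++k) {
      const double* xk = col(k);
      double a = 0.0;
      #pragma omp simd reduction(+:a)
      for (int i = 0; i < n; ++i) a += wp[i] * xj[i] * xk[i];
      A[(size_t)j * p + k] = a;
    }
  }
}

// Precomputed IRLS starting state: eta, resid, w and the log-likelihood at
// a given coefficient vector.  In a scan every pair shares the warm start
// (its eta has no SNP contribution), so this is built once per outcome
// vector instead of once per pair.
struct StartState {
  std::vector<double> beta, eta, resid, w;
  double ll = 0.0;
  bool valid = false;
};

// Newton/IRLS; `start` NULL => zero start.  On success beta and the
// Cholesky of the final information are left in the workspace.
static FitInfo irls_core(Irls& w, const double* y, const double* start,
                         int maxit, double tol_score, double tol_ll,
                         double beta_bound, const StartState* ss = nullptr) {
  FitInfo info{0.0, 0, ST_NON_CONVERGED};
  const int p = w.p;
  double ll;
  if (ss && ss->valid) {
    w.beta = ss->beta;
    w.eta = ss->eta;
    w.resid = ss->resid;
    w.w = ss->w;
    ll = ss->ll;
  } else {
    if (start) std::copy(start, start + p, w.beta.begin());
    else std::fill(w.beta.begin(), w.beta.end(), 0.0);
    w.compute_eta(w.beta.data());
    ll = w.eta_pass(y);
  }

  for (int it = 1; it <= maxit; ++it) {
    info.iterations = it;
    w.accumulate();
    if (!w.cholesky()) {
      info.status = (it == 1) ? ST_COLLINEAR : ST_NON_CONVERGED;
      info.loglik = ll;
      return info;
    }
    double smax = 0.0;
    for (int j = 0; j < p; ++j) smax = std::max(smax, std::abs(w.score[j]));
    if (smax < tol_score) {
      // information already factorized at the final beta
      info.status = ST_OK;
      info.loglik = ll;
      return info;
    }

    w.chol_solve(w.score.data(), w.delta.data());

    // step-halving; the accepted evaluation also refreshes resid and w
    double step = 1.0, ll_new = ll;
    for (int h = 0; h < 6; ++h) {
      for (int j = 0; j < p; ++j) w.beta_new[j] = w.beta[j] + step * w.delta[j];
      w.compute_eta(w.beta_new.data());
      ll_new = w.eta_pass(y);
      if (ll_new >= ll - 1e-12) break;
      step *= 0.5;
    }
    std::swap(w.beta, w.beta_new);

    // coefficient divergence signals (quasi-)complete separation
    double bmax = 0.0;
    for (int j = 0; j < p; ++j) bmax = std::max(bmax, std::abs(w.beta[j]));
    if (bmax > beta_bound) {
      info.status = ST_NON_CONVERGED;
      info.loglik = ll_new;
      return info;
    }

    double rel = std::abs(ll_new - ll) / (std::abs(ll) + 1e-300);
    ll = ll_new;
    if (rel < tol_ll) { info.status = ST_OK; break; }
  }
  info.loglik = ll;
  if (info.status == ST_OK) {
    // refresh information (and its Cholesky) at the final beta
    w.accumulate();
    if (!w.cholesky()) info.status = ST_NON_CONVERGED;
  }
  return info;
}

// [[Rcpp::export]]
Rcpp::List cpp_logistic_fit(const arma::mat& X, const arma::vec& y,
                            int maxit = 50, double tol_score = 1e-8,
                            double tol_ll = 1e-10, double beta_bound = 15.0,
                            Rcpp::Nullable<Rcpp::NumericVector> start = R_NilValue) {
  const int n = X.n_rows, p = X.n_cols;
  if (p > 64) Rcpp::stop("designs with more than 64 columns are not supported");
  Irls w;
  w.resize(n, p);
  std::copy(X.memptr(), X.memptr() + (size_t)n * p, w.X.begin());
  std::vector<double> st;
  const double* stp = nullptr;
  if (start.isNotNull()) {
    Rcpp::NumericVector sv(start.get());
    st.assign(sv.begin(), sv.end());
    if ((int)st.size() == p) stp = st.data();
  }
  FitInfo info = irls_core(w, y.memptr(), stp, maxit, tol_score, tol_ll,
                           beta_bound);
  vec beta(p), se(p, arma::fill::value(NA_REAL));
  mat cov(p, p, arma::fill::value(NA_REAL));
  std::copy(w.beta.begin(), w.beta.end(), beta.memptr());
  if (info.status == ST_OK) {
    // full covariance: solve against each basis vector
    std::vector<double> e(p, 0.0), v(p);
    for (int j = 0; j < p; ++j) {
      std::fill(e.begin(), e.end(), 0.0);
      e[j] = 1.0;
      w.chol_solve(e.data(), v.data());
      for (int i = 0; i < p; ++i) cov(i, j) = v[i];
    }
    cov = 0.5 * (cov + cov.t());  // exact symmetry
    se = arma::sqrt(cov.diag());
  } else if (info.status == ST_COLLINEAR) {
    beta.fill(NA_REAL);
  }
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = beta,
      Rcpp::Named("se") = se,
      Rcpp::Named("vcov") = cov,
      Rcpp::Named("loglik") = info.loglik,
      Rcpp::Named("iterations") = info.iterations,
      Rcpp::Named("status") = info.status);
}

// Fill the pair-specific design columns [1]=dA, [2]=dB, [3]=dA*dB of a
// workspace whose columns [0]=1 and [4..]=covariates are already set.
static void fill_pair_columns(Irls& w, const double* a, const double* b) {
  double* c1 = w.col(1);
  double* c2 = w.col(2);
  double* c3 = w.col(3);
  for (int i = 0; i < w.n; ++i) {
    c1[i] = a[i];
    c2[i] = b[i];
    c3[i] = a[i] * b[i];
  }
}

// One interaction-pair fit; writes {beta3, se3, z, status, n} into out.
static void interaction_pair(Irls& w, const double* dA, const double* dB,
                             const mat& C, const vec& y,
                             const StartState& ss, double* out) {
  const int n = y.n_elem;
  const int p = 4 + C.n_cols;
  bool any_na = false;
  for (int i = 0; i < n; ++i) {
    if (!std::isfinite(dA[i]) || !std::isfinite(dB[i])) { any_na = true; break; }
  }

  if (!any_na) {
    out[4] = n;
    fill_pair_columns(w, dA, dB);
    FitInfo f = irls_core(w, y.memptr(), nullptr, 50, 1e-8, 1e-10, 15.0, &ss);
    if (f.status == ST_OK) {
      out[0] = w.beta[3];
      out[1] = std::sqrt(w.inv_diag(3));
      out[2] = out[0] / out[1];
      out[3] = ST_OK;
    } else {
      out[0] = out[1] = out[2] = NA_REAL;
      out[3] = f.status;
    }
    return;
  }

  // pairwise-complete subset for this pair
  std::vector<int> idx;
  idx.reserve(n);
  for (int i = 0; i < n; ++i)
    if (std::isfinite(dA[i]) && std::isfinite(dB[i])) idx.push_back(i);
  const int m = idx.size();
  out[4] = m;
  if (m < p + 1) { out[0] = out[1] = out[2] = NA_REAL; out[3] = ST_NON_CONVERGED; return; }
  std::vector<double> yy(m);
  double ys = 0.0;
  for (int i = 0; i < m; ++i) { yy[i] = y[idx[i]]; ys += yy[i]; }
  if (ys == 0.0 || ys == m) { out[0] = out[1] = out[2] = NA_REAL; out[3] = ST_NON_CONVERGED; return; }

  Irls ws;
  ws.resize(m, p);
  for (int i = 0; i < m; ++i) {
    ws.col(0)[i] = 1.0;
    ws.col(1)[i] = dA[idx[i]];
    ws.col(2)[i] = dB[idx[i]];
    ws.col(3)[i] = dA[idx[i]] * dB[idx[i]];
    for (uword j = 0; j < C.n_cols; ++j) ws.col(4 + j)[i] = C(idx[i], j);
  }
  FitInfo f = irls_core(ws, yy.data(), nullptr, 50, 1e-8, 1e-10, 15.0);
  if (f.status == ST_OK) {
    out[0] = ws.beta[3];
    out[1] = std::sqrt(ws.inv_diag(3));
    out[2] = out[0] / out[1];
    out[3] = ST_OK;
  } else {
    out[0] = out[1] = out[2] = NA_REAL;
    out[3] = f.status;
  }
}

// Warm start: covariates-only fit [1, C] embedded into the interaction
// coordinate order [1, dA, dB, dA*dB, C], with eta / resid / w / loglik
// precomputed once (the SNP columns contribute nothing at the start point).
static StartState covariate_warm_start(Irls& w, const mat& C, const vec& y) {
  const int n = y.n_elem;
  Irls w0;
  w0.resize(n, 1 + C.n_cols);
  for (int i = 0; i < n; ++i) w0.col(0)[i] = 1.0;
  for (uword j = 0; j < C.n_cols; ++j)
    std::copy(C.colptr(j), C.colptr(j) + n, w0.col(1 + j));
  FitInfo f0 = irls_core(w0, y.memptr(), nullptr, 25, 1e-8, 1e-10, 15.0);
  StartState ss;
  ss.beta.assign(4 + C.n_cols, 0.0);
  if (f0.status == ST_OK) {
    ss.beta[0] = w0.beta[0];
    for (uword j = 0; j < C.n_cols; ++j) ss.beta[4 + j] = w0.beta[1 + j];
  }
  w.beta = ss.beta;
  w.compute_eta(w.beta.data());
  ss.ll = w.eta_pass(y.memptr());
  ss.eta = w.eta;
  ss.resid = w.resid;
  ss.w = w.w;
  ss.valid = true;
  return ss;
}

static Irls make_scan_workspace(const mat& C, int n) {
  const int p = 4 + C.n_cols;
  Irls w;
  w.resize(n, p);
  for (int i = 0; i < n; ++i) w.col(0)[i] = 1.0;
  for (uword j = 0; j < C.n_cols; ++j)
    std::copy(C.colptr(j), C.colptr(j) + n, w.col(4 + j));
  return w;
}

// All pairs between columns of DA (index gene) and DB (partner SNPs).
// Row order: index SNP outer loop, partner SNP inner loop.
// Columns: beta3, se3, z, status, n.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_scan_pairs(const arma::mat& DA, const arma::mat& DB,
                                   const arma::mat& C, const arma::vec& y) {
  const uword pA = DA.n_cols, pB = DB.n_cols, n = DA.n_rows;
  if (4 + C.n_cols > 64) Rcpp::stop("too many covariate columns");
  Rcpp::NumericMatrix out(pA * pB, 5);
  Irls w = make_scan_workspace(C, n);
  StartState ss = covariate_warm_start(w, C, y);
  double buf[5];
  uword r = 0;
  for (uword a = 0; a < pA; ++a) {
    for (uword b = 0; b < pB; ++b, ++r) {
      interaction_pair(w, DA.colptr(a), DB.colptr(b), C, y, ss, buf);
      for (int k = 0; k < 5; ++k) out(r, k) = buf[k];
    }
  }
  colnames(out) = Rcpp::CharacterVector::create("beta3", "se3", "z", "status", "n");
  return out;
}

// Permutation null: for each column of Yperm (one permuted label vector per
// replicate) rescan all pairs and record the per-partner-gene minimum
// two-sided Wald p over OK pairs.  gene_index maps DB columns to 1..G.
// Returns a B x (G + 1) matrix: per-gene minima then the count of OK tests.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_null_min_p(const arma::mat& DA, const arma::mat& DB,
                                   const arma::ivec& gene_index,
                                   const arma::mat& C, const arma::mat& Yperm) {
  const uword pA = DA.n_cols, pB = DB.n_cols, B = Yperm.n_cols, n = DA.n_rows;
  if (4 + C.n_cols > 64) Rcpp::stop("too many covariate columns");
  const int G = gene_index.max();
  Rcpp::NumericMatrix out(B, G + 1);
  Irls w = make_scan_workspace(C, n);
  double buf[5];
  for (uword b = 0; b < B; ++b) {
    vec y = Yperm.col(b);
    StartState ss = covariate_warm_start(w, C, y);
    std::vector<double> max_abs_z(G, -1.0);
    int n_ok = 0;
    for (uword a = 0; a < pA; ++a) {
      for (uword j = 0; j < pB; ++j) {
        interaction_pair(w, DA.colptr(a), DB.colptr(j), C, y, ss, buf);
        if (buf[3] == ST_OK) {
          ++n_ok;
          int g = gene_index[j] - 1;
          double az = std::abs(buf[2]);
          if (az > max_abs_z[g]) max_abs_z[g] = az;
        }
      }
    }
    for (int g = 0; g < G; ++g)
      out(b, g) = (max_abs_z[g] >= 0)
        ? 2.0 * R::pnorm(-max_abs_z[g], 0.0, 1.0, 1, 0) : NA_REAL;
    out(b, G) = n_ok;
    if (b % 8 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
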