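// Gaussian integrated-information (Phi*) engine.
//
// Conventions: Sx = Cov(X(t-tau)), Sy = Cov(X(t)), Sxy = Cov(X(t-tau), X(t)),
// all n x n; the mismatched decoder of a partition predicts each block of the
// present from the same block of the past only.  All information quantities
// are in nats.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double logdet_sym(const mat& M, const char* what) {
  double val, sign;
  log_det(val, sign, M);
  if (!std::isfinite(val) || sign <= 0.0)
    Rcpp::stop("non-positive-definite %s; increase the ridge", what);
  return val;
}

static mat inv_block(const mat& M, const char* what) {
  mat out;
  if (!inv_sympd(out, symmatu(M)))
    Rcpp::stop("singular %s; increase the ridge", what);
  return out;
}

// Mutual information I(X(t-tau); X(t)) = 1/2 log |Sx||Sy|/|J|.
static double mi_gauss(const mat& Sx, const mat& Sy, const mat& Sxy) {
  const uword n = Sx.n_rows;
  mat J(2 * n, 2 * n);
  J.submat(0, 0, n - 1, n - 1) = Sx;
  J.submat(0, n, n - 1, 2 * n - 1) = Sxy;
  J.submat(n, 0, 2 * n - 1, n - 1) = Sxy.t();
  J.submat(n, n, 2 * n - 1, 2 * n - 1) = Sy;
  double ldJ = logdet_sym(symmatu(J), "joint covariance");
  double ldX = logdet_sym(symmatu(Sx), "past covariance");
  double ldY = logdet_sym(symmatu(Sy), "present covariance");
  return 0.5 * (ldX + ldY - ldJ);
}

// Per-partition constants of I~(beta).  With the block-restricted decoder
// q(y|x) = prod_k N(y_k; H_k x_k, D_k), H block-diagonal, Q = D^-1:
//   I~(beta) = -(beta/2) tr(QR) + (beta/2) tr(Q Sy)
//            + (1/2) log|I + beta Sx K| - (beta^2/2) tr(M^-1 W),
// where R = Cov(y - Hx), K = H'QH, W = H'Q Sy Q H, M = Sx^-1 + beta K.
// With Sx = R0'R0 (Cholesky) and the eigendecomposition U L U' of
// C = R0 K R0', both beta-dependent terms reduce to sums over the
// eigenvalues l_i of C (d_i = diag(U' R0 W R0' U)):
//   log|I + beta Sx K| = sum log(1 + beta l_i),
//   tr(M^-1 W)         = sum d_i / (1 + beta l_i),
// so one I~(beta) evaluation is O(n) after an O(n^3) setup.
struct PartCtx {
  double trQR, trQSy;
  vec lambda, d;
};

static PartCtx make_ctx(const mat& Sx, const mat& Sy, const mat& Sxy,
                        const std::vector<uvec>& blocks) {
  const uword n = Sx.n_rows;
  mat Syx = Sxy.t();
  mat H(n, n, fill::zeros), Q(n, n, fill::zeros);
  for (const uvec& b : blocks) {
    mat Sxb_inv = inv_block(Sx(b, b), "past block covariance");
    mat Hb = Syx(b, b) * Sxb_inv;
    H(b, b) = Hb;
    mat Db = Sy(b, b) - Hb * Sxy(b, b);
    Q(b, b) = inv_block(Db, "conditional block covariance");
  }
  PartCtx ctx;
  mat R = Sy - H * Sxy - Syx * H.t() + H * Sx * H.t();
  ctx.trQR = trace(Q * R);
  ctx.trQSy = trace(Q * Sy);
  mat HQ = H.t() * Q;
  mat K = HQ * H;
  mat W = HQ * Sy * Q * H;
  mat R0;
  if (!chol(R0, symmatu(Sx)))
    Rcpp::stop("non-positive-definite past covariance; increase the ridge");
  mat C = R0 * K * R0.t();
  mat U;
  vec l;
  if (!eig_sym(l, U, symmatu(C)))
    Rcpp::stop("eigendecomposition failed in I~(beta) setup");
  ctx.lambda = l;
  mat Wt = R0 * W * R0.t();
  ctx.d = diagvec(U.t() * Wt * U);
  return ctx;
}

static double itilde_ctx(const PartCtx& ctx, double beta) {
  double ld = 0.0, tr2 = 0.0;
  for (uword i = 0; i < ctx.lambda.n_elem; ++i) {
    double den = 1.0 + beta * ctx.lambda(i);
    if (den <= 0.0) return -datum::inf;
    ld += std::log(den);
    tr2 += ctx.d(i) / den;
  }
  return -0.5 * beta * ctx.trQR + 0.5 * beta * ctx.trQSy + 0.5 * ld -
         0.5 * beta * beta * tr2;
}

// Golden-section maximisation of I~(beta) on [lo, hi].
static void maximise_itilde(const PartCtx& ctx, double lo, double hi,
                            double tol, double& ibest, double& bbest) {
  const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = itilde_ctx(ctx, c), fd = itilde_ctx(ctx, d);
  while (b - a > tol) {
    if (fc > fd) {
      b = d; d = c; fd = fc;
      c = b - gr * (b - a);
      fc = itilde_ctx(ctx, c);
    } else {
      a = c; c = d; fc = fd;
      d = a + gr * (b - a);
      fd = itilde_ctx(ctx, d);
    }
  }
  if (fc > fd) { ibest = fc; bbest = c; } else { ibest = fd; bbest = d; }
  // guard against a maximum sitting on the upper bracket edge
  double fhi = itilde_ctx(ctx, hi);
  if (fhi > ibest) { ibest = fhi; bbest = hi; }
  if (!std::isfinite(ibest))
    Rcpp::stop("beta optimisation failed to find a finite I~(beta)");
}

// Unordered bipartitions of local nodes 0..k-1: node 0 always in block A;
// mask m in 1..2^(k-1)-1 puts node j (1-based bit j-1) in block B.
static void mask_blocks(unsigned int m, uword k, uvec& a, uvec& b) {
  std::vector<uword> va, vb;
  va.push_back(0);
  for (uword j = 1; j < k; ++j) {
    if (m & (1u << (j - 1))) vb.push_back(j); else va.push_back(j);
  }
  a = uvec(va); b = uvec(vb);
}

// [[Rcpp::export]]
double cpp_mutual_information(const arma::mat& Sx, const arma::mat& Sy,
                              const arma::mat& Sxy) {
  return mi_gauss(Sx, Sy, Sxy);
}

// blocks: list of 1-based index vectors forming a partition of 1..n
// [[Rcpp::export]]
double cpp_itilde(const arma::mat& Sx, const arma::mat& Sy,
                  const arma::mat& Sxy, const Rcpp::List& blocks,
                  double beta) {
  std::vector<uvec> bl;
  for (R_xlen_t i = 0; i < blocks.size(); ++i) {
    uvec b = Rcpp::as<uvec>(blocks[i]);
    bl.push_back(b - 1);
  }
  PartCtx ctx = make_ctx(Sx, Sy, Sxy, bl);
  return itilde_ctx(ctx, beta);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_phi_partition(const arma::mat& Sx, const arma::mat& Sy,
                                      const arma::mat& Sxy,
                                      const Rcpp::List& blocks,
                                      double beta_max, double tol) {
  std::vector<uvec> bl;
  for (R_xlen_t i = 0; i < blocks.size(); ++i) {
    uvec b = Rcpp::as<uvec>(blocks[i]);
    bl.push_back(b - 1);
  }
  PartCtx ctx = make_ctx(Sx, Sy, Sxy, bl);
  double ib, bb;
  maximise_itilde(ctx, 1e-6, beta_max, tol, ib, bb);
  double mi = mi_gauss(Sx, Sy, Sxy);
  return Rcpp::NumericVector::create(
      Rcpp::Named("phi") = mi - ib, Rcpp::Named("beta_opt") = bb,
      Rcpp::Named("itilde") = ib, Rcpp::Named("mutual_info") = mi);
}

// Phi* for every unordered bipartition, enumeration order = ascending mask.
// Returns (2^(n-1)-1) x 2 matrix: phi, beta_opt.
// [[Rcpp::export]]
arma::mat cpp_mip_all(const arma::mat& Sx, const arma::mat& Sy,
                      const arma::mat& Sxy, double beta_max, double tol) {
  const uword n = Sx.n_rows;
  if (n < 2) Rcpp::stop("need at least 2 nodes for a bipartition");
  const unsigned int npart = (1u << (n - 1)) - 1u;
  mat out(npart, 2);
  double mi = mi_gauss(Sx, Sy, Sxy);
  for (unsigned int m = 1; m <= npart; ++m) {
    uvec a, b;
    mask_blocks(m, n, a, b);
    std::vector<uvec> bl{a, b};
    PartCtx ctx = make_ctx(Sx, Sy, Sxy, bl);
    double ib, bb;
    maximise_itilde(ctx, 1e-6, beta_max, tol, ib, bb);
    out(m - 1, 0) = mi - ib;
    out(m - 1, 1) = bb;
  }
  return out;
}

// MIP search over each subset in `subsets` (list of 1-based index vectors,
// each of size >= 2).  Returns nsub x 4 matrix: phi_mip, local mip mask,
// beta_opt, mutual information of the restricted model.
// [[Rcpp::export]]
arma::mat cpp_subset_report(const arma::mat& Sx, const arma::mat& Sy,
                            const arma::mat& Sxy, const Rcpp::List& subsets,
                            double beta_max, double tol) {
  const R_xlen_t nsub = subsets.size();
  mat out(nsub, 4);
  for (R_xlen_t s = 0; s < nsub; ++s) {
    uvec idx = Rcpp::as<uvec>(subsets[s]) - 1;
    const uword k = idx.n_elem;
    if (k < 2) Rcpp::stop("subsets must have at least 2 nodes");
    mat sSx = Sx(idx, idx), sSy = Sy(idx, idx), sSxy = Sxy(idx, idx);
    double mi = mi_gauss(sSx, sSy, sSxy);
    const unsigned int npart = (1u << (k - 1)) - 1u;
    double best_phi = datum::inf, best_beta = NA_REAL;
    unsigned int best_mask = 0;
    for (unsigned int m = 1; m <= npart; ++m) {
      uvec a, b;
      mask_blocks(m, k, a, b);
      std::vector<uvec> bl{a, b};
      PartCtx ctx = make_ctx(sSx, sSy, sSxy, bl);
      double ib, bb;
      maximise_itilde(ctx, 1e-6, beta_max, tol, ib, bb);
      double phi = mi - ib;
      if (phi < best_phi) {
        best_phi = phi; best_beta = bb; best_mask = m;
      }
    }
    out(s, 0) = best_phi;
    out(s, 1) = best_mask;
    out(s, 2) = best_beta;
    out(s, 3) = mi;
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// VAR(1) recursion x_t = A x_{t-1} + eps_t; eps is T x n (already correlated),
// x0 the state preceding the first row.  Returns T x n.
// [[Rcpp::export]]
arma::mat cpp_var_simulate(const arma::mat& A, const arma::mat& eps,
                           const arma::vec& x0) {
  const uword T = eps.n_rows, n = eps.n_cols;
  mat X(T, n);
  vec x = x0;
  for (uword t = 0; t < T; ++t) {
    x = A * x + eps.row(t).t();
    X.row(t) = x.t();
  }
  return X;
}
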