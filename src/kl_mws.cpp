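// Minibatch-weighted-sampling estimator of the KL decomposition
//   KL(q(z|x) || p(z)) = MI + TC + dimension-wise KL
// over the aggregated posterior of a batch, with the stratified weighting that
// assigns probability 1/N to a sample's own posterior component and
// (N-1)/(N*(M-1)) to every other component (N = dataset size, M = batch size).
// Forward returns the three scalar terms; backward returns analytic gradients
// with respect to the samples z and the posterior parameters (mu, logvar).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

// log-sum-exp over each row
static vec row_lse(const mat& A) {
  vec m = max(A, 1);
  return m + log(sum(exp(A.each_col() - m), 1));
}

static mat weight_mat(int M, double N) {
  double off = (M > 1) ? std::log((N - 1.0) / (N * (M - 1.0))) : -std::log(N);
  mat W(M, M);
  W.fill(off);
  W.diag().fill(-std::log(N));
  return W;
}

// per-dimension log-density matrix: Ld(i,j) = log Normal(z_id; mu_jd, var_jd)
static mat logdens_dim(const mat& z, const mat& mu, const mat& lv, int d) {
  int M = z.n_rows;
  mat diff = repmat(z.col(d), 1, M) - repmat(mu.col(d).t(), M, 1);
  rowvec ivd = exp(-lv.col(d).t());
  mat Ld = -0.5 * square(diff);
  Ld.each_row() %= ivd;
  Ld.each_row() -= 0.5 * lv.col(d).t();
  Ld -= 0.5 * LOG2PI;
  return Ld;
}

// [[Rcpp::export]]
Rcpp::List kl_mws_forward_cpp(const arma::mat& z, const arma::mat& mu,
                              const arma::mat& lv, double N) {
  int M = z.n_rows, D = z.n_cols;
  mat W = weight_mat(M, N);
  mat Lfull(M, M, fill::zeros);
  vec sumSd(M, fill::zeros);
  for (int d = 0; d < D; ++d) {
    mat Ld = logdens_dim(z, mu, lv, d);
    Lfull += Ld;
    sumSd += row_lse(Ld + W);
  }
  vec S = row_lse(Lfull + W);
  vec diagL = Lfull.diag();
  vec logp = -0.5 * LOG2PI * D - 0.5 * sum(square(z), 1);
  double mi = mean(diagL - S);
  double tc = mean(S - sumSd);
  double dw = mean(sumSd - logp);
  return Rcpp::List::create(Rcpp::Named("mi") = mi, Rcpp::Named("tc") = tc,
                            Rcpp::Named("dwkl") = dw);
}

// Fused forward + gradient pass for training: computes the three terms and
// the gradients of (gmi*mi + gtc*tc + gdw*dwkl) in one sweep over the
// per-dimension log-density matrices. The caller rescales the gradients by
// the (scalar) upstream gradient, which is legal because they are linear in
// (gmi, gtc, gdw).
// [[Rcpp::export]]
Rcpp::List kl_mws_fused_cpp(const arma::mat& z, const arma::mat& mu,
                            const arma::mat& lv, double N, double gmi,
                            double gtc, double gdw) {
  int M = z.n_rows, D = z.n_cols;
  mat W = weight_mat(M, N);

  cube L(M, M, D);
  mat Lfull(M, M, fill::zeros);
  vec sumSd(M, fill::zeros);
  for (int d = 0; d < D; ++d) {
    L.slice(d) = logdens_dim(z, mu, lv, d);
    Lfull += L.slice(d);
  }
  mat LW = Lfull + W;
  vec S = row_lse(LW);
  mat A = exp(LW.each_col() - S);
  vec diagL = Lfull.diag();
  vec logp = -0.5 * LOG2PI * D - 0.5 * sum(square(z), 1);

  double c1 = (gtc - gmi) / M;
  double c2 = (gdw - gtc) / M;
  double cd = gmi / M;

  mat gz(M, D, fill::zeros), gmu(M, D, fill::zeros), glv(M, D, fill::zeros);
  for (int d = 0; d < D; ++d) {
    mat LdW = L.slice(d) + W;
    vec Sd = row_lse(LdW);
    sumSd += Sd;
    mat Ad = exp(LdW.each_col() - Sd);
    mat G = c1 * A + c2 * Ad;
    G.diag() += cd;

    mat diff = repmat(z.col(d), 1, M) - repmat(mu.col(d).t(), M, 1);
    rowvec ivd = exp(-lv.col(d).t());
    mat R = diff.each_row() % ivd;
    mat diff2 = square(diff);
    diff2.each_row() %= ivd;
    mat T = 0.5 * diff2 - 0.5;

    gz.col(d) = -sum(G % R, 1);
    gmu.col(d) = sum(G % R, 0).t();
    glv.col(d) = sum(G % T, 0).t();
  }
  gz += (gdw / M) * z;

  double mi = mean(diagL - S);
  double tc = mean(S - sumSd);
  double dw = mean(sumSd - logp);
  return Rcpp::List::create(Rcpp::Named("mi") = mi, Rcpp::Named("tc") = tc,
                            Rcpp::Named("dwkl") = dw, Rcpp::Named("gz") = gz,
                            Rcpp::Named("gmu") = gmu,
                            Rcpp::Named("glogvar") = glv);
}

// [[Rcpp::export]]
Rcpp::List kl_mws_backward_cpp(const arma::mat& z, const arma::mat& mu,
                               const arma::mat& lv, double N, double gmi,
                               double gtc, double gdw) {
  int M = z.n_rows, D = z.n_cols;
  mat W = weight_mat(M, N);

  cube L(M, M, D);
  mat Lfull(M, M, fill::zeros);
  for (int d = 0; d < D; ++d) {
    L.slice(d) = logdens_dim(z, mu, lv, d);
    Lfull += L.slice(d);
  }
  mat LW = Lfull + W;
  mat A = exp(LW.each_col() - row_lse(LW));  // row-softmax of joint

  double c1 = (gtc - gmi) / M;    // coefficient on the joint logsumexp
  double c2 = (gdw - gtc) / M;    // coefficient on per-dimension logsumexps
  double cd = gmi / M;            // coefficient on log q(z_i | x_i)

  mat gz(M, D, fill::zeros), gmu(M, D, fill::zeros), glv(M, D, fill::zeros);
  for (int d = 0; d < D; ++d) {
    mat LdW = L.slice(d) + W;
    mat Ad = exp(LdW.each_col() - row_lse(LdW));
    mat G = c1 * A + c2 * Ad;
    G.diag() += cd;

    mat diff = repmat(z.col(d), 1, M) - repmat(mu.col(d).t(), M, 1);
    rowvec ivd = exp(-lv.col(d).t());
    mat R = diff.each_row() % ivd;               // d logN / d mu (per pair)
    mat diff2 = square(diff);
    diff2.each_row() %= ivd;
    mat T = 0.5 * diff2 - 0.5;  // d logN / d logvar

    gz.col(d) = -sum(G % R, 1);
    gmu.col(d) = sum(G % R, 0).t();
    glv.col(d) = sum(G % T, 0).t();
  }
  // prior term: d/dz of -gdw/M * sum_i log p(z_i)
  gz += (gdw / M) * z;
  return Rcpp::List::create(Rcpp::Named("gz") = gz, Rcpp::Named("gmu") = gmu,
                            Rcpp::Named("glogvar") = glv);
}
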