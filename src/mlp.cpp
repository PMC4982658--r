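// Small multilayer perceptron (three tanh hidden layers, linear output)
// trained by Levenberg-Marquardt backpropagation with validation-based
// early stopping. Runs the repeated train/validate/test sessions of the
// subset screen entirely in compiled code; randomness is drawn from R's
// RNG so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct Net {
  std::vector<mat> W; // (in+1) x out per layer, bias in last row
  std::vector<int> sizes; // input, hidden..., 1
};

static int n_weights(const std::vector<int>& sizes) {
  int w = 0;
  for (size_t l = 1; l < sizes.size(); ++l)
    w += (sizes[l - 1] + 1) * sizes[l];
  return w;
}

static void init_net(Net& net, const std::vector<int>& sizes) {
  net.sizes = sizes;
  net.W.clear();
  for (size_t l = 1; l < sizes.size(); ++l) {
    mat w(sizes[l - 1] + 1, sizes[l]);
    double sc = 1.0 / std::sqrt((double)sizes[l - 1]);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = R::norm_rand() * sc;
    net.W.push_back(w);
  }
}

static vec flatten(const Net& net) {
  int W = n_weights(net.sizes);
  vec out(W);
  int off = 0;
  for (const mat& w : net.W) {
    std::copy(w.begin(), w.end(), out.begin() + off);
    off += w.n_elem;
  }
  return out;
}

static void unflatten(Net& net, const vec& v) {
  int off = 0;
  for (mat& w : net.W) {
    std::copy(v.begin() + off, v.begin() + off + w.n_elem, w.begin());
    off += w.n_elem;
  }
}

// Forward pass; activations (incl. input) stored in A when keep = true.
static vec forward(const Net& net, const mat& X, std::vector<mat>* A) {
  mat cur = X;
  if (A) { A->clear(); A->push_back(cur); }
  size_t L = net.W.size();
  for (size_t l = 0; l < L; ++l) {
    const mat& w = net.W[l];
    mat z = cur * w.rows(0, w.n_rows - 2);
    z.each_row() += w.row(w.n_rows - 1);
    cur = (l + 1 < L) ? mat(tanh(z)) : z;
    if (A) A->push_back(cur);
  }
  return cur.col(0);
}

// Jacobian of the scalar output w.r.t. all weights, one row per sample.
static mat jacobian(const Net& net, const std::vector<mat>& A) {
  size_t L = net.W.size();
  uword n = A[0].n_rows;
  int W = n_weights(net.sizes);
  mat J(n, W);
  // output sensitivities per layer (d yhat / d z_l)
  std::vector<mat> S(L);
  S[L - 1] = ones<mat>(n, 1);
  for (int l = (int)L - 2; l >= 0; --l) {
    const mat& wnext = net.W[l + 1];
    mat back = S[l + 1] * wnext.rows(0, wnext.n_rows - 2).t();
    S[l] = back % (1.0 - square(A[l + 1]));
  }
  int off = 0;
  for (size_t l = 0; l < L; ++l) {
    int nin = net.sizes[l];
    int nout = net.sizes[l + 1];
    for (int j = 0; j < nout; ++j) {
      for (int i = 0; i <= nin; ++i) {
        if (i < nin) J.col(off++) = A[l].col(i) % S[l].col(j);
        else J.col(off++) = S[l].col(j);
      }
    }
  }
  return J;
}

static double mse_of(const Net& net, const mat& X, const vec& y) {
  vec r = forward(net, X, nullptr) - y;
  return dot(r, r) / y.n_elem;
}

// Levenberg-Marquardt with early stopping on a validation set.
// Returns the validation-best weights in `net`.
static bool train_lm(Net& net, const mat& Xtr, const vec& ytr,
                     const mat& Xval, const vec& yval,
                     int max_epochs, int patience) {
  double mu = 1e-2;
  std::vector<mat> A;
  vec yhat = forward(net, Xtr, &A);
  vec r = yhat - ytr;
  double sse = dot(r, r);
  double best_val = mse_of(net, Xval, yval);
  vec best_w = flatten(net);
  int stall = 0;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    mat J = jacobian(net, A);
    mat H = J.t() * J;
    vec g = J.t() * r;
    bool accepted = false;
    vec w0 = flatten(net);
    for (int tries = 0; tries < 8; ++tries) {
      mat Hm = H;
      Hm.diag() += mu;
      vec step;
      bool ok = solve(step, Hm, g, solve_opts::likely_sympd + solve_opts::no_approx);
      if (ok) {
        unflatten(net, vec(w0 - step));
        vec yh = forward(net, Xtr, &A);
        vec rn = yh - ytr;
        double sse_n = dot(rn, rn);
        if (std::isfinite(sse_n) && sse_n < sse) {
          sse = sse_n; r = rn; mu = std::max(mu * 0.1, 1e-12);
          accepted = true;
          break;
        }
      }
      mu *= 10.0;
      if (mu > 1e12) break;
    }
    if (!accepted) { unflatten(net, w0); forward(net, Xtr, &A); break; }
    double vm = mse_of(net, Xval, yval);
    if (vm < best_val - 1e-12) {
      best_val = vm; best_w = flatten(net); stall = 0;
    } else if (++stall >= patience) break;
  }
  unflatten(net, best_w);
  return std::isfinite(best_val);
}

// Fisher-Yates permutation driven by R's RNG.
static uvec r_permutation(uword n) {
  uvec p = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i > 0; --i) {
    uword j = (uword)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// [[Rcpp::export]]
Rcpp::List mlp_sessions_cpp(const arma::mat& X, const arma::vec& y,
                            int sessions, Rcpp::IntegerVector hidden,
                            int max_epochs, int patience) {
  Rcpp::RNGScope scope;
  uword n = X.n_rows;
  std::vector<int> sizes;
  sizes.push_back((int)X.n_cols);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);

  vec ens = zeros<vec>(n);
  vec sess_mse(sessions, fill::value(datum::nan));
  int ok_sessions = 0, failed = 0;
  uword ntr = (uword)std::round(0.4 * n);
  uword nval = (uword)std::round(0.3 * n);
  if (ntr < 2) ntr = 2;
  if (nval < 1) nval = 1;

  for (int s = 0; s < sessions; ++s) {
    bool done = false;
    for (int attempt = 0; attempt < 2 && !done; ++attempt) {
      uvec perm = r_permutation(n);
      uvec itr = perm.subvec(0, ntr - 1);
      uvec ival = perm.subvec(ntr, ntr + nval - 1);
      Net net;
      init_net(net, sizes);
      bool ok = train_lm(net, X.rows(itr), y(itr), X.rows(ival), y(ival),
                         max_epochs, patience);
      if (ok) {
        vec pred = forward(net, X, nullptr);
        if (pred.is_finite()) {
          ens += pred;
          vec r = pred - y;
          sess_mse[s] = dot(r, r) / n;
          ++ok_sessions;
          done = true;
        }
      }
    }
    if (!done) ++failed;
  }
  if (ok_sessions > 0) ens /= ok_sessions;
  return Rcpp::List::create(
    Rcpp::Named("ensemble") = ens,
    Rcpp::Named("session_mse") = sess_mse,
    Rcpp::Named("n_ok") = ok_sessions,
    Rcpp::Named("n_failed") = failed);
}
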