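// Mini-batch Adam trainer for small fully connected networks.
// Architectures: one or two hidden layers with ReLU/Tanh/Sigmoid
// activations, and either a single sigmoid output unit (binary
// cross-entropy) or a two-unit softmax head (categorical cross-entropy
// over the two perfusion classes). All randomness (Glorot-uniform weight
// init, per-epoch shuffling) flows from one std::mt19937 seeded by the
// caller, so training is deterministic given the seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

enum Act { RELU = 1, TANH = 2, SIGMOID = 3 };

static mat act_forward(const mat& z, int code) {
  switch (code) {
    case RELU: return clamp(z, 0.0, datum::inf);
    case TANH: return tanh(z);
    case SIGMOID: return 1.0 / (1.0 + exp(-z));
    default: Rcpp::stop("unknown activation code");
  }
}

// Derivative of the activation, expressed via pre-activation z and
// activation a (whichever is cheaper).
static mat act_backward(const mat& z, const mat& a, int code) {
  switch (code) {
    case RELU: return conv_to<mat>::from(z > 0.0);
    case TANH: return 1.0 - square(a);
    case SIGMOID: return a % (1.0 - a);
    default: Rcpp::stop("unknown activation code");
  }
}

struct AdamState {
  mat mW, vW;
  rowvec mb, vb;
};

// [[Rcpp::export]]
Rcpp::List ffnn_train_cpp(const arma::mat& X, const arma::vec& y,
                          Rcpp::IntegerVector hidden,
                          Rcpp::IntegerVector act_codes,
                          int head_units, int epochs, int batch_size,
                          double lr, double beta1, double beta2,
                          double adam_eps, int seed) {
  const uword n = X.n_rows;
  const uword d = X.n_cols;
  const int n_hidden = hidden.size();
  if (act_codes.size() != n_hidden)
    Rcpp::stop("one activation code per hidden layer required");
  if (head_units != 1 && head_units != 2)
    Rcpp::stop("head must have 1 (sigmoid) or 2 (softmax) units");

  std::mt19937 rng(static_cast<std::uint32_t>(seed));

  // Layer sizes: input, hidden..., output.
  std::vector<uword> sizes;
  sizes.push_back(d);
  for (int l = 0; l < n_hidden; ++l) sizes.push_back(hidden[l]);
  sizes.push_back(static_cast<uword>(head_units));
  const int L = static_cast<int>(sizes.size()) - 1;  // number of weight layers

  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  std::vector<AdamState> adam(L);
  for (int l = 0; l < L; ++l) {
    const double limit = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
    std::uniform_real_distribution<double> unif(-limit, limit);
    W[l].set_size(sizes[l], sizes[l + 1]);
    for (uword j = 0; j < W[l].n_cols; ++j)
      for (uword i = 0; i < W[l].n_rows; ++i)
        W[l](i, j) = unif(rng);
    b[l] = zeros<rowvec>(sizes[l + 1]);
    adam[l].mW = zeros<mat>(sizes[l], sizes[l + 1]);
    adam[l].vW = zeros<mat>(sizes[l], sizes[l + 1]);
    adam[l].mb = zeros<rowvec>(sizes[l + 1]);
    adam[l].vb = zeros<rowvec>(sizes[l + 1]);
  }

  // One-hot targets for the softmax head (column 1 = class "adequate").
  mat Y;
  if (head_units == 2) {
    Y = zeros<mat>(n, 2);
    for (uword i = 0; i < n; ++i) Y(i, y(i) > 0.5 ? 1 : 0) = 1.0;
  }

  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  vec loss_history(epochs, fill::zeros);
  long t = 0;  // Adam timestep
  const double clip = 1e-12;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    for (uword start = 0; start < n; start += batch_size) {
      const uword stop = std::min(start + static_cast<uword>(batch_size), n);
      const uword m = stop - start;
      uvec idx(m);
      for (uword i = 0; i < m; ++i) idx(i) = order[start + i];
      mat Xb = X.rows(idx);

      // Forward pass.
      std::vector<mat> Z(L), Aa(L + 1);
      Aa[0] = Xb;
      for (int l = 0; l < n_hidden; ++l) {
        Z[l] = Aa[l] * W[l];
        Z[l].each_row() += b[l];
        Aa[l + 1] = act_forward(Z[l], act_codes[l]);
      }
      Z[L - 1] = Aa[L - 1] * W[L - 1];
      Z[L - 1].each_row() += b[L - 1];

      mat dZ;  // gradient at the output pre-activation, already / m
      if (head_units == 1) {
        mat P = 1.0 / (1.0 + exp(-Z[L - 1]));
        vec yb = y(idx);
        mat Pc = clamp(P, clip, 1.0 - clip);
        epoch_loss += -accu(yb % log(Pc.col(0)) +
                            (1.0 - yb) % log(1.0 - Pc.col(0)));
        dZ = (P.each_col() - yb) / static_cast<double>(m);
      } else {
        mat Zs = Z[L - 1].each_col() - max(Z[L - 1], 1);
        mat E = exp(Zs);
        mat P = E.each_col() / sum(E, 1);
        mat Yb = Y.rows(idx);
        mat Pc = clamp(P, clip, 1.0 - clip);
        epoch_loss += -accu(Yb % log(Pc));
        dZ = (P - Yb) / static_cast<double>(m);
      }

      // Backward pass with Adam updates (one shared timestep per batch).
      ++t;
      const double bc1 = 1.0 - std::pow(beta1, static_cast<double>(t));
      const double bc2 = 1.0 - std::pow(beta2, static_cast<double>(t));
      for (int l = L - 1; l >= 0; --l) {
        mat gW = Aa[l].t() * dZ;
        rowvec gb = sum(dZ, 0);
        if (l > 0) {
          mat dA = dZ * W[l].t();
          dZ = dA % act_backward(Z[l - 1], Aa[l], act_codes[l - 1]);
        }
        adam[l].mW = beta1 * adam[l].mW + (1.0 - beta1) * gW;
        adam[l].vW = beta2 * adam[l].vW + (1.0 - beta2) * square(gW);
        adam[l].mb = beta1 * adam[l].mb + (1.0 - beta1) * gb;
        adam[l].vb = beta2 * adam[l].vb + (1.0 - beta2) * square(gb);
        W[l] -= lr * (adam[l].mW / bc1) / (sqrt(adam[l].vW / bc2) + adam_eps);
        b[l] -= lr * (adam[l].mb / bc1) / (sqrt(adam[l].vb / bc2) + adam_eps);
      }
    }
    loss_history(ep) = epoch_loss / static_cast<double>(n);
  }

  Rcpp::List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = Rcpp::wrap(W[l]);
    bout[l] = Rcpp::wrap(conv_to<vec>::from(b[l].t()));
  }
  return Rcpp::List::create(Rcpp::Named("weights") = Wout,
                            Rcpp::Named("biases") = bout,
                            Rcpp::Named("loss") = loss_history);
}
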