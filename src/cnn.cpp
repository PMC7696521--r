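// Three-layer CNN for 64x64x3 asymmetry images, single precision.
//
// Architecture (valid-padding 3x3 convolutions, stride 1; 2x2 max pooling
// with floor division; spatial batch norm after the first pool):
//   Conv 32 + ReLU -> Pool -> BN -> Conv 64 + ReLU -> Pool
//   -> Conv 128 + ReLU -> Pool -> Flatten -> Dense 256 + ReLU
//   -> Dropout -> Dense 1 + sigmoid
// Trained with Adam on binary cross-entropy.  All randomness (weight
// init, shuffling, dropout masks) is drawn from R's RNG so a set.seed()
// on the R side makes runs bit-reproducible.
//
// Activations are stored as (channels x H*W*batch) matrices, spatial
// positions column-major per image; convolutions run as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

fmat relu(const fmat& x) {
  fmat y = x;
  float* p = y.memptr();
  for (uword i = 0; i < y.n_elem; ++i) if (p[i] < 0) p[i] = 0;
  return y;
}

// zero gradient entries where the pre-activation was non-positive
void relu_mask_inplace(fmat& g, const fmat& z) {
  const float* pz = z.memptr();
  float* pg = g.memptr();
  for (uword i = 0; i < g.n_elem; ++i) if (pz[i] <= 0) pg[i] = 0;
}

// im2col for a 3x3 valid convolution.
fmat im2col3(const fmat& A, int H, int W, int B) {
  const int C = A.n_rows, OH = H - 2, OW = W - 2;
  fmat col(9 * C, (uword)OH * OW * B);
  for (int b = 0; b < B; ++b) {
    const uword ain = (uword)b * H * W, aout = (uword)b * OH * OW;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r0 = (dj * 3 + di) * C;
        for (int oj = 0; oj < OW; ++oj) {
          col.submat(r0, aout + (uword)oj * OH,
                     r0 + C - 1, aout + (uword)oj * OH + OH - 1) =
            A.cols(ain + (uword)(oj + dj) * H + di,
                   ain + (uword)(oj + dj) * H + di + OH - 1);
        }
      }
    }
  }
  return col;
}

// Adjoint of im2col3: accumulate column gradients back onto the input map.
fmat col2im3(const fmat& dcol, int H, int W, int B, int C) {
  const int OH = H - 2, OW = W - 2;
  fmat dA(C, (uword)H * W * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword ain = (uword)b * H * W, aout = (uword)b * OH * OW;
    for (int dj = 0; dj < 3; ++dj) {
      for (int di = 0; di < 3; ++di) {
        const int r0 = (dj * 3 + di) * C;
        for (int oj = 0; oj < OW; ++oj) {
          dA.cols(ain + (uword)(oj + dj) * H + di,
                  ain + (uword)(oj + dj) * H + di + OH - 1) +=
            dcol.submat(r0, aout + (uword)oj * OH,
                        r0 + C - 1, aout + (uword)oj * OH + OH - 1);
        }
      }
    }
  }
  return dA;
}

// 2x2 max pooling, stride 2, floor division (odd trailing row/col dropped).
// mask records which of the four candidates won, per channel and position.
fmat maxpool2(const fmat& A, int H, int W, int B, umat& mask) {
  const int C = A.n_rows, OH = H / 2, OW = W / 2;
  fmat out(C, (uword)OH * OW * B);
  mask.set_size(C, (uword)OH * OW * B);
  for (int b = 0; b < B; ++b) {
    const uword ain = (uword)b * H * W, aout = (uword)b * OH * OW;
    for (int oj = 0; oj < OW; ++oj) {
      for (int oi = 0; oi < OH; ++oi) {
        const uword q = aout + (uword)oj * OH + oi;
        const uword c0 = ain + (uword)(2 * oj) * H + 2 * oi;
        const uword cand[4] = {c0, c0 + 1, c0 + H, c0 + H + 1};
        for (int c = 0; c < C; ++c) {
          float best = A(c, cand[0]);
          int arg = 0;
          for (int k = 1; k < 4; ++k) {
            const float v = A(c, cand[k]);
            if (v > best) { best = v; arg = k; }
          }
          out(c, q) = best;
          mask(c, q) = arg;
        }
      }
    }
  }
  return out;
}

fmat maxpool2_back(const fmat& dOut, const umat& mask,
                   int H, int W, int B, int C) {
  const int OH = H / 2, OW = W / 2;
  fmat dA(C, (uword)H * W * B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword ain = (uword)b * H * W, aout = (uword)b * OH * OW;
    for (int oj = 0; oj < OW; ++oj) {
      for (int oi = 0; oi < OH; ++oi) {
        const uword q = aout + (uword)oj * OH + oi;
        const uword c0 = ain + (uword)(2 * oj) * H + 2 * oi;
        const uword cand[4] = {c0, c0 + 1, c0 + H, c0 + H + 1};
        for (int c = 0; c < C; ++c) {
          dA(c, cand[mask(c, q)]) += dOut(c, q);
        }
      }
    }
  }
  return dA;
}

struct Weights {
  fmat W1, W2, W3, W4, W5;          // conv kernels (K x F) / dense (in x out)
  fvec b1, b2, b3, b4, b5;
  fvec gamma, beta, rmean, rvar;     // batch norm (32 channels)
};

Weights from_list(const Rcpp::List& w) {
  Weights s;
  s.W1 = conv_to<fmat>::from(Rcpp::as<mat>(w["W1"]));
  s.b1 = conv_to<fvec>::from(Rcpp::as<vec>(w["b1"]));
  s.gamma = conv_to<fvec>::from(Rcpp::as<vec>(w["gamma"]));
  s.beta = conv_to<fvec>::from(Rcpp::as<vec>(w["beta"]));
  s.rmean = conv_to<fvec>::from(Rcpp::as<vec>(w["rmean"]));
  s.rvar = conv_to<fvec>::from(Rcpp::as<vec>(w["rvar"]));
  s.W2 = conv_to<fmat>::from(Rcpp::as<mat>(w["W2"]));
  s.b2 = conv_to<fvec>::from(Rcpp::as<vec>(w["b2"]));
  s.W3 = conv_to<fmat>::from(Rcpp::as<mat>(w["W3"]));
  s.b3 = conv_to<fvec>::from(Rcpp::as<vec>(w["b3"]));
  s.W4 = conv_to<fmat>::from(Rcpp::as<mat>(w["W4"]));
  s.b4 = conv_to<fvec>::from(Rcpp::as<vec>(w["b4"]));
  s.W5 = conv_to<fmat>::from(Rcpp::as<mat>(w["W5"]));
  s.b5 = conv_to<fvec>::from(Rcpp::as<vec>(w["b5"]));
  return s;
}

Rcpp::List to_list(const Weights& s) {
  return Rcpp::List::create(
    Rcpp::Named("W1") = conv_to<mat>::from(s.W1),
    Rcpp::Named("b1") = conv_to<vec>::from(s.b1),
    Rcpp::Named("gamma") = conv_to<vec>::from(s.gamma),
    Rcpp::Named("beta") = conv_to<vec>::from(s.beta),
    Rcpp::Named("rmean") = conv_to<vec>::from(s.rmean),
    Rcpp::Named("rvar") = conv_to<vec>::from(s.rvar),
    Rcpp::Named("W2") = conv_to<mat>::from(s.W2),
    Rcpp::Named("b2") = conv_to<vec>::from(s.b2),
    Rcpp::Named("W3") = conv_to<mat>::from(s.W3),
    Rcpp::Named("b3") = conv_to<vec>::from(s.b3),
    Rcpp::Named("W4") = conv_to<mat>::from(s.W4),
    Rcpp::Named("b4") = conv_to<vec>::from(s.b4),
    Rcpp::Named("W5") = conv_to<mat>::from(s.W5),
    Rcpp::Named("b5") = conv_to<vec>::from(s.b5));
}

// Assemble the (3 x 4096*B) channel-major input block for a set of rows of
// the flattened image matrix (each row: 64x64x3, column-major h, w, c).
fmat input_block(const fmat& X, const uvec& rows) {
  const int B = rows.n_elem;
  fmat A0(3, (uword)4096 * B);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < 3; ++c) {
      A0.submat(c, (uword)b * 4096, c, (uword)b * 4096 + 4095) =
        X.submat(rows(b), (uword)c * 4096, rows(b), (uword)c * 4096 + 4095);
    }
  }
  return A0;
}

struct Cache {
  fmat col1, Z1, A1p; umat m1;
  fvec mu, va, istd; fmat xhat, bn_out;
  fmat col2, Z2, A2p; umat m2;
  fmat col3, Z3, A3p; umat m3;
  fmat X4, Z4, H4, drop;
  frowvec Z5, P;
};

// Forward pass; train = true uses batch statistics and dropout.
void forward(const Weights& s, const fmat& A0, int B, bool train,
             double dropout, double bn_eps, double bn_mom,
             Weights* running_update, Cache& c) {
  c.col1 = im2col3(A0, 64, 64, B);
  c.Z1 = s.W1.t() * c.col1;               // 32 x 3844B
  c.Z1.each_col() += s.b1;
  fmat A1 = relu(c.Z1);
  c.A1p = maxpool2(A1, 62, 62, B, c.m1);    // 32 x 961B

  if (train) {
    c.mu = mean(c.A1p, 1);
    c.va = mean(square(c.A1p.each_col() - c.mu), 1);
    c.istd = 1.0f / sqrt(c.va + (float)bn_eps);
    (void)running_update;
  } else {
    c.mu = s.rmean;
    c.istd = 1.0f / sqrt(s.rvar + (float)bn_eps);
  }
  c.xhat = c.A1p.each_col() - c.mu;
  c.xhat.each_col() %= c.istd;
  c.bn_out = c.xhat.each_col() % s.gamma;
  c.bn_out.each_col() += s.beta;

  c.col2 = im2col3(c.bn_out, 31, 31, B);
  c.Z2 = s.W2.t() * c.col2;               // 64 x 841B
  c.Z2.each_col() += s.b2;
  fmat A2 = relu(c.Z2);
  c.A2p = maxpool2(A2, 29, 29, B, c.m2);  // 64 x 196B

  c.col3 = im2col3(c.A2p, 14, 14, B);
  c.Z3 = s.W3.t() * c.col3;               // 128 x 144B
  c.Z3.each_col() += s.b3;
  fmat A3 = relu(c.Z3);
  c.A3p = maxpool2(A3, 12, 12, B, c.m3);  // 128 x 36B

  c.X4.set_size(4608, B);                 // flatten
  for (int b = 0; b < B; ++b) {
    c.X4.col(b) = vectorise(c.A3p.cols((uword)b * 36, (uword)b * 36 + 35));
  }
  c.Z4 = s.W4.t() * c.X4;                 // 256 x B
  c.Z4.each_col() += s.b4;
  c.H4 = relu(c.Z4);
  if (train && dropout > 0) {
    c.drop.set_size(256, B);
    const float keep_scale = 1.0f / (float)(1.0 - dropout);
    for (uword j = 0; j < c.drop.n_cols; ++j) {
      for (uword i = 0; i < c.drop.n_rows; ++i) {
        c.drop(i, j) = (unif_rand() >= dropout) ? keep_scale : 0.0f;
      }
    }
    c.H4 %= c.drop;
  }
  c.Z5 = s.W5.t() * c.H4;                 // 1 x B (as frowvec via conv)
  c.Z5 += s.b5(0);
  c.P = 1.0f / (1.0f + exp(-c.Z5));
}

struct AdamState {
  std::vector<fmat> m, v;
  long t = 0;
  void init(const std::vector<const fmat*>& params) {
    for (auto* p : params) {
      m.emplace_back(size(*p), fill::zeros);
      v.emplace_back(size(*p), fill::zeros);
    }
  }
};

void adam_step(std::vector<fmat*>& params, const std::vector<fmat>& grads,
               AdamState& st, double lr, double b1, double b2, double eps) {
  st.t += 1;
  const float a1 = (float)(1.0 - std::pow(b1, (double)st.t));
  const float a2 = (float)(1.0 - std::pow(b2, (double)st.t));
  for (size_t k = 0; k < params.size(); ++k) {
    st.m[k] = (float)b1 * st.m[k] + (float)(1.0 - b1) * grads[k];
    st.v[k] = (float)b2 * st.v[k] + (float)(1.0 - b2) * square(grads[k]);
    *params[k] -= (float)lr * (st.m[k] / a1) /
      (sqrt(st.v[k] / a2) + (float)eps);
  }
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cnn_init_cpp() {
  Rcpp::RNGScope scope;
  auto glorot = [](int n_in, int n_out, int fan_in, int fan_out) {
    const double lim = std::sqrt(6.0 / (fan_in + fan_out));
    fmat w(n_in, n_out);
    for (uword j = 0; j < w.n_cols; ++j) {
      for (uword i = 0; i < w.n_rows; ++i) {
        w(i, j) = (float)((unif_rand() * 2.0 - 1.0) * lim);
      }
    }
    return w;
  };
  Weights s;
  s.W1 = glorot(27, 32, 27, 9 * 32);
  s.W2 = glorot(288, 64, 288, 9 * 64);
  s.W3 = glorot(576, 128, 576, 9 * 128);
  s.W4 = glorot(4608, 256, 4608, 256);
  s.W5 = glorot(256, 1, 256, 1);
  s.b1 = fvec(32, fill::zeros);
  s.b2 = fvec(64, fill::zeros);
  s.b3 = fvec(128, fill::zeros);
  s.b4 = fvec(256, fill::zeros);
  s.b5 = fvec(1, fill::zeros);
  s.gamma = fvec(32, fill::ones);
  s.beta = fvec(32, fill::zeros);
  s.rmean = fvec(32, fill::zeros);
  s.rvar = fvec(32, fill::ones);
  return to_list(s);
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, Rcpp::NumericMatrix X,
                         Rcpp::NumericVector y, int epochs, int batch,
                         double lr, double dropout, double beta1,
                         double beta2, double adam_eps, double bn_momentum,
                         double bn_eps, bool shuffle) {
  Rcpp::RNGScope scope;
  Weights s = from_list(weights);
  const int N = X.nrow();
  if (X.ncol() != 12288) Rcpp::stop("images must be 64x64x3 (12288 values)");
  if (y.size() != N) Rcpp::stop("labels must match the number of images");
  fmat Xf = conv_to<fmat>::from(Rcpp::as<mat>(X));
  fvec yf = conv_to<fvec>::from(Rcpp::as<vec>(y));

  AdamState st;
  std::vector<fmat*> params;
  // biases/BN vectors are handled as 1-column matrices through fmat views:
  // keep everything as fmat by aliasing vectors into temporary holders.
  fmat b1m(s.b1), b2m(s.b2), b3m(s.b3), b4m(s.b4), b5m(s.b5),
       gm(s.gamma), bm(s.beta);
  params = {&s.W1, &b1m, &gm, &bm, &s.W2, &b2m, &s.W3, &b3m,
            &s.W4, &b4m, &s.W5, &b5m};
  {
    std::vector<const fmat*> cp(params.begin(), params.end());
    st.init(cp);
  }

  std::vector<double> hist_loss(epochs), hist_acc(epochs);
  uvec order = regspace<uvec>(0, N - 1);
  Cache c;
  for (int ep = 0; ep < epochs; ++ep) {
    if (shuffle) {
      for (int i = N - 1; i > 0; --i) {
        int j = (int)std::floor(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(order(i), order(j));
      }
    }
    double ep_loss = 0.0; long ep_correct = 0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      uvec rows = order.subvec(start, start + B - 1);
      fmat A0 = input_block(Xf, rows);
      s.b1 = b1m.col(0); s.b2 = b2m.col(0); s.b3 = b3m.col(0);
      s.b4 = b4m.col(0); s.b5 = b5m.col(0);
      s.gamma = gm.col(0); s.beta = bm.col(0);
      forward(s, A0, B, true, dropout, bn_eps, bn_momentum, &s, c);
      // moving statistics: seeded from the first batch, momentum-updated
      // afterwards, so inference is usable even after short trainings
      if (st.t == 0) {
        s.rmean = c.mu;
        s.rvar = c.va;
      } else {
        s.rmean = (float)bn_momentum * s.rmean +
          (float)(1.0 - bn_momentum) * c.mu;
        s.rvar = (float)bn_momentum * s.rvar +
          (float)(1.0 - bn_momentum) * c.va;
      }

      // loss and running accuracy
      for (int b = 0; b < B; ++b) {
        const double p = std::min(std::max((double)c.P(b), 1e-7), 1 - 1e-7);
        const double yb = yf(rows(b));
        ep_loss += -(yb * std::log(p) + (1 - yb) * std::log(1 - p));
        ep_correct += ((p >= 0.5) == (yb >= 0.5));
      }

      // backward
      frowvec dZ5(B);
      for (int b = 0; b < B; ++b) dZ5(b) = (c.P(b) - yf(rows(b))) / B;
      fmat dW5 = c.H4 * dZ5.t();
      fmat db5(1, 1); db5(0, 0) = accu(dZ5);
      fmat dH4 = s.W5 * dZ5;
      if (dropout > 0) dH4 %= c.drop;
      fmat dZ4 = dH4;
      relu_mask_inplace(dZ4, c.Z4);
      fmat dW4 = c.X4 * dZ4.t();
      fmat db4 = sum(dZ4, 1);
      fmat dX4 = s.W4 * dZ4;

      fmat dA3p(128, (uword)36 * B);
      for (int b = 0; b < B; ++b) {
        dA3p.cols((uword)b * 36, (uword)b * 36 + 35) =
          reshape(dX4.col(b), 128, 36);
      }
      fmat dA3 = maxpool2_back(dA3p, c.m3, 12, 12, B, 128);
      fmat dZ3 = dA3;
      relu_mask_inplace(dZ3, c.Z3);
      fmat dW3 = c.col3 * dZ3.t();
      fmat db3 = sum(dZ3, 1);
      fmat dA2p = col2im3(s.W3 * dZ3, 14, 14, B, 64);

      fmat dA2 = maxpool2_back(dA2p, c.m2, 29, 29, B, 64);
      fmat dZ2 = dA2;
      relu_mask_inplace(dZ2, c.Z2);
      fmat dW2 = c.col2 * dZ2.t();
      fmat db2 = sum(dZ2, 1);
      fmat dBN = col2im3(s.W2 * dZ2, 31, 31, B, 32);

      // batch-norm backward (batch statistics)
      const float Nbn = (float)dBN.n_cols;
      fmat dgamma = sum(dBN % c.xhat, 1);
      fmat dbeta = sum(dBN, 1);
      fmat dxhat = dBN.each_col() % s.gamma;
      fvec mean_dxhat = mean(dxhat, 1);
      fvec mean_dxhat_xhat = mean(dxhat % c.xhat, 1);
      fmat dA1p = dxhat;
      dA1p.each_col() -= mean_dxhat;
      dA1p -= c.xhat.each_col() % mean_dxhat_xhat;
      dA1p.each_col() %= c.istd;
      (void)Nbn;

      fmat dA1 = maxpool2_back(dA1p, c.m1, 62, 62, B, 32);
      fmat dZ1 = dA1;
      relu_mask_inplace(dZ1, c.Z1);
      fmat dW1 = c.col1 * dZ1.t();
      fmat db1 = sum(dZ1, 1);

      std::vector<fmat> grads = {dW1, db1, dgamma, dbeta, dW2, db2,
                                 dW3, db3, dW4, db4, dW5, db5};
      adam_step(params, grads, st, lr, beta1, beta2, adam_eps);
      Rcpp::checkUserInterrupt();
    }
    hist_loss[ep] = ep_loss / N;
    hist_acc[ep] = (double)ep_correct / N;
  }
  s.b1 = b1m.col(0); s.b2 = b2m.col(0); s.b3 = b3m.col(0);
  s.b4 = b4m.col(0); s.b5 = b5m.col(0);
  s.gamma = gm.col(0); s.beta = bm.col(0);
  return Rcpp::List::create(
    Rcpp::Named("weights") = to_list(s),
    Rcpp::Named("loss") = hist_loss,
    Rcpp::Named("accuracy") = hist_acc);
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_predict_cpp(Rcpp::List weights,
                                    Rcpp::NumericMatrix X, int batch,
                                    double bn_eps) {
  Weights s = from_list(weights);
  const int N = X.nrow();
  if (X.ncol() != 12288) Rcpp::stop("images must be 64x64x3 (12288 values)");
  fmat Xf = conv_to<fmat>::from(Rcpp::as<mat>(X));
  Rcpp::NumericVector out(N);
  Cache c;
  for (int start = 0; start < N; start += batch) {
    const int B = std::min(batch, N - start);
    uvec rows = regspace<uvec>(start, start + B - 1);
    fmat A0 = input_block(Xf, rows);
    forward(s, A0, B, false, 0.0, bn_eps, 0.99, nullptr, c);
    for (int b = 0; b < B; ++b) out[start + b] = (double)c.P(b);
  }
  return out;
}
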