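// GRU sequence-to-sequence core: a bidirectional multi-layer GRU encoder
// compressing a fixed-length multichannel window into a feature vector
// (concatenated final forward/backward top-layer states), and a single-layer
// GRU decoder, initialized with that vector, that autoregressively emits
// primitive tokens. Teacher-forced cross-entropy training with full
// backpropagation through time; gradients are checked against finite
// differences in the test suite.
//
// Conventions: batches are matrix rows; a window batch is a cube
// (batch x channels x time); gate columns are ordered [r | z | n];
// token ids are 0-based here (R passes code - 1).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct GruCache {
  cube r, z, n, ghn;  // (B x H x T) gate activations and the h*U_n term
  cube h;             // (B x H x (T+1)), slice 0 = initial state
};

// forward pass of one unidirectional GRU over time (slices of X)
static GruCache gru_forward(const cube& X, const mat& W, const mat& U,
                            const rowvec& b, const mat& h0) {
  const uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  GruCache c;
  c.r.set_size(B, H, T); c.z.set_size(B, H, T);
  c.n.set_size(B, H, T); c.ghn.set_size(B, H, T);
  c.h.set_size(B, H, T + 1);
  c.h.slice(0) = h0;
  for (uword t = 0; t < T; ++t) {
    mat gx = X.slice(t) * W;
    gx.each_row() += b;
    mat gh = c.h.slice(t) * U;
    mat r = sigmoid(gx.cols(0, H - 1) + gh.cols(0, H - 1));
    mat z = sigmoid(gx.cols(H, 2 * H - 1) + gh.cols(H, 2 * H - 1));
    mat ghn = gh.cols(2 * H, 3 * H - 1);
    mat n = tanh(gx.cols(2 * H, 3 * H - 1) + r % ghn);
    c.r.slice(t) = r; c.z.slice(t) = z; c.n.slice(t) = n; c.ghn.slice(t) = ghn;
    c.h.slice(t + 1) = (1.0 - z) % n + z % c.h.slice(t);
  }
  return c;
}

// backward pass; dH holds per-step gradients on the outputs h_1..h_T
// (already including any gradient on the final state). Returns gradient on
// the input cube; accumulates dW, dU, db; dh0 receives the gradient on h0.
static cube gru_backward(const cube& X, const mat& W, const mat& U,
                         const GruCache& c, const cube& dH,
                         mat& dW, mat& dU, rowvec& db, mat& dh0) {
  const uword B = X.n_rows, T = X.n_slices, H = U.n_rows;
  cube dX(B, X.n_cols, T, fill::zeros);
  mat dh(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    dh += dH.slice(t);
    const mat& r = c.r.slice(t); const mat& z = c.z.slice(t);
    const mat& n = c.n.slice(t); const mat& ghn = c.ghn.slice(t);
    const mat& hprev = c.h.slice(t);
    mat dn = dh % (1.0 - z);
    mat dz = dh % (hprev - n);
    mat dhprev = dh % z;
    mat dan = dn % (1.0 - n % n);
    mat daz = dz % z % (1.0 - z);
    mat dar = (dan % ghn) % r % (1.0 - r);
    mat da(B, 3 * H);
    da.cols(0, H - 1) = dar;
    da.cols(H, 2 * H - 1) = daz;
    da.cols(2 * H, 3 * H - 1) = dan;
    dW += X.slice(t).t() * da;
    db += sum(da, 0);
    dX.slice(t) = da * W.t();
    mat dgh = da;
    dgh.cols(2 * H, 3 * H - 1) = dan % r;
    dU += hprev.t() * dgh;
    dhprev += dgh * U.t();
    dh = dhprev;
  }
  dh0 = dh;
  return dX;
}

static cube reverse_time(const cube& X) {
  cube Y(size(X));
  for (uword t = 0; t < X.n_slices; ++t) Y.slice(t) = X.slice(X.n_slices - 1 - t);
  return Y;
}

struct EncCache {
  std::vector<cube> inputs;          // input cube per layer (fwd time order)
  std::vector<GruCache> fwd, bwd;    // bwd caches are in reversed time
};

static std::string pname(const char* stem, int l, const char* d) {
  return std::string("enc_") + stem + "_" + std::to_string(l) + "_" + d;
}

// runs the bidirectional encoder stack; returns the feature matrix (B x 2H)
static mat encoder_forward(const Rcpp::List& params, const cube& X, int L,
                           EncCache* cache) {
  cube inp = X;
  const uword B = X.n_rows;
  mat feat;
  for (int l = 1; l <= L; ++l) {
    mat Wf = params[pname("W", l, "f")], Uf = params[pname("U", l, "f")];
    rowvec bf = Rcpp::as<rowvec>(params[pname("b", l, "f")]);
    mat Wb = params[pname("W", l, "b")], Ub = params[pname("U", l, "b")];
    rowvec bb = Rcpp::as<rowvec>(params[pname("b", l, "b")]);
    const uword H = Uf.n_rows;
    mat h0(B, H, fill::zeros);
    GruCache cf = gru_forward(inp, Wf, Uf, bf, h0);
    cube rinp = reverse_time(inp);
    GruCache cb = gru_forward(rinp, Wb, Ub, bb, h0);
    if (cache) {
      cache->inputs.push_back(inp);
      cache->fwd.push_back(cf);
      cache->bwd.push_back(cb);
    }
    const uword T = inp.n_slices;
    cube out(B, 2 * H, T);
    for (uword t = 0; t < T; ++t) {
      out.slice(t).cols(0, H - 1) = cf.h.slice(t + 1);
      out.slice(t).cols(H, 2 * H - 1) = cb.h.slice(T - t);  // bwd state at time t
    }
    if (l == L) {
      feat.set_size(B, 2 * H);
      feat.cols(0, H - 1) = cf.h.slice(T);       // final forward state
      feat.cols(H, 2 * H - 1) = cb.h.slice(T);   // final backward state (time 0)
    }
    inp = out;
  }
  return feat;
}

// backprop through the encoder given the gradient on the feature vector
static void encoder_backward(const Rcpp::List& params, const EncCache& cache,
                             int L, const mat& dfeat, Rcpp::List& grads) {
  const uword B = dfeat.n_rows;
  cube dout;  // gradient on the current layer's output, fwd time order
  for (int l = L; l >= 1; --l) {
    mat Wf = params[pname("W", l, "f")], Uf = params[pname("U", l, "f")];
    mat Wb = params[pname("W", l, "b")], Ub = params[pname("U", l, "b")];
    const uword H = Uf.n_rows;
    const cube& inp = cache.inputs[l - 1];
    const uword T = inp.n_slices;

    cube dHf(B, H, T, fill::zeros), dHb(B, H, T, fill::zeros);
    if (l == L) {
      dHf.slice(T - 1) += dfeat.cols(0, H - 1);
      dHb.slice(T - 1) += dfeat.cols(H, 2 * H - 1);  // reversed-time last step
    }
    if (dout.n_slices > 0) {
      for (uword t = 0; t < T; ++t) {
        dHf.slice(t) += dout.slice(t).cols(0, H - 1);
        dHb.slice(T - 1 - t) += dout.slice(t).cols(H, 2 * H - 1);
      }
    }

    mat dWf(size(Wf), fill::zeros), dUf(size(Uf), fill::zeros);
    rowvec dbf(3 * H, fill::zeros);
    mat dWb(size(Wb), fill::zeros), dUb(size(Ub), fill::zeros);
    rowvec dbb(3 * H, fill::zeros);
    mat dh0f, dh0b;

    cube dXf = gru_backward(inp, Wf, Uf, cache.fwd[l - 1], dHf, dWf, dUf, dbf, dh0f);
    cube rinp = reverse_time(inp);
    cube dXb = gru_backward(rinp, Wb, Ub, cache.bwd[l - 1], dHb, dWb, dUb, dbb, dh0b);
    cube dXb_f = reverse_time(dXb);

    dout = dXf + dXb_f;  // becomes gradient on the layer-below output
    grads[pname("W", l, "f")] = dWf; grads[pname("U", l, "f")] = dUf;
    grads[pname("b", l, "f")] = dbf;
    grads[pname("W", l, "b")] = dWb; grads[pname("U", l, "b")] = dUb;
    grads[pname("b", l, "b")] = dbb;
  }
}

// [[Rcpp::export]]
arma::mat cpp_encode(const Rcpp::List& params, const arma::cube& X, int n_layers) {
  return encoder_forward(params, X, n_layers, nullptr);
}

// decoder step input: one-hot previous token concatenated with the encoder
// feature vector, so the feature conditions every step rather than only the
// initial hidden state
static mat decoder_input(const arma::ivec& tokens, const mat& feat, uword V) {
  mat X(feat.n_rows, V + feat.n_cols, fill::zeros);
  for (uword i = 0; i < feat.n_rows; ++i) X(i, tokens(i)) = 1.0;
  X.cols(V, V + feat.n_cols - 1) = feat;
  return X;
}

// one decoder step: previous-token ids (0-based), hidden state and the
// window's feature vector -> class probabilities and the next hidden state
// [[Rcpp::export]]
Rcpp::List cpp_decoder_step(const Rcpp::List& params, const arma::mat& h,
                            const arma::ivec& tokens, const arma::mat& feat) {
  mat W = params["dec_W"], U = params["dec_U"];
  rowvec b = Rcpp::as<rowvec>(params["dec_b"]);
  mat Wo = params["out_W"];
  rowvec bo = Rcpp::as<rowvec>(params["out_b"]);
  const uword B = h.n_rows, D = U.n_rows;
  const uword V = W.n_rows - feat.n_cols;
  mat gx = decoder_input(tokens, feat, V) * W;
  gx.each_row() += b;
  mat gh = h * U;
  mat r = sigmoid(gx.cols(0, D - 1) + gh.cols(0, D - 1));
  mat z = sigmoid(gx.cols(D, 2 * D - 1) + gh.cols(D, 2 * D - 1));
  mat n = tanh(gx.cols(2 * D, 3 * D - 1) + r % gh.cols(2 * D, 3 * D - 1));
  mat hn = (1.0 - z) % n + z % h;
  mat logits = hn * Wo;
  logits.each_row() += bo;
  mat p = exp(logits.each_col() - max(logits, 1));
  p.each_col() /= sum(p, 1);
  return Rcpp::List::create(Rcpp::Named("probs") = p, Rcpp::Named("h") = hn);
}

// teacher-forced loss and full gradient for one minibatch
// dec_in / dec_tgt: (B x Ldec) 0-based token matrices; PAD targets are masked;
// tok_weights (length = vocab) rescales each target token's contribution
// (weighted mean cross-entropy), countering class imbalance; empty = uniform
// [[Rcpp::export]]
Rcpp::List cpp_seq2seq_loss_grad(const Rcpp::List& params, const arma::cube& X,
                                 const arma::imat& dec_in, const arma::imat& dec_tgt,
                                 int n_layers, int pad_id, bool want_grad = true,
                                 Rcpp::NumericVector tok_weights =
                                   Rcpp::NumericVector::create()) {
  EncCache cache;
  mat feat = encoder_forward(params, X, n_layers, want_grad ? &cache : nullptr);

  mat W = params["dec_W"], U = params["dec_U"];
  rowvec b = Rcpp::as<rowvec>(params["dec_b"]);
  mat Wo = params["out_W"];
  rowvec bo = Rcpp::as<rowvec>(params["out_b"]);
  const uword B = X.n_rows, L = dec_in.n_cols, D = U.n_rows, V = Wo.n_cols;
  vec w(V, fill::ones);
  if (tok_weights.size() > 0) {
    if ((uword)tok_weights.size() != V) Rcpp::stop("tok_weights must have vocab length");
    w = Rcpp::as<vec>(tok_weights);
  }

  // decoder forward with caches
  cube onr(B, D, L), onz(B, D, L), onn(B, D, L), onghn(B, D, L), hs(B, D, L + 1);
  cube probs(B, V, L);
  hs.slice(0) = feat;
  const uword Vin = W.n_rows - D;  // vocab size; token one-hot precedes feat
  double loss = 0.0;
  double n_tok = 0.0;
  for (uword t = 0; t < L; ++t) {
    mat gx = decoder_input(ivec(dec_in.col(t)), feat, Vin) * W;
    gx.each_row() += b;
    mat gh = hs.slice(t) * U;
    mat r = sigmoid(gx.cols(0, D - 1) + gh.cols(0, D - 1));
    mat z = sigmoid(gx.cols(D, 2 * D - 1) + gh.cols(D, 2 * D - 1));
    mat ghn = gh.cols(2 * D, 3 * D - 1);
    mat n = tanh(gx.cols(2 * D, 3 * D - 1) + r % ghn);
    onr.slice(t) = r; onz.slice(t) = z; onn.slice(t) = n; onghn.slice(t) = ghn;
    hs.slice(t + 1) = (1.0 - z) % n + z % hs.slice(t);
    mat logits = hs.slice(t + 1) * Wo;
    logits.each_row() += bo;
    mat p = exp(logits.each_col() - max(logits, 1));
    p.each_col() /= sum(p, 1);
    probs.slice(t) = p;
    for (uword i = 0; i < B; ++i) {
      if (dec_tgt(i, t) != pad_id) {
        loss -= w(dec_tgt(i, t)) * std::log(std::max(p(i, dec_tgt(i, t)), 1e-300));
        n_tok += w(dec_tgt(i, t));
      }
    }
  }
  if (n_tok > 0) loss /= n_tok;
  if (!want_grad) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("n_tokens") = n_tok);
  }

  // decoder backward
  mat dW(size(W), fill::zeros), dU(size(U), fill::zeros);
  rowvec db(3 * D, fill::zeros);
  mat dWo(size(Wo), fill::zeros);
  rowvec dbo(V, fill::zeros);
  mat dh(B, D, fill::zeros);
  mat dfeat(B, D, fill::zeros);  // per-step feature-input gradient
  const double inv = n_tok > 0 ? 1.0 / n_tok : 0.0;
  for (uword t = L; t-- > 0;) {
    mat dlogits = probs.slice(t);
    for (uword i = 0; i < B; ++i) {
      if (dec_tgt(i, t) != pad_id) {
        dlogits(i, dec_tgt(i, t)) -= 1.0;
        dlogits.row(i) *= inv * w(dec_tgt(i, t));
      } else {
        dlogits.row(i).zeros();
      }
    }
    dWo += hs.slice(t + 1).t() * dlogits;
    dbo += sum(dlogits, 0);
    dh += dlogits * Wo.t();

    const mat& r = onr.slice(t); const mat& z = onz.slice(t);
    const mat& n = onn.slice(t); const mat& ghn = onghn.slice(t);
    const mat& hprev = hs.slice(t);
    mat dn = dh % (1.0 - z);
    mat dz = dh % (hprev - n);
    mat dhprev = dh % z;
    mat dan = dn % (1.0 - n % n);
    mat daz = dz % z % (1.0 - z);
    mat dar = (dan % ghn) % r % (1.0 - r);
    mat da(B, 3 * D);
    da.cols(0, D - 1) = dar;
    da.cols(D, 2 * D - 1) = daz;
    da.cols(2 * D, 3 * D - 1) = dan;
    mat Xt = decoder_input(ivec(dec_in.col(t)), feat, Vin);
    dW += Xt.t() * da;
    db += sum(da, 0);
    mat dX = da * W.t();
    dfeat += dX.cols(Vin, Vin + D - 1);
    mat dgh = da;
    dgh.cols(2 * D, 3 * D - 1) = dan % r;
    dU += hprev.t() * dgh;
    dhprev += dgh * U.t();
    dh = dhprev;
  }

  Rcpp::List grads;
  grads["dec_W"] = dW; grads["dec_U"] = dU; grads["dec_b"] = db;
  grads["out_W"] = dWo; grads["out_b"] = dbo;
  // the feature receives gradient both as decoder initial state (dh after
  // BPTT) and as the per-step conditioning input (dfeat)
  encoder_backward(params, cache, n_layers, dh + dfeat, grads);
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("n_tokens") = n_tok,
                            Rcpp::Named("grads") = grads);
}
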