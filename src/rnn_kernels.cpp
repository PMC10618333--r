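// Dense recurrent kernels (LSTM stack and GRU) used by the generator and the
// predictor. These mirror the reference R implementations in R/nn.R one to
// one; the test suite checks both routes against each other and against
// numerical gradients.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat sigm(const arma::mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

static arma::mat softmax_rows(arma::mat z) {
  z.each_col() -= arma::max(z, 1);
  z = arma::exp(z);
  z.each_col() /= arma::sum(z, 1);
  return z;
}

// ---- LSTM stack -------------------------------------------------------------

// params: list(emb, layers = list(list(W, U, b), ...), Wo, bo)
// Xin: B x T integer matrix of 1-based token codes
// [[Rcpp::export(name = ".cpp_lstm_forward")]]
List cpp_lstm_forward(List params, IntegerMatrix Xin) {
  arma::mat emb = as<arma::mat>(params["emb"]);
  List layers = params["layers"];
  arma::mat Wo = as<arma::mat>(params["Wo"]);
  arma::vec bo = as<arma::vec>(params["bo"]);
  int B = Xin.nrow(), T = Xin.ncol();
  int L = layers.size();
  int U = Wo.n_rows, V = Wo.n_cols, E = emb.n_cols;

  std::vector<arma::mat> W(L), Uw(L);
  std::vector<arma::rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    List lp = layers[l];
    W[l] = as<arma::mat>(lp["W"]);
    Uw[l] = as<arma::mat>(lp["U"]);
    b[l] = as<arma::rowvec>(lp["b"]);
  }

  arma::cube P(B, V, T);
  arma::cube EmbX(B, E, T);
  std::vector<arma::cube> Ic(L), Fc(L), Gc(L), Oc(L), TCc(L), Cc(L), Hc(L);
  for (int l = 0; l < L; ++l) {
    Ic[l].set_size(B, U, T); Fc[l].set_size(B, U, T); Gc[l].set_size(B, U, T);
    Oc[l].set_size(B, U, T); TCc[l].set_size(B, U, T);
    Cc[l].set_size(B, U, T); Hc[l].set_size(B, U, T);
  }
  std::vector<arma::mat> h(L, arma::mat(B, U, arma::fill::zeros));
  std::vector<arma::mat> c(L, arma::mat(B, U, arma::fill::zeros));

  for (int t = 0; t < T; ++t) {
    arma::mat x(B, E);
    for (int i = 0; i < B; ++i) x.row(i) = emb.row(Xin(i, t) - 1);
    EmbX.slice(t) = x;
    arma::mat inp = x;
    for (int l = 0; l < L; ++l) {
      arma::mat z = inp * W[l] + h[l] * Uw[l];
      z.each_row() += b[l];
      arma::mat ig = sigm(z.cols(0, U - 1));
      arma::mat fg = sigm(z.cols(U, 2 * U - 1));
      arma::mat gg = arma::tanh(z.cols(2 * U, 3 * U - 1));
      arma::mat og = sigm(z.cols(3 * U, 4 * U - 1));
      arma::mat cn = fg % c[l] + ig % gg;
      arma::mat tc = arma::tanh(cn);
      Ic[l].slice(t) = ig; Fc[l].slice(t) = fg; Gc[l].slice(t) = gg;
      Oc[l].slice(t) = og; TCc[l].slice(t) = tc;
      Cc[l].slice(t) = c[l];       // c_{t-1}
      Hc[l].slice(t) = h[l];       // h_{t-1}
      c[l] = cn;
      h[l] = og % tc;
      inp = h[l];
    }
    P.slice(t) = softmax_rows(h[L - 1] * Wo + arma::repmat(bo.t(), B, 1));
  }
  // final hidden states per layer (for completeness)
  List hs(L), cs(L);
  for (int l = 0; l < L; ++l) { hs[l] = h[l]; cs[l] = c[l]; }
  List Il(L), Fl(L), Gl(L), Ol(L), TCl(L), Cl(L), Hl(L);
  for (int l = 0; l < L; ++l) {
    Il[l] = Ic[l]; Fl[l] = Fc[l]; Gl[l] = Gc[l]; Ol[l] = Oc[l];
    TCl[l] = TCc[l]; Cl[l] = Cc[l]; Hl[l] = Hc[l];
  }
  List cache = List::create(_["EmbX"] = EmbX, _["I"] = Il, _["F"] = Fl,
                            _["G"] = Gl, _["O"] = Ol,
                            _["TC"] = TCl, _["C"] = Cl,
                            _["H"] = Hl);
  return List::create(_["P"] = P, _["cache"] = cache,
                      _["h"] = hs, _["c"] = cs);
}

// dlogits: B x V x T cube (gradient on pre-softmax logits)
// [[Rcpp::export(name = ".cpp_lstm_backward")]]
List cpp_lstm_backward(List params, IntegerMatrix Xin, List fwd,
                       arma::cube dlogits) {
  arma::mat emb = as<arma::mat>(params["emb"]);
  List layers = params["layers"];
  arma::mat Wo = as<arma::mat>(params["Wo"]);
  int B = Xin.nrow(), T = Xin.ncol();
  int L = layers.size();
  int U = Wo.n_rows;

  std::vector<arma::mat> W(L), Uw(L);
  for (int l = 0; l < L; ++l) {
    List lp = layers[l];
    W[l] = as<arma::mat>(lp["W"]);
    Uw[l] = as<arma::mat>(lp["U"]);
  }
  List cache = fwd["cache"];
  arma::cube EmbX = as<arma::cube>(cache["EmbX"]);
  List Ic = cache["I"], Fc = cache["F"], Gc = cache["G"], Oc = cache["O"],
       TCc = cache["TC"], Cc = cache["C"], Hc = cache["H"];
  std::vector<arma::cube> I(L), F(L), G(L), O(L), TC(L), C(L), H(L);
  for (int l = 0; l < L; ++l) {
    I[l] = as<arma::cube>(Ic[l]); F[l] = as<arma::cube>(Fc[l]);
    G[l] = as<arma::cube>(Gc[l]); O[l] = as<arma::cube>(Oc[l]);
    TC[l] = as<arma::cube>(TCc[l]); C[l] = as<arma::cube>(Cc[l]);
    H[l] = as<arma::cube>(Hc[l]);
  }

  arma::mat gEmb(emb.n_rows, emb.n_cols, arma::fill::zeros);
  arma::mat gWo(Wo.n_rows, Wo.n_cols, arma::fill::zeros);
  arma::rowvec gbo(Wo.n_cols, arma::fill::zeros);
  std::vector<arma::mat> gW(L), gU(L);
  std::vector<arma::rowvec> gb(L);
  for (int l = 0; l < L; ++l) {
    gW[l].zeros(W[l].n_rows, W[l].n_cols);
    gU[l].zeros(Uw[l].n_rows, Uw[l].n_cols);
    gb[l].zeros(4 * U);
  }
  std::vector<arma::mat> dh(L, arma::mat(B, U, arma::fill::zeros));
  std::vector<arma::mat> dc(L, arma::mat(B, U, arma::fill::zeros));

  for (int t = T - 1; t >= 0; --t) {
    arma::mat dl = dlogits.slice(t);
    // top hidden at step t is the next layer input cached at t+1, easier to
    // recompute: h_top(t) = O % TC at t
    arma::mat htop = O[L - 1].slice(t) % TC[L - 1].slice(t);
    gWo += htop.t() * dl;
    gbo += arma::sum(dl, 0);
    arma::mat dtop = dl * Wo.t();
    arma::mat dlow;
    for (int l = L - 1; l >= 0; --l) {
      arma::mat dht = dh[l] + (l == L - 1 ? dtop : dlow);
      arma::mat ig = I[l].slice(t), fg = F[l].slice(t), gg = G[l].slice(t),
                og = O[l].slice(t), tc = TC[l].slice(t), cp = C[l].slice(t);
      arma::mat do_ = dht % tc;
      arma::mat dct = dc[l] + dht % og % (1.0 - tc % tc);
      arma::mat di = dct % gg;
      arma::mat df = dct % cp;
      arma::mat dg = dct % ig;
      dc[l] = dct % fg;
      arma::mat dz(B, 4 * U);
      dz.cols(0, U - 1) = di % ig % (1.0 - ig);
      dz.cols(U, 2 * U - 1) = df % fg % (1.0 - fg);
      dz.cols(2 * U, 3 * U - 1) = dg % (1.0 - gg % gg);
      dz.cols(3 * U, 4 * U - 1) = do_ % og % (1.0 - og);
      arma::mat xin = (l == 0) ? EmbX.slice(t)
                               : O[l - 1].slice(t) % TC[l - 1].slice(t);
      gW[l] += xin.t() * dz;
      gU[l] += H[l].slice(t).t() * dz;
      gb[l] += arma::sum(dz, 0);
      dh[l] = dz * Uw[l].t();
      dlow = dz * W[l].t();
    }
    for (int i = 0; i < B; ++i) gEmb.row(Xin(i, t) - 1) += dlow.row(i);
  }
  List glayers(L);
  for (int l = 0; l < L; ++l)
    glayers[l] = List::create(_["W"] = gW[l], _["U"] = gU[l],
                              _["b"] = NumericVector(gb[l].begin(), gb[l].end()));
  return List::create(_["emb"] = gEmb, _["layers"] = glayers, _["Wo"] = gWo,
                      _["bo"] = NumericVector(gbo.begin(), gbo.end()));
}

// ---- GRU -------------------------------------------------------------------

// p: list(W (nin x 3U, blocks z|r|n), Uzr (U x 2U), Un (U x U), b (3U))
// X: B x nin x T input cube
// [[Rcpp::export(name = ".cpp_gru_forward")]]
List cpp_gru_forward(List p, arma::cube X) {
  arma::mat W = as<arma::mat>(p["W"]);
  arma::mat Uzr = as<arma::mat>(p["Uzr"]);
  arma::mat Un = as<arma::mat>(p["Un"]);
  arma::rowvec b = as<arma::rowvec>(p["b"]);
  int B = X.n_rows, T = X.n_slices;
  int U = Un.n_cols;
  arma::mat Wzr = W.cols(0, 2 * U - 1);
  arma::mat Wn = W.cols(2 * U, 3 * U - 1);
  arma::rowvec bzr = b.cols(0, 2 * U - 1);
  arma::rowvec bn = b.cols(2 * U, 3 * U - 1);

  arma::cube HS(B, U, T), Z(B, U, T), R(B, U, T), N(B, U, T), HP(B, U, T);
  arma::mat h(B, U, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    arma::mat x = X.slice(t);
    arma::mat zr = x * Wzr + h * Uzr;
    zr.each_row() += bzr;
    arma::mat z = sigm(zr.cols(0, U - 1));
    arma::mat r = sigm(zr.cols(U, 2 * U - 1));
    arma::mat npre = x * Wn + (r % h) * Un;
    npre.each_row() += bn;
    arma::mat n = arma::tanh(npre);
    HP.slice(t) = h;
    h = (1.0 - z) % n + z % h;
    HS.slice(t) = h; Z.slice(t) = z; R.slice(t) = r; N.slice(t) = n;
  }
  return List::create(_["hs"] = HS,
                      _["cache"] = List::create(_["Z"] = Z, _["R"] = R,
                                                _["N"] = N, _["HP"] = HP,
                                                _["X"] = X));
}

// dhs: B x U x T upstream gradients on the hidden states
// [[Rcpp::export(name = ".cpp_gru_backward")]]
List cpp_gru_backward(List p, List fwd, arma::cube dhs) {
  arma::mat W = as<arma::mat>(p["W"]);
  arma::mat Uzr = as<arma::mat>(p["Uzr"]);
  arma::mat Un = as<arma::mat>(p["Un"]);
  List cache = fwd["cache"];
  arma::cube Z = as<arma::cube>(cache["Z"]);
  arma::cube R = as<arma::cube>(cache["R"]);
  arma::cube N = as<arma::cube>(cache["N"]);
  arma::cube HP = as<arma::cube>(cache["HP"]);
  arma::cube X = as<arma::cube>(cache["X"]);
  int B = dhs.n_rows, T = dhs.n_slices;
  int U = Un.n_cols;
  int nin = W.n_rows;
  arma::mat Wzr = W.cols(0, 2 * U - 1);
  arma::mat Wn = W.cols(2 * U, 3 * U - 1);

  arma::mat gW(nin, 3 * U, arma::fill::zeros);
  arma::mat gUzr(U, 2 * U, arma::fill::zeros);
  arma::mat gUn(U, U, arma::fill::zeros);
  arma::rowvec gb(3 * U, arma::fill::zeros);
  arma::cube dX(B, nin, T);
  arma::mat carry(B, U, arma::fill::zeros);

  for (int t = T - 1; t >= 0; --t) {
    arma::mat z = Z.slice(t), r = R.slice(t), n = N.slice(t), hp = HP.slice(t);
    arma::mat x = X.slice(t);
    arma::mat dh = dhs.slice(t) + carry;
    arma::mat dz = dh % (hp - n);
    arma::mat dn = dh % (1.0 - z);
    carry = dh % z;
    arma::mat dnpre = dn % (1.0 - n % n);
    gW.cols(2 * U, 3 * U - 1) += x.t() * dnpre;
    gUn += (r % hp).t() * dnpre;
    gb.cols(2 * U, 3 * U - 1) += arma::sum(dnpre, 0);
    arma::mat tmp = dnpre * Un.t();
    arma::mat dr = tmp % hp;
    carry += tmp % r;
    arma::mat dzpre = dz % z % (1.0 - z);
    arma::mat drpre = dr % r % (1.0 - r);
    arma::mat dzr = arma::join_rows(dzpre, drpre);
    gW.cols(0, 2 * U - 1) += x.t() * dzr;
    gUzr += hp.t() * dzr;
    gb.cols(0, 2 * U - 1) += arma::sum(dzr, 0);
    carry += dzr * Uzr.t();
    dX.slice(t) = dnpre * Wn.t() + dzr * Wzr.t();
  }
  List grads = List::create(_["W"] = gW, _["Uzr"] = gUzr, _["Un"] = gUn,
                            _["b"] = NumericVector(gb.begin(), gb.end()));
  return List::create(_["grads"] = grads, _["dxs"] = dX);
}
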