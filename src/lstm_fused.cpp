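// Fused multi-layer LSTM + linear softmax head: forward pass and, when
// requested, full backpropagation through time in one call. The GCN stage
// stays on the R side (sparse block-diagonal products); this kernel
// receives the per-window GCN outputs as a B x R x K cube.
//
// Dropout is "inverted": masks arrive pre-scaled by 1/(1-p) and are applied
// to every layer output fed upward (all steps for layers below the top; the
// final hidden state only for the top layer, which is all the head sees).
// Gate column blocks in the fused weight matrices are [f | i | g | o].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// X: B x R x K inputs; lstmW: per layer (H+din) x 4H fused gate weights;
// lstmB: per layer length-4H biases; headW/headB: linear head; y: length-B
// labels in {1,2} (empty => no loss); dropMasks: empty list, or per layer a
// B x H x K cube with a single B x H matrix for the top layer.
// [[Rcpp::export(name = ".lstmHeadFused")]]
Rcpp::List lstmHeadFused(const arma::cube& X, Rcpp::List lstmW,
                         Rcpp::List lstmB, const arma::mat& headW,
                         const arma::vec& headB, const arma::ivec& y,
                         Rcpp::List dropMasks, double l2, bool wantGrad) {
  const int nL = lstmW.size();
  const int B = X.n_rows, K = X.n_slices;
  const mat W0 = Rcpp::as<mat>(lstmW[0]);
  const int H = W0.n_cols / 4;
  const bool useDrop = dropMasks.size() > 0;

  std::vector<mat> Wl(nL);
  std::vector<rowvec> bl(nL);
  for (int l = 0; l < nL; ++l) {
    Wl[l] = Rcpp::as<mat>(lstmW[l]);
    bl[l] = Rcpp::as<rowvec>(lstmB[l]);
  }
  std::vector<cube> maskC(nL);
  mat maskTop;
  if (useDrop) {
    for (int l = 0; l < nL - 1; ++l) maskC[l] = Rcpp::as<cube>(dropMasks[l]);
    maskTop = Rcpp::as<mat>(dropMasks[nL - 1]);
  }

  // caches per layer (only kept when gradients are wanted)
  std::vector<cube> Ccat(nL), Cf(nL), Ci(nL), Cg(nL), Co(nL), CcPrev(nL),
      Ctc(nL);
  std::vector<cube> inp(nL);
  inp[0] = X;
  mat hTop;

  for (int l = 0; l < nL; ++l) {
    const int din = Wl[l].n_rows - H;
    const bool feedAll = (l < nL - 1);
    if (wantGrad) {
      Ccat[l].set_size(B, H + din, K);
      Cf[l].set_size(B, H, K); Ci[l].set_size(B, H, K);
      Cg[l].set_size(B, H, K); Co[l].set_size(B, H, K);
      CcPrev[l].set_size(B, H, K); Ctc[l].set_size(B, H, K);
    }
    cube out;
    if (feedAll) out.set_size(B, H, K);
    mat h(B, H, fill::zeros), c(B, H, fill::zeros);
    for (int k = 0; k < K; ++k) {
      mat concat = join_rows(h, inp[l].slice(k));
      mat G = concat * Wl[l];
      G.each_row() += bl[l];
      mat f = sigm(G.cols(0, H - 1));
      mat i_ = sigm(G.cols(H, 2 * H - 1));
      mat g = tanh(G.cols(2 * H, 3 * H - 1));
      mat o = sigm(G.cols(3 * H, 4 * H - 1));
      mat cNew = f % c + i_ % g;
      mat tc = tanh(cNew);
      mat hNew = o % tc;
      if (wantGrad) {
        Ccat[l].slice(k) = concat;
        Cf[l].slice(k) = f; Ci[l].slice(k) = i_;
        Cg[l].slice(k) = g; Co[l].slice(k) = o;
        CcPrev[l].slice(k) = c; Ctc[l].slice(k) = tc;
      }
      if (feedAll) {
        out.slice(k) = useDrop ? mat(hNew % maskC[l].slice(k)) : hNew;
      } else if (k == K - 1) {
        hTop = (useDrop && maskTop.n_elem > 0) ? mat(hNew % maskTop) : hNew;
      }
      h = hNew;
      c = cNew;
    }
    if (feedAll) inp[l + 1] = out;
  }

  mat logits = hTop * headW;
  logits.each_row() += headB.t();
  vec mx = max(logits, 1);
  mat ex = exp(logits.each_col() - mx);
  mat probs = ex.each_col() / sum(ex, 1);

  double ce = NA_REAL;
  const bool haveY = y.n_elem == (uword)B;
  if (haveY) {
    double acc = 0;
    for (int b = 0; b < B; ++b)
      acc += -std::log(std::max(probs(b, y[b] - 1), 1e-12));
    ce = acc / B;
  }

  Rcpp::List res = Rcpp::List::create(
      Rcpp::Named("probs") = probs, Rcpp::Named("hTop") = hTop,
      Rcpp::Named("ce") = ce);
  if (!wantGrad) return res;
  if (!haveY) Rcpp::stop("gradients require labels");

  mat Y(B, 2, fill::zeros);
  for (int b = 0; b < B; ++b) Y(b, y[b] - 1) = 1.0;
  mat dlogits = (probs - Y) / B;
  mat dHeadW = hTop.t() * dlogits + l2 * headW;
  rowvec dHeadB = sum(dlogits, 0);
  mat dhTop = dlogits * headW.t();

  Rcpp::List gW(nL), gB(nL);
  cube dOut;                 // grads wrt layer output fed up (pre-mask)
  bool dOutFull = false;     // top layer: only final step carries a grad
  cube dX;
  for (int l = nL - 1; l >= 0; --l) {
    const int din = Wl[l].n_rows - H;
    mat dW(H + din, 4 * H, fill::zeros);
    rowvec db(4 * H, fill::zeros);
    mat dhNext(B, H, fill::zeros), dcNext(B, H, fill::zeros);
    cube dInp(B, din, K);
    for (int k = K - 1; k >= 0; --k) {
      mat dh = dhNext;
      if (l == nL - 1) {
        if (k == K - 1)
          dh += (useDrop && maskTop.n_elem > 0) ? mat(dhTop % maskTop) : dhTop;
      } else if (dOutFull) {
        dh += useDrop ? mat(dOut.slice(k) % maskC[l].slice(k)) : dOut.slice(k);
      }
      const mat& f = Cf[l].slice(k); const mat& i_ = Ci[l].slice(k);
      const mat& g = Cg[l].slice(k); const mat& o = Co[l].slice(k);
      const mat& tc = Ctc[l].slice(k);
      mat do_ = dh % tc;
      mat dc = dcNext + dh % o % (1.0 - tc % tc);
      mat dG(B, 4 * H);
      dG.cols(0, H - 1) = (dc % CcPrev[l].slice(k)) % f % (1.0 - f);
      dG.cols(H, 2 * H - 1) = (dc % g) % i_ % (1.0 - i_);
      dG.cols(2 * H, 3 * H - 1) = (dc % i_) % (1.0 - g % g);
      dG.cols(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
      dcNext = dc % f;
      dW += Ccat[l].slice(k).t() * dG;
      db += sum(dG, 0);
      mat dconcat = dG * Wl[l].t();
      dhNext = dconcat.cols(0, H - 1);
      dInp.slice(k) = dconcat.cols(H, H + din - 1);
    }
    gW[l] = dW + l2 * Wl[l];
    gB[l] = db;
    dOut = dInp;
    dOutFull = true;
    if (l == 0) dX = dInp;
  }

  res["gradLstmW"] = gW;
  res["gradLstmB"] = gB;
  res["gradHeadW"] = dHeadW;
  res["gradHeadB"] = dHeadB;
  res["dX"] = dX;
  return res;
}
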