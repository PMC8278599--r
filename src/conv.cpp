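// Stride-1 2-D convolution, forward and backward, as im2col + GEMM in
// single precision. Layout matches R's column-major arrays:
// inputs H x W x C, weights k x k x Cin x Cout, outputs Ho x Wo x Cout.
// im2col patch matrices are built in W-dimension chunks so peak memory
// stays modest for large images.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static arma::fmat padInput(const NumericVector& x, int H, int W, int C,
                           int pad) {
    // padded image as (Hp*Wp) x C, column-major spatial linearization
    const int Hp = H + 2 * pad, Wp = W + 2 * pad;
    arma::fmat xp(static_cast<arma::uword>(Hp) * Wp, C, arma::fill::zeros);
    const double* src = x.begin();
    for (int c = 0; c < C; ++c) {
        float* dst = xp.colptr(c);
        for (int w = 0; w < W; ++w) {
            const double* s = src + (static_cast<size_t>(c) * W + w) * H;
            float* d = dst + static_cast<size_t>(w + pad) * Hp + pad;
            for (int h = 0; h < H; ++h) d[h] = static_cast<float>(s[h]);
        }
    }
    return xp;
}

// Fill the im2col patch matrix for output columns [c0, c0+nc): rows are
// output pixels (column-major within the chunk), columns are (dy, dx, c).
static void im2colChunk(const arma::fmat& xp, int Hp, int Ho, int k,
                        int c0, int nc, arma::fmat& P) {
    const int C = xp.n_cols;
    for (int c = 0; c < C; ++c) {
        const float* src = xp.colptr(c);
        for (int dx = 0; dx < k; ++dx) {
            for (int dy = 0; dy < k; ++dy) {
                float* dst = P.colptr((static_cast<size_t>(c) * k + dx) * k + dy);
                for (int j = 0; j < nc; ++j) {
                    const float* s =
                        src + static_cast<size_t>(c0 + j + dx) * Hp + dy;
                    std::memcpy(dst + static_cast<size_t>(j) * Ho, s,
                                sizeof(float) * Ho);
                }
            }
        }
    }
}

// Adjoint of im2colChunk: scatter-add patch gradients back to the padded
// input gradient.
static void col2imChunk(arma::fmat& dxp, int Hp, int Ho, int k,
                        int c0, int nc, const arma::fmat& dP) {
    const int C = dxp.n_cols;
    for (int c = 0; c < C; ++c) {
        float* dst = dxp.colptr(c);
        for (int dx = 0; dx < k; ++dx) {
            for (int dy = 0; dy < k; ++dy) {
                const float* src =
                    dP.colptr((static_cast<size_t>(c) * k + dx) * k + dy);
                for (int j = 0; j < nc; ++j) {
                    float* d = dst + static_cast<size_t>(c0 + j + dx) * Hp + dy;
                    const float* s = src + static_cast<size_t>(j) * Ho;
                    for (int h = 0; h < Ho; ++h) d[h] += s[h];
                }
            }
        }
    }
}

static int chunkCols(int Ho, int Wo, int patch) {
    // aim for <= ~32M floats (128 MB) per patch matrix
    double maxPix = 32.0e6 / patch;
    int nc = static_cast<int>(maxPix / Ho);
    if (nc < 1) nc = 1;
    if (nc > Wo) nc = Wo;
    return nc;
}

// [[Rcpp::export(name = ".cppConvForward")]]
NumericVector cppConvForward(NumericVector x, NumericVector w,
                             NumericVector b, int pad) {
    IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
    const int H = dx[0], W = dx[1], C = dx[2];
    const int k = dw[0], Cin = dw[2], Cout = dw[3];
    if (C != Cin) stop("input has %d channels, layer expects %d", C, Cin);
    const int Hp = H + 2 * pad, Wp = W + 2 * pad;
    const int Ho = Hp - k + 1, Wo = Wp - k + 1;
    const int patch = k * k * Cin;

    arma::fmat xp = padInput(x, H, W, C, pad);
    arma::fmat Wm(patch, Cout);
    for (int i = 0; i < patch * Cout; ++i) Wm(i) = static_cast<float>(w[i]);

    NumericVector out(static_cast<R_xlen_t>(Ho) * Wo * Cout);
    out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);

    const int nc = chunkCols(Ho, Wo, patch);
    arma::fmat P;
    for (int c0 = 0; c0 < Wo; c0 += nc) {
        const int cc = std::min(nc, Wo - c0);
        P.set_size(static_cast<arma::uword>(Ho) * cc, patch);
        im2colChunk(xp, Hp, Ho, k, c0, cc, P);
        arma::fmat Y = P * Wm;  // (Ho*cc) x Cout
        for (int o = 0; o < Cout; ++o) {
            const float* s = Y.colptr(o);
            double* d = out.begin() +
                (static_cast<size_t>(o) * Wo + c0) * Ho;
            const double bo = b[o];
            for (size_t i = 0; i < static_cast<size_t>(Ho) * cc; ++i)
                d[i] = static_cast<double>(s[i]) + bo;
        }
    }
    return out;
}

// [[Rcpp::export(name = ".cppConvBackward")]]
List cppConvBackward(NumericVector x, NumericVector w, NumericVector dy,
                     int pad, bool needDx) {
    IntegerVector dx_ = x.attr("dim"), dw = w.attr("dim"),
        dd = dy.attr("dim");
    const int H = dx_[0], W = dx_[1], C = dx_[2];
    const int k = dw[0], Cin = dw[2], Cout = dw[3];
    const int Ho = dd[0], Wo = dd[1];
    const int Hp = H + 2 * pad, Wp = W + 2 * pad;
    const int patch = k * k * Cin;
    if (C != Cin) stop("input/weight channel mismatch");

    arma::fmat xp = padInput(x, H, W, C, pad);
    arma::fmat Wm(patch, Cout);
    for (int i = 0; i < patch * Cout; ++i) Wm(i) = static_cast<float>(w[i]);

    arma::fmat dWm(patch, Cout, arma::fill::zeros);
    arma::fvec db(Cout, arma::fill::zeros);
    arma::fmat dxp;
    if (needDx)
        dxp.zeros(static_cast<arma::uword>(Hp) * Wp, Cin);

    const int nc = chunkCols(Ho, Wo, patch);
    arma::fmat P;
    for (int c0 = 0; c0 < Wo; c0 += nc) {
        const int cc = std::min(nc, Wo - c0);
        P.set_size(static_cast<arma::uword>(Ho) * cc, patch);
        im2colChunk(xp, Hp, Ho, k, c0, cc, P);
        arma::fmat dYc(static_cast<arma::uword>(Ho) * cc, Cout);
        for (int o = 0; o < Cout; ++o) {
            const double* s = dy.begin() +
                (static_cast<size_t>(o) * Wo + c0) * Ho;
            float* d = dYc.colptr(o);
            for (size_t i = 0; i < static_cast<size_t>(Ho) * cc; ++i)
                d[i] = static_cast<float>(s[i]);
        }
        dWm += P.t() * dYc;
        db += arma::sum(dYc, 0).t();
        if (needDx) {
            arma::fmat dP = dYc * Wm.t();  // (Ho*cc) x patch
            col2imChunk(dxp, Hp, Ho, k, c0, cc, dP);
        }
    }

    NumericVector dWout(static_cast<R_xlen_t>(patch) * Cout);
    dWout.attr("dim") = IntegerVector::create(k, k, Cin, Cout);
    for (int i = 0; i < patch * Cout; ++i) dWout[i] = dWm(i);
    NumericVector dbout(Cout);
    for (int o = 0; o < Cout; ++o) dbout[o] = db(o);

    List res = List::create(_["dW"] = dWout, _["db"] = dbout,
                            _["dx"] = R_NilValue);
    if (needDx) {
        NumericVector dxout(static_cast<R_xlen_t>(H) * W * C);
        dxout.attr("dim") = IntegerVector::create(H, W, C);
        for (int c = 0; c < C; ++c) {
            const float* s = dxp.colptr(c);
            double* d = dxout.begin() + static_cast<size_t>(c) * W * H;
            for (int wcol = 0; wcol < W; ++wcol) {
                const float* sp = s + static_cast<size_t>(wcol + pad) * Hp + pad;
                double* dp = d + static_cast<size_t>(wcol) * H;
                for (int h = 0; h < H; ++h) dp[h] = sp[h];
            }
        }
        res["dx"] = dxout;
    }
    return res;
}

// Separable 2-D filtering with zero padding ("same" size), double
// precision; semantics identical to the R reference .filterSep.
// [[Rcpp::export(name = ".cppSepFilter")]]
NumericMatrix cppSepFilter(NumericMatrix x, NumericVector k) {
    const int nr = x.nrow(), nc = x.ncol(), n = k.size();
    const int half = (n - 1) / 2;
    NumericMatrix tmp(nr, nc), out(nr, nc);
    // along rows (vertical)
    for (int j = 0; j < nc; ++j) {
        const double* xc = &x(0, j);
        double* tc = &tmp(0, j);
        for (int i = 0; i < nr; ++i) {
            double s = 0.0;
            const int t0 = std::max(0, half - i);
            const int t1 = std::min(n, nr - i + half);
            for (int t = t0; t < t1; ++t) s += k[t] * xc[i + t - half];
            tc[i] = s;
        }
    }
    // along columns (horizontal)
    for (int j = 0; j < nc; ++j) {
        double* oc = &out(0, j);
        const int t0 = std::max(0, half - j);
        const int t1 = std::min(n, nc - j + half);
        for (int t = t0; t < t1; ++t) {
            const double kt = k[t];
            const double* tc = &tmp(0, j + t - half);
            for (int i = 0; i < nr; ++i) oc[i] += kt * tc[i];
        }
    }
    return out;
}

// ---- fused per-image training step ----------------------------------
// Full forward through all layers (single precision), loss gradient via
// an R callback on the final activation, then full backward. Keeps all
// intermediate activations (and, when small, im2col patch matrices) in
// float, avoiding per-layer double<->float conversion and R dispatch.

static arma::fmat padFmat(const arma::fmat& A, int H, int W, int pad) {
    if (pad == 0) return A;
    const int Hp = H + 2 * pad, Wp = W + 2 * pad;
    arma::fmat xp(static_cast<arma::uword>(Hp) * Wp, A.n_cols,
                  arma::fill::zeros);
    for (arma::uword c = 0; c < A.n_cols; ++c) {
        const float* s = A.colptr(c);
        float* d = xp.colptr(c);
        for (int w = 0; w < W; ++w)
            std::memcpy(d + static_cast<size_t>(w + pad) * Hp + pad,
                        s + static_cast<size_t>(w) * H, sizeof(float) * H);
    }
    return xp;
}

static arma::fmat cropFmat(const arma::fmat& xp, int Hp, int H, int W,
                           int pad) {
    if (pad == 0) return xp;
    arma::fmat out(static_cast<arma::uword>(H) * W, xp.n_cols);
    for (arma::uword c = 0; c < xp.n_cols; ++c) {
        const float* s = xp.colptr(c);
        float* d = out.colptr(c);
        for (int w = 0; w < W; ++w)
            std::memcpy(d + static_cast<size_t>(w) * H,
                        s + static_cast<size_t>(w + pad) * Hp + pad,
                        sizeof(float) * H);
    }
    return out;
}

// [[Rcpp::export(name = ".cppNetStep")]]
List cppNetStep(NumericVector x, List layers, Function lossGrad) {
    IntegerVector dx = x.attr("dim");
    const int nL = layers.size();
    if (dx.size() != 3) stop("input must be H x W x C");

    std::vector<arma::fmat> Wm(nL);
    std::vector<arma::fvec> bv(nL);
    std::vector<int> kk(nL), cin(nL), cout(nL), pad(nL), act(nL);
    for (int l = 0; l < nL; ++l) {
        List L = layers[l];
        NumericVector w = L["W"];
        IntegerVector dw = w.attr("dim");
        kk[l] = dw[0]; cin[l] = dw[2]; cout[l] = dw[3];
        pad[l] = as<int>(L["pad"]);
        std::string a = as<std::string>(L["activation"]);
        if (a == "relu") act[l] = 0;
        else if (a == "sigmoid") act[l] = 1;
        else stop("unknown activation: %s", a.c_str());
        const int patch = kk[l] * kk[l] * cin[l];
        Wm[l].set_size(patch, cout[l]);
        for (int i = 0; i < patch * cout[l]; ++i)
            Wm[l](i) = static_cast<float>(w[i]);
        NumericVector b = L["b"];
        bv[l].set_size(cout[l]);
        for (int o = 0; o < cout[l]; ++o) bv[l](o) = static_cast<float>(b[o]);
    }
    if (dx[2] != cin[0]) stop("input/first-layer channel mismatch");

    // forward
    std::vector<int> Hs(nL + 1), Ws(nL + 1);
    Hs[0] = dx[0]; Ws[0] = dx[1];
    std::vector<arma::fmat> acts(nL + 1);   // (H*W) x C activations
    std::vector<arma::fmat> pads(nL);       // padded layer inputs
    std::vector<arma::fmat> Pc(nL);         // cached im2col (when small)
    acts[0].set_size(static_cast<arma::uword>(Hs[0]) * Ws[0], dx[2]);
    for (int i = 0; i < static_cast<int>(acts[0].n_elem); ++i)
        acts[0](i) = static_cast<float>(x[i]);

    const arma::uword pCap = 16000000;  // cache im2col up to 64 MB/layer
    for (int l = 0; l < nL; ++l) {
        const int H = Hs[l], W = Ws[l];
        const int Hp = H + 2 * pad[l], Wp = W + 2 * pad[l];
        const int Ho = Hp - kk[l] + 1, Wo = Wp - kk[l] + 1;
        const int patch = kk[l] * kk[l] * cin[l];
        Hs[l + 1] = Ho; Ws[l + 1] = Wo;
        pads[l] = padFmat(acts[l], H, W, pad[l]);
        arma::fmat Z(static_cast<arma::uword>(Ho) * Wo, cout[l]);
        const arma::uword pElem =
            static_cast<arma::uword>(Ho) * Wo * patch;
        if (pElem <= pCap) {
            Pc[l].set_size(static_cast<arma::uword>(Ho) * Wo, patch);
            im2colChunk(pads[l], Hp, Ho, kk[l], 0, Wo, Pc[l]);
            Z = Pc[l] * Wm[l];
        } else {
            const int nc = chunkCols(Ho, Wo, patch);
            arma::fmat P;
            for (int c0 = 0; c0 < Wo; c0 += nc) {
                const int cc = std::min(nc, Wo - c0);
                P.set_size(static_cast<arma::uword>(Ho) * cc, patch);
                im2colChunk(pads[l], Hp, Ho, kk[l], c0, cc, P);
                Z.rows(static_cast<arma::uword>(c0) * Ho,
                       static_cast<arma::uword>(c0 + cc) * Ho - 1) =
                    P * Wm[l];
            }
        }
        Z.each_row() += bv[l].t();
        if (act[l] == 0) Z.transform([](float v) { return v > 0.f ? v : 0.f; });
        else Z.transform([](float v) { return 1.f / (1.f + std::exp(-v)); });
        acts[l + 1] = std::move(Z);
    }

    // loss gradient callback on the (double) final activation
    NumericVector out(static_cast<R_xlen_t>(acts[nL].n_elem));
    out.attr("dim") = IntegerVector::create(Hs[nL], Ws[nL], cout[nL - 1]);
    for (int i = 0; i < static_cast<int>(acts[nL].n_elem); ++i)
        out[i] = static_cast<double>(acts[nL](i));
    List lg = lossGrad(out);
    NumericVector grad = lg["grad"];

    arma::fmat dA(static_cast<arma::uword>(Hs[nL]) * Ws[nL], cout[nL - 1]);
    for (int i = 0; i < static_cast<int>(dA.n_elem); ++i)
        dA(i) = static_cast<float>(grad[i]);

    // backward
    List dWs(nL), dbs(nL);
    for (int l = nL - 1; l >= 0; --l) {
        const int H = Hs[l], W = Ws[l];
        const int Hp = H + 2 * pad[l], Wp = W + 2 * pad[l];
        const int Ho = Hs[l + 1], Wo = Ws[l + 1];
        const int patch = kk[l] * kk[l] * cin[l];
        // through the activation
        arma::fmat& A = acts[l + 1];
        if (act[l] == 0) {
            for (arma::uword i = 0; i < dA.n_elem; ++i)
                if (A(i) <= 0.f) dA(i) = 0.f;
        } else {
            for (arma::uword i = 0; i < dA.n_elem; ++i)
                dA(i) *= A(i) * (1.f - A(i));
        }
        arma::fmat dWm(patch, cout[l], arma::fill::zeros);
        const bool needDx = l > 0;
        arma::fmat dxp;
        if (needDx)
            dxp.zeros(static_cast<arma::uword>(Hp) * Wp, cin[l]);
        if (!Pc[l].is_empty()) {
            dWm = Pc[l].t() * dA;
            if (needDx) {
                arma::fmat dP = dA * Wm[l].t();
                col2imChunk(dxp, Hp, Ho, kk[l], 0, Wo, dP);
            }
        } else {
            const int nc = chunkCols(Ho, Wo, patch);
            arma::fmat P;
            for (int c0 = 0; c0 < Wo; c0 += nc) {
                const int cc = std::min(nc, Wo - c0);
                P.set_size(static_cast<arma::uword>(Ho) * cc, patch);
                im2colChunk(pads[l], Hp, Ho, kk[l], c0, cc, P);
                arma::fmat dZc = dA.rows(
                    static_cast<arma::uword>(c0) * Ho,
                    static_cast<arma::uword>(c0 + cc) * Ho - 1);
                dWm += P.t() * dZc;
                if (needDx) {
                    arma::fmat dP = dZc * Wm[l].t();
                    col2imChunk(dxp, Hp, Ho, kk[l], c0, cc, dP);
                }
            }
        }
        arma::fvec db = arma::sum(dA, 0).t();
        NumericVector dWout(static_cast<R_xlen_t>(patch) * cout[l]);
        dWout.attr("dim") =
            IntegerVector::create(kk[l], kk[l], cin[l], cout[l]);
        for (int i = 0; i < patch * cout[l]; ++i) dWout[i] = dWm(i);
        NumericVector dbout(cout[l]);
        for (int o = 0; o < cout[l]; ++o) dbout[o] = db(o);
        dWs[l] = dWout; dbs[l] = dbout;
        if (needDx) dA = cropFmat(dxp, Hp, H, W, pad[l]);
    }

    return List::create(_["value"] = lg["value"], _["dW"] = dWs,
                        _["db"] = dbs);
}
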