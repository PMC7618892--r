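// Transformer encoder/decoder for de novo peptide sequencing, with manual
// backpropagation and an Adam optimizer. One code path serves both the
// autoregressive next-residue model and the multinomial-diffusion refiner
// (non-causal decoder conditioned on a timestep embedding). Gradients are
// verified against finite differences in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <unordered_map>
#include <random>

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;

// ---------------------------------------------------------------------------
// configuration and parameter containers
// ---------------------------------------------------------------------------

struct Cfg {
  int d, H, ff, n_enc, n_dec, V, max_len, n_charges;
  double lmin, lmax;
  int pad, sos, eos;            // 0-based token ids
  vec masses;                   // per-token residue mass (0 for specials)
  arma::ivec residue_ids;       // 0-based ids of non-special tokens
  bool refiner;
  int T;                        // diffusion steps (refiner only)
  vec alpha_bar;                // length T+1, alpha_bar[0] = 1 (refiner only)
};

static Cfg read_cfg(List c) {
  Cfg g;
  g.d = as<int>(c["d"]); g.H = as<int>(c["H"]); g.ff = as<int>(c["ff"]);
  g.n_enc = as<int>(c["n_enc"]); g.n_dec = as<int>(c["n_dec"]);
  g.V = as<int>(c["V"]); g.max_len = as<int>(c["max_len"]);
  g.n_charges = as<int>(c["n_charges"]);
  g.lmin = as<double>(c["lmin"]); g.lmax = as<double>(c["lmax"]);
  g.pad = as<int>(c["pad"]); g.sos = as<int>(c["sos"]); g.eos = as<int>(c["eos"]);
  g.masses = as<vec>(c["masses"]);
  g.residue_ids = as<arma::ivec>(c["residue_ids"]);
  g.refiner = as<bool>(c["refiner"]);
  g.T = c.containsElementNamed("T") ? as<int>(c["T"]) : 0;
  if (c.containsElementNamed("alpha_bar") && !Rf_isNull(c["alpha_bar"]))
    g.alpha_bar = as<vec>(c["alpha_bar"]);
  if (g.d % 2 != 0) stop("hidden dim must be even");
  if (g.d % g.H != 0) stop("hidden dim must be divisible by heads");
  return g;
}

struct Params {
  std::vector<std::string> names;
  std::unordered_map<std::string, mat> m;
  mat& at(const std::string& k) {
    auto it = m.find(k);
    if (it == m.end()) stop("missing parameter: " + k);
    return it->second;
  }
};

static Params read_params(List L) {
  Params p;
  CharacterVector nm = L.names();
  for (int i = 0; i < L.size(); i++) {
    std::string k = as<std::string>(nm[i]);
    p.names.push_back(k);
    p.m[k] = as<mat>(L[i]);
  }
  return p;
}

static List write_params(Params& p) {
  List out(p.names.size());
  CharacterVector nm(p.names.size());
  for (size_t i = 0; i < p.names.size(); i++) {
    nm[i] = p.names[i];
    out[i] = wrap(p.m[p.names[i]]);
  }
  out.names() = nm;
  return out;
}

struct Grads {
  Params* ref;
  std::unordered_map<std::string, mat> m;
  explicit Grads(Params& p) : ref(&p) {}
  mat& at(const std::string& k) {
    auto it = m.find(k);
    if (it == m.end()) {
      mat& pm = ref->at(k);
      it = m.emplace(k, arma::zeros<mat>(pm.n_rows, pm.n_cols)).first;
    }
    return it->second;
  }
};

// ---------------------------------------------------------------------------
// sinusoidal encodings
// ---------------------------------------------------------------------------

// multi-scale encoding over geometrically spaced wavelengths [lmin, lmax]
static mat multiscale_enc(const vec& x, int d, double lmin, double lmax) {
  int half = d / 2;
  mat E(d, x.n_elem);
  for (int k = 0; k < half; k++) {
    double frac = (half == 1) ? 0.0 : (double)k / (half - 1);
    double lambda = lmin * std::pow(lmax / lmin, frac);
    double w = 2.0 * M_PI / lambda;
    for (arma::uword j = 0; j < x.n_elem; j++) {
      E(2 * k, j) = std::sin(w * x(j));
      E(2 * k + 1, j) = std::cos(w * x(j));
    }
  }
  return E;
}

// standard transformer index positional encoding
static mat pos_enc(int L, int d) {
  int half = d / 2;
  mat E(d, L);
  for (int k = 0; k < half; k++) {
    double w = std::pow(10000.0, -(double)k / half);
    for (int j = 0; j < L; j++) {
      E(2 * k, j) = std::sin(w * j);
      E(2 * k + 1, j) = std::cos(w * j);
    }
  }
  return E;
}

// ---------------------------------------------------------------------------
// layer norm
// ---------------------------------------------------------------------------

struct LNCache { mat xhat; rowvec istd; };

static mat ln_fwd(const mat& X, const mat& g, const mat& b, LNCache& c) {
  rowvec mu = arma::mean(X, 0);
  mat Xc = X.each_row() - mu;
  rowvec v = arma::mean(arma::square(Xc), 0);
  c.istd = 1.0 / arma::sqrt(v + 1e-5);
  c.xhat = Xc.each_row() % c.istd;
  mat Y = c.xhat.each_col() % g.col(0);
  Y.each_col() += b.col(0);
  return Y;
}

static mat ln_bwd(const mat& dY, const LNCache& c, const mat& g,
                  mat& dg, mat& db) {
  dg.col(0) += arma::sum(dY % c.xhat, 1);
  db.col(0) += arma::sum(dY, 1);
  mat dxhat = dY.each_col() % g.col(0);
  rowvec m1 = arma::mean(dxhat, 0);
  rowvec m2 = arma::mean(dxhat % c.xhat, 0);
  mat dX = (dxhat.each_row() - m1) - (c.xhat.each_row() % m2);
  dX.each_row() %= c.istd;
  return dX;
}

// ---------------------------------------------------------------------------
// multi-head attention
// ---------------------------------------------------------------------------

struct AttCache {
  mat Q, K, Vv, concat;        // projections and pre-output concat
  std::vector<mat> P;          // per-head attention probabilities (Lq x Lk)
  mat Xq, Xkv;                 // layer-norm outputs fed to the projections
};

// key_valid: optional 0/1 flags over key positions (nullptr = all valid);
// bias: optional per-head additive attention-score matrices (Lq x Lk)
static mat mha_fwd(Params& p, const std::string& pre, const mat& Xq,
                   const mat& Xkv, int H, bool causal, AttCache& c,
                   const arma::uvec* key_valid = nullptr,
                   const std::vector<mat>* bias = nullptr) {
  int d = Xq.n_rows, dh = d / H;
  double s = 1.0 / std::sqrt((double)dh);
  mat Q = p.at(pre + "Wq") * Xq; Q.each_col() += p.at(pre + "bq").col(0);
  mat K = p.at(pre + "Wk") * Xkv; K.each_col() += p.at(pre + "bk").col(0);
  mat V = p.at(pre + "Wv") * Xkv; V.each_col() += p.at(pre + "bv").col(0);
  int Lq = Xq.n_cols, Lk = Xkv.n_cols;
  mat O(d, Lq);
  c.P.assign(H, mat());
  for (int h = 0; h < H; h++) {
    mat Qh = Q.rows(h * dh, (h + 1) * dh - 1);
    mat Kh = K.rows(h * dh, (h + 1) * dh - 1);
    mat Vh = V.rows(h * dh, (h + 1) * dh - 1);
    mat S = (Qh.t() * Kh) * s;             // Lq x Lk
    if (bias) S += (*bias)[h];
    if (causal) {
      for (int i = 0; i < Lq; i++)
        for (int j = i + 1; j < Lk; j++) S(i, j) = -arma::datum::inf;
    }
    if (key_valid) {
      for (int j = 0; j < Lk; j++)
        if (!(*key_valid)(j)) S.col(j).fill(-arma::datum::inf);
    }
    mat P(Lq, Lk);
    for (int i = 0; i < Lq; i++) {
      rowvec r = S.row(i);
      double mx = r.max();
      r = arma::exp(r - mx);
      P.row(i) = r / arma::accu(r);
    }
    c.P[h] = P;
    O.rows(h * dh, (h + 1) * dh - 1) = Vh * P.t();
  }
  c.Q = Q; c.K = K; c.Vv = V; c.concat = O; c.Xq = Xq; c.Xkv = Xkv;
  mat Y = p.at(pre + "Wo") * O;
  Y.each_col() += p.at(pre + "bo").col(0);
  return Y;
}

static void mha_bwd(Params& p, Grads& g, const std::string& pre,
                    const AttCache& c, const mat& dY, mat& dXq, mat& dXkv,
                    int H, std::vector<mat>* dBias = nullptr) {
  int d = dY.n_rows, dh = d / H;
  double s = 1.0 / std::sqrt((double)dh);
  g.at(pre + "Wo") += dY * c.concat.t();
  g.at(pre + "bo").col(0) += arma::sum(dY, 1);
  mat dO = p.at(pre + "Wo").t() * dY;
  mat dQ(arma::size(c.Q), arma::fill::zeros);
  mat dK(arma::size(c.K), arma::fill::zeros);
  mat dV(arma::size(c.Vv), arma::fill::zeros);
  for (int h = 0; h < H; h++) {
    mat dOh = dO.rows(h * dh, (h + 1) * dh - 1);   // dh x Lq
    const mat& P = c.P[h];                          // Lq x Lk
    mat Vh = c.Vv.rows(h * dh, (h + 1) * dh - 1);
    dV.rows(h * dh, (h + 1) * dh - 1) += dOh * P;   // dh x Lk
    mat dP = dOh.t() * Vh;                          // Lq x Lk
    vec rowdot = arma::sum(dP % P, 1);
    mat dS = P % (dP.each_col() - rowdot);
    if (dBias) (*dBias)[h] += dS;
    dQ.rows(h * dh, (h + 1) * dh - 1) +=
      c.K.rows(h * dh, (h + 1) * dh - 1) * dS.t() * s;
    dK.rows(h * dh, (h + 1) * dh - 1) +=
      c.Q.rows(h * dh, (h + 1) * dh - 1) * dS * s;
  }
  g.at(pre + "Wq") += dQ * c.Xq.t();
  g.at(pre + "bq").col(0) += arma::sum(dQ, 1);
  g.at(pre + "Wk") += dK * c.Xkv.t();
  g.at(pre + "bk").col(0) += arma::sum(dK, 1);
  g.at(pre + "Wv") += dV * c.Xkv.t();
  g.at(pre + "bv").col(0) += arma::sum(dV, 1);
  dXq += p.at(pre + "Wq").t() * dQ;
  dXkv += p.at(pre + "Wk").t() * dK + p.at(pre + "Wv").t() * dV;
}

// ---------------------------------------------------------------------------
// feed-forward block
// ---------------------------------------------------------------------------

struct FFCache { mat z, a; };

static mat ff_fwd(Params& p, const std::string& pre, const mat& Z, FFCache& c) {
  mat H1 = p.at(pre + "W1") * Z;
  H1.each_col() += p.at(pre + "b1").col(0);
  c.a = arma::clamp(H1, 0.0, arma::datum::inf);   // ReLU
  c.z = Z;
  mat Y = p.at(pre + "W2") * c.a;
  Y.each_col() += p.at(pre + "b2").col(0);
  return Y;
}

static mat ff_bwd(Params& p, Grads& g, const std::string& pre,
                  const FFCache& c, const mat& dY) {
  g.at(pre + "W2") += dY * c.a.t();
  g.at(pre + "b2").col(0) += arma::sum(dY, 1);
  mat dA = p.at(pre + "W2").t() * dY;
  dA %= arma::conv_to<mat>::from(c.a > 0);
  g.at(pre + "W1") += dA * c.z.t();
  g.at(pre + "b1").col(0) += arma::sum(dA, 1);
  return p.at(pre + "W1").t() * dA;
}

// ---------------------------------------------------------------------------
// dropout (inverted; training only)
// ---------------------------------------------------------------------------

static mat apply_dropout(const mat& X, double p, std::mt19937_64& rng,
                         mat& mask) {
  mask.set_size(arma::size(X));
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double sc = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < X.n_cols; j++)
    for (arma::uword i = 0; i < X.n_rows; i++)
      mask(i, j) = (U(rng) >= p) ? sc : 0.0;
  return X % mask;
}

// ---------------------------------------------------------------------------
// encoder
// ---------------------------------------------------------------------------

struct EncLayerCache {
  LNCache ln1, ln2; AttCache att; FFCache ff;
  mat dm_att, dm_ff;           // dropout masks (training only)
};

struct EncCache {
  mat X0;                     // embedding input to layer stack
  std::vector<EncLayerCache> layers;
  LNCache lnf;
  vec log1p_inten;
  mat Ecomp;                  // complement-mass sinusoid features per peak
  int charge_col, Npk;
  arma::uvec key_valid;       // per-position validity (for padding)
  bool masked = false;
};

static mat encoder_fwd(Params& p, const Cfg& c, const vec& mz,
                       const vec& inten, double prec_mass, int charge,
                       EncCache& mc, const arma::uvec* peak_valid = nullptr,
                       double drop = 0.0, std::mt19937_64* rng = nullptr) {
  int N = mz.n_elem;
  mat X(c.d, N + 2);
  X.cols(0, N - 1) = multiscale_enc(mz, c.d, c.lmin, c.lmax);
  mc.log1p_inten = arma::log1p(inten);
  X.cols(0, N - 1) += p.at("w_int") * mc.log1p_inten.t();
  // learned lift of the complement-mass encoding: the m/z at which a
  // singly charged b/y partner of this peak would appear
  vec comp = (prec_mass + 2.0 * 1.007276) - mz;
  mc.Ecomp = multiscale_enc(comp, c.d, c.lmin, c.lmax);
  X.cols(0, N - 1) += p.at("Wcomp") * mc.Ecomp;
  X.col(N) = p.at("latent").col(0);
  int ccol = (charge >= 1 && charge <= c.n_charges) ? charge - 1 : c.n_charges;
  vec pm(1); pm(0) = prec_mass;
  X.col(N + 1) = multiscale_enc(pm, c.d, c.lmin, c.lmax).col(0) +
                 p.at("charge_emb").col(ccol);
  mc.charge_col = ccol; mc.Npk = N; mc.X0 = X;
  mc.masked = (peak_valid != nullptr);
  if (mc.masked) {
    mc.key_valid = arma::uvec(N + 2, arma::fill::ones);
    for (int j = 0; j < N; j++) mc.key_valid(j) = (*peak_valid)(j);
  }
  const arma::uvec* kv = mc.masked ? &mc.key_valid : nullptr;
  mc.layers.assign(c.n_enc, EncLayerCache());
  for (int l = 0; l < c.n_enc; l++) {
    std::string pre = "enc" + std::to_string(l) + ".";
    EncLayerCache& lc = mc.layers[l];
    mat Y1 = ln_fwd(X, p.at(pre + "ln1.g"), p.at(pre + "ln1.b"), lc.ln1);
    mat A = mha_fwd(p, pre + "attn.", Y1, Y1, c.H, false, lc.att, kv);
    if (drop > 0 && rng) A = apply_dropout(A, drop, *rng, lc.dm_att);
    X += A;
    mat Y2 = ln_fwd(X, p.at(pre + "ln2.g"), p.at(pre + "ln2.b"), lc.ln2);
    mat F = ff_fwd(p, pre + "ff.", Y2, lc.ff);
    if (drop > 0 && rng) F = apply_dropout(F, drop, *rng, lc.dm_ff);
    X += F;
  }
  return ln_fwd(X, p.at("enc_f.g"), p.at("enc_f.b"), mc.lnf);
}

static void encoder_bwd(Params& p, Grads& g, const Cfg& c, EncCache& mc,
                        const mat& dMem) {
  mat dX = ln_bwd(dMem, mc.lnf, p.at("enc_f.g"),
                  g.at("enc_f.g"), g.at("enc_f.b"));
  for (int l = c.n_enc - 1; l >= 0; l--) {
    std::string pre = "enc" + std::to_string(l) + ".";
    EncLayerCache& lc = mc.layers[l];
    mat dF = lc.dm_ff.n_elem ? mat(dX % lc.dm_ff) : dX;
    mat dZ = ff_bwd(p, g, pre + "ff.", lc.ff, dF);
    dX += ln_bwd(dZ, lc.ln2, p.at(pre + "ln2.g"),
                 g.at(pre + "ln2.g"), g.at(pre + "ln2.b"));
    mat dA = lc.dm_att.n_elem ? mat(dX % lc.dm_att) : dX;
    mat dY1(arma::size(dX), arma::fill::zeros);
    mha_bwd(p, g, pre + "attn.", lc.att, dA, dY1, dY1, c.H);
    dX += ln_bwd(dY1, lc.ln1, p.at(pre + "ln1.g"),
                 g.at(pre + "ln1.g"), g.at(pre + "ln1.b"));
  }
  int N = mc.Npk;
  g.at("w_int").col(0) += dX.cols(0, N - 1) * mc.log1p_inten;
  g.at("Wcomp") += dX.cols(0, N - 1) * mc.Ecomp.t();
  g.at("latent").col(0) += dX.col(N);
  g.at("charge_emb").col(mc.charge_col) += dX.col(N + 1);
}

// ---------------------------------------------------------------------------
// decoder (causal for the autoregressive model, bidirectional for refiner)
// ---------------------------------------------------------------------------

struct DecLayerCache {
  LNCache ln1, ln2, ln3; AttCache self, cross; FFCache ff;
  mat dm_self, dm_cross, dm_ff;
};

struct DecCache {
  std::vector<DecLayerCache> layers;
  LNCache lnf;
  mat Xf, Erem;
  arma::ivec tokens;
  mat F;                       // relative-mass bias features (3*DB x L*Npk)
  int Npk = 0;
  std::vector<std::vector<mat>> bias;    // per layer, per head (L x Lk)
};

// dimensionality and wavelength range of the relative-mass bias features
static const int DB = 64;
static const double BIAS_LMIN = 0.02, BIAS_LMAX = 2000.0;

// residue_budget: precursor residue-sum mass; the decoder input combines
// token embedding, index positional encoding, the prefix-mass sinusoid and
// a learned lift of the remaining-mass sinusoid
// mz: peak m/z values backing the first Npk memory columns (for the
// relative-mass attention bias); pass an empty vec to disable the bias
static mat decoder_fwd(Params& p, const Cfg& c, const mat& memory,
                       const arma::ivec& tokens, const vec& cum_mass,
                       double residue_budget, bool causal, DecCache& mc,
                       double drop = 0.0, std::mt19937_64* rng = nullptr,
                       const vec& mz = vec()) {
  int L = tokens.n_elem;
  mat X(c.d, L);
  for (int j = 0; j < L; j++) X.col(j) = p.at("tok_emb").col(tokens(j));
  X += pos_enc(L, c.d);
  X += multiscale_enc(cum_mass, c.d, c.lmin, c.lmax);
  vec rem = residue_budget - cum_mass;
  mc.Erem = multiscale_enc(rem, c.d, c.lmin, c.lmax);
  X += p.at("Wrem") * mc.Erem;
  mc.tokens = tokens;
  // cross-attention relative-mass bias: for query i (suffix mass s_i) and
  // peak j, three mass differences cover singly/doubly charged y ions and
  // (via the precursor complement) singly charged b ions; each head learns
  // a scalar function of these differences as sinusoid features
  mc.Npk = mz.n_elem;
  int Lk = memory.n_cols;
  bool use_bias = mc.Npk > 0 && p.m.count("dec0.cross.biasU") > 0;
  if (use_bias) {
    double prec2p = residue_budget + 18.010565 + 2.0 * 1.007276;
    mat F(3 * DB, L * mc.Npk);
    for (int j = 0; j < mc.Npk; j++) {
      vec d1 = mz(j) - cum_mass;              // y, charge 1
      vec d2 = 2.0 * mz(j) - cum_mass;        // y, charge 2
      vec d3 = (prec2p - mz(j)) - cum_mass;   // b, charge 1 (complement)
      mat f1 = multiscale_enc(d1, DB, BIAS_LMIN, BIAS_LMAX);
      mat f2 = multiscale_enc(d2, DB, BIAS_LMIN, BIAS_LMAX);
      mat f3 = multiscale_enc(d3, DB, BIAS_LMIN, BIAS_LMAX);
      for (int i = 0; i < L; i++) {
        F.submat(0, i + (arma::uword)L * j, DB - 1, i + (arma::uword)L * j) =
          f1.col(i);
        F.submat(DB, i + (arma::uword)L * j, 2 * DB - 1,
                 i + (arma::uword)L * j) = f2.col(i);
        F.submat(2 * DB, i + (arma::uword)L * j, 3 * DB - 1,
                 i + (arma::uword)L * j) = f3.col(i);
      }
    }
    mc.F = F;
    mc.bias.assign(c.n_dec, std::vector<mat>());
    for (int l = 0; l < c.n_dec; l++) {
      const mat& U = p.at("dec" + std::to_string(l) + ".cross.biasU");
      mc.bias[l].assign(c.H, mat(L, Lk, arma::fill::zeros));
      for (int h = 0; h < c.H; h++) {
        rowvec proj = U.col(h).t() * F;       // 1 x (L*Npk)
        for (int j = 0; j < mc.Npk; j++)
          for (int i = 0; i < L; i++)
            mc.bias[l][h](i, j) = proj(i + (arma::uword)L * j);
      }
    }
  }
  mc.layers.assign(c.n_dec, DecLayerCache());
  for (int l = 0; l < c.n_dec; l++) {
    std::string pre = "dec" + std::to_string(l) + ".";
    DecLayerCache& lc = mc.layers[l];
    mat Y1 = ln_fwd(X, p.at(pre + "ln1.g"), p.at(pre + "ln1.b"), lc.ln1);
    mat A1 = mha_fwd(p, pre + "self.", Y1, Y1, c.H, causal, lc.self);
    if (drop > 0 && rng) A1 = apply_dropout(A1, drop, *rng, lc.dm_self);
    X += A1;
    mat Y2 = ln_fwd(X, p.at(pre + "ln2.g"), p.at(pre + "ln2.b"), lc.ln2);
    mat A2 = mha_fwd(p, pre + "cross.", Y2, memory, c.H, false, lc.cross,
                     nullptr, mc.bias.size() ? &mc.bias[l] : nullptr);
    if (drop > 0 && rng) A2 = apply_dropout(A2, drop, *rng, lc.dm_cross);
    X += A2;
    mat Y3 = ln_fwd(X, p.at(pre + "ln3.g"), p.at(pre + "ln3.b"), lc.ln3);
    mat F = ff_fwd(p, pre + "ff.", Y3, lc.ff);
    if (drop > 0 && rng) F = apply_dropout(F, drop, *rng, lc.dm_ff);
    X += F;
  }
  mc.Xf = ln_fwd(X, p.at("dec_f.g"), p.at("dec_f.b"), mc.lnf);
  mat logits = p.at("Wout") * mc.Xf;
  logits.each_col() += p.at("bout").col(0);
  return logits;
}

// returns gradient wrt memory
static mat decoder_bwd(Params& p, Grads& g, const Cfg& c, DecCache& mc,
                       const mat& memory, const mat& dLogits) {
  g.at("Wout") += dLogits * mc.Xf.t();
  g.at("bout").col(0) += arma::sum(dLogits, 1);
  mat dXf = p.at("Wout").t() * dLogits;
  mat dX = ln_bwd(dXf, mc.lnf, p.at("dec_f.g"),
                  g.at("dec_f.g"), g.at("dec_f.b"));
  mat dMem(arma::size(memory), arma::fill::zeros);
  for (int l = c.n_dec - 1; l >= 0; l--) {
    std::string pre = "dec" + std::to_string(l) + ".";
    DecLayerCache& lc = mc.layers[l];
    mat dF = lc.dm_ff.n_elem ? mat(dX % lc.dm_ff) : dX;
    mat dZ = ff_bwd(p, g, pre + "ff.", lc.ff, dF);
    dX += ln_bwd(dZ, lc.ln3, p.at(pre + "ln3.g"),
                 g.at(pre + "ln3.g"), g.at(pre + "ln3.b"));
    mat dA2 = lc.dm_cross.n_elem ? mat(dX % lc.dm_cross) : dX;
    mat dY2(arma::size(dX), arma::fill::zeros);
    if (mc.bias.size()) {
      int L = dX.n_cols, Lk = memory.n_cols;
      std::vector<mat> dB(c.H, mat(L, Lk, arma::fill::zeros));
      mha_bwd(p, g, pre + "cross.", lc.cross, dA2, dY2, dMem, c.H, &dB);
      mat& gU = g.at(pre + "cross.biasU");
      for (int h = 0; h < c.H; h++) {
        vec dproj(L * mc.Npk);
        for (int j = 0; j < mc.Npk; j++)
          for (int i = 0; i < L; i++)
            dproj(i + (arma::uword)L * j) = dB[h](i, j);
        gU.col(h) += mc.F * dproj;
      }
    } else {
      mha_bwd(p, g, pre + "cross.", lc.cross, dA2, dY2, dMem, c.H);
    }
    dX += ln_bwd(dY2, lc.ln2, p.at(pre + "ln2.g"),
                 g.at(pre + "ln2.g"), g.at(pre + "ln2.b"));
    mat dA1 = lc.dm_self.n_elem ? mat(dX % lc.dm_self) : dX;
    mat dY1(arma::size(dX), arma::fill::zeros);
    mha_bwd(p, g, pre + "self.", lc.self, dA1, dY1, dY1, c.H);
    dX += ln_bwd(dY1, lc.ln1, p.at(pre + "ln1.g"),
                 g.at(pre + "ln1.g"), g.at(pre + "ln1.b"));
  }
  for (int j = 0; j < (int)mc.tokens.n_elem; j++)
    g.at("tok_emb").col(mc.tokens(j)) += dX.col(j);
  g.at("Wrem") += dX * mc.Erem.t();
  return dMem;
}

// ---------------------------------------------------------------------------
// per-example loss + gradient
// ---------------------------------------------------------------------------

struct Psm {
  vec mz, inten;
  double prec_mass;     // neutral precursor mass (Da)
  int charge;
  arma::ivec target;    // residue token ids (0-based), decoding order
};

// running residue-mass sums of a token sequence (includes current token)
static vec cum_masses_of(const arma::ivec& toks, const Cfg& c) {
  vec cm(toks.n_elem);
  double acc = 0;
  for (arma::uword i = 0; i < toks.n_elem; i++) {
    acc += c.masses(toks(i));
    cm(i) = acc;
  }
  return cm;
}

// cross-entropy over columns; accumulates scaled gradients; returns summed
// loss and (via n_correct) teacher-forced argmax hits
static double ce_loss_grad(const mat& logits, const arma::ivec& targets,
                           double scale, mat& dLogits, int& n_correct) {
  int L = logits.n_cols;
  dLogits.set_size(arma::size(logits));
  double loss = 0;
  for (int j = 0; j < L; j++) {
    vec z = logits.col(j);
    double mx = z.max();
    vec e = arma::exp(z - mx);
    double Z = arma::accu(e);
    vec pr = e / Z;
    int t = targets(j);
    loss += -(z(t) - mx - std::log(Z));
    if ((int)z.index_max() == t) n_correct++;
    vec dz = pr * scale;
    dz(t) -= scale;
    dLogits.col(j) = dz;
  }
  return loss;
}

// forward + backward for one PSM under the autoregressive objective
static double ar_example(Params& p, Grads* g, const Cfg& c, const Psm& s,
                         double scale, int& n_tok, int& n_correct,
                         double drop = 0.0, std::mt19937_64* rng = nullptr) {
  int n = s.target.n_elem;            // includes eos
  arma::ivec input(n);
  input(0) = c.sos;
  for (int i = 1; i < n; i++) input(i) = s.target(i - 1);
  vec cm(n); cm(0) = 0;
  for (int i = 1; i < n; i++) cm(i) = cm(i - 1) + c.masses(input(i));
  EncCache ec;
  mat memory = encoder_fwd(p, c, s.mz, s.inten, s.prec_mass, s.charge, ec,
                           nullptr, drop, rng);
  DecCache dc;
  mat logits = decoder_fwd(p, c, memory, input, cm,
                           s.prec_mass - 18.010565, true, dc, drop, rng,
                           s.mz);
  mat dLogits;
  double loss = ce_loss_grad(logits, s.target, scale, dLogits, n_correct);
  n_tok += n;
  if (g) {
    mat dMem = decoder_bwd(p, *g, c, dc, memory, dLogits);
    encoder_bwd(p, *g, c, ec, dMem);
  }
  return loss;
}

// forward + backward for one PSM under the diffusion (x0-prediction)
// objective, given a pre-sampled corrupted sequence x_t and timestep t
static double ref_example(Params& p, Grads* g, const Cfg& c, const Psm& s,
                          const arma::ivec& xt, int t, double scale,
                          int& n_tok, int& n_correct,
                          double drop = 0.0, std::mt19937_64* rng = nullptr) {
  EncCache ec;
  mat memory = encoder_fwd(p, c, s.mz, s.inten, s.prec_mass, s.charge, ec,
                           nullptr, drop, rng);
  mat mem_t(c.d, memory.n_cols + 1);
  mem_t.cols(0, memory.n_cols - 1) = memory;
  mem_t.col(memory.n_cols) = p.at("time_emb").col(t);
  vec cm = cum_masses_of(xt, c);
  DecCache dc;
  mat logits = decoder_fwd(p, c, mem_t, xt, cm,
                           s.prec_mass - 18.010565, false, dc, drop, rng,
                           s.mz);
  mat dLogits;
  double loss = ce_loss_grad(logits, s.target, scale, dLogits, n_correct);
  n_tok += s.target.n_elem;
  if (g) {
    mat dMemT = decoder_bwd(p, *g, c, dc, mem_t, dLogits);
    g->at("time_emb").col(t) += dMemT.col(memory.n_cols);
    mat dMem = dMemT.cols(0, memory.n_cols - 1);
    encoder_bwd(p, *g, c, ec, dMem);
  }
  return loss;
}

// ---------------------------------------------------------------------------
// parameter initialization
// ---------------------------------------------------------------------------

static mat rnorm_mat(int r, int cc, double sd, std::mt19937_64& rng) {
  std::normal_distribution<double> N(0.0, sd);
  mat M(r, cc);
  for (int j = 0; j < cc; j++)
    for (int i = 0; i < r; i++) M(i, j) = N(rng);
  return M;
}

static void add_param(Params& p, const std::string& k, mat v) {
  p.names.push_back(k);
  p.m[k] = std::move(v);
}

static void add_linear(Params& p, const std::string& pre, int dout, int din,
                       std::mt19937_64& rng) {
  double sd = std::sqrt(2.0 / (dout + din));
  add_param(p, pre + "W", rnorm_mat(dout, din, sd, rng));
  add_param(p, pre + "b", arma::zeros<mat>(dout, 1));
}

static void add_attn(Params& p, const std::string& pre, int d,
                     std::mt19937_64& rng) {
  double sd = std::sqrt(1.0 / d);
  for (std::string w : {"Wq", "Wk", "Wv", "Wo"})
    add_param(p, pre + w, rnorm_mat(d, d, sd, rng));
  for (std::string b : {"bq", "bk", "bv", "bo"})
    add_param(p, pre + b, arma::zeros<mat>(d, 1));
}

// [[Rcpp::export]]
List tf_init_params_cpp(List cfg_r, int seed) {
  Cfg c = read_cfg(cfg_r);
  std::mt19937_64 rng((uint64_t)seed);
  Params p;
  add_param(p, "w_int", rnorm_mat(c.d, 1, 0.02, rng));
  add_param(p, "Wcomp", rnorm_mat(c.d, c.d, std::sqrt(1.0 / c.d), rng));
  add_param(p, "Wrem", rnorm_mat(c.d, c.d, std::sqrt(1.0 / c.d), rng));
  add_param(p, "latent", rnorm_mat(c.d, 1, 0.02, rng));
  add_param(p, "charge_emb", rnorm_mat(c.d, c.n_charges + 1, 0.02, rng));
  auto ln_pair = [&](const std::string& pre) {
    add_param(p, pre + "g", arma::ones<mat>(c.d, 1));
    add_param(p, pre + "b", arma::zeros<mat>(c.d, 1));
  };
  for (int l = 0; l < c.n_enc; l++) {
    std::string pre = "enc" + std::to_string(l) + ".";
    ln_pair(pre + "ln1.");
    add_attn(p, pre + "attn.", c.d, rng);
    ln_pair(pre + "ln2.");
    add_param(p, pre + "ff.W1",
              rnorm_mat(c.ff, c.d, std::sqrt(2.0 / (c.ff + c.d)), rng));
    add_param(p, pre + "ff.b1", arma::zeros<mat>(c.ff, 1));
    add_param(p, pre + "ff.W2",
              rnorm_mat(c.d, c.ff, std::sqrt(2.0 / (c.ff + c.d)), rng));
    add_param(p, pre + "ff.b2", arma::zeros<mat>(c.d, 1));
  }
  ln_pair("enc_f.");
  add_param(p, "tok_emb", rnorm_mat(c.d, c.V, 0.02, rng));
  for (int l = 0; l < c.n_dec; l++) {
    std::string pre = "dec" + std::to_string(l) + ".";
    ln_pair(pre + "ln1.");
    add_attn(p, pre + "self.", c.d, rng);
    ln_pair(pre + "ln2.");
    add_attn(p, pre + "cross.", c.d, rng);
    add_param(p, pre + "cross.biasU", arma::zeros<mat>(3 * DB, c.H));
    ln_pair(pre + "ln3.");
    add_param(p, pre + "ff.W1",
              rnorm_mat(c.ff, c.d, std::sqrt(2.0 / (c.ff + c.d)), rng));
    add_param(p, pre + "ff.b1", arma::zeros<mat>(c.ff, 1));
    add_param(p, pre + "ff.W2",
              rnorm_mat(c.d, c.ff, std::sqrt(2.0 / (c.ff + c.d)), rng));
    add_param(p, pre + "ff.b2", arma::zeros<mat>(c.d, 1));
  }
  ln_pair("dec_f.");
  add_param(p, "Wout", rnorm_mat(c.V, c.d, std::sqrt(2.0 / (c.V + c.d)), rng));
  add_param(p, "bout", arma::zeros<mat>(c.V, 1));
  if (c.refiner)
    add_param(p, "time_emb", rnorm_mat(c.d, c.T + 1, 0.02, rng));
  return write_params(p);
}

// [[Rcpp::export]]
double tf_param_count_cpp(List params_r) {
  Params p = read_params(params_r);
  double n = 0;
  for (auto& k : p.names) n += p.m[k].n_elem;
  return n;
}

// ---------------------------------------------------------------------------
// training loop (Adam with global-norm gradient clipping)
// ---------------------------------------------------------------------------

static std::vector<Psm> read_data(List data_r) {
  std::vector<Psm> out(data_r.size());
  for (int i = 0; i < data_r.size(); i++) {
    List e = data_r[i];
    out[i].mz = as<vec>(e["mz"]);
    out[i].inten = as<vec>(e["intensity"]);
    out[i].prec_mass = as<double>(e["precursor_mass"]);
    out[i].charge = as<int>(e["precursor_charge"]);
    out[i].target = as<arma::ivec>(e["target"]);
  }
  return out;
}

// [[Rcpp::export]]
List tf_train_cpp(List params_r, List cfg_r, List data_r, List opt_r,
                  int epochs, double lr, int batch_size, double clip,
                  int seed, bool verbose, double dropout = 0.0,
                  double augment_ppm = 0.0, double augment_int_sd = 0.0) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  std::vector<Psm> data = read_data(data_r);
  int n = data.size();
  if (n == 0) stop("empty training set");

  // optimizer state
  std::unordered_map<std::string, mat> am, av;
  double step = 0;
  if (opt_r.size() > 0) {
    List mm = opt_r["m"], vv = opt_r["v"];
    step = as<double>(opt_r["step"]);
    CharacterVector nm = mm.names();
    for (int i = 0; i < mm.size(); i++) {
      std::string k = as<std::string>(nm[i]);
      am[k] = as<mat>(mm[i]);
      av[k] = as<mat>(vv[i]);
    }
  } else {
    for (auto& k : p.names) {
      am[k] = arma::zeros<mat>(arma::size(p.m[k]));
      av[k] = arma::zeros<mat>(arma::size(p.m[k]));
    }
  }

  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; i++) idx[i] = i;
  vec loss_trace(epochs), acc_trace(epochs);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;

  for (int ep = 0; ep < epochs; ep++) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0; int ep_tok = 0, ep_correct = 0;
    for (int b0 = 0; b0 < n; b0 += batch_size) {
      int b1i = std::min(b0 + batch_size, n);
      // per-example diffusion draws for this batch
      std::vector<arma::ivec> xts(b1i - b0);
      std::vector<int> ts(b1i - b0);
      int batch_tok = 0;
      for (int i = b0; i < b1i; i++) {
        batch_tok += data[idx[i]].target.n_elem;
        if (c.refiner) {
          const arma::ivec& x0 = data[idx[i]].target;
          std::uniform_int_distribution<int> Ut(1, c.T);
          int t = Ut(rng);
          ts[i - b0] = t;
          double ab = c.alpha_bar(t);
          arma::ivec xt(x0.n_elem);
          std::uniform_real_distribution<double> U(0.0, 1.0);
          std::uniform_int_distribution<int> Uk(0, c.residue_ids.n_elem - 1);
          for (arma::uword j = 0; j < x0.n_elem; j++)
            xt(j) = (U(rng) < ab) ? x0(j) : (int)c.residue_ids(Uk(rng));
          xts[i - b0] = xt;
        }
      }
      double scale = 1.0 / batch_tok;
      Grads g(p);
      for (int i = b0; i < b1i; i++) {
        Psm s = data[idx[i]];
        if (augment_ppm > 0) {
          // training-time m/z jitter: decorrelates the finest sinusoid
          // channels so the model cannot memorize exact peak masses
          std::uniform_real_distribution<double> Uj(-augment_ppm * 1e-6,
                                                    augment_ppm * 1e-6);
          for (arma::uword q = 0; q < s.mz.n_elem; q++)
            s.mz(q) *= (1.0 + Uj(rng));
        }
        if (augment_int_sd > 0) {
          // intensity jitter: a spectrum's fixed intensity pattern is
          // otherwise a memorizable fingerprint of its peptide
          std::normal_distribution<double> Nj(0.0, augment_int_sd);
          double mx = 0;
          for (arma::uword q = 0; q < s.inten.n_elem; q++) {
            s.inten(q) *= std::exp(Nj(rng));
            if (s.inten(q) > mx) mx = s.inten(q);
          }
          if (mx > 0) s.inten /= mx;
        }
        if (c.refiner)
          ep_loss += ref_example(p, &g, c, s, xts[i - b0], ts[i - b0],
                                 scale, ep_tok, ep_correct, dropout, &rng);
        else
          ep_loss += ar_example(p, &g, c, s, scale, ep_tok, ep_correct,
                                dropout, &rng);
      }
      // global-norm clip
      double nrm2 = 0;
      for (auto& kv : g.m) nrm2 += arma::accu(kv.second % kv.second);
      double nrm = std::sqrt(nrm2);
      double cs = (clip > 0 && nrm > clip) ? clip / nrm : 1.0;
      step += 1;
      double corr = std::sqrt(1 - std::pow(b2, step)) /
                    (1 - std::pow(b1, step));
      for (auto& kv : g.m) {
        const std::string& k = kv.first;
        mat gk = kv.second * cs;
        am[k] = b1 * am[k] + (1 - b1) * gk;
        av[k] = b2 * av[k] + (1 - b2) * (gk % gk);
        p.m[k] -= lr * corr * am[k] / (arma::sqrt(av[k]) + eps);
      }
    }
    loss_trace(ep) = ep_loss / ep_tok;
    acc_trace(ep) = (double)ep_correct / ep_tok;
    if (verbose)
      Rcout << "epoch " << (ep + 1) << "  loss " << loss_trace(ep)
            << "  token acc " << acc_trace(ep) << "\n";
    Rcpp::checkUserInterrupt();
  }

  List mm(p.names.size()), vv(p.names.size());
  CharacterVector nm(p.names.size());
  for (size_t i = 0; i < p.names.size(); i++) {
    nm[i] = p.names[i];
    mm[i] = wrap(am[p.names[i]]);
    vv[i] = wrap(av[p.names[i]]);
  }
  mm.names() = nm; vv.names() = nm;
  return List::create(
    _["params"] = write_params(p),
    _["opt"] = List::create(_["m"] = mm, _["v"] = vv, _["step"] = step),
    _["loss"] = wrap(loss_trace),
    _["token_accuracy"] = wrap(acc_trace));
}

// ---------------------------------------------------------------------------
// inference entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat tf_encode_cpp(List params_r, List cfg_r, arma::vec mz,
                        arma::vec intensity, double prec_mass, int charge,
                        Nullable<IntegerVector> peak_valid = R_NilValue) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  EncCache ec;
  if (peak_valid.isNotNull()) {
    IntegerVector pv(peak_valid);
    arma::uvec v(pv.size());
    for (int i = 0; i < pv.size(); i++) v(i) = pv[i];
    return encoder_fwd(p, c, mz, intensity, prec_mass, charge, ec, &v);
  }
  return encoder_fwd(p, c, mz, intensity, prec_mass, charge, ec);
}

// last-position next-token logits for a batch of prefixes (0-based residue
// ids, decoding order, WITHOUT the start token)
// [[Rcpp::export]]
arma::mat tf_next_logits_cpp(List params_r, List cfg_r, arma::mat memory,
                             double prec_mass, arma::vec mz,
                             List prefixes) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  int B = prefixes.size();
  mat out(c.V, B);
  for (int b = 0; b < B; b++) {
    arma::ivec pref = as<arma::ivec>(prefixes[b]);
    int L = pref.n_elem + 1;
    arma::ivec input(L);
    input(0) = c.sos;
    vec cm(L); cm(0) = 0;
    for (int i = 1; i < L; i++) {
      input(i) = pref(i - 1);
      cm(i) = cm(i - 1) + c.masses(input(i));
    }
    DecCache dc;
    mat logits = decoder_fwd(p, c, memory, input, cm,
                             prec_mass - 18.010565, true, dc, 0.0, nullptr,
                             mz);
    out.col(b) = logits.col(L - 1);
  }
  return out;
}

// all-position logits for one prefix (for causality tests / scoring)
// [[Rcpp::export]]
arma::mat tf_all_logits_cpp(List params_r, List cfg_r, arma::mat memory,
                            double prec_mass, arma::vec mz,
                            arma::ivec prefix) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  int L = prefix.n_elem + 1;
  arma::ivec input(L);
  input(0) = c.sos;
  vec cm(L); cm(0) = 0;
  for (int i = 1; i < L; i++) {
    input(i) = prefix(i - 1);
    cm(i) = cm(i - 1) + c.masses(input(i));
  }
  DecCache dc;
  return decoder_fwd(p, c, memory, input, cm, prec_mass - 18.010565, true,
                     dc, 0.0, nullptr, mz);
}

// refiner x0-prediction logits for a corrupted sequence x_t at timestep t
// [[Rcpp::export]]
arma::mat tf_refiner_logits_cpp(List params_r, List cfg_r, arma::mat memory,
                                double prec_mass, arma::vec mz,
                                arma::ivec xt, int t) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  mat mem_t(c.d, memory.n_cols + 1);
  mem_t.cols(0, memory.n_cols - 1) = memory;
  mem_t.col(memory.n_cols) = p.at("time_emb").col(t);
  vec cm(xt.n_elem);
  double acc = 0;
  for (arma::uword i = 0; i < xt.n_elem; i++) {
    acc += c.masses(xt(i));
    cm(i) = acc;
  }
  DecCache dc;
  return decoder_fwd(p, c, mem_t, xt, cm, prec_mass - 18.010565, false, dc,
                     0.0, nullptr, mz);
}

// loss and gradients for one example (finite-difference checks); for the
// refiner, xt and t must be supplied
// [[Rcpp::export]]
List tf_loss_grad_cpp(List params_r, List cfg_r, List psm_r, bool with_grads,
                      Nullable<IntegerVector> xt_r = R_NilValue, int t = 0) {
  Cfg c = read_cfg(cfg_r);
  Params p = read_params(params_r);
  List one(1); one[0] = psm_r;
  std::vector<Psm> d = read_data(one);
  int ntok = 0, ncor = 0;
  double scale = 1.0 / d[0].target.n_elem;
  Grads g(p);
  Grads* gp = with_grads ? &g : nullptr;
  double loss;
  if (c.refiner) {
    if (xt_r.isNull()) stop("refiner loss needs xt and t");
    arma::ivec xt = as<arma::ivec>(IntegerVector(xt_r));
    loss = ref_example(p, gp, c, d[0], xt, t, scale, ntok, ncor);
  } else {
    loss = ar_example(p, gp, c, d[0], scale, ntok, ncor);
  }
  loss /= d[0].target.n_elem;
  List gout;
  if (with_grads) {
    List gl(p.names.size());
    CharacterVector nm(p.names.size());
    for (size_t i = 0; i < p.names.size(); i++) {
      nm[i] = p.names[i];
      gl[i] = wrap(g.at(p.names[i]));
    }
    gl.names() = nm;
    gout = gl;
  }
  return List::create(_["loss"] = loss, _["grads"] = gout);
}

// ---------------------------------------------------------------------------
// knapsack reachability table
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
LogicalVector knapsack_build_cpp(NumericVector masses, double max_mass,
                                 double resolution) {
  long nb = (long)std::llround(max_mass / resolution) + 1;
  std::vector<char> reach(nb, 0);
  reach[0] = 1;
  std::vector<long> rb(masses.size());
  for (int k = 0; k < masses.size(); k++)
    rb[k] = (long)std::llround(masses[k] / resolution);
  for (long b = 0; b < nb; b++) {
    if (!reach[b]) continue;
    for (size_t k = 0; k < rb.size(); k++) {
      long nbp = b + rb[k];
      if (nbp < nb) reach[nbp] = 1;
    }
  }
  LogicalVector out(nb);
  for (long b = 0; b < nb; b++) out[b] = (bool)reach[b];
  return out;
}
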