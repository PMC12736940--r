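// Compiled kernel for the rigid-body frame embedding, phosphate positions
// and their analytic Jacobian. The coordinate layout and conventions mirror
// R/layout.R and R/geometry.R exactly:
//   w = (y_1, eta_1, ..., eta_{n-1}, y_n), eta = (crick P 6, inter 6,
//   watson P 6), each 6-block = (scaled Cayley rotation 3, translation 3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static mat skew3(const vec &v) {
  mat S(3, 3, arma::fill::zeros);
  S(0, 1) = -v(2); S(0, 2) = v(1);
  S(1, 0) = v(2);  S(1, 2) = -v(0);
  S(2, 0) = -v(1); S(2, 1) = v(0);
  return S;
}

static mat gibbs_to_rot(const vec &g) {
  mat S = skew3(g);
  double a = 2.0 / (1.0 + arma::dot(g, g));
  return arma::eye(3, 3) + a * (S + S * S);
}

static vec gibbs_half(const vec &g) {
  return g / (1.0 + std::sqrt(1.0 + arma::dot(g, g)));
}

static void dgibbs_rot(const vec &g, mat out[3]) {
  mat S = skew3(g);
  mat SS = S * S;
  double cc = 1.0 + arma::dot(g, g);
  double a = 2.0 / cc;
  for (int k = 0; k < 3; k++) {
    vec e(3, arma::fill::zeros); e(k) = 1.0;
    mat Ek = skew3(e);
    double da = -4.0 * g(k) / (cc * cc);
    out[k] = da * (S + SS) + a * (Ek + Ek * S + S * Ek);
  }
}

static void dgibbs_half_rot(const vec &g, mat out[3]) {
  double alpha = std::sqrt(1.0 + arma::dot(g, g));
  vec h = g / (1.0 + alpha);
  mat Jh = arma::eye(3, 3) / (1.0 + alpha) - (h * g.t()) / (alpha * (1.0 + alpha));
  mat dRh[3];
  dgibbs_rot(h, dRh);
  for (int k = 0; k < 3; k++) {
    out[k] = Jh(0, k) * dRh[0] + Jh(1, k) * dRh[1] + Jh(2, k) * dRh[2];
  }
}

// base-pair frames from inter coordinates (mid-frame composition)
static void bp_frames(const vec &w, int n, double s, const mat &anchorR,
                      const vec &anchorO, cube &G, mat &o) {
  G.slice(0) = anchorR;
  o.col(0) = anchorO;
  for (int a = 0; a < n - 1; a++) {
    int off = a * 24 + 12;
    vec g = w.subvec(off, off + 2) / s;
    vec v = w.subvec(off + 3, off + 5);
    mat Lam = gibbs_to_rot(g);
    mat S = gibbs_to_rot(gibbs_half(g));
    o.col(a + 1) = o.col(a) + G.slice(a) * (S * v);
    G.slice(a + 1) = G.slice(a) * Lam;
  }
}

static const double FLIPD[3] = {1.0, -1.0, -1.0};

// [[Rcpp::export]]
List cpp_embed(const arma::vec &w, int n, double s, const arma::mat &anchorR,
               const arma::vec &anchorO) {
  cube G(3, 3, n);
  mat o(3, n);
  bp_frames(w, n, s, anchorR, anchorO, G, o);
  cube Rw(3, 3, n), Rc(3, 3, n);
  mat rw(3, n), rc(3, n);
  mat FLIP = arma::diagmat(vec(std::vector<double>(FLIPD, FLIPD + 3)));
  for (int a = 0; a < n; a++) {
    int off = a * 24;
    vec gi = w.subvec(off, off + 2) / s;
    vec ti = w.subvec(off + 3, off + 5);
    mat P = gibbs_to_rot(gibbs_half(gi));
    Rw.slice(a) = G.slice(a) * P;
    Rc.slice(a) = G.slice(a) * P.t() * FLIP;
    rw.col(a) = o.col(a) + G.slice(a) * (ti / 2.0);
    rc.col(a) = o.col(a) - G.slice(a) * (ti / 2.0);
  }
  cube pwR(3, 3, n - 1), pcR(3, 3, n - 1);
  mat pwo(3, n - 1), pco(3, n - 1);
  for (int a = 0; a < n - 1; a++) {
    int off = a * 24;
    vec gw = w.subvec(off + 18, off + 20) / s;
    vec qw = w.subvec(off + 21, off + 23);
    pwo.col(a) = rw.col(a + 1) + Rw.slice(a + 1) * qw;
    pwR.slice(a) = Rw.slice(a + 1) * gibbs_to_rot(gw);
    vec gc = w.subvec(off + 6, off + 8) / s;
    vec qc = w.subvec(off + 9, off + 11);
    pco.col(a) = rc.col(a) + Rc.slice(a) * qc;
    pcR.slice(a) = Rc.slice(a) * gibbs_to_rot(gc);
  }
  return List::create(
    Named("bp_R") = G, Named("bp_o") = o,
    Named("watson_R") = Rw, Named("watson_o") = rw,
    Named("crick_R") = Rc, Named("crick_o") = rc,
    Named("phosW_R") = pwR, Named("phosW_o") = pwo,
    Named("phosC_R") = pcR, Named("phosC_o") = pco);
}

// strand: 1 = watson, 2 = crick; junction: 1-based
// [[Rcpp::export]]
arma::mat cpp_phos_positions(const arma::vec &w, int n, double s,
                             const arma::mat &anchorR, const arma::vec &anchorO,
                             const arma::ivec &strand,
                             const arma::ivec &junction) {
  cube G(3, 3, n);
  mat o(3, n);
  bp_frames(w, n, s, anchorR, anchorO, G, o);
  int m = strand.n_elem;
  mat P(3, m);
  mat FLIP = arma::diagmat(vec(std::vector<double>(FLIPD, FLIPD + 3)));
  for (int i = 0; i < m; i++) {
    int a = junction(i) - 1;        // 0-based junction
    int b = (strand(i) == 1) ? a + 1 : a;  // attach base pair (0-based)
    int off = b * 24;
    vec gi = w.subvec(off, off + 2) / s;
    vec ti = w.subvec(off + 3, off + 5);
    mat Ph = gibbs_to_rot(gibbs_half(gi));
    if (strand(i) == 1) {
      vec q = w.subvec(a * 24 + 21, a * 24 + 23);
      P.col(i) = o.col(b) + G.slice(b) * (ti / 2.0) + G.slice(b) * Ph * q;
    } else {
      vec q = w.subvec(a * 24 + 9, a * 24 + 11);
      P.col(i) = o.col(b) - G.slice(b) * (ti / 2.0) + G.slice(b) * Ph.t() * (FLIP * q);
    }
  }
  return P;
}

// Positions plus the exact Jacobian d p / d w, rows (3i, 3i+1, 3i+2) per
// constraint i. An inter perturbation at junction a rotates all downstream
// material rigidly about the origin of base pair a+1 (world axis
// G_{a+1} vee(Lam' dLam)) and translates it by the mid-frame kick
// G_a dS v; intra and own-phosphate coordinates act locally.
// [[Rcpp::export]]
List cpp_phos_jacobian(const arma::vec &w, int n, double s,
                       const arma::mat &anchorR, const arma::vec &anchorO,
                       const arma::ivec &strand, const arma::ivec &junction) {
  int N = 24 * n - 18;
  int m = strand.n_elem;
  cube G(3, 3, n);
  mat o(3, n);
  bp_frames(w, n, s, anchorR, anchorO, G, o);
  mat FLIP = arma::diagmat(vec(std::vector<double>(FLIPD, FLIPD + 3)));

  arma::ivec batt(m);
  mat P(3, m);
  for (int i = 0; i < m; i++) {
    int a = junction(i) - 1;
    int b = (strand(i) == 1) ? a + 1 : a;
    batt(i) = b;
    int off = b * 24;
    vec gi = w.subvec(off, off + 2) / s;
    vec ti = w.subvec(off + 3, off + 5);
    mat Ph = gibbs_to_rot(gibbs_half(gi));
    if (strand(i) == 1) {
      vec q = w.subvec(a * 24 + 21, a * 24 + 23);
      P.col(i) = o.col(b) + G.slice(b) * (ti / 2.0) + G.slice(b) * Ph * q;
    } else {
      vec q = w.subvec(a * 24 + 9, a * 24 + 11);
      P.col(i) = o.col(b) - G.slice(b) * (ti / 2.0) + G.slice(b) * Ph.t() * (FLIP * q);
    }
  }
  mat J(3 * m, N, arma::fill::zeros);
  int maxb = batt.max();
  // inter coordinates
  for (int a = 0; a < maxb; a++) {
    int off = a * 24 + 12;
    vec g = w.subvec(off, off + 2) / s;
    vec v = w.subvec(off + 3, off + 5);
    mat Lam = gibbs_to_rot(g);
    mat S = gibbs_to_rot(gibbs_half(g));
    mat dLam[3], dS[3];
    dgibbs_rot(g, dLam);
    dgibbs_half_rot(g, dS);
    mat M = G.slice(a) * S;
    for (int k = 0; k < 3; k++) {
      mat A = Lam.t() * dLam[k];
      vec sig = {A(2, 1), A(0, 2), A(1, 0)};
      vec omega = G.slice(a + 1) * sig;
      vec tk = G.slice(a) * (dS[k] * v);
      for (int i = 0; i < m; i++) {
        if (batt(i) <= a) continue;
        vec D = P.col(i) - o.col(a + 1);
        J(3 * i + 0, off + k) = (omega(1) * D(2) - omega(2) * D(1) + tk(0)) / s;
        J(3 * i + 1, off + k) = (omega(2) * D(0) - omega(0) * D(2) + tk(1)) / s;
        J(3 * i + 2, off + k) = (omega(0) * D(1) - omega(1) * D(0) + tk(2)) / s;
        for (int r = 0; r < 3; r++) J(3 * i + r, off + 3 + k) = M(r, k);
      }
    }
  }
  // intra and own-phosphate coordinates
  for (int i = 0; i < m; i++) {
    int a = junction(i) - 1;
    int b = batt(i);
    int off = b * 24;
    vec gi = w.subvec(off, off + 2) / s;
    mat dP[3];
    dgibbs_half_rot(gi, dP);
    mat Ph = gibbs_to_rot(gibbs_half(gi));
    if (strand(i) == 1) {
      vec q = w.subvec(a * 24 + 21, a * 24 + 23);
      mat Rb = G.slice(b) * Ph;
      for (int k = 0; k < 3; k++) {
        vec col = G.slice(b) * (dP[k] * q) / s;
        for (int r = 0; r < 3; r++) {
          J(3 * i + r, off + k) = col(r);
          J(3 * i + r, off + 3 + k) = 0.5 * G(r, k, b);
          J(3 * i + r, a * 24 + 21 + k) = Rb(r, k);
        }
      }
    } else {
      vec q = w.subvec(a * 24 + 9, a * 24 + 11);
      vec Fq = FLIP * q;
      mat Rb = G.slice(b) * Ph.t() * FLIP;
      for (int k = 0; k < 3; k++) {
        vec col = G.slice(b) * (dP[k].t() * Fq) / s;
        for (int r = 0; r < 3; r++) {
          J(3 * i + r, off + k) = col(r);
          J(3 * i + r, off + 3 + k) = -0.5 * G(r, k, b);
          J(3 * i + r, a * 24 + 9 + k) = Rb(r, k);
        }
      }
    }
  }
  return List::create(Named("pos") = P, Named("J") = J);
}
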