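// Three-pool Bloch-McConnell transient core.
//
// State ordering (7): Mx_w, My_w, Mz_w, Mx_s, My_s, Mz_s, Mz_m.
// The semisolid pool carries longitudinal magnetization only; its RF
// saturation enters as the absorption rate Rrf_m = pi * w1^2 * g, with the
// lineshape value g supplied by the caller (single lineshape implementation
// lives on the R side).
//
// Tissue parameter column ordering (11), native units:
//   t1w [s], t1t2_ratio [-], kmw [Hz], m0m [M], t2m [us], dmw [ppm],
//   ksw [Hz], m0s [mM], t2s [s], db0 [Hz], rb1 [-]
// Scan parameter column ordering (4): b1 [uT], offset [ppm], ts [s], td [s]

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

static const double GAMMA_UT = 267.522;   // rad s^-1 uT^-1
static const double HZ_PER_PPM = 127.73;  // at 3 T
static const double WATER_MM = 111000.0;  // water proton concentration, mM
static const double TWO_PI = 6.283185307179586;
static const double SOLUTE_PPM = 3.5;     // amide resonance

// Fill A (7x7, s^-1), B (7, s^-1) and the equilibrium vector Meq for one
// tissue/scan pair. Rotating frame of the RF; dB0 adds to all pool
// frequencies; the semisolid resonance sits at -dmw ppm (upfield).
static void bm_fill(const double* pt, const double* ps, double g,
                    double r1s, double r1m,
                    arma::mat& A, arma::vec& B, arma::vec& Meq) {
  const double t1w = pt[0], ratio = pt[1], kmw = pt[2], m0m = pt[3];
  const double dmw = pt[5], ksw = pt[6], m0s = pt[7], t2s = pt[8];
  const double db0 = pt[9], rb1 = pt[10];
  const double b1 = ps[0], omega = ps[1];

  const double fs = m0s / WATER_MM;          // solute pool fraction
  const double fm = m0m / (WATER_MM / 1000.0); // semisolid fraction (M / 111)
  const double kws = ksw * fs;               // detailed balance, fw = 1
  const double kwm = kmw * fm;

  const double r1w = 1.0 / t1w;
  const double r2w = ratio / t1w;            // 1/T2w with T2w = T1w/ratio
  const double r2s = 1.0 / t2s;

  const double w1 = GAMMA_UT * rb1 * b1;     // rad/s
  const double dw = TWO_PI * (db0 - omega * HZ_PER_PPM);
  const double ds = TWO_PI * (SOLUTE_PPM * HZ_PER_PPM + db0 - omega * HZ_PER_PPM);
  const double rrfm = M_PI * w1 * w1 * g;

  A.zeros(7, 7);
  // water transverse
  A(0, 0) = -(r2w + kws); A(0, 1) = dw;          A(0, 3) = ksw;
  A(1, 0) = -dw;          A(1, 1) = -(r2w + kws); A(1, 2) = w1; A(1, 4) = ksw;
  // water longitudinal
  A(2, 1) = -w1; A(2, 2) = -(r1w + kws + kwm); A(2, 5) = ksw; A(2, 6) = kmw;
  // solute transverse
  A(3, 0) = kws; A(3, 3) = -(r2s + ksw); A(3, 4) = ds;
  A(4, 1) = kws; A(4, 3) = -ds; A(4, 4) = -(r2s + ksw); A(4, 5) = w1;
  // solute longitudinal
  A(5, 2) = kws; A(5, 4) = -w1; A(5, 5) = -(r1s + ksw);
  // semisolid longitudinal (RF saturation via rrfm)
  A(6, 2) = kwm; A(6, 6) = -(r1m + kmw + rrfm);

  B.zeros(7);
  B(2) = r1w * 1.0;
  B(5) = r1s * fs;
  B(6) = r1m * fm;

  Meq.zeros(7);
  Meq(2) = 1.0; Meq(5) = fs; Meq(6) = fm;
}

// Closed-form transient solution for one pair; returns the 7-state at the
// end of saturation: M = expm(A*Ts) (M0(1-e^{-R1w Td}) + A^-1 B) - A^-1 B.
static arma::vec bm_solve(const double* pt, const double* ps, double g,
                          double r1s, double r1m) {
  arma::mat A(7, 7);
  arma::vec B(7), Meq(7);
  bm_fill(pt, ps, g, r1s, r1m, A, B, Meq);
  const double ts = ps[2], td = ps[3];
  const double r1w = 1.0 / pt[0];
  arma::vec AinvB = arma::solve(A, B);
  arma::vec Minit = Meq * (1.0 - std::exp(-r1w * td));
  arma::vec M = arma::expmat(A * ts) * (Minit + AinvB) - AinvB;
  return M;
}

// [[Rcpp::export]]
Rcpp::List bm_system_cpp(Rcpp::NumericVector pt, Rcpp::NumericVector ps,
                         double g, double r1s, double r1m) {
  arma::mat A(7, 7);
  arma::vec B(7), Meq(7);
  bm_fill(pt.begin(), ps.begin(), g, r1s, r1m, A, B, Meq);
  return Rcpp::List::create(Rcpp::Named("A") = A,
                            Rcpp::Named("B") = B,
                            Rcpp::Named("Meq") = Meq);
}

// [[Rcpp::export]]
arma::vec bm_evolve_cpp(Rcpp::NumericVector pt, Rcpp::NumericVector ps,
                        double g, double r1s, double r1m) {
  return bm_solve(pt.begin(), ps.begin(), g, r1s, r1m);
}

// Batch signal synthesis: n tissue rows x m scan rows, G is n x m lineshape
// values. Returns normalized water Mz (S/S0) as an n x m matrix.
// [[Rcpp::export]]
arma::mat bm_signal_batch_cpp(const arma::mat& Pt, const arma::mat& Ps,
                              const arma::mat& G, double r1s, double r1m) {
  const arma::uword n = Pt.n_rows, m = Ps.n_rows;
  arma::mat S(n, m);
  arma::mat Ptt = Pt.t(), Pst = Ps.t(); // column-major access per row
  for (arma::uword i = 0; i < n; ++i) {
    const double* pt = Ptt.colptr(i);
    for (arma::uword j = 0; j < m; ++j) {
      arma::vec M = bm_solve(pt, Pst.colptr(j), G(i, j), r1s, r1m);
      S(i, j) = M(2);
    }
  }
  return S;
}

// Paired signal synthesis: row i of Pt with row i of Ps (training-set path).
// [[Rcpp::export]]
arma::vec bm_signal_pairs_cpp(const arma::mat& Pt, const arma::mat& Ps,
                              const arma::vec& g, double r1s, double r1m) {
  const arma::uword n = Pt.n_rows;
  arma::vec s(n);
  arma::mat Ptt = Pt.t(), Pst = Ps.t();
  for (arma::uword i = 0; i < n; ++i) {
    arma::vec M = bm_solve(Ptt.colptr(i), Pst.colptr(i), g(i), r1s, r1m);
    s(i) = M(2);
  }
  return s;
}
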