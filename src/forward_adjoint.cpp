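// Time-critical kernels: sequential implicit-Euler integration of the
// five-class Galerkin ODE system, and the exact discrete adjoint of that
// scheme used for cost gradients.  All operator blocks that do not depend
// on the EPO concentration are assembled once in R and passed in `prec`.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Model {
  int N;
  mat A1, K2base, A3, V4adv, A4const, B5, Xneo;
  mat d, b;               // N x 5 influx representers / boundary rows
  double S0, tauE, eps, epsR, beta2;
  vec mu;                 // 10 sigmoid/mortality shape parameters
  // derived, built once per call
  mat inv1, inv1t, inv3, inv3t;        // constant-class step inverses
  mat M2base, M4base, M5base, dtV4, dtXneo;
  vec d1S;                             // dt * S0 * d1
};

Model unpack(const Rcpp::List& prec, double dt) {
  Model m;
  m.N = Rcpp::as<int>(prec["N"]);
  m.A1 = Rcpp::as<mat>(prec["A1"]);
  m.K2base = Rcpp::as<mat>(prec["K2base"]);
  m.A3 = Rcpp::as<mat>(prec["A3"]);
  m.V4adv = Rcpp::as<mat>(prec["V4adv"]);
  m.A4const = Rcpp::as<mat>(prec["A4const"]);
  m.B5 = Rcpp::as<mat>(prec["B5"]);
  m.Xneo = Rcpp::as<mat>(prec["Xneo"]);
  m.d = Rcpp::as<mat>(prec["d"]);
  m.b = Rcpp::as<mat>(prec["b"]);
  m.S0 = Rcpp::as<double>(prec["S0"]);
  m.tauE = Rcpp::as<double>(prec["tau_E"]);
  m.eps = Rcpp::as<double>(prec["epsilon"]);
  m.epsR = Rcpp::as<double>(prec["epsilon_R"]);
  m.beta2 = Rcpp::as<double>(prec["beta2"]);
  m.mu = Rcpp::as<vec>(prec["mu"]);
  mat I = eye(m.N, m.N);
  m.inv1 = inv(I - dt * m.A1);
  m.inv1t = m.inv1.t();
  m.inv3 = inv(I - dt * m.A3);
  m.inv3t = m.inv3.t();
  m.M2base = I - dt * m.K2base;
  m.M4base = I - dt * m.A4const;
  m.M5base = I - dt * m.B5;
  m.dtV4 = dt * m.V4adv;
  m.dtXneo = dt * m.Xneo;
  m.d1S = dt * m.S0 * m.d.col(0);
  return m;
}

// C^2 regularized Heaviside and its derivative (polynomial transition band).
double Hreg(double s, double e) {
  if (s <= 0) return 0.0;
  if (s >= e) return 1.0;
  double s2 = s * s;
  return s2 * s2 / std::pow(e, 6) * (10 * s2 - 24 * e * s + 15 * e * e);
}
double Hreg_d(double s, double e) {
  if (s <= 0 || s >= e) return 0.0;
  double t = s - e;
  return 60.0 * s * s * s * t * t / std::pow(e, 6);
}

double alpha2_of(double E, const Model& m) {
  return m.mu(0) / (1.0 + std::exp(m.mu(1) * E - m.mu(2)));
}
double alpha2_d_of(double E, const Model& m) {
  double z = std::exp(m.mu(1) * E - m.mu(2));
  return -m.mu(0) * m.mu(1) * z / ((1.0 + z) * (1.0 + z));
}
double nu_of(double E, const Model& m) {
  return (m.mu(3) - m.mu(4)) / (1.0 + std::exp(-m.mu(5) * E + m.mu(6))) + m.mu(4);
}
double nu_d_of(double E, const Model& m) {
  double z = std::exp(-m.mu(5) * E + m.mu(6));
  return (m.mu(3) - m.mu(4)) * m.mu(5) * z / ((1.0 + z) * (1.0 + z));
}
// Regularized neocytolysis excess m(E) = H(tauE - E) * F(mu8 E^-mu9, mu10)
void neo_of(double E, const Model& m, double& val, double& der) {
  double q = std::exp(std::log(m.mu(7)) - m.mu(8) * std::log(E));
  double dq = -m.mu(8) * q / E;
  double H = Hreg(m.tauE - E, m.eps);
  double dH = -Hreg_d(m.tauE - E, m.eps);
  double HF = Hreg(m.mu(9) - q, m.epsR);
  double dHF = Hreg_d(m.mu(9) - q, m.epsR);
  double F = (q - m.mu(9)) * HF + m.mu(9);
  double dF = (HF - (q - m.mu(9)) * dHF) * dq;
  val = H * F;
  der = dH * F + H * dF;
}

// In-place Gaussian elimination with partial pivoting for the small dense
// per-class systems (N ~ 15): avoids LAPACK call overhead and workspace
// allocation inside the time loop.  M and b are overwritten; b becomes x.
inline void ge_solve(mat& M, double* b) {
  int n = M.n_rows;
  for (int k = 0; k < n; ++k) {
    int piv = k; double mx = std::abs(M(k, k));
    for (int i = k + 1; i < n; ++i) {
      double v = std::abs(M(i, k));
      if (v > mx) { mx = v; piv = i; }
    }
    if (piv != k) { M.swap_rows(k, piv); std::swap(b[k], b[piv]); }
    double di = 1.0 / M(k, k);
    for (int i = k + 1; i < n; ++i) {
      double f = M(i, k) * di;
      if (f != 0.0) {
        for (int j = k + 1; j < n; ++j) M(i, j) -= f * M(k, j);
        b[i] -= f * b[k];
      }
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double sum = b[k];
    for (int j = k + 1; j < n; ++j) sum -= M(k, j) * b[j];
    b[k] = sum / M(k, k);
  }
}

// One forward step in place; y is N x 5, E the step-end EPO level.
// y1_frozen: the BFU-E class is autonomous (independent of E and of the
// other classes); when it starts in its own equilibrium it stays there and
// its solve can be skipped.
struct StepScal { double nu, neo; };

struct Work { mat Mbuf; vec tmp; };

inline StepScal forward_step(mat& y, double E, double dt, const Model& m,
                             bool y1_frozen, Work& wk) {
  StepScal s;
  int N = m.N;
  if (!y1_frozen) {
    wk.tmp = y.col(0) + m.d1S;
    y.col(0) = m.inv1 * wk.tmp;
  }
  double g2 = dot(m.b.col(0), y.col(0));
  wk.Mbuf = m.M2base;
  wk.Mbuf.diag() += dt * (alpha2_of(E, m) - m.beta2);
  y.col(1) += dt * g2 * m.d.col(1);
  ge_solve(wk.Mbuf, y.colptr(1));
  double g3 = dot(m.b.col(1), y.col(1));
  wk.tmp = y.col(2) + dt * g3 * m.d.col(2);
  y.col(2) = m.inv3 * wk.tmp;
  s.nu = nu_of(E, m);
  wk.Mbuf = m.M4base;
  for (int idx = 0; idx < N * N; ++idx)
    wk.Mbuf.memptr()[idx] -= s.nu * m.dtV4.memptr()[idx];
  double g4 = dot(m.b.col(2), y.col(2)) / s.nu;
  y.col(3) += dt * g4 * m.d.col(3);
  ge_solve(wk.Mbuf, y.colptr(3));
  double neod;
  neo_of(E, m, s.neo, neod);
  wk.Mbuf = m.M5base;
  if (s.neo != 0.0)
    for (int idx = 0; idx < N * N; ++idx)
      wk.Mbuf.memptr()[idx] -= s.neo * m.dtXneo.memptr()[idx];
  double g5 = s.nu * dot(m.b.col(3), y.col(3));
  y.col(4) += dt * g5 * m.d.col(4);
  ge_solve(wk.Mbuf, y.colptr(4));
  return s;
}

inline bool check_y1_frozen(const mat& y0, const Model& m) {
  vec r = m.inv1 * (y0.col(0) + m.d1S) - y0.col(0);
  double sc = norm(y0.col(0));
  return norm(r) <= 1e-12 * (1.0 + sc);
}

} // namespace

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_simulate(const arma::mat& y0, const arma::vec& Evec,
                        const Rcpp::List& prec, double dt,
                        bool keep_states) {
  Model m = unpack(prec, dt);
  int K = Evec.n_elem;
  mat y = y0;
  vec P(K + 1);
  double sw5 = Rcpp::as<double>(prec["sqrtw5"]);
  P(0) = sw5 * y(0, 4);
  bool frozen = check_y1_frozen(y0, m);
  Work wk; wk.Mbuf.set_size(m.N, m.N); wk.tmp.set_size(m.N);
  cube states;
  if (keep_states) { states.set_size(m.N, 5, K + 1); states.slice(0) = y; }
  for (int k = 1; k <= K; ++k) {
    forward_step(y, Evec(k - 1), dt, m, frozen, wk);
    P(k) = sw5 * y(0, 4);
    if (keep_states) states.slice(k) = y;
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("P") = P, Rcpp::Named("final") = y);
  if (keep_states) out["states"] = states;
  return out;
}

//' @noRd
// [[Rcpp::export]]
Rcpp::List cpp_cost_grad(const arma::mat& y0, const arma::vec& Evec,
                         const Rcpp::List& prec, double dt,
                         double sigO, double sigF, double a, double h0,
                         bool want_grad) {
  Model m = unpack(prec, dt);
  int N = m.N, K = Evec.n_elem;
  double sw5 = Rcpp::as<double>(prec["sqrtw5"]);
  bool frozen = check_y1_frozen(y0, m);
  vec P(K + 1);
  P(0) = sw5 * y0(0, 4);
  double Jtrack = 0.0;
  auto accum = [&](int k, double y50) {
    double ck = (k == 0 || k == K) ? 0.5 : 1.0;
    double ek = a * y50 - h0;
    Jtrack += 0.5 * sigO * dt * ck * ek * ek;
    if (k == K) Jtrack += 0.5 * sigF * ek * ek;
  };

  Work wk; wk.Mbuf.set_size(N, N); wk.tmp.set_size(N);
  if (!want_grad) {                    // lean pass: no state storage
    mat y = y0;
    accum(0, y(0, 4));
    for (int k = 1; k <= K; ++k) {
      forward_step(y, Evec(k - 1), dt, m, frozen, wk);
      P(k) = sw5 * y(0, 4);
      accum(k, y(0, 4));
    }
    return Rcpp::List::create(
      Rcpp::Named("J") = Jtrack, Rcpp::Named("P") = P,
      Rcpp::Named("final") = y);
  }

  cube states(N, 5, K + 1);
  states.slice(0) = y0;
  accum(0, y0(0, 4));
  {
    mat y = y0;
    for (int k = 1; k <= K; ++k) {
      forward_step(y, Evec(k - 1), dt, m, frozen, wk);
      P(k) = sw5 * y(0, 4);
      states.slice(k) = y;
      accum(k, y(0, 4));
    }
  }

  // Discrete adjoint: backward in time, classes 5 -> 2 within each step.
  // The BFU-E adjoint p1 never enters the gradient (its equation has no
  // EPO dependence) and is skipped.
  vec p2(N, fill::zeros), p3(N, fill::zeros), p4(N, fill::zeros),
      p5(N, fill::zeros);
  vec e1(N, fill::zeros); e1(0) = 1.0;
  vec gE(K, fill::zeros);
  for (int k = K; k >= 1; --k) {
    double E = Evec(k - 1);
    double kap2 = m.beta2 - alpha2_of(E, m);
    double a2d = alpha2_d_of(E, m);
    double nu = nu_of(E, m), nud = nu_d_of(E, m);
    double neo, neod;
    neo_of(E, m, neo, neod);
    double ck = (k == K) ? 0.5 : 1.0;
    double ek = a * states(0, 4, k) - h0;
    double w5g = a * sigO * dt * ck * ek + ((k == K) ? a * sigF * ek : 0.0);
    wk.Mbuf = trans(m.M5base - neo * m.dtXneo);
    p5 -= w5g * e1;
    ge_solve(wk.Mbuf, p5.memptr());
    wk.Mbuf = trans(m.M4base - nu * m.dtV4);
    p4 += dt * nu * dot(m.d.col(4), p5) * m.b.col(3);
    ge_solve(wk.Mbuf, p4.memptr());
    wk.tmp = p3 + dt * (dot(m.d.col(3), p4) / nu) * m.b.col(2);
    p3 = m.inv3t * wk.tmp;
    wk.Mbuf = trans(m.M2base);
    wk.Mbuf.diag() -= dt * kap2;
    p2 += dt * dot(m.d.col(2), p3) * m.b.col(1);
    ge_solve(wk.Mbuf, p2.memptr());
    const mat& yk = states.slice(k);
    double g4raw = dot(m.b.col(2), yk.col(2));   // = nu * g4
    gE(k - 1) =
        dt * a2d * dot(p2, yk.col(1))
      - dt * nud * dot(p4, m.V4adv * yk.col(3))
      - dt * neod * dot(p5, m.Xneo * yk.col(4))
      + dt * dot(m.d.col(3), p4) * g4raw * nud / (nu * nu)
      - dt * dot(m.d.col(4), p5) * nud * dot(m.b.col(3), yk.col(3));
  }
  return Rcpp::List::create(
    Rcpp::Named("J") = Jtrack, Rcpp::Named("P") = P,
    Rcpp::Named("final") = states.slice(K), Rcpp::Named("gE") = gE);
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_step(const arma::mat& y0, double E, const Rcpp::List& prec,
                   double dt) {
  Model m = unpack(prec, dt);
  Work wk; wk.Mbuf.set_size(m.N, m.N); wk.tmp.set_size(m.N);
  mat y = y0;
  forward_step(y, E, dt, m, false, wk);
  return y;
}
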