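// Hindmarsh-Rose multiplex dynamics, variational equations and the
// Benettin tangent-space QR method. State ordering: p[0..N-1], q[..], n[..].
// Params vector: a, b, c, d, s, p0, r, Iext, theta_syn, lambda_sig, Vsyn.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct HRSys {
  double a, b, c, d, s, p0, r, Iext, theta, lam, Vsyn;
  mat LB;   // N x N intra (electrical) block-diagonal Laplacian, eps folded out
  mat A;    // N x N symmetric inter (chemical) adjacency
  double eps, gam;
  int N;

  HRSys(const vec& par, const mat& LB_, const mat& A_, double eps_, double gam_)
    : a(par[0]), b(par[1]), c(par[2]), d(par[3]), s(par[4]), p0(par[5]),
      r(par[6]), Iext(par[7]), theta(par[8]), lam(par[9]), Vsyn(par[10]),
      LB(LB_), A(A_), eps(eps_), gam(gam_), N((int)LB_.n_rows) {}

  vec sigmoid(const vec& p) const {
    return 1.0 / (1.0 + exp(-lam * (p - theta)));
  }

  void rhs(const vec& x, vec& dx) const {
    vec p = x.subvec(0, N - 1);
    vec q = x.subvec(N, 2 * N - 1);
    vec n = x.subvec(2 * N, 3 * N - 1);
    vec K = sigmoid(p);
    vec chem = A * K;
    dx.set_size(3 * N);
    dx.subvec(0, N - 1) = q - a * pow(p, 3) + b * square(p) - n + Iext
      - eps * (LB * p) - gam * ((p - Vsyn) % chem);
    dx.subvec(N, 2 * N - 1) = c - d * square(p) - q;
    dx.subvec(2 * N, 3 * N - 1) = r * (s * (p - p0) - n);
  }

  // full 3N x 3N Jacobian at x
  void jac(const vec& x, mat& J) const {
    vec p = x.subvec(0, N - 1);
    vec K = sigmoid(p);
    vec Kp = lam * (K % (1.0 - K));
    vec chem = A * K;
    J.zeros(3 * N, 3 * N);
    // d(pdot)/dp
    J.submat(0, 0, N - 1, N - 1) = -eps * LB;
    for (int i = 0; i < N; ++i) {
      J(i, i) += -3.0 * a * p[i] * p[i] + 2.0 * b * p[i] - gam * chem[i];
      for (int j = 0; j < N; ++j) {
        if (A(i, j) != 0.0)
          J(i, j) += -gam * (p[i] - Vsyn) * A(i, j) * Kp[j];
      }
      J(i, N + i) = 1.0;        // d(pdot)/dq
      J(i, 2 * N + i) = -1.0;   // d(pdot)/dn
      J(N + i, i) = -2.0 * d * p[i];
      J(N + i, N + i) = -1.0;
      J(2 * N + i, i) = r * s;
      J(2 * N + i, 2 * N + i) = -r;
    }
  }

  double jac_trace(const vec& x) const {
    vec p = x.subvec(0, N - 1);
    vec K = sigmoid(p);
    vec chem = A * K;
    double tr = 0.0;
    for (int i = 0; i < N; ++i)
      tr += -3.0 * a * p[i] * p[i] + 2.0 * b * p[i]
        - eps * LB(i, i) - gam * chem[i] - 1.0 - r;
    return tr;
  }

  void check_finite(const vec& x, double t) const {
    if (!x.is_finite() || abs(x.subvec(0, N - 1)).max() > 1e3)
      Rcpp::stop("HR integration diverged (|p| > 1e3 or non-finite) at t = %f",
                 t);
  }
};

static void rk4_state(const HRSys& sys, vec& x, double dt,
                      vec& k1, vec& k2, vec& k3, vec& k4, vec& tmp) {
  sys.rhs(x, k1);
  tmp = x + 0.5 * dt * k1; sys.rhs(tmp, k2);
  tmp = x + 0.5 * dt * k2; sys.rhs(tmp, k3);
  tmp = x + dt * k3;       sys.rhs(tmp, k4);
  x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
}

// [[Rcpp::export]]
arma::vec hr_rhs_cpp(const arma::vec& state, const arma::vec& par,
                     const arma::mat& LB, const arma::mat& A,
                     double eps, double gam) {
  HRSys sys(par, LB, A, eps, gam);
  vec dx; sys.rhs(state, dx);
  return dx;
}

// [[Rcpp::export]]
arma::mat hr_jac_cpp(const arma::vec& state, const arma::vec& par,
                     const arma::mat& LB, const arma::mat& A,
                     double eps, double gam) {
  HRSys sys(par, LB, A, eps, gam);
  mat J; sys.jac(state, J);
  return J;
}

// [[Rcpp::export]]
double hr_trace_cpp(const arma::vec& state, const arma::vec& par,
                    const arma::mat& LB, const arma::mat& A,
                    double eps, double gam) {
  HRSys sys(par, LB, A, eps, gam);
  return sys.jac_trace(state);
}

// [[Rcpp::export]]
Rcpp::List hr_integrate_cpp(const arma::vec& state0, const arma::vec& par,
                            const arma::mat& LB, const arma::mat& A,
                            double eps, double gam, double t_span, double dt,
                            int record_every) {
  HRSys sys(par, LB, A, eps, gam);
  int nsteps = (int)std::lround(t_span / dt);
  int nrec = nsteps / record_every + 1;
  mat out(nrec, state0.n_elem);
  vec times(nrec);
  vec x = state0, k1, k2, k3, k4, tmp;
  out.row(0) = x.t(); times[0] = 0.0;
  int ir = 1;
  for (int step = 1; step <= nsteps; ++step) {
    rk4_state(sys, x, dt, k1, k2, k3, k4, tmp);
    if (step % 1000 == 0) sys.check_finite(x, step * dt);
    if (step % record_every == 0 && ir < nrec) {
      out.row(ir) = x.t(); times[ir] = step * dt; ++ir;
    }
  }
  sys.check_finite(x, nsteps * dt);
  return Rcpp::List::create(Rcpp::Named("times") = times.head(ir),
                            Rcpp::Named("states") = out.rows(0, ir - 1),
                            Rcpp::Named("final_state") = x);
}

// QR with positive diagonal of R
static void qr_pos(mat& Q, vec& logdiag, const mat& Y) {
  mat R;
  qr_econ(Q, R, Y);
  logdiag.set_size(R.n_rows < R.n_cols ? R.n_rows : R.n_cols);
  for (uword i = 0; i < logdiag.n_elem; ++i) {
    double d = R(i, i);
    if (d < 0) Q.col(i) *= -1.0;
    logdiag[i] = std::log(std::abs(d));
  }
}

// Benettin: RK4 on state, RK4 on tangent frame with stage Jacobians.
// [[Rcpp::export]]
Rcpp::List hr_benettin_cpp(const arma::vec& state0, const arma::mat& Q0,
                           const arma::vec& par, const arma::mat& LB,
                           const arma::mat& A, double eps, double gam,
                           double dt, double t_transient, double t_avg,
                           int renorm_steps) {
  HRSys sys(par, LB, A, eps, gam);
  int dim = (int)state0.n_elem, k = (int)Q0.n_cols;
  vec x = state0, k1, k2, k3, k4, tmp;

  int nt = (int)std::lround(t_transient / dt);
  for (int step = 1; step <= nt; ++step) {
    rk4_state(sys, x, dt, k1, k2, k3, k4, tmp);
    if (step % 1000 == 0) sys.check_finite(x, step * dt);
  }

  mat Y = Q0, J1(dim, dim), J2(dim, dim), J3(dim, dim), J4(dim, dim);
  mat G1, G2, G3, G4;
  vec sums(k, fill::zeros), logdiag;
  int na = (int)std::lround(t_avg / dt);
  double trace_sum = 0.0;
  std::vector<double> lam1_hist;
  double t_accum = 0.0;

  for (int step = 1; step <= na; ++step) {
    trace_sum += sys.jac_trace(x);
    // stage states of the driving RK4 step
    sys.rhs(x, k1);
    vec x2 = x + 0.5 * dt * k1; sys.rhs(x2, k2);
    vec x3 = x + 0.5 * dt * k2; sys.rhs(x3, k3);
    vec x4 = x + dt * k3;       sys.rhs(x4, k4);
    sys.jac(x, J1); sys.jac(x2, J2); sys.jac(x3, J3); sys.jac(x4, J4);
    G1 = J1 * Y;
    G2 = J2 * (Y + 0.5 * dt * G1);
    G3 = J3 * (Y + 0.5 * dt * G2);
    G4 = J4 * (Y + dt * G3);
    Y += dt / 6.0 * (G1 + 2.0 * G2 + 2.0 * G3 + G4);
    x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);

    if (step % renorm_steps == 0) {
      mat Q;
      qr_pos(Q, logdiag, Y);
      sums += logdiag;
      Y = Q;
      t_accum = step * dt;
      lam1_hist.push_back(sums[0] / t_accum);
      sys.check_finite(x, t_transient + step * dt);
      if ((step / renorm_steps) % 50 == 0) Rcpp::checkUserInterrupt();
    }
  }
  // fold in growth since the last renormalisation
  if (na % renorm_steps != 0) {
    mat Q;
    qr_pos(Q, logdiag, Y);
    sums += logdiag;
  }
  double T = na * dt;
  return Rcpp::List::create(
    Rcpp::Named("lambda") = sums / T,
    Rcpp::Named("trace_avg") = trace_sum / na,
    Rcpp::Named("lambda1_history") = lam1_hist,
    Rcpp::Named("final_state") = x);
}

// Benettin on a linear flow dx/dt = J x (constant Jacobian): validates the
// QR machinery against the exact exponents eig(J).
// [[Rcpp::export]]
arma::vec linear_benettin_cpp(const arma::mat& J, const arma::mat& Q0,
                              double dt, double t_avg, int renorm_steps) {
  int k = (int)Q0.n_cols;
  mat Y = Q0;
  vec sums(k, fill::zeros), logdiag;
  int na = (int)std::lround(t_avg / dt);
  mat G1, G2, G3, G4;
  for (int step = 1; step <= na; ++step) {
    G1 = J * Y;
    G2 = J * (Y + 0.5 * dt * G1);
    G3 = J * (Y + 0.5 * dt * G2);
    G4 = J * (Y + dt * G3);
    Y += dt / 6.0 * (G1 + 2.0 * G2 + 2.0 * G3 + G4);
    if (step % renorm_steps == 0) {
      mat Q;
      qr_pos(Q, logdiag, Y);
      sums += logdiag;
      Y = Q;
    }
  }
  if (na % renorm_steps != 0) {
    mat Q;
    qr_pos(Q, logdiag, Y);
    sums += logdiag;
  }
  return sums / (na * dt);
}
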