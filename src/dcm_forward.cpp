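// Bilinear DCM forward model: neural state equation, balloon-windkessel
// haemodynamics, and exact forward sensitivities (tangent-linear system).
// All integrators are fixed-step classical RK4 on the input grid: inputs are
// held constant over each bin of width dt.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// oxygen extraction fraction as a function of inflow
static inline double oxy_ext(double f, double E0) {
  return 1.0 - std::pow(1.0 - E0, 1.0 / f);
}

// d/df of f * E(f) / E0
static inline double d_fE_df(double f, double E0) {
  double a = 1.0 - E0;
  double af = std::pow(a, 1.0 / f);
  return (1.0 - af + af * std::log(a) / f) / E0;
}

struct HaemoPar {
  double kappa, gamma, tau, alpha, E0, V0, epsilon, k1, k2, k3;
};

static HaemoPar haemo_from_list(const Rcpp::List& h) {
  HaemoPar p;
  p.kappa = h["kappa"]; p.gamma = h["gamma"]; p.tau = h["tau"];
  p.alpha = h["alpha"]; p.E0 = h["E0"]; p.V0 = h["V0"];
  p.epsilon = h["epsilon"]; p.k1 = h["k1"]; p.k2 = h["k2"]; p.k3 = h["k3"];
  return p;
}

// neural derivative dx = (A + sum_j u_j B_j) x + C u
static inline void neural_deriv(const mat& A, const cube& B, const mat& C,
                                const vec& u, const vec& x, vec& dx) {
  mat M = A;
  for (uword j = 0; j < B.n_slices; ++j)
    if (u(j) != 0.0) M += u(j) * B.slice(j);
  dx = M * x + C * u;
}

// [[Rcpp::export]]
arma::mat cpp_integrate_neural(const arma::mat& A, const arma::cube& B,
                               const arma::mat& C, const arma::mat& U,
                               double dt, const arma::vec& x0) {
  const uword n = A.n_rows, nb = U.n_cols;
  mat X(n, nb);
  vec x = x0, k1(n), k2(n), k3(n), k4(n);
  for (uword t = 0; t < nb; ++t) {
    X.col(t) = x;
    vec u = U.col(t);
    neural_deriv(A, B, C, u, x, k1);
    neural_deriv(A, B, C, u, x + 0.5 * dt * k1, k2);
    neural_deriv(A, B, C, u, x + 0.5 * dt * k2, k3);
    neural_deriv(A, B, C, u, x + dt * k3, k4);
    x += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!x.is_finite())
      Rcpp::stop("neural state diverged (non-finite) at time bin %d", (int)(t + 2));
  }
  return X;
}

// haemodynamic derivative for one region; state (s, f, v, q), input z
static inline void haemo_deriv(const HaemoPar& hp, double z, const double* h,
                               double* dh) {
  double s = h[0], f = std::max(h[1], 1e-8), v = std::max(h[2], 1e-8), q = h[3];
  dh[0] = hp.epsilon * z - hp.kappa * s - hp.gamma * (f - 1.0);
  dh[1] = s;
  double vexp = std::pow(v, 1.0 / hp.alpha);
  dh[2] = (f - vexp) / hp.tau;
  dh[3] = (f * oxy_ext(f, hp.E0) / hp.E0 - vexp * q / v) / hp.tau;
}

static inline double bold_of(const HaemoPar& hp, double v, double q,
                             double scale) {
  return scale * hp.V0 * (hp.k1 * (1.0 - q) + hp.k2 * (1.0 - q / v) +
                          hp.k3 * (1.0 - v));
}

// Full forward model without sensitivities.
// sample_idx: 0-based bin indices at which BOLD is read out.
// [[Rcpp::export]]
Rcpp::List cpp_dcm_forward(const arma::mat& A, const arma::cube& B,
                           const arma::mat& C, const arma::mat& U, double dt,
                           const Rcpp::List& haemo,
                           const arma::uvec& sample_idx, const arma::vec& x0,
                           double scale, bool want_paths) {
  const uword n = A.n_rows, nb = U.n_cols, ns = sample_idx.n_elem;
  HaemoPar hp = haemo_from_list(haemo);

  vec x = x0;
  mat h(4, n);                 // rows: s, f, v, q
  h.row(0).zeros(); h.row(1).ones(); h.row(2).ones(); h.row(3).ones();

  mat Y(ns, n, fill::zeros);
  mat Xpath, Hpath;
  if (want_paths) { Xpath.set_size(n, nb); Hpath.set_size(4 * n, nb); }

  uword next_s = 0;
  vec kx1(n), kx2(n), kx3(n), kx4(n);
  mat kh1(4, n), kh2(4, n), kh3(4, n), kh4(4, n), htmp(4, n);

  for (uword t = 0; t < nb; ++t) {
    if (want_paths) { Xpath.col(t) = x; Hpath.col(t) = vectorise(h); }
    while (next_s < ns && sample_idx(next_s) == t) {
      for (uword i = 0; i < n; ++i)
        Y(next_s, i) = bold_of(hp, std::max(h(2, i), 1e-8), h(3, i), scale);
      ++next_s;
    }
    vec u = U.col(t);
    // RK4 on the joint (x, h) system
    neural_deriv(A, B, C, u, x, kx1);
    for (uword i = 0; i < n; ++i) haemo_deriv(hp, x(i), h.colptr(i), kh1.colptr(i));

    vec x2 = x + 0.5 * dt * kx1; htmp = h + 0.5 * dt * kh1;
    neural_deriv(A, B, C, u, x2, kx2);
    for (uword i = 0; i < n; ++i) haemo_deriv(hp, x2(i), htmp.colptr(i), kh2.colptr(i));

    vec x3 = x + 0.5 * dt * kx2; htmp = h + 0.5 * dt * kh2;
    neural_deriv(A, B, C, u, x3, kx3);
    for (uword i = 0; i < n; ++i) haemo_deriv(hp, x3(i), htmp.colptr(i), kh3.colptr(i));

    vec x4 = x + dt * kx3; htmp = h + dt * kh3;
    neural_deriv(A, B, C, u, x4, kx4);
    for (uword i = 0; i < n; ++i) haemo_deriv(hp, x4(i), htmp.colptr(i), kh4.colptr(i));

    x += dt / 6.0 * (kx1 + 2.0 * kx2 + 2.0 * kx3 + kx4);
    h += dt / 6.0 * (kh1 + 2.0 * kh2 + 2.0 * kh3 + kh4);
    if (!x.is_finite() || !h.is_finite())
      Rcpp::stop("forward model diverged (non-finite) at time bin %d", (int)(t + 2));
  }
  // samples that coincide with the final grid point
  while (next_s < ns) {
    for (uword i = 0; i < n; ++i)
      Y(next_s, i) = bold_of(hp, std::max(h(2, i), 1e-8), h(3, i), scale);
    ++next_s;
  }

  if (want_paths)
    return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("x") = Xpath,
                              Rcpp::Named("h") = Hpath);
  return Rcpp::List::create(Rcpp::Named("y") = Y);
}

// Joint state of the augmented (nominal + tangent) system.
struct AugState {
  vec x;    // n
  mat S;    // n x p   neural sensitivities
  mat h;    // 4 x n   haemodynamic states (s, f, v, q)
  mat Sh;   // 4 x (n*p) haemodynamic tangents, region-major blocks of p
};

// Forward model plus exact Jacobian dy/dtheta via the tangent-linear system.
// ptab: p x 4 integer matrix, rows (code, i, j, ch), all 0-based:
//   code 0: A off-diagonal entry (i,j)          -> dA = e_i e_j'
//   code 1: self log-scale of region i          -> dA = A(i,i) e_i e_i'
//   code 2: B entry (i,j) on input channel ch   -> dB_ch = e_i e_j'
//   code 3: C entry (i, ch)                     -> dC = e_i e_ch'
// The tangent of the haemodynamic stage is the same 4x4 linear operator
// (a function of the nominal states only) for every parameter, so it is
// applied to all p tangent columns of a region with one matrix product.
// [[Rcpp::export]]
Rcpp::List cpp_dcm_forward_sens(const arma::mat& A, const arma::cube& B,
                                const arma::mat& C, const arma::mat& U,
                                double dt, const Rcpp::List& haemo,
                                const arma::uvec& sample_idx,
                                const arma::imat& ptab, double scale) {
  const uword n = A.n_rows, nb = U.n_cols, ns = sample_idx.n_elem,
              p = ptab.n_rows;
  HaemoPar hp = haemo_from_list(haemo);
  const double ia = 1.0 / hp.alpha;

  AugState st;
  st.x.zeros(n);
  st.S.zeros(n, p);
  st.h.set_size(4, n);
  st.h.row(0).zeros(); st.h.row(1).ones(); st.h.row(2).ones(); st.h.row(3).ones();
  st.Sh.zeros(4, n * p);

  mat Y(ns, n, fill::zeros);
  mat J(ns * n, p, fill::zeros);     // rows follow vec(Y) (column-major)

  mat M(n, n), G(n, p), Ti(4, 4, fill::zeros);
  Ti(1, 0) = 1.0;

  auto derivs = [&](const AugState& in, const vec& u, bool has_u,
                    AugState& out) {
    if (has_u) {
      M = A;
      for (uword j = 0; j < B.n_slices; ++j)
        if (u(j) != 0.0) M += u(j) * B.slice(j);
      out.x = M * in.x + C * u;
    } else {
      out.x = A * in.x;
    }
    const mat& Mref = has_u ? M : A;
    G.zeros();
    for (uword k = 0; k < p; ++k) {
      int code = ptab(k, 0), i = ptab(k, 1), j = ptab(k, 2), ch = ptab(k, 3);
      switch (code) {
      case 0: G(i, k) = in.x(j); break;
      case 1: G(i, k) = A(i, i) * in.x(i); break;
      case 2: if (has_u) G(i, k) = u(ch) * in.x(j); break;
      case 3: if (has_u) G(i, k) = u(ch); break;
      }
    }
    out.S = Mref * in.S + G;
    for (uword i = 0; i < n; ++i) {
      haemo_deriv(hp, in.x(i), in.h.colptr(i), out.h.colptr(i));
      double f = std::max(in.h(1, i), 1e-8), v = std::max(in.h(2, i), 1e-8),
             q = in.h(3, i);
      double vexp1 = std::pow(v, ia - 1.0);
      Ti(0, 0) = -hp.kappa; Ti(0, 1) = -hp.gamma;
      Ti(2, 1) = 1.0 / hp.tau;
      Ti(2, 2) = -ia * vexp1 / hp.tau;
      Ti(3, 1) = d_fE_df(f, hp.E0) / hp.tau;
      Ti(3, 2) = -q * (ia - 1.0) * std::pow(v, ia - 2.0) / hp.tau;
      Ti(3, 3) = -vexp1 / hp.tau;
      out.Sh.cols(i * p, i * p + p - 1) = Ti * in.Sh.cols(i * p, i * p + p - 1);
      out.Sh.row(0).subvec(i * p, i * p + p - 1) += hp.epsilon * in.S.row(i);
    }
  };

  AugState k1 = st, k2 = st, k3 = st, k4 = st, tmp = st;
  auto axpy = [&](const AugState& a, double c, const AugState& d,
                  AugState& out) {
    out.x = a.x + c * d.x;
    out.S = a.S + c * d.S;
    out.h = a.h + c * d.h;
    out.Sh = a.Sh + c * d.Sh;
  };

  uword next_s = 0;
  for (uword t = 0; t < nb; ++t) {
    while (next_s < ns && sample_idx(next_s) == t) {
      for (uword i = 0; i < n; ++i) {
        double v = std::max(st.h(2, i), 1e-8), q = st.h(3, i);
        Y(next_s, i) = bold_of(hp, v, q, scale);
        double cv = scale * hp.V0, v2 = v * v;
        for (uword k = 0; k < p; ++k) {
          double dv = st.Sh(2, i * p + k), dq = st.Sh(3, i * p + k);
          J(next_s + ns * i, k) =
              cv * (-hp.k1 * dq - hp.k2 * (dq / v - q * dv / v2) - hp.k3 * dv);
        }
      }
      ++next_s;
    }
    vec u = U.col(t);
    bool has_u = any(u != 0.0);
    derivs(st, u, has_u, k1);
    axpy(st, 0.5 * dt, k1, tmp); derivs(tmp, u, has_u, k2);
    axpy(st, 0.5 * dt, k2, tmp); derivs(tmp, u, has_u, k3);
    axpy(st, dt, k3, tmp);       derivs(tmp, u, has_u, k4);
    double w = dt / 6.0;
    st.x += w * (k1.x + 2.0 * k2.x + 2.0 * k3.x + k4.x);
    st.S += w * (k1.S + 2.0 * k2.S + 2.0 * k3.S + k4.S);
    st.h += w * (k1.h + 2.0 * k2.h + 2.0 * k3.h + k4.h);
    st.Sh += w * (k1.Sh + 2.0 * k2.Sh + 2.0 * k3.Sh + k4.Sh);
    if (!st.x.is_finite() || !st.h.is_finite())
      Rcpp::stop("forward model diverged (non-finite) at time bin %d", (int)(t + 2));
  }
  while (next_s < ns) {
    for (uword i = 0; i < n; ++i) {
      double v = std::max(st.h(2, i), 1e-8), q = st.h(3, i);
      Y(next_s, i) = bold_of(hp, v, q, scale);
      double cv = scale * hp.V0, v2 = v * v;
      for (uword k = 0; k < p; ++k) {
        double dv = st.Sh(2, i * p + k), dq = st.Sh(3, i * p + k);
        J(next_s + ns * i, k) =
            cv * (-hp.k1 * dq - hp.k2 * (dq / v - q * dv / v2) - hp.k3 * dv);
      }
    }
    ++next_s;
  }

  return Rcpp::List::create(Rcpp::Named("y") = Y, Rcpp::Named("J") = J);
}
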