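// Core numerics for the two-muscle elbow model: smoothed Hill curves,
// excitation->activation dynamics, RK4 rollout, and the shooting objective
// with its exact discrete-adjoint gradient.  All state-dependent pieces are
// templated on the scalar type so Jacobians can be taken by complex-step
// differentiation (accurate to machine precision, no subtractive cancellation).

#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const int NX = 4;  // theta, omega, a_flex, a_ext
static const int NU = 2;  // u_flex, u_ext

// parameter-vector layout (packed in R by params_pack())
enum {
  P_FMAX = 0, P_VMAX, P_AA, P_AD, P_C1, P_L0,
  P_B1, P_B2, P_B3, P_C2, P_C3, P_D1, P_D2EFF, P_D3, P_S,
  P_R, P_I, P_TH0, P_ACTSCALE, P_LEN
};

inline double creal_(double x) { return x; }
inline double creal_(const cplx& x) { return x.real(); }

// tanh guarded against overflow of std::tanh(complex) at large |Re|
template <class T>
T stanh(const T& x) {
  double xr = creal_(x);
  if (xr > 19.0)  return 1.0 - 2.0 * exp(-2.0 * x);
  if (xr < -19.0) return -1.0 + 2.0 * exp(2.0 * x);
  return tanh(x);
}

// smooth min(v, 0) with gain k: -log(1 + exp(-k v)) / k, computed stably
template <class T>
T softmin0(const T& v, double k) {
  if (creal_(v) > 0.0) {
    T e = exp(-k * v);
    return -log(1.0 + e) / k;
  }
  T e = exp(k * v);
  return v - log(1.0 + e) / k;
}

// smooth max(v, 0)
template <class T>
T softplus0(const T& v, double k) { return v - softmin0(v, k); }

// smooth step in [0,1]
template <class T>
T sigmoidk(const T& x, double k) { return 0.5 * (1.0 + stanh(k * x)); }

// --- Hill curves -----------------------------------------------------------

// active force-length: exp(-((l^b2 - 1)/b3)^b1), b1 even keeps it smooth
template <class T>
T f_active(const T& l, const double* p) {
  T z = (pow(l, p[P_B2]) - 1.0) / p[P_B3];
  T z2 = z * z;
  double b1 = p[P_B1];
  if (b1 == 2.0) return exp(-z2);
  return exp(-pow(z2, b1 / 2.0));
}

// parallel passive: c1 * (exp(c2 * max(l - c3, 0)) - 1), smoothed max
template <class T>
T f_passive(const T& l, const double* p) {
  T x = softplus0(l - p[P_C3], p[P_S]);
  return p[P_C1] * (exp(p[P_C2] * x) - 1.0);
}

// force-velocity before normalisation; v > 0 is lengthening (eccentric)
template <class T>
T f_velocity_raw(const T& v, const double* p) {
  double k = p[P_S], d1 = p[P_D1], d2 = p[P_D2EFF], d3 = p[P_D3];
  T vc = softmin0(v, k);                       // concentric arg, <= 0
  T fc = (1.0 + vc) / (1.0 - d1 * vc);
  fc = softplus0(fc, k);                       // tension-only clamp
  T vp = softplus0(v, k);                      // eccentric arg, >= 0
  T fe = d2 - (d2 - 1.0) / (1.0 + d3 * vp);
  T s = sigmoidk(v, k);
  return (1.0 - s) * fc + s * fe;
}

inline double f_velocity_norm(const double* p) {
  return f_velocity_raw(0.0, p);  // ~1 + O(log(2)/s); divide out so fv(0) = 1
}

template <class T>
T f_velocity(const T& v, const double* p) {
  return f_velocity_raw(v, p) / f_velocity_norm(p);
}

template <class T>
T muscle_force_t(const T& a, const T& l, const T& v, const double* p) {
  return p[P_FMAX] * (a * f_active(l, p) * f_velocity(v, p) + f_passive(l, p));
}

// first-order excitation->activation dynamics with smooth regime switch;
// act_scale 0 = activation-dependent time constants, 1 = constant
template <class T>
T act_rate(const T& a, const T& u, const double* p) {
  double k = p[P_S];
  T d = u - a;
  T s = sigmoidk(d, k);
  T ita, itd;
  if (p[P_ACTSCALE] < 0.5) {
    T sc = 0.5 + 1.5 * a;
    ita = 1.0 / (p[P_AA] * sc);
    itd = sc / p[P_AD];
  } else {
    ita = T(1.0 / p[P_AA]);
    itd = T(1.0 / p[P_AD]);
  }
  return d * (s * ita + (1.0 - s) * itd);
}

// --- dynamics --------------------------------------------------------------

template <class T>
void dynamics_t(const T* x, const T* u, const double* p, T* dx) {
  double l0 = p[P_L0], r = p[P_R], I = p[P_I], th0 = p[P_TH0], vmax = p[P_VMAX];
  T dth = x[0] - th0;
  T lF = (l0 - r * dth) / l0;
  T lE = (l0 + r * dth) / l0;
  T vF = -(r / l0) * x[1] / vmax;   // strain rate per vmax
  T vE = (r / l0) * x[1] / vmax;
  T FF = muscle_force_t(x[2], lF, vF, p);
  T FE = muscle_force_t(x[3], lE, vE, p);
  dx[0] = x[1];
  dx[1] = r * (FF - FE) / I;
  dx[2] = act_rate(x[2], u[0], p);
  dx[3] = act_rate(x[3], u[1], p);
}

static void rk4_step_d(const double* x, const double* u, double h,
                       const double* p, double* xn) {
  double k1[NX], k2[NX], k3[NX], k4[NX], xt[NX];
  dynamics_t(x, u, p, k1);
  for (int i = 0; i < NX; ++i) xt[i] = x[i] + 0.5 * h * k1[i];
  dynamics_t(xt, u, p, k2);
  for (int i = 0; i < NX; ++i) xt[i] = x[i] + 0.5 * h * k2[i];
  dynamics_t(xt, u, p, k3);
  for (int i = 0; i < NX; ++i) xt[i] = x[i] + h * k3[i];
  dynamics_t(xt, u, p, k4);
  for (int i = 0; i < NX; ++i)
    xn[i] = x[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// complex-step Jacobians of the dynamics: A (NX x NX), B (NX x NU), col-major
static void dyn_jac(const double* x, const double* u, const double* p,
                    double* f, double* A, double* B) {
  const double hs = 1e-100;
  cplx xc[NX], uc[NU], dxc[NX];
  double dx[NX];
  dynamics_t(x, u, p, dx);
  for (int i = 0; i < NX; ++i) f[i] = dx[i];
  for (int j = 0; j < NX; ++j) {
    for (int i = 0; i < NX; ++i) xc[i] = cplx(x[i], i == j ? hs : 0.0);
    for (int i = 0; i < NU; ++i) uc[i] = cplx(u[i], 0.0);
    dynamics_t(xc, uc, p, dxc);
    for (int i = 0; i < NX; ++i) A[i + NX * j] = dxc[i].imag() / hs;
  }
  for (int j = 0; j < NU; ++j) {
    for (int i = 0; i < NX; ++i) xc[i] = cplx(x[i], 0.0);
    for (int i = 0; i < NU; ++i) uc[i] = cplx(u[i], i == j ? hs : 0.0);
    dynamics_t(xc, uc, p, dxc);
    for (int i = 0; i < NX; ++i) B[i + NX * j] = dxc[i].imag() / hs;
  }
}

// --- exported curve evaluators --------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_active_fl(NumericVector l, NumericVector par) {
  const double* p = par.begin();
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = f_active(l[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_passive_fl(NumericVector l, NumericVector par) {
  const double* p = par.begin();
  NumericVector out(l.size());
  for (R_xlen_t i = 0; i < l.size(); ++i) out[i] = f_passive(l[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_force_velocity(NumericVector v, NumericVector par) {
  const double* p = par.begin();
  NumericVector out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = f_velocity(v[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_act_rate(NumericVector a, NumericVector u, NumericVector par) {
  const double* p = par.begin();
  R_xlen_t n = std::max(a.size(), u.size());
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = act_rate(a[i % a.size()], u[i % u.size()], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_dynamics(NumericVector x, NumericVector u, NumericVector par) {
  NumericVector dx(NX);
  dynamics_t(x.begin(), u.begin(), par.begin(), dx.begin());
  return dx;
}

// [[Rcpp::export]]
NumericMatrix cpp_rollout(NumericVector x0, NumericMatrix U, double h,
                          NumericVector par) {
  int N = U.nrow();
  NumericMatrix X(N + 1, NX);
  double x[NX], xn[NX], u[NU];
  for (int i = 0; i < NX; ++i) { x[i] = x0[i]; X(0, i) = x0[i]; }
  for (int k = 0; k < N; ++k) {
    u[0] = U(k, 0); u[1] = U(k, 1);
    rk4_step_d(x, u, h, par.begin(), xn);
    for (int i = 0; i < NX; ++i) { x[i] = xn[i]; X(k + 1, i) = xn[i]; }
  }
  return X;
}

// --- objective + adjoint gradient -----------------------------------------

// smooth |x|: x * tanh(s x)
template <class T>
T smab(const T& x, double s) { return x * stanh(s * x); }

// per-node work-rate penalty term (augmented objective), state-only
template <class T>
T work_node(const T* x, const double* p, double sw) {
  double l0 = p[P_L0], r = p[P_R], th0 = p[P_TH0], vmax = p[P_VMAX];
  T dth = x[0] - th0;
  T lF = (l0 - r * dth) / l0;
  T lE = (l0 + r * dth) / l0;
  T vF = -(r / l0) * x[1] / vmax;
  T vE = (r / l0) * x[1] / vmax;
  T FF = muscle_force_t(x[2], lF, vF, p);
  T FE = muscle_force_t(x[3], lE, vE, p);
  T ldF = -r * x[1];                // muscle-length rate, m/s
  T ldE = r * x[1];
  return smab(ldF * FF, sw) + smab(ldE * FE, sw);
}

static void work_node_grad(const double* x, const double* p, double sw,
                           double* g) {
  const double hs = 1e-100;
  cplx xc[NX];
  for (int j = 0; j < NX; ++j) {
    for (int i = 0; i < NX; ++i) xc[i] = cplx(x[i], i == j ? hs : 0.0);
    g[j] = work_node(xc, p, sw).imag() / hs;
  }
}

// Objective of the shooting problem over controls, with gradient.
// uvec = c(u_flex[1..N], u_ext[1..N]); node-position running cost on nodes
// 1..N (optionally 0), terminal weight w, augmented-Lagrangian terms
// lambda*omega_N + mu/2*omega_N^2 for the terminal-rest constraint.
// [[Rcpp::export]]
List cpp_cost_grad(NumericVector x0, NumericVector uvec, double h,
                   NumericVector par, double theta_target, double w,
                   bool include_node0, double lambda, double mu,
                   bool augmented, double w_exc, double w_work, double s_w) {
  const double* p = par.begin();
  int N = uvec.size() / 2;
  double r = p[P_R];

  // forward rollout, storing all nodes
  std::vector<double> X((N + 1) * NX);
  for (int i = 0; i < NX; ++i) X[i] = x0[i];
  for (int k = 0; k < N; ++k) {
    double u[NU] = { uvec[k], uvec[N + k] };
    rk4_step_d(&X[k * NX], u, h, p, &X[(k + 1) * NX]);
  }

  // objective pieces; node position error e_i = 2 r^2 (theta_i - theta_t)^2
  double J_sse = 0.0;
  int i0 = include_node0 ? 0 : 1;
  for (int k = i0; k <= N; ++k) {
    double d = X[k * NX] - theta_target;
    J_sse += 2.0 * r * r * d * d;
  }
  double dN = X[N * NX] - theta_target;
  double J_end = w * 2.0 * r * r * dN * dN;
  double omega_N = X[N * NX + 1];
  double J_pen = lambda * omega_N + 0.5 * mu * omega_N * omega_N;

  double J_exc = 0.0, J_work = 0.0;
  if (augmented) {
    for (int k = 0; k < 2 * N; ++k) J_exc += uvec[k] * uvec[k];
    J_exc *= w_exc;
    for (int k = 1; k <= N; ++k) J_work += work_node(&X[k * NX], p, s_w);
    J_work *= w_work * h;
  }

  double J = J_sse + J_end;
  double J_total = J + J_pen + (augmented ? (J_exc + J_work) : 0.0);

  // backward adjoint pass
  NumericVector grad(2 * N);
  std::vector<double> lam(NX, 0.0);
  // terminal node seeds
  lam[0] = (1.0 + w) * 4.0 * r * r * dN;   // node N counted in J_sse and J_end
  lam[1] = lambda + mu * omega_N;
  if (augmented) {
    double gw[NX];
    work_node_grad(&X[N * NX], p, s_w, gw);
    for (int i = 0; i < NX; ++i) lam[i] += w_work * h * gw[i];
  }

  double A1[16], A2[16], A3[16], A4[16];
  double B1[8], B2[8], B3[8], B4[8];
  double k1[NX], k2[NX], k3[NX], xs[NX], f[NX];

  for (int k = N - 1; k >= 0; --k) {
    const double* xk = &X[k * NX];
    double u[NU] = { uvec[k], uvec[N + k] };

    // recompute stage states and stage Jacobians
    dyn_jac(xk, u, p, k1, A1, B1);
    for (int i = 0; i < NX; ++i) xs[i] = xk[i] + 0.5 * h * k1[i];
    dyn_jac(xs, u, p, k2, A2, B2);
    for (int i = 0; i < NX; ++i) xs[i] = xk[i] + 0.5 * h * k2[i];
    dyn_jac(xs, u, p, k3, A3, B3);
    for (int i = 0; i < NX; ++i) xs[i] = xk[i] + h * k3[i];
    dyn_jac(xs, u, p, f, A4, B4);

    // adjoint seeds of the four stage slopes
    double s4[NX], s3[NX], s2[NX], s1[NX], tmp[NX];
    for (int i = 0; i < NX; ++i) s4[i] = h / 6.0 * lam[i];
    // s3 = 2h/6 lam + h A4^T s4
    for (int i = 0; i < NX; ++i) {
      double acc = 0.0;
      for (int j = 0; j < NX; ++j) acc += A4[j + NX * i] * s4[j];
      s3[i] = 2.0 * h / 6.0 * lam[i] + h * acc;
    }
    for (int i = 0; i < NX; ++i) {
      double acc = 0.0;
      for (int j = 0; j < NX; ++j) acc += A3[j + NX * i] * s3[j];
      s2[i] = 2.0 * h / 6.0 * lam[i] + 0.5 * h * acc;
    }
    for (int i = 0; i < NX; ++i) {
      double acc = 0.0;
      for (int j = 0; j < NX; ++j) acc += A2[j + NX * i] * s2[j];
      s1[i] = h / 6.0 * lam[i] + 0.5 * h * acc;
    }

    // control gradient: sum_i B_i^T s_i
    for (int j = 0; j < NU; ++j) {
      double acc = 0.0;
      for (int i = 0; i < NX; ++i)
        acc += B1[i + NX * j] * s1[i] + B2[i + NX * j] * s2[i] +
               B3[i + NX * j] * s3[i] + B4[i + NX * j] * s4[i];
      grad[j * N + k] = acc;
    }
    if (augmented) {
      grad[k] += 2.0 * w_exc * uvec[k];
      grad[N + k] += 2.0 * w_exc * uvec[N + k];
    }

    // new adjoint: lam + sum_i A_i^T s_i
    for (int i = 0; i < NX; ++i) {
      double acc = 0.0;
      for (int j = 0; j < NX; ++j)
        acc += A1[j + NX * i] * s1[j] + A2[j + NX * i] * s2[j] +
               A3[j + NX * i] * s3[j] + A4[j + NX * i] * s4[j];
      tmp[i] = lam[i] + acc;
    }
    for (int i = 0; i < NX; ++i) lam[i] = tmp[i];

    // running-cost seed at node k (k >= 1, or 0 if included -- but node 0 is
    // fixed so its seed never reaches the gradient anyway)
    if (k >= 1 || include_node0) {
      double d = X[k * NX] - theta_target;
      lam[0] += 4.0 * r * r * d;
      if (augmented && k >= 1) {
        double gw[NX];
        work_node_grad(xk, p, s_w, gw);
        for (int i = 0; i < NX; ++i) lam[i] += w_work * h * gw[i];
      }
    }
  }

  return List::create(
    _["J_total"] = J_total, _["J"] = J, _["J_SSE"] = J_sse,
    _["J_end"] = J_end, _["J_pen"] = J_pen, _["J_exc"] = J_exc,
    _["J_work"] = J_work, _["omega_N"] = omega_N, _["grad"] = grad);
}
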