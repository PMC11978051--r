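#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Mass-action fusion kinetics over the fusion window [0, T]:
//   dN_i/dt = - sum_j ((a_i + a_j)/2) N_i N_j
//   dF_ii/dt = a_i N_i^2 / 2,  dF_ij/dt = ((a_i+a_j)/2) N_i N_j  (i < j)
// State layout: y = [N_1..N_S, F_11, F_12, ..., F_1S, F_22, ..., F_SS]
// (upper triangle, row-major). The per-genotype cell count
// N_i + 2 F_ii + sum_{j!=i} F_ij is a linear invariant, conserved exactly
// by any Runge-Kutta step.

static inline int tri_index(int S, int i, int j) {
  // i <= j, 0-based, offset after the S N-entries handled by caller
  return i * S - (i * (i - 1)) / 2 + (j - i);
}

static void deriv(const std::vector<double>& y, std::vector<double>& dy,
                  const NumericVector& a, int S) {
  const double* N = y.data();
  double* dN = dy.data();
  // s_i = sum_j ((a_i + a_j)/2) N_j = (a_i * Ntot + sum_j a_j N_j) / 2
  double Ntot = 0.0, aN = 0.0;
  for (int j = 0; j < S; ++j) {
    Ntot += N[j];
    aN += a[j] * N[j];
  }
  for (int i = 0; i < S; ++i) {
    dN[i] = -N[i] * 0.5 * (a[i] * Ntot + aN);
  }
  int k = S;
  for (int i = 0; i < S; ++i) {
    dy[k++] = 0.5 * a[i] * N[i] * N[i]; // F_ii
    for (int j = i + 1; j < S; ++j) {
      dy[k++] = 0.5 * (a[i] + a[j]) * N[i] * N[j]; // F_ij
    }
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// [[Rcpp::export]]
List fuse_window_cpp(NumericVector N0, NumericVector alpha, double T_window,
                     double rtol = 1e-10, double atol = 1e-12) {
  const int S = N0.size();
  if (alpha.size() != S) stop("N0 and alpha must have equal length");
  const int n = S + S * (S + 1) / 2;
  std::vector<double> y(n, 0.0), ynew(n), yerr(n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), ytmp(n);
  for (int i = 0; i < S; ++i) y[i] = N0[i];

  double t = 0.0;
  double amax = 0.0, Ntot = 0.0;
  for (int i = 0; i < S; ++i) {
    if (alpha[i] > amax) amax = alpha[i];
    Ntot += N0[i];
  }
  // initial step: fraction of the kinetic timescale 1/(amax * Ntot)
  double h = T_window;
  if (amax > 0.0 && Ntot > 0.0) {
    double tk = 1.0 / (amax * Ntot);
    if (tk < h) h = tk;
  }
  h *= 0.1;
  if (h <= 0.0) h = T_window;

  long max_steps = 1000000;
  long steps = 0;
  bool have_k1 = false;

  while (t < T_window) {
    if (++steps > max_steps) {
      stop("fusion window integration failed: step limit reached at t=%g "
           "(h=%g, S=%d); kinetics too stiff for tolerances rtol=%g atol=%g",
           t, h, S, rtol, atol);
    }
    if (h > T_window - t) h = T_window - t;
    if (!have_k1) {
      deriv(y, k1, alpha, S);
      have_k1 = true;
    }
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    deriv(ytmp, k2, alpha, S);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    deriv(ytmp, k3, alpha, S);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(ytmp, k4, alpha, S);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    deriv(ytmp, k5, alpha, S);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    deriv(ytmp, k6, alpha, S);
    for (int i = 0; i < n; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    deriv(ynew, k7, alpha, S);

    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double y5 = ynew[i];
      double y4 = y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5));
      double e = (y5 - y4) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / n);

    if (errnorm <= 1.0) {
      t += h;
      y.swap(ynew);
      k1 = k7; // FSAL
      have_k1 = true;
    } else {
      have_k1 = have_k1; // keep k1 for retry at smaller h
    }
    double fac = 0.9 * std::pow(errnorm > 1e-300 ? errnorm : 1e-300, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < 1e-14 * T_window) {
      stop("fusion window integration failed: step collapse at t=%g (h=%g)",
           t, h);
    }
  }

  NumericVector Nout(S);
  for (int i = 0; i < S; ++i) Nout[i] = std::max(y[i], 0.0);
  NumericMatrix F(S, S);
  int k = S;
  for (int i = 0; i < S; ++i) {
    for (int j = i; j < S; ++j) {
      double v = std::max(y[k++], 0.0);
      F(i, j) = v;
      F(j, i) = v;
    }
  }
  return List::create(_["N"] = Nout, _["F"] = F, _["steps"] = (double)steps);
}

// Per-cycle frequency-update weights given fusion counts and survival values.
// w_i = N_i(T) S_i + (1-C) [ 2 F_ii S(2 m_i) + sum_{j != i} F_ij S(m_i + m_j) ]
// Same-type fused cells carry two i nuclei, hence the factor 2 on F_ii.
// [[Rcpp::export]]
NumericVector cycle_weights_cpp(NumericVector NT, NumericMatrix F,
                                NumericVector S_single, NumericMatrix S_pair,
                                double C) {
  const int S = NT.size();
  NumericVector w(S);
  const double oc = 1.0 - C;
  for (int i = 0; i < S; ++i) {
    double acc = NT[i] * S_single[i];
    if (oc > 0.0) {
      acc += oc * 2.0 * F(i, i) * S_pair(i, i);
      for (int j = 0; j < S; ++j) {
        if (j != i) acc += oc * F(i, j) * S_pair(i, j);
      }
    }
    w[i] = acc;
  }
  return w;
}
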