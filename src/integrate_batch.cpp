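#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// State layout (COD units, mg/L):
//   0 S_S, 1 S_H1, 2 S_H2, 3 X_H, 4 X_STO, 5 X_P, 6 S_P, 7 O_cum
// Parameter layout (must match .batch_par_vector() on the R side):
//   0 mu_H, 1 K_S, 2 b_H, 3 K_OH, 4 k_h1, 5 K_X, 6 k_h2, 7 K_XX,
//   8 k_STO, 9 K_STO, 10 mu_STO, 11 Y_H, 12 Y_STO, 13 f_ES, 14 f_EX,
//   15 S_O (dissolved oxygen for the optional switch; +Inf => switch = 1)

static const int NS = 8;

static inline double monod(double s, double k) {
  if (s <= 0.0) return 0.0;
  return s / (k + s); // k == 0 gives 1 for s > 0
}

// Right-hand side in COD units per day. States are clipped at zero before
// rate evaluation so transient integrator undershoot cannot flip rate signs.
static void rhs(const double *yin, const double *p, double *dy) {
  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = yin[i] > 0.0 ? yin[i] : 0.0;

  const double S_S = y[0], S_H1 = y[1], S_H2 = y[2], X_H = y[3],
               X_STO = y[4];
  const double mu_H = p[0], K_S = p[1], b_H = p[2], K_OH = p[3], k_h1 = p[4],
               K_X = p[5], k_h2 = p[6], K_XX = p[7], k_STO = p[8],
               K_STO = p[9], mu_STO = p[10], Y_H = p[11], Y_STO = p[12],
               f_ES = p[13], f_EX = p[14], S_O = p[15];

  const double sw = R_FINITE(S_O) ? S_O / (K_OH + S_O) : 1.0;
  const double f_E = f_ES + f_EX;

  // Surface-saturation (Contois) hydrolysis in the ratio S_H/X_H
  double hyd1 = 0.0, hyd2 = 0.0;
  if (X_H > 0.0) {
    const double r1 = S_H1 / X_H, r2 = S_H2 / X_H;
    hyd1 = k_h1 * monod(r1, K_X) * sw * X_H;
    hyd2 = k_h2 * monod(r2, K_XX) * sw * X_H;
  }
  const double growth  = mu_H * monod(S_S, K_S) * sw * X_H;
  const double storage = k_STO * monod(S_S, K_STO) * sw * X_H;
  const double gr_sto  = mu_STO * X_STO * sw;
  const double decay   = b_H * X_H * sw;

  dy[0] = -growth / Y_H + hyd1 + hyd2 - storage;          // S_S
  dy[1] = -hyd1;                                          // S_H1
  dy[2] = -hyd2;                                          // S_H2
  dy[3] = growth + gr_sto - decay;                        // X_H
  dy[4] = Y_STO * storage - gr_sto / Y_H;                 // X_STO
  dy[5] = f_EX * decay;                                   // X_P
  dy[6] = f_ES * decay;                                   // S_P
  dy[7] = (1.0 - Y_H) / Y_H * (growth + gr_sto)           // O_cum
        + (1.0 - Y_STO) * storage + (1.0 - f_E) * decay;
}

// [[Rcpp::export(name = ".batch_rhs_cpp")]]
NumericVector batch_rhs_cpp(NumericVector y, NumericVector par) {
  if (y.size() != NS) stop("state vector must have length %d", NS);
  NumericVector dy(NS);
  rhs(y.begin(), par.begin(), dy.begin());
  return dy;
}

// Adaptive Dormand-Prince 5(4) with step clamping to the output grid.
// times_day must start at the initial time and be strictly increasing.
// [[Rcpp::export(name = ".integrate_batch_cpp")]]
List integrate_batch_cpp(NumericVector y0, NumericVector par,
                         NumericVector times_day, double rtol, double atol,
                         int max_steps = 2000000) {
  if (y0.size() != NS) stop("initial state must have length %d", NS);
  const int nt = times_day.size();
  if (nt < 2) stop("need at least two output times");

  // Dormand-Prince RK5(4)7M tableau
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
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  NumericMatrix out(nt, NS);
  NumericVector o2rate(nt);

  double y[NS], ytmp[NS], ynew[NS];
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];

  double t = times_day[0];
  rhs(y, par.begin(), k1);
  for (int i = 0; i < NS; ++i) out(0, i) = y[i];
  o2rate[0] = k1[7];

  const double tend = times_day[nt - 1];
  double h = (tend - t) / 1000.0;
  if (h <= 0) stop("output times must be strictly increasing");
  const double hmin = (tend - times_day[0]) * 1e-14;

  int iout = 1;  // next output index to fill
  long nstep = 0;
  bool have_k1 = true; // FSAL: k1 holds f(t, y)

  while (iout < nt) {
    if (++nstep > max_steps)
      return List::create(_["ok"] = false, _["t_last"] = t,
                          _["message"] = "maximum step count exceeded",
                          _["states"] = out, _["o2_rate"] = o2rate);
    double tnext = times_day[iout];
    bool hit = false;
    if (t + h >= tnext) { h = tnext - t; hit = true; }

    if (!have_k1) { rhs(y, par.begin(), k1); have_k1 = true; }

    for (int i = 0; i < NS; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(ytmp, par.begin(), k2);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(ytmp, par.begin(), k3);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(ytmp, par.begin(), k4);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                            a54 * k4[i]);
    rhs(ytmp, par.begin(), k5);
    for (int i = 0; i < NS; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                            a64 * k4[i] + a65 * k5[i]);
    rhs(ytmp, par.begin(), k6);
    for (int i = 0; i < NS; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                            b5 * k5[i] + b6 * k6[i]);
    rhs(ynew, par.begin(), k7);

    double errnorm = 0.0;
    for (int i = 0; i < NS; ++i) {
      double erri = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                         e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = erri / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NS);

    if (errnorm <= 1.0) { // accept
      t += h;
      for (int i = 0; i < NS; ++i) {
        y[i] = ynew[i] > 0.0 ? ynew[i] : 0.0; // nonnegativity floor
        k1[i] = k7[i];                        // FSAL
      }
      // floor clipping invalidates FSAL only if something was clipped
      for (int i = 0; i < NS; ++i)
        if (ynew[i] < 0.0) { have_k1 = false; break; }
      if (hit || std::fabs(t - tnext) <= 1e-12 * std::fabs(tnext)) {
        for (int i = 0; i < NS; ++i) out(iout, i) = y[i];
        double dtmp[NS];
        rhs(y, par.begin(), dtmp);
        o2rate[iout] = dtmp[7];
        ++iout;
      }
      double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
      fac = std::min(5.0, std::max(0.2, fac));
      h *= fac;
    } else { // reject
      double fac = std::max(0.2, 0.9 * std::pow(errnorm, -0.2));
      h *= fac;
      if (h < hmin)
        return List::create(_["ok"] = false, _["t_last"] = t,
                            _["message"] = "step size underflow",
                            _["states"] = out, _["o2_rate"] = o2rate);
    }
  }

  return List::create(_["ok"] = true, _["t_last"] = t,
                      _["message"] = "", _["states"] = out,
                      _["o2_rate"] = o2rate);
}
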