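#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// State layout (22 coordinates):
//  0 S, 1 I, 2 T, 3 R                          -- compartments
//  4 new_to_I, 5 relapse_from_T, 6 relapse_from_R, 7 overdose_deaths,
//  8 left_I, 9 left_T                          -- cumulative flows (year-scoped)
// 10 T_I, 11 R_I, 12 I_T                       -- within-year sub-compartments
// 13 ret_I_from_T, 14 ret_I_from_R, 15 ret_T_from_I -- within-year return flows
// 16 int_I, 17 int_T                           -- integral of I, T over the year
// 18 int_cumleft_I, 19 int_cumret_I, 20 int_cumleft_T, 21 int_cumret_T
//    -- integrals of the year-to-date cumulative leaver / return counts,
//       i.e. yearly averages of the leaver correction components
// Coordinates 4..21 are reset at every calendar-year boundary; the completed
// year's values are emitted as one tally row first.

static const int NSTATE = 22;

// delta schedule: matrix with rows (t_start, slope, intercept); piece i applies
// for t >= t_start[i] (and piece 0 also for t < t_start[0]); delta = slope*t + intercept.
static inline double delta_eval(double t, const double* ds, int npiece) {
  int k = 0;
  for (int i = 1; i < npiece; ++i) {
    if (t >= ds[3 * i]) k = i; else break;
  }
  return ds[3 * k + 1] * t + ds[3 * k + 2];
}

struct Pars {
  double Lambda, mu, beta, eta1, eta2, eta3, omega, rho, kappa, alpha1, alpha2, eps;
  int ri_rho; // whether R_I receives the rho*T_I inflow
};

static inline void ioud_deriv(double t, const double* y, double* dy,
                              const Pars& p, const double* ds, int npiece) {
  const double S = y[0], I = y[1], T = y[2], R = y[3];
  const double N = S + I + T + R;
  if (!(N > 0.0)) stop("degenerate state: total population N must be positive (t = %f)", t);
  const double delta = delta_eval(t, ds, npiece);
  const double bT = 1.0 / (1.0 + p.eps * T);
  const double inc = p.beta * S * I / N;
  const double treat_in = bT * (p.eta1 * I + p.eta2 * I * R / N + p.eta3 * I * S / N);
  const double relT = p.kappa * T;
  const double relR = p.alpha1 * R + p.alpha2 * R * I / N;
  const double toR_I = p.omega * I;
  const double toR_T = p.rho * T;

  dy[0] = p.Lambda - inc - p.mu * S;
  dy[1] = inc + relR + relT - treat_in - toR_I - (p.mu + delta) * I;
  dy[2] = treat_in - relT - toR_T - p.mu * T;
  dy[3] = toR_I + toR_T - relR - p.mu * R;

  dy[4] = inc;
  dy[5] = relT;
  dy[6] = relR;
  dy[7] = delta * I;
  dy[8] = treat_in + toR_I;
  dy[9] = relT + toR_T;

  const double T_I = y[10], R_I = y[11], I_T = y[12];
  dy[10] = treat_in - (p.kappa + p.rho + p.mu) * T_I;
  dy[11] = toR_I + (p.ri_rho ? p.rho * T_I : 0.0) - (p.alpha1 + p.mu + p.alpha2 * I / N) * R_I;
  dy[12] = relT - (bT * (p.eta1 + p.eta2 * R / N + p.eta3 * S / N) + p.omega + p.mu + delta) * I_T;
  dy[13] = p.kappa * T_I;
  dy[14] = p.alpha1 * R_I;
  dy[15] = I_T * (p.eta1 + p.eta3 * S / N) * bT;
  dy[16] = I;
  dy[17] = T;
  dy[18] = y[8];           // running average of the I-leaver count
  dy[19] = y[13] + y[14];  // running average of returns to I
  dy[20] = y[9];
  dy[21] = y[15];
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187, a53 = 64448.0 / 6561,
                    a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600, e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640, e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate from t0 to tstop (no internal events); y updated in place.
// States appended to out rows for every requested output time hit exactly.
static void dp45_segment(double t0, double tstop, double* y, const Pars& p,
                         const double* ds, int npiece,
                         double rtol, double atol,
                         const std::vector<double>& tout, size_t& iout,
                         NumericMatrix& out_states) {
  double t = t0;
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE], k6[NSTATE], k7[NSTATE];
  double ytmp[NSTATE], ynew[NSTATE];
  ioud_deriv(t, y, k1, p, ds, npiece);
  double h = 1e-3;
  long nstep = 0;
  while (t < tstop - 1e-12) {
    if (++nstep > 2000000L) stop("integrator exceeded maximum step count");
    double tnext = tstop;
    if (iout < tout.size() && tout[iout] < tnext) tnext = tout[iout];
    if (t + h > tnext) h = tnext - t;
    if (h < 1e-13 * std::max(1.0, std::fabs(t)))
      stop("integrator step size underflow at t = %f", t);

    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    ioud_deriv(t + c2 * h, ytmp, k2, p, ds, npiece);
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    ioud_deriv(t + c3 * h, ytmp, k3, p, ds, npiece);
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    ioud_deriv(t + c4 * h, ytmp, k4, p, ds, npiece);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    ioud_deriv(t + c5 * h, ytmp, k5, p, ds, npiece);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
    ioud_deriv(t + h, ytmp, k6, p, ds, npiece);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
    ioud_deriv(t + h, ynew, k7, p, ds, npiece);

    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSTATE);

    if (errnorm <= 1.0) { // accept
      t += h;
      for (int i = 0; i < NSTATE; ++i) y[i] = ynew[i];
      for (int i = 0; i < 4; ++i) {
        if (y[i] < 0.0) {
          if (y[i] < -1e-8)
            stop("compartment %d undershot below -1e-8 persons at t = %f (value %g)", i, t, y[i]);
          y[i] = 0.0;
        }
      }
      for (int i = 4; i < NSTATE; ++i) if (y[i] < 0.0 && y[i] > -1e-8) y[i] = 0.0;
      for (int i = 0; i < NSTATE; ++i) k1[i] = k7[i]; // FSAL
      while (iout < tout.size() && tout[iout] <= t + 1e-12) {
        for (int i = 0; i < NSTATE; ++i) out_states(iout, i) = y[i];
        ++iout;
      }
    }
    double fac = (errnorm > 1e-30) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
  }
}

// [[Rcpp::export(name = ".ioud_integrate_cpp")]]
List ioud_integrate_cpp(NumericVector init, double t0, double t1,
                        NumericVector pars, NumericMatrix delta_schedule,
                        NumericVector tout_in,
                        double rtol = 1e-9, double atol = 1e-9,
                        int ri_rho = 1) {
  if (t1 <= t0) stop("t1 must exceed t0");
  if (init.size() != 4) stop("init must have 4 components (S, I, T, R)");
  Pars p;
  p.Lambda = pars["Lambda"]; p.mu = pars["mu"]; p.beta = pars["beta"];
  p.eta1 = pars["eta1"]; p.eta2 = pars["eta2"]; p.eta3 = pars["eta3"];
  p.omega = pars["omega"]; p.rho = pars["rho"]; p.kappa = pars["kappa"];
  p.alpha1 = pars["alpha1"]; p.alpha2 = pars["alpha2"]; p.eps = pars["epsilon"];
  p.ri_rho = ri_rho;

  int npiece = delta_schedule.nrow();
  std::vector<double> ds(npiece * 3);
  for (int i = 0; i < npiece; ++i)
    for (int j = 0; j < 3; ++j) ds[3 * i + j] = delta_schedule(i, j);

  std::vector<double> tout(tout_in.begin(), tout_in.end());
  std::sort(tout.begin(), tout.end());

  // stop points: year boundaries and schedule starts interior to (t0, t1), plus t1
  std::vector<double> stops;
  for (double yb = std::floor(t0) + 1.0; yb < t1 - 1e-12; yb += 1.0)
    if (yb > t0 + 1e-12) stops.push_back(yb);
  for (int i = 0; i < npiece; ++i) {
    double b = ds[3 * i];
    if (std::isfinite(b) && b > t0 + 1e-9 && b < t1 - 1e-9) stops.push_back(b);
  }
  stops.push_back(t1);
  std::sort(stops.begin(), stops.end());

  NumericMatrix out_states(tout.size(), NSTATE);
  double y[NSTATE];
  for (int i = 0; i < 4; ++i) {
    if (init[i] < 0) stop("initial compartments must be nonnegative");
    y[i] = init[i];
  }
  for (int i = 4; i < NSTATE; ++i) y[i] = 0.0;

  std::vector<std::vector<double> > tallies;
  size_t iout = 0;
  while (iout < tout.size() && tout[iout] <= t0 + 1e-12) {
    for (int i = 0; i < NSTATE; ++i) out_states(iout, i) = y[i];
    ++iout;
  }

  double t = t0;
  for (size_t s = 0; s < stops.size(); ++s) {
    double tstop = stops[s];
    if (tstop <= t + 1e-12) continue;
    dp45_segment(t, tstop, y, p, ds.data(), npiece, rtol, atol, tout, iout, out_states);
    t = tstop;
    bool year_boundary = std::fabs(t - std::round(t)) < 1e-9;
    if (year_boundary) {
      double year = std::round(t) - 1.0;
      if (year >= t0 - 1e-9) { // full calendar year covered iff t0 <= year
        bool full = (t0 <= year + 1e-9);
        std::vector<double> row(20);
        row[0] = year;
        row[1] = full ? 1.0 : 0.0;
        row[2] = y[16]; // integral of I over the year (mean, since length 1)
        row[3] = y[17]; // integral of T
        for (int i = 0; i < 12; ++i) row[4 + i] = y[4 + i];
        for (int i = 0; i < 4; ++i) row[16 + i] = y[18 + i];
        tallies.push_back(row);
      }
      // reset year-scoped coordinates (also return-flow accumulators 13..15)
      for (int i = 4; i < NSTATE; ++i) y[i] = 0.0;
    }
  }

  // row layout built above: year, full, int_I, int_T, y[4..15], y[18..21]
  NumericMatrix tal(tallies.size(), 20);
  for (size_t r = 0; r < tallies.size(); ++r)
    for (int j = 0; j < 20; ++j) tal(r, j) = tallies[r][j];
  colnames(tal) = CharacterVector::create(
      "year", "full", "int_I", "int_T", "new_to_I", "relapse_from_T",
      "relapse_from_R", "overdose_deaths", "left_I", "left_T",
      "T_I_end", "R_I_end", "I_T_end",
      "ret_I_from_T", "ret_I_from_R", "ret_T_from_I",
      "avg_left_I", "avg_ret_I", "avg_left_T", "avg_ret_T");

  return List::create(_["times"] = wrap(tout), _["states"] = out_states,
                      _["tallies"] = tal, _["final"] = NumericVector(y, y + NSTATE));
}
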