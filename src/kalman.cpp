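// State-space core for stationary Gaussian movement processes.
//
// Per axis the OUF process is the 2-state (position, velocity) Gaussian
// Markov process whose continuous dynamics matrix has eigenvalues -1/tauP
// and -1/tauV; OU is the 1-state limit (tauV -> 0), IID the memoryless
// limit.  All three share a stationary per-axis positional variance sigma.
// The transition over a step dt is the matrix exponential, the process
// noise follows from the stationary-covariance identity Q = S - Phi S Phi'.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double REPEATED_ROOT_TOL = 1e-6;

struct Phi2 {
  double a11, a12, a21, a22;      // transition
  double q11, q12, q22;           // innovation covariance (symmetric)
};

// OUF transition + innovation covariance for one time step.
static Phi2 ouf_step(double dt, double tauP, double tauV, double sigma) {
  Phi2 out;
  const double l1 = -1.0 / tauP, l2 = -1.0 / tauV;
  // dynamics A = [[0, 1], [-l1*l2, l1+l2]]
  const double A21 = -l1 * l2, A22 = l1 + l2;
  double p11, p12, p21, p22;
  if (std::fabs(tauP - tauV) < REPEATED_ROOT_TOL * tauP) {
    // repeated-root limit: exp(At) = e^{lt} (I + (A - lI) t)
    const double l = -1.0 / tauP, e = std::exp(l * dt);
    p11 = e * (1.0 - l * dt);
    p12 = e * dt;
    p21 = e * A21 * dt;
    p22 = e * (1.0 + (A22 - l) * dt);
  } else {
    // Lagrange interpolation on the two eigenvalues
    const double e1 = std::exp(l1 * dt), e2 = std::exp(l2 * dt);
    const double d = l1 - l2;
    const double c1 = e1 / d, c2 = -e2 / d;
    // exp(At) = c1 (A - l2 I) + c2 (A - l1 I)
    p11 = c1 * (0.0 - l2) + c2 * (0.0 - l1);
    p12 = c1 + c2;
    p21 = c1 * A21 + c2 * A21;
    p22 = c1 * (A22 - l2) + c2 * (A22 - l1);
  }
  out.a11 = p11; out.a12 = p12; out.a21 = p21; out.a22 = p22;
  // stationary covariance S = diag(sigma, sigma/(tauP*tauV))
  const double sv = sigma / (tauP * tauV);
  // Q = S - Phi S Phi'
  out.q11 = sigma - (p11 * p11 * sigma + p12 * p12 * sv);
  out.q12 = -(p11 * p21 * sigma + p12 * p22 * sv);
  out.q22 = sv - (p21 * p21 * sigma + p22 * p22 * sv);
  if (out.q11 < 0.0) out.q11 = 0.0;
  if (out.q22 < 0.0) out.q22 = 0.0;
  return out;
}

// One-axis filter pass.  The filter is run jointly on the observation
// series z and on the constant regressor 1 (same gains, since the error
// covariance recursion is data-free), which yields the innovations
// decomposition of the generalized-least-squares problem for the unknown
// stationary mean mu.  kind: 0 = IID, 1 = OU, 2 = OUF.
//
// mode 0: mu fixed (given), plain log-likelihood
// mode 1: mu profiled out by GLS (profile log-likelihood)
// mode 2: REML: profile log-likelihood - 0.5*log(sum u^2/F) + 0.5*log(2pi)
struct AxisFit { double ll; double mu; };

static AxisFit axis_loglik(const NumericVector& t, const NumericVector& z,
                           int kind, double tauP, double tauV, double sigma,
                           double mu, const NumericVector& errVar,
                           int mode) {
  const int n = t.size();
  const double LOG2PI = 1.8378770664093454836;
  double logdet = 0.0, Svv = 0.0, Suv = 0.0, Suu = 0.0;

  if (kind == 0) {
    for (int i = 0; i < n; i++) {
      const double F = sigma + errVar[i];
      const double v = (mode == 0) ? z[i] - mu : z[i];
      logdet += std::log(F);
      Svv += v * v / F;
      Suv += v / F;
      Suu += 1.0 / F;
    }
  } else if (kind == 1) {
    double m = 0.0, w = 0.0, P = sigma;
    double prev_dt = -1.0, a = 0.0, q = 0.0;
    for (int i = 0; i < n; i++) {
      if (i > 0) {
        const double dt = t[i] - t[i - 1];
        if (dt != prev_dt) {
          a = std::exp(-dt / tauP);
          q = sigma * (1.0 - a * a);
          prev_dt = dt;
        }
        m = a * m;
        w = a * w;
        P = a * a * P + q;
      }
      const double F = P + errVar[i];
      const double v = ((mode == 0) ? z[i] - mu : z[i]) - m;
      const double u = 1.0 - w;
      if (!(F > 0.0) || !std::isfinite(v))
        stop("non-finite Kalman recursion at time index %d", i + 1);
      logdet += std::log(F);
      Svv += v * v / F; Suv += u * v / F; Suu += u * u / F;
      const double K = P / F;
      m += K * v;
      w += K * u;
      P *= (1.0 - K);
    }
  } else {
    // OUF: 2-state filter, observation H = [1, 0]
    double m1 = 0.0, m2 = 0.0, w1 = 0.0, w2 = 0.0;
    double P11 = sigma, P12 = 0.0, P22 = sigma / (tauP * tauV);
    double prev_dt = -1.0;
    Phi2 G;
    for (int i = 0; i < n; i++) {
      if (i > 0) {
        const double dt = t[i] - t[i - 1];
        if (dt != prev_dt) { G = ouf_step(dt, tauP, tauV, sigma);
                             prev_dt = dt; }
        double a1 = G.a11 * m1 + G.a12 * m2;
        double a2 = G.a21 * m1 + G.a22 * m2;
        m1 = a1; m2 = a2;
        a1 = G.a11 * w1 + G.a12 * w2;
        a2 = G.a21 * w1 + G.a22 * w2;
        w1 = a1; w2 = a2;
        // P <- Phi P Phi' + Q
        const double t11 = G.a11 * P11 + G.a12 * P12;
        const double t12 = G.a11 * P12 + G.a12 * P22;
        const double t21 = G.a21 * P11 + G.a22 * P12;
        const double t22 = G.a21 * P12 + G.a22 * P22;
        const double N11 = t11 * G.a11 + t12 * G.a12 + G.q11;
        const double N12 = t11 * G.a21 + t12 * G.a22 + G.q12;
        const double N22 = t21 * G.a21 + t22 * G.a22 + G.q22;
        P11 = N11; P12 = N12; P22 = N22;
      }
      const double F = P11 + errVar[i];
      const double v = ((mode == 0) ? z[i] - mu : z[i]) - m1;
      const double u = 1.0 - w1;
      if (!(F > 0.0) || !std::isfinite(v))
        stop("non-finite Kalman recursion at time index %d", i + 1);
      logdet += std::log(F);
      Svv += v * v / F; Suv += u * v / F; Suu += u * u / F;
      const double K1 = P11 / F, K2 = P12 / F;
      m1 += K1 * v;
      m2 += K2 * v;
      w1 += K1 * u;
      w2 += K2 * u;
      const double Q11 = P11 - K1 * P11, Q12 = P12 - K1 * P12,
                   Q22 = P22 - K2 * P12;
      P11 = Q11; P12 = Q12; P22 = Q22;
    }
  }

  AxisFit out;
  if (mode == 0) {
    out.mu = mu;
    out.ll = -0.5 * (n * LOG2PI + logdet + Svv);
    return out;
  }
  out.mu = Suv / Suu;
  const double quad = Svv - Suv * Suv / Suu;
  out.ll = -0.5 * (n * LOG2PI + logdet + quad);
  if (mode == 2) out.ll += 0.5 * (LOG2PI - std::log(Suu));
  return out;
}

// [[Rcpp::export(name = ".ck_loglik")]]
double ck_loglik(NumericVector t, NumericVector x, NumericVector y,
                 int kind, double tauP, double tauV, double sigma,
                 double mux, double muy, NumericVector errVar) {
  return axis_loglik(t, x, kind, tauP, tauV, sigma, mux, errVar, 0).ll +
         axis_loglik(t, y, kind, tauP, tauV, sigma, muy, errVar, 0).ll;
}

// Profile (mode 1) or restricted (mode 2) log-likelihood with the center
// estimated by GLS inside the filter; returns (ll, mux, muy).
// [[Rcpp::export(name = ".ck_profile")]]
NumericVector ck_profile(NumericVector t, NumericVector x, NumericVector y,
                         int kind, double tauP, double tauV, double sigma,
                         NumericVector errVar, int mode) {
  AxisFit fx = axis_loglik(t, x, kind, tauP, tauV, sigma, 0.0, errVar, mode);
  AxisFit fy = axis_loglik(t, y, kind, tauP, tauV, sigma, 0.0, errVar, mode);
  return NumericVector::create(fx.ll + fy.ll, fx.mu, fy.mu);
}

// Exact stationary simulation at arbitrary times.  Returns n x 4 matrix
// (x, y, vx, vy); velocities are zero for IID/OU.  Uses R's RNG.
// [[Rcpp::export(name = ".ck_simulate")]]
NumericMatrix ck_simulate(NumericVector t, int kind, double tauP,
                          double tauV, double sigma,
                          double mux, double muy) {
  const int n = t.size();
  NumericMatrix out(n, 4);
  const double sd0 = std::sqrt(sigma);

  if (kind == 0) {
    for (int i = 0; i < n; i++) {
      out(i, 0) = mux + norm_rand() * sd0;
      out(i, 1) = muy + norm_rand() * sd0;
    }
    return out;
  }

  if (kind == 1) {
    for (int ax = 0; ax < 2; ax++) {
      double m = norm_rand() * sd0;
      out(0, ax) = m;
      double prev_dt = -1.0, a = 0.0, s = 0.0;
      for (int i = 1; i < n; i++) {
        const double dt = t[i] - t[i - 1];
        if (dt != prev_dt) {
          a = std::exp(-dt / tauP);
          s = std::sqrt(sigma * (1.0 - a * a));
          prev_dt = dt;
        }
        m = a * m + norm_rand() * s;
        out(i, ax) = m;
      }
    }
    for (int i = 0; i < n; i++) { out(i, 0) += mux; out(i, 1) += muy; }
    return out;
  }

  const double sv = std::sqrt(sigma / (tauP * tauV));
  for (int ax = 0; ax < 2; ax++) {
    double z1 = norm_rand() * sd0, z2 = norm_rand() * sv;
    out(0, ax) = z1; out(0, ax + 2) = z2;
    double prev_dt = -1.0;
    Phi2 G;
    double c11 = 0.0, c21 = 0.0, c22 = 0.0;  // chol of Q (lower)
    for (int i = 1; i < n; i++) {
      const double dt = t[i] - t[i - 1];
      if (dt != prev_dt) {
        G = ouf_step(dt, tauP, tauV, sigma);
        c11 = std::sqrt(G.q11);
        c21 = c11 > 0.0 ? G.q12 / c11 : 0.0;
        double r = G.q22 - c21 * c21;
        c22 = r > 0.0 ? std::sqrt(r) : 0.0;
        prev_dt = dt;
      }
      const double w1 = norm_rand(), w2 = norm_rand();
      const double n1 = G.a11 * z1 + G.a12 * z2 + c11 * w1;
      const double n2 = G.a21 * z1 + G.a22 * z2 + c21 * w1 + c22 * w2;
      z1 = n1; z2 = n2;
      out(i, ax) = z1; out(i, ax + 2) = z2;
    }
  }
  for (int i = 0; i < n; i++) { out(i, 0) += mux; out(i, 1) += muy; }
  return out;
}

// RTS smoother for the OUF model, one axis: returns n x 2 matrix of
// smoothed state means (position, velocity) given observations z.
// [[Rcpp::export(name = ".ck_smooth")]]
NumericMatrix ck_smooth(NumericVector t, NumericVector z,
                        double tauP, double tauV, double sigma,
                        double mu, NumericVector errVar) {
  const int n = t.size();
  std::vector<double> fm1(n), fm2(n), fP11(n), fP12(n), fP22(n);
  std::vector<double> pm1(n), pm2(n), pP11(n), pP12(n), pP22(n);
  std::vector<Phi2> Gs(n);

  double m1 = 0.0, m2 = 0.0;
  double P11 = sigma, P12 = 0.0, P22 = sigma / (tauP * tauV);
  double prev_dt = -1.0;
  Phi2 G;
  for (int i = 0; i < n; i++) {
    if (i > 0) {
      const double dt = t[i] - t[i - 1];
      if (dt != prev_dt) { G = ouf_step(dt, tauP, tauV, sigma); prev_dt = dt; }
      Gs[i] = G;
      const double n1 = G.a11 * m1 + G.a12 * m2;
      const double n2 = G.a21 * m1 + G.a22 * m2;
      m1 = n1; m2 = n2;
      const double t11 = G.a11 * P11 + G.a12 * P12;
      const double t12 = G.a11 * P12 + G.a12 * P22;
      const double t21 = G.a21 * P11 + G.a22 * P12;
      const double t22 = G.a21 * P12 + G.a22 * P22;
      const double N11 = t11 * G.a11 + t12 * G.a12 + G.q11;
      const double N12 = t11 * G.a21 + t12 * G.a22 + G.q12;
      const double N22 = t21 * G.a21 + t22 * G.a22 + G.q22;
      P11 = N11; P12 = N12; P22 = N22;
    }
    pm1[i] = m1; pm2[i] = m2; pP11[i] = P11; pP12[i] = P12; pP22[i] = P22;
    const double F = P11 + errVar[i];
    const double v = z[i] - mu - m1;
    const double K1 = P11 / F, K2 = P12 / F;
    m1 += K1 * v;
    m2 += K2 * v;
    const double Q11 = P11 - K1 * P11, Q12 = P12 - K1 * P12,
                 Q22 = P22 - K2 * P12;
    P11 = Q11; P12 = Q12; P22 = Q22;
    fm1[i] = m1; fm2[i] = m2; fP11[i] = P11; fP12[i] = P12; fP22[i] = P22;
  }

  NumericMatrix out(n, 2);
  double s1 = fm1[n - 1], s2 = fm2[n - 1];
  out(n - 1, 0) = s1 + mu; out(n - 1, 1) = s2;
  for (int i = n - 2; i >= 0; i--) {
    const Phi2& g = Gs[i + 1];
    // C = P_f Phi'  (2x2)
    const double C11 = fP11[i] * g.a11 + fP12[i] * g.a12;
    const double C12 = fP11[i] * g.a21 + fP12[i] * g.a22;
    const double C21 = fP12[i] * g.a11 + fP22[i] * g.a12;
    const double C22 = fP12[i] * g.a21 + fP22[i] * g.a22;
    // J = C * inv(P_p)
    const double det = pP11[i + 1] * pP22[i + 1] - pP12[i + 1] * pP12[i + 1];
    double J11, J12, J21, J22;
    if (det > 0.0) {
      const double i11 = pP22[i + 1] / det, i12 = -pP12[i + 1] / det,
                   i22 = pP11[i + 1] / det;
      J11 = C11 * i11 + C12 * i12; J12 = C11 * i12 + C12 * i22;
      J21 = C21 * i11 + C22 * i12; J22 = C21 * i12 + C22 * i22;
    } else {
      J11 = J12 = J21 = J22 = 0.0;
    }
    const double d1 = s1 - pm1[i + 1], d2 = s2 - pm2[i + 1];
    const double t1 = fm1[i] + J11 * d1 + J12 * d2;
    const double t2 = fm2[i] + J21 * d1 + J22 * d2;
    s1 = t1; s2 = t2;
    out(i, 0) = s1 + mu; out(i, 1) = s2;
  }
  return out;
}
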