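#include <Rcpp.h>
using namespace Rcpp;

// Gradient-descent orientation filter (IMU and MARG variants) and a scalar
// random-walk Kalman filter. Quaternions are (w, x, y, z), body-to-earth;
// gyro rates in rad/s; accelerometer in any consistent unit (normalized
// internally); time step in seconds.

static inline void normalize4(double q[4]) {
  double n = std::sqrt(q[0] * q[0] + q[1] * q[1] + q[2] * q[2] + q[3] * q[3]);
  q[0] /= n; q[1] /= n; q[2] /= n; q[3] /= n;
}

// One filter step; returns true if the accelerometer correction was applied,
// false when it degraded to gyro-only integration (zero-norm accelerometer).
static bool madgwick_step(double q[4],
                          double ax, double ay, double az,
                          double gx, double gy, double gz,
                          const double *mag, bool use_mag,
                          double dt, double beta) {
  double q0 = q[0], q1 = q[1], q2 = q[2], q3 = q[3];

  // quaternion rate from gyroscope: 0.5 * q (x) (0, gx, gy, gz)
  double qDot0 = 0.5 * (-q1 * gx - q2 * gy - q3 * gz);
  double qDot1 = 0.5 * ( q0 * gx + q2 * gz - q3 * gy);
  double qDot2 = 0.5 * ( q0 * gy - q1 * gz + q3 * gx);
  double qDot3 = 0.5 * ( q0 * gz + q1 * gy - q2 * gx);

  double anorm = std::sqrt(ax * ax + ay * ay + az * az);
  bool corrected = anorm > 1e-12;
  if (corrected) {
    ax /= anorm; ay /= anorm; az /= anorm;

    // gravity objective: f = R^T e_z - a
    double f1 = 2.0 * (q1 * q3 - q0 * q2) - ax;
    double f2 = 2.0 * (q0 * q1 + q2 * q3) - ay;
    double f3 = 2.0 * (0.5 - q1 * q1 - q2 * q2) - az;

    double s0 = -2.0 * q2 * f1 + 2.0 * q1 * f2;
    double s1 =  2.0 * q3 * f1 + 2.0 * q0 * f2 - 4.0 * q1 * f3;
    double s2 = -2.0 * q0 * f1 + 2.0 * q3 * f2 - 4.0 * q2 * f3;
    double s3 =  2.0 * q1 * f1 + 2.0 * q2 * f2;

    if (use_mag) {
      double mx = mag[0], my = mag[1], mz = mag[2];
      double mnorm = std::sqrt(mx * mx + my * my + mz * mz);
      if (mnorm > 1e-12) {
        mx /= mnorm; my /= mnorm; mz /= mnorm;
        // reference field b = (bx, 0, bz) from the measured field rotated
        // into the earth frame
        double hx = mx * (1 - 2 * (q2 * q2 + q3 * q3)) +
                    my * 2 * (q1 * q2 - q0 * q3) +
                    mz * 2 * (q1 * q3 + q0 * q2);
        double hy = mx * 2 * (q1 * q2 + q0 * q3) +
                    my * (1 - 2 * (q1 * q1 + q3 * q3)) +
                    mz * 2 * (q2 * q3 - q0 * q1);
        double hz = mx * 2 * (q1 * q3 - q0 * q2) +
                    my * 2 * (q2 * q3 + q0 * q1) +
                    mz * (1 - 2 * (q1 * q1 + q2 * q2));
        double bx = std::sqrt(hx * hx + hy * hy);
        double bz = hz;

        double fm1 = 2.0 * bx * (0.5 - q2 * q2 - q3 * q3) +
                     2.0 * bz * (q1 * q3 - q0 * q2) - mx;
        double fm2 = 2.0 * bx * (q1 * q2 - q0 * q3) +
                     2.0 * bz * (q0 * q1 + q2 * q3) - my;
        double fm3 = 2.0 * bx * (q0 * q2 + q1 * q3) +
                     2.0 * bz * (0.5 - q1 * q1 - q2 * q2) - mz;

        s0 += (-2.0 * bz * q2) * fm1 +
              (-2.0 * bx * q3 + 2.0 * bz * q1) * fm2 +
              ( 2.0 * bx * q2) * fm3;
        s1 += ( 2.0 * bz * q3) * fm1 +
              ( 2.0 * bx * q2 + 2.0 * bz * q0) * fm2 +
              ( 2.0 * bx * q3 - 4.0 * bz * q1) * fm3;
        s2 += (-4.0 * bx * q2 - 2.0 * bz * q0) * fm1 +
              ( 2.0 * bx * q1 + 2.0 * bz * q3) * fm2 +
              ( 2.0 * bx * q0 - 4.0 * bz * q2) * fm3;
        s3 += (-4.0 * bx * q3 + 2.0 * bz * q1) * fm1 +
              (-2.0 * bx * q0 + 2.0 * bz * q2) * fm2 +
              ( 2.0 * bx * q1) * fm3;
      }
    }

    double snorm = std::sqrt(s0 * s0 + s1 * s1 + s2 * s2 + s3 * s3);
    if (snorm > 1e-12) {
      qDot0 -= beta * s0 / snorm;
      qDot1 -= beta * s1 / snorm;
      qDot2 -= beta * s2 / snorm;
      qDot3 -= beta * s3 / snorm;
    }
  }

  q[0] += qDot0 * dt;
  q[1] += qDot1 * dt;
  q[2] += qDot2 * dt;
  q[3] += qDot3 * dt;
  normalize4(q);
  return corrected;
}

// [[Rcpp::export]]
List madgwick_step_cpp(NumericVector q0, NumericVector acc, NumericVector gyr,
                       NumericVector mag, double dt, double beta) {
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  bool use_mag = mag.size() == 3;
  double m[3] = {0, 0, 0};
  if (use_mag) { m[0] = mag[0]; m[1] = mag[1]; m[2] = mag[2]; }
  bool corrected = madgwick_step(q, acc[0], acc[1], acc[2],
                                 gyr[0], gyr[1], gyr[2], m, use_mag, dt, beta);
  return List::create(_["q"] = NumericVector::create(q[0], q[1], q[2], q[3]),
                      _["gyro_only"] = !corrected);
}

// [[Rcpp::export]]
NumericMatrix madgwick_filter_cpp(NumericMatrix acc, NumericMatrix gyr,
                                  NumericMatrix mag, NumericVector dt,
                                  double beta, NumericVector q0) {
  int n = acc.nrow();
  bool use_mag = mag.nrow() == n && mag.ncol() == 3;
  NumericMatrix out(n, 4);
  double q[4] = {q0[0], q0[1], q0[2], q0[3]};
  double m[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    if (use_mag) { m[0] = mag(i, 0); m[1] = mag(i, 1); m[2] = mag(i, 2); }
    madgwick_step(q, acc(i, 0), acc(i, 1), acc(i, 2),
                  gyr(i, 0), gyr(i, 1), gyr(i, 2), m, use_mag, dt[i], beta);
    out(i, 0) = q[0]; out(i, 1) = q[1]; out(i, 2) = q[2]; out(i, 3) = q[3];
  }
  return out;
}

// [[Rcpp::export]]
List kalman_filter_cpp(NumericVector z, double a0, double P0,
                       double q_proc, double r_meas) {
  int n = z.size();
  NumericVector est(n), var(n);
  double a = a0, P = P0;
  for (int i = 0; i < n; ++i) {
    if (R_finite(z[i])) {
      P += q_proc;
      double K = P / (P + r_meas);
      a += K * (z[i] - a);
      P *= (1.0 - K);
    }
    est[i] = a;
    var[i] = P;
  }
  return List::create(_["estimate"] = est, _["variance"] = var);
}
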