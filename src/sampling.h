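#ifndef IMMUNOPET_SAMPLING_H
#define IMMUNOPET_SAMPLING_H

#include <cmath>
#include <cstdint>

// Shared trilinear sampling over a column-major (d1,d2,d3) array.
// Coordinates within SNAP_TOL of a lattice point are snapped so that
// identity resampling and right-angle rotations are value-exact.
namespace ipet {

static const double SNAP_TOL = 1e-9;

inline double snap(double x) {
  double r = std::round(x);
  return (std::fabs(x - r) < SNAP_TOL) ? r : x;
}

// mode 0: out-of-bounds -> fill; mode 1: clamp to edge
inline double sample3(const double *a, int d1, int d2, int d3,
                      double f1, double f2, double f3,
                      int mode, double fill) {
  f1 = snap(f1); f2 = snap(f2); f3 = snap(f3);
  if (mode == 1) {
    if (f1 < 0) f1 = 0;
    if (f1 > d1 - 1) f1 = d1 - 1;
    if (f2 < 0) f2 = 0;
    if (f2 > d2 - 1) f2 = d2 - 1;
    if (f3 < 0) f3 = 0;
    if (f3 > d3 - 1) f3 = d3 - 1;
  } else {
    if (f1 < -0.5 || f1 > d1 - 0.5 || f2 < -0.5 || f2 > d2 - 0.5 ||
        f3 < -0.5 || f3 > d3 - 0.5)
      return fill;
  }
  int i1 = (int)std::floor(f1), i2 = (int)std::floor(f2), i3 = (int)std::floor(f3);
  double w1 = f1 - i1, w2 = f2 - i2, w3 = f3 - i3;
  double out = 0.0;
  for (int c3 = 0; c3 <= 1; ++c3) {
    double g3 = c3 ? w3 : 1.0 - w3;
    if (g3 == 0.0) continue;
    int j3 = i3 + c3;
    for (int c2 = 0; c2 <= 1; ++c2) {
      double g2 = c2 ? w2 : 1.0 - w2;
      if (g2 == 0.0) continue;
      int j2 = i2 + c2;
      for (int c1 = 0; c1 <= 1; ++c1) {
        double g1 = c1 ? w1 : 1.0 - w1;
        if (g1 == 0.0) continue;
        int j1 = i1 + c1;
        double v;
        if (j1 < 0 || j1 >= d1 || j2 < 0 || j2 >= d2 || j3 < 0 || j3 >= d3) {
          if (mode == 1) {
            int k1 = j1 < 0 ? 0 : (j1 >= d1 ? d1 - 1 : j1);
            int k2 = j2 < 0 ? 0 : (j2 >= d2 ? d2 - 1 : j2);
            int k3 = j3 < 0 ? 0 : (j3 >= d3 ? d3 - 1 : j3);
            v = a[k1 + (std::int64_t)d1 * (k2 + (std::int64_t)d2 * k3)];
          } else {
            v = fill;
          }
        } else {
          v = a[j1 + (std::int64_t)d1 * (j2 + (std::int64_t)d2 * j3)];
        }
        out += g1 * g2 * g3 * v;
      }
    }
  }
  return out;
}

// Inverse rotation matrix for forward rotation order: about axis 1 ("z",
// rotating the (2,3) plane), then axis 2, then axis 3.  Sampling uses the
// inverse map p_in = Rz(-az) Ry(-ay) Rx(-ax) (p_out - c) + c.
inline void inverse_rotation(double az, double ay, double ax, double M[3][3]) {
  const double d2r = std::atan(1.0) / 45.0;
  double cz = std::cos(-az * d2r), sz = std::sin(-az * d2r);
  double cy = std::cos(-ay * d2r), sy = std::sin(-ay * d2r);
  double cx = std::cos(-ax * d2r), sx = std::sin(-ax * d2r);
  // axis-1 rotation acts on coords (2,3); axis-2 on (1,3); axis-3 on (1,2)
  double Rz[3][3] = {{1, 0, 0}, {0, cz, -sz}, {0, sz, cz}};
  double Ry[3][3] = {{cy, 0, -sy}, {0, 1, 0}, {sy, 0, cy}};
  double Rx[3][3] = {{cx, -sx, 0}, {sx, cx, 0}, {0, 0, 1}};
  double T[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      T[i][j] = 0;
      for (int k = 0; k < 3; ++k) T[i][j] += Ry[i][k] * Rx[k][j];
    }
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      M[i][j] = 0;
      for (int k = 0; k < 3; ++k) M[i][j] += Rz[i][k] * T[k][j];
    }
}

// Rotate a (d1,d2,d3) array about its center, trilinear, fill 0.
inline void rotate_array(const double *in, double *out, int d1, int d2, int d3,
                         double az, double ay, double ax) {
  double M[3][3];
  inverse_rotation(az, ay, ax, M);
  double c1 = (d1 - 1) / 2.0, c2 = (d2 - 1) / 2.0, c3 = (d3 - 1) / 2.0;
  std::int64_t idx = 0;
  for (int i3 = 0; i3 < d3; ++i3) {
    double p3 = i3 - c3;
    for (int i2 = 0; i2 < d2; ++i2) {
      double p2 = i2 - c2;
      for (int i1 = 0; i1 < d1; ++i1, ++idx) {
        double p1 = i1 - c1;
        double f1 = M[0][0] * p1 + M[0][1] * p2 + M[0][2] * p3 + c1;
        double f2 = M[1][0] * p1 + M[1][1] * p2 + M[1][2] * p3 + c2;
        double f3 = M[2][0] * p1 + M[2][1] * p2 + M[2][2] * p3 + c3;
        out[idx] = sample3(in, d1, d2, d3, f1, f2, f3, 0, 0.0);
      }
    }
  }
}

} // namespace ipet

#endif
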