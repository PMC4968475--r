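// Single-layer Stokes boundary-element kernels for a sphere above a plane
// no-slip wall (y = 0).  The wall is enforced exactly through the image
// system of Blake (1971); an optional single mirror reflection across an
// upper plane y = L approximates the free-slip truncation boundary of a
// reduced computational domain.
//
// Panels are spherical quadrilaterals [theta1,theta2] x [phi1,phi2] on a
// sphere of radius a centred at (0, yc, 0); theta is measured from the
// wall-facing pole so the contact region is theta -> 0.  Panel areas are
// exact; centroids sit at the area centroid (cos(theta_c) is the mean of the
// band's cosines), which makes the discrete closed-surface identities exact.

#include <Rcpp.h>
#include <R_ext/Lapack.h>
#include <cmath>

using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Free-space Oseen tensor (times 8*pi*mu): G_ij = d_ij/r + r_i r_j / r^3
static inline void oseen(const double* r, double G[3][3]) {
  double r2 = r[0]*r[0] + r[1]*r[1] + r[2]*r[2];
  double rn = std::sqrt(r2);
  double ir = 1.0 / rn, ir3 = ir / r2;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      G[i][j] = (i == j ? ir : 0.0) + r[i]*r[j]*ir3;
}

// Image part of the Blake wall kernel (times 8*pi*mu).  x is the field
// point, y0 the source (height h0 = y0[1] > 0), wall at y = 0.  Adds
// -S(R) + 2 h0 m_j d/dR_j [ h0 R_i/R^3 - d_{i2}/R - R_i R_2/R^3 ]
// with R = x - image(y0) and m = (1,-1,1).  Verified to cancel the direct
// Stokeslet exactly on the wall (unit tests).
static inline void blake_image(const double* x, const double* y0,
                               double G[3][3]) {
  double h0 = y0[1];
  double R[3] = { x[0] - y0[0], x[1] + y0[1], x[2] - y0[2] };
  double R2 = R[0]*R[0] + R[1]*R[1] + R[2]*R[2];
  double Rn = std::sqrt(R2);
  double iR = 1.0 / Rn, iR3 = iR / R2, iR5 = iR3 / R2;
  double m[3] = { 1.0, -1.0, 1.0 };
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      double Sij = (i == j ? iR : 0.0) + R[i]*R[j]*iR3;
      double dij = (i == j) ? 1.0 : 0.0;
      double di2 = (i == 1) ? 1.0 : 0.0;
      double d2j = (j == 1) ? 1.0 : 0.0;
      double term = h0 * (dij*iR3 - 3.0*R[i]*R[j]*iR5)
        + di2 * R[j] * iR3
        - (dij * R[1] + d2j * R[i]) * iR3
        + 3.0 * R[i] * R[1] * R[j] * iR5;
      G[i][j] = -Sij + 2.0 * h0 * m[j] * term;
    }
  }
}

// Full kernel (times 8*pi*mu): direct Oseen (optional), wall image
// (optional), and a mirror reflection of the wall kernel across y = conf_h
// (optional, conf_h <= 0 disables).  The reflected source keeps the lower
// wall exactly no-slip (the Blake kernel vanishes there for any source) and
// approximately cancels the normal velocity at y = conf_h.
static inline void kernel(const double* x, const double* y0,
                          bool direct, bool wall, double conf_h,
                          double G[3][3]) {
  double tmp[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) G[i][j] = 0.0;
  if (direct) {
    double r[3] = { x[0]-y0[0], x[1]-y0[1], x[2]-y0[2] };
    oseen(r, tmp);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) G[i][j] += tmp[i][j];
  }
  if (wall) {
    blake_image(x, y0, tmp);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) G[i][j] += tmp[i][j];
  }
  if (conf_h > 0.0) {
    // source reflected about y = conf_h, force components mirrored in y
    double ys[3] = { y0[0], 2.0*conf_h - y0[1], y0[2] };
    double m[3] = { 1.0, -1.0, 1.0 };
    double r[3] = { x[0]-ys[0], x[1]-ys[1], x[2]-ys[2] };
    oseen(r, tmp);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) G[i][j] += tmp[i][j]*m[j];
    if (wall) {
      blake_image(x, ys, tmp);
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) G[i][j] += tmp[i][j]*m[j];
    }
  }
}

struct Panel {
  double th1, th2, ph1, ph2;
  double pos[3];    // centroid, lab frame
  double area;
  double diam;
};

static inline void centroid_of(double th1, double th2, double ph1, double ph2,
                               double a, double yc, double* pos,
                               double& area, double& diam) {
  double c1 = std::cos(th1), c2 = std::cos(th2);
  double ct = 0.5 * (c1 + c2);
  if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
  double st = std::sqrt(std::max(0.0, 1.0 - ct*ct));
  double phc = 0.5 * (ph1 + ph2);
  pos[0] = a * st * std::cos(phc);
  pos[1] = yc - a * ct;             // theta = 0 points to the wall (-y)
  pos[2] = a * st * std::sin(phc);
  area = a * a * (c1 - c2) * (ph2 - ph1);
  double dth = a * (th2 - th1);
  double dph = a * st * (ph2 - ph1);
  diam = std::max(dth, dph);
}

static inline double dist3(const double* a, const double* b) {
  double d0 = a[0]-b[0], d1 = a[1]-b[1], d2 = a[2]-b[2];
  return std::sqrt(d0*d0 + d1*d1 + d2*d2);
}

// Accumulate the area-weighted kernel integral of a (sub)panel seen from x by
// recursive adaptive subdivision: a (sub)panel is integrated with its
// centroid value once its diameter is below `1/near_fac` times the distance
// from x to the nearest singularity location (the panel for the direct part,
// its wall image for the image parts), otherwise it is split 2 x 2, uniform
// in cos(theta) and phi so sub-areas stay exact.  The recursion depth is
// capped; refinement concentrates where the kernel is nearly singular.
static void panel_adaptive(const double* x, double th1, double th2,
                           double ph1, double ph2, double a, double yc,
                           bool direct, bool wall, double conf_h,
                           double near_fac, int depth, int max_depth,
                           double acc[3][3]) {
  double pos[3], area, diam;
  centroid_of(th1, th2, ph1, ph2, a, yc, pos, area, diam);
  double d = dist3(x, pos);
  if (wall || conf_h > 0.0) {
    double img[3] = { pos[0], -pos[1], pos[2] };
    double di = dist3(x, img);
    if (!direct || di < d) d = direct ? std::min(d, di) : di;
  }
  double G[3][3];
  if (near_fac * diam <= d || depth >= max_depth) {
    kernel(x, pos, direct, wall, conf_h, G);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) acc[i][j] += G[i][j] * area;
    return;
  }
  double c1 = std::cos(th1), c2 = std::cos(th2), cm = 0.5 * (c1 + c2);
  double thm = std::acos(std::min(1.0, std::max(-1.0, cm)));
  double phm = 0.5 * (ph1 + ph2);
  panel_adaptive(x, th1, thm, ph1, phm, a, yc, direct, wall, conf_h,
                 near_fac, depth + 1, max_depth, acc);
  panel_adaptive(x, th1, thm, phm, ph2, a, yc, direct, wall, conf_h,
                 near_fac, depth + 1, max_depth, acc);
  panel_adaptive(x, thm, th2, ph1, phm, a, yc, direct, wall, conf_h,
                 near_fac, depth + 1, max_depth, acc);
  panel_adaptive(x, thm, th2, phm, ph2, a, yc, direct, wall, conf_h,
                 near_fac, depth + 1, max_depth, acc);
}

static inline void panel_integral(const double* x, const Panel& p,
                                  double a, double yc,
                                  bool direct, bool wall, double conf_h,
                                  double near_fac, int max_depth,
                                  double acc[3][3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) acc[i][j] = 0.0;
  panel_adaptive(x, p.th1, p.th2, p.ph1, p.ph2, a, yc, direct, wall, conf_h,
                 near_fac, 0, max_depth, acc);
}

static std::vector<Panel> make_panels(const NumericMatrix& panels,
                                      double a, double yc) {
  int N = panels.nrow();
  std::vector<Panel> P(N);
  for (int j = 0; j < N; ++j) {
    P[j].th1 = panels(j,0); P[j].th2 = panels(j,1);
    P[j].ph1 = panels(j,2); P[j].ph2 = panels(j,3);
    centroid_of(P[j].th1, P[j].th2, P[j].ph1, P[j].ph2, a, yc,
                P[j].pos, P[j].area, P[j].diam);
  }
  return P;
}

// [[Rcpp::export(name = ".bem_assemble")]]
NumericMatrix bem_assemble(NumericMatrix panels, double a, double yc,
                           double mu, bool wall, double conf_h,
                           double near_fac = 4.0, int max_depth = 7) {
  int N = panels.nrow();
  std::vector<Panel> P = make_panels(panels, a, yc);
  NumericMatrix A(3 * N, 3 * N);
  double pre = 1.0 / (8.0 * PI * mu);
  double acc[3][3];

  for (int i = 0; i < N; ++i) {
    const double* x = P[i].pos;
    double rowsum[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      // free-space part (tracked for the calibrated self term)
      panel_integral(x, P[j], a, yc, true, false, -1.0,
                     near_fac, max_depth, acc);
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c) {
          A(3*i + r, 3*j + c) += pre * acc[r][c];
          rowsum[r][c] += pre * acc[r][c];
        }
      // image / confinement parts
      if (wall || conf_h > 0.0) {
        panel_integral(x, P[j], a, yc, false, wall, conf_h,
                       near_fac, max_depth, acc);
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c)
            A(3*i + r, 3*j + c) += pre * acc[r][c];
      }
    }
    // Self term, direct part: consistency-calibrated so that the discrete
    // operator reproduces the exact uniform-density solution of a translating
    // sphere (single-layer density 3 mu U / (2 a) gives velocity U).
    double diag = 2.0 * a / (3.0 * mu);
    for (int r = 0; r < 3; ++r)
      for (int c = 0; c < 3; ++c)
        A(3*i + r, 3*i + c) += (r == c ? diag : 0.0) - rowsum[r][c];
    // Self term, image parts (regular, but the image of the contact panel
    // sits only 2h below it, so integrate adaptively).
    if (wall || conf_h > 0.0) {
      panel_integral(x, P[i], a, yc, false, wall, conf_h,
                     near_fac, max_depth, acc);
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          A(3*i + r, 3*i + c) += pre * acc[r][c];
    }
  }
  return A;
}

// Disturbance velocity at arbitrary field points from the single-layer
// density q (3N, panel-major) on the sphere surface.
// [[Rcpp::export(name = ".bem_velocity")]]
NumericMatrix bem_velocity(NumericMatrix points, NumericMatrix panels,
                           double a, double yc, NumericVector q,
                           double mu, bool wall, double conf_h,
                           double near_fac = 4.0, int max_depth = 7) {
  int N = panels.nrow(), M = points.nrow();
  std::vector<Panel> P = make_panels(panels, a, yc);
  NumericMatrix U(M, 3);
  double pre = 1.0 / (8.0 * PI * mu);
  double acc[3][3];
  for (int m = 0; m < M; ++m) {
    double x[3] = { points(m,0), points(m,1), points(m,2) };
    double u[3] = { 0.0, 0.0, 0.0 };
    for (int j = 0; j < N; ++j) {
      panel_integral(x, P[j], a, yc, true, wall, conf_h,
                     near_fac, max_depth, acc);
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          u[r] += pre * acc[r][c] * q[3*j + c];
    }
    for (int r = 0; r < 3; ++r) U(m, r) = u[r];
  }
  return U;
}

// Kernel evaluation for unit tests (times the physical 1/(8 pi mu) factor).
// [[Rcpp::export(name = ".bem_kernel")]]
NumericMatrix bem_kernel(NumericVector x, NumericVector y0, double mu,
                         bool wall, double conf_h) {
  double G[3][3];
  double xx[3] = { x[0], x[1], x[2] }, yy[3] = { y0[0], y0[1], y0[2] };
  kernel(xx, yy, true, wall, conf_h, G);
  NumericMatrix out(3, 3);
  double pre = 1.0 / (8.0 * PI * mu);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) out(i, j) = pre * G[i][j];
  return out;
}

// In-place dense solve A X = B via LAPACK dgesv.  A and B are overwritten
// (A with its LU factors, B with the solution); the R wrapper owns both.
// [[Rcpp::export(name = ".bem_solve_inplace")]]
NumericMatrix bem_solve_inplace(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), nrhs = B.ncol(), info = 0;
  if (A.ncol() != n || B.nrow() != n) stop("dimension mismatch");
  std::vector<int> ipiv(n);
  F77_CALL(dgesv)(&n, &nrhs, A.begin(), &n, ipiv.data(), B.begin(), &n, &info);
  if (info != 0) stop("dgesv failed, info = %d", info);
  return B;
}
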