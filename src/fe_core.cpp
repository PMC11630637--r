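// Explicit-midpoint time loop for the whole-cell adhesion model.
// Mirrors the reference R implementations in R/cellfe.R (passive_stress,
// active_traction, boundary_forces, body_forces, assemble_internal_forces);
// the parity between the two routes is asserted in the test suite.
//
// Internal units: um, s, Pa (= pN/um^2), pN; nodal mass in pN s^2/um.
// Drag is folded into the velocity updates semi-implicitly, which is
// unconditionally stable and recovers the overdamped limit v = F/gamma.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Params {
  double mu_c, thickness, drag, kappa_coeff, area_coeff, actin_amp, A0;
  double Kon, Ka, Fa, Kb, Fb, kint, rho_max;
  double ramp_rate, plateau;
  bool use_adhesion, use_active;
};

static inline double tmyo_at(double t, const Params& P) {
  if (!P.use_active) return 0.0;
  double v = P.ramp_rate * t;
  return v < P.plateau ? v : P.plateau;
}

static inline double koff_at(double f, const Params& P) {
  return P.Ka * std::exp(f / P.Fa) + P.Kb * std::exp(-f / P.Fb);
}

// total non-drag force; returns false on element inversion (id via *bad)
static bool eval_forces(const std::vector<double>& px,
                        const std::vector<double>& py,
                        const std::vector<double>& ax,
                        const std::vector<double>& ay,
                        const std::vector<double>& C,
                        const std::vector<double>& trib,
                        const IntegerMatrix& tris,
                        const IntegerVector& bnd,
                        const std::vector<double>& dminv, // 4 per element
                        const std::vector<double>& xi,
                        double t, const Params& P,
                        std::vector<double>& fx, std::vector<double>& fy,
                        int* bad) {
  const int N = (int)px.size(), M = tris.nrow(), B = bnd.size();
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  const double tm = tmyo_at(t, P);

  // internal (passive + active) stress divergence, 1-point quadrature
  for (int e = 0; e < M; ++e) {
    const int i1 = tris(e, 0) - 1, i2 = tris(e, 1) - 1, i3 = tris(e, 2) - 1;
    const double d1x = px[i2] - px[i1], d2x = px[i3] - px[i1];
    const double d1y = py[i2] - py[i1], d2y = py[i3] - py[i1];
    const double detDs = d1x * d2y - d2x * d1y;
    if (!(detDs > 1e-14)) { *bad = e + 1; return false; }
    const double* m = &dminv[4 * e]; // [a b; c d] of Dm^-1
    // F = Ds * DmInv, Ds = [d1x d2x; d1y d2y]
    const double F11 = d1x * m[0] + d2x * m[2];
    const double F12 = d1x * m[1] + d2x * m[3];
    const double F21 = d1y * m[0] + d2y * m[2];
    const double F22 = d1y * m[1] + d2y * m[3];
    const double J = F11 * F22 - F12 * F21;
    if (!(J > 0)) { *bad = e + 1; return false; }
    const double b11 = F11 * F11 + F12 * F12;
    const double b12 = F11 * F21 + F12 * F22;
    const double b22 = F21 * F21 + F22 * F22;
    const double pc = P.mu_c / (J * J);
    const double s11 = P.mu_c * b11 - pc + tm;
    const double s22 = P.mu_c * b22 - pc + tm;
    const double s12 = P.mu_c * b12;
    // spatial shape gradients: rows of Ds^-1; gN1 = -(gN2+gN3)
    const double inv = 1.0 / detDs;
    const double g2x = d2y * inv, g2y = -d2x * inv;
    const double g3x = -d1y * inv, g3y = d1x * inv;
    const double g1x = -g2x - g3x, g1y = -g2y - g3y;
    const double cA = P.thickness * 0.5 * detDs; // thickness * current area
    // f -= R = t*A*sigma*gradN  (equation of motion: m a = -R + f_ext)
    fx[i1] -= cA * (s11 * g1x + s12 * g1y);
    fy[i1] -= cA * (s12 * g1x + s22 * g1y);
    fx[i2] -= cA * (s11 * g2x + s12 * g2y);
    fy[i2] -= cA * (s12 * g2x + s22 * g2y);
    fx[i3] -= cA * (s11 * g3x + s12 * g3y);
    fy[i3] -= cA * (s12 * g3x + s22 * g3y);
  }

  // adhesion springs (mean-field bond field)
  if (P.use_adhesion) {
    for (int i = 0; i < N; ++i) {
      const double ux = (px[i] - ax[i]) * 1e3; // nm
      const double uy = (py[i] - ay[i]) * 1e3;
      const double s = C[i] * P.rho_max * trib[i] * P.kint;
      fx[i] -= s * ux;
      fy[i] -= s * uy;
    }
  }

  // boundary regularization: curvature, actin noise, area penalty
  if (B >= 3 && (P.kappa_coeff > 0 || P.actin_amp > 0 || P.area_coeff > 0)) {
    double area = 0.0, ltot = 0.0;
    std::vector<double> lbar(B), nxv(B), nyv(B), kap(B);
    for (int k = 0; k < B; ++k) {
      const int i = bnd[k] - 1;
      const int ip = bnd[(k - 1 + B) % B] - 1, in = bnd[(k + 1) % B] - 1;
      const double e1x = px[i] - px[ip], e1y = py[i] - py[ip];
      const double e2x = px[in] - px[i], e2y = py[in] - py[i];
      const double l1 = std::sqrt(e1x * e1x + e1y * e1y);
      const double l2 = std::sqrt(e2x * e2x + e2y * e2y);
      if (l1 <= 0 || l2 <= 0) { *bad = -1; return false; }
      const double cr = e1x * e2y - e1y * e2x;
      const double dt_ = e1x * e2x + e1y * e2y;
      const double theta = std::atan2(cr, dt_);
      lbar[k] = 0.5 * (l1 + l2);
      kap[k] = theta / lbar[k];
      double tx = e1x / l1 + e2x / l2, ty = e1y / l1 + e2y / l2;
      double nx = ty, ny = -tx; // outward for CCW loop
      const double nn = std::sqrt(nx * nx + ny * ny);
      if (nn > 1e-300) { nx /= nn; ny /= nn; }
      nxv[k] = nx; nyv[k] = ny;
      area += 0.5 * (px[i] * py[in] - px[in] * py[i]);
      ltot += lbar[k];
    }
    const double adef = P.area_coeff * (P.A0 - area);
    for (int k = 0; k < B; ++k) {
      const int i = bnd[k] - 1;
      double f = -P.kappa_coeff * kap[k] + P.actin_amp * xi[k] +
                 adef * lbar[k] / ltot;
      fx[i] += f * nxv[k];
      fy[i] += f * nyv[k];
    }
  }
  return true;
}

// [[Rcpp::export]]
List fe_core_run(NumericMatrix nodes_ref, IntegerMatrix tris,
                 IntegerVector boundary, NumericVector trib_area,
                 NumericMatrix pos0, NumericMatrix vel0, NumericVector C0,
                 NumericMatrix anchors, double time0,
                 List mat, List kin, List ctrl) {
  const int N = nodes_ref.nrow(), M = tris.nrow(), B = boundary.size();

  Params P;
  P.mu_c = mat["mu_c"]; P.thickness = mat["thickness"];
  P.drag = mat["drag_coeff"]; P.kappa_coeff = mat["kappa_coeff"];
  P.area_coeff = mat["area_coeff"]; P.actin_amp = mat["actin_amp"];
  P.A0 = mat["A0"];
  const double rho_c = mat["rho_c"], density_scale = mat["density_scale"];
  P.Kon = kin["Kon"]; P.Ka = kin["Ka"]; P.Fa = kin["Fa"];
  P.Kb = kin["Kb"]; P.Fb = kin["Fb"]; P.kint = kin["kint"];
  P.rho_max = kin["rho_max"];
  P.use_adhesion = ctrl["use_adhesion"]; P.use_active = ctrl["use_active"];
  P.ramp_rate = ctrl["ramp_rate"]; P.plateau = ctrl["plateau"];
  const double dt = ctrl["dt"];
  const int n_steps = ctrl["n_steps"], save_every = ctrl["save_every"];
  const bool record_fields = ctrl["record_fields"];

  // reference shape-matrix inverses
  std::vector<double> dminv(4 * M);
  for (int e = 0; e < M; ++e) {
    const int i1 = tris(e, 0) - 1, i2 = tris(e, 1) - 1, i3 = tris(e, 2) - 1;
    const double a = nodes_ref(i2, 0) - nodes_ref(i1, 0);
    const double b = nodes_ref(i3, 0) - nodes_ref(i1, 0);
    const double c = nodes_ref(i2, 1) - nodes_ref(i1, 1);
    const double d = nodes_ref(i3, 1) - nodes_ref(i1, 1);
    const double det = a * d - b * c;
    if (det <= 0) stop("reference element %d is degenerate or inverted", e + 1);
    dminv[4 * e + 0] = d / det;  dminv[4 * e + 1] = -b / det;
    dminv[4 * e + 2] = -c / det; dminv[4 * e + 3] = a / det;
  }

  // lumped, mass-scaled nodal masses in pN s^2/um (1 pN s^2/um = 1e-6 kg)
  std::vector<double> mass(N);
  for (int i = 0; i < N; ++i) {
    double m_kg = rho_c * P.thickness * trib_area[i] * 1e-18 * density_scale;
    mass[i] = m_kg / 1e-6;
    if (mass[i] <= 0) stop("node %d has non-positive lumped mass", i + 1);
  }

  std::vector<double> px(N), py(N), vx(N), vy(N), ax(N), ay(N), C(N), trib(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1);
    ax[i] = anchors(i, 0); ay[i] = anchors(i, 1);
    C[i] = C0[i]; trib[i] = trib_area[i];
  }

  const int n_saves = n_steps / save_every + 1;
  NumericVector s_time(n_saves), s_meanC(n_saves), s_meanf(n_saves),
      s_meanfw(n_saves), s_brad(n_saves);
  NumericMatrix C_fields, f_fields;
  if (record_fields) {
    C_fields = NumericMatrix(n_saves, N);
    f_fields = NumericMatrix(n_saves, N);
  }

  std::vector<double> fx(N), fy(N), hx(N), hy(N), vhx(N), vhy(N), xi(B, 0.0),
      fint(N);
  double t = time0;
  int isave = 0;

  auto record = [&](int slot) {
    double sC = 0, sf = 0, sWf = 0, sW = 0;
    for (int i = 0; i < N; ++i) {
      const double ux = (px[i] - ax[i]) * 1e3, uy = (py[i] - ay[i]) * 1e3;
      const double f = P.use_adhesion ? P.kint * std::sqrt(ux * ux + uy * uy)
                                      : 0.0;
      fint[i] = f;
      sC += C[i]; sf += f;
      const double w = C[i] * trib[i];
      sW += w; sWf += w * f;
      if (record_fields) { C_fields(slot, i) = C[i]; f_fields(slot, i) = f; }
    }
    double br = 0;
    for (int k = 0; k < B; ++k) {
      const int i = boundary[k] - 1;
      br += std::sqrt(px[i] * px[i] + py[i] * py[i]);
    }
    s_time[slot] = t; s_meanC[slot] = sC / N; s_meanf[slot] = sf / N;
    s_meanfw[slot] = sW > 0 ? sWf / sW : 0.0;
    s_brad[slot] = B > 0 ? br / B : NA_REAL;
  };
  record(isave++);

  int bad = 0;
  for (int s = 0; s < n_steps; ++s) {
    if (P.actin_amp > 0 && B >= 3) {
      NumericVector u = runif(B);
      for (int k = 0; k < B; ++k) xi[k] = u[k];
    }

    // kinetics at the current (pre-step) extension
    if (P.use_adhesion) {
      for (int i = 0; i < N; ++i) {
        const double ux = (px[i] - ax[i]) * 1e3, uy = (py[i] - ay[i]) * 1e3;
        const double f = P.kint * std::sqrt(ux * ux + uy * uy);
        const double kf = koff_at(f, P);
        double Cn = C[i] * (1.0 - kf * dt) + P.Kon * dt * (1.0 - C[i]);
        C[i] = Cn < 0 ? 0 : (Cn > 1 ? 1 : Cn);
      }
    }

    if (!eval_forces(px, py, ax, ay, C, trib, tris, boundary, dminv, xi, t, P,
                     fx, fy, &bad))
      stop("element inversion during step %d (element %d); the mesh has "
           "collapsed -- reduce dt or the load", s + 1, bad);

    // half-step (drag semi-implicit)
    for (int i = 0; i < N; ++i) {
      const double den = 1.0 + 0.5 * dt * P.drag / mass[i];
      vhx[i] = (vx[i] + 0.5 * dt * fx[i] / mass[i]) / den;
      vhy[i] = (vy[i] + 0.5 * dt * fy[i] / mass[i]) / den;
      hx[i] = px[i] + 0.5 * dt * vx[i];
      hy[i] = py[i] + 0.5 * dt * vy[i];
    }

    if (!eval_forces(hx, hy, ax, ay, C, trib, tris, boundary, dminv, xi,
                     t + 0.5 * dt, P, fx, fy, &bad))
      stop("element inversion during step %d (element %d); the mesh has "
           "collapsed -- reduce dt or the load", s + 1, bad);

    for (int i = 0; i < N; ++i) {
      const double den = 1.0 + dt * P.drag / mass[i];
      vx[i] = (vx[i] + dt * fx[i] / mass[i]) / den;
      vy[i] = (vy[i] + dt * fy[i] / mass[i]) / den;
      px[i] += dt * vhx[i];
      py[i] += dt * vhy[i];
    }
    t = time0 + (s + 1) * dt;

    if (((s + 1) % 1000) == 0) {
      double vmax = 0;
      for (int i = 0; i < N; ++i) {
        const double sp = vx[i] * vx[i] + vy[i] * vy[i];
        if (!std::isfinite(sp))
          stop("non-finite state at step %d; reduce dt", s + 1);
        if (sp > vmax) vmax = sp;
      }
      if (vmax > 1e12)
        stop("energy blow-up detected at step %d (|v| > 1e6 um/s); "
             "reduce dt", s + 1);
    }

    if (((s + 1) % save_every) == 0 && isave < n_saves) record(isave++);
  }

  NumericMatrix pos(N, 2), vel(N, 2);
  NumericVector Cout(N);
  for (int i = 0; i < N; ++i) {
    pos(i, 0) = px[i]; pos(i, 1) = py[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i];
    Cout[i] = C[i];
  }

  List out = List::create(
      _["times"] = s_time[Range(0, isave - 1)],
      _["mean_C"] = s_meanC[Range(0, isave - 1)],
      _["mean_f"] = s_meanf[Range(0, isave - 1)],
      _["mean_f_bond"] = s_meanfw[Range(0, isave - 1)],
      _["boundary_radius"] = s_brad[Range(0, isave - 1)],
      _["positions"] = pos, _["velocities"] = vel, _["C"] = Cout,
      _["time"] = t);
  if (record_fields) {
    out["C_fields"] = C_fields(Range(0, isave - 1), _);
    out["f_fields"] = f_fields(Range(0, isave - 1), _);
  }
  return out;
}

// single force evaluation, exposed for parity tests against the R reference
// [[Rcpp::export]]
NumericMatrix fe_core_forces(NumericMatrix nodes_ref, IntegerMatrix tris,
                             IntegerVector boundary, NumericVector trib_area,
                             NumericMatrix pos, NumericVector C,
                             NumericMatrix anchors, double t,
                             NumericVector xi, List mat, List kin, List ctrl) {
  const int N = nodes_ref.nrow(), M = tris.nrow(), B = boundary.size();
  Params P;
  P.mu_c = mat["mu_c"]; P.thickness = mat["thickness"];
  P.drag = mat["drag_coeff"]; P.kappa_coeff = mat["kappa_coeff"];
  P.area_coeff = mat["area_coeff"]; P.actin_amp = mat["actin_amp"];
  P.A0 = mat["A0"];
  P.Kon = kin["Kon"]; P.Ka = kin["Ka"]; P.Fa = kin["Fa"];
  P.Kb = kin["Kb"]; P.Fb = kin["Fb"]; P.kint = kin["kint"];
  P.rho_max = kin["rho_max"];
  P.use_adhesion = ctrl["use_adhesion"]; P.use_active = ctrl["use_active"];
  P.ramp_rate = ctrl["ramp_rate"]; P.plateau = ctrl["plateau"];

  std::vector<double> dminv(4 * M);
  for (int e = 0; e < M; ++e) {
    const int i1 = tris(e, 0) - 1, i2 = tris(e, 1) - 1, i3 = tris(e, 2) - 1;
    const double a = nodes_ref(i2, 0) - nodes_ref(i1, 0);
    const double b = nodes_ref(i3, 0) - nodes_ref(i1, 0);
    const double c = nodes_ref(i2, 1) - nodes_ref(i1, 1);
    const double d = nodes_ref(i3, 1) - nodes_ref(i1, 1);
    const double det = a * d - b * c;
    if (det <= 0) stop("reference element %d is degenerate or inverted", e + 1);
    dminv[4 * e + 0] = d / det;  dminv[4 * e + 1] = -b / det;
    dminv[4 * e + 2] = -c / det; dminv[4 * e + 3] = a / det;
  }
  std::vector<double> px(N), py(N), ax(N), ay(N), Cv(N), trib(N),
      xiv(B, 0.0), fx(N), fy(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1);
    ax[i] = anchors(i, 0); ay[i] = anchors(i, 1);
    Cv[i] = C[i]; trib[i] = trib_area[i];
  }
  for (int k = 0; k < B && k < xi.size(); ++k) xiv[k] = xi[k];
  int bad = 0;
  if (!eval_forces(px, py, ax, ay, Cv, trib, tris, boundary, dminv, xiv, t, P,
                   fx, fy, &bad))
    stop("element inversion (element %d)", bad);
  NumericMatrix out(N, 2);
  for (int i = 0; i < N; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}
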