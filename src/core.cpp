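// Numerical core for the planar 7-segment / 9-DoF walking model:
// forward kinematics with analytic Jacobians, mass matrix and bias forces,
// constrained (KKT) forward dynamics with Baumgarte stabilization, plastic
// impacts, rigid foot-ground contact geometry (ellipse and double-circle),
// muscle-torque-generator curves, activation dynamics, and an adaptive
// Runge-Kutta-Fehlberg 4(5) phase integrator.
//
// Generalized coordinates (0-based):
//   q[0] base x (hip point, m), q[1] base z (m), q[2] base pitch (rad),
//   q[3..5] left hip / knee / ankle (rad), q[6..8] right hip / knee / ankle.
// Segment order: 0 HAT, 1 L thigh, 2 L shank, 3 L foot, 4 R thigh,
//   5 R shank, 6 R foot.  x forward, z up, CCW angles positive.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::vec;
using arma::mat;
using arma::vec2;

static const int NQ = 9;
static const int NSEG = 7;
static const int NMTG = 12;
static const int NX = 30; // 9 q + 9 qd + 12 a

// ---------------------------------------------------------------------------
// model containers

struct Body {
  vec m;       // 7 masses
  vec I;       // 7 planar inertias about COM
  double Lth, Lsh;
  mat com;     // 7 x 2, COM offsets in segment frames
  double g;
};

struct FootGeom {
  int type;    // 0 ellipse, 1 double-circle
  vec2 rE; double thE, ax, bx;          // ellipse: ankle->centre, rel. angle, semi-axes
  vec2 rH, rF; double radH, radF;       // circles: ankle->centre offsets, radii
};

struct Act {
  vec tau0, omax, sgn, opt, width;      // 12 each
  double ecc, ta, td;
  vec beta;                             // 6 joints
  int variant;
};

struct Model {
  Body b;
  FootGeom f;
  Act a;
  bool has_act;
};

static vec2 getv2(SEXP s) {
  NumericVector v(s);
  vec2 out; out[0] = v[0]; out[1] = v[1];
  return out;
}

static Model parse_model(const List& ml) {
  Model M;
  List b = ml["body"];
  M.b.m = as<vec>(b["mass"]);
  M.b.I = as<vec>(b["inertia"]);
  M.b.Lth = as<double>(b["len_thigh"]);
  M.b.Lsh = as<double>(b["len_shank"]);
  M.b.com = as<mat>(b["com"]);
  M.b.g = as<double>(b["g"]);
  if (M.b.m.n_elem != NSEG || M.b.I.n_elem != NSEG || M.b.com.n_rows != NSEG)
    stop("body parameters must describe exactly 7 segments");
  List f = ml["foot"];
  M.f.type = as<int>(f["type"]);
  if (M.f.type == 0) {
    M.f.rE = getv2(f["r_E"]); M.f.thE = as<double>(f["theta_E"]);
    M.f.ax = as<double>(f["r_x"]); M.f.bx = as<double>(f["r_y"]);
  } else {
    M.f.rH = getv2(f["r_H"]); M.f.radH = as<double>(f["rad_H"]);
    M.f.rF = getv2(f["r_F"]); M.f.radF = as<double>(f["rad_F"]);
  }
  M.has_act = ml.containsElementNamed("act") && !Rf_isNull(ml["act"]);
  if (M.has_act) {
    List a = ml["act"];
    M.a.tau0 = as<vec>(a["tau0"]); M.a.omax = as<vec>(a["omax"]);
    M.a.sgn = as<vec>(a["sgn"]);   M.a.opt = as<vec>(a["opt"]);
    M.a.width = as<vec>(a["width"]);
    M.a.ecc = as<double>(a["ecc"]);
    M.a.ta = as<double>(a["tau_act"]); M.a.td = as<double>(a["tau_deact"]);
    M.a.beta = as<vec>(a["beta"]);
    M.a.variant = as<int>(a["variant"]);
  }
  return M;
}

// ---------------------------------------------------------------------------
// planar helpers

static inline vec2 rot(double th, const vec2& v) {
  double c = std::cos(th), s = std::sin(th);
  vec2 o; o[0] = c * v[0] - s * v[1]; o[1] = s * v[0] + c * v[1];
  return o;
}
static inline vec2 rotT(double th, const vec2& v) { return rot(-th, v); }
// z-cross: omega x r in-plane (CCW positive)
static inline vec2 perp(const vec2& v) { vec2 o; o[0] = -v[1]; o[1] = v[0]; return o; }

// cumulative segment orientations / rates and joint positions
struct Kin {
  double phi[NSEG], phidot[NSEG];
  vec2 hip, kneeL, ankleL, kneeR, ankleR;
};

static Kin compute_kin(const Body& B, const double* q, const double* qd) {
  Kin K;
  K.phi[0] = q[2];
  K.phi[1] = q[2] + q[3];
  K.phi[2] = K.phi[1] + q[4];
  K.phi[3] = K.phi[2] + q[5];
  K.phi[4] = q[2] + q[6];
  K.phi[5] = K.phi[4] + q[7];
  K.phi[6] = K.phi[5] + q[8];
  K.phidot[0] = qd[2];
  K.phidot[1] = qd[2] + qd[3];
  K.phidot[2] = K.phidot[1] + qd[4];
  K.phidot[3] = K.phidot[2] + qd[5];
  K.phidot[4] = qd[2] + qd[6];
  K.phidot[5] = K.phidot[4] + qd[7];
  K.phidot[6] = K.phidot[5] + qd[8];
  K.hip[0] = q[0]; K.hip[1] = q[1];
  vec2 dth; dth[0] = 0; dth[1] = -B.Lth;
  vec2 dsh; dsh[0] = 0; dsh[1] = -B.Lsh;
  K.kneeL = K.hip + rot(K.phi[1], dth);
  K.ankleL = K.kneeL + rot(K.phi[2], dsh);
  K.kneeR = K.hip + rot(K.phi[4], dth);
  K.ankleR = K.kneeR + rot(K.phi[5], dsh);
  return K;
}

// chain tables: angle DoF indices and composition terms per segment
struct Chain {
  int nang; int qidx[4];
  int nterm; int tphi[3]; int tkind[3]; // tkind: 0 = (0,-Lth), 1 = (0,-Lsh), 2 = local
};
static const Chain CHAINS[NSEG] = {
  {1, {2, 0, 0, 0}, 1, {0, 0, 0}, {2, 0, 0}},          // HAT
  {2, {2, 3, 0, 0}, 1, {1, 0, 0}, {2, 0, 0}},          // L thigh
  {3, {2, 3, 4, 0}, 2, {1, 2, 0}, {0, 2, 0}},          // L shank
  {4, {2, 3, 4, 5}, 3, {1, 2, 3}, {0, 1, 2}},          // L foot
  {2, {2, 6, 0, 0}, 1, {4, 0, 0}, {2, 0, 0}},          // R thigh
  {3, {2, 6, 7, 0}, 2, {4, 5, 0}, {0, 2, 0}},          // R shank
  {4, {2, 6, 7, 8}, 3, {4, 5, 6}, {0, 1, 2}},          // R foot
};

static vec2 joint_pivot(const Kin& K, int qi) {
  switch (qi) {
    case 2: case 3: case 6: return K.hip;
    case 4: return K.kneeL;
    case 5: return K.ankleL;
    case 7: return K.kneeR;
    case 8: return K.ankleR;
  }
  return K.hip;
}

// world position, 2x9 Jacobian, velocity, zero-qddot acceleration, angular
// velocity and 1x9 orientation Jacobian of a point fixed in segment `seg`
// at `local` (segment-frame coordinates).
struct PointKin {
  vec2 p, v, a0;
  mat J;        // 2 x 9
  arma::rowvec w; // 1 x 9
  double omega;
};

static PointKin point_kin(const Body& B, const Kin& K, const double* qd,
                          int seg, const vec2& local) {
  PointKin P;
  const Chain& C = CHAINS[seg];
  vec2 dth; dth[0] = 0; dth[1] = -B.Lth;
  vec2 dsh; dsh[0] = 0; dsh[1] = -B.Lsh;
  P.p = K.hip;
  P.a0.zeros();
  for (int t = 0; t < C.nterm; ++t) {
    const vec2& d = (C.tkind[t] == 0) ? dth : (C.tkind[t] == 1 ? dsh : local);
    vec2 rd = rot(K.phi[C.tphi[t]], d);
    P.p += rd;
    double pd = K.phidot[C.tphi[t]];
    P.a0 -= pd * pd * rd;
  }
  P.J.zeros(2, NQ);
  P.J(0, 0) = 1.0; P.J(1, 1) = 1.0;
  P.w.zeros(NQ);
  for (int k = 0; k < C.nang; ++k) {
    int qi = C.qidx[k];
    vec2 lever = perp(P.p - joint_pivot(K, qi));
    P.J(0, qi) = lever[0];
    P.J(1, qi) = lever[1];
    P.w(qi) = 1.0;
  }
  P.v.zeros();
  P.omega = 0;
  for (int j = 0; j < NQ; ++j) {
    P.v[0] += P.J(0, j) * qd[j];
    P.v[1] += P.J(1, j) * qd[j];
    P.omega += P.w(j) * qd[j];
  }
  return P;
}

static void check_finite(const vec& x, const char* what) {
  if (!x.is_finite()) stop("non-finite %s supplied", what);
}

// ---------------------------------------------------------------------------
// mass matrix, bias forces, energy

static mat mass_matrix_impl(const Body& B, const vec& q) {
  vec qd(NQ, arma::fill::zeros);
  Kin K = compute_kin(B, q.memptr(), qd.memptr());
  mat M(NQ, NQ, arma::fill::zeros);
  for (int s = 0; s < NSEG; ++s) {
    vec2 cl; cl[0] = B.com(s, 0); cl[1] = B.com(s, 1);
    PointKin P = point_kin(B, K, qd.memptr(), s, cl);
    M += B.m(s) * (P.J.t() * P.J) + B.I(s) * (P.w.t() * P.w);
  }
  return M;
}

static vec bias_forces_impl(const Body& B, const vec& q, const vec& qd) {
  Kin K = compute_kin(B, q.memptr(), qd.memptr());
  vec c(NQ, arma::fill::zeros);
  vec2 gvec; gvec[0] = 0; gvec[1] = B.g;
  for (int s = 0; s < NSEG; ++s) {
    vec2 cl; cl[0] = B.com(s, 0); cl[1] = B.com(s, 1);
    PointKin P = point_kin(B, K, qd.memptr(), s, cl);
    vec2 f = B.m(s) * (P.a0 + gvec);
    c += P.J.t() * vec(std::vector<double>{f[0], f[1]});
  }
  return c;
}

// [[Rcpp::export]]
arma::mat rf_mass_matrix(List model, arma::vec q) {
  check_finite(q, "q");
  Model M = parse_model(model);
  return mass_matrix_impl(M.b, q);
}

// [[Rcpp::export]]
arma::vec rf_bias_forces(List model, arma::vec q, arma::vec qd) {
  check_finite(q, "q"); check_finite(qd, "qdot");
  Model M = parse_model(model);
  return bias_forces_impl(M.b, q, qd);
}

// [[Rcpp::export]]
List rf_point_kin(List model, arma::vec q, arma::vec qd, int seg, arma::vec local) {
  Model M = parse_model(model);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  vec2 lv; lv[0] = local[0]; lv[1] = local[1];
  PointKin P = point_kin(M.b, K, qd.memptr(), seg - 1, lv);
  return List::create(_["p"] = NumericVector::create(P.p[0], P.p[1]),
                      _["J"] = P.J,
                      _["v"] = NumericVector::create(P.v[0], P.v[1]),
                      _["a0"] = NumericVector::create(P.a0[0], P.a0[1]),
                      _["w"] = NumericVector(P.w.begin(), P.w.end()),
                      _["omega"] = P.omega);
}

// [[Rcpp::export]]
List rf_energy(List model, arma::vec q, arma::vec qd) {
  Model M = parse_model(model);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  double ke = 0, pe = 0;
  for (int s = 0; s < NSEG; ++s) {
    vec2 cl; cl[0] = M.b.com(s, 0); cl[1] = M.b.com(s, 1);
    PointKin P = point_kin(M.b, K, qd.memptr(), s, cl);
    ke += 0.5 * M.b.m(s) * (P.v[0] * P.v[0] + P.v[1] * P.v[1])
        + 0.5 * M.b.I(s) * P.omega * P.omega;
    pe += M.b.m(s) * M.b.g * P.p[1];
  }
  return List::create(_["kinetic"] = ke, _["potential"] = pe,
                      _["total"] = ke + pe);
}

// ---------------------------------------------------------------------------
// ellipse-plane closest point (polar boundary form, bisection + Newton)

struct EllState { double rs, rs1, rs2; };
static EllState ell_radius(double A, double Bx, double phi) {
  double c = std::cos(phi), s = std::sin(phi);
  double D = Bx * Bx * c * c + A * A * s * s;
  double D1 = (A * A - Bx * Bx) * std::sin(2 * phi);
  double D2 = 2 * (A * A - Bx * Bx) * std::cos(2 * phi);
  double Dm12 = 1.0 / std::sqrt(D);
  double AB = A * Bx;
  EllState E;
  E.rs = AB * Dm12;
  E.rs1 = -0.5 * AB * D1 * Dm12 / D;                       // -(AB/2) D^{-3/2} D'
  E.rs2 = -0.5 * AB * (D2 / (D * std::sqrt(D)) - 1.5 * D1 * D1 / (D * D * std::sqrt(D)));
  return E;
}

// derivative of world height of the boundary point w.r.t. the ellipse-frame
// polar angle phi, for world ellipse orientation psi
static double ell_g(double A, double Bx, double psi, double phi, double* gp = 0) {
  EllState E = ell_radius(A, Bx, phi);
  double u = phi + psi;
  double g = E.rs1 * std::sin(u) + E.rs * std::cos(u);
  if (gp) *gp = E.rs2 * std::sin(u) + 2 * E.rs1 * std::cos(u) - E.rs * std::sin(u);
  return g;
}

// returns the ellipse-frame polar angle of the lowest boundary point
static double ellipse_lowest_phi(double A, double Bx, double psi) {
  // lowest point has world polar angle u = phi + psi in (-pi, 0)
  double lo = -M_PI - psi + 1e-12, hi = -psi - 1e-12;
  double glo = ell_g(A, Bx, psi, lo);
  double ghi = ell_g(A, Bx, psi, hi);
  if (glo > 0 || ghi < 0) stop("ellipse closest-point bracket failed");
  // bisection to a narrow bracket
  for (int it = 0; it < 60 && (hi - lo) > 1e-6; ++it) {
    double mid = 0.5 * (lo + hi);
    double gm = ell_g(A, Bx, psi, mid);
    if (gm <= 0) lo = mid; else hi = mid;
  }
  // Newton polish, falling back to bisection if it leaves the bracket
  double x = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    double gp;
    double g = ell_g(A, Bx, psi, x, &gp);
    if (std::fabs(g) < 1e-15) break;
    double step = (gp != 0) ? g / gp : 0.0;
    double xn = x - step;
    if (!(xn > lo && xn < hi) || step == 0.0) {
      // keep the bracket shrinking
      if (g <= 0) lo = x; else hi = x;
      xn = 0.5 * (lo + hi);
    } else {
      if (g <= 0) lo = x; else hi = x;
    }
    if (std::fabs(xn - x) < 1e-16) { x = xn; break; }
    x = xn;
  }
  return x;
}

// [[Rcpp::export]]
List rf_ellipse_lowest(double r_x, double r_y, double psi) {
  if (!(r_x >= r_y && r_y > 0)) stop("ellipse semi-axes must satisfy r_x >= r_y > 0");
  double phi = ellipse_lowest_phi(r_x, r_y, psi);
  EllState E = ell_radius(r_x, r_y, phi);
  vec2 b; b[0] = E.rs * std::cos(phi); b[1] = E.rs * std::sin(phi);
  vec2 w = rot(psi, b); // offset of the contact point from the ellipse centre, world frame
  return List::create(_["phi"] = phi,
                      _["boundary"] = NumericVector::create(b[0], b[1]),
                      _["offset"] = NumericVector::create(w[0], w[1]),
                      _["r_s"] = E.rs);
}

// ---------------------------------------------------------------------------
// contact constraint rows

struct CRow {
  arma::rowvec G;   // 1 x 9
  double gamma;     // acceleration bias (zero-qddot point acceleration component)
  double gap;       // world height of the contact shape's lowest point (NaN for rolling rows)
  int kind;         // 0 contact-normal, 1 rolling-tangential
  int foot;         // 0 left, 1 right
  vec2 pt;          // world contact point
};

enum Mode { AIRBORNE = 0, ELLIPSE_ROLL = 1, HEEL_ROLL = 2, FOREFOOT_ROLL = 3,
            HEEL_ROLL_FOREFOOT_TOUCH = 4, FOREFOOT_ROLL_HEEL_TOUCH = 5 };

// Constraint rows for one contact shape (shape: 0 ellipse, 1 heel circle,
// 2 forefoot circle).  The velocity-level constraints are the e_Z (contact)
// and e_X (rolling) projections of the velocity of the material point at the
// point of closest approach.  They are expressed through the shape centre C
// (a true fixed material point of the foot): with b = P - C,
//   g_z = e_Z.v_C + omega*b_x,  g_x = e_X.v_C - omega*b_z.
// The acceleration bias accounts for the migration of the contact point:
// for a circle b is constant in the world frame; for the ellipse the contact
// point travels along the ground at -rho*omega (rho = boundary curvature
// radius), giving bdot = (-rho*omega - vC_x, -vC_z).
static void rows_for_shape(const Model& M, const Kin& K, const double* qd,
                           int side, int shape, bool with_roll,
                           std::vector<CRow>& out) {
  int seg = (side == 0) ? 3 : 6;
  double phif = K.phi[seg];
  vec2 cl = (shape == 0) ? M.f.rE : (shape == 1 ? M.f.rH : M.f.rF);
  PointKin C = point_kin(M.b, K, qd, seg, cl);
  vec2 b; double rho = 0; bool is_circle = (shape != 0);
  if (is_circle) {
    double rad = (shape == 1) ? M.f.radH : M.f.radF;
    b[0] = 0; b[1] = -rad;
  } else {
    double psi = phif + M.f.thE;
    double phi = ellipse_lowest_phi(M.f.ax, M.f.bx, psi);
    EllState E = ell_radius(M.f.ax, M.f.bx, phi);
    vec2 be; be[0] = E.rs * std::cos(phi); be[1] = E.rs * std::sin(phi);
    b = rot(psi, be);
    // curvature radius at the contact (parametric form)
    double a = M.f.ax, bb = M.f.bx;
    double ct = be[0] / a, st = be[1] / bb;
    rho = std::pow(a * a * st * st + bb * bb * ct * ct, 1.5) / (a * bb);
  }
  vec2 P = C.p + b;
  double om = C.omega;
  CRow rc;
  rc.G = C.J.row(1) + b[0] * C.w;
  rc.gamma = C.a0[1];
  if (!is_circle) rc.gamma += om * (-rho * om - C.v[0]);
  rc.gap = P[1]; rc.kind = 0; rc.foot = side; rc.pt = P;
  out.push_back(rc);
  if (with_roll) {
    CRow rr;
    rr.G = C.J.row(0) - b[1] * C.w;
    rr.gamma = C.a0[0];
    if (!is_circle) rr.gamma += om * C.v[1];
    rr.gap = std::numeric_limits<double>::quiet_NaN();
    rr.kind = 1; rr.foot = side; rr.pt = P;
    out.push_back(rr);
  }
}

static std::vector<CRow> build_rows(const Model& M, const Kin& K, const double* qd,
                                    int side, int mode) {
  std::vector<CRow> out;
  if (mode == AIRBORNE) return out;
  if (M.f.type == 0) {
    if (mode != ELLIPSE_ROLL) stop("ellipse foot supports only AIRBORNE or ELLIPSE_ROLL modes");
    rows_for_shape(M, K, qd, side, 0, true, out);
    return out;
  }
  switch (mode) {
    case HEEL_ROLL:
      rows_for_shape(M, K, qd, side, 1, true, out);
      break;
    case FOREFOOT_ROLL:
      rows_for_shape(M, K, qd, side, 2, true, out);
      break;
    case HEEL_ROLL_FOREFOOT_TOUCH:
      rows_for_shape(M, K, qd, side, 1, true, out);
      rows_for_shape(M, K, qd, side, 2, false, out);
      break;
    case FOREFOOT_ROLL_HEEL_TOUCH:
      rows_for_shape(M, K, qd, side, 2, true, out);
      rows_for_shape(M, K, qd, side, 1, false, out);
      break;
    default:
      stop("double-circle foot does not support mode %d", mode);
  }
  return out;
}

static std::vector<CRow> all_rows(const Model& M, const Kin& K, const double* qd,
                                  int modeL, int modeR) {
  std::vector<CRow> rows = build_rows(M, K, qd, 0, modeL);
  std::vector<CRow> rr = build_rows(M, K, qd, 1, modeR);
  rows.insert(rows.end(), rr.begin(), rr.end());
  if (rows.size() > 6) stop("constraint set has more than 6 rows");
  return rows;
}

// [[Rcpp::export]]
List rf_constraints(List model, arma::vec q, arma::vec qd, int modeL, int modeR) {
  Model M = parse_model(model);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  std::vector<CRow> rows = all_rows(M, K, qd.memptr(), modeL, modeR);
  int m = rows.size();
  mat G(m, NQ); vec gamma(m), gap(m), vres(m);
  IntegerVector kind(m), foot(m);
  mat pts(m, 2);
  for (int i = 0; i < m; ++i) {
    G.row(i) = rows[i].G;
    gamma(i) = rows[i].gamma;
    gap(i) = rows[i].gap;
    kind[i] = rows[i].kind;
    foot[i] = rows[i].foot;
    pts(i, 0) = rows[i].pt[0]; pts(i, 1) = rows[i].pt[1];
    vres(i) = arma::dot(rows[i].G, qd);
  }
  return List::create(_["G"] = G, _["gamma"] = gamma, _["gap"] = gap,
                      _["velocity"] = vres, _["kind"] = kind,
                      _["foot"] = foot, _["points"] = pts);
}

// [[Rcpp::export]]
NumericVector rf_foot_gaps(List model, arma::vec q, int side) {
  Model M = parse_model(model);
  vec qd(NQ, arma::fill::zeros);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  int seg = (side == 0) ? 3 : 6;
  double phif = K.phi[seg];
  if (M.f.type == 0) {
    PointKin C = point_kin(M.b, K, qd.memptr(), seg, M.f.rE);
    double psi = phif + M.f.thE;
    double phi = ellipse_lowest_phi(M.f.ax, M.f.bx, psi);
    EllState E = ell_radius(M.f.ax, M.f.bx, phi);
    vec2 be; be[0] = E.rs * std::cos(phi); be[1] = E.rs * std::sin(phi);
    vec2 b = rot(psi, be);
    return NumericVector::create(_["ellipse"] = C.p[1] + b[1]);
  }
  PointKin Ch = point_kin(M.b, K, qd.memptr(), seg, M.f.rH);
  PointKin Cf = point_kin(M.b, K, qd.memptr(), seg, M.f.rF);
  return NumericVector::create(_["heel"] = Ch.p[1] - M.f.radH,
                               _["forefoot"] = Cf.p[1] - M.f.radF);
}

// ---------------------------------------------------------------------------
// constrained forward dynamics and plastic impact

struct FDResult { vec qdd; vec lambda; };

static FDResult fd_impl(const Model& M, const Kin& K, const vec& q, const vec& qd,
                        const vec& tau, const std::vector<CRow>& rows,
                        double bp, double bv, bool check) {
  int m = rows.size();
  mat Mm = mass_matrix_impl(M.b, q);
  vec c = bias_forces_impl(M.b, q, qd);
  FDResult R;
  if (m == 0) {
    R.qdd = arma::solve(Mm, tau - c, arma::solve_opts::likely_sympd);
    R.lambda = vec();
    return R;
  }
  mat G(m, NQ); vec rhs_c(m);
  for (int i = 0; i < m; ++i) {
    G.row(i) = rows[i].G;
    double vres = arma::dot(rows[i].G, qd);
    rhs_c(i) = -rows[i].gamma - bv * vres;
    if (rows[i].kind == 0) rhs_c(i) -= bp * rows[i].gap;
  }
  if (check && arma::rank(G) < (unsigned)m)
    stop("rank-deficient constraint Jacobian (%d rows, rank %d)", m, (int)arma::rank(G));
  mat A(NQ + m, NQ + m, arma::fill::zeros);
  A.submat(0, 0, NQ - 1, NQ - 1) = Mm;
  A.submat(0, NQ, NQ - 1, NQ + m - 1) = -G.t();
  A.submat(NQ, 0, NQ + m - 1, NQ - 1) = G;
  vec rhs(NQ + m);
  rhs.subvec(0, NQ - 1) = tau - c;
  rhs.subvec(NQ, NQ + m - 1) = rhs_c;
  if (check) {
    double rc = arma::rcond(A);
    if (rc < 1e-12)
      Rcpp::warning("KKT system nearly singular (rcond %g)", rc);
  }
  vec sol = arma::solve(A, rhs);
  R.qdd = sol.subvec(0, NQ - 1);
  R.lambda = sol.subvec(NQ, NQ + m - 1);
  return R;
}

// [[Rcpp::export]]
List rf_fd(List model, arma::vec q, arma::vec qd, arma::vec tau,
           int modeL, int modeR, double bp, double bv, bool check = true) {
  check_finite(q, "q"); check_finite(qd, "qdot"); check_finite(tau, "tau");
  Model M = parse_model(model);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  std::vector<CRow> rows = all_rows(M, K, qd.memptr(), modeL, modeR);
  FDResult R = fd_impl(M, K, q, qd, tau, rows, bp, bv, check);
  return List::create(_["qdd"] = R.qdd, _["lambda"] = R.lambda);
}

// [[Rcpp::export]]
List rf_impact(List model, arma::vec q, arma::vec qd, int modeL, int modeR) {
  check_finite(q, "q"); check_finite(qd, "qdot");
  Model M = parse_model(model);
  Kin K = compute_kin(M.b, q.memptr(), qd.memptr());
  std::vector<CRow> rows = all_rows(M, K, qd.memptr(), modeL, modeR);
  int m = rows.size();
  mat Mm = mass_matrix_impl(M.b, q);
  if (m == 0)
    return List::create(_["qd_post"] = qd, _["impulses"] = vec(),
                        _["dKE"] = 0.0);
  mat G(m, NQ);
  for (int i = 0; i < m; ++i) G.row(i) = rows[i].G;
  if (arma::rank(G) < (unsigned)m)
    stop("rank-deficient constraint Jacobian in impact (%d rows)", m);
  mat A(NQ + m, NQ + m, arma::fill::zeros);
  A.submat(0, 0, NQ - 1, NQ - 1) = Mm;
  A.submat(0, NQ, NQ - 1, NQ + m - 1) = -G.t();
  A.submat(NQ, 0, NQ + m - 1, NQ - 1) = G;
  vec rhs(NQ + m, arma::fill::zeros);
  rhs.subvec(0, NQ - 1) = Mm * qd;
  vec sol = arma::solve(A, rhs);
  vec qdp = sol.subvec(0, NQ - 1);
  vec Lam = sol.subvec(NQ, NQ + m - 1);
  double dke = 0.5 * arma::as_scalar(qdp.t() * Mm * qdp - qd.t() * Mm * qd);
  return List::create(_["qd_post"] = qdp, _["impulses"] = Lam, _["dKE"] = dke);
}

// ---------------------------------------------------------------------------
// muscle-torque-generators and activation dynamics

static inline double s5(double x) {
  if (x <= 0) return 0;
  if (x >= 1) return 1;
  return x * x * x * (10.0 + x * (-15.0 + 6.0 * x));
}

static inline double fA_curve(double theta, double opt, double width) {
  return 1.0 - s5(std::fabs(theta - opt) / width);
}

// s = signed shortening rate (positive when rotating in the MTG's direction)
static inline double fV_curve(double s, double omax, double ecc) {
  if (s >= 0) return 1.0 - s5(s / omax);
  return 1.0 + (ecc - 1.0) * s5(-s / omax);
}

// [[Rcpp::export]]
NumericVector rf_fA(NumericVector theta, double opt, double width) {
  NumericVector out(theta.size());
  for (int i = 0; i < theta.size(); ++i) out[i] = fA_curve(theta[i], opt, width);
  return out;
}

// [[Rcpp::export]]
NumericVector rf_fV(NumericVector s, double omax, double ecc) {
  NumericVector out(s.size());
  for (int i = 0; i < s.size(); ++i) out[i] = fV_curve(s[i], omax, ecc);
  return out;
}

static vec joint_torques_impl(const Model& M, const double* q, const double* qd,
                              const double* a) {
  vec tau(NQ, arma::fill::zeros);
  for (int j = 0; j < 6; ++j) {
    int qi = 3 + j;
    double th = q[qi], om = qd[qi], t = 0;
    for (int k = 0; k < 2; ++k) {
      int mi = 2 * j + k;
      double sg = M.a.sgn(mi);
      t += sg * M.a.tau0(mi) * a[mi]
         * fA_curve(th, M.a.opt(mi), M.a.width(mi))
         * fV_curve(sg * om, M.a.omax(mi), M.a.ecc);
    }
    t -= M.a.beta(j) * om;
    tau(qi) = t;
  }
  return tau;
}

// [[Rcpp::export]]
arma::vec rf_joint_torques(List model, arma::vec q, arma::vec qd, arma::vec a) {
  Model M = parse_model(model);
  if (!M.has_act) stop("model has no actuation block");
  return joint_torques_impl(M, q.memptr(), qd.memptr(), a.memptr());
}

static inline double act_rate(const Act& A, double e, double a) {
  if (A.variant == 0) {
    return (e - a) / (0.5 * (A.ta + A.td));
  }
  // smooth excitation-dependent time constant
  double w = s5((e - a) / 0.1 + 0.5);
  double teff = A.td + (A.ta - A.td) * w;
  return (e - a) / teff;
}

// [[Rcpp::export]]
NumericVector rf_activation_rate(List model, NumericVector e, NumericVector a) {
  Model M = parse_model(model);
  if (!M.has_act) stop("model has no actuation block");
  NumericVector out(e.size());
  for (int i = 0; i < e.size(); ++i) out[i] = act_rate(M.a, e[i], a[i]);
  return out;
}

// ---------------------------------------------------------------------------
// full state derivative and RKF45 phase integrator

static void rhs_impl(const Model& M, int modeL, int modeR, double bp, double bv,
                     const double* x, const double* e, double* dx) {
  vec q(const_cast<double*>(x), NQ, false, true);
  vec qd(const_cast<double*>(x) + NQ, NQ, false, true);
  Kin K = compute_kin(M.b, x, x + NQ);
  vec tau(NQ, arma::fill::zeros);
  if (M.has_act) tau = joint_torques_impl(M, x, x + NQ, x + 2 * NQ);
  std::vector<CRow> rows = all_rows(M, K, x + NQ, modeL, modeR);
  FDResult R = fd_impl(M, K, q, qd, tau, rows, bp, bv, false);
  for (int i = 0; i < NQ; ++i) { dx[i] = x[NQ + i]; dx[NQ + i] = R.qdd(i); }
  if (M.has_act) {
    for (int i = 0; i < NMTG; ++i)
      dx[2 * NQ + i] = act_rate(M.a, e[i], x[2 * NQ + i]);
  } else {
    for (int i = 0; i < NMTG; ++i) dx[2 * NQ + i] = 0.0;
  }
}

// [[Rcpp::export]]
arma::vec rf_rhs(List model, arma::vec x, arma::vec e, int modeL, int modeR,
                 double bp, double bv) {
  Model M = parse_model(model);
  vec dx(NX);
  rhs_impl(M, modeL, modeR, bp, bv, x.memptr(), e.memptr(), dx.memptr());
  return dx;
}

// piecewise-linear control interpolation
static void interp_u(const vec& tn, const mat& U, double t, double* e) {
  int n = tn.n_elem;
  if (n == 1) { for (int i = 0; i < NMTG; ++i) e[i] = U(i, 0); return; }
  if (t <= tn(0)) { for (int i = 0; i < NMTG; ++i) e[i] = U(i, 0); return; }
  if (t >= tn(n - 1)) { for (int i = 0; i < NMTG; ++i) e[i] = U(i, n - 1); return; }
  int k = 0;
  while (k < n - 2 && t > tn(k + 1)) ++k;
  double w = (t - tn(k)) / (tn(k + 1) - tn(k));
  for (int i = 0; i < NMTG; ++i) e[i] = (1 - w) * U(i, k) + w * U(i, k + 1);
}

// Phase integrator.  Default: Fehlberg 4(5) with local extrapolation and
// adaptive steps.  With fixed_steps > 0, classic RK4 with that many equal
// steps per output segment (between consecutive record times / the end) --
// a smooth deterministic map suited to finite-difference sensitivities in
// the multiple-shooting transcription.
// [[Rcpp::export]]
List rf_rollout(List model, arma::vec x0, int modeL, int modeR,
                arma::vec t_u, arma::mat U, double duration,
                double tol, double bp, double bv,
                Nullable<NumericVector> record = R_NilValue,
                int max_steps = 200000, int fixed_steps = 0) {
  Model M = parse_model(model);
  if ((int)x0.n_elem != NX) stop("state must have 30 entries");
  if ((int)U.n_rows != NMTG) stop("controls must have 12 rows");
  std::vector<double> rec;
  if (record.isNotNull()) {
    NumericVector r(record);
    rec.assign(r.begin(), r.end());
    std::sort(rec.begin(), rec.end());
  }
  mat Xrec(NX, rec.size());
  double x[NX], xs[NX], k1[NX], k2[NX], k3[NX], k4[NX], k5[NX], k6[NX];
  double e[NMTG];
  std::copy(x0.begin(), x0.end(), x);
  double t = 0;
  size_t ri = 0;
  // record anything at t = 0
  while (ri < rec.size() && rec[ri] <= 1e-14) {
    for (int i = 0; i < NX; ++i) Xrec(i, ri) = x[i];
    ++ri;
  }
  int nstep = 0;
  if (duration > 0 && fixed_steps > 0) {
    // segment boundaries: record times within (0, duration), then the end
    std::vector<double> seg;
    for (size_t i = ri; i < rec.size(); ++i)
      if (rec[i] > 1e-14 && rec[i] < duration - 1e-14) seg.push_back(rec[i]);
    seg.push_back(duration);
    for (double tstop : seg) {
      double h = (tstop - t) / fixed_steps;
      for (int sstep = 0; sstep < fixed_steps; ++sstep) {
        ++nstep;
        interp_u(t_u, U, t, e);           rhs_impl(M, modeL, modeR, bp, bv, x, e, k1);
        for (int i = 0; i < NX; ++i) xs[i] = x[i] + 0.5 * h * k1[i];
        interp_u(t_u, U, t + 0.5 * h, e); rhs_impl(M, modeL, modeR, bp, bv, xs, e, k2);
        for (int i = 0; i < NX; ++i) xs[i] = x[i] + 0.5 * h * k2[i];
        rhs_impl(M, modeL, modeR, bp, bv, xs, e, k3);
        for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * k3[i];
        interp_u(t_u, U, t + h, e);       rhs_impl(M, modeL, modeR, bp, bv, xs, e, k4);
        for (int i = 0; i < NX; ++i)
          x[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
        t += h;
        if (!std::isfinite(x[0]) || !std::isfinite(x[NQ]))
          stop("integrator produced non-finite state at t = %g", t);
      }
      t = tstop;
      while (ri < rec.size() && rec[ri] <= t + 1e-14) {
        for (int i = 0; i < NX; ++i) Xrec(i, ri) = x[i];
        ++ri;
      }
    }
  } else if (duration > 0) {
    double h = duration / 50.0;
    const double hmin = 1e-12;
    while (t < duration - 1e-14) {
      if (++nstep > max_steps)
        stop("integrator exceeded %d steps at t = %g", max_steps, t);
      double tlim = duration;
      if (ri < rec.size()) tlim = std::min(tlim, rec[ri]);
      if (h > tlim - t) h = tlim - t;
      if (h < hmin) h = hmin;
      // stages
      interp_u(t_u, U, t, e);                 rhs_impl(M, modeL, modeR, bp, bv, x, e, k1);
      for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * 0.25 * k1[i];
      interp_u(t_u, U, t + 0.25 * h, e);      rhs_impl(M, modeL, modeR, bp, bv, xs, e, k2);
      for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * (3.0/32 * k1[i] + 9.0/32 * k2[i]);
      interp_u(t_u, U, t + 3.0/8 * h, e);     rhs_impl(M, modeL, modeR, bp, bv, xs, e, k3);
      for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * (1932.0/2197 * k1[i] - 7200.0/2197 * k2[i] + 7296.0/2197 * k3[i]);
      interp_u(t_u, U, t + 12.0/13 * h, e);   rhs_impl(M, modeL, modeR, bp, bv, xs, e, k4);
      for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * (439.0/216 * k1[i] - 8.0 * k2[i] + 3680.0/513 * k3[i] - 845.0/4104 * k4[i]);
      interp_u(t_u, U, t + h, e);             rhs_impl(M, modeL, modeR, bp, bv, xs, e, k5);
      for (int i = 0; i < NX; ++i) xs[i] = x[i] + h * (-8.0/27 * k1[i] + 2.0 * k2[i] - 3544.0/2565 * k3[i] + 1859.0/4104 * k4[i] - 11.0/40 * k5[i]);
      interp_u(t_u, U, t + 0.5 * h, e);       rhs_impl(M, modeL, modeR, bp, bv, xs, e, k6);
      double errmax = 0;
      for (int i = 0; i < NX; ++i) {
        double x5 = x[i] + h * (16.0/135 * k1[i] + 6656.0/12825 * k3[i] + 28561.0/56430 * k4[i] - 9.0/50 * k5[i] + 2.0/55 * k6[i]);
        double x4 = x[i] + h * (25.0/216 * k1[i] + 1408.0/2565 * k3[i] + 2197.0/4104 * k4[i] - 1.0/5 * k5[i]);
        double sc = tol + tol * std::fabs(x[i]);
        double err = std::fabs(x5 - x4) / sc;
        if (err > errmax) errmax = err;
        xs[i] = x5;
      }
      if (!std::isfinite(errmax))
        stop("integrator produced non-finite state at t = %g", t);
      if (errmax <= 1.0 || h <= 2 * hmin) {
        t += h;
        std::copy(xs, xs + NX, x);
        while (ri < rec.size() && rec[ri] <= t + 1e-14) {
          for (int i = 0; i < NX; ++i) Xrec(i, ri) = x[i];
          ++ri;
        }
      }
      double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      fac = std::min(5.0, std::max(0.1, fac));
      h *= fac;
      if (h > duration / 4.0) h = duration / 4.0;
    }
  }
  while (ri < rec.size()) { // times at/after the end
    for (int i = 0; i < NX; ++i) Xrec(i, ri) = x[i];
    ++ri;
  }
  vec xend(NX);
  std::copy(x, x + NX, xend.begin());
  return List::create(_["x_end"] = xend, _["X"] = Xrec, _["n_steps"] = nstep);
}
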