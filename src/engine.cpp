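// Time-stepping core for the node-and-spring gliding-cell model.
//
// Bodies are laid out cell-major: for each cell, n circular nodes
// (row 0 = leading pole) followed by n-1 rectangular spacers. Forces follow
// the pure-R reference implementations in R/forces.R term for term; a test
// asserts one compiled step equals the R-side force computation.
//
// Integration is semi-implicit (symplectic) Euler with the Stokes drag term
// treated implicitly in the velocity update, which keeps the quasi-overdamped
// regime (m/gamma << dt) stable at the default step size.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct Pars {
  int n_nodes;
  double node_radius, spacer_length, cell_width, mass;
  double k_joint, k_bend, f_prop, gamma, k_contact, friction_mu, dt;
  double kappa, d_break, reform_rate;
  bool ecm;
};

static inline void check_finite(double v, const char *term) {
  if (!std::isfinite(v)) {
    stop(std::string("non-finite value in force term '") + term +
         "' (numerical blow-up; reduce dt or stiffness)");
  }
}

// circle-rectangle overlap; writes depth, world normal (circle -> rect) and
// contact point; returns true on overlap
static bool circle_rect(double cx, double cy, double r,
                        double rpx, double rpy, double rang,
                        double rl, double rw,
                        double &depth, double &nx, double &ny,
                        double &px, double &py) {
  double ca = std::cos(rang), sa = std::sin(rang);
  double dx = cx - rpx, dy = cy - rpy;
  double lx = ca * dx + sa * dy;
  double ly = -sa * dx + ca * dy;
  double hx = rl / 2.0, hy = rw / 2.0;
  double qx = std::max(-hx, std::min(hx, lx));
  double qy = std::max(-hy, std::min(hy, ly));
  if (qx == lx && qy == ly) {
    double ddx = hx - std::fabs(lx), ddy = hy - std::fabs(ly);
    if (ddx < ddy) qx = (lx >= 0) ? hx : -hx; else qy = (ly >= 0) ? hy : -hy;
  }
  double gx = lx - qx, gy = ly - qy;
  double dist = std::sqrt(gx * gx + gy * gy);
  if (dist >= r || dist == 0.0) return false;
  double nlx = -gx / dist, nly = -gy / dist;
  nx = ca * nlx - sa * nly;
  ny = sa * nlx + ca * nly;
  px = rpx + ca * qx - sa * qy;
  py = rpy + sa * qx + ca * qy;
  depth = r - dist;
  return true;
}

// closest points between two segments a0-a1 and b0-b1 (2D); returns the
// squared distance and writes the closest points
static double seg_seg(double a0x, double a0y, double a1x, double a1y,
                      double b0x, double b0y, double b1x, double b1y,
                      double &pax, double &pay, double &pbx, double &pby) {
  double dax = a1x - a0x, day = a1y - a0y;
  double dbx = b1x - b0x, dby = b1y - b0y;
  double rx = a0x - b0x, ry = a0y - b0y;
  double A = dax * dax + day * day;
  double B = dax * dbx + day * dby;
  double C = dbx * dbx + dby * dby;
  double D = dax * rx + day * ry;
  double E = dbx * rx + dby * ry;
  double den = A * C - B * B;
  double s = (den > 1e-14) ? (B * E - C * D) / den : 0.0;
  s = std::max(0.0, std::min(1.0, s));
  double t = (C > 1e-14) ? (B * s + E) / C : 0.0;
  t = std::max(0.0, std::min(1.0, t));
  // re-clamp s for the clamped t
  s = (A > 1e-14) ? (B * t - D) / A : 0.0;
  s = std::max(0.0, std::min(1.0, s));
  pax = a0x + s * dax; pay = a0y + s * day;
  pbx = b0x + t * dbx; pby = b0y + t * dby;
  double dx = pbx - pax, dy = pby - pay;
  return dx * dx + dy * dy;
}

// [[Rcpp::export]]
List advance_cpp(NumericMatrix pos, NumericMatrix vel,
                 NumericVector ang, NumericVector omega,
                 NumericMatrix bonds, List pars_list,
                 int n_cells, int n_steps, int sample_every, double time0) {
  Pars P;
  P.n_nodes = as<int>(pars_list["n_nodes"]);
  P.node_radius = as<double>(pars_list["node_radius"]);
  P.spacer_length = as<double>(pars_list["spacer_length"]);
  P.cell_width = as<double>(pars_list["cell_width"]);
  P.mass = as<double>(pars_list["body_mass"]);
  P.k_joint = as<double>(pars_list["k_joint"]);
  P.k_bend = as<double>(pars_list["k_bend"]);
  P.f_prop = as<double>(pars_list["f_prop"]);
  P.gamma = as<double>(pars_list["gamma_node"]);
  P.k_contact = as<double>(pars_list["k_contact"]);
  P.friction_mu = as<double>(pars_list["friction_mu"]);
  P.dt = as<double>(pars_list["dt"]);
  P.kappa = as<double>(pars_list["kappa"]);
  P.d_break = as<double>(pars_list["d_break"]);
  P.reform_rate = as<double>(pars_list["reform_rate"]);
  P.ecm = as<int>(pars_list["ecm"]) != 0;

  const int n = P.n_nodes;
  const int nb = 2 * n - 1;             // bodies per cell
  const int nsp = n - 1;                // spacers per cell
  const int ntot = n_cells * nb;
  const double half = P.spacer_length / 2.0;
  const double I_sp = P.mass * (P.spacer_length * P.spacer_length +
                                P.cell_width * P.cell_width) / 12.0;
  const double g_rot = P.gamma * (P.spacer_length * P.spacer_length +
                                  P.cell_width * P.cell_width) / 12.0;
  const double overlap_tol = 0.05 * P.cell_width;
  const int n_bonds = bonds.nrow();

  std::vector<double> fx(ntot), fy(ntot), tq(n_cells * nsp);
  int n_samples = (sample_every > 0) ? n_steps / sample_every : 0;
  NumericVector s_t(n_samples);
  NumericMatrix s_x(n_samples, n_cells * n), s_y(n_samples, n_cells * n);
  double first_contact = NA_REAL, max_depth = 0.0;
  int n_breaks = 0, isample = 0;

  for (int step = 0; step < n_steps; ++step) {
    double now = time0 + step * P.dt;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(tq.begin(), tq.end(), 0.0);

    for (int c = 0; c < n_cells; ++c) {
      const int o = c * nb;        // body offset of this cell
      const int os = c * nsp;      // spacer/torque offset

      // joint springs: node j <-> leading end of spacer j,
      //                node j+1 <-> trailing end of spacer j
      for (int j = 0; j < nsp; ++j) {
        int sp = o + n + j;
        double ca = std::cos(ang[os + j]), sa = std::sin(ang[os + j]);
        for (int side = 0; side < 2; ++side) {
          int node = o + (side == 0 ? j : j + 1);
          double sgn = (side == 0) ? 1.0 : -1.0;
          double epx = pos(sp, 0) + sgn * half * ca;
          double epy = pos(sp, 1) + sgn * half * sa;
          double fnx = P.k_joint * (epx - pos(node, 0));
          double fny = P.k_joint * (epy - pos(node, 1));
          fx[node] += fnx; fy[node] += fny;
          fx[sp] -= fnx;  fy[sp] -= fny;
          double armx = epx - pos(sp, 0), army = epy - pos(sp, 1);
          tq[os + j] += armx * (-fny) - army * (-fnx);
        }
        check_finite(fx[sp] + tq[os + j], "joint");
      }

      // angular springs (gradient of E = k/2 (|theta| - pi)^2)
      for (int i = 1; i < n - 1; ++i) {
        double ux = pos(o + i - 1, 0) - pos(o + i, 0);
        double uy = pos(o + i - 1, 1) - pos(o + i, 1);
        double vx = pos(o + i + 1, 0) - pos(o + i, 0);
        double vy = pos(o + i + 1, 1) - pos(o + i, 1);
        double cr = ux * vy - uy * vx, dt_ = ux * vx + uy * vy;
        double den = cr * cr + dt_ * dt_;
        if (den == 0.0) stop("bending: degenerate zero-length arm");
        double theta = std::atan2(cr, dt_);
        double s = (theta < 0) ? -1.0 : 1.0;
        double coef = -P.k_bend * (s * theta - M_PI) * s;
        double fax = coef * (dt_ * vy - cr * vx) / den;
        double fay = coef * (dt_ * (-vx) - cr * vy) / den;
        double fcx = coef * (dt_ * (-uy) - cr * ux) / den;
        double fcy = coef * (dt_ * ux - cr * uy) / den;
        fx[o + i - 1] += fax; fy[o + i - 1] += fay;
        fx[o + i + 1] += fcx; fy[o + i + 1] += fcy;
        fx[o + i] -= fax + fcx; fy[o + i] -= fay + fcy;
        check_finite(fax + fcy, "bending");
      }

      // propulsion at interior nodes, toward the leading pole
      for (int i = 1; i < n - 1; ++i) {
        double dx = pos(o + i - 1, 0) - pos(o + i, 0);
        double dy = pos(o + i - 1, 1) - pos(o + i, 1);
        double len = std::sqrt(dx * dx + dy * dy);
        fx[o + i] += P.f_prop * dx / len;
        fy[o + i] += P.f_prop * dy / len;
      }
    }

    // adhesion bonds (ECM only); bonds cols: cell, node, ax, ay, ux, uy,
    // intact, reform_at (cell/node 1-based). The bond axis (ux, uy) is
    // frozen at formation; the anchor slides freely along it and only
    // perpendicular displacement is loaded.
    if (P.ecm) {
      for (int k = 0; k < n_bonds; ++k) {
        int c = (int)bonds(k, 0) - 1;
        int i = (int)bonds(k, 1) - 1;
        int o = c * nb;
        if (bonds(k, 6) == 0.0) {
          if (bonds(k, 7) <= now) {
            bonds(k, 6) = 1.0;
            bonds(k, 2) = pos(o + i, 0);
            bonds(k, 3) = pos(o + i, 1);
            // bond axis frozen to the local cell axis at formation
            double axx = pos(o + i - 1, 0) - pos(o + i + 1, 0);
            double axy = pos(o + i - 1, 1) - pos(o + i + 1, 1);
            double alen = std::sqrt(axx * axx + axy * axy);
            bonds(k, 4) = axx / alen;
            bonds(k, 5) = axy / alen;
          }
          continue;
        }
        double axx = bonds(k, 4), axy = bonds(k, 5);
        double dx = pos(o + i, 0) - bonds(k, 2);
        double dy = pos(o + i, 1) - bonds(k, 3);
        double axc = dx * axx + dy * axy;
        bonds(k, 2) += axc * axx;      // anchor slides along the bond line
        bonds(k, 3) += axc * axy;
        bonds(k, 8) += axc;
        double lx = dx - axc * axx, ly = dy - axc * axy;
        double stretch = std::sqrt(lx * lx + ly * ly);
        if (stretch > P.d_break) {
          bonds(k, 6) = 0.0;
          bonds(k, 7) = now + R::rexp(1.0 / P.reform_rate);
          bonds(k, 8) = 0.0;
          ++n_breaks;
        } else {
          fx[o + i] -= P.kappa * lx;
          fy[o + i] -= P.kappa * ly;
          check_finite(fx[o + i], "adhesion");
          // adhesion turnover: after one node spacing of axial travel the
          // load is handed to a fresh site at the node's current position
          if (std::fabs(bonds(k, 8)) >= P.spacer_length) {
            bonds(k, 2) = pos(o + i, 0);
            bonds(k, 3) = pos(o + i, 1);
            double nax = pos(o + i - 1, 0) - pos(o + i + 1, 0);
            double nay = pos(o + i - 1, 1) - pos(o + i + 1, 1);
            double nal = std::sqrt(nax * nax + nay * nay);
            bonds(k, 4) = nax / nal;
            bonds(k, 5) = nay / nal;
            bonds(k, 8) = 0.0;
          }
        }
      }
    }

    // contacts between bodies of different cells (circle-circle and
    // circle-rectangle; spacer ends are capped by the node circles)
    for (int ca = 0; ca + 1 < n_cells; ++ca) {
      for (int cb = ca + 1; cb < n_cells; ++cb) {
        int oa = ca * nb, ob = cb * nb;
        for (int a = 0; a < nb; ++a) {
          bool a_circ = a < n;
          for (int b = 0; b < nb; ++b) {
            bool b_circ = b < n;
            double depth, nx, ny, px, py;
            bool hit = false;
            if (!a_circ && !b_circ) {
              // spacer-spacer as capsule-capsule: without it, obliquely
              // crossing cells can tunnel between the node circles
              int ja = a - n, jb = b - n;
              double caa = std::cos(ang[ca * nsp + ja]);
              double saa = std::sin(ang[ca * nsp + ja]);
              double cab = std::cos(ang[cb * nsp + jb]);
              double sab = std::sin(ang[cb * nsp + jb]);
              double pax, pay, pbx, pby;
              double d2 = seg_seg(
                pos(oa + a, 0) - half * caa, pos(oa + a, 1) - half * saa,
                pos(oa + a, 0) + half * caa, pos(oa + a, 1) + half * saa,
                pos(ob + b, 0) - half * cab, pos(ob + b, 1) - half * sab,
                pos(ob + b, 0) + half * cab, pos(ob + b, 1) + half * sab,
                pax, pay, pbx, pby);
              double dist = std::sqrt(d2);
              if (dist < P.cell_width && dist > 0.0) {
                depth = P.cell_width - dist;
                nx = (pbx - pax) / dist; ny = (pby - pay) / dist;
                px = (pax + pbx) / 2.0; py = (pay + pby) / 2.0;
                hit = true;
              }
            } else if (a_circ && b_circ) {
              double dx = pos(ob + b, 0) - pos(oa + a, 0);
              double dy = pos(ob + b, 1) - pos(oa + a, 1);
              double dist = std::sqrt(dx * dx + dy * dy);
              if (dist < 2.0 * P.node_radius && dist > 0.0) {
                depth = 2.0 * P.node_radius - dist;
                nx = dx / dist; ny = dy / dist;
                px = (pos(oa + a, 0) + pos(ob + b, 0)) / 2.0;
                py = (pos(oa + a, 1) + pos(ob + b, 1)) / 2.0;
                hit = true;
              }
            } else if (a_circ) {
              int j = b - n;
              hit = circle_rect(pos(oa + a, 0), pos(oa + a, 1), P.node_radius,
                                pos(ob + b, 0), pos(ob + b, 1),
                                ang[cb * nsp + j], P.spacer_length,
                                P.cell_width, depth, nx, ny, px, py);
            } else {
              int j = a - n;
              hit = circle_rect(pos(ob + b, 0), pos(ob + b, 1), P.node_radius,
                                pos(oa + a, 0), pos(oa + a, 1),
                                ang[ca * nsp + j], P.spacer_length,
                                P.cell_width, depth, nx, ny, px, py);
              if (hit) { nx = -nx; ny = -ny; }  // normal points a -> b
            }
            if (!hit) continue;
            if (!std::isfinite(first_contact)) first_contact = now;
            if (depth > max_depth) max_depth = depth;
            double fmag = P.k_contact * depth;
            double fax_ = -fmag * nx, fay_ = -fmag * ny;
            // regularized Coulomb friction on the tangential slip velocity
            if (P.friction_mu > 0.0) {
              double tx_ = -ny, ty_ = nx;  // contact tangent
              double vax_ = vel(oa + a, 0), vay_ = vel(oa + a, 1);
              double vbx_ = vel(ob + b, 0), vby_ = vel(ob + b, 1);
              if (!a_circ) {
                int j = a - n;
                double armx = px - pos(oa + a, 0), army = py - pos(oa + a, 1);
                vax_ += -omega[ca * nsp + j] * army;
                vay_ += omega[ca * nsp + j] * armx;
              }
              if (!b_circ) {
                int j = b - n;
                double armx = px - pos(ob + b, 0), army = py - pos(ob + b, 1);
                vbx_ += -omega[cb * nsp + j] * army;
                vby_ += omega[cb * nsp + j] * armx;
              }
              double vslip = (vax_ - vbx_) * tx_ + (vay_ - vby_) * ty_;
              double ft = -P.friction_mu * fmag * std::tanh(vslip / 0.5);
              fax_ += ft * tx_; fay_ += ft * ty_;
            }
            fx[oa + a] += fax_; fy[oa + a] += fay_;
            fx[ob + b] -= fax_; fy[ob + b] -= fay_;
            if (!a_circ) {
              int j = a - n;
              double armx = px - pos(oa + a, 0), army = py - pos(oa + a, 1);
              tq[ca * nsp + j] += armx * fay_ - army * fax_;
            }
            if (!b_circ) {
              int j = b - n;
              double armx = px - pos(ob + b, 0), army = py - pos(ob + b, 1);
              tq[cb * nsp + j] += armx * (-fay_) - army * (-fax_);
            }
            check_finite(fax_, "contact");
          }
        }
      }
    }

    if (max_depth > overlap_tol) {
      stop("contact overlap %.4f um exceeds the accepted tolerance (5%% of "
           "cell width); reduce dt or increase k_contact", max_depth);
    }

    // semi-implicit Euler, implicit Stokes drag
    const double lam = 1.0 + P.gamma * P.dt / P.mass;
    const double lam_rot = 1.0 + g_rot * P.dt / I_sp;
    for (int b = 0; b < ntot; ++b) {
      vel(b, 0) = (vel(b, 0) + fx[b] * P.dt / P.mass) / lam;
      vel(b, 1) = (vel(b, 1) + fy[b] * P.dt / P.mass) / lam;
      pos(b, 0) += vel(b, 0) * P.dt;
      pos(b, 1) += vel(b, 1) * P.dt;
      if (!std::isfinite(pos(b, 0)) || !std::isfinite(pos(b, 1))) {
        stop("non-finite position after integration step (body %d)", b + 1);
      }
    }
    for (int s = 0; s < n_cells * nsp; ++s) {
      omega[s] = (omega[s] + tq[s] * P.dt / I_sp) / lam_rot;
      ang[s] += omega[s] * P.dt;
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0 &&
        isample < n_samples) {
      s_t[isample] = time0 + (step + 1) * P.dt;
      for (int c = 0; c < n_cells; ++c) {
        for (int i = 0; i < n; ++i) {
          s_x(isample, c * n + i) = pos(c * nb + i, 0);
          s_y(isample, c * n + i) = pos(c * nb + i, 1);
        }
      }
      ++isample;
    }
  }

  return List::create(
    _["pos"] = pos, _["vel"] = vel, _["ang"] = ang, _["omega"] = omega,
    _["bonds"] = bonds, _["time"] = time0 + n_steps * P.dt,
    _["first_contact"] = first_contact, _["max_depth"] = max_depth,
    _["n_breaks"] = n_breaks,
    _["sample_t"] = s_t, _["sample_x"] = s_x, _["sample_y"] = s_y);
}

// [[Rcpp::export]]
NumericVector draw_reform_waits_cpp(int n, double rate) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = R::rexp(1.0 / rate);
  return out;
}
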