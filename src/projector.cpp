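// Ray-tracing cores: exact Siddon intersections (2-D transaxial LUT +
// on-the-fly axial merge), forward/back projection, arbitrary-segment
// line integrals and the voxel-driven single-scatter model inner loops.
//
// Conventions: lengths in mm, mu in cm^-1 (divided by 10 at the exp() site),
// voxel intervals half-open [low, high), ray parametrised by t in [0,1]
// from crystal A to crystal B (the same t serves the 2-D and 3-D paths
// because z is linear in t).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-12;

// 2-D Amanatides-Woo traversal of the (x, y) grid; records, per crossed
// voxel column, the parametric interval [t0, t1] along the segment.
static void trace2d(double x1, double y1, double x2, double y2,
                    int nx, int ny, double vx, double vy,
                    double x0, double y0,
                    std::vector<int> &col, std::vector<double> &tin,
                    std::vector<double> &tout) {
  const double dx = x2 - x1, dy = y2 - y1;
  double t0 = 0.0, t1 = 1.0;
  // slab clipping
  if (std::fabs(dx) < EPS) {
    if (x1 < x0 || x1 >= x0 + nx * vx) return;
  } else {
    double ta = (x0 - x1) / dx, tb = (x0 + nx * vx - x1) / dx;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (std::fabs(dy) < EPS) {
    if (y1 < y0 || y1 >= y0 + ny * vy) return;
  } else {
    double ta = (y0 - y1) / dy, tb = (y0 + ny * vy - y1) / dy;
    if (ta > tb) std::swap(ta, tb);
    t0 = std::max(t0, ta); t1 = std::min(t1, tb);
  }
  if (t1 <= t0) return;
  const double xs = x1 + t0 * dx, ys = y1 + t0 * dy;
  int ix = (int)std::floor((xs - x0) / vx);
  int iy = (int)std::floor((ys - y0) / vy);
  if (ix < 0) ix = 0; if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0; if (iy > ny - 1) iy = ny - 1;
  const int stepx = (dx > 0) ? 1 : -1, stepy = (dy > 0) ? 1 : -1;
  const double tdx = (std::fabs(dx) < EPS) ? R_PosInf : std::fabs(vx / dx);
  const double tdy = (std::fabs(dy) < EPS) ? R_PosInf : std::fabs(vy / dy);
  double tmx, tmy;
  if (std::fabs(dx) < EPS) tmx = R_PosInf;
  else {
    double bx = x0 + (ix + (stepx > 0 ? 1 : 0)) * vx;
    tmx = (bx - x1) / dx;
  }
  if (std::fabs(dy) < EPS) tmy = R_PosInf;
  else {
    double by = y0 + (iy + (stepy > 0 ? 1 : 0)) * vy;
    tmy = (by - y1) / dy;
  }
  double t = t0;
  while (t < t1 - EPS) {
    double tn = std::min(std::min(tmx, tmy), t1);
    if (tn > t + EPS && ix >= 0 && ix < nx && iy >= 0 && iy < ny) {
      col.push_back(ix + nx * iy);
      tin.push_back(t);
      tout.push_back(tn);
    }
    if (tmx <= tmy) { ix += stepx; tmx += tdx; } else { iy += stepy; tmy += tdy; }
    t = tn;
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) break;
  }
}

// Build the transaxial LUT for a set of bins (crystal pair per bin).
// [[Rcpp::export]]
List cpp_tx_lut(IntegerVector k1, IntegerVector k2,
                NumericVector detx, NumericVector dety,
                int nx, int ny, double vx, double vy,
                double x0, double y0) {
  const int nb = k1.size();
  std::vector<int> ptr(nb + 1, 0), col;
  std::vector<double> tin, tout, d2(nb);
  for (int b = 0; b < nb; ++b) {
    const double ax = detx[k1[b]], ay = dety[k1[b]];
    const double bx = detx[k2[b]], by = dety[k2[b]];
    d2[b] = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay));
    trace2d(ax, ay, bx, by, nx, ny, vx, vy, x0, y0, col, tin, tout);
    ptr[b + 1] = (int)col.size();
  }
  return List::create(_["ptr"] = wrap(ptr), _["col"] = wrap(col),
                      _["tin"] = wrap(tin), _["tout"] = wrap(tout),
                      _["d2"] = wrap(d2));
}

// Shared inner loop for forward (mode 0) and back (mode 1) projection.
// planes: r0/r1 give zA/zB (mm); bins: subset of tx bin ids (0-based).
static void project(int mode, NumericVector img, NumericVector sino,
                    int nx, int ny, int nz, double vz, double z0,
                    IntegerVector ptr, IntegerVector col,
                    NumericVector tin, NumericVector tout, NumericVector d2,
                    NumericVector zA, NumericVector zB,
                    IntegerVector bins, int nbins_tx) {
  const int np = zA.size();
  const int nxy = nx * ny;
  for (int p = 0; p < np; ++p) {
    const double za = zA[p], zb = zB[p];
    const double dz = zb - za;
    const double stepz = (dz > 0) ? 1.0 : -1.0;
    for (int ib = 0; ib < bins.size(); ++ib) {
      const int b = bins[ib];
      const double L3 = std::sqrt(d2[b] * d2[b] + dz * dz);
      const long soff = (long)b + (long)nbins_tx * p;
      double acc = 0.0;
      const double sval = (mode == 1) ? sino[soff] : 0.0;
      if (mode == 1 && sval == 0.0) continue;
      for (int e = ptr[b]; e < ptr[b + 1]; ++e) {
        const int c = col[e];
        double t0 = tin[e], t1 = tout[e];
        if (std::fabs(dz) < EPS) {
          const int iz = (int)std::floor((za - z0) / vz);
          if (iz < 0 || iz >= nz) continue;
          const double w = (t1 - t0) * L3;
          const long vox = (long)c + (long)nxy * iz;
          if (mode == 0) acc += w * img[vox];
          else img[vox] += w * sval;
        } else {
          // split [t0, t1] at z-plane crossings
          double za0 = za + t0 * dz, za1 = za + t1 * dz;
          int iz0 = (int)std::floor((za0 - z0) / vz);
          int iz1 = (int)std::floor((za1 - z0) / vz);
          double t = t0;
          int iz = iz0;
          while (true) {
            double tn;
            if (iz == iz1) tn = t1;
            else {
              const double zbnd = z0 + (iz + (stepz > 0 ? 1 : 0)) * vz;
              tn = (zbnd - za) / dz;
              if (tn > t1) tn = t1;
            }
            if (tn > t && iz >= 0 && iz < nz) {
              const double w = (tn - t) * L3;
              const long vox = (long)c + (long)nxy * iz;
              if (mode == 0) acc += w * img[vox];
              else img[vox] += w * sval;
            }
            if (iz == iz1) break;
            iz += (int)stepz;
            t = tn;
          }
        }
      }
      if (mode == 0) sino[soff] += acc;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericVector img,
                          int nx, int ny, int nz, double vz, double z0,
                          IntegerVector ptr, IntegerVector col,
                          NumericVector tin, NumericVector tout,
                          NumericVector d2,
                          NumericVector zA, NumericVector zB,
                          IntegerVector bins, int nbins_tx) {
  NumericVector sino((R_xlen_t)nbins_tx * zA.size());
  project(0, img, sino, nx, ny, nz, vz, z0, ptr, col, tin, tout, d2,
          zA, zB, bins, nbins_tx);
  return sino;
}

// [[Rcpp::export]]
NumericVector cpp_back(NumericVector sino,
                       int nx, int ny, int nz, double vz, double z0,
                       IntegerVector ptr, IntegerVector col,
                       NumericVector tin, NumericVector tout,
                       NumericVector d2,
                       NumericVector zA, NumericVector zB,
                       IntegerVector bins, int nbins_tx) {
  NumericVector img((R_xlen_t)nx * ny * nz);
  project(1, img, sino, nx, ny, nz, vz, z0, ptr, col, tin, tout, d2,
          zA, zB, bins, nbins_tx);
  return img;
}

// Exact 3-D Siddon line integral of an image along segments P1 -> P2.
// Returns sum(value * intersection length [mm]) per segment.
// [[Rcpp::export]]
NumericVector cpp_line_integrals(NumericMatrix P1, NumericMatrix P2,
                                 NumericVector img,
                                 IntegerVector dims, NumericVector vox,
                                 NumericVector corner) {
  const int n = P1.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p1[3] = {P1(i, 0), P1(i, 1), P1(i, 2)};
    double p2[3] = {P2(i, 0), P2(i, 1), P2(i, 2)};
    double d[3] = {p2[0] - p1[0], p2[1] - p1[1], p2[2] - p1[2]};
    const double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    if (L < EPS) { out[i] = 0.0; continue; }
    double t0 = 0.0, t1 = 1.0;
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      const double lo = corner[a], hi = corner[a] + dims[a] * vox[a];
      if (std::fabs(d[a]) < EPS) {
        if (p1[a] < lo || p1[a] >= hi) { miss = true; break; }
      } else {
        double ta = (lo - p1[a]) / d[a], tb = (hi - p1[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (miss || t1 <= t0) { out[i] = 0.0; continue; }
    int idx[3];
    for (int a = 0; a < 3; ++a) {
      const double s = p1[a] + t0 * d[a];
      idx[a] = (int)std::floor((s - corner[a]) / vox[a]);
      if (idx[a] < 0) idx[a] = 0;
      if (idx[a] > dims[a] - 1) idx[a] = dims[a] - 1;
    }
    double tmax[3], tdel[3];
    int step[3];
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < EPS) { tmax[a] = R_PosInf; tdel[a] = R_PosInf; step[a] = 0; }
      else {
        step[a] = d[a] > 0 ? 1 : -1;
        tdel[a] = std::fabs(vox[a] / d[a]);
        const double bnd = corner[a] + (idx[a] + (step[a] > 0 ? 1 : 0)) * vox[a];
        tmax[a] = (bnd - p1[a]) / d[a];
      }
    }
    double t = t0, acc = 0.0;
    while (t < t1 - EPS) {
      int am = 0;
      if (tmax[1] < tmax[am]) am = 1;
      if (tmax[2] < tmax[am]) am = 2;
      double tn = std::min(tmax[am], t1);
      if (tn > t && idx[0] >= 0 && idx[0] < nx && idx[1] >= 0 && idx[1] < ny &&
          idx[2] >= 0 && idx[2] < nz) {
        acc += img[(long)idx[0] + (long)nx * idx[1] + (long)nx * ny * idx[2]] *
               (tn - t) * L;
      }
      idx[am] += step[am];
      tmax[am] += tdel[am];
      t = tn;
      if (idx[am] < 0 || idx[am] >= dims[am]) break;
    }
    out[i] = acc;
  }
  return out;
}

// Klein-Nishina helpers (incident 511 keV, alpha = 1).
static inline double kn_P(double cost) { return 1.0 / (2.0 - cost); }
static inline double kn_dsdo(double cost, double re2) {
  const double P = kn_P(cost);
  const double sin2 = 1.0 - cost * cost;
  return 0.5 * re2 * P * P * (P + 1.0 / P - sin2);
}

// Walk the mu grid from point e along unit direction d; collect voxels with
// mu >= thr as scattering patches: entry distance (mm), chord (mm), voxel
// linear id, and cumulative mu path (cm^-1 * mm) from e to patch entry.
static void collect_patches(const double *e, const double *d,
                            const NumericVector &mu, const IntegerVector &dims,
                            const NumericVector &vox, const NumericVector &corner,
                            double thr,
                            std::vector<int> &pid, std::vector<double> &pr,
                            std::vector<double> &plen, std::vector<double> &pcum) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // clip to grid along positive ray (t in mm since d is unit)
  double t0 = 0.0, t1 = R_PosInf;
  for (int a = 0; a < 3; ++a) {
    const double lo = corner[a], hi = corner[a] + dims[a] * vox[a];
    if (std::fabs(d[a]) < EPS) {
      if (e[a] < lo || e[a] >= hi) return;
    } else {
      double ta = (lo - e[a]) / d[a], tb = (hi - e[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t1 <= t0) return;
  int idx[3];
  for (int a = 0; a < 3; ++a) {
    idx[a] = (int)std::floor((e[a] + t0 * d[a] - corner[a]) / vox[a]);
    if (idx[a] < 0) idx[a] = 0;
    if (idx[a] > dims[a] - 1) idx[a] = dims[a] - 1;
  }
  double tmax[3], tdel[3];
  int step[3];
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < EPS) { tmax[a] = R_PosInf; tdel[a] = R_PosInf; step[a] = 0; }
    else {
      step[a] = d[a] > 0 ? 1 : -1;
      tdel[a] = std::fabs(vox[a] / d[a]);
      const double bnd = corner[a] + (idx[a] + (step[a] > 0 ? 1 : 0)) * vox[a];
      tmax[a] = (bnd - e[a]) / d[a];
    }
  }
  double t = t0, cum = 0.0;
  while (t < t1 - EPS) {
    int am = 0;
    if (tmax[1] < tmax[am]) am = 1;
    if (tmax[2] < tmax[am]) am = 2;
    double tn = std::min(tmax[am], t1);
    if (tn > t && idx[0] >= 0 && idx[0] < nx && idx[1] >= 0 && idx[1] < ny &&
        idx[2] >= 0 && idx[2] < nz) {
      const long vid = (long)idx[0] + (long)nx * idx[1] + (long)nx * ny * idx[2];
      const double m = mu[vid];
      const double seg = tn - t;
      if (m >= thr) {
        pid.push_back((int)vid);
        pr.push_back(t);
        plen.push_back(seg);
        pcum.push_back(cum);
      }
      cum += m * seg;
    }
    idx[am] += step[am];
    tmax[am] += tdel[am];
    t = tn;
    if (idx[am] < 0 || idx[am] >= dims[am]) break;
  }
}

// Voxel-driven single-scatter model inner loops.
//
// em_pos: emission point coordinates [nE x 3] (mm), em_act: activity values;
// detA/detB: sampled detector coordinates [n x 3] with tx/ring ids;
// lutA: mu line integrals (cm^-1 mm) from each emission point to each A
//       detector [nE x nA];
// lutB: mu line integrals from each *patch-eligible mu voxel* (rows indexed
//       by patch_row[mu voxel id]) to each B detector [nPatch x nB];
// eratio_tab/cb_tab: lookup for the energy-dependent mu scaling c_B.
// Returns a dense span-1 sinogram vector (nbins_tx * n_planes).
// [[Rcpp::export]]
NumericVector cpp_vsm(NumericMatrix em_pos, NumericVector em_act,
                      NumericVector mu, IntegerVector mu_dims,
                      NumericVector mu_vox, NumericVector mu_corner,
                      NumericMatrix patch_centres, IntegerVector patch_row,
                      NumericMatrix detA, IntegerVector txA, IntegerVector ringA,
                      NumericMatrix detB, IntegerVector txB, IntegerVector ringB,
                      NumericMatrix lutA, NumericMatrix lutB,
                      double det_area, double ring_radius,
                      double patch_thr, double re2, double sigma_e,
                      NumericVector eratio_tab, NumericVector cb_tab,
                      IntegerVector pair2bin, LogicalVector aligned, int n_pos,
                      IntegerVector plane_of, int n_rings,
                      int nbins_tx, int n_planes) {
  const int nE = em_pos.nrow(), nA = detA.nrow(), nB = detB.nrow();
  NumericVector sino((R_xlen_t)nbins_tx * n_planes);
  std::vector<int> pid; std::vector<double> pr, plen, pcum;
  for (int ie = 0; ie < nE; ++ie) {
    const double e[3] = {em_pos(ie, 0), em_pos(ie, 1), em_pos(ie, 2)};
    const double act = em_act[ie];
    for (int ia = 0; ia < nA; ++ia) {
      double ua[3] = {detA(ia, 0) - e[0], detA(ia, 1) - e[1], detA(ia, 2) - e[2]};
      const double rA = std::sqrt(ua[0] * ua[0] + ua[1] * ua[1] + ua[2] * ua[2]);
      if (rA < EPS) continue;
      for (int a = 0; a < 3; ++a) ua[a] /= rA;
      // inward face normal of A (cylinder, transaxial)
      const double nAx = -detA(ia, 0) / ring_radius, nAy = -detA(ia, 1) / ring_radius;
      double cosA = -(ua[0] * nAx + ua[1] * nAy);  // photon travels along +ua into A
      cosA = std::fabs(cosA);
      const double epsA = det_area * cosA / (4.0 * M_PI * rA * rA);
      if (epsA <= 0) continue;
      const double survA = std::exp(-lutA(ie, ia) / 10.0);
      // scattered-photon ray: opposite direction
      const double d[3] = {-ua[0], -ua[1], -ua[2]};
      pid.clear(); pr.clear(); plen.clear(); pcum.clear();
      collect_patches(e, d, mu, mu_dims, mu_vox, mu_corner, patch_thr,
                      pid, pr, plen, pcum);
      for (size_t is = 0; is < pid.size(); ++is) {
        const int prow = patch_row[pid[is]];
        if (prow < 0) continue;
        const double Pi = epsA * survA * std::exp(-pcum[is] / 10.0);
        const double muS = mu[pid[is]];
        const double Ps = Pi * (1.0 - std::exp(-muS * plen[is] / 10.0));
        if (Ps <= 0) continue;
        const double s[3] = {patch_centres(prow, 0), patch_centres(prow, 1),
                             patch_centres(prow, 2)};
        for (int ib = 0; ib < nB; ++ib) {
          // skip degenerate LORs on the same crystal position/ring
          if (txB[ib] == txA[ia] && ringB[ib] == ringA[ia]) continue;
          double sb[3] = {detB(ib, 0) - s[0], detB(ib, 1) - s[1], detB(ib, 2) - s[2]};
          const double rB = std::sqrt(sb[0] * sb[0] + sb[1] * sb[1] + sb[2] * sb[2]);
          if (rB < EPS) continue;
          for (int a = 0; a < 3; ++a) sb[a] /= rB;
          const double cost = d[0] * sb[0] + d[1] * sb[1] + d[2] * sb[2];
          const double nBx = -detB(ib, 0) / ring_radius, nBy = -detB(ib, 1) / ring_radius;
          double cosB = std::fabs(sb[0] * nBx + sb[1] * nBy);
          const double omegaB = det_area * cosB / (rB * rB);
          // energy-dependent mu scaling c_B from the scattered energy ratio
          const double er = kn_P(cost);
          double cB;
          {
            const int nt = eratio_tab.size();
            if (er <= eratio_tab[0]) cB = cb_tab[0];
            else if (er >= eratio_tab[nt - 1]) cB = cb_tab[nt - 1];
            else {
              int lo = 0;
              while (lo < nt - 2 && eratio_tab[lo + 1] < er) ++lo;
              const double w = (er - eratio_tab[lo]) /
                               (eratio_tab[lo + 1] - eratio_tab[lo]);
              cB = cb_tab[lo] + w * (cb_tab[lo + 1] - cb_tab[lo]);
            }
          }
          const double survB = std::exp(-cB * lutB(prow, ib) / 10.0);
          const double contrib = act * Ps * (omegaB / sigma_e) *
                                 kn_dsdo(cost, re2) * survB;
          if (contrib <= 0) continue;
          // bin the (A, B) LOR
          const long pk = (long)txA[ia] + (long)n_pos * txB[ib];
          const int bin = pair2bin[pk];
          if (bin == NA_INTEGER) continue;
          int r0, r1;
          if (aligned[pk]) { r0 = ringA[ia]; r1 = ringB[ib]; }
          else { r0 = ringB[ib]; r1 = ringA[ia]; }
          const int plane = plane_of[(long)r0 + (long)n_rings * r1];
          if (plane == NA_INTEGER) continue;
          sino[(R_xlen_t)bin + (R_xlen_t)nbins_tx * plane] += contrib;
        }
      }
    }
  }
  return sino;
}
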