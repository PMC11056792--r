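#include <Rcpp.h>
using namespace Rcpp;

// Batch ray casting against a triangle soup (Moller-Trumbore), used by the
// elastic-foundation contact model to measure penetration depths.
//
// For ray i (origin o_i, unit direction d_i) the first intersection with a
// triangle whose geometric normal has positive dot product with d_i (i.e. the
// ray exits through the opposing surface from inside its solid) and parameter
// t in (tmin, tmax] is reported.  Rays that hit nothing get t = 0.
//
// A per-triangle AABB against the ray's segment AABB rejects most pairs before
// the full intersection test; penetration depths are bounded by the foundation
// depth h, so segments are short and the reject rate is high.

// [[Rcpp::export(name = ".raycast_depths")]]
NumericVector raycast_depths(NumericMatrix orig, NumericMatrix dir,
                             NumericMatrix V, IntegerMatrix F,
                             double tmax, double tmin = 1e-9) {
  const int nr = orig.nrow();
  const int nf = F.nrow();
  NumericVector out(nr);

  // triangle vertex coordinates and AABBs, flattened
  std::vector<double> ax(nf), ay(nf), az(nf), bx(nf), by(nf), bz(nf),
      cx(nf), cy(nf), cz(nf), lox(nf), loy(nf), loz(nf), hix(nf), hiy(nf), hiz(nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f, 0) - 1, ib = F(f, 1) - 1, ic = F(f, 2) - 1;
    ax[f] = V(ia, 0); ay[f] = V(ia, 1); az[f] = V(ia, 2);
    bx[f] = V(ib, 0); by[f] = V(ib, 1); bz[f] = V(ib, 2);
    cx[f] = V(ic, 0); cy[f] = V(ic, 1); cz[f] = V(ic, 2);
    lox[f] = std::min(ax[f], std::min(bx[f], cx[f]));
    loy[f] = std::min(ay[f], std::min(by[f], cy[f]));
    loz[f] = std::min(az[f], std::min(bz[f], cz[f]));
    hix[f] = std::max(ax[f], std::max(bx[f], cx[f]));
    hiy[f] = std::max(ay[f], std::max(by[f], cy[f]));
    hiz[f] = std::max(az[f], std::max(bz[f], cz[f]));
  }

  // uniform grid over the X-Z plane for candidate pruning (rays are short:
  // t <= tmax = foundation depth)
  double gx0 = R_PosInf, gz0 = R_PosInf, gx1 = R_NegInf, gz1 = R_NegInf;
  for (int f = 0; f < nf; ++f) {
    gx0 = std::min(gx0, lox[f]); gz0 = std::min(gz0, loz[f]);
    gx1 = std::max(gx1, hix[f]); gz1 = std::max(gz1, hiz[f]);
  }
  double cell = std::max(1e-6, std::sqrt((gx1 - gx0) * (gz1 - gz0) /
                                         std::max(1, nf)) * 2.0);
  int ncx = std::max(1, (int)((gx1 - gx0) / cell) + 1);
  int ncz = std::max(1, (int)((gz1 - gz0) / cell) + 1);
  std::vector<std::vector<int> > grid((size_t)ncx * ncz);
  for (int f = 0; f < nf; ++f) {
    int ix0 = std::max(0, std::min(ncx - 1, (int)((lox[f] - gx0) / cell)));
    int ix1 = std::max(0, std::min(ncx - 1, (int)((hix[f] - gx0) / cell)));
    int iz0 = std::max(0, std::min(ncz - 1, (int)((loz[f] - gz0) / cell)));
    int iz1 = std::max(0, std::min(ncz - 1, (int)((hiz[f] - gz0) / cell)));
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iz = iz0; iz <= iz1; ++iz)
        grid[(size_t)ix * ncz + iz].push_back(f);
  }

  const double eps = 1e-12;
  std::vector<char> seen(nf, 0);
  std::vector<int> touched;
  touched.reserve(256);
  for (int i = 0; i < nr; ++i) {
    double ox = orig(i, 0), oy = orig(i, 1), oz = orig(i, 2);
    double dx = dir(i, 0), dy = dir(i, 1), dz = dir(i, 2);
    // segment AABB for t in [0, tmax]
    double sx0 = ox + (dx < 0 ? dx * tmax : 0.0), sx1 = ox + (dx > 0 ? dx * tmax : 0.0);
    double sy0 = oy + (dy < 0 ? dy * tmax : 0.0), sy1 = oy + (dy > 0 ? dy * tmax : 0.0);
    double sz0 = oz + (dz < 0 ? dz * tmax : 0.0), sz1 = oz + (dz > 0 ? dz * tmax : 0.0);
    double best = R_PosInf;
    // gather candidates from the grid cells the segment's X-Z AABB overlaps
    if (sx1 < gx0 || sx0 > gx1 || sz1 < gz0 || sz0 > gz1) { out[i] = 0.0; continue; }
    int ix0 = std::max(0, std::min(ncx - 1, (int)((sx0 - gx0) / cell)));
    int ix1 = std::max(0, std::min(ncx - 1, (int)((sx1 - gx0) / cell)));
    int iz0 = std::max(0, std::min(ncz - 1, (int)((sz0 - gz0) / cell)));
    int iz1 = std::max(0, std::min(ncz - 1, (int)((sz1 - gz0) / cell)));
    touched.clear();
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iz = iz0; iz <= iz1; ++iz) {
        const std::vector<int>& cellv = grid[(size_t)ix * ncz + iz];
        for (size_t c = 0; c < cellv.size(); ++c) {
          int f = cellv[c];
          if (!seen[f]) { seen[f] = 1; touched.push_back(f); }
        }
      }
    for (size_t c = 0; c < touched.size(); ++c) {
      int f = touched[c];
      seen[f] = 0;
      if (hix[f] < sx0 || lox[f] > sx1 || hiy[f] < sy0 || loy[f] > sy1 ||
          hiz[f] < sz0 || loz[f] > sz1)
        continue;
      double e1x = bx[f] - ax[f], e1y = by[f] - ay[f], e1z = bz[f] - az[f];
      double e2x = cx[f] - ax[f], e2y = cy[f] - ay[f], e2z = cz[f] - az[f];
      // p = dir x e2
      double px = dy * e2z - dz * e2y;
      double py = dz * e2x - dx * e2z;
      double pz = dx * e2y - dy * e2x;
      double det = e1x * px + e1y * py + e1z * pz;
      // backface-only rule: require dot(dir, n) > 0 with n = e1 x e2;
      // det = e1 . (dir x e2) = dir . (e2 x e1) = -dot(dir, n), so keep det < 0.
      if (det >= -eps) continue;
      double inv = 1.0 / det;
      double tx = ox - ax[f], ty = oy - ay[f], tz = oz - az[f];
      double u = (tx * px + ty * py + tz * pz) * inv;
      if (u < -1e-9 || u > 1.0 + 1e-9) continue;
      // q = t x e1
      double qx = ty * e1z - tz * e1y;
      double qy = tz * e1x - tx * e1z;
      double qz = tx * e1y - ty * e1x;
      double v = (dx * qx + dy * qy + dz * qz) * inv;
      if (v < -1e-9 || u + v > 1.0 + 1e-9) continue;
      double t = (e2x * qx + e2y * qy + e2z * qz) * inv;
      if (t > tmin && t <= tmax && t < best) best = t;
    }
    out[i] = std::isfinite(best) ? best : 0.0;
  }
  return out;
}
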