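#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Triangulated isosurface area by marching tetrahedra.
//
// Each grid cell is split into six tetrahedra sharing the cell's main
// diagonal; within a tetrahedron the iso-crossing of the linearly
// interpolated field is a single triangle (one corner separated) or a
// quadrilateral (two corners separated), so no ambiguous configurations
// exist.  Vertices are placed by linear interpolation along tetrahedron
// edges and triangle areas are summed exactly from cross products.
//
// The grid is virtually padded by one layer of `pad` on every face so
// that a region touching the grid boundary still yields a closed surface.

static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
static const int CORNER[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export(name = ".mt_surface_area")]]
double mt_surface_area(NumericVector field, IntegerVector dim,
                       NumericVector spacing, double level, double pad) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double *v = field.begin();

  // value at padded node (i, j, k) with i in [-1, nx], etc.
  auto val = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return pad;
    return v[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };

  double area = 0.0;
  double cv[8];       // corner values
  double cp[8][3];    // corner positions (physical units)
  double px[4][3];    // interpolated polygon vertices

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        int above = 0;
        for (int c = 0; c < 8; ++c) {
          cv[c] = val(i + CORNER[c][0], j + CORNER[c][1], k + CORNER[c][2]);
          if (cv[c] >= level) ++above;  // inclusive: "at or above"
        }
        if (above == 0 || above == 8) continue;
        for (int c = 0; c < 8; ++c) {
          cp[c][0] = (i + CORNER[c][0]) * sx;
          cp[c][1] = (j + CORNER[c][1]) * sy;
          cp[c][2] = (k + CORNER[c][2]) * sz;
        }
        for (int t = 0; t < 6; ++t) {
          const int *tet = TETS[t];
          int in[4], ni = 0, no = 0, ins[4], outs[4];
          for (int a = 0; a < 4; ++a) {
            in[a] = cv[tet[a]] >= level;
            if (in[a]) ins[ni++] = a; else outs[no++] = a;
          }
          if (ni == 0 || ni == 4) continue;
          auto cross_pt = [&](int a, int b, double *out) {
            const double va = cv[tet[a]], vb = cv[tet[b]];
            const double tfrac = (level - va) / (vb - va);
            for (int d = 0; d < 3; ++d)
              out[d] = cp[tet[a]][d] + tfrac * (cp[tet[b]][d] - cp[tet[a]][d]);
          };
          auto tri_area = [&](const double *a, const double *b,
                              const double *c) -> double {
            double u[3], w[3], x[3];
            for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; w[d] = c[d] - a[d]; }
            x[0] = u[1] * w[2] - u[2] * w[1];
            x[1] = u[2] * w[0] - u[0] * w[2];
            x[2] = u[0] * w[1] - u[1] * w[0];
            return 0.5 * std::sqrt(x[0] * x[0] + x[1] * x[1] + x[2] * x[2]);
          };
          if (ni == 1 || ni == 3) {
            const int apex = (ni == 1) ? ins[0] : outs[0];
            const int *rest = (ni == 1) ? outs : ins;
            for (int a = 0; a < 3; ++a) cross_pt(apex, rest[a], px[a]);
            area += tri_area(px[0], px[1], px[2]);
          } else {  // ni == 2: quadrilateral a-c, a-d, b-d, b-c
            cross_pt(ins[0], outs[0], px[0]);
            cross_pt(ins[0], outs[1], px[1]);
            cross_pt(ins[1], outs[1], px[2]);
            cross_pt(ins[1], outs[0], px[3]);
            area += tri_area(px[0], px[1], px[2]);
            area += tri_area(px[0], px[2], px[3]);
          }
        }
      }
  return area;
}

// Exposed-face surface area of a binary mask: an included voxel face is
// exposed when its 6-neighbour along that axis is excluded or outside.
// [[Rcpp::export(name = ".voxel_face_area")]]
double voxel_face_area(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ax = sy * sz, ay = sx * sz, az = sx * sy;
  const int *m = mask.begin();

  auto inside = [&](int i, int j, int k) -> bool {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return false;
    return m[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] == TRUE;
  };

  double area = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!inside(i, j, k)) continue;
        if (!inside(i - 1, j, k)) area += ax;
        if (!inside(i + 1, j, k)) area += ax;
        if (!inside(i, j - 1, k)) area += ay;
        if (!inside(i, j + 1, k)) area += ay;
        if (!inside(i, j, k - 1)) area += az;
        if (!inside(i, j, k + 1)) area += az;
      }
  return area;
}

// Even-odd (crossing-number) point-in-polygon test over a set of planar
// polygons; a point on any polygon edge or vertex counts as inside.
// `polys` is a list of n x 2 coordinate matrices.
// [[Rcpp::export(name = ".points_in_polygons")]]
LogicalVector points_in_polygons(NumericMatrix pts, List polys, double eps) {
  const int np = pts.nrow();
  LogicalVector out(np);
  const int npoly = polys.size();
  std::vector<NumericMatrix> P;
  P.reserve(npoly);
  for (int q = 0; q < npoly; ++q) P.push_back(as<NumericMatrix>(polys[q]));

  for (int p = 0; p < np; ++p) {
    const double x = pts(p, 0), y = pts(p, 1);
    bool inside = false, boundary = false;
    for (int q = 0; q < npoly && !boundary; ++q) {
      const NumericMatrix &poly = P[q];
      const int nv = poly.nrow();
      bool odd = false;
      for (int a = 0, b = nv - 1; a < nv; b = a++) {
        const double x1 = poly(b, 0), y1 = poly(b, 1);
        const double x2 = poly(a, 0), y2 = poly(a, 1);
        // on-segment check
        const double dx = x2 - x1, dy = y2 - y1;
        const double len2 = dx * dx + dy * dy;
        if (len2 > 0) {
          const double t = ((x - x1) * dx + (y - y1) * dy) / len2;
          if (t >= 0 && t <= 1) {
            const double ex = x1 + t * dx - x, ey = y1 + t * dy - y;
            if (ex * ex + ey * ey <= eps * eps) { boundary = true; break; }
          }
        } else if ((x - x1) * (x - x1) + (y - y1) * (y - y1) <= eps * eps) {
          boundary = true; break;
        }
        if ((y1 > y) != (y2 > y)) {
          const double xint = x1 + (y - y1) / (y2 - y1) * (x2 - x1);
          if (x < xint) odd = !odd;
        }
      }
      if (odd) inside = !inside;  // even-odd parity across polygons
    }
    out[p] = boundary || inside;
  }
  return out;
}
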