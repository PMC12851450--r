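#include <Rcpp.h>
#include <vector>
#include <array>
#include <cstdint>

using namespace Rcpp;

// Volume of the 3D convex hull of integer points (voxel centers), by
// incremental construction.  Orientation predicates use 64-bit integer
// arithmetic and are exact for coordinates |x| <= ~10^5, far beyond any
// lattice used here.  Degenerate inputs (fewer than 4 affinely independent
// points: single point, colinear, coplanar) have volume 0.

typedef std::array<int64_t, 3> P3;

static inline int64_t det3(const P3 &a, const P3 &b, const P3 &c) {
  return a[0] * (b[1] * c[2] - b[2] * c[1])
       - a[1] * (b[0] * c[2] - b[2] * c[0])
       + a[2] * (b[0] * c[1] - b[1] * c[0]);
}

// signed volume (x6) of tetrahedron (a,b,c,d)
static inline int64_t orient(const P3 &a, const P3 &b, const P3 &c, const P3 &d) {
  const P3 ab = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  const P3 ac = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  const P3 ad = {d[0] - a[0], d[1] - a[1], d[2] - a[2]};
  return det3(ab, ac, ad);
}

struct Face { int a, b, c; };

// [[Rcpp::export]]
double convex_hull_volume_cpp(IntegerMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<P3> p(n);
  for (int i = 0; i < n; ++i)
    p[i] = {(int64_t)pts(i, 0), (int64_t)pts(i, 1), (int64_t)pts(i, 2)};

  // initial tetrahedron: four affinely independent points
  int i1 = -1, i2 = -1, i3 = -1;
  for (int i = 1; i < n && i1 < 0; ++i)
    if (p[i] != p[0]) i1 = i;
  if (i1 < 0) return 0.0;
  for (int i = i1 + 1; i < n && i2 < 0; ++i) {
    const P3 u = {p[i1][0] - p[0][0], p[i1][1] - p[0][1], p[i1][2] - p[0][2]};
    const P3 v = {p[i][0] - p[0][0], p[i][1] - p[0][1], p[i][2] - p[0][2]};
    const int64_t cx = u[1] * v[2] - u[2] * v[1];
    const int64_t cy = u[2] * v[0] - u[0] * v[2];
    const int64_t cz = u[0] * v[1] - u[1] * v[0];
    if (cx != 0 || cy != 0 || cz != 0) i2 = i;
  }
  if (i2 < 0) return 0.0;
  for (int i = 0; i < n && i3 < 0; ++i)
    if (orient(p[0], p[i1], p[i2], p[i]) != 0) i3 = i;
  if (i3 < 0) return 0.0;  // coplanar set

  // interior reference point, scaled by 4 to stay integer
  const P3 q4 = {p[0][0] + p[i1][0] + p[i2][0] + p[i3][0],
                 p[0][1] + p[i1][1] + p[i2][1] + p[i3][1],
                 p[0][2] + p[i1][2] + p[i2][2] + p[i3][2]};
  // orientation test against the scaled interior point: sign of
  // orient(4a, 4b, 4c, q4) equals sign of orient(a, b, c, centroid)
  std::vector<P3> p4(n);
  for (int i = 0; i < n; ++i) p4[i] = {4 * p[i][0], 4 * p[i][1], 4 * p[i][2]};
  auto interior_below = [&](int a, int b, int c) {
    return orient(p4[a], p4[b], p4[c], q4) < 0;
  };

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    if (interior_below(a, b, c)) faces.push_back({a, b, c});
    else faces.push_back({a, c, b});
  };
  add_face(0, i1, i2);
  add_face(0, i1, i3);
  add_face(0, i2, i3);
  add_face(i1, i2, i3);

  std::vector<char> visible;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || i == i1 || i == i2 || i == i3) continue;
    visible.assign(faces.size(), 0);
    bool any = false;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (orient(p[faces[f].a], p[faces[f].b], p[faces[f].c], p[i]) > 0) {
        visible[f] = 1;
        any = true;
      }
    }
    if (!any) continue;  // inside or on the current hull
    // horizon: directed edges of visible faces whose reverse is not in a
    // visible face
    std::vector<std::pair<int, int>> edges;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!visible[f]) continue;
      edges.push_back({faces[f].a, faces[f].b});
      edges.push_back({faces[f].b, faces[f].c});
      edges.push_back({faces[f].c, faces[f].a});
    }
    std::vector<Face> kept;
    for (size_t f = 0; f < faces.size(); ++f)
      if (!visible[f]) kept.push_back(faces[f]);
    for (const auto &e : edges) {
      bool reversed_visible = false;
      for (const auto &e2 : edges)
        if (e2.first == e.second && e2.second == e.first) {
          reversed_visible = true;
          break;
        }
      if (!reversed_visible) {
        // horizon edge: new face from edge to p[i], oriented outward
        if (interior_below(e.first, e.second, i))
          kept.push_back({e.first, e.second, i});
        else
          kept.push_back({e.second, e.first, i});
      }
    }
    faces.swap(kept);
  }

  // closed outward-oriented surface: 6V = sum of det(a, b, c)
  long double vol6 = 0.0L;
  for (const auto &f : faces)
    vol6 += (long double)det3(p[f.a], p[f.b], p[f.c]);
  if (vol6 < 0) vol6 = -vol6;
  return (double)(vol6 / 6.0L);
}
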