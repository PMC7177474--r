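#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <utility>
#include <map>

using namespace Rcpp;

// Incremental 3-D convex hull returning volume and surface area only.
// Points far fewer than 10^3 are expected (loop heavy atoms), so the simple
// O(n * f) visibility scan per insertion is plenty fast.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;    // vertex indices, outward-oriented
  Vec3 n;         // non-unit outward normal
  bool alive;
};

inline Vec3 faceNormal(const std::vector<Vec3> &P, int a, int b, int c) {
  return cross(sub(P[b], P[a]), sub(P[c], P[a]));
}

} // namespace

// [[Rcpp::export(name = ".hull_volume_area")]]
List hull_volume_area(NumericMatrix pts) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) stop("points must be an n x 3 matrix");
  if (n < 4) stop("need at least 4 points for a 3-D hull");

  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  if (scale == 0.0) scale = 1.0;
  const double eps = 1e-10 * scale;

  // initial simplex: two farthest-in-x points, then max-area, then max-volume
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  double best = -1.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = norm(sub(P[i], P[j]));
      if (d > best) { best = d; i0 = i; i1 = j; }
    }
  if (best <= eps) // all points coincide
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["degenerate"] = true);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double a2 = norm(cross(sub(P[i], P[i0]), sub(P[i1], P[i0])));
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= eps * scale) // collinear
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["degenerate"] = true);
  Vec3 n0 = faceNormal(P, i0, i1, i2);
  best = -1.0;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2) continue;
    double v = std::fabs(dot(n0, sub(P[i], P[i0])));
    if (v > best) { best = v; i3 = i; }
  }
  if (i3 < 0 || best <= eps * scale * scale) // coplanar
    return List::create(_["volume"] = 0.0, _["area"] = 0.0,
                        _["degenerate"] = true);

  Vec3 interior = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                   (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                   (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<Face> faces;
  auto addFace = [&](int a, int b, int c) {
    Vec3 nn = faceNormal(P, a, b, c);
    if (dot(nn, sub(interior, P[a])) > 0) { std::swap(b, c); nn = faceNormal(P, a, b, c); }
    faces.push_back({a, b, c, nn, true});
  };
  addFace(i0, i1, i2);
  addFace(i0, i1, i3);
  addFace(i0, i2, i3);
  addFace(i1, i2, i3);

  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    // visible faces
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!faces[f].alive) continue;
      double nl = norm(faces[f].n);
      if (nl <= 0) continue;
      if (dot(faces[f].n, sub(P[p], P[faces[f].a])) / nl > eps)
        visible.push_back((int)f);
    }
    if (visible.empty()) continue;
    // horizon = edges used exactly once among visible faces
    std::map<std::pair<int, int>, int> edgeCount;
    std::map<std::pair<int, int>, std::pair<int, int>> edgeDir;
    for (int fi : visible) {
      const Face &f = faces[fi];
      int vs[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (auto &e : vs) {
        std::pair<int, int> key(std::min(e[0], e[1]), std::max(e[0], e[1]));
        edgeCount[key]++;
        edgeDir[key] = {e[0], e[1]};
      }
      faces[fi].alive = false;
    }
    for (auto &kv : edgeCount) {
      if (kv.second != 1) continue;
      auto dir = edgeDir[kv.first];
      addFace(dir.first, dir.second, p);
    }
  }

  double vol = 0.0, area = 0.0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    double a2 = norm(f.n);
    area += 0.5 * a2;
    // signed tetra volume w.r.t. interior point; outward normals => positive
    Vec3 d = sub(P[f.a], interior);
    vol += dot(f.n, d) / 6.0;
  }
  return List::create(_["volume"] = vol, _["area"] = area,
                      _["degenerate"] = false);
}
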