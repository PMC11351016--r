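#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

// Incremental Bowyer-Watson Delaunay triangulation in 3-D.
// Double precision with long-double predicates; callers are expected to
// jitter degenerate (coplanar / cospherical) inputs before calling.

namespace {

typedef long double ld;

struct Tet {
  int v[4];      // vertex indices, oriented so orient3d > 0
  bool alive;
};

// signed volume predicate: > 0 when d is on the positive side of (a,b,c)
ld orient3d(const ld *a, const ld *b, const ld *c, const ld *d) {
  ld adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  ld bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  ld cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy)
       - ady * (bdx * cdz - bdz * cdx)
       + adz * (bdx * cdy - bdy * cdx);
}

// insphere predicate: > 0 when e lies inside the circumsphere of the
// positively oriented tetrahedron (a,b,c,d)
ld insphere(const ld *a, const ld *b, const ld *c, const ld *d, const ld *e) {
  ld ae[4], be[4], ce[4], de[4];
  const ld *p[4] = { a, b, c, d };
  ld *q[4] = { ae, be, ce, de };
  for (int i = 0; i < 4; ++i) {
    ld dx = p[i][0] - e[0], dy = p[i][1] - e[1], dz = p[i][2] - e[2];
    q[i][0] = dx; q[i][1] = dy; q[i][2] = dz;
    q[i][3] = dx * dx + dy * dy + dz * dz;
  }
  // 4x4 determinant expansion along the last column
  ld det = 0;
  ld *m[4] = { ae, be, ce, de };
  for (int i = 0; i < 4; ++i) {
    int r[3], k = 0;
    for (int j = 0; j < 4; ++j) if (j != i) r[k++] = j;
    ld minor =
        m[r[0]][0] * (m[r[1]][1] * m[r[2]][2] - m[r[1]][2] * m[r[2]][1])
      - m[r[0]][1] * (m[r[1]][0] * m[r[2]][2] - m[r[1]][2] * m[r[2]][0])
      + m[r[0]][2] * (m[r[1]][0] * m[r[2]][1] - m[r[1]][1] * m[r[2]][0]);
    ld sign = ((i % 2) == 0) ? 1.0L : -1.0L;
    det += sign * m[i][3] * minor;
  }
  // det as expanded corresponds to -insphere for positive orientation
  return -det;
}

struct Face {
  int a, b, c;   // sorted vertex indices
  bool operator<(const Face &o) const {
    if (a != o.a) return a < o.a;
    if (b != o.b) return b < o.b;
    return c < o.c;
  }
  bool operator==(const Face &o) const {
    return a == o.a && b == o.b && c == o.c;
  }
};

} // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
Rcpp::List delaunay3d_cpp(Rcpp::NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) Rcpp::stop("need at least 4 points for 3-D Delaunay");

  // copy coordinates, appending 4 super-tetra vertices
  std::vector<std::array<ld, 3> > P(n + 4);
  ld lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = 1e300L; hi[d] = -1e300L; }
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      ld v = (ld)pts(i, d);
      P[i][d] = v;
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  ld cx = (lo[0] + hi[0]) / 2, cy = (lo[1] + hi[1]) / 2, cz = (lo[2] + hi[2]) / 2;
  ld span = 0;
  for (int d = 0; d < 3; ++d) span = std::max(span, hi[d] - lo[d]);
  if (span <= 0) span = 1;
  ld R = 100 * span;
  int s0 = n, s1 = n + 1, s2 = n + 2, s3 = n + 3;
  P[s0] = { cx - 3 * R, cy - R,     cz - R };
  P[s1] = { cx + 3 * R, cy - R,     cz - R };
  P[s2] = { cx,         cy + 3 * R, cz - R };
  P[s3] = { cx,         cy,         cz + 3 * R };

  std::vector<Tet> tets;
  {
    Tet t; t.alive = true;
    t.v[0] = s0; t.v[1] = s1; t.v[2] = s2; t.v[3] = s3;
    if (orient3d(P[s0].data(), P[s1].data(), P[s2].data(), P[s3].data()) < 0)
      std::swap(t.v[0], t.v[1]);
    tets.push_back(t);
  }

  bool degenerate = false;
  ld eps_vol = (ld)1e-10 * span * span * span;

  for (int ip = 0; ip < n; ++ip) {
    const ld *p = P[ip].data();
    // find all alive tets whose circumsphere contains p
    std::vector<int> bad;
    for (size_t it = 0; it < tets.size(); ++it) {
      if (!tets[it].alive) continue;
      const Tet &t = tets[it];
      ld s = insphere(P[t.v[0]].data(), P[t.v[1]].data(),
                      P[t.v[2]].data(), P[t.v[3]].data(), p);
      if (s > 0) bad.push_back((int)it);
      else if (std::fabs((double)s) < (double)(eps_vol * span * span))
        degenerate = true;
    }
    if (bad.empty()) { degenerate = true; continue; }

    // cavity boundary: faces of bad tets seen exactly once
    std::vector<std::pair<Face, std::array<int, 3> > > faces; // sorted + oriented
    for (size_t k = 0; k < bad.size(); ++k) {
      Tet &t = tets[bad[k]];
      t.alive = false;
      static const int fidx[4][3] = { {1,2,3}, {0,3,2}, {0,1,3}, {0,2,1} };
      for (int f = 0; f < 4; ++f) {
        std::array<int, 3> ov = { t.v[fidx[f][0]], t.v[fidx[f][1]], t.v[fidx[f][2]] };
        Face fc;
        int a = ov[0], b = ov[1], c = ov[2];
        if (a > b) std::swap(a, b);
        if (b > c) std::swap(b, c);
        if (a > b) std::swap(a, b);
        fc.a = a; fc.b = b; fc.c = c;
        // count occurrences; internal faces appear twice
        bool dup = false;
        for (size_t q = 0; q < faces.size(); ++q) {
          if (faces[q].first == fc) {
            faces.erase(faces.begin() + q);
            dup = true;
            break;
          }
        }
        if (!dup) faces.push_back(std::make_pair(fc, ov));
      }
    }

    // retriangulate the cavity
    for (size_t q = 0; q < faces.size(); ++q) {
      const std::array<int, 3> &ov = faces[q].second;
      Tet t; t.alive = true;
      t.v[0] = ov[0]; t.v[1] = ov[1]; t.v[2] = ov[2]; t.v[3] = ip;
      ld vol = orient3d(P[t.v[0]].data(), P[t.v[1]].data(),
                        P[t.v[2]].data(), P[t.v[3]].data());
      if (std::fabs((double)vol) < (double)eps_vol) degenerate = true;
      if (vol < 0) std::swap(t.v[0], t.v[1]);
      tets.push_back(t);
    }
  }

  // collect tets not touching the super vertices
  std::vector<std::array<int, 4> > out;
  for (size_t it = 0; it < tets.size(); ++it) {
    if (!tets[it].alive) continue;
    const Tet &t = tets[it];
    bool super = false;
    for (int k = 0; k < 4; ++k) if (t.v[k] >= n) super = true;
    if (super) continue;
    std::array<int, 4> v = { t.v[0], t.v[1], t.v[2], t.v[3] };
    std::sort(v.begin(), v.end());
    out.push_back(v);
  }

  Rcpp::IntegerMatrix tm(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i)
    for (int k = 0; k < 4; ++k)
      tm(i, k) = out[i][k] + 1; // 1-based for R
  return Rcpp::List::create(Rcpp::Named("tetrahedra") = tm,
                            Rcpp::Named("degenerate") = degenerate);
}
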