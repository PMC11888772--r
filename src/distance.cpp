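#include <Rcpp.h>
using namespace Rcpp;

// Closest point on triangle (a, b, c) to point p, via the Voronoi-region
// walk of Ericson's "Real-Time Collision Detection" (ch. 5). Returns the
// squared distance. Degenerate (zero-area) triangles fall through to the
// edge/vertex cases, so no special handling is needed.
static double sq_dist_point_triangle(const double *p, const double *a,
                                     const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    return ap[0] * ap[0] + ap[1] * ap[1] + ap[2] * ap[2];
  }

  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    return bp[0] * bp[0] + bp[1] * bp[1] + bp[2] * bp[2];
  }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    double dx[3];
    for (int i = 0; i < 3; ++i) dx[i] = ap[i] - v * ab[i];
    return dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
  }

  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    return cp[0] * cp[0] + cp[1] * cp[1] + cp[2] * cp[2];
  }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    double dx[3];
    for (int i = 0; i < 3; ++i) dx[i] = ap[i] - w * ac[i];
    return dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double dx[3];
    for (int i = 0; i < 3; ++i) dx[i] = bp[i] - w * (c[i] - b[i]);
    return dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double dx[3];
  for (int i = 0; i < 3; ++i) dx[i] = ap[i] - v * ab[i] - w * ac[i];
  return dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2];
}

// Minimum Euclidean distance from each query point to a triangulated
// surface. `faces` is 0-based. Brute force over triangles; adequate for the
// mesh sizes this package targets (<= a few thousand triangles).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points, NumericMatrix vertices,
                                      IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);
  std::vector<double> P(3), A(3), B(3), C(3);
  for (int i = 0; i < np; ++i) {
    P[0] = points(i, 0); P[1] = points(i, 1); P[2] = points(i, 2);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      int ia = faces(f, 0), ib = faces(f, 1), ic = faces(f, 2);
      A[0] = vertices(ia, 0); A[1] = vertices(ia, 1); A[2] = vertices(ia, 2);
      B[0] = vertices(ib, 0); B[1] = vertices(ib, 1); B[2] = vertices(ib, 2);
      C[0] = vertices(ic, 0); C[1] = vertices(ic, 1); C[2] = vertices(ic, 2);
      double d2 = sq_dist_point_triangle(P.data(), A.data(), B.data(), C.data());
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
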