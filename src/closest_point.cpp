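#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a single triangle (a,b,c) to p, after Ericson,
// "Real-Time Collision Detection", ch. 5.1.5. Works for degenerate-free
// triangles; returns squared distance and writes the foot point into out.
static double closestOnTriangle(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) out[i] = a[i];
  } else {
    double bp[3], cp[3];
    for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) out[i] = b[i];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
      } else {
        for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) out[i] = c[i];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i)
                out[i] = b[i] + w*(c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i)
                out[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

// [[Rcpp::export]]
List closest_points_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int nv = V.nrow(), nf = F.nrow(), nq = Q.nrow();
  // column-major copies into contiguous xyz triplets
  std::vector<double> vv(3 * nv), qq(3 * nq);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) vv[3*i + j] = V(i, j);
  for (int i = 0; i < nq; ++i)
    for (int j = 0; j < 3; ++j) qq[3*i + j] = Q(i, j);

  NumericMatrix P(nq, 3);
  IntegerVector tri(nq);
  NumericVector dist(nq);
  double foot[3], best[3];
  for (int q = 0; q < nq; ++q) {
    double bestD = R_PosInf;
    int bestT = -1;
    const double *p = &qq[3*q];
    for (int t = 0; t < nf; ++t) {
      const double *a = &vv[3*F(t,0)];
      const double *b = &vv[3*F(t,1)];
      const double *c = &vv[3*F(t,2)];
      double d = closestOnTriangle(p, a, b, c, foot);
      if (d < bestD) {        // strict: ties keep the lowest triangle index
        bestD = d;
        bestT = t;
        best[0] = foot[0]; best[1] = foot[1]; best[2] = foot[2];
      }
    }
    P(q,0) = best[0]; P(q,1) = best[1]; P(q,2) = best[2];
    tri[q] = bestT;
    dist[q] = std::sqrt(bestD);
  }
  return List::create(_["point"] = P, _["triangle"] = tri, _["distance"] = dist);
}
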