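#include <Rcpp.h>
using namespace Rcpp;

// Signed area of a simple polygon (shoelace). Positive when CCW.
// [[Rcpp::export]]
double polygon_signed_area(NumericMatrix p) {
  int n = p.nrow();
  if (n < 3) return 0.0;
  double a = 0.0;
  for (int i = 0, j = n - 1; i < n; j = i++)
    a += p(j, 0) * p(i, 1) - p(i, 0) * p(j, 1);
  return 0.5 * a;
}

// Sutherland-Hodgman clipping of a subject polygon against a CONVEX clip
// polygon. Both are matrices of (x, y) vertices; the clip polygon must be
// counter-clockwise. Returns the clipped polygon (possibly 0 rows).
// [[Rcpp::export]]
NumericMatrix clip_polygon_convex(NumericMatrix subject, NumericMatrix clip) {
  int nc = clip.nrow();
  std::vector<double> inx, iny, outx, outy;
  for (int i = 0; i < subject.nrow(); ++i) {
    inx.push_back(subject(i, 0));
    iny.push_back(subject(i, 1));
  }
  for (int e = 0; e < nc && !inx.empty(); ++e) {
    double ax = clip(e, 0), ay = clip(e, 1);
    double bx = clip((e + 1) % nc, 0), by = clip((e + 1) % nc, 1);
    double ex = bx - ax, ey = by - ay;
    outx.clear(); outy.clear();
    int n = inx.size();
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double c1 = ex * (iny[i] - ay) - ey * (inx[i] - ax); // >=0: inside (left)
      double c2 = ex * (iny[j] - ay) - ey * (inx[j] - ax);
      bool in1 = c1 >= 0.0, in2 = c2 >= 0.0;
      if (in1) { outx.push_back(inx[i]); outy.push_back(iny[i]); }
      if (in1 != in2) {
        double t = c1 / (c1 - c2);
        outx.push_back(inx[i] + t * (inx[j] - inx[i]));
        outy.push_back(iny[i] + t * (iny[j] - iny[i]));
      }
    }
    inx.swap(outx); iny.swap(outy);
  }
  NumericMatrix res(inx.size(), 2);
  for (size_t i = 0; i < inx.size(); ++i) {
    res(i, 0) = inx[i]; res(i, 1) = iny[i];
  }
  return res;
}

// Area of the intersection of a simple subject polygon with a convex,
// counter-clockwise clip polygon.
// [[Rcpp::export]]
double clipped_area(NumericMatrix subject, NumericMatrix clip) {
  NumericMatrix inter = clip_polygon_convex(subject, clip);
  if (inter.nrow() < 3) return 0.0;
  return std::fabs(polygon_signed_area(inter));
}
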