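#include <Rcpp.h>
using namespace Rcpp;

// Hough circle accumulator. Edge pixels vote for every candidate centre at
// distance r; offsets are deduplicated per radius so one edge pixel
// contributes at most one vote per centre cell, making the peak count an
// estimate of the number of supporting edge pixels.
//
// edge_x, edge_y: 0-based pixel coordinates of edge points.
// Returns an integer array [height, width, n_radii] of vote counts.
// [[Rcpp::export]]
IntegerVector hough_accumulate_cpp(IntegerVector edge_x, IntegerVector edge_y,
                                   int width, int height,
                                   IntegerVector radii) {
  const int nr = radii.size();
  IntegerVector acc(height * width * nr);
  acc.attr("dim") = IntegerVector::create(height, width, nr);
  const int ne = edge_x.size();

  for (int ri = 0; ri < nr; ++ri) {
    const int r = radii[ri];
    const int side = 2 * r + 1;
    // Rasterize unique integer offsets on the circle of radius r.
    std::vector<char> seen(side * side, 0);
    std::vector<int> dx, dy;
    const int nth = (int)std::ceil(2.0 * M_PI * r) + 1;
    for (int t = 0; t < nth; ++t) {
      const double th = 2.0 * M_PI * t / nth;
      const int ox = (int)std::lround(r * std::cos(th));
      const int oy = (int)std::lround(r * std::sin(th));
      const int key = (oy + r) * side + (ox + r);
      if (!seen[key]) {
        seen[key] = 1;
        dx.push_back(ox);
        dy.push_back(oy);
      }
    }
    const int no = dx.size();
    int *slab = INTEGER(acc) + (R_xlen_t)ri * height * width;
    for (int e = 0; e < ne; ++e) {
      const int ex = edge_x[e], ey = edge_y[e];
      for (int o = 0; o < no; ++o) {
        const int cx = ex - dx[o];
        const int cy = ey - dy[o];
        if (cx >= 0 && cx < width && cy >= 0 && cy < height)
          slab[(R_xlen_t)cx * height + cy] += 1;
      }
    }
  }
  return acc;
}
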