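#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Grayscale erosion (op = 0) or dilation (op = 1) with a disk structuring
// element of the given radius. Border pixels use the in-bounds part of the
// neighbourhood. EBImage's morphology is binary, so the grayscale variant
// needed by the white top-hat lives here.
// [[Rcpp::export(name = ".gray_morph_cpp")]]
NumericMatrix gray_morph_cpp(NumericMatrix img, double radius, int op) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> offr, offc;
  const double r2 = radius * radius;
  for (int dy = -r; dy <= r; ++dy) {
    for (int dx = -r; dx <= r; ++dx) {
      if ((double)dy * dy + (double)dx * dx <= r2) {
        offr.push_back(dy);
        offc.push_back(dx);
      }
    }
  }
  const int K = offr.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = img(i, j);
      for (int k = 0; k < K; ++k) {
        int ii = i + offr[k], jj = j + offc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj);
        if (op == 0) { if (v < acc) acc = v; }
        else { if (v > acc) acc = v; }
      }
      out(i, j) = acc;
    }
  }
  return out;
}
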