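#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample of img at (row = y, col = x), 1-based doubles.
// Out-of-bounds -> value 0, valid flag false.
static inline double sample_bilinear(const NumericMatrix &img, double y, double x,
                                     bool &valid) {
  int H = img.nrow(), W = img.ncol();
  if (y < 1.0 || y > (double)H || x < 1.0 || x > (double)W) {
    valid = false;
    return 0.0;
  }
  valid = true;
  int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (y0 > H - 1) y0 = H - 1;
  if (x0 > W - 1) x0 = W - 1;
  double fy = y - y0, fx = x - x0;
  double v00 = img(y0 - 1, x0 - 1);
  double v10 = img(y0, x0 - 1);
  double v01 = img(y0 - 1, x0);
  double v11 = img(y0, x0);
  return (1 - fy) * (1 - fx) * v00 + fy * (1 - fx) * v10 +
         (1 - fy) * fx * v01 + fy * fx * v11;
}

// Warp an image under a centred similarity transform composed with an optional
// per-pixel displacement field: for each output pixel p = (x, y),
//   q = p + u(p);  src = s * R(theta) * (q - c) + c + (tx, ty)
// where c is the image centre. Angles in degrees. ux/uy may be 0x0 matrices.
// [[Rcpp::export]]
List warp_image_cpp(NumericMatrix img, double tx, double ty, double theta_deg,
                    double s, NumericMatrix ux, NumericMatrix uy) {
  int H = img.nrow(), W = img.ncol();
  bool has_field = ux.nrow() == H && ux.ncol() == W;
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th) * s, st = std::sin(th) * s;
  double cx = (W + 1) / 2.0, cy = (H + 1) / 2.0;
  NumericMatrix out(H, W);
  LogicalMatrix valid(H, W);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double x = j + 1.0, y = i + 1.0;
      if (has_field) {
        x += ux(i, j);
        y += uy(i, j);
      }
      double dx = x - cx, dy = y - cy;
      double sx = ct * dx - st * dy + cx + tx;
      double sy = st * dx + ct * dy + cy + ty;
      bool ok;
      out(i, j) = sample_bilinear(img, sy, sx, ok);
      valid(i, j) = ok;
    }
  }
  return List::create(_["image"] = out, _["valid"] = valid);
}

// Mean squared difference between ref and img warped by the similarity
// transform, over pixels that land inside img, evaluated on every
// `stride`-th pixel in each dimension. Returns (mse, n_valid).
// [[Rcpp::export]]
NumericVector warp_mse_cpp(NumericMatrix img, NumericMatrix ref, double tx,
                           double ty, double theta_deg, double s,
                           int stride = 1) {
  int H = img.nrow(), W = img.ncol();
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th) * s, st = std::sin(th) * s;
  double cx = (W + 1) / 2.0, cy = (H + 1) / 2.0;
  double acc = 0.0;
  long n = 0;
  for (int j = 0; j < W; j += stride) {
    for (int i = 0; i < H; i += stride) {
      double dx = j + 1.0 - cx, dy = i + 1.0 - cy;
      double sx = ct * dx - st * dy + cx + tx;
      double sy = st * dx + ct * dy + cy + ty;
      bool ok;
      double v = sample_bilinear(img, sy, sx, ok);
      if (ok) {
        double d = v - ref(i, j);
        acc += d * d;
        ++n;
      }
    }
  }
  return NumericVector::create(n > 0 ? acc / n : R_PosInf, (double)n);
}
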