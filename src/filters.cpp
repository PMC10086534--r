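#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Separable Gaussian convolution with replicate (clamp-to-edge) boundaries.
// Kernel truncated at 3*sigma and renormalized, so a constant image is an
// exact fixed point regardless of sigma.
// [[Rcpp::export]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) stop("sigma must be > 0");
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    double w = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    k[i + radius] = w;
    s += w;
  }
  for (double &w : k) w /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double *kp = k.data();
  const int klen = 2 * radius + 1;
  std::vector<double> buf;

  // vertical pass (contiguous within each column), edge-padded buffer
  buf.assign(nr + 2 * radius, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double *src = &img[(size_t)j * nr];
    for (int d = 0; d < radius; ++d) buf[d] = src[0];
    std::copy(src, src + nr, buf.begin() + radius);
    for (int d = 0; d < radius; ++d) buf[nr + radius + d] = src[nr - 1];
    double *dst = &tmp[(size_t)j * nr];
    for (int i = 0; i < nr; ++i) {
      const double *b = &buf[i];
      double acc = 0.0;
      for (int d = 0; d < klen; ++d) acc += kp[d] * b[d];
      dst[i] = acc;
    }
  }
  // horizontal pass: gather each row into a padded buffer
  buf.assign(nc + 2 * radius, 0.0);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[radius + j] = tmp[(size_t)j * nr + i];
    for (int d = 0; d < radius; ++d) {
      buf[d] = buf[radius];
      buf[nc + radius + d] = buf[nc + radius - 1];
    }
    for (int j = 0; j < nc; ++j) {
      const double *b = &buf[j];
      double acc = 0.0;
      for (int d = 0; d < klen; ++d) acc += kp[d] * b[d];
      out[(size_t)j * nr + i] = acc;
    }
  }
  return out;
}

// One pass of binary dilation with a full 3x3 structuring element;
// pixels outside the image are background.
// [[Rcpp::export]]
LogicalMatrix dilate3x3_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      bool v = false;
      for (int dj = -1; dj <= 1 && !v; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          if (m(ii, jj)) { v = true; break; }
        }
      }
      out(i, j) = v;
    }
  }
  return out;
}

// 3x3 median on a binary mask = majority vote over the 9-cell neighborhood;
// out-of-bounds cells count as background (matches rank filtering on a
// zero-padded 8-bit mask).
// [[Rcpp::export]]
LogicalMatrix median3x3_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int on = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          if (m(ii, jj)) ++on;
        }
      }
      out(i, j) = (on >= 5);
    }
  }
  return out;
}

// Fill interior holes: background connected to the image border by
// 4-connectivity stays background, everything else becomes foreground.
// [[Rcpp::export]]
LogicalMatrix fill_holes_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  stack.reserve((size_t)nr * nc / 4);
  auto push = [&](int i, int j) {
    size_t idx = (size_t)j * nr + i;
    if (!outside[idx] && !m(i, j)) { outside[idx] = 1; stack.push_back((int)idx); }
  };
  for (int i = 0; i < nr; ++i) { push(i, 0); push(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push(0, j); push(nr - 1, j); }
  while (!stack.empty()) {
    int idx = stack.back(); stack.pop_back();
    int i = idx % nr, j = idx / nr;
    if (i > 0) push(i - 1, j);
    if (i < nr - 1) push(i + 1, j);
    if (j > 0) push(i, j - 1);
    if (j < nc - 1) push(i, j + 1);
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = m(i, j) || !outside[(size_t)j * nr + i];
  return out;
}

// Per-point neighbor counts within Euclidean radius (self excluded).
// [[Rcpp::export]]
IntegerVector neighbor_counts_cpp(NumericVector row, NumericVector col, double radius) {
  const int n = row.size();
  IntegerVector out(n);
  const double r2 = radius * radius;
  for (int a = 0; a < n; ++a) {
    int cnt = 0;
    for (int b = 0; b < n; ++b) {
      if (a == b) continue;
      double dr = row[a] - row[b], dc = col[a] - col[b];
      if (dr * dr + dc * dc <= r2) ++cnt;
    }
    out[a] = cnt;
  }
  return out;
}
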