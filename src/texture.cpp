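// Gray-level texture matrix construction for 2D discretised images.
// Images arrive as integer matrices with levels 1..ng; feature formulas are
// evaluated in R from the matrices returned here.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// The four 2D offsets used for co-occurrence and run-length analysis
// (0, 45, 90, 135 degrees at distance 1); symmetric counting.
static const int OFF[4][2] = {{0, 1}, {-1, 1}, {-1, 0}, {-1, -1}};

// [[Rcpp::export]]
NumericVector cpp_glcm(const IntegerMatrix& img, int ng) {
  int h = img.nrow(), w = img.ncol();
  NumericVector out(static_cast<R_xlen_t>(ng) * ng * 4);
  out.attr("dim") = IntegerVector::create(ng, ng, 4);
  for (int a = 0; a < 4; ++a) {
    int dr = OFF[a][0], dc = OFF[a][1];
    for (int r = 0; r < h; ++r) {
      int r2 = r + dr;
      if (r2 < 0 || r2 >= h) continue;
      for (int c = 0; c < w; ++c) {
        int c2 = c + dc;
        if (c2 < 0 || c2 >= w) continue;
        int i = img(r, c) - 1, j = img(r2, c2) - 1;
        // symmetric: count the pair in both orders
        out[a * ng * ng + j * ng + i] += 1.0;
        out[a * ng * ng + i * ng + j] += 1.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(const IntegerMatrix& img, int ng) {
  int h = img.nrow(), w = img.ncol();
  int maxrun = std::max(h, w);
  NumericVector out(static_cast<R_xlen_t>(ng) * maxrun * 4);
  out.attr("dim") = IntegerVector::create(ng, maxrun, 4);
  // walk each direction's maximal runs; directions as in OFF but traversed
  // forward: horizontal, diag up-right, vertical, diag up-left
  for (int a = 0; a < 4; ++a) {
    int dr = -OFF[a][0], dc = OFF[a][1]; // travel down/right variants
    // collect all starting points: cells with no predecessor along (dr,dc)
    for (int r = 0; r < h; ++r) {
      for (int c = 0; c < w; ++c) {
        int pr = r - dr, pc = c - dc;
        if (pr >= 0 && pr < h && pc >= 0 && pc < w) continue; // not a start
        int run = 0, g = -1;
        int cr = r, cc = c;
        while (cr >= 0 && cr < h && cc >= 0 && cc < w) {
          int gi = img(cr, cc);
          if (gi == g) {
            ++run;
          } else {
            if (g > 0) out[a * ng * maxrun + (run - 1) * ng + (g - 1)] += 1.0;
            g = gi;
            run = 1;
          }
          cr += dr; cc += dc;
        }
        if (g > 0) out[a * ng * maxrun + (run - 1) * ng + (g - 1)] += 1.0;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_glszm(const IntegerMatrix& img, int ng) {
  int h = img.nrow(), w = img.ncol();
  std::vector<char> seen(static_cast<size_t>(h) * w, 0);
  std::vector<int> zg, zs; // zone gray level and size
  std::vector<int> stack;
  for (int r0 = 0; r0 < h; ++r0) {
    for (int c0 = 0; c0 < w; ++c0) {
      size_t id0 = static_cast<size_t>(c0) * h + r0;
      if (seen[id0]) continue;
      int g = img(r0, c0);
      int size = 0;
      stack.clear();
      stack.push_back(static_cast<int>(id0));
      seen[id0] = 1;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        ++size;
        int c = id / h, r = id % h;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int r2 = r + dr, c2 = c + dc;
            if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
            size_t id2 = static_cast<size_t>(c2) * h + r2;
            if (!seen[id2] && img(r2, c2) == g) {
              seen[id2] = 1;
              stack.push_back(static_cast<int>(id2));
            }
          }
        }
      }
      zg.push_back(g);
      zs.push_back(size);
    }
  }
  int maxsize = 0;
  for (size_t k = 0; k < zs.size(); ++k) maxsize = std::max(maxsize, zs[k]);
  NumericMatrix out(ng, maxsize);
  for (size_t k = 0; k < zs.size(); ++k) out(zg[k] - 1, zs[k] - 1) += 1.0;
  return List::create(_["matrix"] = out);
}

// Dependence: number of the (up to 8) neighbours whose level differs from
// the centre by at most `alpha`; column index = dependence + 1.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(const IntegerMatrix& img, int ng, int alpha) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(ng, 9);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      int g = img(r, c), dep = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
          if (std::abs(img(r2, c2) - g) <= alpha) ++dep;
        }
      }
      out(g - 1, dep) += 1.0;
    }
  }
  return out;
}

// Per gray level: count n_i and summed absolute deviation s_i of the level
// from the mean of its existing neighbours.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(const IntegerMatrix& img, int ng) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) {
      int g = img(r, c);
      double sum = 0.0;
      int cnt = 0;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (!dr && !dc) continue;
          int r2 = r + dr, c2 = c + dc;
          if (r2 < 0 || r2 >= h || c2 < 0 || c2 >= w) continue;
          sum += img(r2, c2);
          ++cnt;
        }
      }
      out(g - 1, 0) += 1.0;
      if (cnt > 0) out(g - 1, 1) += std::fabs(g - sum / cnt);
    }
  }
  return out;
}
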