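#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Zhang-Suen morphological thinning to a 1-px, 8-connected skeleton.
// Outside-of-image pixels are treated as background.
// [[Rcpp::export(name = ".cf_thin")]]
IntegerMatrix cf_thin(const IntegerMatrix &mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix img = clone(mask);
  std::vector<int> del;
  del.reserve(1024);
  auto at = [&](int r, int c) -> int {
    if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
    return img(r, c);
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!img(r, c)) continue;
          // neighbours p2..p9 clockwise from north (row-1)
          int p2 = at(r - 1, c),     p3 = at(r - 1, c + 1);
          int p4 = at(r, c + 1),     p5 = at(r + 1, c + 1);
          int p6 = at(r + 1, c),     p7 = at(r + 1, c - 1);
          int p8 = at(r, c - 1),     p9 = at(r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          int nb[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int k = 0; k < 8; ++k) if (nb[k] == 0 && nb[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          del.push_back(r + nr * c);
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k) img[del[k]] = 0;
      }
    }
  }
  return img;
}

// Stamp random ellipses ("flow voids") into a binary mask until the number
// of void pixels reaches target_px.  Centres are drawn by rejection sampling
// against `accept` (values in [0,1]), which carries the spatial
// heterogeneity of the void process.  Sizes in pixels: semi-minor axis from
// U[b_lo, b_hi] with probability 1 - p_large, else U[B_lo, B_hi]; the
// aspect ratio (semi-major / semi-minor) from U[asp_lo, asp_hi]; orientation
// uniform.  Returns the mask plus the number of ellipses placed.
// [[Rcpp::export(name = ".cf_stamp_voids")]]
List cf_stamp_voids(int nr, int nc, double target_px, const NumericMatrix &accept,
                    double b_lo, double b_hi, double B_lo, double B_hi,
                    double p_large, double asp_lo, double asp_hi,
                    int max_ellipses) {
  IntegerMatrix voidmask(nr, nc);
  double voided = 0.0;
  int placed = 0, attempts = 0;
  const int max_attempts = max_ellipses * 50;
  while (voided < target_px && placed < max_ellipses && attempts < max_attempts) {
    ++attempts;
    double cx = R::runif(0.0, (double)nc);
    double cy = R::runif(0.0, (double)nr);
    int ai = std::min(nr - 1, (int)std::floor(cy));
    int aj = std::min(nc - 1, (int)std::floor(cx));
    if (R::runif(0.0, 1.0) > accept(ai, aj)) continue;
    double b = (R::runif(0.0, 1.0) < p_large) ? R::runif(B_lo, B_hi)
                                              : R::runif(b_lo, b_hi);
    double a = b * R::runif(asp_lo, asp_hi);
    double phi = R::runif(0.0, M_PI);
    double cphi = std::cos(phi), sphi = std::sin(phi);
    int r0 = std::max(0, (int)std::floor(cy - a)), r1 = std::min(nr - 1, (int)std::ceil(cy + a));
    int c0 = std::max(0, (int)std::floor(cx - a)), c1 = std::min(nc - 1, (int)std::ceil(cx + a));
    for (int c = c0; c <= c1; ++c) {
      double dx = (c + 0.5) - cx;
      for (int r = r0; r <= r1; ++r) {
        double dy = (r + 0.5) - cy;
        double u = (dx * cphi + dy * sphi) / a;
        double v = (-dx * sphi + dy * cphi) / b;
        if (u * u + v * v <= 1.0 && !voidmask(r, c)) {
          voidmask(r, c) = 1;
          voided += 1.0;
        }
      }
    }
    ++placed;
  }
  return List::create(_["mask"] = voidmask, _["n_ellipses"] = placed,
                      _["void_px"] = voided);
}

struct Tip { double x, y, theta; int age; };

// Grow a branching, collision-avoiding vessel network on the pixel grid.
// Each step moves to the 8-neighbour closest to the tip heading; the heading
// receives Gaussian jitter per step.  Centerline length is accumulated in
// the 8-connected chain metric (1 per orthogonal step, sqrt(2) per diagonal
// step) and growth stops as soon as it reaches target_len (pixel units).
// A tip dies when its lookahead neighbourhood (Chebyshev radius `dmin`,
// `look` pixels ahead) touches existing vasculature or the image border.
// [[Rcpp::export(name = ".cf_grow_network")]]
List cf_grow_network(int nr, int nc, double target_len, double jitter,
                     double branch_p, int dmin, int look, int max_tips,
                     int n_seed0, int max_steps) {
  IntegerMatrix occ(nr, nc);
  std::vector<Tip> tips;
  tips.reserve(64);
  double total = 0.0;
  const double SQ2 = std::sqrt(2.0);
  int margin = dmin + 1;

  auto blocked = [&](int r, int c) -> bool {
    for (int dr = -dmin; dr <= dmin; ++dr)
      for (int dc = -dmin; dc <= dmin; ++dc) {
        int rr = r + dr, cc = c + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (occ(rr, cc)) return true;
      }
    return false;
  };
  auto spawn_seed = [&]() -> bool {
    for (int t = 0; t < 400; ++t) {
      int r = margin + (int)std::floor(R::runif(0.0, (double)(nr - 2 * margin)));
      int c = margin + (int)std::floor(R::runif(0.0, (double)(nc - 2 * margin)));
      if (!blocked(r, c)) {
        Tip tp; tp.x = c; tp.y = r; tp.theta = R::runif(0.0, 2.0 * M_PI); tp.age = 0;
        tips.push_back(tp);
        occ(r, c) = 1;
        return true;
      }
    }
    return false;
  };

  for (int s = 0; s < n_seed0; ++s) spawn_seed();
  int steps = 0;
  while (total < target_len && steps < max_steps) {
    if (tips.empty()) {
      if (!spawn_seed()) break;  // saturated: nowhere left to grow
      continue;
    }
    for (size_t i = 0; i < tips.size() && total < target_len; ) {
      ++steps;
      Tip &tp = tips[i];
      tp.theta += R::rnorm(0.0, jitter);
      int dx = (int)std::lround(std::cos(tp.theta));
      int dy = (int)std::lround(std::sin(tp.theta));
      if (dx == 0 && dy == 0) dx = 1;
      int nx = (int)tp.x + dx, ny = (int)tp.y + dy;
      bool die = false;
      if (nx < margin || nx >= nc - margin || ny < margin || ny >= nr - margin)
        die = true;
      else if (occ(ny, nx))
        die = true;
      else if (tp.age >= 4) {
        int lx = (int)tp.x + (int)std::lround(look * std::cos(tp.theta));
        int ly = (int)tp.y + (int)std::lround(look * std::sin(tp.theta));
        lx = std::max(0, std::min(nc - 1, lx));
        ly = std::max(0, std::min(nr - 1, ly));
        if (blocked(ly, lx)) die = true;
      }
      if (die) {
        tips.erase(tips.begin() + i);
        continue;
      }
      occ(ny, nx) = 1;
      total += (dx != 0 && dy != 0) ? SQ2 : 1.0;
      tp.x = nx; tp.y = ny; tp.age += 1;
      if ((int)tips.size() < max_tips && R::runif(0.0, 1.0) < branch_p) {
        Tip nb; nb.x = nx; nb.y = ny;
        double sgn = (R::runif(0.0, 1.0) < 0.5) ? 1.0 : -1.0;
        nb.theta = tp.theta + sgn * (M_PI / 3.0 + R::rnorm(0.0, 0.2));
        nb.age = 0;
        tips.push_back(nb);
      }
      ++i;
    }
  }
  return List::create(_["centerline"] = occ, _["length_px"] = total,
                      _["reached"] = (total >= target_len));
}
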