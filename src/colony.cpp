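#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// 0-based index from a uniform draw; matches the R helper .pick()
static inline int pick(double u, int k) {
  int i = (int)(u * k);
  if (i >= k) i = k - 1;
  if (i < 0) i = 0;
  return i;
}

// free bud sites of a cell given its used-site bitmask (bits 0..3 = sites 1..4),
// in ascending site order; distal sites are 0 and 1
static inline int free_sites(int used, bool distal_only, int *out) {
  int n = 0, lim = distal_only ? 2 : 4;
  for (int s = 0; s < lim; ++s)
    if (!(used & (1 << s))) out[n++] = s;
  return n;
}

// Grow a colony in place until it holds n_target cells, consuming R's RNG
// stream in the documented draw order (see propose_event() on the R side,
// which implements the identical sequence).
//
// cells0: n0 x 7 matrix, columns x, y, theta, type (0 sated / 1 pseudohyphal),
//         mother (1-based, 0 = none), has_pd (0/1), used (bitmask).
// ab:     2 x 3 matrix, rows = type, columns half_length a, half_width b,
//         bud-site boundary parameter phi_beta.
// [[Rcpp::export]]
List cpp_grow_colony(NumericMatrix cells0, int n_target, int n_max,
                     double n_star, double p_a, double p_sp, double p_ps,
                     double gamma_, NumericMatrix ab,
                     double Lx, double Ly, double max_aborts) {
  int n0 = cells0.nrow();
  std::vector<double> x, y, th;
  std::vector<int> type, mother, used;
  std::vector<char> haspd;
  std::vector<int> satedIdx, pseudoIdx;
  x.reserve(n_target); y.reserve(n_target); th.reserve(n_target);
  type.reserve(n_target); mother.reserve(n_target);
  used.reserve(n_target); haspd.reserve(n_target);

  for (int i = 0; i < n0; ++i) {
    x.push_back(cells0(i, 0)); y.push_back(cells0(i, 1));
    th.push_back(cells0(i, 2)); type.push_back((int)cells0(i, 3));
    mother.push_back((int)cells0(i, 4));
    haspd.push_back((char)(cells0(i, 5) != 0));
    used.push_back((int)cells0(i, 6));
    if (type[i] == 0) satedIdx.push_back(i); else pseudoIdx.push_back(i);
  }

  const double a0 = ab(0, 0), b0 = ab(0, 1), phiB0 = ab(0, 2);
  const double a1 = ab(1, 0), b1 = ab(1, 1), phiB1 = ab(1, 2);
  double total_aborts = 0, consec = 0;
  bool stalled = false;
  int fs[4];

  int n = (int)x.size();
  while (n < n_target) {
    if (consec >= max_aborts) { stalled = true; break; }

    int mom = -1, dtype = 0, site = -1;
    bool abort = false;
    bool pre = ((double)n / (double)n_max <= n_star);

    if (pre) {
      mom = pick(unif_rand(), n);
      dtype = 0;
      int k = free_sites(used[mom], false, fs);
      if (k == 0) abort = true; else site = fs[pick(unif_rand(), k)];
    } else {
      double ut = unif_rand();
      bool satedMother = pseudoIdx.empty() || (ut < p_a);
      if (satedMother) {
        mom = satedIdx[pick(unif_rand(), (int)satedIdx.size())];
        dtype = (unif_rand() < p_sp) ? 1 : 0;
        int k = free_sites(used[mom], false, fs);
        if (k == 0) abort = true; else site = fs[pick(unif_rand(), k)];
      } else {
        mom = pseudoIdx[pick(unif_rand(), (int)pseudoIdx.size())];
        if (!haspd[mom]) {
          dtype = 1;
          int k = free_sites(used[mom], true, fs);
          if (k == 0) abort = true; else site = fs[pick(unif_rand(), k)];
        } else if (unif_rand() < gamma_) {
          // redirect to a pseudohyphal cell without a pseudohyphal daughter
          std::vector<int> elig;
          for (size_t j = 0; j < pseudoIdx.size(); ++j)
            if (!haspd[pseudoIdx[j]]) elig.push_back(pseudoIdx[j]);
          if (elig.empty()) abort = true;
          else {
            mom = elig[pick(unif_rand(), (int)elig.size())];
            dtype = 1;
            int k = free_sites(used[mom], true, fs);
            if (k == 0) abort = true; else site = fs[pick(unif_rand(), k)];
          }
        } else {
          dtype = (unif_rand() < p_ps) ? 0 : 1;
          int k = free_sites(used[mom], true, fs);
          if (k == 0) abort = true; else site = fs[pick(unif_rand(), k)];
        }
      }
    }

    if (!abort) {
      // daughter pose: proximal pole on the bud-site point, oriented along
      // the outward ray from the mother's centre through the site
      int mt = type[mom];
      double am = mt ? a1 : a0, bm = mt ? b1 : b0, phb = mt ? phiB1 : phiB0;
      double phi = (site == 0) ? phb : (site == 1) ? -phb
                   : (site == 2) ? M_PI - phb : M_PI + phb;
      double c = std::cos(th[mom]), s = std::sin(th[mom]);
      double cp = am * std::cos(phi), sp = bm * std::sin(phi);
      double px = x[mom] + cp * c - sp * s;
      double py = y[mom] + cp * s + sp * c;
      double ang = std::atan2(py - y[mom], px - x[mom]);
      double ad = dtype ? a1 : a0, bd = dtype ? b1 : b0;
      double cd = std::cos(ang), sd = std::sin(ang);
      double cx = px + ad * cd, cy = py + ad * sd;

      // the daughter boundary must stay inside the domain
      double ex = std::sqrt(ad * ad * cd * cd + bd * bd * sd * sd);
      double ey = std::sqrt(ad * ad * sd * sd + bd * bd * cd * cd);
      bool ok = (cx - ex >= -Lx / 2) && (cx + ex <= Lx / 2) &&
                (cy - ey >= -Ly / 2) && (cy + ey <= Ly / 2);

      // volume exclusion: abort if the new centre lies strictly inside
      // the boundary of any existing cell
      if (ok) {
        for (int j = 0; j < n; ++j) {
          double dx = cx - x[j], dy = cy - y[j];
          double aj = type[j] ? a1 : a0;
          if (dx * dx + dy * dy >= aj * aj) continue;
          double bj = type[j] ? b1 : b0;
          double cj = std::cos(th[j]), sj = std::sin(th[j]);
          double u = dx * cj + dy * sj, v = -dx * sj + dy * cj;
          if ((u / aj) * (u / aj) + (v / bj) * (v / bj) < 1.0) { ok = false; break; }
        }
      }

      if (ok) {
        x.push_back(cx); y.push_back(cy); th.push_back(ang);
        type.push_back(dtype); mother.push_back(mom + 1);
        haspd.push_back(0); used.push_back(0);
        if (dtype == 1) { haspd[mom] = 1; pseudoIdx.push_back(n); }
        else satedIdx.push_back(n);
        used[mom] |= (1 << site);
        ++n;
        consec = 0;
        continue;
      }
    }
    consec += 1; total_aborts += 1;
  }

  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = th[i];
    out(i, 3) = type[i]; out(i, 4) = mother[i];
    out(i, 5) = haspd[i]; out(i, 6) = used[i];
  }
  return List::create(_["cells"] = out, _["aborts"] = total_aborts,
                      _["stalled"] = stalled);
}

// Rasterise ellipse cells onto a pixel grid. Pixel (i, j) (1-based in R)
// has centre (xmin + (i - 0.5) * px, ymin + (j - 0.5) * px); occupied iff
// the centre lies inside or on the boundary of any cell.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(NumericMatrix cells, NumericMatrix ab,
                            double xmin, double ymin, double px,
                            int nx, int ny) {
  IntegerMatrix M(nx, ny);
  int n = cells.nrow();
  for (int i = 0; i < n; ++i) {
    double cx = cells(i, 0), cy = cells(i, 1), t = cells(i, 2);
    int ty = (int)cells(i, 3);
    double a = ab(ty, 0), b = ab(ty, 1);
    double c = std::cos(t), s = std::sin(t);
    double ex = std::sqrt(a * a * c * c + b * b * s * s);
    double ey = std::sqrt(a * a * s * s + b * b * c * c);
    int i0 = std::max(0, (int)std::floor((cx - ex - xmin) / px - 0.5));
    int i1 = std::min(nx - 1, (int)std::ceil((cx + ex - xmin) / px - 0.5));
    int j0 = std::max(0, (int)std::floor((cy - ey - ymin) / px - 0.5));
    int j1 = std::min(ny - 1, (int)std::ceil((cy + ey - ymin) / px - 0.5));
    for (int jj = j0; jj <= j1; ++jj) {
      double pyc = ymin + (jj + 0.5) * px;
      double dy = pyc - cy;
      for (int ii = i0; ii <= i1; ++ii) {
        if (M(ii, jj)) continue;
        double pxc = xmin + (ii + 0.5) * px;
        double dx = pxc - cx;
        double u = dx * c + dy * s, v = -dx * s + dy * c;
        if ((u / a) * (u / a) + (v / b) * (v / b) <= 1.0) M(ii, jj) = 1;
      }
    }
  }
  return M;
}

// Zhang-Suen morphological thinning to a 1-px, 8-connected skeleton.
// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix M = clone(mask);
  std::vector<std::pair<int, int> > del;
  bool changed = true;

  // neighbours p2..p9 clockwise starting north (j + 1 in y-up convention)
  auto nb = [&](int i, int j, int *p) {
    auto at = [&](int ii, int jj) -> int {
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) return 0;
      return M(ii, jj);
    };
    p[0] = at(i, j + 1);     // N
    p[1] = at(i + 1, j + 1); // NE
    p[2] = at(i + 1, j);     // E
    p[3] = at(i + 1, j - 1); // SE
    p[4] = at(i, j - 1);     // S
    p[5] = at(i - 1, j - 1); // SW
    p[6] = at(i - 1, j);     // W
    p[7] = at(i - 1, j + 1); // NW
  };

  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          if (!M(i, j)) continue;
          int p[8];
          nb(i, j, p);
          int B = 0;
          for (int k = 0; k < 8; ++k) B += p[k];
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) {
        changed = true;
        for (size_t k = 0; k < del.size(); ++k)
          M(del[k].first, del[k].second) = 0;
      }
    }
  }
  return M;
}

// Label 8-connected components; 0 = background, components numbered 1..k.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}
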