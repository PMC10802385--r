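// Euler-Maruyama integrator for the chromosome-ensemble pairing model.
//
// Each chromosome is a self-propelled agent in a 2-D nuclear disc:
//   dx_i = dt * ( v0 * d_i + sum_j F_ij + F_boundary ) + sqrt(2 D dt) * eta
// Pair forces derive from Morse (paired-Yukawa) potentials: homologs attract
// on scale ell_a, non-homologs repel on scale ell_r, everyone repels on the
// short excluded-volume scale ell_r1. Homolog pairs within the capture
// distance merge permanently into a composite agent held at a fixed
// separation. Optional active-dumbbell mode represents each chromosome as
// two beads joined by a harmonic bond calibrated so <|r|^2> = ell^2.
//
// All randomness comes from R's RNG so set.seed() at the R level makes every
// trajectory reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Site {
  double x, y;
  int chrom;   // chromosome class index
  int unit;    // motion unit (rep chromosome index)
  int bead;    // global bead index, -1 for composite site
  bool comp;   // composite (captured pair) site
};

inline double sq(double v) { return v * v; }

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericMatrix x0,          // n_beads x 2 bead positions
              NumericMatrix ori0,        // n_chrom x 2 propulsion orientations
              IntegerVector homolog,     // 0-based homolog partner, -1 if none
              NumericVector ell_a,       // per-chromosome attractive scale
              NumericVector ell_r,       // per-chromosome repulsive scale
              double C_a, double C_r, double C_r1, double ell_r1,
              double C_b, double ell_b, double nucleus_radius,
              double v0, double D, double dt,
              int n_steps, int sample_every,
              double capture_dist, double paired_sep,
              double interaction_cutoff,
              bool dumbbell, NumericVector lambda,  // per-chromosome bond stiffness
              IntegerVector paired0,     // 0-based partner or -1
              NumericVector pair_time0,  // capture time (s), NA if unpaired
              NumericMatrix comp0,       // n_chrom x 2 composite centers
              NumericMatrix axis0,       // n_chrom x 2 frozen member axes
              NumericVector last_mag0,   // last realized displacement magnitude
              double t0,
              bool sample_initial)
{
  const int n = ori0.nrow();
  const int beads_per = dumbbell ? 2 : 1;
  const int n_beads = n * beads_per;
  if (x0.nrow() != n_beads)
    stop("bead position matrix has %d rows, expected %d", x0.nrow(), n_beads);

  std::vector<double> xb(n_beads), yb(n_beads);
  for (int b = 0; b < n_beads; ++b) { xb[b] = x0(b, 0); yb[b] = x0(b, 1); }
  std::vector<double> ox(n), oy(n), cx(n), cy(n), ax(n), ay(n), lmag(n), ptime(n);
  std::vector<int> pw(n);
  for (int c = 0; c < n; ++c) {
    ox[c] = ori0(c, 0); oy[c] = ori0(c, 1);
    cx[c] = comp0(c, 0); cy[c] = comp0(c, 1);
    ax[c] = axis0(c, 0); ay[c] = axis0(c, 1);
    lmag[c] = last_mag0[c];
    pw[c] = paired0[c];
    ptime[c] = pair_time0[c];
  }

  const double noise_sd = std::sqrt(2.0 * D * dt);
  const double cutoff2 = sq(interaction_cutoff);
  const double r1_reach = 20.0 * ell_r1;          // exp(-20) ~ 2e-9
  const double wall_reach = 30.0 * ell_b;         // exp(-30) ~ 9e-14

  // sampling bookkeeping
  int n_samp = (sample_initial ? 1 : 0);
  for (int s = 1; s <= n_steps; ++s)
    if (s % sample_every == 0 || s == n_steps) ++n_samp;
  NumericVector times(n_samp);
  NumericMatrix X(n_samp, n), Y(n_samp, n);
  IntegerMatrix P(n_samp, n);
  NumericMatrix B2;
  if (dumbbell) B2 = NumericMatrix(n_samp, n);

  std::vector<Site> sites;  sites.reserve(n_beads);
  std::vector<double> fx(n_beads), fy(n_beads);
  std::vector<int> first(n);

  // display-center helper: fills per-chromosome centers (captured members
  // rendered at +/- paired_sep/2 about the composite center)
  auto record = [&](int row, double t) {
    times[row] = t;
    for (int c = 0; c < n; ++c) {
      double px, py;
      if (pw[c] >= 0) {
        int rep = std::min(c, pw[c]);
        double sgn = (c == rep) ? 0.5 : -0.5;
        px = cx[rep] + sgn * paired_sep * ax[rep];
        py = cy[rep] + sgn * paired_sep * ay[rep];
      } else if (dumbbell) {
        px = 0.5 * (xb[2 * c] + xb[2 * c + 1]);
        py = 0.5 * (yb[2 * c] + yb[2 * c + 1]);
      } else {
        px = xb[c]; py = yb[c];
      }
      X(row, c) = px; Y(row, c) = py; P(row, c) = pw[c];
      if (dumbbell) {
        if (pw[c] >= 0) B2(row, c) = NA_REAL;
        else B2(row, c) = sq(xb[2 * c + 1] - xb[2 * c]) + sq(yb[2 * c + 1] - yb[2 * c]);
      }
    }
  };

  int row = 0;
  if (sample_initial) record(row++, t0);

  for (int step = 0; step < n_steps; ++step) {
    // ---- build interaction sites --------------------------------------
    sites.clear();
    for (int c = 0; c < n; ++c) {
      if (pw[c] >= 0) {
        if (pw[c] > c) sites.push_back({cx[c], cy[c], c, c, -1, true});
      } else if (dumbbell) {
        sites.push_back({xb[2 * c], yb[2 * c], c, c, 2 * c, false});
        sites.push_back({xb[2 * c + 1], yb[2 * c + 1], c, c, 2 * c + 1, false});
      } else {
        sites.push_back({xb[c], yb[c], c, c, c, false});
      }
    }
    const int ns = (int) sites.size();
    std::fill(fx.begin(), fx.begin() + ns, 0.0);
    std::fill(fy.begin(), fy.begin() + ns, 0.0);

    // ---- pair forces ---------------------------------------------------
    for (int i = 0; i < ns; ++i) {
      for (int j = i + 1; j < ns; ++j) {
        if (sites[i].unit == sites[j].unit) continue;  // bond handled separately
        double dxv = sites[i].x - sites[j].x;
        double dyv = sites[i].y - sites[j].y;
        double d2 = dxv * dxv + dyv * dyv;
        if (d2 > cutoff2) continue;
        bool hom = !sites[i].comp && !sites[j].comp &&
                   homolog[sites[i].chrom] == sites[j].chrom;
        double d = std::sqrt(d2);
        double mag;
        double ux, uy;
        if (d > 0.0) {
          ux = dxv / d; uy = dyv / d;
          mag = (d < r1_reach) ? (C_r1 / ell_r1) * std::exp(-d / ell_r1) : 0.0;
          if (hom) {
            double ea = 0.5 * (ell_a[sites[i].chrom] + ell_a[sites[j].chrom]);
            mag -= (C_a / ea) * std::exp(-d / ea);
          } else {
            double er = 0.5 * (ell_r[sites[i].chrom] + ell_r[sites[j].chrom]);
            mag += (C_r / er) * std::exp(-d / er);
          }
        } else {
          // coincident centers: deterministic draw from the seeded stream
          double th = 2.0 * M_PI * unif_rand();
          ux = std::cos(th); uy = std::sin(th);
          mag = C_r1 / ell_r1;
          if (hom) {
            double ea = 0.5 * (ell_a[sites[i].chrom] + ell_a[sites[j].chrom]);
            mag -= C_a / ea;
          } else {
            double er = 0.5 * (ell_r[sites[i].chrom] + ell_r[sites[j].chrom]);
            mag += C_r / er;
          }
        }
        fx[i] += mag * ux; fy[i] += mag * uy;
        fx[j] -= mag * ux; fy[j] -= mag * uy;
      }
      // ---- boundary repulsion (per site) ------------------------------
      double nr = std::sqrt(sq(sites[i].x) + sq(sites[i].y));
      double gap = nucleus_radius - nr;
      if (nr > 0.0 && gap < wall_reach) {
        double bmag = (C_b / ell_b) * std::exp(-gap / ell_b);
        fx[i] -= bmag * sites[i].x / nr;
        fy[i] -= bmag * sites[i].y / nr;
      }
    }

    // ---- dumbbell bond forces -----------------------------------------
    if (dumbbell) {
      for (int i = 0; i < ns; ++i) {
        if (sites[i].comp || sites[i].bead % 2 != 0) continue;
        // site i is bead 0 of a free dumbbell; bead 1 is the next site
        int j = i + 1;
        int c = sites[i].chrom;
        double rx = sites[j].x - sites[i].x;
        double ry = sites[j].y - sites[i].y;
        double k = 2.0 * lambda[c] * D;
        fx[i] += k * rx; fy[i] += k * ry;
        fx[j] -= k * rx; fy[j] -= k * ry;
      }
    }

    // map unit -> first site index for force lookup
    // (sites are emitted in chromosome order, so scan once)
    std::fill(first.begin(), first.end(), -1);
    for (int i = 0; i < ns; ++i)
      if (first[sites[i].unit] < 0) first[sites[i].unit] = i;

    // ---- advance units (fixed chromosome order => deterministic RNG) ---
    for (int c = 0; c < n; ++c) {
      if (pw[c] >= 0 && pw[c] < c) continue;           // non-rep member
      int s0 = first[c];
      if (pw[c] >= 0) {                                // composite agent
        double dxv = dt * (v0 * ox[c] + fx[s0]) + noise_sd * norm_rand();
        double dyv = dt * (v0 * oy[c] + fy[s0]) + noise_sd * norm_rand();
        cx[c] += dxv; cy[c] += dyv;
        if (!std::isfinite(cx[c]) || !std::isfinite(cy[c]))
          stop("non-finite coordinate for composite %d at step %d", c + 1, step + 1);
        double m = std::sqrt(dxv * dxv + dyv * dyv);
        if (m > 0.0) { ox[c] = dxv / m; oy[c] = dyv / m; }
        lmag[c] = m;
      } else if (dumbbell) {
        double mdx = 0.0, mdy = 0.0;
        for (int k = 0; k < 2; ++k) {
          int s = s0 + k;
          int b = sites[s].bead;
          double dxv = dt * (v0 * ox[c] + fx[s]) + noise_sd * norm_rand();
          double dyv = dt * (v0 * oy[c] + fy[s]) + noise_sd * norm_rand();
          xb[b] += dxv; yb[b] += dyv;
          if (!std::isfinite(xb[b]) || !std::isfinite(yb[b]))
            stop("non-finite coordinate for chromosome %d at step %d", c + 1, step + 1);
          mdx += 0.5 * dxv; mdy += 0.5 * dyv;
        }
        double m = std::sqrt(mdx * mdx + mdy * mdy);
        if (m > 0.0) { ox[c] = mdx / m; oy[c] = mdy / m; }
        lmag[c] = m;
      } else {
        double dxv = dt * (v0 * ox[c] + fx[s0]) + noise_sd * norm_rand();
        double dyv = dt * (v0 * oy[c] + fy[s0]) + noise_sd * norm_rand();
        xb[c] += dxv; yb[c] += dyv;
        if (!std::isfinite(xb[c]) || !std::isfinite(yb[c]))
          stop("non-finite coordinate for chromosome %d at step %d", c + 1, step + 1);
        double m = std::sqrt(dxv * dxv + dyv * dyv);
        if (m > 0.0) { ox[c] = dxv / m; oy[c] = dyv / m; }
        lmag[c] = m;
      }
    }

    double t_now = t0 + (step + 1) * dt;

    // ---- permanent pairing capture ------------------------------------
    for (int c = 0; c < n; ++c) {
      int p = homolog[c];
      if (p <= c || pw[c] >= 0 || pw[p] >= 0) continue;
      double mcx, mcy, mpx, mpy;
      if (dumbbell) {
        mcx = 0.5 * (xb[2 * c] + xb[2 * c + 1]);
        mcy = 0.5 * (yb[2 * c] + yb[2 * c + 1]);
        mpx = 0.5 * (xb[2 * p] + xb[2 * p + 1]);
        mpy = 0.5 * (yb[2 * p] + yb[2 * p + 1]);
      } else {
        mcx = xb[c]; mcy = yb[c]; mpx = xb[p]; mpy = yb[p];
      }
      double d = std::sqrt(sq(mcx - mpx) + sq(mcy - mpy));
      if (d <= capture_dist) {
        pw[c] = p; pw[p] = c;
        ptime[c] = t_now; ptime[p] = t_now;
        cx[c] = 0.5 * (mcx + mpx); cy[c] = 0.5 * (mcy + mpy);
        if (d > 0.0) { ax[c] = (mcx - mpx) / d; ay[c] = (mcy - mpy) / d; }
        else {
          double th = 2.0 * M_PI * unif_rand();
          ax[c] = std::cos(th); ay[c] = std::sin(th);
        }
        if (lmag[p] > lmag[c]) { ox[c] = ox[p]; oy[c] = oy[p]; }  // faster member
        lmag[c] = std::max(lmag[c], lmag[p]);
      }
    }

    if ((step + 1) % sample_every == 0 || step + 1 == n_steps)
      record(row++, t_now);
  }

  // ---- final full state (for the stepping API) -------------------------
  NumericMatrix xf(n_beads, 2), of(n, 2), cf(n, 2), af(n, 2);
  IntegerVector pwf(n);
  NumericVector ptf(n), lmf(n);
  for (int b = 0; b < n_beads; ++b) { xf(b, 0) = xb[b]; xf(b, 1) = yb[b]; }
  for (int c = 0; c < n; ++c) {
    of(c, 0) = ox[c]; of(c, 1) = oy[c];
    cf(c, 0) = cx[c]; cf(c, 1) = cy[c];
    af(c, 0) = ax[c]; af(c, 1) = ay[c];
    pwf[c] = pw[c]; ptf[c] = ptime[c]; lmf[c] = lmag[c];
  }

  return List::create(
    _["times"] = times, _["x"] = X, _["y"] = Y, _["partner"] = P,
    _["bond_r2"] = dumbbell ? (RObject) B2 : (RObject) R_NilValue,
    _["state"] = List::create(
      _["beads"] = xf, _["orientations"] = of, _["paired_with"] = pwf,
      _["pair_time"] = ptf, _["comp_center"] = cf, _["pair_axis"] = af,
      _["last_disp"] = lmf, _["time"] = t0 + n_steps * dt));
}
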