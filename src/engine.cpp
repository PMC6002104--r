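// Compiled inner loop for the ring-swarm individual-based model.
//
// The force pass visits each unordered pair once, evaluates the three
// truncated Gaussian kernels at the pairwise minimal-image distance, and
// accumulates, for every individual and zone, four directional sums (side
// R/L of the reference x neighbour heading +/-). The per-submodel sign
// structure is applied afterwards from those sums, keeping the rule logic
// out of the O(N^2) loop. RNG discipline matches the pure-R stepper: one
// uniform per individual per step, drawn from R's stream in index order.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// evaluated with the same association order as the R formula
// exp(-(d - s)^2 / (2 m^2)) / sqrt(2 pi m^2), so both paths agree bitwise
struct Kernel {
  double centre, width, cutoff, denom, root;
  void init(const NumericVector& p) {
    centre = p[0];
    width = p[1];
    cutoff = p[2];
    denom = 2.0 * (width * width);
    root = std::sqrt(2.0 * M_PI * (width * width));
  }
  inline double eval(double d) const {
    if (d > cutoff) return 0.0;
    double z = d - centre;
    return std::exp(-(z * z) / denom) / root;
  }
};

// zone sums per individual: [Rp, Rm, Lp, Lm] x 3 zones (r, al, a)
struct Sums {
  std::vector<double> s; // 12 * n
  int n;
  void reset(int n_) {
    n = n_;
    s.assign(12 * (size_t)n, 0.0);
  }
  // zone: 0 = r, 1 = al, 2 = a; cat: 0 Rp, 1 Rm, 2 Lp, 3 Lm
  inline double& at(int i, int zone, int cat) {
    return s[(size_t)i * 12 + zone * 4 + cat];
  }
};

// own-heading force for individual i in one zone under a submodel
static inline double combine(const double* z, int vi_plus, double q,
                             int submodel, bool align_zone) {
  const double Rp = z[0], Rm = z[1], Lp = z[2], Lm = z[3];
  const double SR = Rp + Rm, SL = Lp + Lm;
  double yp, ym;
  switch (submodel) {
  case 1:
    yp = align_zone ? q * (Rm - Lp) : q * (SR - SL);
    ym = -yp;
    break;
  case 2:
    yp = align_zone ? q * (Rm + Lm - Rp - Lp) : q * (SR - SL);
    ym = -yp;
    break;
  case 3:
    if (align_zone) { yp = q * (Rm - Rp); ym = q * (Lp - Lm); }
    else            { yp = q * SR;        ym = q * SL; }
    break;
  case 4:
    yp = q * (Rm - Lp);
    ym = -yp;
    break;
  default: // 5
    yp = q * Rm;
    ym = q * Lp;
    break;
  }
  return vi_plus ? yp : ym;
}

static void accumulate_pairs(const std::vector<double>& x,
                             const std::vector<int>& v,
                             double L, const Kernel& kr, const Kernel& kal,
                             const Kernel& ka, bool use_r, bool use_al,
                             bool use_a, Sums& sums) {
  const int n = (int)x.size();
  const double halfL = 0.5 * L;
  double maxcut = 0.0;
  if (use_r) maxcut = std::max(maxcut, kr.cutoff);
  if (use_al) maxcut = std::max(maxcut, kal.cutoff);
  if (use_a) maxcut = std::max(maxcut, ka.cutoff);
  sums.reset(n);
  for (int i = 0; i < n - 1; ++i) {
    const double xi = x[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - xi;
      if (dx > halfL) dx -= L;
      else if (dx <= -halfL) dx += L;
      const double d = std::fabs(dx);
      if (d > maxcut || d == 0.0) continue; // coincident: no side
      const double w_r = use_r ? kr.eval(d) : 0.0;
      const double w_al = use_al ? kal.eval(d) : 0.0;
      const double w_a = use_a ? ka.eval(d) : 0.0;
      // side of j seen from i; antipode (dx == L/2) is right for both
      const bool j_right = dx > 0;
      const bool i_right = (dx == halfL) ? true : !j_right;
      const int cat_ij = (j_right ? 0 : 2) + (v[j] > 0 ? 0 : 1);
      const int cat_ji = (i_right ? 0 : 2) + (v[i] > 0 ? 0 : 1);
      if (w_r != 0.0) {
        sums.at(i, 0, cat_ij) += w_r;
        sums.at(j, 0, cat_ji) += w_r;
      }
      if (w_al != 0.0) {
        sums.at(i, 1, cat_ij) += w_al;
        sums.at(j, 1, cat_ji) += w_al;
      }
      if (w_a != 0.0) {
        sums.at(i, 2, cat_ij) += w_a;
        sums.at(j, 2, cat_ji) += w_a;
      }
    }
  }
}

static inline double turning_f(double x, double y0) {
  return 0.5 + 0.5 * std::tanh(x - y0);
}

// wrap onto [0, L); per-step displacements are far below L, so a single
// conditional shift suffices (with a second check so that a tiny negative
// that rounds up to L still maps to 0, as R's %% does)
static inline double wrap_pos(double x, double L) {
  if (x >= L) x -= L;
  else if (x < 0) { x += L; if (x >= L) x -= L; }
  return x;
}

// [[Rcpp::export]]
List run_engine_cpp(NumericVector positions0, IntegerVector directions0,
                    int n_steps, int record_every, double L, double dt,
                    double gamma, double lambda1, double lambda2,
                    double y0, double alpha,
                    double q_r, double q_al, double q_a,
                    NumericVector kr, NumericVector kal, NumericVector ka,
                    int submodel, bool density_dependent,
                    bool apply_alpha_dds, double t0) {
  const int n = positions0.size();
  Kernel Kr, Kal, Ka;
  Kr.init(kr); Kal.init(kal); Ka.init(ka);
  std::vector<double> x(positions0.begin(), positions0.end());
  std::vector<int> v(directions0.begin(), directions0.end());
  Sums sums;

  const int n_frames = n_steps / record_every + 1;
  NumericMatrix pos(n_frames, n);
  IntegerMatrix dir(n_frames, n);
  NumericVector times(n_frames);
  for (int i = 0; i < n; ++i) { pos(0, i) = x[i]; dir(0, i) = v[i]; }
  times[0] = t0;
  int frame = 0;

  std::vector<double> lam(n), speed(n);
  std::vector<int> v_new(n);
  RNGScope rng;

  const bool use_r = q_r != 0.0, use_al = q_al != 0.0, use_a = q_a != 0.0;
  for (int step = 1; step <= n_steps; ++step) {
    accumulate_pairs(x, v, L, Kr, Kal, Ka, use_r, use_al, use_a, sums);
    if (!density_dependent) {
      for (int i = 0; i < n; ++i) {
        const int vp = v[i] > 0;
        const double yr = combine(&sums.at(i, 0, 0), vp, q_r, submodel, false);
        const double yal = combine(&sums.at(i, 1, 0), vp, q_al, submodel, true);
        const double ya = combine(&sums.at(i, 2, 0), vp, q_a, submodel, false);
        lam[i] = lambda1 + lambda2 * turning_f(alpha * (yr - ya + yal), y0);
      }
      for (int i = 0; i < n; ++i)
        x[i] = wrap_pos(x[i] + gamma * v[i] * dt, L);
      for (int i = 0; i < n; ++i) {
        const double u = R::runif(0.0, 1.0);
        if (lam[i] * dt >= u) v[i] = -v[i];
      }
    } else {
      for (int i = 0; i < n; ++i) {
        const int vp = v[i] > 0;
        double yal = combine(&sums.at(i, 1, 0), vp, q_al, submodel, true);
        if (apply_alpha_dds) yal *= alpha;
        lam[i] = lambda1 + lambda2 * turning_f(yal, y0);
      }
      for (int i = 0; i < n; ++i) {
        const double u = R::runif(0.0, 1.0);
        v_new[i] = (lam[i] * dt >= u) ? -v[i] : v[i];
      }
      // recompute forces with the post-flip headings at pre-move positions
      accumulate_pairs(x, v_new, L, Kr, Kal, Ka, use_r, use_al, use_a, sums);
      for (int i = 0; i < n; ++i) {
        const int vp = v_new[i] > 0;
        const double yr = combine(&sums.at(i, 0, 0), vp, q_r, submodel, false);
        const double ya = combine(&sums.at(i, 2, 0), vp, q_a, submodel, false);
        speed[i] = gamma * (1.0 + std::tanh(ya - yr));
      }
      for (int i = 0; i < n; ++i) {
        v[i] = v_new[i];
        x[i] = wrap_pos(x[i] + speed[i] * v[i] * dt, L);
      }
    }
    if (step % record_every == 0) {
      ++frame;
      for (int i = 0; i < n; ++i) { pos(frame, i) = x[i]; dir(frame, i) = v[i]; }
      times[frame] = t0 + (double)step * dt;
    }
    if (step % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["times"] = times, _["positions"] = pos,
                      _["directions"] = dir);
}
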