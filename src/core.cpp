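// Core numerics: analytic test potentials, geometric path-CV projection,
// and the Langevin/bias simulation driver.  All heavy per-step work lives
// here; R wrappers in R/ provide the user-facing interface.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <sstream>

using namespace Rcpp;

static const double KB = 0.008314463; // kJ/(mol K)
// 1 kJ/mol = 1e-6 amu (length/fs)^2 in the kJ/mol--amu--fs unit system,
// so masses enter the equations of motion as m[amu] * MASS_SCALE.
static const double MASS_SCALE = 1.0e6;

// ---------------------------------------------------------------------------
// Potentials
// code 1: Muller-Brown, par = {B}; canonical four-term constants scaled by B
// code 2: harmonic well, par = {k_1, ..., k_dim}
// code 3: quartic double well (1D), par = {height, half_width}
// ---------------------------------------------------------------------------

static const double MB_A[4]  = {-200.0, -100.0, -170.0, 15.0};
static const double MB_a[4]  = {-1.0, -1.0, -6.5, 0.7};
static const double MB_b[4]  = {0.0, 0.0, 11.0, 0.6};
static const double MB_c[4]  = {-10.0, -10.0, -6.5, 0.7};
static const double MB_x0[4] = {1.0, 0.0, -0.5, -1.0};
static const double MB_y0[4] = {0.0, 0.5, 1.5, 1.0};

static double pot_energy_grad(int code, const std::vector<double>& par,
                              const double* x, int dim, double* g) {
  double e = 0.0;
  for (int i = 0; i < dim; ++i) g[i] = 0.0;
  if (code == 1) { // Muller-Brown (dim 2)
    const double B = par[0];
    const double xx = x[0], yy = x[1];
    for (int k = 0; k < 4; ++k) {
      const double dx = xx - MB_x0[k], dy = yy - MB_y0[k];
      const double ex = std::exp(MB_a[k]*dx*dx + MB_b[k]*dx*dy + MB_c[k]*dy*dy);
      const double term = B * MB_A[k] * ex;
      e += term;
      g[0] += term * (2.0*MB_a[k]*dx + MB_b[k]*dy);
      g[1] += term * (MB_b[k]*dx + 2.0*MB_c[k]*dy);
    }
  } else if (code == 2) { // harmonic
    for (int i = 0; i < dim; ++i) {
      e += 0.5 * par[i] * x[i]*x[i];
      g[i] = par[i] * x[i];
    }
  } else if (code == 3) { // double well, U = h ((x/w)^2 - 1)^2
    const double h = par[0], w = par[1];
    const double u = x[0]/w;
    const double q = u*u - 1.0;
    e = h * q * q;
    g[0] = 4.0 * h * q * u / w;
  } else {
    stop("unknown potential code");
  }
  return e;
}

// [[Rcpp::export]]
List cpp_potential_eval(int code, NumericVector par, NumericMatrix X) {
  const int n = X.nrow(), dim = X.ncol();
  std::vector<double> p(par.begin(), par.end());
  NumericVector energy(n);
  NumericMatrix grad(n, dim);
  std::vector<double> xi(dim), gi(dim);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < dim; ++j) xi[j] = X(i, j);
    energy[i] = pot_energy_grad(code, p, xi.data(), dim, gi.data());
    for (int j = 0; j < dim; ++j) grad(i, j) = gi[j];
  }
  return List::create(_["energy"] = energy, _["gradient"] = grad);
}

// ---------------------------------------------------------------------------
// Geometric path CV
// ---------------------------------------------------------------------------

// Fetch node i of a path stored node-major, with linear ghost extension
// one node beyond each end (used for projection outside the path span).
static inline void get_node(const std::vector<double>& nodes, int M, int D,
                            int i, double* out) {
  if (i >= 0 && i < M) {
    for (int j = 0; j < D; ++j) out[j] = nodes[(size_t)i*D + j];
  } else if (i == -1) {
    for (int j = 0; j < D; ++j)
      out[j] = 2.0*nodes[j] - nodes[(size_t)D + j];
  } else if (i == M) {
    for (int j = 0; j < D; ++j)
      out[j] = 2.0*nodes[(size_t)(M-1)*D + j] - nodes[(size_t)(M-2)*D + j];
  } else {
    stop("node index out of range");
  }
}

struct LocResult {
  int m;        // zero-based index of closest node
  int side;     // +1 if z lies before (left of) the closest node
  double s;     // progress, clamped to [-0.1, 1.1]
  double d;     // distance from the path
};

// Closest-node projection: progress s from the geometric closed form,
// distance d from the line through the segment between the two closest
// nodes, projection point P on that line, and analytic gradients.
static void locate_core(const std::vector<double>& nodes, int M, int D,
                        const double* z, LocResult& res,
                        double* P, double* gs, double* gd, bool want_grad) {
  // closest node (ties broken toward the lower index)
  int m = 0;
  double best = R_PosInf;
  for (int i = 0; i < M; ++i) {
    double dd = 0.0;
    for (int j = 0; j < D; ++j) {
      const double df = nodes[(size_t)i*D + j] - z[j];
      dd += df*df;
    }
    if (dd < best - 1e-30) { best = dd; m = i; }
  }
  std::vector<double> zm(D), zprev(D), znext(D);
  get_node(nodes, M, D, m, zm.data());
  get_node(nodes, M, D, m - 1, zprev.data());
  get_node(nodes, M, D, m + 1, znext.data());

  double dprev = 0.0, dnext = 0.0;
  for (int j = 0; j < D; ++j) {
    const double a = z[j] - zprev[j], b = z[j] - znext[j];
    dprev += a*a; dnext += b*b;
  }
  const int side = (dprev <= dnext) ? 1 : -1;

  // v1 = z_m - z, v2 = z - z_{m-1}, v3 = z_{m+1} - z_m
  std::vector<double> v1(D), v2(D), v3(D);
  double n1 = 0.0, n2 = 0.0, n3 = 0.0, a13 = 0.0;
  for (int j = 0; j < D; ++j) {
    v1[j] = zm[j] - z[j];
    v2[j] = z[j] - zprev[j];
    v3[j] = znext[j] - zm[j];
    n1 += v1[j]*v1[j];
    n2 += v2[j]*v2[j];
    n3 += v3[j]*v3[j];
    a13 += v1[j]*v3[j];
  }
  if (n3 < 1e-24) stop("invalid path: degenerate (zero-length) segment");
  double disc = a13*a13 - n3*(n1 - n2);
  if (disc < 0.0) disc = 0.0;
  const double Rr = std::sqrt(disc);
  const double corr = ((Rr - a13)/n3 - 1.0)/2.0;
  double s_raw = (m + corr) / (double)(M - 1);
  double s = s_raw;
  if (s < -0.1) s = -0.1;
  if (s > 1.1) s = 1.1;

  if (want_grad) {
    const double Rsafe = (Rr > 1e-12) ? Rr : 1e-12;
    for (int j = 0; j < D; ++j) {
      const double dR = (-a13*v3[j] + n3*(v1[j] + v2[j])) / Rsafe;
      gs[j] = (dR + v3[j]) / (2.0*n3) / (double)(M - 1);
    }
  }

  // distance: perpendicular distance to the line through the segment
  // between the closest and second-closest node
  std::vector<double> base(D), v4(D);
  if (side > 0) {
    base = zprev;
    for (int j = 0; j < D; ++j) v4[j] = zm[j] - zprev[j];
  } else {
    base = zm;
    for (int j = 0; j < D; ++j) v4[j] = znext[j] - zm[j];
  }
  double n4 = 0.0, proj = 0.0;
  for (int j = 0; j < D; ++j) {
    n4 += v4[j]*v4[j];
    proj += (z[j] - base[j]) * v4[j];
  }
  if (n4 < 1e-24) stop("invalid path: degenerate (zero-length) segment");
  const double t = proj / n4;
  double d2 = 0.0;
  std::vector<double> p(D);
  for (int j = 0; j < D; ++j) {
    P[j] = base[j] + t*v4[j];
    p[j] = z[j] - P[j];
    d2 += p[j]*p[j];
  }
  const double d = std::sqrt(d2);
  if (want_grad) {
    for (int j = 0; j < D; ++j) gd[j] = (d > 1e-12) ? p[j]/d : 0.0;
  }

  res.m = m; res.side = side; res.s = s; res.d = d;
}

static std::vector<double> path_to_vec(const NumericMatrix& nodes) {
  const int M = nodes.nrow(), D = nodes.ncol();
  std::vector<double> v((size_t)M*D);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < D; ++j) v[(size_t)i*D + j] = nodes(i, j);
  return v;
}

// [[Rcpp::export]]
List cpp_path_locate(NumericMatrix nodes, NumericMatrix Z) {
  const int M = nodes.nrow(), D = nodes.ncol();
  if (M < 3) stop("a path needs at least 3 nodes");
  if (Z.ncol() != D) stop("dimension mismatch between path and points");
  std::vector<double> nv = path_to_vec(nodes);
  const int n = Z.nrow();
  IntegerVector mi(n), sidei(n);
  NumericVector sv(n), dv(n);
  NumericMatrix P(n, D), GS(n, D), GD(n, D);
  std::vector<double> z(D), Pi(D), gs(D), gd(D);
  LocResult res;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < D; ++j) z[j] = Z(i, j);
    locate_core(nv, M, D, z.data(), res, Pi.data(), gs.data(), gd.data(), true);
    mi[i] = res.m; sidei[i] = res.side; sv[i] = res.s; dv[i] = res.d;
    for (int j = 0; j < D; ++j) {
      P(i, j) = Pi[j]; GS(i, j) = gs[j]; GD(i, j) = gd[j];
    }
  }
  return List::create(_["m"] = mi, _["side"] = sidei, _["s"] = sv,
                      _["d"] = dv, _["P"] = P,
                      _["grad_s"] = GS, _["grad_d"] = GD);
}

// One pass: place nodes at equal arc length along the piecewise-linear curve.
static void reparam_pass(std::vector<double>& nodes, int M, int D) {
  std::vector<double> cum(M, 0.0);
  for (int i = 1; i < M; ++i) {
    double seg = 0.0;
    for (int j = 0; j < D; ++j) {
      const double df = nodes[(size_t)i*D + j] - nodes[(size_t)(i-1)*D + j];
      seg += df*df;
    }
    seg = std::sqrt(seg);
    if (seg < 1e-14) stop("invalid path: duplicate consecutive nodes");
    cum[i] = cum[i-1] + seg;
  }
  const double L = cum[M-1];
  std::vector<double> out((size_t)M*D);
  for (int j = 0; j < D; ++j) {
    out[j] = nodes[j];
    out[(size_t)(M-1)*D + j] = nodes[(size_t)(M-1)*D + j];
  }
  int seg_i = 1;
  for (int i = 1; i < M - 1; ++i) {
    const double target = L * i / (double)(M - 1);
    while (seg_i < M - 1 && cum[seg_i] < target) ++seg_i;
    const double t = (target - cum[seg_i-1]) / (cum[seg_i] - cum[seg_i-1]);
    for (int j = 0; j < D; ++j)
      out[(size_t)i*D + j] = (1.0 - t)*nodes[(size_t)(seg_i-1)*D + j]
                           + t*nodes[(size_t)seg_i*D + j];
  }
  nodes = out;
}

// Iterate the equal-arc resampling to its fixpoint so that chord lengths
// between consecutive nodes equalize (single passes only equalize arc
// positions, which differ from chords on curved paths).
static void reparam_core(std::vector<double>& nodes, int M, int D) {
  for (int pass = 0; pass < 100; ++pass) {
    reparam_pass(nodes, M, D);
    double mn = R_PosInf, mx = 0.0;
    for (int i = 1; i < M; ++i) {
      double seg = 0.0;
      for (int j = 0; j < D; ++j) {
        const double df = nodes[(size_t)i*D + j] - nodes[(size_t)(i-1)*D + j];
        seg += df*df;
      }
      seg = std::sqrt(seg);
      if (seg < mn) mn = seg;
      if (seg > mx) mx = seg;
    }
    if ((mx - mn)/mx < 1e-10) break;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_reparametrize(NumericMatrix nodes) {
  const int M = nodes.nrow(), D = nodes.ncol();
  if (M < 3) stop("a path needs at least 3 nodes");
  std::vector<double> nv = path_to_vec(nodes);
  reparam_core(nv, M, D);
  NumericMatrix out(M, D);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < D; ++j) out(i, j) = nv[(size_t)i*D + j];
  return out;
}

// Node update from accumulated weights/displacements, with optional memory
// weight of the current path (half-life tau in units of update events).
// Endpoints are held fixed; the path is reparametrized afterwards.
static void path_update_core(std::vector<double>& nodes, int M, int D,
                             std::vector<double>& W, std::vector<double>& Dacc,
                             std::vector<double>& mem, double tau,
                             double smooth) {
  double wtot = 0.0;
  for (int i = 0; i < M; ++i) wtot += W[i];
  if (wtot > 0.0) {
    for (int i = 1; i < M - 1; ++i) {
      const double denom = W[i] + mem[i];
      if (denom > 0.0 && W[i] > 0.0) {
        for (int j = 0; j < D; ++j)
          nodes[(size_t)i*D + j] += Dacc[(size_t)i*D + j] / denom;
      }
    }
    // string-method style smoothing: pull each interior node toward the
    // midpoint of its neighbours; rounds sharp bends and propagates
    // adaptation along the path
    if (smooth > 0.0) {
      std::vector<double> old(nodes);
      for (int i = 1; i < M - 1; ++i)
        for (int j = 0; j < D; ++j)
          nodes[(size_t)i*D + j] = (1.0 - smooth)*old[(size_t)i*D + j]
            + 0.5*smooth*(old[(size_t)(i-1)*D + j] + old[(size_t)(i+1)*D + j]);
    }
    reparam_core(nodes, M, D);
  }
  const double decay = (tau > 0.0) ? std::pow(2.0, -1.0/tau) : 0.0;
  for (int i = 0; i < M; ++i) {
    mem[i] = (mem[i] + W[i]) * decay;
    W[i] = 0.0;
    for (int j = 0; j < D; ++j) Dacc[(size_t)i*D + j] = 0.0;
  }
}

// [[Rcpp::export]]
List cpp_path_update(NumericMatrix nodes, NumericVector W, NumericMatrix Dacc,
                     NumericVector mem, double tau, double smooth) {
  const int M = nodes.nrow(), D = nodes.ncol();
  std::vector<double> nv = path_to_vec(nodes);
  std::vector<double> w(W.begin(), W.end());
  std::vector<double> da = path_to_vec(Dacc);
  std::vector<double> mm(mem.begin(), mem.end());
  path_update_core(nv, M, D, w, da, mm, tau, smooth);
  NumericMatrix out(M, D);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < D; ++j) out(i, j) = nv[(size_t)i*D + j];
  return List::create(_["nodes"] = out, _["mem"] = NumericVector(mm.begin(), mm.end()));
}

// ---------------------------------------------------------------------------
// Simulation driver
// ---------------------------------------------------------------------------

struct Grid {
  double gmin, gbin;
  int n;
  std::vector<double> count, fsum, ubias, dubias;
  Grid(double mn, double mx, double bw) : gmin(mn), gbin(bw) {
    n = (int)std::ceil((mx - mn)/bw - 1e-9);
    count.assign(n, 0.0); fsum.assign(n, 0.0);
    ubias.assign(n, 0.0); dubias.assign(n, 0.0);
  }
  int bin(double x) const {
    const int j = (int)std::floor((x - gmin)/gbin);
    return (j >= 0 && j < n) ? j : -1;
  }
  double center(int j) const { return gmin + (j + 0.5)*gbin; }
  // linear interpolation between bin centers, clamped at the edges
  double interp(const std::vector<double>& v, double x) const {
    double u = (x - gmin)/gbin - 0.5;
    if (u <= 0.0) return v[0];
    if (u >= n - 1) return v[n-1];
    const int j = (int)std::floor(u);
    const double t = u - j;
    return (1.0 - t)*v[j] + t*v[j+1];
  }
};

// [[Rcpp::export]]
List cpp_run_sim(int pot_code, NumericVector pot_par, int dim,
                 NumericVector x0, NumericVector v0, bool has_v0,
                 Nullable<NumericMatrix> path_, List cfg) {
  const double dt       = as<double>(cfg["dt"]);
  const double steps_d  = as<double>(cfg["steps"]);
  const long   steps    = (long)steps_d;
  const int    stride   = as<int>(cfg["stride"]);
  const double Temp     = as<double>(cfg["temperature"]);
  const double gamma    = as<double>(cfg["friction"]);
  const double mass_amu = as<double>(cfg["mass"]);
  const int    bias     = as<int>(cfg["bias_mode"]); // 0 none 1 mtd 2 wtm 3 eabf 4 wtm-eabf
  const double h0       = as<double>(cfg["hill_height"]);
  const double sigG     = as<double>(cfg["hill_sigma"]);
  const int    tauG     = as<int>(cfg["hill_interval"]);
  const double deltaT   = as<double>(cfg["delta_T"]);   // <= 0 means infinite (plain MtD)
  const double ext_mass = as<double>(cfg["ext_mass"]);
  const double sigma    = as<double>(cfg["ext_sigma"]);
  const bool   stab     = as<bool>(cfg["stabilize"]);
  const double conf_k   = as<double>(cfg["conf_k"]);
  const double conf_d0  = as<double>(cfg["conf_d0"]);
  const double gmin     = as<double>(cfg["grid_min"]);
  const double gmax     = as<double>(cfg["grid_max"]);
  const double gbin     = as<double>(cfg["grid_bin"]);
  const double nfull    = as<double>(cfg["abf_nfull"]);
  const long   upd_int  = (long)as<double>(cfg["path_update_interval"]);
  const double tau      = as<double>(cfg["tau"]);
  const double psmooth  = as<double>(cfg["path_smooth"]);
  const long   pmf_int  = (long)as<double>(cfg["pmf_interval"]);
  const double fp_thr   = as<double>(cfg["fp_threshold"]);
  const double kwall    = as<double>(cfg["lambda_wall_k"]);
  const double gamma_l  = as<double>(cfg["ext_friction"]);

  const bool extended = (bias == 3 || bias == 4);
  const bool hills    = (bias == 1 || bias == 2 || bias == 4);
  const bool abf      = (bias == 3 || bias == 4);
  const bool use_path = path_.isNotNull();

  std::vector<double> nodes;
  int M = 0;
  if (use_path) {
    NumericMatrix pm(path_);
    if (pm.ncol() != dim) stop("path dimension does not match the system");
    if (pm.nrow() < 3) stop("a path needs at least 3 nodes");
    M = pm.nrow();
    nodes = path_to_vec(pm);
  } else if (dim < 1) {
    stop("dimension must be positive");
  }

  const double mx = mass_amu * MASS_SCALE;
  const double ml = ext_mass * MASS_SCALE;
  const double kspring = KB * Temp / (sigma * sigma);
  const double kBT = KB * Temp;

  Grid grid(gmin, gmax, gbin);

  // state
  std::vector<double> x(x0.begin(), x0.end()), v(dim, 0.0);
  RNGScope rng;
  if (has_v0) {
    for (int j = 0; j < dim; ++j) v[j] = v0[j];
  } else {
    const double sv = std::sqrt(kBT/mx);
    for (int j = 0; j < dim; ++j) v[j] = sv * norm_rand();
  }

  // path-update accumulators
  std::vector<double> W(M, 0.0), Dacc((size_t)M*dim, 0.0), mem(M, 0.0);

  // CV scratch
  std::vector<double> P(dim), gs(dim), gd(dim);
  LocResult loc;
  double s = 0.0, d = 0.0, lam = 0.0, vlam = 0.0, s_prev = 0.0;
  double epot = 0.0, ebias = 0.0;
  std::vector<double> Fx(dim, 0.0), gpot(dim);
  double Flam = 0.0;

  const double c1 = std::exp(-gamma*dt);
  const double c2 = std::sqrt(std::max(0.0, 1.0 - c1*c1));
  const double c1l = std::exp(-gamma_l*dt);
  const double c2l = std::sqrt(std::max(0.0, 1.0 - c1l*c1l));
  const double svx = std::sqrt(kBT/mx), svl = std::sqrt(kBT/ml);

  long n_hill_skipped = 0;
  int epoch = 0;
  long n_stab = 0, n_switch = 0;
  double sum_jump = 0.0, sum_ext = 0.0;
  int m_prev = -1;

  std::vector<double> ppar(pot_par.begin(), pot_par.end());

  // one force/CV evaluation at the current positions; when `sample` is true
  // the bias accumulators are updated and hills may be deposited
  auto eval_forces = [&](long step, bool sample) {
    epot = pot_energy_grad(pot_code, ppar, x.data(), dim, gpot.data());
    for (int j = 0; j < dim; ++j) Fx[j] = -gpot[j];
    ebias = 0.0;

    // collective variable
    if (use_path) {
      locate_core(nodes, M, dim, x.data(), loc, P.data(), gs.data(), gd.data(), true);
      s = loc.s; d = loc.d;
      if (sample) { if (loc.m != m_prev && m_prev >= 0) ++n_switch; m_prev = loc.m; }
    } else {
      s = x[0]; d = 0.0;
      for (int j = 0; j < dim; ++j) { gs[j] = 0.0; gd[j] = 0.0; }
      gs[0] = 1.0;
    }

    if (extended) {
      // stabilization: a single-step CV change larger than the thermal
      // coupling width signals a discontinuity (path update or shortcut);
      // translate lambda by the jump so the spring extension -- and with it
      // the coupling potential -- is continuous across it
      if (stab && sample && std::fabs(s - s_prev) > sigma) {
        lam += s - s_prev;
        ++n_stab; sum_jump += std::fabs(s - s_prev);
      }
      const double ext = s - lam;
      ebias += 0.5 * kspring * ext * ext;
      for (int j = 0; j < dim; ++j) Fx[j] += -kspring * ext * gs[j];
      Flam = kspring * ext;

      if (sample) {
        const int jb = grid.bin(lam);
        if (jb >= 0) {
          if (abf) {
            grid.count[jb] += 1.0;
            grid.fsum[jb] += kspring * (lam - s);
            const double ramp = std::min(1.0, grid.count[jb]/nfull);
            Flam += ramp * grid.fsum[jb] / grid.count[jb];
          }
        }
        if (hills && step > 0 && (step % tauG) == 0) {
          if (grid.bin(lam) < 0) {
            ++n_hill_skipped;
          } else {
            const double ub = grid.interp(grid.ubias, lam);
            const double h = (deltaT > 0.0) ? h0*std::exp(-ub/(KB*deltaT)) : h0;
            for (int u = 0; u < grid.n; ++u) {
              const double du = grid.center(u) - lam;
              const double gse = h*std::exp(-du*du/(2.0*sigG*sigG));
              grid.ubias[u] += gse;
              grid.dubias[u] += -du/(sigG*sigG) * gse;
            }
          }
        }
      } else {
        const int jb = grid.bin(lam);
        if (jb >= 0 && abf && grid.count[jb] > 0.0) {
          const double ramp = std::min(1.0, grid.count[jb]/nfull);
          Flam += ramp * grid.fsum[jb] / grid.count[jb];
        }
      }
      if (hills) {
        Flam += -grid.interp(grid.dubias, lam);
        ebias += grid.interp(grid.ubias, lam);
      }
      // harmonic walls keep the extended variable on the bias grid
      if (kwall > 0.0) {
        if (lam < grid.gmin) {
          Flam += -kwall*(lam - grid.gmin);
          ebias += 0.5*kwall*(lam - grid.gmin)*(lam - grid.gmin);
        } else if (lam > gmax) {
          Flam += -kwall*(lam - gmax);
          ebias += 0.5*kwall*(lam - gmax)*(lam - gmax);
        }
      }
    } else if (hills) { // direct MtD / WTM on s
      if (sample) {
        const int jb = grid.bin(s);
        if (jb >= 0) grid.count[jb] += 1.0;
        if (step > 0 && (step % tauG) == 0) {
          if (grid.bin(s) < 0) {
            ++n_hill_skipped;
          } else {
            const double ub = grid.interp(grid.ubias, s);
            const double h = (deltaT > 0.0) ? h0*std::exp(-ub/(KB*deltaT)) : h0;
            for (int u = 0; u < grid.n; ++u) {
              const double du = grid.center(u) - s;
              const double gse = h*std::exp(-du*du/(2.0*sigG*sigG));
              grid.ubias[u] += gse;
              grid.dubias[u] += -du/(sigG*sigG) * gse;
            }
          }
        }
      }
      const double dub = grid.interp(grid.dubias, s);
      for (int j = 0; j < dim; ++j) Fx[j] += -dub * gs[j];
      ebias += grid.interp(grid.ubias, s);
    }

    // one-sided harmonic confinement of the path distance
    if (use_path && conf_k > 0.0 && d > conf_d0) {
      const double excess = d - conf_d0;
      ebias += 0.5 * conf_k * excess * excess;
      for (int j = 0; j < dim; ++j) Fx[j] += -conf_k * excess * gd[j];
    }

    double fchk = 0.0;
    for (int j = 0; j < dim; ++j) fchk += Fx[j];
    if (!std::isfinite(fchk) || !std::isfinite(Flam) || !std::isfinite(epot)) {
      std::ostringstream msg;
      msg << "non-finite force/energy at step " << step;
      stop(msg.str());
    }
  };

  eval_forces(0, false);
  if (extended) { lam = s; vlam = 0.0; }
  s_prev = s;
  // re-evaluate so the spring contribution reflects the initialized lambda
  eval_forces(0, false);

  // output buffers
  const long nframes = steps / stride;
  const int ncol = dim + 9; // step,time,x...,s,d,lambda,epot,ebias,temp,epoch
  NumericMatrix traj(nframes, ncol);
  long frame = 0;

  std::vector<double> snap_times;
  List path_snaps;
  std::vector<double> pmf_times;
  std::vector< std::vector<double> > pmf_count, pmf_fsum, pmf_ubias;

  double fp_time = -1.0;

  for (long step = 1; step <= steps; ++step) {
    // BAOAB
    for (int j = 0; j < dim; ++j) v[j] += 0.5*dt*Fx[j]/mx;
    if (extended) vlam += 0.5*dt*Flam/ml;
    for (int j = 0; j < dim; ++j) x[j] += 0.5*dt*v[j];
    if (extended) lam += 0.5*dt*vlam;
    if (gamma > 0.0) {
      for (int j = 0; j < dim; ++j) v[j] = c1*v[j] + c2*svx*norm_rand();
    }
    if (extended && gamma_l > 0.0) vlam = c1l*vlam + c2l*svl*norm_rand();
    for (int j = 0; j < dim; ++j) x[j] += 0.5*dt*v[j];
    if (extended) lam += 0.5*dt*vlam;

    eval_forces(step, true);

    for (int j = 0; j < dim; ++j) v[j] += 0.5*dt*Fx[j]/mx;
    if (extended) vlam += 0.5*dt*Flam/ml;

    if (extended) { sum_ext += std::fabs(s - lam); }
    s_prev = s;

    // first passage
    if (fp_time < 0.0 && s > fp_thr) fp_time = step*dt;

    // path-update accumulation (two bracketing nodes of the continuous
    // node coordinate receive tent weights; displacement is z - P(z))
    if (use_path && upd_int > 0) {
      double sc = s;
      if (sc < 0.0) sc = 0.0;
      if (sc > 1.0) sc = 1.0;
      double sigc = sc*(M - 1);
      int i0 = (int)std::floor(sigc);
      if (i0 > M - 2) i0 = M - 2;
      const double f = sigc - i0;
      const double w0 = 1.0 - f, w1 = f;
      W[i0] += w0; W[i0+1] += w1;
      for (int j = 0; j < dim; ++j) {
        const double disp = x[j] - P[j];
        Dacc[(size_t)i0*dim + j] += w0*disp;
        Dacc[(size_t)(i0+1)*dim + j] += w1*disp;
      }
      if ((step % upd_int) == 0 && step < steps) {
        path_update_core(nodes, M, dim, W, Dacc, mem, tau, psmooth);
        NumericMatrix snap(M, dim);
        for (int i = 0; i < M; ++i)
          for (int j = 0; j < dim; ++j) snap(i, j) = nodes[(size_t)i*dim + j];
        path_snaps.push_back(snap);
        snap_times.push_back(step*dt);
        ++epoch;
      }
    }

    if (pmf_int > 0 && (step % pmf_int) == 0) {
      pmf_times.push_back(step*dt);
      pmf_count.push_back(grid.count);
      pmf_fsum.push_back(grid.fsum);
      pmf_ubias.push_back(grid.ubias);
    }

    if ((step % stride) == 0 && frame < nframes) {
      double ke = 0.0;
      for (int j = 0; j < dim; ++j) ke += 0.5*mx*v[j]*v[j];
      const double tinst = 2.0*ke/(dim*KB);
      int col = 0;
      traj(frame, col++) = (double)step;
      traj(frame, col++) = step*dt;
      for (int j = 0; j < dim; ++j) traj(frame, col++) = x[j];
      traj(frame, col++) = s;
      traj(frame, col++) = d;
      traj(frame, col++) = extended ? lam : NA_REAL;
      traj(frame, col++) = epot;
      traj(frame, col++) = ebias;
      traj(frame, col++) = tinst;
      traj(frame, col++) = (double)epoch;
      ++frame;
    }
  }

  NumericMatrix final_path(M, dim);
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < dim; ++j) final_path(i, j) = nodes[(size_t)i*dim + j];

  List grid_out = List::create(
    _["min"] = grid.gmin, _["bin"] = grid.gbin, _["n"] = grid.n,
    _["count"] = NumericVector(grid.count.begin(), grid.count.end()),
    _["fsum"] = NumericVector(grid.fsum.begin(), grid.fsum.end()),
    _["ubias"] = NumericVector(grid.ubias.begin(), grid.ubias.end()),
    _["dubias"] = NumericVector(grid.dubias.begin(), grid.dubias.end()));

  const int nsnap = (int)pmf_times.size();
  NumericMatrix gc(nsnap, grid.n), gf(nsnap, grid.n), gu(nsnap, grid.n);
  for (int i = 0; i < nsnap; ++i)
    for (int j = 0; j < grid.n; ++j) {
      gc(i, j) = pmf_count[i][j];
      gf(i, j) = pmf_fsum[i][j];
      gu(i, j) = pmf_ubias[i][j];
    }

  return List::create(
    _["traj"] = traj,
    _["dim"] = dim,
    _["first_passage"] = fp_time,
    _["final_path"] = use_path ? (SEXP)final_path : R_NilValue,
    _["path_snapshot_times"] = NumericVector(snap_times.begin(), snap_times.end()),
    _["path_snapshots"] = path_snaps,
    _["grid"] = grid_out,
    _["grid_snapshot_times"] = NumericVector(pmf_times.begin(), pmf_times.end()),
    _["grid_snapshot_count"] = gc,
    _["grid_snapshot_fsum"] = gf,
    _["grid_snapshot_ubias"] = gu,
    _["n_hill_skipped"] = (double)n_hill_skipped,
    _["n_stab"] = (double)n_stab,
    _["n_switch"] = (double)n_switch,
    _["mean_jump"] = n_stab > 0 ? sum_jump/n_stab : 0.0,
    _["mean_ext"] = steps > 0 ? sum_ext/steps : 0.0);
}
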