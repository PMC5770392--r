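// Compiled kernels: pair interactions, Langevin (BAOAB) propagation under
// periodic boundaries, and the hot loops of the trajectory analyses.
//
// Reduced units throughout: k_B T at the protocol temperature = 1 energy unit,
// bead mass = 1, lengths in Angstrom. All randomness is drawn from R's RNG so
// set.seed() in R makes every run reproducible.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline double min_image_1d(double d, double L) {
  // map into (-L/2, L/2]
  return d - L * std::ceil(d / L - 0.5);
}

// hot-path variant: multiply by the precomputed reciprocal; floor(x + 0.5)
// differs from the ceil form only when d/L - 0.5 is an exact integer, which
// the dynamics never hits
static inline double min_image_fast(double d, double L, double invL) {
  return d - L * std::floor(d * invL + 0.5);
}

struct ForceField {
  int n;
  double Lx, Ly, Lz;
  std::vector<double> radius, charge, mass;
  std::vector<int> group; // 0 = DNA, 1 = protein, 2 = crowder
  std::vector<int> b_i, b_j;          std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;     std::vector<double> a_t0, a_kt;
  std::vector<int> c_i, c_j;          std::vector<double> c_r0, c_eps;
  std::vector<int> c_spec;            // 1 = specific protein-DNA contact
  std::vector<int> q_i, q_j;          // precomputed charged pairs
  double lB, kappa, rc_e, eps_ev;
  double sigma_pp, sigma_pd;          // slim cross-sterics (see vignette)
  std::unordered_set<long long> excl; // pairs excluded from excluded-volume
  std::vector<int> com_idx;           double k_com, com_x, com_y, com_z;
  std::vector<int> xy_idx;            std::vector<double> xy_x0, xy_y0;
  double k_xy;
};

static long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

// contact diameter of a pair: additive radii for every pair involving a
// crowder or within the DNA; fixed slim diameters for protein-protein and
// protein-DNA pairs (groove insertion requires sub-additive cross sterics)
static inline double pair_sigma(const ForceField& ff, int i, int j) {
  int gi = ff.group[i], gj = ff.group[j];
  if (gi == 1 && gj == 1) return ff.sigma_pp;
  if ((gi == 1 && gj == 0) || (gi == 0 && gj == 1)) return ff.sigma_pd;
  return ff.radius[i] + ff.radius[j];
}

static ForceField parse_ff(const List& ffl) {
  ForceField ff;
  ff.n = as<int>(ffl["n"]);
  NumericVector box = ffl["box"];
  ff.Lx = box[0]; ff.Ly = box[1]; ff.Lz = box[2];
  ff.radius = as<std::vector<double>>(ffl["radius"]);
  ff.charge = as<std::vector<double>>(ffl["charge"]);
  ff.mass   = as<std::vector<double>>(ffl["mass"]);
  ff.group  = as<std::vector<int>>(ffl["group"]);

  IntegerMatrix bij = ffl["bonds_ij"];      NumericMatrix brk = ffl["bonds_r0k"];
  for (int m = 0; m < bij.nrow(); ++m) {
    ff.b_i.push_back(bij(m,0)); ff.b_j.push_back(bij(m,1));
    ff.b_r0.push_back(brk(m,0)); ff.b_k.push_back(brk(m,1));
  }
  IntegerMatrix aijk = ffl["angles_ijk"];   NumericMatrix atk = ffl["angles_t0k"];
  for (int m = 0; m < aijk.nrow(); ++m) {
    ff.a_i.push_back(aijk(m,0)); ff.a_j.push_back(aijk(m,1)); ff.a_k.push_back(aijk(m,2));
    ff.a_t0.push_back(atk(m,0)); ff.a_kt.push_back(atk(m,1));
  }
  IntegerMatrix cij = ffl["cont_ij"];       NumericMatrix cre = ffl["cont_r0eps"];
  IntegerVector csp = ffl["cont_spec"];
  for (int m = 0; m < cij.nrow(); ++m) {
    ff.c_i.push_back(cij(m,0)); ff.c_j.push_back(cij(m,1));
    ff.c_r0.push_back(cre(m,0)); ff.c_eps.push_back(cre(m,1));
    ff.c_spec.push_back(csp[m]);
  }
  IntegerMatrix qij = ffl["charged_ij"];
  for (int m = 0; m < qij.nrow(); ++m) {
    ff.q_i.push_back(qij(m,0)); ff.q_j.push_back(qij(m,1));
  }
  ff.lB = as<double>(ffl["lB"]);
  ff.kappa = as<double>(ffl["kappa"]);
  ff.rc_e = as<double>(ffl["rc_elec"]);
  ff.eps_ev = as<double>(ffl["eps_ev"]);
  ff.sigma_pp = as<double>(ffl["sigma_pp"]);
  ff.sigma_pd = as<double>(ffl["sigma_pd"]);

  NumericMatrix ex = ffl["excl_ij"]; // includes bonds, 1-3, contacts, intra-nt
  for (int m = 0; m < ex.nrow(); ++m)
    ff.excl.insert(pair_key((int)ex(m,0), (int)ex(m,1), ff.n));

  ff.com_idx = as<std::vector<int>>(ffl["com_idx"]);
  ff.k_com = as<double>(ffl["k_com"]);
  NumericVector ct = ffl["com_target"];
  ff.com_x = ct[0]; ff.com_y = ct[1]; ff.com_z = ct[2];
  ff.xy_idx = as<std::vector<int>>(ffl["xy_idx"]);
  ff.xy_x0 = as<std::vector<double>>(ffl["xy_x0"]);
  ff.xy_y0 = as<std::vector<double>>(ffl["xy_y0"]);
  ff.k_xy = as<double>(ffl["k_xy"]);
  return ff;
}

// Debye-Huckel with force-shift at rc (C1 continuous).
// exp_rc = exp(-kappa*rc), precomputed once per evaluation pass.
static inline void dh_pair(double qq, double r, double lB, double kappa,
                           double rc, double exp_rc, double& u, double& fmag) {
  // fmag = -dU/dr (positive = repulsive push apart)
  double er  = std::exp(-kappa * r);
  double ur  = lB * qq * er / r;
  double dur = -lB * qq * er * (1.0 + kappa * r) / (r * r);
  double urc  = lB * qq * exp_rc / rc;
  double durc = -lB * qq * exp_rc * (1.0 + kappa * rc) / (rc * rc);
  u = ur - urc - (r - rc) * durc;
  fmag = -(dur - durc);
}

// energy components: 0 bonded, 1 native, 2 specific, 3 elec, 4 ev,
// 5 ev protein-crowder, 6 ev protein-DNA
static void compute_forces(const std::vector<double>& x, const ForceField& ff,
                           const std::vector<int>& nl,
                           const std::vector<double>& nl_sig2,
                           std::vector<double>& F, double* e) {
  std::fill(F.begin(), F.end(), 0.0);
  for (int k = 0; k < 7; ++k) e[k] = 0.0;
  const double L[3] = {ff.Lx, ff.Ly, ff.Lz};
  const double invL[3] = {1.0 / ff.Lx, 1.0 / ff.Ly, 1.0 / ff.Lz};

  // bonds
  for (size_t m = 0; m < ff.b_i.size(); ++m) {
    int i = ff.b_i[m], j = ff.b_j[m];
    double d[3];
    for (int c = 0; c < 3; ++c)
      d[c] = min_image_1d(x[3*i+c] - x[3*j+c], L[c]);
    double r = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    double dr = r - ff.b_r0[m];
    e[0] += 0.5 * ff.b_k[m] * dr * dr;
    double fmag = -ff.b_k[m] * dr / r;
    for (int c = 0; c < 3; ++c) {
      F[3*i+c] += fmag * d[c];
      F[3*j+c] -= fmag * d[c];
    }
  }

  // angles
  for (size_t m = 0; m < ff.a_i.size(); ++m) {
    int i = ff.a_i[m], j = ff.a_j[m], k = ff.a_k[m];
    double rij[3], rkj[3];
    for (int c = 0; c < 3; ++c) {
      rij[c] = min_image_1d(x[3*i+c] - x[3*j+c], L[c]);
      rkj[c] = min_image_1d(x[3*k+c] - x[3*j+c], L[c]);
    }
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    double ct = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij*nkj);
    ct = std::max(-1.0 + 1e-12, std::min(1.0 - 1e-12, ct));
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct*ct);
    double dth = th - ff.a_t0[m];
    e[0] += 0.5 * ff.a_kt[m] * dth * dth;
    double coef = ff.a_kt[m] * dth / st;
    for (int c = 0; c < 3; ++c) {
      double fi = coef * (rkj[c]/nkj - ct * rij[c]/nij) / nij;
      double fk = coef * (rij[c]/nij - ct * rkj[c]/nkj) / nkj;
      F[3*i+c] += fi;
      F[3*k+c] += fk;
      F[3*j+c] -= (fi + fk);
    }
  }

  // 12-10 contacts (native + specific)
  for (size_t m = 0; m < ff.c_i.size(); ++m) {
    int i = ff.c_i[m], j = ff.c_j[m];
    double d[3];
    for (int c = 0; c < 3; ++c)
      d[c] = min_image_1d(x[3*i+c] - x[3*j+c], L[c]);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    double r = std::sqrt(r2);
    double s = ff.c_r0[m] / r;
    double s2 = s*s; double s10 = s2*s2*s2*s2*s2; double s12 = s10*s2;
    double eps = ff.c_eps[m];
    double u = eps * (5.0 * s12 - 6.0 * s10);
    e[ff.c_spec[m] ? 2 : 1] += u;
    // -dU/dr = 60 eps (s12 - s10)/r
    double fmag = 60.0 * eps * (s12 - s10) / r2; // per unit d[c]
    for (int c = 0; c < 3; ++c) {
      F[3*i+c] += fmag * d[c];
      F[3*j+c] -= fmag * d[c];
    }
  }

  // electrostatics over precomputed charged pairs
  const double exp_rc = std::exp(-ff.kappa * ff.rc_e);
  for (size_t m = 0; m < ff.q_i.size(); ++m) {
    int i = ff.q_i[m], j = ff.q_j[m];
    double d[3];
    for (int c = 0; c < 3; ++c)
      d[c] = min_image_1d(x[3*i+c] - x[3*j+c], L[c]);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (r2 >= ff.rc_e * ff.rc_e) continue;
    double r = std::sqrt(r2);
    double u, fmag;
    dh_pair(ff.charge[i] * ff.charge[j], r, ff.lB, ff.kappa, ff.rc_e, exp_rc,
            u, fmag);
    e[3] += u;
    for (int c = 0; c < 3; ++c) {
      F[3*i+c] += fmag * d[c] / r;
      F[3*j+c] -= fmag * d[c] / r;
    }
  }

  // WCA excluded volume over neighbor list (sig2 cached at list build)
  const double cbrt2 = 1.2599210498948732;   // 2^(1/3)
  for (size_t m = 0; m < nl.size(); m += 2) {
    int i = nl[m], j = nl[m+1];
    double sig2 = nl_sig2[m / 2];
    double rc2 = sig2 * cbrt2;
    double d[3];
    for (int c = 0; c < 3; ++c)
      d[c] = min_image_fast(x[3*i+c] - x[3*j+c], L[c], invL[c]);
    double r2 = d[0]*d[0] + d[1]*d[1] + d[2]*d[2];
    if (r2 >= rc2) continue;
    double inv2 = sig2 / r2;
    double inv6 = inv2 * inv2 * inv2;
    double u = 4.0 * ff.eps_ev * (inv6 * inv6 - inv6) + ff.eps_ev;
    e[4] += u;
    int gi = ff.group[i], gj = ff.group[j];
    if ((gi == 1 && gj == 2) || (gi == 2 && gj == 1)) e[5] += u;
    if ((gi == 1 && gj == 0) || (gi == 0 && gj == 1)) e[6] += u;
    double fmag = 24.0 * ff.eps_ev * (2.0 * inv6 * inv6 - inv6) / r2;
    for (int c = 0; c < 3; ++c) {
      F[3*i+c] += fmag * d[c];
      F[3*j+c] -= fmag * d[c];
    }
  }

  // DNA COM restraint (keeps the helix centered; force split equally)
  if (!ff.com_idx.empty() && ff.k_com > 0) {
    double cm[3] = {0,0,0};
    for (int idx : ff.com_idx)
      for (int c = 0; c < 3; ++c) cm[c] += x[3*idx+c];
    int nc = (int)ff.com_idx.size();
    for (int c = 0; c < 3; ++c) cm[c] /= nc;
    double dv[3] = {cm[0]-ff.com_x, cm[1]-ff.com_y, cm[2]-ff.com_z};
    e[0] += 0.5 * ff.k_com * (dv[0]*dv[0]+dv[1]*dv[1]+dv[2]*dv[2]);
    for (int idx : ff.com_idx)
      for (int c = 0; c < 3; ++c)
        F[3*idx+c] -= ff.k_com * dv[c] / nc;
  }

  // weak terminal xy restraints (hold helix axis along z)
  for (size_t m = 0; m < ff.xy_idx.size(); ++m) {
    int i = ff.xy_idx[m];
    double dx = x[3*i]   - ff.xy_x0[m];
    double dy = x[3*i+1] - ff.xy_y0[m];
    e[0] += 0.5 * ff.k_xy * (dx*dx + dy*dy);
    F[3*i]   -= ff.k_xy * dx;
    F[3*i+1] -= ff.k_xy * dy;
  }
}

static void build_neighbor_list(const std::vector<double>& x, const ForceField& ff,
                                double skin, std::vector<int>& nl,
                                std::vector<double>& nl_sig2) {
  nl.clear();
  nl_sig2.clear();
  const int n = ff.n;
  const double L[3] = {ff.Lx, ff.Ly, ff.Lz};
  const double invL[3] = {1.0 / ff.Lx, 1.0 / ff.Ly, 1.0 / ff.Lz};
  const double pre = std::pow(2.0, 1.0/6.0);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double sig = pair_sigma(ff, i, j);
      double cut = pre * sig + skin;
      double d0 = min_image_fast(x[3*i] - x[3*j], L[0], invL[0]);
      if (std::fabs(d0) > cut) continue;
      double d1 = min_image_fast(x[3*i+1] - x[3*j+1], L[1], invL[1]);
      if (std::fabs(d1) > cut) continue;
      double d2 = min_image_fast(x[3*i+2] - x[3*j+2], L[2], invL[2]);
      double r2 = d0*d0 + d1*d1 + d2*d2;
      if (r2 >= cut * cut) continue;
      if (ff.excl.count(pair_key(i, j, n))) continue;
      nl.push_back(i); nl.push_back(j);
      nl_sig2.push_back(sig * sig);
    }
  }
}

// [[Rcpp::export]]
List cg_energy_cpp(NumericMatrix pos, List ffl) {
  ForceField ff = parse_ff(ffl);
  std::vector<double> x(3 * ff.n);
  for (int i = 0; i < ff.n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = pos(i, c);
  std::vector<int> nl;
  std::vector<double> nl_sig2;
  build_neighbor_list(x, ff, 0.0, nl, nl_sig2);
  std::vector<double> F(3 * ff.n);
  double e[7];
  compute_forces(x, ff, nl, nl_sig2, F, e);
  NumericMatrix Fm(ff.n, 3);
  for (int i = 0; i < ff.n; ++i)
    for (int c = 0; c < 3; ++c) Fm(i, c) = F[3*i+c];
  return List::create(
    _["bonded"] = e[0], _["native"] = e[1], _["specific"] = e[2],
    _["electrostatic"] = e[3], _["excluded_volume"] = e[4],
    _["ev_protein_crowder"] = e[5], _["ev_protein_dna"] = e[6],
    _["total"] = e[0] + e[1] + e[2] + e[3] + e[4],
    _["forces"] = Fm);
}

// BAOAB Langevin integrator. Positions are never wrapped (analyses use
// minimum-image displacements); gamma = 0 with kT ignored gives velocity
// Verlet. Noise comes from R's RNG.
// stop_threshold > 0 ends the run early once at least that many specific
// contacts are simultaneously formed (checked at recording strides).
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix pos0, NumericMatrix vel0, List ffl,
                double dt, double gamma, double kT,
                int n_steps, int stride, double skin,
                int stop_threshold = 0, double stop_tol = 0.2) {
  ForceField ff = parse_ff(ffl);
  const int n = ff.n;
  std::vector<double> x(3*n), v(3*n), F(3*n), xref(3*n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      x[3*i+c] = pos0(i, c);
      v[3*i+c] = vel0(i, c);
    }
  std::vector<int> nl;
  std::vector<double> nl_sig2;
  build_neighbor_list(x, ff, skin, nl, nl_sig2);
  xref = x;
  double e[7];
  compute_forces(x, ff, nl, nl_sig2, F, e);

  const double c1 = (gamma > 0) ? std::exp(-gamma * dt) : 1.0;
  const double c2 = (gamma > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  const int nf = n_steps / stride + 1;
  NumericVector frames(Dimension(n, 3, nf));
  IntegerVector times(nf);
  int fidx = 0;
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) frames[i + n*c] = x[3*i+c];
  times[0] = 0; fidx = 1;

  const double half = 0.5 * dt;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / ff.mass[i];
      for (int c = 0; c < 3; ++c) {
        v[3*i+c] += half * F[3*i+c] * im;       // B
        x[3*i+c] += half * v[3*i+c];            // A
      }
    }
    if (gamma > 0) {                            // O
      for (int i = 0; i < n; ++i) {
        double sd = std::sqrt(kT / ff.mass[i]);
        for (int c = 0; c < 3; ++c)
          v[3*i+c] = c1 * v[3*i+c] + c2 * sd * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i)
      for (int c = 0; c < 3; ++c)
        x[3*i+c] += half * v[3*i+c];            // A

    // neighbor-list freshness
    double lim = 0.25 * skin * skin;
    bool rebuild = false;
    for (int i = 0; i < n && !rebuild; ++i) {
      double dd = 0;
      for (int c = 0; c < 3; ++c) {
        double d = x[3*i+c] - xref[3*i+c];
        dd += d * d;
      }
      if (dd > lim) rebuild = true;
    }
    if (rebuild) {
      build_neighbor_list(x, ff, skin, nl, nl_sig2);
      xref = x;
    }
    compute_forces(x, ff, nl, nl_sig2, F, e);
    double fsum = 0;
    for (int i = 0; i < 3*n; ++i) fsum += F[i];
    if (!std::isfinite(fsum))
      stop("non-finite force at step %d; system unstable (reduce dt?)", step);
    for (int i = 0; i < n; ++i) {
      double im = 1.0 / ff.mass[i];
      for (int c = 0; c < 3; ++c)
        v[3*i+c] += half * F[3*i+c] * im;       // B
    }

    if (step % stride == 0) {
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          frames[i + n*c + (R_xlen_t)n*3*fidx] = x[3*i+c];
      times[fidx] = step;
      ++fidx;
      if (step % (stride * 50) == 0) Rcpp::checkUserInterrupt();
      if (stop_threshold > 0) {
        int formed = 0;
        for (size_t m = 0; m < ff.c_i.size(); ++m) {
          if (!ff.c_spec[m]) continue;
          int i = ff.c_i[m], j = ff.c_j[m];
          double dd = 0;
          for (int c = 0; c < 3; ++c) {
            double d = min_image_1d(x[3*i+c] - x[3*j+c],
                                    c == 0 ? ff.Lx : (c == 1 ? ff.Ly : ff.Lz));
            dd += d * d;
          }
          if (std::sqrt(dd) <= ff.c_r0[m] * (1.0 + stop_tol)) ++formed;
        }
        if (formed >= stop_threshold) break;
      }
    }
  }

  NumericMatrix pos1(n, 3), vel1(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      pos1(i, c) = x[3*i+c];
      vel1(i, c) = v[3*i+c];
    }
  if (fidx < nf) {            // early exit: trim the recording arrays
    NumericVector fr2(Dimension(n, 3, fidx));
    IntegerVector tm2(fidx);
    for (R_xlen_t k = 0; k < (R_xlen_t)n * 3 * fidx; ++k) fr2[k] = frames[k];
    for (int k = 0; k < fidx; ++k) tm2[k] = times[k];
    frames = fr2; times = tm2;
  }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["pos"] = pos1, _["vel"] = vel1);
}

// [[Rcpp::export]]
NumericMatrix cg_minimum_image_cpp(NumericMatrix d, NumericVector box) {
  NumericMatrix out(d.nrow(), 3);
  for (int i = 0; i < d.nrow(); ++i)
    for (int c = 0; c < 3; ++c)
      out(i, c) = min_image_1d(d(i, c), box[c]);
  return out;
}

// per-frame minimum bead-center distance between two index sets (1-based idx)
// [[Rcpp::export]]
NumericVector cg_min_dist_cpp(NumericVector frames, IntegerVector idxA,
                              IntegerVector idxB, NumericVector box) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    double best = R_PosInf;
    for (int a = 0; a < idxA.size(); ++a) {
      int i = idxA[a] - 1;
      double xi = frames[i + (R_xlen_t)n*3*f];
      double yi = frames[i + n + (R_xlen_t)n*3*f];
      double zi = frames[i + 2*n + (R_xlen_t)n*3*f];
      for (int b = 0; b < idxB.size(); ++b) {
        int j = idxB[b] - 1;
        double dx = min_image_1d(xi - frames[j + (R_xlen_t)n*3*f], box[0]);
        double dy = min_image_1d(yi - frames[j + n + (R_xlen_t)n*3*f], box[1]);
        double dz = min_image_1d(zi - frames[j + 2*n + (R_xlen_t)n*3*f], box[2]);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < best) best = r2;
      }
    }
    out[f] = std::sqrt(best);
  }
  return out;
}

// per-frame, per-bp center distance to nearest crowder center.
// base_i/base_j: 1-based bead indices of the two paired base beads per bp.
// [[Rcpp::export]]
NumericMatrix cg_bp_crowder_dist_cpp(NumericVector frames, IntegerVector base_i,
                                     IntegerVector base_j, IntegerVector idxC,
                                     NumericVector box) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  int nbp = base_i.size();
  NumericMatrix out(nf, nbp);
  for (int f = 0; f < nf; ++f) {
    for (int p = 0; p < nbp; ++p) {
      int i = base_i[p] - 1, j = base_j[p] - 1;
      double cx = 0.5 * (frames[i + (R_xlen_t)n*3*f] + frames[j + (R_xlen_t)n*3*f]);
      double cy = 0.5 * (frames[i + n + (R_xlen_t)n*3*f] + frames[j + n + (R_xlen_t)n*3*f]);
      double cz = 0.5 * (frames[i + 2*n + (R_xlen_t)n*3*f] + frames[j + 2*n + (R_xlen_t)n*3*f]);
      double best = R_PosInf;
      for (int b = 0; b < idxC.size(); ++b) {
        int k = idxC[b] - 1;
        double dx = min_image_1d(cx - frames[k + (R_xlen_t)n*3*f], box[0]);
        double dy = min_image_1d(cy - frames[k + n + (R_xlen_t)n*3*f], box[1]);
        double dz = min_image_1d(cz - frames[k + 2*n + (R_xlen_t)n*3*f], box[2]);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < best) best = r2;
      }
      out(f, p) = std::sqrt(best);
    }
  }
  return out;
}

// per-frame mean nearest-neighbor center distance within one index set
// [[Rcpp::export]]
NumericVector cg_nn_gap_cpp(NumericVector frames, IntegerVector idx,
                            NumericVector box) {
  IntegerVector dim = frames.attr("dim");
  int n = dim[0], nf = dim[2];
  int m = idx.size();
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    double acc = 0;
    for (int a = 0; a < m; ++a) {
      int i = idx[a] - 1;
      double xi = frames[i + (R_xlen_t)n*3*f];
      double yi = frames[i + n + (R_xlen_t)n*3*f];
      double zi = frames[i + 2*n + (R_xlen_t)n*3*f];
      double best = R_PosInf;
      for (int b = 0; b < m; ++b) {
        if (b == a) continue;
        int j = idx[b] - 1;
        double dx = min_image_1d(xi - frames[j + (R_xlen_t)n*3*f], box[0]);
        double dy = min_image_1d(yi - frames[j + n + (R_xlen_t)n*3*f], box[1]);
        double dz = min_image_1d(zi - frames[j + 2*n + (R_xlen_t)n*3*f], box[2]);
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < best) best = r2;
      }
      acc += std::sqrt(best);
    }
    out[f] = acc / m;
  }
  return out;
}
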