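// Compiled core: Metropolis-Hastings sampling of freely jointed chains with
// hard sterics (membrane, tethered ligand spheres) and soft membrane
// potentials; reversible Gillespie phosphorylation cycles; simulated-annealing
// packing search. All randomness comes from a self-contained xoshiro256++
// generator so seeded runs are bit-reproducible across platforms.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct RNG {
  uint64_t s[4];
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {  // splitmix64 expansion of the seed
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0.0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif();
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
  inline void unit_sphere(double &x, double &y, double &z) {
    double a, b, s2;
    do {
      a = 2.0 * unif() - 1.0;
      b = 2.0 * unif() - 1.0;
      s2 = a * a + b * b;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = 2.0 * std::sqrt(1.0 - s2);
    x = a * f; y = b * f; z = 1.0 - 2.0 * s2;
  }
};

struct Rot {  // Rodrigues rotation about unit axis k by angle a, centred at P
  double kx, ky, kz, ca, sa, px, py, pz;
  inline void apply(double &x, double &y, double &z) const {
    double vx = x - px, vy = y - py, vz = z - pz;
    double dot = kx * vx + ky * vy + kz * vz;
    double cx = ky * vz - kz * vy, cy = kz * vx - kx * vz, cz = kx * vy - ky * vx;
    x = px + vx * ca + cx * sa + kx * dot * (1.0 - ca);
    y = py + vy * ca + cy * sa + ky * dot * (1.0 - ca);
    z = pz + vz * ca + cz * sa + kz * dot * (1.0 - ca);
  }
  inline void apply_vec(double &x, double &y, double &z) const {
    double vx = x, vy = y, vz = z;
    double dot = kx * vx + ky * vy + kz * vz;
    double cx = ky * vz - kz * vy, cy = kz * vx - kx * vz, cz = kx * vy - ky * vx;
    x = vx * ca + cx * sa + kx * dot * (1.0 - ca);
    y = vy * ca + cy * sa + ky * dot * (1.0 - ca);
    z = vz * ca + cz * sa + kz * dot * (1.0 - ca);
  }
};

// Residue classes: 0 generic, 1 basic, 2 phosphotyrosine.
// Membrane modes: 0 none, 1 hard wall at z = 0, 2 soft wall (potentials).
// pot = (E_B0, k_PC, E_P0, z_debye, k_S)
inline double bead_energy(double z, int cls, const double *pot, int mode) {
  if (mode == 0) return 0.0;
  if (cls == 1) {  // basic residue: piecewise parabolic well, zero above crossover
    if (pot[1] <= 0.0) return 0.0;
    double zc = std::sqrt(pot[0] / pot[1]);
    return (z < zc) ? pot[1] * z * z - pot[0] : 0.0;
  }
  if (cls == 2) return pot[2] * std::exp(-z / pot[3]);  // screened repulsion
  return (z < 0.0) ? pot[4] * z * z : 0.0;              // soft wall
}

struct System {
  int n_chain = 0, M = 0, L = 0, mode = 1;
  double bond = 0.3;
  std::vector<double> ax, ay, az;          // anchors
  std::vector<int> len, off;               // chain lengths, bead offsets
  std::vector<int> cls;                    // residue class per bead
  std::vector<int> lig_bead;               // global tether bead per ligand
  std::vector<double> lig_R;
  double pot[5] = {0, 0, 0, 0, 0};
  // state
  std::vector<double> bx, by, bz;          // bead coords
  std::vector<double> lx, ly, lz;          // ligand centres
  std::vector<double> ux, uy, uz;          // ligand orientations (unit)
  // pivot joints (chain, j): rotate beads j..len about bead j-1 (anchor if j==1)
  std::vector<int> joint_chain, joint_j;

  void build_joints(const IntegerMatrix &rigid) {
    joint_chain.clear(); joint_j.clear();
    for (int c = 0; c < n_chain; ++c) {
      for (int j = 1; j <= len[c]; ++j) {
        bool ok = true;
        for (int r = 0; r < rigid.nrow(); ++r) {
          if (rigid(r, 0) - 1 != c) continue;
          int lo = rigid(r, 1), hi = rigid(r, 2);
          if (lo < j && j <= hi) { ok = false; break; }
        }
        if (ok) { joint_chain.push_back(c); joint_j.push_back(j); }
      }
    }
  }

  inline int gidx(int c, int res) const { return off[c] + res - 1; }

  bool valid_all() const {
    const double tol = 1e-9;
    if (mode == 1) {
      for (int i = 0; i < M; ++i) if (bz[i] < -tol) return false;
    }
    for (int l = 0; l < L; ++l) {
      if (mode != 0 && lz[l] < lig_R[l] - tol) return false;
      double R2 = (lig_R[l] - tol) * (lig_R[l] - tol);
      for (int i = 0; i < M; ++i) {
        if (i == lig_bead[l]) continue;
        double dx = bx[i] - lx[l], dy = by[i] - ly[l], dz = bz[i] - lz[l];
        if (dx * dx + dy * dy + dz * dz < R2) return false;
      }
      for (int m = l + 1; m < L; ++m) {
        double s = lig_R[l] + lig_R[m] - tol;
        double dx = lx[l] - lx[m], dy = ly[l] - ly[m], dz = lz[l] - lz[m];
        if (dx * dx + dy * dy + dz * dz < s * s) return false;
      }
    }
    return true;
  }

  double energy_all() const {
    double e = 0.0;
    if (mode == 0) return 0.0;
    for (int i = 0; i < M; ++i) e += bead_energy(bz[i], cls[i], pot, mode);
    return e;
  }
};

void init_straight(System &S, RNG &rng, int attempt) {
  for (int c = 0; c < S.n_chain; ++c) {
    double dx = 0, dy = 0, dz = 1;
    if (attempt > 0) {
      double th = rng.unif() * 0.9, ph = rng.unif() * 6.283185307179586;
      dx = std::sin(th) * std::cos(ph);
      dy = std::sin(th) * std::sin(ph);
      dz = std::cos(th);
    }
    for (int k = 1; k <= S.len[c]; ++k) {
      int i = S.gidx(c, k);
      S.bx[i] = S.ax[c] + S.bond * k * dx;
      S.by[i] = S.ay[c] + S.bond * k * dy;
      S.bz[i] = S.az[c] + S.bond * k * dz;
    }
  }
  // centroid of the anchors: ligands start pointing radially outward,
  // perpendicular to their chain, so neither the chain nor the neighbours
  // run through them
  double cx = 0, cy = 0;
  for (int c = 0; c < S.n_chain; ++c) { cx += S.ax[c]; cy += S.ay[c]; }
  cx /= S.n_chain; cy /= S.n_chain;
  for (int l = 0; l < S.L; ++l) {
    int i = S.lig_bead[l];
    double ox = S.bx[i] - cx, oy = S.by[i] - cy;
    double on = std::sqrt(ox * ox + oy * oy);
    if (on < 1e-6 || attempt > 2) {  // degenerate or later retries: random azimuth
      double phi = 2.399963 * l + (attempt > 0 ? rng.unif() * 6.2831853 : 0.0);
      ox = std::cos(phi); oy = std::sin(phi); on = 1.0;
    }
    ox /= on; oy /= on;
    // chain direction at the site (straight chain: bead direction from anchor)
    int c = 0;
    while (c + 1 < S.n_chain && S.off[c + 1] <= i) ++c;
    double dxc = S.bx[i] - S.ax[c], dyc = S.by[i] - S.ay[c], dzc = S.bz[i] - S.az[c];
    double dn = std::sqrt(dxc * dxc + dyc * dyc + dzc * dzc);
    dxc /= dn; dyc /= dn; dzc /= dn;
    double vx = ox, vy = oy, vz = (attempt > 0) ? rng.unif() * 0.2 : 0.0;
    double dot = vx * dxc + vy * dyc + vz * dzc;
    vx -= dot * dxc; vy -= dot * dyc; vz -= dot * dzc;
    double n = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (n < 1e-9) { vx = ox; vy = oy; vz = 0; n = 1.0; }
    vx /= n; vy /= n; vz /= n;
    S.ux[l] = vx; S.uy[l] = vy; S.uz[l] = vz;
    S.lx[l] = S.bx[i] + S.lig_R[l] * vx;
    S.ly[l] = S.by[i] + S.lig_R[l] * vy;
    S.lz[l] = S.bz[i] + S.lig_R[l] * vz;
  }
}

}  // namespace

// [[Rcpp::export]]
List mh_sample_cpp(NumericMatrix anchors, IntegerVector chain_len, double bond,
                   IntegerVector bead_class, IntegerMatrix rigid,
                   NumericMatrix ligands, NumericMatrix lig_u0,
                   IntegerMatrix probe_sites, double probe_radius,
                   int probe_exclude, int probe_mode,
                   int membrane_mode, NumericVector pot,
                   int n_record, int thin, int burnin, int adapt_window,
                   double step_init, double target_acc, double seed,
                   int max_init_tries, NumericMatrix init_beads) {
  System S;
  S.n_chain = chain_len.size();
  S.bond = bond;
  S.mode = membrane_mode;
  S.len.assign(chain_len.begin(), chain_len.end());
  S.off.resize(S.n_chain);
  int M = 0;
  for (int c = 0; c < S.n_chain; ++c) { S.off[c] = M; M += S.len[c]; }
  S.M = M;
  S.ax.resize(S.n_chain); S.ay.resize(S.n_chain); S.az.resize(S.n_chain);
  for (int c = 0; c < S.n_chain; ++c) {
    S.ax[c] = anchors(c, 0); S.ay[c] = anchors(c, 1); S.az[c] = anchors(c, 2);
  }
  S.cls.assign(bead_class.begin(), bead_class.end());
  for (int k = 0; k < 5; ++k) S.pot[k] = pot[k];
  S.L = ligands.nrow();
  S.lig_bead.resize(S.L); S.lig_R.resize(S.L);
  for (int l = 0; l < S.L; ++l) {
    S.lig_bead[l] = S.gidx((int)ligands(l, 0) - 1, (int)ligands(l, 1));
    S.lig_R[l] = ligands(l, 2);
  }
  S.bx.assign(M, 0.0); S.by.assign(M, 0.0); S.bz.assign(M, 0.0);
  S.lx.assign(S.L, 0.0); S.ly.assign(S.L, 0.0); S.lz.assign(S.L, 0.0);
  S.ux.assign(S.L, 0.0); S.uy.assign(S.L, 0.0); S.uz.assign(S.L, 1.0);
  S.build_joints(rigid);

  RNG rng((uint64_t)seed);

  // initial configuration
  bool ok_init = false;
  if (init_beads.nrow() == M) {
    for (int i = 0; i < M; ++i) {
      S.bx[i] = init_beads(i, 0); S.by[i] = init_beads(i, 1); S.bz[i] = init_beads(i, 2);
    }
    if (lig_u0.nrow() == S.L) {
      for (int l = 0; l < S.L; ++l) {
        S.ux[l] = lig_u0(l, 0); S.uy[l] = lig_u0(l, 1); S.uz[l] = lig_u0(l, 2);
        int i = S.lig_bead[l];
        S.lx[l] = S.bx[i] + S.lig_R[l] * S.ux[l];
        S.ly[l] = S.by[i] + S.lig_R[l] * S.uy[l];
        S.lz[l] = S.bz[i] + S.lig_R[l] * S.uz[l];
      }
    }
    ok_init = S.valid_all();
  } else {
    for (int t = 0; t <= max_init_tries && !ok_init; ++t) {
      init_straight(S, rng, t);
      ok_init = S.valid_all();
    }
  }
  if (!ok_init) {
    return List::create(Named("ok_init") = false);
  }

  int nJ = (int)S.joint_chain.size();
  int n_prop = nJ + S.L;
  // contiguous per-chain slices of the joint list (for composed sub-pivots)
  std::vector<int> chain_joint_lo(S.n_chain, 0), chain_joint_n(S.n_chain, 0);
  for (int k = 0; k < nJ; ++k) {
    if (chain_joint_n[S.joint_chain[k]] == 0) chain_joint_lo[S.joint_chain[k]] = k;
    ++chain_joint_n[S.joint_chain[k]];
  }
  double step = step_init;
  // with no membrane and no ligands nothing can reject a pivot, so composed
  // perturbations buy nothing: cap the step at a half-turn in that case
  const double step_min = 1e-4;
  const double step_max = (S.mode == 0 && S.L == 0) ? 3.14159265358979 : 40.0;
  int nS = probe_sites.nrow();
  std::vector<int> site_bead(nS), skip_lo(nS), skip_hi(nS);
  for (int s = 0; s < nS; ++s) {
    int c = probe_sites(s, 0) - 1, res = probe_sites(s, 1);
    site_bead[s] = S.gidx(c, res);
    // residues engulfed by the bound ligand's groove are not obstacles
    skip_lo[s] = S.gidx(c, std::max(1, res - probe_exclude));
    skip_hi[s] = S.gidx(c, std::min(S.len[c], res + probe_exclude));
  }

  IntegerMatrix occ(n_record, nS);
  NumericMatrix site_z(n_record, nS);
  NumericMatrix end_xyz(n_record, 3 * S.n_chain);

  std::vector<double> nbx(M), nby(M), nbz(M);   // proposed coords (moved subset)
  std::vector<char> is_moved(M, 0);
  std::vector<double> nlx(S.L), nly(S.L), nlz(S.L), nux(S.L), nuy(S.L), nuz(S.L);
  std::vector<char> lig_moved(S.L, 0);
  const double tol = 1e-9;

  long long total_props = (long long)burnin + (long long)n_record * thin;
  long long acc_meas = 0, n_meas = 0;
  int acc_win = 0, win_n = 0;
  int rec = 0;

  for (long long it = 0; it < total_props; ++it) {
    bool in_burn = it < burnin;
    int pick = (int)(rng.unif() * n_prop);
    if (pick >= n_prop) pick = n_prop - 1;
    bool accepted = false;

    if (pick < nJ) {
      // ---- pivot move ----
      // The adaptive perturbation size `step` sets the rotation angle; once
      // the angle saturates (a single pivot cannot exceed a half-turn) the
      // surplus is spent on composing several pivots on the same chain, so
      // the acceptance rate remains controllable down to the 0.44 target.
      int c = S.joint_chain[pick];
      int m_sub = 1 + (int)(step / 3.14159265358979);
      double ang_scale = step / m_sub;
      int g0c = S.gidx(c, 1), g1 = S.gidx(c, S.len[c]);
      for (int i = g0c; i <= g1; ++i) { nbx[i] = S.bx[i]; nby[i] = S.by[i]; nbz[i] = S.bz[i]; }
      for (int l = 0; l < S.L; ++l) {
        lig_moved[l] = (S.lig_bead[l] >= g0c && S.lig_bead[l] <= g1);
        if (lig_moved[l]) {
          nlx[l] = S.lx[l]; nly[l] = S.ly[l]; nlz[l] = S.lz[l];
          nux[l] = S.ux[l]; nuy[l] = S.uy[l]; nuz[l] = S.uz[l];
        }
      }
      int jmin = S.joint_j[pick];
      for (int t = 0; t < m_sub; ++t) {
        int j;
        if (t == 0) {
          j = S.joint_j[pick];
        } else {
          int lo = chain_joint_lo[c], n_cj = chain_joint_n[c];
          j = S.joint_j[lo + (int)(rng.unif() * n_cj)];
        }
        if (j < jmin) jmin = j;
        Rot Rt;
        rng.unit_sphere(Rt.kx, Rt.ky, Rt.kz);
        double ang = ang_scale * rng.norm();
        Rt.ca = std::cos(ang); Rt.sa = std::sin(ang);
        if (j == 1) { Rt.px = S.ax[c]; Rt.py = S.ay[c]; Rt.pz = S.az[c]; }
        else { int p = S.gidx(c, j - 1); Rt.px = nbx[p]; Rt.py = nby[p]; Rt.pz = nbz[p]; }
        for (int i = S.gidx(c, j); i <= g1; ++i) Rt.apply(nbx[i], nby[i], nbz[i]);
        for (int l = 0; l < S.L; ++l) {
          if (!lig_moved[l] || S.lig_bead[l] < S.gidx(c, j)) continue;
          Rt.apply(nlx[l], nly[l], nlz[l]);
          Rt.apply_vec(nux[l], nuy[l], nuz[l]);
        }
      }
      int g0 = S.gidx(c, jmin);
      bool valid = true;
      double dE = 0.0;
      for (int i = g0; i <= g1; ++i) {
        if (S.mode == 1 && nbz[i] < -tol) { valid = false; break; }
        if (S.mode != 0) dE += bead_energy(nbz[i], S.cls[i], S.pot, S.mode) -
                                bead_energy(S.bz[i], S.cls[i], S.pot, S.mode);
      }
      if (valid && S.L > 0) {
        for (int i = g0; i <= g1; ++i) is_moved[i] = 1;
        int n_lig_moved = 0;
        for (int l = 0; l < S.L; ++l) {
          lig_moved[l] = lig_moved[l] && (S.lig_bead[l] >= g0);
          if (lig_moved[l]) {
            ++n_lig_moved;
            if (S.mode != 0 && nlz[l] < S.lig_R[l] - tol) { valid = false; break; }
          }
        }
        if (valid) {
          // moved beads vs unmoved ligands
          for (int l = 0; l < S.L && valid; ++l) {
            if (lig_moved[l]) continue;
            double R2 = (S.lig_R[l] - tol) * (S.lig_R[l] - tol);
            for (int i = g0; i <= g1; ++i) {
              double dx = nbx[i] - S.lx[l], dy = nby[i] - S.ly[l], dz = nbz[i] - S.lz[l];
              if (dx * dx + dy * dy + dz * dz < R2) { valid = false; break; }
            }
          }
          // moved ligands vs everything else
          for (int l = 0; l < S.L && valid && n_lig_moved > 0; ++l) {
            if (!lig_moved[l]) continue;
            double R2 = (S.lig_R[l] - tol) * (S.lig_R[l] - tol);
            for (int i = 0; i < M; ++i) {
              if (is_moved[i]) continue;
              double dx = S.bx[i] - nlx[l], dy = S.by[i] - nly[l], dz = S.bz[i] - nlz[l];
              if (dx * dx + dy * dy + dz * dz < R2) { valid = false; break; }
            }
            if (valid && m_sub > 1) {
              // composed sub-pivots are not one rigid transform: moved beads
              // and moved ligands can change relative position
              for (int i = g0; i <= g1; ++i) {
                if (i == S.lig_bead[l]) continue;
                double dx = nbx[i] - nlx[l], dy = nby[i] - nly[l], dz = nbz[i] - nlz[l];
                if (dx * dx + dy * dy + dz * dz < R2) { valid = false; break; }
              }
            }
            for (int m = 0; m < S.L && valid; ++m) {
              if (m == l) continue;
              if (lig_moved[m]) {
                if (m_sub == 1 || m < l) continue;
                double sR = S.lig_R[l] + S.lig_R[m] - tol;
                double dx = nlx[m] - nlx[l], dy = nly[m] - nly[l], dz = nlz[m] - nlz[l];
                if (dx * dx + dy * dy + dz * dz < sR * sR) { valid = false; break; }
              } else {
                double sR = S.lig_R[l] + S.lig_R[m] - tol;
                double dx = S.lx[m] - nlx[l], dy = S.ly[m] - nly[l], dz = S.lz[m] - nlz[l];
                if (dx * dx + dy * dy + dz * dz < sR * sR) { valid = false; break; }
              }
            }
          }
        }
        for (int i = g0; i <= g1; ++i) is_moved[i] = 0;
      }
      if (valid && (dE <= 0.0 || rng.unif() < std::exp(-dE))) {
        for (int i = g0; i <= g1; ++i) { S.bx[i] = nbx[i]; S.by[i] = nby[i]; S.bz[i] = nbz[i]; }
        for (int l = 0; l < S.L; ++l) {
          if (!lig_moved[l]) continue;
          S.lx[l] = nlx[l]; S.ly[l] = nly[l]; S.lz[l] = nlz[l];
          S.ux[l] = nux[l]; S.uy[l] = nuy[l]; S.uz[l] = nuz[l];
        }
        accepted = true;
      }
    } else {
      // ---- ligand reorientation ----
      int l = pick - nJ;
      Rot Rt;
      rng.unit_sphere(Rt.kx, Rt.ky, Rt.kz);
      double ang = std::min(step, 3.14159265358979) * rng.norm();
      Rt.ca = std::cos(ang); Rt.sa = std::sin(ang);
      double vx = S.ux[l], vy = S.uy[l], vz = S.uz[l];
      Rt.apply_vec(vx, vy, vz);
      int ib = S.lig_bead[l];
      double cx2 = S.bx[ib] + S.lig_R[l] * vx;
      double cy2 = S.by[ib] + S.lig_R[l] * vy;
      double cz2 = S.bz[ib] + S.lig_R[l] * vz;
      bool valid = !(S.mode != 0 && cz2 < S.lig_R[l] - tol);
      if (valid) {
        double R2 = (S.lig_R[l] - tol) * (S.lig_R[l] - tol);
        for (int i = 0; i < M; ++i) {
          if (i == ib) continue;
          double dx = S.bx[i] - cx2, dy = S.by[i] - cy2, dz = S.bz[i] - cz2;
          if (dx * dx + dy * dy + dz * dz < R2) { valid = false; break; }
        }
        for (int m = 0; m < S.L && valid; ++m) {
          if (m == l) continue;
          double sR = S.lig_R[l] + S.lig_R[m] - tol;
          double dx = S.lx[m] - cx2, dy = S.ly[m] - cy2, dz = S.lz[m] - cz2;
          if (dx * dx + dy * dy + dz * dz < sR * sR) { valid = false; break; }
        }
      }
      if (valid) {
        S.ux[l] = vx; S.uy[l] = vy; S.uz[l] = vz;
        S.lx[l] = cx2; S.ly[l] = cy2; S.lz[l] = cz2;
        accepted = true;
      }
    }

    if (in_burn) {
      ++win_n;
      if (accepted) ++acc_win;
      if (win_n == adapt_window) {
        double rate = (double)acc_win / win_n;
        if (rate > target_acc) step *= 1.05; else step /= 1.05;
        if (step > step_max) step = step_max;
        if (step < step_min) step = step_min;
        win_n = 0; acc_win = 0;
      }
    } else {
      ++n_meas;
      if (accepted) ++acc_meas;
      if ((it - burnin + 1) % thin == 0 && rec < n_record) {
        for (int s = 0; s < nS; ++s) {
          int i = site_bead[s];
          site_z(rec, s) = S.bz[i];
          double cx2, cy2, cz2;
          if (probe_mode == 1) {
            // region centred on the engulfed site
            cx2 = S.bx[i]; cy2 = S.by[i]; cz2 = S.bz[i];
          } else if (probe_mode == 2) {
            // fixed-normal: probe sits directly above the site
            cx2 = S.bx[i]; cy2 = S.by[i]; cz2 = S.bz[i] + probe_radius;
          } else {
            // tangent sphere, random approach direction per sample
            double dx, dy, dz;
            rng.unit_sphere(dx, dy, dz);
            cx2 = S.bx[i] + probe_radius * dx;
            cy2 = S.by[i] + probe_radius * dy;
            cz2 = S.bz[i] + probe_radius * dz;
          }
          int blocked = 0;
          if (S.mode != 0 && cz2 < probe_radius) blocked = 1;
          if (!blocked) {
            double R2 = probe_radius * probe_radius;
            for (int b = 0; b < M; ++b) {
              if (b >= skip_lo[s] && b <= skip_hi[s]) continue;
              double qx = S.bx[b] - cx2, qy = S.by[b] - cy2, qz = S.bz[b] - cz2;
              if (qx * qx + qy * qy + qz * qz < R2) { blocked = 1; break; }
            }
          }
          if (!blocked) {
            for (int l = 0; l < S.L; ++l) {
              double sR = probe_radius + S.lig_R[l];
              double qx = S.lx[l] - cx2, qy = S.ly[l] - cy2, qz = S.lz[l] - cz2;
              if (qx * qx + qy * qy + qz * qz < sR * sR) { blocked = 1; break; }
            }
          }
          occ(rec, s) = blocked;
        }
        for (int c = 0; c < S.n_chain; ++c) {
          int e = S.gidx(c, S.len[c]);
          end_xyz(rec, 3 * c) = S.bx[e];
          end_xyz(rec, 3 * c + 1) = S.by[e];
          end_xyz(rec, 3 * c + 2) = S.bz[e];
        }
        ++rec;
      }
    }
  }

  NumericMatrix beads_out(M, 3);
  for (int i = 0; i < M; ++i) {
    beads_out(i, 0) = S.bx[i]; beads_out(i, 1) = S.by[i]; beads_out(i, 2) = S.bz[i];
  }
  NumericMatrix ligu_out(S.L, 3);
  for (int l = 0; l < S.L; ++l) {
    ligu_out(l, 0) = S.ux[l]; ligu_out(l, 1) = S.uy[l]; ligu_out(l, 2) = S.uz[l];
  }
  return List::create(
    Named("ok_init") = true,
    Named("occ") = occ,
    Named("site_z") = site_z,
    Named("end_xyz") = end_xyz,
    Named("acc_rate") = n_meas > 0 ? (double)acc_meas / n_meas : NA_REAL,
    Named("step") = step,
    Named("beads") = beads_out,
    Named("lig_u") = ligu_out);
}

// Reversible (de)phosphorylation cycle on a 2^n-state lattice.
// kin, pho: 2^n x n matrices of per-site rates (0 where inapplicable).
// Returns the time-averaged fraction of sites phosphorylated after discarding
// the first burn_frac of events.
// [[Rcpp::export]]
List gillespie_cycle_cpp(NumericMatrix kin, NumericMatrix pho, double ratio,
                         double n_events, double burn_frac, double seed) {
  int n = kin.ncol();
  
  RNG rng((uint64_t)seed);
  int state = 0;
  long long nev = (long long)n_events;
  long long burn = (long long)(burn_frac * n_events);
  double tsum = 0.0, wsum = 0.0;
  std::vector<double> r(2 * n);
  for (long long ev = 0; ev < nev; ++ev) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      bool occ = (state >> i) & 1;
      r[i] = occ ? 0.0 : ratio * kin(state, i);
      r[n + i] = occ ? pho(state, i) : 0.0;
      tot += r[i] + r[n + i];
    }
    if (tot <= 0.0) {
      return List::create(Named("mean_frac") = NA_REAL,
                          Named("absorbed_state") = state);
    }
    double dt = -std::log(rng.unif()) / tot;
    if (ev >= burn) {
      int np = 0;
      for (int i = 0; i < n; ++i) np += (state >> i) & 1;
      tsum += dt;
      wsum += dt * np;
    }
    double u = rng.unif() * tot;
    double acc = 0.0;
    int chosen = 0;
    for (int i = 0; i < 2 * n; ++i) {
      acc += r[i];
      if (u <= acc) { chosen = i; break; }
    }
    if (chosen < n) state |= (1 << chosen);
    else state &= ~(1 << (chosen - n));
  }
  return List::create(Named("mean_frac") = (tsum > 0) ? wsum / (tsum * n) : NA_REAL,
                      Named("absorbed_state") = -1);
}

// Simulated-annealing search for a sterically valid configuration with all
// ligands bound. Minimises a squared-overlap penalty; a zero penalty means a
// feasible witness (re-validated independently in R).
// [[Rcpp::export]]
List pack_anneal_cpp(NumericMatrix anchors, IntegerVector chain_len, double bond,
                     NumericMatrix beads0, NumericMatrix ligands,
                     NumericMatrix lig_u0, double n_iter, double T0, double T1,
                     double step0, double seed) {
  System S;
  S.n_chain = chain_len.size();
  S.bond = bond;
  S.mode = 1;
  S.len.assign(chain_len.begin(), chain_len.end());
  S.off.resize(S.n_chain);
  int M = 0;
  for (int c = 0; c < S.n_chain; ++c) { S.off[c] = M; M += S.len[c]; }
  S.M = M;
  S.ax.resize(S.n_chain); S.ay.resize(S.n_chain); S.az.resize(S.n_chain);
  for (int c = 0; c < S.n_chain; ++c) {
    S.ax[c] = anchors(c, 0); S.ay[c] = anchors(c, 1); S.az[c] = anchors(c, 2);
  }
  S.cls.assign(M, 0);
  S.L = ligands.nrow();
  S.lig_bead.resize(S.L); S.lig_R.resize(S.L);
  for (int l = 0; l < S.L; ++l) {
    S.lig_bead[l] = S.gidx((int)ligands(l, 0) - 1, (int)ligands(l, 1));
    S.lig_R[l] = ligands(l, 2);
  }
  S.bx.resize(M); S.by.resize(M); S.bz.resize(M);
  for (int i = 0; i < M; ++i) {
    S.bx[i] = beads0(i, 0); S.by[i] = beads0(i, 1); S.bz[i] = beads0(i, 2);
  }
  S.lx.resize(S.L); S.ly.resize(S.L); S.lz.resize(S.L);
  S.ux.resize(S.L); S.uy.resize(S.L); S.uz.resize(S.L);
  for (int l = 0; l < S.L; ++l) {
    S.ux[l] = lig_u0(l, 0); S.uy[l] = lig_u0(l, 1); S.uz[l] = lig_u0(l, 2);
    int i = S.lig_bead[l];
    S.lx[l] = S.bx[i] + S.lig_R[l] * S.ux[l];
    S.ly[l] = S.by[i] + S.lig_R[l] * S.uy[l];
    S.lz[l] = S.bz[i] + S.lig_R[l] * S.uz[l];
  }
  IntegerMatrix no_rigid(0, 3);
  S.build_joints(no_rigid);
  RNG rng((uint64_t)seed);

  auto penalty_full = [&]() {
    double p = 0.0;
    for (int i = 0; i < M; ++i) if (S.bz[i] < 0) p += S.bz[i] * S.bz[i];
    for (int l = 0; l < S.L; ++l) {
      if (S.lz[l] < S.lig_R[l]) {
        double d = S.lig_R[l] - S.lz[l];
        p += d * d;
      }
      for (int i = 0; i < M; ++i) {
        if (i == S.lig_bead[l]) continue;
        double dx = S.bx[i] - S.lx[l], dy = S.by[i] - S.ly[l], dz = S.bz[i] - S.lz[l];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < S.lig_R[l] * S.lig_R[l]) {
          double d = S.lig_R[l] - std::sqrt(d2);
          p += d * d;
        }
      }
      for (int m = l + 1; m < S.L; ++m) {
        double sR = S.lig_R[l] + S.lig_R[m];
        double dx = S.lx[m] - S.lx[l], dy = S.ly[m] - S.ly[l], dz = S.lz[m] - S.lz[l];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < sR * sR) {
          double d = sR - std::sqrt(d2);
          p += d * d;
        }
      }
    }
    return p;
  };

  double pen = penalty_full();
  int nJ = (int)S.joint_chain.size();
  int n_prop = nJ + S.L;
  long long iters = (long long)n_iter;
  double cool = (iters > 1) ? std::pow(T1 / T0, 1.0 / (double)(iters - 1)) : 1.0;
  double T = T0;
  std::vector<double> nbx(M), nby(M), nbz(M);
  std::vector<double> nlx(S.L), nly(S.L), nlz(S.L), nux(S.L), nuy(S.L), nuz(S.L);
  std::vector<char> lig_moved(S.L, 0), is_moved(M, 0);

  // penalty contribution of a configuration subset: moved items vs unmoved
  // items plus membrane terms of moved items (interactions within the moved
  // rigid unit are unchanged by the move)
  auto pen_subset = [&](int g0, int g1, bool use_new) {
    double p = 0.0;
    for (int i = g0; i <= g1; ++i) {
      double zi = use_new ? nbz[i] : S.bz[i];
      if (zi < 0) p += zi * zi;
    }
    for (int l = 0; l < S.L; ++l) {
      double cx2 = lig_moved[l] ? (use_new ? nlx[l] : S.lx[l]) : S.lx[l];
      double cy2 = lig_moved[l] ? (use_new ? nly[l] : S.ly[l]) : S.ly[l];
      double cz2 = lig_moved[l] ? (use_new ? nlz[l] : S.lz[l]) : S.lz[l];
      if (lig_moved[l]) {
        if (cz2 < S.lig_R[l]) {
          double d = S.lig_R[l] - cz2;
          p += d * d;
        }
        // moved ligand vs unmoved beads
        for (int i = 0; i < M; ++i) {
          if (is_moved[i] || i == S.lig_bead[l]) continue;
          double dx = S.bx[i] - cx2, dy = S.by[i] - cy2, dz = S.bz[i] - cz2;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < S.lig_R[l] * S.lig_R[l]) {
            double d = S.lig_R[l] - std::sqrt(d2);
            p += d * d;
          }
        }
        // moved ligand vs unmoved ligands
        for (int m = 0; m < S.L; ++m) {
          if (lig_moved[m]) continue;
          double sR = S.lig_R[l] + S.lig_R[m];
          double dx = S.lx[m] - cx2, dy = S.ly[m] - cy2, dz = S.lz[m] - cz2;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < sR * sR) {
            double d = sR - std::sqrt(d2);
            p += d * d;
          }
        }
      } else {
        // unmoved ligand vs moved beads
        for (int i = g0; i <= g1; ++i) {
          if (i == S.lig_bead[l]) continue;
          double xi = use_new ? nbx[i] : S.bx[i];
          double yi = use_new ? nby[i] : S.by[i];
          double zi = use_new ? nbz[i] : S.bz[i];
          double dx = xi - cx2, dy = yi - cy2, dz = zi - cz2;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < S.lig_R[l] * S.lig_R[l]) {
            double d = S.lig_R[l] - std::sqrt(d2);
            p += d * d;
          }
        }
      }
    }
    return p;
  };

  for (long long it = 0; it < iters; ++it, T *= cool) {
    int pick = (int)(rng.unif() * n_prop);
    if (pick >= n_prop) pick = n_prop - 1;
    double step = step0 * (0.15 + T / T0);
    if (pick < nJ) {
      int c = S.joint_chain[pick], j = S.joint_j[pick];
      Rot Rt;
      rng.unit_sphere(Rt.kx, Rt.ky, Rt.kz);
      double ang = step * rng.norm();
      Rt.ca = std::cos(ang); Rt.sa = std::sin(ang);
      if (j == 1) { Rt.px = S.ax[c]; Rt.py = S.ay[c]; Rt.pz = S.az[c]; }
      else { int p = S.gidx(c, j - 1); Rt.px = S.bx[p]; Rt.py = S.by[p]; Rt.pz = S.bz[p]; }
      int g0 = S.gidx(c, j), g1 = S.gidx(c, S.len[c]);
      for (int i = g0; i <= g1; ++i) {
        double x = S.bx[i], y = S.by[i], z = S.bz[i];
        Rt.apply(x, y, z);
        nbx[i] = x; nby[i] = y; nbz[i] = z;
        is_moved[i] = 1;
      }
      for (int l = 0; l < S.L; ++l) {
        lig_moved[l] = (S.lig_bead[l] >= g0 && S.lig_bead[l] <= g1);
        if (lig_moved[l]) {
          double x = S.lx[l], y = S.ly[l], z = S.lz[l];
          Rt.apply(x, y, z);
          nlx[l] = x; nly[l] = y; nlz[l] = z;
          double vx = S.ux[l], vy = S.uy[l], vz = S.uz[l];
          Rt.apply_vec(vx, vy, vz);
          nux[l] = vx; nuy[l] = vy; nuz[l] = vz;
        }
      }
      double p_old = pen_subset(g0, g1, false);
      double p_new = pen_subset(g0, g1, true);
      double dP = p_new - p_old;
      if (dP <= 0.0 || (T > 0 && rng.unif() < std::exp(-dP / T))) {
        for (int i = g0; i <= g1; ++i) { S.bx[i] = nbx[i]; S.by[i] = nby[i]; S.bz[i] = nbz[i]; }
        for (int l = 0; l < S.L; ++l) {
          if (!lig_moved[l]) continue;
          S.lx[l] = nlx[l]; S.ly[l] = nly[l]; S.lz[l] = nlz[l];
          S.ux[l] = nux[l]; S.uy[l] = nuy[l]; S.uz[l] = nuz[l];
        }
        pen += dP;
      }
      for (int i = g0; i <= g1; ++i) is_moved[i] = 0;
      for (int l = 0; l < S.L; ++l) lig_moved[l] = 0;
    } else {
      int l = pick - nJ;
      Rot Rt;
      rng.unit_sphere(Rt.kx, Rt.ky, Rt.kz);
      double ang = std::min(step, 3.14159265358979) * rng.norm();
      Rt.ca = std::cos(ang); Rt.sa = std::sin(ang);
      double vx = S.ux[l], vy = S.uy[l], vz = S.uz[l];
      Rt.apply_vec(vx, vy, vz);
      int ib = S.lig_bead[l];
      lig_moved[l] = 1;
      nux[l] = vx; nuy[l] = vy; nuz[l] = vz;
      nlx[l] = S.bx[ib] + S.lig_R[l] * vx;
      nly[l] = S.by[ib] + S.lig_R[l] * vy;
      nlz[l] = S.bz[ib] + S.lig_R[l] * vz;
      // moved set: the single ligand; g0>g1 so no beads
      double p_old = pen_subset(1, 0, false);
      double p_new = pen_subset(1, 0, true);
      double dP = p_new - p_old;
      if (dP <= 0.0 || (T > 0 && rng.unif() < std::exp(-dP / T))) {
        S.lx[l] = nlx[l]; S.ly[l] = nly[l]; S.lz[l] = nlz[l];
        S.ux[l] = nux[l]; S.uy[l] = nuy[l]; S.uz[l] = nuz[l];
        pen += dP;
      }
      lig_moved[l] = 0;
    }
    if ((it & 0xFFFF) == 0xFFFF) pen = penalty_full();  // guard numeric drift
  }
  pen = penalty_full();
  NumericMatrix beads_out(M, 3);
  for (int i = 0; i < M; ++i) {
    beads_out(i, 0) = S.bx[i]; beads_out(i, 1) = S.by[i]; beads_out(i, 2) = S.bz[i];
  }
  NumericMatrix ligu_out(S.L, 3);
  for (int l = 0; l < S.L; ++l) {
    ligu_out(l, 0) = S.ux[l]; ligu_out(l, 1) = S.uy[l]; ligu_out(l, 2) = S.uz[l];
  }
  return List::create(Named("penalty") = pen,
                      Named("beads") = beads_out,
                      Named("lig_u") = ligu_out);
}
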