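// Metropolis Monte Carlo engine for the nucleosome-level toy chromatin model.
//
// State: per nucleosome a center (nm), an orthonormal frame (in-plane axis a
// and plane normal n; b = n x a implicitly), a wrap fraction in [0.5, 1] and
// a chain id.  Energies in kcal/mol.
//
// Energy terms:
//  - linker springs between consecutive nucleosomes, rest length
//    L0 + (lambda/2) ((1-w_i) + (1-w_j)); asymmetric: stiff when stretched
//    beyond rest (contour-limited DNA), soft under compression (slack DNA
//    bends cheaply);
//  - anisotropic nonbonded term for pairs |i-j| >= 2 (and all cross-chain
//    pairs): ellipsoidal inverse-12 repulsion plus a face-face stacking well
//    of depth eps_stack at center distance r_stack, gated by mutual normal
//    alignment so that stacking is favorable and side-side contact is not;
//  - outer-layer unwrapping penalty eps_unwrap * (1 - w);
//  - biases: harmonic umbrellas on d_stack / q_wrap / ee_z, a constant
//    pulling force along z applied to the terminal nucleosome centers of
//    each chain, and a harmonic tether on a single center (calibration).
//
// Uses R's RNG so that set.seed() in R makes runs bitwise reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PN_PER_KCAL_NM = 6.948;

struct Model {
  double eps_stack, r_stack, stack_width;
  double sigma_inplane, sigma_normal, eps_rep;
  double k_link, k_link_compress, L0, lambda_release;
  double eps_unwrap, cutoff;
  bool allow_unwrap;
};

enum BiasKind { UMBRELLA = 0, CONSTANT_FORCE = 1, TETHER = 2 };
enum CvCode { CV_DSTACK = 0, CV_QWRAP = 1, CV_EEZ = 2 };

struct BiasSpec {
  int kind;
  int cv;
  double center, k, force_pN;
  int nuc;            // 0-based global index (tether)
  double ref[3];
};

struct State {
  int N, nchain;
  std::vector<double> cx, cy, cz;        // centers
  std::vector<double> ax, ay, az;        // in-plane axis a
  std::vector<double> nx, ny, nz;        // normal
  std::vector<double> wrap;
  std::vector<int> chain_start, chain_len;  // per chain
  std::vector<int> chain_of;                // per nucleosome
};

static Model parse_model(List m) {
  Model md;
  md.eps_stack = as<double>(m["eps_stack"]);
  md.r_stack = as<double>(m["r_stack"]);
  md.stack_width = as<double>(m["stack_width"]);
  md.sigma_inplane = as<double>(m["sigma_inplane"]);
  md.sigma_normal = as<double>(m["sigma_normal"]);
  md.eps_rep = as<double>(m["eps_rep"]);
  md.k_link = as<double>(m["k_link"]);
  md.k_link_compress = as<double>(m["k_link_compress"]);
  md.L0 = as<double>(m["L0"]);
  md.lambda_release = as<double>(m["lambda_release"]);
  md.eps_unwrap = as<double>(m["eps_unwrap"]);
  md.cutoff = as<double>(m["cutoff"]);
  md.allow_unwrap = as<bool>(m["allow_unwrap"]);
  return md;
}

static State parse_state(List s) {
  State st;
  NumericMatrix centers = s["centers"], aa = s["axis_a"], nn = s["normal"];
  NumericVector wrap = s["wrap"];
  IntegerVector chain = s["chain"];
  st.N = centers.nrow();
  st.cx.resize(st.N); st.cy.resize(st.N); st.cz.resize(st.N);
  st.ax.resize(st.N); st.ay.resize(st.N); st.az.resize(st.N);
  st.nx.resize(st.N); st.ny.resize(st.N); st.nz.resize(st.N);
  st.wrap.resize(st.N); st.chain_of.resize(st.N);
  for (int i = 0; i < st.N; ++i) {
    st.cx[i] = centers(i, 0); st.cy[i] = centers(i, 1); st.cz[i] = centers(i, 2);
    st.ax[i] = aa(i, 0); st.ay[i] = aa(i, 1); st.az[i] = aa(i, 2);
    st.nx[i] = nn(i, 0); st.ny[i] = nn(i, 1); st.nz[i] = nn(i, 2);
    st.wrap[i] = wrap[i];
    st.chain_of[i] = chain[i];
  }
  int cur = -1;
  for (int i = 0; i < st.N; ++i) {
    if (st.chain_of[i] != cur) {
      cur = st.chain_of[i];
      st.chain_start.push_back(i);
      st.chain_len.push_back(0);
    }
    st.chain_len.back()++;
  }
  st.nchain = (int)st.chain_start.size();
  return st;
}

static std::vector<BiasSpec> parse_biases(List biases) {
  std::vector<BiasSpec> out;
  for (int b = 0; b < biases.size(); ++b) {
    List bl = biases[b];
    BiasSpec bs;
    bs.kind = as<int>(bl["kind_code"]);
    bs.cv = as<int>(bl["cv_code"]);
    bs.center = as<double>(bl["center"]);
    bs.k = as<double>(bl["spring_k"]);
    bs.force_pN = as<double>(bl["force_pN"]);
    bs.nuc = as<int>(bl["nuc"]);
    NumericVector ref = bl["ref"];
    for (int d = 0; d < 3; ++d) bs.ref[d] = ref[d];
    out.push_back(bs);
  }
  return out;
}

static inline double dist(const State& st, int i, int j) {
  double dx = st.cx[j] - st.cx[i], dy = st.cy[j] - st.cy[i],
         dz = st.cz[j] - st.cz[i];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// ---- collective variables -------------------------------------------------

static double cv_value(const State& st, int code) {
  double acc = 0.0;
  int nch = 0;
  for (int c = 0; c < st.nchain; ++c) {
    int s = st.chain_start[c], n = st.chain_len[c];
    double v = 0.0;
    if (code == CV_DSTACK) {
      if (n < 3) stop("d_stack bias needs chains of >= 3 nucleosomes");
      for (int i = s; i < s + n - 2; ++i) v += dist(st, i, i + 2);
      v /= (n - 2);
    } else if (code == CV_QWRAP) {
      for (int i = s; i < s + n; ++i) v += st.wrap[i];
      v /= n;
    } else if (code == CV_EEZ) {
      v = (st.cz[s + n - 1] - st.cz[s]) / n;
    }
    acc += v; nch++;
  }
  return acc / nch;
}

static double bias_energy(const State& st, const std::vector<BiasSpec>& biases) {
  double e = 0.0;
  for (size_t b = 0; b < biases.size(); ++b) {
    const BiasSpec& bs = biases[b];
    if (bs.kind == UMBRELLA) {
      double d = cv_value(st, bs.cv) - bs.center;
      e += 0.5 * bs.k * d * d;
    } else if (bs.kind == CONSTANT_FORCE) {
      double ext = 0.0;
      for (int c = 0; c < st.nchain; ++c) {
        int s = st.chain_start[c], n = st.chain_len[c];
        ext += st.cz[s + n - 1] - st.cz[s];
      }
      e -= bs.force_pN / PN_PER_KCAL_NM * ext;
    } else if (bs.kind == TETHER) {
      double dx = st.cx[bs.nuc] - bs.ref[0], dy = st.cy[bs.nuc] - bs.ref[1],
             dz = st.cz[bs.nuc] - bs.ref[2];
      e += 0.5 * bs.k * (dx * dx + dy * dy + dz * dz);
    }
  }
  return e;
}

// ---- energy terms ---------------------------------------------------------

static double pair_energy(const State& st, const Model& md, int i, int j) {
  double rx = st.cx[j] - st.cx[i], ry = st.cy[j] - st.cy[i],
         rz = st.cz[j] - st.cz[i];
  double r2 = rx * rx + ry * ry + rz * rz;
  if (r2 > md.cutoff * md.cutoff) return 0.0;
  double r = std::sqrt(r2);
  // ellipsoidal repulsion evaluated in both frames; strongest overlap governs
  double ni_r = rx * st.nx[i] + ry * st.ny[i] + rz * st.nz[i];
  double nj_r = rx * st.nx[j] + ry * st.ny[j] + rz * st.nz[j];
  double sp2 = md.sigma_inplane * md.sigma_inplane;
  double sn2 = md.sigma_normal * md.sigma_normal;
  double si2 = (r2 - ni_r * ni_r) / sp2 + ni_r * ni_r / sn2;
  double sj2 = (r2 - nj_r * nj_r) / sp2 + nj_r * nj_r / sn2;
  double s2 = si2 < sj2 ? si2 : sj2;
  if (s2 < 1e-6) s2 = 1e-6;
  double inv = 1.0 / s2;
  double e_rep = md.eps_rep * inv * inv * inv * inv * inv * inv; // (1/s)^12
  double e_stack = 0.0;
  if (md.eps_stack > 0 && r > 1e-9) {
    double dd = r - md.r_stack;
    double radial = std::exp(-dd * dd / (2.0 * md.stack_width * md.stack_width));
    double cnn = st.nx[i] * st.nx[j] + st.ny[i] * st.ny[j] + st.nz[i] * st.nz[j];
    double ai = ni_r / r, aj = nj_r / r;
    double g = cnn * cnn * 0.5 * (ai * ai + aj * aj);
    e_stack = -md.eps_stack * radial * g;
  }
  return e_rep + e_stack;
}

static double linker_energy(const State& st, const Model& md, int i) {
  // linker between i and i+1 (same chain)
  double rest = md.L0 + 0.5 * md.lambda_release *
                          ((1.0 - st.wrap[i]) + (1.0 - st.wrap[i + 1]));
  double dl = dist(st, i, i + 1) - rest;
  double k = dl > 0 ? md.k_link : md.k_link_compress;
  return 0.5 * k * dl * dl;
}

static bool interacting(const State& st, int i, int j) {
  if (st.chain_of[i] != st.chain_of[j]) return true;
  int d = i > j ? i - j : j - i;
  return d >= 2;
}

static double local_energy(const State& st, const Model& md, int i) {
  double e = 0.0;
  for (int j = 0; j < st.N; ++j)
    if (j != i && interacting(st, i, j)) e += pair_energy(st, md, i, j);
  int c = st.chain_of[i];
  int s = 0;
  for (int k = 0; k < st.nchain; ++k)
    if (st.chain_start[k] <= i &&
        i < st.chain_start[k] + st.chain_len[k]) { s = k; break; }
  int cs = st.chain_start[s], cl = st.chain_len[s];
  (void)c;
  if (i > cs) e += linker_energy(st, md, i - 1);
  if (i < cs + cl - 1) e += linker_energy(st, md, i);
  e += md.eps_unwrap * (1.0 - st.wrap[i]);
  return e;
}

static double total_energy(const State& st, const Model& md,
                           const std::vector<BiasSpec>& biases) {
  double e = 0.0;
  for (int i = 0; i < st.N; ++i) {
    for (int j = i + 1; j < st.N; ++j)
      if (interacting(st, i, j)) e += pair_energy(st, md, i, j);
    e += md.eps_unwrap * (1.0 - st.wrap[i]);
  }
  for (int c = 0; c < st.nchain; ++c)
    for (int i = st.chain_start[c]; i < st.chain_start[c] + st.chain_len[c] - 1; ++i)
      e += linker_energy(st, md, i);
  return e + bias_energy(st, biases);
}

// [[Rcpp::export]]
double cpp_total_energy(List state, List model, List biases) {
  State st = parse_state(state);
  Model md = parse_model(model);
  std::vector<BiasSpec> bs = parse_biases(biases);
  return total_energy(st, md, bs);
}

// ---- moves ----------------------------------------------------------------

static void rotate_frame(State& st, int i, double ux, double uy, double uz,
                         double angle) {
  double c = std::cos(angle), s = std::sin(angle), t = 1.0 - c;
  double R[3][3] = {
    {c + ux * ux * t, ux * uy * t - uz * s, ux * uz * t + uy * s},
    {uy * ux * t + uz * s, c + uy * uy * t, uy * uz * t - ux * s},
    {uz * ux * t - uy * s, uz * uy * t + ux * s, c + uz * uz * t}};
  double a0 = st.ax[i], a1 = st.ay[i], a2 = st.az[i];
  double n0 = st.nx[i], n1 = st.ny[i], n2 = st.nz[i];
  st.ax[i] = R[0][0] * a0 + R[0][1] * a1 + R[0][2] * a2;
  st.ay[i] = R[1][0] * a0 + R[1][1] * a1 + R[1][2] * a2;
  st.az[i] = R[2][0] * a0 + R[2][1] * a1 + R[2][2] * a2;
  st.nx[i] = R[0][0] * n0 + R[0][1] * n1 + R[0][2] * n2;
  st.ny[i] = R[1][0] * n0 + R[1][1] * n1 + R[1][2] * n2;
  st.nz[i] = R[2][0] * n0 + R[2][1] * n1 + R[2][2] * n2;
}

// [[Rcpp::export]]
List cpp_run_mc(List state, List model, List biases, int n_sweeps, int stride,
                double kT, double d_trans, double d_rot, double d_wrap) {
  State st = parse_state(state);
  Model md = parse_model(model);
  std::vector<BiasSpec> bs = parse_biases(biases);

  bool any_bias_on_state = bs.size() > 0;
  double e_total = total_energy(st, md, bs);
  long n_moves = 0, n_acc = 0;

  double p_wrap = md.allow_unwrap ? 0.2 : 0.0;
  double p_trans = md.allow_unwrap ? 0.5 : 0.625;

  int n_snap = n_sweeps / stride;
  List snap_centers(n_snap), snap_axis_a(n_snap), snap_normal(n_snap),
       snap_wrap(n_snap);
  NumericVector snap_energy(n_snap);
  IntegerVector snap_step(n_snap);
  int ks = 0;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int m = 0; m < st.N; ++m) {
      int i = (int)(R::unif_rand() * st.N);
      if (i == st.N) i = st.N - 1;
      double u = R::unif_rand();
      double e_old = 0.0, e_new = 0.0, de_bias = 0.0;
      double bak[3];
      int move;
      if (u < p_trans) move = 0;
      else if (u < p_trans + p_wrap) move = 2;
      else move = 1;

      if (move == 0) {                       // rigid translation
        e_old = local_energy(st, md, i);
        double eb_old = any_bias_on_state ? bias_energy(st, bs) : 0.0;
        bak[0] = st.cx[i]; bak[1] = st.cy[i]; bak[2] = st.cz[i];
        st.cx[i] += d_trans * (2.0 * R::unif_rand() - 1.0);
        st.cy[i] += d_trans * (2.0 * R::unif_rand() - 1.0);
        st.cz[i] += d_trans * (2.0 * R::unif_rand() - 1.0);
        e_new = local_energy(st, md, i);
        double eb_new = any_bias_on_state ? bias_energy(st, bs) : 0.0;
        de_bias = eb_new - eb_old;
        double de = e_new - e_old + de_bias;
        ++n_moves;
        if (de <= 0 || R::unif_rand() < std::exp(-de / kT)) {
          e_total += de; ++n_acc;
        } else {
          st.cx[i] = bak[0]; st.cy[i] = bak[1]; st.cz[i] = bak[2];
        }
      } else if (move == 1) {                // rigid rotation (CVs unchanged)
        e_old = local_energy(st, md, i);
        double g0 = R::norm_rand(), g1 = R::norm_rand(), g2 = R::norm_rand();
        double gn = std::sqrt(g0 * g0 + g1 * g1 + g2 * g2);
        if (gn < 1e-12) { gn = 1.0; g0 = 1.0; g1 = g2 = 0.0; }
        double angle = d_rot * (2.0 * R::unif_rand() - 1.0);
        double a0 = st.ax[i], a1 = st.ay[i], a2 = st.az[i];
        double n0 = st.nx[i], n1 = st.ny[i], n2 = st.nz[i];
        rotate_frame(st, i, g0 / gn, g1 / gn, g2 / gn, angle);
        e_new = local_energy(st, md, i);
        double de = e_new - e_old;
        ++n_moves;
        if (de <= 0 || R::unif_rand() < std::exp(-de / kT)) {
          e_total += de; ++n_acc;
        } else {
          st.ax[i] = a0; st.ay[i] = a1; st.az[i] = a2;
          st.nx[i] = n0; st.ny[i] = n1; st.nz[i] = n2;
        }
      } else {                               // wrap increment, reflected
        e_old = local_energy(st, md, i);
        double eb_old = any_bias_on_state ? bias_energy(st, bs) : 0.0;
        double w0 = st.wrap[i];
        double w = w0 + d_wrap * (2.0 * R::unif_rand() - 1.0);
        if (w > 1.0) w = 2.0 - w;
        if (w < 0.5) w = 1.0 - w;
        st.wrap[i] = w;
        e_new = local_energy(st, md, i);
        double eb_new = any_bias_on_state ? bias_energy(st, bs) : 0.0;
        double de = e_new - e_old + (eb_new - eb_old);
        ++n_moves;
        if (de <= 0 || R::unif_rand() < std::exp(-de / kT)) {
          e_total += de; ++n_acc;
        } else {
          st.wrap[i] = w0;
        }
      }
    }
    if (sweep % stride == 0 && ks < n_snap) {
      NumericMatrix C(st.N, 3), A(st.N, 3), Nn(st.N, 3);
      NumericVector W(st.N);
      for (int i = 0; i < st.N; ++i) {
        C(i, 0) = st.cx[i]; C(i, 1) = st.cy[i]; C(i, 2) = st.cz[i];
        A(i, 0) = st.ax[i]; A(i, 1) = st.ay[i]; A(i, 2) = st.az[i];
        Nn(i, 0) = st.nx[i]; Nn(i, 1) = st.ny[i]; Nn(i, 2) = st.nz[i];
        W[i] = st.wrap[i];
      }
      snap_centers[ks] = C; snap_axis_a[ks] = A; snap_normal[ks] = Nn;
      snap_wrap[ks] = W; snap_energy[ks] = e_total; snap_step[ks] = sweep;
      ++ks;
    }
  }

  double e_scratch = total_energy(st, md, bs);
  return List::create(
    _["centers"] = snap_centers, _["axis_a"] = snap_axis_a,
    _["normal"] = snap_normal, _["wrap"] = snap_wrap,
    _["energy"] = snap_energy, _["step"] = snap_step,
    _["acceptance"] = (double)n_acc / (double)n_moves,
    _["e_incremental"] = e_total, _["e_scratch"] = e_scratch);
}
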