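#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Off-lattice biofilm agent-based model.
//
// Cells live in 3D above a planar substrate (z = 0, reflective). Each
// step: (1) motion along the blended unit direction
// (1-F)*u_force + F*u_rand at speed D, (2) per-phenotype Poisson
// logistic division, (3) Poisson removal restricted to the predation
// interface (topmost cell per substrate grid window). Matrix-producing
// (social) cells have a 100-fold larger attractive force constant and a
// 5-fold slower division rate by default; constants are passed in from
// the R wrapper.

namespace {

struct BF {
  std::vector<double> x, y, z;
  std::vector<int> soc;
  // parameters
  double H, Ga, Gs, Gsub, F, r_a, r_s, Kbf, L, dt, D, jitter;
  bool sub_by_pheno;
  bool renorm;  // renormalize the blended direction to unit length
  std::vector<double> ax, ay;

  int n() const { return (int)x.size(); }
  double G(int i) const { return soc[i] ? Gs : Ga; }

  void forces(std::vector<double>& fx, std::vector<double>& fy,
              std::vector<double>& fz) const {
    int N = n();
    fx.assign(N, 0.0); fy.assign(N, 0.0); fz.assign(N, 0.0);
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= 0.0) continue;  // prevented by uniqueness jitter
        double inv2 = 1.0 / d2;
        double invd = std::sqrt(inv2);
        double gbar = 0.5 * (G(i) + G(j));
        // (H/d^6 - gbar/d^2) / d, positive = repulsive
        double c = (H * inv2 * inv2 * inv2 - gbar * inv2) * invd;
        fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
        fx[j] -= c * dx; fy[j] -= c * dy; fz[j] -= c * dz;
      }
      int M = (int)ax.size();
      double gs = sub_by_pheno ? 0.5 * G(i) : Gsub;
      for (int k = 0; k < M; ++k) {
        double dx = x[i] - ax[k], dy = y[i] - ay[k], dz = z[i];
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 <= 0.0) continue;
        double inv2 = 1.0 / d2;
        double invd = std::sqrt(inv2);
        double c = (H * inv2 * inv2 * inv2 - gs * inv2) * invd;
        fx[i] += c * dx; fy[i] += c * dy; fz[i] += c * dz;
      }
    }
  }

  void rand_unit(double& ux, double& uy, double& uz) const {
    for (;;) {
      ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
      double nn = std::sqrt(ux * ux + uy * uy + uz * uz);
      if (nn > 1e-12) { ux /= nn; uy /= nn; uz /= nn; return; }
    }
  }

  void move(double Fw) {
    int N = n();
    std::vector<double> fx, fy, fz;
    forces(fx, fy, fz);
    for (int i = 0; i < N; ++i) {
      double ux, uy, uz;
      rand_unit(ux, uy, uz);
      double nf = std::sqrt(fx[i] * fx[i] + fy[i] * fy[i] + fz[i] * fz[i]);
      double vx, vy, vz;
      if (nf > 0.0) {
        vx = (1.0 - Fw) * fx[i] / nf + Fw * ux;
        vy = (1.0 - Fw) * fy[i] / nf + Fw * uy;
        vz = (1.0 - Fw) * fz[i] / nf + Fw * uz;
      } else {
        vx = ux; vy = uy; vz = uz;
      }
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (nv < 1e-12) { vx = ux; vy = uy; vz = uz; nv = 1.0; }
      if (!renorm) nv = 1.0;  // blend length (<= 1) scales the step
      x[i] += D * vx / nv; y[i] += D * vy / nv; z[i] += D * vz / nv;
      if (z[i] < 0.0) z[i] = -z[i];
      x[i] += (2.0 * unif_rand() - 1.0) * jitter * D;
      y[i] += (2.0 * unif_rand() - 1.0) * jitter * D;
      z[i] += (2.0 * unif_rand() - 1.0) * jitter * D;
      if (z[i] < 0.0) z[i] = -z[i];
    }
  }

  // pick k distinct entries of idx uniformly (partial Fisher-Yates)
  std::vector<int> pick(std::vector<int> idx, int k) const {
    int m = (int)idx.size();
    if (k >= m) return idx;
    for (int i = 0; i < k; ++i) {
      int j = i + (int)(unif_rand() * (m - i));
      if (j >= m) j = m - 1;
      std::swap(idx[i], idx[j]);
    }
    idx.resize(k);
    return idx;
  }

  void duplicate(int i) {
    double nx = x[i] + (2.0 * unif_rand() - 1.0) * jitter * D;
    double ny = y[i] + (2.0 * unif_rand() - 1.0) * jitter * D;
    double nz = z[i] + (2.0 * unif_rand() - 1.0) * jitter * D;
    if (nz < 0.0) nz = -nz;
    x.push_back(nx); y.push_back(ny); z.push_back(nz);
    soc.push_back(soc[i]);
  }

  void divide() {
    int N = n();
    double logistic = 1.0 - (double)N / Kbf;
    if (logistic < 0.0) logistic = 0.0;
    std::vector<int> a_idx, s_idx;
    for (int i = 0; i < N; ++i) (soc[i] ? s_idx : a_idx).push_back(i);
    int ka = (int)R::rpois((double)a_idx.size() * r_a * logistic * dt);
    int ks = (int)R::rpois((double)s_idx.size() * r_s * logistic * dt);
    for (int i : pick(a_idx, ka)) duplicate(i);
    for (int i : pick(s_idx, ks)) duplicate(i);
  }

  std::vector<int> interface_cells() const {
    // topmost cell per occupied substrate grid window (window = D x D)
    std::unordered_map<long long, int> top;
    top.reserve(2 * n());
    for (int i = 0; i < n(); ++i) {
      long long wx = (long long)std::floor(x[i] / D);
      long long wy = (long long)std::floor(y[i] / D);
      long long key = wx * 1000003LL + wy;
      auto it = top.find(key);
      if (it == top.end()) top.emplace(key, i);
      else if (z[i] > z[it->second]) it->second = i;
    }
    std::vector<int> out;
    out.reserve(top.size());
    for (auto& kv : top) out.push_back(kv.second);
    return out;
  }

  void remove() {
    std::vector<int> iface = interface_cells();
    int m = (int)iface.size();
    if (m == 0) return;
    int k = (int)R::rpois((double)m * L * dt);
    if (k <= 0) return;
    std::vector<int> victims = pick(iface, k);
    std::vector<bool> dead(n(), false);
    for (int v : victims) dead[v] = true;
    int w = 0;
    for (int i = 0; i < n(); ++i) {
      if (!dead[i]) {
        x[w] = x[i]; y[w] = y[i]; z[w] = z[i]; soc[w] = soc[i];
        ++w;
      }
    }
    x.resize(w); y.resize(w); z.resize(w); soc.resize(w);
  }
};

BF make_bf(NumericMatrix pos, IntegerVector social, NumericMatrix anchors,
           List par) {
  BF bf;
  int N = pos.nrow();
  bf.x.resize(N); bf.y.resize(N); bf.z.resize(N); bf.soc.resize(N);
  for (int i = 0; i < N; ++i) {
    bf.x[i] = pos(i, 0); bf.y[i] = pos(i, 1); bf.z[i] = pos(i, 2);
    bf.soc[i] = social[i];
  }
  int M = anchors.nrow();
  bf.ax.resize(M); bf.ay.resize(M);
  for (int k = 0; k < M; ++k) { bf.ax[k] = anchors(k, 0); bf.ay[k] = anchors(k, 1); }
  bf.H = par["H"]; bf.Ga = par["G_asocial"]; bf.Gs = par["G_social"];
  bf.Gsub = par["G_substrate"]; bf.F = par["F"];
  bf.r_a = par["r_asocial"]; bf.r_s = par["r_social"];
  bf.Kbf = par["K_BF"]; bf.L = par["L"]; bf.dt = par["dt"];
  bf.D = par["D"]; bf.jitter = par["jitter"];
  bf.sub_by_pheno = par["substrate_by_phenotype"];
  bf.renorm = par["renormalize_direction"];
  return bf;
}

}  // namespace

// [[Rcpp::export]]
List cpp_biofilm_run(NumericMatrix pos, IntegerVector social,
                     NumericMatrix anchors, List par,
                     int steps, double F_weight,
                     bool division, bool removal,
                     int record_every, int stop_mode, int stop_above) {
  BF bf = make_bf(pos, social, anchors, par);
  std::vector<int> rt, rn, rs, ra, rm;
  auto record = [&](int t) {
    int ns = 0;
    for (int s : bf.soc) ns += s;
    rt.push_back(t); rn.push_back(bf.n());
    rs.push_back(ns); ra.push_back(bf.n() - ns);
    rm.push_back((int)bf.interface_cells().size());
  };
  record(0);
  int t = 0;
  bool stopped = false;
  for (int s = 1; s <= steps; ++s) {
    if (bf.n() > 0) {
      bf.move(F_weight);
      if (division) bf.divide();
      if (removal) bf.remove();
    }
    t = s;
    if (stop_mode == 1 && (bf.n() == 0 || bf.n() > stop_above))
      stopped = true;
    if (stop_mode == 2) {
      int ns = 0;
      for (int si : bf.soc) ns += si;
      if (bf.n() == 0 || ns == 0 || ns == bf.n()) stopped = true;
    }
    if ((record_every > 0 && s % record_every == 0) || s == steps || stopped)
      record(t);
    if (stopped) break;
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  int N = bf.n();
  NumericMatrix out_pos(N, 3);
  IntegerVector out_soc(N);
  for (int i = 0; i < N; ++i) {
    out_pos(i, 0) = bf.x[i]; out_pos(i, 1) = bf.y[i]; out_pos(i, 2) = bf.z[i];
    out_soc[i] = bf.soc[i];
  }
  int nr = (int)rt.size();
  IntegerMatrix series(nr, 5);
  for (int i = 0; i < nr; ++i) {
    series(i, 0) = rt[i]; series(i, 1) = rn[i];
    series(i, 2) = rs[i]; series(i, 3) = ra[i]; series(i, 4) = rm[i];
  }
  colnames(series) = CharacterVector::create(
    "t", "n", "n_social", "n_asocial", "interface_size");
  return List::create(_["pos"] = out_pos, _["social"] = out_soc,
                      _["series"] = series, _["t"] = t,
                      _["stopped"] = stopped);
}

// Net pseudo-force on every cell (cell-cell plus substrate anchors).
// [[Rcpp::export]]
NumericMatrix cpp_bf_forces(NumericMatrix pos, IntegerVector social,
                            NumericMatrix anchors, List par) {
  BF bf = make_bf(pos, social, anchors, par);
  std::vector<double> fx, fy, fz;
  bf.forces(fx, fy, fz);
  NumericMatrix out(bf.n(), 3);
  for (int i = 0; i < bf.n(); ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// 1-based indices of the predation interface.
// [[Rcpp::export]]
IntegerVector cpp_bf_interface(NumericMatrix pos, double D) {
  BF bf;
  int N = pos.nrow();
  bf.x.resize(N); bf.y.resize(N); bf.z.resize(N);
  bf.soc.assign(N, 0);
  for (int i = 0; i < N; ++i) {
    bf.x[i] = pos(i, 0); bf.y[i] = pos(i, 1); bf.z[i] = pos(i, 2);
  }
  bf.D = D;
  std::vector<int> ic = bf.interface_cells();
  IntegerVector out((int)ic.size());
  for (int i = 0; i < (int)ic.size(); ++i) out[i] = ic[i] + 1;
  return out;
}
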