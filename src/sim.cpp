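#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time multilevel simulator core.
//
// Draw order per step (kept in lockstep with the R reference
// implementation in R/simulator.R so both produce identical
// trajectories from the same RNG state):
//   [death if death_first]
//   one uniform per group below threshold, in index order (reproduction)
//   if any group at threshold and Ng < Kg: one uniform (splitter index),
//     one uniform (mA), one uniform (mB)
//   [death unless death_first]: one uniform whenever Ng > 0
// Event codes: 0 none, 1 split, 2 abortive split, +4 death.

namespace {

struct Pop {
  std::vector<int> nA, nB;
  int K;
  double b, mu, a;
  int mode;  // 0 neutral, 1 relative, 2 absolute
  int Kg;

  int size() const { return (int)nA.size(); }

  // single death draw; returns true if a death occurred.
  // Total death probability is mu (relative/neutral) or at most mu
  // (absolute), so a draw at or above mu can skip the group scan.
  bool do_death() {
    int ng = size();
    if (ng == 0) return false;
    double u = unif_rand();
    if (u >= mu) return false;
    double cum = 0.0;
    int hit = -1;
    if (mode == 1) {
      double s = 0.0;
      for (int j = 0; j < ng; ++j)
        s += 1.0 - a * ((double)nA[j] / (nA[j] + nB[j]));
      if (s > 0.0) {
        for (int j = 0; j < ng; ++j) {
          double w = 1.0 - a * ((double)nA[j] / (nA[j] + nB[j]));
          cum += mu * w / s;
          if (u < cum) { hit = j; break; }
        }
      }
    } else {
      for (int j = 0; j < ng; ++j) {
        double term = (mode == 2)
          ? (mu / ng) * (1.0 - a * ((double)nA[j] / (nA[j] + nB[j])))
          : mu / ng;
        cum += term;
        if (u < cum) { hit = j; break; }
      }
    }
    if (hit >= 0) {
      nA.erase(nA.begin() + hit);
      nB.erase(nB.begin() + hit);
      return true;
    }
    return false;
  }

  void reproduce() {
    int ng = size();
    double kk = (double)K * (double)K;
    for (int j = 0; j < ng; ++j) {
      int n = nA[j] + nB[j];
      if (n >= K) continue;
      int free = K - n;
      double pA = ((double)(nA[j] * free)) / kk;
      double pB = (b * (double)(nB[j] * free)) / kk;
      double u = unif_rand();
      if (u < pA) nA[j] += 1;
      else if (u < pA + pB) nB[j] += 1;
    }
  }

  // returns 0 no split attempted, 1 split, 2 abortive
  int do_split() {
    int ng = size();
    if (ng == 0 || ng >= Kg) return 0;
    std::vector<int> elig;
    for (int j = 0; j < ng; ++j)
      if (nA[j] + nB[j] == K) elig.push_back(j);
    if (elig.empty()) return 0;
    double u = unif_rand();
    int pick = (int)(u * (double)elig.size());
    if (pick >= (int)elig.size()) pick = (int)elig.size() - 1;
    int j = elig[pick];
    int pa = nA[j], pb = nB[j];
    int mA = (int)(unif_rand() * (pa + 1)); if (mA > pa) mA = pa;
    int mB = (int)(unif_rand() * (pb + 1)); if (mB > pb) mB = pb;
    int d1 = mA + mB, d2 = (pa - mA) + (pb - mB);
    if (d1 == 0 || d2 == 0) return 2;  // abortive: parent unchanged
    nA[j] = mA; nB[j] = mB;
    nA.push_back(pa - mA);
    nB.push_back(pb - mB);
    return 1;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_run_sim(IntegerVector nA0, IntegerVector nB0,
                 int K, double b, double mu, double a,
                 int mode, int Kg, int steps,
                 bool death_first, int record_every, int stop_mode) {
  Pop pop;
  pop.nA.assign(nA0.begin(), nA0.end());
  pop.nB.assign(nB0.begin(), nB0.end());
  pop.K = K; pop.b = b; pop.mu = mu; pop.a = a;
  pop.mode = mode; pop.Kg = Kg;

  std::vector<int> rt, rng_, rallA, rallB, rsa, rsb, rev;
  auto record = [&](int t, int ev) {
    int ng = pop.size(), allA = 0, allB = 0;
    long sa = 0, sb = 0;
    for (int j = 0; j < ng; ++j) {
      sa += pop.nA[j]; sb += pop.nB[j];
      if (pop.nB[j] == 0) ++allA;
      if (pop.nA[j] == 0) ++allB;
    }
    rt.push_back(t); rng_.push_back(ng);
    rallA.push_back(allA); rallB.push_back(allB);
    rsa.push_back((int)sa); rsb.push_back((int)sb);
    rev.push_back(ev);
  };
  record(0, 0);

  int t = 0;
  bool stopped = false;
  for (int s = 1; s <= steps; ++s) {
    int ev = 0;
    if (pop.size() > 0) {
      if (death_first && pop.do_death()) ev |= 4;
      pop.reproduce();
      int sp = pop.do_split();
      if (sp) ev |= sp;
      if (!death_first && pop.do_death()) ev |= 4;
    }
    t = s;
    bool last = (s == steps);
    if (stop_mode >= 1 && pop.size() == 0) stopped = true;
    if (stop_mode == 2 && !stopped) {
      long sa = 0, sb = 0;
      for (int j = 0; j < pop.size(); ++j) { sa += pop.nA[j]; sb += pop.nB[j]; }
      if (sa == 0 || sb == 0) stopped = true;
    }
    if ((record_every > 0 && s % record_every == 0) || last || stopped)
      record(t, ev);
    if (stopped) break;
  }

  int nrec = (int)rt.size();
  IntegerMatrix traj(nrec, 7);
  for (int i = 0; i < nrec; ++i) {
    traj(i, 0) = rt[i]; traj(i, 1) = rng_[i];
    traj(i, 2) = rallA[i]; traj(i, 3) = rallB[i];
    traj(i, 4) = rsa[i]; traj(i, 5) = rsb[i];
    traj(i, 6) = rev[i];
  }
  colnames(traj) = CharacterVector::create(
    "t", "Ng", "Ng_allA", "Ng_allB", "sum_nA", "sum_nB", "event");
  return List::create(_["traj"] = traj,
                      _["nA"] = IntegerVector(pop.nA.begin(), pop.nA.end()),
                      _["nB"] = IntegerVector(pop.nB.begin(), pop.nB.end()),
                      _["t"] = t,
                      _["stopped"] = stopped);
}

// Monte-Carlo estimate of the probability that a single group starting
// at size n0 reaches the splitting threshold K before elimination, with
// per-step survival probability delta and reproduction scale b.
// Independent of the closed-form product solution.
// [[Rcpp::export]]
double cpp_mc_psi(int n0, int K, double delta, double b, int reps) {
  double kk = (double)K * (double)K;
  int succ = 0;
  for (int r = 0; r < reps; ++r) {
    int n = n0;
    for (;;) {
      if (n == K) { ++succ; break; }
      if (unif_rand() >= delta) break;  // group eliminated
      double tplus = b * ((double)(n * (K - n))) / kk;
      if (unif_rand() < tplus) ++n;
    }
  }
  return (double)succ / (double)reps;
}
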