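// Rejection-free kinetic Monte Carlo of competitive hard-disk adsorption on
// a sphere, cylinder or periodic plane. Species are (molecule, orientation)
// classes with fixed adsorption/desorption rates; standard mode rejects
// insertions whose surface projection overlaps an adsorbed disk,
// displacement mode evicts overlapping disks with a logistic acceptance on
// the binding-energy difference.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Disk {
  int species;      // 0-based
  double a, b, c;   // sphere: unit vector; cylinder: (z, arc); plane: (x, y)
};

// Geometry codes: 0 sphere (p1 = R), 1 cylinder (p1 = R, p2 = L),
// 2 plane (p1 = Lx, p2 = Ly)
inline double surf_dist(int geom, double p1, double p2,
                        const Disk &u, const Disk &v) {
  if (geom == 0) {
    double dot = u.a * v.a + u.b * v.b + u.c * v.c;
    if (dot > 1.0) dot = 1.0;
    if (dot < -1.0) dot = -1.0;
    return p1 * std::acos(dot);          // great-circle distance
  }
  double d1 = std::fabs(u.a - v.a);
  double d2 = std::fabs(u.b - v.b);
  if (geom == 1) {
    double circ = 2.0 * M_PI * p1;
    if (d1 > p2 * 0.5) d1 = p2 - d1;     // axial wrap over length L
    if (d2 > circ * 0.5) d2 = circ - d2; // angular wrap (unrolled arc)
  } else {
    if (d1 > p1 * 0.5) d1 = p1 - d1;
    if (d2 > p2 * 0.5) d2 = p2 - d2;
  }
  return std::sqrt(d1 * d1 + d2 * d2);
}

inline Disk random_site(int geom, double p1, double p2, int species) {
  Disk d;
  d.species = species;
  if (geom == 0) {
    double z = 2.0 * unif_rand() - 1.0;
    double phi = 2.0 * M_PI * unif_rand();
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    d.a = r * std::cos(phi);
    d.b = r * std::sin(phi);
    d.c = z;
  } else if (geom == 1) {
    d.a = p2 * unif_rand();              // axial position in [0, L)
    d.b = 2.0 * M_PI * p1 * unif_rand(); // arc position
    d.c = 0.0;
  } else {
    d.a = p1 * unif_rand();
    d.b = p2 * unif_rand();
    d.c = 0.0;
  }
  return d;
}

} // namespace

// [[Rcpp::export(name = ".kmc_run_cpp")]]
List kmc_run_cpp(NumericVector ka, NumericVector kd, NumericVector rp,
                 NumericVector Ebind, int geom, double p1, double p2,
                 double t_end, int mode, double report_interval,
                 double max_events) {
  const int ns = ka.size();
  std::vector<Disk> disks;
  std::vector<int> counts(ns, 0);

  double ka_tot = 0.0;
  for (int i = 0; i < ns; ++i) ka_tot += ka[i];
  double kd_tot = 0.0;

  std::vector<double> rep_times;
  std::vector<std::vector<int>> rep_counts;
  double t = 0.0, next_rep = 0.0;
  double events = 0.0;

  auto record_until = [&](double tnew) {
    while (next_rep <= tnew && next_rep <= t_end + 1e-15) {
      rep_times.push_back(next_rep);
      rep_counts.push_back(counts);
      next_rep += report_interval;
    }
  };

  std::vector<int> overlap_idx;
  while (events < max_events) {
    double rtot = ka_tot + kd_tot;
    if (rtot <= 0.0) break;
    double dt = exp_rand() / rtot;
    double tnew = t + dt;
    if (tnew > t_end) break;
    record_until(tnew);
    t = tnew;
    events += 1.0;

    double u = unif_rand() * rtot;
    if (u < ka_tot) {
      // adsorption attempt
      int sp = ns - 1;
      double acc = 0.0;
      for (int i = 0; i < ns; ++i) {
        acc += ka[i];
        if (u < acc) { sp = i; break; }
      }
      Disk cand = random_site(geom, p1, p2, sp);
      overlap_idx.clear();
      bool blocked = false;
      for (size_t j = 0; j < disks.size(); ++j) {
        double cut = rp[sp] + rp[disks[j].species];
        if (surf_dist(geom, p1, p2, cand, disks[j]) < cut) {
          if (mode == 0) { blocked = true; break; }
          overlap_idx.push_back((int)j);
        }
      }
      if (mode == 0) {
        if (!blocked) {
          disks.push_back(cand);
          counts[sp]++;
          kd_tot += kd[sp];
        }
      } else {
        double esum = 0.0;
        for (int j : overlap_idx) esum += Ebind[disks[j].species];
        double dE = Ebind[sp] - esum;
        double pacc = 1.0 / (1.0 + std::exp(dE));
        if (unif_rand() < pacc) {
          // evict overlapping disks (largest index first)
          for (int k = (int)overlap_idx.size() - 1; k >= 0; --k) {
            int j = overlap_idx[k];
            counts[disks[j].species]--;
            kd_tot -= kd[disks[j].species];
            disks[j] = disks.back();
            disks.pop_back();
          }
          disks.push_back(cand);
          counts[sp]++;
          kd_tot += kd[sp];
        }
      }
    } else {
      // desorption
      double v = u - ka_tot;
      double acc = 0.0;
      int pick = -1;
      for (size_t j = 0; j < disks.size(); ++j) {
        acc += kd[disks[j].species];
        if (v < acc) { pick = (int)j; break; }
      }
      if (pick >= 0) {
        counts[disks[pick].species]--;
        kd_tot -= kd[disks[pick].species];
        disks[pick] = disks.back();
        disks.pop_back();
        // guard against drift in the running sum
        if (disks.empty()) kd_tot = 0.0;
      }
    }
  }
  record_until(t_end + 1e-15);

  const int nrep = (int)rep_times.size();
  IntegerMatrix cm(nrep, ns);
  for (int r = 0; r < nrep; ++r)
    for (int s = 0; s < ns; ++s) cm(r, s) = rep_counts[r][s];
  const int nd = (int)disks.size();
  IntegerVector fs(nd);
  NumericMatrix fp(nd, 3);
  for (int j = 0; j < nd; ++j) {
    fs[j] = disks[j].species + 1;
    fp(j, 0) = disks[j].a;
    fp(j, 1) = disks[j].b;
    fp(j, 2) = disks[j].c;
  }
  return List::create(_["times"] = NumericVector(rep_times.begin(), rep_times.end()),
                      _["counts"] = cm,
                      _["final_species"] = fs,
                      _["final_pos"] = fp,
                      _["t"] = t,
                      _["events"] = events);
}
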