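#include <Rcpp.h>
#include "oxygen.h"
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// Deterministic RNG independent of the C++ standard library's distribution
// implementations: xoshiro-style splitmix64 + mt19937_64 raw draws.
#include <random>
struct CaRng {
  std::mt19937_64 eng;
  explicit CaRng(uint64_t seed) : eng(seed) {}
  double unif() {  // in [0, 1)
    return (eng() >> 11) * (1.0 / 9007199254740992.0);
  }
  int unif_int(int n) {  // in [0, n)
    return std::min(n - 1, (int)(unif() * n));
  }
};

enum CellState : unsigned char { EMPTY = 0, CELL_P = 1, CELL_D = 2, CELL_N = 3 };

struct CaWorld {
  int L;                      // lattice edge (odd), center at (L-1)/2
  std::vector<unsigned char> s;
  int idx(int x, int y, int z) const { return (z * L + y) * L + x; }
};

static void ca_expand(CaWorld& w, int pad) {
  int Lold = w.L, Lnew = Lold + 2 * pad;
  std::vector<unsigned char> snew((size_t)Lnew * Lnew * Lnew, EMPTY);
  for (int z = 0; z < Lold; ++z)
    for (int y = 0; y < Lold; ++y)
      for (int x = 0; x < Lold; ++x)
        snew[((size_t)(z + pad) * Lnew + (y + pad)) * Lnew + (x + pad)] =
            w.s[w.idx(x, y, z)];
  w.L = Lnew;
  w.s.swap(snew);
}

struct Cell { int x, y, z; double r2; };

// [[Rcpp::export]]
List cpp_ca_simulate(double dr_star, List pars, List rad, NumericMatrix events,
                     List offsets_list, NumericVector weights, double R_init,
                     double t_end, double dt, NumericVector sample_times,
                     double seed, double profile_dr, int profile_nmax,
                     Nullable<IntegerVector> init_state, int init_L,
                     bool compact_init, bool uniform_free_placement) {
  const double gamma = as<double>(pars["gamma"]);
  const double a_h = as<double>(pars["a_h"]);
  const double eps = as<double>(pars["epsilon"]);
  const double del = as<double>(pars["delta"]);
  const double rho_h = as<double>(pars["rho_h"]);
  const double rho_an = as<double>(pars["rho_an"]);
  const double rho0 = as<double>(pars["rho0"]);
  const double D = as<double>(pars["D_um2_h"]);
  const int oxy_max_iter = as<int>(pars["oxy_max_iter"]);
  const double alpha = as<double>(rad["alpha"]), beta = as<double>(rad["beta"]);
  const double oer_m = as<double>(rad["oer_m"]), oer_K = as<double>(rad["oer_K"]);
  const double Pmc1 = as<double>(rad["Pmc1"]), Pmc2 = as<double>(rad["Pmc2"]);
  const double tau_mc = as<double>(rad["tau_mc"]);

  // neighborhood components as integer offset tables
  const int ncomp = offsets_list.size();
  std::vector<std::vector<std::array<int, 3>>> comps(ncomp);
  int max_reach = 1;
  for (int c = 0; c < ncomp; ++c) {
    IntegerMatrix m = offsets_list[c];
    comps[c].resize(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
      comps[c][i] = {m(i, 0), m(i, 1), m(i, 2)};
      max_reach = std::max({max_reach, std::abs(m(i, 0)), std::abs(m(i, 1)),
                            std::abs(m(i, 2))});
    }
  }
  std::vector<double> cum_w(ncomp);
  double acc = 0.0;
  for (int c = 0; c < ncomp; ++c) { acc += weights[c]; cum_w[c] = acc; }

  CaRng rng((uint64_t)seed);

  CaWorld w;
  if (init_state.isNotNull()) {
    IntegerVector st(init_state);
    w.L = init_L;
    w.s.resize(st.size());
    for (int i = 0; i < st.size(); ++i) w.s[i] = (unsigned char)st[i];
  } else {
    // initial dense ball of proliferation-competent cells
    int r_vox = (int)std::ceil(R_init / dr_star) + 1;
    int L = 2 * (r_vox + max_reach + 4) + 1;
    w.L = L;
    w.s.assign((size_t)L * L * L, EMPTY);
    int c0 = (L - 1) / 2;
    double rv = R_init / dr_star;
    for (int z = -r_vox; z <= r_vox; ++z)
      for (int y = -r_vox; y <= r_vox; ++y)
        for (int x = -r_vox; x <= r_vox; ++x)
          if (x * x + y * y + z * z <= rv * rv)
            w.s[w.idx(x + c0, y + c0, z + c0)] = CELL_P;
  }

  const double vvox = dr_star * dr_star * dr_star;
  double last_irr = R_NegInf;
  int next_event = 0;

  std::vector<double> out_t, out_R, out_Rn;
  std::vector<NumericMatrix> out_prof;
  long n_div = 0, n_rem = 0;
  long n_init = 0;
  for (auto v : w.s) if (v != EMPTY) ++n_init;

  std::vector<Cell> cells;
  std::vector<int> order;

  auto gather = [&](int want /*0=all,1=pd,2=n*/) {
    cells.clear();
    int c0 = (w.L - 1) / 2;
    for (int z = 0; z < w.L; ++z)
      for (int y = 0; y < w.L; ++y)
        for (int x = 0; x < w.L; ++x) {
          unsigned char st = w.s[w.idx(x, y, z)];
          if (st == EMPTY) continue;
          if (want == 1 && st == CELL_N) continue;
          if (want == 2 && st != CELL_N) continue;
          double dx = x - c0, dy = y - c0, dz = z - c0;
          cells.push_back({x, y, z, dx * dx + dy * dy + dz * dz});
        }
  };

  // radial occupancy binned at single-cell resolution for the oxygen profile
  std::vector<double> rho_sh;
  std::vector<char> chi_sh;
  int n_sh = 0;
  auto solve_oxygen = [&]() {
    gather(0);
    n_sh = 1;
    for (auto& c : cells)
      n_sh = std::max(n_sh, (int)std::floor(std::sqrt(c.r2)) + 1);
    n_sh += 2;
    std::vector<double> cons(n_sh, 0.0), tot(n_sh, 0.0);
    gather(1);
    for (auto& c : cells) cons[(int)std::floor(std::sqrt(c.r2))] += 1.0;
    gather(0);
    for (auto& c : cells) tot[(int)std::floor(std::sqrt(c.r2))] += 1.0;
    for (int i = 0; i < n_sh; ++i) {
      double vs = 4.0 / 3.0 * PI * vvox *
                  (std::pow(i + 1.0, 3) - std::pow((double)i, 3));
      cons[i] *= vvox / vs;
      tot[i] *= vvox / vs;
    }
    int i0 = -1;
    for (int i = 0; i < n_sh; ++i)
      if (tot[i] > 0.1) i0 = i;
    rs_oxygen_core(cons, i0, dr_star, D, rho0, rho_an, a_h, oxy_max_iter,
                   rho_sh, chi_sh);
  };
  auto rho_at = [&](double r2) {
    int sh = (int)std::floor(std::sqrt(r2));
    return (sh < n_sh) ? rho_sh[sh] : rho0;
  };

  auto shuffle_pass = [&]() {
    // greedy inwards shuffle to a fixed point, outermost cells first
    static const int face[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                                   {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
    bool moved = true;
    int c0 = (w.L - 1) / 2;
    while (moved) {
      moved = false;
      gather(0);
      std::sort(cells.begin(), cells.end(),
                [](const Cell& a, const Cell& b) { return a.r2 > b.r2; });
      for (auto& c : cells) {
        int best = -1;
        double best_r2 = c.r2;
        for (int f = 0; f < 6; ++f) {
          int nx = c.x + face[f][0], ny = c.y + face[f][1],
              nz = c.z + face[f][2];
          if (w.s[w.idx(nx, ny, nz)] != EMPTY) continue;
          double dx = nx - c0, dy = ny - c0, dz = nz - c0;
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < best_r2 - 1e-12) { best_r2 = r2; best = f; }
        }
        if (best >= 0) {
          int nx = c.x + face[best][0], ny = c.y + face[best][1],
              nz = c.z + face[best][2];
          w.s[w.idx(nx, ny, nz)] = w.s[w.idx(c.x, c.y, c.z)];
          w.s[w.idx(c.x, c.y, c.z)] = EMPTY;
          moved = true;
        }
      }
    }
  };

  auto record = [&](double t) {
    long np = 0, nd = 0, nn = 0;
    for (auto v : w.s) {
      if (v == CELL_P) ++np;
      else if (v == CELL_D) ++nd;
      else if (v == CELL_N) ++nn;
    }
    double Vt = (np + nd + nn) * vvox, Vnn = nn * vvox;
    out_t.push_back(t);
    out_R.push_back(std::cbrt(3.0 * Vt / (4.0 * PI)));
    out_Rn.push_back(std::cbrt(3.0 * Vnn / (4.0 * PI)));
    // radial concentration profile on shells of width profile_dr
    NumericMatrix prof(profile_nmax, 3);
    std::fill(prof.begin(), prof.end(), 0.0);
    gather(0);
    for (auto& c : cells) {
      double r_um = std::sqrt(c.r2) * dr_star;
      int sh = (int)std::floor(r_um / profile_dr);
      if (sh >= profile_nmax) continue;
      unsigned char st = w.s[w.idx(c.x, c.y, c.z)];
      prof(sh, st == CELL_P ? 0 : st == CELL_D ? 1 : 2) += 1.0;
    }
    for (int i = 0; i < profile_nmax; ++i) {
      double vs = 4.0 / 3.0 * PI * profile_dr * profile_dr * profile_dr *
                  (std::pow(i + 1.0, 3) - std::pow((double)i, 3));
      for (int k = 0; k < 3; ++k) prof(i, k) *= vvox / vs;
    }
    out_prof.push_back(prof);
  };

  size_t next_sample = 0;
  auto maybe_record = [&](double t) {
    while (next_sample < (size_t)sample_times.size() &&
           t >= sample_times[next_sample] - 1e-9) {
      record(t);
      ++next_sample;
    }
  };

  if (compact_init) shuffle_pass();  // compact the voxelised initial ball
  maybe_record(0.0);

  long n_steps = (long)std::ceil(t_end / dt - 1e-9);
  for (long step = 0; step < n_steps; ++step) {
    double t = step * dt;

    // margin check / lattice growth
    gather(0);
    bool need = false;
    for (auto& c : cells)
      if (c.x < max_reach + 1 || c.y < max_reach + 1 || c.z < max_reach + 1 ||
          c.x >= w.L - max_reach - 1 || c.y >= w.L - max_reach - 1 ||
          c.z >= w.L - max_reach - 1) { need = true; break; }
    if (need) ca_expand(w, 8);

    // instantaneous irradiation events
    while (next_event < events.nrow() && events(next_event, 0) <= t + 1e-9) {
      solve_oxygen();
      gather(1);
      for (auto& c : cells) {
        if (w.s[w.idx(c.x, c.y, c.z)] != CELL_P) continue;
        double rho = rho_at(c.r2);
        double deff = events(next_event, 1) * (oer_m * rho + oer_K) /
                      (oer_m * (rho + oer_K));
        double S = std::exp(-(alpha * deff + beta * deff * deff));
        if (rng.unif() > S) w.s[w.idx(c.x, c.y, c.z)] = CELL_D;
      }
      last_irr = events(next_event, 0);
      ++next_event;
    }

    double Pmc = !R_finite(last_irr) ? Pmc1
                 : ((t - last_irr < tau_mc) ? Pmc1 : Pmc2);

    solve_oxygen();

    // (1) division attempts for p/d cells, randomized order
    gather(1);
    order.resize(cells.size());
    for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
    for (size_t i = order.size(); i > 1; --i)
      std::swap(order[i - 1], order[rng.unif_int((int)i)]);
    for (int oi : order) {
      Cell& c = cells[oi];
      unsigned char st = w.s[w.idx(c.x, c.y, c.z)];
      if (st != CELL_P && st != CELL_D) continue;
      if (rho_at(c.r2) <= rho_h) continue;
      if (rng.unif() >= gamma * dt) continue;
      if (st == CELL_D && rng.unif() < Pmc) {  // mitotic catastrophe
        w.s[w.idx(c.x, c.y, c.z)] = EMPTY;
        ++n_rem;
        continue;
      }
      // draw a neighborhood component per attempt
      double u = rng.unif() * acc;
      int comp = 0;
      while (comp < ncomp - 1 && u > cum_w[comp]) ++comp;
      if (uniform_free_placement) {
        // place the daughter uniformly on the free sites (division succeeds
        // whenever any free site exists)
        std::vector<int> free_sites;
        for (size_t k = 0; k < comps[comp].size(); ++k) {
          int nx = c.x + comps[comp][k][0], ny = c.y + comps[comp][k][1],
              nz = c.z + comps[comp][k][2];
          if (w.s[w.idx(nx, ny, nz)] == EMPTY)
            free_sites.push_back(w.idx(nx, ny, nz));
        }
        if (free_sites.empty()) continue;  // space limitation
        w.s[free_sites[rng.unif_int((int)free_sites.size())]] = st;
      } else {
        // draw one site uniformly; the division fails if it is occupied, so
        // the success probability equals the free fraction of the drawn
        // neighborhood - the same logistic crowding factor as the
        // radial-shell production law
        size_t k = (size_t)rng.unif_int((int)comps[comp].size());
        int nx = c.x + comps[comp][k][0], ny = c.y + comps[comp][k][1],
            nz = c.z + comps[comp][k][2];
        if (w.s[w.idx(nx, ny, nz)] != EMPTY) continue;
        w.s[w.idx(nx, ny, nz)] = st;
      }
      ++n_div;
    }

    // (2) anoxic death
    gather(1);
    for (auto& c : cells) {
      unsigned char st = w.s[w.idx(c.x, c.y, c.z)];
      if (st != CELL_P && st != CELL_D) continue;
      if (rho_at(c.r2) <= rho_an && rng.unif() < eps * dt)
        w.s[w.idx(c.x, c.y, c.z)] = CELL_N;
    }

    // (3) removal of necrotic material
    gather(2);
    for (auto& c : cells)
      if (rng.unif() < del * dt) {
        w.s[w.idx(c.x, c.y, c.z)] = EMPTY;
        ++n_rem;
      }

    // (4) rate-independent inwards shuffle
    shuffle_pass();

    maybe_record((step + 1) * dt);
  }

  long n_final = 0;
  for (auto v : w.s) if (v != EMPTY) ++n_final;

  List profs(out_prof.size());
  for (size_t i = 0; i < out_prof.size(); ++i) profs[i] = out_prof[i];
  IntegerVector sfin(w.s.size());
  for (size_t i = 0; i < w.s.size(); ++i) sfin[i] = w.s[i];
  return List::create(
      _["time"] = NumericVector(out_t.begin(), out_t.end()),
      _["R"] = NumericVector(out_R.begin(), out_R.end()),
      _["Rn"] = NumericVector(out_Rn.begin(), out_Rn.end()),
      _["profiles"] = profs, _["n_initial"] = (double)n_init,
      _["n_final"] = (double)n_final, _["n_divisions"] = (double)n_div,
      _["n_removals"] = (double)n_rem, _["L"] = w.L,
      _["state"] = sfin);
}
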