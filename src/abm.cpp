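#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Lattice sites are indexed row-major: site = row * width + col, 0-based.
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R side
// makes runs bit-reproducible.

static inline int rand_below(int k) {
  // uniform integer in [0, k); k >= 1
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

struct Lattice {
  int width, height, l;
  bool periodic;
  std::vector<int> grid;        // 0 = empty, otherwise cell id + 1
  std::vector<int> empty_sites; // list of empty site indices
  std::vector<int> empty_pos;   // site -> position in empty_sites, or -1

  Lattice(int w, int h, bool per) : width(w), height(h), l(w * h), periodic(per),
      grid(l, 0), empty_pos(l, -1) {}

  void rebuild_empties() {
    empty_sites.clear();
    std::fill(empty_pos.begin(), empty_pos.end(), -1);
    for (int s = 0; s < l; ++s) {
      if (grid[s] == 0) {
        empty_pos[s] = empty_sites.size();
        empty_sites.push_back(s);
      }
    }
  }
  void remove_empty(int s) {
    int p = empty_pos[s];
    int last = empty_sites.back();
    empty_sites[p] = last;
    empty_pos[last] = p;
    empty_sites.pop_back();
    empty_pos[s] = -1;
  }
  void add_empty(int s) {
    empty_pos[s] = empty_sites.size();
    empty_sites.push_back(s);
  }
  // neighbor site after displacement (dr, dc); -1 when outside a closed domain
  int shift(int s, int dr, int dc) const {
    int r = s / width + dr, c = s % width + dc;
    if (periodic) {
      r %= height; if (r < 0) r += height;
      c %= width;  if (c < 0) c += width;
    } else if (r < 0 || r >= height || c < 0 || c >= width) {
      return -1;
    }
    return r * width + c;
  }
};

// [[Rcpp::export]]
List abm_run_cpp(int width, int height, IntegerVector init_occ,
                 IntegerMatrix birth_off, IntegerMatrix migr_off,
                 bool migr_full_domain, double pb, double pd, double pm,
                 double dt, int steps, bool periodic,
                 IntegerVector snapshot_steps) {
  if (steps <= 0) stop("'steps' must be positive");
  Lattice lat(width, height, periodic);
  std::vector<int> cell_site;  // cell id -> site, -1 when dead
  for (int s = 0; s < lat.l; ++s) {
    if (init_occ[s] != 0) {
      lat.grid[s] = (int)cell_site.size() + 1;
      cell_site.push_back(s);
    }
  }
  lat.rebuild_empties();

  int nb = birth_off.nrow(), nm = migr_off.nrow();
  std::vector<int> cand(std::max(nb, nm) > 0 ? std::max(nb, nm) : 1);

  IntegerVector rec_step(steps + 1), rec_n(steps + 1),
                rec_blocked(steps + 1), rec_surface(steps + 1);
  NumericVector rec_time(steps + 1);
  List snapshots;
  std::vector<bool> want_snap(steps + 1, false);
  for (int i = 0; i < snapshot_steps.size(); ++i) {
    int st = snapshot_steps[i];
    if (st >= 0 && st <= steps) want_snap[st] = true;
  }

  std::vector<int> snapshot_ids;
  int dead_count = 0;

  auto count_blocked = [&](int &blocked, int &alive) {
    blocked = 0; alive = 0;
    for (size_t id = 0; id < cell_site.size(); ++id) {
      int s = cell_site[id];
      if (s < 0) continue;
      ++alive;
      bool full = true;
      for (int k = 0; k < nb; ++k) {
        int t = lat.shift(s, birth_off(k, 0), birth_off(k, 1));
        // outside a closed domain offers no daughter site, so it does not
        // unblock the cell
        if (t >= 0 && lat.grid[t] == 0) { full = false; break; }
      }
      if (full) ++blocked;
    }
  };

  auto record = [&](int step, double time) {
    int blocked, alive;
    count_blocked(blocked, alive);
    rec_step[step] = step;
    rec_time[step] = time;
    rec_n[step] = alive;
    rec_blocked[step] = blocked;
    rec_surface[step] = alive - blocked;
    if (want_snap[step]) {
      IntegerVector snap(lat.l);
      for (int s = 0; s < lat.l; ++s) snap[s] = lat.grid[s] != 0 ? 1 : 0;
      snapshots.push_back(snap, std::string("step_") + std::to_string(step));
    }
  };

  record(0, 0.0);

  for (int step = 1; step <= steps; ++step) {
    // snapshot of cells alive at step start, in shuffled order
    snapshot_ids.clear();
    for (size_t id = 0; id < cell_site.size(); ++id)
      if (cell_site[id] >= 0) snapshot_ids.push_back((int)id);
    int ns = (int)snapshot_ids.size();
    for (int i = ns - 1; i > 0; --i) {
      int j = rand_below(i + 1);
      std::swap(snapshot_ids[i], snapshot_ids[j]);
    }

    for (int i = 0; i < ns; ++i) {
      int id = snapshot_ids[i];
      int s = cell_site[id];
      if (s < 0) continue;

      // migration attempt
      if (pm > 0 && unif_rand() < pm) {
        int target = -1;
        if (migr_full_domain) {
          if (!lat.empty_sites.empty())
            target = lat.empty_sites[rand_below((int)lat.empty_sites.size())];
        } else {
          int kc = 0;
          for (int k = 0; k < nm; ++k) {
            int t = lat.shift(s, migr_off(k, 0), migr_off(k, 1));
            if (t >= 0 && lat.grid[t] == 0) cand[kc++] = t;
          }
          if (kc > 0) target = cand[rand_below(kc)];
        }
        if (target >= 0) {
          lat.remove_empty(target);
          lat.grid[target] = id + 1;
          lat.grid[s] = 0;
          lat.add_empty(s);
          cell_site[id] = target;
          s = target;
        }
      }

      // birth attempt; a fired-but-blocked attempt still counts as "no birth"
      bool born = false;
      if (pb > 0 && unif_rand() < pb) {
        int kc = 0;
        for (int k = 0; k < nb; ++k) {
          int t = lat.shift(s, birth_off(k, 0), birth_off(k, 1));
          if (t >= 0 && lat.grid[t] == 0) cand[kc++] = t;
        }
        if (kc > 0) {
          int t = cand[rand_below(kc)];
          lat.remove_empty(t);
          lat.grid[t] = (int)cell_site.size() + 1;
          cell_site.push_back(t);
          born = true;
        }
      }

      // death only in the absence of birth
      if (!born && pd > 0 && unif_rand() < pd) {
        lat.grid[s] = 0;
        lat.add_empty(s);
        cell_site[id] = -1;
        ++dead_count;
      }
    }

    // compact the id table occasionally so it does not grow without bound
    if (dead_count > (int)cell_site.size() / 2 && dead_count > 1024) {
      std::vector<int> fresh;
      fresh.reserve(cell_site.size() - dead_count);
      for (size_t id = 0; id < cell_site.size(); ++id) {
        if (cell_site[id] >= 0) {
          lat.grid[cell_site[id]] = (int)fresh.size() + 1;
          fresh.push_back(cell_site[id]);
        }
      }
      cell_site.swap(fresh);
      dead_count = 0;
    }

    record(step, step * dt);
  }

  IntegerVector final_occ(lat.l);
  for (int s = 0; s < lat.l; ++s) final_occ[s] = lat.grid[s] != 0 ? 1 : 0;

  return List::create(
    _["trajectory"] = DataFrame::create(
      _["step"] = rec_step, _["time"] = rec_time, _["n"] = rec_n,
      _["blocked"] = rec_blocked, _["surface"] = rec_surface),
    _["final_occupancy"] = final_occ,
    _["snapshots"] = snapshots);
}

// Exact event-driven simulation of the well-mixed birth-death chain with
// per-capita birth rate lam * (1 - (n/l)^omega) and death rate delta.
// [[Rcpp::export]]
List gillespie_cpp(double l, double omega, double lam, double delta,
                   int n0, double horizon, int max_events) {
  std::vector<double> times;
  std::vector<int> ns;
  times.reserve(1024); ns.reserve(1024);
  double t = 0.0;
  int n = n0;
  times.push_back(t); ns.push_back(n);
  int events = 0;
  while (events < max_events) {
    double u = (double)n / l;
    double brate = lam * (1.0 - std::pow(u, omega)) * n;
    if (brate < 0) brate = 0;
    double drate = delta * n;
    double tot = brate + drate;
    if (tot <= 0 || n == 0) break;
    t += R::rexp(1.0 / tot);
    if (t > horizon) break;
    if (unif_rand() < brate / tot) ++n; else --n;
    times.push_back(t); ns.push_back(n);
    ++events;
  }
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["n"] = IntegerVector(ns.begin(), ns.end()));
}
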