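// Lattice predator-prey simulator: sheep and wolves with energy budgets on a
// toroidal grid whose cells carry a regrowing grass resource. Uses R's RNG
// throughout so set.seed() on the R side fully determines a run.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Herd {
  std::vector<int> x, y, h; // h: heading 0..7 (NetLogo-style persistent walk)
  std::vector<double> e;
  size_t size() const { return x.size(); }
};

inline int runif_int(int n) {
  // uniform integer in [0, n)
  int k = static_cast<int>(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline int wrap(int v, int m) {
  v %= m;
  return v < 0 ? v + m : v;
}

// headings in angular order; a step turns at most one octant (the lattice
// analogue of NetLogo's +-50 degree wiggle before moving forward one unit)
const int DX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
const int DY[8] = {0, 1, 1, 1, 0, -1, -1, -1};

void move_herd(Herd &h, int w, int hgt, double cost) {
  for (size_t i = 0; i < h.size(); ++i) {
    int turn = runif_int(3) - 1;
    h.h[i] = (h.h[i] + turn + 8) % 8;
    h.x[i] = wrap(h.x[i] + DX[h.h[i]], w);
    h.y[i] = wrap(h.y[i] + DY[h.h[i]], hgt);
    h.e[i] -= cost;
  }
}

void compact(Herd &h, const std::vector<char> &alive) {
  size_t j = 0;
  for (size_t i = 0; i < h.size(); ++i) {
    if (alive[i]) {
      h.x[j] = h.x[i];
      h.y[j] = h.y[i];
      h.h[j] = h.h[i];
      h.e[j] = h.e[i];
      ++j;
    }
  }
  h.x.resize(j);
  h.y.resize(j);
  h.h.resize(j);
  h.e.resize(j);
}

} // namespace

// [[Rcpp::export(name = ".sw_simulate")]]
List sw_simulate(List params, int steps, List control) {
  if (steps < 0) stop("`steps` must be non-negative");
  const int width = as<int>(params["width"]);
  const int height = as<int>(params["height"]);
  if (width < 1 || height < 1) stop("grid dimensions must be >= 1");
  const int n_sheep0 = as<int>(params["initial_sheep"]);
  const int n_wolves0 = as<int>(params["initial_wolves"]);
  const double grass_frac = as<double>(params["initial_grass"]);
  const double sheep_gain = as<double>(params["sheep_gain"]);
  const double wolf_gain = as<double>(params["wolf_gain"]);
  const double sheep_repro = as<double>(params["sheep_reproduce"]);
  const double wolf_repro = as<double>(params["wolf_reproduce"]);
  const int regrow = as<int>(params["grass_regrowth"]);
  const double move_cost = as<double>(params["move_cost"]);
  const double graze_prob = as<double>(params["grazing_prob"]);
  const double prey_prob = as<double>(params["predation_prob"]);

  const int ctrl_start = as<int>(control["start"]);
  const double rem_grass = as<double>(control["grass"]);
  const double rem_sheep = as<double>(control["sheep"]);
  const double rem_wolves = as<double>(control["wolves"]);

  const int ncell = width * height;

  RNGScope scope;

  // grass[c] == 0: fully grown; k > 0: regrows after k more steps
  std::vector<int> grass(ncell);
  int n_grown = 0;
  for (int c = 0; c < ncell; ++c) {
    if (R::unif_rand() < grass_frac) {
      grass[c] = 0;
      ++n_grown;
    } else {
      grass[c] = 1 + runif_int(regrow);
    }
  }

  Herd sheep, wolves;
  sheep.x.reserve(4 * n_sheep0);
  sheep.y.reserve(4 * n_sheep0);
  sheep.e.reserve(4 * n_sheep0);
  for (int i = 0; i < n_sheep0; ++i) {
    sheep.x.push_back(runif_int(width));
    sheep.y.push_back(runif_int(height));
    sheep.h.push_back(runif_int(8));
    sheep.e.push_back(1 + runif_int((int)(2 * sheep_gain)));
  }
  for (int i = 0; i < n_wolves0; ++i) {
    wolves.x.push_back(runif_int(width));
    wolves.y.push_back(runif_int(height));
    wolves.h.push_back(runif_int(8));
    wolves.e.push_back(1 + runif_int((int)(2 * wolf_gain)));
  }

  IntegerMatrix counts(steps + 1, 3);
  NumericMatrix removed(steps + 1, 3); // control removals per step (grass, sheep, wolves)
  counts(0, 0) = n_grown;
  counts(0, 1) = sheep.size();
  counts(0, 2) = wolves.size();

  std::vector<int> head(ncell, -1);
  std::vector<int> nxt;

  for (int t = 1; t <= steps; ++t) {
    // 1. move (pay energy cost)
    move_herd(sheep, width, height, move_cost);
    move_herd(wolves, width, height, move_cost);

    // 2a. sheep graze: one grass unit per cell, first sheep listed gets it
    for (size_t i = 0; i < sheep.size(); ++i) {
      int c = sheep.y[i] * width + sheep.x[i];
      if (grass[c] == 0 && R::unif_rand() < graze_prob) {
        sheep.e[i] += sheep_gain;
        grass[c] = regrow;
        --n_grown;
      }
    }

    // 2b. wolves predate: a wolf sharing a cell with >= 1 sheep may eat one
    std::vector<char> sheep_alive(sheep.size(), 1);
    std::fill(head.begin(), head.end(), -1);
    nxt.assign(sheep.size(), -1);
    for (size_t i = 0; i < sheep.size(); ++i) {
      int c = sheep.y[i] * width + sheep.x[i];
      nxt[i] = head[c];
      head[c] = (int)i;
    }
    for (size_t i = 0; i < wolves.size(); ++i) {
      int c = wolves.y[i] * width + wolves.x[i];
      int s = head[c];
      if (s >= 0 && R::unif_rand() < prey_prob) {
        sheep_alive[s] = 0;
        head[c] = nxt[s];
        wolves.e[i] += wolf_gain;
      }
    }
    compact(sheep, sheep_alive);

    // 3. reproduce: parent's energy is split between parent and offspring
    size_t ns = sheep.size();
    for (size_t i = 0; i < ns; ++i) {
      if (R::unif_rand() < sheep_repro) {
        sheep.e[i] /= 2.0;
        int d = runif_int(8);
        sheep.x.push_back(wrap(sheep.x[i] + DX[d], width));
        sheep.y.push_back(wrap(sheep.y[i] + DY[d], height));
        sheep.h.push_back(d);
        sheep.e.push_back(sheep.e[i]);
      }
    }
    size_t nw = wolves.size();
    for (size_t i = 0; i < nw; ++i) {
      if (R::unif_rand() < wolf_repro) {
        wolves.e[i] /= 2.0;
        int d = runif_int(8);
        wolves.x.push_back(wrap(wolves.x[i] + DX[d], width));
        wolves.y.push_back(wrap(wolves.y[i] + DY[d], height));
        wolves.h.push_back(d);
        wolves.e.push_back(wolves.e[i]);
      }
    }

    // 4. energy-depleted agents die
    {
      std::vector<char> alive(sheep.size(), 1);
      for (size_t i = 0; i < sheep.size(); ++i)
        if (sheep.e[i] <= 0) alive[i] = 0;
      compact(sheep, alive);
    }
    {
      std::vector<char> alive(wolves.size(), 1);
      for (size_t i = 0; i < wolves.size(); ++i)
        if (wolves.e[i] <= 0) alive[i] = 0;
      compact(wolves, alive);
    }

    // 5. scheduled control removal (independent Bernoulli per agent/cell)
    if (t >= ctrl_start && (rem_grass > 0 || rem_sheep > 0 || rem_wolves > 0)) {
      if (rem_sheep > 0) {
        std::vector<char> alive(sheep.size(), 1);
        int nrem = 0;
        for (size_t i = 0; i < sheep.size(); ++i)
          if (R::unif_rand() < rem_sheep) { alive[i] = 0; ++nrem; }
        compact(sheep, alive);
        removed(t, 1) = nrem;
      }
      if (rem_wolves > 0) {
        std::vector<char> alive(wolves.size(), 1);
        int nrem = 0;
        for (size_t i = 0; i < wolves.size(); ++i)
          if (R::unif_rand() < rem_wolves) { alive[i] = 0; ++nrem; }
        compact(wolves, alive);
        removed(t, 2) = nrem;
      }
      if (rem_grass > 0) {
        int nrem = 0;
        for (int c = 0; c < ncell; ++c) {
          if (grass[c] == 0 && R::unif_rand() < rem_grass) {
            grass[c] = regrow;
            --n_grown;
            ++nrem;
          }
        }
        removed(t, 0) = nrem;
      }
    }

    // 6. grass regrows
    for (int c = 0; c < ncell; ++c) {
      if (grass[c] > 0 && --grass[c] == 0) ++n_grown;
    }

    counts(t, 0) = n_grown;
    counts(t, 1) = sheep.size();
    counts(t, 2) = wolves.size();
  }

  return List::create(_["counts"] = counts, _["removed"] = removed);
}
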