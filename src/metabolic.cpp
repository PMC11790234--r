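// Elementary-step enzymatic pathway on a toroidal lattice. Molecules are
// individual agents; binding, dissociation and catalysis are table-driven so
// that alternative pathway topologies can be declared from R. Metabolites
// diffuse ten movement substeps per enzyme/complex step. Uses R's RNG.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

inline int runif_int(int n) {
  int k = static_cast<int>(R::unif_rand() * n);
  return k >= n ? n - 1 : k;
}

inline int wrap(int v, int m) {
  v %= m;
  return v < 0 ? v + m : v;
}

const int DX[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DY[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct Pool {
  std::vector<int> code, x, y;
  size_t size() const { return code.size(); }
};

} // namespace

// species codes are 0-based indices into the declared species table.
// bind:  (metabolite, partner, complex) rows + probability; the partner is a
//        free enzyme or an existing complex (mixed inhibition forms ternary
//        complexes this way).
// dis:   (complex, released metabolite, remaining partner) rows + probability;
//        several rows per complex are allowed and tried in declared order.
// cat:   (substrate complex, product complex) rows + probability (irreversible).
// [[Rcpp::export(name = ".met_simulate")]]
List met_simulate(List params, int steps, List control, int stride) {
  if (steps < 0) stop("`steps` must be non-negative");
  if (stride < 1) stop("`stride` must be >= 1");
  const int width = as<int>(params["width"]);
  const int height = as<int>(params["height"]);
  if (width < 1 || height < 1) stop("grid dimensions must be >= 1");
  const IntegerVector init = params["initial_counts"];
  const LogicalVector is_met = params["is_metabolite"];
  const int n_species = init.size();
  const int met_substeps = as<int>(params["metabolite_speed"]);

  const IntegerMatrix bind = params["bind_table"];
  const NumericVector bind_p = params["bind_prob"];
  const IntegerMatrix dis = params["dis_table"];
  const NumericVector dis_p = params["dis_prob"];
  const IntegerMatrix cat = params["cat_table"];
  const NumericVector cat_p = params["cat_prob"];

  const bool continuous = as<bool>(control["continuous"]);
  const double inflow = as<double>(control["inflow"]);
  const int inflow_code = as<int>(control["inflow_code"]);
  const double outflow = as<double>(control["outflow"]);
  const int ctrl_start = as<int>(control["start"]);
  if (inflow < 0 || inflow > 1)
    stop("inflow rate must lie in [0, 1] (molecules are inserted Bernoulli(rate) per step)");

  // dense lookup tables
  std::vector<int> bind_row(n_species * n_species, -1);
  for (int r = 0; r < bind.nrow(); ++r) {
    int a = bind(r, 0), b = bind(r, 1);
    if (a < 0 || a >= n_species || b < 0 || b >= n_species)
      stop("binding table refers to an unknown species code");
    bind_row[a * n_species + b] = r;
  }
  std::vector<std::vector<int>> dis_rows(n_species);
  for (int r = 0; r < dis.nrow(); ++r) dis_rows[dis(r, 0)].push_back(r);
  std::vector<int> cat_row(n_species, -1);
  for (int r = 0; r < cat.nrow(); ++r) cat_row[cat(r, 0)] = r;

  const int ncell = width * height;
  RNGScope scope;

  Pool mets, heavies; // free metabolites vs enzymes+complexes
  for (int s = 0; s < n_species; ++s) {
    Pool &p = is_met[s] ? mets : heavies;
    for (int i = 0; i < init[s]; ++i) {
      p.code.push_back(s);
      p.x.push_back(runif_int(width));
      p.y.push_back(runif_int(height));
    }
  }

  const int n_rec = steps / stride + 1;
  IntegerMatrix counts(n_rec, n_species);
  IntegerVector times(n_rec);
  auto record = [&](int row, int t) {
    times[row] = t;
    for (size_t i = 0; i < mets.size(); ++i) counts(row, mets.code[i])++;
    for (size_t i = 0; i < heavies.size(); ++i) counts(row, heavies.code[i])++;
  };
  record(0, 0);
  int rec_row = 1;

  std::vector<int> head(ncell, -1), nxt;

  for (int t = 1; t <= steps; ++t) {
    // 1. enzymes/complexes take one movement step
    for (size_t i = 0; i < heavies.size(); ++i) {
      int d = runif_int(8);
      heavies.x[i] = wrap(heavies.x[i] + DX[d], width);
      heavies.y[i] = wrap(heavies.y[i] + DY[d], height);
    }

    // per-cell buckets of enzymes/complexes (stable for the rest of the step)
    std::fill(head.begin(), head.end(), -1);
    nxt.assign(heavies.size(), -1);
    for (size_t i = 0; i < heavies.size(); ++i) {
      int c = heavies.y[i] * width + heavies.x[i];
      nxt[i] = head[c];
      head[c] = (int)i;
    }

    // 2. metabolites diffuse fast; binding is attempted after each substep
    std::vector<char> met_alive(mets.size(), 1);
    for (int sub = 0; sub < met_substeps; ++sub) {
      for (size_t i = 0; i < mets.size(); ++i) {
        if (!met_alive[i]) continue;
        int d = runif_int(8);
        mets.x[i] = wrap(mets.x[i] + DX[d], width);
        mets.y[i] = wrap(mets.y[i] + DY[d], height);
        int c = mets.y[i] * width + mets.x[i];
        for (int h = head[c]; h >= 0; h = nxt[h]) {
          int r = bind_row[mets.code[i] * n_species + heavies.code[h]];
          if (r >= 0 && R::unif_rand() < bind_p[r]) {
            heavies.code[h] = bind(r, 2); // partner becomes the complex
            met_alive[i] = 0;             // metabolite is absorbed
            break;
          }
        }
      }
    }
    {
      size_t j = 0;
      for (size_t i = 0; i < mets.size(); ++i) {
        if (met_alive[i]) {
          mets.code[j] = mets.code[i];
          mets.x[j] = mets.x[i];
          mets.y[j] = mets.y[i];
          ++j;
        }
      }
      mets.code.resize(j);
      mets.x.resize(j);
      mets.y.resize(j);
    }

    // 3. dissociation: a complex releases a metabolite on its own cell
    for (size_t i = 0; i < heavies.size(); ++i) {
      const std::vector<int> &rows = dis_rows[heavies.code[i]];
      for (size_t k = 0; k < rows.size(); ++k) {
        int r = rows[k];
        if (R::unif_rand() < dis_p[r]) {
          mets.code.push_back(dis(r, 1));
          mets.x.push_back(heavies.x[i]);
          mets.y.push_back(heavies.y[i]);
          heavies.code[i] = dis(r, 2);
          break;
        }
      }
    }

    // 4. catalysis: substrate complex -> product complex, irreversible
    for (size_t i = 0; i < heavies.size(); ++i) {
      int r = cat_row[heavies.code[i]];
      if (r >= 0 && R::unif_rand() < cat_p[r]) heavies.code[i] = cat(r, 1);
    }

    // 5. chemostat exchange: substrate inflow, metabolite-only outflow
    if (continuous && t >= ctrl_start) {
      if (inflow >= 1.0 || R::unif_rand() < inflow) {
        mets.code.push_back(inflow_code);
        mets.x.push_back(runif_int(width));
        mets.y.push_back(runif_int(height));
      }
      if (outflow > 0) {
        size_t j = 0;
        for (size_t i = 0; i < mets.size(); ++i) {
          if (R::unif_rand() >= outflow) {
            mets.code[j] = mets.code[i];
            mets.x[j] = mets.x[i];
            mets.y[j] = mets.y[i];
            ++j;
          }
        }
        mets.code.resize(j);
        mets.x.resize(j);
        mets.y.resize(j);
      }
    }

    if (t % stride == 0) record(rec_row++, t);
  }

  return List::create(_["times"] = times, _["counts"] = counts);
}
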