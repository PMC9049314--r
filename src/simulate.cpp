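#include <Rcpp.h>
using namespace Rcpp;

// Genotype-table branching-process simulators.
//
// Cells reference genotypes; a genotype records the mutations acquired at the
// division event that created it. Mutation carriers for a genotype are the
// cells in its subtree, computed by one reverse sweep at biopsy (children are
// always created after their parents, so indices increase down the tree).
// This keeps memory O(#division events) rather than O(#cells x #mutations),
// which is required for mutation rates of hundreds per division.

struct GenotypeTable {
  std::vector<int> parent;      // -1 for root
  std::vector<int> n_new;       // neutral mutations created with this genotype
  std::vector<int> n_driver;    // driver mutations created with this genotype
  std::vector<double> s_sum;    // sum of log(1+s) over drivers at this event
  std::vector<double> birth;    // birth rate of cells carrying this genotype
  void add(int par, int nn, int nd, double ss, double b) {
    parent.push_back(par);
    n_new.push_back(nn);
    n_driver.push_back(nd);
    s_sum.push_back(ss);
    birth.push_back(b);
  }
};

static List finalize(const GenotypeTable &gt, const std::vector<int> &cells,
                     double base_birth, int extra_scalar_id = -1,
                     double extra_scalar = 0.0) {
  int n_geno = gt.parent.size();
  int n_cells = cells.size();
  std::vector<int> own(n_geno, 0), carriers(n_geno, 0);
  for (int i = 0; i < n_cells; ++i) own[cells[i]]++;
  for (int i = 0; i < n_geno; ++i) carriers[i] = own[i];
  for (int i = n_geno - 1; i > 0; --i) carriers[gt.parent[i]] += carriers[i];
  // cumulative fitness along the path root -> genotype (forward sweep)
  std::vector<double> cum_s(n_geno, 0.0);
  for (int i = 1; i < n_geno; ++i) cum_s[i] = cum_s[gt.parent[i]] + gt.s_sum[i];
  NumericVector cum_fitness(n_geno);
  for (int i = 0; i < n_geno; ++i) cum_fitness[i] = std::exp(cum_s[i]);
  List out = List::create(
      _["parent"] = IntegerVector(gt.parent.begin(), gt.parent.end()),
      _["n_new"] = IntegerVector(gt.n_new.begin(), gt.n_new.end()),
      _["n_driver"] = IntegerVector(gt.n_driver.begin(), gt.n_driver.end()),
      _["carriers"] = IntegerVector(carriers.begin(), carriers.end()),
      _["cum_fitness"] = cum_fitness,
      _["n_cells"] = n_cells);
  if (extra_scalar_id >= 0) {
    out["subclone_genotype"] = extra_scalar_id + 1;  // 1-based, 0 = none
    out["subclone_carriers"] =
        extra_scalar_id >= 0 ? carriers[extra_scalar_id] : 0;
  } else {
    out["subclone_genotype"] = 0;
    out["subclone_carriers"] = 0;
  }
  out["extra"] = extra_scalar;
  return out;
}

// Stochastic driver-arrival simulator with multiplicative fitness.
// Each daughter cell draws Poisson(mu) new mutations; each new mutation is a
// driver with probability p_driver until max_drivers driver events occurred,
// receiving s ~ Exp(mean = s_mean) and multiplying the birth rate by (1+s).
// Rejection-kinetic update: a random cell is sampled uniformly; an event is
// accepted with probability (b_i + d) / (b_max + d) and is a death with
// probability d / (b_i + d).
// [[Rcpp::export]]
List cpp_sim_selection(double mu, double p_driver, double s_mean, int n_clonal,
                       int max_drivers, int n_final, double birth, double death,
                       int max_retries) {
  for (int attempt = 0; attempt <= max_retries; ++attempt) {
    GenotypeTable gt;
    gt.add(-1, n_clonal, 0, 0.0, birth);
    std::vector<int> cells;
    cells.reserve(n_final + 1);
    cells.push_back(0);
    double b_max = birth;
    int drivers_used = 0;
    bool extinct = false;
    while ((int)cells.size() < n_final) {
      int idx = (int)(unif_rand() * cells.size());
      if (idx >= (int)cells.size()) idx = cells.size() - 1;
      int g = cells[idx];
      double b_g = gt.birth[g];
      if (unif_rand() * (b_max + death) >= (b_g + death)) continue;  // reject
      if (death > 0 && unif_rand() * (b_g + death) < death) {
        cells[idx] = cells.back();
        cells.pop_back();
        if (cells.empty()) { extinct = true; break; }
        continue;
      }
      // division: two daughters, each mutates independently
      for (int dtr = 0; dtr < 2; ++dtr) {
        int k = (int)R::rpois(mu);
        int nd = 0;
        double ss = 0.0;
        if (p_driver > 0 && drivers_used < max_drivers && k > 0) {
          for (int j = 0; j < k && drivers_used < max_drivers; ++j) {
            if (unif_rand() < p_driver) {
              double s = R::rexp(s_mean);
              ss += std::log1p(s);
              nd++;
              drivers_used++;
            }
          }
        }
        int nn = k - nd;
        int new_g = g;
        if (k > 0) {
          double b_new = gt.birth[g] * std::exp(ss);
          gt.add(g, nn, nd, ss, b_new);
          new_g = gt.parent.size() - 1;
          if (b_new > b_max) b_max = b_new;
        }
        if (dtr == 0) {
          cells[idx] = new_g;
        } else {
          cells.push_back(new_g);
        }
      }
    }
    if (!extinct) return finalize(gt, cells, birth);
  }
  stop("population went extinct in every attempt (%d retries)", max_retries);
  return List::create();  // unreachable
}

// Deterministic-subclone simulator: one subclone founded by a random cell when
// the population first reaches 2^t_s cells; its net growth rate (b - d) is
// multiplied by `fitness` (so b_sub = d + fitness * (b - d)). Neutral
// mutations accumulate as in cpp_sim_selection.
// [[Rcpp::export]]
List cpp_sim_deterministic(double mu, int n_clonal, double birth, double death,
                           int n_final, double fitness, double t_s,
                           int max_retries) {
  double trigger_d = std::pow(2.0, t_s);
  int trigger = (trigger_d >= (double)n_final) ? -1
                : std::max(2, (int)std::lround(trigger_d));
  double b_sub = death + fitness * (birth - death);
  for (int attempt = 0; attempt <= max_retries; ++attempt) {
    GenotypeTable gt;
    gt.add(-1, n_clonal, 0, 0.0, birth);
    std::vector<int> cells;
    cells.reserve(n_final + 1);
    cells.push_back(0);
    double b_max = birth;
    int sub_geno = -1;
    bool extinct = false;
    while ((int)cells.size() < n_final) {
      if (sub_geno < 0 && trigger > 0 && (int)cells.size() >= trigger) {
        int idx = (int)(unif_rand() * cells.size());
        if (idx >= (int)cells.size()) idx = cells.size() - 1;
        int g = cells[idx];
        double ss = std::log(b_sub / gt.birth[g]);
        gt.add(g, 0, 1, ss, b_sub);
        sub_geno = gt.parent.size() - 1;
        cells[idx] = sub_geno;
        if (b_sub > b_max) b_max = b_sub;
      }
      int idx = (int)(unif_rand() * cells.size());
      if (idx >= (int)cells.size()) idx = cells.size() - 1;
      int g = cells[idx];
      double b_g = gt.birth[g];
      if (unif_rand() * (b_max + death) >= (b_g + death)) continue;
      if (death > 0 && unif_rand() * (b_g + death) < death) {
        cells[idx] = cells.back();
        cells.pop_back();
        if (cells.empty()) { extinct = true; break; }
        continue;
      }
      for (int dtr = 0; dtr < 2; ++dtr) {
        int k = (int)R::rpois(mu);
        int new_g = g;
        if (k > 0) {
          gt.add(g, k, 0, 0.0, gt.birth[g]);
          new_g = gt.parent.size() - 1;
        }
        if (dtr == 0) {
          cells[idx] = new_g;
        } else {
          cells.push_back(new_g);
        }
      }
    }
    if (!extinct) return finalize(gt, cells, birth, sub_geno, t_s);
  }
  stop("population went extinct in every attempt (%d retries)", max_retries);
  return List::create();  // unreachable
}
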