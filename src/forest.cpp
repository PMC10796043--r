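// Honest subsampled forest engine shared by the regression, causal and
// instrumental forests.  Trees are grown greedily on the split half of a
// household-level subsample; leaf payloads (the sufficient statistics of the
// locally weighted ratio estimator) come from the disjoint estimation half.
//
// type 0: regression   leaf value  = sum(w y) / sum(w)
// type 1: causal       leaf effect = sum(w yres zres) / sum(w zres^2)
// type 2: instrumental leaf effect = sum(w zres yres) / sum(w zres dres)
//
// Splits maximize, for type 0, the weighted between-child sum of squares and,
// for types 1/2, the gain in the negative expected-MSE criterion
//   crit(node) = n_node * tau_hat^2 / Ntr
//              - (1/Ntr + 1/Nest) * (S2_treated/p + S2_control/(1-p))
// evaluated on split-half residualized data with survey-weighted within-leaf
// estimators and variances; Ntr/Nest are the tree-level half sizes.
//
// Node data (response, weight, residuals, treatment flag) are carried in
// contiguous per-node buffers so the split search touches only one scattered
// array (the candidate covariate column).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <random>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// one honesty half of a node: parallel contiguous arrays
struct Half {
  std::vector<int> rows;      // original row ids (for covariate lookup)
  std::vector<double> y, w, z, d;
  std::vector<char> tr;       // treated flag

  void reserve(size_t m) {
    rows.reserve(m); y.reserve(m); w.reserve(m); z.reserve(m); d.reserve(m);
    tr.reserve(m);
  }
  void push(int r, double yi, double wi, double zi, double di, char ti) {
    rows.push_back(r); y.push_back(yi); w.push_back(wi); z.push_back(zi);
    d.push_back(di); tr.push_back(ti);
  }
  size_t size() const { return rows.size(); }
};

struct NodeStats {
  double n = 0.0;            // unweighted count
  double nt = 0.0, nc = 0.0; // treated / control counts
  double sw = 0.0, swy = 0.0;
  double sw_t = 0.0, sw_c = 0.0;
  double swy_t = 0.0, swy_c = 0.0;
  double swy2_t = 0.0, swy2_c = 0.0;
  double swzy = 0.0, swden = 0.0; // w*z*y and w*z^2 (or w*z*d)
};

inline void add_obs(NodeStats& s, const Half& h, size_t k, int type) {
  const double wi = h.w[k], yi = h.y[k];
  s.n += 1.0; s.sw += wi; s.swy += wi * yi;
  if (type != 0) {
    const double zi = h.z[k];
    s.swzy += wi * zi * yi;
    s.swden += wi * zi * (type == 2 ? h.d[k] : zi);
    if (h.tr[k]) {
      s.nt += 1.0; s.sw_t += wi; s.swy_t += wi * yi; s.swy2_t += wi * yi * yi;
    } else {
      s.nc += 1.0; s.sw_c += wi; s.swy_c += wi * yi; s.swy2_c += wi * yi * yi;
    }
  }
}

// negative-EMSE contribution of one (candidate) leaf; false when the ratio
// estimator or the variance penalty is undefined on this half
inline bool emse_crit(const NodeStats& s, double inv_ntr, double K,
                      double* out) {
  if (std::fabs(s.swden) < 1e-12 || s.sw_t <= 0.0 || s.sw_c <= 0.0)
    return false;
  const double tau = s.swzy / s.swden;
  const double pshare = s.sw_t / (s.sw_t + s.sw_c);
  double var_t = s.swy2_t / s.sw_t - (s.swy_t / s.sw_t) * (s.swy_t / s.sw_t);
  double var_c = s.swy2_c / s.sw_c - (s.swy_c / s.sw_c) * (s.swy_c / s.sw_c);
  if (var_t < 0.0) var_t = 0.0;
  if (var_c < 0.0) var_c = 0.0;
  const double V = var_t / pshare + var_c / (1.0 - pshare);
  *out = s.n * tau * tau * inv_ntr - K * V;
  return true;
}

struct Forest {
  std::vector<int> node_var, node_left, node_right, node_depth;
  std::vector<double> node_thr;
  std::vector<double> leaf_sumA, leaf_sumB, leaf_cnt, leaf_value;
  std::vector<int> leaf_inherit;
  std::vector<int> tree_offset;     // length n_trees + 1
  std::vector<int> inbag_hh, inbag_offset;
  std::vector<int> est_rows, est_leaf, est_offset;
};

struct WorkItem {
  int node_id;
  Half split, est;
  int depth;
  double parent_value;
  bool parent_valid;
};

} // namespace

// [[Rcpp::export(name = ".hf_grow_forest")]]
List hf_grow_forest(NumericMatrix X, NumericVector y, NumericVector z,
                    NumericVector d, IntegerVector treated, NumericVector w,
                    IntegerVector hh, int n_households, int type, int n_trees,
                    double sample_fraction, double honesty_fraction, int mtry,
                    int min_node_size, double alpha_imbalance,
                    double imbalance_penalty, int seed) {
  const int n = X.nrow(), p = X.ncol();
  const double* Xp = REAL(X);
  const double* yp = REAL(y);
  const double* zp = REAL(z);
  const double* dp = REAL(d);
  const int* trp = INTEGER(treated);
  const double* wp = REAL(w);

  // household -> member rows
  std::vector<std::vector<int>> rows_of_hh(n_households);
  for (int i = 0; i < n; ++i) rows_of_hh[hh[i]].push_back(i);

  // 0/1 covariates take a counting fast path in the split search
  std::vector<char> is_binary(p, 1);
  for (int j = 0; j < p; ++j) {
    const double* xj = Xp + static_cast<size_t>(j) * n;
    for (int i = 0; i < n; ++i) {
      if (xj[i] != 0.0 && xj[i] != 1.0) { is_binary[j] = 0; break; }
    }
  }

  std::mt19937 master(static_cast<uint32_t>(seed));
  std::vector<uint32_t> tree_seeds(n_trees);
  for (int b = 0; b < n_trees; ++b) tree_seeds[b] = master();

  Forest F;
  F.tree_offset.push_back(0);
  F.inbag_offset.push_back(0);
  F.est_offset.push_back(0);

  std::vector<int> hh_idx(n_households);
  std::vector<int> covar_buf(p);
  std::vector<std::pair<double, int>> xs_s, xs_e;

  int n_sub_hh = static_cast<int>(std::llround(sample_fraction * n_households));
  if (n_sub_hh < 1) n_sub_hh = 1;
  if (n_sub_hh > n_households) n_sub_hh = n_households;

  for (int b = 0; b < n_trees; ++b) {
    std::mt19937 rng(tree_seeds[b]);

    // household-level subsample without replacement (partial Fisher-Yates)
    for (int h = 0; h < n_households; ++h) hh_idx[h] = h;
    for (int k = 0; k < n_sub_hh; ++k) {
      std::uniform_int_distribution<int> U(k, n_households - 1);
      std::swap(hh_idx[k], hh_idx[U(rng)]);
    }
    // honest split of the subsample, again at household level
    int n_tr_hh = static_cast<int>(std::llround(honesty_fraction * n_sub_hh));
    if (n_sub_hh >= 2) {
      if (n_tr_hh < 1) n_tr_hh = 1;
      if (n_tr_hh > n_sub_hh - 1) n_tr_hh = n_sub_hh - 1;
    } else {
      n_tr_hh = 1;
    }
    for (int k = 0; k < n_sub_hh; ++k) {
      std::uniform_int_distribution<int> U(k, n_sub_hh - 1);
      std::swap(hh_idx[k], hh_idx[U(rng)]);
    }

    Half split_half, est_half;
    for (int k = 0; k < n_sub_hh; ++k) {
      Half& target = (k < n_tr_hh) ? split_half : est_half;
      for (int r : rows_of_hh[hh_idx[k]]) {
        target.push(r, yp[r], wp[r], zp[r], dp[r],
                    static_cast<char>(trp[r]));
      }
      F.inbag_hh.push_back(hh_idx[k]);
    }
    F.inbag_offset.push_back(static_cast<int>(F.inbag_hh.size()));

    const double Ntr = std::max<double>(1.0, split_half.size());
    const double Nest = std::max<double>(1.0, est_half.size());
    const double inv_ntr = 1.0 / Ntr;
    const double K = 1.0 / Ntr + 1.0 / Nest;

    auto new_node = [&](int depth) {
      F.node_var.push_back(-1); F.node_thr.push_back(0.0);
      F.node_left.push_back(-1); F.node_right.push_back(-1);
      F.node_depth.push_back(depth);
      F.leaf_sumA.push_back(0.0); F.leaf_sumB.push_back(0.0);
      F.leaf_cnt.push_back(0.0); F.leaf_value.push_back(0.0);
      F.leaf_inherit.push_back(0);
      return static_cast<int>(F.node_var.size()) - 1;
    };

    std::vector<WorkItem> stack;
    {
      WorkItem root;
      root.node_id = new_node(1);
      root.split = std::move(split_half);
      root.est = std::move(est_half);
      root.depth = 1;
      root.parent_value = 0.0;
      root.parent_valid = false;
      stack.push_back(std::move(root));
    }

    while (!stack.empty()) {
      WorkItem it = std::move(stack.back());
      stack.pop_back();
      const int node = it.node_id;
      const int ns = static_cast<int>(it.split.size());
      const int ne = static_cast<int>(it.est.size());

      // estimation-half payload of this node (leaf value if it stays a
      // leaf, and the inherited fallback for descendants)
      NodeStats est;
      for (int k = 0; k < ne; ++k) add_obs(est, it.est, k, type);
      double sumA, sumB;
      if (type == 0) { sumA = est.swy; sumB = est.sw; }
      else           { sumA = est.swzy; sumB = est.swden; }
      double own_value; bool own_valid;
      if (std::fabs(sumB) > 1e-12) { own_value = sumA / sumB; own_valid = true; }
      else { own_value = it.parent_value; own_valid = false; }

      // parent (split-half) stats, and whether a split is even evaluable
      NodeStats par;
      for (int k = 0; k < ns; ++k) add_obs(par, it.split, k, type);
      bool can_split = ns >= 2;
      double par_crit = 0.0;
      if (can_split && type != 0)
        can_split = emse_crit(par, inv_ntr, K, &par_crit);

      int best_var = -1; double best_thr = 0.0, best_gain = 0.0;

      if (can_split) {
        int minside = static_cast<int>(std::ceil(alpha_imbalance * ns));
        if (minside < 1) minside = 1;

        // draw mtry distinct covariates, examined in ascending index order
        for (int j = 0; j < p; ++j) covar_buf[j] = j;
        int m = std::min(mtry, p);
        for (int k = 0; k < m; ++k) {
          std::uniform_int_distribution<int> U(k, p - 1);
          std::swap(covar_buf[k], covar_buf[U(rng)]);
        }
        std::sort(covar_buf.begin(), covar_buf.begin() + m);

        // evaluate one candidate (left stats + est-half left counts)
        auto eval_split = [&](const NodeStats& L, int nL, double est_l_n,
                              double est_l_t, double est_l_c, double thr,
                              int j) {
          const int nR = ns - nL;
          if (nL < minside || nR < minside) return;
          if (type == 0) {
            if (est_l_n < min_node_size || (ne - est_l_n) < min_node_size)
              return;
          } else {
            if (est_l_t < min_node_size || est_l_c < min_node_size) return;
            if ((est.nt - est_l_t) < min_node_size ||
                (est.nc - est_l_c) < min_node_size)
              return;
          }
          double gain;
          if (type == 0) {
            if (L.sw <= 0.0 || (par.sw - L.sw) <= 0.0) return;
            const double swyR = par.swy - L.swy, swR = par.sw - L.sw;
            gain = L.swy * L.swy / L.sw + swyR * swyR / swR -
                   par.swy * par.swy / par.sw;
          } else {
            NodeStats R;
            R.n = par.n - L.n; R.nt = par.nt - L.nt; R.nc = par.nc - L.nc;
            R.sw_t = par.sw_t - L.sw_t; R.sw_c = par.sw_c - L.sw_c;
            R.swy_t = par.swy_t - L.swy_t; R.swy_c = par.swy_c - L.swy_c;
            R.swy2_t = par.swy2_t - L.swy2_t; R.swy2_c = par.swy2_c - L.swy2_c;
            R.swzy = par.swzy - L.swzy; R.swden = par.swden - L.swden;
            double cl, cr;
            if (!emse_crit(L, inv_ntr, K, &cl)) return;
            if (!emse_crit(R, inv_ntr, K, &cr)) return;
            gain = cl + cr - par_crit;
          }
          gain -= imbalance_penalty * (1.0 / nL + 1.0 / nR);
          if (gain > best_gain) {
            best_gain = gain; best_var = j; best_thr = thr;
          }
        };

        for (int jj = 0; jj < m; ++jj) {
          const int j = covar_buf[jj];
          const double* xj = Xp + static_cast<size_t>(j) * n;

          if (is_binary[j]) {
            NodeStats L;
            int nL = 0;
            for (int k = 0; k < ns; ++k) {
              if (xj[it.split.rows[k]] == 0.0) {
                add_obs(L, it.split, k, type);
                ++nL;
              }
            }
            if (nL == 0 || nL == ns) continue;
            double est_l_t = 0.0, est_l_c = 0.0, est_l_n = 0.0;
            for (int k = 0; k < ne; ++k) {
              if (xj[it.est.rows[k]] == 0.0) {
                est_l_n += 1.0;
                if (type != 0) {
                  if (it.est.tr[k]) est_l_t += 1.0; else est_l_c += 1.0;
                }
              }
            }
            eval_split(L, nL, est_l_n, est_l_t, est_l_c, 0.5, j);
            continue;
          }

          xs_s.clear(); xs_e.clear();
          for (int k = 0; k < ns; ++k)
            xs_s.emplace_back(xj[it.split.rows[k]], k);
          for (int k = 0; k < ne; ++k)
            xs_e.emplace_back(xj[it.est.rows[k]], k);
          std::sort(xs_s.begin(), xs_s.end());
          std::sort(xs_e.begin(), xs_e.end());

          NodeStats L;
          int e_ptr = 0;
          double est_l_t = 0.0, est_l_c = 0.0, est_l_n = 0.0;

          for (int i = 0; i + 1 < ns; ++i) {
            add_obs(L, it.split, xs_s[i].second, type);
            if (xs_s[i].first == xs_s[i + 1].first) continue;
            const double thr = 0.5 * (xs_s[i].first + xs_s[i + 1].first);
            while (e_ptr < ne && xs_e[e_ptr].first <= thr) {
              const int k = xs_e[e_ptr].second;
              est_l_n += 1.0;
              if (type != 0) {
                if (it.est.tr[k]) est_l_t += 1.0; else est_l_c += 1.0;
              }
              ++e_ptr;
            }
            eval_split(L, i + 1, est_l_n, est_l_t, est_l_c, thr, j);
          }
        }
      }

      if (best_var >= 0 && best_gain > 0.0) {
        F.node_var[node] = best_var;
        F.node_thr[node] = best_thr;
        WorkItem Litem, Ritem;
        Litem.depth = Ritem.depth = it.depth + 1;
        Litem.parent_value = Ritem.parent_value =
            own_valid ? own_value : it.parent_value;
        Litem.parent_valid = own_valid || it.parent_valid;
        Ritem.parent_valid = Litem.parent_valid;
        const double* xj = Xp + static_cast<size_t>(best_var) * n;
        for (size_t k = 0; k < it.split.size(); ++k) {
          Half& tgt = (xj[it.split.rows[k]] <= best_thr) ? Litem.split
                                                         : Ritem.split;
          tgt.push(it.split.rows[k], it.split.y[k], it.split.w[k],
                   it.split.z[k], it.split.d[k], it.split.tr[k]);
        }
        for (size_t k = 0; k < it.est.size(); ++k) {
          Half& tgt = (xj[it.est.rows[k]] <= best_thr) ? Litem.est
                                                       : Ritem.est;
          tgt.push(it.est.rows[k], it.est.y[k], it.est.w[k], it.est.z[k],
                   it.est.d[k], it.est.tr[k]);
        }
        Litem.node_id = new_node(Litem.depth);
        Ritem.node_id = new_node(Ritem.depth);
        F.node_left[node] = Litem.node_id;
        F.node_right[node] = Ritem.node_id;
        // right pushed first so the left child is processed next (fixed,
        // deterministic traversal order for the node RNG stream)
        stack.push_back(std::move(Ritem));
        stack.push_back(std::move(Litem));
      } else {
        // leaf: estimation-half payload
        F.leaf_sumA[node] = sumA;
        F.leaf_sumB[node] = sumB;
        F.leaf_cnt[node] = static_cast<double>(ne);
        F.leaf_value[node] = own_valid ? own_value : it.parent_value;
        F.leaf_inherit[node] = own_valid ? 0 : 1;
        for (int k = 0; k < ne; ++k) {
          F.est_rows.push_back(it.est.rows[k]);
          F.est_leaf.push_back(node);
        }
      }
    }

    F.est_offset.push_back(static_cast<int>(F.est_rows.size()));
    F.tree_offset.push_back(static_cast<int>(F.node_var.size()));
  }

  return List::create(
      _["n_rows"] = n, _["n_features"] = p, _["n_households"] = n_households,
      _["type"] = type, _["n_trees"] = n_trees,
      _["node_var"] = wrap(F.node_var), _["node_thr"] = wrap(F.node_thr),
      _["node_left"] = wrap(F.node_left), _["node_right"] = wrap(F.node_right),
      _["node_depth"] = wrap(F.node_depth),
      _["leaf_sumA"] = wrap(F.leaf_sumA), _["leaf_sumB"] = wrap(F.leaf_sumB),
      _["leaf_cnt"] = wrap(F.leaf_cnt), _["leaf_value"] = wrap(F.leaf_value),
      _["leaf_inherit"] = wrap(F.leaf_inherit),
      _["tree_offset"] = wrap(F.tree_offset),
      _["inbag_hh"] = wrap(F.inbag_hh),
      _["inbag_offset"] = wrap(F.inbag_offset),
      _["est_rows"] = wrap(F.est_rows), _["est_leaf"] = wrap(F.est_leaf),
      _["est_offset"] = wrap(F.est_offset));
}

namespace {
inline int walk_to_leaf(const int* var, const double* thr, const int* left,
                        const int* right, int node, const double* X, int n,
                        int row) {
  while (var[node] >= 0) {
    const double x = X[static_cast<size_t>(var[node]) * n + row];
    node = (x <= thr[node]) ? left[node] : right[node];
  }
  return node;
}
} // namespace

// Kernel-weighted prediction over all trees (newdata mode).
// [[Rcpp::export(name = ".hf_predict")]]
List hf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  IntegerVector tree_offset = forest["tree_offset"];
  IntegerVector node_var = forest["node_var"];
  NumericVector node_thr = forest["node_thr"];
  IntegerVector node_left = forest["node_left"];
  IntegerVector node_right = forest["node_right"];
  NumericVector leaf_sumA = forest["leaf_sumA"];
  NumericVector leaf_sumB = forest["leaf_sumB"];
  NumericVector leaf_cnt = forest["leaf_cnt"];
  const int n_trees = as<int>(forest["n_trees"]);

  std::vector<double> num(n, 0.0), den(n, 0.0);
  std::vector<int> used(n, 0);
  for (int b = 0; b < n_trees; ++b) {
    const int root = tree_offset[b];
    for (int i = 0; i < n; ++i) {
      const int leaf =
          walk_to_leaf(INTEGER(node_var), REAL(node_thr), INTEGER(node_left),
                       INTEGER(node_right), root, REAL(X), n, i);
      if (leaf_cnt[leaf] > 0.0) {
        num[i] += leaf_sumA[leaf] / leaf_cnt[leaf];
        den[i] += leaf_sumB[leaf] / leaf_cnt[leaf];
        used[i] += 1;
      }
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (used[i] == 0 || std::fabs(den[i]) < 1e-12) ? NA_REAL
                                                         : num[i] / den[i];
  return List::create(_["value"] = out, _["n_trees_used"] = wrap(used));
}

// Out-of-bag prediction: person i uses only trees whose household-level
// subsample excludes i's household.
// [[Rcpp::export(name = ".hf_predict_oob")]]
List hf_predict_oob_cpp(List forest, NumericMatrix X, IntegerVector hh) {
  const int n = X.nrow();
  IntegerVector tree_offset = forest["tree_offset"];
  IntegerVector node_var = forest["node_var"];
  NumericVector node_thr = forest["node_thr"];
  IntegerVector node_left = forest["node_left"];
  IntegerVector node_right = forest["node_right"];
  NumericVector leaf_sumA = forest["leaf_sumA"];
  NumericVector leaf_sumB = forest["leaf_sumB"];
  NumericVector leaf_cnt = forest["leaf_cnt"];
  IntegerVector inbag_hh = forest["inbag_hh"];
  IntegerVector inbag_offset = forest["inbag_offset"];
  const int n_trees = as<int>(forest["n_trees"]);
  const int H = as<int>(forest["n_households"]);

  std::vector<double> num(n, 0.0), den(n, 0.0);
  std::vector<int> used(n, 0);
  std::vector<char> inbag(H, 0);
  for (int b = 0; b < n_trees; ++b) {
    for (int k = inbag_offset[b]; k < inbag_offset[b + 1]; ++k)
      inbag[inbag_hh[k]] = 1;
    const int root = tree_offset[b];
    for (int i = 0; i < n; ++i) {
      if (inbag[hh[i]]) continue;
      const int leaf =
          walk_to_leaf(INTEGER(node_var), REAL(node_thr), INTEGER(node_left),
                       INTEGER(node_right), root, REAL(X), n, i);
      if (leaf_cnt[leaf] > 0.0) {
        num[i] += leaf_sumA[leaf] / leaf_cnt[leaf];
        den[i] += leaf_sumB[leaf] / leaf_cnt[leaf];
        used[i] += 1;
      }
    }
    for (int k = inbag_offset[b]; k < inbag_offset[b + 1]; ++k)
      inbag[inbag_hh[k]] = 0;
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (used[i] == 0 || std::fabs(den[i]) < 1e-12) ? NA_REAL
                                                         : num[i] / den[i];
  return List::create(_["value"] = out, _["n_trees_used"] = wrap(used));
}

// Normalized kernel weights alpha_i(x) for one query point: average over
// (usable) trees of 1/|leaf| for estimation-half members sharing x's leaf.
// exclude_hh >= 0 restricts to trees whose subsample excludes that household.
// [[Rcpp::export(name = ".hf_alpha")]]
List hf_alpha_cpp(List forest, NumericVector xrow, int exclude_hh) {
  IntegerVector tree_offset = forest["tree_offset"];
  IntegerVector node_var = forest["node_var"];
  NumericVector node_thr = forest["node_thr"];
  IntegerVector node_left = forest["node_left"];
  IntegerVector node_right = forest["node_right"];
  NumericVector leaf_cnt = forest["leaf_cnt"];
  IntegerVector inbag_hh = forest["inbag_hh"];
  IntegerVector inbag_offset = forest["inbag_offset"];
  IntegerVector est_rows = forest["est_rows"];
  IntegerVector est_leaf = forest["est_leaf"];
  IntegerVector est_offset = forest["est_offset"];
  const int n_trees = as<int>(forest["n_trees"]);
  const int n = as<int>(forest["n_rows"]);

  std::vector<double> alpha(n, 0.0);
  int used = 0;
  for (int b = 0; b < n_trees; ++b) {
    if (exclude_hh >= 0) {
      bool in = false;
      for (int k = inbag_offset[b]; k < inbag_offset[b + 1]; ++k)
        if (inbag_hh[k] == exclude_hh) { in = true; break; }
      if (in) continue;
    }
    int node = tree_offset[b];
    while (node_var[node] >= 0) {
      const double x = xrow[node_var[node]];
      node = (x <= node_thr[node]) ? node_left[node] : node_right[node];
    }
    if (leaf_cnt[node] <= 0.0) continue;
    ++used;
    const double wleaf = 1.0 / leaf_cnt[node];
    for (int k = est_offset[b]; k < est_offset[b + 1]; ++k)
      if (est_leaf[k] == node) alpha[est_rows[k]] += wleaf;
  }
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += alpha[i];
  if (tot > 0.0)
    for (int i = 0; i < n; ++i) alpha[i] /= tot;
  return List::create(_["alpha"] = wrap(alpha), _["n_trees_used"] = used);
}
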