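#include <Rcpp.h>
using namespace Rcpp;

// Exact interventional Shapley attributions for a tree ensemble.
//
// For a single explained point x, a single background point z and one
// regression tree, the coalition game is
//   nu(S) = f(composite point taking x on S and z elsewhere),
// which decomposes over leaves: a leaf L is reached iff every feature that x
// and z route differently through L's path is routed x-wards (feature in S)
// or z-wards (feature not in S) as the path demands.  With a unique
// x-feature set A and z-feature set B on the path (|A| = a, |B| = b), the
// leaf contributes its value v times
//   (a-1)! b! / (a+b)!   to phi_i for i in A, and
//  -a! (b-1)! / (a+b)!   to phi_i for i in B.
// Features on which x and z agree never enter the game.  The recursion
// below walks each tree once per (x, z) pair, pruning subtrees both points
// leave together, and averages over the background.

struct TreeArrays {
  IntegerVector feat;   // 0-based feature, -1 for leaf
  NumericVector thr;
  IntegerVector yes;    // 0-based child positions
  IntegerVector no;
  NumericVector val;    // leaf value (0 for internal)
};

static const int MAXF = 64;

static void walk(const TreeArrays &tr, int node,
                 const double *x, const double *z,
                 int *state,            // 0 free, 1 forced-x, 2 forced-z
                 int *path, int npath,  // features currently forced
                 int a, int b,
                 const double *lfact, double *phi) {
  int f = tr.feat[node];
  if (f < 0) {  // leaf
    if (a == 0 && b == 0) return;  // reached identically by x and z
    double v = tr.val[node];
    double lden = lfact[a + b];
    if (a > 0) {
      double wpos = std::exp(lfact[a - 1] + lfact[b] - lden);
      for (int i = 0; i < npath; ++i)
        if (state[path[i]] == 1) phi[path[i]] += v * wpos;
    }
    if (b > 0) {
      double wneg = std::exp(lfact[a] + lfact[b - 1] - lden);
      for (int i = 0; i < npath; ++i)
        if (state[path[i]] == 2) phi[path[i]] -= v * wneg;
    }
    return;
  }
  // xgboost stores thresholds and compares features in float32; replicate
  // that exactly, otherwise points lying on a threshold route differently
  int dx = ((float)x[f] < (float)tr.thr[node]) ? tr.yes[node] : tr.no[node];
  int dz = ((float)z[f] < (float)tr.thr[node]) ? tr.yes[node] : tr.no[node];
  if (dx == dz) {
    walk(tr, dx, x, z, state, path, npath, a, b, lfact, phi);
  } else if (state[f] == 1) {
    walk(tr, dx, x, z, state, path, npath, a, b, lfact, phi);
  } else if (state[f] == 2) {
    walk(tr, dz, x, z, state, path, npath, a, b, lfact, phi);
  } else {
    state[f] = 1; path[npath] = f;
    walk(tr, dx, x, z, state, path, npath + 1, a + 1, b, lfact, phi);
    state[f] = 2;
    walk(tr, dz, x, z, state, path, npath + 1, a, b + 1, lfact, phi);
    state[f] = 0;
  }
}

// trees: list of lists with integer vectors feat/yes/no (0-based) and
// numeric vectors thr/val; X: samples to explain; Z: background points.
// Returns an n x p matrix of attributions that sum per row to
// f(x) - mean_z f(z) over the ensemble's leaf contributions.
// [[Rcpp::export]]
NumericMatrix itshap_cpp(List trees, NumericMatrix X, NumericMatrix Z) {
  int n = X.nrow(), p = X.ncol(), nz = Z.nrow(), nt = trees.size();
  if (Z.ncol() != p) stop("background feature count mismatch");
  std::vector<TreeArrays> tv(nt);
  for (int k = 0; k < nt; ++k) {
    List t = trees[k];
    tv[k].feat = t["feat"]; tv[k].thr = t["thr"];
    tv[k].yes = t["yes"];   tv[k].no = t["no"];
    tv[k].val = t["val"];
  }
  double lfact[MAXF + 1];
  lfact[0] = 0.0;
  for (int i = 1; i <= MAXF; ++i) lfact[i] = lfact[i - 1] + std::log((double)i);

  NumericMatrix out(n, p);
  std::vector<double> xrow(p), zrow(p), phi(p);
  std::vector<int> state(p), path(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
    std::fill(phi.begin(), phi.end(), 0.0);
    for (int iz = 0; iz < nz; ++iz) {
      for (int j = 0; j < p; ++j) zrow[j] = Z(iz, j);
      std::fill(state.begin(), state.end(), 0);
      for (int k = 0; k < nt; ++k)
        walk(tv[k], 0, xrow.data(), zrow.data(),
             state.data(), path.data(), 0, 0, 0, lfact, phi.data());
    }
    for (int j = 0; j < p; ++j) out(i, j) = phi[j] / nz;
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
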