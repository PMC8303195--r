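#include <Rcpp.h>
using namespace Rcpp;

// Single-site Metropolis chain on a q1 x q2 spin lattice with frozen
// seed sites.  Vertical adjacency is open (q1 - 1 edges per column),
// horizontal adjacency wraps around each row.  One iteration = one
// proposal: a free site drawn uniformly, then u ~ U(0,1); draws come
// from R's RNG so set.seed() on the R side fixes the trajectory.
// Snapshots is a sorted vector of iteration counts (0 allowed = the
// initial state); the result is a q1 x q2 x L integer array.
// [[Rcpp::export]]
IntegerVector metropolis_chain_cpp(IntegerMatrix init, LogicalMatrix frozen,
                                   double jv, double jh,
                                   NumericVector snapshots) {
  const int q1 = init.nrow(), q2 = init.ncol();
  const int L = snapshots.size();
  IntegerMatrix x = clone(init);

  std::vector<int> free_r, free_c;
  for (int j = 0; j < q2; ++j)
    for (int i = 0; i < q1; ++i)
      if (!frozen(i, j)) { free_r.push_back(i); free_c.push_back(j); }
  const int nfree = (int)free_r.size();

  IntegerVector out(Dimension(q1, q2, L));
  int next_snap = 0;
  const double n_max = snapshots[L - 1];

  // exp(-2 * x_k * (jv * sv + jh * sh)) has few possible exponents;
  // computing exp() directly is cheap enough at these problem sizes.
  double iter = 0.0;
  while (true) {
    while (next_snap < L && snapshots[next_snap] == iter) {
      std::copy(x.begin(), x.end(), out.begin() + (R_xlen_t)next_snap * q1 * q2);
      ++next_snap;
    }
    if (iter >= n_max || nfree == 0) break;

    int pick = (int)(unif_rand() * nfree);
    if (pick >= nfree) pick = nfree - 1;
    const int i = free_r[pick], j = free_c[pick];

    int sv = 0;
    if (i > 0) sv += x(i - 1, j);
    if (i < q1 - 1) sv += x(i + 1, j);
    const int jl = (j == 0) ? q2 - 1 : j - 1;
    const int jr = (j == q2 - 1) ? 0 : j + 1;
    const int sh = x(i, jl) + x(i, jr);

    const double ratio = std::exp(-2.0 * x(i, j) * (jv * sv + jh * sh));
    const double u = unif_rand();
    if (u < ratio) x(i, j) = -x(i, j);
    iter += 1.0;
  }
  // if nfree == 0 the state never changes: fill remaining snapshots
  while (next_snap < L) {
    std::copy(x.begin(), x.end(), out.begin() + (R_xlen_t)next_snap * q1 * q2);
    ++next_snap;
  }
  return out;
}
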