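// Simplex-constrained least squares and the exhaustive vertex search.
//
// delta_c = min_{alpha >= 0, sum alpha = 1} || g_c - V' alpha ||_2
//
// Everything is expressed in inner products (Gram matrix form), so the
// vertex search precomputes one C x C Gram matrix of cluster centers and
// each candidate subset only indexes into it. The solver enumerates the
// support of the optimizer (2^K - 1 subsets, K is small): for each support
// the equality-constrained KKT system is solved with all targets as
// simultaneous right-hand sides, feasible solutions compete on the
// objective. Affinely dependent vertex sets fall back to a pseudo-inverse.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// squared distances (and optionally weights) for all targets given
// G = V V' (K x K), H = V Gm' (K x M), gsq = row norms^2 of targets
static void support_enumeration(const mat& G, const mat& H, const vec& gsq,
                                vec& best_f, mat* best_a) {
  const uword K = G.n_rows, M = H.n_cols;
  best_f.set_size(M);
  best_f.fill(datum::inf);
  if (best_a) {
    best_a->set_size(K, M);
    best_a->fill(1.0 / K);
  }
  const unsigned long n_masks = (1UL << K);
  for (unsigned long maskbits = 1; maskbits < n_masks; ++maskbits) {
    uvec S(K);
    uword s = 0;
    for (uword k = 0; k < K; ++k)
      if (maskbits & (1UL << k)) S(s++) = k;
    S.resize(s);

    mat kkt(s + 1, s + 1, fill::ones);
    kkt.submat(0, 0, s - 1, s - 1) = G.submat(S, S);
    kkt(s, s) = 0.0;
    mat rhs(s + 1, M);
    rhs.rows(0, s - 1) = H.rows(S);
    rhs.row(s).ones();
    mat sol;
    if (!solve(sol, kkt, rhs, solve_opts::no_approx)) {
      mat kkt_pinv;
      if (!pinv(kkt_pinv, kkt)) continue;
      sol = kkt_pinv * rhs;
    }
    mat aS = sol.rows(0, s - 1);
    const mat GSS = G.submat(S, S);
    for (uword j = 0; j < M; ++j) {
      vec a = aS.col(j);
      if (a.min() < -1e-10) continue;
      a = clamp(a, 0.0, datum::inf);
      const double tot = accu(a);
      if (tot <= 0) continue;
      a /= tot;
      const double f = gsq(j) - 2.0 * dot(a, H.submat(S, uvec{j})) +
        dot(a, GSS * a);
      if (f < best_f(j) - 1e-15) {
        best_f(j) = f;
        if (best_a) {
          best_a->col(j).zeros();
          for (uword t = 0; t < s; ++t) (*best_a)(S(t), j) = a(t);
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_simplex_lsq(const arma::mat& G, const arma::mat& H,
                           const arma::vec& gsq) {
  vec best_f;
  mat best_a;
  support_enumeration(G, H, gsq, best_f, &best_a);
  vec deltas = sqrt(clamp(best_f, 0.0, datum::inf));
  return Rcpp::List::create(Rcpp::Named("deltas") = deltas,
                            Rcpp::Named("weights") = best_a);
}

// Exhaustive search over candidate vertex subsets. `subsets` holds 1-based
// cluster indices, one candidate per column; `anchored` holds the 1-based
// indices always included. Returns the candidate minimizing the summed
// margins of all non-vertex centers (ties keep the first, i.e.
// lexicographically smallest, candidate).
// [[Rcpp::export]]
Rcpp::List cpp_vertex_search(const arma::mat& Gram,
                             const arma::umat& subsets,
                             const arma::uvec& anchored) {
  const uword C = Gram.n_rows;
  const uword L = anchored.n_elem;
  const uword n_cand = subsets.n_cols;
  const uword K = L + subsets.n_rows;
  const vec diagG = Gram.diag();

  double best_total = datum::inf;
  uvec best_idx;
  for (uword j = 0; j < n_cand; ++j) {
    uvec vidx(K);
    for (uword l = 0; l < L; ++l) vidx(l) = anchored(l) - 1;
    for (uword t = 0; t < K - L; ++t) vidx(L + t) = subsets(t, j) - 1;

    std::vector<uword> oth;
    std::vector<bool> isv(C, false);
    for (uword t = 0; t < K; ++t) isv[vidx(t)] = true;
    for (uword c = 0; c < C; ++c)
      if (!isv[c]) oth.push_back(c);
    double total = 0.0;
    if (!oth.empty()) {
      uvec others(oth);
      vec best_f;
      support_enumeration(Gram.submat(vidx, vidx), Gram.submat(vidx, others),
                          diagG.elem(others), best_f, nullptr);
      total = accu(sqrt(clamp(best_f, 0.0, datum::inf)));
    }
    if (total < best_total) {
      best_total = total;
      best_idx = vidx + 1;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("vertex_cluster_indices") = Rcpp::IntegerVector(
      best_idx.begin(), best_idx.end()),
    Rcpp::Named("total_margin") = best_total,
    Rcpp::Named("n_candidates_evaluated") = (double) n_cand);
}
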