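// Goldman-Yang style codon model machinery: rate matrix construction,
// transition probabilities via eigendecomposition of the symmetrized
// generator (time-reversible), pairwise likelihood, and Felsenstein
// pruning on trees with branch-class specific omega.
//
// Codon state space: 61 sense codons (universal code). The 61x61 integer
// "type" matrix is precomputed in R: 0 = not a single-nucleotide change,
// 1 = synonymous transversion, 2 = synonymous transition,
// 3 = nonsynonymous transversion, 4 = nonsynonymous transition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_Q(const arma::vec &pi, double kappa, double omega,
                         const arma::imat &type) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double m;
      switch (type(i, j)) {
      case 1: m = 1.0; break;
      case 2: m = kappa; break;
      case 3: m = omega; break;
      case 4: m = kappa * omega; break;
      default: m = 0.0;
      }
      double q = m * pi(j);
      Q(i, j) = q;
      rowsum += q;
    }
    Q(i, i) = -rowsum;
  }
  // scale so expected substitutions per codon per unit time = 1
  double z = 0.0;
  for (int i = 0; i < n; ++i) z -= pi(i) * Q(i, i);
  if (z > 0) Q /= z;
  return Q;
}

struct EigQ {
  arma::mat W;    // diag(1/sqrt(pi)) * V
  arma::mat Winv; // V' * diag(sqrt(pi))
  arma::vec lam;
};

static EigQ eig_gy(const arma::vec &pi, double kappa, double omega,
                   const arma::imat &type) {
  arma::mat Q = build_Q(pi, kappa, omega, type);
  arma::vec s = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= s;          // diag(s) * Q
  B.each_row() /= s.t();      // ... * diag(1/s)
  B = 0.5 * (B + B.t());      // enforce symmetry against roundoff
  EigQ e;
  arma::mat V;
  arma::eig_sym(e.lam, V, B);
  e.W = V;
  e.W.each_col() /= s;
  e.Winv = V.t();
  e.Winv.each_row() %= s.t();
  return e;
}

static arma::mat pmat_from_eig(const EigQ &e, double t) {
  arma::mat P = e.W * arma::diagmat(arma::exp(e.lam * t)) * e.Winv;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_codon_Q(const arma::vec &pi, double kappa, double omega,
                      const arma::imat &type) {
  return build_Q(pi, kappa, omega, type);
}

// [[Rcpp::export]]
arma::mat cpp_pmatrix(const arma::vec &pi, double kappa, double omega,
                      const arma::imat &type, double t) {
  EigQ e = eig_gy(pi, kappa, omega, type);
  return pmat_from_eig(e, t);
}

// Pairwise log-likelihood: sum_k w_k log(pi[i_k] P[i_k, j_k](t)).
// i, j are 0-based codon indices of the site patterns.
// [[Rcpp::export]]
double cpp_pair_loglik(const arma::vec &pi, double kappa, double omega,
                       double t, const arma::imat &type,
                       const arma::ivec &i, const arma::ivec &j,
                       const arma::vec &w) {
  EigQ e = eig_gy(pi, kappa, omega, type);
  arma::mat P = pmat_from_eig(e, t);
  double ll = 0.0;
  for (arma::uword k = 0; k < i.n_elem; ++k) {
    double f = pi(i(k)) * P(i(k), j(k));
    ll += w(k) * std::log(std::max(f, 1e-300));
  }
  return ll;
}

// Log-likelihood plus analytic gradient with respect to the branch
// lengths, via bidirectional (post-order + pre-order) pruning:
// df/dt_e = sum_x A_e[x] (Q_c P_e B_e)[x], with A_e the likelihood of the
// data "above" edge e and B_e the partial below it. No scaling is applied
// (trees here are small, so underflow is not a concern); the scaled
// log-likelihood entry point below remains the general-purpose one.
// [[Rcpp::export]]
List cpp_tree_loglik_grad(const arma::imat &edge, const arma::vec &el,
                          const arma::ivec &eclass, int ntip, int nnode,
                          double kappa, const arma::vec &omegas,
                          const arma::vec &pi, const arma::imat &type,
                          const arma::imat &tipstate, const arma::vec &w) {
  const int ns = pi.n_elem;
  const int npat = tipstate.n_cols;
  const int ntot = ntip + nnode;
  const int ne = edge.n_rows;

  std::vector<EigQ> eigs(omegas.n_elem);
  std::vector<arma::mat> Qs(omegas.n_elem);
  for (arma::uword c = 0; c < omegas.n_elem; ++c) {
    eigs[c] = eig_gy(pi, kappa, omegas(c), type);
    Qs[c] = build_Q(pi, kappa, omegas(c), type);
  }

  std::vector<arma::mat> P(ne), M(ne);     // per-edge transition, contribution
  std::vector<arma::mat> partial(ntot + 1);
  std::vector<bool> started(ntot + 1, false);
  int root = edge(ne - 1, 0);

  for (int e = 0; e < ne; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    P[e] = pmat_from_eig(eigs[eclass(e) - 1], el(e));
    arma::mat Me(ns, npat);
    if (ch <= ntip) {
      arma::vec rs = arma::sum(P[e], 1);
      for (int p = 0; p < npat; ++p) {
        int s = tipstate(ch - 1, p);
        if (s > 0) Me.col(p) = P[e].col(s - 1);
        else       Me.col(p) = rs;
      }
    } else {
      Me = P[e] * partial[ch];
    }
    M[e] = Me;
    if (!started[par]) { partial[par] = Me; started[par] = true; }
    else partial[par] %= Me;
  }

  arma::rowvec f(npat);
  for (int p = 0; p < npat; ++p)
    f(p) = std::max(arma::dot(pi, partial[root].col(p)), 1e-300);
  double ll = arma::dot(w, arma::log(f.t()));

  // pre-order "above" partials per node (likelihood of everything outside
  // the subtree, conditional on the state at the node's parent-facing side)
  std::vector<arma::mat> above(ntot + 1);
  above[root] = arma::repmat(pi, 1, npat);

  // children-of lists in edge order (edges are postorder, so traversing
  // them in reverse visits parents before children)
  arma::vec grad(ne, arma::fill::zeros);
  std::vector<std::vector<int>> childedges(ntot + 1);
  for (int e = 0; e < ne; ++e) childedges[edge(e, 0)].push_back(e);

  for (int e = ne - 1; e >= 0; --e) {
    int par = edge(e, 0), ch = edge(e, 1);
    // A_e = above[par] ∘ product of sibling contributions
    arma::mat A = above[par];
    for (int se : childedges[par])
      if (se != e) A %= M[se];
    // gradient: sum_pat w * A . (Q P B) / f
    const arma::mat &Qc = Qs[eclass(e) - 1];
    arma::mat QP = Qc * P[e];
    arma::mat QPB(ns, npat);
    if (ch <= ntip) {
      arma::vec rs = arma::sum(QP, 1);
      for (int p = 0; p < npat; ++p) {
        int s = tipstate(ch - 1, p);
        if (s > 0) QPB.col(p) = QP.col(s - 1);
        else       QPB.col(p) = rs;
      }
    } else {
      QPB = QP * partial[ch];
    }
    double g = 0.0;
    for (int p = 0; p < npat; ++p)
      g += w(p) * arma::dot(A.col(p), QPB.col(p)) / f(p);
    grad(e) = g;
    if (ch > ntip) above[ch] = P[e].t() * A;
  }

  return List::create(Named("logL") = ll, Named("grad_el") = grad);
}

// Felsenstein pruning log-likelihood on a rooted tree.
//
// edge: 2-column matrix of 1-based node ids (parent, child) in postorder
//       (every child edge appears before the edge leading to its parent);
//       tips are 1..ntip, root is ntip+1 (ape convention).
// el: branch lengths (substitutions/codon); eclass: 1-based omega class
//       per edge; omegas: one omega per class; tipstate: ntip x npat
//       matrix of 1-based codon states, 0 = missing/gap (sums over states).
// [[Rcpp::export]]
double cpp_tree_loglik(const arma::imat &edge, const arma::vec &el,
                       const arma::ivec &eclass, int ntip, int nnode,
                       double kappa, const arma::vec &omegas,
                       const arma::vec &pi, const arma::imat &type,
                       const arma::imat &tipstate, const arma::vec &w) {
  const int ns = pi.n_elem;
  const int npat = tipstate.n_cols;
  const int ntot = ntip + nnode;

  std::vector<EigQ> eigs(omegas.n_elem);
  for (arma::uword c = 0; c < omegas.n_elem; ++c)
    eigs[c] = eig_gy(pi, kappa, omegas(c), type);

  std::vector<arma::mat> partial(ntot + 1);
  std::vector<bool> started(ntot + 1, false);
  arma::vec logscale(npat, arma::fill::zeros);

  int root = edge(edge.n_rows - 1, 0);

  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    arma::mat P = pmat_from_eig(eigs[eclass(e) - 1], el(e));
    arma::mat M(ns, npat);
    if (ch <= ntip) {
      for (int p = 0; p < npat; ++p) {
        int s = tipstate(ch - 1, p);
        if (s > 0) M.col(p) = P.col(s - 1);
        else       M.col(p) = arma::sum(P, 1); // marginalize missing state
      }
    } else {
      // child partial is complete (postorder); rescale before use
      arma::mat &L = partial[ch];
      for (int p = 0; p < npat; ++p) {
        double mx = L.col(p).max();
        if (mx <= 0) mx = 1e-300;
        L.col(p) /= mx;
        logscale(p) += std::log(mx);
      }
      M = P * L;
      partial[ch].reset();
    }
    if (!started[par]) {
      partial[par] = M;
      started[par] = true;
    } else {
      partial[par] %= M;
    }
  }

  double ll = 0.0;
  const arma::mat &Lr = partial[root];
  for (int p = 0; p < npat; ++p) {
    double f = arma::dot(pi, Lr.col(p));
    ll += w(p) * (std::log(std::max(f, 1e-300)) + logscale(p));
  }
  return ll;
}
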