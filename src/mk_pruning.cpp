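#include <Rcpp.h>
using namespace Rcpp;

// Closed-form transition probabilities of the 2-state CTMC with gain rate
// q01 (0 -> 1) and loss rate q10 (1 -> 0) over time t.  P is row-major:
// P[0]=P00, P[1]=P01, P[2]=P10, P[3]=P11.
static inline void pmat2(double q01, double q10, double t, double *P) {
  double s = q01 + q10;
  if (s <= 0.0 || t <= 0.0) {
    P[0] = 1.0; P[1] = 0.0; P[2] = 0.0; P[3] = 1.0;
    return;
  }
  double e = std::exp(-s * t);
  P[0] = (q10 + q01 * e) / s;
  P[1] = (q01 - q01 * e) / s;
  P[2] = (q10 - q10 * e) / s;
  P[3] = (q01 + q10 * e) / s;
}

// [[Rcpp::export(name = ".mk_pmat_cpp")]]
NumericMatrix mk_pmat_cpp(double q01, double q10, double t) {
  double P[4];
  pmat2(q01, q10, t, P);
  NumericMatrix out(2, 2);
  out(0, 0) = P[0]; out(0, 1) = P[1];
  out(1, 0) = P[2]; out(1, 1) = P[3];
  return out;
}

// Felsenstein pruning log-likelihood.
// edge: 2-column integer matrix (parent, child), 1-based ape indexing,
//       rows in postorder (children before their parent's own edge).
// elen: branch length per edge row.
// tipL: ntip x 2 matrix of tip partial likelihoods (missing = (1,1)).
// rootp: length-2 root state prior.
// Per-node rescaling guards against underflow on large trees.
// [[Rcpp::export(name = ".mk_loglik_cpp")]]
double mk_loglik_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                     NumericMatrix tipL, double q01, double q10,
                     NumericVector rootp) {
  int nedge = edge.nrow();
  int nnode = ntip + nedge + 1;  // upper bound on node count (root included)
  std::vector<double> L0(nnode + 1, 1.0), L1(nnode + 1, 1.0);
  std::vector<bool> seen(nnode + 1, false);
  for (int i = 0; i < ntip; ++i) {
    L0[i + 1] = tipL(i, 0);
    L1[i + 1] = tipL(i, 1);
  }
  double logscale = 0.0;
  double P[4];
  int root = -1;
  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    pmat2(q01, q10, elen[e], P);
    double c0 = P[0] * L0[ch] + P[1] * L1[ch];
    double c1 = P[2] * L0[ch] + P[3] * L1[ch];
    if (!seen[par]) { L0[par] = 1.0; L1[par] = 1.0; seen[par] = true; }
    L0[par] *= c0;
    L1[par] *= c1;
    double m = std::max(L0[par], L1[par]);
    if (m > 0.0 && m < 1e-120) {
      L0[par] /= m; L1[par] /= m;
      logscale += std::log(m);
    }
    root = par;  // postorder: last edge's parent is the root
  }
  double lik = rootp[0] * L0[root] + rootp[1] * L1[root];
  if (lik <= 0.0) return R_NegInf;
  return std::log(lik) + logscale;
}

// Marginal ancestral-state reconstruction: P(state = 1) for every internal
// node, by combining downward (subtree) and upward (outside) partials.
// Returns a vector indexed by node number - ntip (1 = root under ape's
// convention root = ntip + 1).
// [[Rcpp::export(name = ".mk_marginal_cpp")]]
NumericVector mk_marginal_cpp(IntegerMatrix edge, NumericVector elen, int ntip,
                              NumericMatrix tipL, double q01, double q10,
                              NumericVector rootp) {
  int nedge = edge.nrow();
  int nnode = ntip + nedge + 1;
  std::vector<double> L0(nnode + 1, 1.0), L1(nnode + 1, 1.0);
  std::vector<bool> seen(nnode + 1, false);
  // Le[e][i]: likelihood of data below edge e's child given parent state i
  std::vector<double> Le0(nedge), Le1(nedge);
  for (int i = 0; i < ntip; ++i) {
    L0[i + 1] = tipL(i, 0);
    L1[i + 1] = tipL(i, 1);
  }
  double P[4];
  int root = -1;
  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    pmat2(q01, q10, elen[e], P);
    Le0[e] = P[0] * L0[ch] + P[1] * L1[ch];
    Le1[e] = P[2] * L0[ch] + P[3] * L1[ch];
    if (!seen[par]) { L0[par] = 1.0; L1[par] = 1.0; seen[par] = true; }
    L0[par] *= Le0[e];
    L1[par] *= Le1[e];
    // normalize to dodge underflow; marginals are scale-free per node
    double m = std::max(L0[par], L1[par]);
    if (m > 0.0) { L0[par] /= m; L1[par] /= m; }
    root = par;
  }
  // Upward pass in reverse postorder (parents before children).
  std::vector<double> U0(nnode + 1, 0.0), U1(nnode + 1, 0.0);
  U0[root] = rootp[0];
  U1[root] = rootp[1];
  // children edge list per parent, to form sibling products
  std::vector<std::vector<int>> kids(nnode + 1);
  for (int e = 0; e < nedge; ++e) kids[edge(e, 0)].push_back(e);
  for (int e = nedge - 1; e >= 0; --e) {
    int par = edge(e, 0), ch = edge(e, 1);
    if (ch <= ntip) continue;
    double a0 = U0[par], a1 = U1[par];
    for (size_t k = 0; k < kids[par].size(); ++k) {
      int se = kids[par][k];
      if (se == e) continue;
      a0 *= Le0[se];
      a1 *= Le1[se];
    }
    pmat2(q01, q10, elen[e], P);
    double u0 = a0 * P[0] + a1 * P[2];
    double u1 = a0 * P[1] + a1 * P[3];
    double m = std::max(u0, u1);
    if (m > 0.0) { u0 /= m; u1 /= m; }
    U0[ch] = u0;
    U1[ch] = u1;
  }
  int nint = nnode - ntip;
  NumericVector out(0);
  // count true internal nodes: those >= ntip+1 that appeared as parents
  int maxnode = root;
  for (int e = 0; e < nedge; ++e)
    if (edge(e, 0) > maxnode) maxnode = edge(e, 0);
  nint = maxnode - ntip;
  NumericVector p1(nint);
  for (int v = ntip + 1; v <= maxnode; ++v) {
    double w0 = U0[v] * L0[v];
    double w1 = U1[v] * L1[v];
    double tot = w0 + w1;
    p1[v - ntip - 1] = tot > 0.0 ? w1 / tot : NA_REAL;
  }
  return p1;
}
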