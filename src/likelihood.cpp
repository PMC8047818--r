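// Felsenstein pruning engine for 20-state amino-acid models with discrete
// gamma categories. Keeps a per-edge "message" cache (P_e %*% partial_child)
// so an MCMC proposal touching a few branches only recomputes the messages
// on the path from the changed edges to the root. Proposals are staged in a
// shadow buffer and swapped in on acceptance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const int NSTATE = 20;

struct PlkEngine {
  int ntip, nnode, S, K;
  // topology (0-based node ids; tips 0..ntip-1, root = ntip)
  std::vector<int> parent;                 // per node, -1 for root
  std::vector<std::vector<int>> children;  // per node
  std::vector<int> post_rank;              // node -> postorder position
  std::vector<int> post_nodes;             // non-root nodes in postorder
  int root;

  arma::imat tipstates;                    // ntip x S, -1 = gap/missing
  arma::mat V, Vinv;
  arma::vec lambda, pi;
  arma::vec crates_cur, crates_prop;
  bool model_dirty;

  std::vector<double> blen_cur, blen_prop; // per non-root node (child of edge)
  std::vector<arma::cube> msg_cur, msg_prop;     // 20 x S x K per non-root node
  std::vector<arma::vec> lfac_cur, lfac_prop;    // per internal node, length S
  double loglik_cur, loglik_prop;
  arma::vec sitell_cur, sitell_prop;

  std::vector<int> dirty;                  // non-root nodes with staged msgs
  std::vector<char> is_dirty;

  // preallocated scratch (single-threaded sampler)
  arma::mat Pbuf, Vscaled;
  arma::cube partbuf;

  void compute_P(double t, double rate, arma::mat &P) {
    arma::vec e = arma::exp(lambda * (t * rate));
    Vscaled = V;
    Vscaled.each_row() %= e.t();
    P = Vscaled * Vinv;
    P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  }

  // partial of an internal node = elementwise product of child messages,
  // reading staged buffers for dirty children
  void node_partial(int u, arma::cube &part) const {
    const std::vector<int> &kids = children[u];
    const arma::cube &m0 = is_dirty[kids[0]] ? msg_prop[kids[0]] : msg_cur[kids[0]];
    if (part.n_elem == 0) const_cast<arma::cube&>(part).set_size(NSTATE, S, K);
    if (kids.size() == 2) {
      const arma::cube &m1 = is_dirty[kids[1]] ? msg_prop[kids[1]] : msg_cur[kids[1]];
      part = m0 % m1;
    } else {
      part = m0;
      for (size_t i = 1; i < kids.size(); ++i) {
        int c = kids[i];
        part %= (is_dirty[c] ? msg_prop[c] : msg_cur[c]);
      }
    }
  }

  // recompute the staged message of non-root node u (and its local scale
  // factor if internal), using staged branch length
  void stage_msg(int u, const arma::vec &crates) {
    double t = blen_prop[u];
    arma::cube &M = msg_prop[u];
    if (M.n_elem == 0) M.set_size(NSTATE, S, K);
    if (u < ntip) {
      for (int k = 0; k < K; ++k) {
        compute_P(t, crates[k], Pbuf);
        arma::mat &slice = M.slice(k);
        for (int s = 0; s < S; ++s) {
          int st = tipstates(u, s);
          if (st < 0) slice.col(s).ones();
          else slice.col(s) = Pbuf.col(st);
        }
      }
    } else {
      node_partial(u, partbuf);
      rescale(u, partbuf);
      for (int k = 0; k < K; ++k) {
        compute_P(t, crates[k], Pbuf);
        M.slice(k) = Pbuf * partbuf.slice(k);
      }
    }
  }

  // per-site rescaling of an internal partial; log factors staged
  void rescale(int u, arma::cube &part) {
    arma::vec &lf = lfac_prop[u];
    if (lf.n_elem == 0) lf.set_size(S);
    for (int s = 0; s < S; ++s) {
      double m = 0.0;
      for (int k = 0; k < K; ++k) {
        double mk = part.slice(k).col(s).max();
        if (mk > m) m = mk;
      }
      if (m > 0.0 && m != 1.0) {
        for (int k = 0; k < K; ++k) part.slice(k).col(s) /= m;
        lf(s) = std::log(m);
      } else {
        lf(s) = 0.0;
      }
    }
  }

  double eval_root() {
    arma::cube &part = partbuf;
    node_partial(root, part);
    rescale(root, part);
    if (sitell_prop.n_elem == 0) sitell_prop.set_size(S);
    // accumulated scale factors: staged value for dirty internals, else cur
    arma::vec fac = lfac_prop[root];
    for (int u = ntip; u < nnode; ++u) {
      if (u == root) continue;
      const arma::vec &lf = is_dirty[u] ? lfac_prop[u] : lfac_cur[u];
      if (lf.n_elem) fac += lf;
    }
    double w = 1.0 / K;
    for (int s = 0; s < S; ++s) {
      double lik = 0.0;
      for (int k = 0; k < K; ++k)
        lik += w * arma::dot(pi, part.slice(k).col(s));
      sitell_prop(s) = (lik > 0 ? std::log(lik) : -1e300) + fac(s);
    }
    loglik_prop = arma::accu(sitell_prop);
    return loglik_prop;
  }

  void mark_dirty(int u) {
    while (u >= 0 && u != root) {
      if (!is_dirty[u]) { is_dirty[u] = 1; dirty.push_back(u); }
      u = parent[u];
    }
  }

  double propose_impl() {
    const arma::vec &crates = model_dirty ? crates_prop : crates_cur;
    std::sort(dirty.begin(), dirty.end(),
              [this](int a, int b) { return post_rank[a] < post_rank[b]; });
    for (int u : dirty) stage_msg(u, crates);
    return eval_root();
  }

  void accept() {
    for (int u : dirty) {
      std::swap(msg_cur[u], msg_prop[u]);
      blen_cur[u] = blen_prop[u];
      if (u >= ntip) std::swap(lfac_cur[u], lfac_prop[u]);
      is_dirty[u] = 0;
    }
    dirty.clear();
    std::swap(lfac_cur[root], lfac_prop[root]);
    if (model_dirty) { crates_cur = crates_prop; model_dirty = false; }
    loglik_cur = loglik_prop;
    std::swap(sitell_cur, sitell_prop);
  }

  void reject() {
    for (int u : dirty) { is_dirty[u] = 0; blen_prop[u] = blen_cur[u]; }
    dirty.clear();
    model_dirty = false;
  }
};

// [[Rcpp::export]]
SEXP plk_engine_new(IntegerMatrix edge_postorder, int ntip,
                    IntegerMatrix tipstates, List model) {
  PlkEngine *e = new PlkEngine();
  e->ntip = ntip;
  e->S = tipstates.ncol();
  e->nnode = ntip + 0;
  int maxnode = 0;
  for (int i = 0; i < edge_postorder.nrow(); ++i) {
    maxnode = std::max(maxnode, edge_postorder(i, 0));
    maxnode = std::max(maxnode, edge_postorder(i, 1));
  }
  e->nnode = maxnode;                       // 1-based count
  e->root = ntip;                           // ape convention: root = ntip+1
  e->parent.assign(e->nnode, -1);
  e->children.assign(e->nnode, {});
  e->post_rank.assign(e->nnode, -1);
  for (int i = 0; i < edge_postorder.nrow(); ++i) {
    int p = edge_postorder(i, 0) - 1, c = edge_postorder(i, 1) - 1;
    e->parent[c] = p;
    e->children[p].push_back(c);
    e->post_rank[c] = i;
    e->post_nodes.push_back(c);
  }
  e->tipstates.set_size(ntip, e->S);
  for (int i = 0; i < ntip; ++i)
    for (int s = 0; s < e->S; ++s) {
      int v = tipstates(i, s);
      e->tipstates(i, s) = (v == NA_INTEGER || v < 1) ? -1 : v - 1;
    }
  e->V = as<arma::mat>(model["V"]);
  e->Vinv = as<arma::mat>(model["Vinv"]);
  e->lambda = as<arma::vec>(model["lambda"]);
  e->pi = as<arma::vec>(model["pi"]);
  e->crates_cur = as<arma::vec>(model["rates"]);
  e->K = e->crates_cur.n_elem;
  e->model_dirty = false;
  e->blen_cur.assign(e->nnode, 0.0);
  e->blen_prop.assign(e->nnode, 0.0);
  e->msg_cur.resize(e->nnode);
  e->msg_prop.resize(e->nnode);
  e->lfac_cur.resize(e->nnode);
  e->lfac_prop.resize(e->nnode);
  e->is_dirty.assign(e->nnode, 0);
  e->loglik_cur = NA_REAL;
  XPtr<PlkEngine> ptr(e, true);
  return ptr;
}

// Full (re)computation from a complete branch-length vector indexed by
// child node (1-based; the root entry is ignored). Accepts immediately.
// [[Rcpp::export]]
double plk_set_blens(SEXP xp, NumericVector blens) {
  XPtr<PlkEngine> e(xp);
  for (int u : e->post_nodes) { e->blen_prop[u] = blens[u]; e->mark_dirty(u); }
  double ll = e->propose_impl();
  e->accept();
  return ll;
}

// [[Rcpp::export]]
double plk_propose(SEXP xp, IntegerVector child_nodes, NumericVector new_blens) {
  XPtr<PlkEngine> e(xp);
  for (int i = 0; i < child_nodes.size(); ++i) {
    int u = child_nodes[i] - 1;
    e->blen_prop[u] = new_blens[i];
    e->mark_dirty(u);
  }
  return e->propose_impl();
}

// Stage new category rates (gamma-shape move); every message is rebuilt.
// [[Rcpp::export]]
double plk_propose_rates(SEXP xp, NumericVector crates) {
  XPtr<PlkEngine> e(xp);
  e->crates_prop = as<arma::vec>(crates);
  e->model_dirty = true;
  for (int u : e->post_nodes) { e->blen_prop[u] = e->blen_cur[u]; e->mark_dirty(u); }
  return e->propose_impl();
}

// [[Rcpp::export]]
void plk_accept(SEXP xp) { XPtr<PlkEngine> e(xp); e->accept(); }

// [[Rcpp::export]]
void plk_reject(SEXP xp) { XPtr<PlkEngine> e(xp); e->reject(); }

// [[Rcpp::export]]
double plk_loglik(SEXP xp) { XPtr<PlkEngine> e(xp); return e->loglik_cur; }

// [[Rcpp::export]]
NumericVector plk_site_loglik(SEXP xp) {
  XPtr<PlkEngine> e(xp);
  return NumericVector(e->sitell_cur.begin(), e->sitell_cur.end());
}
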