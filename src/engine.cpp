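// Internal maximum-likelihood engine: Felsenstein pruning over compressed
// site patterns with a discrete-gamma rate mixture, plus per-branch
// optimization (safeguarded Newton-Raphson on the analytic derivatives,
// Brent fallback).  Trees arrive as ape-style edge matrices (1-based;
// column 1 internal node, column 2 child).  The tree is treated as
// unrooted: every quantity combines two directed subtree partials across
// one edge, which for a reversible, mean-rate-normalized Q is invariant to
// where the computation is rooted.
//
// Branch-length sweeps keep the directed partials exact while they walk
// the tree: a postorder pass caches the tipward partial D[v] of every
// node, then a preorder pass maintains the rootward partial of each edge,
// recomputing sibling contributions with the current (already updated)
// branch lengths, so each one-dimensional optimization sees the exact
// conditional likelihood of its branch.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double SCALE_THRESH = 1e-120;
static const double LOG_ZERO = -1e308;

class Engine {
public:
  int ntip, npat, ncat, nedge, nnode;
  std::vector<int> epar, echild;
  std::vector<double> el;
  std::vector<std::vector<std::pair<int, int> > > children; // node -> (child, edge)
  std::vector<int> parent_edge;                             // node -> edge id or -1
  std::vector<int> postorder;                               // edge ids, children first
  int root;
  std::vector<int> st;
  std::vector<double> w;
  double pi[4], U[16], Ui[16], eva[4];
  std::vector<double> rates;

  size_t blk, sblk; // sizes of a partial block / scale block
  std::vector<std::vector<double> > D, Dsc;  // tipward partials per node
  std::vector<double> Abuf, Asc;             // rootward partial of current edge
  std::vector<double> tmp, tmpsc, tmp2, tmp2sc;
  std::vector<double> ls;
  double last_ll;

  Engine(const IntegerMatrix& edge, const NumericVector& elen, int ntip_,
         const IntegerMatrix& states, const NumericVector& weights,
         const NumericVector& pi_, const NumericMatrix& U_,
         const NumericMatrix& Ui_, const NumericVector& eva_,
         const NumericVector& rates_) {
    ntip = ntip_;
    nedge = edge.nrow();
    npat = states.ncol();
    ncat = rates_.size();
    nnode = 0;
    epar.resize(nedge);
    echild.resize(nedge);
    el.resize(nedge);
    for (int e = 0; e < nedge; e++) {
      epar[e] = edge(e, 0) - 1;
      echild[e] = edge(e, 1) - 1;
      el[e] = elen[e];
      nnode = std::max(nnode, std::max(epar[e], echild[e]) + 1);
    }
    children.assign(nnode, std::vector<std::pair<int, int> >());
    parent_edge.assign(nnode, -1);
    for (int e = 0; e < nedge; e++) {
      children[epar[e]].push_back(std::make_pair(echild[e], e));
      parent_edge[echild[e]] = e;
    }
    root = -1;
    for (int v = 0; v < nnode; v++)
      if (parent_edge[v] < 0 && !children[v].empty()) root = v;
    if (root < 0) stop("tree has no root node");
    // postorder over edges via iterative DFS
    postorder.reserve(nedge);
    std::vector<std::pair<int, int> > stack; // (node, child slot)
    stack.push_back(std::make_pair(root, 0));
    while (!stack.empty()) {
      int v = stack.back().first;
      int& slot = stack.back().second;
      if (slot < (int)children[v].size()) {
        int e = children[v][slot].second;
        int ch = children[v][slot].first;
        slot++;
        stack.push_back(std::make_pair(ch, 0));
        (void)e;
      } else {
        stack.pop_back();
        if (!stack.empty()) {
          int u = stack.back().first;
          int done = stack.back().second - 1;
          postorder.push_back(children[u][done].second);
        }
      }
    }
    if ((int)postorder.size() != nedge) stop("malformed edge matrix");

    st.resize((size_t)ntip * npat);
    for (int t = 0; t < ntip; t++)
      for (int p = 0; p < npat; p++) st[t + (size_t)ntip * p] = states(t, p);
    w.assign(weights.begin(), weights.end());
    for (int i = 0; i < 4; i++) pi[i] = pi_[i];
    for (int i = 0; i < 4; i++)
      for (int j = 0; j < 4; j++) {
        U[i * 4 + j] = U_(i, j);
        Ui[i * 4 + j] = Ui_(i, j);
      }
    for (int i = 0; i < 4; i++) eva[i] = eva_[i];
    rates.assign(rates_.begin(), rates_.end());

    blk = (size_t)ncat * npat * 4;
    sblk = (size_t)ncat * npat;
    D.assign(nnode, std::vector<double>());
    Dsc.assign(nnode, std::vector<double>());
    Abuf.assign(blk, 0.0);
    Asc.assign(sblk, 0.0);
    tmp.assign(blk, 0.0);
    tmpsc.assign(sblk, 0.0);
    tmp2.assign(blk, 0.0);
    tmp2sc.assign(sblk, 0.0);
    ls.resize(ncat);
    last_ll = LOG_ZERO;
  }

  void pmat(double t, double r, double* P) const {
    double ex[4];
    double tt = t * r;
    if (tt < 0.0) tt = 0.0;
    for (int k = 0; k < 4; k++) ex[k] = std::exp(eva[k] * tt);
    for (int i = 0; i < 4; i++)
      for (int j = 0; j < 4; j++) {
        double s = 0.0;
        for (int k = 0; k < 4; k++) s += U[i * 4 + k] * ex[k] * Ui[k * 4 + j];
        P[i * 4 + j] = s < 0.0 ? 0.0 : s;
      }
  }

  // d^m/dt^m exp(Q t r) = U (r Lambda)^m exp(Lambda t r) U^{-1}
  void pmat_deriv(double t, double r, double* P, double* P1,
                  double* P2) const {
    double ex[4], ex1[4], ex2[4];
    double tt = t * r;
    if (tt < 0.0) tt = 0.0;
    for (int k = 0; k < 4; k++) {
      ex[k] = std::exp(eva[k] * tt);
      ex1[k] = ex[k] * eva[k] * r;
      ex2[k] = ex1[k] * eva[k] * r;
    }
    for (int i = 0; i < 4; i++)
      for (int j = 0; j < 4; j++) {
        double s = 0.0, s1 = 0.0, s2 = 0.0;
        for (int k = 0; k < 4; k++) {
          double uk = U[i * 4 + k] * Ui[k * 4 + j];
          s += uk * ex[k];
          s1 += uk * ex1[k];
          s2 += uk * ex2[k];
        }
        P[i * 4 + j] = s < 0.0 ? 0.0 : s;
        P1[i * 4 + j] = s1;
        P2[i * 4 + j] = s2;
      }
  }

  void tip_partial(int v, std::vector<double>& out,
                   std::vector<double>& sc) {
    out.assign(blk, 0.0);
    sc.assign(sblk, 0.0);
    for (int c = 0; c < ncat; c++)
      for (int p = 0; p < npat; p++) {
        double* o = out.data() + ((size_t)c * npat + p) * 4;
        int s = st[v + (size_t)ntip * p];
        if (s >= 0 && s < 4) o[s] = 1.0;
        else o[0] = o[1] = o[2] = o[3] = 1.0;
      }
  }

  // out *= P(el[e]) * D[child of e]; scales accumulate
  void fold_edge(int e, double* out, double* sc) {
    int v = echild[e];
    const double* B = D[v].data();
    const double* Bsc = Dsc[v].data();
    double P[16];
    for (int c = 0; c < ncat; c++) {
      pmat(el[e], rates[c], P);
      for (int p = 0; p < npat; p++) {
        double* o = out + ((size_t)c * npat + p) * 4;
        const double* b = B + ((size_t)c * npat + p) * 4;
        for (int x = 0; x < 4; x++)
          o[x] *= P[x * 4] * b[0] + P[x * 4 + 1] * b[1] +
                  P[x * 4 + 2] * b[2] + P[x * 4 + 3] * b[3];
        sc[(size_t)c * npat + p] += Bsc[(size_t)c * npat + p];
      }
    }
  }

  void rescale(double* out, double* sc) {
    for (int c = 0; c < ncat; c++)
      for (int p = 0; p < npat; p++) {
        double* o = out + ((size_t)c * npat + p) * 4;
        double mx = std::max(std::max(o[0], o[1]), std::max(o[2], o[3]));
        if (mx > 0.0 && mx < SCALE_THRESH) {
          double inv = 1.0 / mx;
          o[0] *= inv; o[1] *= inv; o[2] *= inv; o[3] *= inv;
          sc[(size_t)c * npat + p] += std::log(mx);
        }
      }
  }

  // tipward partials of every node, for the current branch lengths
  void post_D() {
    for (int v = 0; v < ntip; v++)
      if (D[v].empty()) tip_partial(v, D[v], Dsc[v]);
    for (int v = ntip; v < nnode; v++) {
      D[v].assign(blk, 1.0);
      Dsc[v].assign(sblk, 0.0);
    }
    for (size_t k = 0; k < postorder.size(); k++) {
      int e = postorder[k];
      int u = epar[e];
      fold_edge(e, D[u].data(), Dsc[u].data());
      if (children[u].back().second == e)
        rescale(D[u].data(), Dsc[u].data());
    }
  }

  // log-likelihood at the root from cached D (call after post_D)
  double root_ll() {
    double total = 0.0;
    double lognc = std::log((double)ncat);
    const double* R = D[root].data();
    const double* Rsc = Dsc[root].data();
    for (int p = 0; p < npat; p++) {
      double lmax = LOG_ZERO;
      for (int c = 0; c < ncat; c++) {
        const double* r = R + ((size_t)c * npat + p) * 4;
        double s = pi[0] * r[0] + pi[1] * r[1] + pi[2] * r[2] +
                   pi[3] * r[3];
        double l = (s > 0.0 ? std::log(s) : LOG_ZERO) +
                   Rsc[(size_t)c * npat + p];
        ls[c] = l;
        if (l > lmax) lmax = l;
      }
      double acc = 0.0;
      for (int c = 0; c < ncat; c++) acc += std::exp(ls[c] - lmax);
      total += w[p] * (lmax + std::log(acc) - lognc);
    }
    return total;
  }

  double loglik(std::vector<double>* site_out) {
    post_D();
    if (!site_out) return root_ll();
    double total = 0.0;
    double lognc = std::log((double)ncat);
    const double* R = D[root].data();
    const double* Rsc = Dsc[root].data();
    for (int p = 0; p < npat; p++) {
      double lmax = LOG_ZERO;
      for (int c = 0; c < ncat; c++) {
        const double* r = R + ((size_t)c * npat + p) * 4;
        double s = pi[0] * r[0] + pi[1] * r[1] + pi[2] * r[2] +
                   pi[3] * r[3];
        double l = (s > 0.0 ? std::log(s) : LOG_ZERO) +
                   Rsc[(size_t)c * npat + p];
        ls[c] = l;
        if (l > lmax) lmax = l;
      }
      double acc = 0.0;
      for (int c = 0; c < ncat; c++) acc += std::exp(ls[c] - lmax);
      double sl = lmax + std::log(acc) - lognc;
      (*site_out)[p] = sl;
      total += w[p] * sl;
    }
    return total;
  }

  // f(t): LL of the tree when edge e has length t, A = rootward partial at
  // epar[e] (in Abuf/Asc), B = D[echild[e]]
  double edge_ll(int e, double t) {
    const double* B = D[echild[e]].data();
    const double* Bsc = Dsc[echild[e]].data();
    std::vector<double> Ps((size_t)16 * ncat);
    for (int c = 0; c < ncat; c++) pmat(t, rates[c], &Ps[16 * (size_t)c]);
    double total = 0.0;
    double lognc = std::log((double)ncat);
    for (int p = 0; p < npat; p++) {
      double lmax = LOG_ZERO;
      for (int c = 0; c < ncat; c++) {
        const double* Pc = &Ps[16 * (size_t)c];
        const double* a = Abuf.data() + ((size_t)c * npat + p) * 4;
        const double* b = B + ((size_t)c * npat + p) * 4;
        double s = 0.0;
        for (int x = 0; x < 4; x++) {
          double pb = Pc[x * 4] * b[0] + Pc[x * 4 + 1] * b[1] +
                      Pc[x * 4 + 2] * b[2] + Pc[x * 4 + 3] * b[3];
          s += pi[x] * a[x] * pb;
        }
        double l = (s > 0.0 ? std::log(s) : LOG_ZERO) +
                   Asc[(size_t)c * npat + p] + Bsc[(size_t)c * npat + p];
        ls[c] = l;
        if (l > lmax) lmax = l;
      }
      double acc = 0.0;
      for (int c = 0; c < ncat; c++) acc += std::exp(ls[c] - lmax);
      total += w[p] * (lmax + std::log(acc) - lognc);
    }
    return total;
  }

  // f, f', f'' at t for edge e (same caches as edge_ll)
  void edge_ll_deriv(int e, double t, double& f, double& g, double& h) {
    const double* B = D[echild[e]].data();
    const double* Bsc = Dsc[echild[e]].data();
    std::vector<double> Ps(16 * (size_t)ncat), P1s(16 * (size_t)ncat),
        P2s(16 * (size_t)ncat);
    for (int c = 0; c < ncat; c++)
      pmat_deriv(t, rates[c], &Ps[16 * (size_t)c], &P1s[16 * (size_t)c],
                 &P2s[16 * (size_t)c]);
    f = 0.0; g = 0.0; h = 0.0;
    double lognc = std::log((double)ncat);
    std::vector<double> s0(ncat), s1(ncat), s2(ncat), sig(ncat);
    for (int p = 0; p < npat; p++) {
      double smax = LOG_ZERO;
      for (int c = 0; c < ncat; c++) {
        const double* Pc = &Ps[16 * (size_t)c];
        const double* P1c = &P1s[16 * (size_t)c];
        const double* P2c = &P2s[16 * (size_t)c];
        const double* a = Abuf.data() + ((size_t)c * npat + p) * 4;
        const double* b = B + ((size_t)c * npat + p) * 4;
        double v0 = 0.0, v1 = 0.0, v2 = 0.0;
        for (int x = 0; x < 4; x++) {
          double pb = Pc[x * 4] * b[0] + Pc[x * 4 + 1] * b[1] +
                      Pc[x * 4 + 2] * b[2] + Pc[x * 4 + 3] * b[3];
          double pb1 = P1c[x * 4] * b[0] + P1c[x * 4 + 1] * b[1] +
                       P1c[x * 4 + 2] * b[2] + P1c[x * 4 + 3] * b[3];
          double pb2 = P2c[x * 4] * b[0] + P2c[x * 4 + 1] * b[1] +
                       P2c[x * 4 + 2] * b[2] + P2c[x * 4 + 3] * b[3];
          double ax = pi[x] * a[x];
          v0 += ax * pb;
          v1 += ax * pb1;
          v2 += ax * pb2;
        }
        s0[c] = v0; s1[c] = v1; s2[c] = v2;
        sig[c] = Asc[(size_t)c * npat + p] + Bsc[(size_t)c * npat + p];
        if (sig[c] > smax) smax = sig[c];
      }
      double L = 0.0, L1 = 0.0, L2 = 0.0;
      for (int c = 0; c < ncat; c++) {
        double ec = std::exp(sig[c] - smax);
        L += ec * s0[c];
        L1 += ec * s1[c];
        L2 += ec * s2[c];
      }
      if (L <= 0.0) { f += w[p] * LOG_ZERO; continue; }
      double r1 = L1 / L, r2 = L2 / L;
      f += w[p] * (smax + std::log(L) - lognc);
      g += w[p] * r1;
      h += w[p] * (r2 - r1 * r1);
    }
  }

  // Brent's localmin on [a,b], maximizing edge_ll(e, .); never returns a
  // point worse than the incumbent t0.
  void brent_edge(int e, double a, double b, double t0, double tol,
                  double& tbest, double& fbest) {
    const double gold = 0.3819660112501051;
    double x, wx, v, fx, fw, fv, d = 0.0, ee = 0.0;
    x = wx = v = std::min(std::max(t0, a), b);
    fx = fw = fv = -edge_ll(e, x);
    double f0 = -fx, x0 = x;
    for (int iter = 0; iter < 100; iter++) {
      double m = 0.5 * (a + b);
      double tol1 = tol * std::fabs(x) + 1e-10;
      double tol2 = 2.0 * tol1;
      if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
      double p = 0.0, q = 0.0, r = 0.0;
      bool golden = true;
      if (std::fabs(ee) > tol1) {
        r = (x - wx) * (fx - fv);
        q = (x - v) * (fx - fw);
        p = (x - v) * q - (x - wx) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) p = -p;
        q = std::fabs(q);
        double etmp = ee;
        ee = d;
        if (!(std::fabs(p) >= std::fabs(0.5 * q * etmp) || p <= q * (a - x) ||
              p >= q * (b - x))) {
          golden = false;
          d = p / q;
          double u2 = x + d;
          if (u2 - a < tol2 || b - u2 < tol2) d = (m > x) ? tol1 : -tol1;
        }
      }
      if (golden) {
        ee = (x >= m) ? a - x : b - x;
        d = gold * ee;
      }
      double u2 = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0) ? tol1 : -tol1);
      double fu = -edge_ll(e, u2);
      if (fu <= fx) {
        if (u2 >= x) a = x; else b = x;
        v = wx; fv = fw; wx = x; fw = fx; x = u2; fx = fu;
      } else {
        if (u2 < x) a = u2; else b = u2;
        if (fu <= fw || wx == x) {
          v = wx; fv = fw; wx = u2; fw = fu;
        } else if (fu <= fv || v == x || v == wx) {
          v = u2; fv = fu;
        }
      }
    }
    if (-fx > f0) { tbest = x; fbest = -fx; }
    else { tbest = x0; fbest = f0; }
  }

  // Safeguarded Newton on the branch length of edge e; falls back to Brent
  // when curvature is unusable.  Never worse than the incumbent.
  void optimize_edge(int e, double min_bl, double max_bl, double tol) {
    double t = std::min(std::max(el[e], min_bl), max_bl);
    double f, g, h;
    edge_ll_deriv(e, t, f, g, h);
    double t0 = t, f0 = f;
    bool ok = false;
    for (int iter = 0; iter < 12; iter++) {
      double step;
      if (h < -1e-12) step = -g / h;
      else step = (g > 0 ? 1.0 : -1.0) * std::max(0.1 * t, 1e-4);
      if (step > 1.0) step = 1.0;
      if (step < -1.0) step = -1.0;
      double tn = std::min(std::max(t + step, min_bl), max_bl);
      if (std::fabs(tn - t) < tol * std::fabs(t) + 1e-10) { ok = true; break; }
      double fn, gn, hn;
      edge_ll_deriv(e, tn, fn, gn, hn);
      int back = 0;
      while (fn < f - 1e-12 && back < 6) {
        tn = 0.5 * (t + tn);
        edge_ll_deriv(e, tn, fn, gn, hn);
        back++;
      }
      if (fn < f - 1e-12) { ok = false; break; }
      t = tn; f = fn; g = gn; h = hn;
      if (std::fabs(g) < 1e-10) { ok = true; break; }
    }
    if (!ok && !(f > f0)) {
      brent_edge(e, min_bl, max_bl, t0, tol, t, f);
    }
    if (f >= f0) { el[e] = t; last_ll = f; }
    else { el[e] = t0; last_ll = f0; }
  }

  // One exact sweep: optimize every edge in opt_mask while keeping all
  // directed partials current.  Returns the exact tree LL afterwards.
  double sweep(const std::vector<char>& opt_mask, const std::vector<char>& need,
               double min_bl, double max_bl, double tol) {
    post_D();
    // preorder walk maintaining the rootward partial of each visited edge
    struct Frame { int node; int slot; std::vector<double> up, upsc; };
    std::vector<Frame> stack;
    stack.push_back(Frame());
    stack.back().node = root;
    stack.back().slot = 0;
    stack.back().up.assign(blk, 1.0);
    stack.back().upsc.assign(sblk, 0.0);
    while (!stack.empty()) {
      Frame& fr = stack.back();
      int u = fr.node;
      if (fr.slot >= (int)children[u].size()) { stack.pop_back(); continue; }
      int e = children[u][fr.slot].second;
      int v = children[u][fr.slot].first;
      fr.slot++;
      if (!need[v] && !opt_mask[e]) continue;
      // A_e = up[u] * prod over siblings of v of P(t_c) D[c]
      Abuf = fr.up;
      Asc = fr.upsc;
      for (size_t k = 0; k < children[u].size(); k++) {
        int e2 = children[u][k].second;
        if (e2 == e) continue;
        fold_edge(e2, Abuf.data(), Asc.data());
      }
      rescale(Abuf.data(), Asc.data());
      if (opt_mask[e]) optimize_edge(e, min_bl, max_bl, tol);
      if (v >= ntip) {
        bool descend = false;
        for (size_t k = 0; k < children[v].size(); k++)
          if (need[children[v][k].first] ||
              opt_mask[children[v][k].second]) descend = true;
        if (descend) {
          // push child frame with up[v](x) = sum_y P(t_e)_{x,y} A_e(y)
          Frame nf;
          nf.node = v;
          nf.slot = 0;
          nf.up.assign(blk, 0.0);
          nf.upsc = Asc;
          double P[16];
          for (int c = 0; c < ncat; c++) {
            pmat(el[e], rates[c], P);
            for (int p = 0; p < npat; p++) {
              double* o = nf.up.data() + ((size_t)c * npat + p) * 4;
              const double* a = Abuf.data() + ((size_t)c * npat + p) * 4;
              for (int x = 0; x < 4; x++)
                o[x] = P[x * 4] * a[0] + P[x * 4 + 1] * a[1] +
                       P[x * 4 + 2] * a[2] + P[x * 4 + 3] * a[3];
            }
          }
          rescale(nf.up.data(), nf.upsc.data());
          stack.push_back(nf);
        }
      }
    }
    post_D();
    return root_ll();
  }
};

static void check_inputs(const IntegerMatrix& edge, const NumericVector& el,
                         const IntegerMatrix& states,
                         const NumericVector& weights) {
  if (edge.nrow() != el.size()) stop("edge/length size mismatch");
  if (states.ncol() != weights.size()) stop("pattern/weight size mismatch");
}

// [[Rcpp::export]]
double eng_loglik(IntegerMatrix edge, NumericVector el, int ntip,
                  IntegerMatrix states, NumericVector weights,
                  NumericVector pi, NumericMatrix U, NumericMatrix Uinv,
                  NumericVector eva, NumericVector rates) {
  check_inputs(edge, el, states, weights);
  Engine eng(edge, el, ntip, states, weights, pi, U, Uinv, eva, rates);
  return eng.loglik(0);
}

// [[Rcpp::export]]
NumericVector eng_site_loglik(IntegerMatrix edge, NumericVector el, int ntip,
                              IntegerMatrix states, NumericVector weights,
                              NumericVector pi, NumericMatrix U,
                              NumericMatrix Uinv, NumericVector eva,
                              NumericVector rates) {
  check_inputs(edge, el, states, weights);
  Engine eng(edge, el, ntip, states, weights, pi, U, Uinv, eva, rates);
  std::vector<double> site(states.ncol());
  eng.loglik(&site);
  return wrap(site);
}

// Round-robin optimization of the listed edges (1-based indices into the
// edge matrix).  Stops when the log-likelihood gain of a full sweep drops
// below `epsilon` or after `max_sweeps` sweeps.
// [[Rcpp::export]]
List eng_optimize(IntegerMatrix edge, NumericVector el, int ntip,
                  IntegerMatrix states, NumericVector weights,
                  NumericVector pi, NumericMatrix U, NumericMatrix Uinv,
                  NumericVector eva, NumericVector rates,
                  IntegerVector opt_edges, double epsilon, int max_sweeps,
                  double min_bl, double max_bl, double brent_tol) {
  check_inputs(edge, el, states, weights);
  Engine eng(edge, el, ntip, states, weights, pi, U, Uinv, eva, rates);
  std::vector<char> opt_mask(eng.nedge, 0);
  for (int k = 0; k < opt_edges.size(); k++) {
    int e = opt_edges[k] - 1;
    if (e < 0 || e >= eng.nedge) stop("edge index out of range");
    opt_mask[e] = 1;
  }
  // need[v]: does the subtree below v contain an edge to optimize?
  std::vector<char> need(eng.nnode, 0);
  for (size_t k = 0; k < eng.postorder.size(); k++) {
    int e = eng.postorder[k];
    int v = eng.echild[e], u = eng.epar[e];
    if (opt_mask[e] || need[v]) need[u] = 1;
  }
  std::vector<double> sweep_ll;
  double prev = LOG_ZERO, cur = LOG_ZERO;
  bool converged = false;
  for (int sw = 0; sw < max_sweeps; sw++) {
    cur = eng.sweep(opt_mask, need, min_bl, max_bl, brent_tol);
    sweep_ll.push_back(cur);
    if (sw > 0 && cur - prev < epsilon) {
      converged = true;
      break;
    }
    prev = cur;
  }
  return List::create(_["edge_length"] = wrap(eng.el), _["loglik"] = cur,
                      _["sweep_ll"] = wrap(sweep_ll),
                      _["converged"] = converged);
}
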