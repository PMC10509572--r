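// Single-population coalescent MCMC for Y-STR data.
//
// State: a rooted binary genealogy over n haplotypes (node times in
// generations), effective size N and scaled growth g = N*r. The STR
// likelihood is a symmetric single-step (SMM) CTMC on a bounded integer
// allele lattice, evaluated by Felsenstein pruning; the lattice generator
// is eigendecomposed once per locus in R, so a branch message costs two
// K x K products in the eigenbasis. Node-local moves only dirty the path
// to the root, which keeps per-iteration cost near O(depth * K^2 * L).
// All scratch is preallocated: the proposal loop performs no heap
// allocation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Locus {
  int K;
  std::vector<double> V;    // K*K eigenvectors, column-major
  std::vector<double> lam;  // eigenvalues of the unit-rate generator
  double mu;
  std::vector<int> tip;     // lattice state per tip
};

struct Sampler {
  // tree
  int n, nNode, root;
  std::vector<int> parent, child1, child2;
  std::vector<double> time;

  std::vector<Locus> loci;

  // partials: per locus, nNode*K doubles (tips unused); per-node scalelogs
  std::vector<std::vector<double> > part;
  std::vector<std::vector<double> > scale;
  std::vector<double> sumScale, loglik;

  // scratch (sized to max K)
  std::vector<double> w, m1, m2;
  std::vector<int> dirty, path;

  // backup for rollback
  std::vector<int> bkNodes;
  std::vector<std::vector<double> > bkPart, bkScale;
  std::vector<double> bkSumScale, bkLoglik;

  void init() {
    int maxK = 1;
    part.resize(loci.size());
    scale.resize(loci.size());
    bkPart.resize(loci.size());
    bkScale.resize(loci.size());
    sumScale.assign(loci.size(), 0.0);
    loglik.assign(loci.size(), 0.0);
    for (size_t l = 0; l < loci.size(); ++l) {
      part[l].assign((size_t)nNode * loci[l].K, 0.0);
      scale[l].assign(nNode, 0.0);
      bkPart[l].assign((size_t)nNode * loci[l].K, 0.0);
      bkScale[l].assign(nNode, 0.0);
      if (loci[l].K > maxK) maxK = loci[l].K;
    }
    w.resize(maxK); m1.resize(maxK); m2.resize(maxK);
    dirty.reserve(nNode); path.reserve(nNode);
    bkNodes.reserve(nNode);
    bkSumScale.assign(loci.size(), 0.0);
    bkLoglik.assign(loci.size(), 0.0);
  }

  void branchMessage(const Locus &lc, int c, double t, double *out) {
    const int K = lc.K;
    if (c < n) {
      const int s = lc.tip[c];
      for (int j = 0; j < K; ++j)
        w[j] = lc.V[s + (size_t)K * j] * std::exp(lc.mu * t * lc.lam[j]);
    } else {
      const double *p = &part[&lc - &loci[0]][(size_t)c * K];
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        const double *col = &lc.V[(size_t)K * j];
        for (int i = 0; i < K; ++i) acc += col[i] * p[i];
        w[j] = acc * std::exp(lc.mu * t * lc.lam[j]);
      }
    }
    for (int i = 0; i < K; ++i) {
      double acc = 0.0;
      for (int j = 0; j < K; ++j) acc += lc.V[i + (size_t)K * j] * w[j];
      out[i] = acc > 0.0 ? acc : 0.0;  // clip eigen round-off
    }
  }

  double computeNode(size_t l, int v) {
    const Locus &lc = loci[l];
    const int K = lc.K;
    branchMessage(lc, child1[v], time[v] - time[child1[v]], m1.data());
    branchMessage(lc, child2[v], time[v] - time[child2[v]], m2.data());
    double *p = &part[l][(size_t)v * K];
    double mx = 0.0;
    for (int i = 0; i < K; ++i) {
      p[i] = m1[i] * m2[i];
      if (p[i] > mx) mx = p[i];
    }
    if (mx <= 0.0) return -1e300;
    const double inv = 1.0 / mx;
    for (int i = 0; i < K; ++i) p[i] *= inv;
    return std::log(mx);
  }

  double rootLog(size_t l) {
    const int K = loci[l].K;
    const double *p = &part[l][(size_t)root * K];
    double acc = 0.0;
    for (int i = 0; i < K; ++i) acc += p[i];
    return std::log(acc / K);
  }

  void postorderInternal(std::vector<int> &order) {
    order.clear();
    std::vector<int> stack;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      order.push_back(v);
      if (child1[v] >= n) stack.push_back(child1[v]);
      if (child2[v] >= n) stack.push_back(child2[v]);
    }
    std::reverse(order.begin(), order.end());
  }

  void fullLikelihood() {
    std::vector<int> order;
    postorderInternal(order);
    for (size_t l = 0; l < loci.size(); ++l) {
      double ss = 0.0;
      for (size_t k = 0; k < order.size(); ++k) {
        int v = order[k];
        scale[l][v] = computeNode(l, v);
        ss += scale[l][v];
      }
      sumScale[l] = ss;
      loglik[l] = ss + rootLog(l);
    }
  }

  double total() const {
    double acc = 0.0;
    for (size_t l = 0; l < loglik.size(); ++l) acc += loglik[l];
    return acc;
  }

  // recompute partials along `dirty` (bottom-up); returns new total loglik
  double updateDirty() {
    bkNodes = dirty;
    for (size_t l = 0; l < loci.size(); ++l) {
      const int K = loci[l].K;
      bkSumScale[l] = sumScale[l];
      bkLoglik[l] = loglik[l];
      double ss = sumScale[l];
      for (size_t k = 0; k < dirty.size(); ++k) {
        int v = dirty[k];
        std::copy(part[l].data() + (size_t)v * K,
                  part[l].data() + (size_t)v * K + K,
                  bkPart[l].data() + (size_t)v * K);
        bkScale[l][v] = scale[l][v];
        ss -= scale[l][v];
        scale[l][v] = computeNode(l, v);
        ss += scale[l][v];
      }
      sumScale[l] = ss;
      loglik[l] = ss + rootLog(l);
    }
    return total();
  }

  void rollback() {
    for (size_t l = 0; l < loci.size(); ++l) {
      const int K = loci[l].K;
      for (size_t k = 0; k < bkNodes.size(); ++k) {
        int v = bkNodes[k];
        std::copy(bkPart[l].data() + (size_t)v * K,
                  bkPart[l].data() + (size_t)v * K + K,
                  part[l].data() + (size_t)v * K);
        scale[l][v] = bkScale[l][v];
      }
      sumScale[l] = bkSumScale[l];
      loglik[l] = bkLoglik[l];
    }
  }

  void pathToRoot(int v) {
    path.clear();
    while (v != -1) { path.push_back(v); v = parent[v]; }
  }

  // coalescent-with-growth log prior: N(t) = N exp(-r t), r = g / N
  double coalPrior(double N, double g, std::vector<double> &ev) {
    ev.clear();
    for (int v = n; v < nNode; ++v) ev.push_back(time[v]);
    std::sort(ev.begin(), ev.end());
    const double r = g / N;
    double lp = 0.0, lamPrev = 0.0;
    for (int j = 0; j < n - 1; ++j) {
      const double t = ev[j];
      const int k = n - j;
      const double lamT = (r > 0.0) ? (std::exp(r * t) - 1.0) / (r * N)
                                    : t / N;
      lp += -0.5 * k * (k - 1) * (lamT - lamPrev);
      lp += -std::log(N) + r * t;
      lamPrev = lamT;
    }
    return lp;
  }
};

double logPriorN(double N, double meanlog, double sdlog) {
  if (sdlog <= 0.0) return 0.0;
  const double z = (std::log(N) - meanlog) / sdlog;
  return -0.5 * z * z - std::log(N);
}

double logPriorG(double g, double rate) {
  if (rate <= 0.0) return 0.0;
  return -rate * g;
}

}  // namespace

// [[Rcpp::export(name = ".mcmc_run")]]
List mcmc_run(List locusData, IntegerVector parentR, IntegerVector child1R,
              IntegerVector child2R, NumericVector timeR, int nTips,
              int nIter, int burnIn, int thin,
              double priorNMeanlog, double priorNSdlog, double priorGRate,
              double initN, double initG, bool useLikelihood) {
  Sampler sm;
  sm.nNode = parentR.size();
  sm.n = nTips;
  sm.parent.assign(parentR.begin(), parentR.end());
  sm.child1.assign(child1R.begin(), child1R.end());
  sm.child2.assign(child2R.begin(), child2R.end());
  sm.time.assign(timeR.begin(), timeR.end());
  sm.root = -1;
  for (int v = 0; v < sm.nNode; ++v) if (sm.parent[v] == -1) sm.root = v;

  if (useLikelihood) {
    for (int l = 0; l < locusData.size(); ++l) {
      List ld = locusData[l];
      Locus lc;
      NumericMatrix V = ld["V"];
      lc.K = V.nrow();
      lc.V.assign(V.begin(), V.end());
      NumericVector lam = ld["lambda"];
      lc.lam.assign(lam.begin(), lam.end());
      lc.mu = as<double>(ld["mu"]);
      IntegerVector tip = ld["tip"];
      lc.tip.assign(tip.begin(), tip.end());
      sm.loci.push_back(lc);
    }
  }
  sm.init();

  double N = initN, g = initG;
  if (useLikelihood) sm.fullLikelihood();
  double curLL = useLikelihood ? sm.total() : 0.0;
  std::vector<double> evScratch;
  evScratch.reserve(sm.n);
  double curPrior = sm.coalPrior(N, g, evScratch) +
    logPriorN(N, priorNMeanlog, priorNSdlog) + logPriorG(g, priorGRate);

  std::vector<int> internals;
  for (int v = sm.n; v < sm.nNode; ++v) internals.push_back(v);
  const int m = (int)internals.size();

  const int total = burnIn + nIter;
  const int nOut = nIter / thin;
  NumericMatrix trace(nOut, 4);
  colnames(trace) = CharacterVector::create("height", "N", "g", "loglik");
  int row = 0;
  long accepted = 0, proposed = 0;

  RNGScope scope;

  for (int it = 0; it < total; ++it) {
    double u = unif_rand();
    ++proposed;
    if (u < 0.40) {
      // slide one internal node time
      int v = internals[(int)std::floor(unif_rand() * m)];
      double lo = std::max(sm.time[sm.child1[v]], sm.time[sm.child2[v]]);
      double oldT = sm.time[v];
      double newT, logHast = 0.0;
      if (sm.parent[v] == -1) {
        double f = std::exp(0.7 * (unif_rand() - 0.5));
        newT = lo + (oldT - lo) * f;
        logHast = std::log(f);
      } else {
        newT = lo + unif_rand() * (sm.time[sm.parent[v]] - lo);
      }
      sm.time[v] = newT;
      double newPrior = sm.coalPrior(N, g, evScratch) +
        logPriorN(N, priorNMeanlog, priorNSdlog) + logPriorG(g, priorGRate);
      double newLL = curLL;
      bool dirtyDone = false;
      if (useLikelihood) {
        sm.pathToRoot(v);
        sm.dirty = sm.path;
        newLL = sm.updateDirty();
        dirtyDone = true;
      }
      if (std::log(unif_rand()) <
          (newLL - curLL) + (newPrior - curPrior) + logHast) {
        curLL = newLL; curPrior = newPrior; ++accepted;
      } else {
        sm.time[v] = oldT;
        if (dirtyDone) sm.rollback();
      }
    } else if (u < 0.60 && m >= 2) {
      // narrow exchange: swap a child of v with v's sibling
      int v = internals[(int)std::floor(unif_rand() * m)];
      if (sm.parent[v] != -1) {
        int p = sm.parent[v];
        int s = (sm.child1[p] == v) ? sm.child2[p] : sm.child1[p];
        int c = (unif_rand() < 0.5) ? sm.child1[v] : sm.child2[v];
        if (sm.time[v] > sm.time[s]) {
          if (sm.child1[p] == s) sm.child1[p] = c; else sm.child2[p] = c;
          if (sm.child1[v] == c) sm.child1[v] = s; else sm.child2[v] = s;
          sm.parent[s] = v; sm.parent[c] = p;
          double newLL = curLL;
          bool dirtyDone = false;
          if (useLikelihood) {
            sm.pathToRoot(p);
            sm.dirty.clear();
            sm.dirty.push_back(v);
            sm.dirty.insert(sm.dirty.end(), sm.path.begin(), sm.path.end());
            newLL = sm.updateDirty();
            dirtyDone = true;
          }
          // times unchanged: coalescent prior is invariant
          if (std::log(unif_rand()) < newLL - curLL) {
            curLL = newLL; ++accepted;
          } else {
            if (sm.child1[p] == c) sm.child1[p] = s; else sm.child2[p] = s;
            if (sm.child1[v] == s) sm.child1[v] = c; else sm.child2[v] = c;
            sm.parent[s] = p; sm.parent[c] = v;
            if (dirtyDone) sm.rollback();
          }
        }
      }
    } else if (u < 0.70) {
      // scale all internal node times
      double f = std::exp(0.3 * (unif_rand() - 0.5));
      for (int k = 0; k < m; ++k) sm.time[internals[k]] *= f;
      double newPrior = sm.coalPrior(N, g, evScratch) +
        logPriorN(N, priorNMeanlog, priorNSdlog) + logPriorG(g, priorGRate);
      double newLL = curLL;
      if (useLikelihood) {
        sm.fullLikelihood();
        newLL = sm.total();
      }
      if (std::log(unif_rand()) <
          (newLL - curLL) + (newPrior - curPrior) + m * std::log(f)) {
        curLL = newLL; curPrior = newPrior; ++accepted;
      } else {
        const double inv = 1.0 / f;
        for (int k = 0; k < m; ++k) sm.time[internals[k]] *= inv;
        if (useLikelihood) sm.fullLikelihood();
      }
    } else if (u < 0.85) {
      // update N (log random walk, lognormal prior)
      if (priorNSdlog > 0.0) {
        double oldN = N;
        N = N * std::exp(0.4 * (unif_rand() - 0.5));
        double newPrior = sm.coalPrior(N, g, evScratch) +
          logPriorN(N, priorNMeanlog, priorNSdlog) + logPriorG(g, priorGRate);
        // proposal symmetric in log N -> Jacobian term log(N'/N)
        if (std::log(unif_rand()) < (newPrior - curPrior) + std::log(N / oldN)) {
          curPrior = newPrior; ++accepted;
        } else N = oldN;
      }
    } else {
      // update g (reflected random walk, exponential prior)
      if (priorGRate > 0.0) {
        double oldG = g;
        g = g + 0.5 * (unif_rand() - 0.5);
        if (g < 0.0) g = -g;
        double newPrior = sm.coalPrior(N, g, evScratch) +
          logPriorN(N, priorNMeanlog, priorNSdlog) + logPriorG(g, priorGRate);
        if (std::log(unif_rand()) < newPrior - curPrior) {
          curPrior = newPrior; ++accepted;
        } else g = oldG;
      }
    }

    if (it >= burnIn) {
      int k = it - burnIn;
      if ((k + 1) % thin == 0 && row < nOut) {
        trace(row, 0) = sm.time[sm.root];
        trace(row, 1) = N;
        trace(row, 2) = g;
        trace(row, 3) = curLL;
        ++row;
      }
    }
  }

  return List::create(_["trace"] = trace,
                      _["acceptance"] = (double)accepted / proposed);
}
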