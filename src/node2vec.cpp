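// Biased second-order random walks over a weighted graph and skip-gram
// negative-sampling training of node vectors. Self-contained RNG (splitmix64
// seeding an xorshift128+) so identical seeds give identical corpora and
// vectors on every platform; R's RNG state is never touched.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct XorShift128Plus {
  uint64_t s0, s1;
  explicit XorShift128Plus(uint64_t seed) {
    // splitmix64 expansion of the seed into two nonzero state words
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    auto mix = [](uint64_t z) {
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      return z ^ (z >> 31);
    };
    s0 = mix(z);
    z += 0x9E3779B97F4A7C15ULL;
    s1 = mix(z);
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  uint64_t next() {
    uint64_t x = s0;
    const uint64_t y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  // uniform double in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  int below(int n) { return (int)(unif() * n); }
};

// binary search into a cumulative-weight vector
inline int sample_cum(const std::vector<double>& cum, double u) {
  double target = u * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] <= target) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Walker alias table for O(1) draws from a discrete distribution
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double>& w) {
    const int n = (int)w.size();
    prob.assign(n, 0.0);
    alias.assign(n, 0);
    double total = 0.0;
    for (double x : w) total += x;
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    for (int i = 0; i < n; ++i) {
      scaled[i] = w[i] * n / total;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = scaled[l] + scaled[s] - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    for (int i : small) prob[i] = 1.0;
    for (int i : large) prob[i] = 1.0;
  }
  int draw(XorShift128Plus& rng) const {
    double u = rng.unif() * prob.size();
    int i = (int)u;
    if (i >= (int)prob.size()) i = (int)prob.size() - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// precomputed logistic table over [-MAX_EXP, MAX_EXP] (word2vec convention):
// outside the range the gradient is numerically saturated anyway
const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;
struct SigmoidTable {
  double t[EXP_TABLE_SIZE];
  SigmoidTable() {
    for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
      double x = (2.0 * i / EXP_TABLE_SIZE - 1.0) * MAX_EXP;
      t[i] = 1.0 / (1.0 + std::exp(-x));
    }
  }
  double operator()(double x) const {
    if (x <= -MAX_EXP) return 0.0;
    if (x >= MAX_EXP) return 1.0;
    return t[(int)((x + MAX_EXP) * (EXP_TABLE_SIZE / (2.0 * MAX_EXP)))];
  }
};
const SigmoidTable sigmoid_table;

}  // namespace

// Simulate walks_per_node biased random walks from every node.
// weights: dense symmetric non-negative P x P matrix, zero diagonal.
// Bias: unnormalized transition weight w(v,x) * alpha where alpha = 1/p if x
// is the previous node, 1 if x neighbors the previous node, 1/q otherwise.
// Returns a list of integer vectors (1-based node ids); walks truncate at
// dead ends, with the truncation count in attribute "n_truncated".
// [[Rcpp::export(name = ".simulate_walks_cpp")]]
List simulate_walks_cpp(NumericMatrix weights, double p, double q,
                        int walk_length, int walks_per_node, double seed) {
  const int P = weights.nrow();
  if (weights.ncol() != P) stop("weight matrix must be square");
  XorShift128Plus rng((uint64_t)seed);

  // adjacency lists + first-order cumulative weights
  std::vector<std::vector<int> > nbr(P);
  std::vector<std::vector<double> > cumw(P);
  for (int v = 0; v < P; ++v) {
    double acc = 0.0;
    for (int x = 0; x < P; ++x) {
      double w = weights(x, v);
      if (x != v && w > 0.0) {
        nbr[v].push_back(x);
        acc += w;
        cumw[v].push_back(acc);
      }
    }
  }
  const bool unbiased = (p == 1.0 && q == 1.0);

  List walks(P * walks_per_node);
  int n_trunc = 0;
  std::vector<int> buf;
  std::vector<double> cum2;
  int k = 0;
  for (int r = 0; r < walks_per_node; ++r) {
    for (int start = 0; start < P; ++start) {
      buf.clear();
      buf.push_back(start);
      int prev = -1, cur = start;
      while ((int)buf.size() < walk_length) {
        const std::vector<int>& nb = nbr[cur];
        if (nb.empty()) { ++n_trunc; break; }
        int nxt;
        if (unbiased || prev < 0) {
          nxt = nb[sample_cum(cumw[cur], rng.unif())];
        } else {
          cum2.resize(nb.size());
          double acc = 0.0;
          for (size_t i = 0; i < nb.size(); ++i) {
            int x = nb[i];
            double w = weights(x, cur);
            double alpha;
            if (x == prev) alpha = 1.0 / p;
            else if (weights(x, prev) > 0.0) alpha = 1.0;
            else alpha = 1.0 / q;
            acc += w * alpha;
            cum2[i] = acc;
          }
          nxt = nb[sample_cum(cum2, rng.unif())];
        }
        prev = cur;
        cur = nxt;
        buf.push_back(cur);
      }
      IntegerVector w(buf.size());
      for (size_t i = 0; i < buf.size(); ++i) w[i] = buf[i] + 1;
      walks[k++] = w;
    }
  }
  walks.attr("n_truncated") = n_trunc;
  return walks;
}

// Skip-gram with negative sampling over a walk corpus.
// walks: list of 1-based integer vectors. Context window half-width is drawn
// uniformly in {1..window} per center (word2vec convention). Negative nodes
// are drawn from the unigram^(3/4) corpus distribution. Learning rate decays
// linearly from lr to lr_min over all scheduled center positions.
// init_w / init_c: optional P x dim warm-start matrices (input/output side).
// Returns list(w = input vectors, c = context vectors), each P x dim.
// [[Rcpp::export(name = ".sgns_train_cpp")]]
List sgns_train_cpp(List walks, int n_nodes, int dim, int window,
                    int negatives, int epochs, double lr, double lr_min,
                    double seed, Nullable<NumericMatrix> init_w,
                    Nullable<NumericMatrix> init_c) {
  const int P = n_nodes;
  XorShift128Plus rng((uint64_t)seed ^ 0xA5A5A5A55A5A5A5AULL);

  std::vector<double> W((size_t)P * dim), C((size_t)P * dim, 0.0);
  if (init_w.isNotNull()) {
    NumericMatrix m(init_w);
    if (m.nrow() != P || m.ncol() != dim) stop("init_w has wrong shape");
    for (int j = 0; j < dim; ++j)
      for (int i = 0; i < P; ++i) W[(size_t)i * dim + j] = m(i, j);
  } else {
    for (size_t i = 0; i < W.size(); ++i) W[i] = (rng.unif() - 0.5) / dim;
  }
  if (init_c.isNotNull()) {
    NumericMatrix m(init_c);
    if (m.nrow() != P || m.ncol() != dim) stop("init_c has wrong shape");
    for (int j = 0; j < dim; ++j)
      for (int i = 0; i < P; ++i) C[(size_t)i * dim + j] = m(i, j);
  }

  // unigram^(3/4) negative-sampling table (cumulative)
  std::vector<double> count(P, 0.0);
  size_t total_tokens = 0;
  const int n_walks = walks.size();
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector wk = walks[wi];
    total_tokens += wk.size();
    for (int t = 0; t < wk.size(); ++t) {
      int v = wk[t] - 1;
      if (v < 0 || v >= P) stop("walk contains node id outside 1..n_nodes");
      count[v] += 1.0;
    }
  }
  std::vector<double> negw(P);
  double acc = 0.0;
  for (int v = 0; v < P; ++v) {
    negw[v] = std::pow(count[v], 0.75);
    acc += negw[v];
  }
  if (acc <= 0) stop("empty corpus");
  AliasTable neg_alias;
  neg_alias.build(negw);

  const double total_centers =
      (double)total_tokens * (double)epochs;  // lr schedule denominator

  // copy walks into flat buffers once so the hot loop never touches R objects
  std::vector<int> flat;
  flat.reserve(total_tokens);
  std::vector<int> wstart(n_walks + 1, 0);
  for (int wi = 0; wi < n_walks; ++wi) {
    IntegerVector wk = walks[wi];
    for (int t = 0; t < wk.size(); ++t) flat.push_back(wk[t] - 1);
    wstart[wi + 1] = (int)flat.size();
  }

  // dim-templated training loop: fixed trip counts let the compiler unroll
  auto run = [&](auto dim_tag) {
    constexpr int D = decltype(dim_tag)::value;
    double processed = 0.0;
    double grad[D > 0 ? D : 1];
    const int dd = D > 0 ? D : dim;
    (void)dd;
    for (int ep = 0; ep < epochs; ++ep) {
      for (int wi = 0; wi < n_walks; ++wi) {
        const int L = wstart[wi + 1] - wstart[wi];
        const int* wk = &flat[wstart[wi]];
        for (int t = 0; t < L; ++t) {
          double alpha = lr - (lr - lr_min) * (processed / total_centers);
          processed += 1.0;
          int b = 1 + rng.below(window);  // effective half-width
          double* wc = &W[(size_t)wk[t] * D];
          int lo = t - b < 0 ? 0 : t - b;
          int hi = t + b >= L ? L - 1 : t + b;
          for (int s = lo; s <= hi; ++s) {
            if (s == t) continue;
            int pos = wk[s];
            for (int d = 0; d < D; ++d) grad[d] = 0.0;
            for (int n = 0; n <= negatives; ++n) {
              int target;
              double label;
              if (n == 0) { target = pos; label = 1.0; }
              else {
                target = neg_alias.draw(rng);
                if (target == pos) continue;
                label = 0.0;
              }
              double* ct = &C[(size_t)target * D];
              double dot = 0.0;
              for (int d = 0; d < D; ++d) dot += wc[d] * ct[d];
              double g = (label - sigmoid_table(dot)) * alpha;
              for (int d = 0; d < D; ++d) {
                grad[d] += g * ct[d];
                ct[d] += g * wc[d];
              }
            }
            for (int d = 0; d < D; ++d) wc[d] += grad[d];
          }
        }
      }
    }
  };

  // generic fallback mirrors the templated path with a runtime dim
  auto run_generic = [&]() {
    double processed = 0.0;
    std::vector<double> grad(dim);
    for (int ep = 0; ep < epochs; ++ep) {
      for (int wi = 0; wi < n_walks; ++wi) {
        const int L = wstart[wi + 1] - wstart[wi];
        const int* wk = &flat[wstart[wi]];
        for (int t = 0; t < L; ++t) {
          double alpha = lr - (lr - lr_min) * (processed / total_centers);
          processed += 1.0;
          int b = 1 + rng.below(window);
          double* wc = &W[(size_t)wk[t] * dim];
          int lo = t - b < 0 ? 0 : t - b;
          int hi = t + b >= L ? L - 1 : t + b;
          for (int s = lo; s <= hi; ++s) {
            if (s == t) continue;
            int pos = wk[s];
            for (int d = 0; d < dim; ++d) grad[d] = 0.0;
            for (int n = 0; n <= negatives; ++n) {
              int target;
              double label;
              if (n == 0) { target = pos; label = 1.0; }
              else {
                target = neg_alias.draw(rng);
                if (target == pos) continue;
                label = 0.0;
              }
              double* ct = &C[(size_t)target * dim];
              double dot = 0.0;
              for (int d = 0; d < dim; ++d) dot += wc[d] * ct[d];
              double g = (label - sigmoid_table(dot)) * alpha;
              for (int d = 0; d < dim; ++d) {
                grad[d] += g * ct[d];
                ct[d] += g * wc[d];
              }
            }
            for (int d = 0; d < dim; ++d) wc[d] += grad[d];
          }
        }
      }
    }
  };

  switch (dim) {
    case 8: run(std::integral_constant<int, 8>{}); break;
    case 16: run(std::integral_constant<int, 16>{}); break;
    case 30: run(std::integral_constant<int, 30>{}); break;
    default: run_generic();
  }

  NumericMatrix outW(P, dim), outC(P, dim);
  for (int i = 0; i < P; ++i)
    for (int j = 0; j < dim; ++j) {
      outW(i, j) = W[(size_t)i * dim + j];
      outC(i, j) = C[(size_t)i * dim + j];
    }
  return List::create(_["w"] = outW, _["c"] = outC);
}
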