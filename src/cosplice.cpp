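#include <Rcpp.h>
#include <array>
using namespace Rcpp;

// ZOOPS expectation-maximization for one start.
//
// Generative model: with probability lambda a sequence carries exactly one
// motif site at a uniformly chosen offset (site letters ~ PWM, all other
// letters ~ background); with probability 1 - lambda it is pure background.
// Sequences are integer-encoded (A=0, C=1, G=2, T=3). The E-step computes
// posterior site locations, the M-step re-estimates PWM (with pseudocount),
// lambda and background from expected non-site letters. The log-likelihood
// trace is returned so callers can assert monotone convergence.
//
// [[Rcpp::export]]
List zoops_em_cpp(List seqs, int w, NumericMatrix init_pwm,
                  double init_lambda, NumericVector init_bg,
                  int max_iter, double tol, double pseudocount) {
  int n = seqs.size();
  std::vector<std::vector<int>> x(n);
  std::vector<int> len(n), m(n);
  std::vector<double> tot_letter(4, 0.0);
  for (int i = 0; i < n; ++i) {
    IntegerVector si = seqs[i];
    x[i].assign(si.begin(), si.end());
    len[i] = si.size();
    if (len[i] < w) stop("sequence shorter than motif width");
    m[i] = len[i] - w + 1;
    for (int p = 0; p < len[i]; ++p) {
      if (x[i][p] < 0 || x[i][p] > 3) stop("non-ACGT letter in EM input");
      tot_letter[x[i][p]] += 1.0;
    }
  }
  // per-sequence letter counts, for O(1) background log-likelihoods
  std::vector<std::array<double, 4>> letter_counts(n);
  for (int i = 0; i < n; ++i) {
    letter_counts[i] = {0.0, 0.0, 0.0, 0.0};
    for (int p = 0; p < len[i]; ++p) letter_counts[i][x[i][p]] += 1.0;
  }
  NumericMatrix pwm = clone(init_pwm);     // 4 x w
  NumericVector bg = clone(init_bg);       // 4
  double lambda = init_lambda;
  std::vector<double> ll_trace;
  double ll_prev = R_NegInf, ll = R_NegInf;
  std::vector<double> ratio_tab(4 * w), ratio(256);

  for (int iter = 0; iter < max_iter; ++iter) {
    // E-step + accumulate expected counts
    std::vector<double> site_counts(4 * w, 0.0), site_letter(4, 0.0);
    double log_bg_letter[4];
    for (int l = 0; l < 4; ++l) {
      log_bg_letter[l] = std::log(bg[l]);
      for (int k = 0; k < w; ++k) ratio_tab[k * 4 + l] = pwm(l, k) / bg[l];
    }
    double lambda_acc = 0.0;
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double log_bgprod = 0.0;
      for (int l = 0; l < 4; ++l)
        log_bgprod += letter_counts[i][l] * log_bg_letter[l];
      // joint for "no site" and each site offset, relative to bgprod
      if ((int) ratio.size() < m[i]) ratio.resize(m[i]);
      double sum_ratio = 0.0;
      const int* xi = x[i].data();
      for (int j = 0; j < m[i]; ++j) {
        double r = 1.0;
        for (int k = 0; k < w; ++k) r *= ratio_tab[k * 4 + xi[j + k]];
        ratio[j] = r;
        sum_ratio += r;
      }
      double joint0 = (1.0 - lambda);
      double total = joint0 + lambda / m[i] * sum_ratio;
      ll += std::log(total) + log_bgprod;
      double z_site = 1.0 - joint0 / total;
      lambda_acc += z_site;
      for (int j = 0; j < m[i]; ++j) {
        double zj = (lambda / m[i]) * ratio[j] / total;
        if (zj <= 0) continue;
        for (int k = 0; k < w; ++k) {
          int l = x[i][j + k];
          site_counts[k * 4 + l] += zj;
          site_letter[l] += zj;
        }
      }
    }
    ll_trace.push_back(ll);
    // M-step
    lambda = lambda_acc / n;
    if (lambda < 1e-6) lambda = 1e-6;
    if (lambda > 1.0 - 1e-6) lambda = 1.0 - 1e-6;
    for (int k = 0; k < w; ++k) {
      double colsum = 0.0;
      for (int l = 0; l < 4; ++l) colsum += site_counts[k * 4 + l] + pseudocount;
      for (int l = 0; l < 4; ++l)
        pwm(l, k) = (site_counts[k * 4 + l] + pseudocount) / colsum;
    }
    double bgsum = 0.0;
    std::vector<double> bgc(4);
    for (int l = 0; l < 4; ++l) {
      bgc[l] = tot_letter[l] - site_letter[l];
      if (bgc[l] < 0) bgc[l] = 0;
      bgc[l] += pseudocount;
      bgsum += bgc[l];
    }
    for (int l = 0; l < 4; ++l) bg[l] = bgc[l] / bgsum;
    if (iter > 0 && std::fabs(ll - ll_prev) < tol * (1.0 + std::fabs(ll)))
      break;
    ll_prev = ll;
  }
  return List::create(_["pwm"] = pwm, _["lambda"] = lambda, _["bg"] = bg,
                      _["loglik"] = ll,
                      _["ll_trace"] = NumericVector(ll_trace.begin(),
                                                    ll_trace.end()),
                      _["n_iter"] = (int) ll_trace.size());
}

// Dinucleotide-preserving shuffle (random Eulerian path on the
// letter-transition multigraph, Hierholzer traversal with R-RNG-shuffled
// adjacency lists). First and last letters are preserved; dinucleotide
// counts are exactly preserved.
//
// [[Rcpp::export]]
IntegerVector dinuc_shuffle_cpp(IntegerVector seq) {
  int n = seq.size();
  if (n <= 3) return clone(seq);
  // adjacency: for each of 4 vertices, list of successor letters
  std::vector<std::vector<int>> adj(4);
  for (int i = 0; i + 1 < n; ++i) adj[seq[i]].push_back(seq[i + 1]);
  // shuffle each adjacency list with R's RNG (Fisher-Yates)
  for (int v = 0; v < 4; ++v) {
    std::vector<int>& a = adj[v];
    for (int i = (int) a.size() - 1; i > 0; --i) {
      int j = (int) std::floor(unif_rand() * (i + 1));
      std::swap(a[i], a[j]);
    }
  }
  // Hierholzer Euler path from seq[0]; the path exists by construction and
  // every edge is reachable because the original sequence is one walk.
  std::vector<size_t> next_edge(4, 0);
  std::vector<int> stack_, route;
  stack_.reserve(n);
  route.reserve(n);
  stack_.push_back(seq[0]);
  while (!stack_.empty()) {
    int v = stack_.back();
    if (next_edge[v] < adj[v].size()) {
      stack_.push_back(adj[v][next_edge[v]++]);
    } else {
      route.push_back(v);
      stack_.pop_back();
    }
  }
  std::reverse(route.begin(), route.end());
  if ((int) route.size() != n) return clone(seq);  // degenerate; keep input
  return IntegerVector(route.begin(), route.end());
}

// Length of the longest common subsequence: the optimum of a global
// alignment with match = 1, mismatch = 0, gap = 0.
//
// [[Rcpp::export]]
int lcs_length_cpp(std::string a, std::string b) {
  size_t n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (size_t i = 1; i <= n; ++i) {
    for (size_t j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
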