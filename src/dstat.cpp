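#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Max running-sum deviation for every word under every ordering.
//
// For word w with per-gene rates r_i = counts_i / lens_i and mean rate
// mu_w, the running sum after j genes of an ordering is
// R_j = (sum of rates of the first j genes) - j * mu_w.
// Between genes that carry the word, R_j decreases linearly (slope
// -mu_w <= 0), so its maximum over j is attained immediately after a
// carrier gene (or is 0), and its minimum immediately before one (or at
// j = n, where R_n = 0). This lets each ordering be scored by streaming
// the genes once and touching only the words present in each gene.
//
// counts: n x W occurrence-count matrix (genes in rows, observed rank
//         order; words in columns).
// lens:   n sequence lengths (nt).
// orders: n x P matrix of 1-based row orderings; column 1 is typically
//         the identity (observed order), the rest permutations.
// two_sided: score max |R_j| instead of max(0, max_j R_j).
//
// Returns a P x W matrix of deviation statistics.
// [[Rcpp::export]]
NumericMatrix dstat_by_order(IntegerMatrix counts, NumericVector lens,
                             IntegerMatrix orders, bool two_sided = false) {
  const int n = counts.nrow();
  const int W = counts.ncol();
  const int P = orders.ncol();
  if ((int) lens.size() != n) stop("lens must have one entry per gene");
  if (orders.nrow() != n) stop("orders must have one row per gene");
  for (int p = 0; p < P; ++p)
    for (int i = 0; i < n; ++i) {
      int o = orders(i, p);
      if (o < 1 || o > n) stop("ordering index out of range");
    }
  for (int i = 0; i < n; ++i)
    if (!(lens[i] > 0)) stop("sequence lengths must be positive");

  // per-gene adjacency of (word, rate) for nonzero counts, built in two
  // column-major passes over the count matrix
  std::vector<double> inv_len(n);
  for (int i = 0; i < n; ++i) inv_len[i] = 1.0 / lens[i];
  std::vector<int> row_ptr(n + 1, 0);
  std::vector<double> mu(W, 0.0);
  const int* cnt = counts.begin();
  for (int w = 0; w < W; ++w) {
    const int* col = cnt + (size_t) w * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (col[i] != 0) {
        ++row_ptr[i + 1];
        s += col[i] * inv_len[i];
      }
    }
    mu[w] = s / n;
  }
  for (int i = 0; i < n; ++i) row_ptr[i + 1] += row_ptr[i];
  const int nnz = row_ptr[n];
  std::vector<int> word_id(nnz);
  std::vector<double> rate(nnz);
  std::vector<int> fill = row_ptr;
  for (int w = 0; w < W; ++w) {
    const int* col = cnt + (size_t) w * n;
    for (int i = 0; i < n; ++i) {
      if (col[i] != 0) {
        const int at = fill[i]++;
        word_id[at] = w;
        rate[at] = col[i] * inv_len[i];
      }
    }
  }

  NumericMatrix d(P, W);
  std::vector<double> cum(W), mx(W), mn(W);
  for (int p = 0; p < P; ++p) {
    std::fill(cum.begin(), cum.end(), 0.0);
    std::fill(mx.begin(), mx.end(), 0.0);
    std::fill(mn.begin(), mn.end(), 0.0);
    const int* ord = &orders(0, p);
    for (int j = 1; j <= n; ++j) {
      const int g = ord[j - 1] - 1;
      for (int e = row_ptr[g]; e < row_ptr[g + 1]; ++e) {
        const int w = word_id[e];
        if (two_sided) {
          const double before = cum[w] - (j - 1) * mu[w];
          if (before < mn[w]) mn[w] = before;
        }
        cum[w] += rate[e];
        const double after = cum[w] - j * mu[w];
        if (after > mx[w]) mx[w] = after;
      }
    }
    if (two_sided) {
      for (int w = 0; w < W; ++w)
        d(p, w) = mx[w] > -mn[w] ? mx[w] : -mn[w];
    } else {
      for (int w = 0; w < W; ++w) d(p, w) = mx[w];
    }
  }
  return d;
}
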