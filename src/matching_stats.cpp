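#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

// Matching statistics of a query against a subject: for every query
// position i, the length of the longest prefix of the query suffix
// starting at i that occurs somewhere in the subject. Shustring lengths
// are matching statistics + 1, capped at the query end (done in R).
//
// A suffix automaton is built over the reversed subject in linear time;
// streaming the reversed query through it yields, after each character,
// the longest suffix of the processed reversed prefix that is a substring
// of the reversed subject, which maps back to the forward-strand matching
// statistic. Total time and memory are linear in the combined length.

namespace {

struct Sam {
  int A;                  // alphabet size
  std::vector<int> nxt;   // flat states x A transition table, -1 = none
  std::vector<int> link, len;
  int last;

  Sam(int alpha, std::size_t text_len) : A(alpha), last(0) {
    std::size_t cap = 2 * text_len + 2;
    nxt.reserve(cap * A);
    link.reserve(cap);
    len.reserve(cap);
    new_state(0, -1);
  }

  int new_state(int l, int lk) {
    len.push_back(l);
    link.push_back(lk);
    nxt.insert(nxt.end(), A, -1);
    return static_cast<int>(len.size()) - 1;
  }

  inline int go(int v, int c) const {
    return nxt[static_cast<std::size_t>(v) * A + c];
  }
  inline void set_go(int v, int c, int w) {
    nxt[static_cast<std::size_t>(v) * A + c] = w;
  }

  void extend(int c) {
    int cur = new_state(len[last] + 1, -1);
    int p = last;
    while (p != -1 && go(p, c) == -1) {
      set_go(p, c, cur);
      p = link[p];
    }
    if (p == -1) {
      link[cur] = 0;
    } else {
      int q = go(p, c);
      if (len[p] + 1 == len[q]) {
        link[cur] = q;
      } else {
        int clone = new_state(len[p] + 1, link[q]);
        for (int a = 0; a < A; ++a) set_go(clone, a, go(q, a));
        while (p != -1 && go(p, c) == q) {
          set_go(p, c, clone);
          p = link[p];
        }
        link[q] = clone;
        link[cur] = clone;
      }
    }
    last = cur;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::IntegerVector cpp_matching_stats(const std::string& subject,
                                       const std::string& query) {
  if (subject.empty()) Rcpp::stop("subject sequence is empty");
  if (query.empty()) Rcpp::stop("query sequence is empty");

  int code[256];
  std::fill(code, code + 256, -1);
  int A = 0;
  for (std::size_t i = 0; i < subject.size(); ++i) {
    unsigned char ch = static_cast<unsigned char>(subject[i]);
    if (code[ch] < 0) code[ch] = A++;
  }
  if (A > 16) Rcpp::stop("subject alphabet larger than 16 symbols");

  const std::size_t m = subject.size(), n = query.size();
  Sam sam(A, m);
  for (std::size_t i = 0; i < m; ++i) {
    sam.extend(code[static_cast<unsigned char>(subject[m - 1 - i])]);
  }

  Rcpp::IntegerVector ms(n);
  int v = 0, l = 0;
  for (std::size_t j = 0; j < n; ++j) {
    int c = code[static_cast<unsigned char>(query[n - 1 - j])];
    if (c < 0) {
      v = 0;
      l = 0;
    } else {
      while (v != 0 && sam.go(v, c) < 0) {
        v = sam.link[v];
        l = sam.len[v];
      }
      int w = sam.go(v, c);
      if (w >= 0) {
        v = w;
        ++l;
      } else {
        l = 0;
      }
    }
    ms[n - 1 - j] = l;
  }
  return ms;
}
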