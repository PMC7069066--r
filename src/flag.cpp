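// Directed flag-complex enumeration.
//
// A directed n-simplex of a digraph G is an (n+1)-tuple (v0, ..., vn) of
// distinct vertices with an edge vi -> vj for every i < j. Enumeration is by
// recursive extension: the extension candidates of (v0, ..., vk) are the
// common out-neighbours of all members, intersected incrementally. A simplex
// is maximal iff no vertex can be inserted at any position (for insertion at
// position p the vertex must be an out-neighbour of v0..v_{p-1} and an
// in-neighbour of v_p..vk).

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Enumerator {
  int n;
  int max_dim;
  bool want_maximal, want_store_maximal, want_participation, want_nd_in,
      want_store_all;

  std::vector<std::vector<int>> out, in;
  std::vector<std::size_t> edge_off;  // CSR offsets into flattened out lists

  std::vector<double> counts;                     // all simplices per dim
  std::vector<double> max_counts;                 // maximal simplices per dim
  std::vector<std::vector<double>> nd_in;         // [dim][vertex]
  std::vector<std::vector<double>> part_src;      // [dim][edge]
  std::vector<std::vector<double>> part_snk;      // [dim][edge]
  std::vector<std::vector<int>> maximal_flat;     // [dim] flattened tuples
  std::vector<std::vector<int>> all_flat;         // [dim] flattened tuples

  std::vector<int> simp;

  bool has_edge_pos(int u, int v, std::size_t* pos) const {
    const std::vector<int>& o = out[u];
    std::vector<int>::const_iterator it =
        std::lower_bound(o.begin(), o.end(), v);
    if (it == o.end() || *it != v) return false;
    if (pos) *pos = edge_off[u] + (it - o.begin());
    return true;
  }

  std::size_t edge_id(int u, int v) const {
    std::size_t pos = 0;
    has_edge_pos(u, v, &pos);
    return pos;
  }

  // Is there any vertex w that is an out-neighbour of simp[0..p-1] and an
  // in-neighbour of simp[p..k]? Walks the shortest of the involved lists.
  bool insertable_at(int p) const {
    int k = static_cast<int>(simp.size());
    const std::vector<int>* shortest = nullptr;
    for (int i = 0; i < k; ++i) {
      const std::vector<int>& lst = (i < p) ? out[simp[i]] : in[simp[i]];
      if (!shortest || lst.size() < shortest->size()) shortest = &lst;
    }
    for (std::size_t t = 0; t < shortest->size(); ++t) {
      int w = (*shortest)[t];
      bool ok = true;
      for (int i = 0; i < k && ok; ++i) {
        const std::vector<int>& lst = (i < p) ? out[simp[i]] : in[simp[i]];
        if (&lst == shortest) continue;
        ok = std::binary_search(lst.begin(), lst.end(), w);
      }
      if (ok) return true;
    }
    return false;
  }

  void record() {
    int d = static_cast<int>(simp.size()) - 1;
    counts[d] += 1.0;
    if (want_nd_in && d >= 1) nd_in[d][simp.back()] += 1.0;
    if (want_participation && d >= 2) {
      part_src[d][edge_id(simp[0], simp[1])] += 1.0;
      part_snk[d][edge_id(simp[d - 1], simp[d])] += 1.0;
    }
    if (want_store_all)
      all_flat[d].insert(all_flat[d].end(), simp.begin(), simp.end());
  }

  void record_maximal(bool extendable) {
    if (!want_maximal || extendable) return;
    int d = static_cast<int>(simp.size()) - 1;
    for (int p = 0; p <= d; ++p) {
      if (insertable_at(p)) return;  // p = d+1 (append) is `extendable`
    }
    max_counts[d] += 1.0;
    if (want_store_maximal)
      maximal_flat[d].insert(maximal_flat[d].end(), simp.begin(), simp.end());
  }

  void extend(const std::vector<int>& cand) {
    record();
    record_maximal(!cand.empty());
    int d = static_cast<int>(simp.size()) - 1;
    if (d >= max_dim) return;
    std::vector<int> next;
    for (std::size_t t = 0; t < cand.size(); ++t) {
      int w = cand[t];
      const std::vector<int>& ow = out[w];
      next.clear();
      std::set_intersection(cand.begin(), cand.end(), ow.begin(), ow.end(),
                            std::back_inserter(next));
      simp.push_back(w);
      extend(next);
      simp.pop_back();
    }
  }

  void run() {
    int dims = max_dim + 1;
    counts.assign(dims, 0.0);
    max_counts.assign(dims, 0.0);
    if (want_nd_in) nd_in.assign(dims, std::vector<double>(n, 0.0));
    std::size_t m = edge_off.empty() ? 0 : edge_off[n];
    if (want_participation) {
      part_src.assign(dims, std::vector<double>(m, 0.0));
      part_snk.assign(dims, std::vector<double>(m, 0.0));
    }
    if (want_store_maximal) maximal_flat.assign(dims, std::vector<int>());
    if (want_store_all) all_flat.assign(dims, std::vector<int>());
    for (int v = 0; v < n; ++v) {
      simp.assign(1, v);
      extend(out[v]);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List flag_complex_cpp(int n, IntegerVector pre, IntegerVector post,
                      int max_dim, bool maximal, bool store_maximal,
                      bool participation, bool nd_in_degree, bool store_all) {
  Enumerator e;
  e.n = n;
  e.max_dim = max_dim;
  e.want_maximal = maximal || store_maximal;
  e.want_store_maximal = store_maximal;
  e.want_participation = participation;
  e.want_nd_in = nd_in_degree;
  e.want_store_all = store_all;
  e.out.assign(n, std::vector<int>());
  e.in.assign(n, std::vector<int>());
  for (int k = 0; k < pre.size(); ++k) {
    e.out[pre[k]].push_back(post[k]);
    e.in[post[k]].push_back(pre[k]);
  }
  for (int v = 0; v < n; ++v) {
    std::sort(e.out[v].begin(), e.out[v].end());
    std::sort(e.in[v].begin(), e.in[v].end());
  }
  e.edge_off.assign(n + 1, 0);
  for (int v = 0; v < n; ++v) e.edge_off[v + 1] = e.edge_off[v] + e.out[v].size();
  e.run();

  List res;
  res["counts"] = NumericVector(e.counts.begin(), e.counts.end());
  res["maximal_counts"] = NumericVector(e.max_counts.begin(), e.max_counts.end());
  if (nd_in_degree) {
    List ndl(e.max_dim + 1);
    for (int d = 0; d <= e.max_dim; ++d)
      ndl[d] = NumericVector(e.nd_in[d].begin(), e.nd_in[d].end());
    res["nd_in_degree"] = ndl;
  }
  if (participation) {
    // edge order of the CSR layout: by pre vertex, then sorted post
    std::size_t m = e.edge_off[n];
    IntegerVector epre(m), epost(m);
    std::size_t k = 0;
    for (int v = 0; v < n; ++v)
      for (std::size_t t = 0; t < e.out[v].size(); ++t, ++k) {
        epre[k] = v;
        epost[k] = e.out[v][t];
      }
    res["edge_pre"] = epre;
    res["edge_post"] = epost;
    List ps(e.max_dim + 1), pk(e.max_dim + 1);
    for (int d = 0; d <= e.max_dim; ++d) {
      ps[d] = NumericVector(e.part_src[d].begin(), e.part_src[d].end());
      pk[d] = NumericVector(e.part_snk[d].begin(), e.part_snk[d].end());
    }
    res["n_source"] = ps;
    res["n_sink"] = pk;
  }
  if (store_maximal) {
    List ml(e.max_dim + 1);
    for (int d = 0; d <= e.max_dim; ++d) {
      std::size_t rows = (d + 1) ? e.maximal_flat[d].size() / (d + 1) : 0;
      IntegerMatrix mm(d + 1, rows);
      std::copy(e.maximal_flat[d].begin(), e.maximal_flat[d].end(), mm.begin());
      ml[d] = mm;
    }
    res["maximal"] = ml;
  }
  if (store_all) {
    List al(e.max_dim + 1);
    for (int d = 0; d <= e.max_dim; ++d) {
      std::size_t rows = e.all_flat[d].size() / (d + 1);
      IntegerMatrix am(d + 1, rows);
      std::copy(e.all_flat[d].begin(), e.all_flat[d].end(), am.begin());
      al[d] = am;
    }
    res["all"] = al;
  }
  return res;
}
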