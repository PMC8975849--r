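#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Connected components of the k-clique adjacency relation, computed on
// maximal cliques: two maximal cliques of size >= k belong to the same
// component iff they are linked through a chain of maximal-clique overlaps
// of >= k-1 nodes. Overlap >= k-1 is detected exactly as "the two cliques
// share some (k-1)-subset of nodes": every clique emits its (k-1)-subsets
// as packed sort keys, and cliques emitting an identical key are unioned.
// This avoids materializing the quadratic clique-overlap matrix.

struct DSU {
    std::vector<int> parent;
    explicit DSU(int n) : parent(n) {
        for (int i = 0; i < n; ++i) parent[i] = i;
    }
    int find(int x) {
        while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
        return x;
    }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a != b) parent[std::max(a, b)] = std::min(a, b);
    }
};

typedef unsigned __int128 key_t128;

// Emit all r-subsets of (sorted) clique `cl`, packed bits_per_id bits per
// node id, paired with the clique index; recursion depth r <= 10.
static void emit_subsets(const std::vector<int>& cl, int r, int bits,
                         int clique_idx, key_t128 prefix, int start,
                         std::vector<std::pair<key_t128, int> >& out) {
    if (r == 0) {
        out.push_back(std::make_pair(prefix, clique_idx));
        return;
    }
    int n = (int)cl.size();
    for (int i = start; i <= n - r; ++i) {
        emit_subsets(cl, r - 1, bits, clique_idx,
                     (prefix << bits) | (key_t128)cl[i], i + 1, out);
    }
}

// [[Rcpp::export(name = ".cpm_membership")]]
IntegerVector cpm_membership(List cliques, int k, int n_vertices,
                             double max_subsets = 2e8) {
    int nc = cliques.size();
    IntegerVector memb(nc);
    if (nc == 0) return memb;
    if (k < 2) stop("k must be >= 2");
    int r = k - 1;

    std::vector<std::vector<int> > cl(nc);
    double total_subsets = 0.0;
    for (int i = 0; i < nc; ++i) {
        IntegerVector v = cliques[i];
        cl[i].assign(v.begin(), v.end());
        std::sort(cl[i].begin(), cl[i].end());
        int s = (int)cl[i].size();
        if (s < k) stop("clique %d has size %d < k = %d", i + 1, s, k);
        double ch = 1.0;   // C(s, r)
        for (int t = 0; t < r; ++t) ch = ch * (s - t) / (t + 1);
        total_subsets += ch;
    }

    int bits = 1;
    while ((1LL << bits) <= (long long)n_vertices) ++bits;

    DSU dsu(nc);
    if ((long long)r * bits <= 120 && total_subsets <= max_subsets) {
        std::vector<std::pair<key_t128, int> > keys;
        keys.reserve((size_t)total_subsets);
        for (int i = 0; i < nc; ++i) {
            emit_subsets(cl[i], r, bits, i, (key_t128)0, 0, keys);
        }
        std::sort(keys.begin(), keys.end());
        for (size_t i = 1; i < keys.size(); ++i) {
            if (keys[i].first == keys[i - 1].first) {
                dsu.unite(keys[i].second, keys[i - 1].second);
            }
        }
    } else {
        // fallback for huge cliques or ids: pairwise sorted-overlap counts
        for (int i = 0; i < nc; ++i) {
            for (int j = i + 1; j < nc; ++j) {
                size_t a = 0, b = 0, shared = 0;
                while (a < cl[i].size() && b < cl[j].size()) {
                    if (cl[i][a] < cl[j][b]) ++a;
                    else if (cl[i][a] > cl[j][b]) ++b;
                    else { ++shared; ++a; ++b; }
                    if (shared >= (size_t)r) break;
                }
                if (shared >= (size_t)r) dsu.unite(i, j);
            }
        }
    }
    // relabel roots 1..n_components in first-appearance order
    std::vector<int> label(nc, 0);
    int next = 0;
    for (int i = 0; i < nc; ++i) {
        int root = dsu.find(i);
        if (label[root] == 0) label[root] = ++next;
        memb[i] = label[root];
    }
    return memb;
}
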