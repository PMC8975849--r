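#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Triangle preferential-attachment growth core.
//
// Starting from an initial edge list on nodes 1..l, each step adds one new
// node, selects m distinct existing edges (i, j) with probability
// proportional to k_i + k_j (degrees frozen at the step start), links the
// new node to both endpoints of every selected edge (duplicate endpoints
// collapse, so each selection closes a triangle), and finally inserts c
// random edges between non-adjacent *old* node pairs (redrawn on
// collision up to retry_cap, then skipped). Uses R's RNG so runs are
// reproducible under set.seed().

static inline uint64_t pair_key(int a, int b, uint64_t n) {
    if (a > b) std::swap(a, b);
    return (uint64_t)a * n + (uint64_t)b;
}

// [[Rcpp::export(name = ".grow_edges")]]
List grow_edges(IntegerVector src0, IntegerVector dst0, int l, int n_target,
                int m, int c, bool replace = false, int retry_cap = 200) {
    if (l < 2 || n_target < l) stop("need 2 <= l <= n_target");
    if (m < 1 || c < 0) stop("need m >= 1, c >= 0");

    const uint64_t keyn = (uint64_t)n_target + 2;
    std::vector<int> esrc(src0.begin(), src0.end());
    std::vector<int> edst(dst0.begin(), dst0.end());
    std::vector<int> deg(n_target + 1, 0);
    std::unordered_set<uint64_t> present;
    present.reserve((size_t)(n_target) * (2 * m + c) * 2 + 64);

    for (size_t e = 0; e < esrc.size(); ++e) {
        int a = esrc[e], b = edst[e];
        if (a < 1 || a > l || b < 1 || b > l || a == b)
            stop("invalid initial edge");
        uint64_t k = pair_key(a, b, keyn);
        if (present.count(k)) stop("duplicate initial edge");
        present.insert(k);
        deg[a]++; deg[b]++;
    }

    std::vector<double> cum;
    std::vector<int> chosen(m);

    for (int t = l + 1; t <= n_target; ++t) {
        size_t ne = esrc.size();
        if ((!replace && ne < (size_t)m) || ne == 0) {
            stop("growth step for node %d: only %d edges available, need m = %d",
                 t, (int)ne, m);
        }
        // cumulative attachment weights over edges, degrees at step start
        cum.resize(ne);
        double tot = 0.0;
        for (size_t e = 0; e < ne; ++e) {
            tot += (double)deg[esrc[e]] + (double)deg[edst[e]];
            cum[e] = tot;
        }
        int picked = 0;
        int guard = 0;
        while (picked < m) {
            double r = unif_rand() * tot;
            size_t lo = std::lower_bound(cum.begin(), cum.end(), r) - cum.begin();
            if (lo >= ne) lo = ne - 1;
            bool dup = false;
            if (!replace) {
                for (int q = 0; q < picked; ++q)
                    if (chosen[q] == (int)lo) { dup = true; break; }
            }
            if (dup) {
                if (++guard > 10000) {
                    // degenerate weight mass: fall back to first unchosen edge
                    for (size_t e = 0; e < ne; ++e) {
                        bool used = false;
                        for (int q = 0; q < picked; ++q)
                            if (chosen[q] == (int)e) { used = true; break; }
                        if (!used) { lo = e; dup = false; break; }
                    }
                    if (dup) stop("growth step for node %d: cannot pick %d distinct edges", t, m);
                } else continue;
            }
            chosen[picked++] = (int)lo;
        }
        // link the new node to every distinct endpoint of the chosen edges
        for (int q = 0; q < m; ++q) {
            int ids[2] = { esrc[chosen[q]], edst[chosen[q]] };
            for (int s = 0; s < 2; ++s) {
                uint64_t k = pair_key(ids[s], t, keyn);
                if (!present.count(k)) {
                    present.insert(k);
                    esrc.push_back(ids[s]);
                    edst.push_back(t);
                    deg[ids[s]]++; deg[t]++;
                }
            }
        }
        // c random edges between non-adjacent old nodes (1..t-1)
        int n_old = t - 1;
        if (n_old >= 2) {
            for (int q = 0; q < c; ++q) {
                for (int tries = 0; tries < retry_cap; ++tries) {
                    int a = (int)(unif_rand() * n_old) + 1;
                    int b = (int)(unif_rand() * n_old) + 1;
                    if (a > n_old) a = n_old;
                    if (b > n_old) b = n_old;
                    if (a == b) continue;
                    uint64_t k = pair_key(a, b, keyn);
                    if (present.count(k)) continue;
                    present.insert(k);
                    esrc.push_back(std::min(a, b));
                    edst.push_back(std::max(a, b));
                    deg[a]++; deg[b]++;
                    break;
                }
            }
        }
    }
    return List::create(_["src"] = wrap(esrc), _["dst"] = wrap(edst));
}
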