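#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <functional>
#include <limits>

using namespace Rcpp;

// Node-weighted Steiner-tree heuristic (spider merging with 0/1 node
// weights: seeds cost 0, non-seeds cost 1).
//
// Nodes must be passed in lexicographic symbol order (index order == tie
// order). Adjacency is CSR: adjStart (n+1, 0-based offsets into adjList),
// adjList neighbor indices sorted ascending within each node.
//
// Each round scans every candidate center v: a BFS from v assigns every
// node its hop distance, and among equal-hop predecessors the path that
// minimizes the number of new non-seed interior nodes (tie: smallest
// predecessor index). The spider ratio for v and a prefix S of components
// (sorted by path cost, then component id) is
//   (w(v) + sum of path costs to each component in S) / |S|,
// with w(v)=1 iff v is a non-seed not already inside a component. The
// globally cheapest spider (ties: smaller center index; within a center,
// the larger component set) is merged; components touched by a used path
// are absorbed. Merging stops when the best ratio exceeds `cap`.
//
// Returns the final component id per node (-1 = never selected).
// [[Rcpp::export(name = ".kr_steiner")]]
IntegerVector kr_steiner(int n, IntegerVector adjStart, IntegerVector adjList,
                         LogicalVector isSeed, double cap) {
    const int INF = std::numeric_limits<int>::max() / 4;
    std::vector<int> comp(n, -1);
    std::vector<char> active(n, 0);
    int nActive = 0;
    for (int i = 0; i < n; ++i)
        if (isSeed[i]) { comp[i] = i; active[i] = 1; ++nActive; }

    std::vector<int> dist(n), cost(n), parent(n), order;
    order.reserve(n);
    std::vector<int> minCost(n), argMin(n);

    // union-find over component ids, for free (ratio-0) merges
    std::vector<int> uf(n);
    std::function<int(int)> find = [&](int a) {
        while (uf[a] != a) { uf[a] = uf[uf[a]]; a = uf[a]; }
        return a;
    };

    while (nActive >= 2) {
        // collapse all ratio-0 merges at once: components joined by an
        // edge between already-selected nodes recruit nothing, so the
        // greedy order among them cannot change the final node set
        for (int i = 0; i < n; ++i) uf[i] = i;
        bool any0 = false;
        for (int x = 0; x < n; ++x) {
            if (comp[x] < 0) continue;
            for (int e = adjStart[x]; e < adjStart[x + 1]; ++e) {
                int y = adjList[e];
                if (y < x || comp[y] < 0) continue;
                int ra = find(comp[x]), rb = find(comp[y]);
                if (ra != rb) { uf[std::max(ra, rb)] = std::min(ra, rb); any0 = true; }
            }
        }
        if (any0) {
            for (int c = 0; c < n; ++c) {
                if (!active[c]) continue;
                int r = find(c);
                if (r != c) { active[c] = 0; --nActive; active[r] = 1; }
            }
            for (int x = 0; x < n; ++x)
                if (comp[x] >= 0) comp[x] = find(comp[x]);
            if (nActive < 2) break;
        }
        long long bestNum = -1;   // numerator of best ratio
        int bestT = 0;            // denominator (#components merged)
        int bestV = -1;
        std::vector<int> bestMergeNodes;   // center + path nodes
        std::vector<int> bestCompIds;

        for (int v = 0; v < n; ++v) {
            // BFS with per-level min-cost path DP
            std::fill(dist.begin(), dist.end(), -1);
            order.clear();
            dist[v] = 0; cost[v] = 0; parent[v] = -1;
            order.push_back(v);
            for (size_t qi = 0; qi < order.size(); ++qi) {
                int x = order[qi];
                for (int e = adjStart[x]; e < adjStart[x + 1]; ++e) {
                    int y = adjList[e];
                    if (dist[y] == -1) {
                        dist[y] = dist[x] + 1;
                        int w = (!isSeed[y] && comp[y] < 0) ? 1 : 0;
                        cost[y] = cost[x] + w;
                        parent[y] = x;
                        order.push_back(y);
                    } else if (dist[y] == dist[x] + 1) {
                        int w = (!isSeed[y] && comp[y] < 0) ? 1 : 0;
                        int c = cost[x] + w;
                        if (c < cost[y] ||
                            (c == cost[y] && x < parent[y])) {
                            cost[y] = c;
                            parent[y] = x;
                        }
                    }
                }
            }
            // NOTE: the improvement step above can lower cost[x] after some
            // of x's successors were relaxed; re-run a cleanup pass in BFS
            // order until stable (levels are short; this converges fast).
            bool changed = true;
            while (changed) {
                changed = false;
                for (size_t qi = 1; qi < order.size(); ++qi) {
                    int y = order[qi];
                    int w = (!isSeed[y] && comp[y] < 0) ? 1 : 0;
                    for (int e = adjStart[y]; e < adjStart[y + 1]; ++e) {
                        int x = adjList[e];
                        if (dist[x] != dist[y] - 1) continue;
                        int c = cost[x] + w;
                        if (c < cost[y] || (c == cost[y] && x < parent[y])) {
                            cost[y] = c; parent[y] = x; changed = true;
                        }
                    }
                }
            }

            // cheapest reachable member of each active component
            for (int c = 0; c < n; ++c) { minCost[c] = INF; argMin[c] = -1; }
            for (size_t qi = 0; qi < order.size(); ++qi) {
                int x = order[qi];
                int c = comp[x];
                if (c < 0) continue;
                if (cost[x] < minCost[c] ||
                    (cost[x] == minCost[c] && x < argMin[c])) {
                    minCost[c] = cost[x];
                    argMin[c] = x;
                }
            }
            std::vector<std::pair<int, int> > reach;  // (cost, compId)
            for (int c = 0; c < n; ++c)
                if (active[c] && minCost[c] < INF)
                    reach.push_back(std::make_pair(minCost[c], c));
            if (reach.size() < 2) continue;
            std::sort(reach.begin(), reach.end());

            int wv = (!isSeed[v] && comp[v] < 0) ? 1 : 0;
            long long cum = wv;
            long long vNum = -1; int vT = 0;
            for (size_t t = 1; t <= reach.size(); ++t) {
                cum += reach[t - 1].first;
                if (t < 2) continue;
                if (vT == 0 || cum * vT < vNum * (long long)t ||
                    (cum * vT == vNum * (long long)t && (int)t > vT)) {
                    vNum = cum; vT = (int)t;
                }
            }
            if (vT == 0) continue;
            bool better = (bestV < 0) ||
                          (vNum * bestT < bestNum * (long long)vT);
            if (better) {
                bestNum = vNum; bestT = vT; bestV = v;
                bestCompIds.assign(bestT, -1);
                bestMergeNodes.clear();
                bestMergeNodes.push_back(v);
                for (int t = 0; t < bestT; ++t) {
                    int c = reach[t].second;
                    bestCompIds[t] = c;
                    for (int x = argMin[c]; x != -1; x = parent[x])
                        bestMergeNodes.push_back(x);
                }
                if (bestNum == 0) break;   // ratio 0: no center can beat it
            }
        }

        if (bestV < 0) break;   // nothing mergeable (disconnected seeds)
        if (cap < std::numeric_limits<double>::infinity() &&
            (double)bestNum > cap * (double)bestT)
            break;              // cheapest merge exceeds the cost cap

        // execute merge: new nodes + merged components + absorbed components
        std::vector<char> absorb(n, 0);
        for (size_t i = 0; i < bestCompIds.size(); ++i)
            absorb[bestCompIds[i]] = 1;
        int newId = bestCompIds[0];
        for (size_t i = 0; i < bestMergeNodes.size(); ++i) {
            int x = bestMergeNodes[i];
            if (comp[x] >= 0) absorb[comp[x]] = 1;
        }
        for (int c = 0; c < n; ++c)
            if (absorb[c] && c < newId) newId = c;
        int removed = 0;
        for (int c = 0; c < n; ++c)
            if (active[c] && absorb[c] && c != newId) { active[c] = 0; ++removed; }
        nActive -= removed;
        for (int x = 0; x < n; ++x)
            if (comp[x] >= 0 && absorb[comp[x]]) comp[x] = newId;
        for (size_t i = 0; i < bestMergeNodes.size(); ++i)
            comp[bestMergeNodes[i]] = newId;
        active[newId] = 1;
    }

    return IntegerVector(comp.begin(), comp.end());
}
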