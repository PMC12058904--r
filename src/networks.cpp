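// Enumeration of rooted binary phylogenetic trees by sequential leaf
// insertion, k-fold decoration (paired subdivision points + arcs),
// classification of the resulting directed graphs, sound canonical codes for
// leaf-labeled DAGs, and the exhaustive census pipeline.
//
// Vertex numbering convention used throughout (1-based, matching the R side):
//   1..n        leaves, leaf i carries label i
//   n+1         root (in-degree 0, out-degree 1; top of the ancestral root edge)
//   n+2..2n     internal tree vertices
//   2n+1..2n+2k subdivision vertices; pair i has source 2n+2i-1, target 2n+2i
#include <Rcpp.h>
#include "bigint.h"
#include <map>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<int> vi;

// class labels (order matters: >= LBL_NORMAL means normal network)
enum Label { LBL_CYCLIC = 0, LBL_NOT_TREE_CHILD = 1, LBL_SHORTCUT = 2,
             LBL_NORMAL_NOT_HYB = 3, LBL_HYBRIDIZATION = 4 };

struct ClassifyOut {
    bool acyclic;
    bool tree_child;
    bool has_shortcut;
    bool temporal_ok;
    int label;
};

// flat child adjacency: off[v]..off[v+1]-1 index into lst (edge indices)
static void build_adj(int nv, const vi &eu, vi &off, vi &lst) {
    int m = static_cast<int>(eu.size());
    off.assign(nv + 2, 0);
    for (int e = 0; e < m; ++e) off[eu[e] + 1]++;
    for (int v = 1; v <= nv; ++v) off[v + 1] += off[v];
    lst.assign(m, 0);
    vi pos(off.begin(), off.end());
    for (int e = 0; e < m; ++e) lst[pos[eu[e]]++] = e;
}

static int uf_find(vi &p, int x) {
    while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; }
    return x;
}

// Full classification. shortcut_edges (0-based edge indices) collected when
// non-null; dates[v] filled when non-null and a temporal ranking exists.
static ClassifyOut classify_core(int nv, const vi &eu, const vi &ev,
                                 vi *shortcut_edges, vi *dates) {
    int m = static_cast<int>(eu.size());
    ClassifyOut out;
    out.acyclic = out.tree_child = out.temporal_ok = false;
    out.has_shortcut = false;
    out.label = LBL_CYCLIC;

    vi indeg(nv + 1, 0), outdeg(nv + 1, 0);
    for (int e = 0; e < m; ++e) { outdeg[eu[e]]++; indeg[ev[e]]++; }

    vi off, lst;
    build_adj(nv, eu, off, lst);

    // Kahn topological order
    vi order;
    order.reserve(nv);
    {
        vi deg = indeg, stack;
        for (int v = 1; v <= nv; ++v)
            if (deg[v] == 0) stack.push_back(v);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            order.push_back(v);
            for (int i = off[v]; i < off[v + 1]; ++i) {
                int w = ev[lst[i]];
                if (--deg[w] == 0) stack.push_back(w);
            }
        }
    }
    if (static_cast<int>(order.size()) != nv) return out; // cyclic
    out.acyclic = true;

    // tree-child: every non-leaf vertex has a child that is not a reticulation
    out.tree_child = true;
    for (int v = 1; v <= nv && out.tree_child; ++v) {
        if (outdeg[v] == 0) continue;
        bool good = false;
        for (int i = off[v]; i < off[v + 1]; ++i)
            if (indeg[ev[lst[i]]] <= 1) { good = true; break; }
        if (!good) out.tree_child = false;
    }

    // strict-descendant bitsets in reverse topological order
    int W = (nv + 64) / 64;
    std::vector<uint64_t> reach(static_cast<size_t>(nv + 1) * W, 0);
    for (int idx = nv - 1; idx >= 0; --idx) {
        int v = order[idx];
        uint64_t *rv = &reach[static_cast<size_t>(v) * W];
        for (int i = off[v]; i < off[v + 1]; ++i) {
            int c = ev[lst[i]];
            const uint64_t *rc = &reach[static_cast<size_t>(c) * W];
            for (int w = 0; w < W; ++w) rv[w] |= rc[w];
            rv[(c - 1) / 64] |= (1ull << ((c - 1) % 64));
        }
    }

    // shortcut: edge (u,v) with another directed u->v path (parallel edges count)
    for (int v = 1; v <= nv; ++v) {
        if (outdeg[v] < 2) continue;
        for (int i = off[v]; i < off[v + 1]; ++i) {
            int e = lst[i], tgt = ev[e];
            for (int j = off[v]; j < off[v + 1]; ++j) {
                if (j == i) continue;
                int w = ev[lst[j]];
                bool hits = (w == tgt) ||
                    ((reach[static_cast<size_t>(w) * W + (tgt - 1) / 64] >>
                      ((tgt - 1) % 64)) & 1ull);
                if (hits) {
                    out.has_shortcut = true;
                    if (shortcut_edges) shortcut_edges->push_back(e);
                    break;
                }
            }
            if (out.has_shortcut && !shortcut_edges) break;
        }
        if (out.has_shortcut && !shortcut_edges) break;
    }

    // temporal ranking: merge each reticulation with both parents, then the
    // quotient over tree edges must be strictly orderable (a DAG with no
    // tree edge inside a class)
    {
        vi uf(nv + 1);
        for (int v = 1; v <= nv; ++v) uf[v] = v;
        for (int e = 0; e < m; ++e) {
            if (indeg[ev[e]] >= 2) {
                int a = uf_find(uf, eu[e]), b = uf_find(uf, ev[e]);
                if (a != b) uf[a] = b;
            }
        }
        bool ok = true;
        for (int e = 0; e < m && ok; ++e) {
            if (indeg[ev[e]] <= 1 &&
                uf_find(uf, eu[e]) == uf_find(uf, ev[e])) ok = false;
        }
        if (ok) {
            // dense class ids
            vi cid(nv + 1, -1), minv;
            int C = 0;
            for (int v = 1; v <= nv; ++v) {
                int r = uf_find(uf, v);
                if (cid[r] < 0) { cid[r] = C++; minv.push_back(v); }
            }
            vi qdeg(C, 0);
            std::vector<std::pair<int, int>> qe;
            for (int e = 0; e < m; ++e) {
                if (indeg[ev[e]] <= 1) {
                    int a = cid[uf_find(uf, eu[e])], b = cid[uf_find(uf, ev[e])];
                    qe.push_back(std::make_pair(a, b));
                    qdeg[b]++;
                }
            }
            if (!dates) {
                // existence only: plain Kahn on the quotient (flat adjacency)
                vi qoff(C + 2, 0), qlst(qe.size());
                for (size_t i = 0; i < qe.size(); ++i) qoff[qe[i].first + 1]++;
                for (int c = 0; c < C; ++c) qoff[c + 1] += qoff[c];
                vi pos(qoff.begin(), qoff.end());
                for (size_t i = 0; i < qe.size(); ++i)
                    qlst[pos[qe[i].first]++] = qe[i].second;
                vi deg = qdeg, stack;
                int done = 0;
                for (int c = 0; c < C; ++c) if (deg[c] == 0) stack.push_back(c);
                while (!stack.empty()) {
                    int c = stack.back();
                    stack.pop_back();
                    ++done;
                    for (int i = qoff[c]; i < qoff[c + 1]; ++i)
                        if (--deg[qlst[i]] == 0) stack.push_back(qlst[i]);
                }
                out.temporal_ok = (done == C);
            } else {
                // deterministic dates: smallest representative vertex first
                vi date(C, -1);
                int done = 0;
                while (done < C) {
                    int pick = -1;
                    for (int c = 0; c < C; ++c)
                        if (date[c] < 0 && qdeg[c] == 0 &&
                            (pick < 0 || minv[c] < minv[pick])) pick = c;
                    if (pick < 0) break; // quotient cyclic
                    date[pick] = done++;
                    for (size_t i = 0; i < qe.size(); ++i)
                        if (qe[i].first == pick) qdeg[qe[i].second]--;
                }
                if (done == C) {
                    out.temporal_ok = true;
                    dates->assign(nv + 1, -1);
                    for (int v = 1; v <= nv; ++v)
                        (*dates)[v] = date[cid[uf_find(uf, v)]];
                }
            }
        }
    }

    if (!out.tree_child) out.label = LBL_NOT_TREE_CHILD;
    else if (out.has_shortcut) out.label = LBL_SHORTCUT;
    else out.label = out.temporal_ok ? LBL_HYBRIDIZATION : LBL_NORMAL_NOT_HYB;
    return out;
}

// ------------------------------------------------------------- canonical code

// Colour refinement + individualization with full backtracking; the code is
// the lexicographic minimum over all individualization branches, so equal
// codes certify a label-preserving isomorphism and vice versa.
struct Canon {
    int nv, n;
    bool labeled;
    const vi *eu, *ev, *ecol;
    vi outdeg;
    std::string best;
    bool has_best;

    std::string run(int nv_, int n_, const vi &eu_, const vi &ev_,
                    const vi &ecol_, bool labeled_) {
        nv = nv_; n = n_; eu = &eu_; ev = &ev_; ecol = &ecol_; labeled = labeled_;
        outdeg.assign(nv + 1, 0);
        for (size_t e = 0; e < eu_.size(); ++e) outdeg[eu_[e]]++;
        vi col(nv + 1, 0);
        for (int v = 1; v <= nv; ++v) {
            if (outdeg[v] == 0) col[v] = labeled ? v : 0;
            else col[v] = n + 1;
        }
        has_best = false;
        rec(col);
        return best;
    }

    void refine(vi &col) {
        int m = static_cast<int>(eu->size());
        int ncol_prev = -1;
        for (;;) {
            std::vector<std::vector<long long>> sig(nv + 1);
            for (int v = 1; v <= nv; ++v) sig[v].push_back(col[v]);
            for (int e = 0; e < m; ++e) {
                int u = (*eu)[e], v = (*ev)[e], c = (*ecol)[e];
                sig[u].push_back(((long long)(2 * c + 2) << 32) | (uint32_t)(col[v] + 1));
                sig[v].push_back(((long long)(2 * c + 3) << 32) | (uint32_t)(col[u] + 1));
            }
            for (int v = 1; v <= nv; ++v)
                std::sort(sig[v].begin() + 1, sig[v].end());
            // rank distinct signatures
            std::vector<int> idx(nv);
            for (int v = 0; v < nv; ++v) idx[v] = v + 1;
            std::sort(idx.begin(), idx.end(), [&](int a, int b) {
                return sig[a] < sig[b];
            });
            int ncol = 0;
            vi newcol(nv + 1, 0);
            for (int i = 0; i < nv; ++i) {
                if (i > 0 && sig[idx[i]] != sig[idx[i - 1]]) ++ncol;
                newcol[idx[i]] = ncol;
            }
            ++ncol;
            col = newcol;
            if (ncol == ncol_prev) return;
            ncol_prev = ncol;
            if (ncol == nv) return;
        }
    }

    void rec(vi col) {
        refine(col);
        // find smallest non-singleton colour class
        std::map<int, vi> classes;
        for (int v = 1; v <= nv; ++v) classes[col[v]].push_back(v);
        int target = -1;
        for (std::map<int, vi>::const_iterator it = classes.begin();
             it != classes.end(); ++it) {
            if (it->second.size() > 1) { target = it->first; break; }
        }
        if (target < 0) { // discrete
            std::string s = emit(col);
            if (!has_best || s < best) { best = s; has_best = true; }
            return;
        }
        const vi &cell = classes[target];
        for (size_t i = 0; i < cell.size(); ++i) {
            vi col2 = col;
            col2[cell[i]] = -1; // individualize: unique smallest colour
            rec(col2);
        }
    }

    std::string emit(const vi &col) {
        // colours are distinct; normalize to ranks 0..nv-1
        vi byrank(nv), rank(nv + 1, 0), cols;
        cols.reserve(nv);
        for (int v = 1; v <= nv; ++v) cols.push_back(col[v]);
        std::sort(cols.begin(), cols.end());
        for (int v = 1; v <= nv; ++v) {
            int r = static_cast<int>(std::lower_bound(cols.begin(), cols.end(),
                                                      col[v]) - cols.begin());
            rank[v] = r;
            byrank[r] = v;
        }
        std::string s;
        s.reserve(static_cast<size_t>(nv) * 4 + eu->size() * 8);
        for (int r = 0; r < nv; ++r) {
            int v = byrank[r];
            if (outdeg[v] == 0) {
                s += 'L';
                if (labeled) s += std::to_string(v);
            } else s += 'I';
            s += ',';
        }
        s += '|';
        std::vector<std::vector<int>> edges;
        for (size_t e = 0; e < eu->size(); ++e) {
            std::vector<int> t(3);
            t[0] = rank[(*eu)[e]];
            t[1] = rank[(*ev)[e]];
            t[2] = (*ecol)[e];
            edges.push_back(t);
        }
        std::sort(edges.begin(), edges.end());
        for (size_t e = 0; e < edges.size(); ++e) {
            s += std::to_string(edges[e][0]);
            s += '>';
            s += std::to_string(edges[e][1]);
            s += ':';
            s += std::to_string(edges[e][2]);
            s += ';';
        }
        return s;
    }
};

static std::string canon_uniform(int nv, int n, const vi &eu, const vi &ev,
                                 bool labeled) {
    vi ecol(eu.size(), 0);
    Canon c;
    return c.run(nv, n, eu, ev, ecol, labeled);
}

// ------------------------------------------------- induced subdivision tree

// Induced subdivision tree of a decorated tree: the minimal subtree of T_k
// spanning the marked (subdivision) vertices, with pass-through degree-2
// vertices of T suppressed, so its vertices are the marked vertices plus the
// branch points (cf. the non-subdivision vertices of the subtree). Computes
// ell (marked vertices that are not leaves of this subtree) and the number
// of edges of the suppressed topology.
static void steiner_ell(int nv, int root, const vi &eu, const vi &ev,
                        const vi &marked, int &ell, int &steiner_edges) {
    vi off, lst;
    build_adj(nv, eu, off, lst);
    vi cnt(nv + 1, 0), stack, ord;
    // DFS discovery order; children appear after their parent, so a reverse
    // sweep accumulates subtree counts bottom-up
    stack.push_back(root);
    ord.reserve(nv);
    while (!stack.empty()) {
        int v = stack.back();
        stack.pop_back();
        ord.push_back(v);
        for (int i = off[v]; i < off[v + 1]; ++i) stack.push_back(ev[lst[i]]);
    }
    int total = 0;
    vi is_marked(nv + 1, 0);
    for (size_t i = 0; i < marked.size(); ++i) {
        cnt[marked[i]] = 1;
        is_marked[marked[i]] = 1;
        ++total;
    }
    for (size_t i = ord.size(); i-- > 0;) {
        int v = ord[i];
        for (int j = off[v]; j < off[v + 1]; ++j) cnt[v] += cnt[ev[lst[j]]];
    }
    ell = 0;
    for (size_t i = 0; i < marked.size(); ++i)
        if (cnt[marked[i]] >= 2) ++ell;
    // deepest vertex covering all marked = root of the induced subtree
    int rstar = root;
    for (;;) {
        int next = -1;
        for (int i = off[rstar]; i < off[rstar + 1]; ++i)
            if (cnt[ev[lst[i]]] == total) { next = ev[lst[i]]; break; }
        if (next < 0) break;
        rstar = next;
    }
    // topology vertices: all marked, plus unmarked Steiner vertices with
    // >= 2 children leading to marked vertices (branch points; rstar is the
    // only one that may carry cnt == total)
    int tverts = static_cast<int>(marked.size());
    for (int v = 1; v <= nv; ++v) {
        if (is_marked[v]) continue;
        bool in_steiner = (cnt[v] >= 1 && cnt[v] <= total - 1) || v == rstar;
        if (!in_steiner) continue;
        int nch = 0;
        for (int i = off[v]; i < off[v + 1]; ++i)
            if (cnt[ev[lst[i]]] >= 1) ++nch;
        if (nch >= 2) ++tverts;
    }
    steiner_edges = tverts - 1;
}

// --------------------------------------------------------------- census

struct CensusEngine {
    int n, k;
    bool want_reps;
    vi eu, ev;
    long long raw_label[5];
    std::vector<long long> raw_by_ell;
    long long raw_total, cyclic_ell0;
    std::map<std::string, int> normal_idx; // code -> rep index
    std::vector<IntegerMatrix> reps;
    std::vector<bool> rep_hyb;
    Canon canon;

    void run() {
        for (int i = 0; i < 5; ++i) raw_label[i] = 0;
        raw_by_ell.assign(std::max(0, 2 * k), 0);
        raw_total = 0;
        cyclic_ell0 = 0;
        eu.clear(); ev.clear();
        eu.push_back(n + 1); ev.push_back(1);
        insert_leaf(1);
    }

    void insert_leaf(int placed) {
        if (placed == n) { place_point(0); return; }
        int leaf = placed + 1, w = n + 1 + placed;
        int m = static_cast<int>(eu.size());
        for (int i = 0; i < m; ++i) {
            int ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
            eu.push_back(w); ev.push_back(leaf);
            insert_leaf(placed + 1);
            eu.pop_back(); ev.pop_back();
            eu.pop_back(); ev.pop_back();
            ev[i] = ov;
        }
    }

    void place_point(int idx) {
        if (idx == 2 * k) { finish(); return; }
        int w = 2 * n + idx + 1;
        int m = static_cast<int>(eu.size());
        for (int i = 0; i < m; ++i) {
            int ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
            place_point(idx + 1);
            eu.pop_back(); ev.pop_back();
            ev[i] = ov;
        }
    }

    void finish() {
        ++raw_total;
        int nv = 2 * n + 2 * k;
        int ell = 0;
        if (k >= 1) {
            vi marked;
            for (int i = 1; i <= 2 * k; ++i) marked.push_back(2 * n + i);
            int sed = 0;
            steiner_ell(nv, n + 1, eu, ev, marked, ell, sed);
            if (sed != 4 * k - 2 - ell)
                stop("internal error: induced subdivision tree edge identity violated");
        }
        // add arcs
        for (int i = 1; i <= k; ++i) {
            eu.push_back(2 * n + 2 * i - 1);
            ev.push_back(2 * n + 2 * i);
        }
        ClassifyOut c = classify_core(nv, eu, ev, NULL, NULL);
        raw_label[c.label]++;
        if (k >= 1) {
            raw_by_ell[ell]++;
            if (c.label == LBL_CYCLIC && ell == 0) ++cyclic_ell0;
        }
        if (c.label >= LBL_NORMAL_NOT_HYB) {
            std::string code = canon_uniform(nv, n, eu, ev, true);
            std::map<std::string, int>::iterator it = normal_idx.find(code);
            bool hyb = (c.label == LBL_HYBRIDIZATION);
            if (it == normal_idx.end()) {
                int idx = static_cast<int>(reps.size());
                normal_idx[code] = idx;
                int m = static_cast<int>(eu.size());
                IntegerMatrix mat(m, 2);
                for (int e = 0; e < m; ++e) { mat(e, 0) = eu[e]; mat(e, 1) = ev[e]; }
                reps.push_back(mat);
                rep_hyb.push_back(hyb);
            } else if (rep_hyb[it->second] != hyb) {
                stop("internal error: inconsistent hybridization status for one canonical code");
            }
        }
        for (int i = 0; i < k; ++i) { eu.pop_back(); ev.pop_back(); }
    }
};

} // namespace

// [[Rcpp::export]]
List cpp_census(int n, int k, bool want_shapes, bool want_reps) {
    if (n < 1 || k < 0) stop("need n >= 1, k >= 0");
    CensusEngine eng;
    eng.n = n; eng.k = k; eng.want_reps = want_reps;
    eng.run();

    long long kf = 1;
    for (int i = 2; i <= k; ++i) kf *= i;
    NumericVector counts(5);
    CharacterVector lbl = CharacterVector::create(
        "cyclic", "not_tree_child", "shortcut", "normal_not_hyb", "hybridization");
    for (int i = 0; i < 5; ++i) {
        if (eng.raw_label[i] % kf != 0)
            stop("internal error: class tally not divisible by k!");
        counts[i] = static_cast<double>(eng.raw_label[i] / kf);
    }
    counts.attr("names") = lbl;
    NumericVector by_ell(std::max(0, 2 * k));
    for (int i = 0; i < 2 * k; ++i) {
        if (eng.raw_by_ell[i] % kf != 0)
            stop("internal error: ell tally not divisible by k!");
        by_ell[i] = static_cast<double>(eng.raw_by_ell[i] / kf);
    }

    int n_normal = static_cast<int>(eng.reps.size());
    int n_hyb = 0;
    for (int i = 0; i < n_normal; ++i) if (eng.rep_hyb[i]) ++n_hyb;

    IntegerVector shape_sizes;
    int n_shapes = NA_INTEGER;
    if (want_shapes) {
        std::map<std::string, int> shapes;
        for (int i = 0; i < n_normal; ++i) {
            IntegerMatrix mat = eng.reps[i];
            vi eu(mat.nrow()), ev(mat.nrow());
            for (int e = 0; e < mat.nrow(); ++e) { eu[e] = mat(e, 0); ev[e] = mat(e, 1); }
            std::string sc = canon_uniform(2 * n + 2 * k, n, eu, ev, false);
            shapes[sc]++;
        }
        std::vector<int> sz;
        for (std::map<std::string, int>::iterator it = shapes.begin();
             it != shapes.end(); ++it) sz.push_back(it->second);
        std::sort(sz.begin(), sz.end(), std::greater<int>());
        shape_sizes = wrap(sz);
        n_shapes = static_cast<int>(sz.size());
    }

    List reps_out = R_NilValue;
    LogicalVector hyb_out;
    if (want_reps) {
        List rl(n_normal);
        hyb_out = LogicalVector(n_normal);
        for (int i = 0; i < n_normal; ++i) {
            rl[i] = eng.reps[i];
            hyb_out[i] = eng.rep_hyb[i];
        }
        reps_out = rl;
    }

    return List::create(
        _["n"] = n, _["k"] = k,
        _["total"] = static_cast<double>(eng.raw_total / kf),
        _["raw_total"] = static_cast<double>(eng.raw_total),
        _["counts"] = counts,
        _["by_ell"] = by_ell,
        _["cyclic_ell0"] = static_cast<double>(eng.cyclic_ell0),
        _["distinct_normal"] = n_normal,
        _["distinct_hyb"] = n_hyb,
        _["n_shapes"] = n_shapes,
        _["shape_sizes"] = shape_sizes,
        _["reps"] = reps_out,
        _["rep_is_hyb"] = hyb_out);
}

// ------------------------------------------------------- small exported ops

static void edges_from_matrix(IntegerMatrix m, vi &eu, vi &ev) {
    int r = m.nrow();
    eu.assign(r, 0); ev.assign(r, 0);
    for (int e = 0; e < r; ++e) { eu[e] = m(e, 0); ev[e] = m(e, 1); }
}

// [[Rcpp::export]]
List cpp_classify(IntegerMatrix edges, int nv, bool want_dates) {
    vi eu, ev;
    edges_from_matrix(edges, eu, ev);
    vi sc, dates;
    ClassifyOut c = classify_core(nv, eu, ev, &sc, want_dates ? &dates : NULL);
    CharacterVector lbl = CharacterVector::create(
        "cyclic", "not_tree_child", "shortcut", "normal_not_hyb", "hybridization");
    IntegerVector scv(sc.size());
    for (size_t i = 0; i < sc.size(); ++i) scv[i] = sc[i] + 1; // 1-based rows
    SEXP dv = R_NilValue;
    if (want_dates && c.temporal_ok) {
        IntegerVector d(nv);
        for (int v = 1; v <= nv; ++v) d[v - 1] = dates[v];
        dv = d;
    }
    return List::create(
        _["label"] = as<std::string>(lbl[c.label]),
        _["acyclic"] = c.acyclic,
        _["tree_child"] = c.tree_child,
        _["has_shortcut"] = c.has_shortcut,
        _["shortcut_edges"] = scv,
        _["temporal_ok"] = c.temporal_ok,
        _["dates"] = dv);
}

// [[Rcpp::export]]
String cpp_canonical_code(IntegerMatrix edges, int nv, int n, bool labeled) {
    vi eu, ev;
    edges_from_matrix(edges, eu, ev);
    return canon_uniform(nv, n, eu, ev, labeled);
}

// decoration code: tree edges colour 0, arcs colour 1 (pair ids anonymous,
// roles encoded by arc direction)
// [[Rcpp::export]]
String cpp_decoration_code(IntegerMatrix tk_edges, IntegerMatrix pairs,
                           int nv, int n) {
    vi eu, ev;
    edges_from_matrix(tk_edges, eu, ev);
    vi ecol(eu.size(), 0);
    for (int i = 0; i < pairs.nrow(); ++i) {
        eu.push_back(pairs(i, 0));
        ev.push_back(pairs(i, 1));
        ecol.push_back(1);
    }
    Canon c;
    return c.run(nv, n, eu, ev, ecol, true);
}

// [[Rcpp::export]]
List cpp_steiner(IntegerMatrix tk_edges, IntegerVector marked, int nv, int root) {
    vi eu, ev, mk;
    edges_from_matrix(tk_edges, eu, ev);
    for (int i = 0; i < marked.size(); ++i) mk.push_back(marked[i]);
    int ell = 0, sed = 0;
    steiner_ell(nv, root, eu, ev, mk, ell, sed);
    return List::create(_["ell"] = ell, _["steiner_edges"] = sed);
}

// ------------------------------------------------------- tree enumeration

namespace {
struct TreeEnum {
    int n;
    vi eu, ev;
    List out;
    int cnt;

    void rec(int placed) {
        if (placed == n) {
            int m = static_cast<int>(eu.size());
            IntegerMatrix mat(m, 2);
            for (int e = 0; e < m; ++e) { mat(e, 0) = eu[e]; mat(e, 1) = ev[e]; }
            out[cnt++] = mat;
            return;
        }
        int leaf = placed + 1, w = n + 1 + placed;
        int m = static_cast<int>(eu.size());
        for (int i = 0; i < m; ++i) {
            int ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
            eu.push_back(w); ev.push_back(leaf);
            rec(placed + 1);
            eu.pop_back(); ev.pop_back();
            eu.pop_back(); ev.pop_back();
            ev[i] = ov;
        }
    }
};
} // namespace

// [[Rcpp::export]]
List cpp_enumerate_trees(int n) {
    if (n < 1) stop("n must be >= 1");
    // r_n trees
    double rn = 1;
    for (int j = 2; j <= n; ++j) rn *= (2 * j - 3);
    TreeEnum te;
    te.n = n;
    te.out = List(static_cast<int>(rn));
    te.cnt = 0;
    te.eu.push_back(n + 1);
    te.ev.push_back(1);
    te.rec(1);
    return te.out;
}

// ---------------------------------------------- decoration enumeration (R level)

namespace {
struct DecEnum {
    int n, k, nv;
    vi eu, ev;
    std::map<std::string, List> seen;
    long long raw;
    Canon canon;

    void rec(int idx) {
        if (idx == 2 * k) {
            ++raw;
            int m = static_cast<int>(eu.size());
            IntegerMatrix mat(m, 2);
            for (int e = 0; e < m; ++e) { mat(e, 0) = eu[e]; mat(e, 1) = ev[e]; }
            IntegerMatrix pr(k, 2);
            for (int i = 1; i <= k; ++i) {
                pr(i - 1, 0) = 2 * n + 2 * i - 1;
                pr(i - 1, 1) = 2 * n + 2 * i;
            }
            vi ecol(eu.size(), 0), aeu = eu, aev = ev;
            for (int i = 1; i <= k; ++i) {
                aeu.push_back(2 * n + 2 * i - 1);
                aev.push_back(2 * n + 2 * i);
                ecol.push_back(1);
            }
            std::string code = canon.run(nv, n, aeu, aev, ecol, true);
            if (seen.find(code) == seen.end())
                seen[code] = List::create(_["tk_edges"] = mat, _["pairs"] = pr,
                                          _["code"] = code);
            return;
        }
        int w = 2 * n + idx + 1;
        int m = static_cast<int>(eu.size());
        for (int i = 0; i < m; ++i) {
            int ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
            rec(idx + 1);
            eu.pop_back(); ev.pop_back();
            ev[i] = ov;
        }
    }
};
} // namespace

// [[Rcpp::export]]
List cpp_enumerate_decorations(IntegerMatrix tree_edges, int n, int k) {
    if (k < 0) stop("k must be >= 0");
    DecEnum de;
    de.n = n; de.k = k; de.nv = 2 * n + 2 * k;
    edges_from_matrix(tree_edges, de.eu, de.ev);
    de.raw = 0;
    de.rec(0);
    List out(de.seen.size());
    int i = 0;
    for (std::map<std::string, List>::iterator it = de.seen.begin();
         it != de.seen.end(); ++it) out[i++] = it->second;
    return List::create(_["decorations"] = out,
                        _["raw_sequences"] = static_cast<double>(de.raw));
}

// ----------------------------------------------------------- random sampling

// uniform over trees: attach leaf j+1 to an edge chosen uniformly among the
// 2j-1 current edges; uses R's RNG so set.seed() governs reproducibility
// [[Rcpp::export]]
IntegerMatrix cpp_random_tree(int n) {
    if (n < 1) stop("n must be >= 1");
    vi eu, ev;
    eu.push_back(n + 1);
    ev.push_back(1);
    for (int placed = 1; placed < n; ++placed) {
        int m = static_cast<int>(eu.size());
        int i = static_cast<int>(unif_rand() * m);
        if (i >= m) i = m - 1;
        int leaf = placed + 1, w = n + 1 + placed, ov = ev[i];
        ev[i] = w;
        eu.push_back(w); ev.push_back(ov);
        eu.push_back(w); ev.push_back(leaf);
    }
    int m = static_cast<int>(eu.size());
    IntegerMatrix mat(m, 2);
    for (int e = 0; e < m; ++e) { mat(e, 0) = eu[e]; mat(e, 1) = ev[e]; }
    return mat;
}

// [[Rcpp::export]]
List cpp_random_decoration(IntegerMatrix tree_edges, int n, int k) {
    if (k < 0) stop("k must be >= 0");
    vi eu, ev;
    edges_from_matrix(tree_edges, eu, ev);
    for (int idx = 0; idx < 2 * k; ++idx) {
        int m = static_cast<int>(eu.size());
        int i = static_cast<int>(unif_rand() * m);
        if (i >= m) i = m - 1;
        int w = 2 * n + idx + 1, ov = ev[i];
        ev[i] = w;
        eu.push_back(w); ev.push_back(ov);
    }
    int m = static_cast<int>(eu.size());
    IntegerMatrix mat(m, 2);
    for (int e = 0; e < m; ++e) { mat(e, 0) = eu[e]; mat(e, 1) = ev[e]; }
    IntegerMatrix pr(k, 2);
    for (int i = 1; i <= k; ++i) {
        pr(i - 1, 0) = 2 * n + 2 * i - 1;
        pr(i - 1, 1) = 2 * n + 2 * i;
    }
    return List::create(_["tk_edges"] = mat, _["pairs"] = pr,
                        _["nv"] = 2 * n + 2 * k);
}

// batch sampling + classification for Monte Carlo estimation
// [[Rcpp::export]]
NumericVector cpp_mc_classify(int n, int k, int M) {
    if (M < 1) stop("M must be >= 1");
    NumericVector counts(5);
    vi eu, ev;
    for (int s = 0; s < M; ++s) {
        eu.clear(); ev.clear();
        eu.push_back(n + 1); ev.push_back(1);
        for (int placed = 1; placed < n; ++placed) {
            int m = static_cast<int>(eu.size());
            int i = static_cast<int>(unif_rand() * m);
            if (i >= m) i = m - 1;
            int leaf = placed + 1, w = n + 1 + placed, ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
            eu.push_back(w); ev.push_back(leaf);
        }
        for (int idx = 0; idx < 2 * k; ++idx) {
            int m = static_cast<int>(eu.size());
            int i = static_cast<int>(unif_rand() * m);
            if (i >= m) i = m - 1;
            int w = 2 * n + idx + 1, ov = ev[i];
            ev[i] = w;
            eu.push_back(w); ev.push_back(ov);
        }
        for (int i = 1; i <= k; ++i) {
            eu.push_back(2 * n + 2 * i - 1);
            ev.push_back(2 * n + 2 * i);
        }
        ClassifyOut c = classify_core(2 * n + 2 * k, eu, ev, NULL, NULL);
        counts[c.label] += 1;
    }
    counts.attr("names") = CharacterVector::create(
        "cyclic", "not_tree_child", "shortcut", "normal_not_hyb", "hybridization");
    return counts;
}
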