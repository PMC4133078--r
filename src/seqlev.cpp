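#include <Rcpp.h>
#include <vector>
#include <string>
#include <array>
#include <cstring>

using namespace Rcpp;

// Sequence-Levenshtein distance between a and b: the minimum number of
// insertions, deletions and substitutions needed to transform one sequence
// into any prefix of the other, or vice versa.  Realised as the minimum over
// the last row and last column of the (|a|+1) x (|b|+1) Levenshtein DP
// matrix.  Consequences: d_SL(a,b) <= min(|a|,|b|) is NOT guaranteed, but
// d_SL(a,b) <= |a| and <= |b| both hold (transform into the empty prefix),
// and d_SL is symmetric.
static int sl_core(const char *a, int na, const char *b, int nb,
                   std::vector<int> &prev, std::vector<int> &cur)
{
    prev.resize(nb + 1);
    cur.resize(nb + 1);
    for (int j = 0; j <= nb; ++j) prev[j] = j;
    int best = prev[nb]; // cell (0, nb) of the last column
    for (int i = 1; i <= na; ++i) {
        cur[0] = i;
        const char ai = a[i - 1];
        for (int j = 1; j <= nb; ++j) {
            int d = prev[j - 1] + (ai != b[j - 1]);
            const int up = prev[j] + 1;
            const int left = cur[j - 1] + 1;
            if (up < d) d = up;
            if (left < d) d = left;
            cur[j] = d;
        }
        if (cur[nb] < best) best = cur[nb];
        std::swap(prev, cur);
    }
    // prev now holds the last row (i = na)
    for (int j = 0; j <= nb; ++j)
        if (prev[j] < best) best = prev[j];
    return best;
}

// As sl_core, but computes the distance exactly only when it is below
// `cap`, returning some value >= cap otherwise.  Exploits two bounds:
// D[i][j] >= |i - j| (banding: only |i - j| < cap can matter) and the
// non-decreasing row minima of the DP matrix (early abort: once a row's
// minimum reaches cap, every later last-row/last-column entry does too).
static int sl_core_capped(const char *a, int na, const char *b, int nb,
                          int cap, std::vector<int> &prev,
                          std::vector<int> &cur)
{
    if (cap <= 0) return 0;
    const int BIG = cap + 1;
    prev.assign(nb + 1, BIG);
    cur.assign(nb + 1, BIG);
    const int maxj0 = (cap - 1 < nb) ? cap - 1 : nb;
    for (int j = 0; j <= maxj0; ++j) prev[j] = j;
    int best = prev[nb]; // (0, nb): BIG unless nb < cap
    int rowmin = 0;
    for (int i = 1; i <= na; ++i) {
        int lo = i - cap + 1; if (lo < 1) lo = 1;
        int hi = i + cap - 1; if (hi > nb) hi = nb;
        if (lo > hi) return (best < cap) ? best : cap;
        cur[lo - 1] = (lo == 1) ? ((i < BIG) ? i : BIG) : BIG;
        const char ai = a[i - 1];
        rowmin = cur[lo - 1];
        for (int j = lo; j <= hi; ++j) {
            int d = prev[j - 1] + (ai != b[j - 1]);
            const int up = prev[j] + 1;
            const int left = cur[j - 1] + 1;
            if (up < d) d = up;
            if (left < d) d = left;
            if (d > BIG) d = BIG;
            cur[j] = d;
            if (d < rowmin) rowmin = d;
        }
        if (hi == nb && cur[nb] < best) best = cur[nb];
        if (rowmin >= cap) return (best < cap) ? best : cap;
        std::swap(prev, cur);
    }
    // prev is the last row; cells outside its band are BIG
    if (rowmin < best) best = rowmin;
    return (best < cap) ? best : cap;
}

// [[Rcpp::export]]
int c_sl_distance(const std::string &a, const std::string &b)
{
    std::vector<int> prev, cur;
    return sl_core(a.c_str(), (int) a.size(), b.c_str(), (int) b.size(),
                   prev, cur);
}

// Distance matrix between sequences (rows) and references (columns).
// Sequences are truncated to their first `window` bases when window > 0;
// safe because d_SL(ref, s) <= |ref| so bases beyond 2|ref| can never take
// part in an optimal alignment that beats the |ref| bound.
// [[Rcpp::export]]
IntegerMatrix c_sl_matrix(CharacterVector seqs, CharacterVector refs,
                          int window)
{
    const int n = seqs.size(), k = refs.size();
    IntegerMatrix out(n, k);
    std::vector<std::string> rf(k);
    for (int j = 0; j < k; ++j) rf[j] = as<std::string>(refs[j]);
    std::vector<int> prev, cur;
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        if (window > 0 && (int) s.size() > window) s.resize(window);
        for (int j = 0; j < k; ++j)
            out(i, j) = sl_core(rf[j].c_str(), (int) rf[j].size(),
                                s.c_str(), (int) s.size(), prev, cur);
        if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Per-read minimal distance over a reference set (no argmin bookkeeping):
// the workhorse of profiling and of the evolutionary fit's inner loop.
// [[Rcpp::export]]
IntegerVector c_sl_min_delta(CharacterVector seqs, CharacterVector refs,
                             int window)
{
    const int n = seqs.size(), k = refs.size();
    IntegerVector out(n);
    std::vector<std::string> rf(k);
    int maxlen = 0;
    for (int j = 0; j < k; ++j) {
        rf[j] = as<std::string>(refs[j]);
        if ((int) rf[j].size() > maxlen) maxlen = rf[j].size();
    }
    std::vector<int> prev, cur;
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        if (window > 0 && (int) s.size() > window) s.resize(window);
        int best = maxlen + 1;
        for (int j = 0; j < k; ++j) {
            const int d = sl_core_capped(rf[j].c_str(), (int) rf[j].size(),
                                         s.c_str(), (int) s.size(), best,
                                         prev, cur);
            if (d < best) best = d;
            if (best == 0) break;
        }
        out[i] = best;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// Align a reference barcode (rows) against the start of a read (columns)
// and report the edit operations on the optimal Sequence-Levenshtein path.
//
// Endpoint: among DP cells attaining the SL minimum, last-row cells (full
// reference consumed) are preferred, ordered by |j - L| with the smaller j
// first on ties; last-column cells (read exhausted) are the fallback.  This
// gives the fixed op-classification precedence substitution > deletion >
// insertion for the terminal-edit ambiguity.  Backtrace prefers diagonal
// (match/substitution), then up (deletion of a reference base), then left
// (insertion into the read).
//
// Returns integer vector: delta, trim (read prefix length consumed),
// n_ins, n_del, n_sub, n_interpretations (number of distinct
// (ins,del,sub) triples over all optimal endpoints; > 1 marks a
// genuinely ambiguous edit, e.g. a terminal deletion that is equally
// explainable as a substitution).
// [[Rcpp::export]]
IntegerVector c_sl_align(const std::string &read, const std::string &ref,
                         int window)
{
    std::string s = read;
    if (window > 0 && (int) s.size() > window) s.resize(window);
    const int L = (int) ref.size(), W = (int) s.size();
    std::vector<int> D((L + 1) * (W + 1));
    const int stride = W + 1;
    for (int j = 0; j <= W; ++j) D[j] = j;
    for (int i = 1; i <= L; ++i) {
        D[i * stride] = i;
        for (int j = 1; j <= W; ++j) {
            int d = D[(i - 1) * stride + (j - 1)] + (ref[i - 1] != s[j - 1]);
            const int up = D[(i - 1) * stride + j] + 1;
            const int left = D[i * stride + (j - 1)] + 1;
            if (up < d) d = up;
            if (left < d) d = left;
            D[i * stride + j] = d;
        }
    }
    int delta = D[L * stride + W];
    for (int j = 0; j <= W; ++j)
        if (D[L * stride + j] < delta) delta = D[L * stride + j];
    for (int i = 0; i <= L; ++i)
        if (D[i * stride + W] < delta) delta = D[i * stride + W];

    // endpoint selection
    int ei = -1, ej = -1;
    for (int off = 0; off <= W && ei < 0; ++off) {
        if (L - off >= 0 && D[L * stride + (L - off)] == delta) {
            ei = L; ej = L - off;
        } else if (L + off <= W && off > 0 &&
                   D[L * stride + (L + off)] == delta) {
            ei = L; ej = L + off;
        }
    }
    if (ei < 0) {
        for (int i = L; i >= 0; --i)
            if (D[i * stride + W] == delta) { ei = i; ej = W; break; }
    }
    const int trim = ej;

    // backtrace with the fixed precedence match/substitution > deletion >
    // insertion, from an arbitrary endpoint
    auto ops_from = [&](int i, int j, int &nins, int &ndel, int &nsub) {
        nins = ndel = nsub = 0;
        while (i > 0 || j > 0) {
            const int here = D[i * stride + j];
            if (i > 0 && j > 0 &&
                here == D[(i - 1) * stride + (j - 1)] +
                        (ref[i - 1] != s[j - 1])) {
                if (ref[i - 1] != s[j - 1]) ++nsub;
                --i; --j;
            } else if (i > 0 && here == D[(i - 1) * stride + j] + 1) {
                ++ndel; --i;
            } else {
                ++nins; --j;
            }
        }
    };
    int nins, ndel, nsub;
    ops_from(ei, ej, nins, ndel, nsub);

    // distinct op triples over all optimal endpoints
    std::vector<std::array<int, 3> > seen;
    seen.push_back({nins, ndel, nsub});
    for (int j = 0; j <= W; ++j) {
        if (D[L * stride + j] != delta || (L == ei && j == ej)) continue;
        int a, d, su;
        ops_from(L, j, a, d, su);
        std::array<int, 3> t = {a, d, su};
        bool found = false;
        for (size_t q = 0; q < seen.size(); ++q)
            if (seen[q] == t) { found = true; break; }
        if (!found) seen.push_back(t);
    }
    for (int i = 0; i < L; ++i) {
        if (D[i * stride + W] != delta || (i == ei && W == ej)) continue;
        int a, d, su;
        ops_from(i, W, a, d, su);
        std::array<int, 3> t = {a, d, su};
        bool found = false;
        for (size_t q = 0; q < seen.size(); ++q)
            if (seen[q] == t) { found = true; break; }
        if (!found) seen.push_back(t);
    }
    return IntegerVector::create(delta, trim, nins, ndel, nsub,
                                 (int) seen.size());
}

static inline char other_base(char c, int k)
{
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int idx = 0;
    switch (c) {
    case 'A': idx = 0; break;
    case 'C': idx = 1; break;
    case 'G': idx = 2; break;
    default:  idx = 3; break;
    }
    // k in 0..2 selects among the three bases != c
    int pick = (k >= idx) ? k + 1 : k;
    return bases[pick];
}

// Corrupt sequences under the per-read error model: one left-to-right pass
// over template bases; at each base, with probability p[i] an operation is
// drawn with relative probabilities ratios = (ins, del, sub).  Substitution
// always changes the base (uniform over the other three); deletion drops the
// base; insertion emits one uniform random base before the template base and
// keeps the base (at most one insertion per template position per pass).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector c_corrupt(CharacterVector seqs, NumericVector p,
                          NumericVector ratios)
{
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    const int n = seqs.size();
    const double rins = ratios[0], rdel = ratios[1];
    CharacterVector out(n);
    std::string buf;
    for (int i = 0; i < n; ++i) {
        const std::string s = as<std::string>(seqs[i]);
        const double pi = p[i % p.size()];
        buf.clear();
        buf.reserve(2 * s.size() + 1);
        for (size_t t = 0; t < s.size(); ++t) {
            const char c = s[t];
            if (unif_rand() < pi) {
                const double v = unif_rand();
                if (v < rins) {
                    int b = (int) (unif_rand() * 4.0); if (b > 3) b = 3;
                    buf += bases[b];
                    buf += c;
                } else if (v < rins + rdel) {
                    // deleted
                } else {
                    int k = (int) (unif_rand() * 3.0); if (k > 2) k = 2;
                    buf += other_base(c, k);
                }
            } else {
                buf += c;
            }
        }
        out[i] = buf;
        if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// n i.i.d. uniform ACGT sequences of the given length (R RNG).
// [[Rcpp::export]]
CharacterVector c_random_seqs(int n, int len)
{
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    CharacterVector out(n);
    std::string buf((size_t) len, 'A');
    for (int i = 0; i < n; ++i) {
        for (int t = 0; t < len; ++t) {
            int b = (int) (unif_rand() * 4.0); if (b > 3) b = 3;
            buf[t] = bases[b];
        }
        out[i] = buf;
    }
    return out;
}

// Greedy [l,d] set extension: scan candidates in the given order and add a
// candidate when its Sequence-Levenshtein distance to every member already
// in the set is >= dmin.  `seed` holds 1-based indices of the starting
// members.  Returns 1-based indices of the final set (seed first).
// [[Rcpp::export]]
IntegerVector c_greedy_extend(CharacterVector candidates, IntegerVector seed,
                              int dmin)
{
    const int n = candidates.size();
    std::vector<std::string> cand(n);
    for (int i = 0; i < n; ++i) cand[i] = as<std::string>(candidates[i]);
    std::vector<int> chosen;
    std::vector<bool> in(n, false);
    for (int i = 0; i < seed.size(); ++i) {
        const int idx = seed[i] - 1;
        chosen.push_back(idx);
        in[idx] = true;
    }
    std::vector<int> prev, cur;
    for (int i = 0; i < n; ++i) {
        if (in[i]) continue;
        bool ok = true;
        for (size_t m = 0; m < chosen.size(); ++m) {
            const std::string &a = cand[chosen[m]], &b = cand[i];
            if (sl_core(a.c_str(), (int) a.size(), b.c_str(), (int) b.size(),
                        prev, cur) < dmin) { ok = false; break; }
        }
        if (ok) { chosen.push_back(i); in[i] = true; }
        if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    }
    IntegerVector out(chosen.size());
    for (size_t m = 0; m < chosen.size(); ++m) out[m] = chosen[m] + 1;
    return out;
}
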