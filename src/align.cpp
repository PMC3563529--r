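// Affine-gap pairwise DNA alignment: global (Needleman-Wunsch),
// semi-global (whole of one sequence against a subsequence of the other,
// better of both orientations, free end gaps in the host sequence), and
// local (Smith-Waterman, empty alignment admissible).
//
// Gap convention: a gap of length k costs gap_open + k * gap_extend
// (the first gap column pays open + extend), subtracted from the score.
// Traceback tie-breaks are deterministic: among states M > X > Y, and a
// fresh local start is taken only when strictly better than continuing.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Score lookup keyed by residue characters taken from the substitution
// matrix dimnames; unknown residues are a hard error.
struct ScoreTable {
    double tab[256][256];
    bool known[256];
    ScoreTable(const NumericMatrix &sub) {
        for (int i = 0; i < 256; ++i) known[i] = false;
        CharacterVector rn = rownames(sub), cn = colnames(sub);
        if (rn.size() != sub.nrow() || cn.size() != sub.ncol())
            stop("substitution matrix must have row and column names");
        std::vector<unsigned char> rc(rn.size()), cc(cn.size());
        for (int i = 0; i < rn.size(); ++i) {
            std::string s = as<std::string>(rn[i]);
            rc[i] = (unsigned char) s[0];
            known[rc[i]] = true;
        }
        for (int j = 0; j < cn.size(); ++j) {
            std::string s = as<std::string>(cn[j]);
            cc[j] = (unsigned char) s[0];
        }
        for (int i = 0; i < 256; ++i)
            for (int j = 0; j < 256; ++j) tab[i][j] = NEG_INF;
        for (size_t i = 0; i < rc.size(); ++i)
            for (size_t j = 0; j < cc.size(); ++j)
                tab[rc[i]][cc[j]] = sub(i, j);
    }
    inline double s(unsigned char a, unsigned char b) const {
        return tab[a][b];
    }
    void check(const std::string &x) const {
        for (size_t i = 0; i < x.size(); ++i)
            if (!known[(unsigned char) x[i]])
                stop("residue '%s' not covered by the scoring scheme",
                     std::string(1, x[i]).c_str());
    }
};

static inline int baseIdx(unsigned char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

struct AlnResult {
    double score;
    std::string a_aln, b_aln;
    long ncol;                       // alignment columns
    long compared, diffs, tsAG, tsCT, tv;
    long nb[4];                      // A,C,G,T counts over both rows, compared sites
    AlnResult() : score(0), ncol(0), compared(0), diffs(0), tsAG(0),
                  tsCT(0), tv(0) { nb[0] = nb[1] = nb[2] = nb[3] = 0; }
};

static inline void countCol(unsigned char x, unsigned char y, AlnResult &r) {
    int bx = baseIdx(x), by = baseIdx(y);
    if (bx < 0 || by < 0) return;    // gapped or ambiguous: not compared
    r.compared++;
    r.nb[bx]++;
    r.nb[by]++;
    if (bx != by) {
        r.diffs++;
        if ((bx == 0 && by == 2) || (bx == 2 && by == 0)) r.tsAG++;
        else if ((bx == 1 && by == 3) || (bx == 3 && by == 1)) r.tsCT++;
        else r.tv++;
    }
}

enum State { SM = 0, SX = 1, SY = 2 };
enum Ptr { P_M = 0, P_X = 1, P_Y = 2, P_START = 3, P_FREE = 4 };
enum Mode { MODE_GLOBAL = 0, MODE_SEMI_FREE_A = 1, MODE_LOCAL = 2 };

struct Buffers {
    std::vector<double> M, X, Y;
    std::vector<unsigned char> pm, px, py;
    void ensure(size_t n) {
        if (M.size() < n) {
            M.resize(n); X.resize(n); Y.resize(n);
            pm.resize(n); px.resize(n); py.resize(n);
        }
    }
};

// Core DP.  a runs along rows (index i), b along columns (index j).
// MODE_SEMI_FREE_A leaves a's flanking overhangs unpenalized while b must
// be aligned end to end (the "whole of b against a subsequence of a" case).
static AlnResult alignCore(const std::string &a, const std::string &b,
                           const ScoreTable &st, double open, double ext,
                           int mode, bool wantStrings, Buffers &buf) {
    const int n = (int) a.size(), m = (int) b.size();
    const size_t W = (size_t) m + 1;
    buf.ensure((size_t)(n + 1) * W);
    std::vector<double> &M = buf.M, &X = buf.X, &Y = buf.Y;
    std::vector<unsigned char> &pm = buf.pm, &px = buf.px, &py = buf.py;

#define IDX(i, j) ((size_t)(i) * W + (size_t)(j))

    M[IDX(0, 0)] = 0.0;
    X[IDX(0, 0)] = NEG_INF;
    Y[IDX(0, 0)] = NEG_INF;
    for (int i = 1; i <= n; ++i) {
        M[IDX(i, 0)] = NEG_INF;
        Y[IDX(i, 0)] = NEG_INF;
        if (mode == MODE_GLOBAL) {
            X[IDX(i, 0)] = -(open + i * ext);
            px[IDX(i, 0)] = (i == 1) ? P_M : P_X;
        } else if (mode == MODE_SEMI_FREE_A) {
            X[IDX(i, 0)] = 0.0;
            px[IDX(i, 0)] = P_FREE;
        } else {
            X[IDX(i, 0)] = NEG_INF;
        }
    }
    for (int j = 1; j <= m; ++j) {
        M[IDX(0, j)] = NEG_INF;
        X[IDX(0, j)] = NEG_INF;
        if (mode == MODE_LOCAL) {
            Y[IDX(0, j)] = NEG_INF;
        } else {
            Y[IDX(0, j)] = -(open + j * ext);
            py[IDX(0, j)] = (j == 1) ? P_M : P_Y;
        }
    }

    double bestLocal = 0.0;          // local: empty alignment scores 0
    int bestLi = 0, bestLj = 0;

    for (int i = 1; i <= n; ++i) {
        const unsigned char ai = (unsigned char) a[i - 1];
        for (int j = 1; j <= m; ++j) {
            const unsigned char bj = (unsigned char) b[j - 1];
            const size_t dg = IDX(i - 1, j - 1), up = IDX(i - 1, j),
                         lf = IDX(i, j - 1), cu = IDX(i, j);

            // M state: tie preference M > X > Y (> fresh start for local)
            double best = M[dg];
            unsigned char ptr = P_M;
            if (X[dg] > best) { best = X[dg]; ptr = P_X; }
            if (Y[dg] > best) { best = Y[dg]; ptr = P_Y; }
            if (mode == MODE_LOCAL && 0.0 > best) { best = 0.0; ptr = P_START; }
            M[cu] = st.s(ai, bj) + best;
            pm[cu] = ptr;

            best = M[up] - open - ext; ptr = P_M;
            if (X[up] - ext > best) { best = X[up] - ext; ptr = P_X; }
            if (Y[up] - open - ext > best) { best = Y[up] - open - ext; ptr = P_Y; }
            X[cu] = best; px[cu] = ptr;

            best = M[lf] - open - ext; ptr = P_M;
            if (X[lf] - open - ext > best) { best = X[lf] - open - ext; ptr = P_X; }
            if (Y[lf] - ext > best) { best = Y[lf] - ext; ptr = P_Y; }
            Y[cu] = best; py[cu] = ptr;

            if (mode == MODE_LOCAL && M[cu] > bestLocal) {
                bestLocal = M[cu]; bestLi = i; bestLj = j;
            }
        }
    }

    AlnResult res;
    int ei = n, ej = m, estate = SM;

    if (mode == MODE_GLOBAL) {
        double best = M[IDX(n, m)]; estate = SM;
        if (X[IDX(n, m)] > best) { best = X[IDX(n, m)]; estate = SX; }
        if (Y[IDX(n, m)] > best) { best = Y[IDX(n, m)]; estate = SY; }
        res.score = best;
    } else if (mode == MODE_SEMI_FREE_A) {
        double best = NEG_INF; estate = SM; ei = 0;
        for (int i = 0; i <= n; ++i) {
            if (M[IDX(i, m)] > best) { best = M[IDX(i, m)]; ei = i; estate = SM; }
            if (X[IDX(i, m)] > best) { best = X[IDX(i, m)]; ei = i; estate = SX; }
            if (Y[IDX(i, m)] > best) { best = Y[IDX(i, m)]; ei = i; estate = SY; }
        }
        res.score = best;
    } else {                          // local
        res.score = bestLocal;
        if (bestLocal <= 0.0) {       // empty alignment
            res.score = 0.0;
            return res;
        }
        ei = bestLi; ej = bestLj; estate = SM;
    }

    // Traceback (built in reverse).
    std::string ra, rb;
    // semi-global trailing overhang of a, unpenalized
    if (mode == MODE_SEMI_FREE_A && wantStrings)
        for (int t = n; t > ei; --t) { ra += a[t - 1]; rb += '-'; }

    int i = ei, j = ej, stt = estate;
    bool done = false;
    while (!done) {
        if (i == 0 && j == 0) break;
        const size_t cu = IDX(i, j);
        switch (stt) {
        case SM: {
            unsigned char pa = a[i - 1], pb = b[j - 1];
            if (wantStrings) { ra += pa; rb += pb; }
            countCol(pa, pb, res);
            res.ncol++;
            unsigned char p = pm[cu];
            --i; --j;
            if (p == P_START) done = true; else stt = p;
            break;
        }
        case SX: {
            if (j == 0 && mode == MODE_SEMI_FREE_A) {
                // free leading overhang of a
                if (wantStrings)
                    for (int t = i; t >= 1; --t) { ra += a[t - 1]; rb += '-'; }
                done = true;
                break;
            }
            if (wantStrings) { ra += a[i - 1]; rb += '-'; }
            res.ncol++;
            stt = px[cu];
            --i;
            break;
        }
        case SY: {
            if (wantStrings) { ra += '-'; rb += b[j - 1]; }
            res.ncol++;
            stt = py[cu];
            --j;
            break;
        }
        }
    }
    if (wantStrings) {
        res.a_aln.assign(ra.rbegin(), ra.rend());
        res.b_aln.assign(rb.rbegin(), rb.rend());
    }
    return res;
#undef IDX
}

static AlnResult alignDispatch(const std::string &a, const std::string &b,
                               const ScoreTable &st, double open, double ext,
                               const std::string &type, bool wantStrings,
                               Buffers &buf) {
    if (type == "global")
        return alignCore(a, b, st, open, ext, MODE_GLOBAL, wantStrings, buf);
    if (type == "local")
        return alignCore(a, b, st, open, ext, MODE_LOCAL, wantStrings, buf);
    if (type == "semiglobal") {
        // orientation 1: whole of b inside a; orientation 2: whole of a
        // inside b; ties prefer orientation 1
        AlnResult r1 = alignCore(a, b, st, open, ext, MODE_SEMI_FREE_A,
                                 wantStrings, buf);
        AlnResult r2 = alignCore(b, a, st, open, ext, MODE_SEMI_FREE_A,
                                 wantStrings, buf);
        if (r2.score > r1.score) {
            std::swap(r2.a_aln, r2.b_aln);
            return r2;
        }
        return r1;
    }
    stop("unknown alignment type '%s'", type.c_str());
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, NumericMatrix sub,
                    double open, double ext, std::string type) {
    ScoreTable st(sub);
    st.check(a);
    st.check(b);
    Buffers buf;
    AlnResult r = alignDispatch(a, b, st, open, ext, type, true, buf);
    return List::create(
        _["score"] = r.score,
        _["pattern"] = r.a_aln,
        _["subject"] = r.b_aln);
}

// All unordered pairs (i < j, row-major in i) of one sequence set.
// Columns: score, ncol, compared, diffs, tsAG, tsCT, tv, nA, nC, nG, nT.
// [[Rcpp::export]]
NumericMatrix cpp_all_pair_stats(CharacterVector seqs, NumericMatrix sub,
                                 double open, double ext, std::string type) {
    ScoreTable st(sub);
    const int n = seqs.size();
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) {
        ss[i] = as<std::string>(seqs[i]);
        st.check(ss[i]);
    }
    const R_xlen_t np = (R_xlen_t) n * (n - 1) / 2;
    NumericMatrix out(np, 11);
    colnames(out) = CharacterVector::create(
        "score", "ncol", "compared", "diffs", "tsAG", "tsCT", "tv",
        "nA", "nC", "nG", "nT");
    Buffers buf;
    R_xlen_t r = 0;
    for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j, ++r) {
            AlnResult a = alignDispatch(ss[i], ss[j], st, open, ext, type,
                                        false, buf);
            out(r, 0) = a.score;
            out(r, 1) = (double) a.ncol;
            out(r, 2) = (double) a.compared;
            out(r, 3) = (double) a.diffs;
            out(r, 4) = (double) a.tsAG;
            out(r, 5) = (double) a.tsCT;
            out(r, 6) = (double) a.tv;
            out(r, 7) = (double) a.nb[0];
            out(r, 8) = (double) a.nb[1];
            out(r, 9) = (double) a.nb[2];
            out(r, 10) = (double) a.nb[3];
            if ((r & 63) == 0) Rcpp::checkUserInterrupt();
        }
    }
    return out;
}

// Site-pattern counts for all unordered pairs of equal-length gapped rows
// (an MSA); columns where either row is gapped or ambiguous do not count.
// [[Rcpp::export]]
NumericMatrix cpp_msa_pair_stats(CharacterVector rows) {
    const int n = rows.size();
    std::vector<std::string> ss(n);
    for (int i = 0; i < n; ++i) ss[i] = as<std::string>(rows[i]);
    const R_xlen_t np = (R_xlen_t) n * (n - 1) / 2;
    NumericMatrix out(np, 11);
    colnames(out) = CharacterVector::create(
        "score", "ncol", "compared", "diffs", "tsAG", "tsCT", "tv",
        "nA", "nC", "nG", "nT");
    R_xlen_t r = 0;
    for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j, ++r) {
            const std::string &x = ss[i], &y = ss[j];
            if (x.size() != y.size())
                stop("rows %d and %d have different lengths", i + 1, j + 1);
            AlnResult a;
            long nc = 0;
            for (size_t k = 0; k < x.size(); ++k) {
                unsigned char cx = (unsigned char) x[k],
                              cy = (unsigned char) y[k];
                bool gx = (cx == '-' || cx == '.'),
                     gy = (cy == '-' || cy == '.');
                if (gx && gy) continue;   // both-gap columns are dropped
                nc++;
                if (!gx && !gy) countCol(cx, cy, a);
            }
            out(r, 0) = NA_REAL;
            out(r, 1) = (double) nc;
            out(r, 2) = (double) a.compared;
            out(r, 3) = (double) a.diffs;
            out(r, 4) = (double) a.tsAG;
            out(r, 5) = (double) a.tsCT;
            out(r, 6) = (double) a.tv;
            out(r, 7) = (double) a.nb[0];
            out(r, 8) = (double) a.nb[1];
            out(r, 9) = (double) a.nb[2];
            out(r, 10) = (double) a.nb[3];
        }
    }
    return out;
}

// Affine score of a FIXED gapped alignment (global semantics: end gaps
// penalized).  Columns gapped in both rows are removed first.
// [[Rcpp::export]]
double cpp_score_fixed(std::string aAln, std::string bAln, NumericMatrix sub,
                       double open, double ext) {
    if (aAln.size() != bAln.size())
        stop("aligned strings must have equal length");
    ScoreTable st(sub);
    double score = 0.0;
    int prev = 0;                     // 0 match, 1 gap in b, 2 gap in a
    for (size_t k = 0; k < aAln.size(); ++k) {
        unsigned char x = (unsigned char) aAln[k], y = (unsigned char) bAln[k];
        bool gx = (x == '-' || x == '.'), gy = (y == '-' || y == '.');
        if (gx && gy) continue;
        if (!gx && !gy) {
            double s = st.s(x, y);
            if (s == NEG_INF)
                stop("residue pair (%c,%c) not covered by the scoring scheme",
                     x, y);
            score += s;
            prev = 0;
        } else if (gy) {
            score -= (prev == 1) ? ext : (open + ext);
            prev = 1;
        } else {
            score -= (prev == 2) ? ext : (open + ext);
            prev = 2;
        }
    }
    return score;
}

// Site-pattern counts of one fixed gapped alignment.
// [[Rcpp::export]]
List cpp_pair_counts(std::string aAln, std::string bAln) {
    if (aAln.size() != bAln.size())
        stop("aligned strings must have equal length");
    AlnResult a;
    long nc = 0;
    for (size_t k = 0; k < aAln.size(); ++k) {
        unsigned char x = (unsigned char) aAln[k], y = (unsigned char) bAln[k];
        bool gx = (x == '-' || x == '.'), gy = (y == '-' || y == '.');
        if (gx && gy) continue;
        nc++;
        if (!gx && !gy) countCol(x, y, a);
    }
    return List::create(
        _["ncol"] = (double) nc,
        _["compared"] = (double) a.compared,
        _["diffs"] = (double) a.diffs,
        _["tsAG"] = (double) a.tsAG,
        _["tsCT"] = (double) a.tsCT,
        _["tv"] = (double) a.tv,
        _["nA"] = (double) a.nb[0],
        _["nC"] = (double) a.nb[1],
        _["nG"] = (double) a.nb[2],
        _["nT"] = (double) a.nb[3]);
}
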