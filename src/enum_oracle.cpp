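// Brute-force reference scorer: exhaustively enumerates every admissible
// alignment and returns the best affine-gap score.  Exponential in the
// sequence lengths; intended as an independent check of the dynamic
// programming at small sizes, never for real data.

#include <Rcpp.h>
#include <string>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static const double NEG_INF2 = -std::numeric_limits<double>::infinity();

namespace {

struct SubLookup {
    double tab[256][256];
    SubLookup(const NumericMatrix &sub) {
        CharacterVector rn = rownames(sub), cn = colnames(sub);
        for (int i = 0; i < 256; ++i)
            for (int j = 0; j < 256; ++j) tab[i][j] = NEG_INF2;
        for (int i = 0; i < rn.size(); ++i)
            for (int j = 0; j < cn.size(); ++j) {
                std::string r = as<std::string>(rn[i]),
                            c = as<std::string>(cn[j]);
                tab[(unsigned char) r[0]][(unsigned char) c[0]] = sub(i, j);
            }
    }
};

// Enumerate all monotone move sequences (diagonal / gap-in-b / gap-in-a);
// affine cost depends on the previous move only.
void rec(const char *a, int n, const char *b, int m, int i, int j, int prev,
         double acc, const SubLookup &lk, double open, double ext,
         double &best) {
    if (i == n && j == m) {
        if (acc > best) best = acc;
        return;
    }
    if (i < n && j < m)
        rec(a, n, b, m, i + 1, j + 1, 0,
            acc + lk.tab[(unsigned char) a[i]][(unsigned char) b[j]],
            lk, open, ext, best);
    if (i < n)
        rec(a, n, b, m, i + 1, j, 1,
            acc - (prev == 1 ? ext : open + ext), lk, open, ext, best);
    if (j < m)
        rec(a, n, b, m, i, j + 1, 2,
            acc - (prev == 2 ? ext : open + ext), lk, open, ext, best);
}

double globalEnum(const char *a, int n, const char *b, int m,
                  const SubLookup &lk, double open, double ext) {
    double best = NEG_INF2;
    rec(a, n, b, m, 0, 0, -1, 0.0, lk, open, ext, best);
    return best;
}

} // namespace

// [[Rcpp::export]]
double cpp_enum_align_score(std::string a, std::string b, NumericMatrix sub,
                            double open, double ext, std::string type) {
    const int n = (int) a.size(), m = (int) b.size();
    if (n > 12 || m > 12)
        stop("brute-force enumeration is limited to sequences of <= 12 bases");
    SubLookup lk(sub);
    if (type == "global")
        return globalEnum(a.c_str(), n, b.c_str(), m, lk, open, ext);
    if (type == "semiglobal") {
        double best = NEG_INF2;
        // whole of b against every substring of a (empty allowed), then
        // the reverse
        for (int i0 = 0; i0 <= n; ++i0)
            for (int i1 = i0; i1 <= n; ++i1)
                best = std::max(best, globalEnum(a.c_str() + i0, i1 - i0,
                                                 b.c_str(), m, lk, open, ext));
        for (int j0 = 0; j0 <= m; ++j0)
            for (int j1 = j0; j1 <= m; ++j1)
                best = std::max(best, globalEnum(b.c_str() + j0, j1 - j0,
                                                 a.c_str(), n, lk, open, ext));
        return best;
    }
    if (type == "local") {
        double best = 0.0;            // empty alignment admissible
        for (int i0 = 0; i0 < n; ++i0)
            for (int i1 = i0 + 1; i1 <= n; ++i1)
                for (int j0 = 0; j0 < m; ++j0)
                    for (int j1 = j0 + 1; j1 <= m; ++j1)
                        best = std::max(best,
                                        globalEnum(a.c_str() + i0, i1 - i0,
                                                   b.c_str() + j0, j1 - j0,
                                                   lk, open, ext));
        return best;
    }
    stop("unknown alignment type '%s'", type.c_str());
}
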