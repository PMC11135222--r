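#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Residue-indexed encoding against the cost matrix's alphabet; -1 = invalid.
static void build_lut(const std::string& alphabet, int* lut) {
    for (int i = 0; i < 256; ++i) lut[i] = -1;
    for (size_t i = 0; i < alphabet.size(); ++i)
        lut[(unsigned char) alphabet[i]] = (int) i;
}

static std::vector<int> encode(const char* s, const int* lut) {
    size_t n = std::strlen(s);
    std::vector<int> out(n);
    for (size_t i = 0; i < n; ++i) {
        int code = lut[(unsigned char) s[i]];
        if (code < 0)
            stop("invalid residue '%c'", s[i]);
        out[i] = code;
    }
    return out;
}

// Standard Wagner-Fischer dynamic program over substitution costs.
static double dp_dist(const std::vector<int>& a, const std::vector<int>& b,
                      const NumericMatrix& cost, double indel) {
    size_t m = a.size(), n = b.size();
    std::vector<double> prev(n + 1), cur(n + 1);
    for (size_t j = 0; j <= n; ++j) prev[j] = j * indel;
    for (size_t i = 1; i <= m; ++i) {
        cur[0] = i * indel;
        for (size_t j = 1; j <= n; ++j) {
            double sub = prev[j - 1] + cost(a[i - 1], b[j - 1]);
            double del = prev[j] + indel;
            double ins = cur[j - 1] + indel;
            double best = sub < del ? sub : del;
            cur[j] = best < ins ? best : ins;
        }
        std::swap(prev, cur);
    }
    return prev[n];
}

// [[Rcpp::export]]
NumericVector edit_dist_pairs_cpp(CharacterVector a, CharacterVector b,
                                  NumericMatrix cost, double indel,
                                  std::string alphabet) {
    if (a.size() != b.size()) stop("a and b must have equal length");
    int lut[256];
    build_lut(alphabet, lut);
    R_xlen_t n = a.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::vector<int> ea = encode(CHAR(STRING_ELT(a, i)), lut);
        std::vector<int> eb = encode(CHAR(STRING_ELT(b, i)), lut);
        out[i] = dp_dist(ea, eb, cost, indel);
    }
    return out;
}

// [[Rcpp::export]]
NumericMatrix edit_dist_cross_cpp(CharacterVector x, CharacterVector y,
                                  NumericMatrix cost, double indel,
                                  std::string alphabet) {
    int lut[256];
    build_lut(alphabet, lut);
    R_xlen_t nx = x.size(), ny = y.size();
    std::vector< std::vector<int> > ex(nx), ey(ny);
    for (R_xlen_t i = 0; i < nx; ++i) ex[i] = encode(CHAR(STRING_ELT(x, i)), lut);
    for (R_xlen_t j = 0; j < ny; ++j) ey[j] = encode(CHAR(STRING_ELT(y, j)), lut);
    NumericMatrix out(nx, ny);
    for (R_xlen_t i = 0; i < nx; ++i)
        for (R_xlen_t j = 0; j < ny; ++j)
            out(i, j) = dp_dist(ex[i], ey[j], cost, indel);
    return out;
}

// Exhaustive minimal-edit-script oracle: plain recursion over the three
// edit operations, no memoization. Exponential; intended for short strings
// in tests as an independent check on the dynamic program.
static double brute_rec(const std::vector<int>& a, size_t i,
                        const std::vector<int>& b, size_t j,
                        const NumericMatrix& cost, double indel) {
    if (i == a.size()) return (double)(b.size() - j) * indel;
    if (j == b.size()) return (double)(a.size() - i) * indel;
    double sub = brute_rec(a, i + 1, b, j + 1, cost, indel) + cost(a[i], b[j]);
    double del = brute_rec(a, i + 1, b, j, cost, indel) + indel;
    double ins = brute_rec(a, i, b, j + 1, cost, indel) + indel;
    double best = sub < del ? sub : del;
    return best < ins ? best : ins;
}

// [[Rcpp::export]]
NumericVector brute_edit_dist_cpp(CharacterVector a, CharacterVector b,
                                  NumericMatrix cost, double indel,
                                  std::string alphabet) {
    if (a.size() != b.size()) stop("a and b must have equal length");
    int lut[256];
    build_lut(alphabet, lut);
    R_xlen_t n = a.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::vector<int> ea = encode(CHAR(STRING_ELT(a, i)), lut);
        std::vector<int> eb = encode(CHAR(STRING_ELT(b, i)), lut);
        out[i] = brute_rec(ea, 0, eb, 0, cost, indel);
    }
    return out;
}
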