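#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Maximum weighted nested base pairing (Nussinov-style) on the DNA alphabet
// with RNA-like weights: G-C = 3, A-T = 2, G-T = 1.  min_loop unpaired bases
// are required inside every pair.  Deterministic traceback: an unpaired 3'
// base is preferred, then the smallest admissible pairing partner.

static inline int pair_weight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
    return 0;
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string s, int min_loop) {
    const int n = (int) s.size();
    if (n > 700) stop("fold_dp: sequence longer than 700 nt");
    std::vector<std::vector<int> > W(n, std::vector<int>(n, 0));
    for (int len = min_loop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = W[i][j - 1];
            for (int k = i; k <= j - min_loop - 1; ++k) {
                int w = pair_weight(s[k], s[j]);
                if (w == 0) continue;
                int v = w + (k > i ? W[i][k - 1] : 0)
                          + (k + 1 <= j - 1 ? W[k + 1][j - 1] : 0);
                if (v > best) best = v;
            }
            W[i][j] = best;
        }
    }
    IntegerVector pairing(n, 0);
    std::vector<std::pair<int, int> > stack;
    if (n > 0) stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < min_loop + 1) continue;
        if (W[i][j] == W[i][j - 1]) { stack.push_back(std::make_pair(i, j - 1)); continue; }
        for (int k = i; k <= j - min_loop - 1; ++k) {
            int w = pair_weight(s[k], s[j]);
            if (w == 0) continue;
            int v = w + (k > i ? W[i][k - 1] : 0)
                      + (k + 1 <= j - 1 ? W[k + 1][j - 1] : 0);
            if (v == W[i][j]) {
                pairing[k] = j + 1; pairing[j] = k + 1;
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
                break;
            }
        }
    }
    return List::create(Named("pairing") = pairing,
                        Named("weight") = (n > 0 ? W[0][n - 1] : 0));
}
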