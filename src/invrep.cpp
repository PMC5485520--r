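#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Inverted-repeat (hairpin stem) local alignment of a sequence against its
// own reverse complement, EMBOSS einverted style: Watson-Crick matches only
// (G.T is a mismatch on the DNA alphabet), linear gap cost per gapped base,
// total repeat span bounded by max_span.
//
// B(i,j) = best score of a stem alignment whose outer boundary is (i,j);
// the outer column pairs i with j, or leaves i (or j) as a gap.  The inner
// end of the stem is free (local), so a pair step may reset to zero.

static inline bool wc_pair(char a, char b) {
    switch (a) {
    case 'A': return b == 'T';
    case 'T': return b == 'A';
    case 'G': return b == 'C';
    case 'C': return b == 'G';
    }
    return false;
}

// [[Rcpp::export(name = ".invrep_dp")]]
DataFrame invrep_dp(std::string s, double match, double mismatch,
                    double gap_penalty, int max_span, double threshold) {
    const int n = (int) s.size();
    const int maxd = std::min(max_span - 1, n - 1);  // d = j - i
    if (n < 2 || maxd < 1)
        return DataFrame::create(
            Named("start") = IntegerVector(0), Named("end") = IntegerVector(0),
            Named("left_end") = IntegerVector(0),
            Named("right_start") = IntegerVector(0),
            Named("score") = NumericVector(0), Named("matches") = IntegerVector(0),
            Named("mismatches") = IntegerVector(0), Named("gaps") = IntegerVector(0));
    if ((double) n * (maxd + 1) > 2.5e8)
        stop("sequence too long for banded inverted-repeat DP; scan in windows");

    // B[(size_t)i * (maxd + 1) + d], d in 1..maxd
    std::vector<double> B((size_t) n * (maxd + 1), R_NegInf);
    const double NEG = R_NegInf;
    for (int d = 1; d <= maxd; ++d) {
        for (int i = 0; i + d < n; ++i) {
            int j = i + d;
            double sc = wc_pair(s[i], s[j]) ? match : mismatch;
            double inner = 0.0;
            if (d >= 3) {
                double v = B[(size_t)(i + 1) * (maxd + 1) + (d - 2)];
                if (v > 0.0) inner = v;
            }
            double best = sc + inner;
            if (d >= 2) {
                double v1 = B[(size_t)(i + 1) * (maxd + 1) + (d - 1)] - gap_penalty;
                double v2 = B[(size_t) i * (maxd + 1) + (d - 1)] - gap_penalty;
                if (v1 > best) best = v1;
                if (v2 > best) best = v2;
            }
            B[(size_t) i * (maxd + 1) + d] = best;
        }
    }

    // candidate cells at or above threshold
    std::vector<int> ci, cd;
    for (int d = 1; d <= maxd; ++d)
        for (int i = 0; i + d < n; ++i)
            if (B[(size_t) i * (maxd + 1) + d] >= threshold) {
                ci.push_back(i); cd.push_back(d);
            }
    // order by score desc, then leftmost start, then shortest span
    std::vector<int> ord(ci.size());
    for (size_t k = 0; k < ord.size(); ++k) ord[k] = (int) k;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        double sa = B[(size_t) ci[a] * (maxd + 1) + cd[a]];
        double sb = B[(size_t) ci[b] * (maxd + 1) + cd[b]];
        if (sa != sb) return sa > sb;
        if (ci[a] != ci[b]) return ci[a] < ci[b];
        return cd[a] < cd[b];
    });

    std::vector<int> rs, re, rle, rrs, rm, rmm, rg;
    std::vector<double> rsc;
    std::vector<std::pair<int, int> > taken;
    for (size_t k = 0; k < ord.size(); ++k) {
        int i0 = ci[ord[k]], j0 = i0 + cd[ord[k]];
        bool overlap = false;
        for (size_t t = 0; t < taken.size(); ++t)
            if (i0 <= taken[t].second && j0 >= taken[t].first) { overlap = true; break; }
        if (overlap) continue;
        // traceback: prefer pair, then left gap, then right gap
        int i = i0, j = j0;
        int nm = 0, nmm = 0, ng = 0;
        int left_end = i0, right_start = j0;
        for (;;) {
            int d = j - i;
            double cur = B[(size_t) i * (maxd + 1) + d];
            double sc = wc_pair(s[i], s[j]) ? match : mismatch;
            double inner = 0.0;
            bool have_inner = false;
            if (d >= 3) {
                double v = B[(size_t)(i + 1) * (maxd + 1) + (d - 2)];
                if (v > 0.0) { inner = v; have_inner = true; }
            }
            if (cur == sc + inner) {
                if (wc_pair(s[i], s[j])) ++nm; else ++nmm;
                left_end = i; right_start = j;
                if (have_inner) { ++i; --j; continue; }
                break;
            }
            if (d >= 2 && cur == B[(size_t)(i + 1) * (maxd + 1) + (d - 1)] - gap_penalty) {
                ++ng; ++i; continue;
            }
            ++ng; --j;
        }
        taken.push_back(std::make_pair(i0, j0));
        rs.push_back(i0 + 1); re.push_back(j0 + 1);
        rle.push_back(left_end + 1); rrs.push_back(right_start + 1);
        rsc.push_back(B[(size_t) i0 * (maxd + 1) + cd[ord[k]]]);
        rm.push_back(nm); rmm.push_back(nmm); rg.push_back(ng);
    }
    return DataFrame::create(
        Named("start") = wrap(rs), Named("end") = wrap(re),
        Named("left_end") = wrap(rle), Named("right_start") = wrap(rrs),
        Named("score") = wrap(rsc), Named("matches") = wrap(rm),
        Named("mismatches") = wrap(rmm), Named("gaps") = wrap(rg),
        Named("stringsAsFactors") = false);
}
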