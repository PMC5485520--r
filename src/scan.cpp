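#include <Rcpp.h>
using namespace Rcpp;

// Patscan-style target-site scan: a site at transcript offset s (0-based)
// is the reverse complement of the mature miRNA with at most max_mm
// substitutions, none opposite a protected miRNA position.  miRNA position
// p (1-based from the 5' end) faces transcript index s + L - p.

static inline char dna_complement(char a) {
    switch (a) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'G': return 'C';
    case 'C': return 'G';
    }
    return 'N';
}

// [[Rcpp::export(name = ".target_scan")]]
List target_scan(std::string mature, std::string transcript, int max_mm,
                 IntegerVector protected_pos) {
    const int L = (int) mature.size(), T = (int) transcript.size();
    std::vector<bool> prot(L + 1, false);
    for (int k = 0; k < protected_pos.size(); ++k) {
        int p = protected_pos[k];
        if (p >= 1 && p <= L) prot[p] = true;
    }
    std::vector<char> comp(L);
    for (int p = 0; p < L; ++p) comp[p] = dna_complement(mature[p]);

    std::vector<int> offs, nmm;
    List poslists;
    std::vector<IntegerVector> keep;
    for (int s = 0; s + L <= T; ++s) {
        int mm = 0;
        bool ok = true;
        std::vector<int> pos;
        for (int p = 1; p <= L; ++p) {
            if (transcript[s + L - p] != comp[p - 1]) {
                if (prot[p]) { ok = false; break; }
                if (++mm > max_mm) { ok = false; break; }
                pos.push_back(p);
            }
        }
        if (!ok) continue;
        offs.push_back(s);
        nmm.push_back(mm);
        keep.push_back(wrap(pos));
    }
    List plist(keep.size());
    for (size_t k = 0; k < keep.size(); ++k) plist[k] = keep[k];
    return List::create(Named("offset") = wrap(offs),
                        Named("n_mismatches") = wrap(nmm),
                        Named("mismatch_positions") = plist);
}
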