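// Position-weighted local duplex alignment of a miRNA against a 3'UTR.
//
// The miRNA (5'->3') is reversed so that it runs antiparallel along the
// UTR (5'->3'); alignment is Smith-Waterman with affine gaps under a
// complementarity scoring: Watson-Crick pair = match, G:U = wobble,
// anything else = mismatch. Pair scores at miRNA positions
// seedStart..seedEnd (1-based from the miRNA 5' end) are multiplied by
// seedMult. Gap costs are unweighted. The first residue of a gap costs
// gapOpen, each further residue gapExtend.
//
// Multiple sites are reported by iterated alignment with masking: after
// the best site is extracted, its UTR interval is masked and the DP is
// rerun, until no site reaches minScore. This realizes greedy
// suppression of overlapping lower-scoring sites.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int baseIdx(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
    }
    return -1;
}

// q, t are RNA base indices (A=0, C=1, G=2, U=3)
static inline double pairScore(int q, int t, double match, double wobble,
                               double mismatch, char &state) {
    if ((q == 0 && t == 3) || (q == 3 && t == 0) ||
        (q == 1 && t == 2) || (q == 2 && t == 1)) {
        state = 'M';
        return match;
    }
    if ((q == 2 && t == 3) || (q == 3 && t == 2)) {
        state = 'W';
        return wobble;
    }
    state = 'X';
    return mismatch;
}

struct Site {
    int utrStart, utrEnd;     // 0-based half-open
    int mirStart, mirEnd;     // 1-based inclusive miRNA positions
    double score;
    std::string trace;
    bool seedMatched;
};

// One masked Smith-Waterman pass; returns true if a site >= minScore
// was found and fills `out`.
static bool swPass(const std::vector<int> &q, const std::vector<int> &t,
                   const std::vector<double> &w,
                   const std::vector<bool> &masked,
                   double match, double wobble, double mismatch,
                   double gapOpen, double gapExtend, double minScore,
                   int Lm, int seedStart, int seedEnd, Site &out) {
    const int n = (int)q.size(), m = (int)t.size();
    const double NEG = -1e18;
    // (n+1) x (m+1) matrices, row-major
    std::vector<double> H((n + 1) * (m + 1), 0.0);
    std::vector<double> E((n + 1) * (m + 1), NEG);  // gap in miRNA
    std::vector<double> F((n + 1) * (m + 1), NEG);  // gap in UTR
    std::vector<unsigned char> ptrH((n + 1) * (m + 1), 0); // 0 stop,1 diag,2 E,3 F
    std::vector<unsigned char> ptrE((n + 1) * (m + 1), 0); // 0 open,1 extend
    std::vector<unsigned char> ptrF((n + 1) * (m + 1), 0);
    auto at = [m](int i, int j) { return i * (m + 1) + j; };

    double best = 0.0;
    std::vector<std::pair<int, int>> argbest;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int k = at(i, j);
            if (masked[j - 1]) { H[k] = 0; E[k] = NEG; F[k] = NEG; continue; }
            double eOpen = H[at(i, j - 1)] + gapOpen;
            double eExt = E[at(i, j - 1)] + gapExtend;
            E[k] = eOpen >= eExt ? eOpen : eExt;
            ptrE[k] = eOpen >= eExt ? 0 : 1;
            double fOpen = H[at(i - 1, j)] + gapOpen;
            double fExt = F[at(i - 1, j)] + gapExtend;
            F[k] = fOpen >= fExt ? fOpen : fExt;
            ptrF[k] = fOpen >= fExt ? 0 : 1;
            char st;
            double diag = H[at(i - 1, j - 1)] +
                w[i - 1] * pairScore(q[i - 1], t[j - 1], match, wobble,
                                     mismatch, st);
            double h = 0.0; unsigned char p = 0;
            if (diag > h) { h = diag; p = 1; }
            if (E[k] > h) { h = E[k]; p = 2; }
            if (F[k] > h) { h = F[k]; p = 3; }
            H[k] = h; ptrH[k] = p;
            if (h > best + 1e-9) {
                best = h;
                argbest.clear();
                argbest.push_back({i, j});
            } else if (h > 0 && std::abs(h - best) <= 1e-9) {
                argbest.push_back({i, j});
            }
        }
    }
    if (best < minScore || argbest.empty()) return false;

    // traceback each candidate end cell; prefer leftmost UTR start, then
    // smallest UTR end, then smallest miRNA index
    bool have = false;
    for (auto &cell : argbest) {
        int i = cell.first, j = cell.second;
        int endI = i, endJ = j;
        std::string tr;
        while (i > 0 && j > 0 && ptrH[at(i, j)] != 0) {
            unsigned char p = ptrH[at(i, j)];
            if (p == 1) {
                char st;
                pairScore(q[i - 1], t[j - 1], match, wobble, mismatch, st);
                tr.push_back(st);
                --i; --j;
            } else if (p == 2) {        // gap in miRNA: UTR base bulged
                while (true) {
                    tr.push_back('i');
                    unsigned char pe = ptrE[at(i, j)];
                    --j;
                    if (pe == 0) break;
                }
            } else {                    // gap in UTR: miRNA base bulged
                while (true) {
                    tr.push_back('d');
                    unsigned char pf = ptrF[at(i, j)];
                    --i;
                    if (pf == 0) break;
                }
            }
        }
        std::reverse(tr.begin(), tr.end());
        Site cand;
        cand.utrStart = j;            // 0-based start
        cand.utrEnd = endJ;           // half-open end
        // reversed-query indices (i+1..endI) map to miRNA positions
        cand.mirStart = Lm - endI + 1;
        cand.mirEnd = Lm - (i + 1) + 1;
        cand.score = best;
        cand.trace = tr;
        // seed matched: the whole seed (miRNA positions
        // seedStart..seedEnd) is covered, every seed position is a WC
        // pair, and the seed duplex is contiguous -- neither a bulged
        // miRNA base ('d') nor a bulged UTR base ('i') interrupts it
        int need = seedEnd - seedStart + 1, got = 0;
        {
            int pos = cand.mirEnd;    // walk trace 5'->3' on UTR
            for (char c : tr) {
                if (c == 'M' || c == 'W' || c == 'X') {
                    if (pos >= seedStart && pos <= seedEnd && c == 'M')
                        ++got;
                    --pos;
                } else if (c == 'd') {
                    if (pos >= seedStart && pos <= seedEnd) got -= 1000;
                    --pos;
                } else {              // 'i': UTR bulge between pairings
                    if (pos >= seedStart && pos < seedEnd) got -= 1000;
                }
            }
        }
        cand.seedMatched = (got == need) &&
            cand.mirStart <= seedStart && cand.mirEnd >= seedEnd;
        if (!have || cand.utrStart < out.utrStart ||
            (cand.utrStart == out.utrStart && cand.utrEnd < out.utrEnd)) {
            out = cand;
            have = true;
        }
    }
    return have;
}

// [[Rcpp::export(name = ".duplexAlignCpp")]]
List duplexAlignCpp(std::string mirna, std::string utr, double match,
                    double wobble, double mismatch, double gapOpen,
                    double gapExtend, double seedMult, int seedStart,
                    int seedEnd, double minScore, int maxSites) {
    const int Lm = (int)mirna.size();
    std::vector<int> q(Lm), t(utr.size());
    std::vector<double> w(Lm);
    for (int i = 0; i < Lm; ++i) {
        int b = baseIdx(mirna[Lm - 1 - i]);  // reversed miRNA
        if (b < 0) stop("non-canonical character in miRNA sequence");
        q[i] = b;
        int pos = Lm - i;                    // 1-based miRNA position
        w[i] = (pos >= seedStart && pos <= seedEnd) ? seedMult : 1.0;
    }
    for (size_t j = 0; j < utr.size(); ++j) {
        int b = baseIdx(utr[j]);
        if (b < 0) stop("non-canonical character in UTR sequence");
        t[j] = b;
    }

    std::vector<bool> masked(utr.size(), false);
    std::vector<Site> sites;
    for (int iter = 0; iter < maxSites; ++iter) {
        Site s;
        if (!swPass(q, t, w, masked, match, wobble, mismatch, gapOpen,
                    gapExtend, minScore, Lm, seedStart, seedEnd, s))
            break;
        sites.push_back(s);
        for (int j = s.utrStart; j < s.utrEnd; ++j) masked[j] = true;
    }

    int ns = (int)sites.size();
    IntegerVector start(ns), end(ns), mirStart(ns), mirEnd(ns);
    NumericVector score(ns);
    CharacterVector trace(ns);
    LogicalVector seedMatched(ns);
    for (int i = 0; i < ns; ++i) {
        start[i] = sites[i].utrStart;
        end[i] = sites[i].utrEnd;
        mirStart[i] = sites[i].mirStart;
        mirEnd[i] = sites[i].mirEnd;
        score[i] = sites[i].score;
        trace[i] = sites[i].trace;
        seedMatched[i] = sites[i].seedMatched;
    }
    return List::create(_["start"] = start, _["end"] = end,
                        _["mirna_start"] = mirStart,
                        _["mirna_end"] = mirEnd, _["score"] = score,
                        _["trace"] = trace,
                        _["seed_matched"] = seedMatched);
}
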