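#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; -1 for anything else (ambiguity codes never seed)
static inline int base2bits(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline bool base_match(char a, char b) {
    int x = base2bits(a), y = base2bits(b);
    return x >= 0 && x == y;  // N never matches, not even itself
}

struct Hsp {
    int qstart, qend, sstart, send, score;  // 0-based inclusive
};

// Gap-free high-scoring segment pairs between x (query) and y (subject).
//
// Exact k-mer seeds found through a hash of x's k-mers are extended in both
// directions without gaps under an x-drop rule (stop once the running score
// falls more than `xdrop` below the best seen). Seeds falling inside a
// segment already extended on the same diagonal are skipped, so each
// diagonal contributes each segment once. Coordinates returned 1-based.
//
// [[Rcpp::export(name = ".nt_hsps_cpp")]]
DataFrame nt_hsps_cpp(std::string x, std::string y, int k,
                      int match, int mismatch, int xdrop, int min_score) {
    const int nx = (int)x.size(), ny = (int)y.size();
    std::vector<Hsp> out;
    if (nx >= k && ny >= k) {
        // hash k-mers of x
        std::unordered_map<std::uint64_t, std::vector<int> > index;
        index.reserve((size_t)nx * 2);
        const std::uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
        std::uint64_t h = 0; int run = 0;
        for (int i = 0; i < nx; ++i) {
            int b = base2bits(x[i]);
            if (b < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (std::uint64_t)b) & mask;
            if (++run >= k) index[h].push_back(i - k + 1);
        }
        // furthest subject position already covered per diagonal (d = i - j)
        std::unordered_map<long long, int> diag_cov;
        h = 0; run = 0;
        for (int j = 0; j < ny; ++j) {
            int b = base2bits(y[j]);
            if (b < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (std::uint64_t)b) & mask;
            if (run + 1 < k) { ++run; continue; }
            ++run;
            auto hit = index.find(h);
            if (hit == index.end()) continue;
            int j0 = j - k + 1;
            for (int i0 : hit->second) {
                long long d = (long long)i0 - (long long)j0;
                auto cov = diag_cov.find(d);
                if (cov != diag_cov.end() && j0 <= cov->second) continue;
                // extend right from seed end
                int score = match * k, best = score;
                int qi = i0 + k, sj = j0 + k, bq = qi - 1, bs = sj - 1;
                while (qi < nx && sj < ny) {
                    score += base_match(x[qi], y[sj]) ? match : mismatch;
                    if (score > best) { best = score; bq = qi; bs = sj; }
                    if (best - score > xdrop) break;
                    ++qi; ++sj;
                }
                int qend = bq, send = bs;
                // extend left from seed start
                score = best;
                qi = i0 - 1; sj = j0 - 1;
                int lq = i0, ls = j0;
                while (qi >= 0 && sj >= 0) {
                    score += base_match(x[qi], y[sj]) ? match : mismatch;
                    if (score > best) { best = score; lq = qi; ls = sj; }
                    if (best - score > xdrop) break;
                    --qi; --sj;
                }
                diag_cov[d] = send;
                if (best >= min_score)
                    out.push_back(Hsp{lq, qend, ls, send, best});
            }
        }
    }
    const int n = (int)out.size();
    IntegerVector qs(n), qe(n), ss(n), se(n), sc(n), len(n);
    for (int i = 0; i < n; ++i) {
        qs[i] = out[i].qstart + 1; qe[i] = out[i].qend + 1;
        ss[i] = out[i].sstart + 1; se[i] = out[i].send + 1;
        sc[i] = out[i].score; len[i] = out[i].qend - out[i].qstart + 1;
    }
    return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                             _["sstart"] = ss, _["send"] = se,
                             _["score"] = sc, _["length"] = len);
}
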