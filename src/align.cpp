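#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// Exhaustive ungapped scan of every full-length read placement (forward and
// reverse complement) on every reference, keeping placements whose mismatch
// count stays within the read's budget.  Sequences of plain A/C/G/T are
// packed 2 bits per base so a placement is scored with a handful of XOR +
// popcount words; anything containing other letters (e.g. N) takes a byte
// loop where N never matches.

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    }
    return -1;
}

struct Packed {
    std::vector<uint64_t> words; // 2 bits per base, 32 bases per word
    bool clean = true;           // false when any non-ACGT base present
    int len = 0;
};

static Packed pack_seq(const std::string &s) {
    Packed p;
    p.len = (int)s.size();
    p.words.assign(s.size() / 32 + 2, 0ULL); // padded for shifted fetches
    for (size_t i = 0; i < s.size(); ++i) {
        int c = base_code(s[i]);
        if (c < 0) { p.clean = false; c = 0; }
        p.words[i / 32] |= (uint64_t)c << (2 * (i % 32));
    }
    return p;
}

static const uint64_t ODD = 0x5555555555555555ULL;

// mismatches of a packed read placed at ref position p; -1 once over budget
static inline int packed_mm(const Packed &ref, int p,
                            const std::vector<uint64_t> &q,
                            const std::vector<uint64_t> &qmask,
                            int budget) {
    const int off = (2 * p) % 64;
    const int w0 = (2 * p) / 64;
    int mm = 0;
    for (size_t c = 0; c < q.size(); ++c) {
        uint64_t r = ref.words[w0 + c] >> off;
        if (off) r |= ref.words[w0 + c + 1] << (64 - off);
        uint64_t x = (r ^ q[c]) & qmask[c];
        uint64_t y = (x | (x >> 1)) & ODD;
        mm += __builtin_popcountll(y);
        if (mm > budget) return -1;
    }
    return mm;
}

// byte-path mismatch count; 'N' (or any non-ACGT) never matches
static inline int byte_mm(const char *r, const char *q, int L, int budget) {
    int mm = 0;
    for (int b = 0; b < L; ++b) {
        char qb = q[b], rb = r[b];
        if (qb != rb || base_code(qb) < 0) {
            if (++mm > budget) return -1;
        }
    }
    return mm;
}

// [[Rcpp::export]]
DataFrame cpp_scan_hits(CharacterVector reads, CharacterVector refs,
                        IntegerVector max_mm) {
    std::vector<std::string> refseq(refs.size());
    std::vector<Packed> refpack(refs.size());
    for (int j = 0; j < refs.size(); ++j) {
        refseq[j] = as<std::string>(refs[j]);
        refpack[j] = pack_seq(refseq[j]);
    }
    std::vector<int> out_read, out_ref, out_pos, out_mm;
    std::vector<char> out_strand;
    for (int i = 0; i < reads.size(); ++i) {
        std::string fwd = as<std::string>(reads[i]);
        std::string rev = revcomp_str(fwd);
        const int L = (int)fwd.size();
        const int budget = max_mm[i];
        const int nw = (2 * L + 63) / 64;
        for (int strand = 0; strand < 2; ++strand) {
            const std::string &qs = (strand == 0 ? fwd : rev);
            Packed qp = pack_seq(qs);
            std::vector<uint64_t> q(qp.words.begin(), qp.words.begin() + nw);
            std::vector<uint64_t> qmask(nw, ~0ULL);
            {
                int rem = (2 * L) % 64;
                if (rem) qmask[nw - 1] = (~0ULL) >> (64 - rem);
            }
            for (size_t j = 0; j < refseq.size(); ++j) {
                const std::string &R = refseq[j];
                const int n = (int)R.size() - L;
                const bool fast = qp.clean && refpack[j].clean;
                for (int p = 0; p <= n; ++p) {
                    int mm = fast
                        ? packed_mm(refpack[j], p, q, qmask, budget)
                        : byte_mm(R.c_str() + p, qs.c_str(), L, budget);
                    if (mm >= 0) {
                        out_read.push_back(i + 1);
                        out_ref.push_back((int)j + 1);
                        out_pos.push_back(p);
                        out_strand.push_back(strand == 0 ? '+' : '-');
                        out_mm.push_back(mm);
                    }
                }
            }
        }
    }
    CharacterVector strand_col(out_strand.size());
    for (size_t i = 0; i < out_strand.size(); ++i)
        strand_col[i] = std::string(1, out_strand[i]);
    return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                             _["pos"] = out_pos, _["strand"] = strand_col,
                             _["mm"] = out_mm,
                             _["stringsAsFactors"] = false);
}
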