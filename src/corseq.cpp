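#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <string>
#include <vector>
#include <cctype>

using namespace Rcpp;

// Standard genetic code (translation table 1), indexed by 16*b1 + 4*b2 + b3
// with A=0, C=1, G=2, T=3. '*' marks a stop, 'X' an untranslatable triplet.
static const char CODON_TABLE[65] =
    "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int base_index(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 'T'; case 'c': return 'G';
    case 'g': return 'C'; case 't': return 'A';
    default: return 'N';
    }
}

// Translate s[from, from + 3*naa); returns false if any triplet is
// non-ACGT or encodes a stop. On success writes naa letters into out.
static bool translate_window(const std::string &s, size_t from, int naa,
                             std::string &out) {
    out.clear();
    for (int i = 0; i < naa; ++i) {
        int b1 = base_index(s[from + 3 * i]);
        int b2 = base_index(s[from + 3 * i + 1]);
        int b3 = base_index(s[from + 3 * i + 2]);
        if (b1 < 0 || b2 < 0 || b3 < 0) return false;
        char aa = CODON_TABLE[16 * b1 + 4 * b2 + b3];
        if (aa == '*') return false;
        out.push_back(aa);
    }
    return true;
}

static std::string revcomp(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[i] = comp_base(s[s.size() - 1 - i]);
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_peptide_kmers(CharacterVector seqs, int kp) {
    static const std::string AA = "ACDEFGHIKLMNPQRSTVWY";
    bool valid[256] = {false};
    for (char c : AA) valid[(unsigned char)c] = true;
    std::unordered_set<std::string> seen;
    std::vector<std::string> out;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        for (auto &c : s) c = std::toupper((unsigned char)c);
        if ((int)s.size() < kp) continue;
        for (size_t j = 0; j + kp <= s.size(); ++j) {
            bool ok = true;
            for (int l = 0; l < kp; ++l)
                if (!valid[(unsigned char)s[j + l]]) { ok = false; break; }
            if (!ok) continue;
            std::string w = s.substr(j, kp);
            if (seen.insert(w).second) out.push_back(w);
        }
    }
    return wrap(out);
}

// First-match frame search: forward strand first, lower offsets first, then
// the reverse complement. A window qualifies if it is pure ACGT, translates
// without a stop, and its peptide is in the index.
// [[Rcpp::export]]
List cpp_find_frames(CharacterVector reads, CharacterVector peptides, int kp) {
    std::unordered_set<std::string> index;
    index.reserve(peptides.size() * 2);
    for (R_xlen_t i = 0; i < peptides.size(); ++i)
        index.insert(as<std::string>(peptides[i]));

    R_xlen_t n = reads.size();
    IntegerVector orientation(n, NA_INTEGER); // 1 = forward, 2 = reverse
    IntegerVector offset(n, NA_INTEGER);      // 0-based on oriented read
    CharacterVector peptide(n, NA_STRING);
    const int win = 3 * kp;
    std::string aa;
    aa.reserve(kp);

    for (R_xlen_t i = 0; i < n; ++i) {
        std::string fwd = as<std::string>(reads[i]);
        for (auto &c : fwd) c = std::toupper((unsigned char)c);
        if ((int)fwd.size() < win) continue;
        bool found = false;
        for (int ori = 1; ori <= 2 && !found; ++ori) {
            const std::string s = (ori == 1) ? fwd : revcomp(fwd);
            for (size_t j = 0; j + win <= s.size(); ++j) {
                if (!translate_window(s, j, kp, aa)) continue;
                if (index.count(aa)) {
                    orientation[i] = ori;
                    offset[i] = (int)j;
                    peptide[i] = aa;
                    found = true;
                    break;
                }
            }
        }
    }
    return List::create(_["orientation"] = orientation,
                        _["offset"] = offset,
                        _["peptide"] = peptide);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = revcomp(as<std::string>(seqs[i]));
    return out;
}

// Frame-aligned kmer counting: windows start at 0, 3, 6, ...; windows with
// non-ACGT characters are skipped.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector orfs, int k) {
    std::unordered_map<std::string, int> counts;
    for (R_xlen_t i = 0; i < orfs.size(); ++i) {
        std::string s = as<std::string>(orfs[i]);
        if ((int)s.size() < k) continue;
        for (size_t j = 0; j + k <= s.size(); j += 3) {
            bool ok = true;
            for (int l = 0; l < k; ++l)
                if (base_index(s[j + l]) < 0) { ok = false; break; }
            if (!ok) continue;
            ++counts[s.substr(j, k)];
        }
    }
    CharacterVector kmer(counts.size());
    IntegerVector count(counts.size());
    R_xlen_t i = 0;
    for (auto &kv : counts) {
        kmer[i] = kv.first;
        count[i] = kv.second;
        ++i;
    }
    return List::create(_["kmer"] = kmer, _["count"] = count);
}

// In-frame codon counting over kmer strings (length must be a multiple of 3,
// enforced by the caller). Returns counts for the 64 codons in the fixed
// order A<C<G<T on each position, plus the number of skipped kmers.
// [[Rcpp::export]]
List cpp_count_codons(CharacterVector kmers, IntegerVector weights) {
    std::vector<double> counts(64, 0.0);
    int skipped = 0;
    bool weighted = weights.size() > 0;
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        bool ok = true;
        for (char c : s)
            if (base_index(c) < 0) { ok = false; break; }
        if (!ok || s.size() % 3 != 0) { ++skipped; continue; }
        double w = weighted ? (double)weights[i] : 1.0;
        for (size_t j = 0; j + 3 <= s.size(); j += 3) {
            int idx = 16 * base_index(s[j]) + 4 * base_index(s[j + 1]) +
                      base_index(s[j + 2]);
            counts[idx] += w;
        }
    }
    static const char *BASES = "ACGT";
    CharacterVector codon(64);
    NumericVector count(64);
    for (int i = 0; i < 64; ++i) {
        char c[4] = {BASES[i / 16], BASES[(i / 4) % 4], BASES[i % 4], 0};
        codon[i] = c;
        count[i] = counts[i];
    }
    return List::create(_["codon"] = codon, _["count"] = count,
                        _["skipped"] = skipped);
}

// FNV-1a 64-bit hash per string, returned as a double for use as a fixed,
// composition-neutral tie-break order. The ~11-bit precision loss from the
// double conversion is resolved downstream by a final lexicographic key.
// [[Rcpp::export]]
NumericVector cpp_fnv1a(CharacterVector x) {
    NumericVector out(x.size());
    for (R_xlen_t i = 0; i < x.size(); ++i) {
        const char *s = CHAR(STRING_ELT(x, i));
        uint64_t h = 1469598103934665603ULL;
        for (; *s; ++s) {
            h ^= (uint64_t)(unsigned char)*s;
            h *= 1099511628211ULL;
        }
        out[i] = (double)h;
    }
    return out;
}
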