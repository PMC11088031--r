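#pragma once

#include <cstdint>
#include <cstring>
#include <vector>
#include <array>
#include <string>
#include <algorithm>
#include <stdexcept>

// Core data structures shared by the sequence, index, alignment, MSA and
// task-engine translation units. Nucleotides are handled as byte codes
// A=0, C=1, G=2, T=3 throughout; 2-bit packing is used for storage and for
// k-mer hashing.

namespace plrex {

using Codes = std::vector<uint8_t>;

// ---------- sequence core ----------

// -1: not an IUPAC nucleotide code. Ambiguity codes map to the
// lexicographically smallest compatible base (N->A, R->A, Y->C, ...).
int iupac_to_code(char c);

Codes encode_string(const std::string& s);       // throws std::invalid_argument
std::string decode_codes(const Codes& v);
Codes revcomp_codes(const Codes& v);

// SWAR popcount: avoids a libgcc call on baseline x86-64 builds.
inline int popcount64(uint64_t x) {
    x -= (x >> 1) & 0x5555555555555555ULL;
    x = (x & 0x3333333333333333ULL) + ((x >> 2) & 0x3333333333333333ULL);
    x = (x + (x >> 4)) & 0x0F0F0F0F0F0F0F0FULL;
    return static_cast<int>((x * 0x0101010101010101ULL) >> 56);
}

// Mismatch count between two equal-length code segments, eight bases per
// 64-bit word. If limit >= 0, returns early with a value > limit once the
// count exceeds it.
inline long hamming_codes(const uint8_t* a, const uint8_t* b, long n, long limit) {
    long mm = 0;
    long i = 0;
    for (; i + 8 <= n; i += 8) {
        uint64_t x, y;
        std::memcpy(&x, a + i, 8);
        std::memcpy(&y, b + i, 8);
        uint64_t d = x ^ y;
        if (d) {
            d = (d | (d >> 1)) & 0x0101010101010101ULL;
            mm += popcount64(d);
            if (limit >= 0 && mm > limit) return mm;
        }
    }
    for (; i < n; ++i)
        if (a[i] != b[i]) ++mm;
    return mm;
}

// ---------- minhash ----------

inline uint64_t splitmix64(uint64_t& state) {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

inline uint64_t mix64(uint64_t x) {
    x ^= x >> 33;
    x *= 0xFF51AFD7ED558CCDULL;
    x ^= x >> 33;
    x *= 0xC4CEB9FE1A85EC53ULL;
    x ^= x >> 33;
    return x;
}

// Per-table hash: one strong mix of the canonical k-mer shared by all
// tables, then a cheap seeded xor-multiply-xorshift per table. Keeps the
// per-k-mer cost at O(1) strong mixes instead of h of them.
inline uint64_t table_hash(uint64_t mixedKmer, uint64_t seed) {
    uint64_t v = (mixedKmer ^ seed) * 0x9E3779B97F4A7C15ULL;
    v ^= v >> 32;
    return v;
}

struct HashFamily {
    int h;
    int k;
    std::vector<uint64_t> seeds;
};

HashFamily make_family(int h, int k, uint64_t seed);

// Minhash signature over all canonical k-mers of s (len >= k required).
std::vector<uint64_t> signature_of(const uint8_t* s, int len, const HashFamily& fam);

struct KmerIndex {
    HashFamily fam;
    int maxBucket = 1000;
    std::size_t nReads = 0;
    std::vector<int> lens;
    std::vector<std::size_t> offsets;
    std::vector<uint8_t> arena;          // forward codes, concatenated
    long nShortSkipped = 0;              // reads shorter than k (not indexed)
    long nCappedKeys = 0;                // buckets truncated at maxBucket

    // Open-addressing table: hash values are already well mixed, so the
    // masked key itself is the slot; linear probing; cnt == 0 marks empty.
    struct Table {
        struct Slot {                   // 16 bytes: one cache line hit/probe
            uint64_t key;
            uint32_t off;
            uint32_t cnt;
        };
        std::vector<Slot> slots;
        std::vector<uint32_t> ids;      // bucket id lists, concatenated
        uint64_t mask = 0;

        void build(const std::vector<std::pair<uint64_t, uint32_t>>& sorted,
                   int maxBucket, long& nCapped);
        // pointer + count of the bucket for key (count 0 if absent)
        std::pair<const uint32_t*, uint32_t> find(uint64_t key) const {
            uint64_t h = key & mask;
            while (slots[h].cnt != 0) {
                if (slots[h].key == key)
                    return {ids.data() + slots[h].off, slots[h].cnt};
                h = (h + 1) & mask;
            }
            return {nullptr, 0};
        }
    };
    std::vector<Table> tables;
    std::vector<uint8_t> arenaRC;        // reverse-complement codes
    // 2-bit packed forms for the shift alignment, one padding word per read
    std::vector<uint64_t> packedF, packedR;
    std::vector<std::size_t> packOffsets;
    const uint64_t* packed_fwd(std::size_t i) const { return packedF.data() + packOffsets[i]; }
    const uint64_t* packed_rc(std::size_t i) const { return packedR.data() + packOffsets[i]; }

    const uint8_t* read_ptr(std::size_t i) const { return arena.data() + offsets[i]; }
    const uint8_t* read_rc_ptr(std::size_t i) const { return arenaRC.data() + offsets[i]; }
    int read_len(std::size_t i) const { return lens[i]; }

    void build(const std::vector<Codes>& reads, const HashFamily& fam_, int maxBucket_);
    // deduplicated, sorted read ids (0-based)
    std::vector<uint32_t> query(const uint8_t* s, int len) const;
    std::vector<uint32_t> lookup(int table, uint64_t key) const;
};

// ---------- pairwise alignment ----------

struct ShiftAln {
    int shift = 0;
    int overlap = 0;
    int mism = 0;
    bool rc = false;
    bool valid = false;
};

// 2-bit packing for the bit-parallel shift alignment: 32 bases per 64-bit
// word, base i at bits [2i, 2i+2) of word i/32; one zero padding word.
std::vector<uint64_t> pack_codes(const uint8_t* s, int n);

// Mismatches between a[s .. s+ov) (packed, arbitrary base offset s) and
// b[0 .. ov) (packed, word-aligned); early exit once the count exceeds
// limit (limit >= 0).
long hamming_packed(const uint64_t* a, int s, const uint64_t* b, int ov,
                    long limit);

// Best indel-free placement of cand against anchor: every shift in
// [0, alen-1], both orientations; admissible iff overlap >= minOvFrac*|cand|
// and mismatches <= maxMm. Ties: fewer mismatches, larger overlap, smaller
// shift, forward before reverse-complement. All arguments packed
// (pack_codes); candR is the packed reverse complement.
ShiftAln best_alignment_packed(const uint64_t* anchor, int alen,
                               const uint64_t* candF, const uint64_t* candR,
                               int clen, int maxMm, double minOvFrac);

// Convenience wrapper over byte codes (packs internally).
ShiftAln best_alignment_codes(const uint8_t* anchor, int alen,
                              const uint8_t* cand, int clen,
                              int maxMm, double minOvFrac);

// ---------- MSA ----------

struct MsaMember {
    int id = -1;        // caller bookkeeping (read id); not used internally
    int shift = 0;
    bool rc = false;
    Codes seq;          // oriented as placed
};

struct Msa {
    int anchorLen = 0;
    int ncol = 0;
    Codes anchor;
    std::vector<std::array<int, 4>> counts;   // per-column base counts
    std::vector<MsaMember> members;

    void rebuild_counts();
    int coverage(int col) const {
        const auto& c = counts[col];
        return c[0] + c[1] + c[2] + c[3];
    }
    Codes consensus() const;                   // ties: lexicographic (A<C<G<T)
};

Msa build_msa_core(Codes anchor, std::vector<MsaMember> members);

// One pass of the column-content filter; returns number of members removed.
int refine_msa_pass(Msa& m, double frac);
// Runs up to `passes` passes, stopping early at a fixed point.
int refine_msa_core(Msa& m, double frac, int passes);

struct ExtendRes {
    bool ok = false;
    Codes appended;     // consensus bases, 1..stepsize of them
};

ExtendRes extend_from_msa(const Msa& m, int stepsize, int minCov);

// ---------- task engine / finalization ----------

struct PairParams {
    int maxMismatches = 5;
    double minOverlapFrac = 0.5;
    int stepsize = 20;
    int minCoverage = 3;
    double refineFrac = 0.3;
    int refinePasses = 1;
    double mateMaxMismatchFrac = 0.05;
    int minLen = 0;
    int maxLen = 0;
    int strict2MaxHamming = 0;
    double strict1OverlapFrac = 0.5;
    double strict1MatchFrac = 0.95;
    int mergeMinOverlap = 40;
    double mergeMaxMismatchFrac = 0.05;
    bool outward = false;
    int outwardCap = 0;
};

enum TaskState { TASK_ACTIVE = 0, TASK_MATE_FOUND = 1, TASK_FAILED = 2, TASK_STOPPED = 3 };

struct TaskResult {
    int state = TASK_ACTIVE;
    int startLen = 0;
    int matePos = -1;
    Codes contig;
};

struct PairOutcome {
    bool connected[3] = {false, false, false};
    std::string rule[3];
    Codes seq;                 // result sequence (empty if nothing connected)
    int gapStart = -1;         // 0-based, half-open, on seq
    int gapEnd = -1;
    int outLeft = 0;           // outward bases prepended / appended
    int outRight = 0;
    TaskResult tasks[4];       // T1..T4
};

// Merge two partial contigs (mode 0): suffix of c1 against prefix of
// revcomp(c3); longest admissible overlap. ok=false if none.
struct MergeRes {
    bool ok = false;
    int overlap = 0;
    Codes seq;
};
MergeRes merge_partial_core(const Codes& c1, const Codes& c3,
                            int rl2, const PairParams& p);

// Combine four finished tasks under all three strict modes (+ outward).
PairOutcome finalize_core(const TaskResult tasks[4], const PairParams& p);

// Run the four extension tasks of pair `pairIdx` (reads 2*pairIdx and
// 2*pairIdx+1 of the index) to completion and finalize.
PairOutcome run_pair_core(const KmerIndex& idx, std::size_t pairIdx,
                          const PairParams& p);

}  // namespace plrex
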