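#include "core.h"

#include <cmath>

namespace plrex {

// ---------- sequence core ----------

int iupac_to_code(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't':
        case 'U': case 'u': return 3;
        // ambiguity codes: lexicographically smallest compatible base
        case 'R': case 'r': return 0;  // A/G
        case 'Y': case 'y': return 1;  // C/T
        case 'S': case 's': return 1;  // C/G
        case 'W': case 'w': return 0;  // A/T
        case 'K': case 'k': return 2;  // G/T
        case 'M': case 'm': return 0;  // A/C
        case 'B': case 'b': return 1;  // C/G/T
        case 'D': case 'd': return 0;  // A/G/T
        case 'H': case 'h': return 0;  // A/C/T
        case 'V': case 'v': return 0;  // A/C/G
        case 'N': case 'n': return 0;
        default: return -1;
    }
}

Codes encode_string(const std::string& s) {
    if (s.empty()) throw std::invalid_argument("empty sequence");
    Codes out(s.size());
    for (std::size_t i = 0; i < s.size(); ++i) {
        int c = iupac_to_code(s[i]);
        if (c < 0)
            throw std::invalid_argument(
                std::string("non-IUPAC character '") + s[i] + "' at position " +
                std::to_string(i + 1));
        out[i] = static_cast<uint8_t>(c);
    }
    return out;
}

std::string decode_codes(const Codes& v) {
    static const char* b = "ACGT";
    std::string s(v.size(), 'A');
    for (std::size_t i = 0; i < v.size(); ++i) s[i] = b[v[i]];
    return s;
}

Codes revcomp_codes(const Codes& v) {
    Codes out(v.size());
    for (std::size_t i = 0; i < v.size(); ++i)
        out[v.size() - 1 - i] = static_cast<uint8_t>(3 - v[i]);
    return out;
}

// ---------- minhash ----------

HashFamily make_family(int h, int k, uint64_t seed) {
    if (h < 1) throw std::invalid_argument("h must be >= 1");
    if (k < 1 || k > 32) throw std::invalid_argument("k must be in [1, 32]");
    HashFamily fam;
    fam.h = h;
    fam.k = k;
    fam.seeds.resize(h);
    uint64_t state = seed;
    for (int x = 0; x < h; ++x) fam.seeds[x] = splitmix64(state);
    return fam;
}

std::vector<uint64_t> signature_of(const uint8_t* s, int len, const HashFamily& fam) {
    const int k = fam.k;
    if (len < k) throw std::invalid_argument("sequence shorter than k");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int rshift = 2 * (k - 1);
    std::vector<uint64_t> mins(fam.h, UINT64_MAX);
    uint64_t fwd = 0, rev = 0;
    for (int i = 0; i < len; ++i) {
        uint64_t c = s[i];
        fwd = ((fwd << 2) | c) & mask;
        rev = (rev >> 2) | ((3ULL - c) << rshift);
        if (i >= k - 1) {
            uint64_t g = mix64(std::min(fwd, rev));
            for (int x = 0; x < fam.h; ++x) {
                uint64_t v = table_hash(g, fam.seeds[x]);
                mins[x] = v < mins[x] ? v : mins[x];
            }
        }
    }
    return mins;
}

void KmerIndex::Table::build(
    const std::vector<std::pair<uint64_t, uint32_t>>& sorted, int maxBucket,
    long& nCapped) {
    std::size_t nKeys = 0;
    for (std::size_t i = 0; i < sorted.size();) {
        std::size_t j = i;
        while (j < sorted.size() && sorted[j].first == sorted[i].first) ++j;
        ++nKeys;
        i = j;
    }
    std::size_t cap = 16;
    while (cap < nKeys * 2) cap <<= 1;   // load factor <= 0.5
    mask = cap - 1;
    slots.assign(cap, Slot{0, 0, 0});
    ids.clear();
    ids.reserve(sorted.size());
    for (std::size_t i = 0; i < sorted.size();) {
        std::size_t j = i;
        while (j < sorted.size() && sorted[j].first == sorted[i].first) ++j;
        std::size_t take = j - i;
        if (static_cast<long>(take) > maxBucket) {
            take = maxBucket;
            ++nCapped;
        }
        uint64_t key = sorted[i].first;
        uint64_t h = key & mask;
        while (slots[h].cnt != 0) h = (h + 1) & mask;
        slots[h] = Slot{key, static_cast<uint32_t>(ids.size()),
                        static_cast<uint32_t>(take)};
        for (std::size_t q = i; q < i + take; ++q)
            ids.push_back(sorted[q].second);
        i = j;
    }
}

void KmerIndex::build(const std::vector<Codes>& reads, const HashFamily& fam_,
                      int maxBucket_) {
    fam = fam_;
    maxBucket = maxBucket_;
    nReads = reads.size();
    lens.resize(nReads);
    offsets.resize(nReads);
    std::size_t total = 0;
    for (std::size_t i = 0; i < nReads; ++i) total += reads[i].size();
    arena.resize(total);
    arenaRC.resize(total);
    packOffsets.resize(nReads);
    std::size_t off = 0, poff = 0;
    for (std::size_t i = 0; i < nReads; ++i) {
        lens[i] = static_cast<int>(reads[i].size());
        offsets[i] = off;
        packOffsets[i] = poff;
        off += reads[i].size();
        poff += (reads[i].size() + 31) / 32 + 1;
    }
    packedF.resize(poff);
    packedR.resize(poff);
    for (std::size_t i = 0; i < nReads; ++i) {
        std::memcpy(arena.data() + offsets[i], reads[i].data(),
                    reads[i].size());
        Codes rc = revcomp_codes(reads[i]);
        std::memcpy(arenaRC.data() + offsets[i], rc.data(), rc.size());
        auto pf = pack_codes(reads[i].data(), reads[i].size());
        auto pr = pack_codes(rc.data(), rc.size());
        std::copy(pf.begin(), pf.end(), packedF.begin() + packOffsets[i]);
        std::copy(pr.begin(), pr.end(), packedR.begin() + packOffsets[i]);
    }

    std::vector<std::vector<std::pair<uint64_t, uint32_t>>> raw(fam.h);
    for (int x = 0; x < fam.h; ++x) raw[x].reserve(nReads);
    nShortSkipped = 0;
    for (std::size_t i = 0; i < nReads; ++i) {
        if (lens[i] < fam.k) {
            ++nShortSkipped;
            continue;
        }
        auto sig = signature_of(read_ptr(i), lens[i], fam);
        for (int x = 0; x < fam.h; ++x)
            raw[x].emplace_back(sig[x], static_cast<uint32_t>(i));
    }

    tables.assign(fam.h, Table());
    nCappedKeys = 0;
    for (int x = 0; x < fam.h; ++x) {
        auto& v = raw[x];
        std::sort(v.begin(), v.end());
        tables[x].build(v, maxBucket, nCappedKeys);
        v.clear();
        v.shrink_to_fit();
    }
}

std::vector<uint32_t> KmerIndex::lookup(int table, uint64_t key) const {
    auto hit = tables[table].find(key);
    return std::vector<uint32_t>(hit.first, hit.first + hit.second);
}

std::vector<uint32_t> KmerIndex::query(const uint8_t* s, int len) const {
    auto sig = signature_of(s, len, fam);
    std::vector<uint32_t> out;
    out.reserve(64);
    for (int x = 0; x < fam.h; ++x) {
        auto hit = tables[x].find(sig[x]);
        out.insert(out.end(), hit.first, hit.first + hit.second);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
    return out;
}

// ---------- pairwise alignment ----------

static inline bool better_aln(const ShiftAln& a, const ShiftAln& b) {
    // is a better than b?
    if (a.mism != b.mism) return a.mism < b.mism;
    if (a.overlap != b.overlap) return a.overlap > b.overlap;
    if (a.shift != b.shift) return a.shift < b.shift;
    return !a.rc && b.rc;
}

std::vector<uint64_t> pack_codes(const uint8_t* s, int n) {
    std::vector<uint64_t> w((n + 31) / 32 + 1, 0);
    for (int i = 0; i < n; ++i)
        w[i / 32] |= static_cast<uint64_t>(s[i]) << (2 * (i % 32));
    return w;
}

long hamming_packed(const uint64_t* a, int s, const uint64_t* b, int ov,
                    long limit) {
    const int nw = (ov + 31) / 32;
    const int q0 = s / 32;
    const int bshift = 2 * (s % 32);
    long mm = 0;
    for (int k = 0; k < nw; ++k) {
        uint64_t aw = a[q0 + k] >> bshift;
        if (bshift) aw |= a[q0 + k + 1] << (64 - bshift);
        uint64_t d = aw ^ b[k];
        int bases = std::min(32, ov - 32 * k);
        if (bases < 32) d &= (1ULL << (2 * bases)) - 1;
        if (d) {
            d = (d | (d >> 1)) & 0x5555555555555555ULL;
            mm += popcount64(d);
            if (mm > limit) return mm;
        }
    }
    return mm;
}

ShiftAln best_alignment_packed(const uint64_t* anchor, int alen,
                               const uint64_t* candF, const uint64_t* candR,
                               int clen, int maxMm, double minOvFrac) {
    ShiftAln best;
    const int minOv = static_cast<int>(std::ceil(minOvFrac * clen - 1e-9));
    for (int orient = 0; orient < 2; ++orient) {
        const uint64_t* c = orient == 0 ? candF : candR;
        for (int shift = 0; shift < alen; ++shift) {
            int ov = std::min(alen - shift, clen);
            if (ov < 1 || ov < minOv) break;  // overlap only shrinks
            // once a mismatch-free best exists, no smaller overlap can win
            if (best.valid && best.mism == 0 && ov <= best.overlap) break;
            long mm = hamming_packed(anchor, shift, c, ov, maxMm);
            if (mm > maxMm) continue;
            ShiftAln cur{shift, ov, static_cast<int>(mm), orient == 1, true};
            if (!best.valid || better_aln(cur, best)) best = cur;
        }
    }
    return best;
}

ShiftAln best_alignment_codes(const uint8_t* anchor, int alen,
                              const uint8_t* cand, int clen,
                              int maxMm, double minOvFrac) {
    auto aw = pack_codes(anchor, alen);
    auto cf = pack_codes(cand, clen);
    Codes rc(cand, cand + clen);
    rc = revcomp_codes(rc);
    auto cr = pack_codes(rc.data(), clen);
    return best_alignment_packed(aw.data(), alen, cf.data(), cr.data(), clen,
                                 maxMm, minOvFrac);
}

// ---------- MSA ----------

void Msa::rebuild_counts() {
    ncol = anchorLen;
    for (const auto& m : members)
        ncol = std::max(ncol, m.shift + static_cast<int>(m.seq.size()));
    counts.assign(ncol, {0, 0, 0, 0});
    for (int i = 0; i < anchorLen; ++i) counts[i][anchor[i]]++;
    for (const auto& m : members)
        for (std::size_t j = 0; j < m.seq.size(); ++j)
            counts[m.shift + j][m.seq[j]]++;
}

Codes Msa::consensus() const {
    Codes out(ncol, 0);
    for (int i = 0; i < ncol; ++i) {
        int bestB = 0, bestC = counts[i][0];
        for (int b = 1; b < 4; ++b)
            if (counts[i][b] > bestC) {  // strict: ties keep smaller base
                bestC = counts[i][b];
                bestB = b;
            }
        out[i] = static_cast<uint8_t>(bestB);
    }
    return out;
}

Msa build_msa_core(Codes anchor, std::vector<MsaMember> members) {
    Msa m;
    m.anchorLen = static_cast<int>(anchor.size());
    m.anchor = std::move(anchor);
    m.members = std::move(members);
    for (const auto& mem : m.members)
        if (mem.shift < 0) throw std::invalid_argument("negative shift in MSA");
    m.rebuild_counts();
    return m;
}

int refine_msa_pass(Msa& m, double frac) {
    if (m.members.empty()) return 0;
    Codes cons = m.consensus();
    std::vector<char> remove(m.members.size(), 0);
    for (int col = 0; col < m.anchorLen; ++col) {
        int cov = m.coverage(col);
        int cb = cons[col];
        for (int x = 0; x < 4; ++x) {
            if (x == cb) continue;
            int cnt = m.counts[col][x];
            if (cnt == 0) continue;
            if (static_cast<double>(cnt) + 1e-9 < frac * cov) continue;
            bool anchorHasX = (m.anchor[col] == x);
            for (std::size_t mi = 0; mi < m.members.size(); ++mi) {
                const auto& mem = m.members[mi];
                if (col < mem.shift ||
                    col >= mem.shift + static_cast<int>(mem.seq.size()))
                    continue;
                int b = mem.seq[col - mem.shift];
                if (anchorHasX ? (b != x) : (b == x)) remove[mi] = 1;
            }
        }
    }
    int nRemoved = 0;
    std::vector<MsaMember> kept;
    kept.reserve(m.members.size());
    for (std::size_t mi = 0; mi < m.members.size(); ++mi) {
        if (remove[mi])
            ++nRemoved;
        else
            kept.push_back(std::move(m.members[mi]));
    }
    if (nRemoved > 0) {
        m.members = std::move(kept);
        m.rebuild_counts();
    }
    return nRemoved;
}

int refine_msa_core(Msa& m, double frac, int passes) {
    int total = 0;
    for (int p = 0; p < passes; ++p) {
        int r = refine_msa_pass(m, frac);
        total += r;
        if (r == 0) break;
    }
    return total;
}

ExtendRes extend_from_msa(const Msa& m, int stepsize, int minCov) {
    ExtendRes res;
    int i = m.anchorLen;
    if (m.ncol <= i) return res;             // no columns beyond the anchor
    if (m.coverage(i) < minCov) return res;  // first new column unreliable
    int j = i;
    while (j + 1 < m.ncol && (j + 1) - i <= stepsize - 1 &&
           m.coverage(j + 1) >= minCov)
        ++j;
    Codes cons = m.consensus();
    res.ok = true;
    res.appended.assign(cons.begin() + i, cons.begin() + j + 1);
    return res;
}

}  // namespace plrex
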