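#include "core.h"

#include <cmath>

// Per-pair orchestration: four extension tasks advanced in lockstep with
// paired-candidate exchange between partner tasks, followed by strict-mode
// finalization. T1 (start S1, target RC2) and T3 (start S2, target RC1) are
// primary; T2 (start RC2) and T4 (start RC1) are auxiliary and stop when
// their partner stops.

namespace plrex {

namespace {

struct CandEntry {
    uint32_t id;
    ShiftAln aln;
    int filterOverlap = 0;  // candidate span inside the alignment region
    bool rescue = false;
};

struct Task {
    bool primary = false;
    int partner = -1;       // index into task array
    int state = TASK_ACTIVE;
    int startLen = 0;
    int matePos = -1;
    int nextMateCheck = 0;  // monotone scan frontier ("first position" rule)
    Codes contig;
    Codes mateTarget;       // primary only
};

// Overlap-based filter with paired rescue. Keep entries whose mate sits in
// the partner task's retrieved candidate set (the set C, before alignment
// admissibility: a mate positioned left of the partner's window is
// retrieved but not alignable, yet still confirms the pair). Over the rest
// compute T = max_i(floor(O_i*10)/10) and drop O_i < T. O_i is the
// candidate's span inside the alignment region relative to |S|: an
// admissible indel-free placement always accounts for the whole candidate
// (bases protruding past the window feed the extension columns), so
// O_i = |candidate| / |S|. The rule therefore prunes relatively short
// candidates and leaves uniform-length data untouched; dropping protruding
// equal-length candidates instead would starve the extension columns of
// coverage whenever insert-size variance breaks paired rescue.
// All arithmetic exact: floor(O_i*10) = (overlap*10) / |S| in integers.
void filter_batch(std::vector<CandEntry>& batch, int anchorLen,
                  const std::vector<uint32_t>* partnerIds) {
    if (batch.empty()) return;
    if (partnerIds) {
        for (auto& e : batch) {
            uint32_t mate = e.id ^ 1u;
            e.rescue = std::binary_search(partnerIds->begin(),
                                          partnerIds->end(), mate);
        }
    } else {
        for (auto& e : batch) e.rescue = false;
    }
    long t10 = -1;
    for (const auto& e : batch)
        if (!e.rescue)
            t10 = std::max(t10, static_cast<long>(e.filterOverlap) * 10 / anchorLen);
    if (t10 < 0) return;  // all rescued
    std::vector<CandEntry> kept;
    kept.reserve(batch.size());
    for (const auto& e : batch) {
        // O_i < T  <=>  overlap*10 < t10*|S|
        if (e.rescue ||
            static_cast<long>(e.filterOverlap) * 10 >= t10 * anchorLen)
            kept.push_back(e);
    }
    batch = std::move(kept);
}

// Scan new admissible mate placements in ascending order; on success the
// contig is truncated at the mate and the mate's original bases written over
// the tail.
bool check_mate(Task& t, const PairParams& p) {
    const int mlen = static_cast<int>(t.mateTarget.size());
    const long maxMm = static_cast<long>(
        std::ceil(p.mateMaxMismatchFrac * mlen - 1e-9));
    int pFirst = std::max(t.nextMateCheck, p.minLen - mlen);
    if (pFirst < 0) pFirst = 0;
    int pLast = std::min(static_cast<int>(t.contig.size()) - mlen,
                         p.maxLen - mlen);
    for (int pos = pFirst; pos <= pLast; ++pos) {
        long mm = hamming_codes(t.contig.data() + pos, t.mateTarget.data(),
                                mlen, maxMm);
        if (mm <= maxMm) {
            t.state = TASK_MATE_FOUND;
            t.matePos = pos;
            t.contig.resize(pos + mlen);
            std::copy(t.mateTarget.begin(), t.mateTarget.end(),
                      t.contig.begin() + pos);
            return true;
        }
    }
    t.nextMateCheck = std::max(t.nextMateCheck, pLast + 1);
    return false;
}

}  // namespace

MergeRes merge_partial_core(const Codes& c1, const Codes& c3, int rl2,
                            const PairParams& p) {
    MergeRes res;
    const int L1 = static_cast<int>(c1.size());
    const int L3 = static_cast<int>(c3.size());
    Codes rc3 = revcomp_codes(c3);
    int ovHi = std::min({L1, L3, L1 + L3 - p.minLen});
    int ovLo = std::max(p.mergeMinOverlap, L1 + L3 - p.maxLen);
    for (int ov = ovHi; ov >= ovLo; --ov) {  // longest admissible overlap wins
        long maxMm = static_cast<long>(std::floor(p.mergeMaxMismatchFrac * ov + 1e-9));
        long mm = hamming_codes(c1.data() + (L1 - ov), rc3.data(), ov, maxMm);
        if (mm > maxMm) continue;
        res.ok = true;
        res.overlap = ov;
        res.seq = c1;
        res.seq.insert(res.seq.end(), rc3.begin() + ov, rc3.end());
        // original mate bases take precedence at the far end
        int keep = std::min(rl2, static_cast<int>(res.seq.size()));
        std::copy(rc3.end() - keep, rc3.end(), res.seq.end() - keep);
        return res;
    }
    return res;
}

PairOutcome finalize_core(const TaskResult tasks[4], const PairParams& p) {
    PairOutcome out;
    for (int i = 0; i < 4; ++i) out.tasks[i] = tasks[i];
    const TaskResult& t1 = tasks[0];
    const TaskResult& t2 = tasks[1];
    const TaskResult& t3 = tasks[2];
    const TaskResult& t4 = tasks[3];
    const int rl1 = t1.startLen;
    const int rl2 = t3.startLen;
    const bool t1f = (t1.state == TASK_MATE_FOUND);
    const bool t3f = (t3.state == TASK_MATE_FOUND);

    // strict mode 2: both directions found the mate with identical gap length
    // and (near-)identical gap sequence; T1's contig is the result.
    if (t1f && t3f) {
        Codes g1(t1.contig.begin() + rl1, t1.contig.begin() + t1.matePos);
        Codes g3(t3.contig.begin() + rl2, t3.contig.begin() + t3.matePos);
        if (g1.size() == g3.size()) {
            Codes g3rc = revcomp_codes(g3);
            long mm = g1.empty() ? 0
                                 : hamming_codes(g1.data(), g3rc.data(),
                                                 g1.size(), -1);
            if (mm <= p.strict2MaxHamming) {
                out.connected[2] = true;
                out.rule[2] = "both_agree";
            }
        }
    }

    // strict mode 1: mode-2 rule, else exactly one primary task found the
    // mate and the other task's partial extension confirms its gap.
    if (out.connected[2]) {
        out.connected[1] = true;
        out.rule[1] = out.rule[2];
    } else if (t1f != t3f) {
        const TaskResult& tf = t1f ? t1 : t3;   // found
        const TaskResult& to = t1f ? t3 : t1;   // other, partial
        const int rlF = tf.startLen, rlO = to.startLen;
        const int L = static_cast<int>(tf.contig.size());
        const int Lo = static_cast<int>(to.contig.size());
        const int s = tf.matePos - rlF;          // gap size
        // On the found task's coordinates, revcomp(other contig) is
        // right-aligned (both end in the same mate read); its partial gap
        // covers [L - Lo, L - rlO).
        const int ovStart = std::max(rlF, L - Lo);
        const int ovEnd = L - rlO;
        const int ovLen = ovEnd - ovStart;
        if (ovLen >= 0 &&
            static_cast<double>(ovLen) + 1e-9 >= p.strict1OverlapFrac * s) {
            Codes rcO = revcomp_codes(to.contig);
            int matches = 0;
            for (int q = ovStart; q < ovEnd; ++q)
                if (tf.contig[q] == rcO[q - (L - Lo)]) ++matches;
            if (static_cast<double>(matches) + 1e-9 >=
                p.strict1MatchFrac * ovLen) {
                out.connected[1] = true;
                out.rule[1] = t1f ? "t1_confirmed" : "t3_confirmed";
            }
        }
    }

    // strict mode 0: any found primary task connects; otherwise try to merge
    // the two partial contigs.
    MergeRes merged;
    if (t1f || t3f) {
        out.connected[0] = true;
        out.rule[0] = t1f ? (t3f ? "both" : "t1") : "t3";
    } else {
        merged = merge_partial_core(t1.contig, t3.contig, rl2, p);
        if (merged.ok) {
            out.connected[0] = true;
            out.rule[0] = "merged";
        }
    }

    // Result sequence on read 1's strand, shared by every connected mode:
    // T1's contig if T1 found the mate (revcomp of T3's otherwise), or the
    // merged sequence. revcomp(T3 contig) = S1 + revcomp(gap3) + RC2.
    if (t1f)
        out.seq = t1.contig;
    else if (t3f)
        out.seq = revcomp_codes(t3.contig);
    else if (merged.ok)
        out.seq = merged.seq;
    if (!out.seq.empty()) {
        out.gapStart = rl1;
        out.gapEnd = static_cast<int>(out.seq.size()) - rl2;
    }

    // Outward extension: T4's bases beyond RC1 belong left of read 1
    // (reverse strand, so reverse-complemented and prepended); T2 starts
    // from RC2, which already lies on read 1's strand at the 3' end, so its
    // extension is appended as-is.
    if (p.outward && !out.seq.empty() && (out.connected[0] ||
        out.connected[1] || out.connected[2])) {
        int g4 = static_cast<int>(t4.contig.size()) - t4.startLen;
        int takeL = std::min(g4, p.outwardCap);
        if (takeL > 0) {
            Codes ext4(t4.contig.begin() + t4.startLen,
                       t4.contig.begin() + t4.startLen + takeL);
            Codes left = revcomp_codes(ext4);
            out.seq.insert(out.seq.begin(), left.begin(), left.end());
            out.outLeft = takeL;
            out.gapStart += takeL;
            out.gapEnd += takeL;
        }
        int g2 = static_cast<int>(t2.contig.size()) - t2.startLen;
        int takeR = std::min(g2, p.outwardCap);
        if (takeR > 0) {
            out.seq.insert(out.seq.end(), t2.contig.begin() + t2.startLen,
                           t2.contig.begin() + t2.startLen + takeR);
            out.outRight = takeR;
        }
    }
    return out;
}

PairOutcome run_pair_core(const KmerIndex& idx, std::size_t pairIdx,
                          const PairParams& p) {
    const uint32_t id1 = static_cast<uint32_t>(2 * pairIdx);
    const uint32_t id2 = id1 + 1;
    Codes s1(idx.read_ptr(id1), idx.read_ptr(id1) + idx.read_len(id1));
    Codes s2(idx.read_ptr(id2), idx.read_ptr(id2) + idx.read_len(id2));

    Task tasks[4];
    if (static_cast<int>(s1.size()) < idx.fam.k ||
        static_cast<int>(s2.size()) < idx.fam.k) {
        // pair unextendable: reads too short to query the index
        TaskResult tr[4];
        for (int i = 0; i < 4; ++i) {
            tr[i].state = TASK_FAILED;
            tr[i].startLen = (i == 0 || i == 3) ? static_cast<int>(s1.size())
                                                : static_cast<int>(s2.size());
        }
        tr[0].contig = s1;
        tr[1].contig = revcomp_codes(s2);
        tr[2].contig = s2;
        tr[3].contig = revcomp_codes(s1);
        return finalize_core(tr, p);
    }

    Codes rc1 = revcomp_codes(s1);
    Codes rc2 = revcomp_codes(s2);
    tasks[0] = Task{true, 1, TASK_ACTIVE, static_cast<int>(s1.size()), -1, 0,
                    s1, rc2};
    tasks[1] = Task{false, 0, TASK_ACTIVE, static_cast<int>(s2.size()), -1, 0,
                    rc2, Codes()};
    tasks[2] = Task{true, 3, TASK_ACTIVE, static_cast<int>(s2.size()), -1, 0,
                    s2, rc1};
    tasks[3] = Task{false, 2, TASK_ACTIVE, static_cast<int>(s1.size()), -1, 0,
                    rc1, Codes()};

    std::vector<CandEntry> batches[4];
    std::vector<uint32_t> retrIds[4];   // retrieved this iteration
    std::vector<uint32_t> cumIds[4];    // retrieved over the task's run
    std::vector<uint32_t> mergeBuf;
    const int iterCap = p.maxLen + 1;

    for (int iter = 0; iter < iterCap; ++iter) {
        bool anyActive = false;
        bool activeAtStart[4];
        for (int ti = 0; ti < 4; ++ti) {
            activeAtStart[ti] = (tasks[ti].state == TASK_ACTIVE);
            if (activeAtStart[ti]) anyActive = true;
        }
        if (!anyActive) break;

        // ---- gather: retrieve and align candidates for every active task;
        // retrIds keeps the full retrieved set C (minus the pair's own
        // reads) for the partner's paired-rescue lookup
        for (int ti = 0; ti < 4; ++ti) {
            batches[ti].clear();
            retrIds[ti].clear();
            if (!activeAtStart[ti]) continue;
            Task& t = tasks[ti];
            const uint8_t* win = t.contig.data() + (t.contig.size() - t.startLen);
            auto ids = idx.query(win, t.startLen);
            auto packedWin = pack_codes(win, t.startLen);
            for (uint32_t cid : ids) {
                if (cid == id1 || cid == id2) continue;  // self pair excluded
                retrIds[ti].push_back(cid);
                int clen = idx.read_len(cid);
                if (clen < 1) continue;
                ShiftAln a = best_alignment_packed(
                    packedWin.data(), t.startLen, idx.packed_fwd(cid),
                    idx.packed_rc(cid), clen, p.maxMismatches,
                    p.minOverlapFrac);
                if (!a.valid) continue;
                batches[ti].push_back(CandEntry{cid, a, clen, false});
            }
            // accumulate the task's candidate list (ids stay sorted unique)
            mergeBuf.clear();
            std::set_union(cumIds[ti].begin(), cumIds[ti].end(),
                           retrIds[ti].begin(), retrIds[ti].end(),
                           std::back_inserter(mergeBuf));
            cumIds[ti].swap(mergeBuf);
        }

        // ---- per-task: filter, MSA, extend, mate check
        for (int ti = 0; ti < 4; ++ti) {
            if (!activeAtStart[ti]) continue;
            Task& t = tasks[ti];
            const std::vector<uint32_t>* partnerIds = nullptr;
            if (activeAtStart[t.partner]) partnerIds = &cumIds[t.partner];
            filter_batch(batches[ti], t.startLen, partnerIds);

            const uint8_t* winPtr =
                t.contig.data() + (t.contig.size() - t.startLen);
            Codes window(winPtr, winPtr + t.startLen);
            std::vector<MsaMember> members;
            members.reserve(batches[ti].size());
            for (const auto& e : batches[ti]) {
                MsaMember m;
                m.id = static_cast<int>(e.id);
                m.shift = e.aln.shift;
                m.rc = e.aln.rc;
                const uint8_t* src = e.aln.rc ? idx.read_rc_ptr(e.id)
                                              : idx.read_ptr(e.id);
                m.seq.assign(src, src + idx.read_len(e.id));
                members.push_back(std::move(m));
            }
            Msa msa = build_msa_core(window, std::move(members));
            refine_msa_core(msa, p.refineFrac, p.refinePasses);
            ExtendRes ext = extend_from_msa(msa, p.stepsize, p.minCoverage);
            if (!ext.ok) {
                t.state = TASK_FAILED;
                continue;
            }
            t.contig.insert(t.contig.end(), ext.appended.begin(),
                            ext.appended.end());
            if (t.primary && check_mate(t, p)) continue;
            if (static_cast<int>(t.contig.size()) >= p.maxLen)
                t.state = t.primary ? TASK_FAILED : TASK_STOPPED;
        }

        // ---- auxiliary tasks stop as soon as their partner stops
        for (int ti : {1, 3}) {
            if (tasks[ti].state == TASK_ACTIVE &&
                tasks[tasks[ti].partner].state != TASK_ACTIVE)
                tasks[ti].state = TASK_STOPPED;
        }
    }

    TaskResult tr[4];
    for (int i = 0; i < 4; ++i) {
        tr[i].state = tasks[i].state == TASK_ACTIVE ? TASK_STOPPED
                                                    : tasks[i].state;
        tr[i].startLen = tasks[i].startLen;
        tr[i].matePos = tasks[i].matePos;
        tr[i].contig = std::move(tasks[i].contig);
    }
    return finalize_core(tr, p);
}

}  // namespace plrex
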