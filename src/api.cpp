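#include <Rcpp.h>
#include "core.h"

using namespace Rcpp;
using namespace plrex;

// ---------------- helpers ----------------

static std::string u64_hex(uint64_t v) {
    char buf[17];
    std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
    return std::string(buf);
}

static uint64_t hex_u64(const std::string& s) {
    uint64_t v = 0;
    for (char c : s) {
        int d;
        if (c >= '0' && c <= '9') d = c - '0';
        else if (c >= 'a' && c <= 'f') d = c - 'a' + 10;
        else if (c >= 'A' && c <= 'F') d = c - 'A' + 10;
        else stop("invalid hex key '%s'", s.c_str());
        v = (v << 4) | static_cast<uint64_t>(d);
    }
    return v;
}

static Codes encode_or_stop(const std::string& s) {
    try {
        return encode_string(s);
    } catch (const std::invalid_argument& e) {
        stop("invalid sequence: %s", e.what());
    }
}

static PairParams params_from_list(const List& par) {
    PairParams p;
    p.maxMismatches = as<int>(par["max_mismatches"]);
    p.minOverlapFrac = as<double>(par["min_overlap_frac"]);
    p.stepsize = as<int>(par["stepsize"]);
    p.minCoverage = as<int>(par["min_coverage"]);
    p.refineFrac = as<double>(par["refine_frac"]);
    p.refinePasses = as<int>(par["refine_passes"]);
    p.mateMaxMismatchFrac = as<double>(par["mate_max_mismatch_frac"]);
    p.minLen = as<int>(par["min_length"]);
    p.maxLen = as<int>(par["max_length"]);
    p.strict2MaxHamming = as<int>(par["strict2_max_hamming"]);
    p.strict1OverlapFrac = as<double>(par["strict1_overlap_frac"]);
    p.strict1MatchFrac = as<double>(par["strict1_match_frac"]);
    p.mergeMinOverlap = as<int>(par["merge_min_overlap"]);
    p.mergeMaxMismatchFrac = as<double>(par["merge_max_mismatch_frac"]);
    p.outward = as<bool>(par["outward"]);
    p.outwardCap = as<int>(par["outward_cap"]);
    return p;
}

static const char* state_name(int s) {
    switch (s) {
        case TASK_ACTIVE: return "active";
        case TASK_MATE_FOUND: return "mate_found";
        case TASK_FAILED: return "failed";
        default: return "stopped";
    }
}

// ---------------- seqcore ----------------

// [[Rcpp::export]]
IntegerVector cpp_encode(std::string text) {
    Codes c = encode_or_stop(text);
    return IntegerVector(c.begin(), c.end());
}

// [[Rcpp::export]]
std::string cpp_decode(IntegerVector codes) {
    Codes c(codes.size());
    for (int i = 0; i < codes.size(); ++i) {
        if (codes[i] < 0 || codes[i] > 3) stop("codes must be in 0..3");
        c[i] = static_cast<uint8_t>(codes[i]);
    }
    return decode_codes(c);
}

// [[Rcpp::export]]
RawVector cpp_pack(IntegerVector codes) {
    int n = codes.size();
    RawVector out((n + 3) / 4);
    for (int i = 0; i < out.size(); ++i) out[i] = 0;
    for (int i = 0; i < n; ++i) {
        if (codes[i] < 0 || codes[i] > 3) stop("codes must be in 0..3");
        out[i / 4] |= static_cast<Rbyte>(codes[i] << (2 * (i % 4)));
    }
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_unpack(RawVector packed, int len) {
    if (len < 0 || len > 4 * packed.size()) stop("length inconsistent with packed data");
    IntegerVector out(len);
    for (int i = 0; i < len; ++i)
        out[i] = (packed[i / 4] >> (2 * (i % 4))) & 3;
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        Codes c = encode_or_stop(as<std::string>(seqs[i]));
        out[i] = decode_codes(revcomp_codes(c));
    }
    out.names() = seqs.names();
    return out;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
    if (a.size() != b.size()) stop("sequences must have equal length");
    Codes ca = encode_or_stop(a), cb = encode_or_stop(b);
    return static_cast<int>(hamming_codes(ca.data(), cb.data(), ca.size(), -1));
}

// ---------------- minhash_index ----------------

// [[Rcpp::export]]
CharacterVector cpp_family_seeds(int h, int k, double seed) {
    HashFamily fam = make_family(h, k, static_cast<uint64_t>(seed));
    CharacterVector out(h);
    for (int x = 0; x < h; ++x) out[x] = u64_hex(fam.seeds[x]);
    return out;
}

// All h hash values of one canonical k-mer (direct, non-rolling).
// [[Rcpp::export]]
CharacterVector cpp_hash_kmer(std::string kmer, int h, int k, double seed) {
    HashFamily fam = make_family(h, k, static_cast<uint64_t>(seed));
    Codes c = encode_or_stop(kmer);
    if (static_cast<int>(c.size()) != k) stop("k-mer must have length k");
    uint64_t fwd = 0, rev = 0;
    for (int i = 0; i < k; ++i) {
        fwd = (fwd << 2) | c[i];
        rev = (rev << 2) | (3ULL - c[k - 1 - i]);
    }
    uint64_t g = mix64(std::min(fwd, rev));
    CharacterVector out(h);
    for (int x = 0; x < h; ++x) out[x] = u64_hex(table_hash(g, fam.seeds[x]));
    return out;
}

// [[Rcpp::export]]
CharacterVector cpp_signature(std::string seq, int h, int k, double seed) {
    HashFamily fam = make_family(h, k, static_cast<uint64_t>(seed));
    Codes c = encode_or_stop(seq);
    if (static_cast<int>(c.size()) < k) stop("sequence shorter than k");
    auto sig = signature_of(c.data(), c.size(), fam);
    CharacterVector out(h);
    for (int x = 0; x < h; ++x) out[x] = u64_hex(sig[x]);
    return out;
}

// [[Rcpp::export]]
List cpp_build_index(CharacterVector reads, int h, int k, double seed,
                     int max_bucket) {
    if (reads.size() == 0) stop("read set must be non-empty");
    std::vector<Codes> enc(reads.size());
    for (int i = 0; i < reads.size(); ++i)
        enc[i] = encode_or_stop(as<std::string>(reads[i]));
    HashFamily fam = make_family(h, k, static_cast<uint64_t>(seed));
    KmerIndex* idx = new KmerIndex();
    idx->build(enc, fam, max_bucket);
    XPtr<KmerIndex> ptr(idx, true);
    return List::create(_["ptr"] = ptr, _["n_reads"] = (double)idx->nReads,
                        _["n_short_skipped"] = (double)idx->nShortSkipped,
                        _["n_capped_keys"] = (double)idx->nCappedKeys);
}

static KmerIndex* index_from_sexp(SEXP ptr) {
    XPtr<KmerIndex> p(ptr);
    if (!p) stop("invalid index pointer (index objects do not survive sessions)");
    return p.get();
}

// [[Rcpp::export]]
IntegerVector cpp_query(SEXP ptr, std::string seq) {
    KmerIndex* idx = index_from_sexp(ptr);
    Codes c = encode_or_stop(seq);
    if (static_cast<int>(c.size()) < idx->fam.k)
        stop("sequence shorter than k");
    auto ids = idx->query(c.data(), c.size());
    IntegerVector out(ids.size());
    for (std::size_t i = 0; i < ids.size(); ++i) out[i] = ids[i] + 1;
    return out;
}

// [[Rcpp::export]]
IntegerVector cpp_index_lookup(SEXP ptr, int table, std::string key_hex) {
    KmerIndex* idx = index_from_sexp(ptr);
    if (table < 1 || table > idx->fam.h) stop("table out of range");
    auto ids = idx->lookup(table - 1, hex_u64(key_hex));
    IntegerVector out(ids.size());
    for (std::size_t i = 0; i < ids.size(); ++i) out[i] = ids[i] + 1;
    return out;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP ptr) {
    KmerIndex* idx = index_from_sexp(ptr);
    return List::create(_["n_reads"] = (double)idx->nReads,
                        _["h"] = idx->fam.h, _["k"] = idx->fam.k,
                        _["n_short_skipped"] = (double)idx->nShortSkipped,
                        _["n_capped_keys"] = (double)idx->nCappedKeys,
                        _["max_bucket"] = idx->maxBucket);
}

// [[Rcpp::export]]
CharacterVector cpp_index_reads(SEXP ptr, IntegerVector ids) {
    KmerIndex* idx = index_from_sexp(ptr);
    CharacterVector out(ids.size());
    for (int i = 0; i < ids.size(); ++i) {
        int id = ids[i] - 1;
        if (id < 0 || id >= (int)idx->nReads) stop("read id out of range");
        Codes c(idx->read_ptr(id), idx->read_ptr(id) + idx->read_len(id));
        out[i] = decode_codes(c);
    }
    return out;
}

// ---------------- pairwise_align ----------------

// [[Rcpp::export]]
SEXP cpp_best_alignment(std::string anchor, std::string cand,
                        int max_mismatches, double min_overlap_frac) {
    Codes a = encode_or_stop(anchor), c = encode_or_stop(cand);
    ShiftAln r = best_alignment_codes(a.data(), a.size(), c.data(), c.size(),
                                      max_mismatches, min_overlap_frac);
    if (!r.valid) return R_NilValue;
    return List::create(_["shift"] = r.shift, _["overlap"] = r.overlap,
                        _["mismatches"] = r.mism,
                        _["orientation"] = r.rc ? "revcomp" : "forward");
}

// ---------------- msa_engine ----------------

static Msa msa_from_args(const std::string& anchor, CharacterVector seqs,
                         IntegerVector shifts, LogicalVector rc) {
    if (seqs.size() != shifts.size() || seqs.size() != rc.size())
        stop("seqs, shifts and rc must have equal length");
    Codes a = encode_or_stop(anchor);
    std::vector<MsaMember> mem(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        if (shifts[i] < 0) stop("shift must be >= 0");
        mem[i].id = i;
        mem[i].shift = shifts[i];
        mem[i].rc = rc[i];
        Codes cs = encode_or_stop(as<std::string>(seqs[i]));
        mem[i].seq = rc[i] ? revcomp_codes(cs) : cs;
    }
    return build_msa_core(std::move(a), std::move(mem));
}

static List msa_to_list(const Msa& m) {
    IntegerMatrix counts(4, m.ncol);
    IntegerVector coverage(m.ncol);
    for (int i = 0; i < m.ncol; ++i) {
        for (int b = 0; b < 4; ++b) counts(b, i) = m.counts[i][b];
        coverage[i] = m.coverage(i);
    }
    counts.attr("dimnames") =
        List::create(CharacterVector::create("A", "C", "G", "T"), R_NilValue);
    return List::create(_["counts"] = counts, _["coverage"] = coverage,
                        _["anchor_len"] = m.anchorLen, _["ncol"] = m.ncol,
                        _["consensus"] = decode_codes(m.consensus()));
}

// [[Rcpp::export]]
List cpp_build_msa(std::string anchor, CharacterVector seqs,
                   IntegerVector shifts, LogicalVector rc) {
    return msa_to_list(msa_from_args(anchor, seqs, shifts, rc));
}

// Returns which members survive the column-content filter.
// [[Rcpp::export]]
LogicalVector cpp_refine_msa(std::string anchor, CharacterVector seqs,
                             IntegerVector shifts, LogicalVector rc,
                             double refine_frac, int passes) {
    Msa m = msa_from_args(anchor, seqs, shifts, rc);
    refine_msa_core(m, refine_frac, passes);
    LogicalVector keep(seqs.size(), false);
    for (const auto& mem : m.members) keep[mem.id] = true;
    return keep;
}

// [[Rcpp::export]]
std::string cpp_consensus_from_counts(IntegerMatrix counts) {
    if (counts.nrow() != 4) stop("counts must have 4 rows (A,C,G,T)");
    std::string out(counts.ncol(), 'A');
    static const char* b = "ACGT";
    for (int i = 0; i < counts.ncol(); ++i) {
        int bestB = 0, bestC = counts(0, i);
        for (int x = 1; x < 4; ++x)
            if (counts(x, i) > bestC) { bestC = counts(x, i); bestB = x; }
        out[i] = b[bestB];
    }
    return out;
}

// [[Rcpp::export]]
List cpp_extend_window(std::string window, CharacterVector seqs,
                       IntegerVector shifts, LogicalVector rc, int stepsize,
                       int min_coverage) {
    Msa m = msa_from_args(window, seqs, shifts, rc);
    ExtendRes res = extend_from_msa(m, stepsize, min_coverage);
    if (!res.ok)
        return List::create(_["status"] = "failed",
                            _["appended"] = R_NilValue,
                            _["new_window"] = R_NilValue);
    std::string app = decode_codes(res.appended);
    std::string nw = window.substr(app.size()) + app;
    return List::create(_["status"] = "extended", _["appended"] = app,
                        _["new_window"] = nw);
}

// ---------------- task_engine helpers ----------------

// Exact-arithmetic overlap filter: T = max_i(floor(O_i*10)/10) over unpaired
// entries, O_i = overlap/anchor_len; paired entries kept unconditionally.
// [[Rcpp::export]]
List cpp_filter_overlaps(IntegerVector overlaps, int anchor_len,
                         LogicalVector paired) {
    if (overlaps.size() != paired.size())
        stop("overlaps and paired must have equal length");
    if (anchor_len < 1) stop("anchor_len must be >= 1");
    long t10 = -1;
    for (int i = 0; i < overlaps.size(); ++i)
        if (!paired[i])
            t10 = std::max(t10, (long)overlaps[i] * 10 / anchor_len);
    LogicalVector keep(overlaps.size(), true);
    if (t10 >= 0)
        for (int i = 0; i < overlaps.size(); ++i)
            keep[i] = paired[i] || (long)overlaps[i] * 10 >= t10 * anchor_len;
    return List::create(_["keep"] = keep,
                        _["threshold"] = t10 < 0 ? NA_REAL : t10 / 10.0);
}

// ---------------- pair_finalize ----------------

// [[Rcpp::export]]
SEXP cpp_merge_partial(std::string contig1, std::string contig3, int rl2,
                       List params) {
    PairParams p = params_from_list(params);
    Codes c1 = encode_or_stop(contig1), c3 = encode_or_stop(contig3);
    MergeRes r = merge_partial_core(c1, c3, rl2, p);
    if (!r.ok) return R_NilValue;
    return List::create(_["sequence"] = decode_codes(r.seq),
                        _["overlap"] = r.overlap);
}

static List outcome_to_list(const PairOutcome& o) {
    List tasks(4);
    for (int i = 0; i < 4; ++i) {
        const TaskResult& t = o.tasks[i];
        tasks[i] = List::create(
            _["label"] = std::string("T") + std::to_string(i + 1),
            _["state"] = state_name(t.state),
            _["contig"] = decode_codes(t.contig),
            _["start_len"] = t.startLen,
            _["mate_pos"] = t.matePos < 0 ? NA_INTEGER : t.matePos);
    }
    tasks.names() = CharacterVector::create("T1", "T2", "T3", "T4");
    return List::create(
        _["connected"] = LogicalVector::create(o.connected[0], o.connected[1],
                                               o.connected[2]),
        _["rule"] = CharacterVector::create(
            o.rule[0].empty() ? NA_STRING : String(o.rule[0]),
            o.rule[1].empty() ? NA_STRING : String(o.rule[1]),
            o.rule[2].empty() ? NA_STRING : String(o.rule[2])),
        _["sequence"] = o.seq.empty() ? CharacterVector::create(NA_STRING)
                                      : CharacterVector::create(decode_codes(o.seq)),
        _["gap_start"] = o.gapStart < 0 ? NA_INTEGER : o.gapStart,
        _["gap_end"] = o.gapEnd < 0 ? NA_INTEGER : o.gapEnd,
        _["out_left"] = o.outLeft, _["out_right"] = o.outRight,
        _["tasks"] = tasks);
}

static int state_from_name(const std::string& s) {
    if (s == "active") return TASK_ACTIVE;
    if (s == "mate_found") return TASK_MATE_FOUND;
    if (s == "failed") return TASK_FAILED;
    if (s == "stopped") return TASK_STOPPED;
    stop("unknown task state '%s'", s.c_str());
}

// [[Rcpp::export]]
List cpp_finalize_pair(CharacterVector contigs, CharacterVector states,
                       IntegerVector start_lens, IntegerVector mate_pos,
                       List params) {
    if (contigs.size() != 4 || states.size() != 4 || start_lens.size() != 4 ||
        mate_pos.size() != 4)
        stop("finalization needs exactly four tasks (T1..T4)");
    PairParams p = params_from_list(params);
    TaskResult tr[4];
    for (int i = 0; i < 4; ++i) {
        tr[i].state = state_from_name(as<std::string>(states[i]));
        tr[i].startLen = start_lens[i];
        tr[i].matePos = mate_pos[i] == NA_INTEGER ? -1 : mate_pos[i];
        tr[i].contig = encode_or_stop(as<std::string>(contigs[i]));
    }
    return outcome_to_list(finalize_core(tr, p));
}

// ---------------- pipeline ----------------

// [[Rcpp::export]]
List cpp_extend_pair(SEXP ptr, double pair_index, List params) {
    KmerIndex* idx = index_from_sexp(ptr);
    std::size_t pi = static_cast<std::size_t>(pair_index) - 1;
    if (2 * pi + 1 >= idx->nReads) stop("pair index out of range");
    PairParams p = params_from_list(params);
    return outcome_to_list(run_pair_core(*idx, pi, p));
}

// [[Rcpp::export]]
List cpp_extend_all(SEXP ptr, List params, bool verbose) {
    KmerIndex* idx = index_from_sexp(ptr);
    if (idx->nReads % 2 != 0)
        stop("index must hold an even number of reads (interleaved pairs)");
    PairParams p = params_from_list(params);
    const std::size_t nPairs = idx->nReads / 2;

    CharacterVector seqs(nPairs);
    LogicalVector con0(nPairs), con1(nPairs), con2(nPairs);
    CharacterVector rule0(nPairs), rule1(nPairs), rule2(nPairs);
    CharacterVector st1(nPairs), st3(nPairs);
    IntegerVector gapStart(nPairs), gapEnd(nPairs), outL(nPairs), outR(nPairs);
    IntegerVector len1(nPairs), len3(nPairs);

    for (std::size_t i = 0; i < nPairs; ++i) {
        if ((i & 255) == 0) checkUserInterrupt();
        PairOutcome o = run_pair_core(*idx, i, p);
        con0[i] = o.connected[0];
        con1[i] = o.connected[1];
        con2[i] = o.connected[2];
        rule0[i] = o.rule[0].empty() ? NA_STRING : String(o.rule[0]);
        rule1[i] = o.rule[1].empty() ? NA_STRING : String(o.rule[1]);
        rule2[i] = o.rule[2].empty() ? NA_STRING : String(o.rule[2]);
        st1[i] = state_name(o.tasks[0].state);
        st3[i] = state_name(o.tasks[2].state);
        len1[i] = static_cast<int>(o.tasks[0].contig.size());
        len3[i] = static_cast<int>(o.tasks[2].contig.size());
        seqs[i] = o.seq.empty() ? NA_STRING : String(decode_codes(o.seq));
        gapStart[i] = o.gapStart < 0 ? NA_INTEGER : o.gapStart;
        gapEnd[i] = o.gapEnd < 0 ? NA_INTEGER : o.gapEnd;
        outL[i] = o.outLeft;
        outR[i] = o.outRight;
        if (verbose && ((i + 1) % 10000 == 0))
            Rcout << "  processed " << (i + 1) << " / " << nPairs
                  << " pairs\n";
    }
    return List::create(
        _["t1_state"] = st1, _["t3_state"] = st3,
        _["t1_len"] = len1, _["t3_len"] = len3,
        _["connected0"] = con0, _["connected1"] = con1, _["connected2"] = con2,
        _["rule0"] = rule0, _["rule1"] = rule1, _["rule2"] = rule2,
        _["sequence"] = seqs, _["gap_start"] = gapStart, _["gap_end"] = gapEnd,
        _["out_left"] = outL, _["out_right"] = outR);
}

// ---------------- simeval helper ----------------

// For each pair, counts admissible mate placements in the allowed length
// window (either direction), subject to a maximum hamming distance.
// genome oriented 5'->3'; starts 0-based; strand 1 means read 1 was drawn
// from the reverse strand of the fragment.
// [[Rcpp::export]]
IntegerMatrix cpp_count_mate_placements(std::string genome,
                                        IntegerVector starts,
                                        IntegerVector inserts,
                                        IntegerVector strands, int rl1,
                                        int rl2, int min_len, int max_len,
                                        int max_hamming) {
    Codes g = encode_or_stop(genome);
    Codes grc = revcomp_codes(g);
    const long G = static_cast<long>(g.size());
    const int n = starts.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        long st = starts[i];
        long ins = inserts[i];
        bool rev = strands[i] != 0;
        // read 1's strand coordinates: forward genome if rev == false,
        // else reverse-complement genome with origin at fragment end.
        // fragment on read-1 strand occupies [a1, a1+ins) of `ori`.
        const Codes& ori = rev ? grc : g;
        long a1 = rev ? (G - (st + ins)) : st;
        // direction 1: mate of read 1 ends the molecule; placement p from a1
        for (int dir = 0; dir < 2; ++dir) {
            long rdStart, mlen;
            const Codes* strand;
            long base;  // read start on its own strand
            if (dir == 0) {
                strand = &ori;
                base = a1;
                mlen = rl2;
                rdStart = a1 + ins - rl2;  // true mate location
            } else {
                // read 2's strand is the opposite orientation
                strand = rev ? &g : &grc;
                base = G - (a1 + ins);
                mlen = rl1;
                rdStart = base + ins - rl1;
            }
            (void)rdStart;
            const Codes& s = *strand;
            // true mate sequence on this strand
            long trueStart = base + ins - mlen;
            if (trueStart < 0 || trueStart + mlen > G) { out(i, dir) = NA_INTEGER; continue; }
            const uint8_t* mate = s.data() + trueStart;
            int count = 0;
            long pLo = std::max(base + min_len - mlen, 0L);
            long pHi = std::min(base + max_len - mlen,
                                G - mlen);
            for (long pos = pLo; pos <= pHi; ++pos) {
                long mm = hamming_codes(s.data() + pos, mate, mlen,
                                        max_hamming);
                if (mm <= max_hamming) ++count;
            }
            out(i, dir) = count;
        }
    }
    return out;
}
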