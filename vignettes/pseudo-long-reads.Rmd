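---
title: "Connecting paired-end reads into pseudo-long reads: methods and design"
author: "plrex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting paired-end reads into pseudo-long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plrex)
```

## The problem

Paired-end Illumina sequencing reads the two ends of a DNA fragment whose
total span (the *insert size*) is known only as a library-level
distribution. When the insert exceeds the summed read lengths, the interior
of the fragment is unobserved. `plrex` reconstructs that interior from the
redundancy of the data set itself — a small, targeted local assembly per
read pair — producing one *pseudo-long read* per connected pair. Overlapping
pairs (insert below twice the read length) are a different, easier problem
and are deliberately out of scope.

## The extension procedure

All reads are first 2-bit encoded (ambiguity codes are replaced
deterministically by the lexicographically smallest compatible base) and
indexed: for each of $h$ seeded hash functions, the minimum hash value over
a read's canonical $k$-mers is inserted into hash table $t_x$, keyed by
that minimum. Two sequences that share the minimizing $k$-mer under some
hash function collide in that table, so querying the $h$ tables with any
sequence yields, with high probability, the reads that share a $k$-mer
with it. Canonical $k$-mers (the lexicographic minimum of a $k$-mer and its
reverse complement) make retrieval strand-blind; each retrieved candidate is
afterwards aligned in both orientations.

For a pair (S1, S2) with reverse complements RC1, RC2, four extension
tasks run in lockstep: T1 extends S1 towards RC2 and T3 extends S2 towards
RC1 (the *primary* tasks); T2 and T4 start from RC2 and RC1 and exist to
confirm candidates through read pairing (and to supply the optional outward
extension). Each iteration of a task:

1. queries the index with the current window $S$ (the last read-length
   bases of the growing contig);
2. places every retrieved read on $S$ by an indel-free shifted alignment —
   every shift, both orientations, plain Hamming distance; placements need
   at least 50% overlap and at most 5 mismatches, and a candidate is never
   placed left of $S$ (extension is strictly 3');
3. filters candidates: a candidate whose mate was retrieved by the partner
   task is kept unconditionally; over the remaining unpaired candidates the
   decile threshold $T = \max_i(\lfloor 10\,O_i \rfloor / 10)$ of the
   relative spans $O_i$ is computed and candidates with $O_i < T$ are
   dropped;
4. stacks the survivors into a column-wise base-count MSA anchored on $S$
   and refines it: in any anchor column where a non-consensus base $x$
   reaches 0.3 of the column's coverage, members disagreeing with the
   anchor's side of the conflict are removed (candidates from inexact
   repeats produce exactly such columns);
5. appends the consensus of the columns beyond the anchor — at most
   `stepsize` (20) bases, only while every column has coverage at least
   `m` (3) — and slides the window;
6. for primary tasks, scans new admissible end positions in ascending
   order for the mate (Hamming distance at most
   $\lceil 0.05\,|{\rm mate}| \rceil$); the first admissible position wins
   and the mate's original bases are written over the tail.

A task ends when the mate is found, when no reliable extension exists, or
when the contig reaches the maximum allowed length. Auxiliary tasks stop as
soon as their partner stops. The pseudo-long read length window defaults to
$[\max(2\,\ell,\ \mu - 4\sigma),\ \mu + 4\sigma]$ for read length $\ell$
and insert mean/sd $\mu, \sigma$.

### Finalization: strict modes

* **Mode 2** connects a pair only when both primary tasks found their mate,
  with equal gap lengths and (by default) exactly agreeing gap sequences
  (T3's gap is reverse-complemented onto T1's coordinates first).
* **Mode 1** adds the case where exactly one task found the mate and the
  other's partial extension overlaps the filled gap by at least half the
  gap size with at least 95% matching positions.
* **Mode 0** accepts any mate-finding task, and otherwise merges the two
  partial contigs when a suffix of T1's contig overlaps a prefix of the
  reverse complement of T3's by at least 40 positions with at most 5%
  mismatches at a merged length inside the allowed window; the longest
  admissible overlap is used.

Everything is reported on read 1's strand, and positions covered by the
original reads always carry the original bases. With outward extension
enabled, T4's extra bases are reverse-complemented and prepended and T2's
are appended directly: T2 starts from RC2, which already lies on read 1's
strand at the 3' end of the molecule, so its 3' extension continues that
strand. Each side is truncated at `outward_cap` (default: the insert size,
which keeps products bounded without cutting off typical extensions).

## Parameters

| parameter | default | meaning |
|---|---|---|
| `n_tables` ($h$) | 48 | minhash tables; fewer saves memory, loses recall |
| `k` | 20 | k-mer size of the index (1–32) |
| `max_mismatches` | 5 | per-placement mismatch cap (absolute) |
| `min_overlap_frac` | 0.5 | placement overlap, fraction of candidate |
| `stepsize` | 20 | max bases appended per iteration |
| `min_coverage` ($m$) | 3 | min column coverage used for extension |
| `refine_frac` | 0.3 | column-content removal threshold (inclusive) |
| `refine_passes` | 1 | refinement rounds (fixed point stops early) |
| `mate_max_mismatch_frac` | 0.05 | mate acceptance tolerance |
| `strict2_max_hamming` | 0 | mode-2 gap disagreement tolerance |
| `strict1_overlap_frac` / `strict1_match_frac` | 0.5 / 0.95 | mode-1 confirmation |
| `merge_min_overlap` / `merge_max_mismatch_frac` | 40 / 0.05 | mode-0 merge |
| `max_bucket_size` | 1000 | per-key id cap against repeat blow-up |

The mate tolerance of 5% is a package choice: the downstream ambiguity
analysis uses a Hamming radius of 9 on 150 bp reads (6%), so 5% is the
same order of magnitude while staying conservative.

## Design choices in ambiguous corners

* **Overlap filter.** The decile rule compares each candidate's *span
  inside the alignment region* relative to $|S|$. For an indel-free
  placement the whole candidate lies inside that (rightward-open) region,
  so on uniform-length data every $O_i$ equals 1 and the rule is inactive;
  on mixed-length data (e.g. quality-trimmed reads) it prunes relatively
  short, low-information candidates. The clipped overlap
  $\min(|S|-{\rm shift}, |{\rm cand}|)$ is *not* used here: that reading
  would discard every protruding unpaired candidate whenever any unpaired
  candidate overlaps fully, starving the extension columns of coverage as
  soon as insert-size variance decouples the partner windows — and no
  high-variance library could then be connected at the rates this method
  demonstrably achieves. The clipped overlap still governs placement
  admissibility and the exposed `filter_candidates()` operates on whatever
  overlaps the caller supplies.
* **Paired rescue membership.** A candidate's mate counts as "present in
  the partner's candidate list" if the partner task has retrieved it at any
  iteration so far (before alignment admissibility). Accumulating the list
  stabilizes the two partner tasks against drifting apart: the task that
  falls behind finds its confirmations in the partner's past retrievals and
  catches up. Once the partner terminates, all candidates are treated as
  unpaired.
* **Contiguous extension.** The appended stretch ends at the last column
  of an unbroken run of coverage $\ge m$; skipping an under-covered column
  would fabricate sequence.
* **Ties.** Alignment ties prefer fewer mismatches, then larger overlap,
  then smaller shift, then forward orientation; consensus ties prefer the
  lexicographically smallest base. Both are arbitrary but fixed, making
  every run deterministic.
* **Refinement passes.** The column filter runs once by default
  (configurable); consensus is recomputed at each pass.
* **Mode-1 match fraction** is read as a fraction of the overlap's
  positions (not of the gap size); the two coincide at the default
  overlap threshold's boundary and the parameter is configurable.
* **Parallelism.** Pairs are independent; the engine processes them in a
  fixed order, so results are identical for any `threads` setting and any
  rerun with the same seed.

## The bundled simulator

`simulate_genome()` + `simulate_read_pairs()` emulate the data regime the
method targets: a uniform-random reference (optionally with injected
inexact repeats), fragments placed uniformly, insert sizes from a truncated
normal (the truncation excludes overlapping pairs), both strands equally
likely, and i.i.d. per-base substitution errors. Real Illumina data differ
in ways the simulator does not model — position-dependent error rates and
quality profiles, indel errors (rare), coverage biases (GC, mappability),
genuine genomic repeat structure and heterozygosity. Passing tests on these
simulations therefore demonstrate the correctness of the machinery and its
behavior under idealized noise, not performance on any particular real
library; repeat-induced ambiguity is exercised only through the explicit
repeat injection and the ambiguous-mate stratification
(`ambiguous_mate_positions()`, Hamming radius 9 by default).

Evaluation uses the full Levenshtein distance between each produced gap and
the true gap (`gap_edit_distance()`), the *gap error rate*
$\sum \mathrm{edits} / \sum |\mathrm{produced\ gaps}|$, and the *modified*
edit distance, which subtracts the absolute expected-vs-produced length
difference and thereby isolates wrong-base errors from wrong-length errors.

## Problem sizes used in the test suite

The automated checks run three simulation scales chosen to keep the suite
fast while leaving enough pairs for stable rates: a 200 kbp genome at 30x
with 150 bp reads and insert N(500, 150) truncated to [310, 1090] (the
wide-insert regime, ~20,000 pairs), a 400 kbp genome at 30x with 100 bp
reads and insert N(500, 10) (the tight-insert regime, ~60,000 pairs), and
a noiseless 100 kbp data set for exact-recovery checks. Unit tests use
10–50 kbp pilots. Error-rate checks are ratios and stabilize quickly with
the number of gap bases (the tight-insert run evaluates roughly 18 million
gap positions).

## Known limitations

* Indels inside reads are not modeled: placements are strictly
  substitution-only, as appropriate for Illumina chemistry; the package is
  not suitable for long-read data.
* Consensus bases carry no quality values, so connected products are
  written as FASTA.
* Repeats longer than the pseudo-long read length window are fundamentally
  ambiguous; the mate check takes the first admissible position, so such
  pairs tend to come out too short rather than too long. Strict modes 1–2
  remove most of these at the cost of fewer connections.
* The index lives in memory and is rebuilt per run; no on-disk persistence.
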