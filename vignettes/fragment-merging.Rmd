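---
title: "Merging ordered Sanger sequencing fragments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging ordered Sanger sequencing fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sangermerge)
```

## The problem

Sanger capillary sequencing produces reads of roughly 500–800 usable
nucleotides, so a long amplicon, a complete gene, or a small viral genome
(the package was shaped around hepatitis B virus, a circular genome of
3182–3248 nt depending on genotype) must be covered by several overlapping
fragments. The laboratory knows, from its primer scheme, the order of the
fragments and which were sequenced on the reverse strand. What remains is
mechanical but error-prone: trim the unreliable read ends, orient each
read, slide consecutive reads until their overlaps line up, pick a base
wherever two reads disagree, and — for circular genomes — rotate the
finished sequence so it starts at the conventional origin (for HBV, the
EcoRI site G|AATTC defines position 1).

`sangermerge` automates exactly that workflow and nothing more. It is not
a shotgun assembler (fragment order is an input, never inferred) and not a
mapping assembler (reference sequences are only ever used to *check* the
finished sequence).

## Quality trimming

Each AB1 chromatogram contributes base calls and per-base Phred-like
quality scores. A window of `window` consecutive bases (default 10)
advances inwards from each end until every score inside it is at least
`threshold` (default 20, i.e. ≥99% per-base accuracy); the kept region
runs from the first base of the 5′ passing window to the last base of the
3′ passing window. Two details of this rule were genuinely open and are
fixed as follows:

* **The passing window is retained, not skipped.** The window slides
  *until* all its scores pass; keeping the whole passing window is the
  natural reading and matches common trimming practice.
* **Reads shorter than the window** are kept whole when every base passes
  and otherwise trim to length zero. A zero-length trim is an error that
  aborts the run before any merging, since a vanished fragment would
  silently corrupt the chain.

Trimmed fragments get advisory flags — `RED` when less than
`trimmed_pct_threshold` (default 50) percent of the read survived,
else `YELLOW` when the trimmed read is shorter than `warning_length`
(default 200 nt), else `GREEN`; `RED` outranks `YELLOW` when both hold.
FASTA inputs, which are assumed pre-curated, are never trimmed and are
flagged `BLUE` with 100% retained. Flags warn; they never drop a fragment.

## The pairwise merge

Two sequences are merged through a global Needleman–Wunsch alignment with
affine gap penalties and **free end gaps**, so the optimum overlaps the
sequences instead of stretching one across the other. Defaults follow the
classic EMBOSS-style nucleotide scoring: +5 match, −4 mismatch (ambiguity
codes score the mean over their base sets, e.g. A vs R = 0.5), gap open
50, gap extension 0.5. A gap run of length $k$ costs
$50 + 0.5\,(k-1)$; runs touching either sequence end cost nothing. The
huge gap penalties mean internal gaps appear only when the overlap really
contains an indel — appropriate for Sanger data, where a spurious gap
would shift every downstream codon. Traceback ties are broken
deterministically (diagonal, then gap in the second sequence, then gap in
the first), so results are reproducible to the byte.

The merged sequence is read column-by-column off the alignment: overhang
columns contribute their only base; agreeing columns their shared base;
disagreeing columns are **conflicts**, resolved by

1. higher base quality, when both fragments still carry qualities;
2. otherwise greater distance from the read's nearer end (read middles
   are more reliable than read ends);
3. on a full tie, the earlier fragment.

Every conflict is reported with both bases, the chosen base and the rule
that fired. Orientation is reported as `CORRECT` when the overlap joins
the 3′ end of the first sequence to the 5′ end of the second (the
expectation for correctly ordered fragments) and `CHECK` otherwise.

**Degenerate pairs.** With free end gaps the best overlap score is never
negative, and one or two chance end matches still score positive, so "no
credible overlap" cannot be detected at score ≤ 0. The package instead
requires the overlap to score at least `min_overlap_score` (default 20 —
one error-free 4-mer's worth of matches); below that, the sequences are
concatenated sharing exactly one nucleotide, the merge is flagged
`CHECK`, and the final length is $L_1 + L_2 - 1$. Users should treat such
a merge as a signal to relax trimming or re-examine fragment order.

## Chain merging

Fragments are merged by a left fold: merge 1 joins fragments 1 and 2,
merge 2 joins that output with fragment 3, and so on — $n$ fragments,
$n-1$ merges, reproducing sequential pairwise merging where each
intermediate is piped into the next merge. The fold order is part of the
contract; associativity is not assumed. Intermediate merged sequences
carry no quality scores (the original workflow pipes plain FASTA between
merges), so conflicts in later merges fall back to the positional rule.
The fragment count is bounded at 2–12 by default (a practical interface
limit, overridable via `max_fragments`), and merged sequences beyond
100,000 nt trigger a warning, not an error.

## Rotation and reference checking

For circular assemblies, `seq_slide()` rotates the merged sequence so a
landmark motif starts at a chosen 1-based position; the search is
circular (the motif may straddle the sequence end), exact-match and
case-insensitive, with no ambiguity-code expansion. If the motif occurs
more than once the first circular occurrence wins with a warning; if it
is absent the sequence is left unrotated and the run reports it.

`check_against_references()` aligns the merged sequence to each reference
with the same free-end-gap aligner and, for several references,
reconciles the pairwise alignments into one multiple alignment by gap
insertion on the merged sequence's coordinates. A column is conserved
(`|`) only when *all* sequences carry the identical base; a gap in any
row counts as disagreement, a deliberately strict convention that makes
end overhangs visible in the mismatch count. Rotated circular assemblies
are best checked against a doubled reference (`double_reference()`), which
contains every rotation as a substring, at the cost of one sequence
length of unavoidable overhang mismatches.

## The synthetic data generator

`simulate_genome()` and `fragment_genome()` emulate the study conditions
the pipeline targets: a uniform-random genome (with an optional unique
landmark motif), cut into 2–12 fragments at roughly equal spacing, with
consecutive fragments sharing 30–60 nt by default — comfortably above
the ~20 nt at which random 3.2 kb genomes stop producing ambiguous
overlaps — and read lengths in the 500–800 nt Sanger range. Each read is
the genomic core flanked by random junk bases under a quality ramp that
rises linearly from 2 to the plateau of 40 over 30 bases; bases whose
ramp score is below 20 are junk, so default trimming (10/20) removes
exactly the junk and the trim boundary is analytically predictable.
Optionally every second fragment is stored reverse-complemented with its
restoring flags set, and circular plans start at a random rotation.

The generator makes no attempt at realistic electropherogram peaks,
homopolymer slippage, or indel errors; a small substitution injector
exists solely to exercise conflict reporting. Passing tests on this
generator therefore demonstrate the mechanics of trimming, alignment,
consensus and rotation — not robustness to the full error spectrum of
real traces, where indels near read ends can still produce false indels
in the merged sequence and must be caught by the reference check and the
per-merge reports.

## Numerical and design notes

* Alignment is case-insensitive; input case is preserved in all outputs.
* The DP kernel is C++ (three dense score matrices); a 10 kb × 800 nt
  merge takes well under a second and ~200 MB transiently.
* Test problem sizes: property suites run genomes of 1–10 kb with 2–12
  fragments; the exhaustive alignment oracle enumerates all alignments
  for sequences up to 8 nt, and the trim oracle checks every window for
  reads up to 50 nt.
* The ZIP archive is written by a native stored-entry (uncompressed)
  writer with fixed entry timestamps, so identical runs produce
  byte-identical archives; the run's date-time appears only in the
  archive's internal folder name.
* AB1 fixtures written by `write_abif_fixture()` contain only the header,
  directory, base calls (PBAS.1) and qualities (PCON.1) — the minimum a
  reader needs — and round-trip bit-identically. `read_abif()` prefers
  entry number 1 (edited calls) over 2 (raw basecaller output) when both
  exist; which entry the original web tool read is not documented, and
  this choice follows the usual ABIF convention.

## Known limitations

* No automatic fragment ordering or orientation inference; wrong order
  yields `CHECK` merges or one-base concatenations, not a correction.
* Ambiguity codes are carried through, never disambiguated; primer or
  vector sequence is not detected or removed.
* Quality scores do not propagate through merges, so a conflict between
  two already-merged blocks is decided positionally even if the original
  chromatograms disagreed in quality.
* The reference check is pairwise-seeded and progressive, not a full
  multiple-sequence alignment; with highly divergent references the gap
  placement is heuristic (the counts remain exact for the given rows).
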