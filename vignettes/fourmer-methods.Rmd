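---
title: "Two-stage protein database search: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage protein database search: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourmer)
```

## The problem and the approach

Searching a protein query against a large database with full
Smith–Waterman alignment is exact but expensive: every (query, subject)
pair costs O(MN) cell updates. `fourmer` follows the classic seed-based
compromise: a cheap filter first decides whether a subject shows enough
*local* exact similarity to be worth aligning, and only the survivors are
aligned exactly. Both heuristic stages are fully deterministic, so the tool
trades sensitivity for speed in a way that is easy to reason about and to
test.

The filter works on 4-mers. Every substring of four consecutive residues is
packed into a single 32-bit integer (one byte per residue, little-endian
position order over a fixed alphabetical letter coding), so "does this
query 4-mer occur in the subject?" becomes integer set membership. This
packing mirrors vectorized layouts in which sixteen 32-bit subject blocks
are compared per 512-bit operation; here the layout is abstracted away and
only its semantics are kept: for a subject of length N there are N − 3
stride-1 4-mers, padded into ⌈(N−3)/16⌉ sixteen-code blocks, which equals
the ⌈(4N−12)/64⌉ blocks of the quadruplicated byte layout (the identity is
checked exhaustively in the test suite for N up to 10,000).

## The nearby register

A match anywhere in the subject sets one bit per query 4-mer position.
Scanning those M − 3 bits left to right, a 16-bit shift register (the
*nearby* register) tracks the last 16 positions; the subject passes as soon
as the register's popcount **strictly exceeds** the nearby threshold `n`.
Equivalently: some window of at most 16 consecutive query 4-mer positions
contains at least `n + 1` matches. We read "exceeds" strictly because the
default `n = 3` is documented as demanding *four* 4-mer matches in a
16-residue window; a non-strict reading would make the default demand
three. The register starts all-zero, and the implementation uses an
equivalent cumulative-sum sliding window — the observable decision, not the
register representation, is the contract, and the test suite pins it to a
brute-force window-count oracle.

Subject-side positions are deliberately not recorded: contiguous query
4-mers may match at distant subject positions. For random sequences this is
unlikely within a 16-position window, and a false positive merely costs one
alignment that the score threshold then rejects.

## Parameters

| knob | default | meaning |
|---|---|---|
| `nearby` (`-n`) | 3 | window popcount must exceed this; higher = stricter filter, lower sensitivity |
| `cluster` (`-c`) | 21 | reduced alphabet size, 21 = no reduction; smaller = blurrier letters, more filter passes |
| `fast` (`-f`) | off | index subject 4-mers at even offsets only; halves filter work, loses hits |
| `score_threshold` | 80 | minimum raw alignment score for a hit (with BLOSUM62) |
| `gap_open` / `gap_extend` | 11 / 1 | affine gap costs; a gap of length L costs `open + (L−1)·extend` |
| `workers` (`-p`) | all cores | parallel workers; never affects output |
| `batch_size` | 10 | subjects claimed per work unit; balances contention vs. load |

The defaults are the tool's standard operating point; `-n 3 -c 21` is the
configuration used for realistic searches, with `-f` as the non-exhaustive
variant for near-identity lookups.

## Alphabet clustering

To raise filter sensitivity the 21-letter alphabet (20 standard amino
acids + X) can be reduced to as few as 15 letters, so that near-synonymous
residues compare equal during 4-mer matching. Clustering is agglomerative
over background residue frequencies: repeatedly merge the two non-X
clusters with the smallest summed frequency, representing each cluster by
its most frequent member (ties alphabetical). This linkage is the simplest
rule consistent with the documented first merge: at `k = 20` tryptophan
(1.0%) and cysteine (1.3%), the two rarest residues, collapse into one
letter. X never merges. The resulting maps are nested: every cluster at
size k is contained in exactly one cluster at size k − 1, which yields the
monotonicity guarantee that coarsening the alphabet can only add filter
passes, never remove them.

The bundled frequency table uses published UniProt residue composition
statistics with the W and C values fixed at exactly 1.0% and 1.3%; the
remaining 18 values are rescaled to close the sum at 1. Only the two
anchors matter for the documented merges down to about k = 19; the rest is
configuration and can be replaced via `read_frequency_table()` or
`--freq-table`.

**Design decision: clustering applies to the filter stage only.** Reduced
letters make 4-mer matching more permissive, but alignment always scores
the *original* residues with the *unmodified* matrix.
`collapse_matrix_check()` encodes this contract. The alternative — scoring
with a collapsed matrix — is nowhere well-defined (there is no canonical
way to merge BLOSUM rows), and raw hit scores must remain comparable
across cluster settings; this is also what makes hit sets nest cleanly
across `k`.

## Letter normalization

Inputs are normalized to the 21-letter alphabet before encoding or
alignment: ambiguity codes B, Z, J, the rare residues U and O, the stop
symbol `*`, and anything else map to X. This keeps the alphabet at exactly
21 letters, as the clustering assumes, at the cost of scoring former B/Z
residues with the X rows of the matrix. Codes are assigned alphabetically
over the 21 letters, fixed and documented, so packed 4-mer integers are
identical across runs and platforms.

## Alignment

`local_alignment_score()` computes the exact Smith–Waterman score under
affine gaps via the Gotoh recurrences (compiled, linear-memory,
score-only):

$$H_{ij} = \max(0,\; H_{i-1,j-1} + s(a_i,b_j),\; E_{ij},\; F_{ij})$$
$$E_{ij} = \max(H_{i,j-1} - o,\; E_{i,j-1} - e), \qquad
  F_{ij} = \max(H_{i-1,j} - o,\; F_{i-1,j} - e)$$

Striped or vectorized evaluation orders are legitimate optimizations but
must not change any output; correctness is defined by these recurrences,
and the implementation is pinned to an independently written naive O(MN)
dynamic program (and cross-checked against `Biostrings`) on random pairs.

Numerical choices: scores are integers throughout; ties on the maximal
cell resolve to the smallest (query_end, subject_end) in row-major order;
empty sequences score 0 with undefined ends; sequences shorter than four
residues can never pass the filter and simply fail it rather than erroring.
The gap convention charges `gap_open` for the *first* gap residue (tools
differ here: the same model is expressed in `Biostrings` as
`gapOpening = gap_open − gap_extend`). The 11/1 defaults are the standard
BLOSUM62 pairing of blastp; no canonical values were available for this
tool, so the blastp pairing was adopted and both knobs are CLI-overridable.

## Engine and determinism

`search()` encodes and 4-mer-packs the database once up front (excluded
from the GCUPS throughput metric, since its cost amortizes over queries),
then processes queries one after another. Workers claim contiguous batches
of `batch_size` subjects; every (query, subject) pair is aligned iff it
passes the filter, and emitted iff its score reaches the threshold. Hits
are sorted by (query input order, descending score, ascending subject id) —
a convention of this package — before return, which makes the output
byte-identical across `workers` and `batch_size` settings and across
repeated runs. Raw scores only: no E-values or bitscores, and no traceback
(score and end coordinates suffice for ranking; alignment output is a
possible extension).

Subjects, not queries, are k-mer-indexed. For few-query workloads indexing
the queries instead would be cheaper, but the general many-query mode is
the one implemented.

## The synthetic generator

`make_benchmark_db()` builds seeded benchmarks: queries drawn i.i.d. from
the background frequency table, a database of unrelated random proteins,
and a truth table of planted homologs. A planting copies a query segment
into a subject at a known offset with an exact number of point
substitutions (never mutating a residue to itself); the default template
plants verbatim full-query copies. Substitution-only mutation is
deliberate: it preserves the constructive guarantee that an exact shared
substring of length `n + 4` produces `n + 1` consecutive match bits and
therefore *must* pass the full-mode filter, making recovery claims provable
rather than statistical. Default lengths 100–400 bracket typical curated
protein lengths (averages around 360 residues).

What the generator does not emulate: real protein-family evolution
(substitution-matrix-biased mutations, indels), domain structure, composition
bias, or low-complexity regions. Passing tests therefore demonstrate
algorithmic correctness — filter semantics, exact scores, determinism,
monotonicity — not retrieval accuracy on real proteomes, which depends on
how real homologs decay 4-mer identity.

## Validation scales

The test suite checks filter decisions against a string-search +
window-count oracle on 500 random pairs (lengths 4–400, both modes,
several thresholds), alignment scores against the naive DP on 200 random
pairs (lengths 1–200), the constructive filter guarantee on 100 plantings,
and nesting/determinism/recovery properties on a fixed 500-subject,
20-query synthetic benchmark. These sizes keep the full suite under a
couple of minutes on one core while exercising every contract; all
generation is seeded, so failures reproduce exactly.

## Known limitations

- Sensitivity on real, diverged homologs is untested here by construction;
  the synthetic benchmark plants exact or point-mutated copies.
- The filter ignores subject-side match positions, so pathological
  repeat-rich subjects can pass on scattered matches; the score threshold
  is the backstop.
- Fast mode can miss any hit whose shared 4-mers all start at odd subject
  offsets; it is meant for near-identical lookups only.
- Scores are raw and matrix-dependent; comparing across matrices requires
  external normalization.
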