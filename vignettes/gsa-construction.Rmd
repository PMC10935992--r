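---
title: "Constructing generalized suffix arrays with compressed matching statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing generalized suffix arrays with compressed matching statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsams)
```

## The problem

Pangenome collections — many genomes of individuals of one species, or many
isolates of one virus — consist of strings that are nearly identical to a
reference. The generalized suffix array (GSA) of such a collection lists
every suffix coordinate `(d, j)` (document `d`, position `j`) in
lexicographic order, with content ties broken by document index. It is the
workhorse behind BWT construction and full-text indexing, and building it is
often the bottleneck of pangenomic pipelines. `gsams` exploits the
similarity of the strings: almost everything the sorting needs to know about
a suffix is summarised by how its document aligns against the reference.

## Matching statistics and their compressed form

For a document $S$ and reference $R$ (terminated by `$` and `#`
respectively, with `#` < `$` < every alphabet symbol), the matching
statistics at position $i$ record the *matching factor* — the longest prefix
of $S[i..]$ occurring in $R$ — as an occurrence/length pair $(p_i, \ell_i)$.
A well-known consequence of the definition is the decrement law
$\ell_{i+1} \ge \ell_i - 1$: the length sequence is a concatenation of
decrement runs. It therefore suffices to store the entries at *heads*, the
positions where a run restarts ($\ell_j > \ell_{j-1} - 1$); every other
entry is recovered by offsetting from the preceding head. This is the
compressed matching statistics (CMS): head records plus a predecessor
structure over head positions.

The enhanced form (eCMS) replaces the arbitrary occurrence $p_i$ by the
specific occurrence $q_i$ determined by the *insert point* $ip(i)$ — the
rank the suffix $S[i..]$ would occupy among the reference suffixes — and
adds the mismatch character $c_i$ (the character after the factor) and a
side flag $x_i \in \{S, L\}$ saying whether factor-plus-mismatch sorts below
or above the reference suffix at the insert point. Records are kept at
*insert-heads*, the positions where the $q$-sequence breaks its `+1` run;
every head is an insert-head. One package-specific extension: the sentinel
position of every document is always stored as an insert-head, even when
its $q$ continues the run. The stored record equals what offsetting would
reconstruct, so no reconstructed value changes, but the tie-breaking
machinery below can then rely on every document having a stored record at
its end (the unbroken-run case arises whenever a document suffix matches a
reference suffix through to the sentinel, e.g. for a document identical to
the reference).

At non-head positions the reported occurrence continues the decrement run
($p_i = p_{i-1} + 1$), which is exactly what reconstruction from the
preceding head yields; at heads the occurrence is the leftmost rank of the
final search interval, making the output deterministic.

## Computing the eCMS

All reference-side work happens on arrays: the suffix array `SA`, its
inverse `ISA` and the LCP array of the augmented reference. Before
indexing, the reference is *augmented*: for every collection symbol absent
from it, a run of that symbol as long as the longest such run in the
collection is inserted immediately before the terminal `#`. This guarantees
every non-sentinel position has a non-empty factor and a well-defined
insert point. (The placement before `#` is our choice; it keeps the
sentinel terminal and smallest.)

The scan over a document maintains the SA interval of the current factor:
a *right extension* appends the next character with two binary searches at
the current depth; when the extension is empty, the failed search yields
the insert point and side flag for free. Moving one position right uses a
*left contraction*: one `ISA` step from each interval end plus threshold
previous/next-smaller-value queries on the LCP array to widen to the full
interval. The suffix array is built by self-contained prefix doubling
(`order()`-based, $O(n \log n)$); the LCP array by Kasai's algorithm. No
permuted-LCP intermediate is stored.

### The leaf-branch fast path

On similar sequences the matching factor is usually much longer than any
repeat inside the reference, so the contracted interval is almost always a
singleton. The package precomputes blockwise maxima `M` of the LCP array
(block size `b`, by default chosen so `M` has at most 4096 entries, small
enough to stay cache-resident; configurable via `block_size`). The
contraction to depth $\ell_i - 1$ may skip the PSV/NSV queries when
$\ell_i - 1$ strictly exceeds the maxima of the block(s) covering
`ISA[p_i + 1]` *and* the following rank: both boundary LCP entries of the
contracted interval are then provably below the depth, so the interval is
exactly the singleton. Checking both boundary blocks (rather than one) is
deliberate: it makes the heuristic exact rather than merely usually right,
and equality of the fast and slow paths is enforced by test. The knob
`fast_path = FALSE` disables it; the output is bit-identical either way.

## Comparing suffixes and breaking ties

Two collection suffixes are compared from their enhanced entries alone:

1. a smaller insert point sorts first;
2. at equal insert points: a shorter factor with flag `S` sorts first, a
   shorter factor with flag `L` sorts last; at equal lengths `S` precedes
   `L`; at equal length and flag the mismatch characters decide.

This partial order is refined by lexicographic order, never contradicted by
it. When all four components tie, both suffixes share their factor plus
mismatch character — a common prefix of known equal length $\ell + 1$.

How to recurse on such a tie was a genuinely open design point. A tempting
rule — jump to the insert-heads covering the mismatch characters and compare
those — turns out to be unsound: whether a position inside the shared window
is an insert-head depends on factor matches extending *beyond* the window,
so the two sides can land on heads at different offsets, and comparing them
answers a different question. Randomized search over small collections
produces concrete instances where that rule inverts the true order of two
suffixes differing a few characters past the window. `gsams` therefore
recurses at the *stripped positions* $(i + \ell, i' + \ell)$: the offsets
agree on both sides by construction, the stripped prefixes are equal
strings, and each step advances by at least one character, so the recursion
terminates. A tie with $\ell = 0$ means both suffixes sit at their
sentinels — the contents were equal throughout — and is resolved by document
index, the GSA convention. The comparison cost is no longer a constant
number of predecessor queries; in exchange the comparator is exact, and on
similar sequences the chains are short because ties die at the first
divergence from the shared structure.

## The six phases

`build_gsa()` assembles the pipeline:

1. **Reference structures** — augmentation, `SA`/`ISA`/`LCP`, block maxima.
   When no reference is supplied, the first document serves (its `$`
   swapped for `#` in the indexed copy only).
2. **eCMS** — one streaming pass per document.
3. **S\* selection and bucketing** — each suffix is classified S or L
   (smaller/larger than its successor) by a back-to-front scan; S-type
   suffixes with L-type predecessors are S\*. Sentinels are S\* (for a
   length-1 document, by convention, so every document seeds the
   induction). Each S\* suffix lands in the bucket of its insert point;
   buckets in insert-point order are already globally ordered.
4. **Insert-head ranking** — all insert-heads are partially sorted by the
   composite key (insert point; flag; length ascending within `S`,
   descending within `L`; mismatch character), with equal keys sharing a
   dense rank. Per document the rank sequence plus a terminator (one per
   document, below all head ranks, ordered by document index — mirroring
   the `$` tie rule) is laid out in text order. Groups still sharing a
   rank tie on their whole enhanced entry and are ordered with the full
   comparator above. An earlier design refined these groups by suffix-
   sorting the rank string itself; that inherits exactly the misalignment
   problem described above, which is why the comparator does the
   refinement — its agreement with direct string comparison on every head
   pair is a standing test.
5. **Bucket sorting** — inside each bucket, members are ordered by the
   composite key, and full ties by the comparator, which now short-circuits
   through the head ranks whenever its recursion lands with both sides on
   a stored insert-head (duplicated documents resolve this way in one
   lookup).
6. **Induction** — a SAIS-style double scan generalized to a collection:
   sorted S\* suffixes are seeded at the tails of their first-character
   buckets (the `$` bucket holds one sentinel per document in document
   order), a left-to-right scan induces L-type suffixes at bucket heads,
   and a right-to-left scan induces S-type suffixes at bucket tails,
   overwriting the seeds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `block_size` (`b`) | `ceiling(n / 4096)` | LCP block length (symbols) for the fast-path maxima; smaller blocks admit more fast-path hits at the price of a larger `M`. |
| `b_p` | 32 | Predecessor sampling rate: every `b_p`-th stored position is kept in the binary-searched layer, the rest as 32-bit differential gaps scanned linearly. Query cost `O(log(n/b_p) + b_p)`. |
| `fast_path` | `TRUE` | Leaf-branch heuristic; exactness is tested, so this is purely a speed knob. |

## The synthetic generator

`generate_collection(ref_len, m, rate, seed)` draws a uniform random
A/C/G/T reference and emits `m` copies, each mutated at exactly
`floor(rate * ref_len)` distinct uniform positions by substituting one of
the three *other* nucleotides. This emulates the regime the method targets —
collections whose members differ from a reference by scattered
substitutions at a controlled rate — and drives the scaling of head counts
with divergence. It deliberately does not emulate insertions/deletions,
structural rearrangements, uneven mutation clustering, or IUPAC ambiguity
codes in the simulated copies (real FASTA input may carry any IUPAC code;
augmentation handles symbols missing from the reference). Passing tests on
generated data therefore demonstrates correctness of the construction on
substitution-divergent collections of every tested rate — including
rate 0 (identical documents) and high rates where the reference no longer
helps — but says nothing about runtime behaviour under indels, where
matching statistics shift out of phase and heads multiply.

## Numerical and degenerate-input choices

* Positions, SA ranks and intervals are 1-based and inclusive throughout.
* Symbol order is `#` < `$` < alphabet symbols in natural (ASCII) order;
  all documents share one `$`, ties between content-equal suffixes fall to
  the document index.
* A document of length 1 (bare sentinel) is S\* by convention and sorts by
  document index within the leading `$` bucket.
* A reference supplied separately that also occurs verbatim as a document
  is not deduplicated: the indexed copy (with `#`) and the collection copy
  (with `$`) are distinct objects.
* Threshold PSV/NSV queries return "none" when no qualifying position
  exists; the virtual-sentinel convention (`|A| + 1` at query `|A| + 1`)
  keeps the contraction formula total.
* Gaps in the predecessor structure must fit 32-bit integers; violation is
  an error, not silent truncation.

## Scale of the validation suite

The test suite validates every layer against brute force: suffix arrays
against direct suffix sorting up to length 200, matching statistics against
substring search, insert points against the three-case definition applied
to sorted reference suffixes, and the end-to-end construction against the
quadratic-memory `naive_gsa()` oracle on 216 randomized collections
(documents up to 200 symbols, up to 8 documents, substitution rates 0 to
0.3) plus simulated pangenome collections of five 2000-symbol copies at
rate 0.01. These sizes were chosen to exercise every code path — including
empty extensions, unbroken runs, duplicated documents and degenerate
single-symbol documents — while keeping the whole suite fast enough to run
on every change; the construction itself has no hard-coded size limits
beyond R's integer indexing.

## Known limitations

* Everything is in-memory and single-threaded; the design goal is a clear,
  verifiable reference implementation in R, not peak throughput.
* The comparator's tie recursion costs up to one step per shared structural
  block rather than a constant number of predecessor queries; adversarial
  inputs (long low-complexity strings) degrade it, similar collections do
  not.
* Compressed input forms (VCF deltas, variation graphs) and BWT output are
  out of scope.
* `naive_gsa()` and `naive_ms()` are oracles for testing; they are
  quadratic and refuse nothing — keep them to test-scale inputs.
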