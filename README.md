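# gsams — generalized suffix arrays via compressed matching statistics

`gsams` builds the **generalized suffix array (GSA)** of a collection of
highly similar DNA-like sequences — the typical shape of pangenome data:
many genomes or isolates that differ from a reference by scattered
substitutions. Instead of sorting `N` suffixes from raw text, it first
computes a compressed summary of how every document aligns against a
reference, and lets that summary do almost all of the comparison work.

## The method in brief

For a document `S` and reference `R` (sentinels `$` and `#`, with
`# < $ <` every alphabet symbol), the *matching statistics* record at each
position `i` the longest prefix of `S[i..]` occurring in `R`, as a pair
`(p_i, ℓ_i)`. Because `ℓ_{i+1} ≥ ℓ_i − 1`, the length sequence decomposes
into decrement runs and only the run starts (*heads*) need storing — the
**CMS**. The enhanced form (**eCMS**) stores, at *insert-heads*, the
4-tuple `(q_i, ℓ_i, x_i, c_i)`: the reference position `q_i = SA_R[ip(i)]`
given by the *insert point* (the rank `S[i..]` would occupy among `R`'s
suffixes), the factor length, a side flag `x ∈ {S, L}`, and the mismatch
character. A predecessor structure over the stored positions reconstructs
the entry of *any* position in O(1) arithmetic after one lookup.

Two collection suffixes are then compared from their eCMS entries alone
(smaller insert point first; then flag, length and mismatch character), and
the GSA is assembled in six phases: reference indexing, eCMS computation,
S\*-suffix bucketing by insert point, insert-head ranking, bucket-local
sorting, and SAIS-style induction of the remaining suffixes.

## Worked example

The insert-head records of `S = GATGGCACATTGATGG` against
`R = TGATGGCACAGATACT`:

```r
library(gsams)
cc  <- string_collection("GATGGCACATTGATGG")
idx <- reference_index("TGATGGCACAGATACT", cc)
ms  <- matching_statistics("GATGGCACATTGATGG", idx)
ms[ms$is_ihead, c("i", "q", "ell", "x", "c")]
#>   i  q ell x c
#>   1  2   9 L T
#>   9  3   2 L T
#>  11  1   6 S $
#>  16 11   1 S $
#>  17 17   0 L $
```

Reading row one: at position 1 the document matches a factor of length 9
(`GATGGCACA`) whose insert-point occurrence starts at reference position 2;
the factor followed by its mismatch `T` sorts above (`L`) the reference
suffix there. The last row is the sentinel: empty factor, slotted at rank 1.
The other 12 positions of the document need no storage — offsetting from
these five rows reconstructs them exactly (`ems_at()`).

Building a GSA and its run report:

```r
g <- build_gsa(string_collection(c("GATTACA", "GATCACA")))
g
#> Generalized suffix array: 16 suffixes over 2 documents
#>   heads: 4  insert-heads: 7  S*: 6  buckets: 3
head(g$gsa, 3)
#>      d j
#> [1,] 1 8    # the two sentinels, in document order
#> [2,] 2 8
#> [3,] 1 7    # then A$ of document 1 ...
```

`naive_gsa()` (brute force) and `naive_ms()` are shipped as oracles; every
construction path is tested against them. A command-line front end with
verbs `build`, `ms`, `simulate` and `check` lives in `inst/scripts/gsams`.

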