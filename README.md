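# uniqoligo

Selection of unique oligonucleotides from EST databases by pigeonhole
filtration.

An expressed sequence tag (EST) is a short DNA fragment (~200–800 bases)
from sequencing complementary DNA. A **unique oligo** of an EST database is
an l-mer that occurs in exactly one EST and has no approximate occurrence —
no substring within Hamming distance *d* — in any other EST. Unique oligos
are sequence-specific fingerprints of their EST, used in PCR primer design,
microarray probe selection and genomic library probing. This package is for
anyone who needs that uniqueness screen: it finds **all** unique l-mers of a
FASTA database, exactly.

## The algorithm

Comparing all window pairs directly is quadratic. Instead, cut each l-mer
into *k* blocks, the first *k−1* of length *q* = ⌊l/k⌋ and the last at least
as long. If HD(x, y) ≤ d but every block pair had ≥ m+1 mismatches, the
total would be ≥ k(m+1) ≥ d+1 — a contradiction. So some block pair agrees
within *m* mismatches, and it suffices to index length-q seeds and examine
only seed-sharing pairs. Three (k, m) choices give three schemes with
identical output and different costs:

| scheme         | blocks k   | seed budget m | q at l=28, d=6 |
|----------------|------------|---------------|----------------|
| `exact`        | d + 1      | 0             | 4              |
| `one-mismatch` | ⌊d/2⌋ + 1  | 1             | 7              |
| `two-mismatch` | ⌊d/3⌋ + 1  | 2             | 9 (at l = 27)  |

Phase one files every clean q-window into a table keyed by its 2-bit code
(4^q key space). Phase two pairs occurrences within each bucket — and across
m-mutant buckets (3q 1-mutants; 9q(q−1)/2 further 2-mutants) for m ≥ 1 —
extends each seed pair to block-aligned l-mers, verifies HD ≤ d exactly, and
marks both members of every verified cross-EST pair. Unique oligos are the
never-marked clean windows. A brute-force oracle, a deterministic synthetic
EST generator with planted near-repeats, and a parallel driver that
partitions the key space across workers (bit-identical results) round out
the toolkit.

## Worked example

```r
library(uniqoligo)
db <- generate_est_db(20, c(200, 400), seed = 1)   # 20 synthetic ESTs
planted <- plant_repeats(db, list(plant_spec(c(1, 10), c(2, 50), 6)),
                         l = 28, seed = 2)          # 6-substitution repeat
params <- derive_params(28, 6, "one-mismatch")
params
#> oligo search parameters: l=28 d=6 scheme=one-mismatch q=7 k=4 m=1
res <- find_nonunique(planted$db, params)
res
#> unique-oligo search: l=28 d=6, scheme one-mismatch (q=7, k=4, m=1)
#>   5305 clean l-window(s): 4 non-unique, 5301 unique
list(est1 = res$nonunique[[1]], est2 = res$nonunique[[2]])
#> $est1
#> [1] 10 11
#> $est2
#> [1] 50 51
identical(brute_force(planted$db, 28, 6)$nonunique, res$nonunique)
#> [1] TRUE
```

The planted 6-substitution copy (donor at EST 1 offset 10, recipient at
EST 2 offset 50) is marked non-unique in both ESTs, together with the
one-base-shifted window pair it drags along; the remaining 5301 clean
28-windows are unique fingerprints. The brute-force solver returns the
identical mark sets.

A command-line interface wraps the same functions
(`system.file("cli", "uniqoligo.R", package = "uniqoligo")`):

```sh
Rscript uniqoligo.R synth  --num 20 --seed 1 --out ests.fasta
Rscript uniqoligo.R search --in ests.fasta --l 28 --d 6 \
        --scheme one-mismatch --workers 4 --out run
Rscript uniqoligo.R check  --in ests.fasta --l 20 --d 3   # engine vs oracle
```

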