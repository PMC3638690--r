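---
title: "Finding unique oligos in EST databases by pigeonhole filtration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding unique oligos in EST databases by pigeonhole filtration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniqoligo)
```

## The problem

An expressed sequence tag (EST) is a short DNA fragment, typically 200–800
bases, obtained by sequencing complementary DNA. A *unique oligo* of an EST
database is an l-mer (an oligonucleotide of length l, here 20–30 bases) that
occurs in exactly one EST and whose every approximate occurrence — any
substring within Hamming distance d — also lies in that same EST. Unique
oligos act as sequence-specific fingerprints of their EST and are the raw
material for PCR primer and microarray probe selection.

The naive solution compares every pair of l-windows in the database, which is
quadratic in the database size and quickly infeasible. `uniqoligo` implements
the standard remedy: a seed-and-extend *filtration* built on the pigeonhole
principle.

## The model

Cut two l-mers $x$ and $y$ into $k$ consecutive blocks, the first $k-1$ of
length $q$ and the last of length $\ge q$ (so $kq \le l$). If
$\mathrm{HD}(x, y) \le d$ and every block carried at least $m+1$ mismatches,
the total would be at least $k(m+1)$; choosing $k$ so that $k(m+1) \ge d+1$
is impossible to exceed, some block pair must agree within $m$ mismatches.
Three choices of $(k, m)$ give the package's three schemes:

| scheme         | blocks $k$              | per-block budget $m$ |
|----------------|-------------------------|----------------------|
| `exact`        | $d + 1$                 | 0                    |
| `one-mismatch` | $\lfloor d/2\rfloor + 1$ | 1                   |
| `two-mismatch` | $\lfloor d/3\rfloor + 1$ | 2                   |

The search then runs in two phases. Phase one files every clean length-$q$
window of the database into a table keyed by its 2-bit code (A=0, C=1, G=2,
T=3, base 4, most significant first), recording `(sequence, position)`
occurrence pairs; under uniform composition each of the $4^q$ keys holds
$r \approx n/4^q$ entries. Phase two pairs occurrences within each bucket
and, for $m \ge 1$, between each bucket and its m-mutant buckets (the
$3q$ codes at distance 1, plus $9q(q-1)/2$ more at distance 2 for $m = 2$);
each seed pair is extended to the l-mers that contain the seeds *at the same
block offset* and the pair is kept only if the full l-mers verify
$\mathrm{HD} \le d$. Both members of every verified cross-EST pair are marked
non-unique; the unique oligos are the never-marked clean windows.

Because the pigeonhole theorems guarantee the filter misses no qualifying
pair and the verification step is exact, all three schemes return the same
answer as the brute-force solver — they differ only in how many candidate
pairs they must verify. The test suite asserts this equivalence on hundreds
of randomized databases.

## Parameters and defaults

* `l` — oligo length, bases. No default; 27 and 28 are common probe lengths
  and are used throughout the examples.
* `d` — mismatch threshold defining approximate occurrence; `d = 6` with
  `l = 28` is a typical specificity setting.
* `q` — seed length, derived as `floor(l/k)`. The theorems state block
  lengths via `ceil(l/k)`; the floor is deliberate: with `q = floor(l/k)`
  every block (including the longer final one) contains a full length-q
  seed, so indexing only length-q seeds cannot miss a block match. For every
  configuration where `l` is divisible by `k` the two conventions coincide.
  `q` is additionally capped at 25 so that codes remain exact integers in
  the `4^q` key space; any `q <= floor(l/k)` preserves completeness, since
  the pigeonhole argument only needs `k` blocks each containing a full seed.
  A user override must satisfy `k*q <= l`.
* `within_est` (default `FALSE`) — the definition of uniqueness names only
  occurrences in *another* EST, so same-EST repeats do not disqualify an
  oligo by default; the flag enables the stricter policy in both the engine
  and the oracle.
* `revcomp` (default `FALSE`) — strand handling is not part of the base
  problem statement; when enabled, each sequence's reverse complement is
  searched as a shadow carrying the same EST identity and marks are folded
  back to forward coordinates.

Degenerate settings stay correct by construction: `one-mismatch` with
`d <= 1` collapses to a single block whose seed budget over-matches
(`HD <= 1` when `d = 0`), but the engine always verifies extended pairs
against `HD <= d`, so the filter being a superset generator is harmless.

## Numerical and design choices

* **Coordinates** are 0-based and half-open everywhere in memory and in the
  TSV/BED output; the reported oligo string disambiguates any concern.
* **Ambiguous bases.** Sequences are uppercased on load; any window
  containing a character outside `{A,C,G,T}` is skipped for indexing and can
  be reported neither unique nor non-unique.
* **Extension alignment.** Candidates are generated only at block-aligned
  offsets `p - j*q`, not at all `l - q + 1` shifts: the theorems place the
  matching seed at the *same* block index in both l-mers, so block-aligned
  extension is complete. The oracle-equivalence suite validates the choice.
* **Mutant lists** exclude the string itself (size `3q`, not `3q + 1`): the
  identity match is already handled by the same-bucket pass, and exclusion
  avoids processing each bucket against itself twice. Enumeration order is
  deterministic (position-major, substituted-digit-minor) so runs are
  reproducible.
* **Marking** is by window start position, not by l-mer string, and is
  idempotent, so a pair rediscovered through several block indices needs no
  deduplication. Reported totals count marked window positions summed over
  sequences.
* **Sparse index.** The occurrence table stores only occupied keys; memory
  scales with distinct q-mers rather than `4^q`, and the parallel driver
  recovers dense ordering by sorting keys.
* **Parallel ownership.** A worker owns the within-bucket pairs of its key
  chunk and every mutant cross pair whose lower key it owns. Ownership is a
  pure function of the key, so each pair is generated exactly once without
  coordination; workers return only mark sets and the merge is a set union
  (commutative, idempotent), which makes the parallel result bit-identical
  to the serial one for any worker count. Speedup is hardware-dependent and
  is never asserted in tests.
* **Oracle independence.** The brute-force solver shares only the Hamming
  primitive and the clean-window scan with the engine; agreement between the
  two is therefore evidence of correctness, not tautology. A guard refuses
  inputs beyond 20,000 windows to keep its quadratic cost bounded.

## What the synthetic generator emulates

`generate_est_db()` draws i.i.d. uniform `{A,C,G,T}` sequences with lengths
uniform in 200–800 bases by default, matching the record count and length
scale of real EST collections, and `plant_repeats()` overwrites chosen
windows with donor copies carrying an exact number of substitutions so that
ground-truth near-repeats exist at known coordinates. A single integer seed
drives all randomness and the global RNG state is restored afterwards.

Real ESTs are not uniform random DNA: they carry composition bias, poly-A
tails, low-complexity stretches and sequencing-error structure, all of which
raise the background rate of approximate matches and skew the bucket-load
distribution. Passing tests on synthetic data therefore demonstrate
*algorithmic correctness* (the filtration finds exactly the pairs the
brute-force solver finds, on both random and adversarial planted inputs),
not field-calibrated uniqueness rates; on real data the counts will differ
but the engine/oracle agreement argument is input-independent.

At the test suite's problem sizes — hundreds of databases of 5–30 sequences
of 50–400 bp for the oracle-equivalence sweep, 12–20 sequences of 100–400 bp
for the planted-repeat and parallel suites — the full randomized validation
completes in a few minutes on a single CPU.

## Worked example

```{r example}
db <- generate_est_db(20, c(200, 400), seed = 1)
planted <- plant_repeats(db, list(plant_spec(c(1, 10), c(2, 50), 6)),
                         l = 28, seed = 2)
params <- derive_params(28, 6, "one-mismatch")
params
res <- find_nonunique(planted$db, params)
res
head(res$unique_oligos, 3)
# the planted pair is marked in both ESTs
list(est1 = res$nonunique[[1]], est2 = res$nonunique[[2]])
```

The same computation distributed over three workers returns the identical
object, and the brute-force solver agrees exactly:

```{r equivalence}
par3 <- find_nonunique_parallel(planted$db, params, workers = 3)
identical(par3$nonunique, res$nonunique)
identical(brute_force(planted$db, 28, 6)$nonunique, res$nonunique)
```

## Known limitations

* Hamming distance only: insertions and deletions are outside the model, as
  are quality scores, protein alphabets and IUPAC degenerate codes.
* The brute-force oracle is intentionally unscalable; use it for validation,
  not production runs.
* Probe thermodynamics (melting temperature, GC content) are not considered;
  the output is a uniqueness screen, not a finished probe design.
* Parallelism is multicore (forked processes) on one machine; distributed or
  GPU execution is out of scope.
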