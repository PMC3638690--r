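Package: uniqoligo
Title: Unique Oligonucleotide Discovery in EST Databases by Pigeonhole
    Filtration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds unique oligonucleotides (l-mers) in a database of
    expressed sequence tags (ESTs): l-mers that occur in exactly one EST
    and have no occurrence within Hamming distance d in any other EST.
    Implements three pigeonhole-partition filtration schemes that index
    length-q seeds in a hash table and extend matching seed pairs
    (exact, within one mismatch, or within two mismatches) to full
    l-mers for exact Hamming verification, together with a brute-force
    reference solver, a deterministic synthetic EST generator with
    planted approximate repeats, a parallel execution mode that
    partitions the seed key space across workers, and a command-line
    interface reading FASTA and writing TSV/BED.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    parallel,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
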