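# mapbench

Formally defined gold standards and evaluation for read mapping.

Read mappers report locations where a sequencing read aligns to a
reference genome, but "the set of locations a mapper should find" is
surprisingly hard to pin down: alignments that differ by a shifted gap are
not really different, matches inside a short tandem repeat blur into each
other, and copies of a long repeat are genuinely distinct. `mapbench`
makes the target set exact, so that any SAM-producing mapper can be scored
against a mathematically defined optimum rather than against another
mapper.

## The model

For a read *r* of length *m* and a reference *S*, every semi-global
alignment of the full read is identified by the 0-based reference position
*e* where its **last base** aligns; the first and last read base must align
to reference characters (never to a gap). The **error landscape** is

> δ(e) = minimal distance (Hamming or edit) over all such alignments
> ending at *e*,

and the **canonical start** of *e* is the leftmost start among
minimal-distance alignments ending there. Flooding the landscape to water
level *k* + 0.5 yields **lakes** — maximal runs of positions with
δ(e) ≤ *k*. Two lakes belong to the same **match equivalence class** when
they contain trace-equivalent positions (equal canonical starts); a lake
lying between two trace-equivalent positions is absorbed, and the closure
is taken. Every class is one interval (*k*, *first*, *last*) — the **gold
standard**. A mapper is scored in three categories at an error rate
(percent of read length, budget = ⌊rate·m/100⌋):

* **all** — find every feasible class,
* **all-best** — find every class of minimal distance,
* **any-best** — find at least one minimal-distance class,

with the **normalized found intervals** metric: each read gives at most
one point, a read with *n* relevant classes earns 1/*n* per found class;
the score is 100 · points / reads.

The package contains two independent routes to the gold standard: an
optimized pipeline (C++ banded column DP for landscapes, union-find lake
merging, seeded interval extension that inspects only a window around each
mapper-reported match) and a brute-force reference implementation of the
equivalence definitions (`landscape_bruteforce()`,
`gold_intervals_bruteforce()`), which the test suite holds bit-identical
on hundreds of randomized instances. A small simulator generates
haplotypes (SNPs + indels), reads with technology-flavoured errors, FASTQ
output and an origin SAM tying the biological problem (find the sampled
locus) to the mathematical one.

## Worked example

```r
library(mapbench)

refs  <- tibble::tibble(id = "chr", seq = "TTAACGTTTTAACGTTCGTTGG")
reads <- tibble::tibble(id = "r1",  seq = "AACG")

gs <- build_gold(refs, reads, model = "hamming", max_error_rate = 0)
tidy(gs)
#> # A tibble: 5 × 7
#>   read_id contig_id strand     k min_k first  last
#>   <chr>   <chr>     <chr>  <int> <int> <int> <int>
#> 1 r1      chr       +          0     0     5     5
#> 2 r1      chr       +          0     0    13    13
#> 3 r1      chr       -          0     0     7     7
#> 4 r1      chr       -          0     0    15    15
#> 5 r1      chr       -          0     0    19    19
```

`AACG` occurs exactly at 0-based end positions 5 and 13 on the forward
strand, and its reverse complement `CGTT` ends at positions 7, 15 and 19 —
five equivalence classes, each a single position at *k* = 0. Evaluating a
SAM file that reports one record per class:

```r
iv  <- tidy(gs)
sam <- tempfile(fileext = ".sam")
write_sam(tibble::tibble(read_id = "r1", contig_id = "chr",
                         strand = iv$strand, pos = iv$first, cigar = "1M"),
          refs, sam)
res <- evaluate_mapping(gs, parse_sam(sam, reads = reads), reads, refs,
                        category = "all", rate = 0)
res
#> <mapbench_eval> category all at error rate 0%
#>   normalized found intervals: 100.0% (1 points over 1 reads)
#>   missed intervals: 0; unexpected records: 0; invalid records: 0
```

One read, five classes, all found: 1/5 point each, 1 point total, 100%.
Reporting only one of the five records would leave 1/5 point and a score
of 20%.

A command-line interface wrapping the same functions ships under
`inst/cli/mapbench` (subcommands `simulate`, `build-gold`, `evaluate`,
`make-fixture`, `run-all`).

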