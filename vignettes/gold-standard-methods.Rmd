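---
title: "How mapbench defines and scores read-mapping gold standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How mapbench defines and scores read-mapping gold standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapbench)
```

## The problem

Given a reference sequence $S$, a read $r$ of length $m$, a distance
function (Hamming or Levenshtein) and an error budget $k$, a read mapper
should report the locations where $r$ aligns with distance at most $k$.
Counting those locations naively is ill-posed: every alignment of distance
$d$ induces alignments of distance at most $d + 2$ by sliding its first or
last base across a gap, and inside tandem repeats neighbouring placements
of the read are intuitively "the same match" while copies of a long repeat
are not. `mapbench` makes the notion of *match* exact through equivalence
classes of alignments and scores mappers against the resulting classes.

## Matches, landscapes and equivalence classes

**End anchoring.** Only semi-global alignments whose first and last read
base sit on reference characters are considered, and the alignment must
lie fully inside the reference. Dropping gap-flanked end bases loses
nothing (such alignments are never cheaper), and it lets every alignment
be identified by the single reference position $e$ that its last base
occupies.

**Error landscape.** $\delta(e)$ is the minimal distance of an anchored
alignment ending at $e$; the *canonical start* of $e$ is the leftmost
start position among alignments achieving $\delta(e)$. Under Hamming
distance each match occupies exactly one diagonal, so the canonical start
is always $e - m + 1$. Positions where no valid alignment ends carry the
sentinel $m + 1$, one more than the largest possible distance of a real
alignment; this keeps the landscape an integer vector.

**Lakes and merging.** Flooding the landscape to level $k + 0.5$ yields
lakes: maximal runs with $\delta \le k$, the classes of *neighbour
equivalence*. Two positions are *trace equivalent* when their canonical
starts coincide (their alignment traces share a part). The full match
relation additionally absorbs every position lying between two
trace-equivalent feasible positions, and takes the transitive closure;
each resulting class is a contiguous interval $(k, \mathit{first},
\mathit{last})$ of end positions, which is exactly how gold standards are
stored (`write_gsi()` / `read_gsi()`). Because the interval keeps only its
extreme feasible positions, a class may contain interior *separating*
positions with $\delta > k$; every consumer of the gold standard therefore
re-checks feasibility at a reported position instead of trusting interval
membership alone (`evaluate_mapping()` logs records at such positions as
"absorbed" — inside a correct region, but not a valid alignment end).

An instructive consequence, visible in `make_fixture()`'s tandem cases:
in a period-$p$ repeat the per-period exact matches merge into a single
class only once $k \ge 2$, because shifting a periodic alignment by one
period costs an insertion/deletion pair; at $k < 2$ they remain separate
single-position classes. Copies of a repeat longer than the read never
merge — their canonical starts differ by more than any alignment can span.

```{r tandem}
ref <- paste0("TGGTT", strrep("AC", 10), "GGTTG")
autoplot(error_landscape("ACACAC", ref, model = "edit"), k = 2)
intervals_for_read("ACACAC", c(fix = ref), model = "edit", k_max = 2) |>
  dplyr::filter(strand == "+")
```

**Strands.** A reverse-strand match is represented by aligning the
reverse-complemented read left-to-right on forward coordinates; its end
position is the largest reference coordinate it touches. A SAM record with
the reverse flag maps onto this convention without any coordinate
flipping.

## Two independent construction routes

`build_gold(mode = "oracle")` computes full landscapes on both strands of
every contig — exact, and affordable for references up to a few hundred
kilobases times the read count. The optimized landscape is a column-wise
dynamic program in C++ that anchors the first read base by restricting row
one to diagonal entry, folds the last base in as a forced diagonal, and
propagates the leftmost start among cost-achieving predecessors (every
optimal path passes through optimally reached cells, so this is exact).

`build_gold(mode = "seeded")` starts from the matches of a fully sensitive
mapper — at least one record per class — and reconstructs each class
inside a growing window around the seed. The window stops growing on
either side once it is bounded by $m + k$ consecutive infeasible positions
(or a contig border): no trace-equivalence link can span such a stretch,
because two positions sharing a canonical start both lie within the
$m + k$ reference characters that an alignment from that start can touch.
The class computed inside the window therefore equals the class in the
full landscape, bit for bit, while only
$O(\mathit{interval} + m + k)$ reference positions are inspected
(`extend_interval()` reports the count as an attribute). Duplicate seeds
collapse; a seed whose recomputed distance exceeds the budget is skipped
as invalid rather than raising an error, since seed SAMs come from
external mappers. Each seed with distance $d$ seeds construction for every
$k$ from $d$ to the budget, so the standard holds all levels
$0 \le k \le k_{\max}$.

The package deliberately ships a second, independent implementation:
`landscape_bruteforce()` enumerates anchored start positions per end
position and scores the interior with `utils::adist()`, and
`gold_intervals_bruteforce()` builds the classes by explicit closure of
the neighbour/trace definitions over an `igraph` component computation.
The test suite holds the optimized pipeline bit-identical to this
reference on hundreds of randomized instances; neither route shares code
with the other.

## Error rates and evaluation

Budgets are expressed as error *rates* relative to read length so that
mixed-length read sets share one setting; the budget of a read is
$\lfloor \mathit{rate} \cdot m / 100 \rfloor$ — flooring is the
conservative choice (never admits more errors than the stated rate).

`evaluate_mapping()` scores parsed SAM records in three categories at rate
$c$: **all** counts every class at level $k = c$; **all-best** and
**any-best** first annotate each interval with the smallest $k$ of any
contained interval (equivalently, the depth of its deepest lake) and keep
only classes at the read's minimum. A record hits a class iff read, contig
and strand agree, the end position falls inside the interval, and the
recomputed distance at that end position is within budget; the mapper's
own CIGAR/NM distance is never trusted, because mappers differ in how they
choose edit operations while the gold standard is defined over $\delta$.
Records with soft- or hard-clipped alignments are set aside as invalid —
the benchmark is defined for full-read semi-global alignment — and
feasible records outside every class are reported as unexpected (a sanity
check on the gold standard itself). The score is
$100 \cdot \sum_r p_r / |R|$ where a read with $n$ relevant classes earns
$1/n$ per found class (all / all-best) or the full point for any best
class (any-best). Reads without any relevant class are excluded from the
denominator by default — they cannot score a point — but
`scored_reads = "all"` switches to the total read count for studies that
prefer it. Mapper output can be capped at its best $n$ records per read
before scoring (`cap_matches()`), ranking by recomputed distance and
breaking ties with a seeded RNG so results are reproducible.

## The simulator and what it does (not) show

`simulate_reads()` ties the *biological* problem — recover each read's
sampled locus — to the mathematical one. It derives haplotypes from the
reference by independent per-base SNPs (default $10^{-3}$) and indels
(default $10^{-4}$, sizes 1–6), samples reads uniformly from both strands
fully inside the haplotype, and writes FASTQ plus an origin SAM whose
POS/CIGAR encode the sampled alignment projected back to reference
coordinates (at indel borders the projection takes the rightmost reference
base consumed). The `illumina` profile uses fixed-length reads with a
linear substitution-rate ramp from 0.2% at the first base to 2% at the
last — the rising-error shape typical of short-read instruments — and no
indels; the `longread` profile draws Gaussian lengths (default
$400 \pm 40$) with flat substitution and indel error rates (0.5% each).
Base qualities are the Phred encoding of the per-position error
probability. These are deliberately minimal error models chosen for
controllable error structure; they are not calibrated to any instrument,
and simulation cannot reproduce the coverage and sequence-composition
biases of real libraries. Passing tests on simulated reads therefore
demonstrate the correctness of the benchmark machinery, not the field
performance of any mapper.

Because an origin position is a representative of the one class the
mapper should find, the origin SAM doubles as both the seed input for
`build_gold(mode = "seeded")` and the output of a perfect "biological"
mapper: evaluated at a rate admitting its sequencing errors, it scores
exactly 100 in the any-best category. The test suite runs this experiment
at 10,000 36 bp reads from a 100 kb uniform-random reference — large
enough for abundant chance near-matches, small enough to run in a couple
of minutes on one CPU — both error-free at rate 0 and with up to two
sequencing errors per read at rate 8% (a budget of
$\lfloor 8 \cdot 36 / 100 \rfloor = 2$).

## Numerical and design choices

* **Coordinates** are 0-based with closed interval ends throughout the
  package; SAM and GSI I/O convert at the boundary.
* **`N` handling**: `N` mismatches everything, including `N` — a
  deterministic, conservative rule for a symbol that denotes an unknown
  base.
* **Ambiguous DP choices**: canonical starts are defined by the
  leftmost-minimal rule, not by a traceback preference, so no
  tie-breaking order affects the gold standard.
* **Degenerate inputs**: empty reads and out-of-range positions are
  rejected with errors; a read with no feasible match simply contributes
  no intervals; an empty gold standard round-trips as a header-only GSI
  file.
* **Fixture construction**: the repeat fixtures draw repeat units from
  {A,C} and spacers from {G,T}, so spacer-only windows mismatch at every
  column and the stated interval counts are forced by construction for any
  fixture seed.
* **Problem sizes** in tests: randomized cross-checks use reads of 8–40 bp
  against references of 50–500 bp with $k \le 4$ — small enough for the
  quadratic brute-force oracle, large enough to exercise repeats, border
  effects and all feasibility regimes.

## Limitations

Mate pairs, base-quality-aware distances, alignment scores (affine gaps,
Smith–Waterman), colour-space reads, spliced alignment and multi-read
assignment are out of scope; clipped alignments are rejected rather than
projected. The seeded builder inherits the completeness of its seeds: a
class without a seed is silently absent, which is exactly the property the
benchmark measures when the seeds come from the mapper under test.
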