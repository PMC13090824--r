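---
title: "In silico PCR: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico PCR: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ispcr)
```

## The problem and the model

A large fraction of questions asked of raw sequencing data — "is this sample
the species it claims to be?", "is there bacterial or human contamination?",
"what does this specimen's CO1 / 16S / 18S look like?" — have historically
been answered by benchtop PCR against well-characterised primer pairs. In
silico PCR answers them from the reads directly: given a forward and a
reverse primer, reconstruct the sequence between them, exactly as a benchtop
reaction would amplify it.

The model is a *targeted* de Bruijn graph assembly. Nodes are the k-mers
observed in the reads; edges connect k-mers overlapping by k-1 bases. The
forward primer defines the entry points (start k-mers), the oriented reverse
primer defines the exits (end k-mers), and the products are all simple paths
from an entry to an exit whose length falls in the expected product window.
Requiring both a seed *and* a terminator is what gives the method its
specificity: a path that wanders off target is simply never emitted, the
computational analogue of a PCR reaction that needs both primers to anneal
to yield a band.

## Canonical k-mer counting

K-mers are packed into 64-bit integers two bits per base, `A=00, C=01, G=10,
T=11`, leftmost base in the highest bits. This ordering makes integer
comparison equal lexicographic comparison, so the canonical representative —
the smaller of a code and its reverse-complement code — is also the
lexicographically smaller strand. Counting canonical forms makes the table
independent of read orientation, which matters because shotgun reads sample
both strands uniformly.

Two structural rules follow from the encoding:

* **k is odd.** An even-length k-mer can equal its own reverse complement
  (e.g. `ACGT`); such palindromes would make the canonical choice ambiguous
  and double-count themselves. Odd k removes the case entirely, so
  constructors reject even k.
* **k is at most 31.** 31 bases fill 62 of the 64 available bits.

Windows containing any non-`ACGT` character contribute nothing; I/O is
deliberately permissive (IUPAC codes are accepted in reads) and counting is
strict. The R-level helpers `encode_kmer()`/`revcomp_code()` return numeric
codes and are limited to k ≤ 26 because an R double holds integers exactly
only up to 2^53; the counting, seeding and traversal engines keep codes in
native 64-bit form internally, so the full k range is available where it
matters.

The default k is 21: long enough that a 15-base searched primer fits inside
one k-mer with headroom, short enough that modest-depth data still covers
every window of a target locus.

## Primer processing

The searched primer is the 3'-most `trim_len` bases of the input primer
(default 15). Benchtop primers are usually longer than specificity requires
— the extra 5' length tunes melting temperature — and every extra searched
base is an extra opportunity for a mismatch against the sequenced organism,
so trimming *increases* recovery without much specificity cost. Processing
order is: orient (reverse primer only) → trim → IUPAC expansion → mismatch
expansion.

The subtlest convention in the package is the reverse primer's orientation.
The reverse primer is reverse-complemented so it reads on the same strand as
the forward primer; its 3' end therefore lands at the *start* of the
oriented text, so trimming the oriented text keeps its *first* `trim_len`
bases, and end k-mers must *end* with one of the resulting variants.
Products consequently terminate at the trimmed reverse site. (Trimming
before or after orientation is equivalent; what matters is which end of the
oriented text survives.)

IUPAC degeneracies are resolved into the full Cartesian product of
per-position base sets, then all sequences within Hamming distance
`mismatches` (default 2) of any resolved sequence are added. The two
expansions compose: a degenerate position contributes distance 0 to each of
its own resolutions. Mismatches are permitted at any position, including the
3'-terminal base; a benchtop polymerase cares most about the 3' end, but the
assembly graph has no such chemistry, and restricting mismatch positions
would only shrink the seed set. The expansion is capped at 65536 variants —
a fully degenerate searched primer is a usability error, not a use case.

Seed sets are built by scanning the counted table (both orientations of
every canonical key) rather than re-scanning reads: prefix codes of the
forward variants and suffix codes of the oriented reverse variants are
hashed, so the scan is one table pass regardless of how many variants exist.
No minimum count is demanded of a seed beyond presence in the table;
coverage filtering belongs to the traversal, which applies its floor
uniformly to every window including the seed itself.

## Traversal semantics

From each start k-mer a breadth-first enumeration extends paths one base at
a time (successors tried in the fixed order A, C, G, T) through k-mers whose
canonical count is at least `min_count`. Three rules shape the output:

* **Emit-and-continue.** Reaching an end k-mer inside the length window
  records the product but does not stop the path: the window can contain
  several qualifying lengths (nested products), and stopping early would
  hide the longer ones. Deduplication by exact sequence prevents double
  reporting.
* **No revisits within a path.** A path may not step on the same *oriented*
  k-mer twice. Without this rule any tandem repeat between the primers
  yields unboundedly many products. Orientation-specific bookkeeping was
  chosen (rather than canonical-form bookkeeping) because the traversal
  graph's nodes are oriented k-mers: a locus containing an inverted repeat
  legitimately visits a k-mer and later its reverse complement, and
  canonical bookkeeping would forbid reconstructing it.
* **Live-path cap.** At most `max_paths` (default 10000) paths per start
  k-mer are alive at once; beyond that the frontier is truncated and a
  warning names the pair. Highly repetitive or high-error graphs can hold
  astronomically many simple paths; the cap converts a silent hang into an
  observable, deterministic outcome. Tests that compare against exhaustive
  path enumeration raise the cap so the comparison is exact.

`min_count` defaults to 2, which drops k-mers seen once — overwhelmingly
sequencing errors at realistic depths — while keeping genuine low-depth
targets reachable. For error-free simulations it should be 1, and every
such example in the package sets it explicitly.

Products report `min_coverage` and `mean_coverage`, the minimum and mean
canonical count over all k-windows of the product, computed by re-scanning
the product against the table. Output order (pair, descending minimum
coverage, length, sequence) and the fixed successor order make every run
byte-for-byte reproducible; the assembly path contains no randomness at all.

## The synthetic-data generator

`build_genome()` embeds amplicons — forward site + insert +
reverse-complemented reverse site — at random non-overlapping loci on random
strands of a uniform-random background, with optional per-copy
substitutions and multi-copy placement (mimicking high-copy organellar and
ribosomal targets). `simulate_reads()` draws reads uniformly over positions
and strands and applies a substitution-only error model: each base flips to
a uniformly chosen different base with probability `error_rate`. All
randomness flows from one explicit seed through a local RNG, so fixtures
are reproducible and the caller's RNG state is untouched.

What the simulator does *not* emulate: indels, quality-score profiles,
GC-coverage bias, PCR duplicates, fragment-length distributions, and real
contaminant mixtures. Tests passing on these fixtures therefore demonstrate
the *algorithmic* contract — exact recovery when coverage is complete and
k-mers are unique, correct handling of variants, strand symmetry, gating —
not performance on real libraries, where error structure and graph
complexity are harsher. The one deliberately realistic touch is uneven
coverage from uniform sampling, which exercises the coverage floor.

End-to-end validation uses 15 bp primer binding sites, equal to the default
`trim_len`, so the expected product is the embedded amplicon base for base.
With longer sites the product would start at the trimmed forward position
and end at the trimmed reverse position — a coordinate offset, not an
error — and the fixtures avoid that bookkeeping on purpose.

Default study conditions for the end-to-end checks: a 10 kb genome, one
600 bp amplicon (570 bp insert), 150 bp reads at 50x depth (3333 reads),
k = 21, error-free, `min_count = 1`. These sizes keep the full suite and
the acceptance script in the tens of seconds while leaving every window of
the target covered with near-certainty.

## Numerical and degenerate-input choices

* Chunk boundaries for incremental counting are by read count, near-equal,
  remainder to the earlier chunks; with fewer reads than chunks the trailing
  increments repeat the previous spectrum.
* Spectrum histograms pool counts at or above `max_multiplicity` into the
  top bin (default 10000), the usual treatment for plotting and model
  fitting on spectra.
* Read subsetting (`max_reads`) is first-N, applied jointly across input
  files before counting. Random subsampling was considered and left out:
  first-N is reproducible without extra state, and depth experiments can
  shuffle externally if they need randomness.
* Degenerate inputs degrade to empty results, not errors: reads shorter
  than k count nothing, an empty product set writes an empty FASTA, an
  empty table yields an empty spectrum. Configuration contradictions (even
  k, k < searched primer length, min_length > max_length) are fatal before
  any counting starts.
* `primers_not_found` is a reported per-pair outcome, never a process
  failure: a panel run must not abort because one locus is absent.

## Known limitations

* No error correction or bubble popping: a sequencing error inside the
  target at depth comparable to `min_count` splits or truncates products
  rather than being healed.
* Substitution-only validation: indel behaviour is untested by design
  (`simulate_reads` cannot produce them).
* The whole k-mer table lives in memory; the intended scale is desk-sized
  read sets, not production metagenomes.
* Products are reported verbatim with coverage statistics; no ranking,
  consensus-building or nested-product filtering beyond deduplication and
  the deterministic sort. Downstream identity checks (e.g. BLAST) are out
  of scope.
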