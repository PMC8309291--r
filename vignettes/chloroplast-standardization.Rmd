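---
title: "Standardizing chloroplast genome records and measuring the phylogenetic impact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing chloroplast genome records and measuring the phylogenetic impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A typical land-plant chloroplast genome is a circular molecule of roughly
120–160 kb with a quadripartite architecture: a large single-copy region
(LSC) and a small single-copy region (SSC) separated by two inverted
repeats (IRb and IRa) whose sequences are reverse complements of one
another. Two biological and technical facts make the *stored* linear form
of such a genome ambiguous. First, the molecule is circular, so any
rotation of the linearization is the same genome. Second, intramolecular
recombination between the IR copies ("flip-flop" recombination) means every
individual carries isoforms differing in single-copy region orientation, and
assemblers pick one arbitrarily. Public database records therefore disagree
in origin choice and region orientation, and whole-genome alignments built
from mixed forms align non-homologous sequence, degrading downstream
phylogenetics.

`chloronorm` fixes a canonical linearization — the **standard form** — and
provides the machinery to detect it, to diagnose how a record deviates from
it, and to rewrite sequence plus annotations into it:

* origin at the IRa/LSC boundary, reading direction into the LSC;
* region order LSC, IRb, SSC, IRa;
* each region oriented so that its characteristic genes lie mostly on the
  negative strand: *rpl*/*rps* genes for the LSC, all genes for the SSC and
  *rrn* genes for the IRb.

## Structure detection

The partition is taken from annotation: exactly two disjoint
`repeat_region` features of near-equal length (tolerance `irTol`, default
100 bp — annotated copies of an idealized identical pair may differ
slightly at boundaries) split the circle into two gaps; the longer gap is
the LSC, the shorter the SSC. Equal gaps raise an error rather than guess.
Repeat annotations book-ended within 10 bp are merged first, because
short-read assemblies often misassign about 10 bp at IR boundaries. Records
with zero or one usable repeat annotation are classified `no_ir` and
omitted from standardization — with no IR pair there is no way to relate the
record to the standard form.

A de novo finder (`findInvertedRepeats()`) is included for bare sequences.
It requires exact reverse-complement identity and finds the maximal-length
disjoint pair by seeded hashing against the reverse complement of the
circle, with character-level run extension; ties break to the smallest
start coordinate. Exactness keeps the tool deterministic; degraded IRs are
out of scope. The synthetic generator plants IRs whose flanking bases
cannot extend the match, so the annotated arcs are also the unique maximal
pair and the finder can be validated against an exhaustive oracle.

## Orientation voting and classification

Each orientation test counts gene strands inside one region arc
(`strandCounts()`), using only features of kind `gene` wholly inside the
arc; genes straddling arc boundaries are excluded. Gene names are matched
by their leading characters before the first digit, case-insensitively
(`rpl2`, `rps12`, `rrn16` match `rpl`, `rps`, `rrn`). A region needs
flipping when the vote is majority positive. A tied vote falls back to
counting all genes in the arc; a tie that survives the fallback raises
`undeterminedOrientationError` — silent guessing would be worse than an
explicit failure.

IR labels are confirmed by the *rrn* vote: the copy reading its *rrn* genes
majority-negative is IRb. When that copy is not the one positionally
following the LSC, the circle reads LSC, IRa, SSC, IRb — this positional
discrepancy *is* the "inverted IRs" deviation, and repairing it inverts
both copies so the output keeps IRa = revcomp(IRb).

`classifyForm()` gathers four independent causes — cyclic shift, inverted
LSC, inverted SSC, inverted IRs — into one category: `standard` (none),
the single cause's name, or `combination` (two or more).

### The 10 bp shift threshold

The cyclic-shift offset is the position of the LSC start in the stored
record, reported raw in `[0, L)`. A shift counts as a deviation only when
its *circular distance* `min(offset, L - offset)` is at least 10 bp: the
motivation for the threshold is the ~10 bp boundary misassignment noted
above, which can fall on either side of the true boundary, so a 3 bp
"negative" rotation (raw offset `L - 3`) is equally spurious and is also
left untouched. Sub-threshold rotations classify as `standard` and the
residues keep their small rotation.

### Whole-molecule reverse complement

A useful identity the package relies on: for a standard genome
`G = LSC · IRb · SSC · IRa`, the reverse complement is

```
revcomp(G) = IRb · revcomp(SSC) · IRa · revcomp(LSC)
```

because `revcomp(IRa) = IRb`. Read circularly from the LSC, the IR pair is
still in standard arrangement; the deviation is exactly inverted LSC +
inverted SSC + a cyclic shift of `len(SSC) + 2·len(IR)`. A
reverse-complemented record is therefore diagnosed as a `combination` of
those three causes (not as a flip of all three regions), and standardizing
it recovers the original bit-exactly. This falls out of the arithmetic
rather than being a special case, and the test suite asserts it.

## Conversion and the transformation record

`toStandardForm()` applies the two procedures in a fixed order: the cyclic
shift first (left rotation moving the IRa/LSC boundary to the origin), then
in-place inverse complement of each flipped region in standard-form
coordinates. The edit script is returned as a `Transformation`
(`rotateBy`, `invert`) and replaying it on the source record with
`applyTransformation()` reproduces the output exactly — an audit trail for
batch processing.

Feature remapping: rotation shifts coordinates modulo L; inversion of arc
`(a, b)` maps an interval `(s, e, strand)` wholly inside it to
`(a + b − e, a + b − s, −strand)`. Features straddling region boundaries
are dropped with a warning naming them, not split: practical pipelines
re-annotate standardized sequences anyway, and a split policy could be
added behind the same interface later.

## Tree distances and scaling

The impact of standardization on phylogenies is measured with four
distances:

* **RF** — the symmetric difference of nontrivial bipartition sets
  (unrooted, topology only);
* **KC_T** and **KC** — Kendall–Colijn distance at λ = 0 and λ = 0.5. For
  leaves sorted lexicographically, a tree maps to a vector of
  `(1−λ)·m + λ·M` over leaf pairs, where `m` and `M` are the edge count and
  path length from the root to the pair's MRCA, plus per-leaf pendant
  entries `(1−λ) + λ·pendant length`; the distance is the Euclidean norm of
  the vector difference. KC requires rooted trees; `compareSuite()` roots
  both at a user-supplied outgroup, splitting its pendant edge at the
  midpoint (a neutral choice that conserves total tree length);
* **BS** — branch score: the square root of summed squared branch-length
  differences over the union of all bipartitions, pendant edges included,
  an absent split contributing length 0. The square-root (distance) form is
  the convention of the branch-score literature and keeps BS commensurate
  with KC.

Because the maximum of each distance grows with the number of leaves `n`,
values are scaled for comparability across datasets: RF by `2n − 3` (the
branch count of a fully resolved unrooted tree — used even for
multifurcating inputs, so the denominator is a function of `n` alone),
KC_T by `C(n, 2)`, KC by `C(n, 2) + n`, and BS by the sum of branch
lengths of both trees (which bounds the scaled BS by 1, since
`sqrt(Σ(a−b)²) ≤ Σa + Σb` for nonnegative lengths). For `n = 56` these
give 109, 1540 and 1596. Pendant splits are included in BS but excluded
from RF, the standard conventions for each statistic.

At λ = 0 the pendant KC entries are constant 1 and contribute nothing to
the distance, so whether they are carried in the vector does not affect
KC_T; they are carried here so one vector definition serves all λ.

## The synthetic generator

`generateGenome()` builds a standard-form plastome with known ground truth:
default 84 kb LSC + 25 kb IRs + 18 kb SSC = 152 kb, inside the 120–160 kb
envelope of real plastomes. Residues are uniform random with IRa set
bit-exactly to revcomp(IRb); genes (300–1500 bp, placed non-overlapping by
rejection sampling) are planted wholly inside regions with strands
assigned by exact quota — default 75% negative for each characteristic set,
with tie-proof rounding — so orientation votes can never tie by chance.
Each IR copy carries four *rrn* genes, mirrored between copies with
opposite strands, matching the biological arrangement the orientation rule
exploits. Specs that would make a vote undeterminable (no SSC genes, no
*rrn* genes, majority fraction ≤ 0.5) are refused at construction.

`corruptGenome()` applies the deviations in reverse — rotations, in-place
region inversions, whole-molecule reverse complement, and compositions —
and attaches the algebraically-derived expected classification, giving
every test a ground truth. `randomTree()`/`perturbTree()` provide tree
pairs with tunable distance via NNI moves and log-normal branch-length
jitter.

What the generator does **not** emulate: realistic AT-rich base
composition, intergenic structure, introns, degraded or shifted IR
boundaries, multi-exon features, or sequence evolution. Passing the round
trip on synthetic data therefore demonstrates the correctness of the
coordinate arithmetic and the classification logic, not robustness to
messy real-world annotation (duplicate gene features, IR boundary drift),
which the error taxonomy (`no_ir`, `ambiguous`, `undetermined`) is designed
to surface rather than absorb.

## Numerical and design choices

* Internal coordinates are 0-based half-open everywhere; GenBank/GFF3 I/O
  converts to and from 1-based inclusive at the boundary. Origin-spanning
  GenBank `join` locations (and paired GFF3 rows sharing an ID) become one
  wrapping feature with `end > L`.
* All records are treated as circular for arithmetic; a missing circular
  flag in the source only triggers a warning, because the method
  presupposes circularity.
* Residues are uppercased on read; characters outside `{A, C, G, T, N}`
  are rejected so reverse complement is deterministic.
* Distance equality in tests is asserted at 1e−9 relative tolerance;
  distances themselves are plain double-precision arithmetic.
* Test problem sizes: the round-trip suite runs 525 seeded genome ×
  corruption pairs on full-size (~150 kb) genomes; the RF oracle is
  exhaustive over all 5,460 pairs of 6-leaf topologies; scaled-distance
  bounds use 1,000 random 20-leaf pairs; the IR-finder oracle uses 100
  planted-repeat sequences under 2 kb, where the quadratic brute-force
  reference is comfortable.

## Limitations

* Only exact IR pairs are found de novo; annotation-based partitioning is
  the primary path, as in the motivating pipeline.
* Multi-segment (intron-containing) feature locations are collapsed to
  their span on read.
* Boundary-straddling features are dropped during standardization, not
  split.
* GenBank output is a minimal flat-file subset (LOCUS/FEATURES/ORIGIN with
  `gene`/`note` qualifiers), sufficient for round-tripping this package's
  records, not a general GenBank emitter.
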