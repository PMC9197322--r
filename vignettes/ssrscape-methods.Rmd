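---
title: "ssrscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssrscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrscape)
```

## The problem

Simple sequence repeats (SSRs, microsatellites) are tandem repetitions of a
1–6 bp DNA unit whose repeat number mutates quickly, making them workhorse
markers for diversity analysis, fingerprinting and marker-assisted selection.
Reduced-representation sequencing (GBS/ddRAD) yields cheap per-genotype data,
but its coverage is partial and non-uniform, so polymorphic-marker discovery
cannot rely on alignment alone. ssrscape implements the alternative strategy:
mine SSRs from a chromosome-level reference assembly, mine them independently
from each genotype's *de novo* assembled contigs, and identify the same
physical locus across assemblies by the exact identity of the 20 nt of
sequence immediately flanking the tract on both sides. A reference locus
recovered in a genotype with the same repeat count is *monomorphic* there;
with a different count, *polymorphic*; loci whose tract spans ≥ 20 nt on
either side of the comparison are additionally flagged *hypervariable*.

## Mining model

A perfect SSR is a maximal run of a primitive 1–6 bp unit meeting a per-unit
minimum repeat count. The defaults are the widely used MISA-style plant
criteria: at least 10 repeats for mononucleotides, 6 for dinucleotides and 5
for tri- to hexanucleotides, with two tracts at most 100 nt apart merged into
a compound locus. The algorithmic contract:

* **Phase, not canonical form.** The unit is reported in the phase at which
  the tract begins; `TA` and `AT` are distinct motifs and no
  reverse-complement folding is applied. This matches how published motif
  frequency tables count the two separately.
* **Primitivity.** A candidate whose unit is itself a repetition of a shorter
  unit (`ATAT`) is suppressed; the shortest unit wins.
* **Maximality in whole units.** Tracts extend as far as full units go;
  `(TA)6T` is 6 repeats, tract length 12. Hence
  `tract_length == unit_length × repeat_count` for every simple locus.
* **Overlaps.** When surviving candidates overlap, the longer tract wins;
  ties break toward smaller unit length, then leftmost start. Thresholding
  happens *before* resolution, so a sub-threshold tract never suppresses a
  reported one. These rules are declared package behaviour: the upstream
  literature never documents its tool's tie-breaking.
* **N.** `N` terminates any tract; tracts never contain `N`.

The production miner is a vectorised scanner: for each unit length `u` it
marks positions where residue `i` equals residue `i+u`, and every maximal
run of marks is a periodic stretch whose first `u` phases are the possible
tract starts. Emitting **all** phases matters: overlap resolution may
eliminate the first phase (e.g. where a mononucleotide run borrows the first
base of a following dinucleotide tract) and a later phase is then the
correct, independent locus. This subtlety was caught by the package's
second, deliberately naive implementation — a brute-force enumerator over
every (position, unit, extension) triple written in C++ — which the test
suite holds equal to the scanner on thousands of random and repeat-rich
sequences. The two implementations share no code.

## Polymorphism calling

For every reference locus with two full, `N`-free 20-nt flanks, the
signature is the ordered pair (left flank, right flank). Genotype contigs
are mined in both orientations (assembly strand is arbitrary), and each
contig locus with a valid signature is indexed under its pair. Calling is
exact-match only — "similar" flanks are interpreted as identity, consistent
with the exact-matching language used for the validation step of the
original protocol; a mismatch-tolerant mode would trade precision for
recall and is deliberately not the default.

Decision table for a reference locus against one genotype:

| evidence | call |
|---|---|
| no signature hit | absent |
| hit, same motif (same phase), equal count | monomorphic |
| hit, same motif, different count | polymorphic |
| hits with conflicting counts | ambiguous |
| hit with a different motif between identical flanks | ambiguous |
| one genotype locus claimed by several reference loci | ambiguous (all parties) |

Compound loci are compared by their component-motif sequence and total
span: identical structure with a different total length is polymorphic.
Across a panel, per-genotype counts tally distinct reference loci, and a
locus polymorphic in at least one genotype is polymorphic in the union —
the precedence that makes "monomorphic union + polymorphic union = common
loci" an exact partition.

## Genomic context

Each locus is assigned by its midpoint to exactly one category, in fixed
priority order: promoter (TSS −1 kb … +100 bp, strand-aware), TTS
(TES −100 bp … +1 kb), exon, then intron+intergenic (reported merged, as
the source protocol reports them). Nearest TSS breaks ties between genes.
The midpoint-and-priority convention is a declared choice — annotation
tools differ and the upstream protocol does not say which rule its
annotator applied — which is why genome-scale category counts are not used
as acceptance values; the module is instead verified against simulator
truth, where the planted category is known.

## Primer design and e-PCR

The primer picker is a deliberately simple stand-in for a full
thermodynamic designer: it enumerates candidate k-mers (18–27 bp) on both
sides of the tract, filters on Wallace-rule melting temperature
(`2(A+T)+4(G+C)`, 57–63 °C), GC content (30–70 %) and product size
(100–300 bp measured between outer 5′ ends, inclusive), and ranks pairs by
Tm balance, then product size closest to 200 bp. The Wallace rule is exact,
deterministic and testable; nearest-neighbour models, hairpin and dimer
screens are out of scope. Published panels are placed by in-silico PCR:
exact, full-length, ungapped matching of the forward primer and the
reverse complement of the reverse primer in convergent orientation within
±200 bp of a catalogued tract, with roles also tried swapped because the
orientation of published primers relative to the assembly is arbitrary.
Every designed pair must re-amplify its own locus with the exact product
size (a round-trip property in the test suite), and a single substitution
in either primer must abolish placement.

## The simulator: a stated world

`simulate_reference()` / `simulate_genotypes()` generate the fixture world
the comparison assumes, with a complete truth table:

* Backgrounds are rejection-sampled *with the miner itself as the filter*,
  so the reference contains exactly the planted loci — no spurious tracts.
  Junction bases are chosen so a planted tract cannot extend into its
  surroundings, and abutting compound components are constrained so they
  cannot bridge into one periodic stretch.
* Defaults follow the acceptance scenario: 5 genotypes × 200 loci
  (5 chromosomes × 40), variant rate 0.3, full coverage, flank mutations
  off, contigs strand-flipped with probability 0.5. Loci are ≥ 2.5 kb apart
  so e-PCR windows and promoter/TTS windows of neighbours can never
  collide. Unit-length weights (0.15/0.30/0.25/0.15/0.05/0.10 for mono–hexa)
  and counts (threshold + 0–6) give a class mix in which di- and
  trinucleotides dominate and a realistic fraction of tracts crosses the
  20-nt hypervariable span; 10 % of loci are compound.
* Variant deltas are drawn from {−3…−1, +1…+3} and clipped upward when a
  negative delta would push the tract below its mining threshold; with
  `allow_subthreshold = TRUE` the locus becomes undetectable and the truth
  label switches to absent — both paths are tested.
* Each covered locus yields one contig (short GBS-like fragment) with 60 bp
  of intact reference context per side; `flank_mutation_rate` plants a
  substitution inside the 20-nt signature to exercise the exact-match rule.

What a green test on this world does *not* establish: behaviour under
assembly errors, chimeric contigs, flank SNPs between genotypes (real
panels will lose loci to them — they appear as absent, not as wrong
calls), copy-number duplication of flanking sequence, or the coverage
biases of real ddRAD libraries. The simulator is a correctness instrument,
not an error model.

## Numerical conventions

* Density is loci per Mb (10⁶ bp, decimal); the "average distance between
  two SSRs" is span/count — the exact reciprocal of density
  (`spacing_kb = 1000 / per_mb`) — not the mean inter-locus gap. The
  published chromosome tables obey this reciprocal exactly (e.g.
  1000/398.4 = 2.51), which forces the definition.
* Rates are rounded half-up to 2 decimals, count means to integers (base
  R's `round()` would round half to even). One published mean (3,907.65)
  was evidently truncated rather than rounded; the package rounds and the
  discrepancy is documented rather than imitated.
* All emitted coordinates are 1-based inclusive, stated in a comment line
  in every output table.
* Config files round-trip through JSON rather than YAML: the package's
  declared dependencies must be satisfiable offline, and jsonlite is
  universally available where the package is installed.

## Known limitations

* Interrupted/imperfect repeats beyond the compound rule are out of scope.
* The flank match requires perfect 20-mers: one SNP in a flank hides the
  locus from a genotype (by design — the cost of exactness is recall).
* The primer picker does not screen secondary structure.
* Per-genotype statistics assume one contig set per genotype; ploidy and
  allelic mixtures within a genotype are not modelled.
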