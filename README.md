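# ssrscape

Genome-wide microsatellite (SSR) mining and rapid polymorphic-marker
discovery from reduced-representation (GBS/ddRAD) assemblies, in R.

## Who this is for

Plant and animal genomics groups that have (i) a chromosome-level reference
assembly and (ii) cheap per-genotype GBS/ddRAD data, and want
location-specific, ready-to-use polymorphic SSR markers without whole-genome
resequencing. The package covers the full computational path: mining,
density statistics, genomic-region annotation, primer candidates, in-silico
PCR placement of published panels, and monomorphic/polymorphic/hypervariable
classification across a genotype panel — plus a deterministic simulator with
a complete truth table so every step is testable.

## The method in brief

A perfect SSR is a maximal tandem run of a primitive unit `u` (1–6 bp)
with at least `n_min(|u|)` repeats; defaults are the MISA-style criteria
`n_min = 10, 6, 5, 5, 5, 5` for mono- through hexanucleotides, and two
tracts ≤ 100 nt apart merge into one compound locus. Density is reported as
loci/Mb with mean spacing defined by the exact reciprocal
`spacing_kb = 1000 / per_mb`. A reference locus is identified in a genotype's
*de novo* contigs by exact identity of its 20-nt 5′ and 3′ flanking
signatures (both contig orientations are indexed); equal repeat count ⇒
monomorphic, different count ⇒ polymorphic, and a polymorphic locus whose
tract spans ≥ 20 nt in the reference and/or the genotype is hypervariable.
Primer candidates obey 18–27 bp, Wallace-rule Tm 57–63 °C
(`2(A+T) + 4(G+C)`), 30–70 % GC and 100–300 bp product size; published
primer pairs are placed by exact-match e-PCR within ±200 bp of catalogued
tracts. See `vignettes/ssrscape-methods.Rmd` for the full model and the
design decisions.

## Worked example

```r
library(ssrscape)

# a simulated world with planted repeat-number variants and a truth table
cfg   <- sim_config(seed = 1, n_chrom = 2, loci_per_chrom = 10, n_genotypes = 2)
sim   <- simulate_reference(cfg)
panel <- simulate_genotypes(sim)

loci <- mine_ssrs(sim$genome, cfg$thresholds)
head(loci[, c("locus_id", "ssr_class", "ssr", "repeat_count")], 3)
#>          locus_id ssr_class      ssr repeat_count
#> 1 chr01:2935-2967        p3  (ACA)11           11
#> 2 chr01:5811-5850        p4 (CGGA)10           10
#> 3 chr01:8594-8604        p1    (C)11           11

sigs  <- extract_flanks(loci, sim$genome, 20)
calls <- do.call(rbind, lapply(names(panel$contigs), function(g)
  call_genotype(sigs, index_genotype(panel$contigs[[g]], cfg$thresholds), g)))
head(calls[calls$status == "polymorphic", ], 3)
#>        ref_locus_id genotype_id      status genotype_repeat_count
#> 4 chr01:11199-11231         G01 polymorphic                     8
#> 7 chr01:20094-20125         G01 polymorphic                     5
#> 8 chr01:22713-22725         G01 polymorphic                    10
#>   genotype_tract_length matched_strand reason
#> 4                    24              +   <NA>
#> 7                    20              -   <NA>
#> 8                    10              +   <NA>

aggregate_calls(calls)$summary
#>   common monomorphic polymorphic
#> 1     20           9          11
```

Reading the output: all 20 planted loci were recovered in at least one
genotype ("common"); 11 were polymorphic somewhere in the panel (a locus
polymorphic in any genotype counts as polymorphic in the union), 9 were
monomorphic everywhere they matched. `chr01:11199-11231` is a 3-bp-unit
locus whose tract in genotype G01 has 8 repeats (24 nt) versus the
reference count — a hypervariable polymorphic marker, since 24 ≥ 20.
Against the truth table this panel reproduces the planted calls exactly
(that identity is an acceptance criterion of the test suite).

The same steps are reachable from the command line:

```sh
exec/ssrscape simulate --seed 1 --out world/
exec/ssrscape mine --fasta world/reference.fasta --out ssrs.tsv
exec/ssrscape call --fasta world/reference.fasta \
    --contigs world/genotype_G01.fasta,world/genotype_G02.fasta --out calls/
```

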