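Package: ssrscape
Title: Genome-Wide Microsatellite Mining and GBS-Based Polymorphic SSR Discovery
Version: 0.1.0
Authors@R:
    person("ssrscape", "developers", email = "ssrscape@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide discovery of simple sequence repeats (SSRs,
    microsatellites) and for calling polymorphic SSR markers from
    reduced-representation (GBS/ddRAD) assemblies. Detects perfect mono- to
    hexanucleotide repeats under configurable minimum-repeat thresholds, merges
    neighbouring tracts into compound loci, computes genome and per-chromosome
    density statistics, assigns loci to promoter/TTS/exon/intron+intergenic
    regions from a GFF3 annotation, designs primer-pair candidates under
    length/Tm/GC/product-size constraints, places primer panels by exact-match
    in-silico PCR, and classifies reference loci as monomorphic, polymorphic or
    hypervariable by exact 20-nt flank-signature matching against per-genotype
    de novo contigs. Includes a deterministic simulator that plants SSR
    landscapes, gene models and repeat-number variants with a full truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
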