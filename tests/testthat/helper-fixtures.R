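# shared fixture builders; everything is generated in code, nothing on disk

rand_dna <- function(n, alphabet = c("A", "C", "G", "T"), prob = NULL) {
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# repeat-rich sequence: alternating random stretches and tandem blocks, the
# regime where miner/oracle disagreements would hide
rand_repeat_rich <- function(n, with_n = FALSE) {
  ab <- c("A", "C", "G", "T", if (with_n) "N")
  parts <- character(0); len <- 0L
  while (len < n) {
    p <- if (runif(1) < 0.5) rand_dna(sample(5:40, 1), ab)
    else {
      u <- sample(1:6, 1)
      strrep(rand_dna(u), sample(2:14, 1))
    }
    parts <- c(parts, p); len <- len + nchar(p)
  }
  substr(paste(parts, collapse = ""), 1, n)
}

# cube-free Thue-Morse word over G/C: no block ever repeats 3 times in it,
# so it is SSR-free at every mining threshold (all minima >= 5); used as an
# inert interruption/spacer. First and last characters are pinned to G so a
# neighbouring A/T-rich tract can never extend into it.
filler <- function(n) {
  stopifnot(n >= 1)
  bits <- vapply(0:(n - 1), function(i)
    sum(as.integer(intToBits(i))) %% 2L, integer(1))
  s <- paste(c("G", "C")[bits + 1L], collapse = "")
  substr(s, 1L, 1L) <- "G"
  substr(s, n, n) <- "G"
  s
}

oracle_ssrs <- function(seq, thresholds = ssr_thresholds()) {
  as.data.frame(ssrscape:::.ssr_oracle_scan(toupper(seq), thresholds$min_repeats))
}

expect_same_loci <- function(mined, oracle) {
  expect_equal(nrow(mined), nrow(oracle))
  expect_equal(mined$start, oracle$start)
  expect_equal(mined$end, oracle$end)
  expect_equal(mined$motif, oracle$motif)
  expect_equal(mined$repeat_count, oracle$repeat_count)
}

# a tiny two-gene annotation used by the context tests:
# geneA: + strand 5001..8000, exons 5001..5600 and 7500..8000
# geneB: - strand 20001..23000, single exon
tiny_genes <- function() {
  read_gene_models(data.frame(
    seq_id = "chr1",
    type = c("gene", "mRNA", "exon", "exon", "gene", "mRNA", "exon"),
    start = c(5001L, 5001L, 5001L, 7500L, 20001L, 20001L, 20001L),
    end = c(8000L, 8000L, 5600L, 8000L, 23000L, 23000L, 23000L),
    strand = c(rep("+", 4), rep("-", 3)),
    id = c("geneA", "geneA.t1", "geneA.e1", "geneA.e2",
           "geneB", "geneB.t1", "geneB.e1"),
    parent = c(NA, "geneA", "geneA.t1", "geneA.t1", NA, "geneB", "geneB.t1"),
    stringsAsFactors = FALSE))
}

locus_row <- function(seq_id, start, end, motif = "TA", count = NA_integer_,
                      cls = "p2") {
  data.frame(seq_id = seq_id, start = as.integer(start), end = as.integer(end),
             ssr_class = cls, motif = motif, unit_length = nchar(motif),
             repeat_count = count,
             tract_length = as.integer(end - start + 1L),
             ssr = sprintf("(%s)%d", motif, count),
             locus_id = sprintf("%s:%d-%d", seq_id, start, end),
             stringsAsFactors = FALSE)
}

extdata <- function(f) system.file("extdata", f, package = "ssrscape")
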