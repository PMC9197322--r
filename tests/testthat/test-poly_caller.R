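# a minimal hand-built world: one reference locus, contigs derived from it
ref_world <- function(count_ref = 7L, motif = "AG") {
  set.seed(51)
  left <- rand_dna(60); right <- rand_dna(60)
  # junction bases must not extend the tract
  substr(left, 60, 60) <- "C"   # != last motif char G
  substr(right, 1, 1) <- "C"    # != first motif char A
  genome <- c(ref = paste0(left, strrep(motif, count_ref), right))
  loci <- mine_ssrs(genome)
  stopifnot(nrow(loci) == 1L, loci$repeat_count == count_ref)
  sigs <- extract_flanks(loci, genome, 20L)
  list(genome = genome, loci = loci, sigs = sigs, left = left, right = right,
       motif = motif)
}

contig_with_count <- function(w, count) {
  paste0(w$left, strrep(w$motif, count), w$right)
}

test_that("identical contig is monomorphic; changed count is polymorphic", {
  w <- ref_world(7L)
  idx <- index_genotype(c(tig1 = contig_with_count(w, 7L)))
  call <- call_locus(w$sigs, idx)
  expect_equal(call$status, "monomorphic")
  expect_equal(call$genotype_repeat_count, 7L)

  idx9 <- index_genotype(c(tig1 = contig_with_count(w, 9L)))
  call9 <- call_locus(w$sigs, idx9)
  expect_equal(call9$status, "polymorphic")
  expect_equal(call9$genotype_repeat_count, 9L)
  expect_equal(call9$matched_strand, "+")
})

test_that("one substitution inside a flank makes the locus absent", {
  w <- ref_world(7L)
  tig <- contig_with_count(w, 7L)
  # mutate 10 bp left of the tract (inside the 20-nt signature)
  p <- nchar(w$left) - 10L
  old <- substr(tig, p, p)
  substr(tig, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  call <- call_locus(w$sigs, index_genotype(c(tig1 = tig)))
  expect_equal(call$status, "absent")
})

test_that("reverse-complemented contigs match identically, strand recorded", {
  w <- ref_world(7L)
  tig <- contig_with_count(w, 9L)
  fw <- call_locus(w$sigs, index_genotype(c(tig1 = tig)))
  rc <- call_locus(w$sigs, index_genotype(c(tig1 = revcomp(tig))))
  expect_equal(rc$status, fw$status)
  expect_equal(rc$genotype_repeat_count, fw$genotype_repeat_count)
  expect_equal(fw$matched_strand, "+")
  expect_equal(rc$matched_strand, "-")
})

test_that("SSR too close to a contig end is not indexed", {
  w <- ref_world(7L)
  tig <- contig_with_count(w, 7L)
  short <- substr(tig, 56, nchar(tig))  # leaves only 5 bp of left flank
  idx <- index_genotype(c(tig1 = short))
  expect_equal(nrow(idx$entries), 0L)
  expect_equal(call_locus(w$sigs, idx)$status, "absent")
})

test_that("conflicting counts across contigs are ambiguous", {
  w <- ref_world(7L)
  idx <- index_genotype(c(tig1 = contig_with_count(w, 8L),
                          tig2 = contig_with_count(w, 9L)))
  call <- call_locus(w$sigs, idx)
  expect_equal(call$status, "ambiguous")
  # but two contigs agreeing on the count are a single consistent call
  idx2 <- index_genotype(c(tig1 = contig_with_count(w, 9L),
                           tig2 = contig_with_count(w, 9L)))
  expect_equal(call_locus(w$sigs, idx2)$status, "polymorphic")
})

test_that("flank-identical hit with a different motif is ambiguous", {
  w <- ref_world(7L, motif = "AG")
  # TG cannot extend into the C-terminated flanks, so the tract keeps the
  # exact reference coordinates and both flanks match verbatim
  tig <- paste0(w$left, strrep("TG", 7), w$right)
  call <- call_locus(w$sigs, index_genotype(c(tig1 = tig)))
  expect_equal(call$status, "ambiguous")
  expect_equal(call$reason, "motif_mismatch")
})

test_that("an invalid reference signature is absent with a reason", {
  w <- ref_world(7L)
  sig <- w$sigs
  sig$valid <- FALSE
  call <- call_locus(sig, index_genotype(c(tig1 = contig_with_count(w, 7L))))
  expect_equal(call$status, "absent")
  expect_equal(call$reason, "invalid_signature")
})

test_that("compound loci are callable by total span with same structure", {
  set.seed(52)
  left <- rand_dna(60); right <- rand_dna(60)
  substr(left, 60, 60) <- "C"; substr(right, 1, 1) <- "C"
  gapseq <- "GGTCG"
  build <- function(c1, c2) paste0(left, strrep("TA", c1), gapseq,
                                   strrep("ATC", c2), right)
  genome <- c(ref = build(6L, 5L))
  loci <- mine_ssrs(genome)
  expect_equal(loci$ssr_class, "c")
  sigs <- extract_flanks(loci, genome, 20L)
  same <- call_locus(sigs, index_genotype(c(t1 = build(6L, 5L))))
  expect_equal(same$status, "monomorphic")
  diff <- call_locus(sigs, index_genotype(c(t1 = build(6L, 7L))))
  expect_equal(diff$status, "polymorphic")
  expect_equal(diff$genotype_tract_length, 12L + 5L + 21L)
})

test_that("hypervariable keeps polymorphic calls by the and/or span rule", {
  sigs <- rbind(
    data.frame(locus_id = "L1", tract_length = 18L),  # ref (TA)9
    data.frame(locus_id = "L2", tract_length = 20L),  # ref (TA)10
    data.frame(locus_id = "L3", tract_length = 16L))  # ref (TA)8
  calls <- data.frame(
    ref_locus_id = c("L1", "L2", "L3"),
    genotype_id = "G1",
    status = "polymorphic",
    genotype_repeat_count = c(11L, 8L, 9L),
    genotype_tract_length = c(22L, 16L, 18L),
    matched_strand = "+", reason = NA_character_,
    stringsAsFactors = FALSE)
  hv <- hypervariable_calls(calls, sigs)
  expect_equal(sort(hv$ref_locus_id), c("L1", "L2"))  # L3: both < 20 -> dropped
  # monomorphic calls never qualify
  calls$status <- "monomorphic"
  expect_equal(nrow(hypervariable_calls(calls, sigs)), 0L)
})

test_that("aggregation puts mixed-status loci in the polymorphic union", {
  calls <- rbind(
    data.frame(ref_locus_id = "L1", genotype_id = "G1", status = "monomorphic"),
    data.frame(ref_locus_id = "L1", genotype_id = "G2", status = "polymorphic"),
    data.frame(ref_locus_id = "L2", genotype_id = "G1", status = "polymorphic"),
    data.frame(ref_locus_id = "L2", genotype_id = "G2", status = "polymorphic"),
    data.frame(ref_locus_id = "L3", genotype_id = "G1", status = "monomorphic"),
    data.frame(ref_locus_id = "L3", genotype_id = "G2", status = "absent"),
    data.frame(ref_locus_id = "L4", genotype_id = "G1", status = "absent"),
    data.frame(ref_locus_id = "L4", genotype_id = "G2", status = "absent"))
  agg <- aggregate_calls(calls)
  expect_equal(agg$polymorphic_union, c("L1", "L2"))  # L1 poly in >=1 genotype
  expect_equal(agg$monomorphic_union, "L3")
  expect_equal(sort(agg$common), c("L1", "L2", "L3"))
  expect_equal(agg$summary$common,
               agg$summary$monomorphic + agg$summary$polymorphic)
  expect_equal(agg$per_genotype$polymorphic, c(1L, 2L))
  expect_equal(agg$per_genotype$monomorphic, c(2L, 0L))
  # empty panel
  empty <- aggregate_calls(calls[0, ])
  expect_equal(empty$summary$common, 0L)
})

test_that("adding contigs never converts polymorphic to absent", {
  w <- ref_world(7L)
  c1 <- c(tig1 = contig_with_count(w, 9L))
  call1 <- call_locus(w$sigs, index_genotype(c1))
  expect_equal(call1$status, "polymorphic")
  set.seed(53)
  c2 <- c(c1, tig2 = rand_dna(150))  # unrelated contig
  call2 <- call_locus(w$sigs, index_genotype(c2))
  expect_equal(call2$status, "polymorphic")
})
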