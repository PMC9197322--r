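test_that("threshold boundaries are exact for every unit length", {
  thr <- ssr_thresholds()
  cases <- list(
    list(tract = strrep("A", 10), motif = "A", count = 10L, found = TRUE),
    list(tract = strrep("A", 9), found = FALSE),
    list(tract = strrep("TA", 6), motif = "TA", count = 6L, found = TRUE),
    list(tract = strrep("TA", 5), found = FALSE),
    list(tract = strrep("ATC", 5), motif = "ATC", count = 5L, found = TRUE),
    list(tract = strrep("ATC", 4), found = FALSE),
    list(tract = strrep("AGGT", 5), motif = "AGGT", count = 5L, found = TRUE),
    list(tract = strrep("AGGT", 4), found = FALSE),
    list(tract = strrep("ACGTC", 5), motif = "ACGTC", count = 5L, found = TRUE),
    list(tract = strrep("ACGTC", 4), found = FALSE),
    list(tract = strrep("ACGTCC", 5), motif = "ACGTCC", count = 5L, found = TRUE),
    list(tract = strrep("ACGTCC", 4), found = FALSE))
  for (cs in cases) {
    loci <- find_perfect_ssrs(paste0("GG", cs$tract, "CT"), thr)
    if (cs$found) {
      expect_equal(nrow(loci), 1L, info = cs$tract)
      expect_equal(loci$motif, cs$motif)
      expect_equal(loci$repeat_count, cs$count)
      expect_equal(loci$start, 3L)
      expect_equal(loci$end, 2L + nchar(cs$tract))
    } else {
      expect_equal(nrow(loci), 0L, info = cs$tract)
    }
  }
})

test_that("tracts are maximal in full units; trailing partial unit excluded", {
  loci <- find_perfect_ssrs(paste0("C", strrep("TA", 6), "T", "GGC"))
  expect_equal(loci$repeat_count, 6L)
  expect_equal(loci$tract_length, 12L)
  expect_equal(loci$end, 13L)
})

test_that("motifs are reported in tract-start phase and are primitive", {
  # TA and AT counted separately, no canonicalisation
  s <- paste0("C", strrep("TA", 6), "GGC", strrep("AT", 6), "GG")
  loci <- find_perfect_ssrs(s)
  expect_equal(loci$motif, c("TA", "AT"))
  # (AT)n never reported as ATAT
  loci2 <- find_perfect_ssrs(paste0("G", strrep("AT", 8), "C"))
  expect_equal(loci2$motif, "AT")
  expect_equal(loci2$unit_length, 2L)
})

test_that("N terminates tracts and non-DNA characters are an input error", {
  s <- paste0(strrep("A", 6), "N", strrep("A", 6))
  expect_equal(nrow(find_perfect_ssrs(s)), 0L)
  s2 <- paste0("GG", strrep("A", 10), "N", strrep("A", 10), "TT")
  loci <- find_perfect_ssrs(s2)
  expect_equal(nrow(loci), 2L)
  expect_false(any(grepl("N", substring(s2, loci$start, loci$end))))
  expect_error(find_perfect_ssrs("ACGTXACGT"), "position 5")
})

test_that("overlapping candidates resolve to the longer tract", {
  # (A)11 directly followed by (AG)6: mono tract is 11 nt, the dinucleotide
  # stretch reuses the last A, 12 nt, so the dinucleotide tract must win
  s <- paste0("CC", strrep("A", 10), strrep("AG", 6), "TT")
  loci <- find_perfect_ssrs(s)
  expect_true("AG" %in% loci$motif)
  mined <- oracle_ssrs(s)
  expect_same_loci(loci, mined)
})

test_that("planted tracts are recovered exactly at planted coordinates", {
  set.seed(11)
  thr <- ssr_thresholds()
  for (rep in 1:25) {
    u <- sample(1:6, 1)
    count <- thr$min_repeats[u] + sample(0:5, 1)
    motif <- rand_dna(u)
    while (!ssrscape:::is_primitive_motif(motif)) motif <- rand_dna(u)
    # repeat-free background (checked with the independent oracle) whose
    # junction bases cannot extend the tract
    repeat {
      bg1 <- rand_dna(300); bg2 <- rand_dna(300)
      if (substr(bg1, 300, 300) == substr(motif, u, u)) next
      if (substr(bg2, 1, 1) == substr(motif, 1, 1)) next
      if (nrow(oracle_ssrs(paste0(bg1, "GCA", bg2), thr))) next
      break
    }
    s <- paste0(bg1, strrep(motif, count), bg2)
    loci <- find_perfect_ssrs(s, thr)
    expect_equal(nrow(loci), 1L)
    expect_equal(loci$start, 301L)
    expect_equal(loci$end, 300L + u * count)
    expect_equal(loci$motif, motif)
    expect_equal(loci$repeat_count, count)
  }
})

test_that("raising any minimum repeat count never adds loci", {
  set.seed(12)
  base <- ssr_thresholds()
  for (i in 1:10) {
    s <- rand_repeat_rich(3000)
    loci0 <- find_perfect_ssrs(s, base)
    for (u in 1:6) {
      mr <- base$min_repeats
      mr[u] <- mr[u] + 2L
      loci1 <- find_perfect_ssrs(s, ssr_thresholds(mr))
      k0 <- paste(loci0$start, loci0$end, loci0$motif)
      k1 <- paste(loci1$start, loci1$end, loci1$motif)
      expect_lte(nrow(loci1), nrow(loci0))
      # a locus surviving the stricter threshold may differ only because an
      # overlap competitor disappeared; loci at unaffected units persist
      expect_true(all(loci1$repeat_count[loci1$unit_length == u] >= mr[u]))
    }
  }
})

test_that("compound merge boundaries: gap 100 merges, 101 does not, 0 is c*", {
  make <- function(gap) {
    s <- paste0(strrep("TA", 6), filler(gap), strrep("ATC", 5))
    merge_compound(find_perfect_ssrs(s), 100L, seq = s)
  }
  m100 <- make(100L)
  expect_equal(nrow(m100), 1L)
  expect_equal(m100$ssr_class, "c")
  expect_equal(nrow(m100$components[[1]]), 2L)
  expect_equal(m100$start, 1L)
  expect_equal(m100$end, 12L + 100L + 15L)

  m101 <- make(101L)
  expect_equal(nrow(m101), 2L)
  expect_true(all(m101$ssr_class == c("p2", "p3")))

  s0 <- paste0(strrep("TA", 6), strrep("CCG", 5))
  m0 <- merge_compound(find_perfect_ssrs(s0), 100L, seq = s0)
  expect_equal(m0$ssr_class, "c*")
  expect_equal(m0$ssr, "(TA)6(CCG)5")

  # 50-nt interruption appears lower-case in the display string
  m50 <- make(50L)
  expect_equal(m50$ssr, paste0("(TA)6", tolower(filler(50L)), "(ATC)5"))
})

test_that("single loci pass through merge unchanged and bp is conserved", {
  s <- paste0("GC", strrep("AAG", 5), "TT")
  loci <- find_perfect_ssrs(s)
  merged <- merge_compound(loci, 100L, seq = s)
  expect_equal(merged$start, loci$start)
  expect_equal(merged$ssr_class, "p3")
  expect_null(merged$components[[1]])

  set.seed(13)
  for (i in 1:10) {
    s <- rand_repeat_rich(5000)
    loci <- find_perfect_ssrs(s)
    merged <- merge_compound(loci, 100L, seq = s)
    n_simple_out <- sum(!merged$ssr_class %in% c("c", "c*"))
    n_in_compounds <- sum(vapply(merged$components, function(x)
      if (is.null(x)) 0L else nrow(x), integer(1)))
    expect_equal(n_simple_out + n_in_compounds, nrow(loci))
  }
})

test_that("merge_compound rejects unsorted or overlapping input", {
  a <- find_perfect_ssrs(paste0(strrep("TA", 6), "GGGGG", strrep("ATC", 5)))
  expect_error(merge_compound(a[2:1, ], 100L), "sorted")
  b <- a; b$end[1] <- b$start[2] + 1L
  expect_error(merge_compound(b, 100L), "overlap")
})

test_that("hypervariable boundary: span 20 qualifies, 18 does not", {
  l20 <- find_perfect_ssrs(paste0("GC", strrep("TA", 10), "GG"))
  expect_true(is_hypervariable(l20))
  l18 <- find_perfect_ssrs(paste0("GC", strrep("TA", 9), "GG"))
  expect_false(is_hypervariable(l18))
  l10 <- find_perfect_ssrs(paste0("GC", strrep("A", 10), "GG"))
  expect_false(is_hypervariable(l10))
  # compounds measure total span including the interruption
  s <- paste0(strrep("TA", 6), "CCGCC", strrep("TA", 6))
  comp <- merge_compound(find_perfect_ssrs(s), 100L, seq = s)
  expect_equal(comp$ssr_class, "c")
  expect_true(is_hypervariable(comp))
})

test_that("mine_ssrs spans records and writes the MISA-style table", {
  genome <- c(s1 = paste0("GG", strrep("A", 10), "C", strrep("TTG", 6)),
              s2 = paste0("T", strrep("CA", 7), "G"))
  loci <- mine_ssrs(genome)
  expect_equal(loci$seq_id, c("s1", "s2"))  # s1 compound + s2 simple
  expect_equal(loci$ssr_class, c("c", "p2"))
  f <- tempfile(fileext = ".tsv")
  write_misa_tsv(loci, f)
  lines <- readLines(f)
  expect_equal(lines[2], "ID\tSSR nr.\tSSR type\tSSR\tsize\tstart\tend")
  tab <- read.delim(f, comment.char = "#", check.names = FALSE)
  expect_equal(tab$`SSR nr.`, c(1L, 1L))
  expect_equal(tab$start, loci$start)
  expect_equal(tab$size, loci$end - loci$start + 1L)
})

test_that("miner equals the brute-force oracle on repeat-rich sequences", {
  set.seed(21)
  thr <- ssr_thresholds()
  for (i in 1:60) {
    s <- rand_repeat_rich(4000, with_n = (i %% 3 == 0))
    expect_same_loci(find_perfect_ssrs(s, thr), oracle_ssrs(s, thr))
  }
  # and under non-default thresholds
  thr2 <- ssr_thresholds(c(8L, 4L, 3L, 3L, 3L, 3L))
  for (i in 1:20) {
    s <- rand_repeat_rich(2000)
    expect_same_loci(find_perfect_ssrs(s, thr2), oracle_ssrs(s, thr2))
  }
})
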