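#' Build a flank-signature index for one genotype's contigs
#'
#' Mines SSRs from every contig in both orientations (the given sequence and
#' its reverse complement, since de novo contigs have arbitrary strand) and
#' indexes every locus that carries two valid 20-nt flanks under its
#' `(left_flank, right_flank)` key. Loci closer than `flank_len` to a contig
#' end, or with `N` in a flank, are not indexed.
#'
#' @param contigs named character vector of contig sequences.
#' @param thresholds an [ssr_thresholds()] object (must match the reference
#'   mining thresholds).
#' @param flank_len signature flank length (default 20).
#' @return an object of class `genotype_index`: list with `entries`, a
#'   data.frame keyed by `key = left_flank|right_flank` with columns
#'   `contig_id`, `strand`, `motif`, `repeat_count`, `ssr_class`,
#'   `tract_length`, `entry_id` (physical identity of the genotype locus).
#' @export
index_genotype <- function(contigs, thresholds = ssr_thresholds(),
                           flank_len = 20L) {
  stopifnot(is.character(contigs))
  entries <- list()
  for (nm in names(contigs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contigs[[nm]] else revcomp(contigs[[nm]])
      loci <- mine_ssrs(setNames(s, nm), thresholds)
      if (!nrow(loci)) next
      sig <- extract_flanks(loci, setNames(s, nm), flank_len)
      ok <- sig$valid
      if (!any(ok)) next
      loci <- loci[ok, , drop = FALSE]; sig <- sig[ok, , drop = FALSE]
      # physical identity is orientation-independent: use the sense-strand
      # coordinates of the tract on the original contig
      n <- nchar(contigs[[nm]])
      pstart <- if (strand == "+") loci$start else n - loci$end + 1L
      pend <- if (strand == "+") loci$end else n - loci$start + 1L
      entries[[length(entries) + 1L]] <- data.frame(
        key = paste(sig$left_flank, sig$right_flank, sep = "|"),
        contig_id = nm, strand = strand,
        motif = loci$motif, repeat_count = loci$repeat_count,
        ssr_class = loci$ssr_class,
        tract_length = loci$end - loci$start + 1L,
        entry_id = sprintf("%s:%d-%d", nm, pstart, pend),
        stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries)
    else data.frame(key = character(), contig_id = character(),
                    strand = character(), motif = character(),
                    repeat_count = integer(), ssr_class = character(),
                    tract_length = integer(), entry_id = character(),
                    stringsAsFactors = FALSE)
  structure(list(entries = entries, flank_len = flank_len),
            class = "genotype_index")
}

#' @export
print.genotype_index <- function(x, ...) {
  cat("genotype_index:", nrow(x$entries), "indexed signatures (flank",
      x$flank_len, "nt)\n")
  invisible(x)
}

compound_structure <- function(ssr_class, motif) {
  # for compounds, identity of the component motif sequence is carried by the
  # display pattern with repeat counts stripped: "(TA)6x(ATC)5" -> "TA|ATC"
  ifelse(ssr_class %in% c("c", "c*"),
         vapply(regmatches(motif, gregexpr("\\(([ACGTN]+)\\)", motif)),
                function(m) paste(gsub("[()]", "", m), collapse = "|"),
                character(1)),
         motif)
}

call_one <- function(ref_sig, hits) {
  blank <- data.frame(status = "absent", genotype_repeat_count = NA_integer_,
                      genotype_tract_length = NA_integer_,
                      matched_strand = NA_character_, entry_id = NA_character_,
                      reason = NA_character_, stringsAsFactors = FALSE)
  if (!isTRUE(ref_sig$valid)) { blank$reason <- "invalid_signature"; return(blank) }
  if (!nrow(hits)) { blank$reason <- "no_flank_match"; return(blank) }
  hits <- hits[!duplicated(hits$entry_id), , drop = FALSE]
  ref_comp <- ref_sig$ssr_class %in% c("c", "c*")
  hit_comp <- hits$ssr_class %in% c("c", "c*")
  same_structure <- if (ref_comp) {
    hit_comp & compound_structure(hits$ssr_class, hits$motif) ==
      compound_structure(ref_sig$ssr_class, ref_sig$motif)
  } else !hit_comp & hits$motif == ref_sig$motif
  if (!all(same_structure)) {
    blank$status <- "ambiguous"; blank$reason <- "motif_mismatch"
    return(blank)
  }
  lens <- unique(hits$tract_length)
  if (length(lens) > 1L) {
    blank$status <- "ambiguous"; blank$reason <- "conflicting_counts"
    return(blank)
  }
  hit <- hits[1L, , drop = FALSE]
  same <- if (ref_comp) hit$tract_length == ref_sig$tract_length
          else hit$repeat_count == ref_sig$repeat_count
  data.frame(status = if (same) "monomorphic" else "polymorphic",
             genotype_repeat_count = hit$repeat_count,
             genotype_tract_length = hit$tract_length,
             matched_strand = hit$strand, entry_id = hit$entry_id,
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Call one reference locus against a genotype index
#'
#' Requires exact equality of both 20-nt flanks. A flank hit with the same
#' motif (after strand normalisation, which [index_genotype()] performs by
#' indexing both orientations) and equal repeat count is monomorphic; a
#' differing count is polymorphic; no hit is absent; hits with conflicting
#' counts, or a flank-identical hit with a different motif, are ambiguous.
#' Compound loci are compared by component motif sequence and total tract
#' span.
#'
#' @param ref_sig one-row data.frame from [extract_flanks()] for the
#'   reference locus.
#' @param index a [index_genotype()] result.
#' @return one-row data.frame: `ref_locus_id`, `status`,
#'   `genotype_repeat_count`, `genotype_tract_length`, `matched_strand`,
#'   `reason`.
#' @export
call_locus <- function(ref_sig, index) {
  stopifnot(inherits(index, "genotype_index"), nrow(ref_sig) == 1L)
  key <- paste(ref_sig$left_flank, ref_sig$right_flank, sep = "|")
  hits <- index$entries[index$entries$key == key, , drop = FALSE]
  out <- call_one(ref_sig, hits)
  cbind(data.frame(ref_locus_id = ref_sig$locus_id, stringsAsFactors = FALSE),
        out[setdiff(names(out), "entry_id")])
}

#' Call every reference locus against one genotype
#'
#' Vectorised driver over a reference signature catalog. After individual
#' calls, any genotype locus that satisfied more than one reference locus
#' demotes all involved calls to ambiguous (a genotype locus may satisfy at
#' most one reference locus).
#'
#' @param ref_sigs data.frame from [extract_flanks()] on the reference
#'   catalog.
#' @param index a [index_genotype()] result.
#' @param genotype_id identifier recorded in the output.
#' @return data.frame, one row per reference locus: `ref_locus_id`,
#'   `genotype_id`, `status`, `genotype_repeat_count`,
#'   `genotype_tract_length`, `matched_strand`, `reason`.
#' @export
call_genotype <- function(ref_sigs, index, genotype_id = "genotype") {
  stopifnot(inherits(index, "genotype_index"))
  keys <- paste(ref_sigs$left_flank, ref_sigs$right_flank, sep = "|")
  split_entries <- split(seq_len(nrow(index$entries)), index$entries$key)
  rows <- lapply(seq_len(nrow(ref_sigs)), function(i) {
    ix <- split_entries[[keys[i]]]
    hits <- index$entries[if (is.null(ix)) integer(0) else ix, , drop = FALSE]
    call_one(ref_sigs[i, , drop = FALSE], hits)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(ref_locus_id = ref_sigs$locus_id,
                          genotype_id = genotype_id, stringsAsFactors = FALSE),
               out)
  # many-to-one collisions: one genotype locus claimed by several refs
  matched <- !is.na(out$entry_id)
  dup <- out$entry_id[matched][duplicated(out$entry_id[matched])]
  if (length(dup)) {
    hitdup <- matched & out$entry_id %in% dup
    out$status[hitdup] <- "ambiguous"
    out$reason[hitdup] <- "many_to_one"
    out$genotype_repeat_count[hitdup] <- NA_integer_
    out$genotype_tract_length[hitdup] <- NA_integer_
  }
  out$entry_id <- NULL
  rownames(out) <- NULL
  out
}

#' Aggregate polymorphism calls across a genotype panel
#'
#' Produces per-genotype monomorphic/polymorphic counts (distinct reference
#' loci) and the panel-level unions. A reference locus polymorphic in at
#' least one genotype is polymorphic in the union even if monomorphic
#' elsewhere; the monomorphic union holds loci matched somewhere and
#' polymorphic nowhere, so the two unions partition the "common" loci.
#'
#' @param calls data.frame of stacked [call_genotype()] results for one
#'   reference catalog.
#' @return list: `per_genotype` (data.frame `genotype_id`, `monomorphic`,
#'   `polymorphic`), `polymorphic_union`, `monomorphic_union` (character
#'   vectors of reference locus ids), `common` (their union), and `summary`
#'   (one-row data.frame of the three sizes).
#' @export
aggregate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  if (!nrow(calls)) {
    per <- data.frame(genotype_id = character(), monomorphic = integer(),
                      polymorphic = integer(), stringsAsFactors = FALSE)
    return(list(per_genotype = per, polymorphic_union = character(),
                monomorphic_union = character(), common = character(),
                summary = data.frame(common = 0L, monomorphic = 0L,
                                     polymorphic = 0L)))
  }
  gt <- sort(unique(calls$genotype_id))
  per <- do.call(rbind, lapply(gt, function(g) {
    sub <- calls[calls$genotype_id == g, , drop = FALSE]
    data.frame(genotype_id = g,
               monomorphic = length(unique(sub$ref_locus_id[sub$status == "monomorphic"])),
               polymorphic = length(unique(sub$ref_locus_id[sub$status == "polymorphic"])),
               stringsAsFactors = FALSE)
  }))
  poly <- unique(calls$ref_locus_id[calls$status == "polymorphic"])
  mono <- setdiff(unique(calls$ref_locus_id[calls$status == "monomorphic"]), poly)
  list(per_genotype = per, polymorphic_union = poly, monomorphic_union = mono,
       common = union(mono, poly),
       summary = data.frame(common = length(mono) + length(poly),
                            monomorphic = length(mono),
                            polymorphic = length(poly)))
}

#' Hypervariable subset of polymorphism calls
#'
#' Keeps polymorphic calls whose reference tract or genotype tract spans at
#' least `cutoff` nucleotides ("and/or" rule).
#'
#' @param calls data.frame from [call_genotype()] (stacked ok).
#' @param ref_sigs reference signature catalog (provides the reference tract
#'   lengths via `locus_id`/`tract_length`).
#' @param cutoff nucleotide cutoff (default 20).
#' @return the qualifying subset of `calls` with a `hypervariable` column.
#' @export
hypervariable_calls <- function(calls, ref_sigs, cutoff = 20L) {
  ref_len <- ref_sigs$tract_length[match(calls$ref_locus_id, ref_sigs$locus_id)]
  keep <- calls$status == "polymorphic" &
    (ref_len >= cutoff | calls$genotype_tract_length >= cutoff)
  out <- calls[keep & !is.na(keep), , drop = FALSE]
  out$hypervariable <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a polymorphism-call table
#'
#' @param calls stacked [call_genotype()] output.
#' @param ref_sigs reference signatures (for reference counts and the
#'   hypervariable flag).
#' @param path output TSV path.
#' @param cutoff hypervariable cutoff (default 20).
#' @return the path, invisibly.
#' @export
write_calls_tsv <- function(calls, ref_sigs, path, cutoff = 20L) {
  m <- match(calls$ref_locus_id, ref_sigs$locus_id)
  tab <- data.frame(ref_locus_id = calls$ref_locus_id,
                    genotype = calls$genotype_id, status = calls$status,
                    ref_count = ref_sigs$repeat_count[m],
                    geno_count = calls$genotype_repeat_count,
                    strand = calls$matched_strand,
                    hypervariable = calls$status == "polymorphic" &
                      (ref_sigs$tract_length[m] >= cutoff |
                         (!is.na(calls$genotype_tract_length) &
                            calls$genotype_tract_length >= cutoff)),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
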