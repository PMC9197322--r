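#' Minimum-repeat thresholds for SSR mining
#'
#' Constructs the per-unit-length minimum repeat counts used by the miner,
#' plus the maximum interval allowed between the members of a compound locus.
#' Defaults follow the common MISA-style criteria for plant genomes:
#' mononucleotide tracts need at least 10 repeats, dinucleotide 6, and tri-
#' through hexanucleotide 5; two tracts at most 100 nt apart form a compound.
#'
#' @param min_repeats integer vector of length 6; `min_repeats[u]` is the
#'   minimum repeat count for unit length `u`. All values must be >= 2.
#' @param max_compound_interval maximum gap (bp) between consecutive tracts
#'   merged into one compound locus. Must be >= 0.
#' @return an object of class `ssr_thresholds`.
#' @examples
#' ssr_thresholds()
#' ssr_thresholds(min_repeats = c(12, 7, 5, 5, 5, 5))
#' @export
ssr_thresholds <- function(min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
                           max_compound_interval = 100L) {
  min_repeats <- as.integer(min_repeats)
  if (length(min_repeats) != 6L || anyNA(min_repeats) || any(min_repeats < 2L))
    stop("min_repeats must be six integers, all >= 2")
  max_compound_interval <- as.integer(max_compound_interval)
  if (is.na(max_compound_interval) || max_compound_interval < 0L)
    stop("max_compound_interval must be >= 0")
  structure(list(min_repeats = min_repeats,
                 max_compound_interval = max_compound_interval),
            class = "ssr_thresholds")
}

#' @export
print.ssr_thresholds <- function(x, ...) {
  cat("SSR mining thresholds\n")
  cat("  min repeats (unit 1..6):", paste(x$min_repeats, collapse = " "), "\n")
  cat("  max compound interval  :", x$max_compound_interval, "bp\n")
  invisible(x)
}

# TRUE for motifs that are not a repetition of a shorter unit.
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  vapply(seq_along(motif), function(i) {
    ui <- u[i]
    if (ui == 1L) return(TRUE)
    for (d in seq_len(ui - 1L)) {
      if (ui %% d != 0L) next
      if (strrep(substr(motif[i], 1L, d), ui / d) == motif[i]) return(FALSE)
    }
    TRUE
  }, logical(1))
}

empty_loci <- function() {
  data.frame(seq_id = character(), start = integer(), end = integer(),
             ssr_class = character(), motif = character(),
             unit_length = integer(), repeat_count = integer(),
             tract_length = integer(), ssr = character(),
             stringsAsFactors = FALSE)
}

# Greedy overlap resolution: longer tract wins, ties by smaller unit length,
# then leftmost start. Candidates must share one seq_id.
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  ord <- order(-cand$tract_length, cand$unit_length, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cand))) {
    s <- cand$start[i]; e <- cand$end[i]
    if (!any(s <= ke & e >= ks)) {
      kept[i] <- TRUE
      ks <- c(ks, s); ke <- c(ke, e)
    }
  }
  cand <- cand[kept, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Find perfect SSR tracts in one sequence
#'
#' Scans a DNA sequence for maximal perfect tandem repeats of unit length 1-6
#' that meet the per-unit minimum repeat count. Tracts are extended by full
#' repeat units only: a trailing partial unit is excluded, so `(TA)6T` is
#' reported as motif `TA`, 6 repeats, tract length 12. Motifs are reported in
#' the phase at which the tract begins (`TA` and `AT` are distinct motifs; no
#' cyclic or reverse-complement canonicalisation), and non-primitive motifs
#' (`ATAT` for an `AT` tract) are suppressed in favour of the shortest unit.
#' `N` terminates every tract; tracts never contain `N`. When surviving
#' candidate tracts overlap, the longer tract is kept, with ties broken by
#' smaller unit length and then leftmost start.
#'
#' Thresholding happens before overlap resolution: a tract below its
#' unit-length threshold never suppresses a reported one.
#'
#' @param seq a DNA string over `A`,`C`,`G`,`T`,`N` (case-insensitive).
#' @param thresholds an [ssr_thresholds()] object.
#' @param seq_id identifier recorded in the `seq_id` column.
#' @return a data.frame of simple loci sorted by start, with columns
#'   `seq_id`, `start`, `end` (1-based inclusive), `ssr_class` (`p1`..`p6`),
#'   `motif`, `unit_length`, `repeat_count`, `tract_length`, `ssr`
#'   (display string such as `"(TA)6"`).
#' @examples
#' find_perfect_ssrs(paste0("GG", strrep("A", 10), "CT"))
#' @export
find_perfect_ssrs <- function(seq, thresholds = ssr_thresholds(), seq_id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!inherits(thresholds, "ssr_thresholds"))
    stop("thresholds must be built with ssr_thresholds()")
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("non-DNA character '%s' at position %d of '%s'",
                 substr(seq, bad, bad), as.integer(bad), seq_id))
  n <- nchar(seq)
  if (n < 2L) return(empty_loci())
  r <- charToRaw(seq)
  isN <- r == charToRaw("N")

  starts <- integer(0); units <- integer(0); counts <- integer(0)
  for (u in 1:6) {
    minrep <- thresholds$min_repeats[u]
    if (n < u * minrep) next
    # m[i] is TRUE when residues i and i+u match and neither is N; a maximal
    # TRUE-run of length L starting at i is a periodic stretch of L+u residues
    # with period u, i.e. floor((L+u)/u) full repeat units from position i.
    idx <- seq_len(n - u)
    m <- (r[idx] == r[idx + u]) & !isN[idx] & !isN[idx + u]
    rl <- rle(m)
    rend <- cumsum(rl$lengths)
    rstart <- rend - rl$lengths + 1L
    keep <- rl$values & rl$lengths >= (minrep - 1L) * u
    if (!any(keep)) next
    L <- rl$lengths[keep]
    i0 <- rstart[keep]
    # a stretch admits tract starts at each of its first u phases (later
    # starts repeat a phase with fewer units); phase t keeps L+u-t residues
    for (t in 0:(u - 1L)) {
      k <- (L + u - t) %/% u
      ok <- k >= minrep
      if (!any(ok)) next
      starts <- c(starts, i0[ok] + t)
      units <- c(units, rep.int(u, sum(ok)))
      counts <- c(counts, k[ok])
    }
  }
  if (!length(starts)) return(empty_loci())

  motif <- substring(seq, starts, starts + units - 1L)
  cand <- data.frame(seq_id = seq_id, start = starts,
                     end = starts + units * counts - 1L,
                     ssr_class = paste0("p", units), motif = motif,
                     unit_length = units, repeat_count = counts,
                     tract_length = units * counts,
                     stringsAsFactors = FALSE)
  cand <- cand[is_primitive_motif(cand$motif), , drop = FALSE]
  if (!nrow(cand)) return(empty_loci())
  cand <- resolve_overlaps(cand)
  cand$ssr <- sprintf("(%s)%d", cand$motif, cand$repeat_count)
  rownames(cand) <- NULL
  cand
}

#' Merge neighbouring SSR tracts into compound loci
#'
#' Maximal runs of two or more simple loci in which every consecutive gap is
#' at most `max_interval` nucleotides are collapsed into one compound locus.
#' Isolated loci pass through unchanged. A compound is classed `c*` when any
#' pair of its components abuts directly (gap 0) and `c` otherwise. The
#' components are retained in a list column so that no information is lost.
#'
#' @param loci a data.frame of simple loci as returned by
#'   [find_perfect_ssrs()], sorted by `start`, one `seq_id`, non-overlapping.
#' @param max_interval maximum gap in bp (default 100).
#' @param seq optional sequence the loci were mined from; when given, the
#'   interruption sequence between components is embedded lower-case in the
#'   compound display string (MISA convention), otherwise components are
#'   joined with `*`.
#' @return a data.frame with the same columns as the input plus a
#'   `components` list column; compound rows have `NA` `unit_length` and
#'   `repeat_count` and class `c`/`c*`.
#' @examples
#' loci <- find_perfect_ssrs(paste0(strrep("TA", 6), "GCATG", strrep("ATC", 5)))
#' merge_compound(loci)
#' @export
merge_compound <- function(loci, max_interval = 100L, seq = NULL) {
  stopifnot(is.data.frame(loci))
  if (!nrow(loci)) {
    out <- empty_loci()
    out$components <- list()
    return(out)
  }
  if (length(unique(loci$seq_id)) > 1L)
    stop("merge_compound expects loci from a single seq_id")
  if (is.unsorted(loci$start, strictly = TRUE))
    stop("loci must be sorted by start (contract violation)")
  if (any(loci$start[-1L] <= loci$end[-nrow(loci)]))
    stop("loci must be non-overlapping (contract violation)")

  gap <- c(Inf, loci$start[-1L] - loci$end[-nrow(loci)] - 1L)
  grp <- cumsum(gap > max_interval)
  pieces <- lapply(split(seq_len(nrow(loci)), grp), function(ix) {
    sub <- loci[ix, , drop = FALSE]
    if (nrow(sub) == 1L) {
      sub$components <- list(NULL)
      return(sub)
    }
    gaps <- sub$start[-1L] - sub$end[-nrow(sub)] - 1L
    cls <- if (any(gaps == 0L)) "c*" else "c"
    disp <- sub$ssr[1L]
    for (j in seq_along(gaps)) {
      sep <- if (gaps[j] == 0L) ""
        else if (!is.null(seq)) tolower(substr(seq, sub$end[j] + 1L, sub$start[j + 1L] - 1L))
        else "*"
      disp <- paste0(disp, sep, sub$ssr[j + 1L])
    }
    comp <- data.frame(seq_id = sub$seq_id[1L], start = sub$start[1L],
                       end = sub$end[nrow(sub)], ssr_class = cls,
                       motif = disp, unit_length = NA_integer_,
                       repeat_count = NA_integer_,
                       tract_length = sub$end[nrow(sub)] - sub$start[1L] + 1L,
                       ssr = disp, stringsAsFactors = FALSE)
    comp$components <- list(sub[setdiff(names(sub), "components")])
    comp
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine SSR loci from a set of sequences
#'
#' Runs [find_perfect_ssrs()] on every record and, unless `compound = FALSE`,
#' merges neighbours into compound loci with [merge_compound()]. Adds a
#' stable `locus_id` (`<seq_id>:<start>-<end>`).
#'
#' @param genome named character vector of DNA sequences (see [read_fasta()]).
#' @param thresholds an [ssr_thresholds()] object.
#' @param compound merge compound loci? (default TRUE)
#' @return data.frame of loci across all records, sorted by seq_id then start.
#' @export
mine_ssrs <- function(genome, thresholds = ssr_thresholds(), compound = TRUE) {
  stopifnot(is.character(genome))
  if (length(genome) && is.null(names(genome)))
    stop("genome must be a named character vector")
  per <- lapply(seq_along(genome), function(i) {
    loci <- find_perfect_ssrs(genome[[i]], thresholds, seq_id = names(genome)[i])
    if (compound) loci <- merge_compound(loci, thresholds$max_compound_interval,
                                         seq = genome[[i]])
    else loci$components <- rep(list(NULL), nrow(loci))
    loci
  })
  out <- do.call(rbind, per)
  if (is.null(out)) {
    out <- empty_loci()
    out$components <- list()
  }
  if (nrow(out)) {
    out <- out[order(out$seq_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out$locus_id <- sprintf("%s:%d-%d", out$seq_id, out$start, out$end)
  } else out$locus_id <- character(0)
  out
}

#' Hypervariable test for SSR loci
#'
#' A locus is hypervariable when its total tract span (`end - start + 1`,
#' which for compounds includes interruptions) is at least `cutoff`
#' nucleotides; 20 nt is the conventional class-I cutoff used for
#' polymorphism-enriched microsatellites.
#'
#' @param loci data.frame of loci (simple or compound).
#' @param cutoff minimum span in nt (default 20).
#' @return logical vector, one element per locus.
#' @examples
#' loci <- find_perfect_ssrs(paste0("GC", strrep("TA", 10), "GG"))
#' is_hypervariable(loci)  # tract 20 -> TRUE
#' @export
is_hypervariable <- function(loci, cutoff = 20L) {
  stopifnot(is.data.frame(loci))
  (loci$end - loci$start + 1L) >= cutoff
}

#' Write a MISA-style SSR table
#'
#' Emits the classic seven-column tab-separated layout consumed by downstream
#' microsatellite tooling: `ID`, `SSR nr.`, `SSR type`, `SSR`, `size`,
#' `start`, `end`. Coordinates are 1-based inclusive; `SSR nr.` restarts per
#' sequence.
#'
#' @param loci data.frame from [mine_ssrs()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_misa_tsv <- function(loci, path) {
  nr <- stats::ave(seq_len(nrow(loci)), loci$seq_id, FUN = seq_along)
  tab <- data.frame(ID = loci$seq_id, `SSR nr.` = nr,
                    `SSR type` = loci$ssr_class, SSR = loci$ssr,
                    size = loci$end - loci$start + 1L,
                    start = loci$start, end = loci$end,
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq character vector of DNA strings over `ACGTN`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
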