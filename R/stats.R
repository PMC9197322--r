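#' Round half-up
#'
#' Commercial rounding used throughout the reported tables (base R's
#' `round()` rounds half to even). Only defined for non-negative values.
#'
#' @param x numeric vector, `x >= 0`.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  trunc(x * p + 0.5 + 1e-9) / p
}

#' SSR density and mean spacing
#'
#' Density is loci per Mb (1 Mb = 10^6 bp); the average distance between two
#' SSRs is defined as span/count, the exact reciprocal of density
#' (`spacing_kb = 1000 / per_mb`), not the mean gap between consecutive loci.
#' Both are reported half-up to 2 decimals, computed from the raw ratio so
#' the reciprocal identity holds within rounding.
#'
#' @param count number of loci (>= 0).
#' @param span_bp sequence span in bp (>= 1).
#' @return a one-row data.frame: `count`, `span_bp`, `per_mb`, `spacing_kb`.
#'   With `count == 0`, density is 0 and `spacing_kb` is `NA` (flagged
#'   undefined, not infinite).
#' @examples
#' ssr_density(1, 1e6)           # 1.00 per Mb, 1000.00 kb apart
#' spacing_from_per_mb(362.88)   # 2.76
#' @export
ssr_density <- function(count, span_bp) {
  stopifnot(length(count) == 1L, length(span_bp) == 1L, span_bp >= 1, count >= 0)
  per_mb <- round_half_up(count / (span_bp / 1e6), 2L)
  spacing <- if (count == 0) NA_real_ else round_half_up((span_bp / 1e3) / count, 2L)
  data.frame(count = as.integer(count), span_bp = as.numeric(span_bp),
             per_mb = per_mb, spacing_kb = spacing)
}

#' @rdname ssr_density
#' @param per_mb a density in loci/Mb.
#' @export
spacing_from_per_mb <- function(per_mb) {
  stopifnot(all(per_mb > 0))
  round_half_up(1000 / per_mb, 2L)
}

ssr_class_levels <- c("p1", "p2", "p3", "p4", "p5", "p6", "c", "c*")
class_label <- c(p1 = "mono", p2 = "di", p3 = "tri", p4 = "tetra",
                 p5 = "penta", p6 = "hexa", c = "compound", `c*` = "compound")

#' Per-class SSR summary
#'
#' Counts loci per repeat class (mono- through hexanucleotide plus compound),
#' the number of distinct motifs/patterns per class, each class's proportion
#' of the total (percent, 2 decimals half-up) and, when `span_bp` is given,
#' its frequency per Mb.
#'
#' @param loci data.frame of loci (`ssr_class`, `motif` columns), or a
#'   pre-tallied data.frame with columns `class` (mono..hexa, compound),
#'   `count` and optionally `n_motifs` for when only published totals are
#'   available.
#' @param span_bp optional genome span for the per-Mb column.
#' @return data.frame with one row per class present plus stable ordering
#'   mono..hexa, compound: `class`, `count`, `n_motifs`, `proportion_pct`,
#'   and `per_mb` when `span_bp` was supplied.
#' @export
summarize_by_class <- function(loci, span_bp = NULL) {
  stopifnot(is.data.frame(loci))
  lv <- c("mono", "di", "tri", "tetra", "penta", "hexa", "compound")
  if (all(c("class", "count") %in% names(loci))) {
    cls <- factor(loci$class, levels = lv)
    stopifnot(!anyNA(cls))
    count <- as.numeric(loci$count)
    n_motifs <- if ("n_motifs" %in% names(loci)) as.numeric(loci$n_motifs)
                else rep(NA_real_, nrow(loci))
    out <- data.frame(class = as.character(cls), count = count,
                      n_motifs = n_motifs, stringsAsFactors = FALSE)
    out <- out[order(match(out$class, lv)), , drop = FALSE]
  } else {
    cls <- factor(unname(class_label[loci$ssr_class]), levels = lv)
    count <- as.numeric(tapply(rep(1, nrow(loci)), cls, sum, default = 0))
    n_motifs <- as.numeric(tapply(loci$motif, cls, function(m) length(unique(m)),
                                  default = 0))
    out <- data.frame(class = lv, count = count, n_motifs = n_motifs,
                      stringsAsFactors = FALSE)
  }
  total <- sum(out$count)
  out$proportion_pct <- if (total > 0) round_half_up(out$count / total * 100, 2L)
                        else rep(0, nrow(out))
  if (!is.null(span_bp))
    out$per_mb <- round_half_up(out$count / (span_bp / 1e6), 2L)
  rownames(out) <- NULL
  out
}

#' Per-sequence SSR distribution
#'
#' Chromosome-wise locus counts with density per Mb and mean spacing in kb.
#'
#' @param loci data.frame of loci with a `seq_id` column.
#' @param seq_lengths named numeric vector of sequence lengths in bp; every
#'   locus `seq_id` must be present. Sequences with zero loci are included.
#' @return data.frame sorted by `seq_id`: `seq_id`, `count`, `span_bp`,
#'   `per_mb`, `spacing_kb`.
#' @export
summarize_by_sequence <- function(loci, seq_lengths) {
  stopifnot(is.data.frame(loci), is.numeric(seq_lengths),
            !is.null(names(seq_lengths)))
  if (nrow(loci) && !all(loci$seq_id %in% names(seq_lengths)))
    stop("seq_lengths is missing some loci seq_ids")
  ids <- sort(names(seq_lengths))
  rows <- lapply(ids, function(id) {
    cnt <- sum(loci$seq_id == id)
    cbind(seq_id = id, ssr_density(cnt, seq_lengths[[id]]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$seq_id <- as.character(out$seq_id)
  out
}

#' Motif frequency table
#'
#' Tallies motifs of one unit length, sorted by descending frequency with
#' lexicographic tie-break, filtered at a minimum frequency.
#'
#' @param loci data.frame of loci.
#' @param unit_length unit length 1..6 to tabulate.
#' @param min_frequency drop motifs rarer than this (default 1 = keep all).
#' @return data.frame `motif`, `frequency`.
#' @export
motif_frequency_table <- function(loci, unit_length, min_frequency = 1L) {
  stopifnot(unit_length %in% 1:6)
  sub <- loci[!is.na(loci$unit_length) & loci$unit_length == unit_length, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(motif = character(), frequency = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sub$motif)
  out <- data.frame(motif = names(tab), frequency = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$frequency >= min_frequency, , drop = FALSE]
  out <- out[order(-out$frequency, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GBS library panel means
#'
#' Arithmetic means over per-genotype sequencing-library statistics. Read,
#' scaffold and SSR means are rounded to the nearest integer (half-up), GC to
#' 2 decimals.
#'
#' @param rows data.frame with columns `genotype`, `pe_reads`, `gc_pct`,
#'   `scaffolds`, `ssrs`.
#' @return one-row data.frame `mean_reads`, `mean_gc_pct`, `mean_scaffolds`,
#'   `mean_ssrs`.
#' @export
library_summary <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L,
            all(c("pe_reads", "gc_pct", "scaffolds", "ssrs") %in% names(rows)))
  data.frame(
    mean_reads = round_half_up(mean(rows$pe_reads), 0L),
    mean_gc_pct = round_half_up(mean(rows$gc_pct), 2L),
    mean_scaffolds = round_half_up(mean(rows$scaffolds), 0L),
    mean_ssrs = round_half_up(mean(rows$ssrs), 0L))
}
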