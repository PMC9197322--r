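#' GC content of a DNA string
#'
#' @param seq character vector of non-empty DNA strings.
#' @return percent G+C, rounded half-up to 2 decimals.
#' @examples
#' gc_percent("ATGC")  # 50
#' @export
gc_percent <- function(seq) {
  stopifnot(all(nchar(seq) > 0))
  gc <- vapply(strsplit(toupper(seq), ""), function(ch)
    sum(ch %in% c("G", "C")), numeric(1))
  round_half_up(100 * gc / nchar(seq), 2L)
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2(A+T) + 4(G+C)` in degrees C. A deliberately simple, deterministic
#' model adequate for 18-27-mers; nearest-neighbour thermodynamics are out of
#' scope.
#'
#' @param seq character vector of DNA strings.
#' @return Tm in degrees C.
#' @export
tm_wallace <- function(seq) {
  vapply(strsplit(toupper(seq), ""), function(ch)
    2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C")), numeric(1))
}

#' Extract flanking signatures around SSR loci
#'
#' Returns, for each locus, the `flank_len` residues immediately 5' and 3' of
#' the tract. A signature is valid for flank matching only when both flanks
#' are full length and free of `N`; loci closer than `flank_len` to a
#' sequence end yield a truncated, invalid signature.
#'
#' @param loci data.frame of loci (needs `locus_id`, `seq_id`, `start`,
#'   `end`, `motif`, `repeat_count`, `ssr_class`, `tract_length`).
#' @param genome named character vector of sequences.
#' @param flank_len flank length in bp: 20 for polymorphism signatures,
#'   200 for in-silico PCR windows.
#' @return data.frame: `locus_id`, `seq_id`, `left_flank`, `right_flank`,
#'   `motif`, `repeat_count`, `ssr_class`, `tract_length`, `valid`.
#' @export
extract_flanks <- function(loci, genome, flank_len = 20L) {
  stopifnot(is.data.frame(loci), is.character(genome))
  miss <- setdiff(unique(loci$seq_id), names(genome))
  if (length(miss))
    stop("unknown seq_id in loci: ", paste(miss, collapse = ", "))
  if (!"locus_id" %in% names(loci))
    loci$locus_id <- sprintf("%s:%d-%d", loci$seq_id, loci$start, loci$end)
  n <- nrow(loci)
  left <- character(n); right <- character(n); valid <- logical(n)
  for (i in seq_len(n)) {
    s <- genome[[loci$seq_id[i]]]
    ls <- loci$start[i] - flank_len; le <- loci$start[i] - 1L
    rs <- loci$end[i] + 1L; re <- loci$end[i] + flank_len
    left[i] <- substr(s, max(1L, ls), le)
    right[i] <- substr(s, rs, min(nchar(s), re))
    valid[i] <- ls >= 1L && re <= nchar(s) &&
      !grepl("N", left[i], fixed = TRUE) && !grepl("N", right[i], fixed = TRUE)
  }
  data.frame(locus_id = loci$locus_id, seq_id = loci$seq_id,
             left_flank = left, right_flank = right, motif = loci$motif,
             repeat_count = loci$repeat_count, ssr_class = loci$ssr_class,
             tract_length = loci$end - loci$start + 1L, valid = valid,
             stringsAsFactors = FALSE)
}

#' Primer design constraints
#'
#' Defaults: 18-27 bp primer length, 57-63 degC melting temperature, 30-70%
#' GC content and 100-300 bp product size.
#'
#' @param primer_len integer range `c(min, max)` of primer lengths.
#' @param tm numeric range of acceptable Tm (degC, Wallace rule).
#' @param gc numeric range of acceptable GC percent.
#' @param product numeric range of product sizes (bp, outer 5' end to outer
#'   5' end, inclusive).
#' @param search_window how far from the tract primer 5' ends may lie (bp).
#' @return a list of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len = c(18L, 27L), tm = c(57, 63),
                               gc = c(30, 70), product = c(100L, 300L),
                               search_window = 250L) {
  stopifnot(primer_len[1] <= primer_len[2], tm[1] <= tm[2],
            gc[1] <= gc[2], product[1] <= product[2])
  structure(list(primer_len = as.integer(primer_len), tm = tm, gc = gc,
                 product = as.integer(product),
                 search_window = as.integer(search_window)),
            class = "primer_constraints")
}

# Enumerate single-primer candidates on one side of a tract.
# side = "left": sense-strand k-mers wholly 5' of the tract.
# side = "right": k-mers wholly 3'; primer sequence is their reverse complement.
primer_candidates <- function(seq, tract_start, tract_end, constraints, side) {
  n <- nchar(seq)
  lens <- seq(constraints$primer_len[1], constraints$primer_len[2])
  rows <- list()
  for (len in lens) {
    if (side == "left") {
      lo <- max(1L, tract_start - constraints$search_window)
      hi <- tract_start - len
    } else {
      lo <- tract_end + 1L
      hi <- min(n, tract_end + constraints$search_window) - len + 1L
    }
    if (hi < lo) next
    starts <- lo:hi
    kmer <- substring(seq, starts, starts + len - 1L)
    keep <- !grepl("N", kmer, fixed = TRUE)
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <-
      data.frame(gstart = starts[keep], gend = starts[keep] + len - 1L,
                 kmer = kmer[keep], stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gstart = integer(), gend = integer(), primer = character(),
                      tm = numeric(), gc = numeric(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, rows)
  cand$primer <- if (side == "left") cand$kmer else revcomp(cand$kmer)
  cand$tm <- tm_wallace(cand$primer)
  cand$gc <- gc_percent(cand$primer)
  cand <- cand[cand$tm >= constraints$tm[1] & cand$tm <= constraints$tm[2] &
               cand$gc >= constraints$gc[1] & cand$gc <= constraints$gc[2], ,
               drop = FALSE]
  cand$kmer <- NULL
  cand
}

#' Design primer-pair candidates for an SSR locus
#'
#' Enumerates forward primers on the sense strand 5' of the tract and reverse
#' primers (reported 5'->3' in their own reading direction) 3' of it, keeps
#' singles satisfying the length/Tm/GC constraints, pairs them under the
#' product-size constraint (product spans the tract by construction, measured
#' between outer 5' ends inclusive), and ranks pairs by `|Tm_f - Tm_r|`, then
#' product size closest to 200 bp, then leftmost forward start.
#'
#' @param locus one-row data.frame of a locus.
#' @param genome named character vector of sequences.
#' @param constraints a [primer_constraints()] object.
#' @param n_best maximum number of pairs returned (default 5).
#' @param max_candidates cap on per-side candidates entering the pairing
#'   (best Tm first); keeps the search bounded.
#' @return data.frame of pairs (possibly empty, not an error): `locus_id`,
#'   `forward`, `reverse`, `tm_f`, `tm_r`, `gc_f`, `gc_r`, `product_size`,
#'   `start`, `end` (product span, 1-based inclusive).
#' @export
design_primers <- function(locus, genome, constraints = primer_constraints(),
                           n_best = 5L, max_candidates = 60L) {
  stopifnot(is.data.frame(locus), nrow(locus) == 1L)
  seq <- genome[[locus$seq_id]]
  if (is.null(seq)) stop("unknown seq_id: ", locus$seq_id)
  empty <- data.frame(locus_id = character(), forward = character(),
                      reverse = character(), tm_f = numeric(), tm_r = numeric(),
                      gc_f = numeric(), gc_r = numeric(),
                      product_size = integer(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  fwd <- primer_candidates(seq, locus$start, locus$end, constraints, "left")
  rev <- primer_candidates(seq, locus$start, locus$end, constraints, "right")
  if (!nrow(fwd) || !nrow(rev)) return(empty)
  fwd <- fwd[order(abs(fwd$tm - mean(constraints$tm)), fwd$gstart), , drop = FALSE]
  rev <- rev[order(abs(rev$tm - mean(constraints$tm)), rev$gstart), , drop = FALSE]
  fwd <- head(fwd, max_candidates)
  rev <- head(rev, max_candidates)
  pairs <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  product <- rev$gend[pairs$r] - fwd$gstart[pairs$f] + 1L
  ok <- product >= constraints$product[1] & product <= constraints$product[2]
  if (!any(ok)) return(empty)
  pairs <- pairs[ok, , drop = FALSE]; product <- product[ok]
  dtm <- abs(fwd$tm[pairs$f] - rev$tm[pairs$r])
  ord <- order(dtm, abs(product - 200L), fwd$gstart[pairs$f], rev$gend[pairs$r])
  pairs <- pairs[ord, , drop = FALSE]; product <- product[ord]
  take <- head(seq_len(nrow(pairs)), n_best)
  lid <- if ("locus_id" %in% names(locus)) locus$locus_id
         else sprintf("%s:%d-%d", locus$seq_id, locus$start, locus$end)
  data.frame(locus_id = lid,
             forward = fwd$primer[pairs$f[take]],
             reverse = rev$primer[pairs$r[take]],
             tm_f = fwd$tm[pairs$f[take]], tm_r = rev$tm[pairs$r[take]],
             gc_f = fwd$gc[pairs$f[take]], gc_r = rev$gc[pairs$r[take]],
             product_size = product[take],
             start = fwd$gstart[pairs$f[take]],
             end = rev$gend[pairs$r[take]],
             stringsAsFactors = FALSE)
}

#' Write a primer table
#'
#' @param pairs data.frame from [design_primers()] (rows may come from many
#'   loci).
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_primer_tsv <- function(pairs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(pairs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
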