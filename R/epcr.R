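#' In-silico PCR scan of one primer pair around one SSR locus
#'
#' Searches the window `[locus start - window, locus end + window]` (clipped
#' to the sequence) for exact, full-length, ungapped placements of the pair
#' in convergent orientation: the forward primer verbatim on the sense strand
#' with the reverse primer's reverse complement downstream of it. Because
#' published primer orientation relative to the assembly is arbitrary, the
#' roles are also tried swapped (reverse primer verbatim upstream, reverse
#' complement of the forward downstream). The product, measured between the
#' outer 5' ends inclusive, must overlap the SSR tract. All valid placements
#' are returned; no match is an empty result, not an error.
#'
#' @param forward,reverse primer sequences, 5'->3' in their own reading
#'   direction.
#' @param locus one-row data.frame of the catalogued locus (`seq_id`,
#'   `start`, `end`, optionally `locus_id`).
#' @param genome named character vector of sequences.
#' @param window bp searched on each side of the tract (default 200).
#' @param max_mismatch mismatch budget per primer (default 0, exact match).
#' @return data.frame: `locus_id`, `seq_id`, `fwd_start`, `rev_start` (5'
#'   end of the downstream primer site, i.e. its larger coordinate),
#'   `product_size`, `orientation` (`+` forward upstream, `-` roles
#'   swapped).
#' @export
epcr_scan <- function(forward, reverse, locus, genome, window = 200L,
                      max_mismatch = 0L) {
  stopifnot(nrow(locus) == 1L)
  s <- genome[[locus$seq_id]]
  if (is.null(s)) stop("unknown seq_id: ", locus$seq_id)
  ws <- max(1L, locus$start - window)
  we <- min(nchar(s), locus$end + window)
  win <- Biostrings::DNAString(substr(s, ws, we))
  lid <- if ("locus_id" %in% names(locus)) locus$locus_id
         else sprintf("%s:%d-%d", locus$seq_id, locus$start, locus$end)
  empty <- data.frame(locus_id = character(), seq_id = character(),
                      fwd_start = integer(), rev_start = integer(),
                      product_size = integer(), orientation = character(),
                      stringsAsFactors = FALSE)
  find <- function(p) {
    if (nchar(p) == 0L || nchar(p) > length(win)) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(p), win, max.mismatch = max_mismatch)) + ws - 1L
  }
  scan_orient <- function(up, down, orient) {
    up_hits <- find(up)
    down_hits <- find(revcomp(down))
    if (!length(up_hits) || !length(down_hits)) return(empty)
    grid <- expand.grid(u = up_hits, d = down_hits)
    d_end <- grid$d + nchar(down) - 1L  # 5' end of the downstream primer site
    ok <- grid$d > grid$u + nchar(up) - 1L &            # convergent, no overlap
      grid$u <= locus$end & d_end >= locus$start        # product overlaps tract
    if (!any(ok)) return(empty)
    data.frame(locus_id = lid, seq_id = locus$seq_id,
               fwd_start = if (orient == "+") grid$u[ok] else grid$d[ok],
               rev_start = if (orient == "+") d_end[ok] else grid$u[ok],
               product_size = d_end[ok] - grid$u[ok] + 1L,
               orientation = orient, stringsAsFactors = FALSE)
  }
  out <- rbind(scan_orient(forward, reverse, "+"),
               scan_orient(reverse, forward, "-"))
  # a palindromic pair can be found in both orientations at one site
  out <- out[!duplicated(out[c("fwd_start", "rev_start")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a primer panel against an SSR catalog
#'
#' Runs [epcr_scan()] for every pair against every catalogued locus and
#' reports, per pair, the loci it amplifies. Pairs hitting several loci are
#' reported `multi_mapped`, not dropped; pairs hitting none are `unplaced`.
#'
#' @param panel data.frame with columns `id`, `forward`, `reverse`.
#' @param catalog data.frame of SSR loci ([mine_ssrs()] output).
#' @param genome named character vector of sequences.
#' @param window,max_mismatch passed to [epcr_scan()].
#' @return data.frame, one row per pair: `primer_pair_id`, `status`
#'   (`located`/`multi_mapped`/`unplaced`), `n_loci`, `loci`
#'   (comma-separated), `product_sizes`.
#' @export
validate_panel <- function(panel, catalog, genome, window = 200L,
                           max_mismatch = 0L) {
  stopifnot(is.data.frame(panel),
            all(c("id", "forward", "reverse") %in% names(panel)))
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    hits <- lapply(seq_len(nrow(catalog)), function(j) {
      m <- epcr_scan(panel$forward[i], panel$reverse[i],
                     catalog[j, , drop = FALSE], genome, window, max_mismatch)
      if (nrow(m)) data.frame(locus = m$locus_id[1L],
                              product = m$product_size[1L],
                              stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    nh <- if (is.null(hits)) 0L else nrow(hits)
    data.frame(primer_pair_id = panel$id[i],
               status = if (nh == 0L) "unplaced"
                        else if (nh == 1L) "located" else "multi_mapped",
               n_loci = nh,
               loci = if (nh) paste(hits$locus, collapse = ",") else "",
               product_sizes = if (nh) paste(hits$product, collapse = ",") else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(primer_pair_id = character(), status = character(),
                      n_loci = integer(), loci = character(),
                      product_sizes = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a primer panel TSV
#'
#' Expects a header with columns `id`, `forward`, `reverse`; lines starting
#' with `#` are ignored.
#'
#' @param path TSV file path.
#' @return data.frame `id`, `forward`, `reverse` (upper-cased).
#' @export
read_primer_panel <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "forward", "reverse") %in% names(tab)))
    stop("primer panel needs columns: id, forward, reverse")
  tab$forward <- toupper(tab$forward)
  tab$reverse <- toupper(tab$reverse)
  tab
}
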