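#' Read a FASTA file
#'
#' Multi-record, wrapped or unwrapped, CRLF and gzip tolerated (Biostrings
#' backend). Residues are case-folded to uppercase; record ids are the first
#' whitespace-delimited token of each header.
#'
#' @param path FASTA file (plain or gzip).
#' @return named character vector of uppercase sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(out))) stop("duplicate record ids in ", path)
  out
}

#' Write a FASTA file
#'
#' 60-column wrapped output; round-trips byte-stably through [read_fasta()].
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)) || !length(records))
  set <- Biostrings::DNAStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Thin wrapper over [read_gene_models()] for file input.
#'
#' @param path GFF3 file.
#' @return gene-model data.frame.
#' @export
read_gff3 <- function(path) read_gene_models(path)

#' Write gene models as GFF3
#'
#' Emits `gene`/`mRNA`/`exon` features with `ID`/`Parent` attributes,
#' 1-based inclusive coordinates.
#'
#' @param genes gene-model data.frame ([read_gene_models()] layout).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tssrscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$seq_id, g$start, g$end, g$strand, g$gene_id), con)
    writeLines(sprintf("%s\tssrscape\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$seq_id, g$start, g$end, g$strand, mid, g$gene_id), con)
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tssrscape\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$seq_id, ex[j, 1], ex[j, 2], g$strand, mid, j, mid), con)
  }
  invisible(path)
}

#' Run configuration
#'
#' Consolidates every tunable with its conventional default: MISA-style
#' mining thresholds (mono 10, di 6, tri..hexa 5; compound interval 100),
#' the 20-nt signature and 200-bp e-PCR flanks, primer constraints
#' (18-27 bp, 57-63 degC, 30-70% GC, 100-300 bp product), the promoter
#' (-1 kb..+100 bp) and TTS (-100 bp..+1 kb) windows and the 20-nt
#' hypervariable cutoff. All values can be overridden.
#'
#' @param ... overrides of any default field.
#' @return a list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L),
    max_compound_interval = 100L,
    signature_flank = 20L,
    epcr_flank = 200L,
    primer_len = c(18L, 27L),
    primer_tm = c(57, 63),
    primer_gc = c(30, 70),
    product_size = c(100L, 300L),
    promoter_up = 1000L, promoter_down = 100L,
    tts_up = 100L, tts_down = 1000L,
    hypervariable_cutoff = 20L,
    seed = 1L,
    log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file to read or write.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config` object.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Thresholds from a run configuration
#' @param config a [run_config()] object.
#' @return an [ssr_thresholds()] object.
#' @export
config_thresholds <- function(config) {
  ssr_thresholds(config$min_repeats, config$max_compound_interval)
}

ssr_log <- function(level, stage, msg, min_level = "info") {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (ranks[[level]] >= ranks[[min_level]])
    message(sprintf("[%s] %s: %s", toupper(level), stage, msg))
  invisible(NULL)
}
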