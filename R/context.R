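#' Build gene models from a GFF3 annotation
#'
#' Resolves the `gene -> mRNA -> exon` hierarchy through `ID`/`Parent`
#' attributes. Exons may also parent directly to a gene. A gene without any
#' mRNA/exon children uses its own span as a single exon. Transcription
#' start (TSS) and end (TES) are strand-aware: on `-` the TSS is the larger
#' coordinate.
#'
#' @param gff a GFF3 file path (parsed with rtracklayer) or a data.frame with
#'   columns `seq_id`, `type`, `start`, `end`, `strand`, `id`, `parent`.
#' @return data.frame of gene models: `gene_id`, `seq_id`, `strand`, `start`,
#'   `end`, `tss`, `tes`, and an `exons` list column of two-column
#'   (start, end) matrices sorted by position.
#' @export
read_gene_models <- function(gff) {
  if (is.character(gff)) {
    gr <- rtracklayer::import(gff)
    df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(gr)),
                     type = as.character(gr$type),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
                     parent = vapply(
                       if (!is.null(gr$Parent)) as.list(gr$Parent) else
                         rep(list(character(0)), length(gr)),
                       function(p) if (length(p)) p[[1]] else NA_character_,
                       character(1)),
                     stringsAsFactors = FALSE)
  } else df <- gff
  genes <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes))
    return(data.frame(gene_id = character(), seq_id = character(),
                      strand = character(), start = integer(), end = integer(),
                      tss = integer(), tes = integer(),
                      exons = I(list()), stringsAsFactors = FALSE))
  if (anyNA(genes$id)) stop("gene feature without ID attribute")
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  exon <- df[df$type == "exon", , drop = FALSE]
  mrna2gene <- setNames(mrna$parent, mrna$id)
  if (nrow(mrna) && anyNA(mrna$parent)) stop("mRNA feature without Parent")
  exon_gene <- ifelse(exon$parent %in% genes$id, exon$parent,
                      unname(mrna2gene[exon$parent]))
  if (nrow(exon) && anyNA(exon_gene))
    stop("exon with unknown Parent: ",
         paste(exon$parent[is.na(exon_gene)], collapse = ", "))
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ex <- exon[which(exon_gene == g$id), c("start", "end"), drop = FALSE]
    if (!nrow(ex)) ex <- data.frame(start = g$start, end = g$end)
    ex <- ex[!duplicated(ex), , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < g$start | ex$end > g$end))
      stop("exon outside gene span for gene ", g$id)
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons for gene ", g$id)
    tss <- if (g$strand == "-") g$end else g$start
    tes <- if (g$strand == "-") g$start else g$end
    data.frame(gene_id = g$id, seq_id = g$seq_id, strand = g$strand,
               start = g$start, end = g$end, tss = tss, tes = tes,
               exons = I(list(as.matrix(ex))), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, models)
  rownames(out) <- NULL
  out
}

# strand-aware windows: "upstream" means larger coordinates on the - strand
promoter_window <- function(tss, strand, up = 1000L, down = 100L) {
  if (strand == "-") c(tss - down, tss + up) else c(tss - up, tss + down)
}
tts_window <- function(tes, strand, up = 100L, down = 1000L) {
  if (strand == "-") c(tes - down, tes + up) else c(tes - up, tes + down)
}

#' Assign SSR loci to genomic regions
#'
#' Assigns each locus, by its midpoint, to exactly one of four categories
#' with fixed priority: `promoter` (TSS -1 kb .. +100 bp, strand-aware), then
#' `tts` (TES -100 bp .. +1 kb), then `exon`, then `intron_intergenic`.
#' When several genes qualify, the gene whose TSS is nearest to the midpoint
#' wins.
#'
#' @param loci data.frame of loci (`locus_id`, `seq_id`, `start`, `end`).
#' @param genes gene models from [read_gene_models()].
#' @param promoter_up,promoter_down,tts_up,tts_down window sizes in bp.
#' @return data.frame: `locus_id`, `category`, `gene_id` (`NA` for
#'   intron/intergenic loci).
#' @export
assign_regions <- function(loci, genes, promoter_up = 1000L,
                           promoter_down = 100L, tts_up = 100L,
                           tts_down = 1000L) {
  stopifnot(is.data.frame(loci), is.data.frame(genes))
  if (!"locus_id" %in% names(loci))
    loci$locus_id <- sprintf("%s:%d-%d", loci$seq_id, loci$start, loci$end)
  mids <- (loci$start + loci$end) %/% 2L
  n <- nrow(loci)
  category <- rep("intron_intergenic", n)
  gene_id <- rep(NA_character_, n)
  genes_by_seq <- split(seq_len(nrow(genes)), genes$seq_id)
  for (i in seq_len(n)) {
    gi <- genes_by_seq[[loci$seq_id[i]]]
    if (is.null(gi)) next
    sub <- genes[gi, , drop = FALSE]
    mid <- mids[i]
    dtss <- abs(mid - sub$tss)
    in_prom <- vapply(seq_len(nrow(sub)), function(j) {
      w <- promoter_window(sub$tss[j], sub$strand[j], promoter_up, promoter_down)
      mid >= w[1] && mid <= w[2]
    }, logical(1))
    if (any(in_prom)) {
      pick <- which(in_prom)[order(dtss[in_prom], sub$gene_id[in_prom])][1L]
      category[i] <- "promoter"; gene_id[i] <- sub$gene_id[pick]
      next
    }
    in_tts <- vapply(seq_len(nrow(sub)), function(j) {
      w <- tts_window(sub$tes[j], sub$strand[j], tts_up, tts_down)
      mid >= w[1] && mid <= w[2]
    }, logical(1))
    if (any(in_tts)) {
      pick <- which(in_tts)[order(dtss[in_tts], sub$gene_id[in_tts])][1L]
      category[i] <- "tts"; gene_id[i] <- sub$gene_id[pick]
      next
    }
    in_exon <- vapply(seq_len(nrow(sub)), function(j) {
      ex <- sub$exons[[j]]
      any(mid >= ex[, 1] & mid <= ex[, 2])
    }, logical(1))
    if (any(in_exon)) {
      pick <- which(in_exon)[order(dtss[in_exon], sub$gene_id[in_exon])][1L]
      category[i] <- "exon"; gene_id[i] <- sub$gene_id[pick]
    }
  }
  data.frame(locus_id = loci$locus_id, category = category, gene_id = gene_id,
             stringsAsFactors = FALSE)
}

#' Region category counts
#'
#' @param assignments data.frame from [assign_regions()].
#' @return data.frame `category`, `count` over the four fixed categories
#'   (zeros included); counts always sum to `nrow(assignments)`.
#' @export
region_counts <- function(assignments) {
  lv <- c("promoter", "tts", "exon", "intron_intergenic")
  cnt <- table(factor(assignments$category, levels = lv))
  data.frame(category = lv, count = as.integer(cnt), stringsAsFactors = FALSE)
}

#' Genes associated with loci
#'
#' The association is the gene chosen by [assign_regions()]; loci assigned
#' to `intron_intergenic` carry no gene.
#'
#' @param assignments data.frame from [assign_regions()].
#' @return list: `table` (locus_id, gene_id for associated loci) and `genes`
#'   (sorted distinct gene ids).
#' @export
associate_genes <- function(assignments) {
  sub <- assignments[!is.na(assignments$gene_id), c("locus_id", "gene_id")]
  rownames(sub) <- NULL
  list(table = sub, genes = sort(unique(sub$gene_id)))
}
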