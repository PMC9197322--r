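#' Simulation configuration
#'
#' Describes a synthetic reference genome with planted SSR loci and gene
#' models, and a panel of genotypes whose contigs carry planted repeat-number
#' variants — the data shape a GBS/ddRAD polymorphism comparison assumes.
#' Loci are spaced at least 2.5 kb apart so that 200-bp e-PCR windows and the
#' 1-kb promoter/TTS windows of neighbouring loci can never collide.
#'
#' @param seed integer seed; every byte of output is a deterministic function
#'   of it.
#' @param n_chrom number of chromosomes.
#' @param loci_per_chrom planted loci per chromosome.
#' @param spacing integer range of inter-locus spacer lengths (bp).
#' @param unit_weights sampling weights for unit lengths 1..6.
#' @param compound_frac fraction of planted loci that are compound (two
#'   tracts separated by <= 40 bp, abutting with probability 1/4).
#' @param region_mix sampling weights over planted genomic context:
#'   promoter, tts, exon, intron, intergenic.
#' @param n_genotypes panel size.
#' @param variant_rate per-genotype fraction of covered loci given a
#'   repeat-count change.
#' @param delta_choices repeat-count deltas for variants (never 0); negative
#'   draws are clipped up so mutated counts still meet the mining threshold,
#'   unless `allow_subthreshold`.
#' @param allow_subthreshold when TRUE, negative deltas may push a tract
#'   below its threshold; the truth label becomes `absent`.
#' @param flank_mutation_rate per-contig probability of one substitution
#'   inside the 20-nt signature (truth label `absent`).
#' @param coverage fraction of loci represented by a contig per genotype.
#' @param contig_flank bp of reference context kept on each side of a
#'   contig's tract (>= 20).
#' @param strand_flip_prob probability a contig is emitted reverse
#'   complemented.
#' @param thresholds mining thresholds the planted loci must meet.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 7L, n_chrom = 5L, loci_per_chrom = 40L,
                       spacing = c(2500L, 3000L),
                       unit_weights = c(0.15, 0.3, 0.25, 0.15, 0.05, 0.1),
                       compound_frac = 0.1,
                       region_mix = c(promoter = 0.2, tts = 0.1, exon = 0.1,
                                      intron = 0.1, intergenic = 0.5),
                       n_genotypes = 5L, variant_rate = 0.3,
                       delta_choices = c(-3L, -2L, -1L, 1L, 2L, 3L),
                       allow_subthreshold = FALSE,
                       flank_mutation_rate = 0, coverage = 1,
                       contig_flank = 60L, strand_flip_prob = 0.5,
                       thresholds = ssr_thresholds()) {
  stopifnot(variant_rate >= 0, variant_rate <= 1, coverage >= 0, coverage <= 1,
            flank_mutation_rate >= 0, flank_mutation_rate <= 1,
            strand_flip_prob >= 0, strand_flip_prob <= 1,
            contig_flank >= 20L, all(delta_choices != 0L),
            spacing[1] >= 500L, spacing[1] <= spacing[2])
  structure(as.list(environment()), class = "sim_config")
}

rand_bases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_primitive_motif <- function(u) {
  repeat {
    m <- rand_bases(u)
    if (is_primitive_motif(m)) return(m)
  }
}

# Replace characters of `s` at positions `pos` with fresh random bases.
patch_positions <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
  paste(ch, collapse = "")
}

is_rotation <- function(a, b) {
  nchar(a) == nchar(b) && grepl(b, paste0(a, a), fixed = TRUE)
}

# One planted locus spec: simple or two-component compound. Abutting (gap-0)
# compound parts are constrained so the two tracts cannot bridge into one
# periodic stretch at the character level: first and last motif characters
# must differ across the junction and same-unit parts must not be cyclic
# rotations of each other.
sample_locus_spec <- function(config) {
  thr <- config$thresholds$min_repeats
  one <- function() {
    u <- sample(1:6, 1L, prob = config$unit_weights)
    count <- thr[u] + sample(0:6, 1L)
    list(unit = u, count = count, motif = rand_primitive_motif(u))
  }
  if (runif(1) < config$compound_frac) {
    gap <- if (runif(1) < 0.25) 0L else sample(1:40, 1L)
    p1 <- one()
    repeat {
      p2 <- one()
      if (gap > 0L) break
      m1 <- p1$motif; m2 <- p2$motif
      if (substr(m2, 1L, 1L) != substr(m1, 1L, 1L) &&
          substr(m2, nchar(m2), nchar(m2)) != substr(m1, nchar(m1), nchar(m1)) &&
          !(p1$unit == p2$unit && is_rotation(m1, m2))) break
    }
    list(type = "compound", parts = list(p1, p2), gap = gap)
  } else c(list(type = "simple"), one())
}

spec_tract <- function(spec, gap_seq = NULL) {
  if (spec$type == "simple") return(strrep(spec$motif, spec$count))
  p <- spec$parts
  paste0(strrep(p[[1]]$motif, p[[1]]$count),
         if (is.null(gap_seq)) strrep("G", spec$gap) else gap_seq,
         strrep(p[[2]]$motif, p[[2]]$count))
}

# boundary bases that would extend a tract by one residue at either end
left_break_base <- function(motif) substr(motif, nchar(motif), nchar(motif))
right_break_base <- function(motif) substr(motif, 1L, 1L)

resample_base <- function(not) sample(setdiff(c("A", "C", "G", "T"), not), 1L)

# Compose one chromosome; returns sequence + truth rows. Truth coordinates
# are exact; junction bases are chosen to break tract extension, and the
# final sequence is verified by the miner itself (spurious background loci
# are rejection-patched).
build_chromosome <- function(chrom_id, config) {
  n_loci <- config$loci_per_chrom
  specs <- replicate(n_loci, sample_locus_spec(config), simplify = FALSE)
  gapseqs <- lapply(specs, function(sp) {
    if (sp$type != "compound" || sp$gap == 0L) return(NULL)
    g <- rand_bases(sp$gap)
    # interruption must not extend either component
    g <- patch_first_last(g, sp$parts[[1]]$motif, sp$parts[[2]]$motif)
    g
  })
  pieces <- character(0)
  pos <- 0L
  truth <- list()
  for (i in seq_len(n_loci)) {
    sp <- specs[[i]]
    spacer_len <- sample(config$spacing[1]:config$spacing[2], 1L)
    spacer <- rand_bases(spacer_len)
    lmotif <- if (sp$type == "simple") sp$motif else sp$parts[[1]]$motif
    rmotif <- if (sp$type == "simple") sp$motif else sp$parts[[2]]$motif
    substr(spacer, spacer_len, spacer_len) <- resample_base(left_break_base(lmotif))
    tract <- spec_tract(sp, gapseqs[[i]])
    start <- pos + spacer_len + 1L
    end <- start + nchar(tract) - 1L
    pieces <- c(pieces, spacer, tract)
    pos <- end
    truth[[i]] <- data.frame(
      seq_id = chrom_id, start = start, end = end,
      type = sp$type,
      motif = if (sp$type == "simple") sp$motif else NA_character_,
      unit_length = if (sp$type == "simple") sp$unit else NA_integer_,
      repeat_count = if (sp$type == "simple") sp$count else NA_integer_,
      tract_length = nchar(tract), stringsAsFactors = FALSE)
    truth[[i]]$spec <- list(sp)
    truth[[i]]$gap_seq <- list(gapseqs[[i]])
  }
  tail_len <- sample(config$spacing[1]:config$spacing[2], 1L)
  tail_sp <- rand_bases(tail_len)
  pieces <- c(pieces, tail_sp)
  s <- paste(pieces, collapse = "")
  truth <- do.call(rbind, truth)
  # each spacer's first base after a tract must not extend it rightwards
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(truth))) {
    sp <- truth$spec[[i]]
    rmotif <- if (sp$type == "simple") sp$motif else sp$parts[[2]]$motif
    p <- truth$end[i] + 1L
    if (p <= length(ch) && ch[p] == right_break_base(rmotif))
      ch[p] <- resample_base(right_break_base(rmotif))
  }
  s <- paste(ch, collapse = "")
  list(seq = s, truth = truth)
}

patch_first_last <- function(g, left_motif, right_motif) {
  if (nchar(g) == 0L) return(g)
  substr(g, 1L, 1L) <- resample_base(right_break_base(left_motif))
  substr(g, nchar(g), nchar(g)) <- resample_base(left_break_base(right_motif))
  g
}

# Verify a chromosome against its truth with the miner; patch any background
# positions that produced spurious or distorted loci and retry.
verify_chromosome <- function(s, truth, config, max_iter = 50L) {
  in_truth <- function(pos) {
    any(pos >= truth$start & pos <= truth$end)
  }
  for (iter in seq_len(max_iter)) {
    mined <- mine_ssrs(setNames(s, truth$seq_id[1]), config$thresholds)
    ok <- nrow(mined) == nrow(truth) &&
      all(mined$start == truth$start) && all(mined$end == truth$end)
    if (ok) return(s)
    bad <- mined[!(mined$start %in% truth$start & mined$end %in% truth$end), ,
                 drop = FALSE]
    if (!nrow(bad)) {
      # same positions but distorted content should be impossible; rebuild all
      bad <- mined
    }
    pos <- unlist(lapply(seq_len(nrow(bad)), function(i)
      seq.int(bad$start[i], bad$end[i])))
    pos <- unique(pos[!vapply(pos, in_truth, logical(1))])
    if (!length(pos)) stop("simulated chromosome cannot be repaired")
    s <- patch_positions(s, pos)
  }
  stop("background rejection sampling did not converge")
}

# Gene placement around a locus midpoint, guaranteeing the intended region
# category under the 1000/100 promoter and 100/1000 TTS windows.
place_gene <- function(gene_id, seq_id, mid, category, strand) {
  if (category == "promoter") {
    if (strand == "+") { start <- mid + 500L; end <- mid + 1200L }
    else { end <- mid - 500L; start <- mid - 1200L }
    exons <- cbind(start, end)
  } else if (category == "tts") {
    if (strand == "+") { end <- mid - 500L; start <- mid - 1200L }
    else { start <- mid + 500L; end <- mid + 1200L }
    exons <- cbind(start, end)
  } else if (category == "exon") {
    start <- mid - 300L; end <- mid + 300L
    exons <- cbind(start, end)
  } else { # intron
    start <- mid - 800L; end <- mid + 800L
    exons <- rbind(c(start, mid - 400L), c(mid + 400L, end))
  }
  tss <- if (strand == "-") end else start
  tes <- if (strand == "-") start else end
  g <- data.frame(gene_id = gene_id, seq_id = seq_id, strand = strand,
                  start = start, end = end, tss = tss, tes = tes,
                  stringsAsFactors = FALSE)
  g$exons <- I(list(exons))
  g
}

#' Simulate a reference genome with planted SSR loci and gene models
#'
#' Backgrounds are rejection-sampled with the miner itself as the filter, so
#' mining the output recovers exactly the planted loci. Gene models are
#' placed so every region category (promoter, TTS, exon, intron, intergenic)
#' is represented, and planted loci are far enough apart that no window
#' reaches a neighbour.
#'
#' @param config a [sim_config()] object. Byte-identical output under a
#'   fixed seed; independent of the genotype-panel parameters.
#' @return list of class `sim_reference`: `genome` (named character vector),
#'   `genes` (gene-model data.frame as from [read_gene_models()]), `truth`
#'   (per-locus data.frame with coordinates, motif/count, `region`,
#'   `gene_id`, `locus_id`), and `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- character(0)
  truths <- list()
  genes <- list()
  region_lv <- names(config$region_mix)
  for (ci in seq_len(config$n_chrom)) {
    chrom_id <- sprintf("chr%02d", ci)
    built <- build_chromosome(chrom_id, config)
    s <- verify_chromosome(built$seq, built$truth, config)
    truth <- built$truth
    truth$region <- sample(region_lv, nrow(truth), replace = TRUE,
                           prob = config$region_mix)
    truth$gene_id <- NA_character_
    for (i in seq_len(nrow(truth))) {
      if (truth$region[i] == "intergenic") next
      gid <- sprintf("gene_%s_%03d", chrom_id, i)
      strand <- sample(c("+", "-"), 1L)
      mid <- (truth$start[i] + truth$end[i]) %/% 2L
      genes[[length(genes) + 1L]] <-
        place_gene(gid, chrom_id, mid, truth$region[i], strand)
      truth$gene_id[i] <- gid
    }
    genome[chrom_id] <- s
    truths[[ci]] <- truth
  }
  truth <- do.call(rbind, truths)
  truth$locus_id <- sprintf("%s:%d-%d", truth$seq_id, truth$start, truth$end)
  # intron loci fall in the merged intron+intergenic category downstream
  truth$region_category <- ifelse(truth$region %in% c("intron", "intergenic"),
                                  "intron_intergenic", truth$region)
  genes <- if (length(genes)) do.call(rbind, genes) else
    read_gene_models(data.frame(seq_id = character(), type = character(),
                                start = integer(), end = integer(),
                                strand = character(), id = character(),
                                parent = character(), stringsAsFactors = FALSE))
  rownames(truth) <- NULL
  rownames(genes) <- NULL
  structure(list(genome = genome, genes = genes, truth = truth,
                 config = config), class = "sim_reference")
}

#' @export
print.sim_reference <- function(x, ...) {
  cat("sim_reference:", length(x$genome), "chromosomes,",
      nrow(x$truth), "planted loci,", nrow(x$genes), "genes\n")
  invisible(x)
}

mutate_flank_base <- function(contig, positions) {
  p <- positions[sample.int(length(positions), 1L)]
  old <- substr(contig, p, p)
  substr(contig, p, p) <- resample_base(old)
  contig
}

#' Simulate genotype contig panels with planted repeat-number variants
#'
#' Each covered locus becomes one short contig (mimicking a de novo GBS
#' fragment): `contig_flank` bp of intact reference context, the tract with
#' a possibly mutated repeat count, and context again. Variants draw a
#' nonzero count delta, clipped so the mutated tract still meets its mining
#' threshold (unless `allow_subthreshold`, in which case the truth label
#' switches to `absent`). With `flank_mutation_rate > 0` a substitution is
#' planted inside the 20-nt signature, which must make the locus `absent`
#' under exact flank matching. Contigs are reverse complemented with
#' probability `strand_flip_prob`.
#'
#' @param sim a [simulate_reference()] result.
#' @param config optional override of `sim$config` (e.g. a different
#'   `variant_rate`); the genotype stream is seeded with `seed + 1`.
#' @return list of class `sim_panel`: `contigs` (named list of named
#'   character vectors, one per genotype) and `truth_calls` (data.frame:
#'   `genotype_id`, `ref_locus_id`, `expected_status`, `expected_count`,
#'   `expected_tract_length`).
#' @export
simulate_genotypes <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_reference"))
  set.seed(config$seed + 1L)
  thr <- config$thresholds$min_repeats
  truth <- sim$truth
  panels <- list()
  calls <- list()
  for (g in seq_len(config$n_genotypes)) {
    gid <- sprintf("G%02d", g)
    contigs <- character(0)
    for (i in seq_len(nrow(truth))) {
      if (runif(1) >= config$coverage) {
        calls[[length(calls) + 1L]] <- data.frame(
          genotype_id = gid, ref_locus_id = truth$locus_id[i],
          expected_status = "absent", expected_count = NA_integer_,
          expected_tract_length = NA_integer_, stringsAsFactors = FALSE)
        next
      }
      sp <- truth$spec[[i]]
      variant <- runif(1) < config$variant_rate
      status <- if (variant) "polymorphic" else "monomorphic"
      newsp <- sp
      if (variant) {
        if (sp$type == "simple") {
          delta <- sample(config$delta_choices, 1L)
          newc <- sp$count + delta
          if (newc < thr[sp$unit] && !config$allow_subthreshold)
            newc <- sp$count + sample(abs(config$delta_choices), 1L)
          if (newc < thr[sp$unit]) status <- "absent"
          newsp$count <- newc
        } else {
          j <- sample(1:2, 1L)
          part <- sp$parts[[j]]
          delta <- sample(config$delta_choices, 1L)
          newc <- part$count + delta
          if (newc < thr[part$unit]) newc <- part$count + sample(abs(config$delta_choices), 1L)
          newsp$parts[[j]]$count <- newc
        }
      }
      tract <- spec_tract(newsp, truth$gap_seq[[i]])
      s <- sim$genome[[truth$seq_id[i]]]
      left <- substr(s, truth$start[i] - config$contig_flank, truth$start[i] - 1L)
      right <- substr(s, truth$end[i] + 1L, truth$end[i] + config$contig_flank)
      contig <- paste0(left, tract, right)
      if (runif(1) < config$flank_mutation_rate) {
        nl <- nchar(left)
        sigpos <- c((nl - 19L):nl, (nl + nchar(tract) + 1L):(nl + nchar(tract) + 20L))
        contig <- mutate_flank_base(contig, sigpos)
        status <- "absent"
      }
      if (runif(1) < config$strand_flip_prob) contig <- revcomp(contig)
      cname <- sprintf("%s_%s", gid, gsub("[:-]", "_", truth$locus_id[i]))
      contigs[cname] <- contig
      calls[[length(calls) + 1L]] <- data.frame(
        genotype_id = gid, ref_locus_id = truth$locus_id[i],
        expected_status = status,
        expected_count = if (newsp$type == "simple" && status != "absent")
          newsp$count else NA_integer_,
        expected_tract_length = if (status == "absent") NA_integer_
          else nchar(tract),
        stringsAsFactors = FALSE)
    }
    panels[[gid]] <- contigs
  }
  structure(list(contigs = panels, truth_calls = do.call(rbind, calls)),
            class = "sim_panel")
}

#' Write simulated reference and panel to disk
#'
#' Emits `reference.fasta`, `annotation.gff3`, `truth_loci.tsv`,
#' `truth_calls.tsv` and one `genotype_<id>.fasta` per genotype.
#'
#' @param sim a [simulate_reference()] result.
#' @param panel a [simulate_genotypes()] result (optional).
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, panel = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$genome, file.path(dir, "reference.fasta"))
  write_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  truth <- sim$truth[setdiff(names(sim$truth), c("spec", "gap_seq"))]
  con <- file(file.path(dir, "truth_loci.tsv"), "w")
  writeLines("# coordinates are 1-based inclusive", con)
  utils::write.table(truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(panel)) {
    utils::write.table(panel$truth_calls, file.path(dir, "truth_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (gid in names(panel$contigs))
      write_fasta(panel$contigs[[gid]],
                  file.path(dir, sprintf("genotype_%s.fasta", gid)))
  }
  invisible(dir)
}
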