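#' Specification for a toy transcriptome
#'
#' Describes the synthetic genome used by the simulators: a single
#' chromosome carrying non-overlapping, strand-assigned gene models with
#' exon/intron structure, a configurable GC content, and a planted RNA
#' pentamer motif at a given density. Every planted motif position is
#' recorded in the ground truth, so downstream motif analyses can be
#' checked against construction.
#'
#' @param n_genes number of genes (>= 1).
#' @param gene_length_range min/max gene length in nt.
#' @param exon_count_range min/max exons per gene.
#' @param gc_content fraction of G+C in random sequence, in \[0, 1\].
#' @param motif RNA 5-mer to plant (characters A/C/G/U).
#' @param motif_density planted motifs per kilobase of gene.
#' @param noncoding_fraction fraction of genes emitted as non-coding RNAs
#'   (exons but no CDS/UTR features).
#' @param intergenic_length nt of random spacer between genes (also used as
#'   chromosome end padding; must exceed the read length so simulated
#'   inserts never run off the chromosome).
#' @param seed integer seed; identical specs give byte-identical output.
#' @return a list of class `transcriptome_spec`.
#' @export
transcriptome_spec <- function(n_genes = 20,
                               gene_length_range = c(2000, 5000),
                               exon_count_range = c(1, 4),
                               gc_content = 0.5,
                               motif = "GAAGA",
                               motif_density = 2,
                               noncoding_fraction = 0.2,
                               intergenic_length = 300,
                               seed = 1) {
  stopifnot(n_genes >= 1,
            length(gene_length_range) == 2,
            gene_length_range[1] >= 200,
            gene_length_range[1] <= gene_length_range[2],
            exon_count_range[1] >= 1,
            exon_count_range[1] <= exon_count_range[2],
            gc_content >= 0, gc_content <= 1,
            motif_density >= 0,
            noncoding_fraction >= 0, noncoding_fraction <= 1,
            intergenic_length >= 100)
  if (!grepl("^[ACGU]+$", motif)) {
    stop("motif must contain only A, C, G, U characters, got: ", motif)
  }
  structure(as.list(environment()), class = "transcriptome_spec")
}

## Split the exonic part of a gene (transcript order) into labelled
## sub-intervals of given widths; returns genomic 1-based intervals.
split_exonic <- function(exon_starts, exon_ends, strand, widths, labels) {
  ord <- if (strand == "+") seq_along(exon_starts) else rev(seq_along(exon_starts))
  out <- vector("list", 0L)
  li <- 1L
  for (i in ord) {
    ew <- exon_ends[i] - exon_starts[i] + 1L
    off <- 0L
    while (off < ew && li <= length(widths)) {
      take <- min(widths[li], ew - off)
      if (strand == "+") {
        gs <- exon_starts[i] + off
        out[[length(out) + 1L]] <- data.frame(start = gs, end = gs + take - 1L,
                                              type = labels[li])
      } else {
        ge <- exon_ends[i] - off
        out[[length(out) + 1L]] <- data.frame(start = ge - take + 1L, end = ge,
                                              type = labels[li])
      }
      widths[li] <- widths[li] - take
      if (widths[li] == 0L) li <- li + 1L
      off <- off + take
    }
  }
  do.call(rbind, out)
}

#' Build a synthetic transcriptome with planted motifs
#'
#' Generates one chromosome of random sequence carrying the requested gene
#' models. Gene sequence is drawn base-by-base at the requested GC content;
#' the motif is written verbatim (as DNA) into the gene-strand sequence at
#' Poisson-sampled, non-overlapping positions, so reading the recorded
#' genomic interval on the gene strand always spells the motif. Coding genes
#' get 5'UTR/CDS/3'UTR features over their exonic sequence (roughly 10% /
#' 80% / 10% of the mature transcript); non-coding genes get exons only.
#'
#' @param spec a [transcriptome_spec()].
#' @return a list of class `transcriptome` with elements `genome`
#'   (`DNAStringSet`, plus strand), `genes` (`GRanges`, 1-based, with
#'   `gene_id` and `gene_type`), `features` (`GRanges` of exon/CDS/UTR
#'   intervals with `type` and `gene_id`), `motifs` (`GRanges` of planted
#'   motif positions on the gene strand), and `spec`.
#' @export
build_transcriptome <- function(spec) {
  stopifnot(inherits(spec, "transcriptome_spec"))
  set.seed(spec$seed)
  pad <- spec$intergenic_length

  gene_rows <- vector("list", spec$n_genes)
  feat_rows <- vector("list", spec$n_genes)
  motif_rows <- vector("list", spec$n_genes)
  chrom_parts <- character(2L * spec$n_genes + 1L)
  chrom_parts[1] <- random_dna(pad, spec$gc_content)
  cursor <- pad  # genomic length emitted so far

  motif_dna <- rna_to_dna(spec$motif)
  mlen <- nchar(motif_dna)

  for (g in seq_len(spec$n_genes)) {
    L <- sample1(spec$gene_length_range[1]:spec$gene_length_range[2])
    strand <- sample(c("+", "-"), 1L)
    coding <- runif(1) > spec$noncoding_fraction
    gene_id <- sprintf("gene%03d", g)

    ## gene sequence in transcript (gene-strand) orientation
    seq_tx <- random_dna(L, spec$gc_content)
    n_mot <- rpois(1L, spec$motif_density * L / 1000)
    mpos_tx <- integer(0)
    if (n_mot > 0) {
      cand <- sample.int(L - mlen + 1L)
      for (p in cand) {
        if (all(abs(p - mpos_tx) >= mlen)) mpos_tx <- c(mpos_tx, p)
        if (length(mpos_tx) == n_mot) break
      }
      mpos_tx <- sort(mpos_tx)
      for (p in mpos_tx) {
        substr(seq_tx, p, p + mlen - 1L) <- motif_dna
      }
    }

    gs <- cursor + 1L
    ge <- cursor + L
    chrom_parts[2L * g] <- if (strand == "+") seq_tx else revcomp_chr(seq_tx)
    chrom_parts[2L * g + 1L] <- random_dna(pad, spec$gc_content)
    cursor <- ge + pad

    ## transcript position p (1-based) -> genomic start of motif
    mstart_gen <- if (strand == "+") gs + mpos_tx - 1L else ge - mpos_tx - mlen + 2L
    if (length(mstart_gen)) {
      motif_rows[[g]] <- data.frame(start = mstart_gen, end = mstart_gen + mlen - 1L,
                                    strand = strand, gene_id = gene_id)
    }

    ## exon/intron structure along the genomic span
    k_ex <- sample1(spec$exon_count_range[1]:spec$exon_count_range[2])
    n_seg <- 2L * k_ex - 1L
    prop <- runif(n_seg, 0.5, 1.5)
    lens <- pmax(30L, floor(L * prop / sum(prop)))
    lens[n_seg] <- L - sum(lens[-n_seg])
    stopifnot(lens[n_seg] >= 1L)
    seg_end <- gs - 1L + cumsum(lens)
    seg_start <- c(gs, head(seg_end, -1L) + 1L)
    is_exon <- seq_len(n_seg) %% 2L == 1L
    ex_s <- seg_start[is_exon]; ex_e <- seg_end[is_exon]

    exonic <- sum(ex_e - ex_s + 1L)
    if (coding && exonic >= 60L) {
      u5 <- max(1L, round(0.1 * exonic))
      u3 <- max(1L, round(0.1 * exonic))
      cds <- exonic - u5 - u3
      parts <- split_exonic(ex_s, ex_e, strand,
                            widths = c(u5, cds, u3),
                            labels = c("five_prime_UTR", "CDS", "three_prime_UTR"))
      gene_type <- "protein_coding"
    } else {
      parts <- NULL
      gene_type <- "ncRNA"
    }
    feat <- rbind(data.frame(start = ex_s, end = ex_e, type = "exon"), parts)
    feat$strand <- strand
    feat$gene_id <- gene_id
    feat_rows[[g]] <- feat
    gene_rows[[g]] <- data.frame(start = gs, end = ge, strand = strand,
                                 gene_id = gene_id, gene_type = gene_type)
  }

  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chr1"

  genes_df <- do.call(rbind, gene_rows)
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(genes_df$start, genes_df$end),
                                  strand = genes_df$strand,
                                  gene_id = genes_df$gene_id,
                                  gene_type = genes_df$gene_type)
  feats_df <- do.call(rbind, feat_rows)
  features <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(feats_df$start, feats_df$end),
                                     strand = feats_df$strand,
                                     type = feats_df$type,
                                     gene_id = feats_df$gene_id)
  motifs_df <- do.call(rbind, motif_rows)
  motifs <- if (is.null(motifs_df)) {
    GenomicRanges::GRanges(gene_id = character(0))
  } else {
    GenomicRanges::GRanges("chr1",
                           IRanges::IRanges(motifs_df$start, motifs_df$end),
                           strand = motifs_df$strand,
                           gene_id = motifs_df$gene_id)
  }
  structure(list(genome = genome, genes = genes, features = features,
                 motifs = motifs, spec = spec),
            class = "transcriptome")
}

#' Write a synthetic transcriptome to disk
#'
#' Writes the chromosome as FASTA and the gene models as GFF3 (1-based
#' inclusive, gene rows with `ID`, feature rows with `Parent`).
#'
#' @param tx a `transcriptome`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_transcriptome <- function(tx, dir) {
  stopifnot(inherits(tx, "transcriptome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(tx$genome, fa)

  g <- tx$genes
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    type = "gene", ID = tx$genes$gene_id, gene_type = tx$genes$gene_type)
  f <- tx$features
  S4Vectors::mcols(f) <- S4Vectors::DataFrame(
    type = tx$features$type, Parent = tx$features$gene_id,
    phase = ifelse(tx$features$type == "CDS", 0L, NA_integer_))
  S4Vectors::mcols(g)$phase <- NA_integer_
  rtracklayer::export(c(g, f), gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}

#' Read gene models from a GFF3 file
#'
#' Inverse of [write_transcriptome()]'s annotation output; also accepts any
#' GFF3 whose gene rows carry `ID` (and optionally `gene_type`) and whose
#' exon/CDS/UTR rows carry `Parent`.
#'
#' @param path GFF3 file.
#' @return list with `genes` and `features` `GRanges` in the layout used by
#'   the rest of the package.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  is_gene <- gr$type == "gene"
  genes <- gr[is_gene]
  mc <- S4Vectors::mcols(genes)
  gene_type <- if ("gene_type" %in% names(mc)) mc$gene_type else "protein_coding"
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = mc$ID,
                                                  gene_type = gene_type)
  feats <- gr[!is_gene]
  parent <- as.character(unlist(feats$Parent))
  if (length(parent) != length(feats)) stop("malformed annotation: feature without a single Parent")
  S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
    type = as.character(feats$type), gene_id = parent)
  list(genes = genes, features = feats)
}

#' Configuration for simulating a CLIP library
#'
#' Parameters of the read simulator. Crosslink events fall on transcribed
#' positions with a per-position rate of 1, elevated multiplicatively to
#' `motif_boost` at the `proximity_window + 1` positions 0 to
#' `proximity_window` nt 5' of each planted motif start (transcript
#' orientation), so the motif lands inside the -5/+30 analysis window of a
#' site placed there. With `motif_boost = 1` placement is uniform. Control
#' libraries (non-crosslinked, tag-only) share the transcriptome, draw
#' `n_events * control_rate_fraction` events, and have no motif bias.
#'
#' @param n_events unique crosslink events (cDNAs) in a full library.
#' @param motif_boost rate multiplier near planted motifs (>= 1).
#' @param proximity_window crosslink offsets 0..`proximity_window` nt 5' of
#'   a motif start receive the boost (default 5).
#' @param pcr_duplication_mean mean reads per unique cDNA (>= 1).
#' @param read_length total read length: barcode + UMI + insert.
#' @param barcode_map named character vector, sample kind -> barcode.
#' @param umi_length UMI length in nt.
#' @param control_rate_fraction event-rate of the control libraries relative
#'   to the crosslinked library, in \[0, 1\].
#' @param comparison_rate_fraction same for the GA comparison library.
#' @param three_prime_adaptor adaptor sequence (recorded in the layout; the
#'   simulator emits full-length inserts so reads carry no adaptor).
#' @param seed integer seed.
#' @return list of class `clip_sim_config`.
#' @export
clip_sim_config <- function(n_events = 20000,
                            motif_boost = 50,
                            proximity_window = 5,
                            pcr_duplication_mean = 3,
                            read_length = 75,
                            barcode_map = c("PR-crosslinked" = "ACGTA",
                                            "PR-noncrosslinked" = "TGCAT",
                                            "GA-crosslinked" = "GATCG",
                                            "FLAG-crosslinked" = "CTAGC"),
                            umi_length = 6,
                            control_rate_fraction = 0.05,
                            comparison_rate_fraction = 0.10,
                            three_prime_adaptor = "AGATCGGAAGAGC",
                            seed = 1) {
  stopifnot(n_events >= 1, motif_boost >= 1, proximity_window >= 0,
            pcr_duplication_mean >= 1, umi_length >= 1,
            control_rate_fraction >= 0, control_rate_fraction <= 1,
            comparison_rate_fraction >= 0, comparison_rate_fraction <= 1)
  if (length(unique(nchar(barcode_map))) != 1L) {
    stop("all barcodes must have equal length")
  }
  if (anyDuplicated(barcode_map)) stop("barcodes must be unique")
  if (read_length <= nchar(barcode_map[1]) + umi_length) {
    stop("read_length leaves no room for an insert")
  }
  structure(as.list(environment()), class = "clip_sim_config")
}

clip_sample_kinds <- function() {
  c("PR-crosslinked", "PR-noncrosslinked", "GA-crosslinked", "FLAG-crosslinked")
}

#' Simulate a CLIP sequencing library with ground truth
#'
#' Draws unique crosslink events on the transcriptome, then emits
#' truncation-model reads: each read is barcode + UMI + insert, with the
#' insert starting one nucleotide 3' of its crosslink position on the
#' transcript strand, so the standard crosslink-assignment rule recovers the
#' event exactly. PCR duplication is simulated per unique cDNA
#' (1 + Poisson(`pcr_duplication_mean` - 1) reads). No sequencing errors are
#' introduced.
#'
#' @param tx a `transcriptome` from [build_transcriptome()].
#' @param config a [clip_sim_config()].
#' @param sample_kind one of `"PR-crosslinked"` (full depth, motif-boosted),
#'   `"PR-noncrosslinked"` / `"FLAG-crosslinked"` (controls:
#'   `control_rate_fraction` of the depth, no motif bias), or
#'   `"GA-crosslinked"` (comparison: `comparison_rate_fraction`, no bias).
#' @return list of class `clip_library`: `sample_kind`, `reads` (named
#'   `DNAStringSet`), `alignments` (data.frame of 0-based half-open truth
#'   alignments: read_id, ref, start, end, strand), and `truth` (events,
#'   per-read table with UMIs and duplicate structure, n_events).
#' @export
simulate_clip_library <- function(tx, config,
                                  sample_kind = "PR-crosslinked") {
  stopifnot(inherits(tx, "transcriptome"), inherits(config, "clip_sim_config"))
  sample_kind <- match.arg(sample_kind, clip_sample_kinds())
  if (config$read_length > min(IRanges::width(tx$genes))) {
    stop("read_length exceeds the shortest gene")
  }
  kind_idx <- match(sample_kind, clip_sample_kinds())
  set.seed(config$seed + 10007L * (kind_idx - 1L))

  n <- switch(sample_kind,
              "PR-crosslinked" = config$n_events,
              "GA-crosslinked" = max(1L, round(config$n_events * config$comparison_rate_fraction)),
              max(1L, round(config$n_events * config$control_rate_fraction)))
  boost <- if (sample_kind == "PR-crosslinked") config$motif_boost else 1

  ## universe of transcribed positions (1-based genomic) with weights
  gs <- GenomicRanges::start(tx$genes); ge <- GenomicRanges::end(tx$genes)
  gstr <- as.character(GenomicRanges::strand(tx$genes))
  pos <- unlist(mapply(seq.int, gs, ge, SIMPLIFY = FALSE))
  gene_of <- rep(seq_along(gs), ge - gs + 1L)
  wt <- rep(1, length(pos))
  if (boost > 1 && length(tx$motifs) > 0) {
    ms <- GenomicRanges::start(tx$motifs); me <- GenomicRanges::end(tx$motifs)
    mstr <- as.character(GenomicRanges::strand(tx$motifs))
    prox <- unlist(lapply(seq_along(ms), function(i) {
      if (mstr[i] == "+") (ms[i] - config$proximity_window):ms[i]
      else me[i]:(me[i] + config$proximity_window)
    }))
    wt[pos %in% prox] <- boost
  }
  idx <- sample.int(length(pos), n, replace = TRUE, prob = wt)
  ev_pos1 <- pos[idx]
  ev_gene <- gene_of[idx]
  ev_strand <- gstr[ev_gene]

  bc_len <- nchar(config$barcode_map[[1]])
  il <- config$read_length - bc_len - config$umi_length
  barcode <- config$barcode_map[[sample_kind]]
  if (is.null(barcode)) stop("no barcode defined for sample kind ", sample_kind)

  ## UMIs drawn without replacement within each event position, so distinct
  ## events are never merged by the exact-UMI deduplication downstream:
  ## unique (position, UMI) pairs == n_events by construction
  umi_space <- 4L^config$umi_length
  umi_idx <- integer(n)
  for (grp in split(seq_len(n), paste(ev_pos1, ev_strand))) {
    if (length(grp) > umi_space) {
      stop("more events at one position than distinct UMIs; increase umi_length")
    }
    umi_idx[grp] <- sample.int(umi_space, length(grp))
  }
  digits <- vapply(seq_len(config$umi_length) - 1L,
                   function(d) (umi_idx - 1L) %/% 4^d %% 4L,
                   numeric(n))
  if (n == 1L) digits <- matrix(digits, nrow = 1L)
  umis <- apply(digits, 1, function(r)
    paste(c("A", "C", "G", "T")[r + 1L], collapse = ""))
  dup <- 1L + rpois(n, max(0, config$pcr_duplication_mean - 1))

  ## 0-based event positions and 0-based half-open insert spans
  p0 <- as.integer(ev_pos1 - 1L)
  plus <- ev_strand == "+"
  ins_start0 <- as.integer(ifelse(plus, p0 + 1L, p0 - il))
  ins_end0 <- as.integer(ins_start0 + il)
  chr <- tx$genome[[1]]
  if (any(ins_start0 < 0L) || any(ins_end0 > length(chr))) {
    stop("insert extends beyond the chromosome; increase intergenic_length")
  }
  ins_seq <- as.character(Biostrings::extractAt(
    chr, IRanges::IRanges(ins_start0 + 1L, width = il)))
  ins_seq[!plus] <- revcomp_chr(ins_seq[!plus])

  event_id <- sprintf("ev%06d", seq_len(n))
  read_event <- rep(seq_len(n), dup)
  read_id <- sprintf("%s_r%07d", gsub("[^A-Za-z]", "", sample_kind),
                     seq_along(read_event))

  reads <- Biostrings::DNAStringSet(
    paste0(barcode, umis[read_event], ins_seq[read_event]))
  names(reads) <- read_id

  alignments <- data.frame(read_id = read_id, ref = "chr1",
                           start = ins_start0[read_event],
                           end = ins_end0[read_event],
                           strand = ev_strand[read_event],
                           stringsAsFactors = FALSE)
  truth <- list(
    events = data.frame(event_id = event_id, ref = "chr1", pos = p0,
                        strand = ev_strand,
                        gene_id = tx$genes$gene_id[ev_gene],
                        sample = sample_kind, umi = umis,
                        dup_count = dup, stringsAsFactors = FALSE),
    reads = data.frame(read_id = read_id, event_id = event_id[read_event],
                       umi = umis[read_event], stringsAsFactors = FALSE),
    n_events = n)
  structure(list(sample_kind = sample_kind, reads = reads,
                 alignments = alignments, truth = truth,
                 barcode = barcode, umi_length = config$umi_length,
                 three_prime_adaptor = config$three_prime_adaptor),
            class = "clip_library")
}

#' Write a simulated CLIP library to disk
#'
#' Emits reads as FASTQ (constant quality), truth alignments as BED6
#' (0-based half-open; name = read id), the ground-truth event table as
#' JSON, and a small JSON sidecar describing the read layout
#' (barcode, UMI, adaptor).
#'
#' @param lib a `clip_library`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_clip_library <- function(lib, dir) {
  stopifnot(inherits(lib, "clip_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tag <- gsub("[^A-Za-z]", "", lib$sample_kind)
  fq <- file.path(dir, paste0(tag, ".fastq"))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(lib$reads)))
  Biostrings::writeXStringSet(lib$reads, fq, format = "fastq", qualities = qual)

  bed <- file.path(dir, paste0(tag, ".truth.bed"))
  al <- lib$alignments
  utils::write.table(
    data.frame(al$ref, al$start, al$end, al$read_id, 0L, al$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  truth <- file.path(dir, paste0(tag, ".truth.json"))
  jsonlite::write_json(lib$truth$events, truth, digits = NA)

  layout <- file.path(dir, paste0(tag, ".layout.json"))
  jsonlite::write_json(list(barcode_length = nchar(lib$barcode),
                            umi_length = lib$umi_length,
                            barcode_map = setNames(list(lib$sample_kind), lib$barcode),
                            three_prime_adaptor = lib$three_prime_adaptor),
                       layout, auto_unbox = TRUE)
  invisible(c(fastq = fq, bed = bed, truth = truth, layout = layout))
}

#' Default biolayer-interferometry concentration ladders
#'
#' Two-fold dilution series matching the published assay design: 2.1-133.3
#' nM for the arginine-rich PR20/GR20 peptides, 3.1-25 uM for the GP20
#' negative control.
#'
#' @param peptide `"PR20"`, `"GR20"` or `"GP20"`.
#' @return concentrations in molar, ascending.
#' @export
bli_concentration_ladder <- function(peptide = c("PR20", "GR20", "GP20")) {
  peptide <- match.arg(peptide)
  if (peptide == "GP20") 25e-6 / 2^(3:0) else 133.3e-9 / 2^(6:0)
}

#' Simulate biolayer-interferometry association traces
#'
#' Pseudo-first-order 1:1 Langmuir association:
#' \deqn{R(t) = R_{eq}(C)\,(1 - e^{-(k_a C + k_{off}) t}),\quad
#'       R_{eq}(C) = R_{max}\,C / (C + K_d),\quad K_d = k_{off}/k_a,}
#' with additive Gaussian noise of standard deviation `noise_sd * rmax`.
#'
#' @param true_ka association rate constant, 1/(M s).
#' @param true_kd_off dissociation rate constant, 1/s.
#' @param rmax maximal response, instrument response units.
#' @param concentrations analyte concentrations in molar (all > 0).
#' @param times time grid in seconds (strictly increasing).
#' @param noise_sd noise standard deviation as a fraction of `rmax`.
#' @param replicates number of independent replicate experiments.
#' @param seed integer seed.
#' @return data.frame of class `bli_traces` with columns `replicate`,
#'   `concentration_M`, `time_s`, `response`, plus the generating parameters
#'   in attribute `truth`.
#' @export
simulate_bli_dataset <- function(true_ka, true_kd_off, rmax,
                                 concentrations = bli_concentration_ladder("PR20"),
                                 times = seq(0, 600, by = 2),
                                 noise_sd = 0.01, replicates = 3, seed = 1) {
  stopifnot(true_ka > 0, true_kd_off > 0, rmax > 0,
            noise_sd >= 0, replicates >= 1)
  if (length(concentrations) == 0) stop("empty concentration list")
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  set.seed(seed)
  kd <- true_kd_off / true_ka
  grid <- expand.grid(time_s = times, concentration_M = concentrations,
                      replicate = seq_len(replicates))
  kobs <- true_ka * grid$concentration_M + true_kd_off
  req <- rmax * grid$concentration_M / (grid$concentration_M + kd)
  resp <- req * (1 - exp(-kobs * grid$time_s))
  if (noise_sd > 0) resp <- resp + rnorm(nrow(grid), sd = noise_sd * rmax)
  out <- data.frame(replicate = grid$replicate,
                    concentration_M = grid$concentration_M,
                    time_s = grid$time_s, response = resp)
  attr(out, "truth") <- list(ka = true_ka, kd_off = true_kd_off,
                             kd = kd, rmax = rmax)
  class(out) <- c("bli_traces", "data.frame")
  out
}
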