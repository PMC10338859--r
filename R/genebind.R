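#' Count crosslink events per gene and sample
#'
#' An event counts toward a gene when its position lies within the gene span
#' on the same strand (gene spans are half-open on the 0-based event axis,
#' so an event exactly at the gene's first nucleotide counts). Events inside
#' no gene are tallied as intergenic.
#'
#' @param events events data.frame (ref, pos \[0-based\], strand, sample);
#'   may contain several samples.
#' @param genes `GRanges` of gene spans with `gene_id`.
#' @return list with `counts` (gene_id x sample matrix of event counts,
#'   including an `"<intergenic>"` row) and `totals` (per-sample total
#'   events).
#' @export
count_gene_events <- function(events, genes) {
  if (is.null(genes$gene_id)) stop("malformed annotation: genes lack gene_id")
  samples <- unique(events$sample)
  ev_gr <- GenomicRanges::GRanges(events$ref,
                                  IRanges::IRanges(events$pos + 1L, width = 1L),
                                  strand = events$strand)
  hits <- GenomicRanges::findOverlaps(ev_gr, genes)
  gene_of <- rep("<intergenic>", nrow(events))
  gene_of[S4Vectors::queryHits(hits)] <-
    genes$gene_id[S4Vectors::subjectHits(hits)]
  counts <- table(factor(gene_of, levels = c(genes$gene_id, "<intergenic>")),
                  factor(events$sample, levels = samples))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  list(counts = counts, totals = colSums(counts))
}

#' Gene-level binding summary and bound-gene filter
#'
#' Builds the per-gene binding table for a crosslinked sample against its
#' control samples and applies the bound-gene filter: a gene is bound when
#' it carries at least `min_events` crosslink events in the crosslinked
#' sample and its control binding fraction is below `max_control_fraction`.
#' The control fraction is depth-fair: per control, CPM(control) / CPM(gene
#' in crosslinked sample), taking the maximum over controls.
#'
#' @param gene_counts result of [count_gene_events()] (events from all
#'   samples counted together).
#' @param pr_sample name of the crosslinked sample of interest.
#' @param control_samples names of the control samples (e.g. non-crosslinked
#'   and tag-only libraries).
#' @param min_events minimum events in `pr_sample` (default 200).
#' @param max_control_fraction bound requires control fraction strictly
#'   below this (default 0.10).
#' @param control_fraction_basis `"cpm"` (default): control fraction is the
#'   ratio of depth-normalised CPM values, which is invariant to library
#'   depth and asks whether a gene's *share* of control signal approaches
#'   its share of crosslinked signal; `"count"`: raw event-count ratio,
#'   which credits the depth asymmetry between crosslinked and low-yield
#'   control libraries itself.
#' @return data.frame of class `gene_binding_summary`, sorted by `events_PR`
#'   descending: gene_id, events_PR, cpm_PR, events/cpm per control,
#'   control_fraction, bound.
#' @export
filter_bound_genes <- function(gene_counts, pr_sample,
                               control_samples,
                               min_events = 200,
                               max_control_fraction = 0.10,
                               control_fraction_basis = c("cpm", "count")) {
  control_fraction_basis <- match.arg(control_fraction_basis)
  counts <- gene_counts$counts
  totals <- gene_counts$totals
  stopifnot(pr_sample %in% colnames(counts),
            all(control_samples %in% colnames(counts)))
  genes <- setdiff(rownames(counts), "<intergenic>")
  cpm <- sweep(counts, 2, totals, function(x, t) x * 1e6 / ifelse(t > 0, t, 1))
  ev_pr <- counts[genes, pr_sample]
  cpm_pr <- cpm[genes, pr_sample]
  if (any(ev_pr > 0 & cpm_pr == 0)) stop("internal inconsistency: events without CPM")

  basis <- if (control_fraction_basis == "cpm") cpm else counts
  basis_pr <- basis[genes, pr_sample]
  frac <- matrix(0, length(genes), length(control_samples),
                 dimnames = list(genes, control_samples))
  for (cs in control_samples) {
    frac[, cs] <- ifelse(basis_pr > 0, basis[genes, cs] / basis_pr,
                         ifelse(basis[genes, cs] > 0, Inf, 0))
  }
  control_fraction <- apply(frac, 1, max)
  bound <- ev_pr >= min_events & control_fraction < max_control_fraction

  out <- data.frame(gene_id = genes, events_PR = ev_pr, cpm_PR = cpm_pr,
                    stringsAsFactors = FALSE)
  for (cs in control_samples) {
    out[[paste0("events_", cs)]] <- counts[genes, cs]
    out[[paste0("cpm_", cs)]] <- cpm[genes, cs]
  }
  out$control_fraction <- control_fraction
  out$bound <- bound
  out <- out[order(-out$events_PR, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "params") <- list(min_events = min_events,
                              max_control_fraction = max_control_fraction,
                              control_fraction_basis = control_fraction_basis)
  class(out) <- c("gene_binding_summary", "data.frame")
  out
}

#' Annotate crosslink events by genomic region
#'
#' Assigns each event exactly one region class using the precedence
#' CDS > 5'UTR > 3'UTR > non-coding RNA exon > intron > intergenic
#' (strand-aware; "intron" means inside a gene span but in none of its
#' exonic feature classes). The precedence order is a convention and can be
#' overridden.
#'
#' @param events events data.frame (ref, pos, strand).
#' @param genes gene spans `GRanges` with `gene_id` and `gene_type`.
#' @param features feature `GRanges` with `type` (exon, CDS,
#'   five_prime_UTR, three_prime_UTR) and `gene_id`.
#' @param precedence region classes in decreasing priority.
#' @return list with `classes` (factor, one per event) and `proportions`
#'   (named numeric summing to 1 over the event set).
#' @export
annotate_regions <- function(events, genes, features,
                             precedence = c("CDS", "5'UTR", "3'UTR",
                                            "ncRNA", "intron", "intergenic")) {
  if (length(events$ref) && !all(events$ref %in%
        unique(c(as.character(GenomicRanges::seqnames(genes)),
                 as.character(GenomicRanges::seqnames(features)))))) {
    stop("event on unknown reference")
  }
  ev_gr <- GenomicRanges::GRanges(events$ref,
                                  IRanges::IRanges(events$pos + 1L, width = 1L),
                                  strand = events$strand)
  nc_genes <- genes$gene_id[genes$gene_type != "protein_coding"]
  region_of <- list(
    "CDS" = features[features$type == "CDS"],
    "5'UTR" = features[features$type == "five_prime_UTR"],
    "3'UTR" = features[features$type == "three_prime_UTR"],
    "ncRNA" = features[features$type == "exon" &
                         features$gene_id %in% nc_genes],
    "intron" = genes)
  cls <- rep("intergenic", length(ev_gr))
  for (r in rev(setdiff(precedence, "intergenic"))) {
    hit <- IRanges::overlapsAny(ev_gr, region_of[[r]])
    cls[hit] <- r
  }
  cls <- factor(cls, levels = precedence)
  props <- if (length(cls)) table(cls) / length(cls) else table(cls)
  list(classes = cls, proportions = c(props))
}
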