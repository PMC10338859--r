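#' Build a crosslink track from events
#'
#' Aggregates single-nucleotide crosslink events into per-position counts
#' for one sample.
#'
#' @param events events data.frame (ref, pos, strand, ...) for one sample.
#' @return list of class `crosslink_track`: `counts` (data.frame ref, pos,
#'   strand, count) and `total_events`.
#' @export
crosslink_track <- function(events) {
  if (nrow(events) == 0) {
    counts <- data.frame(ref = character(0), pos = integer(0),
                         strand = character(0), count = integer(0))
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(events))),
                            events[c("ref", "pos", "strand")], sum)
    counts <- agg[order(agg$ref, agg$strand, agg$pos), , drop = FALSE]
    rownames(counts) <- NULL
  }
  structure(list(counts = counts, total_events = sum(counts$count)),
            class = "crosslink_track")
}

#' Counts-per-million normalisation of a crosslink track
#'
#' Scales each position's event count by 1e6 over the sample's total
#' events, so track values are comparable across libraries of different
#' depth; the CPM values of a track sum to 1e6.
#'
#' @param track a [crosslink_track()].
#' @return the track with a `cpm` column added to `counts`.
#' @export
cpm_normalize <- function(track) {
  stopifnot(inherits(track, "crosslink_track"))
  if (track$total_events == 0) stop("empty track: no events to normalise")
  track$counts$cpm <- track$counts$count * 1e6 / track$total_events
  track
}

#' Library-depth quality control
#'
#' A crosslinked sample passes when its number of unique crosslink events
#' reaches `min_events` (default 300,000, the depth below which a library is
#' considered too shallow for site-level analysis).
#'
#' @param track a [crosslink_track()] (or anything with `total_events`).
#' @param min_events minimum unique events required.
#' @param sample optional sample label for the summary row.
#' @return data.frame row: sample, unique_events, min_events, pass.
#' @export
sample_qc <- function(track, min_events = 300000, sample = NA_character_) {
  total <- if (inherits(track, "crosslink_track")) track$total_events
           else as.numeric(track)
  data.frame(sample = sample, unique_events = total,
             min_events = min_events, pass = total >= min_events)
}

## Permutation FDR for the event positions of a single gene.
## pos_rel: 0-based positions within the gene (0..L-1), one per event.
## Returns a data.frame: pos_rel (unique event positions), count, score, fdr.
perm_fdr_gene <- function(pos_rel, L, w = 3, n_perm = 100) {
  n <- length(pos_rel)
  if (n == 0) {
    return(data.frame(pos_rel = integer(0), count = integer(0),
                      score = integer(0), fdr = numeric(0)))
  }
  cnt <- tabulate(pos_rel + 1L, nbins = L)
  sc <- window_sum(cnt, w)
  obs_pos <- which(cnt > 0L)
  obs_sc <- sc[obs_pos]

  ths <- sort(unique(obs_sc))                       # ascending thresholds
  ## observed number of event-positions with score >= each threshold
  obs_ge <- length(obs_sc) - findInterval(ths - 1L, sort(obs_sc))
  perm_ge <- numeric(length(ths))
  for (b in seq_len(n_perm)) {
    pp <- sample.int(L, n, replace = TRUE)
    pc <- tabulate(pp, nbins = L)
    psc <- window_sum(pc, w)
    p_obs <- sort(psc[pc > 0L])
    perm_ge <- perm_ge + (length(p_obs) - findInterval(ths - 1L, p_obs))
  }
  fdr_th <- pmin(1, (perm_ge / n_perm) / obs_ge)
  ## enforce FDR monotone non-increasing in score: running minimum taken in
  ## ascending score order, so a higher score never has a larger FDR
  fdr_th <- cummin(fdr_th)
  data.frame(pos_rel = obs_pos - 1L, count = cnt[obs_pos], score = obs_sc,
             fdr = fdr_th[match(obs_sc, ths)])
}

#' Call significant crosslink sites by permutation FDR
#'
#' For each gene, each event-bearing position is scored by the number of
#' events in a window of +/- `half_window` nt around it. The null is built
#' by redistributing the gene's events uniformly at random over the gene's
#' positions `n_perm` times; the FDR at an observed position with score s is
#' the mean number of permuted event-positions scoring >= s divided by the
#' observed number of event-positions scoring >= s (capped at 1, and made
#' monotone non-increasing in score). Positions with FDR below
#' `fdr_threshold` are retained. Ties in score share one FDR value. Events
#' falling outside all genes are tested against fixed-width flanking
#' pseudo-genes (see `intergenic_flank`).
#'
#' @param events events data.frame (ref, pos \[0-based\], strand) for one
#'   sample (pool replicates beforehand if desired).
#' @param genes `GRanges` of gene spans (1-based) with `gene_id`.
#' @param half_window score window half-width in nt (default 3).
#' @param n_perm number of permutations (default 100).
#' @param fdr_threshold retain sites with FDR strictly below this.
#' @param seed integer seed for the permutations.
#' @param intergenic_flank width of the pseudo-gene used for events outside
#'   all genes; `NULL` skips intergenic events entirely.
#' @return data.frame of class `significant_sites`: gene_id, ref, pos
#'   (0-based), strand, count, score, fdr, for retained sites, ordered by
#'   gene then position. All tested positions are returned in attribute
#'   `all_positions`.
#' @export
call_significant_sites <- function(events, genes, half_window = 3,
                                   n_perm = 100, fdr_threshold = 0.05,
                                   seed = 1, intergenic_flank = 10000) {
  set.seed(seed)
  ev_gr <- GenomicRanges::GRanges(events$ref,
                                  IRanges::IRanges(events$pos + 1L, width = 1L),
                                  strand = events$strand)
  hits <- GenomicRanges::findOverlaps(ev_gr, genes)
  gene_idx <- rep(NA_integer_, nrow(events))
  gene_idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)

  res <- vector("list", 0L)
  for (gi in sort(unique(gene_idx[!is.na(gene_idx)]))) {
    sel <- which(gene_idx == gi)
    gs <- GenomicRanges::start(genes)[gi] - 1L  # 0-based gene start
    L <- IRanges::width(genes)[gi]
    tab <- perm_fdr_gene(events$pos[sel] - gs, L, half_window, n_perm)
    if (nrow(tab)) {
      tab$gene_id <- genes$gene_id[gi]
      tab$ref <- events$ref[sel[1]]
      tab$strand <- as.character(GenomicRanges::strand(genes))[gi]
      tab$pos <- tab$pos_rel + gs
      res[[length(res) + 1L]] <- tab
    }
  }

  ## intergenic events: fixed-width pseudo-genes tiled over their span
  inter <- which(is.na(gene_idx))
  if (length(inter) && !is.null(intergenic_flank)) {
    key <- paste(events$ref[inter], events$strand[inter],
                 events$pos[inter] %/% intergenic_flank)
    for (k in unique(key)) {
      sel <- inter[key == k]
      bin0 <- (events$pos[sel[1]] %/% intergenic_flank) * intergenic_flank
      tab <- perm_fdr_gene(events$pos[sel] - bin0, intergenic_flank,
                           half_window, n_perm)
      if (nrow(tab)) {
        tab$gene_id <- NA_character_
        tab$ref <- events$ref[sel[1]]
        tab$strand <- events$strand[sel[1]]
        tab$pos <- tab$pos_rel + bin0
        res[[length(res) + 1L]] <- tab
      }
    }
  }

  cols <- c("gene_id", "ref", "pos", "strand", "count", "score", "fdr")
  all_tab <- if (length(res)) do.call(rbind, res)[, cols] else
    data.frame(gene_id = character(0), ref = character(0), pos = integer(0),
               strand = character(0), count = integer(0), score = integer(0),
               fdr = numeric(0))
  all_tab <- all_tab[order(all_tab$gene_id, all_tab$pos), , drop = FALSE]
  rownames(all_tab) <- NULL
  sig <- all_tab[all_tab$fdr < fdr_threshold, , drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "all_positions") <- all_tab
  attr(sig, "params") <- list(half_window = half_window, n_perm = n_perm,
                              fdr_threshold = fdr_threshold, seed = seed,
                              intergenic_flank = intergenic_flank)
  class(sig) <- c("significant_sites", "data.frame")
  sig
}

#' Write significant sites as BED6 + TSV
#'
#' BED score column is `-10 log10(FDR)`, capped at 1000 (an FDR of 0 over
#' the permutations maps to the cap).
#'
#' @param sites result of [call_significant_sites()].
#' @param bed_path,tsv_path output files (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- pmin(1000, round(-10 * log10(pmax(sites$fdr, 1e-100))))
    utils::write.table(
      data.frame(sites$ref, sites$pos, sites$pos + 1L,
                 ifelse(is.na(sites$gene_id), ".", sites$gene_id),
                 score, sites$strand),
      bed_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(sites), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}
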