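#' Log-space one-sided hypergeometric tail
#'
#' Exact upper-tail probability P(X >= k) for X ~ Hypergeometric(N, K, n)
#' (urn of `N` windows of which `K` contain the pentamer; `n` drawn as
#' foreground), computed entirely in log space so that p-values far below
#' double underflow (e.g. 1e-930) remain representable as log10 values.
#' This is the one-sided Fisher exact test for enrichment of "with" windows
#' in the foreground of a 2x2 presence table.
#'
#' @param k observed foreground windows containing the pentamer.
#' @param K total windows containing the pentamer (fg + bg).
#' @param n number of foreground windows.
#' @param N total number of windows (fg + bg).
#' @return natural-log tail probability (<= 0).
#' @export
log_hyper_tail <- function(k, K, n, N) {
  stopifnot(N >= 0, K >= 0, K <= N, n >= 0, n <= N)
  kmax <- min(K, n)
  jmin <- max(0L, n - (N - K))
  if (k > kmax) return(-Inf)
  j <- max(k, jmin):kmax
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  min(0, logsumexp(lp))
}

## Presence counts: number of windows containing >= 1 occurrence of each
## pentamer (windows as DNAStringSet; pentamers as DNA strings).
pentamer_presence <- function(windows_dna, pentamers_dna) {
  pd <- Biostrings::PDict(pentamers_dna)
  m <- Biostrings::vcountPDict(pd, windows_dna)
  as.integer(rowSums(m > 0L))
}

#' Extract foreground sequence windows around significant sites
#'
#' For each site, takes the window from `up` nt upstream to `down` nt
#' downstream of the crosslinked nucleotide in transcript orientation
#' (default -5..+30, i.e. 36 nt), reverse-complementing minus-strand
#' windows, and returns RNA-sense sequences. Windows truncated by the ends
#' of their gene are dropped and counted.
#'
#' @param sites data.frame with ref, pos (0-based), strand, gene_id (e.g.
#'   [call_significant_sites()] output).
#' @param genome `DNAStringSet` (plus strand).
#' @param genes gene spans `GRanges` with `gene_id`.
#' @param up,down window extent in nt up-/downstream of the site.
#' @return list of class `motif_window_set`: `windows` (RNA-sense character
#'   vector, equal length), `gene_id`, `origin = "foreground"`, `dropped`.
#' @export
extract_windows <- function(sites, genome, genes, up = 5, down = 30) {
  if (!all(sites$ref %in% names(genome))) stop("site on unknown reference")
  gi <- match(sites$gene_id, genes$gene_id)
  gs0 <- GenomicRanges::start(genes)[gi] - 1L      # 0-based gene start
  ge0 <- GenomicRanges::end(genes)[gi] - 1L        # 0-based gene last base
  plus <- sites$strand == "+"
  w_start0 <- ifelse(plus, sites$pos - up, sites$pos - down)
  w_end0 <- w_start0 + up + down                    # inclusive, width up+down+1
  ok <- !is.na(gi) & w_start0 >= gs0 & w_end0 <= ge0
  dropped <- sum(!ok)

  seqs <- character(0)
  if (any(ok)) {
    at <- IRanges::IRanges(w_start0[ok] + 1L, w_end0[ok] + 1L)
    seqs <- as.character(Biostrings::extractAt(genome[[1]], at))
    minus <- !plus[ok]
    seqs[minus] <- revcomp_chr(seqs[minus])
    seqs <- dna_to_rna(seqs)
  }
  structure(list(windows = seqs, gene_id = sites$gene_id[ok],
                 origin = "foreground", dropped = dropped,
                 up = up, down = down),
            class = "motif_window_set")
}

## Eligible background anchor positions (0-based) for one gene: the window
## anchored at q must lie within the gene and contain no significant site.
eligible_anchors <- function(gs0, ge0, strand, site_pos, up, down) {
  if (strand == "+") {
    q <- seq.int(gs0 + up, ge0 - down)
    if (length(site_pos)) {
      bad <- unlist(lapply(site_pos, function(p) (p - down):(p + up)))
      q <- setdiff(q, bad)
    }
  } else {
    q <- seq.int(gs0 + down, ge0 - up)
    if (length(site_pos)) {
      bad <- unlist(lapply(site_pos, function(p) (p - up):(p + down)))
      q <- setdiff(q, bad)
    }
  }
  q
}

#' Sample matched background windows
#'
#' Draws background windows uniformly from the same genes as the foreground
#' set, with the same per-gene multiplicity, restricted to positions whose
#' window contains no significant crosslink site. A gene with no eligible
#' position is skipped with a warning and its multiplicity reassigned to the
#' pooled eligible positions of the remaining genes.
#'
#' @param fg a foreground `motif_window_set` from [extract_windows()].
#' @param sites the significant sites the foreground was built from.
#' @param genome `DNAStringSet`.
#' @param genes gene spans `GRanges` with `gene_id`.
#' @param seed integer seed.
#' @return a `motif_window_set` with `origin = "background"`.
#' @export
sample_background_windows <- function(fg, sites, genome, genes, seed = 1) {
  stopifnot(inherits(fg, "motif_window_set"))
  set.seed(seed)
  up <- fg$up; down <- fg$down
  mult <- table(fg$gene_id)
  gi <- match(names(mult), genes$gene_id)
  anchors <- character(0)
  qs <- integer(0); q_gene <- character(0); q_strand <- character(0)
  pool_q <- integer(0); pool_gene <- character(0); pool_strand <- character(0)
  short <- 0L
  for (i in seq_along(mult)) {
    g <- names(mult)[i]
    gs0 <- GenomicRanges::start(genes)[gi[i]] - 1L
    ge0 <- GenomicRanges::end(genes)[gi[i]] - 1L
    strand <- as.character(GenomicRanges::strand(genes))[gi[i]]
    sp <- sites$pos[sites$gene_id == g]
    elig <- eligible_anchors(gs0, ge0, strand, sp, up, down)
    if (length(elig) == 0L) {
      warning("gene ", g, " has no eligible background position; ",
              "multiplicity reassigned")
      short <- short + mult[[i]]
    } else {
      pick <- elig[sample.int(length(elig), mult[[i]], replace = TRUE)]
      qs <- c(qs, pick)
      q_gene <- c(q_gene, rep(g, mult[[i]]))
      q_strand <- c(q_strand, rep(strand, mult[[i]]))
      pool_q <- c(pool_q, elig)
      pool_gene <- c(pool_gene, rep(g, length(elig)))
      pool_strand <- c(pool_strand, rep(strand, length(elig)))
    }
  }
  if (short > 0L && length(pool_q)) {
    pick <- sample.int(length(pool_q), short, replace = TRUE)
    qs <- c(qs, pool_q[pick])
    q_gene <- c(q_gene, pool_gene[pick])
    q_strand <- c(q_strand, pool_strand[pick])
  }
  if (length(qs) == 0L) {
    return(structure(list(windows = character(0), gene_id = character(0),
                          origin = "background", dropped = 0L,
                          up = up, down = down),
                     class = "motif_window_set"))
  }
  pseudo <- data.frame(ref = names(genome)[1], pos = qs, strand = q_strand,
                       gene_id = q_gene, stringsAsFactors = FALSE)
  out <- extract_windows(pseudo, genome, genes, up = up, down = down)
  out$origin <- "background"
  out
}

#' Pentamer enrichment: foreground vs background windows
#'
#' For each of the 1,024 RNA pentamers, counts windows containing at least
#' one occurrence ("with") in foreground and background (presence, not
#' occurrence counts), and computes the one-sided Fisher exact p-value for
#' enrichment in the foreground from the hypergeometric tail, in log space.
#' Bonferroni correction multiplies by 1,024. Results are sorted by
#' ascending p, ties broken by `fg_with` descending then pentamer
#' lexicographic.
#'
#' @param fg,bg `motif_window_set`s of equal window length (>= 5 nt).
#' @return data.frame of class `pentamer_results`: pentamer, fg_with,
#'   fg_without, bg_with, bg_without, log10_p, p, log10_p_corrected,
#'   p_corrected, p_label (scientific string usable below double
#'   underflow), rank.
#' @export
pentamer_enrichment <- function(fg, bg) {
  stopifnot(inherits(fg, "motif_window_set"), inherits(bg, "motif_window_set"))
  if (length(fg$windows) == 0 || length(bg$windows) == 0) {
    stop("foreground and background must be non-empty")
  }
  wlen <- unique(nchar(c(fg$windows, bg$windows)))
  if (length(wlen) != 1) stop("all windows must have equal length")
  if (wlen < 5) stop("window length below pentamer length")

  pent <- all_kmers(5)
  pent_dna <- Biostrings::DNAStringSet(rna_to_dna(pent))
  fg_dna <- Biostrings::DNAStringSet(rna_to_dna(fg$windows))
  bg_dna <- Biostrings::DNAStringSet(rna_to_dna(bg$windows))
  fg_with <- pentamer_presence(fg_dna, pent_dna)
  bg_with <- pentamer_presence(bg_dna, pent_dna)
  nfg <- length(fg$windows); nbg <- length(bg$windows)

  lp <- vapply(seq_along(pent), function(i) {
    log_hyper_tail(fg_with[i], fg_with[i] + bg_with[i], nfg, nfg + nbg)
  }, numeric(1))
  log10_p <- lp / log(10)
  log10_p_corr <- pmin(0, log10_p + log10(length(pent)))

  out <- data.frame(pentamer = pent,
                    fg_with = fg_with, fg_without = nfg - fg_with,
                    bg_with = bg_with, bg_without = nbg - bg_with,
                    log10_p = log10_p, p = exp(lp),
                    log10_p_corrected = log10_p_corr,
                    p_corrected = 10^log10_p_corr,
                    p_label = format_log10p(log10_p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$log10_p, -out$fg_with, out$pentamer), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("pentamer_results", "data.frame")
  out
}

#' Format a log10 p-value as a scientific-notation string
#'
#' Produces strings like `"3.1e-930"` even when the p-value underflows a
#' double.
#'
#' @param log10_p vector of log10 p-values (<= 0).
#' @param digits significant digits for the mantissa.
#' @return character vector.
#' @export
format_log10p <- function(log10_p, digits = 2) {
  vapply(log10_p, function(lp) {
    if (!is.finite(lp)) return(if (lp < 0) "0" else "1")
    if (lp == 0) return("1")
    e <- floor(lp)
    m <- signif(10^(lp - e), digits)
    if (m >= 10) { m <- m / 10; e <- e + 1 }
    sprintf("%se%d", format(m), e)
  }, character(1))
}

#' Positional profile of a pentamer around crosslink sites
#'
#' For each offset in `-offset_range..offset_range` (transcript
#' orientation, 0 = the crosslinked nucleotide), the fraction of sites whose
#' sequence carries an occurrence of the pentamer starting at that offset.
#' IUPAC degenerate codes are supported (e.g. `GANGA`). A site contributes
#' to an offset only when the full pentamer at that offset lies within the
#' site's gene.
#'
#' @param pentamer RNA 5-mer, possibly degenerate (IUPAC).
#' @param sites sites data.frame (ref, pos, strand, gene_id).
#' @param genome `DNAStringSet`.
#' @param genes gene spans `GRanges` with `gene_id`.
#' @param offset_range maximal absolute offset (default 50).
#' @return data.frame: offset, n_valid (sites evaluable at that offset),
#'   n_match, fraction.
#' @export
positional_profile <- function(pentamer, sites, genome, genes,
                               offset_range = 50) {
  if (nchar(pentamer) != 5) stop("pentamer must have length 5")
  pat <- Biostrings::DNAString(rna_to_dna(pentamer))
  k <- 5L
  offs <- seq.int(-offset_range, offset_range)
  n_valid <- integer(length(offs))
  n_match <- integer(length(offs))
  gi <- match(sites$gene_id, genes$gene_id)
  gs0 <- GenomicRanges::start(genes)[gi] - 1L
  ge0 <- GenomicRanges::end(genes)[gi] - 1L
  chr <- genome[[1]]
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]; plus <- sites$strand[i] == "+"
    ## transcript offsets available so the full pentamer stays inside the gene
    if (plus) {
      lo <- max(-offset_range, gs0[i] - p)
      hi <- min(offset_range, ge0[i] - p - (k - 1L))
    } else {
      lo <- max(-offset_range, p - ge0[i])
      hi <- min(offset_range, p - gs0[i] - (k - 1L))
    }
    if (hi < lo) next
    valid <- offs >= lo & offs <= hi
    n_valid[valid] <- n_valid[valid] + 1L
    ## genomic span covering offsets lo..hi+4 in transcript orientation
    g_start0 <- if (plus) p + lo else p - hi - (k - 1L)
    g_end0 <- if (plus) p + hi + (k - 1L) else p - lo
    s <- as.character(Biostrings::subseq(chr, g_start0 + 1L, g_end0 + 1L))
    if (!plus) s <- revcomp_chr(s)
    m <- Biostrings::matchPattern(pat, Biostrings::DNAString(s), fixed = FALSE)
    if (length(m)) {
      o <- Biostrings::start(m) - 1L + lo
      idx <- match(o, offs)
      n_match[idx] <- n_match[idx] + 1L
    }
  }
  data.frame(offset = offs, n_valid = n_valid, n_match = n_match,
             fraction = ifelse(n_valid > 0, n_match / n_valid, 0))
}

#' Per-gene motif track with crosslink overlay
#'
#' Scans a gene's transcript-orientation sequence for a (possibly
#' degenerate) motif and emits aligned per-position vectors suitable for
#' genome-browser-style plotting: a motif-start indicator and the CPM
#' crosslink signal at each position.
#'
#' @param gene_id gene to scan.
#' @param genome `DNAStringSet`.
#' @param genes gene spans `GRanges` with `gene_id`.
#' @param motif degenerate RNA motif (default `"GANGA"`).
#' @param track optional CPM-normalised [crosslink_track()] providing the
#'   overlay (zero where absent).
#' @return data.frame: position (transcript-orientation offset from the
#'   gene's 5' end, 0-based), genomic_pos (0-based), motif_start (logical),
#'   cpm.
#' @export
motif_track <- function(gene_id, genome, genes, motif = "GANGA",
                        track = NULL) {
  gi <- match(gene_id, genes$gene_id)
  if (is.na(gi)) stop("unknown gene: ", gene_id)
  gs0 <- GenomicRanges::start(genes)[gi] - 1L
  ge0 <- GenomicRanges::end(genes)[gi] - 1L
  strand <- as.character(GenomicRanges::strand(genes))[gi]
  L <- ge0 - gs0 + 1L
  s <- as.character(Biostrings::subseq(genome[[1]], gs0 + 1L, ge0 + 1L))
  if (strand == "-") s <- revcomp_chr(s)
  m <- Biostrings::matchPattern(Biostrings::DNAString(rna_to_dna(motif)),
                                Biostrings::DNAString(s), fixed = FALSE)
  ind <- rep(FALSE, L)
  ind[Biostrings::start(m)] <- TRUE
  genomic <- if (strand == "+") gs0:ge0 else ge0:gs0
  cpm <- numeric(L)
  if (!is.null(track)) {
    tc <- track$counts
    sel <- tc$ref == as.character(GenomicRanges::seqnames(genes))[gi] &
      tc$strand == strand & tc$pos >= gs0 & tc$pos <= ge0
    if (any(sel)) {
      if (is.null(tc$cpm)) stop("track must be CPM-normalised (see cpm_normalize)")
      cpm[match(tc$pos[sel], genomic)] <- tc$cpm[sel]
    }
  }
  data.frame(position = seq_len(L) - 1L, genomic_pos = genomic,
             motif_start = ind, cpm = cpm)
}
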