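#' Library layout for demultiplexing
#'
#' Describes how each raw read is organised: a 5' experimental barcode,
#' followed by a UMI, followed by the cDNA insert, with an optional 3'
#' adaptor that is trimmed when found. Barcodes must remain mutually
#' distinguishable at the allowed mismatch level (pairwise Hamming distance
#' > 2 * `max_barcode_mismatches`).
#'
#' @param barcode_map named character vector: barcode sequence -> sample.
#' @param umi_length UMI length in nt.
#' @param max_barcode_mismatches mismatches tolerated in barcode matching.
#' @param three_prime_adaptor 3' adaptor; `""` disables trimming.
#' @return list of class `library_layout`.
#' @export
library_layout <- function(barcode_map, umi_length,
                           max_barcode_mismatches = 0,
                           three_prime_adaptor = "") {
  stopifnot(length(barcode_map) >= 1, umi_length >= 1,
            max_barcode_mismatches >= 0)
  bcs <- names(barcode_map)
  if (is.null(bcs) || any(bcs == "")) stop("barcode_map must be named by barcode sequence")
  if (length(unique(nchar(bcs))) != 1L) stop("barcodes must have equal length")
  if (anyDuplicated(bcs)) stop("duplicate barcodes in barcode_map")
  if (length(bcs) > 1) {
    for (i in seq_along(bcs)[-1]) {
      d <- hamming(bcs[seq_len(i - 1L)], bcs[i])
      if (any(d <= 2 * max_barcode_mismatches)) {
        stop("ambiguous barcode table: barcodes not distinguishable at ",
             max_barcode_mismatches, " mismatches")
      }
    }
  }
  structure(list(barcode_map = barcode_map,
                 barcode_length = nchar(bcs[1]),
                 umi_length = umi_length,
                 max_barcode_mismatches = max_barcode_mismatches,
                 three_prime_adaptor = three_prime_adaptor),
            class = "library_layout")
}

#' Layout of a simulated library
#'
#' Convenience constructor building the [library_layout()] matching a
#' [clip_sim_config()] (inverting its sample -> barcode map).
#'
#' @param config a `clip_sim_config`.
#' @param ... passed to [library_layout()].
#' @return a `library_layout`.
#' @export
layout_from_config <- function(config, ...) {
  stopifnot(inherits(config, "clip_sim_config"))
  library_layout(setNames(names(config$barcode_map),
                          unname(config$barcode_map)),
                 umi_length = config$umi_length,
                 three_prime_adaptor = config$three_prime_adaptor, ...)
}

#' Demultiplex reads by experimental barcode
#'
#' Assigns each read to at most one sample by its 5' barcode, strips the
#' barcode and UMI from the stored insert (the UMI is retained as metadata),
#' and trims the 3' adaptor from the insert when present. Reads whose
#' barcode matches no sample at the allowed mismatch level go to the
#' unassigned bin.
#'
#' @param reads named `DNAStringSet` (or character vector) of raw reads, or
#'   the path to a FASTQ file.
#' @param layout a [library_layout()].
#' @param min_insert_length inserts shorter than this after trimming are
#'   discarded (reported in the summary).
#' @return list with `assignments` (data.frame: read_id, sample, umi,
#'   insert), `unassigned` (count), `too_short` (count), and `summary`
#'   (per-sample read counts).
#' @export
demultiplex <- function(reads, layout, min_insert_length = 18) {
  stopifnot(inherits(layout, "library_layout"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    names(reads) <- sub("\\s.*$", "", names(reads))
  }
  seqs <- as.character(reads)
  ids <- names(reads) %||% sprintf("read%07d", seq_along(seqs))

  bl <- layout$barcode_length
  bc <- substr(seqs, 1L, bl)
  bcs <- names(layout$barcode_map)
  if (layout$max_barcode_mismatches == 0) {
    sample <- unname(layout$barcode_map[bc])
  } else {
    dmat <- vapply(bcs, function(b) hamming(bc, b), numeric(length(bc)))
    if (length(bc) == 1L) dmat <- matrix(dmat, nrow = 1L)
    best <- apply(dmat, 1L, which.min)
    ok <- dmat[cbind(seq_along(bc), best)] <= layout$max_barcode_mismatches
    sample <- ifelse(ok, unname(layout$barcode_map[bcs[best]]), NA_character_)
  }
  assigned <- !is.na(sample)

  umi <- substr(seqs, bl + 1L, bl + layout$umi_length)
  insert <- substr(seqs, bl + layout$umi_length + 1L, nchar(seqs))
  if (nzchar(layout$three_prime_adaptor)) {
    hit <- regexpr(layout$three_prime_adaptor, insert, fixed = TRUE)
    trim <- hit > 0L
    insert[trim] <- substr(insert[trim], 1L, hit[trim] - 1L)
  }
  long_enough <- nchar(insert) >= min_insert_length
  keep <- assigned & long_enough

  assignments <- data.frame(read_id = ids[keep], sample = sample[keep],
                            umi = umi[keep], insert = insert[keep],
                            stringsAsFactors = FALSE)
  list(assignments = assignments,
       unassigned = sum(!assigned),
       too_short = sum(assigned & !long_enough),
       summary = as.data.frame(table(sample = assignments$sample),
                               responseName = "reads"))
}

#' Read aligned reads from a BED6 file
#'
#' BED6 truth/alignment input: 0-based half-open intervals, `name` = read
#' id. Sample and UMI come from a demultiplexing result joined by read id.
#'
#' @param path BED6 file.
#' @return data.frame with read_id, ref, start, end, strand.
#' @export
read_alignments_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("expected BED6 input")
  data.frame(read_id = bed[[4]], ref = bed[[1]], start = bed[[2]],
             end = bed[[3]], strand = bed[[6]], stringsAsFactors = FALSE)
}

#' Attach demultiplexing metadata to alignments
#'
#' Joins per-read sample and UMI assignments onto an alignment table by
#' read id; reads absent from either side are dropped (unaligned or
#' unassigned).
#'
#' @param alignments data.frame with read_id, ref, start, end, strand
#'   (0-based half-open), e.g. from [read_alignments_bed()].
#' @param demux result of [demultiplex()] (or its `assignments` element).
#' @return data.frame of aligned reads with `sample` and `umi` columns.
#' @export
join_alignments <- function(alignments, demux) {
  d <- if (is.data.frame(demux)) demux else demux$assignments
  m <- match(alignments$read_id, d$read_id)
  keep <- !is.na(m)
  out <- alignments[keep, , drop = FALSE]
  out$sample <- d$sample[m[keep]]
  out$umi <- d$umi[m[keep]]
  rownames(out) <- NULL
  out
}

#' Collapse PCR duplicates by UMI
#'
#' Keeps exactly one representative per (reference, start, strand, UMI)
#' group (per sample when a `sample` column is present). Exact UMI matching
#' only; the operation is idempotent. Reads with a missing or empty UMI are
#' rejected and counted.
#'
#' @param reads data.frame of aligned reads with columns ref, start, end,
#'   strand, umi (and optionally sample).
#' @return list with `unique_cdnas` (one row per group, with `dup_count`)
#'   and `rejected` (reads without a UMI).
#' @export
collapse_duplicates <- function(reads) {
  has_umi <- !is.na(reads$umi) & nzchar(reads$umi)
  rejected <- sum(!has_umi)
  r <- reads[has_umi, , drop = FALSE]
  key_cols <- intersect(c("sample", "ref", "start", "strand", "umi"), names(r))
  key <- do.call(paste, c(r[key_cols], sep = "\r"))
  first <- !duplicated(key)
  out <- r[first, , drop = FALSE]
  out$dup_count <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  list(unique_cdnas = out, rejected = rejected)
}

#' Assign crosslink sites to aligned reads
#'
#' Truncation model: the crosslinked nucleotide is the one immediately 5'
#' of the read's 5' end in transcript orientation. For a plus-strand read
#' covering \[start, end) (0-based half-open) the event is at `start - 1`;
#' for a minus-strand read it is at `end`. Reads whose event would fall
#' outside the reference are dropped and counted.
#'
#' @param reads data.frame of (deduplicated) aligned reads: ref, start, end,
#'   strand, plus any metadata columns to carry through.
#' @param ref_lengths named integer vector of reference lengths (nt); used
#'   to drop minus-strand reads ending at the reference end.
#' @return list with `events` (data.frame: ref, pos \[0-based\], strand,
#'   plus carried metadata) and `dropped` (boundary drop count).
#' @export
assign_crosslink_sites <- function(reads, ref_lengths) {
  plus <- reads$strand == "+"
  pos <- as.integer(ifelse(plus, reads$start - 1L, reads$end))
  lim <- unname(ref_lengths[reads$ref])
  if (any(is.na(lim))) stop("read on unknown reference")
  ok <- pos >= 0L & pos < lim
  keep <- reads[ok, setdiff(names(reads), c("start", "end")), drop = FALSE]
  keep$pos <- pos[ok]
  cols <- c("ref", "pos", "strand",
            setdiff(names(keep), c("ref", "pos", "strand")))
  events <- keep[, cols, drop = FALSE]
  rownames(events) <- NULL
  list(events = events, dropped = sum(!ok))
}

#' Extract crosslink events from a simulated library
#'
#' Convenience wrapper running the full read-processing chain
#' (demultiplex, join to truth alignments, UMI collapse, crosslink
#' assignment) on a [simulate_clip_library()] result.
#'
#' @param lib a `clip_library`.
#' @param tx the `transcriptome` it was simulated on.
#' @param layout optional `library_layout`; defaults to the single-sample
#'   layout of the library.
#' @return the `events` data.frame (ref, pos, strand, sample, umi,
#'   dup_count).
#' @export
extract_events <- function(lib, tx, layout = NULL) {
  stopifnot(inherits(lib, "clip_library"))
  if (is.null(layout)) {
    layout <- library_layout(setNames(lib$sample_kind, lib$barcode),
                             umi_length = lib$umi_length,
                             three_prime_adaptor = lib$three_prime_adaptor)
  }
  dm <- demultiplex(lib$reads, layout)
  al <- join_alignments(lib$alignments, dm)
  uc <- collapse_duplicates(al)
  ref_lengths <- setNames(Biostrings::width(tx$genome), names(tx$genome))
  assign_crosslink_sites(uc$unique_cdnas, ref_lengths)$events
}

#' Write crosslink events as BED6
#'
#' One line per event (0-based half-open single-nucleotide interval),
#' name = sample, score = 1.
#'
#' @param events events data.frame (ref, pos, strand, sample).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_events_bed <- function(events, path) {
  utils::write.table(
    data.frame(events$ref, events$pos, events$pos + 1L,
               events$sample %||% ".", 1L, events$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read crosslink events from BED6
#'
#' @param path BED6 file written by [write_events_bed()] (name column =
#'   sample).
#' @return events data.frame (ref, pos, strand, sample).
#' @export
read_events_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(ref = bed[[1]], pos = bed[[2]], strand = bed[[6]],
             sample = bed[[4]], stringsAsFactors = FALSE)
}
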