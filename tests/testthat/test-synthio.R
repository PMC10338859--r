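test_that("planted motifs are recorded and spell the motif on the gene strand", {
  tx <- fix_tx()
  expect_gt(length(tx$motifs), 0)
  seqs <- Biostrings::extractAt(
    tx$genome[[1]],
    IRanges::IRanges(GenomicRanges::start(tx$motifs),
                     GenomicRanges::end(tx$motifs)))
  seqs <- as.character(seqs)
  minus <- as.character(GenomicRanges::strand(tx$motifs)) == "-"
  seqs[minus] <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[minus])))
  expect_true(all(seqs == "GAAGA"))
  ## density ~2/kb: Poisson count over total gene length
  kb <- sum(IRanges::width(tx$genes)) / 1000
  expect_gt(length(tx$motifs), stats::qpois(0.0005, 2 * kb))
  expect_lt(length(tx$motifs), stats::qpois(0.9995, 2 * kb))
})

test_that("motif density zero plants nothing and bad motifs are rejected", {
  tx <- build_transcriptome(transcriptome_spec(
    n_genes = 1, gene_length_range = c(1000, 1000), motif_density = 0, seed = 3))
  expect_equal(length(tx$motifs), 0)
  expect_error(transcriptome_spec(motif = "GATGA"), "A, C, G, U")
})

test_that("gene sequence GC content tracks the requested value", {
  tx <- build_transcriptome(transcriptome_spec(
    n_genes = 4, gene_length_range = c(3000, 3000), gc_content = 0.35,
    motif_density = 0, seed = 9))
  freq <- Biostrings::letterFrequency(tx$genome, "GC", as.prob = TRUE)
  expect_equal(unname(freq[1, 1]), 0.35, tolerance = 0.03)
})

test_that("the same spec and seed give byte-identical outputs", {
  spec <- transcriptome_spec(n_genes = 3, gene_length_range = c(1000, 2000),
                             seed = 11)
  tx1 <- build_transcriptome(spec)
  tx2 <- build_transcriptome(spec)
  expect_identical(as.character(tx1$genome), as.character(tx2$genome))
  expect_identical(tx1$genes, tx2$genes)
  expect_identical(tx1$motifs, tx2$motifs)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_transcriptome(tx1, d1)
  write_transcriptome(tx2, d2)
  expect_identical(readLines(file.path(d1, "genome.fa")),
                   readLines(file.path(d2, "genome.fa")))
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))

  cfg <- clip_sim_config(n_events = 500, seed = 5)
  l1 <- simulate_clip_library(tx1, cfg, "PR-crosslinked")
  l2 <- simulate_clip_library(tx2, cfg, "PR-crosslinked")
  expect_identical(as.character(l1$reads), as.character(l2$reads))
  expect_identical(l1$truth$events, l2$truth$events)
})

test_that("annotation round-trips through GFF3", {
  tx <- fix_tx()
  d <- withr::local_tempdir()
  write_transcriptome(tx, d)
  ann <- read_gene_annotation(file.path(d, "genes.gff3"))
  expect_equal(ann$genes$gene_id, tx$genes$gene_id)
  expect_equal(GenomicRanges::start(ann$genes), GenomicRanges::start(tx$genes))
  expect_equal(as.character(GenomicRanges::strand(ann$genes)),
               as.character(GenomicRanges::strand(tx$genes)))
  expect_setequal(unique(ann$features$type), unique(tx$features$type))
})

test_that("with no motif boost, event positions are uniform over gene positions", {
  tx <- fix_tx()
  cfg <- clip_sim_config(n_events = 10000, motif_boost = 1, seed = 7)
  lib <- simulate_clip_library(tx, cfg, "PR-crosslinked")
  ## map events onto the concatenated gene-position universe, bin, and GOF-test
  gs <- GenomicRanges::start(tx$genes) - 1L
  ge <- GenomicRanges::end(tx$genes) - 1L
  offsets <- cumsum(c(0, head(ge - gs + 1L, -1)))
  gi <- match(lib$truth$events$gene_id, tx$genes$gene_id)
  u <- offsets[gi] + (lib$truth$events$pos - gs[gi]) + 1L
  M <- sum(ge - gs + 1L)
  bins <- cut(u, breaks = round(seq(0, M, length.out = 51)))
  gof <- suppressWarnings(stats::chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)
})

test_that("motif boost concentrates events near planted motifs as expected", {
  tx <- fix_tx()
  boost <- 50
  cfg <- clip_sim_config(n_events = 50000, motif_boost = boost, seed = 8)
  lib <- simulate_clip_library(tx, cfg, "PR-crosslinked")
  ## analytic expectation: boosted positions are the 6 nt 5' of each motif
  ## start (transcript orientation), weight `boost`, everything else 1
  ms <- GenomicRanges::start(tx$motifs); me <- GenomicRanges::end(tx$motifs)
  mstr <- as.character(GenomicRanges::strand(tx$motifs))
  prox <- unique(unlist(lapply(seq_along(ms), function(i) {
    if (mstr[i] == "+") (ms[i] - 5):ms[i] else me[i]:(me[i] + 5)
  })))
  gene_pos <- unlist(mapply(seq.int, GenomicRanges::start(tx$genes),
                            GenomicRanges::end(tx$genes), SIMPLIFY = FALSE))
  m <- sum(gene_pos %in% prox)
  L <- length(gene_pos)
  p_expect <- boost * m / (boost * m + (L - m))
  obs <- mean((lib$truth$events$pos + 1L) %in% prox)
  expect_equal(obs, p_expect, tolerance = 4 * sqrt(p_expect * (1 - p_expect) /
                                                     cfg$n_events) / p_expect)
})

test_that("PCR duplication conserves reads and keeps (position, UMI) pairs unique", {
  tx <- fix_tx()
  cfg <- clip_sim_config(n_events = 5000, pcr_duplication_mean = 3, seed = 21)
  lib <- simulate_clip_library(tx, cfg, "PR-crosslinked")
  ev <- lib$truth$events
  expect_equal(length(lib$reads), sum(ev$dup_count))
  expect_equal(nrow(lib$truth$reads), length(lib$reads))
  expect_equal(length(lib$reads) / nrow(ev), 3, tolerance = 0.1)
  expect_equal(anyDuplicated(paste(ev$pos, ev$strand, ev$umi)), 0L)
  expect_equal(nrow(ev), cfg$n_events)
})

test_that("reads follow the truncation model: insert starts 1 nt 3' of the crosslink", {
  tx <- fix_tx()
  cfg <- clip_sim_config(n_events = 50, seed = 13)
  lib <- simulate_clip_library(tx, cfg, "PR-crosslinked")
  chr <- tx$genome[[1]]
  rd <- lib$truth$reads[!duplicated(lib$truth$reads$event_id), ]
  ev <- lib$truth$events[match(rd$event_id, lib$truth$events$event_id), ]
  bc <- lib$barcode
  il <- cfg$read_length - nchar(bc) - cfg$umi_length
  for (i in seq_len(nrow(rd))) {
    read <- as.character(lib$reads[[match(rd$read_id[i], names(lib$reads))]])
    expect_equal(substr(read, 1, nchar(bc)), bc)
    expect_equal(substr(read, nchar(bc) + 1, nchar(bc) + cfg$umi_length),
                 ev$umi[i])
    insert <- substr(read, nchar(bc) + cfg$umi_length + 1, nchar(read))
    p0 <- ev$pos[i]
    want <- if (ev$strand[i] == "+") {
      as.character(Biostrings::subseq(chr, p0 + 2, width = il))
    } else {
      as.character(Biostrings::reverseComplement(
        Biostrings::subseq(chr, p0 - il + 1, width = il)))
    }
    expect_equal(insert, want)
  }
})

test_that("controls are shallower and unbiased; read_length is bounded by genes", {
  tx <- fix_tx()
  cfg <- clip_sim_config(n_events = 2000, control_rate_fraction = 0.05,
                         seed = 2)
  ctl <- simulate_clip_library(tx, cfg, "FLAG-crosslinked")
  expect_equal(ctl$truth$n_events, 100)
  expect_error(
    simulate_clip_library(tx, clip_sim_config(read_length = 5000, seed = 1)),
    "shortest gene")
})

test_that("the association model obeys its closed forms", {
  ka <- 1e6; koff <- 0.01; kd <- koff / ka; rmax <- 2
  ## C = Kd, long time: response converges to Rmax / 2
  tr <- simulate_bli_dataset(ka, koff, rmax, concentrations = kd,
                             times = c(0, 10^(2:6)), noise_sd = 0,
                             replicates = 1, seed = 1)
  expect_equal(tail(tr$response, 1), rmax / 2, tolerance = 1e-9)
  ## C = 0: flat zero trace
  tr0 <- simulate_bli_dataset(ka, koff, rmax, concentrations = 0,
                              times = seq(0, 100, 10), noise_sd = 0,
                              replicates = 1, seed = 1)
  expect_true(all(tr0$response == 0))
  ## half-time: R(t1/2) = Req / 2 at t1/2 = ln 2 / kobs
  C <- 5e-9
  kobs <- ka * C + koff
  th <- log(2) / kobs
  trh <- simulate_bli_dataset(ka, koff, rmax, concentrations = C,
                              times = c(0, th), noise_sd = 0,
                              replicates = 1, seed = 1)
  req <- rmax * C / (C + kd)
  expect_equal(trh$response[2], req / 2, tolerance = 1e-12)
  expect_error(simulate_bli_dataset(ka, koff, rmax, concentrations = numeric(0),
                                    times = 0:10), "empty concentration")
})
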