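# A deterministic toy genome for window-arithmetic checks: one plus-strand
# gene and one minus-strand gene on a 400-nt chromosome.
window_fixture <- function() {
  set.seed(2024)
  chrom <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(51, 251),
                                                           c(200, 390)),
                                  strand = c("+", "-"),
                                  gene_id = c("gP", "gM"))
  list(genome = genome, genes = genes, chrom = chrom)
}

test_that("foreground windows span -5..+30 in transcript orientation", {
  fx <- window_fixture()
  sites <- data.frame(ref = "chr1", pos = c(100L, 300L), strand = c("+", "-"),
                      gene_id = c("gP", "gM"))
  ws <- extract_windows(sites, fx$genome, fx$genes)
  expect_equal(ws$dropped, 0)
  expect_equal(nchar(ws$windows), c(36L, 36L))
  ## plus strand site at 0-based 100: genomic [95, 131) read forward
  want_p <- chartr("T", "U", substr(fx$chrom, 96, 131))
  expect_equal(ws$windows[1], want_p)
  ## minus strand site at 300: genomic [270, 306) reverse-complemented
  want_m <- chartr("T", "U", as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(fx$chrom, 271, 306)))))
  expect_equal(ws$windows[2], want_m)
  ## a site 2 nt from its gene's 5' end is dropped and counted
  near <- data.frame(ref = "chr1", pos = 52L, strand = "+", gene_id = "gP")
  ws2 <- extract_windows(near, fx$genome, fx$genes)
  expect_equal(length(ws2$windows), 0)
  expect_equal(ws2$dropped, 1)
})

test_that("background windows avoid significant sites and match gene multiplicity", {
  fx <- window_fixture()
  sites <- data.frame(ref = "chr1", pos = c(100L, 120L, 300L),
                      strand = c("+", "+", "-"),
                      gene_id = c("gP", "gP", "gM"))
  fg <- extract_windows(sites, fx$genome, fx$genes)
  bg1 <- sample_background_windows(fg, sites, fx$genome, fx$genes, seed = 6)
  bg2 <- sample_background_windows(fg, sites, fx$genome, fx$genes, seed = 6)
  expect_identical(bg1$windows, bg2$windows)
  expect_equal(length(bg1$windows), length(fg$windows))
  expect_equal(table(bg1$gene_id), table(fg$gene_id))
  ## no background window may contain a site: verify against eligibility
  ## by reconstructing anchors from the genome (plus-strand gene only)
  gP_bg <- bg1$windows[bg1$gene_id == "gP"]
  expect_true(all(nchar(gP_bg) == 36))

  ## a gene fully tiled by sites contributes nothing and warns
  tiny_genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 120),
                                       strand = "+", gene_id = "gT")
  tiny_sites <- data.frame(ref = "chr1", pos = seq(55L, 115L, by = 5L),
                           strand = "+", gene_id = "gT")
  fg_t <- make_window_set(windows_without(3, "GGGGG", seed = 1),
                          gene_id = "gT")
  expect_warning(
    bg_t <- sample_background_windows(fg_t, tiny_sites, fx$genome, tiny_genes,
                                      seed = 2),
    "no eligible background position")
  expect_equal(length(bg_t$windows), 0)
})

test_that("log-space hypergeometric tail matches exhaustive enumeration (margins <= 30)", {
  worst <- 0
  for (nf in c(1:10, 15, 20, 25, 30)) {
    for (nb in c(1:10, 15, 20, 25, 30)) {
      N <- nf + nb
      for (K in 0:N) {
        ks <- max(0, K - nb):min(K, nf)
        got <- vapply(ks, function(k) exp(log_hyper_tail(k, K, nf, N)),
                      numeric(1))
        want <- vapply(ks, function(k) oracle_hyper_tail(k, K, nf, N),
                       numeric(1))
        worst <- max(worst, abs(got - want) / pmax(want, .Machine$double.xmin))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("the tail agrees with stats machinery and swaps to the complementary tail", {
  ## independent cross-checks on ordinary-sized tables
  cases <- list(c(8, 10, 10, 20), c(3, 12, 30, 60), c(25, 40, 50, 100))
  for (cs in cases) {
    k <- cs[1]; K <- cs[2]; n <- cs[3]; N <- cs[4]
    lp <- log_hyper_tail(k, K, n, N)
    expect_equal(lp, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                                   log.p = TRUE), tolerance = 1e-12)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    expect_equal(exp(lp),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    ## swapping foreground and background gives the complementary tail
    lp_swap <- log_hyper_tail(K - k, K, N - n, N)
    expect_equal(exp(lp_swap), 1 - exp(log_hyper_tail(k + 1, K, n, N)),
                 tolerance = 1e-12)
  }
})

test_that("pentamer enrichment reproduces exact worked examples", {
  ## 100 foreground windows all containing GAAGA vs 100 background without:
  ## p is the hypergeometric point mass 1/choose(200,100)
  fg <- make_window_set(paste0(strrep("C", 10), "GAAGA",
                               windows_without(100, "GAAGA", seed = 3)) |>
                          substr(1, 36))
  bg <- make_window_set(windows_without(100, "GAAGA", seed = 4),
                        origin = "background")
  res <- pentamer_enrichment(fg, bg)
  expect_equal(res$pentamer[1], "GAAGA")
  expect_equal(res$rank[1], 1L)
  gaaga <- res[res$pentamer == "GAAGA", ]
  expect_equal(gaaga$fg_with, 100L)
  expect_equal(gaaga$bg_with, 0L)
  expect_equal(gaaga$log10_p, -lchoose(200, 100) / log(10), tolerance = 1e-12)

  ## identical sets: the one-sided p is never below 1/2
  res_null <- pentamer_enrichment(fg, make_window_set(fg$windows,
                                                      origin = "background"))
  expect_gte(min(res_null$p), 0.5)
})

test_that("a (8,2,2,8) presence table gets the brute-force one-sided p", {
  with_fg <- 8L; n_fg <- 10L; with_bg <- 2L; n_bg <- 10L
  base <- windows_without(20, "GAAGA", seed = 5)
  add <- function(w) paste0("GAAGA", substr(w, 6, 36))
  fg <- make_window_set(c(vapply(base[1:8], add, ""), base[9:10]))
  bg <- make_window_set(c(vapply(base[11:12], add, ""), base[13:20]),
                        origin = "background")
  res <- pentamer_enrichment(fg, bg)
  gaaga <- res[res$pentamer == "GAAGA", ]
  expect_equal(gaaga$fg_with, 8L)
  expect_equal(gaaga$bg_with, 2L)
  want <- sum(vapply(8:10, function(j)
    choose(10, j) * choose(10, 10 - j) / choose(20, 10), numeric(1)))
  expect_equal(gaaga$p, want, tolerance = 1e-12)
  ## Bonferroni over 1,024 pentamers
  expect_equal(gaaga$p_corrected, min(1, 1024 * want), tolerance = 1e-12)
})

test_that("p-value labels survive underflow", {
  expect_equal(format_log10p(-930 + log10(3.1)), "3.1e-930")
  expect_equal(format_log10p(log10(0.05)), "5e-2")
  expect_equal(format_log10p(0), "1")
})

test_that("positional profiles localise planted and degenerate motifs", {
  set.seed(15)
  chrom_parts <- vapply(1:30, function(i) {
    w <- windows_without(1, c("GAAGA", "GGGGG"), seed = 200 + i)
    w <- chartr("U", "T", w)
    paste0(strrep("C", 60), substr(w, 1, 1), "GAAGA",
           substr(w, 7, 36), strrep("C", 54))
  }, character(1))
  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- "chr1"
  glen <- nchar(chrom_parts[1])
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges((0:29) * glen + 1, (1:30) * glen),
    strand = "+", gene_id = sprintf("pg%02d", 1:30))
  ## sites at the base just before each planted GAAGA (offset +1 = motif start)
  sites <- data.frame(ref = "chr1", pos = (0:29) * glen + 60L, strand = "+",
                      gene_id = sprintf("pg%02d", 1:30))
  prof <- positional_profile("GAAGA", sites, genome, genes)
  expect_equal(prof$fraction[prof$offset == 1], 1.0)
  expect_lt(mean(prof$fraction[prof$offset != 1]), 0.05)
  ## a pentamer absent everywhere gives an all-zero profile
  prof0 <- positional_profile("GGGGG", sites, genome, genes)
  expect_true(all(prof0$fraction[prof0$n_valid > 0] == 0))
  ## the degenerate GANGA profile matches GAAGA here (GA[ACGU]GA superset)
  profN <- positional_profile("GANGA", sites, genome, genes)
  expect_equal(profN$fraction[profN$offset == 1], 1.0)
})

test_that("motif tracks flag degenerate motif starts and conserve CPM mass", {
  unit <- "GAGAA"
  chrom <- paste0(strrep("T", 50), strrep(unit, 20), strrep("T", 50))
  genome <- Biostrings::DNAStringSet(chrom)
  names(genome) <- "chr1"
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 150),
                                  strand = "+", gene_id = "gR")
  tr <- motif_track("gR", genome, genes, motif = "GANGA")
  ## (GAGAA)n: GA?GA matches at period-5 positions 2, 7, 12, ... (GAGAA
  ## shifted by 1 spells AGAAG...; GANGA hits start at offsets 1 mod 5 too)
  starts <- which(tr$motif_start) - 1L
  expect_true(all(diff(starts) == 5))
  expect_gt(length(starts), 15)
  ## no-G gene: empty indicator
  genes2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50),
                                   strand = "+", gene_id = "gT")
  expect_false(any(motif_track("gT", genome, genes2)$motif_start))
  ## overlay conserves the gene's CPM mass
  ev <- data.frame(ref = "chr1", pos = c(60L, 60L, 70L, 99L), strand = "+")
  track <- cpm_normalize(crosslink_track(ev))
  tr2 <- motif_track("gR", genome, genes, track = track)
  expect_equal(sum(tr2$cpm), sum(track$counts$cpm))
})
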