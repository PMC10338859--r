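# Shared fixtures and independent oracles, built once per test run.

.fix <- new.env(parent = emptyenv())

## Small transcriptome reused across modules.
fix_tx <- function() {
  if (is.null(.fix$tx)) {
    .fix$tx <- build_transcriptome(transcriptome_spec(
      n_genes = 5, gene_length_range = c(2000, 3000), gc_content = 0.5,
      motif = "GAAGA", motif_density = 2, seed = 42))
  }
  .fix$tx
}

## Independent hypergeometric upper-tail oracle: direct sum of binomial
## coefficients in plain double arithmetic (valid for small margins).
oracle_hyper_tail <- function(k, K, n, N) {
  jmax <- min(K, n)
  if (k > jmax) return(0)
  j <- max(k, max(0, n - (N - K))):jmax
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

## Independent permutation-FDR oracle for one gene: same estimand as the
## package, re-implemented plainly with its own permutation loop.
oracle_perm_fdr <- function(pos_rel, L, w, n_perm, seed) {
  set.seed(seed)
  score_at <- function(cnt, p) sum(cnt[max(1, p - w):min(L, p + w)])
  cnt <- tabulate(pos_rel + 1, nbins = L)
  obs_pos <- which(cnt > 0)
  obs_sc <- vapply(obs_pos, function(p) score_at(cnt, p), numeric(1))
  perm_counts <- matrix(0, n_perm, length(obs_pos))
  for (b in seq_len(n_perm)) {
    pc <- tabulate(sample.int(L, length(pos_rel), replace = TRUE), nbins = L)
    ps <- vapply(which(pc > 0), function(p) score_at(pc, p), numeric(1))
    perm_counts[b, ] <- vapply(obs_sc, function(s) sum(ps >= s), numeric(1))
  }
  fdr <- pmin(1, colMeans(perm_counts) /
                vapply(obs_sc, function(s) sum(obs_sc >= s), numeric(1)))
  ## monotone non-increasing in score
  ord <- order(obs_sc)
  fdr[ord] <- cummin(fdr[ord])
  data.frame(pos_rel = obs_pos - 1, score = obs_sc, fdr = fdr)
}

## Construct a motif_window_set directly from character windows.
make_window_set <- function(windows, gene_id = "geneX",
                            origin = "foreground") {
  structure(list(windows = windows,
                 gene_id = rep(gene_id, length.out = length(windows)),
                 origin = origin, dropped = 0L, up = 5, down = 30),
            class = "motif_window_set")
}

## Random RNA windows of width 36 avoiding the given pentamer(s).
windows_without <- function(n, pentamers, seed) {
  set.seed(seed)
  out <- character(n)
  i <- 1L
  while (i <= n) {
    w <- paste(sample(c("A", "C", "G", "U"), 36, replace = TRUE), collapse = "")
    if (!any(vapply(pentamers, grepl, logical(1), x = w, fixed = TRUE))) {
      out[i] <- w
      i <- i + 1L
    }
  }
  out
}
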