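# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats rnorm runif rpois setNames
#' @importFrom utils head tail
NULL

## Random DNA of given length and GC content (base probabilities
## G = C = gc/2, A = T = (1-gc)/2).
random_dna <- function(n, gc = 0.5) {
  stopifnot(gc >= 0, gc <= 1)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## log(sum(exp(x))) without overflow; returns -Inf for empty input.
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Running window sum of a counts vector: out[i] = sum(x[max(1,i-w)..min(L,i+w)]).
window_sum <- function(x, w) {
  L <- length(x)
  cs <- cumsum(c(0, x))
  hi <- pmin(L, seq_len(L) + w)
  lo <- pmax(0L, seq_len(L) - w - 1L)
  cs[hi + 1L] - cs[lo + 1L]
}

## Hamming distance between equal-length strings, vectorised over x.
hamming <- function(x, y) {
  xm <- matrix(unlist(strsplit(x, "")), ncol = length(x))
  ym <- strsplit(y, "")[[1]]
  colSums(xm != ym)
}

## sample() treats a length-1 vector as 1:x; this picker does not.
sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

## All 4^k k-mers over the RNA alphabet, lexicographic.
all_kmers <- function(k = 5, alphabet = c("A", "C", "G", "U")) {
  grid <- expand.grid(rep(list(alphabet), k), stringsAsFactors = FALSE)
  ## column 1 should vary slowest for lexicographic order
  apply(grid[do.call(order, grid), ], 1, paste, collapse = "")
}
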