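#' Published oligonucleotide and peptide reagent sequences
#'
#' The biotinylated RNA oligonucleotides used in the biolayer-interferometry
#' experiments (five tandem repeats of the GAAGA or AUAAU pentamer, 25 nt,
#' biotin tag not included) and the FLAG-tagged 20-mer dipeptide repeat
#' peptides, with the repeat region followed by a GS linker and the FLAG
#' epitope.
#'
#' @return `dpr_oligos()`: named character vector of RNA sequences
#'   (`GAAGA`, `AUAAU`). `dpr_peptides()`: named character vector of amino
#'   acid sequences (`PR20`, `GR20`).
#' @examples
#' tandem_repeat_units(dpr_oligos()[["GAAGA"]])
#' @export
dpr_oligos <- function() {
  c(GAAGA = "GAGAAGAGAAGAGAAGAGAAGAGAA",
    AUAAU = "AUAAUAUAAUAUAAUAUAAUAUAAU")
}

#' @rdname dpr_oligos
#' @export
dpr_peptides <- function() {
  c(PR20 = "PRPRPRPRPRPRPRPRPRPRPRPRPRPRPRPRPRPRPRPRGSFEGDYKDDDDK",
    GR20 = "GRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGRGSFEGDYKDDDDK")
}

#' Decompose a sequence into tandem repeats of its minimal period
#'
#' Finds the smallest period `p` such that the whole string equals its first
#' `p` characters repeated (the final repeat may be truncated when the length
#' is not a multiple of `p`), and reports the repeat unit and the number of
#' complete units.
#'
#' @param x a single character string.
#' @return list with `period`, `unit`, `n_units` (complete units) and
#'   `remainder` (trailing characters beyond the last complete unit).
#' @examples
#' tandem_repeat_units("GAGAAGAGAAGAGAAGAGAAGAGAA")
#' @export
tandem_repeat_units <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nchar(x) >= 1L)
  chars <- strsplit(x, "")[[1]]
  n <- length(chars)
  for (p in seq_len(n)) {
    tiled <- rep(chars[seq_len(p)], length.out = n)
    if (all(tiled == chars)) {
      return(list(period = p,
                  unit = substr(x, 1L, p),
                  n_units = n %/% p,
                  remainder = substr(x, (n %/% p) * p + 1L, n)))
    }
  }
}

#' Count leading dipeptide repeat units in a peptide
#'
#' Counts how many tandem copies of a two-residue unit occur at the start of
#' a peptide sequence, e.g. the number of PR units preceding the linker/tag
#' of a poly(PR) construct.
#'
#' @param peptide amino acid string.
#' @param unit two-residue repeat unit (default `"PR"`).
#' @return integer number of leading units.
#' @examples
#' count_dipeptide_units(dpr_peptides()[["PR20"]], "PR")
#' @export
count_dipeptide_units <- function(peptide, unit = "PR") {
  stopifnot(nchar(unit) == 2L)
  n <- 0L
  while (substr(peptide, 2L * n + 1L, 2L * n + 2L) == unit) n <- n + 1L
  n
}
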