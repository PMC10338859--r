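---
title: "Methods: crosslink-site analysis and binding kinetics in prclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: crosslink-site analysis and binding kinetics in prclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prclip)
```

## The problem

Arginine-rich dipeptide repeat proteins such as poly(PR), translated from the
*C9orf72* hexanucleotide repeat expansion in ALS/FTD, bind RNA in cells.
iCLIP-style experiments map those contacts at nucleotide resolution: UV
crosslinking covalently traps protein–RNA contacts, the protein of interest is
immunopurified, and reverse transcription truncates at the crosslinked
nucleotide, so the genomic position immediately 5′ of a cDNA's start (in
transcript orientation) identifies the contact site. `prclip` implements the
complete downstream analysis — read processing, site calling, gene-level
quantification, motif analysis — together with a steady-state analysis of
biolayer-interferometry (BLI) binding data, and a synthetic-data generator
that reproduces the statistical structure each stage assumes so that every
stage is testable without external data.

## Read processing

Reads are laid out as experimental barcode, then unique molecular identifier
(UMI), then cDNA insert. `demultiplex()` assigns reads to samples by exact
(or bounded-mismatch) barcode match, keeps the UMI as metadata, and trims the
3′ adaptor from the insert when present; a minimum post-trim insert length
(default 18 nt) guards against adaptor-only reads. PCR duplicates are
collapsed by `collapse_duplicates()` with the exact key
(reference, start, strand, UMI) — no error-tolerant UMI merging, since one
substitution in a UMI is indistinguishable from an independent molecule
without a model of sequencing error, and the simulated reads carry none.
`assign_crosslink_sites()` applies the truncation rule: a plus-strand read
covering `[start, end)` (0-based, half-open — the convention used throughout
for events and read spans) yields an event at `start − 1`; a minus-strand
read yields `end`. Reads whose event would fall off the reference are dropped
and counted. Alignment itself is out of scope: the pipeline consumes
alignments (BED6; ground-truth alignments in synthetic mode) rather than
producing them.

## Site calling by permutation FDR

Each event-bearing position in a gene is scored by the number of events in a
±`half_window` (default 3 nt) window. The null distribution redistributes the
gene's *n* events uniformly over its positions `n_perm` (default 100) times.
For an observed position with score *s*,

FDR(*s*) = min(1, mean over permutations of #{permuted event-positions with
score ≥ *s*} / #{observed event-positions with score ≥ *s*}),

evaluated only at observed event positions (sites are by definition crosslink
positions), with tied scores sharing one value. The estimate is made monotone
non-increasing in score by a running minimum taken in ascending score order,
so a higher-scoring position never reports a larger FDR; taking the running
minimum in the opposite direction would let one extreme cluster pull every
weak position's FDR to zero. Sites with FDR < 0.05 are retained. Events
outside annotated genes are tested within fixed-width (10 kb) flanking
pseudo-genes, recorded in the output metadata. The window half-width and
permutation count follow common practice for this family of CLIP site
callers and are exposed in the configuration; calibration on uniform tracks
(the fraction of events called at threshold 0.05 stays at or below 0.05
within Monte-Carlo error) is part of the test suite.

Per-sample depth is controlled by `sample_qc()`: a crosslinked library needs
at least 300,000 unique events for site-level analysis. The bundled synthetic
runs are intentionally far smaller, so the pipeline's QC enforcement is a
`strict`/`warn` switch.

## Gene-level binding and the bound-gene filter

`count_gene_events()` counts events within gene spans, strand-aware, with
half-open span semantics (an event at the first gene nucleotide counts).
Tracks are depth-normalised as counts per million (CPM): value = count ×
10⁶ / total events, so a sample's CPM values sum to 10⁶. A gene is *bound*
when it has ≥ 200 events in the crosslinked sample and its control binding
fraction is < 10%, taking the maximum over the control conditions
(non-crosslinked and tag-only libraries).

The definition of the control fraction is genuinely open, and both readings
are implemented. The default, `control_fraction_basis = "cpm"`, compares each
gene's *share* of its library between control and crosslinked samples; it is
invariant to sequencing depth and is the right reading when control libraries
are real libraries of comparable character. It is, however, blind to depth
asymmetry: a control that is simply a 20-fold-shallower uniform thinning of
the same signal has a CPM ratio near 1 at every gene. The `"count"` basis
compares raw event counts, crediting exactly that asymmetry — which is the
signal the synthetic generator encodes (controls share the transcriptome and
differ only in rate and the absence of motif bias). The synthetic pipeline
therefore runs with the `"count"` basis, and the choice is recorded in the
output metadata either way.

`annotate_regions()` gives each event exactly one class by the precedence
CDS > 5′UTR > 3′UTR > non-coding-RNA exon > intron > intergenic. The order is
a convention (the classes overlap on the genome) and can be overridden;
proportions always sum to 1.

## Pentamer enrichment with a matched background

Foreground sequences are the windows from 5 nt upstream to 30 nt downstream
(36 nt) of each significant site, in transcript orientation, RNA sense;
windows truncated by gene ends are dropped and counted. The background is
sampled uniformly from the same genes with the same per-gene multiplicity,
restricted to positions whose window overlaps no significant site; a gene
with no eligible position is skipped with a warning and its multiplicity
reassigned to the pooled eligible positions.

For each of the 1,024 RNA pentamers the test is discriminative and
presence-based: the 2×2 table counts windows containing at least one
occurrence versus not, in foreground and background (presence is robust to
repeat-heavy windows dominating occurrence counts). The one-sided enrichment
p-value is the hypergeometric tail, computed in log space
(`log_hyper_tail()`) so that values far below double underflow remain exact
as log₁₀ quantities; `format_log10p()` renders them as strings like
`3.1e-930`. Correction is Bonferroni over exactly 1,024 enumerable pentamers
— conservative and exact, with no discovery heuristic needed at this motif
width. Results are ranked by p, ties broken by foreground count then
lexicographically.

`positional_profile()` reports, per offset in ±50 nt around the site, the
fraction of sites with a motif occurrence starting there (IUPAC degenerate
motifs such as GANGA supported; a site contributes to an offset only where
the full pentamer fits inside its gene), and `motif_track()` emits aligned
motif-start/CPM vectors for browser-style per-gene plots.

## BLI equilibrium analysis

Association traces follow the pseudo-first-order 1:1 Langmuir model
R(t) = R_eq(C)(1 − e^(−(k_a C + k_off) t)) with
R_eq(C) = R_max C / (C + K_d) and K_d = k_off / k_a.
`equilibrium_response()` estimates R_eq as the mean over the final 10% of
time points, declaring non-plateau (and falling back to a single-exponential
asymptote) when the tail drifts by more than 1% of R_eq per 10% of trace
duration — a tolerance chosen because instrument noise at the percent level
makes finer drift unresolvable. `fit_equilibrium_kd()` fits the isotherm by
Levenberg–Marquardt nonlinear least squares, initialised at
R_max⁰ = max R_eq and K_d⁰ = the interpolated half-maximal concentration,
with non-negativity bounds. Fits are flagged low-confidence when the ladder
never reaches half-saturation, carries no curvature (fully saturated), or
the K_d standard error exceeds the estimate. Steady-state analysis is the
primary mode because dissociation in these experiments is too slow to record
fully; per-replicate isotherms are fitted and summarised as mean ± SD, and
`compare_affinities()` applies the two-tailed unpaired (equal-variance)
t test, with explicit handling of zero-pooled-variance degeneracies
(p = 1 for identical means; p below the machine floor, flagged, otherwise).
The default concentration ladders are two-fold series spanning 2.1–133.3 nM
(arginine-rich peptides) and 3.1–25 µM (the non-binding control peptide).

## The synthetic-data generator

`build_transcriptome()` emits one chromosome of random sequence (configurable
GC) carrying non-overlapping, strand-assigned gene models with exon/intron
structure and, for coding genes, 5′UTR/CDS/3′UTR features over roughly
10/80/10% of the mature transcript. A chosen pentamer (default GAAGA) is
planted at Poisson density (default 2/kb) at non-overlapping positions, on
the gene strand, all recorded in ground truth.

`simulate_clip_library()` places unique crosslink events on transcribed
positions with per-position rate 1, raised multiplicatively to `motif_boost`
at the six positions 0–5 nt 5′ of each planted motif start — geometry chosen
so a site placed there carries the motif inside its −5/+30 window. With
`motif_boost = 1` placement is exactly uniform, which is the null used for
calibration tests. The expected motif-proximal fraction follows in closed
form from the weights (boost·m / (boost·m + L − m) for m boosted positions
among L); tests assert that expectation rather than a round number. Reads are
truncation-model: barcode + UMI + insert beginning one nucleotide 3′ of the
crosslink, duplicated 1 + Poisson(mean − 1) times; UMIs are drawn without
replacement within each event position so that unique (position, UMI) pairs
equal the number of events by construction and exact ground-truth recovery is
a meaningful test. Control libraries (non-crosslinked, tag-only) share the
transcriptome, draw 5% of the crosslinked depth by default, and have no
motif bias; the GA comparison library draws 10%. These ratios mirror the
relative depths of the corresponding experimental conditions. Default event
counts (20,000 in the bundled fixture; 50,000 in the larger test
configurations) are chosen for fast, deterministic runs at desk scale —
real libraries are 1–2 orders of magnitude deeper, and the depth QC
threshold reflects that scale, hence the `warn` default.

What the generator does *not* emulate bounds what green tests mean for real
data: no sequencing errors or soft-clipping (alignment is consumed, not
performed), no splicing of reads across junctions, no per-gene affinity
differences beyond motif placement, no crosslinking sequence bias other than
the planted motif, and controls that are ideal uniform thinnings rather than
libraries with their own background structure. Exact ground-truth recovery
therefore validates the bookkeeping (demultiplexing, deduplication,
coordinate arithmetic) and the statistics (calibration, enrichment), not
robustness to alignment artefacts.

`simulate_bli_dataset()` generates noiseless 1:1 association traces plus
additive Gaussian noise with standard deviation expressed as a fraction of
R_max, per replicate.

## Numerical choices and degenerate inputs

* Log-space arithmetic throughout the motif module; `logsumexp` guards the
  tail sums.
* Window scores use integer cumulative sums; permutation draws use R's
  default generator under caller-supplied seeds, and every stochastic
  function takes an explicit seed, so identical configurations are
  bit-identical.
* Zero-event genes return empty site lists (not errors); empty tracks refuse
  CPM normalisation; a gene fully tiled by significant sites contributes no
  background windows and warns.
* Ties in site score share one FDR; ties in pentamer p are broken by
  foreground count, then lexicographically, so ranks are a permutation.
* The interpolated half-max initialiser for K_d falls back to the median
  concentration when the isotherm is flat.

## Problem sizes used in the checks

The bundled test and acceptance configurations use 5–20 genes of 2–5 kb,
20,000–50,000 events per crosslinked library, 100 permutations, and 3 BLI
replicates on a 13-point time-by-concentration grid — sizes at which every
documented property is measurable with tight Monte-Carlo error while the
whole suite runs in minutes. The motif-recovery study condition (boost 50,
density 2/kb, 20 genes × 5 kb, 50,000 events, controls at 5%) recovers the
planted pentamer at rank 1 with Bonferroni-corrected p far below 10⁻⁶ in
essentially every seed, and in none when the boost is absent.

## Known limitations

* Replicate-merged or clustered peak calling (paraclu/clippy-style) is not
  implemented; sites are single nucleotides.
* The enrichment test conditions on presence counts; motif widths other than
  5 and variable-length discovery are out of scope.
* Kinetic (k_a, k_off) global fitting is not the primary analysis; only the
  steady-state isotherm is fitted.
* Real-data mode expects BED6 alignments or events plus GFF3 annotation;
  BAM parsing is left to upstream tools.
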