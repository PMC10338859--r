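# prclip

Crosslink-site analysis and RNA-binding kinetics for dipeptide repeat
iCLIP data.

Arginine-rich dipeptide repeat proteins such as poly(PR), products of the
*C9orf72* repeat expansion in ALS/FTD, bind RNA in cells. iCLIP-style
sequencing locates those contacts at nucleotide resolution: reverse
transcription truncates at the UV-crosslinked nucleotide, so the position
immediately 5′ of a cDNA's start is the contact site. `prclip` implements
the full downstream analysis for such experiments, plus the steady-state
analysis of biolayer-interferometry (BLI) binding measurements used to
validate candidate motifs in vitro:

* **Read processing** — demultiplexing by experimental barcode, UMI-based
  PCR-duplicate collapsing (exact key: reference, start, strand, UMI), and
  truncation-model crosslink assignment (plus strand: `start − 1`; minus
  strand: `end`, on 0-based half-open reads).
* **Site calling** — per-gene permutation FDR: each event position is scored
  by events within ±3 nt and compared against `n_perm` uniform
  redistributions of the gene's events;
  FDR(s) = E[#permuted positions ≥ s] / #observed positions ≥ s, monotone in
  score, sites kept at FDR < 0.05.
* **Gene-level binding** — counts-per-million normalisation
  (value = count · 10⁶ / total), library depth QC (≥ 300,000 unique events),
  and the bound-gene filter: ≥ 200 events in the crosslinked sample and
  < 10% control binding fraction (CPM-ratio or raw-count basis), plus
  genomic region annotation (CDS > 5′UTR > 3′UTR > ncRNA > intron >
  intergenic).
* **Motif analysis** — pentamer enrichment in −5/+30 nt windows around
  significant sites against background windows matched per gene and away
  from sites; one-sided Fisher exact test computed as a log-space
  hypergeometric tail (p-values far below double underflow stay exact as
  log₁₀ values), Bonferroni-corrected over the 1,024 pentamers; positional
  profiles (±50 nt, IUPAC motifs like GANGA) and per-gene motif/CPM tracks.
* **BLI kinetics** — equilibrium responses from association traces (plateau
  check with single-exponential fallback), nonlinear least-squares fit of the
  1:1 Langmuir isotherm R_eq(C) = R_max·C/(C + K_d), per-replicate K_d with
  mean ± SD summaries and a two-tailed unpaired t test between ligands.
* **Synthetic data** — a generator producing a toy transcriptome (FASTA +
  GFF3) with planted motifs, CLIP libraries (FASTQ + ground-truth BED/JSON)
  with motif-biased crosslinking, PCR duplication and low-yield controls,
  and simulated BLI traces — so the entire pipeline is testable offline.

## Worked example

```r
library(prclip)
report <- run_pipeline(default_config())  # 5 genes, 20,000 PR events, 2 controls
print(report)
#> prclip pipeline report
#>   samples: PR-crosslinked, PR-noncrosslinked, FLAG-crosslinked
#>   unique events: PR-crosslinked=20000, PR-noncrosslinked=1000, FLAG-crosslinked=1000
#>   significant sites: 291
#>   bound genes: 5 of 5
#>   top pentamer: GAAGA (corrected p 7.5e-158)
```

The run simulates a 5-gene transcriptome with GAAGA planted at 2/kb and a
50-fold crosslink-rate boost beside each motif, pushes the reads through
demultiplexing, deduplication and crosslink assignment (recovering the
20,000 planted events exactly), calls 291 significant sites, finds all 5
genes bound against the two 5%-depth controls, and ranks GAAGA first among
all 1,024 pentamers with a Bonferroni-corrected p of 7.5×10⁻¹⁵⁸ — the
planted motif recovered end to end. (The depth QC warns, by design: the
fixture is far smaller than a real library.)

Fitting binding data works from traces alone:

```r
traces <- simulate_bli_dataset(true_ka = 1e6, true_kd_off = 0.01, rmax = 1,
                               noise_sd = 0.01, replicates = 3, seed = 1)
fit_bli_replicates(traces)   # one Kd per replicate; true Kd = 10 nM
```

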