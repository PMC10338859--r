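#' Default pipeline configuration
#'
#' Full parameter set of a synthetic end-to-end run, with the analysis
#' thresholds at their standard values (site FDR 0.05, library QC at
#' 300,000 unique events, bound-gene filter at 200 events and <10% control
#' binding, motif window -5/+30). The bundled synthetic fixture is
#' intentionally small (5 genes, 20,000 events), so QC enforcement defaults
#' to `"warn"`.
#'
#' @return nested named list understood by [validate_config()].
#' @export
default_config <- function() {
  list(
    transcriptome = list(n_genes = 5, gene_length_range = c(2000, 5000),
                         exon_count_range = c(1, 4), gc_content = 0.5,
                         motif = "GAAGA", motif_density = 2,
                         noncoding_fraction = 0.2, intergenic_length = 300,
                         seed = 1),
    clip = list(n_events = 20000, motif_boost = 50, proximity_window = 5,
                pcr_duplication_mean = 3, read_length = 75, umi_length = 6,
                control_rate_fraction = 0.05, comparison_rate_fraction = 0.10,
                seed = 1),
    samples = c("PR-crosslinked", "PR-noncrosslinked", "FLAG-crosslinked"),
    pr_sample = "PR-crosslinked",
    control_samples = c("PR-noncrosslinked", "FLAG-crosslinked"),
    sitecall = list(half_window = 3, n_perm = 100, fdr_threshold = 0.05,
                    seed = 1),
    qc = list(min_events = 300000, enforce = "warn"),
    genebind = list(min_events = 200, max_control_fraction = 0.10,
                    control_fraction_basis = "count"),
    motif = list(window_up = 5, window_down = 30, offset_range = 50,
                 background_seed = 1)
  )
}

check_range <- function(errors, cfg, key, lo, hi) {
  v <- cfg
  for (k in strsplit(key, ".", fixed = TRUE)[[1]]) v <- v[[k]]
  if (is.null(v) || !is.numeric(v) || any(v < lo) || any(v > hi)) {
    errors <- c(errors, sprintf("%s must be in [%g, %g]", key, lo, hi))
  }
  errors
}

#' Validate a pipeline configuration
#'
#' Checks parameter ranges and structure; unknown top-level keys are
#' rejected. Accepts a list or the path to a YAML file.
#'
#' @param config named list (see [default_config()]) or YAML path.
#' @return the validated config (class `run_config`), or an error listing
#'   every violation with its key path.
#' @export
validate_config <- function(config = default_config()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    config <- yaml::read_yaml(config)
  }
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  errors <- character(0)
  if (length(unknown)) {
    errors <- c(errors, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  }
  ## fill defaults for missing sections
  config <- utils::modifyList(default_config(), config[intersect(names(config), known)])

  errors <- check_range(errors, config, "sitecall.fdr_threshold", 0, 1)
  errors <- check_range(errors, config, "sitecall.half_window", 0, 1000)
  errors <- check_range(errors, config, "sitecall.n_perm", 1, 1e6)
  errors <- check_range(errors, config, "qc.min_events", 0, Inf)
  errors <- check_range(errors, config, "genebind.min_events", 0, Inf)
  errors <- check_range(errors, config, "genebind.max_control_fraction", 0, 1)
  if (!config$genebind$control_fraction_basis %in% c("cpm", "count")) {
    errors <- c(errors, "genebind.control_fraction_basis must be 'cpm' or 'count'")
  }
  errors <- check_range(errors, config, "motif.window_up", 0, 1000)
  errors <- check_range(errors, config, "motif.window_down", 4, 10000)
  errors <- check_range(errors, config, "clip.motif_boost", 1, Inf)
  errors <- check_range(errors, config, "clip.control_rate_fraction", 0, 1)
  if (!config$qc$enforce %in% c("strict", "warn")) {
    errors <- c(errors, "qc.enforce must be 'strict' or 'warn'")
  }
  if (!config$pr_sample %in% config$samples) {
    errors <- c(errors, "pr_sample missing from the sample sheet (samples)")
  }
  if (!all(config$control_samples %in% config$samples)) {
    errors <- c(errors, "control_samples missing from the sample sheet (samples)")
  }
  if (length(errors)) {
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  }
  class(config) <- c("run_config", "list")
  config
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> extract (demultiplex, UMI collapse, crosslink
#' assignment) -> QC -> site calling -> gene-level binding -> motif
#' enrichment on the configured synthetic dataset, and returns a report
#' bundle with provenance. Reruns with an identical configuration are
#' identical.
#'
#' @param config a validated [validate_config()] result (or a raw list,
#'   validated on entry).
#' @param outdir optional directory; when given, tables are written as
#'   TSV/BED alongside a provenance JSON.
#' @return list of class `prclip_report`: per-sample event tables and QC,
#'   significant sites, gene binding summary, region proportions, pentamer
#'   results, and `provenance`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)

  tx <- build_transcriptome(do.call(transcriptome_spec, config$transcriptome))
  sim_cfg <- do.call(clip_sim_config, config$clip)
  layout <- layout_from_config(sim_cfg)

  ## simulate each library, pool reads, and run the extraction chain once
  libs <- lapply(config$samples, function(k)
    simulate_clip_library(tx, sim_cfg, sample_kind = k))
  names(libs) <- config$samples
  reads <- do.call(c, unname(lapply(libs, `[[`, "reads")))
  alignments <- do.call(rbind, lapply(libs, `[[`, "alignments"))

  dm <- demultiplex(reads, layout)
  al <- join_alignments(alignments, dm)
  uc <- collapse_duplicates(al)
  ref_lengths <- setNames(Biostrings::width(tx$genome), names(tx$genome))
  events <- assign_crosslink_sites(uc$unique_cdnas, ref_lengths)$events

  ## per-sample QC
  qc <- do.call(rbind, lapply(config$samples, function(s) {
    sample_qc(crosslink_track(events[events$sample == s, ]),
              min_events = config$qc$min_events, sample = s)
  }))
  if (!all(qc$pass)) {
    failing <- paste(qc$sample[!qc$pass], collapse = ", ")
    msg <- sprintf("QC: sample(s) below %s unique events: %s",
                   format(config$qc$min_events, big.mark = ",",
                          scientific = FALSE), failing)
    if (config$qc$enforce == "strict") {
      stop(msg, "\nstage: qc; completed stages: simulate, extract")
    }
    warning(msg)
  }

  pr_events <- events[events$sample == config$pr_sample, ]
  sites <- call_significant_sites(
    pr_events, tx$genes,
    half_window = config$sitecall$half_window,
    n_perm = config$sitecall$n_perm,
    fdr_threshold = config$sitecall$fdr_threshold,
    seed = config$sitecall$seed)

  gene_counts <- count_gene_events(events, tx$genes)
  binding <- filter_bound_genes(
    gene_counts, pr_sample = config$pr_sample,
    control_samples = config$control_samples,
    min_events = config$genebind$min_events,
    max_control_fraction = config$genebind$max_control_fraction,
    control_fraction_basis = config$genebind$control_fraction_basis)
  regions <- annotate_regions(pr_events, tx$genes, tx$features)

  fg <- extract_windows(sites, tx$genome, tx$genes,
                        up = config$motif$window_up,
                        down = config$motif$window_down)
  bg <- sample_background_windows(fg, sites, tx$genome, tx$genes,
                                  seed = config$motif$background_seed)
  pent <- pentamer_enrichment(fg, bg)

  report <- structure(list(
    qc = qc,
    events = events,
    sites = sites,
    gene_binding = binding,
    region_proportions = regions$proportions,
    pentamers = pent,
    top_pentamer = pent$pentamer[1],
    provenance = list(package = "prclip",
                      version = as.character(utils::packageVersion("prclip")),
                      config = unclass(config))
  ), class = "prclip_report")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_transcriptome(tx, outdir)
    write_events_bed(events, file.path(outdir, "events.bed"))
    write_sites(sites, file.path(outdir, "sites.bed"),
                file.path(outdir, "sites.tsv"))
    utils::write.table(qc, file.path(outdir, "qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(binding),
                       file.path(outdir, "gene_binding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(pent),
                       file.path(outdir, "pentamers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report$provenance,
                         file.path(outdir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.prclip_report <- function(x, ...) {
  cat("prclip pipeline report\n")
  cat(sprintf("  samples: %s\n", paste(x$qc$sample, collapse = ", ")))
  cat(sprintf("  unique events: %s\n",
              paste(sprintf("%s=%d", x$qc$sample, x$qc$unique_events),
                    collapse = ", ")))
  cat(sprintf("  significant sites: %d\n", nrow(x$sites)))
  cat(sprintf("  bound genes: %d of %d\n", sum(x$gene_binding$bound),
              nrow(x$gene_binding)))
  cat(sprintf("  top pentamer: %s (corrected p %s)\n", x$top_pentamer,
              format_log10p(x$pentamers$log10_p_corrected[1])))
  invisible(x)
}
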