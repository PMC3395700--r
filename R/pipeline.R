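# End-to-end orchestration: reads + genome + gene models + known variants
# -> error profile -> pileup -> site scoring -> annotation -> confidence
# filter -> enrichment universe -> hotspot detection -> reports.

#' Pipeline configuration
#'
#' Every statistical threshold of the method is a named key. Defaults are
#' the method's reference values: depth floor `min_depth = 4`, site-level
#' `fdr = 0.01`, confidence gates `min_ratio = 0.33`, `min_quality = 90`
#' (raw ASCII, Phred+64), `min_ttest_p = 0.05`, `window = 4000`, gene gates
#' `min_snvs = 3`, `gene_q = 0.005`, motif gate `z_gate = 1`,
#' `n_perm = 1000` permutations.
#'
#' @param ... Overrides for any key.
#' @return A named list of class `shm_config`.
#' @export
shm_config <- function(...) {
  cfg <- list(
    min_depth = 4L, fdr = 0.01,
    min_ratio = 0.33, min_quality = 90, min_ttest_p = 0.05,
    window = 4000L, min_snvs = 3L, gene_q = 0.005, z_gate = 1,
    n_perm = 1000L, min_mapq = 1L,
    enrich_mode = "min-reads", enrich_min_reads = 20L, enrich_fdr = 0.05,
    peaks_bed = NULL, allele_aware = FALSE, min_base_quality = NULL,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "shm_config")
}

validate_config <- function(cfg) {
  if (cfg$min_ratio < 0 || cfg$min_ratio > 1)
    stop("min_ratio must lie in [0, 1]")
  if (cfg$fdr <= 0 || cfg$fdr > 1) stop("fdr must lie in (0, 1]")
  if (cfg$min_depth < 1) stop("min_depth must be >= 1")
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [shm_config()] arguments.
#' @return An `shm_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(shm_config, vals)
}

#' Run the full hotspot-detection pipeline
#'
#' @param genome_fa Reference FASTA.
#' @param alignments Coordinate-sorted SAM/BAM of uniquely aligned reads.
#' @param gene_models refFlat or BED12 gene models.
#' @param known_variants VCF or UCSC snp table of known polymorphisms
#'   (`NULL` to skip novelty filtering).
#' @param outdir Output directory.
#' @param config An [shm_config()].
#' @return Invisibly, a list with the intermediate objects (`profile`,
#'   `calls`, `windows`, `hotspots`) and a `counts` vector mirroring the
#'   filtering cascade (total SNVs, high-confidence, promoter, novel,
#'   hotspot genes). Writes `error_profile.tsv`, `snv_calls.tsv`,
#'   `tracks.{known,novel,shm}.bed`, `windows.tsv`,
#'   `report.hotspots.tsv`, `report.hotspot_snvs.tsv` and `run_log.txt`
#'   into `outdir`. Given identical inputs, config and seed the outputs are
#'   byte-identical.
#' @export
run_pipeline <- function(genome_fa, alignments, gene_models,
                         known_variants = NULL, outdir,
                         config = shm_config()) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  genome <- read_genome(genome_fa)
  genes <- read_gene_models(gene_models)
  known <- if (!is.null(known_variants)) read_known_variants(known_variants)
  reads <- read_alignments(alignments, min_mapq = config$min_mapq)
  n_raw <- nrow(reads)
  reads <- deduplicate_reads(reads)
  bases <- expand_alignments(reads, genome)
  profile <- build_error_profile(reads, genome, bases = bases)
  write_error_profile(profile, file.path(outdir, "error_profile.tsv"))
  windows <- promoter_windows(genes, genome, config$window)
  windows <- select_enriched(windows, reads, mode = config$enrich_mode,
                             min_reads = config$enrich_min_reads,
                             fdr = config$enrich_fdr,
                             peaks_bed = config$peaks_bed,
                             genome_length = sum(as.numeric(genome$lens)))
  pileup <- pileup_sites(reads, genome, windows,
                         min_depth = config$min_depth,
                         min_base_quality = config$min_base_quality,
                         bases = bases)
  calls <- score_sites(pileup, profile, min_depth = config$min_depth,
                       fdr = config$fdr)
  called <- calls[called == TRUE]
  called <- annotate_calls(called, windows, known, genome = genome,
                           allele_aware = config$allele_aware)
  called <- confidence_filter(called, pileup,
                              min_ratio = config$min_ratio,
                              min_quality = config$min_quality,
                              min_ttest_p = config$min_ttest_p)
  hotspots <- detect_hotspots(called, windows, genome, pileup,
                              min_snvs = config$min_snvs,
                              gene_q = config$gene_q,
                              z_gate = config$z_gate,
                              n_perm = config$n_perm)
  write_snv_table(called, file.path(outdir, "snv_calls.tsv"))
  write_snv_tracks(called, file.path(outdir, "tracks"))
  fwrite(windows, file.path(outdir, "windows.tsv"), sep = "\t")
  write_hotspot_report(hotspots, file.path(outdir, "report"))
  counts <- c(
    reads_unique = n_raw,
    reads_nonclonal = nrow(reads),
    enriched_promoters = sum(windows$enriched),
    total_snvs = nrow(called),
    high_confidence_snvs = sum(called$high_confidence),
    high_confidence_promoter_snvs = sum(called$high_confidence &
                                        called$promoter),
    high_confidence_novel_promoter_snvs = sum(called$high_confidence &
                                              called$promoter & called$novel),
    candidate_genes = nrow(hotspots$genes),
    hotspot_genes = sum(hotspots$genes$is_hotspot))
  log_lines <- c(
    paste0("shmscan ", packageVersion("shmscan")),
    "-- parameters --",
    paste0(names(unclass(config)), " = ",
           vapply(unclass(config), function(v)
             if (is.null(v)) "NULL" else paste(format(v), collapse = ","),
             "")),
    "-- filtering cascade --",
    paste0(names(counts), " = ", counts))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(profile = profile, windows = windows, pileup = pileup,
                 calls = called, all_scored = calls, hotspots = hotspots,
                 counts = counts))
}
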