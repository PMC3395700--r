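# Promoter-window construction, call annotation (promoter membership,
# novelty, motif context) and the high-confidence filter.

#' Build 4-kb promoter windows around gene TSSs
#'
#' @param genes Gene-model table from [read_gene_models()].
#' @param genome An `shm_genome`, used to clip windows at chromosome edges.
#' @param window_size Total window width in bp, centred on the TSS
#'   (default 4000, i.e. TSS +/- 2 kb).
#' @return data.table `gene, chrom, strand, tss, start, end, enriched`
#'   (0-based half-open; `enriched` initialised to `NA`). When `genes`
#'   carries several records per gene (per-transcript mode), overlapping
#'   windows of one gene are merged.
#' @export
promoter_windows <- function(genes, genome, window_size = 4000L) {
  half <- as.integer(window_size / 2L)
  w <- genes[, .(gene, chrom, strand, tss,
                 start = pmax(tss - half, 0L),
                 end = tss + half)]
  w[, end := pmin(end, genome$lens[chrom])]
  if (anyDuplicated(w$gene)) {
    setkey(w, gene, chrom, start)
    w <- w[, {
      # merge overlapping per-transcript windows of one gene
      grp <- cumsum(c(1L, as.integer(start[-1L] > cummax(head(end, -1L)))))
      .(chrom = chrom[1], strand = strand[1], tss = tss[1],
        start = tapply(start, grp, min), end = tapply(end, grp, max))
    }, by = gene]
    w[, `:=`(start = as.integer(start), end = as.integer(end))]
  }
  w[, enriched := NA]
  setcolorder(w, c("gene", "chrom", "strand", "tss", "start", "end", "enriched"))
  w[]
}

#' Annotate SNV calls with promoter membership, novelty and motif context
#'
#' @param calls Call table from [score_sites()].
#' @param windows Window table with the `enriched` flag set
#'   (see [select_enriched()]); the promoter flag is `TRUE` only inside
#'   enriched windows, and `gene` is taken from the matching window.
#' @param known A known-variant set from [read_known_variants()], or `NULL`
#'   to skip novelty annotation.
#' @param genome Optional `shm_genome`; when supplied, `shm_context_rgyw` /
#'   `shm_context_wa` are set for calls at mutable positions of the AID
#'   motifs (see [scan_motifs()]).
#' @param allele_aware Match known variants by allele as well as position
#'   (default `FALSE`: position-level, the conventional dbSNP-style filter).
#' @return The call table with `promoter`, `gene`, `novel` and motif-context
#'   flags filled in. Annotation is pure: no rows are added or removed.
#' @export
annotate_calls <- function(calls, windows, known, genome = NULL,
                           allele_aware = FALSE) {
  calls <- copy(calls)
  if (nrow(calls) == 0L) return(calls)
  ew <- windows[enriched == TRUE]
  if (nrow(ew)) {
    wid <- assign_window(calls$chrom, calls$pos, ew)
    calls[, promoter := !is.na(wid)]
    calls[, gene := ifelse(is.na(wid), NA_character_, ew$gene[wid])]
  } else {
    calls[, `:=`(promoter = FALSE, gene = NA_character_)]
  }
  if (!is.null(known)) {
    calls[, novel := !is_known(known, chrom, pos,
                               alt = if (allele_aware) alt else NULL)]
  }
  if (!is.null(genome)) {
    calls[, `:=`(shm_context_rgyw = FALSE, shm_context_wa = FALSE)]
    scan_w <- if (nrow(ew)) ew else windows
    wid_all <- assign_window(calls$chrom, calls$pos, scan_w)
    for (wi in unique(wid_all[!is.na(wid_all)])) {
      hits <- scan_motifs(genome, scan_w[wi])
      rows <- which(wid_all == wi)
      calls[rows, shm_context_rgyw := pos %in% hits[motif_class == "RGYW"]$pos]
      calls[rows, shm_context_wa := pos %in% hits[motif_class == "WA"]$pos]
    }
  }
  calls[]
}

# Welch two-sided t-test on raw quality scores; NA when undefined
# (fewer than two observations on either side, or degenerate variance).
quality_ttest <- function(ref_q, alt_q) {
  if (length(ref_q) < 2L || length(alt_q) < 2L) return(NA_real_)
  if (sd(ref_q) == 0 && sd(alt_q) == 0)
    return(if (mean(ref_q) == mean(alt_q)) 1 else 0)
  tryCatch(t.test(ref_q, alt_q)$p.value, error = function(e) NA_real_)
}

#' High-confidence filter for SNV calls
#'
#' A call is high-confidence when (i) its mismatch ratio `k/n` is at least
#' `min_ratio`, (ii) the mean raw-ASCII base quality of the reads carrying
#' the alternate allele is at least `min_quality`, and (iii) a Welch t-test
#' comparing qualities of reference-base reads against alternate-base reads
#' does not reject equality (`p >= min_ttest_p`). When the t-test is
#' undefined (either group smaller than two reads, e.g. `k = n`), the gate
#' passes vacuously.
#'
#' @param calls Call table.
#' @param pileup The `shm_pileup` the calls came from (supplies the
#'   per-read quality detail for the t-test).
#' @param min_ratio Minimum `k/n` (default 0.33).
#' @param min_quality Minimum mean raw-ASCII quality of alternate-base reads
#'   (default 90; with Phred+64 encoding this is Q >= 26 — supply the value
#'   matching your encoding, e.g. 59 for Phred+33).
#' @param min_ttest_p Minimum t-test p-value (default 0.05).
#' @return The call table with `quality_ttest_p` and `high_confidence`
#'   filled in.
#' @export
confidence_filter <- function(calls, pileup, min_ratio = 0.33,
                              min_quality = 90, min_ttest_p = 0.05) {
  if (min_ratio < 0 || min_ratio > 1) stop("min_ratio must lie in [0, 1]")
  calls <- copy(calls)
  if (nrow(calls) == 0L) return(calls)
  det <- pileup$detail
  setkey(det, chrom, pos)
  alt_code <- BASE_CODES[calls$alt]
  tt <- vapply(seq_len(nrow(calls)), function(i) {
    d <- det[.(calls$chrom[i], calls$pos[i])]
    quality_ttest(d[is_mm == FALSE]$qual,
                  d[is_mm == TRUE & base == alt_code[i]]$qual)
  }, 0)
  calls[, quality_ttest_p := tt]
  calls[, high_confidence :=
          ratio >= min_ratio &
          !is.na(mean_alt_qual) & mean_alt_qual >= min_quality &
          (is.na(quality_ttest_p) | quality_ttest_p >= min_ttest_p)]
  calls[]
}
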