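# Per-gene SNV clustering test, AID-motif enrichment by permutation, and
# hotspot classification.
#
# Motif conventions: RGYW and its reverse complement WRCY form one class
# (mutable base: the G of RGYW on the matching strand, equivalently the C of
# WRCY read on the forward strand); WA and its reverse complement TW form the
# second class (mutable A resp. T). R = A/G, Y = C/T, W = A/T.

MOTIF_DEFS <- list(
  list(pattern = "RGYW", offset = 1L, class = "RGYW", strand = "+"),
  list(pattern = "WRCY", offset = 2L, class = "RGYW", strand = "-"),
  list(pattern = "WA",   offset = 1L, class = "WA",   strand = "+"),
  list(pattern = "TW",   offset = 0L, class = "WA",   strand = "-")
)

#' Scan a promoter window for AID target motifs
#'
#' Finds every mutable position of the RGYW/WRCY and WA/TW motif classes in
#' the window. The window sequence is extended by 3 bp on each side so
#' motifs straddling the boundary are found; only mutable positions inside
#' the window are reported. A position occurring in several overlapping
#' motifs of one class is reported once for that class.
#'
#' @param genome An `shm_genome`.
#' @param window One window row (`chrom`, `start`, `end`).
#' @return data.table `chrom, pos, motif_class, strand` of mutable positions
#'   (0-based). `strand` is the strand of the matching motif (`-` means the
#'   reverse-complement spelling matched the forward sequence).
#' @export
scan_motifs <- function(genome, window) {
  stopifnot(nrow(window) == 1L)
  chrlen <- genome$lens[[window$chrom]]
  s0 <- max(window$start - 3L, 0L)
  e0 <- min(window$end + 3L, chrlen)
  subject <- Biostrings::subseq(genome$seqs[[window$chrom]], s0 + 1L, e0)
  hits <- rbindlist(lapply(MOTIF_DEFS, function(m) {
    mt <- Biostrings::matchPattern(m$pattern, subject,
                                   fixed = c(pattern = FALSE, subject = TRUE))
    if (length(mt) == 0L)
      return(data.table(pos = integer(0), motif_class = character(0),
                        strand = character(0)))
    data.table(pos = s0 + BiocGenerics::start(mt) - 1L + m$offset,
               motif_class = m$class, strand = m$strand)
  }))
  hits <- hits[pos >= window$start & pos < window$end]
  hits <- unique(hits, by = c("pos", "motif_class"))
  hits[, chrom := window$chrom]
  setcolorder(hits, c("chrom", "pos", "motif_class", "strand"))
  setkey(hits, pos)
  hits[]
}

#' Per-gene Poisson clustering test
#'
#' Tests, for each gene, whether its count of high-confidence novel promoter
#' SNVs is surprising under a uniform distribution of all such SNVs across
#' the enriched promoter windows: `lambda = total SNVs / enriched windows`,
#' `p = P(X >= k; lambda)`. BH adjustment is applied across the genes with
#' at least one SNV.
#'
#' @param per_gene_counts data.table `gene, k_gene` (genes with zero SNVs may
#'   be included; they get `pvalue = 1` and are excluded from the BH family).
#' @param n_enriched_windows Number of enriched promoter windows (the
#'   universe size).
#' @param total_snvs Total number of high-confidence novel promoter SNVs;
#'   defaults to `sum(per_gene_counts$k_gene)`.
#' @return data.table `gene, k_gene, lambda, pvalue, qvalue`.
#' @export
gene_poisson_test <- function(per_gene_counts, n_enriched_windows,
                              total_snvs = sum(per_gene_counts$k_gene)) {
  if (n_enriched_windows <= 0L) stop("no enriched windows: lambda undefined")
  out <- copy(per_gene_counts)
  lambda <- total_snvs / n_enriched_windows
  out[, lambda := lambda]
  out[, pvalue := ppois(k_gene - 1L, lambda, lower.tail = FALSE)]
  out[k_gene == 0L, pvalue := 1]
  out[, qvalue := NA_real_]
  fam <- out$k_gene >= 1L
  if (any(fam)) out[fam, qvalue := bh_adjust(pvalue)]
  out[]
}

#' Permutation z-score for motif-context enrichment
#'
#' The observed statistic is the number of SNVs sitting at mutable positions
#' of one motif class. Each permutation redraws the same number of positions
#' uniformly without replacement from the window's covered positions and
#' recounts; `z = (obs - mean) / sd` over the permutations. Covered
#' positions (rather than all window positions) are the proposal set because
#' SNVs are only detectable where there is coverage.
#'
#' @param covered Integer vector of covered positions in the window.
#' @param snv_pos Positions of the gene's SNVs (must be a subset of
#'   `covered`).
#' @param mutable_pos Mutable positions of the motif class
#'   (from [scan_motifs()]).
#' @param n_perm Number of permutations (default 1000).
#' @return List `obs, exp, sd, z`. With `sd = 0`: `z` is `Inf` when
#'   `obs > exp`, `-Inf` when `obs < exp`, else 0.
#' @export
permutation_z <- function(covered, snv_pos, mutable_pos, n_perm = 1000L) {
  k <- length(snv_pos)
  stopifnot(k >= 1L)
  if (length(covered) < k)
    stop("fewer covered positions than SNVs to permute")
  if (!all(snv_pos %in% covered))
    stop("SNV positions must be a subset of covered positions")
  member <- covered %in% mutable_pos
  obs <- sum(snv_pos %in% mutable_pos)
  N <- length(covered)
  counts <- vapply(seq_len(n_perm),
                   function(j) sum(member[sample.int(N, k)]), 0L)
  e <- mean(counts)
  s <- sd(counts)
  z <- if (s == 0) {
    if (obs > e) Inf else if (obs < e) -Inf else 0
  } else (obs - e) / s
  list(obs = obs, exp = e, sd = s, z = z)
}

#' Detect SHM hotspots
#'
#' Aggregates high-confidence novel promoter SNVs per gene, applies the
#' Poisson clustering gate, computes motif permutation z-scores for the
#' candidate genes and classifies hotspots: a gene is a hotspot when it has
#' at least `min_snvs` SNVs, a BH-adjusted clustering p-value below
#' `gene_q`, and a z-score strictly greater than `z_gate` for either motif
#' class.
#'
#' @param calls Annotated, confidence-filtered call table.
#' @param windows Window table with `enriched` set.
#' @param genome An `shm_genome`.
#' @param pileup The `shm_pileup` (supplies covered positions for the
#'   permutation proposal).
#' @param min_snvs Count gate (default 3).
#' @param gene_q Clustering gate on adjusted p (default 0.005, strict `<`).
#' @param z_gate Motif gate (default 1, strict `>`).
#' @param n_perm Permutations per gene and class (default 1000).
#' @return List of class `shm_hotspots` with elements
#'   `genes` (per-candidate-gene table: `gene, k_gene, downstream, qvalue,
#'   rgyw_obs, rgyw_exp, rgyw_sd, z_rgyw, wa_obs, wa_exp, wa_sd, z_wa, ts,
#'   tv, is_hotspot`), `tests` (the full gene Poisson table) and `snvs`
#'   (per-SNV table for candidate genes, with motif-context flags).
#' @export
detect_hotspots <- function(calls, windows, genome, pileup,
                            min_snvs = 3L, gene_q = 0.005, z_gate = 1,
                            n_perm = 1000L) {
  hc <- calls[called == TRUE & high_confidence == TRUE & novel == TRUE &
              promoter == TRUE]
  ew <- copy(windows[enriched == TRUE])[, wid := .I]
  n_enriched <- nrow(ew)
  counts <- hc[!is.na(gene), .(k_gene = .N), by = gene]
  tests <- gene_poisson_test(counts, n_enriched)
  cand <- tests[k_gene >= min_snvs & !is.na(qvalue) & qvalue < gene_q]
  cov <- covered_positions(pileup, ew)
  empty_genes <- data.table(
    gene = character(0), k_gene = integer(0), downstream = integer(0),
    qvalue = numeric(0), rgyw_obs = integer(0), rgyw_exp = numeric(0),
    rgyw_sd = numeric(0), z_rgyw = numeric(0), wa_obs = integer(0),
    wa_exp = numeric(0), wa_sd = numeric(0), z_wa = numeric(0),
    ts = integer(0), tv = integer(0), is_hotspot = logical(0))
  snv_rows <- list()
  gene_rows <- list()
  for (g in cand$gene) {
    wrow <- ew[gene == g][1L]
    snvs <- hc[gene == g]
    hits <- scan_motifs(genome, wrow)
    covg <- cov[wid == wrow$wid]$pos
    mz <- lapply(c("RGYW", "WA"), function(cl)
      permutation_z(covg, snvs$pos, hits[motif_class == cl]$pos,
                    n_perm = n_perm))
    names(mz) <- c("RGYW", "WA")
    down <- if (wrow$strand == "+") sum(snvs$pos > wrow$tss)
            else sum(snvs$pos < wrow$tss)
    trans <- sum(is_transition(snvs$ref, snvs$alt))
    gene_rows[[g]] <- data.table(
      gene = g, k_gene = nrow(snvs), downstream = down,
      qvalue = cand[gene == g]$qvalue,
      rgyw_obs = mz$RGYW$obs, rgyw_exp = mz$RGYW$exp, rgyw_sd = mz$RGYW$sd,
      z_rgyw = mz$RGYW$z,
      wa_obs = mz$WA$obs, wa_exp = mz$WA$exp, wa_sd = mz$WA$sd,
      z_wa = mz$WA$z,
      ts = trans, tv = nrow(snvs) - trans,
      is_hotspot = mz$RGYW$z > z_gate || mz$WA$z > z_gate)
    sv <- copy(snvs)
    sv[, `:=`(shm_context_rgyw = pos %in% hits[motif_class == "RGYW"]$pos,
              shm_context_wa = pos %in% hits[motif_class == "WA"]$pos)]
    snv_rows[[g]] <- sv
  }
  genes <- if (length(gene_rows)) rbindlist(gene_rows) else empty_genes
  structure(
    list(genes = genes[order(-k_gene, gene)],
         tests = tests[order(pvalue)],
         snvs = if (length(snv_rows)) rbindlist(snv_rows) else hc[0L]),
    class = "shm_hotspots")
}

#' @export
print.shm_hotspots <- function(x, ...) {
  cat("shm_hotspots:", nrow(x$genes), "candidate gene(s),",
      sum(x$genes$is_hotspot), "classified hotspot(s)\n")
  invisible(x)
}

#' Write the hotspot report
#'
#' Two TSV files: `<prefix>.hotspots.tsv` with one row per candidate gene
#' (SNV count with the downstream-of-TSS count in parentheses, adjusted
#' clustering p, observed/expected/z per motif class, Ts/Tv) and
#' `<prefix>.hotspot_snvs.tsv` with the location and motif-context flags of
#' every SNV in those genes.
#'
#' @param result An `shm_hotspots` from [detect_hotspots()].
#' @param out_prefix Output path prefix.
#' @return Invisibly the two file paths.
#' @export
write_hotspot_report <- function(result, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  g <- result$genes
  report <- data.table(
    gene = g$gene,
    snv_number = sprintf("%d(%d)", g$k_gene, g$downstream),
    p_bh = signif(g$qvalue, 3),
    rgyw_obs = g$rgyw_obs, rgyw_exp = round(g$rgyw_exp, 2),
    z_rgyw = round(g$z_rgyw, 2),
    wa_obs = g$wa_obs, wa_exp = round(g$wa_exp, 2),
    z_wa = round(g$z_wa, 2),
    ts_tv = sprintf("%d/%d", g$ts, g$tv),
    is_hotspot = g$is_hotspot)
  f1 <- paste0(out_prefix, ".hotspots.tsv")
  f2 <- paste0(out_prefix, ".hotspot_snvs.tsv")
  fwrite(report, f1, sep = "\t")
  s <- result$snvs
  loc <- if (nrow(s)) {
    data.table(gene = s$gene, chrom = s$chrom, pos1 = s$pos + 1L,
               ref = s$ref, alt = s$alt, n = s$n, k = s$k,
               shm_context_rgyw = s$shm_context_rgyw,
               shm_context_wa = s$shm_context_wa)
  } else {
    data.table(gene = character(0), chrom = character(0), pos1 = integer(0),
               ref = character(0), alt = character(0), n = integer(0),
               k = integer(0), shm_context_rgyw = logical(0),
               shm_context_wa = logical(0))
  }
  fwrite(loc, f2, sep = "\t")
  invisible(c(hotspots = f1, snvs = f2))
}
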