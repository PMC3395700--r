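# Synthetic-experiment generator: a self-consistent genome, gene models,
# known-variant set and coordinate-sorted aligned reads with planted
# germline SNPs, novel SNVs and motif-context SHM hotspots, plus a
# ground-truth manifest. Reads are emitted directly as alignments (SAM);
# the pipeline's contract starts at aligned reads.

#' Configuration for a synthetic experiment
#'
#' Defaults describe a small promoter-capture-like experiment: 36-bp reads
#' tiling disjoint 4-kb promoter windows at 30x mean depth, with a linearly
#' increasing per-cycle error rate (0.1% at the first cycle to 1% at the
#' last, the shape typical of Illumina data), base qualities uniform in
#' Q30-Q40 under Phred+64 encoding, and 2% exact-duplicate (clonal) reads.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_genes Number of genes; their 4-kb windows never overlap.
#' @param window Promoter window width (bp).
#' @param gene_gap Gap between consecutive windows (bp).
#' @param margin Chromosome margin before the first / after the last window.
#' @param genome_length Total genome length; derived from the layout when
#'   `NULL`. Supplying a value too small to place all genes is an error.
#' @param read_length Read length (bp).
#' @param mean_depth Mean *non-clonal* coverage inside windows: the number
#'   of sampled reads is inflated so that, after clonal (same start and
#'   strand) reads are collapsed, the expected coverage matches this value.
#' @param error_rate_curve Per-cycle mismatch probability, length
#'   `read_length`, each in `[0, 1)`.
#' @param phred_offset Quality-character encoding offset (64 = Illumina-1.3
#'   style "raw ASCII" scores; 33 = Sanger).
#' @param quality_range Integer Phred qualities to draw from, uniformly.
#' @param planted_snp_rate Germline known-SNP rate per window bp.
#' @param snp_af Allele fraction of planted SNPs (1 = homozygous).
#' @param planted_hotspots `data.frame(gene, n_shm, motif_class, af)`; each
#'   row plants `n_shm` transition SHMs at mutable positions of
#'   `motif_class` ("RGYW" or "WA") in that gene's window.
#' @param planted_scattered `data.frame(gene, n_snv, af)`; plants `n_snv`
#'   novel SNVs at uniform positions in that gene's window.
#' @param dup_fraction Fraction of reads duplicated exactly (clonal reads).
#' @param chrom Chromosome name.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 60L,
                       window = 4000L,
                       gene_gap = 2000L,
                       margin = 1000L,
                       genome_length = NULL,
                       read_length = 36L,
                       mean_depth = 30,
                       error_rate_curve = NULL,
                       phred_offset = 64L,
                       quality_range = 30:40,
                       planted_snp_rate = 5e-4,
                       snp_af = 1,
                       planted_hotspots = NULL,
                       planted_scattered = NULL,
                       dup_fraction = 0.02,
                       chrom = "chrS") {
  if (is.null(error_rate_curve))
    error_rate_curve <- seq(0.001, 0.01, length.out = read_length)
  stopifnot(length(error_rate_curve) == read_length,
            all(error_rate_curve >= 0), all(error_rate_curve < 1),
            mean_depth > 0, n_genes >= 1)
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              window = as.integer(window), gene_gap = as.integer(gene_gap),
              margin = as.integer(margin), genome_length = genome_length,
              read_length = as.integer(read_length), mean_depth = mean_depth,
              error_rate_curve = error_rate_curve,
              phred_offset = as.integer(phred_offset),
              quality_range = as.integer(quality_range),
              planted_snp_rate = planted_snp_rate, snp_af = snp_af,
              planted_hotspots = if (!is.null(planted_hotspots))
                as.data.table(planted_hotspots) else NULL,
              planted_scattered = if (!is.null(planted_scattered))
                as.data.table(planted_scattered) else NULL,
              dup_fraction = dup_fraction, chrom = chrom)
  structure(cfg, class = "sim_config")
}

# in-memory shm_genome from a single character sequence
genome_from_string <- function(seqstr, chrom) {
  seqstr <- toupper(seqstr)
  seqs <- Biostrings::DNAStringSet(setNames(seqstr, chrom))
  structure(list(seqs = seqs, raw = setNames(list(charToRaw(seqstr)), chrom),
                 lens = setNames(nchar(seqstr), chrom)),
            class = "shm_genome")
}

#' Simulate the reference side of an experiment
#'
#' Generates the genome, gene models, planted variants and known-variant
#' set, and writes `genome.fa`, `genes.refFlat`, `known.vcf` and the
#' ground-truth manifest `truth.tsv` into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with `genome` (`shm_genome`), `genes`, `windows`,
#'   `variants` (the manifest: `chrom, pos, ref, alt, type, gene,
#'   motif_class, af`) and `paths`.
#' @export
simulate_genome <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  stride <- cfg$window + cfg$gene_gap
  glen <- 2L * cfg$margin + cfg$n_genes * stride
  if (!is.null(cfg$genome_length)) {
    if (cfg$genome_length < glen)
      stop("genome_length ", cfg$genome_length, " too small to place ",
           cfg$n_genes, " non-overlapping windows (need ", glen, ")")
    glen <- as.integer(cfg$genome_length)
  }
  seqstr <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  genome <- genome_from_string(seqstr, cfg$chrom)
  half <- cfg$window %/% 2L
  tss <- cfg$margin + (seq_len(cfg$n_genes) - 1L) * stride + half
  genes <- data.table(
    gene = sprintf("G%03d", seq_len(cfg$n_genes)),
    chrom = cfg$chrom,
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    tss = as.integer(tss))
  genes[, transcripts := paste0(gene, ".1")]
  windows <- promoter_windows(genes, genome, cfg$window)
  # interior region: planted positions stay one read-length inside the
  # window so they sit at full coverage
  interior <- windows[, .(gene, lo = start + cfg$read_length,
                          hi = end - cfg$read_length - 1L)]
  used <- integer(0)
  pick_positions <- function(pool, n) {
    pool <- setdiff(pool, used)
    if (length(pool) < n)
      stop("not enough free positions to plant ", n, " variants")
    pos <- sort(pool[sample.int(length(pool), n)])
    used <<- c(used, pos)
    pos
  }
  variants <- list()
  # germline SNPs (known set)
  n_snp <- round(cfg$planted_snp_rate * cfg$window * cfg$n_genes)
  if (n_snp > 0) {
    pool <- unlist(lapply(seq_len(nrow(interior)),
                          function(i) interior$lo[i]:interior$hi[i]))
    pos <- pick_positions(pool, n_snp)
    ref <- ref_base(genome, rep(cfg$chrom, n_snp), pos)
    variants$snp <- data.table(
      chrom = cfg$chrom, pos = pos, ref = ref,
      alt = random_other_base(ref), type = "snp",
      gene = interior$gene[assign_window(rep(cfg$chrom, n_snp), pos, windows)],
      motif_class = NA_character_, af = cfg$snp_af)
  }
  # motif-context SHM hotspots (transition alleles at mutable positions)
  if (!is.null(cfg$planted_hotspots)) {
    rows <- lapply(seq_len(nrow(cfg$planted_hotspots)), function(i) {
      h <- cfg$planted_hotspots[i]
      wrow <- windows[gene == h$gene]
      if (nrow(wrow) != 1L) stop("unknown gene in planted_hotspots: ", h$gene)
      hits <- scan_motifs(genome, wrow)
      ir <- interior[gene == h$gene]
      pool <- hits[motif_class == h$motif_class & pos >= ir$lo & pos <= ir$hi]$pos
      pos <- pick_positions(pool, h$n_shm)
      ref <- ref_base(genome, rep(cfg$chrom, length(pos)), pos)
      # AID-style transitions: G>A / C>T (RGYW class), A>G / T>C (WA class)
      alt <- c(A = "G", C = "T", G = "A", T = "C")[ref]
      data.table(chrom = cfg$chrom, pos = pos, ref = ref, alt = unname(alt),
                 type = "shm", gene = h$gene, motif_class = h$motif_class,
                 af = h$af)
    })
    variants$shm <- rbindlist(rows)
  }
  # scattered novel SNVs
  if (!is.null(cfg$planted_scattered)) {
    rows <- lapply(seq_len(nrow(cfg$planted_scattered)), function(i) {
      s <- cfg$planted_scattered[i]
      if (s$n_snv == 0L) return(NULL)
      ir <- interior[gene == s$gene]
      if (nrow(ir) != 1L) stop("unknown gene in planted_scattered: ", s$gene)
      pos <- pick_positions(ir$lo:ir$hi, s$n_snv)
      ref <- ref_base(genome, rep(cfg$chrom, length(pos)), pos)
      data.table(chrom = cfg$chrom, pos = pos, ref = ref,
                 alt = random_other_base(ref), type = "snv", gene = s$gene,
                 motif_class = NA_character_, af = s$af)
    })
    variants$snv <- rbindlist(rows[!vapply(rows, is.null, TRUE)])
  }
  variants <- if (length(variants)) rbindlist(variants) else
    data.table(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), type = character(0), gene = character(0),
               motif_class = character(0), af = numeric(0))
  setkey(variants, chrom, pos)
  paths <- c(genome = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.refFlat"),
             known = file.path(dir, "known.vcf"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(genome$seqs, paths[["genome"]])
  write_refflat(genes, genome, paths[["genes"]])
  write_known_vcf(variants[type == "snp"], genome, paths[["known"]])
  fwrite(variants, paths[["truth"]], sep = "\t")
  list(genome = genome, genes = genes, windows = windows,
       variants = variants, paths = paths)
}

write_refflat <- function(genes, genome, path) {
  txs <- fifelse(genes$strand == "+", genes$tss,
                 pmax(genes$tss + 1L - 2000L, 0L))
  txe <- fifelse(genes$strand == "+",
                 pmin(genes$tss + 2000L, genome$lens[genes$chrom]),
                 genes$tss + 1L)
  out <- data.table(genes$gene, genes$transcripts, genes$chrom, genes$strand,
                    txs, txe, txs, txe, 1L,
                    paste0(txs, ","), paste0(txe, ","))
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

write_known_vcf <- function(snps, genome, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(genome$lens),
                   genome$lens),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  lines <- if (nrow(snps)) {
    sprintf("%s\t%d\tsim%d\t%s\t%s\t.\t.\t.",
            snps$chrom, snps$pos + 1L, seq_len(nrow(snps)), snps$ref,
            snps$alt)
  } else character(0)
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Simulate aligned reads
#'
#' Tiles each promoter window with reads at the configured depth, applies
#' planted alleles (each overlapping read carries the alternate allele with
#' probability `af`) and per-cycle sequencing errors, injects exact clonal
#' duplicates, and writes a coordinate-sorted SAM file. Strand is assigned
#' 50/50; for reverse-strand reads the error curve is applied in sequencing
#' -cycle order (i.e. mirrored relative to the reference orientation), and
#' SEQ/QUAL are emitted in reference orientation as SAM requires.
#'
#' @param cfg A [sim_config()].
#' @param sim Result of [simulate_genome()].
#' @param path Output SAM path (default `reads.sam` next to the genome).
#' @return The SAM path, invisibly.
#' @export
simulate_reads <- function(cfg, sim, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(path)) path <- file.path(dirname(sim$paths[["genome"]]),
                                       "reads.sam")
  if (nrow(sim$variants) && cfg$mean_depth <= 0)
    stop("planted variants require positive depth")
  set.seed(cfg$seed + 1L)
  L <- cfg$read_length
  w <- sim$windows
  # mean_depth refers to *non-clonal* coverage: with uniform start positions
  # some reads coincide by chance on (start, strand) and are collapsed by
  # deduplication, so the number of sampled reads is inflated to the value
  # whose expected count of distinct (start, strand) placements matches the
  # requested depth
  width <- w$end - w$start
  n_slots <- 2 * (width - L + 1L)                  # (start, strand) slots
  u <- pmax(1, round(cfg$mean_depth * width / L))  # distinct reads wanted
  if (any(u >= 0.95 * n_slots))
    stop("requested depth saturates the distinct read placements; ",
         "reduce mean_depth or enlarge windows")
  n_per <- as.integer(ceiling(log(1 - u / n_slots) / log(1 - 1 / n_slots)))
  pos0 <- unlist(lapply(seq_len(nrow(w)), function(i)
    sample(w$start[i]:(w$end[i] - L), n_per[i], replace = TRUE)))
  n <- length(pos0)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gint <- sim$genome$raw[[cfg$chrom]]
  # reference-orientation base matrix, one row per read
  idx <- outer(pos0, 0:(L - 1L), "+") + 1L
  M <- matrix(gint[idx], nrow = n)
  # planted alleles
  v <- sim$variants
  for (i in seq_len(nrow(v))) {
    p <- v$pos[i]
    cov <- which(pos0 <= p & pos0 >= p - L + 1L)
    if (!length(cov)) next
    carrier <- cov[runif(length(cov)) < v$af[i]]
    if (length(carrier))
      M[cbind(carrier, p - pos0[carrier] + 1L)] <- charToRaw(v$alt[i])
  }
  # per-cycle errors: column j is query offset j-1 (reference orientation);
  # its sequencing cycle is j-1 on "+" reads and L-j on "-" reads
  curve <- cfg$error_rate_curve
  P <- matrix(0, nrow = n, ncol = L)
  plus <- strand == "+"
  for (j in seq_len(L)) {
    P[plus, j] <- curve[j]
    P[!plus, j] <- curve[L - j + 1L]
  }
  flip <- which(matrix(runif(n * L), nrow = n) < P)
  if (length(flip)) {
    cur <- toupper(rawToChar(M[flip], multiple = TRUE))
    M[flip] <- charToRaw(paste0(random_other_base(cur), collapse = ""))
  }
  # qualities (uniform over quality_range, so orientation is immaterial)
  Q <- matrix(sample(cfg$quality_range + cfg$phred_offset, n * L,
                     replace = TRUE), nrow = n)
  seqs <- substring(rawToChar(as.raw(t(M))),
                    seq(1L, n * L, by = L), seq(L, n * L, by = L))
  quals <- substring(rawToChar(as.raw(t(Q))),
                     seq(1L, n * L, by = L), seq(L, n * L, by = L))
  reads <- data.table(pos0 = pos0, strand = strand, seq = seqs, qual = quals)
  # exact clonal duplicates with re-drawn qualities
  n_dup <- round(cfg$dup_fraction * n)
  if (n_dup > 0) {
    di <- sample.int(n, n_dup, replace = FALSE)
    dup <- reads[di]
    dq <- matrix(sample(cfg$quality_range + cfg$phred_offset, n_dup * L,
                        replace = TRUE), nrow = n_dup)
    dup[, qual := substring(rawToChar(as.raw(t(dq))),
                            seq(1L, n_dup * L, by = L),
                            seq(L, n_dup * L, by = L))]
    reads <- rbind(reads, dup)
  }
  setorder(reads, pos0)
  reads[, qname := sprintf("r%07d", .I)]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", cfg$chrom,
                   sim$genome$lens[[cfg$chrom]]))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, fifelse(reads$strand == "-", 16L, 0L),
                  cfg$chrom, reads$pos0 + 1L, L, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a complete experiment
#'
#' Runs [simulate_genome()] and [simulate_reads()] and returns all paths
#' plus the in-memory objects.
#'
#' @inheritParams simulate_genome
#' @return The [simulate_genome()] result, with `paths[["reads"]]` added.
#' @export
simulate_experiment <- function(cfg, dir) {
  sim <- simulate_genome(cfg, dir)
  sam <- simulate_reads(cfg, sim)
  sim$paths <- c(sim$paths, reads = sam)
  sim
}
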