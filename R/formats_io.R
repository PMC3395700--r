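# External-format readers and writers. Everything is normalised to the
# internal 0-based half-open convention on the way in; display/1-based
# conversions happen on the way out.

#' Read gene models from refFlat or BED12
#'
#' refFlat (UCSC genePred with a leading gene-symbol column) and BED12 are
#' supported; the dialect is detected from the file content. Multi-transcript
#' genes are collapsed to one record per gene symbol.
#'
#' @param path Path to a refFlat (11-column, tab-separated, no header) or
#'   BED12 file.
#' @param collapse How to reduce multiple transcripts of one gene:
#'   `"five_prime"` (default) keeps the 5'-most transcript start on the gene
#'   strand as the single TSS; `"per_transcript"` keeps one record per
#'   transcript (windows built from these are merged downstream).
#' @return A [data.table::data.table] with columns `gene`, `chrom`, `strand`,
#'   `tss` (0-based position of the transcription start site) and
#'   `transcripts` (comma-separated transcript ids).
#' @details The TSS is the transcript start (`txStart`) for `+`-strand genes
#'   and the 0-based last transcribed base (`txEnd - 1`) for `-`-strand genes.
#' @export
read_gene_models <- function(path, collapse = c("five_prime", "per_transcript")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (nfield >= 12 &&
      grepl("^[^\t]+\t[0-9]+\t[0-9]+\t", first)) {
    gm <- read_bed12_models(path)
  } else {
    gm <- read_refflat_models(path)
  }
  if (any(!gm$strand %in% c("+", "-")))
    stop("gene model with missing or invalid strand: ",
         gm$gene[which(!gm$strand %in% c("+", "-"))[1]])
  gm[, tss := fifelse(strand == "+", start, end - 1L)]
  if (collapse == "five_prime") {
    gm <- gm[, {
      if (length(unique(chrom)) > 1L || length(unique(strand)) > 1L)
        stop("gene on multiple chromosomes/strands: ", gene[1])
      .(chrom = chrom[1], strand = strand[1],
        tss = if (strand[1] == "+") min(tss) else max(tss),
        transcripts = paste(tx, collapse = ","))
    }, by = gene]
  } else {
    gm <- gm[, .(gene, chrom, strand, tss, transcripts = tx)]
  }
  if (any(gm$tss < 0)) stop("negative TSS coordinate")
  setcolorder(gm, c("gene", "chrom", "strand", "tss", "transcripts"))
  gm[]
}

read_refflat_models <- function(path) {
  cols <- c("gene", "tx", "chrom", "strand", "start", "end",
            "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  df <- tryCatch(
    read.delim(path, header = FALSE, colClasses = "character"),
    error = function(e) stop("malformed refFlat file: ", conditionMessage(e)))
  if (ncol(df) < 6)
    stop("malformed refFlat file: expected >= 6 tab-separated columns")
  df <- df[, seq_len(min(ncol(df), 11L))]
  names(df) <- cols[seq_len(ncol(df))]
  bad <- which(is.na(suppressWarnings(as.integer(df$start))) |
               is.na(suppressWarnings(as.integer(df$end))))
  if (length(bad))
    stop("malformed refFlat line ", bad[1], ": non-numeric txStart/txEnd")
  dt <- as.data.table(df)
  dt[, `:=`(start = as.integer(start), end = as.integer(end))]
  dt[, .(gene, tx, chrom, strand, start, end)]
}

read_bed12_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED12 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "BED")
  dt <- data.table(
    gene = as.character(gr$name), tx = as.character(gr$name),
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based closed
    end = BiocGenerics::end(gr))
  if (any(dt$strand == "*"))
    stop("BED12 record without strand: ", dt$gene[which(dt$strand == "*")[1]])
  dt
}

#' Read a known-polymorphism set (VCF or UCSC snp table)
#'
#' @param path Path to a VCF (`.vcf`, possibly gzipped) or a UCSC snpNNN-style
#'   table (tab-separated with `bin, chrom, chromStart, chromEnd, name, ...`
#'   columns, as in dbSNP dumps). The dialect is auto-detected from the
#'   extension/header.
#' @return An object of class `shm_known`: a keyed table of 0-based positions
#'   of known single-nucleotide polymorphisms, queried with [is_known()].
#'   Indel records are ignored; all alternate alleles of multi-allelic VCF
#'   records are registered.
#' @export
read_known_variants <- function(path) {
  if (!file.exists(path)) stop("known-variant file not found: ", path)
  head_lines <- readLines(path, n = 5L)
  if (grepl("\\.vcf(\\.gz)?$", path) || any(startsWith(head_lines, "##fileformat=VCF"))) {
    dt <- read_known_vcf(path)
  } else if (grepl("\\.(txt|tsv|bed)(\\.gz)?$", path) ||
             any(grepl("\tchr", head_lines, fixed = TRUE)) ||
             length(head_lines) == 0L) {
    dt <- read_known_ucsc(path)
  } else {
    stop("unrecognised known-variant dialect: ", path)
  }
  setkey(dt, chrom, pos)
  structure(list(sites = unique(dt)), class = "shm_known")
}

read_known_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  m <- vcfR::getFIX(v)
  if (is.null(dim(m))) m <- t(m)      # single-record VCFs drop to a vector
  fix <- as.data.table(m)
  if (nrow(fix) == 0L)
    return(data.table(chrom = character(0), pos = integer(0),
                      alt = character(0)))
  fix[, pos := as.integer(POS) - 1L]  # VCF is 1-based
  # expand multi-allelic ALT; keep SNV alleles only
  out <- fix[, .(alt = strsplit(ALT, ",", fixed = TRUE)[[1]]),
             by = .(chrom = CHROM, pos, REF)]
  out <- out[nchar(REF) == 1L & nchar(alt) == 1L & alt %in% c("A", "C", "G", "T")]
  out[, .(chrom, pos, alt)]
}

read_known_ucsc <- function(path) {
  df <- tryCatch(read.delim(path, header = FALSE, comment.char = "#",
                            colClasses = "character"),
                 error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L)
    return(data.table(chrom = character(0), pos = integer(0),
                      alt = character(0)))
  if (ncol(df) < 3) stop("unrecognised known-variant dialect: ", path)
  # UCSC snp tables carry a leading numeric bin column; tolerate its absence
  off <- if (grepl("^[0-9]+$", df[1, 1]) && ncol(df) >= 4) 1L else 0L
  dt <- data.table(chrom = df[[off + 1L]],
                   pos = as.integer(df[[off + 2L]]),       # chromStart, 0-based
                   end = as.integer(df[[off + 3L]]))
  dt <- dt[end - pos == 1L]                                 # SNV class only
  dt[, .(chrom, pos, alt = NA_character_)]
}

#' Test membership in a known-variant set
#'
#' @param known An object from [read_known_variants()].
#' @param chrom,pos Vectors of chromosome names and 0-based positions.
#' @param alt Optional alternate alleles for allele-aware matching; by default
#'   matching is position-level (any allele at the site counts).
#' @return Logical vector.
#' @export
is_known <- function(known, chrom, pos, alt = NULL) {
  stopifnot(inherits(known, "shm_known"))
  q <- data.table(chrom = chrom, pos = as.integer(pos))
  hit <- !is.na(known$sites[q, on = c("chrom", "pos"), mult = "first", which = TRUE])
  if (!is.null(alt)) {
    qa <- data.table(chrom = chrom, pos = as.integer(pos), alt = alt)
    hit_a <- !is.na(known$sites[qa, on = c("chrom", "pos", "alt"),
                                mult = "first", which = TRUE])
    # records without allele information fall back to position-level matching
    anon <- !is.na(known$sites[q, on = c("chrom", "pos"), mult = "first",
                               which = TRUE]) &
            is.na(known$sites[q, on = c("chrom", "pos"), mult = "first"]$alt)
    hit <- hit_a | (hit & anon)
  }
  hit
}

#' @export
print.shm_known <- function(x, ...) {
  cat("shm_known:", nrow(x$sites), "known variant site(s)\n")
  invisible(x)
}

#' Read uniquely aligned reads from SAM/BAM
#'
#' @param path Coordinate-sorted SAM or BAM file. SAM input is converted to
#'   BAM on the fly (via [Rsamtools::asBam()]).
#' @param min_mapq Minimum mapping quality for a read to count as uniquely
#'   aligned (default 1, i.e. MAPQ-0 multi-mappers are dropped).
#' @return A [data.table::data.table] with one row per retained read:
#'   `qname`, `chrom`, `strand`, `pos0` (0-based leftmost aligned position),
#'   `mapq`, `cigar`, `seq`, `qual` (raw ASCII quality string), `rlen`,
#'   `five_prime` (0-based 5' alignment start used as the clonality key) and
#'   `mean_qual` (mean raw ASCII quality).
#' @export
read_alignments <- function(path, min_mapq = 1L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    # SAM text is line-oriented TSV; fread the 11 mandatory columns
    hdr <- readLines(path, n = 10000L)
    n_hdr <- sum(cumprod(startsWith(hdr, "@")))
    if (n_hdr == length(hdr)) stop("SAM header longer than 10000 lines: ", path)
    raw <- fread(path, skip = n_hdr, header = FALSE, sep = "\t",
                 fill = TRUE, quote = "", select = 1:11,
                 colClasses = list(character = c(1, 3, 6, 10, 11)))
    setnames(raw, c("qname", "flag", "chrom", "pos1", "mapq", "cigar",
                    "rnext", "pnext", "tlen", "seq", "qual"))
    raw <- raw[bitwAnd(flag, 4L) == 0L]          # drop unmapped
    dt <- raw[, .(qname, chrom,
                  strand = fifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
                  pos0 = pos1 - 1L, mapq = as.integer(mapq), cigar,
                  seq, qual)]
  } else {
    res <- Rsamtools::scanBam(
      path,
      param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "strand", "pos", "mapq",
                 "cigar", "seq", "qual"),
        flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
    dt <- data.table(
      qname = res$qname,
      chrom = as.character(res$rname),
      strand = as.character(res$strand),
      pos0 = res$pos - 1L,
      mapq = res$mapq,
      cigar = res$cigar,
      seq = as.character(res$seq),
      qual = as.character(res$qual))
  }
  dt <- dt[is.na(mapq) | mapq >= min_mapq]
  dt[, rlen := nchar(seq)]
  # raw ASCII mean quality; scanBam returns the original quality characters
  qdt <- data.table(
    grp = rep.int(seq_len(nrow(dt)), dt$rlen),
    q = as.integer(charToRaw(paste0(dt$qual, collapse = ""))))
  dt[, mean_qual := qdt[, mean(q), by = grp]$V1]
  refw <- cigar_ref_width(dt$cigar)
  dt[, five_prime := fifelse(strand == "+", pos0, pos0 + refw - 1L)]
  dt[]
}

#' Write browser tracks for annotated SNV calls
#'
#' Writes three BED files partitioning the calls: known SNVs, novel SNVs and
#' SHM-context SNVs (novel calls whose position is a mutable base of an AID
#' motif). Intervals are single-base, 0-based half-open; the name field is
#' `ref>alt`.
#'
#' @param calls Annotated call table (see [annotate_calls()]).
#' @param out_prefix Output path prefix; `<prefix>.known.bed`,
#'   `<prefix>.novel.bed` and `<prefix>.shm.bed` are created.
#' @return Invisibly, the three file paths.
#' @export
write_snv_tracks <- function(calls, out_prefix) {
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("unwritable path: ", dir)
  paths <- paste0(out_prefix, c(".known.bed", ".novel.bed", ".shm.bed"))
  sel <- list(
    calls[novel == FALSE],
    calls[novel == TRUE],
    calls[novel == TRUE & (shm_context_rgyw | shm_context_wa)])
  for (i in seq_along(paths)) {
    bed <- sel[[i]][, .(chrom, start = pos, end = pos + 1L,
                        name = paste0(ref, ">", alt))]
    fwrite(bed, paths[i], sep = "\t", col.names = FALSE)
  }
  invisible(setNames(paths, c("known", "novel", "shm")))
}

#' Write the SNV call table as TSV
#'
#' Positions are written 1-based (column `pos1`) for display; all other
#' columns are verbatim.
#'
#' @param calls Call table.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_snv_table <- function(calls, path) {
  out <- copy(calls)
  out[, pos1 := pos + 1L]
  keep <- intersect(
    c("chrom", "pos1", "ref", "alt", "n", "k", "ratio", "pvalue", "qvalue",
      "mean_ref_qual", "mean_alt_qual", "quality_ttest_p", "called",
      "high_confidence", "novel", "promoter", "gene",
      "shm_context_rgyw", "shm_context_wa"),
    names(out))
  fwrite(out[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}
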