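# Clonal-read deduplication, the experiment-wide per-cycle error profile and
# per-site pileups.
#
# The error profile is indexed by sequencing cycle, not genomic orientation:
# Illumina error rates are a property of the cycle, so for reverse-strand
# alignments the aligned query offset is mirrored (cycle = L - 1 - offset)
# before counting. SEQ/QUAL in SAM records are stored in reference
# orientation, which is why the mirroring is needed at all.
#
# Expanded per-base tables carry bases as integer ASCII codes (A=65, C=67,
# G=71, T=84) so that no per-base string work is done on the hot path.

BASE_CODES <- c(A = 65L, C = 67L, G = 71L, T = 84L)
N_CODE <- 78L

code_to_base <- function(code) {
  c("A", "C", "G", "T")[match(code, BASE_CODES)]
}

#' Collapse clonal reads
#'
#' Reads sharing chromosome, 5' alignment start and strand are presumed PCR
#' duplicates; the one with the highest mean base quality is retained (ties:
#' first encountered in file order).
#'
#' @param reads Read table from [read_alignments()], coordinate-sorted.
#' @return The deduplicated read table, original order preserved.
#' @export
deduplicate_reads <- function(reads) {
  stopifnot(is.data.table(reads))
  if (nrow(reads) == 0L) return(copy(reads))
  unsorted <- reads[, any(diff(pos0) < 0L), by = chrom][V1 == TRUE]
  if (nrow(unsorted))
    stop("input reads are not coordinate-sorted (chromosome ",
         unsorted$chrom[1], ")")
  idx <- reads[, .I[which.max(mean_qual)], by = .(chrom, five_prime, strand)]$V1
  reads[sort(idx)]
}

# Expand alignments to one row per aligned (M/=/X) base.
# Columns: rid, chrom, rpos (0-based reference), qoff (0-based query offset,
# reference orientation), cycle (0-based sequencing cycle), base (ASCII
# code), qual (raw ASCII integer), is_mm. Soft-clipped bases and indels
# never appear.
expand_alignments <- function(reads, genome) {
  simple <- grepl("^[0-9]+M$", reads$cigar)
  if (all(simple)) {
    r <- reads
    rid <- rep.int(seq_len(nrow(r)), r$rlen)
    qoff <- sequence(r$rlen) - 1L
    rpos <- rep.int(r$pos0, r$rlen) + qoff
    base <- as.integer(charToRaw(paste0(r$seq, collapse = "")))
    qual <- as.integer(charToRaw(paste0(r$qual, collapse = "")))
  } else {
    parts <- list()
    if (any(simple)) {
      r <- reads[simple]
      qo <- sequence(r$rlen) - 1L
      parts[[1L]] <- data.table(
        rid = rep.int(which(simple), r$rlen),
        rpos = rep.int(r$pos0, r$rlen) + qo,
        qoff = qo,
        base = as.integer(charToRaw(paste0(r$seq, collapse = ""))),
        qual = as.integer(charToRaw(paste0(r$qual, collapse = ""))))
    }
    r <- reads[!simple]
    parsed <- parse_cigar(r$cigar)
    lst <- vector("list", nrow(r))
    for (j in seq_len(nrow(r))) {
      pr <- cigar_aligned_pairs(parsed[[j]]$len, parsed[[j]]$op)
      sq <- as.integer(charToRaw(r$seq[j]))
      qu <- as.integer(charToRaw(r$qual[j]))
      lst[[j]] <- data.table(
        rid = which(!simple)[j],
        rpos = r$pos0[j] + pr$roff,
        qoff = pr$qoff,
        base = sq[pr$qoff + 1L],
        qual = qu[pr$qoff + 1L])
    }
    parts[[length(parts) + 1L]] <- rbindlist(lst)
    dt <- rbindlist(parts)
    setorder(dt, rid, qoff)
    rid <- dt$rid; qoff <- dt$qoff; rpos <- dt$rpos
    base <- dt$base; qual <- dt$qual
  }
  # sequencing cycle: mirror the query offset for reverse-strand alignments
  rl <- reads$rlen[rid]
  cycle <- qoff
  minus <- reads$strand[rid] == "-"
  cycle[minus] <- rl[minus] - 1L - qoff[minus]
  chromv <- reads$chrom[rid]
  is_mm <- logical(length(rid))
  for (ch in unique(reads$chrom)) {
    rawv <- genome$raw[[ch]]
    if (is.null(rawv)) stop("reads aligned to unknown chromosome: ", ch)
    gi <- as.integer(rawv)
    i <- which(chromv == ch)
    refc <- gi[rpos[i] + 1L]
    is_mm[i] <- base[i] != refc & refc != N_CODE & base[i] != N_CODE
  }
  data.table(rid = rid, chrom = chromv, rpos = rpos, qoff = qoff,
             cycle = cycle, base = base, qual = qual, is_mm = is_mm)
}

#' Build the experiment-wide sequencing error profile
#'
#' For each sequencing cycle i (0-based), the mismatch rate is
#' `p_i = (reads mismatching the reference at cycle i) / (reads with length > i)`,
#' counted over all uniquely aligned, deduplicated reads of the experiment.
#' The derived weights `w_i = p_i / (1 - p_i)` feed the Poisson-Binomial
#' site test.
#'
#' @param reads Deduplicated read table.
#' @param genome An `shm_genome` from [read_genome()].
#' @param bases Optional pre-computed per-base expansion of `reads`
#'   (internal; avoids expanding twice in the pipeline).
#' @return An object of class `shm_error_profile`: list with `p`, `w`,
#'   `mismatch_counts`, `reads_at_cycle` (denominators), `total_reads`,
#'   `read_length`.
#' @export
build_error_profile <- function(reads, genome, bases = NULL) {
  if (nrow(reads) == 0L) stop("cannot build an error profile from zero reads")
  if (is.null(bases)) bases <- expand_alignments(reads, genome)
  L <- max(reads$rlen)
  mm <- integer(L)
  tab <- bases[is_mm == TRUE, .N, by = cycle]
  mm[tab$cycle + 1L] <- tab$N
  denom <- vapply(seq_len(L) - 1L, function(i) sum(reads$rlen > i), 0L)
  p <- ifelse(denom > 0L, mm / denom, 0)
  if (any(p >= 1))
    stop("mismatch rate of 1 at cycle ", which(p >= 1)[1] - 1L,
         "; input alignments look corrupt (wrong reference?)")
  structure(
    list(p = p, w = p / (1 - p), mismatch_counts = mm,
         reads_at_cycle = denom, total_reads = nrow(reads), read_length = L),
    class = "shm_error_profile")
}

#' @export
print.shm_error_profile <- function(x, ...) {
  cat("shm_error_profile:", x$total_reads, "reads, length", x$read_length,
      sprintf("; p in [%.2g, %.2g]\n", min(x$p), max(x$p)))
  invisible(x)
}

#' Write / read a cached error profile (TSV)
#'
#' @param profile An `shm_error_profile`.
#' @param path TSV path (`cycle`, `mismatches`, `reads`, `p`).
#' @return Invisibly `path`, resp. the profile.
#' @export
write_error_profile <- function(profile, path) {
  fwrite(data.table(cycle = seq_along(profile$p) - 1L,
                    mismatches = profile$mismatch_counts,
                    reads = profile$reads_at_cycle,
                    p = profile$p),
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_error_profile
#' @export
read_error_profile <- function(path) {
  dt <- fread(path)
  p <- dt$p
  structure(
    list(p = p, w = p / (1 - p), mismatch_counts = dt$mismatches,
         reads_at_cycle = dt$reads, total_reads = max(dt$reads),
         read_length = nrow(dt)),
    class = "shm_error_profile")
}

#' Per-site pileup over regions of interest
#'
#' Builds one record per covered position inside the supplied windows,
#' restricted to aligned (M/=/X) bases of deduplicated reads. `k` counts all
#' reads mismatching the reference; the reported alternate base is the modal
#' non-reference base (ties broken A < C < G < T). Positions whose reference
#' base is N are skipped. Quality summaries (`mean_ref_qual`,
#' `mean_alt_qual`) and per-read detail are carried for the scorable sites
#' (`n >= min_depth`, `k >= 1`).
#'
#' @param reads Deduplicated read table.
#' @param genome An `shm_genome`.
#' @param windows Promoter-window table ([promoter_windows()]); only
#'   positions inside a window are piled up.
#' @param min_depth Depth floor used to mark coverage and to decide which
#'   sites carry per-read detail for scoring (default 4).
#' @param min_base_quality Optional raw-ASCII quality floor; bases below it
#'   are excluded (default `NULL`, no floor).
#' @param bases Optional pre-computed per-base expansion (internal).
#' @return An object of class `shm_pileup`: list with
#'   `sites` (data.table `chrom, pos, ref, n, k, alt, alt_n, mean_ref_qual,
#'   mean_alt_qual`) and `detail` (per-read rows `chrom, pos, cycle, qual,
#'   base, is_mm` for scorable sites), plus `min_depth`.
#' @export
pileup_sites <- function(reads, genome, windows, min_depth = 4L,
                         min_base_quality = NULL, bases = NULL) {
  stopifnot(nrow(windows) >= 1L)
  if (any(windows$end <= windows$start)) stop("degenerate window")
  if (is.null(bases)) bases <- expand_alignments(reads, genome)
  if (!is.null(min_base_quality)) bases <- bases[qual >= min_base_quality]
  wid <- assign_window(bases$chrom, bases$rpos, windows)
  bases <- bases[!is.na(wid)]
  sites <- bases[, .(n = .N, k = sum(is_mm)), by = .(chrom, pos = rpos)]
  setkey(sites, chrom, pos)
  # reference base per site; N sites are skipped
  refc <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    refc[i] <- as.integer(genome$raw[[ch]])[sites$pos[i] + 1L]
  }
  sites[, ref := code_to_base(refc)]
  sites <- sites[!is.na(ref)]
  # modal alternate base among mismatching reads (tie-break A < C < G < T)
  mm <- bases[is_mm == TRUE, .(cnt = .N), by = .(chrom, pos = rpos, base)]
  setorder(mm, chrom, pos, -cnt, base)
  alt1 <- unique(mm, by = c("chrom", "pos"))
  sites[, `:=`(alt = NA_character_, alt_n = 0L)]
  sites[alt1, on = c("chrom", "pos"),
        `:=`(alt = code_to_base(i.base), alt_n = i.cnt)]
  # per-read detail and quality summaries for scorable sites
  scored <- sites[n >= min_depth & k >= 1L, .(chrom, pos, alt)]
  sites[, `:=`(mean_ref_qual = NA_real_, mean_alt_qual = NA_real_)]
  if (nrow(scored)) {
    detail <- bases[scored, on = c("chrom", rpos = "pos"),
                    .(chrom, pos = rpos, cycle, qual, base, is_mm,
                      alt_code = BASE_CODES[i.alt])]
    mq <- detail[, .(
      mrq = if (any(!is_mm)) mean(qual[!is_mm]) else NA_real_,
      maq = if (any(is_mm & base == alt_code))
              mean(qual[is_mm & base == alt_code]) else NA_real_),
      by = .(chrom, pos)]
    sites[mq, on = c("chrom", "pos"),
          `:=`(mean_ref_qual = i.mrq, mean_alt_qual = i.maq)]
    detail[, alt_code := NULL]
  } else {
    detail <- data.table(chrom = character(0), pos = integer(0),
                         cycle = integer(0), qual = integer(0),
                         base = integer(0), is_mm = logical(0))
  }
  structure(list(sites = sites[], detail = detail, min_depth = min_depth),
            class = "shm_pileup")
}

#' @export
print.shm_pileup <- function(x, ...) {
  cat("shm_pileup:", nrow(x$sites), "covered site(s),",
      nrow(x$sites[n >= x$min_depth & k >= 1L]), "scorable\n")
  invisible(x)
}

#' Positions covered at or above the depth floor
#'
#' @param pileup An `shm_pileup`.
#' @param windows Window table; coverage is reported per window row.
#' @return data.table `wid, chrom, pos` of covered positions.
#' @export
covered_positions <- function(pileup, windows) {
  s <- pileup$sites[n >= pileup$min_depth]
  wid <- assign_window(s$chrom, s$pos, windows)
  data.table(wid = wid, chrom = s$chrom, pos = s$pos)[!is.na(wid)]
}
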