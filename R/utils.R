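# Internal helpers. All coordinates inside the package are 0-based, half-open;
# conversion to/from 1-based conventions (SAM, VCF, display) happens at I/O
# boundaries only.

#' @import data.table
#' @importFrom stats p.adjust ppois rpois runif sd t.test setNames
#' @importFrom utils read.delim write.table packageVersion head tail
#' @importFrom BiocGenerics start end
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", "chrom", "pos", "pos0", "strand", "rid", "qoff", "cycle",
  "rpos", "base", "qual", "is_mm", "ref", "alt", "n", "k", "rlen", "mapq",
  "mean_qual", "five_prime", "gene", "tss", "start", "end", "enriched",
  "wid", "site_id", "ratio", "pvalue", "qvalue", "novel", "promoter",
  "high_confidence", "called", "shm_context_rgyw", "shm_context_wa",
  "k_gene", "motif_class", "reads", "i.gene", "i.strand", "i.tss",
  "i.enriched", "i.wid", "xid", "yid", "af", "type", "mean_ref_qual",
  "mean_alt_qual", "quality_ttest_p", "downstream", "is_hotspot", "seqname",
  "V1", "POS", "ALT", "REF", "CHROM", "pos1", "tx", "transcripts",
  "maq", "i.maq", "aA", "aC", "aG", "aT", "lambda", "lo", "hi", "qname",
  "grp", "q"
))

#' Load a reference genome from FASTA
#'
#' Reads a (uncompressed or bgzipped) FASTA file and returns an accessor
#' object that supports both fast per-base lookup and motif scanning.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `shm_genome`: a list with elements `seqs`
#'   (a [Biostrings::DNAStringSet]), `raw` (per-chromosome raw byte vectors
#'   for O(1) base lookup) and `lens` (named integer chromosome lengths).
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  raw <- lapply(seq_along(seqs),
                function(i) charToRaw(toupper(as.character(seqs[[i]]))))
  names(raw) <- names(seqs)
  structure(
    list(seqs = seqs, raw = raw,
         lens = setNames(Biostrings::width(seqs), names(seqs))),
    class = "shm_genome"
  )
}

#' @export
print.shm_genome <- function(x, ...) {
  cat("shm_genome:", length(x$lens), "sequence(s),",
      format(sum(as.numeric(x$lens)), big.mark = ","), "bp total\n")
  invisible(x)
}

# reference bases (as uppercase characters) at 0-based positions
ref_base <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    rawv <- genome$raw[[ch]]
    if (is.null(rawv)) stop("chromosome not in genome: ", ch)
    out[i] <- strsplit(toupper(rawToChar(rawv[pos[i] + 1L])), "")[[1]]
  }
  out
}

# ---- CIGAR ------------------------------------------------------------------

# split CIGAR strings into per-read integer lengths and op characters
parse_cigar <- function(cigars) {
  lens <- regmatches(cigars, gregexpr("[0-9]+", cigars))
  ops  <- regmatches(cigars, gregexpr("[MIDNSHP=X]", cigars))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# reference-space width consumed by each CIGAR (M/=/X/D/N)
cigar_ref_width <- function(cigars) {
  w <- integer(length(cigars))
  simple <- grepl("^[0-9]+M$", cigars)
  w[simple] <- as.integer(sub("M$", "", cigars[simple]))
  if (any(!simple)) {
    parsed <- parse_cigar(cigars[!simple])
    w[!simple] <- vapply(parsed, function(p)
      sum(p$len[p$op %in% c("M", "=", "X", "D", "N")]), 0L)
  }
  w
}

# For one read, 0-based (query offset, reference offset) pairs of aligned
# (M/=/X) bases; insertions/soft clips consume query only, D/N reference only.
cigar_aligned_pairs <- function(len, op) {
  q <- 0L; r <- 0L
  qo <- integer(0); ro <- integer(0)
  for (j in seq_along(op)) {
    l <- len[j]
    switch(op[j],
      M = , `=` = , X = {
        qo <- c(qo, q + seq_len(l) - 1L)
        ro <- c(ro, r + seq_len(l) - 1L)
        q <- q + l; r <- r + l
      },
      I = , S = { q <- q + l },
      D = , N = { r <- r + l },
      H = , P = NULL,
      stop("unsupported CIGAR op: ", op[j])
    )
  }
  list(qoff = qo, roff = ro)
}

# ---- window assignment ------------------------------------------------------

# Map 0-based positions to window row indices (NA when outside every window).
# Windows may overlap; ties return the first overlapping window and
# `all = TRUE` returns the full many-to-many mapping instead. When windows
# are pairwise disjoint (the common case) a findInterval fast path is used.
assign_window <- function(chrom, pos, windows, all = FALSE) {
  stopifnot(is.data.table(windows))
  w <- copy(windows)[, wid := .I]
  if (!all) {
    disjoint <- w[, {
      o <- order(start)
      .(ok = !anyDuplicated(start[o]) &&
             all(head(cummax(end[o]), -1L) <= start[o][-1L]))
    }, by = chrom][, all(ok)]
    if (isTRUE(disjoint)) {
      res <- rep(NA_integer_, length(pos))
      for (ch in unique(w$chrom)) {
        ws <- w[chrom == ch][order(start)]
        i <- which(chrom == ch)
        fi <- findInterval(pos[i], ws$start)
        ok <- fi > 0L
        ok[ok] <- pos[i][ok] < ws$end[fi[ok]]
        res[i[ok]] <- ws$wid[fi[ok]]
      }
      return(res)
    }
  }
  q <- data.table(chrom = chrom, start = pos, end = pos + 1L,
                  xid = seq_along(pos))
  wk <- w[, .(chrom, start, end, wid)]
  setkey(wk, chrom, start, end)
  ov <- foverlaps(q, wk, by.x = c("chrom", "start", "end"), nomatch = NA)
  if (all) return(ov[!is.na(wid), .(xid, wid)])
  ov[, wid[1L], by = xid][order(xid)]$V1
}

# uniform draw of a base different from `ref` (vectorised)
random_other_base <- function(ref) {
  bases <- c("A", "C", "G", "T")
  vapply(ref, function(b) sample(setdiff(bases, b), 1L), "", USE.NAMES = FALSE)
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}
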