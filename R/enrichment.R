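# Decide which promoter windows count as mark-enriched. The enriched set is
# the universe for every downstream per-gene statistic.

#' Flag mark-enriched promoter windows
#'
#' Three modes are offered, since peak calling proper is out of scope:
#' * `"min-reads"` (default): enriched iff at least `min_reads` deduplicated
#'   reads overlap the window.
#' * `"poisson-background"`: enriched iff the window's read count exceeds the
#'   genome-wide expectation `total_reads * width / genome_length` with a
#'   BH-adjusted Poisson upper-tail p-value at or below `fdr`.
#' * `"external-bed"`: enriched iff the window intersects any interval of a
#'   supplied peak BED (use a dedicated peak caller upstream).
#'
#' @param windows Window table from [promoter_windows()].
#' @param reads Deduplicated read table (ignored in `"external-bed"` mode).
#' @param mode One of `"min-reads"`, `"poisson-background"`, `"external-bed"`.
#' @param min_reads Threshold for `"min-reads"` (default 20).
#' @param fdr Adjusted-p threshold for `"poisson-background"` (default 0.05).
#' @param peaks_bed Path to a BED file of peaks (required in
#'   `"external-bed"` mode).
#' @param genome_length Total genome length for the background rate; by
#'   default the sum of chromosome lengths seen in `reads` is not available
#'   here, so pass it explicitly (e.g. `sum(genome$lens)`).
#' @return The window table with the `enriched` flag and a `reads` count
#'   column set.
#' @export
select_enriched <- function(windows,
                            reads = NULL,
                            mode = c("min-reads", "poisson-background",
                                     "external-bed"),
                            min_reads = 20L,
                            fdr = 0.05,
                            peaks_bed = NULL,
                            genome_length = NULL) {
  mode <- match.arg(mode)
  w <- copy(windows)[, wid := .I]
  if (mode == "external-bed") {
    if (is.null(peaks_bed)) stop("external-bed mode requires a peak BED file")
    if (!file.exists(peaks_bed)) stop("peak BED not found: ", peaks_bed)
    pk <- fread(peaks_bed, header = FALSE,
                col.names = c("chrom", "start", "end")[1:3],
                select = 1:3)
    w[, enriched := FALSE]
    if (nrow(pk)) {
      setkey(pk, chrom, start, end)
      ov <- foverlaps(w[, .(chrom, start, end, wid)], pk,
                      by.x = c("chrom", "start", "end"), nomatch = NULL)
      w[unique(ov$wid), enriched := TRUE]
    }
    w[, wid := NULL]
    return(w[])
  }
  stopifnot(is.data.table(reads))
  # read overlaps window iff [pos0, pos0 + refwidth) intersects [start, end)
  r <- data.table(chrom = reads$chrom, start = reads$pos0,
                  end = reads$pos0 + cigar_ref_width(reads$cigar))
  wk <- w[, .(chrom, start, end, wid)]
  setkey(wk, chrom, start, end)
  ov <- foverlaps(r, wk, by.x = c("chrom", "start", "end"), nomatch = NULL)
  cnt <- ov[, .N, by = wid]
  w[, reads := 0L]
  w[cnt$wid, reads := cnt$N]
  if (mode == "min-reads") {
    w[, enriched := reads >= min_reads]
  } else {
    if (is.null(genome_length))
      stop("poisson-background mode requires genome_length")
    lambda <- nrow(r) * (w$end - w$start) / genome_length
    pv <- ppois(w$reads - 1L, lambda, lower.tail = FALSE)
    w[, enriched := bh_adjust(pv) <= fdr & reads > 0L]
  }
  w[, wid := NULL]
  w[]
}
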