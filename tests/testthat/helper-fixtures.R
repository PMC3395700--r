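# Fixture builders: everything is generated in code at test time.

library(data.table)

# quality string: n copies of Phred q at the given encoding offset
qstr <- function(q, n, offset = 64L) strrep(rawToChar(as.raw(q + offset)), n)

# write a FASTA with one chromosome and load it back
mini_genome <- function(seqstr, chrom = "chrT") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", chrom), seqstr), fa)
  read_genome(fa)
}

# write a minimal SAM file; recs is a data.frame with columns
# qname, flag, pos1, mapq, cigar, seq, qual
write_test_sam <- function(recs, chrom = "chrT", chrlen = 100000L,
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  recs$qname, recs$flag, chrom, recs$pos1, recs$mapq,
                  recs$cigar, recs$seq, recs$qual)
  writeLines(c(hdr, body), path)
  path
}

# minimal refFlat writer
write_test_refflat <- function(rows, path = tempfile(fileext = ".refFlat")) {
  lines <- vapply(rows, function(r)
    paste(r$gene, r$tx, r$chrom, r$strand, r$txStart, r$txEnd,
          r$txStart, r$txEnd, 1L, paste0(r$txStart, ","),
          paste0(r$txEnd, ","), sep = "\t"), "")
  writeLines(lines, path)
  path
}

# minimal VCF writer
write_test_vcf <- function(rows, chrom = "chrS", chrlen = 100000L,
                           path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", chrom, chrlen),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(rows, function(r)
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", r$chrom, r$pos1, r$ref, r$alt), "")
  writeLines(c(hdr, body), path)
  path
}

# cache expensive simulated fixtures across test files (one R process)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

# a small complete experiment with two seeded hotspot genes, used by
# several test files
small_experiment <- function() {
  cached_fixture("small_experiment", {
    cfg <- sim_config(
      seed = 11L, n_genes = 40L, mean_depth = 30,
      planted_hotspots = data.frame(gene = c("G001", "G002", "G003"),
                                    n_shm = 6L, motif_class = "RGYW",
                                    af = 0.5),
      planted_scattered = data.frame(gene = c("G010", "G011"),
                                     n_snv = c(2L, 1L), af = 0.5))
    dir <- file.path(tempdir(), "shmscan_small_exp")
    sim <- simulate_experiment(cfg, dir)
    out <- file.path(tempdir(), "shmscan_small_out")
    res <- run_pipeline(sim$paths[["genome"]], sim$paths[["reads"]],
                        sim$paths[["genes"]], sim$paths[["known"]],
                        outdir = out, config = shm_config(seed = 11L))
    list(cfg = cfg, sim = sim, res = res, out = out)
  })
}
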