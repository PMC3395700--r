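# Deduplication, error profile and pileup on hand-built alignments against
# a hand-built reference.

# reference: 100 kb of repeated ACGT (so base at 0-based pos p is
# c("A","C","G","T")[p %% 4 + 1])
ref_str <- strrep("ACGT", 25000)
ref_genome <- function() cached_fixture("acgt_genome", mini_genome(ref_str))

read_at <- function(pos0, len = 12L, qname = "r", flag = 0L, mapq = 60L,
                    q = 35L, mutate_at = integer(0), mutate_to = "T") {
  seq <- substr(ref_str, pos0 + 1L, pos0 + len)
  if (length(mutate_at)) {
    s <- strsplit(seq, "")[[1]]
    s[mutate_at + 1L] <- mutate_to
    seq <- paste(s, collapse = "")
  }
  data.frame(qname = qname, flag = flag, pos1 = pos0 + 1L, mapq = mapq,
             cigar = paste0(len, "M"), seq = seq, qual = qstr(q, len))
}

test_that("deduplication keeps one read per (chrom, 5' start, strand)", {
  recs <- rbind(
    read_at(100L, qname = "a1", q = 30L),
    read_at(100L, qname = "a2", q = 38L),      # same start, higher quality
    read_at(100L, qname = "b", flag = 16L),    # same pos, minus strand
    read_at(200L, qname = "c1"),
    read_at(300L, qname = "c2"))
  reads <- read_alignments(write_test_sam(recs))
  dd <- deduplicate_reads(reads)
  expect_equal(sort(dd$qname), c("a2", "b", "c1", "c2"))
  # idempotent
  expect_equal(deduplicate_reads(dd), dd)
  # all-distinct input is untouched
  solo <- read_alignments(write_test_sam(rbind(
    read_at(10L, qname = "x"), read_at(20L, qname = "y"),
    read_at(30L, qname = "z"))))
  expect_equal(nrow(deduplicate_reads(solo)), 3L)
})

test_that("reverse-strand reads with the same 5' end are clonal", {
  # minus-strand clones share the *rightmost* aligned base: starts differ
  # but pos0 + len - 1 coincides only when starts coincide for equal
  # lengths, so use different lengths
  recs <- rbind(
    read_at(100L, len = 12L, qname = "m1", flag = 16L, q = 30L),
    read_at(102L, len = 10L, qname = "m2", flag = 16L, q = 38L))
  reads <- read_alignments(write_test_sam(recs))
  expect_equal(unique(reads$five_prime), 111L)
  dd <- deduplicate_reads(reads)
  expect_equal(dd$qname, "m2")
})

test_that("unsorted input is a hard error", {
  recs <- rbind(read_at(500L, qname = "a"), read_at(100L, qname = "b"))
  path <- write_test_sam(recs)
  reads <- read_alignments(path)
  expect_error(deduplicate_reads(reads), "sorted")
})

test_that("error profile counts mismatches per sequencing cycle", {
  genome <- ref_genome()
  clean <- lapply(0:9, function(i) read_at(i * 50L, qname = paste0("c", i)))
  reads <- deduplicate_reads(read_alignments(write_test_sam(do.call(rbind, clean))))
  prof <- build_error_profile(reads, genome)
  expect_equal(prof$p, rep(0, 12))
  expect_equal(prof$w, rep(0, 12))
  expect_equal(prof$total_reads, 10L)

  # 2 of 10 reads mismatch at cycle 5 -> p_5 = 0.2, w_5 = 0.25
  recs <- do.call(rbind, c(
    lapply(0:7, function(i) read_at(i * 50L, qname = paste0("c", i))),
    list(read_at(400L, qname = "m1", mutate_at = 5L),   # ref C -> T
         read_at(448L, qname = "m2", mutate_at = 5L)))) # ref C -> T
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  prof <- build_error_profile(reads, genome)
  expect_equal(prof$p[6], 0.2)
  expect_equal(prof$w[6], 0.25)
  expect_equal(sum(prof$mismatch_counts), 2L)

  # 1 of 4 reads with a mismatch at cycle 0 -> p_0 = 0.25
  recs <- do.call(rbind, c(
    lapply(1:3, function(i) read_at(i * 50L, qname = paste0("c", i))),
    list(read_at(200L, qname = "m", mutate_at = 0L, mutate_to = "G"))))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  prof <- build_error_profile(reads, genome)
  expect_equal(prof$p[1], 0.25)
})

test_that("reverse-strand mismatch cycles are mirrored to sequencing order", {
  genome <- ref_genome()
  # minus-strand read, mismatch at query offset 0 (reference orientation)
  # = sequencing cycle L - 1
  recs <- rbind(
    read_at(100L, qname = "p1"),
    read_at(150L, qname = "p2"),
    read_at(200L, qname = "m", flag = 16L, mutate_at = 0L, mutate_to = "G"),
    read_at(250L, qname = "p3"))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  prof <- build_error_profile(reads, genome)
  expect_equal(prof$mismatch_counts[12], 1L)
  expect_equal(sum(prof$mismatch_counts), 1L)
})

test_that("mixed read lengths use length-aware denominators", {
  genome <- ref_genome()
  recs <- rbind(read_at(100L, len = 12L, qname = "long1"),
                read_at(150L, len = 12L, qname = "long2"),
                read_at(200L, len = 8L, qname = "short",
                        mutate_at = 7L, mutate_to = "A"))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  prof <- build_error_profile(reads, genome)
  expect_equal(prof$read_length, 12L)
  expect_equal(prof$reads_at_cycle, c(rep(3L, 8), rep(2L, 4)))
  expect_equal(prof$p[8], 1 / 3)
})

test_that("degenerate profiles are hard errors", {
  genome <- ref_genome()
  expect_error(build_error_profile(data.table(), genome), "zero reads")
  # every read mismatches at cycle 3 (ref T at both sites) -> p_3 = 1
  recs <- rbind(read_at(100L, qname = "a", mutate_at = 3L, mutate_to = "C"),
                read_at(152L, qname = "b", mutate_at = 3L, mutate_to = "C"))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  expect_error(build_error_profile(reads, genome), "cycle 3")
})

test_that("pileup reports depth, mismatch count and modal alternate", {
  genome <- ref_genome()
  windows <- data.table(gene = "G", chrom = "chrT", strand = "+",
                        tss = 150L, start = 0L, end = 2000L, enriched = TRUE)
  # position 104 (ref A): reads a1,a2 match; g1,g2,g3 carry G
  recs <- rbind(
    read_at(100L, qname = "a1"), read_at(101L, qname = "a2"),
    read_at(102L, qname = "g1", mutate_at = 2L, mutate_to = "G"),
    read_at(103L, qname = "g2", mutate_at = 1L, mutate_to = "G"),
    read_at(104L, qname = "g3", mutate_at = 0L, mutate_to = "G"))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  pu <- pileup_sites(reads, genome, windows)
  site <- pu$sites[pos == 104L]
  expect_equal(site$n, 5L)
  expect_equal(site$k, 3L)
  expect_equal(site$ref, "A")
  expect_equal(site$alt, "G")
  # clean position covered by 4 reads
  clean <- pu$sites[pos == 103L]
  expect_equal(clean$n, 4L)
  expect_equal(clean$k, 0L)
  expect_true(is.na(clean$alt))
})

test_that("tied alternate counts break A < C < G < T", {
  genome <- ref_genome()
  windows <- data.table(gene = "G", chrom = "chrT", strand = "+",
                        tss = 150L, start = 0L, end = 2000L, enriched = TRUE)
  # position 104 (ref A): one read C, one read T
  recs <- rbind(
    read_at(100L, qname = "c1", mutate_at = 4L, mutate_to = "C"),
    read_at(104L, qname = "t1", mutate_at = 0L, mutate_to = "T"))
  reads <- deduplicate_reads(read_alignments(write_test_sam(recs)))
  pu <- pileup_sites(reads, genome, windows)
  expect_equal(pu$sites[pos == 104L]$alt, "C")
})

test_that("sites on reference N are skipped and pileup respects windows", {
  genome <- mini_genome(paste0(strrep("ACGT", 50), "NNNN",
                               strrep("ACGT", 50)))
  windows <- data.table(gene = "G", chrom = "chrT", strand = "+",
                        tss = 200L, start = 0L, end = 300L, enriched = TRUE)
  recs <- read_at(198L, qname = "n1")  # spans the N block at 200..203
  reads <- read_alignments(write_test_sam(recs))
  pu <- pileup_sites(reads, genome, windows)
  expect_false(any(pu$sites$pos %in% 200:203))
  expect_true(all(pu$sites$pos %in% c(198:199, 204:209)))
  # a window restricted to [0, 200) drops the tail positions
  w2 <- data.table(gene = "G", chrom = "chrT", strand = "+",
                   tss = 100L, start = 0L, end = 200L, enriched = TRUE)
  pu2 <- pileup_sites(reads, genome, w2)
  expect_equal(sort(pu2$sites$pos), 198:199)
})

test_that("pileup mismatches are a subset of profile mismatches", {
  fx <- small_experiment()
  prof_mm <- sum(fx$res$profile$mismatch_counts)
  pile_mm <- sum(fx$res$pileup$sites$k)
  expect_lte(pile_mm, prof_mm)
  expect_gt(pile_mm, 0L)
})

test_that("indel and soft-clip bases never enter the pileup", {
  genome <- ref_genome()
  windows <- data.table(gene = "G", chrom = "chrT", strand = "+",
                        tss = 100L, start = 0L, end = 2000L, enriched = TRUE)
  # 4S8M: first 4 bases soft-clipped; 4M2I4M / 4M2D6M exercise indels
  recs <- data.frame(
    qname = c("s", "i", "d"), flag = 0L, pos1 = c(101L, 111L, 121L),
    mapq = 60L, cigar = c("4S8M", "4M2I4M", "4M2D6M"),
    seq = c(paste0("TTTT", substr(ref_str, 101L, 108L)),
            paste0(substr(ref_str, 111L, 114L), "TT",
                   substr(ref_str, 115L, 118L)),
            paste0(substr(ref_str, 121L, 124L),
                   substr(ref_str, 127L, 132L))),
    qual = c(qstr(35, 12), qstr(35, 10), qstr(35, 10)))
  reads <- read_alignments(write_test_sam(recs))
  pu <- pileup_sites(reads, genome, windows)
  expect_equal(pu$sites$k, rep(0L, nrow(pu$sites)))    # no false mismatches
  expect_equal(sort(pu$sites$pos),
               sort(c(100:107, 110:117, 120:123, 126:131)))
})
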