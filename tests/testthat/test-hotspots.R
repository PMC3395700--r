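# Motif scanning, the per-gene Poisson test, permutation z-scores and
# hotspot classification.

pad_genome <- function(core, pad = 30L) {
  # embed a short motif core in an A-homopolymer so no extra motifs appear
  # at the junctions (A runs only extend WA/TW context by design where the
  # core boundary is W anyway; tests account for that)
  mini_genome(paste0(strrep("C", pad), core, strrep("C", pad)))
}

window_over <- function(genome, start, end)
  data.table(gene = "G", chrom = "chrT", strand = "+",
             tss = as.integer(start), start = as.integer(start),
             end = as.integer(end), enriched = TRUE)

test_that("RGYW/WRCY and WA/TW mutable positions are found", {
  pad <- 30L
  g <- pad_genome("AGCT")  # RGYW: A-G-C-T, mutable G at offset 1
  hits <- scan_motifs(g, window_over(g, pad, pad + 4L))
  rgyw <- hits[motif_class == "RGYW"]
  expect_true((pad + 1L) %in% rgyw$pos)
  expect_equal(rgyw[pos == pad + 1L]$strand, "+")
  # AGCT is its own reverse complement: A-G-C-T also fits W-R-C-Y, so the
  # C is a mutable position of the same class on the other strand
  expect_true((pad + 2L) %in% rgyw$pos)
  expect_equal(rgyw[pos == pad + 2L]$strand, "-")

  g2 <- pad_genome("AACT")  # WRCY: A-A-C-T, mutable C at offset 2
  hits2 <- scan_motifs(g2, window_over(g2, pad, pad + 4L))
  rgyw2 <- hits2[motif_class == "RGYW"]
  expect_equal(rgyw2$pos, pad + 2L)
  expect_equal(rgyw2$strand, "-")

  g3 <- pad_genome("TA")    # WA hit at the A, TW hit at the T
  hits3 <- scan_motifs(g3, window_over(g3, pad, pad + 2L))
  wa <- hits3[motif_class == "WA"]
  expect_setequal(wa$pos, c(pad, pad + 1L))
  expect_equal(wa[pos == pad + 1L]$strand, "+")   # WA, mutable A
  expect_equal(wa[pos == pad]$strand, "-")        # TW, mutable T
})

test_that("motifs straddling the window boundary are still found", {
  pad <- 30L
  g <- pad_genome("AGCT")
  # window starts on the motif's C: the RGYW context begins 2 bp upstream
  hits <- scan_motifs(g, window_over(g, pad + 2L, pad + 10L))
  expect_false((pad + 1L) %in% hits$pos)  # mutable G is outside the window
  h2 <- scan_motifs(g, window_over(g, pad + 1L, pad + 10L))
  expect_true((pad + 1L) %in% h2[motif_class == "RGYW"]$pos)
})

test_that("one position counts once per motif class despite overlapping motifs", {
  # GGCT: offsets 0-3 = G-G-C-T; AGGCT contains AGGC? RGYW needs R-G-Y-W.
  # Use AGCTGCT-like overlap: AGCA GCT ... simpler: AGCTT has AGCT only;
  # craft TAGCTA where both TA and AG..A WA hits coexist with RGYW
  g <- pad_genome("AGCAGCT")
  w <- window_over(g, 30L, 37L)
  hits <- scan_motifs(g, w)
  expect_equal(anyDuplicated(hits[, .(pos, motif_class)]), 0L)
})

test_that("no motif spans an N base", {
  g <- mini_genome(paste0(strrep("C", 30), "AGNT", strrep("C", 30)))
  hits <- scan_motifs(g, window_over(g, 30L, 34L))
  expect_equal(nrow(hits), 0L)
})

test_that("mutable positions are strand-symmetric under reverse complement", {
  set.seed(21)
  for (i in 1:25) {
    len <- 400L
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    gf <- mini_genome(s); gr <- mini_genome(rc)
    hf <- scan_motifs(gf, window_over(gf, 0L, len))
    hr <- scan_motifs(gr, window_over(gr, 0L, len))
    for (cl in c("RGYW", "WA")) {
      expect_setequal(hf[motif_class == cl]$pos,
                      len - 1L - hr[motif_class == cl]$pos)
    }
  }
})

test_that("gene Poisson test matches the closed-form tail", {
  counts <- data.table(gene = c("a", "b", "c"), k_gene = c(0L, 3L, 3L))
  out <- gene_poisson_test(counts, n_enriched_windows = 10L,
                           total_snvs = 1L)     # lambda = 0.1
  expect_equal(out[gene == "a"]$pvalue, 1)
  closed <- 1 - exp(-0.1) * (1 + 0.1 + 0.1^2 / 2)
  expect_equal(out[gene == "b"]$pvalue, closed, tolerance = 1e-12)
  expect_equal(closed, 1.547e-4, tolerance = 1e-3)
  # zero-count genes are excluded from the BH family
  expect_true(is.na(out[gene == "a"]$qvalue))
  expect_equal(out[k_gene > 0]$qvalue,
               bh_stepup(out[k_gene > 0]$pvalue))
  expect_error(gene_poisson_test(counts, 0L), "enriched")
})

test_that("permutation z is calibrated against the hypergeometric null", {
  set.seed(9)
  covered <- 0:999
  mutable <- sample(covered, 100L)               # 10% mutable
  # all six SNVs on mutable positions: exp ~ 0.6, z >> 1
  snvs <- sample(mutable, 6L)
  mz <- permutation_z(covered, snvs, mutable, n_perm = 1000L)
  expect_equal(mz$obs, 6L)
  expect_equal(mz$exp, 0.6, tolerance = 0.15)
  expect_equal(mz$sd, 0.73, tolerance = 0.15)
  expect_gt(mz$z, 5)
  # obs at the null mean: |z| small
  null_snvs <- c(sample(mutable, 1L), sample(setdiff(covered, mutable), 9L))
  mz0 <- permutation_z(covered, null_snvs, mutable, n_perm = 1000L)
  expect_equal(mz0$obs, 1L)
  expect_lt(abs(mz0$z), 0.25)
})

test_that("degenerate permutation nulls follow the sign convention", {
  covered <- 0:9
  # every covered position mutable: all permutations equal k, sd = 0
  mz <- permutation_z(covered, c(1L, 2L), covered, n_perm = 200L)
  expect_equal(mz$sd, 0)
  expect_equal(mz$z, 0)
  expect_error(permutation_z(0:1, 0:2, 0:1), "fewer covered")
  expect_error(permutation_z(0:9, 100L, 0:9), "subset")
})

test_that("P(z > 1) under the uniform null approximates the normal tail", {
  set.seed(31)
  covered <- 0:3999
  mutable <- sample(covered, 1000L)   # 25%: the WA-class density scale
  k <- 50L
  hits <- replicate(300, {
    permutation_z(covered, sample(covered, k), mutable, n_perm = 400L)$z > 1
  })
  rate <- mean(hits)
  expect_lt(abs(rate - pnorm(-1)), 0.07)
})

test_that("seeded motif hotspots are recovered end to end", {
  fx <- small_experiment()
  hs <- fx$res$hotspots
  seeded <- c("G001", "G002", "G003")
  expect_true(all(seeded %in% hs$genes$gene))
  g <- hs$genes[gene %in% seeded]
  expect_true(all(g$k_gene >= 3L))
  expect_true(all(g$qvalue < 0.005))
  expect_true(all(g$z_rgyw > 1))
  expect_true(all(g$is_hotspot))
  expect_equal(g$ts + g$tv, g$k_gene)
  # planted SHMs are transitions, so Ts dominates
  expect_true(all(g$ts >= g$tv))
  # scattered-only genes with < 3 SNVs are never candidates
  expect_false("G011" %in% hs$genes$gene)
  # downstream counts respect gene strand and never exceed k
  expect_true(all(g$downstream <= g$k_gene))
})

test_that("uniform-position SNVs pass the motif gate no more than its own null admits", {
  # The z > 1 gate is discrete: its exact admission rate per gene and class
  # is a hypergeometric tail at the smallest integer count with z > 1.
  # Genes seeded with uniformly placed SNVs must not be classified as
  # motif-enriched more often than that analytic admission allows.
  set.seed(17)
  fx <- small_experiment()
  genome <- fx$sim$genome
  windows <- fx$sim$windows
  n_draw <- 40L
  admit <- numeric(0)
  flagged <- logical(0)
  for (i in 1:8) {
    w <- windows[i]
    covered <- w$start:(w$end - 1L)
    hits <- scan_motifs(genome, w)
    k <- 6L
    gate <- list()
    for (cl in c("RGYW", "WA")) {
      mut <- hits[motif_class == cl]$pos
      m <- sum(covered %in% mut)
      mz <- permutation_z(covered, sample(covered, k), mut, n_perm = 500L)
      thr <- ceiling(mz$exp + mz$sd + 1e-9)  # smallest obs with z > 1
      gate[[cl]] <- list(mut = mut,
                         adm = phyper(thr - 1L, m, length(covered) - m, k,
                                      lower.tail = FALSE),
                         thr = thr)
    }
    admit <- c(admit, min(1, gate$RGYW$adm + gate$WA$adm))  # union bound
    for (d in seq_len(n_draw %/% 8)) {
      snv <- sample(covered, k)
      zz <- vapply(c("RGYW", "WA"), function(cl)
        permutation_z(covered, snv, gate[[cl]]$mut, n_perm = 300L)$z, 0)
      flagged <- c(flagged, any(zz > 1))
    }
  }
  alpha <- mean(admit)
  rate <- mean(flagged)
  se <- sqrt(alpha * (1 - alpha) / length(flagged))
  expect_lte(rate, alpha + 3 * se + 0.05)
})

test_that("hotspot reports carry the Table-style schema", {
  fx <- small_experiment()
  prefix <- file.path(tempdir(), "report_test")
  paths <- write_hotspot_report(fx$res$hotspots, prefix)
  rep1 <- fread(paths[["hotspots"]])
  expect_true(all(c("gene", "snv_number", "p_bh", "z_rgyw", "z_wa",
                    "ts_tv") %in% names(rep1)))
  expect_match(rep1$snv_number[1], "^[0-9]+\\([0-9]+\\)$")
  expect_match(rep1$ts_tv[1], "^[0-9]+/[0-9]+$")
  snvs <- fread(paths[["snvs"]])
  expect_true(all(snvs$gene %in% rep1$gene))
  expect_true(any(snvs$shm_context_rgyw))
  # empty result set -> header-only files
  empty <- detect_hotspots(fx$res$calls[0L], fx$res$windows,
                           fx$sim$genome, fx$res$pileup)
  p0 <- write_hotspot_report(empty, file.path(tempdir(), "report_empty"))
  expect_equal(nrow(fread(p0[["hotspots"]])), 0L)
})
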